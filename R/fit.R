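# RNG hygiene: run code under a seed without disturbing the caller's stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Per-variant Wald ratios
#'
#' Each instrument's causal estimate is the ratio of its outcome and
#' exposure associations, `beta_out / beta_exp`, with first-order
#' (delta-method) standard error `se_out / |beta_exp|`; the exposure
#' standard error is deliberately ignored, the conventional first-order
#' approximation. Variants with `beta_exp == 0` have an undefined ratio
#' and are dropped with a message.
#'
#' @param data An `mr_data` from [harmonize()].
#' @return A data frame `snp`, `ratio`, `se`, `weight`
#'   (`weight = 1/se^2`), one row per usable instrument.
#' @export
wald_ratios <- function(data) {
  stopifnot(is.data.frame(data))
  zero <- !is.na(data$beta_exp) & data$beta_exp == 0
  if (any(zero)) {
    message(sprintf("dropping %d instrument(s) with zero exposure beta: %s",
                    sum(zero), paste(data$snp[zero], collapse = ", ")))
    data <- data[!zero, , drop = FALSE]
  }
  if (!nrow(data)) stop("undefined ratio: no instrument has nonzero exposure beta",
                        call. = FALSE)
  se <- data$se_out / abs(data$beta_exp)
  data.frame(snp = data$snp,
             ratio = data$beta_out / data$beta_exp,
             se = se,
             weight = 1 / se^2,
             stringsAsFactors = FALSE)
}

.mr_result <- function(method, beta, se, pvalue, n_snps, df = NA_integer_) {
  data.frame(method = method, beta = beta, se = se,
             ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
             pvalue = pvalue, n_snps = n_snps, df = df,
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted estimator
#'
#' Combines per-variant Wald ratios by inverse-variance weighting,
#' `beta = sum(w * ratio) / sum(w)` with `w = 1/se^2` — algebraically
#' the slope of a weighted through-origin regression of `beta_out` on
#' `beta_exp` with weights `1/se_out^2`. The `"fe"` (fixed-effect)
#' standard error is `sqrt(1/sum(w))`; the default `"mre"`
#' (multiplicative random effects) inflates it by the residual scale of
#' that regression, floored at 1, so heterogeneity widens but never
#' narrows the interval. The point estimate is identical between
#' variants. P-values use a normal reference.
#'
#' @param ratios A data frame from [wald_ratios()] (or an `mr_data`,
#'   which is converted).
#' @param variant `"mre"` (default) or `"fe"`.
#' @return A one-row result data frame (`method`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pvalue`, `n_snps`, `df`).
#' @export
mr_ivw <- function(ratios, variant = c("mre", "fe")) {
  variant <- match.arg(variant)
  if (inherits(ratios, "mr_data")) ratios <- wald_ratios(ratios)
  j <- nrow(ratios)
  if (j < 1L) stop("IVW needs at least one Wald ratio", call. = FALSE)
  if (variant == "mre" && j < 2L) {
    warning("single instrument: falling back to fixed-effect IVW")
    variant <- "fe"
  }
  w <- ratios$weight
  beta <- sum(w * ratios$ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  df <- NA_integer_
  if (variant == "mre") {
    s2 <- sum(w * (ratios$ratio - beta)^2) / (j - 1)
    se <- se * max(1, sqrt(s2))
    df <- j - 1L
  }
  p <- 2 * stats::pnorm(-abs(beta / se))
  .mr_result(paste0("ivw-", variant), beta, se, p, j, df)
}

# weighted-median point estimate on sorted ratios
.wm_point <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  p <- cumsum(w) - w / 2
  if (any(p == 0.5)) return(r[which(p == 0.5)[1L]])
  stats::approx(p, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' The weighted median of the ordered Wald ratios: with normalized
#' weights `w`, breakpoints `p_j = cumsum(w) - w/2` are assigned to the
#' sorted ratios and the estimate interpolates the ratio at `p = 0.5`
#' (a ratio whose breakpoint is exactly 0.5 is returned as is). It is a
#' consistent estimate of the causal effect provided less than half the
#' total weight comes from invalid (pleiotropic) instruments. The
#' standard error is a seeded parametric bootstrap: each ratio is
#' redrawn from `Normal(ratio, se)` and the estimate recomputed; the SE
#' is the standard deviation across replicates. P-values use a normal
#' reference.
#'
#' @inheritParams mr_ivw
#' @param reps Bootstrap replicates (at least 2; default 1000).
#' @param seed Integer seed for the bootstrap (the caller's RNG stream
#'   is left untouched).
#' @return A one-row result data frame.
#' @export
mr_weighted_median <- function(ratios, reps = 1000L, seed = 1L) {
  if (inherits(ratios, "mr_data")) ratios <- wald_ratios(ratios)
  j <- nrow(ratios)
  if (j < 3L) stop("weighted median needs at least 3 instruments", call. = FALSE)
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 2L) stop("reps must be at least 2", call. = FALSE)
  beta <- .wm_point(ratios$ratio, ratios$weight)
  boot <- .with_seed(seed, {
    draws <- matrix(stats::rnorm(reps * j, mean = rep(ratios$ratio, each = reps),
                                 sd = rep(ratios$se, each = reps)),
                    nrow = reps)
    apply(draws, 1L, function(r) .wm_point(r, 1 / ratios$se^2))
  })
  se <- stats::sd(boot)
  p <- 2 * stats::pnorm(-abs(beta / se))
  .mr_result("weighted-median", beta, se, p, j)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome associations on the exposure
#' associations with an unconstrained intercept, weights
#' `1/se_out^2`, after orienting every variant so its exposure beta is
#' non-negative (both betas of a variant are negated together, which
#' leaves the fit invariant to the original allele orientation). The
#' slope estimates the causal effect; the intercept estimates average
#' directional pleiotropy, since a valid instrument with zero exposure
#' association must have zero outcome association. Standard errors are
#' inflated by the residual scale floored at 1, and p-values use a t
#' reference with `J - 2` degrees of freedom. Valid under the InSIDE
#' assumption (pleiotropic effects uncorrelated with instrument
#' strength).
#'
#' @param data An `mr_data` (needs `beta_exp`, `beta_out`, `se_out`).
#' @return A two-row result data frame: methods `"egger-slope"` and
#'   `"egger-intercept"`.
#' @export
mr_egger <- function(data) {
  stopifnot(is.data.frame(data))
  data <- data[!is.na(data$beta_exp) & !is.na(data$beta_out), , drop = FALSE]
  j <- nrow(data)
  if (j < 3L) stop("Egger requires >=3 instruments", call. = FALSE)
  sgn <- ifelse(data$beta_exp < 0, -1, 1)
  x <- data$beta_exp * sgn
  y <- data$beta_out * sgn
  w <- 1 / data$se_out^2
  # closed-form weighted normal equations (cross-checked against lm in tests)
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- y - intercept - slope * x
  s2 <- sum(w * resid^2) / (j - 2)
  infl <- max(1, sqrt(s2))
  se_slope <- sqrt(sw / det) * infl
  se_int <- sqrt(swxx / det) * infl
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = j - 2)
  p_int <- 2 * stats::pt(-abs(intercept / se_int), df = j - 2)
  rbind(.mr_result("egger-slope", slope, se_slope, p_slope, j, j - 2L),
        .mr_result("egger-intercept", intercept, se_int, p_int, j, j - 2L))
}

#' Fit two-sample Mendelian randomization estimators
#'
#' The main fitting interface: runs the requested combined estimators on
#' a harmonized instrument set and collects their causal-effect
#' estimates in one model object. The causal estimate `beta` is on the
#' outcome scale per standard-deviation change in the exposure
#' (a log odds ratio for binary outcomes).
#'
#' @param data An `mr_data` from [harmonize()].
#' @param methods Any of `"ivw"`, `"weighted-median"`, `"egger"`.
#' @param ivw_variant Passed to [mr_ivw()].
#' @param wm_reps,seed Weighted-median bootstrap settings; defaults are
#'   taken from the `mr_config` attached to `data` when present.
#' @return An object of class `mr_fit` with components `results` (one
#'   row per estimate), `ratios`, `data`, `config` and `heterogeneity`
#'   (Cochran's Q). Supports `print()`, `summary()`, `coef()`,
#'   `confint()` and `plot()`.
#' @examples
#' exposure <- vitd_exposure()
#' outcome <- caries_outcome("primary")
#' dat <- harmonize(exposure, outcome, caries_config("primary"))
#' fit <- mr_fit(dat)
#' coef(fit)
#' @export
mr_fit <- function(data,
                   methods = c("ivw", "weighted-median", "egger"),
                   ivw_variant = c("mre", "fe"),
                   wm_reps = NULL, seed = NULL) {
  stopifnot(inherits(data, "mr_data"))
  methods <- match.arg(methods, several.ok = TRUE)
  ivw_variant <- match.arg(ivw_variant)
  cfg <- attr(data, "config")
  if (is.null(wm_reps)) wm_reps <- if (!is.null(cfg)) cfg$wm_bootstrap_reps else 1000L
  if (is.null(seed)) seed <- if (!is.null(cfg)) cfg$rng_seed else 1L
  ratios <- wald_ratios(data)
  res <- list()
  if ("ivw" %in% methods) res$ivw <- mr_ivw(ratios, ivw_variant)
  if ("weighted-median" %in% methods) {
    res$wm <- mr_weighted_median(ratios, reps = wm_reps, seed = seed)
  }
  if ("egger" %in% methods) res$egger <- mr_egger(data)
  results <- do.call(rbind, unname(res))
  rownames(results) <- NULL
  het <- if (nrow(ratios) >= 2L) cochran_q(ratios) else NULL
  structure(list(results = results, ratios = ratios, data = data,
                 config = cfg, heterogeneity = het,
                 ivw_variant = ivw_variant),
            class = "mr_fit")
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$results$beta, object$results$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  r <- object$results
  m <- cbind(r$beta - z * r$se, r$beta + z * r$se)
  dimnames(m) <- list(r$method,
                      sprintf("%g %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2)))
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  nm <- if (!is.null(x$config)) x$config$outcome_name else "outcome"
  cat(sprintf("Two-sample MR fit: %s (%d instruments)\n", nm,
              max(x$results$n_snps)))
  out <- x$results
  out$beta <- signif(out$beta, digits)
  out$se <- signif(out$se, digits)
  out$ci_low <- signif(out$ci_low, digits)
  out$ci_high <- signif(out$ci_high, digits)
  out$pvalue <- signif(out$pvalue, 3)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  if (!is.null(fit$heterogeneity)) {
    h <- fit$heterogeneity
    cat(sprintf("Heterogeneity: Cochran Q = %.2f on %d df (p = %.3g)\n",
                h$Q, h$df, h$pvalue))
  }
  excl <- attr(fit$data, "exclusions")
  if (!is.null(excl) && nrow(excl)) {
    cat(sprintf("Harmonization excluded %d variant(s): %s\n", nrow(excl),
                paste(sprintf("%s [%s]", excl$snp, excl$reason), collapse = ", ")))
  }
  invisible(x)
}

#' Scatter plot of a two-sample MR fit
#'
#' Plots the per-variant outcome associations against the exposure
#' associations (oriented so exposure betas are non-negative) with the
#' fitted IVW (through the origin) and Egger lines.
#'
#' @param x An `mr_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  d <- x$data
  sgn <- ifelse(d$beta_exp < 0, -1, 1)
  graphics::plot(d$beta_exp * sgn, d$beta_out * sgn,
                 xlab = "SNP-exposure beta (oriented)",
                 ylab = "SNP-outcome beta (oriented)", ...)
  graphics::abline(h = 0, col = "grey70")
  r <- x$results
  if (any(r$method %in% c("ivw-mre", "ivw-fe"))) {
    b <- r$beta[r$method %in% c("ivw-mre", "ivw-fe")][1L]
    graphics::abline(0, b, col = "steelblue", lwd = 2)
  }
  if ("egger-slope" %in% r$method) {
    graphics::abline(r$beta[r$method == "egger-intercept"],
                     r$beta[r$method == "egger-slope"],
                     col = "firebrick", lty = 2, lwd = 2)
  }
  invisible(x)
}
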