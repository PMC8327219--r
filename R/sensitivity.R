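#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w * (ratio - beta_ivw)^2)` over the Wald ratios, with
#' `J - 1` degrees of freedom and a chi-square reference. `Q / (J - 1)`
#' equals the squared residual scale used by the multiplicative
#' random-effects IVW standard error.
#'
#' @param ratios A data frame from [wald_ratios()] or an `mr_data`.
#' @return A list `Q`, `df`, `pvalue`.
#' @export
cochran_q <- function(ratios) {
  if (inherits(ratios, "mr_data")) ratios <- wald_ratios(ratios)
  j <- nrow(ratios)
  if (j < 2L) stop("Cochran's Q needs at least 2 ratios", call. = FALSE)
  w <- ratios$weight
  beta <- sum(w * ratios$ratio) / sum(w)
  q <- sum(w * (ratios$ratio - beta)^2)
  list(Q = q, df = j - 1L, pvalue = stats::pchisq(q, df = j - 1L,
                                                  lower.tail = FALSE))
}

#' Leave-one-out sensitivity analysis
#'
#' Re-runs the IVW analysis omitting each instrument in turn, plus the
#' full-set row (`omitted == "none"`, identical to the full IVW result).
#' An omission is flagged as an outlier candidate when its confidence
#' interval excludes the full-set point estimate, the operational form
#' of "no single variant drives the estimate".
#'
#' @param data An `mr_data` with at least 2 usable instruments.
#' @param ivw_variant Passed to [mr_ivw()].
#' @return An `mr_loo` data frame with columns `omitted`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `n_snps`, `outlier`. Supports `plot()`
#'   (forest plot).
#' @export
leave_one_out <- function(data, ivw_variant = c("mre", "fe")) {
  ivw_variant <- match.arg(ivw_variant)
  ratios <- wald_ratios(data)
  j <- nrow(ratios)
  if (j < 2L) stop("leave-one-out needs at least 2 instruments", call. = FALSE)
  fit_one <- function(keep) {
    suppressWarnings(mr_ivw(ratios[keep, , drop = FALSE], ivw_variant))
  }
  full <- fit_one(seq_len(j))
  rows <- lapply(seq_len(j), function(i) {
    r <- fit_one(setdiff(seq_len(j), i))
    data.frame(omitted = ratios$snp[i], beta = r$beta, se = r$se,
               ci_low = r$ci_low, ci_high = r$ci_high, n_snps = r$n_snps,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(omitted = "none", beta = full$beta, se = full$se,
               ci_low = full$ci_low, ci_high = full$ci_high,
               n_snps = full$n_snps, stringsAsFactors = FALSE))))
  out$outlier <- out$ci_low > full$beta | out$ci_high < full$beta
  rownames(out) <- NULL
  structure(out, full_beta = full$beta, class = c("mr_loo", "data.frame"))
}

#' Write a leave-one-out table in forest-plot layout
#'
#' @param x An `mr_loo`.
#' @param path Output TSV path (columns `label`, `estimate`, `ci_low`,
#'   `ci_high`).
#' @return `path`, invisibly.
#' @export
write_loo_table <- function(x, path) {
  stopifnot(inherits(x, "mr_loo"))
  tab <- data.frame(label = ifelse(x$omitted == "none", "All SNPs",
                                   paste("omit", x$omitted)),
                    estimate = x$beta, ci_low = x$ci_low, ci_high = x$ci_high,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
plot.mr_loo <- function(x, ...) {
  n <- nrow(x)
  idx <- rev(seq_len(n))
  graphics::plot(x$beta, idx, xlim = range(x$ci_low, x$ci_high),
                 yaxt = "n", ylab = "", xlab = "IVW estimate (omitting one SNP)",
                 pch = 19, ...)
  graphics::segments(x$ci_low, idx, x$ci_high, idx)
  graphics::abline(v = attr(x, "full_beta"), col = "steelblue", lty = 2)
  graphics::axis(2, at = idx, labels = x$omitted, las = 2, cex.axis = 0.5)
  invisible(x)
}

#' Instrument-subset analysis
#'
#' Runs the IVW analysis on a biologically selected subset of the
#' harmonized instruments, chosen either by nearest-gene annotation or
#' by explicit variant ids (used for the analysis restricted to the
#' conditionally independent variants in the vitamin D transport and
#' synthesis loci, GC and CYP2R1).
#'
#' @param data An `mr_data`.
#' @param genes Character vector of nearest-gene names to keep.
#' @param snps Character vector of variant ids to keep.
#' @param ... Passed to [mr_fit()].
#' @return An `mr_fit` on the subset (IVW only by default).
#' @export
subset_fit <- function(data, genes = NULL, snps = NULL, ...) {
  stopifnot(inherits(data, "mr_data"))
  if (is.null(genes) && is.null(snps)) {
    stop("supply a gene or snp selector", call. = FALSE)
  }
  keep <- rep(FALSE, nrow(data))
  if (!is.null(genes)) keep <- keep | (!is.na(data$gene) & data$gene %in% genes)
  if (!is.null(snps)) keep <- keep | data$snp %in% snps
  if (sum(keep) < 2L) {
    sel <- paste(c(genes, snps), collapse = ", ")
    stop(sprintf("selector {%s} matches %d instrument(s); need at least 2",
                 sel, sum(keep)), call. = FALSE)
  }
  sub <- data[keep, , drop = FALSE]
  attr(sub, "exclusions") <- attr(data, "exclusions")
  attr(sub, "config") <- attr(data, "config")
  class(sub) <- class(data)
  mr_fit(sub, methods = "ivw", ...)
}
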