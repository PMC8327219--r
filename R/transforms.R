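# presentation rounding: half away from zero, as in the published tables.
# The epsilon absorbs binary representation error (1.005 stores just
# below its decimal value); fine for display, not for arithmetic.
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5 + sqrt(.Machine$double.eps)) /
    10^digits
}

#' Express causal estimates as odds ratios
#'
#' For a binary outcome the causal estimate is a log odds ratio per SD
#' change in the exposure; it is reported as `OR = exp(beta)` with
#' confidence interval `exp(beta +/- 1.96 * SE)` (the default
#' `"exponential"` mode). The `"legacy-additive"` mode instead computes
#' `exp(beta) +/- 1.96 * SE`, which reproduces the interval layout of
#' some published tables but is not an interval for the OR on its
#' natural scale; it is provided for comparison only.
#'
#' @param result A result data frame (rows of an `mr_fit`'s `results`,
#'   or the `mr_fit` itself, in which case all causal-effect rows are
#'   transformed; the Egger intercept row, which is not a causal
#'   effect, is left out).
#' @param outcome_name Label for the report.
#' @param ci_mode `"exponential"` (default) or `"legacy-additive"`.
#' @return A data frame of class `mr_transformed` with columns
#'   `outcome`, `method`, `scale`, `estimate`, `ci_low`, `ci_high`,
#'   `pvalue`, `n_snps`.
#' @export
to_odds_ratio <- function(result, outcome_name = NULL,
                          ci_mode = c("exponential", "legacy-additive")) {
  ci_mode <- match.arg(ci_mode)
  if (inherits(result, "mr_fit")) {
    if (is.null(outcome_name) && !is.null(result$config)) {
      outcome_name <- result$config$outcome_name
    }
    result <- result$results[result$results$method != "egger-intercept", ,
                             drop = FALSE]
  }
  if (is.null(outcome_name)) outcome_name <- "outcome"
  est <- exp(result$beta)
  if (ci_mode == "exponential") {
    lo <- exp(result$beta - 1.96 * result$se)
    hi <- exp(result$beta + 1.96 * result$se)
  } else {
    lo <- est - 1.96 * result$se
    hi <- est + 1.96 * result$se
  }
  structure(data.frame(outcome = outcome_name, method = result$method,
                       scale = "odds-ratio", estimate = est,
                       ci_low = lo, ci_high = hi, pvalue = result$pvalue,
                       n_snps = result$n_snps, stringsAsFactors = FALSE),
            class = c("mr_transformed", "data.frame"))
}

#' Express causal estimates as affected tooth surfaces
#'
#' Back-transforms estimates on the standardized DMFS scale to counts of
#' decayed, missing or filled tooth surfaces:
#' `surfaces = beta * scale_factor` with confidence interval
#' `scale_factor * (beta +/- 1.96 * SE)`. The default scale factor of
#' 19.87 surfaces per standardized unit comes from an external adult
#' reference population.
#'
#' @inheritParams to_odds_ratio
#' @param scale_factor Positive number of tooth surfaces per 1-unit
#'   change of the standardized score.
#' @return An `mr_transformed` data frame (`scale = "dmfs-surfaces"`).
#' @export
to_dmfs_surfaces <- function(result, scale_factor = 19.87,
                             outcome_name = NULL) {
  if (!is.numeric(scale_factor) || scale_factor <= 0) {
    stop("scale_factor must be positive", call. = FALSE)
  }
  if (inherits(result, "mr_fit")) {
    if (is.null(outcome_name) && !is.null(result$config)) {
      outcome_name <- result$config$outcome_name
    }
    result <- result$results[result$results$method != "egger-intercept", ,
                             drop = FALSE]
  }
  if (is.null(outcome_name)) outcome_name <- "outcome"
  structure(data.frame(outcome = outcome_name, method = result$method,
                       scale = "dmfs-surfaces",
                       estimate = result$beta * scale_factor,
                       ci_low = scale_factor * (result$beta - 1.96 * result$se),
                       ci_high = scale_factor * (result$beta + 1.96 * result$se),
                       pvalue = result$pvalue, n_snps = result$n_snps,
                       stringsAsFactors = FALSE),
            class = c("mr_transformed", "data.frame"))
}

#' Instrument-strength metrics
#'
#' The variance in the (standardized) exposure explained by each variant
#' is approximated as `2 * beta^2 * f * (1 - f)` with `f` the
#' effect-allele frequency; the panel total is the sum. Per-variant F
#' statistics are `(beta / se)^2`, and the overall F statistic uses the
#' standard approximation
#' `(R2 / (1 - R2)) * (n - J - 1) / J` for `J` instruments in an
#' exposure GWAS of `n` participants. Variants lacking a frequency or
#' beta are skipped with a warning.
#'
#' @param instruments An `instrument_set` (exposure panel).
#' @param n_exposure Exposure-GWAS sample size.
#' @return A list of class `instrument_strength`: `per_snp` (data frame
#'   `snp`, `r2`, `F`), `total_r2`, `overall_F`, `n_snps`, `n_exposure`.
#' @export
instrument_strength <- function(instruments, n_exposure) {
  stopifnot(is.data.frame(instruments), is.numeric(n_exposure))
  skip <- is.na(instruments$eaf) | is.na(instruments$beta)
  if (any(skip)) {
    warning(sprintf("skipping %d variant(s) without eaf or beta: %s",
                    sum(skip), paste(instruments$snp[skip], collapse = ", ")))
    instruments <- instruments[!skip, , drop = FALSE]
  }
  r2 <- 2 * instruments$beta^2 * instruments$eaf * (1 - instruments$eaf)
  fstat <- (instruments$beta / instruments$se)^2
  total <- sum(r2)
  j <- nrow(instruments)
  overall <- (total / (1 - total)) * ((n_exposure - j - 1) / j)
  structure(list(per_snp = data.frame(snp = instruments$snp, r2 = r2,
                                      F = fstat, stringsAsFactors = FALSE),
                 total_r2 = total, overall_F = overall,
                 n_snps = j, n_exposure = n_exposure),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("Instrument strength: %d variants explain %.2f%% of exposure variance\n",
              x$n_snps, 100 * x$total_r2))
  cat(sprintf("overall F = %.1f (exposure n = %d)\n", x$overall_F,
              as.integer(x$n_exposure)))
  invisible(x)
}

#' Render the results report
#'
#' Emits a compact summary table (outcome by method, estimates rounded
#' half-away-from-zero to 2 decimals as in the published layout) in
#' Markdown plus, optionally, a full-precision TSV. Byte-identical when
#' regenerated from the same inputs.
#'
#' @param results An `mr_transformed` data frame, or a list of them
#'   (rows are concatenated).
#' @param strength Optional [instrument_strength()] block.
#' @param file Markdown output path (`NULL` returns the lines).
#' @param tsv Optional path for the full-precision TSV.
#' @return The Markdown lines, invisibly when written to `file`.
#' @export
mr_report <- function(results, strength = NULL, file = NULL, tsv = NULL) {
  if (is.data.frame(results)) results <- list(results)
  tab <- do.call(rbind, lapply(results, as.data.frame))
  if (is.null(tab) || !nrow(tab)) stop("no results to report", call. = FALSE)
  fmt2 <- function(x) sprintf("%.2f", round_half_up(x, 2))
  lines <- c("# Mendelian randomization results", "",
             "| Outcome | Method | N SNPs | Estimate | 95% CI | P |",
             "|---|---|---|---|---|---|",
             sprintf("| %s | %s | %d | %s | %s, %s | %.2g |",
                     tab$outcome, tab$method, tab$n_snps, fmt2(tab$estimate),
                     fmt2(tab$ci_low), fmt2(tab$ci_high), tab$pvalue))
  if (!is.null(strength)) {
    lines <- c(lines, "",
               sprintf("Instruments explain %.1f%% of exposure variance (overall F = %.1f).",
                       100 * round_half_up(strength$total_r2, 3),
                       strength$overall_F))
  }
  if (!is.null(tsv)) {
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
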