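.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Is an allele pair palindromic?
#'
#' A variant is palindromic when its two alleles are strand complements
#' ({A,T} or {C,G}), so the strand on which a study reports it cannot be
#' told from the allele letters alone.
#'
#' @param a1,a2 Allele characters (A/C/G/T, any case). Vectorized.
#' @return Logical vector.
#' @export
is_palindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  ok <- a1 %in% .VALID_ALLELES & a2 %in% .VALID_ALLELES
  if (!all(ok | is.na(a1) | is.na(a2))) {
    bad <- c(a1, a2)[!c(a1, a2) %in% c(.VALID_ALLELES, NA)][1L]
    stop(sprintf("invalid allele '%s'", bad), call. = FALSE)
  }
  unname(.COMPLEMENT[a1] == a2)
}

# Orient one outcome record onto the exposure record's effect allele.
# Returns list(beta, eaf, action) or list(action = "excluded", reason).
.orient_outcome <- function(ea, oa, ea_o, oa_o, beta_o, eaf_o) {
  if (is.na(ea_o) || is.na(oa_o)) {
    return(list(action = "excluded", reason = "missing_outcome"))
  }
  if (ea_o == ea && oa_o == oa) {
    return(list(beta = beta_o, eaf = eaf_o, action = "none"))
  }
  if (ea_o == oa && oa_o == ea) {
    return(list(beta = -beta_o, eaf = 1 - eaf_o, action = "flipped"))
  }
  # try reading the outcome record on the opposite strand
  cea <- unname(.COMPLEMENT[ea_o]); coa <- unname(.COMPLEMENT[oa_o])
  if (cea == ea && coa == oa) {
    return(list(beta = beta_o, eaf = eaf_o, action = "none"))
  }
  if (cea == oa && coa == ea) {
    return(list(beta = -beta_o, eaf = 1 - eaf_o, action = "flipped"))
  }
  list(action = "excluded", reason = "allele_mismatch")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns each variant's exposure and outcome statistics to a common
#' effect allele (the exposure record's printed effect allele is the
#' reference; the outcome side is flipped when needed) and applies the
#' configured palindromic-variant policy. Variants without outcome
#' statistics, with incompatible allele pairs, or flagged as
#' strand-ambiguous palindromes are excluded, never silently dropped:
#' every exclusion is listed with a machine-readable reason in the
#' `exclusions` attribute, and retained + excluded always equals the
#' number of exposure records.
#'
#' Under `"infer-by-frequency"` the strand of a palindromic variant is
#' inferred by comparing effect-allele frequencies (frequencies on
#' opposite sides of 0.5 imply opposite strands, and the outcome record
#' is flipped); the variant is excluded as ambiguous when the
#' exposure-study effect-allele frequency lies inside the open window
#' `(ambiguity_low, ambiguity_high)`, where the inference is unreliable.
#'
#' @param exposure,outcome `instrument_set` tables sharing snp ids.
#' @param config An [mr_config()].
#' @return An `mr_data`: a data frame of retained harmonized pairs with
#'   columns `snp`, `gene`, `effect_allele`, `other_allele`,
#'   `beta_exp`, `se_exp`, `eaf_exp`, `beta_out`, `se_out`, `eaf_out`,
#'   `n_out`, `palindromic`, `ambiguous`, `action`; attributes
#'   `exclusions` (data frame `snp`, `reason`, `detail`) and `config`.
#' @seealso [mr_fit()], [exclusion_report()]
#' @export
harmonize <- function(exposure, outcome, config = mr_config()) {
  stopifnot(inherits(config, "mr_config"))
  if (!length(intersect(exposure$snp, outcome$snp))) {
    stop("no usable instruments: exposure and outcome share no snp ids",
         call. = FALSE)
  }
  policy <- config$palindrome_policy
  ne <- nrow(exposure)
  keep <- logical(ne)
  beta_out <- eaf_out <- se_out <- n_out <- rep(NA_real_, ne)
  action <- rep(NA_character_, ne)
  pal_flag <- amb_flag <- logical(ne)
  excl <- list()
  note_excl <- function(snp, reason, detail = "") {
    excl[[length(excl) + 1L]] <<- c(snp = snp, reason = reason, detail = detail)
  }
  out_idx <- match(exposure$snp, outcome$snp)
  for (i in seq_len(ne)) {
    j <- out_idx[i]
    snp_i <- exposure$snp[i]
    ea <- exposure$effect_allele[i]; oa <- exposure$other_allele[i]
    if (is.na(j)) {
      note_excl(snp_i, "missing_outcome", "snp absent from outcome table")
      next
    }
    if (is.na(outcome$beta[j]) || is.na(outcome$se[j])) {
      note_excl(snp_i, "missing_outcome", "outcome statistics not available")
      next
    }
    ori <- .orient_outcome(ea, oa, outcome$effect_allele[j],
                           outcome$other_allele[j],
                           outcome$beta[j], outcome$eaf[j])
    if (identical(ori$action, "excluded")) {
      note_excl(snp_i, ori$reason,
                sprintf("exposure %s/%s vs outcome %s/%s", ea, oa,
                        outcome$effect_allele[j], outcome$other_allele[j]))
      next
    }
    pal <- is_palindromic(ea, oa)
    eaf_e <- exposure$eaf[i]
    if (pal) {
      if (policy == "drop-all") {
        note_excl(snp_i, "palindromic", "drop-all policy")
        next
      }
      if (policy == "infer-by-frequency") {
        # letter-based alignment carries no strand information for a
        # palindrome; use allele frequencies to infer the strand
        if (!is.na(eaf_e) && !is.na(ori$eaf) &&
            (eaf_e - 0.5) * (ori$eaf - 0.5) < 0) {
          ori$beta <- -ori$beta
          ori$eaf <- 1 - ori$eaf
          ori$action <- "flipped"
        }
        if (!is.na(eaf_e) && eaf_e > config$ambiguity_low &&
            eaf_e < config$ambiguity_high) {
          note_excl(snp_i, "palindromic_ambiguous",
                    sprintf("exposure eaf %g inside (%g, %g)", eaf_e,
                            config$ambiguity_low, config$ambiguity_high))
          next
        }
      }
    }
    keep[i] <- TRUE
    beta_out[i] <- ori$beta
    eaf_out[i] <- if (is.null(ori$eaf)) NA_real_ else ori$eaf
    se_out[i] <- outcome$se[j]
    n_out[i] <- outcome$n[j]
    action[i] <- ori$action
    pal_flag[i] <- pal
  }
  if (!any(keep)) {
    stop("no usable instruments after harmonization", call. = FALSE)
  }
  kept <- data.frame(
    snp = exposure$snp[keep], gene = exposure$gene[keep],
    effect_allele = exposure$effect_allele[keep],
    other_allele = exposure$other_allele[keep],
    beta_exp = exposure$beta[keep], se_exp = exposure$se[keep],
    eaf_exp = exposure$eaf[keep],
    beta_out = beta_out[keep], se_out = se_out[keep], eaf_out = eaf_out[keep],
    n_out = n_out[keep], palindromic = pal_flag[keep],
    ambiguous = amb_flag[keep], action = action[keep],
    stringsAsFactors = FALSE
  )
  exclusions <- if (length(excl)) {
    m <- do.call(rbind, excl)
    data.frame(snp = m[, "snp"], reason = m[, "reason"],
               detail = m[, "detail"], stringsAsFactors = FALSE,
               row.names = NULL)
  } else {
    data.frame(snp = character(), reason = character(), detail = character(),
               stringsAsFactors = FALSE)
  }
  structure(kept, exclusions = exclusions, config = config,
            class = c("mr_data", "data.frame"))
}

#' Exclusion audit of a harmonized data set
#'
#' @param x An `mr_data` from [harmonize()].
#' @param path Optional path; when given, the report is written as TSV
#'   with columns `snp`, `outcome`, `reason`, `detail`.
#' @return The exclusion data frame, invisibly when written.
#' @export
exclusion_report <- function(x, path = NULL) {
  stopifnot(inherits(x, "mr_data"))
  rep <- attr(x, "exclusions")
  rep <- data.frame(snp = rep$snp,
                    outcome = attr(x, "config")$outcome_name,
                    reason = rep$reason, detail = rep$detail,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rep))
  }
  rep
}

#' @export
print.mr_data <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<mr_data> %d harmonized instruments for '%s' (%s policy)\n",
              nrow(x), cfg$outcome_name, cfg$palindrome_policy))
  excl <- attr(x, "exclusions")
  if (nrow(excl)) {
    tab <- table(excl$reason)
    cat("excluded:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}
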