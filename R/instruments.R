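.VALID_ALLELES <- c("A", "C", "G", "T")
.NA_TOKENS <- c("", "NA", "na", "NaN", "nan", ".")

# columns every summary table must name; the rest are optional
.MANDATORY_COLS <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se")
.OPTIONAL_COLS <- c("chr", "pos", "pvalue", "n", "gene")

.parse_numeric <- function(x, col, path) {
  x <- trimws(x)
  x[x %in% .NA_TOKENS] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop(sprintf("malformed numeric value '%s' in column '%s' of %s",
                 x[which(bad)[1L]], col, path), call. = FALSE)
  }
  out
}

.validate_instruments <- function(x, path = "<data>") {
  if (anyDuplicated(x$snp)) {
    dup <- x$snp[duplicated(x$snp)][1L]
    stop(sprintf("duplicate snp id '%s' in %s", dup, path), call. = FALSE)
  }
  for (col in c("effect_allele", "other_allele")) {
    bad <- !is.na(x[[col]]) & !(x[[col]] %in% .VALID_ALLELES)
    if (any(bad)) {
      stop(sprintf("invalid allele '%s' in column '%s' of %s",
                   x[[col]][which(bad)[1L]], col, path), call. = FALSE)
    }
  }
  same <- !is.na(x$effect_allele) & !is.na(x$other_allele) &
    x$effect_allele == x$other_allele
  if (any(same)) {
    stop(sprintf("effect and other allele identical for %s in %s",
                 x$snp[which(same)[1L]], path), call. = FALSE)
  }
  if (any(!is.na(x$se) & x$se <= 0)) {
    stop(sprintf("non-positive standard error in %s", path), call. = FALSE)
  }
  if (any(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1))) {
    stop(sprintf("effect-allele frequency outside [0, 1] in %s", path), call. = FALSE)
  }
  if (!is.null(x$pvalue) && any(!is.na(x$pvalue) & (x$pvalue < 0 | x$pvalue > 1))) {
    stop(sprintf("p-value outside [0, 1] in %s", path), call. = FALSE)
  }
  invisible(x)
}

.as_instrument_set <- function(x, provenance = character()) {
  rownames(x) <- NULL
  structure(x,
            provenance = provenance,
            class = c("instrument_set", "data.frame"))
}

#' Read a GWAS summary-statistic table
#'
#' Reads a tab-separated table of per-variant association statistics
#' (one row per SNP). The header must name at least `snp`,
#' `effect_allele`, `other_allele`, `eaf`, `beta` and `se`; `chr`, `pos`,
#' `pvalue`, `n` and `gene` are carried along when present. Any of
#' `NA`/`nan`/empty encodes a missing cell; allele letters are
#' upper-cased on read. Rows with missing statistics are kept (their
#' bookkeeping happens at harmonization), and row order is preserved.
#'
#' Extremely small printed p-values (below roughly 1e-308) underflow
#' double precision and are read as 0; they still satisfy any selection
#' threshold.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param schema `"exposure"` for instrument (SNP-exposure) tables,
#'   `"outcome"` for SNP-outcome tables. The two schemas share columns;
#'   the label is recorded and used for error messages.
#' @return An `instrument_set`: a `data.frame` with columns
#'   `snp`, `chr`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`, `gene` (missing optional columns are
#'   filled with `NA`), plus a `provenance` attribute recording
#'   substitutions and exclusions.
#' @seealso [write_summary_table()], [apply_proxy_map()], [vitd_exposure()]
#' @export
read_summary_table <- function(path, schema = c("exposure", "outcome")) {
  schema <- match.arg(schema)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = NULL)
  missing_cols <- setdiff(.MANDATORY_COLS, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("%s table %s lacks mandatory column(s): %s",
                 schema, path, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  n <- nrow(raw)
  chr_col <- function(col) {
    if (!col %in% names(raw)) return(rep(NA_character_, n))
    v <- trimws(raw[[col]])
    v[v %in% .NA_TOKENS] <- NA_character_
    v
  }
  out <- data.frame(
    snp = chr_col("snp"),
    chr = as.integer(.parse_numeric(chr_col("chr"), "chr", path)),
    pos = as.integer(.parse_numeric(chr_col("pos"), "pos", path)),
    effect_allele = toupper(chr_col("effect_allele")),
    other_allele = toupper(chr_col("other_allele")),
    eaf = .parse_numeric(chr_col("eaf"), "eaf", path),
    beta = .parse_numeric(chr_col("beta"), "beta", path),
    se = .parse_numeric(chr_col("se"), "se", path),
    pvalue = .parse_numeric(chr_col("pvalue"), "pvalue", path),
    n = .parse_numeric(chr_col("n"), "n", path),
    gene = chr_col("gene"),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$snp))) {
    stop(sprintf("missing snp id in %s", path), call. = FALSE)
  }
  .validate_instruments(out, path)
  .as_instrument_set(out, provenance = sprintf("read %d records from %s (%s schema)",
                                               n, basename(path), schema))
}

#' Write a summary-statistic table
#'
#' Inverse of [read_summary_table()]: writes tab-separated values with a
#' header row and `NA` for missing cells, so that write-then-read is the
#' identity on any valid table.
#'
#' @param x An `instrument_set` (or compatible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Filter instruments on selection thresholds
#'
#' Retains variants that pass the genome-wide significance and
#' minor-allele-frequency thresholds used for instrument selection.
#' Thresholds are applied only where the relevant field is present.
#'
#' @param x An `instrument_set`.
#' @param pvalue_threshold Largest admissible association p-value
#'   (default `5e-8`, genome-wide significance).
#' @param maf_threshold Smallest admissible minor-allele frequency
#'   (default `0.05`).
#' @return The filtered `instrument_set`; exclusions are appended to its
#'   `provenance` attribute.
#' @export
select_instruments <- function(x, pvalue_threshold = 5e-8, maf_threshold = 0.05) {
  prov <- attr(x, "provenance")
  maf <- pmin(x$eaf, 1 - x$eaf)
  drop_p <- !is.na(x$pvalue) & x$pvalue > pvalue_threshold
  drop_f <- !is.na(maf) & maf < maf_threshold
  drop <- drop_p | drop_f
  if (any(drop)) {
    prov <- c(prov, sprintf("excluded %s (%s)", x$snp[drop],
                            ifelse(drop_p[drop], "pvalue above threshold",
                                   "minor allele frequency below threshold")))
  }
  .as_instrument_set(as.data.frame(x)[!drop, , drop = FALSE], provenance = prov)
}

#' Substitute LD proxies for missing instruments
#'
#' Replaces instruments that are absent from the outcome data with
#' linkage-disequilibrium proxies, using a precomputed proxy table
#' (proxy discovery against an LD reference panel is out of scope).
#' A proxy is accepted when its r-squared with the missing variant is at
#' least `r2_threshold` (boundary inclusive); a missing variant whose
#' best proxy falls below the threshold is excluded. Every substitution
#' and exclusion is recorded in the returned set's `provenance`.
#'
#' @param instruments An `instrument_set`.
#' @param proxies A data frame with columns `missing_snp`, `proxy_snp`,
#'   `r2` (r-squared in `[0, 1]`). An empty table leaves `instruments`
#'   unchanged.
#' @param source An `instrument_set` supplying the summary statistics of
#'   the proxy variants. A `proxy_snp` absent from `source` is an error.
#' @param r2_threshold Minimum r-squared for substitution (default 0.7).
#' @return The updated `instrument_set`.
#' @export
apply_proxy_map <- function(instruments, proxies, source, r2_threshold = 0.7) {
  stopifnot(is.data.frame(proxies))
  if (nrow(proxies) == 0L) return(instruments)
  req <- c("missing_snp", "proxy_snp", "r2")
  if (!all(req %in% names(proxies))) {
    stop("proxy table needs columns missing_snp, proxy_snp, r2", call. = FALSE)
  }
  if (any(is.na(proxies$r2) | proxies$r2 < 0 | proxies$r2 > 1)) {
    stop("proxy r2 values must lie in [0, 1]", call. = FALSE)
  }
  out <- as.data.frame(instruments)
  prov <- attr(instruments, "provenance")
  drop_idx <- integer()
  for (i in seq_len(nrow(proxies))) {
    ms <- proxies$missing_snp[i]
    j <- match(ms, out$snp)
    if (is.na(j)) next
    if (proxies$r2[i] >= r2_threshold) {
      ps <- proxies$proxy_snp[i]
      k <- match(ps, source$snp)
      if (is.na(k)) {
        stop(sprintf("proxy snp '%s' not found in the supplied lookup source", ps),
             call. = FALSE)
      }
      out[j, ] <- as.data.frame(source)[k, names(out)]
      prov <- c(prov, sprintf("substituted %s by proxy %s (r2 = %g)",
                              ms, ps, proxies$r2[i]))
    } else {
      drop_idx <- c(drop_idx, j)
      prov <- c(prov, sprintf("excluded %s: best proxy r2 %g below threshold %g",
                              ms, proxies$r2[i], r2_threshold))
    }
  }
  if (length(drop_idx)) out <- out[-drop_idx, , drop = FALSE]
  res <- .as_instrument_set(out, provenance = prov)
  .validate_instruments(res)
  res
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %d variants\n", nrow(x)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  prov <- attr(x, "provenance")
  if (length(prov)) cat("provenance:", length(prov), "entries\n")
  invisible(x)
}

# ---- packaged fixtures ------------------------------------------------------

.mr_extdata <- function(file) {
  path <- system.file("extdata", file, package = "mrwald", mustWork = TRUE)
  path
}

#' Packaged 25(OH)D instrument table
#'
#' The published panel of 83 conditionally independent variants
#' associated with standardized natural-log serum 25-hydroxyvitamin D
#' (discovery GWAS n = 443,734, European ancestry; positions GRCh37),
#' transcribed verbatim from the source publication and frozen as a
#' golden file. Betas are per effect-allele copy on the standardized
#' ln-25(OH)D scale.
#'
#' @return An `instrument_set` of 83 records with nearest-gene
#'   annotation.
#' @seealso [caries_outcome()], [caries_config()]
#' @export
vitd_exposure <- function() {
  read_summary_table(.mr_extdata("vitd_exposure.tsv"), schema = "exposure")
}

#' Packaged dental-caries outcome tables
#'
#' SNP-outcome association statistics for the three dental-caries
#' outcomes, transcribed verbatim from the source publication:
#' `"primary"` (caries in primary teeth, binary, n = 17,035 children),
#' `"permanent"` (caries in permanent teeth in childhood/adolescence,
#' binary, n = 13,386) and `"dmfs"` (decayed/missing/filled tooth
#' surfaces in adults, standardized residual units, n = 26,792). Betas
#' for the binary outcomes are log odds ratios. Rows whose statistics
#' were not available in the outcome GWAS are encoded as `NA`.
#'
#' @param outcome One of `"primary"`, `"permanent"`, `"dmfs"`.
#' @return An `instrument_set` of 83 records aligned row-for-row with
#'   [vitd_exposure()].
#' @export
caries_outcome <- function(outcome = c("primary", "permanent", "dmfs")) {
  outcome <- match.arg(outcome)
  file <- switch(outcome,
                 primary = "caries_primary.tsv",
                 permanent = "caries_permanent.tsv",
                 dmfs = "dmfs.tsv")
  read_summary_table(.mr_extdata(file), schema = "outcome")
}
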