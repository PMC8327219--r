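#' Run the full analysis pipeline
#'
#' Wires the whole workflow for one exposure table and any number of
#' outcome tables: optional LD-proxy substitution, harmonization under
#' each outcome's configuration, the three combined estimators,
#' leave-one-out sensitivity analysis, scale transformation
#' (odds ratios for binary outcomes, tooth surfaces for the
#' quantitative DMFS outcome), optional gene-subset analysis,
#' instrument-strength metrics, and a per-run manifest with input
#' checksums and per-stage record counts.
#'
#' Files written per outcome `<name>`: `<name>_results.tsv`
#' (full-precision estimates), `<name>_exclusions.tsv`,
#' `<name>_leave_one_out.tsv`; plus `report.md` and `manifest.json` for
#' the run.
#'
#' @param exposure Path to the exposure table, or an `instrument_set`.
#' @param outcomes Named character vector of outcome table paths, or a
#'   named list of `instrument_set`s.
#' @param configs A named list of [mr_config()]s (names matching
#'   `outcomes`), or a single config recycled to all outcomes.
#' @param out_dir Output directory (created if needed).
#' @param proxies,proxy_source Optional proxy table and lookup source
#'   for [apply_proxy_map()].
#' @param subset_genes Optional character vector: additionally run the
#'   IVW analysis restricted to instruments at these loci.
#' @param n_exposure Exposure-GWAS sample size for instrument-strength
#'   metrics (`NULL` skips them).
#' @param seed Seed recorded in the manifest and used for bootstrap
#'   draws (overrides each config's `rng_seed`).
#' @param timestamp Timestamp string recorded in the manifest; pass a
#'   fixed value for byte-identical reruns.
#' @return Invisibly, a named list of `mr_fit` objects.
#' @export
mr_run <- function(exposure, outcomes, configs, out_dir,
                   proxies = NULL, proxy_source = NULL,
                   subset_genes = NULL, n_exposure = NULL, seed = 1L,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  checksums <- list()
  if (is.character(exposure)) {
    checksums[["exposure"]] <- unname(tools::md5sum(exposure))
    exposure <- read_summary_table(exposure, "exposure")
  }
  if (is.character(outcomes)) {
    if (is.null(names(outcomes)) || any(!nzchar(names(outcomes)))) {
      stop("outcome paths must be named", call. = FALSE)
    }
    for (nm in names(outcomes)) {
      checksums[[nm]] <- unname(tools::md5sum(outcomes[[nm]]))
    }
    outcomes <- lapply(outcomes, read_summary_table, schema = "outcome")
  }
  if (inherits(configs, "mr_config")) {
    configs <- stats::setNames(rep(list(configs), length(outcomes)),
                               names(outcomes))
  }
  stopifnot(setequal(names(configs), names(outcomes)))
  if (!is.null(proxies)) {
    if (is.null(proxy_source)) stop("proxies given without proxy_source",
                                    call. = FALSE)
    exposure <- apply_proxy_map(exposure, proxies, proxy_source)
  }
  fits <- list()
  transformed <- list()
  counts <- list()
  for (nm in names(outcomes)) {
    cfg <- configs[[nm]]
    cfg$rng_seed <- as.integer(seed)
    dat <- harmonize(exposure, outcomes[[nm]], cfg)
    fit <- mr_fit(dat)
    fits[[nm]] <- fit
    excl <- attr(dat, "exclusions")
    counts[[nm]] <- list(input = nrow(exposure), retained = nrow(dat),
                         excluded = nrow(excl))
    utils::write.table(fit$results, file.path(out_dir, paste0(nm, "_results.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    exclusion_report(dat, file.path(out_dir, paste0(nm, "_exclusions.tsv")))
    loo <- leave_one_out(dat)
    write_loo_table(loo, file.path(out_dir, paste0(nm, "_leave_one_out.tsv")))
    transformed[[nm]] <- if (cfg$outcome_type == "binary") {
      to_odds_ratio(fit)
    } else {
      to_dmfs_surfaces(fit, cfg$dmfs_scale_factor)
    }
    if (!is.null(subset_genes)) {
      sfit <- subset_fit(dat, genes = subset_genes, seed = seed)
      stab <- if (cfg$outcome_type == "binary") to_odds_ratio(sfit) else
        to_dmfs_surfaces(sfit, cfg$dmfs_scale_factor)
      stab$method <- paste0(stab$method, " [", paste(subset_genes, collapse = "/"), "]")
      transformed[[nm]] <- rbind(transformed[[nm]], stab)
    }
  }
  strength <- if (!is.null(n_exposure)) {
    suppressWarnings(instrument_strength(exposure, n_exposure))
  }
  mr_report(transformed, strength = strength,
            file = file.path(out_dir, "report.md"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("mrwald")),
    timestamp = timestamp,
    seed = as.integer(seed),
    input_checksums = checksums,
    configs = lapply(configs, unclass),
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(fits)
}
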