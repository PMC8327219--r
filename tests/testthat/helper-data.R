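# builders for small in-code fixtures

# a minimal valid summary table as a data.frame (writable via
# write_summary_table and readable back)
toy_table <- function(snp = c("rs1", "rs2", "rs3"),
                      effect_allele = c("A", "C", "T"),
                      other_allele = c("G", "T", "C"),
                      eaf = c(0.25, 0.5, 0.75),
                      beta = c(0.02, -0.015, 0.05),
                      se = c(0.004, 0.003, 0.01),
                      pvalue = c(1e-9, 2e-10, 5e-12),
                      n = c(1000, 1000, 1000),
                      chr = c(1L, 2L, 3L),
                      pos = c(100L, 200L, 300L),
                      gene = c("G1", "G2", "G3")) {
  data.frame(snp = snp, chr = chr, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n,
             gene = gene, stringsAsFactors = FALSE)
}

write_toy <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  path
}

read_toy <- function(df, schema = "exposure") {
  read_summary_table(write_toy(df), schema = schema)
}

# an mr_data object built directly from per-variant statistics, for
# estimator tests that do not need the harmonization layer
fake_mr_data <- function(beta_exp, beta_out, se_out,
                         se_exp = rep(0.003, length(beta_exp)),
                         snp = sprintf("rs%d", seq_along(beta_exp)),
                         gene = rep(NA_character_, length(beta_exp)),
                         config = mr_config(outcome_name = "test")) {
  d <- data.frame(snp = snp, gene = gene,
                  effect_allele = "A", other_allele = "G",
                  beta_exp = beta_exp, se_exp = se_exp,
                  eaf_exp = 0.3, beta_out = beta_out, se_out = se_out,
                  eaf_out = 0.3, n_out = 1e4, palindromic = FALSE,
                  ambiguous = FALSE, action = "none",
                  stringsAsFactors = FALSE)
  structure(d,
            exclusions = data.frame(snp = character(), reason = character(),
                                    detail = character(), stringsAsFactors = FALSE),
            config = config,
            class = c("mr_data", "data.frame"))
}

# random estimator inputs under a fixed seed
random_mr_data <- function(j, seed) {
  set.seed(seed)
  fake_mr_data(beta_exp = runif(j, -0.2, 0.2),
               beta_out = rnorm(j, 0, 0.05),
               se_out = runif(j, 0.005, 0.05))
}

# harmonized fixture sets, computed once per test run
caries_data <- local({
  cache <- list()
  function(outcome) {
    if (is.null(cache[[outcome]])) {
      cache[[outcome]] <<- harmonize(vitd_exposure(), caries_outcome(outcome),
                                     caries_config(outcome))
    }
    cache[[outcome]]
  }
})
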