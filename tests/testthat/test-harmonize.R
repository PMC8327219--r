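test_that("palindromic allele pairs are recognized", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_false(is_palindromic("A", "G"))
  expect_identical(is_palindromic(c("a", "g"), c("t", "c")),
                   c(TRUE, TRUE))
  expect_error(is_palindromic("A", "N"), "invalid allele")
})

test_that("orientation follows the exposure effect allele", {
  # printed statistics of rs6698680: exposure effect allele G,
  # outcome reported for allele A -> outcome flipped onto G
  exposure <- read_toy(toy_table(snp = "rs6698680", effect_allele = "G",
                                 other_allele = "A", eaf = 0.464,
                                 beta = -0.012, se = 0.002,
                                 pvalue = 8.99e-10, chr = 1L, pos = 2329661L,
                                 gene = "RER1", n = NA))
  outcome <- read_toy(toy_table(snp = "rs6698680", effect_allele = "A",
                                other_allele = "G", eaf = 0.5311,
                                beta = 0.0085, se = 0.0297, pvalue = 0.775,
                                chr = 1L, pos = 2329661L, gene = NA,
                                n = 17022), schema = "outcome")
  dat <- harmonize(exposure, outcome, mr_config())
  expect_equal(dat$action, "flipped")
  expect_equal(dat$beta_out, -0.0085)
  expect_equal(dat$eaf_out, 1 - 0.5311)
  expect_equal(dat$beta_exp, -0.012)   # exposure side untouched

  # identical orientation: everything unchanged
  same <- harmonize(exposure,
                    read_toy(toy_table(snp = "rs6698680", effect_allele = "G",
                                       other_allele = "A", eaf = 0.4689,
                                       beta = -0.0085, se = 0.0297,
                                       pvalue = 0.775, chr = 1L,
                                       pos = 2329661L, gene = NA, n = 17022),
                             schema = "outcome"),
                    mr_config())
  expect_equal(same$action, "none")
  expect_equal(same$beta_out, -0.0085)
})

test_that("strand-complemented records match; incompatible alleles are excluded", {
  exposure <- read_toy(toy_table(snp = c("rs1", "rs2"),
                                 effect_allele = c("A", "A"),
                                 other_allele = c("G", "G"),
                                 beta = c(0.02, 0.02), se = c(0.004, 0.004),
                                 eaf = c(0.25, 0.25), pvalue = c(1e-9, 1e-9),
                                 n = c(NA, NA), chr = c(1L, 1L),
                                 pos = c(1L, 2L), gene = c(NA, NA)))
  # rs1 reported on the other strand (T/C = complement of A/G);
  # rs2 with alleles that match under no convention
  outcome <- read_toy(toy_table(snp = c("rs1", "rs2"),
                                effect_allele = c("T", "A"),
                                other_allele = c("C", "C"),
                                beta = c(0.01, 0.01), se = c(0.02, 0.02),
                                eaf = c(0.26, 0.5), pvalue = c(0.5, 0.5),
                                n = c(1e4, 1e4), chr = c(1L, 1L),
                                pos = c(1L, 2L), gene = c(NA, NA)),
                      schema = "outcome")
  dat <- harmonize(exposure, outcome, mr_config())
  expect_identical(dat$snp, "rs1")
  expect_equal(dat$beta_out, 0.01)
  excl <- attr(dat, "exclusions")
  expect_identical(excl$snp, "rs2")
  expect_identical(excl$reason, "allele_mismatch")
})

test_that("harmonization is involutive: flipping twice restores the record", {
  flip <- function(beta, eaf) list(beta = -beta, eaf = 1 - eaf)
  b <- 0.0085; f <- 0.5311
  once <- flip(b, f)
  twice <- flip(once$beta, once$eaf)
  expect_identical(twice$beta, b)
  expect_identical(twice$eaf, f)
  # and through the full layer: harmonize, write the harmonized outcome
  # back in exposure orientation, harmonize again -> action "none"
  exposure <- read_toy(toy_table())
  swapped <- toy_table()
  swapped[, c("effect_allele", "other_allele")] <-
    swapped[, c("other_allele", "effect_allele")]
  swapped$beta <- -swapped$beta
  swapped$eaf <- 1 - swapped$eaf
  dat <- harmonize(exposure, read_toy(swapped, schema = "outcome"), mr_config())
  expect_true(all(dat$action == "flipped"))
  expect_equal(dat$beta_out, toy_table()$beta)
})

test_that("palindrome policies reproduce the published instrument counts", {
  expect_equal(nrow(caries_data("primary")), 79L)
  expect_equal(nrow(caries_data("permanent")), 79L)
  expect_equal(nrow(caries_data("dmfs")), 78L)
  # the DMFS frequency filter removes exactly the two published variants
  excl <- attr(caries_data("dmfs"), "exclusions")
  expect_setequal(excl$snp[excl$reason == "palindromic_ambiguous"],
                  c("rs10127775", "rs10832289"))
  # paediatric outcomes keep palindromic variants under assume-forward
  expect_true("rs10127775" %in% caries_data("primary")$snp)
})

test_that("drop-all removes every palindromic variant", {
  cfg <- mr_config(palindrome_policy = "drop-all")
  dat <- harmonize(vitd_exposure(), caries_outcome("dmfs"), cfg)
  expect_false(any(dat$palindromic))
  excl <- attr(dat, "exclusions")
  expect_true(sum(excl$reason == "palindromic") > 0)
})

test_that("count conservation: retained + excluded = exposure records", {
  for (oc in c("primary", "permanent", "dmfs")) {
    dat <- caries_data(oc)
    expect_equal(nrow(dat) + nrow(attr(dat, "exclusions")), 83L)
  }
  # also under a policy that excludes more
  cfg <- mr_config(palindrome_policy = "drop-all")
  dat <- harmonize(vitd_exposure(), caries_outcome("primary"), cfg)
  expect_equal(nrow(dat) + nrow(attr(dat, "exclusions")), 83L)
})

test_that("disjoint snp sets raise 'no usable instruments'", {
  a <- read_toy(toy_table())
  b <- read_toy(toy_table(snp = c("rsX", "rsY", "rsZ")), schema = "outcome")
  expect_error(harmonize(a, b, mr_config()), "no usable instruments")
})

test_that("exclusion report is emitted as TSV", {
  dat <- caries_data("dmfs")
  p <- tempfile(fileext = ".tsv")
  exclusion_report(dat, p)
  rep <- read.delim(p)
  expect_identical(names(rep), c("snp", "outcome", "reason", "detail"))
  expect_equal(nrow(rep), 5L)  # 3 missing + 2 ambiguous palindromes
})
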