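test_that("Wald ratios follow the first-order delta method", {
  d <- fake_mr_data(beta_exp = 0.1, beta_out = 0.02, se_out = 0.01)
  r <- wald_ratios(d)
  expect_equal(r$ratio, 0.2)
  expect_equal(r$se, 0.1)
  expect_equal(r$weight, 100)
  # zero outcome beta -> zero ratio; simultaneous sign flip -> same ratio
  expect_equal(wald_ratios(fake_mr_data(0.1, 0, 0.01))$ratio, 0)
  flipped <- wald_ratios(fake_mr_data(-0.1, -0.02, 0.01))
  expect_equal(flipped$ratio, r$ratio)
  expect_equal(flipped$se, r$se)
})

test_that("instruments with zero exposure beta are dropped, not fatal", {
  d <- fake_mr_data(beta_exp = c(0, 0.1, 0.2),
                    beta_out = c(0.01, 0.02, 0.04),
                    se_out = c(0.01, 0.01, 0.01))
  expect_message(r <- wald_ratios(d), "zero exposure beta")
  expect_equal(nrow(r), 2L)
  d0 <- fake_mr_data(0, 0.01, 0.01)
  expect_error(suppressMessages(wald_ratios(d0)), "undefined ratio")
})

test_that("IVW matches the closed-form weighted mean", {
  ratios <- data.frame(snp = c("a", "b"), ratio = c(0.2, 0.05),
                       se = c(0.1, 0.1), weight = c(100, 100))
  fe <- mr_ivw(ratios, "fe")
  expect_equal(fe$beta, 0.125)
  expect_equal(fe$se, sqrt(1 / 200))
  # identical ratios: estimate = common value, mre falls back to fe width
  same <- data.frame(snp = letters[1:3], ratio = rep(0.3, 3),
                     se = rep(0.05, 3), weight = rep(400, 3))
  expect_equal(mr_ivw(same, "mre")$beta, 0.3)
  expect_equal(mr_ivw(same, "mre")$se, mr_ivw(same, "fe")$se)
  # point estimate is variant-independent
  d <- random_mr_data(20, seed = 5)
  expect_equal(mr_ivw(wald_ratios(d), "mre")$beta,
               mr_ivw(wald_ratios(d), "fe")$beta)
  # single ratio with mre falls back with a warning
  expect_warning(one <- mr_ivw(ratios[1, ], "mre"), "single instrument")
  expect_equal(one$beta, 0.2)
  expect_error(mr_ivw(ratios[0, ]), "at least one")
})

test_that("IVW equals a brute-force weighted through-origin regression", {
  # oracle: minimize sum w (y - b x)^2 with w = 1/se_out^2 by the normal
  # equation b = sum(w x y) / sum(w x^2)
  for (seed in 1:25) {
    d <- random_mr_data(sample(5:40, 1), seed = seed)
    w <- 1 / d$se_out^2
    oracle <- sum(w * d$beta_exp * d$beta_out) / sum(w * d$beta_exp^2)
    expect_equal(mr_ivw(wald_ratios(d), "fe")$beta, oracle, tolerance = 1e-12)
  }
})

test_that("weighted median interpolates the 0.5 breakpoint", {
  # equal weights on {1, 2, 10}: middle breakpoint is exactly 0.5
  ratios <- data.frame(snp = c("a", "b", "c"), ratio = c(1, 2, 10),
                       se = rep(1, 3), weight = rep(1, 3))
  wm <- mr_weighted_median(ratios, reps = 50, seed = 1)
  expect_equal(wm$beta, 2)
  # all weight effectively on one variant returns that variant's ratio
  dom <- data.frame(snp = c("a", "b", "c"), ratio = c(1, 5, 9),
                    se = c(10, 1e-4, 10), weight = c(0.01, 1e8, 0.01))
  expect_equal(mr_weighted_median(dom, reps = 50, seed = 1)$beta, 5)
  # identical ratios: estimate equals the common value
  same <- data.frame(snp = c("a", "b", "c"), ratio = rep(0.7, 3),
                     se = rep(0.1, 3), weight = rep(100, 3))
  expect_equal(mr_weighted_median(same, reps = 50, seed = 1)$beta, 0.7)
  expect_error(mr_weighted_median(ratios, reps = 1), "at least 2")
  expect_error(mr_weighted_median(ratios[1:2, ], reps = 10), "3 instruments")
})

test_that("weighted-median bootstrap is seeded and leaves the RNG alone", {
  d <- random_mr_data(15, seed = 3)
  r <- wald_ratios(d)
  a <- mr_weighted_median(r, reps = 200, seed = 99)
  b <- mr_weighted_median(r, reps = 200, seed = 99)
  expect_identical(a$se, b$se)
  c2 <- mr_weighted_median(r, reps = 200, seed = 100)
  expect_false(identical(a$se, c2$se))
  set.seed(42); x1 <- runif(1)
  set.seed(42); invisible(mr_weighted_median(r, reps = 10, seed = 1)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("Egger recovers an exact linear relationship", {
  set.seed(8)
  x <- runif(10, 0.01, 0.2)
  d <- fake_mr_data(beta_exp = x, beta_out = 0.01 + 0.5 * x,
                    se_out = runif(10, 0.01, 0.05))
  e <- mr_egger(d)
  expect_equal(e$beta[e$method == "egger-slope"], 0.5, tolerance = 1e-10)
  expect_equal(e$beta[e$method == "egger-intercept"], 0.01, tolerance = 1e-10)
  expect_error(mr_egger(d[1:2, ]), ">=3")
})

test_that("Egger matches a weighted lm fit (independent oracle)", {
  for (seed in 1:10) {
    d <- random_mr_data(sample(5:40, 1), seed = 100 + seed)
    sgn <- ifelse(d$beta_exp < 0, -1, 1)
    fit <- lm(I(d$beta_out * sgn) ~ I(d$beta_exp * sgn),
              weights = 1 / d$se_out^2)
    sm <- summary(fit)
    e <- mr_egger(d)
    expect_equal(e$beta[e$method == "egger-intercept"],
                 unname(coef(fit)[1]), tolerance = 1e-10)
    expect_equal(e$beta[e$method == "egger-slope"],
                 unname(coef(fit)[2]), tolerance = 1e-10)
    # lm SEs carry the residual scale; the package floors it at 1
    expect_equal(e$se[e$method == "egger-slope"],
                 unname(sm$coefficients[2, 2]) / min(1, sm$sigma),
                 tolerance = 1e-10)
  }
})

test_that("all estimators are invariant to per-variant sign flips", {
  d <- random_mr_data(21, seed = 17)
  flip <- rep(c(1, -1), length.out = 21)
  d2 <- d
  d2$beta_exp <- d$beta_exp * flip
  d2$beta_out <- d$beta_out * flip
  expect_equal(mr_ivw(wald_ratios(d2))$beta, mr_ivw(wald_ratios(d))$beta)
  expect_equal(mr_weighted_median(wald_ratios(d2), reps = 50, seed = 1)$beta,
               mr_weighted_median(wald_ratios(d), reps = 50, seed = 1)$beta)
  e1 <- mr_egger(d); e2 <- mr_egger(d2)
  expect_equal(e2$beta, e1$beta)
  expect_equal(e2$se, e1$se)
})

test_that("mr_fit collects methods and exposes coef/confint", {
  d <- random_mr_data(12, seed = 2)
  fit <- mr_fit(d, wm_reps = 50, seed = 1)
  expect_s3_class(fit, "mr_fit")
  expect_setequal(fit$results$method,
                  c("ivw-mre", "weighted-median", "egger-slope",
                    "egger-intercept"))
  expect_named(coef(fit), fit$results$method)
  ci <- confint(fit)
  expect_equal(unname(ci[, 1]),
               fit$results$beta - qnorm(0.975) * fit$results$se)
  expect_true(all(fit$results$ci_low < fit$results$ci_high))
  expect_output(print(summary(fit)), "Cochran Q")
})
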