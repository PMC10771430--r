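# MR estimators, directionality, multiplicity and power.

test_that("Wald ratio follows the delta-method closed form", {
  h <- toy_harmonized(bx = 0.5, by = 0.1, se_y = 0.02)
  w <- wald_ratio(h)
  expect_equal(w$beta, 0.2)
  expect_equal(w$se, 0.04)
  null <- wald_ratio(toy_harmonized(bx = 0.5, by = 0))
  expect_equal(null$beta, 0)
  expect_equal(null$pval, 1)
  expect_error(wald_ratio(toy_harmonized(bx = 0, by = 0.1)), "bx = 0")
  # second-order option adds the exposure-side term
  w2 <- wald_ratio(toy_harmonized(bx = 0.5, by = 0.1, se_x = 0.1,
                                  se_y = 0.02), second_order = TRUE)
  expect_gt(w2$se, w$se)
})

test_that("Wald estimates recover the simulated causal effect", {
  reps <- 500
  est <- numeric(reps)
  for (i in seq_len(reps)) {
    r <- simulate_region(sim_config(n_snps = 11, n_exposure = 3000,
                                    n_outcome = 50000,
                                    causal_model = "shared_causal",
                                    theta = 0.3, r2_instrument = 0.1,
                                    seed = 40000L + i))
    idx <- r$truth$causal_idx_exposure
    h <- harmonize(r$tables$protein, r$tables$outcome)
    est[i] <- wald_ratio(h[idx, , drop = FALSE])$beta
  }
  expect_lt(abs(mean(est) - 0.3), 0.02)
})

test_that("IVW equals its weighted-least-squares oracle", {
  set.seed(21)
  h <- toy_harmonized(bx = rnorm(10, 0.2, 0.05), by = rnorm(10, 0.06, 0.02),
                      se_y = runif(10, 0.01, 0.05))
  fit <- mr_ivw(h)
  oracle <- lm(by ~ 0 + bx, data = h, weights = 1 / h$se_y^2)
  expect_equal(fit$beta, unname(coef(oracle)[1]), tolerance = 1e-10)
  # oracle se: lm scales by sqrt(Q/df); ours uses max(1, Q/df)
  q <- attr(fit, "Q")
  df <- nrow(h) - 1
  se_fixed <- sqrt(1 / sum(h$bx^2 / h$se_y^2))
  se_expected <- if (q / df > 1) summary(oracle)$coefficients[1, 2] else se_fixed
  expect_equal(fit$se, se_expected, tolerance = 1e-10)
})

test_that("IVW degenerates to the Wald ratio for identical instruments", {
  h <- toy_harmonized(bx = rep(0.4, 3), by = rep(0.1, 3),
                      se_y = rep(0.02, 3))
  expect_equal(mr_ivw(h)$beta, 0.25)
  expect_equal(mr_ivw(h)$beta, wald_ratio(h[1, ])$beta)
  # two instruments with equal weights average the ratios
  h2 <- toy_harmonized(bx = c(1, 1), by = c(0.1, 0.3), se_y = c(0.1, 0.1))
  expect_equal(mr_ivw(h2)$beta, 0.2)
  expect_error(mr_ivw(h2[1, ]), "wald_ratio")
})

test_that("MR-Egger matches a weighted regression with intercept", {
  set.seed(22)
  h <- toy_harmonized(bx = runif(8, 0.1, 0.5),
                      by = 0.02 + 0.3 * runif(8, 0.1, 0.5) + rnorm(8, 0, 0.01),
                      se_y = runif(8, 0.01, 0.03))
  h$by <- 0.02 + 0.3 * h$bx + rnorm(8, 0, 0.01)
  fit <- mr_egger(h)
  oracle <- lm(by ~ bx, data = h, weights = 1 / h$se_y^2)
  expect_equal(fit$beta, unname(coef(oracle)["bx"]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(coef(oracle)["(Intercept)"]),
               tolerance = 1e-10)
  expect_error(mr_egger(h[1:2, ]), ">= 3")
})

test_that("the Egger intercept test is calibrated without pleiotropy", {
  reps <- 300
  inside <- 0
  for (i in seq_len(reps)) {
    h <- simulate_mr_instruments(30, theta = 0.2, n_exposure = 50000,
                                 n_outcome = 50000, seed = 50000L + i)
    fit <- mr_egger(h)
    if (abs(fit$intercept / fit$intercept_se) < 1.96) inside <- inside + 1
  }
  expect_gte(inside / reps, 0.93)
})

test_that("weighted median resists 40% directional pleiotropy where IVW fails", {
  reps <- 500
  theta <- 0.3
  med <- ivw <- numeric(reps)
  for (i in seq_len(reps)) {
    pleio <- c(rep(0.09, 4), rep(0, 6))   # 40% of instruments biased upward
    h <- simulate_mr_instruments(10, theta = theta, n_outcome = 50000,
                                 r2_per_snp = 0.02,
                                 pleiotropy = pleio, seed = 60000L + i)
    med[i] <- mr_weighted_median(h, nboot = 0)$beta
    ivw[i] <- mr_ivw(h)$beta
  }
  expect_lt(abs(mean(med) - theta), 0.05)
  expect_gt(abs(mean(ivw) - theta), 0.05)
})

test_that("all estimators agree when every ratio is identical", {
  h <- toy_harmonized(bx = c(0.2, 0.3, 0.4, 0.5),
                      by = 0.3 * c(0.2, 0.3, 0.4, 0.5),
                      se_y = rep(0.02, 4))
  expect_equal(mr_ivw(h)$beta, 0.3)
  # a perfect fit: lm warns about zero residuals, the slope is exact
  expect_equal(suppressWarnings(mr_egger(h)$beta), 0.3, tolerance = 1e-9)
  expect_equal(mr_weighted_median(h, nboot = 0)$beta, 0.3)
  expect_equal(mr_weighted_mode(h, nboot = 0)$beta, 0.3, tolerance = 1e-6)
})

test_that("Steiger orders explained variances and handles the boundary", {
  fwd <- mr_steiger(toy_harmonized(bx = sqrt(0.1 / (2 * 0.3 * 0.7)),
                                   by = sqrt(1e-4 / (2 * 0.3 * 0.7))))
  expect_true(fwd$direction_true)
  eq <- mr_steiger(toy_harmonized(bx = 0.2, by = 0.2, n_x = 5000,
                                  n_y = 5000))
  expect_false(eq$direction_true)
  expect_equal(eq$pval, 1)
  h <- toy_harmonized(bx = 0.2, by = 0.1)
  h$eaf <- NA
  expect_error(mr_steiger(h), "eaf")
})

test_that("Bonferroni thresholds reduce to alpha/m", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 20), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0), "m")
})

test_that("analytic power behaves at its boundaries and monotonically", {
  expect_equal(mr_power(10000, 0.1, 0, 1, alpha = 0.05), 0.05)
  p1 <- mr_power(10000, 0.05, 0.1, 1.3)
  p2 <- mr_power(40000, 0.05, 0.1, 1.3)
  expect_gt(p2, p1)
  expect_lte(p2, 1)
  expect_error(mr_power(-1, 0.1, 0.1, 1))
})

test_that("weak instruments inflate Wald bias relative to strong ones", {
  # F ~ 5 vs F ~ 100 at matched theta: |bias| must grow as F shrinks
  reps <- 400
  theta <- 0.3
  est_weak <- est_strong <- numeric(reps)
  n_x <- 1000
  r2_weak <- 5 / (5 + n_x - 2)          # r2 giving F ~ 5
  r2_strong <- 100 / (100 + n_x - 2)
  for (i in seq_len(reps)) {
    hw <- simulate_mr_instruments(1, theta, n_exposure = n_x,
                                  n_outcome = 50000, r2_per_snp = r2_weak,
                                  seed = 70000L + i)
    hs <- simulate_mr_instruments(1, theta, n_exposure = n_x,
                                  n_outcome = 50000, r2_per_snp = r2_strong,
                                  seed = 80000L + i)
    est_weak[i] <- hw$by / hw$bx
    est_strong[i] <- hs$by / hs$bx
  }
  expect_gt(abs(median(est_weak) - theta), abs(median(est_strong) - theta))
})

test_that("MR results export with confidence intervals and flags", {
  path <- withr::local_tempfile(fileext = ".tsv")
  h <- toy_harmonized(bx = c(0.2, 0.3, 0.4), by = c(0.07, 0.085, 0.125))
  write_mr_results(list(mr_ivw(h), mr_egger(h)), path,
                   bonferroni_alpha = 1e-3)
  back <- read.delim(path)
  expect_equal(back$method, c("ivw", "egger"))
  expect_true(all(back$ci_low < back$ci_high))
})
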