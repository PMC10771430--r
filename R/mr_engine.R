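# Two-sample MR estimators, Steiger directionality, Bonferroni control,
# and analytic power.

new_mr_result <- function(method, beta, se, n_snp, intercept = NA_real_,
                          intercept_se = NA_real_,
                          exposure = NA_character_, outcome = NA_character_) {
  structure(list(method = method, beta = beta, se = se,
                 pval = 2 * stats::pnorm(-abs(beta / se)),
                 n_snp = as.integer(n_snp),
                 intercept = intercept, intercept_se = intercept_se,
                 intercept_pval = if (is.na(intercept)) NA_real_ else
                   2 * stats::pnorm(-abs(intercept / intercept_se)),
                 exposure = exposure, outcome = outcome),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR (%s): %s -> %s\n", x$method,
              ifelse(is.na(x$exposure), "exposure", x$exposure),
              ifelse(is.na(x$outcome), "outcome", x$outcome)))
  ci <- x$beta + c(-1, 1) * stats::qnorm(0.975) * x$se
  cat(sprintf("  beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g, n_snp = %d\n",
              x$beta, x$se, ci[1], ci[2], x$pval, x$n_snp))
  if (!is.na(x$intercept)) {
    cat(sprintf("  egger intercept = %.4f (se %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_pval))
  }
  invisible(x)
}

trait_labels <- function(h) {
  c(exposure = attr(h, "exposure_trait") %||% NA_character_,
    outcome = attr(h, "outcome_trait") %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wald ratio (single-instrument MR)
#'
#' `beta = by / bx` with the first-order delta-method standard error
#' `|se_y / bx|` (the convention of standard two-sample MR tooling, which
#' ignores the exposure-side uncertainty); optionally the second-order
#' delta method including `se_x`.
#'
#' @param row one row of a `harmonized_set` (needs `bx`, `by`, `se_y`, and
#'   `se_x` for the second-order option).
#' @param second_order include the exposure-side variance term in the se.
#' @return an `mr_result` with `method = "wald"`.
#' @export
wald_ratio <- function(row, second_order = FALSE) {
  if (nrow(row) != 1L) stop("wald_ratio takes a single harmonized row")
  if (row$bx == 0) stop("Wald ratio undefined: bx = 0")
  beta <- row$by / row$bx
  se <- abs(row$se_y / row$bx)
  if (second_order) {
    se <- sqrt(row$se_y^2 / row$bx^2 + row$by^2 * row$se_x^2 / row$bx^4)
  }
  lab <- trait_labels(row)
  new_mr_result("wald", beta, se, 1L, exposure = lab[["exposure"]],
                outcome = lab[["outcome"]])
}

#' Inverse-variance-weighted MR
#'
#' The fixed-effect IVW estimate is the weighted mean of per-variant Wald
#' ratios with weights `(bx / se_y)^2`, equivalently the zero-intercept
#' weighted regression of `by` on `bx` with weights `1 / se_y^2`. When the
#' heterogeneity statistic Q exceeds its degrees of freedom, the standard
#' error is inflated multiplicatively by `sqrt(Q / (n - 1))`
#' (multiplicative random effects).
#'
#' @param h a `harmonized_set` with at least two rows.
#' @return an `mr_result` with `method = "ivw"` and a `Q` attribute.
#' @export
mr_ivw <- function(h) {
  if (nrow(h) < 2L) stop("IVW needs >= 2 instruments; use wald_ratio()")
  w <- 1 / h$se_y^2
  beta <- sum(w * h$bx * h$by) / sum(w * h$bx^2)
  se <- sqrt(1 / sum(w * h$bx^2))
  q <- sum(w * (h$by - beta * h$bx)^2)
  df <- nrow(h) - 1L
  if (q / df > 1) se <- se * sqrt(q / df)
  lab <- trait_labels(h)
  out <- new_mr_result("ivw", beta, se, nrow(h),
                       exposure = lab[["exposure"]], outcome = lab[["outcome"]])
  attr(out, "Q") <- q
  out
}

#' MR-Egger regression
#'
#' Weighted regression of `by` on `bx` with an intercept (weights
#' `1 / se_y^2`). The slope is the pleiotropy-adjusted causal estimate; a
#' non-zero intercept indicates directional pleiotropy. Instruments are
#' oriented so all `bx >= 0` before fitting (the estimator is defined up to
#' that orientation).
#'
#' @param h a `harmonized_set` with at least three rows.
#' @return an `mr_result` with `method = "egger"`, including the intercept
#'   and its test.
#' @export
mr_egger <- function(h) {
  if (nrow(h) < 3L) stop("MR-Egger needs >= 3 instruments")
  flip <- sign(h$bx); flip[flip == 0] <- 1
  bx <- h$bx * flip; by <- h$by * flip
  fit <- stats::lm(by ~ bx, weights = 1 / h$se_y^2)
  sm <- summary(fit)$coefficients
  lab <- trait_labels(h)
  new_mr_result("egger", sm["bx", 1], sm["bx", 2], nrow(h),
                intercept = sm["(Intercept)", 1],
                intercept_se = sm["(Intercept)", 2],
                exposure = lab[["exposure"]], outcome = lab[["outcome"]])
}

ratio_and_weights <- function(h) {
  list(ratio = h$by / h$bx, w = (h$bx / h$se_y)^2)
}

weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  ratio <- ratio[ord]; w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(ratio[1])
  if (cum[length(cum)] <= 0.5) return(ratio[length(ratio)])
  i <- max(which(cum < 0.5))
  ratio[i] + (ratio[i + 1] - ratio[i]) * (0.5 - cum[i]) / (cum[i + 1] - cum[i])
}

weighted_mode_point <- function(ratio, w, bandwidth_mult = 1.5) {
  s <- sqrt(sum(w / sum(w) * (ratio - sum(w / sum(w) * ratio))^2))
  mad <- stats::mad(ratio)
  disp <- min(s, if (mad > 0) mad else s)
  if (!is.finite(disp) || disp == 0) return(ratio[1])
  bw <- bandwidth_mult * 0.9 * disp * length(ratio)^(-1 / 5)
  d <- stats::density(ratio, weights = w / sum(w), bw = bw)
  d$x[which.max(d$y)]
}

boot_estimates <- function(h, point_fun, nboot, seed) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  est <- numeric(nboot)
  n <- nrow(h)
  for (i in seq_len(nboot)) {
    bx <- stats::rnorm(n, h$bx, h$se_x)
    by <- stats::rnorm(n, h$by, h$se_y)
    est[i] <- point_fun(by / bx, (bx / h$se_y)^2)
  }
  est
}

#' Weighted-median MR
#'
#' The median of the per-variant ratio estimates under cumulative
#' inverse-variance weights: consistent when at least half the weight comes
#' from valid instruments. The standard error is obtained by parametric
#' bootstrap (resampling `bx`, `by` from their sampling distributions).
#'
#' @param h a `harmonized_set` with at least three rows.
#' @param nboot parametric bootstrap draws for the standard error; below 2
#'   the bootstrap is skipped and the se is `NA` (point estimate only).
#' @param seed bootstrap seed (fixed default for reproducibility).
#' @return an `mr_result` with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(h, nboot = 5000, seed = 20240106L) {
  if (nrow(h) < 3L) stop("weighted median needs >= 3 instruments")
  rw <- ratio_and_weights(h)
  beta <- weighted_median_point(rw$ratio, rw$w)
  se <- if (nboot >= 2)
    stats::sd(boot_estimates(h, weighted_median_point, nboot, seed)) else
    NA_real_
  lab <- trait_labels(h)
  new_mr_result("weighted_median", beta, se, nrow(h),
                exposure = lab[["exposure"]], outcome = lab[["outcome"]])
}

#' Weighted-mode MR
#'
#' The mode of a kernel-smoothed, inverse-variance-weighted density of the
#' per-variant ratio estimates: consistent when the largest group of
#' instruments sharing a ratio is valid. Bandwidth is `bandwidth_mult`
#' times a Silverman-style rule on the weighted ratios; the standard error
#' comes from a parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_mult multiplier on the Silverman-style bandwidth.
#' @return an `mr_result` with `method = "weighted_mode"`.
#' @export
mr_weighted_mode <- function(h, nboot = 5000, seed = 20240106L,
                             bandwidth_mult = 1.5) {
  if (nrow(h) < 3L) stop("weighted mode needs >= 3 instruments")
  rw <- ratio_and_weights(h)
  point <- function(ratio, w) weighted_mode_point(ratio, w, bandwidth_mult)
  beta <- point(rw$ratio, rw$w)
  se <- if (nboot >= 2) stats::sd(boot_estimates(h, point, nboot, seed)) else
    NA_real_
  lab <- trait_labels(h)
  new_mr_result("weighted_mode", beta, se, nrow(h),
                exposure = lab[["exposure"]], outcome = lab[["outcome"]])
}

#' Steiger directionality test
#'
#' Compares the variance the instrument explains in the exposure against
#' the variance it explains in the outcome (both via the standardized-scale
#' approximation `2 beta^2 f (1 - f)`). The causal direction is declared
#' TRUE when the instrument explains more exposure than outcome variance.
#' The p-value tests equality of the implied correlations via Fisher's
#' z-transform with the two samples' sizes.
#'
#' @param row one row of a `harmonized_set` (needs `bx`, `by`, `eaf`,
#'   `n_x`, `n_y`).
#' @return an object of class `steiger_result`: list with `r2_exposure`,
#'   `r2_outcome`, `direction_true`, `pval`.
#' @export
mr_steiger <- function(row) {
  if (nrow(row) != 1L) stop("mr_steiger takes a single harmonized row")
  if (is.na(row$eaf)) stop("Steiger test requires eaf")
  r2x <- variance_explained(row$bx, row$eaf)
  r2y <- variance_explained(row$by, row$eaf)
  rx <- sqrt(min(r2x, 1 - 1e-12))
  ry <- sqrt(min(r2y, 1 - 1e-12))
  z <- (atanh(rx) - atanh(ry)) / sqrt(1 / (row$n_x - 3) + 1 / (row$n_y - 3))
  structure(list(r2_exposure = r2x, r2_outcome = r2y,
                 direction_true = r2x > r2y,
                 pval = 2 * stats::pnorm(-abs(z))),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf("Steiger: r2_exposure = %.3g, r2_outcome = %.3g -> %s (p = %.3g)\n",
              x$r2_exposure, x$r2_outcome,
              ifelse(x$direction_true, "TRUE", "FALSE"), x$pval))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests (distinct proteins tested).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (any(m < 1)) stop("m must be >= 1")
  alpha / m
}

#' Analytic power for two-sample MR with a continuous outcome
#'
#' Brion-style power calculation: with the causal effect expressed in
#' outcome-SD units `b = effect_years / outcome_sd_years`, the Wald test
#' statistic is asymptotically `N(b * sqrt(n * R2), 1)` under the
#' alternative, so power at two-sided level `alpha` is
#' `pnorm(-z_{1-alpha/2} + |b| sqrt(n R2)) + pnorm(-z_{1-alpha/2} - |b| sqrt(n R2))`.
#'
#' @param n_outcome outcome GWAS sample size.
#' @param r2_instrument variance of the exposure explained by the
#'   instrument.
#' @param effect_years causal effect in outcome units (e.g. years) per SD
#'   of exposure.
#' @param outcome_sd_years SD of the outcome in the same units.
#' @param alpha two-sided significance level.
#' @return power in [0, 1].
#' @export
mr_power <- function(n_outcome, r2_instrument, effect_years,
                     outcome_sd_years, alpha = 0.05) {
  stopifnot(n_outcome > 0, r2_instrument > 0, outcome_sd_years > 0,
            alpha > 0, alpha < 1)
  b <- effect_years / outcome_sd_years
  ncp <- abs(b) * sqrt(n_outcome * r2_instrument)
  zc <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(-zc + ncp) + stats::pnorm(-zc - ncp)
}

#' Run all multi-instrument MR methods on one harmonized set
#'
#' Convenience wrapper running IVW, MR-Egger, weighted median and weighted
#' mode (skipping, with a note, any method whose minimum instrument count
#' is not met).
#'
#' @param h a `harmonized_set`.
#' @param nboot bootstrap draws for median/mode standard errors.
#' @param seed bootstrap seed.
#' @return named list of `mr_result` objects.
#' @export
mr_all_methods <- function(h, nboot = 1000, seed = 20240106L) {
  out <- list()
  if (nrow(h) >= 2L) out$ivw <- mr_ivw(h)
  if (nrow(h) >= 3L) {
    out$egger <- mr_egger(h)
    out$weighted_median <- mr_weighted_median(h, nboot = nboot, seed = seed)
    out$weighted_mode <- mr_weighted_mode(h, nboot = nboot, seed = seed)
  } else {
    message("fewer than 3 instruments: Egger/median/mode skipped")
  }
  out
}

#' Export MR results as a forest-plot-ready TSV
#'
#' @param results list of `mr_result` objects.
#' @param path output path.
#' @param bonferroni_alpha per-test threshold used for the
#'   `passes_bonferroni` flag (e.g. `bonferroni_threshold(0.05, m)`).
#' @export
write_mr_results <- function(results, path, bonferroni_alpha = 0.05) {
  rows <- lapply(results, function(r) {
    ci <- r$beta + c(-1, 1) * stats::qnorm(0.975) * r$se
    data.frame(exposure = r$exposure, outcome = r$outcome, method = r$method,
               n_snp = r$n_snp, beta = r$beta, se = r$se,
               ci_low = ci[1], ci_high = ci[2], pval = r$pval,
               passes_bonferroni = r$pval < bonferroni_alpha,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
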