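# Two-step network MR with Sobel inference, and multivariable MR.

#' Two-step mediation with the Sobel test
#'
#' Decomposes a protein -> outcome effect into the part running through a
#' mediator (e.g. BMI) and the rest. The indirect effect is the product of
#' the two path estimates, `a * b`; its standard error is the first-order
#' Sobel formula `sqrt(a^2 se_b^2 + b^2 se_a^2)` (optionally the
#' second-order variant adding `se_a^2 se_b^2`), with a two-sided normal
#' test. The proportion mediated is `indirect / total` and is reported
#' unclamped, with a warning outside [0, 1].
#'
#' @param step1 `mr_result` for protein -> mediator (effect `a`).
#' @param step2 `mr_result` for mediator -> outcome (effect `b`).
#' @param total `mr_result` for the univariable protein -> outcome effect.
#' @param second_order include the `se_a^2 se_b^2` term in the Sobel se.
#' @return object of class `mediation_result`: list with `a`, `se_a`, `b`,
#'   `se_b`, `indirect`, `se_indirect`, `pval`, `total`, `direct`
#'   (`total - indirect`), `proportion_mediated` (NA, flagged, when the
#'   total effect is zero).
#' @export
two_step_mediation <- function(step1, step2, total, second_order = FALSE) {
  a <- step1$beta; se_a <- step1$se
  b <- step2$beta; se_b <- step2$se
  indirect <- a * b
  v <- a^2 * se_b^2 + b^2 * se_a^2
  if (second_order) v <- v + se_a^2 * se_b^2
  se_indirect <- sqrt(v)
  z <- if (se_indirect > 0) indirect / se_indirect else 0
  prop <- NA_real_
  if (total$beta == 0) {
    warning("total effect is zero: proportion mediated undefined")
  } else {
    prop <- indirect / total$beta
    if (prop < 0 || prop > 1) {
      warning("proportion mediated outside [0, 1]: ", format(prop))
    }
  }
  structure(list(a = a, se_a = se_a, b = b, se_b = se_b,
                 indirect = indirect, se_indirect = se_indirect,
                 pval = 2 * stats::pnorm(-abs(z)),
                 total = total$beta, direct = total$beta - indirect,
                 proportion_mediated = prop),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Two-step mediation (Sobel):\n")
  cat(sprintf("  a = %.4f (se %.4f), b = %.4f (se %.4f)\n",
              x$a, x$se_a, x$b, x$se_b))
  cat(sprintf("  indirect = %.4f (se %.4f), p = %.3g\n",
              x$indirect, x$se_indirect, x$pval))
  cat(sprintf("  total = %.4f, proportion mediated = %s\n", x$total,
              ifelse(is.na(x$proportion_mediated), "NA",
                     sprintf("%.1f%%", 100 * x$proportion_mediated))))
  invisible(x)
}

#' Multivariable IVW MR
#'
#' Joint direct effects of several exposures: weighted regression (weights
#' `1 / se_y^2`, no intercept) of the variant-outcome effects on the matrix
#' of variant-exposure effects. The instrument set is the union of each
#' exposure's instruments; it must contain more variants than exposures and
#' the exposure-effect matrix must be full column rank.
#'
#' @param bx numeric matrix (variants x exposures) of exposure effects,
#'   with exposure names as column names.
#' @param by numeric vector of outcome effects.
#' @param se_y numeric vector of outcome standard errors.
#' @return object of class `mvmr_result`: list with `exposures`, `beta`,
#'   `se`, `pval` (each named by exposure) and `n_snp`.
#' @export
mvmr_ivw <- function(bx, by, se_y) {
  bx <- as.matrix(bx)
  if (is.null(colnames(bx))) colnames(bx) <- paste0("exposure_", seq_len(ncol(bx)))
  if (nrow(bx) < ncol(bx) + 1L) {
    stop("need at least n_exposures + 1 instruments")
  }
  # An exposure with no instrument signal at all (all-zero column)
  # contributes nothing and gets an NA estimate; collinearity among the
  # remaining exposures is an error.
  zero_col <- apply(bx, 2, function(x) all(x == 0))
  if (any(zero_col)) {
    warning("exposure(s) with all-zero instrument effects: ",
            paste(colnames(bx)[zero_col], collapse = ", "))
  }
  active <- bx[, !zero_col, drop = FALSE]
  if (ncol(active) == 0L) stop("no exposure has non-zero instrument effects")
  qrx <- qr(active)
  if (qrx$rank < ncol(active)) {
    dropped <- colnames(active)[qrx$pivot[seq(qrx$rank + 1L, ncol(active))]]
    stop("exposure effect matrix is rank deficient; collinear exposure(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(by ~ 0 + active, weights = 1 / se_y^2)
  sm <- summary(fit)$coefficients
  beta <- se <- stats::setNames(rep(NA_real_, ncol(bx)), colnames(bx))
  beta[!zero_col] <- sm[, 1]
  se[!zero_col] <- sm[, 2]
  structure(list(exposures = colnames(bx), beta = beta, se = se,
                 pval = 2 * stats::pnorm(-abs(beta / se)),
                 n_snp = nrow(bx)),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat("Multivariable IVW MR (", x$n_snp, " instruments):\n", sep = "")
  for (e in x$exposures) {
    cat(sprintf("  %s: direct beta = %.4f (se %.4f), p = %.3g\n",
                e, x$beta[[e]], x$se[[e]], x$pval[[e]]))
  }
  invisible(x)
}

#' Export mediation results as TSV
#'
#' @param results named list of `mediation_result` (names =
#'   "exposure|mediator|outcome" labels or similar).
#' @param path output path.
#' @export
write_mediation_results <- function(results, path) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(label = nm, a = r$a, se_a = r$se_a, b = r$b, se_b = r$se_b,
               indirect = r$indirect, se_indirect = r$se_indirect,
               p_sobel = r$pval, total = r$total,
               proportion = r$proportion_mediated, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
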