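# Bayesian colocalization: per-SNP approximate Bayes factors, the H0-H4
# enumeration under the single-causal-variant assumption, a
# sum-of-single-effects fine-mapper to relax that assumption, credible-set
# pairwise colocalization, and a simplified multi-trait extension.
#
# All accumulation is in log space (log-sum-exp), so |z| up to several
# hundred is safe.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; -Inf (with attr) when a <= b numerically
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Wakefield log approximate Bayes factor
#'
#' For an estimated effect `beta` with standard error `se` and a normal
#' effect prior with standard deviation `prior_sd`: with `V = se^2`,
#' `z = beta/se` and `r = prior_sd^2 / (prior_sd^2 + V)`,
#' `log ABF = 0.5 log(1 - r) + 0.5 z^2 r`.
#'
#' @param beta,se effect estimate and standard error (vectorized).
#' @param prior_sd prior effect SD (default 0.15, suited to standardized
#'   quantitative traits).
#' @return log ABF (association vs null), same length as `beta`.
#' @export
log_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0)) stop("se must be positive")
  v <- se^2
  z <- beta / se
  r <- prior_sd^2 / (prior_sd^2 + v)
  0.5 * log(1 - r) + 0.5 * z^2 * r
}

new_coloc_result <- function(pp, priors, n_snps, best_snp_h4,
                             component_pair = NULL) {
  names(pp) <- paste0("H", 0:4)
  structure(list(pp = pp, priors = priors, n_snps = as.integer(n_snps),
                 best_snp_h4 = best_snp_h4, component_pair = component_pair),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization posterior probabilities (", x$n_snps, " SNPs):\n",
      sep = "")
  print(round(x$pp, 4))
  if (!is.null(x$component_pair)) {
    cat("  component pair:", paste(x$component_pair, collapse = " x "), "\n")
  }
  if (!is.na(x$best_snp_h4)) cat("  best shared variant:", x$best_snp_h4, "\n")
  invisible(x)
}

# Core H0-H4 enumeration from two aligned per-SNP log Bayes factor vectors.
coloc_from_lbf <- function(l1, l2, snps, priors) {
  p1 <- priors[1]; p2 <- priors[2]; p12 <- priors[3]
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  lh <- c(0,
          log(p1) + s1,
          log(p2) + s2,
          log(p1) + log(p2) + logdiffexp(s1 + s2, s12),
          log(p12) + s12)
  # S1*S2 - S12 is exactly zero for a single-SNP region (warn: H3 is not
  # estimable there); in larger regions a non-positive value is benign
  # floating-point cancellation under one dominant shared signal
  if (!is.finite(lh[4])) {
    if (length(l1) == 1L) {
      warning("single-SNP region: H3 accumulator is zero by construction")
    }
    lh[4] <- -Inf
  }
  denom <- logsumexp(lh)
  pp <- exp(lh - denom)
  joint <- l1 + l2
  best <- snps[which.max(joint)]
  new_coloc_result(pp, c(p1 = p1, p2 = p2, p12 = p12), length(snps), best)
}

#' Bayesian colocalization of two traits (single causal variant)
#'
#' Enumerates the five sharing hypotheses over a region: H0 neither trait
#' associated, H1 only trait 1, H2 only trait 2, H3 both but through
#' distinct variants, H4 both through one shared variant. Per-SNP
#' evidence is the Wakefield ABF from each trait's beta/se; variants are
#' restricted to minor allele frequency above `maf_min` and, when
#' `center_pos` is given, to a window of `window` bp around it.
#'
#' @param t1,t2 `sumstats` tables sharing variant identifiers.
#' @param priors per-SNP prior probabilities `(p1, p2, p12)` of association
#'   with trait 1 only, trait 2 only, and both.
#' @param maf_min minor-allele-frequency filter (default 0.01).
#' @param window half-width in bp of the analysis window around
#'   `center_pos` (default 1 Mb; ignored when `center_pos` is `NULL`).
#' @param center_pos optional centre of the analysis window (e.g. the
#'   cis-pQTL position).
#' @param prior_sd effect prior SD passed to [log_abf()].
#' @return a `coloc_result`.
#' @export
coloc_abf <- function(t1, t2, priors = c(1e-4, 1e-4, 1e-5), maf_min = 0.01,
                      window = 1e6, center_pos = NULL, prior_sd = 0.15) {
  keep1 <- !is.na(t1$eaf) & pmin(t1$eaf, 1 - t1$eaf) > maf_min
  keep2 <- !is.na(t2$eaf) & pmin(t2$eaf, 1 - t2$eaf) > maf_min
  if (!is.null(center_pos)) {
    keep1 <- keep1 & abs(t1$pos - center_pos) <= window
    keep2 <- keep2 & abs(t2$pos - center_pos) <= window
  }
  shared <- intersect(t1$snp[keep1], t2$snp[keep2])
  if (length(shared) == 0L) stop("no shared variants after MAF/window filters")
  i1 <- match(shared, t1$snp)
  i2 <- match(shared, t2$snp)
  l1 <- log_abf(t1$beta[i1], t1$se[i1], prior_sd)
  l2 <- log_abf(t2$beta[i2], t2$se[i2], prior_sd)
  coloc_from_lbf(l1, l2, shared, priors)
}

#' Sum-of-single-effects fine-mapping from summary statistics
#'
#' Iterative Bayesian stepwise selection of up to `L` single-effect
#' components from z-scores and an LD matrix (the summary-statistic
#' formulation with standardized genotypes and phenotype: `X'X = n R`,
#' `X'y = sqrt(n) z`, residual variance fixed at 1). Each component fits a
#' single-effect regression to the residualized z-scores, converts per-SNP
#' Bayes factors into posterior inclusion probabilities `alpha`, and the
#' components are cycled until the posterior means stabilize. The LD
#' matrix is ridge-regularized (`ridge` added to the diagonal) for
#' numerical stability.
#'
#' Each component's 95% credible set is the smallest set of variants whose
#' inclusion probabilities reach `coverage`; sets are kept only if their
#' purity (minimum absolute pairwise correlation) reaches `purity_min`,
#' which discards the diffuse sets produced by null components.
#'
#' @param z vector of z-scores aligned to `ld`.
#' @param ld an `ld_matrix` (PSD within tolerance).
#' @param n GWAS sample size.
#' @param L maximum number of single-effect components.
#' @param prior_sd prior SD of a standardized single-variant effect.
#' @param coverage credible-set coverage level.
#' @param purity_min minimum absolute pairwise LD within a reported set.
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   change in posterior mean effects.
#' @param ridge diagonal regularization added to `ld`.
#' @return an object of class `susie_fit`: list with `alpha` (L x p),
#'   `lbf_variable` (L x p), `credible_sets` (list of lists with `snps`,
#'   `coverage`, `purity`), `converged`, `snps`, `niter`.
#' @export
susie_rss <- function(z, ld, n, L = 10, prior_sd = 0.15, coverage = 0.95,
                      purity_min = 0.5, max_iter = 100, tol = 1e-3,
                      ridge = 1e-4) {
  p <- length(z)
  if (nrow(ld) != p) stop("z and ld dimensions differ")
  snps <- rownames(ld)
  R <- unclass(ld) + diag(ridge, p)
  xtx_diag <- rep(n, p)                  # standardized genotypes
  xty <- sqrt(n) * z
  XtX <- n * R
  V <- prior_sd^2

  alpha <- matrix(1 / p, L, p)
  mu <- matrix(0, L, p)                  # conditional posterior means
  lbf <- matrix(0, L, p)
  B <- alpha * mu                        # per-component posterior mean effects
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    B_old <- B
    for (l in seq_len(L)) {
      b_others <- colSums(B[-l, , drop = FALSE])
      xtr <- xty - as.numeric(XtX %*% b_others)
      bhat <- xtr / xtx_diag
      shat2 <- 1 / xtx_diag
      lbf_l <- 0.5 * log(shat2 / (V + shat2)) +
        0.5 * (bhat^2 / shat2) * (V / (V + shat2))
      a <- exp(lbf_l - logsumexp(lbf_l))
      post_var <- 1 / (1 / V + xtx_diag)
      post_mean <- post_var * xtr
      alpha[l, ] <- a
      mu[l, ] <- post_mean
      lbf[l, ] <- lbf_l
      B[l, ] <- a * post_mean
    }
    if (max(abs(B - B_old)) < tol / sqrt(n)) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) warning("susie_rss did not converge in ", max_iter,
                          " iterations")

  cs <- list()
  absR <- abs(R)
  for (l in seq_len(L)) {
    ord <- order(alpha[l, ], decreasing = TRUE)
    k <- which(cumsum(alpha[l, ord]) >= coverage)[1]
    if (is.na(k)) k <- p
    idx <- sort(ord[seq_len(k)])
    purity <- min(absR[idx, idx])
    if (purity >= purity_min) {
      cs[[length(cs) + 1L]] <- list(component = l, snps = snps[idx],
                                    idx = idx,
                                    coverage = sum(alpha[l, idx]),
                                    purity = purity)
    }
  }
  # deduplicate identical sets from redundant components
  if (length(cs) > 1L) {
    keys <- vapply(cs, function(s) paste(s$idx, collapse = ","), character(1))
    cs <- cs[!duplicated(keys)]
  }
  structure(list(alpha = alpha, lbf_variable = lbf, mu = mu,
                 credible_sets = cs, converged = converged, snps = snps,
                 n = n, niter = iter),
            class = "susie_fit")
}

#' @export
print.susie_fit <- function(x, ...) {
  cat(sprintf("susie fit: %d SNPs, %d credible set(s), %sconverged (%d iterations)\n",
              length(x$snps), length(x$credible_sets),
              ifelse(x$converged, "", "NOT "), x$niter))
  for (s in x$credible_sets) {
    cat(sprintf("  CS (component %d): %d SNP(s), coverage %.3f, purity %.2f\n",
                s$component, length(s$snps), s$coverage, s$purity))
  }
  invisible(x)
}

#' Credible-set-pairwise colocalization from two fine-mapped traits
#'
#' For every pair of signal components (one per trait, restricted to
#' components with a surviving credible set), runs the H0-H4 enumeration on
#' the pair's per-SNP component log Bayes factors, relaxing the
#' single-causal-variant assumption of [coloc_abf()].
#'
#' @param f1,f2 `susie_fit` objects over the same variant list.
#' @param priors `(p1, p2, p12)` per-SNP priors.
#' @return list of `coloc_result`, one per component pair (empty when
#'   either fit has no credible set), each tagged with its component pair.
#' @export
coloc_susie <- function(f1, f2, priors = c(1e-4, 1e-4, 1e-5)) {
  if (!identical(f1$snps, f2$snps)) stop("fits must share one SNP list")
  if (length(f1$credible_sets) == 0L || length(f2$credible_sets) == 0L) {
    return(list())
  }
  out <- list()
  for (s1 in f1$credible_sets) {
    for (s2 in f2$credible_sets) {
      res <- coloc_from_lbf(f1$lbf_variable[s1$component, ],
                            f2$lbf_variable[s2$component, ],
                            f1$snps, priors)
      res$component_pair <- c(s1$component, s2$component)
      out[[length(out) + 1L]] <- res
    }
  }
  out
}

#' Simplified multi-trait colocalization
#'
#' Tests whether one variant is simultaneously causal for all traits, a
#' simplified stand-in for regional multi-trait colocalization: per-SNP
#' log ABFs are summed across traits, and the all-shared configuration is
#' weighed against the null and every all-but-one-trait configuration.
#' When the all-shared posterior falls below `report_threshold`, no
#' candidate variant is reported (`candidate_snp = NA`, the "NA"
#' convention for absent simultaneous colocalization). The result is
#' invariant to trait order.
#'
#' @param tables list of >= 3 `sumstats` tables over a shared variant list.
#' @param prior_all per-SNP prior that one variant is causal for a given
#'   trait configuration.
#' @param prior_sd effect prior SD for [log_abf()].
#' @param report_threshold minimum `pp_all_shared` for naming a candidate.
#' @return object of class `multi_coloc_result`: list with `traits`,
#'   `pp_all_shared`, `candidate_snp` (NA when below threshold), and the
#'   `simplified = TRUE` metadata flag.
#' @export
multi_trait_coloc <- function(tables, prior_all = 1e-5, prior_sd = 0.15,
                              report_threshold = 0.25) {
  if (length(tables) < 3L) {
    stop("multi-trait colocalization needs >= 3 traits; use coloc_abf()")
  }
  shared <- Reduce(intersect, lapply(tables, function(t) t$snp))
  if (length(shared) == 0L) stop("no variants shared by all traits")
  lbf <- vapply(tables, function(t) {
    i <- match(shared, t$snp)
    log_abf(t$beta[i], t$se[i], prior_sd)
  }, numeric(length(shared)))
  lbf <- matrix(lbf, nrow = length(shared))
  total <- rowSums(lbf)
  lw_all <- log(prior_all) + logsumexp(total)
  lw_minus <- vapply(seq_len(ncol(lbf)), function(k) {
    log(prior_all) + logsumexp(total - lbf[, k])
  }, numeric(1))
  lw <- c(0, lw_minus, lw_all)
  pp_all <- exp(lw_all - logsumexp(lw))
  traits <- vapply(tables, function(t) as.character(t$trait[1]), character(1))
  candidate <- if (pp_all >= report_threshold) shared[which.max(total)] else
    NA_character_
  structure(list(traits = traits, pp_all_shared = pp_all,
                 candidate_snp = candidate, n_snps = length(shared),
                 simplified = TRUE),
            class = "multi_coloc_result")
}

#' @export
print.multi_coloc_result <- function(x, ...) {
  cat(sprintf("Multi-trait colocalization (%s; simplified single-variant scan)\n",
              paste(x$traits, collapse = ", ")))
  cat(sprintf("  pp(all traits share one causal variant) = %.3f\n",
              x$pp_all_shared))
  cat("  candidate variant:",
      ifelse(is.na(x$candidate_snp), "NA", x$candidate_snp), "\n")
  invisible(x)
}

#' Export colocalization results as TSV
#'
#' @param results named list of `coloc_result` (names used as the
#'   gene/trait-pair label).
#' @param path output path.
#' @export
write_coloc_results <- function(results, path) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(label = nm, pp_h0 = r$pp[1], pp_h1 = r$pp[2], pp_h2 = r$pp[3],
               pp_h3 = r$pp[4], pp_h4 = r$pp[5], best_snp_h4 = r$best_snp_h4,
               n_snps = r$n_snps, p1 = r$priors[1], p2 = r$priors[2],
               p12 = r$priors[3], stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
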