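# Synthetic GWAS summary statistics over a simulated cis region.
#
# Summary statistics are drawn from the standard multivariate model for
# GWAS z-scores: z ~ N(R %*% lambda, R), where R is the LD matrix and
# lambda the vector of non-centrality values implied by the true per-allele
# effects, allele frequencies and sample size. Per-allele betas are
# recovered on the standardized-phenotype scale with
# se = 1 / sqrt(2 f (1 - f) n).

#' Simulation configuration for a synthetic cis region
#'
#' Defines the ground truth for one simulated locus: the LD structure, the
#' per-trait GWAS sample sizes, and the causal model connecting the protein
#' (exposure), the outcome, and an optional mediator.
#'
#' Causal models:
#' \describe{
#'   \item{null}{no variant affects any trait.}
#'   \item{shared_causal}{one variant drives the protein; the protein has a
#'     causal effect `theta` on the outcome, so the same variant drives both
#'     traits (the colocalization H4 scenario).}
#'   \item{two_causal_in_ld}{the protein and the outcome each have their own
#'     causal variant, correlated at `ld_causal` (the H3 scenario; no
#'     protein -> outcome effect).}
#'   \item{mediated}{the protein affects a mediator (effect `a`), the
#'     mediator affects the outcome (effect `b`), and the protein may also
#'     have a direct effect `theta`; the outcome's total variant effect is
#'     `theta + a * b` times the variant's protein effect.}
#'   \item{reverse}{the variant drives the outcome; the protein inherits a
#'     downstream effect `theta` of the outcome, so the variant explains
#'     more outcome than protein variance (Steiger should return FALSE).}
#'   \item{pleiotropic}{the protein's variant also affects the outcome
#'     directly with per-allele effect `pleio`, violating exclusion
#'     restriction.}
#' }
#'
#' @param n_snps number of variants in the region.
#' @param ld_decay adjacent-variant correlation of the AR(1) LD structure,
#'   in [0, 1).
#' @param n_exposure,n_outcome,n_mediator GWAS sample sizes (>= 2).
#' @param causal_model one of `"null"`, `"shared_causal"`,
#'   `"two_causal_in_ld"`, `"mediated"`, `"reverse"`, `"pleiotropic"`.
#' @param theta true protein -> outcome effect (outcome SD units per SD of
#'   protein; for `reverse`, the outcome -> protein effect).
#' @param a,b mediation path effects (protein -> mediator, SD/SD, and
#'   mediator -> outcome).
#' @param pleio direct per-allele variant -> outcome effect under the
#'   pleiotropic model, on the standardized outcome scale.
#' @param r2_instrument variance of the protein explained by its causal
#'   variant, in (0, 1).
#' @param r2_outcome variance of the outcome explained by the outcome's own
#'   causal variant under `two_causal_in_ld` and `reverse`.
#' @param ld_causal target LD (signed correlation) between the two causal
#'   variants under `two_causal_in_ld`.
#' @param maf_range range the minor allele frequencies are drawn from,
#'   within (0, 0.5].
#' @param chr chromosome label; `pos_start`/`pos_step` lay variants on a
#'   1-based grid.
#' @param seed integer seed; the same config and seed reproduce output
#'   bit-for-bit.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_snps = 200, ld_decay = 0.9,
                       n_exposure = 3000, n_outcome = 370000,
                       n_mediator = 40000,
                       causal_model = c("null", "shared_causal",
                                        "two_causal_in_ld", "mediated",
                                        "reverse", "pleiotropic"),
                       theta = 0, a = 0, b = 0, pleio = 0,
                       r2_instrument = 0.1, r2_outcome = r2_instrument,
                       ld_causal = 0.7,
                       maf_range = c(0.05, 0.5),
                       chr = "1", pos_start = 1e6, pos_step = 1000,
                       seed = 1L) {
  causal_model <- match.arg(causal_model)
  stopifnot(n_snps >= 1, n_exposure >= 2, n_outcome >= 2, n_mediator >= 2,
            ld_decay >= 0, ld_decay < 1,
            r2_instrument > 0, r2_instrument < 1,
            r2_outcome > 0, r2_outcome < 1,
            length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  structure(list(n_snps = as.integer(n_snps), ld_decay = ld_decay,
                 n_exposure = as.integer(n_exposure),
                 n_outcome = as.integer(n_outcome),
                 n_mediator = as.integer(n_mediator),
                 causal_model = causal_model, theta = theta, a = a, b = b,
                 pleio = pleio, r2_instrument = r2_instrument,
                 r2_outcome = r2_outcome, ld_causal = ld_causal,
                 maf_range = maf_range, chr = as.character(chr),
                 pos_start = pos_start, pos_step = pos_step,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' AR(1) LD matrix
#'
#' @param n_snps number of variants.
#' @param rho adjacent-variant correlation in [0, 1); entry (i, j) is
#'   `rho^|i-j|`, a family guaranteed positive definite.
#' @param snps optional identifiers (default `snp_1..snp_n`).
#' @return an `ld_matrix`.
#' @export
ar1_ld <- function(n_snps, rho, snps = paste0("snp_", seq_len(n_snps))) {
  if (rho < 0 || rho >= 1) stop("AR(1) coefficient must lie in [0, 1)")
  r <- rho^abs(outer(seq_len(n_snps), seq_len(n_snps), "-"))
  ld_matrix(r, snps = snps)
}

#' Block-diagonal LD matrix
#'
#' Two-signal scenarios sometimes call for exactly-zero LD between blocks;
#' each block is AR(1) with its own coefficient.
#'
#' @param block_sizes integer vector of block sizes.
#' @param rhos per-block AR(1) coefficients (recycled).
#' @return an `ld_matrix`.
#' @export
block_ld <- function(block_sizes, rhos) {
  rhos <- rep_len(rhos, length(block_sizes))
  n <- sum(block_sizes)
  r <- matrix(0, n, n)
  at <- 0L
  for (k in seq_along(block_sizes)) {
    idx <- at + seq_len(block_sizes[k])
    r[idx, idx] <- rhos[k]^abs(outer(seq_len(block_sizes[k]),
                                     seq_len(block_sizes[k]), "-"))
    at <- at + block_sizes[k]
  }
  ld_matrix(r, snps = paste0("snp_", seq_len(n)))
}

# Non-centrality of the marginal z-score at a causal variant whose
# standardized per-allele effect explains r2 of the trait.
ncp_from_r2 <- function(r2, n) sqrt(n * r2 / (1 - r2))

# Draw one trait's z-scores: z ~ N(R lambda, R) via the Cholesky root.
draw_z <- function(chol_R, R, lambda) {
  mu <- if (all(lambda == 0)) numeric(nrow(R)) else as.numeric(R %*% lambda)
  mu + as.numeric(crossprod(chol_R, stats::rnorm(nrow(R))))
}

z_to_table <- function(z, snps, chr, pos, eaf, n, trait) {
  se <- 1 / sqrt(2 * eaf * (1 - eaf) * n)
  data.frame(snp = snps, chr = chr, pos = pos,
             ea = "A", nea = "G", eaf = eaf,
             beta = z * se, se = se,
             # floored at the smallest positive double so extreme signals
             # (|z| > ~38) keep a representable, nonzero p
             pval = pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin),
             n = n, trait = trait, stringsAsFactors = FALSE)
}

#' Simulate GWAS summary statistics for a cis region
#'
#' Draws per-trait z-scores from `N(R lambda, R)` (independent draws per
#' trait: the two-sample, no-overlap setting), converts them to per-allele
#' beta/se on the standardized-phenotype scale, and records the ground
#' truth. The exposure trait is named `"protein"`, the outcome `"outcome"`,
#' and, under the mediated model, a third trait `"mediator"` is included.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_region`: list with elements `variants`
#'   (data frame snp/chr/pos/maf), `ld` (an `ld_matrix`), `truth` (causal
#'   indices and true effects per trait), and `tables` (named list of
#'   `sumstats` tables aligned to `ld`).
#' @export
simulate_region <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  p <- config$n_snps
  snps <- paste0("snp_", seq_len(p))
  R <- ar1_ld(p, config$ld_decay, snps = snps)
  chol_R <- chol(unclass(R) + diag(1e-10, p))
  maf <- stats::runif(p, config$maf_range[1], config$maf_range[2])
  pos <- config$pos_start + (seq_len(p) - 1L) * config$pos_step

  lam_x <- lam_y <- lam_m <- numeric(p)
  cm <- config$causal_model
  idx_x <- as.integer(ceiling(p / 2))      # exposure causal variant
  idx_y <- NA_integer_
  theta <- config$theta

  if (cm == "shared_causal") {
    lam_x[idx_x] <- ncp_from_r2(config$r2_instrument, config$n_exposure)
    # outcome per-allele effect = theta * exposure per-allele effect
    lam_y[idx_x] <- theta * sqrt(config$r2_instrument) * sqrt(config$n_outcome)
    idx_y <- idx_x
  } else if (cm == "two_causal_in_ld") {
    # place the second causal variant where the AR(1) correlation is
    # closest to ld_causal (exact when ld_causal is a power of ld_decay)
    gap <- if (config$ld_decay > 0) {
      max(1L, as.integer(round(log(config$ld_causal) / log(config$ld_decay))))
    } else 1L
    idx_y <- min(p, idx_x + gap)
    lam_x[idx_x] <- ncp_from_r2(config$r2_instrument, config$n_exposure)
    lam_y[idx_y] <- ncp_from_r2(config$r2_outcome, config$n_outcome)
  } else if (cm == "mediated") {
    lam_x[idx_x] <- ncp_from_r2(config$r2_instrument, config$n_exposure)
    bx <- sqrt(config$r2_instrument)
    lam_m[idx_x] <- config$a * bx * sqrt(config$n_mediator)
    lam_y[idx_x] <- (theta + config$a * config$b) * bx * sqrt(config$n_outcome)
    idx_y <- idx_x
  } else if (cm == "reverse") {
    idx_y <- idx_x
    lam_y[idx_y] <- ncp_from_r2(config$r2_outcome, config$n_outcome)
    lam_x[idx_y] <- theta * sqrt(config$r2_outcome) * sqrt(config$n_exposure)
  } else if (cm == "pleiotropic") {
    lam_x[idx_x] <- ncp_from_r2(config$r2_instrument, config$n_exposure)
    lam_y[idx_x] <- (theta * sqrt(config$r2_instrument) + config$pleio) *
      sqrt(config$n_outcome)
    idx_y <- idx_x
  }

  tables <- list(
    protein = validate_sumstats(z_to_table(
      draw_z(chol_R, R, lam_x), snps, config$chr, pos, maf,
      config$n_exposure, "protein")),
    outcome = validate_sumstats(z_to_table(
      draw_z(chol_R, R, lam_y), snps, config$chr, pos, maf,
      config$n_outcome, "outcome")))
  if (cm == "mediated") {
    tables$mediator <- validate_sumstats(z_to_table(
      draw_z(chol_R, R, lam_m), snps, config$chr, pos, maf,
      config$n_mediator, "mediator"))
  }

  truth <- list(causal_model = cm,
                causal_idx_exposure = if (cm == "null") NA_integer_ else idx_x,
                causal_idx_outcome = idx_y,
                theta = if (cm %in% c("shared_causal", "mediated",
                                      "pleiotropic")) theta else 0,
                a = if (cm == "mediated") config$a else 0,
                b = if (cm == "mediated") config$b else 0,
                lambda = list(protein = lam_x, outcome = lam_y,
                              mediator = if (cm == "mediated") lam_m))

  structure(list(variants = data.frame(snp = snps, chr = config$chr,
                                       pos = pos, maf = maf,
                                       stringsAsFactors = FALSE),
                 ld = R, truth = truth, tables = tables,
                 config = config),
            class = "sim_region")
}

#' Write a simulated region to a directory
#'
#' Tables go to `<trait>.tsv` in the tab-delimited summary-statistics
#' format, the LD matrix to `ld.txt` (+ `.snps` sidecar), and the ground
#' truth to `truth.json`.
#'
#' @param region a `sim_region`.
#' @param dir output directory (created if needed).
#' @export
write_region <- function(region, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (trait in names(region$tables)) {
    write_sumstats(region$tables[[trait]], file.path(dir, paste0(trait, ".tsv")))
  }
  write_ld_matrix(region$ld, file.path(dir, "ld.txt"))
  truth <- region$truth
  truth$lambda <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Simulate a multi-locus panel for reverse MR
#'
#' Emulates the reverse-MR design, where the outcome trait (e.g. age at
#' menarche) has genome-wide significant signals at many quasi-independent
#' loci that are then clumped into instruments. The genome is a
#' block-diagonal LD panel of `n_loci` AR(1) blocks; the central variant of
#' each block carries an outcome effect sized to explain `r2_per_locus` of
#' the outcome. Under a reverse-causal scenario (`kappa != 0`), the outcome
#' affects the protein, so every outcome variant carries a proportional
#' protein effect `kappa`; under the forward/null scenario (`kappa = 0`)
#' the protein is unaffected by the outcome's loci.
#'
#' @param n_loci number of LD blocks (candidate instruments).
#' @param block_size variants per block.
#' @param rho within-block AR(1) coefficient.
#' @param n_outcome,n_protein GWAS sample sizes.
#' @param r2_per_locus outcome variance explained per causal variant.
#' @param kappa outcome -> protein causal effect (SD per SD).
#' @param maf_range allele-frequency range.
#' @param seed integer seed.
#' @return list with `tables` (named `sumstats` list: `outcome`,
#'   `protein`), `ld` (block-diagonal `ld_matrix`), and `truth`.
#' @export
simulate_reverse_panel <- function(n_loci = 30, block_size = 5, rho = 0.5,
                                   n_outcome = 200000, n_protein = 3000,
                                   r2_per_locus = 0.001, kappa = 0,
                                   maf_range = c(0.05, 0.5), seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  R <- block_ld(rep(block_size, n_loci), rho)
  p <- nrow(R)
  snps <- rownames(R)
  chol_R <- chol(unclass(R) + diag(1e-10, p))
  maf <- stats::runif(p, maf_range[1], maf_range[2])
  pos <- 1e6 + (seq_len(p) - 1L) * 1e5
  causal <- (seq_len(n_loci) - 1L) * block_size + ceiling(block_size / 2)

  lam_y <- numeric(p)
  lam_y[causal] <- ncp_from_r2(r2_per_locus, n_outcome)
  # protein inherits kappa times the outcome's standardized variant effect
  lam_x <- numeric(p)
  lam_x[causal] <- kappa * sqrt(r2_per_locus) * sqrt(n_protein)

  tables <- list(
    outcome = validate_sumstats(z_to_table(
      draw_z(chol_R, R, lam_y), snps, "1", pos, maf, n_outcome, "outcome")),
    protein = validate_sumstats(z_to_table(
      draw_z(chol_R, R, lam_x), snps, "1", pos, maf, n_protein, "protein")))
  list(tables = tables, ld = R,
       truth = list(causal_idx = causal, kappa = kappa,
                    r2_per_locus = r2_per_locus))
}

#' Simulate independent multi-instrument MR summary data
#'
#' Generates the per-variant exposure and outcome effects for a set of
#' mutually independent instruments, the setting of multi-instrument MR
#' (IVW, MR-Egger, weighted median/mode). True per-allele exposure effects
#' are sized so each variant explains `r2_per_snp` of the exposure; the
#' outcome effect of variant j is `theta * bx_j + pleiotropy_j`.
#'
#' @param n_snp number of independent instruments.
#' @param theta true exposure -> outcome effect.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param r2_per_snp exposure variance explained per variant.
#' @param maf_range allele-frequency range.
#' @param pleiotropy numeric vector (recycled to `n_snp`) of direct variant
#'   -> outcome effects on the standardized outcome scale; default none.
#' @param seed optional integer seed.
#' @return a `harmonized_set` with a `truth` attribute.
#' @export
simulate_mr_instruments <- function(n_snp, theta, n_exposure = 3000,
                                    n_outcome = 50000, r2_per_snp = 0.02,
                                    maf_range = c(0.05, 0.5),
                                    pleiotropy = 0, seed = NULL) {
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
  }
  f <- stats::runif(n_snp, maf_range[1], maf_range[2])
  bx <- sqrt(r2_per_snp / (2 * f * (1 - f)))
  se_x <- 1 / sqrt(2 * f * (1 - f) * n_exposure)
  se_y <- 1 / sqrt(2 * f * (1 - f) * n_outcome)
  alpha <- rep_len(pleiotropy, n_snp)
  by <- theta * bx + alpha
  h <- data.frame(snp = paste0("iv_", seq_len(n_snp)),
                  bx = stats::rnorm(n_snp, bx, se_x), se_x = se_x,
                  by = stats::rnorm(n_snp, by, se_y), se_y = se_y,
                  eaf = f, n_x = n_exposure, n_y = n_outcome,
                  stringsAsFactors = FALSE)
  attr(h, "exposure_trait") <- "exposure"
  attr(h, "outcome_trait") <- "outcome"
  attr(h, "truth") <- list(theta = theta, bx = bx, by = by,
                           pleiotropy = alpha)
  class(h) <- c("harmonized_set", "data.frame")
  h
}
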