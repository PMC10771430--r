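# Shared fixture builders for the test suite.

# One variant record as a 1-row data frame.
variant_row <- function(snp = "rs1", chr = "1", pos = 1e6, ea = "A",
                        nea = "G", eaf = 0.3, beta = 0.1, se = 0.02,
                        pval = 1e-10, n = 3000, trait = "protein") {
  data.frame(snp = snp, chr = chr, pos = pos, ea = ea, nea = nea,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n,
             trait = trait, stringsAsFactors = FALSE)
}

# A small well-formed sumstats table with k variants.
toy_sumstats <- function(k = 5, trait = "protein", chr = "1",
                         pos = 1e6 + seq_len(k) * 1000,
                         pval = rep(1e-10, k), beta = rep(0.1, k),
                         eaf = rep(0.3, k), n = 3000) {
  validate_sumstats(data.frame(
    snp = paste0("rs", seq_len(k)), chr = chr, pos = pos,
    ea = "A", nea = "G", eaf = eaf, beta = beta, se = 0.02,
    pval = pval, n = n, trait = trait, stringsAsFactors = FALSE))
}

# A harmonized set built directly from effect vectors.
toy_harmonized <- function(bx, by, se_x = rep(0.02, length(bx)),
                           se_y = rep(0.02, length(bx)),
                           eaf = rep(0.3, length(bx)),
                           n_x = 3000, n_y = 50000) {
  h <- data.frame(snp = paste0("iv_", seq_along(bx)), bx = bx, se_x = se_x,
                  by = by, se_y = se_y, eaf = eaf, n_x = n_x, n_y = n_y,
                  stringsAsFactors = FALSE)
  attr(h, "exposure_trait") <- "exposure"
  attr(h, "outcome_trait") <- "outcome"
  class(h) <- c("harmonized_set", "data.frame")
  h
}

# Directly constructed sumstats from z-scores (bypasses simulation noise).
sumstats_from_z <- function(z, trait = "t", n = 10000,
                            eaf = rep(0.3, length(z)),
                            pos = 1e6 + seq_along(z) * 1000) {
  se <- 1 / sqrt(2 * eaf * (1 - eaf) * n)
  validate_sumstats(data.frame(
    snp = paste0("snp_", seq_along(z)), chr = "1", pos = pos,
    ea = "A", nea = "G", eaf = eaf, beta = z * se, se = se,
    pval = pmax(2 * pnorm(-abs(z)), .Machine$double.xmin), n = n,
    trait = trait, stringsAsFactors = FALSE))
}

# z-scores drawn from N(R lambda, R) for a given ld_matrix.
draw_region_z <- function(ld, lambda) {
  p <- nrow(ld)
  mu <- as.numeric(unclass(ld) %*% lambda)
  mu + as.numeric(crossprod(chol(unclass(ld) + diag(1e-10, p)), rnorm(p)))
}
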