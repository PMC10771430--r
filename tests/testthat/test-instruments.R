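# Instrument selection, strength metrics, proxies and clumping.

test_that("variance explained follows the standardized-scale formula", {
  expect_equal(variance_explained(0, 0.3), 0)
  expect_equal(variance_explained(0.1, 0.5), 0.005)
  expect_equal(variance_explained(0.2, 0.1), variance_explained(0.2, 0.9))
  expect_error(variance_explained(0.1, 0), "eaf")
  expect_error(variance_explained(0.1, NA), "eaf")
})

test_that("F-statistic matches its closed form and guards its domain", {
  expect_equal(f_statistic(0.5, 102, 1), 100)
  expect_equal(f_statistic(0, 1000), 0)
  expect_error(f_statistic(1, 100), "r2")
  expect_error(f_statistic(0.1, 2), "n")
})

test_that("F-statistic agrees with an individual-level regression oracle", {
  set.seed(11)
  n <- 10000
  f <- 0.3
  g <- rbinom(n, 2, f)
  beta_true <- 0.25
  y <- beta_true * (g - mean(g)) / sd(g) + rnorm(n)
  fit <- lm(y ~ g)
  f_lm <- summary(fit)$fstatistic[["value"]]
  # package path: per-allele beta on the standardized phenotype
  b_hat <- coef(lm(scale(y) ~ g))[["g"]]
  r2 <- variance_explained(b_hat, mean(g) / 2)
  expect_lt(abs(f_statistic(r2, n) - f_lm) / f_lm, 0.05)
})

test_that("cis window and p-value threshold select and rank instruments", {
  tab <- toy_sumstats(3, pos = c(5e5, 7e5, 9e5),
                      pval = c(1e-9, 1e-12, 1e-6))
  gene <- list(gene = "GENE1", chr = "1", tss = 6e5)
  iv <- select_cis_pqtl(tab, gene)
  expect_equal(nrow(iv), 2)
  expect_equal(iv$snp, c("rs2", "rs1"))   # best (smallest p) first
  expect_true(all(iv$f_stat > 0))
  # F recomputes from the housed formula
  expect_equal(iv$f_stat, f_statistic(iv$r2, iv$n))
})

test_that("the 1 Mb window boundary is inclusive, the step beyond excluded", {
  tss <- 5e6
  tab <- toy_sumstats(2, pos = c(tss + 1e6, tss + 1e6 + 1))
  gene <- list(gene = "G", chr = "1", tss = tss)
  iv <- select_cis_pqtl(tab, gene)
  expect_equal(iv$snp, "rs1")
  expect_equal(abs(iv$distance_to_tss), 1e6)
})

test_that("a gene on another chromosome yields an empty result, not an error", {
  iv <- select_cis_pqtl(toy_sumstats(3), list(gene = "G", chr = "2",
                                              tss = 1e6))
  expect_equal(nrow(iv), 0)
})

test_that("selection is invariant to input row order", {
  tab <- toy_sumstats(6, pval = 10^-runif(6, 6, 20))
  gene <- list(gene = "G", chr = "1", tss = 1e6)
  shuffled <- validate_sumstats(as.data.frame(tab)[sample(6), ])
  expect_equal(select_cis_pqtl(tab, gene), select_cis_pqtl(shuffled, gene))
})

test_that("the causal variant is top-ranked in simulated cis regions", {
  reps <- 200
  hits <- 0
  for (i in seq_len(reps)) {
    r <- simulate_region(sim_config(n_snps = 40, n_exposure = 3000,
                                    causal_model = "shared_causal",
                                    theta = 0, r2_instrument = 0.1,
                                    seed = 3000L + i))
    gene <- list(gene = "G", chr = "1",
                 tss = r$variants$pos[r$truth$causal_idx_exposure])
    iv <- select_cis_pqtl(r$tables$protein, gene)
    if (nrow(iv) > 0 &&
        iv$snp[1] == r$variants$snp[r$truth$causal_idx_exposure]) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / reps, 0.95)
})

test_that("proxy search takes the highest r2 above a strict threshold", {
  ld <- ld_matrix(matrix(c(1, 0.95, 0.92, 0.77,
                           0.95, 1, 0.9, 0.7,
                           0.92, 0.9, 1, 0.6,
                           0.77, 0.7, 0.6, 1), 4, 4),
                  snps = c("lead", "p1", "p2", "p3"))
  cand <- toy_sumstats(3, pval = c(1e-9, 1e-8, 1e-7))
  cand$snp <- c("p1", "p2", "p3")
  px <- find_proxy("lead", ld, cand)
  expect_equal(px$snp, "p1")          # r2 = 0.9025 beats 0.8464
  expect_equal(px$r2, 0.95^2)
  # all candidates at or below the threshold: none
  expect_null(find_proxy("p3", ld, cand[cand$snp != "p3", ]))
  expect_error(find_proxy("absent", ld, cand), "absent")
})

test_that("proxy ties break by candidate p-value", {
  r <- matrix(c(1, 0.9, 0.9,
                0.9, 1, 0.81,
                0.9, 0.81, 1), 3, 3)
  ld <- ld_matrix(r, snps = c("lead", "a", "b"))
  cand <- toy_sumstats(2, pval = c(1e-6, 1e-9))
  cand$snp <- c("a", "b")
  expect_equal(find_proxy("lead", ld, cand)$snp, "b")
})

test_that("clumping follows the greedy smallest-p rule", {
  ld <- ld_matrix(matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2, 2),
                  snps = c("rs1", "rs2"))
  tab <- toy_sumstats(2, pval = c(1e-9, 1e-10))
  kept <- clump(tab, ld)
  expect_equal(kept, "rs2")           # smaller p wins, the other discarded
  ld0 <- ld_matrix(diag(3), snps = paste0("rs", 1:3))
  tab3 <- toy_sumstats(3, pval = c(1e-9, 1e-10, 1e-12))
  expect_setequal(clump(tab3, ld0), paste0("rs", 1:3))
  # nothing significant
  expect_equal(clump(toy_sumstats(2, pval = c(1e-3, 1e-4)), ld0[1:2, 1:2]),
               character())
})

test_that("clumped sets are mutually LD-independent (exhaustive check)", {
  for (s in 1:5) {
    r <- simulate_region(sim_config(n_snps = 20, ld_decay = 0.3,
                                    causal_model = "shared_causal",
                                    theta = 0, seed = 100L + s))
    kept <- clump(r$tables$protein, r$ld, p_threshold = 0.5,
                  r2_threshold = 0.001)
    expect_gte(length(kept), 2)   # weak decay leaves independent variants
    r2 <- unclass(r$ld)[kept, kept]^2
    expect_true(all(r2[upper.tri(r2)] < 0.001))
  }
})

test_that("instrument export writes the forest-plot columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  iv <- select_cis_pqtl(toy_sumstats(3), list(gene = "G", chr = "1",
                                              tss = 1e6))
  write_instruments(iv, path)
  back <- read.delim(path)
  expect_true(all(c("gene", "snp", "pos", "r2", "f_stat") %in% names(back)))
  expect_equal(nrow(back), nrow(iv))
})
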