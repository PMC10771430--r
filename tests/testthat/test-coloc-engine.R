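# Colocalization: Bayes factors, the H0-H4 enumeration, fine-mapping and
# the multi-trait extension.

test_that("the Wakefield log ABF matches its closed form and limits", {
  prior <- 0.15
  r <- prior^2 / (prior^2 + 0.02^2)
  expect_equal(log_abf(0, 0.02, prior), 0.5 * log(1 - r))
  expect_lt(log_abf(0, 0.02, prior), 0)
  # small-V limit: log ABF ~ z^2/2 + 0.5 log(V / prior^2)
  v <- 1e-6; z <- 5
  expect_equal(log_abf(z * sqrt(v), sqrt(v), prior),
               z^2 / 2 + 0.5 * log(v / prior^2), tolerance = 1e-3)
  zs <- seq(0, 10, by = 0.5)
  vals <- log_abf(zs * 0.02, 0.02)
  expect_true(all(diff(vals) > 0))
  expect_error(log_abf(0.1, 0), "se")
})

test_that("posteriors sum to one across random regions", {
  set.seed(31)
  for (i in 1:20) {
    t1 <- sumstats_from_z(rnorm(50, 0, 2), "a")
    t2 <- sumstats_from_z(rnorm(50, 0, 2), "b")
    res <- coloc_abf(t1, t2)
    expect_equal(sum(res$pp), 1, tolerance = 1e-9)
    expect_true(all(res$pp >= 0))
  }
})

test_that("swapping the traits swaps H1 and H2 and fixes H3, H4", {
  set.seed(32)
  t1 <- sumstats_from_z(c(rnorm(30), 8), "a")
  t2 <- sumstats_from_z(rnorm(31), "b")
  ab <- coloc_abf(t1, t2)
  ba <- coloc_abf(t2, t1)
  expect_equal(ab$pp[["H1"]], ba$pp[["H2"]], tolerance = 1e-12)
  expect_equal(ab$pp[["H2"]], ba$pp[["H1"]], tolerance = 1e-12)
  expect_equal(ab$pp[["H3"]], ba$pp[["H3"]], tolerance = 1e-12)
  expect_equal(ab$pp[["H4"]], ba$pp[["H4"]], tolerance = 1e-12)
})

test_that("a doubly null region lands on H0", {
  set.seed(33)
  z1 <- runif(500, -0.99, 0.99)
  z2 <- runif(500, -0.99, 0.99)
  res <- coloc_abf(sumstats_from_z(z1, "a"), sumstats_from_z(z2, "b"))
  expect_gt(res$pp[["H0"]], 0.9)
})

test_that("MAF and window filters restrict the analyzed variants", {
  t1 <- sumstats_from_z(rnorm(20), "a", eaf = c(rep(0.005, 5), rep(0.3, 15)))
  t2 <- sumstats_from_z(rnorm(20), "b", eaf = c(rep(0.005, 5), rep(0.3, 15)))
  res <- coloc_abf(t1, t2, maf_min = 0.01)
  expect_equal(res$n_snps, 15)
  res_w <- coloc_abf(t1, t2, maf_min = 0, center_pos = 1e6 + 1000,
                     window = 5000)
  expect_equal(res_w$n_snps, 6)   # positions within 5 kb of snp_1
  expect_error(coloc_abf(t1, t2, maf_min = 0.4), "shared")
})

test_that("log-space accumulation survives extreme z-scores", {
  z1 <- c(rnorm(20), 200)
  z2 <- c(rnorm(20), 200)
  res <- coloc_abf(sumstats_from_z(z1, "a"), sumstats_from_z(z2, "b"))
  expect_true(all(is.finite(res$pp)))
  expect_equal(sum(res$pp), 1, tolerance = 1e-9)
  expect_gt(res$pp[["H4"]], 0.99)
})

test_that("susie recovers a single strong causal variant", {
  set.seed(34)
  ld <- ar1_ld(100, 0.9)
  hits <- 0
  reps <- 50
  for (i in seq_len(reps)) {
    lambda <- numeric(100); lambda[40] <- 10
    z <- draw_region_z(ld, lambda)
    fit <- susie_rss(z, ld, n = 10000)
    cs <- fit$credible_sets
    if (length(cs) == 1 && "snp_40" %in% cs[[1]]$snps) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("susie separates two independent strong signals", {
  set.seed(35)
  ld <- block_ld(c(50, 50), c(0.9, 0.9))
  lambda <- numeric(100); lambda[25] <- 10; lambda[75] <- 10
  z <- draw_region_z(ld, lambda)
  fit <- susie_rss(z, ld, n = 10000)
  expect_equal(length(fit$credible_sets), 2)
  sets <- lapply(fit$credible_sets, `[[`, "snps")
  expect_length(intersect(sets[[1]], sets[[2]]), 0)
  found <- vapply(sets, function(s) any(c("snp_25", "snp_75") %in% s),
                  logical(1))
  expect_true(all(found))
})

test_that("susie reports no credible set on null data", {
  set.seed(36)
  ld <- ar1_ld(100, 0.5)
  z <- draw_region_z(ld, numeric(100))
  fit <- susie_rss(z, ld, n = 10000)
  expect_equal(length(fit$credible_sets), 0)
})

test_that("susie alpha rows are simplexes and credible sets meet coverage", {
  set.seed(37)
  ld <- ar1_ld(60, 0.9)
  lambda <- numeric(60); lambda[30] <- 8
  fit <- susie_rss(draw_region_z(ld, lambda), ld, n = 10000)
  expect_equal(rowSums(fit$alpha), rep(1, nrow(fit$alpha)), tolerance = 1e-6)
  for (cs in fit$credible_sets) {
    expect_gte(cs$coverage, 0.95)
    expect_gte(cs$purity, 0.5)
  }
})

test_that("credible-set pairwise coloc distinguishes shared from distinct", {
  set.seed(38)
  ld <- block_ld(c(40, 40), c(0.9, 0.9))
  # identical fits: diagonal pairs are H4-dominant
  lambda <- numeric(80); lambda[20] <- 10; lambda[60] <- 10
  z <- draw_region_z(ld, lambda)
  f <- susie_rss(z, ld, n = 10000)
  pairs <- coloc_susie(f, f)
  for (pr in pairs) {
    same <- pr$component_pair[1] == pr$component_pair[2]
    expect_equal(unname(which.max(pr$pp)) == 5, same)
  }
  # disjoint signals: all pairs H3-dominant
  z1 <- draw_region_z(ld, c(numeric(19), 10, numeric(60)))
  z2 <- draw_region_z(ld, c(numeric(59), 10, numeric(20)))
  f1 <- susie_rss(z1, ld, n = 10000)
  f2 <- susie_rss(z2, ld, n = 10000)
  pairs2 <- coloc_susie(f1, f2)
  expect_gt(length(pairs2), 0)
  for (pr in pairs2) expect_equal(unname(which.max(pr$pp)), 4)
  # no credible sets anywhere: empty list
  fnull <- susie_rss(draw_region_z(ld, numeric(80)), ld, n = 10000)
  expect_length(coloc_susie(fnull, fnull), 0)
})

test_that("multi-trait coloc detects a fully shared causal variant", {
  set.seed(39)
  ld <- ar1_ld(60, 0.8)
  lambda <- numeric(60); lambda[30] <- 10
  tabs <- lapply(c("a", "b", "c"), function(tr) {
    sumstats_from_z(draw_region_z(ld, lambda), tr)
  })
  res <- multi_trait_coloc(tabs)
  expect_gt(res$pp_all_shared, 0.8)
  expect_equal(res$candidate_snp, "snp_30")
  expect_true(res$simplified)
})

test_that("multi-trait coloc reports NA when one trait is null", {
  set.seed(40)
  ld <- ar1_ld(60, 0.8)
  lambda <- numeric(60); lambda[30] <- 10
  tabs <- list(sumstats_from_z(draw_region_z(ld, lambda), "a"),
               sumstats_from_z(draw_region_z(ld, lambda), "b"),
               sumstats_from_z(draw_region_z(ld, numeric(60)), "c"))
  res <- multi_trait_coloc(tabs)
  expect_true(is.na(res$candidate_snp))
  expect_error(multi_trait_coloc(tabs[1:2]), "coloc_abf")
})

test_that("multi-trait coloc is invariant to trait order", {
  set.seed(41)
  ld <- ar1_ld(40, 0.8)
  lambda <- numeric(40); lambda[20] <- 9
  tabs <- list(sumstats_from_z(draw_region_z(ld, lambda), "a"),
               sumstats_from_z(draw_region_z(ld, lambda), "b"),
               sumstats_from_z(draw_region_z(ld, lambda * 0.8), "c"))
  r1 <- multi_trait_coloc(tabs)
  r2 <- multi_trait_coloc(rev(tabs))
  expect_equal(r1$pp_all_shared, r2$pp_all_shared, tolerance = 1e-12)
  expect_equal(r1$candidate_snp, r2$candidate_snp)
})

test_that("coloc results export as a TSV with all posteriors", {
  set.seed(42)
  t1 <- sumstats_from_z(c(rnorm(20), 10), "a")
  t2 <- sumstats_from_z(c(rnorm(20), 10), "b")
  res <- list(GENE1 = coloc_abf(t1, t2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coloc_results(res, path)
  back <- read.delim(path)
  expect_equal(back$label, "GENE1")
  expect_equal(back$pp_h0 + back$pp_h1 + back$pp_h2 + back$pp_h3 +
                 back$pp_h4, 1, tolerance = 1e-6)
})
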