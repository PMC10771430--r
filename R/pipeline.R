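# Orchestration of the full screen: per-protein instrument selection,
# Wald MR against the outcome, Bonferroni control, Steiger directionality,
# colocalization of the MR hits, and the reverse-MR arm.

#' Run configuration
#'
#' Collects every threshold and prior of a screen run, plus the synthetic
#' panel settings, in one validated list that round-trips losslessly
#' through YAML.
#'
#' @param mode `"synthetic"` (panel generated by the package's simulator)
#'   or `"files"` (paths below are read from disk).
#' @param protein_paths,outcome_path,mediator_path,ld_path,annotation_path
#'   input paths for `mode = "files"`.
#' @param n_proteins,n_causal synthetic panel: number of proteins screened
#'   and how many truly affect the outcome.
#' @param theta true protein -> outcome effect of the causal proteins.
#' @param n_snps,ld_decay,n_exposure,n_outcome,r2_instrument synthetic
#'   region settings (see [sim_config()]).
#' @param p_instrument instrument significance threshold.
#' @param proxy_r2 minimum squared LD for a proxy.
#' @param clump_r2 clumping threshold for reverse MR.
#' @param maf_min colocalization MAF filter.
#' @param window_bp cis window half-width.
#' @param alpha family-wise error rate for Bonferroni control.
#' @param coloc_priors `(p1, p2, p12)`.
#' @param n_rev_loci,rev_kappa reverse-MR panel settings (see
#'   [simulate_reverse_panel()]).
#' @param seed run seed.
#' @param out_dir output directory or `NULL` for no file output.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"),
                       protein_paths = NULL, outcome_path = NULL,
                       mediator_path = NULL, ld_path = NULL,
                       annotation_path = NULL,
                       n_proteins = 20, n_causal = 3, theta = 0.3,
                       n_snps = 100, ld_decay = 0.9, n_exposure = 3000,
                       n_outcome = 370000, r2_instrument = 0.1,
                       p_instrument = 5e-8, proxy_r2 = 0.8,
                       clump_r2 = 0.001, maf_min = 0.01, window_bp = 1e6,
                       alpha = 0.05, coloc_priors = c(1e-4, 1e-4, 1e-5),
                       n_rev_loci = 30, rev_kappa = 0,
                       seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(p_instrument > 0, p_instrument <= 1,
            proxy_r2 > 0, proxy_r2 <= 1,
            clump_r2 > 0, clump_r2 <= 1,
            maf_min >= 0, maf_min < 0.5,
            window_bp > 0, alpha > 0, alpha < 1,
            length(coloc_priors) == 3, all(coloc_priors > 0),
            n_proteins >= 1, n_causal >= 0, n_causal <= n_proteins)
  structure(list(mode = mode, protein_paths = protein_paths,
                 outcome_path = outcome_path, mediator_path = mediator_path,
                 ld_path = ld_path, annotation_path = annotation_path,
                 n_proteins = as.integer(n_proteins),
                 n_causal = as.integer(n_causal), theta = theta,
                 n_snps = as.integer(n_snps), ld_decay = ld_decay,
                 n_exposure = as.integer(n_exposure),
                 n_outcome = as.integer(n_outcome),
                 r2_instrument = r2_instrument,
                 p_instrument = p_instrument, proxy_r2 = proxy_r2,
                 clump_r2 = clump_r2, maf_min = maf_min,
                 window_bp = window_bp, alpha = alpha,
                 coloc_priors = as.numeric(coloc_priors),
                 n_rev_loci = as.integer(n_rev_loci), rev_kappa = rev_kappa,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Write / read a run configuration (YAML)
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x <- x[!vapply(x, is.null, logical(1))]
  do.call(run_config, x)
}

screen_one_protein <- function(protein_name, region, config, center_pos) {
  gene <- list(gene = protein_name, chr = region$tables$protein$chr[1],
               tss = center_pos)
  iv <- select_cis_pqtl(region$tables$protein, gene,
                        window = config$window_bp,
                        p_threshold = config$p_instrument)
  if (nrow(iv) == 0L) {
    return(list(protein = protein_name, status = "no_instrument"))
  }
  lead <- iv$snp[1]
  proxy_used <- FALSE
  # proxy fallback when the lead variant is absent from the outcome GWAS
  if (!lead %in% region$tables$outcome$snp) {
    px <- find_proxy(lead, region$ld, region$tables$protein,
                     r2_threshold = config$proxy_r2)
    if (is.null(px) || !px$snp %in% region$tables$outcome$snp) {
      return(list(protein = protein_name, status = "no_outcome_match"))
    }
    lead <- px$snp
    proxy_used <- TRUE
  }
  h <- harmonize(region$tables$protein, region$tables$outcome)
  row <- h[h$snp == lead, , drop = FALSE]
  if (nrow(row) == 0L) {
    return(list(protein = protein_name, status = "no_outcome_match"))
  }
  mr <- wald_ratio(row)
  st <- mr_steiger(row)
  list(protein = protein_name, status = "tested", snp = lead,
       is_proxy = proxy_used, f_stat = iv$f_stat[1], r2 = iv$r2[1],
       beta = mr$beta, se = mr$se, pval = mr$pval,
       steiger_true = st$direction_true, steiger_p = st$pval,
       region = region)
}

#' Forward proteome-wide MR + colocalization screen
#'
#' Runs, per protein: cis-pQTL instrument selection (with proxy fallback),
#' single-instrument Wald MR against the outcome, Bonferroni flagging at
#' `alpha / m` (m = number of distinct proteins actually tested), the
#' Steiger directionality test, and — for Bonferroni-significant proteins —
#' colocalization by both the single-variant enumeration and the
#' fine-mapped credible-set pairing. Per-protein failures are logged and
#' skipped, never fatal to the screen.
#'
#' In synthetic mode, proteins `protein_1 .. protein_<n_causal>` truly
#' affect the outcome with effect `theta`; the rest have an instrumented
#' protein but a null outcome effect.
#'
#' @param config a [run_config()].
#' @return object of class `screen_report`: list with `results` (one data
#'   frame row per protein), `coloc` (named list of `coloc_result`),
#'   `counts` (stage bookkeeping), `m`, `threshold`. Written as TSV + JSON
#'   under `config$out_dir` when set.
#' @export
run_forward_screen <- function(config) {
  stopifnot(inherits(config, "run_config"))
  regions <- list()
  if (config$mode == "synthetic") {
    for (i in seq_len(config$n_proteins)) {
      causal <- i <= config$n_causal
      sc <- sim_config(n_snps = config$n_snps, ld_decay = config$ld_decay,
                       n_exposure = config$n_exposure,
                       n_outcome = config$n_outcome,
                       causal_model = "shared_causal",
                       theta = if (causal) config$theta else 0,
                       r2_instrument = config$r2_instrument,
                       seed = config$seed * 10000L + i)
      region <- simulate_region(sc)
      nm <- paste0("protein_", i)
      region$tables$protein$trait <- nm
      regions[[nm]] <- region
    }
  } else {
    outcome <- read_sumstats(config$outcome_path)
    ld <- read_ld_matrix(config$ld_path)
    ann <- read_gene_annotation(config$annotation_path)
    for (path in config$protein_paths) {
      tab <- read_sumstats(path)
      nm <- tab$trait[1]
      gene_row <- ann[ann$gene == nm, , drop = FALSE]
      tss <- if (nrow(gene_row) == 1L) gene_row$tss else
        tab$pos[which.min(tab$pval)]
      regions[[nm]] <- list(tables = list(protein = tab, outcome = outcome),
                            ld = ld,
                            variants = data.frame(pos = tab$pos),
                            center = tss)
    }
  }

  rows <- list()
  for (nm in names(regions)) {
    region <- regions[[nm]]
    center <- region$center %||%
      region$variants$pos[ceiling(nrow(region$variants) / 2)]
    res <- tryCatch(screen_one_protein(nm, region, config, center),
                    error = function(e) {
                      list(protein = nm, status = paste("error:",
                                                        conditionMessage(e)))
                    })
    res$center <- center
    rows[[nm]] <- res
  }

  tested <- Filter(function(r) identical(r$status, "tested"), rows)
  m <- length(tested)
  threshold <- if (m > 0) bonferroni_threshold(config$alpha, m) else NA_real_

  coloc_results <- list()
  tab_rows <- list()
  for (r in rows) {
    sig <- identical(r$status, "tested") && r$pval < threshold
    h4 <- NA_real_; h3 <- NA_real_; susie_best_h4 <- NA_real_
    if (sig) {
      cr <- tryCatch(
        coloc_abf(r$region$tables$protein, r$region$tables$outcome,
                  priors = config$coloc_priors, maf_min = config$maf_min,
                  window = config$window_bp, center_pos = r$center),
        error = function(e) NULL)
      if (!is.null(cr)) {
        coloc_results[[r$protein]] <- cr
        h4 <- cr$pp[["H4"]]; h3 <- cr$pp[["H3"]]
        sb <- tryCatch({
          tabs <- r$region$tables
          shared <- intersect(tabs$protein$snp, tabs$outcome$snp)
          ldm <- r$region$ld
          shared <- intersect(shared, rownames(ldm))
          sub <- unclass(ldm)[shared, shared]
          ldx <- ld_matrix(sub, snps = shared)
          zp <- with(tabs$protein[match(shared, tabs$protein$snp), ],
                     beta / se)
          zo <- with(tabs$outcome[match(shared, tabs$outcome$snp), ],
                     beta / se)
          f1 <- susie_rss(zp, ldx, n = tabs$protein$n[1])
          f2 <- susie_rss(zo, ldx, n = tabs$outcome$n[1])
          pairs <- coloc_susie(f1, f2, priors = config$coloc_priors)
          if (length(pairs) > 0)
            max(vapply(pairs, function(x) x$pp[["H4"]], numeric(1)))
          else NA_real_
        }, error = function(e) NA_real_)
        susie_best_h4 <- sb
      }
    }
    tab_rows[[length(tab_rows) + 1L]] <- data.frame(
      protein = r$protein, status = r$status,
      snp = r$snp %||% NA_character_,
      is_proxy = r$is_proxy %||% NA,
      f_stat = r$f_stat %||% NA_real_, r2 = r$r2 %||% NA_real_,
      beta = r$beta %||% NA_real_, se = r$se %||% NA_real_,
      pval = r$pval %||% NA_real_,
      passes_bonferroni = if (identical(r$status, "tested")) r$pval < threshold else NA,
      steiger_true = r$steiger_true %||% NA,
      pp_h3 = h3, pp_h4 = h4, susie_best_h4 = susie_best_h4,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, tab_rows)
  rownames(results) <- NULL

  counts <- list(n_proteins = length(rows), n_tested = m,
                 n_significant = sum(results$passes_bonferroni, na.rm = TRUE),
                 n_coloc_tested = length(coloc_results),
                 n_h4_gt_0.8 = sum(results$pp_h4 > 0.8, na.rm = TRUE))
  report <- structure(list(results = results, coloc = coloc_results,
                           counts = counts, m = m, threshold = threshold,
                           config = config),
                      class = "screen_report")
  if (!is.null(config$out_dir)) write_screen_report(report, config$out_dir)
  report
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("Forward screen: %d protein(s), %d tested, Bonferroni p < %.3g\n",
              x$counts$n_proteins, x$counts$n_tested, x$threshold))
  cat(sprintf("  %d MR-significant; %d coloc-tested; %d with H4 > 0.8\n",
              x$counts$n_significant, x$counts$n_coloc_tested,
              x$counts$n_h4_gt_0.8))
  invisible(x)
}

write_screen_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$results, file.path(dir, "screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(counts = report$counts, m = report$m, threshold = report$threshold,
         seed = report$config$seed),
    file.path(dir, "screen_summary.json"), auto_unbox = TRUE, digits = NA)
  if (length(report$coloc) > 0) {
    write_coloc_results(report$coloc, file.path(dir, "coloc.tsv"))
  }
  invisible(dir)
}

#' Reverse MR: outcome trait as exposure, protein as outcome
#'
#' Clumps the outcome GWAS to genome-wide significant, LD-independent
#' instruments (p < `p_instrument`, r-squared < `clump_r2`), then runs
#' IVW, MR-Egger, weighted median and weighted mode of the
#' outcome -> protein effect, tabulating which methods reach nominal
#' significance. Methods needing more instruments than survive clumping
#' are skipped with a note.
#'
#' @param config a [run_config()] (`n_rev_loci`, `rev_kappa` drive the
#'   synthetic panel; `mode = "files"` reads `outcome_path`,
#'   `protein_paths[1]`, `ld_path`).
#' @param nboot bootstrap draws for median/mode standard errors.
#' @return object of class `reverse_report`: list with `results` (method
#'   table), `n_instruments`, `n_significant` (methods with p < 0.05).
#' @export
run_reverse_mr <- function(config, nboot = 1000) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "synthetic") {
    panel <- simulate_reverse_panel(n_loci = config$n_rev_loci,
                                    n_outcome = config$n_outcome,
                                    n_protein = config$n_exposure,
                                    kappa = config$rev_kappa,
                                    seed = config$seed)
    outcome_tab <- panel$tables$outcome
    protein_tab <- panel$tables$protein
    ld <- panel$ld
  } else {
    outcome_tab <- read_sumstats(config$outcome_path)
    protein_tab <- read_sumstats(config$protein_paths[1])
    ld <- read_ld_matrix(config$ld_path)
  }
  kept <- clump(outcome_tab, ld, p_threshold = config$p_instrument,
                r2_threshold = config$clump_r2)
  if (length(kept) == 0L) stop("no instruments survive clumping")
  h <- harmonize(outcome_tab, protein_tab)
  h <- h[h$snp %in% kept, , drop = FALSE]
  fits <- if (nrow(h) == 1L) list(wald = wald_ratio(h)) else
    mr_all_methods(h, nboot = nboot, seed = config$seed + 1L)
  results <- do.call(rbind, lapply(fits, function(r) {
    data.frame(method = r$method, n_snp = r$n_snp, beta = r$beta,
               se = r$se, pval = r$pval, significant = r$pval < 0.05,
               stringsAsFactors = FALSE)
  }))
  rownames(results) <- NULL
  report <- structure(list(results = results, n_instruments = nrow(h),
                           n_significant = sum(results$significant),
                           config = config),
                      class = "reverse_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(results, file.path(config$out_dir, "reverse_mr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' @export
print.reverse_report <- function(x, ...) {
  cat(sprintf("Reverse MR: %d instruments; %d of %d methods p < 0.05\n",
              x$n_instruments, x$n_significant, nrow(x$results)))
  print(x$results, row.names = FALSE)
  invisible(x)
}
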