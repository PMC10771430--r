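# cis-pQTL instrument selection and instrument-strength metrics.

#' Variance of a standardized trait explained by one variant
#'
#' For a per-allele effect `beta` on a standardized phenotype and effect
#' allele frequency `f`, the variance explained is approximately
#' `R^2 = 2 beta^2 f (1 - f)`.
#'
#' @param beta per-allele effect estimate (standardized-phenotype scale).
#' @param eaf effect allele frequency, strictly in (0, 1).
#' @return the approximate R-squared (vectorized).
#' @export
variance_explained <- function(beta, eaf) {
  if (any(is.na(eaf)) || any(eaf <= 0) || any(eaf >= 1)) {
    stop("eaf must lie strictly in (0, 1)")
  }
  2 * beta^2 * eaf * (1 - eaf)
}

#' Instrument F-statistic
#'
#' `F = (R^2 / k) / ((1 - R^2) / (n - k - 1))`, where `R^2` is the variance
#' of the exposure explained by the instrument(s), `k` the number of
#' instruments, and `n` the GWAS sample size. F > 10 is the conventional
#' bound for a strong instrument.
#'
#' @param r2 variance explained, in [0, 1).
#' @param n sample size, > k + 1.
#' @param k number of instruments (1 for single-variant cis-pQTL MR).
#' @return the F-statistic (vectorized over `r2`/`n`).
#' @export
f_statistic <- function(r2, n, k = 1) {
  if (any(r2 < 0) || any(r2 >= 1)) stop("r2 must lie in [0, 1)")
  if (any(n <= k + 1)) stop("n must exceed k + 1")
  (r2 / k) / ((1 - r2) / (n - k - 1))
}

#' Select cis-pQTL instruments for a gene
#'
#' Returns the variants lying within `window` base pairs of the gene's
#' transcription start site (1-based, inclusive on both sides) whose
#' p-value passes the significance threshold, ranked by p-value, each
#' annotated with the variance explained and F-statistic. Variants with
#' missing allele frequency are ineligible (R-squared is undefined for
#' them) and are dropped with a message.
#'
#' @param sumstats a `sumstats` table for the protein.
#' @param gene one row of a gene annotation (list/data frame with `gene`,
#'   `chr`, `tss`).
#' @param window cis window half-width in bp (default 1 Mb).
#' @param p_threshold instrument significance threshold (default 5e-8).
#' @return data frame of class `instrument_set` with columns `snp, gene,
#'   distance_to_tss, beta, se, pval, eaf, n, r2, f_stat, is_proxy,
#'   proxy_r2`, best instrument first; zero rows when the gene is on
#'   another chromosome or nothing passes.
#' @export
select_cis_pqtl <- function(sumstats, gene, window = 1e6, p_threshold = 5e-8) {
  if (nrow(sumstats) == 0L) stop("empty summary-statistics table")
  empty <- data.frame(snp = character(), gene = character(),
                      pos = integer(),
                      distance_to_tss = integer(), beta = numeric(),
                      se = numeric(), pval = numeric(), eaf = numeric(),
                      n = numeric(), r2 = numeric(), f_stat = numeric(),
                      is_proxy = logical(), proxy_r2 = numeric(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("instrument_set", "data.frame")
  keep <- as.character(sumstats$chr) == as.character(gene$chr) &
    abs(sumstats$pos - gene$tss) <= window &
    sumstats$pval <= p_threshold
  x <- sumstats[keep, , drop = FALSE]
  if (nrow(x) == 0L) return(empty)
  no_eaf <- is.na(x$eaf)
  if (any(no_eaf)) {
    message(sum(no_eaf), " candidate(s) dropped: missing eaf")
    x <- x[!no_eaf, , drop = FALSE]
    if (nrow(x) == 0L) return(empty)
  }
  r2 <- variance_explained(x$beta, x$eaf)
  out <- data.frame(snp = x$snp, gene = gene$gene, pos = x$pos,
                    distance_to_tss = as.integer(x$pos - gene$tss),
                    beta = x$beta, se = x$se, pval = x$pval, eaf = x$eaf,
                    n = x$n, r2 = r2, f_stat = f_statistic(r2, x$n),
                    is_proxy = FALSE, proxy_r2 = NA_real_,
                    stringsAsFactors = FALSE)
  out <- out[order(out$pval, out$snp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("instrument_set", "data.frame")
  out
}

#' Find an LD proxy for a variant
#'
#' Among candidate variants present in the LD matrix with squared
#' correlation to `snp` strictly above `r2_threshold`, returns the one with
#' the highest r-squared; ties are broken by smaller p-value in the
#' candidate table, then by position.
#'
#' @param snp identifier of the variant needing a proxy.
#' @param ld an `ld_matrix` containing `snp`.
#' @param candidates a `sumstats` table of variants available in the target
#'   GWAS.
#' @param r2_threshold minimum squared correlation, exclusive (default 0.8).
#' @return a list with `snp` (the proxy identifier) and `r2`, or `NULL`
#'   when no candidate qualifies.
#' @export
find_proxy <- function(snp, ld, candidates, r2_threshold = 0.8) {
  if (!snp %in% rownames(ld)) stop("snp absent from LD matrix: ", snp)
  cand <- intersect(setdiff(candidates$snp, snp), rownames(ld))
  if (length(cand) == 0L) return(NULL)
  r2 <- unclass(ld)[snp, cand]^2
  ok <- r2 > r2_threshold
  if (!any(ok)) return(NULL)
  cand <- cand[ok]; r2 <- r2[ok]
  pv <- candidates$pval[match(cand, candidates$snp)]
  pos <- candidates$pos[match(cand, candidates$snp)]
  ord <- order(-r2, pv, pos)
  list(snp = cand[ord[1]], r2 = unname(r2[ord[1]]))
}

#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-p remaining variant passing the
#' significance threshold and discards all remaining variants whose squared
#' correlation with it is at or above `r2_threshold`, yielding a mutually
#' quasi-independent significant set (the instrument set of reverse MR).
#'
#' @param sumstats a `sumstats` table aligned to `ld`.
#' @param ld an `ld_matrix` covering the table's variants.
#' @param p_threshold significance threshold (default 5e-8).
#' @param r2_threshold squared-correlation threshold (default 0.001).
#' @return character vector of retained variant identifiers, in selection
#'   order (ascending p).
#' @export
clump <- function(sumstats, ld, p_threshold = 5e-8, r2_threshold = 0.001) {
  x <- sumstats[sumstats$pval < p_threshold & sumstats$snp %in% rownames(ld), ,
                drop = FALSE]
  if (nrow(x) == 0L) return(character())
  r2 <- unclass(ld)^2
  remaining <- x$snp[order(x$pval, x$snp)]
  kept <- character()
  while (length(remaining) > 0L) {
    lead <- remaining[1]
    kept <- c(kept, lead)
    remaining <- remaining[r2[lead, remaining] < r2_threshold]
  }
  kept
}

#' Export an instrument set as a forest-plot-ready TSV
#'
#' @param instruments an `instrument_set`.
#' @param path output path.
#' @export
write_instruments <- function(instruments, path) {
  cols <- c("gene", "snp", "pos", "distance_to_tss", "beta", "se", "pval",
            "eaf", "r2", "f_stat", "is_proxy")
  utils::write.table(as.data.frame(instruments)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
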