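#' @keywords internal
"_PACKAGE"

# Required columns of a summary-statistics table, in canonical order.
SUMSTATS_COLS <- c("snp", "chr", "pos", "ea", "nea", "eaf", "beta", "se",
                   "pval", "n", "trait")

VALID_ALLELES <- c("A", "C", "G", "T")

#' Validate a GWAS summary-statistics table
#'
#' Checks the per-variant invariants used throughout the package: positive
#' standard errors, effect-allele frequencies strictly inside (0, 1),
#' p-values in (0, 1], positive sample sizes, distinct alleles, and unique
#' variant identifiers. Rows with missing `eaf` are permitted (such variants
#' are later ineligible for R-squared, Steiger and colocalization).
#'
#' @param x data frame with columns `snp, chr, pos, ea, nea, eaf, beta, se,
#'   pval, n, trait`.
#' @param drop_invalid if `TRUE`, rows violating row-level invariants are
#'   dropped with a warning stating the count; if `FALSE` they raise an error.
#' @return the validated (possibly filtered) data frame, with class
#'   `"sumstats"` prepended.
#' @export
validate_sumstats <- function(x, drop_invalid = TRUE) {
  missing_cols <- setdiff(SUMSTATS_COLS, names(x))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x)[, SUMSTATS_COLS]
  x$ea <- toupper(as.character(x$ea))
  x$nea <- toupper(as.character(x$nea))

  bad <- !is.finite(x$se) | x$se <= 0 |
    (!is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1)) |
    !is.finite(x$pval) | x$pval <= 0 | x$pval > 1 |
    !is.finite(x$n) | x$n <= 0 |
    !is.finite(x$beta) |
    x$ea == x$nea |
    !(x$ea %in% VALID_ALLELES) | !(x$nea %in% VALID_ALLELES)
  if (any(bad)) {
    if (!drop_invalid) stop(sum(bad), " row(s) violate summary-statistic invariants")
    warning(sum(bad), " row(s) dropped for violating summary-statistic invariants")
    x <- x[!bad, , drop = FALSE]
  }
  if (nrow(x) == 0L) stop("no valid rows remain after filtering")

  dup <- unique(x$snp[duplicated(x$snp)])
  if (length(dup) > 0L) {
    stop("duplicated snp identifier(s): ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  rownames(x) <- NULL
  class(x) <- c("sumstats", "data.frame")
  x
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-delimited file with one row per variant and validates it.
#' Columns may be renamed through `column_map`, a named character vector
#' mapping canonical names (`snp`, `chr`, `pos`, `ea`, `nea`, `eaf`, `beta`,
#' `se`, `pval`, `n`, `trait`) to the names present in the file. A missing
#' `trait` column is filled with `trait`.
#'
#' @param path path to a tab-delimited text file with a header row.
#' @param column_map optional named character vector, canonical -> file name.
#' @param trait trait label used when the file carries no trait column.
#' @return a validated `sumstats` data frame.
#' @export
read_sumstats <- function(path, column_map = NULL, trait = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(x)) stop("mapped column not in file: ", src)
      names(x)[names(x) == src] <- canon
    }
  }
  if (!"trait" %in% names(x)) {
    x$trait <- if (is.null(trait)) "trait" else trait
  }
  missing_cols <- setdiff(SUMSTATS_COLS, names(x))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  validate_sumstats(x)
}

#' Write a summary-statistics table to tab-delimited text
#'
#' @param x a `sumstats` data frame.
#' @param path output path.
#' @export
write_sumstats <- function(x, path) {
  utils::write.table(as.data.frame(x)[, SUMSTATS_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct / validate an LD correlation matrix
#'
#' An LD matrix is a signed correlation matrix aligned to an ordered list of
#' variant identifiers (its dimnames). It must be symmetric with unit
#' diagonal, entries in [-1, 1], and positive semi-definite up to a small
#' tolerance.
#'
#' @param r square numeric matrix of signed correlations.
#' @param snps ordered character vector of variant identifiers; defaults to
#'   existing rownames.
#' @param tol eigenvalue tolerance for the PSD check.
#' @return the matrix with dimnames set and class `"ld_matrix"` prepended.
#' @export
ld_matrix <- function(r, snps = rownames(r), tol = 1e-8) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square")
  if (is.null(snps)) stop("LD matrix requires variant identifiers")
  if (length(snps) != nrow(r)) stop("snp list length does not match matrix")
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix must have unit diagonal")
  if (any(r < -1 - 1e-12 | r > 1 + 1e-12)) stop("LD entries must lie in [-1, 1]")
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop("LD matrix is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  }
  dimnames(r) <- list(snps, snps)
  class(r) <- c("ld_matrix", class(r))
  r
}

#' Read / write an LD matrix as plain text
#'
#' The matrix is stored as a whitespace-delimited square matrix with a
#' sidecar file (`<path>.snps`) holding the ordered variant list, one
#' identifier per line.
#'
#' @param path path to the matrix file.
#' @return an `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  snps <- readLines(paste0(path, ".snps"))
  r <- as.matrix(utils::read.table(path, header = FALSE))
  ld_matrix(unname(r), snps = snps)
}

#' @rdname read_ld_matrix
#' @param ld an `ld_matrix` to write.
#' @export
write_ld_matrix <- function(ld, path) {
  utils::write.table(format(unclass(ld), digits = 10), path, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(rownames(ld), paste0(path, ".snps"))
  invisible(path)
}

#' Read a gene annotation table
#'
#' Three tab-delimited columns: gene identifier, chromosome label, and
#' 1-based transcription start site.
#'
#' @param path path to the TSV file (header `gene`, `chr`, `tss`).
#' @return data frame with columns `gene`, `chr`, `tss`.
#' @export
read_gene_annotation <- function(path) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("gene", "chr", "tss") %in% names(x))) {
    stop("gene annotation requires columns gene, chr, tss")
  }
  if (any(x$tss < 1)) stop("tss must be >= 1")
  x
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(ea, nea) COMPLEMENT[[ea]] == nea

#' Align one variant record onto another's effect allele
#'
#' Re-expresses record `b` on record `a`'s effect allele, the harmonization
#' step of two-sample MR. If `b`'s alleles are swapped relative to `a`, the
#' effect sign is flipped and `eaf` becomes `1 - eaf`; strand-flipped
#' (complementary) alleles are complemented before comparison. Palindromic
#' variants (A/T or C/G) cannot be resolved by strand and are oriented by
#' allele frequency; when the frequency falls in the ambiguous band
#' (default [0.42, 0.58]) the record is flagged rather than aligned.
#'
#' @param a,b single-row variant records (data frames with at least
#'   `snp, ea, nea, eaf, beta`) sharing the same `snp`.
#' @param ambiguous_band frequency band inside which palindromic variants
#'   are declared unresolvable.
#' @return `b` aligned to `a`'s alleles, with a logical column `ambiguous`
#'   added (`TRUE` when a palindromic variant could not be oriented; such a
#'   record is returned unmodified otherwise).
#' @export
align_alleles <- function(a, b, ambiguous_band = c(0.42, 0.58)) {
  if (a$snp != b$snp) stop("align_alleles requires the same snp identifier")
  ea_a <- toupper(a$ea); nea_a <- toupper(a$nea)
  ea_b <- toupper(b$ea); nea_b <- toupper(b$nea)
  for (al in c(ea_a, nea_a, ea_b, nea_b)) {
    if (!al %in% VALID_ALLELES) stop("invalid allele: ", al)
  }
  b$ambiguous <- FALSE

  if (is_palindromic(ea_a, nea_a)) {
    if (!is_palindromic(ea_b, nea_b) ||
        !setequal(c(ea_a, nea_a), c(ea_b, nea_b))) {
      stop("incompatible allele pairs for snp ", a$snp)
    }
    freq_ok <- !is.na(a$eaf) && !is.na(b$eaf) &&
      (a$eaf < ambiguous_band[1] || a$eaf > ambiguous_band[2]) &&
      (b$eaf < ambiguous_band[1] || b$eaf > ambiguous_band[2])
    if (!freq_ok) {
      b$ambiguous <- TRUE
      return(b)
    }
    # Orient by frequency: the effect allele is the one on the same side of
    # 0.5 in both studies.
    same_side <- (a$eaf > 0.5) == (b$eaf > 0.5)
    if ((ea_b == ea_a && same_side) || (ea_b == nea_a && !same_side)) {
      b$ea <- ea_a; b$nea <- nea_a
      if (ea_b == nea_a) { b$beta <- -b$beta; b$eaf <- 1 - b$eaf }
      return(b)
    }
    # Frequencies disagree with the labelling: flip onto a's effect allele.
    b$ea <- ea_a; b$nea <- nea_a
    if (ea_b == ea_a) { b$beta <- -b$beta; b$eaf <- 1 - b$eaf }
    return(b)
  }

  match_direct <- function(x, y) x[1] == y[1] && x[2] == y[2]
  ab <- c(ea_a, nea_a)
  bb <- c(ea_b, nea_b)
  bb_comp <- unname(COMPLEMENT[bb])

  if (match_direct(ab, bb)) return(b)                      # identical
  if (match_direct(ab, rev(bb))) {                         # swapped
    b$ea <- ea_a; b$nea <- nea_a
    b$beta <- -b$beta
    if (!is.na(b$eaf)) b$eaf <- 1 - b$eaf
    return(b)
  }
  if (match_direct(ab, bb_comp)) {                         # strand flip
    b$ea <- ea_a; b$nea <- nea_a
    return(b)
  }
  if (match_direct(ab, rev(bb_comp))) {                    # strand flip + swap
    b$ea <- ea_a; b$nea <- nea_a
    b$beta <- -b$beta
    if (!is.na(b$eaf)) b$eaf <- 1 - b$eaf
    return(b)
  }
  stop("incompatible allele pairs for snp ", a$snp, ": ",
       ea_a, "/", nea_a, " vs ", ea_b, "/", nea_b)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects two summary-statistics tables on shared variant identifiers,
#' aligns the outcome records onto the exposure's effect alleles with
#' [align_alleles()], and drops palindromic variants whose orientation is
#' frequency-ambiguous.
#'
#' @param exposure,outcome `sumstats` tables.
#' @param ambiguous_band passed to [align_alleles()].
#' @return a `harmonized_set`: data frame with columns `snp, bx, se_x, by,
#'   se_y, eaf, n_x, n_y` and attributes `exposure_trait`, `outcome_trait`.
#' @export
harmonize <- function(exposure, outcome, ambiguous_band = c(0.42, 0.58)) {
  shared <- intersect(exposure$snp, outcome$snp)
  if (length(shared) == 0L) stop("no shared variants to harmonize")
  ex <- exposure[match(shared, exposure$snp), , drop = FALSE]
  out <- outcome[match(shared, outcome$snp), , drop = FALSE]
  rows <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    a <- ex[i, , drop = FALSE]
    b <- align_alleles(a, out[i, , drop = FALSE], ambiguous_band)
    if (b$ambiguous) next
    rows[[i]] <- data.frame(snp = a$snp, bx = a$beta, se_x = a$se,
                            by = b$beta, se_y = b$se, eaf = a$eaf,
                            n_x = a$n, n_y = b$n,
                            stringsAsFactors = FALSE)
  }
  h <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(h) || nrow(h) == 0L) stop("no variants remain after harmonization")
  rownames(h) <- NULL
  attr(h, "exposure_trait") <- exposure$trait[1]
  attr(h, "outcome_trait") <- outcome$trait[1]
  class(h) <- c("harmonized_set", "data.frame")
  h
}
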