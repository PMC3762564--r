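## Per-marker case/control allelic association: the basic 1-df chi-square
## on the 2x2 allele-count table, without continuity correction (the PLINK
## `--assoc` convention). With 6 cases and 3 controls and no missing calls
## the statistic is bounded by 18, attained exactly at complete separation,
## giving -log10(P) = 4.6557.

#' Allele counts for a marker in cases and controls
#'
#' Builds the 2x2 allelic table (cases vs controls x allele A vs B).
#' Missing genotypes are excluded; a heterozygote contributes one copy of
#' each allele.
#'
#' @param dataset a [genotype_dataset()].
#' @param marker_id marker identifier (or column index).
#' @return List with integer fields `case_a`, `case_b`, `ctrl_a`, `ctrl_b`.
#' @export
allelic_counts <- function(dataset, marker_id) {
  j <- if (is.numeric(marker_id)) as.integer(marker_id)
       else match(marker_id, dataset$markers$id)
  if (is.na(j) || j < 1L || j > ncol(dataset$geno))
    stop("marker not found: ", marker_id)
  g <- dataset$geno[, j]
  ph <- dataset$samples$phenotype
  .counts_one <- function(gg) {
    gg <- gg[!is.na(gg)]
    ## copies of allele_a: hom_a -> 2, het -> 1, hom_b -> 0
    a <- sum(2L - gg)
    c(a = a, b = 2L * length(gg) - a)
  }
  ca <- .counts_one(g[ph == "case"])
  co <- .counts_one(g[ph == "control"])
  list(case_a = ca[["a"]], case_b = ca[["b"]],
       ctrl_a = co[["a"]], ctrl_b = co[["b"]])
}

#' Allelic chi-square test on a 2x2 allele-count table
#'
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1 df and no Yates
#' continuity correction; the p-value is the upper tail of the chi-square
#' distribution. A zero margin (monomorphic marker, or no informative
#' samples in a group) yields an untestable result with `chi2 = 0`,
#' `p = 1` rather than an error, so that downstream tables keep one row
#' per marker.
#'
#' @param table list or numeric vector with `case_a`, `case_b`, `ctrl_a`,
#'   `ctrl_b` counts.
#' @return List with `chi2`, `df`, `p`, `neg_log10_p`, `odds_ratio`
#'   (NA when undefined) and `testable` (FALSE when a margin is zero).
#' @export
allelic_chi2 <- function(table) {
  a <- table[["case_a"]]; b <- table[["case_b"]]
  c_ <- table[["ctrl_a"]]; d <- table[["ctrl_b"]]
  stopifnot(a >= 0, b >= 0, c_ >= 0, d >= 0)
  n <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (n == 0 || any(margins == 0))
    return(list(chi2 = 0, df = 1L, p = 1, neg_log10_p = 0,
                odds_ratio = NA_real_, testable = FALSE))
  chi2 <- n * (a * d - b * c_)^2 / prod(as.numeric(margins))
  p <- pchisq(chi2, df = 1L, lower.tail = FALSE)
  or <- if (b * c_ > 0) (a * d) / (b * c_) else NA_real_
  list(chi2 = chi2, df = 1L, p = p, neg_log10_p = -log10(p),
       odds_ratio = or, testable = TRUE)
}

#' Genome-wide case/control allelic association scan
#'
#' Runs [allelic_chi2()] on every marker, preserving genome order, and
#' summarizes the set of markers attaining the maximum -log10(P), grouped
#' by chromosome. Statistics are kept at full double precision; any
#' 2-decimal rounding is display-only.
#'
#' @param dataset a [genotype_dataset()] with at least one case and one
#'   control.
#' @return A data.frame of class `gwas_result` with columns CHR, SNP, BP,
#'   A1, A2, CASE_A, CASE_B, CTRL_A, CTRL_B, CHISQ, P, NEG_LOG10_P,
#'   TESTABLE; attribute `top` holds the maximal markers.
#' @export
gwas <- function(dataset) {
  ph <- dataset$samples$phenotype
  if (!any(ph == "case") || !any(ph == "control"))
    stop("association requires at least one case and one control")
  m <- nrow(dataset$markers)
  res <- data.frame(CHR = dataset$markers$chrom, SNP = dataset$markers$id,
                    BP = dataset$markers$pos_bp,
                    A1 = dataset$markers$allele_a, A2 = dataset$markers$allele_b,
                    CASE_A = integer(m), CASE_B = integer(m),
                    CTRL_A = integer(m), CTRL_B = integer(m),
                    CHISQ = numeric(m), P = numeric(m),
                    NEG_LOG10_P = numeric(m), TESTABLE = logical(m),
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    tab <- allelic_counts(dataset, j)
    r <- allelic_chi2(tab)
    res$CASE_A[j] <- tab$case_a; res$CASE_B[j] <- tab$case_b
    res$CTRL_A[j] <- tab$ctrl_a; res$CTRL_B[j] <- tab$ctrl_b
    res$CHISQ[j] <- r$chi2; res$P[j] <- r$p
    res$NEG_LOG10_P[j] <- r$neg_log10_p; res$TESTABLE[j] <- r$testable
  }
  top <- res[0L, ]
  if (m > 0L && any(res$TESTABLE)) {
    mx <- max(res$NEG_LOG10_P[res$TESTABLE])
    if (mx > 0) top <- res[res$TESTABLE & res$NEG_LOG10_P >= mx - 1e-9, ]
  }
  attr(res, "top") <- top
  class(res) <- c("gwas_result", "data.frame")
  res
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf("gwas_result: %d markers tested (%d untestable)\n",
              nrow(x), sum(!x$TESTABLE)))
  top <- attr(x, "top")
  if (!is.null(top) && nrow(top)) {
    cat(sprintf("maximum -log10(P) = %.4f at %d marker(s):\n",
                max(top$NEG_LOG10_P), nrow(top)))
    by_chr <- table(top$CHR)
    for (ch in names(by_chr))
      cat(sprintf("  chromosome %s: %d marker(s)\n", ch, by_chr[[ch]]))
  }
  invisible(x)
}

#' Write an association scan as a plot-ready TSV
#'
#' @param result a [gwas()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_assoc_tsv <- function(result, path) {
  write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
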