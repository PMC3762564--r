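## Genotype-phenotype segregation analysis of a candidate variant:
## contingency tables over phenotype (normal / affected / suspicious /
## unknown) x genotype (hom_ref / het / hom_alt), discordant-record
## enumeration, and Fisher exact tests. "Suspicious" (tentative) and
## unknown phenotypes are shown in tables but excluded from the
## inferential 2x2 collapse.

SURVEY_PHENOTYPES <- c("normal", "affected", "suspicious", "unknown")
SURVEY_GENOTYPES <- c("hom_ref", "het", "hom_alt")

#' Read a per-individual survey table
#'
#' Tab-separated with a header; requires columns `sample`, `phenotype`,
#' `genotype`, and keeps any further columns (e.g. boolean trait tags) as
#' is.
#'
#' @param path TSV path.
#' @return data.frame of per-individual records.
#' @export
read_survey_tsv <- function(path) {
  rec <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "phenotype", "genotype")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("survey table lacks column(s): ",
                         paste(miss, collapse = ", "))
  rec
}

#' Cross-tabulate genotype by phenotype
#'
#' @param records data.frame with `phenotype` in normal / affected /
#'   suspicious / unknown and `genotype` in hom_ref / het / hom_alt (NA =
#'   missing, tallied separately).
#' @return A `survey_table`: counts matrix (phenotypes x genotypes) with
#'   attributes `missing` (per-phenotype missing-genotype tally) and
#'   `records`.
#' @export
crosstab <- function(records) {
  ph <- factor(records$phenotype, levels = SURVEY_PHENOTYPES)
  if (anyNA(ph) && nrow(records))
    stop("unknown phenotype label(s): ",
         paste(unique(records$phenotype[is.na(ph)]), collapse = ", "))
  gt <- factor(records$genotype, levels = SURVEY_GENOTYPES)
  bad <- !is.na(records$genotype) & is.na(gt)
  if (any(bad))
    stop("unknown genotype label(s): ",
         paste(unique(records$genotype[bad]), collapse = ", "))
  tab <- table(ph[!is.na(gt)], gt[!is.na(gt)])
  counts <- matrix(as.integer(tab), nrow = length(SURVEY_PHENOTYPES),
                   dimnames = list(SURVEY_PHENOTYPES, SURVEY_GENOTYPES))
  structure(counts,
            missing = as.integer(table(ph[is.na(gt)])),
            records = records, class = c("survey_table", "matrix"))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p by the probability-mass rule: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed table's (with 1e-7 relative slack for
#' ties). A zero margin yields p = 1.
#'
#' @param a,b,c,d non-negative integer cell counts (row-major).
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  if (n == 0) stop("empty table")
  r1 <- a + b; c1 <- a + c
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  k <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(k, r1, n - r1, c1)
  pobs <- dhyper(a, r1, n - r1, c1)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

.haldane_or <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5
                                 c <- c + 0.5; d <- d + 0.5 }
  (a * d) / (b * c)
}

.report_2x2 <- function(a, b, c, d, labels) {
  structure(list(table2x2 = matrix(c(a, b, c, d), 2L, byrow = TRUE,
                                   dimnames = labels),
                 fisher_p = if (a + b + c + d > 0) fisher_exact_2x2(a, b, c, d)
                            else 1,
                 odds_ratio = if (a + b + c + d > 0) .haldane_or(a, b, c, d)
                              else NA_real_,
                 insufficient = (a + b) == 0 || (c + d) == 0),
            class = "segregation_report")
}

#' Segregation report for a recessive candidate variant
#'
#' Classifies records against the recessive expectation (affected iff
#' hom_alt): phenocopies are affected individuals not homozygous for the
#' risk allele; non-penetrant individuals are phenotypically normal yet
#' hom_alt. The inferential 2x2 collapses affected vs normal x hom_alt vs
#' other; suspicious and unknown phenotypes are reported descriptively
#' only. The odds ratio uses the Haldane-Anscombe +0.5 correction when a
#' cell is zero.
#'
#' @param tab a [crosstab()] result.
#' @return A list of class `segregation_report`: table2x2, fisher_p,
#'   odds_ratio, insufficient, concordant_count, phenocopies,
#'   non_penetrant (ids when records are attached, else counts).
#' @export
segregation_report <- function(tab) {
  stopifnot(inherits(tab, "survey_table"))
  a <- tab["affected", "hom_alt"]
  b <- sum(tab["affected", c("hom_ref", "het")])
  c_ <- tab["normal", "hom_alt"]
  d <- sum(tab["normal", c("hom_ref", "het")])
  rep <- .report_2x2(a, b, c_, d,
                     list(c("affected", "normal"), c("hom_alt", "other")))
  rep$concordant_count <- a + d
  rec <- attr(tab, "records")
  ph_ids <- gt_ids <- NULL
  if (!is.null(rec) && nrow(rec)) {
    ph_ids <- rec$sample[rec$phenotype == "affected" &
                         !is.na(rec$genotype) & rec$genotype != "hom_alt"]
    gt_ids <- rec$sample[rec$phenotype == "normal" &
                         !is.na(rec$genotype) & rec$genotype == "hom_alt"]
  }
  rep$phenocopies <- ph_ids %||% b
  rep$non_penetrant <- gt_ids %||% c_
  rep$n_phenocopies <- b
  rep$n_non_penetrant <- c_
  rep
}

#' Association between a boolean trait tag and the risk genotype
#'
#' Applies the same 2x2 machinery to a named trait column (e.g. a coat or
#' fundus-appearance tag) versus hom_alt carriage, across all records with
#' a non-missing genotype and trait value.
#'
#' @param records per-individual data.frame (see [read_survey_tsv()]).
#' @param trait_label name of a logical column in `records`.
#' @return A `segregation_report` for trait x genotype.
#' @export
trait_association <- function(records, trait_label) {
  extra <- setdiff(names(records), c("sample", "phenotype", "genotype"))
  if (!trait_label %in% names(records))
    stop("unknown trait tag '", trait_label, "'; available: ",
         if (length(extra)) paste(extra, collapse = ", ") else "(none)")
  tr <- as.logical(records[[trait_label]])
  gt <- records$genotype
  ok <- !is.na(tr) & !is.na(gt)
  a <- sum(ok & tr & gt == "hom_alt")
  b <- sum(ok & tr & gt != "hom_alt")
  c_ <- sum(ok & !tr & gt == "hom_alt")
  d <- sum(ok & !tr & gt != "hom_alt")
  rep <- .report_2x2(a, b, c_, d,
                     list(c(trait_label, paste0("no_", trait_label)),
                          c("hom_alt", "other")))
  rep$concordant_count <- a + d
  rep
}

#' @export
print.segregation_report <- function(x, ...) {
  cat("segregation_report\n")
  print(x$table2x2)
  if (x$insufficient) cat("  insufficient data for the 2x2 collapse\n")
  cat(sprintf("  Fisher two-sided p = %.4g; odds ratio = %.3g\n",
              x$fisher_p, x$odds_ratio))
  if (!is.null(x$n_phenocopies))
    cat(sprintf("  concordant: %d; phenocopies (affected, not hom_alt): %d; non-penetrant (normal, hom_alt): %d\n",
                x$concordant_count, x$n_phenocopies, x$n_non_penetrant))
  invisible(x)
}
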