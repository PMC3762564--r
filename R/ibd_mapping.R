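## Cross-case shared-homozygosity mapping under a recessive model:
## intersect per-case ROH, verify the cases share one homozygous haplotype,
## refine the interval by marker-wise identity, and exclude any locus for
## which an unaffected control is homozygous for the same haplotype.

## ---- interval helpers (1-based inclusive bp) ----

.merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv$start), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1L]) {
    last <- nrow(out)
    if (iv$start[k] <= out$end[last] + 1L)
      out$end[last] <- max(out$end[last], iv$end[k])
    else out <- rbind(out, iv[k, ])
  }
  out
}

.intersect_intervals <- function(a, b) {
  rows <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
    if (s <= e) rows[[length(rows) + 1L]] <- data.frame(start = s, end = e)
  }
  if (length(rows)) .merge_intervals(do.call(rbind, rows))
  else data.frame(start = integer(), end = integer())
}

#' Genomic intervals homozygous in every case
#'
#' A candidate locus is emitted for every maximal interval covered by at
#' least one ROH segment of every case; chromosomes where any case lacks a
#' segment are dropped entirely.
#'
#' @param segments a [call_roh()] result restricted to the case samples.
#' @param cases character vector of case sample ids.
#' @return data.frame with columns chrom, start_bp, end_bp (the ROH core
#'   intervals), one row per locus.
#' @export
shared_roh_loci <- function(segments, cases) {
  stopifnot(length(cases) >= 1L)
  out <- list()
  for (ch in unique(segments$chrom)) {
    per_case <- lapply(cases, function(s) {
      sub <- segments[segments$sample == s & segments$chrom == ch, ]
      .merge_intervals(data.frame(start = sub$start_bp, end = sub$end_bp))
    })
    if (any(vapply(per_case, nrow, 0L) == 0L)) next
    shared <- Reduce(.intersect_intervals, per_case)
    for (k in seq_len(nrow(shared)))
      out[[length(out) + 1L]] <- data.frame(chrom = ch,
                                            start_bp = shared$start[k],
                                            end_bp = shared$end[k],
                                            stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(chrom = character(), start_bp = integer(),
                  end_bp = integer(), stringsAsFactors = FALSE)
}

## Per-marker identity status across cases at marker columns jj:
##   "viol"  — a case is heterozygous, or two cases are homozygous for
##             opposite alleles;
##   "info"  — every non-missing case is homozygous for the same allele;
##   "blank" — all cases missing (compatible but uninformative).
## Returns list(status, shared_code) where shared_code is 0 or 2 for
## "info" markers, NA otherwise.
.identity_status <- function(geno_cases, jj) {
  status <- character(length(jj))
  code <- rep(NA_integer_, length(jj))
  for (k in seq_along(jj)) {
    g <- geno_cases[, jj[k]]
    g <- g[!is.na(g)]
    if (length(g) == 0L) { status[k] <- "blank"; next }
    if (any(g == GENO_HET) || (any(g == GENO_HOM_A) && any(g == GENO_HOM_B))) {
      status[k] <- "viol"
    } else {
      status[k] <- "info"
      code[k] <- g[1L]
    }
  }
  list(status = status, shared_code = code)
}

#' Refine a shared locus by haplotype identity
#'
#' Verifies that every case is homozygous for the same allele at every
#' informative marker inside the ROH core (missing calls are compatible).
#' If some markers violate identity, the core is trimmed to the largest
#' violation-free stretch; the interval is then extended outward
#' marker-by-marker while identity holds. The refined interval may
#' therefore be smaller or larger than the core. A locus whose core
#' violates identity at more than half its markers is discarded.
#'
#' @param dataset a [genotype_dataset()].
#' @param locus one-row data.frame (or list) with chrom, start_bp, end_bp.
#' @param cases character vector of case sample ids.
#' @return A list of class `candidate_locus` (fields chrom, core_start,
#'   core_end, refined_start, refined_end, size_mb, shared_haplotype,
#'   case_support, discarded, reason), or with `discarded = TRUE` when
#'   identity fails across more than 50% of core markers.
#' @export
refine_by_identity <- function(dataset, locus, cases) {
  markers <- dataset$markers
  ch <- locus$chrom
  jj_chr <- which(markers$chrom == ch)
  pos <- markers$pos_bp[jj_chr]
  core_rel <- which(pos >= locus$start_bp & pos <= locus$end_bp)
  if (length(core_rel) == 0L)
    stop("no markers inside locus core on chromosome ", ch)
  geno_cases <- dataset$geno[cases, jj_chr, drop = FALSE]
  st <- .identity_status(geno_cases, seq_along(jj_chr))

  out <- list(chrom = ch, core_start = locus$start_bp, core_end = locus$end_bp,
              refined_start = NA_integer_, refined_end = NA_integer_,
              size_mb = NA_real_,
              core_size_mb = interval_size_mb(locus$start_bp, locus$end_bp),
              shared_haplotype = NULL,
              case_support = setNames(rep(TRUE, length(cases)), cases),
              control_carriers = character(), retained = NA,
              top_assoc_overlap = NA_integer_,
              discarded = FALSE, reason = NA_character_)
  class(out) <- "candidate_locus"

  core_viol <- st$status[core_rel] == "viol"
  if (mean(core_viol) > 0.5) {
    out$discarded <- TRUE
    out$reason <- sprintf("haplotype identity fails at %d of %d core markers",
                          sum(core_viol), length(core_rel))
    return(out)
  }
  ## largest violation-free stretch of core markers
  runs <- true_runs(!core_viol)
  best <- runs[which.max(runs[, "end"] - runs[, "start"]), , drop = FALSE]
  lo <- core_rel[best[1L, "start"]]
  hi <- core_rel[best[1L, "end"]]
  ## extend outward while identity holds
  while (lo > 1L && st$status[lo - 1L] != "viol") lo <- lo - 1L
  while (hi < length(jj_chr) && st$status[hi + 1L] != "viol") hi <- hi + 1L
  ## interval never ends on a missing or heterozygous marker
  while (lo <= hi && st$status[lo] != "info") lo <- lo + 1L
  while (hi >= lo && st$status[hi] != "info") hi <- hi - 1L
  if (lo > hi) {
    out$discarded <- TRUE
    out$reason <- "no informative identity-holding marker remains"
    return(out)
  }
  sel <- lo:hi
  out$refined_start <- pos[lo]
  out$refined_end <- pos[hi]
  out$size_mb <- interval_size_mb(pos[lo], pos[hi])
  code <- st$shared_code[sel]
  out$shared_haplotype <- data.frame(
    marker = markers$id[jj_chr[sel]], pos_bp = pos[sel], shared_code = code,
    allele = ifelse(is.na(code), NA_character_,
                    ifelse(code == GENO_HOM_A,
                           markers$allele_a[jj_chr[sel]],
                           markers$allele_b[jj_chr[sel]])),
    stringsAsFactors = FALSE)
  out
}

#' Recessive-model exclusion of loci carried by controls
#'
#' A control is a carrier of a locus iff it is homozygous for the shared
#' case haplotype at every informative marker of the refined interval
#' (missing calls are compatible). Under a fully penetrant recessive model
#' an aged unaffected control cannot be homozygous for the causal
#' haplotype, so a locus is retained iff it has at most
#' `max_carrier_controls` carriers (default 0; raise to explore incomplete
#' penetrance).
#'
#' @param locus a refined [refine_by_identity()] result.
#' @param dataset a [genotype_dataset()].
#' @param controls character vector of control sample ids.
#' @param max_carrier_controls carriers tolerated before exclusion.
#' @return The locus with `control_carriers` and `retained` filled in.
#' @export
filter_by_controls <- function(locus, dataset, controls,
                               max_carrier_controls = 0L) {
  if (isTRUE(locus$discarded)) return(locus)
  hap <- locus$shared_haplotype
  info <- !is.na(hap$shared_code)
  jj <- match(hap$marker[info], dataset$markers$id)
  want <- hap$shared_code[info]
  carriers <- character()
  for (s in controls) {
    g <- dataset$geno[s, jj]
    if (all(is.na(g) | g == want)) carriers <- c(carriers, s)
  }
  locus$control_carriers <- carriers
  locus$retained <- length(carriers) <= max_carrier_controls
  locus
}

#' Map a recessive locus by association plus shared homozygosity
#'
#' The full pipeline: per-marker allelic association ([gwas()]), per-case
#' ROH calling ([call_roh()]), intersection of case ROH into shared loci
#' ([shared_roh_loci()]), haplotype-identity refinement
#' ([refine_by_identity()]) and control-based exclusion
#' ([filter_by_controls()]). Retained loci are ranked by the number of
#' maximal-association markers they contain, then by size. Association
#' peaks falling outside every shared-homozygosity locus (single-SNP
#' signals with heterozygous cases nearby) are listed in the report as
#' unsupported.
#'
#' @param dataset a [genotype_dataset()] with at least one case and one
#'   control.
#' @param params a [roh_params()].
#' @param max_carrier_controls see [filter_by_controls()].
#' @return An object of class `recessive_map`: list with `loci` (all
#'   candidate loci), `retained` (ranked retained loci), `report`
#'   (one row per locus), `assoc` (the [gwas()] table), `roh`
#'   (case segments), `unsupported_top_markers`.
#' @export
map_recessive <- function(dataset, params = roh_params(),
                          max_carrier_controls = 0L) {
  cases <- case_ids(dataset)
  controls <- control_ids(dataset)
  if (length(cases) < 1L || length(controls) < 1L)
    stop("mapping requires at least one case and one control")

  assoc <- gwas(dataset)
  top <- attr(assoc, "top")
  segs <- call_roh(dataset, cases, params)
  cores <- shared_roh_loci(segs, cases)

  loci <- list()
  for (k in seq_len(nrow(cores))) {
    loc <- refine_by_identity(dataset, cores[k, ], cases)
    loc <- filter_by_controls(loc, dataset, controls, max_carrier_controls)
    if (!isTRUE(loc$discarded) && nrow(top))
      loc$top_assoc_overlap <- sum(top$CHR == loc$chrom &
                                   top$BP >= loc$refined_start &
                                   top$BP <= loc$refined_end)
    else if (!isTRUE(loc$discarded)) loc$top_assoc_overlap <- 0L
    loci[[length(loci) + 1L]] <- loc
  }

  report <- do.call(rbind, c(lapply(loci, function(l) data.frame(
    CHR = l$chrom, START = l$core_start, END = l$core_end,
    SIZE_MB = l$core_size_mb,
    REFINED_START = l$refined_start, REFINED_END = l$refined_end,
    REFINED_SIZE_MB = l$size_mb,
    CONTROL_CARRIERS = paste(l$control_carriers, collapse = ","),
    RETAINED = isTRUE(l$retained), DISCARDED = isTRUE(l$discarded),
    TOP_ASSOC_OVERLAP = l$top_assoc_overlap,
    stringsAsFactors = FALSE)), make.row.names = FALSE))
  if (is.null(report))
    report <- data.frame(CHR = character(), START = integer(),
                         END = integer(), SIZE_MB = numeric(),
                         REFINED_START = integer(), REFINED_END = integer(),
                         REFINED_SIZE_MB = numeric(),
                         CONTROL_CARRIERS = character(),
                         RETAINED = logical(), DISCARDED = logical(),
                         TOP_ASSOC_OVERLAP = integer(),
                         stringsAsFactors = FALSE)

  keep <- vapply(loci, function(l) isTRUE(l$retained), TRUE)
  retained <- loci[keep]
  if (length(retained)) {
    ord <- order(-vapply(retained, function(l) l$top_assoc_overlap, 0L),
                 -vapply(retained, function(l) l$size_mb, 0))
    retained <- retained[ord]
  }

  unsupported <- top[0L, ]
  if (nrow(top)) {
    inside <- rep(FALSE, nrow(top))
    for (l in loci) {
      if (isTRUE(l$discarded)) next
      inside <- inside | (top$CHR == l$chrom & top$BP >= l$refined_start &
                          top$BP <= l$refined_end)
    }
    unsupported <- top[!inside, ]
  }

  structure(list(loci = loci, retained = retained, report = report,
                 assoc = assoc, roh = segs,
                 unsupported_top_markers = unsupported,
                 params = params),
            class = "recessive_map")
}

#' @export
print.candidate_locus <- function(x, ...) {
  if (isTRUE(x$discarded)) {
    cat(sprintf("candidate_locus chr%s: discarded (%s)\n", x$chrom, x$reason))
    return(invisible(x))
  }
  cat(sprintf("candidate_locus chr%s: core %s-%s (%.2f Mb), refined %s-%s (%.2f Mb)\n",
              x$chrom, format(x$core_start, big.mark = ","),
              format(x$core_end, big.mark = ","), x$core_size_mb,
              format(x$refined_start, big.mark = ","),
              format(x$refined_end, big.mark = ","), x$size_mb))
  if (!is.na(x$retained))
    cat(if (x$retained) "  retained: no control carries the haplotype\n"
        else paste0("  excluded: carrier control(s) ",
                    paste(x$control_carriers, collapse = ", "), "\n"))
  invisible(x)
}

#' @export
print.recessive_map <- function(x, ...) {
  cat(sprintf("recessive_map: %d shared loci, %d retained\n",
              length(x$loci), length(x$retained)))
  if (nrow(x$report)) print.data.frame(x$report)
  if (nrow(x$unsupported_top_markers))
    cat(sprintf("%d maximal-association marker(s) outside every shared locus\n",
                nrow(x$unsupported_top_markers)))
  invisible(x)
}

#' @export
summary.recessive_map <- function(object, ...) {
  cat(sprintf("Association: %d markers, max -log10(P) = %.4f at %d marker(s)\n",
              nrow(object$assoc),
              if (nrow(attr(object$assoc, "top"))) max(attr(object$assoc, "top")$NEG_LOG10_P) else NA,
              nrow(attr(object$assoc, "top"))))
  cat(sprintf("Case ROH: %d segment(s), total %.2f Mb\n",
              nrow(object$roh), sum(object$roh$length_kb) / 1000))
  cat(sprintf("Shared loci: %d (total %.2f Mb core); retained after control exclusion: %d\n",
              length(object$loci),
              sum(vapply(object$loci, function(l) l$core_size_mb, 0)),
              length(object$retained)))
  for (l in object$retained) print(l)
  invisible(object)
}

#' Write the locus report as TSV
#' @param x a [map_recessive()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_locus_report <- function(x, path) {
  write.table(x$report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
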