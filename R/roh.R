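## Sliding-window runs-of-homozygosity detection.
##
## A window is a fixed count of consecutive SNPs (the kb window figure is
## carried in the parameters for the record but not enforced, which is the
## effective behavior of the PLINK sliding-window homozygosity scan these
## defaults come from). A window is called homozygous if it contains at
## most `window_max_het` heterozygous and `window_max_missing` missing
## calls; each SNP is scored by the fraction of windows containing it that
## are homozygous, and SNPs at or above `snp_hit_threshold` seed candidate
## runs.

#' Runs-of-homozygosity parameters
#'
#' Defaults reproduce a 1,000 kb / 150 SNP sliding-window scan allowing
#' five missing and one heterozygous call per window with a 0.05 SNP hit
#' threshold, and segment criteria of 1,000 kb minimum length, 150 SNP
#' minimum count and 50 kb/SNP maximum mean density. `seg_max_gap_kb`
#' (default 1,000 kb) splits a run where adjacent SNPs are further apart.
#'
#' @param window_snp SNPs per sliding window.
#' @param window_kb nominal window span in kb (recorded, not enforced).
#' @param window_max_het maximum heterozygous calls in a homozygous window.
#' @param window_max_missing maximum missing calls in a homozygous window.
#' @param snp_hit_threshold minimum fraction of homozygous windows covering
#'   a SNP for it to join a run, in (0, 1].
#' @param seg_min_kb minimum segment length, kb.
#' @param seg_min_snp minimum SNPs per segment.
#' @param seg_max_density_kb_per_snp maximum mean density (segment kb per
#'   SNP).
#' @param seg_max_gap_kb maximum gap between consecutive SNPs in a run, kb.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snp = 150L, window_kb = 1000,
                       window_max_het = 1L, window_max_missing = 5L,
                       snp_hit_threshold = 0.05,
                       seg_min_kb = 1000, seg_min_snp = 150L,
                       seg_max_density_kb_per_snp = 50,
                       seg_max_gap_kb = 1000) {
  p <- list(window_snp = as.integer(window_snp), window_kb = window_kb,
            window_max_het = as.integer(window_max_het),
            window_max_missing = as.integer(window_max_missing),
            snp_hit_threshold = snp_hit_threshold,
            seg_min_kb = seg_min_kb, seg_min_snp = as.integer(seg_min_snp),
            seg_max_density_kb_per_snp = seg_max_density_kb_per_snp,
            seg_max_gap_kb = seg_max_gap_kb)
  stopifnot(p$window_snp >= 1L, p$window_kb > 0, p$window_max_het >= 0L,
            p$window_max_missing >= 0L,
            p$snp_hit_threshold > 0, p$snp_hit_threshold <= 1,
            p$seg_min_kb > 0, p$seg_min_snp >= 1L,
            p$seg_max_density_kb_per_snp > 0, p$seg_max_gap_kb > 0)
  class(p) <- "roh_params"
  p
}

#' Per-SNP homozygous-window fraction
#'
#' For one sample on one chromosome, scores every SNP by the fraction of
#' sliding windows containing it that are homozygous. Near chromosome ends
#' the denominator is the reduced number of existing windows; a chromosome
#' shorter than the window is treated as a single whole-chromosome window.
#'
#' @param calls integer genotype vector (0/1/2/NA) ordered by position.
#' @param params a [roh_params()].
#' @return Numeric vector in \[0, 1\], one value per SNP.
#' @export
window_hom_fraction <- function(calls, params = roh_params()) {
  n <- length(calls)
  if (n == 0L) return(numeric(0))
  w <- min(params$window_snp, n)
  het <- as.integer(!is.na(calls) & calls == GENO_HET)
  mis <- as.integer(is.na(calls))
  ## per-window counts via cumulative sums
  ch <- cumsum(het); cm <- cumsum(mis)
  nw <- n - w + 1L
  starts <- seq_len(nw)
  het_w <- ch[starts + w - 1L] - c(0L, ch)[starts]
  mis_w <- cm[starts + w - 1L] - c(0L, cm)[starts]
  hom <- as.integer(het_w <= params$window_max_het &
                    mis_w <= params$window_max_missing)
  chom <- c(0L, cumsum(hom))
  j <- seq_len(n)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(j, nw)
  (chom[hi + 1L] - chom[lo]) / (hi - lo + 1L)
}

## Candidate runs of hit SNPs on one chromosome -> filtered segments.
.segments_one_chrom <- function(calls, pos, params) {
  frac <- window_hom_fraction(calls, params)
  hit <- frac >= params$snp_hit_threshold
  out <- list()
  runs <- true_runs(hit)
  for (k in seq_len(nrow(runs))) {
    idx <- runs[k, "start"]:runs[k, "end"]
    ## split where the inter-SNP gap exceeds seg_max_gap_kb
    gaps <- diff(pos[idx]) / 1000
    cut <- which(gaps > params$seg_max_gap_kb)
    bounds <- cbind(c(1L, cut + 1L), c(cut, length(idx)))
    for (b in seq_len(nrow(bounds))) {
      sub <- idx[bounds[b, 1L]:bounds[b, 2L]]
      ## trim to terminal confidently homozygous (non-missing, non-het) calls
      ok <- !is.na(calls[sub]) & calls[sub] != GENO_HET
      if (!any(ok)) next
      sub <- sub[min(which(ok)):max(which(ok))]
      n_snp <- length(sub)
      len_kb <- (pos[sub[n_snp]] - pos[sub[1L]] + 1L) / 1000
      if (n_snp >= params$seg_min_snp && len_kb >= params$seg_min_kb &&
          len_kb / n_snp <= params$seg_max_density_kb_per_snp)
        out[[length(out) + 1L]] <- c(first = sub[1L], last = sub[n_snp],
                                     n_snp = n_snp)
    }
  }
  out
}

#' Call runs of homozygosity
#'
#' Detects ROH segments per sample: SNPs whose homozygous-window fraction
#' meets `snp_hit_threshold` form candidate runs, runs are split at gaps
#' wider than `seg_max_gap_kb`, trimmed so both terminal SNPs are
#' confidently homozygous (missing calls inside a run are retained — they
#' are not evidence of homozygosity but do not break the run), and kept if
#' they meet the minimum length, minimum SNP count, and maximum mean
#' density criteria.
#'
#' @param dataset a [genotype_dataset()].
#' @param sample_ids samples to scan (default: all).
#' @param params a [roh_params()].
#' @return A data.frame of class `roh_segments` with columns sample,
#'   chrom, start_bp, end_bp, n_snp, length_kb, length_mb, density_kb_snp.
#' @export
call_roh <- function(dataset, sample_ids = dataset$samples$id,
                     params = roh_params()) {
  stopifnot(all(sample_ids %in% dataset$samples$id))
  markers <- dataset$markers
  rows <- list()
  for (sid in sample_ids) {
    g <- dataset$geno[sid, ]
    for (ch in unique(markers$chrom)) {
      jj <- which(markers$chrom == ch)
      segs <- .segments_one_chrom(g[jj], markers$pos_bp[jj], params)
      for (s in segs) {
        start_bp <- markers$pos_bp[jj[s[["first"]]]]
        end_bp <- markers$pos_bp[jj[s[["last"]]]]
        len_kb <- (end_bp - start_bp + 1L) / 1000
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sid, chrom = ch, start_bp = start_bp, end_bp = end_bp,
          n_snp = s[["n_snp"]], length_kb = len_kb,
          length_mb = interval_size_mb(start_bp, end_bp),
          density_kb_snp = len_kb / s[["n_snp"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(sample = character(), chrom = character(),
                         start_bp = integer(), end_bp = integer(),
                         n_snp = integer(), length_kb = numeric(),
                         length_mb = numeric(), density_kb_snp = numeric(),
                         stringsAsFactors = FALSE)
  class(out) <- c("roh_segments", "data.frame")
  out
}

#' @export
print.roh_segments <- function(x, ...) {
  cat(sprintf("roh_segments: %d segment(s) in %d sample(s); total %.2f Mb\n",
              nrow(x), length(unique(x$sample)), sum(x$length_kb) / 1000))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}
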