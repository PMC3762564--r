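# Independent brute-force oracles and small fixture builders shared by the
# test files. Everything here is deliberately written the slow, literal way
# (explicit window materialization, full-enumeration probabilities, grid
# search) so it shares no code path with the package implementation.

# Brute-force homozygous-window fraction: materialize every window.
oracle_window_fraction <- function(calls, params) {
  n <- length(calls)
  w <- min(params$window_snp, n)
  starts <- seq_len(n - w + 1L)
  hom <- vapply(starts, function(s) {
    win <- calls[s:(s + w - 1L)]
    sum(!is.na(win) & win == 1L) <= params$window_max_het &&
      sum(is.na(win)) <= params$window_max_missing
  }, TRUE)
  vapply(seq_len(n), function(j) {
    covering <- starts[starts <= j & j <= starts + w - 1L]
    mean(hom[match(covering, starts)])
  }, 0)
}

# Brute-force segment caller on one chromosome: hit SNPs, gap splits, end
# trimming and the three segment criteria, all via plain loops.
oracle_call_roh_chrom <- function(calls, pos, params) {
  frac <- oracle_window_fraction(calls, params)
  hit <- frac >= params$snp_hit_threshold
  segs <- list()
  run <- integer()
  flush <- function(run) {
    if (!length(run)) return(NULL)
    is_hom <- !is.na(calls[run]) & calls[run] != 1L
    if (!any(is_hom)) return(NULL)
    run <- run[min(which(is_hom)):max(which(is_hom))]
    len_kb <- (pos[run[length(run)]] - pos[run[1L]] + 1L) / 1000
    if (length(run) >= params$seg_min_snp && len_kb >= params$seg_min_kb &&
        len_kb / length(run) <= params$seg_max_density_kb_per_snp)
      c(start_bp = pos[run[1L]], end_bp = pos[run[length(run)]],
        n_snp = length(run))
    else NULL
  }
  for (j in seq_along(calls)) {
    if (hit[j]) {
      if (length(run) &&
          (pos[j] - pos[run[length(run)]]) / 1000 > params$seg_max_gap_kb) {
        s <- flush(run); if (!is.null(s)) segs[[length(segs) + 1L]] <- s
        run <- integer()
      }
      run <- c(run, j)
    } else {
      s <- flush(run); if (!is.null(s)) segs[[length(segs) + 1L]] <- s
      run <- integer()
    }
  }
  s <- flush(run); if (!is.null(s)) segs[[length(segs) + 1L]] <- s
  if (length(segs)) do.call(rbind, segs) else
    matrix(numeric(), 0L, 3L,
           dimnames = list(NULL, c("start_bp", "end_bp", "n_snp")))
}

# Full-enumeration two-sided Fisher p via binomial coefficients.
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- choose(r1, ks) * choose(n - r1, c1 - ks) / choose(n, c1)
  pobs <- pr[match(a, ks)]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# Grid-search isoelectric point: own Henderson-Hasselbalch charge from the
# Bjellqvist pKa table, coarse 1e-3 grid then 1e-5 refinement.
oracle_pi <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  nterm <- switch(aa[1], A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                  V = 7.44, E = 7.7, 7.5)
  charge <- function(pH) {
    q <- 1 / (1 + 10^(pH - nterm)) - 1 / (1 + 10^(3.55 - pH))
    for (r in aa) {
      q <- q + switch(r,
                      R = 1 / (1 + 10^(pH - 12.0)),
                      K = 1 / (1 + 10^(pH - 10.0)),
                      H = 1 / (1 + 10^(pH - 5.98)),
                      D = -1 / (1 + 10^(4.05 - pH)),
                      E = -1 / (1 + 10^(4.45 - pH)),
                      C = -1 / (1 + 10^(9.0 - pH)),
                      Y = -1 / (1 + 10^(10.0 - pH)),
                      0)
    }
    q
  }
  grid <- seq(0, 14, by = 1e-3)
  i <- which.min(abs(vapply(grid, charge, 0)))
  fine <- seq(max(0, grid[i] - 2e-3), min(14, grid[i] + 2e-3), by = 1e-5)
  fine[which.min(abs(vapply(fine, charge, 0)))]
}

# Scan every downstream in-frame codon of a transcript's 3'UTR; returns the
# number of codons before the first stop (Inf if none).
oracle_utr_codons_to_stop <- function(tx) {
  utr <- substr(tx$mrna_seq, tx$cds_end + 1L, nchar(tx$mrna_seq))
  k <- 0L
  while (3L * (k + 1L) <= nchar(utr)) {
    codon <- substr(utr, 3L * k + 1L, 3L * k + 3L)
    if (codon %in% c("TAA", "TAG", "TGA")) return(k)
    k <- k + 1L
  }
  Inf
}

# Build a genotype_dataset from a code matrix (rows samples, cols markers).
make_dataset <- function(codes, phenotypes, chrom = "1", pos = NULL,
                         spacing_bp = 10000L) {
  codes <- as.matrix(codes)
  n <- nrow(codes); m <- ncol(codes)
  if (is.null(pos)) pos <- spacing_bp * seq_len(m)
  chrom <- rep_len(chrom, m)
  samples <- data.frame(id = sprintf("s%02d", seq_len(n)),
                        phenotype = phenotypes, stringsAsFactors = FALSE)
  markers <- data.frame(chrom = chrom, id = sprintf("m%04d", seq_len(m)),
                        cM = 0, pos_bp = as.integer(pos),
                        allele_a = "A", allele_b = "G",
                        stringsAsFactors = FALSE)
  genotype_dataset(samples, markers, codes)
}

# Random genotype vector with given het/missing rates.
random_calls <- function(n, het = 0.3, miss = 0.05) {
  g <- sample(c(0L, 2L), n, replace = TRUE)
  g[runif(n) < het] <- 1L
  g[runif(n) < miss] <- NA_integer_
  g
}

study_fixture_path <- function() {
  system.file("extdata", "sag_survey.tsv", package = "rohmap")
}
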