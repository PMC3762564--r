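## Seeded generators of (a) inbred case-control cohorts with planted
## identical-by-descent loci and (b) transcripts with an engineered
## downstream in-frame stop, so that every analysis module is testable
## end to end without external data.
##
## Cohort model: each gamete is a mosaic of a small founder-haplotype pool
## (recombination by a Haldane no-interference process, 1 cM ~ 1 Mb), the
## low-diversity structure of an isolate breed descended from few
## founders. Planted loci are painted post hoc: cases receive two copies
## of a designated founder haplotype across the disease interval, decoy
## intervals are painted into all cases and into designated carrier
## controls (with a margin, emulating the longer ancestral haplotype an
## unaffected carrier shares around the block). Painting trades
## coalescent realism for exact control of the truth table.

#' Simulation configuration for a synthetic cohort
#'
#' @param seed integer seed (mandatory; the generator is deterministic per
#'   seed).
#' @param n_founder_haplotypes founder haplotype pool size (default 8,
#'   emulating descent from a small number of founders).
#' @param chromosomes data.frame with columns `name`, `length_bp`, `n_snp`.
#' @param n_cases,n_controls cohort sizes (defaults 6 and 3).
#' @param disease_locus NULL or list(chrom, start_bp, end_bp): interval
#'   over which every case is homozygous identical-by-descent and no
#'   control is.
#' @param decoy_loci list of list(chrom, start_bp, end_bp,
#'   carrier_controls): intervals painted homozygous into all cases and
#'   the listed controls (indices into the control set).
#' @param recomb_rate_cm_mb recombination rate, cM/Mb (Haldane model).
#' @param genotype_missing_rate,genotype_error_rate per-call rates in
#'   \[0,1\]; errors flip hom to het and het to a random hom.
#' @param penetrance,phenocopy_rate P(affected | homozygous carrier) and
#'   P(affected | not).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_founder_haplotypes = 8L,
                       chromosomes = data.frame(name = "1",
                                                length_bp = 26e6,
                                                n_snp = 2000L),
                       n_cases = 6L, n_controls = 3L,
                       disease_locus = NULL, decoy_loci = list(),
                       recomb_rate_cm_mb = 1.0,
                       genotype_missing_rate = 0,
                       genotype_error_rate = 0,
                       penetrance = 1.0, phenocopy_rate = 0) {
  cfg <- list(seed = as.integer(seed),
              n_founder_haplotypes = as.integer(n_founder_haplotypes),
              chromosomes = as.data.frame(chromosomes,
                                          stringsAsFactors = FALSE),
              n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              disease_locus = disease_locus, decoy_loci = decoy_loci,
              recomb_rate_cm_mb = recomb_rate_cm_mb,
              genotype_missing_rate = genotype_missing_rate,
              genotype_error_rate = genotype_error_rate,
              penetrance = penetrance, phenocopy_rate = phenocopy_rate)
  stopifnot(length(cfg$seed) == 1L, !is.na(cfg$seed),
            cfg$n_founder_haplotypes >= 1L,
            all(cfg$chromosomes$n_snp >= 2L),
            all(cfg$chromosomes$length_bp > 0),
            cfg$n_cases >= 1L, cfg$n_controls >= 0L,
            cfg$recomb_rate_cm_mb >= 0,
            cfg$genotype_missing_rate >= 0, cfg$genotype_missing_rate <= 1,
            cfg$genotype_error_rate >= 0, cfg$genotype_error_rate <= 1,
            cfg$penetrance >= 0, cfg$penetrance <= 1,
            cfg$phenocopy_rate >= 0, cfg$phenocopy_rate <= 1)
  all_loci <- c(if (!is.null(disease_locus)) list(disease_locus),
                decoy_loci)
  for (l in all_loci) {
    ci <- match(l$chrom, cfg$chromosomes$name)
    if (is.na(ci)) stop("locus chromosome not in config: ", l$chrom)
    if (l$start_bp < 1 || l$end_bp > cfg$chromosomes$length_bp[ci] ||
        l$start_bp >= l$end_bp)
      stop("locus interval outside chromosome ", l$chrom)
  }
  if (length(all_loci) > 1L) {
    for (i in seq_along(all_loci)[-1L]) for (j in seq_len(i - 1L)) {
      a <- all_loci[[i]]; b <- all_loci[[j]]
      if (a$chrom == b$chrom && a$start_bp <= b$end_bp &&
          b$start_bp <= a$end_bp)
        stop("planted intervals overlap on chromosome ", a$chrom)
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Study-scale simulation preset
#'
#' Five 26-Mb chromosomes at 2,200 SNPs each (~11.8 kb spacing, the
#' density of a high-density canine array scaled to desk size), 8 founder
#' haplotypes, 6 cases / 3 controls, one 2.09-Mb disease locus and four
#' decoy shared-homozygosity loci each carried homozygously by two of the
#' three controls, 1% missing calls.
#'
#' @param seed integer seed.
#' @return A [sim_config()].
#' @export
sim_config_study <- function(seed) {
  chroms <- data.frame(name = c("6", "17", "21", "25", "35"),
                       length_bp = rep(26e6, 5), n_snp = rep(2200L, 5),
                       stringsAsFactors = FALSE)
  sim_config(seed = seed, n_founder_haplotypes = 8L, chromosomes = chroms,
             n_cases = 6L, n_controls = 3L,
             disease_locus = list(chrom = "25", start_bp = 10000000L,
                                  end_bp = 12090000L),
             decoy_loci = list(
               list(chrom = "6", start_bp = 3000000L, end_bp = 5940000L,
                    carrier_controls = c(1L, 2L)),
               list(chrom = "17", start_bp = 8000000L, end_bp = 10960000L,
                    carrier_controls = c(1L, 2L)),
               list(chrom = "21", start_bp = 5000000L, end_bp = 7730000L,
                    carrier_controls = c(1L, 2L)),
               list(chrom = "35", start_bp = 14000000L, end_bp = 16200000L,
                    carrier_controls = c(1L, 2L))),
             genotype_missing_rate = 0.01)
}

#' Null-scenario simulation preset
#'
#' No planted locus and a larger (24-haplotype) founder pool — a
#' relatively outbred cohort in which the mapping pipeline should retain
#' nothing. Smaller than the study preset (4 chromosomes x 1,200 SNPs) so
#' that replicate batteries stay cheap.
#'
#' @param seed integer seed.
#' @return A [sim_config()].
#' @export
sim_config_null <- function(seed) {
  chroms <- data.frame(name = as.character(1:4),
                       length_bp = rep(16e6, 4), n_snp = rep(1200L, 4),
                       stringsAsFactors = FALSE)
  sim_config(seed = seed, n_founder_haplotypes = 24L, chromosomes = chroms,
             n_cases = 6L, n_controls = 3L,
             genotype_missing_rate = 0.01)
}

## Haldane gamete: mosaic over founder haplotype indices at the marker
## positions of one chromosome.
.sim_gamete <- function(founders, pos_bp, length_bp, rate_cm_mb) {
  n_f <- nrow(founders)
  expected_xo <- (length_bp / 1e6) * rate_cm_mb / 100
  n_xo <- rpois(1L, expected_xo)
  breaks <- sort(runif(n_xo, 1, length_bp))
  src <- sample.int(n_f, n_xo + 1L, replace = TRUE)
  seg <- findInterval(pos_bp, breaks) + 1L
  founders[cbind(src[seg], seq_along(pos_bp))]
}

#' Simulate a genotyped cohort with planted IBD loci
#'
#' Founder haplotypes are drawn with per-marker allele frequencies from
#' Uniform(0.1, 0.9); each sample's two gametes are founder mosaics under
#' a seeded Haldane recombination process; the disease interval is painted
#' homozygous (two copies of the designated founder haplotype) into every
#' case, and any control that would be autozygous for it has one gamete
#' repainted; decoy intervals are painted into all cases and the listed
#' carrier controls (with a small marker margin). Genotyping error and
#' missingness are injected last. Phenotypes follow carrier status through
#' the penetrance and phenocopy rates.
#'
#' @param cfg a [sim_config()].
#' @return list(dataset = [genotype_dataset()], truth = `sim_truth` list
#'   with the planted intervals, their marker-index bounds, per-sample
#'   carrier/affection status, and per-marker founder allele frequencies).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cases + cfg$n_controls
  n_f <- cfg$n_founder_haplotypes
  control_margin <- 10L   # extra painted markers around decoys in carriers

  marker_rows <- list()
  gam1 <- list(); gam2 <- list()
  freqs <- list()
  for (ci in seq_len(nrow(cfg$chromosomes))) {
    ch <- cfg$chromosomes$name[ci]
    len <- cfg$chromosomes$length_bp[ci]
    m <- cfg$chromosomes$n_snp[ci]
    spacing <- len / m
    pos <- round(spacing * (seq_len(m) - 0.5) +
                 runif(m, -0.3, 0.3) * spacing)
    pos <- pmax(1, pos)
    pos <- as.integer(cummax(pos) + seq_len(m) - 1L)  # strictly increasing
    pair <- replicate(m, sample(c("A", "C", "G", "T"), 2L))
    p <- runif(m, 0.1, 0.9)
    founders <- matrix(rbinom(n_f * m, 1L, rep(p, each = n_f)), n_f, m)
    g1 <- t(vapply(seq_len(n), function(s)
      .sim_gamete(founders, pos, len, cfg$recomb_rate_cm_mb), integer(m)))
    g2 <- t(vapply(seq_len(n), function(s)
      .sim_gamete(founders, pos, len, cfg$recomb_rate_cm_mb), integer(m)))
    marker_rows[[ci]] <- data.frame(
      chrom = ch, id = sprintf("snp_%s_%05d", ch, seq_len(m)),
      cM = pos / 1e6 * cfg$recomb_rate_cm_mb, pos_bp = pos,
      allele_a = pair[1L, ], allele_b = pair[2L, ],
      stringsAsFactors = FALSE)
    gam1[[ci]] <- g1; gam2[[ci]] <- g2
    freqs[[ch]] <- p
    attr(freqs[[ch]], "founders") <- founders
  }

  case_idx <- seq_len(cfg$n_cases)
  ctrl_idx <- cfg$n_cases + seq_len(cfg$n_controls)
  truth_loci <- list()

  .paint <- function(locus, hap_row, carriers_extra, margin_extra) {
    ci <- match(locus$chrom, cfg$chromosomes$name)
    founders <- attr(freqs[[locus$chrom]], "founders")
    pos <- marker_rows[[ci]]$pos_bp
    jj <- which(pos >= locus$start_bp & pos <= locus$end_bp)
    if (length(jj) == 0L) stop("planted interval contains no markers")
    for (s in case_idx) {
      gam1[[ci]][s, jj] <<- founders[hap_row, jj]
      gam2[[ci]][s, jj] <<- founders[hap_row, jj]
    }
    jj_wide <- max(1L, min(jj) - margin_extra):
               min(length(pos), max(jj) + margin_extra)
    for (s in carriers_extra) {
      gam1[[ci]][s, jj_wide] <<- founders[hap_row, jj_wide]
      gam2[[ci]][s, jj_wide] <<- founders[hap_row, jj_wide]
    }
    list(chrom = locus$chrom, start_bp = pos[min(jj)], end_bp = pos[max(jj)],
         first_marker = min(jj), last_marker = max(jj), hap = hap_row)
  }

  if (!is.null(cfg$disease_locus)) {
    d <- .paint(cfg$disease_locus, 1L, integer(), 0L)
    ## controls carry at most one copy of the disease haplotype
    ci <- match(d$chrom, cfg$chromosomes$name)
    founders <- attr(freqs[[d$chrom]], "founders")
    jj <- d$first_marker:d$last_marker
    alt <- if (n_f >= 2L) 2L else 1L
    for (s in ctrl_idx) {
      hom_d <- all(gam1[[ci]][s, jj] == founders[1L, jj]) &&
               all(gam2[[ci]][s, jj] == founders[1L, jj])
      if (hom_d && n_f >= 2L) gam2[[ci]][s, jj] <- founders[alt, jj]
    }
    truth_loci$disease <- d
  }
  if (length(cfg$decoy_loci)) {
    truth_loci$decoys <- vector("list", length(cfg$decoy_loci))
    for (k in seq_along(cfg$decoy_loci)) {
      dl <- cfg$decoy_loci[[k]]
      hap <- if (n_f >= 2L) 1L + (k %% (n_f - 1L)) + 0L else 1L
      carriers <- ctrl_idx[dl$carrier_controls]
      truth_loci$decoys[[k]] <- c(.paint(dl, hap, carriers, control_margin),
                                  list(carrier_controls = carriers))
    }
  }

  geno <- do.call(cbind, lapply(seq_len(nrow(cfg$chromosomes)),
                                function(ci) gam1[[ci]] + gam2[[ci]]))
  markers <- do.call(rbind, marker_rows)

  ## carrier/affection status (before error/missingness injection)
  carrier <- rep(FALSE, n)
  if (!is.null(cfg$disease_locus)) {
    d <- truth_loci$disease
    ci <- match(d$chrom, cfg$chromosomes$name)
    founders <- attr(freqs[[d$chrom]], "founders")
    jj <- d$first_marker:d$last_marker
    for (s in seq_len(n))
      carrier[s] <- all(gam1[[ci]][s, jj] == founders[1L, jj]) &&
                    all(gam2[[ci]][s, jj] == founders[1L, jj])
  }
  affected <- (carrier & runif(n) < cfg$penetrance) |
              (!carrier & runif(n) < cfg$phenocopy_rate)
  if (is.null(cfg$disease_locus))
    affected <- seq_len(n) %in% case_idx   # labels only; nothing planted

  ## error injection: hom <-> het flips
  if (cfg$genotype_error_rate > 0) {
    err <- matrix(runif(length(geno)) < cfg$genotype_error_rate,
                  nrow(geno))
    hom <- err & geno != GENO_HET
    het <- err & geno == GENO_HET
    geno[hom] <- GENO_HET
    geno[het] <- sample(c(GENO_HOM_A, GENO_HOM_B), sum(het), replace = TRUE)
  }
  if (cfg$genotype_missing_rate > 0)
    geno[matrix(runif(length(geno)) < cfg$genotype_missing_rate,
                nrow(geno))] <- NA_integer_

  ids <- c(sprintf("case%d", seq_len(cfg$n_cases)),
           sprintf("ctrl%d", seq_len(cfg$n_controls)))
  samples <- data.frame(id = ids,
                        phenotype = ifelse(affected, "case", "control"),
                        stringsAsFactors = FALSE)

  ## canonical PED polarity: allele_a is the first allele a reader would
  ## observe, so written PED/MAP files round-trip to identical codes
  first_code <- apply(geno, 2L, function(g) {
    g <- g[!is.na(g)]
    if (length(g)) g[1L] else NA_integer_
  })
  flip <- !is.na(first_code) & first_code == GENO_HOM_B
  if (any(flip)) {
    geno[, flip] <- 2L - geno[, flip]
    tmp <- markers$allele_a[flip]
    markers$allele_a[flip] <- markers$allele_b[flip]
    markers$allele_b[flip] <- tmp
    offset <- 0L
    for (ci in seq_len(nrow(cfg$chromosomes))) {
      ch <- cfg$chromosomes$name[ci]
      m <- cfg$chromosomes$n_snp[ci]
      fl <- flip[offset + seq_len(m)]
      f <- attr(freqs[[ch]], "founders")
      f[, fl] <- 1L - f[, fl]
      p <- as.numeric(freqs[[ch]])
      p[fl] <- 1 - p[fl]
      freqs[[ch]] <- p
      attr(freqs[[ch]], "founders") <- f
      offset <- offset + m
    }
  }

  dataset <- genotype_dataset(samples, markers, geno)
  truth <- structure(list(loci = truth_loci, carrier = setNames(carrier, ids),
                          affected = setNames(affected, ids),
                          founder_freq = lapply(freqs, as.numeric),
                          founder_haplotypes = lapply(freqs, attr, "founders"),
                          config = cfg),
                     class = "sim_truth")
  list(dataset = dataset, truth = truth)
}

SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]

#' Simulate a transcript with an engineered downstream in-frame stop
#'
#' Builds an mRNA whose CDS is `n_codons` random sense codons (beginning
#' ATG) followed by TGA, and whose 3'UTR contains no in-frame stop before
#' `next_stop_offset_nt` bases past the natural stop, an in-frame TAG
#' starting exactly there, and (space permitting) an AATAAA
#' polyadenylation signal 37 bp downstream of that stop.
#'
#' @param n_codons number of sense codons (the stop is codon
#'   `n_codons + 1`).
#' @param next_stop_offset_nt bases between the 3' end of the natural stop
#'   and the first base of the planted in-frame stop; must be divisible
#'   by 3.
#' @param utr_len total 3'UTR length; must exceed
#'   `next_stop_offset_nt + 3`.
#' @param seed integer seed.
#' @return A [transcript()].
#' @export
simulate_transcript <- function(n_codons, next_stop_offset_nt, utr_len,
                                seed = 1L) {
  stopifnot(n_codons >= 1L, next_stop_offset_nt >= 0L,
            next_stop_offset_nt %% 3L == 0L)
  if (utr_len <= next_stop_offset_nt + 3L)
    stop("3'UTR too short to hold the planted stop: need utr_len > ",
         next_stop_offset_nt + 3L)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  utr5 <- paste(sample(bases, 9L, replace = TRUE), collapse = "")
  cds <- paste0("ATG",
                paste(sample(SENSE_CODONS, n_codons - 1L, replace = TRUE),
                      collapse = ""),
                "TGA")
  pre <- paste(sample(SENSE_CODONS, next_stop_offset_nt / 3L,
                      replace = TRUE), collapse = "")
  tail_len <- utr_len - next_stop_offset_nt - 3L
  tail_chars <- sample(bases, tail_len, replace = TRUE)
  polya_pos <- NULL
  if (tail_len >= 37L + 6L) {
    tail_chars[38L:43L] <- c("A", "A", "T", "A", "A", "A")
    polya_pos <- nchar(utr5) + nchar(cds) + next_stop_offset_nt + 3L + 38L
  }
  mrna <- paste0(utr5, cds, pre, "TAG", paste(tail_chars, collapse = ""))
  transcript(id = sprintf("sim_tx_%dc_%dnt", n_codons, next_stop_offset_nt),
             mrna_seq = mrna,
             cds_start = nchar(utr5) + 1L,
             cds_end = nchar(utr5) + nchar(cds),
             polya_signal_pos = polya_pos)
}
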