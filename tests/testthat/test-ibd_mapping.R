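seg_row <- function(sample, chrom, start_mb, end_mb) {
  data.frame(sample = sample, chrom = chrom,
             start_bp = as.integer(start_mb * 1e6),
             end_bp = as.integer(end_mb * 1e6),
             n_snp = 200L, length_kb = (end_mb - start_mb) * 1000,
             length_mb = end_mb - start_mb, density_kb_snp = 10,
             stringsAsFactors = FALSE)
}

test_that("shared loci are the intersection of per-case ROH coverage", {
  cases <- sprintf("case%d", 1:6)
  segs <- do.call(rbind, lapply(seq_along(cases), function(i)
    seg_row(cases[i], "17", 5.0 - 0.1 * i, 7.0 + 0.1 * i)))
  loci <- shared_roh_loci(segs, cases)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$chrom, "17")
  expect_equal(loci$start_bp, 4900000L)   # tightest case bounds
  expect_equal(loci$end_bp, 7100000L)
})

test_that("a chromosome missing a segment in any one case yields no locus", {
  cases <- sprintf("case%d", 1:6)
  segs <- do.call(rbind, lapply(cases[1:5], seg_row,
                                chrom = "17", start_mb = 5, end_mb = 7))
  expect_equal(nrow(shared_roh_loci(segs, cases)), 0L)
})

test_that("multiple disjoint shared intervals on one chromosome are all emitted", {
  cases <- c("c1", "c2")
  segs <- rbind(seg_row("c1", "3", 1, 10),
                seg_row("c2", "3", 2, 4), seg_row("c2", "3", 6, 8))
  loci <- shared_roh_loci(segs, cases)
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$start_bp, c(2e6, 6e6))
  expect_equal(loci$end_bp, c(4e6, 8e6))
})

test_that("the study simulation emits exactly the five planted shared loci", {
  sim <- simulate_cohort(sim_config_study(101))
  segs <- call_roh(sim$dataset, case_ids(sim$dataset))
  loci <- shared_roh_loci(segs, case_ids(sim$dataset))
  planted <- c(sim$truth$loci$decoys,
               list(sim$truth$loci$disease))
  expect_equal(nrow(loci), 5L)
  expect_setequal(loci$chrom,
                  vapply(planted, function(l) l$chrom, ""))
})

# A hand-built identity scenario: 20 markers on one chromosome, core = markers
# 6..15, flanks identical for all cases on both sides.
identity_dataset <- function(core_missing_case = NULL,
                             boundary_conflict = FALSE) {
  m <- 20
  g <- matrix(0L, 6, m)                    # all cases hom allele_a everywhere
  ctrl <- rbind(rep(1L, m), rep(1L, m), rep(1L, m))
  if (boundary_conflict) g[2, 13] <- 2L    # case2 hom for the other allele
  if (!is.null(core_missing_case)) g[core_missing_case, 10] <- NA
  make_dataset(rbind(g, ctrl), rep(c("case", "control"), c(6, 3)))
}

test_that("identity refinement extends across identical flanking markers", {
  ds <- identity_dataset()
  locus <- data.frame(chrom = "1", start_bp = 60000L, end_bp = 150000L)
  ref <- refine_by_identity(ds, locus, case_ids(ds))
  expect_false(ref$discarded)
  # grows to the whole chromosome: identity holds at every flank marker
  expect_equal(ref$refined_start, 10000L)
  expect_equal(ref$refined_end, 200000L)
  expect_gt(ref$size_mb, ref$core_size_mb)
})

test_that("identity violations trim the interval before the violating marker", {
  ds <- identity_dataset(boundary_conflict = TRUE)
  locus <- data.frame(chrom = "1", start_bp = 60000L, end_bp = 150000L)
  ref <- refine_by_identity(ds, locus, case_ids(ds))
  expect_false(ref$discarded)
  expect_equal(ref$refined_start, 10000L)
  expect_equal(ref$refined_end, 120000L)   # marker 13 (130 kb) violates
})

test_that("missing calls inside the core are identity-compatible", {
  ds <- identity_dataset(core_missing_case = 3L)
  locus <- data.frame(chrom = "1", start_bp = 60000L, end_bp = 150000L)
  ref <- refine_by_identity(ds, locus, case_ids(ds))
  expect_false(ref$discarded)
  expect_equal(ref$refined_start, 10000L)
  expect_equal(ref$refined_end, 200000L)
})

test_that("a core violating identity at most markers is discarded with a reason", {
  g <- matrix(0L, 6, 20)
  g[1, 6:15] <- 1L                          # case1 het across the whole core
  ds <- make_dataset(rbind(g, matrix(2L, 3, 20)),
                     rep(c("case", "control"), c(6, 3)))
  locus <- data.frame(chrom = "1", start_bp = 60000L, end_bp = 150000L)
  ref <- refine_by_identity(ds, locus, case_ids(ds))
  expect_true(ref$discarded)
  expect_match(ref$reason, "identity fails")
})

test_that("control carriage follows the homozygous-haplotype rule", {
  m <- 20
  g <- matrix(0L, 6, m)
  ctrl_hom <- rep(0L, m)      # homozygous for the shared haplotype
  ctrl_het <- rep(1L, m)      # heterozygous throughout: not a carrier
  ctrl_opp <- rep(2L, m)      # homozygous for the other allele
  ds <- make_dataset(rbind(g, ctrl_hom, ctrl_hom, ctrl_het),
                     rep(c("case", "control"), c(6, 3)))
  locus <- data.frame(chrom = "1", start_bp = 10000L, end_bp = 200000L)
  ref <- refine_by_identity(ds, locus, case_ids(ds))
  out <- filter_by_controls(ref, ds, control_ids(ds))
  expect_equal(sort(out$control_carriers), c("s07", "s08"))
  expect_false(out$retained)

  ds2 <- make_dataset(rbind(g, ctrl_het, ctrl_opp, ctrl_het),
                      rep(c("case", "control"), c(6, 3)))
  ref2 <- refine_by_identity(ds2, locus, case_ids(ds2))
  out2 <- filter_by_controls(ref2, ds2, control_ids(ds2))
  expect_equal(out2$control_carriers, character(0))
  expect_true(out2$retained)

  # a control missing everywhere is compatible, hence a carrier
  ds3 <- make_dataset(rbind(g, matrix(NA_integer_, 1, m), ctrl_opp, ctrl_het),
                      rep(c("case", "control"), c(6, 3)))
  ref3 <- refine_by_identity(ds3, locus, case_ids(ds3))
  out3 <- filter_by_controls(ref3, ds3, control_ids(ds3))
  expect_equal(out3$control_carriers, "s07")
  expect_false(out3$retained)
})

test_that("exclusion verdicts always name the carriers", {
  sim <- simulate_cohort(sim_config_study(7))
  mp <- map_recessive(sim$dataset)
  rep_ <- mp$report
  excluded <- rep_[!rep_$RETAINED & !rep_$DISCARDED, ]
  expect_true(all(nzchar(excluded$CONTROL_CARRIERS)))
  retained <- rep_[rep_$RETAINED, ]
  expect_true(all(!nzchar(retained$CONTROL_CARRIERS)))
})

test_that("the pipeline is invariant to sample ordering", {
  sim <- simulate_cohort(sim_config(
    seed = 13,
    chromosomes = data.frame(name = c("1", "2"), length_bp = c(12e6, 12e6),
                             n_snp = c(1000L, 1000L)),
    disease_locus = list(chrom = "1", start_bp = 4e6, end_bp = 6.2e6),
    decoy_loci = list(list(chrom = "2", start_bp = 3e6, end_bp = 5.5e6,
                           carrier_controls = 1L))))
  ds <- sim$dataset
  perm <- c(4, 2, 6, 1, 5, 3, 9, 7, 8)
  ds_perm <- genotype_dataset(ds$samples[perm, ], ds$markers,
                              ds$geno[perm, ])
  a <- map_recessive(ds)$report
  b <- map_recessive(ds_perm)$report
  b$CONTROL_CARRIERS <- vapply(strsplit(b$CONTROL_CARRIERS, ","),
                               function(x) paste(sort(x), collapse = ","), "")
  a$CONTROL_CARRIERS <- vapply(strsplit(a$CONTROL_CARRIERS, ","),
                               function(x) paste(sort(x), collapse = ","), "")
  expect_equal(a[order(a$CHR, a$START), ], b[order(b$CHR, b$START), ],
               ignore_attr = TRUE)
})

test_that("a single case passes through as its own intersection", {
  segs <- seg_row("only", "5", 2, 5)
  loci <- shared_roh_loci(segs, "only")
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start_bp, 2e6)
  expect_equal(loci$end_bp, 5e6)
})

test_that("no retained locus yields an empty ranking with a full report", {
  # decoy carried by a control, no disease locus: everything excluded
  sim <- simulate_cohort(sim_config(
    seed = 23,
    chromosomes = data.frame(name = "4", length_bp = 12e6, n_snp = 1000L),
    decoy_loci = list(list(chrom = "4", start_bp = 3e6, end_bp = 5.5e6,
                           carrier_controls = c(1L, 2L)))))
  mp <- map_recessive(sim$dataset)
  expect_equal(length(mp$retained), 0L)
  expect_equal(nrow(mp$report), 1L)
  expect_false(mp$report$RETAINED)
})
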