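test_that("a minimal one-sample PED/MAP pair loads correctly", {
  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  writeLines("f1 s1 0 0 0 2 A A", ped)
  writeLines("25\tm1\t0\t100", map)
  ds <- read_pedmap(ped, map)
  expect_equal(nrow(ds$samples), 1L)
  expect_equal(ds$samples$phenotype, "case")
  expect_equal(unname(ds$geno[1, 1]), 0L)       # hom for first-observed allele
  expect_equal(ds$markers$allele_a, "A")
  expect_equal(ds$markers$chrom, "25")
  expect_equal(ds$markers$pos_bp, 100L)
})

test_that("PED phenotype codes and missing allele pairs map as specified", {
  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  writeLines(c("f a1 0 0 0 2 A G",
               "f a2 0 0 0 1 G G",
               "f a3 0 0 0 0 0 0",
               "f a4 0 0 0 -9 G A"), ped)
  writeLines("1\tm1\t0\t500", map)
  ds <- read_pedmap(ped, map)
  expect_equal(ds$samples$phenotype, c("case", "control", "unknown", "unknown"))
  # het normalization: "A G" and "G A" both het; "0 0" missing
  expect_equal(unname(ds$geno[, 1]), c(1L, 2L, NA, 1L))
})

test_that("round-trip write/read is the identity on a simulated cohort", {
  cfg <- sim_config(seed = 11,
                    chromosomes = data.frame(name = c("1", "2"),
                                             length_bp = c(5e6, 4e6),
                                             n_snp = c(30L, 20L)),
                    n_cases = 6L, n_controls = 3L,
                    genotype_missing_rate = 0.08)
  ds <- simulate_cohort(cfg)$dataset
  expect_equal(sum(ds$samples$phenotype == "case"), 6L)
  expect_equal(sum(ds$samples$phenotype == "control"), 3L)

  prefix <- tempfile()
  write_pedmap(ds, prefix)
  back <- read_pedmap(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  expect_equal(unname(back$geno), unname(ds$geno))
  expect_equal(back$markers$id, ds$markers$id)
  expect_equal(back$markers$pos_bp, ds$markers$pos_bp)
  expect_equal(back$samples$phenotype, ds$samples$phenotype)
  # a second write reproduces the files byte for byte
  prefix2 <- tempfile()
  write_pedmap(back, prefix2)
  expect_identical(readLines(paste0(prefix, ".ped")),
                   readLines(paste0(prefix2, ".ped")))
  # missing calls serialize as "0 0"
  miss <- which(is.na(ds$geno), arr.ind = TRUE)[1, ]
  line <- readLines(paste0(prefix, ".ped"))[miss["row"]]
  f <- strsplit(line, " ")[[1]]
  expect_equal(f[6L + 2L * miss["col"] - 1L], "0")
  expect_equal(f[6L + 2L * miss["col"]], "0")
})

test_that("an empty dataset writes a valid empty PED with a full MAP", {
  ds <- genotype_dataset(
    data.frame(id = character(), phenotype = character()),
    data.frame(chrom = "1", id = "m1", cM = 0, pos_bp = 10L,
               allele_a = "A", allele_b = "G"),
    matrix(integer(), 0L, 1L))
  prefix <- tempfile()
  write_pedmap(ds, prefix)
  back <- read_pedmap(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  expect_equal(nrow(back$samples), 0L)
  expect_equal(back$markers$id, "m1")
})

test_that("malformed PED/MAP input raises informative errors", {
  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  writeLines("f s1 0 0 0 2 A A G", ped)         # 9 fields, expected 8
  writeLines("1\tm1\t0\t100", map)
  expect_error(read_pedmap(ped, map), "PED line 1")

  writeLines(c("f s1 0 0 0 2 A A", "f s2 0 0 0 1 G G", "f s3 0 0 0 1 T T"),
             ped)
  expect_error(read_pedmap(ped, map), "m1.*more than two alleles")

  writeLines(c("f s1 0 0 0 2 A A"), ped)
  writeLines(c("1\tm1\t0\t200", "1\tm2\t0\t100"), map)
  ped2 <- tempfile(fileext = ".ped")
  writeLines("f s1 0 0 0 2 A A G G", ped2)
  expect_error(read_pedmap(ped2, map), "not strictly sorted")
})

write_test_vcf <- function(records,
                           samples = c("s1", "s2", "s3", "s4")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               records), path)
  path
}

test_that("VCF genotype codes map to the dataset model", {
  vcf <- write_test_vcf(paste(c("25", "100", "m1", "A", "G", ".", "PASS",
                                ".", "GT", "0/0", "0/1", "1/1", "./."),
                              collapse = "\t"))
  pheno <- tempfile()
  writeLines(c("sample\tphenotype", "s1\tcase", "s2\tcase",
               "s3\tcontrol", "s4\tunknown"), pheno)
  ds <- read_vcf(vcf, pheno)
  expect_equal(unname(ds$geno[, 1]), c(0L, 1L, 2L, NA))
  expect_equal(ds$samples$phenotype, c("case", "case", "control", "unknown"))
  expect_equal(ds$markers$allele_a, "A")   # REF
  expect_equal(ds$markers$allele_b, "G")   # ALT
})

test_that("multi-allelic VCF records are skipped with a warning", {
  recs <- c(paste(c("1", "100", "m1", "A", "G", ".", ".", ".", "GT",
                    "0/0", "0/0", "1/1", "0/1"), collapse = "\t"),
            paste(c("1", "200", "m2", "A", "G,T", ".", ".", ".", "GT",
                    "0/0", "1/2", "0/0", "0/0"), collapse = "\t"),
            paste(c("1", "300", "m3", "C", "T", ".", ".", ".", "GT",
                    "0|1", "1|1", "0|0", "0/0"), collapse = "\t"))
  vcf <- write_test_vcf(recs)
  expect_warning(ds <- read_vcf(vcf), "multi-allelic")
  expect_equal(nrow(ds$markers), 2L)
  expect_equal(ds$markers$id, c("m1", "m3"))
  # phased genotypes accepted
  expect_equal(unname(ds$geno[, "m3"]), c(1L, 2L, 0L, 0L))
  # all samples unknown without a phenotype table
  expect_true(all(ds$samples$phenotype == "unknown"))
})

test_that("a VCF and its equivalent PED/MAP produce the same dataset", {
  recs <- c(paste(c("7", "1000", "v1", "A", "G", ".", ".", ".", "GT",
                    "0/0", "0/1", "1/1", "./."), collapse = "\t"),
            paste(c("7", "2000", "v2", "C", "T", ".", ".", ".", "GT",
                    "1/1", "1/1", "0/1", "0/0"), collapse = "\t"))
  vcf <- write_test_vcf(recs)
  pheno <- tempfile()
  writeLines(c("sample\tphenotype", "s1\tcase", "s2\tcase",
               "s3\tcontrol", "s4\tcontrol"), pheno)
  from_vcf <- read_vcf(vcf, pheno)

  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  writeLines(c("f s1 0 0 0 2 A A T T",
               "f s2 0 0 0 2 A G T T",
               "f s3 0 0 0 1 G G C T",
               "f s4 0 0 0 1 0 0 C C"), ped)
  writeLines(c("7\tv1\t0\t1000", "7\tv2\t0\t2000"), map)
  from_ped <- read_pedmap(ped, map)
  # same codes up to the per-file allele_a assignment at v2
  expect_equal(unname(from_vcf$geno[, "v1"]), unname(from_ped$geno[, "v1"]))
  expect_equal(unname(from_vcf$geno[, "v2"]),
               unname(2L - from_ped$geno[, "v2"]))   # first-observed allele is ALT
  expect_equal(from_vcf$samples$phenotype, from_ped$samples$phenotype)
})

test_that("round-trip preserves codes and order across random datasets", {
  for (seed in c(3, 5, 9)) {
    cfg <- sim_config(seed = seed,
                      chromosomes = data.frame(name = "12", length_bp = 3e6,
                                               n_snp = 40L),
                      n_cases = 4L, n_controls = 2L,
                      genotype_missing_rate = 0.1)
    ds <- simulate_cohort(cfg)$dataset
    prefix <- tempfile()
    write_pedmap(ds, prefix)
    back <- read_pedmap(paste0(prefix, ".ped"), paste0(prefix, ".map"))
    expect_equal(unname(back$geno), unname(ds$geno))
    expect_equal(back$markers$id, ds$markers$id)
    expect_equal(back$samples$phenotype, ds$samples$phenotype)
  }
})
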