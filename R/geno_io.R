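## Genotype dataset container and PED/MAP + VCF I/O.
##
## Genotypes are held as an integer matrix (samples x markers) of codes
## 0 = hom_a, 1 = het, 2 = hom_b, NA = missing, with codes defined relative
## to the per-marker (allele_a, allele_b) pair. PED files carry no REF/ALT,
## so allele_a/allele_b are assigned by first observation order in the file
## and nothing downstream assumes allele_a is the minor allele.

#' Construct and validate a genotype dataset
#'
#' The uniform in-memory model shared by all readers and by the simulator:
#' a sample table, a marker map, and a diploid call matrix.
#'
#' @param samples data.frame with columns `id` (unique) and `phenotype`
#'   (one of `"case"`, `"control"`, `"unknown"`); optional extra columns
#'   (e.g. `fid`, trait tags) are preserved.
#' @param markers data.frame with columns `chrom`, `id` (unique), `cM`,
#'   `pos_bp` (1-based physical position), `allele_a`, `allele_b`
#'   (`allele_b` may be NA for markers with only one observed allele).
#'   Markers must be strictly sorted by `pos_bp` within each chromosome.
#' @param geno integer matrix, `nrow(samples)` x `nrow(markers)`, codes
#'   0 (hom allele_a), 1 (het), 2 (hom allele_b), NA (missing).
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(samples, markers, geno) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"

  if (anyDuplicated(samples$id))
    stop("duplicate sample ids: ", paste(samples$id[duplicated(samples$id)], collapse = ", "))
  if (anyDuplicated(markers$id))
    stop("duplicate marker ids: ", paste(markers$id[duplicated(markers$id)], collapse = ", "))
  if (!all(samples$phenotype %in% c("case", "control", "unknown")))
    stop("phenotype must be one of case/control/unknown")
  if (nrow(geno) != nrow(samples) || ncol(geno) != nrow(markers))
    stop(sprintf("call matrix is %d x %d but there are %d samples and %d markers",
                 nrow(geno), ncol(geno), nrow(samples), nrow(markers)))
  bad <- !(geno %in% c(0L, 1L, 2L)) & !is.na(geno)
  if (any(bad)) stop("invalid genotype codes (must be 0/1/2/NA)")
  if (nrow(markers) > 0L) {
    if (any(markers$pos_bp < 1L)) stop("marker positions must be >= 1")
    for (ch in unique(markers$chrom)) {
      p <- markers$pos_bp[markers$chrom == ch]
      if (is.unsorted(p, strictly = TRUE))
        stop("markers on chromosome ", ch, " are not strictly sorted by position")
    }
    same <- !is.na(markers$allele_b) & markers$allele_a == markers$allele_b
    if (any(same)) stop("allele_a equals allele_b at marker ",
                        markers$id[which(same)[1L]])
  }
  rownames(geno) <- samples$id
  colnames(geno) <- markers$id
  structure(list(samples = samples, markers = markers, geno = geno),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  ph <- table(factor(x$samples$phenotype, c("case", "control", "unknown")))
  cat(sprintf("genotype_dataset: %d samples (%d cases, %d controls, %d unknown), %d markers on %d chromosome(s)\n",
              nrow(x$samples), ph[["case"]], ph[["control"]], ph[["unknown"]],
              nrow(x$markers), length(unique(x$markers$chrom))))
  miss <- mean(is.na(x$geno))
  if (length(x$geno)) cat(sprintf("  missing call rate: %.3g\n", miss))
  invisible(x)
}

#' Sample ids by phenotype
#' @param dataset a [genotype_dataset()].
#' @return Character vector of sample ids.
#' @export
case_ids <- function(dataset) dataset$samples$id[dataset$samples$phenotype == "case"]

#' @rdname case_ids
#' @export
control_ids <- function(dataset) dataset$samples$id[dataset$samples$phenotype == "control"]

## PED phenotype column <-> labels
.pheno_from_ped <- function(x) {
  out <- rep("unknown", length(x))
  out[x == "1"] <- "control"
  out[x == "2"] <- "case"
  out
}
.pheno_to_ped <- function(x) c(case = "2", control = "1", unknown = "0")[x]

#' Read PLINK text PED/MAP files
#'
#' Parses a 4-column MAP (chrom, id, cM, bp) and a whitespace-separated PED
#' (6 leading columns, then 2 allele fields per marker). Phenotype comes
#' from PED column 6 (1 = control, 2 = case, 0 or -9 = unknown). An allele
#' pair containing "0" is a missing call. Heterozygote allele order is
#' normalized ("A G" and "G A" both map to het).
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @param normalize_chrom if TRUE, strip a leading "chr" prefix from
#'   chromosome names; by default chromosome names are opaque strings
#'   ("25" and "chr25" are distinct).
#' @return A [genotype_dataset()].
#' @export
read_pedmap <- function(ped_path, map_path, normalize_chrom = FALSE) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map <- read.table(map_path, header = FALSE, colClasses = "character",
                    col.names = c("chrom", "id", "cM", "pos_bp"))
  markers <- data.frame(chrom = map$chrom, id = map$id,
                        cM = as.numeric(map$cM), pos_bp = as.integer(map$pos_bp),
                        allele_a = NA_character_, allele_b = NA_character_,
                        stringsAsFactors = FALSE)
  if (normalize_chrom) markers$chrom <- sub("^chr", "", markers$chrom)
  m <- nrow(markers)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  n <- length(fields)
  len <- lengths(fields)
  bad <- which(len != 6L + 2L * m)
  if (length(bad))
    stop(sprintf("PED line %d has %d fields; expected %d for %d MAP markers",
                 bad[1L], len[bad[1L]], 6L + 2L * m, m))
  ped <- if (n) do.call(rbind, fields) else matrix(character(), 0L, 6L + 2L * m)

  samples <- data.frame(fid = ped[, 1L][seq_len(n)], id = ped[, 2L][seq_len(n)],
                        phenotype = .pheno_from_ped(ped[, 6L][seq_len(n)]),
                        stringsAsFactors = FALSE)

  geno <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    a1 <- ped[, 5L + 2L * j]
    a2 <- ped[, 6L + 2L * j]
    obs <- as.vector(rbind(a1, a2))          # file observation order
    alleles <- unique(obs[obs != "0"])
    if (length(alleles) > 2L)
      stop("marker ", markers$id[j], " has more than two alleles: ",
           paste(alleles, collapse = "/"))
    if (length(alleles) >= 1L) markers$allele_a[j] <- alleles[1L]
    if (length(alleles) == 2L) markers$allele_b[j] <- alleles[2L]
    miss <- a1 == "0" | a2 == "0"
    code <- ifelse(a1 != a2, GENO_HET,
                   ifelse(a1 == alleles[1L], GENO_HOM_A, GENO_HOM_B))
    code[miss] <- NA_integer_
    geno[, j] <- as.integer(code)
  }
  genotype_dataset(samples, markers, geno)
}

#' Write a genotype dataset as PLINK text PED/MAP
#'
#' Inverse of [read_pedmap()]: the written pair round-trips to an identical
#' dataset (genotype codes, marker order, phenotypes) whenever `allele_a`
#' is the allele a PED reader observes first at each marker — the canonical
#' polarity produced by [read_pedmap()] and [simulate_cohort()]. PED files
#' carry no REF/ALT, so a dataset in the opposite polarity reloads with
#' equivalent base-level genotypes but swapped (allele_a, allele_b) and
#' mirrored codes at those markers. Missing calls serialize as `0 0`;
#' all-missing markers are written as `0 0` throughout.
#'
#' @param dataset a [genotype_dataset()].
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return Invisibly, the two paths written.
#' @export
write_pedmap <- function(dataset, prefix) {
  markers <- dataset$markers
  samples <- dataset$samples
  geno <- dataset$geno
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")

  write.table(data.frame(markers$chrom, markers$id,
                         markers$cM %||% 0, markers$pos_bp),
              map_path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)

  n <- nrow(samples); m <- nrow(markers)
  allele_strings <- matrix("0 0", n, m)
  for (j in seq_len(m)) {
    a <- markers$allele_a[j]; b <- markers$allele_b[j]
    g <- geno[, j]
    s <- rep("0 0", n)
    s[!is.na(g) & g == GENO_HOM_A] <- paste(a, a)
    s[!is.na(g) & g == GENO_HET] <- paste(a, b)
    s[!is.na(g) & g == GENO_HOM_B] <- paste(b, b)
    allele_strings[, j] <- s
  }
  if (n == 0L) {
    writeLines(character(), ped_path)
  } else {
    lead <- cbind(samples$fid %||% samples$id, samples$id, "0", "0", "0",
                  .pheno_to_ped(samples$phenotype))
    writeLines(apply(cbind(lead, allele_strings), 1L, paste, collapse = " "),
               ped_path)
  }
  invisible(c(ped = ped_path, map = map_path))
}

#' Read genotypes from a VCF file
#'
#' Imports biallelic SNP records into the same dataset model as
#' [read_pedmap()], with REF mapped to allele_a and ALT to allele_b.
#' Multi-allelic records are skipped with a warning; half-calls and GT
#' alleles other than 0/1 are set missing, with the count reported.
#' Phenotypes come from a tab-separated table with header
#' `sample<TAB>phenotype`; VCF samples absent from the table are labeled
#' unknown with a warning.
#'
#' @param vcf_path path to a VCF (v4.x) file with GT fields.
#' @param phenotype_table path to the sample/phenotype TSV, or NULL to
#'   label every sample unknown.
#' @return A [genotype_dataset()].
#' @export
read_vcf <- function(vcf_path, phenotype_table = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))

  snp <- fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (any(!snp)) {
    warning(sum(!snp), " multi-allelic or non-SNP record(s) skipped")
    fix <- fix[snp, , drop = FALSE]
    gt <- gt[snp, , drop = FALSE]
  }

  core <- gsub("\\|", "/", gt)
  code <- matrix(NA_integer_, nrow(core), ncol(core))
  code[core == "0/0"] <- GENO_HOM_A
  code[core == "0/1" | core == "1/0"] <- GENO_HET
  code[core == "1/1"] <- GENO_HOM_B
  odd <- !is.na(core) & !(core %in% c("0/0", "0/1", "1/0", "1/1", "./."))
  if (any(odd))
    message(sum(odd), " half-call or non-{0,1} genotype(s) set to missing")

  ids <- fix$ID
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix$CHROM[noid], ":", fix$POS[noid])
  markers <- data.frame(chrom = fix$CHROM, id = ids, cM = 0,
                        pos_bp = as.integer(fix$POS),
                        allele_a = fix$REF, allele_b = fix$ALT,
                        stringsAsFactors = FALSE)

  sample_ids <- colnames(gt)
  pheno <- rep("unknown", length(sample_ids))
  if (!is.null(phenotype_table)) {
    tab <- read.table(phenotype_table, header = TRUE, sep = "\t",
                      colClasses = "character")
    hit <- match(sample_ids, tab$sample)
    if (anyNA(hit))
      warning("sample(s) absent from phenotype table labeled unknown: ",
              paste(sample_ids[is.na(hit)], collapse = ", "))
    pheno[!is.na(hit)] <- tab$phenotype[hit[!is.na(hit)]]
  }
  samples <- data.frame(id = sample_ids, phenotype = pheno,
                        stringsAsFactors = FALSE)
  genotype_dataset(samples, markers, t(code))
}
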