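## Transcript models and coding-variant consequence deduction, with first-
## class support for non-stop (stop-loss) substitutions: a point mutation
## converting the stop codon to a sense codon extends translation into the
## 3'UTR until the first in-frame stop.

IUPAC_DNA <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))

.codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("cannot translate codon ", codon)
  aa
}

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

#' Construct and validate a transcript model
#'
#' An mRNA sequence with 1-based inclusive CDS coordinates. The CDS must
#' begin with ATG, end with a stop codon and have length divisible by 3,
#' and may contain only unambiguous bases; IUPAC ambiguity codes are
#' tolerated in the UTRs.
#'
#' @param id transcript identifier.
#' @param mrna_seq mRNA sequence string (A/C/G/T, IUPAC outside the CDS).
#' @param cds_start,cds_end 1-based inclusive CDS bounds within `mrna_seq`
#'   (`cds_end` is the last base of the stop codon).
#' @param polya_signal_pos optional 1-based position of the AATAAA signal.
#' @return A list of class `transcript`.
#' @export
transcript <- function(id, mrna_seq, cds_start, cds_end,
                       polya_signal_pos = NULL) {
  mrna_seq <- toupper(mrna_seq)
  stopifnot(cds_start >= 1, cds_end <= nchar(mrna_seq), cds_start < cds_end)
  if (!all(strsplit(mrna_seq, "")[[1]] %in% names(IUPAC_DNA)))
    stop("mRNA contains non-IUPAC characters")
  cds <- substr(mrna_seq, cds_start, cds_end)
  if (nchar(cds) %% 3 != 0) stop("CDS length is not divisible by 3")
  if (grepl("[^ACGT]", cds)) stop("CDS contains ambiguity codes")
  if (substr(cds, 1, 3) != "ATG") stop("CDS does not begin with ATG")
  last <- substr(cds, nchar(cds) - 2, nchar(cds))
  if (!last %in% c("TAA", "TAG", "TGA"))
    stop("CDS does not end with a stop codon (got ", last, ")")
  structure(list(id = id, mrna_seq = mrna_seq,
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end),
                 polya_signal_pos = if (is.null(polya_signal_pos)) NULL
                                    else as.integer(polya_signal_pos)),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  n_sense <- (x$cds_end - x$cds_start + 1L) / 3L - 1L
  cat(sprintf("transcript %s: %d nt mRNA, CDS %d-%d (%d codons + stop), 3'UTR %d nt\n",
              x$id, nchar(x$mrna_seq), x$cds_start, x$cds_end, n_sense,
              nchar(x$mrna_seq) - x$cds_end))
  invisible(x)
}

#' Read a transcript from FASTA plus a CDS sidecar
#'
#' The sidecar (YAML or JSON, chosen by file extension) must define
#' `cds_start` and `cds_end`, optionally `polya_signal_pos`.
#'
#' @param fasta_path single-record mRNA FASTA.
#' @param sidecar_path YAML/JSON file with the CDS coordinates.
#' @return A [transcript()].
#' @export
read_transcript <- function(fasta_path, sidecar_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) stop("expected exactly one FASTA record")
  meta <- if (grepl("\\.json$", sidecar_path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required to read a JSON sidecar")
    jsonlite::fromJSON(sidecar_path)
  } else yaml::read_yaml(sidecar_path)
  transcript(id = sub("\\s.*", "", names(seqs)[1L]),
             mrna_seq = as.character(seqs[[1L]]),
             cds_start = meta$cds_start, cds_end = meta$cds_end,
             polya_signal_pos = meta$polya_signal_pos)
}

#' Parse an HGVS-style coding substitution
#'
#' Accepts strings of the form `c.<pos><ref>><alt>`, e.g. `c.1216T>C`.
#' Positions are 1-based offsets from the first base of the ATG.
#'
#' @param s variant string.
#' @return List of class `cdna_variant` with `c_pos`, `ref`, `alt`.
#' @export
parse_hgvs_c <- function(s) {
  m <- regmatches(s, regexec("^c\\.([0-9]+)([ACGT])>([ACGT])$", s))[[1]]
  if (length(m) == 0L)
    stop("malformed coding variant (expected c.<pos><ref>><alt>): ", s)
  pos <- as.integer(m[2])
  if (pos < 1L) stop("coding positions are >= 1: ", s)
  structure(list(c_pos = pos, ref = m[3], alt = m[4]), class = "cdna_variant")
}

## Translate codons downstream of the CDS (in frame) until a stop.
## Ambiguity codes are tolerated: each ambiguous codon is resolved to all
## readings, and branches that disagree in residues or stop placement are
## all returned. Returns a list of branches, each
## list(residues = character vector, stopped = logical).
.translate_utr_branches <- function(utr_chars, max_branches = 16L) {
  branches <- list(list(residues = character(), stopped = FALSE))
  n_codon <- length(utr_chars) %/% 3L
  for (k in seq_len(n_codon)) {
    chars <- utr_chars[(3L * k - 2L):(3L * k)]
    opts <- lapply(chars, function(b) IUPAC_DNA[[b]])
    codons <- unique(apply(expand.grid(opts, stringsAsFactors = FALSE),
                           1L, paste, collapse = ""))
    aas <- unique(vapply(codons, .codon_aa, ""))
    new <- list()
    for (br in branches) {
      if (br$stopped) { new[[length(new) + 1L]] <- br; next }
      for (aa in aas) {
        nb <- br
        if (aa == "*") nb$stopped <- TRUE else nb$residues <- c(nb$residues, aa)
        new[[length(new) + 1L]] <- nb
      }
    }
    ## deduplicate
    key <- vapply(new, function(b) paste(c(b$residues, b$stopped), collapse = "|"), "")
    branches <- new[!duplicated(key)]
    if (length(branches) > max_branches)
      stop("too many ambiguity resolutions while translating the 3'UTR")
    if (all(vapply(branches, function(b) b$stopped, TRUE))) break
  }
  branches
}

#' Protein consequence of a coding substitution
#'
#' Translates the wild-type CDS, applies the substitution, and classifies
#' the effect. When the stop codon is abolished (stop-loss), translation
#' continues into the 3'UTR until the first in-frame stop; the notation is
#' reported both in the compact dialect `p.*<wt_len><res>ext*<n>` and in
#' HGVS form `p.Ter<wt_len+1><Res>extTer<n>`. If the 3'UTR contains IUPAC
#' ambiguity codes that change the deduced extension, every distinct
#' reading is reported (primary fields hold the first; the rest are in
#' `$alternatives`).
#'
#' @param tx a [transcript()].
#' @param v a [parse_hgvs_c()] variant (or a string, parsed on the fly).
#' @return A list of class `protein_consequence`: kind (one of
#'   `synonymous`, `missense`, `nonsense`, `stop_loss`, `no_change`),
#'   wt_protein, wt_len, mutant_protein, extension_len, ext_first_residue,
#'   next_stop_offset_nt, notation, hgvs, no_stop_found, alternatives.
#' @export
consequence <- function(tx, v) {
  if (is.character(v)) v <- parse_hgvs_c(v)
  cds_len <- tx$cds_end - tx$cds_start + 1L
  if (v$c_pos > cds_len)
    stop("variant position c.", v$c_pos, " lies beyond the CDS (", cds_len, " nt)")
  mpos <- tx$cds_start + v$c_pos - 1L
  have <- substr(tx$mrna_seq, mpos, mpos)
  if (have != v$ref)
    stop(sprintf("reference mismatch at c.%d: transcript has %s, variant says %s",
                 v$c_pos, have, v$ref))

  cds <- substr(tx$mrna_seq, tx$cds_start, tx$cds_end)
  codons <- substring(cds, seq(1, cds_len, 3), seq(3, cds_len, 3))
  wt_len <- length(codons) - 1L
  wt_protein <- paste(vapply(codons[seq_len(wt_len)], .codon_aa, ""),
                      collapse = "")

  codon_idx <- (v$c_pos - 1L) %/% 3L + 1L
  within <- (v$c_pos - 1L) %% 3L + 1L
  mut_codon <- codons[codon_idx]
  substr(mut_codon, within, within) <- v$alt
  wt_aa <- .codon_aa(codons[codon_idx])
  mut_aa <- .codon_aa(mut_codon)

  out <- structure(list(kind = NA_character_, wt_protein = wt_protein,
                        wt_len = wt_len, mutant_protein = NA_character_,
                        extension_len = 0L, ext_first_residue = NA_character_,
                        next_stop_offset_nt = NA_integer_,
                        notation = NA_character_, hgvs = NA_character_,
                        no_stop_found = FALSE, alternatives = list()),
                   class = "protein_consequence")

  if (codon_idx == wt_len + 1L) {           # variant hits the stop codon
    if (mut_aa == "*") {
      out$kind <- "no_change"
      out$mutant_protein <- wt_protein
      out$notation <- "p.(=)"
      out$hgvs <- "p.(=)"
      return(out)
    }
    out$kind <- "stop_loss"
    out$ext_first_residue <- mut_aa
    utr_chars <- strsplit(substr(tx$mrna_seq, tx$cds_end + 1L,
                                 nchar(tx$mrna_seq)), "")[[1]]
    branches <- .translate_utr_branches(utr_chars)
    mk <- function(br) {
      ext_len <- 1L + length(br$residues)
      list(mutant_protein = paste0(wt_protein, mut_aa,
                                   paste(br$residues, collapse = "")),
           extension_len = ext_len,
           next_stop_offset_nt = if (br$stopped) 3L * (ext_len - 1L)
                                 else NA_integer_,
           no_stop_found = !br$stopped,
           notation = sprintf("p.*%d%sext*%d", wt_len, mut_aa, ext_len),
           hgvs = sprintf("p.Ter%d%sextTer%d", wt_len + 1L,
                          AA3[[mut_aa]], ext_len))
    }
    primary <- mk(branches[[1L]])
    out[names(primary)] <- primary
    if (length(branches) > 1L)
      out$alternatives <- lapply(branches[-1L], mk)
    return(out)
  }

  ## variant within a sense codon
  if (mut_aa == wt_aa) {
    out$kind <- "synonymous"
    out$mutant_protein <- wt_protein
    out$notation <- sprintf("p.%s%d=", AA3[[wt_aa]], codon_idx)
  } else if (mut_aa == "*") {
    out$kind <- "nonsense"
    out$mutant_protein <- substr(wt_protein, 1L, codon_idx - 1L)
    out$notation <- sprintf("p.%s%dTer", AA3[[wt_aa]], codon_idx)
  } else {
    out$kind <- "missense"
    mp <- wt_protein
    substr(mp, codon_idx, codon_idx) <- mut_aa
    out$mutant_protein <- mp
    out$notation <- sprintf("p.%s%d%s", AA3[[wt_aa]], codon_idx, AA3[[mut_aa]])
  }
  out$hgvs <- out$notation
  out
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat(sprintf("protein_consequence: %s (%s)\n", x$kind, x$notation))
  if (x$kind == "stop_loss") {
    cat(sprintf("  wild-type %d aa; extension +%d aa starting %s; next in-frame stop %s nt downstream%s\n",
                x$wt_len, x$extension_len, x$ext_first_residue,
                ifelse(is.na(x$next_stop_offset_nt), "not found",
                       x$next_stop_offset_nt),
                if (x$no_stop_found) " (no stop before transcript end)" else ""))
    if (length(x$alternatives))
      cat(sprintf("  %d alternative reading(s) due to UTR ambiguity codes\n",
                  length(x$alternatives)))
  }
  invisible(x)
}
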