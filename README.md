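# rohmap

Homozygosity mapping of autosomal-recessive disease loci in small,
inbred case-control cohorts — plus the sequence-level annotation needed
once a candidate variant is found.

## Who this is for

Geneticists mapping a recessive trait in a genetically isolated
population (purebred dog breeds being the archetype), where long
linkage-disequilibrium blocks let a locus be localized with fewer than
ten individuals, and where the follow-up question is often "what does
this coding variant do to the protein?" — including the unusual
*non-stop* (stop-loss) class, where a substitution abolishes the stop
codon and translation runs into the 3'UTR.

## What it computes

* **Allelic association** (`gwas`): per-marker 1-df chi-square on the
  2×2 allele-count table, uncorrected (no Yates, no exact fallback),
  χ² = N(ad−bc)² / ((a+b)(c+d)(a+c)(b+d)). With 6 cases and 3 controls
  at complete separation, χ² = 18 and −log₁₀(P) = 4.6557.
* **Runs of homozygosity** (`call_roh`): sliding-window scan — 150-SNP
  windows allowing ≤ 1 heterozygous and ≤ 5 missing calls, SNPs kept at a
  0.05 homozygous-window fraction, segments retained at ≥ 1,000 kb,
  ≥ 150 SNPs, ≤ 50 kb/SNP mean density (all configurable via
  `roh_params`).
* **Recessive-model mapping** (`map_recessive`): intersect case ROH into
  loci shared by *every* case, verify and refine each locus by
  shared-haplotype identity (missing-compatible), and exclude any locus
  for which an unaffected control is homozygous for the case haplotype.
* **Variant consequence** (`consequence`): classify a `c.` substitution
  on a transcript model; for stop-loss, translate into the 3'UTR to the
  first in-frame stop and report `p.*405Rext*25`-style and HGVS
  (`p.Ter406ArgextTer25`) notations. `protein_stats` gives Arg+Lys /
  Asp+Glu counts and the isoelectric point (Bjellqvist pKa set, solved by
  bisection).
* **Segregation surveys** (`crosstab`, `segregation_report`,
  `trait_association`): phenotype × genotype tables, phenocopy and
  non-penetrance enumeration, exact 2×2 tests.
* **Synthetic cohorts** (`simulate_cohort`, `simulate_transcript`):
  seeded founder-mosaic genotypes with planted identical-by-descent
  disease and decoy loci, and transcripts with an engineered downstream
  in-frame stop — so the whole pipeline is testable without any data
  download.

Genotypes are read from PLINK text PED/MAP (`read_pedmap`) or VCF
(`read_vcf`) and written back as PED/MAP (`write_pedmap`). A thin CLI
over these functions is in `inst/cli/rohmap.R`.

## Worked example

```r
library(rohmap)

sim <- simulate_cohort(sim_config_study(42))   # 6 cases, 3 controls, ~11k SNPs
mp  <- map_recessive(sim$dataset)
summary(mp)
#> Association: 11000 markers, max -log10(P) = 4.6558 at 8 marker(s)
#> Case ROH: 32 segment(s), total 202.19 Mb
#> Shared loci: 5 (total 12.27 Mb core); retained after control exclusion: 1
#> candidate_locus chr25: core 10,084,254-12,015,252 (1.93 Mb), refined 10,004,999-12,086,175 (2.08 Mb)
#>   retained: no control carries the haplotype
```

Five loci are shared homozygously by all six cases; four are also
carried homozygously by controls and are excluded under the recessive
model; the one retained locus is the planted 2.09-Mb disease interval
(`sim$truth$loci$disease`), recovered to the marker. The core/refined
distinction mirrors how per-case ROH bounds are noisy while the shared
haplotype is not.

Annotating a stop-loss variant on a 405-codon transcript whose first
downstream in-frame stop begins 72 nt past the natural stop:

```r
tx <- simulate_transcript(405L, 72L, 200L, seed = 1)
consequence(tx, "c.1216T>C")
#> protein_consequence: stop_loss (p.*405Rext*25)
#>   wild-type 405 aa; extension +25 aa starting R; next in-frame stop 72 nt downstream
```

The abolished TGA is recoded to arginine and 24 further UTR codons are
translated before the next stop: 25 residues appended, consistent with
offset = 3 × (extension − 1) = 72.

Segregation of a candidate variant across the packaged 80-dog survey
table:

```r
segregation_report(crosstab(read_survey_tsv(
  system.file("extdata", "sag_survey.tsv", package = "rohmap"))))
#> segregation_report
#>          hom_alt other
#> affected      17     2
#> normal         1    17
#>   Fisher two-sided p = 1.947e-07; odds ratio = 144
#>   concordant: 34; phenocopies (affected, not hom_alt): 2; non-penetrant (normal, hom_alt): 1
```

17 of 19 affected dogs are homozygous for the risk allele; the two
wild-type affected dogs are phenocopies (or a second locus), and one
normal homozygote is non-penetrant at its examination age.

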