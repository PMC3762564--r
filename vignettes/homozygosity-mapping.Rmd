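---
title: "Mapping recessive loci by shared homozygosity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive loci by shared homozygosity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohmap)
```

## The mapping problem

In a genetically isolated population — a purebred dog breed is the
archetype — an autosomal-recessive disease allele is usually inherited
identical by descent (IBD) from a single founder. Every affected
individual is then homozygous not just at the causal variant but across
the whole surrounding linkage-disequilibrium block, which in such
populations can span megabases. This makes mapping feasible with a
handful of animals: find the genomic intervals where *all* cases are
homozygous for *one shared* haplotype, and discard the intervals where an
unaffected individual beyond the age of risk is homozygous for that same
haplotype (under full penetrance it cannot carry two copies of the causal
allele). rohmap implements this strategy as a pipeline of small, testable
steps, together with the sequence-level annotation needed once a
candidate variant is found — in particular the non-stop (stop-loss) class
of mutations, where a substitution abolishes the stop codon and
translation runs into the 3'UTR until the next in-frame stop.

## Allelic association

`gwas()` applies the classical 1-df allelic test per marker. With allele
counts $a, b$ in cases and $c, d$ in controls ($N = a+b+c+d$),

$$\chi^2 = \frac{N\,(ad - bc)^2}{(a+b)(c+d)(a+c)(b+d)},$$

with the p-value from the upper tail of $\chi^2_1$. Three choices matter
and are deliberate:

* **No Yates continuity correction and no exact-test fallback.** The
  uncorrected statistic is what classic genome-wide scans of this design
  report. At complete separation of 6 cases and 3 controls the table is
  (12, 0, 0, 6), $\chi^2 = 18$ exactly and $-\log_{10} P = 4.6557$; the
  corrected and exact alternatives give 3.69 and 4.27 respectively, and
  the test suite pins all three values so the choice is visible.
* **Monomorphic and margin-degenerate markers report $p = 1$** (flagged
  untestable) instead of being dropped, so every output table has one row
  per marker and joins stay stable.
* **Full precision.** $-\log_{10} P$ is stored as a double; any
  two-decimal rounding is display formatting only, since a printed "4.65"
  is compatible with either truncation or rounding of 4.6557.

With $n_1$ case and $n_2$ control chromosomes and no missing data the
statistic is bounded by $N = n_1 + n_2$ (here 18), attained exactly at
diagonal tables; the permutation-style test in the suite checks that this
bound is rarely reached by chance on unstructured cohorts.

## Runs of homozygosity

`call_roh()` reimplements the sliding-window ROH scan. A window is
`window_snp` consecutive SNPs (default 150) and is *homozygous* if it
contains at most `window_max_het` heterozygous (default 1) and
`window_max_missing` missing (default 5) calls. Each SNP is scored by the
fraction of windows containing it that are homozygous — near chromosome
ends the denominator is the reduced number of existing windows, and a
chromosome shorter than the window is a single whole-chromosome window.
SNPs scoring at least `snp_hit_threshold` (default 0.05) seed candidate
runs; runs are split where adjacent SNPs are further apart than
`seg_max_gap_kb` (default 1,000 kb), trimmed so both terminal SNPs are
confidently homozygous, and kept if they satisfy all three segment
criteria: length ≥ `seg_min_kb` (default 1,000 kb), SNP count ≥
`seg_min_snp` (default 150), mean density ≤
`seg_max_density_kb_per_snp` (default 50 kb/SNP).

Three design points were genuinely open:

* **The window is defined by SNP count only.** `window_kb` (1,000 kb) is
  recorded in `roh_params` for provenance but not enforced; with these
  flag values that is the effective behavior of the widely used PLINK
  implementation the defaults come from, and silently deviating from it
  would make published block coordinates irreproducible.
* **Gap splitting** is not part of the published criteria set; 1,000 kb
  is the conventional default and is exposed as a parameter.
* **Missing calls inside a run are retained.** They are not evidence of
  homozygosity but do not break a run; trimming guarantees no segment
  starts or ends on a missing or heterozygous call. Density is the
  segment mean (length/SNPs), not a local check.

Correctness is established against a brute-force oracle that materializes
every window explicitly; the suite checks exact equality of segment calls
on hundreds of random instances up to 300 SNPs, plus monotonicity
properties (relaxing window tolerances never shrinks total ROH; raising
the length threshold never grows it).

## From ROH to a candidate locus

`map_recessive()` composes four steps:

1. **Intersection** (`shared_roh_loci`): chromosomes where any case lacks
   a segment are dropped; on the rest, a candidate core is every maximal
   interval covered by at least one segment of *every* case.
2. **Haplotype identity** (`refine_by_identity`): sharing ROH is
   necessary but not sufficient — the cases must be homozygous for the
   *same* allele at every informative marker. Missing calls are treated
   as compatible (a SNP that fails in all individuals should not split a
   real block — array data regularly contain such markers). If identity
   fails somewhere in the core, the core is trimmed to its largest
   violation-free stretch (a locus failing at more than half its core
   markers is discarded with a logged reason); the interval is then
   extended outward marker-by-marker while identity holds. Refined
   intervals can therefore be smaller *or larger* than the ROH core, as
   the per-individual segment bounds are noisy at the edges while the
   underlying shared haplotype is not. The exact trimming/extension rule
   used in the original analyses of this design is not published; this
   reconstruction is documented as such and its behavior is fixed by
   tests. An interval never ends on a missing or heterozygous marker.
3. **Control exclusion** (`filter_by_controls`): a control is a carrier
   iff homozygous for the shared haplotype at every informative marker of
   the refined interval (missing compatible). Under full penetrance any
   carrier control falsifies the locus, so `max_carrier_controls`
   defaults to 0; it is exposed for incomplete-penetrance exploration.
4. **Ranking**: retained loci are ordered by the number of
   maximal-association markers they contain, then by size. Association
   peaks outside every shared-homozygosity interval (the single-SNP
   signal pattern, where nearby markers are heterozygous in cases) are
   reported as unsupported rather than silently dropped.

Interval sizes are displayed in Mb from 1-based inclusive coordinates,
rounded *half-up* to two decimals — base R's round-half-even would turn
the 2,087,255-bp block bounded by 46,893,645–48,980,899 into 2.09 via a
different path on other values; `interval_size_mb()` fixes the
convention.

## Stop-loss annotation and the deduced protein

`consequence()` translates the wild-type CDS (standard genetic code),
applies a `c.` substitution and classifies it. When the stop codon is
abolished, translation continues in frame into the 3'UTR until the first
stop; the extension length $e$ (recoded stop residue plus UTR residues)
relates to the nucleotide offset of the next in-frame stop as
$\mathrm{offset} = 3(e-1)$ — 72 nt downstream means 25 appended residues.
Two notations are emitted: the compact dialect `p.*405Rext*25` (star =
wild-type stop, number = coded residues before it) and the HGVS
recommendation `p.Ter406ArgextTer25`, where the number after `extTer` is
the downstream codon position of the new stop, which equals the count of
added residues. IUPAC ambiguity codes are tolerated in UTRs only; if an
ambiguous UTR position changes the deduced extension, every distinct
reading is reported rather than one being guessed. With no downstream
in-frame stop the consequence is flagged `no_stop_found` with the
extension running to the transcript end.

`protein_stats()` counts charged residues with the ProtParam convention —
positive = Arg + Lys (His excluded; its side-chain pKa of 5.98 leaves it
mostly neutral at physiological pH, and this convention is the one that
makes a 25-residue tail with four Arg/Lys add exactly four "positive
residues"), negative = Asp + Glu — and computes the isoelectric point as
the zero of the Henderson–Hasselbalch net charge under the Bjellqvist pKa
set (D 4.05, E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0; C-terminus
3.55; N-terminus dependent on the first residue). The zero is found by
bisection on pH 0–14, stopping at |charge| < 1e-4 or step < 1e-4; the
suite checks agreement with an independent fine-grid search within 1e-3
pH units and that the net charge at the returned pI is zero within 1e-3.
pI is stored at full precision and displayed at two decimals.

## Segregation surveys

`crosstab()` tabulates phenotype (normal / affected / suspicious /
unknown) against genotype (hom_ref / het / hom_alt).
`segregation_report()` evaluates the recessive expectation: phenocopies
are affected individuals without two risk alleles, non-penetrant
individuals are normal homozygotes. Tentative ("suspicious") and unknown
phenotypes appear in every table but never in the inferential 2×2, which
collapses affected vs normal × hom_alt vs other. `fisher_exact_2x2()`
uses the probability-mass two-sided rule (sum of hypergeometric
probabilities ≤ the observed table's, with 1e-7 relative tie slack — the
mainstream convention) and is verified exhaustively against a
binomial-coefficient enumeration on *every* table with N ≤ 60. Odds
ratios apply the Haldane–Anscombe +0.5 correction when a cell is zero.
One distributional point: a discrete exact p-value is *super-uniform*
under the null, so the suite asserts the calibration property of a valid
conservative test, P(p ≤ α) ≤ α plus Monte-Carlo slack, not strict
uniformity (which a discrete test cannot have).

The packaged `inst/extdata/sag_survey.tsv` expands a published 80-dog
genotype-survey contingency table into synthetic per-dog rows (ids
`dog001`–`dog080`); only the cell counts are real.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the data structure the pipeline assumes:

* **Founder pool.** Per-marker allele frequencies ~ Uniform(0.1, 0.9);
  `n_founder_haplotypes` (default 8) haplotypes drawn from them. Small
  pools produce the long background ROH and low diversity of an inbred
  isolate.
* **Gametes** are founder mosaics under a Haldane (no-interference)
  crossover process at `recomb_rate_cm_mb` (default 1 cM/Mb, the usual
  mammalian rule of thumb) — adequate for LD-block-scale realism and
  cheap.
* **Planting by painting.** The disease interval is painted homozygous
  (founder haplotype 1) into every case; a control that would be
  autozygous for it has one gamete repainted. Decoys are painted into all
  cases *and* their designated carrier controls, the controls with a
  10-marker margin (an unaffected carrier shares the ancestral haplotype
  over a longer stretch than the case consensus, and the margin keeps
  identity extension from walking past what the carrier shares). Painting
  trades coalescent realism for an exact truth table; the trade is
  recorded in the truth object.
* **Noise last.** Errors flip hom↔het symmetrically; missingness is
  uniform. Both default to 0 (no error model is published for the data
  this emulates); presets set 1% missingness. Phenotype follows carrier
  status through `penetrance` (default 1) and `phenocopy_rate` (default
  0).
* **Polarity.** Datasets are emitted in canonical PED polarity (allele_a
  = first allele a reader observes), so written PED/MAP files round-trip
  to identical genotype codes.

Two presets define the package's study conditions. `sim_config_study()`:
five 26-Mb chromosomes × 2,200 SNPs (~11.8 kb spacing — high-density
canine array density scaled to ~11k markers), 8 founders, 6 cases / 3
controls, one 2.09-Mb disease locus, four decoy loci of 2.2–3.0 Mb each
carried by two of the three controls, 1% missing calls.
`sim_config_null()`: 24 founders (relatively outbred), four 16-Mb
chromosomes × 1,200 SNPs, nothing planted. These sizes keep the
end-to-end acceptance checks (single study recovery; 100 null
replicates) cheap while leaving > 150 SNPs inside every planted
interval, the minimum the segment criteria require. The study preset
uses zero genotyping error: a single erroneous heterozygote inside the
planted block splits the identity-refined interval by construction, so
exact planted-bound recovery is a zero-error property; robustness to
error belongs to the (configurable) error model, not the default
conditions.

What passing tests therefore show: the caller equals its brute-force
definition; the pipeline recovers a planted IBD locus at array-like
density and excludes decoys via controls; nothing is retained on
unstructured cohorts. What they do not show: performance under genotyping
error inside the causal block, real canine recombination-map
heterogeneity, population stratification, or locus heterogeneity — the
painting model cannot speak to those.

## Worked example

```{r example}
sim <- simulate_cohort(sim_config_study(42))
mp <- map_recessive(sim$dataset)
mp$report
```

```{r annotate}
tx <- simulate_transcript(405L, 72L, 200L, seed = 1)
consequence(tx, "c.1216T>C")
```

## Known limitations

* PED/MAP and VCF import only; no binary PLINK formats, no dosages, no
  sex-chromosome ploidy handling.
* No phasing or imputation: haplotype identity is judged from homozygous
  genotypes with missing-compatibility, which is exactly right for fully
  inbred blocks and conservative elsewhere.
* The identity-refinement rule is a documented reconstruction (see
  above); alternatives (e.g. allowing k mismatching markers) would change
  refined bounds on noisy data.
* Selenocysteine recoding and genomic-to-transcript coordinate lifting
  across introns are out of scope; annotation works on cDNA coordinates.
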