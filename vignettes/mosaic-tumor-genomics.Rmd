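---
title: "Methods: genomic characterization of somatic-mosaic CRISPR tumor models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic characterization of somatic-mosaic CRISPR tumor models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicevo)
library(dplyr)
```

`mosaicevo` implements the genomic-characterization computations used to
profile tumor evolution in somatic-mosaic CRISPR mouse models: animals in
which tumor-suppressor knockouts are introduced in vivo by Cas9 and
multiple tumor samples per animal (primary sites, metastases, derived cell
lines) are then exome- or genome-sequenced against a matched normal. The
package covers five analysis stages — sgRNA editing-efficiency scoring,
somatic variant filtering, trinucleotide mutation spectra, arm-level
karyotype/aneuploidy/WGD profiling, and shared-mutation progression trees —
plus a synthetic cohort generator that provides ground truth for all of
them. This vignette documents the models, the tunable parameters, the
numerical conventions, and what the synthetic data can and cannot
establish.

## The synthetic cohort generator

All downstream stages are exercised on cohorts produced by
`simulate_cohort()`, because the raw animal sequencing data such analyses
are normally run on cannot be packaged. The generator is first-class,
tested code, and its defaults are the study conditions the package is
designed around:

* **Cohort structure.** 19 mice with 4 tumor samples each (~80 tumor
  samples plus one matched normal per mouse), cycling through primary /
  primary / metastasis / cell-line site labels. These sizes mirror a
  multi-sample murine renal-tumor study; tests and the acceptance script
  scale the cohort down where a property does not need the full size, and
  state the size they use in `n`.
* **Clone tree.** Each mouse carries a truncal trunk (default 5 SNVs
  present in every sample) and private leaf branches (default 15 SNVs plus
  3 indels per sample). Renal tumors in these models show few truncal
  point mutations and mostly private ones, which is why the default trunk
  is small. A `topology = "nested"` mode adds two clades of samples with
  clade-shared mutations for tree-recovery experiments.
* **Read counts.** A heterozygous somatic mutation of multiplicity $m$ on
  a region of tumor total copy number $C$ in a sample of purity $p$ has
  expected variant allele fraction
  $$\mathrm{VAF} = \frac{p\,m}{2(1-p) + p\,C},$$
  and simulated alt counts are binomial draws at that fraction with
  Poisson depths (`mean_depth`, default 80×, a typical exome depth).
  Variant tables are emitted in union re-genotyped form: every mutation of
  a mouse appears as a row in every sample of the mouse, with alt count 0
  where absent — mirroring pipelines that re-interrogate reads across an
  animal's samples.
* **Purity.** The studies this package models estimate purity from a
  lineage-reporter protein stain rather than computationally, and no
  numeric distribution is published; purity is therefore a free
  configuration parameter, defaulting to 0.7 as a realistic
  reporter-sorted tumor fraction.
* **Karyotype.** Arm events default to gain of chromosome 5 and losses of
  chromosomes 12 and 16 — the recurrent events in these murine renal
  tumors. The mouse genome model is 19 acrocentric autosomes, each a
  single q arm spanning the whole chromosome; a 39-arm GRCh37 table is
  included for human-mode analyses. Per-exon log2 read-depth ratios are
  drawn around $\log_2\!\big((p\,C + 2(1-p))/2\big)$ with Gaussian noise
  (`noise_sd_log2`, default 0.1, a typical exome log-ratio dispersion).
  WGD doubles every arm's copy number, and each sample receives a
  cellularity–ploidy probability grid peaked at the true (purity, ploidy)
  pair, emulating the prediction table of allele-specific copy-number
  tools.
* **Editing.** Cut-site pileups span a 50-bp window (half-width 25)
  centered on the expected sgRNA cut site. Tumor reads at positions
  within ±2 bp of the cut are altered at `editing_rate` (default 0.8 —
  these models edit very efficiently); all other positions, and the
  normal compartment, carry a flat background alteration rate of 0.002
  per base. The background is deliberately non-zero so the per-position
  2×2 tables are non-degenerate.
* **Mutational process.** Trinucleotide classes are drawn from
  `default_signature_mix()`, a C>T-dominated mixture (55% of mass on
  `N[C>T]G`) emulating the spontaneous-deamination process that dominates
  renal tumors. Variants are reported on a random strand so that roughly
  half carry purine reference bases, exercising pyrimidine normalization.
* **Indel contexts.** Downstream 20-nt contexts are uniform random by
  default with a configurable fraction (`indel_tandem_fraction`, default
  0.2) forced to be tandem repeats, so the repeat screen sees both
  positive and negative cases.

What the generator does **not** emulate: read-level artifacts (mapping
error, strand bias, FFPE damage), subclonal copy-number mosaicism within a
sample, non-flat sequencing-error profiles, caller-specific false-positive
modes, and germline contamination beyond the purity mixture. Passing the
package's tests therefore establishes that the statistics are implemented
correctly and are well-calibrated under the stated generative model — not
that they are robust to every artifact of real sequencing data.

## Editing-efficiency score

For each targeted gene, each window position contributes a 2×2 table of
altered/reference read counts in tumor versus matched normal. The score
chain is:

1. `position_log_odds()` — the natural log of the sample odds ratio
   $(\mathrm{alt}_T\,\mathrm{ref}_N)/(\mathrm{ref}_T\,\mathrm{alt}_N)$.
   We use the closed-form sample odds ratio with the Haldane–Anscombe
   correction (+0.5 on every cell when any cell is zero) rather than a
   conditional maximum-likelihood estimate: it is deterministic, exact at
   the packaged worked examples, and symmetric zero-alteration positions
   score exactly 0. A two-sided Fisher exact p-value is computed and
   stored alongside each position but does not enter the score.
2. `gene_z_scores()` — z-transform against the mean and **population**
   (n-denominator) standard deviation over the gene's window positions.
   The population convention is stated explicitly so the worked examples
   are exact; a window with zero spread yields all-zero z.
3. `sample_editing_score()` — per gene, the mean z over offsets within
   ±2 bp of the cut site (Cas9 cuts bluntly ~3 bp upstream of the PAM, so
   editing-induced alterations concentrate there), then the mean of those
   per-gene values across genes. Averaging z over the *whole* window
   would be identically ~0 by construction of the z-transform, which is
   why the central window exists; its half-width is configurable.

`call_gene_altered()` flags a targeted gene when ≥2 reads share an
alteration pattern at the cut site **or** region coverage falls below 50%
of a healthy control's median. The two clauses are alternative evidence
modes by default: frameshift indels need not depress coverage, and
homozygous deletions need not leave altered reads. A strict `mode = "and"`
is available, and the per-clause evidence is recorded either way.

Null calibration (editing rate 0 ⇒ mean sample score within ±0.1 over 200
samples), monotonicity in editing rate, and exact agreement of the odds
ratio with direct arithmetic are verified in the test suite and recomputed
by `scripts/acceptance.R`.

## Somatic variant filtering

Two threshold profiles are packaged:

* `murine_filter_profile()` — tumor coverage strictly >20×, normal
  coverage strictly >10×, tumor VAF ≥ 0.1. The strict/inclusive mix is
  intentional and preserved exactly; the boundary cases (depth 20 vs 21,
  VAF 0.099 vs 0.1) are pinned by a packaged 12-variant fixture.
* `msk_filter_profile()` — a human targeted-panel profile: tumor depth
  ≥10, ≥5 alt reads, tumor VAF ≥ 5%, normal VAF < 7%.

`apply_filter()` re-derives VAFs from the read counts, keeps a variant iff
every enabled threshold passes, and annotates rejected variants with the
first failing rule. Filtering is idempotent.

Indel calls additionally pass `repeat_filter()`: the 20 nucleotides
downstream of the call must not contain any motif of length ≤6 repeated
three or more times. "Repeated more than two times" is read as ≥3
**tandem** (consecutive) copies — the microsatellite false-positive
rationale — with a non-tandem "any 3 occurrences" mode behind a flag for
sensitivity analysis (note that the any-occurrence mode fails nearly every
window, since any base appearing three times anywhere triggers it; it is a
diagnostic, not a default). `N` bases never match a motif.

`exclude_sgrna_regions()` removes mutations overlapping sgRNA-targeted
regions (±50 bp by default): those are engineered drivers, and burden,
spectra and trees are computed over nondriver somatic mutations only.

## Mutation spectra

`trinuc_spectrum()` deduplicates mutations per mouse (the same
chrom/pos/ref/alt observed in several samples of one animal counts once),
reverse-complements purine-reference SNVs into the 96 pyrimidine-context
classes, and tallies counts and frequencies per cohort (e.g. metastatic
vs primary-plus-cell-line, or a single pooled cohort). Class counts are
conserved and frequencies sum to 1 per cohort; recovery of a known
generating mixture at n = 1,000 draws (cosine similarity ≥ 0.95) is part
of the acceptance checks. Full signature decomposition is out of scope —
the spectrum is the deliverable.

## Karyotype profiling

* `focal_call()` calls a focal event only when **all** exons spanning the
  region clear |log2| ≥ 0.4 with a consistent sign. The sign-consistency
  requirement is our addition: the all-exons rule presumes a coherent
  event, and a region whose exons exceed the threshold in both directions
  is not one event.
* `arm_calls()` summarizes each arm by the weight-weighted mean of its
  exon log2 ratios and applies an inclusive ±0.2 threshold. This direct
  statistic replaces a broad-level segmentation tool's internals, which
  are out of scope; the printed threshold is retained.
* `karyotype_profile()` median-centers each sample's log2 ratios before
  arm calling, so a genome-wide ploidy shift (WGD) does not saturate every
  arm call; ploidy is instead read from the cellularity–ploidy grid.
  No purity correction is applied to the ratios by default — whether the
  original analyses corrected for purity before thresholding is not
  stated, and at the purities simulated here the uncorrected statistic
  recovers the events comfortably.
* `aneuploidy_and_fcna()` — the aneuploidy score is the count of arms
  called gained or lost; fCNA is the **arm-length-weighted** fraction of
  the genome altered. The exact published aneuploidy-score-to-fCNA
  transformation is cited but not printed in the sources this package
  follows, so the length-weighted fraction — the natural reading of
  "fraction of genome altered" — is an explicit stand-in, with an
  arm-count mode (`mode = "count"`) for cross-checks.
* `select_ploidy()` restricts the grid to the cellularity nearest the
  independent purity estimate and takes the maximum-probability ploidy,
  ties to the lowest ploidy (the conservative, diploid-favoring choice).
* `call_wgd()` — the WGD rule is likewise deferred to an external
  definition that is not printed; we call WGD at ploidy ≥ 3.0, a
  configurable cutoff placed midway between a diploid and a tetraploid
  genome so that typical post-WGD losses do not escape the call.
* `select_het_snps()` / `allelic_imbalance()` — heterozygous SNPs are
  those with normal BAF strictly between 0.2 and 0.8 at ≥15× normal
  coverage; allelic imbalance per segment is the mean mirrored deviation
  |BAF − 0.5| of tumor BAFs, 0 under balance and →0.5 under complete
  single-allele dropout.

## Progression trees

The distance between two samples is 1 minus the number of shared
nondriver somatic mutations over the union carried by either sample — the
Jaccard distance on mutation sets (the source literature calls this a
Hamming distance; we keep the Jaccard name and note the correspondence).
The denominator is read as "nondriver somatic" mutations: the phrase
"nonsomatic" that appears in one description is treated as typographical,
since a denominator of germline variants would make the statistic
meaningless — this reading is flagged here rather than silently applied.

Presence of a mutation in a sample is defined as ≥2 supporting reads in
that sample's union re-genotyped counts, so a truncal mutation missed by a
caller in one sample is not spuriously privatized.

`build_tree()` performs agglomerative complete-linkage clustering with a
deterministic tie rule — among equally distant candidate merges, the
lexicographically smallest sorted member list wins. The rule is our
choice (no tie rule is stated in the sources) and is required for
permutation-invariant, reproducible trees; it is verified against a naive
O(n³) re-computation oracle. We implement the agglomeration directly
rather than delegating to `stats::hclust`, whose tie handling is input-
order-dependent; `hclust` would agree on tie-free inputs. Zero-length
internal branches (equal merge heights, tolerance 1e-12) are collapsed to
polytomies.

`assign_branches()` places each mutation on the branch above the largest
clade whose samples all carry it. Carrier sets that conflict with the
topology (possible under re-genotyping noise) fall back to the largest
clade fully contained in the carrier set — ties to the lexicographically
first clade — and are flagged per mutation rather than dropped; how such
conflicts were handled originally is not stated, so the rule is ours and
is auditable. Root-branch mutations are truncal, leaf-branch mutations
private, everything else shared. `truncal_private_fractions()` pools
per-sample occurrences within each anatomic site class, so a mouse whose
every sample is 70% truncal reports 0.7 regardless of how many samples
carry each mutation.

Trees are serialized as Newick with branch lengths equal to parent merge
height minus child height (`write_newick()`), and re-parse to the same
topology and heights; visualization is programmatic (`autoplot()`).

## Numerical conventions and degenerate inputs

* Odds ratios: +0.5 on all four cells only when some cell is zero; an
  all-zero position is an error, not a silent 0.
* z-transform: population (n) standard deviation; zero spread ⇒ all-zero
  z; fewer than 2 positions is an error.
* VAF at zero depth is 0, flagged via the `"zero_depth"` attribute.
* Distances: two empty mutation sets are at distance 0 by convention,
  flagged via the `"both_empty"` attribute.
* Coordinates: variant tables are 1-based (VCF convention); BED and SEG
  intervals are 0-based half-open; overlap uses the variant's reference
  span.
* Seeds: every simulator accepts an explicit seed, `simulate_cohort()`
  derives per-stage substreams from the single config seed, and the
  pipeline manifest records it; identical config + seed reproduce
  byte-identical outputs.

## Problem sizes used in the packaged checks

The test suite and acceptance script run the statistics at the sizes their
tolerances are designed for: 200 null samples for editing calibration,
1,100 windows for the repeat-screen oracle, 20 single-sample cohorts for
arm-call/fCNA/WGD recovery at purity 0.6 and noise 0.1, 1,000 draws for
spectrum recovery, 200 random distance matrices (n ≤ 8) for the linkage
oracle, 20 nested-topology cohorts for clade recovery, ~200 mutations per
sample for truncal-fraction recovery, and a 3-mouse demo cohort for the
end-to-end run. One statistical note: the VAF-model check spans a 3×3 grid
of (purity, copy-number) cells, so the per-cell bound uses the normal
quantile for a family error rate of 0.001 across the grid rather than a
raw 3·SE per cell, which would false-alarm in roughly 2% of runs.
The exhaustive "all label permutations" form of the linkage-oracle
comparison is intractable at n = 8 (40,320 permutations per matrix); the
packaged check combines full-oracle agreement on 200 matrices with
exhaustive permutation invariance at small n, which tests the same
determinism property.

## Known limitations

* The fCNA transformation and the WGD rule are documented stand-ins for
  cited-but-unprinted definitions (see above); both are configurable.
* Arm calls are made on purity-uncorrected, median-centered ratios; at
  purities below ~0.35 the single-copy-loss signal drops under the 0.2
  threshold and arms will be under-called.
* The progression tree is a sample-level dendrogram, not a subclonal
  deconvolution; mutations private to a subclone shared across samples
  appear truncal to the affected clade.
* The generator's binomial/Poisson model understates real overdispersion;
  calibration results transfer to real data only to the extent that model
  holds.

## A worked example

```{r example, eval = FALSE}
library(mosaicevo)

bundle <- simulate_cohort(cohort_config(n_mice = 3, seed = 7))

# editing efficiency per sample
scores <- score_editing(bundle$pileups)
glance(scores)

# nondriver somatic mutations
flt <- apply_filter(bundle$variants, murine_filter_profile())
nondriver <- exclude_sgrna_regions(
  dplyr::filter(flt, kept), bundle$sgrna_targets
)

# karyotype of one sample
kp <- karyotype_profile(
  dplyr::filter(bundle$seg, sample == "mouse01_s1"),
  arm_table("mm10"),
  grid = dplyr::filter(bundle$grids, sample == "mouse01_s1"),
  purity = 0.7
)
glance(kp)

# progression tree of one mouse
tree <- collapse_zero_branches(
  build_tree(dplyr::filter(nondriver, mouse == "mouse01"))
)
write_newick(tree)
autoplot(tree)
```
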