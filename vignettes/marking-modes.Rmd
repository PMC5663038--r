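---
title: "Plastic and constrained H3K27me3 marking: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plastic and constrained H3K27me3 marking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiconcord)
```

## The classification model

The unit of analysis is the *ortholog record*: one ancestral protogene with
a single gene descendant in each of three species — a pair of close sister
taxa (`Ath`, `Aly`, diverged on the order of 6 Myr) and a more distant
outermost species (`Aal`, ~24 Myr). For each record and each histone mark
the species carrying the mark define one of 2³ = 8 marking patterns.

Two collapses of the pattern space are used:

* *Concordant* marking: the mark is present in at least two of the three
  species. This threshold is the definition used throughout; it is not a
  tunable.
* For H3K27me3, the evolutionary modes: **constrained** if the outermost
  species and at least one sister-pair species are marked (under parsimony
  the mark was present in the common ancestor and never lost), else
  **plastic** if marked anywhere at all, else **unmarked**. The rule is by
  construction symmetric under exchange of the two sister species and
  asymmetric in the outermost one — the `species_config()` object declares
  these roles and makes the classifier reusable for other trios.

For H3K4me3 the analogous collapse is concordant (≥ 2 species) versus
lineage-specific (exactly 1).

### The independence null

Observed pattern abundances are compared with what independent per-species
marking would give. `expected_pattern_fractions()` implements two variants:

* `base = "marked"` (default): per-species marginals are estimated among
  the orthologs marked in ≥ 1 species, pattern probabilities are computed
  under independence and renormalized by 1 − P(no species marked). This is
  the convention that reproduces the published expected-by-chance figures
  (22% single-species, 30% three-species against observed 38%/40%), and it
  is the right yardstick when the question is "given that an ortholog is a
  PRC2 target somewhere, how should its pattern look by chance?".
* `base = "all"`: unconditional marginals over the full record set and
  unconditional pattern probabilities. This is the variant that data
  generated with truly independent per-species marking reproduces exactly,
  so it is the one the generator self-consistency tests use. The two
  variants answer different questions and deliberately coexist; the
  conditioned variant applied to independently generated data is *not*
  expected to match the observed conditional frequencies, because
  conditioning on "marked somewhere" induces dependence between species.

### Cross-clade extension

The outgroup flag records whether an ortholog also carries H3K27me3 in a
distant clade (maize/rice in the motivating data). The category whose
cross-clade fraction is quoted as "concordant" is ambiguous in prose; only
the all-three-species reading reproduces the published 26%, so `"triple"`
is the default of `cross_clade_fraction()`, with every other category
(including `"concordant"` ≥ 2 species) available through the `category`
argument rather than silently guessed.

## Sequence comparison

**Alignment-free (promoters).** Non-coding sequence cannot be reliably
aligned at these distances, so promoters are compared through k-mer
frequency profiles. The default word length is the largest k that a
sequence of length N can still populate, k = ⌊log₄ N⌋ — 4 for the 500-bp
promoter, 5 for a typical 1.2-kb coding sequence. Windows containing `N`
are skipped (deterministically — no random base resolution). K-mers whose
pooled frequency over the *reference collection* exceeds the 95th
percentile are removed before renormalization (`high_frequency_kmers()`,
quantile configurable): over-abundant words compress the dynamic range of
profile correlations. The threshold is a package choice — the protocol the
package follows states the removal but no cutoff — and is therefore
explicit and configurable rather than hidden. Distances are Jensen–Shannon
divergence (base 2, hence bounded [0, 1]; 0·log 0 := 0) and the Pearson
distance 1 − r on the retained coordinates. JSD without a square root is
not a metric; no triangle inequality is asserted or relied upon.

**Alignment-based (coding).** On a supplied pairwise alignment, gap or
ambiguous columns are dropped pairwise and the closed-form F84 distance is
computed from the transition proportion P, transversion proportion Q and
the base frequencies of the concatenated pair. The conventional expected
transition/transversion ratio (default 2.0) is recorded for compatibility
with the classic distance programs but does not enter the closed form,
which inverts the observed P and Q directly; the observed ratio is
reported. When the logarithm arguments hit zero the distance is undefined
and the function fails loudly (saturation) instead of returning a clipped
value.

## Promoter and expression covariates

* The promoter is the ≤ 500 bp immediately upstream of the TSS on the gene
  strand, clipped at chromosome boundaries; empty-after-clipping is an
  error, not a silent zero-length interval.
* 4-mer composition Z-scores compare a class's pooled 4-mer frequencies to
  a reference set (the promoters of orthologs unmarked in all species).
  The statistic is the pooled two-proportion z over total 4-mer windows —
  the simplest statistic whose sign and scale match a "Z-score between
  frequencies"; a per-promoter-mean variant is available via
  `method = "per_promoter"` because the original computation is ambiguous
  between the two. A 4-mer absent from both sets scores 0.
* A promoter harbors a transposable element when the overlap exceeds half
  the TE length, strictly (> 0.5 × TE length; an exact half does not
  count), any qualifying TE sufficing.
* Mean nucleosome occupancy averages only covered bases; sparse tracks do
  not deflate the mean.
* Tissue specificity is the Shannon entropy of the normalized expression
  profile across the 5 tissues (root, shoot, flower, pollen, seed), in
  bits: 0 for single-tissue expression, log₂ 5 ≈ 2.32 for uniform. All-zero
  rows give NA — "no data" is never conflated with "zero specificity".

## Inferential statistics

* **Block enrichment** is a one-sided upper-tail exact binomial test per
  synteny block (successes = genes of the class, trials = genes in the
  block, p₀ = class proportion averaged over all blocks), with enrichment
  declared at raw p < 0.05 — no multiple-testing correction, mirroring the
  original procedure; Benjamini–Hochberg is available but off by default.
* **Fisher co-occurrence tests** are computed by this package's own
  hypergeometric enumeration (two-sided, summing tables no more probable
  than observed, with the conventional 1 + 1e-7 tolerance); the test suite
  checks it against `stats::fisher.test` on every 2×2 table with N ≤ 40.
* **Two-way ANOVA** of sequence similarity on marking concordance and
  marking uniqueness uses Type II sums of squares — the marking classes are
  inevitably unbalanced, and Type II adjusts each main effect for the other
  without penalizing it for an interaction that is off by default (whether
  the original analysis fitted interactions is unstated; the option
  exists). Effect size is ω² = (SS − df·MS_err)/(SS_tot + MS_err), clipped
  at 0.
* **Ohnolog pair concordance** compares the fraction of duplicate pairs
  with both members plastic (resp. constrained) to the squared class
  fraction in the base population, all single-copy orthologs by default
  (giving the reference 2% for both classes); a marked-only base is a flag.

A note on calibration: exact tests on discrete data are conservative —
their attained size is below the nominal α and depends on the trial
counts. The calibration tests therefore simulate blocks of 500–1500 trials
and Fisher tables from two binomial groups of 800, sizes at which the
attained size (computed analytically beforehand: ≈ 0.045–0.048) is close
enough to 0.05 that a 2000-replicate estimate stays within ±0.01 of
nominal. With 30-gene blocks the attained size can drop to ≈ 0.03; that is
a property of exact tests, not a defect of the implementation.

## Hi-C contacts

Contact scores live in [0, 2] because the source maps are color-scale
quantifications. The printed class boundaries are two-decimal values
(weak to 0.59, moderate 0.60–1.29, strong from 1.30), which implies the
underlying convention was rounding; the package uses the half-open
intervals [0, 0.60), [0.60, 1.30), [1.30, 2] so that, e.g., 0.595 falls to
the lower class, reproducing the printed boundaries exactly. Saturated
("white") cells have no numeric score in the sources; they are carried as
an explicit saturation mask and always classify as strong. Matrices are
symmetrized by the elementwise maximum of the two triangles.

A gene overlaps a high-connectivity region with ≥ 1 bp of intersection
(configurable); the original is silent on a minimum. A strong contact is
attributed to a synteny-block category when either anchor bin intersects a
block of that category; a contact touching blocks of two categories counts
in both, symmetrically — documented here because it makes category ECDFs
overlapping rather than partitioned.

## Ohnolog detection

Double-conserved-synteny blocks are found by sliding a 20-gene window
along the outgroup gene order and asking for two distinct descendant
chromosomes with ≥ 3 mapped anchors each; consecutive windows with the
same chromosome pair merge into one block. Window and support are
package choices — the original used unpublished ad hoc scripts with
unstated parameters — so the published pair counts (1573/1449/1780) are
treated as non-reproducible and are not acceptance targets. Only the two
best-supported chromosomes per window are considered (deeper WGD layering
is out of scope). Pairs are one per outgroup anchor mapping into both
regions; same-chromosome pairs within 5 gene positions are tandem
duplicates and excluded (redundant with the distinct-chromosome rule, kept
as a safety net).

## The synthetic world

The generators exist so that every stage has inputs with known ground
truth. Their defaults are a single stated world, chosen once:

* **Marking:** a latent ancestral-target mechanism — an ortholog is an
  ancestral PRC2 target with probability θ = 0.15; targets realize the
  mark in each species with ρ = 0.8; non-targets gain it independently at
  a switch rate of 0.05. θ and ρ were chosen so the marked fraction
  (~25–30%) and the constrained share of marked orthologs come out on the
  scale of the real three-species set; the mechanism itself is an
  invention standing in for unmodeled evolution and only needs to span the
  observed pattern space. θ = 0 yields exactly independent marking (the
  null-consistency regime); θ = ρ = 1 yields all-constrained marking.
  The active mark uses the same mechanism at θ = 0.85, ρ = 0.97,
  switch 0.02, reflecting its near-universal concordance.
* **Promoters:** 500 bp, multinomial sampling from an AT-rich plant-like
  base composition (0.3/0.2/0.2/0.3); constrained-class promoters get +δ/2
  on A and T each with δ = 0.05 — enough to flip 4-mer Z-scores
  qualitatively at n = 1000 promoters, emulating the AT-richness contrast.
* **Expression:** Dirichlet tissue profiles over 5 tissues, concentration
  0.3 for constrained (tissue-specific, low entropy) versus 2 for others,
  scaled by log-normal totals.
* **Synteny blocks:** consecutive 30-gene runs; 10% of blocks designated
  enriched and filled with class genes at 3× the base rate.
* **Contacts:** score(i,j) = clip(1.5·|i−j|⁻¹ + boost·[long-range ∧
  designated] + N(0, 0.05), 0, 2), symmetrized, 20-kb bins. The boost
  default is 1.4: at long range the decay term is near the floor (~0.03),
  so only a boost clearing the 1.30 strong threshold realizes the
  phenomenon the generator exists to emulate — strong chromosome-arm-scale
  contacts for designated blocks (long-range means ≥ 0.6 of the
  chromosome, the scaled-down analog of the 18–23 Mbp band).
* **WGD:** a 200-gene outgroup genome duplicated onto two chromosome
  pairs, each copy lost independently at rate λ (default 0.1); truth =
  pairs with both copies retained.

Every dataset written by `write_synthetic_dataset()` carries a JSON
manifest of its configuration. All generators restore the global RNG state
on exit and are byte-reproducible under a fixed seed.

**What a green test does not establish.** The generators emulate the
*statistical structure* the analysis assumes — marginal rates,
cross-species correlation, composition contrasts, block enrichment,
distance decay — not real genomes: no indels or selection in promoter
evolution, no Hi-C polymer physics or normalization artifacts, no
annotation errors, no phylogenetic non-independence beyond the single
latent state. Consequently the genome-scale published figures that depend
on the real ChIP-seq/Hi-C/annotation data (the 32%/38%/27% connectivity
overlaps, the ohnolog pair counts, TF-family percentages) are *not*
reproduced here; the pipeline's behavior on such data is covered only by
the property and recovery suites.

## Degenerate inputs and numerical conventions

Internal coordinates are 0-based half-open everywhere (GFF3 converted on
read; BED native). Marking flags are tri-state: NA is reserved for absent
genes, and a flag on an absent gene (or a missing flag on a present one)
is a validation error — "unmarked" and "gene lost" are different facts.
Empty categories return NA, never 0. Binomial and Fisher p-values are
exact sums of point masses. ECDFs are right-continuous and end at 1.
Profile distances treat 0·log 0 as 0. The F84 distance refuses saturated
pairs rather than truncating.

## Known limitations

* The ANOVA's pairwise "co-marking" factor coding follows the stated
  definition (a pair is co-marked if at least one member holds both
  marks), but whether the original fitted interactions is unknown.
* DCS detection considers only the two best chromosomes per window and
  does not date duplications (α vs β).
* Dense contact matrices only; chromosome-scale at 20 kb is small enough
  that sparse storage is unnecessary.
* The classifier assumes exactly three species with a declared sister
  pair; more species would need a different parsimony rule.
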