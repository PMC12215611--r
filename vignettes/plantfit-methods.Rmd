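---
title: "Models and methods behind plantfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plantfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantfit)
```

# The problem

In a TnBarSeq colonization screen, a saturated library of randomly barcoded
transposon mutants of a plant-colonizing bacterium is inoculated into soil at
sowing; after several weeks the soil, roots and shoots are harvested and the
barcode population of each sample is sequenced. A mutant whose gene is needed
in a habitat is depleted there relative to the soil it colonized from.
`plantfit` implements the complete analysis for such a screen over five
habitats (`soil`, `At_root`, `At_shoot`, `Bd_root`, `Bd_shoot`) together with
the downstream analyses typically used to dissect an individual hit: gene-tree
clade calling for a protein family, a recombinant-inbred-line (RIL) linkage
scan, a combinatorial glucosinolate breakdown rule model, and dose-response,
qPCR and growth-curve assay computations.

# From reads to fitness

**Barcode extraction** (`extract_barcodes`) locates the first exact occurrence
of a 6-base anchor in each read and takes the following 20 bases. Matching is
exact — no mismatch tolerance in the anchor or barcode — because the amplicon
design places the barcode at high quality and any error correction would
conflate distinct barcodes; reads without an anchored, full-length barcode are
counted as discarded. The anchor sequence is a parameter, not a constant.

**Counting and filtering.** Counting against the mapping table is exact-match;
unmapped barcodes are tallied, never counted (`count_barcodes`). The usability
filter (`filter_barcodes`) keeps barcodes that disrupt a gene (have a locus
tag), sit in the central 10–90% of the gene body (insertions near the ends
often leave function intact), and average at least `min_reference_reads = 3`
reads across the soil reference samples, so that fitness ratios have a
measurable denominator.

**Strain fitness.** Soil is the T0-like reference: the library reaches the
plant from the surrounding substrate. With reference proportion
$r(b)$ (the mean of depth-normalized soil counts), sample depth $d(s)$ and
pseudocount $\epsilon = 1$,
$$f(b,s) = \log_2 \frac{n(b,s) + \epsilon}{d(s)\,r(b) + \epsilon}.$$

**Gene fitness** is the weighted mean of member strains with
Poisson-motivated inverse-variance weights
$w(b,s) = \left(\tfrac{1}{1+n(b,s)} + \tfrac{1}{1+d(s)r(b)}\right)^{-1}$,
followed by centering each sample so that the median gene fitness is exactly
0. Median centering assumes the typical gene is neutral — reasonable for a
genome-scale library — and replaces chromosome-position smoothing, which
matters most for multi-replicon genomes and is out of scope here. Both the
weight formula and the pseudocount are arguments, not constants.

Soil samples are deliberately used twice: averaged into the reference, and
kept as the comparison group in the regression below. Their own fitness
values hover near zero but retain between-sample variance, which is what the
test needs. A per-flat reference is a natural alternative when flats differ
strongly; the global soil mean is the default.

# The differential-fitness model

For each gene and each plant habitat, the fitness values of that habitat's
samples and the soil samples are modelled as

$$\text{fitness} \sim \text{sample\_type} + \text{auxiliary\_community} +
  \text{harvest\_day} + (1 \mid \text{flat})$$

with sample type (habitat vs soil), the auxiliary-community indicator and
harvest day as fixed effects and a per-flat random intercept (fitted with
`lme4`). The sample-type coefficient is the log2 fold change. Its p-value
comes from a likelihood-ratio test against the model without sample type:
among the usual small-sample options for mixed-model fixed effects, the LRT
avoids arbitrary degrees-of-freedom approximations and behaves sensibly when
the random-effect variance is small. When that variance estimate is
essentially zero (or only one flat is present) the model degrades to ordinary
least squares and the coefficient t-test is used — on balanced two-group data
this reduces exactly to the pooled-variance t-test. Constant covariates are
dropped; genes with fewer than 4 usable samples or fewer than 2 per group are
reported as skipped, not silently lost.

**Normality gate.** A linear model is only trustworthy here if its residuals
look Gaussian; founder bottlenecks make some genes wildly non-Gaussian. A
gene is omitted (`omitted_nonnormal`) if the Shapiro–Wilk test rejects
(p < 0.05) in *any* of its habitat-vs-soil fits — the per-fit residual sets
are the natural unit, since residuals only exist per fitted model. Note the
cost: testing four contrasts at level 0.05 each omits roughly 15–18% of
perfectly well-behaved genes. This is intrinsic to an any-of-k gate and is
visible in the package's own recovery benchmark (below).

**Classification.** Within each contrast, Benjamini–Hochberg adjustment over
retained genes, then: `association` if q < 0.05 and log2FC < −1 (mutants
depleted in planta, so the intact gene benefits association),
`negative_association` if q < 0.05 and log2FC > 1, otherwise `indifferent`.
Each habitat is tested against soil separately — matching the per-contrast
volcano view of such screens — rather than in one four-level model; BH is
applied per contrast accordingly.

# Specificity and enrichment

Per gene, the habitats with `association` (and, separately,
`negative_association`) calls form a subset of the four plant habitats, which
is classified: `general` (all four), `host_specific:<host>` (both organs of
one host), `organ_specific:<organ>` (same organ in both hosts),
`single_habitat:<habitat>`, `none`, and `mixed` for every other multi-habitat
pattern — the `mixed` class exists so that the classes partition the gene
universe. `upset_counts` tallies exact intersection patterns per direction.
COG-category enrichment uses a two-sided Fisher exact test per category
against the annotated background with BH across categories; a descriptive
comparison of category composition has no canonical test, and the exact test
is the conservative default at these category sizes.

# The synthetic-data generator

The generator produces every input the pipeline consumes, with the
statistical structure the analysis assumes — no more:

* **Library** (`simulate_library`): each gene gets a Poisson number of unique
  20-mer barcodes (default mean 8.5, the insertion density of a saturated
  mariner library), placed uniformly in the central 10–90% of a 1 kb gene
  body; inoculum abundances are lognormal with log2 standard deviation 1 (a
  typical spread for amplified transposon pools; the screen's inoculum
  distribution is not otherwise constrained).
* **Counts** (`simulate_counts`): soil samples are multinomial draws of
  `read_depth` reads with probabilities proportional to inoculum ×
  2^(soil effect). Plant samples first draw `bottleneck_founders` barcodes
  without replacement weighted by inoculum — the founder bottleneck: a plant
  is colonized by a limited number of cells, so each plant sample starts from
  an incomplete draw of the library — then grow deterministically by
  2^(habitat effect) and are sequenced multinomially. Sampling founders
  without replacement followed by deterministic growth is the simplest
  mechanism that produces a different starting population on each plant
  sample.
* **RIL population** (`simulate_ril_population`): five chromosomes, Poisson
  crossovers (default 1.5 per chromosome per line, the right order for an
  Arabidopsis RIL panel) at uniform positions, residual heterozygosity
  ignored; phenotypes derive from the three causal loci through the rule
  engine, never assigned independently.
* **Protein family** (`simulate_protein_family`): background members mutate a
  seed peptide independently; the designed clade descends from a clade
  ancestor through two anchor-founded subfamilies, so the anchors straddle
  the clade's basal split the way functionally tested genes from two genera
  would.
* **Dose-response** (`simulate_dose_response`): decreasing Hill curve plus
  Gaussian noise floored at 0, over a 1.5-fold serial dilution by default.

Every generator takes a single integer seed and reproduces bit-identically.
What the generator does *not* emulate: biological between-sample variance
beyond the flat effect and multinomial noise, PCR jackpotting, index
hopping, barcode sequencing errors, real genome sequence, linkage between
genes, or 16S community structure. Passing tests therefore demonstrate the
pipeline's correctness under its own model assumptions, not performance on
real sequencing data.

The magnitude distribution of true fitness effects in a real screen is
unknown; planted effects are arguments to the benchmark functions (default
−2 in log2 units, a clearly detectable but not extreme effect), not inferred
quantities.

# Clade calling

Family selection is exact-tag (default `COG0841`, the RND efflux-pump
inner-membrane subunit). Pairwise dissimilarity uses global affine-gap
alignment scores under BLOSUM50 (gap open 10, extend 1 — conventional
defaults, configurable):
$$d_{ij} = 1 - \frac{S_{ij}}{\min(S_{ii}, S_{jj})},$$
which is 0 for identical sequences and scale-free; very dissimilar pairs can
exceed 1 (negative cross-scores) and are documented, not clipped. The
neighbor-joining implementation breaks Q-criterion ties by the
lexicographically smallest pair of cluster ids (a cluster's id is its
smallest leaf label) and truncates negative branch lengths to zero, making
the output order-independent and deterministic; on exactly additive matrices
it reproduces all path lengths. Rooting is at the midpoint of the longest
leaf-to-leaf path — no outgroup is available within a single protein family,
and midpoint rooting is the standard assumption-light choice. The clade is
all leaves under the MRCA of the anchor (functionally tested) genes;
prevalence is the fraction of genomes per taxonomic class with at least one
member, alongside per-genome copy numbers.

# RIL scan and rule engine

The linkage scan is deliberately simple: per marker, the fraction of Ler
alleles among the non-missing lines of a phenotype group, with an exact
two-sided binomial test against 0.5, ordered along the five concatenated
chromosomes. Missing calls are excluded from both numerator and denominator.
Peak calling (`peak_intervals`) reports maximal runs of at least 2
consecutive markers deviating from 0.5 by at least 0.25 — a run-based caller
chosen because single-marker excursions at these panel sizes (~10–30 lines
per phenotype group) are noise.

The glucosinolate rule engine is a total function on the 2×2×2 genotype
space: chain length from MAM (MAM1 → 4C, MAM2 → 3C), side chain from AOP3
(active → hydroxyl, else methylsulfinyl), moiety from ESP (functional →
nitrile, else isothiocyanate), with hydroxyl isothiocyanates reported as
their spontaneous cyclization products (3C → 1,3-Oxazinane-2-thione, 4C →
1,3-Oxazepane-2-thione). Toxicity is a fixed product table: nitriles
non-toxic; 4MSO-ITC (sulforaphane), 3MSO-ITC (iberin) and
1,3-Oxazepane-2-thione toxic to the efflux-pump deletion mutant only;
1,3-Oxazinane-2-thione toxic to wild type and mutant alike. The parental
genotypes map to the parental chemotypes (Col-0 → 4MSO-ITC, Ler-1 →
3OHP-Nitrile).

# Assay models

The dose-response model is a decreasing Hill function with the floor fixed at
0 (full inhibition at saturating dose; a free floor is easy to add but not
identified by typical overnight endpoint data). Fits use
Levenberg–Marquardt least squares with positivity bounds, initialized at
top = max OD, IC50 = dose nearest half-max, hill = 1. Confidence intervals
are Wald intervals from the coefficient covariance; MIC is defined as the
fitted IC50. A series with no decrease across the dose range is flagged
non-identifiable rather than fitted blindly.

Growth-curve rules are step-function exact: the endpoint is the first time
the control reaches 90% of its maximum OD; a sample's final OD is its reading
at the last measured time at or before the endpoint (no interpolation — plate
readers sample densely enough that interpolation adds nothing) minus the
background, defined as the fifth-smallest OD of the series, because plant
material in the well absorbs and settles, making early readings unreliable as
background. Relative expression is $-\Delta\Delta C_T$ with fold change
$2^{-\Delta\Delta C_T}$ — exact arithmetic, no fitting.

# Operating characteristics and problem sizes

`screen_power_benchmark()` and `screen_null_benchmark()` measure the
pipeline on its own generative model. The package's reference configuration —
500 genes × 5 barcodes, four plant habitats × 6 samples plus 6 soil samples,
30 genes planted at log2 effect −2 in `At_shoot`, read depth 250,000, no
founder bottleneck — is sized so a full recovery experiment runs in well
under a minute per replicate on one core; the benchmark aggregates six
replicates so that sensitivity is estimated on 180 planted genes rather than
30. Under this configuration power is essentially 1 and the empirical FDR 0;
unconditional sensitivity (~0.85) is limited almost entirely by the
any-of-four-contrasts normality gate described above, a cost the analysis
accepts by design. The null benchmark (all effects 0) verifies that the
non-indifferent call rate stays within sampling error of the nominal level —
in practice near zero, since a call requires both q < 0.05 and |log2FC| > 1.

```{r, eval = FALSE}
bench <- screen_power_benchmark(seed = 1, n_reps = 6)
bench$sensitivity; bench$fdr; bench$single_habitat_fraction
```

# Known limitations

* The generator's noise model is multinomial-only; real screens add
  overdispersion that would reduce power and inflate the normality gate's
  omissions.
* Gene fitness uses median centering, not position smoothing; for
  multi-replicon or highly biased genomes a positional normalization would
  be preferable.
* The dissimilarity d = 1 − S/min(S_ii, S_jj) is not a metric and NJ makes
  no ultrametric assumption; clade calls depend on the anchors chosen, and
  the midpoint root can move a deep clade's MRCA if the family contains a
  single extremely divergent sequence.
* The RIL scan tests each marker marginally; it does not model epistasis,
  which the rule engine itself generates (the WT-toxic class requires a
  three-locus combination), so secondary peaks are attenuated rather than
  sharp.
* Wald intervals for Hill parameters can undercover when the dose grid
  barely brackets the IC50; profile likelihood would be the upgrade.
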