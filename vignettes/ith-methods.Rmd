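---
title: "Quantifying multi-sector intratumoural heterogeneity: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multi-sector intratumoural heterogeneity: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ithscape)
```

This vignette is the package's own account of the science it implements:
the scoring model, the generative model behind the synthetic cohorts, the
numerical choices made where the methodology left room, and what the
validation does and does not demonstrate.

## The ITH scoring model

A patient contributes $k \in [2, 5]$ tumour sectors. Every ITH score
follows one scheme: compute a pairwise dissimilarity $d(s_i, s_j)$ for all
$\binom{k}{2}$ sector pairs, and report the median as the patient score.
The median (not the mean) keeps a single aberrant sector pair from
dominating; for $k = 2$ the single pairwise value is the score.

* **Immune-ITH** uses $d = 1 - \rho$ with $\rho$ the Spearman correlation
  between the two sectors' immune-subset proportion vectors, so the score
  lives in $[0, 2]$: 0 for rank-identical compositions, 2 for perfectly
  reversed ones. Spearman ties receive average ranks — the standard
  convention. A composition with zero rank variance (all subsets equal)
  has no defined correlation; the package raises an error naming the
  patient and sector rather than propagating `NaN`, so silent corruption
  is impossible.
* **RNA-ITH** is the same construction across genes. The gene universe is
  whatever survives the expression filter (counts-per-million $> 1$ in at
  least 5% of samples, applied at load time when raw counts are given).
* **DNA-ITH** is $|A \mathbin{\triangle} B| / |A \cup B|$ per sector pair
  — mutations private to one sector over the union — with mutation
  identity the (chrom, pos, ref, alt) site key. An empty union scores 0.
  The pairwise reading (rather than pooling all sectors at once) matches
  the framing of all three scores as pairwise sector comparisons.
* **Density heterogeneity** is the sample SD ($n-1$) of per-region cell
  density, one SD per cell type, combined by unweighted mean. The
  combination rule was genuinely open; the unweighted mean is the least
  informative choice and is documented in the score object.

Patients are split at the cohort **median** immune-ITH; scores exactly at
the cutoff go to the low group, making the split deterministic and
reproducible (an all-tied cohort is all-low by construction).

The Euclidean immune-ITH variant uses raw proportion vectors without
re-normalisation. Whether the distance is computed on raw or normalised
vectors changes the scale but, in our validation, not the ranking — the
operative property is its rank concordance with the Spearman score, which
the acceptance checks measure (cohort Spearman $\rho > 0.8$ at $n = 50$).

## Phylogenies

Sector trees are built by standard Saitou–Nei neighbour joining (via
`ape::nj`) from either Hamming distances between binary mutational
profiles or $1 - \rho$ expression distances. Three choices deserve note:

* The adjacent non-tumour sample has, by definition of somatic calling,
  no somatic mutations; its profile is the zero vector, which makes it
  the natural outgroup.
* Hamming distances are unnormalised site counts, not fractions.
* NJ can estimate negative branch lengths on non-additive input; these
  are clamped to zero and the clamped deficit is retained as a tree
  attribute and reported. On additive matrices NJ is exact: the tree's
  path distances reproduce the input to $10^{-9}$, which the tests verify
  against a least-squares enumeration over all unrooted 4-taxon
  topologies.
* Newick serialization quotes labels containing whitespace; the writer is
  in-package because the upstream serializer rewrites spaces as
  underscores even inside quotes, which breaks round-tripping.

## Immunoediting

The score for a sample (sector or patient) is
$\mathrm{observed}/\mathrm{expected}$ where observed counts
neoantigen-bearing non-silent sites and
$\mathbb{E} = N_\mathrm{nonsilent}\sum_c f(c)\, p(c)$
over the 96 pyrimidine-collapsed trinucleotide contexts $c$: $f(c)$ is the
sample's spectrum over its own non-silent sites, and $p(c)$ the
cohort-wide fraction of non-silent mutations in context $c$ carrying at
least one predicted neoantigen. Two design choices:

* $p(c)$ is estimated **leave-one-patient-out** so a strongly edited or
  neoantigen-rich sample cannot contaminate its own expectation. Contexts
  absent from the background receive add-one smoothing
  $p(c) = (k+1)/(n+2)$.
* The expectation is context-probability based rather than
  peptide-resampling based. The guard for this formulation is the
  neutral-calibration property: with editing disabled the mean
  observed:expected ratio over patients stays within 5% of 1 at cohort
  scale ($\geq 2000$ mutations), which the acceptance suite checks.

For **stratified detection** (ITH group × HLA status), per-sector ratios
are pseudo-replicated — a patient's trunk mutations recur in every sector
— and right-skewed at small counts, so a rank test of ratios against 1 is
anti-conservative (we observed false "depletion" calls under the neutral
generator). Detection therefore aggregates patient-level counts per
stratum and applies a one-sided Poisson test of total observed against
total expected; per-sector ratios remain available for plotting and the
between-stratum rank-sum comparisons are still emitted. With four strata
tested per cohort, detection in the validation uses a Bonferroni-adjusted
$\alpha = 0.05/4$.

## Copy-number events

The altered genome fraction compares each segment's integer CN with the
sample's **length-weighted** median CN — the only choice invariant to
splitting segments — with ties resolved to the lower CN so a genome that
is half diploid, half tetraploid reports as altered rather than silently
neutral. Cytoband status (deleted/neutral/amplified) compares the band's
length-weighted mean CN with that same per-sector median (a ploidy proxy;
gene-level CN calling is out of scope), and group differences use
two-sided Fisher exact tests, BH-adjusted across bands within direction.
HLA-LOH is a strict threshold call: any class-I allele with minor CN
$< 0.5$ (0.5 itself is intact).

## Networks and the expression signature

DEGs between ITH groups default to a sector-level two-sided rank-sum test
with BH adjustment at FDR < 0.01. The test is deliberately pluggable: a
moderated linear-model statistic can be substituted without touching the
rest of the pipeline. Sector-level testing without a patient blocking
factor overstates the effective sample size; the leave-one-patient-out
stability check (consistency $> 0.95$ on planted signal) is the control
for that caveat. The network gate is $|\rho| \geq 0.4$ with raw
$p < 0.05$ per (gene, subset) pair — the absolute value is intentional
(negative couplings are biologically meaningful and kept as signed
edges), and no multiplicity adjustment is applied at the edge level,
matching the gating convention the thresholds come from. Networks are
computed per ITH group over that group's sectors.

Signature segregation of an external (single-biopsy) cohort z-scores each
signature gene across patients and contrasts the mean z of up-in-high
genes with that of up-in-low genes; a positive contrast is "high-like"
(ties to low-like). This rule is deterministic, exactly antisymmetric
under signature sign-flip, and invariant to gene-wise affine rescaling of
the expression matrix — properties the tests assert exactly. It stands in
for an unspecified clustering step in the original analysis; it is a
stated substitute, validated by ground-truth recovery, not a claim about
the original implementation.

The bootstrap FDR of a signature's survival split resamples patients with
replacement and counts the fraction of replicates whose log-rank test
fails at $\alpha = 0.05$. Each replicate analyses the distinct patients
drawn: duplicated patients have identical expression columns, hence
identical group calls, and counting them twice pseudo-replicates the
log-rank comparison — empirically inflating the null rejection rate
several-fold. With duplicates collapsed the null replicate failure
fraction sits near $1 - \alpha$, as it should.

## The synthetic cohort generator

The generator is first-class, tested code; it emulates a ~28-patient
hepatocellular-carcinoma-style multi-sector study (2–5 sectors per
patient) in which a single per-patient heterogeneity dial $h > 0$ drives
sector divergence in every layer:

* **Immune**: patient baseline composition
  $\sim \mathrm{Dirichlet}(2 \cdot \mathbf{1}_{15})$; sector compositions
  $\sim \mathrm{Dirichlet}\!\left(\tfrac{K}{h}\,\text{baseline}\right)$
  with precision $K = 60$, so dispersion grows with $h$.
* **Expression**: sector log-expression = gene baseline
  ($\mathcal{N}(6, 1.5^2)$) + $\mathcal{N}(0, \sigma\sqrt{h})$ sector
  noise with $\sigma = 1$. Planted DEGs (50 per direction) shift by
  $\pm 0.6$ with the ITH group and carry a patient-level effect;
  planted immune-coupled genes are affine in a subset's proportion with
  effect size giving Spearman $\rho \approx 0.7$; all remaining genes are
  independent sector noise, so they form an exact permutation null for
  the network's false-edge calibration (a shared patient effect in null
  genes would couple them to the immune baselines through patient
  identity and inflate the false-edge rate — we measured ~10% — without
  any true association).
* **Mutations**: 50 trunk mutations in every sector plus per-sector
  private mutations $\sim \mathrm{Poisson}(30\,h)$; contexts drawn from a
  configurable 96-context spectrum (default uniform), classes
  silent/missense/nonsense at 0.3/0.6/0.1; non-silent sites acquire
  neoantigens with per-context probability ramping 0.05–0.25, multiplied
  by the editing factor (default 0.5) for "edited" patients — defined as
  low-dial, HLA-intact, mirroring where depletion is biologically
  expected; binder IC50s are drawn below 500 nM.
* **Copy number**: two arm-level segments per chromosome; aberration
  probability $\min(0.6,\, 0.05 + 0.25\,h)$.
* **HLA**: per-patient LOH events ($1.5\times$ base probability in
  low-dial patients), realised as one allele's minor CN drawn in
  $[0, 0.45]$ across all sectors (clonal LOH).
* **Densities**: scaled CD4/CD8/Treg sector proportions plus noise.
* **Outcome**: exponential recurrence with baseline hazard
  $\log 2 / 20$ per month (20-month median), multiplied by the hazard
  ratio (default 2) for the high-dial half; independent exponential
  censoring tuned to the censoring rate.

The dial is drawn log-uniformly on $[0.01, 6]$. This range and $K = 60$
were fixed at design time by direct simulation so that the generator's
own stated behaviour holds — the estimated immune-ITH is monotone in $h$
(cohort Spearman $\rho > 0.9$ at $n = 40$) and the median split recovers
the ground-truth split for $\geq 90\%$ of patients; a narrower dial
range leaves the 15-subset Spearman estimator's sampling noise (a single
pair for 2-sector patients) dominating the between-patient signal.

Determinism: one global seed drives per-patient substreams, so the same
config is byte-identical and appending patients never perturbs earlier
ones. Group-dependent quantities (editing flags, DEG shifts, outcomes)
are drawn in later passes keyed by the same substreams.

**What the generator does not emulate**: spatial geometry and
autocorrelation between sectors (the sampling protocol's layout is not
modelled), overlapping gated immune subsets (the 15 subsets are a true
composition summing to 1 — safe because no score depends on the sum),
read-level noise, subclonal copy-number structure within a sector, and
biopsy-site bias in the external single-biopsy cohorts (patient-level
expression is a sector mean). Passing the validation therefore shows the
statistics are implemented correctly and recover planted structure of
realistic magnitude; it does not show robustness to those unmodelled
features of real data.

## Numerical and problem-size choices

Tolerances: brute-force oracle comparisons at $10^{-9}$–$10^{-12}$
(pure-arithmetic paths), NJ additivity at $10^{-9}$. Degenerate inputs
fail loudly: constant vectors in correlations, empty unions in DNA-ITH
(score 0 by definition), empty strata (skipped with a warning), collinear
Cox covariates (explicit error, never silent `NA`), all-censored log-rank
input. Validation problem sizes — 40-patient cohorts for recovery
properties, 50 for metric concordance, 200 × 50 seeds for survival
recovery, 300 for signature segregation, B = 200 bootstrap — were chosen
as the smallest sizes at which the corresponding population properties
are comfortably resolved; the full default pipeline (28 patients, all
stages) runs in a few seconds.

Cox models use the Efron tie convention, the standard default. The
hazard-ratio recovery check reports the median estimate across simulation
seeds against the planted value (per-seed estimates at $n = 200$ carry a
sampling SE of ≈ 0.16 on the log scale, so a per-seed window would
conflate sampling noise with bias) along with per-seed log-rank power.

## Known limitations

* Sector-level DEG testing ignores within-patient correlation (see
  above); treat the DEG list as a screening set.
* The immunoediting expectation assumes context-independent neoantigen
  probability given the spectrum; real epitope likelihood varies with
  peptide content beyond the trinucleotide context.
* Cytoband calls inherit the ploidy proxy (per-sector weighted-median
  CN); whole-genome duplications shift the reference rather than being
  called as events.
* The bootstrap FDR is an operational replicate-failure fraction, not a
  formal FDR in the multiple-testing sense; it is comparable across
  signatures, which is how it is used.
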