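# ithscape

Multi-sector analysis of intratumoural heterogeneity (ITH) in solid
tumours, written for cancer-genomics and tumour-immunology groups who
profile several spatially distinct regions ("sectors") of the same tumour
and want to connect how *internally heterogeneous* a tumour is — in its
immune composition, transcriptome, mutations and copy number — with immune
escape and patient outcome. The package implements the full analysis as
reusable, tested functions, together with a synthetic multi-sector cohort
generator with known ground truth so every stage can be validated
end-to-end without access to patient data.

## What it computes

**ITH scores.** For a patient with sectors *s₁ … sₖ* (k ≥ 2), each score is
the median over all unordered sector pairs of a pairwise dissimilarity:

- immune-ITH: 1 − ρ, with ρ the Spearman rank correlation between the two
  sectors' immune-subset proportion vectors (15 CyTOF-style subsets);
  an alternative Euclidean-distance variant is provided;
- RNA-ITH: 1 − ρ across genes between the two sectors' expression profiles;
- DNA-ITH: |A △ B| / |A ∪ B|, the fraction of mutations private to one
  sector of the pair;
- density heterogeneity: the sample SD of in-tissue cell density
  (CD4⁺ / CD8⁺ / Treg) across regions.

Patients are split into low/high immune-ITH groups at the cohort median
(ties to low). All downstream stages consume this split.

**Phylogenies.** Per patient, neighbour-joining trees of the sectors plus
the adjacent non-tumour sample, from Hamming distances on mutational
presence profiles (DNA) or 1 − Spearman ρ (RNA), written as newick.

**Genomic events.** Non-silent mutation counting; neoantigen filtering
(8–11-mer epitopes, IC50 < 500 nM); clonal vs subclonal neoantigen sites
(present in all vs only some sectors); HLA loss of heterozygosity (minor
allele copy number < 0.5); altered genome fraction (length of segments
whose integer CN differs from the length-weighted median CN, over total
length); cytoband-level deletion/amplification comparison between ITH
groups by two-sided Fisher exact tests with Benjamini–Hochberg adjustment.

**Immunoediting.** For each sector or patient, the observed number of
neoantigen-bearing non-silent mutations over the number expected from the
empirical trinucleotide mutational spectrum:
`expected = N_nonsilent · Σ_c f(c) p(c)`, where `f(c)` is the sample's
context spectrum and `p(c)` the cohort-wide per-context neoantigen
probability estimated leave-one-patient-out. A ratio below 1 indicates
immune-driven depletion; stratified tests localise depletion to
ITH-group × HLA-status strata.

**Networks.** Differentially expressed genes between ITH groups
(rank-sum, BH-adjusted, FDR < 0.01), immune-lineage genes removed via a
deconvolution-style exclusion list, then a bipartite gene–immune-subset
network of Spearman correlations gated at |ρ| ≥ 0.4 and p < 0.05, with
signed edges.

**Survival.** Kaplan–Meier / log-rank and Cox proportional hazards (Efron
ties) on recurrence outcomes; segregation of an external cohort by the
ITH expression signature (mean z-score contrast of up-in-high vs up-in-low
genes); bootstrap false-discovery estimate of the signature's survival
split; leave-one-patient-out stability of the DEG signature.

## Worked example

```r
library(ithscape)

cohort <- generate_cohort(cohort_config(n_patients = 28, seed = 1))
scores <- cohort_ith(cohort$bundle, "immune_spearman")
head(scores, 4)
#>   patient_id          metric     value n_sectors
#> 1        P01 immune_spearman 0.4964286         2
#> 2        P02 immune_spearman 0.5232143         4
#> 3        P03 immune_spearman 0.3571429         3
#> 4        P04 immune_spearman 0.0250000         2
```

P01's two sectors have immune compositions whose ranks correlate at
ρ ≈ 0.50, so its immune-ITH is 1 − ρ ≈ 0.50 — a fairly heterogeneous
tumour; P04's sectors are nearly concordant (score 0.025). The median
split then yields two groups of 14 at a cutoff of 0.125:

```r
groups <- assign_ith_groups(scores)
table(groups$group)
#> high  low
#>   14   14

cl <- classify_clonality(subset(cohort$bundle$mutations, patient_id == "P01"))
cl[c("clonal", "subclonal", "total")]
#> $clonal   [1] 3
#> $subclonal [1] 25
#> $total    [1] 28
```

P01 carries 28 neoantigenic mutation sites of which only 3 are clonal
(shared by both sectors) — consistent with its high ITH score. Survival by
ITH group on this small simulated cohort:

```r
rec <- cohort$bundle$clinical
rec$group <- groups$group[match(rec$patient_id, groups$patient_id)]
km_logrank(rec)
#> Log-rank: chisq = 1.320 (df = 1), p = 0.2506; HR[low vs high] = 0.625 [0.278, 1.404]
```

The high-ITH group recurs faster (HR for low vs high 0.625, i.e. ≈ 1.6
the other way), though 28 patients are underpowered for significance —
the package's validation uses larger simulated cohorts for that.

The whole analysis, end to end, with all tables written to a directory:

```r
res <- run_pipeline(pipeline_config(out_dir = "results_demo", seed = 1))
```

A thin command-line front end with the same stages lives at
`inst/cli/ithscape.R` (`simulate`, `ith`, `phylo`, `editing`, `cnv`,
`network`, `survival`, `run`).

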