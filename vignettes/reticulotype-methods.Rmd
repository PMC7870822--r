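---
title: "Individualized perturbed-correlation PPI networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized perturbed-correlation PPI networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reticulotype)
```

## The method

Bulk expression profiling of a disease cohort against a small set of healthy
controls usually feeds group-level statistics: differential expression,
enrichment of the average contrast. Those summaries erase exactly the
patient-to-patient variability that matters for stratifying a heterogeneous
disease. The approach implemented here characterizes **each patient
separately** by how their transcriptome *rewires* a reference co-expression
structure, and then grounds that rewiring in physical biology by keeping only
gene pairs that are known protein–protein interactions (PPIs). The result —
one network per patient, which we call a *reticulotype* — supports topology
comparisons, gene-set enrichment, and association with clinical variables at
the level of the individual.

The construction has four steps:

1. **Reference correlation.** Over the control cohort (n samples), compute
   the Pearson correlation r for every pair of genes that survives the
   expression filters (`fit_reference()`).
2. **Single-patient perturbation.** Append one patient profile to the
   control matrix and recompute each pair's correlation r′ over the n + 1
   samples (`perturb()`). The patient is removed again before the next
   patient is processed; the reference is fitted once and never refitted.
3. **Significance.** The change Δ = r′ − r is referred to the
   sample-specific-network statistic

   z = Δ / σ,  σ = (1 − r²)/(n − 1),

   with a two-sided standard-normal p-value, Bonferroni-corrected over the
   family of tested pairs. For example r = 0, n = 5, r′ = 0.9 gives
   z = 0.9·4 = 3.6.
4. **Interactome mapping.** Significant pairs are intersected with a
   consolidated PPI interactome (`build_reticulotype()`); edges are
   significant perturbed pairs that are also physical interactions, nodes
   are their endpoints. Per-edge provenance (r, r′, z, p) is stored so
   downstream modules never recompute.

### Expression filters

Filters are evaluated on **control columns only**: genes with zero counts in
every control are dropped, then genes must reach `min_count` (default 10)
counts in at least one control (`any_sample`) or in every control
(`all_samples`, a robustness variant). Only protein-coding genes enter the
network construction, since edges are interpreted as PPIs. The per-gene
coefficient of variation is reported as sd/mean × 100 with the sample (n − 1)
standard deviation.

Correlations are computed on log2 counts-per-million (+1) by default. The
input scale for the correlation is genuinely an open choice — raw counts let
a few high-count genes dominate through heteroskedasticity, so the log scale
is the default and `normalize = "raw"` is retained for sensitivity analysis.

### The Bonferroni family

Two family modes are exposed. `tested_pairs` (default) tests every valid
gene pair and corrects over all of them, matching the construction order
*test first, map to the interactome second*. `interactome_pairs` restricts
testing to pairs that are interactome edges; the family is then the number
of interactome pairs actually tested. The second mode is a deliberate,
clearly-labelled deviation that makes large families tractable and is used
in most of the package's own validation experiments. Zero-variance genes are
excluded from testing and never counted in the family: an undefined
correlation must not silently become 0.

### Small-sample behaviour of the Z statistic — read this

The scale σ = (1 − r²)/(n − 1) is an asymptotic (large-reference) result.
The package's own null-calibration experiment (in
`scripts/acceptance.R` and the acceptance test suite) draws patients from
the *same* generative model as the controls and measures how often a patient
presents any Bonferroni-significant edge. At the small reference size the
method is typically used with (n = 5 controls), that family-wise error rate
is measured near 1, not near the nominal α = 0.05; a companion unit test
shows the same statistic is well calibrated (null sd of z ≈ 1) at n = 30.
In other words, at n = 5 the statistic is an *effect-size ranking*, not a
calibrated test: edges should be read as "pairs whose correlation this
patient perturbs most strongly relative to (1 − r²)", and cross-patient
contrasts (overlap, unique edges, enrichment differences) remain meaningful
because every patient is scored against the same reference with the same
family. Users who need calibrated per-edge error control should use a larger
reference cohort. We deliberately did not substitute a different statistic:
the worked examples, defaults, and validation experiments all implement the
method as defined.

## Network statistics

* **Topology** (`network_topology()`): density 2E/(V(V−1)); diameter = the
  largest finite shortest-path distance; characteristic path length = the
  mean shortest-path distance over connected pairs. Disconnected pairs are
  ignored and the summary carries a `path_metrics_partial` flag whenever the
  network has more than one component — the convention of the standard
  network-analyzer tools this output is meant to match. Heterogeneity is
  sqrt(population variance of degree)/mean degree.
* **Overlap** (`pairwise_overlap()`): O(A,B) = |A ∩ B| / min(|A|, |B|), on
  node sets or canonical edge sets, within one cohort or across two. Note
  O ≥ Jaccard always, with equality exactly when the intersection is empty
  or the sets coincide.
* **Unique edges** (`unique_edges()`, `unique_feature_edges()`): edges
  present in exactly one patient's network; the count of unique edges
  touching a named gene set (e.g. a fibrosis program) serves as that
  patient's feature burden.
* **Grubbs screen** (`grubbs_test()`): two-sided, single-outlier, no
  iteration — G = max|x − mean|/sd against the t-based critical value
  ((n−1)/√n)·√(t²/(n−2+t²)), t = t(α/2n, n−2). A constant vector yields no
  outlier.
* **Enrichment** (`hypergeom_enrich()`, `enrich_cohort()`): upper-tail
  hypergeometric P[X ≥ k] per gene set, Benjamini–Hochberg q across the
  catalog, correction applied **per patient**; cohort summaries (the
  fraction of patients enriched for each set) are computed afterwards. The
  default universe is the intersection of interactome proteins with the
  filtered expression genes — enrichment is evaluated on the space networks
  are actually drawn from — and is configurable because the "right" universe
  is a genuine judgment call.
* **Clinical association** (`associate()`): Pearson or Spearman, chosen
  explicitly per variable rather than by an automated normality gate —
  silently automating that choice would hide an analyst decision. Spearman
  p-values are exact (permutation distribution) for n ≤ 8. Missing clinical
  values are deleted pairwise and the effective n is reported.

## The synthetic cohort generator

No real myectomy RNA-Seq data ships with the package; every validation runs
on cohorts from `simulate_cohort()`, which makes the ground truth knowable.

**Count model.** Gene g in sample s has
log mean = b_g + τ·z_gs, counts ~ NB(mean, dispersion), where b_g is drawn
uniformly on log(100)–log(2000) (the moderately-to-highly expressed genes
that dominate co-expression structure), dispersion is 0.1 (typical bulk
RNA-Seq), and z_gs is a unit-variance latent Gaussian. Genes in a module
share a per-sample factor f with loading √ρ:
z = √ρ·f + √(1−ρ)·ε, so any two module genes have latent correlation ρ.

The biological spread τ = 1.0 was calibrated once, openly: NB observation
noise attenuates the *realized* count-scale correlation to roughly
τ²ρ/(τ² + dispersion + 1/mean), and τ = 1.0 is the smallest round value at
which a ρ = 0.9 module expresses a mean pairwise correlation above 0.5 in a
20-sample control cohort while planted perturbations remain recoverable with
high precision at n = 5. The implied latent coefficient of variation
(≈ 130%) sits inside the range reported for heterogeneous disease cohorts.

**Perturbations.** A patient perturbation names a module and an effect:

* `decouple` sets all loadings to 0 for that sample — every within-module
  pair loses its correlation, and all pairs are recorded as planted truth.
* `flip` negates the loading of alternate (even-indexed) module genes, so
  pairs spanning the two sign groups flip their latent correlation from ρ
  to −ρ; exactly those cross-sign pairs are the planted truth. Negating
  *all* loadings would perturb nothing — the patient's point would move
  along the common latent line, leaving every pair correlation intact —
  which is why flip is defined as a per-gene sign assignment.
* A flipped module's factor is drawn conditioned on activity (|f| ≥ 1).
  A rewired program whose factor happens to be ≈ 0 in the one profiled
  sample leaves no trace in the data, so unconditioned draws would make the
  truth labels vacuous for some patients and recall would measure label
  noise rather than the method.

**Interactome.** The declared fraction (default 0.5) of within-module pairs
becomes PPI edges, plus Erdős–Rényi background at probability 1.6·10⁻³ —
the density of a consolidated human interactome with ~15,000 proteins and
~190,000 interactions.

**Clinical table.** The clinical variable (default "CO", intercept 6 L/min)
is a linear function of the patient's planted, interactome-covered
perturbation burden (slope −0.04 per pair) plus Gaussian noise (sd 0.5):
severity tracks how much of the patient's rewiring is visible to the
pipeline.

All randomness flows from a single integer seed through one stream;
generation is bit-reproducible.

### What the generator does and does not emulate

It reproduces the features the method is sensitive to: a small control
cohort, overdispersed counts, block-correlated modules, patient-specific
rewiring, an incomplete interactome, and clinical variables driven by
molecular burden with noise. It does **not** emulate transcriptome scale
(10⁴ genes), batch effects, isoform structure, hub-dominated interactome
degree distributions, or correlated clinical confounders. Passing tests
therefore demonstrate correctness and qualitative behaviour of the
*pipeline*, not effect sizes to be expected on real tissue.

## Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` rerun these end to end:

* **Oracle equivalence** — r/r′ against a two-pass brute-force Pearson
  recomputation on 1,000 random small instances (≤ 6 genes, ≤ 8 samples,
  agreement to 10⁻¹²); hypergeometric p against exhaustive subset
  enumeration for universes up to N = 12; topology metrics against a
  Floyd–Warshall oracle on all 1,024 labelled 5-node graphs plus 1,500
  random 6–7-node graphs.
* **Null calibration** — 100 genes, 5 controls, 200 null patients
  (measured FWER reported as-is; see the small-sample discussion above).
* **Planted recovery** — 200 genes, one ρ = 0.9 flipped module of 20 genes
  per patient, PPI coverage 0.5: per-patient recall and cohort precision of
  planted, covered pairs.
* **Node-versus-edge contrast** — two 6-patient cohorts over the same
  36-gene pool wired as the rows versus the columns of a 6×6 grid: the same
  proteins, different interactions. Within a cohort, edge overlap falls
  well below node overlap; across cohorts, node overlap stays substantial
  while edge overlap collapses toward zero.
* **Enrichment contrast** — all patients flip the "fibrosis" module, none
  perturb "hypertrophy": cohort enrichment frequencies separate completely.
* **Clinical association** — 12 patients each flipping three private
  fibrosis-program modules of graded size (4–15 genes), so fibrosis burden
  varies strongly across the cohort; the number of unique fibrosis edges is
  correlated with the generated cardiac-output variable.

These sizes keep every experiment deterministic, seed-reproducible, and
fast enough to rerun routinely.

## Known limitations

* The perturbation statistic is anti-conservative at the small reference
  sizes it is typically applied to (measured, discussed above); treat edges
  as rankings unless the reference cohort is large.
* Recall of planted signal is *not* monotone in the reference size at
  strong effects: shrinking n inflates raw recall together with false
  positives. Precision, not recall, is the quantity that improves with n.
* Identifier namespaces are taken at face value: no symbol/accession
  mapping is attempted, and expression-versus-interactome coverage is
  reported rather than fixed.
* Interactions are undirected, unweighted, and binary; confidence scores
  and directionality in source files are ignored.
* The enrichment universe and the per-patient correction family are
  configurable choices, not settled facts; defaults are documented above.
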