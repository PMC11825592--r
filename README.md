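# netcentral

Density-integrated centrality analysis of structural brain connectomes,
with a fully synthetic test bed.

## What this is for

In temporal lobe epilepsy, the "hubness" of specific grey-matter
regions — notably the piriform cortex — in the structural connectome is
a candidate marker of sustained epileptic activity: more central nodes
are hypothesized in drug-resistant patients, with centrality increasing
with disease duration and predicting worse surgical outcome.
`netcentral` implements the full analysis chain for testing such
hypotheses on streamline-count connectomes from probabilistic
tractography, for researchers working with region-by-region count
matrices and clinical covariate tables.

Patient diffusion-MRI data of this kind generally cannot be shared, so
the package also ships a synthetic cohort generator that emulates the
statistical structure of such a study — a plantable group effect on one
node's centrality and a duration covariate rank-coupled to it — making
every stage of the pipeline testable end to end.

## The method

Per subject, a raw asymmetric count matrix `C` (default 82×82: Desikan
cortical parcels, subcortical structures and a piriform ROI per
hemisphere) with per-region waytotals `w` is processed as:

1. normalize: `C'[i,j] = C[i,j] / w[i]`
2. symmetrize: `W = (C' + C'ᵀ) / 2`
3. threshold: for each density `d` in 20–40% (1% steps), keep the
   `k = round(d · n(n−1)/2)` strongest edges, binarized.

At each of the 21 densities, node degree and (unnormalized, undirected)
betweenness centrality are computed and then **summed across the
sweep** — an AUC over network densities — giving one
threshold-independent value per node per subject.

Inference on the integrated values:

* permutation t-tests (pooled-variance t, 100,000 label permutations,
  add-one two-tailed p, exhaustive enumeration when cheap) comparing
  drug-resistant vs drug-sensitive groups at Bonferroni
  `α = 0.05/4 = 0.0125` for the primary bilateral-piriform family;
* Cohen's d with pooled SD (so `t = d·√(n_A n_B / n)` exactly);
* Spearman correlations with epilepsy duration (t-approximation
  p-values), with age at MRI as a negative control;
* OLS covariate adjustment (resistance + duration, then additionally
  sex, laterality, MRI-lesion dummy, onset age) with listwise deletion;
* exploratory whole-network scans with Benjamini–Hochberg FDR over all
  nodes;
* a surgical subanalysis (ILAE class 1 vs other outcomes, ≥ 1 year
  follow-up) at `α = 0.05/10 = 0.005`.

## Worked example

```r
library(netcentral)

cohort <- generateCohort(cohortSpec(seed = 1))   # 82 nodes, 43+19+2 subjects
config <- analysisConfig(nPermutations = 10000L,
                         exploratoryPermutations = 2000L, seed = 1)
report <- runStudy(cohort, config)
report
```

```
Study analysis report
  primary tests (alpha = 0.0125 ):
        node      metric        t         d          p significant
 lh_piriform      degree 2.149296 0.5920809 0.03479652       FALSE
 lh_piriform betweenness 2.013016 0.5545388 0.04609539       FALSE
 rh_piriform      degree 1.601597 0.4412025 0.12088791       FALSE
 rh_piriform betweenness 1.501458 0.4136168 0.14078592       FALSE
  duration correlations:
        node      metric        rho            p significant
 lh_piriform      degree 0.47814934 9.727028e-05        TRUE
 lh_piriform betweenness 0.46177443 1.796537e-04        TRUE
 rh_piriform      degree 0.12924298 3.208520e-01       FALSE
 rh_piriform betweenness 0.08491339 5.152715e-01       FALSE
  surgery subanalysis (alpha = 0.005 ):
        node      metric         t          d          p               direction
 lh_piriform      degree -1.823575 -0.7444713 0.08159184 smaller in seizure-free
 ...
```

The cohort in this seed carries a planted left-piriform degree effect
(target standardized difference 0.85; the value realized in any single
simulated cohort varies with sampling, here d = 0.59) and a planted
duration coupling (target Spearman ρ = 0.39, here realized 0.48 after
measurement). The left piriform tests show the expected direction, the
right-side tests do not approach significance, and operated
seizure-free subjects show smaller centrality (negative d) — the
qualitative pattern the pipeline is designed to detect. Detection
significance in a single cohort of this size is not guaranteed; see the
methods vignette for the power analysis and for repeated-cohort
detection rates.

Individual stages are exposed as ordinary functions:
`generateBaseConnectome()`, `plantCentralityEffect()`,
`normalizeByWaytotal()`, `symmetrize()`, `thresholdToDensity()`,
`densitySweep()`, `nodeDegree()`, `betweennessCentrality()`,
`integrateAcrossDensities()`, `subjectCentrality()`,
`permutationTwoSample()`, `cohensD()`, `spearmanCorr()`, `olsAdjust()`,
`fdrBH()`. Cohorts round-trip through plain text via `writeCohort()` /
`readCohort()`, and thin command-line wrappers live in
`inst/scripts/`.

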