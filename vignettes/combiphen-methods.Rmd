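---
title: "Methods: from ligand-combination perturbations to phenotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ligand-combination perturbations to phenotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combiphen)
```

combiphen implements the computational chain used to ask how microenvironmental
ligands — classically EGF, OSM and TGFB acting on mammary epithelial cells —
combine to produce cellular phenotypes that single ligands do not. The chain
runs from live-cell tracking data to per-condition phenotype metrics, from
those metrics to Highest Single Agent (HSA) tests of *emergence*, from bulk
RNA-seq counts to differential expression, transcriptional modules and
HSA-based *synergy* calls, and finally to partial least squares models that
link replicate-level expression to replicate-level phenotype and yield gene
signatures that can be validated against external data. Every stage can be
exercised offline against a paired synthetic-data generator that records its
own ground truth.

This vignette documents the models, the tunable parameters and their defaults,
the places where a design had to be chosen among reasonable alternatives, and
the limits of what the synthetic tests demonstrate.

## Track-derived phenotypes

Four metrics summarise each condition x replicate:

* **Cell count fold change** `count_fc`: cells per field at 24 h divided by
  the field's count at treatment time (frame 0), averaged over fields.
* **Motility**: the ordinary-least-squares slope (intercept included) of the
  mean squared displacement against lag over lags of 0.5–6 h. For
  two-dimensional Brownian motion MSD(tau) = 4 D tau, so slope/4 estimates the
  diffusion coefficient D (px^2/h). The MSD is time-averaged within tracks
  over all overlapping frame pairs and pooled across tracks weighted by pair
  count; this estimator has the lowest variance among the common variants and
  is translation- and rotation-invariant. The intercept absorbs the positive
  offset that centroid-detection noise adds at every lag. Before the MSD,
  tracks containing any displacement greater than 200 px within one 30-min
  interval are removed entirely (strict inequality at the boundary): such
  jumps are tracker identity switches, and removing the whole track rather
  than the offending step avoids stitching two different cells into one
  trajectory.
* **Nearest-neighbour ratio**: the mean distance from each cell centroid to
  its k-th nearest neighbour divided by the expectation under complete
  spatial randomness at the same intensity lambda = n/A,
  E_k = Gamma(k + 1/2) / ((k-1)! sqrt(pi lambda)) (the Clark–Evans
  construction; for k = 1 this is 1/(2 sqrt(lambda))). Ratios below 1 mean
  clustering, above 1 spreading. The neighbour order k is exposed as a
  parameter and defaults to 1 — the nearest *other* cell — because the
  distinction between "nearest" and "second nearest" in the source protocols
  is ambiguous once self-distance (always zero) is excluded. No edge
  correction is applied; with reflecting-boundary simulations the bias at
  n ≈ 500 cells per 1024^2 px field is within the Monte-Carlo noise (the CSR
  calibration test holds the mean ratio within 1.00 ± 0.05).
* **Cytoplasmic area**: the mean segmented area of cells present at 24 h.

The evaluation time is snapped to the nearest available frame, so light frame
dropping does not shift the metric definitions.

### Response magnitude

Each treated replicate is compared against the vehicle (PBS) replicate of the
same batch: rel_i = (m_i − m_i^PBS) / m_i^PBS per metric, and the *phenotypic
response magnitude* is the Euclidean norm of the resulting 4-vector. The
relative-difference scaling makes the four metrics unitless and commensurable
before taking the norm; the origin corresponds exactly to "no change from
vehicle", and the magnitude is zero only there. Absolute differences would
let the largest-valued metric (motility, in px^2/h) dominate the norm.

## Emergence under the Highest Single Agent model

The HSA model posits that a combination's expected response equals the best
constituent single-agent response. A combination metric is called **emergent**
when it differs significantly from *each* constituent single-ligand condition
— one-way ANOVA followed by Tukey's honest significant difference test, with
adjusted p < 0.05 (strict) for every combination-vs-single pair. The HSA
expectation (the most extreme single-ligand mean on the side the combination
deviates towards) is reported for interpretation but does not enter the call.
Replicate means (n = 3) are the experimental units; fields within a replicate
are averaged first.

ANOVA and Tukey are computed directly from group summaries (with the
Tukey–Kramer standard error and the studentized-range distribution via
`ptukey`), which makes the Monte-Carlo calibration loops in the test suite
cheap; both are verified against `stats::aov`/`stats::TukeyHSD` to 1e-10.
Dunnett many-to-one contrasts against a control use `multcomp::glht`, whose
multivariate-t quantiles are fixed by a seed. All panel contrasts are
standardised on ANOVA + Tukey (Dunnett for vs-control comparisons) — a
deliberate simplification relative to workflows that mix in marginal-means
models for individual panels.

Calibration facts, measured by simulation in the test suite: under an
HSA-consistent null (combination and singles all equal), requiring both
Tukey-adjusted pairs simultaneously gives an emergent-call rate of ~0.6% at
alpha = 0.05; with a 3-within-group-SD injected effect at n = 3 the
Monte-Carlo power is ~0.61. That power ceiling is a property of the
studentized-range critical value at these tiny group sizes (per-pair critical
|t| = q(.95, 3, 6)/sqrt(2) ≈ 3.07 against a noncentrality of
3/sqrt(2/3) ≈ 3.67), not of the implementation; detecting 3-SD effects with
n = 3 reliably would require relaxing the family-wise adjustment or more
replicates.

## Differential expression, DEG burden and modules

Counts are normalised to log2 counts-per-million with a pseudocount of 1.
Within each two-group contrast the per-sample totals are corrected by
median-of-ratios size factors (per-sample median of the ratio to the per-gene
geometric mean): with a few hundred strongly induced genes, raw totals shift
every null gene's fold change by the induced genes' share of the library, and
that composition bias is exactly what median-of-ratios normalisation removes.

The DE engine is intentionally simple — the package's contribution lies
elsewhere — and stands behind an interface that also accepts precomputed
DESeq2-style tables verbatim (`import_de_table()`). The log2 fold change is
the mean log2-CPM difference; p-values default to the empirical-Bayes
moderated t-statistic of limma (`lmFit`/`eBayes` with a mean–variance trend)
on the log2-CPM matrix. Moderation matters at n = 3 per side: an unmoderated
per-gene t-test has at most 4 degrees of freedom, its smallest attainable
p-values are too large to survive Benjamini–Hochberg correction across 10^4
genes, and genes with accidentally identical replicate values produce
degenerate statistics. An unmoderated t remains available
(`method = "t"`; pooled-variance by default, which is calibrated at small
equal n, whereas Welch's df estimate makes the test conservative at n = 3).
Measured on the package's own negative-binomial generator: type-I error
0.053 under the null; observed FDR 0.065 at q < 0.05 with 5% planted
two-log2 effects.

DEGs are counted with the strict rule |LFC| > 1.5 and q < 0.05, and the
per-condition DEG count is regressed against the condition-mean phenotypic
response magnitude (OLS; R^2 and slope-test p).

For module discovery, the most strongly regulated genes per condition (top
200 up and top 200 down by fold change among genes with p < 0.05 and
|LFC| > 1.5; ties broken by gene id) are pooled as a union — the merge rule is
not uniquely determined by the source protocols, and the union with
per-condition membership is the permissive choice. Their LFC-by-condition
matrix is clustered with K-means (Euclidean distance, 10 random restarts —
the standard R idiom in place of k-means++ seeding) and the number of modules
K is selected by the gap statistic with B = 50 uniform reference sets drawn
over the per-feature bounding box, taking the smallest k with
Gap(k) >= Gap(k+1) − s_{k+1} (`cluster::clusGap`, `spaceH0 = "original"`,
`"Tibs2001SEmax"`). Module scores are per-module median LFC per condition.
Degenerate inputs (all rows identical) short-circuit to K = 1.

## Additive expression null and HSA synergy calls

Two complementary questions are asked of combination expression:

1. **Is the bulk response additive?** For genes upregulated (LFC > 0.5
   vs T0) in at least one constituent single, the additive prediction is the
   sum of the single-ligand LFCs; the fit of observed combination LFC on this
   prediction (OLS R^2) quantifies global additivity.
2. **Which genes escape the additive/HSA picture?** A gene is **positively
   synergistic** when its combination expression exceeds *each* constituent
   single-ligand condition by more than 1.5 log2 units with adjusted p < 0.05
   in every combination-vs-single contrast, and negatively synergistic
   symmetrically. All inequalities are strict and the classes are mutually
   exclusive. The contrasts are computed directly between the combination and
   single-ligand samples (not by differencing vs-T0 LFCs), which preserves
   proper error estimates. The rule extends unchanged to the triple
   combination against its three singles — an extension beyond the pairwise
   setting the rule was formulated in, and labelled as such.

Measured recovery at the test fixture's conditions (dispersion 0.02, 100
planted +2-log2-beyond-HSA genes among 10^4): recall 0.93, false-positive
rate 5e-4; under a purely additive generator the total call rate is below
0.1% and the additive R^2 exceeds 0.95 at technical-level noise
(dispersion 0.01). At biological dispersion (0.05) the same additive R^2 is
bounded by replicate noise to roughly 0.65–0.9 — the regime real triplicate
experiments live in.

## PLS1, VIP scores and signatures

One PLS regression is fitted per phenotype metric (PLS1), using
replicate-level LFC profiles as predictors and the replicate-level metric as
the response, so biological replicate-to-replicate covariation between
expression and phenotype informs the fit. Predictors are autoscaled and the
response standardised; the preprocessing is recorded and inverted on output.
The fit is the classical NIPALS sequence

    w_a = X_a' y_a / ||X_a' y_a||,   t_a = X_a w_a,
    p_a = X_a' t_a / (t_a' t_a),     c_a = y_a' t_a / (t_a' t_a),

with deflation of X and y after each component; SSY_a = c_a^2 (t_a' t_a) is
the response variance captured by component a. At full rank the fitted values
coincide with ordinary least squares (tested to 1e-6), scores are mutually
orthogonal, and requested components beyond the informative rank are dropped
with a warning.

Before fitting, low-information genes are removed by a variance ranking.
For abundance-scale input the ranking follows the variance-stabilising idea
popular in single-cell feature selection: a loess trend (span 0.3) of log10
variance on log10 mean assigns each gene an expected sd, values standardised
by that sd are clipped at sqrt(n), and genes are ranked by the variance of
the clipped values. For signed input such as LFC matrices the mean *is*
biological signal, a mean trend would absorb exactly the coordinated
programs the model should find, so genes are ranked by clipped variance
directly. The pipeline models the top 600 of 2500 simulated genes — the same
"model a top-variable subset" proportion as selecting 2500 from a ~20k-gene
transcriptome.

The number of components is chosen by leave-one-out cross-validation:
RMSEP(A) from LOO predictions with preprocessing refit in every fold, and
RRMSEP(A) = RMSEP(A)/sd(y) so that 1.0 is the no-skill reference (the
normalisation is a package choice; "relative" is not otherwise pinned down).
The elbow rule is made explicit: the smallest A whose relative improvement to
A+1 falls below 5%, or where the curve turns up, or where the error is
already at the noise floor (RRMSEP <= 0.05). On pure-noise responses the
minimum LOO RRMSEP sits slightly *above* 1 (overfitting inflates prediction
error); on noiseless rank-1 data RRMSEP(1) is below 0.05 and A = 1 is chosen.

Variable importance in projection follows the standard weight-based formula

    VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a ),

whose squares average to exactly 1 over the p genes (asserted to 1e-8 on
every fitted model, and checked against an independent implementation to
1e-10). Each gene's sign is the sign of its correlation with the
first-component scores — the model's dominant latent direction — not the sign
of its regression coefficient. A phenotype **signature** is the top 100
genes by VIP among the positively correlated genes plus the top 100 among the
negatively correlated ones (ties by gene id; shortfalls recorded;
zero-correlation genes belong to neither side).

External expression matrices are mapped into a fitted model by restricting to
the model's genes, z-scoring each gene within the external dataset (external
cohorts have their own location and scale), imputing absent model genes at
the post-scaling mean of 0, and applying the standardized regression vector;
predictions return on the model's response scale. Overlap below 50% of model
genes triggers a warning, zero overlap an error.

## Validation

Signatures are validated two ways. Against CRISPR gene-effect tables, a gene
is "essential" when its mean gene-effect across the provided cell lines is at
or below −0.5 (the conventional depletion bound; the aggregation across lines
is a package choice — mean — and the threshold is exposed). The 2x2 signature
x essentiality table is tested with Pearson's chi-squared without continuity
correction (large-count regime). Against paired measurements, predicted and
measured phenotypes are compared by squared Pearson correlation with its
t-test p.

## The synthetic-data generator

The generator emulates the study design the analysis assumes: 8 treatment
conditions (PBS, three single ligands, three pairs, one triple) x 3
replicates, with paired track and count data and a recorded ground truth.

**Tracks.** Initial centroids per field follow the condition's point pattern
(uniform/CSR; a Thomas cluster process, offspring sd 40 px, ~10 offspring per
parent, as the clustered contrast; a jittered grid as the dispersed
contrast). Each frame (0.5 h apart, 49 frames = 24 h) every cell takes an
isotropic Gaussian step with per-axis variance 2 D dt and reflects at the
boundary of the 1024^2 px field — reflection keeps density stable for the
spatial statistics, where absorbing edges would thin the pattern. Divisions
are per-cell Bernoulli events with probability `division_rate * dt`; the
daughter appears at the parent position plus a 2-px Gaussian offset, which
preserves a realistic short-range clustering signal. Areas are lognormal
(CV 0.3) and constant along a track. The default field seeds 200 cells; the
fields' true density is not published, so this is a fixture choice. The
default per-condition D (30–150 px^2/h), division rates (0.008–0.045 /h) and
areas (380–650 px^2) mirror the qualitative single-ligand hierarchy the
assay reports: EGF drives proliferation, motility and larger cells, OSM
modest growth with tight clustering, TGFB close to vehicle alone, with
emergent motility in EGF-containing combinations and emergent
spreading/enlargement in EGF+TGFB.

**Counts.** Gene g in condition c has mean
`library_size * 2^(baseline_g + sum of single-ligand effects + synergy)`
with NB noise (variance mu + dispersion mu^2). Baselines are N(5, 2) log2
units, dispersion 0.05 (a typical bulk RNA-seq asymptotic dispersion for
cell lines) and library scale 20, i.e. a median gene count around 600 —
roughly a 2M-read gene-level experiment; at much shallower depth the +1 CPM
pseudocount visibly compresses low-count fold changes. Per-ligand responsive
fractions default to EGF 12%, OSM 8%, TGFB 3% with effect sd 1.5 log2,
mirroring the ligands' transcriptional footprint hierarchy. Combination
means are additive in log2 except for listed synergy genes, which receive an
extra log2 shift — the generator's null *is* the additive model the analysis
tests.

**Linked experiments.** A set of 50 driver genes carries a rank-one program:
each ligand contributes a latent activity (EGF 1.2, OSM 0.8, TGFB 0.4,
additive in combinations) and driver g responds with `loading_g` times the
condition's activity, loadings U(1, 2) — placing the driver program at the
top of the fold-change distribution, as the phenotype-driving programs in the
motivating biology are. Each replicate's phenotype metric is a linear map of
the *realised* replicate-level driver LFCs plus Gaussian noise at
signal-to-noise ratio 3, so expression and phenotype share replicate-level
variation — the property the replicate-paired PLSR design exploits. With
weaker loadings the drivers become statistically indistinguishable from
incidental single-ligand responders: in an 8-condition design any
single-ligand response profile correlates ~0.8 with the additive latent
activity, which bounds what *any* method could recover. Track parameters for
the linked experiment are derived from the condition-mean phenotypes
(D = motility/4, division rate = log(count_fc)/24 h), keeping the imaging arm
qualitatively consistent. External "cell lines" draw a latent activity
uniformly over the panel's range, add per-gene line effects (sd 0.5 log2),
and carry the model-implied true phenotype plus measurement noise.

**What the generator does not emulate** — and what passing tests therefore do
not demonstrate about real data: no image formation or segmentation error
(the jump filter is exercised by construction, not by realistic tracker
failures); no cell-cell exclusion, contact inhibition or directed/collective
migration; division-independent cell loss is absent; library composition is
the only RNA-seq artefact modelled (no GC/length bias, batch structure or
outlier samples); ligand response profiles are independent across background
genes, whereas real co-regulation would make signature recovery harder; and
the expression-phenotype link is linear by construction, which is the
assumption PLSR itself makes.

## Numerical and reproducibility choices

All generators are pure functions of (parameters, seed); a single master seed
spawns labelled child streams (`derive_seed`), so adding a stage never
perturbs another stage's draws. The pipeline (`run_pipeline()`) writes only
plain-text tables, records an md5 manifest keyed by the hash of the
normalised analytical configuration (the output directory is excluded from
the hash), and is bit-reproducible for a fixed configuration. Degenerate
inputs follow explicit conventions: flat ANOVA/Tukey/Dunnett groups give
p = 1, zero-variance predictors carry zero PLS weight, all-identical module
input gives K = 1, and a flat DE gene gives p = 1.

The test-suite problem sizes are chosen so the whole suite runs in a few
minutes on one core: 500 tracks x 49 frames for diffusion recovery, 20 CSR
layouts of 500 points, 10^4 Monte-Carlo replicates for the emergence and
Tukey calibrations, 10^4 genes x 3 replicates per side for the DE, additivity
and synergy recoveries, 20 seeds of 240 points for the gap statistic, and a
24-sample x 2500-gene linked experiment for end-to-end recovery.

## Known limitations

* The emergence test's power at n = 3 is modest (see above); the calibration
  is honest but the design is under-powered for 3-SD effects.
* The DE engine is a moderated-t on log2-CPM, not a count GLM; users with
  DESeq2 results should import them (`import_de_table()`), which the whole
  downstream chain accepts unchanged.
* Synergy recall is bounded by fold-change estimator noise: at biological
  dispersion and n = 3, a planted +2-log2 gene misses the strict 1.5
  threshold in roughly one contrast out of ten.
* RRMSEP-based component selection with 24 samples rarely supports more than
  two components; the `a_max` default of 10 is a ceiling, not a target.
* The Clark–Evans ratio is computed without edge correction and is biased
  for very sparse fields (n below ~50 cells).
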