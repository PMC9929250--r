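---
title: "Methods: multilevel proteomic analysis of paired tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilevel proteomic analysis of paired tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its statistical methods: the model
behind each stage, the conventions chosen where published practice is silent
or ambiguous, and what the synthetic-cohort tests do and do not establish
about real data.

## Data model

Each cohort carries up to three feature-by-sample abundance matrices —
proteome, phospho-proteome, and TF (transcription factor) DNA-binding
activity from a TFRE pull-down — over the same paired tumor/NAT samples,
plus clinical endpoints (DFS/OS), a binary mutation table over a driver
panel, a kinase→substrate-site map, a TF→target-gene network and GMT gene
sets. Raw-scale intensities are nonnegative with `NA` marking missing cells;
all identifiers are opaque case-sensitive symbols (no ID mapping anywhere).
Phospho-sites are written `PROT_S123` with 1-based residue positions; the
reader rejects duplicate site rows rather than merging them, because there
is no defensible automatic merge rule for ambiguously localized sites.

## Normalization and QC

The proteome is normalized by **fraction of total** (FOT): each column is
divided by its sum over observed entries and scaled by 1e6, so every
sample's observed signal sums to one million. This models equal protein
loading per MS run and removes per-sample depth multiplicatively — and
exactly, which is why the per-sample log2 offsets in the synthetic generator
vanish after normalization. An important consequence used throughout the
tests: FOT data are *compositional*. Planting an absolute log2 effect of e
on a set of features yields a measured (relative) effect of roughly
e − log2(T/N total-mass ratio); with the default planted effect structure
that compression is a few tenths of a log2 unit. Recovery expectations are
therefore stated at the generator's reference effect (2.0 log2), where the
measured contrast clears the 2-fold screen with a wide margin.

The phospho and TF layers are **quantile normalized** (via limma's
mean-of-order-statistics construction: ties receive the mean of the
reference values they span, missing entries are excluded from ranking and
stay missing). Missing values are then imputed with the **per-layer global
minimum** — the convention that matches detection-limit (MNAR) missingness —
and log2-transformed. The order "normalize → impute → log2" is the package
default; `fot_normalize()`, `impute_min()`, `log2_transform()` compose
freely for other conventions.

Sample QC flags a sample when its median observed log2 abundance exceeds
Q3 + 1.5·IQR of the cohort's median distribution. Quartiles use linear
interpolation (R's type-7 default), fixed here so the rule is reproducible.
Exclusions propagate to the paired partner (`partner_failed`), so the
retained set contains only complete tumor/NAT pairs. A dip-style bimodality
screen is available but disabled by default: no published numeric criterion
exists, so it is opt-in with an explicit threshold.

**Detection filtering.** Minimum imputation is safe for rank tests but
poisonous for distance geometry and for features that are mostly missing in
both tissues: such features carry no recoverable signal. `filter_by_detection()`
implements the usual ">50% of samples" rule and should precede the
differential screen; clustering uses a stricter convention (below).

## Differential screens

Tumor-vs-NAT contrasts use the paired Wilcoxon signed-rank test on log2
values, with zero differences dropped. The exact signed-rank null is used
for n ≤ 25 without tied |differences|; with ties an explicit sign-flip
enumeration is used up to n = 14 (2^14 terms; beyond that exhaustive
enumeration is not computationally sensible), else the tie-corrected normal
approximation with continuity correction. Group contrasts use the rank-sum
test, exact when untied and the smaller arm has ≤ 10 observations. Both
report two-sided p as 2·min(tails), capped at 1. BH correction is standard
step-up.

Fold changes are computed on the linear scale; the paired default is the
median of per-pair ratios and the unpaired default the ratio of group
medians (medians for robustness — both conventions appear in published
supplements, so the method is an explicit argument everywhere). DEPs are
FC > 2 (strict) with BH p < 0.05.

The **six-group partition** classifies features whose tumor/NAT ratios
differ ≥ 2-fold between histologies: up in both with DGC-dominant ratio
(ratio-of-ratios ≥ 2) vs IGC-dominant, discordant directions, and the two
down-regulated analogues. The within-partition dominance rule is not printed
anywhere authoritative; the 2-fold ratio-of-ratios convention used here is
declared, tested for disjointness and rule fidelity, and not calibrated to
any published group counts.

## KSEA

Kinase activity is scored as z = (s̄ − p̄)·√m/δ with s̄ the mean log2
fold change of the kinase's m ≥ 3 quantified substrate sites and p̄, δ the
mean and SD of all quantified site fold changes — the standard form of the
kinase-substrate enrichment score. Sites mapped to several kinases
contribute to each. Significance comes from a two-sided permutation null
(random size-m substrate sets without replacement, add-one correction
p = (b+1)/(n_perm+1)); a Kruskal–Wallis statistic is sometimes mentioned in
this context in the literature without a defined role, and is deliberately
not used. The z-score is antisymmetric under negating all fold changes and
invariant to positive rescaling; both are tested.

## TF activity and master TFs

A protein is **TFRE enriched** when its mean normalized TF-layer abundance
exceeds 4× (strictly) its mean normalized proteome abundance; annotated TFs
are always reported. A **master TF** of a subtype must jointly pass
(a) tumor-upregulated activity — paired signed-rank p < 0.05 and fold change
\> 2 by the *mean* ratio: a master TF's gain is concentrated in its subtype,
and a median of per-pair ratios would discard exactly the signal the
criterion is about; (b) subtype-upregulated activity — one-vs-rest rank-sum
p < 0.05 and median-ratio FC > 1.5, the lower bar reflecting the noisier
activity readout; and (c) hypergeometric enrichment (upper tail) of its
target genes among the supplied DEP set at p < 0.05. The enrichment universe
defaults to all quantified proteins (passed explicitly), not the network's
target space; the DEP set may be the up- or down-regulated set per query, so
repressor-style TFs can be interrogated without special-casing. Nomination
is monotone in all thresholds (relaxing never removes a nominated TF).

The kinase→TF network retains Spearman correlations between per-sample
kinase activities (substrate means of centered log2 abundances) and TF
phospho-sites with rho > 0 and p < 0.05 (exact null for n ≤ 9 without ties,
t-approximation otherwise), requiring ≥ 5 shared samples.

## Consensus clustering and k selection

`consensus_cluster()` is the Monti resampling construction: per repetition a
fraction (0.8) of samples is drawn without replacement, clustered by
average-linkage agglomerative clustering on Euclidean distance, and cut at
every k in 2…6; consensus(i,j) is the co-clustering rate among co-sampled
repetitions (1000 by default). Final labels cluster 1 − consensus with the
same linkage. The per-k CDF area A(k) is the integral over [0,1] of the
empirical CDF of upper-triangle consensus values, computed exactly as
1 − mean(consensus); the relative delta-area is Δ(2) = A(2) and
Δ(k) = (A(k) − A(k−1))/A(k−1), and `select_k()` returns argmax Δ.

Two deliberate deviations from the commonly cited tool's defaults, both
forced by measurable failure modes on synthetic data:

* **Feature subsampling** (fraction 0.8) accompanies item subsampling. Item
  resampling alone leaves the pairwise distances of retained samples fixed,
  so even structureless data yields a crisp consensus — the known
  overconfidence of consensus clustering. Feature resampling re-randomizes
  the noise per repetition, restoring an informative null.
* **Ambiguity flag via PAC** (proportion of ambiguous clustering: consensus
  entries strictly inside (0.1, 0.9)). Real structure makes the consensus
  crisp at the true k, so min over k of PAC sits at 0; structureless data
  keeps every k fuzzy and the minimum stays above ~0.2. The flag triggers at
  min-PAC > 0.1, the midpoint of that gap on simulated planted and null
  cohorts. A delta-area flatness rule cannot do this job: on null data the
  small A(2) inflates Δ(3), so the delta profile is *not* flat.

**Clustering features** (`clustering_features()`): the most variable
features among those *fully quantified* in the samples to be clustered. Both
halves matter: a single min-imputed cell contributes the squared distance of
hundreds of noise features and otherwise dominates the Euclidean geometry,
and variance ranking on imputed data otherwise selects detection-marginal
features whose imputed/observed bimodality fakes structure. Published
analyses typically cluster tumor-upregulated proteins; with the generator's
planted structure the subtype signal lives in the variable-feature space,
and the feature list remains a caller-supplied argument with no hidden
filtering.

Subtype **signature proteins** are one-vs-rest rank-sum p < 0.05 with
median-ratio FC > 2 (raw p, per the signature convention), optionally capped
at the top n (200 for cross-cohort projection) by ascending p with FC as the
tie-break. **Concordance** between two labelings is the Pearson chi-square
(no continuity correction) plus, per cluster of the first labeling, the
percentage of members in its modal cluster of the second, rounded half away
from zero — at zero decimals this reproduces printed values like 15/23 → 65%
and 27/28 → 96%; a `digits` argument covers one-decimal reporting
(2212/2512 → 88.1%).

## LPS classifier

For two classes, features are z-scored on the training cohort, weighted by
their two-sample t-statistic, and summed into a linear predictor score
(LPS). A Gaussian (MLE mean and sd) is fitted to the LPS within each class;
priors are uniform because the predictor targets external cohorts of
unknown composition. The posterior for class 1 is π₁φ₁/(π₁φ₁ + π₂φ₂); calls
require posterior ≥ 0.75 and `unclassified` is a first-class outcome, with a
`strict` argmax mode behind a flag. New cohorts are standardized with their
*own* feature means/sds (per-cohort z-scores) by default — the convention
implied by validating on an external cohort — with `standardize = "training"`
available. With equal class sds the posterior is the logistic
σ(Δμ·(LPS − μ̄)/σ²), which the tests verify against direct density
evaluation.

## Immune scoring

`ssgsea_score()` ranks one sample's features by descending expression (ties
broken by original order, which leaves scores invariant to permuting tied
out-of-set genes) and sums the difference between the rank-weighted in-set
ECDF (weights rank^α, α = 0.25) and the unweighted out-of-set ECDF,
normalized by the number of out-of-set genes. The normalization constant is
irrelevant to every downstream use (ranks, ratios, clustering inputs); with
α = 0 the score is purely rank-based and invariant to monotone transforms.
Sets need ≥ 10 quantified genes by default. `cell_scores()` averages
immune-category and stroma-category signature scores into `immune_score` and
`stroma_score`; `microenvironment_score` is their sum by definition. This
engine is deliberately *not* a reimplementation of any curated 64-signature
compendium with spillover compensation: its validity surface is recovery of
planted cell-type weight profiles, never numeric parity with published
compendium scores. The Th1/Th2 ratio is (Th1 + ε)/(Th2 + ε); enrichment
scores are signed, so analyses that need strictly positive denominators pass
a unit stabilizer, and ε = 0 remains the default with undefined ratios
flagged rather than silently patched. Published Th1/Th2 comparisons use
p < 0.1/FC > 1.2 in one figure and 0.05/2 elsewhere; both remain parameters.

## Cell cycle

Module scores follow the binned-control construction: features are binned
into 24 equal-occupancy bins by average expression; each module gene draws
100 control genes (with replacement) from its bin; the score is
mean(module) − mean(controls) per sample, exactly invariant to adding a
constant everywhere. Phases: S iff s > g2m and s > 0; G2M iff g2m ≥ s and
g2m > 0; else G1 ("neither score positive" is G1). The S/G2M gene lists are
inputs (GMT); the synthetic signatures ship 15 genes each.

## Clinical statistics

Kaplan–Meier estimates (product-limit with Greenwood variance), the log-rank
test (O−E chi-square with hypergeometric variance, df = groups − 1) and Cox
proportional hazards (Efron ties — the common default; the source
publications do not state one) delegate to the survival package and are
cross-checked in the tests against independently coded oracles (hand
product-limit, O/E/V tally, a one-covariate Newton–Raphson partial
likelihood). `optimal_cutpoint()` scans candidate cutpoints between the 10th
and 90th marker percentiles, scores each by the standardized two-group
log-rank statistic, and returns the argmax with ties broken toward the
median. The selection-bias-corrected p-value of the maximal statistic is out
of scope; an optional permutation reference reports how often permuted
markers reach the observed maximum, and is labelled a reference, not a
corrected p. Mutation cis/trans screens run Fisher's exact test on
mutated/wild-type × up/not-up tables (the dichotomization is the caller's,
e.g. above the cohort median), BH-corrected across proteins within each
mutated gene; cis means the protein symbol equals the mutated gene.

## The synthetic cohort generator

`generate_cohort()` draws per-feature Gaussian log2 baselines (proteome
N(20, 1.5), phospho N(18, 1.5), TF N(15, 1.5)), per-feature noise σ = 0.5,
and per-sample offsets (σ = 0.15, removed exactly by normalization), then
plants, in deterministic reserved feature blocks:

* tumor/NAT effects per histology at ±2.8/±2.0/±1.5 log2 (reference effect
  2.0; the 1.4× and 0.75× arms create the histology-dominant patterns the
  six-group partition classifies);
* K = 3 DGC and K = 2 IGC subtypes (balanced sizes, randomly assigned
  within histology) with 60 signature proteins each at +2.0 in the
  subtype's tumors;
* three active kinases (shifts +2, −2, +1.5 on 25 substrate sites each, in
  a designated subtype's tumors) and a patient-level latent coupling two of
  them to TF phospho-sites — patient-level so it drives cross-sample
  correlation without perturbing paired fold changes;
* one master TF per subtype: activity +1 in all tumors of its histology
  plus +2 in its own subtype, 30 target-gene proteins at +1.5 in that
  subtype, against ten tumor-up decoy TFs that must fail nomination;
* mutation effects (cis −1.5 on the gene's own protein, trans +1.2 on 20
  targets), cell-type weight profiles with Th1- and Th2-skewed patient
  groups, and cell-cycle phase shifts (+1.2);
* exponential DFS/OS with subtype hazard multipliers (DGC 1/2/4,
  IGC 1/2.5) and uniform censoring on [0, 60] months.

Missingness is a decreasing logistic function of log2 abundance (midpoint at
the layer's 10th percentile, unit scale) — the MNAR structure that justifies
minimum imputation. Cohort sizes default to 40 DGC + 50 IGC patients and
2,000/3,000/150 features: large enough for clustering and survival contrasts,
small enough that the full test battery runs in about a minute.
`effect_scale = 0` yields a null cohort (all planted effects zero, hazard
multipliers 1) for calibration checks. Determinism: one Mersenne-Twister
stream consumed in a fixed order, so equal seeds give bitwise-equal cohorts.

Two generator conventions deserve emphasis. Planted feature *identities* are
fixed reserved index blocks — only noise, assignment, missingness, mutations
and survival are random — so cross-cohort experiments (training the LPS
classifier on one cohort, validating on another) are well defined. And
single-feature planted anchors (master TFs, the cis/trans mutation genes,
the coupled TF phospho-sites) are placed at fixed moderately-high baselines:
a planted master TF below the detection filter would be unrecoverable by
construction, making the planted truth incoherent with its own definition.
Block-planted effects keep fully random baselines, so detection-limit
censoring of the truth is still exercised (and recovery metrics are
evaluated over the detectable universe).

What the generator does **not** emulate: peptide-level quantification,
batch or instrument drift, correlated feature blocks beyond the planted
structure, realistic mutation co-occurrence, competing risks, or the heavy
right tail of real iBAQ distributions. Passing recovery tests therefore
demonstrates that the pipeline's logic is correct and calibrated under the
stated model — not that its thresholds are optimal for any particular real
cohort.

## Numerical conventions collected

* Quartiles: linear interpolation (type 7), everywhere.
* Strict inequalities at published thresholds: FC > 2 (a feature at exactly
  2 is not called), TFRE ratio > 4.
* Two-sided rank-test p = 2·min(tails), capped at 1; permutation p with
  add-one correction.
* Subset percentages round half away from zero (65.2 → 65, 12.5 → 13).
* Fold changes require strictly positive (imputed) values; zero denominators
  are an error, never an Inf.
* Exact-test boundaries: signed-rank exact at n ≤ 25 untied / n ≤ 14 tied;
  rank-sum exact at min(n) ≤ 10 untied; Spearman exact at n ≤ 9 untied.
* Degenerate inputs fail loudly (all-missing columns, constant covariates,
  single-column quantile normalization warns and returns identity) rather
  than returning silently patched values; the one deliberate exception is
  the Fisher test on a degenerate margin, which returns p = 1 with a flag,
  because mutation screens routinely contain all-wild-type genes.

## Known limitations

* The six-group dominance rule and the TF-subtype fold-change bar (1.5) are
  declared conventions, validated structurally but not against restricted
  patient data.
* The cutpoint search reports the uncorrected maximally selected statistic;
  treat its significance via the permutation reference only.
* ssGSEA scores are engine-specific up to a normalization constant; only
  ranks, ratios and recovery behavior are meaningful across engines.
* Consensus clustering with feature subsampling slightly departs from the
  commonly cited tool; with feature subsampling disabled
  (`feature_fraction = 1`) the construction matches it, but the ambiguity
  flag loses its null calibration.
* Whether imputation should use the per-layer or per-sample minimum is
  genuinely ambiguous in the field; the per-layer convention is implemented
  and the choice is isolated in `impute_min()`.
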