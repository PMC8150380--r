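---
title: "Cross-species prediction of essential genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species prediction of essential genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A gene is *essential* when its loss of function is lethal or blocks
development. Genome-scale screens that establish essentiality directly
(RNAi knock-down, deletion collections) exist for only a handful of model
organisms, so an attractive alternative is to *predict* essentiality from
features that are cheap to compute for any sequenced genome — sequence
composition, gene architecture, conservation (ortholog-group size),
expression breadth (number of cells expressing the gene), ribosome
profiling, histone-methylation peak overlaps (H3K4me3, H3K27me3), variant
effects, protein-interaction-network centralities, and chromosomal
position. Within a single species such classifiers work well; the harder
question, and the one this package operationalises, is whether a
classifier trained on one species can rank the genes of *another* species
— training on a worm-like species A and scoring a fly-like species B —
using only features that are comparable between the two.

`crossess` implements that protocol end to end: per-gene feature
derivation from standard file formats, harmonization of two species'
feature tables, consensus feature selection, within-species evaluation
under strong class imbalance, cross-species transfer prediction, ranked-list
validation against an independent lethal-phenotype database, and
chromosome-level landscapes of the predicted probabilities. Because the
multi-omics tables that motivated the protocol are large external
downloads, the package ships a synthetic twin-species generator with
planted, partially shared signal so that every stage is exercised and
tested offline.

## Labels: extremes only, imbalance kept

Reference essentiality probabilities per gene (produced by earlier
within-species predictors or screens) are thresholded: probability > 0.7
labels a gene *essential*, probability < 0.1 *non-essential*, everything
between is *unlabeled*. Only the two extreme classes are used for
training; unlabeled genes are still scored at prediction time. The
resulting training sets are heavily imbalanced (a few percent essential).
We deliberately neither oversample (SMOTE-style synthesis can inject bias)
nor undersample (it discards majority-class information): imbalance is the
reality of the biological problem, and threshold-independent metrics
(ROC-AUC and PR-AUC) are used throughout. PR-AUC is the metric to watch
under imbalance — a random ranker's PR-AUC equals the class prevalence,
not 0.5.

## Consensus feature selection

Two selectors with different inductive biases run on the standardized
labeled data and their selections are intersected:

* **Elastic net** — penalized logistic regression over a grid of mixing
  parameters `alpha` in {0.1, ..., 0.9} with 5-fold cross-validation; the
  selection is the nonzero support at the deviance-minimising
  `(alpha, lambda)`. The elastic net is liberal: with thousands of
  training genes it reliably keeps every real feature but admits dozens of
  noise features at `lambda.min`.
* **Ensemble sparse PLS** — 100 stratified 80% subsamples; on each, a
  sparse partial-least-squares fit for the centered ±1 response: per
  component the covariance vector `Z = X'y` is soft-thresholded at
  `eta = 0.7` of its largest absolute entry, normalized, and both `X` and
  `y` are deflated by the component score. A feature is selected on a
  subsample when it carries nonzero weight in any component; the ensemble
  keeps features selected in at least 50% of subsamples. This selector is
  conservative: noise features essentially never reach half of the maximal
  covariance.

The intersection inherits the elastic net's recall and the ensemble's
specificity. One parameter deserves comment: the number of SPLS
components `K`. Because the soft threshold is *relative to the largest*
covariance entry, a single component keeps only the dominant tier of
features; when true effect sizes are heterogeneous (they always are —
the generator jitters coefficients per species), weaker real features sit
below `0.7 * max|Z|` and are recovered only after the dominant directions
have been deflated away. With `K = 2` we measured 75% recall of planted
features on the default generator; `K = 4` recovers all of them at
essentially unchanged false-selection rates, so `K = 4` is the default.
All selection hyperparameters are exposed in `select_features()`.

Feature *importance* across heterogeneous model families uses one uniform
contract — permutation importance (drop in held-out ROC-AUC when a column
is shuffled), rescaled so each model's top feature scores 100 — and
features are ranked by the exact median across families
(`median_importance()`), ties broken lexicographically.

## Model families and evaluation protocols

Six families sit behind the single `ess_fit()` surface: two
gradient-boosted-tree parameterizations (classic shallow-tree/small-step
"GBM" and a regularized, column-subsampling "XGB"), penalized-free
logistic regression (GLM), random forest (RF), a radial-kernel SVM, and a
single-hidden-layer neural network (NN). The learners are established
library implementations; the protocol around them — stratified inner
cross-validated grid search maximizing ROC-AUC, deterministic seeding,
the strict feature-order contract at prediction time — is the package's.
Default grids are small (2–3 configurations per family) to keep the
resampling protocols desk-scale; they are arguments, not constants.

Two within-species protocols:

* `subsample_grid()` — stratified splits at training fractions 0.1–0.9
  (10% increments), **feature selection inside each training split** so no
  test information leaks into the selection, all families fit per split,
  metrics on the held-out fraction, and a permutation-null background
  model per split as the negative control. The null permutes the labels
  across the *whole* labeled set and then runs the identical
  split/fit/evaluate path, so its ROC-AUC is centred at 0.5 by
  construction; permuting only the training labels while scoring against
  the real test labels is *not* centred at 0.5 on this kind of data —
  essential genes sit in the tails of the informative features, and a
  noise-fit model scores such atypical genes systematically lower,
  pushing that variant of the null below chance.
  The number of repeats per fraction defaults to 5 and is configurable;
  whether the original protocol resampled once or repeatedly per fraction
  is not documented, so the repeat count is exposed rather than fixed.
* `bootstrap_evaluate()` — B stratified 90/10 train/test resamples (the
  protocol-scale value is B = 1000; tests and the acceptance script use
  reduced B) on a *fixed* feature set, hyperparameters tuned once on the
  full labeled set and reused per replicate, reporting per-replicate
  ROC-AUC/PR-AUC with 5–95% intervals.

As an overfitting control, `nonredundant_filter()` reduces the gene set to
cluster centroids: greedy clustering in descending sequence-length order,
joining a centroid when global-alignment identity (match +1, mismatch −1,
linear gap −2; identity = matches / full alignment length, terminal gaps
included) exceeds 25%. A shared-4-mer count prescreen decides which
centroid alignments are worth computing — the same design as
UCLUST/USEARCH greedy clustering — which keeps the control tractable at a
few thousand proteins. Metrics on the filtered set should stay inside the
unfiltered bootstrap's 5–95% interval; they do on the default generator.

## Cross-species transfer and validation

`harmonize()` makes the two species comparable: feature-name
intersection, removal of features constant in either species, then
z-scoring *within* each species. Per-species standardization is the
simplest contract under which a model trained on one species' features can
meaningfully score the other's: each feature enters in units of
within-species standard deviations. `cross_predict()` then fits the
transfer family (XGB by default, the strongest family in our evaluations)
on all labeled genes of the training species restricted to the consensus
features, scores every target-species gene, and returns a
deterministically ordered ranking (ties broken by gene id).

Validation deliberately avoids the target species' training labels.
Rankings are compared to reference probabilities by tie-aware Spearman
correlation, and walked against an independent lethal-phenotype database:
`cumulative_lethal_ratio()` reports, at every prefix of the ranking, the
fraction of database-covered genes annotated lethal, in both directions
(top-down and bottom-up). Genes absent from the database are excluded
from numerator *and* denominator — counting them as non-lethal would
conflate missingness with viability; the coverage at each prefix is
reported alongside. Both directions necessarily converge to the overall
lethal prevalence among covered genes; a good ranking starts high
top-down and low bottom-up.

`probability_track()` and `heterochromatin_summary()` reproduce the
landscape view: per-gene BedGraph records (0-based half-open spans),
binned gene densities, and an inside/outside-heterochromatin comparison of
probabilities by gene midpoint (rank-sum test, normal approximation,
"high probability" meaning > 0.5). Midpoint membership — not overlap
fraction — defines inside/outside, since the landscape plots point
coordinates.

## The synthetic twin-species generator

`generate_world()` emulates exactly the statistical structure the
protocol needs and nothing more:

* Two species share `n_shared_features` named feature columns (default
  120) of which `n_informative` (default 20) carry signal; each species
  additionally has private noise columns, and the derived sequence /
  annotation features computed by `featurize()` join the shared pool as
  realistic uninformative columns.
* Latent essentiality score = shared informative features × species
  coefficients + Gaussian noise (`noise_sd = 0.5`). Species coefficients
  are the shared base coefficients (magnitude `effect_size = 1`, random
  signs) perturbed **multiplicatively** by `1 + N(0, coef_jitter_sd)`,
  default jitter 0.3. Multiplicative jitter keeps two limits honest: with
  `effect_size = 0` the world is a true null (features carry no signal at
  all), and as the jitter grows the two species' coefficient vectors
  decorrelate as `1/(1 + sd^2)`, so transfer degrades to chance — both
  limits are tested.
* Reference probabilities are a monotone rank-based rescaling of the
  latent score placing the top `essential_prevalence` fraction (default
  5%, within the 3–5% range typical of metazoan essentiality screens)
  strictly above 0.7 and the bottom 85% strictly below 0.1, so the fixed
  label thresholds always carve out non-empty classes; true essential
  flags are the top fraction by latent score.
* Genes are placed uniformly on five 20-Mb chromosomes; each chromosome
  carries heterochromatic blocks at both ends (20% of its length in
  total, mimicking heterochromatic arms). An essential gene first placed
  inside heterochromatin is re-drawn into euchromatin with probability
  `1 − het_depletion` (default depletion multiplier 0.2). A side effect
  worth noting: this makes *distance from the chromosome centre* a
  genuinely informative derived feature, as in real genomes.
* Proteins are random sequences of 80–200 residues with 5% of genes
  generated as mutated copies (~90% identity) of non-duplicated genes, so
  the redundancy filter has planted work to do.
* The phenotype database covers each gene with probability 0.6 and
  annotates lethality at 0.9 for essential and 0.02 for non-essential
  genes. The false-lethal rate 0.02 reflects the low but nonzero
  off-target/annotation error of large RNAi screen collections; it keeps
  the bottom of a good ranking clearly below half the overall lethal
  prevalence, which is the qualitative shape the validation curves are
  tested against.

One RNG stream per world, so a configuration is bit-reproducible from its
seed. What the generator does *not* emulate: realistic sequence
evolution, raw reads or peak calling (peaks, alignments and expression
arrive as precomputed columns or files), correlated feature blocks, and
feature-specific distributions (everything informative is Gaussian).
Passing tests on this world therefore demonstrate that the *protocol* is
implemented correctly and recovers planted structure — not that any
particular real genome will reach the same metric values.

## Numerical and interface choices

* Coordinates: 1-based inclusive internally (GFF3 native); BED input is
  0-based half-open and converted on read; BedGraph output converts back.
  The abutting-interval cases are pinned by tests in both directions.
* ROC-AUC is the Mann–Whitney statistic computed from average ranks, so
  ties count ½ exactly; PR-AUC is average precision with tied scores
  grouped at one threshold. Both are checked against brute-force oracles
  to 1e-12.
* Missing feature values are imputed by the within-species per-feature
  median, with a per-feature imputation log attached to the table; how
  the original multi-omics tables encoded missingness is not documented
  anywhere, so imputation is explicit and inspectable rather than silent.
* EST BLAST hits count at `evalue <= 1e-10` — the boundary value counts.
* A gene in several ortholog groups receives its largest group's size
  (logged); betweenness is reported unnormalized (only relative order
  matters after standardization); closeness is per-component
  `(n_reachable − 1)/Σd`, zero for isolates.
* Degenerate inputs fail loudly and early: single-class training labels,
  empty feature intersections, `hi <= lo` thresholds, empty phenotype
  databases, eta outside `[0, 1)`, `K` beyond the rank bound.
* Problem sizes in the tests: the study-scale world is 3000 genes per
  species (about 2800 labeled after thresholding); the subsample grid and
  learning-curve properties run on a 700-gene world; bootstrap checks use
  B = 50 and the demonstration pipeline B = 10. These sizes were chosen
  so the planted-signal properties hold with comfortable margins while a
  full check run stays in the minutes range on a laptop.
* The pipeline master seed fans out to per-stage seeds by stage-name
  hashing, so inserting a new stage never shifts another stage's stream;
  `run_all()` writes a manifest with the configuration echo, stage seeds
  and output checksums, and reruns are byte-identical.

## Known limitations

Real cross-species feature tables need curation the package does not
attempt (unit harmonization beyond z-scoring, ortholog-aware feature
mapping, batch effects between data sources). The SVM and NN backends are
not bit-reproducible across platforms (their internal optimizers do not
expose full seeding); the deterministic contract covers GLM, GBM, XGB and
RF. The redundancy filter's k-mer prescreen can in principle miss a
>25%-identity pair with no shared 4-mers; such pairs are essentially
impossible among real homologs of the lengths handled here. GO/pathway
enrichment of predicted essential genes is out of scope.
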