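---
title: "Models and methods behind tcemm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tcemm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tcemm` studies whether *individual* T-cell molecular mismatches (TcEMMs)
between a kidney donor's and recipient's HLA proteins predict
death-censored graft failure (DCGF), as opposed to the usual practice of
summarizing all mismatches into a single PIRCHE-II load. This vignette is
the package's own account of the models it implements, the parameters that
matter, what the synthetic data generator does and does not emulate, and
the numerical and design choices that were genuinely open.

## 1. The mismatch derivation engine

For each pair, the engine enumerates every 15-amino-acid window of every
donor HLA protein (both haplotypes at HLA-A, -B, -C, -DRB1, -DQB1) and the
seven 9-mer binding cores inside each 15-mer. A core is a TcEMM iff it
(i) occurs in a donor protein, (ii) is absent from the recipient's own
HLA-derived 9-mer repertoire, and (iii) is predicted to be presented by at
least one recipient DRB1 allele. Because the union of the cores of all
15-mers of a protein equals the set of all 9-mer windows of that protein,
the implementation enumerates 9-mer windows directly; `enumerate_15mers()`
and `enumerate_cores()` expose the constituent operations and the test
suite checks the equivalence against a brute-force triple loop.

Design choices that were open, and how they were resolved:

* **Self-repertoire filtering.** The self repertoire is a pure sequence
  set: any 9-mer occurring anywhere in the recipient's five-locus HLA
  peptidome excludes the matching donor core, with *no* binding filter.
  The alternative reading (subtract only self cores that themselves bind
  recipient DRB1) is available as
  `self_repertoire_binding_filtered = TRUE`. The default is the stricter,
  sequence-level subtraction; it is the more conservative definition of
  "foreign".
* **Binding is assessed at the core level only.** A 15-mer contributes a
  TcEMM exactly when one of its cores passes the self and presentation
  filters; no separate 15-mer-level binding test is applied.
* **Population identity of a TcEMM is the 9-mer string alone**, not the
  (core, presenting allele) combination — mismatch counts across pairs
  with different DRB1 types must refer to the same object.
* **Score aggregation.** The default per-pair score is the number of
  distinct presented non-self cores; `pirche_score(set, "core_presenter")`
  counts (core × presenting allele) combinations instead, since both
  conventions circulate.
* **Coordinates** are 0-based half-open internally and 1-based in
  human-readable output.

### The presentation model

Trained MHC class II binding predictors are proprietary or heavyweight;
`tcemm` instead ships a deterministic pluggable stand-in.
`default_presentation_model()` assigns every DRB1 allele a 9 × 20
position-weight matrix drawn reproducibly from a hash of the allele name
and a model seed; a core's score is the sum of its per-position weights,
and the per-allele threshold is the empirical `(1 - q_bind)` quantile of
scores over a shared pool of 100,000 seeded random cores. Consequences:

* a fraction `q_bind` of random cores is presented (the test suite checks
  the calibration to ±0.01);
* calls are a pure deterministic function of (core, allele name, seed), so
  registry *version* differences isolate sequence changes — exactly how an
  external predictor's per-allele models persist across database releases;
* `q_bind` (default 0.20) is the single knob controlling mismatch density.
  The default keeps synthetic per-pair scores in the tens, the order of
  magnitude seen in allele-level registry analyses, while leaving most
  donor cores unpresented.

Anything implementing `score`/`threshold`/`presented` can replace it, so
real predictions can be plugged in without touching the pipeline.

## 2. The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which every statistical property of the pipeline is validated.

* **Genotypes.** Individuals are two independent draws from a pool of
  five-locus haplotypes with Dirichlet(1) frequencies; donors and
  recipients are independent. Sampling whole haplotypes induces linkage
  disequilibrium, and therefore correlated TcEMM columns — the central
  nuisance structure of the real analysis (the test suite verifies that
  cores private to one haplotype have positively correlated columns).
* **Covariates** follow the covariate schema of registry analyses of DCGF:
  recipient age/sex/time on dialysis/insurance, donor age/sex/type,
  transplant era, induction, calcineurin-inhibitor type, steroid use,
  cold-ischemia time, donor:recipient weight ratio. Values are drawn from
  truncated normals / exponentials / multinomials with roughly realistic
  ranges; they are complete by construction (no missingness, hence no
  imputation step). Default covariate effects are modest (|β| ≤ 0.3 on
  the log-time scale) so that planted mismatch signal dominates.
* **Survival.** Latent log failure time `log T* = mu + x'beta + sigma W`
  with standard minimum-Gumbel `W` (a Weibull AFT model); observed time is
  the minimum of `T*`, an independent exponential censoring time (rate
  0.02/year, standing in for death) and administrative censoring at 15
  years. The intercept `mu` is tuned by bisection — on fixed random draws,
  so the event fraction is monotone in `mu` — to a target death-censored
  event fraction of 0.17, the rate characteristic of registry-scale DCGF
  cohorts. `sigma` defaults to 0.9.
* **Planted effects** are per-core log-time coefficients (negative =
  harmful); a planted core with coefficient β multiplies carriers' median
  graft survival by `e^beta` and has true hazard ratio
  `exp(-beta/sigma)`. Plantable cores must be realizable from the pool;
  `generate_cohort()` validates them against the derived matrix and
  `choose_planted_cores()` picks cores in a support range.

What the generator does *not* emulate: real registry marginal covariate
distributions, informative censoring, competing risks, missing data,
serology-to-allele imputation error, and the true IMGT/HLA allele
sequences and frequencies. Passing tests therefore demonstrate that the
*pipeline machinery* is correct and calibrated under a faithful
data-generating model — not that any particular real-world mismatch is
harmful.

## 3. Per-mismatch screening

Each TcEMM with support ≥ `min_support` (default 50 pairs, inclusive)
enters one multivariable Weibull AFT fit with all clinical covariates and
recipient-DRB1 indicator columns (one per allele, most frequent allele as
reference). The hazard ratio is `HR = exp(-beta/sigma)` with a delta-method
CI on `log HR` using the joint (β, log σ) covariance; p-values across all
converged screened fits are Benjamini–Hochberg adjusted (non-converged
fits are excluded from the multiplicity count and flagged). The AFT family
is used because the proportional-hazards assumption demonstrably fails for
some binary mismatch exposures; `ph_test()` (scaled Schoenfeld residuals)
and `aic_compare()` document this per mismatch. The Cox entry in
`aic_compare()` uses the partial likelihood and is flagged as heuristic:
a partial likelihood is not strictly commensurable with full parametric
likelihoods, but the comparison mirrors field practice.

The cohort-level mismatch-load model `score_association()` uses
`log(score + 1)` as exposure — the +1 keeps zero-mismatch pairs defined
and maps them to exposure 0 — univariably and adjusted for all covariates.

## 4. Selection and post-selection inference

`cv_select_lambda()` fits an L1-penalized Cox model (glmnet; Breslow ties)
with TcEMM columns penalized and clinical/DRB1 columns unpenalized, over
100 log-spaced penalties down to 1% of the all-zero penalty, choosing the
penalty minimizing 10-fold cross-validated partial-likelihood deviance
with event-stratified, seed-deterministic folds. Binary TcEMM columns are
deliberately *not* standardized — standardizing binary indicators would
penalize rare mismatches less per carrier — while continuous clinical
covariates are centered and scaled (they are unpenalized, so this affects
only conditioning). A hand-written Breslow-gradient KKT check
(`kkt_check()`) verifies stationarity of every fitted solution, using
glmnet's convention of renormalizing penalty factors to sum to the number
of columns.

Post-selection inference defaults to **sample splitting**: selection is
(re-)run on one event-stratified half and an unpenalized Cox refit on the
held-out half yields Wald CIs that are valid conditional on the selection.
The polyhedral fixed-penalty approach used by dedicated
selective-inference tooling was deliberately not replicated: splitting is
assumption-light, transparent, and its validity is directly testable (the
suite checks ~5% type-I error on nulls forced into the selection). The
cost is a power loss from halving; `method = "naive"` (full-data refit,
with a validity warning) is available for comparison. A warning is issued
when the selected set exceeds one tenth of the held-out events.

One joint Lasso is fit over all TcEMMs; HLA class of origin (I, II, or
both) is used only for reporting counts, not to split the model.

## 5. Co-expression profiles

Pairwise Pearson correlation of the binary columns (the phi coefficient;
constant columns are dropped) is soft-thresholded as `a = |r|^beta` with
β = 4, chosen because it reconciles the canonical paired cutoffs of this
analysis: `0.74^4 ≈ 0.2998 ≈ 0.3`, so an adjacency threshold of 0.3 is the
same criterion as a correlation threshold of 0.74. Adjacency is unsigned,
consistent with that pairing. Profiles are the connected components (size
≥ 2) of the thresholded graph; everything else is a singleton. Components
— not WGCNA modules with topological overlap and tree cutting — are used
because the quantity of interest is simply "which mismatches travel
together above the cutoff". The graph is exported to GraphML with screen/
selection status as node attributes.

## 6. Positional composition comparison

Selected vs unselected cores are compared position-by-position via
Jensen–Shannon divergence (base-2, bounded by 1 bit, symmetric) between
pseudocounted position frequency matrices (Laplace pseudocount 0.5 avoids
zero-frequency instabilities), with a group-label permutation null, the
add-one p-value estimator `p = (1 + #{perm ≥ obs}) / (1 + n_perm)`, and BH
adjustment across the nine positions. JS divergence replaces the exact
internal statistic of dedicated logo-difference tooling; since the
scientific use is hypothesis testing against a permutation null (and the
reference analysis reports a null finding), the choice of a bounded
symmetric divergence is immaterial to validity and is tested for type-I
error and power directly. The default comparison is Lasso-selected vs
unselected; passing the post-selection-significant set instead gives the
alternative contrast.

## 7. Registry version sensitivity

`diff_versions()` re-derives every pair's TcEMM set under two registry
versions with the *same* presentation model (weights are keyed by allele
name + seed, not sequence) and reports the population-level symmetric
difference and the affected pairs. Pairs not carrying an edited allele can
never be affected, which the tests exploit with constructed single-residue
edits.

## 8. Numerical choices, degenerate inputs, problem sizes

* Registry names are two-field (`LOCUS*gg:pp`); higher fields/suffixes are
  rejected. Sequences must be ≥ 15 residues (else no 15-mer exists) over
  the 20-letter alphabet.
* Proteins shorter than 15 yield an empty window list with a warning, not
  an error; `enumerate_cores()` on a non-15-mer is an error.
* Cores carried by *every* pair (support = n) are included by the support
  filter but flagged non-converged (a constant column is not estimable);
  constant columns are likewise dropped before correlation.
* All-censored outcomes, empty haplotype pools, misaligned pair ids,
  unresolvable alleles, out-of-range p-values and unknown annotation keys
  are hard errors naming the offending object.
* Every stochastic step takes an explicit seed; child seeds are derived by
  a fixed integer recurrence and stay below 2^31. `withr::with_seed`
  guarantees no leakage into the caller's RNG state.
* Bisection for `mu` runs on fixed draws to machine-level reproducibility;
  tolerance 0.002 on the event fraction, 60 iterations maximum.
* Validation problem sizes: engine-vs-oracle equivalence on 50 random
  pairs; AFT bias/coverage on 200 replicates of n = 5,000; FDR control on
  50 replicates of 200 null mismatches (n = 400); selection sensitivity on
  20 cohorts of n = 3,000 with 10 planted among 300; full-pipeline
  determinism at n = 2,000. These sizes were chosen as the smallest at
  which the corresponding asymptotic or calibration statements are
  comfortably testable.

## 9. Known limitations

* The presentation model is a calibrated random surrogate: it preserves
  the combinatorial and statistical structure of the problem but has no
  biochemical content; absolute mismatch identities are meaningless
  outside a given (registry, seed) pair.
* Loci DRB3/4/5, DQA1, DPA1 and DPB1 are not modelled, and recipient
  presentation is restricted to DRB1 — both restrictions mirror the
  analytical setting this package reproduces.
* Partial/unsequenced alleles, serology-level typing and nearest-allele
  substitution are out of scope: the registry is assumed complete at the
  protein level.
* Synthetic cohorts are far smaller than national registries; rare-
  mismatch behaviour (single-carrier TcEMMs) is present but power
  statements at registry scale do not transfer.
* The Cox-vs-AFT AIC comparison is heuristic by construction (partial vs
  full likelihood) and is labelled as such in the output.
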