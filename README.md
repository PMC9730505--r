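# tcemm

Dissecting individual T-cell molecular mismatches in kidney transplantation.

Cumulative HLA molecular-mismatch scores — eplet loads on the B-cell side,
the PIRCHE-II score on the T-cell side — predict transplant outcomes, but a
single summed score hides which *individual* mismatched peptides carry the
risk. `tcemm` implements, on synthetic registry-scale cohorts, the full
analytical pipeline for answering that question: it derives each donor:
recipient pair's T-cell molecular mismatches (TcEMMs), screens every TcEMM
for association with death-censored graft failure (DCGF), selects the most
predictive subset by penalized regression with valid post-selection
inference, profiles co-expressed mismatches as a correlation network, and
quantifies how allele-registry updates perturb the calls.

The package is aimed at transplant immunogenetics and biostatistics groups
who want to prototype, validate, or power such analyses without access to
restricted registry data: every input can be simulated with controlled
ground truth.

## The science in brief

**TcEMM derivation (peptidome differencing).** For a donor:recipient pair
typed at HLA-A, -B, -C, -DRB1 and -DQB1, every 15-mer peptide of every
donor HLA protein is enumerated, along with its seven 9-amino-acid binding
cores. A core *c* is a TcEMM of the pair iff

1. *c* occurs in a donor HLA protein,
2. *c* is absent from the recipient's own HLA-derived 9-mer repertoire, and
3. *c* is predicted to be presented by at least one recipient HLA-DRB1
   allele.

The per-pair PIRCHE-II-style score is the number of such distinct cores.
Presentation is delegated to a pluggable model; the default is a
deterministic per-allele position-weight matrix calibrated so that a
configurable fraction `q_bind` of random cores is called presented.

**Survival screening.** Each TcEMM (binary present/absent, modelled across
pairs as a *TcEMM expression matrix*) with support ≥ 50 pairs enters a
multivariable Weibull accelerated failure time (AFT) model of time to DCGF,
adjusted for clinical covariates and the recipient's DRB1 alleles:

    log T = mu + beta * TcEMM + gamma' x + sigma * W,   W ~ min-Gumbel

with the hazard ratio recovered as `HR = exp(-beta / sigma)` and p-values
corrected by Benjamini–Hochberg. AFT is used instead of Cox because the
proportional-hazards assumption fails for some mismatches; `aic_compare()`
reproduces that model-family comparison.

**Selection and inference.** A Lasso-penalized Cox model (clinical and DRB1
columns unpenalized, 10-fold cross-validated penalty) selects a sparse
TcEMM subset; sample-splitting post-selection inference then yields valid
confidence intervals for the selected mismatches.

**Networks, logos, registry versions.** Co-expressed TcEMMs (driven by HLA
linkage disequilibrium) are profiled as connected components of the graph
with adjacency `|r|^4 >= 0.3` (equivalently `|r| >= 0.3^(1/4) = 0.74`);
positional amino-acid composition of selected vs unselected cores is
compared by per-position Jensen–Shannon divergence with a permutation
test; and `diff_versions()` quantifies how many TcEMM calls change between
two allele-registry releases.

## Worked example

```r
library(tcemm)

registry <- synthesize_registry(4, 10, seed = 7)
model    <- default_presentation_model(registry, q_bind = 0.2, seed = 5)
pool     <- sample_haplotype_pool(registry, 10, seed = 3)

dry <- generate_cohort(registry, pool, model, cohort_config(600, seed = 11))
planted <- setNames(rep(-0.5, 3), choose_planted_cores(dry$matrix, 3, c(100, 500)))
gen <- generate_cohort(registry, pool, model,
                       cohort_config(600, seed = 11, planted_effects = planted),
                       precomputed = dry[c("pairs", "matrix")])

scr <- screen_tcemm(gen$cohort, gen$matrix, min_support = 50)
scr[scr$tcemm %in% names(planted), c("tcemm", "support", "hr", "p", "q")]
#>         tcemm support       hr            p           q
#> 34  CFHSVQIQV     148 1.641238 4.463473e-02 0.201118888
#> 94  EKLHALTWC     157 2.261631 3.334248e-04 0.011050915
#> 254 MNWPHYMRE     146 2.450470 7.218403e-05 0.006677023
```

Three harmful mismatches were planted with AFT coefficient −0.5 (shorter
graft survival); at 600 pairs the screen recovers all three with hazard
ratios above 1, two of them surviving FDR correction — exactly the
behaviour expected at this sample size. `print(gen$matrix)` summarizes the
mismatch matrix, and

```r
run_all(run_config(out_dir = "out", seed = 42, n_pairs = 2000))
```

executes the whole pipeline (screen → Lasso selection → post-selection
inference → co-expression profiles → positional comparison), writing every
artifact (TSV/JSON/GraphML) plus an MD5 checksum manifest.

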