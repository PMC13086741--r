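---
title: "Methods: NB contrasts, permutation FDR and valence gene classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NB contrasts, permutation FDR and valence gene classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valenceDE)
```

## The analysis problem

valenceDE analyses bulk RNA-seq experiments in which sexually immature
female butterflies are exposed to one of three social-training treatments —
no exposure (naive), exposure to an attractive male (positive training) or
to an unattractive one (negative training) — and sensory or brain tissue is
sequenced immediately afterwards. The scientific questions are which genes
respond to either training context (valence-independent "learning" genes),
which respond in opposite directions under the two contexts
(valence-associated genes), and which are unique to one context. Each
tissue is analysed independently with a three-level treatment design of 10
replicates per treatment (30 libraries per tissue).

The pipeline has four computational stages: (1) per-gene
negative-binomial (NB) Wald contrasts, (2) an empirical significance
procedure built from treatment-label permutations, (3) rule-based gene
classification, and (4) reporting. A simulator with planted gene classes
provides ground-truthed inputs for every stage.

## The count model and differential testing

Counts for gene $i$ in sample $j$ are modelled as
$y_{ij} \sim \mathrm{NB}(\mu_{ij}, \alpha_i)$ with
$\mathrm{Var}(y_{ij}) = \mu_{ij} + \alpha_i \mu_{ij}^2$ and
$\log \mu_{ij} = \log s_j + \beta_{i,\mathrm{treat}(j)}$,
i.e. a log-link GLM `y ~ treatment` with the library-size factor $s_j$ as
an offset. The three Wald contrasts are positive-vs-naive,
negative-vs-naive and negative-vs-positive (label on the right is the
reference); by construction the third equals the difference of the first
two in the same fitted model.

* **Filtering.** Genes with a total count below 10 across all samples are
  removed before any model fitting. The retention summary reports the
  integer percentage with halves rounded away from zero.
* **Size factors** are classical median-of-ratios: the median over
  everywhere-positive genes of each sample's ratio to the gene's geometric
  mean, rescaled to geometric mean 1. When no gene is positive everywhere,
  an explicit `pseudo_reference` flag switches to geometric means over
  positive counts only; the default errors instead of silently changing
  estimators.
* **Dispersions** are per-gene method-of-moments estimates on normalized
  counts, $\hat\alpha_i = \max(0, (v_i - m_i)/m_i^2)$, shrunk halfway
  (weight `trend_weight = 0.5` by default) toward a fitted mean-dispersion
  trend $\alpha(\mu) = a_0 + a_1/\mu$ with non-negative coefficients. This
  is a deliberately simple, fully testable estimator rather than an
  empirical-Bayes MAP fit: its behaviour is validated by simulation
  (recovering generative dispersions within 25% at $n = 500$), and the
  permutation procedure below reuses the same dispersions for observed and
  null fits, which makes the final DEG calls largely insensitive to
  dispersion misestimation.
* **Fitting.** Because the design is a single factor, the likelihood
  separates by treatment group and each group log-mean is a concave 1-D
  problem. It is solved by damped Newton steps on the score
  $\sum_j (y_{ij}-\mu_{ij})/(1+\alpha_i\mu_{ij})$ (ridge $10^{-6}$ on the
  information, steps clipped to $\pm 5$, convergence $|\Delta\beta| <
  10^{-8}$, at most 100 iterations), vectorized across genes. Standard
  errors come from the observed information at the MLE, and p-values are
  two-sided against the standard normal, the usual Wald convention.
  Gene-group combinations with all-zero counts have no finite MLE; such
  genes are flagged non-converged, carry `NA` statistics and are never
  called DEGs. The solver is verified against brute-force likelihood
  maximization (`optim`) on random instances to $10^{-4}$ in the
  coefficients and $10^{-6}$ in the p-values.
* **Shrinkage.** Reported effect sizes additionally include a shrunken
  log2 fold change: the posterior mode under a zero-centred Cauchy prior
  (scale 1 log2 unit by default) with the likelihood approximated as
  normal at the Wald estimate. This reproduces the qualitative contract of
  heavy-tailed shrinkage estimators: the shrunken value always lies
  between 0 and the raw estimate, is monotone in the standard error, and
  converges to the raw estimate as the standard error vanishes. Exact
  replication of apeglm's adaptively fitted prior is out of scope; the
  downstream classification rules only require the monotone-shrinkage
  contract.
* **Outliers.** No outlier filtering is applied: the criterion used in the
  original analysis is not specified, and inventing one silently would
  change results invisibly. The low-count filter is the only gene removal.

At 10 replicates per group the NB Wald test is known to be mildly
anticonservative. On simulated null data (2,000 genes, dispersion 0.5) the
raw p-value distribution's Kolmogorov–Smirnov distance from uniform
measures about 0.014 in the test suite — small, but the empirical
significance procedure below is the calibration that actually matters for
DEG calls.

## Permutation-based empirical FDR

Rather than an analytic multiple-testing correction, significance is
assessed against per-gene null distributions built by refitting the model
on label-permuted designs:

1. For $k = 1, \dots, K$ the treatment labels of the tissue's 30 samples
   are uniformly permuted (the label multiset, and hence the 10/10/10
   balance, is preserved by construction; each permutation is
   deterministic given the seed and iteration index).
2. The NB contrasts are refit on each permuted design, reusing the
   observed size factors (label-free by definition) and dispersions
   (refitting them 1000 times adds compute without changing the
   exchangeability argument). Each gene × contrast p-value is recorded;
   a non-converged permutation fit contributes a null p of 1.0 and is
   counted in the run log.
3. A gene's threshold for a contrast is the
   $\lceil \alpha_{\mathrm{tail}} K \rceil$-th smallest of its $K$ null
   p-values, and the gene is a DEG when its observed p falls **strictly
   below** that threshold ("below the 1% tail"; ties resolve
   conservatively to not-DEG).

The per-gene null follows the production analyses this emulates; it also
means a gene's threshold adapts to its own null behaviour instead of
assuming gene independence. With $\alpha_{\mathrm{tail}} = 0.01$ and
$K = 200$ the threshold is the 2nd-smallest null p, and under the global
null the expected flag rate is $2/201 \approx 0.995\%$ by exchangeability;
the acceptance script measures this calibration end to end. $K$ must be at
least $1/\alpha_{\mathrm{tail}}$ so the tail is non-empty — the
configuration constructor enforces this before any compute. The default
$K$ in this package is 200, chosen so a full per-tissue analysis at 2,000–
3,000 genes runs in seconds; production configurations use $K = 1000$.

## Gene classification rules

Let the three DEG flags per gene define a cell of the three-set Venn
diagram: `unique_pos`, `unique_neg`, `unique_negpos`, three pairwise
shared cells, `shared_all`, or `none`. The partition is exhaustive and
mutually exclusive, and is tested against direct enumeration of the eight
flag patterns.

**Learning (valence-independent) genes** are DEGs in *both*
training-vs-naive contrasts whose shrunken log2 fold changes agree in
sign — "similar expression patterns in both contexts" operationalized as
sign agreement, with zero shrunken estimates excluded.

**Valence-associated (antagonistic) genes** use a threshold rule on
*treatment-relative* expression. Each treatment's relative value is the
mean of $\log_2(\text{normalized count} + 1)$ over its replicates minus
the equal-weight grand mean of the three treatment means, so the three
values sum to zero and the naive treatment gets a meaningful non-zero
value. (A naive-referenced log2 fold change would be identically zero for
naive, which would make a window on "naive expression" vacuous;
grand-mean centring is the minimal interpretation under which all three
thresholds in the rule are meaningful.) A gene is valence-associated when

* its naive relative value lies in $[-w, w]$ with $w = 0.075$ (inclusive,
  "between"),
* its positive and negative relative values exceed $m = 0.5$ in opposite
  directions (strict inequalities: $\mathrm{Pos} < -m$ and
  $\mathrm{Neg} > m$, or the mirror), and
* it is a DEG in the negative-vs-positive contrast (the cross-reference is
  implemented as an intersection).

Swapping the two training labels maps case (1) genes to case (2) genes and
leaves the set unchanged, a symmetry the test suite checks.

### A noise bound worth knowing about

The $\pm 0.075$ naive window is tight relative to replicate noise at this
design size. At dispersion $\alpha = 0.2$ and $n = 10$ replicates, any
estimate of a treatment's mean log2 expression carries a standard error of
roughly $\sqrt{\ln(1+\alpha)/n} / \ln 2 \approx 0.2$ log2 units, and the
grand-mean-centred naive value about $0.17$ — more than twice the window
half-width. A gene whose true naive relative value is exactly 0 therefore
lands inside the window only about 35% of the time; this is a property of
the rule at this sample size, not of any particular estimator (it follows
from the Fisher information of the NB model), and would require on the
order of 100 replicates to overcome. The package applies the rule exactly
as stated; users should read the valence list as high-precision (planted
null genes essentially never qualify — the antagonism condition and the
DEG requirement see to that) but noise-limited in recall. The shared-flag
learning rule has no such window and recovers planted learning genes with
sensitivity above 0.8 in the test suite.

## The simulator

`simulate_counts()` draws NB counts with per-gene baseline means
log-uniform on a configurable range (default $[10, 1000]$), per-sample
depth factors log-uniform on $[0.7, 1.4]$ (so normalization is actually
exercised), and planted classes assigned deterministically: fractions are
converted to integer counts by largest-remainder rounding, genes take
classes in id order, and effect signs alternate within a class.
`unique_*` genes get the effect in one training context,
`shared_learning` the same sign in both, `antagonistic` mirrored signs.
The generator reproduces the emulated design (3 treatments × 10
replicates per tissue) by default; dispersion defaults to 0.5 for
null/calibration datasets, with 0.2 used in the planted-recovery analyses.

What the simulator does *not* emulate: read-level artifacts (it starts
from counts, as the analysis does), batch structure, correlated genes,
gene-length effects, and realistic mean-dispersion relationships fitted
from the real libraries (the deposited raw data's library-size spread and
dispersions are not reported, so defaults were chosen once for
testability). Passing tests therefore demonstrate correctness of the
computation and calibration under the model's own assumptions, not
fidelity to every property of the real sequencing data.

## Numerical and design choices

* Newton/IRLS contract: ridge $10^{-6}$, step clip $\pm 5$, tolerance
  $10^{-8}$, max 100 iterations; group separability makes this exact IRLS
  for the one-factor design.
* Integer percentages round half away from zero (so 79.5% prints as 80%).
* Permutation streams derive one 32-bit-safe seed per iteration from the
  base seed, so permutation $k$ is reproducible in isolation.
* Heatmap ordering (average-linkage hierarchical clustering of Euclidean
  distances on the Z-scored matrix, rows and columns) is fixed so output
  tables are deterministic; the ordered table contains exactly the input
  Z-scores, permuted. Fewer than two DEGs skips the heatmap with a
  warning.
* The variance-stabilizing transform is $\log_2(y_{ij}/s_j + 1)$ followed
  by per-gene Z-scoring; zero-variance genes get all-zero rows and a
  warning.
* Pipeline outputs are byte-deterministic given the configuration; the
  manifest records the configuration hash (output location excluded), all
  thresholds, retention, DEG/partition/learning/valence counts and the
  package version.
* Problem sizes in the shipped analyses (2,000–3,000 genes, $K = 200$)
  were chosen so each stage completes in seconds while leaving hundreds
  of planted genes per class for stable sensitivity estimates.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_counts(sim_config(
  n_genes = 2000, dispersion = 0.2, effect_lfc = 2,
  frac_unique_pos = 0.05, frac_antagonistic = 0.05, seed = 1
))
filtered <- filter_low_counts(sim$counts)
norm <- normalization_model(filtered)
res <- shrink_lfc(fit_contrasts(filtered, sim$design, norm))
null <- build_null(filtered, sim$design, norm,
                   perm_config(K = 200, alpha_tail = 0.01, seed = 2))
flags <- call_degs(res, null)
trel <- treatment_relative_lfc(filtered, sim$design, norm)
classify_genes(flags, res, trel)
```

The `analysis/` directory runs the same stages as numbered scripts over
three simulated tissues and writes all tables under `results/`.

## Known limitations

* The dispersion estimator uses the marginal (all-sample) variance, so
  strongly differentially expressed genes get inflated dispersions; the
  per-gene permutation threshold absorbs most of the calibration impact,
  but raw Wald p-values for such genes are conservative.
* The Cauchy-prior shrinkage uses a fixed prior scale rather than fitting
  it to the data.
* Permutation refits reuse observed dispersions; a per-permutation
  dispersion refit is not implemented.
* The valence rule's recall at the emulated design size is noise-limited,
  as quantified above.
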