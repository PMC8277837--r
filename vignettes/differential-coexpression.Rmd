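---
title: "Differential co-expression network analysis with asmnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-expression network analysis with asmnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Motivation

Differential expression alone tells you which genes shift in abundance
between a diseased and a healthy condition; it says nothing about how
the *co-regulation* of genes changes. asmnet implements the
complementary differential-wiring toolkit used in transcriptome studies
of conditions such as asthmatic airway smooth muscle: condition-specific
co-expression networks, regulator prioritization, connectivity rewiring,
and per-pair differential correlation, all validated end to end against
a count simulator with planted ground truth.

```{r setup}
library(asmnet)
```

## The model, stage by stage

### Filtering, normalization and differential expression

Counts are converted to counts per million (CPM); a gene is kept when
its CPM reaches `cpm_threshold` (default 0.5) in at least
`sample_fraction` (default 50%) of the samples. The boundary convention
— *keep* when at least half the samples clear the cutoff — follows the
usual edgeR-style reading of low-count filtering; both knobs are
arguments, so the stricter reading is one call away. Expression is
`log2(CPM + 0.5)`; the pseudocount (on the CPM scale) keeps zero counts
finite at `-1` and is configurable.

The differential-expression stage is deliberately plain: an ordinary
per-gene linear model of log2-CPM on condition, with centred age and a
sex indicator as optional covariates, a two-sided t-test on the
condition coefficient, and Benjamini–Hochberg adjustment (calls at
`padj <= 0.1` by default, split into up/down by the sign of the
coefficient). We do not reimplement negative-binomial shrinkage
estimators: the downstream network stages consume only the DE gene
*list*, and a DE table computed elsewhere can be supplied via
`de_table` in `pipeline_config()`. A gene with numerically zero
residual variance is reported at p = 1 when its coefficient is also
zero (no signal), and at p = 0 otherwise.

### Regulatory impact factors

For TF *i* and DE gene *j* with per-condition mean abundances `e1`
(case), `e2` (control), average abundance `a = (e1 + e2)/2`,
differential expression `dE = e1 - e2`, phenotype impact factor
`PIF = a * dE`, and within-condition correlations `r1`, `r2`:

$$RIF1_i = \frac{1}{n_{de}}\sum_j PIF_j\,(r_{1ij}-r_{2ij})^2
\qquad
RIF2_i = \frac{1}{n_{de}}\sum_j \left[(e_{1j} r_{1ij})^2-(e_{2j} r_{2ij})^2\right]$$

Both are z-standardized across TFs (sample SD) and a TF is significant
when either |z| ≥ 2. Design choices worth knowing: condition 1 is the
case group, so swapping the labels negates both raw scores exactly; a
gene that is both TF and DE gene contributes in both roles but the
self-pair is excluded (its correlation is identically 1 in both
conditions and would add a spurious `e1² − e2²` term to RIF2); TFs that
are constant within a condition are dropped with a warning. Note that
RIF1 weights the squared wiring change by the *signed* PIF — planted
regulators whose targets move in opposite directions partially cancel,
which is inherent to the metric, not an implementation artifact.

### PCIT networks, hubs, scale-free fit

The partial correlation and information theory (PCIT) algorithm prunes
a Pearson correlation matrix by examining every gene trio (x, y, z):
the three first-order partial correlations give the trio tolerance
`eps` (the mean of the partial/marginal ratios), and pair (x, y) is
eliminated when some z satisfies `|r_xy| < |eps·r_xz|` and
`|r_xy| < |eps·r_yz|`. The compiled O(n³) implementation is tested for
exact equality against a literal pure-R transcription of this
definition. Numerical guards: legs are clipped to |r| ≤ 1 − 1e−12
inside the partial-correlation formula, and a ratio with zero
denominator contributes 0 to `eps` — both rules exist so degenerate
synthetic inputs (duplicated genes, diagonal matrices) stay defined
without affecting generic data.

Edges retained for the condition networks must be PCIT-significant,
have |r| ≥ 0.95, pass the per-edge correlation t-test
(`t = r√((n−2)/(1−r²))`, p < 0.05) — the one place the per-condition
sample size enters — and touch the anchor set (DE genes plus
significant TFs; the full TF list via `anchor_tfs = "all"`). Hubs are
nodes whose degree strictly exceeds mean + 2 sample SD of the degree
distribution. The scale-free fit bins degrees into 10 equal-width bins
on the log10 scale and reports R² of the regression of log10 P(k) on
the mean log10 k per occupied bin; an exact power law is exactly linear
in these coordinates, and fewer than three occupied bins yields NaN
with a warning.

### Union network and differential connectivity

The case and control networks are merged into a central reference
network with `case_only` / `control_only` / `shared` flags on nodes and
edges. Genes absent from one condition's network count as degree 0
there — required for DK to be defined over the union gene set. Within
each condition, connectivity is standardized as `K = k / max(k)`; the
differential connectivity `DK = K_case − K_control` lies in [−1, 1] and
is z-scored over union genes (mean subtracted, sample SD; both choices
exposed as `center` and `sd_type` since raw-DK z-scoring is an equally
defensible reading). Calls at |z| ≥ 1.96 are connectivity `gain` or
`loss` in the case condition; a condition swap negates DK exactly and
flips the calls.

### Differential correlation and the nine classes

Per gene pair, the within-condition correlations are Fisher-stabilized
(`z = atanh r`) and their difference is tested with
`z_diff = (z_case − z_control)/√(1/(n_case−3) + 1/(n_control−3))`,
two-sided normal, BH-adjusted over all tested pairs. Each pair also
receives a class label: the per-condition status is `+` / `−` when the
correlation t-test is significant at `class_alpha = 0.05` (the
convention of the DGCA family of tools; the per-condition alpha is a
parameter), else `0`, giving the nine `case/control` classes
`+/+, +/−, +/0, −/+, −/0, −/−, 0/+, 0/0, 0/−`. At five samples per
group the variance term `1/(n−3)` is 0.5 and the test has very little
power; the scan warns below ten samples per group rather than
pretending otherwise. The scan evaluates correlations in row blocks so
an all-pairs scan over tens of thousands of genes is memory-bounded;
the anchored universe is the default.

### Over-representation and marker intersection

Enrichment of a query list in user-supplied GMT gene sets is a
one-sided hypergeometric tail within a declared universe (default: all
genes surviving the CPM filter), BH-adjusted; both raw and adjusted
p-values are reported because pathway-level calls in this literature
are often made on the raw p < 0.05. Redundant significant terms are
grouped by Cohen's kappa of their query-membership indicators (computed
over the query genes only), single-linkage at kappa ≥ 0.4, with group
numbering tied to term order for determinism. Marker-list comparison
(e.g. against a curated ferroptosis resource) is a case-normalized
exact intersection.

## What the simulator emulates — and what it does not

`simulate_counts()` draws a latent Gaussian layer — one factor per
module and sample; targets load with weight `√rho_within`, the module's
TF *is* the factor; rewired modules zero (or sign-flip) the target
loadings in the case condition — and maps each latent value through its
normal CDF onto a negative-binomial marginal (quantile matching), whose
mean carries the planted log2 fold changes for DE genes and a
log-normal (σ = 0.2) per-sample library-size factor. This preserves
planted rank correlations under a realistic count likelihood, gives
overdispersed marginals, and makes every downstream stage testable
against the emitted truth tables.

Defaults emulate a small case/control tissue study: 1,000 genes, 50
TFs, 5 samples per group, 10 modules of 10 genes at latent correlation
0.9, 30% of modules rewired, 5% DE genes at |log2FC| = 2, NB dispersion
0.1, and a baseline abundance distribution (log2-normal, mean 3, SD 4,
rescaled to a ~3×10⁵-read library so per-gene depth is study-like) wide
enough that the CPM filter removes a realistic low-expression tail
(~15–25%). Age and sex are emitted with zero planted effect, so the
covariate-adjusted DE path is exercised without confounding.

Not emulated: read-level structure, isoforms, batch effects, gene
length (so CPM-vs-TPM questions do not arise), covariate-correlated
expression, and any real biological annotation — so passing tests
demonstrate the *algorithms* are correct and calibrated under the
stated generative model, not that the biology of any particular tissue
is recovered.

Two generator options exist because recoverability scenarios need them:
`de_placement = "rewired_targets"` plants the DE genes on a rewired
module's targets (the configuration in which a differential regulator
is recoverable by RIF), and `de_sign = "up"` keeps the planted signs
coherent so signed-PIF cancellation does not mask the regulator.
Defaults remain `random` / `both`.

## Numerical choices and problem sizes

Planted-recovery scenarios in the test-suite use well-expressed
baselines (log2-normal mean 6, SD 1.5–2) so count noise does not
attenuate the planted latent correlations that the scenarios are about,
and 20 samples per group so correlation estimates are stable. The
rewiring-recovery scenario uses `rho_within = 0.93`: TF–target
correlations `√0.93 ≈ 0.964` clear the 0.95 edge filter while
target–target correlations (0.93) do not, so each module is a star
around its TF and regulator collapse is identifiable by degree; at
higher rho the module becomes a clique and the regulator is no longer
distinguishable from its targets. Because sample correlations at
n = 20 sit close to the 0.95 boundary, an occasional simulated
regulator retains too few control edges to reach |z| ≥ 1.96 — across
seeds both planted regulators are flagged in roughly three quarters of
runs and at least one essentially always.

Suite problem sizes (chosen to exercise every path while keeping a full
run to a few minutes on one core): PCIT oracle equivalence on ten
30×30 matrices; Fisher-z calibration on 10,000 null pairs and power on
2,000 planted pairs at n = 20/group; RIF recovery over 100 simulations
of 120 genes; the end-to-end determinism check on the default
1,000-gene scenario run twice.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_counts(sim_config(seed = 7))
dir <- tempfile(); paths <- write_simulation(sim, dir)
cfg <- pipeline_config(counts = paths[["counts"]],
                       samples = paths[["samples"]],
                       tfs = paths[["tfs"]],
                       outdir = file.path(dir, "out"), seed = 7)
manifest <- run_pipeline(cfg)
str(manifest$stages$rewire)
```

On this seed the run filters 1,000 genes to 850, calls 26 DE genes,
flags 5 TFs by RIF, builds case/control networks of a few hundred
anchored edges each, and reports the union-network DK table with its
gain/loss calls; the planted rewired regulators appear in the loss
list. All outputs are plain TSV/SIF/JSON under `outdir`, and a re-run
with the same seed is byte-identical (the manifest differs only in
timings).

## Known limitations

* The DE stage is an ordinary linear model on log2-CPM; with very few
  samples it is less powerful than shrinkage-based NB methods, which is
  why an external DE table is accepted.
* PCIT is O(n³): ~15,000 genes is hours of compute on one core, and
  the method's published uses run at that scale; the compiled core
  supports it, but the package's test scenarios stay in the
  hundreds-to-thousands range.
* The Fisher z-test at n = 5/group is honest but near-powerless; the
  scan warns and the nine-class labels lean on per-condition t-tests
  that share the same weakness.
* Kappa grouping is quadratic in the number of significant terms;
  fine for hundreds of terms, not for tens of thousands.
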