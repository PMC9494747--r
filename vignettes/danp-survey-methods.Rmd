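---
title: "Methods: DEMATEL-ANP survey analysis, agreement statistics and the MER linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DEMATEL-ANP survey analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(danpsurvey)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the parameters that matter, the numerical choices, what
the synthetic generator does and does not emulate, and the design decisions
taken where the methodology left genuine freedom.

## The analysis pipeline

The package analyzes surveys in which each judge (a "modeler" in the staged
model-intercomparison setting the package was built for) expresses

1. one reciprocal pairwise comparison matrix (PCM) per variable category,
2. one PCM over the categories themselves, and
3. one direct-influence matrix over the categories,

against a fixed *protocol*: variables grouped into categories, each tagged
with the release stage at which it becomes available. The packaged default
protocol has 7 categories, 55 variables and 5 stages, with 28 variables at
stage 1.

The chain from raw judgments to stage importances is, per retained judge:

- **Local priorities.** Each PCM's priority vector is its normalized
  principal right eigenvector, obtained by power iteration. For a perfectly
  consistent matrix $a_{ij} = w_i / w_j$ this reproduces $w$ exactly.
- **Consistency screening.** $CI = (\lambda_{max} - n)/(n-1)$,
  $CR = CI / RI(n)$ with Saaty's published random indices for orders 1–15.
  $CR > 0.10$ flags a matrix for review; $CR > 0.30$ excludes the judge
  outright. Both thresholds are arguments; the defaults are the conventional
  screening rules. $n = 2$ matrices are always consistent and defined to
  have $CR = 0$; orders above 15 are rejected rather than extrapolated.
- **DEMATEL.** The direct-influence matrix is scaled by
  $s = \max(\max_i \sum_j d_{ij},\ \max_j \sum_i d_{ij})$, which keeps the
  spectral radius of $N = D/s$ below one (checked numerically, not assumed);
  the total relation matrix $T = N (I - N)^{-1}$ then sums all direct and
  indirect influence paths. Row sums $G$ and column sums $R$ give each
  category's influence given and received; the sign of $G - R$ classifies
  net influencers versus net receivers, with $|G - R| \le 10^{-9}$ reported
  as a third class, `neutral`, which degenerate (e.g. symmetric) inputs
  need even though real panels do not.
- **ANP coupling.** Column-normalizing $T$ yields the cluster weighting
  matrix $C$; supermatrix entry $W_{ij} = C_{\mathrm{cat}(i),\mathrm{cat}(j)}
  \cdot w_{\mathrm{cat}(i)}(i)$. Columns sum to one by construction, and
  this is asserted, not trusted, at every step.
- **Limit priorities.** Powers of the supermatrix are taken by repeated
  squaring until all columns agree to within $10^{-9}$; the common column is
  the global priority vector. Because within-category columns of $W$ are
  identical, the limit factorizes: the global priority of variable $i$
  equals its local weight times the stationary weight of its category under
  $C$. One consequence worth recording: the "per-stage normalized
  importance" (each variable's within-category rank score normalized over
  its category's importance share) *is* the global importance in this
  construction, so stage importances are simply within-stage sums of global
  importances and automatically partition 1.
- **Pooling.** Mean ± sd across judges (sd with denominator $n - 1$, zero
  for a single judge). Influence profiles are pooled the same way —
  per-judge $T$ first, then averaged — rather than computing $T$ of the
  averaged direct matrix, because the reported quantity is the panel's mean
  influence level, and the two orders differ for a nonlinear map.

### Agreement and group statistics

Panel agreement uses the tie-corrected Kendall coefficient of concordance.
Judges' priority vectors are converted to mid-ranks ascending in importance
(ties share the average rank, so every row sums to $n(n+1)/2$), and

$$W = \frac{12\,SS}{m^2 (n^3 - n) - m F}, \qquad
  F = \sum_{\text{judges}} \sum_{\text{tie groups}} (t^3 - t),$$

with $SS$ the sum of squared deviations of per-item rank sums from their
mean. With no ties $F = 0$ and the classic formula is recovered (the test
suite asserts this to $10^{-12}$). Significance uses the chi-square
approximation $\chi^2 = m (n - 1) W$ on $n - 1$ degrees of freedom; for
small panels an exact permutation test (independent permutations of each
judge's ranks) is available behind a flag.

Group differences use the one-way Wilks' lambda MANOVA,
$\Lambda = \det(\mathbf{W}) / \det(\mathbf{W} + \mathbf{B})$, with Rao's F
approximation for the p-value. Two practical constraints shape its use on
survey data. First, priority weights sum to one, so the full
judges-by-variables matrix is rank-deficient by construction; the
category-level helper therefore drops one column (the last item by default,
selectable). Second, grouping 20 judges by 12 model types inevitably
produces singleton groups; these are dropped with a message, and the test
requires at least two groups of at least two judges. Univariate per-variable
follow-up ANOVAs are reported with unadjusted p-values by default — the
survey tradition this package serves reports per-variable significance
without multiplicity correction — with Holm adjustment available as an
option (`adjust = "holm"`); the default is a faithful choice, not an
endorsement.

### The MER linkage

Given a per-stage ensemble error series (RRMSE, accepted as fraction or
percent — the unit is carried through, never converted) and the cumulative
stage importance $\Sigma P_s$, the model error rate is defined as the ratio

$$\mathrm{MER}_s = \mathrm{RRMSE}_s / \Sigma P_s,$$

the error per unit of modeling importance accessed by stage $s$ — the only
reading under which a MER value exists per stage, which is how such tables
are presented. The incremental alternative
$\Delta \mathrm{RRMSE} / \Delta \Sigma P$ is nonetheless implemented behind
`incremental = TRUE` and labelled distinctly in the output, since the ratio
and slope readings answer different questions (total versus marginal value
of data). Stage-over-stage summaries are percent changes against stage 1.
The identities $\mathrm{MER}_s \cdot \Sigma P_s = \mathrm{RRMSE}_s$ and
scale-equivariance in the error unit are asserted in the tests.

## The synthetic survey generator

The raw questionnaire responses of the motivating study design are not
public, so the generator is the package's source of analyzable data — a
first-class, tested component, not a fixture. It emulates:

- **Latent consensus and dissent.** Per category, a shared weight vector is
  drawn from a Dirichlet distribution (concentration 5 by default, giving
  realistic dispersion with all-positive weights); each judge's realized
  weights are $\alpha \cdot \text{shared} + (1 - \alpha) \cdot
  \text{idiosyncratic draw}$. The mixture weight $\alpha$ (default 0.7)
  controls panel concordance: Kendall's $W$ rises monotonically in $\alpha$
  (a calibration trend the acceptance suite checks across
  $\alpha \in \{0, 0.25, 0.5, 0.75, 1\}$, 100 replicates each).
- **Judgment noise.** PCM entries are
  $a_{ij} = (w_i / w_j) \exp(\varepsilon_{ij})$ with independent
  $\varepsilon \sim N(0, \sigma^2)$ on the log scale — the natural error
  model for ratio judgments, and the only one for which $\sigma = 0$ gives
  $CR = 0$ exactly. Entries are clipped to the judgment-scale range
  $[1/9, 9]$ before the reciprocal lower triangle is mirrored, so matrices
  stay valid at the scale boundary. The default $\sigma = 0.5$ was set by
  calibrating the $\sigma \to CR$ map against the study condition the
  package emulates — a retained-panel mean consistency ratio of about
  $7 \pm 1\%$ — which $\sigma = 0.5$ reproduces (mean CR $\approx 0.07$,
  with a realistic minority of matrices crossing the 10% review threshold).
  Mean CR is monotone in $\sigma$, checked over
  $\sigma \in \{0, 0.1, 0.2, 0.4\}$ with 200 matrices per level.
- **Ratio bounding.** Latent weight vectors are shrunk order-preservingly in
  log space until $\max w / \min w \le 9$. Without this, a noise-free PCM
  built from an extreme Dirichlet draw would be altered by scale clipping
  and no longer consistent with its own weights; with it, the zero-noise
  pipeline recovers the generator's ground truth to $10^{-6}$, which the
  acceptance suite asserts end to end.
- **Group structure.** Model types and experience classes are assigned by
  cycling the 12 standard type labels and 4 experience bands over the
  panel. Optional group effects add a configured shift to one category's
  latent weights for one group before renormalization, giving MANOVA
  power experiments a known signal.
- **Influence noise.** Each judge's direct-influence matrix is the ground
  truth plus element-wise half-normal noise (sd 0.05 by default), keeping
  entries non-negative and the diagonal zero.
- **Error series.** `generate_rrmse()` inverts the MER definition,
  $\mathrm{RRMSE}_s = \mathrm{MER}^{true}_s \cdot \Sigma P^{true}_s$ plus
  optional truncated Gaussian noise, so the error-linkage stage has an
  exact round-trip test at zero noise.

Everything is deterministic given the spec's seed.

What the generator does **not** emulate: correlated judgment errors within a
judge (each $\varepsilon_{ij}$ is independent, whereas human inconsistency
is often structured), systematic response styles (e.g. centrality bias on
the verbal scale), missing responses, or any coupling between a judge's
consistency and their group membership. Passing parameter-recovery tests
therefore demonstrates that the pipeline inverts its own generative model —
a necessary check that says nothing about whether real panels satisfy that
model.

## Numerical choices

- Reciprocity and unit-diagonal tolerance on input: $|a_{ij} a_{ji} - 1|
  \le 10^{-9}$ (scale-free). Matrix entries are serialized as decimal text
  at full double precision (`%.17g`), so write→read round trips are
  bit-identical.
- Power iteration: tolerance $10^{-12}$ on the weight vector, cap 10,000
  iterations; non-convergence is an error (it signals pathological input),
  never a silent fallback. The eigenvector method was chosen over the row
  geometric mean as the canonical ANP input; the two agree to $10^{-6}$ in
  the near-consistency limit (asserted at $\sigma = 0.002$), which guards
  the choice against divergence on well-behaved data.
- Supermatrix limit: repeated squaring with column renormalization at every
  step to absorb floating-point drift, spread tolerance $10^{-9}$, cap 200
  squarings. Periodic chains, whose plain powers oscillate, are handled by
  also testing the Cesàro average of two successive powers; a 2×2
  permutation supermatrix thus yields (0.5, 0.5) exactly.
- Zero columns in $T$ fall back to uniform cluster weights for that target
  category, with a message — a degenerate case that valid surveys do not
  produce but that the function contract covers.
- The strict Saaty-scale membership check on PCM entries is opt-in
  (`strict_scale = TRUE`), because instruments differ in the verbal scales
  they admit; positivity and reciprocity are always enforced.

## Design decisions on genuinely open points

- **Aggregation across judges.** Both standard routes are provided:
  element-wise geometric-mean aggregation of judgments
  (`aggregate_pcms()`, used where a single group matrix is needed) and
  retention of per-judge priorities with arithmetic summarization
  (`mean_priorities()`, `importance_table()`), because group tables report
  mean ± sd across judges, implying per-judge priorities exist throughout.
- **DEMATEL→ANP coupling.** Column-normalized $T$ as the cluster weighting
  matrix — the standard hybrid ("DANP") convention for integrating relation
  strength into the network.
- **No within-category inner dependence.** Variable-level dependence is
  expressed only through the category-level influence matrix; the survey
  instrument this package models collects no variable-by-variable influence
  judgments, so modeling inner dependence would invent data.
- **Rank construction.** Mid-ranks of per-judge priority weights, ascending
  in importance. This is the conventional operationalization when the
  instrument yields ratio-scale priorities rather than direct rankings.
- **MANOVA power experiment design.** The acceptance suite's
  detection-power experiment uses a high-consensus panel
  ($\alpha = 0.9$, $\sigma = 0.2$) with a $+1.5$ latent shift on one
  climate variable for one (two-member) model-type group. At the default
  survey-emulating conditions ($\alpha = 0.7$, $\sigma = 0.5$), power
  against a single two-member group plateaus around two thirds regardless
  of shift size: the 9:1 judgment-scale bound caps the expressible
  separation, and twelve model types over twenty judges leave only eight
  residual degrees of freedom once singleton groups are dropped. That
  plateau is itself a finding about the survey design — a panel of this
  shape cannot reliably resolve model-type effects of any size — and
  mirrors the structural limitation that only a minority of model types
  can be sampled more than once in such studies.

## Problem sizes used in the checks

The packaged test and acceptance suites run, per invocation: 100 random
tables for the tie-corrected concordance oracle; 50 random 7×7 instances
for the Neumann-series DEMATEL oracle (spectral radius held at ≤ 0.9, series
summed to 400 terms) and 50 random 10-variable supermatrices for the
stationary-vector oracle; 20-modeler surveys on the full 55-variable
protocol for recovery (one zero-noise run plus 50 replicates at
$\sigma = 0.1$); and 100-replicate calibration sweeps for each of the CR,
concordance and power trends. These sizes were chosen to make Monte-Carlo
standard errors small relative to the asserted margins while keeping a full
run in the order of a minute.

## Known limitations

- The published per-variable importance table packaged with this repository
  exercises the aggregation arithmetic only; the raw judgments behind it
  are not public, so the pipeline's numerical outputs cannot be compared
  against that study's PCM-level data. Two of its five printed stage totals
  (stages 1 and 4) disagree with the sum of their own printed per-variable
  entries by one display unit — a rounding artifact of the source table —
  so only the internally consistent stages (2, 3, 5) are asserted.
- Concordance significance relies on the chi-square approximation, which is
  anti-conservative for very small $m$ and $n$; use the permutation option
  there.
- Wilks' lambda assumes multivariate normality within groups and common
  covariance; priority weights are compositional and bounded, so for small
  panels the test is approximate. A log-ratio transform before testing is a
  reasonable alternative the package leaves to the caller.
- The MER linkage is descriptive — a ratio of observed error to elicited
  importance — and carries no causal claim about why error changes across
  stages.
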