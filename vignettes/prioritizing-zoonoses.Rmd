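---
title: "Methods: AHP criterion weighting and weighted decision-tree scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AHP criterion weighting and weighted decision-tree scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zooprior)
```

## The problem

Joint prioritization of zoonotic diseases between human and animal health
agencies is usually attempted where the data to support a fully quantitative
ranking — prevalence, incidence, burden estimates — do not exist. zooprior
implements a semi-quantitative workflow for exactly that setting: the
stakeholders agree on *criteria* that define what makes a disease important,
attach one answerable *categorical question* to each criterion, rank the
criteria by pairwise comparison, and push each candidate disease through a
weighted decision tree built from the questions. The output is a ranked,
normalized disease list with a per-disease trace showing exactly where every
point came from — the transparency is the method's main selling point, so the
package treats the trace as a first-class object rather than a by-product.

The pipeline is:

1. **Configuration** — a disease list (15–30 entries recommended), 5–9
   criteria, one question per criterion with a binomial or ordinal
   multinomial answer scale.
2. **Criterion ranking** — each participant fills a Saaty pairwise-comparison
   matrix; matrices are aggregated; the Analytic Hierarchy Process (AHP)
   turns the aggregate into a priority vector.
3. **Sequential weighting** — the n ranked criteria receive integer weights
   n, n−1, …, 1 from best to worst.
4. **Decision-tree scoring** — each disease's categorical answers are scored,
   weighted, summed, and normalized against the maximum total.

## The AHP layer

A participant's judgments form a positive reciprocal matrix $A$ with
$a_{ij}$ the judged importance of criterion $i$ over $j$ on the 1–9 ratio
scale (and $a_{ji} = 1/a_{ij}$, enforced at construction). Priorities are the
normalized principal right eigenvector $p$ of $A$, computed by power
iteration with an L1 convergence tolerance of $10^{-12}$ and a 10,000
iteration cap; positivity of $A$ guarantees a dominant positive eigenpair, so
non-convergence is a numerical pathology and is reported as an error rather
than silently accepted. A row-geometric-mean derivation is offered as an
alternative (`method = "geometric_mean"`); the two agree exactly on
consistent matrices, which the test suite asserts to $10^{-9}$.

Judgment coherence is summarized by Saaty's consistency machinery:
$\lambda_{\max} = \tfrac{1}{n}\sum_i (Ap)_i / p_i$,
$CI = (\lambda_{\max} - n)/(n - 1)$, and $CR = CI / RI(n)$, where $RI(n)$ is
the expected $CI$ of a random reciprocal matrix of the same order. A $CR$
above 0.1 conventionally flags incoherent judgments; because the workflow is
meant to be facilitated live and never rejects a participant's input, the
package only warns on high $CR$ — it never refuses a matrix.

**Random-index constants.** The packaged $RI$ table uses the large-sample
re-estimates of Alonso & Lamata (2006) — 0.5245, 0.8815, 1.1086, 1.2479,
1.3417, 1.4056, 1.4499 for $n = 3,\dots,9$, extended to $n = 15$ — rather
than Saaty's original 1980 figures. The original value at $n = 3$ (0.58) is
an artifact of a small early simulation: a Monte-Carlo estimate under the
standard generating model (entries uniform on the 17-value scale
$\{1/9,\dots,1/2,1,2,\dots,9\}$) gives ≈ 0.523, and the test suite checks
every packaged constant against exactly that oracle (10,000 matrices per
order, tolerance 0.05). Since $CR$ is advisory here, the choice has no effect
on any ranking; it only makes the reported ratios accurate.

**Group aggregation.** The workflow says only that participants' responses
are merged. Two standard conventions are implemented: aggregation of
individual judgments (*AIJ*, element-wise geometric mean of the matrices,
which preserves reciprocity) and aggregation of individual priorities
(*AIP*, arithmetic mean of the individual eigenvectors, renormalized). AIJ is
the default because it keeps the group result inside the same mathematical
object — a reciprocal matrix with its own $\lambda_{\max}$ and $CR$ — and is
the usual choice when participants act as a single synthetic decision maker.

**Sequential weights.** AHP produces continuous priorities, but the workflow
deliberately collapses them to the integers $n,\dots,1$ in ranking order;
the continuous values are kept in the output for inspection, and
`prioritize(weight_scheme = "raw-priorities")` scores with them directly for
sensitivity comparisons. Priorities tied within $10^{-9}$ are broken by the
configured criterion order; the tie is recorded and warned about, since the
sequential-integer rule forces a strict order that the data do not support.
Averaging tied weights was rejected because it would break the "integers
n…1" contract that downstream scores rely on.

## The scoring layer

Each question's answer is scored in $[0, 1]$:

- **binomial**: the designated full-score answer scores 1, the other 0. The
  full-score answer is a per-question configuration field, not a global
  "yes", because groups decide it per question.
- **multinomial** ($m$ ordered categories, 2–5 recommended): the $k$-th
  category scores $k/m$, so the lowest category of a 3-answer question scores
  1/3, not 0.

The binomial rule is kept as a genuine special case even though applying
$k/m$ with $m = 2$ would give $\{1/2, 1\}$: the two rules are part of the
method's definition, and the package preserves that asymmetry rather than
"fixing" it. The weighted score of a question is $q = w \cdot s$; a
disease's total is $T = \sum q$, bounded by $0 \le T \le \sum_r w_r =
n(n+1)/2$. Totals are normalized as $N = T / T_{\max}$ against the maximum
*observed* total, so the top disease always scores 1; `normalize =
"max-possible"` divides by $\sum w_r$ instead when comparability across runs
matters more than a fixed top score. Ties in $T$ share a rank (competition
ranking, 1-1-3) and fall back on the configured disease order, making the
output deterministic.

Although the method is described as a decision tree — nodes ordered by
descending criterion weight — every disease traverses every node, so the
tree is mathematically a weighted sum and node order affects only the
presentation of the trace. The test suite asserts this order-invariance
explicitly.

The leave-one-out `sensitivity_scan()` drops each criterion in turn,
re-assigns sequential weights $n-1,\dots,1$ over the remaining criteria in
their unchanged relative order, re-scores, and counts rank changes — a
direct, deterministic implementation of the sensitivity analysis the
workflow calls for.

## The synthetic-data generator

`synth_spec()` fixes the simulated study conditions. Defaults mirror the
package's running example: 5 criteria with latent importance vector
$v = (5, 4, 3, 2, 1)$, 10 participants, 20 diseases, judgment noise
$\sigma = 0.1$. A participant's judgment of pair $(i, j)$ is generated as

$$a_{ij} = \frac{v_i}{v_j} \, e^{\varepsilon}, \qquad
  \varepsilon \sim \mathcal{N}(0, \sigma^2),$$

independently per upper-triangle cell, with the reciprocal filled in exactly
and values clamped to $[1/9, 9]$ (the clamp rate is reported, so a $\sigma$
large enough to saturate the scale is visible). Multiplicative log-normal
noise on a consistent matrix is the standard judgment-error model in AHP
simulation work; at $\sigma = 0$ every matrix is exactly consistent and the
latent order is recovered with certainty. Answers are categorical draws from
per-question probability vectors (uniform unless specified). All generation
is seed-deterministic; `rank_recovery()` runs the whole
generate-aggregate-weight pipeline repeatedly and reports the fraction of
replicates recovering the full latent order per noise level.

What the generator does *not* emulate: systematic inter-sector disagreement
(two stakeholder blocs with different latent vectors), correlated answers
across questions, and strategic or anchored judgment behaviour. Passing
rank-recovery tests therefore says the pipeline's algebra is sound and
noise-robust, not that a real facilitated group will converge.

## Numerical and design notes

- Power iteration: tolerance $10^{-12}$ (L1 change), max 10,000 iterations;
  $\lambda_{\max}$ from the Rayleigh-style mean of $(Ap)_i/p_i$, which
  coincides with the eigenvalue at convergence and remains meaningful for
  geometric-mean priorities.
- $CI$ is clamped-checked: values below $-10^{-9}$ raise an error since
  $\lambda_{\max} \ge n$ for reciprocal matrices.
- Ratios outside $[1/9, 9]$ in input files warn but are accepted — elicited
  spreadsheets sometimes contain chained comparisons — while non-positive
  ratios are hard errors.
- Recommendations (5–9 criteria, 6–12 participants, 15–30 diseases, ≤ 5
  categories) are warnings by default and errors under `--strict`,
  reflecting that they are guidance about group dynamics, not mathematical
  requirements.
- Missing answer cells are hard errors by default; `missing_as_lowest` maps
  them to the lowest ordinal category with a per-cell message, the most
  conservative completion consistent with the scoring rules.
- File dialects are plain text (YAML configuration, CSV judgments/answers,
  CSV/JSON/Markdown reports) so runs diff cleanly and fixtures live in the
  repository; CSV output rounds floats to 6 decimals, JSON keeps full
  precision, and every command writes a manifest with input digests.

## Problem sizes used in the test suite

Unit and property tests run on 2–8 criteria and up to 10 diseases with
seeded random configurations; the exhaustive scoring check enumerates all 36
answer vectors of a 4-criterion configuration with two binomial and two
3-category questions; the random-index oracle uses 10,000 matrices per order
for $n = 3,\dots,9$; and the rank-recovery experiment runs 500 replicates per
noise level over $\sigma \in \{0, 0.1, 0.3, 0.8\}$ under the default study
conditions. These sizes give stable Monte-Carlo estimates (±2 percentage
points at 500 replicates) while keeping the default suite fast.

## Known limitations

- Single-level AHP only: no criterion hierarchies or sub-criteria, no
  incomplete-matrix completion — every pair must be judged.
- Disease entries are opaque names; no taxonomy validation is attempted,
  since lists legitimately mix diseases, pathogens and grouped categories.
- The per-question data sources are free-text notes; the package checks
  answers against scales, not against the sources themselves.
- Normalization against the observed maximum makes scores comparable within
  a run, not across runs with different configurations.
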