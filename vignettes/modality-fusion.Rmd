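---
title: "Fusing multi-source school-district learning-modality reports with a hidden Markov model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing multi-source school-district learning-modality reports with a hidden Markov model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modalhmm)
library(dplyr)
```

## The problem

During the 2020–2021 U.S. school year, several surveillance feeds tracked
which learning modality each public school district offered each week —
fully remote (no face-to-face instruction), hybrid, or fully in-person
(five days a week for all grades). The four feeds modalhmm models —
Burbio (media reports and manual website review), MCH Strategic Data
(phone surveys), the Return to Learn Tracker (automated website scraping,
`R2LT`), and state dashboards (`SD`) — were individually incomplete, had
very different coverage, and sometimes contradicted each other in the
same district and week. modalhmm reconciles them into a single weekly
consensus modality per district, with a posterior confidence, by treating
the true modality as the hidden state of a Markov chain and each source's
report as a noisy categorical observation of it.

## The model

For each district, the true modality $X_t \in \{1,2,3\}$ (1 = remote,
2 = hybrid, 3 = in-person) evolves as a first-order Markov chain with a
$3\times3$ row-stochastic transition matrix $T$, $T_{ij} = \Pr(X_{t+1} =
j \mid X_t = i)$, shared by all districts and constant over the year.
Each source $s$ reports, in the weeks it covers, a modality $Y^s_t$ drawn
from its own $3\times3$ emission matrix row $E^s_{X_t\cdot}$; given the
hidden state the four channels are conditionally independent, so a week's
observation probability is the product over *present* sources, and a
source that does not report contributes a factor of 1 (it is marginalized
out). An initial distribution $\pi$ completes the parameter set — 45 free
parameters in all.

Two modelling consequences matter in practice:

* **Missing weeks are not dropped.** A district's sequence runs
  contiguously from its first to its last reported week; interior weeks
  with no reports stay in the sequence with observation probability 1, so
  the chain smooths modality estimates *through* coverage gaps, borrowing
  strength from both sides of the gap.
* **No source is trusted a priori.** The emission matrices are estimated
  from the data, so a source that frequently disagrees with the consensus
  ends up with a flatter emission row and correspondingly less influence.
  There is no hand-set source hierarchy.

## Estimation

`fit_hmm()` runs Baum–Welch EM over all district sequences jointly:
forward–backward smoothing gives per-week state posteriors
($\gamma$) and per-step transition posteriors ($\xi$); the M-step pools
expected counts across districts. Each source's emission matrix is
re-estimated only from district-weeks where that source reported. The
total log-likelihood is non-decreasing across iterations — the test suite
asserts this on every fit with an absolute slack of `1e-8` for floating
point.

Numerical and algorithmic choices:

* **Scaling, not logs, inside the recursions.** The forward and backward
  variables are renormalized each week; the log-likelihood is the sum of
  log scaling constants, so 100-week sequences cannot underflow. A
  padding week (beyond a short sequence's end, used to keep the district
  × week array rectangular) has scaling constant exactly 1 and
  contributes nothing.
* **Initialization.** Emission matrices start diagonal-dominant (0.8
  on-diagonal, 0.1 off) and transitions sticky (0.9 on-diagonal), both
  perturbed by seeded uniform noise of magnitude 0.05; $\pi$ starts
  uniform. A converged fit on this kind of data is itself
  diagonal-dominant, and a sticky start avoids label-degenerate local
  maxima while remaining generic. By default 5 seeded restarts are run
  and the best final log-likelihood kept.
* **Convergence.** Relative log-likelihood improvement below `1e-6`, or
  500 iterations. On the reference synthetic panel the fit typically
  converges in well under 50 iterations.
* **Zero cells.** After each M-step, emission cells are floored at
  `1e-10` and rows renormalized so later Viterbi decoding never takes
  `log(0)`. Transition or emission rows with zero expected support (a
  state never visited, a source never observed) keep their previous
  values rather than being re-estimated from nothing.
* **Ties.** Posterior MAP and Viterbi argmaxes break ties toward the
  lowest state index, making all decoded output deterministic.
* **$\pi$ is estimated by EM** from week-1 posteriors. It is needed for a
  well-defined likelihood even though it is of little substantive
  interest; no downstream result in this package is sensitive to it.

One pooled national model is fitted rather than per-state models: the
sources' reporting behaviour, not the states' policies, is what the
emission matrices describe, and pooling maximizes the data behind each of
the 45 parameters.

## Label switching and confidence

An unsupervised HMM's likelihood is invariant under permutation of hidden
state indices, so a fitted state "2" need not mean hybrid.
`derive_labeling()` resolves this by majority report: for each hidden
state, all reports (four sources pooled, unweighted) over district-weeks
whose MAP state is that hidden state are counted, and states are assigned
to modalities greedily in descending count order — a valid permutation
even if two states share a majority modality. Unweighted pooling is the
plain reading of "most common reported modality"; since R2LT contributes
most reports it dominates the counts, which is harmless because labeling
only needs the majority to point the right way. `apply_labeling()` then
permutes posteriors and relabels states.

A district-week is called *high confidence* when its maximum posterior
probability is at least 0.75 (inclusive). The threshold is a reporting
convention, not a model parameter; `confidence_filter()` takes any cutoff
in $(0,1]$, and the retained fraction is monotone non-increasing in it.
The reported `confidence` is the posterior of the MAP state (smoothing
marginal), not a Viterbi path probability: marginal posteriors are the
quantity a per-week threshold is meaningful for. Both MAP and Viterbi
paths are exposed; MAP is the default summary.

## What the synthetic generator emulates — and what it does not

Because the four real feeds are proprietary, the package validates itself
on synthetic panels. `reference_generator_spec()` encodes the study
conditions:

* **Dynamics and noise**: ground truth from `reference_hmm_params()`,
  the fitted national parameterization (self-transitions
  0.903/0.961/0.983; R2LT on-diagonal fidelity ≈ 0.99; MCH in-person
  fidelity ≈ 0.60, etc.). Printed three-decimal rows can sum to
  $1 \pm 10^{-3}$, so rows are renormalized once at construction.
* **Coverage**: per-source marginal presence rates derived from the
  observed district-week volumes on a 14,688-district × 42-week grid —
  BURBIO 37,589/616,896 ≈ 0.061, MCH 58,137/616,896 ≈ 0.094, R2LT
  343,596/616,896 ≈ 0.557, SD 24,732/616,896 ≈ 0.040.
* **Coverage structure**: state dashboards are only active for the final
  40% of weeks (they largely came online in February 2021), and MCH goes
  dark for a contiguous 8-week February–March block. Within a window the
  per-week rate is scaled up so the *marginal* rate — what the
  district-week volumes measure — is preserved.
* **Initial distribution**: $\pi = (0.25, 0.35, 0.40)$, approximating
  early-fall national shares. No published value exists; recovery results
  are insensitive to it (it governs one week out of 43).

The generator deliberately simplifies in two ways. Source presence is
independent across sources, weeks, and districts given the window masks,
whereas real coverage is strongly structured (a state dashboard covers
all districts of its state; panel participation persists). And all
districts share one 43-week grid, whereas real districts enter and leave
reporting at different times. Passing recovery tests therefore shows the
*estimator* is correct and well-calibrated at realistic sparsity — not
that real-data biases (systematically wrong sources, modality-definition
mismatches) are absent; with no ground truth for the real year, no
desk-scale test could show that.

## Agreement statistics and trends

`pairwise_agreement()` computes, for each pair of trackers (the four
sources plus the fused `"HMM"` output), the share of district-weeks
*where both report* that they agree; pairs with no overlap are `NA`, not
zero. `agreement_ttest()` compares, for one tracker, its weekly agreement
series with the HMM against its weekly agreement with each other source,
by a *paired* one-sided t-test across weeks. The week is the sampling
unit: district-weeks within a week are strongly dependent (they share
state policy shocks), so treating them as independent would overstate
significance, while weekly pairing also absorbs common seasonal swings.
If every weekly difference is exactly zero the statistic is reported as 0
with one-sided p = 0.5.

`weekly_shares()` reports, per week (optionally by state or by the
six-level county urban–rural classification), the share of districts in
each modality *among districts with an inferred modality that week* — the
only computable denominator, since districts with no observed window have
no inference. An option restricts to high-confidence district-weeks.
`state_endpoint_summary()` reads a state-stratified trend at three
reference weeks and reports in-person percentages and the start-to-end
change in percentage points.

## Validation: problem sizes and what is checked

The test suite checks, among other properties:

* exact agreement (tolerance `1e-9`) of likelihood, posteriors, and
  Viterbi with brute-force enumeration over all $3^L$ hidden paths on 100
  random instances with $L \le 8$ and random missingness;
* EM monotonicity on every fit in the suite;
* parameter recovery on the reference conditions at 3,000 districts ×
  43 weeks: each self-transition and representative emission cell within
  ±0.02 of truth after label alignment, identity labeling recovered, and
  labeled MAP accuracy ≥ 90% of district-weeks;
* generator consistency at 10,000 districts (empirical one-step
  transition frequencies within ±0.01) and stationarity of a long
  simulation against the leading eigenvector of $T$.

The 3,000 × 43 size matches the recovery experiment
`scripts/acceptance.R` re-runs; it gives roughly 129,000 district-weeks
and ~97,000 observations, enough that the binomial standard error of
every checked cell is well under the ±0.02 band. `recovery_experiment()`
exposes the same harness for any generator spec.

## Known limitations

* The chain is time-homogeneous; a modality change driven by an outbreak
  with planned reopening violates the Markov assumption, as does any
  secular drift in source reliability.
* The consensus is only as good as the sources: a bias shared by the
  heavier sources becomes the consensus.
* Real missingness is not missing-at-random within a week grid in the way
  the generator's independence assumption describes; agreement statistics
  on real panels should be read with the coverage structure in mind.
* `agreement_ttest()` inherits the usual caveats of t-tests on bounded
  proportions over ~40 weeks; it is a directional check, not an effect
  size estimate.
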