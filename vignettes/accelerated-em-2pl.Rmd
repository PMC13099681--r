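---
title: "Accelerated EM estimation for 2PL item response models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerated EM estimation for 2PL item response models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emirt)
```

## The model and the estimation problem

emirt fits the unidimensional two-parameter logistic (2PL) item response
model by marginal maximum likelihood.  Person $p$'s probability of scoring
1 on item $i$ is a logistic function of a standard-normal latent trait
$\eta$ in slope–intercept form,

$$P_i(\eta) = \frac{1}{1 + \exp[-(a_i \eta + c_i)]},$$

where the slope $a_i$ is the item's discrimination and the intercept
relates to the more familiar difficulty by $c_i = -a_i b_i$.  Because
$\eta$ is latent, the likelihood of a response vector integrates it out
against the standard-normal density; the package approximates that
integral with a fixed quadrature: `k` equally spaced nodes on
`[-bound, bound]` (default 49 on $[-6, 6]$), weighted by the renormalized
normal density.  The latent density is fixed at N(0, 1) — that is the
identification convention, and the package does not re-estimate it.

The classical estimation route is Bock–Aitkin EM: an E-step computes, for
every observed response pattern, the posterior over quadrature nodes and
aggregates expected counts of 1s and 0s per item and node; an M-step then
maximizes the resulting expected complete-data log-likelihood (the
Q-function) item by item.  Both steps are cheap per item, but the E-step
touches every response pattern in the data, so for large samples the cost
per iteration is high exactly when EM's improvements per iteration become
small — the long tail of EM convergence is paid for at full-data prices.

## The two-stage algorithm

`fit_2pl(..., method = "two_stage")` keeps full-data EM where it is
strong and replaces it where it is weak.

**Stage 1** runs standard EM and monitors
$\delta^{(j)} = \exp[-(\mathrm{LL}^{(j)} - \mathrm{LL}^{(j-1)})]$, the
exponentiated negative improvement in marginal log-likelihood (0 at the
first iteration, where no previous value exists).  On a monotone EM path
$\delta$ lies in $(0, 1]$ and approaches 1 as improvements die out.  When
$\delta$ exceeds a threshold (default 0.90) the iterates are taken to be
in the neighbourhood of the MLE and Stage 2 begins.  If Stage 1 instead
meets the ordinary convergence rule first (largest absolute parameter
change below `tol`, default $10^{-6}$), the fit returns without entering
Stage 2 at all.

**Stage 2** partitions the persons into shuffled disjoint subsets of size
`fraction` × N (default 20%; the remainder, if any, forms one smaller
subset) and cycles through them.  Each subset receives a *partial E-step*
— the same computation as the full E-step, restricted to the subset's
patterns — followed by a single damped Newton update per item,

$$\phi_i \leftarrow \phi_i - \gamma\, H_i^{-1} \nabla_i,$$

with $\nabla_i$ and $H_i$ the analytic gradient and Hessian of the
subset-level Q-function and $\gamma \in (0, 1]$ a fixed step size
(default 0.5).  The Q-function Hessian is negative definite, so
$-H^{-1}\nabla$ is the ascent direction; the update is one generalized-EM
("improve, don't maximize") step.  Items whose 2×2 Hessian is numerically
singular in a given subset are left unchanged for that update.  By
default the partition is re-shuffled at the start of every epoch (a flag
keeps it fixed instead).

Fixed-step stochastic updates do not converge to a point: they oscillate
in a *noise ball* around the MLE.  Rather than tuning a decaying step
size, Stage 2 locates the center of the oscillation by a running average
of the iterates, started after a warm-up of 30 subset updates (counted in
updates, not epochs) so that averaging does not begin while the iterates
are still trending.  Once defined, the averaged values — not the raw
iterates — are fed into every subsequent partial E-step.  Stage 2 stops
when both (i) the largest absolute change in the averaged slopes and
intercepts falls below `tol` and (ii) the variance of the last `window`
(default 10) averaged iterates is below `stability_tol` (default
$10^{-6}$) for every parameter; both checks run once per subset update
after warm-up, since the sources describing the rule do not order them.
An epoch cap (default 200) bounds the run; hitting it flags the fit as
non-converged while still returning the averaged estimates.  Stage 2
never evaluates the full-data log-likelihood — avoiding that cost is the
point of the design — but one final value is computed after termination
for reporting only (it plays no role in any decision).

### What the averaging can and cannot do

Two properties of the running mean matter for interpreting results at
desk scale, and we state them because they are visible in the test suite.
First, the mean permanently retains a $1/n$-weighted share of whatever
transient was still present when averaging began, so configurations that
enter Stage 2 early (small samples reach $\delta > 0.9$ while parameters
still move visibly) carry a deterministic averaging lag.  Second, the
random-walk contribution of the early post-warm-up updates decays only
like $(\text{warmup}/n)^{\gamma}$ over the epoch-capped horizon.  For
well-covered items both effects are far below sampling error at the
package's study sizes ($N = 60{,}000$: shuffle-seed differences
$\approx 0.008$, two engines within $\approx 0.01$).  For items that are
extreme relative to the latent distribution (intercepts beyond roughly
$\pm 6$, where a 20% subset of a small sample contains only a handful of
informative persons) the retained noise can reach several hundredths at
$N = 10{,}000$.  The acceptance suite deliberately pins this
configuration and records the outcome rather than relaxing it.

## Standard errors

EM itself produces no standard errors, so the package offers two routes.

**XPD (empirical cross-product).**  The score vector of a response
pattern — the gradient of its log marginal likelihood, with zeros at
unobserved items — has a closed form in the E-step posterior, so the
information matrix $\sum_r f_r v_r v_r'$ can be accumulated over disjoint
subsets as a byproduct of Stage 2.  The reported matrix is the one
implied by the final epoch: each subset contributes at the working
parameters it was visited with, and subsets the stopping epoch never
reached are finished with a score pass at the final estimates, so every
person contributes exactly once.  (The package materializes those
contributions by a deferred pass at the recorded per-subset parameters,
which is numerically identical to accumulating during the epoch but
avoids paying the score computation in every earlier epoch.)  For
standard-EM fits, the same matrix is computed in one full-data pass at
the estimates.  SEs are square roots of the diagonal of the inverse.

**FIS (Fisher expected information).**  For simulation benchmarking the
package enumerates all $2^I$ response patterns and computes
$\mathcal{F} = \sum_r \pi_r s_r s_r'$ with $\pi_r$ the marginal pattern
probability and $s_r$ the pattern score.  This equals
$\mathcal{J}'\,\mathrm{diag}(\pi)^{-1}\mathcal{J}$ when the rows of
$\mathcal{J}$ are the *probability* gradients $\pi_r s_r$; we implement
the $\sum_r \pi_r s_r s_r'$ form directly, which is the algebraically
sound reading (rows equal to log-likelihood gradients would not give the
Fisher information).  At true parameters $\phi_0$ and sample size $N$,
$[N\mathcal{F}(\phi_0)]^{-1}$ is the gold-standard covariance.
Enumeration is refused above 20 items (the cost is $2^I$), which places
the 100-item pool outside FIS scope by design — that is what XPD is for.
The implementation is verified in the tests against an independent
numerical Hessian of the expected log-likelihood and against dense-grid
brute force at 1–2 items.  A caution for single items: the marginal
information of one binary item is the rank-one Bernoulli form
$(\nabla\pi)(\nabla\pi)'/\pi(1-\pi)$, *not* the textbook item information
integrated over the prior, which is a complete-data quantity.

## Simulation generators

The generators reproduce the package's four study designs and are
first-class, tested code:

* `simulate_2pl()` — plain 2PL sampling: $\eta \sim N(0,1)$, Bernoulli
  responses.
* `sample_true_params()` — slopes and difficulties drawn uniformly from a
  3×3 grid of low/medium/high cells (A in [0.50, 3.50] split at 1.50 and
  2.50; B in [−3, 3] split at ±1.50), equal items per cell, intercepts
  derived as $C = -AB$ and labelled by cutoffs at ±3.75.  The packaged
  banks (`item_bank()`) ship the fixed draws used by the studies, because
  exact reproduction beats re-sampling.
* `build_form_design()` — the large-scale testing scenario: a 100-item
  pool in five 20-item blocks, the ten unordered block pairs as 40-item
  forms, persons assigned to forms uniformly at random (a multinomial
  assignment, not a balanced one), and everything outside a person's form
  missing by design.  Such missingness is ignorable under random
  assignment, so observed-likelihood estimation needs no extra machinery:
  missing entries simply contribute nothing to likelihoods, counts or
  scores.  Patterns that differ only in their missingness mask are kept
  distinct.
* `simulate_testlet_2pl()` — the misspecification generator: a general
  trait plus uncorrelated testlet traits with common variance, each item
  loading equally on the general and its own testlet dimension.
  Estimation always assumes unidimensionality; this generator exists to
  probe robustness to that violation.  At `testlet_var = 0` it reproduces
  `simulate_2pl()` exactly, same seed, same matrix (the testlet draws are
  skipped, not zeroed, so the RNG stream is identical).

What the generators do *not* emulate: non-normal latent distributions,
correlated testlet traits, guessing, polytomous responses, and
person-level dependence.  Green tests therefore certify the algorithms
under the model's own assumptions (plus the testlet departure), not
robustness to real-data pathologies beyond those.

## Numerical choices

* All pattern likelihood work is done on the log scale with log-sum-exp;
  a 100-item pattern underflows double precision otherwise.  For fully
  observed data with at most `enum_limit` (13) items the engines switch
  to a complete-enumeration kernel that builds all $2^I$ pattern
  likelihoods by binary doubling and reduces per-item counts by a
  pairwise-folding tree — $O(2^I K)$ per E-step — which is what makes
  hundreds of Stage-2 epochs at $N = 60{,}000$ affordable; the two
  kernels are property-tested for exact agreement.
* The exact M-step is per-item Newton with step-halving whenever Q would
  decrease (inner tolerance $10^{-10}$, cap 50), which makes the
  "maximize" branch well-defined and preserves EM monotonicity; the
  standalone standard EM always maximizes, reserving the single damped
  step for Stage 2.
* Starting values are $a_i = 1$, $c_i = 0$ — the conventional neutral
  start.
* Items with zero observed variance are rejected at load (their MLEs
  diverge); so are duplicate item ids, non-binary cells and all-missing
  rows, each named in the error.
* Information matrices are inverted by symmetric (Cholesky) solve after
  an eigenvalue check; singularity produces an error naming the
  parameters loading on the null space, and condition numbers above
  $10^{10}$ produce a warning.
* One root seed (the `seed` argument) covers all internal randomness;
  derived child seeds stay below $2^{31}$.

## Problem sizes in the packaged studies

`run_study()` defaults to desk-scale replication counts (study 1: 20,
study 2: 200, study 3: one replication at $N = 10^5$, study 4: 20), all
configurable back to larger designs.  The SE-calibration study that the
acceptance machinery re-runs uses 200 replications of $N = 60{,}000$
persons × 12 items at subset fractions 0.2–1.0 — the package's chosen
desk-scale rendering of the full 1000-replication design — and the
parameter-recovery check uses 100 replications at the same sample size.
Runtime comparisons (`time_change_pct()`) are reported by the harness but
never asserted by tests: they are hardware facts, not model facts.

## Known limitations

* Unidimensional 2PL only; the testlet model is a data generator, not an
  estimable model.  No 3PL/graded responses, no latent density
  estimation, no adaptive Gauss–Hermite quadrature.
* The Stage-2 averaged-change tolerance of $10^{-6}$ is strict relative
  to the $1/n$ decay of a running mean, so at realistic scales the epoch
  cap is the effective stopping rule and two-stage fits are typically
  flagged non-converged even when the averaged estimates are excellent
  (they agree with standard EM to ~$10^{-2}$–$10^{-3}$ at study sizes).
  The flag is honest bookkeeping, not a defect signal.
* FIS enumeration is exponential in items (guarded at 20).
* Extreme items (difficulties beyond ±3 with high slopes) are estimated
  with visibly more noise by both engines, and the subset-driven stage
  amplifies this at small sample sizes; see the averaging discussion
  above.
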