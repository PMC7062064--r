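---
title: "Selecting exponential mixtures for inter-event times by MDL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting exponential mixtures for inter-event times by MDL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ietmix)
```

## The modelling problem

Sequences of time-stamped events produced by human individuals — contacts
recorded by proximity sensors, emails, messages, transactions — are usually
bursty: the durations between consecutive events (inter-event times, IETs)
have apparently long-tailed distributions rather than the exponential
distribution a Poisson process would produce.  One mechanistic explanation is
that an individual switches between a small number of behavioural states
(say, active and inactive) and generates events as a Poisson process within
each state.  Under that hypothesis the IET distribution should be close to a
mixture of exponential distributions (EMM),

$$p(\tau;\pi,\mu)=\sum_{j=1}^{k}\frac{\pi_j}{\mu_j}\,
  e^{-\tau/\mu_j},\qquad \pi_j\ge 0,\ \textstyle\sum_j\pi_j=1,\ \mu_j>0,$$

and the scientifically interesting quantity is $k$, the number of states the
data support.  `ietmix` fits EMMs and selects $k$ with six criteria,
emphasising codelength (minimum description length, MDL) criteria that remain
valid for mixtures.

## Estimation

`em_fit()` runs the standard EM iteration: the E step computes
responsibilities $\gamma_{ij}\propto \pi_j p(\tau_i;\mu_j)$ with rows
normalised, and the M step sets $\pi_j$ to the mean responsibility and
$\mu_j$ to the responsibility-weighted mean of the data.  Three numerical
choices matter:

* **Initialization.** Weights start at $1/k$ and $\log_{10}\mu_j^{(0)}$ is
  drawn uniformly on $[\log_{10}\tau_{\min},\log_{10}\tau_{\max}]$
  (`em_init()`).  Means in real IET data span several orders of magnitude;
  a log-uniform draw places most initial means at small values while still
  covering the tail.
* **Stopping.** The iteration stops when the relative change of the marginal
  log-likelihood falls below `tol` (default $10^{-10}$) or after `max_iter`
  (default 1000) iterations.  Convergence-based stopping dominates any fixed
  iteration count in effect; both knobs are exposed.
* **Log-space densities and a collapse guard.** All densities are evaluated
  in log space with log-sum-exp reductions, since with $\mu$ ratios of
  $10^2$–$10^7$ linear-space products underflow.  A component whose weight
  drops below $10^{-12}$, or whose mean drops below
  $10^{-12}\min_i\tau_i$, is frozen out of the E step for the rest of the
  run; it ends the run unused.

Because the mixture likelihood has local maxima, `fit_emm()` restarts EM
(10 times by default; restart $r$ uses sub-seed `seed + r - 1` for full
reproducibility) and keeps the run with the largest *joint* likelihood of
data and completed assignments, described next.

## Latent variable completion

An EMM is not identifiable — with $k=2$ and $\mu_1=\mu_2$, every weight
split gives the same distribution — so the classical asymptotic-normality
argument behind AIC and BIC fails for the marginal likelihood.
`complete_latent()` restores identifiability by hard-assigning each
$\tau_i$ to the component maximising $\pi_j p(\tau_i;\mu_j)$ (ties go to the
lowest index, for determinism), dropping components that receive no point.
With $n_j$ points in component $j$, $k^*$ the number of used components,
$\hat\pi_j=n_j/n$ and $\hat\mu_j$ the within-component mean, the joint
codelength of data and assignments is

$$-\log p(\tau,\hat z;\hat\theta)=
  nH\!\Big(\frac{n_1}{n},\dots,\frac{n_{k^*}}{n}\Big)
  +\sum_j n_j\log\hat\mu_j+n .$$

$k^*$, not the requested $k$, enters every completed criterion: requesting
many components is harmless if they collapse.

## The six selection criteria

With $L=-\log p(\tau;\hat\theta_{\mathrm{EM}})$ and
$J=-\log p(\tau,\hat z;\hat\theta)$:

| criterion | codelength |
|---|---|
| AIC | $L + 2k-1$ |
| BIC | $L + \frac{2k-1}{2}\log n$ |
| AIC\_LVC | $J + 2k^*-1$ |
| BIC\_LVC | $J + \frac{k^*-1}{2}\log n + \frac12\sum_j\log n_j$ |
| NML\_LVC | $J + \log C_{\mathrm{EMM}}(n,k^*) + \ell(m'_{\min}) + \ell(m'_{\max})$ |
| DNML | $L_{\mathrm{NML}}(\tau\mid\hat z) + L_{\mathrm{NML}}(\hat z) + \ell(m'_{\min}) + \ell(m'_{\max})$ |

All scores are in nats and are minimised.  AIC and BIC are computed from the
marginal likelihood of the restart chosen by joint likelihood — the package
runs one restart policy, not two.

### Parametric complexities

The normalized-maximum-likelihood (NML) codelength adds to the maximised
likelihood the log *parametric complexity*, the log-integral of the maximised
likelihood over all datasets.  For a single exponential distribution with the
mean confined to $[e^{m_{\min}}, e^{m_{\max}}]$ (integer bounds, so that they
are cheap to encode),

$$\log C_{\exp}(n)=n\log n-n-\log\Gamma(n)+\log(m_{\max}-m_{\min}),$$

implemented in `log_c_exp()`.  The completed-mixture complexity
$C_{\mathrm{EMM}}(n,k^*)$ follows the exact convolution recursion

$$C_{\mathrm{EMM}}(n,k+1)=\sum_{r_1+r_2=n}\binom{n}{r_1}
  \Big(\frac{r_1}{n}\Big)^{r_1}\Big(\frac{r_2}{n}\Big)^{r_2}
  C_{\mathrm{EMM}}(r_1,k)\,C_{\mathrm{EMM}}(r_2,1)$$

with $C_{\mathrm{EMM}}(n,1)=(n/e)^n (m'_{\max}-m'_{\min})/\Gamma(n)$ and the
conventions $0^0=1$, $C_{\mathrm{EMM}}(0,\cdot)=1$ (required for the boundary
terms $r_1\in\{0,n\}$; they agree with direct enumeration on tiny cases).
The recursion costs $O(n^2k^*)$ and is implemented in compiled code in log
space — $(n/e)^n$ overflows double precision near $n\approx 700$
(`log_c_emm()`).  The DNML criterion instead encodes the assignment sequence
with the multinomial complexity $C_{\mathrm{mult}}(n,k^*)$, computed by the
$O(n+k^*)$ recursion
$C_{\mathrm{mult}}(n,k)=C_{\mathrm{mult}}(n,k-1)+\frac{n}{k-2}
C_{\mathrm{mult}}(n,k-2)$, also in log space (`log_c_mult()`).  Both
recursions are validated in the test suite against brute-force enumeration
over assignments/compositions at small $n$.

### Integer bounds and their code

The component means are confined to $[e^{m'_{\min}},e^{m'_{\max}}]$ with
$m'_{\min}=\lfloor\log\min_j\hat\mu_j\rfloor$ and
$m'_{\max}=\lceil\log\max_j\hat\mu_j\rceil$ (`mu_bounds()`).  When floor and
ceiling coincide (all means on one integer power of $e$) the upper bound is
widened by one; a zero-width range would give a codelength of $-\infty$.
The two integers are themselves encoded with a universal prefix code
(`integer_codelength()`): a sign bit plus Rissanen's universal code for
$|m|+1$, $\ell_N(j)=\log c_0+\log 2\,(\log_2 j+\log_2\log_2 j+\cdots)$
keeping positive terms only, $c_0\approx 2.865$.  The iterated logarithm is
taken base 2 because that is the base for which the series satisfies the
Kraft inequality (the natural-base analogue diverges); the result is
converted to nats.  Any valid prefix code here shifts all models' scores by
$O(1)$ nats in the same direction, so the choice rarely affects which $k$
wins; the function is deliberately small and swappable.

### Tie-breaking

`select_model()` scans a candidate grid (default $k=1,\dots,10,20,50,100$)
and returns, per criterion, the $k$ minimising the score, breaking ties
toward smaller $k$: exactly equal scores in practice mean the extra
components collapsed onto the same effective model.

## Power-law baselines

For comparison with the heavy-tail literature the package fits two pure
power laws.  `pareto_mle()` is the closed-form maximum-likelihood Pareto
fit, $\hat b=\min_i\tau_i$ and
$\hat a=1+[\frac1n\sum_i\log(\tau_i/\hat b)]^{-1}$.  `plfit()` implements
the continuous-data dialect of the KS-minimising tail fit: every unique data
value is a candidate threshold, the tail exponent is the Pareto MLE on the
tail, and the threshold minimising the Kolmogorov–Smirnov distance between
the empirical and fitted tail CDFs wins (candidates with fewer than two tail
points are skipped; no small-tail penalty is applied).
`truncated_likelihood_comparison()` evaluates EMM, Pareto and tail fits on
three nested point sets (all points; $\tau>\min_i\tau_i$; $\tau\ge\hat b$)
*without* renormalising the full-data fits on the subsets — on the tail set
the EMM deliberately pays for the mass it assigns below $\hat b$.  For
survival and odds-ratio plots the tail fit is rescaled by the tail fraction
$n'/n$ (`rescaled_tail_survival()`), since it only describes the upper
$n'$ points.

## Preprocessing raw event streams

`events_to_iets()` applies the conventions used for sensor-based contact
data: events recorded at the same time are aggregated; runs of events in
consecutive resolution-sized windows (spacing exactly equal to the
resolution, e.g. 20 s) are collapsed to their first event, because they
represent one continuing contact rather than many short ones; and,
optionally, gaps whose endpoints fall on different days are discarded, since
overnight gaps reflect the circadian rhythm rather than the within-day event
dynamics.  An event at time $t$ belongs to day
$\lfloor (t-\mathrm{day\_origin})/\mathrm{day\_length}\rfloor$; no calendar
convention is imposed, and the anchoring of day boundaries (local midnight
versus recording start) is left configurable because recordings differ.
Zero gaps surviving preprocessing raise an error rather than being dropped
silently: the merging rules guarantee a positive minimum, so a zero
indicates mis-set flags, and the log-uniform initializer needs
$\tau_{\min}>0$.  For directed records (messages, ratings) events are
attributed to the sender only; for undirected contacts, to both endpoints.

## What the synthetic generators emulate

`generate_emm_dataset()` draws labelled i.i.d. samples from a known EMM, the
exact model the estimator assumes; `generate_switching_events()` simulates
the mechanistic story instead — a modulated Poisson process that alternates
exponentially distributed dwell periods between states and emits events at
the state's rate.  With dwell times long relative to the event rates its
IET distribution approaches an EMM whose weights are proportional to the
expected event count per dwell; the test suite checks this convergence in
Kolmogorov distance.  Neither generator reproduces circadian rhythms,
weekly cycles, correlations between consecutive IETs, or measurement
artefacts of real sensors, so passing recovery tests show correctness of the
estimator under its own assumptions, not that real data are EMMs.
Ground-truth labels travel in an attribute that no fitting code path reads.

## Experiment sizes and reproducibility

Every stochastic function takes an explicit integer seed and is a pure
function of it; `fit_emm()` and `select_model()` derive deterministic
sub-seeds per restart and grid entry, and `recovery_experiment()` per
repeat.  The packaged recovery experiments use $n=2000$ IETs per repeat, 50
repeats, 10 restarts and the candidate grid $k\in\{1,2,3,4\}$ — the grid
brackets the true component counts (1 and 2) on both sides while keeping a
full experiment to a few minutes; enlarging the grid changes the selected
$k^*$ only through additional collapsing components.  Parameter-recovery
checks use $n=10^4$ with the well-separated truth
$\pi=(0.5,0.5),\ \mu=(1,100)$ and require means within 10% and weights
within 0.05 of truth.

## Known limitations

* The NML codelength of the *marginal* (uncompleted) EMM is not computed;
  no closed form is available, and the completed codelengths are the point
  of the method.
* AIC/BIC for $k\ge2$ are reported for comparison despite lacking
  theoretical justification for non-identifiable models.
* The $C_{\mathrm{EMM}}$ recursion is $O(n^2k^*)$; for $n\gtrsim10^5$ and
  large grids it dominates runtime.
* `plfit()` pins one dialect of the tail-fitting algorithm; other public
  implementations differ in candidate pruning and discreteness handling and
  can select slightly different thresholds on empirical data.
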