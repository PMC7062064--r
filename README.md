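# ietmix

Exponential mixture models (EMMs) for inter-event times, with model
selection by minimum description length.

## The problem

Event streams recorded from human behaviour — sensor-detected face-to-face
contacts, emails, messages, online transactions — are bursty: the
inter-event times (IETs) between consecutive events of one individual
typically look long-tailed, not exponential.  A mechanistic explanation is
that individuals switch among a few hidden states (active, inactive, ...)
and behave as a Poisson process within each state, which makes the IET
distribution a mixture of exponentials,

    p(τ; π, μ) = Σ_j (π_j / μ_j) exp(−τ / μ_j),    j = 1..k.

The question `ietmix` answers is: **how many components k do the data
actually support, and does an EMM describe them as well as the power laws
habitually fitted to such data?**

Choosing k is not routine, because mixture models are non-identifiable and
the classical AIC/BIC theory does not apply to their maximum-likelihood
estimator.  The package therefore completes the latent component
assignments (hard assignment ẑ, effective component count k* = number of
components actually used) and applies codelength criteria to the joint
likelihood of data and assignments:

* `AIC`, `BIC` — marginal-likelihood criteria, for reference;
* `AIC_LVC`, `BIC_LVC` — the same penalties applied to the completed joint
  likelihood, with k*;
* `NML_LVC` — the normalized-maximum-likelihood codelength of the completed
  model, with the exact O(n²k*) parametric-complexity recursion for the
  completed exponential mixture;
* `DNML` — the decomposed NML codelength: NML of the data given the
  assignments plus NML of the assignment sequence (multinomial complexity,
  O(n + k*) recursion).

All criteria are codelengths in nats; smaller is better.  Pareto
maximum-likelihood and KS-minimizing power-law tail ("PLFit") baselines,
raw-event preprocessing, and seeded synthetic generators (labelled EMM
samples, state-switching Poisson streams) complete the pipeline.  Intended
users: researchers in computational social science, temporal networks and
epidemiological modelling who work with per-individual event timestamps.

## Worked example

Simulate a bursty individual whose true behaviour has two states (mean IETs
1 and 100 time units, equally likely), then ask each criterion for k:

```r
library(ietmix)

truth <- emm_params(weights = c(0.5, 0.5), means = c(1, 100))
tau <- generate_emm_dataset(truth, n = 2000, seed = 42)

report <- select_model(tau, k_grid = 1:5, seed = 7)
print(report)
#> Model selection over k in {1, 2, 3, 4, 5}, n = 2000
#> Selected models:
#>  criterion k k_star    score
#>        AIC 2      2 7896.565
#>        BIC 2      2 7904.967
#>    AIC_LVC 3      2 7956.259
#>    BIC_LVC 3      2 7963.967
#>    NML_LVC 3      2 7971.670
#>       DNML 3      2 7972.134
```

Every criterion recovers k* = 2 effective components (the AIC_LVC–DNML rows
request k = 3 but one component collapses; k*, not k, is the scientific
answer).  The completed fit recovers the generating parameters:

```r
print(report$fits[["2"]])
#> EMM fit: k = 2 (k* = 2), n = 2000, marginal log-lik -7893.5654, 16 iteration(s)
#>   weight_hat  mean_hat  n_j
#> 1      0.507   1.00279 1014
#> 2      0.493 102.43735  986
```

Comparison with the power-law fits, on all points and on the tail the
KS-minimizing fit selects for itself:

```r
pl <- plfit(tau)
cmp <- truncated_likelihood_comparison(tau, report$fits[["2"]],
                                       pareto_mle(tau), pl)
print(cmp)
#> n = 2000, n'' (tau > min) = 1999, n' (tau >= b_hat) = 41
#>   model       all above_min      tail
#>     EMM -7893.565 -7892.862 -401.7894
#>  Pareto -9707.601 -9711.819 -398.1008
#>   PLFit        NA        NA -226.6276
```

On the full data the EMM's log-likelihood beats the Pareto fit by some 1800
nats; on the 41-point tail the tail-optimized fit wins, as expected — it
discards 98% of the points and pays nothing for them, while the EMM's
likelihood there still includes the mass it devotes to small IETs.

Raw event streams are handled by `read_events()` + `events_to_iets()`
(same-time aggregation, merging of runs at the recording resolution,
optional exclusion of cross-day gaps), or from the shell via the
`exec/ietmix` script:

```sh
Rscript exec/ietmix preprocess --input events.txt --resolution 20 \
    --exclude-cross-day --min-iets 100 --out out/
Rscript exec/ietmix fit-select --input out/u1.iet --criterion dnml --seed 1 --out out/
```

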