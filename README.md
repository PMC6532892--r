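# onglide

Attractor-landscape modelling of nuclear pitch accent onglides.

## The problem

In German focus intonation, speakers signal the pragmatic status of a word
in two ways at once: categorically, by choosing a falling versus rising
nuclear pitch accent, and continuously, by making rises larger or smaller.
Both move together as focus narrows (broad → narrow → contrastive): rises
become both more frequent and bigger. A model that treats category choice
and phonetic realisation as separate modules needs two mechanisms for what
looks like one gradient.

`onglide` implements a dynamical-systems account in which the signed tonal
onglide *x* (semitones of f0 movement toward the accent target; negative =
falling, positive = rising) is the state of a noisy double-well system

    V(x) = 18x^4 − k·x^3 − 7.5x^2,
    x_{i+1} = x_i + F(x_i)·dt + σ·√dt·η_i,   F = −dV/dx,  η ~ N(0,1)

with one attractor per accent category. A single control parameter *k*
tilts the landscape: raising *k* deepens the rising well (more rises)
while moving its minimum outward (bigger rises). Producing one accent is
one simulated trajectory over a fixed time window; its final state is the
onglide. The long-run ensemble follows the stationary law
p(x) ∝ exp(−2V(x)/σ²), which the package evaluates by quadrature as a
deterministic oracle and fast fitting backend.

The package covers the full analysis pipeline: landscape algebra (fixed
points, bifurcation, stationary densities), the stochastic simulator
(Euler–Maruyama, C++ kernel, bit-reproducible under a seed), the
sign-preserving log normalisation `sign(y)·log(|y|+1)`, fall/rise
summaries, speaker-strategy grouping (fall users vs. rise-dominant), a
simulation-based grid search for *k* per focus condition and group, a
two-Gaussian EM mixture with bootstrap contrasts, and a synthetic-data
generator emulating a 27-speaker × 3-condition × 20-word production study.

## Worked example

```r
library(onglide)

ls <- landscape("cubic_tilt", k = 5.4)
fixed_points(ls)
#>     location      kind  potential curvature degenerate
#> 1 -0.3575953 attractor -0.4177971  24.20696      FALSE
#> 2  0.0000000  repeller  0.0000000 -15.00000      FALSE
#> 3  0.5825953 attractor -1.5397677  39.43804      FALSE

rising_probability(ls)                        # stationary mass at x > 0
#> 0.8831
mean(simulate(ls, nsim = 2500, seed = 1) > 0) # ensemble agrees
#> 0.8824
```

At a strong rightward tilt (k = 5.4) the rising attractor is deeper
(−1.54 vs −0.42) and sits further out (0.58 vs −0.36), and ~88% of
simulated accents come out rising.

Fitting the tilt per focus condition on synthetic study data:

```r
d <- generate_onglides(generator_spec(seed = 42))
d$onglide_norm <- signed_log(d$onglide_st)
fit <- landscape_fit(onglide_norm ~ condition, d, method = "quadrature")
summary(fit)
#>      stratum k_hat   n obs_prop_rising fit_prop_rising obs_median_rising fit_median_rising distance
#>        broad   0.2 540          0.5130          0.5169            0.4389            0.4135  0.02931
#>  contrastive   5.8 540          0.9000          0.9007            0.5853            0.5623  0.02372
#>       narrow   3.2 540          0.7537          0.7546            0.5101            0.4885  0.02248
```

One tilt per condition reproduces both the fall/rise balance
(`obs_prop_rising` vs `fit_prop_rising`) and the location of the rising
mode, and the fitted tilts are ordered broad < narrow < contrastive —
the "volume control" the model posits for prosodic prominence. Use
`method = "simulation"` for the reference stochastic grid search,
`plot(fit)` for the distance curves, and `run_pipeline()` to chain
generation, normalisation, summaries, grouping, fitting and the mixture
analysis into one reproducible run with CSV outputs.

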