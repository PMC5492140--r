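# evoentropy

Macroevolutionary diversity as a lognormal stochastic process, with an
entropy-based scale of evolutionary stage.

## The problem and the model

How "far along" is the evolution of life at a given epoch — on Earth, or on a
newly discovered exoplanet?  `evoentropy` implements a compact stochastic
framework that turns that question into a number of bits.

The number of living species (or genera) through time is modelled as a
stochastic process *L(t)* whose marginal at each time *t* > *ts* is lognormal:

    L(t) ~ Lognormal( M(t),  sigma_L^2 (t - ts) )

Five boundary parameters determine everything: the start time *ts* and its
known count *Ns* (one species at the origin of life), the end time *te*, and
the mean count *Ne* and standard deviation *dNe* at *te*.  The log-location
*M(t)* is chosen so the process mean E[L(t)] = m(t) follows a prescribed
mean-value curve through (*ts*, *Ns*) and (*te*, *Ne*) — exponential (the
mean of a geometric Brownian motion), straight line, parabola, a cubic with
prescribed local extrema (the non-monotonic Phanerozoic genus-diversity
trend), or a generic polynomial.  The volatility is calibrated from the
end-time spread:

    sigma_L = sqrt( ln(1 + (dNe/Ne)^2) / (te - ts) )

Three constructions are layered on top:

* **Peak locus** — for every time *p* there is a unique b-lognormal density
  (a lognormal shifted to start at a "birth" time *b*; one per species)
  whose peak sits exactly on the mean curve at (*p*, m(*p*)).  Its
  parameters mu(*p*), sigma(*p*), *b*(*p*) are closed-form.
* **EvoEntropy** — the sign-reversed, origin-anchored Shannon differential
  entropy of that family, EvoEntropy(*p*) = −[H(*p*) − H(*ts*)], in bits per
  individual: zero at the origin of life, growing as organisms organize.
* **Molecular clock** — when the mean is exponential with rate *B* and the
  volatility tie sigma_L^2 = 2*B* holds, EvoEntropy is *exactly* linear:
  (B/ln 2)(p − ts), the same straight-line-in-time behaviour as the
  molecular clock of molecular evolution.

A Monte-Carlo simulator draws trajectories whose ensembles recover the
analytic mean and standard-deviation bands, and YAML scenario files plus a
small CLI drive the whole pipeline to CSV/JSON artifacts.

## Worked example: Phanerozoic genus diversity

One genus 530 Myr ago growing to 4000 ± 1000 genera today along a cubic
trend with a local maximum 400 Myr ago and a local minimum 220 Myr ago:

```r
library(evoentropy)
proc <- lognormal_process(ts = -530, Ns = 1, te = 0, Ne = 4000, dNe = 1000,
                          family = "cubic", tMax = -400, tmin = -220)
summary(proc)
#> Lognormal diversity process --- summary
#>   start: t = -530, count = 1 (known exactly)
#>   end:   t = 0, mean count = 4000, sd = 1000
#>   mean-curve family:      cubic
#>   volatility sigmaL:      0.0106951 time^(-1/2)
#>   band at te:             mean 4000, +/- 1000
#>   variation coeff at te:  0.25

evo_entropy(proc, p = c(-530, -400, -220, 0))
#> [1]  0.000000 10.047466  9.234165 12.073837
```

The volatility rounds to 0.011 Myr^(-1/2).  EvoEntropy starts at 0 bits at
the Cambrian origin, jumps to about 10 bits by the first diversity maximum,
dips with the end-Permian trough, and reaches **12.074 bits/individual
today**.  Under exponential growth on Earth as a whole (1 species 3.5 Gyr
ago to 5×10⁷ today) the clock instead reads:

```r
earth <- boundary_conditions(ts = -3.5e9, Ns = 1, te = 0, Ne = 5e7, dNe = 3e7)
gbm_evo_entropy(earth, p = 0)
#> [1] 25.57542        # = log2(5e7) bits
```

Simulation cross-check — 1000 trajectories of the cubic process:

```r
ens <- simulate_paths(proc, seq(-530, 0, length.out = 54),
                      n_paths = 1000, seed = 1)
st <- ensemble_stats(ens)
c(st$mean[54], st$stddev[54])   # 4042.6, 1012.4  (analytic: 4000, 1000)
recover_sigma(ens)              # 0.01071         (analytic: 0.01070)
```

The same pipeline is scriptable:

```sh
Rscript inst/cli/evoentropy-cli.R run --scenario markov-korotayev-cubic \
    --out artifacts --seed 3 --paths 1000
```

which writes band, peak-locus, entropy and ensemble CSVs plus a JSON
summary for the shipped scenario (`earth-gbm` and
`markov-korotayev-cubic` fixtures live in `inst/extdata/`).

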