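---
title: "Methods: lognormal diversity processes, the peak locus, and EvoEntropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lognormal diversity processes, the peak locus, and EvoEntropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoentropy)
```

## The model

`evoentropy` treats the number of living species (or genera) on a planet as
a stochastic process $L(t)$ whose marginal law at every $t > t_s$ is
lognormal,

$$L(t) \sim \mathrm{Lognormal}\!\big(M(t),\ \sigma_L^2 (t - t_s)\big),$$

with the point mass $\Pr\{L(t_s) = N_s\} = 1$ at the start.  This is an
assumption, not a derivation: lognormality is the natural "multiplicative
noise" law for populations whose growth compounds, and it makes both the
mean and the entropy analytically tractable.  The model is fully specified
by five boundary numbers:

| parameter | meaning | units |
|---|---|---|
| $t_s$ | start time (origin of life; count known exactly) | time |
| $N_s$ | count at $t_s$ (1 in origin-of-life scenarios) | count |
| $t_e$ | end time (0 = the present) | time |
| $N_e$ | mean count at $t_e$ | count |
| $\delta N_e$ | standard deviation of the count at $t_e$ | count |

Time units are abstract; each scenario file declares its own (`yr` or
`Myr`), and every formula is unit-consistent provided $\sigma_L$ carries
time$^{-1/2}$.  The lognormal mean identity
$m(t) = e^{M(t)} e^{\sigma_L^2 (t-t_s)/2}$ inverts exactly, so prescribing
any positive mean curve $m(t)$ determines $M(t)$; and requiring the process
standard deviation at $t_e$ to equal $\delta N_e$ calibrates the volatility,

$$\sigma_L = \sqrt{\frac{\ln\!\big[1 + (\delta N_e/N_e)^2\big]}{t_e - t_s}}.$$

The standard-deviation band is $m(t)\big[1 \pm \sqrt{e^{\sigma_L^2 (t-t_s)}
- 1}\big]$.  For large $\sigma_L$ the lower curve goes negative; this is a
faithful property of the mean-minus-one-sd curve of a skewed law, and the
package deliberately does **not** clip it in data exports (a plotting layer
may clip visually).

## Mean-curve families

All families are calibrated through $(t_s, N_s)$ and $(t_e, N_e)$:
exponential (GBM mean) with rate $B = \ln(N_e/N_s)/(t_e - t_s)$; the
straight line; the parabola in $t - t_s$ with vertex at $t_e$; the cubic in
$t - t_s$ whose derivative vanishes exactly at two prescribed interior
instants $t_{Max} < t_{min}$ (the Phanerozoic shape: a Devonian-era maximum
and an end-Permian minimum); and a generic Horner-evaluated polynomial.
Curves may be evaluated at $t < t_s$ for plotting, but all process-level
operations reject times before $t_s$, where the process is undefined.

Orientation of the parabola follows the boundary values: with $N_e > N_s$
it increases toward its vertex, with $N_e < N_s$ it decreases (the
mass-extinction use).  The formula is implemented as stated and no
orientation is imposed.  Exotic cubic configurations can dip below zero
between the extrema; the curve evaluators allow this (they are just
polynomials), while the peak-locus and entropy consumers reject
non-positive means, since $m$ enters a logarithm and a peak height.

No fitting is performed anywhere: curves are forward-evaluated from stated
parameters.  Fitting diversity data is out of scope.

## The peak locus

For each abscissa $p$ there is exactly one b-lognormal — a lognormal
density in time starting at a birth instant $b$, representing one species'
lifetime curve — whose peak lies at $(p, m(p))$:

$$\sigma(p) = \frac{e^{\sigma_L^2 p / 2}}{\sqrt{2\pi}\, m(p)}, \qquad
  \mu(p) = \frac{e^{\sigma_L^2 p}}{4\pi\, m(p)^2} - \frac{p\,\sigma_L^2}{2},
  \qquad b(p) = p - e^{\mu(p) - \sigma(p)^2}.$$

Two conventions deserve comment.

**Absolute-$p$ exponents.**  The exponents above use the absolute abscissa
$p$, not $p - t_s$.  For $t_s \neq 0$ this makes $\mu(p)$ and $\sigma(p)$
depend on where the time origin is placed — an origin-dependence the
framework does not otherwise have.  The package implements the absolute
convention as the default because it is the one that reproduces the
published present-day Phanerozoic entropy value; the origin-anchored
alternative ($p - t_s$ in every exponent) is exposed behind
`convention = "shifted"` for sensitivity analysis.  The two coincide when
$t_s = 0$.

**Boundary form.**  Substituting $e^{\sigma_L^2} = [1 +
(\delta N_e/N_e)^2]^{1/(t_e - t_s)}$ rewrites the locus purely in the five
boundary parameters (`peak_locus_boundary()`); the package verifies the two
forms agree to $10^{-12}$ relative.

$p$ is allowed anywhere $m(p) > 0$, including beyond $t_e$: the
construction is pointwise, with no coupling between abscissae.

## EvoEntropy

The Shannon differential entropy of the locus member at $p$, in bits, is
$H(p) = \frac{1}{\ln 2}\big[\ln(\sqrt{2\pi}\sigma(p)) + \mu(p) +
\tfrac12\big]$; differential entropy can be negative for narrow densities,
which is not an error since only differences are used.  EvoEntropy anchors
it at the origin of life and flips the sign so that increasing organization
reads as increasing bits:

$$\mathrm{EvoEntropy}(p) = -\big[H(p) - H(t_s)\big]
  = \frac{1}{\ln 2}\left\{\frac{e^{\sigma_L^2 t_s}}{4\pi N_s^2}
  - \frac{e^{\sigma_L^2 p}}{4\pi\, m(p)^2}
  + \ln\frac{m(p)}{N_s}\right\}.$$

Two modes are exposed, because the framework itself is ambivalent about
$\delta N_e$:

* `"with_end_stddev"` (default) keeps the calibrated $\sigma_L$ in the two
  power terms.  This is the form under which the cubic Phanerozoic scenario
  gives **12.074 bits/individual** at $p = 0$.
* `"squashed"` sets the power terms to one — the $\delta N_e = 0$ limit, a
  property of the deterministic trend alone.  The same scenario then gives
  12.081 bits.  One can argue EvoEntropy, being a single deterministic
  curve, should not depend on the end-time spread at all; yet the published
  present-day value is reproduced only with the spread retained.  The
  package implements both, documents both, and declares neither "correct".

The dominant term for large counts is $\ln m(p)/\ln 2$; the constant
$1/(4\pi) \approx 0.0795775$ and the inverse-square term are small
corrections, so the curve is logarithm-shaped: nearly vertical at the
Cambrian-like onset, flattening later, with no interior extrema when the
mean is monotone.

**The molecular clock.**  For an exponential mean with rate $B$ *and* the
GBM volatility tie $\sigma_L^2 = 2B$, the first two terms cancel exactly
and EvoEntropy collapses to the straight line $\frac{B}{\ln 2}(p - t_s)$ —
the same linear-in-time behaviour as the molecular clock, with the slope as
divergence rate.  Two GBM calibrations therefore coexist in the package,
and they are not the same process:

* `lognormal_process(..., family = "gbm")` — boundary calibration:
  $B = \ln(N_e/N_s)/(t_e - t_s)$ and $\sigma_L$ from $\delta N_e$.  The
  closed form `gbm_evo_entropy()` is its exact clock line; at $p = t_e$ it
  equals $\log_2(N_e/N_s)$ (25.575 bits for $N_e = 5\times 10^7$).
* `gbm_process(A, B)` — the tied construction with $\sigma_L =
  \sqrt{2B}$ and time origin 0.  Only under the tie is the locus
  $\sigma(p)$ constant in $p$ and the locus EvoEntropy exactly linear; the
  package's linearity tests use this construction.  (Without the tie the
  "squashed" EvoEntropy of an exponential mean is *not* exactly linear —
  its inverse-square term still varies near $t_s$; the cancellation in the
  clock theorem genuinely needs the tie.)

## Simulator

The framework specifies only the marginals of $L(t)$, not its correlation
structure.  The simulator commits to the minimal consistent choice — a
single standard Brownian driver per path,

$$L(t) = \exp\!\big(M(t) + \sigma_L W(t - t_s)\big),$$

which has exactly the required marginals, is Markovian, and reduces to
classical geometric Brownian motion for the exponential mean.  This is an
implementation choice, not a claim of the framework.  Reproducibility: one
root seed; per-path seeds are drawn sequentially from the root-seeded
stream, so enlarging the ensemble never alters earlier paths.  Every path
starts at exactly $N_s$ and stays strictly positive by construction.
`recover_sigma()` inverts the variation-coefficient identity from the
sample coefficient of variation at the final grid time.

What the synthetic ensembles emulate is the *model's* stochasticity, under
its own lognormal-marginal and shared-driver assumptions.  They do not
emulate features of real diversity data — sampling and preservation biases
of the fossil record, discrete extinction pulses, taxonomic reassignment
noise, or correlation structure beyond Markovian — so passing
recovery tests demonstrates internal consistency of the calibration, not
fidelity to empirical biodiversity curves.

## Numerical choices

* The degenerate marginal at $t = t_s$ (and everywhere when $\sigma_L = 0$)
  is a distinct `point_mass` object, never a limiting density; consumers
  must branch on it.
* Quadrature checks substitute $u = \ln n$ so that near-delta lognormal
  spikes (the peak-locus members have $\sigma(p) \sim 10^{-4}$ in the
  Phanerozoic scenario) are integrated over their actual support;
  normalization is verified to $10^{-8}$ and first moments to $10^{-6}$
  relative.
* Polynomials are Horner-evaluated; the cubic is assembled so its
  derivative factors exactly through the prescribed extrema, and a zero
  structural denominator raises a degenerate-configuration error rather
  than returning `Inf`.
* Closed-form identities (boundary vs volatility parameterisations, locus
  entropy vs direct b-lognormal entropy) are asserted at $10^{-12}$ to
  $10^{-10}$; "exact" linearity of the clock is asserted at the
  machine-rounding level of second differences.

## Problem sizes

The shipped scenarios use 201-point evaluation grids.  The test suite runs
property checks on dozens of randomized processes and a
$10^5$-path ensemble on a 21-point grid for the recovery check (end-time
mean within 1%, spread within 3%, volatility within 5% — tolerances set by
the central-limit scaling at that ensemble size); the whole suite
completes in well under a minute.  These sizes are the package's own
defaults; all generators scale.

## Limitations

* The framework is parametric and forward-only: no likelihoods, no fitting
  to empirical diversity databases, no uncertainty on the five boundary
  numbers themselves.
* One b-lognormal per species is a metaphor for cladistic succession; no
  tree topology is represented.
* The absolute-$p$ exponent convention makes locus parameters
  origin-dependent for $t_s \neq 0$ (see above); results quoted in bits
  are convention-dependent in the fourth significant figure for the
  scenarios shipped.
* Bits are the only exposed unit (nats are internal); "bits per
  individual" inherits the framework's interpretation of the b-lognormal
  as an individual-level lifetime density.
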