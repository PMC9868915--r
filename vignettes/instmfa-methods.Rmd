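---
title: "Models and methods in instmfa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in instmfa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(instmfa)
```

# The estimation problem

Isotopically non-stationary metabolic flux analysis (INST-MFA) estimates
intracellular reaction rates from the *transient* labelling of metabolic
intermediates after a ¹³C-labelled substrate is supplied. In a heterotrophic
cell culture fed a bolus of [U-¹³C₆]glucose, each intermediate's
mass-isotopologue distribution (MID) — the vector $a_0,\dots,a_n$ of
fractions of molecules carrying $0,\dots,n$ heavy carbons — relaxes from
unlabelled towards an isotopic steady state. The *rate* of that relaxation
carries the information: it depends on the fluxes through the reactions
producing and consuming each pool and on the pool sizes, which set the
turnover time constants. At isotopic steady state in a purely glucose-fed
network all pools converge to the substrate enrichment and the pattern
becomes uninformative; the time-courses are where the fluxes are.

The unknowns are collected in a `flux_state`: net fluxes $v$ (relative to a
glucose uptake fixed at 1), nonnegative exchange fluxes for reversible
reactions (forward $= \max(v,0) + v_{exch}$, backward
$= \max(-v,0) + v_{exch}$), and pool sizes $P$. Steady-state mass balance
$S\,v = 0$ over the balanced pools makes most net fluxes linear functions of
a small free set; `flux_state()` performs that solve and refuses states that
drive an irreversible reaction negative.

# Atom-transition models

Models are plain text, one declaration per line: pools with carbon counts
and roles (`source`, `sink`, `symmetric`), substrates with labelling
specifications, measurement groups, and reactions with per-carbon atom maps
such as

```
ana: PEP.c (abc) + CO2 (d) -> MAL (abcd)
```

The parser enforces carbon conservation per reaction (each atom-map letter
appears exactly once on each side) and checks every map length against the
declared carbon count. Rotationally symmetric intermediates (succinate,
fumarate) are handled by splitting every flow that *produces* the symmetric
pool into two half-weight variants with the product map reversed; because
the initial state is unlabelled (hence orientation-symmetric), scrambling at
production keeps the pool's isotopomer distribution symmetric at all times,
which the brute-force oracle verifies positionally.

Measured fragments rarely equal single pools: extraction mixes subcellular
compartments and may dilute a fragment with pre-existing unlabelled
material. A measurement group therefore composes an observable MID as a
simplex-weighted sum of pool MIDs plus an unlabelled fraction times the
$M_0$ vector; weights and unlabelled fractions may be declared fixed or
`free` (fitted). Mixing parameters are shared across time points and
replicates per metabolite — the natural reading of extraction mixing, which
is a property of the sample workup rather than of a time point.

# EMU decomposition and simulation

Simulating full isotopomer distributions costs $2^n$ states per pool. The
elementary metabolite unit (EMU) decomposition instead back-traces, from
each measured fragment, exactly those atom subsets whose labelling can reach
it. Within one EMU size $k$ the balances are linear,

$$P \,\frac{dX}{dt} = A(v)\,X + B(v)\,Y(t),$$

with $X$ the stacked $k$-sized EMU MIDs, $A$ built from the flows among
same-size EMUs minus total pool consumption on the diagonal, and $Y$ the
inputs: substrate EMUs and convolution nodes, where a product EMU draws
carbons from two reactant molecules and its MID is the Cauchy product of the
component MIDs. Sizes are solved in increasing order, so every input is
known when needed.

Two backends solve the cascade:

* **`expm` (default).** Per level, $M = P^{-1}A$ is eigendecomposed once
  per flux state and the solution is propagated exactly across the nodes of
  a dense internal grid (geometric spacing towards $t=0$, where the
  dynamics are fastest). Inputs are represented as cubic Hermite
  interpolants between nodes — their nodal values *and* exact derivatives
  are available, since $\dot X = M X + U$ is free once $X$ is known and
  convolution derivatives follow from the product rule — and the
  variation-of-constants integrals $\int_0^h e^{\lambda(h-s)} s^k\,ds$ are
  evaluated in closed form with a Taylor fallback for small $|\lambda h|$.
  For constant inputs (a step substrate feeding a chain) the scheme is
  exact to rounding; with convolution inputs the observed accuracy on the
  bundled networks is $\sim 5\times10^{-6}$ at 40 grid nodes and
  $\sim 3\times10^{-8}$ at 150. If an eigenbasis is ill-conditioned
  (defective $M$, e.g. identical cascaded pools) the level falls back to a
  stiff ODE solve.
* **`lsoda`.** The whole cascade is stacked into one ODE system and
  integrated with a stiff-capable solver (default `rtol = 1e-8`,
  `atol = 1e-10`); convolution inputs are evaluated exactly from the
  current state. This is the high-accuracy reference: at
  `rtol = 1e-11` it agrees with an independent brute-force positional
  isotopomer integration to $\sim 10^{-13}$ on every bundled network.

Pool sizes spanning orders of magnitude make the cascade stiff, which is
why both backends are built around implicit/exact propagation rather than
explicit stepping. The initial condition is the unlabelled state; data are
assumed natural-abundance corrected, so natural abundance never enters the
simulator.

`CO2` is simulated as an ordinary balanced 1-carbon pool by default — it is
both produced (decarboxylations) and consumed (PEP carboxylase) — rather
than as a fixed-enrichment sink; a fixed-pattern CO₂ can be expressed by
declaring it a `source` if wanted.

# Measurement processing

* `correct_natural_abundance()` solves the nonnegative least-squares system
  $C x = a^{obs}$ with the binomial carbon correction matrix
  $C_{ij} = \binom{n-j}{i-j} p^{\,i-j} (1-p)^{n-j-(i-j)}$ at
  $p = 0.0107$. Only the ¹³C correction core is implemented; corrections
  for heavy isotopes of other elements (and resolution-dependent merging of
  near-isobars) are an extension point, not reproduced.
* `deconvolute_mid()` strips an overlapping species (the UDP/UDP-glucose
  case) by least squares under simplex constraints. Because the observed
  vector is itself a valid MID, $\alpha = 0$ always fits exactly; the
  operation therefore returns the *maximal* contaminant fraction consistent
  with the best attainable residual, the convention under which an exact
  mixture is inverted to its true components, and flags $\alpha \approx 1$
  as degenerate.
* `fractional_enrichment()` is $\sum_i a_i\, i / n$, and
  `normalize_to_substrate()` divides by the labelled substrate fraction,
  flagging values above 1.05.

# Objective, error model, acceptance

Measurements are weighted by a mol%-dependent error: $\sigma$ equals
`sigma_min` below 0.5 mol%, `sigma_max` above 25 mol%, and ramps linearly
in between; the ramp avoids placing large absolute errors on small
isotopologue signals. The objective is the variance-weighted SSR over all
isotopologues, time points and replicates (fitted simultaneously), plus
residuals of fixed-output ("biomass") flux measurements. Optional MS
normalisation factors — one multiplicative factor per (fragment, time,
replicate) group — are solved in closed form at each evaluation, since the
objective is linear in them, and are counted as parameters in the
bookkeeping.

A fit is accepted when its SSR lies between the $\alpha/2$ and
$1-\alpha/2$ quantiles of $\chi^2_{n-p}$. `calibrate_error_model()` scans
(`sigma_min`, `sigma_max`) pairs from small to large, rescoring the
incumbent residuals (default; a refit mode exists but the rescore is much
cheaper and the scan is monotone either way), and returns the smallest
acceptable pair — the most precise weighting the data support.

# Optimization

`fit_fluxes()` runs multistart Levenberg–Marquardt (`minpack.lm`): free net
fluxes start log-uniform in $[0.01, 2]$, exchanges log-uniform in
$[0.01, 10]$, pool sizes log-uniform over three decades, mixing fractions
uniform; starts whose dependent fluxes violate irreversibility are redrawn,
so every restart begins inside the feasible flux cone. Bounds are enforced
by transformation (log for pools, exchanges and irreversible free fluxes;
logit/stick-breaking for fractions and weights), keeping the LM core
unconstrained; the only residual-side guard inflates the residuals if a
*dependent* flux leaves the cone, which no per-parameter transform can
prevent, and clamps log-scale quantities into a huge finite box so that
finite-difference excursions cannot overflow the linear algebra. Gradients
are forward finite differences. Convergence uses a relative-SSR tolerance
of $10^{-9}$ with an iteration cap; the cap is an argument because
Monte-Carlo refits warm-started at the optimum need far fewer iterations
than cold multistarts.

# Uncertainty

* **Continuation** (`continuation_ci()`): one parameter is stepped away
  from its optimum with all others re-optimized (warm-started), and the
  95% bound is where the profiled SSR crosses
  $SSR_{min} + \chi^2_{1,0.95}$, refined by bisection once bracketed. A
  flat profile yields an unbounded interval rather than an error. Any
  better solution discovered during the walk replaces the incumbent and
  the continuation restarts.
* **Monte Carlo** (`monte_carlo()`): the best-fit simulated measurements
  are perturbed with Gaussian noise at the error-model sigmas (flux
  measurements at their own errors) and refitted from the best-fit
  vector; 1000 rounds at full scale. The refits use a warm-start
  Levenberg–Marquardt loop (fresh finite-difference Jacobian per
  iteration, Marquardt-scaled damping) built for the quadratic regime
  around the incumbent optimum; its ensemble spreads agree with deep
  `nls.lm` refits to within a few percent at a fraction of the cost. Warm
  single-start refits are the tractable default; a multistart per round
  is possible via the same machinery but was not needed on the bundled
  problems. Failures are recorded, never dropped, and a failure rate
  above 10% aborts.
* **Percentile CIs** (`ci_from_ensemble()`): rank and discard
  $\lfloor (1-\text{level}/100)/2 \cdot n \rfloor$ from each end — 83 per
  end for an 83.4% interval on 1000 rounds, 25 for 95%.
* **Significance** (`compare_conditions()`): two conditions differ at
  $P = 0.05$ when their 83.4% CIs do not overlap, assuming equal
  variances. A two-sided variance-ratio test at 0.05 on the ensemble
  standard deviations gates the unequal-variance correction
  $[1 - 2\Phi(-1.96\sqrt{1+\rho^2}/(1+\rho))]\times100\%$ with
  $\rho$ the sd ratio (83.4% at $\rho=1$, approaching 95% as the
  variances diverge; the 1.96 is kept literal). The gate's test and the
  use of ensemble sds for $\rho$ are this package's choices — the rule's
  published form names neither — and both are exposed as arguments.

# Multivariate analysis

PCA (`flux_pca()`) and PLS-DA (`flux_plsda()`) operate on stacked Monte
Carlo net-flux ensembles from two conditions
(`flux_ensemble_matrix()`): pool sizes, exchange fluxes, mixing parameters
and pseudo (dilution/mixing) reactions are excluded, and columns are
autoscaled to mean 0, variance 1 with the sample-sd ($n-1$) convention of
`prcomp`. PCA is computed from the SVD with a deterministic sign rule
(largest-magnitude loading positive) and is cross-checked against `prcomp`
and a covariance eigendecomposition in the tests. PLS-DA is NIPALS PLS2 on
a centred class-indicator response with standard VIP scores
(mean-square 1); validation is by 5-fold cross-validated classification
accuracy and a 100-permutation test of the component-1 class separation,
since published PLS-DA analyses of this kind defer validation details to
supplements. Two components are the default; more are an argument.

# The synthetic-experiment generator

`experiment_design()` + `generate_experiment()` emulate the study
conditions the analysis assumes: a bolus of [U-¹³C₆]glucose at 60%
enrichment at $t=0$; sampling at 0, 0.5, 1, 2, 4, 8, 10, 15, 20, 30, 60,
120 and 270 minutes; three replicate cultures; Gaussian noise with the
mol%-dependent error model (1.20–1.90 mol% by default) added on the
fraction scale. By default the noise is *not* truncated at zero: the
quantities being emulated are natural-abundance-corrected MIDs, whose
near-zero channels legitimately carry small negative values after
correction, and untruncated noise keeps the weighted SSR chi-squared
distributed and the estimator unbiased. `clamp = TRUE` instead clamps to
$[0,1]$ and renormalizes each MID, emulating bounded raw-signal tables;
that truncation raises every near-zero channel by about
$\sigma/\sqrt{2\pi}$ (≈0.5 mol% at the default error floor), which
depresses the SSR below its nominal expectation and measurably biases
fluxes that feed intermediate mass channels (the anaplerotic route in the
desk network) — the reason corrected-scale emulation is the default for
statistical calibration work. One master seed expands into per-replicate,
per-metabolite streams so partial regeneration is reproducible.

Substrate arrival can be a step (default), a pure lag, first-order
saturation (`delayed_substrate()`), or a distribution of delays across a
cell population (`aggregate_population()`, an expectation over per-delay
simulations via discrete quadrature) — the abstraction standing in for
diffusion-limited substrate access in cell aggregates, whose geometric
detail is not modelled. `simulate_piecewise()` chains balanced flux states
across time segments; `scenario_transient_dilution()` uses it to reproduce
the characteristic transient dip in hexose-phosphate enrichment when an
unlabelled carbohydrate store is mobilized for a limited window.

What the generator does *not* emulate: natural-abundance contamination
(data are generated on the corrected scale the fitter consumes),
instrument drift or peak-integration artifacts, biological replicate
variation beyond measurement noise, and flux/pool drift during the
time-course (the pseudo-steady-state assumption is built in). Passing
recovery tests on these data therefore validates the estimation machinery,
not the upstream measurement pipeline.

# Bundled networks and problem sizes

The `"arabidopsis"` model transcribes the published compartmented
central-carbon network of heterotrophic arabidopsis cells (cytosolic and
plastidic glycolysis, oxidative PPP with transketolase/transaldolase
rearrangements, TCA cycle with succinate/fumarate scrambling, anaplerosis,
starch/sucrose synthesis) with textbook atom maps; the published model's
own maps are not printed, so positional TCA/PPP details carry transcription
risk, and small output fluxes (pyruvate, acetyl-CoA, erythrose-4-phosphate,
UDP-glucose withdrawals) were added to close pool balances implied by the
published flux table. `arabidopsis_reference_state()` balances it at the
published control values; dependent fluxes reproduce the remaining table
entries to printed rounding.

Estimation-scale studies run on the compact `"desk"` network (11 fitted
parameters: 3 free net fluxes, 1 exchange, 6 pool sizes, 1 unlabelled
fraction), which preserves the features that make the inference hard —
an unlabelled influx competing with labelled uptake, a convolution node
from anaplerotic carboxylation, a malic-enzyme return flux, vacuolar
dilution of an organic acid, and turnover times from tens of seconds to
tens of minutes — at a size where a 20-repetition recovery study with
8-start fits and 100 Monte Carlo rounds per repetition completes on one
CPU in minutes. The full-network, full-parameter design (hundreds of
normalisations and ~100 fluxes) is supported by the same code paths but is
not exercised at that scale in the test suite; the bookkeeping that its
degrees of freedom and acceptance window imply is checked exactly.

Numerical choices used by the bundled studies: simulation grid of 36–40
internal nodes for fitting (discretization error $\sim 5\times10^{-6}$,
three orders of magnitude below measurement noise) and 150 for data
generation; LM iteration caps of 50–60 for cold multistarts, a deep
polish of the winning start, and 5 warm-refit iterations per Monte Carlo
round (warm refits converge in 2–4; ensemble spreads are unchanged from
deeper solves). A multistart batch whose
best SSR lands above the acceptance window has, by the acceptance rule
itself, failed to find an adequate optimum; `fit_until_accepted()` re-runs
such an analysis with fresh random batches before any uncertainty
analysis, mirroring what the full-scale 32-start budget exists to
prevent.

# Known limitations

* Carbon-only tracers; no ²H/¹⁵N, no cumomer formulation.
* The natural-abundance correction ignores resolution-dependent behaviour
  of Orbitrap-class instruments.
* Monte Carlo refits are single-start from the optimum; a pathological
  landscape could hide secondary modes from the ensembles.
* Mixing weights are shared across time points; time-varying extraction
  artifacts are not representable.
* The significance machinery compares parameters one at a time; there is
  no multiplicity control across fluxes, matching the published rule.
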