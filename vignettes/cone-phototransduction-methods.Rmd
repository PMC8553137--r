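---
title: "Methods: a well-stirred model of the cone flash response and its sensitivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a well-stirred model of the cone flash response and its sensitivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conesens)
```

# The model

`conesens` implements a deterministic kinetic model of phototransduction in
the cone outer segment (COS), reduced to a well-stirred compartment. Cone
biochemistry is poorly constrained compared to rods — many parameters are
known only as wide interspecies ranges — so the package's purpose is less to
predict a single response than to ask *which* parameter uncertainties matter,
via variance-based global sensitivity analysis, and to find consistent
parameter sets by constrained stochastic fitting.

## Activation cascade

A flash of $\Phi$ photoisomerizations activates visual pigment uniformly
over the disc stack. With surface densities (molecules per µm² of disc
membrane) $R^*$, $G^*$ (free activated transducin) and $E^*$ (activated PDE
catalytic subunits; each holoenzyme carries two, which activate
independently, so the activatable pool is $E_{tot} = 2\,[\mathrm{PDE}]_\sigma$):

$$\frac{dR^*}{dt} = -k_R R^*, \qquad R^*(0) = \Phi / S_{disc}$$
$$\frac{dG^*}{dt} = \nu_{RG} R^* \frac{G_\sigma - G^* - E^*}{G_\sigma}
  - k_{GE}(E_{tot} - E^*)G^*$$
$$\frac{dE^*}{dt} = k_{GE}(E_{tot} - E^*)G^* - k_E E^*$$

One $G^*$ is consumed per activated subunit, which makes the depletion
factor $(G_\sigma - G^* - E^*)/G_\sigma$ exact; free $G^*$ has no
independent decay — it must complex into $E^*$ before decaying at $k_E$.
This bookkeeping yields the conservation identity (activated transducin
ever produced equals $G^* + E^*$ plus the amount already decayed) that the
test suite verifies by quadrature. A genuine factor-of-two ambiguity exists
in the literature over whether the coupling coefficient $k_{GE}$ should be
read per holoenzyme or per subunit; the form above is the one consistent
with writing the subunit pool as twice the holoenzyme density, and the
sensitivity results reported by the package carry a tolerance wide enough to
cover the alternative.

$S_{disc}$ comes from a continuum frustum approximation of the tapered disc
stack (base radius $R_b$, tip radius $R_t$, $n$ discs, two faces each).

## cGMP and calcium

The second-messenger pair evolves as

$$\frac{d[cG]}{dt} = \alpha([Ca^{2+}])
  - \big(\beta_{dark} + \beta_{light}(E^*)\big)[cG]$$
$$\frac{d[Ca^{2+}]}{dt} = \frac{1}{B_{Ca}}
  \left( \frac{f_{Ca}\,J_{cG}([cG])}{2FV} - \frac{J_{ex}([Ca^{2+}])}{FV} \right)
  \times 10^9$$

with the Hill-type CNG channel current
$J_{cG} = J_{cG}^{max}\, [cG]^{m_{cG}} / (K_{cG}^{m_{cG}} + [cG]^{m_{cG}})$,
the Michaelis exchanger current
$J_{ex} = J_{ex}^{sat}\,[Ca^{2+}]/(K_{ex} + [Ca^{2+}])$, and the
calcium-inhibited cyclase
$\alpha = \alpha_{min} + (\alpha_{max} - \alpha_{min})
 \,K_{cyc}^{m_{cyc}} / (K_{cyc}^{m_{cyc}} + [Ca^{2+}]^{m_{cyc}})$.
CNG influx carries charge 2 per calcium ion, exchanger efflux charge 1.
Light-driven hydrolysis converts the surface density of activated subunits
into a volumetric rate through the same volume-to-surface factor
$\eta = \tfrac12 \nu \epsilon_0$ used for density conversions:
$\beta_{light} = k^*_{\sigma;hyd}\,(E^*/2)/\eta$ with
$k^*_{\sigma;hyd} = (k_{cat}/K_m) / (N_{Av} B_{cG})$. The cGMP buffering
power enters *only* through $k^*_{\sigma;hyd}$; the dark turnover
$\beta_{dark}$ and the cyclase rate are effective volumetric rates as
measured. The coupling cascade → cGMP is one-way.

## The well-stirred reduction

The parent spatial picture resolves radial and axial diffusion in a
3-D outer segment. This package deliberately collapses it: for flashes of
uniform intensity all fields are spatially uniform to leading order, and
variance-based sensitivity analysis attributes essentially zero variance to
the geometry and membrane/cytosolic diffusion coefficients. Diffusion
coefficients are therefore carried in the parameter set but enter no
equation, and currents are whole-cell totals in pA (channel localization
drops out). The reduction is exact for the dark steady state and for the
cascade; for the transient flash response it overestimates the response
amplitude: at the best-fit parameter point a 940-photoisomerization flash —
experimentally a half-maximal stimulus — suppresses about 84% of the dark
current here rather than ~50%. Passing tests therefore demonstrate the
internal consistency of the reduced model and the correctness of the
estimators, not quantitative agreement of transient amplitudes with
recordings. Quantities anchored on the dark state (dark concentrations,
dark current, their variance decomposition) and on the cascade (peak E*,
activation/shutoff structure) are insensitive to the reduction and
reproduce the full-scale analysis closely.

## The dark steady state and the a_min reparameterization

In darkness, synthesis balances hydrolysis and calcium influx balances
efflux:

$$\alpha([Ca^{2+}]_{dark}) = \beta_{dark}[cG]_{dark}, \qquad
  J_{ex}([Ca^{2+}]_{dark}) = \tfrac12 f_{Ca} J_{cG}([cG]_{dark}).$$

Because both sides saturate, solutions do not exist for arbitrary
parameters: a dark steady state requires
$1 + \big(\alpha_{min}/(\beta_{dark} K_{cG})\big)^{m_{cG}} <
 \big(1 - 2J_{ex}^{sat}/(J_{cG}^{max} f_{Ca})\big)^{-1}$.
Given all other parameters, admissible minimum cyclase rates form an
interval $[0, \xi]$, $\xi = \min(\alpha_{max}, \chi)$ with $\chi$ the root
of the equality version of the constraint. The unitless coordinate
$a_{min} = \alpha_{min}/\xi \in [0,1]$ — "how close the cell sits to the
impossibility of a dark state" — replaces $\alpha_{min}$ wherever
independent sampling is required: uniform draws of $a_{min}$ keep every
sampled parameter set admissible by construction, which the suite checks on
10^4 draws.

`solve_dark_state()` solves the 2×2 balance by closed-form elimination of
$[cG]$ and monotone bracketed root finding in $[Ca^{2+}]$ (relative
tolerance 1e-10; both maps are monotone so the bracket is guaranteed). A
vectorized bisection (`dark_state_batch()`, 80 halvings) evaluates designs
of 10^5+ draws in seconds; the two independent code paths are
cross-checked against each other in the tests. At the best-fit point the
balance reproduces the printed dark cGMP (2.65 µM at the printed dark
calcium) and the full solve gives (2.62 µM, 0.207 µM, 26.05 pA), within
the few-percent self-consistency of the rounded published values.

# Functionals of the flash response

Nine scalars summarize a response: early-rise curvatures `I_act` (current
drop) and `E_act` (total E*), both least-squares fits of $\tfrac12 A t^2$
on [0, 10 ms]; the normalized maximum drop `I_drop`; peak total subunits
`E_peak`; recovery rate `E_rec` (log-linear exponential fit of the drop on
[0.135 s, 0.5 s] — fitted to the *current* drop, following the defining
text rather than the symbol's name); time-to-peak `T_peak` (grid argmax
with 3-point parabolic refinement, since sub-grid handling is otherwise
unspecified); the dark current `J_dark`; the overshoot `J_over`
(largest excess of current above the dark current, normalized — the
transient "negative drop" seen in cones); and `L2`, the rms misfit to a
target trace at the target's sample times (window = the target's support).
Nonpositive samples are dropped before the log-linear recovery fit; if
fewer than three remain the functional is undefined and propagates as `NA`
so samplers can exclude it per-row.

# Sensitivity analysis

*Local* indices are normalized forward differences with a 5% relative
step, $Q_i = (y(x^*_i(1+h)) / y(x^*) - 1)/h$, computed with deterministic
solver settings and a cached base evaluation.

*Global* analysis uses Sobol indices on plain Monte Carlo Saltelli designs:
independent uniform draws over the literature ranges (with $a_{min}$ as the
cyclase coordinate), hybrid matrices per target, the Saltelli (2010)
estimator for first-order/closed indices and the Jansen estimator for
total effects, normalized by the pooled sample variance of $f(A), f(B)$.
Pairs use two-column swaps (closed pair index). Estimates are reported
unclamped — small negative values are an expected Monte Carlo artifact and
are preserved. Failed evaluations are excluded pairwise with their design
rows and counted. Confidence intervals: 95% normal intervals for the
numerator and denominator means, combined into a 90% ratio interval by the
order-preserving properties of division; this construction is conservative
(a percentile bootstrap, provided as a cross-check, gives nested and
somewhat narrower intervals). A denominator interval straddling zero is
flagged as unbounded.

Estimator correctness is established on analytic fixtures: an additive
linear model (exact variance decomposition, first-order = total) and the
Ishigami function ($a=7$, $b=0.1$; $S_1 = 0.3139$, $S_2 = 0.4424$,
$S_3 = 0$, $S^{tot}_3 = 0.2437$ from the closed-form decomposition).

# Parameter fitting

`run_chain()` is a Metropolis–Hastings random walk whose stationary density
combines soft range penalties, an rms-error weight and a hard constraint
set $K$:
$\pi(x) \propto \big(\prod_i 2^{-\gamma\,\mathrm{dist}(x_i, I_i)}\big)
 \cdot \|e(x)\|^{-\beta} \cdot \mathbf{1}_K(x)$.
`dist` is the distance to the expected interval normalized by its width
(zero inside), making $\gamma$ unit-free across heterogeneous parameters.
$K$ bounds both raw parameters and the *derived* dark-state quantities
(dark cGMP, dark calcium, dark current), so every retained sample is a
physiologically admissible cell. Proposals are componentwise Gaussian in
range-normalized coordinates, applied one randomly chosen coordinate per
step: the feasible set is a thin slice of the parameter box (roughly 5
in 10^5 uniform draws satisfy $K$), and joint perturbation of all ~24
coordinates almost never stays inside it. Geometry and the calcium
diffusion coefficient stay fixed. Starts are found by vectorized rejection
sampling of the soft box.

Defaults $\gamma = 5$, $\beta = 2$ give a gently error-weighted exploration
of $K$; for point estimation the package uses $\beta = 50$ and proposal
scale 1% of range width, which behaves as a stochastic descent. The chain
is not run to stationarity — the deliverable is the minimum-error sample,
and chains are resumable by passing a previous best as `init`. On a
zero-noise synthetic self-target a 60,000-step chain recovers the response
to an rms of ~0.04 pA while landing far from the generating parameters in
several coordinates (e.g. the dark turnover rate trades off against the
hydrolytic efficiency): the model is strongly non-identifiable from a
single flash trace, which is precisely the motivation for the variance
decomposition above.

# Synthetic data

Recordings of transducin-knockout mouse cones (flash family ~40–6,000
photoisomerizations, half-maximal near 940) are not available as deposited
data; `generate_experiment()` emulates them by simulating the model at a
known parameter vector and adding iid Gaussian current noise (default sd
0.3 pA, chosen as visually comparable to published trace jitter; a
calibration constant, configurable). The generator reproduces the
monotone intensity family; it does not emulate electrode/photon noise
physics, cell-to-cell variability, or the amplitude attenuation of the
spatial model noted above. Default time base: 0.5 s at 1 ms sampling (the
true sampling of the recordings is unpublished).

# Numerical choices and problem sizes

- Integration: `lsoda` via compiled right-hand sides, rtol 1e-8, atol
  1e-12 (cascade) / 1e-10 (full model); output grid 0.1 ms for functional
  fitting (0.5 ms suffices for peak-E* scans, with parabolic peak
  refinement). All functionals change by < 0.5% under grid halving.
- Dark-state roots: relative tolerance 1e-10 (scalar); 80 bisection
  halvings (batch). Negative-concentration guards abort integration rather
  than clamp silently.
- Sensitivity runs in the acceptance script use N = 10^5 base samples for
  the dark-current indices and N = 5×10^4 for the cascade pair index
  (the full-scale analysis used 10^5 per statistic); at these sizes the
  Monte Carlo standard error of the reported indices is ~0.01–0.03.
- Ties in `T_peak` resolve to the earliest grid maximum before parabolic
  refinement; degenerate parabolas (non-concave triples) fall back to the
  grid value.

# Known limitations

- Transient amplitudes inherit the well-stirred bias discussed above;
  comparisons with recordings should use dark-state quantities, timing and
  rank-order sensitivity structure, not absolute drop amplitudes.
- No light adaptation or steady backgrounds: flashes from darkness only.
- The cyclase floor parameterization assumes the literature ratio
  constraint $\alpha_{max}/\alpha_{min}$ applies at the dark operating
  point; direct measurements of $a_{min}$ do not exist.
- Indices are estimated by plain Monte Carlo (as in the source analysis),
  not quasi-random sequences; at desk-scale N the pair indices carry
  percentage-point-level noise.
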