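---
title: "Models and methods behind the hydration-water pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the hydration-water pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroshell)
```

## The scientific problem

Water in the first hydration layer of a water-soluble polymer behaves very
differently from bulk water: it stays mobile far below the bulk freezing
point, its relaxation slows in a super-Arrhenius fashion on cooling, and
the apparent "dynamical transition" seen in elastic neutron scans moves
with the instrument's energy resolution — the signature of a kinetic
process rather than a thermodynamic one. Poly(ethylene glycol)/water is
the standard model system: the polymer's ether oxygens accept hydrogen
bonds from water, the water collects in pools along the chain, and
H/D isotope substitution lets neutron experiments look at polymer and
water separately.

This package implements, as reusable and tested code, the quantitative
chain that connects the three kinds of raw material such a study
produces — reduced QENS spectra, reduced 1-D SANS curves, and MD
trajectories — to the physical quantities of interest: relaxation times
and their temperature law, chain conformation, hydrogen-bond kinetics, and
the geometry of the confined water network. Because raw instrument and
simulation data are bulky and proprietary-format, the package also ships
generators that emulate every input with known ground truth; all claims
made by the test suite are claims about those synthetic conditions, a
point discussed at the end.

## QENS: from spectra to relaxation times

A quasi-elastic spectrometer measures the incoherent dynamic structure
factor $S(q, \Delta E)$, the Fourier transform of the intermediate
scattering function (ISF) $F(q,t)$. The package works in the time domain:

$$F_s(q,t) = \int S(q,\Delta E)\cos(\Delta E\, t/\hbar)\,d\Delta E, \qquad
  F(q,t) = \frac{F_s(q,t)}{F_{\mathrm{res}}(q,t)},$$

with the trapezoid rule on the measured window and the instrument
resolution divided out in the time domain (`isf_from_spectrum()`).
Numerical choices that matter:

* **Symmetrized (cosine) transform.** Detailed-balance asymmetry is
  ignored; in the regime of interest $\hbar\omega \ll k_B T$ and spectra
  are treated as classical/symmetric.
* **Resolution cutoff.** Times where the resolution's own transform has
  decayed below 1% of its $t=0$ value are dropped (recorded in a
  `dropped` attribute): beyond them the division is pure noise
  amplification. For a Gaussian resolution of FWHM 17.5 µeV this limits
  the window to roughly 270 ps; a 1 µeV backscattering-like resolution
  reaches ~20× further. This is exactly why the two instrument classes see
  different onset temperatures.
* **Error propagation.** The spectrum's per-point uncertainty is pushed
  through the transform and the division, giving each ISF point an
  uncertainty that grows as the resolution transform decays. The KWW fit
  then uses inverse-variance weights (`qens_q_scaling()` does this
  automatically), which is what keeps the q-scaling exponent stable at the
  percent level instead of being dominated by the noisiest long-time
  points.
* **Finite-window bias.** Truncating the energy window at $\pm W$
  convolves the time signal with a kernel of width $\hbar/W$ and removes a
  tail mass that inflates the normalized ISF by a constant factor, which
  the free KWW amplitude $A$ absorbs. Recovery of $(\tau,\beta)$ to
  $10^{-3}$ relative on noiseless input needs a window that holds the
  stretched exponential's slow spectral tails (the generator enforces a
  90% norm check) and fit times above a few $\hbar/W$.

The ISF is fitted with the Kohlrausch–Williams–Watts form
$A\exp[-(t/\tau)^\beta]$ by Levenberg–Marquardt with three starts in the
stretching exponent ($\beta_0 \in \{0.3, 0.6, 0.9\}$, best residual wins)
and $\beta$ bounded to $(0.1, 1]$ (`fit_kww()`). Both the bare $\tau$ and
the Gamma-weighted mean $\langle\tau\rangle = (\tau/\beta)\Gamma(1/\beta)$
are reported; published figures rarely say which "average relaxation
time" they plot, so both are exposed, and the q-scaling step uses
$\langle\tau\rangle$ — for constant $\beta$ the two differ only by a
constant factor, leaving the fitted exponent unchanged.

Elastic scans (`sum_elastic()`) integrate $S$ over $|\Delta E| \le$ the
elastic window and sum over a q range with uniform weights (the weighting
within "a defined q range" is a free choice; uniform is the simplest
defensible one). The default windows, 1 µeV and 17.5 µeV, mirror the two
instrument resolutions, since the window is precisely what makes the
onset resolution-dependent. The onset itself (`detect_onset()`) is the
breakpoint of a continuous two-segment piecewise-linear model found by
exhaustive search over interior grid temperatures with at least four
points per segment — exhaustive search over a ~150-point grid costs
milliseconds and has no local-minimum pitfalls. On noiseless bilinear
input the true break is recovered to one grid step for any distinct slope
pair; at noise σ = 0.005 the mean error stays below a few tenths of a
kelvin on a 2 K grid.

## Relaxation kinetics and extrapolation

Arrhenius ($\tau = \tau_0 e^{E_A/k_B T}$) and super-Arrhenius / VFT
($\tau = \tau_0 e^{K T_0/(T - T_0)}$) laws are both linear in log space,
so they are fitted by weighted linear regression of $\ln\tau$ — exact,
reproducible, and matching the multiplicative error structure of
relaxation-time data. $T_0$, the divergence temperature, is a fixed input
and never fitted: the experimental protocol is to compare literature
values (124, 136, 176 K for water) on the same five-point data set, and a
joint three-parameter fit on five points is ill-conditioned.
`evaluate_tau()` extrapolates with first-order propagation from the
parameter covariance; published tables rarely state how their ±
uncertainties were computed, so agreement in the error bars is expected
only in order of magnitude, while the central values are exact arithmetic.
`crossover_temperature()` brackets and bisects the difference of the two
log-laws to 0.01 K; a dense-grid scan is the test oracle. As
$T_0 \to 0^+$ with $K T_0$ held fixed the VFT law reduces to Arrhenius
with $E_A = k_B\,(K T_0)$, which the tests verify numerically — a useful
sanity check that the two parameterizations share one temperature scale.

## SANS: contrast variation and chain form factor

For a mixed h/d-polymer solution in an H₂O/D₂O solvent, the forward model
is the two-term zero-average-contrast (ZAC) expression: a single-chain
term weighted by $(\rho_d-\rho_s)^2 \phi_d\phi_h/\phi_P^2$ and an
average-contrast term weighted by the squared difference between the
composition-weighted polymer SLD and the solvent SLD. The second term
vanishes identically when the solvent matches the mean polymer SLD — the
match point. The package evaluates the printed two-term form literally
and validates it against the partial-structure-factor decomposition it
implies ($S_{dd} = x_d x_h n v P_S + x_d^2 n\phi v P_T$, etc.), an
algebraic identity the tests check to $10^{-10}$; the published
three-partial relation contains an obvious typographical duplication, so
the decomposition implied by the two-term form is the one used.

The match point is found from a solvent series by fitting a line to the
*signed* $\sqrt I$: intensity is quadratic in contrast, so $\sqrt I$ is
the absolute value of a linear function, and every split of the series
into a negative-sign head and positive-sign tail is tried, keeping the
split with the smallest weighted residual (`match_point()`). The root of
the winning line is the match fraction. The contrast-series generator
records, by default, the average-contrast term that dominates a real
detector signal away from match; with the single-chain floor included
(`include_single_chain = TRUE`) the apparent minimum shifts — a genuine
systematic of the method worth demonstrating, not a bug.

The excluded-volume chain form factor uses the standard
incomplete-gamma expression with $U = q^2 R_g^2 (2\nu+1)(2\nu+2)/6$,
evaluated through the regularized `pgamma`; the printed formula is 0/0 at
$U = 0$, so below $U = 10^{-4}$ a Taylor expansion keeps $P(0) = 1$
exact. At $\nu = 1/2$ it collapses to the Debye function (verified to
$10^{-6}$ over $qR_g \in [0,10]$), and its high-q log-log slope is the
Porod exponent $-1/\nu$ (verified to 0.02 for
$\nu \in \{1/3, 1/2, 3/5\}$). `fit_sans()` does weighted
Levenberg–Marquardt with a Guinier-based starting radius and multi-start
in $\nu$; $\nu$ may be frozen at 1/2 (theta solvent) or 3/5 (good
solvent). Instrument resolution smearing (wavelength spreads of order
18% are typical on the relevant instruments) is deliberately not
modelled and is a known systematic of the fitted radii.

## Trajectory observables

A hydrogen bond is declared when the donor–acceptor oxygen distance is
within 3.5 Å and the O–H···O angle measured *at the hydrogen* (180° =
linear) is at least 150°. The angle vertex is the standard reading of the
O–H···O notation and is stated explicitly because published criteria are
often ambiguous on this point. By default water donates to the polymer's
ether oxygens — the polymer roles carry no hydroxyl hydrogens, chain ends
not being modelled — and water–water bonding is available by selection.
`find_hbonds()` is validated frame-by-frame against a brute-force
all-pairs, all-images checker on random fixtures.

The bond indicator $h(t)$ feeds two multiple-time-origin estimators
(`correlation_functions()`): the intermittent correlator
$C(t) = \langle h(0)h(t)\rangle/\langle h\rangle$, indifferent to breaks
and reforms in between, and the continuous correlator
$S(t) = \langle h(0)H(t)\rangle/\langle h\rangle$ with $H(t)$ the running
product of $h$ over every intermediate frame (strict continuity; a
grace-period option exists but defaults to off). Conventions that the
estimators pin down:

* the pair universe is every pair bonded in at least one frame, and
  $\langle h\rangle$ is taken over that universe — the normalization is
  otherwise undefined for never-bonded pairs;
* for each lag the averages run over all valid time origins, and
  $\langle h\rangle$ over the same origins, so both curves equal 1 at
  $t=0$ and $C(t) \ge S(t)$ holds exactly, not just asymptotically;
* $C$ is computed by exact FFT autocorrelation (integer counts), $S$ by
  run-length enumeration, so both are exact sums, not stochastic
  estimates, given the series.

The 1/e crossing times of $C$ and $S$ are the structural relaxation time
and the mean bond lifetime; `relax_time_1e()` interpolates linearly
between the bracketing samples and refuses curves that never cross. The
two-state telegraph generator provides closed forms
($C \to p + (1-p)e^{-(k_{on}+k_{off})t}$, $S \to e^{-k_{off}t}$) that the
estimators reproduce to 0.02 RMS at $10^5$ frames.

`rdf()` is the standard minimum-image pair histogram normalized by
ideal-gas shell counts; a Poisson gas gives $g \equiv 1$ within counting
error and a fixed pair reproduces the hand normalization exactly.
`incoherent_isf()` and `msd_and_jumps()` work on coordinates unwrapped by
accumulating per-step minimum-image displacements, valid while no atom
moves half a box edge in one frame — true for any sanely sampled
trajectory and for the generators. Jumps between trapping sites are
detected on block-averaged (coarse-grained) positions so in-trap
libration does not masquerade as diffusion; the residence time is the
time between successive jumps.

The water volume-distribution function $V(r)$ treats the water region as
the union of spheres of radius 1.7 Å (about water's van der Waals radius)
around the water oxygens, with periodic images; $V(r)$ is the Monte-Carlo
fraction of a probe sphere of radius $r$, centred at points drawn
uniformly inside the region, that lies inside the region. This definition
reproduces both diagnostics used in practice: its large-$r$ asymptote is
the water volume fraction of the box (the slab generator constructs that
fraction exactly, grid-covering the slab and offsetting the outer planes
by the coverage depth), and the x-intercept of its initial slope is the
"confining length" of a water pool. One geometry factor deserves
emphasis: for an isolated *spherical* pool of radius $R$ the initial
slope is $-9/(16R)$, so the intercept sits at $16R/9 \approx 1.8 R$, not
at $R$ — the confining length measures lateral extent in units set by the
pool shape, and the tests assert the analytic value rather than the
nominal radius. Per-probe fractions use independent sampling offsets, so
the reported Monte-Carlo standard error is honest.

## Synthetic study conditions

The generators' defaults encode the conditions the analyses are meant to
face: five q values between 0.53 and 1.85 Å⁻¹ with
$\tau(q) = 30\,\mathrm{ps} \cdot q^{-2.65}$ and $\beta = 0.6$ at room
temperature; a 17.5 µeV FWHM Gaussian resolution with 1% multiplicative
spectral noise; an energy grid of ±3000 µeV at 3 µeV spacing, wide enough
to hold the stretched exponential's spectral tails (the generator rejects
windows holding less than 90% of the norm); elastic scans on a 2 K grid
from 10 to 300 K; hydrogen-bond kinetics at rates of order 0.01 ps⁻¹
sampled every 1 ps for $10^5$ frames; trap-jump walkers with 4 Å site
spacing, 200 ps mean residence and 0.4 Å libration in a 40 Å box; and a
35% water slab for the volume distribution. Test problem sizes (60-point
time grids, 25–60 bond pairs, 1500-frame Brownian runs, 100–200
Monte-Carlo replicates) were chosen so each estimator's sampling error
sits comfortably below the tolerance it is tested against.

What the generators do *not* emulate — and hence what green tests do not
establish about real data: multiple scattering and detector efficiency in
QENS; detailed-balance asymmetry; instrument resolution functions that
are non-Gaussian or q-dependent; SANS resolution smearing and
incoherent-background subtleties; force-field realism, finite-size
effects, or microsecond-scale sampling in MD (published bond-lifetime
tables from long simulations are contracts for real trajectory input, not
something a desk-scale synthetic trajectory reproduces). The pipeline's
correctness is established against closed forms and brute-force oracles;
its applicability to a given instrument still requires the usual
instrument-specific reduction upstream.

## Known limitations

Orthorhombic boxes only (the target simulations use cubic boxes);
triclinic lattices are rejected with a clear error. Text-based trajectory
dialects only (extended-XYZ, GRO) — binary formats need external
conversion. The ZAC forward model takes the inter-chain form-factor
component as an input function rather than predicting it. Uncertainties
on extrapolated relaxation times are first-order propagation and should
be read as scale estimates, not confidence intervals.
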