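---
title: "Models and methods: water confined in lipid cubic mesophases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: water confined in lipid cubic mesophases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesowater)
```

# The system and the three analyses

Inverse bicontinuous cubic phases (IBCPs) are lipid mesophases whose
bilayer drapes a triply periodic minimal surface — gyroid (space group
Ia3d), diamond (Pn3m) or primitive (Im3m) — separating two
interpenetrating water-channel networks. Water confined in those
channels interacts with the lipid headgroups; near the interface its
hydrogen-bond (HB) network is disrupted, and this interfacial
population shapes the ultrafast intermolecular dynamics of the whole
confined water pool.

`mesowater` implements three linked analyses for such systems:

1. **SAXS indexing and mesophase geometry** — assign Bragg peaks to a
   cubic space group, fit the lattice parameter, and derive channel
   size, lipid length and the interfacial water fraction.
2. **THz spectral decomposition** — convert ATR intensities to water
   absorption spectra, decompose them into a Debye background,
   high-frequency terms and two damped-harmonic-oscillator (DHO)
   intermolecular modes (HB stretching near 150 cm^-1, libration near
   410 cm^-1), and convert fitted widths to lifetimes and Arrhenius
   activation energies over temperature.
3. **Hydrogen-bond profiling** — count HBs in coordinate frames by the
   geometric criterion, resolve coordination against distance from the
   membrane midplane, and locate the bulk-recovery distance.

A synthetic-data module generates inputs for all three with recorded
ground truth, so the full pipeline is testable without measured data.

# SAXS indexing

For a cubic lattice the Bragg spacings obey $d_{hkl} = a/\sqrt{N}$,
$N = h^2 + k^2 + l^2$, so peaks sit at $q_N = 2\pi\sqrt{N}/a$. The
allowed $N$ sequences are fixed by extinction rules: $\{6, 8, 14,
16,\dots\}$ for Ia3d, $\{2, 3, 4, 6,\dots\}$ for Pn3m and $\{2, 4, 6,
8,\dots\}$ for Im3m. `index_phase()` assigns the observed peaks, in
order, to each candidate's first allowed reflections and fits $a$ by
least squares of $q$ on $2\pi\sqrt{N}$ **through the origin** — the
spacing relation has no intercept — keeping the candidate with the
smallest relative RMS residual.

Two-peak data can be genuinely ambiguous: the gyroid signature
$\sqrt{8/6} \approx 1.155$ and the diamond signature $\sqrt{3/2}
\approx 1.225$ are close, and a degenerate doublet fits neither well.
Whenever two candidates' residuals agree within 10% (relative) the
assignment carries an `ambiguous` flag and the full residual table, so
no near-tie is ever resolved silently. Three or more reflections
separate the groups reliably: on synthetic peak sets with 0.5%
position noise the correct group is selected in well over 95% of
cases, and misassignments coincide with flagged near-ties.

Peak detection (`detect_peaks()`) smooths with a 5-point centered
moving average and requires maxima to rise at least 2% of the maximum
intensity above a rolling-minimum baseline; both knobs are exposed
because instrument noise floors differ.

# Mesophase geometry

With $A_0$ the minimal-surface area per unit cell normalized by $a^2$
(3.091, 1.919, 2.345 for Ia3d, Pn3m, Im3m) and $\chi$ the
Euler-Poincare characteristic (-8, -2, -4), the water-channel radius
is

$$ r = \sqrt{\frac{A_0}{-2\pi\chi}}\,a - l, $$

with $l$ the lipid length. Some of the literature labels this
expression a "diameter"; dimensional analysis of the parallel-surface
construction identifies it as the radius, so `channel_diameter()`
returns both $r$ and $2r$ and downstream tables use the diameter,
which lands in the 3-7 nm range typical of swollen phases.

The lipid length comes from the volume balance
$\phi_L = 2A_0(l/a) + \tfrac{4\pi\chi}{3}(l/a)^3$, inverted on the
monotone branch $l/a \in (0, \sqrt{A_0/(-2\pi\chi)})$ where the cubic
is increasing; the root is bracketed by `uniroot` and polished with
Newton steps to an absolute tolerance of 1e-12 in $l/a$. Volume
fractions beyond the cubic's maximum on that branch (≈0.955 for Im3m)
have no physical solution and raise an error.

The interfacial water fraction uses the analytic calibration for
swollen monolinolein-sugar-ester systems,

$$ f_{w,int} = \frac{-0.543\,K_0 - 2.092}{\Gamma}, \qquad
   \Gamma = \frac{f_w\,a^3}{4\pi|\chi|}, $$

with $a$ entering **numerically in nanometres** (the calibration's
units; recorded in the output metadata). $K_0$ is a dimensionless
curvature parameter of that calibration which the source literature
defines elsewhere; since its convention is not self-evident we require
it as an explicit argument, and offer `k0_convention = TRUE` for the
documented choice $K_0 = 2\pi\chi/A_0$ (integrated Gaussian curvature
per unit surface), under which a Pn3m phase at $a = 10$ nm and $f_w =
0.5$ gives $f_{w,int} \approx 0.074$. Raw values outside $[0, 1]$ are
clamped and flagged. Temperatures with phase coexistence cannot be
resolved into per-phase water contents, so `geometry_series()` emits
their geometry fields as missing with a recorded reason.

# THz spectral decomposition

## From intensities to water spectra

In single-reflection ATR geometry the evanescent wave samples an
effective thickness

$$ d_s(\nu) = \frac{\lambda}{2\pi\sqrt{n_C^2\sin^2\theta - n_s^2}},
   \qquad \lambda = 10^4/\nu \ \mu m, $$

requiring total internal reflection $n_C\sin\theta > n_s$ (diamond
crystal $n_C = 2.42$, $\theta = \pi/4$; sample indices 1.47, 1.44,
1.41 for 30, 40, 50% water content, taken at their room-temperature
visible-wavelength values). The absorption coefficient follows from
Beer-Lambert, $\alpha = \ln(I_0/I)/d_s$. We default to the natural
logarithm — standard for absorption coefficients in cm^-1 — with a
`decadic` switch that rescales by $\ln 10$; the choice is recorded in
the output. The lipid contribution is removed pointwise,
$\Delta\alpha = \alpha - \phi_m\,\alpha_m$, with the reference
resampled (and a warning issued) if its grid differs.

## The line-shape model

$$ \Delta\alpha(\nu) = a_{LF}\,\alpha_{LF}(\nu) +
   a_{HF}\,\alpha_{HF}(\nu) + \sum_{i=1}^{2} L_i(\nu) $$

with the modified DHO modes

$$ L_i(\nu) = \frac{a_{0,i}\,\omega_{0,i}^2\,\nu^2}
   {4\pi^3\left[(\nu_{0,i}^2 - \nu^2)^2 +
   (\omega_{0,i}^2/\pi^2)\,\nu^2\right]}, $$

a Debye-type low-frequency term $\alpha_{LF} = a_0 e^{-\nu/\nu_0}
\nu^2/(\nu^2 + \omega_0^2)$ and two fixed-shape high-frequency terms
$t_i$ with detuned centers $\nu_{b,i}^2 + \omega_i^2/(4\pi)$. The
$\pi$-factor groupings printed in the literature are typographically
ambiguous; the forms above are the ones implemented, each isolated in
a single function (`eval_dho()`, `eval_background()`) so an
alternative grouping is a one-line swap. Two properties anchor the
physics regardless of grouping: $L_i(\nu_{0,i}) = a_{0,i}/(4\pi)$
independent of width, and the fitted $\omega_{0,i}$ is the
Lorentzian-type width entering the lifetime relation below.

The background **shape** parameters are fixed inputs (the calibration
that fixes them experimentally lives outside this package); only the
scale factors $a_{LF}, a_{HF}$ float by default. The package defaults
are chosen so the background is smooth and subdominant over 100-500
cm^-1: the LF term (a0 = 150, nu0 = 70, omega0 = 25 cm^-1) decays like
a sub-50 cm^-1 Debye relaxation should, contributing under 8% of the
stretching peak at 147 cm^-1, and the HF terms (centers 620 and 820
cm^-1) contribute about 4% of the libration peak inside the window.
Early in development we used a slower-decaying LF tail and larger HF
terms; both choices leaked enough amplitude under the modes to
correlate strongly with the fitted widths (and to open a spurious
minimum in which a broadened libration DHO replaces the HF tail), so
they were revised to the values above, which respect the Debye
assignment and the subdominance requirement. The synthetic generator
uses the same defaults, keeping tests self-consistent.

## Fitting

`fit_thz_model()` minimizes unweighted least squares on $\Delta\alpha$
over [60, 540] cm^-1 (the acquisition range is 50-550 cm^-1 at 2 cm^-1
resolution; trimming avoids edge artifacts) with box-bounded
Levenberg-Marquardt: centers within ±60 cm^-1 of the initial value,
widths in [10, 2000] cm^-1, amplitudes non-negative. Eight parameters
float by default: both scales plus amplitude, center and width of each
DHO mode. Because cold starts with ~10% parameter offsets can fall
into a bound-pinned local minimum (a displaced, over-broadened DHO
absorbing a neighbouring term), the fitter detects a fitted center
resting on its box bound and retries from a 3x3 grid of ±30 cm^-1
center offsets inside the original bounds, keeping the lowest-SSE
solution. Non-convergence is returned as a flag with best-so-far
parameters, never silently. One-sigma errors come from
$s^2 (J^\top J)^{-1}$ at the optimum (no bootstrap by default).

Under the generator's study conditions (1% of-peak additive noise,
2 cm^-1 grid) the stretching width is the least determined quantity,
with a ~1% relative standard error; centers are determined to ~0.2
cm^-1.

## Lifetimes and Arrhenius analysis

Each fitted width maps to a lifetime via $\tau_i = 1/(\omega_{0,i}c)$
with $c$ in cm/s, reported in femtoseconds ($\omega = 180$ cm^-1 gives
$\tau = 185$ fs); the identity $\tau\,\omega\,c = 1$ holds exactly and
uncertainties propagate as $|d\tau/d\omega|\sigma_\omega$. Lifetimes
outside the 50-200 fs band typical of intermolecular water modes are
flagged as advisory.

`arrhenius_fit()` regresses $\ln v$ on $1/T$; $E_a$ is the slope times
$R = 8.314$ J/mol/K. The sign convention $v = v_\infty
\exp(E_a/RT)$ makes $E_a$ positive for lifetimes that lengthen on
cooling, matching the positive slope of lifetime-vs-$1/T$ plots.
`analyze_series()` fits a temperature series sequentially with warm
starts, excludes non-converged temperatures from the Arrhenius stage
(skipping it with a reason below 3 usable temperatures), and reports
per-mode activation energies. At 1% spectral noise and 15
temperatures spanning 298-340 K the statistical floor on $E_a$ is
roughly 0.15-0.25 kJ/mol, so barriers in the 1.5-7.5 kJ/mol range are
recovered to better than 10%.

# Hydrogen-bond profiling

The geometric criterion is the canonical one: a bond exists when the
donor-to-acceptor heavy-atom distance is at most 0.35 nm under the
minimum-image convention **and** the angle at the donor between the
donor→H and donor→acceptor vectors is at most 30 degrees, evaluated
for every donor hydrogen. We state the angle convention explicitly
because an equivalent formulation (donor-H-acceptor ≥ 150 degrees)
exists; both cutoffs are arguments. Donors are water oxygens and lipid
oxygens bearing a hydrogen; acceptors are water oxygens and any lipid
oxygen; only water-involving bonds (water-water, water-lipid) are
recorded.

`find_hbonds()` uses a linked-cell neighbor list whose result is, by
construction and by test, identical to the all-pairs search — the
brute-force path stays available as `method = "brute"` and the two are
compared on random periodic frames in the test suite. Boxes smaller
than twice the cutoff along a periodic direction are refused.

`hb_profile()` bins each water by the folded distance of its oxygen
from the membrane midplane ($|z_O - z_{mid}|$, minimum image along the
normal; 0.1 nm bins by default) and reports per-bin mean bonds per
water, pooled over frames, split into water-water and water-lipid
parts; empty bins are kept and flagged. The bulk reference comes from
pure-water boxes (`bulk_value()`), and `bulk_recovery_distance()`
returns the smallest occupied bin from which the total coordination
stays within 2% (configurable — the source analyses quote no
tolerance, so we fix one explicitly) of bulk outward; if no bin
qualifies the result is flagged unreached rather than extrapolated.
Because the recovery distance is physically temperature-invariant, the
acceptance analyses summarize it as the median over the temperature
series.

# The synthetic generators

The generators emulate the statistical structure each analysis
assumes, with every true parameter recorded in a `ground_truth` list
sufficient to recompute expected outputs (`expected_hb_profile()` does
exactly that for slabs). They do **not** emulate instrument response,
form factors, or real water structure — passing tests demonstrate that
the estimators recover what the data contain, not that real spectra
look like these.

* `gen_saxs()` places Gaussian peaks at $2\pi\sqrt{N}/a$ with $1/N$
  amplitudes on a linear background, multiplicative Gaussian noise
  (indexing must be amplitude-insensitive, and is).
* `gen_thz_series()` composes spectra from the model above with
  temperature-invariant centers and widths driven by per-mode
  Arrhenius lifetime laws; defaults place the stretching mode at 147
  cm^-1 with $E_a = 3.5$ kJ/mol (width ≈190 cm^-1 at 298 K) and the
  libration at 412 cm^-1 with $E_a = 7.4$ kJ/mol (≈280 cm^-1),
  matching the scale of confined-water observations. Noise is
  additive, 1% of the peak. With `raw = TRUE` the spectra are pushed
  back through the lipid-addition and ATR relations to exercise the
  full conversion chain.
* `gen_slab_frames()` imposes HB statistics **by construction** rather
  than by simulation: isolated donor-acceptor clusters sit on a
  jittered exclusion grid (spacing 1 nm, guaranteeing no accidental
  inter-cluster bonds), and each primary water donates one bond with
  a position- and temperature-dependent probability, to a partner
  water (oriented so it cannot donate back) or, in a Gaussian band
  around ±1.5 nm, to a lipid head oxygen. The expected per-bin mean
  coordination is $M(x, T) = m_b(T)\,[1 - \delta(x)]$ with an imposed
  bulk Arrhenius law $m_b(T) = C e^{E_a/RT}$ ($E_a = 1.48$ kJ/mol,
  $m_b = 0.9$ at 308 K — a dimer-statistics scale, deliberately not a
  physical water coordination number) and a deficit $\delta(x)$ of
  depth 0.14 out to 1 nm, decaying as
  $\sqrt{(x_{edge}-x)/(x_{edge}-1)}$ up to $x_{edge} = 1.5 + 0.9 =
  2.4$ nm. The square-root (concave) ramp keeps the 2%-of-bulk
  crossing within one 0.1 nm bin of $x_{edge}$, which is what the
  recovery-distance contract measures; a linear ramp would place the
  crossing two bins short. Two variance-reduction devices make the
  imposed expectations sharp at 10 frames per temperature: the
  whole-lattice z-shift is stratified across frames (so the frame
  ensemble samples the ramp evenly), and per-bin bond counts are
  floor-dithered with a random phase carried across frames (unbiased,
  cumulative error below one bond per bin). The number of waters per
  frame follows from the exclusion-grid density rather than being a
  free argument, since the grid is what guarantees the no-accidental-
  bond construction.

# Problem sizes and runtime

The shipped tests and the acceptance script use: 200 synthetic peak
sets for indexing; 20 noise seeds for DHO recovery; 50 replicates for
noisy Arrhenius recovery; 50 random frames for the neighbor-list
equivalence; and slabs at 7 temperatures with 10 frames per
temperature (about 290 waters per slab frame, 250 per bulk frame).
These sizes put every statistical check at least ~3 sigma from its
threshold while keeping the whole suite under a minute of computation
for the spectral parts and under half a minute for the slab part.

# Known limitations

* ATR optics use fixed real refractive indices; there is no
  Fresnel-exact or Kramers-Kronig treatment.
* The stretching band is fitted as a single water population; the
  two-population (bulk-like + interfacial) decomposition is out of
  scope.
* The indexing covers the three bicontinuous cubic groups only — no
  hexagonal, lamellar or micellar phases, no form-factor modelling.
* The slab generator's coordination scale is not a physical water
  coordination number; it validates counting, binning and recovery
  logic, not water physics.
* $K_0$ in the interfacial calibration must be supplied (or the
  documented convention accepted); results scale accordingly.
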