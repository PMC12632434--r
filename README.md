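# mesowater

Structure and hydrogen-bond dynamics of water confined in inverse
bicontinuous cubic lipid mesophases.

Lipid cubic phases — gyroid (Ia3d), diamond (Pn3m) and primitive
(Im3m) — drape a bilayer over a triply periodic minimal surface,
confining water in two interpenetrating channel networks a few
nanometres wide. Near the lipid interface water is undercoordinated,
and this interfacial population governs the ultrafast dynamics of the
hydrogen-bond network. `mesowater` is an R toolkit for the three
analyses that quantify this picture:

* **SAXS cubic-phase indexing and geometry.** Bragg peaks at
  $q_N = 2\pi\sqrt{N}/a$ (allowed $N = h^2+k^2+l^2$ per space group)
  are indexed by zero-intercept least squares; the mesophase geometry
  follows from the minimal-surface relations — channel radius
  $r = \sqrt{A_0/(-2\pi\chi)}\,a - l$, lipid length from
  $\phi_L = 2A_0(l/a) + \tfrac{4\pi\chi}{3}(l/a)^3$, and the
  interfacial water fraction
  $f_{w,int} = (-0.543K_0 - 2.092)/\Gamma$ with
  $\Gamma = f_w a^3/(4\pi|\chi|)$.
* **THz absorption decomposition.** ATR intensities become absorption
  spectra through the effective thickness
  $d_s = \lambda/(2\pi\sqrt{n_C^2\sin^2\theta - n_s^2})$ and the
  Beer-Lambert law; water spectra $\Delta\alpha(\nu)$ are decomposed
  into a Debye background, fixed high-frequency terms and two modified
  damped harmonic oscillators (hydrogen-bond stretching ~150 cm⁻¹,
  libration ~410 cm⁻¹). Fitted widths map to lifetimes via
  $\tau = 1/(\omega_0 c)$ and, over a temperature series, to Arrhenius
  activation energies $E_a$ from $\ln\tau$ vs $1/T$.
* **Hydrogen-bond profiling.** Bonds are counted by the geometric
  criterion (donor-acceptor distance ≤ 0.35 nm, H-donor-acceptor angle
  ≤ 30°) with a neighbor list verified against brute force, binned by
  distance from the membrane midplane, and compared with bulk-water
  boxes to locate the bulk-recovery distance $x_c$.

A synthetic-data module (`gen_saxs`, `gen_thz_series`,
`gen_slab_frames`) generates all three kinds of input with recorded
ground truth, so the entire pipeline is testable end to end.

## Worked example

```r
library(mesowater)

## a synthetic diamond-phase SAXS profile at 1% noise
sim   <- gen_saxs("Pn3m", a_nm = 12, n_peaks = 4, noise_sd = 0.01, seed = 7)
fit   <- index_phase(detect_peaks(sim$profile))
print(fit)
#> Cubic phase assignment: Pn3m
#>   a = 12.0224 nm (se 0.0033), relative RMS residual 0.000632, 4 peaks

l <- lipid_length(0.5, coef(fit)[["a_nm"]], "Pn3m")     # 1.632 nm
channel_diameter(coef(fit)[["a_nm"]], l, "Pn3m")$channel_diameter
#> [1] 6.132496
interfacial_water_fraction(0.5, coef(fit)[["a_nm"]], "Pn3m",
                           k0_convention = TRUE)$f_w_int
#> [1] 0.0423

## a 15-temperature THz series: fit, lifetimes, activation energies
thz  <- gen_thz_series(noise_sd = 0.01, seed = 1)
init <- thz_model(stretching = list(a = 3300, nu0 = 152, omega = 170),
                  libration  = list(a = 4500, nu0 = 405, omega = 300))
series <- analyze_series(thz$spectra, init)
print(series)
#> THz temperature series: 15 temperatures (298-340 K), 15 converged
#> Arrhenius fit [stretching]: E_a = 3.566 +/- 0.12 kJ/mol, r^2 = 0.9861 (n = 15)
#> Arrhenius fit [libration]:  E_a = 7.464 +/- 0.074 kJ/mol, r^2 = 0.9987 (n = 15)
```

The indexed lattice parameter lands within 0.2% of the generator's
12 nm truth; the recovered activation energies sit within 2% of the
imposed 3.5 and 7.4 kJ/mol, with the libration barrier roughly twice
the stretching barrier — the signature separating hindered rotation
from hydrogen-bond stretching dynamics in confined water.

For slab frames:

```r
slab  <- gen_slab_frames(seed = 1)
prof  <- hb_profile(slab$slab[["308"]],
                    n_HB_bulk = bulk_value(slab$bulk[["308"]]))
bulk_recovery_distance(prof)$x_c   # ~2.4 nm: headgroup band + 0.9 nm shell
```

`run_pipeline(config)` chains simulate → index → fit → Arrhenius →
interfacial-fraction stages from a nested list or YAML config and
writes a combined report (geometry and lifetime tables, resolved
config, provenance log).

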