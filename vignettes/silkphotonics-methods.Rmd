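---
title: "Methods: disordered-fiber optics in silkphotonics"
author: "silkphotonics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disordered-fiber optics in silkphotonics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`silkphotonics` models the optics of fibers that contain a dense, random
population of axially elongated ("filamentary") air voids — the structure
found in wild-silkmoth cocoon fibers and engineered in biomimetic
regenerated-silk and PVDF fibers. Five physical stages are covered:

1. **Disorder synthesis** (`sample_void_population`,
   `rasterize_cross_section`, `longitudinal_index_sequence`): random fiber
   cross-sections whose void statistics emulate SEM-measured fibers.
2. **Beam propagation** (`make_gaussian_beam`, `propagate`): a scalar
   split-step (paraxial) engine that carries a field along the fiber axis
   through the disorder.
3. **Localization analysis** (`average_log_profile`,
   `fit_localization_length`, `invert_mean_free_path`, `xi_sweep`,
   `hotspot_fwhm`, `transport_ring_image`): the transverse Anderson
   localization observables.
4. **Cylinder scattering** (`cylinder_scattering`,
   `independent_mean_free_path`, `polarization_anisotropy`): exact
   Bessel-series efficiencies for infinite dielectric cylinders, the
   analytic handle on form birefringence.
5. **Radiometry and time-of-flight** (`radiometric_summary`,
   `fit_photon_lifetime`): radiative-cooling figures of merit and photon
   lifetimes from pulse cross-correlations.

# The localization model

A transversely disordered but longitudinally invariant refractive-index
profile localizes a beam in the transverse plane: after an initial
diffusive broadening the beam's mean width saturates, and the
ensemble-averaged exit intensity develops an exponential tail

$$ I(r) \sim \exp(-2 |r| / \xi), $$

whose decay scale is the localization length $\xi$. The transport mean
free path $l^{*}$ follows from the transverse-localization relation

$$ \xi = l^{*} \exp\!\left(\pi k_\perp l^{*2} / 2\right),
   \qquad k_\perp = 2/\omega_0, $$

where $\omega_0$ is the 1/e *field* radius of the entrance beam. The map
$l \mapsto l\,e^{\pi k_\perp l^2/2}$ is strictly increasing, so
`invert_mean_free_path()` solves it by bracketed bisection to $10^{-9}$
relative accuracy; at the reference inputs $\xi = 4.6\,\mu m$,
$\omega_0 = 2\,\mu m$ it returns $l^{*} = 0.989\,\mu m$.

The $\omega_0$ convention is a genuine choice: "beam width" could mean
FWHM or a 1/e radius. We adopt the 1/e *field* radius because
$k_\perp = 2/\omega_0$ presumes it; a different convention rescales
$k_\perp$ by a constant and shifts $l^*$ accordingly.

# The synthetic disorder and what it does (not) capture

`sample_void_population()` draws a Poisson number of elliptical voids
(expected count `density * pi * R^2`) and places them by dart throwing
with strict non-overlap of bounding circles (up to $10^4$ attempts per
void, then an explicit packing error naming the achieved density).
Defaults are the conditions the package's own experiments use:

* **density** 2.2 voids/$\mu m^2$ — the measured areal density of comet
  moth cocoon fibers (5.5 and 17 voids/$\mu m^2$ are the regenerated-silk
  and PVDF values; at those densities smaller voids must be requested or
  packing fails, as in the real materials whose voids are finer).
* **size_range** semi-major axes 0.10–0.25 $\mu m$, i.e. void diameters
  0.2–0.5 $\mu m$, within the observed "hundreds of nanometres" span.
  Two further considerations pin the default: the rasterizer refuses
  grids coarser than the smallest void semi-axis, so the sizes must stay
  resolvable at the visible-light grid spacings the engine needs; and in
  this size window the independent-scattering mean free path at 600 nm
  comes out at $l^{*} \approx 0.8\,\mu m$, the same order as the measured
  $\sim 1\,\mu m$, with a cross-section that decreases monotonically with
  wavelength (larger voids straddle the first Mie resonance, where the
  wavelength dependence inverts and no clean trend exists).
* **eccentricity** uniform in [0, 0.6] — a one-parameter stand-in for
  "irregularly shaped" voids that stays analytically rasterizable.
* **radial sorting** on: the mean semi-axis ramps linearly from the top
  of the size range at the fiber center to the bottom at the edge,
  reproducing the observed small-at-the-edge arrangement. The real
  gradient is unquantified; the linear ramp is the simplest monotone
  choice.
* **refractive indices** $n_\mathrm{matrix} = 1.54$ (silk fibroin in the
  visible, literature value), $n_\mathrm{void} = 1$,
  $n_\mathrm{background} = 1$. The true complex index of comet-moth
  fibroin across 0.4–14 $\mu m$ is not tabulated anywhere we know of;
  all indices are overridable.

`longitudinal_index_sequence()` extends a cross-section axially:
`invariant` (ideal filamentary voids), `morphing` (void centers follow a
random walk whose rms transverse displacement reaches one mean void size
after one `correlation_length` — real filamentary voids drift slowly),
and `particulate` (fully resampled planes, emulating 3D particulate
voids, the diffusive control).

The generator does **not** emulate: true void irregularity beyond
ellipses, size-correlated void clustering, the sericin coating's index
(the optional `sericin_band` is simply void-free matrix), material
absorption in the visible, or axial tapering. Conclusions from passing
tests are therefore about the *model class* — random non-overlapping
ellipse disorder — not about any specific real fiber.

# The propagation engine and its numerical choices

`propagate()` advances the scalar envelope with the symmetric split-step
Fourier scheme: half a diffraction step in the spectral domain, the phase
screen $\exp(i k_0 (n - n_\mathrm{ref})\,\mathrm{d}z)$ in the real
domain, half a diffraction step. Choices that matter:

* **Reference index** $n_\mathrm{ref} = n_\mathrm{matrix}$, minimizing
  the phase-screen magnitude inside the fiber where the beam lives.
* **Sampling rules**, enforced as refusals, not warnings:
  $\mathrm{d}z \le \lambda / (2\,\max|n - n_\mathrm{ref}|)$ and
  $h \le \lambda / (4\,\max n)$. These bounds cap the per-step phase
  jump at $\pi$; they are necessary, not sufficient. At the silk/air
  contrast the split-step error scatters power into the absorber long
  before the bound is reached — exit power through 100 $\mu m$ of
  disorder rises from $6\times10^{-4}$ at $\mathrm{d}z = 0.5\,\mu m$ to
  0.93 at $\mathrm{d}z = 0.05\,\mu m$ on a fixed realization. The
  default $\mathrm{d}z = 0.1\,\mu m$ is chosen from that convergence
  study, and quantitative transport observables should be checked against
  a halved step.
* **Absorbing rim**: a super-Gaussian amplitude mask of width at least
  $5\lambda$; absorbed power is tallied so that (field + tally) is
  conserved to $10^{-6}$ in lossless media — unitarity is a test, not an
  assumption. Experiment geometries must keep the background margin wider
  than the rim; an absorber overlapping the fiber clips the localized
  tail and biases $\xi$ (we observed exactly this before widening the
  default margins).
* **Scalar paraxial approximation**: at the silk/air contrast
  ($\Delta n = 0.54$) scattering angles leave the paraxial cone, so the
  engine is a *qualitative* model of the localization phenomenology —
  adequate for ordering and trend observables, not for quantitative
  $\xi(\lambda)$ prediction. Polarization physics is delegated to the
  cylinder-scattering module.
* **Imaging aperture**: the localization measurements this package
  emulates image the exit facet through an NA = 0.55 objective, which
  cannot collect the wide-angle halo that the paraxial engine retains on
  the grid. `na_filter()` applies the corresponding spectral aperture
  (super-Gaussian edge at $k_\perp = k_0 \cdot \mathrm{NA}$), and
  `xi_sweep()`/`transport_ring_image()` apply it to exit fields by
  default before any intensity analysis.

# Localization analysis choices

* "Averaged intensity profile" is read as *ensemble-and-azimuth average
  of the linear intensity, logarithm afterwards*; the alternative
  (average of log) weighs dark speckles heavily and is not what imaging
  cameras produce.
* Profiles are taken about each image's intensity-weighted centroid, not
  the grid center, since localized hotspots wander off-axis.
* The default tail-fit window runs from the radius where the profile
  falls to 10% of its peak to the radius where it meets 10x the noise
  floor (median of the outermost decile); the window actually used is
  recorded in every fit. Fixed windows can be supplied and are preferred
  when comparing conditions (the default window's outer edge follows the
  noise floor, which shifts with wavelength and absorber geometry).
* Hotspot FWHM: azimuthal average about the refined peak (centroid of
  the above-half-max pixels near the maximum), half-maximum crossing by
  linear interpolation. A flat-topped plateau maximum is an error, not a
  guess.
* Ring transport: the contrast score is (mean intensity in an annulus of
  width twice the aperture diameter at the ring radius minus the mean
  elsewhere inside the fiber) over their sum, bounded in [-1, 1].

# Cylinder scattering

Infinite-cylinder efficiencies at normal incidence use the standard
Bessel-series solution truncated at order $x + 4x^{1/3} + 2$ ($x < 200$
enforced). Polarization naming follows the fiber-measurement convention:
**TE has E along the fiber/void axis** (the textbook literature often
swaps these labels; our TE is the "E-parallel / Case I" solution). The
host must be lossless (real-argument Hankel functions; base R Bessel
functions), while the cylinder index may be complex — complex-argument
$J_n$ comes from Miller's downward recurrence with the
$J_0 + 2\sum J_{2k} = 1$ normalization. Correctness is pinned by three
independent anchors: Rayleigh closed forms
($Q_{TE} = \pi^2 x^3 (m^2-1)^2/8$,
$Q_{TM} = \pi^2 x^3 (m^2-1)^2 / (4 (m^2+1)^2)$, derived from the
small-argument expansions), the optical theorem
($Q_\mathrm{ext}$ from the forward amplitude equals $Q_\mathrm{sca}$ for
lossless media), and frozen reference values from an independent
implementation on another Bessel stack. The Rayleigh TE/TM ratio
$(m^2+1)^2/2 > 1$ is the analytic root of the observed form
birefringence: light polarized along the voids scatters more strongly.

Transport estimates use the independent-scattering approximation,
$l = 1/(\rho \langle \sigma \rangle)$ with
$\langle \sigma \rangle = \langle Q_\mathrm{sca} \cdot 2r \rangle$
averaged over the size distribution by 64-point Gauss–Legendre
quadrature. At 2.2 voids/$\mu m^2$ the voids are a sizable area fraction,
so this is an order-of-magnitude estimate (asserted in tests only as the
bracket 0.1–10 $\mu m$); mean free paths beyond $10^6\,\mu m$ are
reported as `Inf` (dilute limit).

# Radiometry

Emissivity is $1 - R - T$ (Kirchhoff), clipped to [0, 1] with a warning
for excursions up to $10^{-3}$ (instrument noise) and refused beyond.
Weighted scalars are $\int f w\,\mathrm{d}\lambda / \int w\,\mathrm{d}\lambda$
by trapezoidal quadrature on the union grid — exact for piecewise-linear
data and free of oscillation artifacts. Bounds: solar weighting nominally
0.28–4.0 $\mu m$, capped to the spectrum's coverage and required to span
at least 0.4–2.5 $\mu m$; thermal weighting 2.5–25 $\mu m$ at 300 K
(must span 4–14 $\mu m$); window band 8–14 $\mu m$ (the atmospheric
transparency window). Published scalar figures for real fibers never
state their integration bounds, so bounds are always reported alongside
the scalars rather than assumed comparable.

The solar weight is a clearly labeled synthetic stand-in — a 5777 K
Planck curve times a smooth parametric attenuation envelope (logistic UV
cutoff, Gaussian water/CO$_2$ dips). It reproduces the gross shape of
the terrestrial solar spectrum, not its line structure; a user-supplied
AM 1.5 table always takes precedence and is marked
`weight_provenance = "user"`.

# Time-of-flight

Synthetic cross-correlation traces convolve a Gaussian IRF (the
measured IRF's functional form is not parameterized anywhere, and a
Gaussian matches its symmetric single-peak shape) with the causal
normalized decay $e^{-t/\tau}\,\theta(t)$, preserving area exactly so
$\tau = 0$ degenerates to the IRF itself. The fit model is
`baseline + amplitude * (IRF conv decay)(t - t0)` — baseline and time
offset are fitted because measured traces sit on a floor and carry
trigger jitter; Levenberg–Marquardt (`minpack.lm`) with multi-start
$\tau$ initialization on $\{0.25, 0.5, 1, 2, 4\}\times$(trace width
minus IRF width, floored at one sample). The sampling precondition
$\mathrm{d}t \le \min(\mathrm{FWHM}, \tau)/10$ is a refusal.

# Problem sizes of the shipped experiments

The test suite exercises the full pipeline at desk scale, chosen once as
the package's canonical demonstration sizes:

* **Localized-vs-diffusive dichotomy**: fiber radius 6 $\mu m$ at 2.2
  voids/$\mu m^2$, grid $240^2$ at 0.075 $\mu m$, $L = 150\,\mu m$,
  $\lambda = 0.6\,\mu m$, $\mathrm{d}z = 0.1\,\mu m$, ensembles of 10
  seeds per arm. Invariant disorder saturates near 8 $\mu m^2$
  mean-square width while plane-resampled (particulate) disorder grows
  to roughly three times that level.
* **Wavelength trend**: fixed disorder across
  $\lambda \in \{450, 500, 600, 700\}$ nm, grid $288^2$ at
  0.0703 $\mu m$, $L = 120\,\mu m$.
* **Ring transport**: the demonstration geometry (1 $\mu m$ apertures,
  30 $\mu m$ ring, $L = 400\,\mu m$, $\lambda = 0.6\,\mu m$) inside a
  40-$\mu m$-diameter fiber — the diameter of the real fibers the
  demonstration used — on a $500^2$ grid at
  $\mathrm{d}z = 0.0625\,\mu m$, with ring-demo void semi-axes
  0.125–0.25 $\mu m$ so the void-resolvability rule admits that grid.

Larger runs (the 300–1500 $\mu m$ segment set, denser ensembles) use the
same functions with bigger arguments via `xi_sweep()` or
`run_localization_experiment()`.

# Known limitations

* Scalar and paraxial: no polarization coupling, no wide-angle accuracy,
  no backscattering; at $\Delta n = 0.54$ the engine's $\xi$ values are
  phenomenological, not quantitative predictions. In particular the
  engine lands in the deep-localization regime (fitted $\xi$ of one to
  two void spacings), where its fitted $\xi$ *decreases* mildly with
  wavelength over 450–700 nm — the opposite of the weak-localization
  expectation that the localization relation with the
  independent-scattering $l^*(\lambda)$ encodes ($\xi$ rising steeply
  with $\lambda$ for sub-resonance voids) and of what is observed in
  real nanostructured fibers. Reproducing the measured
  weak-localization regime ($\xi \approx 4.6\,\mu m \gg$ void
  spacing) at the true contrast requires a wide-angle vectorial solver
  and is out of scope.
* Independent scattering ignores positional correlations that matter at
  the packed densities of real fibers.
* The localized-tail fit is sensitive to the interplay of fiber radius,
  absorber position and noise floor; comparisons across conditions
  should fix the window.
* The synthetic solar weight is not AM 1.5; scalar solar figures based
  on it are internally consistent but not comparable to published
  values beyond ~0.05 absolute.
* The void-free "control" fiber is a perfect circular multimode
  waveguide; its symmetry gives it image-preserving properties real
  control fibers lack (see the ring-transport discussion in the test
  suite).
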