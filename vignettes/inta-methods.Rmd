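---
title: "Models and methods behind intar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind intar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement problem

Extracellular vesicles (EVs) in blood plasma are heavily outnumbered by
large lipoproteins (chylomicrons/ULDL, VLDL, IDL) of overlapping size
(roughly 30-1000 nm), so sizing alone cannot count EVs. The two particle
classes differ in composition and hence in refractive index (RI): EVs sit
below ~1.40, lipoproteins above it. Interferometric nanoparticle tracking
analysis (iNTA) records, at kilohertz frame rates, both the Brownian motion
of each particle (giving its hydrodynamic size) and its interferometric
scattering (iSCAT) contrast (giving its scattering cross-section). Size and
cross-section together determine an *effective refractive index* -- the
index of the homogeneous sphere that would scatter the same -- and in the
size-RI plane EVs and large lipoproteins form largely separate populations.

`intar` implements this pipeline end to end in R, together with a
ground-truth-labelled simulator used to validate every stage.

## Physical models

**Diffusion.** A particle of hydrodynamic diameter $d$ in a fluid of
viscosity $\eta$ at temperature $T$ diffuses with
$D = k_B T / (3 \pi \eta d)$ (Stokes-Einstein). The simulator and the
estimator call one shared implementation
(`stokes_einstein_diffusion()` / `stokes_einstein_diameter()`), so the
round trip is exact by construction.

**Scattering.** The forward model is the Mie partial-wave series for a
homogeneous, non-absorbing sphere in a homogeneous medium
(`mie_cross_section()`), truncated at
$N = \lceil x + 4x^{1/3} + 2 \rceil$ terms, $x = \pi d\, n_m / \lambda$.
An independently coded Rayleigh closed form
(`rayleigh_cross_section()`) serves as a small-particle oracle in the
tests; the two agree within 1% for $d \le \lambda_{med}/20$, $m \le 1.2$.

**Contrast.** iSCAT contrast is proportional to the scattered field
amplitude: $C = A\sqrt{\sigma}$. The amplitude $A$ is an instrument
calibration constant (`contrast_calibration()`).

**RI inversion.** `invert_effective_ri()` solves
$\sigma_{\mathrm{Mie}}(d, n_p) = \hat\sigma$ for $n_p$ by Brent's method on
$[n_m, n_{max}]$. $\sigma$ is strictly increasing in $n_p$ throughout the
biological regime, so the root is unique. (Strict monotonicity over the
full default bracket $[1.33, 2.5]$ in fact fails in a corner of the
domain -- at $d = 300$ nm the first Mie resonance flattens $\sigma(n)$
above $n \approx 2.4$ -- which is why the bracket is configurable and the
estimation pipeline clamps out-of-bracket solutions rather than failing.)

## The simulator: what it emulates, and what not

`simulate_sample()` draws particles from named populations
(`population_spec()`): diameters lognormal, RIs normal truncated at the
medium index, each matched to a stated median and interquartile range.
Medians and IQRs are the natural parameters here because measured size
distributions of these particles are right-skewed. The shipped presets
(`population_presets()`) carry the iNTA-measured size/RI distributions and
stock concentrations of SKMEL37-derived EVs (97 nm, RI 1.37), chylomicrons
(57 nm, 1.52) and VLDLs (46 nm, 1.49).

Each particle performs a 3-D Brownian walk at the frame rate (default
5 kHz) inside an observation volume: a square field of view (7.1 um) times
a focal slab (default total depth 1.0 um about the focus). The trajectory
is truncated the first time the particle leaves the volume; re-entries
would be new particle ids, matching what frame-to-frame linking would do.
Per-frame contrast is $A\sqrt{\sigma(d, n_p)}$ plus i.i.d. Gaussian noise.

Expected trajectory counts are proportional to concentration:
$E[N] = c \cdot V_{obs} \cdot T \cdot k_{entry}$, with the entry-rate
constant $k_{entry}$ (default 10 /s, the order of the inverse slab
residence time of a ~100 nm particle). The constant is deliberately not
treated as known: absolute concentrations are obtained the way the
instrument obtains them, through a bead dilution-series calibration
(`fit_concentration_calibration()`), which absorbs $k_{entry}$, the
volume, and every other proportionality.

Deliberate simplifications (all documented limits on what a green test can
establish):

* no axial (z-dependent) modulation of contrast -- per-frame contrast
  noise is purely additive Gaussian;
* no hydrodynamic wall effects, particle interactions, or flow;
* localization error enters only through the image pipeline (when used);
  trajectory-level simulations have noise-free positions.

**Free parameters chosen once.** Neither the calibration amplitude nor the
per-frame contrast noise of the real instrument is published. We fixed
$A = 0.01$ contrast per $\sqrt{\mathrm{nm}^2}$ (about 3% contrast for a
100 nm, RI 1.40 sphere -- a typical iSCAT scale) and per-frame contrast
noise sd 0.03. The noise value was chosen, before any acceptance
measurement, so that the RI-precision gate boundary (below) falls near
$d \approx 50$ nm: the qualitative feature that RI becomes unreliable for
particles smaller than ~50 nm, with RI spread growing as size shrinks.

## Per-particle estimation

Only trajectories with **more than 100 localizations** are analyzed; the
filter value is the instrument default and is applied at record
construction.

**Diffusion: covariance-based estimator (CVE).**
$\hat D = \langle \Delta x^2 \rangle / 2\Delta t +
\langle \Delta x_t \Delta x_{t+1} \rangle / \Delta t$, averaged over x and
y. The covariance term exactly cancels the positive bias that static
localization noise adds to the mean squared displacement, making the
estimator unbiased and parameter-free -- the reason it is preferred here
over MSD line fits, whose bias depends on the fitted lag range. The
standard error uses the estimator's known variance formula (Vestergaard et
al., Phys. Rev. E 89, 022726, 2014).

**Cross-section and RI.** The per-trajectory contrast summary is the
*median* of the per-frame contrasts (robust to heavy tails; negative
medians clamp to $\sigma = 0$). $\hat\sigma = (C/A)^2$, and
$\hat n_p$ inverts the Mie model at $\hat d$.

**Precision gate (IQR_S).** For each particle, a Monte-Carlo simulation
(default 200 replicates) redraws its per-frame contrasts about the
estimated value with the configured noise sd, takes each replicate's
median, and re-inverts to RI at fixed diameter. The interquartile range of
those replicate RIs -- IQR_S -- measures how precisely this particle's RI
can be known given contrast noise alone (diameter is treated as exact,
matching the definition). Records pass the gate iff IQR_S is strictly
below the cutoff (default 0.05), and population median RIs are reported
over passing records only. The inversion inside the Monte-Carlo uses a
cached $\log\sigma(d, n)$ grid (60 log-spaced diameters x 235 indices,
linear interpolation, square-root law below the first grid level);
the grid error in $n$ is $\ll 10^{-3}$, far below IQR_S resolution.

**Selection bias the estimator does not undo.** The >100-localization
filter keeps slower -- larger -- particles preferentially, because
residence time in the focal slab scales like $1/D \propto d$. For the EV
preset (median 97 nm, IQR 79-120 nm) the *analyzed* trajectories' true
median diameter is ~106 nm. The pipeline recovers the analyzed particles'
parameters accurately (median within ~1.5%); it does not reweight back to
the pre-filter population, and neither does the real measurement, whose
reported medians carry the same selection. The same mechanism biases the
gated RI median of small, dim populations (e.g. VLDL) downward: the gate
conditions on favourable size/contrast fluctuations. Tests therefore
compare estimates against the truth of the analyzed particles, plus the
one RI anchor the gate is designed for (EV median RI within 0.01).

## Classification

A random forest over (diameter, log10 cross-section, RI) is trained on
records from pure samples (`train_ev_classifier()`). No random-forest
package ships with the target environment, so the forest is implemented in
the package: bagged CART grown to purity, Gini splits, `mtry = 1` of the 3
features, 200 trees, class-balanced bootstrap (each tree resamples
min(n0, n1) records per class), out-of-bag accuracy reported, Gini-gain
feature importance via `tidy()`. Training and prediction are deterministic
given the seed.

`classify_particles()` labels a record EV when the forest probability
$p_{EV}$ reaches the confidence threshold (default 0.8; boundary ties go
to the label, EV side), LP when $p_{EV} \le 1 - $ threshold, and leaves it
unclassified otherwise. Raising the threshold can only shrink the
classified set (tested as an invariant). The relative EV concentration is
the classified count ratio $n_{EV} / (n_{EV} + n_{LP})$: with one
calibration factor for all particles this equals
$C_{EV} / (C_{EV} + C_{LP})$.

**Mixture linearity and expected fractions.** In mixture experiments the
expected relative EV concentration must be computed from *measured*
concentrations of the pure stocks (trajectory counts through the same
calibration), not from nominal particle numbers: the length filter keeps
different fractions of EVs and of faster-diffusing VLDLs (about 2.5x
apart), and this detection-efficiency difference cancels only when the
expected value is built from the same measurement process -- which is how
the mixtures are designed in practice ("equal numbers as estimated by the
instrument"). With that accounting, simulated EV:VLDL mixtures across
expected fractions 0-1 read back with slope ~0.94 and intercept ~0.03,
pure-sample mislabel rates of a few percent, and ~88% of particles
classified at the 0.8 threshold.

## Concentration and plasma back-calculation

`fit_concentration_calibration()` fits a least-squares line through the
origin of known concentration against trajectories per 10 minutes (counts
are normalized to a 10-minute equivalent before the factor is applied).
`trajectories_to_concentration()` multiplies count rate, factor and
dilution. `back_calculate_plasma_concentration()` inverts the enrichment
model $measured = original \times recovery \times V_{plasma}/V_{final}$;
the shipped presets are SEC (80%, 0.5 to 0.1 mL), DMC (33%, 0.5 to
0.1 mL) and DG (25%, 6 to 0.1 mL). Reported values are rounded to 2
significant figures only at display time; full precision is kept
internally. No trajectory-length- or size-dependent detection-efficiency
correction is applied to absolute concentrations -- a known limitation of
count-based calibration transferred from beads to biological particles.

## Image-level pipeline

The optional frame pipeline closes the loop at the pixel level.
`render_frames()` draws each localization as a radially symmetric
interferometric point-spread function (Gaussian core, sd 1.5 px, plus one
negative ring at 3.5 px) scaled by its contrast on a unit background with
Gaussian pixel noise; 55 nm pixels by default.

`median_background_correct()` removes static structure by the pixel-wise
temporal median -- rolling with an odd window, or global over the whole
recording (`window = Inf`). Two numerical pitfalls worth knowing, both
found by the closure tests and both inherent to rolling medians rather
than to this implementation:

* if a particle dwells near one pixel for more than about half the
  window, the median absorbs part of its signal; worse, the resulting
  "trail" is centred on the particle's local median position, so the
  localization is repelled from its own path average. That error is
  *positively correlated* with the particle's displacement and inflates
  CVE diffusion estimates (we measured +15% at a 151-frame window for a
  200 nm particle at 5 kHz). The window must be much longer than the
  single-pixel dwell time; for static backgrounds the global median is
  exact and free of the effect;
* `runmed`'s shrinking end-windows make the first/last few frames
  background-equal (spots vanish there) and can leave faint phantom
  imprints near a track's temporal ends.

`radial_variance_transform()` computes, per pixel, the variance of mean
intensities on integer-radius rings (default 1-6 px) centred there,
via FFT convolution (borders wrap; detections keep a margin). It peaks at
centres of radially symmetric patterns and is invariant under constant
offsets. Detection takes thresholded local maxima ("auto" threshold:
median + 10 robust sd of sampled maps), suppresses secondary maxima
within a separation radius when they are weaker than half their
neighbour (the PSF ring responds at ~10% of the central peak ~4 px away;
two genuine particles respond comparably and both survive), refines
positions by parabolic interpolation, reads contrast off the corrected
frame, and links detections by greedy nearest-neighbour within
`max_disp_px`, with no gap closing. Tracks at or below the
minimum-localization filter are discarded.

In the dilute regime the pipeline is validated end to end: simulate, then
render at signal-to-noise 5, then detect and link, recovering 100% of
trajectories longer than 150 frames with diffusion estimates unbiased
within a few percent. At high particle densities, close encounters merge
detections and split tracks (no gap closing), so closure degrades -- the
reason instruments dilute to a few trajectories per second.

## Numerical choices and degenerate inputs

* Mie series: truncation as above; index-matched spheres return exactly 0.
* Inversion: Brent to 1e-9 in $n$; $\sigma = 0 \to n_m$; above-bracket
  $\sigma$ errors by default, clamps to the bracket edge inside the
  estimation pipeline and the IQR_S Monte-Carlo.
* Degenerate population IQRs (q25 = q75 = median) yield exactly constant
  draws; inconsistent quantiles are rejected.
* Trajectories without consecutive-frame pairs cannot be estimated and
  error; non-positive $\hat D$ records are excluded with a warning.
* All randomness flows through seeds passed to the generating functions;
  identical seeds give byte-identical outputs, and seeded evaluation
  restores the caller's RNG state.
* Probability ties at the confidence threshold are resolved toward the
  confident side with a 1e-9 numerical guard.

## Interfaces

Tibbles in, tibbles out: trajectories (`particle_id`, `frame`, `x_um`,
`y_um`, `contrast`), particle records, and classified records are plain
data frames that pipe through `estimate_particles()`,
`classify_particles()`, `quantify_sample()`. Fitted objects follow broom
conventions (`tidy()`, `glance()`); `plot_size_ri()`,
`plot_mixture_linearity()` and `autoplot()` give the standard views.
Files are CSV plus a JSON sidecar for ground truth and configuration
(content-hashed for provenance); frame stacks serialize as plain text. A
thin command-line wrapper over these functions ships in `inst/cli/inta.R`
with subcommands `simulate`, `analyze`, `train`, `classify`, `quantify`;
configuration is a JSON file mirroring the constructor arguments
(`default_config()`).
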