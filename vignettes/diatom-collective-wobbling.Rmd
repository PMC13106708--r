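---
title: "Modeling phytochrome-gated collective wobbling in diatom populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling phytochrome-gated collective wobbling in diatom populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The phenomenon and the model

Populations of elongated pennate diatoms such as *Phaeodactylum tricornutum*,
sinking quietly after a brief mixing phase, can align near-vertically and
"wobble" — oscillate their tilt — in synchrony, with a natural period of
roughly 140 s per cell. The collective response is gated by a diatom
phytochrome (DPH): it appears under blue (430 nm) or far-red (780 nm)
illumination, is suppressed by red (660 nm), is absent in phytochrome
knockouts, and can be entrained by red or far-red light whose intensity is
pulsed at the natural wobble period. The population signal is read out by
laser diffractometry, and chlorophyll autofluorescence — itself modulated at
the wobble frequency — is a candidate carrier for the cell-to-cell coupling.

`diatomsync` packages this entire chain as a synthetic-data generator plus
the matching analysis pipeline:

1. **Light and photoreceptor** (`light_field()`, `dph_steady_state()`). A
   protocol is a set of spectral bands, constant or sinusoidally modulated.
   The photoreceptor is a two-state pigment with tabulated activation and
   deactivation cross-sections; because photoconversion is fast relative to
   the 140 s wobble, we use the photostationary state within each time step,
   `a = K_act / (K_act + K_deact)`. This makes sensing *ratiometric*:
   scaling all irradiances together leaves `a` unchanged, which is exactly
   the observed blue-to-red-ratio (not total-intensity) dependence. No
   numeric cross-sections are published, so the defaults (activation 1 at
   430 and 780 nm; deactivation 1 at 660 nm and 0.3 at 617 nm; 0 at 530 nm)
   are a qualitative parameterization of the published photoreversibility
   spectrum, stored in configuration and overridable.

2. **Population dynamics** (`simulate_population()`). The literature frames
   the synchronization in terms of weakly coupled phase oscillators but
   writes no equations, so we adopt the minimal model with the stated
   structure — a Kuramoto mean field with external sinusoidal forcing,
   integrated by Euler–Maruyama:

   d&phi;<sub>i</sub> = [&omega;<sub>i</sub> + g<sup>K</sup> K R sin(&Phi; &minus; &phi;<sub>i</sub>)
   + g<sup>F</sup> F &Sigma;<sub>b</sub> m<sub>b</sub> sin(&psi;<sub>b</sub>(t) &minus; &phi;<sub>i</sub>)] dt
   + (2D dt)<sup>1/2</sup> &eta;<sub>i</sub>

   where `(R, Phi)` is the population order parameter (standing in for the
   perceived mean autofluorescence field) and `(m_b, psi_b)` the amplitude
   and phase of each modulated band. Cell tilt is
   `beta_i = beta0 + A sin(phi_i)`.

3. **Observation** (`observe_population()`, `ratio_series()`,
   `emit_fluorescence()`). A geometric forward model for the 32-ring
   laser-diffraction size distribution, the VD1/VD2 `Ratio` orientation
   proxy, and a two-band (λ>645, λ>715 nm) autofluorescence model.

4. **Spectral characterization** (`power_spectrum()`,
   `characterize_peak()`). A variance-normalized FFT periodogram,
   topographic peak prominences, the std(Pro) > 1 fit-mode switch, Gaussian
   fitting, the Pk/FWHM amplitude, and entrainment indices.

5. **Experiment families** (`run_experiment()`): wavelength scan, composed
   red:blue mixing, pulsed-light entrainment, and fluorescence assays, in
   triplicate, with JSON specs and CSV outputs.

## Gating: which light terms does the photoreceptor control?

Knockouts lose both the constant-light collective response and pulsed
entrainment, so the functional-photoreceptor flag gates both the coupling
and the forcing term. The *coupling* gate is the photostationary activation
`a(t)` itself: more red light, lower activation, weaker effective coupling,
smaller collective amplitude — the red:blue mixing phenotype.

The *forcing* gate cannot be the photostationary activation: under pure red
light the steady state is exactly zero, yet pulsed red light entrains
functional strains (this differential response to modulated red light is one
of the paper-level observations the package reproduces). We therefore gate
forcing by the *photoconversion cross-section* `c(lambda)` (activation plus
deactivation weight) of the modulated band: a band the photoreceptor cannot
photoconvert (green) cannot entrain, red and far-red can, and knockouts
never do. The single-gate variant demanded by a strict photostationary
reading remains available via
`simulate_population(forcing_gate = "activation")`.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_cells` | 500 | – | population in the observation volume; large enough that the incoherent floor `E[R] ≈ (√π/2) N^{-1/2} ≈ 0.04` is well separated from synchrony |
| `duration`, `dt` | 7200, 1 | s | the 2 h continuous-light assay at ≥1 Hz sampling |
| `natural_period_mean` | 140 | s | the observed natural wobble period |
| `natural_period_cv` | 0.05 | – | inter-cell dispersion is not quantified in the literature; 5% is a fixture choice that sets the Kuramoto critical coupling |
| `coupling_gain` K | 0.007 | rad s⁻¹ | ≈2× the critical coupling `K_c = 2 σ_ω sqrt(2/π) ≈ 0.0036` for the default dispersion. This is the regime where both observed behaviors coexist: the photostationary gate modulates collective amplitude measurably (red:blue mixing), while the constant-blue state remains about as coherent as pulsed-light locking. A first choice of ~3× critical saturated the amplitude response and was revised once on that ground. |
| `forcing_gain` F | 0.002 | rad s⁻¹ per µmol m⁻² s⁻¹ | with ~4–8 µmol modulated irradiance the locking range `F·m` covers ≈7σ of the natural-frequency spread, so pulsed light at the natural period entrains essentially the whole functional population |
| `phase_noise_intensity` D | 1e-4 | rad² s⁻¹ | weak phase diffusion (σ ≈ 0.17 rad over one period); keeps trajectories stochastic without masking synchrony |
| `mixing_duration` | 100 | s | agitation phase; phases re-randomized every step, excluded from all spectral analyses |
| `mean_tilt` β₀, `wobble_amplitude` A | 0.35, 0.25 | rad | `A < β₀` is enforced so the projected-length observable is monotone in sin(φ) over a cycle and the population signal oscillates at ω, not 2ω |
| `cell_density` | 3e8 | cells L⁻¹ | the assay concentration |
| `noise_cv` (observation) | 0.05 | – | multiplicative lognormal instrument noise; not characterized in the literature, 5% is a typical scale |

## The laser-diffraction forward model

True diffraction inversion is out of scope; the forward model reproduces the
interpretive logic of the two size bands. Each cell's volume share (total
concentration = density × spheroid volume ≈ 14.8 µL L⁻¹) is split between
the bin containing its apparent projected major extent
`L(β) = sqrt(r1² cos²β + r2² sin²β)` and the bin containing the minor axis
`r2`, with weight `w(β) = (L − r2)/(r1 − r2)`. A face-on cell registers
entirely at its major length (VD2 band), an end-on cell entirely at its
minor length (VD1 band), so tilting moves signal between the bands in
opposite directions and `Ratio = ΣVD1/ΣVD2` rises monotonically as cells go
end-on. A literal "one unit in each bin" deposit cannot produce a
time-varying Ratio at the default geometry (the apparent length never leaves
the VD2 band for β ∈ [0.10, 0.60] rad), which is why the weighted split is
used. Band membership is by bin center, stable under grid refinement; the
per-time bin sum is conserved exactly before noise.

## What the generator emulates — and what it does not

A green test establishes that the *model* population behaves like the
observed one at the level of the published claims: spectral selectivity of
synchronization, knockout nulls, ratiometric suppression, pulsed
entrainment, two-band fluorescence modulation. It does not establish
anything about real instrument physics (Mie scattering, ring geometry,
obscuration), hydrodynamics, sinking speeds, photophysiology (quenching,
variable fluorescence), red-noise instrument drift, or the biochemical
mechanism linking photoreceptor state to motility. In particular:

* An incoherent *finite* population is not spectrally flat: N drifting
  oscillators leave an O(1/N) power bump near the wobble band. Knockout
  runs therefore show a weak but topographically prominent bump over the
  small multiplicative noise floor, and are compared against a matched
  incoherent-population Monte-Carlo null rather than against "no peak at
  all". For the same reason the fit-mode switch may classify knockout
  spectra as `main_peak`; real knockout records, with their red-noise
  backgrounds, land in `full_spectrum` mode instead.
* The published per-wavelength relative-prominence statistics derive from
  real instrument recordings and are not reproduction targets.

## Numerical choices

* **Integration**: explicit Euler–Maruyama at `dt = 1 s ≪ 140 s`; a
  dt/10-refinement oracle test bounds the order-parameter error at 0.02.
* **Seeds**: one root seed; frequency draw, initial phases, dynamic noise
  and measurement noise use separate derived sub-streams (`sub_seed()`), so
  identical configurations are bit-reproducible.
* **Periodogram**: single non-Welch FFT periodogram, no taper (a Hann
  window sits behind a flag, off by default), zero frequency excluded,
  power normalized so the retained bins sum to the signal variance
  (Parseval, tested at 1e-9).
* **Relative prominence**: normalized by the median spectral power; the
  normalization is not defined in the source description and the median
  reference reproduces order-unity values for noise-dominated spectra.
* **Fit-mode switch**: sample (n−1) standard deviation of the relative
  prominences; with fewer than two detected peaks the deviation is
  undefined and full-spectrum mode is used. Ties in prominence break toward
  lower frequency.
* **Gaussian fit**: least squares on (log Pk, f0, log σ), multi-start
  Nelder–Mead refined by box-constrained L-BFGS-B with f0 confined to the
  fitted frequency range (preventing a narrow-peak fit from escaping past
  Nyquist); `main_peak` mode fits a ±5·FWHM window around the most
  prominent peak with the initial width taken from the half-width at
  half-prominence.
* **Degenerate inputs**: a zero VD2 band sum flags the time point invalid
  rather than dropping it; interior invalid samples make sampling
  non-uniform and abort the analysis (no silent resampling); series shorter
  than 64 valid samples are refused; sinusoid depth is capped at 1 so
  irradiance never goes negative.

## Open design points, decided

* **Coupling topology**: global mean field. The directional-signal
  possibility raised by the autofluorescence geometry is left as an
  extension.
* **Pulsed-light gating**: instantaneous photostationary activation for the
  coupling gate (a `time_averaged` mode exists); photoconversion
  cross-section for the forcing gate, as argued above.
* **Normalization of the mixing-family amplitude**: to the matched
  blue-only baseline arm, since the published normalization is unstated.
* **Replicate summaries**: per-replicate fit, then mean ± sample SD over
  seeds (n = 3), matching the published triplicate convention.
* **Pulsed protocol normalization**: the modulated band is max-normalized
  (stated irradiance = peak), matching a source attenuated "down to a
  maximum value"; all other protocols treat stated irradiance as the mean.

## Limitations

The coupling gain, forcing gain, noise intensities and anisotropy are
fixture parameters, not measurements; conclusions about *mechanism* cannot
be drawn from them. The observation model is geometric, not optical. The
fluorescence coupling loop is not closed by default — the mean-field term
already abstracts perceived autofluorescence, and whether the photoreceptor
truly reads the time-modulated autofluorescence of neighbours is exactly
the open biological question this model cannot settle.
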