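# diatomsync

Simulation and analysis of **phytochrome-gated collective "wobbling" in
diatom populations**.

Elongated pennate diatoms such as *Phaeodactylum tricornutum*, sinking
undisturbed after a brief mixing phase, can synchronize the periodic
oscillation ("wobbling", natural period ≈ 140 s) of their near-vertical
tilt. The collective behavior is controlled by a diatom phytochrome (DPH):
it appears under blue (430 nm) or far-red (780 nm) light, is suppressed by
red (660 nm) in a ratiometric blue:red fashion, is absent in phytochrome
knockouts, and can be entrained by red/far-red light pulsed at the natural
period — a stimulus that mimics the wobble-modulated chlorophyll
autofluorescence of neighboring cells. The population readout is a
laser-diffraction size distribution, summarized by the orientation proxy

> Ratio(t) = Σ VD1 / Σ VD2,

the quotient of the volume concentrations in the size bands of the cell's
minor (VD1 = 2.5–3.5 µm) and major (VD2 = 7.33–14 µm) axes.

`diatomsync` provides, for anyone who wants to prototype or stress-test
analyses of such experiments without instrument data:

* a **two-state photoreceptor model**: photostationary activation
  `a = K_act/(K_act + K_deact)` under arbitrary multiband illumination
  protocols (JSON-serializable), with a parameterized action spectrum;
* a **light-gated Kuramoto population simulator**:
  `dφᵢ = [ωᵢ + gᴷ K R sin(Φ−φᵢ) + gᶠ F m sin(ψ(t)−φᵢ)] dt + √(2D dt) η`,
  with mean-field coupling (standing for perceived autofluorescence),
  sinusoidal forcing from modulated bands, phytochrome gating, knockout
  genotypes, and a 100 s mixing phase;
* a **laser-diffraction forward model**: 32 log-spaced size classes,
  orientation-dependent volume deposits, the Ratio proxy, lognormal
  instrument noise;
* a **two-band autofluorescence model** (λ>645 / λ>715 nm);
* the **spectral peak characterization** used for such records:
  variance-normalized FFT periodogram, topographic peak prominences (Pro),
  the std(Pro) > 1 fit-mode switch, Gaussian fit, peak amplitude Pk, FWHM,
  the Pk/FWHM oscillation amplitude, and pulsed-versus-constant
  entrainment indices;
* **experiment runners** for the four assay families (wavelength scan,
  composed red:blue, pulsed entrainment, fluorescence), in triplicate,
  with CSV/JSON outputs and a small CLI.

See `vignettes/diatom-collective-wobbling.Rmd` for the model, parameter
choices, and limitations.

## Worked example

Simulate the standard continuous-blue assay (500 wild-type cells, 2 h,
430 nm at 8 µmol photons m⁻² s⁻¹), observe it through the diffractometer
model, and characterize the Ratio spectrum:

```r
library(diatomsync)

field <- light_field(spectral_band(430, 8), 7200)
cfg   <- sim_config(seed = 1)                 # 500 WT cells, 7200 s, dt 1 s
traj  <- simulate_population(cfg, field)
traj
#> population_trajectory: 500 WT cells, 7201 samples @ dt 1 s
#>   mean R (sedimentation phase): 0.817; mean DPH activation: 1.000

set.seed(sub_seed(1, 77))                     # measurement-noise stream
scs <- observe_population(traj)               # time x 32 size classes
rs  <- trim_ratio_series(ratio_series(scs), 100)  # drop the mixing phase
characterize_peak(power_spectrum(preprocess(rs)))
#> spectral_peak_summary [main_peak]: Pk 0.007448, f0 0.007147 Hz (period 139.9 s), FWHM 0.0001114 Hz
#>   Pk/FWHM = 66.85; 1200 prominence(s), top 3.36e+05
```

Reading the output: the population synchronizes under blue light (order
parameter R ≈ 0.82, where the incoherent floor for N = 500 is ≈ 0.04), DPH
is fully activated, and the Ratio periodogram has one towering peak
(std(Pro) ≫ 1 → `main_peak` fit) at f₀ = 0.00715 Hz, i.e. a collective
wobble period of 139.9 s, with normalized oscillation amplitude
Pk/FWHM ≈ 67. A knockout run (`sim_config(seed = 1,
genotype = genotype("KO"))`) yields Pk/FWHM below 0.1 — the
wild-type/knockout contrast exceeds two orders of magnitude.

Full assay families run from a spec:

```r
spec <- experiment_spec("pulsed", genotypes = c("WT", "KO"), seeds = 1:3)
res  <- run_pulsed(spec)       # entrainment indices per strain/wavelength
```

or from the command line:

```sh
Rscript inst/cli/diatom-sync.R run --config spec.json --out results/
Rscript inst/cli/diatom-sync.R analyze --ratio-csv ratio.csv --tmin 100
Rscript inst/cli/diatom-sync.R fixtures --out fixtures/
```

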