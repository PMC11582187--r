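# gelstrain

Epicardial hydrogel patches can restrain ventricular dilation after
myocardial infarction, but a patch only helps if its mechanics suit the
heart it sits on: its **gel point** — the frequency f<sub>GP</sub> at which
the storage modulus G′ equals the loss modulus G″, and the common modulus
G′<sub>GP</sub> there — should match the heart rate and myocardial
stiffness of the target species.  Below f<sub>GP</sub> the patch flows and
relaxes prestress; above it the patch carries elastic load.  `gelstrain`
implements the computational side of designing such "heart-rate-matched"
viscoelastic gelatin patches and of measuring their effect on regional wall
mechanics, for two audiences: biomaterials researchers tuning
dynamically-crosslinked hydrogel recipes, and cardiac imaging analysts
quantifying strain coordination at an infarct border.

The package has four connected parts:

* **Linear viscoelasticity** — a generalized Maxwell (Prony series)
  material G(t) = Σ G<sub>i</sub> e<sup>−t/τ<sub>i</sub></sup> with
  storage/loss moduli
  G′(ω) = Σ G<sub>i</sub>(ωτ<sub>i</sub>)²/(1+(ωτ<sub>i</sub>)²),
  G″(ω) = Σ G<sub>i</sub>(ωτ<sub>i</sub>)/(1+(ωτ<sub>i</sub>)²);
  gel-point extraction from frequency sweeps (`find_gel_point()`),
  second-order Maxwell fitting of stress-relaxation curves
  (`fit_relaxation()`), and Boltzmann-superposition stress simulation under
  arbitrary strain histories (`simulate_stress()`,
  `cycles_to_convergence()`).
* **Formulation design** — a calibration from measured design points
  mapping a recipe (gelatin wt%, fluorinated:plain phenylboronic-acid
  crosslinker fraction) to its gel point (`predict_gel_point()`), a
  species-aware matcher (`match_formulation()`), and a constructor of
  Maxwell spectra realizing a recipe's gel point
  (`formulation_to_modes()`).
* **Strain mapping** — the 24-segment circumferential strain analysis of
  left-ventricular short-axis wall contours: per-segment
  ε<sub>cc</sub> = (l<sub>systolic</sub> − l<sub>diastolic</sub>) /
  l<sub>diastolic</sub> × 100 %, the circular adjacent-segment strain
  differential Δε<sub>cc</sub>[k] = |ε<sub>cc</sub>[k] −
  ε<sub>cc</sub>[k+1]|, and its maximum over the cardiac cycle, which peaks
  at the infarct border (`analyze_cine()` and friends), plus scalar
  histology formulas (`tunel_fraction()`, `infarct_percentage()`,
  `min_wall_thickness()`).
* **Synthetic data** — seeded generators for rheometer sweeps, relaxation
  curves and a beating-ventricle contour phantom with known per-segment
  ground truth (`generate_sweep()`, `generate_relaxation_curve()`,
  `generate_lv_cycle()`), so the whole pipeline is testable without any
  instrument data.

Everything is data-frame-first and pipe-friendly: sweeps, relaxation
curves, contours and strain maps are tibbles; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

Design a rat-matched patch, realize it as a Maxwell material, "measure" it
with a simulated noisy sweep, and recover the gel point:

```r
library(gelstrain)

match_formulation(heart_spec("rat", g_myo_pa = 5000, h_myo_mm = 2,
                             h_graft_mm = 0.3, rate_band_hz = c(3.5, 4.5)))
#>   species gtn_wt_percent fpba_fraction f_gp_hz g_gp_pa target_modulus_pa within_band
#> 1     rat             15           0.2       4    1300              1300        TRUE

modes <- formulation_to_modes(formulation(15, 0.2))
modes
#> Maxwell spectrum: 2 mode(s), G0 = 3550.03 Pa
#>   modulus_pa  tau_s
#> 1       710. 0.209
#> 2      2840. 0.0209

sweep <- generate_sweep(modes, 0.5, 10, 40, noise_cv = 0.01, seed = 1)
find_gel_point(sweep)
#>   f_gp_hz g_gp_pa
#> 1    4.17   1330.
```

The matcher returns the 15 wt% gelatin recipe with 20 % fluorinated
crosslinker, whose calibrated gel point (4 Hz, 1.3 kPa) sits inside the
requested rat heart-rate band; the constructed two-mode spectrum realizes
that gel point, and re-measuring it from a 1 %-noise simulated sweep
recovers it to a few percent.

Strain mapping on a synthetic infarcted ventricle (90° noncontractile arc
centred at 90°, 1 % contour noise):

```r
out <- generate_lv_cycle(lv_phantom_spec(transition_width_deg = 0,
                                         point_noise_sd_mm = 0.035,
                                         seed = 1))
sm <- analyze_cine(out$cine)
glance(sm)
#>   n_frames n_segments reference_frame_index end_systole_index
#> 1       20         24                     0                10
#>   mean_systolic_strain_pct min_systolic_strain_pct max_peak_strain_differential_pct
#> 1                -5.276543                -22.8904                         81.77465

d <- sm$differentials
d$boundary_index[which.max(d$delta_epsilon_cc_pct)]   # 8
out$truth$border_boundaries                           # 2 8
```

Healthy wall contracts about −20 %, the infarct arc stretches passively,
and the largest strain differential localizes the infarct border: boundary
8 (between segments 8 and 9, i.e. at 135°) is one of the generator's two
true border boundaries.  With a perfectly sharp (zero-width) border the
wall has a radial step at each infarct edge, so the differential there is
dominated by that step; smoothing the transition
(`transition_width_deg > 0`) gives differentials on the scale of the
healthy-infarct strain contrast instead.

## Command line

A thin wrapper over the same functions lives at `inst/cli/gelstrain.R`
(subcommands `design`, `gelpoint`, `fit-relax`, `strain`, `synth`; exit
codes 0 ok / 2 config / 3 data / 4 numerical).

## Documentation

The methods vignette (`vignettes/patch-design-and-strain-mapping.Rmd`)
describes the model assumptions, the calibration construction, the
segmentation geometry, the synthetic generators and their limitations, and
every numerically consequential design choice.
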