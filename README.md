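# batmri

Quantitative water-fat MRI analysis of human supraclavicular brown adipose
tissue (BAT) under cold exposure.

Cold-activated BAT combusts intracellular lipid to produce heat, and that
combustion is visible in chemical-shift encoded (Dixon) MRI as a drop in the
proton-density fat fraction (FF). `batmri` implements the complete analysis
chain for a paired thermoneutral / post-cooling protocol:

1. **Water-fat reconstruction.** A six-echo complex gradient-echo signal is
   modelled per voxel as

   ```
   s(t) = (W + F · Σₘ αₘ e^{i 2π fₘ t}) · e^{i 2π ψ t} · e^{−t/T2*}
   ```

   with water and fat amplitudes `W`, `F`, a six-peak triglyceride fat
   spectrum `(fₘ, αₘ)`, off-resonance field map `ψ` (Hz) and a
   mono-exponential `T2*`. Fitting uses variable projection over
   `(ψ, R2*)` — the amplitudes are solved linearly at each candidate — with
   the water-fat ambiguity in `ψ` resolved by a low-resolution grid search
   plus region growing that propagates the spatially smooth field-map
   branch. The fat fraction is then

   ```
   FF(x,y,z) = SignalFat(x,y,z) / (SignalFat(x,y,z) + SignalWater(x,y,z))
   ```

2. **Threshold segmentation and global analysis.** Estimated BAT volume
   (`Vol_BAT` = voxel count × 0.548 µL), global FF (`FF_Glob`) and T2*
   (`T2*_Glob`) inside FF threshold ranges (30–100% by default), 0.5%-bin
   volume histograms, per-10%-interval volume changes, and full
   (lower, upper) threshold-sweep heatmaps of every cold-induced change.
   Voxels below the lower threshold are excluded in both the thermoneutral
   and post-cooling ROIs for the paired FF/T2* comparisons. A deltoid
   subcutaneous fat ROI (`FF_SAT`, 70–100%) serves as negative control.

3. **Mass and energy.** FF is read as a volume fraction: 1 µL of lipid is
   0.92 mg and 9.4·10⁻³ kcal; 1 µL of lean (water-bound) tissue is 1.06 mg
   and 1.0·10⁻³ kcal. A voxel of 1 µL at FF 50% is therefore 0.5 µL fat +
   0.5 µL lean, and depot totals give tissue mass and metabolizable energy
   content per FF range.

4. **Voxel-wise analysis.** After 3×3 in-plane neighborhood smoothing of
   both time points, per-voxel (FF, ΔFF, T2*, ΔT2*) tables, 2-D joint
   histograms, and k-means clustering with the elbow rule (smallest k whose
   between-/total-variance ratio reaches 95%).

Because no MRI data are deposited with the study this package follows, all
stages are exercised end-to-end on a **synthetic digital phantom**: a
seeded supraclavicular-like depot with lobular low/high-lipid texture
(FF 0.30–1.00), T2* rising from ~10 ms at low FF to ~22 ms at high FF, a
smooth polynomial off-resonance field, a disjoint subcutaneous control
region, and a cold-exposure response that concentrates losses in lipid-rich
zones with gains in leaner ones.

## Worked example

```r
library(batmri)

ph     <- generate_phantom(shape = c(32, 32, 8), seed = 7)
echoes <- simulate_echo_series(ph, acquisition_params(noise_sd = 0.005), seed = 1)
maps   <- reconstruct_maps(echoes)
maps
#> Quantitative water-fat maps: 32 x 32 x 8 grid, 8192 fitted voxels
#>   FF 0.032-0.994, T2* 1.0-200.0 ms, field map -253..247 Hz

depot_summary(maps$ff, maps$t2star, roi_mask(ph$roi, 0.548),
              threshold_range(30, 100))
#>             label     timepoint lower upper n_voxels vol_ml ff_glob t2_glob
#> 1 supraclavicular thermoneutral    30   100      721 0.3951   52.19   13.63

depot_totals(maps$ff, roi_mask(ph$roi, 0.548), threshold_range(30, 100))
#> Depot composition, FF 30-100%
#>   volume 0.4 mL; fat 0.2 g, lean 0.2 g; energy 2.1 kcal (91% from fat)

voxel_composition(0.5, 1)   # a 1-uL voxel at FF 50%
#>   fat_volume lean_volume fat_mass lean_mass fat_energy lean_energy total_energy
#> 1        0.5         0.5     0.46      0.53     0.0047       5e-04       0.0052

estimated_volume(93275, 0.548)   # the protocol's voxel-count example
#> [1] 51.1147
```

Here 721 segmented voxels × 0.548 µL give a 0.40 mL depot with a global FF
of 52% and T2* of 13.6 ms; its energy equivalent (2.1 kcal) is 91% lipid.
A full cohort run — nine simulated subjects, both time points, all tables,
sweep grids and the cluster report written as CSV/JSON —:

```r
report <- run_pipeline(default_config(seed = 1), out_dir = "bat_run")
```

## Vignette

`vignettes/bat-quantification.Rmd` documents the signal model and fitting
strategy, the phantom's design (what it emulates and what it deliberately
does not), all tunable parameters with units and defaults, numerical
choices, and known limitations.
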