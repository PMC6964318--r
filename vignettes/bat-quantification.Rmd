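---
title: "Quantifying brown adipose tissue with water-fat MRI: models, phantom and design choices"
author: "batmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying brown adipose tissue with water-fat MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batmri)
```

## The measurement problem

Human brown adipose tissue (BAT) in the supraclavicular depot burns
intracellular lipid when activated by cold. In chemical-shift encoded MRI
the lipid content of every voxel is visible as the proton-density fat
fraction (FF), so a paired thermoneutral / post-cooling scan pair turns
thermogenesis into an imaging observable: activated regions lose FF, and
the lost lipid volume can be translated into mass and metabolizable
energy. The catch is that every downstream number — "BAT volume",
"global FF", "energy content" — depends on how the depot is segmented,
because supraclavicular adipose tissue is a juxtaposition of low- and
high-lipid zones and the cold response is spatially heterogeneous. This
package implements the full analysis chain and makes the
threshold-dependence itself a first-class output (threshold-sweep grids),
exercised end-to-end on a synthetic phantom.

## Signal model and reconstruction

Per voxel, the complex signal at echo time $t$ is modelled as

$$ s(t) = \Big(W + F \sum_m \alpha_m e^{i 2\pi f_m t}\Big)\,
   e^{i 2\pi \psi t}\, e^{-t/T_2^*}, $$

with complex water/fat amplitudes $W, F$, a multi-peak fat spectrum
$(f_m, \alpha_m)$ with $\sum_m \alpha_m = 1$, off-resonance $\psi$ (Hz) and
a single mono-exponential $T_2^*$ shared by both species. The default
spectrum is the standard six-peak triglyceride model (relative amplitudes
0.047, 0.039, 0.006, 0.120, 0.700, 0.088 at +0.60, −0.50, −1.95, −2.60,
−3.40, −3.80 ppm from water); it is stored as data
(`fat_spectrum_6peak()`) and can be overridden. Acquisition defaults
follow the supraclavicular protocol: six echoes, first TE 1.98 ms, echo
spacing 1.75 ms, 3 T.

**Fitting.** For fixed $(\psi, R_2^*)$ the amplitudes enter linearly, so
each voxel reduces to a 2-column complex least-squares problem (variable
projection, solved in closed form from the 2×2 Gram system). The two
nonlinear parameters are then refined by Gauss–Newton on the projected
residual; the normal matrix of this parameterisation is analytically
diagonal, so $\psi$ and $R_2^*$ update independently, with per-voxel step
halving. $T_2^*$ is bounded to 1–200 ms.

**Field-map ambiguity.** The residual as a function of $\psi$ is periodic
with $1/\Delta TE$ (571 Hz) and has local minima whose basins correspond
to water-fat role exchange ("swaps"). Resolution follows the standard
two-stage scheme: a low-resolution (in-plane block-averaged) grid search
over $\psi \in \pm 1/(2\Delta TE)$ in 2 Hz steps — well below the 435 Hz
dominant fat shift — followed by region growing. Growth starts at the
strongest-signal voxel on its global residual minimum; each frontier
voxel, visited in order of decreasing magnitude, accepts the local minimum
nearest the median $\psi$ of its already-labelled 6-neighbours. This
exploits the one physical constraint that distinguishes the true branch:
$B_0$ inhomogeneity is spatially smooth while swaps are not. The grown
field is upsampled as the initialisation for full-resolution fitting.

The fat fraction is computed from the magnitude amplitudes,
$FF = |F| / (|F| + |W|)$, matching the signal-fat-fraction definition;
voxels with no signal or a singular subproblem are flagged in `fit_ok`
and carry `NA`, never a silent zero. On the noiseless 32×32×8 phantom the
round trip recovers FF to ~4·10⁻⁸ and $T_2^*$ to ~4·10⁻⁶ ms — the model
space contains the truth, so residual error is purely numerical — and the
relevant tests assert the much looser 0.005 / 0.5 ms bounds that remain
meaningful under model mismatch.

**Not corrected** (deliberately, matching the protocol this mirrors):
T1 bias (flip angle 8°, TR 15 ms), eddy-current phase errors, noise-floor
bias in magnitude amplitudes. These shift absolute FF slightly but cancel
to first order in the paired pre/post differences the analysis is about.

## Segmentation and global quantities

Thresholds are expressed in percent and applied inclusively
(`lower ≤ FF ≤ upper`). The default lower floor of 30% excludes the
boundary voxels adjacent to muscle. Two selection conventions coexist, and
the package keeps them explicit:

- **Volume and energy** segment each time point independently — the depot
  may genuinely shrink or grow across the threshold.
- **Paired FF and T2\*** use the joint rule: voxels below threshold at
  either time point are excluded from both, so the comparison is always
  within the same tissue sample.

Transformed ROIs remain floating-point; fractional weights multiply voxel
contributions by default, with an optional binarised mode for integer
voxel counting (the convention behind the worked 93,275-voxel → 51 mL
example). Threshold-sweep grids evaluate every admissible (lower, upper)
pair at 1% steps — fine enough to resolve single-percent extrema — using
sorted prefix sums (volume/energy, exact) and 2-D binned box sums at the
step granularity (paired FF/T2*). Statistics follow the protocol:
Shapiro-Wilk on differences, two-sided paired t-tests at 0.05,
no multiple-comparison correction; zero-variance differences are reported
as degenerate (`p = NA`, or `p = 1` for identical pairs) rather than a
spurious `p = 0`.

## Mass and energy

FF is read directly as a volume fraction: a 1 µL voxel at FF 50% is
0.5 µL fat + 0.5 µL lean tissue. Composition constants (per µL: fat
0.92 mg, 9.4·10⁻³ kcal; lean 1.06 mg, 1.0·10⁻³ kcal) live in
`composition_constants()` rather than being hard-coded, because published
per-voxel worked values (0.455 mg fat / 0.540 mg lean at FF 50%) differ
slightly from what the stated densities give (0.460 / 0.530); the package
follows the stated constants and leaves them auditable. Since the lipid
energy density is ~9× the lean one, depot energy is lipid-dominated
(≥ 80% whenever mean FF ≥ 0.3), which is why energy conclusions are so
sensitive to the analysed FF range: losses concentrate in the 70–100%
range while the 30–70% range can show a gain.

## The synthetic phantom

No imaging data are deposited with the study this package follows, so the
phantom is the test bed and defines the study conditions. Defaults: grid
64×64×16, voxel volume 0.548 µL (the protocol's per-voxel analysis
volume; its stated 1.1 mm acquisition resolution would give 1.331 µL —
reconstruction interpolation presumably intervenes, and the phantom
treats voxel volume as a free parameter rather than resolving this),
nine subjects.

**Anatomy and texture.** An ellipsoidal depot ROI (semi-axes varying
±20% across subjects) and a disjoint subcutaneous slab (the FF_SAT
control) sit inside a body mask. Depot FF is a logistic-sharpened sum of
seeded Gaussian blobs mapped to [0.30, 1.00], giving lobular low/high-FF
zones with the high-lipid mode near FF 0.72 — the placement matters: it
puts the bulk of the tissue close above the 50% and 70% thresholds, which
is what makes threshold-crossing (and hence threshold-dependence of every
global quantity) possible. A per-subject composition bias varies mean FF
moderately across the cohort. $T_2^*$ is a monotone map of FF (~10 ms at
FF 0.3 to ~22 ms at FF 1.0) plus smooth noise; the field map is a smooth
random low-order polynomial spanning tens of Hz.

**Cold response.** Post-cooling FF is
$\,ff - m(x)\,[L\,\sigma((ff-\tau)/w) - G\,\sigma(-(ff-\tau)/w)] +
\varepsilon$, clipped to [0, 1]: lipid-rich voxels lose up to $L$, lean
voxels gain up to $G$, with a logistic transition at $\tau$. The factor
$m(x)$ is a seeded smooth *response field* with mean 1 and range
$1 \pm h$ ($h = 1$ by default, sharpened to near-bimodal): strongly
responding and near-silent zones coexist, as they do in real tissue. This
heterogeneity is not decorative — with a spatially uniform response, the
joint-rule FF change would grow more negative as the lower threshold
rises, the opposite of what tissue with threshold-crossing losers shows.
Defaults ($L = 0.16$, $G = 0.08$, $\tau = 0.45$, $w = 0.05$, voxel noise
0.015, $T_2^*$ shift +1.5 ms) were frozen after a design scan at the
study conditions against the qualitative pattern the analysis must
resolve: FF decrease shrinking as the lower threshold moves 30→70%,
volume decrease growing, energy change negative at 70–100% and positive
at 30–70%, per-bin volume loss at 90–100% with gain at 30–40%, and a null
subcutaneous control. The effect size is stronger than a typical human
cohort's (global FF drop ~14 vs ~3.5 percentage points) so that the
directional pattern is resolvable with nine subjects on a 64×64×16 grid;
the package's statistics do not depend on that scale.

**What the phantom does not emulate:** real anatomy, coil sensitivities,
motion and respiration, registration error (pre and post are generated on
a common grid; the deformation-field interface is exercised with
synthetic smooth fields instead), partial-volume mixing at depot
boundaries, and T1/spectral-model mismatch. Passing tests therefore
demonstrate correctness of the analysis chain under the stated forward
model, not robustness to acquisition artifacts.

**Cohort mode.** `simulate_cohort()` runs the full
simulate→reconstruct path per subject when `use_recon = TRUE`; by default
it uses the truth maps plus Gaussian measurement noise at the level the
reconstruction delivers (FF sd 0.003, T2* sd 0.2 ms, from the noise study
at SNR ≈ 200). Reconstruction accuracy is validated separately at
32×32×8; the cohort-level analyses are about segmentation and statistics,
and this split keeps the default test and acceptance runs to tens of
seconds.

## Voxel-wise analysis

Both time-point stacks are smoothed with a 3×3 *in-plane* neighborhood
mean (edge replication) before differencing; the neighborhood is read as
2-D because the protocol writes two dimensions, with a 3×3×3 variant
behind the `three_d` flag. Joint histograms use half-open bins (top edge
closed) so marginals conserve counts, defaulting to 1% FF × 1 ms T2*.

K-means clustering (on z-scored columns, since FF in percent and T2* in
ms are incommensurate) selects k by the explained-variance elbow rule:
the smallest k whose between-group / total sum-of-squares ratio reaches
95%. Each k gets seeded random restarts plus a warm start from the
previous solution with one added centre, which guarantees the
explained-variance curve is non-decreasing. Two caveats are inherent to
the rule and surfaced honestly: explained variance at k = 1 is zero by
definition, so k = 1 can never satisfy a positive cutoff; and diffuse
continuum-like clouds (including this phantom's pooled voxel table) may
reach no cutoff at any small k, which is reported with a warning and a
fall-back to `k_max` rather than silently accepting a spurious partition.
On genuinely clustered data (four planted blobs) the rule selects k = 4
with near-perfect label recovery.

## Numerical choices, in brief

- Field-map grid step 2 Hz over ±285.7 Hz; local minima detected on the
  circular residual profile; seeds per connected component.
- Gauss–Newton: 40 iterations, up to 8 step halvings, convergence to the
  initialisation's basin (by design — basin choice is the field map's
  job).
- Degenerate voxels (zero signal, singular Gram system) are flagged, not
  guessed.
- Prefix-sum sweep evaluation is exact for volume/energy; paired FF/T2*
  grids bin at the sweep step, so threshold pairs are resolved at step
  granularity (values lying exactly on interior bin edges are a
  measure-zero event for continuous data).
- All randomness is seeded and every output is reproducible
  bit-for-bit from a configuration; `run_pipeline()` writes the resolved
  configuration beside its outputs.

## Problem sizes used by tests and the acceptance run

Unit and property tests use 16³ random volumes and 32×32×8 phantoms; the
round-trip fixture is built once per test run. The cohort suite runs nine
subjects at 64×64×16 in truth-map mode (~15 s); the acceptance script
additionally reconstructs one noiseless 32×32×8 subject (~1 s). These
sizes were chosen so the whole battery runs comfortably on a laptop while
every stage is still exercised at realistic dimensionality.

## Known limitations

- Signal FF is used as a volume fraction without proton-density or T1
  correction, as in the protocol; absolute masses inherit that bias.
- The energy framework counts standing energy content, not flux; no
  statement about expenditure is possible from two time points.
- Registration is consumed, never computed: the deformation interface
  accepts external dense fields (pulling convention, mm) and the package
  ships only synthetic test fields.
- The elbow rule's 95% cutoff is a convention; for continuum-like data it
  is better read as "no clear cluster structure" than as a cluster count.
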