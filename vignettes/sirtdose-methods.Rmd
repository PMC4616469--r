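---
title: "Partition-model dosimetry for Y-90 microsphere SIRT: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partition-model dosimetry for Y-90 microsphere SIRT: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirtdose)
```

# The dosimetry model

Selective internal radiation therapy (SIRT) delivers Y-90-labelled resin
microspheres to liver tumors through the hepatic artery. Because neither the
Tc-99m macroaggregated-albumin (MAA) surrogate injected at planning
angiography nor the microspheres themselves redistribute after implantation,
the effective half-life in tissue equals the physical half-life and the
absorbed dose of a tissue compartment is fully determined by its initial
activity and mass:

$$D = k \, \frac{A_0}{m}, \qquad k = 49.67\ \mathrm{Gy\,kg\,GBq^{-1}},$$

with $A_0$ the initial compartment activity (GBq) and $m$ the compartment
mass (kg). The constant $k$ is the canonical value for complete in-situ
decay of Y-90 (half-life 2.67 d, mean beta energy 0.927 MeV, essentially
full local absorption); numerically integrating the total decay energy from
those physical constants gives 49.4–49.7 Gy kg/GBq, and the package pins
`Y90_DOSE_CONSTANT = 49.67`, exposed as an argument of every dose function
for sensitivity analysis.

The **partition model** used here has four compartments: tumor, *in-target*
normal liver (non-tumorous liver supplied by the treated artery),
*out-target* normal liver (supplied by other arteries), and the lungs,
which receive activity through arteriovenous shunting. The injected
activity $A$ is apportioned as

$$A_{0,\mathrm{lung}} = A \cdot \mathrm{LSF}, \qquad
  A_{0,p} = (1-\mathrm{LSF})\, A \,
  \frac{C_p V_p}{\sum_{q} C_q V_q}, \quad p \in \{\mathrm{tm,in,out}\},$$

where $C_p$ is the mean count concentration of partition $p$ on the
emission scan, $V_p$ its VOI volume, and LSF the lung shunt fraction. The
lungs are apportioned first because the LSF is, by definition, the shunted
fraction of everything injected; the count-proportional split then divides
the remainder among the liver partitions. Conservation
$\sum A_{0,c} = A$ is exact by construction and enforced in tests to
$10^{-9}$ relative. Because only count *ratios* enter, the model is
invariant to the absolute count scale, and doses are linear (homogeneous of
degree one) in the injected activity.

Masses use tissue densities of 1.0 kg/L for tumor and liver partitions and
0.3 kg/L for the lungs. The lung mass uses a population CT-based lung
volume of 3.3 L (0.99 kg) rather than a per-case measurement, since the
emission scans do not delineate the whole lungs.

The lung shunt fraction is measured two ways, matching clinical practice:

* **Planar (planning)**: on the conjugate anterior/posterior whole-body MAA
  scan, $\mathrm{LSF} = TC_\mathrm{lung} / (TC_\mathrm{lung} +
  TC_\mathrm{liver})$ with $TC$ the conjugate-view counts of the lung and
  liver ROIs. The anterior and posterior ROI counts are combined by the
  geometric mean, the standard conjugate-view estimator; the source does
  not state the combination rule, so this choice is pinned here and noted
  as a design decision. Planar attenuation is off by default
  ($\mu = 0$); `project_planar()` exposes $\mu$ for sensitivity studies.
* **Volumetric (post-treatment)**: Y-90 PET covers one bed position, so
  only the basal lungs are imaged. Whole-lung counts are extrapolated as
  (mean basal-lung concentration) × (3.3 L), and the LSF is that total over
  total lung-plus-liver counts. For uniform lung activity the extrapolation
  is insensitive to the covered fraction; its bias on a non-uniform lung
  equals the deviation of the basal from the whole-lung mean concentration.

# Activity planning

`plan_partition_model()` inverts the dose model in closed form. The
required activity delivers the tumor dose requirement (default 120 Gy); the
tolerance activity of a compartment is the largest activity keeping it at
or below its limit (lung < 20 Gy; in-target normal liver < 70 Gy; when the
in-target volume is small, out-target normal liver < 30 Gy instead). The
recommendation is the minimum of the required activity and the applicable
tolerance activities; a binding tolerance is reported as the limiting
constraint together with the implied reduction fraction, rather than
failing, because treatment proceeds at reduced activity in practice.
The switch to the out-target limit is an explicit flag plus an automatic
volume cutoff (in-target volume below 10% of the total liver volume — the
clinical rule gives no numeric threshold, so the default is configurable
and the choice is recorded in the plan output). Compartments that receive
no activity have unbounded tolerance, returned as `Inf`.

Patients with LSF above 0.2 are excluded (`plan_partition_model()` raises
an error). The alternative **BSA method** prescribes
$A = (\mathrm{BSA} - 0.2) + V_\mathrm{tm}/V_\mathrm{liver}$ GBq with the
DuBois body surface area $0.007184\,W^{0.425}H^{0.725}$; the BSA formula
variant is pinned (the clinical reference cites the method without printing
the formula). `lsf_reduction()` applies the manufacturer's shunt-based
schedule: full activity below LSF 0.10, 20% reduction in [0.10, 0.15), 40%
in [0.15, 0.20), exclusion at 0.20 — the stated rule fixes only the 40%
maximum and the exclusion threshold; the interior band edges follow the
manufacturer convention.

# The synthetic phantom and cohort generator

No imaging data from the underlying cohort are public, so every downstream
stage is exercised on seeded digital phantoms with known ground truth.

**Geometry.** Compartments are ellipsoids on a regular grid (default
96×96×96 at 4 mm isotropic; axes x = left–right, y = anterior–posterior,
z = caudal–cranial). The default anatomy places a 230 mL tumor beside a
408 mL in-target liver, a 500 mL out-target liver above them, and two lung
ellipsoids cranially whose voxelized volume is ≈3.30 L — deliberately equal
to the 3.3 L extrapolation constant, so that perfect-measurement pipelines
are self-consistent. Compartments are pairwise disjoint (checked
voxel-wise); the liver–lung gap is only ≈2 voxels so that realistic
resolution blur spills liver counts into the lung region, as on real MAA
scans. Distances from every compartment to the grid edge exceed 14 mm, so
Gaussian blur at the default widths conserves total counts to well within
0.1%.

**Acquisition model.** `build_phantom()` fills compartments with
modality-specific concentrations and rescales the lung uniformly so the
lung share of total activity equals the true LSF exactly.
`simulate_emission_image()` applies a separable Gaussian point-spread
function (SPECT-like MAA default FWHM 12 mm, PET default 6 mm — written
in-package since no installed R package provides 3-D Gaussian volume
filtering), then Poisson noise at `noise_scale` expected counts per unit
activity (default 500, giving ≈10⁶ counts per scan, a realistic planar/
SPECT count level), then crops axial slices beyond the covered fraction of
the lung extent (PET default 0.4, counted from the caudal end so the liver
and basal lungs are retained). Scanner physics beyond this surrogate —
collimator response, scatter, reconstruction algorithms, attenuation maps —
is out of scope, so tests passing here show correctness of the
*quantification and dosimetry chain*, not robustness to real reconstruction
artifacts.

**Modality discrepancy.** Clinically, MAA overestimates the lung shunt and
the normal-liver dose and underestimates the tumor dose relative to
post-treatment PET. The generator reproduces these directions mechanically
rather than by fiat at the *measurement* stage: each case draws a
microsphere lung shunt (mean 0.018) and adds a nonnegative MAA excess-shunt
component (mean 0.042, so MAA shunts average 0.060), reflecting the smaller,
degradable MAA particles; the MAA tumor-to-normal uptake ratio is the
microsphere ratio times a factor below 1 (mean 0.7). A shared per-case
physiology with a nonnegative excess is used instead of independent draws
because shunting is a property of the patient's vasculature — and
independent draws would produce the observed ordering in only ≈80% of
cases, which is not how consistently the discrepancy is observed. The wider
SPECT blur additionally moves tumor counts into adjacent in-target liver
and liver counts into the lung ROI, reinforcing all three directions.

**Outcomes.** Progression-free survival is exponential with a mean switched
at a true microsphere tumor dose of 200 Gy — 286 days above, 92 days at or
below — and censored at a 400-day follow-up horizon (the simplest model
matching the two reported group means; the reported ranges all fall below
400 days, consistent with that horizon). `make_cohort()` can force an exact
group split (e.g. 14 high / 8 low) by rejection-sampling the injected
activity until the true tumor dose lands on the assigned side of the
threshold; injected activities are otherwise drawn from a truncated normal
(mean 2.3 GBq, SD 1.2, range 0.3–3.9).

All randomness flows from one integer seed: each case's seed is derived
from the base seed and the case counter through an integer mixing step (so
cohorts with nearby base seeds do not share case streams), and acquisition
noise uses fixed offsets of the case seed. Cohorts are therefore pure
functions of $(n, \mathrm{params}, \mathrm{seed})$.

# Statistical stages

Paired Student t tests, Pearson correlation, and the 2×2 chi-squared test
(no continuity correction by default) compare planning-scan and
post-treatment dosimetry; these wrap the standard `stats` routines, and the
test suite checks them against closed-form evaluations computed inline.
Survival uses `survival::survfit`/`survdiff`: the product-limit estimator
with the restricted mean over the observed horizon and its Greenwood-based
standard error (group summaries of the form "286 ± 56 days" are treated as
restricted mean ± SE — the dispersion convention is not stated in the
clinical literature this mirrors, so it is pinned here), the median as the
first time survival reaches 0.5 (`NA` if never), and the 1-df log-rank test
with the hypergeometric variance and simultaneous-risk-set tie handling.
All tests are two-sided at α = 0.05.

A note on power: with exponential PFS means of 286 vs 92 days (hazard ratio
3.1), 22 patients split 14/8 yield about 18 expected events, for which the
two-sided log-rank test has roughly two-thirds power — a single small
cohort can detect the effect, but not reliably across replicates. The power property test therefore uses
66 cases (45/21), where power exceeds 95%.

# Numerical choices and degenerate inputs

* Conservation of apportioned activity is exact algebraically; tests
  enforce $10^{-9}$ relative.
* Tolerance inversions are closed-form; round-trips through the dose
  calculator reproduce the requirement/limits to $10^{-9}$ relative.
* Zero-count liver with LSF < 1, empty VOIs, all-zero planar ROIs, zero
  compartment mass with positive activity, and overlapping ellipsoids all
  raise typed errors rather than returning NaN.
* A dose exactly at the dichotomization threshold is "low" (the high group
  is strictly above).
* The Gaussian kernel is discretized at ±4σ and renormalized, so interior
  sources conserve counts; grid edges are zero-padded.
* Label grids are cached per geometry, since cohort replicates share one
  anatomy.

# Problem sizes

The test suite and the analysis scripts run at desk scale by design: the
default 96³ phantom for quantification and bias checks (≈1 s per simulated
case), a 48³ phantom with the same 384 mm anatomy for pure-bookkeeping
tests, 100 replicates for the bias-direction and survival-power checks,
1000 random measurement sets for conservation/safety properties, and a
22-case imaging cohort in the worked analysis. These sizes are stated here
so results are reproducible as printed; all scale up linearly via the
corresponding arguments.

# Known limitations

* Partition (not voxel-wise) dosimetry: heterogeneous intra-compartment
  dose is invisible by construction; dose-volume histograms are out of
  scope.
* Perfect VOI delineation from the phantom label grid; manual ROI
  variability, segmentation error and SPECT/PET co-registration error are
  not modeled.
* The MAA/microsphere discrepancy model is a stand-in with the right
  directions and magnitudes, not an estimate of particle physics.
* Planar attenuation and scatter are off by default; the conjugate-view
  geometric mean removes depth dependence only for thin sources.
* The PFS model is a two-regime exponential; real progression hazards are
  neither constant nor threshold-switched.
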