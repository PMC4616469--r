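# sirtdose

Partition-model dosimetry and activity planning for selective internal
radiation therapy (SIRT) with Y-90 resin microspheres.

SIRT treats unresectable liver malignancy by injecting Y-90-labelled
microspheres into the hepatic artery. Planning uses a Tc-99m MAA surrogate
scan; post-treatment Y-90 PET/CT shows where the microspheres actually
went. This package implements the full quantitative chain connecting the
two, for medical physicists and imaging researchers who want a tested,
scriptable reference implementation:

* **Four-compartment partition model** — tumor, in-target normal liver,
  out-target normal liver, lungs. Injected activity `A` is apportioned as
  `A0_lung = A·LSF` and `A0_p = (1−LSF)·A·C_pV_p/Σ C_qV_q` over the liver
  partitions, and absorbed dose follows the permanent-implant relation
  `D = 49.67 · A0 / m` (Gy, GBq, kg), with densities 1.0 kg/L (liver,
  tumor) and 0.3 kg/L (lung).
* **Lung shunt fraction** — planar conjugate-view estimate
  `LSF = TC_lung/(TC_lung + TC_liver)` (geometric-mean counts), and the
  volumetric PET estimate with whole-lung counts extrapolated from the
  basal lungs using a 3.3 L lung volume.
* **Activity planning** — closed-form inversion for the tumor dose
  requirement (>120 Gy) under tolerance limits (lung <20 Gy, in-target
  <70 Gy or out-target <30 Gy), LSF-based exclusion (>0.2), the DuBois BSA
  method, and the manufacturer's 20/40% shunt-based reduction schedule.
* **Digital emission phantoms** — seeded ellipsoid phantoms with
  modality-specific uptake, Gaussian resolution blur, Poisson counts and
  partial axial PET coverage, with exact ground truth for every quantity.
* **Cohort statistics** — paired t/Pearson/chi-squared modality comparison,
  200 Gy dose dichotomization, Kaplan–Meier and log-rank PFS analysis.

## Worked example

```r
library(sirtdose)

# planning-scan measurements for one case
m <- partition_measurements(
  tumor      = voi_measurement(500,  total_counts = 800),
  in_target  = voi_measurement(1000, total_counts = 150),
  out_target = voi_measurement(300,  total_counts = 50),
  lsf = 0.05)

dose_report(2, m)           # dosimetry at 2 GBq injected
#>   compartment apportioned_activity_gbq mass_kg    dose_gy
#> 1       tumor                    1.520    0.50 150.996800
#> 2   in_target                    0.285    1.00  14.155950
#> 3  out_target                    0.095    0.30  15.728833
#> 4        lung                    0.100    0.99   5.017172

plan <- plan_partition_model(m)
plan$required_activity      # activity for a 120 Gy tumor dose
#> [1] 1.589438
plan$tolerance_activities   # activities at each tolerance limit
#>      lung in_target out_target
#>  7.972619  9.886918   3.814922
```

Reading the numbers: at 2 GBq, 76% of the non-shunted activity goes to the
tumor (151 Gy), and the lungs receive 5 Gy through the 5% shunt. The plan
recommends 1.59 GBq — the activity that delivers exactly 120 Gy to the
tumor — since every tolerance activity is higher; the lung limit alone
would allow 7.97 GBq.

The end-to-end synthetic study lives in `analysis/` (run in order):

```sh
Rscript analysis/01_simulate_cohort.R   # 22 simulated cases, both modalities
Rscript analysis/02_dosimetry.R         # per-case dose reports, paired table
Rscript analysis/03_plan_activity.R     # PM plans + BSA method
Rscript analysis/04_compare_survival.R  # paired tests, KM + log-rank
```

which prints, among other things (seed 20260):

```
tumor       dose: MAA  179.3 +/-  88.3 Gy | PET  229.4 +/- 110.7 Gy
LSF MAA-PET mean diff 0.049 (p = 3.58e-10)
PFS high group: restricted mean   259 +/-  39 d, median 240 d, n = 13
PFS low  group: restricted mean    51 +/-  14 d, median  30 d, n = 9
Log-rank: chi2 = 14.42, p = 0.000146
```

i.e. the planning scan overestimates the lung shunt and underestimates the
tumor dose relative to post-treatment PET, and patients whose true tumor
dose exceeds 200 Gy progress later. Tables land in `results/`.

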