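# Synthetic cohorts with known ground truth: per-case modality-specific
# phantoms, simulated acquisitions, and dose-dependent progression-free
# survival. All randomness flows from one integer seed via a per-case
# counter (case i uses seed + i).

# inverse-CDF truncated normal; sd = 0 returns the mean (clamped)
.rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

#' Cohort generation parameters
#'
#' Distributions for the per-case draws. Tumor-to-normal uptake ratio (TNR)
#' is drawn for the microsphere distribution; the MAA TNR is the microsphere
#' TNR times a factor below 1, reflecting the poorer tumor selectivity of
#' MAA particles. The microsphere lung shunt is drawn directly and the MAA
#' shunt adds a nonnegative excess component (MAA degradation and smaller
#' particle size shunt more activity to the lungs), so the MAA shunt
#' stochastically dominates the microsphere shunt case by case. Defaults
#' give cohort LSF means near 0.060 (MAA) and 0.018 (microsphere).
#' Progression-free survival is exponential with a mean switched at a true
#' tumor-dose threshold, censored at a follow-up horizon.
#'
#' Each distribution is `c(mean, sd, min, max)`.
#'
#' @param phantom A [phantom_spec()] template (geometry, grid, blur, noise
#'   and PET coverage are taken from it; concentrations and `lsf_true` are
#'   overridden per case).
#' @param tnr_microsphere,tnr_ratio_maa,lsf_microsphere,lsf_maa_excess,injected_gbq
#'   Truncated-normal parameter vectors `c(mean, sd, min, max)`.
#' @param pfs List with `threshold` (Gy, on the true microsphere tumor
#'   dose), `mean_high`, `mean_low` (days), `horizon` (censoring, days).
#' @return Object of class `cohort_params`.
#' @export
cohort_params <- function(phantom = phantom_spec(),
                          tnr_microsphere = c(mean = 5, sd = 1, min = 1.5, max = 12),
                          tnr_ratio_maa = c(mean = 0.7, sd = 0.08, min = 0.4, max = 0.95),
                          lsf_microsphere = c(mean = 0.018, sd = 0.015, min = 0.001, max = 0.19),
                          lsf_maa_excess = c(mean = 0.042, sd = 0.025, min = 0.003, max = 0.12),
                          injected_gbq = c(mean = 2.3, sd = 1.2, min = 0.3, max = 3.9),
                          pfs = list(threshold = 200, mean_high = 286,
                                     mean_low = 92, horizon = 400)) {
  structure(list(phantom = phantom, tnr_microsphere = tnr_microsphere,
                 tnr_ratio_maa = tnr_ratio_maa,
                 lsf_microsphere = lsf_microsphere,
                 lsf_maa_excess = lsf_maa_excess,
                 injected_gbq = injected_gbq, pfs = pfs),
            class = "cohort_params")
}

.draw1 <- function(p) .rtruncnorm(1, p[["mean"]], p[["sd"]], p[["min"]], p[["max"]])

# counter-based per-case seed: mixes the base seed and case index so that
# cohorts with nearby base seeds do not share case streams (stays < 2^31)
.case_seed <- function(seed, i) {
  as.integer(((as.double(seed) %% 65536) * 32749 + i * 2654435761) %% 2147483647)
}

# truth block for given concentrations/lsf on the fixed voxelized geometry;
# `counts` is the per-compartment voxel count vector (names of COMPARTMENTS)
.truth_block <- function(counts, voxel_volume, conc, lsf) {
  act <- vapply(names(COMPARTMENTS), function(nm) {
    if (nm == "lung") return(0)
    conc[[nm]] * voxel_volume * counts[[nm]]
  }, 0)
  liver_total <- sum(act)
  act[["lung"]] <- lsf / (1 - lsf) * liver_total
  vols <- vapply(names(COMPARTMENTS), function(nm)
    voxel_volume * counts[[nm]], 0)
  list(activity = act, volume_ml = vols, lsf = lsf)
}

# perfect-measurement partition_measurements from a truth block
.truth_measurements <- function(tb) {
  partition_measurements(
    tumor = voi_measurement(tb$volume_ml[["tumor"]],
                            total_counts = tb$activity[["tumor"]]),
    in_target = voi_measurement(tb$volume_ml[["in_target"]],
                                total_counts = tb$activity[["in_target"]]),
    out_target = voi_measurement(tb$volume_ml[["out_target"]],
                                 total_counts = tb$activity[["out_target"]]),
    lung_total_counts = tb$activity[["lung"]],
    lsf = tb$lsf)
}

#' Generate one synthetic case
#'
#' Draws the case's uptake parameters, builds the MAA and microsphere truth
#' phantoms on the shared geometry, simulates both acquisitions (SPECT-like
#' blur and full coverage for MAA plus a conjugate planar pair; PET-like
#' blur and partial axial lung coverage for the microsphere scan), and
#' fills the ground-truth block (activities, LSFs, doses at the injected
#' activity) and the PFS record.
#'
#' @param params A [cohort_params()].
#' @param case_seed Integer seed for this case's draws and noise.
#' @param imaging If `FALSE`, skip volume synthesis (truth and PFS only).
#' @param group Optional forced dose group (`"high"` or `"low"`): injected
#'   activity is redrawn until the true tumor dose falls on that side of
#'   the PFS dose threshold.
#' @return Object of class `synthetic_case`: list with `truth` (per-modality
#'   truth blocks, injected activity, true dose reports, dose group),
#'   `pfs` (time, uncensored time, event, group) and, when `imaging`,
#'   `maa_volume`, `pet_volume`, `planar_pair`.
#' @export
make_case <- function(params, case_seed, imaging = TRUE, group = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(as.integer(case_seed))
  spec0 <- params$phantom
  counts <- .label_counts(spec0)
  vv <- prod(spec0$voxel_size) / 1000

  tnr_ms <- .draw1(params$tnr_microsphere)
  tnr_maa <- tnr_ms * .draw1(params$tnr_ratio_maa)
  lsf_ms <- .draw1(params$lsf_microsphere)
  lsf_maa <- min(lsf_ms + .draw1(params$lsf_maa_excess), 0.199)
  conc <- list(
    maa = c(tumor = tnr_maa, in_target = 1, out_target = 1, lung = 0),
    microsphere = c(tumor = tnr_ms, in_target = 1, out_target = 1, lung = 0))

  tb_ms <- .truth_block(counts, vv, conc$microsphere, lsf_ms)
  tb_maa <- .truth_block(counts, vv, conc$maa, lsf_maa)
  m_ms <- .truth_measurements(tb_ms)

  thr <- params$pfs$threshold
  injected <- .draw1(params$injected_gbq)
  dose_ms <- function(a) .report_dose(dose_report(a, m_ms), "tumor")
  if (!is.null(group)) {
    group <- match.arg(group, c("high", "low"))
    for (tries in seq_len(10000)) {
      d <- dose_ms(injected)
      if ((group == "high") == (d > thr)) break
      injected <- .draw1(params$injected_gbq)
      if (tries == 10000)
        stop("could not draw an injected activity matching the forced dose group",
             call. = FALSE)
    }
  }
  true_dose_ms <- dose_report(injected, m_ms)
  true_dose_maa <- dose_report(injected, .truth_measurements(tb_maa))
  tumor_dose <- .report_dose(true_dose_ms, "tumor")
  grp <- if (tumor_dose > thr) "high" else "low"

  mean_pfs <- if (grp == "high") params$pfs$mean_high else params$pfs$mean_low
  t_raw <- rexp(1, 1 / mean_pfs)
  pfs <- list(time = min(t_raw, params$pfs$horizon),
              time_uncensored = t_raw,
              event = as.integer(t_raw <= params$pfs$horizon),
              group = grp)

  out <- list(truth = list(microsphere = tb_ms, maa = tb_maa,
                           injected_gbq = injected,
                           dose_microsphere = true_dose_ms,
                           dose_maa = true_dose_maa,
                           tumor_dose_gy = tumor_dose,
                           group = grp,
                           tnr = c(maa = tnr_maa, microsphere = tnr_ms)),
              pfs = pfs)
  if (imaging) {
    spec <- spec0
    spec$activity_concentration <- conc
    spec$lsf_true <- c(maa = lsf_maa, microsphere = lsf_ms)
    maa_truth <- build_phantom(spec, "maa")
    ms_truth <- build_phantom(spec, "microsphere")
    out$maa_volume <- simulate_emission_image(
      maa_truth, spec$psf_fwhm[["maa"]], spec$noise_scale,
      coverage = 1, seed = case_seed + 10000L)
    out$planar_pair <- project_planar(out$maa_volume, attenuation_mu = 0)
    out$pet_volume <- simulate_emission_image(
      ms_truth, spec$psf_fwhm[["microsphere"]], spec$noise_scale,
      coverage = spec$pet_axial_coverage, seed = case_seed + 20000L)
  }
  class(out) <- "synthetic_case"
  out
}

#' Quantify a synthetic case with the measurement pipeline
#'
#' Runs the study's measurement procedure on one simulated case: liver
#' partition VOIs on each modality's volume; the MAA lung shunt fraction
#' from the conjugate planar pair (lung vs liver ROIs projected from the
#' label grid); the microsphere-PET lung counts extrapolated from the
#' basal-lung mean concentration and converted to an LSF against the liver
#' partitions.
#'
#' @param case A [make_case()] result with imaging.
#' @param lung_volume_ml Whole-lung volume for the PET extrapolation (mL).
#' @return List with `maa` and `pet` [partition_measurements()].
#' @export
measure_case <- function(case, lung_volume_ml = DEFAULT_LUNG_VOLUME_ML) {
  stopifnot(inherits(case, "synthetic_case"), !is.null(case$maa_volume))
  liver_tags <- c("tumor", "in_target", "out_target")
  vois_maa <- lapply(liver_tags, function(l) measure_voi(case$maa_volume, l))
  lung_roi <- planar_roi(case$planar_pair, case$maa_volume$labels, "lung")
  liver_roi <- planar_roi(case$planar_pair, case$maa_volume$labels, liver_tags)
  lsf_maa <- lung_shunt_fraction(lung_roi, liver_roi)
  maa <- partition_measurements(vois_maa[[1]], vois_maa[[2]], vois_maa[[3]],
                                lung_total_counts = conjugate_counts(lung_roi),
                                lsf = lsf_maa)
  vois_pet <- lapply(liver_tags, function(l) measure_voi(case$pet_volume, l))
  basal <- measure_voi(case$pet_volume, "lung")  # covered basal lungs only
  lung_total <- extrapolate_lung_counts(basal$mean_concentration,
                                        lung_volume_ml)
  lsf_pet <- lsf_from_pet(lung_total, vois_pet)
  pet <- partition_measurements(vois_pet[[1]], vois_pet[[2]], vois_pet[[3]],
                                lung_total_counts = lung_total, lsf = lsf_pet)
  list(maa = maa, pet = pet)
}

#' Generate a synthetic cohort
#'
#' `n` cases via [make_case()], each from a per-case seed derived
#' deterministically from the base seed and the case counter.
#' Returns tidy per-case tables; full case objects (with volumes) are kept
#' only when `keep_cases = TRUE`, since imaging volumes are large.
#'
#' @param n Number of cases (>= 1).
#' @param params A [cohort_params()].
#' @param seed Integer base seed.
#' @param imaging Simulate volumes and measure them (slower).
#' @param group_sizes Optional named vector `c(high = , low = )` forcing the
#'   dose-group split; must sum to `n`.
#' @param keep_cases Keep the raw case objects.
#' @return List with `truth` (per-case true activities, LSFs, doses,
#'   injected activity, group), `survival` (case, time_days,
#'   time_uncensored, event, group) and, when `imaging`, `measurements`
#'   (case x modality x compartment measured table plus measured LSFs).
#' @export
make_cohort <- function(n, params = cohort_params(), seed = 1L,
                        imaging = FALSE, group_sizes = NULL,
                        keep_cases = FALSE) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  n <- as.integer(n)
  groups <- if (is.null(group_sizes)) rep(list(NULL), n)
            else {
              stopifnot(sum(group_sizes) == n,
                        all(c("high", "low") %in% names(group_sizes)))
              as.list(rep(c("high", "low"), group_sizes[c("high", "low")]))
            }
  truth <- vector("list", n); surv <- vector("list", n)
  meas <- vector("list", n); cases <- if (keep_cases) vector("list", n)
  for (i in seq_len(n)) {
    cs <- make_case(params, case_seed = .case_seed(seed, i),
                    imaging = imaging, group = groups[[i]])
    tb <- cs$truth
    truth[[i]] <- data.frame(
      case = i,
      injected_gbq = tb$injected_gbq,
      lsf_true_maa = tb$maa$lsf, lsf_true_microsphere = tb$microsphere$lsf,
      tnr_maa = tb$tnr[["maa"]], tnr_microsphere = tb$tnr[["microsphere"]],
      tumor_dose_gy = tb$tumor_dose_gy, group = tb$group)
    surv[[i]] <- data.frame(case = i, time_days = cs$pfs$time,
                            time_uncensored = cs$pfs$time_uncensored,
                            event = cs$pfs$event, group = cs$pfs$group)
    if (imaging) {
      mm <- measure_case(cs)
      row <- function(modality, m) data.frame(
        case = i, modality = modality,
        compartment = c("tumor", "in_target", "out_target"),
        volume_ml = vapply(c("tumor", "in_target", "out_target"),
                           function(k) m[[k]]$volume_ml, 0),
        total_counts = vapply(c("tumor", "in_target", "out_target"),
                              function(k) m[[k]]$total_counts, 0),
        lung_total_counts = m$lung_total_counts, lsf = m$lsf,
        injected_gbq = tb$injected_gbq, row.names = NULL)
      meas[[i]] <- rbind(row("maa", mm$maa), row("microsphere", mm$pet))
    }
    if (keep_cases) cases[[i]] <- cs
  }
  out <- list(truth = do.call(rbind, truth), survival = do.call(rbind, surv))
  if (imaging) out$measurements <- do.call(rbind, meas)
  if (keep_cases) out$cases <- cases
  out
}
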