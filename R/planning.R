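# Activity planning: invert the partition model for the tumor dose
# requirement and the organ tolerance limits, plus the BSA method with
# lung-shunt-based reduction.

#' Planning constraints
#'
#' The dose requirement and tolerance limits used for partition-model
#' activity planning: tumor dose requirement > 120 Gy, lung limit < 20 Gy,
#' in-target normal liver limit < 70 Gy; when the in-target normal liver is
#' considerably small, the out-target normal liver limit < 30 Gy is used
#' instead. Patients with a lung shunt fraction above 0.2 are excluded from
#' treatment.
#'
#' @param tumor_dose_requirement Gy, tumor dose the plan must deliver.
#' @param lung_limit,in_target_limit,out_target_limit Tolerance limits (Gy).
#' @param lsf_exclusion LSF above which the patient is excluded.
#' @param use_out_target_limit If `TRUE`, the out-target limit replaces the
#'   in-target limit regardless of in-target volume.
#' @param small_in_target_fraction When the in-target volume is below this
#'   fraction of the total liver volume, the out-target limit is used
#'   automatically.
#' @return Object of class `planning_constraints`.
#' @export
planning_constraints <- function(tumor_dose_requirement = 120,
                                 lung_limit = 20,
                                 in_target_limit = 70,
                                 out_target_limit = 30,
                                 lsf_exclusion = 0.2,
                                 use_out_target_limit = FALSE,
                                 small_in_target_fraction = 0.1) {
  for (nm in c("tumor_dose_requirement", "lung_limit", "in_target_limit",
               "out_target_limit"))
    .assert_scalar(get(nm), nm, lo = 1e-12)
  .assert_scalar(lsf_exclusion, "lsf_exclusion", lo = 1e-12, hi = 1)
  structure(list(tumor_dose_requirement = tumor_dose_requirement,
                 lung_limit = lung_limit,
                 in_target_limit = in_target_limit,
                 out_target_limit = out_target_limit,
                 lsf_exclusion = lsf_exclusion,
                 use_out_target_limit = isTRUE(use_out_target_limit),
                 small_in_target_fraction = small_in_target_fraction),
            class = "planning_constraints")
}

# activity fraction reaching `compartment` for measurements m
.activity_fraction <- function(m, compartment) {
  if (compartment == "lung") return(m$lsf)
  counts <- c(tumor = m$tumor$total_counts,
              in_target = m$in_target$total_counts,
              out_target = m$out_target$total_counts)
  (1 - m$lsf) * counts[[compartment]] / sum(counts)
}

#' Activity required for a target tumor dose
#'
#' Closed-form inversion of the dose model: the unique injected activity `A`
#' with tumor dose equal to `target_dose`,
#' `A = target_dose * mass_tm / (k * f_tm)` where `f_tm` is the tumor
#' activity fraction `(1 - lsf) * C_tm V_tm / sum(C V)`.
#'
#' @param m A [partition_measurements()].
#' @param target_dose Gy.
#' @param dose_constant Gy·kg/GBq.
#' @return Required activity (GBq).
#' @export
activity_for_tumor_dose <- function(m, target_dose,
                                    dose_constant = Y90_DOSE_CONSTANT) {
  stopifnot(inherits(m, "partition_measurements"))
  .assert_scalar(target_dose, "target_dose")
  f <- .activity_fraction(m, "tumor")
  if (f <= 0) stop("cannot plan: tumor activity fraction is zero", call. = FALSE)
  mass <- compartment_mass(m$tumor$volume_ml, "tumor")
  target_dose * mass / (dose_constant * f)
}

#' Tolerance activity of a compartment
#'
#' The largest injected activity keeping the compartment's absorbed dose at
#' or below its tolerance limit; `Inf` when no activity reaches the
#' compartment (its dose is zero at any activity).
#'
#' @param m A [partition_measurements()].
#' @param compartment `"lung"`, `"in_target"` or `"out_target"` (tumor has a
#'   requirement, not a tolerance).
#' @param limit Tolerance limit (Gy).
#' @param lung_volume_ml Whole-lung volume (mL) for the lung mass.
#' @param dose_constant Gy·kg/GBq.
#' @return Activity (GBq), possibly `Inf`.
#' @export
tolerance_activity <- function(m, compartment, limit,
                               lung_volume_ml = DEFAULT_LUNG_VOLUME_ML,
                               dose_constant = Y90_DOSE_CONSTANT) {
  stopifnot(inherits(m, "partition_measurements"))
  compartment <- match.arg(compartment, c("lung", "in_target", "out_target"))
  .assert_scalar(limit, "limit")
  f <- .activity_fraction(m, compartment)
  if (f <= 0) return(Inf)
  vol <- if (compartment == "lung") lung_volume_ml
         else m[[compartment]]$volume_ml
  mass <- compartment_mass(vol, compartment)
  limit * mass / (dose_constant * f)
}

#' Partition-model activity plan
#'
#' Computes the activity required for the tumor dose requirement and the
#' tolerance activities of the lungs and the applicable normal-liver
#' partition, then recommends the minimum. Applicable liver limit: in-target
#' normal liver, unless its volume is small relative to the total liver
#' (below `small_in_target_fraction`) or `use_out_target_limit` is set, in
#' which case the out-target limit applies. When a tolerance caps the plan,
#' the recommended activity is the cap and `reduction_fraction` records the
#' relative reduction versus the required activity.
#'
#' @param m A [partition_measurements()]; its `lsf` must not exceed
#'   `constraints$lsf_exclusion` (the patient would be excluded from SIRT).
#' @param constraints A [planning_constraints()].
#' @param lung_volume_ml,dose_constant Passed to the dose model.
#' @return Object of class `activity_plan`: list with `required_activity`,
#'   `tolerance_activities` (named, all three), `applicable` (names of the
#'   tolerances enforced), `recommended_activity`, `limiting_constraint`
#'   (`NA` when unconstrained), `feasible`, `reduction_fraction`,
#'   `liver_limit_used`.
#' @export
plan_partition_model <- function(m, constraints = planning_constraints(),
                                 lung_volume_ml = DEFAULT_LUNG_VOLUME_ML,
                                 dose_constant = Y90_DOSE_CONSTANT) {
  stopifnot(inherits(m, "partition_measurements"),
            inherits(constraints, "planning_constraints"))
  if (m$lsf > constraints$lsf_exclusion)
    stop(sprintf("patient excluded: LSF %.3f exceeds exclusion threshold %.2f",
                 m$lsf, constraints$lsf_exclusion), call. = FALSE)
  required <- activity_for_tumor_dose(m, constraints$tumor_dose_requirement,
                                      dose_constant)
  tol <- c(lung = tolerance_activity(m, "lung", constraints$lung_limit,
                                     lung_volume_ml, dose_constant),
           in_target = tolerance_activity(m, "in_target",
                                          constraints$in_target_limit,
                                          lung_volume_ml, dose_constant),
           out_target = tolerance_activity(m, "out_target",
                                           constraints$out_target_limit,
                                           lung_volume_ml, dose_constant))
  total_liver <- m$tumor$volume_ml + m$in_target$volume_ml +
    m$out_target$volume_ml
  small_in <- m$in_target$volume_ml <
    constraints$small_in_target_fraction * total_liver
  liver_limit <- if (constraints$use_out_target_limit || small_in)
    "out_target" else "in_target"
  applicable <- c("lung", liver_limit)
  cap <- min(tol[applicable])
  recommended <- min(required, cap)
  feasible <- required <= cap
  limiting <- if (feasible) NA_character_ else applicable[which.min(tol[applicable])]
  structure(list(required_activity = required,
                 tolerance_activities = tol,
                 applicable = applicable,
                 recommended_activity = recommended,
                 limiting_constraint = limiting,
                 feasible = feasible,
                 reduction_fraction = if (feasible) 0 else 1 - recommended / required,
                 liver_limit_used = liver_limit),
            class = "activity_plan")
}

#' Body-surface-area method activity
#'
#' The conventional resin-microsphere prescription: with the DuBois body
#' surface area `BSA = 0.007184 * W^0.425 * H^0.725` (m^2, W in kg, H in
#' cm), the recommended activity is
#' `A = (BSA - 0.2) + V_tumor / V_liver` GBq, where the last term is the
#' fractional tumor involvement of the liver.
#'
#' @param height_cm,weight_kg Patient height and weight, positive.
#' @param tumor_volume_ml,total_liver_volume_ml Tumor and whole-liver
#'   volumes; tumor must not exceed liver.
#' @return Activity in GBq.
#' @export
bsa_activity <- function(height_cm, weight_kg, tumor_volume_ml,
                         total_liver_volume_ml) {
  .assert_scalar(height_cm, "height_cm", lo = 1e-9)
  .assert_scalar(weight_kg, "weight_kg", lo = 1e-9)
  .assert_scalar(tumor_volume_ml, "tumor_volume_ml", lo = 0)
  .assert_scalar(total_liver_volume_ml, "total_liver_volume_ml", lo = 1e-9)
  if (tumor_volume_ml > total_liver_volume_ml)
    stop("tumor volume exceeds total liver volume", call. = FALSE)
  bsa <- 0.007184 * weight_kg^0.425 * height_cm^0.725
  (bsa - 0.2) + tumor_volume_ml / total_liver_volume_ml
}

#' Lung-shunt-based activity reduction
#'
#' Manufacturer's reduction schedule for resin microspheres: full activity
#' for LSF below 0.10, 20% reduction for LSF in [0.10, 0.15), 40% reduction
#' for LSF in [0.15, 0.20); LSF of 0.20 or more excludes the patient from
#' SIRT. The maximum applied reduction is therefore 40%.
#'
#' @param activity Planned activity (GBq).
#' @param lsf Lung shunt fraction in `[0, 1]`.
#' @return Reduced activity (GBq).
#' @export
lsf_reduction <- function(activity, lsf) {
  .assert_scalar(activity, "activity")
  .assert_scalar(lsf, "lsf", 0, 1)
  if (lsf >= 0.20)
    stop(sprintf("patient excluded: LSF %.3f is 0.20 or above", lsf),
         call. = FALSE)
  factor <- if (lsf < 0.10) 1.0 else if (lsf < 0.15) 0.80 else 0.60
  activity * factor
}
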