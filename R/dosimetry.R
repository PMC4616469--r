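# Four-compartment partition-model dosimetry for Y-90 microsphere SIRT.
#
# The model divides the perfused anatomy into tumor, in-target normal liver
# (non-tumorous liver fed by the treated artery), out-target normal liver
# (fed by other arteries) and lungs. Injected activity is apportioned among
# the compartments by relative imaging counts; since neither Tc-99m MAA nor
# Y-90 resin microspheres redistribute after implantation, the absorbed dose
# of a compartment is proportional to its initial activity divided by its
# mass.

#' Compartment tags used throughout the package
#'
#' Integer label codes for the four partition-model compartments as stored
#' in phantom label grids: tumor = 1, in-target normal liver = 2, out-target
#' normal liver = 3, lung = 4 (0 is background).
#'
#' @format Named integer vector of length 4.
#' @export
COMPARTMENTS <- c(tumor = 1L, in_target = 2L, out_target = 3L, lung = 4L)

#' Physical dose constant for Y-90 permanent implants
#'
#' Absorbed dose per unit initial activity per unit mass,
#' in Gy·kg/GBq, for complete decay of Y-90 in situ
#' (half-life 2.67 days, mean beta energy 0.927 MeV, all energy absorbed
#' locally). `D = Y90_DOSE_CONSTANT * A0 / mass`.
#'
#' @export
Y90_DOSE_CONSTANT <- 49.67

# kg per litre, by compartment
.TISSUE_DENSITY <- c(tumor = 1.0, in_target = 1.0, out_target = 1.0, lung = 0.3)

#' Default whole-lung volume (mL)
#'
#' CT-based population average lung volume used to convert lung counts to a
#' lung mass and to extrapolate whole-lung counts from partial axial
#' coverage: 3.3 L.
#'
#' @export
DEFAULT_LUNG_VOLUME_ML <- 3300

.assert_scalar <- function(x, name, lo = 0, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

#' Construct a VOI measurement
#'
#' A volume-of-interest measurement as read off an emission volume: the VOI
#' volume (mL), its mean count concentration (counts/mL) and total counts.
#' Supply `total_counts` or `mean_concentration`; the other is derived.
#'
#' @param volume_ml VOI volume in mL (non-negative).
#' @param total_counts Total counts in the VOI.
#' @param mean_concentration Mean counts per mL.
#' @return An object of class `voi_measurement` with fields `volume_ml`,
#'   `mean_concentration`, `total_counts`.
#' @export
voi_measurement <- function(volume_ml, total_counts = NULL,
                            mean_concentration = NULL) {
  .assert_scalar(volume_ml, "volume_ml")
  if (is.null(total_counts) && is.null(mean_concentration))
    stop("supply `total_counts` or `mean_concentration`", call. = FALSE)
  if (is.null(total_counts)) {
    .assert_scalar(mean_concentration, "mean_concentration")
    total_counts <- mean_concentration * volume_ml
  } else {
    .assert_scalar(total_counts, "total_counts")
    if (is.null(mean_concentration))
      mean_concentration <- if (volume_ml > 0) total_counts / volume_ml else 0
  }
  structure(list(volume_ml = volume_ml,
                 mean_concentration = mean_concentration,
                 total_counts = total_counts),
            class = "voi_measurement")
}

#' Bundle the per-case partition measurements
#'
#' The inputs of the partition model for one case and one modality: VOI
#' measurements of the three liver partitions, total lung counts, and the
#' lung shunt fraction.
#'
#' @param tumor,in_target,out_target [voi_measurement()] objects.
#' @param lung_total_counts Whole-lung counts (planar conjugate counts for
#'   MAA, extrapolated PET counts post-treatment). Only used for record
#'   keeping and PET-side LSF computation; apportionment uses `lsf`.
#' @param lsf Lung shunt fraction in `[0, 1]`.
#' @return Object of class `partition_measurements`.
#' @export
partition_measurements <- function(tumor, in_target, out_target,
                                   lung_total_counts = 0, lsf = 0) {
  for (v in list(tumor, in_target, out_target))
    if (!inherits(v, "voi_measurement"))
      stop("liver partitions must be `voi_measurement` objects", call. = FALSE)
  .assert_scalar(lung_total_counts, "lung_total_counts")
  .assert_scalar(lsf, "lsf", 0, 1)
  liver_counts <- tumor$total_counts + in_target$total_counts +
    out_target$total_counts
  if (lsf < 1 && liver_counts <= 0)
    stop("at least one liver partition must have positive counts when lsf < 1",
         call. = FALSE)
  structure(list(tumor = tumor, in_target = in_target,
                 out_target = out_target,
                 lung_total_counts = lung_total_counts, lsf = lsf),
            class = "partition_measurements")
}

#' Compartment mass from volume
#'
#' Converts a compartment volume to mass using the partition-model tissue
#' densities: 1.0 kg/L for tumor and liver partitions, 0.3 kg/L for lung.
#'
#' @param volume_ml Volume in mL.
#' @param compartment One of `"tumor"`, `"in_target"`, `"out_target"`,
#'   `"lung"`.
#' @return Mass in kg.
#' @export
compartment_mass <- function(volume_ml, compartment) {
  .assert_scalar(volume_ml, "volume_ml")
  compartment <- match.arg(compartment, names(.TISSUE_DENSITY))
  volume_ml / 1000 * .TISSUE_DENSITY[[compartment]]
}

#' Apportion injected activity among the four compartments
#'
#' The lungs receive `injected * lsf` (the shunted fraction, by definition
#' of the lung shunt fraction); the remainder is split among tumor,
#' in-target and out-target normal liver proportionally to their total VOI
#' counts (C·V). Conservation is exact.
#'
#' @param injected Injected activity (GBq).
#' @param m A [partition_measurements()] object.
#' @return Named numeric vector of initial activities (GBq) for
#'   `tumor`, `in_target`, `out_target`, `lung`.
#' @export
apportion_activity <- function(injected, m) {
  .assert_scalar(injected, "injected")
  stopifnot(inherits(m, "partition_measurements"))
  counts <- c(tumor = m$tumor$total_counts,
              in_target = m$in_target$total_counts,
              out_target = m$out_target$total_counts)
  liver_total <- sum(counts)
  a_lung <- injected * m$lsf
  if (liver_total > 0) {
    a_liver <- (injected - a_lung) * counts / liver_total
  } else {
    if (m$lsf < 1 && injected > 0)
      stop("cannot apportion: zero liver counts with lsf < 1", call. = FALSE)
    a_liver <- counts * 0
  }
  c(a_liver, lung = a_lung)
}

#' Absorbed dose of one compartment
#'
#' For a permanent Y-90 implant the absorbed dose is
#' `D = k * A0 / mass` with `k` the dose constant (Gy·kg/GBq), `A0` the
#' initial compartment activity (GBq) and `mass` the compartment mass (kg).
#'
#' @param a0 Initial activity in the compartment (GBq).
#' @param mass Compartment mass (kg), positive.
#' @param dose_constant Gy·kg/GBq; defaults to [Y90_DOSE_CONSTANT].
#' @return Absorbed dose in Gy.
#' @export
absorbed_dose <- function(a0, mass, dose_constant = Y90_DOSE_CONSTANT) {
  .assert_scalar(a0, "a0")
  if (!is.numeric(mass) || length(mass) != 1L || is.na(mass) || mass <= 0)
    stop("`mass` must be a single positive number", call. = FALSE)
  dose_constant * a0 / mass
}

#' Full per-compartment dose report
#'
#' Composes [apportion_activity()], [compartment_mass()] and
#' [absorbed_dose()] for all four compartments. The lung mass is taken from
#' a whole-lung volume (default 3.3 L) at 0.3 kg/L, since lung volume is
#' not measured on the emission scan itself.
#'
#' @param injected Injected activity (GBq).
#' @param m A [partition_measurements()] object.
#' @param lung_volume_ml Whole-lung volume in mL used for the lung mass.
#' @param dose_constant Gy·kg/GBq.
#' @return A `data.frame` with one row per compartment and columns
#'   `compartment`, `apportioned_activity_gbq`, `mass_kg`, `dose_gy`;
#'   attributes `injected_gbq` and `lsf` record the inputs.
#' @export
dose_report <- function(injected, m, lung_volume_ml = DEFAULT_LUNG_VOLUME_ML,
                        dose_constant = Y90_DOSE_CONSTANT) {
  a0 <- apportion_activity(injected, m)
  vols <- c(tumor = m$tumor$volume_ml, in_target = m$in_target$volume_ml,
            out_target = m$out_target$volume_ml, lung = lung_volume_ml)
  comps <- names(COMPARTMENTS)
  mass <- vapply(comps, function(k) compartment_mass(vols[[k]], k), 0)
  dose <- vapply(comps, function(k) {
    if (mass[[k]] > 0) absorbed_dose(a0[[k]], mass[[k]], dose_constant)
    else if (a0[[k]] == 0) 0
    else stop(sprintf("undefined dose: compartment `%s` has zero mass but positive activity", k),
              call. = FALSE)
  }, 0)
  out <- data.frame(compartment = comps,
                    apportioned_activity_gbq = unname(a0[comps]),
                    mass_kg = unname(mass),
                    dose_gy = unname(dose),
                    row.names = NULL)
  attr(out, "injected_gbq") <- injected
  attr(out, "lsf") <- m$lsf
  out
}

# convenience accessor used by planning and tests
.report_dose <- function(report, compartment) {
  report$dose_gy[match(compartment, report$compartment)]
}
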