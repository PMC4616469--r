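# VOI / ROI quantification: count measurements on emission volumes,
# conjugate-view planar counts, lung shunt fraction, and extrapolation of
# whole-lung counts from partial axial PET coverage.

#' Measure a volume of interest on an emission volume
#'
#' Takes the VOI from the label grid (perfect delineation): volume is the
#' labeled voxel count times the voxel volume, total counts the voxel-value
#' sum, mean concentration their ratio.
#'
#' @param image An [activity_volume()].
#' @param label Compartment tag (name in [COMPARTMENTS]) or integer code.
#' @return A [voi_measurement()].
#' @export
measure_voi <- function(image, label) {
  stopifnot(inherits(image, "activity_volume"))
  code <- if (is.character(label)) COMPARTMENTS[[match.arg(label, names(COMPARTMENTS))]]
          else as.integer(label)
  sel <- image$labels == code
  n <- sum(sel)
  if (n == 0L) stop(sprintf("empty VOI: label %s absent from label grid", label),
                    call. = FALSE)
  total <- sum(image$values[sel])
  voi_measurement(volume_ml = n * image$voxel_volume, total_counts = total)
}

#' Anterior/posterior ROI counts
#'
#' Container for the counts of one region of interest on a conjugate planar
#' pair.
#'
#' @param anterior_counts,posterior_counts Non-negative ROI count sums.
#' @return Object of class `planar_roi_counts`.
#' @export
planar_roi_counts <- function(anterior_counts, posterior_counts) {
  .assert_scalar(anterior_counts, "anterior_counts")
  .assert_scalar(posterior_counts, "posterior_counts")
  structure(list(anterior_counts = anterior_counts,
                 posterior_counts = posterior_counts),
            class = "planar_roi_counts")
}

#' Conjugate-view counts (geometric mean)
#'
#' Combines anterior and posterior planar counts of one ROI by the geometric
#' mean, the standard conjugate-view estimator that cancels first-order
#' depth dependence of attenuation.
#'
#' @param roi A [planar_roi_counts()].
#' @return Combined counts, `sqrt(anterior * posterior)`.
#' @export
conjugate_counts <- function(roi) {
  stopifnot(inherits(roi, "planar_roi_counts"))
  sqrt(roi$anterior_counts * roi$posterior_counts)
}

#' Lung shunt fraction from planar lung and liver ROIs
#'
#' `LSF = TC_lung / (TC_lung + TC_liver)` where `TC` are conjugate-view
#' total counts of the lung and liver ROIs on the planar whole-body scan.
#'
#' @param lung,liver [planar_roi_counts()] for the two ROIs.
#' @return The lung shunt fraction in `[0, 1]`.
#' @export
lung_shunt_fraction <- function(lung, liver) {
  tc_lung <- conjugate_counts(lung)
  tc_liver <- conjugate_counts(liver)
  if (tc_lung + tc_liver <= 0)
    stop("undefined LSF: lung and liver conjugate counts are both zero",
         call. = FALSE)
  tc_lung / (tc_lung + tc_liver)
}

#' Extrapolate whole-lung counts from basal-lung coverage
#'
#' Post-treatment PET covers only the basal lungs; whole-lung counts are
#' presumed by multiplying the mean basal-lung count concentration by a
#' population lung volume (default 3.3 L).
#'
#' @param basal_mean_concentration Mean counts per mL in the scan-covered
#'   basal lungs.
#' @param lung_volume_ml Whole-lung volume in mL.
#' @return Extrapolated total lung counts.
#' @export
extrapolate_lung_counts <- function(basal_mean_concentration,
                                    lung_volume_ml = DEFAULT_LUNG_VOLUME_ML) {
  .assert_scalar(basal_mean_concentration, "basal_mean_concentration")
  .assert_scalar(lung_volume_ml, "lung_volume_ml")
  basal_mean_concentration * lung_volume_ml
}

#' Lung shunt fraction from volumetric measurements
#'
#' Post-treatment analogue of the planar LSF: the extrapolated whole-lung
#' counts divided by the total of lung plus liver-partition counts.
#'
#' @param lung_total Whole-lung counts (e.g. from
#'   [extrapolate_lung_counts()]).
#' @param partitions List of three [voi_measurement()]s (tumor, in-target,
#'   out-target).
#' @return Fraction in `[0, 1]`.
#' @export
lsf_from_pet <- function(lung_total, partitions) {
  .assert_scalar(lung_total, "lung_total")
  liver <- sum(vapply(partitions, function(v) v$total_counts, 0))
  if (lung_total + liver <= 0)
    stop("undefined LSF: all counts zero", call. = FALSE)
  lung_total / (lung_total + liver)
}
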