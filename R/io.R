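# On-disk interchange: activity volumes as NIfTI pairs (values + labels),
# planar pairs and tabular outputs as CSV.

#' Write an activity volume as a NIfTI pair
#'
#' Writes `<prefix>_activity.nii.gz` (float values) and
#' `<prefix>_labels.nii.gz` (integer compartment codes) with the voxel
#' spacing recorded in the header.
#'
#' @param vol An [activity_volume()].
#' @param prefix Path prefix (directory must exist).
#' @return Invisibly, the two file paths.
#' @export
write_volume <- function(vol, prefix) {
  stopifnot(inherits(vol, "activity_volume"))
  fa <- paste0(prefix, "_activity.nii.gz")
  fl <- paste0(prefix, "_labels.nii.gz")
  img <- RNifti::asNifti(structure(vol$values, pixdim = vol$voxel_size))
  lab <- RNifti::asNifti(structure(vol$labels, pixdim = vol$voxel_size),
                         datatype = "int16")
  RNifti::writeNifti(img, fa)
  RNifti::writeNifti(lab, fl)
  invisible(c(activity = fa, labels = fl))
}

#' Read an activity volume from a NIfTI pair
#'
#' @param prefix Path prefix used by [write_volume()].
#' @return An [activity_volume()].
#' @export
read_volume <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, "_activity.nii.gz"))
  lab <- RNifti::readNifti(paste0(prefix, "_labels.nii.gz"))
  voxel_size <- RNifti::pixdim(img)[1:3]
  activity_volume(array(as.numeric(img), dim = dim(img)),
                  array(as.integer(lab), dim = dim(lab)),
                  voxel_size)
}

#' Read a partition-measurements table
#'
#' Reads a CSV with one row per case, modality and liver compartment
#' (columns `case`, `modality`, `compartment`, `volume_ml`, `total_counts`,
#' `lung_total_counts`, `lsf`, `injected_gbq`) and returns one
#' [partition_measurements()] per case and modality.
#'
#' @param path CSV path.
#' @return Nested list `result[[case]][[modality]]`, each element a list
#'   with `measurements` and `injected_gbq`.
#' @export
read_measurements_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case", "modality", "compartment", "volume_ml", "total_counts",
            "lung_total_counts", "lsf", "injected_gbq")
  if (!all(need %in% names(df)))
    stop("measurements CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (cs in unique(df$case)) {
    out[[as.character(cs)]] <- list()
    for (md in unique(df$modality[df$case == cs])) {
      sub <- df[df$case == cs & df$modality == md, ]
      voi <- function(k) {
        r <- sub[sub$compartment == k, ]
        if (nrow(r) != 1) stop(sprintf("case %s/%s: need one `%s` row", cs, md, k),
                               call. = FALSE)
        voi_measurement(r$volume_ml, total_counts = r$total_counts)
      }
      out[[as.character(cs)]][[md]] <- list(
        measurements = partition_measurements(
          voi("tumor"), voi("in_target"), voi("out_target"),
          lung_total_counts = sub$lung_total_counts[1], lsf = sub$lsf[1]),
        injected_gbq = sub$injected_gbq[1])
    }
  }
  out
}

#' Flatten a dose report to a one-row-per-compartment data frame
#'
#' @param report A [dose_report()] result.
#' @param case,modality Identifiers added as columns.
#' @return `data.frame` suitable for `rbind`-ing across cases.
#' @export
dose_report_row <- function(report, case = NA, modality = NA) {
  cbind(data.frame(case = case, modality = modality), report,
        injected_gbq = attr(report, "injected_gbq"),
        lsf = attr(report, "lsf"))
}
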