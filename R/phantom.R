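# Digital emission phantoms: ellipsoidal compartments on a regular grid,
# with modality-specific activity concentrations, Gaussian resolution blur,
# Poisson count noise, partial axial PET coverage, and conjugate planar
# projection. Axis convention: x = left->right, y = anterior->posterior,
# z = caudal->cranial; planar projection is along y.

#' Construct an activity volume
#'
#' A 3-D grid of per-voxel activity (or counts) plus a parallel integer
#' label grid identifying the compartments (codes in [COMPARTMENTS],
#' 0 = background).
#'
#' @param values Non-negative numeric 3-D array.
#' @param labels Integer 3-D array, same shape.
#' @param voxel_size Length-3 voxel edge lengths in mm.
#' @return Object of class `activity_volume` with fields `values`, `labels`,
#'   `voxel_size` (mm) and `voxel_volume` (mL).
#' @export
activity_volume <- function(values, labels, voxel_size) {
  stopifnot(is.array(values), is.array(labels),
            identical(dim(values), dim(labels)),
            length(dim(values)) == 3L, length(voxel_size) == 3L,
            all(voxel_size > 0))
  if (any(values < 0)) stop("activity values must be non-negative", call. = FALSE)
  if (!all(labels %in% c(0L, COMPARTMENTS)))
    stop("labels must be 0 (background) or a compartment code", call. = FALSE)
  structure(list(values = values, labels = labels,
                 voxel_size = as.numeric(voxel_size),
                 voxel_volume = prod(voxel_size) / 1000),  # mm^3 -> mL
            class = "activity_volume")
}

#' Default compartment geometry
#'
#' Ellipsoid layout on the default 384 mm cube: tumor and in-target normal
#' liver side by side caudally, out-target normal liver above them, and two
#' lung ellipsoids cranially whose combined volume is about 3.3 L (matching
#' the whole-lung volume used for count extrapolation). Compartments are
#' pairwise disjoint with a narrow liver-lung gap so resolution blur can
#' spill liver counts into the lungs, as on real planar MAA scans.
#'
#' @return A `data.frame` with columns `label`, `cx`, `cy`, `cz` (center,
#'   mm), `ax`, `ay`, `az` (semi-axes, mm). Multiple rows may share a label.
#' @export
default_geometry <- function() {
  data.frame(
    label = c("tumor", "in_target", "out_target", "lung", "lung"),
    cx = c(140, 230, 185, 100, 280),
    cy = c(190, 190, 190, 190, 190),
    cz = c(110, 110, 200, 305, 305),
    ax = c(38, 48, 70, 55, 55),
    ay = c(38, 45, 45, 110, 110),
    az = c(38, 45, 38, 65, 65),
    stringsAsFactors = FALSE
  )
}

#' Phantom specification
#'
#' Everything needed to synthesize one case's emission volumes for both
#' modalities: grid, compartment geometry, per-modality activity
#' concentrations, true lung shunt fraction, per-modality resolution
#' (FWHM), Poisson count scaling, PET axial lung coverage and the seed.
#'
#' The lung concentration entries are placeholders: [build_phantom()]
#' rescales the lung uniformly so that the lung share of total phantom
#' activity equals `lsf_true` for the requested modality.
#'
#' @param grid_shape Three positive integers (voxels per axis).
#' @param voxel_size mm per axis (length 1 or 3).
#' @param geometry Ellipsoid table as in [default_geometry()].
#' @param activity_concentration Named list with elements `maa` and
#'   `microsphere`, each a named vector of concentrations (activity per mL)
#'   for `tumor`, `in_target`, `out_target`, `lung`.
#' @param lsf_true True lung shunt fraction(s) in `[0, 0.3]`; either one
#'   number or a named vector with elements `maa` and `microsphere`.
#' @param psf_fwhm Named vector, Gaussian resolution FWHM in mm per
#'   modality (SPECT-like MAA default 12, PET default 6).
#' @param noise_scale Expected counts per unit activity (0 = noiseless).
#' @param pet_axial_coverage Fraction of the lung axial extent inside the
#'   PET field of view, in `(0, 1]`.
#' @param seed Integer seed for the acquisition noise.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L),
                         voxel_size = 4,
                         geometry = default_geometry(),
                         activity_concentration = list(
                           maa = c(tumor = 3.5, in_target = 1, out_target = 1,
                                   lung = 0),
                           microsphere = c(tumor = 5, in_target = 1,
                                           out_target = 1, lung = 0)),
                         lsf_true = c(maa = 0.06, microsphere = 0.018),
                         psf_fwhm = c(maa = 12, microsphere = 6),
                         noise_scale = 500,
                         pet_axial_coverage = 0.4,
                         seed = 1L) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            length(voxel_size) == 3L, all(voxel_size > 0),
            all(c("maa", "microsphere") %in% names(activity_concentration)),
            all(geometry$ax > 0), all(geometry$ay > 0), all(geometry$az > 0))
  if (length(lsf_true) == 1L && is.null(names(lsf_true)))
    lsf_true <- c(maa = unname(lsf_true), microsphere = unname(lsf_true))
  stopifnot(all(c("maa", "microsphere") %in% names(lsf_true)))
  if (any(lsf_true < 0 | lsf_true > 0.3))
    stop("lsf_true must lie in [0, 0.3]", call. = FALSE)
  for (conc in activity_concentration)
    if (any(conc < 0)) stop("activity concentrations must be >= 0", call. = FALSE)
  .assert_scalar(noise_scale, "noise_scale")
  .assert_scalar(pet_axial_coverage, "pet_axial_coverage", lo = 1e-9, hi = 1)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 geometry = geometry,
                 activity_concentration = activity_concentration,
                 lsf_true = lsf_true,
                 psf_fwhm = psf_fwhm,
                 noise_scale = noise_scale,
                 pet_axial_coverage = pet_axial_coverage,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# label grids are pure functions of (grid, voxel size, geometry); cache them
# so cohort generation does not re-rasterize the shared geometry per case
.phantom_cache <- new.env(parent = emptyenv())

.geometry_key <- function(spec) {
  paste(c(spec$grid_shape, signif(spec$voxel_size, 12),
          vapply(spec$geometry, function(col) paste(col, collapse = ","), "")),
        collapse = "|")
}

# label grid for a spec; errors on voxel-wise overlap of distinct labels
.label_grid <- function(spec) {
  key <- .geometry_key(spec)
  cached <- .phantom_cache[[key]]
  if (!is.null(cached)) return(cached$labels)
  labels <- .label_grid_compute(spec)
  .phantom_cache[[key]] <- list(
    labels = labels,
    counts = vapply(COMPARTMENTS, function(code) sum(labels == code), 0L))
  labels
}

# per-compartment voxel counts (cached with the grid)
.label_counts <- function(spec) {
  .label_grid(spec)
  .phantom_cache[[.geometry_key(spec)]]$counts
}

.label_grid_compute <- function(spec) {
  d <- spec$grid_shape; vs <- spec$voxel_size
  cx <- (seq_len(d[1]) - 0.5) * vs[1]
  cy <- (seq_len(d[2]) - 0.5) * vs[2]
  cz <- (seq_len(d[3]) - 0.5) * vs[3]
  labels <- array(0L, dim = d)
  g <- spec$geometry
  for (i in seq_len(nrow(g))) {
    u2 <- outer(outer(((cx - g$cx[i]) / g$ax[i])^2,
                      ((cy - g$cy[i]) / g$ay[i])^2, `+`),
                ((cz - g$cz[i]) / g$az[i])^2, `+`)
    inside <- u2 <= 1
    code <- COMPARTMENTS[[g$label[i]]]
    clash <- inside & labels != 0L & labels != code
    if (any(clash))
      stop(sprintf("geometry error: `%s` ellipsoid overlaps another compartment",
                   g$label[i]), call. = FALSE)
    labels[inside] <- code
  }
  labels
}

#' Build the ground-truth activity phantom for one modality
#'
#' Fills each compartment's voxels with its concentration times the voxel
#' volume, then rescales the lung compartment uniformly so that the lung
#' share of total phantom activity equals the modality's true lung shunt
#' fraction. Deterministic: noise enters only at [simulate_emission_image()].
#'
#' @param spec A [phantom_spec()].
#' @param modality `"maa"` or `"microsphere"`.
#' @return An [activity_volume()] of true per-voxel activity.
#' @export
build_phantom <- function(spec, modality = c("maa", "microsphere")) {
  stopifnot(inherits(spec, "phantom_spec"))
  modality <- match.arg(modality)
  labels <- .label_grid(spec)
  conc <- spec$activity_concentration[[modality]]
  vv <- prod(spec$voxel_size) / 1000
  values <- array(0, dim = spec$grid_shape)
  for (nm in names(COMPARTMENTS)) {
    sel <- labels == COMPARTMENTS[[nm]]
    values[sel] <- (if (nm %in% names(conc)) conc[[nm]] else 0) * vv
  }
  lsf <- spec$lsf_true[[modality]]
  lung_sel <- labels == COMPARTMENTS[["lung"]]
  liver_total <- sum(values[!lung_sel])
  if (liver_total <= 0 && lsf < 1)
    stop("degenerate phantom: zero activity outside the lungs", call. = FALSE)
  n_lung <- sum(lung_sel)
  if (lsf > 0) {
    if (n_lung == 0L)
      stop("geometry error: lsf_true > 0 but no lung voxels", call. = FALSE)
    values[lung_sel] <- lsf / (1 - lsf) * liver_total / n_lung
  } else if (n_lung > 0L) {
    values[lung_sel] <- 0
  }
  if (sum(values) <= 0)
    stop("degenerate phantom: zero total activity", call. = FALSE)
  activity_volume(values, labels, spec$voxel_size)
}

# separable Gaussian convolution along one axis, zero-padded edges.
# kernel is discretized and normalized, so interior sources conserve counts.
.blur_axis <- function(a, sigma_vox, axis) {
  if (sigma_vox <= 0) return(a)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- dnorm(seq(-r, r), sd = sigma_vox)
  k <- k / sum(k)
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  b <- aperm(a, perm)
  db <- dim(b)
  m <- matrix(b, nrow = db[1])
  n <- db[1]
  # band matrix applying the kernel with zero padding
  kmat <- matrix(0, n, n)
  for (j in seq(-r, r)) {
    idx <- seq_len(n)
    tgt <- idx + j
    ok <- tgt >= 1 & tgt <= n
    kmat[cbind(tgt[ok], idx[ok])] <- kmat[cbind(tgt[ok], idx[ok])] + k[j + r + 1]
  }
  out <- kmat %*% m
  array(aperm(array(out, db), order(perm)), dim = d)
}

#' Gaussian volume blur
#'
#' Separable 3-D Gaussian filter with the stated full width at half maximum,
#' zero-padded at the grid edges (sources away from the edge conserve total
#' counts).
#'
#' @param values 3-D array.
#' @param fwhm_mm Scalar FWHM in mm.
#' @param voxel_size Length-3 mm per axis.
#' @return Blurred array of the same shape.
#' @export
gaussian_blur <- function(values, fwhm_mm, voxel_size) {
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(values)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3)
    values <- .blur_axis(values, sigma_mm / voxel_size[ax], ax)
  values
}

#' Simulate an emission acquisition
#'
#' Applies the modality's Gaussian resolution blur, draws Poisson counts at
#' `noise_scale` expected counts per unit activity (skipped when 0), and
#' restricts the axial field of view: slices beyond the stated fraction of
#' the lung axial extent, counted from the caudal end (so the liver and the
#' basal lungs are retained), are cropped away together with their labels.
#'
#' @param truth An [activity_volume()] of true activity.
#' @param psf_fwhm Resolution FWHM in mm (>= 0).
#' @param noise_scale Expected counts per unit activity (>= 0). When
#'   positive the returned values are Poisson counts.
#' @param coverage Fraction of the lung axial extent covered, in `(0, 1]`.
#' @param seed Integer seed for the Poisson draw.
#' @return An [activity_volume()] (possibly with fewer axial slices).
#' @export
simulate_emission_image <- function(truth, psf_fwhm = 0, noise_scale = 0,
                                    coverage = 1, seed = 1L) {
  stopifnot(inherits(truth, "activity_volume"))
  if (psf_fwhm < 0 || noise_scale < 0)
    stop("`psf_fwhm` and `noise_scale` must be >= 0", call. = FALSE)
  .assert_scalar(coverage, "coverage", lo = 1e-9, hi = 1)
  values <- gaussian_blur(truth$values, psf_fwhm, truth$voxel_size)
  if (noise_scale > 0) {
    set.seed(as.integer(seed))
    values <- array(rpois(length(values), values * noise_scale),
                    dim = dim(values))
  }
  labels <- truth$labels
  if (coverage < 1) {
    zs <- which(apply(labels == COMPARTMENTS[["lung"]], 3, any))
    if (length(zs) > 0) {
      keep_lung <- max(1L, ceiling(coverage * length(zs)))
      z_top <- zs[1] - 1L + keep_lung
      values <- values[, , seq_len(z_top), drop = FALSE]
      labels <- labels[, , seq_len(z_top), drop = FALSE]
    }
  }
  activity_volume(values, labels, truth$voxel_size)
}

#' Conjugate planar projection
#'
#' Projects the volume along the anterior-posterior axis (y) into an
#' anterior and a posterior planar image with exponential depth attenuation
#' `exp(-mu * depth)`; depth is measured from the respective detector face.
#' The posterior image is left-right mirrored to match display convention.
#' With `mu = 0` both reduce to the plain axis sum.
#'
#' @param truth An [activity_volume()].
#' @param attenuation_mu Linear attenuation coefficient per mm (>= 0).
#' @return List with `anterior` and `posterior` matrices (x by z; posterior
#'   mirrored in x) and `attenuation_mu`.
#' @export
project_planar <- function(truth, attenuation_mu = 0) {
  stopifnot(inherits(truth, "activity_volume"))
  if (attenuation_mu < 0) stop("`attenuation_mu` must be >= 0", call. = FALSE)
  d <- dim(truth$values)
  dy <- truth$voxel_size[2]
  depth <- (seq_len(d[2]) - 0.5) * dy
  w_ant <- exp(-attenuation_mu * depth)
  w_post <- rev(w_ant)
  ant <- matrix(0, d[1], d[3]); post <- matrix(0, d[1], d[3])
  for (iy in seq_len(d[2])) {
    slab <- truth$values[, iy, ]
    ant <- ant + slab * w_ant[iy]
    post <- post + slab * w_post[iy]
  }
  list(anterior = ant, posterior = post[rev(seq_len(d[1])), , drop = FALSE],
       attenuation_mu = attenuation_mu)
}

#' ROI counts for a compartment group on a planar pair
#'
#' Builds the 2-D ROI by projecting the label grid along y: a planar pixel
#' belongs to the ROI when any voxel in its column carries one of the
#' requested labels. Returns the anterior/posterior count sums over the ROI
#' (the posterior image is un-mirrored before summation so the masks
#' correspond).
#'
#' @param planar Output of [project_planar()].
#' @param labels 3-D label grid of the projected volume.
#' @param compartments Character vector of compartment tags forming the ROI
#'   (e.g. `c("tumor", "in_target", "out_target")` for the liver ROI).
#' @return A [planar_roi_counts()].
#' @export
planar_roi <- function(planar, labels, compartments) {
  codes <- COMPARTMENTS[compartments]
  mask3 <- array(labels %in% codes, dim = dim(labels))
  mask <- apply(mask3, c(1, 3), any)
  post <- planar$posterior[rev(seq_len(nrow(planar$posterior))), , drop = FALSE]
  planar_roi_counts(sum(planar$anterior[mask]), sum(post[mask]))
}
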