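#' ALPS regions of interest
#'
#' Spherical ROI definition for the diffusivity-along-perivascular-spaces
#' (ALPS) index: one sphere in the superior corona radiata (SCR, projection
#' fibres) and one in the superior longitudinal fasciculus (SLF, association
#' fibres) per hemisphere, at the level of the lateral-ventricle body. The
#' default centers are 0-based voxel indices in the JHU-ICBM FA template grid
#' (1 mm, 182 x 218 x 182) and can be overridden for other spaces.
#'
#' @param centers 4 x 3 matrix of 0-based voxel indices with row names
#'   `left_scr`, `left_slf`, `right_scr`, `right_slf`.
#' @param diameter_mm Sphere diameter in mm (default 5).
#' @param space Free-text name of the template grid the centers refer to.
#' @return An object of class `alps_rois`.
#' @export
#' @examples
#' alps_rois()
alps_rois <- function(centers = NULL, diameter_mm = 5,
                      space = "JHU-ICBM-FA-1mm") {
  if (is.null(centers)) {
    centers <- rbind(
      left_scr = c(116, 110, 99),
      left_slf = c(128, 110, 99),
      right_scr = c(64, 110, 99),
      right_slf = c(51, 110, 99)
    )
  }
  centers <- as.matrix(centers)
  need <- c("left_scr", "left_slf", "right_scr", "right_slf")
  if (nrow(centers) != 4 || !all(need %in% rownames(centers))) {
    abort("`centers` must be a 4 x 3 matrix with rows left_scr, left_slf, right_scr, right_slf.")
  }
  check_scalar(diameter_mm, "diameter_mm", positive = TRUE)
  structure(
    list(
      centers = centers[need, , drop = FALSE],
      diameter_mm = diameter_mm, space = space
    ),
    class = "alps_rois"
  )
}

#' @export
print.alps_rois <- function(x, ...) {
  cat(
    "<alps_rois> ", x$diameter_mm, " mm spheres in ", x$space, "\n",
    sep = ""
  )
  print(x$centers)
  invisible(x)
}

# Logical array: voxels whose centers lie within radius (world mm) of the
# world position of the 0-based center voxel.
sphere_mask <- function(vg, center_ijk, radius_mm, name = "ROI") {
  shape <- dim(vg$data)[1:3]
  if (any(center_ijk < 0) || any(center_ijk > shape - 1)) {
    abort(paste0(name, " center lies outside the volume grid."))
  }
  c_world <- voxel_to_world(vg, matrix(center_ijk, 1))
  # bounding box in voxel units
  half <- ceiling(radius_mm / vg$voxel_size) + 1
  lo <- pmax(0, floor(center_ijk - half))
  hi <- pmin(shape - 1, ceiling(center_ijk + half))
  grid <- as.matrix(expand.grid(
    x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]
  ))
  w <- voxel_to_world(vg, grid)
  d2 <- rowSums(sweep(w, 2, as.numeric(c_world))^2)
  sel <- grid[d2 <= radius_mm^2, , drop = FALSE]
  if (nrow(sel) == 0) {
    abort(paste0(name, ": empty ROI sphere (check center and diameter)."))
  }
  mask <- array(FALSE, shape)
  mask[sel + 1] <- TRUE
  mask
}

#' Compute the ALPS index from directional diffusivity maps
#'
#' Extracts mean x-, y-, and z-axis diffusivities from the four ROI spheres
#' and forms, per hemisphere,
#' \deqn{ALPS = \frac{mean(D_{xx,proj}, D_{xx,assoc})}{mean(D_{yy,proj}, D_{zz,assoc})}}
#' where "proj" is the SCR sphere and "assoc" the SLF sphere. The reported
#' `alps_mean` is the average of the left and right indices. No correction
#' for white-matter asymmetry is applied.
#'
#' @param dxx,dyy,dzz [volume_grid()]s of diffusivity along the x, y, and z
#'   axes (mm^2/s), on a shared grid and affine.
#' @param rois An [alps_rois()].
#' @return An object of class `alps_result`: per-hemisphere ROI means, the
#'   left/right indices, and their average. `tidy()` returns the table.
#' @export
#' @examples
#' vg <- function(v) volume_grid(array(v, c(32, 32, 16)))
#' rois <- alps_rois(centers = rbind(
#'   left_scr = c(8, 16, 8), left_slf = c(12, 16, 8),
#'   right_scr = c(24, 16, 8), right_slf = c(20, 16, 8)
#' ), space = "phantom")
#' compute_alps(vg(1.6e-3), vg(0.8e-3), vg(0.8e-3), rois) # index = 2
compute_alps <- function(dxx, dyy, dzz, rois) {
  if (!inherits(rois, "alps_rois")) abort("`rois` must be an alps_rois.")
  check_same_grid(dxx, dyy, "diffusivity maps")
  check_same_grid(dxx, dzz, "diffusivity maps")
  radius <- rois$diameter_mm / 2
  roi_mean <- function(vol, roi) {
    m <- sphere_mask(vol, rois$centers[roi, ], radius, name = roi)
    mean(vol$data[m])
  }
  per_hemi <- function(side) {
    scr <- paste0(side, "_scr")
    slf <- paste0(side, "_slf")
    vals <- c(
      dxx_proj = roi_mean(dxx, scr),
      dxx_assoc = roi_mean(dxx, slf),
      dyy_proj = roi_mean(dyy, scr),
      dzz_assoc = roi_mean(dzz, slf)
    )
    if (any(vals <= 0)) {
      abort(paste0("non-positive mean diffusivity in ", side, " hemisphere ROIs."))
    }
    denom <- mean(vals[c("dyy_proj", "dzz_assoc")])
    if (denom <= 0) abort("non-positive ALPS denominator.")
    c(vals, alps = mean(vals[c("dxx_proj", "dxx_assoc")]) / denom)
  }
  left <- per_hemi("left")
  right <- per_hemi("right")
  res <- dplyr::bind_rows(
    tibble(hemisphere = "left", !!!as.list(left)),
    tibble(hemisphere = "right", !!!as.list(right))
  )
  structure(
    list(
      rois = res,
      alps_left = unname(left["alps"]),
      alps_right = unname(right["alps"]),
      alps_mean = unname((left["alps"] + right["alps"]) / 2)
    ),
    class = "alps_result"
  )
}

#' @export
print.alps_result <- function(x, ...) {
  cat(sprintf(
    "<alps_result> left %.4f, right %.4f, mean %.4f\n",
    x$alps_left, x$alps_right, x$alps_mean
  ))
  invisible(x)
}

#' @rdname compute_alps
#' @param x An `alps_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.alps_result <- function(x, ...) {
  dplyr::bind_rows(
    x$rois,
    tibble(hemisphere = "mean", alps = x$alps_mean)
  )
}

#' Choroid plexus volume fraction
#'
#' Ratio of choroid plexus volume (CPV) to intracranial volume (ICV); a
#' normalization that removes inter-subject head-size differences.
#'
#' @param cpv_mm3 Choroid plexus volume in mm^3 (> 0).
#' @param icv_mm3 Intracranial volume in mm^3 (> 0).
#' @return The fraction `cpv_mm3 / icv_mm3`.
#' @export
#' @examples
#' cpv_fraction(1500, 1.5e6)
cpv_fraction <- function(cpv_mm3, icv_mm3) {
  check_scalar(cpv_mm3, "cpv_mm3", positive = TRUE)
  check_scalar(icv_mm3, "icv_mm3", positive = TRUE)
  cpv_mm3 / icv_mm3
}

#' Choroid plexus volume from a label map
#'
#' Counts voxels carrying the choroid plexus label(s) and multiplies by the
#' voxel volume.
#'
#' @param labels Integer [volume_grid()] label map.
#' @param choroid_labels Label value(s) marking choroid plexus voxels.
#' @return Volume in mm^3.
#' @export
cpv_from_labels <- function(labels, choroid_labels) {
  if (!inherits(labels, "volume_grid")) abort("`labels` must be a volume_grid.")
  sum(labels$data %in% choroid_labels) * voxel_volume(labels)
}
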