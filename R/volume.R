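#' Construct a volume grid
#'
#' The common currency of all imaging operations: a 3-D (or 4-D, with a
#' trailing time/direction axis) scalar field on a voxel lattice, together
#' with voxel dimensions in mm and a voxel-to-world affine.
#'
#' @param data Numeric 3-D or 4-D array.
#' @param voxel_size Numeric length-3 vector, mm per spatial axis.
#' @param affine 4x4 voxel-to-world matrix; defaults to a scaling by
#'   `voxel_size` with the origin at voxel (0, 0, 0).
#' @return An object of class `volume_grid`.
#' @export
#' @examples
#' vg <- volume_grid(array(0, c(4, 4, 4)), voxel_size = c(1, 1, 2))
#' dim(vg)
volume_grid <- function(data, voxel_size = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L))) {
    abort("`data` must be a 3-D or 4-D array.")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) ||
    any(voxel_size <= 0)) {
    abort("`voxel_size` must be three positive numbers (mm).")
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || any(!is.finite(affine))) {
    abort("`affine` must be a finite 4x4 matrix.")
  }
  structure(
    list(data = data, voxel_size = voxel_size, affine = affine),
    class = "volume_grid"
  )
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' @export
print.volume_grid <- function(x, ...) {
  cat(
    "<volume_grid> ", paste(dim(x$data), collapse = " x "),
    " voxels, voxel size ", paste(signif(x$voxel_size, 4), collapse = " x "),
    " mm\n",
    sep = ""
  )
  invisible(x)
}

# Voxel volume in mm^3.
voxel_volume <- function(vg) prod(vg$voxel_size)

# World coordinates (mm) of 0-based voxel indices (n x 3 matrix).
voxel_to_world <- function(vg, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  h <- cbind(ijk, 1) %*% t(vg$affine)
  h[, 1:3, drop = FALSE]
}

# Refuse to combine grids whose shape or affine disagree (tol on affine).
check_same_grid <- function(a, b, what = "volumes", tol = 1e-4) {
  if (!identical(dim(a$data)[1:3], dim(b$data)[1:3])) {
    abort(paste0(what, " are on different grids (shape mismatch)."))
  }
  if (max(abs(a$affine - b$affine)) > tol) {
    abort(paste0(
      what, " have different affines (max difference ",
      format(max(abs(a$affine - b$affine))), "); no silent resampling."
    ))
  }
  invisible(NULL)
}

#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [volume_grid()].
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  img <- tryCatch(
    RNifti::readNifti(path),
    error = function(e) {
      abort(paste0("not a readable NIfTI file: ", path, " (", conditionMessage(e), ")"))
    }
  )
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  vox <- abs(RNifti::pixdim(img))[1:3]
  data <- array(as.vector(img), dim(img)) # plain array, no RNifti attributes
  volume_grid(data, voxel_size = vox, affine = unclass(aff)[1:4, 1:4])
}

#' Write a volume grid as NIfTI
#'
#' @param vg A [volume_grid()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vg, path) {
  if (!inherits(vg, "volume_grid")) abort("`vg` must be a volume_grid.")
  img <- RNifti::asNifti(vg$data)
  RNifti::pixdim(img) <- c(vg$voxel_size, rep(1, length(dim(vg$data)) - 3))
  RNifti::qform(img) <- structure(vg$affine, code = 2L)
  RNifti::sform(img) <- structure(vg$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct a diffusion gradient table
#'
#' @param bvals Numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs Matrix of gradient directions, `length(bvals)` x 3; rows for
#'   b > 0 must be unit vectors.
#' @return An object of class `gradient_table`.
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- matrix(as.numeric(bvecs), ncol = 3)
  if (nrow(bvecs) != length(bvals)) {
    abort("`bvecs` must have one row per b-value.")
  }
  if (!any(bvals <= 0)) {
    abort("gradient table needs at least one b = 0 entry.")
  }
  nz <- bvals > 0
  norms <- sqrt(rowSums(bvecs[nz, , drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-3)) {
    abort("gradient directions for b > 0 must be unit vectors (|g| = 1 within 1e-3).")
  }
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  shells <- sort(unique(round(x$bvals[x$bvals > 0])))
  cat(
    "<gradient_table> ", length(x$bvals), " volumes; shells b = ",
    paste(shells, collapse = ", "), "; ", sum(x$bvals <= 0), " b0\n",
    sep = ""
  )
  invisible(x)
}

# Single-shell check: exactly one distinct nonzero b (within rel tolerance).
assert_single_shell <- function(gtab) {
  b <- gtab$bvals[gtab$bvals > 0]
  if (length(b) < 6) {
    abort("need at least 6 diffusion-weighted volumes on one shell.")
  }
  if (diff(range(b)) > 1e-6 * max(b)) {
    abort("multi-shell gradient table: the single-shell model needs one nonzero b-value.")
  }
  invisible(max(b))
}

#' Read / write FSL-dialect bval and bvec files
#'
#' FSL convention: one whitespace-separated row of b-values, and three rows
#' (x, y, z) of gradient components.
#'
#' @param bval_path,bvec_path File paths.
#' @return `read_bval_bvec()` returns a [gradient_table()].
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  vec <- as.matrix(read.table(bvec_path))
  if (nrow(vec) != 3) {
    abort("bvec file must have three rows (x, y, z components).")
  }
  gradient_table(bvals, t(vec))
}

#' @param gtab A [gradient_table()].
#' @rdname read_bval_bvec
#' @export
write_bval_bvec <- function(gtab, bval_path, bvec_path) {
  writeLines(paste(format(gtab$bvals, trim = TRUE), collapse = " "), bval_path)
  rows <- apply(t(gtab$bvecs), 1, function(r) {
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")
  })
  writeLines(rows, bvec_path)
  invisible(NULL)
}

#' Evenly spread unit directions on the sphere
#'
#' Deterministic Fibonacci-spiral directions, used for the default 64-direction
#' single-shell acquisition scheme (b = 1000 s/mm^2 plus five b = 0 volumes).
#'
#' @param n_directions Number of diffusion-weighted directions.
#' @param n_b0 Number of b = 0 volumes, prepended.
#' @param b Shell b-value in s/mm^2.
#' @return A [gradient_table()].
#' @export
default_dwi_scheme <- function(n_directions = 64, n_b0 = 5, b = 1000) {
  i <- seq_len(n_directions) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n_directions
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  gradient_table(
    bvals = c(rep(0, n_b0), rep(b, n_directions)),
    bvecs = rbind(matrix(0, n_b0, 3), dirs)
  )
}
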