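#' Voxel grid geometry
#'
#' A voxel grid describes the sampling geometry shared by every volume in a
#' cohort: array dimensions, voxel edge lengths in millimetres, and the 4x4
#' voxel-to-world affine. All lesions, the atlas and derived weight maps must
#' live on one common grid; featurization refuses mismatched inputs.
#'
#' @param dims integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size_mm numeric vector of length 3, voxel edge lengths (> 0).
#' @param affine 4x4 voxel-to-world transform; defaults to a diagonal scaling
#'   by `voxel_size_mm` with zero origin.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(dims, voxel_size_mm, affine = NULL) {
  dims <- as.integer(dims)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(dims) != 3L || any(dims < 1L)) {
    stop("`dims` must be three integers, all >= 1", call. = FALSE)
  }
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stop("`voxel_size_mm` must be three positive reals", call. = FALSE)
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps) {
    stop("`affine` must be an invertible 4x4 matrix", call. = FALSE)
  }
  structure(
    list(dims = dims, voxel_size_mm = voxel_size_mm, affine = affine),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$dims, collapse = " x "),
      " voxels @ ", paste(signif(x$voxel_size_mm, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Test whether two volumes (or grids) share a voxel grid
#'
#' Grids agree when dimensions are identical, voxel sizes agree within
#' `tol` mm and affines agree elementwise within `tol`.
#'
#' @param a,b `voxel_grid`, `lesion_volume`, `brain_volume` or
#'   `atlas_definition` objects.
#' @param tol numeric tolerance (default 1e-3).
#' @return logical.
#' @export
check_same_grid <- function(a, b, tol = 1e-3) {
  ga <- as_voxel_grid(a)
  gb <- as_voxel_grid(b)
  identical(ga$dims, gb$dims) &&
    all(abs(ga$voxel_size_mm - gb$voxel_size_mm) <= tol) &&
    all(abs(ga$affine - gb$affine) <= tol)
}

#' @rdname check_same_grid
#' @param x an object carrying a grid.
#' @export
as_voxel_grid <- function(x) {
  if (inherits(x, "voxel_grid")) return(x)
  if (!is.null(x$grid) && inherits(x$grid, "voxel_grid")) return(x$grid)
  stop("cannot extract a voxel grid from object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

#' Construct a volumetric image on a grid
#'
#' `brain_volume` is the generic container (atlas label fields, weight maps);
#' `lesion_volume` additionally carries a patient identifier and the binarity
#' flag and enforces values in \[0, 1\].
#'
#' @param data 3-D numeric array matching `grid$dims`.
#' @param grid a `voxel_grid`.
#' @return A `brain_volume`.
#' @export
brain_volume <- function(data, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  data <- as.array(data)
  if (length(dim(data)) != 3L || !all(dim(data) == grid$dims)) {
    stop("`data` must be a 3-D array with dimensions matching the grid",
         call. = FALSE)
  }
  structure(list(data = data, grid = grid), class = "brain_volume")
}

#' @rdname brain_volume
#' @param patient_id identifier string.
#' @param is_binary logical; TRUE when values are exactly {0, 1}.
#' @export
lesion_volume <- function(data, grid, patient_id = NA_character_,
                          is_binary = NULL) {
  vol <- brain_volume(data, grid)
  v <- vol$data
  if (anyNA(v) || min(v) < 0 || max(v) > 1) {
    stop("lesion values must lie in [0, 1] with no missing entries",
         call. = FALSE)
  }
  if (is.null(is_binary)) is_binary <- all(v == 0 | v == 1)
  vol$patient_id <- as.character(patient_id)
  vol$is_binary <- isTRUE(is_binary)
  class(vol) <- c("lesion_volume", "brain_volume")
  vol
}

#' @export
print.brain_volume <- function(x, ...) {
  cat("<", class(x)[1], "> ", sep = "")
  if (!is.null(x$patient_id) && !is.na(x$patient_id)) {
    cat(x$patient_id, " ")
  }
  cat(paste(x$grid$dims, collapse = "x"), "voxels, values in [",
      signif(min(x$data), 4), ",", signif(max(x$data), 4), "]\n")
  invisible(x)
}

#' Load a 3-D NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file into a `lesion_volume` (when `expect_binary`)
#' or a generic `brain_volume`. Binary masks are enforced by thresholding at
#' 0.5; a warning is raised if the stored values were not already {0, 1}.
#'
#' @param path file path.
#' @param expect_binary logical; threshold values at 0.5 into {0, 1}.
#' @param patient_id optional identifier attached to binary masks.
#' @return `lesion_volume` if `expect_binary`, otherwise `brain_volume`.
#' @export
load_volume <- function(path, expect_binary = FALSE, patient_id = NA_character_) {
  if (!file.exists(path)) stop("no such volume file: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    dim(img) <- d[1:3]
    d <- dim(img)
  }
  if (length(d) != 3L) {
    stop("expected a 3-D volume, got ", length(d), "-D data in ", path,
         call. = FALSE)
  }
  aff <- unclass(RNifti::xform(img))
  aff <- matrix(as.numeric(aff), 4L, 4L)
  vsz <- sqrt(colSums(aff[1:3, 1:3]^2))
  grid <- voxel_grid(d, vsz, aff)
  values <- array(as.numeric(img), dim = d)
  if (expect_binary) {
    if (any(values != 0 & values != 1)) {
      warning("non-binary values found in '", basename(path),
              "'; thresholding at 0.5", call. = FALSE)
    }
    values <- (values >= 0.5) + 0
    lesion_volume(values, grid, patient_id = patient_id, is_binary = TRUE)
  } else {
    brain_volume(values, grid)
  }
}

#' Write a volume to NIfTI
#'
#' Values and grid round-trip through [load_volume()] within 1e-6 (exactly,
#' for integer-valued data, which is stored as int32).
#'
#' @param volume `brain_volume` or `lesion_volume`.
#' @param path destination `.nii` or `.nii.gz` path; the directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "brain_volume"))
  if (!dir.exists(dirname(path))) {
    stop("cannot write volume: directory does not exist: ", dirname(path),
         call. = FALSE)
  }
  v <- volume$data
  integral <- all(v == round(v)) && max(abs(v)) < 2^31
  img <- RNifti::asNifti(v)
  RNifti::pixdim(img) <- volume$grid$voxel_size_mm
  img <- RNifti::`sform<-`(img, structure(volume$grid$affine, code = 2L))
  RNifti::writeNifti(img, path,
                     datatype = if (integral) "int32" else "double")
  invisible(path)
}

# Shift a 3-D array by s voxels along one axis, filling exposed planes with 0.
shift_zero <- function(x, s, axis) {
  if (s == 0L) return(x)
  d <- dim(x)
  n <- d[axis]
  out <- array(0, d)
  if (abs(s) >= n) return(out)
  src <- if (s > 0L) seq_len(n - s) else seq.int(1L - s, n)
  dst <- if (s > 0L) seq.int(1L + s, n) else seq_len(n + s)
  if (axis == 1L) out[dst, , ] <- x[src, , ]
  else if (axis == 2L) out[, dst, ] <- x[, src, ]
  else out[, , dst] <- x[, , src]
  out
}

#' Gaussian smoothing of a lesion mask
#'
#' Separable per-axis Gaussian filter with `sigma_voxels =
#' fwhm_mm / (voxel_size_mm * 2 * sqrt(2 * log(2)))`. The kernel is truncated
#' at 4 sigma and normalised to unit sum, and out-of-volume space is treated
#' as zero (non-brain), so lesions touching the volume edge lose mass while
#' interior mass is conserved. Output values are clipped to \[0, 1\] and the
#' result is marked non-binary.
#'
#' @param mask a `lesion_volume` with values in \[0, 1\].
#' @param fwhm_mm full width at half maximum of the kernel, in mm (> 0);
#'   default 8.
#' @return A smoothed `lesion_volume`.
#' @export
gaussian_smooth <- function(mask, fwhm_mm = 8) {
  stopifnot(inherits(mask, "lesion_volume"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0) {
    stop("`fwhm_mm` must be a single positive number", call. = FALSE)
  }
  sigma_vox <- fwhm_mm / (mask$grid$voxel_size_mm * 2 * sqrt(2 * log(2)))
  out <- mask$data
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    r <- max(1L, as.integer(ceiling(4 * s)))
    k <- stats::dnorm(seq.int(-r, r), sd = s)
    k <- k / sum(k)
    acc <- array(0, dim(out))
    for (j in seq_along(k)) {
      acc <- acc + k[j] * shift_zero(out, j - r - 1L, axis)
    }
    out <- acc
  }
  out <- pmin(pmax(out, 0), 1)
  lesion_volume(out, mask$grid, patient_id = mask$patient_id,
                is_binary = FALSE)
}
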