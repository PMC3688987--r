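#' Voxel grid with brain mask
#'
#' A light container tying 3D array dimensions to physical voxel sizes and a
#' boolean brain mask. All masked datasets, component maps and statistic maps
#' in this package are expressed over the `TRUE` voxels of a grid's mask, in
#' column-major (array) order.
#'
#' @param dims integer(3), array dimensions (all >= 1).
#' @param voxel_size numeric(3), voxel edge lengths in mm.
#' @param mask logical array of dimension `dims`, or `NULL` for an all-`TRUE`
#'   mask. Must contain at least one `TRUE` voxel.
#' @return An object of class `voxel_grid` with elements `dims`, `voxel_size`,
#'   `mask` (logical array) and `n_voxels` (number of in-mask voxels).
#' @export
voxel_grid <- function(dims, voxel_size = c(2, 2, 2), mask = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop("`dims` must be three integers >= 1", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive lengths (mm)", call. = FALSE)
  if (is.null(mask)) {
    mask <- array(TRUE, dim = dims)
  } else {
    mask <- array(as.logical(mask), dim = dims)
    if (!identical(dim(mask), dims)) stop("mask dimensions do not match `dims`", call. = FALSE)
  }
  if (!any(mask)) stop("mask must contain at least one TRUE voxel", call. = FALSE)
  structure(list(dims = dims, voxel_size = voxel_size, mask = mask,
                 n_voxels = sum(mask)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels (%.3g x %.3g x %.3g mm), %d in mask\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$n_voxels))
  invisible(x)
}

#' One subject's masked 4D timeseries
#'
#' @param data numeric matrix, timepoints x in-mask voxels; all values finite.
#' @param grid a [voxel_grid()]; `ncol(data)` must equal `grid$n_voxels`.
#' @param tr repetition time in seconds.
#' @param subject_id character scalar.
#' @return An object of class `masked_dataset`.
#' @export
masked_dataset <- function(data, grid, tr = 2, subject_id = "subject") {
  data <- as.matrix(data)
  stopifnot(inherits(grid, "voxel_grid"))
  if (ncol(data) != grid$n_voxels)
    stop(sprintf("data has %d columns but the mask has %d voxels",
                 ncol(data), grid$n_voxels), call. = FALSE)
  if (!all(is.finite(data))) stop("data contains non-finite values", call. = FALSE)
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("`tr` must be a positive scalar (seconds)", call. = FALSE)
  structure(list(data = data, grid = grid, tr = as.numeric(tr),
                 subject_id = as.character(subject_id)),
            class = "masked_dataset")
}

#' @export
print.masked_dataset <- function(x, ...) {
  cat(sprintf("<masked_dataset> subject '%s': %d timepoints x %d voxels, TR = %g s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Extract in-mask voxels from a 3D or 4D array
#'
#' @param x numeric array with dimensions `grid$dims` (3D) or
#'   `c(grid$dims, t)` (4D).
#' @param grid a [voxel_grid()].
#' @return For 3D input, a numeric vector of in-mask values; for 4D input a
#'   `t x n_voxels` matrix (rows are timepoints/volumes).
#' @export
mask_volumes <- function(x, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)) || !identical(d[1:3], grid$dims))
    stop("array dimensions do not match the grid", call. = FALSE)
  idx <- which(grid$mask)
  if (length(d) == 3L) return(as.numeric(x[idx]))
  nt <- d[4]
  m <- matrix(x, nrow = prod(d[1:3]), ncol = nt)
  t(m[idx, , drop = FALSE])
}

#' Re-embed masked values into full volume space
#'
#' Out-of-mask voxels are zero. Inverse of [mask_volumes()] on in-mask voxels.
#'
#' @param x numeric vector (one volume) or `t x n_voxels` matrix.
#' @param grid a [voxel_grid()].
#' @return A 3D array (vector input) or 4D array with time as 4th dimension.
#' @export
unmask_volumes <- function(x, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  idx <- which(grid$mask)
  if (is.matrix(x)) {
    if (ncol(x) != length(idx)) stop("column count does not match mask", call. = FALSE)
    out <- matrix(0, nrow = prod(grid$dims), ncol = nrow(x))
    out[idx, ] <- t(x)
    array(out, dim = c(grid$dims, nrow(x)))
  } else {
    if (length(x) != length(idx)) stop("length does not match mask", call. = FALSE)
    out <- numeric(prod(grid$dims))
    out[idx] <- x
    array(out, dim = grid$dims)
  }
}

#' Convert a Gaussian FWHM in mm to a sigma in voxel units
#'
#' @param fwhm full width at half maximum, mm (>= 0).
#' @param voxel_size voxel edge length, mm (> 0).
#' @return `fwhm / (2 * sqrt(2 * log(2))) / voxel_size`.
#' @export
fwhm_to_sigma <- function(fwhm, voxel_size) {
  if (!is.numeric(fwhm) || any(fwhm < 0)) stop("`fwhm` must be >= 0", call. = FALSE)
  if (!is.numeric(voxel_size) || any(voxel_size <= 0))
    stop("`voxel_size` must be > 0", call. = FALSE)
  fwhm / (2 * sqrt(2 * log(2))) / voxel_size
}

# 1D discrete Gaussian convolution matrix with zero ("constant" background)
# padding; kernel normalised to unit sum so constants are preserved away from
# the boundary.
gaussian_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma))
  offs <- seq(-r, r)
  k <- exp(-offs^2 / (2 * sigma^2))
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    rows <- j + offs
    ok <- rows >= 1L & rows <= n
    K[rows[ok], j] <- K[rows[ok], j] + k[ok]
  }
  K
}

#' Separable 3D Gaussian smoothing of volumes
#'
#' Smooths each volume of a 3D or 4D array with a separable Gaussian of the
#' given FWHM (mm), using the grid's voxel sizes per axis and zero-padded
#' borders. Smoothing operates in unmasked volume space; callers that work on
#' masked data should unmask, smooth, and re-mask (see
#' [smooth_masked_dataset()]).
#'
#' @param x numeric array, `grid$dims` or `c(grid$dims, t)`.
#' @param fwhm FWHM in mm; `0` returns `x` unchanged.
#' @param grid a [voxel_grid()].
#' @return Array of the same shape as `x`.
#' @export
gaussian_smooth <- function(x, fwhm, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.numeric(fwhm) || length(fwhm) != 1L || fwhm < 0)
    stop("`fwhm` must be a single value >= 0", call. = FALSE)
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)) || !identical(d[1:3], grid$dims))
    stop("array dimensions do not match the grid", call. = FALSE)
  if (fwhm == 0) return(x)
  sig <- fwhm_to_sigma(fwhm, grid$voxel_size)
  Ks <- lapply(1:3, function(a) gaussian_kernel_matrix(grid$dims[a], sig[a]))
  n1 <- d[1]; n2 <- d[2]; n3 <- d[3]
  smooth_one <- function(v) {
    # axis 1
    v <- array(Ks[[1]] %*% matrix(v, n1, n2 * n3), dim = c(n1, n2, n3))
    # axis 2
    v <- aperm(array(Ks[[2]] %*% matrix(aperm(v, c(2, 1, 3)), n2, n1 * n3),
                     dim = c(n2, n1, n3)), c(2, 1, 3))
    # axis 3
    v <- aperm(array(Ks[[3]] %*% matrix(aperm(v, c(3, 1, 2)), n3, n1 * n2),
                     dim = c(n3, n1, n2)), c(2, 3, 1))
    v
  }
  if (length(d) == 3L) return(smooth_one(x))
  out <- array(0, dim = d)
  for (tt in seq_len(d[4])) out[, , , tt] <- smooth_one(x[, , , tt])
  out
}

#' Smooth a masked dataset's volumes
#'
#' Unmasks each volume (out-of-mask voxels set to zero), applies
#' [gaussian_smooth()], and re-masks. This is the smoothing convention used
#' for the "additionally smoothed" subject spatial maps.
#'
#' @param x a [masked_dataset()] or a `t x n_voxels` matrix.
#' @param fwhm FWHM in mm.
#' @param grid required when `x` is a matrix.
#' @return Same type as `x`.
#' @export
smooth_masked_dataset <- function(x, fwhm, grid = NULL) {
  if (inherits(x, "masked_dataset")) {
    sm <- smooth_masked_dataset(x$data, fwhm, x$grid)
    return(masked_dataset(sm, x$grid, tr = x$tr, subject_id = x$subject_id))
  }
  stopifnot(is.matrix(x), inherits(grid, "voxel_grid"))
  if (fwhm == 0) return(x)
  vol <- unmask_volumes(x, grid)
  mask_volumes(gaussian_smooth(vol, fwhm, grid), grid)
}

# DCT-II drift basis: columns k = 1..K with period > cutoff, K = floor(2*N*tr/cutoff)
dct_drift_basis <- function(n, tr, cutoff) {
  K <- floor(2 * n * tr / cutoff)
  if (K < 1L) return(NULL)
  tt <- seq_len(n) - 0.5
  vapply(seq_len(K), function(k) cos(pi * tt * k / n), numeric(n))
}

#' High-pass temporal filtering by discrete-cosine drift removal
#'
#' Removes, per voxel, the least-squares projection onto an intercept plus the
#' discrete-cosine basis functions with period longer than `cutoff` seconds
#' (frequencies below `1/cutoff` Hz). The voxel mean is always removed. The
#' operator is an orthogonal projection, hence idempotent.
#'
#' @param dataset a [masked_dataset()].
#' @param cutoff cutoff period in seconds; must exceed `2 * tr`.
#' @return A filtered [masked_dataset()].
#' @export
highpass_filter <- function(dataset, cutoff = 100) {
  stopifnot(inherits(dataset, "masked_dataset"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 2 * dataset$tr)
    stop(sprintf("cutoff (%.3g s) must exceed 2 * TR (%.3g s): no passband",
                 cutoff, 2 * dataset$tr), call. = FALSE)
  x <- dataset$data
  n <- nrow(x)
  x <- sweep(x, 2L, colMeans(x))
  B <- dct_drift_basis(n, dataset$tr, cutoff)
  if (!is.null(B)) {
    # columns of the DCT basis are orthogonal; project out analytically
    B <- sweep(B, 2L, sqrt(colSums(B^2)), "/")
    x <- x - B %*% crossprod(B, x)
  }
  masked_dataset(x, dataset$grid, tr = dataset$tr, subject_id = dataset$subject_id)
}

#' Read a 4D NIfTI file as a masked dataset
#'
#' @param file path to a `.nii`/`.nii.gz` 4D image.
#' @param mask_file path to a 3D mask image on the same grid; `NULL` uses an
#'   all-ones mask.
#' @param subject_id subject identifier; defaults to the file base name.
#' @return A [masked_dataset()]; the TR is taken from the NIfTI header.
#' @export
read_masked_dataset <- function(file, mask_file = NULL, subject_id = NULL) {
  img <- RNifti::readNifti(file)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4D image", call. = FALSE)
  pd <- RNifti::pixdim(img)
  mask <- NULL
  if (!is.null(mask_file)) {
    m <- RNifti::readNifti(mask_file)
    if (!identical(dim(m)[1:3], d[1:3])) stop("mask grid does not match image", call. = FALSE)
    mask <- array(m != 0, dim = d[1:3])
  }
  grid <- voxel_grid(d[1:3], voxel_size = pd[1:3], mask = mask)
  tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 2
  if (is.null(subject_id)) subject_id <- sub("\\.nii(\\.gz)?$", "", basename(file))
  masked_dataset(mask_volumes(img[], grid), grid, tr = tr, subject_id = subject_id)
}

#' Write volumes to NIfTI-1
#'
#' Writes a 3D array, a 4D array, or masked values (re-embedded via the grid)
#' as 32-bit float NIfTI-1 with the grid's voxel sizes; masks are written as
#' uint8.
#'
#' @param x 3D/4D array, or vector/matrix of in-mask values.
#' @param file output path (`.nii` or `.nii.gz`).
#' @param grid a [voxel_grid()].
#' @param tr repetition time for the 4th dimension, seconds.
#' @param datatype NIfTI datatype, `"float"` or `"uint8"`.
#' @return `file`, invisibly.
#' @export
write_volumes <- function(x, file, grid, tr = 2, datatype = "float") {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(dim(x)) || length(dim(x)) < 3L) x <- unmask_volumes(x, grid)
  pix <- grid$voxel_size
  if (length(dim(x)) == 4L) pix <- c(pix, tr)
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- pix
  RNifti::writeNifti(img, file, datatype = datatype)
  invisible(file)
}
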