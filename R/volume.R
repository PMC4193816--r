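#' CT volume container
#'
#' A `ct_volume` wraps a 3D array of Hounsfield units together with its voxel
#' spacing and world origin. Axes follow the radiological convention used
#' throughout the package: the first two array indices span the axial plane
#' (in-plane, typically 0.5 mm pixels) and the third index runs along the
#' scanner axis (axial slices, typically 2.5 mm apart). The world position of
#' voxel `(i, j, k)` (1-based) is `origin + (c(i, j, k) - 1) * spacing`, in mm.
#'
#' @param data 3D numeric array of HU values.
#' @param spacing Numeric length-3, voxel spacing in mm (all > 0).
#' @param origin Numeric length-3, world position of voxel (1,1,1) in mm.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(0.5, 0.5, 2.5), origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three finite positive numbers (mm).", call. = FALSE)
  }
  if (length(origin) != 3 || any(!is.finite(origin))) {
    stop("`origin` must be three finite numbers (mm).", call. = FALSE)
  }
  if (any(!is.finite(data))) stop("HU values must all be finite.", call. = FALSE)
  structure(
    list(data = data, spacing = spacing, origin = origin),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU range [%g, %g]\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

# world mm -> continuous 1-based voxel index (matrix n x 3 in, n x 3 out)
world_to_index <- function(vol, w) {
  w <- matrix(w, ncol = 3)
  sweep(sweep(w, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
}

# continuous voxel index -> world mm
index_to_world <- function(vol, idx) {
  idx <- matrix(idx, ncol = 3)
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

# world z (mm) of axial slice k
slice_z <- function(vol, k) vol$origin[3] + (k - 1) * vol$spacing[3]

# axial slice index nearest to world z
z_to_slice <- function(vol, z) {
  k <- round((z - vol$origin[3]) / vol$spacing[3]) + 1
  as.integer(pmin(pmax(k, 1L), dim(vol$data)[3]))
}

# Extract axial slice k as a 2D plane object (image + 2D world geometry).
axial_plane <- function(vol, k) {
  stopifnot(k >= 1, k <= dim(vol$data)[3])
  list(
    img = vol$data[, , k],
    spacing = vol$spacing[1:2],
    origin = vol$origin[1:2],
    kind = "axial",
    # world position of in-plane point (a, b): origin2 + (px-1)*spacing2, z fixed
    to_world = local({
      z <- slice_z(vol, k)
      function(p2) cbind(p2[, 1, drop = TRUE], p2[, 2, drop = TRUE], z)
    })
  )
}

#' Read a CT volume from a NIfTI-1 file
#'
#' Loads HU data and voxel spacing from a NIfTI-1 file. Only axis-aligned
#' (orthogonal, non-rotated) orientations are supported; anything else raises
#' an explicit error rather than silently resampling.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [ct_volume()].
#' @export
read_ct_volume <- function(path) {
  if (!file.exists(path)) stop("Volume file not found: ", path, call. = FALSE)
  img <- tryCatch(
    RNifti::readNifti(path),
    error = function(e) stop("Failed to read NIfTI volume '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(dim(img)) != 3) {
    stop("Expected a 3D volume, got ", length(dim(img)), " dimensions.", call. = FALSE)
  }
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3 || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0)) {
    stop("NIfTI header carries no usable voxel spacing.", call. = FALSE)
  }
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- c(0, 0, 0)
  if (!inherits(xf, "try-error") && is.matrix(xf)) {
    rot <- xf[1:3, 1:3]
    offdiag <- rot; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-4 * max(abs(diag(rot)), 1))) {
      stop("Unsupported non-axis-aligned NIfTI orientation; ",
           "reorient the volume to an orthogonal axial stack first.", call. = FALSE)
    }
  }
  ct_volume(array(as.numeric(img), dim = dim(img)), spacing = pd[1:3], origin = origin)
}

#' Write a CT volume to a NIfTI-1 file
#'
#' HU values are stored as signed 16-bit integers (the native CT data type);
#' values are rounded to the nearest integer, so integer-valued volumes
#' round-trip losslessly.
#'
#' @param vol A [ct_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  arr <- round(vol$data)
  if (any(arr < -32768 | arr > 32767)) {
    stop("HU values outside the signed 16-bit range.", call. = FALSE)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

# Trilinear interpolation of a ct_volume at world coordinates.
# `w` is an n x 3 matrix of world mm positions; positions outside the grid get
# `outside` (sentinel background). Exact on-grid positions reproduce the voxel
# value bit-exactly (all fractional weights collapse to 0/1).
trilinear_sample <- function(vol, w, outside = -1024) {
  g <- world_to_index(vol, w)
  d <- dim(vol$data)
  inb <- g[, 1] >= 1 & g[, 1] <= d[1] &
         g[, 2] >= 1 & g[, 2] <= d[2] &
         g[, 3] >= 1 & g[, 3] <= d[3]
  out <- rep(outside, nrow(g))
  if (!any(inb)) return(out)
  g <- g[inb, , drop = FALSE]
  i0 <- floor(g[, 1]); j0 <- floor(g[, 2]); k0 <- floor(g[, 3])
  fx <- g[, 1] - i0; fy <- g[, 2] - j0; fz <- g[, 3] - k0
  i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2]); k1 <- pmin(k0 + 1, d[3])
  # clamp the base as well (handles g exactly at the upper bound)
  i0 <- pmin(i0, d[1]); j0 <- pmin(j0, d[2]); k0 <- pmin(k0, d[3])
  v <- vol$data
  at <- function(i, j, k) v[cbind(i, j, k)]
  val <-
    at(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(i1, j0, k0) * fx       * (1 - fy) * (1 - fz) +
    at(i0, j1, k0) * (1 - fx) * fy       * (1 - fz) +
    at(i1, j1, k0) * fx       * fy       * (1 - fz) +
    at(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
    at(i1, j0, k1) * fx       * (1 - fy) * fz +
    at(i0, j1, k1) * (1 - fx) * fy       * fz +
    at(i1, j1, k1) * fx       * fy       * fz
  out[inb] <- val
  out
}

# Bilinear interpolation on a 2D image at continuous 1-based pixel coordinates.
bilinear_sample <- function(img, px, py, outside = -1024) {
  d <- dim(img)
  inb <- px >= 1 & px <= d[1] & py >= 1 & py <= d[2]
  out <- rep(outside, length(px))
  if (!any(inb)) return(out)
  x <- px[inb]; y <- py[inb]
  i0 <- floor(x); j0 <- floor(y)
  fx <- x - i0; fy <- y - j0
  i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2])
  i0 <- pmin(i0, d[1]); j0 <- pmin(j0, d[2])
  val <- img[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
         img[cbind(i1, j0)] * fx       * (1 - fy) +
         img[cbind(i0, j1)] * (1 - fx) * fy +
         img[cbind(i1, j1)] * fx       * fy
  out[inb] <- val
  out
}

# 3x3 box smoothing with replicated edges; keeps dimensions.
box_smooth3 <- function(img) {
  d <- dim(img)
  if (d[1] < 3 || d[2] < 3) return(img)
  pad <- img[c(1, 1:d[1], d[1]), c(1, 1:d[2], d[2])]
  acc <- matrix(0, d[1], d[2])
  for (di in 0:2) for (dj in 0:2) {
    acc <- acc + pad[di + 1:d[1], dj + 1:d[2]]
  }
  acc / 9
}
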