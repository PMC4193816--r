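#' Reslice a CT volume on an oblique plane
#'
#' Samples the volume by trilinear interpolation on an arbitrarily oriented
#' plane (oblique multiplanar reformation). The plane is given by a world
#' origin and two in-plane unit axes; each output pixel is the trilinear
#' interpolation of the volume at its world position, with positions outside
#' the grid filled with a sentinel background value.
#'
#' @param vol A [ct_volume()].
#' @param origin World position (mm) mapped to in-plane coordinate (0, 0).
#' @param u,v In-plane axis direction vectors (must be non-parallel; they are
#'   orthonormalized with Gram-Schmidt).
#' @param extent Length-2 plane extents in mm (or a single number for a
#'   square plane), covering `[-extent/2, extent/2]` around the origin.
#' @param pixel_mm In-plane pixel spacing in mm.
#' @param outside Sentinel HU for samples outside the volume.
#' @return A plane object: list with `img` (2D matrix), `spacing`, `origin`
#'   (in-plane mm of pixel (1,1)), `kind = "oblique"`, and `to_world()`
#'   mapping in-plane mm coordinates to world mm.
#' @export
reslice_oblique <- function(vol, origin, u, v, extent = 80, pixel_mm = NULL,
                            outside = -1024) {
  stopifnot(inherits(vol, "ct_volume"))
  if (is.null(pixel_mm)) pixel_mm <- min(vol$spacing[1:2])
  if (length(extent) == 1) extent <- c(extent, extent)
  u <- as.numeric(u); v <- as.numeric(v)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("Degenerate plane axes.", call. = FALSE)
  u <- u / nu
  v <- v - sum(v * u) * u
  nv <- sqrt(sum(v^2))
  if (nv < 1e-8) stop("Degenerate (parallel) plane axes.", call. = FALSE)
  v <- v / nv
  a <- seq(-extent[1] / 2, extent[1] / 2, by = pixel_mm)
  b <- seq(-extent[2] / 2, extent[2] / 2, by = pixel_mm)
  grid <- expand.grid(a = a, b = b)
  W <- rep(origin, each = nrow(grid)) +
    outer(grid$a, u) + outer(grid$b, v)
  img <- matrix(trilinear_sample(vol, W, outside = outside),
                nrow = length(a), ncol = length(b))
  list(
    img = img,
    spacing = c(pixel_mm, pixel_mm),
    origin = c(a[1], b[1]),
    kind = "oblique",
    axes = list(origin = origin, u = u, v = v),
    to_world = function(p2) {
      p2 <- matrix(p2, ncol = 2)
      rep(origin, each = nrow(p2)) + outer(p2[, 1], u) + outer(p2[, 2], v)
    }
  )
}
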