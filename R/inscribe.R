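#' Tracking configuration
#'
#' Numeric parameters of the inscribed-circle centerline tracker. The oblique
#' sweep advances in 2 degree steps up to 240 degrees by default; the circle
#' inscription grows the radius in 0.25 mm steps while at least 95% of 72
#' perimeter samples remain lumen-like, and alternates growth with a
#' re-centering step (centroid of the lumen-like samples on the first
#' violating ring) until the centre moves less than 0.05 mm.
#'
#' Lumen membership is judged against a local reference HU (the median of a
#' 5x5 patch around the seed) within `hu_tol`; the plane image is smoothed
#' with a 3x3 box filter first so that image noise does not break the
#' perimeter-coverage test. `hu_tol` must stay below the lumen-to-background
#' contrast (40 HU for the default phantom).
#'
#' @param lumen_hu Expected lumen HU (non-contrast blood, about 40 HU); a
#'   seed whose local reference differs from this by more than `hu_tol` is
#'   rejected as lying outside the lumen.
#' @param step_deg Angular step of the oblique sweep (degrees).
#' @param span_deg Angular span of the oblique sweep (degrees); planes are
#'   generated endpoint-inclusive, so the defaults give 121 planes.
#' @param hu_tol Lumen-membership HU tolerance around the local reference.
#' @param growth_mm Circle radius growth step (mm).
#' @param r_min_mm,r_max_mm Radius search range (mm); an inscription that
#'   reaches `r_max_mm` without meeting the vessel wall is treated as a seed
#'   placed outside the lumen.
#' @param coverage Fraction of perimeter samples that must be lumen-like for
#'   the radius to keep growing.
#' @param n_perimeter Number of perimeter samples per ring.
#' @param center_tol Centering convergence tolerance (mm).
#' @param max_iter Maximum expand/centre iterations.
#' @param smooth Apply the 3x3 box smoothing before membership testing.
#' @param max_diameter_jump Maximum relative diameter change between
#'   consecutive tracked cross-sections; a larger jump means the section is
#'   no longer the vessel (e.g. the sweep clipped the end of the volume) and
#'   tracking truncates there.
#' @param plane_extent Oblique reslice window size (mm).
#' @param pixel_mm Oblique reslice pixel size (mm); `NULL` = in-plane voxel.
#' @param correction_passes Number of perpendicular-correction passes.
#' @return A list of class `tracking_config`.
#' @export
tracking_config <- function(step_deg = 2, span_deg = 240,
                            lumen_hu = 40,
                            hu_tol = 25, growth_mm = 0.25,
                            r_min_mm = 1, r_max_mm = 25,
                            coverage = 0.95, n_perimeter = 72L,
                            center_tol = 0.05, max_iter = 50L,
                            smooth = TRUE,
                            max_diameter_jump = 0.3,
                            plane_extent = 80, pixel_mm = NULL,
                            correction_passes = 2L) {
  stopifnot(step_deg > 0, span_deg >= 0, step_deg <= max(span_deg, step_deg),
            hu_tol > 0, growth_mm > 0, center_tol > 0,
            r_min_mm > 0, r_max_mm > r_min_mm, coverage > 0, coverage <= 1)
  structure(
    list(step_deg = step_deg, span_deg = span_deg, lumen_hu = lumen_hu,
         hu_tol = hu_tol,
         growth_mm = growth_mm, r_min_mm = r_min_mm, r_max_mm = r_max_mm,
         coverage = coverage, n_perimeter = as.integer(n_perimeter),
         center_tol = center_tol, max_iter = as.integer(max_iter),
         smooth = smooth, max_diameter_jump = max_diameter_jump,
         plane_extent = plane_extent, pixel_mm = pixel_mm,
         correction_passes = as.integer(correction_passes)),
    class = "tracking_config"
  )
}

#' Inscribe a circle in a vessel cross-section
#'
#' Dynamically expands and re-centres a circle inside the lumen-like region
#' of a 2D cross-sectional image: the radius grows while at least
#' `cfg$coverage` of the perimeter samples stay within `cfg$hu_tol` of the
#' local lumen reference HU, and the centre moves to the centroid of the
#' lumen-like samples on the first violating ring, alternating until the
#' centre is stationary.
#'
#' @param plane A plane object (from [reslice_oblique()] or an axial slice):
#'   list with `img`, `spacing` (2), `origin` (2, in-plane mm of pixel (1,1)).
#' @param seed In-plane mm coordinates of the seed point.
#' @param cfg A [tracking_config()].
#' @param lumen_ref Optional explicit lumen reference HU; by default the
#'   median HU of the 5x5 pixel patch around the seed.
#' @return List with `center` (in-plane mm), `radius` (mm, the largest
#'   inscribed radius plus half a growth step), `ref` (reference HU used),
#'   `iterations`.
#' @export
inscribe_circle <- function(plane, seed, cfg = tracking_config(),
                            lumen_ref = NULL) {
  img <- if (isTRUE(cfg$smooth)) box_smooth3(plane$img) else plane$img
  sp <- plane$spacing; org <- plane$origin
  d <- dim(img)
  to_px <- function(p) cbind((p[, 1] - org[1]) / sp[1] + 1,
                             (p[, 2] - org[2]) / sp[2] + 1)
  spx <- to_px(matrix(seed, 1, 2))
  if (spx[1] < 1 || spx[1] > d[1] || spx[2] < 1 || spx[2] > d[2]) {
    rlang::abort("Seed lies outside the plane image.",
                 class = "aortacalc_seed_error")
  }
  ref <- lumen_ref
  if (is.null(ref)) {
    ci <- round(spx[1]); cj <- round(spx[2])
    ii <- pmax(1, ci - 2):pmin(d[1], ci + 2)
    jj <- pmax(1, cj - 2):pmin(d[2], cj + 2)
    ref <- stats::median(img[ii, jj])
    if (!is.null(cfg$lumen_hu) && abs(ref - cfg$lumen_hu) > cfg$hu_tol) {
      rlang::abort(
        sprintf("Seed neighbourhood (HU %.0f) is not lumen-like (expected %.0f +/- %.0f).",
                ref, cfg$lumen_hu, cfg$hu_tol),
        class = "aortacalc_seed_error")
    }
  }
  seed_val <- bilinear_sample(img, spx[1], spx[2], outside = NA)
  if (is.na(seed_val) || abs(seed_val - ref) > cfg$hu_tol) {
    rlang::abort(
      sprintf("Seed pixel (HU %.0f) is not lumen-like (reference %.0f +/- %.0f).",
              seed_val, ref, cfg$hu_tol),
      class = "aortacalc_seed_error")
  }
  ang <- seq(0, 2 * pi, length.out = cfg$n_perimeter + 1)[-(cfg$n_perimeter + 1)]
  ca <- cos(ang); sa <- sin(ang)
  radii <- seq(cfg$r_min_mm, cfg$r_max_mm, by = cfg$growth_mm)
  nr <- length(radii)

  grow <- function(center) {
    # all rings at once: nr x n_perimeter sample grid
    px <- (center[1] + outer(radii, ca) - org[1]) / sp[1] + 1
    py <- (center[2] + outer(radii, sa) - org[2]) / sp[2] + 1
    vals <- matrix(bilinear_sample(img, as.numeric(px), as.numeric(py),
                                   outside = NA),
                   nrow = nr)
    member <- !is.na(vals) & abs(vals - ref) <= cfg$hu_tol
    frac <- rowMeans(member)
    fail <- which(frac < cfg$coverage)
    list(first_fail = if (length(fail)) fail[1] else NA_integer_,
         member = member)
  }

  center <- as.numeric(seed)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    g <- grow(center)
    if (is.na(g$first_fail)) {
      rlang::abort(
        "Lumen-like region is unbounded up to r_max; the seed is likely in background.",
        class = "aortacalc_seed_error")
    }
    if (g$first_fail == 1L) {
      rlang::abort("Inscribed circle collapsed below the minimum radius.",
                   class = "aortacalc_degenerate_lumen")
    }
    if (iter >= cfg$max_iter) break
    # centring: per-ray lumen boundary (first non-member sample along each
    # radial ray); the centroid of the boundary polygon halves the offset of
    # the centre from the true axis at every iteration on a convex section
    ff <- apply(!g$member, 2, function(col) {
      w <- which(col); if (length(w)) w[1] else NA_integer_
    })
    rb <- ifelse(is.na(ff), cfg$r_max_mm,
                 ifelse(ff == 1L, 0, radii[pmax(ff - 1L, 1L)]))
    centroid <- c(center[1] + mean(rb * ca), center[2] + mean(rb * sa))
    move <- sqrt(sum((centroid - center)^2))
    center <- centroid
    if (move < cfg$center_tol) break
  }
  # refinement: the boundary centroid is biased on asymmetric sections (for a
  # curved tube the section bulges toward the inner curvature); move to the
  # Chebyshev centre of the ray-boundary polygon, which maximizes the
  # inscribed radius
  for (pass in 1:3) {
    g <- grow(center)
    ff <- apply(!g$member, 2, function(col) {
      w <- which(col); if (length(w)) w[1] else NA_integer_
    })
    bounded <- !is.na(ff) & ff > 1L
    if (sum(bounded) < 8L) break
    bx <- center[1] + radii[ff[bounded] - 1L] * ca[bounded]
    by <- center[2] + radii[ff[bounded] - 1L] * sa[bounded]
    fn <- function(p) -min(sqrt((bx - p[1])^2 + (by - p[2])^2))
    opt <- stats::optim(center, fn, method = "Nelder-Mead",
                        control = list(reltol = 1e-6, maxit = 200))
    move <- sqrt(sum((opt$par - center)^2))
    center <- opt$par
    if (move < cfg$center_tol) break
  }
  g <- grow(center)
  if (is.na(g$first_fail)) {
    rlang::abort(
      "Lumen-like region is unbounded up to r_max; the seed is likely in background.",
      class = "aortacalc_seed_error")
  }
  if (g$first_fail == 1L) {
    rlang::abort("Inscribed circle collapsed below the minimum radius.",
                 class = "aortacalc_degenerate_lumen")
  }
  list(center = center,
       radius = radii[g$first_fail - 1L] + cfg$growth_mm / 2,
       ref = ref, iterations = iter)
}
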