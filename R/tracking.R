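new_centerline <- function(df) {
  df$point <- seq_len(nrow(df))
  df <- df[, c("point", "x", "y", "z", "diameter_mm", "nx", "ny", "nz",
               "arc_mm", "plane")]
  class(df) <- c("tac_centerline", class(tibble::tibble()))
  df
}

empty_track <- function() {
  tibble::tibble(x = double(), y = double(), z = double(),
                 diameter_mm = double(), nx = double(), ny = double(),
                 nz = double(), plane = character())
}

with_arc_length <- function(df) {
  if (nrow(df) == 0) { df$arc_mm <- double(); return(df) }
  P <- as.matrix(df[, c("x", "y", "z")])
  if (nrow(P) < 2) { df$arc_mm <- 0; return(df) }
  step <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  df$arc_mm <- c(0, cumsum(step))
  df
}

#' Track the vessel over axial slices
#'
#' Applies the circle inscription slice by slice, starting from a seed point
#' and walking toward lower axial levels (the descending aorta below the seed
#' pair, or the ascending aorta below `C_A` down to the left main coronary
#' level). The centre found on each slice seeds the next one; tracking stops
#' with a truncation warning when inscription first fails (the vessel or the
#' volume ends).
#'
#' @param vol A [ct_volume()].
#' @param start World-mm seed (on the vessel axis at the starting slice).
#' @param cfg A [tracking_config()].
#' @param stop_z Optional world z (mm) at which to stop (inclusive).
#' @param direction `-1` to walk toward smaller z (default), `+1` upward.
#' @return A centerline tibble (one point per successfully tracked slice,
#'   ordered in tracking order).
#' @export
track_descending <- function(vol, start, cfg = tracking_config(),
                             stop_z = NULL, direction = -1L) {
  stopifnot(inherits(vol, "ct_volume"), length(start) == 3)
  k <- z_to_slice(vol, start[3])
  nk <- dim(vol$data)[3]
  seed2 <- start[1:2]
  rows <- list()
  first <- TRUE
  while (k >= 1 && k <= nk) {
    z <- slice_z(vol, k)
    if (!is.null(stop_z) &&
        ((direction < 0 && z < stop_z - 1e-9) ||
         (direction > 0 && z > stop_z + 1e-9))) break
    plane <- axial_plane(vol, k)
    res <- tryCatch(inscribe_circle(plane, seed2, cfg), error = identity)
    if (!inherits(res, "error") && !first) {
      d_prev <- rows[[length(rows)]]$diameter_mm
      if (abs(2 * res$radius - d_prev) > cfg$max_diameter_jump * d_prev) {
        res <- simpleError(sprintf(
          "cross-section diameter jumped from %.1f to %.1f mm",
          d_prev, 2 * res$radius))
      }
    }
    if (inherits(res, "error")) {
      if (first) stop(res)
      rlang::warn(sprintf(
        "Axial tracking truncated at z = %.1f mm (slice %d): %s",
        z, k, conditionMessage(res)), class = "aortacalc_truncation")
      break
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      x = res$center[1], y = res$center[2], z = z,
      diameter_mm = 2 * res$radius,
      nx = 0, ny = 0, nz = 1, plane = "axial"
    )
    seed2 <- res$center
    first <- FALSE
    k <- k + direction
  }
  df <- if (length(rows)) dplyr::bind_rows(rows) else empty_track()
  new_centerline(with_arc_length(df))
}

#' Track the aortic arch over a semitoroidal sweep of oblique planes
#'
#' Reconstructs oblique planes by trilinear interpolation along a
#' semitoroidal path: planes contain the rotation axis through the midpoint
#' of the `C_A`-`C_D` seed chord (perpendicular to the chord and to the axial
#' direction) and rotate from the chord plane in `cfg$step_deg` steps up to
#' `cfg$span_deg` (endpoint-inclusive; 121 planes at the defaults). The
#' circle found on each plane seeds the next; tracking stops early with a
#' truncation warning if the path exits the vessel or the volume.
#'
#' @param vol A [ct_volume()].
#' @param seeds List with `C_A` and `C_D` world-mm seed points at the level
#'   of the pulmonary artery bifurcation.
#' @param cfg A [tracking_config()].
#' @return A centerline tibble ordered from the ascending (`C_A`) side to the
#'   descending side, one point per successfully tracked plane, with an
#'   `angle_deg` attribute recording the plane angles.
#' @export
track_arch <- function(vol, seeds, cfg = tracking_config()) {
  stopifnot(inherits(vol, "ct_volume"),
            all(c("C_A", "C_D") %in% names(seeds)))
  A <- as.numeric(seeds$C_A); D <- as.numeric(seeds$C_D)
  M <- (A + D) / 2
  chord <- A - M
  if (sqrt(sum(chord[1:2]^2)) < 1e-6) {
    stop("Seed points must be separated in the axial plane.", call. = FALSE)
  }
  e_c <- chord / sqrt(sum(chord^2))
  e_z <- c(0, 0, 1)
  u <- cross3(e_c, e_z); u <- u / sqrt(sum(u^2))
  angles <- seq(0, cfg$span_deg, by = cfg$step_deg)
  c_prev <- A
  rows <- list()
  kept_angles <- numeric(0)
  for (th in angles) {
    vdir <- cos(th * pi / 180) * e_c + sin(th * pi / 180) * e_z
    rel <- c_prev - M
    c_proj <- M + sum(rel * u) * u + sum(rel * vdir) * vdir
    plane <- tryCatch(
      reslice_oblique(vol, c_proj, u, vdir, extent = cfg$plane_extent,
                      pixel_mm = cfg$pixel_mm),
      error = identity)
    res <- if (inherits(plane, "error")) plane else {
      tryCatch(inscribe_circle(plane, c(0, 0), cfg), error = identity)
    }
    if (!inherits(res, "error") && length(rows) > 0) {
      d_prev <- rows[[length(rows)]]$diameter_mm
      if (abs(2 * res$radius - d_prev) > cfg$max_diameter_jump * d_prev) {
        res <- simpleError(sprintf(
          "cross-section diameter jumped from %.1f to %.1f mm",
          d_prev, 2 * res$radius))
      }
    }
    if (inherits(res, "error")) {
      rlang::warn(sprintf(
        "Arch tracking truncated at plane angle %.0f deg: %s",
        th, conditionMessage(res)), class = "aortacalc_truncation")
      break
    }
    ctr <- plane$to_world(matrix(res$center, 1, 2))[1, ]
    nrm <- cross3(u, vdir); nrm <- nrm / sqrt(sum(nrm^2))
    rows[[length(rows) + 1]] <- tibble::tibble(
      x = ctr[1], y = ctr[2], z = ctr[3],
      diameter_mm = 2 * res$radius,
      nx = nrm[1], ny = nrm[2], nz = nrm[3], plane = "oblique"
    )
    kept_angles <- c(kept_angles, th)
    c_prev <- ctr
  }
  df <- if (length(rows)) dplyr::bind_rows(rows) else empty_track()
  out <- new_centerline(with_arc_length(df))
  attr(out, "angle_deg") <- kept_angles
  out
}

#' Perpendicularity correction of a tracked centerline
#'
#' The axial and semitoroidal planes are not necessarily perpendicular to the
#' true vessel axis (a tilted descending aorta or a non-toroidal arch makes
#' the raw cross-sections oblique, overestimating diameters by 1/cos of the
#' tilt). This post-processing re-estimates tangents from the smoothed
#' polyline, reslices each cross-section in the plane orthogonal to its
#' tangent, re-inscribes the circle and updates centre and diameter. Points
#' where re-inscription fails keep their prior estimate (with a warning).
#'
#' @param centerline A centerline tibble (merged and ordered).
#' @param vol The [ct_volume()] it was tracked in.
#' @param cfg A [tracking_config()]; `cfg$correction_passes` controls the
#'   number of passes.
#' @return The corrected centerline; every plane normal equals the local
#'   tangent.
#' @export
perpendicular_correction <- function(centerline, vol, cfg = tracking_config()) {
  df <- centerline
  n <- nrow(df)
  if (n < 3) return(df)
  for (pass in seq_len(max(cfg$correction_passes, 0L))) {
    P <- as.matrix(df[, c("x", "y", "z")])
    Ps <- apply(P, 2, running_mean5)
    tang <- tangents_of(Ps)
    failed <- 0L
    for (i in seq_len(n)) {
      t <- tang[i, ]
      h <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      u1 <- cross3(t, h); u1 <- u1 / sqrt(sum(u1^2))
      u2 <- cross3(t, u1)
      res <- tryCatch({
        plane <- reslice_oblique(vol, P[i, ], u1, u2,
                                 extent = cfg$plane_extent,
                                 pixel_mm = cfg$pixel_mm)
        inscribe_circle(plane, c(0, 0), cfg)
      }, error = identity)
      if (inherits(res, "error")) { failed <- failed + 1L; df$nx[i] <- t[1]; df$ny[i] <- t[2]; df$nz[i] <- t[3]; next }
      ctr <- P[i, ] + res$center[1] * u1 + res$center[2] * u2
      df$x[i] <- ctr[1]; df$y[i] <- ctr[2]; df$z[i] <- ctr[3]
      df$diameter_mm[i] <- 2 * res$radius
      df$nx[i] <- t[1]; df$ny[i] <- t[2]; df$nz[i] <- t[3]
    }
    if (failed > 0) {
      rlang::warn(sprintf(
        "Perpendicular correction kept the prior estimate at %d point(s).",
        failed), class = "aortacalc_truncation")
    }
  }
  new_centerline(with_arc_length(df))
}

running_mean5 <- function(x) {
  n <- length(x)
  if (n < 5) return(x)
  out <- x
  for (i in seq_len(n)) {
    lo <- max(1, i - 2); hi <- min(n, i + 2)
    out[i] <- mean(x[lo:hi])
  }
  out
}

tangents_of <- function(P) {
  n <- nrow(P)
  tg <- matrix(0, n, 3)
  tg[1, ] <- P[2, ] - P[1, ]
  tg[n, ] <- P[n, ] - P[n - 1, ]
  if (n > 2) tg[2:(n - 1), ] <- P[3:n, ] - P[1:(n - 2), ]
  tg / sqrt(rowSums(tg^2))
}

#' Extract the full thoracic-aorta centerline
#'
#' Orchestrates the complete extraction: the ascending aorta below `C_A`
#' (axial planes, down to `proximal_z` — typically the left main coronary
#' level), the curvilinear arch (semitoroidal oblique sweep between the
#' seeds), and the descending aorta below `C_D` (axial planes to the end of
#' the volume); merges the three tracks proximal-to-distal, de-duplicates
#' overlap at the junctions (keeping the point whose plane is more
#' perpendicular to the local tangent), and applies the perpendicularity
#' correction. The result is an ordered, arc-length-parameterized list of
#' roughly 150 centerline points with local diameters.
#'
#' @param vol A [ct_volume()].
#' @param seeds List with `C_A` and `C_D` world-mm seed points.
#' @param cfg A [tracking_config()].
#' @param proximal_z Optional world z (mm) of the proximal terminus on the
#'   ascending limb (the LMCA level); `NULL` tracks as far down as the
#'   vessel supports inscription.
#' @return A `tac_centerline` tibble, ordered proximal to distal.
#' @export
extract_centerline <- function(vol, seeds, cfg = tracking_config(),
                               proximal_z = NULL) {
  seed_z <- seeds$C_A[3]
  arch <- track_arch(vol, seeds, cfg)
  asc <- track_descending(vol, seeds$C_A, cfg, stop_z = proximal_z)
  desc <- track_descending(vol, seeds$C_D, cfg)
  # the oblique sweep beyond the seed chord plane re-covers the limbs below
  # the seed level, which the axial tracks own: clip it there
  dz <- vol$spacing[3]
  arch <- arch[arch$z >= seed_z - 1e-6, ]
  asc <- asc[nrow(asc):1, ]                 # proximal -> distal = bottom -> up
  merged <- dplyr::bind_rows(
    asc[, c("x", "y", "z", "diameter_mm", "nx", "ny", "nz", "plane")],
    arch[, c("x", "y", "z", "diameter_mm", "nx", "ny", "nz", "plane")],
    desc[, c("x", "y", "z", "diameter_mm", "nx", "ny", "nz", "plane")]
  )
  merged <- dedup_merged(merged, tol = 0.25 * dz)
  out <- new_centerline(with_arc_length(merged))
  out <- perpendicular_correction(out, vol, cfg)
  attr(out, "seed_z") <- seed_z
  out
}

# drop near-duplicate consecutive points, keeping the one whose stored plane
# normal is more perpendicular to the local travel direction
dedup_merged <- function(df, tol) {
  n <- nrow(df)
  if (n < 2) return(df)
  P <- as.matrix(df[, c("x", "y", "z")])
  keep <- rep(TRUE, n)
  last <- 1
  for (i in 2:n) {
    d <- sqrt(sum((P[i, ] - P[last, ])^2))
    if (d < tol) {
      ref <- if (i < n) P[i + 1, ] - P[last, ] else P[i, ] - P[max(last - 1, 1), ]
      nref <- sqrt(sum(ref^2))
      if (nref < 1e-9) { keep[i] <- FALSE; next }
      ref <- ref / nref
      al_last <- abs(sum(as.numeric(df[last, c("nx", "ny", "nz")]) * ref))
      al_i <- abs(sum(as.numeric(df[i, c("nx", "ny", "nz")]) * ref))
      if (al_i > al_last) { keep[last] <- FALSE; last <- i } else keep[i] <- FALSE
    } else last <- i
  }
  df[keep, ]
}
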