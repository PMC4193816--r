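#' Synthetic aorta CT phantom specification
#'
#' Describes an analytically known thoracic-aorta phantom: a hyperintense
#' lumen tube built from an ascending cylinder, a torus-arc arch and a
#' descending cylinder inside a soft-tissue background, plus calcific lesions
#' of known geometry and the four anatomical landmarks (LMCA, RSA, LSA, CS)
#' used to partition the vessel. Every geometric quantity (centerline,
#' tangents, diameters, segment boundaries, per-lesion Agatston scores) is
#' available in closed form, so the downstream image-analysis stages can be
#' validated against exact ground truth.
#'
#' The default geometry emulates an adult thoracic aorta on a 250 mm
#' field of view: 28 mm lumen diameter, 30 mm arch radius with a 180° arch
#' whose limbs descend vertically, seed level (pulmonary artery bifurcation)
#' 40 mm below the arch, and an inter-subclavian arch segment of 30 mm.
#'
#' @param dim Grid size in voxels (3 axes). Default `c(512, 512, 80)`.
#' @param spacing Voxel spacing in mm. Default `c(0.5, 0.5, 2.5)` (2.5 mm
#'   axial slices).
#' @param origin World position of voxel (1,1,1), mm.
#' @param arch_center Torus centre (mm). The arch lies in the `y = arch_center[2]`
#'   plane.
#' @param arch_radius_mm Torus major radius R (mm).
#' @param arch_span_deg Angular span of the arch arc, degrees, symmetric about
#'   the top of the arch.
#' @param asc_bottom_z,desc_bottom_z World z (mm) of the lower ends of the
#'   ascending and descending limbs (tangent-continuous with the arch).
#' @param diameter_mm Lumen diameter (mm); a single number or a function of
#'   arc length s (mm) returning the local diameter.
#' @param background_hu,noise_sd Background HU level and Gaussian noise sd
#'   (noise applies to background voxels only; lumen and lesions are uniform).
#' @param lumen_hu Lumen HU (must stay below the 130 HU calcium threshold).
#' @param lesions List of [lesion_spec()] objects.
#' @param landmarks Named list with `LMCA`, `RSA`, `LSA`, `CS` world positions
#'   (mm); `NULL` places the defaults on the path.
#' @param seed_level_mm Axial (z) level of the tracking seed pair, mm.
#' @param seed Integer seed for the background noise generator.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(512, 512, 80),
                         spacing = c(0.5, 0.5, 2.5),
                         origin = c(0, 0, 0),
                         arch_center = NULL,
                         arch_radius_mm = 30,
                         arch_span_deg = 180,
                         asc_bottom_z = NULL,
                         desc_bottom_z = NULL,
                         diameter_mm = 28,
                         background_hu = 0,
                         noise_sd = 5,
                         lumen_hu = 40,
                         lesions = list(),
                         landmarks = NULL,
                         seed_level_mm = NULL,
                         seed = 1L) {
  dim <- as.integer(dim); spacing <- as.numeric(spacing)
  stopifnot(length(dim) == 3, all(dim >= 4), length(spacing) == 3)
  if (any(spacing <= 0)) stop("All voxel spacings must be > 0.", call. = FALSE)
  if (lumen_hu >= 130) {
    stop("`lumen_hu` must stay below the 130 HU calcium threshold.", call. = FALSE)
  }
  ext <- (dim - 1) * spacing + origin     # world position of last voxel centre
  if (is.null(arch_center)) {
    arch_center <- c(origin[1] + (ext[1] - origin[1]) / 2,
                     origin[2] + (ext[2] - origin[2]) / 2,
                     origin[3] + 0.77 * (ext[3] - origin[3]))
  }
  R <- arch_radius_mm
  half <- arch_span_deg / 2 * pi / 180
  th_a <- pi / 2 - half                    # ascending end of the arc
  th_d <- pi / 2 + half                    # descending end
  arc_end_a <- arch_center + R * c(cos(th_a), 0, sin(th_a))
  arc_end_d <- arch_center + R * c(cos(th_d), 0, sin(th_d))
  zspan <- ext[3] - origin[3]
  d0 <- if (is.function(diameter_mm)) 32 else diameter_mm
  if (is.null(asc_bottom_z)) asc_bottom_z <- origin[3] + 0.45 * zspan
  if (is.null(desc_bottom_z)) {
    desc_bottom_z <- origin[3] + d0 / 2 + 1.5 * spacing[3]
  }
  if (is.null(seed_level_mm)) seed_level_mm <- origin[3] + 0.65 * zspan
  # limb bottoms: tangent-continuous extensions of the arc ends
  tan_a <- c(sin(th_a), 0, -cos(th_a))     # outward (downstream -> upstream) at asc end
  tan_d <- c(-sin(th_d), 0, cos(th_d))     # downstream direction at desc end
  pieces <- list()
  if (arc_end_a[3] > asc_bottom_z + 1e-9) {
    # extend the limb downward along the reversed arc tangent until z hits
    # asc_bottom_z (vertical when the arc spans 180 degrees)
    ta <- (arc_end_a[3] - asc_bottom_z) / abs(tan_a[3])
    asc_from <- arc_end_a + ta * tan_a
    pieces <- c(pieces, list(list(type = "seg", from = asc_from, to = arc_end_a)))
  }
  if (arch_span_deg > 0) {
    pieces <- c(pieces, list(list(type = "arc", center = arch_center, R = R,
                                  theta0 = th_a, theta1 = th_d)))
  }
  if (arc_end_d[3] > desc_bottom_z + 1e-9) {
    td <- (arc_end_d[3] - desc_bottom_z) / abs(tan_d[3])
    desc_to <- arc_end_d + td * tan_d
    pieces <- c(pieces, list(list(type = "seg", from = arc_end_d, to = desc_to)))
  }
  if (length(pieces) == 0) stop("Degenerate phantom: no path pieces.", call. = FALSE)
  spec <- structure(
    list(dim = dim, spacing = spacing, origin = origin,
         pieces = pieces,
         arch_center = arch_center, arch_radius_mm = R,
         arch_span_deg = arch_span_deg,
         diameter_mm = diameter_mm,
         background_hu = background_hu, noise_sd = noise_sd,
         lumen_hu = lumen_hu, lesions = lesions,
         landmarks = landmarks, seed_level_mm = seed_level_mm,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
  if (is.null(landmarks)) spec$landmarks <- default_landmarks(spec)
  spec
}

#' Single-tube phantom specification
#'
#' A reduced phantom: one straight cylindrical lumen between two world points
#' (possibly tilted), used to exercise the axial tracking stage in isolation.
#'
#' @param from,to World end points of the tube axis (mm); the path runs
#'   proximal at `from` to distal at `to`.
#' @inheritParams phantom_spec
#' @return A `phantom_spec` whose path is the single segment.
#' @export
tube_phantom_spec <- function(from, to,
                              dim = c(128, 128, 48),
                              spacing = c(1, 1, 2.5),
                              origin = c(0, 0, 0),
                              diameter_mm = 28,
                              background_hu = 0, noise_sd = 0,
                              lumen_hu = 40, lesions = list(), seed = 1L) {
  spec <- structure(
    list(dim = as.integer(dim), spacing = as.numeric(spacing), origin = origin,
         pieces = list(list(type = "seg", from = from, to = to)),
         arch_center = NULL, arch_radius_mm = 0, arch_span_deg = 0,
         diameter_mm = diameter_mm,
         background_hu = background_hu, noise_sd = noise_sd,
         lumen_hu = lumen_hu, lesions = lesions,
         landmarks = NULL, seed_level_mm = NULL, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  spec
}

#' Torus-arc phantom specification
#'
#' A reduced phantom consisting of the arch arc alone (no limb cylinders),
#' used to exercise the semitoroidal oblique tracking stage in isolation.
#'
#' @inheritParams phantom_spec
#' @export
torus_phantom_spec <- function(arch_center, arch_radius_mm = 30,
                               arch_span_deg = 240,
                               dim = c(160, 64, 60),
                               spacing = c(1, 1, 2.5),
                               origin = c(0, 0, 0),
                               diameter_mm = 25,
                               background_hu = 0, noise_sd = 0,
                               lumen_hu = 40, lesions = list(), seed = 1L) {
  half <- arch_span_deg / 2 * pi / 180
  structure(
    list(dim = as.integer(dim), spacing = as.numeric(spacing), origin = origin,
         pieces = list(list(type = "arc", center = arch_center,
                            R = arch_radius_mm,
                            theta0 = pi / 2 - half, theta1 = pi / 2 + half)),
         arch_center = arch_center, arch_radius_mm = arch_radius_mm,
         arch_span_deg = arch_span_deg,
         diameter_mm = diameter_mm,
         background_hu = background_hu, noise_sd = noise_sd,
         lumen_hu = lumen_hu, lesions = lesions,
         landmarks = NULL, seed_level_mm = NULL, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# ---- analytic path -------------------------------------------------------

piece_length <- function(p) {
  if (p$type == "seg") sqrt(sum((p$to - p$from)^2)) else p$R * (p$theta1 - p$theta0)
}

path_total_length <- function(spec) sum(vapply(spec$pieces, piece_length, 0))

# Evaluate the analytic centerline at arc lengths s (vector, mm from the
# proximal terminus). Returns list(points = n x 3, tangents = n x 3).
path_eval <- function(spec, s) {
  lens <- vapply(spec$pieces, piece_length, 0)
  cum <- c(0, cumsum(lens))
  total <- cum[length(cum)]
  s <- pmin(pmax(s, 0), total)
  pts <- matrix(0, length(s), 3)
  tg <- matrix(0, length(s), 3)
  for (i in seq_along(spec$pieces)) {
    p <- spec$pieces[[i]]
    sel <- s >= cum[i] & (s < cum[i + 1] | (i == length(spec$pieces) & s <= cum[i + 1]))
    if (!any(sel)) next
    sl <- s[sel] - cum[i]
    if (p$type == "seg") {
      u <- (p$to - p$from) / lens[i]
      pts[sel, ] <- rep(p$from, each = sum(sel)) + outer(sl, u)
      tg[sel, ] <- matrix(u, sum(sel), 3, byrow = TRUE)
    } else {
      th <- p$theta0 + sl / p$R
      pts[sel, ] <- cbind(p$center[1] + p$R * cos(th),
                          p$center[2],
                          p$center[3] + p$R * sin(th))
      tg[sel, ] <- cbind(-sin(th), 0, cos(th))
    }
  }
  list(points = pts, tangents = tg)
}

path_radius <- function(spec, s) {
  d <- spec$diameter_mm
  if (is.function(d)) d(s) / 2 else rep(d / 2, length(s))
}

# Distance of world points W (n x 3) to the analytic path; returns
# list(dist, s) with the arc length of the closest path point. With
# `flat_ends = TRUE`, points whose projection falls beyond the global path
# termini get infinite distance (flat tube end faces instead of rounded caps).
path_distance <- function(spec, W, flat_ends = FALSE) {
  lens <- vapply(spec$pieces, piece_length, 0)
  cum <- c(0, cumsum(lens))
  n <- nrow(W)
  np <- length(spec$pieces)
  best_d <- rep(Inf, n); best_s <- rep(0, n)
  for (i in seq_along(spec$pieces)) {
    p <- spec$pieces[[i]]
    if (p$type == "seg") {
      u <- (p$to - p$from) / lens[i]
      rel <- sweep(W, 2, p$from)
      traw <- as.numeric(rel %*% u)
      t <- pmin(pmax(traw, 0), lens[i])
      proj <- rep(p$from, each = n) + outer(as.numeric(t), u)
      d <- sqrt(rowSums((W - proj)^2))
      if (flat_ends) {
        if (i == 1) d[traw < 0] <- Inf
        if (i == np) d[traw > lens[i]] <- Inf
      }
      s <- cum[i] + as.numeric(t)
    } else {
      dx <- W[, 1] - p$center[1]; dz <- W[, 3] - p$center[3]
      th <- atan2(dz, dx)
      # map the angle into the window centred on the arc midpoint, so points
      # beyond either end clamp to the nearer endpoint (spans up to 360 deg)
      mid <- (p$theta0 + p$theta1) / 2
      th <- th + 2 * pi * (th < mid - pi) - 2 * pi * (th >= mid + pi)
      thc <- pmin(pmax(th, p$theta0), p$theta1)
      if (flat_ends) {
        beyond <- rep(FALSE, n)
        if (i == 1) beyond <- beyond | th < p$theta0
        if (i == np) beyond <- beyond | th > p$theta1
      }
      px <- p$center[1] + p$R * cos(thc)
      pz <- p$center[3] + p$R * sin(thc)
      d <- sqrt((W[, 1] - px)^2 + (W[, 2] - p$center[2])^2 + (W[, 3] - pz)^2)
      if (flat_ends) d[beyond] <- Inf
      s <- cum[i] + (thc - p$theta0) * p$R
    }
    upd <- d < best_d
    best_d[upd] <- d[upd]; best_s[upd] <- s[upd]
  }
  list(dist = best_d, s = best_s)
}

# Default landmark placement on the analytic path (world mm).
default_landmarks <- function(spec) {
  stopifnot(spec$arch_span_deg > 0)
  M <- spec$arch_center; R <- spec$arch_radius_mm
  # RSA/LSA symmetric about the arch top, 1 radian apart (30 mm inter-subclavian
  # arch segment at R = 30 mm, a typical adult value)
  dth <- 0.5
  rsa <- M + R * c(cos(pi / 2 - dth), 0, sin(pi / 2 - dth))
  lsa <- M + R * c(cos(pi / 2 + dth), 0, sin(pi / 2 + dth))
  asc <- spec$pieces[[1]]
  stopifnot(asc$type == "seg")
  zb <- asc$from[3]
  lmca_z <- zb + 0.12 * (asc$to[3] - zb)
  u <- (asc$to - asc$from) / piece_length(asc)
  lmca <- asc$from + (lmca_z - zb) / u[3] * u
  desc <- spec$pieces[[length(spec$pieces)]]
  cs_z <- desc$to[3] + 0.55 * (desc$from[3] - desc$to[3])
  cs <- c(M[1] + 10, M[2] + 12, cs_z)   # off-axis: only its axial level is used
  list(LMCA = lmca, RSA = rsa, LSA = lsa, CS = cs)
}

# Tracking seed pair implied by the phantom geometry (world mm).
phantom_seeds <- function(spec) {
  stopifnot(!is.null(spec$seed_level_mm))
  z <- spec$seed_level_mm
  first <- spec$pieces[[1]]; last <- spec$pieces[[length(spec$pieces)]]
  seg_at_z <- function(p, z) {
    u <- (p$to - p$from) / piece_length(p)
    p$from + (z - p$from[3]) / u[3] * u
  }
  list(C_A = seg_at_z(first, z), C_D = seg_at_z(last, z))
}

# ---- lesions -------------------------------------------------------------

#' Calcific lesion specification
#'
#' @param center World-mm centre of the lesion.
#' @param extents Lesion extents (full widths) in mm, length 3.
#' @param hu Uniform HU value (>= 130 for a true calcification).
#' @param shape `"cuboid"` (axis-aligned) or `"ellipsoid"`.
#' @param segment Nominal segment label 1-5 (ground truth), or `NA`.
#' @param id Optional identifier used in error messages and tables.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, extents, hu, shape = c("cuboid", "ellipsoid"),
                        segment = NA_integer_, id = NA_integer_) {
  shape <- match.arg(shape)
  stopifnot(length(center) == 3, length(extents) == 3, all(extents > 0))
  structure(list(center = as.numeric(center), extents = as.numeric(extents),
                 hu = hu, shape = shape, segment = as.integer(segment),
                 id = id),
            class = "lesion_spec")
}

#' Place a wall lesion on the phantom lumen boundary
#'
#' Positions a lesion tangent to the lumen surface (half in, half out — the
#' intimal/medial wall location of aortic calcification) at a given arc
#' length and circumferential angle.
#'
#' @param spec A `phantom_spec`.
#' @param s Arc length along the analytic centerline (mm).
#' @param angle Circumferential angle (radians) around the local tangent.
#' @param extents Lesion extents in mm (full widths).
#' @param hu Uniform lesion HU.
#' @inheritParams lesion_spec
#' @export
wall_lesion <- function(spec, s, angle = 0, extents = c(3, 3, 2.5), hu = 300,
                        shape = "cuboid", segment = NA_integer_,
                        id = NA_integer_) {
  ev <- path_eval(spec, s)
  t <- ev$tangents[1, ]
  h <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  n1 <- cross3(t, h); n1 <- n1 / sqrt(sum(n1^2))
  n2 <- cross3(t, n1)
  w <- cos(angle) * n1 + sin(angle) * n2
  ctr <- ev$points[1, ] + path_radius(spec, s) * w
  lesion_spec(ctr, extents, hu, shape = shape, segment = segment, id = id)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# logical mask of voxel centres inside a lesion, over an index bbox
lesion_voxel_box <- function(spec_grid, lesion) {
  lo <- lesion$center - lesion$extents / 2
  hi <- lesion$center + lesion$extents / 2
  i0 <- ceiling((lo - spec_grid$origin) / spec_grid$spacing) + 1
  i1 <- floor((hi - spec_grid$origin) / spec_grid$spacing) + 1
  # clamp in grid; report whether the analytic box exceeds the grid
  inside <- all(lo >= spec_grid$origin - 1e-9) &&
    all(hi <= spec_grid$origin + (spec_grid$dim - 1) * spec_grid$spacing + 1e-9)
  list(i0 = pmax(i0, 1L), i1 = pmin(i1, spec_grid$dim), inside = inside)
}

lesion_member <- function(lesion, W) {
  d <- sweep(W, 2, lesion$center)
  if (lesion$shape == "cuboid") {
    abs(d[, 1]) <= lesion$extents[1] / 2 + 1e-9 &
      abs(d[, 2]) <= lesion$extents[2] / 2 + 1e-9 &
      abs(d[, 3]) <= lesion$extents[3] / 2 + 1e-9
  } else {
    (d[, 1] / (lesion$extents[1] / 2))^2 +
      (d[, 2] / (lesion$extents[2] / 2))^2 +
      (d[, 3] / (lesion$extents[3] / 2))^2 <= 1 + 1e-9
  }
}

# ---- generation ----------------------------------------------------------

#' Generate a synthetic CT phantom with analytic ground truth
#'
#' Rasterizes the phantom lumen and lesions into a HU volume (background +
#' Gaussian noise elsewhere, uniform lumen and lesion values, HU rounded to
#' integers as on a real scanner) and returns the exact parametric ground
#' truth: centerline samples with tangents and diameters, segment boundaries
#' derived from the landmarks, the seed pair, and per-lesion Agatston scores
#' computed with the independent per-voxel oracle [analytic_agatston()].
#'
#' @param spec A [phantom_spec()] (or reduced tube/torus variant).
#' @param gt_ds Ground-truth centerline sampling step, mm.
#' @return A list with elements `volume` (a [ct_volume()]), `truth` (list:
#'   `centerline` tibble, `total_length_mm`, `boundaries_mm`,
#'   `segment_lengths_cm`, `seeds`, `lesions` tibble), and `spec`.
#' @export
generate_phantom <- function(spec, gt_ds = 0.5) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dim; sp <- spec$spacing; org <- spec$origin
  ext <- org + (d - 1) * sp
  total <- path_total_length(spec)
  ss <- seq(0, total, by = gt_ds)
  ev <- path_eval(spec, ss)
  rad <- path_radius(spec, ss)
  # path (+ lumen radius, projected off-axis: the tube ends are flat) must
  # stay inside the grid
  marg <- rad * sqrt(pmax(1 - ev$tangents^2, 0))
  lo <- apply(ev$points - marg, 2, min); hi <- apply(ev$points + marg, 2, max)
  if (any(lo < org - 1e-9) || any(hi > ext + 1e-9)) {
    stop("Phantom lumen tube leaves the volume grid; shrink the geometry ",
         "or enlarge the grid.", call. = FALSE)
  }

  set.seed(spec$seed)
  arr <- array(spec$background_hu, dim = d)
  if (spec$noise_sd > 0) {
    arr <- arr + array(stats::rnorm(prod(d), 0, spec$noise_sd), dim = d)
  }

  # lumen rasterization restricted to the tube bounding box
  pad <- max(rad) + 2 * max(sp)
  i0 <- pmax(floor((lo - pad - org) / sp) + 1, 1)
  i1 <- pmin(ceiling((hi + pad - org) / sp) + 1, d)
  xs <- org[1] + (seq(i0[1], i1[1]) - 1) * sp[1]
  ys <- org[2] + (seq(i0[2], i1[2]) - 1) * sp[2]
  zs <- org[3] + (seq(i0[3], i1[3]) - 1) * sp[3]
  W <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  pd <- path_distance(spec, W, flat_ends = TRUE)
  member <- pd$dist <= path_radius(spec, pd$s)
  if (any(member)) {
    idx <- as.matrix(expand.grid(i = seq(i0[1], i1[1]),
                                 j = seq(i0[2], i1[2]),
                                 k = seq(i0[3], i1[3])))[member, , drop = FALSE]
    arr[idx] <- spec$lumen_hu
  }

  # lesions override lumen/background
  grid <- list(dim = d, spacing = sp, origin = org)
  for (li in seq_along(spec$lesions)) {
    L <- spec$lesions[[li]]
    box <- lesion_voxel_box(grid, L)
    if (!box$inside) {
      stop("Lesion ", if (is.na(L$id)) li else L$id,
           " extends outside the volume grid.", call. = FALSE)
    }
    ii <- seq(box$i0[1], box$i1[1]); jj <- seq(box$i0[2], box$i1[2])
    kk <- seq(box$i0[3], box$i1[3])
    Wl <- as.matrix(expand.grid(x = org[1] + (ii - 1) * sp[1],
                                y = org[2] + (jj - 1) * sp[2],
                                z = org[3] + (kk - 1) * sp[3]))
    mem <- lesion_member(L, Wl)
    if (any(mem)) {
      idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))[mem, , drop = FALSE]
      arr[idx] <- L$hu
    }
  }

  arr <- round(arr)
  vol <- ct_volume(arr, spacing = sp, origin = org)

  truth <- list(
    centerline = tibble::tibble(
      s = ss,
      x = ev$points[, 1], y = ev$points[, 2], z = ev$points[, 3],
      tx = ev$tangents[, 1], ty = ev$tangents[, 2], tz = ev$tangents[, 3],
      diameter_mm = 2 * rad
    ),
    total_length_mm = total
  )

  if (!is.null(spec$landmarks) && !is.null(spec$seed_level_mm)) {
    truth$seeds <- phantom_seeds(spec)
    truth$boundaries_mm <- phantom_boundaries(spec)
    truth$segment_lengths_cm <- diff(truth$boundaries_mm) / 10
  }

  if (length(spec$lesions) > 0) {
    les <- purrr::imap(spec$lesions, function(L, i) {
      sL <- path_distance(spec, matrix(L$center, 1, 3))$s
      tibble::tibble(
        lesion = if (is.na(L$id)) i else L$id,
        x = L$center[1], y = L$center[2], z = L$center[3],
        hu = L$hu,
        nominal_segment = L$segment,
        true_segment = if (!is.null(truth$boundaries_mm)) {
          segment_of_arc(sL, truth$boundaries_mm)
        } else NA_integer_,
        s_mm = sL,
        agatston = analytic_agatston(L, vol)
      )
    })
    truth$lesions <- dplyr::bind_rows(les)
  } else {
    truth$lesions <- tibble::tibble(
      lesion = integer(), x = double(), y = double(), z = double(),
      hu = double(), nominal_segment = integer(), true_segment = integer(),
      s_mm = double(), agatston = double()
    )
  }

  list(volume = vol, truth = truth, spec = spec)
}

# analytic segment boundaries (arc length mm) from landmarks + seed level
phantom_boundaries <- function(spec) {
  lm <- spec$landmarks
  proj <- function(p) path_distance(spec, matrix(p, 1, 3))$s
  lens <- vapply(spec$pieces, piece_length, 0)
  cum <- c(0, cumsum(lens))
  first <- spec$pieces[[1]]; last <- spec$pieces[[length(spec$pieces)]]
  s_at_z_seg <- function(p, s0, z) {
    u <- (p$to - p$from) / piece_length(p)
    s0 + (z - p$from[3]) / u[3]
  }
  b12 <- s_at_z_seg(first, 0, spec$seed_level_mm)
  b45 <- s_at_z_seg(last, cum[length(cum) - 1], lm$CS[3])
  b <- c(proj(lm$LMCA), b12, proj(lm$RSA), proj(lm$LSA), b45,
         path_total_length(spec))
  names(b) <- c("start", "b12", "b23", "b34", "b45", "end")
  b
}

segment_of_arc <- function(s, boundaries) {
  # half-open [b_i, b_{i+1}): boundary hits belong to the distal segment
  idx <- findInterval(s, boundaries[2:5]) + 1L
  pmin(pmax(idx, 1L), 5L)
}

# ---- Agatston oracle -----------------------------------------------------

agatston_weight <- function(hu) {
  w <- integer(length(hu))
  w[hu >= 130] <- 1L
  w[hu >= 200] <- 2L
  w[hu >= 300] <- 3L
  w[hu >= 400] <- 4L
  w
}

#' Per-voxel brute-force Agatston oracle
#'
#' Computes the Agatston score of a single lesion directly from its analytic
#' geometry and the rasterized volume, independently of the pipeline's
#' connected-component scorer: for each axial slice, the number of lesion
#' voxels at or above 130 HU times the pixel area (mm^2), weighted 1/2/3/4 by
#' the slice-peak HU band (130-199 / 200-299 / 300-399 / >= 400), summed over
#' slices. Returns 0 when no voxel reaches the threshold.
#'
#' @param lesion A [lesion_spec()].
#' @param vol The [ct_volume()] the lesion was rasterized into.
#' @return The Agatston score (numeric scalar).
#' @export
analytic_agatston <- function(lesion, vol) {
  stopifnot(inherits(lesion, "lesion_spec"), inherits(vol, "ct_volume"))
  grid <- list(dim = dim(vol$data), spacing = vol$spacing, origin = vol$origin)
  box <- lesion_voxel_box(grid, lesion)
  ii <- seq(box$i0[1], box$i1[1]); jj <- seq(box$i0[2], box$i1[2])
  kk <- seq(box$i0[3], box$i1[3])
  px_area <- vol$spacing[1] * vol$spacing[2]
  score <- 0
  for (k in kk) {
    W <- as.matrix(expand.grid(x = vol$origin[1] + (ii - 1) * vol$spacing[1],
                               y = vol$origin[2] + (jj - 1) * vol$spacing[2],
                               z = slice_z(vol, k)))
    mem <- lesion_member(lesion, W)
    if (!any(mem)) next
    hu <- vol$data[, , k][as.matrix(expand.grid(i = ii, j = jj))[mem, , drop = FALSE]]
    hot <- hu >= 130
    if (!any(hot)) next
    score <- score + sum(hot) * px_area * agatston_weight(max(hu[hot]))
  }
  score
}
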