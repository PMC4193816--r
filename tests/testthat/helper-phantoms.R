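# Shared fixture builders. Everything is generated in code at test time;
# heavier phantoms are cached per session so several test files can reuse
# them without regenerating.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# binary-style disk image plane (lumen-valued disk on background)
disk_plane <- function(R = 20, center = c(60, 60), size = 120, hu = 40) {
  img <- matrix(0, size, size)
  for (i in seq_len(size)) {
    j <- which((i - center[1])^2 + (seq_len(size) - center[2])^2 <= R^2)
    img[i, j] <- hu
  }
  list(img = img, spacing = c(1, 1), origin = c(1, 1))
}

# small full aorta phantom (192 x 192 x 60 at 1/1/2.5 mm), all stages usable
small_phantom_spec <- function(noise_sd = 0, lesions = list(), seed = 1L) {
  phantom_spec(
    dim = c(192, 192, 60), spacing = c(1, 1, 2.5),
    arch_center = c(96, 96, 105), arch_radius_mm = 28,
    diameter_mm = 26, asc_bottom_z = 55, seed_level_mm = 90,
    noise_sd = noise_sd, lesions = lesions, seed = seed
  )
}

# the same phantom with one mid-segment wall lesion per segment, all centres
# at least 5 mm from the segment boundaries
lesioned_phantom <- function() {
  cached("lesioned_phantom", function() {
    spec0 <- small_phantom_spec()
    b <- aortacalc:::phantom_boundaries(spec0)
    mids <- (b[1:5] + b[2:6]) / 2
    les <- lapply(seq_along(mids), function(i) {
      wall_lesion(spec0, mids[i], angle = i, extents = c(4, 4, 2.5),
                  hu = 200 + 60 * i, segment = i, id = i)
    })
    spec <- small_phantom_spec(lesions = les)
    generate_phantom(spec)
  })
}

small_phantom <- function() {
  cached("small_phantom", function() generate_phantom(small_phantom_spec()))
}

small_centerline <- function() {
  cached("small_centerline", function() {
    ph <- small_phantom()
    suppressWarnings(extract_centerline(
      ph$volume, ph$truth$seeds, proximal_z = ph$spec$landmarks$LMCA[3]))
  })
}

lesioned_centerline <- function() {
  cached("lesioned_centerline", function() {
    ph <- lesioned_phantom()
    suppressWarnings(extract_centerline(
      ph$volume, ph$truth$seeds, proximal_z = ph$spec$landmarks$LMCA[3]))
  })
}

# distance of each row of P to the closest analytic ground-truth sample
truth_errors <- function(cl, truth) {
  Q <- t(as.matrix(truth$centerline[, c("x", "y", "z")]))
  P <- as.matrix(cl[, c("x", "y", "z")])
  apply(P, 1, function(p) sqrt(min(colSums((Q - p)^2))))
}

# straight synthetic centerline tibble along +z (for pure-geometry tests)
straight_centerline <- function(length_mm = 150, step = 1, diameter = 25) {
  n <- length_mm / step + 1
  df <- tibble::tibble(
    x = 0, y = 0, z = seq(0, length_mm, by = step),
    diameter_mm = diameter, nx = 0, ny = 0, nz = 1,
    plane = "axial"
  )
  df$arc_mm <- df$z
  df$point <- seq_len(nrow(df))
  df <- df[, c("point", "x", "y", "z", "diameter_mm", "nx", "ny", "nz",
               "arc_mm", "plane")]
  class(df) <- c("tac_centerline", class(tibble::tibble()))
  attr(df, "seed_z") <- NULL
  df
}
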