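test_that("axial tracking follows a vertical cylinder slice by slice", {
  spec <- tube_phantom_spec(c(64, 64, 2.5), c(64, 64, 102.5),
                            dim = c(128, 128, 48), spacing = c(1, 1, 2.5),
                            diameter_mm = 28)
  ph <- generate_phantom(spec)
  cl <- suppressWarnings(track_descending(ph$volume, c(64, 64, 100)))
  expect_equal(nrow(cl), 40)           # one point per axial slice
  err <- sqrt((cl$x - 64)^2 + (cl$y - 64)^2)
  expect_lt(max(err), 0.5)             # centres within half an in-plane voxel
  expect_lt(max(abs(cl$diameter_mm - 28)), 1)
  expect_true(all(diff(cl$arc_mm) > 0))
})

test_that("a seed on the bottom slice yields a single-point track", {
  spec <- tube_phantom_spec(c(64, 64, 0), c(64, 64, 80),
                            dim = c(128, 128, 40), spacing = c(1, 1, 2.5),
                            diameter_mm = 24)
  ph <- generate_phantom(spec)
  cl <- track_descending(ph$volume, c(64, 64, 0))
  expect_equal(nrow(cl), 1)
})

test_that("a tilted cylinder is recovered on its axis after correction", {
  a <- 10 * pi / 180
  from <- c(45, 64, 18)
  to <- from + 80 * c(sin(a), 0, cos(a))
  spec <- tube_phantom_spec(from, to, dim = c(128, 128, 48),
                            spacing = c(1, 1, 2.5), diameter_mm = 28)
  ph <- generate_phantom(spec)
  cl <- suppressWarnings(track_descending(ph$volume,
                                          from + 75 * c(sin(a), 0, cos(a))))
  corr <- suppressWarnings(perpendicular_correction(cl, ph$volume))
  u <- c(sin(a), 0, cos(a))
  P <- as.matrix(corr[, c("x", "y", "z")])
  rel <- sweep(P, 2, from)
  off_axis <- sqrt(rowSums((rel - outer(as.numeric(rel %*% u), u))^2))
  expect_lt(max(off_axis), 1)          # within one voxel of the tilted axis
})

test_that("perpendicular correction brings diameters within 2% at 20 degrees", {
  a <- 20 * pi / 180
  from <- c(45, 64, 18)
  to <- from + 80 * c(sin(a), 0, cos(a))
  spec <- tube_phantom_spec(from, to, dim = c(128, 128, 48),
                            spacing = c(1, 1, 2.5), diameter_mm = 28)
  ph <- generate_phantom(spec)
  cl <- suppressWarnings(track_descending(ph$volume,
                                          from + 75 * c(sin(a), 0, cos(a))))
  corr <- suppressWarnings(perpendicular_correction(cl, ph$volume))
  expect_lt(max(abs(corr$diameter_mm - 28)) / 28, 0.02)
  # normals equal the local tangents
  expect_true(all(abs(corr$nx * 0 + corr$ny * 0 +
                        sqrt(corr$nx^2 + corr$ny^2 + corr$nz^2) - 1) < 1e-6))
})

test_that("correction is a no-op on an already-perpendicular straight track", {
  spec <- tube_phantom_spec(c(64, 64, 2.5), c(64, 64, 102.5),
                            dim = c(128, 128, 48), spacing = c(1, 1, 2.5),
                            diameter_mm = 28)
  ph <- generate_phantom(spec)
  cl <- suppressWarnings(track_descending(ph$volume, c(64, 64, 100)))
  corr <- suppressWarnings(perpendicular_correction(cl, ph$volume))
  expect_lt(max(abs(corr$diameter_mm - cl$diameter_mm)), 0.5)
  expect_lt(max(abs(corr$x - cl$x)), 0.25)
  expect_lt(max(abs(corr$y - cl$y)), 0.25)
})

test_that("the default oblique sweep generates 121 endpoint-inclusive planes", {
  ph <- small_phantom()
  arch <- suppressWarnings(track_arch(ph$volume, ph$truth$seeds))
  expect_equal(length(attr(arch, "angle_deg")), 121)
  expect_equal(attr(arch, "angle_deg")[1], 0)
  expect_equal(attr(arch, "angle_deg")[121], 240)
  expect_equal(nrow(arch), 121)
})

test_that("a zero-span sweep produces a single plane at the seed level", {
  ph <- small_phantom()
  arch <- suppressWarnings(
    track_arch(ph$volume, ph$truth$seeds, tracking_config(span_deg = 0)))
  expect_equal(nrow(arch), 1)
  expect_equal(arch$z[1], ph$truth$seeds$C_A[3], tolerance = 1)
})

test_that("arch tracking recovers the analytic torus centerline", {
  # torus arch with tangent limb stubs; the sweep's own domain is the region
  # above the seed level (the axial tracks own the limbs below)
  spec <- phantom_spec(dim = c(256, 128, 60), spacing = c(1, 1, 2.5),
                       arch_center = c(128, 64, 100), arch_radius_mm = 30,
                       arch_span_deg = 240, diameter_mm = 25,
                       asc_bottom_z = 70, desc_bottom_z = 70,
                       seed_level_mm = 80, noise_sd = 0)
  ph <- generate_phantom(spec)
  arch <- suppressWarnings(track_arch(ph$volume, ph$truth$seeds))
  corr <- suppressWarnings(perpendicular_correction(arch, ph$volume))
  keep <- corr$z >= ph$spec$seed_level_mm
  err <- truth_errors(corr[keep, ], ph$truth)
  expect_lt(max(err), 1)                       # within one in-plane voxel
  dd <- abs(corr$diameter_mm[keep] - 25)
  expect_lt(median(dd), 1)                     # diameters within 1 mm
  expect_lt(max(dd), spec$spacing[3])          # bounded by the slice thickness
})

test_that("full extraction merges the tracks proximal to distal", {
  ph <- small_phantom()
  cl <- small_centerline()
  expect_true(all(diff(cl$arc_mm) > 0))
  # consecutive spacing bounded by twice the axial spacing
  expect_lt(max(diff(cl$arc_mm)), 2 * ph$volume$spacing[3])
  # no self-intersection: all points at least one diameter apart in index
  # space are farther than 0 in arc; total length close to the analytic truth
  truth_len <- ph$truth$total_length_mm - ph$truth$boundaries_mm[["start"]]
  expect_lt(abs(max(cl$arc_mm) - truth_len) / truth_len, 0.02)
  err <- truth_errors(cl, ph$truth)
  expect_lt(median(err), 0.5)
  expect_lt(max(err), 1)
})

test_that("extraction is deterministic and mirror-symmetric", {
  ph <- small_phantom()
  cl1 <- small_centerline()
  cl2 <- suppressWarnings(extract_centerline(
    ph$volume, ph$truth$seeds, proximal_z = ph$spec$landmarks$LMCA[3]))
  expect_identical(as.data.frame(cl1), as.data.frame(cl2))

  # mirror the volume left-right; mirrored seeds must give the mirrored track
  d <- dim(ph$volume$data)
  ext_x <- ph$volume$origin[1] + (d[1] - 1) * ph$volume$spacing[1]
  mvol <- ct_volume(ph$volume$data[d[1]:1, , ], ph$volume$spacing,
                    ph$volume$origin)
  ms <- list(C_A = ph$truth$seeds$C_A, C_D = ph$truth$seeds$C_D)
  ms$C_A[1] <- ext_x - ms$C_A[1]
  ms$C_D[1] <- ext_x - ms$C_D[1]
  mcl <- suppressWarnings(extract_centerline(
    mvol, ms, proximal_z = ph$spec$landmarks$LMCA[3]))
  expect_equal(nrow(mcl), nrow(cl1))
  expect_lt(max(abs((ext_x - mcl$x) - cl1$x)), 0.3)
  expect_lt(max(abs(mcl$z - cl1$z)), 0.3)
})

test_that("tracking tolerates noise at realistic levels", {
  spec <- small_phantom_spec(noise_sd = 20, seed = 9)
  ph <- generate_phantom(spec)
  cl <- suppressWarnings(extract_centerline(
    ph$volume, ph$truth$seeds, proximal_z = spec$landmarks$LMCA[3]))
  err <- truth_errors(cl, ph$truth)
  expect_lt(median(err), 1)            # within one in-plane voxel (median)
})

test_that("seed perturbation within the lumen leaves the centerline stable", {
  ph <- small_phantom()
  cl1 <- small_centerline()
  s2 <- ph$truth$seeds
  s2$C_A <- s2$C_A + c(2, 2, 0)
  s2$C_D <- s2$C_D + c(-2, 1, 0)
  cl2 <- suppressWarnings(extract_centerline(
    ph$volume, s2, proximal_z = ph$spec$landmarks$LMCA[3]))
  P1 <- t(as.matrix(cl1[, c("x", "y", "z")]))
  dev <- apply(as.matrix(cl2[, c("x", "y", "z")]), 1,
               function(p) sqrt(min(colSums((P1 - p)^2))))
  expect_lt(median(dev), 0.5)
})
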