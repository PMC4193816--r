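test_that("phantom spec enforces its invariants", {
  expect_error(phantom_spec(spacing = c(0.5, -1, 2.5)), "spacing")
  expect_error(phantom_spec(lumen_hu = 150), "130 HU")
  expect_error(
    generate_phantom(tube_phantom_spec(c(5, 64, 20), c(5, 64, 100),
                                       dim = c(128, 128, 48),
                                       spacing = c(1, 1, 2.5))),
    "leaves the volume grid")
})

test_that("a no-lesion, zero-noise phantom contains no calcium candidates", {
  ph <- small_phantom()
  expect_lt(max(ph$volume$data), 130)
  expect_equal(nrow(detect_candidates(ph$volume)), 0)
})

test_that("arch arc length matches the analytic circular-arc formula", {
  spec <- torus_phantom_spec(arch_center = c(80, 32, 80), arch_radius_mm = 30,
                             arch_span_deg = 240)
  ph <- generate_phantom(spec)
  expect_equal(ph$truth$total_length_mm, 30 * (240 * pi / 180),
               tolerance = 1e-10)
  expect_equal(ph$truth$total_length_mm, 125.66, tolerance = 1e-4)
})

test_that("ground-truth segment lengths tile the landmarked centerline", {
  ph <- small_phantom()
  b <- ph$truth$boundaries_mm
  expect_true(all(diff(b) > 0))
  expect_equal(sum(ph$truth$segment_lengths_cm) * 10,
               b[["end"]] - b[["start"]], tolerance = 1e-9)
})

test_that("the voxel-level Agatston oracle reproduces hand-computed scores", {
  # a 2x2 mm single-slice lesion at 0.25 mm^2 pixels: area 4 mm^2 (the
  # centre sits between pixel centres so the extent covers exactly 4 pixels)
  mk <- function(hu) {
    les <- lesion_spec(center = c(40.25, 40.25, 20), extents = c(2, 2, 2.4),
                       hu = hu, id = 1)
    spec <- tube_phantom_spec(c(15, 15, 10), c(15, 15, 90),
                              dim = c(160, 160, 40),
                              spacing = c(0.5, 0.5, 2.5),
                              diameter_mm = 10, lesions = list(les))
    ph <- generate_phantom(spec)
    analytic_agatston(les, ph$volume)
  }
  expect_equal(mk(450), 16)   # weight 4 band
  expect_equal(mk(135), 4)    # weight 1 band
  expect_equal(mk(320), 12)   # weight 3 band
  expect_equal(mk(120), 0)    # below the 130 HU threshold
})

test_that("every rasterized lesion at >= 130 HU leaves at least one hot voxel", {
  set.seed(42)
  for (i in 1:20) {
    ctr <- runif(3, 30, 60)
    ext <- runif(3, c(1, 1, 2.5), 4)   # >= 1 voxel in each axis
    hu <- runif(1, 130, 800)
    shape <- sample(c("cuboid", "ellipsoid"), 1)
    les <- lesion_spec(ctr, pmax(ext, c(1, 1, 2.5)), hu, shape = shape)
    spec <- tube_phantom_spec(c(10, 10, 10), c(10, 10, 90),
                              dim = c(96, 96, 40), spacing = c(1, 1, 2.5),
                              diameter_mm = 8, lesions = list(les))
    ph <- generate_phantom(spec)
    expect_gte(sum(ph$volume$data >= 130), 1)
    expect_gt(analytic_agatston(les, ph$volume), 0)
  }
})

test_that("the oracle is invariant to lesion order and disk round trips", {
  les <- list(
    lesion_spec(c(30, 30, 25), c(3, 3, 2.5), 300, id = 1),
    lesion_spec(c(60, 60, 50), c(4, 4, 2.5), 450, id = 2)
  )
  spec <- tube_phantom_spec(c(10, 10, 10), c(10, 10, 90),
                            dim = c(96, 96, 40), spacing = c(1, 1, 2.5),
                            diameter_mm = 8, lesions = les, noise_sd = 3)
  ph1 <- generate_phantom(spec)
  spec2 <- spec; spec2$lesions <- rev(les)
  ph2 <- generate_phantom(spec2)
  s1 <- vapply(les, analytic_agatston, 0, vol = ph1$volume)
  s2 <- vapply(les, analytic_agatston, 0, vol = ph2$volume)
  expect_identical(s1, s2)

  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_ct_volume(ph1$volume, path)
  vol2 <- read_ct_volume(path)
  expect_identical(vapply(les, analytic_agatston, 0, vol = vol2), s1)
})

test_that("a lesion outside the grid is rejected by name", {
  les <- lesion_spec(c(200, 10, 10), c(3, 3, 3), 300, id = 7)
  spec <- tube_phantom_spec(c(10, 10, 10), c(10, 10, 90),
                            dim = c(96, 96, 40), spacing = c(1, 1, 2.5),
                            diameter_mm = 8, lesions = list(les))
  expect_error(generate_phantom(spec), "Lesion 7")
})

test_that("phantom generation is deterministic under a fixed seed", {
  ph1 <- generate_phantom(small_phantom_spec(noise_sd = 10, seed = 5))
  ph2 <- generate_phantom(small_phantom_spec(noise_sd = 10, seed = 5))
  expect_identical(ph1$volume$data, ph2$volume$data)
})
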