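# small hand-built volumes for the connected-component and scoring rules
vol_from_voxels <- function(voxels, hu, dim = c(24, 24, 8),
                            spacing = c(1, 1, 2.5)) {
  arr <- array(0, dim = dim)
  for (i in seq_len(nrow(voxels))) {
    arr[voxels[i, 1], voxels[i, 2], voxels[i, 3]] <- hu[i]
  }
  ct_volume(arr, spacing = spacing)
}

test_that("disjoint phantom lesions are detected as exactly k candidates", {
  ph <- lesioned_phantom()
  cand <- detect_candidates(ph$volume)
  expect_equal(nrow(cand), nrow(ph$truth$lesions))
  expect_true(all(cand$state == "candidate"))
  expect_true(all(cand$n_voxels > 0))
})

test_that("a volume peaking below the threshold yields no candidates", {
  vol <- vol_from_voxels(cbind(5:8, 5, 2), rep(129, 4))
  expect_equal(nrow(detect_candidates(vol)), 0)
})

test_that("voxels sharing only a corner join under 26-connectivity", {
  vol <- vol_from_voxels(rbind(c(5, 5, 2), c(6, 6, 3), c(5, 6, 2), c(6, 5, 2),
                               c(5, 5, 3)),
                         rep(200, 5))
  # all five voxels touch at faces/edges/corners across two slices
  cand <- detect_candidates(vol, min_area_mm2 = 0)
  expect_equal(nrow(cand), 1)
  vol2 <- vol_from_voxels(rbind(c(5, 5, 2), c(7, 7, 2)), rep(200, 2))
  expect_equal(nrow(detect_candidates(vol2, min_area_mm2 = 0)), 2)
})

test_that("sub-millimetre components are discarded by the area rule", {
  # one voxel at 0.25 mm^2 pixels: below the 1 mm^2 operational minimum
  vol <- vol_from_voxels(cbind(5, 5, 2), 300, spacing = c(0.5, 0.5, 2.5))
  expect_equal(nrow(detect_candidates(vol)), 0)
  expect_equal(nrow(detect_candidates(vol, min_area_mm2 = 0.2)), 1)
})

test_that("the pipeline scorer reproduces hand-computed Agatston values", {
  # 4 mm^2 single slice at 450 HU -> 4 x 4 = 16
  vol <- vol_from_voxels(as.matrix(expand.grid(5:6, 5:6, 3)), rep(450, 4))
  cand <- detect_candidates(vol)
  expect_equal(cand$agatston, 16)
  # two slices: 2 mm^2 at 135 and 3 mm^2 at 210 -> 2x1 + 3x2 = 8
  vox <- rbind(c(5, 5, 3), c(6, 5, 3), c(5, 5, 4), c(6, 5, 4), c(7, 5, 4))
  vol <- vol_from_voxels(vox, c(135, 135, 210, 210, 210))
  cand <- detect_candidates(vol)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$agatston, 8)
  # empty slice table scores zero
  expect_equal(agatston_score(tibble::tibble(area_mm2 = double(),
                                             peak_hu = double())), 0)
})

test_that("crossing a weight-band edge doubles the score", {
  mk <- function(hu) {
    vol <- vol_from_voxels(as.matrix(expand.grid(5:6, 5:6, 3)), rep(hu, 4))
    detect_candidates(vol)$agatston
  }
  expect_equal(mk(200), 2 * mk(199))
  expect_equal(mk(400), 4 / 3 * mk(300))
})

test_that("validation accepts wall lesions and rejects distant structures", {
  ph <- lesioned_phantom()
  cl <- lesioned_centerline()
  cand <- validate_lesions(detect_candidates(ph$volume), cl)
  expect_true(all(cand$state == "accepted"))

  # synthetic vertebral blob 40 mm from the centerline
  spec <- small_phantom_spec()
  spine <- lesion_spec(c(96, 150, 50), c(6, 6, 5), 400, id = 99)
  ph2 <- generate_phantom(small_phantom_spec(lesions = list(spine)))
  cand2 <- validate_lesions(detect_candidates(ph2$volume), cl)
  expect_equal(cand2$state, "rejected")
  expect_gt(cand2$dist_mm, 25)
})

test_that("acceptance is monotone non-decreasing in the margin factor", {
  ph <- lesioned_phantom()
  cl <- lesioned_centerline()
  cand <- detect_candidates(ph$volume)
  margins <- c(0.5, 0.8, 1, 1.5, 2.5, 4)
  n_acc <- vapply(margins, function(m) {
    sum(validate_lesions(cand, cl, margin = m)$state == "accepted")
  }, 0L)
  expect_true(all(diff(n_acc) >= 0))
})

test_that("lesions are assigned to the segment holding their projection", {
  ph <- lesioned_phantom()
  cl <- lesioned_centerline()
  lm <- do.call(landmark_set, ph$spec$landmarks)
  seg <- divide_segments(cl, lm, seed_z = ph$spec$seed_level_mm)
  cand <- assign_segment(validate_lesions(detect_candidates(ph$volume), cl),
                         cl, seg)
  # match detected lesions to ground truth by their uniform HU
  truth <- ph$truth$lesions
  got <- cand$segment[match(truth$hu, cand$peak_hu)]
  expect_equal(got, truth$nominal_segment)
  expect_equal(got, truth$true_segment)
})

test_that("an arc length exactly on a boundary belongs to the distal segment", {
  cl <- straight_centerline(length_mm = 150, step = 1)
  lm <- landmark_set(LMCA = c(0, 0, 0), RSA = c(0, 0, 60),
                     LSA = c(0, 0, 90), CS = c(0, 0, 120))
  seg <- divide_segments(cl, lm, seed_z = 30)
  expect_equal(aortacalc:::arc_to_segment(45, seg), 2L)   # mid-segment 2
  expect_equal(aortacalc:::arc_to_segment(90, seg), 4L)   # 3|4 boundary -> 4
  expect_equal(aortacalc:::arc_to_segment(60, seg), 3L)   # 2|3 boundary -> 3
})

test_that("score accumulation conserves totals exactly", {
  ph <- lesioned_phantom()
  cl <- lesioned_centerline()
  lm <- do.call(landmark_set, ph$spec$landmarks)
  seg <- divide_segments(cl, lm, seed_z = ph$spec$seed_level_mm)
  cand <- assign_segment(validate_lesions(detect_candidates(ph$volume), cl),
                         cl, seg)
  st <- accumulate_scores(cand[cand$state == "accepted", ], seg)
  expect_identical(attr(st, "total"), sum(st$agatston))
  expect_identical(sum(st$agatston), sum(cand$agatston[cand$state == "accepted"]))
  expect_identical(sum(st$n_lesions), nrow(cand))
  # pipeline scores equal the per-voxel oracle per lesion
  truth <- ph$truth$lesions
  expect_equal(cand$agatston[match(truth$hu, cand$peak_hu)], truth$agatston)
})

test_that("an empty lesion set accumulates to all zeros", {
  cl <- straight_centerline()
  lm <- landmark_set(LMCA = c(0, 0, 0), RSA = c(0, 0, 60),
                     LSA = c(0, 0, 90), CS = c(0, 0, 120))
  seg <- divide_segments(cl, lm, seed_z = 30)
  st <- accumulate_scores(detect_candidates(
    ct_volume(array(0, c(8, 8, 4)), c(1, 1, 2.5))), seg)
  expect_equal(st$agatston, rep(0, 5))
  expect_equal(st$n_lesions, rep(0L, 5))
  expect_equal(attr(st, "total"), 0)
})

test_that("lesions confined to segments 1 and 5 give standard == extended", {
  row <- tibble::tibble(tac_seg1 = 12, tac_seg2 = 0, tac_seg3 = 0,
                        tac_seg4 = 0, tac_seg5 = 7.5)
  d <- derive_tac(row)
  expect_equal(d$standard_tac, d$extended_tac)
})
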