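test_that("standard and extended TAC derive from the segment scores", {
  d <- derive_tac(tibble::tibble(tac_seg1 = 0, tac_seg2 = 0, tac_seg3 = 10,
                                 tac_seg4 = 20, tac_seg5 = 0))
  expect_equal(c(d$standard_tac, d$extended_tac), c(0, 30))
  d <- derive_tac(tibble::tibble(tac_seg1 = 5, tac_seg2 = 0, tac_seg3 = 0,
                                 tac_seg4 = 0, tac_seg5 = 7))
  expect_equal(c(d$standard_tac, d$extended_tac), c(12, 12))
  d <- derive_tac(tibble::tibble(tac_seg1 = 0, tac_seg2 = 0, tac_seg3 = 0,
                                 tac_seg4 = 0, tac_seg5 = 0))
  expect_equal(c(d$standard_tac, d$extended_tac), c(0, 0))
  expect_error(derive_tac(tibble::tibble(tac_seg1 = 1)), "tac_seg")
  expect_error(derive_tac(tibble::tibble(tac_seg1 = NA, tac_seg2 = 0,
                                         tac_seg3 = 0, tac_seg4 = 0,
                                         tac_seg5 = 0)), "missing")
})

test_that("reclassification groups follow their defining rules", {
  mk <- function(cac, segs) {
    df <- tibble::tibble(cac = cac,
                         tac_seg1 = segs[1], tac_seg2 = segs[2],
                         tac_seg3 = segs[3], tac_seg4 = segs[4],
                         tac_seg5 = segs[5])
    classify_group(df)$group
  }
  expect_equal(mk(0, c(0, 0, 0, 0, 0)), 1L)   # free of calcium
  expect_equal(mk(0, c(0, 0, 40, 0, 0)), 3L)  # extended-only detection
  expect_equal(mk(12, c(0, 0, 40, 0, 0)), 2L) # any CAC -> standard detection
  expect_equal(mk(0, c(3, 0, 0, 0, 0)), 2L)   # standard TAC -> group 2
})

test_that("a single fully calcified subject has 100% prevalence everywhere", {
  df <- tibble::tibble(tac_seg1 = 1, tac_seg2 = 2, tac_seg3 = 3,
                       tac_seg4 = 4, tac_seg5 = 5)
  prev <- prevalence_by_segment(df)
  expect_equal(prev$pct, rep(100, 5))
  expect_error(prevalence_by_segment(df[0, ]), "Empty")
})

test_that("lesion shares and densities follow the constructed counts", {
  counts <- c(412, 371, 2803, 3824, 3421)
  lens <- c(2.9, 4.5, 3.0, 7.0, 4.9)
  ld <- lesion_distribution(counts, lens)
  expect_equal(attr(ld, "total"), 10831)
  expect_equal(ld$share_pct, c(4, 3, 26, 35, 32))
  # ascending aorta (segments 1 + 2) carries 7% of all lesions
  expect_equal(unname(round(100 * sum(counts[1:2]) / sum(counts))), 7)
  # scaling identity: doubling every length halves the densities
  ld2 <- lesion_distribution(counts, 2 * lens)
  expect_equal(ld2$per_cm, ld$per_cm / 2)
  # single-lesion cohort: 100% in its segment
  ld3 <- lesion_distribution(c(0, 0, 1, 0, 0))
  expect_equal(ld3$share_pct, c(0, 0, 100, 0, 0))
  # zero lesions: shares reported as zeros with the flag set
  ld4 <- lesion_distribution(rep(0, 5))
  expect_equal(ld4$share_pct, rep(0, 5))
  expect_true(isTRUE(attr(ld4, "undefined_shares")))
})

test_that("age-independent positivity gives flat tertile prevalence", {
  spec <- cohort_spec(mode = "stochastic", seed = 31)
  co <- generate_cohort(spec)
  at <- age_tertile_prevalence(co)
  any_ <- at[at$measure == "any", ]
  p <- sum(any_$n_positive) / sum(any_$n)
  se <- sqrt(p * (1 - p) / min(any_$n))
  expect_lt(max(abs(any_$n_positive / any_$n - p)), 3 * se)
})

test_that("equal ages still partition into near-equal tertiles", {
  df <- tibble::tibble(age = rep(50, 10), tac_seg1 = 0, tac_seg2 = 0,
                       tac_seg3 = rep(c(0, 1), 5), tac_seg4 = 0, tac_seg5 = 0)
  at <- age_tertile_prevalence(df)
  sizes <- unique(at$n)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_error(age_tertile_prevalence(df[1:2, ]), "at least 3")
})

test_that("Framingham risk is deterministic and increases with age", {
  base <- tibble::tibble(sex = "male", age = 55, tc_mmol = 5.5,
                         hdl_mmol = 1.2, sbp = 130, smoker = FALSE,
                         diabetes = FALSE)
  r1 <- framingham_risk(base)$frs_pct
  r2 <- framingham_risk(base)$frs_pct
  expect_identical(r1, r2)
  ages <- seq(30, 74, by = 2)
  risks <- framingham_risk(dplyr::mutate(base[rep(1, length(ages)), ],
                                         age = ages))$frs_pct
  expect_true(all(diff(risks) > 0))
  expect_true(all(risks >= 0 & risks <= 100))
})

test_that("Framingham risk matches the frozen hand-computed fixture", {
  df <- tibble::tibble(
    sex = c("male", "female", "male"),
    age = c(57, 61, 48),
    tc_mmol = c(5.7, 6.2, 4.9),
    hdl_mmol = c(1.3, 1.5, 1.1),
    sbp = c(130, 142, 118),
    smoker = c(FALSE, TRUE, TRUE),
    diabetes = c(FALSE, FALSE, TRUE)
  )
  expect_equal(framingham_risk(df)$frs_pct,
               c(13.5279706806, 17.8162206934, 21.3233423205),
               tolerance = 1e-9)
})

test_that("a missing covariate is reported by name", {
  df <- tibble::tibble(sex = "male", age = 50, tc_mmol = 5, hdl_mmol = 1.2,
                       sbp = 120, smoker = FALSE)
  expect_error(framingham_risk(df), "diabetes")
  df$diabetes <- NA
  expect_error(framingham_risk(df), "diabetes")
})

test_that("group comparisons mirror the stratified-table structure", {
  co <- generate_cohort(cohort_spec(seed = 7))
  gc_ <- group_comparisons(co)
  td <- tidy(gc_)
  expect_setequal(td$variable, c("age", "frs_pct", "male", "hypertension",
                                 "hypercholesterolemia", "smoker", "diabetes"))
  # the sex imbalance of the reclassification group is highly significant
  expect_lt(td$p_value[td$variable == "male"], 0.001)
  expect_lt(td$p_value[td$variable == "age"], 0.001)
  # diabetes does not differ between groups
  expect_gt(td$p_value[td$variable == "diabetes"], 0.05)
  gl <- glance(gc_)
  expect_equal(gl$n, 970)
  expect_equal(gl$n_group1 + gl$n_group2 + gl$n_group3, 970)
})

test_that("identical groups show no pairwise Tukey difference", {
  vals <- rep(stats::qnorm(stats::ppoints(60), 50, 5), 2)
  df <- tibble::tibble(
    age = c(vals, stats::qnorm(stats::ppoints(60), 70, 5)),
    sex = "male", hypertension = FALSE, hypercholesterolemia = FALSE,
    smoker = FALSE, diabetes = FALSE,
    group = rep(c(1L, 2L, 3L), each = 60)
  )
  gc_ <- group_comparisons(df, continuous = "age",
                           categorical = list(male = df$sex == "male"))
  td <- tidy(gc_)
  age_row <- td[td$variable == "age", ]
  expect_gt(age_row$p_12, 0.99)     # groups 1 and 2 are identical
  expect_lt(age_row$p_13, 0.001)    # group 3 differs
})

test_that("cohort consistency identities hold on any cohort", {
  for (sd_ in c(2, 9)) {
    for (mode in c("exact-marginal", "stochastic")) {
      co <- generate_cohort(cohort_spec(mode = mode, seed = sd_))
      s <- tac_detection_summary(co)
      expect_equal(s$ext_pos - s$std_pos, s$extended_only)
      expect_equal(sum(co$group == 1), s$n - sum(co$cac > 0 | co$extended_tac > 0))
      expect_true(all(co$standard_tac <= co$extended_tac))
    }
  }
})
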