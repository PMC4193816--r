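# report-parity rounding: nearest integer, halves away from zero
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

seg_cols <- paste0("tac_seg", 1:5)

check_segments_present <- function(data) {
  miss <- setdiff(seg_cols, names(data))
  if (length(miss)) {
    stop("Missing per-segment TAC score column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyNA(data[seg_cols])) {
    stop("Per-segment TAC scores contain missing values; the cohort analysis ",
         "is complete-case only.", call. = FALSE)
  }
  invisible(TRUE)
}

#' Derive standard and extended TAC scores
#'
#' Standard TAC counts only segments 1 and 5 (the ascending and distal
#' descending portions a routine cardiac scan covers); extended TAC sums all
#' five segments, including the arch region. Standard TAC <= extended TAC by
#' construction.
#'
#' @param data Subject tibble with columns `tac_seg1` ... `tac_seg5`.
#' @return `data` with `standard_tac` and `extended_tac` columns.
#' @export
derive_tac <- function(data) {
  check_segments_present(data)
  dplyr::mutate(
    data,
    standard_tac = .data$tac_seg1 + .data$tac_seg5,
    extended_tac = .data$tac_seg1 + .data$tac_seg2 + .data$tac_seg3 +
      .data$tac_seg4 + .data$tac_seg5
  )
}

#' Classify subjects into reclassification groups
#'
#' Group 1: free of calcifications (CAC = 0 and extended TAC = 0).
#' Group 2: detected by the standard method (CAC > 0 or standard TAC > 0).
#' Group 3: detected exclusively by the extended method (CAC = 0, standard
#' TAC = 0, extended TAC > 0). The three groups are exhaustive and mutually
#' exclusive.
#'
#' @param data Subject tibble with `cac` and per-segment TAC scores.
#' @return `data` with an integer `group` column.
#' @export
classify_group <- function(data) {
  if (!"cac" %in% names(data)) stop("Missing `cac` column.", call. = FALSE)
  if (!all(c("standard_tac", "extended_tac") %in% names(data))) {
    data <- derive_tac(data)
  }
  dplyr::mutate(
    data,
    group = dplyr::case_when(
      .data$cac == 0 & .data$extended_tac == 0 ~ 1L,
      .data$cac > 0 | .data$standard_tac > 0 ~ 2L,
      TRUE ~ 3L
    )
  )
}

#' Per-segment TAC prevalence
#'
#' @param data Subject tibble with per-segment TAC scores.
#' @return Tibble with `segment`, `n_positive`, `pct` (nearest-integer
#'   percentage of subjects with a positive score in that segment).
#' @export
prevalence_by_segment <- function(data) {
  if (nrow(data) == 0) stop("Empty cohort.", call. = FALSE)
  check_segments_present(data)
  n <- nrow(data)
  np <- vapply(seg_cols, function(cl) sum(data[[cl]] > 0), 0L)
  tibble::tibble(
    segment = 1:5,
    n_positive = unname(np),
    pct = unname(round_half_up(100 * np / n))
  )
}

#' Detection overlap between standard and extended TAC assessment
#'
#' @param data Subject tibble.
#' @return One-row tibble with counts and nearest-integer percentages:
#'   extended/standard TAC positives, CAC positives, joint and
#'   extended-exclusive detection.
#' @export
tac_detection_summary <- function(data) {
  if (!all(c("standard_tac", "extended_tac") %in% names(data))) {
    data <- derive_tac(data)
  }
  n <- nrow(data)
  cnt <- function(x) sum(x)
  pct <- function(k) round_half_up(100 * k / n)
  ext <- cnt(data$extended_tac > 0)
  std <- cnt(data$standard_tac > 0)
  cacp <- cnt(data$cac > 0)
  both <- cnt(data$cac > 0 & data$extended_tac > 0)
  neither <- cnt(data$cac == 0 & data$extended_tac == 0)
  excl <- cnt(data$extended_tac > 0 & data$standard_tac == 0)
  tibble::tibble(
    n = n,
    ext_pos = ext, ext_pct = pct(ext),
    std_pos = std, std_pct = pct(std),
    cac_pos = cacp, cac_pct = pct(cacp),
    both_pos = both, both_pct = pct(both),
    neither_pos = neither, neither_pct = pct(neither),
    extended_only = excl, extended_only_pct = pct(excl)
  )
}

#' Spatial lesion distribution across segments
#'
#' @param lesion_counts Either a length-5 numeric vector of per-segment
#'   lesion totals, or a subject tibble with `lesions_seg1` ...
#'   `lesions_seg5` columns (summed over subjects).
#' @param segment_lengths_cm Length-5 vector of cohort-average segment
#'   lengths in cm (the per-cm normalizer), or `NULL` to skip densities.
#' @return Tibble with `segment`, `n_lesions`, `share_pct` (nearest-integer
#'   percentage of the total) and `per_cm` (lesions per cm of segment).
#'   When the total is zero the shares are reported as zeros and the
#'   `undefined_shares` attribute is set.
#' @export
lesion_distribution <- function(lesion_counts, segment_lengths_cm = NULL) {
  if (is.data.frame(lesion_counts)) {
    cols <- paste0("lesions_seg", 1:5)
    miss <- setdiff(cols, names(lesion_counts))
    if (length(miss)) stop("Missing lesion count column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    counts <- unname(vapply(cols, function(cl) sum(lesion_counts[[cl]]), 0))
  } else {
    stopifnot(length(lesion_counts) == 5)
    counts <- as.numeric(lesion_counts)
  }
  total <- sum(counts)
  out <- tibble::tibble(segment = 1:5, n_lesions = counts)
  if (total > 0) {
    out$share_pct <- round_half_up(100 * counts / total)
  } else {
    out$share_pct <- rep(0, 5)
    attr(out, "undefined_shares") <- TRUE
  }
  if (!is.null(segment_lengths_cm)) {
    stopifnot(length(segment_lengths_cm) == 5, all(segment_lengths_cm > 0))
    out$per_cm <- counts / as.numeric(segment_lengths_cm)
  }
  attr(out, "total") <- total
  out
}

#' TAC prevalence by age tertile
#'
#' Tertile cut points come from the empirical cohort age distribution (ranks,
#' ties broken by subject order, sizes n/3 each up to rounding). For each
#' tertile the any-segment and per-segment prevalence is reported.
#'
#' @param data Subject tibble with `age` and per-segment TAC scores.
#' @return Long tibble with `tertile` (1-3), `n`, `measure` (`"any"` or
#'   `"seg1"` ... `"seg5"`), `n_positive`, `pct`.
#' @export
age_tertile_prevalence <- function(data) {
  if (nrow(data) < 3) stop("Need at least 3 subjects for tertiles.",
                           call. = FALSE)
  if (!"age" %in% names(data)) stop("Missing `age` column.", call. = FALSE)
  check_segments_present(data)
  n <- nrow(data)
  r <- order(order(data$age, seq_len(n)))
  bounds <- c(round(n / 3), round(2 * n / 3))
  tert <- findInterval(r, bounds, left.open = TRUE) + 1L
  any_pos <- rowSums(as.matrix(data[seg_cols])) > 0
  purrr::map_dfr(1:3, function(t) {
    sel <- tert == t
    m <- sum(sel)
    meas <- c(list(any = any_pos[sel]),
              stats::setNames(lapply(seg_cols, function(cl) data[[cl]][sel] > 0),
                              paste0("seg", 1:5)))
    np <- unname(vapply(meas, sum, 0L))
    tibble::tibble(
      tertile = t, n = m,
      measure = names(meas),
      n_positive = np,
      pct = round_half_up(100 * np / m)
    )
  })
}

#' Compare the reclassification groups
#'
#' Age and 10-year Framingham risk are compared across the three groups with
#' one-way ANOVA plus Tukey's HSD post hoc test; categorical factors (sex and
#' risk factors) with a chi-square test plus pairwise 2x2 chi-square tests
#' under a Bonferroni correction (factor 3). Significance at p < 0.05.
#'
#' @param data Subject tibble with a `group` column (see [classify_group()]).
#' @param continuous Character vector of continuous variables to compare.
#' @param categorical Named list mapping report labels to logical expressions
#'   of columns; the default compares male sex and the four risk-factor flags.
#' @return An object of class `tac_comparison`; see [tidy.tac_comparison()].
#' @export
group_comparisons <- function(data,
                              continuous = c("age", "frs_pct"),
                              categorical = NULL) {
  if (!"group" %in% names(data)) data <- classify_group(data)
  data$group <- factor(data$group, levels = 1:3)
  gsz <- table(data$group)
  if (any(gsz == 0)) {
    rlang::warn("At least one group is empty; comparisons skipped for it.")
  }
  if (is.null(categorical)) {
    categorical <- list(
      male = data$sex == "male",
      hypertension = data$hypertension,
      hypercholesterolemia = data$hypercholesterolemia,
      smoker = data$smoker,
      diabetes = data$diabetes
    )
    categorical <- categorical[!vapply(categorical, is.null, TRUE)]
  }
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  cont <- purrr::map_dfr(continuous, function(v) {
    if (!v %in% names(data)) return(NULL)
    if (sum(gsz >= 2) < 2) return(NULL)
    fit <- stats::aov(stats::reformulate("group", v), data = data)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$group
    means <- tapply(data[[v]], data$group, mean)
    sds <- tapply(data[[v]], data$group, stats::sd)
    tibble::tibble(
      variable = v, test = "anova",
      statistic = summary(fit)[[1]][["F value"]][1], p_value = p,
      g1 = sprintf("%.1f±%.1f", means[1], sds[1]),
      g2 = sprintf("%.1f±%.1f", means[2], sds[2]),
      g3 = sprintf("%.1f±%.1f", means[3], sds[3]),
      p_12 = tk["2-1", "p adj"], p_13 = tk["3-1", "p adj"],
      p_23 = tk["3-2", "p adj"]
    )
  })
  cat_ <- purrr::map_dfr(names(categorical), function(v) {
    flag <- categorical[[v]]
    tab <- table(data$group, factor(flag, levels = c(FALSE, TRUE)))
    ct <- suppressWarnings(stats::chisq.test(tab))
    pw <- vapply(pairs, function(pr) {
      sub <- tab[as.character(pr), , drop = FALSE]
      min(suppressWarnings(stats::chisq.test(sub))$p.value * 3, 1)
    }, 0)
    cnt <- tab[, "TRUE"]
    tibble::tibble(
      variable = v, test = "chi-square",
      statistic = unname(ct$statistic), p_value = ct$p.value,
      g1 = sprintf("%d (%d%%)", cnt[1], round_half_up(100 * cnt[1] / gsz[1])),
      g2 = sprintf("%d (%d%%)", cnt[2], round_half_up(100 * cnt[2] / gsz[2])),
      g3 = sprintf("%d (%d%%)", cnt[3], round_half_up(100 * cnt[3] / gsz[3])),
      p_12 = pw[1], p_13 = pw[2], p_23 = pw[3]
    )
  })
  structure(
    list(continuous = cont, categorical = cat_,
         group_n = as.integer(gsz),
         group_pct = round_half_up(100 * as.integer(gsz) / nrow(data)),
         n = nrow(data)),
    class = "tac_comparison"
  )
}

#' @export
print.tac_comparison <- function(x, ...) {
  cat(sprintf("Reclassification group comparison (n = %d)\n", x$n))
  cat(sprintf("  Group sizes: %s  (%s%%)\n",
              paste(x$group_n, collapse = " / "),
              paste(x$group_pct, collapse = " / ")))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `tac_comparison` from [group_comparisons()].
#' @param ... Unused.
#' @return A tibble with one row per compared variable: per-group summaries,
#'   the omnibus statistic and p value, and the three pairwise post-hoc p
#'   values (Tukey HSD for continuous, Bonferroni-corrected chi-square for
#'   categorical variables).
#' @method tidy tac_comparison
#' @export
tidy.tac_comparison <- function(x, ...) {
  dplyr::bind_rows(x$continuous, x$categorical)
}

#' Glance at a group comparison
#'
#' @inheritParams tidy.tac_comparison
#' @return A one-row tibble with cohort and group sizes and the number of
#'   significant variables at p < 0.05.
#' @method glance tac_comparison
#' @export
glance.tac_comparison <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n = x$n, n_group1 = x$group_n[1], n_group2 = x$group_n[2],
    n_group3 = x$group_n[3],
    n_significant = sum(td$p_value < 0.05)
  )
}

#' Empirical type-I error of the group ANOVA
#'
#' Draws all three groups from one normal distribution and records how often
#' the one-way ANOVA rejects at the nominal level — a calibration check that
#' the omnibus test keeps its size at the cohort's group-size pattern.
#'
#' @param n_sims Number of null simulations.
#' @param group_n Group sizes.
#' @param alpha Nominal level.
#' @param seed Integer seed.
#' @return Rejection rate (scalar in `[0, 1]`).
#' @export
anova_type1_rate <- function(n_sims = 1000, group_n = c(211, 648, 111),
                             alpha = 0.05, seed = 1L) {
  set.seed(seed)
  g <- factor(rep(seq_along(group_n), group_n))
  rej <- vapply(seq_len(n_sims), function(i) {
    y <- stats::rnorm(sum(group_n))
    fit <- stats::aov(y ~ g)
    summary(fit)[[1]][["Pr(>F)"]][1] < alpha
  }, TRUE)
  mean(rej)
}
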