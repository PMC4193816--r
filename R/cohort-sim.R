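#' Synthetic cohort specification
#'
#' Describes a cohort of subjects with coronary (CAC) and per-segment thoracic
#' aorta (TAC) calcium, clinical covariates and per-segment lesion counts.
#' Two construction modes are supported:
#'
#' * `"exact-marginal"` — a deterministic construction whose marginal counts
#'   (extended/standard TAC positives, CAC positives, joint counts,
#'   reclassification group sizes, per-segment positives, age-tertile
#'   positives, per-segment lesion totals, and per-group covariate counts)
#'   equal the requested integers exactly; subject order is then shuffled
#'   with the seed.
#' * `"stochastic"` — independent sampling of each subject from the prevalence
#'   targets, with an optional age-dependence hook on segment positivity.
#'
#' The default counts describe a primary-prevention screening cohort of 970
#' subjects (77% men, age 57 +/- 9) in which extending the scan over the arch
#' raises TAC detection from 31% to 64% of subjects.
#'
#' @param n Number of subjects.
#' @param mode `"exact-marginal"` or `"stochastic"`.
#' @param male_fraction,age_mean,age_sd Marginal demographics (stochastic
#'   mode; exact mode uses the per-group values in `exact`).
#' @param risk_prevalence Named list of risk-factor prevalences in `[0,1]`:
#'   `hypertension`, `hypercholesterolemia`, `smoker`, `diabetes`.
#' @param seg_prevalence Length-5 vector of per-segment TAC prevalence targets.
#' @param cac_prevalence CAC prevalence target.
#' @param age_beta Log-odds slope of segment positivity per SD of age
#'   (stochastic mode hook; 0 = age-independent).
#' @param score_meanlog,score_sdlog Log-normal parameters of positive
#'   per-segment TAC scores.
#' @param cac_meanlog,cac_sdlog Log-normal parameters of positive CAC scores.
#' @param exact List of exact-marginal counts; see [cohort_exact_defaults()].
#' @param seed Integer seed governing all randomness.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 970L,
                        mode = c("exact-marginal", "stochastic"),
                        male_fraction = 754 / 970,
                        age_mean = 57, age_sd = 9,
                        risk_prevalence = list(
                          hypertension = 476 / 970,
                          hypercholesterolemia = 796 / 970,
                          smoker = 524 / 970,
                          diabetes = 83 / 970
                        ),
                        seg_prevalence = c(39, 116, 407, 534, 296) / 970,
                        cac_prevalence = 598 / 970,
                        age_beta = 0,
                        score_meanlog = log(140), score_sdlog = 1.6,
                        cac_meanlog = log(65), cac_sdlog = 1.6,
                        exact = cohort_exact_defaults(),
                        seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  prevs <- c(unlist(risk_prevalence), seg_prevalence, cac_prevalence,
             male_fraction)
  if (any(prevs < 0 | prevs > 1)) {
    stop("All prevalences must lie in [0, 1].", call. = FALSE)
  }
  spec <- structure(
    list(n = as.integer(n), mode = mode, male_fraction = male_fraction,
         age_mean = age_mean, age_sd = age_sd,
         risk_prevalence = risk_prevalence,
         seg_prevalence = seg_prevalence, cac_prevalence = cac_prevalence,
         age_beta = age_beta,
         score_meanlog = score_meanlog, score_sdlog = score_sdlog,
         cac_meanlog = cac_meanlog, cac_sdlog = cac_sdlog,
         exact = exact, seed = as.integer(seed)),
    class = "cohort_spec"
  )
  if (mode == "exact-marginal") validate_exact_counts(spec)
  spec
}

#' Default exact-marginal cohort counts
#'
#' The integer marginals of the default screening cohort: joint CAC/TAC
#' detection counts, the three reclassification groups (free of calcium /
#' detected by the standard method / detected only by the extended method)
#' with their covariate counts, per-segment positive counts, per-age-tertile
#' positive counts, and per-segment lesion totals.
#'
#' @return A named list of counts.
#' @export
cohort_exact_defaults <- function() {
  list(
    ext_pos = 618L,          # extended TAC > 0
    std_pos = 296L,          # standard TAC (segments 1 + 5) > 0
    cac_pos = 598L,          # CAC > 0
    both_pos = 457L,         # CAC > 0 and extended TAC > 0
    neither = 211L,          # CAC = 0 and extended TAC = 0
    seg_counts = c(39L, 116L, 407L, 534L, 296L),
    group_counts = c(211L, 648L, 111L),
    tertile_pos = c(122L, 209L, 287L),
    lesion_totals = c(412L, 371L, 2803L, 3824L, 3421L),
    group_age = list(c(50, 8), c(59, 8), c(55, 8)),
    group_male = c(167L, 527L, 60L),
    group_hypertension = c(80L, 354L, 42L),
    group_hypercholesterolemia = c(146L, 561L, 89L),
    group_diabetes = c(19L, 54L, 10L),
    group_smoker = c(104L, 371L, 49L)
  )
}

validate_exact_counts <- function(spec) {
  e <- spec$exact; n <- spec$n
  fail <- function(msg) stop("Inconsistent exact-marginal counts: ", msg,
                             call. = FALSE)
  if (e$std_pos > e$ext_pos) fail("std_pos > ext_pos (standard-positive must be a subset of extended-positive)")
  if (e$both_pos > min(e$ext_pos, e$cac_pos)) fail("both_pos > min(ext_pos, cac_pos)")
  if (e$neither != n - e$ext_pos - (e$cac_pos - e$both_pos)) {
    fail(sprintf("neither (%d) != n - ext_pos - cac_only (%d)",
                 e$neither, n - e$ext_pos - (e$cac_pos - e$both_pos)))
  }
  if (sum(e$group_counts) != n) fail("group counts do not sum to n")
  if (e$group_counts[1] != e$neither) fail("group 1 count != neither count")
  g3 <- e$group_counts[3]
  if (g3 > e$ext_pos - e$both_pos) fail("group 3 count > CAC-free extended positives")
  sc <- e$seg_counts
  if (max(sc[1], sc[5]) > e$std_pos) fail("segment 1/5 count > std_pos")
  if (sc[1] + sc[5] < e$std_pos) fail("seg1 + seg5 counts < std_pos (cannot cover the standard positives)")
  if (sum(sc[2:4]) < e$ext_pos - e$std_pos) fail("segments 2-4 counts cannot cover the extended-only positives")
  if (any(sc > e$ext_pos)) fail("a segment count exceeds ext_pos")
  if (sum(e$tertile_pos) != e$ext_pos) fail("tertile positives do not sum to ext_pos")
  if (any(e$lesion_totals < sc)) fail("fewer lesions than positive subjects in a segment")
  invisible(TRUE)
}

#' Generate a synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject: demographics, risk factors,
#'   CAC score, per-segment TAC scores (`tac_seg1` ... `tac_seg5`),
#'   per-segment lesion counts, and the derived columns added by
#'   [derive_tac()], [classify_group()] and [framingham_risk()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  df <- if (spec$mode == "exact-marginal") {
    cohort_exact(spec)
  } else {
    cohort_stochastic(spec)
  }
  df <- derive_tac(df)
  df <- classify_group(df)
  df <- framingham_risk(df)
  df
}

# deterministic exact-marginal construction (see cohort_spec docs)
cohort_exact <- function(spec) {
  e <- spec$exact; n <- spec$n
  ext <- e$ext_pos; std <- e$std_pos; sc <- e$seg_counts
  g3 <- e$group_counts[3]

  seg_pos <- matrix(FALSE, n, 5)
  # standard-scan segments: s5 on subjects 1..c5, s1 on the tail of 1..std so
  # that together they cover exactly the standard positives 1..std
  if (sc[5] > 0) seg_pos[seq_len(sc[5]), 5] <- TRUE
  if (sc[1] > 0) seg_pos[(std - sc[1] + 1):std, 1] <- TRUE
  # arch-region segments: cover the extended-only subjects first (largest
  # segment first), then spend the remaining quota from the top of the list
  uncovered <- if (ext > std) (std + 1):ext else integer(0)
  for (sgi in c(4L, 3L, 2L)) {
    quota <- sc[sgi]
    take <- utils::head(uncovered, min(quota, length(uncovered)))
    seg_pos[take, sgi] <- TRUE
    uncovered <- setdiff(uncovered, take)
    rest <- quota - length(take)
    if (rest > 0) {
      cand <- which(!seg_pos[seq_len(ext), sgi])
      seg_pos[utils::head(cand, rest), sgi] <- TRUE
    }
  }
  if (length(uncovered) > 0) {
    stop("Inconsistent exact-marginal counts: segments 2-4 cannot cover all ",
         "extended-only positives.", call. = FALSE)
  }

  cac_pos <- rep(FALSE, n)
  a <- (ext - e$both_pos) - g3          # CAC-free standard positives
  if (a < 0) stop("Inconsistent exact-marginal counts: group 3 exceeds the ",
                  "CAC-free extended positives.", call. = FALSE)
  cac_pos[seq_len(ext)] <- TRUE
  if (a > 0) cac_pos[seq_len(a)] <- FALSE
  if (g3 > 0) cac_pos[(std + 1):(std + g3)] <- FALSE
  n_cac_only <- e$cac_pos - e$both_pos
  if (n_cac_only > 0) cac_pos[ext + seq_len(n_cac_only)] <- TRUE

  grp <- rep(2L, n)
  if (g3 > 0) grp[(std + 1):(std + g3)] <- 3L
  if (e$neither > 0) grp[(ext + n_cac_only + 1):n] <- 1L

  # per-group covariates: flags assigned by rotated position blocks so the
  # flags are not mutually degenerate
  male <- hyp <- chol <- diab <- smok <- rep(FALSE, n)
  assign_flag <- function(flag, counts, offset_frac) {
    for (g in 1:3) {
      members <- which(grp == g)
      m <- length(members); k <- counts[g]
      if (k == 0) next
      off <- floor(offset_frac * m)
      pos <- ((off + seq_len(k) - 1) %% m) + 1
      flag[members[pos]] <- TRUE
    }
    flag
  }
  male <- assign_flag(male, e$group_male, 0)
  hyp <- assign_flag(hyp, e$group_hypertension, 0.2)
  chol <- assign_flag(chol, e$group_hypercholesterolemia, 0.4)
  diab <- assign_flag(diab, e$group_diabetes, 0.6)
  smok <- assign_flag(smok, e$group_smoker, 0.8)

  # ages: per-group normal quantiles, then exact repair of the age-tertile
  # positive counts by swapping ages between a positive subject in a surplus
  # tertile and a negative subject in a deficit tertile (the age multiset,
  # hence the tertile boundaries, is invariant under the swaps)
  age <- numeric(n)
  for (g in 1:3) {
    members <- which(grp == g)
    pars <- e$group_age[[g]]
    age[members] <- stats::qnorm(stats::ppoints(length(members)),
                                 pars[1], pars[2])
  }
  ext_flag <- rowSums(seg_pos) > 0
  age <- repair_tertiles(age, ext_flag, e$tertile_pos)

  # covariate magnitudes (seeded; marginal counts above stay exact)
  set.seed(spec$seed + 1L)
  sbp <- round(stats::rnorm(n, 124 + 22 * hyp, 10))
  dbp <- round(sbp - 45 + stats::rnorm(n, 0, 5))
  tc <- round(stats::rnorm(n, 5.3 + 0.9 * chol, 0.7), 2)
  hdl <- round(pmax(stats::rnorm(n, 1.25 + 0.2 * (!male), 0.25), 0.6), 2)
  ldl <- round(pmax(tc - hdl - 0.5, 0.5), 2)

  # scores and lesion counts
  scores <- matrix(0, n, 5)
  set.seed(spec$seed + 2L)
  for (sgi in 1:5) {
    pos <- which(seg_pos[, sgi])
    scores[pos, sgi] <- round(stats::qlnorm(stats::runif(length(pos)),
                                            spec$score_meanlog,
                                            spec$score_sdlog), 1)
    scores[pos, sgi] <- pmax(scores[pos, sgi], 0.1)  # strictly positive
  }
  cac <- rep(0, n)
  pos <- which(cac_pos)
  cac[pos] <- pmax(round(stats::qlnorm(stats::runif(length(pos)),
                                       spec$cac_meanlog, spec$cac_sdlog), 1),
                   0.1)
  nles <- matrix(0L, n, 5)
  for (sgi in 1:5) {
    pos <- which(seg_pos[, sgi])
    m <- length(pos)
    if (m == 0) next
    total <- e$lesion_totals[sgi]
    base <- total %/% m; extra <- total %% m
    nles[pos, sgi] <- base + (seq_len(m) <= extra)
  }

  df <- tibble::tibble(
    id = seq_len(n),
    sex = ifelse(male, "male", "female"),
    age = age, sbp = sbp, dbp = dbp,
    tc_mmol = tc, hdl_mmol = hdl, ldl_mmol = ldl,
    hypertension = hyp, hypercholesterolemia = chol,
    smoker = smok, diabetes = diab,
    cac = cac,
    tac_seg1 = scores[, 1], tac_seg2 = scores[, 2], tac_seg3 = scores[, 3],
    tac_seg4 = scores[, 4], tac_seg5 = scores[, 5],
    lesions_seg1 = nles[, 1], lesions_seg2 = nles[, 2],
    lesions_seg3 = nles[, 3], lesions_seg4 = nles[, 4],
    lesions_seg5 = nles[, 5]
  )
  # shuffle subject order with the seed, then relabel ids
  set.seed(spec$seed)
  df <- df[sample.int(n), ]
  df$id <- seq_len(n)
  df
}

# swap ages between tertiles until the per-tertile positive counts match
repair_tertiles <- function(age, pos, target) {
  n <- length(age)
  bounds <- c(round(n / 3), round(2 * n / 3))
  tert_of <- function(age) {
    r <- order(order(age, seq_len(n)))   # rank with ties broken by index
    findInterval(r, c(bounds[1], bounds[2]), left.open = TRUE) + 1L
  }
  for (iter in seq_len(4L * n)) {
    tert <- tert_of(age)
    cnt <- vapply(1:3, function(t) sum(pos & tert == t), 0L)
    if (all(cnt == target)) return(age)
    a <- which(cnt > target)[1]          # surplus tertile
    b <- which(cnt < target)[1]          # deficit tertile
    # move one positive from a to b: swap its age with a negative in b whose
    # age is closest to the a/b boundary (minimal distortion)
    ia <- which(pos & tert == a); ib <- which(!pos & tert == b)
    if (length(ib) == 0) stop("Cannot repair age tertiles: no negative ",
                              "subject available in the deficit tertile.",
                              call. = FALSE)
    pick_a <- ia[which.max(if (b > a) age[ia] else -age[ia])]
    pick_b <- ib[which.max(if (b > a) -age[ib] else age[ib])]
    tmp <- age[pick_a]; age[pick_a] <- age[pick_b]; age[pick_b] <- tmp
  }
  stop("Age-tertile repair did not converge.", call. = FALSE)
}

cohort_stochastic <- function(spec) {
  n <- spec$n
  set.seed(spec$seed)
  male <- stats::runif(n) < spec$male_fraction
  age <- stats::rnorm(n, spec$age_mean, spec$age_sd)
  rp <- spec$risk_prevalence
  hyp <- stats::runif(n) < rp$hypertension
  chol <- stats::runif(n) < rp$hypercholesterolemia
  smok <- stats::runif(n) < rp$smoker
  diab <- stats::runif(n) < rp$diabetes
  sbp <- round(stats::rnorm(n, 124 + 22 * hyp, 10))
  dbp <- round(sbp - 45 + stats::rnorm(n, 0, 5))
  tc <- round(stats::rnorm(n, 5.3 + 0.9 * chol, 0.7), 2)
  hdl <- round(pmax(stats::rnorm(n, 1.25 + 0.2 * (!male), 0.25), 0.6), 2)
  ldl <- round(pmax(tc - hdl - 0.5, 0.5), 2)
  zage <- (age - spec$age_mean) / spec$age_sd
  scores <- matrix(0, n, 5)
  nles <- matrix(0L, n, 5)
  for (sgi in 1:5) {
    p <- spec$seg_prevalence[sgi]
    pi <- if (p %in% c(0, 1) || spec$age_beta == 0) rep(p, n) else {
      stats::plogis(stats::qlogis(p) + spec$age_beta * zage)
    }
    pos <- stats::runif(n) < pi
    scores[pos, sgi] <- pmax(round(stats::rlnorm(sum(pos), spec$score_meanlog,
                                                 spec$score_sdlog), 1), 0.1)
    nles[pos, sgi] <- 1L + stats::rpois(sum(pos), 5)
  }
  cac <- rep(0, n)
  cpos <- stats::runif(n) < spec$cac_prevalence
  cac[cpos] <- pmax(round(stats::rlnorm(sum(cpos), spec$cac_meanlog,
                                        spec$cac_sdlog), 1), 0.1)
  tibble::tibble(
    id = seq_len(n),
    sex = ifelse(male, "male", "female"),
    age = age, sbp = sbp, dbp = dbp,
    tc_mmol = tc, hdl_mmol = hdl, ldl_mmol = ldl,
    hypertension = hyp, hypercholesterolemia = chol,
    smoker = smok, diabetes = diab,
    cac = cac,
    tac_seg1 = scores[, 1], tac_seg2 = scores[, 2], tac_seg3 = scores[, 3],
    tac_seg4 = scores[, 4], tac_seg5 = scores[, 5],
    lesions_seg1 = nles[, 1], lesions_seg2 = nles[, 2],
    lesions_seg3 = nles[, 3], lesions_seg4 = nles[, 4],
    lesions_seg5 = nles[, 5]
  )
}
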