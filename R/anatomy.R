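#' Anatomical landmark set
#'
#' The four user-indicated landmarks bounding the five thoracic-aorta
#' segments: left main coronary artery (LMCA), right and left subclavian
#' arteries (RSA, LSA) and the coronary sinus (CS), as world-mm positions.
#'
#' @param LMCA,RSA,LSA,CS World-mm positions (length-3 numeric).
#' @return A named list of class `landmark_set`.
#' @export
landmark_set <- function(LMCA, RSA, LSA, CS) {
  lm <- list(LMCA = as.numeric(LMCA), RSA = as.numeric(RSA),
             LSA = as.numeric(LSA), CS = as.numeric(CS))
  if (any(vapply(lm, length, 0L) != 3)) {
    stop("Each landmark must be a world-mm position of length 3.", call. = FALSE)
  }
  structure(lm, class = "landmark_set")
}

#' Project a landmark onto the centerline
#'
#' Returns the arc length of the centerline point closest (Euclidean) to the
#' landmark; ties break toward the proximal point. A landmark farther than
#' 5 cm from the centerline triggers a warning (implausible placement).
#'
#' @param centerline A centerline tibble.
#' @param point World-mm position.
#' @return Arc length (mm) of the nearest centerline point.
#' @export
project_landmark <- function(centerline, point) {
  stopifnot(nrow(centerline) > 0, length(point) == 3)
  P <- as.matrix(centerline[, c("x", "y", "z")])
  d2 <- rowSums(sweep(P, 2, as.numeric(point))^2)
  i <- which.min(d2)   # which.min returns the first (proximal) minimizer
  if (sqrt(d2[i]) > 50) {
    rlang::warn(sprintf(
      "Landmark is %.0f mm from the centerline; placement looks implausible.",
      sqrt(d2[i])), class = "aortacalc_implausible_landmark")
  }
  centerline$arc_mm[i]
}

#' Divide the centerline into the five anatomical segments
#'
#' Partitions the centerline arc length into five contiguous labelled
#' intervals. Proximal to distal the boundaries are: the LMCA projection
#' (start); the seed-pair axial level on the ascending limb (1|2); the RSA
#' projection (2|3); the LSA projection (3|4); the CS axial level projected
#' onto the descending limb (4|5); and the distal terminus. Segments 1 and 5
#' thereby coincide with the coverage of a standard cardiac scan, while
#' segments 2-4 are the arch region that only the extended scan sees.
#' Boundary points belong to the distal segment.
#'
#' @param centerline A centerline tibble (must start at the LMCA level).
#' @param landmarks A [landmark_set()].
#' @param seed_z Axial level (world z, mm) of the tracking seed pair; by
#'   default taken from the centerline's `seed_z` attribute.
#' @return A `tac_segments` tibble: `segment` (1-5), `start_mm`, `end_mm`,
#'   `length_cm`.
#' @export
divide_segments <- function(centerline, landmarks, seed_z = NULL) {
  stopifnot(inherits(landmarks, "landmark_set"), nrow(centerline) >= 6)
  if (is.null(seed_z)) seed_z <- attr(centerline, "seed_z")
  if (is.null(seed_z)) {
    stop("`seed_z` is required (no seed level recorded on the centerline).",
         call. = FALSE)
  }
  total <- max(centerline$arc_mm)
  b23 <- project_landmark(centerline, landmarks$RSA)
  b34 <- project_landmark(centerline, landmarks$LSA)
  # 1|2: seed level on the ascending limb = proximal-most point at that level;
  # 4|5: CS level on the descending limb = distal-most point at that level
  asc_half <- centerline[centerline$arc_mm <= b23, ]
  i12 <- which.min(abs(asc_half$z - seed_z))
  b12 <- asc_half$arc_mm[i12]
  desc_half <- centerline[centerline$arc_mm >= b34, ]
  i45 <- which.min(abs(desc_half$z - landmarks$CS[3]))
  b45 <- desc_half$arc_mm[i45]
  b <- c(0, b12, b23, b34, b45, total)
  if (any(diff(b) <= 0)) {
    bad <- which(diff(b) <= 0)[1]
    nm <- c("start", "1|2", "2|3", "3|4", "4|5", "end")
    stop(sprintf(
      "Segment boundaries are not strictly increasing: %s (%.1f mm) >= %s (%.1f mm).",
      nm[bad], b[bad], nm[bad + 1], b[bad + 1]), call. = FALSE)
  }
  out <- tibble::tibble(
    segment = 1:5,
    start_mm = b[1:5],
    end_mm = b[2:6],
    length_cm = diff(b) / 10
  )
  class(out) <- c("tac_segments", class(tibble::tibble()))
  out
}

#' Segment lengths in cm
#'
#' @param segments A `tac_segments` tibble from [divide_segments()].
#' @return Named numeric vector of the five segment lengths (cm), the per-cm
#'   normalizer of the cohort lesion-density statistics.
#' @export
segment_lengths <- function(segments) {
  stopifnot(nrow(segments) == 5)
  stats::setNames(segments$length_cm, paste0("seg", segments$segment))
}

# segment id containing an arc length (boundaries belong to the distal side)
arc_to_segment <- function(arc_mm, segments) {
  b <- c(segments$start_mm[1], segments$end_mm)
  idx <- findInterval(arc_mm, b[2:5]) + 1L
  pmin(pmax(idx, 1L), 5L)
}
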