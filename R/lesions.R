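#' Detect calcium candidate lesions
#'
#' Candidate calcifications are the 26-connected 3D components of voxels at
#' or above the calcium threshold (130 HU by convention). Components whose
#' maximal single-slice area falls below `min_area_mm2` (1 mm^2, the
#' classical operational minimum) are discarded.
#'
#' @param vol A [ct_volume()] calibrated in HU.
#' @param threshold Calcium threshold, HU.
#' @param min_area_mm2 Minimum single-slice area for a candidate.
#' @return A tibble with one row per candidate: `lesion`, `n_voxels`,
#'   `volume_mm3`, `peak_hu`, centroid (`x`, `y`, `z`, world mm), `agatston`,
#'   `state` (`"candidate"`), and a `slices` list-column holding the
#'   per-axial-slice areas (mm^2) and peak HU.
#' @export
detect_candidates <- function(vol, threshold = 130, min_area_mm2 = 1) {
  stopifnot(inherits(vol, "ct_volume"))
  d <- dim(vol$data)
  idx <- which(vol$data >= threshold)
  empty <- tibble::tibble(
    lesion = integer(), n_voxels = integer(), volume_mm3 = double(),
    peak_hu = double(), x = double(), y = double(), z = double(),
    agatston = double(), state = character(), slices = list()
  )
  if (length(idx) == 0) return(empty)
  coords <- arrayInd(idx, d)
  # undirected 26-connectivity: 13 half-space neighbour offsets
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), , drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (o in seq_len(nrow(offs))) {
    nc <- coords + matrix(offs[o, ], nrow(coords), 3, byrow = TRUE)
    ok <- nc[, 1] >= 1 & nc[, 1] <= d[1] &
          nc[, 2] >= 1 & nc[, 2] <= d[2] &
          nc[, 3] >= 1 & nc[, 3] <= d[3]
    nlin <- (nc[, 3] - 1) * d[1] * d[2] + (nc[, 2] - 1) * d[1] + nc[, 1]
    m <- match(nlin, idx)
    hit <- ok & !is.na(m)
    from <- c(from, which(hit)); to <- c(to, m[hit])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  px_area <- vol$spacing[1] * vol$spacing[2]
  vox_vol <- prod(vol$spacing)
  hu <- vol$data[idx]
  W <- index_to_world(vol, coords)
  rows <- lapply(seq_len(max(comp)), function(ci) {
    sel <- comp == ci
    ks <- coords[sel, 3]
    hus <- hu[sel]
    sl <- tibble::tibble(k = sort(unique(ks)))
    sl$z_mm <- slice_z(vol, sl$k)
    sl$area_mm2 <- vapply(sl$k, function(k) sum(ks == k) * px_area, 0)
    sl$peak_hu <- vapply(sl$k, function(k) max(hus[ks == k]), 0)
    if (max(sl$area_mm2) < min_area_mm2) return(NULL)
    tibble::tibble(
      n_voxels = sum(sel),
      volume_mm3 = sum(sel) * vox_vol,
      peak_hu = max(hus),
      x = mean(W[sel, 1]), y = mean(W[sel, 2]), z = mean(W[sel, 3]),
      agatston = agatston_score(sl),
      state = "candidate",
      slices = list(sl)
    )
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty)
  out <- dplyr::bind_rows(rows)
  out$lesion <- seq_len(nrow(out))
  out[, c("lesion", "n_voxels", "volume_mm3", "peak_hu", "x", "y", "z",
          "agatston", "state", "slices")]
}

#' Agatston score of one lesion
#'
#' The classical per-slice rule: for every axial slice the lesion touches,
#' its area on that slice (mm^2) times a weight of 1/2/3/4 set by the
#' slice-peak HU band (130-199 / 200-299 / 300-399 / >= 400), summed over
#' slices. Scores are computed on the native slices with no slice-thickness
#' rescaling.
#'
#' @param slices A per-slice tibble with columns `area_mm2` and `peak_hu`
#'   (as stored in the `slices` list-column of [detect_candidates()]).
#' @return The Agatston score (numeric scalar; 0 for an empty lesion).
#' @export
agatston_score <- function(slices) {
  if (is.null(slices) || nrow(slices) == 0) return(0)
  stopifnot(all(c("area_mm2", "peak_hu") %in% names(slices)))
  sum(slices$area_mm2 * agatston_weight(slices$peak_hu))
}

#' Validate candidate lesions against the vessel geometry
#'
#' Automated surrogate of the interactive validation step (in the original
#' workflow the reader clicks each highlighted candidate): a candidate is
#' accepted when its centroid lies within `margin` times the local lumen
#' radius of the nearest centerline point — aortic wall calcifications pass,
#' while vertebral, rib or coronary-root calcium farther from the axis is
#' rejected.
#'
#' @param candidates Candidate tibble from [detect_candidates()].
#' @param centerline A centerline tibble with local diameters.
#' @param margin Acceptance margin as a multiple of the local lumen radius.
#' @return The candidate tibble with `state` set to `"accepted"` or
#'   `"rejected"` and columns `dist_mm` (centroid-to-centerline distance) and
#'   `arc_mm` (arc length of the nearest centerline point).
#' @export
validate_lesions <- function(candidates, centerline, margin = 1.5) {
  if (nrow(candidates) == 0) {
    candidates$dist_mm <- double(); candidates$arc_mm <- double()
    return(candidates)
  }
  stopifnot(nrow(centerline) > 0)
  P <- as.matrix(centerline[, c("x", "y", "z")])
  C <- as.matrix(candidates[, c("x", "y", "z")])
  near <- vapply(seq_len(nrow(C)), function(i) {
    d2 <- rowSums(sweep(P, 2, C[i, ])^2)
    j <- which.min(d2)
    c(sqrt(d2[j]), centerline$arc_mm[j], centerline$diameter_mm[j] / 2)
  }, numeric(3))
  candidates$dist_mm <- near[1, ]
  candidates$arc_mm <- near[2, ]
  candidates$state <- ifelse(candidates$dist_mm <= margin * near[3, ],
                             "accepted", "rejected")
  candidates
}

#' Assign lesions to anatomical segments
#'
#' Each lesion centroid is orthogonally projected onto the centerline (its
#' nearest centerline point) and the lesion is associated with the segment
#' whose arc-length interval contains that projection; hits exactly on a
#' boundary go to the distal segment.
#'
#' @param lesions Validated lesion tibble (with `arc_mm` from
#'   [validate_lesions()]; it is computed here if absent).
#' @param centerline A centerline tibble.
#' @param segments A `tac_segments` tibble from [divide_segments()].
#' @return The lesion tibble with an integer `segment` column.
#' @export
assign_segment <- function(lesions, centerline, segments) {
  if (nrow(lesions) == 0) { lesions$segment <- integer(); return(lesions) }
  if (!"arc_mm" %in% names(lesions)) {
    lesions <- validate_lesions(lesions, centerline, margin = Inf)
  }
  lesions$segment <- arc_to_segment(lesions$arc_mm, segments)
  lesions
}

#' Accumulate per-segment Agatston scores
#'
#' @param lesions Assigned lesion tibble (only rows with
#'   `state == "accepted"` are counted; pass a pre-filtered table to override).
#' @param segments A `tac_segments` tibble (defines the five segment labels).
#' @return A `tac_scores` tibble with one row per segment: `segment`,
#'   `n_lesions`, `agatston`; the `total` attribute carries the summed score
#'   (equal to the sum of the five rows by construction).
#' @export
accumulate_scores <- function(lesions, segments) {
  acc <- lesions[lesions$state %in% c("accepted", "candidate"), ]
  out <- tibble::tibble(segment = 1:5, n_lesions = 0L, agatston = 0)
  if (nrow(acc) > 0) {
    stopifnot(!any(is.na(acc$segment)))
    agg <- dplyr::count(acc, .data$segment, wt = NULL, name = "n")
    sums <- stats::aggregate(acc$agatston, by = list(segment = acc$segment), sum)
    out$n_lesions[agg$segment] <- agg$n
    out$agatston[sums$segment] <- sums$x
  }
  attr(out, "total") <- sum(out$agatston)
  class(out) <- c("tac_scores", class(tibble::tibble()))
  out
}
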