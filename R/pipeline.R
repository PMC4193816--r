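#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis — phantom geometry,
#' tracking numerics, detection and validation thresholds, reporting options
#' and the master seed — into one serializable object. All numeric choices
#' are surfaced here; nothing is hard-coded downstream.
#'
#' @param n_subjects Number of synthetic subjects to image and score.
#' @param grid_dim,grid_spacing Phantom grid (voxels) and spacing (mm).
#' @param lesions_per_subject Mean number of wall lesions per subject
#'   (Poisson; at least 0).
#' @param lesion_hu_range,lesion_size_range Uniform ranges for lesion HU and
#'   in-plane extent (mm).
#' @param noise_sd Background noise sd (HU).
#' @param tracking A [tracking_config()].
#' @param validation_margin Acceptance margin of [validate_lesions()].
#' @param volume_paths Optional character vector of pre-existing NIfTI
#'   volumes to analyse instead of generating phantoms; all paths must exist
#'   at run start.
#' @param seed Master seed; all per-subject randomness derives from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 3,
                            grid_dim = c(128, 128, 44),
                            grid_spacing = c(1, 1, 2.5),
                            lesions_per_subject = 4,
                            lesion_hu_range = c(150, 500),
                            lesion_size_range = c(2, 4),
                            noise_sd = 5,
                            tracking = tracking_config(),
                            validation_margin = 1.5,
                            volume_paths = NULL,
                            seed = 1L) {
  cfg <- structure(
    list(n_subjects = as.integer(n_subjects),
         grid_dim = as.integer(grid_dim),
         grid_spacing = as.numeric(grid_spacing),
         lesions_per_subject = lesions_per_subject,
         lesion_hu_range = lesion_hu_range,
         lesion_size_range = lesion_size_range,
         noise_sd = noise_sd,
         tracking = tracking,
         validation_margin = validation_margin,
         volume_paths = volume_paths,
         seed = as.integer(seed),
         version = as.character(utils::packageVersion("aortacalc"))),
    class = "pipeline_config"
  )
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (!is.null(cfg$volume_paths)) {
    missing <- cfg$volume_paths[!file.exists(cfg$volume_paths)]
    if (length(missing)) {
      stop("Configured volume path(s) do not exist: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  stopifnot(cfg$n_subjects >= 1, cfg$validation_margin > 0)
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [pipeline_config()] (`tracking:` holds [tracking_config()] arguments).
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("Config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  tr <- do.call(tracking_config, y$tracking %||% list())
  y$tracking <- NULL
  do.call(pipeline_config, c(y, list(tracking = tr)))
}

# geometry scaled to an arbitrary grid: arch radius and lumen diameter sized
# from the grid extent so the tube always fits
scaled_phantom_spec <- function(cfg, subject_seed, lesions = list()) {
  ext <- (cfg$grid_dim - 1) * cfg$grid_spacing
  R <- min(0.16 * ext[1], 30)
  dia <- min(0.9 * R, 28)
  ztop <- 0.95 * ext[3] - R - dia / 2
  phantom_spec(
    dim = cfg$grid_dim, spacing = cfg$grid_spacing,
    arch_center = c(ext[1] / 2, ext[2] / 2, ztop),
    arch_radius_mm = R, diameter_mm = dia,
    asc_bottom_z = 0.45 * ext[3],
    desc_bottom_z = dia / 2 + 1.5 * cfg$grid_spacing[3],
    seed_level_mm = 0.45 * ext[3] + 0.6 * (ztop - 0.45 * ext[3]),
    noise_sd = cfg$noise_sd, lesions = lesions, seed = subject_seed
  )
}

# seeded per-subject wall lesions along the path
subject_lesions <- function(cfg, spec0, subject_seed) {
  set.seed(subject_seed)
  n <- stats::rpois(1, cfg$lesions_per_subject)
  if (n == 0) return(list())
  total <- path_total_length(spec0)
  s <- stats::runif(n, 0.05 * total, 0.95 * total)
  ang <- stats::runif(n, 0, 2 * pi)
  hu <- stats::runif(n, cfg$lesion_hu_range[1], cfg$lesion_hu_range[2])
  sz <- stats::runif(n, cfg$lesion_size_range[1], cfg$lesion_size_range[2])
  lapply(seq_len(n), function(i) {
    wall_lesion(spec0, s[i], ang[i],
                extents = c(sz[i], sz[i], max(sz[i], spec0$spacing[3])),
                hu = hu[i], id = i)
  })
}

#' Run the end-to-end synthetic pipeline
#'
#' For each subject: generate a phantom volume (or read a configured one),
#' extract the centerline from the seed pair, partition it into the five
#' segments from the landmarks, detect, validate, score and assign lesions,
#' and accumulate per-segment Agatston scores; then assemble the cohort-level
#' report (detection summary, per-segment prevalence, lesion distribution).
#' All outputs are written as CSV plus a JSON manifest with content hashes,
#' so identical config + seed reproduce byte-identical tables.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return List with `subjects` (per-subject score tibble), `lesions`
#'   (all-lesion tibble), `detection`, `prevalence`, `distribution` report
#'   tibbles, `segment_lengths_cm`, and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- load_pipeline_config(config)
  validate_pipeline_config(config)
  cfg <- config
  subj_rows <- list(); les_rows <- list(); seg_len <- matrix(0, 0, 5)
  for (si in seq_len(cfg$n_subjects)) {
    sseed <- cfg$seed * 1000L + si
    spec0 <- scaled_phantom_spec(cfg, sseed)
    lesions <- subject_lesions(cfg, spec0, sseed)
    ph <- generate_phantom(scaled_phantom_spec(cfg, sseed, lesions))
    vol <- ph$volume
    lm <- do.call(landmark_set, ph$spec$landmarks)
    cl <- suppressWarnings(extract_centerline(
      vol, ph$truth$seeds, cfg$tracking, proximal_z = lm$LMCA[3]))
    seg <- divide_segments(cl, lm, seed_z = ph$spec$seed_level_mm)
    cand <- detect_candidates(vol)
    cand <- validate_lesions(cand, cl, margin = cfg$validation_margin)
    cand <- assign_segment(cand, cl, seg)
    st <- accumulate_scores(cand[cand$state == "accepted", ], seg)
    subj_rows[[si]] <- tibble::tibble(
      id = si,
      tac_seg1 = st$agatston[1], tac_seg2 = st$agatston[2],
      tac_seg3 = st$agatston[3], tac_seg4 = st$agatston[4],
      tac_seg5 = st$agatston[5],
      lesions_seg1 = st$n_lesions[1], lesions_seg2 = st$n_lesions[2],
      lesions_seg3 = st$n_lesions[3], lesions_seg4 = st$n_lesions[4],
      lesions_seg5 = st$n_lesions[5],
      n_centerline_points = nrow(cl),
      centerline_length_mm = max(cl$arc_mm)
    )
    if (nrow(cand)) {
      lr <- cand[, c("lesion", "n_voxels", "volume_mm3", "peak_hu",
                     "x", "y", "z", "agatston", "state", "segment")]
      lr$id <- si
      les_rows[[length(les_rows) + 1]] <- lr
    }
    seg_len <- rbind(seg_len, seg$length_cm)
  }
  subjects <- dplyr::bind_rows(subj_rows)
  subjects$cac <- 0  # coronary calcium is a tabular input, absent in phantoms
  subjects <- derive_tac(subjects)
  subjects <- classify_group(subjects)
  lesions <- if (length(les_rows)) dplyr::bind_rows(les_rows) else
    tibble::tibble()
  mean_len <- colMeans(seg_len)
  report <- list(
    subjects = subjects,
    lesions = lesions,
    detection = tac_detection_summary(subjects),
    prevalence = prevalence_by_segment(subjects),
    distribution = lesion_distribution(subjects, mean_len),
    segment_lengths_cm = mean_len
  )
  if (!is.null(out_dir)) {
    report$manifest <- write_tables(report, out_dir, cfg)
  }
  report
}

#' Write pipeline report tables and a manifest
#'
#' @param report Report list from [run_pipeline()].
#' @param dir Output directory.
#' @param config The `pipeline_config` used (recorded in the manifest).
#' @return The manifest (list), invisibly written to `manifest.json`:
#'   package version, seed, and an md5 content hash per written table.
#' @export
write_tables <- function(report, dir, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("subjects", "lesions", "detection", "prevalence", "distribution")
  files <- character(0)
  for (tb in tabs) {
    df <- report[[tb]]
    if (is.null(df) || !is.data.frame(df) || nrow(df) == 0) next
    df <- dplyr::select(df, -dplyr::any_of("slices"))
    f <- file.path(dir, paste0(tb, ".csv"))
    readr::write_csv(df, f)
    files[tb] <- f
  }
  manifest <- list(
    package = "aortacalc",
    version = as.character(utils::packageVersion("aortacalc")),
    seed = if (!is.null(config)) config$seed else NA,
    tables = lapply(files, function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
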