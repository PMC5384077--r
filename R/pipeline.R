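# End-to-end pipeline: registration -> morphology -> velocimetry ->
# hemodynamics -> statistics, plus configuration handling and provenance.

#' Pipeline configuration
#'
#' All tunable parameters of the pipeline in one nested list, with
#' defaults reproducing the acquisition constants of the conjunctival
#' imaging protocol (1.25 um/pixel, 50 frames/s, 1 s sequences).
#'
#' @param ... named overrides for any top-level section (the override is
#'   merged element-wise into that section).
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    acquisition = list(pixel_size_um = 1.25, frame_rate_hz = 50,
                       duration_s = 1),
    registration = list(blink_z = 4, min_correlation = 0.4,
                        max_gradient = 0.2, max_shift_frac = 0.1),
    segmentation = list(scale_min_px = 1, scale_max_px = 30, n_scales = 8,
                        threshold = "otsu", min_area_px = 50),
    diametry = list(station_spacing_px = 5, profile_half_um = 60,
                    min_length_um = 50, min_d_um = 6, max_d_um = 75),
    flow = list(variance_factor = 2),
    velocimetry = list(min_stations = 20, quality_floor = 2),
    hemodynamics = list(k = 1.6, eta_plasma = 1.2),
    statistics = list(covariates = default_adjustment_covariates(),
                      alpha = 0.05),
    seed = 1
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop(sprintf("unknown config section '%s'", nm))
    if (is.list(cfg[[nm]])) {
      for (k in names(over[[nm]])) cfg[[nm]][[k]] <- over[[nm]][[k]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return \code{read_config} returns a \code{pipeline_config}.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @param config a \code{pipeline_config}.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  string_hash(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA))
}

frangi_scales_from_config <- function(cfg) {
  exp(seq(log(cfg$segmentation$scale_min_px),
          log(cfg$segmentation$scale_max_px),
          length.out = cfg$segmentation$n_scales))
}

#' Process one image sequence into per-vessel measurements
#'
#' Runs frame screening, longest-run selection, registration, vessel
#' segmentation, centerline extraction, diametry, flow detection and STI
#' velocimetry on a single sequence. Vessel identity for de-duplication is
#' the connected component of the skeleton before bifurcation cutting:
#' segments cut from the same component are measurements along the same
#' vessel, and only the longest-centerline segment per vessel is retained
#' downstream.
#'
#' @param seq an \code{\link{image_sequence}}.
#' @param config a \code{\link{pipeline_config}}.
#' @param types optional named character vector mapping segment ids
#'   (as character) to vessel types ("arteriole"/"venule"); unknown ids
#'   stay "unlabeled".
#' @return list with \code{measurements} (data frame, one row per admitted
#'   segment), \code{quality} (frame screening report), \code{run},
#'   \code{registration} (the \code{registered_sequence}), \code{n_segments_total},
#'   \code{n_discarded_short}, and \code{rejections} (segment id ->
#'   reason).
#' @export
process_sequence <- function(seq, config = pipeline_config(), types = NULL) {
  stopifnot(inherits(seq, "image_sequence"))
  rcfg <- config$registration
  quality <- score_frame_quality(seq, rcfg$blink_z, rcfg$min_correlation,
                                 rcfg$max_gradient)
  run <- longest_valid_run(quality)
  reg <- register(seq, run, rcfg$max_shift_frac)

  mask <- segment_vessels(reg$average,
                          scales = frangi_scales_from_config(config),
                          threshold = config$segmentation$threshold,
                          min_area_px = config$segmentation$min_area_px)
  mask <- mask & reg$mask
  cl <- extract_centerlines(mask, seq$pixel_size_um,
                            config$diametry$min_length_um)
  segments <- cl$segments
  segments <- filter_by_variance(segments, reg, mask,
                                 config$flow$variance_factor)

  rows <- list()
  rejections <- character(0)
  for (seg in segments) {
    seg <- measure_diameter(seg, reg$average, seq$pixel_size_um,
                            config$diametry$station_spacing_px,
                            config$diametry$profile_half_um)
    if (!is.null(seg$rejected)) {
      rejections[as.character(seg$id)] <- seg$rejected
      next
    }
    if (seg$diameter_um < config$diametry$min_d_um ||
        seg$diameter_um > config$diametry$max_d_um) {
      rejections[as.character(seg$id)] <- "diameter out of range"
      next
    }
    v <- NA_real_; slope <- NA_real_; qual <- NA_real_; reliable <- FALSE
    if (isTRUE(seg$flow_detected)) {
      sti <- build_sti(reg, seg, config$velocimetry$min_stations)
      if (is.null(sti$rejected)) {
        sti <- tryCatch(
          estimate_band_slope(sti, config$velocimetry$quality_floor),
          error = function(e) NULL)
        if (!is.null(sti)) {
          v <- sti$velocity_mm_s
          slope <- sti$slope_px_per_frame
          qual <- sti$quality
          reliable <- sti$reliable
        }
      } else {
        rejections[as.character(seg$id)] <- sti$rejected
      }
    }
    type <- if (!is.null(types)) types[as.character(seg$id)] else NA_character_
    seg <- label_vessel_type(seg, type)
    rows[[length(rows) + 1]] <- data.frame(
      segment_id = seg$id,
      vessel_id = seg$parent,
      type = seg$type,
      length_um = seg$length_um,
      n_stations = seg$n_stations,
      d_um = seg$diameter_um,
      flow_detected = isTRUE(seg$flow_detected),
      v_mm_s = v,
      slope_px_per_frame = slope,
      sti_quality = qual,
      v_reliable = reliable
    )
  }
  measurements <- if (length(rows)) do.call(rbind, rows) else
    data.frame(segment_id = integer(0), vessel_id = integer(0),
               type = character(0), length_um = numeric(0),
               n_stations = integer(0), d_um = numeric(0),
               flow_detected = logical(0), v_mm_s = numeric(0),
               slope_px_per_frame = numeric(0), sti_quality = numeric(0),
               v_reliable = logical(0))
  list(measurements = measurements, quality = quality, run = run,
       registration = reg, n_segments_total = length(segments),
       n_discarded_short = cl$n_discarded_short, rejections = rejections)
}

#' Run the full pipeline over a set of sequences and a subject table
#'
#' Processes every sequence, keeps one record per vessel (longest
#' centerline), joins subject covariates, computes the derived
#' hemodynamic descriptors, and runs the group-level statistics (ANOVA,
#' unadjusted and adjusted mixed models, velocity-diameter slopes) when
#' two or more groups are present. All tables carry a provenance record
#' (config hash, seed).
#'
#' @param sequences named list: subject id -> \code{image_sequence} (or a
#'   list of sequences per subject); or paths to multi-page TIFF files.
#' @param subjects subject table: \code{subject_id}, \code{group},
#'   covariates, \code{hct} as a fraction. Subject ids must be unique (one
#'   eye per subject is the caller's responsibility).
#' @param config a \code{\link{pipeline_config}}.
#' @param types optional list: subject id -> named type vector passed to
#'   \code{\link{process_sequence}}.
#' @param out_dir optional directory; when given, writes vessels.csv,
#'   subjects.csv, statistics JSON and provenance.json there.
#' @return list with \code{vessels} (hemodynamics table, one row per
#'   vessel), \code{statistics} (list or NULL), \code{per_sequence}
#'   reports, and \code{provenance}.
#' @export
run_pipeline <- function(sequences, subjects, config = pipeline_config(),
                         types = NULL, out_dir = NULL) {
  if (!is.data.frame(subjects) || nrow(subjects) == 0) {
    stop("subject table is empty")
  }
  need <- c("subject_id", "group", "hct")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) {
    stop(sprintf("subject table lacks column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(subjects$subject_id)) {
    stop("subject ids must be unique (one eye per subject)")
  }
  if (is.null(names(sequences)) ||
      !all(names(sequences) %in% subjects$subject_id)) {
    stop("sequences must be named by subject ids present in the subject table")
  }

  all_rows <- list()
  reports <- list()
  for (sid in names(sequences)) {
    sq <- sequences[[sid]]
    if (is.character(sq)) {
      sq <- read_sequence_tiff(sq, config$acquisition$pixel_size_um,
                               config$acquisition$frame_rate_hz)
    }
    res <- process_sequence(sq, config,
                            types = if (!is.null(types)) types[[sid]])
    reports[[sid]] <- res[c("quality", "run", "n_segments_total",
                            "n_discarded_short", "rejections")]
    meas <- res$measurements
    if (nrow(meas)) {
      meas$subject_id <- sid
      meas$vessel_id <- paste0(sid, "_V", meas$vessel_id)
      all_rows[[sid]] <- meas
    }
  }
  vessels <- do.call(rbind, all_rows)
  rownames(vessels) <- NULL

  if (!is.null(vessels) && nrow(vessels)) {
    vessels <- dedupe_longest(vessels)
    with_flow <- vessels[vessels$flow_detected & !is.na(vessels$v_mm_s), ,
                         drop = FALSE]
    vessels <- hemodynamics_table(with_flow, subjects,
                                  config$hemodynamics$k,
                                  config$hemodynamics$eta_plasma)
  } else {
    vessels <- data.frame()
  }

  # group statistics need at least two groups with two measured subjects
  stats <- NULL
  if (nrow(vessels)) {
    sids <- unique(vessels$subject_id)
    gtab <- table(subjects$group[match(sids, subjects$subject_id)])
    if (length(gtab) >= 2 && all(gtab >= 2)) {
      stats <- cohort_statistics(vessels, subjects, config)
    }
  }

  prov <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    n_sequences = length(sequences),
    n_vessels = nrow(vessels),
    package_version = as.character(utils::packageVersion("conjflow")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  out <- list(vessels = vessels, statistics = stats,
              per_sequence = reports, provenance = prov)
  if (!is.null(out_dir)) write_pipeline_outputs(out, subjects, out_dir)
  out
}

#' Group-level statistics for a vessel-level hemodynamics table
#'
#' ANOVA, unadjusted and adjusted mixed models for every descriptor, and
#' velocity-diameter slopes; the structure mirrors the stratified
#' descriptor tables and beta/CI/P model tables of clinical reports.
#'
#' @param vessels hemodynamics table (one row per vessel).
#' @param subjects subject table.
#' @param config a \code{\link{pipeline_config}}.
#' @return nested list: \code{anova}, \code{models} (per descriptor,
#'   unadjusted and adjusted), \code{slopes}.
#' @export
cohort_statistics <- function(vessels, subjects, config = pipeline_config()) {
  descr <- intersect(descriptor_columns, names(vessels))
  covs <- intersect(config$statistics$covariates, names(subjects))
  anv <- lapply(descr, function(d) group_anova(vessels, subjects, d))
  names(anv) <- descr
  models <- lapply(descr, function(d) {
    list(
      unadjusted = fit_mixed_model(vessels, subjects, d, adjusted = FALSE),
      adjusted = fit_mixed_model(vessels, subjects, d, adjusted = TRUE,
                                 covariates = covs)
    )
  })
  names(models) <- descr
  slopes <- rbind(
    velocity_diameter_slopes(vessels, subjects, adjusted = FALSE),
    velocity_diameter_slopes(vessels, subjects, adjusted = TRUE,
                             covariates = covs)
  )
  list(anova = anv, models = models, slopes = slopes)
}

write_pipeline_outputs <- function(result, subjects, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$vessels, file.path(out_dir, "vessels.csv"),
            row.names = FALSE)
  write.csv(subjects, file.path(out_dir, "subjects.csv"), row.names = FALSE)
  if (!is.null(result$statistics)) {
    st <- result$statistics
    json <- list(
      anova = lapply(st$anova, function(a)
        list(p_value = a$p_value, summary = a$summary)),
      models = lapply(st$models, function(m)
        lapply(m, function(f) list(
          coefficients = f$coefficients, sigma_b2 = f$sigma_b2,
          sigma_e2 = f$sigma_e2, n_subjects = f$n_subjects,
          n_vessels = f$n_vessels))),
      slopes = st$slopes
    )
    jsonlite::write_json(json, file.path(out_dir, "statistics.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  jsonlite::write_json(result$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' Read a vessel-type annotation table
#'
#' Arteriole/venule labels come from visual inspection of flow direction
#' (divergence into branches vs collection into larger vessels); this
#' reads a CSV of segment id -> type and validates the label vocabulary.
#'
#' @param path CSV file with columns \code{segment_id} and \code{type}.
#' @return named character vector: segment id (as character) -> type.
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("segment_id", "type") %in% names(df))) {
    stop("annotation file must have columns segment_id, type")
  }
  bad <- setdiff(unique(df$type), c("arteriole", "venule", "unlabeled"))
  if (length(bad)) {
    stop(sprintf("unknown vessel type label '%s'", bad[1]))
  }
  setNames(df$type, as.character(df$segment_id))
}
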