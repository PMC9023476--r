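#' Pipeline configuration
#'
#' Bundles the tunable parameters of every stage: acquisition calibration,
#' vessel-geometry thresholds, velocimetry settings and the screening-
#' statistics thresholds, plus the master seed from which per-stage child
#' seeds are derived deterministically.
#'
#' @param fps acquisition frame rate, frames/s.
#' @param um_per_px pixel pitch, um/pixel.
#' @param spur_px skeleton spur-pruning floor, pixels.
#' @param min_quality segment quality floor for inclusion.
#' @param min_length_um segment length floor for inclusion, um.
#' @param velocimetry a [velocimetry_config()].
#' @param p_enter,p_remove stepwise entry/removal thresholds.
#' @param classification_cut fitted-probability classification threshold.
#' @param hl_groups Hosmer-Lemeshow risk groups.
#' @param seed master integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fps = 60, um_per_px = 1.5,
                            spur_px = 10, min_quality = 0.5,
                            min_length_um = 50,
                            velocimetry = velocimetry_config(),
                            p_enter = 0.05, p_remove = 0.10,
                            classification_cut = 0.5, hl_groups = 10,
                            seed = 1L) {
  stopifnot(fps > 0, um_per_px > 0, spur_px >= 1,
            min_quality >= 0, min_quality <= 1,
            p_enter > 0, p_enter < 1, p_remove > 0, p_remove < 1,
            hl_groups >= 3)
  structure(
    list(
      fps = fps, um_per_px = um_per_px, spur_px = spur_px,
      min_quality = min_quality, min_length_um = min_length_um,
      velocimetry = velocimetry,
      p_enter = p_enter, p_remove = p_remove,
      classification_cut = classification_cut, hl_groups = hl_groups,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

# deterministic child seed for a named stage (double arithmetic keeps every
# intermediate exact and the result below 2^31)
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer(((as.numeric(seed) %% 1000003) * 1009 + h * 131) %% 2000000011)
}

#' Extract haemodynamic parameters from one video
#'
#' Full imaging chain for one acquisition: sharpest-frame selection and
#' rigid registration, vessel segmentation on the reference frame,
#' centerline extraction with spur pruning, per-point EDT diameters,
#' per-segment spatio-temporal images and CWT axial velocities, and the
#' derived cross-sectional velocity, flow and wall shear rate.
#'
#' @param stack a [frame_stack()].
#' @param config a [pipeline_config()].
#' @return A list: `haemodynamics` (tibble, one row per included segment:
#'   `segment_id`, `d_um`, `va_mm_s`, `vs_mm_s`, `q_pl_s`, `wsr_per_s`,
#'   `quality`, `length_um`, `va_status`), `registration`, `mask`,
#'   `centerlines`, `segments` (the summary table including excluded
#'   segments).
#' @export
extract_haemodynamics <- function(stack, config = pipeline_config()) {
  reg <- register_frames(stack)
  # segment on the temporal mean of the registered stack: advecting
  # aggregates average into a near-uniform tube and noise shrinks ~1/sqrt(T)
  ref <- apply(reg$registered$frames, c(1, 2), mean)
  mask <- segment_vessels(ref, um_per_px = stack$um_per_px)
  cl <- extract_centerlines(mask, min_length_px = config$spur_px)
  if (nrow(cl) == 0) {
    return(list(
      haemodynamics = tibble::tibble(
        segment_id = integer(), d_um = numeric(), va_mm_s = numeric(),
        vs_mm_s = numeric(), q_pl_s = numeric(), wsr_per_s = numeric(),
        quality = numeric(), length_um = numeric(), va_status = character()
      ),
      registration = reg, mask = mask, centerlines = cl,
      segments = summarise_segments(cl)
    ))
  }
  cl <- edt_diameter(mask, cl)
  seg_summary <- summarise_segments(
    cl, frame = ref,
    min_quality = config$min_quality, min_length_um = config$min_length_um
  )
  rows <- purrr::map_dfr(
    seg_summary$segment_id[seg_summary$included],
    function(sid) {
      pts <- dplyr::filter(cl, .data$segment_id == sid)
      est <- tryCatch({
        sti <- build_sti(reg$registered, pts)
        estimate_axial_velocity_cwt(sti, config$velocimetry)
      }, error = function(e) NULL)
      info <- dplyr::filter(seg_summary, .data$segment_id == sid)
      if (is.null(est) || est$status != "ok") {
        return(tibble::tibble(
          segment_id = sid, d_um = info$mean_diameter_um,
          va_mm_s = NA_real_, vs_mm_s = NA_real_,
          q_pl_s = NA_real_, wsr_per_s = NA_real_,
          quality = info$quality, length_um = info$length_um,
          va_status = if (is.null(est)) "sti_failed" else est$status
        ))
      }
      h <- segment_haemodynamics(info$mean_diameter_um, est$va_mm_s,
                                 config$velocimetry)
      tibble::tibble(
        segment_id = sid, h,
        quality = info$quality, length_um = info$length_um,
        va_status = "ok"
      )
    }
  )
  list(
    haemodynamics = rows, registration = reg, mask = mask,
    centerlines = cl, segments = seg_summary
  )
}

#' Run the full synthetic screening pipeline into a run directory
#'
#' End-to-end orchestration at desk scale: simulate a handful of
#' ground-truthed videos and push them through registration, geometry and
#' velocimetry; simulate a two-group cohort; apply LOD imputation and
#' log10 transforms; produce the group-comparison table, the stepwise
#' screening model, the ROC analysis and the model-comparison report. All
#' tables are written as CSV under `out_dir` together with a manifest
#' (config, seed, package version, per-stage timings); re-running with
#' the same seed reproduces every CSV bit-identically.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param n_videos number of synthetic videos to extract (default 2).
#' @param cohort a [cohort_sim_config()]; its seed is overridden by the
#'   pipeline's child seed.
#' @param candidates stepwise candidate predictors (after transforms).
#' @param log10_vars variables to log10-transform before modelling.
#' @return The manifest list, invisibly; side effect: CSV/JSON files in
#'   `out_dir` (`shifts_video<i>.csv`, `segments_video<i>.csv`,
#'   `haemodynamics.csv`, `cohort.csv`, `comparisons.csv`,
#'   `screening_model.csv`, `roc_points.csv`, `model_report.csv`,
#'   `manifest.json`).
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(),
                         n_videos = 2,
                         cohort = cohort_sim_config(),
                         candidates = c("vs_mm_s", "nt_probnp", "adiponectin",
                                        "hfabp", "age"),
                         log10_vars = c("nt_probnp", "adiponectin", "hfabp",
                                        "wsr_per_s")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, code) {
    ts <- Sys.time()
    res <- tryCatch(force(code), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- round(as.numeric(Sys.time() - ts, units = "secs"), 3)
    res
  }

  haemo <- stage("extract", {
    purrr::map_dfr(seq_len(n_videos), function(i) {
      vcfg <- video_sim_config(
        fps = config$fps, um_per_px = config$um_per_px,
        seed = child_seed(config$seed, paste0("video", i))
      )
      sim <- render_vessel_video(vcfg)
      ext <- extract_haemodynamics(sim$stack, config)
      write_registration_shifts(
        ext$registration, file.path(out_dir, sprintf("shifts_video%d.csv", i))
      )
      write_segments(
        ext$centerlines, file.path(out_dir, sprintf("segments_video%d.csv", i))
      )
      dplyr::mutate(ext$haemodynamics,
                    video = i, subject_id = sprintf("V%02d", i),
                    .before = 1)
    })
  })
  utils::write.csv(haemo, file.path(out_dir, "haemodynamics.csv"),
                   row.names = FALSE)
  patient_means <- aggregate_patient(haemo)

  cohort_tbl <- stage("simulate_cohort", {
    cohort$seed <- child_seed(config$seed, "cohort")
    simulate_cohort(cohort)
  })
  prepped <- stage("prep", {
    cohort_tbl |>
      impute_below_lod() |>
      apply_log10(intersect(log10_vars, names(cohort_tbl)))
  })
  utils::write.csv(prepped, file.path(out_dir, "cohort.csv"), row.names = FALSE)

  comparisons <- stage("compare", {
    vars <- setdiff(
      names(prepped),
      c("subject_id", "group", grep("_below_lod$", names(prepped), value = TRUE))
    )
    purrr::map_dfr(vars, ~ compare_groups(prepped, .x))
  })
  utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)

  screen <- stage("screen", {
    prepped$case <- as.numeric(prepped$group == "post_mi")
    sw <- stepwise_wald(prepped, "case", candidates,
                        p_enter = config$p_enter, p_remove = config$p_remove)
    roc <- if (length(sw$selected)) {
      roc_curve(sw$model$fitted, sw$model$y,
                classification_cut = config$classification_cut)
    } else NULL
    hl <- if (length(sw$selected)) {
      hosmer_lemeshow(sw$model, g = config$hl_groups)
    } else NULL
    specs <- list(selected = sw$selected)
    for (v in candidates) specs[[v]] <- v
    specs <- specs[vapply(specs, length, integer(1)) > 0]
    report <- model_comparison_report(
      prepped, "case", specs, classification_cut = config$classification_cut
    )
    list(stepwise = sw, roc = roc, hl = hl, report = report)
  })
  utils::write.csv(tidy(screen$stepwise$model),
                   file.path(out_dir, "screening_model.csv"), row.names = FALSE)
  if (!is.null(screen$roc)) {
    utils::write.csv(screen$roc$curve, file.path(out_dir, "roc_points.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(screen$report, file.path(out_dir, "model_report.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "ocuflow",
    version = as.character(utils::packageVersion("ocuflow")),
    seed = config$seed,
    config = list(
      fps = config$fps, um_per_px = config$um_per_px,
      spur_px = config$spur_px, min_quality = config$min_quality,
      min_length_um = config$min_length_um,
      k_axial_to_cross = config$velocimetry$k_axial_to_cross,
      p_enter = config$p_enter, p_remove = config$p_remove,
      classification_cut = config$classification_cut,
      hl_groups = config$hl_groups
    ),
    n_videos = n_videos,
    n_control = cohort$n_control, n_case = cohort$n_case,
    selected = screen$stepwise$selected,
    stage_seconds = timings,
    total_seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(manifest, list(
    patient_means = patient_means, screen = screen, comparisons = comparisons
  )))
}
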