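#' Pipeline run configuration
#'
#' Bundles every tunable parameter of the measurement chain so a run can be
#' archived and reproduced exactly: identical config and seed give
#' bit-identical CSV outputs.
#'
#' @param output_dir directory for generated files.
#' @param n_patients synthetic cohort size.
#' @param seed global random seed.
#' @param timepoints subset of `c("PRE", "FU1")` to simulate/measure.
#' @param knee_angle_bent included knee angle of the flexed acquisition
#'   (degrees).
#' @param voxel_spacing isotropic mask spacing, mm.
#' @param resample_step centerline resampling step, mm.
#' @param smooth_window moving-average window (odd).
#' @param section_step cross-section plane spacing, mm.
#' @param icp_max_iter,icp_tol ICP iteration cap and RMS-improvement
#'   stopping tolerance (mm).
#' @param plane_convention tortuosity decomposition convention, see
#'   [project_centerline()].
#' @param normality normality-test variant, see [paired_compare()].
#' @param alpha significance level.
#' @param write_files when FALSE, [run_simulate()] keeps phantoms in memory
#'   only (no mesh/mask files written); records and reports are unaffected.
#' @return list of class `run_config`.
#' @export
run_config <- function(output_dir = tempfile("fpmorph_run_"),
                       n_patients = 3L, seed = 1L,
                       timepoints = c("PRE"),
                       knee_angle_bent = 90,
                       voxel_spacing = 0.5, resample_step = 1,
                       smooth_window = 5L, section_step = 5,
                       icp_max_iter = 200L, icp_tol = 1e-4,
                       plane_convention = "ap_in_front",
                       normality = "lilliefors", alpha = 0.05,
                       write_files = TRUE) {
  cfg <- list(output_dir = output_dir, n_patients = as.integer(n_patients),
              seed = as.integer(seed), timepoints = timepoints,
              knee_angle_bent = knee_angle_bent,
              voxel_spacing = voxel_spacing, resample_step = resample_step,
              smooth_window = as.integer(smooth_window),
              section_step = section_step,
              icp_max_iter = as.integer(icp_max_iter), icp_tol = icp_tol,
              plane_convention = plane_convention,
              normality = normality, alpha = alpha,
              write_files = isTRUE(write_files))
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config)[sort(names(unclass(config)))], tmp,
                       digits = NA, auto_unbox = TRUE)
  unname(tools::md5sum(tmp))
}

log_stage <- function(config, stage, case, msg) {
  message(sprintf("[%s] %s | %s | %s", format(Sys.time(), "%H:%M:%S"),
                  stage, case, msg))
}

#' Simulate a phantom cohort
#'
#' Generates `n_patients` paired limb phantoms per requested timepoint and
#' (optionally) writes their meshes (ASCII STL), binary masks (NIfTI) and a
#' JSON manifest linking every file to its ground truth. The archived config
#' (JSON, with its hash) sits next to the outputs.
#'
#' @param config a [run_config()].
#' @return list of class `phantom_manifest`: `patients` (nested list of
#'   phantom pairs with truth), `config`, `config_hash`, and `paths` when
#'   files were written.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$n_patients < 1) stop("n_patients must be >= 1")
  h <- config_hash(config)
  if (config$write_files) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(config), file.path(config$output_dir, "config.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  patients <- list()
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", i)
    patients[[pid]] <- list()
    for (tp in config$timepoints) {
      pair <- make_limb_phantom(seed = config$seed + 1000L * i,
                                timepoint = tp,
                                knee_angle_bent = config$knee_angle_bent)
      entry <- list(pair = pair,
                    truth = list(straight = pair$straight$truth,
                                 bent = pair$bent$truth,
                                 true_transform = list(
                                   rotation = pair$true_transform$rotation,
                                   translation = pair$true_transform$translation)))
      if (config$write_files) {
        pdir <- file.path(config$output_dir, pid, tp)
        dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
        for (cfg_name in c("straight", "bent")) {
          ph <- pair[[cfg_name]]
          write_stl(ph$vessel, file.path(pdir, paste0("vessel_", cfg_name, ".stl")))
          write_stl(ph$femur, file.path(pdir, paste0("femur_", cfg_name, ".stl")))
          write_stl(ph$tibia, file.path(pdir, paste0("tibia_", cfg_name, ".stl")))
        }
        write_transform_json(pair$true_transform,
                             file.path(pdir, "true_transform.json"))
        entry$paths <- pdir
      }
      patients[[pid]][[tp]] <- entry
      log_stage(config, "simulate", paste(pid, tp), "phantom generated")
    }
  }
  manifest <- structure(list(patients = patients, config = config,
                             config_hash = h),
                        class = "phantom_manifest")
  if (config$write_files) {
    truth_rows <- manifest_truth_table(manifest)
    write.csv(truth_rows, file.path(config$output_dir, "ground_truth.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = h, n_patients = config$n_patients,
           timepoints = config$timepoints,
           patients = lapply(patients, function(pp) lapply(pp, function(e) e$paths))),
      file.path(config$output_dir, "manifest.json"),
      digits = NA, auto_unbox = TRUE, null = "null")
  }
  manifest
}

manifest_truth_table <- function(manifest) {
  rows <- list()
  for (pid in names(manifest$patients))
    for (tp in names(manifest$patients[[pid]])) {
      tr <- manifest$patients[[pid]][[tp]]$truth
      for (cfg_name in c("straight", "bent"))
        for (seg in c("sfa", "pa")) {
          t1 <- tr[[cfg_name]][[seg]]
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = pid, timepoint = tp, configuration = cfg_name,
            segment = toupper(seg), length = t1$length,
            tortuosity = t1$tortuosity, mean_diameter = t1$mean_diameter,
            stringsAsFactors = FALSE)
        }
    }
  do.call(rbind, rows)
}

# Measure one phantom configuration through the full chain:
# voxelize -> extract -> resample -> smooth -> split -> metrics ->
# cross-sections -> decomposition.
measure_phantom_config <- function(ph, config) {
  mask <- voxelize(ph$vessel, spacing = config$voxel_spacing)
  seeds <- phantom_seeds(ph)
  line <- extract_centerline(mask, seeds$start, seeds$end)
  line <- resample_uniform(line, config$resample_step)
  line <- smooth_moving_average(line, config$smooth_window)
  sp <- split_at_landmark(line, ph$landmark_adductor_hiatus)
  frame <- anatomical_frame(ph$tibia$vertices, ph$anterior_hint,
                            proximal_point = ph$hinge$point)
  out <- list()
  for (seg in c("sfa", "pa")) {
    seg_line <- sp[[seg]]
    secs <- suppressWarnings(
      cross_sections(seg_line, ph$vessel, step = config$section_step))
    rec <- list(length = curve_length(seg_line),
                tortuosity = tortuosity_index(seg_line),
                mean_diameter = mean_diameter(secs),
                t_front = NA_real_, t_lat = NA_real_)
    if (seg == "pa") {
      rec$t_front <- projected_tortuosity(seg_line, frame, "front",
                                          config$plane_convention)
      rec$t_lat <- projected_tortuosity(seg_line, frame, "lateral",
                                        config$plane_convention)
    }
    out[[seg]] <- rec
  }
  out$centerline <- line
  out
}

#' Measure a phantom cohort
#'
#' Runs registration (femur-based ICP of the bent acquisition onto the
#' straight reference), centerline extraction, segment splitting,
#' morphometry and tortuosity decomposition for every
#' (patient, timepoint, configuration) in the manifest. Per-case failures
#' are caught, logged and collected in an exceptions table; the run
#' continues.
#'
#' @param config a [run_config()].
#' @param manifest a `phantom_manifest` from [run_simulate()].
#' @return list with `records` (one data.frame row per (patient, timepoint,
#'   configuration, segment) carrying the config hash as provenance),
#'   `registrations` (per-case ICP summaries) and `exceptions`.
#' @export
run_measure <- function(config, manifest) {
  stopifnot(inherits(config, "run_config"), inherits(manifest, "phantom_manifest"))
  rows <- list(); regs <- list(); exceptions <- list()
  for (pid in names(manifest$patients)) {
    for (tp in names(manifest$patients[[pid]])) {
      pair <- manifest$patients[[pid]][[tp]]$pair
      reg <- tryCatch({
        icp <- icp_rigid(pair$bent$femur$vertices, pair$straight$femur$vertices,
                         max_iter = config$icp_max_iter, tol = config$icp_tol)
        true_inv <- invert_transform(pair$true_transform)
        err <- compose_transforms(icp$transform, pair$true_transform)
        list(patient_id = pid, timepoint = tp, rms = icp$rms,
             n_iter = icp$n_iter,
             rotation_error_deg = rotation_angle_deg(err),
             translation_error_mm = vec_norm(
               apply_transform(c(0, 0, 0), icp$transform) -
               apply_transform(c(0, 0, 0), true_inv)),
             transform = icp$transform)
      }, error = function(e) e)
      if (inherits(reg, "error")) {
        exceptions[[length(exceptions) + 1L]] <- data.frame(
          patient_id = pid, timepoint = tp, stage = "register",
          message = conditionMessage(reg))
        log_stage(config, "register", paste(pid, tp), "FAILED")
        next
      }
      regs[[length(regs) + 1L]] <- reg
      log_stage(config, "register", paste(pid, tp),
                sprintf("rms %.4f mm, rot err %.4f deg", reg$rms,
                        reg$rotation_error_deg))
      for (cfg_name in c("straight", "bent")) {
        ph <- pair[[cfg_name]]
        res <- tryCatch(measure_phantom_config(ph, config),
                        error = function(e) e)
        if (inherits(res, "error")) {
          exceptions[[length(exceptions) + 1L]] <- data.frame(
            patient_id = pid, timepoint = tp, stage = paste0("measure_", cfg_name),
            message = conditionMessage(res))
          log_stage(config, "measure", paste(pid, tp, cfg_name), "FAILED")
          next
        }
        for (seg in c("sfa", "pa")) {
          r <- res[[seg]]
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = pid, timepoint = tp, configuration = cfg_name,
            segment = toupper(seg), length = r$length,
            tortuosity = r$tortuosity, mean_diameter = r$mean_diameter,
            t_front = r$t_front, t_lat = r$t_lat,
            config_hash = manifest$config_hash, stringsAsFactors = FALSE)
        }
        log_stage(config, "measure", paste(pid, tp, cfg_name), "ok")
      }
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else NULL
  out <- list(records = records,
              registrations = regs,
              exceptions = if (length(exceptions)) do.call(rbind, exceptions) else NULL)
  if (config$write_files && !is.null(records)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(records, file.path(config$output_dir, "records.csv"),
              row.names = FALSE)
  }
  out
}

#' Report stage of the pipeline
#'
#' Thin wrapper around [build_results_report()] that also archives the
#' report tables as CSV/JSON next to the run outputs.
#'
#' @param config a [run_config()].
#' @param records morphometry records data.frame.
#' @return a `results_report`.
#' @export
run_report <- function(config, records) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(records) || nrow(records) == 0) stop("empty records table")
  rep <- build_results_report(records, alpha = config$alpha,
                              normality = config$normality)
  if (config$write_files) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(rep$summary, file.path(config$output_dir, "summary.csv"),
              row.names = FALSE)
    if (!is.null(rep$comparisons))
      write.csv(rep$comparisons, file.path(config$output_dir, "comparisons.csv"),
                row.names = FALSE)
    jsonlite::write_json(
      list(summary = rep$summary, decomposition = rep$decomposition,
           comparisons = rep$comparisons, notes = rep$notes),
      file.path(config$output_dir, "report.json"),
      digits = NA, auto_unbox = TRUE, dataframe = "rows", null = "null")
  }
  rep
}
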