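#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]: output
#' directory, seed, the simulated sonications (one [sim_config()] override
#' list per run), the thermometry method, and the dose parameters. Validation
#' happens before any stage runs and names the offending field.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer master seed; run `i` uses `seed + i`.
#' @param runs list of per-run override lists passed to [sim_config()]
#'   (power, duration, pattern, ...). Defaults to three runs spanning the
#'   studied 3-6 W, 100-180 s envelope on a reduced 64 x 64 grid so the demo
#'   stays fast.
#' @param method thermometry method, `"referenced"` or `"referenceless"`.
#' @param order drift-polynomial order (`NULL` = method default).
#' @param threshold_CEM necrosis threshold, equivalent minutes.
#' @param baseline_temp_C absolute tissue baseline, degC.
#' @param observer_noise_frac tracing-noise SD for the synthetic histology.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            runs = list(
                              list(sonication_power_W = 3, sonication_duration_s = 100),
                              list(sonication_power_W = 4, sonication_duration_s = 100),
                              list(sonication_power_W = 6, sonication_duration_s = 180)),
                            method = "referenced", order = NULL,
                            threshold_CEM = 70, baseline_temp_C = 37,
                            observer_noise_frac = 0.05) {
  cfg <- list(out_dir = out_dir, seed = seed, runs = runs, method = method,
              order = order, threshold_CEM = threshold_CEM,
              baseline_temp_C = baseline_temp_C,
              observer_noise_frac = observer_noise_frac)
  validate_pipeline_config(cfg)
}

#' @rdname pipeline_config
#' @param config a raw config list (e.g. from a JSON file).
#' @export
validate_pipeline_config <- function(config) {
  required <- c("out_dir", "seed", "runs", "method", "threshold_CEM",
                "baseline_temp_C")
  missing <- setdiff(required, names(config))
  abort_if(length(missing) > 0,
           paste0("pipeline config is missing required field(s): ",
                  paste(missing, collapse = ", ")))
  abort_if(!config$method %in% c("referenced", "referenceless"),
           "field 'method' must be 'referenced' or 'referenceless'")
  abort_if(!is_scalar_num(config$threshold_CEM) || config$threshold_CEM <= 0,
           "field 'threshold_CEM' must be a positive number")
  abort_if(!is.list(config$runs) || length(config$runs) < 1,
           "field 'runs' must be a nonempty list")
  structure(config, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with the [pipeline_config()] fields.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  raw$out_dir <- as.character(raw$out_dir)
  raw$seed <- as.integer(raw$seed)
  for (f in c("threshold_CEM", "baseline_temp_C", "observer_noise_frac"))
    if (!is.null(raw[[f]])) raw[[f]] <- as.numeric(raw[[f]])
  if (!is.null(raw$method)) raw$method <- as.character(raw$method)
  validate_pipeline_config(raw)
}

# small default grid for demo runs: physics unchanged, 8x fewer pixels
demo_sim_overrides <- function() {
  list(grid_shape = c(64L, 64L), pixel_spacing_mm = 150 / 64,
       n_slices = 3L, noise_sd_rad = 0.02,
       drift_coeffs = c(0.10, 0.05, -0.04, 0.02, -0.01, 0.03))
}

#' Run the full simulate-to-agreement pipeline
#'
#' Executes the computational tail of an ablation study end to end, per run:
#' simulate ground truth, render the wrapped-phase acquisition, reconstruct
#' drift-corrected temperatures, accumulate CEM43 dose, threshold to an MRTI
#' volume, synthesize traced histology and its volume; then compares the
#' histology and MRTI volume series with Bland-Altman / correlation /
#' paired-t statistics. All artifacts are written under `config$out_dir` and a
#' JSON manifest with per-stage parameters and md5 hashes is returned (and
#' written) for reproducibility.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (a list; also at
#'   `file.path(out_dir, "manifest.json")`).
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(unclass(config))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(code, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    list(name = name, status = "ok",
         elapsed_s = round(proc.time()[["elapsed"]] - t0, 3), result = out)
  }
  manifest <- list(seed = config$seed, method = config$method, stages = list())
  files <- character()

  truths <- NULL
  s_sim <- stage("simulate", {
    lapply(seq_along(config$runs), function(i) {
      ov <- utils::modifyList(demo_sim_overrides(), config$runs[[i]])
      ov$seed <- config$seed + i
      ov$baseline_temp_C <- config$baseline_temp_C
      cfg <- do.call(sim_config, ov)
      simulate_ground_truth(cfg,
        dose_params(threshold_CEM = config$threshold_CEM,
                    baseline_temp_C = config$baseline_temp_C))
    })
  })
  truths <- s_sim$result

  s_temp <- stage("temperature", {
    lapply(truths, function(gt) {
      series <- render_phase_series(gt$temperature)
      prfs_temperature_series(series, default_brain_mask(gt$config),
                              method = config$method, order = config$order,
                              baseline_temp_C = config$baseline_temp_C)
    })
  })
  temps <- s_temp$result

  s_dose <- stage("dose", {
    lapply(seq_along(temps), function(i) {
      dose <- accumulate_cem43(temps[[i]],
        dose_params(threshold_CEM = config$threshold_CEM,
                    baseline_temp_C = config$baseline_temp_C))
      f <- file.path(config$out_dir, sprintf("dose_run%02d.nii.gz", i))
      write_dose_map(dose, f)
      files <<- c(files, f)
      dose
    })
  })
  doses <- s_dose$result

  s_vol <- stage("volume", {
    mrti <- vapply(doses, function(d)
      dose_volume(d, threshold = config$threshold_CEM)$volume_cm3, numeric(1))
    hist_vol <- vapply(seq_along(truths), function(i) {
      sect <- synthesize_histology(truths[[i]],
        observer_noise_frac = config$observer_noise_frac %||% 0,
        seed = config$seed + 100L + i)
      histology_volume(sect)
    }, numeric(1))
    vols <- tibble::tibble(run = seq_along(mrti),
                           ground_truth_cm3 = vapply(truths, `[[`,
                             numeric(1), "necrosis_volume_cm3"),
                           histology_cm3 = hist_vol, mrti_cm3 = mrti)
    f <- file.path(config$out_dir, "volumes.csv")
    readr::write_csv(vols, f)
    files <<- c(files, f)
    vols
  })
  vols <- s_vol$result

  s_agree <- stage("agree", {
    ba <- bland_altman(vols$histology_cm3, vols$mrti_cm3)
    f <- file.path(config$out_dir, "agreement.json")
    jsonlite::write_json(as.list(glance(ba)), f, auto_unbox = TRUE, digits = NA)
    files <<- c(files, f)
    ba
  })

  for (s in list(s_sim, s_temp, s_dose, s_vol, s_agree)) {
    s$result <- NULL
    manifest$stages[[s$name]] <- s
  }
  manifest$files <- lapply(stats::setNames(files, basename(files)),
                           function(f) unname(tools::md5sum(f)))
  manifest$volumes <- as.list(vols)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
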