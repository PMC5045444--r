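#' Default end-to-end configuration
#'
#' Nested configuration consumed by [run_pipeline()] and the command-line
#' wrapper, with one section per stage. All values are plain scalars or
#' vectors so the configuration round-trips losslessly through YAML
#' ([read_config()] / [write_config()]). Flow rates are given in the bench
#' units (ul/min, ml/min) and converted internally to SI.
#'
#' @param spot `"R1"`, `"R2"` or `"R3"`.
#' @param seed Root seed; each stochastic stage derives its own seed from
#'   it, so a re-run of the same configuration is bit-identical.
#' @return Nested list of class `flowspot_config`.
#' @export
default_config <- function(spot = "R1", seed = 0L) {
  structure(list(
    seed = as.integer(seed),
    design = list(
      spot = spot,
      wavelength = 488e-9, focal_length = 10e-3, aperture_side = 3e-3,
      zones_per_side = 128L, phase_levels = 16L,
      refractive_index = 1.4632, aperture_profile = "uniform",
      edge_pitch = 110e-6,
      max_iterations = 150L, feedback_strength = 0.7,
      stage_levels = c(64L, 32L, 16L), stage_iterations = 15L,
      convergence_tol = 1e-9,
      eval_oversample = 2L, eval_pad = 2L),
    flow = list(
      kinematic_viscosity = 1.004e-6, density = 998,
      sample_rate_ul_min = 60, sheath_rate_ml_min = 7.2, K_Q = 0.75,
      straight_width = 310e-6, straight_height = 163e-6),
    simulate = list(
      spot_source = "ideal",          # "ideal" or "design"
      total_power = 20e-3,
      diameter = 5e-6, concentration_per_ml = 5e6,
      brightness_cv = 0.05, stream_width = 15e-6,
      lateral_offset_sd = 15e-6 / 4,
      velocity = 4.8,
      sampling_rate = 1e7, gain = 1, snr = 20,
      additive_frac = 0.01, baseline_frac = 0.02,
      duration = 0.02, noise = TRUE),
    analyze = list(L = 110e-6, retain = 0.9)),
    class = "flowspot_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path File path.
#' @param config A configuration list.
#' @return `read_config()` returns the configuration; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "flowspot_config")
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

cfg_optical <- function(d) {
  optical_config(wavelength = d$wavelength, focal_length = d$focal_length,
                 aperture_side = d$aperture_side,
                 zones_per_side = d$zones_per_side,
                 phase_levels = d$phase_levels,
                 refractive_index = d$refractive_index,
                 aperture_profile = d$aperture_profile)
}

#' Run the full design-to-analysis pipeline
#'
#' Executes the five stages in order -- mask design, spot evaluation, chip
#' hydraulics, waveform simulation, pulse analysis -- writing each stage's
#' outputs under `out_dir` and a manifest (configuration snapshot, derived
#' seeds, file paths and MD5 checksums) as `manifest.json`. Stage outputs:
#'
#' * `design/`: `mask.csv` (integer level matrix), `mask.json` (sidecar
#'   metadata), `relief_nm.csv`, `design_log.csv`.
#' * `evaluate/`: `metrics.json` (efficiency, RMSA, RMSI, dimensions).
#' * `flow/`: `flow.json` (split ratio, Q_HS/Q_VS, pressure drops, V_AVR,
#'   V_MAX).
#' * `simulate/`: `waveform.csv`, `truth.csv`.
#' * `analyze/`: `events.csv`, `stats.json`, `histogram.csv`.
#'
#' @param config A configuration from [default_config()] / [read_config()].
#' @param out_dir Output directory (created if missing).
#' @param stages Character vector of stages to run (default all five).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("design", "evaluate", "flow",
                                    "simulate", "analyze")) {
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  seeds <- list(design = config$seed, simulate = config$seed + 1000L)
  add <- function(p) { paths[[length(paths) + 1L]] <<- p; p }
  design <- NULL

  if ("design" %in% stages) {
    d <- config$design
    oc <- cfg_optical(d)
    dg <- design_grid(oc)
    tgt <- make_target(d$spot, n = dg$n, pitch = dg$pitch,
                       edge_pitch = d$edge_pitch)
    design <- gs_design(tgt, oc, gs_options(
      max_iterations = d$max_iterations, rng_seed = seeds$design,
      feedback_strength = d$feedback_strength,
      stage_levels = d$stage_levels,
      stage_iterations = d$stage_iterations,
      convergence_tol = d$convergence_tol))
    dd <- file.path(out_dir, "design")
    dir.create(dd, showWarnings = FALSE)
    add(write_mask_csv(design$mask, file.path(dd, "mask.csv")))
    meta <- list(spot = d$spot, wavelength = d$wavelength,
                 focal_length = d$focal_length,
                 aperture_side = d$aperture_side,
                 levels = oc$phase_levels, zone_pitch = zone_pitch(oc),
                 seed = seeds$design,
                 converged = design$converged,
                 final = as.list(design$log[nrow(design$log),
                                            c("eta", "rmsa", "rmsi")]))
    jsonlite::write_json(meta, add(file.path(dd, "mask.json")),
                         auto_unbox = TRUE, digits = NA)
    relief <- phase_to_relief(design$mask, oc)
    utils::write.table(round(relief$height * 1e9, 3),
                       add(file.path(dd, "relief_nm.csv")), sep = ",",
                       row.names = FALSE, col.names = FALSE)
    utils::write.csv(design$log, add(file.path(dd, "design_log.csv")),
                     row.names = FALSE)
  }

  eval_field <- NULL
  if ("evaluate" %in% stages) {
    if (is.null(design)) stop("evaluate stage needs the design stage",
                              call. = FALSE)
    d <- config$design
    oc <- cfg_optical(d)
    eval_field <- mask_focal_field(design$mask, oc,
                                   oversample = d$eval_oversample,
                                   pad_factor = d$eval_pad)
    tgt_fine <- retarget(design$target, nrow(eval_field$values),
                         eval_field$sample_pitch)
    met <- evaluate_spot(eval_field, tgt_fine, design$aperture)
    ed <- file.path(out_dir, "evaluate")
    dir.create(ed, showWarnings = FALSE)
    jsonlite::write_json(
      list(eta = met$eta, rmsa = met$rmsa, rmsi = met$rmsi, dims = met$dims),
      add(file.path(ed, "metrics.json")), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }

  if ("flow" %in% stages) {
    fcfg <- config$flow
    fluid <- flow_config(kinematic_viscosity = fcfg$kinematic_viscosity,
                         density = fcfg$density,
                         sample_rate = ul_per_min(fcfg$sample_rate_ul_min),
                         sheath_rate = fcfg$sheath_rate_ml_min * 1e-6 / 60,
                         K_Q = fcfg$K_Q)
    net <- example_network()
    sp <- split_sheath_flow(net, fluid)
    q_straight <- fluid$sample_rate + fluid$sheath_rate
    vel <- centerline_velocity(q_straight, fcfg$straight_width,
                               fcfg$straight_height)
    flow_out <- list(
      split_ratio = sp$ratio, Q_HS = sp$Q_HS, Q_VS = sp$Q_VS,
      dP_vertical = path_pressure_drop(net$vertical_path, sp$Q_VS, fluid),
      dP_horizontal = path_pressure_drop(net$horizontal_path, sp$Q_HS, fluid),
      V_AVR = vel$V_AVR, V_MAX = vel$V_MAX, max_to_mean = vel$ratio)
    fd <- file.path(out_dir, "flow")
    dir.create(fd, showWarnings = FALSE)
    jsonlite::write_json(flow_out, add(file.path(fd, "flow.json")),
                         auto_unbox = TRUE, digits = NA)
  }

  run <- NULL
  if ("simulate" %in% stages) {
    s <- config$simulate
    spot <- if (identical(s$spot_source, "design")) {
      if (is.null(eval_field))
        stop("spot_source 'design' needs the evaluate stage", call. = FALSE)
      spot_model_from_field(eval_field, s$total_power)
    } else {
      ideal_spot_model(config$design$spot, total_power = s$total_power)
    }
    pop <- bead_population(diameter = s$diameter,
                           concentration = s$concentration_per_ml * 1e6,
                           brightness_cv = s$brightness_cv,
                           lateral_offset_sd = s$lateral_offset_sd,
                           stream_width = s$stream_width)
    acq <- acquisition_config(sampling_rate = s$sampling_rate,
                              gain = s$gain, snr = s$snr,
                              additive_frac = s$additive_frac,
                              baseline_frac = s$baseline_frac,
                              duration = s$duration,
                              rng_seed = seeds$simulate, noise = s$noise)
    run <- simulate_run(spot, pop, velocity = s$velocity,
                        sample_rate = ul_per_min(
                          config$flow$sample_rate_ul_min),
                        acquisition = acq)
    sd_ <- file.path(out_dir, "simulate")
    dir.create(sd_, showWarnings = FALSE)
    utils::write.csv(
      data.frame(time_s = seq_along(run$samples) / run$sampling_rate,
                 signal = run$samples),
      add(file.path(sd_, "waveform.csv")), row.names = FALSE)
    utils::write.csv(run$truth, add(file.path(sd_, "truth.csv")),
                     row.names = FALSE)
  }

  if ("analyze" %in% stages) {
    if (is.null(run)) stop("analyze stage needs the simulate stage",
                           call. = FALSE)
    an <- analyze_waveform(run, spot_kind = config$design$spot,
                           nominal_velocity = config$simulate$velocity,
                           L = config$analyze$L)
    ad <- file.path(out_dir, "analyze")
    dir.create(ad, showWarnings = FALSE)
    ev <- an$events
    ev$pulse_ids <- NULL
    utils::write.csv(ev, add(file.path(ad, "events.csv")), row.names = FALSE)
    st <- an$stats
    st$gated <- if (!is.null(st$gated)) unclass(st$gated) else NULL
    jsonlite::write_json(st, add(file.path(ad, "stats.json")),
                         auto_unbox = TRUE, digits = NA)
    clean <- an$events[an$events$flag == "clean", ]
    if (nrow(clean) >= 2L) {
      h <- graphics::hist(clean$total_area, breaks = 30, plot = FALSE)
      utils::write.csv(data.frame(bin_left = h$breaks[-length(h$breaks)],
                                  bin_right = h$breaks[-1],
                                  count = h$counts),
                       add(file.path(ad, "histogram.csv")),
                       row.names = FALSE)
    }
  }

  manifest <- list(package_version = as.character(
                     utils::packageVersion("flowspot")),
                   config = unclass(config), seeds = seeds,
                   outputs = as.list(stats::setNames(
                     unname(tools::md5sum(unlist(paths))), unlist(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a quantized mask as an integer level matrix
#'
#' Row-major CSV of integers in `0 .. levels - 1` (one row per mask row, no
#' header), the format handed to mask fabrication.
#'
#' @param mask A quantized [phase_mask()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mask_csv <- function(mask, path) {
  stopifnot(inherits(mask, "phase_mask"))
  if (!mask$quantized) stop("mask must be quantized", call. = FALSE)
  lev <- round(mask$phase / (2 * pi / mask$levels)) %% mask$levels
  utils::write.table(lev, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a mask written by [write_mask_csv()]
#'
#' @param path CSV path.
#' @param levels Number of phase levels encoded in the file.
#' @param zone_pitch Physical zone pitch in metres.
#' @return A quantized [phase_mask()].
#' @export
read_mask_csv <- function(path, levels, zone_pitch) {
  lev <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(lev) <- NULL
  phase_mask(lev * 2 * pi / levels, zone_pitch, quantized = TRUE,
             levels = levels)
}
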