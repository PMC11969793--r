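#' Run configuration
#'
#' A self-describing configuration for one reproducible planning run:
#' phantom definition (or a label-map path), drive settings, scan
#' angles, solver controls and seed. Defaults reproduce the clinical
#' protocol: 150 kHz, 31 mA RMS/cm^2, angles 0 / +-15 / +-30 axial and
#' +-10 sagittal.
#'
#' @param phantom a [phantom_spec()], or a path to a NIfTI label map.
#' @param conductivity a [conductivity_table()].
#' @param frequency_khz,current_density_mA_cm2 drive settings.
#' @param axial_angles,sagittal_angles trial-plan rotation angles in
#'   degrees (0 is always the reference and is not listed here).
#' @param duty_weights per-pair duty fractions (AP, LR).
#' @param combination "mean" or "max".
#' @param tol solver relative-residual tolerance.
#' @param seed integer seed (forwarded to the phantom spec).
#' @param write_fields write per-plan field NIfTI volumes into the
#'   bundle.
#' @return object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(),
                       conductivity = conductivity_table(),
                       frequency_khz = 150,
                       current_density_mA_cm2 = 31,
                       axial_angles = c(15, -15, 30, -30),
                       sagittal_angles = c(10, -10),
                       duty_weights = c(0.5, 0.5),
                       combination = "mean",
                       tol = 1e-8,
                       seed = NULL,
                       write_fields = FALSE) {
  if (!is.null(seed) && inherits(phantom, "phantom_spec"))
    phantom$seed <- as.integer(seed)
  structure(list(phantom = phantom, conductivity = conductivity,
                 frequency_khz = frequency_khz,
                 current_density_mA_cm2 = current_density_mA_cm2,
                 axial_angles = axial_angles,
                 sagittal_angles = sagittal_angles,
                 duty_weights = duty_weights, combination = combination,
                 tol = tol, write_fields = write_fields),
            class = "run_config")
}

#' Build the plan list from configured angles
#' @param config a [run_config()].
#' @return list of [plan_spec()]; the reference plan first.
#' @export
config_plans <- function(config) {
  plans <- list(plan_spec("Plan1", "none", 0))
  k <- 2L
  for (a in config$axial_angles) {
    plans[[k]] <- plan_spec(paste0("Plan", k), "axial", a); k <- k + 1L
  }
  for (a in config$sagittal_angles) {
    plans[[k]] <- plan_spec(paste0("Plan", k), "sagittal", a); k <- k + 1L
  }
  plans
}

config_to_list <- function(config) {
  ph <- config$phantom
  phantom_field <- if (inherits(ph, "phantom_spec")) {
    list(spec = list(shape = ph$shape, spacing = ph$spacing,
                     body_semiaxes = ph$body_semiaxes,
                     organs = ph$organs,
                     tumor_center = ph$tumor_center,
                     tumor_radius_mm = ph$tumor_radius_mm,
                     asymmetry_mm = ph$asymmetry_mm,
                     jitter_mm = ph$jitter_mm, seed = ph$seed))
  } else list(labelmap = as.character(ph))
  list(phantom = phantom_field,
       conductivity = list(frequency_khz = config$conductivity$frequency_khz,
                           sigma = as.list(config$conductivity$sigma)),
       frequency_khz = config$frequency_khz,
       current_density_mA_cm2 = config$current_density_mA_cm2,
       axial_angles = config$axial_angles,
       sagittal_angles = config$sagittal_angles,
       duty_weights = config$duty_weights,
       combination = config$combination,
       tol = config$tol,
       write_fields = config$write_fields)
}

#' Read a run configuration from YAML (JSON is valid YAML)
#' @param path config file path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  phantom <- if (!is.null(y$phantom$labelmap)) {
    y$phantom$labelmap
  } else {
    s <- y$phantom$spec
    organs <- lapply(s$organs, function(o)
      organ(o$tissue, unlist(o$center), unlist(o$semiaxes),
            o$shape %||% "ellipsoid", isTRUE(o$shiftable)))
    phantom_spec(shape = unlist(s$shape), spacing = unlist(s$spacing),
                 body_semiaxes = unlist(s$body_semiaxes), organs = organs,
                 tumor_center = unlist(s$tumor_center),
                 tumor_radius_mm = s$tumor_radius_mm,
                 asymmetry_mm = s$asymmetry_mm %||% 0,
                 jitter_mm = s$jitter_mm %||% 0,
                 seed = s$seed %||% 1L)
  }
  cond <- conductivity_table(unlist(y$conductivity$sigma),
                             y$conductivity$frequency_khz %||% 150)
  run_config(phantom = phantom, conductivity = cond,
             frequency_khz = y$frequency_khz %||% 150,
             current_density_mA_cm2 = y$current_density_mA_cm2 %||% 31,
             axial_angles = unlist(y$axial_angles),
             sagittal_angles = unlist(y$sagittal_angles),
             duty_weights = unlist(y$duty_weights) %||% c(0.5, 0.5),
             combination = y$combination %||% "mean",
             tol = y$tol %||% 1e-8,
             write_fields = isTRUE(y$write_fields))
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' Execute a full planning run into an output bundle
#'
#' Generates (or loads) the phantom, runs the rotation scan, and writes
#' a self-describing output bundle: `metrics.csv` (one row per plan),
#' `summary.csv` (best-trial improvements), `dvh/<structure>_<plan>.csv`,
#' `plans/<plan>.json` (realized patch geometry), optional
#' `fields/<plan>.nii.gz`, the echoed `run_config.yaml`, and `run.log`.
#' Re-running from the echoed config reproduces `metrics.csv`
#' byte-identically.
#'
#' @param config a [run_config()].
#' @param out_dir output bundle directory (created if needed).
#' @param quiet suppress progress messages.
#' @return the `scan_result`, invisibly.
#' @export
run_bundle <- function(config, out_dir, quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    if (!quiet) message(msg)
  }
  cat("", file = logf)  # truncate
  log_line("ttfplan run: ", config$frequency_khz, " kHz, ",
           config$current_density_mA_cm2, " mA/cm2, combination=",
           config$combination)

  grid <- if (inherits(config$phantom, "phantom_spec")) {
    log_line("generating phantom (seed ", config$phantom$seed, ")")
    generate_phantom(config$phantom)
  } else {
    log_line("reading label map ", config$phantom)
    read_labelmap(config$phantom)
  }

  plans <- config_plans(config)
  log_line("scanning ", length(plans), " plans")
  scan <- run_protocol_scan(grid, config$conductivity,
                            current_density_mA_cm2 = config$current_density_mA_cm2,
                            frequency_khz = config$frequency_khz,
                            duty_weights = config$duty_weights,
                            combination = config$combination,
                            plans = plans, tol = config$tol,
                            keep_fields = config$write_fields)

  utils::write.csv(scan$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(scan$best)) {
    summ <- data.frame(index = names(scan$best),
                       best_plan = unname(scan$best),
                       reference = unlist(scan$metrics[1, names(scan$best)],
                                          use.names = FALSE),
                       improvement_pct = unname(scan$improvement_pct))
    utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  dvh_dir <- file.path(out_dir, "dvh")
  dir.create(dvh_dir, showWarnings = FALSE)
  for (tn in names(scan$dvh)) for (pid in names(scan$dvh[[tn]])) {
    utils::write.csv(scan$dvh[[tn]][[pid]],
                     file.path(dvh_dir, paste0(gsub("\\W", "_", tn), "_",
                                               pid, ".csv")),
                     row.names = FALSE)
  }
  plan_dir <- file.path(out_dir, "plans")
  dir.create(plan_dir, showWarnings = FALSE)
  center <- scan$center
  ref_arrays <- place_reference_arrays(center)
  for (pl in plans) {
    arrays <- rotate_plan(ref_arrays, pl)
    geom <- lapply(arrays, function(a)
      list(pair_id = a$pair_id, side = a$side, polarity = a$polarity,
           direction = a$d, disc_radius_mm = a$disc_radius_mm,
           n_discs = nrow(a$offsets)))
    jsonlite::write_json(list(plan_id = pl$plan_id, plane = pl$plane,
                              angle_deg = pl$angle_deg,
                              rotation_center_mm = center, arrays = geom),
                         file.path(plan_dir, paste0(pl$plan_id, ".json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  if (config$write_fields && !is.null(scan$fields)) {
    fdir <- file.path(out_dir, "fields")
    dir.create(fdir, showWarnings = FALSE)
    for (pid in names(scan$fields))
      write_fieldmap(scan$fields[[pid]], grid,
                     file.path(fdir, paste0(pid, ".nii.gz")))
  }
  write_run_config(config, file.path(out_dir, "run_config.yaml"))
  log_line("done: E_p = ", signif(scan$E_p, 6), " V/cm")
  invisible(scan)
}

#' Render a human-readable report from an existing bundle
#'
#' Reads the CSV outputs of [run_bundle()] (no re-solving) and returns
#' the report as a character vector of lines; byte-stable across
#' invocations.
#'
#' @param bundle_dir path to a bundle written by [run_bundle()].
#' @return character vector of report lines, invisibly; also printed.
#' @export
render_report <- function(bundle_dir) {
  mf <- file.path(bundle_dir, "metrics.csv")
  if (!file.exists(mf)) stop("not a run bundle (no metrics.csv): ", bundle_dir)
  m <- utils::read.csv(mf)
  lines <- c("Plan-quality indices (field in V/cm)",
             sprintf("%-7s %-9s %7s %8s %8s %8s %8s %8s",
                     "plan", "plane", "angle", "E_min", "E_mean", "E_max",
                     "HI", "CI"),
             sprintf("%-7s %-9s %7.1f %8.4f %8.4f %8.4f %8.4f %8.4f",
                     m$plan_id, m$plane, m$angle_deg, m$E_min, m$E_mean,
                     m$E_max, m$HI, m$CI))
  sf <- file.path(bundle_dir, "summary.csv")
  if (file.exists(sf)) {
    s <- utils::read.csv(sf)
    lines <- c(lines, "", "Best trial plan vs reference",
               sprintf("%-7s %-7s %+8.2f%%", s$index, s$best_plan,
                       s$improvement_pct))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
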