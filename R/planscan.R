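#' Run the 7-plan rotation-scan protocol on one phantom
#'
#' Places the reference montage at the tumor centroid, builds the six
#' rotated trial montages, solves the conduction problem for both
#' electrode pairs of every plan at the prescribed current density,
#' combines the two sequential orientations, and evaluates all
#' plan-quality indices against the reference plan's prescription.
#'
#' @param grid a [tissue_grid()] phantom with a GTV.
#' @param table a [conductivity_table()].
#' @param current_density_mA_cm2 drive current density (default 31,
#'   the device's clinical value).
#' @param frequency_khz drive frequency (informational; the quasi-static
#'   model is frequency-independent once the conductivities are fixed).
#' @param duty_weights per-pair duty fractions (AP, LR), summing to 1.
#' @param combination "mean" or "max" rule for [combine_pairs()].
#' @param layout an [electrode_layout()].
#' @param plans list of [plan_spec()]; default [protocol_plans()].
#' @param tol solver relative-residual tolerance.
#' @param keep_fields if TRUE, the per-plan combined field grids are
#'   returned (memory permitting).
#' @param dvh_structures character vector of tissue names for which DVH
#'   curves are computed (default just the GTV).
#' @return object of class `scan_result`: `metrics` (data.frame, one row
#'   per plan), `E_p`, `best` (per-index best trial plan ids),
#'   `improvement_pct` (per-index), `dvh` (list), and optionally
#'   `fields`.
#' @export
run_protocol_scan <- function(grid, table = conductivity_table(),
                              current_density_mA_cm2 = 31,
                              frequency_khz = 150,
                              duty_weights = c(0.5, 0.5),
                              combination = "mean",
                              layout = electrode_layout(),
                              plans = protocol_plans(),
                              tol = 1e-8,
                              keep_fields = FALSE,
                              dvh_structures = "GTV") {
  stopifnot(inherits(grid, "tissue_grid"))
  sigma <- conductivity_grid(grid, table)
  center <- tumor_centroid(grid)
  ref_arrays <- place_reference_arrays(center, layout)
  surf <- surface_mask(body_mask(grid))
  mask <- gtv_mask(grid)

  fields <- vector("list", length(plans))
  names(fields) <- vapply(plans, `[[`, "", "plan_id")
  meta <- list()
  for (i in seq_along(plans)) {
    pl <- plans[[i]]
    arrays <- rotate_plan(ref_arrays, pl)
    pair_fields <- list()
    for (pair in c("AP", "LR")) {
      pa <- Filter(function(a) a$pair_id == pair, arrays)
      src <- pa[[which(vapply(pa, `[[`, "", "polarity") == "source")]]
      snk <- pa[[which(vapply(pa, `[[`, "", "polarity") == "sink")]]
      src_p <- tryCatch(realize_array(src, grid, surf), error = function(e)
        stop(pl$plan_id, " (", pair, "): ", conditionMessage(e)))
      snk_p <- tryCatch(realize_array(snk, grid, surf), error = function(e)
        stop(pl$plan_id, " (", pair, "): ", conditionMessage(e)))
      sv <- unlist(lapply(src_p, `[[`, "voxels"))
      kv <- unlist(lapply(snk_p, `[[`, "voxels"))
      tgt <- target_current(src, current_density_mA_cm2)
      sol <- tryCatch(
        solve_pair(sigma, grid$spacing, sv, kv, tgt, tol = tol),
        error = function(e) stop(pl$plan_id, " (", pair, "): ",
                                 conditionMessage(e)))
      pair_fields[[pair]] <- field_magnitude(sol$phi, grid$spacing)
    }
    fields[[i]] <- combine_pairs(pair_fields$AP, pair_fields$LR,
                                 duty_weights, combination)
    meta[[i]] <- data.frame(plan_id = pl$plan_id, plane = pl$plane,
                            angle_deg = pl$angle_deg)
  }

  ref_stats <- field_stats(fields[[1]], mask)
  e_p <- prescribed_field(ref_stats)

  metrics <- do.call(rbind, lapply(seq_along(plans), function(i) {
    m <- plan_metrics(fields[[i]], mask, e_p)
    cbind(meta[[i]], as.data.frame(as.list(m)))
  }))
  rownames(metrics) <- NULL
  # indices normalized to the reference plan (ratios; Table-2 style)
  for (col in c("E_mean", "E_min", "HI", "CI")) {
    ref_v <- metrics[[col]][1]
    metrics[[paste0(col, "_rel")]] <-
      if (ref_v != 0) metrics[[col]] / ref_v else NA_real_
  }

  dvh_list <- list()
  for (tn in dvh_structures) {
    lbl <- as.integer(names(grid$label_names)[grid$label_names == tn])
    if (!length(lbl)) next
    smask <- grid$labels %in% lbl
    dim(smask) <- dim(grid$labels)
    if (!any(smask)) next
    dvh_list[[tn]] <- lapply(fields, function(f) dvh(f, smask, e_p))
  }

  res <- structure(list(metrics = metrics, E_p = e_p,
                        plans = plans, dvh = dvh_list,
                        center = center), class = "scan_result")
  if (length(plans) > 1) {
    res$best <- vapply(c("E_mean", "E_min", "HI", "CI"),
                       function(ix) select_best(res, ix), "")
    res$improvement_pct <- vapply(c("E_mean", "E_min", "HI", "CI"),
                                  function(ix) {
                                    b <- res$best[[ix]]
                                    improvement(metrics[[ix]][1],
                                                metrics[[ix]][metrics$plan_id == b],
                                                ix)
                                  }, numeric(1))
  }
  if (keep_fields) res$fields <- fields
  res
}

#' @method print scan_result
#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result> ", nrow(x$metrics), " plans, E_p = ",
      signif(x$E_p, 4), " V/cm\n", sep = "")
  print(x$metrics[, c("plan_id", "plane", "angle_deg", "E_min", "E_mean",
                      "E_max", "HI", "CI")], digits = 4)
  if (!is.null(x$best)) {
    cat("best trial plan per index:\n")
    for (ix in names(x$best))
      cat(sprintf("  %-7s %s (%+.2f%%)\n", ix, x$best[[ix]],
                  x$improvement_pct[[ix]]))
  }
  invisible(x)
}

#' Select the best trial plan for an index
#'
#' The reference plan (first row) is excluded: only the trial plans
#' compete. HI is minimized; E_mean, E_min and CI are maximized. Ties
#' break deterministically toward the plan closest to the reference
#' geometry: smallest |angle|, then axial before sagittal, then
#' positive angle before negative.
#'
#' @param scan a `scan_result`.
#' @param index one of "E_mean", "E_min", "HI", "CI".
#' @return the winning trial plan id.
#' @export
select_best <- function(scan, index) {
  if (!index %in% c("E_mean", "E_min", "HI", "CI"))
    stop("unknown index: ", index)
  m <- scan$metrics[-1, , drop = FALSE]  # trials only
  if (!nrow(m)) stop("no trial plans to select from")
  v <- m[[index]]
  best_v <- if (index == "HI") min(v) else max(v)
  cand <- m[abs(v - best_v) < .Machine$double.eps * 64 | v == best_v, ,
            drop = FALSE]
  ord <- order(abs(cand$angle_deg),
               match(cand$plane, c("axial", "sagittal", "none")),
               -sign(cand$angle_deg))
  cand$plan_id[ord[1]]
}

#' Percentage improvement of the best trial over the reference
#'
#' For E_mean, E_min and CI: (best - ref)/ref x 100. For HI the sign is
#' inverted, (ref - best)/ref x 100, so that positive always means
#' better; a 0/0 HI comparison counts as 0% improvement.
#'
#' @param ref_value reference-plan value of the index.
#' @param best_value best trial-plan value.
#' @param index one of "E_mean", "E_min", "HI", "CI".
#' @return percent improvement (positive = trial better).
#' @export
improvement <- function(ref_value, best_value, index) {
  if (!index %in% c("E_mean", "E_min", "HI", "CI"))
    stop("unknown index: ", index)
  if (index == "HI") {
    if (ref_value == 0) {
      if (best_value == 0) return(0)
      stop("reference HI is 0 but trial HI is not; improvement undefined")
    }
    (ref_value - best_value) / ref_value * 100
  } else {
    if (ref_value <= 0) stop("reference ", index, " must be > 0")
    (best_value - ref_value) / ref_value * 100
  }
}

#' Cohort summary of best-plan improvements
#'
#' Arithmetic mean of the per-phantom best-trial improvements for each
#' index, one summary row for the whole cohort.
#'
#' @param scans list of `scan_result` objects.
#' @return data.frame with one row per index: index, mean_improvement_pct, n.
#' @export
summarize_cohort <- function(scans) {
  if (!length(scans)) stop("empty cohort")
  idx <- c("E_mean", "E_min", "HI", "CI")
  imp <- t(vapply(scans, function(s) s$improvement_pct[idx], numeric(4)))
  data.frame(index = idx,
             mean_improvement_pct = colMeans(imp),
             n = length(scans),
             row.names = NULL)
}
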