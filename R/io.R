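#' Read single-cell trajectory tables
#'
#' Reads the comma-delimited long-format trajectory schema
#' `cell_id,time_min,volume_um3,area_um2[,condition]` (empty fields are
#' missing values; a leading `#` comment line is skipped). Rows are sorted
#' by time within each cell; malformed content is reported with the
#' offending line number.
#'
#' @param path File path.
#' @return A data frame in the trajectory schema.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) {
    stop("read_trajectories: file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("cell_id", "time_min")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("read_trajectories: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!any(c("volume_um3", "area_um2") %in% names(df))) {
    stop("read_trajectories: need at least one of volume_um3, area_um2",
         call. = FALSE)
  }
  for (col in intersect(c("volume_um3", "area_um2"), names(df))) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad) > 0) {
      stop("read_trajectories: negative ", col, " at data line ", bad[1],
           call. = FALSE)
    }
  }
  key <- paste(df$cell_id, df$time_min)
  if (anyDuplicated(key)) {
    stop("read_trajectories: duplicate (cell_id, time) pair at data line ",
         which(duplicated(key))[1], call. = FALSE)
  }
  df <- df[order(df$cell_id, df$time_min), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write single-cell trajectory tables
#'
#' Writes the schema read by [read_trajectories()], with a provenance
#' comment line (package version and seed if supplied). Empty fields
#' encode missing values.
#'
#' @param df Trajectory data frame.
#' @param path Output path.
#' @param seed Optional seed to record in the provenance line.
#' @export
write_trajectories <- function(df, path, seed = NULL) {
  hdr <- paste0("# osmovol ",
                as.character(utils::packageVersion("osmovol")),
                if (!is.null(seed)) paste0(" seed=", seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
}

#' Read and write shock protocol files
#'
#' Delimited text with header `time_s,piso_over_p`; one medium-exchange
#' event per row.
#'
#' @param path File path.
#' @param duration,dt Protocol duration and sampling interval (s), for
#'   [read_shock_protocol()].
#' @return `read_shock_protocol`: a [shock_protocol()].
#' @export
read_shock_protocol <- function(path, duration, dt = 1) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "piso_over_p") %in% names(df))) {
    stop("read_shock_protocol: header must be time_s,piso_over_p",
         call. = FALSE)
  }
  shock_protocol(df$time_s, df$piso_over_p, duration = duration, dt = dt)
}

#' @rdname read_shock_protocol
#' @param protocol A [shock_protocol()] to write.
#' @export
write_shock_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "shock_protocol"))
  utils::write.csv(data.frame(time_s = protocol$times_s,
                              piso_over_p = protocol$ratios),
                   path, row.names = FALSE)
}

#' Configuration for a spreading-study run
#'
#' Validated key set for [run_study()]; unknown keys are rejected to catch
#' typos.
#'
#' @param input Path to a trajectory table, or `NULL` to generate a
#'   synthetic cohort from `preset`.
#' @param preset Condition preset name for generation (ignored when
#'   `input` is given).
#' @param n_cells Cohort size for generation.
#' @param out_dir Output directory.
#' @param onset_threshold Onset contact-area threshold (um^2).
#' @param flux_window_min Initial-flux window (min).
#' @param r_growth Growth rate fixed during volume fits (fraction/hr).
#' @param fit_volume Whether to run the (xi, tau) volume fits (the slowest
#'   stage).
#' @param seed Integer seed.
#' @param ... Unknown keys: rejected.
#' @return A list of class `run_config`.
#' @export
study_config <- function(input = NULL, preset = "control", n_cells = 30,
                         out_dir = "results", onset_threshold = 100,
                         flux_window_min = 10, r_growth = 0.05,
                         fit_volume = TRUE, seed = 1, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("study_config: unknown key(s): ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  }
  structure(list(input = input, preset = preset, n_cells = n_cells,
                 out_dir = out_dir, onset_threshold = onset_threshold,
                 flux_window_min = flux_window_min, r_growth = r_growth,
                 fit_volume = fit_volume, seed = seed),
            class = "run_config")
}

#' Run the spreading-study pipeline
#'
#' Chains the analysis stages on a trajectory table (read from
#' `config$input` or generated from the configured preset): onset
#' alignment, area-ansatz fit, optional (xi, tau) volume fit, initial
#' fluxes, speed terciles, and the flux regression. Writes a per-cell
#' results table and a key-value summary under `config$out_dir`, both
#' headed by a provenance line; reruns with the same config and seed are
#' byte-identical.
#'
#' @param config A [study_config()].
#' @return Invisibly, a list with `cells` (per-cell results data frame),
#'   `regression`, `excluded` (cell ids) and the file paths written.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$input)) {
    traj <- read_trajectories(config$input)
    if (!"condition" %in% names(traj)) traj$condition <- "input"
  } else {
    cfg <- condition_preset(config$preset, n_cells = config$n_cells,
                            seed = config$seed)
    traj <- generate_spreading_cohort(cfg)$trajectories
  }
  results <- fit_cohort(traj, onset_threshold = config$onset_threshold,
                        flux_window_min = config$flux_window_min,
                        r_growth = config$r_growth,
                        fit_volume = config$fit_volume)
  cells <- results$cells
  reg <- if (sum(!is.na(cells$dAdt) & !is.na(cells$dVdt)) >= 3) {
    flux_regression(cells$dAdt, cells$dVdt)
  } else NULL

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- paste0("# osmovol ",
                 as.character(utils::packageVersion("osmovol")),
                 " seed=", config$seed)
  cells_path <- file.path(config$out_dir, "cells.csv")
  con <- file(cells_path, "w")
  writeLines(prov, con)
  utils::write.csv(format(cells, digits = 10, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, na = "", quote = FALSE)
  close(con)
  summary_path <- file.path(config$out_dir, "summary.csv")
  lines <- c(prov, "key,value",
             paste0("n_cells,", nrow(cells)),
             paste0("n_excluded,", length(results$excluded)),
             paste0("n_slow,", sum(cells$group == "slow", na.rm = TRUE)),
             paste0("n_moderate,", sum(cells$group == "moderate", na.rm = TRUE)),
             paste0("n_fast,", sum(cells$group == "fast", na.rm = TRUE)))
  if (!is.null(reg)) {
    lines <- c(lines,
               paste0("flux_slope,", format(reg$slope, digits = 10)),
               paste0("flux_intercept,", format(reg$intercept, digits = 10)),
               paste0("flux_r_squared,", format(reg$r_squared, digits = 10)))
  }
  writeLines(lines, summary_path)
  invisible(list(cells = cells, regression = reg,
                 excluded = results$excluded,
                 paths = c(cells = cells_path, summary = summary_path)))
}

#' Per-cell pipeline over a trajectory table
#'
#' Applies onset alignment, the area-ansatz fit, optionally the (xi, tau)
#' volume fit, and the initial-flux slopes to every cell in a long
#' trajectory table, then assigns speed terciles. Cells failing onset
#' detection are excluded and listed, never silently dropped.
#'
#' @param traj Long trajectory data frame
#'   (`cell_id,time_min,volume_um3,area_um2[,condition]`).
#' @param onset_threshold Onset contact-area threshold (um^2).
#' @param flux_window_min Initial-flux window (min).
#' @param r_growth Growth rate fixed during volume fits (fraction/hr).
#' @param fit_volume Whether to fit (xi, tau) per cell.
#' @return A list with `cells` (one row per retained cell: fitted
#'   parameters, fluxes, group, convergence flags) and `excluded`.
#' @export
fit_cohort <- function(traj, onset_threshold = 100, flux_window_min = 10,
                       r_growth = 0.05, fit_volume = TRUE) {
  ids <- unique(traj$cell_id)
  rows <- list()
  excluded <- character(0)
  for (id in ids) {
    cell <- traj[traj$cell_id == id, , drop = FALSE]
    cell <- cell[order(cell$time_min), , drop = FALSE]
    aligned <- tryCatch(align_spreading_onset(cell, onset_threshold),
                        osmovol_onset_error = function(e) NULL)
    if (is.null(aligned)) {
      excluded <- c(excluded, id)
      next
    }
    afit <- fit_area_ansatz(aligned)
    fx <- initial_fluxes(aligned, flux_window_min)
    xi <- tau <- NA_real_
    vconv <- NA
    if (fit_volume && afit$converged && !any(is.na(afit$estimates))) {
      anz <- spreading_ansatz(afit$estimates["A_init"],
                              afit$estimates["A0"],
                              afit$estimates["tau_a"])
      vfit <- try(fit_volume_params(aligned, anz, r_growth = r_growth),
                  silent = TRUE)
      if (!inherits(vfit, "try-error")) {
        xi <- vfit$estimates["xi"]
        tau <- vfit$estimates["tau"]
        vconv <- vfit$converged
      }
    }
    rows[[id]] <- data.frame(
      cell_id = id,
      condition = if ("condition" %in% names(cell)) cell$condition[1] else NA,
      A_init = unname(afit$estimates["A_init"]),
      A0 = unname(afit$estimates["A0"]),
      tau_a = unname(afit$estimates["tau_a"]),
      area_converged = afit$converged,
      xi = unname(xi), tau = unname(tau), volume_converged = vconv,
      dAdt = fx$dAdt, dVdt = fx$dVdt)
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  if (!is.null(cells) && sum(!is.na(cells$dAdt)) >= 3) {
    cells$group <- classify_by_speed(cells$dAdt)
  } else if (!is.null(cells)) {
    cells$group <- NA
  }
  list(cells = cells, excluded = excluded)
}
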