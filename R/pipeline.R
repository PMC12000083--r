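# End-to-end orchestration: dataset -> raw angles -> REFRAME -> comparison
# tables, waveform summaries and plots.

#' Cycle-normalized joint angles for every marker set, knee and trial
#'
#' Mirrors left-side pose series into the right-knee convention, extracts
#' joint angles and resamples each trial onto the normalized gait cycle.
#'
#' @param ds A `marker_set_dataset` ([build_study()] or [read_dataset()]).
#' @param n_norm Samples per normalized cycle (default 101).
#' @return Nested list `angles[[set]][[knee]][[trial]]` of [joint_angles()]
#'   over the percent-cycle domain.
#' @export
dataset_angles <- function(ds, n_norm = 101L) {
  lapply(ds$sets, function(s) {
    lapply(s$trials, function(trials) {
      lapply(trials, function(rec) {
        fem <- rec$femur; tib <- rec$tibia
        if (fem$side == "L" && !isTRUE(fem$mirrored)) {
          fem <- mirror_left_to_right(fem)
          tib <- mirror_left_to_right(tib)
        }
        ja <- compute_joint_angles(fem, tib)
        ev <- fem$events
        if (is.null(ev)) ev <- c(1L, nrow(ja$angles))
        normalize_gait_cycle(ja, ev, n_norm = n_norm)[[1L]]
      })
    })
  })
}

# Concatenate the angle matrices of a knee's trials (n_trials * n_norm x 3).
concat_knee <- function(trials) {
  do.call(rbind, lapply(trials, function(ja) ja$angles))
}

#' Run REFRAME across a whole study
#'
#' Fits one constant correction pair per marker set and knee, using all of
#' the knee's trials concatenated after cycle normalization.  The reference
#' flexion signal is the reference marker set's raw (uncorrected) flexion
#' for the same knee; the reference set itself is optimized against its own
#' raw flexion.
#'
#' @param angles_by_set Output of [dataset_angles()].
#' @param config A [reframe_config()]; `config$reference_label` selects the
#'   reference marker set (falls back to the first set, with a warning, if
#'   absent).
#' @return List with `transforms[[set]][[knee]]` (`reframe_result`s) and
#'   `angles[[set]][[knee]][[trial]]` (corrected [joint_angles()]).
#' @export
reframe_study <- function(angles_by_set, config = reframe_config()) {
  sets <- names(angles_by_set)
  ref_lab <- config$reference_label
  if (!ref_lab %in% sets) {
    warning(sprintf("reference marker set '%s' not present; using '%s'",
                    ref_lab, sets[1L]), call. = FALSE)
    ref_lab <- sets[1L]
  }
  transforms <- list(); corrected <- list()
  for (lab in sets) {
    transforms[[lab]] <- list()
    corrected[[lab]] <- list()
    for (kid in names(angles_by_set[[lab]])) {
      trials <- angles_by_set[[lab]][[kid]]
      m <- concat_knee(trials)
      ref_flex <- concat_knee(angles_by_set[[ref_lab]][[kid]])[, 1L]
      res <- reframe(joint_angles(m, domain = seq_len(nrow(m))),
                     ref_flex, config)
      transforms[[lab]][[kid]] <- res
      n_norm <- nrow(trials[[1L]]$angles)
      corrected[[lab]][[kid]] <- lapply(seq_along(trials), function(i) {
        idx <- ((i - 1L) * n_norm + 1L):(i * n_norm)
        joint_angles(res$optimized$angles[idx, , drop = FALSE],
                     domain = trials[[i]]$domain, domain_type = "pct",
                     rate_hz = trials[[i]]$rate_hz, meta = trials[[i]]$meta)
      })
      names(corrected[[lab]][[kid]]) <- names(trials)
    }
  }
  list(transforms = transforms, angles = corrected,
       reference_label = ref_lab)
}

#' Mean +/- SD waveforms per marker set
#'
#' Pointwise mean and standard deviation across all knees and trials, per
#' marker set and angle channel, in the clinical display sign (flexion
#' positive).
#'
#' @param angles_by_set Nested angle list ([dataset_angles()] or the
#'   corrected angles from [reframe_study()]).
#' @param stage Stage label attached to the rows.
#' @return Data frame with columns `set`, `channel`, `pct`, `mean_deg`,
#'   `sd_deg`, `stage`.
#' @export
mean_sd_waveforms <- function(angles_by_set, stage = "raw") {
  out <- list()
  for (lab in names(angles_by_set)) {
    mats <- unlist(angles_by_set[[lab]], recursive = FALSE)
    if (length(mats) == 1L)
      warning("single trial: SD band has zero width", call. = FALSE)
    pct <- mats[[1L]]$domain
    for (ch in 1:3) {
      sgn <- if (ch == 1L) -1 else 1  # display flexion positive
      vals <- vapply(mats, function(ja) sgn * ja$angles[, ch],
                     numeric(length(pct)))
      vals <- matrix(vals, nrow = length(pct))
      out[[length(out) + 1L]] <- data.frame(
        set = lab, channel = c("flexion", "adduction", "introt")[ch],
        pct = pct,
        mean_deg = rowMeans(vals),
        sd_deg = if (ncol(vals) > 1L) apply(vals, 1L, stats::sd) else 0,
        stage = stage)
    }
  }
  do.call(rbind, out)
}

#' Plot mean +/- SD joint-angle waveforms
#'
#' Three stacked panels (flexion shown positive), x-axis in percent of the
#' gait cycle, one line per marker set with a shaded +/-1 SD band; raw and
#' optimized stages are shown side by side when both are present.
#'
#' @param waveforms Data frame from [mean_sd_waveforms()] (stages may be
#'   row-bound).
#' @return A ggplot object.
#' @export
plot_mean_sd <- function(waveforms) {
  waveforms$channel <- factor(waveforms$channel,
                              levels = c("flexion", "adduction", "introt"),
                              labels = c("Flexion (+) [deg]",
                                         "Ab/Adduction [deg]",
                                         "Int/Ext Rotation [deg]"))
  p <- ggplot2::ggplot(waveforms,
                       ggplot2::aes(x = pct, y = mean_deg,
                                    colour = set, fill = set)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean_deg - sd_deg,
                                      ymax = mean_deg + sd_deg),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.5) +
    ggplot2::labs(x = "% of gait cycle", y = NULL,
                  colour = "Marker set", fill = "Marker set") +
    ggplot2::theme_minimal()
  if (length(unique(waveforms$stage)) > 1L) {
    p + ggplot2::facet_grid(channel ~ stage, scales = "free_y")
  } else {
    p + ggplot2::facet_grid(channel ~ ., scales = "free_y")
  }
}

#' Run the full pipeline
#'
#' Simulates (or loads) a multi-marker-set dataset, extracts and normalizes
#' joint angles, fits REFRAME per marker set and knee, and writes
#' comparison tables, frame transformations, waveform summaries, figures,
#' a run manifest and a log under `out_dir`.
#'
#' @param input A [synthetic_config()], a `marker_set_dataset`, or a path
#'   to a dataset directory ([write_dataset()] layout).
#' @param config A [reframe_config()].
#' @param out_dir Output directory.
#' @param n_norm Samples per normalized gait cycle (default 101).
#' @param make_plots Write figure files (default `TRUE`).
#' @return Invisibly, a list with `angles_raw`, `reframed`, `table_raw`,
#'   `table_reframed`, `waveforms`, `n_not_converged` and `out_dir`.
#' @export
run_pipeline <- function(input, config = reframe_config(), out_dir,
                         n_norm = 101L, make_plots = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("tables", "transforms", "waveforms", "figures"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logline <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(fmt, ...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  if (inherits(input, "synthetic_config")) {
    logline("simulating synthetic study (seed %d)", input$seed)
    ds <- build_study(input)
    source_desc <- list(kind = "synthetic", seed = input$seed)
  } else if (inherits(input, "marker_set_dataset")) {
    ds <- input
    source_desc <- list(kind = "dataset")
  } else if (is.character(input) && length(input) == 1L) {
    logline("reading dataset from %s", input)
    ds <- read_dataset(input)
    source_desc <- list(kind = "path", path = input)
  } else stop_invalid("input must be a synthetic_config, dataset or path")

  logline("extracting and normalizing joint angles (%d-point cycles)", n_norm)
  angles_raw <- dataset_angles(ds, n_norm = n_norm)
  single_set <- length(angles_raw) < 2L
  if (single_set)
    warning("single marker set: pairwise tables will be empty", call. = FALSE)

  logline("running REFRAME (reference: %s)", config$reference_label)
  rf <- reframe_study(angles_raw, config)
  n_bad <- 0L
  for (lab in names(rf$transforms)) for (kid in names(rf$transforms[[lab]])) {
    res <- rf$transforms[[lab]][[kid]]
    logline("  %s / %s: cost %.3f -> %.5f deg, %s", lab, kid,
            res$cost_initial, res$cost_final,
            if (res$converged) "converged" else "NOT converged")
    if (!res$converged) n_bad <- n_bad + 1L
    write_reframe_result(res, file.path(out_dir, "transforms",
                                        sprintf("%s_%s.json", lab, kid)))
  }

  table_raw <- NULL; table_ref <- NULL
  if (!single_set) {
    table_raw <- pairwise_rmse_table(angles_raw, stage = "raw")
    table_ref <- pairwise_rmse_table(rf$angles, stage = "reframed")
    write_comparison_table(table_raw,
                           file.path(out_dir, "tables", "rmse_raw.csv"))
    write_comparison_table(table_ref,
                           file.path(out_dir, "tables", "rmse_reframed.csv"))
  }
  wf <- rbind(mean_sd_waveforms(angles_raw, stage = "raw"),
              mean_sd_waveforms(rf$angles, stage = "reframed"))
  utils::write.csv(wf, file.path(out_dir, "waveforms", "mean_sd.csv"),
                   row.names = FALSE)
  if (make_plots) {
    p <- plot_mean_sd(wf)
    ggplot2::ggsave(file.path(out_dir, "figures", "mean_sd.pdf"), p,
                    width = 9, height = 7)
  }
  manifest <- list(
    tool = "reframekin", version = as.character(utils::packageVersion("reframekin")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input = source_desc,
    reframe_config = unclass(config),
    n_norm = n_norm,
    n_not_converged = n_bad
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (n_bad > 0L)
    warning(sprintf("%d REFRAME fits did not converge", n_bad), call. = FALSE)
  logline("done (%d non-converged fits)", n_bad)
  invisible(list(dataset = ds, angles_raw = angles_raw, reframed = rf,
                 table_raw = table_raw, table_reframed = table_ref,
                 waveforms = wf, n_not_converged = n_bad, out_dir = out_dir))
}
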