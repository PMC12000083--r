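# Waveform comparison metrics and their mean +/- SD aggregation.

#' Root-mean-square error between two waveforms
#'
#' @param a,b Numeric vectors of equal length (degrees).
#' @return `sqrt(mean((a - b)^2))`, in degrees.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("waveforms must have equal length")
  if (length(a) < 1L) stop_invalid("waveforms must be non-empty")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop_invalid("waveforms must be finite")
  sqrt(mean((a - b)^2))
}

#' Root-mean-square of a waveform
#'
#' Equivalent to the RMSE of the waveform against constant zero.
#'
#' @param a Numeric vector (degrees).
#' @return RMS value in degrees.
#' @export
rms <- function(a) {
  if (length(a) < 1L) stop_invalid("waveform must be non-empty")
  rmse(a, rep(0, length(a)))
}

#' Two-level mean +/- SD aggregation of per-trial values
#'
#' Aggregates trial-level values (i) per knee across its trials and
#' (ii) overall across all trials and knees, using the sample standard
#' deviation (n - 1).  Groups of size one report SD 0 with a warning flag.
#'
#' @param values Numeric vector of per-trial values.
#' @param knee Vector of knee identifiers, same length as `values`.
#' @return A list with data frames `per_knee` (columns `knee`, `mean`,
#'   `sd`, `n`, `single`) and `overall` (one row, same columns without
#'   `knee`).
#' @export
aggregate_trials <- function(values, knee) {
  if (length(values) < 1L) stop_invalid("no values to aggregate")
  if (length(values) != length(knee))
    stop_invalid("values and knee must have equal length")
  agg1 <- function(v) {
    n <- length(v)
    single <- n == 1L
    if (single)
      warning("group of size 1: SD reported as 0", call. = FALSE)
    c(mean = mean(v), sd = if (single) 0 else stats::sd(v), n = n,
      single = as.numeric(single))
  }
  ks <- unique(knee)
  per <- t(vapply(ks, function(k) agg1(values[knee == k]), numeric(4L)))
  per_knee <- data.frame(knee = ks, mean = per[, 1L], sd = per[, 2L],
                         n = as.integer(per[, 3L]),
                         single = per[, 4L] > 0, row.names = NULL)
  ov <- agg1(values)
  overall <- data.frame(mean = ov[1L], sd = ov[2L], n = as.integer(ov[3L]),
                        single = ov[4L] > 0, row.names = NULL)
  list(per_knee = per_knee, overall = overall)
}

# Channel labels used in comparison tables, in fixed display order.
.channels <- c("flexion", "adduction", "introt")

#' Pairwise RMSE comparison table across marker sets
#'
#' For every unordered pair of marker sets and each angle channel, computes
#' the RMSE between cycle-normalized waveforms per knee and trial, then
#' aggregates to mean +/- SD (overall across all trials and knees, and
#' optionally per knee).
#'
#' @param angles_by_set Nested named list:
#'   `angles_by_set[[set]][[knee]][[trial]]` is a [joint_angles()] series
#'   (or an n x 3 angle matrix); all sets must share the same knee/trial
#'   keys and sample counts.
#' @param stage Stage label stored with the table, e.g. `"raw"` or
#'   `"reframed"`.
#' @param level `"overall"` (default) or `"per_knee"`.
#' @return A `comparison_table`: a data frame with columns `set_a`,
#'   `set_b`, `channel`, `stage`, `mean_deg`, `sd_deg`, `n` (plus `knee`
#'   when `level = "per_knee"`).
#' @export
pairwise_rmse_table <- function(angles_by_set, stage = "raw",
                                level = c("overall", "per_knee")) {
  level <- match.arg(level)
  sets <- names(angles_by_set)
  if (length(sets) < 2L)
    stop_invalid("at least two marker sets are required")
  keys <- lapply(angles_by_set, function(s)
    unlist(lapply(names(s), function(k) paste(k, names(s[[k]]), sep = "/"))))
  ref_keys <- sort(keys[[1L]])
  for (s in sets[-1L]) {
    miss <- c(setdiff(ref_keys, keys[[s]]), setdiff(keys[[s]], ref_keys))
    if (length(miss))
      stop_missing_data(sprintf("marker set '%s' has unmatched knee/trial keys", s),
                        miss)
  }
  get_mat <- function(x) if (inherits(x, "joint_angles")) x$angles else as.matrix(x)
  rows <- list()
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (j <= i) next
    a <- sets[i]; b <- sets[j]
    knees <- names(angles_by_set[[a]])
    per_trial <- do.call(rbind, lapply(knees, function(k) {
      trials <- names(angles_by_set[[a]][[k]])
      do.call(rbind, lapply(trials, function(tr) {
        ma <- get_mat(angles_by_set[[a]][[k]][[tr]])
        mb <- get_mat(angles_by_set[[b]][[k]][[tr]])
        data.frame(knee = k, trial = tr,
                   channel = .channels,
                   value = vapply(1:3, function(ch) rmse(ma[, ch], mb[, ch]),
                                  numeric(1L)))
      }))
    }))
    for (ch in .channels) {
      sub <- per_trial[per_trial$channel == ch, ]
      agg <- suppressWarnings(aggregate_trials(sub$value, sub$knee))
      if (level == "overall") {
        rows[[length(rows) + 1L]] <- data.frame(
          set_a = a, set_b = b, channel = ch, stage = stage,
          mean_deg = agg$overall$mean, sd_deg = agg$overall$sd,
          n = agg$overall$n)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          set_a = a, set_b = b, channel = ch, stage = stage,
          knee = agg$per_knee$knee, mean_deg = agg$per_knee$mean,
          sd_deg = agg$per_knee$sd, n = agg$per_knee$n)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "level") <- level
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Render a comparison table as text
#'
#' Lays the table out as a marker-set grid (one block per channel) with
#' `mean +/- SD` cells and empty diagonal, the conventional presentation
#' for pairwise waveform RMSE.
#'
#' @param x A `comparison_table` at overall level.
#' @param ... Unused.
#' @return Character vector of lines.
#' @export
format.comparison_table <- function(x, ...) {
  if (!identical(attr(x, "level"), "overall"))
    return(format(as.data.frame(unclass(x))))
  sets <- unique(c(x$set_a, x$set_b))
  lines <- sprintf("Pairwise RMSE (deg), stage: %s", x$stage[1L])
  for (ch in unique(x$channel)) {
    lines <- c(lines, paste0("  [", ch, "]"))
    hdr <- sprintf("  %-12s", "")
    for (s in sets) hdr <- paste0(hdr, sprintf("%-16s", s))
    lines <- c(lines, hdr)
    for (a in sets) {
      row <- sprintf("  %-12s", a)
      for (b in sets) {
        if (a == b) { row <- paste0(row, sprintf("%-16s", "-")); next }
        hit <- x[x$channel == ch &
                   ((x$set_a == a & x$set_b == b) |
                      (x$set_a == b & x$set_b == a)), ]
        cell <- sprintf("%.1f +/- %.1f", hit$mean_deg[1L], hit$sd_deg[1L])
        row <- paste0(row, sprintf("%-16s", cell))
      }
      lines <- c(lines, row)
    }
  }
  lines
}

#' Write a comparison table as long-format CSV
#'
#' @param x A `comparison_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = FALSE)
  invisible(path)
}
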