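# Plain-text serialization: pose/angle series CSVs with JSON sidecars, and
# whole-dataset directories.

sidecar_path <- function(path) paste0(path, ".json")

series_sidecar <- function(x) {
  list(knee = x$meta$knee, side = x$side, trial = x$meta$trial,
       marker_set = x$meta$marker_set, rate_hz = x$rate_hz,
       mirrored = x$mirrored, events = x$events)
}

#' Write a femur/tibia pose pair as CSV with JSON sidecar
#'
#' CSV columns: `sample, time_s, seg, r11..r33` (row-major rotation
#' entries, `seg` in `femur`/`tibia`); a sidecar JSON (`<path>.json`)
#' carries knee id, side, trial, marker-set label, sampling rate, the
#' mirrored flag and event indices.
#'
#' @param femur,tibia [pose_series()] objects of equal length.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(femur, tibia, path) {
  one <- function(x) {
    n <- dim(x$R)[3L]
    m <- t(matrix(x$R, nrow = 9L))  # row of column-major entries per sample
    # reorder column-major (r11 r21 r31 r12 ...) -> row-major r11 r12 ...
    m <- m[, c(1L, 4L, 7L, 2L, 5L, 8L, 3L, 6L, 9L), drop = FALSE]
    colnames(m) <- c("r11", "r12", "r13", "r21", "r22", "r23",
                     "r31", "r32", "r33")
    data.frame(sample = seq_len(n), time_s = x$time_s, seg = x$seg, m)
  }
  df <- rbind(one(femur), one(tibia))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(series_sidecar(femur), sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a femur/tibia pose pair written by [write_pose_csv()]
#'
#' @param path CSV path (sidecar expected at `<path>.json`).
#' @return List with `femur` and `tibia` [pose_series()] objects.
#' @export
read_pose_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  one <- function(seg) {
    sub <- df[df$seg == seg, , drop = FALSE]
    sub <- sub[order(sub$sample), , drop = FALSE]
    n <- nrow(sub)
    ent <- as.matrix(sub[, c("r11", "r21", "r31", "r12", "r22", "r32",
                             "r13", "r23", "r33")])
    R <- array(t(ent), c(3L, 3L, n))
    pose_series(R, rate_hz = meta$rate_hz, seg = seg,
                side = if (is.null(meta$side)) "R" else meta$side,
                mirrored = isTRUE(meta$mirrored),
                events = meta$events, time_s = sub$time_s,
                meta = list(knee = meta$knee, trial = meta$trial,
                            marker_set = meta$marker_set),
                check = FALSE)
  }
  list(femur = one("femur"), tibia = one("tibia"))
}

#' Write a joint-angle series as CSV with JSON sidecar
#'
#' CSV columns: `sample, pct_cycle, flex_deg, add_deg, introt_deg`, with
#' flexion in the clinical display sign (positive flexion).
#'
#' @param x A [joint_angles()] series.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_angle_csv <- function(x, path) {
  if (!inherits(x, "joint_angles")) stop_invalid("x must be a joint_angles series")
  disp <- to_clinical_display(x)
  df <- data.frame(sample = seq_len(nrow(disp)),
                   pct_cycle = if (x$domain_type == "pct") x$domain else NA,
                   flex_deg = disp$flex_deg, add_deg = disp$add_deg,
                   introt_deg = disp$introt_deg)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  side <- list(domain_type = x$domain_type, rate_hz = x$rate_hz,
               knee = x$meta$knee, trial = x$meta$trial,
               marker_set = x$meta$marker_set)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a joint-angle series written by [write_angle_csv()]
#'
#' @param path CSV path.
#' @return A [joint_angles()] series (internal sign convention restored).
#' @export
read_angle_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  ang <- cbind(-df$flex_deg, df$add_deg, df$introt_deg)
  if (identical(meta$domain_type, "pct")) {
    joint_angles(ang, domain = df$pct_cycle, domain_type = "pct",
                 rate_hz = meta$rate_hz,
                 meta = list(knee = meta$knee, trial = meta$trial,
                             marker_set = meta$marker_set))
  } else {
    joint_angles(ang, domain_type = "frame", rate_hz = meta$rate_hz,
                 meta = list(knee = meta$knee, trial = meta$trial,
                             marker_set = meta$marker_set))
  }
}

#' Write a synthetic dataset to a directory
#'
#' Layout: one sub-directory per marker set holding one pose CSV (plus
#' sidecar) per knee/trial; `manifest.json` with the design keys, seed and
#' per-set misalignment constants; `ground_truth.json` with the true joint
#' angles per knee/trial.
#'
#' @param ds A `marker_set_dataset` from [build_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  if (!inherits(ds, "marker_set_dataset"))
    stop_invalid("ds must be a marker_set_dataset")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lab in names(ds$sets)) {
    sdir <- file.path(dir, lab)
    dir.create(sdir, showWarnings = FALSE)
    for (kid in names(ds$sets[[lab]]$trials)) {
      for (tr in names(ds$sets[[lab]]$trials[[kid]])) {
        rec <- ds$sets[[lab]]$trials[[kid]][[tr]]
        write_pose_csv(rec$femur, rec$tibia,
                       file.path(sdir, sprintf("%s_%s.csv", kid, tr)))
      }
    }
  }
  manifest <- list(
    design = ds$design,
    seed = ds$config$seed,
    rate_hz = ds$config$rate_hz,
    trials_per_knee = ds$config$trials_per_knee,
    marker_sets = lapply(ds$sets, function(s)
      list(fem = s$misalignment$fem, tib = s$misalignment$tib,
           sta_scale = s$sta_scale))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  truth <- lapply(ds$truth, function(trials)
    lapply(trials, function(ja) unname(ja$angles)))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       digits = NA)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A `marker_set_dataset` (the stored `config` holds only the
#'   fields recorded in the manifest).
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  design <- as.data.frame(man$design)
  sets <- lapply(man$marker_sets, function(s) {
    list(misalignment = list(fem = s$fem, tib = s$tib),
         sta_scale = s$sta_scale, trials = list())
  })
  for (lab in names(sets)) {
    sdir <- file.path(dir, lab)
    files <- list.files(sdir, pattern = "\\.csv$", full.names = TRUE)
    for (f in files) {
      pair <- read_pose_csv(f)
      kid <- pair$femur$meta$knee
      tr <- sprintf("T%d", pair$femur$meta$trial)
      sets[[lab]]$trials[[kid]][[tr]] <- pair
    }
    sets[[lab]]$trials <- sets[[lab]]$trials[design$knee]
  }
  truth <- NULL
  tp <- file.path(dir, "ground_truth.json")
  if (file.exists(tp)) {
    raw <- jsonlite::read_json(tp, simplifyVector = TRUE)
    truth <- lapply(raw, function(trials)
      lapply(seq_len(dim(trials)[1L]), function(i)
        joint_angles(trials[i, , ], domain_type = "frame",
                     rate_hz = man$rate_hz)))
  }
  cfg <- list(seed = man$seed, rate_hz = man$rate_hz,
              trials_per_knee = man$trials_per_knee)
  structure(list(config = cfg, design = design, truth = truth, sets = sets),
            class = "marker_set_dataset")
}
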