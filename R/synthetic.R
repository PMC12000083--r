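# Synthetic multi-marker-set gait study generator.
#
# One underlying tibio-femoral motion per knee/trial is observed through
# several "marker sets" that differ only by constant misorientations of the
# femoral and tibial frames (plus an optional flexion-coupled soft-tissue
# perturbation), so every pipeline stage can be tested against known ground
# truth.

# Harmonic shape coefficients for the two flexion bumps (unit peak, exact
# zero at 0% cycle).  Obtained once by projecting smooth sin^2 bump
# prototypes (stance bump on 0-40% of the cycle, swing bump on 55-100%)
# onto 8 harmonics; the partial sums below ARE the closed-form waveforms.
.stance_shape <- list(
  a = c(0.1114532255, -0.2103909581, -0.1147587044, 0.0150033188,
        0.0000000000, -0.0032780360, 0.0031637738, -0.0020492626),
  b = c(0.3430177572, 0.1528579786, -0.0833770792, -0.0461754673,
        0.0000000000, -0.0100887576, -0.0022986162, -0.0014888764)
)
.swing_shape <- list(
  a = c(0.0615973028, -0.2458924035, -0.0521207320, 0.0168736229,
        -0.0078261226, 0.0040060324, -0.0020591267, 0.0009765794),
  b = c(-0.3889100637, -0.0798952851, 0.1022926962, 0.0122594046,
        0.0078261226, 0.0055138305, 0.0010491775, 0.0030056022)
)
# The constant term makes each shape exactly zero at 0% of the cycle.
.stance_shape$c0 <- -sum(.stance_shape$a)
.swing_shape$c0 <- -sum(.swing_shape$a)

# Evaluate a harmonic shape (trig polynomial) at cycle fractions p in [0,1].
eval_shape <- function(shape, p, n_harmonics = 8L) {
  n_harmonics <- min(n_harmonics, length(shape$a))
  y <- rep(shape$c0, length(p))
  for (k in seq_len(n_harmonics))
    y <- y + shape$a[k] * cos(2 * pi * k * p) + shape$b[k] * sin(2 * pi * k * p)
  y
}

#' Ground-truth gait waveforms
#'
#' Closed-form harmonic waveforms emulating treadmill gait: a flexion curve
#' with an early-stance flexion wave and a swing peak, a double-bump
#' ab/adduction excursion and a smooth int/external rotation excursion.
#' The ab/adduction shape is deliberately decorrelated from the axial
#' rotation shape (second vs first harmonic) so that no constant frame
#' re-orientation can collapse one true channel into the other.  All
#' channels are exactly zero at 0% (and 100%) of the cycle.
#'
#' @param p Cycle fraction(s) in `[0, 1]`.
#' @param stance_peak_deg,swing_peak_deg Peak displayed flexion of the
#'   stance and swing bumps, degrees.
#' @param n_harmonics Number of harmonics of the flexion shapes to use
#'   (max 8; default 8).
#' @return `gait_flexion_deg`: displayed (positive) flexion in degrees.
#' @export
gait_flexion_deg <- function(p, stance_peak_deg = 18, swing_peak_deg = 60,
                             n_harmonics = 8L) {
  stance_peak_deg * eval_shape(.stance_shape, p, n_harmonics) +
    swing_peak_deg * eval_shape(.swing_shape, p, n_harmonics)
}

#' @rdname gait_flexion_deg
#' @param amp_deg Amplitude parameter in degrees.
#' @export
gait_adduction_deg <- function(p, amp_deg = 1.5) {
  amp_deg * sin(4 * pi * p)
}

#' @rdname gait_flexion_deg
#' @export
gait_introt_deg <- function(p, amp_deg = 2.5) {
  amp_deg * (sin(2 * pi * p) + 0.3 * sin(4 * pi * p))
}

#' Default per-marker-set frame misalignments
#'
#' Constant femoral and tibial frame misorientations (Cardan triplets,
#' degrees) imposed on each synthetic marker set, loosely patterned on the
#' magnitudes reported for real marker sets: longitudinal (z) offsets of
#' order a few to fifteen degrees, x/y offsets of a few degrees.
#' `sta_scale` scales the soft-tissue-artifact amplitude per set (the
#' cylinder-fit style set gets a small residual).
#'
#' @return Named list of per-set specs with elements `fem`, `tib`
#'   (length-3 Cardan triplets in degrees) and `sta_scale`.
#' @export
marker_set_presets <- function() {
  list(
    PiG        = list(fem = c(0.5, -2.0, 14.0), tib = c(-0.5, 1.0, 8.0),
                      sta_scale = 1.0),
    PiG_wand   = list(fem = c(2.5, -1.0, 2.5), tib = c(1.0, -1.5, 2.0),
                      sta_scale = 1.0),
    MA         = list(fem = c(2.5, -1.0, 2.8), tib = c(1.2, -1.2, 2.2),
                      sta_scale = 1.0),
    KAD        = list(fem = c(1.5, -0.5, 6.0), tib = c(0.8, 0.5, 12.0),
                      sta_scale = 1.0),
    MiKneeSoTA = list(fem = c(2.0, -2.0, -1.0), tib = c(-1.0, 1.5, -2.0),
                      sta_scale = 0.2)
  )
}

#' Synthetic study configuration
#'
#' Defaults emulate the study design: 15 subjects x 2 knees x 9 recorded
#' steps at 200 Hz, five marker sets differing by constant frame
#' misorientations, treadmill gait at a standardized speed (cycle duration
#' 1.1 s).
#'
#' @param n_subjects Number of subjects (default 15).
#' @param knees_per_subject Knees per subject (default 2; the second knee
#'   of each subject is generated as a left knee).
#' @param trials_per_knee Recorded steps per knee (default 9).
#' @param rate_hz Sampling rate in Hz (default 200).
#' @param cycle_s Gait cycle duration in seconds (default 1.1).
#' @param stance_peak_deg,swing_peak_deg,n_harmonics Flexion waveform
#'   parameters (see [gait_flexion_deg()]).
#' @param add_amp_deg,introt_amp_deg Ground-truth ab/adduction and
#'   int/external rotation amplitudes in degrees (defaults 1.5 and 2.5).
#' @param hip_rom_deg Range of the femoral (hip flexion) excursion used to
#'   animate the femur in the lab frame, degrees (default 40).
#' @param marker_sets Per-set misalignment specs ([marker_set_presets()]).
#' @param sta_amp_deg Soft-tissue-artifact rotation amplitude in degrees
#'   (default 1; set 0 to disable).
#' @param sta_coupling Dimensionless coupling of STA amplitude to
#'   instantaneous flexion (default 1).
#' @param amp_sd Relative SD of per-trial waveform amplitude variability
#'   (default 0.05).
#' @param timing_sd SD of per-trial cycle phase jitter, in cycle fractions
#'   (default 0).
#' @param seed RNG seed; a fixed seed makes [build_study()] output
#'   byte-identical across runs.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 15L, knees_per_subject = 2L,
                             trials_per_knee = 9L, rate_hz = 200,
                             cycle_s = 1.1,
                             stance_peak_deg = 18, swing_peak_deg = 60,
                             n_harmonics = 8L,
                             add_amp_deg = 1.5, introt_amp_deg = 2.5,
                             hip_rom_deg = 40,
                             marker_sets = marker_set_presets(),
                             sta_amp_deg = 1, sta_coupling = 1,
                             amp_sd = 0.05, timing_sd = 0,
                             seed = 1L) {
  if (any(c(n_subjects, knees_per_subject, trials_per_knee) < 1L))
    stop_invalid("design counts must be >= 1")
  if (any(c(stance_peak_deg, swing_peak_deg, add_amp_deg, introt_amp_deg,
            sta_amp_deg, amp_sd, timing_sd) < 0))
    stop_invalid("amplitudes and SDs must be non-negative")
  structure(
    list(n_subjects = as.integer(n_subjects),
         knees_per_subject = as.integer(knees_per_subject),
         trials_per_knee = as.integer(trials_per_knee),
         rate_hz = rate_hz, cycle_s = cycle_s,
         stance_peak_deg = stance_peak_deg, swing_peak_deg = swing_peak_deg,
         n_harmonics = as.integer(n_harmonics),
         add_amp_deg = add_amp_deg, introt_amp_deg = introt_amp_deg,
         hip_rom_deg = hip_rom_deg,
         marker_sets = marker_sets,
         sta_amp_deg = sta_amp_deg, sta_coupling = sta_coupling,
         amp_sd = amp_sd, timing_sd = timing_sd,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate the ground-truth motion of one knee
#'
#' Draws per-trial amplitude (and optionally timing) perturbations and
#' evaluates the closed-form waveforms; flexion is stored as negative
#' `alpha_x` per the rotation convention.
#'
#' @param config A [synthetic_config()].
#' @param knee_seed Integer seed for this knee's trial perturbations.
#' @return A list of `trials_per_knee` [joint_angles()] series (frame
#'   domain, right-knee convention).
#' @export
generate_base_motion <- function(config, knee_seed) {
  set.seed(knee_seed)
  n <- max(2L, round(config$rate_hz * config$cycle_s))
  p0 <- (seq_len(n) - 1L) / (n - 1L)  # 0..1 inclusive, one full cycle
  lapply(seq_len(config$trials_per_knee), function(tr) {
    sc <- 1 + stats::rnorm(3L, 0, config$amp_sd)
    shift <- if (config$timing_sd > 0) stats::rnorm(1L, 0, config$timing_sd) else 0
    p <- (p0 + shift) %% 1
    flex <- sc[1L] * gait_flexion_deg(p, config$stance_peak_deg,
                                      config$swing_peak_deg,
                                      config$n_harmonics)
    addv <- sc[2L] * gait_adduction_deg(p, config$add_amp_deg)
    intr <- sc[3L] * gait_introt_deg(p, config$introt_amp_deg)
    joint_angles(cbind(-flex, addv, intr), domain_type = "frame",
                 rate_hz = config$rate_hz, meta = list(trial = tr))
  })
}

# Smooth zero-mean perturbation series used for the STA model: a random
# low-order harmonic series, standardized to unit RMS.
smooth_noise <- function(p, n_harm = 3L) {
  w <- stats::rnorm(2L * n_harm) / rep(seq_len(n_harm), each = 2L)
  y <- rep(0, length(p))
  for (k in seq_len(n_harm))
    y <- y + w[2L * k - 1L] * sin(2 * pi * k * p) + w[2L * k] * cos(2 * pi * k * p)
  y <- y - mean(y)
  s <- sqrt(mean(y^2))
  if (s > 0) y / s else y
}

#' Observe a true motion through one marker set
#'
#' Builds nominal femoral and tibial pose series realizing the true joint
#' rotation (the femur swings about the lab mediolateral axis like a hip),
#' post-multiplies each segment's orientation by the set's constant frame
#' misalignment, and optionally adds a zero-mean, flexion-coupled
#' soft-tissue rotation emulating swing-phase crosstalk.
#'
#' @param truth A [joint_angles()] series of true joint angles.
#' @param misalignment List with `fem` and `tib` Cardan triplets (degrees).
#' @param config A [synthetic_config()] (supplies rate, hip excursion and
#'   the STA model).
#' @param sta_scale Per-set STA amplitude scale (default 1).
#' @param trial_seed Integer seed for the STA realization.
#' @return List with `femur` and `tibia` [pose_series()] objects
#'   (right-side convention) with events at the cycle boundaries.
#' @export
observe_through_marker_set <- function(truth, misalignment, config,
                                       sta_scale = 1, trial_seed = 1L) {
  n <- nrow(truth$angles)
  p <- (seq_len(n) - 1L) / (n - 1L)
  hip <- -config$hip_rom_deg * (0.5 * cos(2 * pi * p) - 0.2 * cos(4 * pi * p))
  Tarr <- cardan_series_to_array(truth$angles)
  Fem <- cardan_series_to_array(cbind(hip, 0, 0))
  Tib <- array(0, c(3L, 3L, n))
  for (i in 1:3) for (k in 1:3) {
    acc <- 0
    for (j in 1:3) acc <- acc + Fem[i, j, ] * Tarr[j, k, ]
    Tib[i, k, ] <- acc
  }
  Rm_f <- cardan_to_matrix(misalignment$fem)
  Rm_t <- cardan_to_matrix(misalignment$tib)
  post <- function(arr, M) {
    out <- array(0, c(3L, 3L, n))
    for (i in 1:3) for (k in 1:3) {
      acc <- 0
      for (j in 1:3) acc <- acc + arr[i, j, ] * M[j, k]
      out[i, k, ] <- acc
    }
    out
  }
  Fobs <- post(Fem, Rm_f)
  Tobs <- post(Tib, Rm_t)
  amp <- config$sta_amp_deg * sta_scale
  if (amp > 0) {
    set.seed(trial_seed)
    flex_disp <- -truth$angles[, 1L]
    coupling <- config$sta_coupling * flex_disp / max(1, config$swing_peak_deg)
    wobble <- function() {
      phi <- stats::runif(2L, 0, 2 * pi)
      ang_y <- amp * (coupling * sin(4 * pi * p + phi[1L]) +
                        0.3 * smooth_noise(p))
      ang_z <- amp * (coupling * sin(4 * pi * p + phi[2L]) +
                        0.3 * smooth_noise(p))
      cardan_series_to_array(cbind(0, ang_y, ang_z))
    }
    post_series <- function(arr, W) {
      out <- array(0, c(3L, 3L, n))
      for (i in 1:3) for (k in 1:3) {
        acc <- 0
        for (j in 1:3) acc <- acc + arr[i, j, ] * W[j, k, ]
        out[i, k, ] <- acc
      }
      out
    }
    Fobs <- post_series(Fobs, wobble())
    Tobs <- post_series(Tobs, wobble())
  }
  ev <- c(1L, n)
  list(
    femur = pose_series(Fobs, config$rate_hz, seg = "femur", events = ev,
                        check = FALSE),
    tibia = pose_series(Tobs, config$rate_hz, seg = "tibia", events = ev,
                        check = FALSE)
  )
}

#' Build a full synthetic multi-marker-set study
#'
#' Assembles the complete marker-set x knee x trial cross product.  Left
#' knees (the second knee of each subject) are generated in left-side
#' coordinates; downstream processing must pass them through
#' [mirror_left_to_right()], exercising the side convention.
#'
#' @param config A [synthetic_config()].
#' @return A `marker_set_dataset`: list with `config`, `design` (data
#'   frame of subject/knee/side), `truth` (`truth[[knee]][[trial]]` true
#'   [joint_angles()]), and `sets`
#'   (`sets[[label]]$trials[[knee]][[trial]]` with `femur`/`tibia`
#'   [pose_series()], plus the set's `misalignment`).
#' @export
build_study <- function(config = synthetic_config()) {
  design <- do.call(rbind, lapply(seq_len(config$n_subjects), function(s)
    do.call(rbind, lapply(seq_len(config$knees_per_subject), function(k)
      data.frame(subject = s, knee_index = k,
                 knee = sprintf("S%02d_K%d", s, k),
                 side = if (k %% 2L == 0L) "L" else "R")))))
  truth <- list()
  sets <- lapply(config$marker_sets, function(ms)
    list(misalignment = ms[c("fem", "tib")], sta_scale = ms$sta_scale,
         trials = list()))
  set_names <- names(config$marker_sets)
  for (r in seq_len(nrow(design))) {
    kid <- design$knee[r]
    knee_seed <- config$seed * 10000L + r
    trials <- generate_base_motion(config, knee_seed)
    truth[[kid]] <- trials
    for (si in seq_along(set_names)) {
      lab <- set_names[si]
      ms <- config$marker_sets[[lab]]
      per_trial <- lapply(seq_along(trials), function(tr) {
        obs <- observe_through_marker_set(
          trials[[tr]], ms, config, sta_scale = ms$sta_scale,
          trial_seed = knee_seed + 100L * si + tr)
        if (design$side[r] == "L") {
          obs$femur$R <- mirror_orientation(obs$femur$R)
          obs$tibia$R <- mirror_orientation(obs$tibia$R)
          obs$femur$side <- "L"; obs$tibia$side <- "L"
        }
        obs$femur$meta <- list(knee = kid, trial = tr, marker_set = lab)
        obs$tibia$meta <- obs$femur$meta
        obs
      })
      names(per_trial) <- sprintf("T%d", seq_along(trials))
      sets[[lab]]$trials[[kid]] <- per_trial
    }
  }
  names(truth) <- design$knee
  structure(
    list(config = config, design = design, truth = truth, sets = sets),
    class = "marker_set_dataset"
  )
}

#' @export
print.marker_set_dataset <- function(x, ...) {
  cat(sprintf("<marker_set_dataset> %d marker sets x %d knees x %d trials\n",
              length(x$sets), nrow(x$design), x$config$trials_per_knee))
  invisible(x)
}
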