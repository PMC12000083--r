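# Fixtures built in code: small noiseless study configurations and observed
# single-trial series with known imposed misalignments.

tiny_config <- function(...) {
  defaults <- list(n_subjects = 1L, knees_per_subject = 2L,
                   trials_per_knee = 2L, rate_hz = 100, cycle_s = 1.0,
                   sta_amp_deg = 0, amp_sd = 0, seed = 42L)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# One noiseless pure-flexion trial observed through a given misalignment,
# returned as a cycle-normalized joint_angles series.
observed_trial <- function(mis, n_norm = 101L, seed = 5L,
                           add_amp = 0, introt_amp = 0) {
  cfg <- synthetic_config(n_subjects = 1L, knees_per_subject = 1L,
                          trials_per_knee = 1L, rate_hz = 100, cycle_s = 1.0,
                          add_amp_deg = add_amp, introt_amp_deg = introt_amp,
                          sta_amp_deg = 0, amp_sd = 0, seed = seed)
  truth <- generate_base_motion(cfg, seed)[[1L]]
  obs <- observe_through_marker_set(truth, mis, cfg, sta_scale = 0)
  ja <- compute_joint_angles(obs$femur, obs$tibia)
  list(truth = truth,
       normalized = normalize_gait_cycle(ja, c(1L, nrow(ja$angles)),
                                         n_norm = n_norm)[[1L]])
}

random_triplet <- function(max_deg = 85) {
  c(stats::runif(1, -max_deg, max_deg),
    stats::runif(1, -max_deg, max_deg),
    stats::runif(1, -max_deg, max_deg))
}

# Rotation angle (deg) of a rotation matrix, for "distance from identity".
rotation_angle_deg <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}
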