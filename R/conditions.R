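# Structured conditions used across the package.

stop_invalid <- function(msg, ..., call. = FALSE) {
  cnd <- structure(
    class = c("reframekin_invalid_argument", "reframekin_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  )
  stop(cnd)
}

stop_invalid_state <- function(msg, ...) {
  cnd <- structure(
    class = c("reframekin_invalid_state", "reframekin_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  )
  stop(cnd)
}

# Degenerate (gimbal-locked) orientation: |cos(beta_y)| below tolerance.
# `resolution` carries the conventional fallback triplet (gamma_z = 0, the
# free rotation folded into alpha_x); `samples` the offending sample indices
# when raised from a series.
stop_gimbal <- function(resolution, samples = NULL) {
  msg <- sprintf(
    "degenerate orientation: |beta_y| within gimbal tolerance of 90 degrees%s (conventional resolution: alpha_x = %.6f, beta_y = %.6f, gamma_z = 0)",
    if (is.null(samples)) "" else
      sprintf(" at sample(s) %s", paste(utils::head(samples, 5L), collapse = ", ")),
    resolution[1L], resolution[2L]
  )
  cnd <- structure(
    class = c("reframekin_gimbal_error", "reframekin_error",
              "error", "condition"),
    list(message = msg, call = NULL, resolution = resolution, samples = samples)
  )
  stop(cnd)
}

stop_missing_data <- function(msg, keys) {
  cnd <- structure(
    class = c("reframekin_missing_data", "reframekin_error",
              "error", "condition"),
    list(message = paste0(msg, ": ", paste(keys, collapse = ", ")),
         call = NULL, keys = keys)
  )
  stop(cnd)
}
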