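# Small 3-vector helpers shared across modules. Coordinates are always
# n x 3 numeric matrices in Angstrom.

vec_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

vec_norm <- function(u) sqrt(sum(u^2))

vec_unit <- function(u) {
  n <- vec_norm(u)
  if (n < .Machine$double.eps^0.5) {
    abort_geometry("Cannot normalize a (near-)zero vector.")
  }
  u / n
}

#' Angle at the middle point of three positions
#'
#' Returns the angle a-b-c (at `b`) in degrees, in `[0, 180]`.
#' @noRd
point_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# Condition classes used by the command-line wrapper to map failures onto
# exit codes: config/selection -> 2, input format -> 3, geometry/numeric -> 4.
abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "stereomd_config_error", ...)
}
abort_format <- function(msg, ...) {
  rlang::abort(msg, class = "stereomd_format_error", ...)
}
abort_geometry <- function(msg, ...) {
  rlang::abort(msg, class = "stereomd_geometry_error", ...)
}
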