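#' Rotation state at a given time
#'
#' Evaluates the spin-up schedule: a linear ramp from rest to the final
#' speed over `t_ramp`, constant afterwards. With `t_ramp = 0` the start
#' is a step: the speed is `omega_final` for any t > 0 and the angular
#' acceleration is reported as 0 (with a one-time warning), since the
#' Euler term of a true step is not representable.
#'
#' @param schedule a [rotation_schedule()].
#' @param t time(s) in s, >= 0; vectorized.
#' @return list with `omega` (signed, rad/s) and `domega` (rad/s^2).
#' @examples
#' omega_at(rotation_schedule(150, 0.01), 0.005)  # 75 rad/s, 15000 rad/s^2
#' @export
omega_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "rotation_schedule"), all(t >= 0))
  s <- schedule$sense
  if (schedule$t_ramp == 0) {
    if (schedule$omega_final > 0 && !isTRUE(the$warned_step_ramp)) {
      warning("t_ramp = 0: step start; dOmega/dt reported as 0", call. = FALSE)
      the$warned_step_ramp <- TRUE
    }
    return(list(omega = s * schedule$omega_final * (t > 0 | schedule$omega_final == 0),
                domega = rep(0, length(t))))
  }
  frac <- pmin(t / schedule$t_ramp, 1)
  list(omega = s * schedule$omega_final * frac,
       domega = s * ifelse(t < schedule$t_ramp,
                           schedule$omega_final / schedule$t_ramp, 0))
}

# package-local mutable state (warning latches)
the <- new.env(parent = emptyenv())

#' Non-inertial body acceleration in the co-rotating frame
#'
#' Sum of the centrifugal, Coriolis and Euler accelerations for a frame
#' rotating at `omega` (rad/s, axis normal to the disc plane, positive
#' counterclockwise) with angular acceleration `domega`:
#' \deqn{S = -\Omega \times (\Omega \times r) - 2 \Omega \times V
#'   - \dot\Omega \times r}
#' The Euler term is written as \eqn{-\dot\Omega \times r}, which equals
#' the equivalent form \eqn{r \times \dot\Omega} by antisymmetry of the
#' cross product. Gravity is not included (disc-plane dynamics).
#'
#' @param pos n x 2 matrix of in-plane positions (m), rotation center at
#'   the origin (a length-2 vector is accepted for a single point).
#' @param vel n x 2 matrix of in-plane velocities in the rotating frame
#'   (m/s).
#' @param omega signed rotation speed (rad/s).
#' @param domega signed angular acceleration (rad/s^2).
#' @return n x 2 matrix of accelerations (m/s^2).
#' @examples
#' body_acceleration(c(0.032, 0), c(0, 0), 150, 0)  # centrifugal only: 720 m/s^2
#' @export
body_acceleration <- function(pos, vel, omega, domega = 0) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 2)
  if (is.null(dim(vel))) vel <- matrix(vel, ncol = 2)
  stopifnot(ncol(pos) == 2, ncol(vel) == 2, nrow(pos) == nrow(vel))
  # centrifugal: -W x (W x r) = omega^2 r (in-plane)
  cen_x <- omega^2 * pos[, 1]
  cen_y <- omega^2 * pos[, 2]
  # Coriolis: -2 W x V = 2 omega (V_y, -V_x)
  cor_x <- 2 * omega * vel[, 2]
  cor_y <- -2 * omega * vel[, 1]
  # Euler: -dW/dt x r = domega (r_y, -r_x)
  eul_x <- domega * pos[, 2]
  eul_y <- -domega * pos[, 1]
  cbind(cen_x + cor_x + eul_x, cen_y + cor_y + eul_y)
}
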