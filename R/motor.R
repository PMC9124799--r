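#' Two-joint arm forward kinematics
#'
#' End-effector position of a planar two-link arm:
#' `x = L1 cos(phi1) + L2 cos(phi1 + phi2)`,
#' `y = L1 sin(phi1) + L2 sin(phi1 + phi2)`.
#'
#' @param phi1,phi2 Joint angles (rad); vectors give a trajectory.
#' @param link_lengths Lengths `(L1, L2)`.
#' @return A 2-column matrix `(x, y)`.
#' @export
#' @examples
#' arm_forward_kinematics(0, 0, c(0.5, 0.5)) # fully extended: (1, 0)
arm_forward_kinematics <- function(phi1, phi2, link_lengths = c(0.5, 0.5)) {
  L1 <- link_lengths[1]; L2 <- link_lengths[2]
  cbind(x = L1 * cos(phi1) + L2 * cos(phi1 + phi2),
        y = L1 * sin(phi1) + L2 * sin(phi1 + phi2))
}

#' Generate a random reachable motor-control task
#'
#' Draws a smooth random target movement for the end-effector of a
#' two-joint arm over `duration_ms`. The target is constructed in joint
#' space — angular velocities are a low-order random Fourier series — and
#' mapped through the forward kinematics, so every point is reachable by
#' construction and the implied angular velocities reproduce the target
#' path exactly under Euler integration. The network input is a clock-like
#' signal: `n_clock_channels` channels active in consecutive,
#' non-overlapping time slots tiling `[0, duration)`.
#'
#' @param duration_ms Movement duration (ms).
#' @param n_clock_channels Number of clock input channels.
#' @param link_lengths Lengths `(L1, L2)`.
#' @param initial_angles Starting pose (rad).
#' @param n_harmonics Fourier order of the random velocity profiles.
#' @param omega_sd Amplitude scale of the angular-velocity harmonics and of
#'   the per-joint constant drift component (rad/s). The drift gives each
#'   movement a net reach direction; the harmonics shape it.
#' @param dt Step size (ms).
#' @param seed Integer seed.
#' @return An object of class `arm_task`: `target_trajectory` (`T x 2`,
#'   Euclidean), `target_velocities` (`T x 2` joint angular velocities,
#'   rad/s), `angles` (`T x 2`), `clock_input` (`n_clock_channels x T` 0/1
#'   matrix), `link_lengths`, `initial_angles`, `duration_ms`, `dt`.
#' @export
generate_motor_task <- function(duration_ms = 500, n_clock_channels = 20,
                                link_lengths = c(0.5, 0.5),
                                initial_angles = c(pi / 4, pi / 2),
                                n_harmonics = 3, omega_sd = 1.5,
                                dt = 1, seed = 1L) {
  set.seed(as.integer(seed))
  Tn <- as.integer(round(duration_ms / dt))
  tt <- seq_len(Tn) * dt / duration_ms # normalized time in (0, 1]
  omega <- sapply(1:2, function(k) {
    drift <- stats::rnorm(1, sd = omega_sd)
    amp <- stats::rnorm(n_harmonics, sd = omega_sd / sqrt(n_harmonics))
    phs <- stats::runif(n_harmonics, 0, 2 * pi)
    drift + rowSums(sapply(seq_len(n_harmonics), function(m)
      amp[m] * sin(2 * pi * m * tt + phs[m])))
  })
  angles <- matrix(0, Tn, 2)
  ang <- initial_angles
  for (t in seq_len(Tn)) {
    ang <- ang + omega[t, ] * dt / 1000
    angles[t, ] <- ang
  }
  target <- arm_forward_kinematics(angles[, 1], angles[, 2], link_lengths)
  slot <- pmin(floor((seq_len(Tn) - 1) / (Tn / n_clock_channels)) + 1,
               n_clock_channels)
  clock <- matrix(0, n_clock_channels, Tn)
  clock[cbind(slot, seq_len(Tn))] <- 1
  structure(list(target_trajectory = target, target_velocities = omega,
                 angles = angles, clock_input = clock,
                 link_lengths = link_lengths, initial_angles = initial_angles,
                 duration_ms = duration_ms, dt = dt,
                 n_clock_channels = n_clock_channels, seed = as.integer(seed)),
            class = "arm_task")
}

#' @export
print.arm_task <- function(x, ...) {
  cat(sprintf("arm_task: %g ms movement, %d clock channels, links (%g, %g)\n",
              x$duration_ms, x$n_clock_channels,
              x$link_lengths[1], x$link_lengths[2]))
  invisible(x)
}

#' Integrate joint angular-velocity commands into an end-effector trajectory
#'
#' Euler-integrates the joint angles from the commanded angular velocities
#' and maps each pose through the forward kinematics.
#'
#' @param initial_angles Starting pose (rad).
#' @param velocity_commands `T x 2` matrix of angular velocities (rad/s).
#' @param link_lengths Lengths `(L1, L2)`.
#' @param dt Step size (ms).
#' @return List with `trajectory` (`T x 2`) and `angles` (`T x 2`).
#' @export
integrate_motor_commands <- function(initial_angles, velocity_commands,
                                     link_lengths = c(0.5, 0.5), dt = 1) {
  if (any(!is.finite(velocity_commands))) stop("non-finite motor commands")
  ang_cum <- apply(velocity_commands * dt / 1000, 2, cumsum)
  if (is.null(dim(ang_cum))) ang_cum <- matrix(ang_cum, 1)
  angles <- sweep(ang_cum, 2, initial_angles, `+`)
  list(trajectory = arm_forward_kinematics(angles[, 1], angles[, 2],
                                           link_lengths),
       angles = angles)
}

#' Trajectory mean squared error
#' @param trajectory,target `T x 2` matrices of Euclidean positions.
#' @return Mean squared error over steps and coordinates.
#' @export
trajectory_mse <- function(trajectory, target) {
  mean((trajectory - target)^2)
}
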