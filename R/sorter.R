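#' Gate a pulse generator from classifier probabilities
#'
#' The winning class selects which of the three pulse generators fires:
#' Category "extra" holds the shaft at 0 degrees, Category I turns +120
#' (clockwise), Category II turns -120 (anticlockwise). The pulse onset is
#' delayed by \code{dMax * (1 - p_max)} seconds, so confident calls actuate
#' immediately and uncertain ones later — never by more than \code{dMax}.
#'
#' @param probabilities length-3 non-negative vector summing to 1.
#' @param dMax maximum onset delay in seconds (default 0.5).
#' @return A \linkS4class{PulseCommand}.
#' @examples
#' gateSignal(c(0.34, 0.33, 0.33))  # delay 0.33 s, target 0 degrees
#' @export
gateSignal <- function(probabilities, dMax = 0.5) {
  p <- as.numeric(probabilities)
  if (length(p) != 3 || any(!is.finite(p)) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-6)
    stop("probabilities must be a valid 3-class distribution")
  phase <- which.max(p)                       # ties toward the lowest code
  targets <- c(0, 120, -120)
  new("PulseCommand", phase = as.integer(phase),
      delay = dMax * (1 - p[phase]), amplitude = 1,
      targetAngle = targets[phase])
}

# per-phase alignment angles (rad): phase 1 -> 0, phase 2 -> +120, 3 -> -120
.phaseAngles <- function() c(0, 2 * pi / 3, -2 * pi / 3)

# wrap an angular difference (deg) into [-180, 180)
.wrapDeg <- function(x) ((x + 180) %% 360) - 180

#' Simulate the variable-reluctance stepper motor
#'
#' Integrates the coupled electro-mechanical system with a fixed-step
#' 4th-order Runge-Kutta scheme (deSolve, method "rk4"). Each phase k has
#' inductance \code{L_k(theta) = Lmin + (Lmax - Lmin) (1 + cos(theta -
#' theta_k)) / 2} with alignment angles 0, +120, -120 degrees; the electrical
#' equation per phase is \code{V_k = R i_k + d(L_k i_k)/dt} (drive voltage on
#' the active phase once the onset delay has elapsed, zero otherwise);
#' reluctance torque is \code{sum(i_k^2 dL_k/dtheta / 2)}; the mechanics are
#' \code{J domega/dt = torque - friction}. The energized phase's alignment
#' angle is a stable equilibrium, so the shaft steps to the commanded target
#' and settles.
#'
#' @param params a \linkS4class{MotorParams}.
#' @param command a \linkS4class{PulseCommand}.
#' @param horizon simulation length in seconds (>= 1).
#' @param dt fixed integrator step in seconds (<= 1e-3).
#' @param settleTolDeg settle band around the target, degrees.
#' @param initialVelocity initial shaft angular velocity in rad/s (0 for the
#'   normal sorting start; nonzero to study perturbation decay).
#' @return A \linkS4class{Trajectory}; the settle time is the first instant
#'   after which the shaft stays within the band for the rest of the horizon.
#' @examples
#' tr <- simulateMotor(motorParams(), gateSignal(c(0, 1, 0)))
#' finalAngle(tr)
#' @export
simulateMotor <- function(params = motorParams(), command,
                          horizon = 1.5, dt = 1e-4, settleTolDeg = 1,
                          initialVelocity = 0) {
  stopifnot(is(params, "MotorParams"), is(command, "PulseCommand"))
  if (dt > 1e-3) stop("dt must be <= 1e-3 s")
  if (horizon < 1) stop("horizon must be >= 1 s")
  thK <- .phaseAngles()
  dL <- params@Lmax - params@Lmin
  viscous <- params@frictionModel == "viscous"

  rhs <- function(t, y, parms) {
    theta <- y[1]; omega <- y[2]; psi <- y[3:5]
    Lk <- params@Lmin + dL * (1 + cos(theta - thK)) / 2
    ik <- psi / Lk
    dLdth <- -dL / 2 * sin(theta - thK)
    V <- numeric(3)
    if (command@amplitude == 1 && t >= command@delay)
      V[command@phase] <- params@driveVoltage
    torque <- sum(ik^2 * dLdth) / 2
    fr <- if (viscous) params@friction * omega
          else params@friction * sign(omega)
    list(c(omega, (torque - fr) / params@inertia, V - params@resistance * ik))
  }

  times <- seq(0, horizon, by = dt)
  y0 <- c(theta = params@initialPosition * pi / 180, omega = initialVelocity,
          psi1 = 0, psi2 = 0, psi3 = 0)
  sol <- deSolve::ode(y0, times, rhs, parms = NULL, method = "rk4")
  if (any(!is.finite(sol)))
    stop("integration became non-finite; reduce dt (currently ", dt, " s)")

  theta <- sol[, "theta"]; omega <- sol[, "omega"]
  Lmat <- params@Lmin + dL * (1 + cos(outer(theta, thK, "-"))) / 2
  currents <- sol[, c("psi1", "psi2", "psi3")] / Lmat
  amp <- as.numeric(command@amplitude == 1 & sol[, "time"] >= command@delay)
  states <- data.frame(time_s = sol[, "time"],
                       theta_deg = theta * 180 / pi,
                       omega_rad_s = omega,
                       i1_A = currents[, 1], i2_A = currents[, 2],
                       i3_A = currents[, 3], pulse_amplitude = amp)

  dev <- abs(.wrapDeg(states$theta_deg - command@targetAngle))
  out <- which(dev >= settleTolDeg)
  if (length(out) == 0) {
    settled <- TRUE; st <- states$time_s[1]
  } else if (max(out) == length(dev)) {
    settled <- FALSE; st <- NA_real_
  } else {
    settled <- TRUE; st <- states$time_s[max(out) + 1L]
  }
  new("Trajectory", states = states, settleTime = st, settled = settled,
      finalAngle = states$theta_deg[length(dev)],
      targetAngle = command@targetAngle)
}

#' Classify one lemon and simulate the sorting actuation
#'
#' Full pipeline stage: colour features are extracted when an image is
#' supplied (the three physical properties must then accompany it), the
#' trained model predicts the category, the winning probability gates a
#' pulse command, and the motor simulation turns the shaft to the category's
#' basket angle.
#'
#' @param input a one-row record data.frame, or an
#'   \linkS4class{ImageSample} (then \code{weight}, \code{dlRatio} and
#'   \code{thickness} are required).
#' @param model a trained \linkS4class{LemonGrader}.
#' @param params a \linkS4class{MotorParams}.
#' @param weight,dlRatio,thickness physical measurements used with image
#'   input (g, dimensionless, mm).
#' @param ... passed to \code{\link{simulateMotor}}.
#' @return list with \code{trajectory} (\linkS4class{Trajectory}) and
#'   \code{audit} (features, probabilities, command, settle time, final
#'   angle).
#' @examples
#' recs <- do.call(rbind, lapply(1:3, function(k) sampleFeatures(k, 20, k)))
#' model <- trainGrader(recs, trainingConfig(seed = 1))
#' out <- classifyAndSort(sampleFeatures("CAT_II", 1, 5), model)
#' out$audit$final_angle_deg
#' @export
classifyAndSort <- function(input, model, params = motorParams(),
                            weight = NULL, dlRatio = NULL, thickness = NULL,
                            ...) {
  stopifnot(is(model, "LemonGrader"))
  if (is(input, "ImageSample")) {
    if (is.null(weight) || is.null(dlRatio) || is.null(thickness))
      stop("image input needs weight, dlRatio and thickness")
    cf <- extractFeatures(input)
    feats <- cbind(cf, weight = weight, dl_ratio = dlRatio,
                   thickness = thickness)
  } else {
    feats <- input
  }
  pred <- predictGrader(model, feats)
  cmd <- gateSignal(pred$probabilities[1, ])
  traj <- simulateMotor(params, cmd, ...)
  list(trajectory = traj,
       audit = list(features = as.list(featureMatrix(feats)[1, ]),
                    probabilities = as.numeric(pred$probabilities[1, ]),
                    predicted = pred$category[1],
                    phase = cmd@phase, delay_s = cmd@delay,
                    target_angle_deg = cmd@targetAngle,
                    settle_time_s = settleTime(traj),
                    final_angle_deg = finalAngle(traj)))
}

#' Write a trajectory to CSV
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
writeTrajectory <- function(trajectory, path) {
  stopifnot(is(trajectory, "Trajectory"))
  utils::write.csv(trajectory@states, path, row.names = FALSE)
  invisible(path)
}
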