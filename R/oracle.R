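#' Straight-line cursor intention oracle
#'
#' The optimal goal-directed intention for a cursor under a quadratic
#' movement cost: equal-length velocity vectors pointing at the target.
#' When the remaining distance is smaller than one step at full speed, the
#' velocity is shortened to land exactly on the goal (no overshoot); at the
#' goal the intended velocity is zero.
#'
#' @param pose Current cursor position (3-vector, task units).
#' @param goal A [goal_point()].
#' @param speed Positive oracle speed in task units per timestep.
#' @param dt Timestep length (default 1).
#' @return Intended velocity vector (units: pose units per timestep).
#' @export
cursor_oracle <- function(pose, goal, speed = 0.5, dt = 1) {
  if (!is.finite(speed) || speed <= 0) stop("oracle speed must be positive")
  pose <- if (inherits(pose, "kin_state")) pose$pose else as.numeric(pose)
  e <- goal$position - pose
  d <- sqrt(sum(e^2))
  if (d == 0) return(rep(0, length(e)))
  if (d <= speed * dt) e / dt else speed * e / d
}

#' Chain-oracle controller settings
#'
#' @param mu Positive damping of the least-squares inverse (prevents
#'   singular pseudo-inversion near singular chain poses).
#' @param omega_max Positive per-joint speed cap, radians per timestep
#'   (infinity-norm bound on the commanded joint velocity).
#' @param delta Positive wrist radius (task units) at which the reach
#'   switches from the wrist-approach phase to the fingertip-touch phase.
#' @return An object of class `chain_oracle_spec`.
#' @export
chain_oracle_spec <- function(mu = 1e-2, omega_max = 0.1, delta = 0.3) {
  if (!is.finite(mu) || mu <= 0) {
    stop("damping mu must be positive (mu = 0 makes the pseudo-inverse singular)")
  }
  if (omega_max <= 0 || delta <= 0) stop("omega_max and delta must be positive")
  structure(list(mu = mu, omega_max = omega_max, delta = delta),
            class = "chain_oracle_spec")
}

#' Resolved-rate intention oracle for an articulated chain
#'
#' Computes an incremental joint-angle update toward the wand by one damped
#' least-squares step on the quadratic marker error,
#' \deqn{\Delta\theta = J^\top (J J^\top + \mu I)^{-1} e,}
#' where `J` stacks the task Jacobians of the active markers (wrist in
#' phase 1; both fingertips in phase 2) and `e` the stacked marker errors.
#' The step is rescaled so that no joint exceeds `omega_max`.  This is the
#' standard closed-form incremental optimal-control step for a spring-like
#' end-effector penalty and stands in for an iterative physics-engine
#' solver.
#'
#' @param chain A [chain_model()].
#' @param angles Current joint angles.
#' @param goal A [goal_wand()].
#' @param spec A [chain_oracle_spec()].
#' @param phase Reach phase (1 = wrist approach, 2 = fingertip touch).  If
#'   `NULL`, chosen from the wrist-wand distance against `spec$delta`.
#' @return Intended joint velocity (radians per timestep).
#' @export
chain_oracle <- function(chain, angles, goal, spec = chain_oracle_spec(),
                         phase = NULL) {
  if (goal$kind != "wand") stop("chain_oracle needs a wand goal")
  angles <- as.numeric(angles)
  if (length(angles) != chain$n_joints) {
    stop("chain has ", chain$n_joints, " joints but got ",
         length(angles), " angles")
  }
  pose <- .chain_pose(chain, angles)
  .chain_oracle_at(chain, pose, goal, spec, phase)
}

# Damped-least-squares step given a precomputed chain pose (shared with the
# closed-loop trial runner, which also needs the pose for distances).
.chain_oracle_at <- function(chain, pose, goal, spec, phase = NULL) {
  if (is.null(phase)) {
    dw <- sqrt(sum((pose$markers$wrist - goal$position)^2))
    phase <- if (dw > spec$delta) 1L else 2L
  }
  if (phase == 1L) {
    e <- goal$position - pose$markers$wrist
    J <- .marker_jacobian(chain, pose, "wrist")
  } else {
    tp <- goal$touch_points
    tips <- c("thumb_tip", "mid_tip")[seq_len(nrow(tp))]
    e <- as.numeric(t(tp) - vapply(tips, function(nm) pose$markers[[nm]],
                                   numeric(3)))
    J <- do.call(rbind, lapply(tips, function(nm)
      .marker_jacobian(chain, pose, nm)))
  }
  dth <- as.numeric(crossprod(J, solve(J %*% t(J) + spec$mu * diag(nrow(J)), e)))
  mx <- max(abs(dth))
  if (mx > spec$omega_max) dth <- dth * spec$omega_max / mx
  dth
}

#' Intention model-mismatch specification
#'
#' Describes how the signal actually driving neural activity deviates from
#' the intention oracle used for training labels.
#'
#' * `"none"` -- no mismatch, the oracle drives encoding directly.
#' * `"noise"` -- a randomly directed vector whose norm is `noise_pct`
#'   percent of the oracle norm is added each timestep.
#' * `"linear"` -- a fixed invertible operator `M` is applied.
#' * `"arc"` -- the intention is rotated away from the straight-line
#'   direction by an angle that grows with distance from the goal through a
#'   logistic function, producing arcing reaches.
#'
#' @param kind One of `"none"`, `"noise"`, `"linear"`, `"arc"`.
#' @param noise_pct Nonnegative noise magnitude, percent of the oracle norm.
#' @param M Square mismatch matrix (linear kind); must be invertible.
#' @param phi_max Maximal arc rotation angle, degrees in `[0, 90]`.
#' @param sigmoid_midpoint,sigmoid_slope Logistic parameters mapping the
#'   goal distance (task units) to the rotation angle.
#' @return An object of class `mismatch_spec`.
#' @export
mismatch_spec <- function(kind = c("none", "noise", "linear", "arc"),
                          noise_pct = 0, M = NULL, phi_max = 0,
                          sigmoid_midpoint = 3, sigmoid_slope = 1) {
  kind <- match.arg(kind)
  if (kind == "noise" && noise_pct < 0) stop("noise_pct must be nonnegative")
  if (kind == "linear") {
    if (is.null(M)) stop("linear mismatch needs a matrix M")
    M <- as.matrix(M)
    if (nrow(M) != ncol(M)) stop("M must be square")
    if (abs(det(M)) < .Machine$double.eps^0.5) stop("M must be invertible")
  }
  if (kind == "arc" && (phi_max < 0 || phi_max > 90)) {
    stop("phi_max must lie in [0, 90] degrees")
  }
  if (sigmoid_slope <= 0) stop("sigmoid_slope must be positive")
  structure(list(kind = kind, noise_pct = noise_pct, M = M,
                 phi_max = phi_max, sigmoid_midpoint = sigmoid_midpoint,
                 sigmoid_slope = sigmoid_slope),
            class = "mismatch_spec")
}

#' Add random intention noise to an oracle action
#'
#' The perturbed intention is `o + (noise_pct/100) * ||o|| * r` with `r`
#' uniform on the unit sphere; the result is not renormalized, so at 100%
#' noise the perturbation has the same norm as the oracle action.
#'
#' @param o Oracle action (velocity vector).
#' @param noise_pct Nonnegative percentage.
#' @return Perturbed velocity vector.
#' @export
apply_intention_noise <- function(o, noise_pct) {
  if (noise_pct < 0) stop("noise_pct must be nonnegative")
  if (noise_pct == 0) return(o)
  r <- stats::rnorm(length(o))
  nr <- sqrt(sum(r^2))
  while (nr == 0) {  # astronomically unlikely; keep r on the sphere
    r <- stats::rnorm(length(o))
    nr <- sqrt(sum(r^2))
  }
  o + (noise_pct / 100) * sqrt(sum(o^2)) * r / nr
}

#' Apply a fixed linear intention mismatch
#'
#' @param o Oracle action.
#' @param M Square matrix of matching dimension.
#' @return `M %*% o` as a plain vector.
#' @export
apply_linear_mismatch <- function(o, M) {
  M <- as.matrix(M)
  if (ncol(M) != length(o) || nrow(M) != length(o)) {
    stop("M is ", nrow(M), "x", ncol(M), " but the action has length ",
         length(o))
  }
  as.numeric(M %*% o)
}

# Composed arc rotation: angle th (radians) applied sequentially in the
# xy, yz and zx coordinate planes, in that fixed order.
.arc_rotation <- function(th) {
  ct <- cos(th); st <- sin(th)
  Rxy <- matrix(c(ct, st, 0, -st, ct, 0, 0, 0, 1), 3, 3)
  Ryz <- matrix(c(1, 0, 0, 0, ct, st, 0, -st, ct), 3, 3)
  Rzx <- matrix(c(ct, 0, -st, 0, 1, 0, st, 0, ct), 3, 3)
  Rzx %*% Ryz %*% Rxy
}

#' Apply the distance-dependent arc intention mismatch
#'
#' The user intention is the oracle action rotated by the same angle in all
#' three coordinate planes (xy, then yz, then zx); the angle is
#' `phi_max * sigmoid((d - midpoint)/slope)` where `d` is the current
#' distance to the goal.  Far from the goal the intention arcs away from the
#' straight line by up to `phi_max` degrees; near the goal the discrepancy
#' vanishes, so both the oracle and the mismatched intention solve the task.
#' The rotation preserves the action norm.
#'
#' @param o Oracle action (3-vector).
#' @param pose Current cursor position.
#' @param goal A [goal_point()].
#' @param spec A [mismatch_spec()] of kind `"arc"`.
#' @return Rotated velocity vector.
#' @export
apply_arc_mismatch <- function(o, pose, goal, spec) {
  if (spec$phi_max < 0 || spec$phi_max > 90) {
    stop("phi_max must lie in [0, 90] degrees")
  }
  if (spec$phi_max == 0) return(o)
  pose <- if (inherits(pose, "kin_state")) pose$pose else as.numeric(pose)
  d <- sqrt(sum((goal$position - pose)^2))
  th <- (spec$phi_max * pi / 180) /
    (1 + exp(-(d - spec$sigmoid_midpoint) / spec$sigmoid_slope))
  as.numeric(.arc_rotation(th) %*% o)
}

# Dispatch a mismatch spec on one action; pose/goal needed for the arc kind.
.apply_mismatch <- function(o, spec, pose = NULL, goal = NULL) {
  switch(spec$kind,
         none = o,
         noise = apply_intention_noise(o, spec$noise_pct),
         linear = apply_linear_mismatch(o, spec$M),
         arc = apply_arc_mismatch(o, pose, goal, spec))
}

#' Sample a random rotation matrix
#'
#' Uniformly distributed 3x3 rotation (det +1), via QR of a Gaussian matrix
#' with sign correction.  Used as the canonical well-conditioned,
#' norm-preserving linear intention mismatch.
#'
#' @param d Dimension (default 3).
#' @return A `d` x `d` rotation matrix.
#' @export
random_rotation <- function(d = 3) {
  qr_ <- qr(matrix(stats::rnorm(d * d), d, d))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))), d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
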