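#' Kinematic state of an effector
#'
#' The state carries the effector pose (cursor position in task units, or
#' joint angles in radians), the per-timestep velocity, and the timestep
#' index.  Pose and velocity always have the same dimension `D`.
#'
#' @param pose Numeric vector, the effector pose.
#' @param velocity Numeric vector of the same length as `pose`; defaults to
#'   zero (effector at rest).
#' @param t Nonnegative integer timestep index.
#' @return An object of class `kin_state` with fields `pose`, `velocity`, `t`.
#' @export
#' @examples
#' kin_state(c(0, 0, 0))
kin_state <- function(pose, velocity = rep(0, length(pose)), t = 0L) {
  pose <- as.numeric(pose)
  velocity <- as.numeric(velocity)
  if (length(pose) != length(velocity)) {
    stop("pose has length ", length(pose), " but velocity has length ",
         length(velocity))
  }
  if (!all(is.finite(pose)) || !all(is.finite(velocity))) {
    stop("kinematic state must be finite")
  }
  structure(list(pose = pose, velocity = velocity, t = as.integer(t)),
            class = "kin_state")
}

#' @export
print.kin_state <- function(x, ...) {
  cat("<kin_state> D =", length(x$pose), " t =", x$t, "\n")
  cat("  pose:    ", format(x$pose, digits = 4), "\n")
  cat("  velocity:", format(x$velocity, digits = 4), "\n")
  invisible(x)
}

#' Advance an effector state by one timestep
#'
#' Position is physically governed by the velocity: the pose advances with
#' the *current* velocity, and the commanded velocity becomes the state
#' velocity for the next step,
#' \deqn{p_{t+1} = p_t + \Delta t\, v_t, \qquad v_{t+1} = \textrm{new velocity}.}
#' This matches the block structure of the steady-state velocity Kalman
#' filter state update (see [decode_step()]), so a newly commanded velocity
#' moves the effector one step later.
#'
#' @param state A [kin_state()].
#' @param new_velocity Numeric vector, the commanded velocity for the next
#'   step; same length as the pose.
#' @param dt Positive timestep length in task-time units (default 1; all
#'   speeds in the package are per timestep).
#' @return The advanced `kin_state`.
#' @export
integrate_state <- function(state, new_velocity, dt = 1) {
  new_velocity <- as.numeric(new_velocity)
  if (length(new_velocity) != length(state$pose)) {
    stop("state has dimension ", length(state$pose),
         " but new_velocity has length ", length(new_velocity))
  }
  if (!all(is.finite(new_velocity))) stop("new_velocity must be finite")
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive number")
  kin_state(state$pose + dt * state$velocity, new_velocity, state$t + 1L)
}

.axis_vec <- function(a) {
  if (is.character(a)) {
    switch(a,
           x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
           stop("unknown joint axis '", a, "'"))
  } else {
    a <- as.numeric(a)
    nrm <- sqrt(sum(a^2))
    if (nrm == 0) stop("joint axis must be nonzero")
    a / nrm
  }
}

#' Articulated kinematic chain model
#'
#' A serial chain of revolute joints.  Each joint rotates about its axis
#' (expressed in the frame of the preceding link) and is followed by a rigid
#' link extending along the local x axis.  Named markers are attached to
#' links at a scalar offset along the link direction; they play the role of
#' the wrist and fingertip identifiers whose Cartesian coordinates enter the
#' reach objective.
#'
#' @param link_lengths Positive numeric vector; one link per joint.
#' @param joint_axes List (or character vector) of per-joint axes; each entry
#'   is `"x"`, `"y"`, `"z"` or a 3-vector.
#' @param base_position 3-vector, position of the chain base.
#' @param markers Named list; each entry `list(link = i, offset = s)` places
#'   the marker at offset `s` along link `i` (from that link's joint origin).
#' @return An object of class `chain_model`.
#' @export
chain_model <- function(link_lengths, joint_axes,
                        base_position = c(0, 0, 0), markers = list()) {
  link_lengths <- as.numeric(link_lengths)
  if (any(!is.finite(link_lengths)) || any(link_lengths <= 0)) {
    stop("link lengths must be strictly positive")
  }
  n <- length(link_lengths)
  if (length(joint_axes) != n) {
    stop("need one joint axis per link: got ", length(joint_axes),
         " axes for ", n, " links")
  }
  axes <- lapply(seq_len(n), function(i) .axis_vec(joint_axes[[i]]))
  for (m in markers) {
    if (m$link < 1 || m$link > n) stop("marker link index out of range")
  }
  structure(list(n_joints = n, link_lengths = link_lengths, axes = axes,
                 base_position = as.numeric(base_position), markers = markers),
            class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat("<chain_model>", x$n_joints, "revolute joints, markers:",
      paste(names(x$markers), collapse = ", "), "\n")
  invisible(x)
}

# Rodrigues rotation matrix about unit axis a by angle th
.rot_axis <- function(a, th) {
  ct <- cos(th); st <- sin(th)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * ct + st * K + (1 - ct) * (a %o% a)
}

# Full pose of the chain: per-joint world origins, world rotations after
# each joint, world joint axes, and marker positions.
.chain_pose <- function(chain, angles) {
  n <- chain$n_joints
  R <- diag(3)
  p <- chain$base_position
  origins <- matrix(0, 3, n)     # joint i origin (world)
  axes_w <- matrix(0, 3, n)      # joint i axis (world)
  rots <- vector("list", n)      # rotation after joint i
  for (i in seq_len(n)) {
    origins[, i] <- p
    axes_w[, i] <- R %*% chain$axes[[i]]
    R <- R %*% .rot_axis(chain$axes[[i]], angles[i])
    rots[[i]] <- R
    p <- p + R %*% c(chain$link_lengths[i], 0, 0)
  }
  markers <- lapply(chain$markers, function(m) {
    as.numeric(origins[, m$link] + rots[[m$link]] %*% c(m$offset, 0, 0))
  })
  list(origins = origins, axes = axes_w, rots = rots, markers = markers)
}

#' Forward kinematics of a chain
#'
#' Composes the per-joint rotations along the chain and returns the world
#' position of every named marker.
#'
#' @param chain A [chain_model()].
#' @param angles Numeric vector of joint angles (radians), one per joint.
#' @return Named list of marker positions (3-vectors).
#' @export
forward_kinematics <- function(chain, angles) {
  angles <- as.numeric(angles)
  if (length(angles) != chain$n_joints) {
    stop("chain has ", chain$n_joints, " joints but got ",
         length(angles), " angles")
  }
  .chain_pose(chain, angles)$markers
}

# Geometric Jacobian (3 x n_joints) of one marker: column j is
# a_j x (p_marker - q_j) for joints j on the path to the marker, else 0.
.marker_jacobian <- function(chain, pose, marker_name) {
  m <- chain$markers[[marker_name]]
  pm <- pose$markers[[marker_name]]
  J <- matrix(0, 3, chain$n_joints)
  for (j in seq_len(m$link)) {
    a <- pose$axes[, j]
    r <- pm - pose$origins[, j]
    J[, j] <- c(a[2] * r[3] - a[3] * r[2],
                a[3] * r[1] - a[1] * r[3],
                a[1] * r[2] - a[2] * r[1])
  }
  J
}

#' Reach goals
#'
#' `goal_point()` is a point target for the cursor task.  `goal_wand()` is a
#' wand target for the chain task: a wrist approach point plus up to two
#' touch points that the fingertip markers must contact.
#'
#' @param position 3-vector (cursor goal position).
#' @return An object of class `bci_goal`.
#' @export
goal_point <- function(position) {
  position <- as.numeric(position)
  if (!all(is.finite(position))) stop("goal position must be finite")
  structure(list(kind = "cursor_point", position = position),
            class = "bci_goal")
}

#' @rdname goal_point
#' @param wrist 3-vector, the wand position approached by the wrist marker.
#' @param touch_points Matrix with one row per touch point (at most 2), or
#'   `NULL` to touch the wand point itself.
#' @export
goal_wand <- function(wrist, touch_points = NULL) {
  wrist <- as.numeric(wrist)
  if (is.null(touch_points)) touch_points <- matrix(wrist, 1, 3)
  touch_points <- matrix(as.numeric(touch_points), ncol = 3)
  if (nrow(touch_points) > 2) stop("a wand goal carries at most 2 touch points")
  if (!all(is.finite(wrist)) || !all(is.finite(touch_points))) {
    stop("goal positions must be finite")
  }
  structure(list(kind = "wand", position = wrist, touch_points = touch_points),
            class = "bci_goal")
}

#' Distance from the effector to the goal
#'
#' For a cursor goal, the Euclidean distance from the pose (or supplied
#' point) to the goal.  For a wand goal the reach has two phases: in phase 1
#' the wrist marker approaches the wand; in phase 2 each fingertip marker
#' must reach its touch point and the distance is the maximum fingertip
#' error.
#'
#' @param x A `kin_state`, a bare position vector, or (wand goals) a named
#'   marker list from [forward_kinematics()] containing `wrist` and the
#'   fingertip markers.
#' @param goal A [goal_point()] or [goal_wand()].
#' @param phase Reach phase, 1 or 2 (wand goals only).
#' @param fingertips Character vector naming the fingertip markers used in
#'   phase 2 (in the same order as the goal's touch points).
#' @return Nonnegative distance.
#' @export
distance_to_goal <- function(x, goal, phase = 1L,
                             fingertips = c("thumb_tip", "mid_tip")) {
  if (goal$kind == "cursor_point") {
    p <- if (inherits(x, "kin_state")) x$pose else as.numeric(x)
    sqrt(sum((p - goal$position)^2))
  } else if (goal$kind == "wand") {
    if (!is.list(x) || is.null(x$wrist)) {
      stop("wand goals need a marker list with a 'wrist' entry")
    }
    if (phase == 1L) {
      sqrt(sum((x$wrist - goal$position)^2))
    } else {
      tp <- goal$touch_points
      fingertips <- fingertips[seq_len(nrow(tp))]
      d <- vapply(seq_len(nrow(tp)), function(i) {
        sqrt(sum((x[[fingertips[i]]] - tp[i, ])^2))
      }, numeric(1))
      max(d)
    }
  } else {
    stop("unknown goal kind '", goal$kind, "'")
  }
}

#' Default arm-like chain preset
#'
#' An 8-degree-of-freedom serial chain that preserves the proximal-to-distal
#' structure of an arm: two "shoulder" joints on short links, one "elbow",
#' two "wrist" joints, and three "finger" joints with short distal links.
#' Markers: `wrist` (end of the wrist segment), `thumb_tip` (end of the
#' second finger link) and `mid_tip` (end of the most distal link).
#' Proximal joints move every marker through long links; the most distal
#' joint moves only the fingertip through the shortest link, so the task
#' excites the joints very unevenly -- the feature that drives per-joint
#' differences in encoding-model recovery speed.
#'
#' @return A [chain_model()].
#' @export
arm_chain <- function() {
  chain_model(
    link_lengths = c(0.10, 0.10, 1.00, 1.00, 0.10, 0.10, 0.30, 0.15),
    joint_axes = list("z", "y", "y", "z", "y", "z", "y", "y"),
    base_position = c(0, 0, 0),
    markers = list(
      wrist = list(link = 6L, offset = 0.10),
      thumb_tip = list(link = 7L, offset = 0.30),
      mid_tip = list(link = 8L, offset = 0.15)
    )
  )
}

#' Read or write a chain definition as JSON
#'
#' @param chain A [chain_model()].
#' @param path File path.
#' @return `chain_to_json()` invisibly returns `path`; `chain_from_json()`
#'   returns the `chain_model`.
#' @export
chain_to_json <- function(chain, path) {
  doc <- list(
    link_lengths = chain$link_lengths,
    joint_axes = lapply(chain$axes, as.numeric),
    base_position = chain$base_position,
    markers = lapply(chain$markers, function(m)
      list(link = m$link, offset = m$offset))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname chain_to_json
#' @export
chain_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  markers <- lapply(doc$markers, function(m)
    list(link = as.integer(m$link), offset = as.numeric(m$offset)))
  chain_model(doc$link_lengths, doc$joint_axes, doc$base_position, markers)
}

#' Write recorded trajectories as CSV
#'
#' One row per timestep with columns `trial`, `t`, pose entries and velocity
#' entries.
#'
#' @param records List of trial records from [run_session()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
trajectories_to_csv <- function(records, path) {
  rows <- lapply(records, function(r) {
    if (r$T_k == 0L) return(NULL)
    df <- data.frame(trial = r$trial, t = seq_len(r$T_k))
    pose <- r$pose
    vel <- r$v
    colnames(pose) <- paste0("pose", seq_len(ncol(pose)))
    colnames(vel) <- paste0("vel", seq_len(ncol(vel)))
    cbind(df, as.data.frame(pose), as.data.frame(vel))
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
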