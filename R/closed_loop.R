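#' Assisted-decoding action blend
#'
#' During training the executed velocity is the deterministic weighted sum
#' `beta * oracle + (1 - beta) * decoder`, the assisted-decoding form of
#' oracle mixing: early trials can lean on the oracle to keep state
#' sampling task-relevant, later trials run the decoder alone.
#'
#' @param o Oracle action.
#' @param a_dec Decoded action.
#' @param beta Blend weight in `[0, 1]`.
#' @return Blended velocity vector.
#' @export
blend_action <- function(o, a_dec, beta) {
  if (!is.finite(beta) || beta < 0 || beta > 1) {
    stop("beta must lie in [0, 1]")
  }
  beta * o + (1 - beta) * a_dec
}

#' Closed-loop session configuration
#'
#' Bundles everything one simulated training session needs: the task
#' preset, trial counts and horizons, the assistance schedule, goal
#' sampling, the mismatch and update specifications, and the three
#' independent random seeds (encoding model, neural noise, goals) so that
#' mismatch studies can share the encoding realization across conditions.
#'
#' @param task `"cursor"` (3D point-to-point reaches) or `"arm"`
#'   (kinematic-chain wand reaches).
#' @param K Number of reach trials.
#' @param T_max Maximum timesteps per reach.
#' @param epsilon Goal tolerance in task units (cursor: cursor-goal
#'   distance; arm: maximum fingertip-touchpoint distance).
#' @param beta Assistance schedule, length `K` in `[0, 1]`.  Default:
#'   `beta_1 = 1` (pure assisted first trial) and 0 afterwards.
#' @param exec_noise_pct Intention noise (percent) injected into the
#'   *executed* oracle action whenever `beta > 0`, to keep the first-trial
#'   regression design well conditioned; labels stay noise-free.
#' @param N Neuron count.
#' @param snr Target per-neuron signal-to-noise ratio.
#' @param speed Cursor oracle speed (task units/timestep).
#' @param workspace Length-2 cursor workspace bounds, replicated per axis.
#' @param chain [chain_model()] for the arm task.
#' @param chain_spec [chain_oracle_spec()] for the arm oracle.
#' @param wand_radius Length-2 radial shell (task units) in which wand
#'   goals are placed.
#' @param wand_touch_offset Half-separation of the two wand touch points.
#' @param init_pose Initial pose (cursor position or joint angles).
#' @param joint_limits Optional length-2 numeric range (radians); when
#'   given, arm joint angles are clamped to it after every step.  `NULL`
#'   (default) leaves joints unlimited.
#' @param reset_between Reset the pose between reaches?  Default: the
#'   cursor continues from the previous endpoint, the arm resets.
#' @param mismatch A [mismatch_spec()].
#' @param update An [update_spec()]; its `K` is synchronized to the session.
#' @param init_scale Initial-decoder scale (see [init_decoder()]).
#' @param dt Timestep length.
#' @param seed Integer master seed; three stream seeds (model, goals,
#'   noise) are derived from it.
#' @return An object of class `loop_config`.
#' @export
loop_config <- function(task = c("cursor", "arm"), K = 100L, T_max = 200L,
                        epsilon = 0.5, beta = NULL, exec_noise_pct = 5,
                        N = 10L, snr = 1, speed = 0.5,
                        workspace = c(-10, 10),
                        chain = NULL, chain_spec = chain_oracle_spec(),
                        wand_radius = c(1.0, 2.0), wand_touch_offset = 0.1,
                        init_pose = NULL, joint_limits = NULL,
                        reset_between = NULL,
                        mismatch = mismatch_spec("none"),
                        update = update_spec("ftl"),
                        init_scale = 0.01, dt = 1, seed = 1L) {
  task <- match.arg(task)
  K <- as.integer(K)
  if (K < 1L) stop("K must be at least 1")
  if (T_max < 1L) stop("T_max must be at least 1")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (is.null(beta)) beta <- c(1, rep(0, K - 1L))
  if (length(beta) == 1L) beta <- rep(beta, K)
  if (length(beta) != K || any(beta < 0) || any(beta > 1)) {
    stop("beta must be a length-K schedule in [0, 1]")
  }
  if (task == "cursor") {
    if (diff(workspace) <= 0) stop("degenerate workspace bounds")
    D <- 3L
    if (is.null(init_pose)) init_pose <- c(0, 0, 0)
    if (is.null(reset_between)) reset_between <- FALSE
    rectify <- FALSE
  } else {
    if (is.null(chain)) chain <- arm_chain()
    D <- chain$n_joints
    if (is.null(init_pose)) {
      init_pose <- c(0.3, -0.5, 0.8, 0.2, -0.3, 0.2, 0.3, 0.3)[seq_len(D)]
      init_pose[is.na(init_pose)] <- 0.2
    }
    if (is.null(reset_between)) reset_between <- TRUE
    rectify <- TRUE
  }
  update$K <- K
  seed <- as.integer(seed)
  structure(list(task = task, K = K, T_max = as.integer(T_max),
                 epsilon = epsilon, beta = beta,
                 exec_noise_pct = exec_noise_pct,
                 N = as.integer(N), D = D, snr = snr, speed = speed,
                 workspace = workspace, chain = chain,
                 chain_spec = chain_spec, wand_radius = wand_radius,
                 wand_touch_offset = wand_touch_offset,
                 init_pose = as.numeric(init_pose),
                 joint_limits = joint_limits,
                 reset_between = reset_between, rectify = rectify,
                 mismatch = mismatch, update = update,
                 init_scale = init_scale, dt = dt, seed = seed,
                 seeds = list(model = seed, goals = seed + 1000003L,
                              noise = seed + 2000003L)),
            class = "loop_config")
}

#' Sample a reach goal
#'
#' Cursor task: uniform over the configured cubic workspace.  Arm task: the
#' wand is placed at a uniform radius within the configured shell, in a
#' random front-facing direction, with two touch points offset
#' symmetrically perpendicular to the radial direction.  Uses the current
#' RNG stream.
#'
#' @param config A [loop_config()].
#' @return A [goal_point()] or [goal_wand()].
#' @export
sample_goal <- function(config) {
  if (config$task == "cursor") {
    goal_point(stats::runif(3, config$workspace[1], config$workspace[2]))
  } else {
    u <- stats::rnorm(3)
    u[1] <- abs(u[1])  # keep the wand in the front half-space
    u <- u / sqrt(sum(u^2))
    r <- stats::runif(1, config$wand_radius[1], config$wand_radius[2])
    wand <- config$chain$base_position + r * u
    perp <- c(-u[2], u[1], 0)
    if (sum(perp^2) < 1e-12) perp <- c(0, 1, 0)
    perp <- perp / sqrt(sum(perp^2))
    off <- config$wand_touch_offset
    goal_wand(wand, rbind(wand + off * perp, wand - off * perp))
  }
}

# One closed-loop reach.  Records every per-step sample; termination:
# success iff the goal condition is met before T_max steps have run.
.run_trial <- function(params, model, config, goal, state0, beta, k) {
  Tm <- config$T_max
  N <- config$N; D <- config$D
  n_mat <- matrix(0, Tm, N)
  v_mat <- matrix(0, Tm, D)
  o_mat <- matrix(0, Tm, D)
  a_mat <- matrix(0, Tm, D)
  p_mat <- matrix(0, Tm, D)
  pose <- state0$pose
  vel <- state0$velocity
  Fv <- params$F_v; bv <- params$b_v; Gv <- params$G_v
  A <- model$A
  sdvec <- sqrt(model$sigma2)
  mm <- config$mismatch
  dt <- config$dt
  arm <- config$task == "arm"
  phase <- 1L
  success <- FALSE
  diverged <- FALSE
  steps <- 0L
  repeat {
    if (!all(is.finite(pose)) || !all(is.finite(vel)) ||
        max(abs(pose)) > 1e8 || max(abs(vel)) > 1e8) {
      # unstable closed loop: end the reach as a failure before the recorded
      # samples can overflow downstream Gram-matrix products
      diverged <- TRUE
      break
    }
    if (arm) {
      cpose <- .chain_pose(config$chain, pose)
      if (phase == 1L) {
        dw <- sqrt(sum((cpose$markers$wrist - goal$position)^2))
        if (dw <= config$chain_spec$delta) phase <- 2L  # latches
      }
      if (phase == 2L &&
          distance_to_goal(cpose$markers, goal, 2L) <= config$epsilon) {
        success <- TRUE
        break
      }
    } else {
      if (sqrt(sum((pose - goal$position)^2)) <= config$epsilon) {
        success <- TRUE
        break
      }
    }
    if (steps >= Tm) break
    o <- if (arm) {
      .chain_oracle_at(config$chain, cpose, goal, config$chain_spec, phase)
    } else {
      cursor_oracle(pose, goal, config$speed, dt)
    }
    u <- .apply_mismatch(o, mm, pose = pose, goal = goal)
    n <- as.numeric(A %*% u) + stats::rnorm(N) * sdvec
    a_dec <- as.numeric(Fv %*% n + bv + Gv %*% vel)
    o_exec <- if (beta > 0 && config$exec_noise_pct > 0) {
      apply_intention_noise(o, config$exec_noise_pct)
    } else o
    a <- beta * o_exec + (1 - beta) * a_dec
    steps <- steps + 1L
    n_mat[steps, ] <- n
    v_mat[steps, ] <- vel
    o_mat[steps, ] <- o
    a_mat[steps, ] <- a_dec
    p_mat[steps, ] <- pose
    pose <- pose + dt * vel
    if (arm && !is.null(config$joint_limits)) {
      pose <- pmin(pmax(pose, config$joint_limits[1]), config$joint_limits[2])
    }
    vel <- a
  }
  idx <- seq_len(steps)
  list(trial = k, goal = goal,
       n = n_mat[idx, , drop = FALSE], v = v_mat[idx, , drop = FALSE],
       o = o_mat[idx, , drop = FALSE], a_dec = a_mat[idx, , drop = FALSE],
       pose = p_mat[idx, , drop = FALSE],
       step_loss = rowSums((a_mat[idx, , drop = FALSE] -
                              o_mat[idx, , drop = FALSE])^2),
       success = success, T_k = steps, diverged = diverged,
       final_state = if (diverged) kin_state(rep(0, D)) else
         kin_state(pose, vel, state0$t + steps))
}

#' Read a session configuration from JSON
#'
#' The document's fields mirror the arguments of [loop_config()]; a
#' `mismatch` block (with `kind` and its parameters) and an `update` block
#' (with `rule`, `lr0`, `lambda`, `ridge`, `schedule`) are expanded into
#' their specification objects.
#'
#' @param path Path to a JSON config file.
#' @return A [loop_config()].
#' @export
loop_config_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(doc$mismatch)) {
    mm <- doc$mismatch
    doc$mismatch <- mismatch_spec(
      kind = mm$kind,
      noise_pct = mm$noise_pct %||% 0,
      M = if (!is.null(mm$M)) matrix(unlist(mm$M), nrow = sqrt(length(unlist(mm$M)))),
      phi_max = mm$phi_max %||% 0,
      sigmoid_midpoint = mm$sigmoid_midpoint %||% 3,
      sigmoid_slope = mm$sigmoid_slope %||% 1)
  }
  if (!is.null(doc$update)) {
    up <- doc$update
    doc$update <- update_spec(rule = up$rule %||% "ftl",
                              lr0 = up$lr0 %||% 300,
                              lambda = up$lambda %||% 0.9,
                              ridge = up$ridge %||% 5,
                              schedule = up$schedule %||% "linear")
  }
  doc <- doc[names(doc) %in% names(formals(loop_config))]
  do.call(loop_config, doc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one closed-loop reach trial
#'
#' Loops while the goal condition is unmet and the horizon has not expired.
#' Each step queries the oracle for the training label, applies any
#' intention mismatch to obtain the signal driving the neurons, simulates
#' neural activity, decodes, blends with the assistance weight, and
#' advances the effector.  All per-step samples are recorded.
#'
#' @param params Current [decoder_params()].
#' @param model An [encoding_model()].
#' @param config A [loop_config()].
#' @param goal A goal from [sample_goal()].
#' @param state Starting [kin_state()].
#' @param beta Assistance weight for this trial.
#' @param k Trial index (tagging only).
#' @return A trial record: per-step matrices `n`, `v`, `o`, `a_dec`,
#'   `pose`, the per-step losses, `success`, duration `T_k`, and the final
#'   state.
#' @export
run_trial <- function(params, model, config, goal,
                      state = kin_state(config$init_pose), beta = 0, k = 1L) {
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  if (params$N != config$N || params$D != config$D ||
      model$N != config$N || model$D != config$D) {
    stop("decoder/encoder dimensions do not match the session config")
  }
  .run_trial(params, model, config, goal, state, beta, k)
}

.record_dataset <- function(rec) {
  if (rec$T_k == 0L) return(NULL)
  bci_dataset(rec$n, rec$v, rec$o,
              trial = rep(rec$trial, rec$T_k), t = seq_len(rec$T_k))
}

# Deterministic pilot reach under the pure oracle, used to measure a
# representative oracle action norm for arm SNR calibration.
.arm_pilot_speed <- function(config) {
  wand <- config$chain$base_position + c(1.5, 0.4, 0.3)
  off <- config$wand_touch_offset
  goal <- goal_wand(wand, rbind(wand + c(0, off, 0), wand - c(0, off, 0)))
  ang <- config$init_pose
  vel <- rep(0, config$D)
  phase <- 1L
  norms <- numeric(0)
  for (s in seq_len(config$T_max)) {
    cpose <- .chain_pose(config$chain, ang)
    if (phase == 1L) {
      dw <- sqrt(sum((cpose$markers$wrist - goal$position)^2))
      if (dw <= config$chain_spec$delta) phase <- 2L
    }
    if (phase == 2L &&
        distance_to_goal(cpose$markers, goal, 2L) <= config$epsilon) break
    o <- .chain_oracle_at(config$chain, cpose, goal, config$chain_spec, phase)
    norms <- c(norms, sqrt(sum(o^2)))
    ang <- ang + config$dt * vel
    vel <- o
  }
  if (length(norms) == 0L) return(config$chain_spec$omega_max)
  sqrt(mean(norms^2))
}

#' Run a full closed-loop training session
#'
#' Executes the dataset-aggregation meta-algorithm: `K` reach trials; after
#' each trial its samples are appended to the aggregate and the configured
#' update rule produces the next decoder.  Three independent random streams
#' (encoding model + initial decoder, goal sequence, neural/execution
#' noise) make paired comparisons across conditions possible.
#'
#' @param config A [loop_config()].
#' @return An object of class `bci_session`: `history` (decoder held at the
#'   start of each trial, length `K + 1` including the post-session
#'   update), `records` (per-trial records), `dataset` (the aggregated
#'   [bci_dataset()]), `summary` (per-trial data frame with `sse`, `mse`,
#'   `T_k`, `success`), `model`, `final` and `best` decoders, and the
#'   config.  `best` is the held decoder of the lowest-MSE trial within the
#'   final 20% of trials.
#' @export
run_session <- function(config) {
  set.seed(config$seeds$model)
  model <- sample_encoding_model(config$N, config$D, rectify = config$rectify)
  snr_speed <- if (config$task == "cursor") config$speed else
    .arm_pilot_speed(config)
  model <- calibrate_noise(model, speed = snr_speed, target_snr = config$snr)
  params <- init_decoder(config$N, config$D, scale = config$init_scale,
                         dt = config$dt)
  set.seed(config$seeds$goals)
  goals <- lapply(seq_len(config$K), function(i) sample_goal(config))
  set.seed(config$seeds$noise)

  spec <- config$update
  # FTL executes through RLS (identical solution, O(1)/sample); the ridge=0
  # variant has no RLS prior, so it falls back to dense refits per trial
  use_rls <- spec$rule %in% c("ftl", "rls") && spec$ridge > 0
  use_dense_ftl <- spec$rule %in% c("ftl", "rls") && spec$ridge == 0
  if (use_rls) {
    rls <- rls_init(config$N, config$D, ridge = spec$ridge, dt = config$dt)
  }
  history <- vector("list", config$K + 1L)
  history[[1L]] <- params
  records <- vector("list", config$K)
  chunks <- vector("list", config$K)
  state <- kin_state(config$init_pose)
  for (k in seq_len(config$K)) {
    rec <- .run_trial(params, model, config, goals[[k]], state,
                      config$beta[k], k)
    records[[k]] <- rec
    chunk <- .record_dataset(rec)
    chunks[[k]] <- chunk
    params <- tryCatch({
      if (use_rls) {
        if (!is.null(chunk)) rls <- rls_update(rls, chunk)
        if (!is.null(rls$P)) rls_params(rls) else params
      } else if (use_dense_ftl) {
        agg <- do.call(dataset_bind, chunks[seq_len(k)])
        if (is.null(agg$n) || nrow(agg$n) == 0L) params else
          ftl_update(agg, spec, dt = config$dt)
      } else if (is.null(chunk)) {
        params
      } else if (spec$rule == "ogd") {
        ogd_update(params, chunk, spec, k)
      } else {
        ma_update(params, chunk, spec)
      }
    }, error = function(e) {
      stop("update failed after trial ", k, ": ", conditionMessage(e),
           call. = FALSE)
    })
    history[[k + 1L]] <- params
    state <- if (config$reset_between) kin_state(config$init_pose) else
      rec$final_state
  }
  summary <- data.frame(
    trial = seq_len(config$K),
    sse = vapply(records, function(r) sum(r$step_loss), numeric(1)),
    T_k = vapply(records, function(r) r$T_k, numeric(1)),
    success = vapply(records, function(r) r$success, logical(1))
  )
  summary$mse <- ifelse(summary$T_k > 0, summary$sse / summary$T_k, 0)
  tail_idx <- seq.int(max(1L, ceiling(0.8 * config$K)), config$K)
  nonzero <- tail_idx[summary$T_k[tail_idx] > 0]
  best_k <- if (length(nonzero)) nonzero[which.min(summary$mse[nonzero])] else
    config$K
  structure(list(model = model, history = history, records = records,
                 dataset = do.call(dataset_bind, chunks),
                 summary = summary, config = config,
                 final = params, best = history[[best_k]],
                 best_trial = best_k),
            class = "bci_session")
}

#' @export
print.bci_session <- function(x, ...) {
  cat("<bci_session>", x$config$task, "task,", x$config$K, "trials,",
      nrow(x$dataset$n), "samples aggregated\n")
  cat("  update rule:", x$config$update$rule,
      " success rate:", format(mean(x$summary$success), digits = 3), "\n")
  invisible(x)
}

#' Write session outputs to a directory
#'
#' Emits `trials.csv` (per-step trajectories), `summary.csv` (per-trial
#' SSE/MSE, duration, success), `params_final.json`, `params_best.json` and
#' `manifest.json` (config and seeds).
#'
#' @param session A `bci_session`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
session_to_dir <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  trajectories_to_csv(session$records, file.path(dir, "trials.csv"))
  utils::write.csv(session$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  decoder_to_json(session$final, file.path(dir, "params_final.json"))
  decoder_to_json(session$best, file.path(dir, "params_best.json"))
  cfg <- session$config
  manifest <- list(task = cfg$task, K = cfg$K, T_max = cfg$T_max,
                   epsilon = cfg$epsilon, N = cfg$N, D = cfg$D,
                   snr = cfg$snr, speed = cfg$speed,
                   update = unclass(cfg$update),
                   mismatch = list(kind = cfg$mismatch$kind),
                   seed = cfg$seed, seeds = cfg$seeds)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
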