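#' Task preset configurations
#'
#' `cursor_preset()`: 3D cursor reaches in the default workspace cube with
#' 10 velocity-tuned neurons at SNR 1, up to 200 timesteps per reach and
#' 100 reaches.  `arm_preset()`: wand reaches with the 8-joint chain, 75
#' neurons (rectified tuning), up to 150 timesteps and 50 reaches.
#'
#' @param seed Master seed.
#' @param update An [update_spec()], or a rule name passed to
#'   [default_update()].
#' @param K Number of reaches.
#' @param ... Further arguments to [loop_config()].
#' @return A [loop_config()].
#' @export
cursor_preset <- function(seed = 1L, update = default_update("ftl"),
                          K = 100L, ...) {
  if (is.character(update)) update <- default_update(update)
  args <- list(task = "cursor", K = K, T_max = 200L, epsilon = 0.5,
               N = 10L, snr = 1, speed = 0.5, update = update, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(loop_config, args)
}

#' @rdname cursor_preset
#' @export
arm_preset <- function(seed = 1L, update = default_update("ftl"),
                       K = 50L, ...) {
  if (is.character(update)) update <- default_update(update)
  args <- list(task = "arm", K = K, T_max = 150L, epsilon = 0.2,
               N = 75L, snr = 1, update = update, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(loop_config, args)
}

#' Default update specification per rule
#'
#' Shared defaults: ridge 1 for all rules (OGD spreads it as `ridge / K`
#' per update), moving-average weight `lambda = 0.9`, and the tuned OGD
#' schedule `eta_k = lr0 * k` with `lr0` chosen by [tune_ogd_rate()] on the
#' default cursor preset.
#'
#' @param rule `"ftl"`, `"ogd"`, `"ma"` or `"rls"`.
#' @return An [update_spec()].
#' @export
default_update <- function(rule = c("ftl", "ogd", "ma", "rls")) {
  rule <- match.arg(rule)
  update_spec(rule = rule, lr0 = 300, lambda = 0.9, ridge = 5)
}

#' Run repeated sessions of one configuration
#'
#' Repeats the closed-loop session with consecutive master seeds and
#' collects per-trial losses; optionally also the empirical regret and
#' encoding-recovery curves of each repeat.
#'
#' @param config A [loop_config()] (its seed is replaced per repeat).
#' @param repeats Number of repeats.
#' @param seed First master seed; repeat `r` uses `seed + r - 1`.
#' @param regret Also compute per-repeat regret curves?
#' @param recovery Also compute per-repeat recovery curves?
#' @param keep_sessions Return the full session objects?
#' @return List with matrices `sse`, `mse`, `T_k`, `success`
#'   (repeats x trials) and optional `regret` / `recovery` /
#'   `sessions` lists.
#' @export
run_repeats <- function(config, repeats = 20L, seed = config$seed,
                        regret = FALSE, recovery = FALSE,
                        keep_sessions = FALSE) {
  K <- config$K
  sse <- matrix(0, repeats, K)
  mse <- matrix(0, repeats, K)
  T_k <- matrix(0, repeats, K)
  success <- matrix(FALSE, repeats, K)
  regrets <- if (regret) vector("list", repeats)
  recoveries <- if (recovery) vector("list", repeats)
  sessions <- if (keep_sessions) vector("list", repeats)
  for (r in seq_len(repeats)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r - 1L)
    cfg$seeds <- list(model = cfg$seed, goals = cfg$seed + 1000003L,
                      noise = cfg$seed + 2000003L)
    s <- run_session(cfg)
    sse[r, ] <- s$summary$sse
    mse[r, ] <- s$summary$mse
    T_k[r, ] <- s$summary$T_k
    success[r, ] <- s$summary$success
    if (regret) {
      regrets[[r]] <- empirical_regret(s$history, s$dataset,
                                       ridge = config$update$ridge)
    }
    if (recovery) recoveries[[r]] <- encoding_recovery(s$dataset, s$model)
    if (keep_sessions) sessions[[r]] <- s
  }
  out <- list(sse = sse, mse = mse, T_k = T_k, success = success)
  if (regret) out$regret <- regrets
  if (recovery) out$recovery <- recoveries
  if (keep_sessions) out$sessions <- sessions
  out
}

#' Mean loss over the final stretch of a session
#'
#' The "asymptotic" loss used throughout the mismatch analyses: the mean
#' per-trial loss over the final 20% of trials.
#'
#' @param sse Per-trial loss vector or a repeats-by-trials matrix (averaged
#'   over repeats first).
#' @param frac Tail fraction (default 0.2).
#' @return Scalar asymptotic loss.
#' @export
asymptotic_sse <- function(sse, frac = 0.2) {
  if (is.matrix(sse)) sse <- colMeans(sse)
  K <- length(sse)
  mean(sse[seq.int(max(1L, ceiling((1 - frac) * K) + 1L), K)])
}

#' Grid search for the OGD learning-rate scale
#'
#' Runs short cursor sessions over a grid of `lr0` values and reports the
#' mean cumulative SSE of each, the criterion used to fix the package's
#' default.  Divergent settings surface as very large losses.
#'
#' @param lr0_grid Candidate values of the schedule base `lr0`.
#' @param seed Base seed.
#' @param repeats Repeats per candidate.
#' @param K Reaches per session.
#' @return Data frame with columns `lr0` and `mean_cum_sse`, ordered as the
#'   grid.
#' @export
tune_ogd_rate <- function(lr0_grid = c(3e3, 1e4, 3e4, 1e5, 3e5),
                          seed = 1L, repeats = 5L, K = 50L) {
  res <- vapply(lr0_grid, function(lr0) {
    cfg <- cursor_preset(seed = seed, K = K,
                         update = update_spec("ogd", lr0 = lr0, ridge = 1))
    rep <- run_repeats(cfg, repeats = repeats, seed = seed)
    mean(rowSums(rep$sse))
  }, numeric(1))
  data.frame(lr0 = lr0_grid, mean_cum_sse = res)
}

.preset_names <- c("cursor_compare", "arm_compare", "arm_recovery",
                   "cursor_noise", "cursor_arc")

.curve_summary <- function(sse, condition) {
  K <- ncol(sse)
  data.frame(condition = condition, trial = seq_len(K),
             mean_sse = colMeans(sse),
             median_sse = apply(sse, 2, stats::median),
             se2 = 2 * apply(sse, 2, stats::sd) / sqrt(nrow(sse)))
}

#' Run a named experiment preset
#'
#' Reproduces the package's standard simulation protocols at configurable
#' scale:
#'
#' * `cursor_compare` -- FTL vs tuned OGD vs MA(0.9) on the cursor task.
#' * `arm_compare` -- the same comparison on the chain-arm task.
#' * `arm_recovery` -- FTL arm sessions with per-joint encoding-recovery
#'   curves.
#' * `cursor_noise` -- FTL cursor sessions across intention-noise levels
#'   (percent of oracle norm).
#' * `cursor_arc` -- FTL cursor sessions across arc-mismatch angles
#'   (degrees).
#'
#' Curves are summarized as mean with 2-standard-error bars across repeats.
#'
#' @param name Preset name.
#' @param repeats Session repeats per condition (preset default if `NULL`).
#' @param K Reaches per session (preset default if `NULL`).
#' @param seed Base seed.
#' @param levels Condition levels for the mismatch presets (noise
#'   percentages or arc angles).
#' @param regret Also compute mean empirical-regret curves (comparison
#'   presets only)?
#' @param out Optional output directory for `summary.csv` (plus
#'   `recovery.csv` / `regret.csv` where applicable) and `manifest.json`.
#' @return List with `summary` (per-condition mean curves), `detail`
#'   (per-condition `run_repeats()` results), optional `regret`, and
#'   `manifest`.
#' @export
run_experiment_preset <- function(name, repeats = NULL, K = NULL, seed = 1L,
                                  levels = NULL, regret = FALSE, out = NULL) {
  if (!name %in% .preset_names) {
    stop("unknown preset '", name, "'; available: ",
         paste(.preset_names, collapse = ", "))
  }
  detail <- list()
  summary <- NULL
  recovery_tab <- NULL
  if (name %in% c("cursor_compare", "arm_compare")) {
    if (is.null(repeats)) repeats <- if (name == "cursor_compare") 20L else 10L
    maker <- if (name == "cursor_compare") cursor_preset else arm_preset
    for (rule in c("ftl", "ogd", "ma")) {
      cfg <- if (is.null(K)) maker(seed = seed, update = rule) else
        maker(seed = seed, update = rule, K = K)
      detail[[rule]] <- run_repeats(cfg, repeats = repeats, seed = seed,
                                    regret = regret)
      summary <- rbind(summary, .curve_summary(detail[[rule]]$sse, rule))
    }
  } else if (name == "arm_recovery") {
    if (is.null(repeats)) repeats <- 20L
    cfg <- if (is.null(K)) arm_preset(seed = seed) else
      arm_preset(seed = seed, K = K)
    detail$ftl <- run_repeats(cfg, repeats = repeats, seed = seed,
                              recovery = TRUE)
    summary <- .curve_summary(detail$ftl$sse, "ftl")
    recovery_tab <- do.call(rbind, lapply(seq_along(detail$ftl$recovery),
      function(r) cbind(repeat_ = r, detail$ftl$recovery[[r]])))
  } else {
    if (is.null(repeats)) repeats <- 10L
    if (name == "cursor_noise") {
      if (is.null(levels)) levels <- c(0, 50, 100, 200)
      specs <- lapply(levels, function(v)
        if (v == 0) mismatch_spec("none") else
          mismatch_spec("noise", noise_pct = v))
    } else {
      if (is.null(levels)) levels <- c(0, 15, 30, 45)
      specs <- lapply(levels, function(v)
        if (v == 0) mismatch_spec("none") else
          mismatch_spec("arc", phi_max = v))
    }
    for (i in seq_along(levels)) {
      cfg <- if (is.null(K)) {
        cursor_preset(seed = seed, mismatch = specs[[i]])
      } else {
        cursor_preset(seed = seed, K = K, mismatch = specs[[i]])
      }
      lab <- paste0("level_", levels[i])
      detail[[lab]] <- run_repeats(cfg, repeats = repeats, seed = seed)
      summary <- rbind(summary, .curve_summary(detail[[lab]]$sse, lab))
    }
  }
  regret_tab <- NULL
  if (regret) {
    for (cond in names(detail)) {
      if (is.null(detail[[cond]]$regret)) next
      curves <- detail[[cond]]$regret
      regret_tab <- rbind(regret_tab, data.frame(
        condition = cond, trial = curves[[1]]$trial,
        mean_regret = Reduce(`+`, lapply(curves, `[[`, "regret")) /
          length(curves)))
    }
  }
  manifest <- list(preset = name, repeats = repeats, seed = seed,
                   K = if (is.null(K)) "preset default" else K,
                   levels = levels)
  if (!is.null(out)) {
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    utils::write.csv(summary, file.path(out, "summary.csv"),
                     row.names = FALSE)
    if (!is.null(recovery_tab)) {
      utils::write.csv(recovery_tab, file.path(out, "recovery.csv"),
                       row.names = FALSE)
    }
    if (!is.null(regret_tab)) {
      utils::write.csv(regret_tab, file.path(out, "regret.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out_list <- list(summary = summary, detail = detail, manifest = manifest)
  if (!is.null(regret_tab)) out_list$regret <- regret_tab
  out_list
}
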