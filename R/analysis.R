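#' Per-trial loss summaries
#'
#' `trial_sse()` is the sum over timesteps of the squared error between the
#' decoded (pre-blend) action and the oracle label; `trial_mse()` divides
#' by the trial duration.  SSE is the headline metric because it folds
#' per-step error together with acquisition time; MSE normalizes trial
#' length away.
#'
#' @param record A trial record from [run_trial()] / [run_session()].
#' @return Nonnegative loss (0 for a zero-step record).
#' @export
trial_sse <- function(record) {
  if (record$T_k == 0L) return(0)
  sum((record$a_dec - record$o)^2)
}

#' @rdname trial_sse
#' @export
trial_mse <- function(record) {
  if (record$T_k == 0L) return(0)
  trial_sse(record) / record$T_k
}

#' Best decoder in hindsight
#'
#' The fixed decoder minimizing the total surrogate loss over the realized
#' sample sequence -- the comparator in the regret definition.  It is the
#' follow-the-leader fit on the full dataset, and by construction has no
#' access to goals.
#'
#' @param data The aggregated [bci_dataset()].
#' @param ridge Ridge coefficient (use the same value as the training
#'   algorithms for a matched comparison).
#' @param dt Timestep.
#' @return A [decoder_params()].
#' @export
best_in_hindsight <- function(data, ridge = 1, dt = 1) {
  fit_by_regression(data, ridge = ridge, dt = dt)$params
}

#' Empirical regret curve
#'
#' Cumulative excess loss of the learning sequence over the best fixed
#' decoder in hindsight:
#' \deqn{\mathrm{Regret}_k = \sum_{k' \le k}
#'   \left[L(\pi^{(k')}, D^{(k')}) - L(\pi^\flat, D^{(k')})\right],}
#' where \eqn{\pi^{(k')}} is the decoder *held during* trial `k'`,
#' evaluated on that trial's realized samples, and \eqn{\pi^\flat} is fit
#' once on all `K` trials.  The final value is nonnegative; individual
#' increments need not be.
#'
#' @param history Decoder history from [run_session()] (length `K` or
#'   `K + 1`; with `K + 1` entries the first `K` -- the held decoders --
#'   are used).
#' @param data The aggregated [bci_dataset()].
#' @param ridge Ridge used to fit the hindsight comparator.
#' @return A data frame of class `regret_curve` with columns `trial`,
#'   `loss`, `loss_best`, `regret`; the comparator is attached as the
#'   `"pi_best"` attribute.
#' @export
empirical_regret <- function(history, data, ridge = 1) {
  trials <- sort(unique(data$trial))
  K <- length(trials)
  if (length(history) == K + 1L) history <- history[seq_len(K)]
  if (length(history) != K) {
    stop("history has ", length(history), " decoders for ", K, " trials")
  }
  pi_best <- best_in_hindsight(data, ridge = ridge)
  loss_k <- numeric(K)
  loss_b <- numeric(K)
  for (i in seq_len(K)) {
    batch <- dataset_trials(data, trials[i])
    if (nrow(batch$n) == 0L) next
    loss_k[i] <- surrogate_loss(history[[i]], batch)
    loss_b[i] <- surrogate_loss(pi_best, batch)
  }
  out <- data.frame(trial = trials, loss = loss_k, loss_best = loss_b,
                    regret = cumsum(loss_k - loss_b))
  attr(out, "pi_best") <- pi_best
  class(out) <- c("regret_curve", class(out))
  out
}

#' Regret growth exponent
#'
#' Slope of the least-squares line of `log(regret)` against `log(k)` over a
#' trial range -- the empirical order of regret growth (1 for linear
#' accumulation, about 0.5 for square-root, well below 0.5 for
#' logarithmic).
#'
#' @param curve A `regret_curve` (or any data frame with `trial` and
#'   `regret` columns).
#' @param fit_range Length-2 inclusive trial range.
#' @return The fitted exponent.
#' @export
regret_growth_exponent <- function(curve, fit_range) {
  keep <- curve$trial >= fit_range[1] & curve$trial <= fit_range[2]
  r <- curve$regret[keep]
  k <- curve$trial[keep]
  if (any(r <= 0)) {
    stop("regret must be positive over the fit range; start the range ",
         "after the curve becomes positive")
  }
  unname(stats::coef(stats::lm(log(r) ~ log(k)))[2])
}

#' Encoding-model recovery curve
#'
#' For each prefix `D(1:k)` of the aggregated dataset, re-estimates the
#' encoding matrix by regressing the neural activity on the oracle action
#' (`A_hat = argmin sum ||n_t - A o_t||^2`, with a tiny ridge for
#' stability) and reports, per degree of freedom, the Pearson correlation
#' across neurons between the estimated and true columns of `A`.  Because
#' closed-loop sampling concentrates on task-relevant movements, columns
#' for heavily used joints are recovered in fewer trials than rarely
#' excited distal joints.
#'
#' @param data The aggregated [bci_dataset()].
#' @param true_model The generating [encoding_model()] (simulation only).
#' @param ridge Tiny stabilizing ridge on the action Gram matrix.
#' @return A data frame of class `recovery_curve`: one row per trial, one
#'   `dof<d>` column per degree of freedom, `NA` where the prefix has
#'   fewer samples than degrees of freedom.
#' @export
encoding_recovery <- function(data, true_model, ridge = 1e-8) {
  trials <- sort(unique(data$trial))
  D <- ncol(data$o)
  A <- true_model$A
  G <- matrix(0, D, D)
  Cx <- matrix(0, D, true_model$N)
  count <- 0L
  out <- matrix(NA_real_, length(trials), D)
  for (i in seq_along(trials)) {
    batch <- dataset_trials(data, trials[i])
    if (nrow(batch$o) > 0L) {
      G <- G + crossprod(batch$o)
      Cx <- Cx + crossprod(batch$o, batch$n)
      count <- count + nrow(batch$o)
    }
    if (count < D) next  # too few samples: leave entries flagged NA
    A_hat <- t(solve(G + ridge * diag(D), Cx))  # N x D
    for (d in seq_len(D)) {
      if (stats::sd(A_hat[, d]) > 0 && stats::sd(A[, d]) > 0) {
        out[i, d] <- stats::cor(A_hat[, d], A[, d])
      }
    }
  }
  res <- data.frame(trial = trials)
  colnames(out) <- paste0("dof", seq_len(D))
  res <- cbind(res, as.data.frame(out))
  class(res) <- c("recovery_curve", class(res))
  res
}

#' Trials until a recovery correlation threshold is reached
#'
#' First trial index at which the recovery correlation of a degree of
#' freedom exceeds the threshold; `Inf` if it never does within the
#' session.
#'
#' @param curve A `recovery_curve` from [encoding_recovery()].
#' @param dof Degree-of-freedom index.
#' @param threshold Correlation threshold (default 0.8).
#' @return Trial index or `Inf`.
#' @export
trials_to_recover <- function(curve, dof, threshold = 0.8) {
  vals <- curve[[paste0("dof", dof)]]
  hit <- which(!is.na(vals) & vals > threshold)
  if (length(hit) == 0L) Inf else curve$trial[hit[1]]
}

#' First trial at which a loss curve plateaus
#'
#' The first trial index from which the curve stays within a fractional
#' band of its tail level (the median over the final half of trials).
#'
#' @param sse Per-trial loss curve (e.g. median SSE across repeats).
#' @param frac Band half-width as a fraction of the tail level.
#' @param tail_start First trial of the tail window; defaults to the second
#'   half.
#' @return Trial index (`Inf` if the curve never settles into the band).
#' @export
plateau_trial <- function(sse, frac = 0.25, tail_start = NULL) {
  K <- length(sse)
  if (is.null(tail_start)) tail_start <- floor(K / 2) + 1L
  level <- stats::median(sse[tail_start:K])
  inside <- abs(sse - level) <= frac * level
  ok <- rev(cumprod(rev(inside))) > 0  # inside from here to the end
  if (!any(ok)) Inf else which(ok)[1]
}
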