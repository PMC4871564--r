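#' Aggregated imitation dataset
#'
#' Ordered (state, neural activity, oracle action) triples collected by the
#' closed-loop process, stored as row-aligned matrices with trial and
#' timestep tags.  `v` holds the realized closed-loop velocity at each time
#' (the regressor used alongside the neural activity); `o` holds the oracle
#' label.
#'
#' @param n `M x N` neural activity matrix.
#' @param v `M x D` realized-velocity matrix.
#' @param o `M x D` oracle-action matrix.
#' @param trial Integer vector of trial indices (length `M`).
#' @param t Integer vector of within-trial timesteps.
#' @return An object of class `bci_dataset`.
#' @export
bci_dataset <- function(n, v, o, trial = rep(1L, nrow(n)),
                        t = seq_len(nrow(n))) {
  n <- as.matrix(n); v <- as.matrix(v); o <- as.matrix(o)
  M <- nrow(n)
  if (nrow(v) != M || nrow(o) != M || length(trial) != M || length(t) != M) {
    stop("dataset components must have one row per sample")
  }
  if (ncol(v) != ncol(o)) stop("v and o must share the intention dimension")
  structure(list(n = n, v = v, o = o,
                 trial = as.integer(trial), t = as.integer(t)),
            class = "bci_dataset")
}

#' @export
print.bci_dataset <- function(x, ...) {
  cat("<bci_dataset>", nrow(x$n), "samples,", length(unique(x$trial)),
      "trials,", ncol(x$n), "neurons,", ncol(x$o), "intention dims\n")
  invisible(x)
}

#' Subset a dataset by trial
#'
#' @param data A [bci_dataset()].
#' @param trials Integer vector of trial indices to keep.
#' @return A [bci_dataset()] with the selected trials.
#' @export
dataset_trials <- function(data, trials) {
  keep <- data$trial %in% trials
  bci_dataset(data$n[keep, , drop = FALSE], data$v[keep, , drop = FALSE],
              data$o[keep, , drop = FALSE], data$trial[keep], data$t[keep])
}

#' Concatenate datasets (dataset aggregation)
#'
#' @param ... [bci_dataset()] objects in temporal order.
#' @return The aggregated [bci_dataset()].
#' @export
dataset_bind <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0L) return(NULL)
  bci_dataset(do.call(rbind, lapply(parts, `[[`, "n")),
              do.call(rbind, lapply(parts, `[[`, "v")),
              do.call(rbind, lapply(parts, `[[`, "o")),
              unlist(lapply(parts, `[[`, "trial")),
              unlist(lapply(parts, `[[`, "t")))
}

#' Parameter-update rule specification
#'
#' @param rule One of `"ogd"` (online gradient descent, one step per batch
#'   with rate `1/eta_k`), `"ma"` (moving average / smoothBatch), `"ftl"`
#'   (follow-the-regularized-leader on all aggregated data) or `"rls"`
#'   (FTL executed exactly by recursive least squares; the default FTL
#'   executor).
#' @param lr0 Positive base of the OGD schedule `eta_k = lr0 * k` (the
#'   schedule whose rate grows linearly in the trial index, giving the
#'   logarithmic-regret regime); `schedule = "constant"` uses
#'   `eta_k = lr0` instead.
#' @param lambda Moving-average weight in `[0, 1]` on the new batch fit.
#' @param ridge Shared nonnegative ridge coefficient; OGD uses `ridge / K`
#'   per update so that the total regularization magnitude matches the
#'   batch algorithms.
#' @param K Planned trial count (for the OGD ridge split).
#' @param schedule `"linear"` or `"constant"` OGD learning-rate schedule.
#' @return An object of class `update_spec`.
#' @export
update_spec <- function(rule = c("ftl", "ogd", "ma", "rls"), lr0 = 300,
                        lambda = 0.9, ridge = 5, K = 100L,
                        schedule = c("linear", "constant")) {
  rule <- match.arg(rule)
  schedule <- match.arg(schedule)
  if (lr0 <= 0) stop("lr0 must be positive")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (ridge < 0) stop("ridge must be nonnegative")
  structure(list(rule = rule, lr0 = lr0, lambda = lambda, ridge = ridge,
                 K = as.integer(K), schedule = schedule),
            class = "update_spec")
}

#' Surrogate imitation loss of a decoder on a batch
#'
#' Sum over samples of the squared error between the decoder output
#' `F_v n + b_v + G_v v` and the oracle action -- the loss every update rule
#' optimizes.  The ridge penalty is not included; see [ridge_penalty()].
#'
#' @param params A [decoder_params()].
#' @param batch A [bci_dataset()].
#' @return Nonnegative total squared error.
#' @export
surrogate_loss <- function(params, batch) {
  if (is.null(batch$n) || nrow(batch$n) == 0L) stop("batch is empty")
  Z <- cbind(batch$n, 1, batch$v)
  R <- Z %*% t(.as_weights(params)) - batch$o
  sum(R^2)
}

#' Ridge penalty of a decoder
#'
#' `ridge * (||F_v||_F^2 + ||G_v||_F^2)`; the bias is never penalized.
#'
#' @param params A [decoder_params()].
#' @param ridge Nonnegative coefficient.
#' @return The penalty value.
#' @export
ridge_penalty <- function(params, ridge) {
  ridge * (sum(params$F_v^2) + sum(params$G_v^2))
}

#' Online gradient descent update
#'
#' One step in the direction of the negative gradient of the regularized
#' batch loss,
#' \deqn{\pi^{(k+1)} = \pi^{(k)} - \frac{1}{\eta_k}\nabla_\pi
#'   \left[L(\pi^{(k)}, D^{(k+1)}) + \frac{\mathrm{ridge}}{K}\lVert\pi\rVert^2\right],}
#' with the gradient taken over all entries of `F_v`, `b_v`, `G_v` (the
#' bias is excluded from the penalty term, as in the batch fit).
#'
#' @param params Current [decoder_params()].
#' @param batch The newest trial's [bci_dataset()].
#' @param spec An [update_spec()] (uses `lr0`, `schedule`, `ridge`, `K`).
#' @param k Trial index, determining `eta_k`.
#' @return Updated [decoder_params()].
#' @export
ogd_update <- function(params, batch, spec, k = 1L) {
  eta_k <- if (spec$schedule == "linear") spec$lr0 * k else spec$lr0
  W <- .as_weights(params)
  Z <- cbind(batch$n, 1, batch$v)
  R <- Z %*% t(W) - batch$o
  grad <- 2 * crossprod(R, Z) +
    2 * (spec$ridge / spec$K) * sweep(W, 2, .ridge_mask(params$N, params$D), `*`)
  if (!all(is.finite(grad))) stop("non-finite OGD gradient")
  .from_weights(W - grad / eta_k, params$N, params$D, dt = params$dt)
}

#' Moving-average (smoothBatch) update
#'
#' Convex combination of the current parameters with the ridge-regression
#' minimizer on the newest batch alone:
#' `(1 - lambda) * params + lambda * argmin L(pi, D(k+1))`.
#'
#' @inheritParams ogd_update
#' @return Updated [decoder_params()].
#' @export
ma_update <- function(params, batch, spec) {
  if (spec$lambda < 0 || spec$lambda > 1) stop("lambda must lie in [0, 1]")
  if (spec$lambda == 0) return(params)
  fit <- fit_by_regression(batch, ridge = spec$ridge, dt = params$dt)
  W <- (1 - spec$lambda) * .as_weights(params) +
    spec$lambda * .as_weights(fit$params)
  .from_weights(W, params$N, params$D, dt = params$dt)
}

#' Follow-the-(regularized-)leader update
#'
#' Full re-estimation on all observed data: the ridge-regression minimizer
#' over the aggregate `D(1:k+1)`.  With `ridge > 0` this is FTRL.  The
#' streaming [rls_update()] executor computes the identical solution in
#' O(1) per sample.
#'
#' @param data The aggregated [bci_dataset()].
#' @param spec An [update_spec()] (uses `ridge`).
#' @param dt Timestep carried into the parameters.
#' @return Updated [decoder_params()].
#' @export
ftl_update <- function(data, spec, dt = 1) {
  fit_by_regression(data, ridge = spec$ridge, dt = dt)$params
}

#' Recursive least squares: streaming FTL executor
#'
#' Maintains the inverse regressor Gram matrix `P = (Z'Z + ridge * Itilde)^-1`
#' and the cross-moment `B = Z'O` under per-sample Sherman--Morrison rank-1
#' updates, so the parameters after any number of streamed samples equal
#' the batch ridge fit on everything seen so far.  The ridge prior excludes
#' the bias coordinate (matching [fit_by_regression()]); since that prior
#' Gram is singular in the bias direction, `P` is formed by a direct solve
#' once the first sample arrives (the Gram is then provably nonsingular for
#' `ridge > 0`) and updated rank-1 thereafter.
#'
#' @param N Neuron count.
#' @param D Intention dimension.
#' @param ridge Positive ridge coefficient (the prior).
#' @param dt Timestep.
#' @return An `rls_state` object.
#' @export
rls_init <- function(N, D, ridge = 1, dt = 1) {
  if (ridge <= 0) stop("RLS needs ridge > 0 as its prior")
  p <- N + 1L + D
  structure(list(N = N, D = D, p = p, ridge = ridge, dt = dt,
                 P = NULL, S = diag(ridge * .ridge_mask(N, D), p),
                 B = matrix(0, p, D), count = 0L),
            class = "rls_state")
}

#' @rdname rls_init
#' @param state An `rls_state`.
#' @param batch A [bci_dataset()] of new samples (processed in order); an
#'   empty batch leaves the state unchanged.
#' @export
rls_update <- function(state, batch) {
  M <- if (is.null(batch$n)) 0L else nrow(batch$n)
  if (M == 0L) return(state)
  Z <- cbind(batch$n, 1, batch$v)
  O <- batch$o
  for (i in seq_len(M)) {
    z <- Z[i, ]
    state$B <- state$B + z %o% O[i, ]
    state$count <- state$count + 1L
    if (is.null(state$P)) {
      state$S <- state$S + z %o% z
      state$P <- tryCatch(solve(state$S), error = function(e) NULL)
      if (!is.null(state$P)) state$S <- NULL  # else keep accumulating S
    } else {
      Pz <- as.numeric(state$P %*% z)
      state$P <- state$P - (Pz %o% Pz) / (1 + sum(z * Pz))
      state$P <- (state$P + t(state$P)) / 2  # keep symmetric against drift
    }
  }
  if (!is.null(state$P) && any(diag(state$P) <= 0)) {
    stop("RLS inverse Gram lost positive definiteness; re-factorize from the raw data")
  }
  state
}

#' @rdname rls_init
#' @export
rls_params <- function(state) {
  if (is.null(state$P)) {
    stop("RLS state has no invertible Gram yet (no samples streamed)")
  }
  .from_weights(t(state$P %*% state$B), state$N, state$D, dt = state$dt)
}
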