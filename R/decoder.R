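#' Steady-state velocity Kalman filter decoder parameters
#'
#' The decoder family is the steady-state velocity Kalman filter (SSVKF)
#' treated directly as a parameterized policy:
#' \deqn{v_{t+1} = F_v n_t + b_v + G_v v_t, \qquad p_{t+1} = p_t + \Delta t\, v_t.}
#' `F_v` reads velocity out of the neural activity, `b_v` absorbs firing
#' offsets, and `G_v` is the velocity prior dynamics (smoothing).  No
#' explicit Kalman recursion is run; the steady-state gain is whatever the
#' regression fit produces.
#'
#' @param F_v `D x N` matrix.
#' @param b_v Length-`D` bias vector.
#' @param G_v `D x D` matrix.
#' @param dt Positive timestep length.
#' @return An object of class `decoder_params`.
#' @export
decoder_params <- function(F_v, b_v, G_v, dt = 1) {
  F_v <- as.matrix(F_v); G_v <- as.matrix(G_v); b_v <- as.numeric(b_v)
  D <- nrow(F_v)
  if (length(b_v) != D || nrow(G_v) != D || ncol(G_v) != D) {
    stop("inconsistent decoder shapes: F_v is ", D, "x", ncol(F_v),
         ", b_v length ", length(b_v), ", G_v ", nrow(G_v), "x", ncol(G_v))
  }
  if (!all(is.finite(F_v)) || !all(is.finite(b_v)) || !all(is.finite(G_v))) {
    stop("decoder parameters must be finite")
  }
  if (dt <= 0) stop("dt must be positive")
  structure(list(F_v = F_v, b_v = b_v, G_v = G_v, dt = dt,
                 N = ncol(F_v), D = D),
            class = "decoder_params")
}

#' @export
print.decoder_params <- function(x, ...) {
  cat("<decoder_params> D =", x$D, " N =", x$N, " dt =", x$dt, "\n")
  invisible(x)
}

# Flatten to the D x (N+1+D) weight matrix W = [F_v | b_v | G_v] acting on
# the regressor z = [n; 1; v]; and back.
.as_weights <- function(params) cbind(params$F_v, params$b_v, params$G_v)

.from_weights <- function(W, N, D, dt = 1) {
  decoder_params(F_v = W[, seq_len(N), drop = FALSE],
                 b_v = W[, N + 1],
                 G_v = W[, (N + 2):(N + 1 + D), drop = FALSE],
                 dt = dt)
}

# Ridge mask: penalize F_v and G_v blocks, never the bias.
.ridge_mask <- function(N, D) c(rep(1, N), 0, rep(1, D))

#' One decoding step
#'
#' Applies the SSVKF: the new velocity is read from the neural activity and
#' the previous velocity, and the pose advances with the *current* velocity.
#'
#' @param n Neural activity vector (length `N`).
#' @param state A [kin_state()].
#' @param params A [decoder_params()].
#' @return List with `action` (the new velocity) and `state` (the advanced
#'   [kin_state()] whose velocity is the action).
#' @export
decode_step <- function(n, state, params) {
  n <- as.numeric(n)
  if (length(n) != params$N) {
    stop("decoder expects ", params$N, " neurons, got ", length(n))
  }
  if (length(state$velocity) != params$D) {
    stop("decoder dimension ", params$D, " does not match state dimension ",
         length(state$velocity))
  }
  v_new <- as.numeric(params$F_v %*% n + params$b_v +
                        params$G_v %*% state$velocity)
  list(action = v_new,
       state = integrate_state(state, v_new, dt = params$dt))
}

#' Fit the decoder by ridge regression
#'
#' Solves the surrogate imitation problem: regress the oracle actions `o_t`
#' on the regressors `[n_t; 1; v_t]`, where `v_t` is the realized
#' closed-loop velocity at time `t`, with one shared design for all target
#' dimensions.  The ridge penalty applies to the `F_v` and `G_v` blocks but
#' not to the bias, so noiseless identifiable data is recovered exactly at
#' `ridge = 0`.
#'
#' @param data A [bci_dataset()] (or any list with matrices `n`, `v`, `o`).
#' @param ridge Nonnegative ridge coefficient.
#' @param dt Timestep carried into the returned parameters.
#' @return List with `params` (a [decoder_params()]) and `report` (residual
#'   variance per target dimension, effective sample count, ridge used).
#' @export
fit_by_regression <- function(data, ridge = 1, dt = 1) {
  if (is.null(data$n) || nrow(data$n) == 0L) stop("dataset is empty")
  if (ridge < 0) stop("ridge must be nonnegative")
  Z <- cbind(data$n, 1, data$v)
  O <- data$o
  N <- ncol(data$n); D <- ncol(data$v)
  G <- crossprod(Z) + diag(ridge * .ridge_mask(N, D), ncol(Z))
  B <- crossprod(Z, O)
  Wt <- tryCatch(solve(G, B), error = function(e) {
    stop("singular regression design",
         if (ridge == 0) " at ridge = 0; supply ridge > 0" else "",
         call. = FALSE)
  })
  params <- .from_weights(t(Wt), N, D, dt = dt)
  resid <- O - Z %*% Wt
  list(params = params,
       report = list(residual_variance = colMeans(resid^2),
                     n_samples = nrow(Z), ridge = ridge))
}

#' Random initial decoder
#'
#' A stable, poorly performing starting point: entries of `F_v` and `G_v`
#' are i.i.d. `N(0, scale^2)`, the bias is zero, and `G_v` is rescaled
#' whenever its spectral radius approaches 1 so the autonomous velocity
#' dynamics are contractive (bounded output).  `scale = 0` gives the
#' all-zero decoder.
#'
#' @param N Neuron count.
#' @param D Intention dimension.
#' @param scale Nonnegative standard deviation of the initial entries.
#' @param dt Timestep.
#' @param seed Optional seed.
#' @return A [decoder_params()].
#' @export
init_decoder <- function(N, D, scale = 0.01, dt = 1, seed = NULL) {
  if (scale < 0) stop("scale must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  F_v <- matrix(stats::rnorm(D * N, sd = scale), D, N)
  G_v <- matrix(stats::rnorm(D * D, sd = scale), D, D)
  rho <- max(Mod(eigen(G_v, only.values = TRUE)$values))
  if (rho >= 0.95) G_v <- G_v * 0.9 / rho
  decoder_params(F_v, rep(0, D), G_v, dt = dt)
}

#' Serialize decoder parameters to or from JSON
#'
#' Matrices are written row-major with a shape header.
#'
#' @param params A [decoder_params()].
#' @param path File path.
#' @export
decoder_to_json <- function(params, path) {
  doc <- list(N = params$N, D = params$D, dt = params$dt,
              F_v = apply(params$F_v, 1, as.numeric, simplify = FALSE),
              b_v = params$b_v,
              G_v = apply(params$G_v, 1, as.numeric, simplify = FALSE))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname decoder_to_json
#' @export
decoder_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x, D) {
    if (is.matrix(x)) x else matrix(unlist(x), nrow = D, byrow = TRUE)
  }
  decoder_params(F_v = as_mat(doc$F_v, doc$D), b_v = doc$b_v,
                 G_v = as_mat(doc$G_v, doc$D), dt = doc$dt)
}
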