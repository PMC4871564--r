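#' Linear-Gaussian neural encoding model
#'
#' Synthetic neural activity is generated from the user's intended velocity
#' `o` as `n = A o + c`, `c ~ N(0, C)`.  `A` maps intention to firing-rate
#' units; `C` defaults to a scaled identity `sigma2 * I` calibrated so the
#' per-neuron signal-to-noise ratio hits a target (see [calibrate_noise()]).
#'
#' @param A `N x D` encoding matrix (neurons by intention dimensions).
#' @param sigma2 Noise variance; a scalar (isotropic `C = sigma2 I`) or a
#'   length-`N` vector (diagonal `C`).
#' @return An object of class `encoding_model` with fields `A`, `sigma2`,
#'   `N`, `D`.
#' @export
encoding_model <- function(A, sigma2 = 0) {
  A <- as.matrix(A)
  if (!all(is.finite(A))) stop("A must be finite")
  if (any(sigma2 < 0)) stop("noise variance must be nonnegative")
  if (!(length(sigma2) %in% c(1L, nrow(A)))) {
    stop("sigma2 must be a scalar or one value per neuron")
  }
  structure(list(A = A, sigma2 = sigma2, N = nrow(A), D = ncol(A)),
            class = "encoding_model")
}

#' @export
print.encoding_model <- function(x, ...) {
  cat("<encoding_model>", x$N, "neurons x", x$D, "intention dims, sigma2 =",
      format(x$sigma2, digits = 4), "\n")
  invisible(x)
}

#' Sample a random encoding matrix
#'
#' Entries of `A` are i.i.d. standard normal.  With `rectify = TRUE`
#' negative entries are set to zero, giving neurons that do not encode every
#' degree of freedom (used for the arm task).  Noise is left at zero; set it
#' with [calibrate_noise()].
#'
#' @param N Number of neurons (positive).
#' @param D Intention dimension (positive).
#' @param rectify Zero out negative entries of `A`?
#' @param seed Optional integer seed for reproducibility.
#' @return An [encoding_model()] with `sigma2 = 0`.
#' @export
sample_encoding_model <- function(N, D, rectify = FALSE, seed = NULL) {
  if (N < 1 || D < 1) stop("N and D must be positive integers")
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(stats::rnorm(N * D), N, D)
  if (rectify) A[A < 0] <- 0
  encoding_model(A, sigma2 = 0)
}

#' Calibrate the noise variance to a target signal-to-noise ratio
#'
#' SNR is operationalized as signal power over noise variance under the
#' oracle action distribution: directions uniform on the unit sphere in `D`
#' dimensions, norm equal to the oracle speed.  For that distribution the
#' expected squared signal of neuron `i` is `speed^2 ||A_i||^2 / D`, so
#' \deqn{\sigma^2 = \frac{\mathrm{speed}^2}{D\,\mathrm{SNR}}\,
#'   \mathrm{mean}_i \lVert A_{i\cdot}\rVert^2}
#' (averaged over neurons by default; `per_neuron = TRUE` instead gives each
#' neuron its own variance so every neuron individually sits at the target).
#'
#' @param model An [encoding_model()] (or a bare `A` matrix).
#' @param speed Oracle action norm (task units per timestep).
#' @param target_snr Positive target SNR (default 1, i.e. noise magnitude
#'   roughly equal to signal magnitude per neuron).
#' @param per_neuron Calibrate each neuron separately?
#' @return The model with `sigma2` set (a matrix input returns a new model).
#' @export
calibrate_noise <- function(model, speed, target_snr = 1, per_neuron = FALSE) {
  if (target_snr <= 0) stop("target_snr must be positive")
  A <- if (inherits(model, "encoding_model")) model$A else as.matrix(model)
  if (all(A == 0)) stop("A is identically zero: SNR is undefined")
  D <- ncol(A)
  sig <- speed^2 * rowSums(A^2) / D   # E[(A o)_i^2]
  sigma2 <- if (per_neuron) sig / target_snr else mean(sig) / target_snr
  encoding_model(A, sigma2 = sigma2)
}

#' Generate one sample of neural activity
#'
#' `n = A o_user + c` with `c ~ N(0, sigma2 I)` (or diagonal `C`).  The
#' driving signal is the *user intention* -- after any model mismatch --
#' while the unmismatched oracle provides the training label; with no
#' mismatch the two coincide and the oracle is used twice.
#'
#' @param o_user Intended velocity driving the neurons (length `D`).
#' @param model An [encoding_model()].
#' @return Numeric length-`N` activity vector.
#' @export
encode <- function(o_user, model) {
  o_user <- as.numeric(o_user)
  if (length(o_user) != model$D) {
    stop("model expects intention dimension ", model$D, ", got ",
         length(o_user))
  }
  n <- as.numeric(model$A %*% o_user)
  if (any(model$sigma2 > 0)) {
    n <- n + stats::rnorm(model$N, sd = sqrt(model$sigma2))
  }
  n
}

#' Serialize an encoding model to or from JSON
#'
#' @param model An [encoding_model()].
#' @param path File path.
#' @export
encoding_to_json <- function(model, path) {
  doc <- list(N = model$N, D = model$D, sigma2 = model$sigma2,
              A = apply(model$A, 1, as.numeric, simplify = FALSE))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname encoding_to_json
#' @export
encoding_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- if (is.matrix(doc$A)) doc$A else
    matrix(unlist(doc$A), nrow = doc$N, byrow = TRUE)
  encoding_model(A, sigma2 = doc$sigma2)
}
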