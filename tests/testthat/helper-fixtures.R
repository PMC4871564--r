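# Shared small fixtures, all generated in code.

# a tiny 3-link planar chain (all joints about z), unit-ish links
planar_chain <- function(lengths = c(1, 0.8, 0.5)) {
  n <- length(lengths)
  chain_model(lengths, as.list(rep("z", n)),
              markers = list(tip = list(link = n, offset = lengths[n])))
}

# independent forward kinematics via 4x4 homogeneous transforms
fk_homogeneous <- function(chain, angles) {
  rot4 <- function(a, th) {
    ct <- cos(th); st <- sin(th)
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    R <- diag(3) * ct + st * K + (1 - ct) * (a %o% a)
    H <- diag(4); H[1:3, 1:3] <- R
    H
  }
  trans4 <- function(v) { H <- diag(4); H[1:3, 4] <- v; H }
  H <- trans4(chain$base_position)
  out <- list()
  for (i in seq_len(chain$n_joints)) {
    H <- H %*% rot4(chain$axes[[i]], angles[i])
    for (nm in names(chain$markers)) {
      m <- chain$markers[[nm]]
      if (m$link == i) {
        out[[nm]] <- as.numeric((H %*% c(m$offset, 0, 0, 1))[1:3])
      }
    }
    H <- H %*% trans4(c(chain$link_lengths[i], 0, 0))
  }
  out
}

# random small dataset with a known generating decoder (noiseless unless sd > 0)
random_dataset <- function(M, N, D, params = NULL, sd = 0, seed = 1) {
  set.seed(seed)
  n <- matrix(rnorm(M * N), M, N)
  v <- matrix(rnorm(M * D), M, D)
  if (is.null(params)) {
    o <- matrix(rnorm(M * D), M, D)
  } else {
    o <- n %*% t(params$F_v) + rep(1, M) %o% params$b_v + v %*% t(params$G_v) +
      matrix(rnorm(M * D, sd = sd), M, D)
  }
  bci_dataset(n, v, o)
}

random_params <- function(N, D, seed = 1, dt = 1) {
  set.seed(seed)
  decoder_params(matrix(rnorm(D * N), D, N), rnorm(D),
                 matrix(rnorm(D * D) * 0.3, D, D), dt = dt)
}

# brute-force ridge solution via explicitly assembled normal equations
normal_equations_fit <- function(data, ridge) {
  Z <- cbind(data$n, 1, data$v)
  mask <- c(rep(1, ncol(data$n)), 0, rep(1, ncol(data$v)))
  t(solve(crossprod(Z) + diag(ridge * mask, ncol(Z)), crossprod(Z, data$o)))
}

tiny_cursor_config <- function(seed = 1, K = 10L, rule = "ftl", ...) {
  cursor_preset(seed = seed, K = K, update = default_update(rule), ...)
}
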