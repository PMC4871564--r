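test_that("surrogate loss equals a per-sample loop summation", {
  p <- random_params(4, 3, seed = 1)
  data <- random_dataset(25, 4, 3, seed = 2)
  ref <- 0
  for (i in 1:25) {
    pred <- as.numeric(p$F_v %*% data$n[i, ] + p$b_v + p$G_v %*% data$v[i, ])
    ref <- ref + sum((pred - data$o[i, ])^2)
  }
  expect_equal(surrogate_loss(p, data), ref, tolerance = 1e-10)

  truth <- random_params(4, 3, seed = 3)
  own <- random_dataset(10, 4, 3, params = truth, sd = 0, seed = 4)
  expect_lt(surrogate_loss(truth, own), 1e-20)
  one <- bci_dataset(matrix(0, 1, 4), matrix(0, 1, 3), matrix(0, 1, 3))
  shifted <- decoder_params(truth$F_v * 0, c(1, 0, 0), truth$G_v * 0)
  expect_equal(surrogate_loss(shifted, one), 1)
  expect_error(surrogate_loss(p, list(n = NULL)), "empty")
})

test_that("OGD leaves zero-loss parameters unchanged and vanishes at rate zero", {
  truth <- random_params(4, 3, seed = 5)
  own <- random_dataset(20, 4, 3, params = truth, sd = 0, seed = 6)
  spec <- update_spec("ogd", lr0 = 100, ridge = 0)
  upd <- ogd_update(truth, own, spec, k = 1)
  expect_equal(upd$F_v, truth$F_v, tolerance = 1e-10)
  expect_equal(upd$G_v, truth$G_v, tolerance = 1e-10)

  spec_inf <- update_spec("ogd", lr0 = 1e300, ridge = 3)
  p <- random_params(4, 3, seed = 7)
  batch <- random_dataset(15, 4, 3, seed = 8)
  upd2 <- ogd_update(p, batch, spec_inf, k = 1)
  expect_equal(upd2$F_v, p$F_v, tolerance = 1e-12)
})

test_that("the OGD gradient matches central finite differences", {
  p <- random_params(3, 2, seed = 9)
  batch <- random_dataset(12, 3, 2, seed = 10)
  spec <- update_spec("ogd", lr0 = 1, ridge = 2, K = 10L,
                      schedule = "constant")
  upd <- ogd_update(p, batch, spec, k = 1)
  # recover the analytic gradient from the unit-rate step
  grad <- cbind(p$F_v - upd$F_v, p$b_v - upd$b_v, p$G_v - upd$G_v)
  obj <- function(q) {
    surrogate_loss(q, batch) + ridge_penalty(q, spec$ridge / spec$K)
  }
  h <- 1e-6
  for (block in c("F_v", "b_v", "G_v")) {
    for (idx in seq_along(p[[block]])) {
      qp <- p; qp[[block]][idx] <- qp[[block]][idx] + h
      qm <- p; qm[[block]][idx] <- qm[[block]][idx] - h
      fd <- (obj(qp) - obj(qm)) / (2 * h)
      col_off <- switch(block, F_v = 0, b_v = ncol(p$F_v) * nrow(p$F_v),
                        G_v = (ncol(p$F_v) + 1) * nrow(p$F_v))
      expect_equal(grad[idx + col_off], fd, tolerance = 1e-5)
    }
  }
})

test_that("moving-average update interpolates between old and batch fit", {
  p <- random_params(4, 3, seed = 11)
  batch <- random_dataset(30, 4, 3, seed = 12)
  fit <- fit_by_regression(batch, ridge = 3)$params

  expect_identical(ma_update(p, batch, update_spec("ma", lambda = 0)), p)
  at1 <- ma_update(p, batch, update_spec("ma", lambda = 1, ridge = 3))
  expect_equal(at1$F_v, fit$F_v, tolerance = 1e-12)
  half <- ma_update(p, batch, update_spec("ma", lambda = 0.5, ridge = 3))
  expect_equal(half$F_v, (p$F_v + fit$F_v) / 2, tolerance = 1e-12)
  expect_equal(half$b_v, (p$b_v + fit$b_v) / 2, tolerance = 1e-12)
  expect_equal(half$G_v, (p$G_v + fit$G_v) / 2, tolerance = 1e-12)
})

test_that("MA retains its initialization gap exactly as (1 - lambda)^k", {
  lam <- 0.9
  spec <- update_spec("ma", lambda = lam, ridge = 1)
  pA <- random_params(3, 2, seed = 13)
  pB <- random_params(3, 2, seed = 14)
  gap0 <- pA$F_v - pB$F_v
  set.seed(15)
  for (k in 1:6) {
    batch <- random_dataset(20, 3, 2, seed = 20 + k)
    pA <- ma_update(pA, batch, spec)
    pB <- ma_update(pB, batch, spec)
    expect_equal(pA$F_v - pB$F_v, (1 - lam)^k * gap0, tolerance = 1e-10)
  }
})

test_that("FTL is the batch minimizer on the aggregate", {
  d1 <- random_dataset(20, 4, 3, seed = 16)
  d2 <- random_dataset(25, 4, 3, seed = 17)
  spec <- update_spec("ftl", ridge = 2)
  p <- ftl_update(d1, spec)
  # after one trial FTL equals MA with lambda = 1 on the same batch
  pm <- ma_update(random_params(4, 3, seed = 18), d1,
                  update_spec("ma", lambda = 1, ridge = 2))
  expect_equal(p$F_v, pm$F_v, tolerance = 1e-12)

  agg <- dataset_bind(d1, d2)
  pf <- ftl_update(agg, spec)
  W_ref <- normal_equations_fit(agg, 2)
  expect_equal(cbind(pf$F_v, pf$b_v, pf$G_v), W_ref, tolerance = 1e-10)

  # duplicating every sample leaves the unregularized solution unchanged
  pf0 <- ftl_update(agg, update_spec("ftl", ridge = 0))
  dup <- dataset_bind(agg, agg)
  pf0d <- ftl_update(dup, update_spec("ftl", ridge = 0))
  expect_equal(pf0$F_v, pf0d$F_v, tolerance = 1e-8)
})

test_that("RLS reproduces the batch ridge fit after every streamed sample", {
  N <- 4; D <- 3; ridge <- 2
  data <- random_dataset(200, N, D, seed = 19)
  st <- rls_init(N, D, ridge = ridge)
  worst <- 0
  for (i in 1:200) {
    st <- rls_update(st, bci_dataset(data$n[i, , drop = FALSE],
                                     data$v[i, , drop = FALSE],
                                     data$o[i, , drop = FALSE]))
    prefix <- bci_dataset(data$n[1:i, , drop = FALSE],
                          data$v[1:i, , drop = FALSE],
                          data$o[1:i, , drop = FALSE])
    batch <- fit_by_regression(prefix, ridge = ridge)$params
    stream <- rls_params(st)
    worst <- max(worst,
                 max(abs(stream$F_v - batch$F_v)),
                 max(abs(stream$b_v - batch$b_v)),
                 max(abs(stream$G_v - batch$G_v)))
  }
  expect_lt(worst, 1e-8)
})

test_that("RLS is chunking-invariant and inert on empty input", {
  data <- random_dataset(60, 3, 2, seed = 20)
  st1 <- rls_init(3, 2, ridge = 1)
  st1 <- rls_update(st1, data)
  st2 <- rls_init(3, 2, ridge = 1)
  st2 <- rls_update(st2, dataset_trials(bci_dataset(
    data$n, data$v, data$o, trial = rep(1:2, each = 30)), 1))
  st2 <- rls_update(st2, dataset_trials(bci_dataset(
    data$n, data$v, data$o, trial = rep(1:2, each = 30)), 2))
  p1 <- rls_params(st1); p2 <- rls_params(st2)
  expect_equal(p1$F_v, p2$F_v, tolerance = 1e-10)
  expect_equal(p1$G_v, p2$G_v, tolerance = 1e-10)

  before <- rls_params(st1)
  st1b <- rls_update(st1, list(n = NULL))
  expect_equal(rls_params(st1b)$F_v, before$F_v)
  expect_error(rls_init(3, 2, ridge = 0), "ridge > 0")
})

test_that("dataset aggregation bookkeeping is consistent", {
  d1 <- random_dataset(10, 3, 2, seed = 21)
  d2 <- random_dataset(15, 3, 2, seed = 22)
  d2$trial <- rep(2L, 15)
  agg <- dataset_bind(d1, d2)
  expect_equal(nrow(agg$n), 25)
  expect_equal(nrow(dataset_trials(agg, 2)$n), 15)
  expect_equal(dataset_trials(agg, 1)$o, d1$o)
})
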