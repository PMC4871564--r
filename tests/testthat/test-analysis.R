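test_that("trial losses sum per-step squared errors", {
  rec <- list(T_k = 2L,
              a_dec = rbind(c(1, 0, 0), c(0, 1, 1)),
              o = rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_equal(trial_sse(rec), 3)   # per-step losses 1 and 2
  expect_equal(trial_mse(rec), 1.5)
  expect_equal(trial_sse(list(T_k = 0L)), 0)

  set.seed(1)
  rec2 <- list(T_k = 7L, a_dec = matrix(rnorm(21), 7, 3),
               o = matrix(rnorm(21), 7, 3))
  ref <- sum(vapply(1:7, function(t) sum((rec2$a_dec[t, ] - rec2$o[t, ])^2),
                    numeric(1)))
  expect_equal(trial_sse(rec2), ref, tolerance = 1e-12)
})

test_that("the hindsight decoder minimizes total loss over the history", {
  cfg <- tiny_cursor_config(seed = 2, K = 8L)
  s <- run_session(cfg)
  pb <- best_in_hindsight(s$dataset, ridge = 1e-6)
  ftl <- ftl_update(s$dataset, update_spec("ftl", ridge = 1e-6))
  expect_equal(pb$F_v, ftl$F_v, tolerance = 1e-12)
  total <- surrogate_loss(pb, s$dataset)
  for (p in s$history) {
    expect_lte(total, surrogate_loss(p, s$dataset) + 1e-9)
  }
  # beats random perturbations of itself (small sample certificate)
  small <- bci_dataset(s$dataset$n[1:10, ], s$dataset$v[1:10, ],
                       s$dataset$o[1:10, ])
  pb10 <- best_in_hindsight(small, ridge = 1e-8)
  base <- surrogate_loss(pb10, small)
  set.seed(3)
  for (i in 1:2000) {
    q <- pb10
    q$F_v <- q$F_v + matrix(rnorm(30, sd = 1e-2), 3, 10)
    q$b_v <- q$b_v + rnorm(3, sd = 1e-2)
    q$G_v <- q$G_v + matrix(rnorm(9, sd = 1e-2), 3, 3)
    expect_gte(surrogate_loss(q, small), base - 1e-12)
  }
})

test_that("empirical regret matches a hand-assembled toy computation", {
  # 4 one-sample trials in 1D with N = 1 neuron; o = n exactly, so the
  # best fixed decoder is F = 1, G = 0, b = 0 with zero loss
  data <- bci_dataset(n = matrix(c(1, 2, -1, 3), 4, 1),
                      v = matrix(c(0.5, -0.2, 0.3, 0.1), 4, 1),
                      o = matrix(c(1, 2, -1, 3), 4, 1),
                      trial = 1:4, t = rep(1L, 4))
  make_p <- function(f) decoder_params(matrix(f, 1, 1), 0, matrix(0, 1, 1))
  history <- list(make_p(0), make_p(0.5), make_p(1), make_p(0.8))
  curve <- empirical_regret(history, data, ridge = 0)
  pb <- attr(curve, "pi_best")
  expect_equal(as.numeric(pb$F_v), 1, tolerance = 1e-9)
  expect_equal(as.numeric(pb$G_v), 0, tolerance = 1e-9)
  losses <- c((0 - 1)^2, (0.5 * 2 - 2)^2, (1 * -1 - -1)^2, (0.8 * 3 - 3)^2)
  expect_equal(curve$loss, losses, tolerance = 1e-9)
  expect_equal(curve$regret, cumsum(losses), tolerance = 1e-8)

  # decoders identical to the comparator have identically zero regret
  hist0 <- list(pb, pb, pb, pb)
  expect_equal(empirical_regret(hist0, data, ridge = 0)$regret, rep(0, 4),
               tolerance = 1e-9)
  expect_error(empirical_regret(history[1:2], data), "decoders for")
})

test_that("final regret of a learning run is nonnegative", {
  cfg <- tiny_cursor_config(seed = 4, K = 10L)
  s <- run_session(cfg)
  curve <- empirical_regret(s$history, s$dataset, ridge = 1e-8)
  expect_gte(curve$regret[10], -1e-6)
})

test_that("regret exponents recover known growth laws", {
  k <- 1:500
  expect_equal(regret_growth_exponent(data.frame(trial = k, regret = k),
                                      c(50, 500)), 1, tolerance = 0.01)
  expect_equal(regret_growth_exponent(data.frame(trial = k, regret = sqrt(k)),
                                      c(50, 500)), 0.5, tolerance = 0.01)
  expect_lt(regret_growth_exponent(data.frame(trial = k,
                                              regret = log(k + 1)),
                                   c(50, 500)), 0.3)
  expect_error(regret_growth_exponent(data.frame(trial = k, regret = k - 10),
                                      c(1, 500)), "positive")
})

test_that("encoding recovery is exact on noiseless exciting data", {
  set.seed(5)
  A <- matrix(rnorm(18), 6, 3)
  model <- encoding_model(A, sigma2 = 0)
  o <- matrix(rnorm(60), 20, 3)
  data <- bci_dataset(n = o %*% t(A), v = matrix(0, 20, 3), o = o,
                      trial = rep(1:2, each = 10), t = rep(1:10, 2))
  curve <- encoding_recovery(data, model)
  expect_equal(unname(as.matrix(curve[2, -1])), matrix(1, 1, 3),
               tolerance = 1e-6)

  # the estimate itself matches the dense normal-equations solve
  G <- crossprod(o); Cx <- crossprod(o, data$n)
  A_ref <- t(solve(G + 1e-8 * diag(3), Cx))
  curve_one <- encoding_recovery(
    bci_dataset(data$n, data$v, data$o), model)
  expect_equal(nrow(curve_one), 1)

  # correlation is invariant under positive column rescaling
  model2 <- encoding_model(sweep(A, 2, c(2, 3, 0.5), `*`), sigma2 = 0)
  data2 <- bci_dataset(n = o %*% t(model2$A), v = matrix(0, 20, 3), o = o,
                       trial = rep(1:2, each = 10), t = rep(1:10, 2))
  curve2 <- encoding_recovery(data2, model2)
  expect_equal(unname(as.matrix(curve2[2, -1])), matrix(1, 1, 3),
               tolerance = 1e-6)

  expect_equal(trials_to_recover(curve, 1), 1)
  none <- curve; none$dof1 <- rep(0.1, 2)
  expect_identical(trials_to_recover(none, 1), Inf)
})

test_that("plateau detection finds where a curve settles", {
  curve <- c(100, 40, 10, 3, 2.1, rep(2, 45))
  expect_equal(plateau_trial(curve), 5)
  expect_identical(plateau_trial(c(5, 5, 5, 5, 100)), Inf)
})

test_that("experiment presets run end to end at toy scale", {
  res <- run_experiment_preset("cursor_compare", repeats = 2L, K = 6L,
                               seed = 1)
  expect_setequal(unique(res$summary$condition), c("ftl", "ogd", "ma"))
  expect_equal(nrow(res$summary), 18)
  expect_true(all(is.finite(res$summary$mean_sse)))

  dir <- withr::local_tempdir()
  res2 <- run_experiment_preset("cursor_noise", repeats = 2L, K = 5L,
                                seed = 1, levels = c(0, 100), out = dir)
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_error(run_experiment_preset("nope"), "available")
})
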