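test_that("cursor oracle points at the target with fixed speed", {
  expect_equal(cursor_oracle(c(0, 0, 0), goal_point(c(2, 0, 0)), speed = 0.1),
               c(0.1, 0, 0))
  expect_equal(cursor_oracle(c(1, 1, 1), goal_point(c(1, 1, 1)), speed = 0.5),
               c(0, 0, 0))
  expect_error(cursor_oracle(c(0, 0, 0), goal_point(c(1, 0, 0)), speed = 0),
               "positive")
})

test_that("cursor oracle actions are equal-length until the final approach", {
  set.seed(5)
  for (i in 1:1000) {
    p <- runif(3, -10, 10); g <- runif(3, -10, 10)
    o <- cursor_oracle(p, goal_point(g), speed = 0.5)
    d <- sqrt(sum((g - p)^2))
    if (d > 0.5) {
      expect_equal(sqrt(sum(o^2)), 0.5, tolerance = 1e-12)
    } else {
      expect_equal(p + o, g, tolerance = 1e-12)  # no overshoot
    }
  }
})

test_that("chain oracle is zero at the target and bounded per joint", {
  ch <- planar_chain(c(1, 1, 0.5))
  ang <- c(0.3, -0.2, 0.4)
  tip <- forward_kinematics(ch, ang)$tip
  # a wand sitting exactly on the wrist/tip markers gives a zero action
  ch2 <- chain_model(c(1, 1, 0.5), list("z", "z", "z"),
                     markers = list(wrist = list(link = 3, offset = 0.5),
                                    thumb_tip = list(link = 3, offset = 0.5),
                                    mid_tip = list(link = 3, offset = 0.5)))
  g <- goal_wand(tip, rbind(tip, tip))
  o <- chain_oracle(ch2, ang, g, chain_oracle_spec())
  expect_equal(o, rep(0, 3), tolerance = 1e-12)

  set.seed(9)
  spec <- chain_oracle_spec(omega_max = 0.05)
  for (i in 1:20) {
    ang <- runif(3, -pi, pi)
    g <- goal_wand(runif(3, -1, 1))
    o <- chain_oracle(ch2, ang, g, spec)
    expect_lte(max(abs(o)), 0.05 + 1e-12)
  }
})

test_that("chain oracle step descends the marker cost", {
  # 1-link: sign of the update matches the finite-difference gradient
  ch <- chain_model(1, list("z"),
                    markers = list(wrist = list(link = 1, offset = 1),
                                   thumb_tip = list(link = 1, offset = 1),
                                   mid_tip = list(link = 1, offset = 1)))
  g <- goal_wand(c(cos(0.5), sin(0.5), 0))
  cost <- function(a) {
    sum((forward_kinematics(ch, a)$wrist - g$position)^2)
  }
  for (a0 in c(0.1, 0.9, -0.4)) {
    o <- chain_oracle(ch, a0, g, chain_oracle_spec(delta = 1e-6))
    fd <- (cost(a0 + 1e-6) - cost(a0 - 1e-6)) / 2e-6
    expect_equal(sign(o), -sign(fd))
  }

  # 2-link: the step reduces phase-1 cost, and its direction agrees with a
  # brute-force one-step search over joint increments in a small ball
  ch2 <- chain_model(c(1, 0.7), list("z", "y"),
                     markers = list(wrist = list(link = 2, offset = 0.7),
                                    thumb_tip = list(link = 2, offset = 0.7),
                                    mid_tip = list(link = 2, offset = 0.7)))
  g2 <- goal_wand(c(0.5, 0.9, -0.3))
  cost2 <- function(a) sum((forward_kinematics(ch2, a)$wrist - g2$position)^2)
  set.seed(21)
  spec2 <- chain_oracle_spec(mu = 1e-4, delta = 1e-6, omega_max = 0.05)
  for (i in 1:5) {
    a0 <- runif(2, -1, 1)
    o <- chain_oracle(ch2, a0, g2, spec2)
    expect_lt(cost2(a0 + o), cost2(a0))
    # formula reproduced with a finite-difference Jacobian
    e <- g2$position - forward_kinematics(ch2, a0)$wrist
    J_fd <- matrix(0, 3, 2)
    for (j in 1:2) {
      ap <- a0; ap[j] <- ap[j] + 1e-6
      am <- a0; am[j] <- am[j] - 1e-6
      J_fd[, j] <- (forward_kinematics(ch2, ap)$wrist -
                      forward_kinematics(ch2, am)$wrist) / 2e-6
    }
    ref <- as.numeric(t(J_fd) %*% solve(J_fd %*% t(J_fd) + 1e-4 * diag(3), e))
    if (max(abs(ref)) > 0.05) ref <- ref * 0.05 / max(abs(ref))
    expect_equal(o, ref, tolerance = 1e-4)
    # cost reduction is close to the best one-step reduction found by a
    # brute-force search over the same joint-increment box
    grid <- expand.grid(d1 = seq(-0.05, 0.05, length.out = 41),
                        d2 = seq(-0.05, 0.05, length.out = 41))
    best_cost <- min(apply(grid, 1, function(d) cost2(a0 + as.numeric(d))))
    red_o <- cost2(a0) - cost2(a0 + o)
    red_best <- cost2(a0) - best_cost
    expect_gt(red_o, 0.5 * red_best)
  }
})

test_that("intention noise has the stated geometry", {
  o <- c(0.3, -0.4, 0)
  expect_identical(apply_intention_noise(o, 0), o)
  set.seed(13)
  for (i in 1:200) {
    u <- apply_intention_noise(o, 100)
    expect_equal(sqrt(sum((u - o)^2)), 0.5, tolerance = 1e-12)
  }
  expect_error(apply_intention_noise(o, -5), "nonnegative")
})

test_that("intention noise is unbiased (Monte Carlo sphere mean)", {
  o <- c(1, 2, -1)
  set.seed(101)
  draws <- t(replicate(20000, apply_intention_noise(o, 150)))
  mc_se <- 1.5 * sqrt(sum(o^2)) / sqrt(20000)  # per-axis scale of the noise
  expect_lt(max(abs(colMeans(draws) - o)), 5 * mc_se)
})

test_that("linear mismatch is exact matrix application", {
  o <- c(1, -2, 0.5)
  expect_equal(apply_linear_mismatch(o, diag(3)), o)
  expect_equal(apply_linear_mismatch(o, 2 * diag(3)), 2 * o)
  set.seed(17)
  M <- matrix(rnorm(9), 3, 3)
  ref <- vapply(1:3, function(i) sum(M[i, ] * o), numeric(1))  # loop oracle
  expect_equal(apply_linear_mismatch(o, M), ref, tolerance = 1e-14)
  expect_error(apply_linear_mismatch(c(1, 2), M), "length")
})

test_that("arc mismatch rotates without changing the norm, saturating far out", {
  g <- goal_point(c(0, 0, 0))
  spec0 <- mismatch_spec("arc", phi_max = 0)
  o <- c(0.5, 0, 0)
  expect_equal(apply_arc_mismatch(o, c(5, 0, 0), g, spec0), o)

  spec <- mismatch_spec("arc", phi_max = 45, sigmoid_midpoint = 3,
                        sigmoid_slope = 1)
  set.seed(23)
  for (i in 1:50) {
    p <- runif(3, -10, 10)
    oo <- rnorm(3)
    u <- apply_arc_mismatch(oo, p, g, spec)
    expect_equal(sqrt(sum(u^2)), sqrt(sum(oo^2)), tolerance = 1e-12)
  }
  # far from the goal the per-plane rotation angle saturates at phi_max
  far <- apply_arc_mismatch(c(1, 0, 0), c(1e3, 0, 0), g, spec)
  ref <- apply_arc_mismatch(c(1, 0, 0), c(1e6, 0, 0), g, spec)
  expect_equal(far, ref, tolerance = 1e-6)
  # total rotation shrinks toward zero at the goal
  # at the goal the logistic sits at sigma(-midpoint/slope) ~ 0.047, so the
  # residual composed rotation is a few degrees at most
  near <- apply_arc_mismatch(c(1, 0, 0), c(1e-3, 0, 0), g, spec)
  angle <- function(u) acos(sum(u * c(1, 0, 0)) / sqrt(sum(u^2)))
  expect_lt(angle(near), 0.1)
  expect_gt(angle(far), angle(near))
  expect_error(mismatch_spec("arc", phi_max = 120), "phi_max")
})

test_that("mismatch wrappers are the identity at neutral parameters", {
  o <- c(0.2, -0.1, 0.4)
  expect_identical(apply_intention_noise(o, 0), o)
  expect_equal(apply_linear_mismatch(o, diag(3)), o)
  expect_equal(apply_arc_mismatch(o, c(4, 4, 4), goal_point(c(0, 0, 0)),
                                  mismatch_spec("arc", phi_max = 0)), o)
})
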