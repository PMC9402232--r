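test_that("Bell-Evans rate law: zero-force identity, magnitude, sign convention", {
  cfg <- physical_config()
  expect_equal(transition_rate(bell_transition(0.49, 0.48), 0, cfg), 0.49)
  # direct scalar evaluation of the exponential
  expect_equal(transition_rate(bell_transition(0.22, 0.55), 6, cfg),
               0.22 * exp(6 * 0.55 / 4.11), tolerance = 1e-12)
  # negative distance: exponent exactly -1 at F = kBT/|x|
  expect_equal(transition_rate(bell_transition(1, -1), 4.11, cfg), exp(-1))
  # magnitude of force enters; sign only selects directional x
  expect_equal(transition_rate(bell_transition(1, 0.5), -4, cfg),
               transition_rate(bell_transition(1, 0.5), 4, cfg))
  tr_dir <- bell_transition(1, x_minus = 1, x_plus = 2)
  expect_equal(transition_rate(tr_dir, -4.11, cfg), exp(1))
  expect_equal(transition_rate(tr_dir, 4.11, cfg), exp(2))
  expect_error(transition_rate(bell_transition(1, 1), NaN, cfg), "non-finite")
})

test_that("slip distribution: survival, mean, force-independence at x = 0", {
  cfg <- physical_config()
  m <- slip_ref()
  k5 <- 0.49 * exp(5 * 0.48 / 4.11)
  expect_equal(bond_survival(m, 1, 5, cfg), exp(-k5), tolerance = 1e-12)
  expect_equal(bond_survival(m, 1, 5, cfg), 0.4153, tolerance = 1e-3)
  expect_equal(bond_mean_lifetime(m, 5, cfg), 1.138, tolerance = 1e-3)
  expect_equal(bond_survival(m, 0, 5, cfg), 1)
  m2 <- slip_model(bell_transition(2, 0))
  for (f in c(0, 3, 12)) expect_equal(bond_mean_lifetime(m2, f, cfg), 0.5)
})

test_that("two-state slip mixture: degenerate limits, mean, density at 0", {
  cfg <- physical_config()
  b1 <- bell_transition(1, 0); b2 <- bell_transition(4, 0)
  m <- two_state_slip_model(0.5, b1, b2)
  expect_equal(bond_mean_lifetime(m, 7, cfg), 0.625)
  expect_equal(bond_density(m, 0, 7, cfg), 0.5 * 1 + 0.5 * 4)
  # p1 = 1 collapses to the slip distribution of b1u
  m1 <- two_state_slip_model(1, b1, b2)
  tt <- c(0.1, 1, 5)
  expect_equal(bond_density(m1, tt, 3, cfg),
               bond_density(slip_model(b1), tt, 3, cfg))
  expect_error(two_state_slip_model(1.2, b1, b2))
})

test_that("catch generator assembles the sub-generator with zero row sums", {
  m <- catch_model(bell_transition(5, 0), bell_transition(0.5, 0),
                   bell_transition(2, 0), bell_transition(0.1, 0))
  g <- catch_generator(m, 0)
  expect_equal(g$Q, matrix(c(-5.5, 0.5, 2, -2.1), 2, 2, byrow = TRUE))
  expect_equal(g$r, c(5, 0.1))
  # conservation at arbitrary force: -Q 1 = r
  m2 <- catch_ref()
  for (f in c(0, 4.7, 12)) {
    g2 <- catch_generator(m2, f)
    expect_equal(-as.numeric(g2$Q %*% c(1, 1)), g2$r, tolerance = 1e-12)
  }
  # decoupled states give a diagonal Q
  g3 <- catch_generator(catch_decoupled(), 2)
  expect_equal(g3$Q[1, 2], 0)
  expect_equal(g3$Q[2, 1], 0)
})

test_that("catch first-passage distribution matches slip limit and linear-solve mean", {
  cfg <- physical_config()
  # decoupled limit reduces exactly to slip with rate k10
  md <- catch_decoupled(k10 = 2)
  ms <- slip_model(bell_transition(2, 0))
  tt <- c(0.01, 0.5, 2, 10)
  expect_equal(bond_density(md, tt, 3, cfg), bond_density(ms, tt, 3, cfg),
               tolerance = 1e-9)
  expect_equal(bond_survival(md, tt, 3, cfg), bond_survival(ms, tt, 3, cfg),
               tolerance = 1e-9)
  # sequential two-step process: mean = 1/k12 + 1/k20
  mseq <- catch_model(bell_transition(0, 0), bell_transition(1, 0),
                      bell_transition(0, 0), bell_transition(0.5, 0))
  expect_equal(bond_mean_lifetime(mseq, 0, cfg), 1 / 1 + 1 / 0.5)
  # linear-solve oracle: mean = -pi Q^{-1} 1, frozen value 2.6/10.55
  m <- catch_model(bell_transition(5, 0), bell_transition(0.5, 0),
                   bell_transition(2, 0), bell_transition(0.1, 0))
  g <- catch_generator(m, 0)
  oracle <- -as.numeric(c(1, 0) %*% solve(g$Q) %*% c(1, 1))
  expect_equal(oracle, 0.2464455, tolerance = 1e-6)
  expect_equal(bond_mean_lifetime(m, 0, cfg), oracle, tolerance = 1e-12)
  expect_equal(bond_survival(m, 0, 0, cfg), 1)
  expect_error(catch_model(bell_transition(1, 0), bell_transition(1, 0),
                           bell_transition(1, 0), bell_transition(1, 0),
                           pi0 = c(0.7, 0.7)), "sum to 1")
})

test_that("exponential-mixture form: weights sum to 1, rates positive, eigvals real negative", {
  cfg <- physical_config()
  set.seed(41)
  for (i in 1:25) {
    m <- catch_model(bell_transition(10^runif(1, -2, 1), runif(1, -1, 2)),
                     bell_transition(10^runif(1, -2, 1), runif(1, -1, 2)),
                     bell_transition(10^runif(1, -2, 1), runif(1, -2, 1)),
                     bell_transition(10^runif(1, -2, 1), runif(1, -1, 2)))
    f <- runif(1, 0, 13)
    ld <- lifetime_distribution(m, f, cfg)
    expect_equal(sum(ld$weights), 1, tolerance = 1e-9)
    expect_true(all(ld$rates > 0))
    ev <- eigen(catch_generator(m, f, cfg)$Q)$values
    expect_true(all(abs(Im(ev)) == 0))
    expect_true(all(Re(ev) < 0))
    # mixture reproduces the closed-form survival
    tt <- c(0.05, 0.3, 2)
    expect_equal(colSums(ld$weights * exp(-outer(ld$rates, tt))),
                 bond_survival(m, tt, f, cfg), tolerance = 1e-8)
  }
})

test_that("survival curves are monotone with S(0)=1 and densities integrate to 1", {
  cfg <- physical_config()
  models <- list(slip_ref(),
                 two_state_slip_model(0.3, bell_transition(8, 0.1),
                                      bell_transition(0.4, 0.6)),
                 catch_ref())
  tt <- seq(0, 50, length.out = 400)
  for (m in models) {
    for (f in c(0, 6)) {
      S <- bond_survival(m, tt, f, cfg)
      expect_equal(S[1], 1)
      expect_true(all(diff(S) <= 1e-12))
      expect_lt(S[length(S)], 0.05)
      Z <- stats::integrate(function(t) bond_density(m, t, f, cfg), 0, Inf,
                            rel.tol = 1e-9)$value
      expect_equal(Z, 1, tolerance = 1e-6)
    }
  }
})

test_that("closed-form means match adaptive quadrature of t*f(t)", {
  cfg <- physical_config()
  models <- list(slip_ref(),
                 two_state_slip_model(0.3, bell_transition(8, 0.1),
                                      bell_transition(0.4, 0.6)),
                 catch_ref())
  for (m in models) {
    for (f in c(0, 2, 9, 15)) {
      q <- stats::integrate(function(t) t * bond_density(m, t, f, cfg), 0, Inf,
                            rel.tol = 1e-10)$value
      expect_equal(bond_mean_lifetime(m, f, cfg), q, tolerance = 1e-6)
    }
  }
  curve <- mean_lifetime_curve(slip_ref(), c(0, 5, 10), cfg)
  expect_true(all(diff(curve$mean_lifetime_s) < 0))  # x > 0: monotone decreasing
})

test_that("zero-force mean flags the 100 s fitting constraint correctly", {
  expect_equal(zero_force_mean(slip_model(bell_transition(0.49, 0.48))),
               1 / 0.49, tolerance = 1e-12)
  expect_gt(zero_force_mean(slip_model(bell_transition(0.009, 0.5))), 100)
  # all exit rates >= 1 bounds the mean well below 100 s
  m <- catch_model(bell_transition(1, 0.1), bell_transition(0.5, 0.5),
                   bell_transition(2, -0.5), bell_transition(1.5, 0.2))
  expect_lt(zero_force_mean(m), 100)
})

test_that("model JSON serialization round-trips bit-exactly", {
  models <- list(
    slip = slip_model(bell_transition(0.49, 0.48)),
    ts = two_state_slip_model(1 / 3, bell_transition(pi, 0.123456789012345),
                              bell_transition(0.4, -1.7)),
    catch = catch_model(bell_transition(13.57, 0, fixed_x = TRUE),
                        bell_transition(0.15, x_minus = 4.72, x_plus = 2.73),
                        bell_transition(6.27, x_minus = 3.46, x_plus = 15),
                        bell_transition(0.22, x_minus = 0.55, x_plus = 0.98),
                        pi0 = c(1, 0)))
  for (m in models) {
    m2 <- model_from_json(model_to_json(m))
    attr(m2, "kBT") <- NULL
    expect_identical(unclass(m2), unclass(m))
  }
  # file round trip with a recorded kBT
  p <- tempfile(fileext = ".json")
  model_to_json(models$slip, path = p, cfg = physical_config(4.28))
  m3 <- model_from_json(p)
  expect_identical(attr(m3, "kBT"), 4.28)
})
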