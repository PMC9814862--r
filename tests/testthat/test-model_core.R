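test_that("effective weight matches the closed form and rejects bad input", {
  expect_equal(effective_weight(3, 1, 16), 3)          # K = 1: no renormalization
  expect_equal(effective_weight(1, 2, 2), 4 / 9)       # q^2/(2q-1)^2 at K = q
  for (q in c(3, 5, 16)) expect_equal(effective_weight(1, q, q), q^2 / (2 * q - 1)^2)
  # frozen 30-digit oracle value
  expect_equal(effective_weight(2.5, 1.8, 3), 1.55817174515235457, tolerance = 1e-15)
  expect_error(effective_weight(-1, 1, 16), "W must be")
  expect_error(effective_weight(1, 0.5, 16), "K must be")
  expect_error(effective_weight(1, 1, 0.5), "q must be")
})

test_that("effective weight is strictly decreasing in K and equals W at K = 1", {
  set.seed(11)
  for (i in 1:200) {
    W <- runif(1, 0.01, 50)
    q <- runif(1, 1, 30)
    expect_equal(effective_weight(W, 1, q), W, tolerance = 1e-14)
    K <- sort(runif(2, 1, 20))
    expect_gt(effective_weight(W, K[1], q), effective_weight(W, K[2], q))
  }
})

test_that("effective energy reduces to U without water and matches the oracle", {
  expect_equal(effective_energy(zb_params(Q = 2, q = 16, U = 1, E = 0, T = 0.5)), 1)
  # q = 1 forces W~ = W/K^2, so U~ = U - 2E
  expect_equal(effective_energy(zb_params(Q = 2, q = 1, U = 1, E = 1, T = 0.37)), -1,
               tolerance = 1e-12)
  expect_equal(effective_energy(zb_params(Q = 2, q = 16, U = 2, E = 2.2, T = 0.7)),
               0.78275541372093451, tolerance = 1e-13)
})

test_that("reduced-unit stability parameter matches closed forms and limits", {
  # alpha = -1 collapses the denominator to q^2
  expect_equal(s_tilde_internal(internal_params(1, -1, 299, 16)),
               (exp(1) - 1) / 299, tolerance = 1e-14)
  # frozen oracle value
  expect_equal(s_tilde_internal(internal_params(0.4, 0.3, 100, 16)),
               0.067360121400917553, tolerance = 1e-13)
  # tau -> Inf: all Boltzmann factors -> 1
  for (a in c(-1, 0, 2)) {
    expect_equal(s_tilde_internal(internal_params(1e9, a, 50, 16)), 0,
                 tolerance = 1e-6)
  }
  # tau -> 0 follows the analytic limit instead of overflowing to NaN
  expect_identical(s_tilde_internal(internal_params(1e-4, -1, 100, 16)), Inf)
  expect_identical(s_tilde_internal(internal_params(1e-4, -0.5, 100, 16)), Inf)
  expect_equal(s_tilde_internal(internal_params(1e-4, 0.5, 100, 16)), -1 / 100)
})

test_that("stability curves are monotone for alpha < 0 and single-peaked for alpha > 0", {
  taus <- exp(seq(log(0.02), log(50), length.out = 400))
  for (a in c(-1, -0.5, -0.1)) {
    s <- s_tilde_internal(internal_params(taus, a, 100, 16))
    expect_true(all(diff(s) < 0))          # divergence at tau -> 0, decay to 0
  }
  for (a in c(0.05, 0.3, 1)) {
    s <- s_tilde_internal(internal_params(taus, a, 100, 16))
    expect_equal(n_interior_maxima(s), 1)  # one interior maximum
    # tau -> 0 limit is pinned within sigma of 0; decays to 0 at large tau
    expect_lt(abs(s_tilde_internal(internal_params(1e-4, a, 100, 16))),
              1 / 100 + 1e-9)
    expect_lt(abs(s[length(s)]), 1e-2)
  }
})

test_that("lab-unit stability parameter matches the oracle and the weight identity", {
  p <- lab_params(t0 = 251.0, h = 5754, h_ps = 5701, Q = 299, q = 16)
  expect_equal(s_tilde_lab(300, p, R = 8.314), 1.1072598033, tolerance = 1e-10)
  # zero energies make every Boltzmann factor 1
  p0 <- lab_params(t0 = 200, h = 1e-12, h_ps = 0, Q = 50)
  expect_equal(s_tilde_lab(300, p0), 0, tolerance = 1e-12)
  expect_error(s_tilde_lab(250, p), "t0")
  # unit-system consistency with the effective-weight route, 1000 draws
  set.seed(42)
  for (i in 1:1000) {
    p <- draw_lab_params()
    T <- p$t0 + runif(1, 20, 200)
    d <- R_GAS * (T - p$t0)
    via_weight <- (effective_weight(exp(2 * p$h / d), exp(p$h_ps / d), p$q) - 1) / p$Q
    expect_equal(s_tilde_lab(T, p), via_weight, tolerance = 1e-12)
  }
})

test_that("order parameter honors its analytic identities and limits", {
  # sigma = 1: only the helical state exists
  for (s in c(0, 0.5, 1, 10, 1e6)) expect_equal(order_parameter(s, 1), 1)
  # s~ = 1 simplifies to (1 + sigma)/2
  expect_equal(order_parameter(1, 0.25), 0.625)
  sig <- seq(0.01, 1, length.out = 100)
  expect_equal(order_parameter(rep(1, 100), sig), (1 + sig) / 2, tolerance = 1e-12)
  # s~ -> 0 gives sigma^2; s~ -> Inf gives 1
  expect_equal(order_parameter(0, 0.04), 0.0016)
  expect_equal(order_parameter(1e-12, sig), sig^2, tolerance = 1e-9)
  expect_equal(order_parameter(1e12, sig), rep(1, 100), tolerance = 1e-9)
  expect_equal(order_parameter(Inf, 0.1), 1)
  expect_error(order_parameter(1, 0), "sigma")
  expect_error(order_parameter(-2, 0.5), "outside the model")
})

test_that("order parameter is non-decreasing in s~ and bounded in [0, 1]", {
  s_grid <- seq(0, 100, length.out = 5000)
  for (sig in c(0.003, 0.04, 0.3, 1)) {
    th <- order_parameter(s_grid, sig)
    expect_true(all(diff(th) >= -1e-12))   # non-decreasing up to rounding at theta ~ 1
    expect_true(all(th >= 0 & th <= 1))
  }
})

test_that("model melt curves reproduce the published shapes", {
  # heat + cold denaturation: interior maximum of theta
  th_c <- theta_curve(seq(265, 330, length.out = 200), p_1c_dark())
  expect_equal(n_interior_maxima(th_c$theta), 1)
  imax <- which.max(th_c$theta)
  expect_gt(imax, 1)
  expect_lt(imax, nrow(th_c))
  # heat-only: theta decreases monotonically beyond its maximum-stability point
  th_a <- theta_curve(seq(273, 370, length.out = 200), p_1a_dark())
  jmax <- which.max(th_a$theta)
  expect_true(all(diff(th_a$theta[jmax:nrow(th_a)]) < 0))
  # Q -> 1 leaves only the helical state: flat curve at 1
  pQ1 <- lab_params(t0 = 240, h = 2000, h_ps = 2000, Q = 1 + 1e-9)
  expect_equal(theta_curve(seq(280, 320, length.out = 20), pQ1)$theta,
               rep(1, 20), tolerance = 1e-6)
  expect_error(theta_curve(c(250, 300), p_1c_dark()), "t0")
  expect_error(theta_curve(c(300, 290), p_1c_dark()), "increasing")
})
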