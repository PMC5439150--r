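test_that("polynomial and innovation-variance evaluation", {
  expect_equal(eval_poly(0.3, 17), 0.3)
  expect_equal(eval_poly(c(0.1, 0.2), 2), 0.5)
  expect_equal(eval_poly(c(1, 1, 1), 3), 13)
  expect_error(eval_poly(numeric(0), 1), "non-empty")
  expect_equal(innovation_variance(0, 3), 1)
  expect_equal(innovation_variance(c(0, log(2)), 1), 2)
  expect_equal(innovation_variance(c(0.5, -0.1), 3), exp(0.2))
  # overflow guard caps the exponent
  expect_true(is.finite(innovation_variance(c(1000), 1)))
})

test_that("covariance matches symbolic forward substitution on hand-solved cases", {
  eff <- sad_effect(within = list(y = "100"))
  # theta = 0.5, sigma2 = 1: p(t1) = e1, p(t2) = 0.5 p(t1) + e2
  P <- sad_covariance(eff, c(0.5, 0), times = 1:2)
  expect_equal(unname(P), rbind(c(1, 0.5), c(0.5, 1.25)), tolerance = 1e-12)
  # theta = 0 everywhere: independence, P = D
  P0 <- sad_covariance(eff, c(0, log(3)), times = 1:3)
  expect_equal(unname(P0), diag(3, 3), tolerance = 1e-12)
})

test_that("the 6x6 L factor matches the printed two-trait pattern", {
  eff <- sad_effect(
    within = list(y1 = "100", y2 = "100"),
    crosses = list(sad_cross("y1", "y2", 1, 1, 0), sad_cross("y2", "y1", 1, 1, 0)),
    initial_correlation = TRUE
  )
  theta1 <- 0.3; theta2 <- 0.4; d21 <- 0.25; d12 <- 0.35; rho <- 0.6
  par <- c(theta1, theta2, d21, d12, 0, 0, atanh(rho))
  ld <- build_LD(eff, par, times = 1:3)
  L <- unname(ld$L)
  expected <- diag(6)
  expected[2, 1] <- -rho
  expected[3, 1] <- -theta1; expected[3, 2] <- -d12   # y1(2) on y1(1), y2(1)
  expected[4, 1] <- -d21;    expected[4, 2] <- -theta2
  expected[5, 3] <- -theta1; expected[5, 4] <- -d12
  expected[6, 3] <- -d21;    expected[6, 4] <- -theta2
  expect_equal(L, expected, tolerance = 1e-12)
  expect_true(all(diag(ld$L) == 1))
  expect_true(all(ld$D > 0))
})

test_that("lags truncate to the available history", {
  eff <- sad_effect(within = list(y = sad_within(2, c(0, 0), 0)))
  par <- c(0.4, 0.2, 0)  # a1, a2, b0
  ld <- build_LD(eff, par, times = 1:2)
  # row for t2 carries only the lag-1 coefficient; no t0 exists
  expect_equal(unname(ld$L[2, 1]), -0.4)
  ld3 <- build_LD(eff, par, times = 1:3)
  expect_equal(unname(ld3$L[3, 1]), -0.2)
})

test_that("P^-1 reconstructed from the covariance equals L' D^-1 L", {
  set.seed(77)
  for (r in 1:20) {
    eff <- random_small_effect()
    par <- random_effect_params(eff)
    times <- 1:sample(2:4, 1)
    ld <- build_LD(eff, par, times)
    P <- sad_covariance(eff, par, times, declared_order = FALSE)
    lhs <- solve(P)
    rhs <- t(ld$L) %*% diag(1 / ld$D) %*% ld$L
    expect_equal(lhs, rhs, tolerance = 1e-10, ignore_attr = TRUE)
    # PD by construction
    expect_no_error(chol(P))
  }
})

test_that("without cross terms the two-trait covariance is block diagonal by trait", {
  set.seed(78)
  w1 <- sad_within(1, 1, 1)
  w2 <- sad_within(2, c(0, 0), 0)
  eff <- sad_effect(within = list(y1 = w1, y2 = w2))
  par <- random_effect_params(eff)
  times <- 1:4
  P <- sad_covariance(eff, par, times)
  cells <- trait_time_cells(times, c("y1", "y2"))
  i1 <- which(cells$trait == "y1"); i2 <- which(cells$trait == "y2")
  expect_equal(max(abs(P[i1, i2])), 0)
})

test_that("diagonal blocks equal single-trait constructions", {
  set.seed(79)
  times <- 1:4
  eff <- sad_effect(within = list(y1 = "111", y2 = "2001"))
  par <- random_effect_params(eff)
  P <- sad_covariance(eff, par, times)
  cells <- trait_time_cells(times, c("y1", "y2"))
  # split the parameter slice by hand: y1 a (2), y2 a (2), y1 b (2), y2 b (2)
  p1 <- c(par[1:2], par[5:6])
  p2 <- c(par[3:4], par[7:8])
  P1 <- sad_covariance(sad_effect(within = list(y1 = sad_within("111"))), p1, times)
  P2 <- sad_covariance(sad_effect(within = list(y2 = sad_within("2001"))), p2, times)
  i1 <- which(cells$trait == "y1"); i2 <- which(cells$trait == "y2")
  expect_equal(unname(P[i1, i1]), unname(P1), tolerance = 1e-12)
  expect_equal(unname(P[i2, i2]), unname(P2), tolerance = 1e-12)
})

test_that("Monte-Carlo forward recursion reproduces the covariance", {
  set.seed(80)
  n_rep <- 2e5
  for (r in 1:20) {
    eff <- random_small_effect()
    par <- random_effect_params(eff)
    T_ <- sample(2:4, 1)
    times <- 1:T_
    P <- sad_covariance(eff, par, times)
    emp <- mc_recursion_cov(eff, par, times, c("y1", "y2"), n_rep = n_rep)
    se <- sqrt((outer(diag(P), diag(P)) + P^2) / n_rep)
    expect_true(all(abs(emp - P) < 3.5 * se),
                info = sprintf("rep %d: max z = %.2f", r, max(abs(emp - P) / se)))
  }
})

test_that("a lag-0 cross at a single time point matches the recursive closed form", {
  # u1 = e1, u2 = delta u1 + e2 with var(e1) = s1, var(e2) = s2:
  # cov = [[s1, delta s1], [delta s1, delta^2 s1 + s2]]
  eff <- sad_effect(
    within = list(y1 = "100", y2 = "100"),
    crosses = list(sad_cross("y1", "y2", 0, 0, 0))
  )
  delta <- 0.7; s1 <- 1.5; s2 <- 0.5
  par <- c(0.3, 0.4, delta, log(s1), log(s2))  # thetas unused at T = 1
  P <- sad_covariance(eff, par, times = 1)
  expected <- rbind(
    c(s1, delta * s1),
    c(delta * s1, delta^2 * s1 + s2)
  )
  expect_equal(unname(P), expected, tolerance = 1e-12)
})

test_that("correlation_from_covariance behaves", {
  expect_equal(unname(correlation_from_covariance(diag(c(2, 5)))), diag(2))
  C <- correlation_from_covariance(rbind(c(1, 0.5), c(0.5, 1.25)))
  expect_equal(C[1, 2], 0.5 / sqrt(1.25), tolerance = 1e-12)
  set.seed(81)
  M <- crossprod(matrix(rnorm(25), 5))
  C2 <- correlation_from_covariance(M)
  expect_equal(C2, t(C2))
  expect_true(all(abs(C2) <= 1 + 1e-12))
  expect_error(correlation_from_covariance(diag(c(1, 0))), "positive")
})
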