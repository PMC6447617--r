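test_that("the mean-field RHS conserves total abundance and matches the rates", {
  set.seed(20)
  spec <- ensemble_spec(8, c_M = 0.5, c_L = 0.3, family = "abs-normal",
                        mu = 1, sigma = 0.3)
  com <- sample_community(spec, eps1 = 1, eps2 = 0.7, eps3 = 0)
  for (k in 1:5) {
    eta <- runif(8); eta <- eta / sum(eta)
    r <- meanfield_rhs(eta, com)
    expect_lt(abs(sum(r)), 1e-12)
    # cross-check against the jump process drift: rhs = omega - eta * sum(omega)
    w <- replacement_rates(eta, com)
    expect_equal(r, w - eta * sum(w), tolerance = 1e-12)
  }
  # neutral mean field is static
  com0 <- coop_community(matrix(0, 4, 4), eps1 = 0, eps2 = 0, eps3 = 0)
  expect_equal(meanfield_rhs(c(0.4, 0.3, 0.2, 0.1), com0), rep(0, 4))
})

test_that("the cooperation cycle relaxes to the uniform coexistence state", {
  com <- coop_community(cycle_matrix(7), eps1 = 1, eps2 = 0, eps3 = 0)
  fit <- coop_equilibrium(com, method = "integrate",
                          init = (1:7) / sum(1:7))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$m - 1 / 7)), 1e-8)
})

test_that("the unsupported chain collapses to the self-supported terminal species", {
  com <- coop_community(chain_selfloop_matrix(7), eps1 = 1, eps2 = 0, eps3 = 0)
  fit <- coop_equilibrium(com, method = "integrate")
  cl <- fit$classification
  expect_identical(cl$survivors, 7L)
  expect_equal(cl$fraction_extinct, 6 / 7)
  expect_equal(fit$m[7], 1, tolerance = 1e-8)
})

test_that("Perron-Frobenius solutions match closed forms and reject reducible input", {
  # cyclic permutation matrix: uniform state by symmetry
  pf <- pf_stationary(cycle_matrix(9))
  expect_equal(pf$m, rep(1 / 9, 9))
  expect_equal(pf$alpha, 1)
  # 2x2 closed form: alpha = sqrt(2), left eigenvector (sqrt(2), 1)
  M <- matrix(c(0, 2, 1, 0), 2, 2)   # M[1,2] = 1, M[2,1] = 2
  pf2 <- pf_stationary(M)
  expect_equal(pf2$alpha, sqrt(2), tolerance = 1e-12)
  v <- c(sqrt(2), 1); v <- v / sum(v)
  expect_equal(pf2$m, v, tolerance = 1e-12)
  # normalizations: sum(v) = 1, v.w = 1
  expect_equal(sum(pf2$v), 1)
  expect_equal(sum(pf2$v * pf2$w), 1)
  # independence of eps1
  expect_equal(pf_stationary(M, eps1 = 3)$m, pf2$m)
  # reducible input is rejected with a pruning hint
  expect_error(pf_stationary(chain_selfloop_matrix(5)), "IrreducibilityError")
})

test_that("long-time integration agrees with the Perron-Frobenius state", {
  set.seed(21)
  for (k in 1:5) {
    com <- random_coop_community(12, c_M = 0.4, mu = 1, sigma = 0.3)
    m_pf <- pf_stationary(com$M)$m
    fit <- coop_equilibrium(com, method = "integrate",
                            init = runif(12, 0.5, 1.5))
    expect_lt(max(abs(fit$m - m_pf)), 1e-8)
  }
})

test_that("the matrix-exponential flow solves the cooperative mean field exactly", {
  set.seed(22)
  com <- random_coop_community(6, c_M = 0.8, mu = 1, sigma = 0.25)
  init <- runif(6, 0.5, 1.5); init <- init / sum(init)
  expect_equal(time_solution_pure_cooperation(com$M, 1, init, 0), init)
  times <- c(0, 0.7, 2.3, 6)
  tr <- meanfield_trajectory(com, init = init, times = times,
                             rtol = 1e-11, atol = 1e-13)
  for (i in 2:4) {
    cf <- time_solution_pure_cooperation(com$M, 1, init, times[i])
    expect_lt(max(abs(tr[i, ] - cf)), 1e-8)
  }
  # large-t limit reaches v / sum(v)
  m_pf <- pf_stationary(com$M)$m
  expect_lt(max(abs(time_solution_pure_cooperation(com$M, 1, init, 80) - m_pf)),
            1e-9)
})

test_that("integration preserves the simplex within tolerance", {
  set.seed(23)
  spec <- ensemble_spec(20, c_M = 0.5, c_H = 0.3, family = "abs-normal",
                        mu = 0.3, sigma = 0.1)
  com <- sample_community(spec, eps1 = 1, eps2 = 0, eps3 = 1)
  tr <- meanfield_trajectory(com, times = seq(0, 40, by = 0.5))
  expect_lt(max(abs(rowSums(tr) - 1)), 1e-9)
  expect_true(all(tr >= 0))
})

test_that("global stability: many interior starts reach the same state", {
  set.seed(24)
  com <- random_coop_community(10, c_M = 0.5, mu = 1, sigma = 0.3)
  fits <- lapply(1:8, function(k)
    coop_equilibrium(com, method = "integrate", init = runif(10, 0.1, 1))$m)
  ref <- fits[[1]]
  for (m in fits[-1]) expect_lt(max(abs(m - ref)), 1e-6)
})

test_that("exploitation on top of an irreducible cooperative web leaves no extinctions", {
  set.seed(25)
  for (k in 1:5) {
    com <- random_coop_community(15, c_M = 0.5, mu = 1, sigma = 0.2,
                                 c_L = 0.2, eps2 = 1)
    fit <- coop_equilibrium(com, method = "integrate")
    expect_true(fit$classification$feasible)
    # rates stay positive along the way
    expect_no_error(replacement_rates(fit$m, com))
  }
})

test_that("unsupported species vanish at stationarity", {
  set.seed(26)
  M <- sample_cooperation(ensemble_spec(8, c_M = 0.6, family = "abs-normal",
                                        mu = 1, sigma = 0.2))
  M[, 3] <- 0   # species 3 receives no support
  com <- coop_community(M, eps1 = 1, eps2 = 0, eps3 = 0)
  fit <- coop_equilibrium(com, method = "integrate")
  expect_lt(fit$m[3], 1e-9)
})

test_that("classification applies a strict threshold with ties surviving", {
  cl <- classify_equilibrium(rep(1 / 5, 5))
  expect_true(cl$feasible)
  expect_equal(cl$fraction_extinct, 0)
  # exactly at the threshold counts as survival
  m <- c(1 / 25, 1 - 1 / 25, rep(0, 3))
  cl2 <- classify_equilibrium(m)
  expect_false(1L %in% cl2$extinct)
  expect_equal(sort(cl2$extinct), 3:5)
})
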