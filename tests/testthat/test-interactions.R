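test_that("trivial and degenerate ensembles sample as expected", {
  set.seed(1)
  expect_equal(sample_cooperation(ensemble_spec(10)), matrix(0, 10, 10))
  M <- sample_cooperation(ensemble_spec(7, c_M = 1, family = "constant", mu = 1))
  expect_equal(diag(M), rep(0, 7))
  expect_true(all(M[row(M) != col(M)] == 1))
  expect_equal(sample_exploitation(ensemble_spec(5)), matrix(0, 5, 5))
  expect_equal(sample_harm(ensemble_spec(5)), matrix(0, 5, 5))
})

test_that("sampled matrices satisfy their class invariants exhaustively", {
  set.seed(2)
  spec <- ensemble_spec(60, c_M = 0.4, c_L = 0.3, c_H = 0.2,
                        family = "gamma", mu = 0.5, sigma = 0.3)
  M <- sample_cooperation(spec)
  expect_true(all(M >= 0))
  L <- sample_exploitation(spec)
  for (i in 1:59) for (j in (i + 1):60)
    expect_true(L[i, j] * L[j, i] < 0 || (L[i, j] == 0 && L[j, i] == 0))
  H <- sample_harm(spec)
  expect_true(all(H <= 0))
  expect_true(all(!(H[upper.tri(H)] != 0 & t(H)[upper.tri(H)] != 0)))
  # joint sampling: disjoint supports, verified by brute-force pair scan
  com <- sample_community(spec)
  nz <- (com$M != 0) + (com$L != 0) + (com$H != 0)
  expect_true(all(nz <= 1))
  expect_length(validate_interactions(com), 0)
})

test_that("realized connectivity matches the ensemble probability", {
  set.seed(3)
  spec <- ensemble_spec(100, c_L = 0.3, family = "uniform", mu = 0.5,
                        sigma = 0.2)
  L <- sample_exploitation(spec)
  npairs <- choose(100, 2)
  k <- sum(L[upper.tri(L)] != 0)
  ci <- qbinom(c(0.005, 0.995), npairs, 0.3)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("harm magnitudes follow the entry distribution", {
  set.seed(4)
  spec <- ensemble_spec(50, c_H = 0.4, family = "abs-normal", mu = 0.3,
                        sigma = 0.1)
  vals <- replicate(20, {
    H <- sample_harm(spec)
    mean(-H[H != 0])
  })
  mom <- entry_moments(spec)
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - mom[["mean"]]), 3 * se)
})

test_that("analytic effective stats match the printed dilution formulas", {
  # full connectivity: formulas collapse to the base moments
  s1 <- effective_stats(ensemble_spec(10, c_M = 1, family = "gamma",
                                      mu = 2, sigma = 0.5, rho = 0.3))
  expect_equal(s1$sigma_Q, 0.5)
  expect_equal(s1$rho_Q, 0.3)
  # c = 0.5, mu = 1, sigma = 0: sigma_Q^2 = 0.25 and rho_Q = 1
  s2 <- effective_stats(ensemble_spec(10, c_M = 0.5, family = "constant", mu = 1))
  expect_equal(s2$sigma_Q^2, 0.25)
  expect_equal(s2$rho_Q, 1)
  # rho = 0 but c < 1 leaves a positive effective correlation
  s3 <- effective_stats(ensemble_spec(10, c_M = 0.6, family = "gamma",
                                      mu = 1, sigma = 0.4, rho = 0))
  expect_gt(s3$rho_Q, 0)
  expect_equal(s3$rho_Q, (1 - 0.6) / (0.4^2 + (1 - 0.6)))
})

test_that("analytic effective stats agree with sampled matrices in all families", {
  set.seed(5)
  fams <- list(
    list(family = "abs-normal", mu = 0.5, sigma = 0.3),
    list(family = "gamma", mu = 0.5, sigma = 0.25),
    list(family = "lognormal", mu = 0.5, sigma = 0.25),
    list(family = "uniform", mu = 0.5, sigma = 0.2))
  for (f in fams) {
    spec <- ensemble_spec(120, c_M = 0.5, family = f$family,
                          mu = f$mu, sigma = f$sigma, rho = 0)
    ana <- effective_stats(spec)
    reps <- replicate(20, {
      st <- effective_stats(sample_cooperation(spec))
      c(st$mu_Q, st$sigma_Q, st$rho_Q)
    })
    for (k in 1:3) {
      est <- mean(reps[k, ])
      se <- sd(reps[k, ]) / sqrt(ncol(reps))
      target <- c(ana$mu_Q, ana$sigma_Q, ana$rho_Q)[k]
      expect_lt(abs(est - target), 4 * se,
                label = sprintf("%s moment %d (%.4f vs %.4f)",
                                f$family, k, est, target))
    }
  }
})

test_that("correlated pairs realize the requested correlation (Gaussian case)", {
  set.seed(6)
  spec <- ensemble_spec(150, c_M = 1, family = "abs-normal", mu = 2,
                        sigma = 0.3, rho = 0.6)
  M <- sample_cooperation(spec)
  st <- effective_stats(M)
  # mu >> sigma: folding is negligible and the pair correlation is ~rho
  expect_lt(abs(st$rho_Q - 0.6), 0.05)
})

test_that("invalid specifications are rejected with informative errors", {
  expect_error(ensemble_spec(5, c_M = 1.2), "connectivities")
  expect_error(ensemble_spec(5, rho = 1.5), "rho")
  expect_error(ensemble_spec(5, family = "cauchy"), "unknown entry-distribution")
  expect_error(ensemble_spec(5, family = "uniform", mu = 0.1, sigma = 0.5),
               "negative lower endpoint")
  expect_error(sample_community(ensemble_spec(5, c_M = 0.6, c_L = 0.5)),
               "c_M \\+ c_L \\+ c_H")
})

test_that("irreducibility agrees with a transitive-closure oracle", {
  expect_true(is_irreducible(cycle_matrix(7)))
  chain <- matrix(0, 7, 7)
  for (i in 1:6) chain[i, i + 1] <- 1
  expect_false(is_irreducible(chain))
  set.seed(7)
  for (k in 1:25) {
    M <- matrix(rbinom(64, 1, 0.15) * runif(64), 8, 8)
    diag(M) <- 0
    expect_identical(is_irreducible(M), warshall_strongly_connected(M))
  }
})

test_that("pruning cascades reach an order-independent fixed point", {
  # every node of a cycle is supported
  pr <- prune_unsupported(cycle_matrix(7))
  expect_identical(pr$survivors, 1:7)
  expect_length(pr$removed, 0)
  # hand-traced cascade: chain plus terminal self-link leaves only the end
  pr2 <- prune_unsupported(chain_selfloop_matrix(7))
  expect_identical(pr2$survivors, 7L)
  expect_equal(sum(lengths(pr2$removed)), 6)
  # idempotence
  pr3 <- prune_unsupported(pr2$M_pruned)
  expect_length(pr3$removed, 0)
  # random sparse matrices: fixed point equals sequential deletion in
  # shuffled orders (one-at-a-time oracle)
  set.seed(8)
  for (k in 1:15) {
    M <- matrix(rbinom(100, 1, 0.12) * runif(100), 10, 10)
    diag(M) <- 0
    ref <- prune_unsupported(M)$survivors
    for (rep in 1:3) {
      alive <- rep(TRUE, 10)
      repeat {
        idx <- which(alive)
        if (!length(idx)) break
        unsupported <- idx[colSums(M[idx, idx, drop = FALSE] > 0) == 0]
        if (!length(unsupported)) break
        drop1 <- unsupported[sample.int(length(unsupported), 1)]
        alive[drop1] <- FALSE                    # delete one at random
      }
      expect_identical(which(alive), ref)
    }
  }
})

test_that("constant-effort normalization divides by in-degree", {
  Q <- matrix(0, 3, 3)
  Q[1, 2] <- 1; Q[3, 2] <- 1; Q[2, 3] <- 4
  N <- constant_effort_normalize(Q)
  expect_equal(N[1, 2], 0.5)
  expect_equal(N[3, 2], 0.5)
  expect_equal(N[2, 3], 4)
  expect_identical(N != 0, Q != 0)
  # one incoming link per species leaves the matrix unchanged
  expect_equal(constant_effort_normalize(cycle_matrix(5)), cycle_matrix(5))
})

test_that("edge-list I/O round-trips exactly and validates on load", {
  dir <- withr::local_tempdir()
  # empty file with S = 3 gives three zero matrices
  f0 <- file.path(dir, "empty.tsv")
  writeLines("source\ttarget\tweight\tclass", f0)
  com0 <- read_edgelist(f0, 3)
  expect_equal(com0$M, matrix(0, 3, 3))
  # the 7-cycle written as class-M unit edges
  com_cycle <- coop_community(cycle_matrix(7), eps1 = 1, eps2 = 0, eps3 = 0)
  f1 <- file.path(dir, "cycle.tsv")
  write_edgelist(com_cycle, f1)
  expect_equal(read_edgelist(f1, 7)$M, cycle_matrix(7))
  # random community: write -> read -> write is byte identical
  set.seed(9)
  spec <- ensemble_spec(15, c_M = 0.3, c_L = 0.2, c_H = 0.2,
                        family = "lognormal", mu = 1, sigma = 0.7)
  com <- sample_community(spec)
  f2 <- file.path(dir, "a.tsv"); f3 <- file.path(dir, "b.tsv")
  write_edgelist(com, f2)
  com2 <- read_edgelist(f2, 15)
  write_edgelist(com2, f3)
  expect_identical(readLines(f2), readLines(f3))
  expect_identical(com2$M, com$M)
  # violations are itemized
  f4 <- file.path(dir, "bad.tsv")
  writeLines(c("source\ttarget\tweight\tclass",
               "1\t2\t0.5\tX",
               "1\t2\t0.5\tM",
               "1\t2\t0.5\tM"), f4)
  expect_error(read_edgelist(f4, 3), "unknown interaction class")
  f5 <- file.path(dir, "bad2.tsv")
  writeLines(c("source\ttarget\tweight\tclass",
               "1\t2\t-0.5\tM"), f5)
  expect_error(read_edgelist(f5, 3), "M\\[1,2\\]")
})

test_that("community constraint violations are reported pairwise", {
  M <- matrix(0, 3, 3); L <- matrix(0, 3, 3)
  M[1, 2] <- 1; L[1, 2] <- 0.5; L[2, 1] <- -0.5
  expect_error(coop_community(M, L), "more than one interaction type")
  L2 <- matrix(0, 3, 3); L2[1, 2] <- 0.5; L2[2, 1] <- 0.5
  expect_error(coop_community(matrix(0, 3, 3), L2), "sign antisymmetry")
})
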