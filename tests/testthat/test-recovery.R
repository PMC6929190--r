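test_that("OMP recovers trivial instances exactly", {
  inst <- sparse_instance(8, 12, 2, seed = 1)
  # y equal to one column: one iteration, zero residual
  res <- omp(inst$A[, 3L], inst$A, sparsity = 3)
  expect_equal(res$support[1L], 3L)
  expect_lt(res$residual_norm, 1e-10)
  expect_equal(res$terminated_by, "stagnation")  # nothing left to explain
  # identity A: theta_hat = y after N iterations
  y <- c(3, -1, 2, 0.5)
  res_id <- omp(y, diag(4), sparsity = 4)
  expect_equal(res_id$theta_hat, y, tolerance = 1e-10)
})

test_that("OMP matches the exhaustive best-subset oracle on small instances", {
  # At 8 measurements for 2-sparse targets among 12 atoms the instance
  # sits near OMP's phase transition (m < 2k log n), so greedy selection
  # is expected to find the globally best 2-subset on most but not all
  # draws; whenever it reaches a near-zero residual it must match the
  # oracle exactly.
  ok <- 0L
  n_trials <- 200L
  for (s in seq_len(n_trials)) {
    inst <- sparse_instance(8, 12, 2, seed = 1000 + s)
    res <- omp(inst$y, inst$A, sparsity = 2)
    oracle <- best_subset_residual(inst$y, inst$A, 2)
    if (res$residual_norm <= oracle + 1e-8) ok <- ok + 1L
    if (res$residual_norm < 1e-8) expect_lte(oracle, 1e-8)
  }
  expect_gte(ok / n_trials, 0.8)
})

test_that("residuals are orthogonal to the support and non-increasing (all solvers)", {
  for (s in 1:5) {
    inst <- sparse_instance(32, 64, 5, seed = 200 + s)
    for (alg in c("omp", "swomp", "swamp")) {
      res <- switch(alg,
                    omp = omp(inst$y, inst$A, sparsity = 8),
                    swomp = swomp(inst$y, inst$A, alpha = 0.8,
                                  max_iterations = 10),
                    swamp = swamp(inst$y, inst$A,
                                  swamp_config(alpha = 0.8, L0 = 2)))
      # orthogonality of the final residual to every selected atom
      if (length(res$support))
        expect_lt(max(abs(crossprod(inst$A[, res$support, drop = FALSE],
                                    res$residual))),
                  1e-8 * sqrt(sum(inst$y^2)))
      # trace invariants: residual non-increasing, support non-decreasing
      tr <- res$stage_trace
      expect_true(all(diff(tr$residual_norm) <= 1e-8))
      expect_true(all(diff(tr$support_size) >= 0))
      # nonzeros confined to the support
      expect_true(all(which(res$theta_hat != 0) %in% res$support))
    }
  }
})

test_that("SWOMP with alpha = 1 reproduces the OMP support sequence", {
  for (s in 1:5) {
    inst <- sparse_instance(16, 32, 3, seed = 300 + s)
    res_omp <- omp(inst$y, inst$A, sparsity = 5)
    res_sw <- swomp(inst$y, inst$A, alpha = 1, max_iterations = 5)
    k <- min(length(res_omp$support), length(res_sw$support))
    expect_equal(res_sw$support[seq_len(k)], res_omp$support[seq_len(k)])
  }
  # all-zero observation: empty support, zero residual, stagnation
  z <- swomp(numeric(16), sparse_instance(16, 32, 3, seed = 1)$A, alpha = 0.8)
  expect_length(z$support, 0L)
  expect_equal(z$residual_norm, 0)
  expect_equal(z$terminated_by, "stagnation")
})

test_that("SWOMP recovers 5-sparse signals at the cardiac ECG threshold", {
  good <- 0L
  for (s in 1:50) {
    inst <- sparse_instance(64, 128, 5, seed = 400 + s)
    res <- swomp(inst$y, inst$A, alpha = 0.83, max_iterations = 20)
    x_hat <- res$theta_hat
    if (matching_rate(inst$theta, x_hat) > 0.99) good <- good + 1L
  }
  expect_gte(good / 50, 0.9)
})

test_that("higher thresholds admit weakly fewer atoms per pass", {
  inst <- sparse_instance(64, 128, 5, seed = 99)
  alphas <- seq(0.6, 0.95, by = 0.05)
  n_first <- vapply(alphas, function(a) {
    u <- abs(drop(crossprod(inst$A, inst$y)))
    sum(u >= a * max(u))
  }, numeric(1))
  expect_true(all(diff(n_first) <= 0))
  # and the full solver's selected support follows the same weak trend
  sizes <- vapply(alphas, function(a)
    length(swomp(inst$y, inst$A, alpha = a, max_iterations = 3)$support),
    numeric(1))
  expect_true(all(diff(sizes) <= 2))
})

test_that("initial sparsity estimation follows the RIP bound", {
  inst <- sparse_instance(16, 32, 3, seed = 5)
  # delta_k near 1 drives the right side to zero: k0 = 1 immediately
  expect_equal(estimate_initial_sparsity(inst$y, inst$A, delta_k = 0.999), 1L)
  # identity matrix, y = e1: full correlation mass at k0 = 1 already
  expect_equal(estimate_initial_sparsity(c(1, 0, 0, 0), diag(4),
                                         delta_k = 0.3), 1L)
  expect_equal(estimate_initial_sparsity(numeric(4), diag(4)), 0L)
  # Proposition direction: the estimate underestimates the true sparsity
  under <- 0L
  n_trials <- 200L
  for (s in seq_len(n_trials)) {
    inst <- sparse_instance(128, 256, 20, seed = 600 + s)
    k0 <- estimate_initial_sparsity(inst$y, inst$A, L0 = 1, delta_k = 0.3)
    if (k0 <= 20L) under <- under + 1L
  }
  expect_gte(under / n_trials, 0.95)
})

test_that("SWAMP never exceeds the support cap and stays oracle-competitive", {
  # tiny instances: whenever SWAMP reaches the residual tolerance its fit
  # is as good as the exhaustive best-2-subset least squares
  for (s in 1:20) {
    inst <- sparse_instance(8, 12, 2, seed = 700 + s)
    res <- swamp(inst$y, inst$A, swamp_config(alpha = 0.8, L0 = 1))
    expect_lte(max(res$stage_trace$support_size), floor(8 / 2))
    if (res$terminated_by == "residual_tol") {
      oracle <- best_subset_residual(inst$y, inst$A, 2)
      expect_lte(res$residual_norm, max(oracle * (1 + 1e-6), 1e-3))
    }
  }
})

test_that("SWAMP recovers the exact support in the benchmark sparse regime", {
  # scaled-down version of the N=1024/k=100/CR=0.7 regime for speed
  hits <- 0L
  for (s in 1:10) {
    theta <- make_ksparse(256, 25, seed = 800 + s)
    ens <- gaussian_ensemble(256, 0.7, seed = 900 + s)
    obs <- sense(ens, theta)
    rec <- cs_reconstruct(obs, NULL, "swamp",
                          config = swamp_config(alpha = 0.83))
    if (matching_rate(theta, rec$x_hat) > 0.999) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("recovery success degrades with increasing sparsity", {
  rate_for_k <- function(k) {
    succ <- 0L
    for (s in 1:50) {
      theta <- make_ksparse(64, k, seed = 1500 + 71 * k + s)
      ens <- gaussian_ensemble(64, 0.5, seed = 2500 + 91 * k + s)
      obs <- sense(ens, theta)
      rec <- cs_reconstruct(obs, NULL, "swamp",
                            config = swamp_config(alpha = 0.83, L0 = 1))
      if (matching_rate(theta, rec$x_hat) > 0.99) succ <- succ + 1L
    }
    succ / 50
  }
  rates <- vapply(c(5, 12, 24), rate_for_k, numeric(1))
  expect_true(all(diff(rates) <= 0.05))
  expect_gt(rates[1L], rates[3L])
})

test_that("reconstruct_signal maps coefficients through the domain exactly", {
  d <- dct_domain(16)
  ens <- gaussian_ensemble(16, 0.75, seed = 3)
  theta <- make_ksparse(16, 2, seed = 4)
  x <- synthesize(d, theta)
  obs <- sense(ens, x)
  rec <- cs_reconstruct(obs, d, "omp", sparsity = 2)
  # zero coefficients give the zero signal
  zero_res <- omp(numeric(12), matrix(rnorm(12 * 16), 12, 16), sparsity = 1)
  zero_res$theta_hat[] <- 0
  expect_equal(reconstruct_signal(zero_res, d), numeric(16))
  # per-sample dot-product oracle for D theta
  oracle <- vapply(seq_len(16), function(i) sum(d$atoms[i, ] * rec$theta),
                   numeric(1))
  expect_equal(rec$x_hat, oracle, tolerance = 1e-10)
})
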