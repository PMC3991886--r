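test_that("the tight-binding limit is piecewise linear with the stoichiometric breakpoint", {
  tc <- simulate_titration(n = 32, Q = 0.93, K = Inf, P = 1.5, L = 76)
  D <- tc$added_oligo
  db <- 32 * 1.5 / 76  # 0.632 nmol
  expected <- 1 - 0.93 * pmin(D / db, 1)
  expect_equal(tc$relative_fluorescence, expected)
  expect_equal(min(tc$relative_fluorescence), 0.07)
})

test_that("zero quench gives a flat curve and theta stays within [0, 1]", {
  tc <- simulate_titration(n = 32, Q = 0, K = 20)
  expect_equal(tc$relative_fluorescence, rep(1, length(tc$added_oligo)))
  for (K in c(0.5, 50, Inf)) {
    tc <- simulate_titration(n = 45, Q = 1, K = K)
    expect_true(all(tc$relative_fluorescence >= 0 & tc$relative_fluorescence <= 1))
  }
  expect_error(simulate_titration(n = 32, Q = 0.9, grid = c(0, 0.2, 0.1)),
               "increase strictly")
})

test_that("finite-affinity curves lie above the tight-binding curve before the breakpoint", {
  tight <- simulate_titration(n = 32, Q = 0.93, K = Inf)
  loose <- simulate_titration(n = 32, Q = 0.93, K = 50)
  pre <- which(tight$added_oligo > 0 & tight$added_oligo < 32 * 1.5 / 76)
  expect_true(all(loose$relative_fluorescence[pre] > tight$relative_fluorescence[pre]))
})

test_that("a noiseless tight-binding curve is inverted exactly", {
  fit <- fit_site_size(simulate_titration(n = 32, Q = 0.93))
  expect_equal(fit$site_size_n, 32, tolerance = 1e-6)
  expect_equal(fit$quench_Q, 0.93, tolerance = 1e-6)
})

test_that("equilibrium-mode fitting recovers parameters and approaches the breakpoint fit", {
  fit <- fit_site_size(simulate_titration(n = 32, Q = 0.93, K = 500),
                       mode = "equilibrium")
  expect_equal(fit$site_size_n, 32, tolerance = 1e-3)
  expect_equal(fit$quench_Q, 0.93, tolerance = 1e-3)
  expect_equal(fit$k_obs, 500, tolerance = 0.01)
  # tight-binding equivalence
  bp <- fit_site_size(simulate_titration(n = 32, Q = 0.93, K = 1e6))
  eq <- fit_site_size(simulate_titration(n = 32, Q = 0.93, K = 1e6),
                      mode = "equilibrium")
  expect_equal(eq$site_size_n, bp$site_size_n, tolerance = 0.01)
})

test_that("unsaturated titrations are refused with a clear message", {
  short <- simulate_titration(n = 32, Q = 0.93, grid = seq(0, 0.5, by = 0.1))
  expect_error(fit_site_size(short), "not saturated")
  expect_error(fit_site_size(simulate_titration(n = 32, Q = 0.93,
                                                grid = c(0, 0.5, 1, 1.5, 2))),
               "at least 6")
})

test_that("noisy replicates recover site size and quench at the reported precision", {
  fits <- lapply(1:20, function(s) {
    fit_site_size(simulate_titration(n = 32, Q = 0.93, noise_sd = 0.02,
                                     seed = 5000 + s))
  })
  n_hat <- vapply(fits, `[[`, numeric(1), "site_size_n")
  q_hat <- vapply(fits, `[[`, numeric(1), "quench_Q")
  expect_gte(mean(abs(n_hat - 32) <= 2 & abs(q_hat - 0.93) <= 0.03), 0.95)
  expect_lt(abs(mean(n_hat) - 32), 1)
})

test_that("salt-mode comparison separates constant from transitioning proteins", {
  same <- lapply(c(2, 100, 300), function(s) {
    fit_site_size(simulate_titration(n = 32, Q = 0.93, noise_sd = 0.01,
                                     seed = s, salt_mM = s))
  })
  expect_equal(compare_salt_modes(same)$verdict, "salt-independent")
  # the salt-dependent scenario: low-salt 31 nt, high-salt 45 nt
  trans <- list(
    fit_site_size(simulate_titration(n = 31, Q = 0.93, noise_sd = 0.01,
                                     seed = 1, salt_mM = 2)),
    fit_site_size(simulate_titration(n = 45, Q = 0.93, noise_sd = 0.01,
                                     seed = 2, salt_mM = 300)))
  v <- compare_salt_modes(trans)
  expect_equal(v$verdict, "mode transition")
  expect_equal(v$low_salt_n, 31, tolerance = 0.1)
  expect_equal(v$high_salt_n, 45, tolerance = 0.1)
  expect_error(compare_salt_modes(trans[1]), "two or more")
})
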