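tab3 <- ssb_composition()

test_that("generated proteins realize the reconstructed counts exactly", {
  rec <- generate_protein(142, tab3$percent["DpsSSB", ], seed = 1, id = "DpsSSB-like")
  expect_equal(nchar(rec$residues), 142L)
  cnt <- count_residues(rec)
  expect_identical(unclass(cnt),
                   unclass(reconstruct_counts(tab3$percent["DpsSSB", ], 142)))
  expect_equal(residue_percentages(cnt), tab3$percent["DpsSSB", ])
})

test_that("a one-residue composition gives the constant sequence", {
  row <- structure(c(100, rep(0, 19)), names = canonical_residues())
  expect_equal(generate_protein(4, row, seed = 9)$residues, "AAAA")
})

test_that("generators are deterministic in their seed and leave the RNG alone", {
  a <- generate_protein(142, tab3$percent["DpsSSB", ], seed = 7)
  b <- generate_protein(142, tab3$percent["DpsSSB", ], seed = 7)
  d <- generate_protein(142, tab3$percent["DpsSSB", ], seed = 8)
  expect_identical(a$residues, b$residues)
  expect_false(identical(a$residues, d$residues))
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(generate_titration(32, 0.9, noise_sd = 0.02, seed = 1))
  after <- rnorm(3)
  expect_identical(before, after)
  t1 <- generate_titration(32, 0.9, noise_sd = 0.02, seed = 4)
  t2 <- generate_titration(32, 0.9, noise_sd = 0.02, seed = 4)
  expect_identical(t1, t2)
})

test_that("every generator is inverted exactly by its analyzer at zero noise", {
  # titration -> site size and quench
  fit <- fit_site_size(generate_titration(n = 31, Q = 0.81))
  expect_equal(fit$site_size_n, 31, tolerance = 1e-6)
  expect_equal(fit$quench_Q, 0.81, tolerance = 1e-6)
  # melting -> Tm
  expect_equal(extract_tm(generate_melting(tm = 69))$value, 69, tolerance = 0.01)
  # thermogram -> DSC peak
  expect_equal(extract_tm(generate_thermogram(tm = 63), method = "dsc-peak")$value, 63)
  # time course -> half-life (grid point and off-grid)
  expect_equal(half_life(generate_timecourse(15))$minutes, 15, tolerance = 1e-9)
  # off-grid true value: linear interpolation on a convex decay overshoots
  # by at most the grid-step curvature
  expect_lt(abs(half_life(generate_timecourse(20))$minutes - 20), 1)
  # calibration -> generating line
  cal <- suppressWarnings(fit_calibration(generate_calibration()))
  expect_equal(cal$slope, -0.065)
  expect_equal(cal$r_squared, 1)
  # composition row -> counts (round trip through a realized sequence)
  rec <- generate_protein(213, tab3$percent["ParSSB", ], seed = 2)
  expect_equal(residue_percentages(count_residues(rec)), tab3$percent["ParSSB", ])
})

test_that("generator guard rails reject impossible scenarios", {
  expect_error(generate_melting(tm = 99), "inside")
  expect_error(generate_timecourse(half_life = -1))
  expect_error(generate_calibration(slope = 0))
})

test_that("the salt-transition scenario emerges from its generator parameters", {
  fits <- list(
    fit_site_size(generate_titration(n = 31, Q = 0.93, salt_mM = 2)),
    fit_site_size(generate_titration(n = 45, Q = 0.93, salt_mM = 300)))
  v <- compare_salt_modes(fits)
  expect_equal(v$verdict, "mode transition")
})
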