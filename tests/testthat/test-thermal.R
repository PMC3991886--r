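test_that("midpoint and derivative read-offs agree on symmetric sigmoids", {
  for (tm in c(75, 58)) {
    m <- generate_melting(tm)
    expect_equal(extract_tm(m, method = "midpoint")$value, tm, tolerance = 0.05)
    expect_equal(extract_tm(m, method = "derivative")$value, tm, tolerance = 0.26)
  }
})

test_that("midpoint extraction stays within half a grid step under 1% noise", {
  errs <- vapply(1:100, function(s) {
    m <- generate_melting(70, noise_sd = 0.0035, seed = s)  # 1% of amplitude
    extract_tm(m)$value - 70
  }, numeric(1))
  expect_lte(max(abs(errs)), 0.5)
})

test_that("midpoint Tm is invariant to affine rescaling of the signal", {
  m <- generate_melting(64, noise_sd = 0.002, seed = 3)
  t1 <- extract_tm(m$temperature, m$signal)$value
  t2 <- extract_tm(m$temperature, 5 + 40 * m$signal)$value
  expect_equal(t1, t2)
})

test_that("transitionless or malformed traces are refused", {
  temp <- seq(25, 95, by = 1)
  expect_error(extract_tm(temp, rep(0.6, length(temp))), "no transition")
  expect_error(extract_tm(c(1, 2, 3), c(1, 2, 3)), "at least 10")
  expect_error(extract_tm(rev(temp), seq_along(temp)), "strictly")
})

test_that("DSC peak read-off returns the thermogram maximum", {
  expect_equal(extract_tm(generate_thermogram(78.5), method = "dsc-peak")$value, 78.5)
  expect_equal(extract_tm(generate_thermogram(109.3, grid = seq(60, 120, 0.1)),
                          method = "dsc-peak")$value, 109.3)
})

test_that("duplex destabilization matches the published temperature drops", {
  expect_equal(delta_tm(75, 58), 17)
  expect_equal(delta_tm(75, 62), 13)
  expect_equal(delta_tm(70, 70), 0)
  expect_equal(delta_tm(62, 75), -delta_tm(75, 62))
  free <- extract_tm(generate_melting(75))
  bound <- extract_tm(generate_melting(58))
  expect_equal(delta_tm(free, bound), 17, tolerance = 0.01)
})

test_that("half-life interpolation handles exact hits, crossings and censoring", {
  expect_equal(half_life(c(0, 15), c(1.0, 0.5))$minutes, 15)
  expect_equal(half_life(c(0, 10), c(1.0, 0.0))$minutes, 5)
  cens <- half_life(c(0, 15, 30, 45), c(1.0, 0.8, 0.6, 0.6))
  expect_true(cens$censored)
  expect_equal(cens$minutes, 45)
  expect_equal(format(cens), ">45")
  expect_error(half_life(c(0, 5), c(0.4, 0.2)), "already inactivated")
})

test_that("half-life is monotone in pointwise-larger activity series", {
  t <- c(0, 1, 2.5, 5, 10, 15, 30, 45, 60)
  slow <- exp(-t * log(2) / 20)
  fast <- exp(-t * log(2) / 8)
  expect_gte(half_life(t, slow)$minutes, half_life(t, fast)$minutes)
  bump <- pmin(slow + 0.05, 1)
  expect_gte(half_life(t, bump)$minutes, half_life(t, slow)$minutes)
})
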