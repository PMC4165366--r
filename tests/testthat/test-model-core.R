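test_that("Freeman-Tukey transform matches its closed form and symmetry", {
  # balanced counts sit exactly at pi/2: asin(sqrt(a)) + asin(sqrt(1-a))
  expect_equal(ft_transform(5, 10)$z, pi / 2)
  # direct evaluation of the double-arcsine at the boundary
  expect_equal(ft_transform(0, 10)$z, asin(sqrt(1 / 11)))
  expect_equal(ft_transform(0, 10)$variance, 1 / 10.5)
  # reflection symmetry about pi/2, exactly
  for (n in c(10, 25, 200)) {
    x <- 0:n
    z <- ft_transform(x, n)$z
    expect_equal(z + rev(z), rep(pi, n + 1))
    # strictly monotone in x
    expect_true(all(diff(z) > 0))
    # FT is a smoothed arcsine: close to 2*asin(sqrt((x+0.5)/(n+1))) away
    # from the boundary, where the smoothing deviates most at small n
    dev <- abs(z - 2 * asin(sqrt((x + 0.5) / (n + 1))))
    expect_lt(max(dev[-c(1, n + 1)]), 0.05)
    expect_lt(max(dev), 0.15)
  }
  expect_error(ft_transform(11, 10), "0 <= x <= n")
  expect_error(ft_transform(0, 0), ">= 1")
})

test_that("backtransform inverts the mean map and clips", {
  expect_equal(ft_backtransform(pi / 2), 0.5)
  expect_equal(ft_backtransform(2 * asin(sqrt(0.8))), 0.8)
  expect_equal(ft_backtransform(4), 1)
  expect_equal(ft_backtransform(-1), 0)
  # round trip lands in the natural count bracket
  for (n in c(10, 40, 200)) {
    x <- 0:n
    p <- ft_backtransform(ft_transform(x, n)$z)
    expect_true(all(p >= x / (n + 1) - 1e-12))
    expect_true(all(p <= (x + 1) / (n + 1) + 1e-12))
  }
})

test_that("variance inflation follows the beta-binomial factor", {
  expect_equal(ft_variance(20), 1 / 20.5)
  expect_equal(ft_variance(20, 0.004), (0.004 * 19 + 1) / 20.5)
  expect_error(ft_variance(20, 1), "rho")
})

test_that("bias maps are the printed odds weighting and mutually inverse", {
  expect_equal(bias_adjusted_mu(0.8, 0.5), 0.8)
  expect_equal(bias_adjusted_mu(0.8, 0.6), 0.48 / (0.48 + 0.08))
  expect_equal(bias_adjusted_mu(0.5, 0.6), 0.6)
  expect_equal(bias_invert_mu(bias_adjusted_mu(0.8, 0.6), 0.6), 0.8)
  expect_equal(bias_invert_mu(0.6, 0.6), 0.5)
  expect_equal(bias_invert_mu(0.37, 0.5), 0.37)
  grid <- expand.grid(m = seq(0.02, 0.98, by = 0.04),
                      f = seq(0.05, 0.95, by = 0.09))
  rt <- bias_invert_mu(bias_adjusted_mu(grid$m, grid$f), grid$f)
  expect_lt(max(abs(rt - grid$m)), 1e-10)
  expect_error(bias_adjusted_mu(0, 0.5), "strictly inside")
  expect_error(bias_adjusted_mu(0.5, 1), "strictly inside")
  expect_error(bias_invert_mu(1, 0.5), "strictly inside")
})

test_that("beta-binomial sampler matches its mean/variance law", {
  set.seed(42)
  x <- rbetabinom(1e5, 20, 0.5, 0)
  expect_lt(abs(mean(x) - 10), 3 * sqrt(5 / 1e5))
  x <- rbetabinom(1e5, 20, 0.5, 0.004)
  v_true <- 0.25 * 20 * (0.004 * 19 + 1)
  expect_lt(abs(var(x) - v_true) / v_true, 0.05)
  # variance law across a (n, mu, rho) grid, within Monte-Carlo slack
  for (cfg in list(c(15, 0.3, 0.01), c(50, 0.7, 0.05), c(100, 0.5, 0.2))) {
    x <- rbetabinom(4e4, cfg[1], cfg[2], cfg[3])
    v_true <- cfg[2] * (1 - cfg[2]) * cfg[1] * (cfg[3] * (cfg[1] - 1) + 1)
    expect_lt(abs(var(x) - v_true) / v_true, 0.1)
    expect_lt(abs(mean(x) - cfg[1] * cfg[2]) / (cfg[1] * cfg[2]), 0.05)
  }
  # reproducible under a fixed seed
  set.seed(7); a <- rbetabinom(100, 30, 0.5, 0.01)
  set.seed(7); b <- rbetabinom(100, 30, 0.5, 0.01)
  expect_identical(a, b)
  expect_error(rbetabinom(10, 20, 1), "strictly inside")
  expect_error(rbetabinom(10, 20, 0.5, -0.1), "rho")
})
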