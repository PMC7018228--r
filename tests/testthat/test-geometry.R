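test_that("angular separation wraps, is symmetric and 2*pi-periodic", {
  expect_equal(angular_separation(0, pi), pi)
  expect_equal(angular_separation(0.1, 2 * pi - 0.1), 0.2)
  for (k in c(-3L, 0L, 5L)) {
    expect_equal(angular_separation(1.3, 1.3 + 2 * pi * k), 0)
  }
  set.seed(1)
  a <- stats::runif(50, -20, 20); b <- stats::runif(50, -20, 20)
  expect_equal(angular_separation(a, b), angular_separation(b, a))
  expect_true(all(angular_separation(a, b) >= 0 &
                  angular_separation(a, b) <= pi))
  expect_error(angular_separation(NaN, 0), "finite")
})

test_that("euclidean distance matches hand values and rejects mismatches", {
  expect_equal(euclidean_distance(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(euclidean_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(euclidean_distance(c(1, 1, 1), c(2, 2, 2)), sqrt(3))
  expect_error(euclidean_distance(c(0, 0), c(0, 0, 0)), "mismatch")
})

test_that("hyperbolic distance reduces to radial geodesics and diameters", {
  expect_equal(hyperbolic_distance(3, 1, 7, 1), 4)
  expect_equal(hyperbolic_distance(5, 0, 5, pi), 10)
  # coincident points at zero distance despite round-off
  expect_equal(hyperbolic_distance(12.3456, 0.7, 12.3456, 0.7), 0)
})

test_that("approximate distance matches its closed form and the exact law", {
  expect_equal(hyperbolic_distance_approx(10, 0, 10, 2), 20)
  expect_equal(hyperbolic_distance_approx(10, 0, 10, 0.5),
               20 + 2 * log(0.25), tolerance = 1e-12)
  expect_error(hyperbolic_distance_approx(5, 1, 5, 1), "undefined")
  # exact agrees with the approximation within 1% at large radii
  exact <- hyperbolic_distance(10, 0, 10, 0.5)
  approx <- hyperbolic_distance_approx(10, 0, 10, 0.5)
  expect_lt(abs(exact - approx) / exact, 0.01)
})

test_that("approximation error < 1% for small separations above 10*exp(-min(r))", {
  # the closed form drops a sin(dtheta/2) ~ dtheta/2 factor, so it is
  # accurate for dtheta well below pi and above the e^{-r} floor
  set.seed(7)
  for (rep in 1:200) {
    r1 <- stats::runif(1, 6, 15); r2 <- stats::runif(1, 6, 15)
    lo <- 10 * exp(-min(r1, r2))
    dth <- stats::runif(1, lo, 1)
    ex <- hyperbolic_distance(r1, 0, r2, dth)
    ap <- hyperbolic_distance_approx(r1, 0, r2, dth)
    expect_lt(abs(ex - ap) / ex, 0.01)
  }
})

test_that("distances are symmetric, non-negative, triangle-inequality safe", {
  set.seed(11)
  for (rep in 1:200) {
    r <- stats::runif(3, 0, 12); th <- stats::runif(3, 0, 2 * pi)
    d12 <- hyperbolic_distance(r[1], th[1], r[2], th[2])
    d21 <- hyperbolic_distance(r[2], th[2], r[1], th[1])
    d13 <- hyperbolic_distance(r[1], th[1], r[3], th[3])
    d23 <- hyperbolic_distance(r[2], th[2], r[3], th[3])
    expect_equal(d12, d21)
    expect_gte(d12, 0)
    expect_lte(d13, d12 + d23 + 1e-9)
  }
})

test_that("angular agreement is alignment-invariant and discriminates", {
  set.seed(19)
  th <- stats::runif(200, 0, 2 * pi)
  # same angles rotated and reflected: perfect agreement
  expect_equal(angular_agreement(th, (2 * pi - th + 0.77) %% (2 * pi)), 1,
               tolerance = 1e-12)
  # small noise: high agreement
  noisy <- (th + stats::rnorm(200, 0, 0.2)) %% (2 * pi)
  expect_gt(angular_agreement(th, noisy), 0.9)
  # unrelated angles: low agreement
  expect_lt(angular_agreement(th, stats::runif(200, 0, 2 * pi)), 0.3)
})

test_that("exact and approximate hyperbolic distances converge as radii grow", {
  dth <- 0.3
  rel_err <- vapply(c(3, 12), function(r) {
    ex <- hyperbolic_distance(r, 0, r, dth)
    abs(ex - hyperbolic_distance_approx(r, 0, r, dth)) / ex
  }, numeric(1))
  expect_lt(rel_err[2L], rel_err[1L])
  expect_lt(rel_err[2L], 1e-3)
})
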