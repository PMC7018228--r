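test_that("connection probabilities match their closed forms", {
  expect_equal(connection_prob_h2(12, 12, 2.5), 0.5)
  expect_equal(connection_prob_h2(12 + 2 / 2.5, 12, 2.5), 1 / (1 + exp(1)))
  expect_gt(connection_prob_h2(11, 12, 200), 1 - 1e-12)
  expect_lt(connection_prob_h2(13, 12, 200), 1e-12)

  expect_equal(connection_prob_s1(0.02, 2, 5, 0.002, 3), 0.5)
  expect_equal(connection_prob_s1(2 * 0.002 * 10, 2, 5, 0.002, 2), 0.2)
  expect_equal(connection_prob_s1(0, 2, 5, 0.002, 3), 1)
  # strictly decreasing in distance
  x <- seq(0, 30, length.out = 50)
  expect_true(all(diff(connection_prob_h2(x, 12, 2.5)) < 0))
})

test_that("kappa <-> radius mapping is the popularity-similarity convention", {
  R <- 20
  expect_equal(kappa_to_radius(2, 2, R), R)
  expect_equal(kappa_to_radius(2 * exp(R / 2), 2, R), 0)
  set.seed(3)
  kap <- 2 * exp(stats::runif(100, 0, 5))
  back <- radius_to_kappa(kappa_to_radius(kap, 2, R), 2, R)
  expect_equal(back, kap, tolerance = 1e-12)
  expect_error(kappa_to_radius(1, 2, R), "kappa")
})

test_that("S1 and H2 connection laws coincide under the change of variables", {
  set.seed(5)
  for (rep in 1:50) {
    mu <- stats::runif(1, 1e-4, 1e-2)
    beta <- stats::runif(1, 1.2, 6)
    kappa0 <- stats::runif(1, 1, 3)
    kap <- kappa0 * (1 - stats::runif(2))^(-1 / 1.7)
    th <- stats::runif(2, 0, 2 * pi)
    R <- s1_disk_radius(mu, kappa0)
    r <- kappa_to_radius(kap, kappa0, R)
    dth <- angular_separation(th[1], th[2])
    if (dth == 0) next
    p_s1 <- connection_prob_s1(dth, kap[1], kap[2], mu, beta)
    x <- hyperbolic_distance_approx(r[1], th[1], r[2], th[2])
    p_h2 <- connection_prob_h2(x, R, beta)
    expect_lt(abs(p_s1 - p_h2) / p_s1, 1e-9)
  }
})

test_that("mu calibration hits the target mean degree", {
  kap <- rep(10, 400)
  mu <- calibrate_mu(kap, 2.5, 10)
  expect_lt(abs(navmaps:::s1_expected_mean_degree(kap, 2.5, mu) - 10) / 10,
            0.02)
  # doubling the target approximately halves mu
  mu2 <- calibrate_mu(kap, 2.5, 20)
  expect_lt(abs(mu2 / mu - 2) , 0.2)
  expect_error(calibrate_mu(kap, 2.5, 400), "N - 1")
})

test_that("calibrated ensembles realize the target degree when generated", {
  gen <- generate_s1_network(
    s1_config(N = 2000, gamma = 10, kappa0 = 10, beta = 2.5,
              mean_degree = 10, seed = 3L))
  kbar <- mean(degrees(gen$connectome))
  expect_lt(abs(kbar - 10) / 10, 0.05)
})

test_that("log-likelihood matches closed forms and a brute-force oracle", {
  # two nodes at distance exactly R, connected: log(1/2)
  # antipodal points at radius R/2 sit exactly at distance R
  m <- hyperbolic_map(c("a", "b"), c(6, 6), c(0, pi), R = 12, beta = 3)
  x <- connectome(c("a", "b"), rbind(c("a", "b")))
  expect_equal(log_likelihood(x, m), log(0.5), tolerance = 1e-10)

  # complete 3-node graph: sum of log p over the three pairs
  m3 <- hyperbolic_map(c("a", "b", "c"), c(3, 4, 5), c(0, 1, 4),
                       R = 10, beta = 2)
  x3 <- connectome(c("a", "b", "c"),
                   rbind(c("a", "b"), c("a", "c"), c("b", "c")))
  ps <- connection_prob_h2(c(
    hyperbolic_distance(3, 0, 4, 1),
    hyperbolic_distance(3, 0, 5, 4),
    hyperbolic_distance(4, 1, 5, 4)), 10, 2)
  expect_equal(log_likelihood(x3, m3), sum(log(ps)))

  # random 5-node graph vs independent double-loop oracle
  set.seed(9)
  x5 <- random_spatial_instance(5, p = 0.5, seed = 9)
  m5 <- hyperbolic_map(x5$nodes, stats::runif(5, 1, 8),
                       stats::runif(5, 0, 2 * pi), R = 9, beta = 2.2)
  expect_equal(log_likelihood(x5, m5), oracle_loglik(x5, m5),
               tolerance = 1e-10)
})

test_that("log-likelihood is invariant under rotation and reflection", {
  d <- demo_s1()
  base <- log_likelihood(d$x, d$map)
  rot <- d$map; rot$theta <- (rot$theta + 1.234) %% (2 * pi)
  ref <- d$map; ref$theta <- (2 * pi - ref$theta) %% (2 * pi)
  expect_equal(log_likelihood(d$x, rot), base, tolerance = 1e-8)
  expect_equal(log_likelihood(d$x, ref), base, tolerance = 1e-8)
})

test_that("hyperbolic map serialization round-trips", {
  m <- hyperbolic_map(c("a", "b"), c(1, 2), c(0.5, 3.1), R = 8, beta = 2.5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hyperbolic_map(m, f)
  m2 <- read_hyperbolic_map(f)
  expect_equal(m2$r, m$r)
  expect_equal(m2$theta, m$theta)
  expect_equal(m2$R, m$R)
  expect_equal(m2$beta, m$beta)
})
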