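test_that("hidden degrees are deterministic Pareto draws with the right mean", {
  cfg <- s1_config(N = 1e5, gamma = 3, kappa0 = 2, seed = 21L)
  k1 <- sample_hidden_degrees(cfg)
  k2 <- sample_hidden_degrees(cfg)
  expect_identical(k1, k2)
  expect_true(all(k1 >= 2))
  # Pareto mean kappa0*(gamma-1)/(gamma-2) = 4, within 3 standard errors
  se <- stats::sd(k1) / sqrt(length(k1))
  expect_lt(abs(mean(k1) - 4), 3 * se)
  expect_error(s1_config(N = 10, gamma = 2), "gamma")
})

test_that("S1 generation is seed-deterministic and hits the target degree", {
  cfg <- s1_config(N = 2000, gamma = 2.7, beta = 2.5, mean_degree = 10,
                   seed = 5L)
  g1 <- generate_s1_network(cfg)
  g2 <- generate_s1_network(cfg)
  expect_identical(g1$connectome$edges, g2$connectome$edges)
  expect_identical(g1$truth$kappa, g2$truth$kappa)
  expect_lt(abs(mean(degrees(g1$connectome)) - 10) / 10, 0.05)
})

test_that("higher beta yields higher mean local clustering", {
  mk <- function(beta) {
    g <- generate_s1_network(s1_config(N = 1000, gamma = 2.7, beta = beta,
                                       mean_degree = 10, seed = 31L))
    navmaps:::mean_local_clustering(as_igraph(g$connectome))
  }
  expect_gt(mk(5), mk(1.5))
})

test_that("generated networks reproduce the S1 connection-probability curve", {
  g <- generate_s1_network(s1_config(N = 2000, gamma = 2.7, beta = 2.5,
                                     mean_degree = 10, seed = 1L))
  tr <- g$truth
  pr <- navmaps:::pair_indices(tr$N)
  xresc <- angular_separation(tr$theta[pr$i], tr$theta[pr$j]) /
    (tr$mu * tr$kappa[pr$i] * tr$kappa[pr$j])
  amat <- navmaps:::adjacency_matrix(g$connectome)
  conn <- amat[cbind(pr$i, pr$j)]
  br <- 10^seq(log10(min(xresc)), log10(max(xresc)), length.out = 21L)
  bin <- findInterval(xresc, br, rightmost.closed = TRUE, all.inside = TRUE)
  ok <- 0L; occupied <- 0L
  for (b in sort(unique(bin))) {
    sel <- bin == b
    pbar <- mean(1 / (1 + xresc[sel]^tr$beta))
    f <- mean(conn[sel])
    band <- 3 * sqrt(max(pbar * (1 - pbar), 1e-12) / sum(sel))
    occupied <- occupied + 1L
    if (abs(f - pbar) <= band + 1e-12) ok <- ok + 1L
  }
  expect_gte(ok / occupied, 0.9)
})

test_that("planted angular arcs are placed where configured", {
  cfg <- s1_config(N = 60, beta = 3, mean_degree = 8, seed = 2L,
                   planted_clusters = list(
                     list(center = 0, width = 0.3, n = 30),
                     list(center = pi, width = 0.3, n = 30)))
  g <- generate_s1_network(cfg)
  th <- g$truth$theta
  expect_true(all(angular_separation(th[1:30], 0) <= 0.151))
  expect_true(all(angular_separation(th[31:60], pi) <= 0.151))
})

test_that("euclidean generator decays with distance and is deterministic", {
  cfg <- euclidean_config(N = 1500, box = 100, decay_scale = 10, seed = 9L)
  x <- generate_euclidean_connectome(cfg)
  expect_identical(x$edges, generate_euclidean_connectome(cfg)$edges)
  curve <- empirical_connection_probability(x, euclidean_metric(x),
                                            n_bins = 10L)
  occ <- which(curve$pair_count >= 50)
  f <- curve$fraction_connected[occ]
  se <- sqrt(pmax(f * (1 - f), 1e-12) / curve$pair_count[occ])
  # non-increasing across bins, within 3 binomial standard errors
  for (k in seq_len(length(occ) - 1L)) {
    expect_lte(f[k + 1L], f[k] + 3 * (se[k] + se[k + 1L]))
  }
})

test_that("a huge decay scale flattens the connection curve near 1", {
  cfg <- euclidean_config(N = 300, box = 10, decay_scale = 1e6, seed = 4L)
  x <- generate_euclidean_connectome(cfg)
  curve <- empirical_connection_probability(x, euclidean_metric(x),
                                            n_bins = 5L)
  occ <- curve$pair_count > 0
  expect_true(all(curve$fraction_connected[occ] > 0.99))
})

test_that("max_link_length removes all long links", {
  cfg <- euclidean_config(N = 400, box = 100, decay_scale = 30,
                          max_link_length = 25, seed = 6L)
  x <- generate_euclidean_connectome(cfg)
  met <- euclidean_metric(x)
  idx <- cbind(match(x$edges[, 1], x$nodes), match(x$edges[, 2], x$nodes))
  expect_true(all(met[idx] <= 25))
})
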