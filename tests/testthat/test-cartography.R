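arc_map <- function(n_per_arc = 10L, width = 0.3, centers = c(0, pi),
                    seed = 1L) {
  set.seed(seed)
  th <- unlist(lapply(centers, function(ctr) {
    (ctr + stats::runif(n_per_arc, -width / 2, width / 2)) %% (2 * pi)
  }))
  n <- length(th)
  hyperbolic_map(sprintf("v%03d", seq_len(n)), r = rep(5, n), theta = th,
                 R = 10, beta = 2.5)
}

test_that("the critical gap method recovers two planted arcs exactly", {
  m <- arc_map()
  p <- critical_gap_communities(m)
  expect_equal(length(unique(unclass(p))), 2L)
  # each arc is exactly one community
  expect_equal(length(unique(unclass(p)[1:10])), 1L)
  expect_equal(length(unique(unclass(p)[11:20])), 1L)
  expect_false(unclass(p)[1] == unclass(p)[11])
})

test_that("critical gap partitions are rotation invariant up to labels", {
  m <- arc_map(seed = 3L)
  p1 <- critical_gap_communities(m)
  m2 <- m
  m2$theta <- (m2$theta + 1.234) %% (2 * pi)
  p2 <- critical_gap_communities(m2)
  expect_equal(nmi(p1, p2), 1)
  # single node: one community
  m1 <- hyperbolic_map("a", 1, 0.3, R = 5, beta = 2)
  expect_equal(unname(unclass(critical_gap_communities(m1))), "c1")
})

test_that("uniform angles below the critical gap give a single community", {
  n <- 50L
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  m <- hyperbolic_map(paste0("u", 1:n), rep(3, n), th, R = 8, beta = 2)
  # all gaps are 2*pi/n, below (2*pi/n)*log(n)
  expect_equal(length(unique(unclass(critical_gap_communities(m)))), 1L)
})

test_that("NMI matches hand-computed contingency values", {
  ids <- c("1", "2", "3", "4")
  pa <- partition(stats::setNames(c("x", "x", "y", "y"), ids))
  pb <- partition(stats::setNames(c("x", "y", "x", "y"), ids))
  expect_equal(nmi(pa, pa), 1)
  expect_equal(nmi(pa, pb), 0) # all joint cells 1/4: zero information
  single <- partition(stats::setNames(rep("z", 4), ids))
  expect_equal(nmi(pa, single), 0)
  expect_equal(nmi(single, single), 1)
  expect_equal(nmi(pa, pb), nmi(pb, pa))
  # permuting labels changes nothing
  pc <- partition(stats::setNames(c("q", "q", "w", "w"), ids))
  expect_equal(nmi(pa, pc), 1)
  expect_error(nmi(pa, partition(stats::setNames("x", "9"))), "node set")
  # alternative normalizations stay within [0, 1] and agree at the extremes
  expect_equal(nmi(pa, pc, normalization = "max"), 1)
  expect_equal(nmi(pa, pb, normalization = "sqrt"), 0)
})

test_that("angular localization flags a planted arc and not the full set", {
  set.seed(13)
  n <- 200L
  th <- stats::runif(n, 0, 2 * pi)
  arc <- (stats::runif(20, -0.15, 0.15)) %% (2 * pi)
  th[1:20] <- arc
  m <- hyperbolic_map(sprintf("v%03d", 1:n), rep(4, n), th, R = 9, beta = 2)
  rep1 <- angular_localization(m, m$node_ids[1:20], n_samples = 10000L,
                               seed = 3L)
  expect_lt(rep1$p_value, 0.01)
  expect_lt(rep1$ratio, 0.2)

  rep2 <- angular_localization(m, m$node_ids, n_samples = 200L, seed = 4L)
  expect_equal(rep2$ratio, 1)
  expect_equal(rep2$p_value, 1)
  expect_error(angular_localization(m, m$node_ids[1]), "at least 2")
  expect_error(angular_localization(m, c("v001", "nope")), "missing")
})

test_that("localization p-values are roughly uniform for random clusters", {
  set.seed(21)
  n <- 100L
  m <- hyperbolic_map(paste0("v", 1:n), rep(4, n),
                      stats::runif(n, 0, 2 * pi), R = 9, beta = 2)
  pvals <- vapply(1:200, function(k) {
    cl <- sample(m$node_ids, 10L)
    angular_localization(m, cl, n_samples = 200L, seed = 1000L + k)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("region angular span measures the smallest containing arc", {
  m <- hyperbolic_map(c("a", "b", "c"), rep(2, 3), c(0, 0.1, 0.2),
                      R = 6, beta = 2)
  expect_equal(region_angular_span(m, c("a", "b", "c")), 0.2 / (2 * pi))
  expect_equal(region_angular_span(m, "a"), 0)
  m2 <- hyperbolic_map(c("a", "b"), c(1, 1), c(1.2, 1.2), R = 6, beta = 2)
  expect_equal(region_angular_span(m2, c("a", "b")), 0)
  # wraparound: angles straddling 0
  m3 <- hyperbolic_map(c("a", "b"), c(1, 1), c(0.1, 2 * pi - 0.1),
                       R = 6, beta = 2)
  expect_equal(region_angular_span(m3, c("a", "b")), 0.2 / (2 * pi))
  # many uniform angles span almost the full circle
  set.seed(8)
  n <- 100L
  mu <- hyperbolic_map(paste0("u", 1:n), rep(2, n),
                       stats::runif(n, 0, 2 * pi), R = 6, beta = 2)
  expect_gte(region_angular_span(mu, mu$node_ids), 0.9)
})

test_that("empirical connection curves hit the trivial limits", {
  x <- random_spatial_instance(10, p = 1.1, seed = 5) # complete
  curve <- empirical_connection_probability(x, euclidean_metric(x), 5L)
  occ <- curve$pair_count > 0
  expect_true(all(curve$fraction_connected[occ] == 1))
  expect_equal(sum(curve$pair_count), 45)

  ids <- paste0("e", 1:10)
  pos <- matrix(stats::runif(30), 10, 3, dimnames = list(ids, NULL))
  empty <- set_positions(connectome(ids, NULL), pos)
  curve2 <- empirical_connection_probability(empty, euclidean_metric(empty), 5L)
  occ2 <- curve2$pair_count > 0
  expect_true(all(curve2$fraction_connected[occ2] == 0))
  expect_true(all(is.nan(curve2$fraction_connected[!occ2])))
})

test_that("normalized angular separation lies in [0, 1]", {
  expect_equal(normalized_angular_separation(0, pi), 1)
  expect_equal(normalized_angular_separation(0.3, 0.3), 0)
  expect_equal(normalized_angular_separation(0, pi / 2), 0.5)
})

test_that("annotation partitions and NMI integrate with communities", {
  m <- arc_map(seed = 9L)
  ids <- m$node_ids
  x <- connectome(ids, cbind(ids[1:19], ids[2:20]))
  ann <- data.frame(region = rep(c("front", "back"), each = 10L),
                    row.names = ids)
  x <- navmaps:::set_annotations(x, ann)
  p_ann <- annotation_partition(x, "region")
  p_cgm <- critical_gap_communities(m)
  expect_equal(nmi(p_cgm, p_ann), 1)
})
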