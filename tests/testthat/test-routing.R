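test_that("greedy routing follows the protocol on the worked instance", {
  w <- instance_w()
  r <- greedy_route(w$x, w$metric, "s", "f")
  expect_true(r$success)
  expect_equal(r$path, c("s", "m", "f"))
  expect_equal(r$hops, 2L)

  # m forwards back toward s; loop detected
  r2 <- greedy_route(w$x, w$metric, "s", "t")
  expect_false(r2$success)
  expect_equal(r2$path[length(r2$path)], "s") # ends at the first revisit

  r3 <- greedy_route(w$x, w$metric, "m", "m")
  expect_true(r3$success)
  expect_equal(r3$hops, 0L)
  expect_equal(r3$geometric_length, 0)

  expect_error(greedy_route(w$x, w$metric, "zz", "t"), "unknown")
})

test_that("navigability on the worked instance matches the hand enumeration", {
  w <- instance_w()
  nav <- navigability(w$x, w$metric)
  expect_equal(nav$success_rate, 10 / 12)
  expect_equal(nav$pair_count, 12)
  expect_equal(unname(nav$incoming_sr["t"]), 1 / 3)
  expect_equal(unname(nav$outgoing_sr["s"]), 2 / 3)
  expect_true(all(nav$topological_stretch$values == 1))
})

test_that("complete graphs are perfectly navigable with unit stretch", {
  x <- random_spatial_instance(5, p = 1.1, seed = 2) # p > 1: complete K5
  nav <- navigability(x, euclidean_metric(x))
  expect_equal(nav$success_rate, 1)
  expect_equal(nav$pair_count, 20)
  expect_true(all(nav$topological_stretch$values == 1))
  expect_true(all(abs(nav$geometric_stretch$values - 1) < 1e-12))
})

test_that("a constructed instance exhibits geometric stretch below 1", {
  inst <- instance_short_detour()
  r <- greedy_route(inst$x, inst$metric, "s", "T")
  expect_true(r$success)
  expect_equal(r$path, c("s", "b", "c", "T"))
  nav <- navigability(inst$x, inst$metric)
  expect_gt(sum(nav$geometric_stretch$values < 1), 0)
  expect_true(all(nav$topological_stretch$values >= 1))
})

test_that("routing agrees with the brute-force oracle on random instances", {
  for (seed in 1:60) {
    n <- 2L + (seed %% 9L)
    x <- random_spatial_instance(n, p = 0.4, seed = seed)
    met <- euclidean_metric(x)
    for (s in x$nodes) {
      for (t in x$nodes) {
        if (s == t) next
        got <- greedy_route(x, met, s, t)
        want <- oracle_greedy(x, met, s, t)
        expect_identical(got$success, want$success)
        expect_identical(got$path, want$path)
      }
    }
  }
})

test_that("pairs spanning components are excluded from the denominator", {
  x <- connectome(c("a", "b", "c", "d"), rbind(c("a", "b"), c("c", "d")))
  pos <- matrix(stats::runif(12), 4, 3,
                dimnames = list(c("a", "b", "c", "d"), NULL))
  x <- set_positions(x, pos)
  nav <- navigability(x, euclidean_metric(x))
  expect_equal(nav$pair_count, 4) # 2 ordered pairs per 2-node component
  expect_equal(nav$success_rate, 1)
})

test_that("success rate is invariant under global isometries", {
  x <- random_spatial_instance(30, p = 0.15, seed = 77)
  base <- navigability(x, euclidean_metric(x))$success_rate
  # rotation about z plus translation
  ang <- 0.83
  rot <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
               c(0, 0, 1))
  x2 <- x
  pos2 <- x$positions %*% t(rot) + rep(c(5, -2, 11), each = nrow(x$positions))
  rownames(pos2) <- x$nodes
  x2 <- set_positions(x2, pos2)
  expect_equal(navigability(x2, euclidean_metric(x2))$success_rate, base)

  # hyperbolic rotation + reflection leave SR unchanged
  d <- demo_s1()
  sr <- navigability(d$x, hyperbolic_metric(d$map))$success_rate
  m2 <- d$map
  m2$theta <- (2 * pi - (m2$theta + 0.5)) %% (2 * pi)
  expect_equal(navigability(d$x, hyperbolic_metric(m2))$success_rate, sr)
})

test_that("directed routing follows out-neighbors only", {
  # a -> b -> c, with c positioned so undirected routing from c would reach a
  x <- connectome(c("a", "b", "c"), NULL,
                  directed_edges = rbind(c("a", "b"), c("b", "c")))
  pos <- rbind(a = c(0, 0, 0), b = c(1, 0, 0), c = c(2, 0, 0))
  x <- set_positions(x, pos)
  met <- euclidean_metric(x)
  expect_true(greedy_route(x, met, "a", "c", directed = TRUE)$success)
  # no out-edges from c: directed route fails immediately
  r <- greedy_route(x, met, "c", "a", directed = TRUE)
  expect_false(r$success)
  # undirected version succeeds
  expect_true(greedy_route(x, met, "c", "a", directed = FALSE)$success)
})

test_that("navigability reports are serializable JSON with a stable schema", {
  w <- instance_w()
  nav <- navigability(w$x, w$metric)
  f <- withr::local_tempfile(fileext = ".json")
  write_navigability_report(nav, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$success_rate, nav$success_rate)
  expect_equal(back$topological_stretch$mean, nav$topological_stretch$mean)
  expect_equal(back$outgoing_sr$s, unname(nav$outgoing_sr["s"]))
})
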