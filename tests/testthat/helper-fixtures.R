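# Shared fixtures and independent oracles, built in code at test time.

# Worked 4-node spatial instance: a path graph whose Euclidean layout makes
# greedy routing fail for exactly 2 of the 12 ordered pairs.
instance_w <- function() {
  x <- connectome(c("t", "m", "s", "f"),
                  rbind(c("s", "m"), c("m", "f"), c("f", "t")))
  pos <- rbind(t = c(0, 0, 0), m = c(1, 0, 0), s = c(2, 0, 0), f = c(1, 5, 0))
  x <- set_positions(x, pos)
  list(x = x, metric = euclidean_metric(x))
}

# Instance whose greedy path is topologically longer but geometrically
# shorter than the hop-minimal path (geometric stretch < 1 for s -> T).
instance_short_detour <- function() {
  x <- connectome(c("T", "s", "a", "b", "c"),
                  rbind(c("s", "a"), c("a", "T"),
                        c("s", "b"), c("b", "c"), c("c", "T")))
  pos <- rbind(T = c(0, 0, 0), s = c(10, 0, 0), a = c(5, 8, 0),
               b = c(6, 0, 0), c = c(3, 0, 0))
  x <- set_positions(x, pos)
  list(x = x, metric = euclidean_metric(x))
}

# Random G(n, p) connectome with uniform random 3D positions.
random_spatial_instance <- function(n, p = 0.4, seed = 1L) {
  set.seed(seed)
  ids <- paste0("v", seq_len(n))
  pairs <- t(utils::combn(ids, 2L))
  sel <- stats::runif(nrow(pairs)) < p
  pos <- matrix(stats::runif(3L * n), n, 3L, dimnames = list(ids, NULL))
  x <- suppressWarnings(connectome(ids, pairs[sel, , drop = FALSE]))
  set_positions(x, pos)
}

# Independent brute-force greedy-routing simulator (pure R, no shared code
# with the package's C++ routing core).
oracle_greedy <- function(x, metric, source, target) {
  adj <- list()
  for (id in x$nodes) adj[[id]] <- character(0)
  for (k in seq_len(nrow(x$edges))) {
    a <- unname(x$edges[k, 1L]); b <- unname(x$edges[k, 2L])
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  path <- source
  if (source == target) {
    return(list(success = TRUE, path = path))
  }
  visited <- source
  cur <- source
  repeat {
    nb <- adj[[cur]]
    if (length(nb) == 0L) return(list(success = FALSE, path = path))
    nb <- nb[order(metric[nb, target], nb, method = "radix")]
    nxt <- nb[1L]
    path <- c(path, nxt)
    if (nxt == target) return(list(success = TRUE, path = path))
    if (nxt %in% visited) return(list(success = FALSE, path = path))
    visited <- c(visited, nxt)
    cur <- nxt
    if (length(path) - 1L >= length(x$nodes)) {
      return(list(success = FALSE, path = path))
    }
  }
}

# Independent double-loop Bernoulli log-likelihood oracle.
oracle_loglik <- function(x, map) {
  ids <- x$nodes
  amat <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_len(nrow(x$edges))) {
    amat[x$edges[k, 1L], x$edges[k, 2L]] <- TRUE
    amat[x$edges[k, 2L], x$edges[k, 1L]] <- TRUE
  }
  acc <- 0
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      ii <- match(ids[i], map$node_ids)
      jj <- match(ids[j], map$node_ids)
      dth <- min(abs(map$theta[ii] - map$theta[jj]),
                 2 * pi - abs(map$theta[ii] - map$theta[jj]))
      arg <- cosh(map$r[ii]) * cosh(map$r[jj]) -
        sinh(map$r[ii]) * sinh(map$r[jj]) * cos(dth)
      d <- acosh(max(arg, 1))
      p <- 1 / (1 + exp(map$beta / 2 * (d - map$R)))
      p <- min(max(p, 1e-15), 1 - 1e-15)
      acc <- acc + if (amat[ids[i], ids[j]]) log(p) else log(1 - p)
    }
  }
  acc
}

# A small S1 demo network reused by several tests (cached per session).
demo_s1 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- generate_s1_network(
        s1_config(N = 300, gamma = 2.7, beta = 3, mean_degree = 10,
                  seed = 7L))
      comp <- connected_components(gen$connectome)[[1L]]
      cache <<- list(
        x = induced_connectome(gen$connectome, comp),
        truth = gen$truth,
        map = s1_to_hyperbolic(gen$truth))
    }
    cache
  }
})
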