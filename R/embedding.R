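#' Embedding configuration
#'
#' Tunables of the Metropolis-Hastings likelihood maximization. Defaults
#' are chosen for networks of a few hundred to a few thousand nodes.
#'
#' @param beta optional fixed inverse temperature; when `NULL` it is
#'   estimated with [infer_beta()].
#' @param restarts independent MH runs; the best final likelihood wins.
#' @param sweeps_max maximum number of MH sweeps (one proposal per node per
#'   sweep).
#' @param plateau_sweeps stop after this many sweeps without a likelihood
#'   gain above `tol`.
#' @param tol plateau gain threshold; default `1e-4 * N`, set at run time.
#' @param local_sigma standard deviation of the local angular proposal;
#'   default `2*pi/sqrt(N)`, set at run time.
#' @param global_move_prob probability of proposing a uniform angle instead
#'   of a local step.
#' @param seed integer seed.
#' @return an `embedding_config` list.
#' @export
embedding_config <- function(beta = NULL, restarts = 3L, sweeps_max = 3000L,
                             plateau_sweeps = 100L, tol = NULL,
                             local_sigma = NULL, global_move_prob = 0.1,
                             seed = 1L) {
  stopifnot(restarts >= 1, sweeps_max >= 1, plateau_sweeps >= 1,
            global_move_prob >= 0, global_move_prob <= 1)
  structure(list(beta = beta, restarts = as.integer(restarts),
                 sweeps_max = as.integer(sweeps_max),
                 plateau_sweeps = as.integer(plateau_sweeps), tol = tol,
                 local_sigma = local_sigma,
                 global_move_prob = global_move_prob,
                 seed = as.integer(seed)),
            class = "embedding_config")
}

# Mean local clustering coefficient; nodes of degree < 2 are excluded.
mean_local_clustering <- function(g) {
  mean(igraph::transitivity(g, type = "local"), na.rm = TRUE)
}

#' Estimate the inverse temperature beta from clustering
#'
#' S1 surrogate networks are generated with hidden degrees equal to the
#' observed degrees, uniform angles and mu calibrated to the observed mean
#' degree; beta is bisected on (1.01, 10] until the surrogates' mean local
#' clustering coefficient matches the observed one within 0.01 (5
#' surrogates per evaluation). Mean local clustering increases
#' monotonically with beta, which makes the bisection well posed.
#'
#' @param x a `connectome`.
#' @param seed integer seed.
#' @param tol clustering match tolerance (default 0.01).
#' @param n_surrogates surrogates averaged per evaluation (default 5).
#' @return beta estimate (> 1). If no beta in range reaches the observed
#'   clustering, the nearest boundary is returned with a warning.
#' @export
infer_beta <- function(x, seed = 1L, tol = 0.01, n_surrogates = 5L) {
  g <- as_igraph(x)
  c_obs <- mean_local_clustering(g)
  if (!is.finite(c_obs) || c_obs <= 0) {
    warning("graph has no measurable clustering; returning lower boundary")
    return(1.01)
  }
  deg <- degrees(x)
  kappa <- pmax(deg, 1)
  kbar <- mean(deg)
  n <- length(kappa)
  pr <- pair_indices(n)
  i <- pr$i; j <- pr$j
  kk <- kappa[i] * kappa[j]
  rng <- local_rng(seed)

  surrogate_clustering <- function(beta) {
    mu <- calibrate_mu(kappa, beta, kbar)
    cs <- vapply(seq_len(n_surrogates), function(s) {
      theta <- rng(stats::runif(n, 0, 2 * pi))
      dth <- angular_separation(theta[i], theta[j])
      p <- 1 / (1 + (dth / (mu * kk))^beta)
      linked <- rng(stats::runif(length(p)) < p)
      gs <- igraph::graph_from_edgelist(cbind(i[linked], j[linked]),
                                        directed = FALSE)
      gs <- igraph::add_vertices(gs, max(0L, n - igraph::vcount(gs)))
      mean_local_clustering(gs)
    }, numeric(1))
    mean(cs, na.rm = TRUE)
  }

  lo <- 1.01; hi <- 10
  c_lo <- surrogate_clustering(lo)
  if (abs(c_obs - c_lo) <= tol) return(lo)
  if (c_obs < c_lo) {
    warning("observed clustering below the beta > 1 range; returning boundary")
    return(lo)
  }
  c_hi <- surrogate_clustering(hi)
  if (abs(c_obs - c_hi) <= tol) return(hi)
  if (c_obs > c_hi) {
    warning("observed clustering above the beta <= 10 range; returning boundary")
    return(hi)
  }
  for (it in seq_len(20L)) {
    mid <- (lo + hi) / 2
    c_mid <- surrogate_clustering(mid)
    if (abs(c_mid - c_obs) <= tol) return(mid)
    if (c_mid < c_obs) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Maximum-likelihood hyperbolic embedding
#'
#' Infers angular coordinates for a connected graph by maximizing the
#' Bernoulli likelihood of its topology under the H2 connection law, with
#' Metropolis-Hastings over angles. Radial coordinates are fixed from the
#' observed degrees: kappa_i = max(k_i, 1) mapped through the
#' popularity-similarity convention with mu calibrated to the observed mean
#' degree. Angles start uniformly at random; each sweep proposes one move
#' per node (local Gaussian step, occasionally a uniform redraw), accepted
#' with probability min(1, exp(delta log L)). The best map across restarts
#' is returned.
#'
#' @param x a connected `connectome`.
#' @param config an [embedding_config].
#' @return a [hyperbolic_map] with attributes `loglik` (final), `loglik0`
#'   (initial, winning restart), `trace` (per-sweep log-likelihood of the
#'   winning restart), `beta`, `mu`, `restart_logliks`, `acceptance_rate`.
#' @export
embed_h2 <- function(x, config = embedding_config()) {
  if (length(connected_components(x)) != 1L) {
    stop("graph is disconnected; embed components separately")
  }
  n <- length(x$nodes)
  deg <- degrees(x)
  kappa <- pmax(deg, 1)
  kappa0 <- min(kappa)
  beta <- config$beta
  if (is.null(beta)) beta <- infer_beta(x, seed = config$seed)
  mu <- calibrate_mu(kappa, beta, mean(deg))
  R <- s1_disk_radius(mu, kappa0)
  if (R <= 0) stop("implied disk radius not positive (graph too dense)")
  r <- kappa_to_radius(kappa, kappa0, R)
  tol <- if (is.null(config$tol)) 1e-4 * n else config$tol
  sigma <- if (is.null(config$local_sigma)) 2 * pi / sqrt(n) else config$local_sigma
  edges0 <- cbind(match(x$edges[, 1L], x$nodes),
                  match(x$edges[, 2L], x$nodes)) - 1L
  storage.mode(edges0) <- "integer"

  rng <- local_rng(config$seed)
  best <- NULL
  restart_logliks <- numeric(config$restarts)
  for (k in seq_len(config$restarts)) {
    theta0 <- rng(stats::runif(n, 0, 2 * pi))
    mh_seed <- (config$seed + 7919L * k) %% .Machine$integer.max
    res <- embed_mh_cpp(edges0, n, r, R, beta, theta0,
                        config$sweeps_max, config$plateau_sweeps, tol,
                        sigma, config$global_move_prob, mh_seed)
    restart_logliks[k] <- res$loglik
    if (is.null(best) || res$loglik > best$loglik) {
      best <- res
      best$theta0 <- theta0
    }
  }
  map <- hyperbolic_map(x$nodes, r, best$theta, R = R, beta = beta)
  attr(map, "loglik") <- best$loglik
  attr(map, "loglik0") <- if (length(best$trace) > 0) NULL else NULL
  # initial likelihood of the winning restart, for convergence reporting
  map0 <- hyperbolic_map(x$nodes, r, best$theta0, R = R, beta = beta)
  attr(map, "loglik0") <- log_likelihood(x, map0)
  attr(map, "trace") <- best$trace
  attr(map, "beta") <- beta
  attr(map, "mu") <- mu
  attr(map, "restart_logliks") <- restart_logliks
  attr(map, "acceptance_rate") <- best$acceptance_rate
  map
}
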