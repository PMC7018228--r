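#' Configuration for the S1 synthetic-network generator
#'
#' @param N node count (>= 2).
#' @param gamma power-law exponent of the hidden-degree (Pareto)
#'   distribution; must exceed 2 so the mean is finite.
#' @param kappa0 minimum hidden degree.
#' @param beta inverse temperature (> 1).
#' @param mean_degree target expected mean degree.
#' @param planted_clusters optional list of planted angular arcs, each a
#'   list/vector with elements `center` (radians), `width` (radians,
#'   < 2*pi) and `n` (node count). Remaining nodes get uniform angles.
#' @param seed integer seed; all randomness in the generator flows from it.
#' @return an `s1_config` list.
#' @export
s1_config <- function(N, gamma = 2.7, kappa0 = 2, beta = 2.5,
                      mean_degree = 10, planted_clusters = NULL, seed = 1L) {
  stopifnot(N >= 2, gamma > 2, kappa0 > 0, beta > 1, mean_degree > 0)
  if (!is.null(planted_clusters)) {
    tot <- sum(vapply(planted_clusters, function(p) p[["n"]], numeric(1)))
    if (tot > N) stop("planted clusters exceed N nodes")
    widths <- vapply(planted_clusters, function(p) p[["width"]], numeric(1))
    if (any(widths <= 0 | widths >= 2 * pi)) stop("arc widths must be in (0, 2*pi)")
  }
  structure(list(N = as.integer(N), gamma = gamma, kappa0 = kappa0,
                 beta = beta, mean_degree = mean_degree,
                 planted_clusters = planted_clusters,
                 seed = as.integer(seed)),
            class = "s1_config")
}

#' Sample hidden degrees from a Pareto distribution
#'
#' Density proportional to kappa^(-gamma) for kappa >= kappa0. Mean
#' kappa0 * (gamma - 1) / (gamma - 2), finite only for gamma > 2.
#'
#' @param config an [s1_config].
#' @return numeric vector of N hidden degrees; deterministic given the
#'   config's seed.
#' @export
sample_hidden_degrees <- function(config) {
  if (config$gamma <= 2) stop("gamma must exceed 2 (finite-mean regime)")
  rng <- local_rng(config$seed)
  u <- rng(stats::runif(config$N))
  config$kappa0 * (1 - u)^(-1 / (config$gamma - 1))
}

# Run `expr`-style draws under a temporary RNG state seeded with `seed`,
# restoring the caller's state. Returns a function that evaluates its
# argument inside that state; successive calls continue the stream.
local_rng <- function(seed) {
  state <- NULL
  seed <- as.integer(seed %% .Machine$integer.max)
  function(expr) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, globalenv())
    on.exit({
      state <<- get(".Random.seed", globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, globalenv())
      }
    })
    expr
  }
}

#' Generate a synthetic S1-model network with ground truth
#'
#' Hidden degrees are Pareto draws, angles uniform on the circle (or placed
#' in planted arcs), mu is calibrated to the target mean degree, and each
#' unordered pair is linked independently with the S1 connection
#' probability.
#'
#' @param config an [s1_config].
#' @return a list with elements `connectome` and `truth` (an [s1_params]
#'   holding the generating coordinates and parameters).
#' @export
generate_s1_network <- function(config) {
  n <- config$N
  kappa <- sample_hidden_degrees(config)
  rng <- local_rng(config$seed + 1L)
  theta <- rng({
    if (is.null(config$planted_clusters)) {
      stats::runif(n, 0, 2 * pi)
    } else {
      th <- numeric(n)
      used <- 0L
      for (pc in config$planted_clusters) {
        m <- as.integer(pc[["n"]])
        th[used + seq_len(m)] <-
          (pc[["center"]] + stats::runif(m, -pc[["width"]] / 2, pc[["width"]] / 2)) %% (2 * pi)
        used <- used + m
      }
      th[used + seq_len(n - used)] <- stats::runif(n - used, 0, 2 * pi)
      th
    }
  })
  mu <- calibrate_mu(kappa, config$beta, config$mean_degree)
  pr <- pair_indices(n)
  i <- pr$i; j <- pr$j
  dth <- angular_separation(theta[i], theta[j])
  p <- connection_prob_s1(dth, kappa[i], kappa[j], mu, config$beta)
  linked <- rng(stats::runif(length(p)) < p)
  ids <- sprintf("n%04d", seq_len(n))
  conn <- connectome(ids, cbind(ids[i[linked]], ids[j[linked]]))
  truth <- s1_params(ids, kappa, theta, mu, config$beta)
  list(connectome = conn, truth = truth)
}

#' Configuration for the 3D spatial-network generator
#'
#' @param N node count.
#' @param box side lengths of the 3D box (length-3 vector or scalar).
#' @param decay_scale lambda, the length scale of the connection-probability
#'   decay (same units as `box`).
#' @param beta_e sharpness exponent of the decay.
#' @param max_link_length optional hard cutoff: links longer than this are
#'   removed, emulating partial-volume datasets that miss long-range
#'   connections.
#' @param decay either `"powerlaw"` (p = 1/(1 + (d/lambda)^beta_e)) or
#'   `"exponential"` (p = exp(-d/lambda)).
#' @param seed integer seed.
#' @return a `euclidean_config` list.
#' @export
euclidean_config <- function(N, box = c(100, 100, 100), decay_scale = 10,
                             beta_e = 3, max_link_length = NULL,
                             decay = c("powerlaw", "exponential"), seed = 1L) {
  decay <- match.arg(decay)
  if (length(box) == 1L) box <- rep(box, 3L)
  stopifnot(N >= 2, all(box > 0), decay_scale > 0, beta_e > 0)
  if (!is.null(max_link_length)) stopifnot(max_link_length > 0)
  structure(list(N = as.integer(N), box = box, decay_scale = decay_scale,
                 beta_e = beta_e, max_link_length = max_link_length,
                 decay = decay, seed = as.integer(seed)),
            class = "euclidean_config")
}

#' Generate a 3D spatial network with distance-decaying connectivity
#'
#' N points uniform in a box; pair (i, j) linked with probability
#' 1/(1 + (d_ij/lambda)^beta_e) (or exp(-d/lambda)); links longer than
#' `max_link_length`, when set, are removed.
#'
#' @param config a [euclidean_config].
#' @return a `connectome` with positions attached.
#' @export
generate_euclidean_connectome <- function(config) {
  n <- config$N
  rng <- local_rng(config$seed)
  pos <- rng(matrix(stats::runif(3 * n) * rep(config$box, each = n), n, 3))
  ids <- sprintf("n%04d", seq_len(n))
  rownames(pos) <- ids
  pr <- pair_indices(n)
  i <- pr$i; j <- pr$j
  d <- sqrt(rowSums((pos[i, , drop = FALSE] - pos[j, , drop = FALSE])^2))
  p <- switch(config$decay,
    powerlaw = 1 / (1 + (d / config$decay_scale)^config$beta_e),
    exponential = exp(-d / config$decay_scale))
  linked <- rng(stats::runif(length(p)) < p)
  if (!is.null(config$max_link_length)) {
    linked <- linked & d <= config$max_link_length
  }
  connectome(ids, cbind(ids[i[linked]], ids[j[linked]]), positions = pos)
}

#' Write the ground truth of a generated S1 network
#'
#' JSON with per-node kappa and theta plus global mu and beta.
#'
#' @param truth an [s1_params].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_s1_truth <- function(truth, path) {
  jsonlite::write_json(
    list(mu = truth$mu, beta = truth$beta,
         nodes = data.frame(id = truth$node_ids, kappa = truth$kappa,
                            theta = truth$theta)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
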