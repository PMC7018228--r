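#' Rewiring configuration for the randomization baselines
#'
#' @param epsilon per-swap cost tolerance as a fraction of the total wiring
#'   cost D (default 1/60).
#' @param swap_multiplier target number of successful swaps per link
#'   (default 100, i.e. 100 * L successful swaps).
#' @param max_attempt_factor attempts allowed per requested swap
#'   (default 100).
#' @param seed integer seed.
#' @return a `rewire_config` list.
#' @export
rewire_config <- function(epsilon = 1 / 60, swap_multiplier = 100,
                          max_attempt_factor = 100, seed = 1L) {
  stopifnot(epsilon >= 0, swap_multiplier > 0, max_attempt_factor > 0)
  structure(list(epsilon = epsilon, swap_multiplier = swap_multiplier,
                 max_attempt_factor = max_attempt_factor,
                 seed = as.integer(seed)),
            class = "rewire_config")
}

#' Null model 1: random position swap
#'
#' Permutes the node-to-position assignment uniformly at random, leaving
#' the topology untouched. Destroys the coupling between geometry and
#' structure while preserving both marginally. Works on a `connectome`
#' (permutes 3D positions) or on a [hyperbolic_map] (permutes the (r, theta)
#' coordinate pairs among nodes).
#'
#' @param x a `connectome` with positions, or a `hyperbolic_map`.
#' @param seed integer seed.
#' @return object of the same class with permuted coordinates.
#' @export
shuffle_positions <- function(x, seed = 1L) {
  rng <- local_rng(seed)
  if (inherits(x, "hyperbolic_map")) {
    perm <- rng(sample.int(length(x$node_ids)))
    x$r <- x$r[perm]
    x$theta <- x$theta[perm]
    return(x)
  }
  if (is.null(x$positions)) stop("no positions attached")
  perm <- rng(sample.int(length(x$nodes)))
  pos <- x$positions[perm, , drop = FALSE]
  rownames(pos) <- x$nodes
  x$positions <- pos
  x
}

run_rewire <- function(x, config, metric = NULL) {
  L <- nrow(x$edges)
  if (L < 2L) stop("rewiring needs at least 2 links")
  n <- length(x$nodes)
  edges0 <- cbind(match(x$edges[, 1L], x$nodes),
                  match(x$edges[, 2L], x$nodes)) - 1L
  cost_constrained <- !is.null(metric)
  if (cost_constrained) {
    metric <- check_metric(metric, x$nodes)
    d_edges <- metric[edges0 + 1L]
    D <- sum(d_edges)
    eps_D <- config$epsilon * D
  } else {
    metric <- matrix(0, 1, 1)
    D <- NA_real_
    eps_D <- 0
  }
  target <- config$swap_multiplier * L
  res <- rewire_cpp(edges0, n, target, config$max_attempt_factor * target,
                    cost_constrained, metric, eps_D, keep_log = TRUE,
                    seed = config$seed)
  if (res$accepted < target) {
    warning("attempt budget exhausted: ", res$accepted, " of ", target,
            " requested swaps performed")
  }
  ids <- x$nodes
  out <- x
  out$edges <- canonical_edges(cbind(ids[res$edges[, 1L] + 1L],
                                     ids[res$edges[, 2L] + 1L]), ids)
  out$directed_edges <- NULL
  info <- list(attempts = res$attempts, accepted = res$accepted,
               target = target, epsilon = if (cost_constrained) config$epsilon else NA_real_,
               D = D, seed = config$seed)
  if (!is.null(res$swap_log) && nrow(res$swap_log) > 0) {
    sl <- res$swap_log + 1L
    info$swap_log <- data.frame(a = ids[sl[, 1L]], b = ids[sl[, 2L]],
                                c = ids[sl[, 3L]], d = ids[sl[, 4L]])
  } else {
    info$swap_log <- data.frame(a = character(0), b = character(0),
                                c = character(0), d = character(0))
  }
  attr(out, "rewire_info") <- info
  out
}

#' Null model 2: degree-preserving rewiring (configuration model)
#'
#' Repeated double-edge swaps (a-b, c-d) -> (a-c, b-d) on four distinct
#' nodes, rejecting swaps that would create self-loops or duplicate edges,
#' until `swap_multiplier * L` successful swaps or the attempt budget is
#' exhausted (then a warning). Preserves N, L and the degree sequence
#' exactly; positions are untouched.
#'
#' @param x a `connectome`.
#' @param config a [rewire_config].
#' @return the rewired `connectome`; an attribute `rewire_info` records
#'   attempts, acceptances and the swap log.
#' @export
rewire_degree_preserving <- function(x, config = rewire_config()) {
  run_rewire(x, config, metric = NULL)
}

#' Null model 3: cost-preserving rewiring
#'
#' As [rewire_degree_preserving()], but a candidate swap is additionally
#' accepted only if |(d_AB + d_CD) - (d_AC + d_BD)| < epsilon * D, where D
#' is the total wiring cost of the input graph (sum of metric distances
#' over its edges, each undirected edge counted once, computed once on the
#' input and never updated). Preserves the degree sequence and keeps the
#' total cost near the original.
#'
#' @inheritParams rewire_degree_preserving
#' @param metric pairwise distance matrix (node ids as dimnames).
#' @return the rewired `connectome` with a `rewire_info` attribute
#'   (including epsilon and D).
#' @export
rewire_cost_preserving <- function(x, metric, config = rewire_config()) {
  run_rewire(x, config, metric = metric)
}

#' Total wiring cost of a connectome under a metric
#'
#' @param x a `connectome`.
#' @param metric pairwise distance matrix.
#' @return sum of metric distances over the undirected edges.
#' @export
total_cost <- function(x, metric) {
  metric <- check_metric(metric, x$nodes)
  idx <- cbind(match(x$edges[, 1L], x$nodes), match(x$edges[, 2L], x$nodes))
  sum(metric[idx])
}
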