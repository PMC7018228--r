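#' Pairwise metric oracles
#'
#' A metric is represented as a dense symmetric matrix of pairwise distances
#' with node ids as dimnames. `euclidean_metric` builds it from a
#' connectome's 3D positions; `hyperbolic_metric` from a hyperbolic map
#' using the exact law-of-cosines distance.
#'
#' @param x a `connectome` with positions.
#' @return distance matrix with node-id dimnames.
#' @export
euclidean_metric <- function(x) {
  if (is.null(x$positions)) stop("connectome has no positions")
  euclidean_distance_matrix(x$positions)
}

#' @rdname euclidean_metric
#' @param map a [hyperbolic_map].
#' @export
hyperbolic_metric <- function(map) {
  m <- hyperbolic_distance_matrix(map$r, map$theta)
  dimnames(m) <- list(map$node_ids, map$node_ids)
  m
}

check_metric <- function(metric, nodes) {
  if (!is.matrix(metric)) stop("metric must be a distance matrix")
  ids <- rownames(metric)
  if (is.null(ids) || !all(nodes %in% ids)) {
    stop("metric must cover every node (node ids as dimnames)")
  }
  metric[nodes, nodes, drop = FALSE]
}

#' Greedy routing of a single source/target pair
#'
#' The signal is forwarded, at each step, to the neighbor of the current
#' node that is closest to the target under the metric (ties broken by the
#' lexicographically smallest node id). Success when the target is reached;
#' failure when the next hop is a node already visited (the walk is then
#' provably stuck in a loop) or, as a backstop, after N hops.
#'
#' @param x a `connectome`.
#' @param metric pairwise distance matrix (node ids as dimnames).
#' @param source,target node ids.
#' @param directed forward along out-neighbors of the directed edge set.
#' @return a `routing_outcome` list: `source`, `target`, `success`, `path`
#'   (node-id sequence from the source; on failure it ends at the first
#'   revisited node), `hops`, `geometric_length`.
#' @export
greedy_route <- function(x, metric, source, target, directed = FALSE) {
  s <- match(source, x$nodes)
  t <- match(target, x$nodes)
  if (is.na(s) || is.na(t)) stop("unknown node id")
  metric <- check_metric(metric, x$nodes)
  if (!all(is.finite(metric))) stop("metric contains non-finite distances")
  adj <- adjacency_index(x, directed = directed)
  res <- greedy_route_cpp(adj, metric, rank_c(x$nodes), s - 1L, t - 1L,
                          length(x$nodes))
  structure(
    list(source = source, target = target, success = res$success,
         path = x$nodes[res$path + 1L],
         hops = length(res$path) - 1L,
         geometric_length = res$geometric_length),
    class = "routing_outcome")
}

#' Navigability of a connectome under a metric
#'
#' Runs greedy routing over every ordered source/target pair within
#' connected components (pairs spanning components are excluded from both
#' numerator and denominator; source = target pairs are excluded). Reports
#' the success rate, topological stretch (greedy hops over BFS shortest-path
#' hops), geometric stretch (greedy geometric length over the geometric
#' length of the hop-minimal path, taking among hop-minimal paths the one of
#' minimal geometric length), and the per-node locally outgoing and
#' incoming success rates.
#'
#' @inheritParams greedy_route
#' @return a `navigability_report` list: `success_rate`, `pair_count`,
#'   `topological_stretch` and `geometric_stretch` (each with `values`,
#'   `mean`, `p10`, `p90` over successful pairs), `outgoing_sr` and
#'   `incoming_sr` (named per-node fractions, `NaN` for nodes with no
#'   eligible pairs).
#' @export
navigability <- function(x, metric, directed = FALSE) {
  metric <- check_metric(metric, x$nodes)
  if (!all(is.finite(metric))) stop("metric contains non-finite distances")
  radj <- adjacency_index(x, directed = directed)
  uadj <- adjacency_index(x, directed = FALSE)
  g <- as_igraph(x)
  comp <- as.integer(igraph::components(g)$membership[x$nodes])
  res <- navigability_cpp(radj, uadj, metric, rank_c(x$nodes), comp)
  summarize <- function(v) {
    if (length(v) == 0L) {
      list(values = numeric(0), mean = NaN, p10 = NaN, p90 = NaN)
    } else {
      q <- stats::quantile(v, c(0.1, 0.9), names = FALSE, type = 7)
      list(values = v, mean = mean(v), p10 = q[1L], p90 = q[2L])
    }
  }
  out_sr <- res$out_succ / res$out_tot
  in_sr <- res$in_succ / res$in_tot
  names(out_sr) <- names(in_sr) <- x$nodes
  structure(
    list(success_rate = if (res$pair_count > 0) res$successes / res$pair_count else NaN,
         pair_count = res$pair_count,
         topological_stretch = summarize(res$topological_stretch),
         geometric_stretch = summarize(res$geometric_stretch),
         outgoing_sr = out_sr,
         incoming_sr = in_sr),
    class = "navigability_report")
}

#' @export
print.navigability_report <- function(x, ...) {
  cat("<navigability_report> SR = ", signif(x$success_rate, 4),
      " over ", x$pair_count, " ordered pairs\n",
      "  topological stretch: mean ", signif(x$topological_stretch$mean, 4),
      " [", signif(x$topological_stretch$p10, 4), ", ",
      signif(x$topological_stretch$p90, 4), "] (10/90 pct)\n",
      "  geometric stretch:   mean ", signif(x$geometric_stretch$mean, 4),
      " [", signif(x$geometric_stretch$p10, 4), ", ",
      signif(x$geometric_stretch$p90, 4), "] (10/90 pct)\n", sep = "")
  invisible(x)
}

#' Serialize a navigability report to JSON
#'
#' Stable schema: scalar `success_rate` and `pair_count`; `mean`, `p10`,
#' `p90` summaries for both stretches; per-node outgoing/incoming rates.
#' Per-pair stretch values are omitted from the JSON (they can be large).
#'
#' @param report a `navigability_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_navigability_report <- function(report, path) {
  strip <- function(s) s[c("mean", "p10", "p90")]
  jsonlite::write_json(
    list(success_rate = report$success_rate,
         pair_count = report$pair_count,
         topological_stretch = strip(report$topological_stretch),
         geometric_stretch = strip(report$geometric_stretch),
         outgoing_sr = as.list(report$outgoing_sr),
         incoming_sr = as.list(report$incoming_sr)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
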