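#' Angular communities by the critical gap method
#'
#' Nodes are sorted by angle on the circle; every consecutive gap
#' (including the wraparound gap) strictly greater than the critical gap
#' splits communities. The default critical gap is the asymptotic expected
#' maximal gap of N uniform angles, g_c = (2*pi/N) * log(N), so communities
#' are angular intervals more isolated than uniform placement would
#' produce. The output is invariant under global rotation of the map.
#'
#' @param map a [hyperbolic_map].
#' @param critical_gap the gap threshold in radians; default
#'   `(2*pi/N) * log(N)`.
#' @return a `partition`: named character vector mapping node id ->
#'   community label (`"c1"`, `"c2"`, ... in angular order starting after
#'   the largest gap).
#' @export
critical_gap_communities <- function(map, critical_gap = NULL) {
  n <- length(map$node_ids)
  if (n == 0L) stop("empty map")
  if (is.null(critical_gap)) critical_gap <- (2 * pi / n) * log(n)
  if (n == 1L) {
    return(partition(stats::setNames("c1", map$node_ids)))
  }
  ord <- order(map$theta, rank_c(map$node_ids), method = "radix")
  th <- map$theta[ord]
  gaps <- c(diff(th), th[1L] + 2 * pi - th[n]) # gap after each sorted node
  cut_after <- which(gaps > critical_gap)
  if (length(cut_after) == 0L) {
    labels <- rep("c1", n)
  } else {
    # start labeling after the largest gap so labels are rotation-stable
    start <- cut_after[which.max(gaps[cut_after])]
    shifted <- c((start + 1):n, seq_len(start))[seq_len(n)]
    if (start == n) shifted <- seq_len(n)
    comm <- cumsum(c(TRUE, gaps[shifted[-n]] > critical_gap))
    labels <- character(n)
    labels[shifted] <- paste0("c", comm)
  }
  out <- character(n)
  out[ord] <- labels
  partition(stats::setNames(out, map$node_ids))
}

#' Partition of a node set into communities
#'
#' @param assignment named character vector: node id -> community label.
#' @return object of class `partition`.
#' @export
partition <- function(assignment) {
  if (is.null(names(assignment)) || anyDuplicated(names(assignment))) {
    stop("assignment must be named by unique node ids")
  }
  structure(as.character(assignment), names = names(assignment),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("<partition> ", length(x), " nodes in ", length(unique(unclass(x))),
      " communities\n", sep = "")
  invisible(x)
}

#' Normalized mutual information between two partitions
#'
#' NMI computed from the joint label contingency table with natural logs.
#' The default normalization is 2 I / (H1 + H2) (arithmetic mean); `"max"`
#' and `"sqrt"` normalizations are selectable. When both entropies are zero
#' (both partitions single-cluster) the partitions are identical and NMI is
#' 1; when exactly one entropy is zero the mutual information is zero and
#' NMI is 0.
#'
#' @param p1,p2 `partition`s (or named label vectors) over the same node
#'   set.
#' @param normalization `"arithmetic"` (default), `"max"` or `"sqrt"`.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(p1, p2, normalization = c("arithmetic", "max", "sqrt")) {
  normalization <- match.arg(normalization)
  ids <- names(p1)
  if (!setequal(ids, names(p2)) || length(p1) != length(p2)) {
    stop("partitions must cover the same node set")
  }
  a <- factor(unclass(p1)[ids])
  b <- factor(unclass(p2)[ids])
  tab <- table(a, b)
  n <- sum(tab)
  pj <- tab / n
  pa <- rowSums(pj)
  pb <- colSums(pj)
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  ha <- h(pa); hb <- h(pb)
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz]))
  if (ha == 0 && hb == 0) return(1)
  denom <- switch(normalization,
    arithmetic = (ha + hb) / 2,
    max = max(ha, hb),
    sqrt = sqrt(ha * hb))
  if (denom == 0) return(0)
  max(0, mi / denom)
}

#' Angular localization of a node subset (permutation test)
#'
#' The observed statistic is the mean angular separation over all
#' within-subset pairs; the null distribution is the same statistic for
#' uniformly random equally sized subsets drawn without replacement from
#' all map nodes (subset members included). The p-value is the plain
#' fraction of null samples with mean separation less than or equal to the
#' observed one.
#'
#' @param map a [hyperbolic_map].
#' @param cluster character vector of node ids, length >= 2.
#' @param n_samples number of null subsets (default 10000).
#' @param seed integer seed.
#' @param cluster_name label carried into the report.
#' @return a `localization_report` list: `cluster_name`, `n_nodes`,
#'   `mean_sep_observed`, `mean_sep_null`, `ratio` (observed / null),
#'   `p_value`, `n_samples`.
#' @export
angular_localization <- function(map, cluster, n_samples = 10000L, seed = 1L,
                                 cluster_name = "cluster") {
  m <- length(cluster)
  if (m < 2L) stop("cluster must contain at least 2 nodes")
  idx <- match(cluster, map$node_ids)
  if (anyNA(idx)) {
    stop("cluster node(s) missing from map: ",
         paste(utils::head(cluster[is.na(idx)], 5L), collapse = ", "))
  }
  n <- length(map$node_ids)
  mean_sep <- function(th) {
    d <- abs(outer(th, th, "-")) %% (2 * pi)
    d <- pi - abs(pi - d)
    sum(d[upper.tri(d)]) / (length(th) * (length(th) - 1) / 2)
  }
  obs <- mean_sep(map$theta[idx])
  rng <- local_rng(seed)
  null <- rng(vapply(seq_len(n_samples), function(s) {
    mean_sep(map$theta[sample.int(n, m)])
  }, numeric(1)))
  structure(
    list(cluster_name = cluster_name, n_nodes = m,
         mean_sep_observed = obs, mean_sep_null = mean(null),
         ratio = obs / mean(null),
         p_value = sum(null <= obs) / n_samples,
         n_samples = as.integer(n_samples)),
    class = "localization_report")
}

#' @export
print.localization_report <- function(x, ...) {
  cat("<localization_report> '", x$cluster_name, "' (", x$n_nodes,
      " nodes): <dtheta>obs = ", signif(x$mean_sep_observed, 4),
      ", <dtheta>rand = ", signif(x$mean_sep_null, 4),
      ", ratio = ", signif(x$ratio, 4), ", P = ", x$p_value,
      " (", x$n_samples, " samples)\n", sep = "")
  invisible(x)
}

#' Serialize a localization report to JSON
#' @param report a `localization_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_localization_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Angular span of a node subset
#'
#' The smallest arc containing all the subset's angles (2*pi minus the
#' largest gap among the sorted angles, wraparound included), expressed as
#' a fraction of the full circle.
#'
#' @param map a [hyperbolic_map].
#' @param cluster character vector of node ids, length >= 1.
#' @return fraction of the circle in `[0, 1]`.
#' @export
region_angular_span <- function(map, cluster) {
  if (length(cluster) == 0L) stop("empty cluster")
  idx <- match(cluster, map$node_ids)
  if (anyNA(idx)) stop("cluster node(s) missing from map")
  th <- sort(map$theta[idx])
  if (length(th) == 1L) return(0)
  gaps <- c(diff(th), th[1L] + 2 * pi - th[length(th)])
  span <- 2 * pi - max(gaps)
  span / (2 * pi)
}

#' Normalized angular separation of two nodes
#'
#' Minimal angular separation divided by pi, so it lies in `[0, 1]`.
#' @param theta1,theta2 angles in radians.
#' @return normalized separation(s).
#' @export
normalized_angular_separation <- function(theta1, theta2) {
  angular_separation(theta1, theta2) / pi
}

#' Empirical connection probability versus distance
#'
#' All unordered node pairs are binned by metric distance into `n_bins`
#' equal-width bins over the observed range; the fraction of connected
#' pairs is reported per bin. Empty bins get count 0 and fraction `NaN`.
#'
#' @param x a `connectome` (N >= 2).
#' @param metric pairwise distance matrix (node ids as dimnames).
#' @param n_bins number of bins (>= 1).
#' @return data.frame with columns `bin_center`, `fraction_connected`,
#'   `pair_count`.
#' @export
empirical_connection_probability <- function(x, metric, n_bins = 20L) {
  n <- length(x$nodes)
  if (n < 2L) stop("need at least 2 nodes")
  if (n_bins < 1L) stop("n_bins must be >= 1")
  metric <- check_metric(metric, x$nodes)
  a <- adjacency_matrix(x)
  ut <- upper.tri(metric)
  d <- metric[ut]
  conn <- a[ut]
  rng <- range(d)
  if (rng[1L] == rng[2L]) {
    breaks <- c(rng[1L] - 0.5, rng[1L] + 0.5)
    n_bins <- 1L
  } else {
    breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  }
  bin <- findInterval(d, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  hits <- vapply(seq_len(n_bins), function(b) sum(conn[bin == b]), numeric(1))
  data.frame(
    bin_center = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2,
    fraction_connected = ifelse(cnt > 0, hits / cnt, NaN),
    pair_count = cnt)
}

#' Partition from an annotation column
#'
#' @param x a `connectome` with annotations.
#' @param label_set name of the annotation column.
#' @return a `partition`.
#' @export
annotation_partition <- function(x, label_set) {
  if (is.null(x$annotations) || !(label_set %in% names(x$annotations))) {
    stop("annotation column not found: ", label_set)
  }
  partition(stats::setNames(as.character(x$annotations[[label_set]]),
                            x$nodes))
}
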