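#' Construct a connectome object
#'
#' A connectome is an undirected, unweighted graph over string node ids,
#' optionally carrying a directed edge set, 3D Euclidean node positions and
#' categorical node annotations (e.g. anatomical region, hemisphere).
#'
#' @param nodes character vector of unique node identifiers.
#' @param edges two-column character matrix (or data.frame) of undirected
#'   edges. Self-loops are dropped with a warning; duplicates are collapsed.
#' @param directed_edges optional two-column character matrix of ordered
#'   edges. When supplied, the undirected edge set must equal its
#'   symmetrized projection (it is recomputed if `edges` is `NULL`).
#' @param positions optional numeric matrix with one row per node (rownames
#'   are node ids) and 3 columns (x, y, z). Must cover every node.
#' @param annotations optional data.frame of categorical labels, rownames
#'   are node ids, one column per label set.
#' @return An object of class `connectome` with elements `nodes`, `edges`,
#'   `directed_edges`, `positions`, `annotations`.
#' @export
connectome <- function(nodes, edges, directed_edges = NULL, positions = NULL,
                       annotations = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids")
  if (length(nodes) == 0L) stop("a connectome needs at least one node")

  symmetrizing <- FALSE
  if (!is.null(directed_edges)) {
    directed_edges <- canonical_edges(directed_edges, nodes, directed = TRUE)
    if (is.null(edges)) {
      edges <- directed_edges
      symmetrizing <- TRUE # reciprocal pairs collapse silently
    }
  }
  edges <- if (symmetrizing) {
    suppressWarnings(canonical_edges(edges, nodes, directed = FALSE))
  } else {
    canonical_edges(edges, nodes, directed = FALSE)
  }

  if (!is.null(directed_edges)) {
    sym <- suppressWarnings(
      canonical_edges(directed_edges, nodes, directed = FALSE))
    if (!identical(edge_keys(sym, nodes), edge_keys(edges, nodes))) {
      stop("undirected edges must equal the symmetrized directed edge set")
    }
  }

  obj <- structure(
    list(nodes = nodes, edges = edges, directed_edges = directed_edges,
         positions = NULL, annotations = NULL),
    class = "connectome")
  if (!is.null(positions)) obj <- set_positions(obj, positions)
  if (!is.null(annotations)) obj <- set_annotations(obj, annotations)
  obj
}

# Canonicalize an edge table: character matrix, self-loops dropped (warning),
# duplicates collapsed (warning), endpoints validated, undirected edges
# stored with the lexicographically smaller id first, rows sorted.
canonical_edges <- function(edges, nodes, directed = FALSE) {
  if (is.null(edges) || NROW(edges) == 0L) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns")
  storage.mode(edges) <- "character"
  unknown <- setdiff(c(edges), nodes)
  if (length(unknown) > 0L) {
    stop("edge endpoint(s) not declared as nodes: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  if (!directed) {
    flip <- match(edges[, 1L], nodes) > match(edges[, 2L], nodes)
    edges[flip, ] <- edges[flip, c(2L, 1L)]
  }
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) collapsed")
    edges <- edges[!dup, , drop = FALSE]
  }
  edges <- edges[order(match(edges[, 1L], nodes), match(edges[, 2L], nodes)),
                 , drop = FALSE]
  dimnames(edges) <- list(NULL, c("from", "to"))
  edges
}

edge_keys <- function(edges, nodes) {
  sort(paste(match(edges[, 1L], nodes), match(edges[, 2L], nodes)))
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " undirected edges", sep = "")
  if (!is.null(x$directed_edges)) {
    cat(", ", nrow(x$directed_edges), " directed edges", sep = "")
  }
  if (!is.null(x$positions)) cat(", 3D positions")
  if (!is.null(x$annotations)) {
    cat(", annotations: ", paste(names(x$annotations), collapse = ", "),
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Number of nodes / edges
#' @param x a `connectome`.
#' @return integer count.
#' @export
n_nodes <- function(x) length(x$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(x) nrow(x$edges)

#' Attach 3D positions to a connectome
#'
#' @param x a `connectome`.
#' @param positions numeric matrix, rownames are node ids, 3 columns.
#'   Rows for unknown nodes are skipped with a warning; a node of the
#'   graph without a position is an error (all-or-none).
#' @return the connectome with `$positions` set (rows in node order).
#' @export
set_positions <- function(x, positions) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must have 3 columns (x, y, z)")
  storage.mode(positions) <- "double"
  ids <- rownames(positions)
  if (is.null(ids)) stop("positions must have node ids as rownames")
  extra <- setdiff(ids, x$nodes)
  if (length(extra) > 0L) {
    warning(length(extra), " position row(s) for unknown node(s) skipped: ",
            paste(utils::head(extra, 5L), collapse = ", "))
    positions <- positions[!(ids %in% extra), , drop = FALSE]
    ids <- rownames(positions)
  }
  missing <- setdiff(x$nodes, ids)
  if (length(missing) > 0L) {
    stop("no position for node(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  if (!all(is.finite(positions))) stop("positions must be finite")
  x$positions <- positions[x$nodes, , drop = FALSE]
  colnames(x$positions) <- c("x", "y", "z")
  x
}

set_annotations <- function(x, annotations) {
  annotations <- as.data.frame(annotations)
  ids <- rownames(annotations)
  extra <- setdiff(ids, x$nodes)
  if (length(extra) > 0L) {
    warning(length(extra), " annotation row(s) for unknown node(s) skipped")
    annotations <- annotations[!(ids %in% extra), , drop = FALSE]
  }
  missing <- setdiff(x$nodes, rownames(annotations))
  if (length(missing) > 0L) {
    stop("no annotation for node(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  x$annotations <- annotations[x$nodes, , drop = FALSE]
  x
}

#' Read a two-column edge list
#'
#' One edge per line, two whitespace-separated tokens; lines starting with
#' `#` are ignored. Duplicate lines are collapsed and self-loops dropped,
#' each with a warning. Node ids are taken in order of first appearance.
#'
#' @param path path to the edge-list file.
#' @param directed if `TRUE`, the file is read as ordered edges and both the
#'   directed and the symmetrized undirected edge sets are populated.
#' @return a `connectome`.
#' @export
read_edge_list <- function(path, directed = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad) > 0L) {
    stop("malformed edge line ", lineno[bad[1L]], ": '", lines[bad[1L]], "'")
  }
  m <- do.call(rbind, toks)
  nodes <- unique(c(t(m)))
  if (directed) {
    connectome(nodes, edges = NULL, directed_edges = m)
  } else {
    connectome(nodes, edges = m)
  }
}

#' Write an edge list
#' @param x a `connectome`.
#' @param path output path.
#' @param directed write the directed edge set instead of the undirected one.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path, directed = FALSE) {
  edges <- if (directed) x$directed_edges else x$edges
  if (is.null(edges)) stop("no directed edges to write")
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read node positions (id, x, y, z) and attach them to a connectome
#'
#' @param path four-column TSV (no header): node id, x, y, z.
#' @param x the `connectome` to attach to.
#' @return the connectome with positions attached.
#' @export
read_positions <- function(path, x) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = c("character", rep("numeric", 3)))
  if (ncol(tab) != 4L) stop("positions file must have 4 columns")
  pos <- as.matrix(tab[, 2:4])
  rownames(pos) <- tab[[1L]]
  set_positions(x, pos)
}

#' @rdname read_positions
#' @param ... passed through.
#' @export
write_positions <- function(x, path, ...) {
  if (is.null(x$positions)) stop("no positions attached")
  # %.17g survives a write/read round trip bit-exactly
  fmt <- function(v) sprintf("%.17g", v)
  utils::write.table(
    data.frame(id = x$nodes, fmt(x$positions[, 1L]), fmt(x$positions[, 2L]),
               fmt(x$positions[, 3L])),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read categorical node annotations
#'
#' TSV with a header row: first column `id`, then one column per label set.
#'
#' @param path annotation TSV.
#' @param x the `connectome` to attach to.
#' @return the connectome with `$annotations` set.
#' @export
read_annotations <- function(path, x) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  rownames(tab) <- tab[[1L]]
  set_annotations(x, tab[, -1L, drop = FALSE])
}

#' Connected components of a connectome
#'
#' @param x a `connectome`.
#' @return list of character vectors (node sets), a partition of the node
#'   set, sorted by decreasing size then by lexicographically smallest
#'   member; members of each component are sorted lexicographically.
#' @export
connected_components <- function(x) {
  g <- as_igraph(x)
  memb <- igraph::components(g)$membership
  comps <- split(x$nodes, memb[x$nodes])
  comps <- lapply(comps, function(v) v[order_c(v)])
  firsts <- vapply(comps, `[`, character(1), 1L)
  comps <- comps[order(-lengths(comps), rank_c(firsts))]
  names(comps) <- NULL
  comps
}

# Locale-independent (C collation) lexicographic helpers; node-id ordering
# must be reproducible across platforms.
order_c <- function(v) order(v, method = "radix")
rank_c <- function(v) {
  r <- integer(length(v))
  r[order(v, method = "radix")] <- seq_along(v)
  r
}

#' Convert a connectome to an igraph graph
#' @param x a `connectome`.
#' @param directed use the directed edge set.
#' @return an `igraph` graph whose vertex names are the node ids.
#' @export
as_igraph <- function(x, directed = FALSE) {
  if (directed && is.null(x$directed_edges)) stop("no directed edges")
  edges <- if (directed) x$directed_edges else x$edges
  igraph::graph_from_data_frame(
    as.data.frame(edges),
    directed = directed,
    vertices = data.frame(name = x$nodes))
}

# 0-based adjacency list in node order (out-neighbors when directed),
# for the C++ routing core.
adjacency_index <- function(x, directed = FALSE) {
  n <- length(x$nodes)
  edges <- if (directed) x$directed_edges else x$edges
  if (directed && is.null(edges)) stop("no directed edges")
  i <- match(edges[, 1L], x$nodes)
  j <- match(edges[, 2L], x$nodes)
  if (directed) {
    from <- i; to <- j
  } else {
    from <- c(i, j); to <- c(j, i)
  }
  adj <- split(to - 1L, factor(from, levels = seq_len(n)))
  lapply(unname(adj), as.integer)
}

# Dense logical adjacency matrix (undirected).
adjacency_matrix <- function(x) {
  n <- length(x$nodes)
  a <- matrix(FALSE, n, n, dimnames = list(x$nodes, x$nodes))
  i <- match(x$edges[, 1L], x$nodes)
  j <- match(x$edges[, 2L], x$nodes)
  a[cbind(i, j)] <- TRUE
  a[cbind(j, i)] <- TRUE
  a
}

#' Degree sequence in node order
#' @param x a `connectome`.
#' @return named integer vector of undirected degrees.
#' @export
degrees <- function(x) {
  d <- integer(length(x$nodes))
  names(d) <- x$nodes
  tab <- table(c(x$edges[, 1L], x$edges[, 2L]))
  d[names(tab)] <- as.integer(tab)
  d
}
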