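#' Pipeline configuration
#'
#' Declarative description of a full study: where the network comes from
#' (a `connectome`, an edge-list path, or a generator config), which stages
#' to run, which null models with how many replicates, one master seed and
#' an output directory.
#'
#' @param input a `connectome`, a path to an edge-list file, an
#'   [s1_config] or a [euclidean_config].
#' @param stages ordered subset of `"euclidean_routing"`, `"embed"`,
#'   `"hyperbolic_routing"`, `"null_models"`, `"cartography"`.
#' @param null_model_list subset of `"position_swap"`, `"rewire"`,
#'   `"cost_rewire"`.
#' @param replicates_per_null randomizations per null model (default 10).
#' @param seed master seed; every stage derives its own stream from it.
#' @param output_dir where artifacts are written; `NULL` for none.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input,
                            stages = c("euclidean_routing", "embed",
                                       "hyperbolic_routing", "null_models",
                                       "cartography"),
                            null_model_list = c("position_swap", "rewire",
                                                "cost_rewire"),
                            replicates_per_null = 10L, seed = 1L,
                            output_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  null_model_list <- match.arg(null_model_list, several.ok = TRUE)
  structure(list(input = input, stages = stages,
                 null_model_list = null_model_list,
                 replicates_per_null = as.integer(replicates_per_null),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

resolve_input <- function(input) {
  if (inherits(input, "connectome")) return(list(connectome = input))
  if (inherits(input, "s1_config")) {
    gen <- generate_s1_network(input)
    return(list(connectome = gen$connectome, truth = gen$truth))
  }
  if (inherits(input, "euclidean_config")) {
    return(list(connectome = generate_euclidean_connectome(input)))
  }
  if (is.character(input) && length(input) == 1L) {
    return(list(connectome = read_edge_list(input)))
  }
  stop("unsupported pipeline input")
}

nav_summary <- function(rep) {
  list(success_rate = rep$success_rate, pair_count = rep$pair_count,
       topological_stretch = rep$topological_stretch[c("mean", "p10", "p90")],
       geometric_stretch = rep$geometric_stretch[c("mean", "p10", "p90")])
}

# Mean +/- sd of greedy-routing success rate over null replicates.
null_sweep <- function(x, metric, map, model, replicates, seed,
                       epsilon = 1 / 60) {
  srs <- vapply(seq_len(replicates), function(k) {
    sk <- (seed + 1000L * k) %% .Machine$integer.max
    if (model == "position_swap") {
      if (!is.null(map)) {
        m2 <- shuffle_positions(map, seed = sk)
        navigability(x, hyperbolic_metric(m2))$success_rate
      } else {
        x2 <- shuffle_positions(x, seed = sk)
        navigability(x2, euclidean_metric(x2))$success_rate
      }
    } else if (model == "rewire") {
      x2 <- rewire_degree_preserving(x, rewire_config(seed = sk))
      navigability(x2, metric)$success_rate
    } else { # cost_rewire
      x2 <- rewire_cost_preserving(x, metric,
                                   rewire_config(epsilon = epsilon, seed = sk))
      navigability(x2, metric)$success_rate
    }
  }, numeric(1))
  list(model = model, replicates = replicates, mean_sr = mean(srs),
       sd_sr = stats::sd(srs), values = srs)
}

#' Run the full navigability study
#'
#' Executes the requested stages in order: greedy routing in the Euclidean
#' (anatomical) embedding, maximum-likelihood hyperbolic embedding, greedy
#' routing in the inferred hyperbolic map, null-model baselines (reported
#' as mean +/- sd of the success rate over replicates), and geometric
#' cartography. Fully reproducible from (config, seed); artifacts are
#' written under `output_dir` when set.
#'
#' @param config a [pipeline_config].
#' @return a `study_report` list with one entry per executed stage plus
#'   provenance (seed, package version, stage list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- resolve_input(config$input)
  x <- inp$connectome
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  report <- list(
    provenance = list(seed = config$seed, stages = config$stages,
                      n_nodes = length(x$nodes), n_edges = nrow(x$edges),
                      package_version = as.character(utils::packageVersion("navmaps"))))
  map <- NULL
  emb_x <- NULL
  message("[pipeline] input: ", length(x$nodes), " nodes, ",
          nrow(x$edges), " edges (seed ", config$seed, ")")

  for (stage in config$stages) {
    if (stage == "euclidean_routing") {
      if (is.null(x$positions)) {
        stop("stage 'euclidean_routing' requires node positions")
      }
      rep_e <- navigability(x, euclidean_metric(x))
      report$euclidean_routing <- nav_summary(rep_e)
      message("[pipeline] euclidean routing: SR = ",
              signif(rep_e$success_rate, 4))
    } else if (stage == "embed") {
      comps <- connected_components(x)
      emb_x <- x
      if (length(comps) > 1L) {
        message("[pipeline] embedding the largest component (",
                length(comps[[1L]]), " of ", length(x$nodes), " nodes)")
        emb_x <- induced_connectome(x, comps[[1L]])
      }
      map <- embed_h2(emb_x, embedding_config(seed = config$seed))
      report$embedding <- list(beta = attr(map, "beta"),
                               mu = attr(map, "mu"),
                               loglik = attr(map, "loglik"),
                               loglik0 = attr(map, "loglik0"),
                               n_embedded = length(map$node_ids))
      if (!is.null(out_dir)) {
        write_hyperbolic_map(map, file.path(out_dir, "hyperbolic_map.tsv"))
      }
      message("[pipeline] embedded: logL ", signif(attr(map, "loglik"), 6),
              " (beta = ", signif(attr(map, "beta"), 3), ")")
    } else if (stage == "hyperbolic_routing") {
      if (is.null(map)) {
        stop("stage 'hyperbolic_routing' requires stage 'embed' first")
      }
      rep_h <- navigability(emb_x, hyperbolic_metric(map))
      report$hyperbolic_routing <- nav_summary(rep_h)
      message("[pipeline] hyperbolic routing: SR = ",
              signif(rep_h$success_rate, 4))
    } else if (stage == "null_models") {
      geom_x <- if (!is.null(map)) emb_x else x
      metric <- if (!is.null(map)) {
        hyperbolic_metric(map)
      } else if (!is.null(x$positions)) {
        euclidean_metric(x)
      } else {
        stop("stage 'null_models' requires positions or stage 'embed' first")
      }
      report$null_models <- lapply(config$null_model_list, function(m) {
        res <- null_sweep(geom_x, metric, map, m,
                          config$replicates_per_null, config$seed)
        message("[pipeline] null '", m, "': mean SR = ",
                signif(res$mean_sr, 4), " +/- ", signif(res$sd_sr, 3))
        res
      })
      names(report$null_models) <- config$null_model_list
    } else if (stage == "cartography") {
      if (is.null(map)) {
        stop("stage 'cartography' requires stage 'embed' first")
      }
      comm <- critical_gap_communities(map)
      carto <- list(n_communities = length(unique(unclass(comm))))
      if (!is.null(emb_x$annotations)) {
        carto$nmi <- lapply(names(emb_x$annotations), function(ls) {
          nmi(comm, annotation_partition(emb_x, ls))
        })
        names(carto$nmi) <- names(emb_x$annotations)
      }
      report$cartography <- carto
      message("[pipeline] cartography: ", carto$n_communities,
              " angular communities")
    }
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "study_report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
  }
  structure(report, class = "study_report")
}

#' Subgraph induced by a node subset
#'
#' @param x a `connectome`.
#' @param nodes character vector of node ids to keep.
#' @return the induced `connectome` (positions/annotations subset too).
#' @export
induced_connectome <- function(x, nodes) {
  keep <- x$nodes[x$nodes %in% nodes]
  e <- x$edges[x$edges[, 1L] %in% keep & x$edges[, 2L] %in% keep, ,
               drop = FALSE]
  out <- connectome(keep, e)
  if (!is.null(x$positions)) {
    out <- set_positions(out, x$positions[keep, , drop = FALSE])
  }
  if (!is.null(x$annotations)) {
    out <- set_annotations(out, x$annotations[keep, , drop = FALSE])
  }
  out
}
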