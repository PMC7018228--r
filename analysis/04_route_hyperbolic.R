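#!/usr/bin/env Rscript
# Stage 4: greedy routing on the inferred hyperbolic map.
#
# The central contrast of the study: navigability under the inferred
# effective geometry approaches 1 even where the anatomical embedding
# routes poorly.

suppressPackageStartupMessages(library(navmaps))
p <- function(...) file.path("results", "data", ...)

x <- read_edge_list(p("s1_uniform.edges.tsv"))
x <- induced_connectome(x, connected_components(x)[[1L]])
map <- read_hyperbolic_map(file.path("results", "embedding",
                                     "s1_uniform.map.tsv"))
nav <- navigability(x, hyperbolic_metric(map))
cat(sprintf("hyperbolic routing: SR = %.3f over %d pairs\n",
            nav$success_rate, nav$pair_count))
cat(sprintf("  stretch: topological %.3f [%.2f, %.2f], geometric %.3f [%.2f, %.2f] (10/90 pct)\n",
            nav$topological_stretch$mean, nav$topological_stretch$p10,
            nav$topological_stretch$p90, nav$geometric_stretch$mean,
            nav$geometric_stretch$p10, nav$geometric_stretch$p90))
write_navigability_report(
  nav, file.path("results", "routing", "s1_uniform.hyperbolic.json"))

eu <- jsonlite::read_json(file.path("results", "routing",
                                    "spatial_cut.euclidean.json"))
cat(sprintf("contrast: hyperbolic SR %.3f vs Euclidean SR %.3f (long-range-suppressed spatial net)\n",
            nav$success_rate, eu$success_rate))
cat("wrote results/routing/s1_uniform.hyperbolic.json\n")
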