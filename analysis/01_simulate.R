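#!/usr/bin/env Rscript
# Stage 1: simulate the study's synthetic connectomes.
#
# Four networks are produced under results/data/:
#   s1_uniform   - S1-model network, N = 300, uniform angles (the embedding
#                  and hyperbolic-routing testbed; ground truth saved)
#   s1_planted   - S1-model network, N = 200, two planted angular arcs
#                  (the cartography testbed)
#   spatial_full - 3D spatial network, distance-decaying connectivity
#   spatial_cut  - same generator with links > 30 length units removed,
#                  mimicking partial-volume, neuron-level datasets

suppressPackageStartupMessages(library(navmaps))
seed <- 1L
dir.create(file.path("results", "data"), recursive = TRUE,
           showWarnings = FALSE)
p <- function(...) file.path("results", "data", ...)

s1 <- generate_s1_network(
  s1_config(N = 300, gamma = 2.7, beta = 3, mean_degree = 10, seed = seed))
write_edge_list(s1$connectome, p("s1_uniform.edges.tsv"))
write_s1_truth(s1$truth, p("s1_uniform.truth.json"))
cat(sprintf("s1_uniform:   N = %d, L = %d, <k> = %.2f\n",
            n_nodes(s1$connectome), n_edges(s1$connectome),
            mean(degrees(s1$connectome))))

planted <- generate_s1_network(
  s1_config(N = 200, gamma = 2.7, beta = 3, mean_degree = 10,
            seed = seed + 11L,
            planted_clusters = list(
              list(center = 0, width = 0.3, n = 100),
              list(center = pi, width = 0.3, n = 100))))
write_edge_list(planted$connectome, p("s1_planted.edges.tsv"))
write_s1_truth(planted$truth, p("s1_planted.truth.json"))
# planted arc memberships double as categorical annotations
ann <- data.frame(id = planted$truth$node_ids,
                  arc = rep(c("arcA", "arcB"), each = 100L))
utils::write.table(ann, p("s1_planted.annotations.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("s1_planted:   N = %d, L = %d, two arcs of 100 nodes\n",
            n_nodes(planted$connectome), n_edges(planted$connectome)))

for (cut in c(FALSE, TRUE)) {
  cfg <- euclidean_config(N = 300, box = 100, decay_scale = 10, beta_e = 3,
                          max_link_length = if (cut) 30 else NULL,
                          seed = seed + 7L)
  sp <- generate_euclidean_connectome(cfg)
  stem <- if (cut) "spatial_cut" else "spatial_full"
  write_edge_list(sp, p(paste0(stem, ".edges.tsv")))
  write_positions(sp, p(paste0(stem, ".positions.tsv")))
  cat(sprintf("%s: N = %d, L = %d, <k> = %.2f\n", format(stem, width = 12),
              n_nodes(sp), n_edges(sp), mean(degrees(sp))))
}
cat("wrote results/data/\n")
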