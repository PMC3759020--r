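#!/usr/bin/env Rscript
# Stage 2 — from raw responses to word-matched semantic networks.
#
# Binary incidence matrices per group, the word-matched (>= 2 subjects in
# each group) vocabulary, phi correlations between word response profiles,
# and the binarized PMFG per group. Writes matrices, correlation tables,
# GraphML networks and edge lists.

suppressPackageStartupMessages(library(fluencynet))
out_dir <- "results"

datasets <- read_fluency(file.path(out_dir, "responses.csv"))
mats <- lapply(datasets, build_response_matrix)
vocab <- select_wmcn_vocabulary(mats[[1]], mats[[2]], min_subjects = 2)
message(sprintf("word-matched vocabulary: %d words common to both groups", length(vocab)))

mats <- lapply(mats, restrict_vocabulary, vocab = vocab)
cors <- lapply(mats, word_correlations)
keep <- intersect(cors[[1]]$vocabulary, cors[[2]]$vocabulary)
cors <- lapply(cors, restrict_correlations, vocab = keep)

for (gl in names(datasets)) {
  write_response_matrix(mats[[gl]], file.path(out_dir, sprintf("response_matrix_%s.csv", gl)))
  write_correlation_matrix(cors[[gl]], file.path(out_dir, sprintf("correlations_%s.csv", gl)))
  g <- build_pmfg(cors[[gl]], network_kind = "WMCN", group = gl)
  write_graphml(g, file.path(out_dir, sprintf("network_%s.graphml", gl)))
  write_edge_list(g, file.path(out_dir, sprintf("edges_%s.csv", gl)))
  message(sprintf("group %s: PMFG with %d nodes, %d edges (mean degree %.2f)",
                  gl, igraph::vcount(g), igraph::ecount(g), mean_degree(g)))
}
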