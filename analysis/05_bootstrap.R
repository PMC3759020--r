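#!/usr/bin/env Rscript
# Stage 5 — bootstrapped partial-network comparison of the two groups.
#
# Repeatedly draws a shared random word subset (the study ratio, 40 of 75,
# scaled to the current vocabulary), rebuilds each group's partial PMFG
# from its correlation submatrix, and compares the resulting L, D and CC
# distributions with pooled t-tests. Note: the t-test treats bootstrap
# replicates as independent observations, which is anticonservative; the
# p-values are reported as-is for comparability.

suppressPackageStartupMessages(library(fluencynet))
out_dir <- "results"
seed <- 1L
realizations <- 2000L

files <- sort(list.files(out_dir, pattern = "^correlations_.*\\.csv$", full.names = TRUE))
groups <- sub("^correlations_(.*)\\.csv$", "\\1", basename(files))
cors <- Map(read_correlation_matrix, files, groups)
names(cors) <- groups

V <- length(cors[[1]]$vocabulary)
subset_size <- max(4L, floor(V * 8 / 15))
boot <- bootstrap_partial(cors[[1]], cors[[2]], subset_size = subset_size,
                          realizations = realizations, seed = seed)
print(boot)
write_distributions(boot, file.path(out_dir, "bootstrap_values.csv"))
summary <- lapply(c(L = "L", D = "D", CC = "CC"), function(m) {
  list(a = list(group = groups[1], mean = boot$a[[m]]$mean, sd = boot$a[[m]]$sd),
       b = list(group = groups[2], mean = boot$b[[m]]$mean, sd = boot$b[[m]]$sd),
       t = boot$tests[[m]]$t, df = boot$tests[[m]]$df, p = boot$tests[[m]]$p)
})
jsonlite::write_json(summary, file.path(out_dir, "bootstrap.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote ", file.path(out_dir, "bootstrap.json"))
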