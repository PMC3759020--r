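#' Configuration for a full pipeline run
#'
#' @param profiles named list of two [group_profile()]s used to simulate
#'   input data; ignored when `input` is given.
#' @param input optional path to a long-format response file (CSV/JSON)
#'   containing exactly two groups; overrides `profiles`.
#' @param network_kind `"WMCN"` (word-matched, default) or `"SMCN"`.
#' @param min_subjects per-group production threshold for the word-matched
#'   vocabulary.
#' @param er_realizations Erdos-Renyi null draws.
#' @param bootstrap_size,bootstrap_realizations partial-network bootstrap
#'   settings.
#' @param reference,reference_realizations ER reference mode for
#'   [summarize_network()].
#' @param disconnection policy for disconnected ER draws.
#' @param seed master seed; all stage seeds are derived from it.
#' @param out_dir output directory (created if absent).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(profiles = default_profiles(),
                            input = NULL,
                            network_kind = c("WMCN", "SMCN"),
                            min_subjects = 2L,
                            er_realizations = 10000L,
                            bootstrap_size = 40L,
                            bootstrap_realizations = 10000L,
                            reference = c("mean", "single"),
                            reference_realizations = 100L,
                            disconnection = c("largest_component", "resample"),
                            seed = 1L,
                            out_dir = "results") {
  structure(list(profiles = profiles, input = input,
                 network_kind = match.arg(network_kind),
                 min_subjects = as.integer(min_subjects),
                 er_realizations = as.integer(er_realizations),
                 bootstrap_size = as.integer(bootstrap_size),
                 bootstrap_realizations = as.integer(bootstrap_realizations),
                 reference = match.arg(reference),
                 reference_realizations = as.integer(reference_realizations),
                 disconnection = match.arg(disconnection),
                 seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full fluency-network pipeline and write a result bundle
#'
#' Stages: (1) simulate (or load) the two groups' responses; (2) build
#' response matrices and, for a word-matched run, the common vocabulary;
#' (3) word correlations; (4) PMFG networks; (5) small-world metrics per
#' group; (6) Erdos-Renyi null distributions with empirical p-values of the
#' observed L, D, CC; (7) bootstrapped partial-network comparison; (8)
#' leave-one-out impact scores and their group comparison. Each stage's
#' table is written under `cfg$out_dir`; a manifest records the seed,
#' configuration and package version. All randomness derives from
#' `cfg$seed`, so a rerun with the same configuration reproduces the bundle
#' exactly.
#'
#' For an SMCN run (whole-group vocabularies, generally different between
#' groups) the bootstrap and impact comparisons are skipped: they require a
#' shared vocabulary.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly) list with all in-memory stage results and `paths` to
#'   the written artifacts.
#' @export
run_pipeline <- function(cfg = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(cfg$seed, 6L)
  paths <- list()
  t0 <- Sys.time()

  # stage 1: data
  if (!is.null(cfg$input)) {
    say("[input] reading %s", cfg$input)
    datasets <- read_fluency(cfg$input)
    if (length(datasets) != 2L) stop_fl("pipeline expects exactly two groups", "input_error")
  } else {
    say("[simulate] generating two synthetic groups (seed %d)", cfg$seed)
    datasets <- generate_pair(cfg$profiles[[1L]], cfg$profiles[[2L]],
                              seed = seeds[[1L]])
  }
  labels <- names(datasets)

  # stage 2: matrices + vocabulary selection
  mats <- lapply(datasets, build_response_matrix)
  if (cfg$network_kind == "WMCN") {
    vocab <- select_wmcn_vocabulary(mats[[1L]], mats[[2L]],
                                    min_subjects = cfg$min_subjects)
    say("[vocabulary] %d common words (>= %d subjects per group)",
        length(vocab), cfg$min_subjects)
    mats <- lapply(mats, restrict_vocabulary, vocab = vocab)
  }
  for (gl in labels) {
    paths[[paste0("response_matrix_", gl)]] <-
      write_response_matrix(mats[[gl]], file.path(cfg$out_dir, sprintf("response_matrix_%s.csv", gl)))
  }

  # stage 3: correlations
  cors <- lapply(mats, word_correlations)
  if (cfg$network_kind == "WMCN" &&
      !identical(cors[[1L]]$vocabulary, cors[[2L]]$vocabulary)) {
    # zero-variance exclusions may differ between groups; keep the overlap
    keep <- intersect(cors[[1L]]$vocabulary, cors[[2L]]$vocabulary)
    cors <- lapply(cors, restrict_correlations, vocab = keep)
  }
  for (gl in labels) {
    paths[[paste0("correlations_", gl)]] <-
      write_correlation_matrix(cors[[gl]], file.path(cfg$out_dir, sprintf("correlations_%s.csv", gl)))
  }

  # stage 4: PMFG networks
  nets <- lapply(labels, function(gl) {
    build_pmfg(cors[[gl]], network_kind = cfg$network_kind, group = gl)
  })
  names(nets) <- labels
  for (gl in labels) {
    paths[[paste0("network_", gl)]] <-
      write_graphml(nets[[gl]], file.path(cfg$out_dir, sprintf("network_%s.graphml", gl)))
    paths[[paste0("edges_", gl)]] <-
      write_edge_list(nets[[gl]], file.path(cfg$out_dir, sprintf("edges_%s.csv", gl)))
  }
  say("[pmfg] %s", paste(sprintf("%s: %d nodes / %d edges", labels,
                                 vapply(nets, igraph::vcount, 1),
                                 vapply(nets, igraph::ecount, 1)), collapse = "; "))

  # stage 5: metrics
  metr_seeds <- derive_seeds(seeds[[2L]], length(labels))
  metrics <- lapply(seq_along(labels), function(i) {
    summarize_network(nets[[i]], reference = cfg$reference,
                      realizations = cfg$reference_realizations,
                      seed = metr_seeds[[i]], disconnection = cfg$disconnection)
  })
  names(metrics) <- labels
  paths$metrics <- write_metrics(metrics, file.path(cfg$out_dir, "metrics.csv"))

  # stage 6: ER null distributions + empirical significance
  er_seeds <- derive_seeds(seeds[[3L]], length(labels))
  er <- lapply(seq_along(labels), function(i) {
    g <- nets[[i]]
    null <- simulate_er(er_spec(igraph::vcount(g),
                                igraph::ecount(g) / choose(igraph::vcount(g), 2),
                                realizations = cfg$er_realizations,
                                seed = er_seeds[[i]]),
                        disconnection = cfg$disconnection)
    obs <- c(L = metrics[[i]]$L, D = metrics[[i]]$D, CC = metrics[[i]]$CC)
    ps <- vapply(c("L", "D", "CC"), function(m) {
      empirical_significance(obs[[m]], null[[m]], side = "two")
    }, numeric(1L))
    list(null = null, observed = obs, p = ps)
  })
  names(er) <- labels
  er_summary <- lapply(er, function(x) {
    list(observed = as.list(x$observed),
         null = lapply(c(L = "L", D = "D", CC = "CC"), function(m) {
           list(mean = x$null[[m]]$mean, sd = x$null[[m]]$sd)
         }),
         empirical_p = as.list(x$p),
         disconnected_fraction = x$null$disconnected_fraction)
  })
  paths$er_null <- file.path(cfg$out_dir, "er_null.json")
  jsonlite::write_json(er_summary, paths$er_null, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("[er-null] %d realizations per group; all empirical p in [%.2g, %.2g]",
      cfg$er_realizations, min(unlist(lapply(er, `[[`, "p"))),
      max(unlist(lapply(er, `[[`, "p"))))

  boot <- NULL
  impact <- NULL
  impact_test <- NULL
  if (cfg$network_kind == "WMCN") {
    # stage 7: bootstrapped partial networks; for vocabularies smaller than
    # the requested subset the study's 40-of-75 subset ratio is kept instead
    V <- length(cors[[1L]]$vocabulary)
    subset_size <- min(cfg$bootstrap_size, max(4L, floor(V * 8 / 15)))
    if (subset_size < cfg$bootstrap_size) {
      say("[bootstrap] vocabulary has %d words; subset size reduced to %d",
          V, subset_size)
    }
    boot <- bootstrap_partial(cors[[1L]], cors[[2L]],
                              subset_size = subset_size,
                              realizations = cfg$bootstrap_realizations,
                              seed = seeds[[4L]])
    paths$bootstrap_values <- write_distributions(
      boot, file.path(cfg$out_dir, "bootstrap_values.csv"))
    boot_summary <- lapply(c(L = "L", D = "D", CC = "CC"), function(m) {
      list(a = list(group = labels[1L], mean = boot$a[[m]]$mean, sd = boot$a[[m]]$sd),
           b = list(group = labels[2L], mean = boot$b[[m]]$mean, sd = boot$b[[m]]$sd),
           t = boot$tests[[m]]$t, df = boot$tests[[m]]$df, p = boot$tests[[m]]$p)
    })
    paths$bootstrap <- file.path(cfg$out_dir, "bootstrap.json")
    jsonlite::write_json(boot_summary, paths$bootstrap, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    say("[bootstrap] %d realizations of %d-word partial networks",
        boot$realizations, boot$subset_size)

    # stage 8: impact scores
    impact <- lapply(labels, function(gl) impact_scores(cors[[gl]], group = gl))
    names(impact) <- labels
    impact_test <- compare_impact(impact[[1L]], impact[[2L]])
    paths$impact <- write_impact(do.call(rbind, unname(lapply(impact, as.data.frame))),
                                 file.path(cfg$out_dir, "impact.csv"))
    paths$impact_test <- file.path(cfg$out_dir, "impact_test.json")
    jsonlite::write_json(impact_test, paths$impact_test, auto_unbox = TRUE, digits = NA)
    say("[impact] t(%d) = %.3f, p = %.3g", impact_test$df, impact_test$t, impact_test$p)
  }

  manifest <- list(
    package = "fluencynet",
    version = as.character(utils::packageVersion("fluencynet")),
    seed = cfg$seed,
    network_kind = cfg$network_kind,
    groups = labels,
    config = cfg[c("min_subjects", "er_realizations", "bootstrap_size",
                   "bootstrap_realizations", "reference",
                   "reference_realizations", "disconnection")],
    source_digest = vapply(nets, igraph::graph_attr, "", name = "source_digest"),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z")
  )
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  say("[done] %d artifacts in %s (%.1f s)", length(paths), cfg$out_dir,
      as.numeric(Sys.time() - t0, units = "secs"))

  invisible(list(datasets = datasets, matrices = mats, correlations = cors,
                 networks = nets, metrics = metrics, er = er, bootstrap = boot,
                 impact = impact, impact_test = impact_test, paths = paths,
                 config = cfg))
}
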