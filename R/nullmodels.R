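#' Specification of an Erdos-Renyi null ensemble
#'
#' @param n node count (>= 3).
#' @param p edge probability in (0, 1]. For a PMFG-matched null this is
#'   E / (N(N-1)/2) = 3(N-2) / choose(N, 2), fully determined by N.
#' @param realizations number of G(n, p) draws.
#' @param seed RNG seed (NULL uses the current stream).
#' @return object of class `er_spec`.
#' @export
er_spec <- function(n, p, realizations = 10000L, seed = NULL) {
  n <- as.integer(n)
  realizations <- as.integer(realizations)
  if (n < 3L) stop_fl("n must be at least 3", "size_error")
  if (!is.numeric(p) || p <= 0 || p > 1) stop_fl("p must be in (0, 1]", "input_error")
  if (realizations < 1L) stop_fl("realizations must be >= 1", "input_error")
  structure(list(n = n, p = p, realizations = realizations, seed = seed),
            class = "er_spec")
}

#' ER-matched probability of a PMFG
#'
#' Edge probability of the Erdos-Renyi reference matched to a PMFG on `n`
#' nodes: 3(n-2) edges over choose(n, 2) pairs.
#'
#' @param n node count.
#' @return the matched edge probability.
#' @export
pmfg_matched_p <- function(n) {
  if (n < 3L) stop_fl("n must be at least 3", "size_error")
  (3 * (n - 2)) / choose(n, 2)
}

#' Distribution of a network metric over null realizations
#'
#' @param metric metric name ("L", "D" or "CC").
#' @param values numeric vector, one value per realization.
#' @return object of class `metric_distribution` with fields `metric`,
#'   `values`, `mean`, `sd`.
#' @export
metric_distribution <- function(metric, values) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values))) {
    stop_fl("values must be a non-empty finite numeric vector", "input_error")
  }
  structure(list(metric = metric, values = values,
                 mean = mean(values), sd = stats::sd(values)),
            class = "metric_distribution")
}

#' @export
print.metric_distribution <- function(x, ...) {
  cat(sprintf("<metric_distribution> %s over %d realizations: %.4f (%.4f)\n",
              x$metric, length(x$values), x$mean,
              if (is.na(x$sd)) 0 else x$sd))
  invisible(x)
}

#' Simulate the Erdos-Renyi null distributions of L, D and CC
#'
#' Draws `realizations` independent G(n, p) graphs and records the average
#' shortest path length (L), diameter (D) and mean local clustering (CC) of
#' each. CC is always computed on the full draw. Path metrics on a
#' disconnected draw follow the `disconnection` policy:
#' `"largest_component"` (default) computes L and D on the largest connected
#' component; `"resample"` redraws the graph until connected. The fraction
#' of affected realizations is reported either way.
#'
#' @param spec an [er_spec()].
#' @param disconnection `"largest_component"` or `"resample"`.
#' @return object of class `er_null`: list with `L`, `D`, `CC`
#'   ([metric_distribution()] each), `disconnected_fraction`, `spec` and
#'   `disconnection`.
#' @export
simulate_er <- function(spec, disconnection = c("largest_component", "resample")) {
  stopifnot(inherits(spec, "er_spec"))
  disconnection <- match.arg(disconnection)
  reps <- spec$realizations
  L <- D <- CC <- numeric(reps)
  n_disc <- 0L
  with_seed(spec$seed, {
    for (r in seq_len(reps)) {
      g <- igraph::sample_gnp(spec$n, spec$p)
      if (!igraph::is_connected(g)) {
        n_disc <- n_disc + 1L
        if (disconnection == "resample") {
          repeat {
            g <- igraph::sample_gnp(spec$n, spec$p)
            if (igraph::is_connected(g)) break
          }
          gc_path <- g
        } else {
          gc_path <- largest_component(g)
        }
      } else {
        gc_path <- g
      }
      CC[r] <- clustering_coef(g)
      if (igraph::vcount(gc_path) < 2L) {
        # pathological draw (empty largest component): no path exists
        L[r] <- NA_real_
        D[r] <- NA_real_
      } else {
        L[r] <- igraph::mean_distance(gc_path, directed = FALSE, weights = NA)
        D[r] <- igraph::diameter(gc_path, directed = FALSE, unconnected = FALSE,
                                 weights = NA)
      }
    }
  })
  if (anyNA(L)) stop_fl("degenerate ER draw with no paths; increase p", "input_error")
  structure(list(L = metric_distribution("L", L),
                 D = metric_distribution("D", D),
                 CC = metric_distribution("CC", CC),
                 disconnected_fraction = n_disc / reps,
                 disconnection = disconnection,
                 spec = spec),
            class = "er_null")
}

#' @export
print.er_null <- function(x, ...) {
  cat(sprintf("<er_null> G(n=%d, p=%.4f), %d realizations (%.1f%% disconnected, policy %s)\n",
              x$spec$n, x$spec$p, x$spec$realizations,
              100 * x$disconnected_fraction, x$disconnection))
  for (m in c("L", "D", "CC")) {
    cat(sprintf("  %-2s %.3f (%.3f)\n", m, x[[m]]$mean, x[[m]]$sd))
  }
  invisible(x)
}

#' Empirical p-value of an observed metric against a null distribution
#'
#' Add-one empirical p-value: (1 + number of simulated values at least as
#' extreme as the observation) / (realizations + 1). The add-one smoothing
#' means an observation beyond all R simulated values yields 1 / (R + 1),
#' never exactly zero. Two-sided extremity is measured as absolute deviation
#' from the null mean.
#'
#' @param observed observed metric value.
#' @param dist a [metric_distribution()].
#' @param side `"two"`, `"greater"` or `"less"`.
#' @return the empirical p-value.
#' @export
empirical_significance <- function(observed, dist, side = c("two", "greater", "less")) {
  stopifnot(inherits(dist, "metric_distribution"), is.finite(observed))
  side <- match.arg(side)
  v <- dist$values
  R <- length(v)
  extreme <- switch(side,
    greater = sum(v >= observed),
    less    = sum(v <= observed),
    two     = sum(abs(v - mean(v)) >= abs(observed - mean(v)))
  )
  (1 + extreme) / (R + 1)
}

#' Pooled-variance two-sample t-test
#'
#' Independent two-sample t-test with pooled variance; degrees of freedom
#' n_x + n_y - 2.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop_fl("each sample needs at least 2 observations", "insufficient_data_error")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = length(x) + length(y) - 2L, p = 1))
    stop_fl("zero pooled variance with unequal means: t is undefined",
            "undefined_statistic_error")
  }
  res <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter), p = res$p.value)
}

#' Bootstrapped partial-network comparison of two groups
#'
#' Repeatedly draws a random subset of the common vocabulary, rebuilds each
#' group's PMFG from its correlation submatrix (re-filtering, not taking an
#' induced subgraph), computes L, D and CC of each partial network, and
#' compares the two groups' resulting distributions metric by metric with a
#' pooled two-sample t-test. By default the same word subset is used for
#' both groups within a realization (`subsets = "shared"`), which removes
#' between-group subset noise; `"independent"` draws a separate subset per
#' group; `"exhaustive"` enumerates every subset of the given size once
#' (only sensible for toy vocabularies).
#'
#' @param c_a,c_b [correlation_matrix()] objects on the same vocabulary
#'   (word-matched networks).
#' @param subset_size words per partial network (default 40).
#' @param realizations bootstrap draws (default 10000); ignored for
#'   `subsets = "exhaustive"`.
#' @param seed RNG seed.
#' @param subsets `"shared"`, `"independent"` or `"exhaustive"`.
#' @return object of class `bootstrap_comparison`: per-group
#'   [metric_distribution()]s under `a` and `b`, t statistics and p-values
#'   per metric under `tests`, plus the settings. Note the t-tests treat
#'   bootstrap replicates as independent observations (as is conventional
#'   for this design), which is anticonservative.
#' @export
bootstrap_partial <- function(c_a, c_b, subset_size = 40L, realizations = 10000L,
                              seed = NULL, subsets = c("shared", "independent", "exhaustive")) {
  stopifnot(inherits(c_a, "correlation_matrix"), inherits(c_b, "correlation_matrix"))
  subsets <- match.arg(subsets)
  if (!identical(c_a$vocabulary, c_b$vocabulary)) {
    stop_fl("both groups must share the same (word-matched) vocabulary", "input_error")
  }
  V <- length(c_a$vocabulary)
  subset_size <- as.integer(subset_size)
  if (subset_size < 3L || subset_size > V) {
    stop_fl("subset_size must be between 3 and the vocabulary size", "input_error")
  }
  draw_metrics <- function(C, idx) {
    g <- build_pmfg(C[idx, idx, drop = FALSE])
    c(L = aspl(g), D = net_diameter(g), CC = clustering_coef(g))
  }
  if (subsets == "exhaustive") {
    if (choose(V, subset_size) > 1e4) {
      stop_fl("exhaustive enumeration is only supported for small vocabularies",
              "input_error")
    }
    idx_list <- combn(V, subset_size, simplify = FALSE)
  } else {
    idx_list <- with_seed(seed, {
      lapply(seq_len(as.integer(realizations)), function(r) {
        if (subsets == "shared") {
          list(sort(sample.int(V, subset_size)))
        } else {
          list(sort(sample.int(V, subset_size)), sort(sample.int(V, subset_size)))
        }
      })
    })
  }
  res_a <- res_b <- matrix(NA_real_, length(idx_list), 3L,
                           dimnames = list(NULL, c("L", "D", "CC")))
  for (r in seq_along(idx_list)) {
    ii <- idx_list[[r]]
    ia <- if (is.list(ii)) ii[[1L]] else ii
    ib <- if (is.list(ii) && length(ii) == 2L) ii[[2L]] else ia
    res_a[r, ] <- draw_metrics(c_a$C, ia)
    res_b[r, ] <- draw_metrics(c_b$C, ib)
  }
  dists <- function(m) {
    list(L = metric_distribution("L", m[, "L"]),
         D = metric_distribution("D", m[, "D"]),
         CC = metric_distribution("CC", m[, "CC"]))
  }
  tests <- lapply(c(L = "L", D = "D", CC = "CC"), function(m) {
    tryCatch(two_sample_t(res_a[, m], res_b[, m]),
             fluencynet_undefined_statistic_error = function(e) {
               # both distributions degenerate (e.g. subset = full vocabulary)
               list(t = NA_real_, df = nrow(res_a) * 2L - 2L, p = NA_real_)
             })
  })
  structure(list(a = dists(res_a), b = dists(res_b), tests = tests,
                 subset_size = subset_size, realizations = nrow(res_a),
                 subsets = subsets,
                 groups = c(a = c_a$group, b = c_b$group)),
            class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat(sprintf("<bootstrap_comparison> %d realizations of %d-word partial networks (%s subsets)\n",
              x$realizations, x$subset_size, x$subsets))
  for (m in c("L", "D", "CC")) {
    cat(sprintf("  %-2s %s: %.3f (%.3f) vs %s: %.3f (%.3f)  t=%.2f df=%d p=%.3g\n",
                m, x$groups[["a"]], x$a[[m]]$mean, x$a[[m]]$sd,
                x$groups[["b"]], x$b[[m]]$mean, x$b[[m]]$sd,
                x$tests[[m]]$t, x$tests[[m]]$df, x$tests[[m]]$p))
  }
  invisible(x)
}

#' Export null/bootstrap distributions as CSV (one row per realization)
#'
#' @param x an `er_null` or `bootstrap_comparison`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distributions <- function(x, path) {
  df <- if (inherits(x, "er_null")) {
    data.frame(realization = seq_along(x$L$values),
               L = x$L$values, D = x$D$values, CC = x$CC$values)
  } else if (inherits(x, "bootstrap_comparison")) {
    data.frame(realization = rep(seq_along(x$a$L$values), 2L),
               group = rep(c(x$groups[["a"]], x$groups[["b"]]),
                           each = length(x$a$L$values)),
               L = c(x$a$L$values, x$b$L$values),
               D = c(x$a$D$values, x$b$D$values),
               CC = c(x$a$CC$values, x$b$CC$values))
  } else {
    stop_fl("unsupported object", "format_error")
  }
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
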