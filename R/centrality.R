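#' Leave-one-word-out impact scores
#'
#' Quantifies the importance of each word for the spread of activation in
#' the semantic network: the impact score of word i is the ASPL of the
#' network re-estimated without word i minus the ASPL of the full network.
#' Canonically ("rebuild" mode, the default) the word's row and column are
#' deleted from the correlation matrix and the PMFG is rebuilt from scratch
#' before the ASPL is recomputed. A positive score means removing the word
#' lengthens average paths (the word helps activation spread); a negative
#' score means removal shortens them. The faster non-canonical "subgraph"
#' mode deletes the node from the full PMFG instead of re-filtering; if that
#' disconnects the network the ASPL is taken on the largest component.
#'
#' @param cm a [correlation_matrix()] on at least 4 words.
#' @param group group label for the output (defaults to the matrix's own).
#' @param mode `"rebuild"` (canonical) or `"subgraph"`.
#' @return data.frame of class `impact_result` with columns `word`, `group`,
#'   `wc`, one row per word (in vocabulary order), and attribute
#'   `full_aspl`.
#' @export
impact_scores <- function(cm, group = NULL, mode = c("rebuild", "subgraph")) {
  stopifnot(inherits(cm, "correlation_matrix"))
  mode <- match.arg(mode)
  if (is.null(group)) group <- cm$group
  V <- length(cm$vocabulary)
  if (V < 4L) stop_fl("impact scores need at least 4 words", "size_error")
  full <- build_pmfg(cm)
  full_aspl <- aspl(full)
  wc <- vapply(seq_len(V), function(i) {
    if (mode == "rebuild") {
      g <- build_pmfg(cm$C[-i, -i, drop = FALSE])
    } else {
      g <- igraph::delete_vertices(full, i)
      if (!igraph::is_connected(g)) g <- largest_component(g)
    }
    aspl(g) - full_aspl
  }, numeric(1L))
  structure(data.frame(word = cm$vocabulary, group = group, wc = wc,
                       stringsAsFactors = FALSE),
            full_aspl = full_aspl, mode = mode,
            class = c("impact_result", "data.frame"))
}

#' Compare impact-score vectors of two groups
#'
#' Pooled two-sample t-test over the two groups' word impact vectors,
#' computed on the same word-matched vocabulary.
#'
#' @param a,b `impact_result` objects over the same words in the same order.
#' @return list with `t`, `df`, `p`.
#' @export
compare_impact <- function(a, b) {
  stopifnot(inherits(a, "impact_result"), inherits(b, "impact_result"))
  if (!identical(a$word, b$word)) {
    stop_fl("impact results must cover the same vocabulary in the same order",
            "input_error")
  }
  two_sample_t(a$wc, b$wc)
}

#' Write an impact table as CSV
#'
#' Rows are sorted by absolute impact, descending, so the most structurally
#' important words come first.
#'
#' @param x an `impact_result` (or an rbind of several groups').
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_impact <- function(x, path) {
  df <- as.data.frame(x)[order(-abs(x$wc)), c("word", "group", "wc")]
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Paired plot data for a word-by-word impact chart
#'
#' Long-format table (word index vs impact per group) for plotting the two
#' groups' impact profiles side by side.
#'
#' @param a,b `impact_result` objects over the same words.
#' @return data.frame with columns `index`, `word`, `group`, `wc`.
#' @export
impact_plot_data <- function(a, b) {
  stopifnot(identical(a$word, b$word))
  rbind(
    data.frame(index = seq_along(a$word), word = a$word, group = a$group, wc = a$wc),
    data.frame(index = seq_along(b$word), word = b$word, group = b$group, wc = b$wc)
  )
}
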