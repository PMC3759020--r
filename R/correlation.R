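#' Word-by-word correlation matrix of response profiles
#'
#' Computes the Pearson correlation between every pair of word response
#' profiles (the binary column vectors of a response matrix). For binary
#' profiles this is the phi coefficient. Words with zero profile variance
#' (produced by every subject, or by none after vocabulary restriction)
#' have undefined correlations; they are removed and reported via the
#' `excluded` field rather than silently kept.
#'
#' @param m a `response_matrix` with at least two subjects.
#' @return object of class `correlation_matrix`: list with `C` (symmetric
#'   numeric matrix, unit diagonal, dimnames = vocabulary), `vocabulary`,
#'   `excluded` (zero-variance words removed) and `group`.
#' @export
word_correlations <- function(m) {
  if (!inherits(m, "response_matrix")) stop_fl("expected a response_matrix", "format_error")
  if (nrow(m) < 2L) stop_fl("need at least 2 subjects to correlate profiles",
                            "insufficient_data_error")
  x <- unclass(m)
  storage.mode(x) <- "double"
  v <- apply(x, 2L, stats::var)
  excluded <- colnames(x)[v == 0]
  if (length(excluded) > 0L) {
    warning(sprintf("excluding %d zero-variance word(s): %s",
                    length(excluded), paste(excluded, collapse = ", ")))
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) == 0L) stop_fl("all words have zero variance", "insufficient_data_error")
  C <- stats::cor(x)
  C[C > 1] <- 1
  C[C < -1] <- -1
  diag(C) <- 1
  correlation_matrix(C, excluded = excluded, group = attr(m, "group"))
}

#' Construct a correlation matrix object
#'
#' Validates symmetry, unit diagonal and the \[-1, 1\] range.
#'
#' @param C symmetric numeric matrix with word dimnames.
#' @param excluded words dropped for zero variance (bookkeeping only).
#' @param group optional group label.
#' @return a `correlation_matrix`.
#' @export
correlation_matrix <- function(C, excluded = character(), group = NA_character_) {
  if (!is.matrix(C) || !is.numeric(C) || nrow(C) != ncol(C)) {
    stop_fl("C must be a square numeric matrix", "format_error")
  }
  if (is.null(colnames(C)) || anyDuplicated(colnames(C))) {
    stop_fl("C must have unique word dimnames", "format_error")
  }
  rownames(C) <- colnames(C)
  if (any(!is.finite(C))) stop_fl("correlation entries must be finite", "input_error")
  if (max(abs(C - t(C))) > 1e-12) stop_fl("C must be symmetric", "input_error")
  if (max(abs(diag(C) - 1)) > 1e-12) stop_fl("diagonal must be 1", "input_error")
  if (min(C) < -1 - 1e-12 || max(C) > 1 + 1e-12) {
    stop_fl("entries must lie in [-1, 1]", "input_error")
  }
  structure(list(C = C, vocabulary = colnames(C),
                 excluded = as.character(excluded), group = group),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d words (%d excluded for zero variance)%s\n",
              length(x$vocabulary), length(x$excluded),
              if (is.na(x$group)) "" else sprintf(", group '%s'", x$group)))
  invisible(x)
}

#' Restrict a correlation matrix to a word subset
#'
#' @param cm a `correlation_matrix`.
#' @param vocab words to keep (must be present).
#' @return the sub-`correlation_matrix`, rows/columns in `vocab` order.
#' @export
restrict_correlations <- function(cm, vocab) {
  stopifnot(inherits(cm, "correlation_matrix"))
  missing <- setdiff(vocab, cm$vocabulary)
  if (length(missing) > 0L) {
    stop_fl(paste0("words not in vocabulary: ", paste(missing, collapse = ", ")),
            "lookup_error")
  }
  correlation_matrix(cm$C[vocab, vocab, drop = FALSE], group = cm$group)
}

#' Write a correlation matrix as labeled CSV at full precision
#'
#' Values are written with 17 significant digits so that
#' [read_correlation_matrix()] round-trips exactly.
#'
#' @param cm a `correlation_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "correlation_matrix"))
  C <- cm$C
  chr <- matrix(sprintf("%.17g", C), nrow(C), dimnames = dimnames(C))
  df <- data.frame(word = rownames(C), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a correlation matrix written by [write_correlation_matrix()]
#'
#' @param path CSV path.
#' @param group optional group label.
#' @return a `correlation_matrix`.
#' @export
read_correlation_matrix <- function(path, group = NA_character_) {
  df <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                 colClasses = "character")
  words <- df[[1L]]
  C <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(C) <- "double"
  dimnames(C) <- list(words, colnames(df)[-1])
  correlation_matrix(C, group = group)
}
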