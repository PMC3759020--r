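#' Normalize fluency word tokens
#'
#' Trims surrounding whitespace, collapses internal runs of whitespace to a
#' single space, and case-folds to lower case. An optional variant map then
#' rewrites surface variants to a canonical token (e.g. merging plurals),
#' since exact string matching is the default behaviour.
#'
#' @param x character vector of raw tokens.
#' @param variant_map optional named character vector; names are variants,
#'   values the canonical tokens they map to.
#' @return character vector of normalized tokens.
#' @export
#' @examples
#' normalize_token(c("  Dog ", "CAT"))
normalize_token <- function(x, variant_map = NULL) {
  x <- tolower(gsub("[[:space:]]+", " ", trimws(as.character(x))))
  if (!is.null(variant_map)) {
    if (is.null(names(variant_map))) {
      stop_fl("variant_map must be a named character vector", "format_error")
    }
    variants <- normalize_token(names(variant_map))
    canon <- normalize_token(unname(variant_map))
    hit <- match(x, variants)
    x[!is.na(hit)] <- canon[hit[!is.na(hit)]]
  }
  x
}

#' Construct a fluency dataset for one group
#'
#' A fluency dataset is the raw output of a timed category fluency task for
#' one group: an ordered word list per subject. Tokens are normalized on
#' construction; subjects left with no responses are dropped with a warning.
#'
#' @param group group label (single string).
#' @param subjects named list; each element is a character vector of
#'   responses in production order, named by subject id.
#' @param variant_map optional variant-merge table, see [normalize_token()].
#' @return an object of class `fluency_dataset` with fields `group` and
#'   `subjects`.
#' @export
fluency_dataset <- function(group, subjects, variant_map = NULL) {
  if (!is.character(group) || length(group) != 1L || !nzchar(group)) {
    stop_fl("group must be a single non-empty string", "format_error")
  }
  if (!is.list(subjects) || is.null(names(subjects)) ||
      anyDuplicated(names(subjects)) || any(!nzchar(names(subjects)))) {
    stop_fl("subjects must be a list uniquely named by subject id", "format_error")
  }
  subjects <- lapply(subjects, function(r) {
    r <- normalize_token(r, variant_map)
    r[nzchar(r)]
  })
  empty <- vapply(subjects, length, 1L) == 0L
  if (any(empty)) {
    warning(sprintf("dropping %d subject(s) with no valid responses in group '%s': %s",
                    sum(empty), group, paste(names(subjects)[empty], collapse = ", ")))
    subjects <- subjects[!empty]
  }
  if (length(subjects) == 0L) stop_fl("no subjects with responses", "empty_input_error")
  subjects <- subjects[order(names(subjects), method = "radix")]
  structure(list(group = group, subjects = subjects), class = "fluency_dataset")
}

#' @export
print.fluency_dataset <- function(x, ...) {
  n_words <- length(unique(unlist(x$subjects)))
  cat(sprintf("<fluency_dataset> group '%s': %d subjects, %d distinct words\n",
              x$group, length(x$subjects), n_words))
  invisible(x)
}

#' Read verbal-fluency responses
#'
#' Reads long-format responses (one row per produced word) and returns one
#' [fluency_dataset()] per group. The CSV layout has columns `group`,
#' `subject`, `order`, `word`; the JSON layout is an array of objects with
#' the same fields. Per-subject production order is restored from `order`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @param variant_map optional variant-merge table, see [normalize_token()].
#' @return named list of `fluency_dataset`, one per group label.
#' @export
read_fluency <- function(path, format = c("auto", "csv", "json"), variant_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_fl(paste0("file not found: ", path), "io_error")
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  } else {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L) stop_fl("no responses in input file", "empty_input_error")
  needed <- c("group", "subject", "order", "word")
  if (!all(needed %in% names(df))) {
    stop_fl(paste0("missing required columns: ",
                   paste(setdiff(needed, names(df)), collapse = ", ")), "format_error")
  }
  df <- df[order(df$group, df$subject, df$order), , drop = FALSE]
  out <- lapply(split(df, df$group), function(g) {
    subj <- lapply(split(g$word, g$subject), as.character)
    fluency_dataset(as.character(g$group[1L]), subj, variant_map = variant_map)
  })
  out[order(names(out))]
}

#' Write verbal-fluency responses
#'
#' Inverse of [read_fluency()]: serializes one or more fluency datasets to
#' the long CSV or JSON layout (columns `group`, `subject`, `order`, `word`).
#'
#' @param datasets a `fluency_dataset` or a list of them.
#' @param path output file path.
#' @param format `"auto"`, `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_fluency <- function(datasets, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (inherits(datasets, "fluency_dataset")) datasets <- list(datasets)
  rows <- do.call(rbind, lapply(datasets, function(ds) {
    do.call(rbind, lapply(names(ds$subjects), function(id) {
      w <- ds$subjects[[id]]
      data.frame(group = ds$group, subject = id, order = seq_along(w),
                 word = w, stringsAsFactors = FALSE)
    }))
  }))
  if (format == "csv") {
    write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(rows, path, dataframe = "rows")
  }
  invisible(path)
}

#' Build the binary subject-by-word incidence matrix
#'
#' Codes a group's responses in a binary manner: cell (i, j) is 1 if subject
#' i produced word j at least once (repetitions collapse to a single 1), and
#' 0 otherwise. The vocabulary is the union of all tokens in the group,
#' sorted lexicographically so that all downstream tie-breaking is
#' deterministic.
#'
#' @param ds a [fluency_dataset()].
#' @return integer matrix of class `response_matrix` (subjects in rows,
#'   words in columns) with attribute `group`.
#' @export
build_response_matrix <- function(ds) {
  if (!inherits(ds, "fluency_dataset")) stop_fl("expected a fluency_dataset", "format_error")
  vocab <- sort(unique(unlist(ds$subjects, use.names = FALSE)), method = "radix")
  ids <- names(ds$subjects)
  m <- matrix(0L, nrow = length(ids), ncol = length(vocab),
              dimnames = list(ids, vocab))
  for (id in ids) m[id, unique(ds$subjects[[id]])] <- 1L
  structure(m, group = ds$group, class = c("response_matrix", class(m)))
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> group '%s': %d subjects x %d words\n",
              attr(x, "group"), nrow(x), ncol(x)))
  invisible(x)
}

#' Select the word-matched (WMCN) vocabulary
#'
#' Returns the words produced by at least `min_subjects` subjects in *each*
#' of two groups — the vocabulary on which directly comparable word-matched
#' correlation networks are built. Symmetric in its two arguments.
#'
#' @param a,b `response_matrix` objects for the two groups.
#' @param min_subjects minimum number of producing subjects per group
#'   (default 2).
#' @return lexicographically sorted character vector of common words.
#' @export
select_wmcn_vocabulary <- function(a, b, min_subjects = 2L) {
  stopifnot(inherits(a, "response_matrix"), inherits(b, "response_matrix"))
  common <- intersect(colnames(a), colnames(b))
  keep <- common[colSums(a[, common, drop = FALSE]) >= min_subjects &
                 colSums(b[, common, drop = FALSE]) >= min_subjects]
  if (length(keep) == 0L) {
    stop_fl("no common words meet the minimum-subject threshold", "empty_vocabulary_error")
  }
  sort(keep, method = "radix")
}

#' Restrict a response matrix to a vocabulary subset
#'
#' @param m a `response_matrix`.
#' @param vocab character vector of words; must all be present in `m`.
#' @return the column-subset `response_matrix` (subject rows unchanged).
#' @export
restrict_vocabulary <- function(m, vocab) {
  stopifnot(inherits(m, "response_matrix"))
  missing <- setdiff(vocab, colnames(m))
  if (length(missing) > 0L) {
    stop_fl(paste0("words not in vocabulary: ", paste(missing, collapse = ", ")),
            "lookup_error")
  }
  out <- m[, vocab, drop = FALSE]
  structure(out, group = attr(m, "group"), class = class(m))
}

#' Write a response matrix as CSV
#'
#' Subjects in rows, vocabulary as the header row; first column holds the
#' subject ids.
#'
#' @param m a `response_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(m, path) {
  df <- data.frame(subject = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a response matrix written by [write_response_matrix()]
#'
#' @param path CSV path.
#' @param group group label to attach.
#' @return a `response_matrix`.
#' @export
read_response_matrix <- function(path, group = NA_character_) {
  df <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df[[1L]])
  structure(m, group = group, class = c("response_matrix", class(m)))
}
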