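#' Specification of the clustering-and-switching fluency generator
#'
#' The generator emulates the retrieval process behind a timed category
#' fluency task: a subject knows a personal subset of a structured lexicon
#' (subcategories such as pets, farm animals, ...), retrieves words within
#' the current subcategory (clustering) and jumps to a new subcategory
#' (switching) with a fixed probability after each emission or when the
#' current subcategory is exhausted. This walk induces the within-
#' subcategory co-occurrence correlation that the network analysis assumes.
#'
#' @param n_subjects subjects per group.
#' @param subcategories named integer vector: words per subcategory.
#' @param zipf_exponent Zipf-like exponent for within-subcategory retrieval
#'   weights (word of rank r has weight r^-s); 0 gives uniform retrieval.
#' @param retrieval_mean,retrieval_sd mean and sd of the per-subject number
#'   of words produced (Gaussian, rounded, truncated below at 3).
#' @param p_switch probability of leaving the current subcategory after
#'   each emission.
#' @param p_know probability that a subject knows a subcategory's
#'   top-ranked word (lexicon coverage at the head of the frequency
#'   distribution).
#' @param know_decay rank decay of word knowledge: the probability of
#'   knowing the rank-r word of a subcategory is `p_know * r^-know_decay`.
#'   0 gives flat coverage; positive values concentrate shared vocabulary
#'   on high-frequency words, as in real acquisition.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(n_subjects = 27L,
                           subcategories = default_subcategories(),
                           zipf_exponent = 1.5,
                           retrieval_mean = 16,
                           retrieval_sd = 4,
                           p_switch = 0.35,
                           p_know = 0.95,
                           know_decay = 0.8) {
  n_subjects <- as.integer(n_subjects)
  subcategories <- vapply(subcategories, as.integer, 1L)
  if (n_subjects < 1L) stop_fl("n_subjects must be >= 1", "parameter_error")
  if (is.null(names(subcategories)) || any(subcategories < 1L)) {
    stop_fl("subcategories must be a named vector of sizes >= 1", "parameter_error")
  }
  for (p in c(p_switch, p_know)) {
    if (!is.numeric(p) || p < 0 || p > 1) {
      stop_fl("probabilities must lie in [0, 1]", "parameter_error")
    }
  }
  if (retrieval_mean <= 0 || retrieval_sd < 0) {
    stop_fl("retrieval length parameters must be positive", "parameter_error")
  }
  if (retrieval_mean > sum(subcategories)) {
    stop_fl("mean retrieval length exceeds the lexicon size", "parameter_error")
  }
  if (!is.numeric(know_decay) || know_decay < 0) {
    stop_fl("know_decay must be non-negative", "parameter_error")
  }
  structure(list(n_subjects = n_subjects, subcategories = subcategories,
                 zipf_exponent = zipf_exponent,
                 retrieval_mean = retrieval_mean, retrieval_sd = retrieval_sd,
                 p_switch = p_switch, p_know = p_know, know_decay = know_decay),
            class = "generator_spec")
}

#' Default subcategory layout of the synthetic animal lexicon
#'
#' Twelve subcategories loosely following the granularity of published
#' animal-category norms, 194 words in total; word tokens are
#' `<subcategory><rank>` (e.g. `pets03`).
#'
#' @return named integer vector of subcategory sizes.
#' @export
default_subcategories <- function() {
  c(pets = 15L, farm = 18L, african = 22L, birds = 21L, fish = 18L,
    insects = 16L, reptiles = 14L, rodents = 10L, forest = 16L,
    ocean = 20L, exotic = 12L, arctic = 12L)
}

#' A group profile: a label plus generator-spec overrides
#'
#' @param label group label (e.g. `"NH"`, `"CI"`).
#' @param ... overrides passed to [generator_spec()].
#' @param base a `generator_spec` to start from.
#' @return object of class `group_profile` with fields `label` and `spec`.
#' @export
group_profile <- function(label, ..., base = generator_spec()) {
  stopifnot(inherits(base, "generator_spec"))
  over <- list(...)
  args <- unclass(base)
  args[names(over)] <- over
  structure(list(label = label, spec = do.call(generator_spec, args)),
            class = "group_profile")
}

#' Load the two shipped default group profiles
#'
#' Reads the packaged YAML configurations `nh_like.yaml` and `ci_like.yaml`:
#' a larger-lexicon-coverage, longer-retrieval profile and a smaller,
#' shorter one, mirroring the reported behavioural group difference
#' (implanted children produce fewer words than normal-hearing peers).
#'
#' @return named list of two [group_profile()]s (`nh_like`, `ci_like`).
#' @export
default_profiles <- function() {
  read_one <- function(fname) {
    path <- system.file("extdata", fname, package = "fluencynet")
    if (!nzchar(path)) stop_fl(paste0("missing packaged profile ", fname), "io_error")
    read_profile(path)
  }
  list(nh_like = read_one("nh_like.yaml"), ci_like = read_one("ci_like.yaml"))
}

#' Read a group profile from a YAML file
#'
#' @param path YAML file with a `label` field and [generator_spec()] fields.
#' @return a [group_profile()].
#' @export
read_profile <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$label)) stop_fl("profile must carry a label", "format_error")
  label <- y$label
  y$label <- NULL
  if (!is.null(y$subcategories)) y$subcategories <- unlist(y$subcategories)
  do.call(group_profile, c(list(label = label), y))
}

lexicon_table <- function(spec) {
  subcat <- rep(names(spec$subcategories), spec$subcategories)
  rank <- unlist(lapply(spec$subcategories, seq_len), use.names = FALSE)
  data.frame(word = sprintf("%s%02d", subcat, rank),
             subcategory = subcat,
             weight = rank^(-spec$zipf_exponent),
             p_know = pmin(1, spec$p_know * rank^(-spec$know_decay)),
             stringsAsFactors = FALSE)
}

#' Map synthetic words to their generating subcategory
#'
#' @param spec a `generator_spec`.
#' @return named character vector: subcategory per word token.
#' @export
lexicon_subcategories <- function(spec) {
  lex <- lexicon_table(spec)
  stats::setNames(lex$subcategory, lex$word)
}

#' Generate one group's fluency dataset
#'
#' Runs the clustering-and-switching walk once per subject (see
#' [generator_spec()]) and returns the resulting ordered, duplicate-free
#' word lists as a [fluency_dataset()].
#'
#' @param profile a [group_profile()].
#' @param seed RNG seed.
#' @return a [fluency_dataset()].
#' @export
generate_group <- function(profile, seed = NULL) {
  stopifnot(inherits(profile, "group_profile"))
  spec <- profile$spec
  lex <- lexicon_table(spec)
  with_seed(seed, {
    subjects <- lapply(seq_len(spec$n_subjects), function(s) {
      known <- which(runif(nrow(lex)) < lex$p_know)
      if (length(known) == 0L) return(character())
      len <- max(3L, round(rnorm(1, spec$retrieval_mean, spec$retrieval_sd)))
      len <- min(len, length(known))
      walk_subject(lex[known, , drop = FALSE], len, spec$p_switch)
    })
    names(subjects) <- sprintf("%s%02d", gsub("[^[:alnum:]]", "", tolower(profile$label)),
                               seq_len(spec$n_subjects))
    fluency_dataset(profile$label, subjects)
  })
}

# one subject's retrieval walk over their known lexicon
walk_subject <- function(known, len, p_switch) {
  out <- character(len)
  avail <- split(seq_len(nrow(known)), known$subcategory)
  current <- NA_character_
  for (k in seq_len(len)) {
    counts <- vapply(avail, length, 1L)
    open <- names(counts)[counts > 0L]
    if (length(open) == 0L) {
      out <- out[seq_len(k - 1L)]
      break
    }
    need_switch <- is.na(current) || length(avail[[current]]) == 0L ||
      runif(1) < p_switch
    if (need_switch) {
      cands <- setdiff(open, current)
      if (length(cands) == 0L) cands <- open
      w <- counts[cands]
      current <- if (length(cands) == 1L) cands else sample(cands, 1L, prob = w)
    }
    pool <- avail[[current]]
    pick <- if (length(pool) == 1L) pool else {
      sample(pool, 1L, prob = known$weight[pool])
    }
    out[k] <- known$word[pick]
    avail[[current]] <- setdiff(pool, pick)
  }
  out
}

#' Generate a matched pair of group datasets
#'
#' Independent draws for the two groups from child seeds derived from one
#' master seed, so a single integer reproduces the whole pair.
#'
#' @param nh_like,ci_like [group_profile()]s (defaults: the shipped
#'   profiles).
#' @param seed master RNG seed.
#' @return named list of two [fluency_dataset()]s, named by group label.
#' @export
generate_pair <- function(nh_like = default_profiles()$nh_like,
                          ci_like = default_profiles()$ci_like,
                          seed = NULL) {
  seeds <- derive_seeds(seed, 2L)
  out <- list(generate_group(nh_like, seed = seeds[[1L]]),
              generate_group(ci_like, seed = seeds[[2L]]))
  names(out) <- vapply(out, function(d) d$group, "")
  out
}
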