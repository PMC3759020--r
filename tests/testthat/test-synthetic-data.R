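small_profile <- function(label = "G", ...) {
  sc <- c(one = 8L, two = 8L, three = 8L)
  group_profile(label, n_subjects = 10L, subcategories = sc,
                retrieval_mean = 8, retrieval_sd = 2, ...)
}

test_that("generation is seed-deterministic and respects the lexicon", {
  pr <- small_profile()
  d1 <- generate_group(pr, seed = 4)
  d2 <- generate_group(pr, seed = 4)
  expect_identical(d1, d2)
  d3 <- generate_group(pr, seed = 5)
  expect_false(identical(d1, d3))
  lex <- names(lexicon_subcategories(pr$spec))
  for (resp in d1$subjects) {
    expect_false(anyDuplicated(resp) > 0)
    expect_true(all(resp %in% lex))
  }
})

test_that("a single subcategory with p_switch = 0 confines every list to it", {
  pr <- group_profile("G", n_subjects = 8L, subcategories = c(only = 12L),
                      retrieval_mean = 6, retrieval_sd = 1, p_switch = 0)
  d <- generate_group(pr, seed = 2)
  subcat <- lexicon_subcategories(pr$spec)
  expect_true(all(unlist(lapply(d$subjects, function(r) subcat[r])) == "only"))
})

test_that("longer retrieval stochastically increases distinct-word counts", {
  short_counts <- long_counts <- numeric(10)
  for (s in 1:10) {
    short <- generate_group(small_profile(retrieval_mean = 5, retrieval_sd = 1), seed = s)
    long <- generate_group(small_profile(retrieval_mean = 12, retrieval_sd = 1), seed = s)
    short_counts[s] <- length(unique(unlist(short$subjects)))
    long_counts[s] <- length(unique(unlist(long$subjects)))
  }
  expect_gt(mean(long_counts), mean(short_counts))
})

test_that("default profiles hit the calibration anchors for distinct words", {
  counts <- t(vapply(1:20, function(s) {
    pr <- generate_pair(seed = s)
    c(length(unique(unlist(pr[[1]]$subjects))),
      length(unique(unlist(pr[[2]]$subjects))))
  }, numeric(2)))
  # anchors: roughly 132 (NH-like) and 106 (CI-like) distinct words, +/- 25%
  expect_gt(mean(counts[, 1]), 132 * 0.75)
  expect_lt(mean(counts[, 1]), 132 * 1.25)
  expect_gt(mean(counts[, 2]), 106 * 0.75)
  expect_lt(mean(counts[, 2]), 106 * 1.25)
})

test_that("the word-matched vocabulary of a default pair is non-empty and strictly smaller", {
  pr <- generate_pair(seed = 12)
  ma <- build_response_matrix(pr[[1]])
  mb <- build_response_matrix(pr[[2]])
  vocab <- select_wmcn_vocabulary(ma, mb)
  expect_gt(length(vocab), 0)
  expect_lt(length(vocab), ncol(ma))
  expect_lt(length(vocab), ncol(mb))
})

test_that("the walk plants within-subcategory correlation structure", {
  subcat_of <- lexicon_subcategories(default_profiles()$nh_like$spec)
  ok <- 0
  runs <- 100
  for (s in 1:runs) {
    pr <- generate_pair(seed = 2000 + s)
    good <- TRUE
    for (ds in pr) {
      m <- build_response_matrix(ds)
      cm <- suppressWarnings(word_correlations(m))
      sc <- subcat_of[cm$vocabulary]
      same <- outer(sc, sc, "==")
      ut <- upper.tri(cm$C)
      if (mean(cm$C[ut & same]) <= mean(cm$C[ut & !same])) good <- FALSE
    }
    if (good) ok <- ok + 1
  }
  expect_gte(ok, 0.95 * runs)
})

test_that("PMFG edges concentrate within planted subcategories", {
  subcat_of <- lexicon_subcategories(default_profiles()$nh_like$spec)
  for (s in 1:20) {
    ds <- generate_group(default_profiles()$nh_like, seed = 3000 + s)
    cm <- suppressWarnings(word_correlations(build_response_matrix(ds)))
    g <- build_pmfg(cm)
    el <- igraph::as_edgelist(g)
    within_rate <- mean(subcat_of[el[, 1]] == subcat_of[el[, 2]])
    # chance rate of a within-subcategory pair among all node pairs
    sc <- subcat_of[igraph::V(g)$name]
    tab <- table(sc)
    chance <- sum(choose(tab, 2)) / choose(length(sc), 2)
    expect_gt(within_rate, chance)
  }
})

test_that("profiles round-trip through YAML and invalid parameters are rejected", {
  p <- default_profiles()
  expect_identical(p$nh_like$label, "NH")
  expect_identical(p$ci_like$label, "CI")
  expect_identical(p$nh_like$spec$subcategories, default_subcategories())
  expect_error(generator_spec(p_switch = 1.5), class = "fluencynet_parameter_error")
  expect_error(generator_spec(retrieval_mean = 1e6),
               class = "fluencynet_parameter_error")
  expect_error(generator_spec(know_decay = -1), class = "fluencynet_parameter_error")
})
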