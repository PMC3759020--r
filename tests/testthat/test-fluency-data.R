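test_that("reading preserves groups, order and tokens, and round-trips", {
  df <- toy_long_df()
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, csv, row.names = FALSE)
  ds <- read_fluency(csv)
  expect_named(ds, c("A", "B"))
  expect_s3_class(ds$A, "fluency_dataset")
  expect_identical(ds$A$subjects$a1, c("cat", "dog", "lion"))
  expect_identical(ds$B$subjects$b2, c("dog", "whale", "cat"))

  # write -> read reproduces the datasets exactly, in both formats
  for (ext in c(".csv", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_fluency(ds, f)
    back <- read_fluency(f)
    expect_equal(back, ds)
  }
})

test_that("token normalization trims, case-folds and applies variant maps", {
  expect_identical(normalize_token(c("  Dog ", "CAT", "sea  lion")),
                   c("dog", "cat", "sea lion"))
  ds <- fluency_dataset("g", list(s1 = c("  Dog ", "doggy")),
                        variant_map = c(doggy = "dog"))
  expect_identical(ds$subjects$s1, c("dog", "dog"))
})

test_that("input validation raises classed errors", {
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(group = "A", subject = "s", word = "cat"), bad,
            row.names = FALSE)
  expect_error(read_fluency(bad), class = "fluencynet_format_error")
  empty <- withr::local_tempfile(fileext = ".csv")
  write.csv(toy_long_df()[0, ], empty, row.names = FALSE)
  expect_error(read_fluency(empty), class = "fluencynet_empty_input_error")
  expect_error(read_fluency("no/such/file.csv"), class = "fluencynet_io_error")
  # subjects with no usable responses are dropped with a warning
  expect_warning(
    ds <- fluency_dataset("g", list(s1 = "cat", s2 = c("", "  "))),
    "no valid responses")
  expect_named(ds$subjects, "s1")
})

test_that("response matrix is binary, sorted, and collapses repetitions", {
  ds <- fluency_dataset("g", list(s1 = c("cat", "dog", "cat"), s2 = "dog"))
  m <- build_response_matrix(ds)
  expect_identical(colnames(m), c("cat", "dog"))
  expect_identical(unname(unclass(m)[, "cat"]), c(1L, 0L))
  expect_true(all(m %in% 0:1))
  expect_true(all(colSums(m) >= 1))

  # one subject, two words -> 1 x 2 matrix of ones
  m1 <- build_response_matrix(fluency_dataset("g", list(s = c("b", "a"))))
  expect_identical(dim(m1), c(1L, 2L))
  expect_true(all(m1 == 1L))

  # incidence is insensitive to within-subject response order
  ds2 <- fluency_dataset("g", list(s1 = c("dog", "cat", "cat"), s2 = "dog"))
  expect_equal(unclass(build_response_matrix(ds2)), unclass(m))
})

test_that("word-matched vocabulary applies the per-group threshold symmetrically", {
  a <- build_response_matrix(fluency_dataset("A", list(
    s1 = c("cat", "dog", "lion"), s2 = c("cat", "dog"), s3 = "lion")))
  b <- build_response_matrix(fluency_dataset("B", list(
    t1 = c("cat", "lion"), t2 = c("cat", "dog"), t3 = "fox")))
  # "lion": 2 in A but 1 in B -> excluded; "cat": (2, 2)+ -> included
  expect_identical(select_wmcn_vocabulary(a, b), "cat")
  expect_identical(select_wmcn_vocabulary(a, b), select_wmcn_vocabulary(b, a))
  expect_identical(select_wmcn_vocabulary(a, b, min_subjects = 1), c("cat", "dog", "lion"))
  expect_error(select_wmcn_vocabulary(a, b, min_subjects = 4),
               class = "fluencynet_empty_vocabulary_error")
})

test_that("vocabulary restriction subsets columns and validates words", {
  m <- build_response_matrix(fluency_dataset("g", list(
    s1 = c("cat", "dog", "fox"), s2 = c("dog", "fox"))))
  expect_equal(restrict_vocabulary(m, colnames(m)), m)
  one <- restrict_vocabulary(m, "dog")
  expect_identical(dim(one), c(2L, 1L))
  expect_error(restrict_vocabulary(m, c("dog", "yeti")),
               class = "fluencynet_lookup_error")
})

test_that("response matrices round-trip through CSV", {
  m <- build_response_matrix(fluency_dataset("g", list(
    s1 = c("cat", "dog"), s2 = "dog")))
  f <- withr::local_tempfile(fileext = ".csv")
  write_response_matrix(m, f)
  back <- read_response_matrix(f, group = "g")
  expect_equal(unclass(back), unclass(m))
})
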