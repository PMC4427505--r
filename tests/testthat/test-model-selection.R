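test_that("fold plans have the prescribed nested geometry", {
  plan <- make_fold_plan(100, repeats = 4, folds = 4, seed = 42)
  expect_identical(length(plan$outer), 16L)
  for (e in plan$outer) {
    expect_identical(length(e$test), 25L)
    expect_identical(length(e$train), 75L)
    expect_identical(length(intersect(e$train, e$test)), 0L)
    expect_identical(length(e$inner), 16L)
    for (f in e$inner) {
      expect_true(all(c(f$train, f$test) %in% e$train))
      expect_identical(length(intersect(f$train, f$test)), 0L)
      expect_identical(sort(c(f$train, f$test)), sort(e$train))
    }
  }
  # within one repeat the four test splits partition the corpus
  for (r in 1:4) {
    tests <- unlist(lapply(plan$outer[vapply(plan$outer, `[[`, 1L, "repeat_ix") == r],
                           `[[`, "test"))
    expect_identical(sort(tests), 1:100)
  }
  # each item appears in exactly `repeats` outer test splits
  counts <- table(unlist(lapply(plan$outer, `[[`, "test")))
  expect_true(all(counts == 4))
})

test_that("fold plans are reproducible from the seed and near-equal for odd sizes", {
  p1 <- make_fold_plan(103, seed = 7)
  p2 <- make_fold_plan(103, seed = 7)
  expect_identical(p1, p2)
  p3 <- make_fold_plan(103, seed = 8)
  expect_false(identical(p1$outer[[1]]$test, p3$outer[[1]]$test))
  sizes <- vapply(p1$outer, function(e) length(e$test), integer(1))
  expect_true(max(sizes) - min(sizes) <= 1)
  expect_error(make_fold_plan(3, folds = 4), "smaller")
})

test_that("hyperparameter selection maximizes inner mean MCC with tie-to-smallest", {
  x <- random_binary_matrix(60, 6, seed = 19)
  y <- random_labels(60, seed = 19)
  plan <- make_fold_plan(60, repeats = 1, folds = 4, seed = 3)
  inner <- plan$outer[[1]]$inner
  fitter <- function(xt, yt, v) fit_naive_bayes(xt, yt, alpha = v)
  chosen <- select_hyperparameter(fitter, c(0.1, 1, 10), x, y, inner)
  mccs <- attr(chosen, "mean_mcc")
  expect_equal(as.numeric(chosen),
               as.numeric(names(mccs)[which.max(mccs)]))
  # single-value grid returns that value
  expect_equal(as.numeric(select_hyperparameter(fitter, 2, x, y, inner)), 2)
  # a constant fit function ties everywhere -> smallest value wins
  const_fit <- function(xt, yt, v) pkddi:::new_ddi_model(
    weights = stats::setNames(rep(0, ncol(xt)), colnames(xt)),
    bias = 1, classifier = "const")
  expect_equal(as.numeric(select_hyperparameter(const_fit, c(5, 2, 9), x, y,
                                                inner)), 2)
})

test_that("strong regularization loses to weak on separable data", {
  x <- pkddi:::new_occurrence_matrix(
    cbind(f1 = rep(c(1, 0), each = 20), f2 = rep(c(0, 1), each = 20)),
    kinds = c(f1 = "unigram", f2 = "unigram")
  )
  y <- rep(c("relevant", "irrelevant"), each = 20)
  plan <- make_fold_plan(40, repeats = 1, folds = 4, seed = 5)
  fitter <- function(xt, yt, v) suppressWarnings(
    fit_regularized_linear(xt, yt, "logistic", C = v))
  chosen <- select_hyperparameter(fitter, c(1e-6, 10), x, y,
                                  plan$outer[[1]]$inner)
  expect_equal(as.numeric(chosen), 10)
})

test_that("failing grid values are disqualified with a warning", {
  x <- random_binary_matrix(40, 4, seed = 23)
  y <- random_labels(40, seed = 23)
  plan <- make_fold_plan(40, repeats = 1, folds = 4, seed = 2)
  fitter <- function(xt, yt, v) {
    if (v < 0) stop("bad value")
    fit_naive_bayes(xt, yt, alpha = v)
  }
  expect_warning(
    chosen <- select_hyperparameter(fitter, c(-1, 1), x, y,
                                    plan$outer[[1]]$inner),
    "disqualified")
  expect_equal(as.numeric(chosen), 1)
  expect_error(
    suppressWarnings(select_hyperparameter(fitter, c(-1, -2), x, y,
                                           plan$outer[[1]]$inner)),
    "every grid value")
})

test_that("permutation test matches exhaustive enumeration for F <= 12", {
  cases <- list(
    c(3, -1, 2),
    c(1, 1),
    c(0.2, -0.1, 0.05, 0.3, -0.4),
    pkddi:::local_seed(55, stats::rnorm(8, mean = 0.3)),
    pkddi:::local_seed(56, stats::rnorm(12, mean = 0.1))
  )
  for (d in cases) {
    a <- d
    b <- rep(0, length(d))
    for (tails in c("one", "two")) {
      expect_equal(paired_permutation_test(a, b, tails),
                   oracle_permutation_p(a, b, tails), tolerance = 1e-12)
    }
  }
})

test_that("permutation test honors its documented edge cases", {
  # equal vectors: d = 0 everywhere, every permutation ties
  expect_equal(paired_permutation_test(c(1, 2, 3), c(1, 2, 3), "two"), 1)
  expect_equal(paired_permutation_test(c(1, 2, 3), c(1, 2, 3), "one"), 1)
  # F = 2, d = (1, 1): one-tailed 1/4, two-tailed 1/2
  expect_equal(paired_permutation_test(c(2, 2), c(1, 1), "one"), 0.25)
  expect_equal(paired_permutation_test(c(2, 2), c(1, 1), "two"), 0.5)
  # identity permutation included: p >= 2^-F
  a <- pkddi:::local_seed(77, stats::rnorm(10) + 2)
  expect_gte(paired_permutation_test(a, rep(0, 10), "one"), 2^-10)
  expect_error(paired_permutation_test(1:3, 1:2), "length")
  expect_error(paired_permutation_test(rep(1, 21), rep(0, 21)), "F > 20")
})

test_that("permutation test is symmetric between the two configurations", {
  a <- pkddi:::local_seed(91, stats::rnorm(9, 0.2))
  b <- pkddi:::local_seed(92, stats::rnorm(9))
  expect_equal(paired_permutation_test(a, b, "two"),
               paired_permutation_test(b, a, "two"))
  p_ab <- paired_permutation_test(a, b, "one")
  p_ba <- paired_permutation_test(b, a, "one")
  expect_gte(p_ab + p_ba, 1)
})
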