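test_that("class occurrence statistics match a manual tally", {
  x <- toy_matrix()
  st <- class_occurrence_stats(x, toy_labels)
  # hand-counted on the 6-document fixture
  expect_equal(unname(st$p), c(3 / 3, 2 / 3, 2 / 3))
  expect_equal(unname(st$n), c(0, 1 / 3, 1 / 3))
  expect_identical(st$m_pos, 3L)
  expect_identical(st$m_neg, 3L)
  expect_error(class_occurrence_stats(x, rep("relevant", 6)), "both classes")
})

test_that("VTT angles follow arctan(p/n) - pi/4 with its limit conventions", {
  x <- toy_matrix()
  st <- class_occurrence_stats(x, toy_labels)
  m <- fit_vtt(x, toy_labels)
  expect_equal(unname(m$weights[1]), pi / 2 - pi / 4) # n = 0, p > 0
  # p = 1, n = 0 -> pi/4; p = 0, n = 1 -> -pi/4
  x2 <- pkddi:::new_occurrence_matrix(
    cbind(f1 = c(1, 1, 0, 0), f2 = c(0, 0, 1, 1)),
    kinds = c(f1 = "unigram", f2 = "unigram")
  )
  m2 <- fit_vtt(x2, c("relevant", "relevant", "irrelevant", "irrelevant"))
  expect_equal(unname(m2$weights), c(pi / 4, -pi / 4))
  # p = n > 0 for all features -> all angles 0, lambda 0, all scores 0
  x3 <- pkddi:::new_occurrence_matrix(
    cbind(f1 = c(1, 0, 1, 0), f2 = c(1, 1, 1, 1)),
    kinds = c(f1 = "unigram", f2 = "unigram")
  )
  m3 <- fit_vtt(x3, c("relevant", "irrelevant", "irrelevant", "relevant"))
  expect_equal(unname(m3$weights), c(0, 0))
  expect_equal(m3$bias, 0)
  expect_equal(predict(m3, x3)$score, rep(0, 4))
  expect_identical(predict(m3, x3)$label, rep("irrelevant", 4)) # tie rule
})

test_that("the VTT pseudo-document lies exactly on the hyperplane", {
  for (seed in 1:5) {
    x <- random_binary_matrix(40, 12, seed = seed)
    y <- random_labels(40, seed = seed)
    m <- fit_vtt(x, y)
    st <- class_occurrence_stats(x, y)
    pseudo <- (st$p + st$n) / 2
    expect_equal(sum(m$weights * pseudo) + m$bias, 0, tolerance = 1e-13)
  }
})

test_that("VTT rejects dense inputs and resource columns", {
  x <- toy_matrix()
  dense <- x
  dense[1, 1] <- 0.5
  expect_error(fit_vtt(dense, toy_labels), "binary")
  counts <- structure(
    tibble::tibble(document = rownames(x), r = rep(1L, 6)),
    class = c("ddi_resource_counts", "tbl_df", "tbl", "data.frame")
  )
  expect_error(fit_vtt(attach_counts(x, counts), toy_labels), "fit_vtt_ner")
})

test_that("Naive Bayes scores equal the enumerated Bernoulli log posterior-odds", {
  x <- pkddi:::new_occurrence_matrix(
    cbind(f1 = c(1, 1, 0, 0), f2 = c(1, 0, 1, 0)),
    kinds = c(f1 = "unigram", f2 = "unigram")
  )
  y <- c("relevant", "relevant", "relevant", "irrelevant")
  for (alpha in c(0.5, 1, 2)) {
    m <- fit_naive_bayes(x, y, alpha = alpha)
    expect_equal(predict(m, x)$score,
                 unname(oracle_nb_log_odds(unclass(x), y, unclass(x), alpha)),
                 tolerance = 1e-12)
  }
  # larger fixture
  x2 <- random_binary_matrix(30, 6, seed = 9)
  y2 <- random_labels(30, seed = 9)
  m2 <- fit_naive_bayes(x2, y2, alpha = 1)
  expect_equal(predict(m2, x2)$score,
               unname(oracle_nb_log_odds(unclass(x2), y2, unclass(x2), 1)),
               tolerance = 1e-10)
  expect_error(fit_naive_bayes(x2, y2, alpha = 0), "positive")
})

test_that("Naive Bayes limiting behavior: huge alpha flattens weights", {
  x <- random_binary_matrix(20, 4, seed = 2)
  y <- random_labels(20, seed = 2)
  m <- fit_naive_bayes(x, y, alpha = 1e8)
  expect_true(all(abs(m$weights) < 1e-6))
  expect_equal(m$bias, log(sum(y == "relevant") / sum(y == "irrelevant")),
               tolerance = 1e-4)
  # balanced classes + identical within-class counts -> zero weight
  xb <- pkddi:::new_occurrence_matrix(
    cbind(f1 = c(1, 0, 1, 0)), kinds = c(f1 = "unigram"))
  mb <- fit_naive_bayes(xb, c("relevant", "relevant", "irrelevant", "irrelevant"), 1)
  expect_equal(unname(mb$weights), 0)
})

test_that("dLDA matches the Gaussian-density posterior-odds oracle", {
  x <- pkddi:::local_seed(31, {
    matrix(rnorm(30), nrow = 10) + rep(c(1, 0), c(5, 5))
  })
  colnames(x) <- paste0("g", 1:3)
  y <- rep(c("relevant", "irrelevant"), c(5, 5))
  for (gamma in c(0, 0.3, 1)) {
    m <- fit_dlda(x, y, gamma = gamma)
    s <- drop(x %*% m$weights) + m$bias
    expect_equal(s, unname(oracle_gaussian_nb_log_odds(x, y, x, gamma)),
                 tolerance = 1e-10)
  }
  # identical class means -> zero weights
  x0 <- rbind(diag(3), diag(3))
  colnames(x0) <- paste0("g", 1:3)
  m0 <- fit_dlda(x0, rep(c("relevant", "irrelevant"), c(3, 3)), gamma = 0.5)
  expect_equal(unname(m0$weights), rep(0, 3))
})

test_that("dLDA gamma = 1 reduces to nearest-centroid up to uniform scale", {
  x <- pkddi:::local_seed(17, matrix(rnorm(40), nrow = 10))
  colnames(x) <- paste0("g", 1:4)
  y <- random_labels(10, seed = 17)
  m <- fit_dlda(x, y, gamma = 1, include_prior = FALSE)
  dmu <- colMeans(x[y == "relevant", ]) - colMeans(x[y == "irrelevant", ])
  ratio <- m$weights / dmu
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-9)
})

test_that("LDA agrees with dLDA on diagonal-covariance data", {
  # features independently scaled -> within-class covariance is diagonal
  spec_x <- pkddi:::local_seed(23, {
    n <- 600
    mu <- c(0.8, -0.5, 0.3)
    y <- rep(c("relevant", "irrelevant"), each = n / 2)
    x <- matrix(rnorm(3 * n), ncol = 3) %*% diag(c(1, 2, 0.5))
    x[y == "relevant", ] <- sweep(x[y == "relevant", ], 2, mu, `+`)
    colnames(x) <- paste0("g", 1:3)
    list(x = x, y = y)
  })
  m_lda <- fit_lda(spec_x$x, spec_x$y, gamma = 0)
  m_dlda <- fit_dlda(spec_x$x, spec_x$y, gamma = 0)
  cosine <- sum(m_lda$weights * m_dlda$weights) /
    sqrt(sum(m_lda$weights^2) * sum(m_dlda$weights^2))
  # directions agree up to the (small, off-diagonal) sampling noise
  expect_gt(cosine, 0.999)
})

test_that("LDA converges to the closed-form discriminant on 2-feature Gaussians", {
  sigma <- matrix(c(1, 0.6, 0.6, 1.5), 2)
  dmu <- c(1, -0.5)
  w_true <- solve(sigma, dmu)
  err <- vapply(c(200, 2000, 20000), function(n) {
    dat <- pkddi:::local_seed(n + 5L, {
      ch <- chol(sigma)
      y <- rep(c("relevant", "irrelevant"), each = n / 2)
      x <- matrix(rnorm(2 * n), ncol = 2) %*% ch
      x[y == "relevant", ] <- sweep(x[y == "relevant", ], 2, dmu, `+`)
      colnames(x) <- c("g1", "g2")
      list(x = x, y = y)
    })
    m <- fit_lda(dat$x, dat$y, gamma = 0)
    w <- m$weights / sqrt(sum(m$weights^2))
    sqrt(sum((w - w_true / sqrt(sum(w_true^2)))^2))
  }, numeric(1))
  expect_lt(err[3], 0.02)
  expect_true(err[3] < err[1]) # error shrinks with n
})

test_that("LDA gamma = 1 direction is proportional to the mean difference", {
  x <- pkddi:::local_seed(29, matrix(rnorm(60), nrow = 12))
  colnames(x) <- paste0("g", 1:5)
  y <- rep(c("relevant", "irrelevant"), each = 6)
  m <- fit_lda(x, y, gamma = 1)
  dmu <- colMeans(x[y == "relevant", ]) - colMeans(x[y == "irrelevant", ])
  cosine <- sum(m$weights * dmu) / sqrt(sum(m$weights^2) * sum(dmu^2))
  expect_equal(cosine, 1, tolerance = 1e-9)
})

test_that("LDA handles rank-deficiency through its SVD projection step", {
  x <- pkddi:::local_seed(37, matrix(rnorm(40), nrow = 10))
  x <- cbind(x, x[, 1] + x[, 2]) # exactly collinear column
  colnames(x) <- paste0("g", 1:5)
  y <- random_labels(10, seed = 37)
  m <- fit_lda(x, y, gamma = 0.1)
  expect_identical(m$notes$rank, 4L)
  expect_true(all(is.finite(m$weights)))
})

test_that("regularized linear models behave across the C range", {
  x <- pkddi:::new_occurrence_matrix(
    cbind(f1 = c(1, 1, 1, 0, 0, 0), f2 = c(0, 1, 0, 1, 0, 1)),
    kinds = c(f1 = "unigram", f2 = "unigram")
  )
  y <- rep(c("relevant", "irrelevant"), each = 3)
  for (loss in c("logistic", "hinge")) {
    # glmnet warns about the deliberately tiny per-class counts
    m_big <- suppressWarnings(fit_regularized_linear(x, y, loss, C = 1e4))
    pred <- predict(m_big, x)
    expect_identical(pred$label, y) # separable: zero training error
    m_small <- suppressWarnings(fit_regularized_linear(x, y, loss, C = 1e-4))
    expect_lt(sqrt(sum(m_small$weights^2)), sqrt(sum(m_big$weights^2)))
    expect_lt(sqrt(sum(m_small$weights^2)), 0.05)
  }
})

test_that("logistic scores match an independent optimizer on a 6x2 fixture", {
  x <- cbind(f1 = c(0.2, 1.1, 0.7, -0.3, -0.9, 0.1),
             f2 = c(1.0, 0.4, -0.2, -1.1, 0.3, -0.6))
  y <- c("relevant", "relevant", "relevant", "irrelevant", "irrelevant",
         "irrelevant")
  for (C in c(0.1, 1, 10)) {
    m <- suppressWarnings(fit_regularized_linear(x, y, "logistic", C = C))
    ref <- oracle_logistic_fit(x, as.integer(y == "relevant"), C)
    s_pkg <- drop(x %*% m$weights) + m$bias
    s_ref <- drop(x %*% ref$weights) + ref$bias
    expect_equal(s_pkg, s_ref, tolerance = 1e-4)
  }
})

test_that("prediction is structural: bias-only models, duplication, permutation", {
  m <- pkddi:::new_ddi_model(weights = c(f1 = 0, f2 = 0), bias = 0.7,
                             classifier = "toy")
  x <- random_binary_matrix(8, 2, seed = 4)
  pred <- predict(m, x)
  expect_equal(pred$score, rep(0.7, 8))
  # duplicating a document duplicates its score
  x2 <- pkddi:::new_occurrence_matrix(rbind(x, x[1, , drop = FALSE]),
                                      kinds = feature_kinds(x))
  m2 <- fit_naive_bayes(x, random_labels(8, seed = 4), 1)
  expect_equal(predict(m2, x2)$score[9], predict(m2, x2)$score[1])
  # permutation equivariance
  perm <- c(5, 2, 8, 1, 3, 7, 6, 4)
  xp <- pkddi:::matrix_rows(x, perm)
  expect_equal(predict(m2, xp)$score, predict(m2, x)$score[perm])
  expect_error(predict(m2, x[, 1, drop = FALSE]), "feature space")
})

test_that("VTT-NER reduces to plain VTT at beta = 0 and is neutral at c = 1", {
  x <- random_binary_matrix(24, 5, seed = 6)
  y <- random_labels(24, seed = 6)
  counts <- structure(
    tibble::tibble(document = rownames(x),
                   res = rep(1L, 24)), # c_j = 1 everywhere
    class = c("ddi_resource_counts", "tbl_df", "tbl", "data.frame")
  )
  xc <- attach_counts(x, counts)
  m_plain <- fit_vtt(x, y)
  m_ner <- pkddi:::.vtt_ner_model(xc, y, c("NER:res" = 0.5), "linear")
  expect_equal(predict(m_ner, xc)$score, predict(m_plain, x)$score)
  m_ner0 <- pkddi:::.vtt_ner_model(xc, y, c("NER:res" = 0), "linear")
  expect_equal(predict(m_ner0, xc)$score, predict(m_plain, x)$score)
})

test_that("VTT-NER selects informative count features and helps held-out MCC", {
  spec <- generator_spec(
    400, n_features = 12, unit = "sentence", prior_relevant = 0.5, seed = 13,
    p_range = c(0.15, 0.35), n_range = c(0.15, 0.35),
    resources = list(drugs = list(entries = c("drugkazolq", "pharmoxinq"),
                                  rate_pos = 3, rate_neg = 0.4))
  )
  corpus <- sample_corpus(spec)
  lex <- as_lexicon(c("drugkazolq", "pharmoxinq"), "drugs")
  plan <- make_fold_plan(corpus, repeats = 1, folds = 4, seed = 8)
  vocab <- build_vocabulary(corpus, "unigram")
  x <- vectorize(corpus, vocab)
  xc <- attach_counts(x, compute_resource_counts(corpus, list(lex)))
  fold <- plan$outer[[1]]
  y <- corpus$label
  m_ner <- fit_vtt_ner(pkddi:::matrix_rows(xc, fold$train), y[fold$train],
                       inner_folds = lapply(fold$inner, function(f)
                         list(train = match(f$train, fold$train),
                              test = match(f$test, fold$train))))
  expect_gt(m_ner$ner$beta[["NER:drugs"]], 0)
  m_txt <- fit_vtt(pkddi:::matrix_rows(x, fold$train), y[fold$train])
  mcc_ner <- mcc_score(confusion_from_predictions(
    predict(m_ner, pkddi:::matrix_rows(xc, fold$test))$label, y[fold$test]))
  mcc_txt <- mcc_score(confusion_from_predictions(
    predict(m_txt, pkddi:::matrix_rows(x, fold$test))$label, y[fold$test]))
  expect_gte(mcc_ner, mcc_txt)
})

test_that("fits are deterministic given data and hyperparameters", {
  x <- random_binary_matrix(30, 6, seed = 15)
  y <- random_labels(30, seed = 15)
  expect_identical(fit_vtt(x, y), fit_vtt(x, y))
  expect_identical(fit_naive_bayes(x, y, 1), fit_naive_bayes(x, y, 1))
  expect_identical(fit_lda(x, y, 0.2), fit_lda(x, y, 0.2))
  expect_identical(fit_regularized_linear(x, y, "logistic", 1)$weights,
                   fit_regularized_linear(x, y, "logistic", 1)$weights)
})

test_that("the hinge solver agrees with an independent libsvm fit", {
  x <- pkddi:::local_seed(83, matrix(rbinom(150 * 10, 1, 0.3), 150))
  colnames(x) <- paste0("f", 1:10)
  y <- pkddi:::local_seed(84,
    ifelse(rowSums(x[, 1:3]) + rnorm(150, 0, 0.6) > 1, "relevant", "irrelevant"))
  # tight solver settings for the cross-check (the pipeline default is looser)
  m <- fit_regularized_linear(x, y, "hinge", C = 1, tol = 1e-5,
                              max_epochs = 5000)
  ref <- e1071::svm(x = x, y = factor(y, levels = c("irrelevant", "relevant")),
                    scale = FALSE, kernel = "linear", cost = 1)
  w_ref <- drop(t(ref$coefs) %*% ref$SV)
  b_ref <- -ref$rho
  if (ref$levels[ref$labels[1]] != "relevant") {
    w_ref <- -w_ref
    b_ref <- -b_ref
  }
  cosine <- sum(m$weights * w_ref) / sqrt(sum(m$weights^2) * sum(w_ref^2))
  expect_gt(cosine, 0.9999)
  # compare decision values, not thresholded labels: many binary rows sit
  # numerically on the boundary where the sign is ill-conditioned
  s_ref <- drop(x %*% w_ref) + b_ref
  expect_lt(max(abs(predict(m, x)$score - s_ref)), 0.01)
  expect_true(m$notes$converged)
})
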