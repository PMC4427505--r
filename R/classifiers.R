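#' Class-conditional occurrence statistics
#'
#' For each feature i, the unsmoothed occurrence probabilities
#' `p_i` (fraction of relevant-class training documents with the feature) and
#' `n_i` (same for the irrelevant class).
#'
#' @param x documents-by-features matrix (binary cells for text features).
#' @param labels character/factor vector of `"relevant"` / `"irrelevant"`.
#' @return a `ddi_class_stats` list: `p`, `n` (named numeric vectors),
#'   `m_pos`, `m_neg`.
#' @export
class_occurrence_stats <- function(x, labels) {
  labels <- as.character(labels)
  pos <- labels == "relevant"
  neg <- labels == "irrelevant"
  if (!any(pos) || !any(neg)) {
    stop("both classes must be present to estimate occurrence statistics")
  }
  structure(
    list(p = colMeans(unclass_matrix(x)[pos, , drop = FALSE] != 0),
         n = colMeans(unclass_matrix(x)[neg, , drop = FALSE] != 0),
         m_pos = sum(pos), m_neg = sum(neg)),
    class = "ddi_class_stats"
  )
}

new_ddi_model <- function(weights, bias, classifier, hyperparameters = list(),
                          ner = NULL, notes = list()) {
  structure(
    list(weights = weights, bias = bias, classifier = classifier,
         hyperparameters = hyperparameters, ner = ner, notes = notes),
    class = "ddi_model"
  )
}

#' @export
print.ddi_model <- function(x, ...) {
  cat(sprintf("<ddi_model %s: %d features, bias %.4g%s>\n", x$classifier,
              length(x$weights), x$bias,
              if (!is.null(x$ner)) paste0(", ", length(x$ner$beta), " NER resource(s)")
              else ""))
  invisible(x)
}

.assert_binary_text <- function(x) {
  txt <- unclass_matrix(x)[, text_columns(x), drop = FALSE]
  if (!all(txt %in% c(0, 1))) {
    stop("this classifier requires binary text features; found non-binary cells")
  }
}

#' Variable Trigonometric Threshold classifier
#'
#' Each feature's weight is its 'angle' in binary class space,
#' `phi_i = arctan(p_i / n_i) - pi/4`, with the conventions
#' `arctan = pi/2` when `n_i = 0, p_i > 0` and `phi_i = 0` when
#' `p_i = n_i = 0`. The threshold `lambda = sum_i phi_i (p_i + n_i)/2` places
#' the neutral pseudo-document `x_i = (p_i + n_i)/2` exactly on the
#' separating hyperplane, so the model score is
#' `sum_i phi_i x_i - lambda`. The classifier expects sparse binary inputs
#' and refuses dense transformed matrices.
#'
#' @inheritParams class_occurrence_stats
#' @return a `ddi_model` with `classifier = "vtt"`.
#' @export
fit_vtt <- function(x, labels) {
  .assert_binary_text(x)
  if (length(matrix_columns_of_kind(x, "resource_count"))) {
    stop("matrix has resource-count columns; use fit_vtt_ner()")
  }
  stats <- class_occurrence_stats(x, labels)
  phi <- vtt_angles(stats$p, stats$n)
  lambda <- sum(phi * (stats$p + stats$n) / 2)
  new_ddi_model(weights = phi, bias = -lambda, classifier = "vtt",
                notes = list(lambda = lambda, stats = stats))
}

vtt_angles <- function(p, n) {
  ang <- atan2(p, n) # equals atan(p/n) for p,n >= 0, pi/2 when n=0,p>0
  ang[p == 0 & n == 0] <- pi / 4 # angle contribution defined as 0
  ang - pi / 4
}

#' VTT with named-entity count features
#'
#' The text part is a plain VTT fit; each resource j contributes an
#' additional score term in its mention count `c_j`. The default
#' (`ner_form = "linear"`) term is `beta_j * (c_j - 1)`, the literal linear
#' reading of the modified hyperplane; `ner_form = "exponential"` uses
#' `1 - beta_j^(1 - c_j)`, an alternative that is likewise 0 at `c_j = 1` and
#' monotone in `c_j` for `beta_j < 1`. Each `beta_j` is selected on the inner
#' folds by maximizing mean MCC (ties go to the smallest value), with other
#' resources held at their current values (sequentially, starting from 0).
#'
#' @inheritParams fit_vtt
#' @param beta_grid non-negative candidate values; must include 0.
#' @param inner_folds list of `list(train =, test =)` index pairs into the
#'   rows of `x` (e.g. `fold_plan$outer[[f]]$inner`).
#' @param ner_form `"linear"` or `"exponential"`.
#' @return a `ddi_model` with `classifier = "vtt_ner"` and a `ner` component
#'   (`beta`, `form`, `resources`).
#' @export
fit_vtt_ner <- function(x, labels, beta_grid = c(0, 0.01, 0.05, 0.1, 0.5, 1),
                        inner_folds, ner_form = c("linear", "exponential")) {
  ner_form <- match.arg(ner_form)
  res_cols <- matrix_columns_of_kind(x, "resource_count")
  if (!length(res_cols)) stop("no resource-count columns; use fit_vtt()")
  if (!any(beta_grid == 0)) stop("beta grid must include 0")
  beta_grid <- sort(beta_grid)
  resources <- colnames(x)[res_cols]
  labels <- as.character(labels)

  beta <- stats::setNames(rep(0, length(resources)), resources)
  for (j in resources) {
    mcc_by_beta <- vapply(beta_grid, function(b) {
      trial <- beta
      trial[j] <- b
      vals <- vapply(inner_folds, function(fold) {
        m <- .vtt_ner_model(matrix_rows(x, fold$train), labels[fold$train],
                            trial, ner_form)
        pred <- predict(m, matrix_rows(x, fold$test))
        mcc_score(confusion_from_predictions(pred$label, labels[fold$test]))
      }, numeric(1))
      mean(vals)
    }, numeric(1))
    beta[j] <- beta_grid[which.max(mcc_by_beta)] # which.max: first (smallest) on ties
  }
  .vtt_ner_model(x, labels, beta, ner_form)
}

.vtt_ner_model <- function(x, labels, beta, ner_form) {
  txt <- detach_counts(x)
  base <- fit_vtt(txt, labels)
  w <- stats::setNames(numeric(ncol(x)), colnames(x))
  w[names(base$weights)] <- base$weights
  new_ddi_model(weights = w, bias = base$bias, classifier = "vtt_ner",
                hyperparameters = list(beta = beta),
                ner = list(beta = beta, form = ner_form,
                           resources = names(beta)),
                notes = base$notes)
}

#' Bernoulli Naive Bayes with a symmetric Beta prior
#'
#' Per class, the occurrence probability of feature i is estimated by the
#' posterior mean under a Beta(alpha, alpha) prior:
#' `theta_i = (k_i + alpha) / (m + 2 alpha)`. The resulting linear model is
#' the log posterior-odds: weights
#' `w_i = log[theta_+i (1-theta_-i) / (theta_-i (1-theta_+i))]` and bias
#' `b = sum_i log[(1-theta_+i)/(1-theta_-i)] + log(m_+/m_-)` (the class-prior
#' term can be dropped with `include_prior = FALSE`).
#'
#' @inheritParams fit_vtt
#' @param alpha positive concentration parameter of the Beta prior.
#' @param include_prior include `log(m_+/m_-)` in the bias (default TRUE).
#' @return a `ddi_model` with `classifier = "naive_bayes"`.
#' @export
fit_naive_bayes <- function(x, labels, alpha = 1, include_prior = TRUE) {
  if (alpha <= 0) stop("alpha must be positive")
  .assert_binary_text(x)
  labels <- as.character(labels)
  pos <- labels == "relevant"
  neg <- labels == "irrelevant"
  if (!any(pos) || !any(neg)) stop("both classes must be present")
  x <- unclass_matrix(x)
  k_pos <- colSums(x[pos, , drop = FALSE])
  k_neg <- colSums(x[neg, , drop = FALSE])
  th_pos <- (k_pos + alpha) / (sum(pos) + 2 * alpha)
  th_neg <- (k_neg + alpha) / (sum(neg) + 2 * alpha)
  w <- log(th_pos * (1 - th_neg)) - log(th_neg * (1 - th_pos))
  b <- sum(log(1 - th_pos) - log(1 - th_neg)) +
    if (include_prior) log(sum(pos) / sum(neg)) else 0
  new_ddi_model(weights = w, bias = b, classifier = "naive_bayes",
                hyperparameters = list(alpha = alpha, include_prior = include_prior))
}

#' Diagonal linear discriminant analysis with variance shrinkage
#'
#' Estimates only per-feature pooled within-class variances `v_i` and shrinks
#' them toward their mean: `v~_i = (1 - gamma) v_i + gamma * mean(v)`.
#' Weights are `w_i = (mu_+i - mu_-i) / v~_i` with the midpoint bias
#' `b = -sum_i w_i (mu_+i + mu_-i)/2 + log(m_+/m_-)`. Equivalent to a
#' Gaussian Naive Bayes posterior-odds rule with shared per-class variances.
#'
#' @inheritParams fit_naive_bayes
#' @param gamma shrinkage intensity in `[0, 1]`.
#' @return a `ddi_model` with `classifier = "dlda"`.
#' @export
fit_dlda <- function(x, labels, gamma = 0, include_prior = TRUE) {
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  labels <- as.character(labels)
  pos <- labels == "relevant"
  neg <- labels == "irrelevant"
  if (sum(pos) < 2L || sum(neg) < 2L) stop("need >= 2 documents per class")
  x <- unclass_matrix(x)
  mu_pos <- colMeans(x[pos, , drop = FALSE])
  mu_neg <- colMeans(x[neg, , drop = FALSE])
  ss <- colSums(sweep(x[pos, , drop = FALSE], 2, mu_pos)^2) +
        colSums(sweep(x[neg, , drop = FALSE], 2, mu_neg)^2)
  v <- ss / (nrow(x) - 2)
  v_shrunk <- (1 - gamma) * v + gamma * mean(v)
  if (any(v_shrunk == 0)) {
    stop("zero shrunk variance for some feature; use gamma > 0")
  }
  w <- (mu_pos - mu_neg) / v_shrunk
  b <- -sum(w * (mu_pos + mu_neg) / 2) +
    if (include_prior) log(sum(pos) / sum(neg)) else 0
  new_ddi_model(weights = w, bias = b, classifier = "dlda",
                hyperparameters = list(gamma = gamma, include_prior = include_prior))
}

#' Regularized linear discriminant analysis
#'
#' The training matrix is first projected onto the subspace of nonzero
#' singular values of its centered version (removing rank-deficiency), the
#' pooled within-class covariance is estimated there and shrunk toward a
#' diagonal equal-variance target,
#' `Sigma_gamma = (1 - gamma) Sigma + gamma (tr(Sigma)/d) I`, and the
#' discriminant direction `w = Sigma_gamma^{-1} (mu_+ - mu_-)` is mapped back
#' to feature space. Bias is the class-midpoint rule plus the log prior odds.
#'
#' @inheritParams fit_dlda
#' @return a `ddi_model` with `classifier = "lda"`.
#' @export
fit_lda <- function(x, labels, gamma = 0, include_prior = TRUE) {
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  labels <- as.character(labels)
  pos <- labels == "relevant"
  neg <- labels == "irrelevant"
  if (sum(pos) < 2L || sum(neg) < 2L) stop("need >= 2 documents per class")
  x <- unclass_matrix(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc)
  tol <- max(sv$d) * 1e-10
  r <- sum(sv$d > tol)
  if (r < 1L) stop("training matrix is constant; LDA undefined")
  v_r <- sv$v[, seq_len(r), drop = FALSE]
  z <- xc %*% v_r
  mu_pos <- colMeans(z[pos, , drop = FALSE])
  mu_neg <- colMeans(z[neg, , drop = FALSE])
  zc <- z
  zc[pos, ] <- sweep(z[pos, , drop = FALSE], 2, mu_pos)
  zc[neg, ] <- sweep(z[neg, , drop = FALSE], 2, mu_neg)
  sigma <- crossprod(zc) / (nrow(x) - 2)
  sigma_g <- (1 - gamma) * sigma
  diag(sigma_g) <- diag(sigma_g) + gamma * (sum(diag(sigma)) / r)
  w_sub <- tryCatch(solve(sigma_g, mu_pos - mu_neg), error = function(e) {
    stop("within-class covariance is singular; use gamma > 0 (", conditionMessage(e), ")")
  })
  w <- drop(v_r %*% w_sub)
  names(w) <- colnames(x)
  mu_pos_full <- colMeans(x[pos, , drop = FALSE])
  mu_neg_full <- colMeans(x[neg, , drop = FALSE])
  b <- -sum(w * (mu_pos_full + mu_neg_full) / 2) +
    if (include_prior) log(sum(pos) / sum(neg)) else 0
  new_ddi_model(weights = w, bias = b, classifier = "lda",
                hyperparameters = list(gamma = gamma, include_prior = include_prior),
                notes = list(rank = r))
}

#' L2-regularized SVM or logistic regression
#'
#' The penalized-loss objective `1/2 ||w||^2 + C * sum_d loss(y_d, s_d)` with
#' hinge loss (linear SVM, solved by the package's compiled dual
#' coordinate-descent routine, the standard large-scale linear-SVM algorithm;
#' the bias enters as an augmented constant feature) or logistic loss (solved
#' by the ridge path in \pkg{glmnet} with `lambda = 1/(n C)`, which makes the
#' two parameterizations proportional). Solver tolerances and iteration caps
#' are fixed and recorded in the returned model.
#'
#' @inheritParams fit_vtt
#' @param loss `"logistic"` or `"hinge"`.
#' @param C positive regularization strength (large C = weak regularization).
#' @param tol,max_epochs hinge-solver convergence tolerance (on the maximal
#'   projected gradient) and epoch cap.
#' @return a `ddi_model` with `classifier = "logreg"` or `"svm"`.
#' @export
fit_regularized_linear <- function(x, labels, loss = c("logistic", "hinge"),
                                   C = 1, tol = 1e-2, max_epochs = 100L) {
  loss <- match.arg(loss)
  if (C <= 0) stop("C must be positive")
  y <- factor(as.character(labels), levels = c("irrelevant", "relevant"))
  if (any(is.na(y))) stop("labels must be 'relevant'/'irrelevant'")
  if (nlevels(droplevels(y)) < 2L) stop("both classes must be present")
  xm <- unclass_matrix(x)
  if (loss == "hinge") {
    yy <- ifelse(y == "relevant", 1, -1)
    fit <- local_seed(760013L, .svm_dcd(xm, yy, C, 1, tol, as.integer(max_epochs)))
    w <- stats::setNames(fit$weights, colnames(xm))
    return(new_ddi_model(weights = w, bias = fit$bias, classifier = "svm",
                         hyperparameters = list(C = C, tol = tol,
                                                max_epochs = max_epochs),
                         notes = list(converged = fit$converged,
                                      epochs = fit$epochs)))
  }
  n <- nrow(xm)
  lam <- 1 / (n * C)
  fit <- glmnet::glmnet(xm, y, family = "binomial", alpha = 0, lambda = lam,
                        standardize = FALSE, thresh = 1e-10, maxit = 1e6)
  cf <- as.matrix(stats::coef(fit))
  w <- cf[-1, 1]
  names(w) <- colnames(xm)
  new_ddi_model(weights = w, bias = cf[1, 1], classifier = "logreg",
                hyperparameters = list(C = C, lambda = lam))
}

#' Predict scores and labels from a fitted linear model
#'
#' The confidence score is `sum_i w_i x_i + b` plus, for NER-aware VTT
#' models, the per-resource count terms. The predicted label is `relevant`
#' iff the score is strictly positive (scores of exactly 0 go to
#' `irrelevant`).
#'
#' @param object a `ddi_model`.
#' @param newdata documents-by-features matrix in the model's feature space.
#' @param ... unused.
#' @return a tibble with columns `document`, `score`, `label`.
#' @export
predict.ddi_model <- function(object, newdata, ...) {
  xm <- unclass_matrix(newdata)
  if (ncol(xm) != length(object$weights) ||
      (!is.null(colnames(xm)) && !is.null(names(object$weights)) &&
       !identical(colnames(xm), names(object$weights)))) {
    stop("feature space of newdata does not match the model")
  }
  score <- drop(xm %*% object$weights) + object$bias
  if (!is.null(object$ner)) {
    for (j in object$ner$resources) {
      cj <- xm[, j]
      bj <- object$ner$beta[[j]]
      term <- if (object$ner$form == "linear") {
        bj * (cj - 1)
      } else if (bj == 0) {
        rep(0, length(cj))
      } else {
        1 - bj^(1 - cj)
      }
      # the textual weight slot for resource columns is zero; add the NER term
      score <- score + term
    }
  }
  tibble::tibble(
    document = rownames(xm) %||% as.character(seq_len(nrow(xm))),
    score = unname(score),
    label = ifelse(score > 0, "relevant", "irrelevant")
  )
}
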