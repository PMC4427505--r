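#' Default hyperparameter grids
#'
#' Regularization strength C for SVM/logistic regression (7 log-spaced
#' values), Beta-prior concentration alpha for Naive Bayes, covariance
#' shrinkage gamma for LDA/dLDA, NER weight beta for the VTT, and the PCA
#' dimensionalities evaluated as separate configurations.
#'
#' @return a named list of numeric grids.
#' @export
default_grids <- function() {
  list(
    C = 10^seq(-3, 3),
    alpha = c(0.01, 0.1, 0.5, 1, 2, 5, 10),
    gamma = seq(0, 1, by = 0.1),
    beta = c(0, 0.01, 0.05, 0.1, 0.5, 1),
    pca_k = c(100, 200, 400, 600, 800, 1000)
  )
}

#' Experiment configuration
#'
#' Bundles every choice that defines one pipeline run: classifier, n-gram
#' order, metadata usage, transform chain, NER resources and grids.
#'
#' @param classifier one of `"vtt"`, `"svm"`, `"logreg"`, `"naive_bayes"`,
#'   `"lda"`, `"dlda"`.
#' @param ngram_order `"bigram"` (unigrams + bigrams) or `"unigram"`.
#' @param include_metadata emit metadata features (abstract corpora only).
#' @param metadata_fields metadata field subset, for ablation experiments.
#' @param transform `"none"`, `"idf"` or `"tfidf"`.
#' @param l2 apply L2 length normalization.
#' @param pca_k `NULL` or the number of principal components.
#' @param lexicons optional list of `ddi_lexicon` resources whose mention
#'   counts are attached as features.
#' @param ner_form VTT NER term form, `"linear"` or `"exponential"`.
#' @param include_prior include the log class-prior odds in NB/LDA/dLDA bias.
#' @param vocabulary_scope `"corpus"` builds the vocabulary once on the full
#'   corpus before fold splitting (the pipeline default); `"train"` rebuilds
#'   it per training split (strict leak-free mode).
#' @param grids hyperparameter grids, see [default_grids()].
#' @param label free-text configuration label used in reports.
#' @return a `ddi_config` list.
#' @export
pipeline_config <- function(classifier = c("vtt", "svm", "logreg",
                                           "naive_bayes", "lda", "dlda"),
                            ngram_order = c("bigram", "unigram"),
                            include_metadata = TRUE,
                            metadata_fields = c("mesh", "rn", "si",
                                                "authors", "journal"),
                            transform = c("none", "idf", "tfidf"),
                            l2 = FALSE, pca_k = NULL, lexicons = NULL,
                            ner_form = c("linear", "exponential"),
                            include_prior = TRUE,
                            vocabulary_scope = c("corpus", "train"),
                            grids = default_grids(), label = NULL) {
  classifier <- match.arg(classifier)
  ngram_order <- match.arg(ngram_order)
  transform <- match.arg(transform)
  ner_form <- match.arg(ner_form)
  vocabulary_scope <- match.arg(vocabulary_scope)
  dense <- transform != "none" || l2 || !is.null(pca_k)
  if (classifier == "vtt" && dense) {
    stop("VTT requires sparse binary inputs; feature transforms are not supported")
  }
  if (classifier == "naive_bayes" && !is.null(lexicons)) {
    stop("Naive Bayes does not accept non-binary NER count features")
  }
  if (!is.null(lexicons) && inherits(lexicons, "ddi_lexicon")) lexicons <- list(lexicons)
  structure(
    list(classifier = classifier, ngram_order = ngram_order,
         include_metadata = include_metadata, metadata_fields = metadata_fields,
         transform = transform, l2 = l2, pca_k = pca_k, lexicons = lexicons,
         ner_form = ner_form, include_prior = include_prior,
         vocabulary_scope = vocabulary_scope, grids = grids,
         label = label %||% paste0(
           classifier, "/", ngram_order,
           if (transform != "none") paste0("+", transform) else "",
           if (l2) "+l2" else "",
           if (!is.null(pca_k)) paste0("+pca", pca_k) else "",
           if (!is.null(lexicons)) paste0(
             "+", paste(vapply(lexicons, `[[`, character(1), "resource_name"),
                        collapse = ",")) else ""
         )),
    class = "ddi_config"
  )
}

# fit function dispatch for the tunable classifiers
.classifier_fitter <- function(config) {
  switch(config$classifier,
    svm = function(x, y, v) fit_regularized_linear(x, y, "hinge", C = v),
    logreg = function(x, y, v) fit_regularized_linear(x, y, "logistic", C = v),
    naive_bayes = function(x, y, v)
      fit_naive_bayes(x, y, alpha = v, include_prior = config$include_prior),
    lda = function(x, y, v)
      fit_lda(x, y, gamma = v, include_prior = config$include_prior),
    dlda = function(x, y, v)
      fit_dlda(x, y, gamma = v, include_prior = config$include_prior),
    vtt = NULL
  )
}

.classifier_grid <- function(config) {
  switch(config$classifier,
    svm = , logreg = config$grids$C,
    naive_bayes = config$grids$alpha,
    lda = , dlda = config$grids$gamma,
    vtt = NULL
  )
}

#' Evaluate one configuration under a fold plan
#'
#' For every outer fold: fit the transform chain on the training split only,
#' choose the classifier hyperparameter on the nested inner folds by mean
#' MCC, train on the outer training split, and score the held-out test
#' split with F1, MCC and iAUC. The report collects the 16 per-fold triples;
#' their arithmetic means estimate generalization performance.
#'
#' @param corpus a labeled `ddi_corpus`.
#' @param config a `ddi_config`.
#' @param plan a nested `ddi_fold_plan` for this corpus. All configurations
#'   compared against each other must share the plan.
#' @return a `ddi_eval`: tibble with one row per outer fold (`repeat_ix`,
#'   `fold_ix`, `f1`, `mcc`, `iauc`, `hyperparameter`), with the
#'   configuration and plan metadata in attributes.
#' @export
evaluate_configuration <- function(corpus, config, plan) {
  stopifnot(inherits(config, "ddi_config"), inherits(plan, "ddi_fold_plan"))
  if (plan$n != nrow(corpus)) stop("fold plan does not match corpus size")
  labels <- corpus$label
  full_x <- NULL
  if (config$vocabulary_scope == "corpus") {
    full_x <- .featurize(corpus, config)
  }
  rows <- purrr::map(plan$outer, function(fold) {
    if (is.null(full_x)) {
      vocab <- build_vocabulary(
        corpus[fold$train, ], config$ngram_order,
        config$include_metadata && corpus_unit(corpus) == "abstract",
        config$metadata_fields
      )
      x <- vectorize(corpus, vocab)
      if (!is.null(config$lexicons)) {
        x <- attach_counts(x, compute_resource_counts(corpus, config$lexicons))
      }
    } else {
      x <- full_x
    }
    chain <- NULL
    if (config$transform != "none" || config$l2 || !is.null(config$pca_k)) {
      chain <- fit_transform_chain(matrix_rows(x, fold$train),
                                   transform = config$transform,
                                   l2 = config$l2, pca_k = config$pca_k)
      x_use <- apply_transform_chain(chain, x)
    } else {
      x_use <- x
    }
    fit <- .fit_outer(x_use, labels, config, fold, chain)
    pred <- predict(fit$model, matrix_rows_generic(x_use, fold$test))
    truth <- labels[fold$test]
    conf <- confusion_from_predictions(pred$label, truth)
    tibble::tibble(
      repeat_ix = fold$repeat_ix, fold_ix = fold$fold_ix,
      f1 = f1_score(conf), mcc = mcc_score(conf),
      iauc = iauc_score(pred$score, truth),
      hyperparameter = fit$hyper_label
    )
  })
  report <- dplyr::bind_rows(rows)
  structure(report,
            config = config, plan_seed = plan$seed, plan_n = plan$n,
            class = c("ddi_eval", class(report)))
}

# transform-aware nested hyperparameter selection + final fit on one outer fold
.fit_outer <- function(x_use, labels, config, fold, chain) {
  labels <- as.character(labels)
  x_tr <- matrix_rows_generic(x_use, fold$train)
  y_tr <- labels[fold$train]
  if (config$classifier == "vtt") {
    if (!is.null(config$lexicons)) {
      # beta selection needs inner folds re-indexed into x_use rows
      model <- fit_vtt_ner(x_use, labels, beta_grid = config$grids$beta,
                           inner_folds = fold$inner, ner_form = config$ner_form)
      # refit text part on the training split only, keeping selected beta
      model <- .vtt_ner_model(x_tr, y_tr, model$ner$beta, config$ner_form)
      return(list(model = model,
                  hyper_label = paste(names(model$ner$beta), "=",
                                      model$ner$beta, collapse = "; ")))
    }
    return(list(model = fit_vtt(x_tr, y_tr), hyper_label = NA_character_))
  }
  fitter <- .classifier_fitter(config)
  grid <- .classifier_grid(config)
  if (is.null(fold$inner)) stop("fold plan has no inner folds for hyperparameter selection")
  chosen <- select_hyperparameter(fitter, grid, x_use, labels, fold$inner)
  list(model = fitter(x_tr, y_tr, as.numeric(chosen)),
       hyper_label = format(as.numeric(chosen)))
}

# build the full-corpus occurrence matrix for a configuration
.featurize <- function(corpus, config) {
  vocab <- build_vocabulary(
    corpus, config$ngram_order,
    config$include_metadata && corpus_unit(corpus) == "abstract",
    config$metadata_fields
  )
  x <- vectorize(corpus, vocab)
  if (!is.null(config$lexicons)) {
    x <- attach_counts(x, compute_resource_counts(corpus, config$lexicons))
  }
  x
}

#' @rdname evaluate_configuration
#' @export
featurize_corpus <- function(corpus, config) .featurize(corpus, config)

#' Pairwise permutation comparison of configurations
#'
#' Exact paired sign-flip permutation tests between all pairs of reports on
#' one shared fold plan, plus flags for the best configuration and every
#' configuration not significantly different from it (one-tailed p > 0.05).
#'
#' @param reports list of `ddi_eval` reports sharing one fold plan.
#' @param measure `"iauc"`, `"mcc"` or `"f1"`.
#' @param tails `"one"` or `"two"` (pairwise table only; the
#'   indistinguishable-from-best flag always uses the one-tailed test).
#' @param alpha significance level for the flags.
#' @return a list with `pairwise` (tibble of p-values) and `summary`
#'   (per-configuration means with `best` / `indistinguishable_from_best`).
#' @export
compare_configurations <- function(reports, measure = c("iauc", "mcc", "f1"),
                                   tails = c("one", "two"), alpha = 0.05) {
  measure <- match.arg(measure)
  tails <- match.arg(tails)
  stopifnot(length(reports) >= 2L)
  seeds <- vapply(reports, attr, numeric(1), "plan_seed")
  ns <- vapply(reports, attr, numeric(1), "plan_n")
  if (length(unique(seeds)) != 1L || length(unique(ns)) != 1L) {
    stop("reports were not evaluated on the same fold plan")
  }
  labs <- vapply(reports, function(r) attr(r, "config")$label, character(1))
  vals <- lapply(reports, function(r) r[[measure]])
  means <- vapply(vals, mean, numeric(1))
  pairs <- utils::combn(length(reports), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tibble::tibble(
      config_a = labs[i], config_b = labs[j], measure = measure,
      mean_a = means[i], mean_b = means[j],
      p_value = paired_permutation_test(vals[[i]], vals[[j]], tails = tails)
    )
  })
  best <- which.max(means)
  indist <- vapply(seq_along(reports), function(i) {
    if (i == best) return(TRUE)
    paired_permutation_test(vals[[best]], vals[[i]], tails = "one") > alpha
  }, logical(1))
  list(
    pairwise = pairwise,
    summary = tibble::tibble(configuration = labs, mean = means,
                             best = seq_along(labs) == best,
                             indistinguishable_from_best = indist)
  )
}

#' Run a full experiment and write its artifacts
#'
#' End-to-end configuration run: featurize, evaluate under a (freshly built
#' or supplied) nested fold plan, and write the fold plan, per-fold metrics,
#' means, chosen hyperparameters and top-feature lists to `out_dir`.
#'
#' @param corpus a labeled `ddi_corpus`.
#' @param config a `ddi_config`.
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param plan optional pre-built `ddi_fold_plan`; by default one is built
#'   from `seed`.
#' @param seed seed for the fold plan.
#' @param repeats,folds plan geometry.
#' @return a list with `report` (the `ddi_eval`), `plan`, `model` (fitted on
#'   the full corpus for feature inspection) and `paths`.
#' @export
run_experiment <- function(corpus, config, out_dir = NULL, plan = NULL,
                           seed = 1L, repeats = 4L, folds = 4L) {
  if (is.null(plan)) plan <- make_fold_plan(corpus, repeats, folds, seed = seed)
  report <- evaluate_configuration(corpus, config, plan)
  x <- .featurize(corpus, config)
  full_model <- .full_corpus_model(x, corpus$label, config, plan)
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$plan <- write_fold_plan(plan, file.path(out_dir, "fold_plan.json"))
    paths$folds <- file.path(out_dir, "fold_metrics.tsv")
    readr::write_tsv(tibble::as_tibble(report), paths$folds, progress = FALSE)
    paths$means <- file.path(out_dir, "mean_metrics.tsv")
    readr::write_tsv(glance(report), paths$means, progress = FALSE)
    paths$features <- file.path(out_dir, "top_features.tsv")
    readr::write_tsv(top_features(full_model, k = min(20, length(full_model$weights))),
                     paths$features, progress = FALSE)
    paths$model <- file.path(out_dir, "model.json")
    write_model(full_model, paths$model)
  }
  list(report = report, plan = plan, model = full_model, paths = paths)
}

# full-corpus fit used for feature-importance reporting
.full_corpus_model <- function(x, labels, config, plan) {
  chain <- NULL
  x_use <- x
  if (config$transform != "none" || config$l2 || !is.null(config$pca_k)) {
    chain <- fit_transform_chain(x, transform = config$transform,
                                 l2 = config$l2, pca_k = config$pca_k)
    x_use <- apply_transform_chain(chain, x)
  }
  labels <- as.character(labels)
  if (config$classifier == "vtt") {
    if (!is.null(config$lexicons)) {
      return(fit_vtt_ner(x_use, labels, beta_grid = config$grids$beta,
                         inner_folds = plan$outer[[1]]$inner,
                         ner_form = config$ner_form))
    }
    return(fit_vtt(x_use, labels))
  }
  fitter <- .classifier_fitter(config)
  chosen <- select_hyperparameter(fitter, .classifier_grid(config), x_use,
                                  labels, plan$outer[[1]]$inner)
  fitter(x_use, labels, as.numeric(chosen))
}

#' Serialize a fitted model to JSON
#'
#' @param model a `ddi_model`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(
    list(classifier = model$classifier,
         weights = as.list(model$weights), bias = model$bias,
         hyperparameters = model$hyperparameters,
         ner = model$ner,
         vocabulary_hash = digest_features(names(model$weights))),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

# order-sensitive checksum of the feature list (base R, no extra deps)
digest_features <- function(features) {
  if (is.null(features)) return(NA_character_)
  x <- paste(features, collapse = "")
  raw <- utf8ToInt(x)
  h1 <- 0; h2 <- 0
  for (v in raw) {
    h1 <- (h1 * 31 + v) %% 2147483647
    h2 <- (h2 * 131 + v) %% 2147483629
  }
  sprintf("%d-%d-%d", length(features), h1, h2)
}
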