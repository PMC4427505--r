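#' Repeated nested cross-validation fold plan
#'
#' Each repeat partitions the documents uniformly at random into `folds`
#' near-equal folds; each fold in turn is the 25% test split while the
#' remaining 75% is the training split, giving `repeats * folds` outer
#' folds. Inside each outer training split the same scheme builds
#' `repeats * folds` inner folds used for hyperparameter selection. The plan
#' is fully determined by `seed`, and all configurations of an experiment are
#' meant to share one plan. Folds are not stratified by class.
#'
#' @param corpus a `ddi_corpus`, or an integer number of documents.
#' @param repeats,folds plan geometry (defaults 4 x 4 = 16 outer folds).
#' @param seed integer seed the plan is regenerated from.
#' @param inner logical; also build the nested inner plans.
#' @return a `ddi_fold_plan`: list with `n`, `ids`, `seed`, geometry and
#'   `outer`, a list of `list(repeat_ix, fold_ix, train, test, inner)` where
#'   `inner` is a list of `list(train, test)` index pairs (indices into the
#'   full document set).
#' @export
make_fold_plan <- function(corpus, repeats = 4L, folds = 4L, seed = 1L,
                           inner = TRUE) {
  n <- if (is.numeric(corpus)) as.integer(corpus) else nrow(corpus)
  ids <- if (is.numeric(corpus)) as.character(seq_len(n)) else corpus_doc_ids(corpus)
  if (n < folds) stop("corpus smaller than the number of folds")
  outer <- local_seed(seed, {
    plan <- list()
    for (r in seq_len(repeats)) {
      assignment <- .random_partition(n, folds)
      for (f in seq_len(folds)) {
        test <- which(assignment == f)
        train <- which(assignment != f)
        entry <- list(repeat_ix = r, fold_ix = f, train = train, test = test)
        if (inner) {
          entry$inner <- list()
          for (ri in seq_len(repeats)) {
            a_in <- .random_partition(length(train), folds)
            for (fi in seq_len(folds)) {
              entry$inner[[length(entry$inner) + 1L]] <-
                list(train = train[a_in != fi], test = train[a_in == fi])
            }
          }
        }
        plan[[length(plan) + 1L]] <- entry
      }
    }
    plan
  })
  structure(
    list(n = n, ids = ids, repeats = repeats, folds = folds, seed = seed,
         outer = outer),
    class = "ddi_fold_plan"
  )
}

# near-equal random partition of n items into k groups (sizes differ by <= 1)
.random_partition <- function(n, k) {
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  sample(rep(seq_len(k), sizes))
}

# evaluate a block with a private RNG stream, restoring the caller's state
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' @export
print.ddi_fold_plan <- function(x, ...) {
  cat(sprintf("<ddi_fold_plan: %d docs, %d x %d outer folds, seed %d%s>\n",
              x$n, x$repeats, x$folds, x$seed,
              if (!is.null(x$outer[[1]]$inner)) " (nested)" else ""))
  invisible(x)
}

#' Serialize / replay a fold plan
#'
#' @param plan a `ddi_fold_plan`.
#' @param path JSON output path.
#' @return `path` invisibly.
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(
    list(n = plan$n, ids = plan$ids, repeats = plan$repeats,
         folds = plan$folds, seed = plan$seed,
         outer = lapply(plan$outer, function(e) {
           list(repeat_ix = e$repeat_ix, fold_ix = e$fold_ix,
                train = e$train, test = e$test)
         })),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' Select a hyperparameter value by inner-fold mean MCC
#'
#' For each candidate value the model is trained on each inner 75% split and
#' its MCC measured on the inner 25% split; the value with the highest mean
#' MCC wins, ties going to the smallest value. A value whose training fails
#' on any inner fold is disqualified with a warning.
#'
#' @param fit_fun function `(x_train, labels_train, value)` returning a
#'   `ddi_model`.
#' @param grid non-empty numeric vector of candidate values.
#' @param x full document matrix (inner fold indices index into its rows).
#' @param labels full label vector.
#' @param inner_folds list of `list(train =, test =)` index pairs.
#' @return the chosen grid value, with the per-value mean MCCs in
#'   `attr(, "mean_mcc")`.
#' @export
select_hyperparameter <- function(fit_fun, grid, x, labels, inner_folds) {
  if (!length(grid)) stop("hyperparameter grid is empty")
  grid <- sort(grid)
  labels <- as.character(labels)
  mean_mcc <- rep(NA_real_, length(grid))
  fold_data <- lapply(inner_folds, function(fold) {
    list(x_tr = matrix_rows_generic(x, fold$train), y_tr = labels[fold$train],
         x_te = matrix_rows_generic(x, fold$test), y_te = labels[fold$test])
  })
  for (g in seq_along(grid)) {
    vals <- tryCatch(
      vapply(fold_data, function(fd) {
        m <- fit_fun(fd$x_tr, fd$y_tr, grid[g])
        pred <- predict(m, fd$x_te)
        mcc_score(confusion_from_predictions(pred$label, fd$y_te))
      }, numeric(1)),
      error = function(e) {
        warning("grid value ", grid[g], " disqualified: ", conditionMessage(e))
        NULL
      }
    )
    if (!is.null(vals)) mean_mcc[g] <- mean(vals)
  }
  if (all(is.na(mean_mcc))) stop("every grid value failed during inner cross-validation")
  best <- which(mean_mcc == max(mean_mcc, na.rm = TRUE))[1] # smallest on ties
  structure(grid[best], mean_mcc = stats::setNames(mean_mcc, grid))
}

matrix_rows_generic <- function(x, rows) {
  if (inherits(x, "occurrence_matrix")) matrix_rows(x, rows)
  else x[rows, , drop = FALSE]
}

#' Exact paired sign-flip permutation test
#'
#' For per-fold paired metric vectors `a` and `b`, enumerates all `2^F` sign
#' assignments of the differences `d_f = a_f - b_f` and uses the mean
#' difference as the test statistic. The one-tailed p-value is the fraction
#' of permuted means at least as large as the observed mean; the two-tailed
#' p-value uses absolute values. Counting is non-strict (>=) and includes the
#' identity permutation, so `p >= 2^-F`.
#'
#' @param a,b numeric vectors of per-fold metrics, equal length `F <= 20`.
#' @param tails `"one"` or `"two"`.
#' @return the exact p-value.
#' @export
paired_permutation_test <- function(a, b, tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (length(a) != length(b)) stop("paired vectors differ in length")
  f <- length(a)
  if (f > 20L) stop("F > 20: exact enumeration infeasible; Monte-Carlo mode not supported")
  d <- a - b
  obs <- mean(d)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), f)))
  perm_means <- drop(signs %*% d) / f
  eps <- 1e-12
  if (tails == "one") {
    mean(perm_means >= obs - eps)
  } else {
    mean(abs(perm_means) >= abs(obs) - eps)
  }
}
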