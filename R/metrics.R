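#' Confusion counts with `relevant` as the positive class
#'
#' @param pred_labels,true_labels character vectors of equal length with
#'   values `"relevant"` / `"irrelevant"`.
#' @return a `ddi_confusion` list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_from_predictions <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels)) {
    stop("prediction and truth vectors differ in length")
  }
  pred <- as.character(pred_labels) == "relevant"
  truth <- as.character(true_labels) == "relevant"
  structure(
    list(TP = sum(pred & truth), FP = sum(pred & !truth),
         TN = sum(!pred & !truth), FN = sum(!pred & truth)),
    class = "ddi_confusion"
  )
}

#' @rdname confusion_from_predictions
#' @param TP,FP,TN,FN non-negative integer counts.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN), class = "ddi_confusion")
}

#' Balanced F1 score
#'
#' Harmonic mean of precision and recall; defined as 0 when `TP = 0`.
#'
#' @param confusion a `ddi_confusion`.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(confusion) {
  tp <- confusion$TP
  if (tp == 0) return(0)
  p <- tp / (tp + confusion$FP)
  r <- tp / (tp + confusion$FN)
  2 * p * r / (p + r)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the standard
#' convention of 0 whenever a denominator factor vanishes (e.g. all
#' predictions in one class).
#'
#' @param confusion a `ddi_confusion`.
#' @return MCC in `[-1, 1]`.
#' @export
mcc_score <- function(confusion) {
  tp <- as.numeric(confusion$TP); fp <- as.numeric(confusion$FP)
  tn <- as.numeric(confusion$TN); fn <- as.numeric(confusion$FN)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Area under the interpolated precision-recall curve
#'
#' Documents are ranked by descending confidence score; tied scores are
#' grouped into a single cut. After each distinct score value the
#' (recall, precision) operating point is recorded, the interpolated
#' precision at recall level r is the maximum precision over cuts with
#' recall >= r, and the iAUC averages the interpolated precision over the P
#' recall levels `k/P`, k = 1..P, where P is the number of positives.
#' Invariant to strictly monotone transformations of the scores.
#'
#' @param scores numeric confidence scores (higher = more relevant).
#' @param labels `"relevant"` / `"irrelevant"` truth labels.
#' @return iAUC in `(0, 1]`.
#' @export
iauc_score <- function(scores, labels) {
  truth <- as.character(labels) == "relevant"
  if (length(scores) != length(truth)) stop("scores and labels differ in length")
  npos <- sum(truth)
  if (npos == 0) stop("iAUC undefined without positive items")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  t <- truth[o]
  cut_at <- cumsum(rle(s)$lengths) # last index of each tied score group
  tp <- cumsum(t)[cut_at]
  k <- cut_at
  precision <- tp / k
  recall <- tp / npos
  levels_r <- seq_len(npos) / npos
  interp <- vapply(levels_r, function(r) {
    max(precision[recall >= r - 1e-12])
  }, numeric(1))
  mean(interp)
}

#' Competition ("1224") ranks
#'
#' Tied values share the minimal rank; the next distinct value's rank is one
#' plus the number of strictly better entries.
#'
#' @param values numeric vector.
#' @param higher_is_better logical; if `FALSE`, smaller values rank first.
#' @return integer vector of ranks.
#' @export
competition_ranks <- function(values, higher_is_better = TRUE) {
  if (!length(values)) stop("cannot rank an empty vector")
  v <- if (higher_is_better) -values else values
  vapply(v, function(x) 1L + sum(v < x), integer(1))
}

#' Rank product of F1, MCC and iAUC across configurations
#'
#' Ranks each configuration's across-fold mean F1, MCC and iAUC by
#' competition ranking and multiplies the three ranks into the RP3 summary.
#'
#' @param reports a list of `ddi_eval` reports, or a data frame with columns
#'   `f1`, `mcc` and `iauc` (one row per configuration) and optionally a
#'   `configuration` label column.
#' @return a `ddi_rank_table` tibble with per-measure ranks and `rp3`,
#'   sorted by increasing `rp3`.
#' @export
rank_product_rp3 <- function(reports) {
  if (is.data.frame(reports)) {
    means <- tibble::as_tibble(reports)
    if (!"configuration" %in% names(means)) {
      means$configuration <- paste0("config_", seq_len(nrow(means)))
    }
  } else {
    if (inherits(reports, "ddi_eval")) reports <- list(reports)
    means <- purrr::map_dfr(reports, function(r) {
      g <- glance(r)
      tibble::tibble(configuration = g$configuration, f1 = g$f1, mcc = g$mcc,
                     iauc = g$iauc)
    })
  }
  stopifnot(all(c("f1", "mcc", "iauc") %in% names(means)))
  out <- means |>
    dplyr::mutate(
      rank_f1 = competition_ranks(.data$f1),
      rank_mcc = competition_ranks(.data$mcc),
      rank_iauc = competition_ranks(.data$iauc),
      rp3 = .data$rank_f1 * .data$rank_mcc * .data$rank_iauc
    ) |>
    dplyr::arrange(.data$rp3)
  structure(out, class = c("ddi_rank_table", class(out)))
}

#' Most discriminative features of a fitted linear model
#'
#' Features are ordered by hyperplane coefficient: large positive weights
#' push documents toward the relevant class, large negative weights toward
#' the irrelevant class. With `standardized = TRUE` each weight is multiplied
#' by the training-split standard deviation of its feature (for a binary
#' feature with occurrence rate q, `sqrt(q (1 - q))`).
#'
#' @param model a `ddi_model`.
#' @param k how many features per direction.
#' @param standardized logical; report standardized coefficients.
#' @param train training matrix (required when `standardized = TRUE`).
#' @return a tibble with columns `direction` (`relevant`/`irrelevant`),
#'   `rank`, `feature`, `weight`.
#' @export
top_features <- function(model, k = 20, standardized = FALSE, train = NULL) {
  w <- model$weights
  if (standardized) {
    if (is.null(train)) stop("standardized coefficients need the training matrix")
    sdv <- apply(unclass_matrix(train), 2, stats::sd)
    w <- w * sdv
  }
  if (k > length(w)) {
    warning("k exceeds the number of features; clipped to ", length(w))
    k <- length(w)
  }
  o <- order(w, decreasing = TRUE)
  dplyr::bind_rows(
    tibble::tibble(direction = "relevant", rank = seq_len(k),
                   feature = names(w)[o[seq_len(k)]],
                   weight = unname(w[o[seq_len(k)]])),
    tibble::tibble(direction = "irrelevant", rank = seq_len(k),
                   feature = names(w)[rev(o)[seq_len(k)]],
                   weight = unname(w[rev(o)[seq_len(k)]]))
  )
}
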