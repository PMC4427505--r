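#' Inverse document frequency statistics
#'
#' Fits per-feature IDF values on a training occurrence matrix:
#' `idf_i = log(N / (c_i + 1))` with natural logarithm, where `N` is the
#' number of training documents and `c_i` the number of training documents in
#' which feature i occurs (binary cells, so total occurrences = document
#' frequency). A feature occurring in every document gets a slightly negative
#' IDF (`log(N/(N+1))`), which is permitted.
#'
#' @param train numeric documents-by-features matrix (binary cells).
#' @return a `ddi_transform` of type `"idf"` carrying `N` and `idf`.
#' @export
fit_idf <- function(train) {
  if (!nrow(train) || !ncol(train)) stop("cannot fit IDF on an empty matrix")
  n <- nrow(train)
  c_i <- colSums(train != 0)
  structure(
    list(type = "idf", N = n, c_i = c_i, idf = log(n / (c_i + 1)),
         features = colnames(train)),
    class = "ddi_transform"
  )
}

#' Apply an IDF or TFIDF transform
#'
#' Each cell becomes `x_i * idf_i`. With `tf_normalize = TRUE` (TFIDF) each
#' row is additionally divided by that document's count of occurring
#' features; all-zero rows pass through unchanged.
#'
#' @param x occurrence matrix to transform (train or test rows).
#' @param stats a `ddi_transform` from [fit_idf()].
#' @param tf_normalize logical; `TRUE` gives TFIDF.
#' @return a real-valued matrix of the same shape.
#' @export
apply_idf <- function(x, stats, tf_normalize = FALSE) {
  stopifnot(inherits(stats, "ddi_transform"), stats$type == "idf")
  if (!identical(colnames(x), stats$features)) {
    stop("feature mismatch between matrix and fitted IDF statistics")
  }
  out <- sweep(unclass_matrix(x), 2, stats$idf, `*`)
  if (tf_normalize) {
    k <- rowSums(x != 0)
    k[k == 0] <- 1 # all-zero rows pass through
    out <- out / k
  }
  out
}

#' L2-normalize document vectors
#'
#' Each nonzero row is scaled to unit Euclidean norm; zero rows are left
#' unchanged.
#'
#' @param x real-valued matrix.
#' @return matrix of the same shape.
#' @export
l2_normalize <- function(x) {
  nrm <- sqrt(rowSums(unclass_matrix(x)^2))
  nrm[nrm == 0] <- 1
  unclass_matrix(x) / nrm
}

#' Principal component projection fitted on training documents
#'
#' Mean-centered PCA via singular value decomposition; components are ordered
#' by decreasing explained variance and sign-fixed so each component's
#' largest-magnitude loading is positive. If `k` exceeds the rank of the
#' centered training matrix it is clipped to the rank (the effective value is
#' recorded in the returned stats).
#'
#' @param train real-valued training matrix (at least 2 rows).
#' @param k number of components to retain.
#' @return a `ddi_transform` of type `"pca"` with `mean`, `basis`
#'   (features x k), `sdev` and the effective `k`.
#' @export
fit_pca <- function(train, k) {
  if (nrow(train) < 2L) stop("PCA needs at least 2 training documents")
  if (k < 1L) stop("k must be >= 1")
  train <- unclass_matrix(train)
  mu <- colMeans(train)
  xc <- sweep(train, 2, mu)
  sv <- svd(xc)
  tol <- max(sv$d) * 1e-10
  rank <- sum(sv$d > tol)
  if (rank < 1L) stop("training matrix has rank 0; PCA undefined")
  k_eff <- as.integer(min(k, rank))
  basis <- sv$v[, seq_len(k_eff), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(k_eff)) {
    pivot <- which.max(abs(basis[, j]))
    if (basis[pivot, j] < 0) basis[, j] <- -basis[, j]
  }
  rownames(basis) <- colnames(train)
  structure(
    list(type = "pca", mean = mu, basis = basis,
         sdev = sv$d[seq_len(k_eff)] / sqrt(nrow(train) - 1),
         k = k_eff, k_requested = k, features = colnames(train)),
    class = "ddi_transform"
  )
}

#' @rdname fit_pca
#' @param x matrix of rows to project (train or test).
#' @param stats a `ddi_transform` from [fit_pca()].
#' @export
project_pca <- function(x, stats) {
  stopifnot(inherits(stats, "ddi_transform"), stats$type == "pca")
  x <- unclass_matrix(x)
  if (ncol(x) != length(stats$mean)) {
    stop("dimension mismatch: matrix has ", ncol(x), " features, PCA expects ",
         length(stats$mean))
  }
  scores <- sweep(x, 2, stats$mean) %*% stats$basis
  colnames(scores) <- paste0("PC", seq_len(stats$k))
  scores
}

#' Fit and apply a feature transform chain
#'
#' Composition order is `{none | idf | tfidf}` then optional L2
#' normalization then optional PCA. All statistics are estimated on the
#' training rows only; `apply_transform_chain()` can then be used on any
#' compatible rows (train or test) without touching the fitted statistics.
#' Resource-count columns, when present, are passed through untransformed and
#' re-attached after the chain (transforms are defined on the text features).
#'
#' @param train training occurrence matrix.
#' @param transform `"none"`, `"idf"` or `"tfidf"`.
#' @param l2 logical; apply L2 length normalization.
#' @param pca_k `NULL` for no projection, else number of components.
#' @return a `ddi_transform_chain` object.
#' @export
fit_transform_chain <- function(train, transform = c("none", "idf", "tfidf"),
                                l2 = FALSE, pca_k = NULL) {
  transform <- match.arg(transform)
  res_cols <- if (inherits(train, "occurrence_matrix")) {
    matrix_columns_of_kind(train, "resource_count")
  } else integer(0)
  txt <- if (length(res_cols)) unclass_matrix(train)[, -res_cols, drop = FALSE]
         else unclass_matrix(train)
  idf_stats <- if (transform != "none") fit_idf(txt) else NULL
  staged <- .apply_pre_pca(txt, transform, l2, idf_stats)
  pca_stats <- if (!is.null(pca_k)) fit_pca(staged, pca_k) else NULL
  structure(
    list(transform = transform, l2 = l2, pca_k = pca_k,
         idf = idf_stats, pca = pca_stats,
         res_features = if (length(res_cols)) colnames(train)[res_cols] else character(0),
         features = colnames(txt)),
    class = "ddi_transform_chain"
  )
}

.apply_pre_pca <- function(txt, transform, l2, idf_stats) {
  out <- switch(transform,
    none = unclass_matrix(txt),
    idf = apply_idf(txt, idf_stats, tf_normalize = FALSE),
    tfidf = apply_idf(txt, idf_stats, tf_normalize = TRUE)
  )
  if (l2) out <- l2_normalize(out)
  out
}

#' @rdname fit_transform_chain
#' @param chain a fitted `ddi_transform_chain`.
#' @param x rows to transform (same feature space as the training matrix).
#' @export
apply_transform_chain <- function(chain, x) {
  stopifnot(inherits(chain, "ddi_transform_chain"))
  res_cols <- if (inherits(x, "occurrence_matrix")) {
    matrix_columns_of_kind(x, "resource_count")
  } else integer(0)
  txt <- if (length(res_cols)) unclass_matrix(x)[, -res_cols, drop = FALSE]
         else unclass_matrix(x)
  if (!identical(colnames(txt), chain$features)) {
    stop("feature mismatch between matrix and fitted transform chain")
  }
  out <- .apply_pre_pca(txt, chain$transform, chain$l2, chain$idf)
  if (!is.null(chain$pca)) out <- project_pca(out, chain$pca)
  if (length(res_cols)) {
    res <- unclass_matrix(x)[, res_cols, drop = FALSE]
    kinds <- c(stats::setNames(rep("transformed", ncol(out)), colnames(out)),
               stats::setNames(rep("resource_count", ncol(res)), colnames(res)))
    out <- cbind(out, res)
    out <- new_occurrence_matrix(out, kinds = kinds)
  }
  out
}

# strip occurrence_matrix class/attrs for numeric work
unclass_matrix <- function(x) {
  if (inherits(x, "occurrence_matrix")) {
    attr(x, "kinds") <- NULL
    class(x) <- c("matrix", "array")
  }
  x
}
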