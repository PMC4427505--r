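#' Count lexicon mentions in a token sequence
#'
#' Greedy, non-overlapping, left-to-right, longest-match-first dictionary
#' matching over normalized (stemmed) tokens: at each position the longest
#' lexicon entry matching the upcoming tokens is consumed and counted;
#' otherwise the scan advances one token. Matching is case-insensitive by
#' construction since both sides pass through [normalize_text()].
#'
#' @param tokens character vector of normalized tokens.
#' @param lexicon a `ddi_lexicon` from [read_lexicon()] or [as_lexicon()].
#' @return non-negative integer count of matches.
#' @export
count_matches <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "ddi_lexicon"))
  n <- length(tokens)
  if (!n) return(0L)
  entries <- lexicon$entries
  lens <- lengths(entries)
  max_len <- max(lens)
  # index entries by joined string per length for O(1) lookup
  by_len <- lapply(seq_len(max_len), function(L) {
    keys <- vapply(entries[lens == L], paste, character(1), collapse = " ")
    if (length(keys)) stats::setNames(rep(TRUE, length(keys)), keys) else logical(0)
  })
  count <- 0L
  i <- 1L
  while (i <= n) {
    matched <- 0L
    for (L in seq(min(max_len, n - i + 1L), 1L)) {
      if (!length(by_len[[L]])) next
      key <- paste(tokens[i:(i + L - 1L)], collapse = " ")
      if (!is.na(by_len[[L]][key])) {
        matched <- L
        break
      }
    }
    if (matched > 0L) {
      count <- count + 1L
      i <- i + matched
    } else {
      i <- i + 1L
    }
  }
  count
}

#' Per-document lexicon mention counts
#'
#' For abstract corpora, counts are computed over title + abstract text; for
#' sentence corpora, over the sentence text only.
#'
#' @param corpus a `ddi_corpus`.
#' @param lexicons a list of `ddi_lexicon` objects (or a single one).
#' @return a `ddi_resource_counts` tibble: `document` id column plus one
#'   integer count column per resource.
#' @export
compute_resource_counts <- function(corpus, lexicons) {
  if (inherits(lexicons, "ddi_lexicon")) lexicons <- list(lexicons)
  stopifnot(length(lexicons) >= 1L)
  unit <- corpus_unit(corpus)
  toks <- lapply(seq_len(nrow(corpus)), function(i) {
    if (unit == "abstract") {
      c(normalize_text(corpus$title[i]), normalize_text(corpus$abstract[i]))
    } else {
      normalize_text(corpus$text[i])
    }
  })
  out <- tibble::tibble(document = corpus_doc_ids(corpus))
  for (lex in lexicons) {
    out[[lex$resource_name]] <-
      vapply(toks, count_matches, integer(1), lexicon = lex)
  }
  structure(out, class = c("ddi_resource_counts", class(out)))
}

#' Attach resource-count columns to an occurrence matrix
#'
#' Extends a documents-by-features matrix with one integer column per
#' resource, flagged with kind `"resource_count"`. Count column names are
#' prefixed with `NER:` to keep them disjoint from text features.
#'
#' @param x an `occurrence_matrix`.
#' @param counts a `ddi_resource_counts` tibble aligned with the matrix rows.
#' @return an `occurrence_matrix` with the extra columns.
#' @export
attach_counts <- function(x, counts) {
  stopifnot(inherits(x, "occurrence_matrix"))
  if (nrow(counts) != nrow(x)) {
    stop("row-count mismatch: matrix has ", nrow(x), " documents, counts have ",
         nrow(counts))
  }
  if (!identical(as.character(counts$document), rownames(x))) {
    stop("document ids in counts do not align with matrix rows")
  }
  res <- as.matrix(counts[setdiff(names(counts), "document")])
  if (any(res < 0) || any(res != round(res))) {
    stop("resource counts must be non-negative integers")
  }
  colnames(res) <- paste0("NER:", setdiff(names(counts), "document"))
  kinds <- c(feature_kinds(x),
             stats::setNames(rep("resource_count", ncol(res)), colnames(res)))
  new_occurrence_matrix(cbind(unclass_matrix(x), res), kinds = kinds)
}

#' @rdname attach_counts
#' @export
detach_counts <- function(x) {
  res <- matrix_columns_of_kind(x, "resource_count")
  if (!length(res)) return(x)
  new_occurrence_matrix(unclass_matrix(x)[, -res, drop = FALSE],
                        kinds = feature_kinds(x)[-res])
}

#' Load a pre-computed resource count table
#'
#' Supports external NER tools whose per-document outputs are exported as a
#' TSV with a `document` id column and one integer column per resource.
#' Counts are re-aligned to corpus order; documents missing from the table
#' are an error, unknown extra documents are dropped with a warning.
#'
#' @param path path to the TSV file.
#' @param corpus the `ddi_corpus` the counts describe.
#' @return a `ddi_resource_counts` tibble in corpus order.
#' @export
load_count_table <- function(path, corpus) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    document = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (!"document" %in% names(tab)) stop("count table needs a 'document' column")
  ids <- corpus_doc_ids(corpus)
  missing <- setdiff(ids, tab$document)
  if (length(missing)) {
    stop("count table is missing documents: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(tab$document, ids)
  if (length(extra)) {
    warning("count table has unknown documents (ignored): ",
            paste(extra, collapse = ", "))
  }
  tab <- tab[match(ids, tab$document), , drop = FALSE]
  vals <- as.matrix(tab[setdiff(names(tab), "document")])
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("resource counts must be non-negative integers")
  }
  structure(tab, class = c("ddi_resource_counts", class(tibble::as_tibble(tab))))
}
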