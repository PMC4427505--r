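#' Normalize raw text into a token sequence
#'
#' The feature-extraction convention used throughout the package:
#' lowercase; split on whitespace; strip surrounding punctuation
#' (`.,;:()[]{}"'!?` and angle quotes) while keeping internal hyphens,
#' periods and slashes; replace standalone runs of digits with `#`
#' (digit runs embedded in alphanumeric tokens such as `p450` are kept, which
#' is what reproduces features like `#.#-fold` alongside `cytochrom p450`);
#' Porter-stem purely alphabetic token parts (hyphen-separated parts are
#' stemmed independently, so `co-administration` becomes `co-administr`);
#' finally drop tokens shorter than 2 characters, keeping the special numeric
#' token `#`.
#'
#' @param text a character scalar (or vector, concatenated with spaces).
#' @param field optional field name, unused in normalization itself but
#'   convenient for callers tracking provenance.
#' @return character vector of normalized tokens (possibly empty).
#' @examples
#' normalize_text("a 2.5-fold increase in AUC")
#' @export
normalize_text <- function(text, field = NULL) {
  text <- paste(text, collapse = " ")
  if (!nzchar(trimws(text))) return(character(0))
  text <- tolower(text)
  tokens <- strsplit(text, "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  punct <- "[.,;:()\\[\\]{}\"'!?«»‘’“”]"
  tokens <- gsub(paste0("^", punct, "+"), "", tokens, perl = TRUE)
  tokens <- gsub(paste0(punct, "+$"), "", tokens, perl = TRUE)
  tokens <- tokens[nzchar(tokens)]
  # mask digit runs that are not embedded in alphanumeric material
  tokens <- gsub("(?<![a-z0-9])[0-9]+(?![a-z0-9])", "#", tokens, perl = TRUE)
  tokens <- stem_tokens_cached(tokens)
  tokens[nchar(tokens) >= 2L | tokens == "#"]
}

# stemming is a pure function of the token; corpora repeat tokens massively,
# so results are cached in a package-local environment
.stem_cache <- new.env(parent = emptyenv())

stem_tokens_cached <- function(tokens) {
  if (!length(tokens)) return(tokens)
  uniq <- unique(tokens)
  known <- vapply(uniq, function(t) !is.null(.stem_cache[[t]]), logical(1))
  for (t in uniq[!known]) .stem_cache[[t]] <- stem_token(t)
  vapply(tokens, function(t) .stem_cache[[t]], character(1), USE.NAMES = FALSE)
}

# stem hyphen-separated purely-alphabetic parts; leave mixed material alone
stem_token <- function(token) {
  if (grepl("^[a-z]+$", token)) return(porter_stem(token))
  if (grepl("-", token, fixed = TRUE)) {
    parts <- strsplit(token, "-", fixed = TRUE)[[1]]
    parts <- vapply(parts, function(p) {
      if (grepl("^[a-z]+$", p)) porter_stem(p) else p
    }, character(1), USE.NAMES = FALSE)
    return(paste(parts, collapse = "-"))
  }
  token
}

#' Metadata feature strings for one bibliographic record
#'
#' Metadata values are treated as single, unstemmed, field-prefixed tokens:
#' `MeSH:<term>`, `Substance:<RN or SI value>`, `Author:<name>`,
#' `Journal:<title>`.
#'
#' @param record one corpus row (a one-row `ddi_corpus` or an equivalent list).
#' @param fields subset of metadata fields to emit; any of `"mesh"`, `"rn"`,
#'   `"si"`, `"authors"`, `"journal"`.
#' @return character vector of metadata feature strings (possibly empty).
#' @export
metadata_tokens <- function(record,
                            fields = c("mesh", "rn", "si", "authors", "journal")) {
  fields <- match.arg(fields, several.ok = TRUE)
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
    for (col in c("authors", "mesh_terms", "rn_substances", "si_ids")) {
      if (is.list(record[[col]])) record[[col]] <- record[[col]][[1]]
    }
  }
  out <- character(0)
  tag <- function(prefix, x) {
    x <- x[!is.na(x) & nzchar(x)]
    if (!length(x)) character(0) else paste0(prefix, x)
  }
  if ("mesh" %in% fields) out <- c(out, tag("MeSH:", record$mesh_terms))
  if ("rn" %in% fields) out <- c(out, tag("Substance:", record$rn_substances))
  if ("si" %in% fields) out <- c(out, tag("Substance:", record$si_ids))
  if ("authors" %in% fields) out <- c(out, tag("Author:", record$authors))
  if ("journal" %in% fields && nzchar(record$journal %||% "")) {
    out <- c(out, paste0("Journal:", record$journal))
  }
  out
}

#' N-gram features from a normalized token sequence
#'
#' Bigrams are adjacent token pairs joined by a single space and are formed
#' within one text field only; callers extract n-grams per field so bigrams
#' never span the title/abstract boundary.
#'
#' @param tokens character vector from [normalize_text()].
#' @param order `"unigram"` (unigrams only) or `"bigram"`
#'   (unigrams plus bigrams).
#' @return character vector of feature strings.
#' @export
extract_ngrams <- function(tokens, order = c("bigram", "unigram")) {
  order <- match.arg(order)
  if (!length(tokens)) return(character(0))
  out <- tokens
  if (order == "bigram" && length(tokens) >= 2L) {
    out <- c(out, paste(tokens[-length(tokens)], tokens[-1]))
  }
  out
}

# per-document feature sets (text n-grams + optional metadata), in corpus order
document_feature_sets <- function(corpus, order = "bigram",
                                  include_metadata = TRUE,
                                  metadata_fields = c("mesh", "rn", "si",
                                                      "authors", "journal")) {
  unit <- corpus_unit(corpus)
  n <- nrow(corpus)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (unit == "abstract") {
      feats <- c(
        extract_ngrams(normalize_text(corpus$title[i]), order),
        extract_ngrams(normalize_text(corpus$abstract[i]), order)
      )
      if (include_metadata) {
        rec <- list(
          mesh_terms = corpus$mesh_terms[[i]], rn_substances = corpus$rn_substances[[i]],
          si_ids = corpus$si_ids[[i]], authors = corpus$authors[[i]],
          journal = corpus$journal[i]
        )
        feats <- c(feats, metadata_tokens(rec, fields = metadata_fields))
      }
    } else {
      feats <- extract_ngrams(normalize_text(corpus$text[i]), order)
    }
    out[[i]] <- unique(feats)
  }
  out
}

#' Build the feature vocabulary for a corpus
#'
#' The union of text n-gram features (and, optionally, metadata features)
#' over all documents, with features occurring in fewer than `min_df`
#' documents removed. Feature ordering is deterministic (byte-wise
#' lexicographic), independent of locale and run order.
#'
#' @inheritParams document_feature_sets
#' @param corpus a `ddi_corpus`.
#' @param min_df minimum document frequency (default 2).
#' @return a `ddi_vocabulary` tibble with columns `feature`, `kind`
#'   (`unigram`/`bigram`/`metadata`) and `df`.
#' @export
build_vocabulary <- function(corpus, order = c("bigram", "unigram"),
                             include_metadata = TRUE,
                             metadata_fields = c("mesh", "rn", "si",
                                                 "authors", "journal"),
                             min_df = 2L) {
  order <- match.arg(order)
  if (!nrow(corpus)) stop("cannot build a vocabulary from an empty corpus")
  sets <- document_feature_sets(corpus, order, include_metadata, metadata_fields)
  tab <- table(unlist(sets))
  feats <- names(tab)[tab >= min_df]
  df <- as.integer(tab[tab >= min_df])
  o <- order(feats, method = "radix")
  feats <- feats[o]
  df <- df[o]
  kind <- ifelse(grepl("^(MeSH|Substance|Author|Journal):", feats), "metadata",
                 ifelse(grepl(" ", feats, fixed = TRUE), "bigram", "unigram"))
  vocab <- tibble::tibble(feature = feats, kind = kind, df = df)
  structure(vocab, unit = corpus_unit(corpus), order = order,
            include_metadata = include_metadata,
            metadata_fields = metadata_fields,
            class = c("ddi_vocabulary", class(vocab)))
}

#' Binary term-document occurrence matrix
#'
#' Cell (d, i) is 1 iff feature i occurs at least once in document d's
#' included fields; out-of-vocabulary tokens are ignored. Rows follow corpus
#' order, columns follow vocabulary order.
#'
#' @param corpus a `ddi_corpus`.
#' @param vocab a `ddi_vocabulary` built with a compatible unit.
#' @return an `occurrence_matrix`: numeric matrix with feature-kind metadata
#'   in `attr(, "kinds")` and document ids as row names.
#' @export
vectorize <- function(corpus, vocab) {
  if (!inherits(vocab, "ddi_vocabulary")) stop("vocab must be a ddi_vocabulary")
  if (!identical(attr(vocab, "unit"), corpus_unit(corpus))) {
    stop("vocabulary unit (", attr(vocab, "unit"),
         ") does not match corpus unit (", corpus_unit(corpus), ")")
  }
  sets <- document_feature_sets(
    corpus, attr(vocab, "order"), attr(vocab, "include_metadata"),
    attr(vocab, "metadata_fields")
  )
  x <- matrix(0, nrow = nrow(corpus), ncol = nrow(vocab),
              dimnames = list(corpus_doc_ids(corpus), vocab$feature))
  for (i in seq_along(sets)) {
    j <- match(sets[[i]], vocab$feature)
    j <- j[!is.na(j)]
    if (length(j)) x[i, j] <- 1
  }
  new_occurrence_matrix(x, kinds = stats::setNames(vocab$kind, vocab$feature))
}

new_occurrence_matrix <- function(x, kinds) {
  stopifnot(is.matrix(x), identical(colnames(x), names(kinds)))
  storage.mode(x) <- "double"
  structure(x, kinds = kinds, class = c("occurrence_matrix", "matrix", "array"))
}

#' @rdname vectorize
#' @param x an `occurrence_matrix`.
#' @param kind one of the feature kinds (`"unigram"`, `"bigram"`,
#'   `"metadata"`, `"resource_count"`).
#' @return for `feature_kinds()`, the named kind vector; for
#'   `matrix_columns_of_kind()`, the column indices of that kind.
#' @export
feature_kinds <- function(x) attr(x, "kinds")

#' @rdname vectorize
#' @export
matrix_columns_of_kind <- function(x, kind) which(feature_kinds(x) %in% kind)

# text+metadata columns (everything the binary invariant applies to)
text_columns <- function(x) {
  which(!(feature_kinds(x) %in% "resource_count"))
}

# subset rows keeping attributes
matrix_rows <- function(x, rows) {
  out <- x[rows, , drop = FALSE]
  new_occurrence_matrix(out, kinds = feature_kinds(x))
}
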