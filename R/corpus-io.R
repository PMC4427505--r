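#' Labeled corpus containers
#'
#' A `ddi_corpus` is a tibble with one row per classification unit plus a
#' `unit` attribute. Abstract corpora carry bibliographic records
#' (`record_id`, `title`, `abstract`, list-columns `authors`, `mesh_terms`,
#' `rn_substances`, `si_ids`, and `journal`); sentence corpora carry
#' (`record_id`, `sentence_index`, `text`). Every row has a `label` in
#' `"relevant"` / `"irrelevant"` (abstract records may also be `"unlabeled"`).
#'
#' @param data tibble of records.
#' @param unit `"abstract"` or `"sentence"`.
#' @return a `ddi_corpus` tibble.
#' @export
new_corpus <- function(data, unit = c("abstract", "sentence")) {
  unit <- match.arg(unit)
  data <- tibble::as_tibble(data)
  if (unit == "abstract") {
    needed <- c("record_id", "title", "abstract", "authors", "journal",
                "mesh_terms", "rn_substances", "si_ids", "label")
    missing <- setdiff(needed, names(data))
    if (length(missing)) {
      stop("abstract corpus is missing columns: ", paste(missing, collapse = ", "))
    }
    if (anyDuplicated(data$record_id)) {
      dups <- unique(data$record_id[duplicated(data$record_id)])
      stop("duplicate record_id in corpus: ", paste(dups, collapse = ", "))
    }
    ok <- data$label %in% c("relevant", "irrelevant", "unlabeled")
  } else {
    needed <- c("record_id", "sentence_index", "text", "label")
    missing <- setdiff(needed, names(data))
    if (length(missing)) {
      stop("sentence corpus is missing columns: ", paste(missing, collapse = ", "))
    }
    key <- paste(data$record_id, data$sentence_index, sep = "#")
    if (anyDuplicated(key)) {
      dups <- unique(key[duplicated(key)])
      stop("duplicate (record_id, sentence_index) keys: ", paste(dups, collapse = ", "))
    }
    if (any(!nzchar(data$text))) stop("sentence text must be non-empty")
    ok <- data$label %in% c("relevant", "irrelevant")
  }
  if (!all(ok)) {
    stop("invalid labels: ", paste(unique(data$label[!ok]), collapse = ", "))
  }
  structure(data, unit = unit, class = c("ddi_corpus", class(data)))
}

#' @export
print.ddi_corpus <- function(x, ...) {
  cat(sprintf("<ddi_corpus: %d %ss; %d relevant / %d irrelevant>\n",
              nrow(x), corpus_unit(x),
              sum(x$label == "relevant"), sum(x$label == "irrelevant")))
  NextMethod()
}

#' @rdname new_corpus
#' @param corpus a `ddi_corpus`.
#' @export
corpus_unit <- function(corpus) {
  unit <- attr(corpus, "unit")
  if (is.null(unit)) stop("not a ddi_corpus: no unit attribute")
  unit
}

# document identifiers used as occurrence-matrix row names
corpus_doc_ids <- function(corpus) {
  if (corpus_unit(corpus) == "abstract") corpus$record_id
  else paste(corpus$record_id, corpus$sentence_index, sep = "#")
}

# label strings found in files are mapped onto the canonical vocabulary
.label_aliases <- c(
  "relevant" = "relevant", "irrelevant" = "irrelevant",
  "ddi-relevant" = "relevant", "ddi-irrelevant" = "irrelevant",
  "positive" = "relevant", "negative" = "irrelevant",
  "unlabeled" = "unlabeled"
)

normalize_labels <- function(labels) {
  key <- tolower(trimws(labels))
  out <- unname(.label_aliases[key])
  if (anyNA(out)) {
    stop("unknown label value(s): ", paste(unique(labels[is.na(out)]), collapse = ", "))
  }
  out
}

#' Read a labeled abstract corpus in MEDLINE flat-file format
#'
#' Parses NLM-tagged flat files (`PMID`, `TI`, `AB`, `AU`, `JT`, `MH`, `RN`,
#' `SI`), where records are separated by blank lines and continuation lines
#' are indented. Field values are joined with spaces across continuations.
#'
#' @param path path to a MEDLINE flat file.
#' @param labels named character vector (names = record ids) or a two-column
#'   data frame (`record_id`, `label`) assigning a relevance label to each
#'   record. Labels may use documented aliases such as `"DDI-relevant"`.
#' @param on_missing what to do with parsed records absent from `labels`:
#'   `"error"` (default, strict), `"skip"`, or `"unlabeled"`.
#' @return a `ddi_corpus` with `unit = "abstract"`, rows in file order.
#' @export
read_medline_corpus <- function(path, labels,
                                on_missing = c("error", "skip", "unlabeled")) {
  on_missing <- match.arg(on_missing)
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels$label), as.character(labels$record_id))
  }
  records <- parse_medline_file(path)
  if (!length(records)) stop("no records found in ", path)
  ids <- vapply(records, function(r) r$record_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate PMID in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  unknown <- setdiff(ids, names(labels))
  if (length(unknown) && on_missing == "error") {
    stop("records missing from labels: ", paste(unknown, collapse = ", "))
  }
  if (on_missing == "skip") {
    records <- records[ids %in% names(labels)]
    ids <- ids[ids %in% names(labels)]
  }
  lab <- rep("unlabeled", length(ids))
  known <- ids %in% names(labels)
  lab[known] <- normalize_labels(labels[ids[known]])
  data <- tibble::tibble(
    record_id = ids,
    title = vapply(records, function(r) r$title, character(1)),
    abstract = vapply(records, function(r) r$abstract, character(1)),
    authors = lapply(records, function(r) r$authors),
    journal = vapply(records, function(r) r$journal, character(1)),
    mesh_terms = lapply(records, function(r) r$mesh_terms),
    rn_substances = lapply(records, function(r) r$rn_substances),
    si_ids = lapply(records, function(r) r$si_ids),
    label = unname(lab)
  )
  new_corpus(data, unit = "abstract")
}

# MEDLINE flat-file parser: "TAG - value" lines, indented continuations,
# blank-line record separators
parse_medline_file <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  records <- list()
  fields <- list()
  tag <- NULL
  flush <- function(fields) {
    if (!length(fields)) return(NULL)
    get1 <- function(t) if (is.null(fields[[t]])) "" else paste(fields[[t]], collapse = " ")
    getn <- function(t) if (is.null(fields[[t]])) character(0) else fields[[t]]
    pmid <- get1("PMID")
    if (!nzchar(pmid)) stop("record without PMID field")
    list(record_id = pmid, title = get1("TI"), abstract = get1("AB"),
         authors = getn("AU"), journal = get1("JT"),
         mesh_terms = getn("MH"), rn_substances = getn("RN"),
         si_ids = getn("SI"))
  }
  for (i in seq_along(lines)) {
    line <- sub("\\s+$", "", lines[i])
    if (!nzchar(line)) {
      rec <- flush(fields)
      if (!is.null(rec)) records[[length(records) + 1L]] <- rec
      fields <- list()
      tag <- NULL
    } else if (grepl("^[A-Z0-9]{1,4}\\s*- ", line)) {
      tag <- sub("^([A-Z0-9]{1,4})\\s*- .*$", "\\1", line)
      value <- sub("^[A-Z0-9]{1,4}\\s*- ", "", line)
      fields[[tag]] <- c(fields[[tag]], value)
    } else if (grepl("^\\s+\\S", line) && !is.null(tag)) {
      k <- length(fields[[tag]])
      fields[[tag]][k] <- paste(fields[[tag]][k], trimws(line))
    } else {
      stop("malformed MEDLINE line ", i, " in ", path, ": ", substr(line, 1, 60))
    }
  }
  rec <- flush(fields)
  if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  records
}

#' Write an abstract corpus as a MEDLINE flat file
#'
#' @param corpus an abstract-unit `ddi_corpus`.
#' @param path output path.
#' @return `path`, invisibly. Labels are not written; pair the file with a
#'   label table for [read_medline_corpus()].
#' @export
write_medline_corpus <- function(corpus, path) {
  stopifnot(corpus_unit(corpus) == "abstract")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    emit <- function(tag, values) {
      for (v in values) {
        if (nzchar(v)) writeLines(sprintf("%-4s- %s", tag, v), con)
      }
    }
    emit("PMID", corpus$record_id[i])
    emit("TI", corpus$title[i])
    emit("AB", corpus$abstract[i])
    emit("AU", corpus$authors[[i]])
    emit("JT", corpus$journal[i])
    emit("MH", corpus$mesh_terms[[i]])
    emit("RN", corpus$rn_substances[[i]])
    emit("SI", corpus$si_ids[[i]])
    writeLines("", con)
  }
  invisible(path)
}

#' Read a labeled sentence corpus
#'
#' Tab-separated file with a header row and columns `record_id`,
#' `sentence_index`, `text`, `label`.
#'
#' @param path path to the TSV file.
#' @return a `ddi_corpus` with `unit = "sentence"`, rows in file order.
#' @export
read_sentence_corpus <- function(path) {
  data <- readr::read_tsv(path, col_types = readr::cols(
    record_id = readr::col_character(),
    sentence_index = readr::col_integer(),
    text = readr::col_character(),
    label = readr::col_character()
  ), progress = FALSE)
  missing <- setdiff(c("record_id", "sentence_index", "text", "label"), names(data))
  if (length(missing)) {
    stop("sentence corpus file lacks required columns: ", paste(missing, collapse = ", "))
  }
  data$label <- normalize_labels(data$label)
  if (any(data$label == "unlabeled")) stop("sentence records must be labeled")
  new_corpus(data[, c("record_id", "sentence_index", "text", "label")],
             unit = "sentence")
}

#' @rdname read_sentence_corpus
#' @param corpus a sentence-unit `ddi_corpus`.
#' @export
write_sentence_corpus <- function(corpus, path) {
  stopifnot(corpus_unit(corpus) == "sentence")
  readr::write_tsv(tibble::as_tibble(corpus), path, progress = FALSE)
  invisible(path)
}

#' Read a plain-text lexicon
#'
#' One entry per line, UTF-8; blank lines are skipped and duplicate entries
#' (after normalization) are collapsed. Entries are normalized with the same
#' tokenize/mask/stem pipeline applied to document text
#' (see [normalize_text()]) so that matching happens in stem space.
#'
#' @param path path to the lexicon file.
#' @param resource_name short identifier for the resource (e.g. `"i-Drugs"`).
#' @return a `ddi_lexicon`: list with `resource_name`, `entries` (list of
#'   stemmed token vectors) and `surface` (original lines, deduplicated).
#' @export
read_lexicon <- function(path, resource_name) {
  lines <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    stop("lexicon file ", path, " has no entries; an empty lexicon is a configuration mistake")
  }
  as_lexicon(lines, resource_name)
}

#' @rdname read_lexicon
#' @param entries character vector of surface-form entries.
#' @export
as_lexicon <- function(entries, resource_name) {
  entries <- entries[nzchar(trimws(entries))]
  if (!length(entries)) stop("lexicon has no entries")
  toks <- lapply(entries, normalize_text)
  keep <- lengths(toks) > 0L
  toks <- toks[keep]
  entries <- entries[keep]
  if (!length(toks)) stop("lexicon entries vanish under normalization")
  key <- vapply(toks, paste, character(1), collapse = " ")
  dedup <- !duplicated(key)
  structure(
    list(resource_name = resource_name,
         entries = toks[dedup],
         surface = entries[dedup]),
    class = "ddi_lexicon"
  )
}

#' @export
print.ddi_lexicon <- function(x, ...) {
  cat(sprintf("<ddi_lexicon '%s': %d entries>\n", x$resource_name, length(x$entries)))
  invisible(x)
}
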