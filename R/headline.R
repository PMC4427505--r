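#' Run the full-scale benchmark configuration on a real corpus
#'
#' Desk-scale synthetic tests validate the machinery; reproducing the
#' headline corpus results additionally requires the released labeled
#' corpora, which are not bundled. Given a local copy of the abstract corpus
#' (MEDLINE flat file plus a label table) this runs the strongest benchmark
#' configuration — regularized LDA on unigrams + bigrams with metadata
#' features — under the standard 4 x 4 nested cross-validation and returns
#' the metric report for manual comparison.
#'
#' @param medline_path MEDLINE flat file of the labeled abstracts.
#' @param labels_path TSV with columns `record_id`, `label`.
#' @param seed fold-plan seed.
#' @param classifier classifier to run (default `"lda"`).
#' @param ngram_order n-gram order (default `"bigram"`).
#' @return a list with `report` (a `ddi_eval`) and `means` (its glance row).
#' @export
run_headline_benchmark <- function(medline_path, labels_path, seed = 1L,
                                   classifier = "lda", ngram_order = "bigram") {
  if (!file.exists(medline_path)) {
    stop("abstract corpus not found at '", medline_path,
         "'; download the released corpus and point medline_path at it")
  }
  if (!file.exists(labels_path)) {
    stop("label table not found at '", labels_path, "'")
  }
  labels <- readr::read_tsv(labels_path, col_types = readr::cols(
    record_id = readr::col_character(), label = readr::col_character()
  ), progress = FALSE)
  corpus <- read_medline_corpus(medline_path, labels)
  config <- pipeline_config(classifier = classifier, ngram_order = ngram_order)
  plan <- make_fold_plan(corpus, seed = seed)
  report <- evaluate_configuration(corpus, config, plan)
  list(report = report, means = glance(report))
}
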