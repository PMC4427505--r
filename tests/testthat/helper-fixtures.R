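# Small corpora built in code for the I/O and feature tests.

medline_fixture_text <- function() {
  paste(
    "PMID- 1001",
    "TI  - Ketoconazole strongly inhibits midazolam clearance",
    "AB  - Coadministration of ketoconazole increased the AUC of midazolam",
    "      2.5-fold in healthy subjects.",
    "AU  - Smith J",
    "AU  - Jones K",
    "JT  - Clin Pharmacol Ther",
    "MH  - Drug Interactions",
    "MH  - Humans",
    "RN  - Enzyme Inhibitors",
    "SI  - DrugBank/DB01026",
    "",
    "PMID- 1002",
    "TI  - Population pharmacokinetics of drug X",
    "AU  - Lee H",
    "JT  - J Pharm Sci",
    "MH  - Humans",
    "",
    sep = "\n"
  )
}

write_medline_fixture <- function() {
  path <- tempfile("fixture", fileext = ".medline")
  writeLines(medline_fixture_text(), path)
  path
}

medline_fixture_labels <- function() {
  c("1001" = "DDI-relevant", "1002" = "DDI-irrelevant")
}

sentence_fixture_tsv <- function() {
  path <- tempfile("sentences", fileext = ".tsv")
  writeLines(c(
    "record_id\tsentence_index\ttext\tlabel",
    "1001\t0\tKetoconazole inhibits midazolam metabolism.\tDDI-relevant",
    "1001\t1\tTwelve subjects were enrolled.\tirrelevant",
    "1002\t0\tThe mean clearance was 5.2 L/h.\tirrelevant"
  ), path)
  path
}

# deterministic toy occurrence matrix with both classes
toy_matrix <- function(n_docs = 6, n_feat = 3) {
  x <- matrix(
    c(1, 1, 0,
      1, 0, 1,
      1, 1, 1,
      0, 0, 1,
      0, 1, 0,
      0, 0, 0),
    nrow = 6, byrow = TRUE,
    dimnames = list(paste0("d", 1:6), paste0("feat", 1:3))
  )
  pkddi:::new_occurrence_matrix(
    x, kinds = stats::setNames(rep("unigram", 3), colnames(x))
  )
}

toy_labels <- c("relevant", "relevant", "relevant", "irrelevant", "irrelevant",
                "irrelevant")

# random binary occurrence matrix for property-style tests
random_binary_matrix <- function(n, k, seed = 1, prob = 0.4) {
  m <- pkddi:::local_seed(seed, matrix(rbinom(n * k, 1, prob), nrow = n))
  dimnames(m) <- list(paste0("d", seq_len(n)), paste0("f", seq_len(k)))
  pkddi:::new_occurrence_matrix(
    m, kinds = stats::setNames(rep("unigram", k), colnames(m))
  )
}

random_labels <- function(n, seed = 1, prob = 0.5) {
  pkddi:::local_seed(seed + 99L,
    ifelse(runif(n) < prob, "relevant", "irrelevant"))
}
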