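#' Specification of a synthetic labeled corpus
#'
#' Defines a two-class Bernoulli occurrence model with known parameters:
#' labels are drawn with prior `prior_relevant`; feature i occurs in a
#' relevant document with probability `p[i]` and in an irrelevant one with
#' probability `n[i]`, independently given the class. Occurring features are
#' rendered as token text so the full tokenize/stem/mask pipeline runs on the
#' generated documents. Optional components add class-conditional metadata
#' emission, Poisson-distributed lexicon mentions (injected as literal
#' lexicon entries, so dictionary matching recovers the drawn counts), and a
#' shared latent topic that flips a block of features to induce within-class
#' feature covariance.
#'
#' Default class priors match the reference corpora: 909 relevant / 294
#' irrelevant abstracts and 1396 relevant / 3204 irrelevant sentences.
#'
#' @param n_docs number of documents.
#' @param p,n per-feature occurrence probabilities (equal length). If `NULL`,
#'   `n_features` probabilities are drawn once from `p_range` / `n_range`
#'   using `seed`.
#' @param n_features number of features when `p`/`n` are drawn.
#' @param p_range,n_range uniform ranges for drawn probabilities.
#' @param prior_relevant class prior for the relevant class; defaults to the
#'   abstract-corpus imbalance for `unit = "abstract"` and the
#'   sentence-corpus imbalance for `unit = "sentence"`.
#' @param unit `"abstract"` or `"sentence"`.
#' @param metadata optional list of per-field specs
#'   `list(mesh = list(term =, prob_pos =, prob_neg =), ...)`.
#' @param resources optional named list; each element
#'   `list(entries =, rate_pos =, rate_neg =)` adds a lexicon whose mention
#'   count per document is Poisson with the class-conditional rate.
#' @param covariance_block optional list `list(features =, flip_prob =)`:
#'   with probability `flip_prob` a document's latent topic inverts the
#'   occurrences of the listed feature indices.
#' @param seed integer seed; the corpus is reproducible from the spec.
#' @return a `ddi_generator_spec`.
#' @export
generator_spec <- function(n_docs, p = NULL, n = NULL, n_features = 50L,
                           p_range = c(0.05, 0.45), n_range = c(0.05, 0.45),
                           prior_relevant = NULL,
                           unit = c("abstract", "sentence"),
                           metadata = NULL, resources = NULL,
                           covariance_block = NULL, seed = 1L) {
  unit <- match.arg(unit)
  if (is.null(prior_relevant)) {
    prior_relevant <- if (unit == "abstract") 909 / 1203 else 1396 / 4600
  }
  if (is.null(p) || is.null(n)) {
    probs <- local_seed(seed + 10007L, {
      list(p = stats::runif(n_features, p_range[1], p_range[2]),
           n = stats::runif(n_features, n_range[1], n_range[2]))
    })
    p <- p %||% probs$p
    n <- n %||% probs$n
  }
  if (length(p) != length(n)) stop("p and n must have equal length")
  if (any(p < 0 | p > 1 | n < 0 | n > 1)) stop("probabilities must lie in [0, 1]")
  if (prior_relevant <= 0 || prior_relevant > 1) stop("prior must be in (0, 1]")
  if (!is.null(resources)) {
    for (r in resources) {
      if (r$rate_pos < 0 || r$rate_neg < 0) stop("Poisson rates must be >= 0")
    }
  }
  structure(
    list(n_docs = as.integer(n_docs), p = p, n = n,
         vocabulary = synthetic_vocabulary(length(p)),
         prior_relevant = prior_relevant, unit = unit,
         metadata = metadata, resources = resources,
         covariance_block = covariance_block, seed = as.integer(seed)),
    class = "ddi_generator_spec"
  )
}

#' @rdname generator_spec
#' @export
synthetic_vocabulary <- function(n_features) {
  # stemmer-stable pseudo-words: consonant-vowel syllables, no English suffixes
  syll <- c("ba", "de", "fi", "go", "ku", "lo", "mu", "na", "po", "ru",
            "ta", "vo", "zi", "ke", "du", "sa", "mi", "bo")
  k <- length(syll)
  vapply(seq_len(n_features) - 1L, function(i) {
    paste0(syll[(i %/% (k * k)) %% k + 1L], syll[(i %/% k) %% k + 1L],
           syll[i %% k + 1L], "q")
  }, character(1))
}

#' Sample a labeled corpus from a generator specification
#'
#' @param spec a `ddi_generator_spec`.
#' @return a `ddi_corpus` of the spec's unit, with the spec stored in
#'   `attr(, "truth")` and the drawn occurrence matrix in
#'   `attr(, "occurrences")` (documents x features, before text rendering).
#' @export
sample_corpus <- function(spec) {
  stopifnot(inherits(spec, "ddi_generator_spec"))
  d <- spec$n_docs
  k <- length(spec$p)
  out <- local_seed(spec$seed, {
    label <- ifelse(stats::runif(d) < spec$prior_relevant, "relevant", "irrelevant")
    prob <- matrix(spec$n, nrow = d, ncol = k, byrow = TRUE)
    prob[label == "relevant", ] <- matrix(spec$p, nrow = sum(label == "relevant"),
                                          ncol = k, byrow = TRUE)
    z <- matrix(as.integer(stats::runif(d * k) < prob), nrow = d)
    if (!is.null(spec$covariance_block)) {
      cb <- spec$covariance_block
      flip <- stats::runif(d) < cb$flip_prob
      z[flip, cb$features] <- 1L - z[flip, cb$features]
    }
    texts <- character(d)
    meta <- list(mesh = vector("list", d))
    res_counts <- NULL
    if (!is.null(spec$resources)) {
      res_counts <- matrix(0L, nrow = d, ncol = length(spec$resources),
                           dimnames = list(NULL, names(spec$resources)))
    }
    for (i in seq_len(d)) {
      words <- spec$vocabulary[z[i, ] == 1L]
      if (!is.null(spec$resources)) {
        for (j in seq_along(spec$resources)) {
          r <- spec$resources[[j]]
          rate <- if (label[i] == "relevant") r$rate_pos else r$rate_neg
          cnt <- stats::rpois(1, rate)
          res_counts[i, j] <- cnt
          if (cnt > 0) {
            words <- c(words, sample(r$entries, cnt, replace = TRUE))
          }
        }
      }
      texts[i] <- paste(sample(words), collapse = " ")
      if (!is.null(spec$metadata$mesh)) {
        m <- spec$metadata$mesh
        pr <- if (label[i] == "relevant") m$prob_pos else m$prob_neg
        meta$mesh[[i]] <- if (stats::runif(1) < pr) m$term else character(0)
      } else {
        meta$mesh[[i]] <- character(0)
      }
    }
    list(label = label, z = z, texts = texts, meta = meta, res_counts = res_counts)
  })
  ids <- sprintf("S%05d", seq_len(d))
  corpus <- if (spec$unit == "abstract") {
    new_corpus(tibble::tibble(
      record_id = ids, title = "", abstract = out$texts,
      authors = rep(list(character(0)), d), journal = "",
      mesh_terms = out$meta$mesh,
      rn_substances = rep(list(character(0)), d),
      si_ids = rep(list(character(0)), d),
      label = out$label
    ), unit = "abstract")
  } else {
    new_corpus(tibble::tibble(
      record_id = ids, sentence_index = 0L,
      # "." keeps the text field non-empty but normalizes to zero tokens
      text = ifelse(nzchar(out$texts), out$texts, "."),
      label = out$label
    ), unit = "sentence")
  }
  colnames(out$z) <- spec$vocabulary
  attr(corpus, "truth") <- spec
  attr(corpus, "occurrences") <- out$z
  attr(corpus, "resource_counts") <- out$res_counts
  corpus
}

#' Bayes-optimal reference weights for a generator specification
#'
#' The exact Bernoulli Naive Bayes log posterior-odds computed from the true
#' generative parameters: `w_i = log[p_i (1-n_i) / (n_i (1-p_i))]` and
#' `b = sum_i log[(1-p_i)/(1-n_i)] + log[prior/(1-prior)]`. Under the
#' generator's conditional-independence assumption this is the Bayes-optimal
#' linear rule; fitted models should approach it as the corpus grows.
#'
#' @param spec a `ddi_generator_spec` with all `p`, `n` strictly inside
#'   (0, 1).
#' @return a `ddi_model` with `classifier = "bayes_reference"`.
#' @export
optimal_reference_weights <- function(spec) {
  stopifnot(inherits(spec, "ddi_generator_spec"))
  if (any(spec$p <= 0 | spec$p >= 1 | spec$n <= 0 | spec$n >= 1)) {
    stop("reference weights need p, n strictly inside (0, 1)")
  }
  w <- log(spec$p * (1 - spec$n)) - log(spec$n * (1 - spec$p))
  names(w) <- spec$vocabulary
  b <- sum(log(1 - spec$p) - log(1 - spec$n)) +
    log(spec$prior_relevant / (1 - spec$prior_relevant))
  new_ddi_model(weights = w, bias = b, classifier = "bayes_reference")
}
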