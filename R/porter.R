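#' Porter stemmer
#'
#' Suffix-stripping stemmer for English words, implemented from the classic
#' 1980 algorithm definition (steps 1a-5b, with the measure/condition rules
#' computed on the candidate stem). Words of two characters or fewer, and
#' words containing anything other than lowercase letters, are returned
#' unchanged; callers are expected to lowercase first.
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("interactions", "increased", "studies", "significantly"))
#' @export
porter_stem <- function(words) {
  vapply(words, porter_stem1, character(1), USE.NAMES = FALSE)
}

# letter classification: y is a vowel when preceded by a consonant
.porter_types <- function(chars) {
  n <- length(chars)
  type <- character(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% c("a", "e", "i", "o", "u")) {
      type[i] <- "v"
    } else if (ch == "y") {
      type[i] <- if (i == 1L) "c" else if (type[i - 1L] == "v") "c" else "v"
    } else {
      type[i] <- "c"
    }
  }
  type
}

# measure m of a stem: number of vowel->consonant transitions in [C](VC)^m[V]
.porter_measure <- function(stem) {
  if (!nzchar(stem)) return(0L)
  type <- .porter_types(strsplit(stem, "", fixed = TRUE)[[1]])
  vals <- rle(type)$values
  m <- 0L
  for (i in seq_along(vals)) {
    if (i < length(vals) && vals[i] == "v" && vals[i + 1L] == "c") m <- m + 1L
  }
  m
}

.porter_has_vowel <- function(stem) {
  if (!nzchar(stem)) return(FALSE)
  any(.porter_types(strsplit(stem, "", fixed = TRUE)[[1]]) == "v")
}

.porter_double_consonant <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L)
  b <- substr(word, n, n)
  if (a != b) return(FALSE)
  type <- .porter_types(strsplit(word, "", fixed = TRUE)[[1]])
  type[n] == "c"
}

# *o: stem ends cvc where the final consonant is not w, x or y
.porter_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  type <- .porter_types(chars)
  type[n - 2L] == "c" && type[n - 1L] == "v" && type[n] == "c" &&
    !(chars[n] %in% c("w", "x", "y"))
}

.ends_with <- function(word, suffix) {
  nw <- nchar(word)
  ns <- nchar(suffix)
  nw > ns && substr(word, nw - ns + 1L, nw) == suffix
}

.chop <- function(word, k) substr(word, 1L, nchar(word) - k)

porter_stem1 <- function(word) {
  if (nchar(word) <= 2L || !grepl("^[a-z]+$", word)) return(word)

  # step 1a
  if (.ends_with(word, "sses")) {
    word <- .chop(word, 2L)
  } else if (.ends_with(word, "ies")) {
    word <- paste0(.chop(word, 3L), "i")
  } else if (!.ends_with(word, "ss") && .ends_with(word, "s")) {
    word <- .chop(word, 1L)
  }

  # step 1b
  fired <- FALSE
  if (.ends_with(word, "eed")) {
    if (.porter_measure(.chop(word, 3L)) > 0L) word <- .chop(word, 1L)
  } else if (.ends_with(word, "ed") && .porter_has_vowel(.chop(word, 2L))) {
    word <- .chop(word, 2L)
    fired <- TRUE
  } else if (.ends_with(word, "ing") && .porter_has_vowel(.chop(word, 3L))) {
    word <- .chop(word, 3L)
    fired <- TRUE
  }
  if (fired) {
    if (.ends_with(word, "at") || .ends_with(word, "bl") || .ends_with(word, "iz")) {
      word <- paste0(word, "e")
    } else if (.porter_double_consonant(word) &&
               !(substr(word, nchar(word), nchar(word)) %in% c("l", "s", "z"))) {
      word <- .chop(word, 1L)
    } else if (.porter_measure(word) == 1L && .porter_cvc(word)) {
      word <- paste0(word, "e")
    }
  }

  # step 1c
  if (.ends_with(word, "y") && .porter_has_vowel(.chop(word, 1L))) {
    word <- paste0(.chop(word, 1L), "i")
  }

  # step 2 (condition: m > 0 on the stem)
  step2 <- list(
    c("ational", "ate"), c("tional", "tion"), c("enci", "ence"), c("anci", "ance"),
    c("izer", "ize"), c("abli", "able"), c("alli", "al"), c("entli", "ent"),
    c("eli", "e"), c("ousli", "ous"), c("ization", "ize"), c("ation", "ate"),
    c("ator", "ate"), c("alism", "al"), c("iveness", "ive"), c("fulness", "ful"),
    c("ousness", "ous"), c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble")
  )
  word <- .porter_rule_set(word, step2, min_measure = 1L)

  # step 3
  step3 <- list(
    c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
    c("ical", "ic"), c("ful", ""), c("ness", "")
  )
  word <- .porter_rule_set(word, step3, min_measure = 1L)

  # step 4 (m > 1); "ion" needs the stem to end in s or t
  step4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
             "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize")
  step4 <- step4[order(-nchar(step4))]
  for (suf in step4) {
    if (.ends_with(word, suf)) {
      stem <- .chop(word, nchar(suf))
      ok <- .porter_measure(stem) > 1L
      if (ok && suf == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- last %in% c("s", "t")
      }
      if (ok) word <- stem
      break
    }
  }

  # step 5a
  if (.ends_with(word, "e")) {
    stem <- .chop(word, 1L)
    m <- .porter_measure(stem)
    if (m > 1L || (m == 1L && !.porter_cvc(stem))) word <- stem
  }

  # step 5b
  if (.porter_double_consonant(word) &&
      substr(word, nchar(word), nchar(word)) == "l" &&
      .porter_measure(.chop(word, 1L)) > 1L) {
    word <- .chop(word, 1L)
  }

  word
}

# apply the first (longest) matching rule from a (suffix, replacement) list,
# subject to the measure condition evaluated on the stem
.porter_rule_set <- function(word, rules, min_measure) {
  lens <- vapply(rules, function(r) nchar(r[1]), integer(1))
  for (r in rules[order(-lens)]) {
    if (.ends_with(word, r[1])) {
      stem <- .chop(word, nchar(r[1]))
      if (.porter_measure(stem) >= min_measure) word <- paste0(stem, r[2])
      return(word)
    }
  }
  word
}
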