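# Per-token input vectors: [word embedding | one-hot case feature |
# terminology-dictionary index], 25 + 7 + 1 = 33 dimensions by default.

.case_classes <- c("numeric", "allLower", "allUpper", "initialUpper",
                   "mainly_numeric", "contains_digit", "other")

#' Feature configuration
#'
#' @param embed_dim Word-embedding dimension (default 25).
#' @param oov_policy How to embed out-of-vocabulary words: `"zero"` (zero
#'   vector) or `"random"` (a deterministic pseudo-random vector derived from
#'   `seed` and the word).
#' @param seed Seed used by the `"random"` OOV policy.
#' @return A list with class `feature_config`; total input width is
#'   `embed_dim + 8` (7 case dimensions + 1 terminology dimension).
#' @export
feature_config <- function(embed_dim = 25L, oov_policy = c("zero", "random"),
                           seed = 1L) {
  structure(list(embed_dim = as.integer(embed_dim), case_dim = 7L, dict_dim = 1L,
                 oov_policy = match.arg(oov_policy), seed = as.integer(seed)),
            class = "feature_config")
}

#' Case feature of a token
#'
#' One-hot over `numeric, allLower, allUpper, initialUpper, mainly_numeric,
#' contains_digit, other`; the first matching predicate in that order wins.
#' Digit-containing tokens are excluded from the pure letter classes so that
#' `mainly_numeric` and `contains_digit` are reachable.
#'
#' @param token A non-empty token string.
#' @return Named numeric vector of length 7 with exactly one 1.
#' @export
case_feature <- function(token) {
  if (!is.character(token) || length(token) != 1 || is.na(token) || nchar(token) == 0) {
    stop("case_feature requires a single non-empty token")
  }
  cls <- .case_classes[.case_class(token)]
  setNames(as.numeric(.case_classes == cls), .case_classes)
}

# vectorized case classification (1-based index into .case_classes)
.case_class <- function(words) {
  nc <- nchar(words)
  nd <- nc - nchar(gsub("[0-9]", "", words))
  has_letter <- grepl("[[:alpha:]]", words)
  lower_eq <- words == tolower(words)
  upper_eq <- words == toupper(words)
  init_up <- grepl("^[[:upper:]]", words) &
    substring(words, 2) == tolower(substring(words, 2))
  cls <- rep(7L, length(words))
  cls[nd > 0] <- 6L
  cls[nd > nc / 2] <- 5L
  cls[nd == 0 & has_letter & init_up] <- 4L
  cls[nd == 0 & has_letter & upper_eq] <- 3L
  cls[nd == 0 & has_letter & lower_eq] <- 2L
  cls[nd == nc] <- 1L
  cls
}

#' Terminology-dictionary feature
#'
#' The 0-based index into [element_tags()] of each token's gazetteer BIO
#' label; 0 (the index of `"O"`) for unmatched tokens.
#'
#' @param matches Output of [match_terms()].
#' @param n Sentence length.
#' @return Integer vector of length `n` with values in `0..36`.
#' @export
dict_feature <- function(matches, n) {
  tags <- encode_bio(spans(matches$start, matches$end, matches$label), n)
  match(tags, element_tags()) - 1L
}

#' Build or load a word-embedding table
#'
#' `load_embeddings()` reads the text format `word f1 ... fD`, one word per
#' line.  `random_embeddings()` draws a seeded Gaussian table for a fixed
#' vocabulary (used by the synthetic experiments in place of pretrained
#' vectors).
#'
#' @param path Embedding file path.
#' @return Numeric matrix with lowercase words as rownames.
#' @export
load_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  parts <- strsplit(lines, "[[:space:]]+")
  dims <- unique(vapply(parts, length, integer(1))) - 1L
  if (length(dims) != 1) stop("inconsistent embedding dimensions in ", path)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(dims)))
  rownames(mat) <- tolower(vapply(parts, `[[`, character(1), 1))
  mat
}

#' @rdname load_embeddings
#' @param words Vocabulary.
#' @param dim Embedding dimension.
#' @param seed RNG seed.
#' @param sd Standard deviation of the entries.
#' @export
random_embeddings <- function(words, dim = 25L, seed = 1L, sd = 0.3) {
  words <- unique(tolower(words))
  mat <- with_seed(seed, matrix(rnorm(length(words) * dim, sd = sd),
                                nrow = length(words), ncol = dim))
  rownames(mat) <- words
  mat
}

# deterministic embedding for an OOV word under the "random" policy
.oov_vector <- function(word, dim, seed) {
  h <- sum(utf8ToInt(word) * seq_along(utf8ToInt(word))) %% 1000003L
  with_seed((seed + h) %% .Machine$integer.max, rnorm(dim, sd = 0.3))
}

# run code under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Featurize a sentence
#'
#' Concatenates, per token and in this order, the lowercased-lookup word
#' embedding, the one-hot case feature and the raw terminology index.
#'
#' @param tokens Token data.frame or character vector of words.
#' @param embeddings Embedding matrix (lowercase rownames).
#' @param dicts A [dictionary_set()] used for the terminology feature.
#' @param config A [feature_config()].
#' @return Numeric matrix of shape `n x (embed_dim + 8)`.
#' @export
featurize_sentence <- function(tokens, embeddings, dicts,
                               config = feature_config()) {
  if (is.character(tokens)) tokens <- tokens_from_words(tokens)
  if (ncol(embeddings) != config$embed_dim) {
    stop("embedding table has ", ncol(embeddings), " dimensions but config says ",
         config$embed_dim)
  }
  n <- nrow(tokens)
  D <- config$embed_dim + config$case_dim + config$dict_dim
  out <- matrix(0, nrow = n, ncol = D)
  if (n == 0) return(out)
  words <- tolower(tokens$text)
  idx <- match(words, rownames(embeddings))
  hit <- !is.na(idx)
  if (any(hit)) out[hit, seq_len(config$embed_dim)] <- embeddings[idx[hit], ]
  if (config$oov_policy == "random" && any(!hit)) {
    for (i in which(!hit)) {
      out[i, seq_len(config$embed_dim)] <- .oov_vector(words[i], config$embed_dim,
                                                       config$seed)
    }
  }
  out[cbind(seq_len(n), config$embed_dim + .case_class(tokens$text))] <- 1
  matches <- match_terms(tokens, dicts)
  out[, D] <- dict_feature(matches, n)
  out
}
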