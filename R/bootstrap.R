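# Dictionary-driven corpus bootstrapping: tokenization, gazetteer matching,
# rule-based candidate extraction and default role/attribute linking.

#' Tokenize raw text
#'
#' Splits on whitespace and punctuation while preserving intra-word hyphens
#' and apostrophes ("b-value" is one token).  Character offsets reconstruct
#' the input exactly.
#'
#' @param text A single string.
#' @return data.frame with columns `text`, `position`, `char_start`,
#'   `char_end` (1-based, inclusive).
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || text == "") {
    return(tokens_from_words(character()))
  }
  pat <- "[[:alnum:]]+(?:[-'][[:alnum:]]+)*|[^[:alnum:][:space:]]"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(tokens_from_words(character()))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  data.frame(text = substring(text, starts, starts + lens - 1L),
             position = seq_along(starts),
             char_start = starts,
             char_end = starts + lens - 1L,
             stringsAsFactors = FALSE)
}

#' Construct a dictionary set
#'
#' One term list per category (trigger categories use their tag abbreviation,
#' e.g. `"Acq"`; argument and attribute categories their code).  Terms are
#' matched case-insensitively and may span several tokens.
#'
#' @param entries Named list mapping category to a character vector of terms.
#' @return An object of class `dictionary_set`.
#' @export
dictionary_set <- function(entries) {
  bad <- setdiff(names(entries), span_categories())
  if (length(bad)) stop("unknown dictionary categories: ", paste(bad, collapse = ", "))
  entries <- lapply(entries, function(x) {
    x <- trimws(tolower(x))
    if (any(x == "")) stop("empty term in dictionary")
    unique(x)
  })
  obj <- structure(list(entries = entries), class = "dictionary_set")
  attr(obj, "term_index") <- .term_index(obj)
  obj
}

#' @export
print.dictionary_set <- function(x, ...) {
  sizes <- vapply(x$entries, length, integer(1))
  cat("<dictionary_set>", sum(sizes), "terms in", length(sizes), "categories\n")
  invisible(x)
}

#' Read/write dictionary files
#'
#' Dictionaries live in a directory of UTF-8 files named `<CATEGORY>.txt`,
#' one term per line.
#'
#' @param dir Directory path.
#' @return [read_dictionaries()] returns a [dictionary_set()];
#'   [write_dictionaries()] returns `dir` invisibly.
#' @export
read_dictionaries <- function(dir) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  entries <- lapply(files, function(f) readLines(f, encoding = "UTF-8", warn = FALSE))
  names(entries) <- sub("\\.txt$", "", basename(files))
  entries <- lapply(entries, function(x) x[trimws(x) != ""])
  dictionary_set(entries)
}

#' @rdname read_dictionaries
#' @param dicts A [dictionary_set()].
#' @export
write_dictionaries <- function(dicts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cat in names(dicts$entries)) {
    writeLines(dicts$entries[[cat]], file.path(dir, paste0(cat, ".txt")),
               useBytes = TRUE)
  }
  invisible(dir)
}

# category class used for match tie-breaking: trigger > argument > attribute
.category_rank <- function(cat) {
  trig <- vapply(.ne_events, function(e) e$tag, character(1))
  ifelse(cat %in% trig, 1L, ifelse(cat %in% argument_categories()$code, 2L, 3L))
}

#' Match dictionary terms against a token sequence
#'
#' Case-insensitive, leftmost-longest, non-overlapping greedy matching.  When
#' several categories match the same longest span, the tie is broken by class
#' (trigger > argument > attribute), then by lexicographic category label.
#'
#' @param tokens Token data.frame (see [tokenize_text()]) or character vector
#'   of words.
#' @param dicts A [dictionary_set()].
#' @return data.frame with columns `start`, `end`, `label`, `matched_text`.
#' @export
match_terms <- function(tokens, dicts) {
  if (is.character(tokens)) tokens <- tokens_from_words(tokens)
  words <- tolower(tokens$text)
  n <- length(words)
  empty <- data.frame(start = integer(), end = integer(), label = character(),
                      matched_text = character(), stringsAsFactors = FALSE)
  if (n == 0 || !length(dicts$entries)) return(empty)
  idx <- .term_index(dicts)
  start <- integer(); end <- integer(); label <- character()
  i <- 1L
  while (i <= n) {
    cand <- idx$by_first[[words[i]]]
    best_len <- 0L; best_cat <- NA_character_
    for (ci in cand) {
      tt <- idx$tokens[[ci]]
      L <- length(tt)
      if (i + L - 1L > n || L < best_len) next
      if (L == 1L || all(words[(i + 1L):(i + L - 1L)] == tt[-1L])) {
        cat <- idx$category[ci]
        if (L > best_len) {
          best_len <- L; best_cat <- cat
        } else if (L == best_len && !identical(cat, best_cat)) {
          r_new <- .category_rank(cat); r_old <- .category_rank(best_cat)
          if (r_new < r_old || (r_new == r_old && cat < best_cat)) best_cat <- cat
        }
      }
    }
    if (best_len > 0L) {
      start <- c(start, i); end <- c(end, i + best_len - 1L)
      label <- c(label, best_cat)
      i <- i + best_len
    } else {
      i <- i + 1L
    }
  }
  if (!length(start)) return(empty)
  data.frame(start = start, end = end, label = label,
             matched_text = vapply(seq_along(start), function(k) {
               paste(words[start[k]:end[k]], collapse = " ")
             }, character(1)),
             stringsAsFactors = FALSE)
}

# tokenized terms indexed by first token (cached on the dictionary set)
.term_index <- function(dicts) {
  cached <- attr(dicts, "term_index")
  if (!is.null(cached)) return(cached)
  cats <- rep(names(dicts$entries),
              vapply(dicts$entries, length, integer(1)))
  toks <- lapply(unlist(dicts$entries, use.names = FALSE),
                 function(t) tokenize_text(t)$text)
  first <- vapply(toks, `[[`, character(1), 1)
  idx <- list(tokens = toks, category = cats,
              by_first = split(seq_along(toks), first))
  idx
}

#' Extract candidate event mentions from gazetteer matches
#'
#' Rule 1: a trigger match plus at least two argument matches admissible for
#' that trigger's event category yields a candidate mention.  Rule 2: a
#' Deactivate trigger plus at least one BRI match suffices.  One candidate is
#' produced per trigger occurrence.
#'
#' @param tokens Token data.frame or character vector of words.
#' @param matches Output of [match_terms()].
#' @return List of candidates, each with elements `category`, `trigger`
#'   (match row), `arguments`, `attributes` (match data.frames).
#' @export
extract_mentions <- function(tokens, matches) {
  if (is.character(tokens)) tokens <- tokens_from_words(tokens)
  trig_tags <- vapply(.ne_events, function(e) e$tag, character(1))
  attr_codes <- attribute_categories()$code
  is_trig <- matches$label %in% trig_tags
  is_attr <- matches$label %in% attr_codes
  candidates <- list()
  for (ti in which(is_trig)) {
    category <- event_from_tag(matches$label[ti])
    admissible <- unique(unlist(lapply(.ne_events[[category]]$slots, `[[`, "categories")))
    args <- matches[!is_trig & !is_attr & matches$label %in% admissible &
                      seq_len(nrow(matches)) != ti, , drop = FALSE]
    rule1 <- nrow(args) >= 2
    rule2 <- category == "Deactivate" && any(args$label == "BRI")
    if (rule1 || rule2) {
      candidates[[length(candidates) + 1L]] <- list(
        category = category,
        trigger = matches[ti, , drop = FALSE],
        arguments = args,
        attributes = matches[is_attr, , drop = FALSE])
    }
  }
  candidates
}

#' Link a candidate's arguments and attributes to its trigger
#'
#' Every argument match is linked with the single role of the trigger's event
#' category that admits its argument category.  Each attribute match is
#' attached to the nearest argument of its paired category (token distance,
#' ties to the left); when no paired-category argument exists it falls back to
#' the nearest linked argument of any category, which [validate_event()] will
#' flag.  Arguments admitting no role are left unlinked and reported in the
#' `"unlinked"` attribute of the result.
#'
#' @param candidate A candidate from [extract_mentions()].
#' @return An [event_mention()]; unlinked matches, if any, are attached as the
#'   `"unlinked"` attribute.
#' @export
propose_links <- function(candidate) {
  ev <- .ne_events[[candidate$category]]
  rl <- empty_role_links()
  unlinked <- candidate$arguments[0, , drop = FALSE]
  for (i in seq_len(nrow(candidate$arguments))) {
    a <- candidate$arguments[i, , drop = FALSE]
    k <- which(vapply(ev$slots, function(s) a$label %in% s$categories, logical(1)))
    if (!length(k)) {
      unlinked <- rbind(unlinked, a)
      next
    }
    rl <- rbind(rl, data.frame(role = ev$slots[[k[1]]]$role, start = a$start,
                               end = a$end, category = a$label,
                               stringsAsFactors = FALSE))
  }
  al <- empty_attribute_links()
  paired <- attribute_categories()
  span_dist <- function(s1, e1, s2, e2) {
    if (e1 < s2) s2 - e1 else if (e2 < s1) s1 - e2 else 0L
  }
  for (i in seq_len(nrow(candidate$attributes))) {
    at <- candidate$attributes[i, , drop = FALSE]
    want <- paired$argument[match(at$label, paired$code)]
    cand_idx <- which(rl$category == want)
    if (!length(cand_idx)) cand_idx <- seq_len(nrow(rl))  # lenient fallback
    if (!length(cand_idx)) next
    d <- vapply(cand_idx, function(j) {
      span_dist(at$start, at$end, rl$start[j], rl$end[j])
    }, integer(1))
    best <- cand_idx[d == min(d)]
    j <- best[which.min(rl$start[best])]  # ties to the left
    al <- rbind(al, data.frame(arg_start = rl$start[j], start = at$start,
                               end = at$end, category = at$label,
                               stringsAsFactors = FALSE))
  }
  o <- order(rl$start)
  m <- event_mention(candidate$category,
                     c(candidate$trigger$start, candidate$trigger$end),
                     rl[o, , drop = FALSE], al)
  if (nrow(unlinked)) attr(m, "unlinked") <- unlinked
  m
}

#' Bootstrap an annotated corpus from raw sentences
#'
#' Runs [tokenize_text()], [match_terms()], [extract_mentions()] and
#' [propose_links()] on each sentence; BIO tags come from the gazetteer
#' matches.
#'
#' @param texts Character vector of sentences.
#' @param dicts A [dictionary_set()].
#' @return List of [annotated_sentence()] objects (sentences with no
#'   candidate mention are kept, with empty mention lists).
#' @export
bootstrap_corpus <- function(texts, dicts) {
  lapply(texts, function(txt) {
    tokens <- tokenize_text(txt)
    matches <- match_terms(tokens, dicts)
    cands <- extract_mentions(tokens, matches)
    mentions <- lapply(cands, propose_links)
    tags <- encode_bio(spans(matches$start, matches$end, matches$label),
                       nrow(tokens))
    annotated_sentence(tokens, tags, mentions)
  })
}
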