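# Annotated-sentence container and the tab-separated corpus format:
# one token per line "position<TAB>word<TAB>bio_tag<TAB>role_label<TAB>[p1,p2,...]",
# blank line between sentences.

#' Construct an annotated sentence
#'
#' @param tokens A token data.frame (see [tokenize_text()]) or a character
#'   vector of words, in which case character offsets are reconstructed by
#'   joining with single spaces.
#' @param tags BIO element tags, one per token.
#' @param mentions List of [event_mention()] objects grounded in this
#'   sentence.
#' @return An object of class `annotated_sentence`.
#' @export
annotated_sentence <- function(tokens, tags = rep("O", nrow(tokens)), mentions = list()) {
  if (is.character(tokens)) tokens <- tokens_from_words(tokens)
  stopifnot(nrow(tokens) == length(tags))
  bad <- !tags %in% element_tags()
  if (any(bad)) stop("unknown BIO tag(s): ", paste(unique(tags[bad]), collapse = ", "))
  structure(list(tokens = tokens, tags = tags, mentions = mentions),
            class = "annotated_sentence")
}

tokens_from_words <- function(words) {
  n <- length(words)
  if (n == 0) {
    return(data.frame(text = character(), position = integer(),
                      char_start = integer(), char_end = integer(),
                      stringsAsFactors = FALSE))
  }
  w <- nchar(words)
  starts <- cumsum(c(1L, head(w, -1) + 1L))
  data.frame(text = words, position = seq_len(n),
             char_start = as.integer(starts),
             char_end = as.integer(starts + w - 1L),
             stringsAsFactors = FALSE)
}

#' @export
print.annotated_sentence <- function(x, ...) {
  cat(paste(x$tokens$text, collapse = " "), "\n")
  cat(paste(x$tags, collapse = " "), "\n")
  cat(length(x$mentions), "mention(s)\n")
  invisible(x)
}

# Merge per-mention link rows into one per-token table; clashes (one token
# claimed with different labels by two mentions) are rejected because the flat
# column format cannot represent them.
merge_link_rows <- function(mentions, n) {
  rows <- data.frame(position = seq_len(n), role_label = "", stringsAsFactors = FALSE)
  rows$positions <- rep(list(integer()), n)
  for (m in mentions) {
    mr <- encode_link_rows(m, n)
    for (i in seq_len(n)) {
      if (mr$role_label[i] == "") next
      if (rows$role_label[i] != "" && rows$role_label[i] != mr$role_label[i]) {
        stop("token ", i, " participates in two mentions with conflicting labels (",
             rows$role_label[i], " vs ", mr$role_label[i], ")")
      }
      rows$role_label[i] <- mr$role_label[i]
      if (length(mr$positions[[i]])) {
        rows$positions[[i]] <- sort(unique(c(rows$positions[[i]], mr$positions[[i]])))
      }
    }
  }
  rows
}

format_poslist <- function(p) {
  if (!length(p)) "" else paste0("[", paste(p, collapse = ","), "]")
}

parse_poslist <- function(s, lineno) {
  s <- trimws(s)
  if (s == "") return(integer())
  if (!grepl("^\\[[0-9]+(,[0-9]+)*\\]$", s)) {
    stop("line ", lineno, ": malformed position list '", s, "'")
  }
  as.integer(strsplit(substr(s, 2, nchar(s) - 1L), ",", fixed = TRUE)[[1]])
}

#' Write an annotated corpus
#'
#' @param sentences List of [annotated_sentence()] objects.
#' @param path Output file path.
#' @return `path` invisibly.
#' @export
write_corpus <- function(sentences, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  blocks <- vapply(sentences, function(sent) {
    n <- nrow(sent$tokens)
    rows <- merge_link_rows(sent$mentions, n)
    lines <- sprintf("%d\t%s\t%s\t%s\t%s",
                     seq_len(n), sent$tokens$text, sent$tags,
                     rows$role_label,
                     vapply(rows$positions, format_poslist, character(1)))
    paste(lines, collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), con, useBytes = TRUE)
  invisible(path)
}

#' Read an annotated corpus
#'
#' @param path Path to a corpus file written by [write_corpus()] (or produced
#'   by hand in the same five-column format).
#' @return List of [annotated_sentence()] objects.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  block <- integer()
  flush_block <- function(idx) {
    if (!length(idx)) return(invisible())
    words <- character(); tags <- character()
    labels <- character(); plists <- list()
    for (j in seq_along(idx)) {
      ln <- idx[j]
      parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
      if (length(parts) < 3 || length(parts) > 5) {
        stop("line ", ln, ": expected 3-5 tab-separated columns, found ", length(parts))
      }
      parts <- c(parts, rep("", 5 - length(parts)))
      if (!grepl("^[0-9]+$", parts[1])) {
        stop("line ", ln, ": non-integer position '", parts[1], "'")
      }
      if (as.integer(parts[1]) != j) {
        stop("line ", ln, ": position ", parts[1], " out of order (expected ", j, ")")
      }
      words[j] <- parts[2]; tags[j] <- parts[3]
      labels[j] <- parts[4]; plists[[j]] <- parse_poslist(parts[5], ln)
    }
    rows <- data.frame(position = seq_along(idx), role_label = labels,
                       stringsAsFactors = FALSE)
    rows$positions <- plists
    mentions <- parse_link_rows(tags, rows)
    sentences[[length(sentences) + 1L]] <<-
      annotated_sentence(words, tags, mentions)
  }
  for (i in seq_along(lines)) {
    if (trimws(lines[i]) == "") {
      flush_block(block); block <- integer()
    } else {
      block <- c(block, i)
    }
  }
  flush_block(block)
  sentences
}
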