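# Strict precision/recall/F1 scoring for elements, arcs and whole events,
# and the stratified few-shot fivefold protocol (train on one fifth, test on
# the remaining four).

#' Precision, recall and F1 from match counts
#'
#' Any zero denominator yields 0 for that metric (standard convention in
#' information-extraction evaluation).
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
prf <- function(tp, fp, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp); fn <- as.numeric(fn)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

# generic strict set scorer: pred/gold are data.frames with a `label` column
# and key columns; a prediction is TP iff its full key (including label)
# appears in gold.
set_score <- function(pred, gold, key_cols) {
  keyof <- function(df) {
    if (!nrow(df)) return(character())
    do.call(paste, c(lapply(df[key_cols], as.character), list(sep = "\r")))
  }
  pk <- keyof(pred); gk <- keyof(gold)
  labels <- sort(unique(c(pred$label, gold$label)))
  counts <- data.frame(label = labels,
                       tp = vapply(labels, function(lb) sum(pk[pred$label == lb] %in%
                                                              gk[gold$label == lb]), integer(1)),
                       stringsAsFactors = FALSE, row.names = NULL)
  counts$fp <- vapply(labels, function(lb) sum(pred$label == lb), integer(1)) - counts$tp
  counts$fn <- vapply(labels, function(lb) sum(gold$label == lb), integer(1)) - counts$tp
  per <- matrix(0, nrow(counts), 3,
                dimnames = list(NULL, c("precision", "recall", "f1")))
  for (i in seq_len(nrow(counts))) {
    per[i, ] <- prf(counts$tp[i], counts$fp[i], counts$fn[i])
  }
  counts <- cbind(counts, as.data.frame(per))
  micro <- prf(sum(counts$tp), sum(counts$fp), sum(counts$fn))
  macro <- if (nrow(counts)) {
    c(precision = mean(counts$precision), recall = mean(counts$recall),
      f1 = mean(counts$f1))
  } else c(precision = 0, recall = 0, f1 = 0)
  structure(list(by_label = counts, micro = micro, macro = macro),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$by_label, row.names = FALSE)
  cat(sprintf("micro: P=%.3f R=%.3f F1=%.3f\n", x$micro[1], x$micro[2], x$micro[3]))
  invisible(x)
}

rbind_all <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (!length(lst)) return(NULL)
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

# flatten per-sentence span sets into one keyed data.frame
.flat_spans <- function(sent_spans) {
  rbind_all(lapply(seq_along(sent_spans), function(i) {
    s <- sent_spans[[i]]
    if (is.character(s)) s <- decode_bio(s)
    if (!is.null(s$tags)) s <- decode_bio(s$tags)
    if (!nrow(s)) return(NULL)
    data.frame(sentence = i, start = s$start, end = s$end, label = s$label,
               stringsAsFactors = FALSE)
  }))
}

#' Strict element scoring
#'
#' A predicted span is a true positive iff its label and both boundaries
#' match a gold span exactly.
#'
#' @param pred,gold Parallel per-sentence lists; each entry may be a span
#'   data.frame (see [spans()]), a BIO tag vector, or an
#'   [annotated_sentence()].
#' @return An `eval_report`: per-label counts with P/R/F1, micro and macro
#'   aggregates.
#' @export
score_elements <- function(pred, gold) {
  stopifnot(length(pred) == length(gold))
  empty <- data.frame(sentence = integer(), start = integer(), end = integer(),
                      label = character(), stringsAsFactors = FALSE)
  p <- .flat_spans(pred); g <- .flat_spans(gold)
  set_score(if (is.null(p)) empty else p, if (is.null(g)) empty else g,
            c("sentence", "start", "end", "label"))
}

.flat_arcs <- function(sent_arcs) {
  out <- rbind_all(lapply(seq_along(sent_arcs), function(i) {
    a <- sent_arcs[[i]]
    if (!is.null(a$mentions)) a <- mentions_to_arcs(a$mentions, nrow(a$tokens))
    if (!nrow(a)) return(NULL)
    data.frame(sentence = i, dep = a$dep, head = a$head, label = a$relation,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(sentence = integer(), dep = integer(), head = integer(),
                      label = character(), stringsAsFactors = FALSE)
  }
  out[out$label != "none", , drop = FALSE]
}

#' Strict arc scoring
#'
#' An arc is a true positive iff its dependent start, head start and
#' event-qualified relation label all match; reported per relation label.
#' `"none"` self-arcs are excluded.
#'
#' @param pred,gold Parallel per-sentence lists of arc data.frames
#'   (`dep`, `head`, `relation`) or [annotated_sentence()] objects (gold arcs
#'   are derived from their mentions).
#' @return An `eval_report`.
#' @export
score_links <- function(pred, gold) {
  stopifnot(length(pred) == length(gold))
  set_score(.flat_arcs(pred), .flat_arcs(gold), c("sentence", "dep", "head", "label"))
}

.mention_key <- function(m, mode) {
  trig <- sprintf("%s@%d-%d", m$category, m$trigger[1], m$trigger[2])
  if (mode == "relaxed") return(trig)
  rl <- m$role_links[order(m$role_links$role, m$role_links$start), , drop = FALSE]
  paste(trig, paste(sprintf("%s:%d-%d", rl$role, rl$start, rl$end), collapse = ";"),
        sep = "|")
}

#' Event-level scoring
#'
#' Strict mode (default): a predicted mention is a true positive iff its
#' trigger span, event category and complete role-link set match a gold
#' mention.  Relaxed mode: trigger span and category only.
#'
#' @param pred,gold Parallel per-sentence lists of mention lists (or
#'   [annotated_sentence()] objects).
#' @param mode `"strict"` or `"relaxed"`.
#' @return An `eval_report` keyed by event category.
#' @export
score_events <- function(pred, gold, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  stopifnot(length(pred) == length(gold))
  flat <- function(sent_mentions) {
    rbind_all(lapply(seq_along(sent_mentions), function(i) {
      ms <- sent_mentions[[i]]
      if (!is.null(ms$mentions)) ms <- ms$mentions
      if (!length(ms)) return(NULL)
      data.frame(sentence = i,
                 key = vapply(ms, .mention_key, character(1), mode = mode),
                 label = vapply(ms, `[[`, character(1), "category"),
                 stringsAsFactors = FALSE)
    }))
  }
  empty <- data.frame(sentence = integer(), key = character(),
                      label = character(), stringsAsFactors = FALSE)
  p <- flat(pred); g <- flat(gold)
  set_score(if (is.null(p)) empty else p, if (is.null(g)) empty else g,
            c("sentence", "key"))
}

#' Stratified fivefold few-shot split
#'
#' Each event category is shuffled and divided into five equal parts (sizes
#' differing by at most one).  Fold `i` trains on part `i` and tests on the
#' other four parts, simulating annotation scarcity.
#'
#' @param corpus List of [annotated_sentence()] objects; each sentence is
#'   stratified by the category of its first mention (sentences without
#'   mentions form their own stratum).
#' @param seed Seed controlling the shuffle.
#' @return List of five `list(train, test)` index pairs.
#' @export
fivefold_split <- function(corpus, seed = 1L) {
  cats <- vapply(corpus, function(s) {
    if (length(s$mentions)) s$mentions[[1]]$category else "(none)"
  }, character(1))
  part <- integer(length(corpus))
  with_seed(seed, {
    for (cat in unique(cats)) {
      idx <- which(cats == cat)
      if (cat != "(none)" && length(idx) < 5) {
        stop("category ", cat, " has only ", length(idx),
             " mentions; five parts need at least 5")
      }
      idx <- idx[sample.int(length(idx))]
      part[idx] <- rep_len(1:5, length(idx))
    }
  })
  lapply(1:5, function(i) list(train = which(part == i), test = which(part != i)))
}

#' Run the few-shot fivefold protocol
#'
#' For each fold, a fresh model is trained on the one-fifth training part and
#' evaluated on the four-fifths test part; element spans, arcs and events are
#' scored strictly and the counts pooled over folds into micro scores.
#'
#' @param corpus Annotated corpus (gold mentions required).
#' @param dicts,embeddings,config Passed to [init_model()].
#' @param adv An [adv_config()] or `NULL` for plain training.
#' @param epochs,batch_size Training-schedule overrides.
#' @param seed Controls the fold split, initialization and training.
#' @param folds Optional precomputed folds from [fivefold_split()].
#' @return List with pooled `element`, `link` and `event` reports plus a
#'   per-fold summary data.frame.
#' @export
run_fewshot_protocol <- function(corpus, dicts, embeddings,
                                 config = neuroeae_config(), adv = NULL,
                                 epochs = NULL, batch_size = NULL, seed = 1L,
                                 folds = NULL) {
  if (is.null(folds)) folds <- fivefold_split(corpus, seed = seed)
  feats <- lapply(corpus, function(sent) {
    featurize_sentence(sent$tokens, embeddings, dicts, config$feature)
  })
  pred_tags <- vector("list", 0); gold_sents <- vector("list", 0)
  pred_arcs <- vector("list", 0); pred_events <- vector("list", 0)
  per_fold <- NULL
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    model <- init_model(dicts, embeddings, config, seed = seed + fi)
    model <- train_freeat(model, corpus[f$train], adv = adv, epochs = epochs,
                          batch_size = batch_size, seed = seed + fi,
                          features = feats[f$train])
    preds <- lapply(feats[f$test], function(X) {
      p <- model$params
      H <- encoder_forward(X, p, model$config, train = FALSE)$H
      em <- emit_forward(H, p)
      tags <- element_tags()[crf_decode(em$E, p$trans)]
      arcs <- decode_links(head_forward(H, p)$probs, model$config$theta)
      list(tags = tags, arcs = arcs, mentions = assemble_events(tags, arcs))
    })
    gold <- corpus[f$test]
    el <- score_elements(lapply(preds, `[[`, "tags"), gold)
    li <- score_links(lapply(preds, `[[`, "arcs"), gold)
    ev <- score_events(lapply(preds, `[[`, "mentions"), gold)
    per_fold <- rbind(per_fold, data.frame(
      fold = fi, element_f1 = el$micro["f1"], link_f1 = li$micro["f1"],
      event_f1 = ev$micro["f1"], row.names = NULL))
    pred_tags <- c(pred_tags, lapply(preds, `[[`, "tags"))
    pred_arcs <- c(pred_arcs, lapply(preds, `[[`, "arcs"))
    pred_events <- c(pred_events, lapply(preds, `[[`, "mentions"))
    gold_sents <- c(gold_sents, gold)
  }
  list(element = score_elements(pred_tags, gold_sents),
       link = score_links(pred_arcs, gold_sents),
       event = score_events(pred_events, gold_sents),
       per_fold = per_fold)
}
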