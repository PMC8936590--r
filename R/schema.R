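# Event schema: six event categories, nine argument categories, three
# attribute categories, the BIO element tag set and the relation label set.

#' Argument categories of the event schema
#'
#' The nine entity categories that can fill argument roles.  Three of them
#' (data-acquisition device, stimuli-response mode, study participant) are
#' attribute-bearing: a modifier token may attach to them.
#'
#' @return A data.frame with columns `code`, `attribute_bearing`.
#' @export
argument_categories <- function() {
  data.frame(
    code = c("BRI", "COG", "ACQ", "SEN", "STP", "TSK", "AOB", "TOL", "RLT"),
    attribute_bearing = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Attribute categories and the argument category each is paired to
#'
#' @return A data.frame with columns `code`, `argument`.
#' @export
attribute_categories <- function() {
  data.frame(
    code = c("ACQ_A", "SEN_A", "STP_A"),
    argument = c("ACQ", "SEN", "STP"),
    stringsAsFactors = FALSE
  )
}

# Slot arity codes: "one" exactly one, "plus" one or more, "star" zero or more.
.ne_events <- local({
  slot <- function(role, categories, arity) {
    list(role = role, categories = categories, arity = arity)
  }
  brain_slots <- list(
    slot("cause", "COG", "one"),
    slot("affect", "BRI", "plus")
  )
  list(
    Activate = list(tag = "Act", slots = brain_slots),
    Deactivate = list(tag = "Deact", slots = brain_slots),
    Effect = list(tag = "Eff", slots = brain_slots),
    PerformExperiment = list(tag = "Exp", slots = list(
      slot("participates_in", "STP", "star"),
      slot("uses", "TSK", "plus"),
      slot("by", "SEN", "star")
    )),
    # The `from` slot admits BRI as well as STP: worked examples link a brain
    # area to an acquisition trigger through this role.
    Acquisition = list(tag = "Acq", slots = list(
      slot("produces", "AOB", "star"),
      slot("uses", "ACQ", "plus"),
      slot("from", c("STP", "BRI"), "star")
    )),
    PerformAnalysis = list(tag = "Ana", slots = list(
      slot("produces", "RLT", "plus"),
      slot("on", "AOB", "star"),
      slot("uses", "TOL", "plus")
    ))
  )
})

#' Event categories and their role slots
#'
#' Each of the six event categories defines a trigger tag abbreviation and a
#' list of role slots `(role, admissible argument categories, arity)` with
#' arity `"one"` (exactly one), `"plus"` (one or more) or `"star"` (zero or
#' more).
#'
#' @return Named list of event definitions.
#' @export
event_categories <- function() .ne_events

#' @rdname event_categories
#' @param tag A trigger tag abbreviation such as `"Acq"`.
#' @export
event_from_tag <- function(tag) {
  ev <- vapply(.ne_events, function(e) e$tag, character(1))
  nm <- names(ev)[match(tag, ev)]
  if (is.na(nm)) stop("unknown trigger tag: ", tag)
  nm
}

#' All 18 span categories in canonical order
#'
#' 6 trigger tags, 9 argument codes, 3 attribute codes.  Trigger spans are
#' labelled by the event tag abbreviation (e.g. `"Acq"`).
#'
#' @return Character vector of length 18.
#' @export
span_categories <- function() {
  c(vapply(.ne_events, function(e) e$tag, character(1), USE.NAMES = FALSE),
    argument_categories()$code,
    attribute_categories()$code)
}

#' The BIO element tag set
#'
#' `"O"` plus B-/I- tags for each of the 6 trigger, 9 argument and 3 attribute
#' categories: 37 labels.  `"O"` is first, so its 0-based index (used by the
#' terminology feature) is 0.
#'
#' @return Character vector of length 37.
#' @export
element_tags <- function() {
  cats <- span_categories()
  c("O", as.vector(rbind(paste0("B-", cats), paste0("I-", cats))))
}

#' The relation label set for role-attribute recognition
#'
#' The 14 event-qualified roles that occur in the scored relation inventory
#' (note that `Acquisition-from` is not among them), the 3 attribute
#' relations, and `"none"`: 18 labels.
#'
#' @return Character vector of length 18.
#' @export
relation_labels <- function() {
  c("Activate-cause", "Activate-affect",
    "Deactivate-cause", "Deactivate-affect",
    "Effect-cause", "Effect-affect",
    "PerformExperiment-participates_in", "PerformExperiment-uses",
    "PerformExperiment-by",
    "Acquisition-produces", "Acquisition-uses",
    "PerformAnalysis-produces", "PerformAnalysis-on", "PerformAnalysis-uses",
    "ACQ-attribute", "SEN-attribute", "STP-attribute",
    "none")
}

# Role name as printed in annotation files ("participates_in" -> "Participates_in").
role_file_label <- function(role) {
  paste0(toupper(substr(role, 1, 1)), substr(role, 2, nchar(role)))
}
role_from_file_label <- function(label) {
  paste0(tolower(substr(label, 1, 1)), substr(label, 2, nchar(label)))
}

#' Construct a span set
#'
#' @param start,end 1-based inclusive token positions.
#' @param label Span category: a trigger tag (e.g. `"Acq"`), an argument code
#'   (e.g. `"BRI"`) or an attribute code (e.g. `"ACQ_A"`).
#' @return A data.frame with columns `start`, `end`, `label`.
#' @export
spans <- function(start = integer(), end = start, label = character()) {
  stopifnot(length(start) == length(end), length(start) == length(label))
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   label = as.character(label), stringsAsFactors = FALSE)
  bad <- !df$label %in% span_categories()
  if (any(bad)) stop("unknown span label(s): ", paste(unique(df$label[bad]), collapse = ", "))
  df
}

#' Encode a span set as a BIO tag sequence
#'
#' @param span_set A data.frame as returned by [spans()].
#' @param n Sentence length in tokens.
#' @return Character vector of `n` tags over the [element_tags()] label set.
#' @export
encode_bio <- function(span_set, n) {
  n <- as.integer(n)
  if (nrow(span_set) == 0) return(rep("O", n))
  if (any(span_set$start < 1L) || any(span_set$end > n) ||
      any(span_set$start > span_set$end)) {
    stop("span out of bounds for sentence of length ", n)
  }
  o <- order(span_set$start)
  s <- span_set[o, , drop = FALSE]
  if (nrow(s) > 1) {
    clash <- which(s$start[-1] <= s$end[-nrow(s)])
    if (length(clash)) {
      i <- clash[1]
      stop(sprintf("overlapping spans: %s@%d-%d and %s@%d-%d",
                   s$label[i], s$start[i], s$end[i],
                   s$label[i + 1], s$start[i + 1], s$end[i + 1]))
    }
  }
  tags <- rep("O", n)
  for (i in seq_len(nrow(s))) {
    tags[s$start[i]] <- paste0("B-", s$label[i])
    if (s$end[i] > s$start[i]) {
      tags[(s$start[i] + 1L):s$end[i]] <- paste0("I-", s$label[i])
    }
  }
  tags
}

#' Decode a BIO tag sequence into a span set
#'
#' Maximal `B-X (I-X)*` runs become spans.  A stray `I-X` with no preceding
#' `B-X`/`I-X` of the same category is repaired to `B-X` (lenient decoding of
#' model output).
#'
#' @param tags Character vector over the [element_tags()] label set.
#' @return A span data.frame (see [spans()]).
#' @export
decode_bio <- function(tags) {
  known <- element_tags()
  bad <- !tags %in% known
  if (any(bad)) stop("unknown BIO tag(s): ", paste(unique(tags[bad]), collapse = ", "))
  n <- length(tags)
  if (n == 0) return(spans())
  isO <- tags == "O"
  pre <- substr(tags, 1, 1)
  lab <- substring(tags, 3)
  prev_O <- c(TRUE, isO[-n])
  prev_lab <- c("", lab[-n])
  # a token opens a span if tagged B-X, or if it is a stray/label-switching I-X
  opens <- !isO & (pre == "B" | prev_O | prev_lab != lab)
  if (!any(opens)) return(spans())
  start <- which(opens)
  closes <- c(opens[-1] | isO[-1], TRUE)  # last token of each span
  end <- which(closes & !isO)
  spans(start, end, lab[start])
}

#' Construct an event mention
#'
#' @param category Event category name, e.g. `"Acquisition"`.
#' @param trigger Integer vector `c(start, end)` of the trigger span.
#' @param role_links data.frame with columns `role`, `start`, `end`,
#'   `category` (one row per argument link).
#' @param attribute_links data.frame with columns `arg_start`, `start`, `end`,
#'   `category` (one row per attribute link; `arg_start` is the start position
#'   of the argument the attribute modifies).
#' @return An object of class `event_mention`.
#' @export
event_mention <- function(category, trigger,
                          role_links = empty_role_links(),
                          attribute_links = empty_attribute_links()) {
  for (cl in c("start", "end")) role_links[[cl]] <- as.integer(role_links[[cl]])
  for (cl in c("arg_start", "start", "end")) {
    attribute_links[[cl]] <- as.integer(attribute_links[[cl]])
  }
  structure(list(category = category,
                 trigger = as.integer(trigger),
                 role_links = role_links,
                 attribute_links = attribute_links),
            class = "event_mention")
}

#' @rdname event_mention
#' @export
empty_role_links <- function() {
  data.frame(role = character(), start = integer(), end = integer(),
             category = character(), stringsAsFactors = FALSE)
}

#' @rdname event_mention
#' @export
empty_attribute_links <- function() {
  data.frame(arg_start = integer(), start = integer(), end = integer(),
             category = character(), stringsAsFactors = FALSE)
}

#' @export
print.event_mention <- function(x, ...) {
  cat(sprintf("<%s event> trigger @%d-%d\n", x$category, x$trigger[1], x$trigger[2]))
  for (i in seq_len(nrow(x$role_links))) {
    cat(sprintf("  %s: %s @%d-%d\n", x$role_links$role[i], x$role_links$category[i],
                x$role_links$start[i], x$role_links$end[i]))
  }
  for (i in seq_len(nrow(x$attribute_links))) {
    cat(sprintf("  attribute %s @%d-%d -> arg @%d\n", x$attribute_links$category[i],
                x$attribute_links$start[i], x$attribute_links$end[i],
                x$attribute_links$arg_start[i]))
  }
  invisible(x)
}

#' Validate an event mention against the schema
#'
#' Checks trigger well-formedness, role admissibility, slot arities (`one`
#' slots filled exactly once, `plus` slots at least once) and attribute
#' attachment (attributes may only attach to attribute-bearing argument
#' categories, and only to their paired category).  Violations are data, not
#' errors.
#'
#' @param mention An [event_mention()].
#' @return Character vector of violation messages; empty if valid.
#' @export
validate_event <- function(mention) {
  v <- character()
  ev <- .ne_events[[mention$category]]
  if (is.null(ev)) return(sprintf("unknown event category '%s'", mention$category))
  if (length(mention$trigger) != 2 || anyNA(mention$trigger) ||
      mention$trigger[1] < 1 || mention$trigger[2] < mention$trigger[1]) {
    v <- c(v, "empty or malformed trigger span")
  }
  slots <- ev$slots
  slot_names <- vapply(slots, `[[`, character(1), "role")
  rl <- mention$role_links
  for (i in seq_len(nrow(rl))) {
    k <- match(rl$role[i], slot_names)
    if (is.na(k)) {
      v <- c(v, sprintf("role '%s' not defined for %s", rl$role[i], mention$category))
    } else if (!rl$category[i] %in% slots[[k]]$categories) {
      v <- c(v, sprintf("category %s not admissible for role '%s' of %s",
                        rl$category[i], rl$role[i], mention$category))
    }
  }
  for (s in slots) {
    cnt <- sum(rl$role == s$role)
    if (s$arity == "one" && cnt != 1) {
      v <- c(v, sprintf("role '%s' of %s requires exactly one argument (found %d)",
                        s$role, mention$category, cnt))
    } else if (s$arity == "plus" && cnt < 1) {
      v <- c(v, sprintf("role '%s' of %s requires at least one argument",
                        s$role, mention$category))
    }
  }
  ac <- attribute_categories()
  arg_bearing <- argument_categories()
  al <- mention$attribute_links
  for (i in seq_len(nrow(al))) {
    k <- match(al$arg_start[i], rl$start)
    if (is.na(k)) {
      v <- c(v, sprintf("attribute @%d attached to position %d which is no argument start",
                        al$start[i], al$arg_start[i]))
      next
    }
    argcat <- rl$category[k]
    if (!isTRUE(arg_bearing$attribute_bearing[match(argcat, arg_bearing$code)])) {
      v <- c(v, sprintf("attribute @%d attached to non-attribute-bearing category %s",
                        al$start[i], argcat))
    } else if (ac$argument[match(al$category[i], ac$code)] != argcat) {
      v <- c(v, sprintf("attribute category %s does not pair with argument category %s",
                        al$category[i], argcat))
    }
  }
  v
}

#' Encode a mention's trigger-centred link rows
#'
#' The trigger token's row carries the sorted start positions of all linked
#' arguments; each argument-start row carries its role name and the sorted
#' start positions of its attributes (empty if none).  Positions are 1-based
#' span starts.
#'
#' @param mention A validated [event_mention()].
#' @param n Sentence length in tokens.
#' @return data.frame with one row per token: `position`, `role_label`,
#'   `positions` (list column of integer vectors).
#' @export
encode_link_rows <- function(mention, n) {
  n <- as.integer(n)
  refs <- c(mention$trigger, mention$role_links$start, mention$role_links$end,
            mention$attribute_links$start, mention$attribute_links$end)
  if (length(refs) && (max(refs) > n || min(refs) < 1)) {
    stop("mention references tokens outside the sentence (n = ", n, ")")
  }
  rows <- data.frame(position = seq_len(n), role_label = "", stringsAsFactors = FALSE)
  rows$positions <- rep(list(integer()), n)
  tr <- mention$trigger
  rows$role_label[tr[1]:tr[2]] <- "Trigger"
  rows$positions[[tr[1]]] <- sort(unique(mention$role_links$start))
  rl <- mention$role_links
  for (i in seq_len(nrow(rl))) {
    rows$role_label[rl$start[i]:rl$end[i]] <- role_file_label(rl$role[i])
    atts <- mention$attribute_links$start[mention$attribute_links$arg_start == rl$start[i]]
    if (length(atts)) rows$positions[[rl$start[i]]] <- sort(unique(atts))
  }
  rows
}

# Inverse of encode_link_rows for one sentence: reconstruct mentions from BIO
# tags plus link rows.  Span categories come from the tags; roles from the
# argument rows; trigger category from the trigger span's tag.
parse_link_rows <- function(tags, rows) {
  sp <- decode_bio(tags)
  span_at <- function(p) {
    k <- which(sp$start == p)
    if (length(k) != 1) stop("link position ", p, " is not a span start")
    sp[k, , drop = FALSE]
  }
  trig_pos <- rows$position[rows$role_label == "Trigger" &
                              vapply(rows$positions, length, integer(1)) > 0]
  # a trigger with no arguments still has a "Trigger" row; catch span starts
  all_trig <- rows$position[rows$role_label == "Trigger"]
  trig_starts <- intersect(sp$start, all_trig)
  mentions <- list()
  for (tp in trig_starts) {
    tspan <- span_at(tp)
    category <- event_from_tag(tspan$label)
    argpos <- rows$positions[[tp]]
    rl <- empty_role_links(); al <- empty_attribute_links()
    for (ap in argpos) {
      aspan <- span_at(ap)
      role <- role_from_file_label(rows$role_label[ap])
      rl <- rbind(rl, data.frame(role = role, start = aspan$start, end = aspan$end,
                                 category = aspan$label, stringsAsFactors = FALSE))
      for (attp in rows$positions[[ap]]) {
        aspan2 <- span_at(attp)
        al <- rbind(al, data.frame(arg_start = ap, start = aspan2$start,
                                   end = aspan2$end, category = aspan2$label,
                                   stringsAsFactors = FALSE))
      }
    }
    o <- order(rl$start)
    mentions[[length(mentions) + 1L]] <-
      event_mention(category, c(tspan$start, tspan$end), rl[o, , drop = FALSE], al)
  }
  mentions
}

#' Map event mentions to a provenance document
#'
#' One activity per mention (typed by its event category and labelled by its
#' trigger text), one entity/agent record per argument (study participants
#' become agents), one attribute record per attribute.  Role links become
#' typed relations: `produces` maps to `generated`, `participates_in` to
#' `associated_with`, attribute links to `has_attribute`, all other roles to
#' `used`; the original role name is retained on the relation.
#'
#' @param sentences A list of annotated sentences (see [read_corpus()]), or a
#'   single annotated sentence.
#' @return An object of class `prov_document` with elements `records` and
#'   `relations`.
#' @export
events_to_provenance <- function(sentences) {
  if (!is.null(sentences$tokens)) sentences <- list(sentences)
  records <- list(); relations <- list()
  aid <- 0L
  for (si in seq_along(sentences)) {
    sent <- sentences[[si]]
    words <- sent$tokens$text
    span_text <- function(s, e) paste(words[s:e], collapse = " ")
    for (m in sent$mentions) {
      aid <- aid + 1L
      act_id <- sprintf("activity_%d", aid)
      records[[act_id]] <- list(kind = "activity", type = m$category,
                                label = span_text(m$trigger[1], m$trigger[2]))
      rl <- m$role_links
      arg_ids <- character(nrow(rl))
      for (i in seq_len(nrow(rl))) {
        id <- sprintf("%s_arg%d", act_id, i)
        arg_ids[i] <- id
        kind <- if (rl$category[i] == "STP") "agent" else "entity"
        records[[id]] <- list(kind = kind, type = rl$category[i],
                              label = span_text(rl$start[i], rl$end[i]))
        reltype <- switch(rl$role[i],
                          produces = "generated",
                          participates_in = "associated_with",
                          "used")
        relations[[length(relations) + 1L]] <-
          list(type = reltype, role = rl$role[i], activity = act_id, element = id)
      }
      al <- m$attribute_links
      for (i in seq_len(nrow(al))) {
        id <- sprintf("%s_att%d", act_id, i)
        records[[id]] <- list(kind = "attribute", type = al$category[i],
                              label = span_text(al$start[i], al$end[i]))
        k <- match(al$arg_start[i], rl$start)
        relations[[length(relations) + 1L]] <-
          list(type = "has_attribute", role = "attribute",
               element = if (is.na(k)) act_id else arg_ids[k], attribute = id)
      }
    }
  }
  structure(list(records = records, relations = relations), class = "prov_document")
}

#' Serialize a provenance document as PROV-JSON
#'
#' Records are grouped into the PROV-JSON `activity` / `entity` / `agent`
#' sections (attribute records are emitted as entities typed `Attribute`);
#' relations go into `used`, `wasGeneratedBy`, `wasAssociatedWith` and a
#' `has_attribute` extension section, each carrying its `prov:role`.
#'
#' @param doc A `prov_document`.
#' @param path Output file path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_prov_json <- function(doc, path = NULL) {
  sec <- list(activity = list(), entity = list(), agent = list(),
              used = list(), wasGeneratedBy = list(),
              wasAssociatedWith = list(), has_attribute = list())
  for (id in names(doc$records)) {
    r <- doc$records[[id]]
    body <- list(`prov:type` = r$type, `prov:label` = r$label)
    key <- switch(r$kind, activity = "activity", agent = "agent", "entity")
    if (r$kind == "attribute") body$`prov:type` <- paste0("Attribute:", r$type)
    sec[[key]][[id]] <- body
  }
  ri <- 0L
  for (rel in doc$relations) {
    ri <- ri + 1L
    id <- sprintf("_:r%d", ri)
    if (rel$type == "used") {
      sec$used[[id]] <- list(`prov:activity` = rel$activity,
                             `prov:entity` = rel$element, `prov:role` = rel$role)
    } else if (rel$type == "generated") {
      sec$wasGeneratedBy[[id]] <- list(`prov:entity` = rel$element,
                                       `prov:activity` = rel$activity,
                                       `prov:role` = rel$role)
    } else if (rel$type == "associated_with") {
      sec$wasAssociatedWith[[id]] <- list(`prov:activity` = rel$activity,
                                          `prov:agent` = rel$element,
                                          `prov:role` = rel$role)
    } else {
      sec$has_attribute[[id]] <- list(`prov:element` = rel$element,
                                      `prov:attribute` = rel$attribute)
    }
  }
  json <- jsonlite::toJSON(sec, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(json)) return(invisible(NULL))
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path, useBytes = TRUE)
  invisible(path)
}
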