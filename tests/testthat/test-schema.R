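test_that("label inventories have the documented sizes and structure", {
  expect_length(element_tags(), 37)
  expect_identical(element_tags()[1], "O")
  expect_length(relation_labels(), 18)
  expect_identical(sum(endsWith(relation_labels(), "-attribute")), 3L)
  expect_true("none" %in% relation_labels())
  expect_false("Acquisition-from" %in% relation_labels())

  expect_length(event_categories(), 6)
  ac <- argument_categories()
  expect_identical(nrow(ac), 9L)
  expect_identical(sort(ac$code[ac$attribute_bearing]), c("ACQ", "SEN", "STP"))
  at <- attribute_categories()
  expect_identical(nrow(at), 3L)
  expect_identical(at$argument, sub("_A$", "", at$code))
})

test_that("encode_bio reproduces the worked-example tag row", {
  s <- spans(c(3, 5, 8), c(3, 5, 9), c("AOB", "Acq", "BRI"))
  expect_identical(encode_bio(s, 9),
                   c("O", "O", "B-AOB", "O", "B-Acq", "O", "O", "B-BRI", "I-BRI"))
  expect_identical(encode_bio(spans(), 3), c("O", "O", "O"))
  expect_error(encode_bio(spans(c(1, 2), c(2, 3), c("BRI", "COG")), 5),
               "overlapping.*BRI.*COG")
  expect_error(encode_bio(spans(4, 6, "BRI"), 5), "out of bounds")
})

test_that("decode_bio inverts encode_bio and repairs stray I tags", {
  expect_identical(
    sort_spans(decode_bio(c("O", "O", "B-AOB", "O", "B-Acq", "O", "O", "B-BRI", "I-BRI"))),
    sort_spans(spans(c(3, 5, 8), c(3, 5, 9), c("AOB", "Acq", "BRI"))))
  expect_identical(nrow(decode_bio(c("O", "O"))), 0L)
  expect_identical(decode_bio(c("O", "I-BRI", "O")), spans(2, 2, "BRI"))
  # B-X followed by I-Y opens a new Y span
  expect_identical(sort_spans(decode_bio(c("B-BRI", "I-COG"))),
                   sort_spans(spans(c(1, 2), c(1, 2), c("BRI", "COG"))))
  expect_error(decode_bio(c("O", "B-XXX")), "unknown BIO tag")
})

test_that("BIO encode/decode are mutually inverse on 1000 random span sets", {
  set.seed(71)
  for (i in 1:1000) {
    n <- sample(3:14, 1)
    s <- sort_spans(random_span_set(n))
    expect_identical(sort_spans(decode_bio(encode_bio(s, n))), s)
  }
})

worked_mention <- function() {
  event_mention(
    "Acquisition", c(5, 5),
    data.frame(role = c("produces", "from"), start = c(3, 8), end = c(3, 9),
               category = c("AOB", "BRI"), stringsAsFactors = FALSE),
    data.frame(arg_start = 3, start = 2, end = 2, category = "ACQ_A",
               stringsAsFactors = FALSE))
}

test_that("encode_link_rows reproduces the worked-example rows", {
  rows <- encode_link_rows(worked_mention(), 9)
  expect_identical(rows$role_label[5], "Trigger")
  expect_identical(rows$positions[[5]], c(3L, 8L))
  expect_identical(rows$role_label[3], "Produces")
  expect_identical(rows$positions[[3]], 2L)
  expect_identical(rows$role_label[8], "From")
  expect_identical(rows$role_label[9], "From")
  expect_identical(rows$role_label[2], "")  # attribute tokens carry no role
  expect_error(encode_link_rows(worked_mention(), 4), "outside the sentence")

  m2 <- event_mention("Activate", c(2, 2),
                      data.frame(role = c("cause", "affect"), start = c(1, 3),
                                 end = c(1, 3), category = c("COG", "BRI"),
                                 stringsAsFactors = FALSE))
  rows2 <- encode_link_rows(m2, 3)
  expect_true(all(lengths(rows2$positions[c(1, 3)]) == 0))
})

test_that("validate_event enforces slots, arities and attribute pairing", {
  ok <- event_mention("Activate", c(2, 2),
                      data.frame(role = c("cause", "affect", "affect"),
                                 start = c(1, 3, 5), end = c(1, 3, 5),
                                 category = c("COG", "BRI", "BRI"),
                                 stringsAsFactors = FALSE))
  expect_identical(validate_event(ok), character(0))

  no_uses <- event_mention("Acquisition", c(1, 1),
                           data.frame(role = "produces", start = 2, end = 2,
                                      category = "AOB", stringsAsFactors = FALSE))
  v <- validate_event(no_uses)
  expect_length(v, 1)
  expect_match(v, "uses.*at least one")

  expect_match(validate_event(event_mention("Activate", integer())),
               "trigger", all = FALSE)
  # two cause links violate the exactly-one arity
  two_cause <- event_mention("Effect", c(3, 3),
                             data.frame(role = c("cause", "cause", "affect"),
                                        start = c(1, 2, 4), end = c(1, 2, 4),
                                        category = c("COG", "COG", "BRI"),
                                        stringsAsFactors = FALSE))
  expect_match(validate_event(two_cause), "exactly one", all = FALSE)
  # attribute on a non-attribute-bearing argument is flagged
  wm <- worked_mention()
  expect_match(validate_event(wm), "non-attribute-bearing", all = FALSE)
})

test_that("events_to_provenance obeys the record-count formula", {
  sent <- annotated_sentence(
    strsplit(worked_text, " ")[[1]],
    c("O", "B-ACQ_A", "B-AOB", "O", "B-Acq", "O", "O", "B-BRI", "I-BRI"),
    list(worked_mention()))
  doc <- events_to_provenance(sent)
  expect_length(doc$records, 1 + 2 + 1)  # activity + arguments + attribute
  expect_length(doc$relations, 2 + 1)
  kinds <- vapply(doc$records, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "activity"), 1L)
  expect_identical(unname(doc$records[[1]]$label), "obtained")

  expect_length(events_to_provenance(list())$records, 0)

  set.seed(9)
  g <- small_world(seed = 9, n = 25)
  for (sent in g$sentences) {
    m <- sent$mentions[[1]]
    doc <- events_to_provenance(sent)
    expect_length(doc$records,
                  1 + nrow(m$role_links) + nrow(m$attribute_links))
  }
})

test_that("PROV-JSON serialization has well-formed sections", {
  g <- small_world(seed = 10, n = 8)
  doc <- events_to_provenance(g$sentences)
  json <- write_prov_json(doc)
  parsed <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  expect_true(all(c("activity", "entity", "agent", "used", "wasGeneratedBy")
                  %in% names(parsed)))
  n_rec <- length(parsed$activity) + length(parsed$entity) + length(parsed$agent)
  expect_identical(n_rec, length(doc$records))
  # every relation endpoint exists among the records
  ids <- c(names(parsed$activity), names(parsed$entity), names(parsed$agent))
  for (u in parsed$used) {
    expect_true(u$`prov:activity` %in% ids && u$`prov:entity` %in% ids)
  }
})
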