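test_that("prf matches hand arithmetic including zero-denominator conventions", {
  expect_equal(prf(3, 1, 1), c(precision = 0.75, recall = 0.75, f1 = 0.75))
  expect_equal(prf(0, 0, 0), c(precision = 0, recall = 0, f1 = 0))
  expect_equal(prf(0, 5, 0), c(precision = 0, recall = 0, f1 = 0))
  expect_equal(prf(0, 0, 5), c(precision = 0, recall = 0, f1 = 0))
  set.seed(41)
  for (i in 1:500) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    got <- prf(tp, fp, fn)
    p <- if (tp + fp) tp / (tp + fp) else 0
    r <- if (tp + fn) tp / (tp + fn) else 0
    expect_equal(unname(got["f1"]),
                 if (p + r) 2 * p * r / (p + r) else 0, tolerance = 1e-12)
  }
})

test_that("score_elements is strict on labels and boundaries", {
  gold <- list(spans(c(2, 5), c(3, 5), c("BRI", "Acq")))
  expect_equal(unname(score_elements(gold, gold)$micro), c(1, 1, 1))
  # boundary off by one: 1 FP + 1 FN
  off <- list(spans(c(2, 5), c(4, 5), c("BRI", "Acq")))
  r <- score_elements(off, gold)
  bri <- r$by_label[r$by_label$label == "BRI", ]
  expect_identical(c(bri$tp, bri$fp, bri$fn), c(0L, 1L, 1L))
  # wrong label likewise
  wl <- list(spans(c(2, 5), c(3, 5), c("COG", "Acq")))
  r2 <- score_elements(wl, gold)
  expect_identical(sum(r2$by_label$fp), 1L)
  expect_identical(sum(r2$by_label$fn), 1L)
})

test_that("element counts equal a brute-force set intersection oracle", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    pred <- lapply(1:3, function(j) random_span_set(n))
    gold <- lapply(1:3, function(j) random_span_set(n))
    r <- score_elements(pred, gold)
    keys <- function(lst) unlist(lapply(seq_along(lst), function(j) {
      s <- lst[[j]]
      sprintf("%d|%d|%d|%s", j, s$start, s$end, s$label)
    }))
    pk <- keys(pred); gk <- keys(gold)
    expect_identical(sum(r$by_label$tp), length(intersect(pk, gk)))
    expect_identical(sum(r$by_label$fp), length(setdiff(pk, gk)))
    expect_identical(sum(r$by_label$fn), length(setdiff(gk, pk)))
  }
})

test_that("score_links is keyed by (dep, head, qualified relation)", {
  gold <- list(data.frame(dep = c(3, 8), head = c(5, 5),
                          relation = c("Acquisition-produces", "Acquisition-uses"),
                          stringsAsFactors = FALSE))
  expect_equal(unname(score_links(gold, gold)$micro), c(1, 1, 1))
  wrong <- list(data.frame(dep = c(3, 8), head = c(5, 5),
                           relation = c("Acquisition-produces", "Acquisition-produces"),
                           stringsAsFactors = FALSE))
  r <- score_links(wrong, gold)
  expect_identical(sum(r$by_label$tp), 1L)
  expect_identical(sum(r$by_label$fp), 1L)
  expect_identical(sum(r$by_label$fn), 1L)
  # "none" self-arcs are ignored
  with_none <- list(rbind(gold[[1]],
                          data.frame(dep = 1, head = 1, relation = "none",
                                     stringsAsFactors = FALSE)))
  expect_equal(unname(score_links(with_none, gold)$micro), c(1, 1, 1))
})

test_that("event scoring: strict requires role sets, relaxed only the trigger", {
  full <- event_mention("Activate", c(2, 2),
                        data.frame(role = c("cause", "affect"), start = c(1, 4),
                                   end = c(1, 4), category = c("COG", "BRI"),
                                   stringsAsFactors = FALSE))
  missing_arg <- event_mention("Activate", c(2, 2),
                               data.frame(role = "cause", start = 1, end = 1,
                                          category = "COG", stringsAsFactors = FALSE))
  expect_equal(unname(score_events(list(list(full)), list(list(full)))$micro), c(1, 1, 1))
  strict <- score_events(list(list(missing_arg)), list(list(full)))
  expect_identical(sum(strict$by_label$tp), 0L)
  expect_identical(sum(strict$by_label$fp), 1L)
  expect_identical(sum(strict$by_label$fn), 1L)
  relaxed <- score_events(list(list(missing_arg)), list(list(full)), mode = "relaxed")
  expect_identical(sum(relaxed$by_label$tp), 1L)
  # strict TP never exceeds relaxed TP
  set.seed(43)
  g <- small_world(seed = 43, n = 20)
  gold <- lapply(g$sentences, `[[`, "mentions")
  pred <- lapply(gold, function(ms) {
    m <- ms[[1]]
    if (runif(1) < 0.5 && nrow(m$role_links) > 1) {
      m$role_links <- m$role_links[-1, , drop = FALSE]
    }
    list(m)
  })
  s <- score_events(pred, gold); rl <- score_events(pred, gold, mode = "relaxed")
  expect_lte(sum(s$by_label$tp), sum(rl$by_label$tp))
})

test_that("fivefold_split stratifies 1-train/4-test with parts within one", {
  g <- generate_corpus(synth_config(seed = 44, n_mentions = 240))
  folds <- fivefold_split(g$sentences, seed = 2)
  expect_length(folds, 5)
  all_idx <- seq_along(g$sentences)
  cats <- vapply(g$sentences, function(s) s$mentions[[1]]$category, "")
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), all_idx)
    expect_equal(length(f$train) + length(f$test), length(all_idx))
  }
  # the five training parts partition the corpus
  parts <- lapply(folds, `[[`, "train")
  expect_setequal(unlist(parts), all_idx)
  expect_identical(sum(lengths(parts)), length(all_idx))
  # per-category part sizes differ by at most one
  for (cat in unique(cats)) {
    sizes <- vapply(parts, function(p) sum(cats[p] == cat), integer(1))
    expect_lte(max(sizes) - min(sizes), 1L)
  }
  # reproducible from the seed, different under another seed
  expect_identical(fivefold_split(g$sentences, seed = 2), folds)
  expect_false(identical(fivefold_split(g$sentences, seed = 3), folds))
})

test_that("a 100-per-category corpus splits into 20 train / 80 test", {
  props <- setNames(rep(1 / 6, 6), names(event_categories()))
  g <- generate_corpus(synth_config(seed = 45, n_mentions = 600,
                                    proportions = props))
  cats <- vapply(g$sentences, function(s) s$mentions[[1]]$category, "")
  folds <- fivefold_split(g$sentences, seed = 1)
  for (f in folds) {
    for (cat in unique(cats)) {
      n_cat <- sum(cats == cat)
      expect_lte(abs(sum(cats[f$train] == cat) - n_cat / 5), 1)
      expect_lte(abs(sum(cats[f$test] == cat) - 4 * n_cat / 5), 1)
    }
  }
})

test_that("categories with fewer than five mentions are rejected", {
  g <- generate_corpus(synth_config(seed = 46, n_mentions = 60))
  cats <- vapply(g$sentences, function(s) s$mentions[[1]]$category, "")
  keep <- c(which(cats == "Effect")[1:8], which(cats == "Activate")[1:3])
  expect_error(fivefold_split(g$sentences[keep], seed = 1),
               "Activate.*at least 5")
})

test_that("micro aggregates equal pooled-count recomputation", {
  g <- small_world(seed = 47, n = 15)
  gold <- lapply(g$sentences, `[[`, "tags")
  pred <- gold
  pred[[1]][which(pred[[1]] != "O")[1]] <- "O"  # drop one span
  r <- score_elements(pred, gold)
  expect_equal(unname(r$micro),
               unname(prf(sum(r$by_label$tp), sum(r$by_label$fp),
                          sum(r$by_label$fn))))
})
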