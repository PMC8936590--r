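test_that("the encoder has the documented shape and is deterministic", {
  model <- tiny_model(hidden = 64, layers = 3, embed_dim = 25)
  X <- matrix(rnorm(6 * 33), 6, 33)
  H <- encode_sentence(model, X)
  expect_identical(dim(H), c(6L, 128L))          # n x 2d with d = 64
  expect_identical(encode_sentence(model, X), H) # same input -> same output
  expect_identical(dim(encode_sentence(model, X[1, , drop = FALSE])), c(1L, 128L))
  expect_error(encode_sentence(model, X[0, , drop = FALSE]), "empty")
})

test_that("head_score matches an independent recomputation of the formula", {
  set.seed(6)
  l <- 3; d2 <- 8; R <- length(relation_labels())
  params <- list(selU = matrix(rnorm(l * d2), l, d2),
                 selW = matrix(rnorm(l * d2), l, d2),
                 selb = rnorm(l),
                 selV = matrix(rnorm(R * l), R, l),
                 selc = numeric(R))
  hi <- rnorm(d2); hj <- rnorm(d2)
  for (k in c(1L, 5L, 18L)) {
    got <- head_score(hi, hj, params, k)
    want <- sum(params$selV[k, ] * tanh(params$selU %*% hi + params$selW %*% hj +
                                          params$selb))
    expect_equal(got$score, want, tolerance = 1e-12)
    expect_equal(got$prob, 1 / (1 + exp(-want)), tolerance = 1e-12)
  }
  # V(r) = 0 gives score 0 and probability 1/2
  params$selV[] <- 0
  expect_identical(head_score(hi, hj, params, 2L)$prob, 0.5)
  # probability is strictly increasing in the score
  s <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(1 / (1 + exp(-s))) > 0))
})

test_that("batch head scores agree with the single-pair formula", {
  ne <- asNamespace("neuroevents")
  model <- tiny_model()
  H <- matrix(rnorm(3 * 2 * model$config$hidden), 3)
  fw <- ne$head_forward(H, model$params)
  for (i in 1:3) for (j in 1:3) {
    row <- (i - 1) * 3 + j
    one <- head_score(H[i, ], H[j, ], model$params, 4L)
    expect_equal(fw$probs[row, 4], one$prob, tolerance = 1e-12)
  }
})

test_that("rar_loss matches hand-computed cross-entropy and is non-negative", {
  # 2 tokens: gold arc (1 -> 2) under the first relation; token 2 self-"none"
  labs <- relation_labels()
  gold <- data.frame(dep = c(1L, 2L), head = c(2L, 2L),
                     relation = c(labs[1], "none"), stringsAsFactors = FALSE)
  probs <- matrix(0.2, 4, length(labs))
  probs[2, 1] <- 0.9            # pair (1,2), gold relation
  probs[4, length(labs)] <- 0.8 # pair (2,2), "none"
  hand <- -(log(0.9) + log(0.8) + sum(log(1 - 0.2)) * (4 * length(labs) - 2))
  expect_equal(rar_loss(probs, gold), hand, tolerance = 1e-9)

  # perfect predictions give (numerically) zero loss
  Y <- matrix(0, 4, length(labs)); Y[2, 1] <- 1; Y[4, length(labs)] <- 1
  expect_lt(rar_loss(Y, gold), 1e-8)

  set.seed(7)
  for (i in 1:20) {
    p <- matrix(runif(4 * length(labs)), 4)
    expect_gte(rar_loss(p, gold), 0)
  }
})

test_that("decode_links equals brute-force filtering and drops none arcs", {
  labs <- relation_labels()
  n <- 5
  set.seed(11)
  probs <- matrix(runif(n * n * length(labs)), n * n)
  theta <- 0.5
  got <- decode_links(probs, theta)
  idx_dep <- rep(1:n, each = n); idx_head <- rep(1:n, n)
  brute <- NULL
  for (r in which(labs != "none")) for (p in seq_len(n * n)) {
    if (probs[p, r] > theta) {
      brute <- rbind(brute, data.frame(dep = idx_dep[p], head = idx_head[p],
                                       relation = labs[r], prob = probs[p, r],
                                       stringsAsFactors = FALSE))
    }
  }
  expect_identical(sorted_arcs(got[c("dep", "head", "relation")]),
                   sorted_arcs(brute[c("dep", "head", "relation")]))
  expect_false(any(got$relation == "none"))
  expect_identical(nrow(decode_links(matrix(0.1, 9, length(labs)), 0.5)), 0L)

  # worked thresholding example: two of three candidate arcs survive
  p2 <- matrix(0, 64, length(labs))
  p2[(3 - 1) * 8 + 5, match("Acquisition-produces", labs)] <- 0.9
  p2[(8 - 1) * 8 + 5, match("Acquisition-uses", labs)] <- 0.6
  p2[(2 - 1) * 8 + 5, match("Acquisition-uses", labs)] <- 0.3
  got2 <- decode_links(p2, 0.5)
  expect_identical(nrow(got2), 2L)
  expect_setequal(got2$dep, c(3L, 8L))
})

test_that("joint_loss is the component sum", {
  expect_identical(joint_loss(0, 0), 0)
  expect_identical(joint_loss(2.5, 0), 2.5)
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1, 0, 10); b <- runif(1, 0, 10)
    expect_identical(joint_loss(a, b), a + b)
  }
})

test_that("the full joint backprop matches finite differences", {
  ne <- asNamespace("neuroevents")
  set.seed(19)
  model <- tiny_model()
  n <- 4
  X <- matrix(rnorm(n * model$config$input_dim), n)
  tags <- sample.int(length(element_tags()), n, TRUE)
  Y <- ne$arcs_to_matrix(ne$mentions_to_arcs(list(), n), n)
  g <- ne$sentence_grads(model, X, tags, Y, train = FALSE)
  h <- 1e-5
  for (nm in c("enc1f_Wx", "enc2b_Wh", "emitU", "trans", "selU", "selV")) {
    for (probe in 1:3) {
      i <- sample.int(length(model$params[[nm]]), 1)
      mp <- model; mp$params[[nm]][i] <- mp$params[[nm]][i] + h
      mm <- model; mm$params[[nm]][i] <- mm$params[[nm]][i] - h
      fd <- (ne$sentence_loss(mp, X, tags, Y)$loss -
               ne$sentence_loss(mm, X, tags, Y)$loss) / (2 * h)
      expect_equal(g$grads[[nm]][i], fd, tolerance = 1e-4)
    }
  }
  # gradient wrt the inputs (used by adversarial training)
  for (probe in 1:5) {
    i <- sample.int(length(X), 1)
    Xp <- X; Xp[i] <- Xp[i] + h
    Xm <- X; Xm[i] <- Xm[i] - h
    fd <- (ne$sentence_loss(model, Xp, tags, Y)$loss -
             ne$sentence_loss(model, Xm, tags, Y)$loss) / (2 * h)
    expect_equal(g$dX[i], fd, tolerance = 1e-4)
  }
})

test_that("assemble_events recovers the gold mention from oracle scores", {
  # oracle-injected tags and arcs for an acquisition sentence with a device
  # attribute: "High b-value fMRI was obtained through the EEG scanner"
  tags <- c("O", "B-ACQ_A", "B-AOB", "O", "B-Acq", "O", "O", "B-ACQ", "I-ACQ")
  arcs <- data.frame(dep = c(3L, 8L, 2L), head = c(5L, 5L, 8L),
                     relation = c("Acquisition-produces", "Acquisition-uses",
                                  "ACQ-attribute"),
                     prob = 0.9, stringsAsFactors = FALSE)
  ms <- assemble_events(tags, arcs)
  expect_length(ms, 1)
  expect_identical(ms[[1]]$category, "Acquisition")
  expect_identical(ms[[1]]$trigger, c(5L, 5L))
  expect_identical(ms[[1]]$role_links$start, c(3L, 8L))
  expect_identical(ms[[1]]$role_links$role, c("produces", "uses"))
  expect_identical(ms[[1]]$attribute_links$start, 2L)
  expect_identical(ms[[1]]$attribute_links$arg_start, 8L)
  expect_length(validate_event(ms[[1]]), 0)
  expect_type(attr(ms[[1]], "violations"), "character")
  # an attribute arc pointing at an argument of the wrong category is dropped
  arcs_bad_att <- arcs
  arcs_bad_att$head[3] <- 3L  # AOB is not attribute-bearing
  expect_identical(nrow(assemble_events(tags, arcs_bad_att)[[1]]$attribute_links), 0L)

  # schema-incompatible arcs are discarded
  bad <- data.frame(dep = 8L, head = 5L, relation = "Activate-affect",
                    prob = 0.9, stringsAsFactors = FALSE)
  ms2 <- assemble_events(tags, bad)
  expect_identical(nrow(ms2[[1]]$role_links), 0L)

  # no trigger decoded -> no mentions
  expect_length(assemble_events(c("O", "B-BRI"), arcs[0, ]), 0)
})

test_that("predict_events runs end-to-end and flags mentions", {
  g <- small_world(seed = 16, n = 30)
  cfg <- neuroeae_config(hidden = 8, layers = 1, scorer_width = 8, lr = 5e-3)
  model <- init_model(g$resources$dicts, g$embeddings, cfg, seed = 1)
  model <- train_model(model, g$sentences, epochs = 8, seed = 1)
  preds <- lapply(g$sentences[1:5], function(s) predict_events(model, s))
  expect_true(all(vapply(preds, is.list, logical(1))))
  for (m in unlist(preds, recursive = FALSE)) {
    expect_s3_class(m, "event_mention")
    expect_type(attr(m, "violations"), "character")
  }
  # raw strings are tokenized on the fly; empty input gives no mentions
  expect_type(predict_events(model, "no terms here at all"), "list")
  expect_length(predict_events(model, ""), 0)
})

test_that("the joint loss strictly decreases over 20 full-batch steps", {
  ne <- asNamespace("neuroevents")
  g <- small_world(seed = 17, n = 50)
  cfg <- neuroeae_config(hidden = 16, layers = 1, scorer_width = 16,
                         keep_prob = 1, lr = 1e-3)
  model <- init_model(g$resources$dicts, g$embeddings, cfg, seed = 4)
  data <- ne$prepare_corpus(model, g$sentences)
  opt <- ne$adam_init(model$params)
  losses <- numeric(21)
  for (step in 1:21) {
    grads <- NULL; tot <- 0
    for (s in data) {
      sg <- ne$sentence_grads(model, s$X, s$tags, s$Y, train = FALSE)
      grads <- ne$acc_grads(grads, sg$grads, 1 / length(data))
      tot <- tot + sg$loss
    }
    losses[step] <- tot / length(data)
    st <- ne$adam_step(model$params, grads, opt, cfg$lr)
    model$params <- st$params; opt <- st$state
  }
  expect_true(all(diff(losses[1:21]) < 0))
})

test_that("models survive a save/load round trip", {
  model <- tiny_model()
  f <- withr::local_tempfile(fileext = ".json")
  save_model(model, f)
  back <- load_model(f)
  for (nm in names(model$params)) {
    expect_equal(back$params[[nm]], model$params[[nm]], tolerance = 1e-12)
  }
  X <- matrix(rnorm(3 * model$config$input_dim), 3)
  expect_equal(encode_sentence(back, X), encode_sentence(model, X),
               tolerance = 1e-12)
})
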