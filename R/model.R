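# The joint model: feature config + BiLSTM encoder + CRF element tagger +
# head-selection role/attribute scorer, with Adam training.

#' Model configuration
#'
#' Defaults follow the reference hyperparameters: 25-dim word vectors, 3
#' BiLSTM layers of hidden size 64 per direction, tanh activations, dropout
#' keep-probability 0.9, Adam with learning rate 1e-3, decoding threshold
#' 0.5.
#'
#' @param embed_dim Word-embedding dimension.
#' @param hidden LSTM hidden size per direction (`d`; encoder output is `2d`).
#' @param layers Number of BiLSTM layers.
#' @param scorer_width Width `l` of the tanh scoring layers.
#' @param keep_prob Dropout keep-probability applied between BiLSTM layers
#'   during training.
#' @param theta Arc decoding threshold in (0, 1).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Default number of training iterations.
#' @param oov_policy,seed Passed to [feature_config()].
#' @return A list of class `neuroeae_config`.
#' @export
neuroeae_config <- function(embed_dim = 25L, hidden = 64L, layers = 3L,
                            scorer_width = 64L, keep_prob = 0.9, theta = 0.5,
                            lr = 1e-3, batch_size = 8L, epochs = 100L,
                            oov_policy = "zero", seed = 1L) {
  stopifnot(theta > 0, theta < 1, keep_prob > 0, keep_prob <= 1)
  fc <- feature_config(embed_dim, oov_policy, seed)
  structure(list(embed_dim = as.integer(embed_dim), hidden = as.integer(hidden),
                 layers = as.integer(layers), scorer_width = as.integer(scorer_width),
                 keep_prob = keep_prob, theta = theta, lr = lr,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 feature = fc,
                 input_dim = fc$embed_dim + fc$case_dim + fc$dict_dim),
            class = "neuroeae_config")
}

#' Initialize a joint model
#'
#' @param dicts [dictionary_set()] used for the terminology feature.
#' @param embeddings Word-embedding matrix (lowercase rownames); its column
#'   count must equal `config$embed_dim`.
#' @param config A [neuroeae_config()].
#' @param seed Seed for parameter initialization.
#' @return An object of class `neuroeae_model`.
#' @export
init_model <- function(dicts, embeddings, config = neuroeae_config(), seed = 1L) {
  if (ncol(embeddings) != config$embed_dim) {
    stop("embedding dimension ", ncol(embeddings), " != config embed_dim ",
         config$embed_dim)
  }
  K <- length(element_tags())
  R <- length(relation_labels())
  d2 <- 2L * config$hidden
  l <- config$scorer_width
  params <- with_seed(seed, {
    p <- init_encoder_params(config$input_dim, config$hidden, config$layers)
    p$emitU <- glorot(l, d2)
    p$emitb <- numeric(l)
    p$emitV <- glorot(K, l)
    p$emitc <- numeric(K)
    p$trans <- matrix(0, K, K)
    p$selU <- glorot(l, d2)
    p$selW <- glorot(l, d2)
    p$selb <- numeric(l)
    p$selV <- glorot(R, l)
    # gold arcs are sparse among the n^2 * R candidates, so the per-relation
    # bias starts at a negative logit; otherwise early training wades through
    # an all-arcs-at-0.5 flood before anything structural can be learned
    p$selc <- rep(-4, R)
    p
  })
  structure(list(config = config, params = params, embeddings = embeddings,
                 dicts = dicts, seed = as.integer(seed)),
            class = "neuroeae_model")
}

#' @export
print.neuroeae_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<neuroeae_model> %d BiLSTM layer(s), d=%d, %d parameters\n",
              x$config$layers, x$config$hidden, np))
  invisible(x)
}

# emission scores: n x K, with tanh hidden layer; returns cache for backprop
emit_forward <- function(H, params) {
  A <- H %*% t(params$emitU) + matrix(params$emitb, nrow(H), length(params$emitb),
                                      byrow = TRUE)
  Z <- tanh(A)
  E <- Z %*% t(params$emitV) + matrix(params$emitc, nrow(H), length(params$emitc),
                                      byrow = TRUE)
  list(E = E, Z = Z)
}

emit_backward <- function(H, params, fw, dE) {
  dZ <- (dE %*% params$emitV) * (1 - fw$Z^2)
  list(grads = list(emitV = t(dE) %*% fw$Z, emitc = colSums(dE),
                    emitU = t(dZ) %*% H, emitb = colSums(dZ)),
       dH = dZ %*% params$emitU)
}

# full forward/backward for one sentence; returns losses, param grads and the
# gradient wrt the input feature matrix (needed for adversarial training)
sentence_grads <- function(model, X, tags_idx, Y, train = TRUE) {
  p <- model$params
  enc <- encoder_forward(X, p, model$config, train = train)
  H <- enc$H
  em <- emit_forward(H, p)
  crf <- crf_grad(em$E, p$trans, tags_idx)
  hs <- head_forward(H, p)
  probs <- pmin(pmax(hs$probs, 1e-12), 1 - 1e-12)
  l_rar <- -sum(Y * log(probs) + (1 - Y) * log(1 - probs))
  emb <- emit_backward(H, p, em, crf$dE)
  hsb <- head_backward(H, p, hs, Y)
  dH <- emb$dH + hsb$dH
  encb <- encoder_backward(enc, p, model$config, dH)
  grads <- c(encb$grads, emb$grads, hsb$grads)
  grads$trans <- crf$dT
  list(l_ner = crf$nll, l_rar = l_rar, loss = crf$nll + l_rar,
       grads = grads, dX = encb$dX)
}

# forward-only joint loss (no dropout)
sentence_loss <- function(model, X, tags_idx, Y) {
  p <- model$params
  H <- encoder_forward(X, p, model$config, train = FALSE)$H
  em <- emit_forward(H, p)
  l_ner <- crf_loglik(em$E, p$trans, tags_idx)$nll
  hs <- head_forward(H, p)
  probs <- pmin(pmax(hs$probs, 1e-12), 1 - 1e-12)
  l_rar <- -sum(Y * log(probs) + (1 - Y) * log(1 - probs))
  list(l_ner = l_ner, l_rar = l_rar, loss = l_ner + l_rar)
}

# elementwise accumulation of two named grad lists
acc_grads <- function(a, b, w = 1) {
  if (is.null(a)) return(lapply(b, function(x) x * w))
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]] * w
  a
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# precompute features and gold targets for a corpus; `features` may carry
# already-computed feature matrices (they depend only on embeddings/dicts)
prepare_corpus <- function(model, corpus, features = NULL) {
  lapply(seq_along(corpus), function(i) {
    sent <- corpus[[i]]
    X <- if (!is.null(features)) features[[i]] else
      featurize_sentence(sent$tokens, model$embeddings, model$dicts,
                         model$config$feature)
    tags_idx <- match(sent$tags, element_tags())
    n <- nrow(X)
    Y <- arcs_to_matrix(mentions_to_arcs(sent$mentions, n), n)
    list(X = X, tags = tags_idx, Y = Y, n = n)
  })
}

#' Train the joint model
#'
#' Plain joint training: minimizes the CRF tagging loss plus the
#' head-selection loss with Adam on shuffled minibatches.  For adversarial
#' training see [train_freeat()].
#'
#' @param model A model from [init_model()].
#' @param corpus List of [annotated_sentence()] objects with gold mentions.
#' @param epochs Number of passes over the corpus (default from the config).
#' @param batch_size Minibatch size (default from the config).
#' @param seed Seed controlling shuffling and dropout.
#' @param verbose Print per-epoch losses.
#' @return The trained model, with a `loss_trace` data.frame attached as the
#'   `"history"` attribute.
#' @export
train_model <- function(model, corpus, epochs = NULL, batch_size = NULL,
                        seed = 1L, verbose = FALSE) {
  train_freeat(model, corpus, adv = NULL, epochs = epochs,
               batch_size = batch_size, seed = seed, verbose = verbose)
}

#' Predict event mentions for a sentence
#'
#' Decodes BIO tags with Viterbi, arcs by thresholding, discards arcs whose
#' (trigger category, relation) pair or argument category is
#' schema-incompatible, and assembles one mention per predicted trigger.
#' Each mention carries its [validate_event()] violations in the
#' `"violations"` attribute.
#'
#' @param model A trained model.
#' @param sentence An [annotated_sentence()], a token data.frame, or a raw
#'   string (tokenized with [tokenize_text()]).
#' @return List of [event_mention()] objects.
#' @export
predict_events <- function(model, sentence) {
  tokens <- if (is.character(sentence)) {
    tokenize_text(sentence)
  } else if (!is.null(sentence$tokens)) sentence$tokens else sentence
  n <- nrow(tokens)
  if (n == 0) return(list())
  X <- featurize_sentence(tokens, model$embeddings, model$dicts,
                          model$config$feature)
  decode_events_from_scores(model, X)
}

# decoding given a feature matrix (split out so oracle tests can inject X)
decode_events_from_scores <- function(model, X) {
  p <- model$params
  H <- encoder_forward(X, p, model$config, train = FALSE)$H
  em <- emit_forward(H, p)
  tags <- element_tags()[crf_decode(em$E, p$trans)]
  hs <- head_forward(H, p)
  arcs <- decode_links(hs$probs, model$config$theta)
  assemble_events(tags, arcs)
}

#' Assemble event mentions from decoded tags and arcs
#'
#' @param tags BIO tag sequence.
#' @param arcs data.frame of decoded arcs (`dep`, `head`, `relation`).
#' @return List of [event_mention()] objects with validation flags.
#' @export
assemble_events <- function(tags, arcs) {
  sp <- decode_bio(tags)
  trig_tags <- vapply(.ne_events, function(e) e$tag, character(1))
  mentions <- list()
  for (k in which(sp$label %in% trig_tags)) {
    tstart <- sp$start[k]
    category <- event_from_tag(sp$label[k])
    ev <- .ne_events[[category]]
    slot_roles <- vapply(ev$slots, `[[`, character(1), "role")
    rl <- empty_role_links()
    role_arcs <- arcs[arcs$head == tstart &
                        startsWith(arcs$relation, paste0(category, "-")), ,
                      drop = FALSE]
    for (i in seq_len(nrow(role_arcs))) {
      role <- sub(paste0("^", category, "-"), "", role_arcs$relation[i])
      si <- which(sp$start == role_arcs$dep[i])
      if (!length(si)) next
      cat_i <- sp$label[si[1]]
      j <- match(role, slot_roles)
      if (is.na(j) || !cat_i %in% ev$slots[[j]]$categories) next
      rl <- rbind(rl, data.frame(role = role, start = sp$start[si[1]],
                                 end = sp$end[si[1]], category = cat_i,
                                 stringsAsFactors = FALSE))
    }
    al <- empty_attribute_links()
    if (nrow(rl)) {
      att_arcs <- arcs[arcs$head %in% rl$start & endsWith(arcs$relation, "-attribute"), ,
                       drop = FALSE]
      for (i in seq_len(nrow(att_arcs))) {
        want_arg <- sub("-attribute$", "", att_arcs$relation[i])
        j <- match(att_arcs$head[i], rl$start)
        if (is.na(j) || rl$category[j] != want_arg) next
        si <- which(sp$start == att_arcs$dep[i])
        if (!length(si) || sp$label[si[1]] != paste0(want_arg, "_A")) next
        al <- rbind(al, data.frame(arg_start = att_arcs$head[i],
                                   start = sp$start[si[1]], end = sp$end[si[1]],
                                   category = sp$label[si[1]],
                                   stringsAsFactors = FALSE))
      }
    }
    m <- event_mention(category, c(sp$start[k], sp$end[k]),
                       rl[order(rl$start), , drop = FALSE], al)
    attr(m, "violations") <- validate_event(m)
    mentions[[length(mentions) + 1L]] <- m
  }
  mentions
}

#' Save / load a model
#'
#' The checkpoint is a single JSON archive holding the configuration, label
#' inventories, dictionaries, embeddings and all parameter tensors.
#'
#' @param model A `neuroeae_model`.
#' @param path File path.
#' @return `path` invisibly; `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  obj <- list(
    config = unclass(model$config)[c("embed_dim", "hidden", "layers",
                                     "scorer_width", "keep_prob", "theta", "lr",
                                     "batch_size", "epochs")],
    oov_policy = model$config$feature$oov_policy,
    feature_seed = model$config$feature$seed,
    seed = model$seed,
    tags = element_tags(), relations = relation_labels(),
    dicts = model$dicts$entries,
    vocab = rownames(model$embeddings),
    embeddings = unname(model$embeddings),
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = length(p), data = as.numeric(p))
    }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(neuroeae_config, c(obj$config, list(oov_policy = obj$oov_policy,
                                                     seed = obj$feature_seed)))
  emb <- matrix(obj$embeddings, nrow = length(obj$vocab))
  rownames(emb) <- obj$vocab
  dicts <- dictionary_set(as.list(obj$dicts))
  model <- init_model(dicts, emb, cfg, seed = obj$seed)
  for (nm in names(obj$params)) {
    d <- obj$params[[nm]]$dim
    x <- obj$params[[nm]]$data
    model$params[[nm]] <- if (length(d) == 2) matrix(x, d[1], d[2]) else x
  }
  model
}
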