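# Shared fixtures and independent oracles.

# ---- worked example (9-token acquisition sentence) ----

worked_text <- "High b-value fMRI was obtained through the central sulcus"

worked_dicts <- function() {
  dictionary_set(list(Acq = "obtained", AOB = "fMRI", BRI = "central sulcus",
                      ACQ_A = "b-value"))
}

# ---- random valid span sets ----

random_span_set <- function(n, max_spans = 4) {
  cats <- span_categories()
  start <- integer(); end <- integer(); label <- character()
  free <- seq_len(n)
  for (k in seq_len(sample.int(max_spans + 1, 1) - 1)) {
    if (!length(free)) break
    s <- free[sample.int(length(free), 1)]
    run <- s
    while (length(run) < 3 && (max(run) + 1) %in% free && runif(1) < 0.4) {
      run <- c(run, max(run) + 1)
    }
    start <- c(start, min(run)); end <- c(end, max(run))
    label <- c(label, sample(cats, 1))
    free <- setdiff(free, run)
  }
  spans(start, end, label)
}

sorted_arcs <- function(a) {
  a <- a[order(a$dep, a$head, a$relation), , drop = FALSE]
  rownames(a) <- NULL
  a
}

sort_spans <- function(s) {
  s <- s[order(s$start), , drop = FALSE]
  rownames(s) <- NULL
  s
}

# ---- brute-force CRF oracle ----

crf_brute <- function(E, Tr, tags) {
  n <- nrow(E); K <- ncol(E)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  sc <- apply(seqs, 1, function(y) {
    s <- sum(E[cbind(seq_len(n), y)])
    if (n > 1) s <- s + sum(Tr[cbind(y[-n], y[-1])])
    s
  })
  mx <- max(sc)
  logZ <- mx + log(sum(exp(sc - mx)))
  gold <- sum(E[cbind(seq_len(n), tags)]) +
    if (n > 1) sum(Tr[cbind(tags[-n], tags[-1])]) else 0
  list(logZ = logZ, loglik = gold - logZ, scores = sc, seqs = seqs,
       best = seqs[which.max(sc), ])
}

# ---- tiny model for numeric tests ----

tiny_model <- function(hidden = 4, layers = 2, scorer_width = 3, embed_dim = 5,
                       keep_prob = 1, seed = 3, lr = 1e-3) {
  cfg <- neuroeae_config(embed_dim = embed_dim, hidden = hidden, layers = layers,
                         scorer_width = scorer_width, keep_prob = keep_prob,
                         lr = lr)
  emb <- random_embeddings(c("alpha", "beta", "gamma"), dim = embed_dim, seed = 2)
  init_model(dictionary_set(list(BRI = "alpha")), emb, cfg, seed = seed)
}

# small synthetic world shared by slower tests
small_world <- function(seed = 5, n = 60) {
  g <- generate_corpus(synth_config(seed = seed, n_mentions = n))
  g$embeddings <- random_embeddings(g$resources$vocab, dim = 25, seed = seed)
  g
}
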