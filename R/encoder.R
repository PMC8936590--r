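# Multi-layer bidirectional LSTM encoder built on the compiled cell kernels.
# Parameters live in a flat named list so one optimizer handles everything.

rev_rows <- function(M) M[rev(seq_len(nrow(M))), , drop = FALSE]

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -r, r), nr, nc)
}

# parameter names for layer l, direction dir in c("f", "b")
.enc_names <- function(l, dir) {
  sprintf("enc%d%s_%s", l, dir, c("Wx", "Wh", "b"))
}

init_encoder_params <- function(input_dim, hidden, layers) {
  params <- list()
  for (l in seq_len(layers)) {
    d_in <- if (l == 1) input_dim else 2L * hidden
    for (dir in c("f", "b")) {
      nm <- .enc_names(l, dir)
      params[[nm[1]]] <- glorot(4L * hidden, d_in)
      params[[nm[2]]] <- glorot(4L * hidden, hidden)
      b <- numeric(4L * hidden)
      b[(hidden + 1):(2 * hidden)] <- 1  # forget-gate bias
      params[[nm[3]]] <- b
    }
  }
  params
}

#' Encode a feature matrix with the BiLSTM
#'
#' @param model A model from [init_model()].
#' @param X Feature matrix (`n x input_dim`), one row per token.
#' @return Hidden-state matrix `n x 2d` (forward and backward states
#'   concatenated).
#' @export
encode_sentence <- function(model, X) {
  encoder_forward(X, model$params, model$config, train = FALSE)$H
}

encoder_forward <- function(X, params, config, train = FALSE) {
  if (nrow(X) == 0) stop("cannot encode an empty sentence")
  keep <- config$keep_prob
  layers <- config$layers
  inp <- X
  caches <- vector("list", layers)
  for (l in seq_len(layers)) {
    nf <- .enc_names(l, "f"); nb <- .enc_names(l, "b")
    fwd <- lstm_cell_forward(inp, params[[nf[1]]], params[[nf[2]]], params[[nf[3]]])
    bwd <- lstm_cell_forward(rev_rows(inp), params[[nb[1]]], params[[nb[2]]],
                             params[[nb[3]]])
    H <- cbind(fwd$H, rev_rows(bwd$H))
    mask <- NULL
    if (train && keep < 1 && l < layers) {
      mask <- matrix(rbinom(length(H), 1, keep) / keep, nrow(H), ncol(H))
      Hout <- H * mask
    } else {
      Hout <- H
    }
    caches[[l]] <- list(input = inp, fwd = fwd, bwd = bwd, mask = mask)
    inp <- Hout
  }
  list(H = inp, caches = caches)
}

encoder_backward <- function(fw, params, config, dH) {
  layers <- config$layers
  hidden <- config$hidden
  grads <- list()
  d_out <- dH
  for (l in rev(seq_len(layers))) {
    cache <- caches_l <- fw$caches[[l]]
    if (!is.null(cache$mask)) d_out <- d_out * cache$mask
    nf <- .enc_names(l, "f"); nb <- .enc_names(l, "b")
    dHf <- d_out[, seq_len(hidden), drop = FALSE]
    dHb <- rev_rows(d_out[, hidden + seq_len(hidden), drop = FALSE])
    bf <- lstm_cell_backward(cache$input, params[[nf[1]]], params[[nf[2]]],
                             cache$fwd, dHf)
    bb <- lstm_cell_backward(rev_rows(cache$input), params[[nb[1]]],
                             params[[nb[2]]], cache$bwd, dHb)
    grads[[nf[1]]] <- bf$dWx; grads[[nf[2]]] <- bf$dWh; grads[[nf[3]]] <- as.numeric(bf$db)
    grads[[nb[1]]] <- bb$dWx; grads[[nb[2]]] <- bb$dWh; grads[[nb[3]]] <- as.numeric(bb$db)
    d_out <- bf$dX + rev_rows(bb$dX)
  }
  list(grads = grads, dX = d_out)
}
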