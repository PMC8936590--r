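# Free adversarial training: iterative perturbation of the input embedding
# vectors, reusing the input gradient of each update step, with the combined
# clean + adversarial joint objective.

#' Adversarial training configuration
#'
#' The perturbation radius is `eps = alpha * sqrt(D)` by default, where `D`
#' is the input embedding dimension; the literal `alpha * D` reading can be
#' toggled with `radius = "linear"`.
#'
#' @param alpha Perturbation factor (default 0.01).
#' @param k Inner replay count `K` (each minibatch is visited `K` consecutive
#'   times; the outer epoch count is divided by `K`).
#' @param radius `"sqrt"` for `alpha * sqrt(D)`, `"linear"` for `alpha * D`.
#' @return A list of class `adv_config`.
#' @export
adv_config <- function(alpha = 0.01, k = 3L, radius = c("sqrt", "linear")) {
  stopifnot(alpha >= 0, k >= 1)
  structure(list(alpha = alpha, k = as.integer(k), radius = match.arg(radius)),
            class = "adv_config")
}

adv_epsilon <- function(adv, D) {
  if (adv$radius == "sqrt") adv$alpha * sqrt(D) else adv$alpha * D
}

flat_norm <- function(xs) sqrt(sum(vapply(xs, function(x) sum(x^2), numeric(1))))

#' One perturbation step
#'
#' `r_next = r_prev + eps * g / ||g||` (global L2 norm across the whole
#' batch), then projection onto the L2 ball of radius `eps`.  A zero gradient
#' leaves the perturbation unchanged.
#'
#' @param g Gradient of the loss wrt the perturbed inputs: a matrix or a list
#'   of matrices (one per sentence in the batch).
#' @param r_prev Current perturbation, same shape as `g`.
#' @param eps Step size and projection radius.
#' @return The updated perturbation, same shape as the input.
#' @export
perturb_step <- function(g, r_prev, eps) {
  single <- !is.list(g)
  if (single) { g <- list(g); r_prev <- list(r_prev) }
  gn <- flat_norm(g)
  if (gn == 0) return(if (single) r_prev[[1]] else r_prev)  # zero-grad guard
  r <- Map(function(ri, gi) ri + eps * gi / gn, r_prev, g)
  rn <- flat_norm(r)
  if (rn > eps) r <- lapply(r, function(ri) ri * (eps / rn))
  if (single) r[[1]] else r
}

#' Combined clean + adversarial loss of a batch
#'
#' Evaluates the joint loss on the original inputs and again on the inputs
#' shifted by `r_adv`, and sums the two, mirroring the training objective.
#' With `r_adv = 0` this is exactly twice the clean loss.
#'
#' @param model A `neuroeae_model`.
#' @param batch A prepared batch: list of `list(X, tags, Y)` entries (see
#'   [train_freeat()]); a corpus of [annotated_sentence()] objects is
#'   prepared automatically.
#' @param r_adv List of perturbation matrices, one per batch entry.
#' @return Scalar: summed clean plus perturbed joint loss over the batch.
#' @export
adversarial_loss <- function(model, batch, r_adv) {
  if (length(batch) && !is.null(batch[[1]]$tokens)) {
    batch <- prepare_corpus(model, batch)
  }
  tot <- 0
  for (i in seq_along(batch)) {
    s <- batch[[i]]
    tot <- tot + sentence_loss(model, s$X, s$tags, s$Y)$loss +
      sentence_loss(model, s$X + r_adv[[i]], s$tags, s$Y)$loss
  }
  tot
}

#' Train the joint model with free adversarial training
#'
#' Each minibatch is replayed `K` consecutive times.  Every replay runs a
#' clean pass and a pass on the perturbed inputs, takes one Adam step on the
#' summed objective, and re-uses the perturbed pass's input gradient to
#' update the perturbation (normalized step of length `eps`, projected back
#' onto the `eps`-ball).  The perturbation is reset at every new batch, and
#' the outer epoch count is `ceiling(epochs / K)`.  With `adv = NULL` this is
#' plain joint training (single clean pass per batch, `epochs` outer epochs).
#'
#' @inheritParams train_model
#' @param adv An [adv_config()], or `NULL` for plain training.
#' @return The trained model; the `"history"` attribute holds a data.frame
#'   with per-outer-epoch mean clean joint loss.
#' @export
train_freeat <- function(model, corpus, adv = adv_config(), epochs = NULL,
                         batch_size = NULL, seed = 1L, verbose = FALSE,
                         features = NULL) {
  epochs <- if (is.null(epochs)) model$config$epochs else as.integer(epochs)
  batch_size <- if (is.null(batch_size)) model$config$batch_size else as.integer(batch_size)
  data <- prepare_corpus(model, corpus, features)
  ns <- length(data)
  if (!ns) stop("empty training corpus")
  K <- if (is.null(adv)) 1L else adv$k
  outer_epochs <- as.integer(ceiling(epochs / K))
  D <- model$config$input_dim
  eps <- if (is.null(adv)) 0 else adv_epsilon(adv, D)
  opt <- adam_init(model$params)
  trace <- numeric(outer_epochs)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (ep in seq_len(outer_epochs)) {
    ord <- sample.int(ns)
    ep_loss <- 0; ep_count <- 0L
    for (bs in split(ord, ceiling(seq_along(ord) / batch_size))) {
      r_adv <- lapply(data[bs], function(s) s$X * 0)
      for (rep_i in seq_len(K)) {
        grads <- NULL
        gX <- vector("list", length(bs))
        clean_loss <- 0
        for (bi in seq_along(bs)) {
          s <- data[[bs[bi]]]
          cl <- sentence_grads(model, s$X, s$tags, s$Y, train = TRUE)
          clean_loss <- clean_loss + cl$loss
          grads <- acc_grads(grads, cl$grads, 1 / length(bs))
          if (!is.null(adv) && adv$alpha > 0) {
            pt <- sentence_grads(model, s$X + r_adv[[bi]], s$tags, s$Y, train = TRUE)
            grads <- acc_grads(grads, pt$grads, 1 / length(bs))
            gX[[bi]] <- pt$dX
          }
        }
        if (!is.null(adv) && adv$alpha > 0) {
          r_adv <- perturb_step(gX, r_adv, eps)
        }
        st <- adam_step(model$params, grads, opt, model$config$lr)
        model$params <- st$params
        opt <- st$state
        ep_loss <- ep_loss + clean_loss
        ep_count <- ep_count + length(bs)
      }
    }
    trace[ep] <- ep_loss / (ep_count)
    if (verbose) message(sprintf("epoch %d/%d: mean clean joint loss %.4f",
                                 ep, outer_epochs, trace[ep]))
  }
  attr(model, "history") <- data.frame(epoch = seq_len(outer_epochs),
                                       loss = trace)
  model
}
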