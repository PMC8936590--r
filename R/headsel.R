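# Multi-head selection layer: every token scores every candidate head under
# every relation label; sigmoid probabilities allow multi-label arcs.
# Pair rows are ordered dependent-major: row (i-1)*n + j is (dep i, head j).

pair_index <- function(n) {
  list(dep = rep(seq_len(n), each = n), head = rep_len(seq_len(n), n * n))
}

#' Head-selection score for a single token pair
#'
#' Computes `V_k f(U h_i + W h_j + b)` with `f = tanh`, the score that token
#' `j` heads token `i` under relation `k`; the selection probability is its
#' sigmoid.
#'
#' @param hi,hj Hidden-state vectors of the dependent and candidate head.
#' @param params Named list with `selU` (`l x 2d`), `selW` (`l x 2d`), `selb`
#'   (`l`), `selV` (`R x l`), `selc` (`R`).
#' @param relation Relation index (1-based) or label from
#'   [relation_labels()].
#' @return List with `score` and `prob`.
#' @export
head_score <- function(hi, hj, params, relation = 1L) {
  if (is.character(relation)) relation <- match(relation, relation_labels())
  z <- tanh(params$selU %*% hi + params$selW %*% hj + params$selb)
  s <- drop(params$selV[relation, , drop = FALSE] %*% z) + params$selc[relation]
  list(score = s, prob = 1 / (1 + exp(-s)))
}

# batch scores for all pairs; returns probs (n^2 x R) plus caches for backprop
head_forward <- function(H, params) {
  n <- nrow(H)
  idx <- pair_index(n)
  P1 <- H %*% t(params$selU)  # n x l
  P2 <- H %*% t(params$selW)
  Zpre <- P1[idx$dep, , drop = FALSE] + P2[idx$head, , drop = FALSE] +
    matrix(params$selb, n * n, length(params$selb), byrow = TRUE)
  Z <- tanh(Zpre)
  S <- Z %*% t(params$selV) + matrix(params$selc, n * n, nrow(params$selV),
                                     byrow = TRUE)
  probs <- 1 / (1 + exp(-S))
  list(probs = probs, S = S, Z = Z, P1 = P1, P2 = P2, idx = idx, n = n)
}

# gradient of summed BCE; returns grads for selector params and dH
head_backward <- function(H, params, fw, Y) {
  dS <- fw$probs - Y
  dZ <- (dS %*% params$selV) * (1 - fw$Z^2)
  dV <- t(dS) %*% fw$Z
  dc <- colSums(dS)
  db <- colSums(dZ)
  dP1 <- rowsum(dZ, fw$idx$dep)   # groups 1..n in order
  dP2 <- rowsum(dZ, fw$idx$head)
  dU <- t(dP1) %*% H
  dW <- t(dP2) %*% H
  dH <- dP1 %*% params$selU + dP2 %*% params$selW
  list(grads = list(selU = dU, selW = dW, selb = db, selV = dV, selc = dc),
       dH = dH)
}

#' Gold arcs of a sentence's mentions
#'
#' Arc direction is dependent-to-head: argument start to trigger start under
#' the event-qualified role, attribute start to argument start under the
#' `<category>-attribute` relation.  Role links whose qualified label is not
#' in the 18-label relation inventory are dropped.  Every token that is not a
#' dependent of any arc carries a self-arc labelled `"none"`.
#'
#' @param mentions List of [event_mention()] objects.
#' @param n Sentence length.
#' @return data.frame with columns `dep`, `head`, `relation`.
#' @export
mentions_to_arcs <- function(mentions, n) {
  labs <- relation_labels()
  dep <- integer(); head_ <- integer(); rel <- character()
  for (m in mentions) {
    rl <- m$role_links
    for (i in seq_len(nrow(rl))) {
      q <- paste0(m$category, "-", rl$role[i])
      if (q %in% labs) {
        dep <- c(dep, rl$start[i]); head_ <- c(head_, m$trigger[1]); rel <- c(rel, q)
      }
    }
    al <- m$attribute_links
    for (i in seq_len(nrow(al))) {
      q <- paste0(sub("_A$", "", al$category[i]), "-attribute")
      if (q %in% labs) {
        dep <- c(dep, al$start[i]); head_ <- c(head_, al$arg_start[i]); rel <- c(rel, q)
      }
    }
  }
  loose <- setdiff(seq_len(n), dep)
  data.frame(dep = c(dep, loose), head = c(head_, loose),
             relation = c(rel, rep("none", length(loose))),
             stringsAsFactors = FALSE)
}

# binary target matrix (n^2 x R) from an arc data.frame
arcs_to_matrix <- function(arcs, n) {
  labs <- relation_labels()
  Y <- matrix(0, n * n, length(labs))
  if (nrow(arcs)) {
    k <- match(arcs$relation, labs)
    if (anyNA(k)) stop("unknown relation label(s): ",
                       paste(unique(arcs$relation[is.na(k)]), collapse = ", "))
    Y[cbind((arcs$dep - 1L) * n + arcs$head, k)] <- 1
  }
  Y
}

#' Summed binary cross-entropy of the head-selection layer
#'
#' @param probs `n^2 x 18` matrix of arc probabilities (dependent-major pair
#'   order).
#' @param gold_arcs data.frame of gold arcs (`dep`, `head`, `relation`), e.g.
#'   from [mentions_to_arcs()].
#' @return Non-negative scalar loss.
#' @export
rar_loss <- function(probs, gold_arcs) {
  n <- as.integer(sqrt(nrow(probs)))
  stopifnot(n * n == nrow(probs))
  Y <- arcs_to_matrix(gold_arcs, n)
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  -sum(Y * log(p) + (1 - Y) * log(1 - p))
}

#' Threshold decoding of head-selection probabilities
#'
#' Keeps every arc with probability strictly above the threshold and drops
#' `"none"` self-arcs.
#'
#' @param probs `n^2 x 18` probability matrix (dependent-major pair order).
#' @param theta Decoding threshold in (0, 1).
#' @return data.frame with columns `dep`, `head`, `relation`, `prob`.
#' @export
decode_links <- function(probs, theta = 0.5) {
  n <- as.integer(sqrt(nrow(probs)))
  stopifnot(n * n == nrow(probs), theta > 0, theta < 1)
  labs <- relation_labels()
  hits <- which(probs > theta, arr.ind = TRUE)
  if (!nrow(hits)) {
    return(data.frame(dep = integer(), head = integer(), relation = character(),
                      prob = numeric(), stringsAsFactors = FALSE))
  }
  idx <- pair_index(n)
  out <- data.frame(dep = idx$dep[hits[, 1]], head = idx$head[hits[, 1]],
                    relation = labs[hits[, 2]],
                    prob = probs[hits], stringsAsFactors = FALSE)
  out <- out[out$relation != "none", , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$dep, out$head), , drop = FALSE]
}

#' Joint training objective
#'
#' @param l_ner CRF tagging loss.
#' @param l_rar Head-selection loss.
#' @return Their sum.
#' @export
joint_loss <- function(l_ner, l_rar) l_ner + l_rar
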