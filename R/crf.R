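# Linear-chain CRF over element tags: sequence score = sum of emissions plus
# sum of pairwise transitions; normalization by the forward algorithm in
# log-space; exact gradients by forward-backward.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# column/row log-sum-exp without apply() overhead
.lse_cols <- function(M) {
  mx <- M[cbind(max.col(t(M)), seq_len(ncol(M)))]
  mx + log(colSums(exp(M - rep(mx, each = nrow(M)))))
}
.lse_rows <- function(M) {
  mx <- M[cbind(seq_len(nrow(M)), max.col(M))]
  mx + log(rowSums(exp(M - mx)))
}

crf_alphas <- function(E, Tr) {
  n <- nrow(E); K <- ncol(E)
  alpha <- matrix(0, n, K)
  alpha[1, ] <- E[1, ]
  if (n > 1) for (t in 2:n) {
    alpha[t, ] <- E[t, ] + .lse_cols(alpha[t - 1, ] + Tr)  # rows k -> cols j
  }
  alpha
}

crf_betas <- function(E, Tr) {
  n <- nrow(E); K <- ncol(E)
  beta <- matrix(0, n, K)
  if (n > 1) for (t in (n - 1):1) {
    M <- Tr + matrix(E[t + 1, ] + beta[t + 1, ], K, K, byrow = TRUE)
    beta[t, ] <- .lse_rows(M)
  }
  beta
}

crf_sequence_score <- function(E, Tr, tags) {
  n <- nrow(E)
  s <- sum(E[cbind(seq_len(n), tags)])
  if (n > 1) s <- s + sum(Tr[cbind(tags[-n], tags[-1])])
  s
}

#' CRF log-likelihood of a tag sequence
#'
#' @param emissions `n x K` matrix of per-token tag scores.
#' @param transitions `K x K` transition score matrix (`T[a, b]` scores tag
#'   `a` followed by tag `b`).
#' @param tags Integer tag indices (1-based) of the gold sequence, or a
#'   character vector over [element_tags()].
#' @return List with `loglik` (<= 0), `logZ`, `score` and `nll` (the negative
#'   log-likelihood, the tagging loss contribution).
#' @export
crf_loglik <- function(emissions, transitions, tags) {
  if (is.character(tags)) {
    idx <- match(tags, element_tags())
    if (anyNA(idx)) stop("unknown tag(s): ", paste(tags[is.na(idx)], collapse = ", "))
    tags <- idx
  }
  K <- ncol(emissions)
  if (length(tags) != nrow(emissions)) stop("tag/emission length mismatch")
  if (any(tags < 1 | tags > K)) stop("tag index outside the label set")
  alpha <- crf_alphas(emissions, transitions)
  logZ <- logsumexp(alpha[nrow(emissions), ])
  score <- crf_sequence_score(emissions, transitions, tags)
  ll <- score - logZ
  list(loglik = ll, logZ = logZ, score = score, nll = -ll)
}

# NLL plus exact gradients wrt emissions and transitions (compiled kernel).
crf_grad <- function(E, Tr, tags) {
  crf_grad_cpp(E, Tr, as.integer(tags))
}

#' Viterbi decoding
#'
#' Ties are broken toward the lowest tag index at every backpointer.
#'
#' @inheritParams crf_loglik
#' @return Integer vector of tag indices of the highest-scoring sequence.
#' @export
crf_decode <- function(emissions, transitions) {
  n <- nrow(emissions); K <- ncol(emissions)
  if (n == 0) return(integer())
  delta <- matrix(-Inf, n, K)
  back <- matrix(0L, n, K)
  delta[1, ] <- emissions[1, ]
  if (n > 1) for (t in 2:n) {
    M <- delta[t - 1, ] + transitions  # K x K
    back[t, ] <- max.col(t(M), ties.method = "first")  # lowest tag index wins
    delta[t, ] <- emissions[t, ] + M[cbind(back[t, ], seq_len(K))]
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
  path
}
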