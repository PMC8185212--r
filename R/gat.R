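# Gate-augmented graph attention layer.
#
# One layer maps node embeddings X (N x F) under an adjacency A to new
# embeddings:
#   x'_i  = W x_i
#   e_ij  = x'_i^T E x'_j + x'_j^T E x'_i          (symmetric, on A_ij > 0)
#   a_ij  = softmax_{j in N_i}(e_ij) * A_ij        (N_i = {j : A_ij > 0})
#   x''_i = sum_j a_ij x'_j
#   c_i   = logistic(D . (x_i || x''_i) + b)
#   out_i = c_i x_i + (1 - c_i) x''_i
# The attention is bilinear and symmetric (no LeakyReLU, no multi-head);
# for a weighted adjacency the A_ij factor is applied after softmax
# normalization, so weighted rows need not sum to 1.

.LOGIT_CLIP <- 50  # logits clipped to +/- 50 before exponentiation

#' Random parameters of one gated attention layer
#'
#' Weight matrices are Glorot-uniform, gate bias 0.
#'
#' @param F feature width.
#' @return list with `W` (FxF), `E` (FxF), `D` (length 2F), `b` (scalar).
#' @export
gatLayerParams <- function(F) {
  list(W = .glorot(F, F), E = .glorot(F, F),
       D = as.numeric(.glorot(1, 2 * F)), b = 0)
}

.glorot <- function(nout, nin) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nout * nin, -l, l), nout, nin)
}

#' Symmetric bilinear attention logits
#'
#' Computes `e_ij = x'_i^T E x'_j + x'_j^T E x'_i` with `x' = W x`, only on
#' the support of `A` (`A_ij > 0`); entries off the support are `-Inf`.
#' Logits on the support are clipped to +/- 50.
#'
#' @param X N x F node embedding matrix.
#' @param params layer parameters (see [gatLayerParams()]).
#' @param A adjacency matrix (binary or weighted).
#' @return N x N matrix of logits, `-Inf` off the support.
#' @export
attentionLogits <- function(X, params, A) {
  stopifnot(ncol(X) == ncol(params$W), all(dim(A) == nrow(X)))
  Xp <- X %*% t(params$W)
  S <- (Xp %*% params$E) %*% t(Xp)
  L <- S + t(S)
  L <- pmin(pmax(L, -.LOGIT_CLIP), .LOGIT_CLIP)
  L[!(A > 0)] <- -Inf
  L
}

#' Normalized, adjacency-modulated attention weights
#'
#' Row-wise softmax of the logits over each node's neighbourhood
#' (max-subtracted for stability), multiplied elementwise by `A`.  With a
#' binary adjacency every row sums to exactly 1 over the neighbourhood.
#'
#' @param logits N x N logit matrix (`-Inf` off support).
#' @param A adjacency matrix.
#' @return N x N attention weight matrix.
#' @export
attentionWeights <- function(logits, A) {
  sup <- A > 0
  L <- logits
  L[!sup] <- -Inf
  m <- apply(L, 1, max)
  Z <- exp(L - m)
  Z[!sup] <- 0
  (Z / rowSums(Z)) * A
}

#' Attention-weighted neighbourhood aggregation
#'
#' `x''_i = sum_j a_ij x'_j` with `x' = W x`.
#'
#' @param X N x F node embeddings.
#' @param a N x N attention weights.
#' @param params layer parameters.
#' @return N x F aggregated embeddings.
#' @export
aggregateNeighbors <- function(X, a, params) {
  a %*% (X %*% t(params$W))
}

#' Gated residual update
#'
#' Per-node convex combination `c_i x_i + (1 - c_i) x''_i` with the gate
#' `c_i = logistic(D . (x_i || x''_i) + b)`; `D` and `b` are shared across
#' nodes.
#'
#' @param Xin,Xagg N x F input and aggregated embeddings.
#' @param params layer parameters.
#' @return N x F updated embeddings.
#' @export
gatedUpdate <- function(Xin, Xagg, params) {
  stopifnot(all(dim(Xin) == dim(Xagg)))
  cg <- stats::plogis(cbind(Xin, Xagg) %*% params$D + params$b)
  cg <- as.numeric(cg)
  cg * Xin + (1 - cg) * Xagg
}

#' One full gated attention layer
#'
#' Convenience composition of [attentionLogits()], [attentionWeights()],
#' [aggregateNeighbors()] and [gatedUpdate()].
#'
#' @inheritParams attentionLogits
#' @return N x F updated node embeddings.
#' @export
gatLayer <- function(X, params, A) {
  L <- attentionLogits(X, params, A)
  a <- attentionWeights(L, A)
  gatedUpdate(X, aggregateNeighbors(X, a, params), params)
}

# ---- internal forward/backward with cache (training path) ----

.gatForward <- function(H, A, sup, params) {
  Xp <- H %*% t(params$W)
  S <- (Xp %*% params$E) %*% t(Xp)
  L <- S + t(S)
  clip <- abs(L) > .LOGIT_CLIP
  L <- pmin(pmax(L, -.LOGIT_CLIP), .LOGIT_CLIP)
  L[!sup] <- -Inf
  m <- apply(L, 1, max)
  Z <- exp(L - m)
  Z[!sup] <- 0
  P <- Z / rowSums(Z)
  a <- P * A
  Xagg <- a %*% Xp
  z <- as.numeric(cbind(H, Xagg) %*% params$D + params$b)
  cg <- stats::plogis(z)
  out <- cg * H + (1 - cg) * Xagg
  list(out = out, H = H, Xp = Xp, P = P, a = a, A = A, sup = sup,
       clip = clip, Xagg = Xagg, cg = cg)
}

.gatBackward <- function(dOut, cache, params) {
  F <- ncol(cache$H)
  H <- cache$H; Xagg <- cache$Xagg; cg <- cache$cg
  dc <- rowSums(dOut * (H - Xagg))
  dH <- dOut * cg
  dXagg <- dOut * (1 - cg)
  dz <- dc * cg * (1 - cg)
  dD <- as.numeric(crossprod(cbind(H, Xagg), dz))
  db <- sum(dz)
  dG <- outer(dz, params$D)
  dH <- dH + dG[, seq_len(F), drop = FALSE]
  dXagg <- dXagg + dG[, F + seq_len(F), drop = FALSE]
  da <- dXagg %*% t(cache$Xp)
  dXp <- crossprod(cache$a, dXagg)
  dP <- da * cache$A
  dA <- da * cache$P
  rs <- rowSums(cache$P * dP)
  dL <- cache$P * (dP - rs)
  dL[cache$clip | !cache$sup] <- 0
  dS <- dL + t(dL)
  dXp <- dXp + dS %*% cache$Xp %*% t(params$E) +
    t(dS) %*% cache$Xp %*% params$E
  dE <- crossprod(cache$Xp, dS %*% cache$Xp)
  dW <- crossprod(dXp, H)
  dH <- dH + dXp %*% params$W
  list(dH = dH, dW = dW, dE = dE, dD = dD, db = db, dA = dA)
}
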