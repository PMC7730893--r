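#' @title Negative-focused weight-biased softmax (w-softmax)
#' @description
#' The w-softmax loss widens angular decision margins by biasing every
#' negative class's weight vector toward the positive class's weight
#' vector before the softmax: with unit-norm class weights `w_j` and bias
#' strength `gamma >= 0`, each negative column is replaced by
#' `w_i' = (gamma * w_c + w_i) / ||gamma * w_c + w_i||` while the positive
#' column is kept. Logits are inner products of the (biased) unit weights
#' with the unnormalized feature vector, so the probabilities equal
#' `softmax([w_c . x, {w_j' . x}])`. Setting `gamma = 0` recovers plain
#' softmax cross-entropy exactly, in both the loss value and its
#' gradients.
#' @name wsoftmax
NULL

normalize_columns <- function(W) {
  nrm <- sqrt(colSums(W^2))
  if (any(nrm < 1e-12)) stop("cannot normalize a zero weight column")
  sweep(W, 2, nrm, "/")
}

#' Bias the negative class weights toward the positive class
#'
#' @param W `d x C` matrix of unit-norm class weight columns.
#' @param c_idx Index of the positive class column.
#' @param gamma Non-negative bias strength; 0 leaves `W` unchanged.
#' @return `d x C` matrix: column `c_idx` untouched, every other column
#'   replaced by the renormalized biased vector.
#' @export
bias_negative_weights <- function(W, c_idx, gamma) {
  if (gamma < 0) stop("gamma must be non-negative")
  if (c_idx < 1 || c_idx > ncol(W)) stop("positive class index out of range")
  if (gamma == 0) return(W)
  out <- W
  wc <- W[, c_idx]
  for (i in seq_len(ncol(W))[-c_idx]) {
    v <- gamma * wc + W[, i]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) {
      stop("degenerate bias: gamma * w_c + w_i vanishes for class ", i)
    }
    out[, i] <- v / nv
  }
  out
}

#' Class probabilities under w-softmax
#'
#' @param x Feature vector of length `d` (not normalized; its magnitude
#'   scales the logits).
#' @param W `d x C` matrix of unit-norm class weights.
#' @param c_idx Positive class index.
#' @param gamma Bias strength.
#' @return Probability vector of length `C` (entries in (0, 1), summing
#'   to 1).
#' @export
wsoftmax_probabilities <- function(x, W, c_idx, gamma) {
  if (any(!is.finite(x))) stop("non-finite feature vector")
  Wb <- bias_negative_weights(W, c_idx, gamma)
  z <- drop(crossprod(Wb, x))
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' w-softmax cross-entropy loss with analytic gradients
#'
#' Computes the mean cross-entropy over a batch where each sample's
#' negative weights are biased toward its own positive class. At
#' `gamma = 0` the biasing is skipped and the function is exactly standard
#' softmax cross-entropy on the logits `W^T x`. For `gamma > 0` gradients
#' flow through the full bias-and-renormalize chain, for both the features
#' and the weight matrix.
#'
#' @param X `N x d` feature matrix (one row per sample).
#' @param labels Integer class indices in `1..C`.
#' @param W `d x C` weight matrix; columns are expected unit-norm (the
#'   function itself does not renormalize).
#' @param gamma Non-negative bias strength.
#' @param grads If `TRUE` (default) also return `dX` and `dW`.
#' @return List with `loss` (scalar mean loss), `probs` (`N x C`), and if
#'   requested `dX` (`N x d`) and `dW` (`d x C`), gradients of the mean
#'   loss.
#' @export
wsoftmax_loss <- function(X, labels, W, gamma = 1, grads = TRUE) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  N <- nrow(X)
  C <- ncol(W)
  labels <- as.integer(labels)
  if (any(labels < 1 | labels > C)) stop("label out of range 1..C")
  if (gamma < 0) stop("gamma must be non-negative")
  if (any(!is.finite(X))) stop("non-finite features")

  if (gamma == 0) {
    Z <- X %*% W
    Zs <- Z - apply(Z, 1, max)
    P <- exp(Zs) / rowSums(exp(Zs))
    loss <- -mean(log(P[cbind(seq_len(N), labels)]))
    if (!grads) return(list(loss = loss, probs = P))
    G <- P
    G[cbind(seq_len(N), labels)] <- G[cbind(seq_len(N), labels)] - 1
    G <- G / N
    return(list(loss = loss, probs = P, dX = G %*% t(W), dW = t(X) %*% G))
  }

  P <- matrix(0, N, C)
  dX <- if (grads) matrix(0, N, ncol(X)) else NULL
  dW <- if (grads) matrix(0, nrow(W), C) else NULL
  loss <- 0
  for (n in seq_len(N)) {
    x <- X[n, ]
    cdx <- labels[n]
    wc <- W[, cdx]
    Wb <- W          # per-sample biased weights
    Vn <- numeric(C) # ||gamma w_c + w_i||
    for (i in seq_len(C)[-cdx]) {
      v <- gamma * wc + W[, i]
      nv <- sqrt(sum(v^2))
      if (nv < 1e-12) stop("degenerate bias for class ", i)
      Wb[, i] <- v / nv
      Vn[i] <- nv
    }
    z <- drop(crossprod(Wb, x))
    zs <- z - max(z)
    e <- exp(zs)
    p <- e / sum(e)
    P[n, ] <- p
    loss <- loss - log(p[cdx])
    if (grads) {
      g <- p
      g[cdx] <- g[cdx] - 1 # dL/dz for this sample
      dX[n, ] <- drop(Wb %*% g)
      # back through w_i' = v_i / ||v_i||: P_i u = (u - w_i'(w_i'.u))/||v_i||
      dwc <- g[cdx] * x
      for (i in seq_len(C)[-cdx]) {
        u <- g[i] * x
        pu <- (u - Wb[, i] * sum(Wb[, i] * u)) / Vn[i]
        dW[, i] <- dW[, i] + pu
        dwc <- dwc + gamma * pu
      }
      dW[, cdx] <- dW[, cdx] + dwc
    }
  }
  loss <- loss / N
  if (grads) {
    dX <- dX / N
    dW <- dW / N
    list(loss = loss, probs = P, dX = dX, dW = dW)
  } else {
    list(loss = loss, probs = P)
  }
}
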