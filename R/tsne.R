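# Exact t-distributed stochastic neighbor embedding (suitable for the few
# thousand segments a desk-scale study produces; O(n^2) memory and time).

#' t-SNE embedding of a feature matrix
#'
#' Classic exact t-SNE: per-point Gaussian bandwidths calibrated to the
#' target perplexity by bisection, symmetrized affinities with early
#' exaggeration, and momentum gradient descent on the Student-t low-
#' dimensional similarities. Deterministic given `seed`.
#'
#' @param X Numeric matrix (rows = points).
#' @param dims Output dimensionality.
#' @param perplexity Target perplexity (effective neighborhood size);
#'   reduced automatically when there are few points.
#' @param max_iter Gradient-descent iterations.
#' @param learning_rate Gradient step size.
#' @param seed Integer seed for the initial layout.
#' @return An n x `dims` coordinate matrix.
#' @export
tsne_embed <- function(X, dims = 2, perplexity = 30, max_iter = 300,
                       learning_rate = 100, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 4)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  sq <- rowSums(X^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(X), 0)
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) {
        h <- 0
      } else {
        p <- w / sw
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(h - logU) < 1e-5) break
      if (h > logU) {
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    w <- exp(-di * beta)
    pi <- w / max(sum(w), .Machine$double.eps)
    P[i, -i] <- pi
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- with_seed(seed, matrix(stats::rnorm(n * dims, 0, 1e-4), n, dims))
  dY <- matrix(0, n, dims)
  momentum <- 0.5
  exaggeration <- 4
  for (iter in seq_len(max_iter)) {
    Pe <- if (iter <= 50) P * exaggeration else P
    sqy <- rowSums(Y^2)
    num <- 1 / (1 + pmax(outer(sqy, sqy, "+") - 2 * tcrossprod(Y), 0))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
    if (iter == 250) momentum <- 0.8
    dY <- momentum * dY - learning_rate * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
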