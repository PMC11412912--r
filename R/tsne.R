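# Compact exact t-SNE (no Barnes-Hut tree): intended for the small point
# sets this package embeds (an observed fingerprint plus a handful of
# standards, or a few dozen replicates). Visualization only -- assignments
# are never read off the layout.

perplexity_probs <- function(d2_row, perplexity, tol = 1e-5, max_iter = 50L) {
  # binary search the Gaussian bandwidth so the row entropy matches
  # log(perplexity)
  beta <- 1
  lo <- -Inf; hi <- Inf
  target <- log(perplexity)
  for (i in seq_len(max_iter)) {
    p <- exp(-d2_row * beta)
    sum_p <- sum(p)
    if (sum_p == 0) { p <- rep(1 / length(p), length(p)); break }
    h <- log(sum_p) + beta * sum(d2_row * p) / sum_p
    p <- p / sum_p
    if (abs(h - target) < tol) break
    if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
    else            { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
  }
  p
}

#' t-SNE layout of a small set of frequency vectors
#'
#' Exact (dense) t-distributed stochastic neighbour embedding with fixed seed,
#' used to visualise similarity among exon detection-frequency tables or
#' replicate profiles. Deterministic under a fixed seed.
#'
#' @param X numeric matrix, rows = points.
#' @param perplexity Gaussian perplexity; must be `< nrow(X)`.
#' @param seed integer seed for the initial layout.
#' @param n_iter gradient-descent iterations.
#' @return numeric matrix `nrow(X)` x 2 of layout coordinates.
#' @export
tsne_layout <- function(X, perplexity = min(5, nrow(X) - 1), seed = 1L,
                        n_iter = 400L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 points to embed")
  if (perplexity >= n) stop("perplexity must be < number of points")
  d2 <- as.matrix(dist(X))^2
  P <- matrix(0, n, n)
  for (i in seq_len(n)) P[i, -i] <- perplexity_probs(d2[i, -i], perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, .Machine$double.eps)
  set.seed(seed)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  momentum <- 0.5
  eta <- 100
  exaggeration <- 4
  for (iter in seq_len(n_iter)) {
    Pe <- if (iter <= 100L) P * exaggeration else P
    num <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.eps)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    if (iter == 250L) momentum <- 0.8
    inc <- momentum * inc - eta * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
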