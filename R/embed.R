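# Exact (O(n^2)) t-SNE for modest point sets. Conditional input
# similarities are calibrated per point to a target perplexity by bisection
# on the Gaussian precision; the 2-D map minimizes KL(P || Q) with the
# Student-t kernel by gradient descent with momentum and early exaggeration.
# Deterministic given `seed`.

tsne_embed <- function(X, seed, perplexity = 30, n_iter = 400, eta = 100,
                       exaggeration = 4, exaggeration_iter = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("too few points to embed", call. = FALSE)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  perplexity <- max(perplexity, 2)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s == 0) { p <- rep(1 / length(di), length(di)); break }
      H <- log(s) + beta * sum(di * p) / s
      p <- p / s
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  V <- matrix(0, n, 2)
  momentum <- 0.5
  for (it in seq_len(n_iter)) {
    Pex <- if (it <= exaggeration_iter) P * exaggeration else P
    sum_y <- rowSums(Y^2)
    num <- 1 / (1 + outer(sum_y, sum_y, "+") - 2 * Matrix::tcrossprod(Y))
    num <- as.matrix(num)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    G <- (Pex - Q) * num
    grad <- 4 * (diag(rowSums(G)) %*% Y - G %*% Y)
    if (it == 250) momentum <- 0.8
    V <- momentum * V - eta * grad
    Y <- Y + V
    Y <- sweep(Y, 2, colMeans(Y))
  }
  dimnames(Y) <- list(rownames(X), c("dim1", "dim2"))
  Y
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
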