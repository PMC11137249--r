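## Random sample sets as d x n matrices, drawn from the current RNG state.
rand_samples <- function(n, d, scale = 1) {
  matrix(stats::runif(d * n, 0, scale), d, n)
}

## Independent brute-force HSIC oracle: explicit double loop over the trace
## of the product of double-centered Gram matrices. Deliberately naive.
hsic_brute <- function(X, Y, sigma_x, sigma_y) {
  n <- ncol(X)
  kmat <- function(M, s) {
    K <- matrix(0, n, n)
    for (p in 1:n) for (q in 1:n) {
      K[p, q] <- exp(-sum((M[, p] - M[, q])^2) / s^2)
    }
    K
  }
  H <- diag(n) - matrix(1 / n, n, n)
  A <- H %*% kmat(X, sigma_x) %*% H
  B <- H %*% kmat(Y, sigma_y) %*% H
  tr <- 0
  for (p in 1:n) for (q in 1:n) tr <- tr + A[p, q] * B[q, p]
  tr / (n - 1)^2
}

## Build a filled sample_memory from column matrices (column 1 pushed last,
## i.e. column 1 of each matrix becomes the current sample).
fill_memory <- function(X, Y, Z, capacity = ncol(X)) {
  mem <- sample_memory(capacity)
  for (i in rev(seq_len(ncol(X)))) {
    mem <- memory_push(mem, X[, i], Y[, i], Z[, i])
  }
  mem
}

## Central finite differences of f(W, b) around a layer's parameters.
fd_layer_grad <- function(f, W, b, h = 1e-5) {
  dW <- W * 0
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W))) {
    Wp <- W; Wp[i, j] <- Wp[i, j] + h
    Wm <- W; Wm[i, j] <- Wm[i, j] - h
    dW[i, j] <- (f(Wp, b) - f(Wm, b)) / (2 * h)
  }
  db <- numeric(length(b))
  for (i in seq_along(b)) {
    bp <- b; bp[i] <- bp[i] + h
    bm <- b; bm[i] <- bm[i] - h
    db[i] <- (f(W, bp) - f(W, bm)) / (2 * h)
  }
  list(dW = dW, db = db)
}

## Relative error between two gradient-like lists, guarded for zero grads.
rel_err <- function(a, b) {
  denom <- max(abs(unlist(b)), 1e-8)
  max(abs(unlist(a) - unlist(b))) / denom
}
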