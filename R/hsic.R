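#' Gaussian similarity kernel
#'
#' Evaluates the radial-basis similarity `exp(-||a - b||^2 / sigma^2)` between
#' two vectors. Note the bandwidth convention: the exponent denominator is
#' `sigma^2`, not `2 sigma^2`. All HSIC estimators and plasticity terms in the
#' package use this kernel.
#'
#' @param a,b Numeric vectors of equal length.
#' @param sigma Positive bandwidth.
#' @return A scalar in `(0, 1]`; exactly 1 iff `a == b`.
#' @examples
#' gaussian_kernel(c(0, 0), c(1, 0), 0.5) # exp(-4)
#' @export
gaussian_kernel <- function(a, b, sigma) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("gaussian_kernel: 'a' and 'b' must have the same length")
  }
  check_sigma(sigma)
  exp(-sum((a - b)^2) / sigma^2)
}

check_sigma <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("bandwidth 'sigma' must be a single positive number")
  }
  invisible(sigma)
}

## Samples as a matrix with one column per sample. Accepts a list of vectors,
## a numeric vector (univariate samples) or a d x n matrix.
as_sample_matrix <- function(x) {
  if (is.list(x)) {
    d <- unique(lengths(x))
    if (length(x) == 0L) stop("empty sample set")
    if (length(d) != 1L) stop("ragged sample set: unequal vector lengths")
    x <- matrix(as.numeric(unlist(x)), nrow = d, ncol = length(x))
  } else if (is.null(dim(x))) {
    x <- matrix(as.numeric(x), nrow = 1L)
  } else {
    x <- as.matrix(x)
  }
  if (ncol(x) == 0L) stop("empty sample set")
  storage.mode(x) <- "double"
  x
}

## Pairwise squared Euclidean distances between columns of A and columns of B.
pairwise_sqdist <- function(A, B = A) {
  an <- colSums(A^2)
  bn <- colSums(B^2)
  D <- outer(an, bn, "+") - 2 * crossprod(A, B)
  D[D < 0] <- 0
  D
}

#' Gram matrix of Gaussian kernel evaluations
#'
#' @param samples Samples: a `d x n` matrix (one column per sample), a list of
#'   equal-length numeric vectors, or a plain numeric vector of scalar samples.
#' @param sigma Positive bandwidth.
#' @return An `n x n` symmetric matrix with unit diagonal, entries in `(0, 1]`.
#' @export
gram_matrix <- function(samples, sigma) {
  check_sigma(sigma)
  X <- as_sample_matrix(samples)
  K <- exp(-pairwise_sqdist(X) / sigma^2)
  ## enforce exact symmetry/unit diagonal against rounding
  K <- (K + t(K)) / 2
  diag(K) <- 1
  K
}

#' One-sided (row) centering of a Gram matrix
#'
#' Subtracts each row's mean from the row, so every row of the result sums to
#' zero. This is the centering convention used by the diagonal "surprise"
#' terms of the learning rule.
#'
#' @param K A square numeric matrix.
#' @return Matrix of the same shape with zero row sums.
#' @export
center_rows <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("center_rows: 'K' must be square")
  K - rowMeans(K)
}

#' Double centering of a Gram matrix
#'
#' Computes `H K H` with `H = I - (1/n) 11'`; rows and columns of the result
#' each sum to zero. This is the centering used by the HSIC estimator.
#'
#' @inheritParams center_rows
#' @return Matrix of the same shape with zero row and column sums.
#' @export
double_center <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("double_center: 'K' must be square")
  K <- K - rowMeans(K)
  t(t(K) - colMeans(K))
}

#' HSIC statistical estimator
#'
#' The biased empirical Hilbert-Schmidt Independence Criterion
#' `(N - 1)^-2 tr(K_X H K_Y H)` with Gaussian kernels. Used here as a proxy
#' for the mutual information between layer activations and inputs or labels.
#'
#' @param X,Y Paired sample sets (same number of samples); see
#'   [gram_matrix()] for accepted layouts.
#' @param sigma_x,sigma_y Kernel bandwidths for `X` and `Y`.
#' @return A nonnegative scalar; symmetric in `(X, Y)`.
#' @export
hsic <- function(X, Y, sigma_x, sigma_y) {
  X <- as_sample_matrix(X)
  Y <- as_sample_matrix(Y)
  n <- ncol(X)
  if (ncol(Y) != n) stop("hsic: 'X' and 'Y' must have the same sample count")
  if (n < 2L) stop("hsic: at least 2 samples required")
  KX <- double_center(gram_matrix(X, sigma_x))
  KY <- double_center(gram_matrix(Y, sigma_y))
  sum(KX * t(KY)) / (n - 1)^2
}

#' Layer-wise information-bottleneck objective
#'
#' `HSIC(X, Z) - gamma * HSIC(Y, Z)`: compression of the input representation
#' traded against preservation of label information, evaluated at one hidden
#' layer. Minimized independently at every hidden layer during training.
#'
#' @param X Inputs, `Y` one-hot labels, `Z` layer activations (paired).
#' @param Y,Z See `X`.
#' @param params Kernel parameters from [kernel_params()].
#' @return A scalar (can be negative).
#' @export
hsic_objective <- function(X, Y, Z, params) {
  stopifnot(inherits(params, "kernel_params"))
  hsic(X, Z, params$sigma_x, params$sigma_z) -
    params$gamma * hsic(Y, Z, params$sigma_y, params$sigma_z)
}

#' Diagonal (per-sample) bound on the bottleneck objective
#'
#' The per-sample form
#' `(N - 1)^-2 sum_p [kbar(x_p, x_p) - gamma * kbar(y_p, y_p)] kbar(z_p, z_p)`,
#' where `kbar(a_p, a_p)` is the diagonal of the one-sided centered Gram
#' matrix (the "surprise" of sample `p`). The three-factor learning rule is
#' exactly gradient descent on this quantity; [full_hsic_gradient()] is its
#' analytic gradient and is finite-difference-checked against it.
#'
#' @inheritParams hsic_objective
#' @return A scalar.
#' @export
hsic_bound <- function(X, Y, Z, params) {
  stopifnot(inherits(params, "kernel_params"))
  X <- as_sample_matrix(X); Y <- as_sample_matrix(Y); Z <- as_sample_matrix(Z)
  n <- ncol(X)
  if (ncol(Y) != n || ncol(Z) != n) stop("hsic_bound: unequal sample counts")
  if (n < 2L) stop("hsic_bound: at least 2 samples required")
  sx <- 1 - rowMeans(gram_matrix(X, params$sigma_x))
  sy <- 1 - rowMeans(gram_matrix(Y, params$sigma_y))
  sz <- 1 - rowMeans(gram_matrix(Z, params$sigma_z))
  sum((sx - params$gamma * sy) * sz) / (n - 1)^2
}

#' Surprise of one sample within a set
#'
#' `1 - (1/N) sum_n k(x_p, x_n, sigma)`: one minus the mean kernel similarity
#' of sample `p` to the whole set (the self term is included in the mean).
#' Zero when all samples are identical; approaches 1 as the sample becomes
#' arbitrarily novel. The modulation signal is built from differences of
#' input- and label-surprise.
#'
#' @param p Index (1-based) of the sample of interest.
#' @param samples Sample set; see [gram_matrix()] for layouts.
#' @param sigma Positive bandwidth.
#' @return A scalar in `[0, 1)`.
#' @export
surprise <- function(p, samples, sigma) {
  check_sigma(sigma)
  X <- as_sample_matrix(samples)
  n <- ncol(X)
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p > n || p != round(p)) {
    stop("surprise: index 'p' out of range")
  }
  k <- exp(-colSums((X - X[, p])^2) / sigma^2)
  1 - mean(k)
}

## Surprise of every sample at once (rowMeans of the Gram matrix).
surprise_all <- function(samples, sigma) {
  1 - rowMeans(gram_matrix(samples, sigma))
}

#' Kernel parameters for the HSIC bottleneck
#'
#' Bundles the three Gaussian bandwidths and the bottleneck balance
#' `gamma`. `sigma_x` acts on raw inputs (features scaled to `[0,1]` by the
#' data generators), `sigma_z` on hidden-layer activations, `sigma_y` on
#' one-hot labels. `gamma` weights label-information preservation against
#' input compression; `gamma = 1` recovers the unweighted objective.
#'
#' @param sigma_x,sigma_z,sigma_y Positive bandwidths.
#' @param gamma Positive balance parameter.
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(sigma_x, sigma_z, sigma_y, gamma = 1) {
  for (v in list(sigma_x, sigma_z, sigma_y)) check_sigma(v)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("'gamma' must be a single positive number")
  }
  structure(list(sigma_x = sigma_x, sigma_z = sigma_z, sigma_y = sigma_y,
                 gamma = gamma),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf(
    "HSIC kernel parameters: sigma_x = %g, sigma_z = %g, sigma_y = %g, gamma = %g\n",
    x$sigma_x, x$sigma_z, x$sigma_y, x$gamma))
  invisible(x)
}
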