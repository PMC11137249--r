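#' Similarity drive between the current and a past layer output
#'
#' `alpha(z_p) = k(z_0, z_p) (z_0 - z_p)`: a vector that drives the current
#' representation toward (or, with a negative modulating weight, away from) a
#' buffered one, with strength weighted by their kernel similarity.
#'
#' @param z0 Current layer output.
#' @param zp A buffered layer output of the same length.
#' @param sigma_z Positive bandwidth of the layer kernel.
#' @return A numeric vector of the same length as `z0`.
#' @export
alpha_drive <- function(z0, zp, sigma_z) {
  z0 <- as.numeric(z0); zp <- as.numeric(zp)
  if (length(z0) != length(zp)) stop("alpha_drive: length mismatch")
  check_sigma(sigma_z)
  gaussian_kernel(z0, zp, sigma_z) * (z0 - zp)
}

#' Global modulation signal of the three-factor rule
#'
#' Computes the layer-wise modulating factor `xi` (one value per output
#' neuron) from the working-memory contents:
#' \deqn{\xi = \frac{2}{\sigma_z^2 N (N-1)^2} \Big[ \sum_{p \ne 0} c_p\,
#'   \alpha(z_p) + c_0 \sum_{p \ne 0} \alpha(z_p) \Big],}
#' where `c_p = surprise_x(p) - gamma * surprise_y(p)` is the input-minus-label
#' surprise of sample `p` over the buffer (self-inclusive means, bandwidths
#' `sigma_x` / `sigma_y`) and `alpha` is [alpha_drive()] of the current output
#' `z_0` against each buffered output. `N` is the number of samples currently
#' held. The product of `xi` with the local Hebbian factor is exactly the
#' gradient of [hsic_bound()] over the buffer contents under the locality
#' approximation that current weights do not affect past outputs.
#'
#' @param mem A [sample_memory()] holding at least 2 samples.
#' @param params [kernel_params()].
#' @return Numeric vector of length `nrow(mem$z)`.
#' @export
modulation_signal <- function(mem, params) {
  stopifnot(inherits(mem, "sample_memory"), inherits(params, "kernel_params"))
  n <- mem$size
  if (n < 2L) stop("modulation_signal: memory must hold at least 2 samples")
  cc <- surprise_all(mem$x, params$sigma_x) -
    params$gamma * surprise_all(mem$y, params$sigma_y)
  z0 <- mem$z[, 1L]
  Zp <- mem$z[, -1L, drop = FALSE]
  diffs <- z0 - Zp                      # column p: z_0 - z_p
  k0p <- exp(-colSums(diffs^2) / params$sigma_z^2)
  A <- diffs * rep(k0p, each = nrow(diffs))   # columns alpha(z_p)
  pref <- 2 / (params$sigma_z^2 * n * (n - 1)^2)
  as.numeric(pref * (A %*% cc[-1L] + rowSums(A) * cc[1L]))
}

#' Trace-form modulation signal
#'
#' The counterpart of [modulation_signal()] obtained by differentiating the
#' double-centered trace estimator itself (the quantity [hsic_objective()]
#' reports) with respect to the current sample's parameter dependence:
#' \deqn{\xi = -\frac{4}{\sigma_z^2 (N-1)^2} \sum_{p \ne 0}
#'   \big[H (K_X - \gamma K_Y) H\big]_{0p}\, \alpha(z_p),}
#' where the Gram matrices run over the buffer and `H` is the centering
#' matrix. Unlike the diagonal surprise weighting, the underlying objective
#' is bounded, so prolonged training cannot push representations
#' indefinitely apart; [hsic_train()] uses this form by default
#' (`xi_form = "centered"`).
#'
#' @inheritParams modulation_signal
#' @return Numeric vector of length `nrow(mem$z)`.
#' @export
modulation_signal_centered <- function(mem, params) {
  stopifnot(inherits(mem, "sample_memory"), inherits(params, "kernel_params"))
  if (mem$size < 2L) {
    stop("modulation_signal_centered: memory must hold at least 2 samples")
  }
  D <- double_center(gram_matrix(mem$x, params$sigma_x) -
                       params$gamma * gram_matrix(mem$y, params$sigma_y))
  mod_signal_centered(mem$z[, 1L], mem$z[, -1L, drop = FALSE], D[1L, -1L],
                      params$sigma_z)
}

activation_gate <- function(activation, u) {
  switch(activation,
         relu = as.numeric(u > 0),
         identity = rep(1, length(u)),
         tanh = 1 - tanh(u)^2,
         stop(sprintf("no derivative registered for activation '%s'",
                      activation)))
}

#' Local (Hebbian) factor of the three-factor rule
#'
#' The part of the update that depends only on the current pre- and
#' post-synaptic activity: the derivative of the layer's activation at the
#' current drive (the post-synaptic gate) and the current pre-synaptic input.
#' For rate layers the gate is evaluated at the membrane potential; for
#' instantaneous layers at the drive `W z_in + b`.
#'
#' @param layer A layer from [rate_layer()] or [dense_layer()].
#' @param z_in Current input vector to the layer.
#' @return A `local_factor` object with fields `post_gate` and `pre_activity`.
#' @export
local_factor <- function(layer, z_in) {
  stopifnot(inherits(layer, "hsic_layer"))
  z_in <- as.numeric(z_in)
  if (length(z_in) != ncol(layer$W)) stop("local_factor: input length mismatch")
  u <- if (layer$kind == "rate") layer$u
       else as.numeric(layer$W %*% z_in + layer$b)
  structure(list(post_gate = activation_gate(layer$activation, u),
                 pre_activity = z_in),
            class = "local_factor")
}

#' Assemble the three-factor weight update
#'
#' Combines the local factor `beta` with the global modulation `xi` into the
#' synaptic update `dW[i, j] = xi[i] * gate[i] * pre[j]`,
#' `db[i] = xi[i] * gate[i]` — a rank-one, fully local update. The result is a
#' descent direction: optimizers apply `theta <- theta - eta * delta`.
#'
#' @param beta A [local_factor()].
#' @param xi Modulation vector, one entry per output neuron.
#' @return A `weight_delta` list with `dW` and `db`.
#' @export
assemble_update <- function(beta, xi) {
  stopifnot(inherits(beta, "local_factor"))
  xi <- as.numeric(xi)
  if (length(xi) != length(beta$post_gate)) {
    stop("assemble_update: 'xi' length must equal the number of output neurons")
  }
  g <- xi * beta$post_gate
  structure(list(dW = tcrossprod(g, beta$pre_activity), db = g),
            class = "weight_delta")
}

#' Exact layer-wise gradient over the working memory
#'
#' The unapproximated gradient of [hsic_bound()] with respect to the layer's
#' parameters, with every buffered output recomputed as `f(theta, x_p)` from
#' the buffered inputs so that all cross-sample dependencies are retained:
#' \deqn{\nabla_\theta \bar k(z_p, z_p) = \frac{2}{N \sigma_z^2} \sum_n
#'   k(z_p, z_n) (z_p - z_n) (\nabla_\theta f(\theta, x_p)
#'   - \nabla_\theta f(\theta, x_n)).}
#' Serves as the validation oracle for the three-factor approximation: when
#' the cross-sample Jacobians are dropped, this gradient collapses to
#' [assemble_update()] of [local_factor()] and [modulation_signal()]. The
#' layer is evaluated through its instantaneous (steady-state) map.
#'
#' @param mem A [sample_memory()] whose `x` entries are the layer's inputs.
#' @param layer A dense-kind layer (see [dense_layer()]).
#' @param params [kernel_params()].
#' @return A `weight_delta` list with `dW` and `db` (a descent direction).
#' @export
full_hsic_gradient <- function(mem, layer, params) {
  stopifnot(inherits(mem, "sample_memory"), inherits(layer, "hsic_layer"),
            inherits(params, "kernel_params"))
  n <- mem$size
  if (n < 2L) stop("full_hsic_gradient: memory must hold at least 2 samples")
  X <- mem$x
  U <- layer$W %*% X + layer$b          # drive per sample (columns)
  Z <- apply_activation(layer$activation, U)
  G <- apply(U, 2, function(u) activation_gate(layer$activation, u))
  G <- matrix(G, nrow = nrow(U))
  cc <- surprise_all(mem$x, params$sigma_x) -
    params$gamma * surprise_all(mem$y, params$sigma_y)
  K <- gram_matrix(Z, params$sigma_z)
  M <- K * cc                           # M[p, n] = c_p k(z_p, z_n)
  ## A[, p] = sum_n M[p, n] (z_p - z_n); B[, n] = sum_p M[p, n] (z_p - z_n)
  A <- t(t(Z) * rowSums(M)) - Z %*% t(M)
  B <- Z %*% M - t(t(Z) * colSums(M))
  GA <- G * A
  GB <- G * B
  pref <- 2 / (params$sigma_z^2 * n * (n - 1)^2)
  structure(list(dW = pref * (tcrossprod(GA, X) - tcrossprod(GB, X)),
                 db = pref * (rowSums(GA) - rowSums(GB))),
            class = "weight_delta")
}

#' @export
print.weight_delta <- function(x, ...) {
  cat(sprintf("weight delta: dW %d x %d, |dW|_max = %.3g, |db|_max = %.3g\n",
              nrow(x$dW), ncol(x$dW), max(abs(x$dW)), max(abs(x$db))))
  invisible(x)
}
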