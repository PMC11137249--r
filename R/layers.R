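apply_activation <- function(activation, u) {
  switch(activation,
         relu = pmax(u, 0),
         identity = u,
         tanh = tanh(u),
         stop(sprintf("unknown activation '%s'", activation)))
}

new_layer <- function(W, b, kind, activation, tau_m = NULL) {
  layer <- list(W = W, b = b, kind = kind, activation = activation)
  if (kind == "rate") {
    layer$tau_m <- tau_m
    layer$u <- numeric(nrow(W))
  }
  class(layer) <- "hsic_layer"
  layer
}

init_weights <- function(out_dim, in_dim) {
  lim <- 1 / sqrt(in_dim)
  matrix(stats::runif(out_dim * in_dim, -lim, lim), out_dim, in_dim)
}

#' Instantaneous dense layer
#'
#' A fully connected layer `z = phi(W z_in + b)`. Weights are initialized
#' uniformly in `[-1/sqrt(fan_in), 1/sqrt(fan_in)]` from the current RNG
#' state; biases start at zero.
#'
#' @param in_dim,out_dim Layer dimensions.
#' @param activation One of `"relu"`, `"identity"`, `"tanh"`.
#' @param W,b Optional explicit parameters.
#' @return An `hsic_layer` of kind `"dense"`.
#' @export
dense_layer <- function(in_dim, out_dim, activation = "relu",
                        W = NULL, b = NULL) {
  if (is.null(W)) W <- init_weights(out_dim, in_dim)
  if (is.null(b)) b <- numeric(out_dim)
  stopifnot(nrow(W) == out_dim, ncol(W) == in_dim, length(b) == out_dim)
  new_layer(W, b, "dense", activation)
}

#' Leaky-integrate rate layer
#'
#' A layer of rate-coded leaky-integrate neurons whose membrane potentials
#' relax toward the synaptic drive with time constant `tau_m`:
#' `tau_m du/dt = -u + W z_in + b`, output `z = relu(u)`. The membrane state
#' persists across sample presentations (the dynamics have no reset term).
#'
#' @inheritParams dense_layer
#' @param tau_m Membrane time constant in ms.
#' @return An `hsic_layer` of kind `"rate"`.
#' @export
rate_layer <- function(in_dim, out_dim, tau_m = 5, activation = "relu",
                       W = NULL, b = NULL) {
  stopifnot(tau_m > 0)
  if (is.null(W)) W <- init_weights(out_dim, in_dim)
  if (is.null(b)) b <- numeric(out_dim)
  new_layer(W, b, "rate", activation, tau_m = tau_m)
}

#' One Euler step of a rate layer
#'
#' Forward-Euler update `u <- u + (dt/tau_m)(-u + W z_in + b)` followed by the
#' static nonlinearity.
#'
#' @param layer A rate-kind [rate_layer()].
#' @param z_in Input vector held during this step.
#' @param dt Step size in ms (`0 < dt <= tau_m` for stability).
#' @return A list with the updated `layer` and its output vector `z`.
#' @export
rate_step <- function(layer, z_in, dt) {
  stopifnot(inherits(layer, "hsic_layer"), layer$kind == "rate", dt > 0)
  drive <- as.numeric(layer$W %*% z_in + layer$b)
  layer$u <- layer$u + (dt / layer$tau_m) * (drive - layer$u)
  if (!all(is.finite(layer$u))) stop("rate_step: membrane state diverged")
  list(layer = layer, z = apply_activation(layer$activation, layer$u))
}

#' Instantaneous forward pass of a dense layer
#'
#' @param layer A dense-kind [dense_layer()].
#' @param z_in Input vector.
#' @return Output vector `phi(W z_in + b)`.
#' @export
dense_forward <- function(layer, z_in) {
  stopifnot(inherits(layer, "hsic_layer"), layer$kind == "dense")
  if (length(z_in) != ncol(layer$W)) stop("dense_forward: shape mismatch")
  as.numeric(apply_activation(layer$activation,
                              layer$W %*% as.numeric(z_in) + layer$b))
}

#' Feedforward network specification
#'
#' Builds a stack of hidden layers (rate or dense) plus a linear output layer
#' read out through a softmax cross-entropy rule during training. Hidden
#' layers are trained layer-wise by the three-factor rule; the output layer
#' by a local delta rule. Weight draws come from the current RNG state.
#'
#' @param input_dim Input dimensionality.
#' @param hidden Integer vector of hidden-layer widths.
#' @param n_classes Number of output classes.
#' @param kind `"rate"` (leaky-integrate hidden layers) or `"dense"`.
#' @param tau_m Membrane time constant (rate layers), ms.
#' @param bias_init Initial bias of the hidden layers. A small positive
#'   value keeps ReLU units responsive at initialization; the output layer
#'   starts at zero bias.
#' @return An `hsic_network`: list of `hsic_layer`s (`$layers`) plus the
#'   output layer (`$output`).
#' @export
hsic_network <- function(input_dim, hidden, n_classes, kind = c("rate", "dense"),
                         tau_m = 5, bias_init = 0) {
  kind <- match.arg(kind)
  dims <- c(input_dim, hidden)
  layers <- vector("list", length(hidden))
  for (i in seq_along(hidden)) {
    b0 <- rep(bias_init, dims[i + 1])
    layers[[i]] <- if (kind == "rate") {
      rate_layer(dims[i], dims[i + 1], tau_m = tau_m, b = b0)
    } else {
      dense_layer(dims[i], dims[i + 1], b = b0)
    }
  }
  out <- dense_layer(dims[length(dims)], n_classes, activation = "identity")
  structure(list(layers = layers, output = out, kind = kind),
            class = "hsic_network")
}

#' Present one sample to the network
#'
#' Holds the input fixed for `dt_sample` ms, stepping every layer in
#' feedforward order each `dt` (a signal therefore takes one timestep per
#' layer to propagate). Rate layers integrate their membrane dynamics; dense
#' layers respond instantaneously. Returns each hidden layer's output at the
#' end of the presentation window — these are the activations stored in the
#' working memory — together with the output-layer scores.
#'
#' @param net An [hsic_network()].
#' @param x Input vector.
#' @param dt Integration step, ms.
#' @param dt_sample Presentation time per sample, ms (`>= dt`).
#' @return List with updated `net`, hidden outputs `z` (list), per-layer
#'   inputs `z_in` (list), and output scores `scores`.
#' @export
run_sample <- function(net, x, dt = 1, dt_sample = 20) {
  stopifnot(inherits(net, "hsic_network"), dt_sample >= dt)
  n_steps <- max(1L, round(dt_sample / dt))
  L <- length(net$layers)
  z <- vector("list", L)
  ## carry previous outputs so layer l sees layer l-1's latest output
  for (l in seq_len(L)) {
    z[[l]] <- if (net$layers[[l]]$kind == "rate") {
      apply_activation(net$layers[[l]]$activation, net$layers[[l]]$u)
    } else numeric(nrow(net$layers[[l]]$W))
  }
  z_in <- vector("list", L)
  for (step in seq_len(n_steps)) {
    prev <- as.numeric(x)
    for (l in seq_len(L)) {
      z_in[[l]] <- prev
      if (net$layers[[l]]$kind == "rate") {
        st <- rate_step(net$layers[[l]], prev, dt)
        net$layers[[l]] <- st$layer
        z[[l]] <- st$z
      } else {
        z[[l]] <- dense_forward(net$layers[[l]], prev)
      }
      prev <- z[[l]]
    }
  }
  scores <- as.numeric(net$output$W %*% z[[L]] + net$output$b)
  list(net = net, z = z, z_in = z_in, scores = scores)
}

## Steady-state forward pass (the dt_sample -> Inf limit of run_sample):
## each layer evaluated at its ODE fixed point. X is d x n (columns samples).
## Returns list(z = list of per-layer activation matrices, scores = c x n).
forward_steady <- function(net, X) {
  X <- as_sample_matrix(X)
  Z <- X
  zs <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    Z <- apply_activation(net$layers[[l]]$activation,
                          net$layers[[l]]$W %*% Z + net$layers[[l]]$b)
    zs[[l]] <- Z
  }
  list(z = zs, scores = net$output$W %*% Z + net$output$b)
}
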