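#' Training configuration for the three-factor rule
#'
#' Defaults are the small-dataset experiment settings: 1 ms integration
#' steps, 5 ms membrane time constant, 20 ms presentations, working-memory
#' capacity (effective batch size) 64, bottleneck balance `gamma = 10`,
#' kernel bandwidths 0.3 / 2 / 0.25 for inputs / layer activity / one-hot
#' labels, learning rate 1e-4 and 25 epochs. Updates are applied with Adam
#' (default hyper-parameters); since the rule only defines the update up to a
#' proportionality constant, Adam's scale invariance makes that constant
#' immaterial.
#'
#' @param dt Integration step, ms.
#' @param dt_sample Presentation time per sample, ms.
#' @param tau_m Membrane time constant of rate layers, ms.
#' @param N Working-memory capacity (effective batch size), `>= 2`.
#' @param sigma_x,sigma_z,sigma_y,gamma Kernel/bottleneck parameters; see
#'   [kernel_params()].
#' @param eta Learning rate of the three-factor updates.
#' @param eta_out Learning rate of the output layer's cross-entropy delta
#'   rule (always applied with Adam; the readout problem is convex and its
#'   rate is independent of the plasticity rule).
#' @param epochs Training epochs.
#' @param optimizer `"adam"` (default; scale-invariant, so the rule's
#'   unspecified proportionality constant is immaterial) or `"sgd"`.
#' @param xi_scale `"gradient"` (default) applies the exactly normalized
#'   [modulation_signal()]; `"raw"` applies the bare double sum over the
#'   buffer, absorbing the gradient prefactor `2/(sigma_z^2 N (N-1)^2)`
#'   into the proportionality constant of the update (only meaningful with
#'   `optimizer = "sgd"`).
#' @param xi_source `"oracle"` (exact modulation from the buffer) or
#'   `"reservoir"` (readout of pre-trained auxiliary reservoirs).
#' @param xi_form `"centered"` (default) weights the similarity drives by
#'   the current sample's row of the double-centered `K_x - gamma K_y` over
#'   the buffer — the modulation obtained by differentiating the trace-form
#'   estimator itself, whose optimum is bounded; `"surprise"` uses the
#'   diagonal surprise-difference weights of [modulation_signal()] (the
#'   per-sample bound's gradient), whose label term is unbounded below and
#'   can disperse late representations.
#' @param update_every `"sample"` (default) applies one update per
#'   presentation, at the window end; `"step"` applies plasticity at every
#'   integration step (plasticity as part of the continuous-time dynamics).
#' @param seed Integer seed controlling initialization and sample order.
#' @return An `hsic_config` object.
#' @export
hsic_config <- function(dt = 1, dt_sample = 20, tau_m = 5, N = 64,
                        sigma_x = 0.3, sigma_z = 2, sigma_y = 0.25,
                        gamma = 10, eta = 1e-4, eta_out = 1e-2, epochs = 25,
                        optimizer = c("adam", "sgd"),
                        xi_scale = c("gradient", "raw"),
                        xi_source = c("oracle", "reservoir"),
                        xi_form = c("centered", "surprise"),
                        update_every = c("sample", "step"), seed = 1) {
  stopifnot(dt > 0, dt_sample >= dt, tau_m > 0, N >= 2, eta >= 0, epochs >= 0)
  structure(list(dt = dt, dt_sample = dt_sample, tau_m = tau_m,
                 N = as.integer(N),
                 kernel = kernel_params(sigma_x, sigma_z, sigma_y, gamma),
                 eta = eta, eta_out = eta_out, epochs = as.integer(epochs),
                 optimizer = match.arg(optimizer),
                 xi_scale = match.arg(xi_scale),
                 xi_source = match.arg(xi_source),
                 xi_form = match.arg(xi_form),
                 update_every = match.arg(update_every),
                 seed = as.integer(seed)),
            class = "hsic_config")
}

## ---- Adam ----------------------------------------------------------------

#' Initialize an Adam optimizer state
#'
#' @param template A named list of numeric arrays with the shapes of the
#'   parameters to be optimized.
#' @return An `adam_state`.
#' @export
adam_init <- function(template) {
  z <- lapply(template, function(p) array(0, dim = if (is.null(dim(p)))
    length(p) else dim(p)))
  structure(list(m = z, v = z, t = 0L), class = "adam_state")
}

#' One Adam update step
#'
#' Standard Adam moment updates (`beta1 = 0.9`, `beta2 = 0.999`,
#' `eps = 1e-8`) applied to a descent direction; the returned `step` is
#' subtracted from the parameters by the caller.
#'
#' @param state An [adam_init()] state.
#' @param delta Named list of descent directions (same shapes as the
#'   template).
#' @param eta Learning rate.
#' @param beta1,beta2,eps Adam hyper-parameters.
#' @return List with updated `state` and the `step` to subtract.
#' @export
adam_apply <- function(state, delta, eta, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  stopifnot(inherits(state, "adam_state"))
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  step <- vector("list", length(delta))
  names(step) <- names(delta)
  for (k in seq_along(delta)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * delta[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * delta[[k]]^2
    step[[k]] <- eta * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(state = state, step = step)
}

## ---- output layer --------------------------------------------------------

softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

#' Cross-entropy delta rule for the output layer
#'
#' The local softmax cross-entropy gradient for the final readout layer:
#' `dW = (softmax(W z_in + b) - y) z_in'`, `db = softmax(...) - y`. This is
#' the only supervised, task-specific update in the network; all hidden
#' layers are trained by the unsupervised-in-form three-factor rule.
#'
#' @param layer The output [dense_layer()] (identity activation).
#' @param z_in Current input to the layer (last hidden activity).
#' @param y_true One-hot label vector.
#' @return A `weight_delta` (descent direction).
#' @export
output_layer_update <- function(layer, z_in, y_true) {
  stopifnot(inherits(layer, "hsic_layer"))
  z_in <- as.numeric(z_in); y_true <- as.numeric(y_true)
  if (length(z_in) != ncol(layer$W) || length(y_true) != nrow(layer$W)) {
    stop("output_layer_update: shape mismatch")
  }
  err <- softmax(as.numeric(layer$W %*% z_in + layer$b)) - y_true
  structure(list(dW = tcrossprod(err, z_in), db = err),
            class = "weight_delta")
}

## ---- shared internals ----------------------------------------------------

## Modulation from the trace-form estimator: weights w are the current
## sample's off-diagonal row of the double-centered K_x - gamma K_y over the
## buffer (length ncol(Zpast)); descent direction for the trace objective
## restricted to the current sample's parameter dependence.
mod_signal_centered <- function(z0, Zpast, w, sigma_z) {
  n <- ncol(Zpast) + 1L
  diffs <- z0 - Zpast
  k0p <- exp(-colSums(diffs^2) / sigma_z^2)
  A <- diffs * rep(k0p, each = nrow(diffs))
  -(4 / (sigma_z^2 * (n - 1)^2)) * as.numeric(A %*% w)
}

## Modulation for one layer given the current activity z0, the buffered past
## activities (columns, newest first) and the shared surprise weights cc
## (length ncol(Zpast) + 1, entry 1 = current sample).
mod_signal_split <- function(z0, Zpast, cc, sigma_z) {
  n <- ncol(Zpast) + 1L
  diffs <- z0 - Zpast
  k0p <- exp(-colSums(diffs^2) / sigma_z^2)
  A <- diffs * rep(k0p, each = nrow(diffs))
  (2 / (sigma_z^2 * n * (n - 1)^2)) *
    as.numeric(A %*% cc[-1L] + rowSums(A) * cc[1L])
}

push_cols <- function(M, v, N) {
  if (is.null(M)) return(matrix(v))
  cbind(v, M[, seq_len(min(ncol(M), N - 1L)), drop = FALSE],
        deparse.level = 0)
}

accuracy_of <- function(scores, label) {
  mean(max.col(t(scores)) == label)
}

eval_network <- function(net, data, kp) {
  fw <- forward_steady(net, t(data$X))
  L <- length(net$layers)
  hs <- vapply(seq_len(L), function(l) {
    hsic_objective(t(data$X[data$test, , drop = FALSE]),
                   t(data$Y[data$test, , drop = FALSE]),
                   fw$z[[l]][, data$test, drop = FALSE], kp)
  }, numeric(1))
  list(train_acc = accuracy_of(fw$scores[, data$train, drop = FALSE],
                               data$label[data$train]),
       test_acc = accuracy_of(fw$scores[, data$test, drop = FALSE],
                              data$label[data$test]),
       hsic = hs)
}

## ---- main fitting function -----------------------------------------------

#' Train a network with the three-factor HSIC bottleneck rule
#'
#' Fits a feedforward network of leaky-integrate rate neurons (or
#' instantaneous ReLU units) to a labeled dataset, one sample at a time.
#' Each presentation holds the input for `dt_sample` ms; the window-end
#' activations are pushed into each layer's working memory; every hidden
#' layer then applies the three-factor update — local Hebbian factor times
#' the global modulation signal computed from the buffer (or read out from a
#' pre-trained auxiliary reservoir) — and the output layer applies the local
#' cross-entropy delta rule. No error is propagated across layers.
#'
#' @param data A `labeled_dataset` from [gen_linear()], [gen_xor()] or
#'   [load_benchmark()].
#' @param hidden Integer vector of hidden-layer widths.
#' @param config An [hsic_config()].
#' @param kind `"rate"` for leaky-integrate hidden layers (default) or
#'   `"dense"` for instantaneous artificial units.
#' @param reservoirs When `config$xi_source == "reservoir"`: a list of
#'   pre-trained [init_reservoir()] states, one per hidden layer, with input
#'   dimension `ncol(data$X) + ncol(data$Y) + hidden[l]` and output dimension
#'   `hidden[l]`.
#' @return An object of class `hsic_net` with the trained network, the
#'   per-epoch accuracy and per-layer bottleneck history (`$history`, epoch 0
#'   = initialization), and the configuration. Methods: [predict.hsic_net()],
#'   `print`, `summary`, `coef`, `plot`.
#' @export
hsic_train <- function(data, hidden = 4, config = hsic_config(),
                       kind = c("rate", "dense"), bias_init = 0.1,
                       reservoirs = NULL) {
  stopifnot(inherits(data, "labeled_dataset"), inherits(config, "hsic_config"))
  kind <- match.arg(kind)
  kp <- config$kernel
  use_res <- config$xi_source == "reservoir"
  if (use_res && (is.null(reservoirs) || length(reservoirs) != length(hidden))) {
    stop("hsic_train: supply one pre-trained reservoir per hidden layer")
  }
  set.seed(config$seed)
  net <- hsic_network(ncol(data$X), hidden, ncol(data$Y), kind = kind,
                      tau_m = config$tau_m, bias_init = bias_init)
  L <- length(net$layers)
  ## flat Adam moment buffers (hot loop: avoid per-step list allocation)
  opt <- lapply(seq_len(L + 1L), function(l) {
    lay <- if (l <= L) net$layers[[l]] else net$output
    list(mW = 0 * lay$W, vW = 0 * lay$W, mb = 0 * lay$b, vb = 0 * lay$b,
         t = 0L)
  })
  n_res_steps <- max(1L, round(config$dt_sample / config$dt))

  Xmem <- NULL; Ymem <- NULL
  Zmem <- vector("list", L)
  history <- NULL
  record <- function(epoch) {
    ev <- eval_network(net, data, kp)
    row <- data.frame(epoch = epoch, train_acc = ev$train_acc,
                      test_acc = ev$test_acc)
    row[paste0("hsic_layer", seq_len(L))] <- as.list(ev$hsic)
    rbind(history, row)
  }
  history <- record(0L)

  use_adam <- config$optimizer == "adam"
  ## applies to the reservoir path too: its readout approximates the
  ## normalized signal, so the same rescaling keeps the two sources
  ## interchangeable
  raw_scale <- identical(config$xi_scale, "raw")
  per_step <- identical(config$update_every, "step")
  centered_form <- identical(config$xi_form, "centered")
  ## local mirrors of the layer state: the per-timestep dynamics below avoid
  ## S3 dispatch and per-call allocation (this loop runs epochs * samples *
  ## (dt_sample/dt) times)
  Wl <- lapply(net$layers, `[[`, "W")
  bl <- lapply(net$layers, `[[`, "b")
  ul <- lapply(net$layers, function(l) if (l$kind == "rate") l$u)
  is_rate <- vapply(net$layers, function(l) l$kind == "rate", logical(1))
  acts <- vapply(net$layers, `[[`, character(1), "activation")
  step_frac <- vapply(net$layers, function(l) {
    if (l$kind == "rate") config$dt / l$tau_m else NA_real_
  }, numeric(1))
  Wout <- net$output$W
  bout <- net$output$b
  sync_net <- function() {
    for (l in seq_len(L)) {
      net$layers[[l]]$W <<- Wl[[l]]
      net$layers[[l]]$b <<- bl[[l]]
      if (is_rate[l]) net$layers[[l]]$u <<- ul[[l]]
    }
    net$output$W <<- Wout
    net$output$b <<- bout
  }

  eta <- config$eta
  eta_out <- config$eta_out
  sigx <- kp$sigma_x; sigy <- kp$sigma_y; sigz <- kp$sigma_z
  gam <- kp$gamma
  Ncap <- config$N
  apply_adam <- function(l, dW, db, rate) {
    o <- opt[[l]]
    o$t <- o$t + 1L
    bc1 <- 1 - 0.9^o$t
    bc2 <- 1 - 0.999^o$t
    o$mW <- 0.9 * o$mW + 0.1 * dW
    o$vW <- 0.999 * o$vW + 0.001 * dW^2
    o$mb <- 0.9 * o$mb + 0.1 * db
    o$vb <- 0.999 * o$vb + 0.001 * db^2
    opt[[l]] <<- o
    list(W = rate * (o$mW / bc1) / (sqrt(o$vW / bc2) + 1e-8),
         b = rate * (o$mb / bc1) / (sqrt(o$vb / bc2) + 1e-8))
  }

  ## Plasticity rides on the integration loop: at the configured granularity
  ## each hidden layer applies the three-factor update and the output layer
  ## the delta rule, using the instantaneous activity. The input/label
  ## surprise weights are fixed within a presentation (x and y are held), so
  ## they are computed once per sample; each layer's z memory holds the
  ## previous samples' window-end activity (lags -1 .. -(N-1)) while the
  ## current activity plays the role of the lag-0 entry.
  for (epoch in seq_len(config$epochs)) {
    order <- sample(data$train)
    for (i in order) {
      x <- data$X[i, ]
      y <- data$Y[i, ]
      Xmem <- push_cols(Xmem, x, Ncap)
      Ymem <- push_cols(Ymem, y, Ncap)
      n <- ncol(Xmem)
      learn <- n >= 2L
      cc <- NULL
      if (learn && !use_res) {
        if (centered_form) {
          D <- double_center(gram_matrix(Xmem, sigx) -
                               gam * gram_matrix(Ymem, sigy))
          cc <- D[1, -1]                 # off-diagonal row of current sample
        } else {
          cc <- surprise_all(Xmem, sigx) - gam * surprise_all(Ymem, sigy)
        }
      }
      z <- vector("list", L)
      for (step in seq_len(n_res_steps)) {
        plastic <- learn && (per_step || step == n_res_steps)
        prev <- x
        for (l in seq_len(L)) {
          if (is_rate[l]) {
            u <- ul[[l]] + step_frac[l] *
              (as.numeric(Wl[[l]] %*% prev) + bl[[l]] - ul[[l]])
            ul[[l]] <- u
          } else {
            u <- as.numeric(Wl[[l]] %*% prev) + bl[[l]]
          }
          zl <- if (acts[l] == "relu") u * (u > 0) else
            apply_activation(acts[l], u)
          z[[l]] <- zl
          if (use_res) {
            ## the auxiliary network integrates continuously regardless of
            ## when its readout is consumed
            reservoirs[[l]] <- reservoir_step(reservoirs[[l]], c(x, y, zl))
          }
          if (plastic) {
            xi <- if (use_res) reservoirs[[l]]$ro else if (centered_form)
              mod_signal_centered(zl, Zmem[[l]], cc, sigz) else
              mod_signal_split(zl, Zmem[[l]], cc, sigz)
            if (raw_scale) xi <- xi * (sigz^2 * n * (n - 1)^2 / 2)
            g <- xi * (if (acts[l] == "relu") (u > 0) else
                         activation_gate(acts[l], u))
            if (use_adam) {
              st <- apply_adam(l, tcrossprod(g, prev), g, eta)
              Wl[[l]] <- Wl[[l]] - st$W
              bl[[l]] <- bl[[l]] - st$b
            } else {
              Wl[[l]] <- Wl[[l]] - eta * tcrossprod(g, prev)
              bl[[l]] <- bl[[l]] - eta * g
            }
          }
          prev <- zl
        }
        if (per_step || step == n_res_steps) {
          err <- softmax(as.numeric(Wout %*% z[[L]]) + bout) - y
          st <- apply_adam(L + 1L, tcrossprod(err, z[[L]]), err, eta_out)
          Wout <- Wout - st$W
          bout <- bout - st$b
        }
      }
      if (!all(is.finite(z[[L]])) || !is.finite(sum(Wl[[L]]))) {
        stop("hsic_train: weights diverged")
      }
      ## freeze this presentation's window-end activity as the newest past
      ## entry (capacity N - 1: the lag-0 slot is the live activity)
      for (l in seq_len(L)) {
        Zmem[[l]] <- push_cols(Zmem[[l]], z[[l]], Ncap - 1L)
      }
    }
    sync_net()
    history <- record(epoch)
  }
  sync_net()

  structure(list(net = net, config = config, history = history,
                 hidden = hidden, kind = kind, rule = "hsic",
                 n_classes = ncol(data$Y), seed = config$seed,
                 final_train_acc = history$train_acc[nrow(history)],
                 final_test_acc = history$test_acc[nrow(history)]),
            class = "hsic_net")
}

#' Backpropagation baseline
#'
#' Trains the same architecture (instantaneous ReLU layers only) end-to-end
#' on the softmax cross-entropy loss with per-sample Adam updates — the
#' non-plausible reference the three-factor rule is compared against.
#'
#' @inheritParams hsic_train
#' @return An `hsic_net` object with `rule = "backprop"`.
#' @export
train_backprop <- function(data, hidden = 4, config = hsic_config()) {
  stopifnot(inherits(data, "labeled_dataset"), inherits(config, "hsic_config"))
  set.seed(config$seed)
  net <- hsic_network(ncol(data$X), hidden, ncol(data$Y), kind = "dense")
  L <- length(net$layers)
  opt <- lapply(seq_len(L + 1L), function(l) {
    lay <- if (l <= L) net$layers[[l]] else net$output
    adam_init(list(dW = lay$W, db = lay$b))
  })
  history <- NULL
  record <- function(epoch) {
    ev <- eval_network(net, data, config$kernel)
    row <- data.frame(epoch = epoch, train_acc = ev$train_acc,
                      test_acc = ev$test_acc)
    row[paste0("hsic_layer", seq_len(L))] <- as.list(ev$hsic)
    rbind(history, row)
  }
  history <- record(0L)
  for (epoch in seq_len(config$epochs)) {
    order <- sample(data$train)
    for (i in order) {
      grads <- backprop_grads(net, data$X[i, ], data$Y[i, ])
      for (l in seq_len(L + 1L)) {
        lay <- if (l <= L) net$layers[[l]] else net$output
        if (config$optimizer == "adam") {
          res <- adam_apply(opt[[l]], grads[[l]], config$eta)
          opt[[l]] <- res$state
          lay$W <- lay$W - res$step$dW
          lay$b <- lay$b - as.numeric(res$step$db)
        } else {
          lay$W <- lay$W - config$eta * grads[[l]]$dW
          lay$b <- lay$b - config$eta * as.numeric(grads[[l]]$db)
        }
        if (l <= L) net$layers[[l]] <- lay else net$output <- lay
      }
    }
    history <- record(epoch)
  }
  structure(list(net = net, config = config, history = history,
                 hidden = hidden, kind = "dense", rule = "backprop",
                 n_classes = ncol(data$Y), seed = config$seed,
                 final_train_acc = history$train_acc[nrow(history)],
                 final_test_acc = history$test_acc[nrow(history)]),
            class = "hsic_net")
}

## Exact per-sample cross-entropy gradients for a dense ReLU stack.
backprop_grads <- function(net, x, y) {
  L <- length(net$layers)
  z <- vector("list", L + 1L)
  u <- vector("list", L)
  z_prev <- as.numeric(x)
  for (l in seq_len(L)) {
    u[[l]] <- as.numeric(net$layers[[l]]$W %*% z_prev + net$layers[[l]]$b)
    z[[l]] <- apply_activation(net$layers[[l]]$activation, u[[l]])
    z_prev <- z[[l]]
  }
  scores <- as.numeric(net$output$W %*% z_prev + net$output$b)
  err <- softmax(scores) - as.numeric(y)
  grads <- vector("list", L + 1L)
  grads[[L + 1L]] <- list(dW = tcrossprod(err, z[[L]]), db = err)
  back <- as.numeric(crossprod(net$output$W, err))
  for (l in rev(seq_len(L))) {
    d <- back * activation_gate(net$layers[[l]]$activation, u[[l]])
    zin <- if (l == 1L) as.numeric(x) else z[[l - 1L]]
    grads[[l]] <- list(dW = tcrossprod(d, zin), db = d)
    if (l > 1L) back <- as.numeric(crossprod(net$layers[[l]]$W, d))
  }
  grads
}

## ---- methods -------------------------------------------------------------

#' Predict from a trained network
#'
#' Evaluates the network at its steady state (the long-presentation limit of
#' the rate dynamics, identical to the instantaneous forward pass for dense
#' networks).
#'
#' @param object An `hsic_net`.
#' @param newdata Feature matrix (rows are samples) or a `labeled_dataset`
#'   (its full feature matrix is used).
#' @param type `"class"` (integer labels), `"prob"` (softmax probabilities)
#'   or `"score"` (raw output-layer scores).
#' @param ... Unused.
#' @return A vector of class labels or an `n x c` matrix.
#' @export
predict.hsic_net <- function(object, newdata,
                             type = c("class", "prob", "score"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "labeled_dataset")) newdata$X else
    as.matrix(newdata)
  fw <- forward_steady(object$net, t(X))
  switch(type,
         class = max.col(t(fw$scores)),
         prob = t(apply(fw$scores, 2, softmax)),
         score = t(fw$scores))
}

#' @export
print.hsic_net <- function(x, ...) {
  rule <- if (x$rule == "hsic") "three-factor HSIC rule" else "backpropagation"
  cat(sprintf("Feedforward %s network trained by %s\n",
              x$kind, rule))
  cat(sprintf("  architecture: %s -> %d classes\n",
              paste(x$hidden, collapse = " -> "), x$n_classes))
  cat(sprintf("  %d epochs, seed %d; final accuracy: train %.3f, test %.3f\n",
              max(x$history$epoch), x$seed, x$final_train_acc,
              x$final_test_acc))
  invisible(x)
}

#' @export
summary.hsic_net <- function(object, ...) {
  print(object)
  h <- object$history
  hs_cols <- grep("^hsic_layer", names(h), value = TRUE)
  cat("  layer-wise bottleneck objective (test set):\n")
  for (cn in hs_cols) {
    cat(sprintf("    %s: %.4g (epoch 0) -> %.4g (final)\n",
                cn, h[[cn]][1], h[[cn]][nrow(h)]))
  }
  invisible(object)
}

#' @export
coef.hsic_net <- function(object, ...) {
  c(lapply(object$net$layers, function(l) list(W = l$W, b = l$b)),
    list(output = list(W = object$net$output$W, b = object$net$output$b)))
}

#' Plot training history
#'
#' Two panels: train/test accuracy per epoch, and the per-layer bottleneck
#' objective per epoch.
#'
#' @param x An `hsic_net`.
#' @param ... Passed to `matplot`.
#' @export
plot.hsic_net <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$train_acc, h$test_acc), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "epoch",
                    ylab = "accuracy", ylim = c(0, 1), ...)
  graphics::legend("bottomright", c("train", "test"), lty = 1,
                   col = c("black", "red"), bty = "n")
  hs_cols <- grep("^hsic_layer", names(h), value = TRUE)
  graphics::matplot(h$epoch, as.matrix(h[hs_cols]), type = "l", lty = 1,
                    xlab = "epoch", ylab = "HSIC bottleneck", ...)
  graphics::legend("topright", hs_cols, lty = 1,
                   col = seq_along(hs_cols), bty = "n")
  invisible(x)
}
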