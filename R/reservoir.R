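#' Parameters of the auxiliary reservoir
#'
#' Defaults follow the reservoir working-memory experiment: 2000
#' leaky-integrate tanh neurons with time constant 5 ms, recurrent gain
#' (chaos level) 1.2, 1 ms Euler steps, 20 ms per sample presentation and an
#' LMS readout learning rate of 5e-4 trained for 10 epochs.
#'
#' @param n_neurons Recurrent population size.
#' @param tau_r Neuron time constant, ms.
#' @param lambda_chaos Recurrent gain; values above 1 put the autonomous
#'   dynamics in the chaotic regime that serves as a fading memory.
#' @param dt Integration step, ms (`dt <= tau_r`).
#' @param dt_sample Presentation time per sample, ms.
#' @param connection_density Fraction of nonzero recurrent weights.
#' @param learn_rate LMS readout learning rate.
#' @param epochs Pre-training epochs over the stream.
#' @param seed Integer seed for all initialization draws.
#' @return A `reservoir_params` object.
#' @export
reservoir_params <- function(n_neurons = 2000, tau_r = 5, lambda_chaos = 1.2,
                             dt = 1, dt_sample = 20, connection_density = 0.1,
                             learn_rate = 5e-4, epochs = 10, seed = 1) {
  stopifnot(n_neurons >= 1, tau_r > 0, dt > 0, dt <= tau_r, lambda_chaos > 0,
            connection_density > 0, connection_density <= 1,
            dt_sample >= dt, epochs >= 0)
  structure(list(n_neurons = as.integer(n_neurons), tau_r = tau_r,
                 lambda_chaos = lambda_chaos, dt = dt, dt_sample = dt_sample,
                 connection_density = connection_density,
                 learn_rate = learn_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "reservoir_params")
}

#' Initialize a reservoir
#'
#' Recurrent weights are sparse Gaussian with per-entry variance
#' `1/(density * n_neurons)`, so the spectral radius of `lambda * W_rr` is
#' approximately `lambda`. Input and feedback weights are uniform in
#' `[-1, 1]`; readout weights start at zero; membrane potentials start
#' small-random. All draws are derived from `params$seed`.
#'
#' @param params A [reservoir_params()].
#' @param input_dim Dimension of the input signal.
#' @param output_dim Dimension of the readout (the modulation signal).
#' @return An `hsic_reservoir` state object.
#' @export
init_reservoir <- function(params, input_dim, output_dim) {
  stopifnot(inherits(params, "reservoir_params"), input_dim >= 1,
            output_dim >= 1)
  n <- params$n_neurons
  set.seed(params$seed)
  mask <- matrix(stats::runif(n * n) < params$connection_density, n, n)
  W_rr <- matrix(stats::rnorm(n * n, 0,
                              1 / sqrt(params$connection_density * n)), n, n)
  W_rr[!mask] <- 0
  u <- stats::rnorm(n, 0, 0.25)
  state <- list(params = params,
                W_rr = W_rr,
                W_ir = matrix(stats::runif(n * input_dim, -1, 1), n, input_dim),
                W_fb = matrix(stats::runif(n * output_dim, -1, 1), n, output_dim),
                W_o = matrix(0, output_dim, n),
                u = u, r = tanh(u), ro = numeric(output_dim),
                input_dim = as.integer(input_dim),
                output_dim = as.integer(output_dim))
  class(state) <- "hsic_reservoir"
  state
}

#' One Euler step of the reservoir dynamics
#'
#' `u <- u + (dt/tau_r)(-u + lambda W_rr r + W_ir r_i + W_fb ro)`, then
#' `r = tanh(u)` and `ro = W_o r`. The feedback term uses the readout from
#' the previous step, avoiding an algebraic loop.
#'
#' @param state An `hsic_reservoir`.
#' @param r_i Input vector.
#' @param dt Step size, ms (defaults to the state's configured step).
#' @return The updated state.
#' @export
reservoir_step <- function(state, r_i, dt = state$params$dt) {
  stopifnot(inherits(state, "hsic_reservoir"), dt > 0)
  drive <- state$params$lambda_chaos * (state$W_rr %*% state$r) +
    state$W_ir %*% as.numeric(r_i) + state$W_fb %*% state$ro
  state$u <- state$u + (dt / state$params$tau_r) * (as.numeric(drive) - state$u)
  if (!all(is.finite(state$u))) stop("reservoir_step: state diverged")
  state$r <- tanh(state$u)
  state$ro <- as.numeric(state$W_o %*% state$r)
  state
}

#' LMS FORCE update of the readout weights
#'
#' `W_o <- W_o - eta (ro - xi_true) r'` — stochastic gradient descent on the
#' instantaneous squared readout error, the least-mean-squares variant of
#' FORCE learning. Only the readout is plastic; the recurrent, input and
#' feedback weights stay fixed. The readout `ro` is refreshed after the
#' update so the feedback carries the corrected signal.
#'
#' @param state An `hsic_reservoir`.
#' @param xi_true Target modulation vector (readout dimension).
#' @param eta Learning rate.
#' @return The updated state.
#' @export
force_lms_update <- function(state, xi_true, eta = state$params$learn_rate) {
  stopifnot(inherits(state, "hsic_reservoir"))
  xi_true <- as.numeric(xi_true)
  if (length(xi_true) != state$output_dim) {
    stop("force_lms_update: target length must equal the readout dimension")
  }
  err <- state$ro - xi_true
  state$W_o <- state$W_o - eta * tcrossprod(err, state$r)
  state$ro <- as.numeric(state$W_o %*% state$r)
  state
}

run_stream <- function(state, stream, learn) {
  n_steps <- max(1L, round(state$params$dt_sample / state$params$dt))
  sq_err <- 0; n_err <- 0L
  preds <- list(); targs <- list(); times <- list()
  t_ms <- 0
  for (s in stream) {
    for (step in seq_len(n_steps)) {
      state <- reservoir_step(state, s$r_i)
      t_ms <- t_ms + state$params$dt
      if (!is.null(s$xi)) {
        if (learn) state <- force_lms_update(state, s$xi)
        sq_err <- sq_err + sum((state$ro - s$xi)^2)
        n_err <- n_err + 1L
        preds[[length(preds) + 1L]] <- state$ro
        targs[[length(targs) + 1L]] <- s$xi
        times[[length(times) + 1L]] <- t_ms
      }
    }
  }
  list(state = state,
       mse = if (n_err > 0L) sq_err / n_err else NA_real_,
       pred = if (length(preds)) do.call(rbind, preds) else NULL,
       targ = if (length(targs)) do.call(rbind, targs) else NULL,
       t = unlist(times))
}

#' Pre-train the reservoir readout on a target stream
#'
#' Presents each `(r_i, xi_true)` pair for `dt_sample` ms, stepping the
#' dynamics each `dt` and applying [force_lms_update()] after every step
#' (warm-up entries with a `NULL` target are integrated without learning).
#' Repeats for `params$epochs` passes. Because the target is the working
#' memory modulation signal — a fixed post-processing of the reservoir's own
#' input history — this training is task-agnostic and can be done a priori,
#' before the primary network ever sees data.
#'
#' @param state An `hsic_reservoir` from [init_reservoir()].
#' @param stream A list of entries `list(r_i = <input>, xi = <target or NULL>)`,
#'   e.g. from [gen_reservoir_stream()].
#' @param epochs Number of passes (defaults to the configured value).
#' @return The trained state, with a per-epoch mean squared readout error
#'   trace in `$history`.
#' @export
pretrain_reservoir <- function(state, stream, epochs = state$params$epochs) {
  stopifnot(inherits(state, "hsic_reservoir"), length(stream) > 0)
  history <- numeric(0)
  for (ep in seq_len(epochs)) {
    out <- run_stream(state, stream, learn = TRUE)
    state <- out$state
    history <- c(history, out$mse)
  }
  state$history <- c(state$history, history)
  state
}

#' Evaluate a trained reservoir against the exact modulation signal
#'
#' Runs the dynamics over a stream with all weights frozen and reports the
#' root-mean-square readout error normalized by the target's standard
#' deviation (NRMSE), per readout element and overall, plus the full
#' prediction/target traces. A constant target reproduced exactly gives
#' NRMSE 0 by definition.
#'
#' @param state A trained `hsic_reservoir`.
#' @param stream As in [pretrain_reservoir()].
#' @return A `reservoir_eval` list: `nrmse`, `nrmse_element`, `mse`, and a
#'   long-format `traces` data frame (columns `t`, `element`, `target`,
#'   `prediction`).
#' @export
evaluate_reservoir <- function(state, stream) {
  out <- run_stream(state, stream, learn = FALSE)
  nrmse_of <- function(pred, targ) {
    rmse <- sqrt(mean((pred - targ)^2))
    s <- stats::sd(targ)
    if (s == 0) { if (rmse == 0) 0 else Inf } else rmse / s
  }
  per_el <- vapply(seq_len(ncol(out$pred)), function(j) {
    nrmse_of(out$pred[, j], out$targ[, j])
  }, numeric(1))
  traces <- data.frame(
    t = rep(out$t, times = ncol(out$pred)),
    element = rep(seq_len(ncol(out$pred)), each = nrow(out$pred)),
    target = as.numeric(out$targ),
    prediction = as.numeric(out$pred))
  structure(list(nrmse = nrmse_of(out$pred, out$targ),
                 nrmse_element = per_el, mse = out$mse, traces = traces),
            class = "reservoir_eval")
}

#' @export
print.hsic_reservoir <- function(x, ...) {
  cat(sprintf(
    "Rate reservoir: %d neurons (tau_r = %g ms, lambda = %g), %d -> %d readout\n",
    x$params$n_neurons, x$params$tau_r, x$params$lambda_chaos,
    x$input_dim, x$output_dim))
  if (!is.null(x$history)) {
    cat(sprintf("  pre-trained %d epochs; final readout MSE %.3g\n",
                length(x$history), x$history[length(x$history)]))
  }
  invisible(x)
}

#' @export
print.reservoir_eval <- function(x, ...) {
  cat(sprintf("Reservoir evaluation: overall NRMSE %.3f (per element: %s)\n",
              x$nrmse, paste(sprintf("%.2f", x$nrmse_element), collapse = ", ")))
  invisible(x)
}
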