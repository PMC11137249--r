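test_that("adam reproduces a hand-stepped two-iteration scalar trace", {
  st <- adam_init(list(w = 0))
  g1 <- 0.5; g2 <- -0.2; eta <- 0.1
  r1 <- adam_apply(st, list(w = g1), eta)
  ## step 1: m = 0.1 g1 / (1 - 0.9), v = 0.001 g1^2 / (1 - 0.999)
  expect_equal(as.numeric(r1$step$w),
               eta * g1 / (sqrt(g1^2) + 1e-8))
  r2 <- adam_apply(r1$state, list(w = g2), eta)
  m2 <- (0.9 * 0.1 * g1 + 0.1 * g2) / (1 - 0.9^2)
  v2 <- (0.999 * 0.001 * g1^2 + 0.001 * g2^2) / (1 - 0.999^2)
  expect_equal(as.numeric(r2$step$w), eta * m2 / (sqrt(v2) + 1e-8))
})

test_that("adam: zero deltas leave parameters unchanged, constant deltas approach eta steps", {
  st <- adam_init(list(W = matrix(0, 2, 2)))
  for (k in 1:5) {
    r <- adam_apply(st, list(W = matrix(0, 2, 2)), 0.01)
    st <- r$state
    expect_equal(max(abs(r$step$W)), 0)
  }
  st <- adam_init(list(w = 0))
  for (k in 1:500) {
    r <- adam_apply(st, list(w = 3.7), 0.05)
    st <- r$state
  }
  expect_equal(as.numeric(r$step$w), 0.05, tolerance = 1e-3)
})

test_that("output layer delta rule matches finite differences of the cross-entropy", {
  set.seed(71)
  lay <- dense_layer(4, 3, activation = "identity",
                     W = matrix(rnorm(12, 0, 0.5), 3, 4), b = rnorm(3, 0, 0.2))
  z_in <- runif(4)
  y <- c(0, 1, 0)
  upd <- output_layer_update(lay, z_in, y)
  ce <- function(W, b) {
    s <- as.numeric(W %*% z_in + b)
    -sum(y * (s - log(sum(exp(s)))))
  }
  fd <- fd_layer_grad(ce, lay$W, lay$b)
  expect_lt(rel_err(list(upd$dW, upd$db), fd), 1e-6)
  ## uniform prediction: rows scale as (1/c - y)
  lay0 <- dense_layer(4, 3, activation = "identity",
                      W = matrix(0, 3, 4), b = rep(0, 3))
  upd0 <- output_layer_update(lay0, z_in, y)
  expect_equal(upd0$dW, (rep(1 / 3, 3) - y) %o% z_in)
  ## a saturated correct prediction emits a vanishing delta
  layc <- dense_layer(4, 3, activation = "identity",
                      W = rbind(0, 50 * z_in, 0) / sum(z_in^2), b = rep(0, 3))
  expect_lt(max(abs(output_layer_update(layc, z_in, y)$dW)), 1e-6)
})

test_that("backprop baseline gradients match finite differences", {
  set.seed(73)
  net <- hsic_network(3, c(4, 3), 2, kind = "dense")
  x <- runif(3); y <- c(1, 0)
  grads <- hsichebb:::backprop_grads(net, x, y)
  loss_with <- function(lidx) function(W, b) {
    n2 <- net
    if (lidx <= 2) {
      n2$layers[[lidx]]$W <- W; n2$layers[[lidx]]$b <- b
    } else {
      n2$output$W <- W; n2$output$b <- b
    }
    fw <- hsichebb:::forward_steady(n2, matrix(x))
    s <- as.numeric(fw$scores)
    -sum(y * (s - log(sum(exp(s)))))
  }
  for (l in 1:3) {
    lay <- if (l <= 2) net$layers[[l]] else net$output
    fd <- fd_layer_grad(loss_with(l), lay$W, lay$b)
    expect_lt(rel_err(grads[[l]], fd), 1e-5)
  }
})

test_that("a zero learning rate leaves the network at its initialization", {
  data <- gen_linear(60, 10, seed = 3)
  cfg <- hsic_config(seed = 3, eta = 0, eta_out = 0, epochs = 2, N = 8)
  fit <- hsic_train(data, hidden = 3, config = cfg)
  set.seed(3)
  ref <- hsic_network(2, 3, 2, kind = "rate", tau_m = 5)
  expect_equal(fit$net$layers[[1]]$W, ref$layers[[1]]$W)
  expect_equal(fit$net$output$W, ref$output$W)
  expect_equal(fit$history$test_acc[1], fit$history$test_acc[nrow(fit$history)])
})

test_that("training is deterministic given the configuration and seed", {
  data <- gen_xor(80, 16, seed = 5)
  cfg <- hsic_config(seed = 5, epochs = 2, N = 8)
  f1 <- hsic_train(data, hidden = c(4, 3), config = cfg)
  f2 <- hsic_train(data, hidden = c(4, 3), config = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net$layers[[2]]$W, f2$net$layers[[2]]$W)
  b <- train_backprop(data, hidden = 3, config = cfg)
  b2 <- train_backprop(data, hidden = 3, config = cfg)
  expect_identical(b$history, b2$history)
})

test_that("backprop baseline solves the separable task", {
  data <- gen_linear(300, 50, seed = 7)
  cfg <- hsic_config(seed = 7, eta = 1e-3, epochs = 40, optimizer = "adam")
  fit <- train_backprop(data, hidden = 8, config = cfg)
  ## the boundary has no margin at this scale; near-perfect is the target
  expect_gte(fit$final_test_acc, 0.9)
  expect_gte(fit$final_train_acc, 0.95)
})

test_that("three-factor updates do not flow across layers", {
  ## the update of layer 2 is a function of its own buffer and current
  ## activity only: changing layer 1's weights after the forward quantities
  ## are fixed cannot change it
  set.seed(79)
  kp <- kernel_params(0.3, 2, 0.25, gamma = 10)
  lay1 <- rate_layer(2, 5)
  lay2 <- rate_layer(5, 3)
  mem2 <- sample_memory(6)
  z1_hist <- rand_samples(6, 5)
  for (i in 6:1) {
    mem2 <- memory_push(mem2, runif(2), sample(c(1, 0)),
                        pmax(as.numeric(lay2$W %*% z1_hist[, i] + lay2$b), 0))
  }
  z_in2 <- z1_hist[, 1]
  xi2 <- modulation_signal(mem2, kp)
  upd_before <- assemble_update(local_factor(dense_layer(5, 3, W = lay2$W, b = lay2$b), z_in2), xi2)
  lay1$W <- lay1$W * 2 + 1              # layer 1 changes arbitrarily
  upd_after <- assemble_update(local_factor(dense_layer(5, 3, W = lay2$W, b = lay2$b), z_in2), xi2)
  expect_identical(upd_before$dW, upd_after$dW)
})

test_that("reservoir-sourced modulation wires through the training loop", {
  data <- gen_linear(60, 10, seed = 13)
  cfg <- hsic_config(seed = 13, epochs = 1, N = 8, xi_source = "reservoir")
  ## a silent (zero-readout) reservoir emits xi = 0: hidden layers must stay
  ## at initialization while the output layer still learns
  res <- init_reservoir(reservoir_params(n_neurons = 40, seed = 13),
                        input_dim = 2 + 2 + 3, output_dim = 3)
  fit <- hsic_train(data, hidden = 3, config = cfg, reservoirs = list(res))
  set.seed(13)
  ref <- hsic_network(2, 3, 2, kind = "rate", tau_m = 5, bias_init = 0.1)
  expect_equal(fit$net$layers[[1]]$W, ref$layers[[1]]$W)
  expect_false(isTRUE(all.equal(fit$net$output$W, ref$output$W)))
  ## one reservoir per hidden layer is enforced
  expect_error(hsic_train(data, hidden = c(3, 3), config = cfg,
                          reservoirs = list(res)), "one pre-trained")
})

test_that("the fitted object exposes the standard modelling methods", {
  data <- gen_linear(120, 20, seed = 11)
  cfg <- hsic_config(seed = 11, epochs = 2, N = 8)
  fit <- hsic_train(data, hidden = 3, config = cfg)
  expect_s3_class(fit, "hsic_net")
  pred <- predict(fit, data)
  expect_length(pred, 120)
  expect_true(all(pred %in% 1:2))
  pr <- predict(fit, data$X[1:5, ], type = "prob")
  expect_equal(dim(pr), c(5, 2))
  expect_equal(rowSums(pr), rep(1, 5))
  cf <- coef(fit)
  expect_length(cf, 2)                   # one hidden layer + output
  expect_equal(dim(cf[[1]]$W), c(3, 2))
  expect_output(print(fit), "three-factor")
  expect_output(summary(fit), "bottleneck")
  expect_equal(nrow(fit$history), 3)     # epoch 0 + 2 epochs
  expect_true(all(fit$history$test_acc >= 0 & fit$history$test_acc <= 1))
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})
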