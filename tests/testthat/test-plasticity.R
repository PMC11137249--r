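test_that("similarity drive has the kernel-weighted difference form", {
  expect_equal(alpha_drive(c(1, 2), c(1, 2), 0.5), c(0, 0))
  expect_equal(alpha_drive(c(1, 0), c(0, 0), 1), exp(-1) * c(1, 0))
  set.seed(1)
  a <- runif(3); b <- runif(3)
  expect_equal(alpha_drive(a, b, 0.8),
               gaussian_kernel(a, b, 0.8) * (a - b))
  ## swapping arguments negates the difference factor
  expect_equal(alpha_drive(a, b, 0.8), -gaussian_kernel(a, b, 0.8) * (b - a))
  expect_error(alpha_drive(c(1, 2), c(1, 2, 3), 1), "length")
})

test_that("modulation signal matches a written-out two-sample expansion", {
  kp <- kernel_params(0.4, 1.3, 0.7, gamma = 2)
  x0 <- 0.2; x1 <- 0.9; y0 <- c(1, 0); y1 <- c(0, 1); z0 <- 0.6; z1 <- 0.1
  mem <- sample_memory(2)
  mem <- memory_push(mem, x1, y1, z1)
  mem <- memory_push(mem, x0, y0, z0)
  ## N = 2: surprise of each sample over {current, previous}, self-inclusive
  sx <- 1 - (1 + gaussian_kernel(x0, x1, 0.4)) / 2
  sy <- 1 - (1 + gaussian_kernel(y0, y1, 0.7)) / 2
  cc <- sx - 2 * sy                       # same for both samples by symmetry
  a1 <- gaussian_kernel(z0, z1, 1.3) * (z0 - z1)
  xi_hand <- (2 / (1.3^2 * 2 * 1)) * (a1 * cc + a1 * cc)
  expect_equal(modulation_signal(mem, kp), xi_hand, tolerance = 1e-12)
})

test_that("modulation vanishes for a zero-information memory", {
  kp <- kernel_params(0.5, 1, 0.5, gamma = 3)
  mem <- sample_memory(5)
  for (i in 1:5) mem <- memory_push(mem, c(0.3, 0.3), c(1, 0), c(2, 2, 2))
  expect_equal(modulation_signal(mem, kp), c(0, 0, 0))
  beta <- local_factor(dense_layer(2, 3, W = matrix(1, 3, 2)), c(0.3, 0.3))
  upd <- assemble_update(beta, modulation_signal(mem, kp))
  expect_equal(upd$dW, matrix(0, 3, 2))
  expect_equal(upd$db, c(0, 0, 0))
})

test_that("modulation is invariant to reordering of the past entries", {
  set.seed(5)
  kp <- kernel_params(0.5, 0.9, 0.6, gamma = 1.5)
  X <- rand_samples(6, 2); Y <- rand_samples(6, 2); Z <- rand_samples(6, 3)
  xi_ref <- modulation_signal(fill_memory(X, Y, Z), kp)
  for (rep in 1:5) {
    perm <- c(1, 1 + sample(5))          # keep the current sample in place
    xi_perm <- modulation_signal(
      fill_memory(X[, perm], Y[, perm], Z[, perm]), kp)
    expect_equal(xi_perm, xi_ref, tolerance = 1e-12)
  }
})

test_that("modulation requires at least two stored samples", {
  mem <- memory_push(sample_memory(4), 0.1, c(1, 0), 0.5)
  expect_error(modulation_signal(mem, kernel_params(1, 1, 1)), "at least 2")
})

test_that("local factor gates by the activation derivative", {
  ## all-negative drive: ReLU gates all zero, so any update is zero
  lay <- dense_layer(2, 3, W = matrix(-1, 3, 2), b = c(-0.1, -0.2, -0.3))
  beta <- local_factor(lay, c(0.5, 0.5))
  expect_equal(beta$post_gate, c(0, 0, 0))
  upd <- assemble_update(beta, c(10, -5, 3))
  expect_equal(max(abs(upd$dW)), 0)
  ## identity activation: gates all one
  lin <- dense_layer(2, 2, activation = "identity")
  expect_equal(local_factor(lin, c(0.1, 0.9))$post_gate, c(1, 1))
  ## mixed-sign drives gate elementwise
  set.seed(9)
  lay2 <- dense_layer(2, 4, W = matrix(rnorm(8), 4, 2), b = rnorm(4))
  z_in <- runif(2)
  u <- as.numeric(lay2$W %*% z_in + lay2$b)
  expect_equal(local_factor(lay2, z_in)$post_gate, as.numeric(u > 0))
  expect_error(local_factor(dense_layer(2, 2, activation = "tanh"), c(1, 1)),
               NA)
})

test_that("assembled update is the rank-one three-factor product", {
  set.seed(13)
  lay <- dense_layer(3, 4)
  z_in <- runif(3)
  beta <- local_factor(lay, z_in)
  xi <- rnorm(4)
  upd <- assemble_update(beta, xi)
  expect_equal(upd$dW, (xi * beta$post_gate) %o% z_in)
  expect_equal(upd$db, xi * beta$post_gate)
  expect_equal(assemble_update(beta, rep(0, 4))$dW, matrix(0, 4, 3))
  expect_error(assemble_update(beta, c(1, 2)), "length")
})

test_that("assembled update is a pure function of gate, pre-activity and xi", {
  ## locality: nothing else about the layer or its history can change it
  beta <- structure(list(post_gate = c(1, 0, 1), pre_activity = c(0.2, 0.7)),
                    class = "local_factor")
  xi <- c(0.3, -0.4, 0.1)
  ref <- assemble_update(beta, xi)
  again <- assemble_update(beta, xi)
  expect_identical(ref$dW, again$dW)
  expect_equal(ref$dW, (xi * c(1, 0, 1)) %o% c(0.2, 0.7))
})

test_that("centered modulation is the restricted gradient of the trace estimator", {
  set.seed(15)
  kp <- kernel_params(0.6, 1.1, 0.8, gamma = 2.3)
  n <- 6; din <- 3; dout <- 4
  lay <- dense_layer(din, dout, activation = "relu",
                     W = matrix(rnorm(dout * din, 0, 0.7), dout, din),
                     b = rnorm(dout, 0, 0.2))
  X <- rand_samples(n, din)
  Y <- matrix(0, 2, n); Y[cbind(sample(1:2, n, TRUE), 1:n)] <- 1
  Z <- vapply(seq_len(n), function(i) dense_forward(lay, X[, i]),
              numeric(dout))
  mem <- fill_memory(X, Y, Z)
  upd <- assemble_update(local_factor(lay, X[, 1]),
                         modulation_signal_centered(mem, kp))
  fd <- fd_layer_grad(function(W, b) {
    Zr <- Z
    Zr[, 1] <- pmax(as.numeric(W %*% X[, 1] + b), 0)
    hsic_objective(X, Y, Zr, kp)
  }, lay$W, lay$b)
  expect_lt(rel_err(list(upd$dW, upd$db), fd), 1e-5)
  ## zero-information memory still yields a zero signal
  memc <- sample_memory(4)
  for (i in 1:4) memc <- memory_push(memc, c(0.2, 0.2), c(1, 0), c(1, 1))
  expect_equal(modulation_signal_centered(memc, kp), c(0, 0))
})

test_that("exact memory gradient matches central finite differences", {
  set.seed(17)
  kp <- kernel_params(0.7, 0.9, 0.6, gamma = 1.7)
  for (case in list(list(n = 4, din = 2, dout = 3, act = "relu"),
                    list(n = 6, din = 3, dout = 4, act = "identity"))) {
    lay <- dense_layer(case$din, case$dout, activation = case$act,
                       W = matrix(rnorm(case$dout * case$din, 0, 0.8),
                                  case$dout, case$din),
                       b = rnorm(case$dout, 0, 0.3))
    X <- rand_samples(case$n, case$din)
    Y <- matrix(0, 2, case$n)
    Y[cbind(sample(1:2, case$n, TRUE), 1:case$n)] <- 1
    Z <- vapply(seq_len(case$n),
                function(i) dense_forward(lay, X[, i]),
                numeric(case$dout))
    mem <- fill_memory(X, Y, matrix(Z, case$dout))
    g <- full_hsic_gradient(mem, lay, kp)
    fd <- fd_layer_grad(function(W, b) {
      Zt <- apply_fun <- vapply(seq_len(case$n), function(i) {
        u <- as.numeric(W %*% X[, i] + b)
        if (case$act == "relu") pmax(u, 0) else u
      }, numeric(case$dout))
      hsic_bound(X, Y, matrix(Zt, case$dout), kp)
    }, lay$W, lay$b)
    expect_lt(rel_err(list(g$dW, g$db), fd), 1e-4)
  }
})

test_that("three-factor update equals the gradient with cross-sample Jacobians zeroed", {
  set.seed(19)
  kp <- kernel_params(0.6, 1.1, 0.8, gamma = 2.2)
  n <- 5; din <- 3; dout <- 4
  lay <- dense_layer(din, dout, activation = "relu",
                     W = matrix(rnorm(dout * din, 0, 0.7), dout, din),
                     b = rnorm(dout, 0, 0.2))
  X <- rand_samples(n, din)
  Y <- matrix(0, 2, n); Y[cbind(sample(1:2, n, TRUE), 1:n)] <- 1
  Z <- vapply(seq_len(n), function(i) dense_forward(lay, X[, i]),
              numeric(dout))
  mem <- fill_memory(X, Y, Z)
  upd <- assemble_update(local_factor(lay, X[, 1]),
                         modulation_signal(mem, kp))
  ## restricted oracle: past outputs frozen, only the current one recomputed
  fd <- fd_layer_grad(function(W, b) {
    Zr <- Z
    Zr[, 1] <- pmax(as.numeric(W %*% X[, 1] + b), 0)
    hsic_bound(X, Y, Zr, kp)
  }, lay$W, lay$b)
  expect_lt(rel_err(list(upd$dW, upd$db), fd), 1e-5)
})

test_that("exact gradient approaches the three-factor update as history collapses onto the present", {
  set.seed(23)
  kp <- kernel_params(0.6, 1.1, 0.8, gamma = 1.4)
  n <- 5; din <- 3; dout <- 3
  lay <- dense_layer(din, dout, activation = "identity",
                     W = matrix(rnorm(dout * din, 0, 0.6), dout, din))
  x0 <- runif(din)
  Y <- matrix(0, 2, n); Y[cbind(sample(1:2, n, TRUE), 1:n)] <- 1
  deltas <- c(0.3, 0.03, 0.003)
  gaps <- vapply(deltas, function(d) {
    ## past inputs shrink toward the current one
    X <- x0 + matrix(c(numeric(din), runif(din * (n - 1), -d, d)), din, n)
    Z <- vapply(seq_len(n), function(i) dense_forward(lay, X[, i]),
                numeric(dout))
    mem <- fill_memory(X, Y, Z)
    g_full <- full_hsic_gradient(mem, lay, kp)
    upd <- assemble_update(local_factor(lay, X[, 1]),
                           modulation_signal(mem, kp))
    max(abs(g_full$dW - upd$dW))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], gaps[1] / 50)
})

test_that("dead layer gives a zero exact gradient", {
  kp <- kernel_params(0.5, 1, 0.5)
  lay <- dense_layer(2, 3, W = matrix(0, 3, 2), b = c(-1, -1, -1))
  set.seed(29)
  X <- rand_samples(4, 2)
  Y <- matrix(0, 2, 4); Y[cbind(c(1, 2, 1, 2), 1:4)] <- 1
  Z <- matrix(0, 3, 4)
  g <- full_hsic_gradient(fill_memory(X, Y, Z), lay, kp)
  expect_equal(max(abs(g$dW)), 0)
  expect_equal(max(abs(g$db)), 0)
})
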