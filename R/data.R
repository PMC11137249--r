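new_labeled_dataset <- function(X, label, n_classes, train, test, seed) {
  Y <- matrix(0, nrow(X), n_classes)
  Y[cbind(seq_len(nrow(X)), label)] <- 1
  structure(list(X = X, Y = Y, label = label, train = train, test = test,
                 seed = seed),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf(
    "Labeled dataset: %d samples (%d train / %d test), %d features, %d classes\n",
    nrow(x$X), length(x$train), length(x$test), ncol(x$X), ncol(x$Y)))
  invisible(x)
}

#' Linearly separable dataset on the unit square
#'
#' Draws `n` points uniformly from `[0,1] x [0,1]` and labels them by a fixed
#' hyperplane through the square's center, with a seed-drawn normal
#' direction — the dataset is exactly linearly separable by construction.
#' `n_test` points are held out for testing.
#'
#' @param n Total number of samples.
#' @param n_test Held-out test samples (`< n`).
#' @param seed Integer seed.
#' @return A `labeled_dataset` with fields `X` (features in `[0,1]^2`), `Y`
#'   (one-hot labels), `label`, `train`, `test`.
#' @export
gen_linear <- function(n = 1000, n_test = 100, seed = 1) {
  stopifnot(n > n_test, n_test >= 0)
  set.seed(seed)
  X <- matrix(stats::runif(2 * n), n, 2)
  theta <- stats::runif(1, 0, 2 * pi)
  w <- c(cos(theta), sin(theta))
  label <- ifelse((X - 0.5) %*% w > 0, 2L, 1L)
  test <- sample.int(n, n_test)
  new_labeled_dataset(X, as.integer(label), 2L,
                      train = setdiff(seq_len(n), test), test = test,
                      seed = seed)
}

#' XOR dataset with Gaussian cluster noise
#'
#' Draws samples in equal numbers around the four corners of the unit square
#' with isotropic Gaussian noise (clipped back to `[0,1]^2`); the label is
#' the exclusive-or of the corner coordinates, so no linear classifier can do
#' substantially better than 75% at small noise.
#'
#' @inheritParams gen_linear
#' @param noise_sd Standard deviation of the cluster noise.
#' @return A `labeled_dataset`.
#' @export
gen_xor <- function(n = 1000, n_test = 100, noise_sd = 0.1, seed = 1) {
  stopifnot(n > n_test, noise_sd >= 0)
  set.seed(seed)
  corners <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  idx <- rep_len(1:4, n)[sample.int(n)]
  X <- corners[idx, , drop = FALSE] +
    matrix(stats::rnorm(2 * n, 0, noise_sd), n, 2)
  X <- pmin(pmax(X, 0), 1)
  label <- ifelse(xor(corners[idx, 1] == 1, corners[idx, 2] == 1), 2L, 1L)
  test <- sample.int(n, n_test)
  new_labeled_dataset(X, as.integer(label), 2L,
                      train = setdiff(seq_len(n), test), test = test,
                      seed = seed)
}

#' Random stream of reservoir inputs with exact modulation targets
#'
#' Generates the training signal for the auxiliary reservoir: per sample, a
#' uniform random input `x`, a random one-hot label `y` and uniform random
#' hidden activations `z`; the reservoir input is the concatenation
#' `[x; y; z]` (the quantities that must be buffered), and the target is the
#' exact modulation signal computed by [modulation_signal()] over a rolling
#' working memory of capacity `N`. The first `N - 1` entries carry no target
#' (`xi = NULL`, warm-up) since the memory is not yet full.
#'
#' @param n_samples Stream length (`>= N`).
#' @param input_dim Dimension of `x`.
#' @param z_dim Dimension of `z` (and of the target signal).
#' @param N Working-memory capacity (effective batch size).
#' @param params [kernel_params()]; defaults to the reservoir experiment
#'   settings (`sigma = 0.5` for all kernels, `gamma = 2`).
#' @param n_classes Number of classes for the random one-hot labels.
#' @param xi_form Target form: `"surprise"` ([modulation_signal()], default)
#'   or `"centered"` ([modulation_signal_centered()], matching
#'   [hsic_train()]'s default modulation).
#' @param seed Integer seed.
#' @return A list of entries `list(r_i, xi, x, y, z)`; `xi` is `NULL` during
#'   warm-up.
#' @export
gen_reservoir_stream <- function(n_samples = 100, input_dim = 20, z_dim = 10,
                                 N = 10,
                                 params = kernel_params(0.5, 0.5, 0.5, gamma = 2),
                                 n_classes = 10,
                                 xi_form = c("surprise", "centered"),
                                 seed = 1) {
  stopifnot(n_samples >= N, N >= 2)
  xi_fun <- switch(match.arg(xi_form),
                   surprise = modulation_signal,
                   centered = modulation_signal_centered)
  set.seed(seed)
  mem <- sample_memory(N)
  stream <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    x <- stats::runif(input_dim)
    y <- numeric(n_classes)
    y[sample.int(n_classes, 1)] <- 1
    z <- stats::runif(z_dim)
    mem <- memory_push(mem, x, y, z)
    stream[[i]] <- list(r_i = c(x, y, z),
                        xi = if (mem$size == N) xi_fun(mem, params),
                        x = x, y = y, z = z)
  }
  stream
}

#' Load an external image benchmark (optional)
#'
#' Reads MNIST (IDX format) or CIFAR-10 (binary batches) from a local
#' directory; features are scaled to `[0,1]` and labels one-hot encoded with
#' the standard train/test split. No download is attempted: if the files are
#' absent a classed error of condition `hsichebb_missing_data` is raised. The
#' core experiments and tests never require this loader.
#'
#' @param name `"mnist"` or `"cifar10"`.
#' @param path Directory containing the standard files.
#' @return A `labeled_dataset`.
#' @export
load_benchmark <- function(name = c("mnist", "cifar10"), path) {
  name <- match.arg(name)
  missing_data <- function(msg) {
    stop(structure(class = c("hsichebb_missing_data", "error", "condition"),
                   list(message = paste0(msg, " (external data required; ",
                                         "no download is attempted)"),
                        call = sys.call(-1))))
  }
  if (missing(path) || !dir.exists(path)) {
    missing_data(sprintf("benchmark '%s': data directory not found", name))
  }
  if (name == "mnist") {
    files <- c("train-images-idx3-ubyte", "train-labels-idx1-ubyte",
               "t10k-images-idx3-ubyte", "t10k-labels-idx1-ubyte")
    paths <- file.path(path, files)
    if (!all(file.exists(paths))) missing_data("benchmark 'mnist': IDX files missing")
    read_idx_images <- function(f) {
      con <- file(f, "rb"); on.exit(close(con))
      hdr <- readBin(con, "integer", 4, size = 4, endian = "big")
      n <- hdr[2]; px <- hdr[3] * hdr[4]
      raw <- readBin(con, "integer", n * px, size = 1, signed = FALSE)
      matrix(raw / 255, n, px, byrow = TRUE)
    }
    read_idx_labels <- function(f) {
      con <- file(f, "rb"); on.exit(close(con))
      hdr <- readBin(con, "integer", 2, size = 4, endian = "big")
      readBin(con, "integer", hdr[2], size = 1, signed = FALSE) + 1L
    }
    Xtr <- read_idx_images(paths[1]); ltr <- read_idx_labels(paths[2])
    Xte <- read_idx_images(paths[3]); lte <- read_idx_labels(paths[4])
    X <- rbind(Xtr, Xte)
    new_labeled_dataset(X, c(ltr, lte), 10L,
                        train = seq_len(nrow(Xtr)),
                        test = nrow(Xtr) + seq_len(nrow(Xte)), seed = NA)
  } else {
    files <- c(paste0("data_batch_", 1:5, ".bin"), "test_batch.bin")
    paths <- file.path(path, files)
    if (!all(file.exists(paths))) missing_data("benchmark 'cifar10': batches missing")
    read_batch <- function(f) {
      raw <- readBin(f, "integer", file.size(f), size = 1, signed = FALSE)
      M <- matrix(raw, nrow = 3073)
      list(label = M[1, ] + 1L, X = t(M[-1, , drop = FALSE]) / 255)
    }
    batches <- lapply(paths, read_batch)
    X <- do.call(rbind, lapply(batches, `[[`, "X"))
    lab <- unlist(lapply(batches, `[[`, "label"))
    n_train <- 50000L
    new_labeled_dataset(X, lab, 10L, train = seq_len(n_train),
                        test = n_train + seq_len(nrow(X) - n_train), seed = NA)
  }
}
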