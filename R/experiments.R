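#' Run a packaged experiment protocol
#'
#' Reproduces one of the study's protocols at a configurable scale and
#' writes per-seed CSV metrics, an aggregate JSON summary and a PNG figure
#' to `out_dir`.
#'
#' * `"reservoir"`: pre-train an auxiliary reservoir on a random input
#'   stream with exact modulation-signal targets, then evaluate the frozen
#'   readout on a held-out stream (reports NRMSE per element and overall).
#' * `"linear"`: train single-hidden-layer rate networks on the linearly
#'   separable dataset over `n_seeds` seeds.
#' * `"xor"`: train two-hidden-layer rate networks on the XOR dataset.
#' * `"batch_sweep"`: sweep the working-memory capacity `N` on XOR and
#'   record final train accuracy per capacity and seed.
#' * `"benchmarks"`: train a dense network on MNIST/CIFAR-10 from a local
#'   copy of the data; raises a classed error when the data are absent.
#'
#' @param name Experiment name.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param seed Base seed; per-run seeds are derived from it.
#' @param n_seeds Number of seeds for the training experiments.
#' @param config An [hsic_config()] (training experiments).
#' @param n,n_test Dataset size and held-out size.
#' @param reservoir_cfg A [reservoir_params()] (reservoir experiment).
#' @param sizes Memory capacities for `"batch_sweep"`.
#' @param benchmark_path Local data directory for `"benchmarks"`.
#' @param benchmark Which benchmark (`"mnist"` or `"cifar10"`).
#' @param hidden Hidden widths for `"benchmarks"` (dense network).
#' @return A list with the experiment's aggregate results (invisibly the
#'   same object that is serialized to JSON).
#' @export
run_experiment <- function(name = c("reservoir", "linear", "xor",
                                    "batch_sweep", "benchmarks"),
                           out_dir = NULL, seed = 1, n_seeds = 3,
                           config = hsic_config(seed = seed),
                           n = 1000, n_test = 100,
                           reservoir_cfg = reservoir_params(seed = seed),
                           sizes = c(2, 4, 8, 16),
                           benchmark_path = NULL, benchmark = "mnist",
                           hidden = c(128, 64)) {
  name <- match.arg(name)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  result <- switch(
    name,
    reservoir = experiment_reservoir(out_dir, seed, reservoir_cfg),
    linear = experiment_train(out_dir, "linear", seed, n_seeds, config,
                              n, n_test),
    xor = experiment_train(out_dir, "xor", seed, n_seeds, config, n, n_test),
    batch_sweep = sweep_batch_size(sizes = sizes, n_seeds = max(n_seeds, 5),
                                   seed = seed, config = config, n = n,
                                   n_test = n_test, out_dir = out_dir),
    benchmarks = experiment_benchmark(out_dir, seed, config, benchmark_path,
                                      benchmark, hidden))
  if (!is.null(out_dir)) {
    jsonlite::write_json(result$summary,
                         file.path(out_dir, paste0(name, "_summary.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}

experiment_reservoir <- function(out_dir, seed, rp) {
  stream_params <- kernel_params(0.5, 0.5, 0.5, gamma = 2)
  train_stream <- gen_reservoir_stream(n_samples = 100, N = 10,
                                       params = stream_params, seed = seed)
  test_stream <- gen_reservoir_stream(n_samples = 100, N = 10,
                                      params = stream_params,
                                      seed = seed + 10000L)
  dims <- c(length(train_stream[[1]]$r_i), length(train_stream[[1]]$z))
  res <- init_reservoir(rp, dims[1], dims[2])
  res <- pretrain_reservoir(res, train_stream)
  ev <- evaluate_reservoir(res, test_stream)
  if (!is.null(out_dir)) {
    utils::write.csv(ev$traces, file.path(out_dir, "reservoir_traces.csv"),
                     row.names = FALSE)
    grDevices::png(file.path(out_dir, "reservoir.png"), 900, 600)
    el <- ev$traces$element == 1
    graphics::plot(ev$traces$t[el], ev$traces$target[el], type = "l",
                   xlab = "t (ms)", ylab = "modulation signal (element 1)")
    graphics::lines(ev$traces$t[el], ev$traces$prediction[el], col = "red")
    graphics::legend("topright", c("target", "reservoir readout"), lty = 1,
                     col = c("black", "red"), bty = "n")
    grDevices::dev.off()
  }
  list(eval = ev, reservoir = res,
       summary = list(nrmse = ev$nrmse,
                      nrmse_element = as.numeric(ev$nrmse_element),
                      train_mse = res$history[length(res$history)]))
}

experiment_train <- function(out_dir, task, seed, n_seeds, config, n, n_test) {
  hidden <- if (task == "linear") 4 else c(10, 4)
  runs <- vector("list", n_seeds)
  for (k in seq_len(n_seeds)) {
    sk <- seed + (k - 1L)
    data <- if (task == "linear") gen_linear(n, n_test, seed = sk) else
      gen_xor(n, n_test, seed = sk)
    cfg <- config
    cfg$seed <- as.integer(sk)
    runs[[k]] <- hsic_train(data, hidden = hidden, config = cfg)
  }
  hist <- do.call(rbind, lapply(seq_len(n_seeds), function(k) {
    cbind(seed = seed + (k - 1L), runs[[k]]$history)
  }))
  final <- vapply(runs, `[[`, numeric(1), "final_test_acc")
  hs_cols <- grep("^hsic_layer", names(hist), value = TRUE)
  hsic_drop <- vapply(hs_cols, function(cn) {
    mean(vapply(runs, function(r) {
      h <- r$history
      h[[cn]][nrow(h)] - h[[cn]][1]
    }, numeric(1)))
  }, numeric(1))
  if (!is.null(out_dir)) {
    utils::write.csv(hist, file.path(out_dir, paste0(task, "_history.csv")),
                     row.names = FALSE)
    grDevices::png(file.path(out_dir, paste0(task, ".png")), 900, 600)
    plot(runs[[1]])
    grDevices::dev.off()
  }
  list(runs = runs, history = hist,
       summary = list(task = task, n_seeds = n_seeds,
                      mean_final_test_acc = mean(final),
                      sd_final_test_acc = stats::sd(final),
                      mean_hsic_change = as.list(hsic_drop)))
}

#' Sweep the working-memory capacity
#'
#' Trains XOR networks at several effective batch sizes `N` over multiple
#' seeds and reports the mean final train accuracy per capacity — probing
#' how learning performance grows with working-memory capacity.
#'
#' @param sizes Integer capacities to sweep.
#' @param n_seeds Seeds per capacity.
#' @param seed Base seed.
#' @param config Base [hsic_config()]; `N` is overridden per run.
#' @param n,n_test Dataset size and held-out size.
#' @param out_dir Optional output directory for CSV/PNG.
#' @return List with the per-run data frame (`$results`) and the aggregate
#'   `$summary` (per-capacity mean and standard error).
#' @export
sweep_batch_size <- function(sizes = c(2, 4, 8, 16), n_seeds = 5, seed = 1,
                             config = hsic_config(seed = seed), n = 1000,
                             n_test = 100, out_dir = NULL) {
  rows <- NULL
  for (N in sizes) {
    for (k in seq_len(n_seeds)) {
      sk <- seed + (k - 1L)
      cfg <- config
      cfg$N <- as.integer(N)
      cfg$seed <- as.integer(sk)
      fit <- hsic_train(gen_xor(n, n_test, seed = sk), hidden = c(10, 4),
                        config = cfg)
      rows <- rbind(rows, data.frame(N = N, seed = sk,
                                     final_train_acc = fit$final_train_acc,
                                     final_test_acc = fit$final_test_acc))
    }
  }
  agg <- do.call(rbind, lapply(split(rows, rows$N), function(d) {
    data.frame(N = d$N[1], mean_train_acc = mean(d$final_train_acc),
               se_train_acc = stats::sd(d$final_train_acc) / sqrt(nrow(d)))
  }))
  agg <- agg[order(agg$N), ]
  if (!is.null(out_dir)) {
    utils::write.csv(rows, file.path(out_dir, "batch_sweep.csv"),
                     row.names = FALSE)
    grDevices::png(file.path(out_dir, "batch_sweep.png"), 700, 500)
    graphics::plot(agg$N, agg$mean_train_acc, log = "x", type = "b",
                   xlab = "effective batch size N",
                   ylab = "final train accuracy", ylim = c(0, 1))
    graphics::arrows(agg$N, agg$mean_train_acc - agg$se_train_acc, agg$N,
                     agg$mean_train_acc + agg$se_train_acc, angle = 90,
                     code = 3, length = 0.04)
    grDevices::dev.off()
  }
  list(results = rows, aggregate = agg,
       summary = list(N = agg$N, mean_train_acc = agg$mean_train_acc,
                      se_train_acc = agg$se_train_acc))
}

experiment_benchmark <- function(out_dir, seed, config, path, benchmark,
                                 hidden) {
  data <- load_benchmark(benchmark, path)
  cfg <- config
  cfg$seed <- as.integer(seed)
  fit <- hsic_train(data, hidden = hidden, config = cfg, kind = "dense")
  if (!is.null(out_dir)) {
    utils::write.csv(fit$history,
                     file.path(out_dir, paste0(benchmark, "_history.csv")),
                     row.names = FALSE)
  }
  list(fit = fit,
       summary = list(benchmark = benchmark,
                      final_test_acc = fit$final_test_acc))
}
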