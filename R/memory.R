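#' Working-memory sample buffer
#'
#' A ring buffer holding the last `N` `(x, y, z)` triples seen by a layer:
#' input vector, one-hot label and the layer's output for that sample,
#' stored with the weights current at presentation time. Its capacity is the
#' rule's *effective batch size* — the number of past samples the global
#' modulation signal integrates over. Entries are kept newest-first: column 1
#' is the current sample (lag 0), column `k` is lag `-(k - 1)`.
#'
#' @param capacity Integer `>= 2`.
#' @return An empty `sample_memory` object.
#' @seealso [memory_push()], [memory_get()], [modulation_signal()]
#' @export
sample_memory <- function(capacity) {
  if (!is.numeric(capacity) || length(capacity) != 1L ||
      capacity != round(capacity) || capacity < 2) {
    stop("sample_memory: 'capacity' must be an integer >= 2")
  }
  structure(list(capacity = as.integer(capacity),
                 x = NULL, y = NULL, z = NULL, size = 0L),
            class = "sample_memory")
}

#' Push a sample into the working memory
#'
#' Inserts `(x, y, z)` at lag 0, shifting all stored samples one step into
#' the past; when the buffer is full the oldest entry is evicted.
#'
#' @param mem A [sample_memory()].
#' @param x,y,z Numeric vectors; dimensions must match any stored entries.
#' @return The updated `sample_memory`.
#' @export
memory_push <- function(mem, x, y, z) {
  stopifnot(inherits(mem, "sample_memory"))
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  if (mem$size > 0L) {
    if (length(x) != nrow(mem$x) || length(y) != nrow(mem$y) ||
        length(z) != nrow(mem$z)) {
      stop("memory_push: dimension mismatch with stored entries")
    }
    keep <- seq_len(min(mem$size, mem$capacity - 1L))
    mem$x <- cbind(x, mem$x[, keep, drop = FALSE], deparse.level = 0)
    mem$y <- cbind(y, mem$y[, keep, drop = FALSE], deparse.level = 0)
    mem$z <- cbind(z, mem$z[, keep, drop = FALSE], deparse.level = 0)
  } else {
    mem$x <- matrix(x); mem$y <- matrix(y); mem$z <- matrix(z)
  }
  mem$size <- ncol(mem$x)
  mem
}

#' Retrieve a stored sample by lag
#'
#' @param mem A [sample_memory()].
#' @param lag 0 for the current sample, `-p` for the sample pushed `p` steps
#'   ago.
#' @return A list with elements `x`, `y`, `z`.
#' @export
memory_get <- function(mem, lag = 0) {
  stopifnot(inherits(mem, "sample_memory"))
  j <- 1L - as.integer(lag)
  if (lag > 0 || j > mem$size) stop("memory_get: lag out of range")
  list(x = mem$x[, j], y = mem$y[, j], z = mem$z[, j])
}

#' @export
print.sample_memory <- function(x, ...) {
  cat(sprintf("Working-memory buffer: %d / %d samples", x$size, x$capacity))
  if (x$size > 0L) {
    cat(sprintf(" (dims x=%d, y=%d, z=%d)", nrow(x$x), nrow(x$y), nrow(x$z)))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.sample_memory <- function(x, ...) {
  if (x$size == 0L) return(data.frame(lag = integer(0)))
  df <- data.frame(lag = -(seq_len(x$size) - 1L))
  add <- function(df, M, prefix) {
    V <- t(M)
    colnames(V) <- paste0(prefix, seq_len(ncol(V)))
    cbind(df, as.data.frame(V, row.names = NULL))
  }
  df <- add(df, x$x, "x")
  df <- add(df, x$y, "y")
  add(df, x$z, "z")
}
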