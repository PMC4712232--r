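#' Potential movie
#'
#' A node/channel-by-frame matrix of potentials (mV) with its sampling rate.
#' Used for epicardial source potentials, full-torso body-surface potentials
#' and sampled electrode (ECG) potentials.
#'
#' @param values Numeric matrix, rows = nodes or channels, columns = frames.
#' @param rate Sampling rate in Hz (the mapping experiments use 2048 Hz).
#' @param role One of `"epicardial_source"`, `"body_surface"`, `"electrode"`.
#' @return Object of class `potential_movie`.
#' @export
potential_movie <- function(values,
                            rate = 2048,
                            role = c("epicardial_source", "body_surface",
                                     "electrode")) {
  role <- match.arg(role)
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("non-finite potentials", call. = FALSE)
  stopifnot(rate > 0)
  structure(list(values = values, rate = rate, role = role),
            class = "potential_movie")
}

#' @export
print.potential_movie <- function(x, ...) {
  cat(sprintf("<potential_movie [%s]: %d x %d @ %g Hz (%.1f ms)>\n",
              x$role, nrow(x$values), ncol(x$values), x$rate,
              1000 * ncol(x$values) / x$rate))
  invisible(x)
}

#' Frame times of a movie (ms)
#' @param m A [potential_movie()].
#' @return Numeric vector, frame f at `(f - 1) / rate` seconds.
#' @export
frame_times <- function(m) (seq_len(ncol(m$values)) - 1) / m$rate * 1000

#' Write / read a potential movie as a delimited matrix plus JSON sidecar
#'
#' The matrix is stored as tab-separated text (rows = nodes/channels) and the
#' sidecar `<path>.json` records units, sampling rate, role and node count.
#'
#' @param m A [potential_movie()].
#' @param path Path of the matrix file.
#' @return `write_movie()` returns `path` invisibly; `read_movie()` the movie.
#' @export
write_movie <- function(m, path) {
  utils::write.table(m$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(units = "mV", sampling_rate_hz = m$rate,
                            role = m$role, node_count = nrow(m$values)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(vals) <- NULL
  potential_movie(vals, rate = meta$sampling_rate_hz, role = meta$role)
}

#' Tidy a potential movie into long format
#'
#' @param x A [potential_movie()].
#' @param ... Unused.
#' @return Tibble with columns `node`, `time_ms`, `potential_mv`.
#' @export
tidy.potential_movie <- function(x, ...) {
  tibble::tibble(node = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
                 time_ms = rep(frame_times(x), each = nrow(x$values)),
                 potential_mv = as.vector(x$values))
}
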