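#' Names of the 10 temporal compression statistics
#'
#' Mean, median, minimum, maximum, standard deviation, variance and the
#' 25th, 50th, 75th and 95th quantiles. The median and the 50th quantile are
#' both emitted (they are numerically identical) to honor the 10-fold
#' factorization of the feature space.
#'
#' @return Character vector of length 10.
#' @export
compressor_names <- function() {
  c("mean", "median", "min", "max", "std", "variance",
    "q25", "q50", "q75", "q95")
}

#' Compress a feature time series into 10 statistics
#'
#' @param series Numeric vector (length >= 1): one feature's values over the
#'   windows of one channel.
#' @return Named numeric vector of length 10 (see [compressor_names()]).
#'   Quantiles use linear interpolation; variance and standard deviation are
#'   population (divisor N) statistics.
#' @export
compress_series <- function(series) {
  if (!length(series)) stop("cannot compress an empty series")
  q <- unname(quantile(series, c(0.25, 0.5, 0.75, 0.95), type = 7))
  v <- mean((series - mean(series))^2)
  c(mean = mean(series), median = q[2], min = min(series), max = max(series),
    std = sqrt(v), variance = v, q25 = q[1], q50 = q[2], q75 = q[3], q95 = q[4])
}

#' Compress a feature cube into one flat vector per subject
#'
#' Applies [compress_series()] over the window axis of every
#' (channel, feature) pair and flattens channel-major, then feature, then
#' statistic, giving a vector of length `channels x 43 x 10` (8170 for the
#' standard 19-channel montage).
#'
#' @param cube A [compute_feature_cube()] result.
#' @return An object of class `compressed_vector`: list with `subject_id`,
#'   `group`, `values` and `column_names`
#'   (labels `"channel|feature|statistic"`).
#' @export
compress_cube <- function(cube) {
  stopifnot(inherits(cube, "feature_cube"))
  d <- dim(cube$values)
  if (d[2] < 1) stop("feature cube has no windows")
  cn <- compressor_names()
  nstat <- length(cn)
  vals <- numeric(d[1] * d[3] * nstat)
  labs <- character(length(vals))
  k <- 0L
  for (ch in seq_len(d[1])) {
    for (f in seq_len(d[3])) {
      vals[(k + 1):(k + nstat)] <- compress_series(cube$values[ch, , f])
      labs[(k + 1):(k + nstat)] <- paste(cube$channel_names[ch],
                                         cube$feature_names[f], cn, sep = "|")
      k <- k + nstat
    }
  }
  structure(list(subject_id = cube$subject_id, group = cube$group,
                 values = vals, column_names = labs),
            class = "compressed_vector")
}

#' @export
print.compressed_vector <- function(x, ...) {
  cat(sprintf("<compressed_vector> %s (group: %s), length %d\n",
              x$subject_id, x$group, length(x$values)))
  invisible(x)
}

#' Write compressed vectors as a wide per-cohort CSV
#'
#' One row per subject: `subject_id`, `group`, then one named column per
#' channel x feature x statistic combination.
#'
#' @param vectors List of [compress_cube()] results with identical columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_compressed_csv <- function(vectors, path) {
  stopifnot(length(vectors) >= 1)
  cols <- vectors[[1]]$column_names
  for (v in vectors) {
    if (!identical(v$column_names, cols)) stop("inconsistent column names")
  }
  m <- do.call(rbind, lapply(vectors, function(v) v$values))
  df <- data.frame(subject_id = vapply(vectors, `[[`, "", "subject_id"),
                   group = vapply(vectors, `[[`, "", "group"),
                   m, check.names = FALSE)
  names(df)[-(1:2)] <- cols
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a wide compressed-vector CSV
#'
#' @param path File written by [write_compressed_csv()].
#' @return List of `compressed_vector` objects.
#' @export
read_compressed_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cols <- setdiff(names(df), c("subject_id", "group"))
  lapply(seq_len(nrow(df)), function(i) {
    structure(list(subject_id = df$subject_id[i], group = df$group[i],
                   values = as.numeric(df[i, cols]), column_names = cols),
              class = "compressed_vector")
  })
}
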