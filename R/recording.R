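#' Standard 19-channel 10-20 montage labels
#'
#' Electrode labels of the international 10-20 system in the 19-channel
#' referential montage used throughout the package.
#'
#' @format Character vector of length 19.
#' @export
CHANNELS_1020 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
  "T3", "C3", "Cz", "C4", "T4",
  "T5", "P3", "Pz", "P4", "T6", "O1", "O2"
)

#' Construct an EEG recording
#'
#' Container for one subject's multichannel EEG: a channels x samples numeric
#' matrix plus sampling rate, group label and channel names.
#'
#' @param data Numeric matrix, channels in rows, samples in columns. All
#'   values must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param subject_id Opaque subject identifier.
#' @param group Group label, conventionally one of `"control"`, `"mci"`,
#'   `"ad"` (free-form labels are allowed).
#' @param channel_names Character vector, one label per row of `data`.
#'   Defaults to the first `nrow(data)` labels of [CHANNELS_1020].
#'
#' @return An object of class `eeg_recording` with fields `data`, `fs`,
#'   `subject_id`, `group`, `channel_names`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 512), 2), fs = 256,
#'                      subject_id = "s1", group = "control",
#'                      channel_names = c("Fp1", "Fp2"))
#' rec
eeg_recording <- function(data, fs, subject_id = "subject", group = NA_character_,
                          channel_names = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channel_names)) {
    if (nrow(data) > length(CHANNELS_1020)) {
      channel_names <- sprintf("ch%02d", seq_len(nrow(data)))
    } else {
      channel_names <- CHANNELS_1020[seq_len(nrow(data))]
    }
  }
  rec <- structure(
    list(data = data, fs = as.numeric(fs), subject_id = as.character(subject_id),
         group = as.character(group), channel_names = as.character(channel_names)),
    class = "eeg_recording"
  )
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.matrix(rec$data)) stop("recording data must be a matrix")
  if (nrow(rec$data) != length(rec$channel_names)) {
    stop("recording has ", nrow(rec$data), " rows but ",
         length(rec$channel_names), " channel names")
  }
  if (!is.finite(rec$fs) || rec$fs <= 0) stop("sampling rate must be > 0")
  if (any(!is.finite(rec$data))) stop("recording contains non-finite samples")
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s (group: %s)\n", x$subject_id, x$group))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Write an EEG recording to CSV
#'
#' One CSV per subject: comment header lines carrying the sampling rate,
#' group and subject id (`# fs=256` etc.), then one row per channel with the
#' channel name in the first column.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_recording_csv()]
#' @export
write_recording_csv <- function(rec, path) {
  validate_recording(rec)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs=%s", format(rec$fs, digits = 15)),
    sprintf("# group=%s", rec$group),
    sprintf("# subject_id=%s", rec$subject_id)
  ), con)
  df <- data.frame(channel = rec$channel_names, rec$data, check.names = FALSE)
  utils::write.table(df, con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an EEG recording from CSV
#'
#' Reads either the dialect written by [write_recording_csv()] (comment
#' header, channel names in column 1) or a plain headerless channels x
#' samples CSV, in which case `fs` must be supplied.
#'
#' @param path Input file path.
#' @param fs Sampling rate override; required for plain matrices without a
#'   `# fs=` header line.
#' @return An [eeg_recording()].
#' @export
read_recording_csv <- function(path, fs = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  meta <- list(fs = fs, group = NA_character_, subject_id = basename(path))
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    if (key == "fs") meta$fs <- as.numeric(val)
    if (key == "group") meta$group <- val
    if (key == "subject_id") meta$subject_id <- val
  }
  if (is.null(meta$fs)) stop("no '# fs=' header in ", path, "; supply fs")
  cells <- strsplit(body, ",", fixed = TRUE)
  first <- vapply(cells, `[`, "", 1L)
  named <- any(is.na(suppressWarnings(as.numeric(first))))
  if (named) {
    chn <- first
    dat <- t(vapply(cells, function(r) as.numeric(r[-1L]),
                    numeric(length(cells[[1L]]) - 1L)))
  } else {
    chn <- NULL
    dat <- t(vapply(cells, as.numeric, numeric(length(cells[[1L]]))))
  }
  eeg_recording(dat, fs = meta$fs, subject_id = meta$subject_id,
                group = meta$group, channel_names = chn)
}
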