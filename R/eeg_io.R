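# Continuous EEG container and on-disk formats.
#
# Native container: float32 little-endian channel-multiplexed binary (.dat)
# with a JSON sidecar header (.json) and an events CSV (.events.csv). The
# BrainVision .vhdr/.vmrk/.eeg triplet can be imported read-only for the
# BINARY MULTIPLEXED INT_16 / IEEE_FLOAT_32 dialects.

#' Construct an EEG recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param channel_labels Character vector of unique 10-20 channel names,
#'   one per row of `data`.
#' @param sampling_rate Sampling rate in Hz.
#' @param events Data frame with columns `sample` (0-based sample index of
#'   stimulus onset), `trial_id`, `code`; may have zero rows.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, channel_labels, sampling_rate,
                          events = data.frame(sample = integer(), trial_id = integer(),
                                              code = character())) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_labels),
            sampling_rate > 0)
  if (anyDuplicated(channel_labels))
    stopf("duplicate channel labels: %s",
          paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "))
  events <- as.data.frame(events)
  if (nrow(events) &&
      (any(events$sample < 0) || any(events$sample >= ncol(data))))
    stopf("event sample indices must lie in [0, %d)", ncol(data))
  structure(list(data = data, channel_labels = channel_labels,
                 sampling_rate = sampling_rate, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %d channels x %d samples @ %g Hz, %d events>\n",
              nrow(x$data), ncol(x$data), x$sampling_rate, nrow(x$events)))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

# index of a channel, with a lookup error naming the channel
channel_index <- function(rec, channel) {
  i <- match(channel, rec$channel_labels)
  if (anyNA(i))
    stopf("channel(s) not found in recording: %s",
          paste(channel[is.na(i)], collapse = ", "))
  i
}

#' Write / read a recording in the native container
#'
#' `write_recording(rec, prefix)` creates `<prefix>.dat` (float32
#' little-endian, multiplexed), `<prefix>.json` (labels, rate, sample count)
#' and `<prefix>.events.csv`. The round-trip is lossless up to float32
#' precision of the samples.
#'
#' @param rec An `eeg_recording`.
#' @param prefix Path prefix (no extension).
#' @return `write_recording` returns `prefix` invisibly; `read_recording`
#'   returns the `eeg_recording`.
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(paste0(prefix, ".dat"), "wb")
  writeBin(as.vector(rec$data), con, size = 4, endian = "little")
  close(con)
  header <- list(format = "brainload-eeg", version = 1L,
                 channel_labels = rec$channel_labels,
                 sampling_rate = rec$sampling_rate,
                 n_samples = ncol(rec$data))
  jsonlite::write_json(header, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(rec$events, paste0(prefix, ".events.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  hpath <- paste0(prefix, ".json")
  dpath <- paste0(prefix, ".dat")
  if (!file.exists(hpath) || !file.exists(dpath))
    stopf("recording files not found at prefix '%s'", prefix)
  h <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  nchan <- length(h$channel_labels)
  nsamp <- as.integer(h$n_samples)
  expected <- 4 * nchan * nsamp
  got <- file.size(dpath)
  if (got != expected)
    stopf("data file '%s' length mismatch: expected %d bytes, found %d",
          dpath, expected, got)
  con <- file(dpath, "rb")
  x <- readBin(con, numeric(), n = nchan * nsamp, size = 4, endian = "little")
  close(con)
  epath <- paste0(prefix, ".events.csv")
  events <- if (file.exists(epath))
    utils::read.csv(epath, stringsAsFactors = FALSE)
  else data.frame(sample = integer(), trial_id = integer(), code = character())
  eeg_recording(matrix(x, nrow = nchan), h$channel_labels, h$sampling_rate, events)
}

# parse a BrainVision INI-style header into a list of sections
parse_vision_ini <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "latin1")
  lines <- lines[!grepl("^\\s*(;|$)", lines)]
  sections <- list()
  current <- NULL
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      current <- gsub("^\\[|\\]\\s*$", "", ln)
      sections[[current]] <- character()
    } else if (!is.null(current) && grepl("=", ln, fixed = TRUE)) {
      key <- sub("=.*$", "", ln)
      val <- sub("^[^=]*=", "", ln)
      sections[[current]][trimws(key)] <- val
    }
  }
  sections
}

#' Import a BrainVision recording
#'
#' Reads the `.vhdr` header plus its `.eeg` data and `.vmrk` marker siblings.
#' Only the BINARY, MULTIPLEXED, INT_16 or IEEE_FLOAT_32 dialect is
#' supported; INT_16 samples are scaled by the per-channel resolution so the
#' returned data are in microvolts. Marker positions (1-based data points in
#' the file format) become 0-based event sample indices.
#'
#' @param vhdr_path Path to the `.vhdr` header file.
#' @return An `eeg_recording`.
#' @export
import_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) stopf("header file '%s' not found", vhdr_path)
  ini <- parse_vision_ini(vhdr_path)
  ci <- ini[["Common Infos"]]
  if (is.null(ci)) stopf("'%s' has no [Common Infos] section", vhdr_path)
  if (toupper(ci[["DataFormat"]] %||% "") != "BINARY")
    stopf("unsupported BrainVision dialect: DataFormat '%s' (only BINARY)",
          ci[["DataFormat"]] %||% "?")
  if (toupper(ci[["DataOrientation"]] %||% "") != "MULTIPLEXED")
    stopf("unsupported BrainVision dialect: DataOrientation '%s' (only MULTIPLEXED)",
          ci[["DataOrientation"]] %||% "?")
  bfmt <- toupper(ini[["Binary Infos"]][["BinaryFormat"]] %||% "")
  if (!bfmt %in% c("INT_16", "IEEE_FLOAT_32"))
    stopf("unsupported BrainVision dialect: BinaryFormat '%s'", bfmt)
  nchan <- as.integer(ci[["NumberOfChannels"]])
  rate <- 1e6 / as.numeric(ci[["SamplingInterval"]])  # interval is in microseconds

  chinfo <- ini[["Channel Infos"]]
  labels <- character(nchan)
  resolution <- rep(1, nchan)
  for (i in seq_len(nchan)) {
    entry <- chinfo[[sprintf("Ch%d", i)]]
    if (is.null(entry)) stopf("channel Ch%d missing from [Channel Infos]", i)
    parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) resolution[i] <- as.numeric(parts[3])
  }

  dir <- dirname(vhdr_path)
  dpath <- file.path(dir, ci[["DataFile"]])
  bytes <- if (bfmt == "INT_16") 2L else 4L
  size <- file.size(dpath)
  if (is.na(size) || size %% (bytes * nchan) != 0)
    stopf("data file '%s' length %s is not a multiple of %d channels x %d bytes",
          dpath, size, nchan, bytes)
  nsamp <- size / (bytes * nchan)
  con <- file(dpath, "rb")
  raw <- if (bfmt == "INT_16")
    readBin(con, integer(), n = nchan * nsamp, size = 2, signed = TRUE,
            endian = "little")
  else readBin(con, numeric(), n = nchan * nsamp, size = 4, endian = "little")
  close(con)
  data <- matrix(as.numeric(raw), nrow = nchan) * resolution

  events <- data.frame(sample = integer(), trial_id = integer(), code = character())
  mfile <- ci[["MarkerFile"]]
  if (!is.null(mfile) && file.exists(file.path(dir, mfile))) {
    mk <- parse_vision_ini(file.path(dir, mfile))[["Marker Infos"]]
    if (length(mk)) {
      rows <- lapply(seq_along(mk), function(j) {
        parts <- strsplit(mk[[j]], ",", fixed = TRUE)[[1]]
        data.frame(sample = as.integer(parts[3]) - 1L, trial_id = j,
                   code = trimws(parts[2]), type = trimws(parts[1]),
                   stringsAsFactors = FALSE)
      })
      rows <- do.call(rbind, rows)
      rows <- rows[rows$type == "Stimulus", c("sample", "trial_id", "code")]
      rows$trial_id <- seq_len(nrow(rows))
      events <- rows
    }
  }
  eeg_recording(data, labels, rate, events)
}
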