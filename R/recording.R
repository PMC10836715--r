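#' Multichannel recording container
#'
#' A `recording` bundles a channels-by-samples signal matrix with its
#' sampling rate and per-channel cortical-system labels. It is the common
#' currency passed between the generator, the irreversibility estimator, the
#' stage classifier and the latent-space analysis.
#'
#' @param data numeric matrix, channels x samples (arbitrary amplitude units).
#' @param fs sampling rate in Hz (> 0).
#' @param channel_ids character vector of channel identifiers; defaults to
#'   `"ch01"`, `"ch02"`, ...
#' @param system_of named character vector mapping every channel id to a
#'   system label (e.g. `"visual"`, `"auditory"`, `"parietal"`). A single
#'   unnamed value is recycled to all channels.
#'
#' @return an object of class `recording` with fields `data`, `fs`,
#'   `channel_ids`, `system_of`.
#' @examples
#' rec <- recording(matrix(rnorm(200), 2), fs = 100)
#' print(rec)
#' @export
recording <- function(data, fs, channel_ids = NULL, system_of = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2) stop("a recording needs at least 2 channels")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("'fs' must be a single positive sampling rate in Hz")
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("recording data must be finite (no NaN/Inf)")
  }
  if (is.null(channel_ids)) {
    channel_ids <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != nrow(data) || anyDuplicated(channel_ids)) {
    stop("'channel_ids' must be unique and match nrow(data)")
  }
  if (is.null(system_of)) system_of <- "cortex"
  if (length(system_of) == 1 && is.null(names(system_of))) {
    system_of <- setNames(rep(as.character(system_of), nrow(data)), channel_ids)
  }
  system_of <- setNames(as.character(system_of), names(system_of))
  if (!setequal(names(system_of), channel_ids)) {
    stop("'system_of' must name exactly the channels in 'channel_ids'")
  }
  system_of <- system_of[channel_ids]
  rownames(data) <- channel_ids
  structure(
    list(data = data, fs = fs, channel_ids = channel_ids,
         system_of = system_of),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  tab <- table(x$system_of)
  cat("  systems:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.recording <- function(x) dim(x$data)

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)
duration_s <- function(rec) ncol(rec$data) / rec$fs

# Replace the data matrix, keeping metadata (used by filters/resamplers).
with_data <- function(rec, data) {
  recording(data, fs = rec$fs, channel_ids = rec$channel_ids,
            system_of = rec$system_of)
}

#' Write / read a recording as plain-text files
#'
#' The on-disk container is three sidecar files sharing a path prefix:
#' `<prefix>_data.csv` (samples x channels, header row of channel ids),
#' `<prefix>_channels.csv` (`channel_id,system`) and `<prefix>_meta.json`
#' (sampling rate and dimensions).
#'
#' @param rec a [recording].
#' @param prefix file path prefix (directories must exist).
#' @return `write_recording()` the prefix, invisibly; `read_recording()` a
#'   [recording].
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "recording"))
  df <- as.data.frame(t(rec$data))
  write.csv(df, paste0(prefix, "_data.csv"), row.names = FALSE)
  write.csv(data.frame(channel_id = rec$channel_ids,
                       system = unname(rec$system_of)),
            paste0(prefix, "_channels.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, n_channels = n_channels(rec), n_samples = n_samples(rec)),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"))
  chans <- read.csv(paste0(prefix, "_channels.csv"),
                    colClasses = "character")
  dat <- as.matrix(read.csv(paste0(prefix, "_data.csv"), check.names = FALSE))
  if (ncol(dat) != nrow(chans)) {
    stop("channel metadata does not match the data matrix: ",
         nrow(chans), " metadata rows vs ", ncol(dat), " data columns")
  }
  recording(t(dat), fs = meta$fs, channel_ids = chans$channel_id,
            system_of = setNames(chans$system, chans$channel_id))
}

#' Load a recording from disk
#'
#' Thin format dispatcher over the package's plain-text container (see
#' [write_recording()]).
#'
#' @param path path prefix of the container.
#' @param format currently only `"csv"`.
#' @return a [recording].
#' @export
load_recording <- function(path, format = c("csv")) {
  format <- match.arg(format)
  if (!file.exists(paste0(path, "_meta.json"))) {
    stop("no recording container at prefix '", path,
         "': missing ", path, "_meta.json")
  }
  read_recording(path)
}
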