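# Single-file array containers for epoched EEG and scalogram stacks.
# One dataset per file; contents are the in-memory objects serialized with
# R's native format, validated on read.

#' Write / read an epoched-EEG dataset container
#'
#' @param epochs An `eeg_epochs` object.
#' @param path File path (conventionally `.eegds`).
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns
#'   the `eeg_epochs` object.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  saveRDS(epochs, path, version = 2L)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "eeg_epochs")) {
    abort_arg(sprintf("`%s` does not contain an epoched-EEG dataset.", path))
  }
  x
}

#' Write / read a scalogram dataset container
#'
#' @param scalograms A `scalogram_set` object.
#' @param path File path (conventionally `.scds`).
#' @return `write_scalograms` returns `path` invisibly; `read_scalograms`
#'   returns the `scalogram_set`.
#' @export
write_scalograms <- function(scalograms, path) {
  stopifnot(inherits(scalograms, "scalogram_set"))
  saveRDS(scalograms, path, version = 2L)
  invisible(path)
}

#' @rdname write_scalograms
#' @export
read_scalograms <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "scalogram_set")) {
    abort_arg(sprintf("`%s` does not contain a scalogram dataset.", path))
  }
  x
}
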