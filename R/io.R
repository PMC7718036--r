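# Plain-text spike-train files: '#'-prefixed header lines carrying
# metadata (window, model, seed), then one trial per line with ascending
# spike times separated by single spaces. Times are written with 17
# significant digits so that a write/read round trip is bit-exact.

#' Read and write spike-train files
#'
#' The file format is one trial per line (ascending spike times in
#' seconds, space-separated; an empty line is a zero-spike trial),
#' preceded by `#`-prefixed header lines. The header `# window: <w>`
#' records the observation window; `write_spike_trains()` also records
#' the trial count and, when known, the generating model and seed.
#'
#' @param set A [spike_train_set()].
#' @param path File path.
#' @param seed Optional seed to record in the header (metadata only).
#' @return `write_spike_trains()` returns `path` invisibly;
#'   `read_spike_trains()` returns a [spike_train_set()].
#' @examples
#' s <- spike_train_set(list(c(0.2, 0.9), numeric(0), 0.5), window = 1)
#' f <- tempfile(fileext = ".txt")
#' write_spike_trains(s, f)
#' identical(read_spike_trains(f)$trains, s$trains)
#' @export
write_spike_trains <- function(set, path, seed = NULL) {
  header <- c(sprintf("# window: %.17g", set$window),
              sprintf("# n_trials: %d", length(set$trains)))
  model <- attr(set, "model")
  if (!is.null(model)) {
    cfg <- model_to_config(model)
    header <- c(header, sprintf(
      "# model: %s",
      paste(sprintf("%s=%s", names(cfg), unlist(cfg)), collapse = " ")))
  }
  if (!is.null(seed)) header <- c(header, sprintf("# seed: %d", seed))
  body <- vapply(set$trains, function(tt)
    paste(sprintf("%.17g", tt), collapse = " "), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_spike_trains
#' @param window Observation window; required if the file header does not
#'   carry one.
#' @export
read_spike_trains <- function(path, window = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_header <- grepl("^#", lines)
  # headers must precede the body; a '#' later is malformed
  if (any(is_header) && any(is_header & cumsum(!is_header) > 0))
    stop("malformed file: '#' header line inside the trial body",
         call. = FALSE)
  for (h in lines[is_header]) {
    m <- regmatches(h, regexec("^#\\s*window:\\s*(\\S+)\\s*$", h))[[1]]
    if (length(m) == 2L) {
      w <- suppressWarnings(as.numeric(m[2]))
      if (is.na(w)) stop("unparsable window in header: ", h, call. = FALSE)
      if (is.null(window)) window <- w
    }
  }
  if (is.null(window))
    stop("no '# window:' header in ", path,
         "; supply the 'window' argument", call. = FALSE)
  body_idx <- which(!is_header)
  trains <- vector("list", length(body_idx))
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    line <- trimws(lines[i])
    if (nchar(line) == 0L) { trains[[k]] <- numeric(0); next }
    toks <- strsplit(line, "\\s+")[[1]]
    tt <- suppressWarnings(as.numeric(toks))
    if (anyNA(tt))
      stop("line ", i, ": malformed spike time '",
           toks[which(is.na(tt))[1]], "'", call. = FALSE)
    if (any(tt <= 0) || any(tt > window))
      stop("line ", i, ": spike times must lie in (0, window = ",
           window, "]", call. = FALSE)
    if (is.unsorted(tt, strictly = TRUE))
      stop("line ", i, ": spike times are not strictly increasing",
           call. = FALSE)
    trains[[k]] <- tt
  }
  spike_train_set(trains, window)
}
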