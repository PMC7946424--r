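# On-disk containers: plain-text pulse-time files, a keyed store for
# multi-band pulse-train sets (directory with a JSON index), and an EEG
# epochs container (JSON metadata + float64 binary payload).

#' Read / write pulse times as plain text
#'
#' One pulse time in seconds per line, full double precision.
#'
#' @param path File path.
#' @return `read_pulses`: numeric vector of pulse times.
#' @export
read_pulses <- function(path) {
  x <- scan(path, what = numeric(), quiet = TRUE)
  if (length(x) && is.unsorted(x, strictly = TRUE))
    stop("pulse file is not strictly increasing")
  x
}

#' @param times Numeric pulse times in seconds (or a [pulse_train()]).
#' @rdname read_pulses
#' @export
write_pulses <- function(times, path) {
  if (inherits(times, "pulse_train")) times <- times$times
  writeLines(sprintf("%.17g", times), path)
  invisible(path)
}

#' Keyed on-disk store for pulse-train sets and response tables
#'
#' A directory with an `index.json` mapping keys to per-key files. Numeric
#' vectors (pulse trains, waveforms) are stored as full-precision text;
#' matrices as little-endian float64 binary with dimensions in the index.
#' Keys use `/`-separated paths (e.g. `"ear1/band2"`).
#'
#' @param store Directory path (created if needed).
#' @param key Character key.
#' @param value Numeric vector or matrix.
#' @return `write_keyed` returns `store` invisibly; `read_keyed` the stored
#'   object; `keyed_keys` all keys.
#' @export
write_keyed <- function(store, key, value) {
  dir.create(store, showWarnings = FALSE, recursive = TRUE)
  idx_path <- file.path(store, "index.json")
  idx <- if (file.exists(idx_path))
    jsonlite::read_json(idx_path, simplifyVector = FALSE) else list()
  fname <- paste0(gsub("/", "__", key), if (is.matrix(value)) ".bin"
                  else ".txt")
  if (is.matrix(value)) {
    con <- file(file.path(store, fname), "wb")
    writeBin(as.numeric(t(value)), con, 8, endian = "little")
    close(con)
    idx[[key]] <- list(file = fname, type = "matrix",
                       dim = dim(value))
  } else {
    writeLines(sprintf("%.17g", as.numeric(value)),
               file.path(store, fname))
    idx[[key]] <- list(file = fname, type = "vector",
                       length = length(value))
  }
  jsonlite::write_json(idx, idx_path, auto_unbox = TRUE)
  invisible(store)
}

#' @rdname write_keyed
#' @export
read_keyed <- function(store, key) {
  idx <- jsonlite::read_json(file.path(store, "index.json"),
                             simplifyVector = FALSE)
  meta <- idx[[key]]
  if (is.null(meta)) stop(sprintf("key '%s' not found in store", key))
  path <- file.path(store, meta$file)
  if (meta$type == "matrix") {
    d <- unlist(meta$dim)
    con <- file(path, "rb")
    x <- readBin(con, "double", prod(d), 8, endian = "little")
    close(con)
    matrix(x, nrow = d[1], byrow = TRUE)
  } else {
    scan(path, what = numeric(), quiet = TRUE)
  }
}

#' @rdname write_keyed
#' @export
keyed_keys <- function(store) {
  names(jsonlite::read_json(file.path(store, "index.json"),
                            simplifyVector = FALSE))
}

#' Write / read an epoched EEG container
#'
#' Layout: `meta.json` (`fs`, `n_epochs`, `n_samples`, `unit`) plus
#' `data.bin`, float64 little-endian, epochs stored row after row.
#'
#' @param rec An [epoched_recording()] (or plain matrix with `fs`).
#' @param dir Container directory.
#' @param fs Sampling rate, required when `rec` is a plain matrix.
#' @return `write_eeg` returns `dir` invisibly; `read_eeg` an
#'   `epoched_recording`.
#' @export
write_eeg <- function(rec, dir, fs = NULL) {
  if (inherits(rec, "epoched_recording")) {
    y <- rec$y; fs <- rec$fs
  } else {
    y <- as.matrix(rec)
    if (is.null(fs)) stop("fs required for a plain matrix")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(fs = fs, n_epochs = nrow(y), n_samples = ncol(y),
         unit = "microvolt"),
    file.path(dir, "meta.json"), auto_unbox = TRUE)
  con <- file(file.path(dir, "data.bin"), "wb")
  writeBin(as.numeric(t(y)), con, 8, endian = "little")
  close(con)
  invisible(dir)
}

#' @rdname write_eeg
#' @export
read_eeg <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  con <- file(file.path(dir, "data.bin"), "rb")
  x <- readBin(con, "double", meta$n_epochs * meta$n_samples, 8,
               endian = "little")
  close(con)
  epoched_recording(matrix(x, nrow = meta$n_epochs, byrow = TRUE),
                    fs = meta$fs)
}
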