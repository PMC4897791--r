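#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for mono or multi-channel 16-bit (or 8/32-bit
#' integer) PCM files. Multi-channel input is mixed down by averaging.
#'
#' @param path Path to a `.wav` file.
#' @return A `rumble_wave` list with `samples` (numeric in \[-1, 1\]) and
#'   `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "raw", size)
    } else if (identical(id, "data")) {
      dat <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stop("missing fmt/data chunk in ", path)
  u16 <- function(r, off) sum(as.integer(r[off + 1:2]) * c(1, 256))
  u32 <- function(r, off) sum(as.numeric(r[off + 1:4]) * 256^(0:3))
  n_chan <- u16(fmt, 2)
  rate <- u32(fmt, 4)
  bits <- u16(fmt, 14)
  if (!bits %in% c(8L, 16L, 32L)) stop("unsupported bit depth: ", bits)
  if (bits == 8L) {
    x <- (as.integer(dat) - 128) / 127
  } else {
    # symmetric full-scale so a write/read cycle is bit-exact
    x <- readBin(dat, "integer", length(dat) / (bits / 8), bits / 8,
                 signed = TRUE, endian = "little") / (2^(bits - 1) - 1)
  }
  if (n_chan > 1L) x <- colMeans(matrix(x, nrow = n_chan))
  structure(list(samples = x, sample_rate = rate), class = "rumble_wave")
}

#' Write a PCM WAV file
#'
#' Writes a mono 16-bit PCM RIFF/WAVE file. Samples are clipped to
#' \[-1, 1\] and quantized symmetrically so that a read/write round trip
#' of already-quantized data is bit-exact.
#'
#' @param wave A `rumble_wave` (or list with `samples`, `sample_rate`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(wave, path) {
  x <- pmin(1, pmax(-1, wave$samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  fs <- as.integer(wave$sample_rate)
  con <- file(path, "wb")
  on.exit(close(con))
  wch <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  w32 <- function(v) writeBin(as.integer(v), con, 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, 2, endian = "little")
  wch("RIFF"); w32(36 + 2 * n); wch("WAVE")
  wch("fmt "); w32(16); w16(1); w16(1); w32(fs); w32(fs * 2); w16(2); w16(16)
  wch("data"); w32(2 * n)
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

#' Read and validate a call annotation table
#'
#' Reads a CSV with one row per segmented call (`call_id`, `file`,
#' `t_start_s`, `t_end_s`, `individual`, `maturity_group`) and checks it
#' against the audio files: IDs non-empty, files present, segment times
#' within each file's duration.
#'
#' @param path Path to the annotation CSV.
#' @param wav_dir Directory holding the WAV files named in `file`; set
#'   `NULL` to skip audio checks.
#' @return The validated annotation data frame.
#' @export
read_annotations <- function(path, wav_dir = dirname(path)) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("call_id", "file", "t_start_s", "t_end_s", "individual",
            "maturity_group")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(!nzchar(ann$individual)) || anyNA(ann$individual))
    stop("empty individual IDs in annotation table")
  if (any(ann$t_end_s <= ann$t_start_s))
    stop("segment end must exceed segment start")
  if (!is.null(wav_dir)) {
    for (i in seq_len(nrow(ann))) {
      f <- file.path(wav_dir, ann$file[i])
      if (!file.exists(f)) stop("missing audio file: ", f)
      w <- read_wav(f)
      dur <- length(w$samples) / w$sample_rate
      if (ann$t_end_s[i] > dur + 1e-6)
        stop("segment for ", ann$call_id[i], " exceeds file duration")
    }
  }
  ann
}

#' Write a per-call feature table as CSV
#'
#' @param features Data frame, one row per call.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
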