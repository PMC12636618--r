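# File I/O: minimal RIFF WAV reader/writer (PCM 16/24/32-bit and IEEE
# float32), YAML configuration with validation, CSV trial tables, and run
# manifests.

#' Read a WAV file
#'
#' Supports PCM 16/24/32-bit and IEEE float32, mono or stereo.
#'
#' @param path file path.
#' @return an [audio_clip()] with float waveform in `[-1, 1]`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (id == "data") {
      data <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("malformed WAV: ", path)
  bytes <- fmt$bits / 8
  n <- length(data) / bytes
  x <- if (fmt$audio_format == 3 && fmt$bits == 32) {
    readBin(data, "double", n, 4, endian = "little")
  } else if (fmt$audio_format == 1 && fmt$bits == 16) {
    readBin(data, "integer", n, 2, signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 1 && fmt$bits == 32) {
    readBin(data, "integer", n, 4, endian = "little") / 2147483648
  } else if (fmt$audio_format == 1 && fmt$bits == 24) {
    m <- matrix(as.integer(data), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v[v >= 8388608] <- v[v >= 8388608] - 16777216
    v / 8388608
  } else stop("unsupported WAV encoding (format ", fmt$audio_format,
              ", ", fmt$bits, " bits)")
  if (fmt$channels == 2)
    x <- matrix(x, ncol = 2, byrow = TRUE)
  audio_clip(x, fmt$rate)
}

#' Write a WAV file
#'
#' @param clip an [audio_clip()].
#' @param path file path.
#' @param format `"float32"` (default, lossless for analysis signals) or
#'   `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  x <- as.matrix(clip$waveform)
  nch <- ncol(x); nsamp <- nrow(x)
  inter <- as.numeric(t(x))           # interleave channels
  bytes <- if (format == "float32") 4L else 2L
  data_size <- length(inter) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(if (format == "float32") 3L else 1L, con, 2, endian = "little")
  writeBin(as.integer(nch), con, 2, endian = "little")
  writeBin(as.integer(clip$rate), con, 4, endian = "little")
  writeBin(as.integer(clip$rate * nch * bytes), con, 4, endian = "little")
  writeBin(as.integer(nch * bytes), con, 2, endian = "little")
  writeBin(as.integer(8 * bytes), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (format == "float32") {
    writeBin(inter, con, 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmin(pmax(inter, -1), 1) * 32767)), con, 2,
             endian = "little")
  }
  invisible(path)
}

#' Read a YAML configuration file
#'
#' @param path YAML file path.
#' @param required character vector of top-level keys that must be present.
#' @return named list.
#' @export
read_config <- function(path, required = character()) {
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("config parse error in ", path,
                                           ": ", conditionMessage(e)))
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config ", path, " is missing required keys: ",
         paste(missing, collapse = ", "))
  cfg
}

#' Write a trial table as CSV
#'
#' @param tab data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seeds, package version, and digests
#' of the input/output files of a run; one manifest per CLI invocation.
#'
#' @param path output JSON path.
#' @param config configuration list.
#' @param seed top-level seed.
#' @param files character vector of file paths to digest.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config = list(), seed = NA, files = character()) {
  digests <- if (length(files)) as.list(tools::md5sum(files)) else list()
  man <- list(package = "percept",
              version = as.character(utils::packageVersion("percept")),
              seed = seed, config = config, file_digests = digests)
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, pretty = TRUE, digits = NA),
             path)
  invisible(man)
}
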