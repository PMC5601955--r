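# On-disk session bundles: session.json (metadata) + signal.csv | signal.f32.
# The binary dialect is little-endian float32, column-major; it round-trips
# quantized sessions bit-exactly (every mid-tread level k * 2^-m * fullscale is
# exactly representable in binary32). CSV is written with 17 significant
# digits, so it round-trips doubles to printed precision.

SESSION_FORMAT_VERSION <- "1.0"

#' Write an EMG session bundle to disk
#'
#' A bundle is a directory holding `session.json` (protocol, contraction
#' ranges, provenance, format version) plus one signal file: `signal.csv`
#' (one column per channel, header row, 17 significant digits) or
#' `signal.f32` (little-endian 32-bit float, column-major).
#'
#' @param session an `emg_session`
#' @param path directory to create/overwrite
#' @param dialect `"f32"` (default, exact for quantized signals) or `"csv"`
#' @return `path`, invisibly
#' @seealso [read_session()]
#' @export
write_session <- function(session, path, dialect = c("f32", "csv")) {
  dialect <- match.arg(dialect)
  validate_session(session)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory: ", path, call. = FALSE)

  sig <- session$signal
  signal_file <- if (dialect == "f32") "signal.f32" else "signal.csv"
  meta <- list(
    format_version = SESSION_FORMAT_VERSION,
    protocol = unclass(session$protocol),
    ranges = session$ranges,
    provenance = session$provenance,
    signal = list(file = signal_file, dialect = dialect,
                  n_samples = nrow(sig), n_channels = ncol(sig),
                  storage_order = "column-major")
  )
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (dialect == "f32") {
    con <- file(file.path(path, signal_file), "wb")
    on.exit(close(con))
    writeBin(as.numeric(sig), con, size = 4, endian = "little")
  } else {
    txt <- apply(sig, 2, function(col) formatC(col, digits = 17, format = "g"))
    if (!is.matrix(txt)) txt <- matrix(txt, nrow = nrow(sig))
    colnames(txt) <- sprintf("ch%02d", seq_len(ncol(sig)))
    utils::write.csv(txt, file.path(path, signal_file), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' Read an EMG session bundle
#'
#' Parses `session.json`, loads the signal file named there, and validates
#' the reconstructed session. Shape mismatches between metadata and the
#' signal file (including truncated binary files) raise explicit errors.
#'
#' @param path bundle directory written by [write_session()]
#' @return an `emg_session`
#' @export
read_session <- function(path) {
  meta_path <- file.path(path, "session.json")
  if (!file.exists(meta_path)) stop("no session.json in ", path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format_version, SESSION_FORMAT_VERSION))
    stop("unknown session format version: ",
         meta$format_version %||% "<missing>", call. = FALSE)
  pr <- meta$protocol
  protocol <- protocol_spec(pr$sampling_rate, pr$n_channels, pr$bit_depth,
                            pr$movements, pr$n_repetitions, pr$contraction_s,
                            pr$rest_s, pr$gain)
  ns <- meta$signal$n_samples
  nc <- meta$signal$n_channels
  sig_path <- file.path(path, meta$signal$file)
  if (!file.exists(sig_path)) stop("missing signal file: ", sig_path, call. = FALSE)
  if (identical(meta$signal$dialect, "f32")) {
    expected <- ns * nc
    con <- file(sig_path, "rb")
    on.exit(close(con))
    vals <- readBin(con, what = "numeric", n = expected + 1, size = 4,
                    endian = "little")
    if (length(vals) != expected)
      stop(sprintf("signal file holds %d values; metadata declares %d x %d = %d (truncated or corrupt bundle)",
                   length(vals), ns, nc, expected), call. = FALSE)
    sig <- matrix(vals, nrow = ns, ncol = nc)
  } else if (identical(meta$signal$dialect, "csv")) {
    df <- utils::read.csv(sig_path)
    if (ncol(df) != nc)
      stop(sprintf("signal.csv has %d columns; metadata declares %d channels",
                   ncol(df), nc), call. = FALSE)
    if (nrow(df) != ns)
      stop(sprintf("signal.csv has %d rows; metadata declares %d samples (truncated?)",
                   nrow(df), ns), call. = FALSE)
    sig <- as.matrix(df)
    dimnames(sig) <- NULL
    storage.mode(sig) <- "double"
  } else {
    stop("unknown signal dialect: ", meta$signal$dialect, call. = FALSE)
  }
  ranges <- as.data.frame(meta$ranges)
  emg_session(protocol, sig, ranges, provenance = meta$provenance %||% "imported")
}
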