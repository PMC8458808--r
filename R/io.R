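# Session interchange: EDF for the EEG channel, a `time_s,temp_c` CSV
# sidecar for the temperature channel, and a YAML study manifest.
#
# EDF (European Data Format) stores 16-bit integers with a per-signal
# affine physical calibration; the reader/writer here covers the plain EDF
# subset (no annotations), enough for single- or multi-channel continuous
# recordings with an integer number of samples per 1-s data record.

.pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width, flag = " ")
}

#' Write signals to an EDF file
#'
#' @param x Numeric vector (one channel) or matrix with one column per
#'   channel.
#' @param sampling_rate Sampling rate, Hz; must divide into whole samples
#'   per 1-s record.
#' @param path Output path.
#' @param labels Channel label(s) (<= 16 characters each).
#' @param physical_dim Physical dimension string (default `"uV"`).
#' @param physical_range Length-2 numeric `c(min, max)` declared calibration
#'   range, or `NULL` to use the (slightly widened) data range. A signal
#'   exceeding the declared range is an error: no silent clipping.
#' @return `path`, invisibly.
#' @export
write_edf <- function(x, sampling_rate, path, labels = "EEG",
                      physical_dim = "uV", physical_range = NULL) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  ns <- ncol(x)
  labels <- rep_len(labels, ns)
  spr <- round(sampling_rate)
  if (abs(spr - sampling_rate) > 1e-9)
    stop("`sampling_rate` must be an integer number of samples per second",
         call. = FALSE)
  n <- nrow(x)
  n_rec <- ceiling(n / spr)
  if (n_rec * spr > n)  # pad the trailing partial record with the last value
    x <- rbind(x, matrix(rep(x[n, ], each = n_rec * spr - n), ncol = ns))
  if (is.null(physical_range)) {
    m <- max(abs(x), 1e-6)
    physical_range <- c(-m, m) * 1.0001
  }
  if (any(x < physical_range[1]) || any(x > physical_range[2]))
    stop("signal exceeds the declared physical range; refusing to clip",
         call. = FALSE)
  dmin <- -32768; dmax <- 32767

  con <- tryCatch(suppressWarnings(file(path, "wb")),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing", call. = FALSE))
  on.exit(close(con))
  hdr <- paste0(.pad_field("0", 8),
                .pad_field("X", 80),
                .pad_field("Startdate X thermoEEG", 80),
                .pad_field("01.01.21", 8),
                .pad_field("00.00.00", 8),
                .pad_field(256 * (ns + 1), 8),
                .pad_field("", 44),
                .pad_field(n_rec, 8),
                .pad_field(1, 8),
                .pad_field(ns, 4))
  field <- function(vals, width)
    paste0(vapply(vals, .pad_field, "", width = width), collapse = "")
  hdr <- paste0(hdr,
                field(labels, 16),
                field(rep("", ns), 80),
                field(rep(physical_dim, ns), 8),
                field(rep(format(physical_range[1], digits = 7), ns), 8),
                field(rep(format(physical_range[2], digits = 7), ns), 8),
                field(rep(dmin, ns), 8),
                field(rep(dmax, ns), 8),
                field(rep("", ns), 80),
                field(rep(spr, ns), 8),
                field(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)

  scale <- (dmax - dmin) / (physical_range[2] - physical_range[1])
  dig <- round((x - physical_range[1]) * scale + dmin)
  # interleave: per record, all samples of signal 1, then signal 2, ...
  out <- integer(n_rec * spr * ns)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * spr + 1):(r * spr)
    for (j in seq_len(ns)) {
      out[(pos + 1):(pos + spr)] <- dig[rows, j]
      pos <- pos + spr
    }
  }
  writeBin(as.integer(out), con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' @param path Path to a plain EDF file.
#' @return A list with `signals` (list of per-channel lists: `label`,
#'   `physical_dim`, `sampling_rate`, `physical_range`, `data` in physical
#'   units), `n_records` and `record_duration`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: no signals",
                                call. = FALSE)
  rdn <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdn(16); rdn(80)
  dims <- rdn(8)
  pmin <- as.numeric(rdn(8)); pmax <- as.numeric(rdn(8))
  dmin <- as.numeric(rdn(8)); dmax <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8))
  rdn(32)

  total <- sum(spr) * n_rec
  raw <- readBin(con, integer(), n = total, size = 2, signed = TRUE,
                 endian = "little")
  if (length(raw) < total) stop("truncated EDF data section", call. = FALSE)
  signals <- vector("list", ns)
  offs <- c(0, cumsum(spr))
  rec_len <- sum(spr)
  for (j in seq_len(ns)) {
    idx <- as.vector(outer((offs[j] + 1):offs[j + 1],
                           (seq_len(n_rec) - 1) * rec_len, `+`))
    d <- raw[idx]
    phys <- pmin[j] + (d - dmin[j]) * (pmax[j] - pmin[j]) / (dmax[j] - dmin[j])
    signals[[j]] <- list(label = labels[j], physical_dim = dims[j],
                         sampling_rate = spr[j] / rec_dur,
                         physical_range = c(pmin[j], pmax[j]),
                         data = phys)
  }
  list(signals = signals, n_records = n_rec, record_duration = rec_dur)
}

#' Write a temperature channel as CSV
#'
#' @param profile A `temperature_profile` or any data frame with `time_s`
#'   and `temp_c` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_temperature_csv <- function(profile, path) {
  df <- data.frame(time_s = profile$time_s, temp_c = profile$temp_c)
  ok <- tryCatch({
    suppressWarnings(utils::write.csv(df, path, row.names = FALSE,
                                      quote = FALSE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write temperature CSV to '", path, "'",
                call. = FALSE)
  invisible(path)
}

#' Read a temperature CSV (`time_s,temp_c`)
#'
#' @param path Path to a CSV with header exactly `time_s,temp_c`.
#' @return A data frame with numeric `time_s` and `temp_c`.
#' @export
read_temperature_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "time_s,temp_c")
    stop("malformed temperature CSV '", path,
         "': line 1 must be the header 'time_s,temp_c'", call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  tn <- suppressWarnings(as.numeric(df$time_s))
  cn <- suppressWarnings(as.numeric(df$temp_c))
  bad <- which(!is.finite(tn) | !is.finite(cn))
  if (length(bad))
    stop("malformed temperature CSV '", path, "': parse error at line ",
         bad[1] + 1L, call. = FALSE)
  data.frame(time_s = tn, temp_c = cn)
}

#' Write a session recording to disk (EDF + temperature CSV)
#'
#' @param rec A `session_recording`.
#' @param eeg_path Output EDF path.
#' @param temp_path Output CSV path.
#' @param physical_range Declared EDF calibration range; `NULL` fits the
#'   data.
#' @return Invisibly, a list with the two paths.
#' @export
write_session <- function(rec, eeg_path, temp_path, physical_range = NULL) {
  stopifnot(inherits(rec, "session_recording"))
  write_edf(rec$eeg, rec$sampling_rate, eeg_path,
            labels = paste0("EEG ", rec$session_id),
            physical_range = physical_range)
  write_temperature_csv(rec$temperature, temp_path)
  invisible(list(eeg_path = eeg_path, temp_path = temp_path))
}

#' Read a session recording from disk
#'
#' Loads the EEG from an EDF file (first channel, with a warning if more
#' are present) and the temperature sidecar CSV, and validates their
#' alignment: the temperature channel must span the EEG duration to within
#' one epoch length.
#'
#' @param eeg_path EDF path.
#' @param temp_path Temperature CSV path.
#' @param session_id Identifier; defaults to the EDF file name.
#' @param epoch_length Alignment tolerance, seconds (default 5).
#' @return A `session_recording`. The attached `validation` attribute
#'   records the EEG duration, temperature span and largest temperature
#'   sampling gap.
#' @export
read_session <- function(eeg_path, temp_path, session_id = NULL,
                         epoch_length = 5) {
  edf <- read_edf(eeg_path)
  if (length(edf$signals) > 1)
    warning("EDF has ", length(edf$signals),
            " channels; using the first as the EEG channel")
  sig <- edf$signals[[1]]
  temp <- read_temperature_csv(temp_path)
  eeg_dur <- length(sig$data) / sig$sampling_rate
  span <- max(temp$time_s) - min(temp$time_s)
  if (min(temp$time_s) > epoch_length ||
      max(temp$time_s) < eeg_dur - epoch_length)
    stop(sprintf(paste0("temperature channel [%g, %g] s does not cover the ",
                        "EEG span [0, %g] s to within one epoch"),
                 min(temp$time_s), max(temp$time_s), eeg_dur), call. = FALSE)
  profile <- data.frame(time_s = temp$time_s, temp_c = temp$temp_c,
                        phase = "unknown", stringsAsFactors = FALSE)
  class(profile) <- c("temperature_profile", "data.frame")
  rec <- structure(list(eeg = sig$data, sampling_rate = sig$sampling_rate,
                        temperature = profile,
                        session_id = session_id %||%
                          sub("\\.edf$", "", basename(eeg_path)),
                        seed = NA_integer_, config = NULL),
                   class = "session_recording")
  attr(rec, "validation") <- list(
    eeg_duration_s = eeg_dur, temp_span_s = span,
    max_temp_gap_s = if (nrow(temp) > 1) max(diff(temp$time_s)) else NA_real_)
  rec
}

#' Write a study manifest (YAML)
#'
#' @param sessions Data frame with columns `session_id`, `eeg_path`,
#'   `temp_path`, `seed`.
#' @param params A [study_params()] list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(sessions, params, path) {
  stopifnot(all(c("session_id", "eeg_path", "temp_path") %in%
                  names(sessions)))
  if (anyDuplicated(sessions$session_id))
    stop("session ids must be unique", call. = FALSE)
  obj <- list(sessions = lapply(seq_len(nrow(sessions)), function(i)
                as.list(sessions[i, ])),
              params = params[setdiff(names(params), "bands")])
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a study manifest (YAML)
#'
#' @param path Manifest path.
#' @param check_files Verify that the referenced files exist (default TRUE).
#' @return A list of class `study_manifest` with `sessions` (data frame) and
#'   `params`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  obj <- yaml::read_yaml(path)
  sessions <- do.call(rbind, lapply(obj$sessions, as.data.frame))
  if (anyDuplicated(sessions$session_id))
    stop("session ids must be unique", call. = FALSE)
  if (check_files) {
    missing <- c(sessions$eeg_path[!file.exists(sessions$eeg_path)],
                 sessions$temp_path[!file.exists(sessions$temp_path)])
    if (length(missing))
      stop("manifest references missing files: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- do.call(study_params, obj$params %||% list())
  structure(list(sessions = sessions, params = p), class = "study_manifest")
}
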