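# ---- minimal standard EDF (16-bit) reader/writer ----
# Fixed-layout ASCII header (256 bytes + 256 per signal, field-major),
# then data records of little-endian int16 samples, one second per
# record here. Physical/digital scaling follows the EDF linear mapping;
# round-trip error is bounded by half a quantization step.

# format a number into an 8-char EDF ASCII field
.edf_num <- function(v) {
  s <- sprintf("%.8g", v)
  if (nchar(s) > 8) s <- sprintf("%.4g", v)
  if (nchar(s) > 8) s <- sprintf("%.2g", v)
  s
}
.edf_field <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)  # left-justified, space padded
}

#' Write a recording to EDF
#'
#' Standard 16-bit EDF with 1-s data records. Each channel's physical
#' range is set symmetrically from its extreme value, so the
#' quantization step is `2*max(abs(x))/65535`. A YAML sidecar
#' (`<path>.yaml`) records the light-schedule anchor (`start_zt`,
#' `lights_on_zt = 0`) since EDF clock times do not carry the ZT
#' convention.
#'
#' @param rec a [recording]; `fs` must be a positive integer.
#' @param path output file path (`.edf`).
#' @param sidecar write the YAML light-schedule sidecar.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, sidecar = TRUE) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  ns <- length(rec$channels)
  n_rec <- n_samples(rec) %/% fs
  if (n_rec < 1) stop("recording shorter than one 1-s data record")
  pm <- vapply(rec$channels, function(x) {
    m <- max(abs(range(x)), 1e-9)
    as.numeric(.edf_num(m * 1.0001))  # header value must round-trip
  }, numeric(1))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_field("0", 8), .edf_field("synthetic animal", 80),
    .edf_field("somnus synthetic recording", 80),
    .edf_field("01.01.00", 8), .edf_field("00.00.00", 8),
    .edf_field(256 * (ns + 1), 8), .edf_field("", 44),
    .edf_field(n_rec, 8), .edf_field(1, 8), .edf_field(ns, 4),
    paste(vapply(names(rec$channels), .edf_field, "", width = 16),
          collapse = ""),
    paste(rep(.edf_field("synthetic", 80), ns), collapse = ""),
    paste(rep(.edf_field("au", 8), ns), collapse = ""),
    paste(vapply(-pm, function(v) .edf_field(.edf_num(v), 8), ""),
          collapse = ""),
    paste(vapply(pm, function(v) .edf_field(.edf_num(v), 8), ""),
          collapse = ""),
    paste(rep(.edf_field(-32768, 8), ns), collapse = ""),
    paste(rep(.edf_field(32767, 8), ns), collapse = ""),
    paste(rep(.edf_field("", 80), ns), collapse = ""),
    paste(rep(.edf_field(fs, 8), ns), collapse = ""),
    paste(rep(.edf_field("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  # digital samples, record-major: [record][signal][sample]
  dig <- lapply(seq_len(ns), function(i) {
    x <- rec$channels[[i]][1:(n_rec * fs)]
    d <- round((x + pm[i]) * 65535 / (2 * pm[i])) - 32768
    as.integer(pmin(32767, pmax(-32768, d)))
  })
  m <- matrix(0L, nrow = fs * ns, ncol = n_rec)
  for (i in seq_len(ns))
    m[((i - 1) * fs + 1):(i * fs), ] <- matrix(dig[[i]], nrow = fs)
  writeBin(as.vector(m), con, size = 2, endian = "little")
  if (sidecar)
    yaml::write_yaml(list(start_zt = rec$start_zt, lights_on_zt = 0,
                          fs = fs), paste0(path, ".yaml"))
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path EDF file path. If `<path>.yaml` exists it supplies the ZT
#'   anchor (`start_zt`); otherwise `start_zt = 0`.
#' @param require_channels channel names that must be present (default
#'   the EEG1/EEG2/EMG montage; set `NULL` to accept any).
#' @return a [recording].
#' @export
read_recording <- function(path, require_channels = c("EEG1", "EEG2", "EMG")) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  vraw <- readBin(con, "raw", 8)
  if (length(vraw) < 8 || vraw[1] != charToRaw("0") ||
      !all(vraw[-1] == charToRaw(" ")))
    stop("not an EDF file (bad version field)")
  rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes (recomputed from ns)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16); fld(80); fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (length(unique(spr / rec_dur)) != 1L)
    stop("inconsistent sampling rate across channels")
  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                 signed = TRUE, endian = "little")
  m <- matrix(raw, nrow = sum(spr))
  offs <- cumsum(c(0, spr))
  channels <- lapply(seq_len(ns), function(i) {
    d <- as.vector(m[(offs[i] + 1):offs[i + 1], ])
    (d - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i]) + pmin_[i]
  })
  names(channels) <- labels
  if (!is.null(require_channels) &&
      !all(require_channels %in% labels))
    stop("missing channel(s): ",
         paste(setdiff(require_channels, labels), collapse = ", "))
  start_zt <- 0
  sc <- paste0(path, ".yaml")
  if (file.exists(sc)) {
    y <- yaml::read_yaml(sc)
    if (!is.null(y$start_zt)) start_zt <- y$start_zt
  }
  recording(channels, fs = spr[1] / rec_dur, start_zt = start_zt)
}

#' EDF quantization step of a written channel
#'
#' `(phys_max - phys_min) / (dig_max - dig_min)`; round-trip error is at
#' most half this step.
#' @param x the channel data as written.
#' @export
edf_quantization_step <- function(x) {
  pm <- as.numeric(.edf_num(max(abs(range(x)), 1e-9) * 1.0001))
  2 * pm / 65535
}
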