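# Minimal EDF (16-bit European Data Format) reader/writer, enough for
# CHB-MIT-style continuous EEG: one fixed sampling rate, 1-s data records,
# int16 samples with per-channel physical scaling. Seizure annotations use
# a plain-text side-car "<file>.seizures.txt" (one "onset<TAB>offset" pair
# per line, seconds), which mirrors how CHB-MIT ships its labels outside
# the EDF proper.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording as EDF with an annotation side-car
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path; annotations go to
#'   `paste0(path, ".seizures.txt")` when the recording has seizures.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  N <- nrow(rec$signal)
  n <- ncol(rec$signal)
  nrec <- ceiling(n / fs)
  pad <- nrec * fs - n
  sig <- if (pad > 0) cbind(rec$signal, matrix(0, N, pad)) else rec$signal

  pmin_ <- apply(sig, 1L, min)
  pmax_ <- apply(sig, 1L, max)
  same <- pmax_ <= pmin_
  pmax_[same] <- pmin_[same] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8L),
    .edf_pad(rec$subject_id, 80L),
    .edf_pad("hdseizure synthetic", 80L),
    .edf_pad("01.01.20", 8L), .edf_pad("00.00.00", 8L),
    .edf_pad(256L * (1L + N), 8L),
    .edf_pad(sprintf("NS=%d", n), 44L),       # true sample count (non-standard)
    .edf_pad(nrec, 8L), .edf_pad(1L, 8L), .edf_pad(N, 4L))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, .edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  field(rec$channels, 16L)
  field(rep("synthetic EEG", N), 80L)
  field(rep("uV", N), 8L)
  field(sprintf("%.8g", pmin_), 8L)
  field(sprintf("%.8g", pmax_), 8L)
  field(rep(dmin, N), 8L)
  field(rep(dmax, N), 8L)
  field(rep("", N), 80L)
  field(rep(fs, N), 8L)
  field(rep("", N), 32L)

  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    block <- sig[, cols, drop = FALSE]
    dig <- round((block - pmin_) / scale) + dmin
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  }
  if (nrow(rec$seizures) > 0L)
    writeLines(sprintf("%.6f\t%.6f", rec$seizures$onset,
                       rec$seizures$offset),
               paste0(path, ".seizures.txt"))
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads a 16-bit EDF file written by [write_edf()] or any EDF with a
#' uniform sampling rate. If `channels` is given, exactly those channels
#' are returned in that (canonical) order regardless of their order in the
#' file; missing channels raise an error naming every absentee. A
#' `<path>.seizures.txt` side-car, when present, populates the seizure
#' annotations.
#'
#' @param path EDF file path.
#' @param channels Optional character vector of required channel labels
#'   (e.g. [chbmit_montage()]).
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8L)                                   # version
  subject_id <- rd(80L)
  rd(80L); rd(8L); rd(8L); rd(8L)
  reserved <- rd(44L)
  nrec <- as.integer(rd(8L))
  recdur <- as.numeric(rd(8L))
  N <- as.integer(rd(4L))
  rdn <- function(width) vapply(seq_len(N), function(i) rd(width), "")
  labels <- rdn(16L)
  rdn(80L); rdn(8L)
  pmin_ <- as.numeric(rdn(8L))
  pmax_ <- as.numeric(rdn(8L))
  dmin <- as.numeric(rdn(8L))
  dmax <- as.numeric(rdn(8L))
  rdn(80L)
  spr <- as.integer(rdn(8L))               # samples per record per channel
  rdn(32L)
  if (length(unique(spr)) != 1L)
    stop("mixed sampling rates are not supported", call. = FALSE)
  fs <- spr[1L] / recdur
  total <- nrec * spr[1L]
  sig <- matrix(0, nrow = N, ncol = total)
  for (r in seq_len(nrec)) {
    raw <- readBin(con, "integer", n = N * spr[1L], size = 2L,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1L], ncol = N)
    cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    sig[, cols] <- t(block)
  }
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  sig <- sig * scale + (pmin_ - dmin * scale)
  ntrue <- if (grepl("^NS=", reserved))
    as.integer(sub("^NS=", "", reserved)) else total
  sig <- sig[, seq_len(min(ntrue, total)), drop = FALSE]

  if (!is.null(channels)) {
    missing <- setdiff(channels, labels)
    if (length(missing))
      stop("EDF is missing required channel(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    sig <- sig[match(channels, labels), , drop = FALSE]
    labels <- channels
  }
  ann_path <- paste0(path, ".seizures.txt")
  seiz <- if (file.exists(ann_path)) {
    tab <- utils::read.table(ann_path, col.names = c("onset", "offset"))
    tab
  } else NULL
  eeg_recording(sig, fs, seizures = seiz, subject_id = subject_id,
                channels = labels)
}
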