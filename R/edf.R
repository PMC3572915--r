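## Minimal European Data Format (EDF) I/O for continuous recordings.
##
## EDF stores an ASCII header (256 bytes global + 256 per signal) and
## data records of little-endian 16-bit integers, mapped linearly from
## physical to digital range per signal.  One-second records are used;
## the recording is truncated to a whole number of seconds on write.

.pad <- function(x, n) {
  s <- substr(as.character(x), 1, n)
  formatC(s, width = n, flag = "-")
}

#' Write a recording to an EDF file
#'
#' @param rec A `dmn_recording` (microvolt channels x time matrix).
#' @param path Output file path.
#' @return `path`, invisibly.  Values are quantised to the 16-bit EDF
#'   grid over each channel's physical range.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "dmn_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$samples)
  nrec <- floor(ncol(rec$samples) / fs)
  if (nrec < 1) stop("recording shorter than one EDF record (1 s)")
  x <- rec$samples[, seq_len(nrec * fs), drop = FALSE]
  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  same <- pmax_ - pmin_ < 1e-9
  pmax_[same] <- pmin_[same] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .pad("0", 8), .pad(rec$subject_id, 80),
    .pad(paste("condition", rec$condition), 80),
    .pad("01.01.26", 8), .pad("00.00.00", 8),
    .pad(256 * (1 + ns), 8), .pad("", 44),
    .pad(nrec, 8), .pad(1, 8), .pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    .pad(rec$channel_names, 16),
    .pad(rep("AgAgCl electrode", ns), 80),
    .pad(rep("uV", ns), 8),
    .pad(formatC(pmin_, format = "g", digits = 7), 8),
    .pad(formatC(pmax_, format = "g", digits = 7), 8),
    .pad(rep(dmin, ns), 8), .pad(rep(dmax, ns), 8),
    .pad(rep("", ns), 80), .pad(rep(fs, ns), 8), .pad(rep("", ns), 32))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  ## re-read the rounded physical limits so scaling matches the header
  pmin_h <- as.numeric(formatC(pmin_, format = "g", digits = 7))
  pmax_h <- as.numeric(formatC(pmax_, format = "g", digits = 7))
  gain <- (dmax - dmin) / (pmax_h - pmin_h)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((x[ch, idx] - pmin_h[ch]) * gain[ch] + dmin)
      writeBin(as.integer(pmax(dmin, pmin(dmax, dig))), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf] (or any plain continuous EDF)
#'
#' @param path EDF file path.
#' @return A `dmn_recording` with microvolt samples.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)
  subject_id <- trimws(rd(80))
  recinfo <- trimws(rd(80))
  rd(8); rd(8); rd(8); rd(44)
  nrec <- as.integer(trimws(rd(8)))
  dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  labs <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)   # transducer
  for (i in seq_len(ns)) rd(8)    # units
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) trimws(rd(8)), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) trimws(rd(8)), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) trimws(rd(8)), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) trimws(rd(8)), ""))
  for (i in seq_len(ns)) rd(80)   # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) trimws(rd(8)), ""))
  for (i in seq_len(ns)) rd(32)
  fs <- spr[1] / dur
  out <- matrix(0, ns, nrec * spr[1])
  for (r in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2,
                     signed = TRUE, endian = "little")
      phys <- (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) /
              (dmax[ch] - dmin[ch]) + pmin_[ch]
      out[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
    }
  }
  condition <- if (grepl("eyes_open", recinfo)) "eyes_open"
               else "eyes_closed"
  new_recording(out, fs, subject_id = subject_id,
                channel_names = labs, condition = condition)
}
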