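#' Construct a recording object
#'
#' @param samples Channels x time numeric matrix, microvolts.
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier.
#' @param channel_names Optional channel labels (defaults to rownames).
#' @param condition `"eyes_closed"` or `"eyes_open"`.
#' @return Object of class `dmn_recording`.
#' @export
new_recording <- function(samples, fs, subject_id = "S01",
                          channel_names = rownames(samples),
                          condition = c("eyes_closed", "eyes_open")) {
  condition <- match.arg(condition)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("samples must be a channels x time numeric matrix")
  if (anyNA(samples)) stop("samples contain NA")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(samples)))
  rownames(samples) <- channel_names
  structure(list(subject_id = subject_id, samples = samples, fs = fs,
                 channel_names = channel_names, condition = condition),
            class = "dmn_recording")
}

#' Cut a recording into fixed-length epochs
#'
#' Consecutive windows of `epoch_len_s` seconds with fractional overlap;
#' a partial tail window is dropped.
#'
#' @param rec A `dmn_recording`.
#' @param epoch_len_s Epoch length in seconds (default 1.7).
#' @param overlap_frac Fraction of overlap between consecutive epochs in
#'   \[0, 1) (default 0.5).
#' @return Object of class `dmn_epochs`: `epochs` (n_epochs x channels x
#'   samples array), `fs`, `epoch_len_s`, `rejected_count`.
#' @examples
#' rec <- new_recording(matrix(rnorm(2 * 3000), 2), fs = 300)
#' es <- segment_epochs(rec, 1.7, 0)
#' dim(es$epochs)
#' @export
segment_epochs <- function(rec, epoch_len_s = 1.7, overlap_frac = 0.5) {
  stopifnot(inherits(rec, "dmn_recording"))
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must be in [0, 1)")
  L <- round(epoch_len_s * rec$fs)
  N <- ncol(rec$samples)
  if (N < L) stop("recording shorter than one epoch")
  step <- max(1L, round(L * (1 - overlap_frac)))
  starts <- seq.int(1L, N - L + 1L, by = step)
  nch <- nrow(rec$samples)
  ep <- array(0, dim = c(length(starts), nch, L))
  for (k in seq_along(starts))
    ep[k, , ] <- rec$samples[, starts[k]:(starts[k] + L - 1L)]
  structure(list(epochs = ep, fs = rec$fs, epoch_len_s = epoch_len_s,
                 channel_names = rec$channel_names,
                 subject_id = rec$subject_id, rejected_count = 0L),
            class = "dmn_epochs")
}

#' Remove epochs exceeding an absolute amplitude threshold
#'
#' @param es A `dmn_epochs` object.
#' @param amp_thresh_uv Peak amplitude threshold in microvolts
#'   (default 100).
#' @return The `dmn_epochs` object with offending epochs removed and
#'   `rejected_count` updated.
#' @export
reject_artifact_epochs <- function(es, amp_thresh_uv = 100) {
  stopifnot(inherits(es, "dmn_epochs"))
  if (amp_thresh_uv <= 0) stop("amplitude threshold must be positive")
  peak <- apply(abs(es$epochs), 1, max)
  keep <- peak <= amp_thresh_uv
  if (!any(keep)) stop("all epochs rejected at threshold ",
                       amp_thresh_uv, " uV")
  es$rejected_count <- es$rejected_count + sum(!keep)
  es$epochs <- es$epochs[keep, , , drop = FALSE]
  es
}

# Hann-tapered one-sided FFT of all epochs.
# Returns list(coef = complex array n_epochs x channels x n_bins,
#              freqs, scale) with scale the PSD normalisation so that
# coef*Conj(coef)*scale has units uV^2/Hz.
.epoch_spectra <- function(es) {
  L <- dim(es$epochs)[3]
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))   # Hann taper
  nb <- floor(L / 2) + 1L
  ne <- dim(es$epochs)[1]
  nch <- dim(es$epochs)[2]
  coef <- array(complex(real = 0), dim = c(ne, nch, nb))
  for (k in seq_len(ne)) {
    x <- t(es$epochs[k, , , drop = TRUE])
    if (nch == 1) x <- matrix(es$epochs[k, 1, ], ncol = 1)
    X <- stats::mvfft(x * w)
    coef[k, , ] <- t(X[seq_len(nb), , drop = FALSE])
  }
  freqs <- (seq_len(nb) - 1) / L * es$fs
  scale <- 2 / (es$fs * sum(w^2))
  list(coef = coef, freqs = freqs, scale = scale)
}

# indices of frequency bins whose centre lies in [low, high)
.band_bins <- function(freqs, edges) {
  which(freqs >= edges[1] & freqs < edges[2])
}

#' Band-limited cross-spectral matrices
#'
#' Per epoch, a Hann-tapered discrete Fourier transform is taken; the
#' channels x channels cross-spectral matrix is averaged over epochs and
#' over the frequency bins whose centre lies in \[low, high) Hz, with a
#' power-spectral-density normalisation (uV^2/Hz).  The result is
#' Hermitian positive semidefinite by construction.
#'
#' @param es A `dmn_epochs` object.
#' @param bands Named list of band edges in Hz (default: the five
#'   standard bands in [dmn_constants]).
#' @return Named list of `dmn_cross_spectrum` objects, one per band,
#'   each with `band`, `edges`, `matrix` (complex), `n_epochs_used`.
#' @export
band_cross_spectra <- function(es, bands = dmn_constants$bands) {
  stopifnot(inherits(es, "dmn_epochs"))
  ny <- es$fs / 2
  for (b in names(bands))
    if (bands[[b]][1] <= 0 || bands[[b]][2] > ny)
      stop("band ", b, " outside (0, Nyquist = ", ny, ") Hz")
  sp <- .epoch_spectra(es)
  ne <- dim(sp$coef)[1]
  nch <- dim(sp$coef)[2]
  out <- list()
  for (b in names(bands)) {
    bins <- .band_bins(sp$freqs, bands[[b]])
    if (!length(bins))
      stop("band ", b, " contains no frequency bins at this resolution")
    C <- matrix(complex(real = 0), nch, nch)
    for (k in seq_len(ne)) {
      Xb <- sp$coef[k, , bins, drop = FALSE]
      dim(Xb) <- c(nch, length(bins))
      C <- C + Xb %*% Conj(t(Xb))
    }
    C <- C * sp$scale / (ne * length(bins))
    C <- (C + Conj(t(C))) / 2            # Hermitian to machine precision
    dimnames(C) <- list(es$channel_names, es$channel_names)
    out[[b]] <- structure(list(band = b, edges = bands[[b]], matrix = C,
                               n_epochs_used = ne,
                               subject_id = es$subject_id),
                          class = "dmn_cross_spectrum")
  }
  out
}
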