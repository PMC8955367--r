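# Band definitions, filtering, Welch PSD, between-state tests -----------------

#' Frequency band specification
#'
#' @param name band name.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return object of class `band_spec`.
#' @export
band_spec <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1)
  if (!(low > 0 && high > low))
    stop(sprintf("invalid band '%s': need 0 < low < high (got %g, %g)",
                 name, low, high), call. = FALSE)
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' Default EEG frequency bands
#'
#' theta 3-7, alpha 7-13, beta 13-30, gamma 30-60 Hz.
#'
#' @param names optional subset of band names to return.
#' @return named list of [band_spec()] objects.
#' @export
default_bands <- function(names = c("theta", "alpha", "beta", "gamma")) {
  all <- list(theta = band_spec("theta", 3, 7),
              alpha = band_spec("alpha", 7, 13),
              beta  = band_spec("beta", 13, 30),
              gamma = band_spec("gamma", 30, 60))
  unknown <- setdiff(names, names(all))
  if (length(unknown))
    stop("unknown band(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  all[names]
}

# Zero-phase filtering helper: forward-backward application of an IIR or FIR
# filter, column-wise over a samples x channels matrix.
.filtfilt_mat <- function(b, a, x) {
  apply(x, 2, function(col) as.numeric(signal::filtfilt(b, a, col)))
}

#' Pre-process a continuous multichannel recording
#'
#' Applies a zero-phase 0.5-60 Hz band-pass (cascaded Butterworth high- and
#' low-pass) and a 50 Hz notch, cuts the recording into consecutive
#' non-overlapping fixed-length epochs, and removes each epoch's per-channel
#' mean (baseline correction).
#'
#' @param recording a [multichannel_epoch()] (of any duration) or a numeric
#'   samples x channels matrix.
#' @param rate sampling rate in Hz (taken from `recording` when it is a
#'   `multichannel_epoch`); must exceed 120 Hz so the 60 Hz edge is below
#'   Nyquist.
#' @param epoch_seconds epoch length, default 10 s.
#' @param band_pass numeric `c(low, high)` pass band in Hz.
#' @param notch power-line frequency to remove, Hz (`NULL` to skip).
#' @return list of [multichannel_epoch()] objects (possibly empty, with a
#'   warning, if the recording is shorter than one epoch).
#' @export
preprocess <- function(recording, rate = NULL, epoch_seconds = 10,
                       band_pass = c(0.5, 60), notch = 50) {
  if (inherits(recording, "multichannel_epoch")) {
    x <- recording$data; rate <- recording$rate; chans <- recording$channels
  } else {
    x <- as.matrix(recording)
    if (is.null(rate)) stop("rate must be given for matrix input", call. = FALSE)
    chans <- colnames(x)
  }
  if (rate <= 2 * band_pass[2])
    stop(sprintf("sampling rate %g Hz too low for a %g Hz band edge",
                 rate, band_pass[2]), call. = FALSE)
  nyq <- rate / 2
  hp <- signal::butter(2, band_pass[1] / nyq, type = "high")
  lp <- signal::butter(4, band_pass[2] / nyq, type = "low")
  x <- .filtfilt_mat(hp$b, hp$a, x)
  x <- .filtfilt_mat(lp$b, lp$a, x)
  if (!is.null(notch)) {
    bs <- signal::butter(2, c(notch - 1, notch + 1) / nyq, type = "stop")
    x <- .filtfilt_mat(bs$b, bs$a, x)
  }
  n_ep <- nrow(x) %/% round(rate * epoch_seconds)
  if (n_ep == 0) {
    warning("recording shorter than one epoch; returning no epochs")
    return(list())
  }
  len <- round(rate * epoch_seconds)
  lapply(seq_len(n_ep), function(i) {
    seg <- x[((i - 1) * len + 1):(i * len), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))  # baseline correction
    multichannel_epoch(seg, rate, chans)
  })
}

#' Zero-phase narrowband filter of an epoch
#'
#' FIR band-pass (Hamming-windowed, order about three cycles of the low
#' cutoff) applied forward and backward so the net phase shift is zero --
#' required because downstream phase-locking analysis is phase-sensitive.
#'
#' @param epoch a [multichannel_epoch()].
#' @param band a [band_spec()].
#' @return a [multichannel_epoch()] of the band-limited signal.
#' @export
band_filter <- function(epoch, band) {
  stopifnot(inherits(epoch, "multichannel_epoch"), inherits(band, "band_spec"))
  nyq <- epoch$rate / 2
  if (band$high >= nyq)
    stop(sprintf("band '%s' upper edge %g Hz not below Nyquist %g Hz",
                 band$name, band$high, nyq), call. = FALSE)
  ord <- round(3 * epoch$rate / band$low)
  ord <- min(ord, floor((nrow(epoch$data) - 1) / 4))
  if (ord %% 2 == 1) ord <- ord + 1  # even order so the band-pass has a passband at center
  b <- as.numeric(signal::fir1(ord, c(band$low, band$high) / nyq, type = "pass"))
  out <- .filtfilt_mat(b, 1, epoch$data)
  colnames(out) <- epoch$channels
  multichannel_epoch(out, epoch$rate, epoch$channels)
}

#' Welch power spectral density
#'
#' Hann-windowed overlapping-segment average periodogram (one-sided density,
#' units^2/Hz) per channel. Defaults: 2 s windows, 50% overlap.
#'
#' @param x numeric vector, samples x channels matrix, or
#'   [multichannel_epoch()].
#' @param rate sampling rate, Hz.
#' @param window_sec segment length in seconds.
#' @param overlap fractional overlap between segments in `[0, 1)`.
#' @param demean remove each segment's mean before windowing.
#' @return list with `freq` (Hz) and `psd` (bins x channels matrix).
#' @export
welch_psd <- function(x, rate = NULL, window_sec = 2, overlap = 0.5,
                      demean = TRUE) {
  if (inherits(x, "multichannel_epoch")) { rate <- x$rate; x <- x$data }
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (is.null(rate)) stop("rate must be given", call. = FALSE)
  nwin <- round(window_sec * rate)
  if (nrow(x) < 2 * nwin)
    stop("signal too short: need at least two Welch windows", call. = FALSE)
  step <- max(1, round(nwin * (1 - overlap)))
  starts <- seq(1, nrow(x) - nwin + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1))  # Hann
  scale <- 1 / (rate * sum(w^2))
  nfreq <- nwin %/% 2 + 1
  acc <- matrix(0, nfreq, ncol(x))
  for (s in starts) {
    seg <- x[s:(s + nwin - 1), , drop = FALSE]
    if (demean) seg <- sweep(seg, 2, colMeans(seg))
    spec <- stats::mvfft(seg * w)
    p <- Mod(spec[seq_len(nfreq), , drop = FALSE])^2 * scale
    # one-sided: double everything except DC (and Nyquist when nwin even)
    dbl <- rep(2, nfreq); dbl[1] <- 1
    if (nwin %% 2 == 0) dbl[nfreq] <- 1
    acc <- acc + p * dbl
  }
  psd <- acc / length(starts)
  colnames(psd) <- colnames(x)
  list(freq = (seq_len(nfreq) - 1) * rate / nwin, psd = psd)
}

#' Mean band power per channel
#'
#' Mean of the Welch PSD over the frequency bins inside the band.
#'
#' @param epoch a [multichannel_epoch()].
#' @param band a [band_spec()].
#' @param ... passed to [welch_psd()].
#' @return named numeric vector, one power per channel.
#' @export
welch_band_power <- function(epoch, band, ...) {
  stopifnot(inherits(band, "band_spec"))
  ps <- welch_psd(epoch, ...)
  sel <- ps$freq >= band$low & ps$freq <= band$high
  if (!any(sel))
    stop(sprintf("no PSD bins inside band '%s'", band$name), call. = FALSE)
  colMeans(ps$psd[sel, , drop = FALSE])
}

#' Tidy per-epoch band-power table
#'
#' @param epochs list of [multichannel_epoch()].
#' @param bands list of [band_spec()] (default: all four standard bands).
#' @param condition optional condition label recorded in the table.
#' @param ... passed to [welch_psd()].
#' @return data.frame with columns epoch, channel, band, power, condition.
#' @export
band_power_table <- function(epochs, bands = default_bands(),
                             condition = NA_character_, ...) {
  rows <- lapply(seq_along(epochs), function(i) {
    per_band <- lapply(bands, function(b) {
      p <- welch_band_power(epochs[[i]], b, ...)
      data.frame(epoch = i, channel = names(p), band = b$name, power = unname(p),
                 condition = condition, stringsAsFactors = FALSE)
    })
    do.call(rbind, per_band)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired between-state test of band power
#'
#' Two-sided paired t-test per channel x band between two matched band-power
#' tables (pairing by epoch index). Degenerate all-zero differences return
#' p = 1 (no evidence of a difference).
#'
#' @param easy,hard band-power tables from [band_power_table()] with matching
#'   epochs, channels and bands.
#' @param alpha significance level for the `significant` flag.
#' @param p_adjust multiple-comparison correction method passed to
#'   [stats::p.adjust()]; `"none"` (default) matches common practice of
#'   reporting uncorrected per-channel tests.
#' @return data.frame with columns channel, band, p, significant.
#' @export
paired_band_test <- function(easy, hard, alpha = 0.05, p_adjust = "none") {
  key <- function(d) paste(d$epoch, d$channel, d$band)
  easy <- easy[order(easy$band, easy$channel, easy$epoch), ]
  hard <- hard[order(hard$band, hard$channel, hard$epoch), ]
  if (nrow(easy) != nrow(hard) || !identical(key(easy), key(hard)))
    stop("tables are not matched epoch-by-epoch across channels and bands",
         call. = FALSE)
  cells <- unique(easy[c("channel", "band")])
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- easy$channel == cells$channel[i] & easy$band == cells$band[i]
    d <- hard$power[sel] - easy$power[sel]
    p <- if (stats::sd(d) == 0) {
      # degenerate: constant difference -- no evidence if zero, certain if not
      if (all(d == 0)) 1.0 else 0.0
    } else {
      stats::t.test(d)$p.value
    }
    data.frame(channel = cells$channel[i], band = cells$band[i], p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p <- stats::p.adjust(out$p, method = p_adjust)
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}
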