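# Coupled-oscillator synthetic signal generator -------------------------------
#
# Stands in for multichannel EEG: each channel carries a narrowband
# oscillation; channels sharing a coupling group share one band-limited
# driver phase, perturbed per channel by band-limited Gaussian phase jitter
# of marginal standard deviation sigma, so the expected pairwise PLV of a
# coupled pair has the closed form exp(-sigma^2).

#' Construct a multichannel epoch container
#'
#' @param data numeric matrix, samples x channels.
#' @param rate sampling rate in Hz.
#' @param channels channel labels (defaults to `colnames(data)`).
#' @return object of class `multichannel_epoch`.
#' @export
multichannel_epoch <- function(data, rate, channels = colnames(data)) {
  data <- as.matrix(data)
  if (is.null(channels)) channels <- paste0("CH", seq_len(ncol(data)))
  stopifnot(length(channels) == ncol(data), rate > 0)
  colnames(data) <- channels
  structure(list(data = data, rate = rate, channels = channels),
            class = "multichannel_epoch")
}

#' @export
print.multichannel_epoch <- function(x, ...) {
  cat(sprintf("<multichannel_epoch> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$rate, nrow(x$data) / x$rate))
  invisible(x)
}

#' Oscillator specification for one frequency band
#'
#' Describes a set of channels carrying narrowband oscillations with optional
#' pairwise phase coupling. Channels listed together in a coupling group share
#' a common band-limited driver phase; each coupled channel additionally
#' receives independent band-limited Gaussian phase jitter with marginal
#' standard deviation `phase_jitter_sigma` (radians). Channels in no group get
#' fully independent drivers.
#'
#' The jitter is band-limited (default bandwidth: the smaller of 8 Hz and the
#' band's low edge) rather than white, so the instantaneous phase recovered by
#' the analytic signal tracks it; under this design the expected PLV of a
#' coupled pair is exp(-sigma^2), since the phase difference of the pair is
#' Gaussian with variance 2 sigma^2.
#'
#' @param band_center center frequency, Hz.
#' @param band_width full bandwidth of the driver, Hz.
#' @param coupling_groups list of character vectors of channel labels; groups
#'   must be disjoint subsets of `channels`.
#' @param phase_jitter_sigma per-channel phase jitter standard deviation,
#'   radians (applies to coupled channels).
#' @param amplitude_noise_sigma additive broadband noise level, as a fraction
#'   of each channel's signal standard deviation.
#' @param sample_rate sampling rate, Hz.
#' @param epoch_seconds epoch duration, s.
#' @param channels montage labels; defaults to the 62-channel 10-20 montage.
#' @param jitter_bandwidth bandwidth of the phase jitter, Hz; `NULL` uses
#'   `min(8, band low edge)`.
#' @return object of class `oscillator_spec`.
#' @export
oscillator_spec <- function(band_center, band_width,
                            coupling_groups = list(),
                            phase_jitter_sigma = 0,
                            amplitude_noise_sigma = 0,
                            sample_rate = 500,
                            epoch_seconds = 10,
                            channels = montage_1020(),
                            jitter_bandwidth = NULL) {
  low <- band_center - band_width / 2
  high <- band_center + band_width / 2
  nyq <- sample_rate / 2
  if (band_width <= 0)
    stop("band_width must be positive", call. = FALSE)
  if (low <= 0 || high >= nyq)
    stop(sprintf("band %g-%g Hz outside (0, Nyquist = %g Hz)", low, high, nyq),
         call. = FALSE)
  if (phase_jitter_sigma < 0)
    stop("phase_jitter_sigma must be >= 0", call. = FALSE)
  if (amplitude_noise_sigma < 0)
    stop("amplitude_noise_sigma must be >= 0", call. = FALSE)
  channels <- as.character(channels)
  all_grouped <- unlist(coupling_groups)
  if (anyDuplicated(all_grouped))
    stop("coupling groups must be disjoint", call. = FALSE)
  unknown <- setdiff(all_grouped, channels)
  if (length(unknown))
    stop("coupling group channels not in montage: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(jitter_bandwidth)) jitter_bandwidth <- min(8, low)
  structure(list(band_center = band_center, band_width = band_width,
                 coupling_groups = lapply(coupling_groups, as.character),
                 phase_jitter_sigma = phase_jitter_sigma,
                 amplitude_noise_sigma = amplitude_noise_sigma,
                 sample_rate = sample_rate, epoch_seconds = epoch_seconds,
                 channels = channels, jitter_bandwidth = jitter_bandwidth),
            class = "oscillator_spec")
}

# Complex analytic band-limited Gaussian noise of length n: flat one-sided
# spectrum on [low, high] Hz, zero elsewhere. Real part is the signal; the
# one-sided spectrum makes the returned series exactly analytic.
.analytic_band_noise <- function(n, rate, low, high) {
  freqs <- (seq_len(n) - 1) * rate / n
  keep <- which(freqs >= low & freqs <= high & freqs <= rate / 2)
  if (!length(keep))
    stop("band contains no FFT bins at this length/rate", call. = FALSE)
  spec <- complex(length.out = n)
  spec[keep] <- complex(real = stats::rnorm(length(keep)),
                        imaginary = stats::rnorm(length(keep)))
  z <- stats::fft(spec, inverse = TRUE) / n
  s <- stats::sd(Re(z))
  if (s == 0) stop("degenerate driver realisation", call. = FALSE)
  z / s
}

# Real low-pass Gaussian noise with marginal sd exactly `sigma`, built by
# zeroing all FFT bins above `bw` Hz.
.lowpass_noise <- function(n, rate, bw, sigma) {
  if (sigma == 0) return(numeric(n))
  x <- stats::rnorm(n)
  spec <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * rate / n
  fold <- pmin(freqs, rate - freqs)
  spec[fold > bw] <- 0
  e <- Re(stats::fft(spec, inverse = TRUE) / n)
  s <- stats::sd(e)
  if (s == 0) return(numeric(n))
  e / s * sigma
}

#' Generate one synthetic multichannel epoch
#'
#' Each coupling group shares one narrowband driver; member channels are the
#' real part of the driver with per-channel band-limited phase jitter applied
#' to its instantaneous phase. Ungrouped channels get independent drivers.
#' Deterministic given `seed`.
#'
#' @param spec an [oscillator_spec()].
#' @param seed integer seed.
#' @return a [multichannel_epoch()].
#' @export
generate_epoch <- function(spec, seed) {
  stopifnot(inherits(spec, "oscillator_spec"))
  n <- round(spec$sample_rate * spec$epoch_seconds)
  low <- spec$band_center - spec$band_width / 2
  high <- spec$band_center + spec$band_width / 2
  chans <- spec$channels
  withr::with_seed(as.integer(seed), {
    out <- matrix(0, n, length(chans), dimnames = list(NULL, chans))
    grouped <- character(0)
    for (grp in spec$coupling_groups) {
      z <- .analytic_band_noise(n, spec$sample_rate, low, high)
      amp <- Mod(z); phase <- Arg(z)
      for (ch in grp) {
        eps <- .lowpass_noise(n, spec$sample_rate, spec$jitter_bandwidth,
                              spec$phase_jitter_sigma)
        out[, ch] <- amp * cos(phase + eps)
      }
      grouped <- c(grouped, grp)
    }
    for (ch in setdiff(chans, grouped)) {
      out[, ch] <- Re(.analytic_band_noise(n, spec$sample_rate, low, high))
    }
    if (spec$amplitude_noise_sigma > 0) {
      for (j in seq_along(chans)) {
        out[, j] <- out[, j] +
          stats::rnorm(n, 0, spec$amplitude_noise_sigma * stats::sd(out[, j]))
      }
    }
    multichannel_epoch(out, spec$sample_rate, chans)
  })
}

#' Condition specification: one labelled state of a two-state dataset
#'
#' @param label condition label, e.g. `"easy"` or `"hard"`.
#' @param oscillator_specs one [oscillator_spec()] or a list of them (one per
#'   band); per-epoch signals are the sum of the band components.
#' @param n_epochs number of epochs to generate.
#' @param seed integer seed for this condition.
#' @return object of class `condition_spec`.
#' @export
condition_spec <- function(label, oscillator_specs, n_epochs, seed) {
  if (inherits(oscillator_specs, "oscillator_spec"))
    oscillator_specs <- list(oscillator_specs)
  stopifnot(length(oscillator_specs) >= 1,
            all(vapply(oscillator_specs, inherits, logical(1), "oscillator_spec")),
            n_epochs >= 1)
  ref <- oscillator_specs[[1]]
  for (sp in oscillator_specs) {
    if (!identical(sp$channels, ref$channels) ||
        sp$sample_rate != ref$sample_rate ||
        sp$epoch_seconds != ref$epoch_seconds)
      stop("all oscillator specs of a condition must share montage, rate and epoch length",
           call. = FALSE)
  }
  structure(list(label = as.character(label),
                 oscillator_specs = oscillator_specs,
                 n_epochs = as.integer(n_epochs), seed = as.integer(seed)),
            class = "condition_spec")
}

#' Generate a labelled two-condition epoch collection
#'
#' @param easy,hard [condition_spec()] objects sharing montage, sampling rate
#'   and epoch length.
#' @return object of class `epoch_dataset`: list with `epochs` (list of
#'   [multichannel_epoch()]), `labels` (factor), `channels`, `rate`.
#' @export
generate_dataset <- function(easy, hard) {
  stopifnot(inherits(easy, "condition_spec"), inherits(hard, "condition_spec"))
  r1 <- easy$oscillator_specs[[1]]; r2 <- hard$oscillator_specs[[1]]
  if (!identical(r1$channels, r2$channels) || r1$sample_rate != r2$sample_rate ||
      r1$epoch_seconds != r2$epoch_seconds)
    stop("conditions must share montage, rate and epoch length", call. = FALSE)
  gen_condition <- function(cond) {
    lapply(seq_len(cond$n_epochs), function(i) {
      parts <- lapply(seq_along(cond$oscillator_specs), function(b) {
        ep_seed <- cond$seed + (i - 1L) * length(cond$oscillator_specs) + (b - 1L)
        generate_epoch(cond$oscillator_specs[[b]], ep_seed)
      })
      dat <- Reduce(`+`, lapply(parts, `[[`, "data"))
      multichannel_epoch(dat, parts[[1]]$rate, parts[[1]]$channels)
    })
  }
  e_eps <- gen_condition(easy); h_eps <- gen_condition(hard)
  structure(list(
    epochs = c(e_eps, h_eps),
    labels = factor(c(rep(easy$label, easy$n_epochs),
                      rep(hard$label, hard$n_epochs)),
                    levels = c(easy$label, hard$label)),
    channels = r1$channels, rate = r1$sample_rate),
    class = "epoch_dataset")
}

#' Two-state strong-effect condition pair
#'
#' Convenience builder for the canonical synthetic experiment: the easy state
#' has fully independent channels; the hard state adds one densely coupled
#' frontal-parietal channel group. Classification of the two states from
#' node-importance features is then driven solely by the planted coupling.
#'
#' @param seed base integer seed; the two conditions use `seed` and
#'   `seed + 500000`.
#' @param n_epochs epochs per condition.
#' @param group channel labels of the coupled group planted in the hard state.
#' @param sigma phase jitter sd (radians) within the planted group.
#' @param band_center,band_width driver band (default alpha, 7-13 Hz).
#' @param channels montage.
#' @return list with elements `easy` and `hard` ([condition_spec()]s).
#' @export
two_state_specs <- function(seed, n_epochs = 40,
                            group = c("F3", "FZ", "F4", "P3", "PZ", "P4"),
                            sigma = 0.3,
                            band_center = 10, band_width = 6,
                            channels = montage_1020()) {
  base <- function(groups, sig) {
    oscillator_spec(band_center, band_width, coupling_groups = groups,
                    phase_jitter_sigma = sig, channels = channels)
  }
  list(
    easy = condition_spec("easy", base(list(), 0), n_epochs, seed),
    hard = condition_spec("hard", base(list(group), sigma), n_epochs,
                          seed + 500000L)
  )
}
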