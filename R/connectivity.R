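# PLV connectivity and surrogate-data binarization ----------------------------
#
# The phase locking value of two narrowband signals is the magnitude of the
# time-averaged unit phasor of their instantaneous phase difference:
#   PLV = | mean_t exp(i * (phi1(t) - phi2(t))) |
# with phases taken from the analytic (Hilbert) signal. Edges of the
# binarized network are PLV values exceeding a per-band surrogate threshold.

#' Analytic signal via the Hilbert transform
#'
#' Complex series `Z(t) = X(t) + i * HT(X(t))` computed by one-sided FFT
#' masking; `Mod(Z)` is the instantaneous amplitude and `Arg(Z)` the
#' instantaneous phase.
#'
#' @param x numeric vector (a single narrowband channel).
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2 || stats::sd(x) == 0)
    stop("analytic signal undefined for constant or empty input", call. = FALSE)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of a narrowband signal
#'
#' @param x numeric vector, already band-limited.
#' @return phase in radians, wrapped to (-pi, pi].
#' @export
analytic_phase <- function(x) {
  Arg(analytic_signal(x))
}

#' PLV from two phase series
#'
#' @param p1,p2 phase series in radians, equal length.
#' @return scalar in `[0, 1]`.
#' @export
plv_from_phases <- function(p1, p2) {
  if (length(p1) != length(p2))
    stop("phase series lengths differ", call. = FALSE)
  Mod(mean(exp(1i * (p1 - p2))))
}

# Sample index window after discarding `edge_trim` seconds at each end
# (Hilbert transform transients bias phase estimates at epoch boundaries).
.trim_idx <- function(n, rate, edge_trim) {
  k <- round(edge_trim * rate)
  if (2 * k >= n) stop("edge_trim leaves no samples", call. = FALSE)
  (k + 1):(n - k)
}

#' Phase locking value of a channel pair
#'
#' @param x1,x2 narrowband signals of equal length (>= 100 samples).
#' @param rate sampling rate in Hz; needed when `edge_trim > 0`.
#' @param edge_trim seconds discarded at each end before averaging
#'   (default 0.25 s).
#' @return PLV scalar in `[0, 1]`.
#' @export
plv_pair <- function(x1, x2, rate = NULL, edge_trim = 0.25) {
  if (length(x1) != length(x2))
    stop("signals have different lengths", call. = FALSE)
  if (length(x1) < 100)
    stop("signals too short for a stable PLV (need >= 100 samples)",
         call. = FALSE)
  p1 <- analytic_phase(x1)
  p2 <- analytic_phase(x2)
  idx <- if (edge_trim > 0) {
    if (is.null(rate)) stop("rate required when edge_trim > 0", call. = FALSE)
    .trim_idx(length(x1), rate, edge_trim)
  } else seq_along(x1)
  plv_from_phases(p1[idx], p2[idx])
}

# Phase matrix (trimmed samples x channels) of an epoch, optionally
# band-filtering first.
.epoch_phases <- function(epoch, band = NULL, edge_trim = 0.25) {
  if (!is.null(band)) epoch <- band_filter(epoch, band)
  ph <- vapply(seq_len(ncol(epoch$data)), function(j) {
    tryCatch(analytic_phase(epoch$data[, j]),
             error = function(e) stop(sprintf("channel %s: %s",
                                              epoch$channels[j],
                                              conditionMessage(e)),
                                      call. = FALSE))
  }, numeric(nrow(epoch$data)))
  colnames(ph) <- epoch$channels
  idx <- if (edge_trim > 0) .trim_idx(nrow(ph), epoch$rate, edge_trim)
         else seq_len(nrow(ph))
  ph[idx, , drop = FALSE]
}

#' PLV adjacency matrix of an epoch
#'
#' Computes the phase locking value between all channel pairs. All phases are
#' extracted once per channel; the full matrix is then one complex
#' cross-product, identical pairwise to [plv_pair()].
#'
#' @param epoch a [multichannel_epoch()] (narrowband, or supply `band`).
#' @param band optional [band_spec()]; when given, the epoch is band-filtered
#'   first and the band name is recorded.
#' @param edge_trim seconds discarded at each epoch end (default 0.25 s).
#' @param epoch_id optional identifier stored in the result.
#' @return object of class `plv_matrix`: list with `values` (symmetric n x n
#'   matrix, unit diagonal), `band`, `epoch_id`, `node_labels`.
#' @export
plv_matrix <- function(epoch, band = NULL, edge_trim = 0.25, epoch_id = NA) {
  stopifnot(inherits(epoch, "multichannel_epoch"))
  if (ncol(epoch$data) < 2) stop("need at least 2 channels", call. = FALSE)
  ph <- .epoch_phases(epoch, band, edge_trim)
  e <- exp(1i * ph)
  v <- Mod(crossprod(Conj(e), e)) / nrow(e)
  v <- (v + t(v)) / 2          # enforce exact symmetry
  v[v > 1] <- 1
  diag(v) <- 1
  dimnames(v) <- list(epoch$channels, epoch$channels)
  structure(list(values = v,
                 band = if (is.null(band)) NA_character_ else band$name,
                 epoch_id = epoch_id, node_labels = epoch$channels),
            class = "plv_matrix")
}

#' @export
print.plv_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<plv_matrix> %d nodes, band %s, PLV range [%.3f, %.3f]\n",
              length(x$node_labels), x$band, min(off), max(off)))
  invisible(x)
}

#' Surrogate-data significance threshold for PLV edges
#'
#' Builds a null distribution of PLV under "same spectrum, no phase relation"
#' by circularly time-shifting one channel of randomly chosen pairs by a
#' random offset of at least `min_shift` seconds, then takes the
#' `(1 - alpha)` percentile of the pooled surrogate PLVs as the per-band
#' threshold. A circular shift of a signal shifts its analytic phase series
#' identically, so phases are extracted once per epoch and shifted directly.
#'
#' @param epochs list of [multichannel_epoch()] (narrowband, or supply
#'   `band`).
#' @param band optional [band_spec()] applied to each epoch.
#' @param n_surrogates number of surrogate PLV draws (>= 19; default 200).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed; the draw is deterministic given it.
#' @param edge_trim seconds discarded at each epoch end.
#' @param min_shift minimum circular shift in seconds (default 1 s).
#' @return object of class `threshold_spec`: list with `band`, `threshold`,
#'   `n_surrogates`, `alpha`, `method`, `seed`, `surrogate_plv`.
#' @export
surrogate_threshold <- function(epochs, band = NULL, n_surrogates = 200,
                                alpha = 0.05, seed = 1, edge_trim = 0.25,
                                min_shift = 1) {
  if (inherits(epochs, "multichannel_epoch")) epochs <- list(epochs)
  stopifnot(length(epochs) >= 1)
  if (n_surrogates < 19)
    stop("n_surrogates must be >= 19 for a 0.05-level percentile", call. = FALSE)
  rate <- epochs[[1]]$rate
  n_samp <- nrow(epochs[[1]]$data)
  if (n_samp < 2 * min_shift * rate)
    stop("epochs too short for a meaningful circular shift (need >= 2 s)",
         call. = FALSE)
  phases <- lapply(epochs, .epoch_phases, band = band, edge_trim = edge_trim)
  n_ch <- ncol(phases[[1]])
  if (n_ch < 2) stop("need at least 2 channels", call. = FALSE)
  nt <- nrow(phases[[1]])
  shift_range <- c(ceiling(min_shift * rate), nt - ceiling(min_shift * rate))
  if (shift_range[2] < shift_range[1])
    stop("epochs too short for a meaningful circular shift", call. = FALSE)
  sur <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_surrogates), function(s) {
      ep <- sample.int(length(phases), 1)
      pr <- sample.int(n_ch, 2)
      off <- sample(seq(shift_range[1], shift_range[2]), 1)
      p1 <- phases[[ep]][, pr[1]]
      p2 <- phases[[ep]][, pr[2]]
      p2s <- c(p2[(off + 1):nt], p2[1:off])
      plv_from_phases(p1, p2s)
    }, numeric(1))
  })
  structure(list(band = if (is.null(band)) NA_character_ else band$name,
                 threshold = unname(stats::quantile(sur, 1 - alpha, type = 7)),
                 n_surrogates = n_surrogates, alpha = alpha,
                 method = "circular_shift", seed = as.integer(seed),
                 surrogate_plv = sur),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("<threshold_spec> band %s: T = %.4f (alpha = %g, %d circular-shift surrogates)\n",
              x$band, x$threshold, x$alpha, x$n_surrogates))
  invisible(x)
}

#' Construct a binary network object
#'
#' @param adjacency symmetric 0/1 matrix (diagonal is zeroed).
#' @param node_labels labels (default from dimnames).
#' @param band,condition optional annotations.
#' @return object of class `binary_network`.
#' @export
binary_network <- function(adjacency, node_labels = rownames(adjacency),
                           band = NA_character_, condition = NA_character_) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be square", call. = FALSE)
  if (!all(adjacency %in% c(0, 1)))
    stop("adjacency must be 0/1", call. = FALSE)
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    stop("adjacency must be symmetric", call. = FALSE)
  diag(adjacency) <- 0
  if (is.null(node_labels)) node_labels <- paste0("V", seq_len(nrow(adjacency)))
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(node_labels, node_labels)
  structure(list(adjacency = adjacency, node_labels = node_labels,
                 band = band, condition = condition),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges, band %s\n",
              length(x$node_labels), sum(x$adjacency) / 2, x$band))
  invisible(x)
}

#' Binarize a PLV matrix against a threshold
#'
#' An edge is present iff PLV strictly exceeds the threshold; the diagonal is
#' zeroed (no self-loops).
#'
#' @param plv a [plv_matrix()].
#' @param thr a [threshold_spec()] (its band must match) or a bare numeric
#'   threshold in `[0, 1]`.
#' @param condition optional condition label carried to the network.
#' @return a [binary_network()].
#' @export
binarize <- function(plv, thr, condition = NA_character_) {
  stopifnot(inherits(plv, "plv_matrix"))
  if (inherits(thr, "threshold_spec")) {
    if (!is.na(thr$band) && !is.na(plv$band) && !identical(thr$band, plv$band))
      stop(sprintf("band mismatch: PLV is '%s', threshold is '%s'",
                   plv$band, thr$band), call. = FALSE)
    tval <- thr$threshold
  } else {
    tval <- as.numeric(thr)
    if (tval < 0 || tval > 1) stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  adj <- (plv$values > tval) * 1L
  diag(adj) <- 0L
  binary_network(adj, plv$node_labels, band = plv$band, condition = condition)
}
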