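# Independent brute-force oracles used to cross-check the implementation.

# All-pairs hop distances by boolean matrix powers: D[i,j] = min k with
# (A^k)[i,j] > 0 (Inf if never reached within n-1 powers).
oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(n)
  pow <- diag(n)
  for (k in seq_len(max(n - 1, 1))) {
    pow <- (pow %*% adj > 0) * 1
    newly <- pow > 0 & reach == 0
    D[newly & is.infinite(D)] <- k
    reach <- reach | pow > 0
  }
  dimnames(D) <- dimnames(adj)
  D
}

# Straight-line evaluation of the importance score from first principles.
oracle_wkpn <- function(adj) {
  D <- oracle_distances(adj)
  d <- max(D[is.finite(D)])
  N <- sapply(0:d, function(K) rowSums(D <= K))
  if (nrow(D) == 1) N <- matrix(N, nrow = 1)
  H <- apply(N, 2, function(col) {
    p <- col / sum(col)
    -sum(p * log(p))
  })
  cw <- H / sum(H)
  S <- sweep(N, 2, colSums(N), "/")
  Q <- as.numeric(S %*% cw)
  names(Q) <- rownames(adj)
  list(N = N, d = d, H = H, c = cw, S = S, Q = Q)
}

# Random symmetric 0/1 adjacency with labels, edge probability p.
random_adjacency <- function(n, p = 0.3) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a <- a + t(a)
  labs <- sprintf("N%02d", seq_len(n))
  dimnames(a) <- list(labs, labs)
  a
}

# Remove 2*pi jumps from a wrapped phase series.
unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(p[1], dp))
}

# Small helper montages keep the signal-level tests fast.
small_montage <- function(n) paste0("CH", sprintf("%02d", seq_len(n)))

make_epoch <- function(seed, channels = small_montage(2), groups = list(),
                       sigma = 0, center = 10, width = 6, rate = 500,
                       seconds = 10) {
  spec <- oscillator_spec(center, width, coupling_groups = groups,
                          phase_jitter_sigma = sigma, sample_rate = rate,
                          epoch_seconds = seconds, channels = channels)
  generate_epoch(spec, seed)
}
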