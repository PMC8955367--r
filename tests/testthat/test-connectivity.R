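test_that("analytic phase of a cosine advances at the carrier frequency", {
  rate <- 500
  t <- seq_len(10 * rate) / rate
  ph <- analytic_phase(cos(2 * pi * 10 * t))
  interior <- 500:4500
  slope <- stats::coef(stats::lm(y ~ x, data.frame(
    x = t[interior], y = unwrap_phase(ph[interior]))))[2]
  expect_equal(unname(slope), 2 * pi * 10, tolerance = 0.01)
})

test_that("sine lags cosine by pi/2 and negation shifts phase by pi", {
  rate <- 500
  t <- seq_len(10 * rate) / rate
  pc <- analytic_phase(cos(2 * pi * 10 * t))
  ps <- analytic_phase(sin(2 * pi * 10 * t))
  interior <- 500:4500
  dphi <- Arg(exp(1i * (pc - ps)))[interior]
  expect_lt(max(abs(dphi - pi / 2)), 0.01)
  pm <- analytic_phase(-cos(2 * pi * 10 * t))
  dneg <- Arg(exp(1i * (pc - pm)))[interior]
  expect_lt(max(abs(abs(dneg) - pi)), 0.01)
})

test_that("analytic phase of a constant signal is an error", {
  expect_error(analytic_phase(rep(1, 100)), "constant")
})

test_that("PLV of a signal with itself is exactly 1", {
  ep <- make_epoch(1, channels = "A")
  expect_identical(plv_pair(ep$data[, 1], ep$data[, 1], rate = 500), 1)
})

test_that("PLV under a constant phase lag stays 1", {
  rate <- 500
  t <- seq_len(10 * rate) / rate
  x1 <- cos(2 * pi * 10 * t)
  x2 <- cos(2 * pi * 10 * t - 1.1)
  expect_equal(plv_pair(x1, x2, rate = rate), 1, tolerance = 1e-3)
})

test_that("PLV is symmetric and amplitude-invariant", {
  ep <- make_epoch(2, channels = c("A", "B"))
  x1 <- ep$data[, 1]; x2 <- ep$data[, 2]
  expect_identical(plv_pair(x1, x2, rate = 500), plv_pair(x2, x1, rate = 500))
  expect_equal(plv_pair(x1, x2, rate = 500), plv_pair(10 * x1, x2, rate = 500),
               tolerance = 1e-9)
})

test_that("PLV input validation", {
  expect_error(plv_pair(rnorm(100), rnorm(99)), "lengths")
  expect_error(plv_pair(rnorm(50), rnorm(50)), "too short")
})

test_that("null PLV of independent uniform phases follows sqrt(pi)/(2 sqrt(N))", {
  set.seed(4)
  n <- 5000
  draws <- vapply(seq_len(100), function(i)
    plv_from_phases(stats::runif(n, -pi, pi), numeric(n)), numeric(1))
  expect_equal(mean(draws), sqrt(pi) / (2 * sqrt(n)), tolerance = 0.1)
})

test_that("plv_matrix matches pairwise plv_pair and handles relabeling", {
  ep <- make_epoch(5, channels = c("A", "B", "C"),
                   groups = list(c("A", "B")), sigma = 0.5)
  pm <- plv_matrix(ep)
  expect_identical(rownames(pm$values), c("A", "B", "C"))
  expect_equal(diag(pm$values), stats::setNames(rep(1, 3), c("A", "B", "C")))
  for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_equal(pm$values[pr[1], pr[2]],
                 plv_pair(ep$data[, pr[1]], ep$data[, pr[2]], rate = 500),
                 tolerance = 1e-10)
  }
  perm <- c(3, 1, 2)
  ep_p <- multichannel_epoch(ep$data[, perm], ep$rate)
  pm_p <- plv_matrix(ep_p)
  expect_equal(pm_p$values, pm$values[perm, perm], tolerance = 1e-12)
})

test_that("identical channels give an all-ones PLV matrix", {
  ep <- make_epoch(6, channels = "A")
  dat <- cbind(A = ep$data[, 1], B = ep$data[, 1], C = ep$data[, 1])
  pm <- plv_matrix(multichannel_epoch(dat, 500))
  expect_equal(unname(pm$values), matrix(1, 3, 3), tolerance = 1e-9)
})

test_that("surrogate thresholds are deterministic, ordered in alpha, and bounded by locked pairs", {
  eps <- lapply(1:4, function(i)
    make_epoch(10 + i, channels = c("A", "B", "C"),
               groups = list(c("A", "B"))))
  t1 <- surrogate_threshold(eps, n_surrogates = 100, alpha = 0.05, seed = 3)
  t2 <- surrogate_threshold(eps, n_surrogates = 100, alpha = 0.05, seed = 3)
  expect_identical(t1$threshold, t2$threshold)
  t_loose <- surrogate_threshold(eps, n_surrogates = 100, alpha = 0.5, seed = 3)
  t_tight <- surrogate_threshold(eps, n_surrogates = 100, alpha = 0.01, seed = 3)
  expect_lt(t_loose$threshold, t_tight$threshold)
  # a perfectly locked pair always exceeds any surrogate percentile
  pm <- plv_matrix(eps[[1]])
  expect_gt(pm$values["A", "B"], t_tight$threshold)
})

test_that("surrogate_threshold validates surrogate count and epoch length", {
  eps <- list(make_epoch(1, channels = c("A", "B")))
  expect_error(surrogate_threshold(eps, n_surrogates = 10), ">= 19")
  short <- multichannel_epoch(matrix(rnorm(600), ncol = 2), 500, c("A", "B"))
  expect_error(surrogate_threshold(list(short), n_surrogates = 20),
               "circular shift")
})

test_that("binarize respects strict threshold semantics and band matching", {
  ep <- make_epoch(9, channels = c("A", "B", "C", "D"))
  pm <- plv_matrix(ep)
  empty <- binarize(pm, 1)
  expect_equal(sum(empty$adjacency), 0)
  full <- binarize(pm, 0)
  expect_equal(sum(full$adjacency), 4 * 3)
  expect_equal(unname(diag(full$adjacency)), rep(0L, 4))
  thr <- surrogate_threshold(list(ep), n_surrogates = 20, seed = 1)
  thr$band <- "beta"
  pm$band <- "alpha"
  expect_error(binarize(pm, thr), "band mismatch")
})

test_that("edge count decreases monotonically as the threshold rises", {
  ep <- make_epoch(12, channels = small_montage(6),
                   groups = list(small_montage(6)[1:3]), sigma = 0.8)
  pm <- plv_matrix(ep)
  counts <- vapply(seq(0, 1, by = 0.05), function(tv)
    sum(binarize(pm, tv)$adjacency) / 2, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], choose(6, 2))
  expect_equal(counts[length(counts)], 0)
})
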