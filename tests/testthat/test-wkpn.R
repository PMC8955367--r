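path_net <- function() {
  a <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  a["A", "B"] <- a["B", "A"] <- a["B", "C"] <- a["C", "B"] <- 1
  binary_network(a)
}

star_net <- function(n_leaves = 3) {
  n <- n_leaves + 1
  a <- matrix(0, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1
  labs <- c("HUB", paste0("L", seq_len(n_leaves)))
  dimnames(a) <- list(labs, labs)
  binary_network(a)
}

cycle_net <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    a[i, j] <- a[j, i] <- 1
  }
  labs <- sprintf("C%02d", seq_len(n))
  dimnames(a) <- list(labs, labs)
  binary_network(a)
}

test_that("shortest paths match hand-checkable cases and the matrix-power oracle", {
  D <- shortest_path_lengths(path_net())
  expect_equal(D["A", "C"], 2)
  expect_equal(unname(diag(D)), rep(0, 3))
  disc <- binary_network(matrix(0, 2, 2, dimnames = list(c("A", "B"),
                                                         c("A", "B"))))
  expect_identical(shortest_path_lengths(disc)["A", "B"], Inf)
  set.seed(11)
  for (i in 1:40) {
    adj <- random_adjacency(sample(2:12, 1), p = stats::runif(1, 0.1, 0.6))
    expect_equal(shortest_path_lengths(adj), oracle_distances(adj))
  }
})

test_that("K-order propagation numbers on the path and star graphs", {
  ko <- k_order_numbers(path_net())
  expect_equal(ko$d, 2)
  expect_equal(unname(ko$N[, "K0"]), c(1L, 1L, 1L))
  expect_equal(unname(ko$N[, "K1"]), c(2L, 3L, 2L))
  expect_equal(unname(ko$N[, "K2"]), c(3L, 3L, 3L))
  ks <- k_order_numbers(star_net())
  expect_equal(unname(ks$N[, "K1"]), c(4L, 2L, 2L, 2L))
})

test_that("edgeless graphs have d = 0 and unit propagation numbers", {
  a <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  ko <- k_order_numbers(binary_network(a))
  expect_equal(ko$d, 0)
  expect_equal(unname(ko$N[, 1]), rep(1L, 4))
})

test_that("structure entropy: frozen value, uniform maximum, bounds", {
  expect_equal(structure_entropy(c(2, 3, 2)), 1.0789922, tolerance = 1e-6)
  expect_equal(structure_entropy(rep(5, 8)), log(8))
  expect_error(structure_entropy(c(0, 1)), ">= 1")
  set.seed(12)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    h <- structure_entropy(sample(1:n, n, replace = TRUE))
    expect_gt(h, 0)
    expect_lte(h, log(n) + 1e-12)
  }
})

test_that("vertex-transitive graphs have uniform importance 1/n", {
  for (net in list(cycle_net(6),
                   binary_network(1 - diag(5),
                                  node_labels = paste0("K", 1:5)))) {
    q <- node_importance(net)$Q
    expect_equal(unname(q), rep(1 / length(q), length(q)), tolerance = 1e-12)
  }
})

test_that("the star center dominates importance and is the only marked node", {
  prof <- node_importance(star_net())
  expect_equal(prof$ranking[1], "HUB")
  expect_gt(prof$Q["HUB"], max(prof$Q[-1]))
  mk <- mark_nodes(prof, 0.8)
  expect_identical(mk$marked, "HUB")
  expect_equal(unname(range(mk$normalized)), c(0, 1))
})

test_that("importance matches the brute-force oracle on random graphs", {
  set.seed(13)
  for (i in 1:40) {
    adj <- random_adjacency(sample(2:12, 1), p = stats::runif(1, 0.05, 0.7))
    prof <- node_importance(adj)
    orc <- oracle_wkpn(adj)
    expect_equal(prof$d, orc$d)
    expect_equal(unname(prof$N), unname(orc$N))
    expect_equal(unname(prof$H), unname(orc$H), tolerance = 1e-12)
    expect_equal(unname(prof$c), unname(orc$c), tolerance = 1e-12)
    expect_equal(unname(prof$S), unname(orc$S), tolerance = 1e-12)
    expect_equal(prof$Q, orc$Q, tolerance = 1e-12)
    expect_equal(sum(prof$Q), 1, tolerance = 1e-12)
  }
})

test_that("propagation counts grow with K up to the component size", {
  set.seed(14)
  for (i in 1:10) {
    adj <- random_adjacency(10, p = 0.2)
    ko <- k_order_numbers(adj)
    expect_true(all(apply(ko$N, 1, function(r) all(diff(r) >= 0))))
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
      adj, mode = "undirected"))
    sizes <- comp$csize[comp$membership]
    expect_equal(unname(ko$N[, ncol(ko$N)]), unname(sizes))
  }
})

test_that("relabeling nodes permutes importance identically", {
  set.seed(15)
  adj <- random_adjacency(8, p = 0.3)
  perm <- sample(8)
  padj <- adj[perm, perm]
  q1 <- node_importance(adj)$Q
  q2 <- node_importance(padj)$Q
  expect_equal(q2, q1[perm], tolerance = 1e-14)
})

test_that("tied scores rank deterministically by node label", {
  prof <- node_importance(cycle_net(5))
  expect_identical(prof$ranking, sort(prof$node_labels))
})

test_that("alternative normalization and inverted weights keep Q a distribution", {
  set.seed(16)
  adj <- random_adjacency(9, p = 0.3)
  for (prof in list(node_importance(adj, normalization = "minmax"),
                    node_importance(adj, invert_weights = TRUE))) {
    expect_equal(sum(prof$Q), 1, tolerance = 1e-12)
    expect_true(all(prof$Q >= 0))
    expect_setequal(prof$ranking, rownames(adj))
  }
})

test_that("mark_nodes threshold semantics and degenerate input", {
  prof <- node_importance(star_net())
  expect_identical(mark_nodes(prof, 1)$marked, character(0))
  at0 <- mark_nodes(prof, 0)$marked
  expect_setequal(at0, names(prof$Q)[prof$Q > min(prof$Q)])
  expect_warning(mk <- mark_nodes(node_importance(cycle_net(4))),
                 "constant")
  expect_identical(mk$marked, character(0))
})

test_that("weighted degree centrality equals strength", {
  expect_equal(unname(wdc(star_net())), c(3, 1, 1, 1))
  expect_equal(unname(wdc(binary_network(1 - diag(4)))), rep(3, 4))
  set.seed(17)
  w <- matrix(stats::runif(49), 7, 7)
  w <- (w + t(w)) / 2
  expect_equal(unname(wdc(w)), unname(rowSums(w) - diag(w)))
})

test_that("weighted PageRank is uniform on regular graphs and sums to 1", {
  pr <- wpr(cycle_net(6))
  expect_equal(unname(pr), rep(1 / 6, 6), tolerance = 1e-8)
  set.seed(18)
  w <- matrix(stats::runif(64), 8, 8)
  w <- (w + t(w)) / 2
  expect_equal(sum(wpr(w)), 1, tolerance = 1e-8)
})

test_that("weighted PageRank agrees with the igraph implementation", {
  set.seed(19)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    w <- matrix(stats::runif(n * n), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    labs <- paste0("V", seq_len(n))
    dimnames(w) <- list(labs, labs)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    ref <- igraph::page_rank(g, damping = 0.85)$vector
    expect_equal(wpr(w), ref, tolerance = 1e-7)
  }
})
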