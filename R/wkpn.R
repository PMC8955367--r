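# K-order propagation number node importance ----------------------------------
#
# Each node is treated as an infection source; N[v, K] counts the nodes
# within shortest-path distance K of v (self included), for K = 0..d where d
# is the largest finite shortest-path length in the network. The Shannon
# entropy H_K of the node distribution of N[, K] measures network
# heterogeneity at order K; importance is the entropy-weighted average of the
# per-order node shares:
#   Q_v = sum_K c_K * S[v, K],  c_K = H_K / sum(H),  S[v, K] = N[v, K] / sum(N[, K])
# so that sum_v Q_v = 1.

.as_adjacency <- function(net) {
  if (inherits(net, "binary_network")) return(net$adjacency)
  if (inherits(net, "plv_matrix")) return(net$values)
  m <- as.matrix(net)
  if (nrow(m) != ncol(m)) stop("adjacency must be square", call. = FALSE)
  if (is.null(rownames(m))) {
    labs <- paste0("V", seq_len(nrow(m)))
    dimnames(m) <- list(labs, labs)
  }
  m
}

#' Unweighted shortest-path length matrix
#'
#' Breadth-first hop counts between all node pairs; `Inf` for unreachable
#' pairs, 0 on the diagonal.
#'
#' @param net a [binary_network()] or 0/1 adjacency matrix.
#' @return symmetric numeric matrix of hop counts.
#' @export
shortest_path_lengths <- function(net) {
  adj <- .as_adjacency(net)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  d <- igraph::distances(g, algorithm = "unweighted")
  dimnames(d) <- dimnames(adj)
  d
}

#' K-order propagation numbers
#'
#' `N[v, K]` is the number of nodes (self included) whose shortest-path
#' distance from `v` is at most `K`, for `K = 0, ..., d`; `d` is the maximum
#' finite shortest-path length over all pairs (0 for an edgeless graph).
#' Unreachable nodes are never counted.
#'
#' @param net a [binary_network()] or 0/1 adjacency matrix.
#' @return list with `N` (integer nodes x (d+1) matrix, columns named
#'   `K0..Kd`) and `d`.
#' @export
k_order_numbers <- function(net) {
  D <- shortest_path_lengths(net)
  finite <- D[is.finite(D)]
  d <- as.integer(max(finite))
  N <- vapply(0:d, function(K) as.integer(rowSums(D <= K)), integer(nrow(D)))
  if (nrow(D) == 1) N <- matrix(N, nrow = 1)
  dimnames(N) <- list(rownames(D), paste0("K", 0:d))
  list(N = N, d = d)
}

#' Structure entropy of one propagation order
#'
#' Shannon entropy (nats) of the node-share distribution
#' `p_v = N[v] / sum(N)`. Since every `N[v] >= 1`, all shares are positive
#' and `0 < H <= log(n)`, with equality at the uniform distribution (always
#' the case at `K = 0`).
#'
#' @param n_k numeric vector of K-order propagation numbers (all >= 1).
#' @return entropy in nats.
#' @export
structure_entropy <- function(n_k) {
  if (any(n_k < 1)) stop("propagation numbers must be >= 1", call. = FALSE)
  p <- n_k / sum(n_k)
  -sum(p * log(p))
}

.normalize_weights <- function(h, normalization, invert) {
  if (invert) {
    # interpret large H_K as "orders that discriminate nodes less":
    # weight by the complement of the normalized entropy
    w <- 1 - h / sum(h)
    if (sum(w) == 0) w <- rep(1, length(h))  # single order: fall back to uniform
  } else if (normalization == "minmax") {
    w <- (h - min(h)) / if (diff(range(h)) > 0) diff(range(h)) else 1
    if (sum(w) == 0) w <- rep(1, length(h))
  } else {
    w <- h
  }
  w / sum(w)
}

.normalize_shares <- function(N, normalization) {
  if (normalization == "minmax") {
    S <- apply(N, 2, function(col) {
      r <- diff(range(col))
      s <- if (r > 0) (col - min(col)) / r else rep(1, length(col))
      if (sum(s) == 0) s <- rep(1, length(col))
      s / sum(s)
    })
    if (nrow(N) == 1) S <- matrix(S, nrow = 1)
    dimnames(S) <- dimnames(N)
    S
  } else {
    sweep(N, 2, colSums(N), "/")
  }
}

#' WKPN node importance
#'
#' Computes the full importance profile of a binary network: K-order
#' propagation numbers `N`, per-order structure entropies `H`, entropy
#' weights `c` (summing to 1), per-order node shares `S` (each column summing
#' to 1), importance scores `Q = S %*% c` (summing to 1), and the ranking of
#' nodes by decreasing `Q` with ties broken by node-label order.
#'
#' @param net a [binary_network()] or 0/1 adjacency matrix.
#' @param normalization `"sum"` (default; shares of the column/row totals) or
#'   `"minmax"` (min-max scaled then renormalized to sum 1).
#' @param invert_weights if `TRUE`, weight each order by the complement of its
#'   normalized entropy instead of the entropy itself (large-H orders are the
#'   ones where node importances differ least; the default follows the
#'   literal entropy weighting).
#' @return object of class `importance_profile` with fields `N`, `H`, `c`,
#'   `S`, `Q`, `ranking`, `d`, `node_labels`.
#' @export
node_importance <- function(net, normalization = c("sum", "minmax"),
                            invert_weights = FALSE) {
  normalization <- match.arg(normalization)
  ko <- k_order_numbers(net)
  labs <- rownames(ko$N)
  H <- apply(ko$N, 2, structure_entropy)
  if (length(labs) == 1) {
    # single-node graph: trivially the only node carries all importance
    prof <- list(N = ko$N, H = H, c = 1, S = matrix(1, 1, 1, dimnames = dimnames(ko$N)),
                 Q = stats::setNames(1, labs), ranking = labs, d = ko$d,
                 node_labels = labs, normalization = normalization,
                 invert_weights = invert_weights)
    return(structure(prof, class = "importance_profile"))
  }
  cw <- .normalize_weights(H, normalization, invert_weights)
  S <- .normalize_shares(ko$N, normalization)
  Q <- as.numeric(S %*% cw)
  names(Q) <- labs
  ranking <- labs[order(-Q, labs)]
  structure(list(N = ko$N, H = H, c = cw, S = S, Q = Q, ranking = ranking,
                 d = ko$d, node_labels = labs, normalization = normalization,
                 invert_weights = invert_weights),
            class = "importance_profile")
}

#' @export
print.importance_profile <- function(x, n = 5, ...) {
  cat(sprintf("<importance_profile> %d nodes, d = %d, top nodes: %s\n",
              length(x$Q), x$d,
              paste(utils::head(x$ranking, n), collapse = ", ")))
  invisible(x)
}

#' Mark the most important nodes
#'
#' Min-max normalizes the importance scores to `[0, 1]` and marks the nodes
#' whose normalized importance strictly exceeds the threshold.
#'
#' @param profile an [node_importance()] profile (or named numeric `Q`).
#' @param threshold marking threshold on the normalized score (default 0.8).
#' @return object of class `marked_importance`: list with `normalized`
#'   (named vector in `[0, 1]`) and `marked` (character labels).
#' @export
mark_nodes <- function(profile, threshold = 0.8) {
  q <- if (inherits(profile, "importance_profile")) profile$Q else profile
  if (length(q) < 2) stop("need at least 2 nodes", call. = FALSE)
  r <- diff(range(q))
  if (r == 0) {
    warning("constant importance scores: no nodes marked")
    normalized <- stats::setNames(rep(0, length(q)), names(q))
    return(structure(list(normalized = normalized, marked = character(0),
                          threshold = threshold), class = "marked_importance"))
  }
  normalized <- (q - min(q)) / r
  structure(list(normalized = normalized,
                 marked = names(q)[normalized > threshold],
                 threshold = threshold),
            class = "marked_importance")
}

#' Weighted degree centrality (node strength)
#'
#' Sum of incident edge weights per node (plain degree on a binary network).
#'
#' @param net a [plv_matrix()], [binary_network()] or weight matrix.
#' @return named numeric vector of node strengths.
#' @export
wdc <- function(net) {
  w <- .as_adjacency(net)
  diag(w) <- 0
  rowSums(w)
}

#' Weighted PageRank
#'
#' PageRank on the undirected weighted graph: each edge acts as two directed
#' arcs with transition probability proportional to its weight. Solved by
#' power iteration; nodes with zero strength redistribute uniformly.
#'
#' @param net a [plv_matrix()], [binary_network()] or weight matrix.
#' @param damping damping factor (default 0.85).
#' @param tol L1 convergence tolerance (default 1e-9).
#' @param max_iter iteration cap; exceeding it is an error.
#' @return named numeric vector of scores summing to 1.
#' @export
wpr <- function(net, damping = 0.85, tol = 1e-9, max_iter = 1e4) {
  w <- .as_adjacency(net)
  diag(w) <- 0
  n <- nrow(w)
  s <- rowSums(w)
  P <- w / ifelse(s > 0, s, 1)        # row-stochastic where strength > 0
  dangling <- s == 0
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    x_new <- damping * (as.numeric(x %*% P) + sum(x[dangling]) / n) +
      (1 - damping) / n
    if (sum(abs(x_new - x)) < tol) {
      names(x_new) <- rownames(w)
      return(x_new)
    }
    x <- x_new
  }
  stop("weighted PageRank did not converge", call. = FALSE)
}
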