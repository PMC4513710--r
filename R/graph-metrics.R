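# Graph measures of binary undirected networks: degree, clustering,
# characteristic path length, local efficiency, degree-preserving
# Markov-chain null ensembles and small-worldness.

.as_adj <- function(net) {
  a <- if (inherits(net, "binary_network")) net$adjacency else as.matrix(net)
  storage.mode(a) <- "double"
  if (!isTRUE(all.equal(a, t(a))) || any(diag(a) != 0) ||
      !all(a %in% c(0, 1)))
    stop("expected a binary symmetric adjacency matrix with zero diagonal")
  a
}

# all-pairs shortest-path matrix by boolean matrix powers; Inf where
# unreachable, 0 on the diagonal.  Fast for the dense 64-node case.
.dist_matrix <- function(a) {
  n <- nrow(a)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[a > 0] <- 1
  diag(D) <- 0
  cur <- a > 0
  d <- 1
  repeat {
    nxt <- (cur %*% a) > 0
    new <- nxt & !is.finite(D)
    diag(new) <- FALSE
    if (!any(new)) break
    d <- d + 1
    D[new] <- d
    cur <- nxt
  }
  D
}

#' Node degrees and mean degree
#'
#' @param net A `binary_network` or adjacency matrix.
#' @return List with per-node `degrees` and scalar `mean_degree`
#'   (= `2 |edges| / N`).
#' @export
mean_degree <- function(net) {
  a <- .as_adj(net)
  d <- rowSums(a)
  list(degrees = d, mean_degree = mean(d))
}

#' Clustering coefficient
#'
#' `C_i = 2 E_i / (D_i (D_i - 1))` with `E_i` the number of edges among node
#' i's neighbours; nodes with degree <= 1 are assigned `C_i = 0` (the 0/0
#' convention of the Brain Connectivity Toolbox), and the mean is over all N
#' nodes.
#'
#' @param net A `binary_network` or adjacency matrix.
#' @return List with `per_node`, `triangles` (`E_i`) and scalar `mean`.
#' @export
clustering_coef <- function(net) {
  a <- .as_adj(net)
  d <- rowSums(a)
  e_i <- diag(a %*% a %*% a) / 2  # edges among neighbours of i
  c_i <- ifelse(d > 1, 2 * e_i / (d * (d - 1)), 0)
  list(per_node = c_i, triangles = e_i, mean = mean(c_i))
}

#' Characteristic path length
#'
#' Shortest paths by breadth-first expansion; per-node means `L_i` and the
#' characteristic path length `L` (mean of `L_i`) are taken over reachable
#' pairs only, and the number of unreachable (unordered) pairs is reported.
#'
#' @param net A `binary_network` or adjacency matrix.
#' @return List with the `distances` matrix, `per_node` `L_i`, scalar
#'   `mean` and `n_unreachable_pairs`.
#' @export
characteristic_path_length <- function(net) {
  a <- .as_adj(net)
  n <- nrow(a)
  if (sum(a) == 0)
    stop(errorCondition("path length undefined: graph has no edges",
                        class = c("plvnet_no_paths", "error", "condition")))
  D <- .dist_matrix(a)
  off <- D
  diag(off) <- NA
  l_i <- apply(off, 1, function(r) {
    r <- r[!is.na(r) & is.finite(r)]
    if (length(r)) mean(r) else NA_real_
  })
  n_unreach <- sum(is.infinite(off)) / 2
  list(distances = D, per_node = l_i, mean = mean(l_i, na.rm = TRUE),
       n_unreachable_pairs = n_unreach)
}

#' Local efficiency
#'
#' For each node the subgraph induced on its neighbours is formed;
#' `E(G_i)` is the mean over neighbour pairs of the inverse shortest-path
#' length within that subgraph (unreachable pairs contribute 0), and nodes
#' with fewer than two neighbours contribute 0.  `E_local` is the mean over
#' all N nodes.
#'
#' @param net A `binary_network` or adjacency matrix.
#' @return List with `per_node` efficiencies and scalar `mean`.
#' @export
local_efficiency <- function(net) {
  a <- .as_adj(net)
  n <- nrow(a)
  e_i <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) next
    sub <- a[nb, nb, drop = FALSE]
    Ds <- .dist_matrix(sub)
    inv <- 1 / Ds
    inv[!is.finite(inv)] <- 0  # unreachable
    diag(inv) <- 0
    e_i[i] <- sum(inv) / (length(nb) * (length(nb) - 1))
  }
  list(per_node = e_i, mean = mean(e_i))
}

#' All graph measures of one network
#'
#' @param net A `binary_network` or adjacency matrix.
#' @return A `graph_metrics` list: `mean_degree`, `clustering`,
#'   `path_length`, `local_efficiency`, `n_unreachable_pairs` plus the
#'   per-node vectors.
#' @export
graph_metrics <- function(net) {
  dg <- mean_degree(net)
  cl <- clustering_coef(net)
  pl <- tryCatch(characteristic_path_length(net),
                 plvnet_no_paths = function(e) {
                   list(per_node = NULL, mean = NA_real_,
                        n_unreachable_pairs = NA_real_)
                 })
  le <- local_efficiency(net)
  structure(list(mean_degree = dg$mean_degree, degrees = dg$degrees,
                 clustering = cl$mean, clustering_per_node = cl$per_node,
                 path_length = pl$mean, path_length_per_node = pl$per_node,
                 local_efficiency = le$mean,
                 local_efficiency_per_node = le$per_node,
                 n_unreachable_pairs = pl$n_unreachable_pairs),
            class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf(
    "Graph metrics: D = %.3f | C = %.4f | L = %.4f | E_local = %.4f (%s unreachable pairs)\n",
    x$mean_degree, x$clustering, x$path_length, x$local_efficiency,
    format(x$n_unreachable_pairs)))
  invisible(x)
}

#' Degree-preserving Markov-chain null ensemble
#'
#' Each null network is produced by repeated double-edge swaps: two edges
#' `(a, b)` and `(c, d)` with four distinct endpoints and no pre-existing
#' `(a, d)` or `(c, b)` are rewired to `(a, d)`, `(c, b)`.  The swap budget
#' is `swap_factor * |edges|` attempted swaps per network; the degree
#' sequence is preserved exactly.
#'
#' @param net A `binary_network` or adjacency matrix.
#' @param n_random Ensemble size (default 100).
#' @param seed Integer seed.
#' @param swap_factor Attempted swaps per edge (default 10).
#' @return List of adjacency matrices.
#' @export
null_ensemble <- function(net, n_random = 100, seed = 1, swap_factor = 10) {
  a0 <- .as_adj(net)
  e0 <- which(upper.tri(a0) & a0 == 1, arr.ind = TRUE)
  if (nrow(e0) < 2) stop("need at least 2 edges for degree-preserving swaps")
  set.seed(seed)
  n_attempt <- swap_factor * nrow(e0)
  out <- vector("list", n_random)
  any_success <- FALSE
  for (r in seq_len(n_random)) {
    a <- a0
    edges <- e0
    m <- nrow(edges)
    pick <- matrix(sample.int(m, 2 * n_attempt, replace = TRUE),
                   ncol = 2)
    flip <- matrix(runif(2 * n_attempt) < 0.5, ncol = 2)
    for (s in seq_len(n_attempt)) {
      i1 <- pick[s, 1]; i2 <- pick[s, 2]
      if (i1 == i2) next
      ab <- edges[i1, ]; cd <- edges[i2, ]
      if (flip[s, 1]) ab <- rev(ab)
      if (flip[s, 2]) cd <- rev(cd)
      a_ <- ab[1]; b_ <- ab[2]; c_ <- cd[1]; d_ <- cd[2]
      if (length(unique(c(a_, b_, c_, d_))) < 4) next
      if (a[a_, d_] == 1 || a[c_, b_] == 1) next
      a[a_, b_] <- a[b_, a_] <- 0
      a[c_, d_] <- a[d_, c_] <- 0
      a[a_, d_] <- a[d_, a_] <- 1
      a[c_, b_] <- a[b_, c_] <- 1
      edges[i1, ] <- sort(c(a_, d_))
      edges[i2, ] <- sort(c(c_, b_))
      any_success <- TRUE
    }
    out[[r]] <- a
  }
  if (!any_success)
    warning("no legal degree-preserving swap found; returning copies")
  out
}

#' Small-worldness against a null ensemble
#'
#' `gamma = C / C_random`, `lambda = L / L_random`, `S = gamma / lambda`,
#' with `C_random`, `L_random` the ensemble means of the null networks'
#' clustering and characteristic path length (same reachable-pairs
#' convention throughout).  `S > 1` indicates small-world organization.
#'
#' @param net A `binary_network` or adjacency matrix.
#' @param nulls Non-empty list of null adjacency matrices
#'   ([null_ensemble()]).
#' @param seed Seed recorded in the summary (provenance only).
#' @return A `null_summary` with `C`, `L`, `C_random`, `L_random`, `gamma`,
#'   `lambda`, `S`, the per-null values and the ensemble size.
#' @export
small_worldness <- function(net, nulls, seed = NA_integer_) {
  if (!length(nulls)) stop("null ensemble must be non-empty")
  cl <- clustering_coef(net)$mean
  pl <- characteristic_path_length(net)$mean
  c_r <- vapply(nulls, function(x) clustering_coef(x)$mean, numeric(1))
  l_r <- vapply(nulls, function(x) characteristic_path_length(x)$mean,
                numeric(1))
  C_random <- mean(c_r)
  L_random <- mean(l_r)
  if (C_random == 0)
    stop(errorCondition("small-worldness undefined: null ensemble has zero clustering",
                        class = c("plvnet_null_degenerate", "error",
                                  "condition")))
  gamma <- cl / C_random
  lambda <- pl / L_random
  structure(list(C = cl, L = pl, C_random = C_random, L_random = L_random,
                 gamma = gamma, lambda = lambda, S = gamma / lambda,
                 per_null_C = c_r, per_null_L = l_r,
                 ensemble_size = length(nulls), seed = seed),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf(
    "Small-worldness vs %d nulls: C = %.4f (C_rand %.4f), L = %.4f (L_rand %.4f)\n  gamma = %.3f, lambda = %.3f, S = %.3f\n",
    x$ensemble_size, x$C, x$C_random, x$L, x$L_random, x$gamma, x$lambda,
    x$S))
  invisible(x)
}
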