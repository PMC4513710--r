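# Conversion of weighted connectivity matrices to binary undirected networks
# over the connection-density ladder (5 % to 100 % in 5 % steps).

# round half away from zero, so edge counts are reproducible across platforms
.round_half_up <- function(x) floor(x + 0.5)

#' Threshold a connectivity matrix at a connection density
#'
#' Keeps the `k = round(density_pct/100 * M)` strongest of the
#' `M = N(N-1)/2` upper-triangle weights (half-up rounding).  Ties are broken
#' deterministically: descending weight, then ascending `(i, j)` index pair.
#'
#' @param weights A `connectivity_matrix` or a plain symmetric numeric
#'   matrix.
#' @param density_pct Density in percent, in `(0, 100]`.
#' @return A `binary_network`: binary symmetric `adjacency` with zero
#'   diagonal, `density_pct` and provenance metadata.
#' @export
threshold_by_density <- function(weights, density_pct) {
  stopifnot(density_pct > 0, density_pct <= 100)
  meta <- list(band = NULL, condition = NULL, subject_id = NULL)
  if (inherits(weights, "connectivity_matrix")) {
    meta <- weights[c("band", "condition", "subject_id")]
    w <- weights$weights
  } else {
    w <- as.matrix(weights)
  }
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  m <- nrow(ut)
  k <- .round_half_up(density_pct / 100 * m)
  if (k == 0) stop("density ", density_pct, " % yields zero edges")
  vals <- w[ut]
  ord <- order(-vals, ut[, 1], ut[, 2])
  sel <- ord[seq_len(k)]
  a <- matrix(0L, n, n, dimnames = dimnames(w))
  a[ut[sel, , drop = FALSE]] <- 1L
  a <- a + t(a)
  structure(list(adjacency = a, density_pct = density_pct,
                 band = meta$band, condition = meta$condition,
                 subject_id = meta$subject_id),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  n <- nrow(x$adjacency)
  cat("Binary network:", n, "nodes,", sum(x$adjacency) / 2, "edges (",
      x$density_pct, "% density)\n")
  invisible(x)
}

#' Binary networks across the 5-100 % density ladder
#'
#' Twenty networks at densities 5, 10, ..., 100 %.  Because thresholding
#' keeps the top-ranked edges under one deterministic ranking, the edge sets
#' are nested from sparse to dense.
#'
#' @param weights As [threshold_by_density()].
#' @param densities Density percentages (default `seq(5, 100, by = 5)`).
#' @export
density_ladder <- function(weights, densities = seq(5, 100, by = 5)) {
  lapply(densities, function(d) threshold_by_density(weights, d))
}

#' Write / read a binary network as an edge-list TSV
#'
#' Two columns `i`, `j` (1-based upper-triangle indices), one row per edge.
#'
#' @param net A `binary_network`.
#' @param path File path.
#' @export
write_network_tsv <- function(net, path) {
  e <- which(upper.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  utils::write.table(data.frame(i = e[, 1], j = e[, 2]), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @param n_nodes Node count of the stored network.
#' @export
read_network_tsv <- function(path, n_nodes) {
  e <- utils::read.table(path, sep = "\t", header = TRUE)
  a <- matrix(0L, n_nodes, n_nodes)
  a[cbind(e$i, e$j)] <- 1L
  a <- a + t(a)
  structure(list(adjacency = a, density_pct = NA_real_, band = NULL,
                 condition = NULL, subject_id = NULL),
            class = "binary_network")
}
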