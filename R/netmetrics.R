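# Validate a weight matrix: square, symmetric, nonnegative, zero diagonal.
check_weights <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("W must be a square matrix")
  if (any(W < 0)) stop("W must be nonnegative")
  if (max(abs(W - t(W))) > 1e-12) stop("W must be symmetric")
  if (any(diag(W) != 0)) stop("W must have a zero diagonal")
  invisible(W)
}

#' Nodal and global strength
#'
#' Nodal strength is the sum of a node's link weights; the global index is
#' the across-node mean of the nodal strengths. For PLV weights (each in
#' \[0, 1\]) the global strength lies in \[0, N-1\].
#'
#' @param W symmetric nonnegative weight matrix with zero diagonal.
#' @return list with `nodal` (vector) and `global` (scalar).
#' @export
node_strength <- function(W) {
  check_weights(W)
  s <- rowSums(W)
  list(nodal = s, global = mean(s))
}

#' Weighted clustering coefficients
#'
#' Onnela-style weighted clustering: with weights normalized by the network
#' maximum, `w_hat = W / max(W)`, the nodal coefficient is the sum of
#' geometric-mean triangle intensities around the node divided by the number
#' of possible neighbor pairs `k_i (k_i - 1)` (`k_i` = count of nonzero
#' links); nodes with fewer than two links get 0. The global coefficient is
#' the across-node mean. Values lie in \[0, 1\] and index network
#' segregation.
#'
#' @param W symmetric nonnegative weight matrix with zero diagonal.
#' @return `nodal_cc`: numeric vector of per-node coefficients.
#' @export
nodal_cc <- function(W) {
  check_weights(W)
  mx <- max(W)
  if (mx == 0) {
    warning("all-zero weight matrix; clustering coefficients are 0")
    return(numeric(nrow(W)))
  }
  Wh <- (W / mx)^(1 / 3)
  num <- diag(Wh %*% Wh %*% Wh)
  k <- rowSums(W > 0)
  cc <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  as.numeric(cc)
}

#' @rdname nodal_cc
#' @return `global_cc`: the mean of the nodal coefficients.
#' @export
global_cc <- function(W) mean(nodal_cc(W))

#' Weighted shortest-path distances
#'
#' Link length is the reciprocal weight (`l_ij = 1 / w_ij`, infinite for
#' absent links — the standard mapping for PLV-weighted networks); pairwise
#' distances are Dijkstra shortest paths on those lengths, with zeros on the
#' diagonal and `Inf` between disconnected components.
#'
#' @param W symmetric nonnegative weight matrix with zero diagonal.
#' @return matrix of shortest-path distances.
#' @export
graph_distances <- function(W) {
  check_weights(W)
  n <- nrow(W)
  len <- 1 / W
  len[!is.finite(len)] <- 0              # igraph: 0 means "no edge" here
  g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  # igraph orders vertices as given; restore plain numeric matrix
  unname(d[seq_len(n), seq_len(n)])
}

#' Characteristic path length and global efficiency
#'
#' Path length is the mean shortest-path distance over node pairs with
#' finite distance; efficiency is the mean reciprocal distance over all
#' pairs (disconnected pairs contribute 0). High efficiency / short path
#' length index an integrated network.
#'
#' @param d distance matrix from [graph_distances()].
#' @return list with `pl` and `efficiency`.
#' @export
path_length_and_efficiency <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  off <- d[row(d) != col(d)]
  fin <- off[is.finite(off)]
  if (!length(fin)) stop("all node pairs are disconnected")
  list(pl = mean(fin), efficiency = mean(ifelse(is.finite(off), 1 / off, 0)))
}

#' All weighted network indices of a connectivity matrix
#'
#' Convenience wrapper: global strength, global and nodal clustering
#' coefficients, characteristic path length and global efficiency of one
#' weight matrix (no thresholding or binarization — the full weighted
#' network is used).
#'
#' @param W a weight matrix or a `conn_matrix` from [plv_matrix()].
#' @return list with `strength`, `cc`, `pl`, `efficiency`, `nodal_cc`.
#' @export
network_indices <- function(W) {
  if (inherits(W, "conn_matrix")) W <- W$W
  check_weights(W)
  s <- node_strength(W)
  ncc <- nodal_cc(W)
  pe <- path_length_and_efficiency(graph_distances(W))
  list(strength = s$global, cc = mean(ncc), pl = pe$pl,
       efficiency = pe$efficiency, nodal_cc = ncc)
}
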