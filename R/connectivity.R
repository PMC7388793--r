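#' Instantaneous phase via the analytic signal
#'
#' Phase of the analytic signal (the signal plus i times its quadrature,
#' built with the FFT Hilbert construction), in (-pi, pi]. The input should
#' already be band-limited (output of [bandpass_filter()]); phase of a
#' broadband signal is not meaningful.
#'
#' @param x numeric vector, or matrix with one signal per row.
#' @return phase series (radians), same shape as `x`.
#' @export
instantaneous_phase <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  if (any(rowSums(x != 0) == 0))
    stop("phase undefined for an all-zero signal")
  ph <- t(Arg(analytic_cols(t(x))))
  if (vec) ph[1, ] else ph
}

# Analytic signal of each column (FFT Hilbert construction).
analytic_cols <- function(x) {
  x + 1i * hilbert_cols(x)
}

# Hilbert transform (imaginary part of the analytic signal) of each real
# column, packing column pairs into one complex FFT: for real x1, x2 the
# analytic operator is complex-linear, so T(x1 + i x2) = A1 + i A2 and the
# two transforms unpack as h1 = Im(S) - x2, h2 = x1 - Re(S).
hilbert_cols <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  x2 <- if (m %% 2) cbind(x, 0) else x
  odd <- seq(1L, ncol(x2), 2L)
  even <- odd + 1L
  Y <- x2[, odd, drop = FALSE] + 1i * x2[, even, drop = FALSE]
  S <- stats::mvfft(stats::mvfft(Y) * h, inverse = TRUE) / n
  H <- matrix(0, n, ncol(x2))
  H[, odd] <- Im(S) - x2[, even, drop = FALSE]
  H[, even] <- x2[, odd, drop = FALSE] - Re(S)
  H[, seq_len(m), drop = FALSE]
}

#' Phase-locking value of two phase series
#'
#' `PLV = | mean_t exp(i (phi_i(t) - phi_j(t))) |`: 1 for perfectly locked
#' phases (any constant lag), 0 for phase differences spread uniformly on
#' the circle.
#'
#' @param phase_i,phase_j phase series (radians), equal length >= 2.
#' @return scalar in \[0, 1\].
#' @export
plv <- function(phase_i, phase_j) {
  if (length(phase_i) != length(phase_j))
    stop("phase series must have equal length")
  if (length(phase_i) < 2) stop("need at least 2 samples")
  d <- phase_i - phase_j
  sqrt(mean(cos(d))^2 + mean(sin(d))^2)
}

#' Band-limited PLV connectivity matrix
#'
#' Per kept epoch: band-pass every node time series (3rd-order zero-phase
#' Butterworth), extract instantaneous phases, drop `edge_trim` of the
#' samples at each epoch edge (quadrature-transform edge artifacts), and
#' compute all pairwise PLVs over the remaining samples. The matrix is the
#' arithmetic mean over epochs: symmetric, zero diagonal, entries in
#' \[0, 1\]. Zero-lag phase relations are not excluded.
#'
#' @param node_epochs array n_epochs x n_nodes x samples (e.g. from
#'   [apply_inverse()]), or a single n_nodes x samples matrix.
#' @param fs sampling rate (Hz).
#' @param band band name, `c(lo, hi)` pair, or band data-frame row.
#' @param edge_trim fraction of samples discarded at each epoch edge before
#'   the PLV sum (default 0.1).
#' @return object of class `conn_matrix` with elements `W`, `band`,
#'   `n_epochs`.
#' @export
plv_matrix <- function(node_epochs, fs, band, edge_trim = 0.1) {
  if (is.matrix(node_epochs))
    node_epochs <- array(node_epochs, c(1, dim(node_epochs)))
  stopifnot(length(dim(node_epochs)) == 3)
  n_ep <- dim(node_epochs)[1]
  n_nodes <- dim(node_epochs)[2]
  ns <- dim(node_epochs)[3]
  # batch all epochs: one samples x (nodes * epochs) matrix
  X <- matrix(aperm(node_epochs, c(3, 2, 1)), nrow = ns)
  plv_core(X, n_nodes, n_ep, fs, band, edge_trim)
}

# PLV work-horse on pre-shaped data (columns = nodes within epochs).
plv_core <- function(X, n_nodes, n_ep, fs, band, edge_trim) {
  b <- band_lookup(band)
  ns <- nrow(X)
  trim <- floor(edge_trim * ns)
  keep <- (trim + 1L):(ns - trim)
  zero <- which(colSums(X != 0) == 0)
  if (length(zero))
    stop("all-zero node series (node ",
         paste(unique((zero - 1L) %% n_nodes + 1L), collapse = ", "),
         ") in epoch ", paste(unique((zero - 1L) %/% n_nodes + 1L),
                              collapse = ", "))
  d <- butter_design(3, c(b$lo, b$hi) / (fs / 2), "pass")
  Xf <- filtfilt_zi(d$b, d$a, X)
  # unit phasors of the analytic signal (cos/sin of the instantaneous phase)
  Hf <- hilbert_cols(Xf)[keep, , drop = FALSE]
  Xf <- Xf[keep, , drop = FALSE]
  Mo <- sqrt(Xf^2 + Hf^2)
  Mo[Mo == 0] <- .Machine$double.xmin
  Cn <- Xf / Mo
  Sn <- Hf / Mo
  i1 <- seq_len(n_nodes)
  i2 <- n_nodes + i1
  acc <- matrix(0, n_nodes, n_nodes)
  for (e in seq_len(n_ep)) {
    cols <- ((e - 1L) * n_nodes + 1L):(e * n_nodes)
    # one Gram matrix gives all cos/sin cross-sums over time
    P <- crossprod(cbind(Cn[, cols, drop = FALSE], Sn[, cols, drop = FALSE]))
    Re <- P[i1, i1] + P[i2, i2]
    M <- P[i2, i1]
    Im <- M - t(M)
    acc <- acc + sqrt(Re^2 + Im^2)
  }
  W <- acc / (n_ep * length(keep))
  diag(W) <- 0
  W <- (W + t(W)) / 2
  W[W > 1] <- 1
  structure(list(W = W, band = b, n_epochs = n_ep), class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  off <- x$W[upper.tri(x$W)]
  cat(sprintf(
    "<conn_matrix> %s band (%g-%g Hz), %d nodes, %d epochs, mean PLV %.3f\n",
    x$band$name, x$band$lo, x$band$hi, nrow(x$W), x$n_epochs, mean(off)))
  invisible(x)
}
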