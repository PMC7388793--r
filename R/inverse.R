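#' Diagonal noise covariance from screened epochs
#'
#' Per-sensor noise variances pooled over all kept epochs (each epoch is
#' demeaned per channel before pooling); off-diagonal covariance is
#' discarded by construction. Only the non-EOG channels are used.
#'
#' @param es an [epoch_set()] with at least one kept epoch.
#' @return named numeric vector of per-sensor variances.
#' @export
estimate_noise_cov <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  kept <- kept_epochs(es)
  if (!length(kept)) stop("no kept epochs")
  ei <- which(!(es$labels %in% es$eog_channels))
  ss <- numeric(length(ei))
  ntot <- 0L
  for (e in kept) {
    x <- es$epochs[e, ei, , drop = TRUE]
    x <- x - rowMeans(x)
    ss <- ss + rowSums(x^2)
    ntot <- ntot + ncol(x)
  }
  v <- ss / (ntot - length(kept))
  if (any(v <= 0))
    stop("degenerate noise covariance: constant sensor(s) ",
         paste(es$labels[ei][v <= 0], collapse = ", "))
  setNames(v, es$labels[ei])
}

#' Depth-weighted minimum-L2-norm inverse operator
#'
#' Builds the linear kernel `K = R L' (L R L' + lambda2 C)^-1` of the
#' depth-weighted minimum-norm estimator, where `L` is the leadfield,
#' `C = diag(noise_variances)` and the source prior
#' `R = diag(||l_i||^(-2 gamma))` is scaled so `trace(L R L') = trace(C)`.
#' `J = K M` then minimizes
#' `||C^(-1/2) (M - L J)||^2 + lambda2 ||R^(-1/2) J||^2`. The depth
#' exponent `gamma` counteracts the superficial bias of the plain minimum
#' norm; `lambda2 = 1 / snr^2` follows the usual regularization convention.
#'
#' @param fm a [make_forward_model()] object (provides `L`).
#' @param noise_variances per-sensor variances (see [estimate_noise_cov()]).
#' @param gamma depth-weighting exponent (>= 0; default 0.6, calibrated for
#'   balanced deep/shallow recovery in the spherical geometry).
#' @param snr assumed amplitude signal-to-noise ratio (> 0; default 3).
#' @return object of class `inverse_operator` with elements `kernel`
#'   (n_sources x n_sensors), `lambda2`, `gamma`, `noise_variances`.
#' @export
build_inverse_operator <- function(fm, noise_variances, gamma = 0.6,
                                   snr = 3) {
  stopifnot(inherits(fm, "forward_model"), gamma >= 0, snr > 0)
  L <- fm$gain
  if (length(noise_variances) != nrow(L))
    stop("need one noise variance per sensor")
  if (any(noise_variances <= 0)) stop("noise variances must be positive")
  lambda2 <- 1 / snr^2
  r <- colSums(L^2)^(-gamma)              # ||l_i||^(-2*gamma)
  LR <- L * rep(r, each = nrow(L))        # L R
  G <- LR %*% t(L)                        # L R L'
  r <- r * sum(noise_variances) / sum(diag(G))
  G <- G * (sum(noise_variances) / sum(diag(G)))
  A <- G + lambda2 * diag(noise_variances, nrow(L))
  K <- tryCatch(t(solve(A, L * rep(r, each = nrow(L)))),
                error = function(e) stop("singular inverse system: ",
                                         conditionMessage(e)))
  structure(list(kernel = K, lambda2 = lambda2, gamma = gamma,
                 noise_variances = noise_variances),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf(
    "<inverse_operator> %d sources x %d sensors (gamma=%g, lambda2=%g)\n",
    nrow(x$kernel), ncol(x$kernel), x$gamma, x$lambda2))
  invisible(x)
}

#' Apply an inverse operator and extract node time series
#'
#' Computes the source estimate `J = K M` for every kept epoch and returns
#' the rows of `J` at the forward model's node seed sources (one seed source
#' per parcel — the regional representative is the seed's own time series,
#' not a parcel average). EOG channels are dropped before applying the
#' kernel.
#'
#' @param op an [build_inverse_operator()] result.
#' @param es an [epoch_set()]; only kept epochs are mapped.
#' @param fm the [make_forward_model()] used to build `op`.
#' @return numeric array, n_kept_epochs x n_nodes x epoch_samples.
#' @export
apply_inverse <- function(op, es, fm) {
  stopifnot(inherits(op, "inverse_operator"), inherits(es, "epoch_set"),
            inherits(fm, "forward_model"))
  ei <- which(!(es$labels %in% es$eog_channels))
  if (length(ei) != ncol(op$kernel))
    stop("sensor count (", length(ei),
         ") does not match inverse kernel (", ncol(op$kernel), ")")
  Kn <- op$kernel[fm$node_seeds, , drop = FALSE]
  kept <- kept_epochs(es)
  if (!length(kept)) stop("no kept epochs")
  ns <- dim(es$epochs)[3]
  out <- array(NA_real_, c(length(kept), nrow(Kn), ns))
  for (i in seq_along(kept)) {
    out[i, , ] <- Kn %*% es$epochs[kept[i], ei, , drop = TRUE]
  }
  out
}
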