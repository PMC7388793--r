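#' @title Zero-phase IIR filtering
#' @description Internal filtering core shared by the preprocessing and
#'   spectral layers. Filter design is delegated to [signal::butter()]; the
#'   forward-backward application uses steady-state initial conditions and
#'   odd-reflection padding so that edge transients are suppressed (a constant
#'   input maps to ~0 for a high-pass, and passband sinusoids keep their
#'   amplitude up to the signal edges).
#' @name filters-internal
#' @keywords internal
NULL

# Steady-state initial state of a direct-form-II-transposed filter for a unit
# step input: solve (I - A) zi = B with A the transposed companion matrix.
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  a <- c(a, rep(0, nf - length(a)))
  b <- c(b, rep(0, nf - length(b)))
  b <- b / a[1]
  a <- a / a[1]
  n <- nf - 1L
  if (n == 0L) return(numeric(0))
  comp <- matrix(0, n, n)
  comp[1, ] <- -a[-1]
  if (n > 1L) comp[cbind(2:n, 1:(n - 1))] <- 1
  A <- t(comp)
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n) - A, B)
}

#' Zero-phase (forward-backward) IIR filter
#'
#' Applies an IIR filter forward and backward so the net phase response is
#' zero. The input is extended at both ends by odd reflection and the filter
#' state is initialized at its step-response steady state, which removes the
#' start-up transients a naive two-pass application leaves behind.
#'
#' @param b,a numerator / denominator filter coefficients (e.g. from
#'   [signal::butter()]).
#' @param x numeric vector, or matrix with one signal per column
#'   (samples in rows).
#' @return filtered data, same shape as `x`.
#' @keywords internal
filtfilt_zi <- function(b, a, x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  padlen <- 3L * max(length(a), length(b))
  if (nrow(x) <= padlen + 1L)
    stop("signal too short for zero-phase filtering (need > ", padlen + 1L,
         " samples)")
  y <- filtfilt_cpp(b, a, x, lfilter_zi(b, a), padlen)
  if (vec) y[, 1] else y
}

# Butterworth designs (normalized to Nyquist), cached per parameter set.
butter_design <- function(order, w, type) {
  flt <- signal::butter(order, w, type = type)
  list(b = as.numeric(flt$b), a = as.numeric(flt$a))
}
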