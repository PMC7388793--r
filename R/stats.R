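#' ANCOVA group comparison of one network measure
#'
#' Fits `value ~ group + covariate` and tests the group term against the
#' covariate-only model:
#' `F = ((SSE_reduced - SSE_full) / df_group) / (SSE_full / df_resid)`,
#' with partial eta squared `SS_group / (SS_group + SS_resid)` as the effect
#' size and the p value from the F distribution (two-tailed by
#' construction). Raw group means and SDs are reported alongside.
#'
#' @param values numeric vector, one scalar measure per subject.
#' @param group factor or character group label per subject.
#' @param covariate numeric covariate per subject (e.g. premorbid IQ).
#' @return object of class `group_comparison`: `F`, `df`, `p`,
#'   `partial_eta2`, `group_stats` (mean, sd, n per group), plus the fitted
#'   full model.
#' @export
ancova_group_compare <- function(values, group, covariate) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("need at least 2 subjects per group")
  if (!all(is.finite(values)) || !all(is.finite(covariate)))
    stop("values and covariate must be finite")
  dat <- data.frame(y = values, g = group, x = covariate)
  full <- lm(y ~ g + x, data = dat)
  red <- lm(y ~ x, data = dat)
  if (any(!is.finite(coef(full))))
    stop("singular design: covariate collinear with group")
  sse_f <- sum(residuals(full)^2)
  sse_r <- sum(residuals(red)^2)
  df_g <- nlevels(group) - 1L
  df_r <- nrow(dat) - nlevels(group) - 1L
  ss_g <- sse_r - sse_f
  Fstat <- (ss_g / df_g) / (sse_f / df_r)
  gs <- do.call(rbind, lapply(levels(group), function(l) {
    v <- values[group == l]
    data.frame(group = l, mean = mean(v), sd = sd(v), n = length(v))
  }))
  structure(list(F = Fstat, df = c(df_g, df_r),
                 p = pf(Fstat, df_g, df_r, lower.tail = FALSE),
                 partial_eta2 = ss_g / (ss_g + sse_f),
                 group_stats = gs, model = full),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> F(%d, %d) = %.3f, p = %.4g, partial eta2 = %.3f\n",
              x$df[1], x$df[2], x$F, x$p, x$partial_eta2))
  print(x$group_stats, row.names = FALSE)
  invisible(x)
}

#' Bonferroni-adjusted significance threshold
#'
#' `alpha / m`. The two families used by the pipeline are the global family
#' (4 network measures x 6 bands, m = 24, threshold 0.05/24 = 0.002083) and
#' the nodal family (148 nodal clustering coefficients, m = 148, threshold
#' 0.05/148 = 0.000338).
#'
#' @param alpha family-wise error rate.
#' @param m number of comparisons in the family (>= 1).
#' @return adjusted per-test threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' @rdname bonferroni_threshold
#' @return `bonferroni_families`: the pipeline's two family sizes.
#' @export
bonferroni_families <- function() c(global = 24L, nodal = 148L)

#' Covariate-adjusted post-hoc pairwise comparisons
#'
#' For each pair of groups, the covariate-adjusted mean difference from the
#' full ANCOVA model (a contrast of the group coefficients), its t test, and
#' the Bonferroni-corrected p value (multiplied by the number of pairs,
#' capped at 1). `direction` is the sign of the adjusted difference
#' (first minus second group).
#'
#' @inheritParams ancova_group_compare
#' @return data frame: `pair`, `diff`, `t`, `p_bonferroni`, `direction`.
#' @export
posthoc_pairwise <- function(values, group, covariate) {
  group <- factor(group)
  dat <- data.frame(y = values, g = group, x = covariate)
  full <- lm(y ~ g + x, data = dat)
  V <- vcov(full)
  cf <- coef(full)
  lv <- levels(group)
  df_r <- full$df.residual
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  m <- length(pairs)
  out <- do.call(rbind, lapply(pairs, function(p) {
    # contrast on the treatment-coded group coefficients
    v <- setNames(numeric(length(cf)), names(cf))
    n1 <- paste0("g", p[1]); n2 <- paste0("g", p[2])
    if (n1 %in% names(v)) v[n1] <- 1
    if (n2 %in% names(v)) v[n2] <- -1
    est <- sum(v * cf)
    se <- sqrt(drop(t(v) %*% V %*% v))
    tval <- est / se
    praw <- 2 * pt(-abs(tval), df_r)
    data.frame(pair = paste(p, collapse = " - "), diff = est, t = tval,
               p_bonferroni = min(1, m * praw),
               direction = sign(est), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Partial Pearson correlation with bootstrap confidence interval
#'
#' Residualizes `x` and `y` on the covariates (ordinary least squares with
#' intercept) and correlates the residuals. The p value uses the t transform
#' with `n - 2 - n_covariates` degrees of freedom (two-tailed). The
#' confidence interval is the percentile interval of the statistic over
#' `n_boot` resamples of subjects drawn with replacement (simple random
#' sampling), re-residualizing within each resample; the resampling stream
#' is fully determined by `seed`.
#'
#' @param x,y numeric vectors (one value per subject).
#' @param covariates optional numeric vector, matrix or data frame of
#'   covariates (e.g. medication dose, illness duration); `NULL` for a plain
#'   Pearson correlation.
#' @param n_boot number of bootstrap resamples (default 5000).
#' @param conf confidence level (default 0.95).
#' @param seed integer RNG seed.
#' @return object of class `correlation_result`: `r`, `p`, `ci95`,
#'   `n_boot`, `n`, `covariates` (labels).
#' @export
partial_pearson_bootstrap <- function(x, y, covariates = NULL,
                                      n_boot = 5000, conf = 0.95, seed = 1) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  Z <- NULL
  if (!is.null(covariates)) {
    Z <- as.matrix(as.data.frame(covariates))
    if (nrow(Z) != n) stop("covariates must have one row per subject")
  }
  k <- if (is.null(Z)) 0L else ncol(Z)
  if (n < k + 3L) stop("need at least n_covariates + 3 subjects")

  pcor <- function(xi, yi, Zi) {
    if (is.null(Zi)) {
      rx <- xi - mean(xi); ry <- yi - mean(yi)
    } else {
      D <- cbind(1, Zi)
      rx <- xi - D %*% solve(crossprod(D), crossprod(D, xi))
      ry <- yi - D %*% solve(crossprod(D), crossprod(D, yi))
    }
    sx <- sqrt(sum(rx^2)); sy <- sqrt(sum(ry^2))
    if (sx <= 1e-10 * sqrt(sum(xi^2)) || sy <= 1e-10 * sqrt(sum(yi^2)) ||
        sx == 0 || sy == 0)
      stop("zero residual variance after adjusting for covariates")
    sum(rx * ry) / (sx * sy)
  }

  r <- pcor(x, y, Z)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tval), df)

  set.seed(seed)
  if (is.null(Z)) {
    # vectorized: all resamples at once
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    X <- matrix(x[idx], nrow = n); Y <- matrix(y[idx], nrow = n)
    X <- X - rep(colMeans(X), each = n); Y <- Y - rep(colMeans(Y), each = n)
    num <- colSums(X * Y)
    den <- sqrt(colSums(X^2) * colSums(Y^2))
    rb <- ifelse(den > 0, num / den, NA_real_)
  } else {
    rb <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      tryCatch(pcor(x[i], y[i], Z[i, , drop = FALSE]),
               error = function(e) NA_real_)
    }, numeric(1))
  }
  a <- (1 - conf) / 2
  ci <- unname(quantile(rb, c(a, 1 - a), na.rm = TRUE))
  structure(list(r = r, p = p, ci95 = ci, n_boot = n_boot, n = n,
                 conf = conf,
                 covariates = if (is.null(Z)) character() else colnames(Z)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "<correlation_result> r = %.3f, p = %.4g, %g%% CI [%.3f, %.3f] (%d boots, n = %d)\n",
    x$r, x$p, 100 * x$conf, x$ci95[1], x$ci95[2], x$n_boot, x$n))
  if (length(x$covariates))
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}
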