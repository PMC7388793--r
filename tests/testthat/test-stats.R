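test_that("ANCOVA matches the matrix least-squares decomposition", {
  set.seed(1)
  for (rep in 1:5) {
    n <- 30
    g <- factor(rep(c("a", "b", "c"), each = 10))
    x <- rnorm(n, 100, 10)
    y <- 2 + 0.1 * x + (as.integer(g) == 3) * 1.5 + rnorm(n)
    cmp <- ancova_group_compare(y, g, x)
    Xf <- cbind(1, g == "b", g == "c", x)
    Xr <- cbind(1, x)
    sse <- function(X) sum((y - X %*% solve(crossprod(X), crossprod(X, y)))^2)
    ss_g <- sse(Xr) - sse(Xf)
    F_or <- (ss_g / 2) / (sse(Xf) / (n - 4))
    expect_lt(abs(cmp$F - F_or), 1e-8)
    expect_lt(abs(cmp$partial_eta2 - ss_g / (ss_g + sse(Xf))), 1e-10)
    expect_equal(cmp$p, pf(F_or, 2, n - 4, lower.tail = FALSE))
  }
})

test_that("a null group effect yields near-zero partial eta squared", {
  set.seed(2)
  y <- rep(c(5, 5, 5), each = 12) + 0   # identical means, no covariate link
  y <- y + rep(rnorm(12, sd = 1e-8), 3)
  cmp <- ancova_group_compare(y, rep(c("a", "b", "c"), each = 12), rnorm(36))
  expect_lt(cmp$partial_eta2, 0.2)
  expect_error(ancova_group_compare(rnorm(4), c("a", "a", "a", "b")[c(1, 2, 3, 4)],
                                    rnorm(4)), "2 subjects")
})

test_that("Bonferroni thresholds reproduce the two analysis families", {
  expect_equal(bonferroni_threshold(0.05, 24), 0.002083, tolerance = 1e-3)
  expect_equal(bonferroni_threshold(0.05, 148), 0.000338, tolerance = 1e-3)
  expect_equal(bonferroni_threshold(0.07, 1), 0.07)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
  expect_equal(unname(bonferroni_families()), c(24L, 148L))
})

test_that("post-hoc pairwise contrasts find the deviant group only", {
  set.seed(3)
  y <- c(rnorm(30, 10, 1), rnorm(30, 10, 1), rnorm(30, 20, 1))
  g <- rep(c("g1", "g2", "g3"), each = 30)
  cv <- rnorm(90)
  ph <- posthoc_pairwise(y, g, cv)
  expect_equal(ph$pair, c("g1 - g2", "g1 - g3", "g2 - g3"))
  expect_gt(ph$p_bonferroni[1], 0.05)
  expect_lt(ph$p_bonferroni[2], 1e-6)
  expect_lt(ph$p_bonferroni[3], 1e-6)
  expect_true(all(ph$p_bonferroni <= 1))
  expect_equal(ph$direction[2], -1)
  # swapping the two groups of a pair flips its direction
  g_sw <- ifelse(g == "g1", "g3", ifelse(g == "g3", "g1", "g2"))
  ph_sw <- posthoc_pairwise(y, g_sw, cv)
  expect_equal(ph_sw$direction[2], -ph$direction[2])
})

test_that("post-hoc contrasts agree with emmeans adjusted comparisons", {
  skip_if_not_installed("emmeans")
  set.seed(4)
  y <- c(rnorm(15, 1), rnorm(15, 2), rnorm(15, 2.5))
  g <- rep(c("a", "b", "c"), each = 15)
  cv <- rnorm(45)
  ph <- posthoc_pairwise(y, g, cv)
  fit <- lm(y ~ g + x, data = data.frame(y = y, g = factor(g), x = cv))
  em <- summary(pairs(emmeans::emmeans(fit, "g"), adjust = "bonferroni"))
  expect_equal(ph$diff, em$estimate, tolerance = 1e-10)
  expect_equal(ph$p_bonferroni, em$p.value, tolerance = 1e-10)
})

test_that("partial correlation residualizes covariates out", {
  x <- 1:20
  r <- partial_pearson_bootstrap(x, x + 0, n_boot = 200, seed = 1)
  expect_equal(r$r, 1)
  set.seed(5)
  z <- rnorm(100)
  x2 <- z + 0.01 * rnorm(100)           # x is (almost) the covariate
  y2 <- rnorm(100)
  r2 <- partial_pearson_bootstrap(x2, y2, covariates = data.frame(z = z),
                                  n_boot = 200, seed = 1)
  expect_lt(abs(r2$r), 0.1)
  expect_error(partial_pearson_bootstrap(z, z, covariates = data.frame(z = z),
                                         n_boot = 10, seed = 1),
               "zero residual variance")
})

test_that("bootstrap confidence intervals are seed-deterministic", {
  set.seed(6)
  x <- rnorm(34)
  y <- 0.5 * x + rnorm(34)
  a <- partial_pearson_bootstrap(x, y, n_boot = 2000, seed = 99)
  b <- partial_pearson_bootstrap(x, y, n_boot = 2000, seed = 99)
  expect_identical(a$ci95, b$ci95)
  expect_true(a$ci95[1] <= a$r && a$r <= a$ci95[2])
  # with covariates: looped path, still deterministic
  cv <- data.frame(z = rnorm(34))
  a2 <- partial_pearson_bootstrap(x, y, covariates = cv, n_boot = 500,
                                  seed = 7)
  b2 <- partial_pearson_bootstrap(x, y, covariates = cv, n_boot = 500,
                                  seed = 7)
  expect_identical(a2$ci95, b2$ci95)
})
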