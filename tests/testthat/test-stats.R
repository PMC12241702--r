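# factorial / mixed ANOVA, correlations, Fisher z, sensitivity analysis

test_that("two-way ANOVA matches a hand decomposition on a balanced toy", {
  # 2 x 2, n = 3 per cell
  y <- c(10, 11, 12,   14, 15, 16,   20, 19, 21,   30, 31, 29)
  g <- rep(c("a", "a", "b", "b"), each = 3)
  r <- rep(c("x", "y", "x", "y"), each = 3)
  out <- two_way_anova(y, g, r)
  # manual Type-III (= balanced textbook) decomposition
  cm <- matrix(c(11, 15, 20, 30), 2, byrow = TRUE)  # cell means
  gm <- mean(cm)
  ss_g <- 6 * sum((rowMeans(cm) - gm)^2)
  ss_r <- 6 * sum((colMeans(cm) - gm)^2)
  ss_int <- 3 * sum((cm - outer(rowMeans(cm) - gm, colMeans(cm) - gm, "+") -
                       gm)^2)
  ss_err <- sum((y - rep(t(cm), each = 3))^2)
  expect_equal(out$F[out$effect == "group"],
               (ss_g / 1) / (ss_err / 8), tolerance = 1e-10)
  expect_equal(out$F[out$effect == "region"],
               (ss_r / 1) / (ss_err / 8), tolerance = 1e-10)
  expect_equal(out$F[out$effect == "group:region"],
               (ss_int / 1) / (ss_err / 8), tolerance = 1e-10)
  expect_equal(out$partial_eta_sq[out$effect == "group"],
               ss_g / (ss_g + ss_err), tolerance = 1e-10)
  # algebraic identity eta_p^2 = F df_e / (F df_e + df_err)
  expect_equal(out$partial_eta_sq,
               out$F * out$df_effect /
                 (out$F * out$df_effect + out$df_error), tolerance = 1e-10)
  expect_equal(out$df_error[1], 8L)
})

test_that("constant response gives zero F everywhere; empty cells error", {
  out <- two_way_anova(rep(5, 12), rep(c("a", "b"), 6),
                       rep(c("x", "y"), each = 6))
  expect_true(all(out$F == 0))
  expect_error(two_way_anova(1:6, c("a", "a", "a", "a", "b", "b"),
                             c("x", "x", "y", "y", "x", "x")), "empty")
})

test_that("ANCOVA regresses out the covariate", {
  set.seed(8)
  cov <- rnorm(40)
  g <- rep(c("a", "b"), 20); r <- rep(c("x", "y"), each = 20)
  y <- 2 * cov + rnorm(40, sd = 0.1)   # response driven by covariate only
  out <- two_way_anova(y, g, r, covariate = cov)
  expect_lt(out$p[out$effect == "covariate"], 1e-10)
  expect_gt(out$p[out$effect == "group"], 0.05)
})

test_that("mixed ANOVA agrees with the independent aov error-stratum fit", {
  set.seed(14)
  n <- 24
  g <- rep(c("a", "b"), each = n / 2)
  r <- rep(c("x", "y"), n / 2)
  w1 <- rnorm(n, 3); w2 <- w1 - rnorm(n, 0.5, 0.3)
  out <- mixed_anova(cbind(w1, w2), g, r)
  long <- data.frame(y = c(w1, w2),
                     acc = factor(rep(c("c", "i"), each = n)),
                     g = factor(rep(g, 2)), rg = factor(rep(r, 2)),
                     id = factor(rep(seq_len(n), 2)))
  ref <- summary(stats::aov(y ~ acc * g * rg + Error(id / acc), data = long))
  within_tab <- ref[["Error: id:acc"]][[1]]
  wrow <- function(nm) within_tab[match(nm, trimws(rownames(within_tab))),
                                  "F value"]
  expect_equal(out$F[out$effect == "accuracy"], wrow("acc"),
               tolerance = 1e-8)
  expect_equal(out$F[out$effect == "accuracy:group"], wrow("acc:g"),
               tolerance = 1e-8)
  between_tab <- ref[["Error: id"]][[1]]
  expect_equal(out$F[out$effect == "group"],
               between_tab[match("g", trimws(rownames(between_tab))),
                           "F value"], tolerance = 1e-8)
  # identical within-levels kill the within effect (a degenerate-stratum
  # warning from the underlying epsilon computation is expected)
  out0 <- suppressWarnings(mixed_anova(cbind(w1, w1), g, r))
  expect_equal(out0$F[out0$effect == "accuracy"], 0)
  # subjects missing a level are dropped with a warning
  w2b <- w2; w2b[1] <- NA
  expect_warning(mixed_anova(cbind(w1, w2b), g, r), "excluded")
})

test_that("simulated metacognitive subjects show the accuracy effect", {
  co <- simulate_cohort(cohort_spec(n_per_group = 12L,
                                    region_split = c(A = 6L, B = 6L),
                                    seed = 55))
  ca <- confidence_by_accuracy(co$trials)
  expect_true(mean(ca$conf_correct - ca$conf_incorrect, na.rm = TRUE) > 0)
  out <- mixed_anova(ca[, c("conf_correct", "conf_incorrect")],
                     ca$group, ca$region)
  expect_lt(out$p[out$effect == "accuracy"], 0.05)
})

test_that("Spearman matches the rank formula and survives monotone maps", {
  expect_equal(spearman_corr(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_corr(1:8, -(1:8))$rho, -1)
  a <- c(1.37, -0.56, 0.36, 0.63, 0.4, -0.11, 1.51, -0.09, 2.02, -0.06)
  b <- c(2.67, 1.73, -1.03, 0.35, 0.27, 0.53, 1.23, -2.75, -0.42, 1.26)
  res <- spearman_corr(a, b)
  expect_equal(res$rho, -0.05454545455, tolerance = 1e-9)   # 1 - 6*sum(d^2)/(n(n^2-1))
  expect_equal(res$p, stats::cor.test(a, b, method = "spearman",
                                      exact = FALSE)$p.value,
               tolerance = 1e-9)
  expect_equal(spearman_corr(exp(a), atan(b))$rho, res$rho)
  expect_error(spearman_corr(rep(1, 6), 1:6), "zero rank variance")
  perm <- spearman_corr(a, b, permutation = TRUE, n_perm = 2000, seed = 3)
  expect_gt(perm$p, 0.5)   # null-ish fixture
})

test_that("partial Spearman follows the first-order formula", {
  x <- c(3, 1, 4, 1, 5, 9); y <- c(2, 7, 1, 8, 2, 8); z <- c(4, 5, 9, 2, 6, 5)
  res <- partial_spearman(x, y, z)
  expect_equal(res$rho, 0.371895282, tolerance = 1e-8)  # frozen residual-regression value
  expect_error(partial_spearman(x, y, x), "degenerate")
  # covariate unrelated to both: partial ~= simple
  set.seed(77)
  xx <- rnorm(2000); yy <- xx + rnorm(2000); zz <- rnorm(2000)
  expect_lt(abs(partial_spearman(xx, yy, zz)$rho -
                  spearman_corr(xx, yy)$rho), 0.05)
})

test_that("Fisher z reproduces printed transforms and inverts tanh", {
  expect_equal(round(fisher_z(0.384), 3), 0.405)
  expect_equal(round(fisher_z(-0.583), 3), -0.667)
  expect_equal(fisher_z(0), 0)
  expect_error(fisher_z(1), "< 1")
  zz <- seq(-3.9, 3.9, by = 0.3)
  expect_equal(fisher_z(tanh(zz)), zz, tolerance = 1e-12)
})

test_that("correlation comparison gives the printed Z and is antisymmetric", {
  c1 <- compare_correlations(0.384, 33, 0.033, 33)
  expect_equal(round(c1$z_observed, 2), 1.44)
  c2 <- compare_correlations(0.463, 33, 0.36, 33)
  expect_equal(round(c2$z_observed, 3), 0.481)
  swap <- compare_correlations(0.033, 33, 0.384, 33)
  expect_equal(swap$z_observed, -c1$z_observed)
  expect_equal(compare_correlations(0.5, 30, 0.5, 40)$z_observed, 0)
  expect_error(compare_correlations(0.5, 3, 0.5, 40), "n > 3")
})

test_that("sensitivity analysis matches the Poisson-mixture oracle", {
  sens <- anova_sensitivity(n_total = 66, alpha = 0.05, power = 0.80,
                            df_effect = 1, n_cells = 4)
  # the detectable effect for the two-site case-control frame
  expect_lt(abs(sens$f - 0.35), 0.01)
  # oracle: recompute power at the returned f via the central-F mixture
  crit <- qf(0.95, 1, 62)
  expect_equal(oracle_ncf_power(crit, 1, 62, 66 * sens$f^2), 0.80,
               tolerance = 1e-3)
  # power is monotone in n: doubling n shrinks the detectable f
  expect_lt(anova_sensitivity(132, n_cells = 4)$f, sens$f)
  # a power target at or below alpha is met by a null effect
  expect_equal(anova_sensitivity(66, power = 1e-4)$f, 0)
})
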