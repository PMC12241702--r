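# ---- inference layer -------------------------------------------------------

anova_table <- function(effects, ss_eff, ss_err, df_eff, df_err) {
  # an exactly-zero effect SS is reported as F = 0 even when the error SS
  # also vanishes (all-constant response), rather than 0/0
  f <- ifelse(ss_eff <= 1e-12, 0, (ss_eff / df_eff) / (ss_err / df_err))
  data.frame(effect = effects, F = f, df_effect = df_eff, df_error = df_err,
             p = stats::pf(f, df_eff, df_err, lower.tail = FALSE),
             partial_eta_sq = ifelse(ss_eff + ss_err <= 1e-12, 0,
                                     ss_eff / (ss_eff + ss_err)),
             stringsAsFactors = FALSE)
}

#' Two-way factorial ANOVA with partial eta squared
#'
#' Type-III sums of squares (sum-to-zero contrasts) for a group x region
#' layout, optionally with a numeric covariate regressed out (ANCOVA).
#' Partial eta squared is SS_effect / (SS_effect + SS_error).
#'
#' @param values Numeric response, one value per subject.
#' @param factor_group,factor_region Factors (coerced) of the same length.
#' @param covariate Optional numeric covariate.
#' @return Data frame of class `anova_result` with one row per effect:
#'   `effect, F, df_effect, df_error, p, partial_eta_sq`.
#' @export
two_way_anova <- function(values, factor_group, factor_region,
                          covariate = NULL) {
  g <- factor(factor_group); r <- factor(factor_region)
  if (any(table(g, r) == 0L)) abort("empty group x region cell")
  d <- data.frame(y = values, g = g, r = r)
  form <- y ~ g * r
  if (!is.null(covariate)) {
    d$cov <- as.numeric(covariate)
    form <- y ~ cov + g * r
  }
  if (stats::var(d$y) < 1e-24) {
    # constant response: every effect SS is exactly zero
    eff <- c(if (!is.null(covariate)) "covariate", "group", "region",
             "group:region")
    out <- anova_table(eff, rep(0, length(eff)), 0, rep(1L, length(eff)),
                       length(values) - length(eff) - 1L)
    class(out) <- c("anova_result", "data.frame")
    return(out)
  }
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- stats::lm(form, data = d)
  a3 <- car::Anova(fit, type = 3)
  keep <- setdiff(rownames(a3), c("(Intercept)", "Residuals"))
  ss_err <- a3["Residuals", "Sum Sq"]
  df_err <- a3["Residuals", "Df"]
  out <- anova_table(relabel_effects(keep), a3[keep, "Sum Sq"], ss_err,
                     a3[keep, "Df"], df_err)
  class(out) <- c("anova_result", "data.frame")
  out
}

# map model-term tokens to readable effect labels, within factor first
relabel_effects <- function(terms, within_name = NULL) {
  dict <- c(g = "group", r = "region", cov = "covariate", W = within_name)
  ord <- c(within_name, "covariate", "group", "region")
  vapply(terms, function(tm) {
    tok <- unname(dict[strsplit(tm, ":", fixed = TRUE)[[1]]])
    paste(tok[order(match(tok, ord))], collapse = ":")
  }, character(1), USE.NAMES = FALSE)
}

#' Mixed (split-plot) ANOVA on accuracy-conditioned confidence
#'
#' Repeated-measures ANOVA with one two-level within-subject factor
#' (typically mean confidence on correct vs incorrect responses) and two
#' between-subject factors, via the multivariate linear model route with
#' Type-III sums of squares. Every effect is reported with partial eta
#' squared against its own error stratum.
#'
#' @param within Two-column numeric matrix or data frame: per-subject means
#'   at the two within-levels (e.g. `cbind(correct, incorrect)`).
#' @param between_group,between_region Between-subject factors.
#' @param within_name Label for the within factor (default `"accuracy"`).
#' @return Data frame of class `anova_result`.
#' @export
mixed_anova <- function(within, between_group, between_region,
                        within_name = "accuracy") {
  w <- as.matrix(within)
  stopifnot(ncol(w) == 2L)
  keep_rows <- stats::complete.cases(w)
  if (!all(keep_rows)) {
    warning(sprintf("%d subject(s) missing a within-level mean; excluded",
                    sum(!keep_rows)))
    w <- w[keep_rows, , drop = FALSE]
    between_group <- between_group[keep_rows]
    between_region <- between_region[keep_rows]
  }
  g <- factor(between_group); r <- factor(between_region)
  d <- data.frame(g = g, r = r)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- stats::lm(w ~ g * r, data = d)
  idata <- data.frame(W = factor(c("L1", "L2")))
  av <- car::Anova(fit, idata = idata, idesign = ~W, type = 3)
  s <- summary(av, multivariate = FALSE)
  tab <- s$univariate.tests
  keep <- setdiff(rownames(tab), "(Intercept)")
  out <- anova_table(relabel_effects(keep, within_name),
                     tab[keep, "Sum Sq"], tab[keep, "Error SS"],
                     tab[keep, "num Df"], tab[keep, "den Df"])
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Per-subject mean confidence on correct and incorrect responses
#'
#' Aggregation step feeding [mixed_anova()]: one row per subject with the
#' two within-level means; subjects lacking correct or incorrect trials get
#' `NA` for the missing level.
#'
#' @param trials A multi-subject [trial_table()].
#' @return Data frame `subject_id, conf_correct, conf_incorrect` plus
#'   `group`/`region` when present.
#' @export
confidence_by_accuracy <- function(trials) {
  ids <- unique(trials$subject_id)
  rows <- lapply(ids, function(id) {
    tr <- trials[trials$subject_id == id, , drop = FALSE]
    out <- data.frame(
      subject_id = id,
      conf_correct = if (any(tr$correct)) mean(tr$confidence[tr$correct]) else NA_real_,
      conf_incorrect = if (any(!tr$correct)) mean(tr$confidence[!tr$correct]) else NA_real_,
      stringsAsFactors = FALSE)
    if (!is.null(tr$group)) out$group <- tr$group[1]
    if (!is.null(tr$region)) out$region <- tr$region[1]
    out
  })
  do.call(rbind, rows)
}

#' Spearman rank correlation
#'
#' Average ranks for ties; two-sided p from the t approximation
#' `t = rho * sqrt((n-2) / (1-rho^2))` on n-2 df (appropriate for the
#' n of a few dozen this layer targets), optionally a permutation p; the
#' Fisher transform `z = atanh(rho)` is reported alongside.
#'
#' @param x,y Paired numeric vectors, n >= 4.
#' @param permutation If `TRUE`, p by `n_perm` random permutations instead
#'   of the t approximation.
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation p-value.
#' @return List of class `corr_result`: `rho, z, p, n, method`.
#' @export
spearman_corr <- function(x, y, permutation = FALSE, n_perm = 10000L,
                          seed = 1L) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) abort("need at least 4 complete pairs")
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0)
    abort("zero rank variance")
  rho <- stats::cor(rank(x), rank(y))
  if (permutation) {
    obs <- abs(rho)
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i)
        abs(stats::cor(rank(x), rank(sample(y)))) >= obs - 1e-12,
        logical(1)))
    })
    p <- (hits + 1) / (n_perm + 1)
    method <- "permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    method <- "t-approximation"
  }
  structure(list(rho = rho, z = safe_fisher_z(rho), p = p, n = n,
                 method = method),
            class = "corr_result")
}

# atanh with signed infinity at |rho| = 1 (perfect rank agreement)
safe_fisher_z <- function(rho) {
  if (abs(rho) >= 1) sign(rho) * Inf else atanh(rho)
}

#' Partial Spearman correlation
#'
#' Rank-transforms all three variables, then the first-order partial
#' Pearson correlation on the ranks:
#' `(r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`.
#' Two-sided p from the t approximation on n-3 df.
#'
#' @param x,y Paired numeric vectors (n >= 5).
#' @param covariate Control variable.
#' @return List of class `corr_result`.
#' @export
partial_spearman <- function(x, y, covariate) {
  ok <- stats::complete.cases(x, y, covariate)
  x <- x[ok]; y <- y[ok]; z <- covariate[ok]
  n <- length(x)
  if (n < 5L) abort("need at least 5 complete triples")
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0 || stats::sd(rz) == 0)
    abort("zero rank variance")
  r_xy <- stats::cor(rx, ry); r_xz <- stats::cor(rx, rz)
  r_yz <- stats::cor(ry, rz)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12)
    abort("degenerate control: covariate perfectly rank-correlated")
  rho <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  tt <- rho * sqrt((n - 3) / max(1e-12, 1 - rho^2))
  p <- 2 * stats::pt(-abs(tt), n - 3)
  structure(list(rho = rho, z = safe_fisher_z(rho), p = p, n = n,
                 method = "partial (Pearson on ranks)"),
            class = "corr_result")
}

#' @export
print.corr_result <- function(x, ...) {
  cat(sprintf("rho = %.3f, z = %.3f, p = %.4g, n = %d (%s)\n",
              x$rho, x$z, x$p, x$n, x$method))
  invisible(x)
}

#' Fisher z transform
#'
#' Variance-stabilizing transform `z = atanh(rho)` of a correlation.
#' @param rho Correlation in (-1, 1).
#' @return `atanh(rho)`.
#' @export
fisher_z <- function(rho) {
  if (any(abs(rho) >= 1)) abort("|rho| must be < 1")
  atanh(rho)
}

#' Compare two independent correlations
#'
#' `z_observed = (atanh(rho1) - atanh(rho2)) / sqrt(1/(n1-3) + 1/(n2-3))`
#' with a one-sided p-value `P(Z > |z_observed|)` for the directional
#' question "is the stronger correlation reliably stronger".
#'
#' @param rho1,rho2 The two correlations; @param n1,n2 their sample sizes
#'   (both > 3).
#' @return List of class `corr_comparison`: `z_observed, p`.
#' @export
compare_correlations <- function(rho1, n1, rho2, n2) {
  if (n1 <= 3 || n2 <= 3) abort("need n > 3 in both samples")
  z_obs <- (fisher_z(rho1) - fisher_z(rho2)) /
    sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(z_observed = z_obs,
                 p = stats::pnorm(abs(z_obs), lower.tail = FALSE)),
            class = "corr_comparison")
}

#' @export
print.corr_comparison <- function(x, ...) {
  cat(sprintf("Z_observed = %.3f, one-sided p = %.4g\n", x$z_observed, x$p))
  invisible(x)
}

#' Minimal detectable effect of a factorial ANOVA (sensitivity analysis)
#'
#' Smallest Cohen's f for which a fixed-effects F test at `alpha` with
#' `df_effect` numerator df and `n_total - n_cells` denominator df reaches
#' the target power (noncentrality `lambda = n_total * f^2`), root-found to
#' 1e-4.
#'
#' @param n_total Total sample size.
#' @param alpha Significance level.
#' @param power Target power in (0, 1) (default 0.80).
#' @param df_effect Numerator degrees of freedom (default 1).
#' @param n_cells Number of design cells (default 4 for a 2 x 2 design).
#' @return List with `f` (minimal detectable Cohen's f), `eta_sq_p`
#'   (the corresponding partial eta squared `f^2 / (1 + f^2)`), and the
#'   achieved `power`.
#' @export
anova_sensitivity <- function(n_total, alpha = 0.05, power = 0.80,
                              df_effect = 1L, n_cells = 4L) {
  stopifnot(power > 0, power < 1, alpha > 0, alpha < 1,
            n_total > n_cells)
  df_err <- n_total - n_cells
  crit <- stats::qf(1 - alpha, df_effect, df_err)
  pw <- function(f) stats::pf(crit, df_effect, df_err, ncp = n_total * f^2,
                              lower.tail = FALSE)
  if (pw(10) < power) abort("target power unreachable")
  # any power target at or below the test size alpha is met at f = 0
  if (power <= pw(0)) return(list(f = 0, eta_sq_p = 0, power = pw(0)))
  f <- stats::uniroot(function(f) pw(f) - power, c(1e-8, 10),
                      tol = 1e-4)$root
  list(f = f, eta_sq_p = f^2 / (1 + f^2), power = pw(f))
}
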