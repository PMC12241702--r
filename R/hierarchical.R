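# ---- hierarchical Bayesian meta-d' -----------------------------------------
#
# Subject-level log M-ratios are partially pooled within groups:
#   mu_logM[g] ~ Normal(0, 1),  sigma_logM[g] ~ Half-Normal(1),
#   logM[s] ~ Normal(mu_logM[group], sigma_logM[group]^2),
#   meta_d[s] = exp(logM[s]) * d'[s].
# Type-1 parameters (d', c) and the response rates are taken from the
# subject's own data and held fixed, so only the metacognitive level is
# sampled — the standard device for confidence-rating models. The
# likelihood is one 8-bin multinomial per stimulus class (response x
# confidence), which never needs zero-count padding.

hmeta_model_string <- function() {
"model {
  for (g in 1:G) {
    mu_logM[g] ~ dnorm(0, 1)
    sig_logM[g] ~ dnorm(0, 1) T(0,)
    tau_logM[g] <- 1 / (sig_logM[g] * sig_logM[g])
  }
  for (s in 1:S) {
    # non-centered: keeps the sampler out of the hierarchical funnel
    eta[s] ~ dnorm(0, 1)
    logM[s] <- mu_logM[grp[s]] + sig_logM[grp[s]] * eta[s]
    metad[s] <- exp(logM[s]) * dp[s]
    metac[s] <- cratio[s] * metad[s]
    mu_s[s, 1] <-  metad[s] / 2
    mu_s[s, 2] <- -metad[s] / 2
    for (k in 1:K1) {
      ld_lo[s, k] ~ dnorm(-0.5, 1)
      ld_hi[s, k] ~ dnorm(-0.5, 1)
    }
    tlo[s, 1] <- metac[s] - exp(ld_lo[s, 1])
    thi[s, 1] <- metac[s] + exp(ld_hi[s, 1])
    for (k in 2:K1) {
      tlo[s, k] <- tlo[s, k - 1] - exp(ld_lo[s, k])
      thi[s, k] <- thi[s, k - 1] + exp(ld_hi[s, k])
    }
    for (j in 1:2) {
      den_df[s, j] <- phi(metac[s] - mu_s[s, j])
      # response 'different': bins from metac downward, confidence 1..K
      q[s, j, 1] <- rr_df[s, j] *
        (phi(metac[s] - mu_s[s, j]) - phi(tlo[s, 1] - mu_s[s, j])) / den_df[s, j]
      for (k in 2:K1) {
        q[s, j, k] <- rr_df[s, j] *
          (phi(tlo[s, k - 1] - mu_s[s, j]) - phi(tlo[s, k] - mu_s[s, j])) / den_df[s, j]
      }
      q[s, j, K] <- rr_df[s, j] * phi(tlo[s, K1] - mu_s[s, j]) / den_df[s, j]
      # response 'identical': bins from metac upward, confidence 1..K
      q[s, j, K + 1] <- rr_id[s, j] *
        (phi(thi[s, 1] - mu_s[s, j]) - phi(metac[s] - mu_s[s, j])) / (1 - den_df[s, j])
      for (k in 2:K1) {
        q[s, j, K + k] <- rr_id[s, j] *
          (phi(thi[s, k] - mu_s[s, j]) - phi(thi[s, k - 1] - mu_s[s, j])) / (1 - den_df[s, j])
      }
      q[s, j, 2 * K] <- rr_id[s, j] * (1 - phi(thi[s, K1] - mu_s[s, j])) / (1 - den_df[s, j])
      for (b in 1:(2 * K)) {
        qf[s, j, b] <- ifelse(q[s, j, b] < 1.0E-10, 1.0E-10, q[s, j, b])
        qn[s, j, b] <- qf[s, j, b] / sum(qf[s, j, 1:(2 * K)])
      }
      counts[s, j, 1:(2 * K)] ~ dmulti(qn[s, j, 1:(2 * K)], N[s, j])
    }
  }
}"
}

#' Hierarchical Bayesian estimation of group-level metacognitive efficiency
#'
#' Fits the partially pooled log M-ratio model by MCMC (JAGS). Per-subject
#' type-1 parameters are computed from the supplied count tables with the
#' 1/(2N) extreme-rate correction and held fixed; subject log M-ratios
#' shrink toward their group mean. No count padding is applied.
#'
#' @param t2_list List of `type2_counts` arrays, one per subject.
#' @param group Vector of group labels, one per subject (>= 2 subjects per
#'   group).
#' @param seed Integer seed; chains get derived RNG seeds, so identical
#'   data + seed reproduce the posterior exactly.
#' @param n_chains,n_draws,n_warmup MCMC layout (defaults 4 chains x 2000
#'   retained draws after 1000 warm-up iterations per chain).
#' @param rhat_limit Convergence threshold on the potential scale reduction
#'   factor (default 1.1).
#' @return Object of class `hierarchical_fit`: `group_summary` (posterior
#'   mean/sd/95% CrI of the group mean log M-ratio and of its exp),
#'   `contrast` (first minus second group, when exactly two),
#'   `subject_mratios` (posterior means), `rhat`, `n_eff`, `converged`,
#'   `seed`, and the `mcmc.list` in `samples`.
#' @export
fit_meta_d_hierarchical <- function(t2_list, group, seed,
                                    n_chains = 4L, n_draws = 2000L,
                                    n_warmup = 1000L, rhat_limit = 1.1) {
  S <- length(t2_list)
  stopifnot(S == length(group), S >= 2L)
  grp <- factor(group)
  if (any(table(grp) < 2L)) abort("need at least 2 subjects per group")
  if (missing(seed)) abort("seed must be supplied")
  K <- dim(t2_list[[1]])[3]
  dp <- numeric(S); cratio <- numeric(S)
  rr_id <- matrix(0, S, 2); counts <- array(0L, c(S, 2, 2 * K))
  N <- matrix(0L, S, 2)
  for (s in seq_len(S)) {
    t2 <- unclass(t2_list[[s]])
    t1 <- type2_to_type1(t2_list[[s]])
    sd1 <- compute_type1_sdt(t1)
    dp[s] <- sd1$d_prime
    if (abs(dp[s]) < 1e-12) abort("subject %d has d' = 0", s)
    cratio[s] <- sd1$criterion_c / dp[s]
    rr_id[s, ] <- c(sd1$hit_rate, sd1$fa_rate)
    for (j in 1:2) {   # 1 = identical stimuli, 2 = different
      counts[s, j, 1:K] <- t2[j, "different", ]
      counts[s, j, (K + 1):(2 * K)] <- t2[j, "identical", ]
      N[s, j] <- sum(counts[s, j, ])
    }
  }
  data <- list(S = S, G = nlevels(grp), grp = as.integer(grp), K = K,
               K1 = K - 1L, dp = dp, cratio = cratio,
               rr_id = rr_id, rr_df = 1 - rr_id, counts = counts, N = N)
  inits <- lapply(seq_len(n_chains), function(ch) list(
    mu_logM = rep(0, nlevels(grp)), sig_logM = rep(0.5, nlevels(grp)),
    eta = rep(0, S),
    ld_lo = matrix(-0.5, S, K - 1L), ld_hi = matrix(-0.5, S, K - 1L),
    .RNG.name = "base::Mersenne-Twister",
    .RNG.seed = split_seed(seed, 500L + ch)))
  jm <- rjags::jags.model(textConnection(hmeta_model_string()), data = data,
                          inits = inits, n.chains = n_chains,
                          n.adapt = max(100L, n_warmup %/% 2L), quiet = TRUE)
  stats::update(jm, n.iter = n_warmup - n_warmup %/% 2L, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("mu_logM", "sig_logM", "logM"),
                              n.iter = n_draws, progress.bar = "none")
  mat <- as.matrix(samp)
  gd <- coda::gelman.diag(samp, multivariate = FALSE, autoburnin = FALSE)
  rhat <- gd$psrf[, 1]
  n_eff <- coda::effectiveSize(samp)
  lev <- levels(grp)
  mu_name <- function(g) if (length(lev) == 1L) "mu_logM" else
    sprintf("mu_logM[%d]", g)
  gs <- do.call(rbind, lapply(seq_along(lev), function(g) {
    v <- mat[, mu_name(g)]
    data.frame(group = lev[g], mean_log_mratio = mean(v), sd = stats::sd(v),
               ci_lower = unname(stats::quantile(v, 0.025)),
               ci_upper = unname(stats::quantile(v, 0.975)),
               m_ratio = mean(exp(v)), stringsAsFactors = FALSE)
  }))
  contrast <- NULL
  if (length(lev) == 2L) {
    dvec <- mat[, "mu_logM[1]"] - mat[, "mu_logM[2]"]
    contrast <- list(groups = lev, mean = mean(dvec),
                     ci = unname(stats::quantile(dvec, c(0.025, 0.975))),
                     prob_positive = mean(dvec > 0))
  }
  subj <- colMeans(exp(mat[, sprintf("logM[%d]", seq_len(S)), drop = FALSE]))
  structure(list(group_summary = gs, contrast = contrast,
                 subject_mratios = unname(subj),
                 rhat = rhat, n_eff = n_eff,
                 converged = all(is.finite(rhat)) && max(rhat) < rhat_limit,
                 seed = seed, samples = samp),
            class = "hierarchical_fit")
}

#' @export
print.hierarchical_fit <- function(x, ...) {
  cat("Hierarchical Bayesian meta-d' fit\n")
  print(x$group_summary, row.names = FALSE, digits = 3)
  if (!is.null(x$contrast))
    cat(sprintf("  contrast %s - %s: %.3f [%.3f, %.3f], P(>0) = %.3f\n",
                x$contrast$groups[1], x$contrast$groups[2], x$contrast$mean,
                x$contrast$ci[1], x$contrast$ci[2], x$contrast$prob_positive))
  cat(sprintf("  max rhat = %.3f; converged: %s\n",
              max(x$rhat), x$converged))
  invisible(x)
}
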