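# Independent reference implementations used as oracles. These deliberately
# take the slow, literal route (explicit loops, grids) so they share no code
# path with the package functions they check.

# --- brute-force learning-point scan ----------------------------------------
# literal transcription of the two-condition rule: for every candidate
# position, re-check "three consecutive 20s among eligible trials" and
# "no later double-5" with explicit loops
oracle_learning_point <- function(minerals, rewards,
                                  convention = "run_end") {
  stopifnot(length(minerals) == length(rewards))
  elig <- which(minerals != 4)
  r <- rewards[elig]
  ne <- length(r)
  if (ne < 3) return(NA_integer_)
  for (j in 3:ne) {
    if (r[j] == 20 && r[j - 1] == 20 && r[j - 2] == 20) {
      ok <- TRUE
      if (j < ne) {
        for (k in (j + 1):ne) {
          if (k < ne && r[k] == 5 && r[k + 1] == 5) { ok <- FALSE; break }
        }
      }
      if (ok) {
        pick <- if (convention == "run_end") j else j - 2
        return(as.integer(elig[pick]))
      }
    }
  }
  NA_integer_
}

# random one-phase transaction set consistent with a reward matrix
random_phase_transactions <- function(n_trials, mat, seed) {
  set.seed(seed)
  minerals <- sample(1:4, n_trials, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1))
  aliens <- sample(1:3, n_trials, replace = TRUE)
  data.frame(trial_index = seq_len(n_trials), mineral = minerals,
             alien = aliens, reward = mat[cbind(aliens, minerals)])
}

# --- grid-search meta-d' oracle ---------------------------------------------
# exhaustive profile over meta_d with nested optimization of the type-2
# criteria only (Nelder-Mead on the log-increments); independent of the
# package's joint bounded quasi-Newton route
# the grid spans the same signed range the estimator searches: tables with
# essentially no metacognitive signal can have their maximum-likelihood
# meta-d' slightly below zero, and clipping the grid at zero would make the
# oracle disagree on exactly those tables
oracle_grid_meta_d <- function(t2, d_prime, criterion_c,
                               grid = seq(-1, 5, by = 0.01)) {
  counts <- unclass(t2)
  n_levels <- dim(counts)[3]
  k <- n_levels - 1L
  c_over_d <- criterion_c / d_prime
  # self-contained likelihood: bin probabilities written out directly from
  # normal CDFs, conditioned within each stimulus x response cell
  nll_crit <- function(lt, meta_d) {
    meta_c <- c_over_d * meta_d
    tau_low <- meta_c - cumsum(exp(lt[1:k]))
    tau_high <- meta_c + cumsum(exp(lt[(k + 1):(2 * k)]))
    ll <- 0
    for (s in 1:2) {
      mu <- if (s == 1) meta_d / 2 else -meta_d / 2   # identical, different
      cdf_hi <- stats::pnorm(c(meta_c, tau_high, Inf), mean = mu)
      cdf_lo <- stats::pnorm(c(meta_c, tau_low, -Inf), mean = mu)
      p_hi <- diff(cdf_hi) / (1 - stats::pnorm(meta_c, mean = mu))
      p_lo <- -diff(cdf_lo) / stats::pnorm(meta_c, mean = mu)
      ll <- ll + sum(counts[s, 1, ] * log(pmax(p_hi, 1e-10))) +
        sum(counts[s, 2, ] * log(pmax(p_lo, 1e-10)))
    }
    -ll
  }
  best_nll <- Inf; best_m <- NA_real_
  warm <- rep(log(0.5), 2 * k)
  for (m in grid) {
    o <- stats::optim(warm, nll_crit, meta_d = m, method = "Nelder-Mead",
                      control = list(maxit = 800, reltol = 1e-9))
    warm <- o$par
    if (o$value < best_nll) { best_nll <- o$value; best_m <- m }
  }
  list(meta_d = best_m, nll = best_nll)
}

# random type-2 count table drawn from the generative model itself
random_type2_table <- function(seed, n_per_stim = 120L) {
  set.seed(seed)
  d <- runif(1, 0.8, 2.5)
  cc <- runif(1, -0.3, 0.3)
  mr <- runif(1, 0.3, 1.3)
  p <- subject_params(d_prime_true = d, m_ratio_true = mr,
                      bias_true = runif(1, 2.2, 3.2), criterion_true = cc,
                      seed = seed)
  tr <- simulate_confidence_trials(p, n_trials = 2L * n_per_stim)
  t1 <- tabulate_type1(tr)
  sd1 <- compute_type1_sdt(t1)
  list(t2 = tabulate_type2(tr), d_prime = sd1$d_prime,
       criterion_c = sd1$criterion_c, true_m_ratio = mr)
}

# multinomial draw of a type-2 count table straight from the model at the
# canonical recovery design: d' = 1.5, c = 0, equally spaced type-2
# criteria (+/- 0.5, 1.0, 1.5); used for estimator-recovery studies
sample_model_table <- function(meta_d, seed, n_trials = 1000L,
                               d_prime = 1.5, spacing = 0.5) {
  ec <- expected_type2_counts(d_prime, 0, meta_d, -spacing * (1:3),
                              spacing * (1:3), 1, 1)
  set.seed(seed)
  cnt <- array(0, dim = dim(ec), dimnames = dimnames(unclass(ec)))
  for (s in 1:2) {
    draw <- stats::rmultinom(1, n_trials %/% 2L, c(ec[s, 1, ], ec[s, 2, ]))[, 1]
    cnt[s, 1, ] <- draw[1:4]; cnt[s, 2, ] <- draw[5:8]
  }
  class(cnt) <- "type2_counts"
  cnt
}

refit_meta_d <- function(cnt) {
  sd1 <- compute_type1_sdt(type2_to_type1(cnt))
  fit_meta_d_mle(cnt, sd1$d_prime, sd1$criterion_c)$meta_d
}

# --- noncentral-F tail probability via the Poisson mixture ------------------
# P(F' > q) as a Poisson(ncp/2)-weighted sum of central F tails; independent
# of stats::pf's own noncentral branch
oracle_ncf_power <- function(q, df1, df2, ncp, terms = 200L) {
  j <- 0:terms
  w <- stats::dpois(j, ncp / 2)
  tails <- vapply(j, function(jj)
    stats::pf(q * df1 / (df1 + 2 * jj), df1 + 2 * jj, df2,
              lower.tail = FALSE), numeric(1))
  sum(w * tails)
}

# small helpers used across test files
make_trials <- function(stim, resp, conf, id = "S1") {
  trial_table(rep(id, length(stim)), stim, resp, conf)
}
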