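# ---- type-2 SDT model -------------------------------------------------------
#
# Evidence model: a trial produces evidence x; "identical" stimuli have mean
# +d'/2, "different" stimuli -d'/2, unit variance. The subject responds
# "identical" iff x > c. At the metacognitive level the same geometry is
# re-scaled: means +/- meta_d/2 and a carried-over criterion
# meta_c = c * meta_d / d'. On each side of meta_c, n_levels - 1 additional
# type-2 criteria partition the axis into confidence bins; confidence grows
# with distance from meta_c. Only the response-conditional bin probabilities
# enter the likelihood, so the type-1 performance itself is not re-fit.

#' Response-conditional confidence-bin probabilities of the meta-d' model
#'
#' @param meta_d Metacognitive sensitivity (z-units).
#' @param meta_c Scaled type-1 criterion on the meta level.
#' @param tau_low Type-2 criteria below `meta_c` for "different" responses,
#'   strictly decreasing, length `n_levels - 1`.
#' @param tau_high Type-2 criteria above `meta_c` for "identical" responses,
#'   strictly increasing, length `n_levels - 1`.
#' @param n_levels Confidence scale length.
#' @return Array `p[stimulus, response, confidence]` of conditional
#'   probabilities P(confidence | stimulus, response); each
#'   (stimulus, response) slice sums to 1.
#' @export
meta_d_cell_probs <- function(meta_d, meta_c, tau_low, tau_high, n_levels = 4L) {
  stopifnot(length(tau_low) == n_levels - 1L, length(tau_high) == n_levels - 1L)
  if (any(diff(tau_low) >= 0) || any(tau_low >= meta_c))
    abort("tau_low must be strictly decreasing below meta_c")
  if (any(diff(tau_high) <= 0) || any(tau_high <= meta_c))
    abort("tau_high must be strictly increasing above meta_c")
  mu <- c(identical = meta_d / 2, different = -meta_d / 2)
  p <- array(NA_real_, dim = c(2L, 2L, n_levels),
             dimnames = list(stimulus = names(mu),
                             response = c("identical", "different"),
                             confidence = as.character(seq_len(n_levels))))
  b_hi <- c(meta_c, tau_high, Inf)    # ascending bounds, response "identical"
  b_lo <- c(meta_c, tau_low, -Inf)    # descending bounds, response "different"
  for (s in 1:2) {
    ph <- stats::pnorm(b_hi - mu[s])
    pl <- stats::pnorm(b_lo - mu[s])
    num_hi <- diff(ph)                     # P(bin k, resp identical | stim)
    num_lo <- -diff(pl)                    # P(bin k, resp different | stim)
    den_hi <- 1 - stats::pnorm(meta_c - mu[s])
    den_lo <- stats::pnorm(meta_c - mu[s])
    p[s, "identical", ] <- num_hi / den_hi
    p[s, "different", ] <- num_lo / den_lo
  }
  p
}

#' Expected type-2 counts under the full model
#'
#' Combines the type-1 response probabilities at (`d_prime`, `criterion_c`)
#' with the meta-level conditional confidence probabilities; useful for
#' self-consistency checks and as the generative kernel of the cohort
#' simulator.
#'
#' @inheritParams meta_d_cell_probs
#' @param d_prime,criterion_c Type-1 parameters.
#' @param n_identical,n_different Trials per stimulus class.
#' @return A `type2_counts`-shaped array of expected (non-integer) counts.
#' @export
expected_type2_counts <- function(d_prime, criterion_c, meta_d,
                                  tau_low, tau_high,
                                  n_identical, n_different, n_levels = 4L) {
  pc <- meta_d_cell_probs(meta_d, criterion_c * meta_d / d_prime,
                          tau_low, tau_high, n_levels)
  p_resp_id <- c(identical = stats::pnorm(d_prime / 2 - criterion_c),
                 different = stats::pnorm(-d_prime / 2 - criterion_c))
  n_stim <- c(identical = n_identical, different = n_different)
  out <- array(NA_real_, dim = dim(pc), dimnames = dimnames(pc))
  for (s in 1:2) {
    out[s, "identical", ] <- n_stim[s] * p_resp_id[s] * pc[s, "identical", ]
    out[s, "different", ] <- n_stim[s] * (1 - p_resp_id[s]) * pc[s, "different", ]
  }
  class(out) <- "type2_counts"
  out
}

# unpack optimizer parameter vector into criteria
theta_to_criteria <- function(theta, meta_c, n_levels) {
  k <- n_levels - 1L
  inc_low <- exp(theta[2:(k + 1)])
  inc_high <- exp(theta[(k + 2):(2 * k + 1)])
  list(tau_low = meta_c - cumsum(inc_low),
       tau_high = meta_c + cumsum(inc_high))
}

# negative log-likelihood of the response-conditional multinomials
meta_d_negll <- function(theta, counts, c_over_d, n_levels, floor = 1e-10) {
  meta_d <- theta[1]
  meta_c <- c_over_d * meta_d
  cr <- theta_to_criteria(theta, meta_c, n_levels)
  p <- meta_d_cell_probs(meta_d, meta_c, cr$tau_low, cr$tau_high, n_levels)
  -sum(counts * log(pmax(p, floor)))
}

#' Maximum-likelihood meta-d' fit
#'
#' Maximizes the response-conditional multinomial likelihood of the
#' confidence counts over `meta_d` and the 2 x (`n_levels` - 1) type-2
#' criteria. Criteria are parameterized as positive increments in log-space
#' on each side of the scaled type-1 criterion, which enforces the required
#' monotone ordering. The bounded quasi-Newton optimizer (`L-BFGS-B`,
#' tolerance 1e-8) is run from five deterministic starting points and the
#' best likelihood is kept; no count padding is applied.
#'
#' @param t2 A `type2_counts` array (see [tabulate_type2()]).
#' @param d_prime,criterion_c Type-1 parameters from [compute_type1_sdt()].
#' @param n_levels Confidence scale length (defaults to the array dimension).
#' @return An object of class `sdt_fit`: list with `d_prime`, `criterion_c`,
#'   `meta_d`, `m_ratio` (`NA` and flagged if `d_prime == 0`),
#'   `type2_criteria` (named vector, low side descending then high side
#'   ascending), `log_likelihood`, `converged`, `d_prime_zero`.
#' @export
fit_meta_d_mle <- function(t2, d_prime, criterion_c,
                           n_levels = dim(t2)[3]) {
  counts <- unclass(t2)
  stopifnot(length(dim(counts)) == 3L, all(counts >= 0))
  d_zero <- abs(d_prime) < 1e-12
  # with d' = 0 the criterion cannot be carried over as a ratio; the unscaled
  # type-1 criterion is used and the efficiency ratio is undefined
  c_over_d <- if (d_zero) 0 else criterion_c / d_prime
  k <- n_levels - 1L
  starts <- lapply(c(0.1, 0.5, 1, 1.5, 2.5), function(m0)
    c(m0, rep(log(0.5), k), rep(log(0.5), k)))
  lower <- c(-5, rep(-7, 2 * k))
  upper <- c(5, rep(2.5, 2 * k))
  best <- NULL
  any_conv <- FALSE
  for (th0 in starts) {
    fit <- tryCatch(
      stats::optim(th0, meta_d_negll, counts = counts, c_over_d = c_over_d,
                   n_levels = n_levels, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e-8 / .Machine$double.eps,
                                  maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(structure(list(d_prime = d_prime, criterion_c = criterion_c,
                          meta_d = NA_real_, m_ratio = NA_real_,
                          type2_criteria = rep(NA_real_, 2 * k),
                          log_likelihood = NA_real_, converged = FALSE,
                          d_prime_zero = d_zero,
                          message = "all optimizer starts failed"),
                     class = "sdt_fit"))
  meta_d <- best$par[1]
  cr <- theta_to_criteria(best$par, c_over_d * meta_d, n_levels)
  structure(list(
    d_prime = d_prime, criterion_c = criterion_c, meta_d = meta_d,
    m_ratio = if (d_zero) NA_real_ else meta_d / d_prime,
    type2_criteria = c(stats::setNames(cr$tau_low, paste0("low", 1:k)),
                       stats::setNames(cr$tau_high, paste0("high", 1:k))),
    log_likelihood = -best$value,
    converged = any_conv,
    d_prime_zero = d_zero), class = "sdt_fit")
}

#' @export
print.sdt_fit <- function(x, ...) {
  cat("Type-2 SDT fit\n")
  cat(sprintf("  d'        = %.3f   c      = %.3f\n", x$d_prime, x$criterion_c))
  cat(sprintf("  meta-d'   = %.3f   M-ratio = %s\n", x$meta_d,
              if (is.na(x$m_ratio)) "NA (d' = 0)" else sprintf("%.3f", x$m_ratio)))
  cat(sprintf("  logLik    = %.3f   converged: %s\n",
              x$log_likelihood, x$converged))
  invisible(x)
}

#' Full per-subject fit from raw trials
#'
#' Convenience wrapper: tabulates, fits type-1 SDT, the meta-d' MLE and the
#' metacognitive bias for one subject.
#'
#' @param trials A [trial_table()] for one subject.
#' @param n_levels Confidence scale length.
#' @return An `sdt_fit` augmented with `meta_bias`, `overconfident` and the
#'   count tables.
#' @export
fit_subject <- function(trials, n_levels = 4L) {
  t1 <- tabulate_type1(trials)
  sd1 <- compute_type1_sdt(t1)
  t2 <- tabulate_type2(trials, n_levels)
  fit <- fit_meta_d_mle(t2, sd1$d_prime, sd1$criterion_c, n_levels)
  mb <- compute_meta_bias(trials, n_levels)
  fit$meta_bias <- mb$meta_bias
  fit$overconfident <- mb$overconfident
  fit$type1_counts <- t1
  fit$type2_counts <- t2
  fit
}

#' Fit every subject in a trials table
#'
#' @param trials A multi-subject [trial_table()].
#' @param n_levels Confidence scale length.
#' @return Data frame with one row per subject:
#'   `subject_id, d_prime, criterion, meta_d, m_ratio, meta_bias, converged`
#'   plus `group`/`region` when present in the input.
#' @export
fit_subjects <- function(trials, n_levels = 4L) {
  ids <- unique(trials$subject_id)
  rows <- lapply(ids, function(id) {
    tr <- trials[trials$subject_id == id, , drop = FALSE]
    f <- fit_subject(tr, n_levels)
    out <- data.frame(subject_id = id, d_prime = f$d_prime,
                      criterion = f$criterion_c, meta_d = f$meta_d,
                      m_ratio = f$m_ratio, meta_bias = f$meta_bias,
                      converged = f$converged, stringsAsFactors = FALSE)
    if (!is.null(tr$group))  out$group  <- tr$group[1]
    if (!is.null(tr$region)) out$region <- tr$region[1]
    out
  })
  do.call(rbind, rows)
}
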