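#' Tabulate type-1 outcomes
#'
#' Classifies each trial as hit (identical called identical), miss
#' (identical called different), false alarm (different called identical)
#' or correct rejection (different called different).
#'
#' @param trials A [trial_table()] for a single subject.
#' @return An object of class `type1_counts`: named integer vector with
#'   elements `hits, misses, false_alarms, correct_rejections`.
#' @export
tabulate_type1 <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0L) abort("no trials")
  s_id <- trials$stimulus == "identical"
  r_id <- trials$response == "identical"
  out <- c(hits = sum(s_id & r_id),
           misses = sum(s_id & !r_id),
           false_alarms = sum(!s_id & r_id),
           correct_rejections = sum(!s_id & !r_id))
  structure(as.integer(out), names = names(out), class = "type1_counts")
}

#' Type-1 sensitivity and criterion under equal-variance SDT
#'
#' d' = z(hit rate) - z(false-alarm rate); c = -(z(HR) + z(FAR)) / 2.
#' Rates of exactly 0 or 1 are moved inward by 1/(2N) for the stimulus
#' class concerned (N = trials of that class) before the probit inversion,
#' the standard correction for extreme proportions.
#'
#' @param counts A `type1_counts` vector (see [tabulate_type1()]).
#' @return List with `d_prime`, `criterion_c`, and the adjusted
#'   `hit_rate` / `fa_rate` actually inverted.
#' @export
compute_type1_sdt <- function(counts) {
  h <- counts[["hits"]]; m <- counts[["misses"]]
  fa <- counts[["false_alarms"]]; cr <- counts[["correct_rejections"]]
  n_sig <- h + m; n_noise <- fa + cr
  if (n_sig == 0L) abort("no trials with stimulus 'identical'")
  if (n_noise == 0L) abort("no trials with stimulus 'different'")
  hr <- adjust_rate(h / n_sig, n_sig)
  far <- adjust_rate(fa / n_noise, n_noise)
  zh <- stats::qnorm(hr); zf <- stats::qnorm(far)
  list(d_prime = zh - zf, criterion_c = -0.5 * (zh + zf),
       hit_rate = hr, fa_rate = far)
}

# 1/(2N) correction for rates of exactly 0 or 1
adjust_rate <- function(p, n) {
  if (p <= 0) 1 / (2 * n) else if (p >= 1) 1 - 1 / (2 * n) else p
}

#' Tabulate response-conditional confidence counts
#'
#' Builds the 2 (stimulus) x 2 (response) x `n_levels` (confidence) count
#' array that carries all the information the type-2 model uses: correct
#' high-confidence responses are the meta-hits, incorrect high-confidence
#' responses the meta-false-alarms, and so on. Collapsing over confidence
#' recovers the type-1 table.
#'
#' @inheritParams tabulate_type1
#' @param n_levels Confidence scale length (default 4).
#' @return A `type2_counts` array with
#'   `dim = c(2, 2, n_levels)` and dimnames
#'   `stimulus = c("identical","different")`,
#'   `response = c("identical","different")`, `confidence = 1..n_levels`.
#' @export
tabulate_type2 <- function(trials, n_levels = 4L) {
  if (is.null(trials) || nrow(trials) == 0L) abort("no trials")
  conf <- as.integer(trials$confidence)
  bad <- which(is.na(conf) | conf < 1L | conf > n_levels)
  if (length(bad))
    abort("confidence out of range 1..%d at trial %d (subject %s)",
          n_levels, bad[1], as.character(trials$subject_id[bad[1]]))
  lv <- c("identical", "different")
  tab <- table(factor(trials$stimulus, levels = lv),
               factor(trials$response, levels = lv),
               factor(conf, levels = seq_len(n_levels)))
  arr <- array(as.integer(tab), dim = c(2L, 2L, n_levels),
               dimnames = list(stimulus = lv, response = lv,
                               confidence = as.character(seq_len(n_levels))))
  class(arr) <- "type2_counts"
  arr
}

#' Collapse a type-2 table to type-1 counts
#' @param t2 A `type2_counts` array.
#' @return A `type1_counts` vector.
#' @export
type2_to_type1 <- function(t2) {
  m <- apply(unclass(t2), c(1, 2), sum)
  out <- c(hits = m["identical", "identical"],
           misses = m["identical", "different"],
           false_alarms = m["different", "identical"],
           correct_rejections = m["different", "different"])
  structure(as.integer(out), names = names(out), class = "type1_counts")
}

#' Metacognitive bias: mean confidence over all trials
#'
#' The subject's overall propensity towards high or low confidence,
#' irrespective of accuracy. On a 1..4 scale the midpoint is 2.5; subjects
#' above the midpoint are labeled overconfident.
#'
#' @inheritParams tabulate_type1
#' @param n_levels Confidence scale length, used only for the midpoint.
#' @return List with `meta_bias` (mean confidence), `midpoint`, and
#'   logical `overconfident` (`meta_bias > midpoint`).
#' @export
compute_meta_bias <- function(trials, n_levels = 4L) {
  if (is.null(trials) || nrow(trials) == 0L) abort("no trials")
  mb <- mean(trials$confidence)
  mid <- (1 + n_levels) / 2
  list(meta_bias = mb, midpoint = mid, overconfident = mb > mid)
}
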