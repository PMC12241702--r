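# ---- alien trading game ----------------------------------------------------
#
# Four minerals are sold to three alien species. Minerals 1-3 pay 5, 10 or 20
# coins depending on the alien (each mineral has exactly one 20-coin buyer);
# mineral 4 pays 10 coins to every alien and serves only to probe alien
# preference. After 48 trials the 5- and 20-coin contingencies swap and the
# player must re-learn the optimal mapping.

#' The reward matrix of the trading game
#'
#' Rows are aliens 1-3, columns minerals 1-4 (coins per transaction).
#' @return A 3 x 4 integer matrix of class `reward_matrix`.
#' @export
build_reward_matrix <- function() {
  m <- matrix(c(5, 10, 20, 10,
                20, 5, 10, 10,
                10, 20, 5, 10),
              nrow = 3, byrow = TRUE,
              dimnames = list(alien = paste0("alien", 1:3),
                              mineral = paste0("mineral", 1:4)))
  storage.mode(m) <- "integer"
  class(m) <- c("reward_matrix", class(m))
  m
}

#' Reverse the trading rules
#'
#' Swaps every 5-coin payoff with 20 and vice versa; 10-coin payoffs
#' (including all of mineral 4) are unchanged. The operation is an
#' involution: reversing twice restores the original matrix.
#'
#' @param m A `reward_matrix`.
#' @return The reversed `reward_matrix`.
#' @export
reverse_rules <- function(m) {
  out <- m
  out[m == 5L] <- 20L
  out[m == 20L] <- 5L
  out
}

#' Build the 68-trial mineral schedule
#'
#' 48 pre-reversal trials (each mineral 12 times) followed by 20
#' post-reversal trials (each mineral 5 times), in a random order that is a
#' pure function of the seed — the same seed yields the same order for every
#' subject, mirroring a presentation order frozen across participants.
#'
#' @param seed Integer seed fixing the order.
#' @return Data frame with columns `trial_index` (1..68), `mineral` (1..4),
#'   `phase` (`"pre_reversal"`/`"post_reversal"`).
#' @export
build_schedule <- function(seed) {
  pre <- with_seed(split_seed(seed, 101L), sample(rep(1:4, each = 12L)))
  post <- with_seed(split_seed(seed, 102L), sample(rep(1:4, each = 5L)))
  data.frame(trial_index = 1:68,
             mineral = as.integer(c(pre, post)),
             phase = rep(c("pre_reversal", "post_reversal"), c(48L, 20L)),
             stringsAsFactors = FALSE)
}

#' Detect the learning point in one phase of the game
#'
#' Learning is complete at the earliest trial satisfying both conditions:
#' (1) it ends a run of three consecutive maximal (20-coin) transactions
#' among 20-eligible trials — mineral-4 trials, on which 20 coins can never
#' be earned, neither extend nor interrupt the run; and (2) no two
#' consecutive minimal (5-coin) transactions occur at any later point in the
#' phase (again counted among eligible trials only). Positions are 1-based
#' within the phase and, by default, count mineral-4 trials in the index.
#'
#' @param transactions Data frame with columns `trial_index, mineral, alien,
#'   reward`, ordered, all from a single phase.
#' @param matrix The phase-appropriate `reward_matrix` (used to validate the
#'   recorded rewards).
#' @param convention `"run_end"` (default): report the trial completing the
#'   three-run; `"run_start"`: report its first trial.
#' @param count_mineral4 If `TRUE` (default) positions are counted over all
#'   trials of the phase; if `FALSE`, over 20-eligible trials only.
#' @return Integer position, or `NA_integer_` if no qualifying run exists
#'   (censored; see [score_game()] for explicit flags).
#' @export
detect_learning <- function(transactions, matrix,
                            convention = c("run_end", "run_start"),
                            count_mineral4 = TRUE) {
  convention <- match.arg(convention)
  tx <- as.data.frame(transactions)
  if (nrow(tx) == 0L) abort("empty transaction list")
  o <- order(tx$trial_index)
  tx <- tx[o, , drop = FALSE]
  expect <- matrix[cbind(tx$alien, tx$mineral)]
  bad <- which(tx$reward != expect)
  if (length(bad))
    abort("reward inconsistent with matrix at trial_index %d (got %d, matrix says %d)",
          tx$trial_index[bad[1]], tx$reward[bad[1]], expect[bad[1]])
  elig <- which(tx$mineral != 4L)
  r <- tx$reward[elig]                   # rewards on 20-eligible trials
  ne <- length(r)
  if (ne < 3L) return(NA_integer_)
  is20 <- r == 20L
  is5 <- r == 5L
  # eligible indices ending a run of three consecutive 20s
  run_end <- which(is20 &
                     c(FALSE, is20[-ne]) &
                     c(FALSE, FALSE, is20[seq_len(ne - 2L)]))
  if (!length(run_end)) return(NA_integer_)
  # double-5 pairs among eligible trials: pair starts at eligible index k
  pair5 <- which(is5[-ne] & is5[-1])
  for (j in run_end) {
    if (!any(pair5 > j)) {               # condition (2): none strictly after
      pick <- if (convention == "run_end") j else j - 2L
      pos <- if (count_mineral4) {
        phase_pos <- seq_len(nrow(tx))
        phase_pos[elig[pick]]
      } else pick
      return(as.integer(pos))
    }
  }
  NA_integer_
}

#' Score a full 68-trial game record
#'
#' Splits the record at the reversal (trial 48/49), detects the learning
#' point in each phase — the pre-reversal phase against the original reward
#' matrix, the post-reversal phase against the reversed matrix, with
#' positions re-counted from the first post-reversal trial — and tallies
#' mineral-4 alien choices. Non-learners are censored (`NA` speed with the
#' `learned_*` flag `FALSE`), never silently numeric.
#'
#' @param transactions Data frame `trial_index, mineral, alien, reward` for
#'   trials 1..68 of one subject.
#' @param matrix The pre-reversal `reward_matrix`
#'   (default [build_reward_matrix()]).
#' @param n_pre,n_total Phase boundary and total length (default 48, 68).
#' @inheritParams detect_learning
#' @return List of class `game_metrics`: `learning_speed`,
#'   `relearning_speed` (integer or `NA`), `learned_pre`, `learned_post`,
#'   `mineral4_choices` (counts per alien), `phase_lengths`.
#' @export
score_game <- function(transactions, matrix = build_reward_matrix(),
                       n_pre = 48L, n_total = 68L,
                       convention = "run_end", count_mineral4 = TRUE) {
  tx <- as.data.frame(transactions)
  idx <- sort(unique(tx$trial_index))
  gaps <- setdiff(seq_len(n_total), idx)
  if (length(gaps))
    abort("missing trials: %s", paste(gaps, collapse = ", "))
  pre <- tx[tx$trial_index <= n_pre, , drop = FALSE]
  post <- tx[tx$trial_index > n_pre, , drop = FALSE]
  post$trial_index <- post$trial_index - n_pre
  ls <- detect_learning(pre, matrix, convention, count_mineral4)
  rs <- detect_learning(post, reverse_rules(matrix), convention, count_mineral4)
  m4 <- tx[tx$mineral == 4L, , drop = FALSE]
  structure(list(
    learning_speed = ls, relearning_speed = rs,
    learned_pre = !is.na(ls), learned_post = !is.na(rs),
    mineral4_choices = tabulate(m4$alien, nbins = 3L),
    phase_lengths = c(pre = n_pre, post = n_total - n_pre)),
    class = "game_metrics")
}

#' @export
print.game_metrics <- function(x, ...) {
  fmt <- function(v, ok, n) if (ok) sprintf("%d trials", v) else
    sprintf("censored (no learning in %d trials)", n)
  cat("Trading-game metrics\n")
  cat("  learning speed:    ", fmt(x$learning_speed, x$learned_pre,
                                   x$phase_lengths["pre"]), "\n")
  cat("  re-learning speed: ", fmt(x$relearning_speed, x$learned_post,
                                   x$phase_lengths["post"]), "\n")
  cat("  mineral-4 choices: ", paste(x$mineral4_choices, collapse = "/"), "\n")
  invisible(x)
}

#' Alien preference on the fixed-value mineral
#'
#' Counts to which alien each mineral-4 transaction went. A preference is
#' flagged when the maximum count exceeds the uniform expectation by more
#' than `margin_sd` binomial standard deviations.
#'
#' @param transactions Data frame with `mineral` and `alien` columns.
#' @param margin_sd Flagging margin in binomial SD units (default 2).
#' @return List with `counts` (length 3), `expected` (uniform), and logical
#'   `preference`.
#' @export
mineral4_preference <- function(transactions, margin_sd = 2) {
  tx <- as.data.frame(transactions)
  m4 <- tx[tx$mineral == 4L, , drop = FALSE]
  counts <- tabulate(m4$alien, nbins = 3L)
  n <- sum(counts)
  expd <- n / 3
  sd <- sqrt(n * (1 / 3) * (2 / 3))
  list(counts = counts, expected = expd,
       preference = n > 0 && max(counts) > expd + margin_sd * sd)
}

#' Score every subject in a transactions table
#'
#' @param transactions Multi-subject data frame with columns
#'   `subject_id, trial_index, mineral, alien, reward`.
#' @inheritParams score_game
#' @return Data frame `subject_id, learning_speed, relearning_speed,
#'   learned_pre, learned_post`.
#' @export
score_subjects <- function(transactions, matrix = build_reward_matrix(),
                           convention = "run_end", count_mineral4 = TRUE) {
  ids <- unique(transactions$subject_id)
  rows <- lapply(ids, function(id) {
    g <- score_game(transactions[transactions$subject_id == id, , drop = FALSE],
                    matrix, convention = convention,
                    count_mineral4 = count_mineral4)
    data.frame(subject_id = id, learning_speed = g$learning_speed,
               relearning_speed = g$relearning_speed,
               learned_pre = g$learned_pre, learned_post = g$learned_post,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read / write trading-game transactions
#' @param path CSV path with header `subject_id,trial_index,mineral,alien,reward`.
#' @return Data frame of transactions.
#' @export
read_transactions <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial_index", "mineral", "alien", "reward")
  miss <- setdiff(need, names(d))
  if (length(miss)) abort("transactions file missing columns: %s",
                          paste(miss, collapse = ", "))
  d$trial_index <- as.integer(d$trial_index)
  d$mineral <- as.integer(d$mineral)
  d$alien <- as.integer(d$alien)
  d$reward <- as.integer(d$reward)
  d
}

#' @rdname read_transactions
#' @param transactions Data frame to write.
#' @export
write_transactions <- function(transactions, path) {
  cols <- c("subject_id", "trial_index", "mineral", "alien", "reward")
  utils::write.csv(as.data.frame(transactions)[, cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
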