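# trading game: rewards, reversal, schedule, learning detection

test_that("reward matrix matches the game design", {
  m <- build_reward_matrix()
  expect_equal(m[1, 3], 20L)
  expect_equal(m[3, 4], 10L)
  expect_equal(m[2, 1], 20L)
  for (j in 1:3) expect_setequal(as.integer(m[, j]), c(5L, 10L, 20L))
  expect_true(all(m[, 4] == 10L))
})

test_that("rule reversal swaps 5 and 20, fixes 10, and is an involution", {
  m <- build_reward_matrix()
  r <- reverse_rules(m)
  expect_equal(r[1, 1], 20L)           # 5 -> 20
  expect_equal(r[1, 3], 5L)            # 20 -> 5
  expect_equal(r[1, 4], 10L)           # 10 fixed
  expect_identical(unclass(reverse_rules(r)), unclass(m))
  for (j in 1:3) expect_setequal(as.integer(r[, j]), c(5L, 10L, 20L))
  expect_true(all(r[, 4] == 10L))
})

test_that("schedule has the designed trial counts and is seed-frozen", {
  s <- build_schedule(17)
  expect_equal(nrow(s), 68L)
  expect_equal(sum(s$phase == "pre_reversal"), 48L)
  expect_equal(table(s$mineral[s$phase == "pre_reversal"]),
               table(rep(1:4, each = 12)))
  expect_equal(table(s$mineral[s$phase == "post_reversal"]),
               table(rep(1:4, each = 5)))
  expect_identical(build_schedule(17), s)
  expect_false(identical(build_schedule(18)$mineral, s$mineral))
})

test_that("learning detection honors the two-condition rule", {
  m <- build_reward_matrix()
  # immediate learner: 20,20,20 on minerals 1-3 then whatever
  tx1 <- data.frame(trial_index = 1:5, mineral = c(1, 2, 3, 1, 2),
                    alien = c(2, 3, 1, 2, 3), reward = c(20, 20, 20, 20, 20))
  expect_equal(detect_learning(tx1, m), 3L)
  expect_equal(detect_learning(tx1, m, convention = "run_start"), 1L)
  # a mineral-4 trial inside the run neither breaks nor extends it
  tx2 <- data.frame(trial_index = 1:4, mineral = c(1, 4, 2, 3),
                    alien = c(2, 1, 3, 1), reward = c(20, 10, 20, 20))
  expect_equal(detect_learning(tx2, m), 4L)
  expect_equal(oracle_learning_point(tx2$mineral, tx2$reward), 4L)
  # early run invalidated by a later double-5; later clean run accepted
  tx3 <- data.frame(trial_index = 1:10,
                    mineral = c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1),
                    alien = c(2, 3, 1, 1, 2, 2, 2, 3, 1, 2),
                    reward = c(20, 20, 20, 5, 5, 10, 20, 20, 20, 20))
  expect_equal(detect_learning(tx3, m), 9L)
  expect_equal(oracle_learning_point(tx3$mineral, tx3$reward), 9L)
  # no qualifying run -> censored
  tx4 <- data.frame(trial_index = 1:3, mineral = c(1, 2, 3),
                    alien = c(1, 1, 1), reward = c(5, 10, 20))
  expect_true(is.na(detect_learning(tx4, m)))
  expect_error(detect_learning(tx4[0, ], m), "empty")
  bad <- tx1; bad$reward[2] <- 5
  expect_error(detect_learning(bad, m), "inconsistent")
})

test_that("detector equals the exhaustive reference scan on random games", {
  m <- build_reward_matrix()
  for (seed in 1:1000) {
    tx <- random_phase_transactions(48L, m, seed)
    got <- detect_learning(tx, m)
    want <- oracle_learning_point(tx$mineral, tx$reward)
    expect_identical(got, want, label = sprintf("seed %d", seed))
  }
})

test_that("appending a terminal double-5 invalidates a qualifying run", {
  m <- build_reward_matrix()
  for (seed in 1:100) {
    tx <- random_phase_transactions(30L, m, seed)
    base <- detect_learning(tx, m)
    if (is.na(base)) next
    extra <- data.frame(trial_index = 31:32, mineral = c(1L, 2L),
                        alien = c(1L, 2L), reward = c(5L, 5L))
    ext <- detect_learning(rbind(tx, extra), m)
    # any learning point must now come from a run ending after trial 30,
    # which is impossible -> censored
    expect_true(is.na(ext), label = sprintf("seed %d", seed))
  }
})

test_that("full-game scoring splits phases and flags censoring", {
  m <- build_reward_matrix()
  sched <- build_schedule(5)
  # optimal agent: always the 20-alien (phase-appropriate), mineral 4 to 1
  best20 <- function(mat, mineral) which(mat[, mineral] == 20L)
  tx <- do.call(rbind, lapply(seq_len(68), function(i) {
    mat <- if (i <= 48) m else reverse_rules(m)
    mn <- sched$mineral[i]
    a <- if (mn == 4L) 1L else best20(mat, mn)
    data.frame(subject_id = "opt", trial_index = i, mineral = mn,
               alien = a, reward = mat[a, mn])
  }))
  g <- score_game(tx)
  # learning point = the trial completing three eligible 20s in each phase
  pre_m <- sched$mineral[1:48]
  expect_equal(g$learning_speed, which(cumsum(pre_m != 4L) == 3L)[1])
  post_m <- sched$mineral[49:68]
  expect_equal(g$relearning_speed, which(cumsum(post_m != 4L) == 3L)[1])
  expect_true(g$learned_pre && g$learned_post)
  expect_equal(sum(g$mineral4_choices), 17L)
  # perseverative agent: keeps the old mapping after reversal
  tx2 <- tx
  post <- tx2$trial_index > 48 & tx2$mineral != 4L
  old_alien <- vapply(which(post), function(r)
    best20(m, tx2$mineral[r]), integer(1))
  tx2$alien[post] <- old_alien
  tx2$reward[post] <- reverse_rules(m)[cbind(old_alien, tx2$mineral[post])]
  g2 <- score_game(tx2)
  expect_false(g2$learned_post)
  expect_true(is.na(g2$relearning_speed))
  # missing trials are reported with their indices
  expect_error(score_game(tx[tx$trial_index != 10, ]), "missing trials: 10")
})

test_that("scoring is invariant to CSV round-trip", {
  p <- subject_params(seed = 9)
  tx <- simulate_trading_agent(p, build_schedule(3))
  g1 <- score_game(tx)
  f <- tempfile(fileext = ".csv")
  write_transactions(tx, f)
  g2 <- score_game(read_transactions(f))
  expect_identical(g1[c("learning_speed", "relearning_speed",
                        "learned_pre", "learned_post")],
                   g2[c("learning_speed", "relearning_speed",
                        "learned_pre", "learned_post")])
  unlink(f)
})

test_that("mineral-4 preference flags only real asymmetry", {
  tx_pref <- data.frame(mineral = rep(4L, 17), alien = rep(2L, 17))
  p1 <- mineral4_preference(tx_pref)
  expect_equal(p1$counts, c(0L, 17L, 0L))
  expect_true(p1$preference)
  tx_flat <- data.frame(mineral = rep(4L, 17),
                        alien = rep(c(1L, 2L, 3L), c(6, 6, 5)))
  p2 <- mineral4_preference(tx_flat)
  expect_false(p2$preference)
  expect_equal(sum(p2$counts), 17L)
})
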