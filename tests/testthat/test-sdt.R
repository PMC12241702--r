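# type-1 tabulation, equal-variance SDT, type-2 tables, meta-bias

test_that("type-1 tabulation partitions trials and is order-invariant", {
  perfect <- make_trials(rep(c("different", "identical"), each = 36),
                         rep(c("different", "identical"), each = 36),
                         rep(3, 72))
  expect_equal(unclass(tabulate_type1(perfect)),
               c(hits = 36L, misses = 0L, false_alarms = 0L,
                 correct_rejections = 36L),
               ignore_attr = TRUE)
  # identical stimulus answered "different" is a miss
  tr <- make_trials(c("identical", "identical", "different"),
                    c("different", "identical", "identical"),
                    c(2, 4, 1))
  t1 <- tabulate_type1(tr)
  expect_equal(t1[["misses"]], 1L)
  expect_equal(t1[["false_alarms"]], 1L)
  shuffled <- tr[c(3, 1, 2), ]
  expect_equal(unclass(tabulate_type1(shuffled)), unclass(t1),
               ignore_attr = TRUE)
  expect_error(tabulate_type1(tr[0, ]), "no trials")
})

test_that("d' and criterion match the independent probit computation", {
  # chance symmetry
  sym <- compute_type1_sdt(structure(c(hits = 18L, misses = 18L,
                                       false_alarms = 18L,
                                       correct_rejections = 18L),
                                     class = "type1_counts"))
  expect_equal(sym$d_prime, 0, tolerance = 1e-12)
  expect_equal(sym$criterion_c, 0, tolerance = 1e-12)
  # hits 30/36, FA 9/36: frozen values from a separate probit evaluation
  f <- compute_type1_sdt(structure(c(hits = 30L, misses = 6L,
                                     false_alarms = 9L,
                                     correct_rejections = 27L),
                                   class = "type1_counts"))
  expect_equal(f$d_prime, 1.641911316, tolerance = 1e-8)
  expect_equal(f$criterion_c, -0.146465908, tolerance = 1e-8)
  # extreme rate engages the 1/(2N) correction and stays finite
  g <- compute_type1_sdt(structure(c(hits = 36L, misses = 0L,
                                     false_alarms = 9L,
                                     correct_rejections = 27L),
                                   class = "type1_counts"))
  expect_equal(g$hit_rate, 1 - 1 / 72)
  expect_true(is.finite(g$d_prime))
  expect_error(compute_type1_sdt(structure(
    c(hits = 0L, misses = 0L, false_alarms = 9L, correct_rejections = 27L),
    class = "type1_counts")), "identical")
})

test_that("type-2 table marginalizes back to type-1 and checks confidence", {
  set.seed(31)
  n <- 60
  tr <- make_trials(sample(c("identical", "different"), n, TRUE),
                    sample(c("identical", "different"), n, TRUE),
                    sample(1:4, n, TRUE))
  t2 <- tabulate_type2(tr)
  expect_equal(sum(t2), n)
  expect_equal(unclass(type2_to_type1(t2)),
               unclass(tabulate_type1(tr)), ignore_attr = TRUE)
  # all-correct subject has empty incorrect cells
  ac <- make_trials(rep("identical", 10), rep("identical", 10),
                    rep(c(3, 4), 5))
  t2c <- tabulate_type2(ac)
  expect_equal(sum(t2c["identical", "different", ]), 0)
  expect_equal(sum(t2c["different", , ]), 0)
  bad <- data.frame(subject_id = "S9", stimulus = "identical",
                    response = "identical", confidence = 5)
  expect_error(tabulate_type2(bad), "confidence out of range.*S9")
})

test_that("hand-tabulated 12-trial fixture matches the type-2 table", {
  stim <- c("identical", "identical", "identical", "identical", "identical",
            "identical", "different", "different", "different", "different",
            "different", "different")
  resp <- c("identical", "identical", "different", "identical", "different",
            "identical", "different", "identical", "different", "different",
            "identical", "different")
  conf <- c(4, 3, 1, 4, 2, 1, 3, 2, 4, 4, 1, 2)
  t2 <- tabulate_type2(make_trials(stim, resp, conf))
  # enumeration by hand: identical&identical -> conf 4,3,4,1
  expect_equal(as.numeric(t2["identical", "identical", ]), c(1, 0, 1, 2))
  # identical&different -> conf 1,2
  expect_equal(as.numeric(t2["identical", "different", ]), c(1, 1, 0, 0))
  # different&identical -> conf 2,1
  expect_equal(as.numeric(t2["different", "identical", ]), c(1, 1, 0, 0))
  # different&different -> conf 3,4,4,2
  expect_equal(as.numeric(t2["different", "different", ]), c(0, 1, 1, 2))
})

test_that("metacognitive bias is the plain mean confidence", {
  all4 <- make_trials(rep("identical", 8), rep("identical", 8), rep(4, 8))
  expect_equal(compute_meta_bias(all4)$meta_bias, 4)
  flat <- make_trials(rep("identical", 8), rep("different", 8),
                      rep(1:4, 2))
  mb <- compute_meta_bias(flat)
  expect_equal(mb$meta_bias, 2.5)
  expect_false(mb$overconfident)   # midpoint itself is not over-confident
  # a group built to mean 3.5 is labeled overconfident
  hi <- make_trials(rep("identical", 8), rep("identical", 8),
                    rep(c(3, 4), 4))
  expect_true(compute_meta_bias(hi)$overconfident)
  # invariant to correctness labels: same confidences, flipped responses
  flipped <- make_trials(rep("identical", 8), rep("identical", 8),
                         rep(1:4, 2))
  expect_equal(compute_meta_bias(flipped)$meta_bias, mb$meta_bias)
})
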