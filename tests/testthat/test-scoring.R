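# Consistency scoring, grade bands and the group partition.

test_that("score_subject reproduces the reference arithmetic", {
  s <- score_subject(c(flute = 13.28, violin = 16.58, horns = 19.67,
                       piano = 7.16, oboe = 8.77))
  expect_equal(s$total_de, 65.46)
  expect_equal(s$mean_de, 13.092)
  expect_equal(as.character(s$grade), "satisfactory")

  # a missing repeat leaves both the numerator and the denominator
  s <- score_subject(c(0.35, 16.06, NA, 0.86, 25.71))
  expect_equal(s$total_de, 42.98)
  expect_equal(s$n_valid, 4)
  expect_equal(s$mean_de, 10.745)

  s <- score_subject(c(x = 7.5))
  expect_equal(s$total_de, 7.5)
  expect_equal(s$mean_de, 7.5)
})

test_that("score_subject is permutation-invariant and rejects bad input", {
  x <- c(13.28, 16.58, 19.67, 7.16, 8.77)
  set.seed(1)
  for (i in 1:5) {
    s <- score_subject(sample(x))
    expect_equal(s$total_de, 65.46)
    expect_equal(s$mean_de, 13.092)
  }
  expect_error(score_subject(c(NA_real_, NA_real_)), "no valid")
  expect_error(score_subject(c(5, -1)), "nonnegative")
})

test_that("grade bands are half-open and partition the nonnegative line", {
  expect_equal(as.character(classify_grade(c(0, 9.999, 10, 12.999, 13,
                                             15.999, 16, 100))),
               c("excellent", "excellent", "very_well", "very_well",
                 "satisfactory", "satisfactory", "poor", "poor"))
  # reference examples
  expect_equal(as.character(classify_grade(c(7.296, 8.232, 13.856, 19.358))),
               c("excellent", "excellent", "satisfactory", "poor"))
  expect_error(classify_grade(-0.1), "nonnegative")
  set.seed(7)
  g <- classify_grade(rexp(200, rate = 1 / 15))
  expect_false(anyNA(g))  # every mean maps to exactly one grade
})

test_that("repeat_distance handles repeats, missingness and over-presentation", {
  resp <- data.frame(
    subject_id = c("a", "a", "a", "a", "b"),
    stimulus_id = c("fl", "fl", "ob", "ob", "fl"),
    presentation = c(1, 2, 1, 2, 1),
    r = c(200, 200, 255, 0, 10), g = c(10, 10, 0, 255, 10),
    b = c(10, 10, 0, 0, 10))
  expect_equal(repeat_distance(resp, "a", "fl"), 0)
  # red vs green golden value from the verified reference chain
  expect_equal(repeat_distance(resp, "a", "ob"), 86.6085, tolerance = 1e-3)
  expect_true(is.na(repeat_distance(resp, "b", "fl")))
  resp$missing <- c(FALSE, TRUE, FALSE, FALSE, FALSE)
  expect_true(is.na(repeat_distance(resp, "a", "fl")))
  bad <- data.frame(subject_id = "a", stimulus_id = "fl",
                    presentation = 1:3, r = 1, g = 1, b = 1)
  expect_error(repeat_distance(bad, "a", "fl"), "more than two")
})

test_that("score_subjects aggregates a response table end to end", {
  resp <- data.frame(
    subject_id = rep(c("s1", "s2"), each = 4),
    stimulus_id = rep(c("fl", "fl", "ob", "ob"), 2),
    presentation = rep(c(1, 2, 1, 2), 2),
    r = c(100, 100, 50, 50,   0, 255, 30, 30),
    g = c(100, 100, 50, 50,   0, 255, 30, 30),
    b = c(100, 100, 50, 50,   0, 255, 30, 30))
  out <- score_subjects(resp, c(fl = "flute", ob = "oboe"))
  expect_equal(nrow(out), 2)
  expect_equal(out$mean_de[out$subject_id == "s1"], 0)
  expect_equal(as.character(out$grade), c("excellent", "poor"))
  part <- partition_groups(out)
  expect_equal(part$synesthetes$subject_id, "s1")
  expect_equal(part$non_synesthetes$subject_id, "s2")
  expect_equal(as.integer(part$census), c(1L, 0L, 0L))
})

test_that("partition of an empty score table yields empty groups", {
  empty <- score_table(matrix(1, 1, 1))[0, ]
  part <- partition_groups(empty)
  expect_equal(nrow(part$synesthetes), 0)
  expect_equal(nrow(part$non_synesthetes), 0)
  expect_equal(sum(part$census), 0)
})

test_that("response CSVs round-trip and reconstruct color columns", {
  resp <- data.frame(subject_id = "s1", stimulus_id = c("a", "b"),
                     presentation = 1L,
                     r = c(200, 12), g = c(40, 200), b = c(120, 77))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_responses(resp, path)
  back <- read_responses(path)
  expect_equal(back$r, resp$r)
  expect_equal(back$hex, c("#C82878", "#0CC84D"))
  # hex-only input reconstructs rgb and hsl
  hexonly <- data.frame(subject_id = "s1", stimulus_id = "a",
                        presentation = 1L, hex = "#C82878")
  write.csv(hexonly, path, row.names = FALSE)
  back2 <- read_responses(path)
  expect_equal(c(back2$r, back2$g, back2$b), c(200, 40, 120))
  expect_false(is.na(back2$h))
})
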