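test_that("group totals reproduce the reported control and experimental figures", {
  expect_identical(group_total(c(3, 6, 5, 25, 14)), 200L)
  expect_identical(group_total(c(2, 1, 2, 27, 21)), 223L)
  crispr_post <- c(0, 1, 2, 13, 9); shrna_post <- c(1, 2, 3, 15, 9)
  expect_identical(group_total(crispr_post) + group_total(shrna_post), 224L)
  expect_identical(group_total(rep(1, 5) * c(5, 0, 0, 0, 0)), 5L)
})

test_that("record-based and histogram-based totals agree and ignore ordering", {
  rec <- generate_cohort(default_cohort_spec(), rng_seed = 17)
  expect_identical(group_total(rec, "control", "pre"), 200L)
  expect_identical(group_total(rec, "control", "post"), 223L)
  expect_identical(group_total(rec, "experimental", "post"), 224L)
  expect_identical(
    group_total(rec, c("experimental_crispr", "experimental_shrna"), "post"),
    224L)
  shuffled <- rec[rev(seq_len(nrow(rec))), ]
  expect_identical(group_total(shuffled, "control", "pre"), 200L)
  expect_error(group_total(rec, "no_such_arm", "pre"), "no patients")
})

test_that("mean change reproduces the reported per-patient increases", {
  expect_equal(mean_change_from_totals(200, 223, 53), 0.43)
  expect_equal(mean_change_from_totals(217, 224, 55), 0.13)
  rec <- generate_cohort(default_cohort_spec(), rng_seed = 17)
  expect_equal(mean_change(rec, "control"), 0.43)
  flat <- data.frame(patient_id = letters[1:4], arm = "control",
                     score_pre = c(2, 3, 4, 5), score_post = c(2, 3, 4, 5))
  expect_equal(mean_change(flat), 0)
})

test_that("half-up rounding is used for mean change", {
  expect_equal(round_half_up(0.125, 2), 0.13)   # base round() would give 0.12
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(mean_change_from_totals(0, 1, 8), 0.13)  # 0.125 rounds up
})

test_that("accuracy matches analytic cases and a counting oracle", {
  expect_equal(accuracy(confusion_table(TP = 1, FP = 0, FN = 0, TN = 1)), 1)
  expect_equal(accuracy(confusion_table(TP = 49, FP = 1, FN = 1, TN = 49)), 0.98)
  set.seed(99)
  for (rep in 1:25) {
    counts <- rpois(4, 20)
    if (sum(counts) == 0) counts[1] <- 1
    ct <- confusion_table(counts[1], counts[2], counts[3], counts[4])
    # brute-force oracle: materialize one unit per count and tally
    units <- rep(c("TP", "FP", "FN", "TN"), counts)
    expect_equal(accuracy(ct), sum(units %in% c("TP", "TN")) / length(units))
  }
  expect_error(confusion_table(-1, 0, 0, 0), "non-negative")
  expect_error(accuracy(confusion_table(0, 0, 0, 0)), "empty")
})

test_that("score-level accuracy binarizes to matches over total", {
  pred <- c(1, 2, 3, 4, 5, 3, 2)
  ref <- c(1, 2, 3, 4, 4, 3, 1)
  ct <- score_confusion(pred, ref)
  expect_equal(accuracy(ct), 5 / 7)
  expect_equal(accuracy(score_confusion(ref, ref)), 1)
})

test_that("one-way ANOVA of change matches a hand-computed decomposition", {
  # 6-patient toy: control changes (0, 1, 2); experimental changes (2, 3, 4)
  rec <- data.frame(
    patient_id = letters[1:6],
    arm = rep(c("control", "experimental_crispr"), each = 3),
    score_pre = c(1, 2, 3, 1, 1, 1),
    score_post = c(1, 3, 5, 3, 4, 5))
  ch <- rec$score_post - rec$score_pre
  grand <- mean(ch)
  ssb <- 3 * (mean(ch[1:3]) - grand)^2 + 3 * (mean(ch[4:6]) - grand)^2
  ssw <- sum((ch[1:3] - mean(ch[1:3]))^2) + sum((ch[4:6] - mean(ch[4:6]))^2)
  f_hand <- (ssb / 1) / (ssw / 4)
  out <- compare_groups(rec)
  expect_equal(out$F, f_hand)
  expect_equal(out$df, c(1, 4))
  expect_equal(unname(out$means), c(1, 3))
})

test_that("identical groups give F near 0 and extreme separation is significant", {
  rec <- data.frame(
    patient_id = paste0("p", 1:20),
    arm = rep(c("control", "experimental_shrna"), each = 10),
    score_pre = rep(2, 20),
    score_post = rep(c(3, 2), 10))
  out <- compare_groups(rec)
  expect_lt(out$F, 1e-10)
  expect_gt(out$p_value, 0.99)
  sep <- data.frame(
    patient_id = paste0("p", 1:40),
    arm = rep(c("control", "experimental_crispr"), each = 20),
    score_pre = c(rep(4, 20), rep(1, 20)),
    score_post = c(rep(4, 20), rep(5, 20)))
  outs <- compare_groups(sep)
  expect_lt(outs$p_value, 0.05)
  expect_true(outs$significant)
})

test_that("summarize assembles group rows and audits printed totals", {
  spec <- default_cohort_spec()
  rec <- generate_cohort(spec, rng_seed = 5)
  s <- summarize_cohort(rec, spec$printed_totals)
  ctl <- s$groups[s$groups$group == "control", ]
  expect_identical(c(ctl$n, ctl$total_pre, ctl$total_post), c(53L, 200L, 223L))
  expect_equal(ctl$mean_change, 0.43)
  exp_row <- s$groups[s$groups$group == "experimental", ]
  expect_identical(exp_row$total_post, 224L)
  # the reported experimental pre total (217) disagrees with its own counts (212)
  bad <- s$audit[s$audit$flag, ]
  expect_identical(nrow(bad), 1L)
  expect_identical(bad$group, "experimental")
  expect_identical(bad$timepoint, "pre")
  expect_identical(c(bad$printed, bad$derived), c(217L, 212L))
})

test_that("scores CSV round-trips through the long format", {
  rec <- generate_cohort(default_cohort_spec(), rng_seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scores_csv(rec, path)
  back <- read_scores_csv(path)
  back <- back[match(rec$patient_id, back$patient_id), ]
  rownames(back) <- NULL
  expect_identical(back$score_pre, rec$score_pre)
  expect_identical(back$score_post, rec$score_post)
  expect_identical(back$arm, rec$arm)
})
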