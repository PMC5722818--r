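test_that("the normality gate picks the expected test", {
  set.seed(40)
  picks <- vapply(1:200, function(i)
    as.character(chooseTest(rnorm(42), rnorm(21))), "")
  # false-switch rate of two 0.05-level gates ~ 1 - 0.95^2 ~ 0.0975
  expect_gt(mean(picks == "t_two_tailed"), 0.8)
  expect_lt(mean(picks == "t_two_tailed"), 0.99)
  picksLN <- vapply(1:100, function(i)
    as.character(chooseTest(rlnorm(42, sdlog = 1), rnorm(21))), "")
  expect_gte(mean(picksLN == "wilcoxon_rank_sum"), 0.8)
  expect_error(chooseTest(rnorm(2), rnorm(10)), "3 observations")
})

test_that("compareGroups reports means, SDs, and symmetric p-values", {
  set.seed(41)
  a <- rnorm(20, 1); b <- rnorm(12, 2)
  r1 <- compareGroups(a, b, test = "t_two_tailed")
  r2 <- compareGroups(b, a, test = "t_two_tailed")
  expect_equal(r1$p_raw, r2$p_raw)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$mean_a, mean(a)); expect_equal(r1$sd_b, sd(b))
  # identical degenerate groups: p = 1 by convention, flagged
  rd <- compareGroups(rep(2, 5), rep(2, 7))
  expect_equal(rd$p_raw, 1)
  expect_true(rd$degenerate)
  # identical non-degenerate samples under rank-sum: p = 1
  x <- c(1, 2, 3, 4, 5)
  expect_equal(compareGroups(x, x, test = "wilcoxon_rank_sum")$p_raw, 1)
})

test_that("reference delta effect is detected in ~all replicates", {
  set.seed(42)
  hits <- 0
  for (i in 1:500) {
    r <- compareGroups(rnorm(42, 4.33, 0.25), rnorm(21, 4.81, 0.34),
                       test = "t_two_tailed")
    if (r$p_raw < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 500, 0.99)
})

test_that("Bonferroni adjustment is capped, stamped, and FWER-controlling", {
  expect_equal(as.numeric(bonferroniAdjust(0.001, 40)), 0.04)
  expect_equal(as.numeric(bonferroniAdjust(0.5, 40)), 1.0)
  expect_equal(attr(bonferroniAdjust(0.5, 40), "family_size"), 40)
  expect_error(bonferroniAdjust(runif(10), 5), "at least")
  # adjusted >= raw always
  p <- runif(40)
  expect_true(all(bonferroniAdjust(p, 40) >= p))
  # empirical FWER under a true null with real two-group tests
  set.seed(43)
  fwer <- vapply(1:300, function(i) {
    praw <- vapply(1:40, function(j)
      compareGroups(rnorm(8), rnorm(8), test = "t_two_tailed")$p_raw, 0.0)
    any(bonferroniAdjust(praw, 40) < 0.05)
  }, TRUE)
  expect_lte(mean(fwer), 0.05 + 2 * sqrt(0.05 * 0.95 / 300))
})

test_that("significant ranges are maximal runs of consecutive bins", {
  expect_identical(significantRanges(1:5, c(TRUE, TRUE, FALSE, TRUE, TRUE)),
                   "1-2, 4-5")
  expect_identical(significantRanges(1:5, rep(FALSE, 5)), "")
  expect_identical(significantRanges(1:5, c(FALSE, TRUE, FALSE, FALSE, TRUE)),
                   "2, 5")
  expect_identical(significantRanges(1:40, rep(TRUE, 40)), "1-40")
})

test_that("deficitProfile assembles profiles, ranges, and both p-value sets", {
  # synthetic feature table with a known effect confined to bins 3-5
  set.seed(44)
  mkRows <- function(subj, grp, shift) {
    do.call(rbind, lapply(1:40, function(b)
      data.frame(subject_id = subj, group = grp, condition = "EO",
                 trial = 1L, feature = "power",
                 scope = paste0("bin:", b),
                 value = rnorm(1, ifelse(b %in% 3:5, shift, 0), 0.3),
                 status = "ok", stringsAsFactors = FALSE)))
  }
  ft <- rbind(
    do.call(rbind, lapply(sprintf("H%02d", 1:10), mkRows, grp = "healthy",
                          shift = 0)),
    do.call(rbind, lapply(sprintf("C%02d", 1:10), mkRows, grp = "concussed",
                          shift = 2)))
  rep1 <- deficitProfile(ft, "power", "EO")
  res <- deficitResults(rep1)
  expect_equal(nrow(res), 40)
  expect_true(all(res$p_bonferroni >= res$p_raw))
  bins <- as.integer(sub("bin:", "", res$scope))
  expect_true(all(res$significant[bins %in% 3:5]))
  # raw profile must contain the injected run (null bins may add ~2
  # false positives at alpha = 0.05); under Bonferroni the run is exact
  expect_match(deficitRanges(rep1)$ranges, "3-5")
  repB <- deficitProfile(ft, "power", "EO", adjust = "bonferroni")
  expect_identical(deficitRanges(repB)$ranges, "3-5")
  # every scope appears exactly once (report completeness)
  expect_identical(sort(bins), 1:40)
  expect_length(reportMeta(rep1)$excluded, 0)
  # errors: missing group
  expect_error(deficitProfile(ft[ft$group == "healthy", ], "power", "EO"),
               "both groups")
})

test_that("trial pooling is available and labeled; subject mode is default", {
  ft <- do.call(rbind, lapply(c("H1", "H2", "H3", "C1", "C2", "C3"),
    function(s) data.frame(
      subject_id = s, group = ifelse(grepl("H", s), "healthy", "concussed"),
      condition = "EO", trial = 1:3, feature = "apen", scope = "broadband",
      value = rnorm(3, ifelse(grepl("H", s), 0, 1)), status = "ok",
      stringsAsFactors = FALSE)))
  rs <- deficitProfile(ft, "apen", "EO")
  rt <- deficitProfile(ft, "apen", "EO", unit = "trial")
  expect_identical(reportMeta(rs)$unit, "subject")
  expect_equal(deficitResults(rs)$n_a, 3)   # 3 subject means
  expect_equal(deficitResults(rt)$n_a, 9)   # 9 pooled trials
})
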