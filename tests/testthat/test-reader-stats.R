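test_that("score tables validate vocabulary, range and uniqueness", {
  tbl <- simulate_score_table(seed = 2)
  expect_s3_class(tbl, "score_table")
  expect_equal(nrow(tbl), 3 * 17 * 5 * 5)

  df <- data.frame(reader = "R1", case = "C1", modality = "PAN",
                   criterion = "artefacts", score = 6)
  expect_error(score_table(df), "row")
  df$score <- 3
  expect_error(score_table(rbind(df, df)), "duplicate")
  df$modality <- "MRI"
  expect_error(score_table(df), "unknown modality")
  df$modality <- "PAN"; df$criterion <- "sharpness"
  expect_error(score_table(df), "unknown criterion")
  expect_error(score_table(df[, 1:4]), "missing columns")
})

test_that("load_scores round-trips a well-formed CSV", {
  tbl <- simulate_score_table(seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(tbl, f, row.names = FALSE)
  back <- load_scores(f)
  expect_equal(nrow(back), 1275)
  expect_equal(sort(unique(back$modality)), sort(score_modalities()))
})

test_that("aggregation reproduces printed across-reader averages", {
  # per-reader means as published for six (modality, criterion) rows
  expect_equal(across_reader_average(c(2.35, 3.53, 4.06)), 3.31)
  expect_equal(across_reader_average(c(4.71, 5.00, 4.88)), 4.86)
  expect_equal(across_reader_average(c(2.59, 3.41, 4.35)), 3.45)
  expect_equal(across_reader_average(c(2.35, 3.76, 4.18)), 3.43)
  expect_equal(across_reader_average(c(4.47, 3.82, 4.76)), 4.35)
  expect_equal(across_reader_average(c(2.47, 3.76, 4.00)), 3.41)
})

test_that("aggregate_scores computes reader means, averages and total points", {
  grid <- expand.grid(reader = c("R1", "R2"), case = paste0("C", 1:4),
                      modality = c("PAN", "PETI_BONE"),
                      criterion = score_criteria(), stringsAsFactors = FALSE)
  grid$score <- 5L
  agg <- aggregate_scores(score_table(grid))
  expect_true(all(agg$by_reader$mean == 5))
  expect_true(all(agg$by_reader$sd == 0))
  expect_true(all(agg$summary$average == 5))
  # total points: 5 criteria x 2 readers x mean 5 = 50
  expect_equal(agg$totals$total_points, c(50, 50))

  # mixed scores: across-reader average is the mean of reader means
  grid$score <- ifelse(grid$reader == "R1", 2L, 4L)
  agg2 <- aggregate_scores(score_table(grid))
  expect_true(all(agg2$summary$average == 3))
  expect_true(all(agg2$summary$average >=
                    tapply(agg2$by_reader$mean,
                           paste(agg2$by_reader$modality, agg2$by_reader$criterion),
                           min)[paste(agg2$summary$modality, agg2$summary$criterion)]))
})

test_that("signed-rank statistic and exact p match the textbook example", {
  res <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(res$statistic, 0)
  expect_equal(res$w_plus + res$w_minus, 5 * 6 / 2)
  expect_equal(res$p_value, 0.0625)
  expect_equal(res$direction, 1)
  expect_match(res$method, "exact")
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "no nonzero pairs")
})

test_that("exact p equals the brute-force enumeration oracle (no ties, n <= 12)", {
  set.seed(19)
  for (n in c(5, 8, 10, 12)) {
    for (rep in 1:5) {
      # continuous draws: no ties, no zeros almost surely
      x <- round(runif(n, 0, 100), 3)
      y <- round(runif(n, 0, 100), 3)
      res <- wilcoxon_signed_rank(x, y)
      expect_equal(res$p_value, brute_force_signed_rank_p(x, y),
                   tolerance = 1e-12)
      # two-sided p is invariant under swapping the samples
      expect_equal(wilcoxon_signed_rank(y, x)$p_value, res$p_value,
                   tolerance = 1e-12)
      # rank-sum identity after zero removal
      expect_equal(res$w_plus + res$w_minus, res$n * (res$n + 1) / 2)
    }
  }
})

test_that("exact p agrees with the reference implementation in stats", {
  set.seed(23)
  for (rep in 1:10) {
    x <- round(runif(9, 0, 50), 3)
    y <- round(runif(9, 0, 50), 3)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(wilcoxon_signed_rank(x, y)$p_value, ref, tolerance = 1e-12)
  }
})

test_that("large tied samples use the corrected normal approximation", {
  x <- c(3, 4, 5, 5, 4, 3, 2, 5, 4, 3, 4, 5, 3, 4, 2, 5, 4, 3, 5, 2, 4)
  y <- c(2, 3, 4, 3, 3, 2, 3, 4, 3, 2, 3, 4, 2, 3, 3, 4, 2, 4, 3, 3, 2)
  res <- wilcoxon_signed_rank(x, y)
  expect_match(res$method, "normal")
  expect_true(res$p_value > 0 && res$p_value < 1)
  # same tie structure through the reference implementation (both use the
  # tie- and continuity-corrected normal approximation)
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                             exact = FALSE, correct = TRUE))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("a +1 ordinal shift makes every comparison significant and positive", {
  tbl <- simulate_score_table(shift = c(PAN = 0L, PVMI40 = 1L, PVMI60 = 1L,
                                        PETI_BONE = 1L, PETI_COMBO = 1L),
                              seed = 7)
  cmp <- compare_modalities(tbl, baseline = "PAN")
  expect_equal(nrow(cmp), 4 * 5)
  expect_true(all(cmp$status == "ok"))
  expect_true(all(cmp$significant))
  expect_true(all(cmp$direction == 1))
})

test_that("identical modalities are flagged untestable, a lone baseline yields no rows", {
  tbl <- simulate_score_table(shift = c(PAN = 0L, PETI_BONE = 0L), seed = 9)
  cmp <- compare_modalities(tbl, baseline = "PAN")
  expect_true(all(cmp$status == "untestable"))
  expect_true(all(!cmp$significant))

  only <- simulate_score_table(shift = c(PAN = 0L), seed = 9)
  expect_equal(nrow(compare_modalities(only, baseline = "PAN")), 0)
  expect_error(compare_modalities(only, baseline = "PETI_BONE"),
               "not present")
})

test_that("unpaired keys are an error and p-adjustment is available", {
  tbl <- simulate_score_table(shift = c(PAN = 0L, PETI_BONE = 1L), seed = 3)
  broken <- tbl[!(tbl$modality == "PETI_BONE" & tbl$reader == "R1" &
                    tbl$case == "C1"), ]
  expect_error(compare_modalities(score_table(broken), baseline = "PAN"),
               "unpaired")

  cmp_raw <- compare_modalities(tbl, baseline = "PAN")
  cmp_adj <- compare_modalities(tbl, baseline = "PAN", p_adjust = "bonferroni")
  ok <- cmp_raw$status == "ok"
  expect_true(all(cmp_adj$p_value[ok] >= cmp_raw$p_value[ok]))
})

test_that("the score simulator is seeded and respects its shift construction", {
  a <- simulate_score_table(seed = 31)
  b <- simulate_score_table(seed = 31)
  expect_identical(a, b)
  tbl <- simulate_score_table(shift = c(PAN = 0L, PETI_BONE = 2L), seed = 13)
  wide <- merge(tbl[tbl$modality == "PAN", c("reader", "case", "criterion", "score")],
                tbl[tbl$modality == "PETI_BONE", c("reader", "case", "criterion", "score")],
                by = c("reader", "case", "criterion"))
  expect_true(all(wide$score.y == pmin(5L, wide$score.x + 2L)))
})

test_that("the bundled reader-study summary aggregates to the published averages", {
  summ <- reader_study_summary()
  expect_equal(nrow(summ), 75)
  avg <- tapply(summ$mean, paste(summ$modality, summ$criterion),
                across_reader_average)
  expect_equal(unname(avg[["PAN bone_quality"]]), 3.31)
  expect_equal(unname(avg[["PETI_BONE bone_quality"]]), 4.86)
  expect_equal(unname(avg[["PETI_COMBO diagnostic_acceptability"]]), 3.94)
  # total points per modality (sum of the 15 per-reader means)
  tot <- tapply(summ$mean, summ$modality, sum)
  expect_equal(unname(round(tot[["PETI_BONE"]], 1)), 67.6, tolerance = 0.11)
  expect_gt(tot[["PETI_BONE"]], tot[["PETI_COMBO"]])
  expect_gt(tot[["PETI_COMBO"]], tot[["PVMI60"]])
})
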