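test_that("normalization conventions give the documented arithmetic", {
  s <- summarize_calls(c(indel = 70, offtarget_translocation = 2,
                         general_translocation = 4, aav_integration = 24,
                         uncut = 900))
  expect_identical(s$total_events, 1000L)
  expect_equal(s$editing_efficiency, 7.6)
  expect_equal(s$aav_pct_of_total, 2.4)
  expect_equal(s$aav_pct_of_edited, 24 / 100 * 100)  # 24 of 76 + 24

  # all-uncut input: efficiency zero, AAV percentages well-defined
  s0 <- summarize_calls(c(uncut = 500))
  expect_equal(s0$editing_efficiency, 0)
  expect_equal(s0$aav_pct_of_total, 0)
  expect_true(is.na(s0$ot_tx_pct_of_edited))  # zero edited denominator

  # empty input: all-zero summary, undefined percentages, no errors
  se <- summarize_calls(list())
  expect_identical(se$total_events, 0L)
  expect_true(is.na(se$editing_efficiency))
})

test_that("normalization identity links the two AAV denominators", {
  # aav/total divided by aav/(edited+aav) equals the (edited+aav) fraction
  # of total events; the in-study pairing 11.0% vs 52.0% implies ~21.2%
  expect_equal(11.0 / 52.0, 0.212, tolerance = 0.005)
  withr::with_seed(61, {
    for (i in 1:25) {
      cnt <- c(indel = sample(0:500, 1), large_deletion = sample(0:50, 1),
               offtarget_translocation = sample(0:20, 1),
               general_translocation = sample(0:20, 1),
               aav_integration = sample(1:300, 1), uncut = sample(100:5000, 1))
      s <- summarize_calls(cnt)
      edited_aav <- sum(cnt) - cnt[["uncut"]]
      expect_equal(s$aav_pct_of_total / s$aav_pct_of_edited,
                   edited_aav / s$total_events)
      # class fractions of total sum to 100%
      expect_equal(sum(tidy(s)$pct_of_total, na.rm = TRUE), 100)
    }
  })
})

test_that("fold changes reproduce the reported comparisons", {
  expect_identical(fold_change(0.56, 0.13), 4.3)
  expect_identical(fold_change(0.1, 0.003), 33.3)
  expect_gte(fold_change(0.1, 0.003), 30)
  expect_identical(fold_change(2.7, 2.7), 1)
  expect_true(is.na(suppressMessages(fold_change(1, 0))))
  expect_false(is.na(fold_change(1, 0, pseudocount = 0.01)))
})

test_that("group comparison is a two-sided Welch t-test", {
  # degenerate identical groups
  same <- compare_groups(c(1, 1, 1), c(1, 1, 1))
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)

  # clear separation with tiny jitter
  sep <- compare_groups(c(1, 1.001, 0.999), c(2, 2.001, 1.999))
  expect_lt(sep$p_value, 0.01)

  # agrees with the reference implementation
  withr::with_seed(62, {
    a <- rnorm(5, 1, 0.5); b <- rnorm(7, 1.4, 0.8)
    ours <- compare_groups(a, b)
    ref <- stats::t.test(a, b)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$p_value, ref$p.value)
  })

  expect_error(compare_groups(1, c(1, 2)), "n >= 2")
})

test_that("Welch p agrees with an exhaustive permutation oracle at 6 vs 6", {
  withr::with_seed(63, {
    a <- rnorm(6, 0, 1)
    b <- rnorm(6, 1.2, 1)
  })
  ours <- compare_groups(a, b)$p_value
  # exhaustive two-sample permutation test on the mean difference
  pool <- c(a, b)
  combs <- utils::combn(12, 6)
  obs <- abs(mean(a) - mean(b))
  diffs <- apply(combs, 2, function(ix) {
    abs(mean(pool[ix]) - mean(pool[-ix]))
  })
  perm_p <- mean(diffs >= obs - 1e-12)
  expect_lt(abs(ours - perm_p), 0.02)
})

test_that("vector junction profile covers empty and uniform regimes", {
  v <- fix_vector()
  empty <- vector_junction_profile(
    tibble::tibble(class = character(0), prey_pos = integer(0)), v)
  expect_true(is.na(empty$itr_fraction))
  expect_identical(empty$n_junctions, 0L)

  # uniform breakpoints: ITR fraction ~ total ITR length / vector length
  n <- 4000
  pos <- withr::with_seed(64, sample.int(nchar(v$sequence), n) - 1L)
  calls <- tibble::tibble(class = "aav_integration", prey_pos = pos)
  prof <- vector_junction_profile(calls, v)
  p0 <- 290 / 4700
  expect_lt(abs(prof$itr_fraction - p0), 3 * sqrt(p0 * (1 - p0) / n))
  expect_identical(sum(prof$histogram$count), as.integer(n))
})

test_that("autoplot and tidiers produce well-formed output", {
  calls <- fix_small_calls()
  s <- summarize_calls(calls)
  g <- glance(s)
  expect_identical(nrow(g), 1L)
  td <- tidy(s)
  expect_true(all(c("class", "n", "pct_of_total") %in% names(td)))
  expect_s3_class(autoplot(s), "ggplot")
  prof <- vector_junction_profile(calls, fix_vector())
  expect_s3_class(autoplot(prof), "ggplot")
})
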