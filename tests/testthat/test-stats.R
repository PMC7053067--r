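test_that("complete-case filtering reports per-arm exclusions", {
  withr::with_seed(31, {
    u <- matrix(runif(251 * 4, 0.3, 0.9), 251, 4)
  })
  panel <- make_panel(u, rep(c("A", "B"), c(124, 127)))
  # knock out one follow-up utility for 5 A-subjects and 4 B-subjects
  drop_a <- sprintf("S%03d", 1:5)
  drop_b <- sprintf("S%03d", 125:128)
  panel$utility[panel$subject_id %in% drop_a & panel$visit_month == 12] <- NA
  panel$utility[panel$subject_id %in% drop_b & panel$visit_month == 24] <- NA
  cc <- complete_cases(panel)
  rep_a <- cc$report[cc$report$arm == "A", ]
  rep_b <- cc$report[cc$report$arm == "B", ]
  expect_equal(rep_a$retained, 119L)
  expect_equal(rep_a$pct, 4L)     # 5 of 124 -> 4%
  expect_equal(rep_b$retained, 123L)
  expect_equal(rep_b$pct, 3L)     # 4 of 127 -> 3%
  expect_setequal(cc$excluded, c(drop_a, drop_b))
  expect_equal(nrow(cc$data), (119 + 123) * 4)
  # no missing data: identity filter, empty report
  cc0 <- complete_cases(make_panel(u, rep(c("A", "B"), c(124, 127))))
  expect_equal(sum(cc0$report$excluded), 0L)
  expect_length(cc0$excluded, 0)
  # everything missing aborts
  panel$utility <- NA
  expect_error(complete_cases(panel), "no complete cases")
})

test_that("change from baseline is a plain difference with the right sign", {
  u <- rbind(c(0.5, 0.5, 0.5, 0.5),
             c(0.60, 0.65, 0.68, 0.71))
  ch <- change_from_baseline(make_panel(u, c("A", "A")))
  expect_equal(ch$change[ch$subject_id == "S001"], rep(0, 3))
  expect_equal(ch$change[ch$subject_id == "S002" & ch$visit_month == 24],
               0.11)
  expect_true(all(ch$change[ch$subject_id == "S002"] > 0))  # improvement
  expect_equal(ch$baseline[ch$subject_id == "S002"], rep(0.60, 3))
})

test_that("one-sample t matches hand arithmetic and the degenerate contract", {
  r <- within_group_test(c(0.1, 0.2, 0.3))
  expect_equal(r$t, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$t, 3.464, tolerance = 1e-3)
  expect_equal(r$df, 2)
  expect_equal(r$p, 0.0742, tolerance = 1e-3)
  z <- within_group_test(rep(0, 5))
  expect_true(z$degenerate)
  expect_equal(z$estimate, 0)
  expect_equal(z$p, 1)
  c5 <- within_group_test(rep(0.2, 5))
  expect_equal(c5$p, 0)
  expect_error(within_group_test(0.1), "at least 2")
})

test_that("two-sample pooled t matches hand arithmetic; Welch available", {
  r <- between_group_test(c(0.2, 0.3), c(0.0, 0.1))
  expect_equal(r$estimate, 0.2)
  expect_equal(r$se, 0.0707, tolerance = 1e-3)
  expect_equal(r$t, 2.828, tolerance = 1e-3)
  expect_equal(r$df, 2)
  w <- between_group_test(c(0.2, 0.3, 0.1), c(0.0, 0.4, 0.1, 0.2),
                          welch = TRUE)
  ref <- t.test(c(0.2, 0.3, 0.1), c(0.0, 0.4, 0.1, 0.2))
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-8)
})

test_that("t statistics agree with the reference implementation", {
  withr::with_seed(32, {
    for (i in 1:25) {
      x <- rnorm(sample(5:60, 1), sd = runif(1, 0.5, 2))
      y <- rnorm(sample(5:60, 1), mean = runif(1, -1, 1))
      one <- within_group_test(x)
      ref1 <- t.test(x, mu = 0, conf.level = 1 - 0.05 / 3)
      expect_equal(one$t, unname(ref1$statistic), tolerance = 1e-10)
      expect_equal(one$p, ref1$p.value, tolerance = 1e-10)
      expect_equal(c(one$ci_lo, one$ci_hi), as.numeric(ref1$conf.int),
                   tolerance = 1e-10)
      two <- between_group_test(x, y)
      ref2 <- t.test(x, y, var.equal = TRUE)
      expect_equal(two$t, unname(ref2$statistic), tolerance = 1e-10)
      expect_equal(two$p, ref2$p.value, tolerance = 1e-10)
    }
  })
})

test_that("rejection power at the adjusted level matches noncentral-t", {
  # true mean change 0.11, SD 0.2, n = 119: analytic power at alpha 0.017
  n <- 119; ncp <- 0.11 / (0.2 / sqrt(n)); q <- qt(1 - 0.017 / 2, n - 1)
  power <- pt(-q, n - 1, ncp) + pt(q, n - 1, ncp, lower.tail = FALSE)
  expect_gt(power, 0.99)
  withr::with_seed(33, {
    rej <- vapply(1:200, function(i) {
      r <- within_group_test(rnorm(n, 0.11, 0.2))
      r$p < 0.017
    }, logical(1))
  })
  expect_gt(mean(rej), 0.95)
})

test_that("Bonferroni adjustment divides the family level and caps p", {
  b <- bonferroni(c(0.5, 0.004), k = 3)
  expect_equal(b$threshold, 0.05 / 3)
  expect_equal(round(b$threshold, 3), 0.017)
  expect_equal(b$p_adj, c(1, 0.012))
  expect_error(bonferroni(0.5, k = 0), "k must be")
})

test_that("repeated-measures ANOVA detects injected arm effects and is
           location invariant", {
  withr::with_seed(34, {
    n <- 60
    base <- rnorm(2 * n, 0.6, 0.08)
    u <- sapply(c(0, 5, 12, 24), function(v)
      base + ifelse(rep(c(TRUE, FALSE), each = n) & v > 0, 0.12, 0) +
        rnorm(2 * n, 0, 0.05))
  })
  panel <- make_panel(u, rep(c("A", "B"), each = n))
  a <- repeated_measures_anova(panel)
  expect_setequal(a$effect, c("arm", "visit", "arm:visit"))
  expect_lt(a$p[a$effect == "arm"], 0.001)
  expect_lt(a$p[a$effect == "arm:visit"], 0.001)
  eps <- attr(a, "gg_epsilon")
  expect_true(eps > 1 / 3 && eps <= 1 + 1e-9)  # bounds for k = 4
  expect_true(all(a$p_gg[a$effect != "arm"] >= a$p[a$effect != "arm"] |
                    eps >= 1))
  # adding a constant to every utility leaves all F statistics unchanged
  panel2 <- panel; panel2$utility <- panel2$utility + 0.17
  a2 <- repeated_measures_anova(panel2)
  expect_equal(a2$F, a$F, tolerance = 1e-9)
  # singular designs abort
  expect_error(repeated_measures_anova(panel[panel$arm == "A", ]),
               "singular")
})

test_that("responsiveness statistics are the defined ratios", {
  ch <- c(-0.1, 0.1, 0.3)  # mean 0.1, sd 0.2
  bl <- c(0.5, 0.7, 0.6)
  r <- responsiveness(ch, bl, group = "A")
  expect_equal(r$srm, 0.5)
  expect_equal(r$es, 0.1 / sd(bl))
  expect_identical(sign(r$es), sign(r$srm))
  # constant change: SRM undefined, ES still defined
  rc <- responsiveness(c(0.2, 0.2, 0.2), bl)
  expect_true(is.na(rc$srm))
  expect_true(rc$degenerate)
  expect_equal(rc$es, 0.2 / sd(bl))
})

test_that("a group with larger true change has larger ES and SRM", {
  withr::with_seed(35, {
    ord <- replicate(200, {
      bl <- rnorm(60, 0.6, 0.1)
      ra <- responsiveness(rnorm(60, 0.12, 0.1), bl, "A")
      rb <- responsiveness(rnorm(60, 0.02, 0.1), bl, "B")
      c(ra$es > rb$es, ra$srm > rb$srm)
    })
  })
  expect_gt(mean(ord[1, ]), 0.95)
  expect_gt(mean(ord[2, ]), 0.95)
})

test_that("H&Y strata summaries are Tukey boxplot statistics", {
  s <- hy_strata(rep(1, 5), c(1, 2, 3, 4, 5), min_n = 3)
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$whisker_lo, 1)
  expect_equal(s$whisker_hi, 5)
  expect_equal(s$n_outliers, 0L)
  # an extreme point becomes an outlier; whiskers clip to the data range
  s2 <- hy_strata(rep(2, 6), c(1, 2, 3, 4, 5, 50), min_n = 3)
  expect_equal(s2$n_outliers, 1L)
  expect_equal(attr(s2, "outliers")[["2"]], 50)
  expect_equal(s2$whisker_hi, 5)
  # degenerate box: all values identical
  s3 <- hy_strata(rep(1.5, 4), rep(0.8, 4), min_n = 3)
  expect_true(all(unlist(s3[c("median", "q1", "q3", "whisker_lo",
                              "whisker_hi")]) == 0.8))
  # conservation and reliability flag
  withr::with_seed(36, {
    stage <- sample(c(1, 1.5, 2, 2.5, 3), 200, TRUE,
                    prob = c(0.3, 0.3, 0.25, 0.13, 0.02))
    val <- rnorm(200)
  })
  tab <- hy_strata(stage, val)
  expect_equal(sum(tab$n), 200L)
  expect_true(all(tab$low_reliability == (tab$n < 10)))
  expect_true(all(tab$q1 <= tab$median & tab$median <= tab$q3))
  expect_error(hy_strata(c(1, 6), c(0.1, 0.2)), "H&Y")
})
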