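make_measure_tibble <- function(Y, measure = "y_ASI") {
  n <- nrow(Y)
  tibble::tibble(
    specimen_id = rep(sprintf("s%02d", seq_len(n)), each = 6L),
    condition = rep(rep(c("intact", "partial", "complete"), each = 2L), n),
    configuration = rep(c("d0", "d1"), 3L * n),
    measure = measure,
    value = as.vector(t(Y))
  )
}

test_that("the within-specimen F test matches the aov oracle", {
  set.seed(11)
  for (rep in 1:5) {
    Y <- matrix(rnorm(66, rep(c(0, 2, 0, 3, 1, 6), each = 11), 2), 11, 6) +
      rnorm(11, 0, 3)
    tb <- make_measure_tibble(Y)
    a <- rm_anova(tb)
    df <- transform(as.data.frame(tb), cell = paste(condition, configuration))
    fit <- summary(stats::aov(value ~ cell + Error(specimen_id), data = df))
    s <- fit[["Error: Within"]][[1]]
    expect_equal(a$F, s[["F value"]][1], tolerance = 1e-9)
    expect_equal(a$p, s[["Pr(>F)"]][1], tolerance = 1e-9)
    expect_equal(a$df, c(5L, 50L))
  }
})

test_that("the two-cell reduction equals the squared paired t statistic", {
  set.seed(12)
  Y <- matrix(rnorm(22, c(0, 4), 2), 11, 2, byrow = TRUE)
  tb <- make_measure_tibble(Y[, c(1, 2, 1, 2, 1, 2)])
  tb <- tb[tb$condition == "intact", ]
  a <- rm_anova(tb)
  t_stat <- stats::t.test(Y[, 2] - Y[, 1])$statistic
  expect_equal(a$F, unname(t_stat^2), tolerance = 1e-9)
})

test_that("degenerate and incomplete inputs are handled", {
  # all cells identical within specimen: F = 0, p = 1
  Y <- matrix(rep(c(1, 5, 3), each = 6), 3, 6, byrow = TRUE)
  a <- rm_anova(make_measure_tibble(Y))
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  # incomplete specimen dropped with a warning
  tb <- make_measure_tibble(matrix(rnorm(18), 3, 6))
  expect_warning(a2 <- rm_anova(tb[-1, ]), "incomplete")
  expect_equal(a2$n, 2L)
  # fewer than 2 complete specimens: error
  expect_error(suppressWarnings(rm_anova(tb[1:11, ])), "at least 2")
})

test_that("Bonferroni adjustment is min(1, m p) and strata follow the thresholds", {
  set.seed(13)
  Y <- matrix(rnorm(36, rep(c(0, 8, 0, 8, 0, 8), each = 6), 1), 6, 6) +
    rnorm(6, 0, 1)
  a <- rm_anova(make_measure_tibble(Y))
  expect_equal(nrow(a$posthoc), 5L) # five cells vs the unloaded intact baseline
  expect_equal(a$posthoc$p_adj, pmin(1, 5 * a$posthoc$p_raw))
  expect_true(all(diff(order(a$posthoc$p_raw)) == diff(order(a$posthoc$p_adj))))
  all_pairs <- rm_anova(make_measure_tibble(Y), posthoc = "all")
  expect_equal(nrow(all_pairs$posthoc), 15L)
  expect_equal(all_pairs$posthoc$p_adj, pmin(1, 15 * all_pairs$posthoc$p_raw))
  expect_identical(kneelax:::significance_stratum(c(0.2, 0.01, 0.0005)), c("ns", "**", "***"))
  # tidy/glance accessors
  expect_s3_class(generics::tidy(a), "tbl_df")
  expect_equal(generics::glance(a)$p.value, a$p)
})

test_that("Greenhouse-Geisser epsilon is bounded and rescales the dfs", {
  set.seed(14)
  Y <- matrix(rnorm(48, rep(c(0, 3, 0, 3, 0, 3), each = 8), 1), 8, 6) +
    rnorm(8, 0, 2)
  Y[, 6] <- Y[, 6] * 4 # break sphericity
  a_plain <- rm_anova(make_measure_tibble(Y))
  a_gg <- rm_anova(make_measure_tibble(Y), gg = TRUE)
  expect_gte(a_gg$epsilon, 1 / 5)
  expect_lte(a_gg$epsilon, 1)
  expect_lt(a_gg$epsilon, 1 - 1e-6) # sphericity really is broken here
  expect_equal(a_gg$F, a_plain$F)
  expect_equal(
    a_gg$p,
    stats::pf(a_gg$F, a_gg$epsilon * 5, a_gg$epsilon * 35, lower.tail = FALSE)
  )
})

test_that("effect size is the mean paired difference over its sample SD", {
  expect_error(effect_size(c(1, 1, 1, 1)), "Zero standard deviation")
  expect_equal(effect_size(c(0, 2)), 1 / sqrt(2))
  set.seed(15)
  d <- rnorm(1e5, 1.4, 1)
  expect_equal(effect_size(d), 1.4, tolerance = 0.01)
})

test_that("paired sample size matches the closed-form power oracle", {
  # large effects bottom out at the n = 2 floor
  expect_equal(sample_size_paired(50), 2L)
  for (d in c(0.5, 1.0, 1.4)) {
    oracle <- ceiling(stats::power.t.test(
      delta = d, sd = 1, sig.level = 0.05, power = 0.8, type = "paired"
    )$n)
    expect_equal(sample_size_paired(d), oracle)
  }
  # power is attained at n and not at n - 1
  n <- sample_size_paired(0.5)
  expect_gte(power_paired_t(n, 0.5), 0.8)
  expect_lt(power_paired_t(n - 1, 0.5), 0.8)
  expect_error(sample_size_paired(0.001, n_max = 50), "No n")
})

test_that("the summary table mirrors the study layout", {
  set.seed(16)
  Y <- matrix(rnorm(36, rep(c(0, 3, 1, 4, 1, 9), each = 6), 1.5), 6, 6)
  tb <- make_measure_tibble(Y)
  d <- compute_deltas(tb)
  s <- summary_table(d)
  expect_equal(s$measure, "y_ASI")
  expect_named(s, c(
    "measure", "Delta1[intact]", "Delta0[partial]", "Delta1[partial]",
    "Delta0[complete]", "Delta1[complete]", "p", "stratum"
  ))
  expect_match(s[["Delta1[intact]"]], "±")
  # the identically-zero unloaded intact column is not reported
  expect_false(any(grepl("Delta0\\[intact\\]", names(s))))
  # single specimen: means equal the values, no SD shown
  s1 <- summary_table(d[d$specimen_id == "s01", ])
  expect_false(grepl("±", s1[["Delta1[intact]"]]))
  expect_true(is.na(s1$p))
  # empty input: empty table, no crash
  s0 <- summary_table(d[0, ])
  expect_equal(nrow(s0), 0L)
})
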