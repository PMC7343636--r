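test_that("pooled t-test handles identical and degenerate inputs", {
  x <- c(3, 5, 7, 9)
  cmp <- two_sample_t(x, x)
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$hedges_g, 0)

  same <- rep(4, 5)
  expect_equal(two_sample_t(same, same)$p_value, 1)
  expect_error(two_sample_t(rep(4, 5), rep(6, 5)), "degenerate")
})

test_that("t-test from raw values equals t-test from summaries", {
  set.seed(11)
  for (i in 1:5) {
    a <- rnorm(sample(5:40, 1), mean = 10, sd = 4)
    b <- rnorm(sample(5:40, 1), mean = 12, sd = 6)
    raw <- two_sample_t(a, b)
    summ <- two_sample_t(group_summary("a", length(a), mean(a), sd(a)),
                         group_summary("b", length(b), mean(b), sd(b)))
    expect_equal(raw$t_statistic, summ$t_statistic, tolerance = 1e-10)
    expect_equal(raw$p_value, summ$p_value, tolerance = 1e-10)
    # against the reference implementation
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(raw$t_statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(raw$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("Hedges' g has the documented symmetry and correction behavior", {
  a <- group_summary("a", 20, 50, 10)
  b <- group_summary("b", 25, 50, 12)
  expect_equal(hedges_g(a, b), 0)

  c1 <- group_summary("a", 12, 60, 9)
  c2 <- group_summary("b", 15, 48, 11)
  expect_equal(hedges_g(c1, c2), -hedges_g(c2, c1))
  expect_gt(hedges_g(c1, c2), 0)  # control-minus-treated sign convention

  for (df in c(20, 50, 141)) {
    expect_lt(abs(hedges_correction(df) - hedges_correction(df, "approx")),
              1e-3)
    expect_lt(hedges_correction(df), 1)
  }
  expect_error(hedges_g(group_summary("a", 4, 1, 0),
                        group_summary("b", 4, 1, 0)), "degenerate")
})

test_that("published effect sizes are reproduced from their summaries", {
  for (row in table1_summaries()) {
    g <- hedges_g(row$control, row$treated)
    expect_lt(abs(g - row$printed_g) / row$printed_g, 0.02)
  }
})

# classical balanced two-way decomposition, the Type III oracle
balanced_anova_ss <- function(df) {
  r <- nrow(df) / 4
  gm <- mean(df$value)
  am <- tapply(df$value, df$cell_type, mean)
  bm <- tapply(df$value, df$treatment, mean)
  cm <- tapply(df$value, list(df$cell_type, df$treatment), mean)
  ss_a <- 2 * r * sum((am - gm)^2)
  ss_b <- 2 * r * sum((bm - gm)^2)
  ss_ab <- r * sum((cm - outer(am - gm, bm - gm, "+") - gm)^2)
  c(cell_type = ss_a, treatment = ss_b, interaction = ss_ab)
}

test_that("Type III sums of squares match the balanced closed form", {
  set.seed(12)
  for (i in 1:5) {
    df <- expand.grid(cell_type = c("cSCC", "keratinocyte"),
                      treatment = c("untreated", "treated"),
                      rep = 1:6)
    df$value <- rnorm(nrow(df), mean = 50, sd = 15) +
      5 * (df$cell_type == "cSCC") * (df$treatment == "treated")
    tab <- two_way_anova_unbalanced(df)
    want <- balanced_anova_ss(df)
    expect_equal(tab$sum_of_squares[tab$term == "cell_type"],
                 unname(want["cell_type"]), tolerance = 1e-8)
    expect_equal(tab$sum_of_squares[tab$term == "treatment"],
                 unname(want["treatment"]), tolerance = 1e-8)
    expect_equal(tab$sum_of_squares[tab$term == "cell_type:treatment"],
                 unname(want["interaction"]), tolerance = 1e-8)
    expect_true(all(tab$sum_of_squares >= 0))
    expect_true(all(tab$df >= 1))
  }
})

test_that("identical cell patterns give zero F everywhere", {
  df <- expand.grid(cell_type = c("cSCC", "keratinocyte"),
                    treatment = c("untreated", "treated"), rep = 1:3)
  df$value <- rep(c(10, 20, 30), each = 4)  # same value set in every cell
  tab <- two_way_anova_unbalanced(df)
  keep <- tab$term != "Residuals"
  expect_true(all(abs(tab$F[keep]) < 1e-10))
  expect_true(all(tab$p[keep] > 0.999))
})

test_that("unbalanced designs are accepted and degenerate ones rejected", {
  set.seed(13)
  df <- data.frame(
    cell_type = rep(c("cSCC", "keratinocyte"), c(14, 9)),
    treatment = c(rep(c("untreated", "treated"), c(6, 8)),
                  rep(c("untreated", "treated"), c(5, 4))),
    value = rnorm(23, 50, 10))
  tab <- two_way_anova_unbalanced(df)
  expect_identical(nrow(tab), 4L)
  expect_true(all(tab$sum_of_squares >= 0))

  one_level <- data.frame(cell_type = "cSCC",
                          treatment = rep(c("untreated", "treated"), 4),
                          value = rnorm(8))
  expect_error(two_way_anova_unbalanced(one_level), "design error")
})

test_that("dose-response summaries order groups by dose", {
  eff <- data.frame(group = rep(c("control", "treated_1x"), each = 3),
                    percent_of_pre = 100)
  tab <- dose_response_summary(eff)
  expect_equal(tab$mean_reduction, c(0, 0))
  expect_equal(tab$sd_reduction, c(0, 0))

  single <- dose_response_summary(data.frame(group = "treated_2x",
                                             percent_of_pre = c(30, 40)))
  expect_identical(nrow(single), 1L)
  expect_equal(single$mean_reduction, 65)

  set.seed(14)
  design <- data.frame(group = c("control", "treated_1x", "treated_2x"),
                       cell_type = "cSCC", n = 25,
                       kill = c(0, 0.35, 0.7), pre_count = 50)
  sim <- simulate_treatment_effects(design)
  tab <- dose_response_summary(sim)
  expect_identical(tab$group, c("control", "treated_1x", "treated_2x"))
  expect_true(all(diff(tab$mean_reduction) > 0))
})

test_that("the count-level effect simulator respects its bounds", {
  set.seed(15)
  design <- data.frame(group = "treated_1x", cell_type = "cSCC",
                       n = 40, kill = 0.5, pre_count = 60)
  sim <- simulate_treatment_effects(design)
  expect_identical(nrow(sim), 40L)
  expect_true(all(sim$post_value <= sim$pre_value))
  expect_true(all(sim$percent_of_pre >= 0 & sim$percent_of_pre <= 100))
  expect_lt(abs(mean(sim$percent_of_pre) - 50), 10)
})
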