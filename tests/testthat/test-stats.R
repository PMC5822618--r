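make_groups_df <- function(x, y) {
  data.frame(group = rep(c("a", "b"), c(length(x), length(y))),
             value = c(x, y))
}

test_that("compare_continuous gates on normality and matches exact Wilcoxon", {
  # identical groups: p = 1 whichever branch the gate selects, and exactly
  # 1 under the forced Wilcoxon branch
  df <- make_groups_df(c(1, 2, 3), c(1, 2, 3))
  expect_equal(compare_continuous(df, "value")$p_value, 1.0)
  expect_equal(compare_continuous(df, "value", test = "wilcoxon")$p_value,
               1.0)

  # fully separated small groups: exact p = 2 / C(8,4)
  df2 <- make_groups_df(c(1, 2, 3, 4), c(10, 11, 12, 13))
  res2 <- compare_continuous(df2, "value", test = "wilcoxon")
  expect_match(res2$test_name, "Exact Wilcoxon")
  expect_equal(res2$p_value, 2 / choose(8, 4), tolerance = 1e-12)
  expect_equal(res2$p_value,
               oracle_wilcoxon_p(c(1, 2, 3, 4), c(10, 11, 12, 13)),
               tolerance = 1e-12)

  # constant variable: warning, Wilcoxon branch
  df3 <- make_groups_df(c(5, 5, 5), c(5, 5, 6))
  expect_warning(res3 <- compare_continuous(df3, "value"), "Shapiro")
  expect_match(res3$test_name, "Wilcoxon")

  # summaries carry both conventions
  expect_true(all(c("mean", "sd", "median", "q1", "q3") %in%
                    names(res2$summary)))
  expect_error(compare_continuous(make_groups_df(1:2, 1:5), "value"),
               ">= 3")
})

test_that("Wilcoxon branch equals full-enumeration oracles (n <= 12)", {
  set.seed(31)
  sizes <- list(c(3, 3), c(4, 4), c(5, 5), c(6, 6), c(4, 8), c(3, 9))
  for (sz in sizes) {
    x <- round(rcauchy(sz[1]), 3)
    y <- round(rcauchy(sz[2]) + 2, 3)
    df <- make_groups_df(x, y)
    res <- compare_continuous(df, "value", test = "wilcoxon")
    expect_match(res$test_name, "Exact Wilcoxon")
    expect_equal(res$p_value, oracle_wilcoxon_p(x, y), tolerance = 1e-10,
                 label = paste("sizes", sz[1], sz[2]))
  }
})

test_that("compare_categorical matches Fisher enumeration", {
  # balanced table: p = 1
  df <- data.frame(group = rep(c("a", "b"), each = 10),
                   flag = rep(c(TRUE, FALSE, TRUE, FALSE), c(5, 5, 5, 5)))
  expect_equal(compare_categorical(df, "flag")$p_value, 1.0)
  # perfectly separated: p = 2 / C(20,10)
  df2 <- data.frame(group = rep(c("a", "b"), each = 10),
                    flag = rep(c(TRUE, FALSE), each = 10))
  expect_equal(compare_categorical(df2, "flag")$p_value,
               2 / choose(20, 10), tolerance = 1e-12)
  # random tables equal the hypergeometric enumeration oracle
  set.seed(17)
  for (i in 1:5) {
    g <- rep(c("a", "b"), c(6, 6))
    f <- runif(12) < 0.5
    df3 <- data.frame(group = g, flag = f)
    if (length(unique(f)) < 2) next
    tab <- table(factor(g), factor(f, levels = c(FALSE, TRUE)))
    expect_equal(compare_categorical(df3, "flag")$p_value,
                 oracle_fisher_p(tab), tolerance = 1e-10)
  }
  # a group with no rows is an error
  df4 <- data.frame(group = rep("a", 6), flag = rep(c(TRUE, FALSE), 3))
  expect_error(compare_categorical(df4, "flag"), "two groups")
})

test_that("adjusted_group_means reduces to raw means without covariate spread", {
  set.seed(5)
  df <- data.frame(group = rep(c("a", "b"), each = 20),
                   y = c(rnorm(20, 1), rnorm(20, 2)),
                   age = 50, lv_mass = 80, bmi = 25, female = TRUE)
  # constant covariates are collinear with the intercept -> error
  expect_error(adjusted_group_means(df, "y"), "rank-deficient")
  # covariates balanced across groups (periods divide the group size) but
  # not collinear with one another
  df$age <- rep(c(40, 60), 20)
  df$lv_mass <- rep(c(70, 80, 90, 100), 10)
  df$bmi <- rep(c(20, 24, 28, 32, 36), 8)
  df$female <- rep(c(TRUE, FALSE, FALSE, TRUE), 10)
  a <- adjusted_group_means(df, "y")
  raw <- as.vector(tapply(df$y, df$group, mean))
  expect_equal(unname(a$adjusted_means), raw, tolerance = 1e-10)
  # adjusted-mean difference equals the group coefficient
  expect_equal(unname(diff(a$adjusted_means)),
               unname(coef(a$model)["groupb"]), tolerance = 1e-12)
})

test_that("adjusted_group_means recovers an injected effect and hand OLS", {
  set.seed(88)
  n <- 200
  grp <- rep(c("control", "mvd_risk"), each = n / 2)
  bmi <- rnorm(n, 28, 5)
  y <- 2 + 1.0 * (grp == "mvd_risk") - 0.05 * bmi + rnorm(n, 0, 0.1)
  df <- data.frame(group = grp, y = y, bmi = bmi)
  a <- adjusted_group_means(df, "y", covariates = "bmi")
  eff <- unname(a$adjusted_means["mvd_risk"] - a$adjusted_means["control"])
  expect_equal(eff, 1.0, tolerance = 0.05)
  expect_lt(a$group_p, 1e-6)

  # 3+3 integer hand case against the normal-equations oracle
  hand <- data.frame(group = rep(c("a", "b"), each = 3),
                     y = c(3, 5, 4, 8, 9, 10),
                     x = c(1, 2, 3, 2, 3, 4))
  X <- cbind(1, as.numeric(hand$group == "b"), hand$x)
  beta <- solve(t(X) %*% X, t(X) %*% hand$y)
  ah <- adjusted_group_means(hand, "y", covariates = "x")
  expect_equal(unname(coef(ah$model)), as.vector(beta), tolerance = 1e-10)

  # complete-case handling is reported
  df$bmi[1:5] <- NA
  a2 <- adjusted_group_means(df, "y", covariates = "bmi")
  expect_equal(a2$n_dropped, 5L)
  expect_equal(a2$n_used, n - 5L)
})

test_that("Tukey-adjusted pairwise contrasts appear for > 2 groups", {
  set.seed(12)
  df <- data.frame(group = rep(c("a", "b", "c"), each = 15),
                   y = rnorm(45) + rep(c(0, 0.3, 2), each = 15),
                   x = rnorm(45))
  a <- adjusted_group_means(df, "y", covariates = "x")
  expect_equal(nrow(a$pairwise), 3L)
  expect_true(all(a$pairwise$adjusted == "tukey"))
  expect_true(all(a$pairwise$p_value >= 0 & a$pairwise$p_value <= 1))
  # the well-separated contrast dominates
  pc <- a$pairwise[a$pairwise$contrast == "c - a", "p_value"]
  expect_lt(pc, 0.001)
})

test_that("build_tables renders gated summaries for both study tables", {
  ch <- gen_cohort(cohort_spec_default(), seed = 2)
  tb <- build_tables(ch$table)
  expect_true(all(c("variable", "mvd_risk", "control", "p_value", "test")
                  %in% names(tb$table1)))
  expect_equal(tb$table2$variable,
               c("rest_mbf", "stress_mbf", "mpr", "lvef", "lv_mass", "ecv",
                 "native_t1"))
  # normally generated stress MBF renders as mean +/- SD
  stress_row <- tb$table2[tb$table2$variable == "stress_mbf", ]
  expect_match(stress_row$mvd_risk, "±")
  # deterministic under a fixed seed
  tb2 <- build_tables(gen_cohort(cohort_spec_default(), seed = 2)$table)
  expect_identical(tb, tb2)
  # empty group errors
  solo <- ch$table[ch$table$group == "control", ]
  expect_error(build_tables(solo), "nonempty")
})
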