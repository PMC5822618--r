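#' Normality-gated two-group comparison of a continuous variable
#'
#' Shapiro-Wilk normality is assessed per group at `alpha_normality`; if
#' both groups pass, a two-sided pooled-variance t-test is used and the
#' groups are summarized as mean +/- SD. Otherwise the Wilcoxon-Mann-Whitney
#' test is used (exact when the combined sample is at most `exact_max_n`
#' and tie-free; normal approximation with continuity correction otherwise)
#' and the groups are summarized as median \[Q1, Q3\]. A constant variable
#' (Shapiro-Wilk undefined) falls to the Wilcoxon branch with a warning.
#'
#' @param table Data frame with a two-level `group` column.
#' @param variable Name of the numeric column to compare.
#' @param alpha_normality Per-group Shapiro-Wilk gate.
#' @param exact_max_n Combined-n cutoff for the exact Wilcoxon distribution.
#' @param welch Use Welch's t-test instead of pooled variance.
#' @param group_col Name of the grouping column.
#' @param test `"auto"` applies the normality gate; `"t"` or `"wilcoxon"`
#'   forces a branch.
#' @return A list of class `perf_test_result`: `variable`, `test_name`,
#'   `statistic`, `p_value`, `summary` (per-group data.frame), `normal`,
#'   `normality_p`, `exact`, `n`.
#' @export
compare_continuous <- function(table, variable, alpha_normality = 0.05,
                               exact_max_n = 50, welch = FALSE,
                               group_col = "group",
                               test = c("auto", "t", "wilcoxon")) {
  test <- match.arg(test)
  groups <- split(table[[variable]], table[[group_col]])
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (length(groups) != 2) stop("exactly two groups are required")
  if (any(vapply(groups, length, 1L) < 3)) {
    stop("each group needs >= 3 non-missing values")
  }
  sw <- lapply(groups, function(v) {
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
  })
  sw_p <- unlist(sw)
  if (test == "auto" && any(is.na(sw_p))) {
    warning("Shapiro-Wilk undefined (constant values); using Wilcoxon")
  }
  normal <- switch(test,
    auto = all(!is.na(sw_p)) && all(sw_p >= alpha_normality),
    t = TRUE,
    wilcoxon = FALSE)
  x <- groups[[1]]; y <- groups[[2]]
  n_tot <- length(x) + length(y)
  if (normal) {
    tt <- stats::t.test(x, y, var.equal = !welch)
    test_name <- if (welch) "Welch t-test" else "Two-sample t-test (pooled)"
    statistic <- unname(tt$statistic)
    p <- tt$p.value
    exact <- NA
  } else {
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- n_tot <= exact_max_n && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    test_name <- if (exact) "Exact Wilcoxon-Mann-Whitney"
                 else "Wilcoxon-Mann-Whitney (normal approximation)"
    statistic <- unname(wt$statistic)
    p <- wt$p.value
  }
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    data.frame(group = g, n = length(v), mean = mean(v), sd = stats::sd(v),
               median = stats::median(v),
               q1 = unname(stats::quantile(v, 0.25)),
               q3 = unname(stats::quantile(v, 0.75)))
  }))
  structure(list(variable = variable, test_name = test_name,
                 statistic = statistic, p_value = p, summary = summ,
                 normal = normal, normality_p = sw_p, exact = exact,
                 n = vapply(groups, length, 1L)),
            class = "perf_test_result")
}

#' Two-group comparison of a categorical flag (Fisher exact)
#'
#' Two-sided Fisher exact test of a binary flag against the two-level
#' group, via the hypergeometric distribution.
#'
#' @param table Data frame with `group` and the flag column.
#' @param flag Name of the logical/binary column.
#' @param group_col Name of the grouping column.
#' @return A `perf_test_result` with `summary` giving n and percentage per
#'   group.
#' @export
compare_categorical <- function(table, flag, group_col = "group") {
  g <- factor(table[[group_col]])
  f <- table[[flag]]
  ok <- !is.na(f) & !is.na(g)
  g <- droplevels(g[ok]); f <- f[ok]
  if (nlevels(g) != 2) stop("exactly two groups are required")
  f <- factor(as.logical(f), levels = c(FALSE, TRUE))
  tab <- table(g, f)
  if (any(rowSums(tab) == 0)) stop("a group has no observations for ", flag)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  summ <- do.call(rbind, lapply(levels(g), function(lev) {
    n <- sum(g == lev)
    k <- sum(f[g == lev] == TRUE)
    data.frame(group = lev, n = n, count = k, pct = 100 * k / n)
  }))
  structure(list(variable = flag, test_name = "Fisher exact",
                 statistic = NA_real_, p_value = ft$p.value, summary = summ,
                 normal = NA, normality_p = NULL, exact = TRUE,
                 n = rowSums(tab)),
            class = "perf_test_result")
}

#' Covariate-adjusted group means of a perfusion outcome
#'
#' Ordinary least squares of the outcome on the group indicator plus
#' covariates (complete-case; dropped rows are counted). Adjusted group
#' means are model predictions with every covariate held at its grand mean
#' over the analysis rows, so the adjusted-mean difference equals the group
#' coefficient. With more than two groups, pairwise differences are
#' Tukey-adjusted (studentized-range p-values).
#'
#' @param table Cohort data frame.
#' @param outcome Outcome column (e.g. `rest_mbf`, `stress_mbf`, `mpr`).
#' @param covariates Covariate columns; logical columns are coded 0/1.
#' @param group_col Name of the grouping column.
#' @return A list of class `adjusted_means`: `outcome`, `covariates`,
#'   `adjusted_means` (per group), `group_p`, `covariate_p`, `pairwise`
#'   (with Tukey-adjusted p when > 2 groups), `n_used`, `n_dropped`,
#'   `model`.
#' @export
adjusted_group_means <- function(table, outcome,
                                 covariates = c("age", "lv_mass", "bmi",
                                                "female"),
                                 group_col = "group") {
  cols <- c(outcome, covariates, group_col)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  dat <- table[, cols]
  cc <- stats::complete.cases(dat)
  n_dropped <- sum(!cc)
  dat <- dat[cc, ]
  dat[[group_col]] <- factor(dat[[group_col]])
  for (cv in covariates) {
    if (is.logical(dat[[cv]])) dat[[cv]] <- as.numeric(dat[[cv]])
  }
  fml <- stats::as.formula(paste(outcome, "~", group_col, "+",
                                 paste(covariates, collapse = " + ")))
  mm <- stats::model.matrix(fml, dat)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    bad <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(fml, data = dat)
  levs <- levels(dat[[group_col]])
  newdata <- dat[rep(1, length(levs)), , drop = FALSE]
  newdata[[group_col]] <- factor(levs, levels = levs)
  for (cv in covariates) newdata[[cv]] <- mean(dat[[cv]])
  adj <- stats::predict(fit, newdata = newdata)
  names(adj) <- levs

  coefs <- summary(fit)$coefficients
  grp_rows <- grep(paste0("^", group_col), rownames(coefs))
  cov_p <- coefs[covariates, "Pr(>|t|)"]
  if (length(levs) == 2) {
    group_p <- coefs[grp_rows, "Pr(>|t|)"]
    pairwise <- data.frame(contrast = paste(levs[2], "-", levs[1]),
                           estimate = coefs[grp_rows, "Estimate"],
                           p_value = group_p, adjusted = "none")
  } else {
    group_p <- stats::anova(fit)[group_col, "Pr(>F)"]
    V <- stats::vcov(fit)
    df_res <- fit$df.residual
    prs <- utils::combn(levs, 2, simplify = FALSE)
    pairwise <- do.call(rbind, lapply(prs, function(pr) {
      cvec <- stats::setNames(numeric(length(stats::coef(fit))),
                              names(stats::coef(fit)))
      for (s in c(1, -1)) {
        lev <- pr[if (s == 1) 2 else 1]
        nm <- paste0(group_col, lev)
        if (nm %in% names(cvec)) cvec[nm] <- cvec[nm] + s
      }
      est <- sum(cvec * stats::coef(fit))
      se <- sqrt(drop(t(cvec) %*% V %*% cvec))
      p <- stats::ptukey(sqrt(2) * abs(est / se), length(levs), df_res,
                         lower.tail = FALSE)
      data.frame(contrast = paste(pr[2], "-", pr[1]), estimate = est,
                 p_value = p, adjusted = "tukey")
    }))
  }
  structure(list(outcome = outcome, covariates = covariates,
                 adjusted_means = adj, group_p = unname(group_p),
                 covariate_p = cov_p, pairwise = pairwise,
                 n_used = nrow(dat), n_dropped = n_dropped, model = fit),
            class = "adjusted_means")
}

#' Descriptive study tables with normality-gated summaries
#'
#' Builds a patient-characteristics table (age, BMI, female and risk-factor
#' flags) and an imaging-parameters table (rest/stress MBF, MPR, LVEF, LV
#' mass, ECV, native T1), each row summarized as mean +/- SD or
#' median \[Q1, Q3\] per the normality gate, with the matching test's
#' p-value; categorical rows are n (%) with Fisher exact p.
#'
#' @param table Cohort data frame (see [gen_cohort()]).
#' @param group_col Name of the grouping column.
#' @return A list: `table1` and `table2` data.frames (columns `variable`,
#'   one per group, `p_value`, `test`).
#' @export
build_tables <- function(table, group_col = "group") {
  g <- factor(table[[group_col]])
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    stop("both groups must be nonempty")
  }
  levs <- levels(g)

  cont_row <- function(var) {
    res <- compare_continuous(table, var, group_col = group_col)
    cells <- vapply(levs, function(lev) {
      s <- res$summary[res$summary$group == lev, ]
      if (res$normal) sprintf("%.2f ± %.2f", s$mean, s$sd)
      else sprintf("%.2f [%.2f, %.2f]", s$median, s$q1, s$q3)
    }, character(1))
    c(variable = var, cells, p_value = format_p(res$p_value),
      test = res$test_name)
  }
  cat_row <- function(var) {
    res <- compare_categorical(table, var, group_col = group_col)
    cells <- vapply(levs, function(lev) {
      s <- res$summary[res$summary$group == lev, ]
      sprintf("%d (%.0f%%)", s$count, s$pct)
    }, character(1))
    c(variable = var, cells, p_value = format_p(res$p_value),
      test = res$test_name)
  }
  as_df <- function(rows) {
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- c("variable", levs, "p_value", "test")
    df
  }
  t1_cont <- intersect(c("age", "bmi"), names(table))
  t1_cat <- intersect(c("female", "diabetes", "smoking", "htn", "hld"),
                      names(table))
  t2_cont <- intersect(c("rest_mbf", "stress_mbf", "mpr", "lvef", "lv_mass",
                         "ecv", "native_t1"), names(table))
  list(table1 = as_df(c(lapply(t1_cont, cont_row), lapply(t1_cat, cat_row))),
       table2 = as_df(lapply(t2_cont, cont_row)))
}

format_p <- function(p) {
  if (p < 0.001) "<0.001" else sprintf("%.3f", p)
}

#' @export
print.perf_test_result <- function(x, ...) {
  cat(sprintf("%s: %s, p = %.4g\n", x$variable, x$test_name, x$p_value))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
print.adjusted_means <- function(x, ...) {
  cat(sprintf("Adjusted means of %s (covariates: %s)\n", x$outcome,
              paste(x$covariates, collapse = ", ")))
  print(round(x$adjusted_means, 4))
  cat(sprintf("group p = %.4g; n used = %d, dropped = %d\n",
              x$group_p, x$n_used, x$n_dropped))
  invisible(x)
}
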