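test_that("rm ANOVA agrees with the brute-force oracle on random tables", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(3:8, 1); k <- sample(3:5, 1)
    y <- random_table(n, k)
    fit <- rm_anova(longitudinal_table(y))
    ora <- oracle_rm_anova(y)
    expect_equal(fit$F, ora$F, tolerance = 1e-8)
    expect_equal(fit$epsilon, ora$epsilon, tolerance = 1e-8)
    expect_equal(fit$df1, ora$df1, tolerance = 1e-8)
    expect_equal(fit$df2, ora$df2, tolerance = 1e-8)
    expect_equal(fit$p, ora$p, tolerance = 1e-8)
    expect_gte(fit$epsilon, 1 / (k - 1))
    expect_lte(fit$epsilon, 1)
    # fractional df keep the exact ratio df2/df1 = n - 1
    expect_equal(fit$df2 / fit$df1, n - 1, tolerance = 1e-12)
  }
})

test_that("rm ANOVA F matches aov's within-subject stratum", {
  set.seed(55)
  y <- random_table(6, 4)
  long <- data.frame(val = as.vector(y),
                     subj = factor(rep(rownames(y), 4)),
                     tp = factor(rep(colnames(y), each = 6)))
  av <- summary(stats::aov(val ~ tp + Error(subj / tp), data = long))
  f_aov <- av[["Error: subj:tp"]][[1]]["tp", "F value"]
  fit <- rm_anova(longitudinal_table(y))
  expect_equal(fit$F, f_aov, tolerance = 1e-10)
})

test_that("degenerate tables are handled, not errored", {
  # identical columns: subject offsets only, no time effect
  y <- matrix(rep(c(3, 7, 11, 20), 4), 4, 4)
  fit <- rm_anova(longitudinal_table(y))
  expect_identical(fit$F, 0)
  expect_identical(fit$p, 1)
  # fully constant table
  fitc <- rm_anova(longitudinal_table(matrix(5, 4, 3)))
  expect_identical(fitc$F, 0)
  expect_identical(fitc$p, 1)
  # fewer than 2 complete cases
  bad <- matrix(c(1, NA, 2, 3, NA, 4), 2, 3)
  expect_error(suppressWarnings(rm_anova(longitudinal_table(bad))),
               "complete-case")
})

test_that("epsilon is exactly 1 for a spherical (identity) covariance", {
  set.seed(77)
  for (k in 3:5) {
    y <- whitened_table(12, k)
    fit <- rm_anova(longitudinal_table(y))
    expect_equal(fit$epsilon, 1, tolerance = 1e-6)
  }
})

test_that("F is invariant to per-subject constants", {
  set.seed(13)
  y <- random_table(5, 4)
  f1 <- rm_anova(longitudinal_table(y))$F
  y2 <- y + matrix(runif(5, 0, 50), 5, 4)
  f2 <- rm_anova(longitudinal_table(y2))$F
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("incomplete subjects are dropped with a warning", {
  y <- random_table(5, 3)
  y[2, 3] <- NA
  expect_warning(fit <- rm_anova(longitudinal_table(y)), "dropped")
  expect_identical(fit$n, 4L + 0L)
})

test_that("Tukey post hoc covers all pairs with studentized-range p-values", {
  set.seed(23)
  y <- random_table(6, 4)
  tk <- suppressWarnings(tukey_posthoc(longitudinal_table(y)))
  expect_identical(nrow(tk), 6L)            # k(k-1)/2 for k = 4
  expect_true(all(tk$p_adj >= 0 & tk$p_adj <= 1))
  # q recomputed from first principles for one pair
  a <- rm_anova(longitudinal_table(y))
  m <- colMeans(y)
  q12 <- abs(m[2] - m[1]) / sqrt(a$ms_error / a$n)
  expect_equal(tk$q[tk$timepoint_a == "t1" & tk$timepoint_b == "t2"],
               unname(q12), tolerance = 1e-10)
  expect_equal(tk$p_adj[1],
               stats::ptukey(tk$q[1], 4, a$df_error, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical columns: all adjusted p = 1
  same <- matrix(rep(c(3, 7, 11, 20, 5), 4), 5, 4)
  tks <- tukey_posthoc(longitudinal_table(same))
  expect_true(all(tks$p_adj == 1))

  # huge separation: two timepoints 100 pooled SDs apart, n = 6
  set.seed(3)
  ybig <- cbind(t1 = rnorm(6, 10, 1), t2 = rnorm(6, 110, 1))
  tkb <- tukey_posthoc(longitudinal_table(ybig))
  expect_lt(tkb$p_adj, 1e-4)
})

test_that("percent remaining normalizes to baseline and flags zeros", {
  y <- matrix(c(2e6, 1e6, 0,
                1e6, 5e5, 0,
                2e5, 1e5, 0), 3, 3)
  dimnames(y) <- list(c("A", "B", "C"), c("day0", "day3", "day16"))
  # subject C has zero baseline
  expect_warning(pct <- percent_remaining(longitudinal_table(y),
                                          baseline = "day0"), "zero baseline")
  expect_identical(attr(pct, "excluded_subjects"), "C")
  expect_identical(unname(pct[, "day0"]), c(100, 100))
  expect_identical(unname(pct["A", "day16"]), 10)  # 2e5 of 2e6
  expect_identical(unname(pct["A", "day3"]), 50)
  expect_identical(unname(pct["B", "day16"]), 10)
})

test_that("detectability tally formats x/n per timepoint", {
  flags <- data.frame(
    subject = rep(sprintf("M%d", 1:7), 2),
    timepoint = rep(c("day0", "day16"), each = 7),
    detectable = c(rep(TRUE, 7), rep(c(TRUE, FALSE), c(2, 5))))
  tly <- detectability_tally(flags, timepoints = c("day0", "day16"))
  expect_identical(tly$label, c("7/7", "2/7"))
  expect_identical(tly$fraction, c(1, 2 / 7))
  all_false <- within(flags, detectable <- FALSE)
  expect_identical(detectability_tally(all_false)$label, c("0/7", "0/7"))
})

test_that("long CSV round-trips through the table constructor", {
  df <- data.frame(subject = rep(c("A", "B", "C"), each = 2),
                   timepoint = rep(c("day0", "day9"), 3),
                   cell_count = c(10, 5, 20, 12, 8, 0),
                   detectable = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_longitudinal_csv(df, path)
  rt <- read_longitudinal_csv(path)
  expect_identical(rt$table$counts["B", "day9"], 12)
  expect_identical(rt$table$timepoints, c("day0", "day9"))
  expect_identical(rt$flags$detectable,
                   c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
})
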