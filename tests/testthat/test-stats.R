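test_that("column means of the packaged tables match the published values", {
  tabs <- reference_tables()
  expect_equal(unname(column_means(tabs$control)),
               c(51.42, 63.72, 73.78, 82.76, 90.43, 94.52))
  expect_equal(unname(column_means(tabs$baseline)),
               c(52.14, 63.96, 64.89, 66.13, 67.83, 68.95))
  expect_equal(table_max(tabs$control), 97.83)
})

test_that("column means are exact on constants and permutation-invariant", {
  m <- matrix(7.77, nrow = 4, ncol = 2)
  tab <- accuracy_table(m, paste0("s", 1:4), c(10, 20), "control")
  expect_equal(unname(column_means(tab)), c(7.77, 7.77))
  tabs <- reference_tables()
  shuf <- tabs$control
  set.seed(3)
  ord <- sample(nrow(shuf$values))
  shuf <- accuracy_table(shuf$values[ord, ], shuf$subjects[ord],
                         shuf$budgets, "control")
  expect_equal(column_means(shuf), column_means(tabs$control))
})

test_that("rounding of the reported means is half-up at two decimals", {
  # control budget-40 column averages to exactly 82.755
  tabs <- reference_tables()
  expect_equal(mean(tabs$control$values[, "40"]), 82.755, tolerance = 1e-12)
  expect_equal(unname(column_means(tabs$control)["40"]), 82.76)
})

test_that("accuracy tables validate their grid and round-trip through CSV", {
  expect_error(accuracy_table(matrix(c(1, NA), 1), "s", c(10, 20), "x"),
               "missing")
  expect_error(accuracy_table(matrix(c(50, 101), 1), "s", c(10, 20), "x"),
               "0, 100")
  tabs <- reference_tables()
  path <- tempfile(fileext = ".csv")
  write_accuracy_table(tabs$control, path)
  back <- read_accuracy_table(path, "control")
  expect_equal(back$values, tabs$control$values)
  expect_equal(back$budgets, tabs$control$budgets)
})

test_that("Shapiro-Wilk matches the reference implementation across n", {
  set.seed(10)
  for (n in c(4, 6, 8, 12, 25, 50, 120, 400)) {
    for (rep_ in 1:3) {
      x <- switch(1 + rep_ %% 3, rnorm(n), rexp(n), runif(n))
      mine <- shapiro_wilk(x)
      ref <- shapiro.test(x)
      expect_equal(mine$W, unname(ref$statistic), tolerance = 1e-6)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-4)
    }
  }
})

test_that("Shapiro-Wilk retains normality on every packaged budget column", {
  tabs <- reference_tables()
  for (tab in tabs) {
    for (j in seq_len(ncol(tab$values))) {
      expect_gt(shapiro_wilk(tab$values[, j])$p_value, 0.05)
    }
  }
})

test_that("Shapiro-Wilk rejects a clearly non-normal sample", {
  set.seed(42)
  x <- rexp(50)
  expect_lt(shapiro_wilk(x)$p_value, 0.05)
})

test_that("Shapiro-Wilk W is affine-invariant and inputs are validated", {
  set.seed(2)
  x <- rnorm(30)
  a <- shapiro_wilk(x)
  b <- shapiro_wilk(3.5 * x - 11)
  expect_equal(a$W, b$W, tolerance = 1e-8)
  expect_error(shapiro_wilk(c(1, 2)), "at least 3")
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
})

test_that("QQ points are ordered, symmetric and near-perfect for normal quantiles", {
  x <- c(-3, -1, 0, 1, 3)
  q <- qq_points(x)
  expect_true(all(diff(q$theoretical) > 0))
  expect_true(all(diff(q$sample) >= 0))
  # symmetric sample: flipping signs mirrors the point set
  q2 <- qq_points(-x)
  expect_equal(q2$sample, rev(-q$sample))
  # constructed normal quantiles correlate almost perfectly
  n <- 40
  perfect <- qnorm((seq_len(n) - 0.375) / (n + 0.25))
  qp <- qq_points(perfect)
  expect_gt(cor(qp$theoretical, qp$sample), 0.999)
  expect_error(qq_points(1), "at least 2")
})

test_that("the paired t-test matches hand computation and the reference", {
  r <- paired_t_two_tailed(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2L)
  same <- paired_t_two_tailed(c(1, 2), c(1, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(paired_t_two_tailed(c(1, 2), c(0, 1, 2)), "equal length")
  expect_error(paired_t_two_tailed(c(2, 3), c(1, 2)), "zero variance")
  set.seed(6)
  x <- rnorm(12, 1)
  y <- rnorm(12)
  mine <- paired_t_two_tailed(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  # antisymmetry in t, invariant p
  swap <- paired_t_two_tailed(y, x)
  expect_equal(swap$t, -mine$t)
  expect_equal(swap$p_value, mine$p_value)
})

test_that("the full group comparison reproduces the published analysis", {
  tabs <- reference_tables()
  rep_ <- compare_groups(tabs$control, tabs$baseline, budget = 60)
  expect_equal(rep_$paired_t$t, 17.87, tolerance = 0.005)
  expect_equal(rep_$paired_t$df, 9L)
  expect_lt(rep_$paired_t$p_value, 1e-7)
  expect_equal(rep_$mean_diff, 25.573, tolerance = 1e-6)
  expect_equal(rep_$max_cell$control, 97.83)
  expect_true(all(rep_$normality$control$normal))
  expect_true(all(rep_$normality$baseline$normal))
  # identical tables: zero difference
  same <- compare_groups(tabs$control, tabs$control, budget = 60)
  expect_equal(same$paired_t$t, 0)
  expect_equal(same$mean_diff, 0)
})

test_that("stat reports serialize to JSON", {
  tabs <- reference_tables()
  rep_ <- compare_groups(tabs$control, tabs$baseline)
  txt <- report_to_json(rep_)
  doc <- jsonlite::fromJSON(txt)
  expect_equal(doc$paired_t$df, 9)
  expect_equal(doc$means$control[["60"]], 94.52)
})
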