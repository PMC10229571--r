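test_that("BH adjustment matches the closed-form step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH adjustment is order-preserving and matches the step-up oracle", {
  # independent textbook step-up: adj_(i) = min_{j >= i} p_(j) * m / j
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
    out <- numeric(m)
    out[o] <- adj
    out
  }
  set.seed(41)
  for (i in 1:5) {
    p <- runif(20)
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= 0))
  }
})

test_that("two-group Tukey p equals the pooled t-test p", {
  set.seed(43)
  x <- c(rnorm(8, 0), rnorm(8, 1))
  g <- rep(c("a", "b"), each = 8)
  cmp <- anova_tukey(x, g, log_transform = "never")
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(cmp$pairwise$p_tukey, tt$p.value, tolerance = 1e-6)
  expect_equal(cmp$p_value, tt$p.value, tolerance = 1e-6)
})

test_that("well-separated groups are all distinguished, identical groups are not", {
  set.seed(44)
  # means 5 pooled SDs apart, n = 10 per group: power ~ 1
  x <- c(rnorm(10, 0), rnorm(10, 5), rnorm(10, 10))
  g <- rep(c("AS", "AM", "SM"), each = 10)
  cmp <- anova_tukey(x, g, log_transform = "never")
  expect_lt(cmp$p_value, 1e-6)
  expect_true(all(cmp$pairwise$p_tukey < 0.05))
  expect_true(all(cmp$pairwise$p_bh >= cmp$pairwise$p_tukey))
  expect_equal(sort(unname(cmp$letters)), c("a", "b", "c"))

  # jitter-free identical groups: degenerate path, single letter
  flat <- anova_tukey(rep(1, 6), rep(c("a", "b"), each = 3),
                      log_transform = "never")
  expect_equal(flat$p_value, 1)
  expect_equal(unname(flat$letters), c("a", "a"))
})

test_that("compact letters share a letter exactly for non-significant pairs", {
  set.seed(45)
  # AM and SM drawn identically, AS well below both
  x <- c(rnorm(10, 0), rnorm(10, 6), rnorm(10, 6))
  g <- rep(c("AS", "AM", "SM"), each = 10)
  cmp <- anova_tukey(x, g, log_transform = "never")
  l <- cmp$letters
  expect_equal(unname(l["AM"]), unname(l["SM"]))
  expect_false(l["AS"] == l["AM"])
})

test_that("skewed responses trigger the automatic log transform", {
  set.seed(46)
  x <- rlnorm(60, 0, 1.5)
  g <- rep(c("a", "b", "c"), each = 20)
  cmp <- anova_tukey(x, g)
  expect_true(cmp$log_transformed)
  cmp2 <- anova_tukey(x, g, log_transform = "never")
  expect_false(cmp2$log_transformed)
})

test_that("boxplot screening uses Tukey hinges and 1.5 IQR fences", {
  expect_equal(boxplot_outliers(1:5), rep(FALSE, 5))
  expect_equal(boxplot_outliers(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(boxplot_outliers(rep(7, 6)), rep(FALSE, 6))
  expect_warning(f <- boxplot_outliers(c(1, 2, 3)), "skipped")
  expect_equal(f, rep(FALSE, 3))
})

test_that("outlier fences are translation- and scale-equivariant", {
  set.seed(47)
  x <- c(rnorm(20), 8, -7)
  f <- boxplot_outliers(x)
  expect_true(any(f))
  expect_equal(boxplot_outliers(3 * x + 100), f)
  expect_equal(boxplot_outliers(-2 * x), f)
})

test_that("group comparisons reject invalid inputs", {
  expect_error(anova_tukey(1:5, rep("a", 5)), "2 groups")
  expect_error(anova_tukey(1:3, c("a", "b", "b")), "2 observations")
})
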