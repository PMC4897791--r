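table1_annotations <- function() {
  t1 <- table1_subjects()
  data.frame(individual = rep(t1$individual, t1$n_calls),
             maturity_group = rep(t1$maturity_group, t1$n_calls),
             stringsAsFactors = FALSE)
}

test_that("the inclusion rule reproduces the reference cohort exactly", {
  sel <- suppressMessages(select_calls(table1_annotations(), seed = 1))
  expect_equal(length(unique(sel$individual)), 10)
  counts <- table(sel$maturity_group)
  expect_equal(as.integer(counts[["group1"]]), 79)
  expect_equal(as.integer(counts[["group2"]]), 83)
})

test_that("subsampling is capped, seeded, idempotent and never additive", {
  ann <- data.frame(individual = c(rep("a", 10), rep("b", 25), rep("c", 4)),
                    row = 1:39)
  sel <- suppressMessages(select_calls(ann, seed = 3))
  expect_equal(sum(sel$individual == "a"), 10)   # boundary: exactly kept
  expect_equal(sum(sel$individual == "b"), 20)   # capped
  expect_false("c" %in% sel$individual)          # dropped
  sel2 <- suppressMessages(select_calls(ann, seed = 3))
  expect_identical(sel, sel2)
  # idempotence
  sel3 <- suppressMessages(select_calls(sel, seed = 99))
  expect_identical(sort(sel3$row), sort(sel$row))
  expect_error(suppressMessages(select_calls(ann[ann$individual == "c", ])),
               "no individuals")
})

test_that("two-group F agrees with explicit sums of squares and oneway.test", {
  set.seed(12)
  for (rep in 1:8) {
    x <- rnorm(sample(4:6, 1) * 2, sd = 2)
    g <- rep(c("a", "b"), length(x) / 2)
    res <- two_group_anova_f(x, g)
    expect_equal(res$F, oracle_anova_f(x, g), tolerance = 1e-10)
    ow <- oneway.test(x ~ g, var.equal = TRUE)
    expect_equal(res$F, unname(ow$statistic), tolerance = 1e-10)
    expect_equal(res$p, unname(ow$p.value), tolerance = 1e-10)
    expect_equal(res$df2, length(x) - 2L)
  }
  expect_equal(two_group_anova_f(c(1, 2, 1, 2), c("a", "a", "b", "b"))$F, 0)
  expect_error(two_group_anova_f(1:4, rep("a", 4)), "two groups")
})

test_that("F from published moments matches the printed statistic within rounding", {
  rec <- anova_f_from_moments(77.14, 7.6, 79, 104.53, 7.7, 83)
  expect_equal(rec$df2, 160L)
  expect_lt(abs(rec$F - 520.382) / 520.382, 0.005)
  # raw samples with those exact moments give the same F
  make <- function(n, m, s) {
    z <- scale(rnorm(n))
    as.numeric(z * s + m)
  }
  set.seed(2)
  x <- c(make(79, 77.14, 7.6), make(83, 104.53, 7.7))
  g <- rep(c("g1", "g2"), c(79, 83))
  expect_equal(two_group_anova_f(x, g)$F, rec$F, tolerance = 1e-8)
})

test_that("the ANOVA screen keeps separated features and reports exclusions", {
  set.seed(3)
  n <- 60
  g <- rep(c("a", "b"), each = n / 2)
  feats <- data.frame(strong = rnorm(n, ifelse(g == "a", 0, 3)),
                      null = rnorm(n))
  expect_message(scr <- anova_screen(feats, g), "excluded")
  expect_true(scr$keep[scr$feature == "strong"])
  expect_false(scr$keep[scr$feature == "null"])
  expect_equal(scr$df2, rep(n - 2L, 2))
})

test_that("PIC matches its hand transcription and flags identity features", {
  x <- c(10, 10, 12, 12, 20, 20, 24, 24)
  ind <- rep(c("a", "b"), each = 4)
  pt <- pic_screen(data.frame(f = x), ind)
  or <- oracle_pic(x, ind)
  expect_equal(pt$mean_cv_within, or$mean_cv_within, tolerance = 1e-12)
  expect_equal(pt$cv_between, or$cv_between, tolerance = 1e-12)
  expect_equal(pt$pic, or$pic, tolerance = 1e-12)
  expect_gt(pt$pic, 1)
  expect_true(pt$keep)
})

test_that("PIC is scale invariant and the correction flag acts on CVw only", {
  set.seed(4)
  x <- rnorm(40, 50, 5)
  ind <- rep(letters[1:5], each = 8)
  a <- suppressMessages(pic_screen(data.frame(f = x), ind))
  b <- suppressMessages(pic_screen(data.frame(f = 1000 * x), ind))
  expect_equal(a$pic, b$pic, tolerance = 1e-12)
  d <- suppressMessages(pic_screen(data.frame(f = x), ind,
                                   small_sample_correction = FALSE))
  expect_equal(a$mean_cv_within / d$mean_cv_within, 1 + 1 / 32,
               tolerance = 1e-12)   # n = 8 per individual
  expect_equal(a$cv_between, d$cv_between)
})

test_that("PIC degenerate and low-identity cases behave as documented", {
  # constant within, different between -> infinite PIC with warning
  x <- rep(c(10, 20), each = 4)
  ind <- rep(c("a", "b"), each = 4)
  expect_warning(pt <- pic_screen(data.frame(f = x), ind), "Inf")
  expect_equal(pt$pic, Inf)
  # within-variance >> between-variance -> excluded
  set.seed(6)
  y <- rnorm(80, 100, 30)
  ind2 <- rep(letters[1:4], each = 20)
  expect_message(pt2 <- pic_screen(data.frame(f = y), ind2), "excluded")
  expect_lt(pt2$pic, 1)
  expect_false(pt2$keep)
  expect_error(pic_screen(data.frame(f = 1:4), c("a", "a", "a", "b")),
               "at least 2 calls")
})
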