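test_that("discriminant classification matches MASS::lda with equal priors", {
  skip_if_not_installed("MASS")
  set.seed(21)
  for (rep in 1:6) {
    k <- sample(2:3, 1)
    n <- 20
    y <- sample(letters[1:k], n, replace = TRUE)
    while (length(unique(y)) < k) y <- sample(letters[1:k], n, replace = TRUE)
    X <- matrix(rnorm(n * 3), n) + 2 * outer(as.integer(factor(y)), 1:3)
    fit <- lda_fit(X, y)
    ours <- lda_classify(fit, X)
    ref <- MASS::lda(X, grouping = y, prior = rep(1 / k, k))
    theirs <- as.character(predict(ref, X)$class)
    expect_equal(ours, theirs)
  }
})

test_that("well-separated Gaussian classes classify held-out data near perfectly", {
  set.seed(22)
  n <- 400
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 2), n) + ifelse(y == "a", 0, 7)  # Mahalanobis ~ 7
  train <- sample(n, n / 2)
  fit <- lda_fit(X[train, ], y[train])
  acc <- mean(lda_classify(fit, X[-train, ]) == y[-train])
  expect_gt(acc, 0.99)
})

test_that("training on duplicated points reproduces labels exactly", {
  X <- rbind(matrix(1:6, 2, 3), matrix(1:6, 2, 3) + 5)
  y <- c("a", "b", "c", "d")
  expect_warning(fit <- lda_fit(X, y), "ridge")
  expect_equal(lda_classify(fit, X), y)
})

test_that("error reduction matches the published classification pairs", {
  expect_equal(error_reduction(98, 200 / 3), 94)
  expect_equal(error_reduction(55, 19.6), 44, tolerance = 0.001)
  expect_equal(error_reduction(37, 37), 0)
  expect_error(error_reduction(50, 100), "below 100")
})

test_that("perfect separation drives p to the permutation floor", {
  set.seed(23)
  n_ind <- 8; n_call <- 6
  ind <- rep(sprintf("i%d", 1:n_ind), each = n_call)
  grp <- rep(rep(c("g1", "g2"), each = n_ind / 2), each = n_call)
  X <- cbind(ifelse(grp == "g1", 0, 30) + rnorm(n_ind * n_call),
             rnorm(n_ind * n_call))
  pd <- run_pdfa(X, test = grp, control = ind, n_selections = 10,
                 n_permutations = 99, n_perm_selections = 3, seed = 1)
  expect_equal(pd$p_value, 1 / 100)
  expect_gt(pd$pct_correct_crossval, 99)
  expect_gt(pd$error_reduction_pct, 90)
  expect_equal(length(pd$perm_distribution), 99)
})

test_that("the result is bit-reproducible under a fixed seed", {
  set.seed(24)
  ind <- rep(sprintf("i%d", 1:6), each = 5)
  grp <- rep(rep(c("g1", "g2"), each = 3), each = 5)
  X <- matrix(rnorm(60), 30)
  a <- run_pdfa(X, test = grp, control = ind, n_selections = 5,
                n_permutations = 19, n_perm_selections = 2, seed = 7)
  b <- run_pdfa(X, test = grp, control = ind, n_selections = 5,
                n_permutations = 19, n_perm_selections = 2, seed = 7)
  expect_identical(a, b)
  c2 <- run_pdfa(X, test = grp, control = ind, n_selections = 5,
                 n_permutations = 19, n_perm_selections = 2, seed = 8)
  expect_false(identical(a$perm_distribution, c2$perm_distribution))
})

test_that("p is invariant to relabelling the classes", {
  set.seed(25)
  ind <- rep(sprintf("i%d", 1:8), each = 5)
  grp <- rep(rep(c("g1", "g2"), each = 4), each = 5)
  X <- matrix(rnorm(80), 40) + ifelse(grp == "g1", 0, 1.5)
  a <- run_pdfa(X, test = grp, control = ind, n_selections = 5,
                n_permutations = 49, n_perm_selections = 2, seed = 3)
  relab <- c(g1 = "ZZZ", g2 = "AAA")[grp]
  b <- run_pdfa(X, test = relab, control = ind, n_selections = 5,
                n_permutations = 49, n_perm_selections = 2, seed = 3)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$pct_correct_crossval, b$pct_correct_crossval)
})

test_that("permuting subjects, not calls, protects against pseudoreplication", {
  # strong individual effects, no group effect: subject-level permutation
  # must not find significance while call-level shuffling is fooled
  set.seed(26)
  n_ind <- 10; n_call <- 12
  ind <- rep(sprintf("i%02d", 1:n_ind), each = n_call)
  grp <- rep(rep(c("g1", "g2"), each = 5), each = n_call)
  mu <- rnorm(n_ind, 0, 4)
  X <- cbind(mu[as.integer(factor(ind))] + rnorm(n_ind * n_call, 0, 0.5),
             mu[as.integer(factor(ind))] * 0.7 + rnorm(n_ind * n_call, 0, 0.5))
  subj <- run_pdfa(X, test = grp, control = ind, n_selections = 10,
                   n_permutations = 199, n_perm_selections = 3, seed = 5)
  naive <- run_pdfa(X, test = grp, restriction = rep("all", length(grp)),
                    n_selections = 10, n_permutations = 199,
                    n_perm_selections = 3, seed = 5)
  expect_gt(subj$p_value, 0.05)
  expect_lt(naive$p_value, subj$p_value)
})

test_that("design violations are rejected", {
  ind <- rep(c("i1", "i2", "i3", "i4"), each = 4)
  grp <- rep(c("g1", "g2"), 8)           # control levels span both groups
  X <- matrix(rnorm(32), 16)
  expect_error(run_pdfa(X, test = grp, control = ind), "nested design violated")
  grp2 <- rep(c("g1", "g1", "g2", "g2"), each = 4)
  expect_error(run_pdfa(X, test = grp2, control = ind,
                        restriction = grp2), "exactly one")
  expect_error(run_pdfa(X, test = grp2), "exactly one")
  # a single control level per test level cannot be permuted
  ind3 <- rep(c("i1", "i2"), each = 8)
  grp3 <- rep(c("g1", "g2"), each = 8)
  expect_error(run_pdfa(X, test = grp3, control = ind3), "more control levels")
})
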