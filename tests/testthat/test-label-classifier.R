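# Cohort splitting, hand-rolled LDA, and confusion-matrix metrics.

test_that("split_cohort partitions deterministically at the requested sizes", {
  cohort <- as.list(1:10)
  sp <- split_cohort(cohort, train_fraction = 0.8, seed = 4)
  expect_length(sp$train, 8L)
  expect_length(sp$test, 2L)
  expect_setequal(c(unlist(sp$train), unlist(sp$test)), 1:10)

  big <- as.list(1:622)
  sp622 <- split_cohort(big, seed = 1, train_count = 500)
  expect_length(sp622$train, 500L)
  expect_length(sp622$test, 122L)

  sp_a <- split_cohort(big, seed = 7)
  sp_b <- split_cohort(big, seed = 7)
  sp_c <- split_cohort(big, seed = 8)
  expect_identical(sp_a$train_idx, sp_b$train_idx)
  expect_false(identical(sp_a$train_idx, sp_c$train_idx))
  expect_error(split_cohort(list()), "empty")
})

test_that("fit_lda recovers hand-computed means, pooled variance and priors", {
  x <- matrix(c(-2.2, -2, -1.8, 1.8, 2, 2.2), ncol = 1)
  lab <- factor(c("a", "a", "a", "b", "b", "b"))
  m <- fit_lda(x, lab)
  expect_equal(unname(m$class_means[, 1]), c(-2, 2))
  expect_equal(m$pooled_covariance[1, 1], 0.04)
  expect_equal(unname(m$priors), c(0.5, 0.5))
  expect_equal(as.character(predict_lda(m, 1.0)), "b")

  # empirical priors from imbalanced counts: 419/75/6
  set.seed(2)
  xx <- matrix(rnorm(500 * 2), ncol = 2)
  ll <- factor(rep(c("Green", "Yellow", "Red"), c(419, 75, 6)),
               levels = c("Green", "Yellow", "Red"))
  mm <- fit_lda(xx, ll)
  expect_equal(unname(mm$priors), c(0.838, 0.150, 0.012))

  expect_error(fit_lda(x, factor(rep("a", 6))), "2 classes")
})

test_that("ridge handles duplicated feature columns without changing calls", {
  set.seed(31)
  x <- matrix(rnorm(80), ncol = 2)
  x[1:20, ] <- x[1:20, ] + 3
  lab <- factor(rep(c("a", "b"), each = 20))
  x_dup <- cbind(x, x[, 2])          # singular pooled covariance
  m_dup <- fit_lda(x_dup, lab)
  expect_gt(m_dup$ridge, 0)
  m <- fit_lda(x, lab)
  expect_identical(predict_lda(m_dup, x_dup), predict_lda(m, x))
})

test_that("predict_lda matches the brute-force Gaussian discriminant oracle", {
  oracle_predict <- function(model, x) {
    # evaluate the full Gaussian discriminant per class, no shared terms
    inv <- solve(model$pooled_covariance +
                   diag(model$ridge, ncol(model$class_means)))
    apply(x, 1, function(row) {
      scores <- vapply(seq_along(model$classes), function(k) {
        mu <- model$class_means[k, ]
        -0.5 * t(row - mu) %*% inv %*% (row - mu) + model$log_priors[k]
      }, numeric(1))
      model$classes[which.max(scores)]
    })
  }
  set.seed(12)
  for (rep in 1:8) {
    d <- sample(1:5, 1); k <- sample(2:4, 1)
    n <- 100
    x <- matrix(rnorm(n * d), ncol = d)
    lab <- factor(sample(letters[1:k], n, replace = TRUE))
    while (any(table(lab) < 2)) lab <- factor(sample(letters[1:k], n, replace = TRUE))
    m <- fit_lda(x, lab)
    xt <- matrix(rnorm(50 * d), ncol = d)
    expect_identical(as.character(predict_lda(m, xt)),
                     unname(oracle_predict(m, xt)))
  }
})

test_that("tie-breaking and degenerate geometry follow the stated rules", {
  x <- matrix(c(-1, -1.1, -0.9, 1, 1.1, 0.9), ncol = 1)
  lab <- factor(c("first", "first", "first", "second", "second", "second"),
                levels = c("first", "second"))
  m <- fit_lda(x, lab)
  # exactly equidistant with equal priors -> first class
  expect_equal(as.character(predict_lda(m, 0)), "first")

  # identical class means -> argmax prior everywhere
  set.seed(9)
  v <- rnorm(60)
  lab2 <- factor(rep(c("rare", "common"), c(10, 50)), levels = c("rare", "common"))
  v <- v - ave(v, lab2)              # force both class means to 0
  m2 <- fit_lda(matrix(v, ncol = 1), lab2)
  expect_true(all(predict_lda(m2, matrix(rnorm(20), ncol = 1)) == "common"))
})

test_that("well-separated spherical gaussians are classified almost perfectly", {
  set.seed(77)
  n <- 200; d <- 3
  mu <- c(10, 0, 0)                   # |mu1 - mu2| = 10 sigma
  xtr <- rbind(matrix(rnorm(n * d), ncol = d),
               sweep(matrix(rnorm(n * d), ncol = d), 2, mu, `+`))
  ytr <- factor(rep(c("a", "b"), each = n))
  m <- fit_lda(xtr, ytr)
  xte <- rbind(matrix(rnorm(n * d), ncol = d),
               sweep(matrix(rnorm(n * d), ncol = d), 2, mu, `+`))
  yte <- factor(rep(c("a", "b"), each = n))
  acc <- mean(predict_lda(m, xte) == yte)
  expect_gte(acc, 0.99)
})

test_that("fit_lda recovers simulated class means within 3 standard errors", {
  set.seed(123)
  n <- 1000; d <- 4
  true_means <- rbind(a = c(0, 1, -1, 2), b = c(1, -1, 0, 0.5))
  lab <- factor(sample(c("a", "b"), n, replace = TRUE))
  x <- t(vapply(as.character(lab), function(cl)
    true_means[cl, ] + rnorm(d), numeric(d)))
  m <- fit_lda(x, lab)
  for (cl in c("a", "b")) {
    se <- 1 / sqrt(sum(lab == cl))
    expect_true(all(abs(m$class_means[cl, ] - true_means[cl, ]) < 3 * se))
  }
})

test_that("fit_lda agrees with the MASS oracle on a random instance", {
  skip_if_not_installed("MASS")
  set.seed(55)
  x <- matrix(rnorm(300 * 3), ncol = 3)
  x[1:100, 1] <- x[1:100, 1] + 2
  x[101:200, 2] <- x[101:200, 2] - 2
  lab <- factor(rep(c("a", "b", "c"), each = 100))
  m <- fit_lda(x, lab)
  ref <- MASS::lda(x, lab)
  xt <- matrix(rnorm(100 * 3), ncol = 3)
  expect_equal(as.character(predict_lda(m, xt)),
               as.character(predict(ref, xt)$class))
})

test_that("prf_from_counts reproduces printed-table arithmetic", {
  hip <- prf_from_counts(104, 119, 107, 122)
  expect_equal(round(hip$precision, 1), 87.4)
  expect_equal(round(hip$recall, 1), 97.2)
  expect_equal(round(hip$f_score, 1), 92.0)
  expect_equal(round(hip$accuracy, 1), 85.2)

  ankle_gy <- prf_from_counts(107, 115, 114, 122)
  expect_equal(round(ankle_gy$f_score, 1), 93.4)
  expect_equal(round(ankle_gy$accuracy, 1), 87.7)

  # zero-denominator rule
  z <- prf_from_counts(0, 0, 5, 100)
  expect_true(is.na(z$precision))
  expect_equal(z$recall, 0)
  expect_true(is.na(z$f_score))
})

test_that("classification_report counts, metrics and merge behave", {
  truth <- factor(rep(c("Green", "Yellow", "Red"), c(8, 3, 1)),
                  levels = c("Green", "Yellow", "Red"))
  pred <- truth
  rep0 <- classification_report(truth, pred)
  expect_equal(rep0$accuracy, 100)
  expect_true(all(rep0$per_class$f_score == 100))
  expect_equal(sum(rep0$confusion), rep0$n_test)

  # off-diagonal mass only between Green and Yellow: merging cannot lower accuracy
  pred2 <- as.character(truth)
  pred2[c(1, 2, 9)] <- c("Yellow", "Yellow", "Green")
  rep2 <- classification_report(truth, pred2, merge = c("Green", "Yellow"))
  expect_lt(rep2$accuracy, 100)
  expect_equal(rep2$merged$accuracy, 100)
  expect_gte(rep2$merged$accuracy, rep2$accuracy)
  expect_equal(rep2$merged$merged_class, "Green+Yellow")

  expect_error(classification_report(truth, pred2[-1]), "equal length")
})
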