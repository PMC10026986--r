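test_that("condensation computes plain median and MAD per condition", {
  win <- data.frame(label = c("a", "b"), onset = c(0, 10),
                    duration = c(10, 10))
  t <- 0:19
  v <- c(rep(2, 10), c(1, 2, 3, 4, 100, 3, 3, 3, 3, 3))
  cd <- condense_markers(v, t, win, normalize = FALSE)
  expect_equal(cd$mad[1], 0)                        # constant window
  expect_equal(cd$median[2], 3)
  expect_equal(cd$mad[2], 0)                        # majority at the median
  # the spec'd hand-computable example
  cd5 <- condense_markers(c(1, 2, 3, 4, 100), 0:4,
                          data.frame(label = "x", onset = 0,
                                     duration = 5),
                          normalize = FALSE, min_points = 5)
  expect_equal(cd5$median, 3)
  expect_equal(cd5$mad, 1)
})

test_that("z-scoring over the protocol gives mean 0 and sd 1", {
  set.seed(30)
  v <- rnorm(100, 5, 3)
  win <- data.frame(label = "all", onset = 0, duration = 100)
  mu <- mean(v); sdv <- sd(v)
  z <- (v - mu) / sdv
  cd <- condense_markers(v, 0:99, win, normalize = TRUE,
                         min_points = 10)
  expect_equal(cd$median, median(z))
  expect_equal(abs(mean(z)), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("sparse conditions are flagged missing with a warning", {
  win <- data.frame(label = c("a", "b"), onset = c(0, 50),
                    duration = c(50, 5))
  expect_warning(
    cd <- condense_markers(rnorm(55), 0:54, win, normalize = FALSE),
    "'b' has 5 valid points")
  expect_true(is.na(cd$mad[2]))
  expect_false(is.na(cd$mad[1]))
})

test_that("condensation is permutation-invariant and affine-equivariant", {
  set.seed(31)
  v <- rnorm(60)
  t <- 0:59
  win <- data.frame(label = "w", onset = 0, duration = 60)
  cd <- condense_markers(v, t, win, normalize = FALSE)
  perm <- sample(60)
  cdp <- condense_markers(v[perm], t[perm], win, normalize = FALSE)
  expect_equal(cd$median, cdp$median)
  expect_equal(cd$mad, cdp$mad)
  cda <- condense_markers(3 * v + 2, t, win, normalize = FALSE)
  expect_equal(cda$median, 3 * cd$median + 2)
  expect_equal(cda$mad, 3 * cd$mad)        # scale, not location
})

test_that("Friedman statistic matches the rank formula and references", {
  # identical columns: degenerate, statistic 0, p = 1
  bm <- matrix(rep(1:6, 3), ncol = 3)
  ft <- friedman_test(bm)
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p_value, 1)

  # random table vs the explicit tie-corrected rank formula
  set.seed(32)
  for (i in 1:10) {
    m <- matrix(sample(1:5, 24, replace = TRUE), nrow = 6)
    ft <- friedman_test(m)
    r <- t(apply(m, 1, rank))
    n <- nrow(m); k <- ncol(m)
    Rj <- colSums(r)
    num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
    den <- sum(r^2) - n * k * (k + 1)^2 / 4
    expect_equal(ft$statistic, num / den, tolerance = 1e-12)
    expect_equal(ft$p_value,
                 pchisq(num / den, k - 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }

  # strictly ordered rows attain the closed-form maximum n (k - 1)
  m <- t(replicate(10, sort(runif(4))))
  expect_equal(friedman_test(m)$statistic, 10 * 3, tolerance = 1e-12)
})

test_that("Friedman exact permutation agrees with the chi-square tail", {
  set.seed(33)
  m <- matrix(rnorm(15), nrow = 5)
  fa <- friedman_test(m)
  fe <- friedman_test(m, exact = TRUE)
  expect_equal(fe$statistic, fa$statistic)
  expect_true(fe$p_value >= 0 && fe$p_value <= 1)
  # the permutation p-value of the observed statistic can never be 0
  expect_gt(fe$p_value, 0)
  expect_error(friedman_test(matrix(rnorm(40), 10, 4), exact = TRUE),
               "n <= 8")
})

test_that("Friedman input contracts are enforced", {
  expect_error(friedman_test(matrix(1, 6, 2)), "3 conditions")
  expect_error(friedman_test(matrix(1, 3, 3)), "5 subjects")
  m <- matrix(rnorm(18), 6, 3); m[2, 2] <- NA
  expect_error(friedman_test(m), "missing")
})

test_that("Wilcoxon exact p equals its closed form for one-signed data", {
  out <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(out$p_value, 0.0625)
  expect_equal(out$statistic, 15)
  expect_warning(out2 <- wilcoxon_signed_rank(1:4, 1:4), "zero")
  expect_equal(out2$p_value, 1)
})

test_that("Wilcoxon exact p matches full sign enumeration", {
  set.seed(34)
  for (i in 1:5) {
    d <- round(rnorm(6), 2)
    d[d == 0] <- 0.1
    out <- wilcoxon_signed_rank(d, rep(0, 6))
    # brute force over all 2^6 sign assignments with average ranks
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    ws <- apply(expand.grid(rep(list(c(0, 1)), 6)), 1,
                function(s) sum(r[s == 1]))
    p_le <- mean(ws <= w_obs + 1e-9)
    p_ge <- mean(ws >= w_obs - 1e-9)
    expect_equal(out$p_value, min(1, 2 * min(p_le, p_ge)),
                 tolerance = 1e-12)
  }
})

test_that("large-sample Wilcoxon approximation tracks the reference", {
  set.seed(35)
  a <- rnorm(40); b <- rnorm(40, 0.4)
  out <- wilcoxon_signed_rank(a, b)
  ref <- wilcox.test(a, b, paired = TRUE, exact = FALSE,
                     correct = TRUE)
  expect_equal(out$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("Bonferroni threshold is alpha over the test count", {
  expect_equal(round(bonferroni_threshold(0.05, 9), 4), 0.0056)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_true(0.004 < bonferroni_threshold(0.05, 9))
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

# a small labelled feature table with planted structure
make_cv_table <- function(n_sub = 20, noise = 0.15, informative = TRUE,
                          seed = 40) {
  set.seed(seed)
  conds <- c("rest", "stress1", "stress2", "stress3")
  lev <- c(rest = 0, stress1 = 1, stress2 = 4, stress3 = 5)
  rows <- expand.grid(subject = seq_len(n_sub), condition = conds,
                      stringsAsFactors = FALSE)
  y <- lev[rows$condition]
  f1 <- if (informative) y + rnorm(nrow(rows), sd = noise)
        else rnorm(nrow(rows))
  feats <- data.frame(f1 = f1,
                      f2 = rnorm(nrow(rows)),
                      f3 = rnorm(nrow(rows)))
  feature_table(feats, rows$subject, rows$condition, unname(y),
                ifelse(rows$condition %in% c("rest", "stress1"),
                       "low", "high"))
}

test_that("folds are subject-stratified and deterministic", {
  tb <- make_cv_table()
  cv <- kernel_regression_cv(tb, selected = "f1", seed = 2)
  df <- split(cv$fold, tb$subject)
  expect_true(all(vapply(df, function(f) length(unique(f)) == 1L,
                         logical(1))))
  cv2 <- kernel_regression_cv(tb, selected = "f1", seed = 2)
  expect_identical(cv$predicted, cv2$predicted)
  expect_identical(cv$rmse, cv2$rmse)
})

test_that("a linear target is interpolated almost perfectly", {
  tb <- make_cv_table(noise = 0.02)
  cv <- kernel_regression_cv(tb, selected = "f1", lambda = 1e-6,
                             seed = 3)
  expect_lt(cv$rmse, 0.05)
})

test_that("permuted labels give chance-level regression error", {
  tb <- make_cv_table(informative = FALSE, seed = 41)
  cv <- kernel_regression_cv(tb, selected = c("f1", "f2", "f3"),
                             seed = 4)
  expect_lt(abs(cv$rmse - sd(tb$stress_level)), 0.1 * sd(tb$stress_level))
})

test_that("held-out predictions never use their own row", {
  tb <- make_cv_table()
  cv1 <- kernel_regression_cv(tb, selected = "f1", seed = 5)
  i <- which(cv1$fold == 1L)[1]
  tb2 <- tb
  tb2$features$f1[i] <- tb2$features$f1[i] + 50
  cv2 <- kernel_regression_cv(tb2, selected = "f1", seed = 5)
  same_fold_other <- setdiff(which(cv1$fold == 1L), i)
  expect_equal(cv1$predicted[same_fold_other],
               cv2$predicted[same_fold_other])
  expect_false(isTRUE(all.equal(cv1$predicted[i], cv2$predicted[i])))
})

test_that("separable classes are classified perfectly", {
  tb <- make_cv_table(noise = 0.05)
  cv <- kernel_nb_classify_cv(tb, selected = "f1", seed = 6)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$sensitivity, 1)
  expect_equal(cv$specificity, 1)
})

test_that("uninformative features classify at chance level", {
  tb <- make_cv_table(n_sub = 37, informative = FALSE, seed = 43)
  cv <- kernel_nb_classify_cv(tb, selected = c("f1", "f2", "f3"),
                              seed = 7)
  n <- length(cv$observed)
  band <- 1.96 * sqrt(0.25 / n)
  expect_gt(cv$accuracy, 0.5 - band)
  expect_lt(cv$accuracy, 0.5 + band)
  # determinism
  cv2 <- kernel_nb_classify_cv(tb, selected = c("f1", "f2", "f3"),
                               seed = 7)
  expect_identical(cv$accuracy, cv2$accuracy)
})

test_that("nested MRMR selection finds the informative feature", {
  tb <- make_cv_table(n_sub = 15, noise = 0.3, seed = 44)
  cv <- kernel_regression_cv(tb, selected = NULL, n_features = 1,
                             seed = 8)
  expect_true(all(vapply(cv$selected, identical, logical(1), "f1")))
  expect_lt(cv$rmse, 1)
})

test_that("the condition-wise report flags planted variability", {
  set.seed(45)
  n_sub <- 12
  conds <- c("rest", "stress1", "stress2", "stress3")
  sds <- c(rest = 0.2, stress1 = 0.5, stress2 = 0.8, stress3 = 1.1)
  rows <- expand.grid(subject = seq_len(n_sub), condition = conds,
                      stringsAsFactors = FALSE)
  feats <- data.frame(
    heart_to_brain.SAI.alpha.Cz.mad =
      sds[rows$condition] * (1 + 0.2 * rnorm(nrow(rows))),
    heart_to_brain.SAI.delta.Cz.mad = abs(rnorm(nrow(rows), 1, 0.2)))
  tb <- feature_table(feats, rows$subject, rows$condition,
                      unname(c(rest = 0, stress1 = 1, stress2 = 4,
                               stress3 = 5)[rows$condition]),
                      ifelse(rows$condition %in% c("rest", "stress1"),
                             "low", "high"))
  rep <- stress_stats_report(tb)
  expect_equal(rep$threshold, 0.05 / 1)     # single channel here
  fr <- rep$friedman
  expect_true(fr$significant[fr$band == "alpha"])
  expect_false(fr$significant[fr$band == "delta"])
  expect_true(all(names(rep$wilcoxon) ==
                  fr$feature[fr$significant]))
})
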