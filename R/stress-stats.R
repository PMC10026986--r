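#' Condense a time-resolved marker into per-condition median and MAD
#'
#' Optionally z-scores the series over the whole protocol first (using
#' valid points only), then computes, within each condition window, the
#' median and the median absolute deviation
#' \eqn{MAD = median(|x - median(x)|)} — plain, with no consistency
#' constant — over valid points.  Conditions with fewer than
#' \code{min_points} valid points are returned as NA with a warning.
#'
#' @param values Numeric marker series.
#' @param times Time stamps in seconds, aligned with \code{values}.
#' @param windows Data frame with columns \code{label}, \code{onset},
#'   \code{duration} (seconds); windows are closed at onset, open at
#'   onset + duration.
#' @param valid Optional logical mask (default: finite values).
#' @param normalize Z-score over the full protocol first (default TRUE).
#' @param min_points Minimum valid points per condition (default 10).
#' @return Data frame with columns \code{label}, \code{median},
#'   \code{mad}, \code{n_valid}.
#' @export
condense_markers <- function(values, times, windows, valid = NULL,
                             normalize = TRUE, min_points = 10L) {
  if (length(values) != length(times)) stop("values/times length mismatch")
  if (is.null(valid)) valid <- is.finite(values)
  valid <- valid & is.finite(values)
  if (normalize) {
    mu <- mean(values[valid])
    sdv <- stats::sd(values[valid])
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    values <- (values - mu) / sdv
  }
  out <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    inw <- valid & times >= w$onset - 1e-9 &
      times < w$onset + w$duration - 1e-9
    x <- values[inw]
    if (length(x) < min_points) {
      warning("condition '", w$label, "' has ", length(x),
              " valid points (< ", min_points, "); marked missing")
      data.frame(label = w$label, median = NA_real_, mad = NA_real_,
                 n_valid = length(x))
    } else {
      md <- stats::median(x)
      data.frame(label = w$label, median = md,
                 mad = stats::median(abs(x - md)), n_valid = length(x))
    }
  })
  do.call(rbind, out)
}

#' Friedman test across repeated conditions
#'
#' Rank-based Friedman chi-square over a subjects x conditions block
#' design, with average-rank tie correction, referenced against the
#' chi-square distribution with \eqn{k - 1} degrees of freedom (an exact
#' permutation p-value is available for small samples).
#'
#' @param block_matrix Numeric matrix, subjects in rows, conditions in
#'   columns; no missing cells.
#' @param exact Compute the permutation p-value by enumerating all
#'   within-row rank orderings (only allowed for <= 8 subjects).
#' @return List with \code{statistic}, \code{df}, \code{p_value},
#'   \code{method}.
#' @export
friedman_test <- function(block_matrix, exact = FALSE) {
  block_matrix <- as.matrix(block_matrix)
  n <- nrow(block_matrix)
  k <- ncol(block_matrix)
  if (k < 3L) stop("need at least 3 conditions")
  if (n < 5L) stop("need at least 5 subjects")
  if (anyNA(block_matrix))
    stop("missing cells; complete the block design before testing")
  r <- t(apply(block_matrix, 1L, rank))
  if (sum(r^2) - n * k * (k + 1)^2 / 4 <= 0)
    return(list(statistic = 0, df = k - 1, p_value = 1,
                method = "Friedman (degenerate: all ranks tied)"))
  ft <- stats::friedman.test(block_matrix)
  stat <- unname(ft$statistic)
  if (exact) {
    if (n > 8L) stop("exact permutation only supported for n <= 8")
    perms <- permutations_of(k)
    stat_of <- function(r) {
      Rj <- colSums(r)
      num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
      den <- sum(r^2) - n * k * (k + 1)^2 / 4
      if (den <= 0) 0 else num / den
    }
    r0 <- t(apply(block_matrix, 1L, rank))
    npk <- nrow(perms)
    total <- npk^n
    count <- 0L
    # enumerate all assignments of a permutation to each subject
    grid_count <- function(level, r) {
      if (level > n) {
        if (stat_of(r) >= stat - 1e-12) count <<- count + 1L
        return(invisible(NULL))
      }
      for (pi in seq_len(npk)) {
        r[level, ] <- r0[level, perms[pi, ]]
        grid_count(level + 1L, r)
      }
    }
    grid_count(1L, r0)
    p <- count / total
    return(list(statistic = stat, df = k - 1, p_value = p,
                method = "Friedman (exact permutation)"))
  }
  list(statistic = stat, df = unname(ft$parameter),
       p_value = ft$p.value, method = "Friedman (chi-square)")
}

permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test on paired differences.  Zero differences
#' are dropped (count reported); ties get average ranks.  For \eqn{n \le
#' 25} retained pairs the null distribution of the positive-rank sum is
#' enumerated exactly over all \eqn{2^n} sign assignments (by dynamic
#' programming over doubled ranks, so tied average ranks are handled
#' exactly); above that a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b Equal-length paired samples.
#' @return List with \code{statistic} (positive-rank sum W+),
#'   \code{p_value}, \code{n_used}, \code{n_zero}, \code{method}.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- a - b
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n_used = 0L,
                n_zero = n_zero, method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25L) {
    # exact enumeration via DP on 2 * ranks (integers even with ties)
    r2 <- as.integer(round(2 * r))
    maxs <- sum(r2)
    f <- c(1, rep(0, maxs))          # counts over W2 = 0..maxs
    for (ri in r2) {
      shifted <- c(rep(0, ri), f[seq_len(maxs + 1L - ri)])
      f <- f + shifted
    }
    f <- f / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(f[seq_len(w2 + 1L)])
    p_ge <- sum(f[(w2 + 1L):(maxs + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie-corrected)"
  }
  list(statistic = w, p_value = p, n_used = n, n_zero = n_zero,
       method = method)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Uncorrected significance level (default 0.05).
#' @param n_tests Number of comparisons (e.g. 9 channels).
#' @return \code{alpha / n_tests}.
#' @examples
#' round(bonferroni_threshold(0.05, 9), 4)   # 0.0056
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (n_tests < 1L) stop("n_tests must be >= 1")
  alpha / n_tests
}

# subject-stratified fold assignment: all rows of a subject share a fold
make_subject_folds <- function(subjects, n_folds, seed) {
  us <- unique(subjects)
  if (length(us) < n_folds)
    stop("need at least n_folds subjects")
  set.seed(seed)
  shuffled <- sample(us)
  fold_of <- rep(seq_len(n_folds), length.out = length(us))
  names(fold_of) <- shuffled
  unname(fold_of[as.character(subjects)])
}

#' Cross-validated Gaussian-kernel ridge regression of stress level
#'
#' Predicts the per-condition stress encoding (0 rest, 1/4/5 for the
#' three stressors) from selected coupling features with kernel ridge
#' regression, \eqn{\hat\alpha = (K + \lambda I)^{-1} y}, using a
#' Gaussian kernel whose bandwidth is the median pairwise training
#' distance.  Folds are stratified by subject: all four conditions of one
#' subject share a fold, so subject identity never leaks across folds.
#' When \code{selected} is NULL, MRMR selection of the top
#' \code{n_features} features is re-run inside every training fold.
#'
#' @param table A [feature_table()] (or data frame with \code{subject},
#'   \code{stress_level} and feature columns).
#' @param selected Character vector of feature names, or NULL for nested
#'   per-fold MRMR selection.
#' @param lambda Ridge regularisation strength (default 0.027).
#' @param n_folds Number of folds (default 5).
#' @param n_features Features to select when nested (default 5).
#' @param seed Fold seed.
#' @return Object of class \code{cv_result} with \code{fold} (per row),
#'   \code{predicted}, \code{observed}, \code{rmse}, \code{selected}
#'   (per fold), \code{lambda}, \code{bandwidths}.
#' @export
kernel_regression_cv <- function(table, selected = NULL, lambda = 0.027,
                                 n_folds = 5L, n_features = 5L,
                                 seed = 1L) {
  df <- as_feature_df(table)
  y <- df$stress_level
  folds <- make_subject_folds(df$subject, n_folds, seed)
  pred <- rep(NA_real_, nrow(df))
  sel_by_fold <- vector("list", n_folds)
  bw <- numeric(n_folds)
  feat_cols <- attr(df, "feature_cols")
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    te <- !tr
    sel <- selected
    if (is.null(sel)) {
      rk <- mrmr_rank(df[tr, feat_cols, drop = FALSE], y[tr],
                      mode = "regression", n_select = n_features,
                      seed = seed)
      sel <- rk$feature[seq_len(n_features)]
    }
    Xtr <- scale(as.matrix(df[tr, sel, drop = FALSE]))
    ctr <- attr(Xtr, "scaled:center"); sct <- attr(Xtr, "scaled:scale")
    sct[sct == 0 | !is.finite(sct)] <- 1
    Xte <- sweep(sweep(as.matrix(df[te, sel, drop = FALSE]), 2, ctr),
                 2, sct, "/")
    Xtr <- sweep(sweep(as.matrix(df[tr, sel, drop = FALSE]), 2, ctr),
                 2, sct, "/")
    Dtr <- as.matrix(stats::dist(Xtr))
    sig <- stats::median(Dtr[upper.tri(Dtr)])
    if (!is.finite(sig) || sig <= 0) sig <- 1
    K <- exp(-Dtr^2 / (2 * sig^2))
    ybar <- mean(y[tr])              # centred target: ridge shrinks
    # per-sample loss normalisation: the ridge term scales with the
    # training size, so lambda is a dimensionless strength
    alpha <- tryCatch(solve(K + diag(lambda * nrow(K), nrow(K)),
                            y[tr] - ybar),
                      error = function(e)
                        stop("degenerate kernel matrix in fold ", f))
    D2te <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") -
      2 * Xte %*% t(Xtr)
    Kte <- exp(-pmax(D2te, 0) / (2 * sig^2))
    pred[te] <- drop(Kte %*% alpha) + ybar
    sel_by_fold[[f]] <- sel
    bw[f] <- sig
  }
  structure(list(fold = folds, predicted = pred, observed = y,
                 rmse = sqrt(mean((pred - y)^2)),
                 selected = sel_by_fold, lambda = lambda,
                 bandwidths = bw, task = "regression", seed = seed),
            class = "cv_result")
}

#' Cross-validated kernel naive Bayes classification of stress class
#'
#' Classifies low stress (rest, stressor 1) versus high stress (stressors
#' 2, 3) with a naive Bayes classifier whose per-feature class
#' densities are Gaussian kernel density estimates (Silverman bandwidth),
#' with class priors from the training fold.  Folds are subject-
#' stratified; if a training fold misses a class the folds are redrawn
#' once with a new seed, then an error is raised.
#'
#' @inheritParams kernel_regression_cv
#' @return A \code{cv_result} with \code{accuracy}, \code{sensitivity}
#'   (high-stress detection rate) and \code{specificity}.
#' @export
kernel_nb_classify_cv <- function(table, selected = NULL, n_folds = 5L,
                                  n_features = 5L, seed = 1L) {
  df <- as_feature_df(table)
  y <- factor(df$stress_class, levels = c("low", "high"))
  feat_cols <- attr(df, "feature_cols")
  folds <- make_subject_folds(df$subject, n_folds, seed)
  ok <- all(vapply(seq_len(n_folds), function(f)
    length(unique(y[folds != f])) == 2L, logical(1)))
  if (!ok) {
    folds <- make_subject_folds(df$subject, n_folds, seed + 1L)
    ok <- all(vapply(seq_len(n_folds), function(f)
      length(unique(y[folds != f])) == 2L, logical(1)))
    if (!ok) stop("a training fold contains a single class")
  }
  pred <- factor(rep(NA_character_, nrow(df)), levels = levels(y))
  sel_by_fold <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    sel <- selected
    if (is.null(sel)) {
      rk <- mrmr_rank(df[tr, feat_cols, drop = FALSE], y[tr],
                      mode = "classification", n_select = n_features,
                      seed = seed)
      sel <- rk$feature[seq_len(n_features)]
    }
    priors <- table(y[tr]) / length(tr)
    loglik <- matrix(log(as.numeric(priors)), nrow = length(te),
                     ncol = 2L, byrow = TRUE)
    for (cl in seq_along(levels(y))) {
      rows <- tr[y[tr] == levels(y)[cl]]
      for (s in sel) {
        xs <- df[rows, s]
        b <- stats::bw.nrd0(xs)
        if (!is.finite(b) || b <= 0)
          b <- max(1e-8, 1e-3 * (stats::sd(xs) + 1e-8))
        xe <- df[te, s]
        dens <- vapply(xe, function(v)
          mean(stats::dnorm(v, mean = xs, sd = b)), numeric(1))
        loglik[, cl] <- loglik[, cl] + log(pmax(dens, 1e-300))
      }
    }
    pred[te] <- levels(y)[max.col(loglik)]
    sel_by_fold[[f]] <- sel
  }
  tp <- sum(pred == "high" & y == "high")
  tn <- sum(pred == "low" & y == "low")
  structure(list(fold = folds, predicted = pred, observed = y,
                 accuracy = mean(pred == y),
                 sensitivity = tp / sum(y == "high"),
                 specificity = tn / sum(y == "low"),
                 selected = sel_by_fold, task = "classification",
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  if (x$task == "regression") {
    cat("Subject-stratified CV kernel ridge regression: RMSE ",
        signif(x$rmse, 5), " (lambda ", x$lambda, ", ",
        max(x$fold), " folds)\n", sep = "")
  } else {
    cat("Subject-stratified CV kernel naive Bayes: accuracy ",
        signif(x$accuracy, 4), ", sensitivity ",
        signif(x$sensitivity, 4), ", specificity ",
        signif(x$specificity, 4), "\n", sep = "")
  }
  invisible(x)
}

#' Condition-wise statistical report over a feature table
#'
#' For every (direction, branch, band) marker group, runs a Friedman test
#' per channel on the chosen condensation across the four conditions, and
#' pairwise Wilcoxon signed-rank tests between conditions, with the
#' Bonferroni threshold \code{alpha / n_channels}.
#'
#' @param table A [feature_table()].
#' @param alpha Uncorrected significance level (default 0.05).
#' @return Object of class \code{stats_report}: data frame \code{friedman}
#'   (one row per direction x branch x band x channel), list
#'   \code{wilcoxon} (pairwise p-values for significant markers),
#'   \code{threshold}, \code{alpha}.
#' @export
stress_stats_report <- function(table, alpha = 0.05) {
  df <- as_feature_df(table)
  feat_cols <- attr(df, "feature_cols")
  meta <- parse_feature_names(feat_cols)
  channels <- unique(meta$channel)
  thr <- bonferroni_threshold(alpha, length(channels))
  conds <- unique(df$condition)
  subs <- unique(df$subject)
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    fc <- feat_cols[i]
    bm <- matrix(NA_real_, length(subs), length(conds),
                 dimnames = list(subs, conds))
    bm[cbind(match(df$subject, subs), match(df$condition, conds))] <-
      df[[fc]]
    ft <- friedman_test(bm)
    data.frame(meta[i, ], statistic = ft$statistic,
               p_value = ft$p_value, significant = ft$p_value < thr)
  })
  fr <- do.call(rbind, rows)
  wil <- lapply(feat_cols[fr$significant], function(fc) {
    bm <- matrix(NA_real_, length(subs), length(conds),
                 dimnames = list(subs, conds))
    bm[cbind(match(df$subject, subs), match(df$condition, conds))] <-
      df[[fc]]
    pairs <- utils::combn(conds, 2, simplify = FALSE)
    ps <- vapply(pairs, function(pr)
      wilcoxon_signed_rank(bm[, pr[1]], bm[, pr[2]])$p_value, numeric(1))
    names(ps) <- vapply(pairs, paste, character(1), collapse = " vs ")
    ps
  })
  names(wil) <- feat_cols[fr$significant]
  structure(list(friedman = fr, wilcoxon = wil, threshold = thr,
                 alpha = alpha, n_channels = length(channels)),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("Condition-wise Friedman tests: ", nrow(x$friedman),
      " marker-channel combinations, Bonferroni threshold ",
      signif(x$threshold, 4), " (alpha ", x$alpha, " / ",
      x$n_channels, " channels)\n", sep = "")
  sig <- x$friedman[x$friedman$significant, ]
  cat(nrow(sig), "significant after correction\n")
  invisible(x)
}
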