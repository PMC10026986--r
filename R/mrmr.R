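#' Plug-in mutual information on equal-width bins
#'
#' Histogram (plug-in) estimate of \eqn{I(x; y) = \sum_{ij} p_{ij}
#' \log_2 [p_{ij} / (p_i p_j)]} in bits.  Continuous variables are
#' discretised into \code{n_bins} equal-width bins over their range;
#' factors and character vectors are used as-is.  A constant variable
#' carries no information and returns 0.
#'
#' @param x,y Equal-length variables (numeric, factor, or character).
#' @param n_bins Number of equal-width bins for continuous variables
#'   (default 10).
#' @return Mutual information in bits (non-negative).
#' @examples
#' z <- rep(1:4, 25)
#' mutual_information(z, z)   # 2 bits: identical uniform 4-symbol vars
#' @export
mutual_information <- function(x, y, n_bins = 10L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 8L) stop("need at least 8 observations")
  bx <- discretize_equal_width(x, n_bins)
  by <- discretize_equal_width(y, n_bins)
  if (is.null(bx) || is.null(by)) return(0)
  tab <- table(bx, by)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log2(pij[nz] / outer(pi_, p_j)[nz]))
  max(mi, 0)
}

# map a variable to discrete codes; NULL marks a constant (zero MI)
discretize_equal_width <- function(x, n_bins) {
  if (is.factor(x) || is.character(x) || is.logical(x))
    return(as.integer(factor(x)))
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("non-finite values")
  rg <- range(x)
  if (rg[1] == rg[2]) return(NULL)
  b <- floor((x - rg[1]) / (rg[2] - rg[1]) * n_bins) + 1L
  pmin(b, as.integer(n_bins))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Ranks features against a target by the six-step MRMR procedure:
#' \enumerate{
#'   \item seed the selected set with the single most relevant feature
#'     (largest \eqn{I(x, y)});
#'   \item among candidates with nonzero relevance and \emph{zero}
#'     redundancy with the selected set, repeatedly admit the most
#'     relevant;
#'   \item once every remaining relevant candidate is redundant, admit by
#'     largest mutual information quotient
#'     \eqn{MIQ_x = I(x,y) / [\frac{1}{|S|}\sum_{z \in S} I(x, z)]};
#'   \item features with zero relevance are appended in seeded-random
#'     order.
#' }
#' Relevance is the candidate's own mutual information with the target
#' (the standard MRMR definition); an averaged-over-\eqn{S} variant is
#' available via \code{literal_relevance} (see the methods vignette).
#' "Zero" means below \code{tol} bits, absorbing floating-point noise.
#'
#' @param table A data frame (or matrix) of features, or a
#'   \code{feature_table}.
#' @param target Target vector (numeric for regression, factor for
#'   classification), or the name of a column of \code{table}.
#' @param mode \code{"regression"} or \code{"classification"}; controls
#'   only how the target is discretised.
#' @param n_bins Bins for the MI estimator (default 10).
#' @param n_select Stop after ranking this many features (default all;
#'   the remainder keeps column order and is tagged phase
#'   \code{"unranked"}).
#' @param literal_relevance If TRUE, relevance is averaged over the
#'   selected set (constant across candidates within a step).
#' @param tol Zero threshold in bits (default 1e-12).
#' @param seed Seed for the random step-6 tail (default 1).
#' @return Object of class \code{mrmr_result}: data frame with columns
#'   \code{rank}, \code{feature}, \code{relevance}, \code{redundancy},
#'   \code{miq}, \code{phase}.
#' @export
mrmr_rank <- function(table, target, mode = c("regression",
                                              "classification"),
                      n_bins = 10L, n_select = NULL,
                      literal_relevance = FALSE, tol = 1e-12, seed = 1L) {
  mode <- match.arg(mode)
  if (inherits(table, "feature_table")) table <- table$features
  table <- as.data.frame(table)
  if (is.character(target) && length(target) == 1L) {
    y <- table[[target]]
    table <- table[, setdiff(names(table), target), drop = FALSE]
  } else y <- target
  if (mode == "classification") y <- factor(y)
  nf <- ncol(table)
  if (nf < 1L) stop("need at least one feature")
  feats <- names(table)
  V <- vapply(table, function(x) mutual_information(x, y, n_bins),
              numeric(1))
  n_select <- if (is.null(n_select)) nf else min(as.integer(n_select), nf)

  sel <- integer(0)
  phase <- character(0)
  red <- numeric(0)
  miq <- numeric(0)
  # pairwise MI with selected features, grown one column per admission
  R <- matrix(NA_real_, nrow = nf, ncol = 0)
  remaining <- seq_len(nf)

  admit <- function(i, ph, w, q) {
    sel <<- c(sel, i); phase <<- c(phase, ph)
    red <<- c(red, w); miq <<- c(miq, q)
    remaining <<- setdiff(remaining, i)
    if (length(remaining) && length(sel) < n_select) {
      newcol <- rep(NA_real_, nf)
      newcol[remaining] <- vapply(remaining, function(j)
        mutual_information(table[[j]], table[[i]], n_bins), numeric(1))
      R <<- cbind(R, newcol)
    }
  }

  # step 1: most relevant feature
  admit(which.max(V), "step-1", 0, NA_real_)

  while (length(remaining) && length(sel) < n_select) {
    rel <- if (literal_relevance) {
      rep(mean(V[sel]), length(remaining))
    } else V[remaining]
    Wsum <- rowSums(R[remaining, , drop = FALSE])
    Wmiq <- Wsum / length(sel)
    # squared-set scaling for the zero-redundancy screen; zero is zero
    # under either normalisation
    zero_red <- Wsum / length(sel)^2 <= tol
    cand <- which(rel > tol & zero_red)
    if (length(cand)) {
      pick <- cand[which.max(rel[cand])]
      admit(remaining[pick], "step-2", Wmiq[pick], NA_real_)
      next
    }
    cand <- which(rel > tol)
    if (length(cand)) {
      q <- rel[cand] / Wmiq[cand]
      pick <- cand[which.max(q)]
      admit(remaining[pick], "step-4", Wmiq[pick], max(q))
      next
    }
    # step 6: all remaining relevance is zero; seeded-random order
    set.seed(seed)
    ord <- remaining[sample.int(length(remaining))]
    for (i in ord) {
      if (length(sel) >= n_select) break
      sel <- c(sel, i); phase <- c(phase, "step-6")
      red <- c(red, NA_real_); miq <- c(miq, NA_real_)
    }
    remaining <- setdiff(remaining, sel)
    break
  }
  if (length(remaining)) {        # early stop at n_select
    sel <- c(sel, remaining)
    phase <- c(phase, rep("unranked", length(remaining)))
    red <- c(red, rep(NA_real_, length(remaining)))
    miq <- c(miq, rep(NA_real_, length(remaining)))
  }
  out <- data.frame(rank = seq_along(sel), feature = feats[sel],
                    relevance = V[sel], redundancy = red, miq = miq,
                    phase = phase, stringsAsFactors = FALSE)
  class(out) <- c("mrmr_result", class(out))
  out
}

#' @export
print.mrmr_result <- function(x, n = 10L, ...) {
  cat("MRMR ranking of", nrow(x), "features (top", min(n, nrow(x)),
      "shown):\n")
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 4)
  invisible(x)
}
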