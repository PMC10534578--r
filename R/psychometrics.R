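#' Spearman rank correlation with a significance test
#'
#' Computes Spearman's rho as the Pearson correlation of midranks (average
#' ranks for ties). The two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom; for
#' very small samples (n <= 8) the exact permutation distribution of rho is
#' enumerated instead.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), neither constant.
#' @return List with `rho`, `p_value`, `n` and `method`.
#' @examples
#' spearman_rho(1:10, (1:10)^3)$rho   # 1: monotone invariance
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: constant input vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- .all_permutations(n)
    stat <- function(ryp) stats::cor(rx, ryp)
    rhos <- apply(perms, 1L, function(idx) stat(ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

# all permutations of 1..n as an n! x n matrix (n <= 8 keeps this small)
.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(row totals))`
#' with sample (n - 1 denominator) variances.
#'
#' @param item_matrix Numeric matrix, n respondents x k items (n >= 2,
#'   k >= 2, no missing values).
#' @return List with `alpha`, `k` and `n`.
#' @examples
#' set.seed(1)
#' f <- rnorm(50)
#' X <- sapply(1:4, function(i) f + rnorm(50, sd = 0.5))
#' cronbach_alpha(X)$alpha
#' @export
cronbach_alpha <- function(item_matrix) {
  X <- as.matrix(item_matrix)
  if (anyNA(X)) stop("missing values are not supported")
  n <- nrow(X); k <- ncol(X)
  if (n < 2L || k < 2L) stop("need at least 2 rows and 2 items")
  total_var <- stats::var(rowSums(X))
  if (total_var == 0) stop("alpha undefined: total score has zero variance")
  item_var <- apply(X, 2L, stats::var)
  list(alpha = k / (k - 1) * (1 - sum(item_var) / total_var), k = k, n = n)
}

#' Confusion table for a dependence classification
#'
#' Either supply the four cell counts directly, or `predicted`/`truth`
#' logical vectors (TRUE = dependent) from which they are tabulated.
#'
#' @param tp,fp,fn,tn Non-negative cell counts: predicted-dependent x
#'   truly-dependent margins.
#' @param predicted,truth Logical vectors; used when cell counts are absent.
#' @return Object of class `confusion_table`.
#' @examples
#' confusion_table(tp = 130, fp = 126, fn = 82, tn = 454)
#' @export
confusion_table <- function(tp = NULL, fp = NULL, fn = NULL, tn = NULL,
                            predicted = NULL, truth = NULL) {
  if (is.null(tp)) {
    stopifnot(is.logical(predicted), is.logical(truth),
              length(predicted) == length(truth))
    tp <- sum(predicted & truth); fp <- sum(predicted & !truth)
    fn <- sum(!predicted & truth); tn <- sum(!predicted & !truth)
  }
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  structure(as.list(counts), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("dependence", "independence"),
                              truth = c("dependence", "independence")))
  print(m)
  invisible(x)
}

#' Sensitivity and specificity of a confusion table
#'
#' Sensitivity is the fraction of truly dependent subjects classified
#' dependent, `tp / (tp + fn)`; specificity the fraction of independent
#' subjects classified independent, `tn / (tn + fp)`.
#'
#' @param table A `confusion_table`.
#' @return List with `sensitivity` and `specificity`.
#' @examples
#' sensitivity_specificity(confusion_table(tp = 130, fp = 126,
#'                                         fn = 82, tn = 454))
#' @export
sensitivity_specificity <- function(table) {
  stopifnot(inherits(table, "confusion_table"))
  if (table$tp + table$fn == 0)
    stop("sensitivity undefined: no truly dependent subjects")
  if (table$tn + table$fp == 0)
    stop("specificity undefined: no truly independent subjects")
  list(sensitivity = table$tp / (table$tp + table$fn),
       specificity = table$tn / (table$tn + table$fp))
}

#' ROC curve of a dependence score against a binary truth
#'
#' Higher scores indicate greater dependence; at each candidate threshold t
#' a subject is classified dependent when `score >= t`. Candidate
#' thresholds are the unique observed scores (default) or the midpoints
#' between adjacent unique scores, in both cases with a `+Inf` sentinel so
#' the curve starts at (0, 0) and ends at (1, 1).
#'
#' @param scores Numeric score vector.
#' @param truth Logical vector, TRUE for truly dependent subjects; both
#'   classes must be present.
#' @param placement `"unique"` (thresholds at observed scores, default) or
#'   `"midpoint"` (between adjacent observed scores).
#' @return Object of class `roc_curve`: data frame with columns
#'   `threshold`, `sensitivity`, `specificity`, `fpr`, ordered from the
#'   (0, 0) to the (1, 1) corner.
#' @examples
#' rc <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' auc(rc)   # 1: perfect separation
#' @export
roc_curve <- function(scores, truth, placement = c("unique", "midpoint")) {
  placement <- match.arg(placement)
  stopifnot(length(scores) == length(truth), is.logical(truth))
  if (anyNA(scores) || anyNA(truth)) stop("missing values are not supported")
  if (all(truth) || !any(truth))
    stop("both classes must be present to build a ROC curve")
  u <- sort(unique(scores), decreasing = TRUE)
  thr <- if (placement == "unique") c(Inf, u)
         else c(Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, min(u))
  npos <- sum(truth); nneg <- sum(!truth)
  sens <- vapply(thr, function(t) sum(scores >= t & truth) / npos, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & !truth) / nneg, numeric(1))
  out <- data.frame(threshold = thr, sensitivity = sens,
                    specificity = spec, fpr = 1 - spec)
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Area under a ROC curve
#'
#' Trapezoidal area over the (false positive rate, sensitivity) points.
#' Equals the Mann--Whitney probability that a randomly chosen dependent
#' subject outscores a randomly chosen independent one, ties counted 1/2.
#'
#' @param curve A `roc_curve`.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  x <- curve$fpr; y <- curve$sensitivity
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Youden-optimal cut-off from a ROC curve
#'
#' Maximizes the Youden index `J = sensitivity + specificity - 1` over the
#' curve's candidate thresholds. When several thresholds tie on J the
#' smallest (most sensitive) finite threshold is returned.
#'
#' @param curve A `roc_curve` with at least one finite threshold.
#' @return List with `cutoff`, `J`, `sensitivity` and `specificity` at the
#'   optimum.
#' @examples
#' rc <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' youden_cutoff(rc)$J   # 1
#' @export
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  J <- curve$sensitivity + curve$specificity - 1
  best <- max(J)
  idx <- which(J >= best - 1e-12)
  finite <- idx[is.finite(curve$threshold[idx])]
  pick <- if (length(finite)) finite[which.min(curve$threshold[finite])]
          else idx[length(idx)]
  list(cutoff = curve$threshold[pick], J = J[pick],
       sensitivity = curve$sensitivity[pick],
       specificity = curve$specificity[pick])
}

#' Kaiser--Meyer--Olkin measure of sampling adequacy
#'
#' `KMO = sum(r_ij^2) / (sum(r_ij^2) + sum(q_ij^2))` over off-diagonal
#' pairs, where `q_ij = -s_ij / sqrt(s_ii * s_jj)` are the anti-image
#' partial correlations obtained from `S = solve(R)`.
#'
#' @param correlation_matrix Symmetric positive-definite p x p correlation
#'   matrix, p >= 2.
#' @return KMO value in \[0, 1\].
#' @export
kmo <- function(correlation_matrix) {
  R <- as.matrix(correlation_matrix)
  p <- nrow(R)
  stopifnot(p >= 2L, ncol(R) == p)
  if (max(abs(R - t(R))) > 1e-8 || max(abs(diag(R) - 1)) > 1e-8)
    stop("input must be a symmetric correlation matrix with unit diagonal")
  if (rcond(R) < 1e-8) stop("correlation matrix is (near-)singular")
  S <- solve(R)
  Q <- -S / sqrt(diag(S) %o% diag(S))
  off <- upper.tri(R)
  r2 <- sum(R[off]^2); q2 <- sum(Q[off]^2)
  if (r2 + q2 == 0)
    stop("KMO undefined for an identity correlation matrix")
  r2 / (r2 + q2)
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity:
#' `chi2 = -(n - 1 - (2p + 5)/6) * log(det(R))` on `p(p-1)/2` degrees of
#' freedom.
#'
#' @param correlation_matrix p x p correlation matrix with positive
#'   determinant.
#' @param n Number of observations the matrix was estimated from (n > p).
#' @return List with `chi2`, `df` and `p_value`.
#' @export
bartlett_sphericity <- function(correlation_matrix, n) {
  R <- as.matrix(correlation_matrix)
  p <- nrow(R)
  stopifnot(ncol(R) == p, n > p)
  d <- det(R)
  if (d <= 0) stop("determinant must be positive")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(d)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Exploratory factor analysis by principal components
#'
#' Eigendecomposition of the sample correlation matrix: loadings are
#' eigenvectors scaled by the square roots of their eigenvalues, variance
#' explained is eigenvalue / p, and the number of retained factors follows
#' the Kaiser rule (eigenvalue strictly greater than 1). When two or more
#' factors are retained the retained loadings are varimax-rotated.
#'
#' @param item_matrix Numeric n x p matrix (n > p), no constant columns; or
#'   pass a precomputed correlation matrix via `correlation` and `n`.
#' @param correlation Optional p x p correlation matrix replacing
#'   `cor(item_matrix)`.
#' @param n Number of observations when `correlation` is supplied.
#' @return Object of class `factor_solution`: `eigenvalues`,
#'   `variance_pct`, `cumulative_pct`, `n_retained`, `loadings` (p x p
#'   unrotated), `rotated` (p x k varimax-rotated retained loadings, or the
#'   unrotated column when k = 1), `n`, `p`.
#' @examples
#' kaiser_retained(c(3.86, 1.08, 0.96, 0.76))   # 2
#' @export
pca_efa <- function(item_matrix = NULL, correlation = NULL, n = NULL) {
  if (is.null(correlation)) {
    X <- as.matrix(item_matrix)
    if (anyNA(X)) stop("missing values are not supported")
    if (any(apply(X, 2L, stats::sd) == 0)) stop("constant item column")
    if (nrow(X) <= ncol(X)) stop("need more observations than items")
    R <- stats::cor(X); n <- nrow(X)
  } else {
    R <- as.matrix(correlation)
    if (is.null(n)) stop("supply n with a precomputed correlation matrix")
  }
  p <- ncol(R)
  e <- eigen(R, symmetric = TRUE)
  vals <- e$values
  L <- e$vectors %*% diag(sqrt(pmax(vals, 0)), p)
  # sign convention: largest-magnitude loading in each column positive
  sgn <- apply(L, 2L, function(col) sign(col[which.max(abs(col))]))
  L <- sweep(L, 2L, ifelse(sgn == 0, 1, sgn), `*`)
  rownames(L) <- colnames(R)
  k <- kaiser_retained(vals)
  rotated <- if (k >= 2L) varimax_rotate(L[, seq_len(k), drop = FALSE])$loadings
             else L[, seq_len(max(k, 1L)), drop = FALSE]
  structure(list(eigenvalues = vals,
                 variance_pct = vals / p * 100,
                 cumulative_pct = cumsum(vals / p * 100),
                 n_retained = k,
                 loadings = L, rotated = rotated, n = n, p = p),
            class = "factor_solution")
}

#' Number of factors retained by the Kaiser rule
#'
#' @param eigenvalues Numeric vector of eigenvalues.
#' @return Count of eigenvalues strictly greater than 1.
#' @export
kaiser_retained <- function(eigenvalues) {
  sum(eigenvalues > 1)
}

#' @export
print.factor_solution <- function(x, digits = 2, ...) {
  cat("PCA-based exploratory factor analysis (", x$p, " items, n = ",
      x$n, ")\n", sep = "")
  tab <- data.frame(eigenvalue = round(x$eigenvalues, digits),
                    pct_variance = round(x$variance_pct, digits),
                    cumulative_pct = round(x$cumulative_pct, digits))
  print(tab)
  cat("factors retained (Kaiser):", x$n_retained, "\n")
  invisible(x)
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation maximizing the varimax criterion (the sum over
#' factors of the variance of squared loadings) by iterated pairwise planar
#' rotations. Rows are Kaiser-normalized during optimization by default.
#' Columns of the result are sign-fixed (largest-magnitude loading
#' positive) and ordered by explained variance.
#'
#' @param loadings p x k loading matrix, k >= 2, p > k.
#' @param normalize Kaiser row-normalization during optimization (default
#'   TRUE).
#' @param eps Convergence tolerance on the criterion improvement per sweep.
#' @param max_sweeps Iteration cap; exceeding it is an error reporting the
#'   criterion trace.
#' @return List with `loadings` (rotated), `rotmat` (orthonormal k x k
#'   matrix with `loadings = input %*% rotmat`), `sweeps`, `criterion`.
#' @examples
#' L <- cbind(c(rep(0.8, 3), rep(0, 3)), c(rep(0, 3), rep(0.8, 3)))
#' r <- varimax_rotate(L + 0.01)
#' max(abs(crossprod(r$rotmat) - diag(2)))   # orthonormal
#' @export
varimax_rotate <- function(loadings, normalize = TRUE, eps = 1e-8,
                           max_sweeps = 1000L) {
  L0 <- as.matrix(loadings)
  p <- nrow(L0); k <- ncol(L0)
  stopifnot(k >= 2L, p > k)
  h <- if (normalize) sqrt(rowSums(L0^2)) else rep(1, p)
  h[h == 0] <- 1
  A <- L0 / h
  Tm <- diag(k)
  crit <- function(M) {
    M2 <- M^2
    sum(apply(M2, 2L, function(cc) sum(cc^2) - sum(cc)^2 / p))
  }
  trace <- numeric(0)
  last <- crit(A)
  for (sweep in seq_len(max_sweeps)) {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      x <- A[, i]; y <- A[, j]
      u <- x^2 - y^2; v <- 2 * x * y
      num <- 2 * (sum(u * v) - sum(u) * sum(v) / p)
      den <- sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2) / p
      phi <- atan2(num, den) / 4
      if (abs(phi) > .Machine$double.eps) {
        G <- diag(k); G[i, i] <- G[j, j] <- cos(phi)
        G[i, j] <- -sin(phi); G[j, i] <- sin(phi)
        A <- A %*% G
        Tm <- Tm %*% G
      }
    }
    now <- crit(A)
    trace <- c(trace, now)
    if (now - last < eps) {
      L <- A * h
      sgn <- apply(L, 2L, function(col) sign(col[which.max(abs(col))]))
      sgn[sgn == 0] <- 1
      ord <- order(-colSums(L^2))
      L <- sweep(L, 2L, sgn, `*`)[, ord, drop = FALSE]
      Tm <- sweep(Tm, 2L, sgn, `*`)[, ord, drop = FALSE]
      dimnames(L) <- list(rownames(L0), paste0("factor", seq_len(k)))
      return(list(loadings = L, rotmat = Tm, sweeps = sweep,
                  criterion = now))
    }
    last <- now
  }
  stop("varimax did not converge in ", max_sweeps,
       " sweeps; criterion trace tail: ",
       paste(signif(utils::tail(trace, 5), 8), collapse = ", "))
}
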