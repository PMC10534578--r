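test_that("Spearman rho: monotone invariance, reversal, and the no-ties identity", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rho(1:10, 11 - (1:10))$rho, -1)
  # frozen hand example: d^2 sum = 4 -> 1 - 24/120
  expect_equal(spearman_rho(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$rho, 0.8)
  # classic 1 - 6 sum d^2 / (n(n^2-1)) identity whenever there are no ties
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(9:40, 1)
    x <- sample(seq_len(1000), n); y <- sample(seq_len(1000), n)
    d <- rank(x) - rank(y)
    expect_equal(spearman_rho(x, y)$rho,
                 1 - 6 * sum(d^2) / (n * (n^2 - 1)), tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("Spearman p-values agree with stats::cor.test", {
  set.seed(7)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  ours <- spearman_rho(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  # t approximation vs the reference's AS 89 Edgeworth p: close, not identical
  expect_equal(ours$p_value, ref$p.value, tolerance = 0.1)
  # exact small-sample path: with 5 distinct ranks only the identity and the
  # full reversal reach |rho| = 1, so the permutation p is 2/5!
  expect_equal(spearman_rho(1:5, c(3, 8, 21, 55, 144))$p_value, 2 / 120)
  expect_equal(spearman_rho(1:5, -c(3, 8, 21, 55, 144))$p_value, 2 / 120)
})

test_that("Cronbach's alpha: identities and a hand-computed matrix", {
  X <- cbind(a = c(1, 2, 3, 5), b = c(1, 2, 3, 5), c = c(1, 2, 3, 5))
  expect_equal(cronbach_alpha(X)$alpha, 1)
  # two items with zero sample covariance -> alpha 0
  Y <- cbind(c(1, 2, 1, 2), c(1, 1.5, 1.5, 1))
  expect_equal(stats::cov(Y)[1, 2], 0)
  expect_equal(cronbach_alpha(Y)$alpha, 0)
  # 4 x 3 hand matrix: item variances 5/3, 9/4, 17/4; total variance 65/3
  H <- matrix(c(1, 2, 3, 4, 2, 2, 4, 5, 0, 3, 3, 5), 4, 3)
  expect_equal(cronbach_alpha(H)$alpha, 3 / 2 * (1 - (5/3 + 9/4 + 17/4) / (65/3)))
  # covariance-form identity on random matrices
  set.seed(11)
  for (rep in 1:10) {
    Z <- matrix(rnorm(15 * 4), 15, 4) + rnorm(15)
    C <- stats::cov(Z); k <- ncol(Z)
    expect_equal(cronbach_alpha(Z)$alpha,
                 k / (k - 1) * (1 - sum(diag(C)) / sum(C)),
                 tolerance = 1e-12)
  }
  expect_error(cronbach_alpha(cbind(c(1, 1), c(1, 1))), "zero variance")
})

test_that("sensitivity/specificity reproduce the printed paired-table fractions", {
  adm <- sensitivity_specificity(confusion_table(tp = 130, fp = 126,
                                                 fn = 82, tn = 454))
  expect_equal(adm$sensitivity, 130 / 212)
  expect_equal(adm$specificity, 454 / 580)
  dis <- sensitivity_specificity(confusion_table(tp = 333, fp = 129,
                                                 fn = 41, tn = 289))
  expect_equal(dis$sensitivity, 333 / 374)
  expect_equal(dis$specificity, 289 / 418)
  perfect <- sensitivity_specificity(confusion_table(tp = 10, fp = 0,
                                                     fn = 0, tn = 10))
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1))
  expect_error(sensitivity_specificity(confusion_table(tp = 0, fp = 3,
                                                       fn = 0, tn = 7)),
               "sensitivity undefined")
})

test_that("ROC curve geometry: endpoints, monotonicity, degenerate cases", {
  rc <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(rc$fpr[1], 0); expect_equal(rc$sensitivity[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$sensitivity[nrow(rc)], 1)
  expect_true(any(rc$fpr == 0 & rc$sensitivity == 1))  # passes through (0,1)
  # all scores equal: the two corner points only
  rc2 <- roc_curve(rep(3, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(nrow(rc2), 2)
  expect_equal(rc2$sensitivity, c(0, 1))
  set.seed(5)
  sc <- round(rnorm(40), 1); tr <- runif(40) < 0.4
  rc3 <- roc_curve(sc, tr)
  expect_true(all(diff(rc3$sensitivity) >= 0))
  expect_true(all(diff(rc3$fpr) >= 0))
  # 6-point hand example against exhaustive threshold enumeration
  sc6 <- c(1, 2, 3, 4, 5, 6); tr6 <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  rc6 <- roc_curve(sc6, tr6)
  for (i in seq_len(nrow(rc6))) {
    t <- rc6$threshold[i]
    expect_equal(rc6$sensitivity[i], sum(sc6 >= t & tr6) / 3)
    expect_equal(rc6$specificity[i], sum(sc6 < t & !tr6) / 3)
  }
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both classes")
})

test_that("trapezoid AUC equals the Mann-Whitney pairwise estimate", {
  expect_equal(auc(roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))), 1)
  set.seed(9)
  for (rep in 1:25) {
    n <- sample(10:80, 1)
    sc <- sample(seq_len(12), n, replace = TRUE)  # heavy ties
    tr <- runif(n) < 0.5
    if (all(tr) || !any(tr)) next
    expect_equal(auc(roc_curve(sc, tr)), mw_auc(sc, tr), tolerance = 1e-12)
  }
  # label-independent scores give AUC near one half
  set.seed(10)
  sc <- rnorm(10000); tr <- runif(10000) < 0.5
  expect_equal(auc(roc_curve(sc, tr)), 0.5, tolerance = 0.02)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  sc <- round(rnorm(200), 1); tr <- runif(200) < 0.4
  ref <- as.numeric(pROC::auc(pROC::roc(response = tr, predictor = sc,
                                        levels = c(FALSE, TRUE),
                                        quiet = TRUE, direction = "<")))
  expect_equal(auc(roc_curve(sc, tr)), ref, tolerance = 1e-12)
})

test_that("Youden cut-off matches the exhaustive scan with smallest-threshold ties", {
  rc <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(youden_cutoff(rc)$J, 1)
  set.seed(21)
  for (rep in 1:25) {
    sc <- sample(seq_len(8), 30, replace = TRUE)
    tr <- sc + rnorm(30, sd = 2) > 4.5
    if (all(tr) || !any(tr)) next
    got <- youden_cutoff(roc_curve(sc, tr))
    want <- scan_youden(sc, tr)
    expect_equal(got$J, want$J, tolerance = 1e-12)
    expect_equal(got$cutoff, want$cutoff)
  }
  # uninformative scores: J = 0
  rcu <- roc_curve(rep(2, 8), rep(c(TRUE, FALSE), 4))
  expect_equal(youden_cutoff(rcu)$J, 0)
})

test_that("KMO: p = 2 degeneracy, hand-inverted 3x3 case, error contracts", {
  R2 <- matrix(c(1, 0.37, 0.37, 1), 2, 2)
  expect_equal(kmo(R2), 0.5)
  # equicorrelated r = 0.5, p = 3: anti-image partials are all 1/3,
  # so KMO = (3 r^2) / (3 r^2 + 3/9) = 9/13
  R3 <- matrix(0.5, 3, 3); diag(R3) <- 1
  expect_equal(kmo(R3), 9 / 13, tolerance = 1e-12)
  # independently coded oracle on random positive-definite matrices
  set.seed(31)
  for (rep in 1:10) {
    X <- matrix(rnorm(60 * 5), 60, 5) %*% diag(5) + rnorm(60)
    R <- stats::cor(X)
    S <- solve(R); Q <- -S / sqrt(diag(S) %o% diag(S))
    off <- upper.tri(R)
    expect_equal(kmo(R), sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2)),
                 tolerance = 1e-12)
  }
  near_sing <- matrix(1 - 1e-9, 3, 3); diag(near_sing) <- 1
  expect_error(kmo(near_sing), "singular")
  expect_error(kmo(diag(3)), "identity")
})

test_that("Bartlett's sphericity: identity matrix, closed form, df", {
  expect_equal(bartlett_sphericity(diag(4), n = 50)$chi2, 0)
  # equicorrelated determinant (1-r)^2 (1+2r)
  r <- 0.3; R <- matrix(r, 3, 3); diag(R) <- 1
  got <- bartlett_sphericity(R, n = 100)
  expect_equal(got$chi2, -(100 - 1 - 11 / 6) * log((1 - r)^2 * (1 + 2 * r)),
               tolerance = 1e-12)
  expect_equal(got$df, 3)
  expect_equal(bartlett_sphericity(diag(10), n = 100)$df, 45)
})

test_that("PCA-based EFA: eigen structure, Kaiser retention, loadings", {
  expect_equal(kaiser_retained(printed_eigenvalues), 2)
  expect_equal(kaiser_retained(rep(1, 10)), 0)  # strict rule
  set.seed(41)
  f1 <- rnorm(300); f2 <- rnorm(300)
  X <- cbind(sapply(1:4, function(i) f1 + rnorm(300, sd = 0.6)),
             sapply(1:3, function(i) f2 + rnorm(300, sd = 0.6)))
  fs <- pca_efa(X)
  p <- ncol(X)
  expect_equal(sum(fs$eigenvalues), p, tolerance = 1e-9)
  expect_true(all(diff(fs$eigenvalues) <= 1e-12))
  expect_equal(fs$cumulative_pct[p], 100, tolerance = 1e-9)
  expect_equal(fs$n_retained, 2)
  # loadings reproduce the correlation matrix: L %*% t(L) == R
  R <- stats::cor(X)
  expect_equal(fs$loadings %*% t(fs$loadings), R, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_error(pca_efa(cbind(X, 1)), "constant")
})

test_that("varimax rotation: orthonormality, communalities, simple structure", {
  set.seed(51)
  for (rep in 1:10) {
    L <- matrix(rnorm(10 * 2, sd = 0.3), 10, 2)
    L[1:6, 1] <- L[1:6, 1] + 0.7; L[7:10, 2] <- L[7:10, 2] + 0.7
    r <- varimax_rotate(L)
    expect_equal(crossprod(r$rotmat), diag(2), ignore_attr = TRUE,
                 tolerance = 1e-10)
    expect_equal(rowSums(r$loadings^2), rowSums(L^2), ignore_attr = TRUE,
                 tolerance = 1e-10)
    expect_equal(L %*% r$rotmat, r$loadings, ignore_attr = TRUE,
                 tolerance = 1e-10)
  }
  # perfect simple structure is a fixed point up to sign/permutation
  Lp <- cbind(c(0.9, 0.8, 0.85, 0, 0, 0), c(0, 0, 0, 0.9, 0.8, 0.85))
  rp <- varimax_rotate(Lp, normalize = FALSE)
  expect_equal(abs(rp$loadings)[abs(rp$loadings) > 1e-6],
               c(0.9, 0.8, 0.85, 0.9, 0.8, 0.85), tolerance = 1e-6)
})

test_that("varimax matches the reference implementation's optimum", {
  set.seed(61)
  L <- matrix(rnorm(12 * 2, sd = 0.25), 12, 2)
  L[1:7, 1] <- L[1:7, 1] + 0.65; L[8:12, 2] <- L[8:12, 2] + 0.65
  ours <- varimax_rotate(L)$loadings
  ref <- unclass(stats::varimax(L, normalize = TRUE, eps = 1e-10)$loadings)
  # compare up to column order and sign via absolute cross-products
  agree <- abs(crossprod(ours, ref)) / sqrt(colSums(ours^2) %o% colSums(ref^2))
  expect_true(all(apply(agree, 1, max) > 1 - 1e-6))
})

test_that("planted two-block loadings are recovered from rotated PCA", {
  set.seed(71)
  f1 <- rnorm(842); f2 <- 0.4 * f1 + sqrt(1 - 0.16) * rnorm(842)
  X <- cbind(sapply(1:6, function(i) 0.75 * f1 + 0.2 * f2 + rnorm(842, sd = 0.62)),
             sapply(1:4, function(i) 0.2 * f1 + 0.75 * f2 + rnorm(842, sd = 0.62)))
  fs <- pca_efa(X)
  rot <- varimax_rotate(fs$loadings[, 1:2])$loadings
  dom <- apply(abs(rot), 1, which.max)
  planted <- rep(c(1, 2), c(6, 4))
  expect_gte(max(mean(dom == planted), mean(dom == 3 - planted)), 0.9)
})
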