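test_that("CPM normalization scales columns to one million", {
  m <- matrix(c(1, 3, 2, 2, 5, 0, 1, 1, 2, 9, 0, 3), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  cpm <- cpm_normalize(toy_expr(m))
  expect_equal(colSums(cpm$values), c(s1 = 1e6, s2 = 1e6, s3 = 1e6))
  expect_equal(cpm$values, sweep(m, 2, colSums(m), "/") * 1e6)  # arithmetic
  expect_identical(cpm$normalization, "cpm")

  two <- matrix(c(1, 3), 2, 1, dimnames = list(c("a", "b"), "s"))
  # need >=1 column; check proportionality on a 2x2
  m2 <- cbind(two, two * 4); colnames(m2) <- c("s1", "s2")
  out <- cpm_normalize(toy_expr(m2))
  expect_equal(unname(out$values[, 1]), c(250000, 750000))

  fixed <- matrix(c(25e4, 75e4), 2, 2,
                  dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(cpm_normalize(toy_expr(fixed))$values, fixed)  # fixed point

  z <- matrix(c(1, 2, 0, 0), 2, 2,
              dimnames = list(c("a", "b"), c("ok", "empty")))
  expect_error(cpm_normalize(toy_expr(z)), "empty")
})

test_that("VST uses median-of-ratios size factors and is monotone", {
  m <- matrix(c(10, 100, 40, 10, 100, 40), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  v <- vst_normalize(toy_expr(m))
  expect_equal(unname(v$size_factors), c(1, 1))
  expect_equal(v$values[, 1], v$values[, 2])

  # doubled library: size factors differ by 2, transformed columns equal
  m2 <- cbind(s1 = c(10, 100, 40), s2 = 2 * c(10, 100, 40))
  rownames(m2) <- paste0("g", 1:3)
  v2 <- vst_normalize(toy_expr(m2))
  expect_equal(unname(v2$size_factors[2] / v2$size_factors[1]), 2)
  expect_equal(unname(v2$values[, 1]), unname(v2$values[, 2]))

  # zero count maps to log2(0 + 1) = 0 when the size factor is 1
  m3 <- cbind(s1 = c(0, 100, 40), s2 = c(0, 100, 40))
  rownames(m3) <- paste0("g", 1:3)
  v3 <- vst_normalize(toy_expr(m3))
  expect_equal(unname(v3$values[1, ]), c(0, 0))

  # monotone within each sample
  set.seed(2)
  m4 <- matrix(rpois(60, 50), 20, 3,
               dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  v4 <- vst_normalize(toy_expr(m4))
  for (j in 1:3)
    expect_equal(order(v4$values[, j]), order(m4[, j], seq_len(20)))

  allzero <- matrix(c(0, 3, 4, 0), 2, 2,
                    dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_warning(vst_normalize(toy_expr(allzero)), "library-size")
})

test_that("PI is the median of the present set genes, robust to layout", {
  m <- matrix(rep(c(1, 2, 3, 4, 100, 7), 2), 6, 2,
              dimnames = list(c(paste0("p", 1:5), "bg"), c("s1", "s2")))
  em <- toy_expr(m, "vst")
  pi5 <- compute_pi(em, paste0("p", 1:5))
  expect_equal(unname(pi5$pi), c(3, 3))   # median by enumeration
  expect_equal(pi5$n_genes_used, 5L)

  # constant set genes -> PI equals the constant; single-gene set degenerate
  expect_equal(unname(compute_pi(em, "p2")$pi), c(2, 2))

  # invariant to row order and to genes outside the set; missing set genes
  # dropped with count recorded
  perm <- em; perm$values <- em$values[sample(6), , drop = FALSE]
  expect_equal(compute_pi(perm, c(paste0("p", 1:5), "absent"))$pi, pi5$pi)
  expect_equal(compute_pi(perm, c(paste0("p", 1:5), "absent"))$n_genes_used, 5L)
  expect_error(compute_pi(em, c("nope1", "nope2")), "missing")
  expect_error(compute_pi(toy_expr(m), "p1"), "cpm or vst")
})

test_that("PI on CPM data ignores per-sample count rescaling", {
  set.seed(8)
  m <- matrix(rpois(300, 60), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  scl <- m; scl[, 4] <- scl[, 4] * 7
  set_genes <- paste0("g", 1:9)
  p1 <- compute_pi(cpm_normalize(toy_expr(m)), set_genes)
  p2 <- compute_pi(cpm_normalize(toy_expr(scl)), set_genes)
  expect_equal(p1$pi, p2$pi)
})

test_that("group comparisons use the exact Wilcoxon null at small n", {
  # enumeration oracle: all 20 assignments of ranks for 3 vs 3
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  combos <- combn(6, 3)
  w_obs <- sum(rank(c(a, b))[1:3]) - 6
  w_all <- apply(combos, 2, function(ix) sum(rank(c(a, b))[ix]) - 6)
  p_exact <- mean(abs(w_all - 4.5) >= abs(w_obs - 4.5))
  cmp <- compare_pi_groups(c(a, b), rep(c("A", "B"), each = 3), "A", "B")
  expect_equal(cmp$p_value, p_exact)
  expect_equal(cmp$p_value, 0.1)
  expect_equal(cmp$W, 0)

  same <- compare_pi_groups(c(1, 2, 3, 1, 2, 3),
                            rep(c("A", "B"), each = 3), "A", "B")
  expect_equal(same$p_value, 1)
  expect_error(compare_pi_groups(c(1, 2), c("A", "A"), "A", "B"), "empty")
})

test_that("Wilcoxon comparison holds its nominal type-I error", {
  set.seed(31)
  hits <- replicate(1000, {
    v <- rnorm(24)
    compare_pi_groups(v, rep(c("A", "B"), 12), "A", "B")$p_value < 0.05
  })
  expect_gte(mean(hits), 0.035)
  expect_lte(mean(hits), 0.065)
})

test_that("principal components recover the planted PI factor", {
  set.seed(5)
  n <- 60; g <- 40
  z <- rnorm(n)
  load <- runif(g, 0.5, 1)
  m <- outer(load, z) + matrix(rnorm(g * n, 0, 0.05), g, n)
  dimnames(m) <- list(paste0("g", 1:g), paste0("s", 1:n))
  em <- toy_expr(m, "vst")
  piv <- compute_pi(em, paste0("g", 1:9))
  pc <- pc_pi_correlation(em, piv, k = 3)
  expect_gt(abs(pc$rho[1]), 0.99)

  # permuted PI decouples from every component
  pc_null <- pc_pi_correlation(em, sample(piv$pi), k = 3)
  expect_true(all(abs(pc_null$rho) < 0.35))

  # scores match a brute-force SVD oracle up to sign (10 x 8 toy)
  set.seed(6)
  toy <- matrix(rnorm(80), 10, 8,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  emt <- toy_expr(toy, "vst")
  pct <- pc_pi_correlation(emt, rnorm(8), k = 3)
  cen <- t(toy) - colMeans(t(toy))[col(t(toy))]
  cen <- scale(t(toy), center = TRUE, scale = FALSE)
  sv <- svd(cen)
  oracle <- sv$u %*% diag(sv$d)
  for (j in 1:3) {
    d1 <- max(abs(pct$scores[, j] - oracle[, j]))
    d2 <- max(abs(pct$scores[, j] + oracle[, j]))
    expect_lt(min(d1, d2), 1e-8)
  }
  const <- toy_expr(matrix(1, 3, 4, dimnames = list(letters[1:3],
                                                    LETTERS[1:4])), "vst")
  expect_error(pc_pi_correlation(const, rnorm(4)), "constant")
})

test_that("Spearman correlation of PI with covariates is rank-based", {
  v <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(correlate_pi_covariate(v, exp(v))$rho, 1)
  expect_equal(correlate_pi_covariate(v, -v^3)$rho, -1)

  # brute-force rank formula on 6 hand pairs (no ties)
  x <- c(10, 20, 30, 40, 50, 60); y <- c(12, 9, 44, 30, 60, 41)
  d <- rank(x) - rank(y)
  rho_brute <- 1 - 6 * sum(d^2) / (6 * (36 - 1))
  expect_equal(correlate_pi_covariate(x, y)$rho, rho_brute)

  expect_warning(out <- correlate_pi_covariate(v, rep(1, 6)), "constant")
  expect_true(is.na(out$rho))
  expect_error(correlate_pi_covariate(c(1, 2), c(1, 2)), "at least 3")
})
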