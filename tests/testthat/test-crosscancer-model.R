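# cohort helper: n patients, d of them dead, times 1..n
mk_cancer <- function(cc, n, d, times = seq_len(n)) {
  data.frame(sample_id = sprintf("%s_%02d", cc, seq_len(n)),
             cancer_type = cc, survival_days = times,
             event = c(rep(TRUE, d), rep(FALSE, n - d)),
             stringsAsFactors = FALSE)
}

test_that("dichotomization takes extreme survivors with stable tie-breaks", {
  # exactly 2k patients, k deaths among the k shortest -> all assigned
  co <- mk_cancer("A", 8, 4)
  d <- dichotomize(co, k = 4)
  expect_equal(nrow(d), 8L)
  expect_setequal(d$sample_id[d$outcome == 0], sprintf("A_%02d", 1:4))
  expect_setequal(d$sample_id[d$outcome == 1], sprintf("A_%02d", 5:8))
  expect_true(all(d$event[d$outcome == 0]))

  # tie at the k-th shortest time: lexicographically smaller id kept
  co2 <- data.frame(sample_id = c("A_05", "A_01", "A_03", "A_02", "A_04",
                                  "A_06"),
                    cancer_type = "A",
                    survival_days = c(10, 10, 50, 60, 70, 80),
                    event = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                    stringsAsFactors = FALSE)
  d2 <- dichotomize(co2, k = 1)
  expect_identical(d2$sample_id[d2$outcome == 0], "A_01")
  expect_identical(d2$sample_id[d2$outcome == 1], "A_06")

  # censored patients admitted to the long-surviving group
  expect_false(all(d$event[d$outcome == 1]))

  # failing cancers excluded with a warning
  both <- rbind(mk_cancer("A", 40, 20), mk_cancer("B", 10, 3))
  expect_warning(d3 <- dichotomize(both, k = 5), "B")
  expect_setequal(unique(d3$cancer_type), "A")
})

# small design with a planted outcome signal in gene g1
model_fixture <- function(seed = 31, n_per = 30, n_genes = 25, signal = 2) {
  set.seed(seed)
  cohort <- rbind(mk_cancer("A", n_per, n_per, times = sample(n_per)),
                  mk_cancer("B", n_per, n_per, times = sample(n_per)))
  expr_by <- lapply(split(cohort, cohort$cancer_type), function(s) {
    late <- s$survival_days > median(s$survival_days)
    m <- matrix(rnorm(n_genes * nrow(s)), n_genes,
                dimnames = list(paste0("g", seq_len(n_genes)), s$sample_id))
    m["g1", ] <- m["g1", ] + signal * late
    expression_matrix(m, "vst")
  })
  list(cohort = cohort, expr_by = expr_by)
}

test_that("scaling is per cancer and the 70/30 split is outcome-balanced", {
  fx <- model_fixture()
  des <- dichotomize(fx$cohort, k = 9)               # 36 patients
  des <- scale_and_partition(fx$expr_by, des, seed = 3)
  feat <- attr(des, "features")
  for (cc in c("A", "B")) {
    blk <- feat[des$cancer_type == cc, ]
    expect_true(all(abs(colMeans(blk)) < 1e-12))
    expect_true(all(abs(apply(blk, 2, sd) - 1) < 1e-12))
  }
  expect_equal(sum(des$partition == "train"), 26L)   # ceil(0.7 * 36) per stratum
  expect_equal(sum(des$partition == "test"), 10L)
  tr_out <- table(des$outcome[des$partition == "train"])
  expect_lte(abs(diff(as.numeric(tr_out))), 1)

  des_b <- scale_and_partition(fx$expr_by, dichotomize(fx$cohort, k = 9),
                               seed = 3)
  expect_identical(des$partition, des_b$partition)   # seeded determinism
})

test_that("lasso finds a perfectly separating feature; null labels give chance AUC", {
  fx <- model_fixture(seed = 32, n_per = 40, signal = 50)
  des <- scale_and_partition(fx$expr_by, dichotomize(fx$cohort, k = 12),
                             seed = 4)
  fit <- fit_model(des, "lasso", seed = 4)
  nz <- names(fit$coefficients)
  expect_true("g1" %in% nz)
  expect_equal(evaluate_model(fit, des)$auc, 1)

  # destroyed signal: test AUC near chance
  fx0 <- model_fixture(seed = 33, n_per = 70, signal = 0)
  des0 <- scale_and_partition(fx0$expr_by, dichotomize(fx0$cohort, k = 21),
                              seed = 5)
  fit0 <- fit_model(des0, "lasso", seed = 5)
  auc0 <- evaluate_model(fit0, des0)$auc
  expect_gte(auc0, 0.35); expect_lte(auc0, 0.65)
})

test_that("ridge keeps dense coefficients where lasso zeroes them", {
  fx <- model_fixture(seed = 34, n_per = 40, signal = 1)
  des <- scale_and_partition(fx$expr_by, dichotomize(fx$cohort, k = 12),
                             seed = 6)
  lasso <- fit_model(des, "lasso", seed = 6)
  ridge <- fit_model(des, "ridge", seed = 6)
  p <- length(rownames(fx$expr_by$A$values))
  expect_lt(length(lasso$coefficients) - 1, p)       # some exact zeros
  expect_equal(length(ridge$coefficients) - 1, p)    # none exactly zero
  expect_equal(ridge$hyperparameters$alpha, 0)
  expect_equal(lasso$hyperparameters$alpha, 1)
})

test_that("random forest and linear SVM run behind the same interface", {
  fx <- model_fixture(seed = 35, n_per = 30, signal = 3)
  des <- scale_and_partition(fx$expr_by, dichotomize(fx$cohort, k = 9),
                             seed = 7)
  rf <- fit_model(des, "random_forest", seed = 7)
  expect_lte(rf$hyperparameters$mtry, 1000)
  expect_gt(evaluate_model(rf, des)$auc, 0.6)
  sv <- fit_model(des, "linear_svm", seed = 7)
  expect_true(sv$hyperparameters$cost %in% 10^(-5:4))
  expect_gt(evaluate_model(sv, des)$auc, 0.6)
})

test_that("ROC/AUC follow the Mann-Whitney identity and monotone invariance", {
  expect_equal(roc_curve(rep(0.3, 10), rep(0:1, 5))$auc, 0.5)
  expect_equal(roc_curve(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 1, 1, 1))$auc, 1)

  s <- c(0.1, 0.9, 0.4, 0.35, 0.8, 0.2); y <- c(0, 1, 1, 0, 1, 0)
  u <- sum(outer(s[y == 1], s[y == 0],
                 function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(roc_curve(s, y)$auc, u / (3 * 3))
  expect_equal(roc_curve(exp(5 * s), y)$auc, roc_curve(s, y)$auc)
  expect_error(roc_curve(s, rep(1, 6)), "single-class")
})

test_that("the paired AUC comparison agrees with the reference DeLong test", {
  skip_if_not_installed("pROC")
  set.seed(36)
  y <- rbinom(80, 1, 0.5)
  s1 <- y + rnorm(80); s2 <- y + rnorm(80, 0, 3)
  d <- delong_test(s1, s2, y)
  ref <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE),
                        pROC::roc(y, s2, quiet = TRUE), method = "delong")
  expect_equal(d$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(d$auc1, as.numeric(ref$roc1$auc), tolerance = 1e-10)
})

test_that("permutation draws are seeded, redrawn on failure, and degenerate cleanly", {
  fx <- model_fixture(seed = 37, n_per = 30, signal = 3)
  pr1 <- permutation_null(fx$expr_by, fx$cohort, pic_cancers = c("A", "B"),
                          n_draws = 4, set_size = 2, k = 9, seed = 8)
  pr2 <- permutation_null(fx$expr_by, fx$cohort, pic_cancers = c("A", "B"),
                          n_draws = 4, set_size = 2, k = 9, seed = 8)
  expect_identical(pr1$draws, pr2$draws)
  # every draw contains both PICs -> rho undefined, reported missing
  expect_true(is.na(pr1$rho))
  expect_equal(unique(pr1$draws$n_pics), 2L)
})

test_that("full-cohort assessment applies the held-out rule per cancer", {
  set.seed(38)
  # cancer A large (many uncensored beyond training), cancer B small
  fx <- model_fixture(seed = 38, n_per = 80, signal = 3)
  small <- mk_cancer("C", 26, 26, times = sample(26))
  set.seed(39)
  fx$expr_by$C <- expression_matrix(
    matrix(rnorm(25 * 26), 25, dimnames = list(paste0("g", 1:25),
                                               small$sample_id)), "vst")
  cohort <- rbind(fx$cohort, small)
  des <- scale_and_partition(fx$expr_by,
                             suppressWarnings(dichotomize(cohort, k = 12)),
                             seed = 9)
  fit <- fit_model(des, "lasso", seed = 9)
  res <- full_cohort_assessment(fit, cohort, fx$expr_by, des,
                                pic_cancers = c("A", "C"))
  expect_identical(res$flag[res$cancer == "A"], "held_out")
  expect_identical(res$flag[res$cancer == "C"], "includes_training")
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))

  missing_gene_expr <- fx$expr_by
  missing_gene_expr$A$values <- missing_gene_expr$A$values[-1, ]
  expect_error(full_cohort_assessment(fit, cohort, missing_gene_expr, des,
                                      pic_cancers = "A"),
               "missing")
})
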