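#' Extreme-survivor dichotomization
#'
#' For each cancer, takes the k shortest-surviving patients who died
#' (outcome 0) and, from the remaining patients, the k longest-surviving
#' patients, censored allowed (outcome 1). k defaults to 18, the top/bottom
#' quartile of the smallest cohort in the original study (mesothelioma).
#' Ties at the k-th time are broken by sample id. Cancers with fewer than k
#' uncensored deaths or fewer than 2k patients are excluded with a warning.
#'
#' @param cohort cohort data.frame.
#' @param k extreme-group size per cancer (18).
#' @return data.frame of class `dichotomized_design`: sample_id,
#'   cancer_type, survival_days, event, outcome (0 short / 1 long).
#' @export
dichotomize <- function(cohort, k = 18) {
  rows <- lapply(unique(cohort$cancer_type), function(cc) {
    sub <- cohort[cohort$cancer_type == cc, ]
    dead <- sub[sub$event, ]
    if (nrow(dead) < k || nrow(sub) < 2 * k) {
      warning("cancer ", cc, " fails dichotomization preconditions; excluded")
      return(NULL)
    }
    dead <- dead[order(dead$survival_days, dead$sample_id), ]
    short <- dead[seq_len(k), ]
    rest <- sub[!sub$sample_id %in% short$sample_id, ]
    rest <- rest[order(-rest$survival_days, rest$sample_id), ]
    long <- rest[seq_len(k), ]
    out <- rbind(short, long)
    out$outcome <- rep(c(0L, 1L), each = k)
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no cancer passed dichotomization")
  rownames(out) <- NULL
  out <- out[, c("sample_id", "cancer_type", "survival_days", "event",
                 "outcome")]
  class(out) <- c("dichotomized_design", "data.frame")
  out
}

# gene-wise z-scale a genes x samples matrix; zero-variance genes -> 0
scale_genes <- function(v, warn_constant = TRUE) {
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  zero <- sdv == 0
  if (any(zero) && warn_constant)
    warning(sum(zero), " zero-variance gene(s) scaled to 0")
  sdv[zero] <- 1
  out <- (v - mu) / sdv
  out[zero, ] <- 0
  out
}

#' Scale expression within cancers and partition into train/test
#'
#' Gene-wise z-scaling (mean 0, SD 1) computed within each cancer over the
#' design samples before the cohorts are combined, then a 70/30 train/test
#' split stratified by outcome (per-stratum ceiling on the training share),
#' seeded for reproducibility.
#'
#' @param expr_by_cancer named list of VST `expr_mat` per cancer.
#' @param design a [dichotomize()] result.
#' @param seed integer seed for the partition.
#' @param train_frac training fraction (0.7).
#' @return the design with columns `partition` ("train"/"test") added and a
#'   `features` attribute: samples x genes scaled matrix aligned with rows.
#' @export
scale_and_partition <- function(expr_by_cancer, design, seed = 1L,
                                train_frac = 0.7) {
  blocks <- lapply(unique(design$cancer_type), function(cc) {
    ids <- design$sample_id[design$cancer_type == cc]
    em <- expr_by_cancer[[cc]]
    if (is.null(em)) stop("no expression for cancer ", cc)
    if (em$normalization != "vst") stop("expression for ", cc, " is not VST")
    missing <- setdiff(ids, colnames(em$values))
    if (length(missing))
      stop("samples missing from expression: ",
           paste(utils::head(missing, 3), collapse = ", "))
    t(scale_genes(em$values[, ids, drop = FALSE], warn_constant = FALSE))
  })
  feat <- do.call(rbind, blocks)
  feat <- feat[design$sample_id, , drop = FALSE]

  set.seed(seed)
  part <- rep("test", nrow(design))
  for (o in unique(design$outcome)) {
    ix <- which(design$outcome == o)
    n_tr <- ceiling(train_frac * length(ix))
    part[sample(ix, n_tr)] <- "train"
  }
  design$partition <- part
  attr(design, "features") <- feat
  design
}

#' Fit a cross-cancer extreme-survivor classifier
#'
#' Trains outcome ~ scaled expression on the training partition. Families:
#' `lasso` / `ridge` — penalized binomial regression ([glmnet::cv.glmnet()],
#' 5-fold CV, lambda by the one-standard-error rule, alpha 1 / 0);
#' `random_forest` — default randomForest settings except mtry capped at
#' 1000; `linear_svm` — linear-kernel SVM, cost selected over the grid
#' 1e-5..1e4 (decade steps) by 5-fold cross-validation error.
#'
#' @param design a partitioned design from [scale_and_partition()].
#' @param family one of "lasso", "ridge", "random_forest", "linear_svm".
#' @param seed seed for CV fold assignment / tree bootstrap.
#' @param cv_measure CV loss for lambda selection: "deviance" (default) or
#'   "mse".
#' @return object of class `prolif_model` with the fitted object, family,
#'   selected hyperparameters and nonzero coefficients (linear families).
#' @export
fit_model <- function(design, family = c("lasso", "ridge", "random_forest",
                                         "linear_svm"),
                      seed = 1L, cv_measure = c("deviance", "mse")) {
  family <- match.arg(family)
  cv_measure <- match.arg(cv_measure)
  feat <- attr(design, "features")
  tr <- design$partition == "train"
  x <- feat[tr, , drop = FALSE]
  y <- design$outcome[tr]
  if (length(unique(y)) < 2L) stop("single-class training set")
  set.seed(seed)
  if (family %in% c("lasso", "ridge")) {
    alpha <- if (family == "lasso") 1 else 0
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", nfolds = 5,
                            alpha = alpha,
                            type.measure = if (cv_measure == "mse") "mse"
                                           else "deviance")
    cf <- as.matrix(stats::coef(cv, s = "lambda.1se"))
    nz <- cf[cf[, 1] != 0, 1]
    fitted <- cv
    hyper <- list(alpha = alpha, lambda = cv$lambda.1se)
  } else if (family == "random_forest") {
    if (!requireNamespace("randomForest", quietly = TRUE))
      stop("randomForest package required for family 'random_forest'")
    mtry <- min(1000, floor(sqrt(ncol(x))))
    fitted <- randomForest::randomForest(x, factor(y), mtry = mtry)
    nz <- NULL
    hyper <- list(mtry = mtry)
  } else {
    if (!requireNamespace("e1071", quietly = TRUE))
      stop("e1071 package required for family 'linear_svm'")
    costs <- 10^(-5:4)
    errs <- vapply(costs, function(cst) {
      f <- e1071::svm(x, factor(y), kernel = "linear", cost = cst, cross = 5)
      1 - f$tot.accuracy / 100
    }, numeric(1))
    best <- costs[which.min(errs)]
    fitted <- e1071::svm(x, factor(y), kernel = "linear", cost = best)
    w <- t(fitted$coefs) %*% fitted$SV
    nz <- stats::setNames(drop(w), colnames(x))
    hyper <- list(cost = best, cv_error = min(errs))
  }
  structure(list(family = family, fit = fitted, coefficients = nz,
                 hyperparameters = hyper, genes = colnames(x),
                 seed = seed),
            class = "prolif_model")
}

#' @export
print.prolif_model <- function(x, ...) {
  cat(sprintf("cross-cancer survival classifier (%s)\n", x$family))
  if (!is.null(x$coefficients) && x$family %in% c("lasso", "ridge"))
    cat(sprintf("  %d nonzero coefficients (lambda = %.4g)\n",
                sum(names(x$coefficients) != "(Intercept)"),
                x$hyperparameters$lambda))
  invisible(x)
}

#' Score samples with a fitted classifier
#' @param object a `prolif_model`.
#' @param newx samples x genes matrix on the model's gene set.
#' @param ... unused.
#' @return numeric score per sample (higher = predicted long survival).
#' @export
predict.prolif_model <- function(object, newx, ...) {
  newx <- newx[, object$genes, drop = FALSE]
  switch(object$family,
    lasso = ,
    ridge = drop(stats::predict(object$fit, newx = newx, s = "lambda.1se",
                                type = "link")),
    random_forest = stats::predict(object$fit, newx, type = "prob")[, "1"],
    linear_svm = {
      dv <- attr(stats::predict(object$fit, newx, decision.values = TRUE),
                 "decision.values")
      s <- drop(dv)
      # orient so higher score = class "1"
      if (grepl("^1", colnames(dv)[1])) s else -s
    })
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 outcomes.
#' @return list with `fpr`, `tpr` (curve points) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("single-class labels: AUC undefined")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  # collapse tied score thresholds
  last <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, tp[last] / sum(y == 1))
  fpr <- c(0, fp[last] / sum(y == 0))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Evaluate a classifier on the held-out test partition
#'
#' @param model a `prolif_model`.
#' @param design the partitioned design the model was trained on.
#' @return list of class `model_eval`: `auc`, `roc`, `scores`, `labels`,
#'   `test_ids`.
#' @export
evaluate_model <- function(model, design) {
  te <- design$partition == "test"
  if (!any(te)) stop("empty test partition")
  labels <- design$outcome[te]
  if (length(unique(labels)) < 2L) stop("single-class test set: AUC undefined")
  scores <- predict(model, attr(design, "features")[te, , drop = FALSE])
  roc <- roc_curve(scores, labels)
  structure(list(auc = roc$auc, roc = roc, scores = scores, labels = labels,
                 test_ids = design$sample_id[te]),
            class = "model_eval")
}

#' @export
print.model_eval <- function(x, ...) {
  cat(sprintf("test-set ROC AUC = %.3f (n = %d)\n", x$auc, length(x$labels)))
  invisible(x)
}

#' DeLong test for two correlated ROC AUCs
#'
#' Paired comparison of two classifiers scored on the same test samples,
#' using the placement-value covariance estimator.
#'
#' @param scores1,scores2 score vectors on the same samples.
#' @param labels shared 0/1 outcomes.
#' @return list with `auc1`, `auc2`, `z`, `p_value`.
#' @export
delong_test <- function(scores1, scores2, labels) {
  labels <- as.integer(labels)
  pos <- labels == 1; neg <- labels == 0
  m <- sum(pos); n <- sum(neg)
  if (m < 2 || n < 2) stop("need at least 2 samples per class")
  placements <- function(s) {
    sp <- s[pos]; sn <- s[neg]
    v10 <- vapply(sp, function(x) mean((x > sn) + 0.5 * (x == sn)), numeric(1))
    v01 <- vapply(sn, function(x) mean((sp > x) + 0.5 * (sp == x)), numeric(1))
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  p1 <- placements(scores1); p2 <- placements(scores2)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  z <- (p1$auc - p2$auc) / sqrt(var_diff)
  list(auc1 = p1$auc, auc2 = p2$auc, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Random-cancer-set permutation null for the PIC-only model
#'
#' Repeatedly samples `set_size` distinct cancers, dichotomizes, scales,
#' partitions, fits a classifier and records its test AUC together with the
#' number of planted/classified PICs in the draw. Draws in which a cancer
#' fails dichotomization preconditions are redrawn (count logged), keeping
#' `n_draws` effective draws. Summaries: Spearman rho between the number of
#' PICs and the AUC, and the empirical exceedance p of a reference AUC
#' (e.g. the PIC-only model's).
#'
#' @param expr_by_cancer named list of VST `expr_mat` per cancer.
#' @param cohort cohort data.frame.
#' @param pic_cancers character vector: which cancers are PICs.
#' @param n_draws number of effective draws (1000; scale down for quick
#'   runs).
#' @param set_size cancers per draw (7).
#' @param family model family (lasso).
#' @param k dichotomization group size (18).
#' @param seed integer seed.
#' @param reference_auc optional AUC against which the exceedance p is
#'   computed.
#' @return list of class `permutation_run`: `draws` data.frame (cancers,
#'   n_pics, auc), `rho`, `rho_p`, `exceedance_p`, `n_redrawn`.
#' @export
permutation_null <- function(expr_by_cancer, cohort, pic_cancers,
                             n_draws = 1000, set_size = 7,
                             family = "lasso", k = 18, seed = 1L,
                             reference_auc = NULL) {
  cancers <- intersect(unique(cohort$cancer_type), names(expr_by_cancer))
  if (length(cancers) < set_size) stop("fewer cancers than set_size")
  set.seed(seed)
  draws <- vector("list", n_draws)
  n_redrawn <- 0L
  i <- 1L
  while (i <= n_draws) {
    pick <- sample(cancers, set_size)
    sub <- cohort[cohort$cancer_type %in% pick, ]
    des <- tryCatch(
      suppressWarnings(dichotomize(sub, k = k)),
      error = function(e) NULL)
    if (is.null(des) || length(unique(des$cancer_type)) < set_size) {
      n_redrawn <- n_redrawn + 1L
      next
    }
    des <- scale_and_partition(expr_by_cancer, des,
                               seed = seed + i)
    fit <- fit_model(des, family = family, seed = seed + i)
    ev <- evaluate_model(fit, des)
    draws[[i]] <- data.frame(draw = i,
                             cancers = paste(sort(pick), collapse = ","),
                             n_pics = sum(pick %in% pic_cancers),
                             auc = ev$auc, stringsAsFactors = FALSE)
    i <- i + 1L
  }
  dd <- do.call(rbind, draws)
  if (stats::sd(dd$n_pics) == 0) {
    rho <- NA_real_; rho_p <- NA_real_
  } else {
    ct <- suppressWarnings(stats::cor.test(dd$n_pics, dd$auc,
                                           method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate); rho_p <- ct$p.value
  }
  exceedance_p <- if (is.null(reference_auc)) NA_real_ else
    mean(dd$auc >= reference_auc)
  structure(list(draws = dd, rho = rho, rho_p = rho_p,
                 exceedance_p = exceedance_p, n_redrawn = n_redrawn,
                 set_size = set_size, seed = seed),
            class = "permutation_run")
}

#' @export
print.permutation_run <- function(x, ...) {
  cat(sprintf("permutation null: %d draws of %d cancers\n",
              nrow(x$draws), x$set_size))
  cat(sprintf("  AUC: median %.3f, max %.3f; rho(#PICs, AUC) = %.3f (p = %.3g)\n",
              stats::median(x$draws$auc), max(x$draws$auc), x$rho, x$rho_p))
  if (!is.na(x$exceedance_p))
    cat(sprintf("  empirical exceedance p of reference AUC: %.3g\n",
                x$exceedance_p))
  invisible(x)
}

#' Full-cohort stratification by the PIC-only model
#'
#' Applies a fitted classifier to every patient of each PIC (expression
#' scaled gene-wise within the cancer over the scored samples) and compares
#' the top and bottom quartiles of the predicted score with Kaplan-Meier
#' curves and the log-rank test. Cancers with more than 25 uncensored
#' patients outside the training set are evaluated on non-training patients
#' only (flag `held_out`); the rest are evaluated on the full cohort
#' including training patients (flag `includes_training`).
#'
#' @param model a `prolif_model`.
#' @param cohort cohort data.frame.
#' @param expr_by_cancer named list of VST `expr_mat` per cancer.
#' @param design the partitioned design used in training (for training ids).
#' @param pic_cancers cancers to assess.
#' @param min_heldout uncensored non-training patients required to evaluate
#'   held-out only (25).
#' @return data.frame: cancer, n_scored, flag, logrank_chisq, p_value.
#' @export
full_cohort_assessment <- function(model, cohort, expr_by_cancer, design,
                                   pic_cancers, min_heldout = 25) {
  train_ids <- design$sample_id[design$partition == "train"]
  rows <- lapply(pic_cancers, function(cc) {
    sub <- cohort[cohort$cancer_type == cc, ]
    held <- sub[!sub$sample_id %in% train_ids, ]
    if (sum(held$event) > min_heldout) {
      use <- held; flag <- "held_out"
    } else {
      use <- sub; flag <- "includes_training"
    }
    em <- expr_by_cancer[[cc]]
    missing <- setdiff(model$genes, rownames(em$values))
    if (length(missing))
      stop("genes missing for scoring: ",
           paste(utils::head(missing, 5), collapse = ", "))
    x <- t(scale_genes(em$values[model$genes, use$sample_id, drop = FALSE],
                       warn_constant = FALSE))
    sc <- predict(model, x)
    km <- km_quartile_test(use$survival_days, use$event, sc)
    data.frame(cancer = cc, n_scored = nrow(use), flag = flag,
               logrank_chisq = km$chisq, p_value = km$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
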