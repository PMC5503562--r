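#' Per-cancer Cox regression of survival on the proliferative index
#'
#' One [cox_fit()] per cancer of overall survival on the within-cancer PI
#' (computed on VST expression). Cancers without PI values are skipped with
#' a warning.
#'
#' @param cohort cohort data.frame.
#' @param pi_by_cancer named list of `pi_index` objects (or named numeric
#'   vectors keyed by sample id), one per cancer type.
#' @return data.frame of class `pic_scan`: cancer, coefficient, p_value, n,
#'   n_events, converged.
#' @export
pi_survival_scan <- function(cohort, pi_by_cancer) {
  cancers <- unique(cohort$cancer_type)
  rows <- lapply(cancers, function(cc) {
    if (!cc %in% names(pi_by_cancer)) {
      warning("no PI for cancer ", cc, "; skipped")
      return(NULL)
    }
    sub <- cohort[cohort$cancer_type == cc, ]
    v <- as_pi_values(pi_by_cancer[[cc]])
    if (inherits(pi_by_cancer[[cc]], "pi_index"))
      names(v) <- pi_by_cancer[[cc]]$sample_ids
    v <- v[sub$sample_id]
    f <- cox_fit(sub$survival_days, sub$event, unname(v))
    data.frame(cancer = cc, coefficient = f$coefficient,
               p_value = f$p_value, n = f$n, n_events = f$n_events,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pic_scan", "data.frame")
  out
}

#' Transcriptome-wide Cox scan
#'
#' Fits one single-covariate Cox model per (cancer, transcript) on VST
#' expression and collects Wald p-values into a cancers x transcripts
#' matrix. Fits that fail (non-convergence, constant transcript, too few
#' events) take p = 1, so the matrix is complete.
#'
#' @param cohort cohort data.frame.
#' @param expr_by_cancer named list of VST `expr_mat` objects per cancer
#'   (columns matching that cancer's sample ids).
#' @param min_variance optional minimum per-cancer transcript variance;
#'   transcripts below it are not fitted and take p = 1 (default 0 = scan
#'   everything).
#' @return numeric matrix, rows = cancers, columns = transcripts, entries
#'   in (0, 1].
#' @export
transcriptome_survival_scan <- function(cohort, expr_by_cancer,
                                        min_variance = 0) {
  cancers <- intersect(unique(cohort$cancer_type), names(expr_by_cancer))
  genes <- rownames(expr_by_cancer[[cancers[1]]]$values)
  pmat <- matrix(1, length(cancers), length(genes),
                 dimnames = list(cancers, genes))
  for (cc in cancers) {
    em <- expr_by_cancer[[cc]]
    if (em$normalization != "vst")
      stop("expression for ", cc, " is not VST normalized")
    sub <- cohort[cohort$cancer_type == cc, ]
    v <- em$values[, sub$sample_id, drop = FALSE]
    lay <- cox_layout(sub$survival_days, sub$event)
    vr <- if (min_variance > 0) apply(v, 1, stats::var) else NULL
    for (g in seq_len(nrow(v))) {
      if (!is.null(vr) && vr[g] < min_variance) next
      f <- cox_fit(sub$survival_days, sub$event, v[g, ], layout = lay)
      pmat[cc, g] <- f$p_value
    }
  }
  pmat
}

#' Select transcripts sharing survival association across cancers
#'
#' Transcripts whose uncorrected Cox p-value is below `alpha` in at least
#' `min_cancers` cancers (strict inequality on both thresholds' boundaries:
#' p exactly equal to alpha does not count).
#'
#' @param pmat cancers x transcripts p-value matrix.
#' @param alpha per-test threshold (0.05).
#' @param min_cancers minimum number of cancers (9).
#' @return list gene set (`name`, `genes`).
#' @export
select_shared_transcripts <- function(pmat, alpha = 0.05, min_cancers = 9) {
  hits <- colSums(pmat < alpha)
  list(name = sprintf("shared_p%g_in%d", alpha, min_cancers),
       genes = colnames(pmat)[hits >= min_cancers])
}

#' Cluster cancers on their survival-association profiles
#'
#' Hierarchical agglomeration (Euclidean distance, Ward linkage, `ward.D2`)
#' of the -log10 Cox p-value rows restricted to the selected transcripts,
#' with a k-group cut (default 2: the PIC / non-PIC dichotomy).
#'
#' @param pmat cancers x transcripts p-value matrix.
#' @param transcripts gene set (or character vector) to restrict to.
#' @param k number of clusters to cut (2).
#' @return list with `hclust` (the tree), `clusters` (named cut membership).
#' @export
cluster_cancers <- function(pmat, transcripts, k = 2) {
  if (is.list(transcripts)) transcripts <- transcripts$genes
  if (length(transcripts) < 1L) stop("no transcripts to cluster on")
  if (nrow(pmat) < 2L) stop("need at least 2 cancers")
  m <- -log10(pmat[, transcripts, drop = FALSE])
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "ward.D2")
  list(hclust = hc, clusters = stats::cutree(hc, k = k))
}

#' Classify proliferation-informative cancers
#'
#' Bonferroni-corrects the per-cancer PI Cox p-values over the number of
#' cancers scanned and labels as PIC every cancer with corrected p strictly
#' below `alpha`.
#'
#' @param scan output of [pi_survival_scan()].
#' @param n_cancers Bonferroni factor (default: rows of `scan`).
#' @param alpha significance level (0.05).
#' @return `scan` with columns `p_corrected` and `is_pic` added; class
#'   `pic_labels`.
#' @export
identify_pics <- function(scan, n_cancers = nrow(scan), alpha = 0.05) {
  scan$p_corrected <- pmin(1, scan$p_value * n_cancers)
  scan$is_pic <- scan$p_corrected < alpha
  class(scan) <- c("pic_labels", "data.frame")
  scan
}

#' @export
print.pic_labels <- function(x, ...) {
  cat(sprintf("PIC classification: %d/%d cancers proliferation-informative\n",
              sum(x$is_pic), nrow(x)))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Kaplan-Meier comparison of score quartiles
#'
#' Partitions samples at the 25th/75th percentiles of a score (PI or a model
#' prediction), estimates Kaplan-Meier curves for the two extreme quartiles
#' and tests them with the two-group log-rank test. Samples tied exactly at
#' a quartile boundary go to the extreme group.
#'
#' @param time,event survival outcome.
#' @param score per-sample score.
#' @return list with `chisq` (log-rank statistic), `p_value`, `fit`
#'   (a `survfit` over both groups), `n_low`, `n_high`.
#' @export
km_quartile_test <- function(time, event, score) {
  if (length(score) < 4L) stop("need at least 4 samples")
  if (max(score) - min(score) <= 0) stop("constant score")
  qs <- stats::quantile(score, c(0.25, 0.75), type = 7)
  low <- score <= qs[1]
  high <- score >= qs[2]
  if (!any(low) || !any(high)) stop("empty quartile after tie handling")
  keep <- low | high
  grp <- factor(ifelse(low[keep], "low", "high"), levels = c("low", "high"))
  tt <- time[keep]; ev <- event[keep]
  sd_ <- survival::survdiff(survival::Surv(tt, ev) ~ grp)
  fit <- survival::survfit(survival::Surv(tt, ev) ~ grp)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(sd_$chisq), p_value = p, fit = fit,
       n_low = sum(low), n_high = sum(high))
}
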