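#' Split an expression matrix by cancer type
#'
#' @param expr an `expr_mat` (any normalization).
#' @param cohort cohort data.frame with sample_id, cancer_type.
#' @return named list of `expr_mat`, one per cancer.
#' @export
split_by_cancer <- function(expr, cohort) {
  stopifnot(inherits(expr, "expr_mat"))
  cancers <- unique(cohort$cancer_type)
  out <- lapply(cancers, function(cc) {
    ids <- intersect(cohort$sample_id[cohort$cancer_type == cc],
                     colnames(expr$values))
    em <- expression_matrix(expr$values[, ids, drop = FALSE],
                            expr$normalization)
    em
  })
  names(out) <- cancers
  out
}

#' Run the PIC discovery stage on a cohort
#'
#' Per cancer: VST-normalize raw counts, compute the PI, Cox-regress
#' survival on PI; then Bonferroni-correct across cancers and classify
#' PICs. Optionally also runs the transcriptome-wide scan, the
#' shared-transcript selection and the Ward clustering consistency check.
#'
#' @param expr raw-count `expr_mat` for the whole cohort.
#' @param cohort cohort data.frame.
#' @param pi_genes PI gene set.
#' @param alpha significance level (0.05).
#' @param min_cancers shared-transcript threshold (9).
#' @param full whether to run the transcriptome scan + clustering (TRUE).
#' @return list: `vst_by_cancer`, `pi_by_cancer`, `pic_labels`, and when
#'   `full`, `pvalue_matrix`, `shared_transcripts`, `clustering`.
#' @export
run_pic_analysis <- function(expr, cohort, pi_genes, alpha = 0.05,
                             min_cancers = 9, full = TRUE) {
  raw_by_cancer <- split_by_cancer(expr, cohort)
  vst_by_cancer <- lapply(raw_by_cancer, vst_normalize)
  pi_by_cancer <- lapply(vst_by_cancer, compute_pi, genes = pi_genes)
  scan <- pi_survival_scan(cohort, pi_by_cancer)
  labels <- identify_pics(scan, n_cancers = nrow(scan), alpha = alpha)
  out <- list(vst_by_cancer = vst_by_cancer, pi_by_cancer = pi_by_cancer,
              pic_labels = labels)
  if (full) {
    pmat <- transcriptome_survival_scan(cohort, vst_by_cancer)
    shared <- select_shared_transcripts(pmat, alpha = alpha,
                                        min_cancers = min_cancers)
    out$pvalue_matrix <- pmat
    out$shared_transcripts <- shared
    if (length(shared$genes) >= 1L && nrow(pmat) >= 2L)
      out$clustering <- cluster_cancers(pmat, shared, k = 2)
  }
  out
}

#' Fit and evaluate the PIC-only and all-cancer classifiers
#'
#' Dichotomizes the cohorts, scales/partitions and fits one model on the
#' PIC-only set and one on all cancers, returning both evaluations.
#'
#' @param vst_by_cancer named list of VST `expr_mat` per cancer.
#' @param cohort cohort data.frame.
#' @param pic_cancers character vector of PIC cancer types.
#' @param family model family ("lasso").
#' @param k dichotomization group size (18).
#' @param seed integer seed.
#' @return list with `pic` and `all`, each holding `design`, `model`,
#'   `eval`.
#' @export
fit_crosscancer_models <- function(vst_by_cancer, cohort, pic_cancers,
                                   family = "lasso", k = 18, seed = 1L) {
  one <- function(sub_cohort) {
    des <- dichotomize(sub_cohort, k = k)
    des <- scale_and_partition(vst_by_cancer, des, seed = seed)
    mod <- fit_model(des, family = family, seed = seed)
    list(design = des, model = mod, eval = evaluate_model(mod, des))
  }
  list(pic = one(cohort[cohort$cancer_type %in% pic_cancers, ]),
       all = one(cohort))
}
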