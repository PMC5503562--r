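#' Counts-per-million normalization
#'
#' Scales each sample's raw counts to sum to one million; used for
#' cross-cancer and cross-tissue proliferative-index comparisons.
#'
#' @param expr an `expr_mat` with raw counts.
#' @return an `expr_mat` with normalization `"cpm"`.
#' @export
cpm_normalize <- function(expr) {
  stopifnot(inherits(expr, "expr_mat"))
  if (expr$normalization != "raw_counts")
    stop("cpm_normalize expects raw counts, got ", expr$normalization)
  tot <- colSums(expr$values)
  if (any(tot == 0))
    stop("zero-total sample(s): ",
         paste(colnames(expr$values)[tot == 0], collapse = ", "))
  out <- sweep(expr$values, 2, tot, "/") * 1e6
  expression_matrix(out, "cpm")
}

#' Variance-stabilizing transformation of raw counts
#'
#' Median-of-ratios size factors (computed over genes with all-positive
#' counts, relative to the gene-wise geometric mean) followed by
#' log2(count / size_factor + 1). Monotone per sample and approximately
#' variance-stabilizing for negative-binomial counts at moderate means; used
#' for all intra-cancer analyses. When no gene has all-positive counts the
#' size factors fall back to relative library sizes, with a warning. An
#' externally computed transformed table can be substituted via
#' `expression_matrix(values, "vst")`.
#'
#' @param expr an `expr_mat` with raw counts and at least 2 samples.
#' @return an `expr_mat` with normalization `"vst"`; size factors are kept
#'   in the `size_factors` element.
#' @export
vst_normalize <- function(expr) {
  stopifnot(inherits(expr, "expr_mat"))
  if (expr$normalization != "raw_counts")
    stop("vst_normalize expects raw counts, got ", expr$normalization)
  v <- expr$values
  if (ncol(v) < 2L) stop("vst_normalize needs at least 2 samples")
  pos <- rowSums(v > 0) == ncol(v)
  if (!any(pos)) {
    warning("no gene with all-positive counts; using library-size factors")
    sf <- colSums(v) / exp(mean(log(colSums(v))))
  } else {
    lgm <- rowMeans(log(v[pos, , drop = FALSE]))
    sf <- apply(log(v[pos, , drop = FALSE]) - lgm, 2,
                function(lr) exp(stats::median(lr)))
  }
  out <- log2(sweep(v, 2, sf, "/") + 1)
  res <- expression_matrix(out, "vst")
  res$size_factors <- sf
  res
}

#' Compute the proliferative index
#'
#' Per-sample median of the normalized expression of a proliferation gene
#' set (by default the 131-gene PCNA meta-gene signature of Venet et al.).
#' Set genes absent from the matrix are dropped (the median is robust to set
#' shrinkage); the number actually used is recorded.
#'
#' @param expr an `expr_mat`, normalization `"cpm"` or `"vst"`.
#' @param genes a gene set as from [read_gene_set()] (list with `name`,
#'   `genes`) or a character vector of symbols.
#' @return object of class `pi_index`: named numeric `pi` per sample plus
#'   `normalization`, `gene_set`, `n_genes_used`.
#' @export
compute_pi <- function(expr, genes) {
  stopifnot(inherits(expr, "expr_mat"))
  if (!expr$normalization %in% c("cpm", "vst"))
    stop("compute_pi expects cpm or vst normalized expression, got ",
         expr$normalization)
  if (is.character(genes)) genes <- list(name = "custom", genes = genes)
  present <- intersect(genes$genes, rownames(expr$values))
  if (length(present) == 0L)
    stop("no gene-set gene found in the matrix; first missing: ",
         paste(utils::head(genes$genes, 5), collapse = ", "))
  sub <- expr$values[present, , drop = FALSE]
  pi_vals <- apply(sub, 2, stats::median)
  structure(list(pi = pi_vals,
                 sample_ids = colnames(expr$values),
                 normalization = expr$normalization,
                 gene_set = genes$name,
                 n_genes_used = length(present)),
            class = "pi_index")
}

#' @export
print.pi_index <- function(x, ...) {
  cat(sprintf("proliferative index: %d samples, %d '%s' genes used [%s]\n",
              length(x$pi), x$n_genes_used, x$gene_set, x$normalization))
  print(summary(unname(x$pi)))
  invisible(x)
}

# accept a pi_index or a named numeric vector
as_pi_values <- function(pi) {
  if (inherits(pi, "pi_index")) pi$pi else pi
}

#' Compare PI between two sample groups
#'
#' Two-sided Wilcoxon rank-sum test of PI between groups `a` and `b`
#' (tumor vs adjacent normal, T1 vs T4 stage, and so on). The exact null is
#' used for combined n <= 20 without ties, the normal approximation with
#' continuity correction otherwise.
#'
#' @param pi a `pi_index` or named numeric vector.
#' @param labels categorical label per sample (same order as pi values).
#' @param a,b the two label values to compare.
#' @return list of class `pi_comparison`: W statistic, p_value, group
#'   medians and sizes.
#' @export
compare_pi_groups <- function(pi, labels, a, b) {
  v <- as_pi_values(pi)
  stopifnot(length(labels) == length(v))
  xa <- v[!is.na(labels) & labels == a]
  xb <- v[!is.na(labels) & labels == b]
  if (length(xa) == 0L || length(xb) == 0L)
    stop("empty group: ", if (length(xa) == 0L) a else b)
  exact <- (length(xa) + length(xb) <= 20) && !anyDuplicated(c(xa, xb))
  wt <- stats::wilcox.test(xa, xb, alternative = "two.sided",
                           exact = exact, correct = TRUE)
  structure(list(group_a = a, group_b = b,
                 W = unname(wt$statistic), p_value = wt$p.value,
                 median_a = stats::median(xa), median_b = stats::median(xb),
                 n_a = length(xa), n_b = length(xb)),
            class = "pi_comparison")
}

#' @export
print.pi_comparison <- function(x, ...) {
  cat(sprintf("Wilcoxon %s (n=%d, median %.3g) vs %s (n=%d, median %.3g): W = %g, p = %.3g\n",
              x$group_a, x$n_a, x$median_a, x$group_b, x$n_b, x$median_b,
              x$W, x$p_value))
  invisible(x)
}

#' Correlation between principal components and PI
#'
#' PCA of the samples (genes centered across samples) followed by the
#' Spearman correlation of each of the first k component scores with the
#' proliferative index — the check that a large share of transcriptome
#' variance tracks proliferation.
#'
#' @param expr a VST `expr_mat`.
#' @param pi a `pi_index` or numeric vector aligned with the samples.
#' @param k number of leading components (default 5).
#' @return list with `rho` (length k), `scores` (samples x k) and
#'   `var_explained`.
#' @export
pc_pi_correlation <- function(expr, pi, k = 5) {
  stopifnot(inherits(expr, "expr_mat"))
  if (expr$normalization != "vst")
    stop("pc_pi_correlation expects vst normalization")
  v <- as_pi_values(pi)
  m <- t(expr$values)                 # samples x genes
  if (all(apply(m, 2, stats::sd) == 0)) stop("constant matrix: no variance")
  k <- min(k, nrow(m) - 1L, ncol(m))
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = k)
  rho <- apply(pc$x[, seq_len(k), drop = FALSE], 2, function(s)
    stats::cor(s, v, method = "spearman"))
  list(rho = rho,
       scores = pc$x[, seq_len(k), drop = FALSE],
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}

#' Spearman correlation of PI with a per-sample covariate
#'
#' Used for tumor purity, mutation burden and similar per-sample metrics.
#' Ties are handled with average ranks; a constant covariate yields a
#' missing rho with a warning.
#'
#' @param pi a `pi_index` or numeric vector.
#' @param covariate numeric vector aligned with pi.
#' @return list with `rho`, `p_value`, `n`.
#' @export
correlate_pi_covariate <- function(pi, covariate) {
  v <- as_pi_values(pi)
  ok <- !is.na(v) & !is.na(covariate)
  if (sum(ok) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(covariate[ok]) == 0) {
    warning("constant covariate: rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = sum(ok)))
  }
  ct <- suppressWarnings(
    stats::cor.test(v[ok], covariate[ok], method = "spearman",
                    alternative = "two.sided", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
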