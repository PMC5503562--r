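#' Correlate PI with somatic mutation burden
#'
#' Burden is log10 of each patient's total mutation count over all variant
#' classes, with a +1 pseudocount so zero-mutation patients are retained at
#' the bottom of the ranking (Spearman depends only on ranks). Computed
#' pooled over all patients and/or within each cancer.
#'
#' @param pi a `pi_index` or named numeric vector keyed by sample id.
#' @param catalog mutation catalog data.frame.
#' @param cohort cohort data.frame (sample_id, cancer_type).
#' @param scope "pooled", "per_cancer", or "both".
#' @return list with `pooled` (rho, p_value, n) and/or `per_cancer`
#'   data.frame.
#' @export
mutation_burden_correlation <- function(pi, catalog, cohort,
                                        scope = c("both", "pooled",
                                                  "per_cancer")) {
  scope <- match.arg(scope)
  v <- as_pi_values(pi)
  if (inherits(pi, "pi_index")) names(v) <- pi$sample_ids
  counts <- table(factor(catalog$sample_id, levels = cohort$sample_id))
  ids <- intersect(cohort$sample_id, names(v))
  if (length(ids) < 3L) stop("no overlapping patients with PI and mutations")
  burden <- log10(as.numeric(counts[ids]) + 1)
  piv <- v[ids]
  out <- list()
  if (scope %in% c("both", "pooled"))
    out$pooled <- correlate_pi_covariate(piv, burden)
  if (scope %in% c("both", "per_cancer")) {
    cc_of <- cohort$cancer_type[match(ids, cohort$sample_id)]
    out$per_cancer <- do.call(rbind, lapply(unique(cc_of), function(cc) {
      ix <- cc_of == cc
      if (sum(ix) < 3L) return(NULL)
      r <- correlate_pi_covariate(piv[ix], burden[ix])
      data.frame(cancer = cc, rho = r$rho, p_value = r$p_value, n = r$n,
                 stringsAsFactors = FALSE)
    }))
  }
  out
}

#' Per-gene mutation vs PI scan
#'
#' For each cancer and gene: group A = samples carrying at least one
#' missense or nonsense mutation in the gene, group B = samples with only
#' synonymous or no mutation in the gene (samples whose only mutations in
#' the gene are of class "other" are excluded from both groups); a two-sided
#' Wilcoxon test of PI between groups. Genes with fewer than `min_mutated`
#' qualifying mutated samples in a cancer are skipped there; cancers with
#' fewer than `min_genes` eligible genes are skipped entirely. Per-cancer
#' p-values are combined per gene across contributing cancers with Fisher's
#' method and Benjamini-Hochberg adjusted across genes.
#'
#' @param pi_by_cancer named list of `pi_index` (or named numeric) per
#'   cancer.
#' @param catalog mutation catalog.
#' @param cohort cohort data.frame.
#' @param min_mutated qualifying mutated samples required per cancer (5).
#' @param min_genes eligible genes required for a cancer to be analyzed
#'   (100).
#' @param min_cancers cancers a gene must be eligible in to be combined (2).
#' @return list with `per_cancer` (gene, cancer, p, direction, n_mut,
#'   n_wt) and `combined` (gene, chisq, df, p_value, q_value, n_cancers),
#'   plus `skipped_cancers`.
#' @export
gene_mutation_scan <- function(pi_by_cancer, catalog, cohort,
                               min_mutated = 5, min_genes = 100,
                               min_cancers = 2) {
  qual <- catalog[catalog$variant_class %in% c("missense", "nonsense"), ]
  syn <- catalog[catalog$variant_class == "synonymous", ]
  other <- catalog[catalog$variant_class == "other", ]
  per <- list(); skipped <- character()
  for (cc in names(pi_by_cancer)) {
    ids <- cohort$sample_id[cohort$cancer_type == cc]
    v <- as_pi_values(pi_by_cancer[[cc]])
    if (inherits(pi_by_cancer[[cc]], "pi_index"))
      names(v) <- pi_by_cancer[[cc]]$sample_ids
    v <- v[intersect(ids, names(v))]
    qcc <- qual[qual$sample_id %in% names(v), ]
    tab <- table(qcc$gene, qcc$sample_id)
    mut_samples <- lapply(rownames(tab), function(g)
      colnames(tab)[tab[g, ] > 0])
    names(mut_samples) <- rownames(tab)
    eligible <- names(mut_samples)[vapply(mut_samples, length,
                                          integer(1)) >= min_mutated]
    if (length(eligible) < min_genes) {
      skipped <- c(skipped, cc)
      next
    }
    occ <- other[other$sample_id %in% names(v), ]
    scc <- syn[syn$sample_id %in% names(v), ]
    res <- lapply(eligible, function(g) {
      ga <- mut_samples[[g]]
      # exclusions: samples whose only mutations in g are class "other"
      oth_only <- setdiff(occ$sample_id[occ$gene == g],
                          c(ga, scc$sample_id[scc$gene == g]))
      gb <- setdiff(names(v), c(ga, oth_only))
      if (length(gb) < 2L) return(NULL)
      wt <- stats::wilcox.test(v[ga], v[gb], alternative = "two.sided",
                               exact = FALSE, correct = TRUE)
      data.frame(gene = g, cancer = cc, p_value = wt$p.value,
                 direction = sign(stats::median(v[ga]) -
                                    stats::median(v[gb])),
                 n_mut = length(ga), n_wt = length(gb),
                 stringsAsFactors = FALSE)
    })
    per[[cc]] <- do.call(rbind, res)
  }
  per_cancer <- do.call(rbind, per)
  if (is.null(per_cancer))
    return(list(per_cancer = NULL, combined = NULL,
                skipped_cancers = skipped))
  rownames(per_cancer) <- NULL
  counts <- table(per_cancer$gene)
  comb_genes <- names(counts)[counts >= min_cancers]
  combined <- do.call(rbind, lapply(comb_genes, function(g) {
    ps <- per_cancer$p_value[per_cancer$gene == g]
    fc <- if (length(ps) == 1L)
      list(chisq = -2 * log(ps), df = 2L, p_value = ps)
    else fisher_combine(ps)
    data.frame(gene = g, chisq = fc$chisq, df = fc$df, p_value = fc$p_value,
               n_cancers = length(ps), stringsAsFactors = FALSE)
  }))
  if (!is.null(combined)) {
    combined$q_value <- fdr_adjust(combined$p_value)
    combined <- combined[order(combined$p_value), ]
    rownames(combined) <- NULL
  }
  list(per_cancer = per_cancer, combined = combined,
       skipped_cancers = skipped)
}

#' Fisher's combined p-value
#'
#' chi-square = -2 sum(ln p_i), referred to the upper tail of a chi-square
#' distribution with 2k degrees of freedom.
#'
#' @param p_values vector of at least 2 p-values in (0, 1].
#' @return list with `chisq`, `df`, `p_value`.
#' @export
fisher_combine <- function(p_values) {
  if (length(p_values) < 2L) stop("need at least 2 p-values")
  if (any(p_values <= 0)) stop("p-value of 0: log undefined")
  if (any(p_values > 1)) stop("p-values must be in (0, 1]")
  chisq <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg q-values
#' @param p_values vector of p-values in [0, 1].
#' @return step-up adjusted q-values.
#' @export
fdr_adjust <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Correlate cell-line PI with drug EC50
#'
#' Line-level PI is the median normalized expression over all probes mapping
#' to PI genes; each drug's EC50 values are correlated with PI by Spearman
#' rank correlation, BH-adjusted across drugs. A negative rho means
#' higher-proliferating lines are more sensitive (lower EC50). Drugs with
#' fewer than `min_lines` lines carrying both measurements are skipped.
#'
#' @param panel drug panel as from [simulate_drug_panels()]: `expression`
#'   (probes x lines), `probe_map` (probe, gene), `ec50` (lines x drugs).
#' @param genes PI gene set (list or character).
#' @param min_lines minimum lines per drug (10).
#' @return data.frame: drug, rho, p_value, q_value, n.
#' @export
drug_ec50_correlation <- function(panel, genes, min_lines = 10) {
  if (is.list(genes) && !is.null(genes$genes)) genes <- genes$genes
  probes <- panel$probe_map$probe[panel$probe_map$gene %in% genes]
  probes <- intersect(probes, rownames(panel$expression))
  if (length(probes) == 0L) stop("no PI probe mapped in the panel")
  pi_line <- apply(panel$expression[probes, , drop = FALSE], 2,
                   stats::median)
  lines <- intersect(names(pi_line), rownames(panel$ec50))
  rows <- lapply(colnames(panel$ec50), function(dr) {
    e <- panel$ec50[lines, dr]
    ok <- !is.na(e)
    if (sum(ok) < min_lines) {
      warning("drug ", dr, " below line threshold; skipped")
      return(NULL)
    }
    ct <- suppressWarnings(stats::cor.test(pi_line[lines][ok], e[ok],
                                           method = "spearman",
                                           exact = FALSE))
    data.frame(drug = dr, rho = unname(ct$estimate), p_value = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no drug passed the line threshold")
  out$q_value <- fdr_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Rank treatments by their effect on PI-gene expression
#'
#' For each treatment of a probe x treatment rank matrix (rank 1 = strongest
#' up-regulation), the median rank over all probes mapping to PI genes is
#' computed; each treatment is then scored by the fraction of treatments
#' with a numerically larger (i.e. more down-regulated) median PI rank.
#' Proliferation-activating treatments therefore score near 1 (top of the
#' list) and anti-proliferative treatments near 0 (bottom decile).
#'
#' @param rank_matrix list with `ranks` (probes x treatments integer
#'   matrix, each column a permutation of 1..P) and `probe_map`.
#' @param genes PI gene set.
#' @return data.frame: treatment, median_rank, percentile, ordered by
#'   percentile (strongest PI up-regulation first).
#' @export
cmap_pi_rank <- function(rank_matrix, genes) {
  if (is.list(genes) && !is.null(genes$genes)) genes <- genes$genes
  probes <- rank_matrix$probe_map$probe[rank_matrix$probe_map$gene %in% genes]
  probes <- intersect(probes, rownames(rank_matrix$ranks))
  if (length(probes) == 0L) stop("no PI probe mapped in the rank matrix")
  med <- apply(rank_matrix$ranks[probes, , drop = FALSE], 2, stats::median)
  pct <- vapply(med, function(m) mean(med > m), numeric(1))
  out <- data.frame(treatment = colnames(rank_matrix$ranks),
                    median_rank = unname(med), percentile = unname(pct),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$percentile), ]
  rownames(out) <- NULL
  out
}

#' Kolmogorov-Smirnov comparison of two treatments' PI-probe ranks
#'
#' @param rank_matrix as in [cmap_pi_rank()].
#' @param genes PI gene set.
#' @param treatment_a,treatment_b column names to compare.
#' @return list with `statistic`, `p_value`.
#' @export
compare_treatment_ranks <- function(rank_matrix, genes, treatment_a,
                                    treatment_b) {
  if (is.list(genes) && !is.null(genes$genes)) genes <- genes$genes
  probes <- rank_matrix$probe_map$probe[rank_matrix$probe_map$gene %in% genes]
  probes <- intersect(probes, rownames(rank_matrix$ranks))
  if (length(probes) == 0L) stop("no PI probe mapped in the rank matrix")
  a <- rank_matrix$ranks[probes, treatment_a]
  b <- rank_matrix$ranks[probes, treatment_b]
  ks <- suppressWarnings(stats::ks.test(a, b))
  list(statistic = unname(ks$statistic), p_value = ks$p.value)
}
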