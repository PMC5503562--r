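#' Construct an expression matrix object
#'
#' Light container for a genes x samples numeric matrix plus its
#' normalization state (`raw_counts`, `cpm`, `vst` or `scaled`).
#'
#' @param values numeric matrix with gene symbols as rownames and sample ids
#'   as colnames.
#' @param normalization one of `"raw_counts"`, `"cpm"`, `"vst"`, `"scaled"`.
#' @return an object of class `expr_mat`.
#' @export
expression_matrix <- function(values, normalization = "raw_counts") {
  normalization <- match.arg(normalization,
                             c("raw_counts", "cpm", "vst", "scaled"))
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids; collapse before constructing")
  if (normalization == "raw_counts" && any(values < 0))
    stop("raw counts must be non-negative")
  structure(list(values = values, normalization = normalization),
            class = "expr_mat")
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$normalization))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Read a genes x samples expression TSV
#'
#' Expects a header row of sample ids and gene symbols in the first column
#' (TCGA Level 3 style; composite "symbol|entrez" ids are split on "|" and
#' the symbol kept). Duplicate gene rows are collapsed.
#'
#' @param path TSV file path.
#' @param collapse how to collapse duplicate gene rows: `"sum"` (default,
#'   counts are additive over features), `"mean"` or `"max"`.
#' @return an `expr_mat` with normalization `"raw_counts"`.
#' @export
read_expression <- function(path, collapse = c("sum", "mean", "max")) {
  collapse <- match.arg(collapse)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("format error: empty or single-column expression file: ", path)
  genes <- sub("\\|.*$", "", df[[1]])
  num <- df[, -1, drop = FALSE]
  samples <- colnames(num)
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(num)), nrow = nrow(num))
  )
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("parse error: non-numeric value at gene '%s', sample '%s'",
                 genes[bad[1]], samples[bad[2]]))
  }
  if (anyDuplicated(genes)) {
    if (collapse == "sum") {
      vals <- rowsum(vals, group = genes, reorder = FALSE)
    } else {
      fun <- if (collapse == "mean") colMeans else function(m) apply(m, 2, max)
      idx <- split(seq_along(genes), factor(genes, levels = unique(genes)))
      vals <- do.call(rbind, lapply(idx, function(ix) fun(vals[ix, , drop = FALSE])))
    }
    genes <- unique(genes)
  }
  dimnames(vals) <- list(genes, samples)
  expression_matrix(vals, "raw_counts")
}

#' Write an expression matrix to TSV
#' @param expr an `expr_mat`.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# leading T/N/M stage number, "T1a" -> "T1"; anything unparseable -> NA
normalize_stage <- function(x, prefix) {
  out <- rep(NA_character_, length(x))
  hit <- grepl(paste0("^", prefix, "[0-4]"), x)
  out[hit] <- substr(x[hit], 1, 2)
  out
}

#' Read a per-patient clinical table
#'
#' Requires columns `sample_id`, `cancer_type`, `survival_days`, `event`.
#' When the raw TCGA-style columns `days_to_death` / `days_to_last_followup`
#' are present instead of `survival_days`, survival is their per-patient
#' maximum. Pathologic stage strings are reduced to the whole-stage ordinal
#' (e.g. "T1a" to "T1"); missing stages stay missing.
#'
#' @param path TSV file path.
#' @return a data.frame cohort table.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  req <- c("sample_id", "cancer_type")
  if (!all(req %in% colnames(df)))
    stop("missing required columns: ", paste(setdiff(req, colnames(df)), collapse = ", "))
  if (!"survival_days" %in% colnames(df)) {
    if (!all(c("days_to_death", "days_to_last_followup") %in% colnames(df)))
      stop("need survival_days or days_to_death + days_to_last_followup")
    df$survival_days <- pmax(
      suppressWarnings(as.numeric(df$days_to_death)),
      suppressWarnings(as.numeric(df$days_to_last_followup)), na.rm = TRUE)
  }
  df$survival_days <- as.numeric(df$survival_days)
  if (any(is.na(df$survival_days)))
    stop("validation error: missing/non-numeric survival_days")
  if (any(df$survival_days < 0))
    stop("validation error: negative survival_days")
  if (any(df$survival_days == 0))
    warning("survival_days of 0 present (flagged, retained)")
  ev <- df$event
  ev_map <- c("0" = FALSE, "1" = TRUE, "FALSE" = FALSE, "TRUE" = TRUE)
  ev_chr <- toupper(as.character(ev))
  if (!all(ev_chr %in% names(ev_map)))
    stop("validation error: unknown event code(s): ",
         paste(unique(ev_chr[!ev_chr %in% names(ev_map)]), collapse = ", "))
  df$event <- unname(ev_map[ev_chr])
  for (s in c("T", "N", "M")) {
    col <- paste0("stage_", s)
    if (col %in% colnames(df)) df[[col]] <- normalize_stage(df[[col]], s)
  }
  dup <- duplicated(df[, c("cancer_type", "sample_id")])
  if (any(dup))
    stop("validation error: duplicate sample_id within a cancer")
  df
}

#' Write a cohort table to TSV
#' @param cohort cohort data.frame.
#' @param path output path.
#' @export
write_clinical <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Restrict a cohort to adequately powered cancers
#'
#' Keeps only cancer types with at least `min_patients` patients of whom at
#' least `min_deaths` died (observed events), the study inclusion rule
#' (defaults 50 and 25).
#'
#' @param cohort cohort data.frame.
#' @param min_patients minimum cohort size (default 50).
#' @param min_deaths minimum observed deaths (default 25).
#' @return the filtered cohort (possibly zero rows, with a warning).
#' @export
filter_cohorts <- function(cohort, min_patients = 50, min_deaths = 25) {
  stopifnot(min_patients > 0, min_deaths > 0)
  n <- table(cohort$cancer_type)
  d <- tapply(cohort$event, cohort$cancer_type, sum)
  keep <- names(n)[n >= min_patients & d[names(n)] >= min_deaths]
  out <- cohort[cohort$cancer_type %in% keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no cancer type meets the inclusion thresholds")
  rownames(out) <- NULL
  out
}

#' Read a gene set (one symbol per line)
#' @param path file path.
#' @param name set name (default: file base name).
#' @return list with `name` and `genes`.
#' @export
read_gene_set <- function(path, name = NULL) {
  genes <- readLines(path)
  genes <- trimws(genes)
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop("empty gene set: ", path)
  genes <- unique(genes)
  list(name = if (is.null(name)) sub("\\.[^.]*$", "", basename(path)) else name,
       genes = genes)
}

# MAF variant-classification vocabulary -> closed class set
variant_class_map <- c(
  Missense_Mutation = "missense",
  Nonsense_Mutation = "nonsense",
  Silent = "synonymous",
  Synonymous = "synonymous"
)

#' Read a MAF-like somatic mutation table
#'
#' Requires columns `sample_id`, `gene` and a variant classification column
#' (`variant_class` or MAF `Variant_Classification`). Classifications are
#' mapped onto {missense, nonsense, synonymous, other}; anything outside the
#' vocabulary becomes "other" with a warning.
#'
#' @param path TSV file path.
#' @return data.frame with sample_id, gene, variant_class.
#' @export
read_mutations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  vc_col <- intersect(c("variant_class", "Variant_Classification"),
                      colnames(df))[1]
  if (is.na(vc_col) || !all(c("sample_id", "gene") %in% colnames(df)))
    stop("mutation table needs sample_id, gene and a variant classification column")
  vc <- variant_class_map[df[[vc_col]]]
  unmapped <- is.na(vc) & tolower(df[[vc_col]]) %in%
    c("missense", "nonsense", "synonymous", "other")
  vc[unmapped] <- tolower(df[[vc_col]][unmapped])
  if (anyNA(vc)) {
    warning(sprintf("%d mutation(s) with unmapped classification recorded as 'other' (e.g. %s)",
                    sum(is.na(vc)), df[[vc_col]][which(is.na(vc))[1]]))
    vc[is.na(vc)] <- "other"
  }
  data.frame(sample_id = df$sample_id, gene = df$gene,
             variant_class = unname(vc), stringsAsFactors = FALSE)
}

#' Run configuration
#'
#' Bundles the inclusion thresholds, significance levels, permutation count
#' and seed used across a pipeline run; [write_manifest()] records them next
#' to every set of outputs.
#'
#' @param min_patients,min_deaths cohort inclusion thresholds (50 / 25).
#' @param alpha per-test significance threshold (0.05).
#' @param min_cancers cancers a transcript must be significant in to count
#'   as shared (9).
#' @param n_permutations random cancer-set draws for the null (1000).
#' @param seed integer RNG seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(min_patients = 50, min_deaths = 25, alpha = 0.05,
                       min_cancers = 9, n_permutations = 1000, seed = 1L) {
  cfg <- list(min_patients = min_patients, min_deaths = min_deaths,
              alpha = alpha, min_cancers = min_cancers,
              n_permutations = n_permutations, seed = as.integer(seed))
  num <- unlist(cfg[c("min_patients", "min_deaths", "alpha",
                      "min_cancers", "n_permutations")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all thresholds must be positive")
  class(cfg) <- "run_config"
  cfg
}

#' Write a run manifest
#' @param cfg a `run_config`.
#' @param path output file.
#' @param inputs named character vector of input file paths.
#' @export
write_manifest <- function(cfg, path, inputs = character()) {
  lines <- c(
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste0("r_version: ", R.version.string),
    paste0("seed: ", cfg$seed),
    paste0("min_patients: ", cfg$min_patients),
    paste0("min_deaths: ", cfg$min_deaths),
    paste0("alpha: ", cfg$alpha),
    paste0("min_cancers: ", cfg$min_cancers),
    paste0("n_permutations: ", cfg$n_permutations),
    if (length(inputs)) paste0("input_", names(inputs), ": ", inputs)
  )
  writeLines(lines, path)
  invisible(path)
}
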