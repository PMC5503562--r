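# Small fixtures shared across test files; everything is generated in code.

# a compact simulation config for fast module tests
small_sim_config <- function(seed = 1L, ...) {
  args <- list(n_cancers = 4, n_pics = 2, n_patients = 60, n_genes = 60,
               pi_set_size = 10, sf_set_size = 10, n_drivers = 2,
               n_lines = 60, n_probes = 100, n_treatments = 12,
               n_antiprolif = 2, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# write a genes x samples TSV and return its path
write_expr_tsv <- function(mat, genes = rownames(mat),
                           samples = colnames(mat)) {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(gene = genes, mat, check.names = FALSE)
  colnames(df) <- c("gene", samples)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# toy raw-count expression object
toy_expr <- function(values, normalization = "raw_counts") {
  expression_matrix(values, normalization)
}

# brute-force Efron/exact partial likelihood for untied, uncensored data:
# direct product over ordered deaths (oracle, independent of the package's
# Newton path)
brute_partial_loglik <- function(beta, time, x) {
  ord <- order(time)
  x <- x[ord]
  n <- length(x)
  ll <- 0
  for (i in seq_len(n)) {
    risk <- i:n
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

brute_cox_coef <- function(time, x, lower = -15, upper = 15) {
  opt <- optimize(function(b) brute_partial_loglik(b, time, x),
                  interval = c(lower, upper), maximum = TRUE,
                  tol = 1e-10)
  opt$maximum
}
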