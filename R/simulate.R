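#' Simulation configuration
#'
#' Defines the multi-cancer generative model: negative-binomial RNA-seq
#' counts driven by a latent per-patient proliferation score z, exponential
#' survival whose hazard depends on z only in the planted
#' proliferation-informative cancers (PICs), a second latent factor w that
#' drives survival in the remaining cancers through a disjoint gene block
#' partitioned into cancer-specific sub-blocks (so each non-PIC's survival
#' transcripts are unique to it and carry no cross-cancer signal), plus
#' stage, mutation-burden and drug-response couplings to z.
#'
#' @param n_cancers number of cancer types (19).
#' @param n_pics number of planted PICs (7).
#' @param n_patients patients per cancer (150).
#' @param n_genes total genes (1000).
#' @param pi_set_size proliferation gene-set size (131).
#' @param sf_set_size second-factor gene-block size (100).
#' @param beta_range loadings of PI genes on z, drawn uniformly (0.5..1).
#' @param gamma log-hazard per unit z in PICs (0.8).
#' @param gamma2 log-hazard per unit w in non-PICs (0.8).
#' @param mu_sd SD of per-cancer baseline PI shifts (0.5).
#' @param baseline_hazard exponential event rate per day (1/1000).
#' @param censoring target censoring fraction (0.4).
#' @param mutation_intercept log mean somatic mutations per patient (log 50).
#' @param mutation_slope b in log E[mutations] = a + b z (0.5).
#' @param n_drivers planted driver genes (3).
#' @param driver_slope logistic slope of driver mutation on z (2).
#' @param driver_intercept logistic intercept (-2).
#' @param n_lines cell lines in the drug panel (200).
#' @param n_drugs drugs with EC50s (24).
#' @param n_targeting proliferation-targeting drugs with tau > 0 (4).
#' @param tau EC50 slope on line-level z for targeting drugs (1).
#' @param n_probes probes in the treatment rank matrix (1000).
#' @param n_treatments treatments (50).
#' @param n_antiprolif planted anti-proliferative treatments (5).
#' @param seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cancers = 19, n_pics = 7, n_patients = 150,
                       n_genes = 1000, pi_set_size = 131, sf_set_size = 100,
                       beta_range = c(0.5, 1), gamma = 0.8, gamma2 = 0.8,
                       mu_sd = 0.5, baseline_hazard = 1 / 1000,
                       censoring = 0.4,
                       mutation_intercept = log(50), mutation_slope = 0.5,
                       n_drivers = 3, driver_slope = 2, driver_intercept = -2,
                       n_lines = 200, n_drugs = 24, n_targeting = 4, tau = 1,
                       n_probes = 1000, n_treatments = 50, n_antiprolif = 5,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_pics > cfg$n_cancers) stop("n_pics must be <= n_cancers")
  counts <- unlist(cfg[c("n_cancers", "n_pics", "n_patients", "n_genes",
                         "pi_set_size", "sf_set_size", "n_lines", "n_drugs",
                         "n_probes", "n_treatments")])
  if (any(counts <= 0)) stop("all counts must be positive")
  if (cfg$pi_set_size + cfg$sf_set_size + cfg$n_drivers > cfg$n_genes)
    stop("gene blocks exceed n_genes")
  if (cfg$censoring < 0 || cfg$censoring >= 1)
    stop("censoring must be in [0, 1)")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

# gene naming: PI block, second-factor block, planted drivers, background
sim_gene_names <- function(cfg) {
  c(sprintf("PIG%03d", seq_len(cfg$pi_set_size)),
    sprintf("SFG%03d", seq_len(cfg$sf_set_size)),
    sprintf("DRV%03d", seq_len(cfg$n_drivers)),
    sprintf("BGG%04d", seq_len(cfg$n_genes - cfg$pi_set_size -
                                 cfg$sf_set_size - cfg$n_drivers)))
}

#' Simulate a multi-cancer expression + clinical cohort
#'
#' Draws, for each cancer c and patient i, a latent proliferation score
#' z_i ~ Normal(mu_c, 1) and a second factor w_i ~ Normal(0, 1); counts for
#' gene g are negative binomial with mean s_i * q_g * exp(beta_g z_i +
#' lambda_g w_i [g in the cancer's own second-factor sub-block]) and
#' gene-wise dispersion. beta_g > 0 on the PI block and zero elsewhere; the
#' disjoint second-factor block is partitioned into cancer-specific
#' sub-blocks so that each non-PIC carries its own survival-associated
#' genes (survival patterns unique to each non-PIC, with no transcript
#' block shared across them). Survival is exponential with hazard
#' h0 * exp(gamma_c z_i) in planted PICs and h0 * exp(gamma2_c w_i)
#' otherwise, with independent exponential censoring at the configured
#' rate. Pathologic T stage follows z (plus noise) in PICs and is
#' independent of z in non-PICs. Fully deterministic given the config seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `expr` (raw-count `expr_mat`), `clinical` (cohort
#'   data.frame), `truth` (planted parameters: per-patient z/w, per-cancer
#'   PIC flags and hazard coefficients, per-gene loadings) and `pi_genes`
#'   (the designated PI gene set).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genes <- sim_gene_names(cfg)
  G <- cfg$n_genes
  pi_idx <- seq_len(cfg$pi_set_size)
  sf_idx <- cfg$pi_set_size + seq_len(cfg$sf_set_size)

  beta <- numeric(G)
  beta[pi_idx] <- stats::runif(cfg$pi_set_size, cfg$beta_range[1],
                               cfg$beta_range[2])
  lambda <- numeric(G)
  lambda[sf_idx] <- stats::runif(cfg$sf_set_size, cfg$beta_range[1],
                                 cfg$beta_range[2])
  q <- stats::rlnorm(G, meanlog = log(50), sdlog = 1)
  disp <- stats::runif(G, 0.05, 0.5)
  size <- 1 / disp

  cancers <- sprintf("CANCER%02d", seq_len(cfg$n_cancers))
  is_pic <- seq_len(cfg$n_cancers) <= cfg$n_pics
  mu_c <- stats::rnorm(cfg$n_cancers, 0, cfg$mu_sd)
  gamma_c <- ifelse(is_pic, cfg$gamma, 0)
  gamma2_c <- ifelse(is_pic, 0, cfg$gamma2)

  # each non-PIC owns a disjoint sub-block of the second-factor genes, so
  # its survival-associated transcripts are unique to it
  non_pics <- cancers[!is_pic]
  sf_cancer <- rep(NA_character_, G)
  if (length(non_pics) > 0)
    sf_cancer[sf_idx] <- rep(non_pics, length.out = cfg$sf_set_size)

  n_tot <- cfg$n_cancers * cfg$n_patients
  cancer_of <- rep(cancers, each = cfg$n_patients)
  sample_id <- sprintf("%s_S%03d", cancer_of,
                       rep(seq_len(cfg$n_patients), cfg$n_cancers))
  z <- stats::rnorm(n_tot, rep(mu_c, each = cfg$n_patients), 1)
  w <- stats::rnorm(n_tot, 0, 1)
  s <- stats::rlnorm(n_tot, 0, 0.25)

  # counts: genes x samples; second-factor loadings apply only within the
  # sub-block's own cancer
  log_mu <- outer(beta, z) + log(q) +
    matrix(log(s), G, n_tot, byrow = TRUE)
  for (cc in non_pics) {
    gix <- which(!is.na(sf_cancer) & sf_cancer == cc)
    six <- which(cancer_of == cc)
    if (length(gix) && length(six))
      log_mu[gix, six] <- log_mu[gix, six] + outer(lambda[gix], w[six])
  }
  counts <- matrix(
    stats::rnbinom(G * n_tot, size = rep(size, n_tot), mu = exp(log_mu)),
    nrow = G, dimnames = list(genes, sample_id))

  # survival
  gam_z <- rep(gamma_c, each = cfg$n_patients)
  gam_w <- rep(gamma2_c, each = cfg$n_patients)
  haz <- cfg$baseline_hazard * exp(gam_z * z + gam_w * w)
  t_event <- stats::rexp(n_tot, rate = haz)
  if (cfg$censoring > 0) {
    c_rate <- cfg$baseline_hazard * cfg$censoring / (1 - cfg$censoring)
    t_cens <- stats::rexp(n_tot, rate = c_rate)
  } else {
    t_cens <- rep(Inf, n_tot)
  }
  event <- t_event <= t_cens
  days <- ceiling(pmin(t_event, t_cens))

  # pathologic T stage: follows z in PICs, pure noise in non-PICs
  stage_driver <- ifelse(rep(is_pic, each = cfg$n_patients),
                         z + stats::rnorm(n_tot), stats::rnorm(n_tot, 0, 1.5))
  stage_T <- paste0("T", findInterval(stage_driver, c(-1, 0, 1)) + 1)

  clinical <- data.frame(
    sample_id = sample_id, cancer_type = cancer_of,
    survival_days = as.numeric(days), event = event,
    stage_T = stage_T, stage_N = NA_character_, stage_M = NA_character_,
    stringsAsFactors = FALSE)

  truth <- list(
    patients = data.frame(sample_id = sample_id, cancer_type = cancer_of,
                          z = z, w = w, size_factor = s,
                          stringsAsFactors = FALSE),
    cancers = data.frame(cancer_type = cancers, is_pic = is_pic,
                         gamma = gamma_c, gamma2 = gamma2_c, mu = mu_c,
                         stringsAsFactors = FALSE),
    genes = data.frame(gene = genes, beta = beta, lambda = lambda,
                       sf_cancer = sf_cancer, q = q, dispersion = disp,
                       stringsAsFactors = FALSE),
    seed = cfg$seed)

  list(expr = expression_matrix(counts, "raw_counts"),
       clinical = clinical,
       truth = truth,
       pi_genes = list(name = "planted_pi", genes = genes[pi_idx]))
}

#' Simulate a somatic mutation catalog tied to the planted cohort
#'
#' Per-patient total mutation count is Poisson with log mean
#' `mutation_intercept + mutation_slope * z_i`. Planted driver genes carry a
#' missense/nonsense mutation with probability logistic in z; the remaining
#' count is scattered uniformly over the gene universe with class
#' frequencies missense .5, nonsense .1, synonymous .3, other .1.
#'
#' @param truth the `truth` element of [simulate_cohort()].
#' @param cohort the matching clinical table.
#' @param cfg the same [sim_config()].
#' @return data.frame mutation catalog (sample_id, gene, variant_class).
#' @export
simulate_mutations <- function(truth, cohort, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!setequal(truth$patients$sample_id, cohort$sample_id))
    stop("truth and cohort sample ids do not match")
  set.seed(cfg$seed + 1L)
  pts <- truth$patients
  n <- nrow(pts)
  genes <- truth$genes$gene
  drivers <- genes[grepl("^DRV", genes)]

  n_mut <- stats::rpois(n, exp(cfg$mutation_intercept +
                                 cfg$mutation_slope * pts$z))
  bg <- data.frame(
    sample_id = rep(pts$sample_id, n_mut),
    gene = sample(setdiff(genes, drivers), sum(n_mut), replace = TRUE),
    variant_class = sample(c("missense", "nonsense", "synonymous", "other"),
                           sum(n_mut), replace = TRUE,
                           prob = c(.5, .1, .3, .1)),
    stringsAsFactors = FALSE)

  drv <- do.call(rbind, lapply(drivers, function(g) {
    p <- stats::plogis(cfg$driver_intercept + cfg$driver_slope * pts$z)
    hit <- stats::runif(n) < p
    if (!any(hit)) return(NULL)
    data.frame(sample_id = pts$sample_id[hit], gene = g,
               variant_class = sample(c("missense", "nonsense"),
                                      sum(hit), replace = TRUE,
                                      prob = c(.8, .2)),
               stringsAsFactors = FALSE)
  }))
  out <- rbind(bg, drv)
  rownames(out) <- NULL
  out
}

#' Simulate a drug-response panel and a treatment rank matrix
#'
#' Cell lines carry a proliferation surrogate z_l; line expression for the
#' planted gene blocks follows the same loadings on a normalized
#' (microarray-like) scale with two probes per gene. For
#' proliferation-targeting drugs log EC50 = kappa - tau * z_l + noise
#' (higher-proliferating lines are more sensitive); other drugs have tau = 0.
#' The rank matrix ranks per-treatment differential-expression scores
#' (rank 1 = strongest up-regulation); planted anti-proliferative treatments
#' shift PI probes strongly down, pushing their ranks toward the bottom.
#'
#' @param truth the `truth` element of [simulate_cohort()] (for loadings).
#' @param cfg the same [sim_config()].
#' @return list with `panel` (elements `expression` probes x lines,
#'   `probe_map`, `ec50` lines x drugs, `z` line scores, `targeting_drugs`)
#'   and `rank_matrix` (elements `ranks` probes x treatments, `probe_map`,
#'   `antiprolif_treatments`).
#' @export
simulate_drug_panels <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  genes <- truth$genes$gene
  beta <- truth$genes$beta
  nl <- cfg$n_lines
  z_l <- stats::rnorm(nl)
  lines <- sprintf("LINE%03d", seq_len(nl))

  # two probes per gene, normalized intensity scale
  probe_map <- data.frame(
    probe = paste0(rep(genes, each = 2), c("_at1", "_at2")),
    gene = rep(genes, each = 2), stringsAsFactors = FALSE)
  b_probe <- rep(beta, each = 2)
  exprs <- outer(b_probe, z_l) +
    matrix(stats::rnorm(length(b_probe) * nl, 0, 0.5),
           length(b_probe), nl)
  dimnames(exprs) <- list(probe_map$probe, lines)

  drugs <- sprintf("DRUG%02d", seq_len(cfg$n_drugs))
  targeting <- drugs[seq_len(cfg$n_targeting)]
  tau_d <- ifelse(drugs %in% targeting, cfg$tau, 0)
  ec50 <- sapply(seq_along(drugs), function(j)
    exp(-tau_d[j] * z_l + stats::rnorm(nl, 0, 0.5)))
  dimnames(ec50) <- list(lines, drugs)

  # treatment rank matrix on its own probe universe
  p_probes <- paste0("P", sprintf("%05d", seq_len(cfg$n_probes)))
  # map first 2*pi_set probes (capped) onto PI genes, rest onto background
  pi_genes <- genes[grepl("^PIG", genes)]
  n_pi_probes <- min(2L * length(pi_genes), cfg$n_probes %/% 2L)
  rank_map <- data.frame(
    probe = p_probes,
    gene = c(rep(pi_genes, length.out = n_pi_probes),
             paste0("NPG", seq_len(cfg$n_probes - n_pi_probes))),
    stringsAsFactors = FALSE)
  treatments <- sprintf("TREAT%03d", seq_len(cfg$n_treatments))
  anti <- treatments[seq_len(cfg$n_antiprolif)]
  score <- matrix(stats::rnorm(cfg$n_probes * cfg$n_treatments),
                  cfg$n_probes, cfg$n_treatments,
                  dimnames = list(p_probes, treatments))
  pi_rows <- rank_map$gene %in% pi_genes
  score[pi_rows, treatments %in% anti] <-
    score[pi_rows, treatments %in% anti] - 4
  # rank 1 = highest positive differential expression
  ranks <- apply(-score, 2, rank, ties.method = "first")
  storage.mode(ranks) <- "integer"

  list(panel = list(expression = exprs, probe_map = probe_map, ec50 = ec50,
                    z = stats::setNames(z_l, lines),
                    targeting_drugs = targeting),
       rank_matrix = list(ranks = ranks, probe_map = rank_map,
                          antiprolif_treatments = anti))
}
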