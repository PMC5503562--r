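#' Precompute the risk-set layout for a survival vector
#'
#' Sorts a (time, event) pair once so that many single-covariate Cox fits
#' against the same survival outcome (e.g. a transcriptome-wide scan) can
#' reuse the ordering and tie structure.
#'
#' @param time numeric vector of follow-up times (days).
#' @param event logical (or 0/1) vector; TRUE when death was observed.
#' @return an object of class `cox_layout` holding the sort order, the tie
#'   groups of event times and their first risk-set positions.
#' @keywords internal
cox_layout <- function(time, event) {
  stopifnot(length(time) == length(event))
  event <- as.logical(event)
  if (anyNA(time) || anyNA(event)) stop("time/event must not contain NA")
  ord <- order(time)
  t_s <- time[ord]
  e_s <- event[ord]
  ev_pos <- which(e_s)                      # event positions in sorted order
  if (length(ev_pos) > 0L) {
    ev_time <- t_s[ev_pos]
    grp <- cumsum(c(TRUE, diff(ev_time) > 0))  # tie group per event
    d_g <- tabulate(grp)                       # events per group
    # first sorted position whose time >= group's event time
    first_pos <- vapply(unique(ev_time), function(tt) {
      match(TRUE, t_s >= tt)
    }, integer(1))
    # within-group Efron index (k-1)/d
    k_in_g <- sequence(d_g)
    c_k <- (k_in_g - 1) / d_g[grp]
  } else {
    grp <- integer(0); d_g <- integer(0); first_pos <- integer(0)
    c_k <- numeric(0)
  }
  structure(list(
    ord = ord, n = length(time), ev_pos = ev_pos, grp = grp,
    d_g = d_g, first_pos = first_pos, c_k = c_k,
    no_ties = all(d_g == 1L),
    n_events = length(ev_pos)
  ), class = "cox_layout")
}

# Efron partial log-likelihood, score and information for scalar beta,
# given covariate already sorted by the layout's order.
cox_efron_derivs <- function(beta, x_s, lay) {
  eta <- beta * x_s
  eta <- eta - max(eta)                 # guard overflow; PL is shift-invariant
  w <- exp(eta)
  wx <- w * x_s
  wx2 <- wx * x_s
  # suffix sums (risk sets): S*(pos) = sum over j >= pos
  S0 <- rev(cumsum(rev(w)))
  S1 <- rev(cumsum(rev(wx)))
  S2 <- rev(cumsum(rev(wx2)))
  g <- lay$grp
  fp <- lay$first_pos
  if (lay$no_ties) {            # Efron correction vanishes: c_k all zero
    A0 <- S0[fp]
    A1 <- S1[fp]
    A2 <- S2[fp]
  } else {
    # tied-event (death) sums per group
    D0 <- rowsum(w[lay$ev_pos], g)[, 1]
    D1 <- rowsum(wx[lay$ev_pos], g)[, 1]
    D2 <- rowsum(wx2[lay$ev_pos], g)[, 1]
    c_k <- lay$c_k
    A0 <- S0[fp][g] - c_k * D0[g]
    A1 <- S1[fp][g] - c_k * D1[g]
    A2 <- S2[fp][g] - c_k * D2[g]
  }
  xi <- x_s[lay$ev_pos]
  loglik <- sum(eta[lay$ev_pos]) - sum(log(A0))
  r1 <- A1 / A0
  score <- sum(xi) - sum(r1)
  info <- sum(A2 / A0 - r1 * r1)
  list(loglik = loglik, score = score, info = info)
}

#' Single-covariate Cox proportional-hazards fit
#'
#' Maximizes the Efron tie-corrected partial likelihood by Newton's method
#' (tolerance 1e-9 on the step, at most `max_iter` iterations) and reports
#' the Wald test of the coefficient. Fits that do not converge — the
#' coefficient runs beyond `coef_cap` (a maximum likelihood estimate heading
#' to infinity, e.g. a covariate perfectly ordering the deaths) or the
#' iteration cap is hit — are flagged and assigned p = 1, the convention
#' used throughout the per-cancer and transcriptome-wide scans. Degenerate
#' inputs (constant covariate, fewer than 2 events) take the same convention.
#'
#' @param time follow-up times.
#' @param event logical/0-1 death indicator.
#' @param covariate numeric covariate (e.g. proliferative index).
#' @param layout optional precomputed [cox_layout()] for `time`/`event`.
#' @param coef_cap non-convergence bound on |coefficient| (default 15).
#' @param max_iter Newton iteration cap (default 50).
#' @param tol convergence tolerance (default 1e-9).
#' @return object of class `cox_fit`: coefficient, se, Wald z, p_value, n,
#'   n_events, converged flag and failure reason (if any).
#' @examples
#' set.seed(1)
#' tt <- rexp(60); ev <- rbinom(60, 1, 0.7); x <- rnorm(60)
#' cox_fit(tt, ev, x)
#' @export
cox_fit <- function(time, event, covariate, layout = NULL,
                    coef_cap = 15, max_iter = 50L, tol = 1e-9) {
  if (is.null(layout)) layout <- cox_layout(time, event)
  n <- layout$n
  stopifnot(length(covariate) == n)
  fail <- function(reason) {
    structure(list(coefficient = NA_real_, se = NA_real_, z = NA_real_,
                   p_value = 1, n = n, n_events = layout$n_events,
                   converged = FALSE, reason = reason),
              class = "cox_fit")
  }
  if (layout$n_events < 2L) return(fail("fewer than 2 events"))
  x_s <- covariate[layout$ord]
  if (max(x_s) - min(x_s) <= 0) return(fail("constant covariate"))
  beta <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d <- cox_efron_derivs(beta, x_s, layout)
    if (!is.finite(d$score) || !is.finite(d$info) || d$info <= 0)
      return(fail("singular information"))
    step <- d$score / d$info
    # dampen wild steps
    if (abs(step) > 5) step <- sign(step) * 5
    beta <- beta + step
    if (abs(beta) > coef_cap) return(fail("coefficient diverging"))
    if (abs(step) < tol) { converged <- TRUE; break }
  }
  if (!converged) return(fail("iteration cap reached"))
  d <- cox_efron_derivs(beta, x_s, layout)
  se <- 1 / sqrt(d$info)
  z <- beta / se
  structure(list(coefficient = beta, se = se, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 n = n, n_events = layout$n_events,
                 converged = TRUE, reason = NA_character_),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Cox PH fit: coef = %.4f (se %.4f), Wald z = %.3f, p = %.3g\n",
                x$coefficient, x$se, x$z, x$p_value))
  } else {
    cat(sprintf("Cox PH fit: did not converge (%s); p set to 1\n", x$reason))
  }
  cat(sprintf("  n = %d, events = %d\n", x$n, x$n_events))
  invisible(x)
}

# Efron partial log-likelihood at a given beta (exposed for oracles/tests).
#' @keywords internal
cox_partial_loglik <- function(beta, time, event, covariate) {
  lay <- cox_layout(time, event)
  cox_efron_derivs(beta, covariate[lay$ord], lay)$loglik
}
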