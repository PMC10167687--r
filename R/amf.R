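#' Monomer/assembled cutoff fraction for a protein
#'
#' The SEC axis is split at the fraction corresponding to twice the
#' protein's monomeric molecular weight: anything eluting strictly earlier
#' (higher apparent MW) is counted as assembled, the rest as monomeric. The
#' (possibly fractional) cutoff is clamped into `[1, max_fraction]`.
#'
#' @param mmw monomeric molecular weight(s) in kDa.
#' @param cal [fit_calibration()].
#' @param max_fraction last fraction on the grid.
#' @return numeric cutoff fraction(s).
#' @export
assembled_cutoff_fraction <- function(mmw, cal, max_fraction = 49L) {
  if (any(!is.finite(mmw) | mmw <= 0)) stop2("monomeric MW must be > 0")
  pmin(pmax(mw_to_fraction(cal, 2 * mmw), 1), max_fraction)
}

#' Assembled mass fraction per protein and sample
#'
#' AMF = signal in the assembled range (fractions strictly below the
#' cutoff) divided by the total detected signal, using all fractions -- no
#' peak extraction is involved. Samples with zero total signal for a protein
#' are excluded.
#'
#' @param traces [protein_traces()] (or peptide traces already summed per
#'   protein).
#' @param cutoffs named numeric vector of cutoff fractions per protein_id;
#'   proteins without a cutoff (no MW annotation) are skipped.
#' @return data.table (protein_id, sample_id, amf).
#' @export
compute_amf <- function(traces, cutoffs) {
  dt <- as.data.table(traces)
  dt <- dt[protein_id %in% names(cutoffs)]
  res <- dt[, {
    cut <- cutoffs[[protein_id[1L]]]
    tot <- sum(intensity)
    if (tot > 0) .(amf = sum(intensity[fraction_index < cut]) / tot)
    else .(amf = NA_real_)
  }, by = .(protein_id, sample_id)]
  res[!is.na(amf)]
}

#' Shrink unit-interval observations away from the boundaries
#'
#' Beta regression requires responses strictly inside (0,1); the standard
#' shrinkage y' = (y (n - 1) + 0.5) / n maps `[0,1]` onto
#' `[0.5/n, 1 - 0.5/n]`, where n is the sample size.
#'
#' @param y values in `[0,1]`.
#' @param n sample size (>= 2).
#' @export
transform_unit_interval <- function(y, n) {
  if (n < 2L) stop2("n must be >= 2")
  if (any(y < 0 | y > 1, na.rm = TRUE)) stop2("y must lie in [0,1]")
  (y * (n - 1) + 0.5) / n
}

# beta log-likelihood under mean/precision parameterization
beta_loglik <- function(y, mu, phi) sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))

# ML fit of a beta regression with logit mean link and constant precision;
# X is the design matrix for the mean. Returns loglik and coefficients.
beta_ml_fit <- function(y, X) {
  k <- ncol(X)
  neg <- function(par) {
    mu <- plogis(drop(X %*% par[seq_len(k)]))
    -beta_loglik(y, mu, exp(par[k + 1L]))
  }
  ## moment-based starts, plus dispersed precision starts for robustness
  mu0 <- pmin(pmax(mean(y), 1e-3), 1 - 1e-3)
  phi0 <- max(mu0 * (1 - mu0) / max(var(y), 1e-6) - 1, 1)
  b0 <- tryCatch(qlogis(pmin(pmax(drop(solve(crossprod(X), crossprod(X, y))), 1e-4), 1 - 1e-4)),
                 error = function(e) rep(qlogis(mu0), k))
  ## the linear solve gives fitted values, not coefficients; fall back to simple start
  if (k == 1L) b0 <- qlogis(mu0)
  starts <- list(c(b0, log(phi0)), c(b0, log(phi0) + 2), c(b0, 1))
  best <- NULL
  for (s in starts) {
    f <- tryCatch(nlminb(s, neg, lower = c(rep(-30, k), -10),
                         upper = c(rep(30, k), 25),
                         control = list(rel.tol = 1e-12, iter.max = 500L)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$objective < best$objective)) best <- f
  }
  if (is.null(best)) return(list(loglik = NA_real_, coef = rep(NA_real_, k + 1L),
                                 converged = FALSE))
  list(loglik = -best$objective, coef = best$par,
       phi = exp(best$par[k + 1L]), converged = best$convergence == 0L)
}

#' Beta-regression likelihood-ratio test for a two-group difference
#'
#' Fits, by maximum likelihood, a beta regression of the bounded response on
#' the condition label (logit mean link, constant precision) and the
#' intercept-only null model, and compares them by a likelihood-ratio test
#' against chi-square with one degree of freedom. Bounded responses such as
#' mass fractions violate the assumptions of a t test; the beta model is the
#' standard alternative.
#'
#' @param y responses strictly inside (0,1) (see [transform_unit_interval()]).
#' @param group two-level factor/character/logical of the same length.
#' @return list: `p_value`, `statistic`, `converged`, `estimate` (difference
#'   of fitted group means). Degenerate inputs (all responses equal) return
#'   p = 1 with `converged = FALSE`.
#' @export
beta_lrt <- function(y, group) {
  stopifnot(length(y) == length(group))
  if (any(y <= 0 | y >= 1)) stop2("responses must be strictly inside (0,1)")
  g <- as.integer(factor(group)) - 1L
  if (length(unique(g)) != 2L) stop2("group must have exactly 2 levels")
  if (min(table(g)) < 2L) stop2("need >= 2 samples per condition")
  if (stats::sd(y) < 1e-12) {
    return(list(p_value = 1, statistic = 0, converged = FALSE, estimate = 0))
  }
  full <- beta_ml_fit(y, cbind(1, g))
  null <- beta_ml_fit(y, matrix(1, length(y)))
  if (!is.finite(full$loglik) || !is.finite(null$loglik)) {
    return(list(p_value = 1, statistic = NA_real_, converged = FALSE,
                estimate = NA_real_))
  }
  stat <- max(2 * (full$loglik - null$loglik), 0)
  mu <- plogis(c(full$coef[1L], full$coef[1L] + full$coef[2L]))
  list(p_value = pchisq(stat, df = 1L, lower.tail = FALSE), statistic = stat,
       converged = full$converged && null$converged, estimate = mu[1L] - mu[2L])
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, the step-up false
#' discovery rate correction used for every multiple-testing adjustment in
#' the pipeline.
#'
#' @param p p-values in `[0,1]`.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Differential assembled-mass-fraction analysis
#'
#' Computes per-sample AMF values, per-condition means and their difference
#' (condition A minus condition B), tests each protein by
#' [transform_unit_interval()] + [beta_lrt()], adjusts by Benjamini-Hochberg
#' and calls a protein significant when |difference| >= `min_diff` and
#' adjusted p <= `alpha`.
#'
#' @param traces [protein_traces()].
#' @param design design matrix.
#' @param mw MW annotation (protein_id, mw_kda).
#' @param cal [fit_calibration()].
#' @param condition_a,condition_b the two conditions compared.
#' @param min_diff minimum absolute mean AMF difference (0.3 by default; 0.25
#'   is a common exploratory choice).
#' @param alpha adjusted-p threshold.
#' @return data.table, one row per testable protein: amf_a, amf_b, diff,
#'   p_value, adjusted_p, significant, direction, converged.
#' @export
amf_differential <- function(traces, design, mw, cal, condition_a, condition_b,
                             min_diff = 0.3, alpha = 0.05) {
  des <- as.data.table(design)[condition %in% c(condition_a, condition_b)]
  if (!nrow(des)) stop2("conditions not found in design")
  mwdt <- as.data.table(mw)
  cutoffs <- setNames(assembled_cutoff_fraction(mwdt$mw_kda, cal, n_fractions(traces)),
                      mwdt$protein_id)
  amf <- compute_amf(as.data.table(traces)[sample_id %in% des$sample_id] |>
                       protein_traces(n_fractions(traces)), cutoffs)
  amf <- merge(amf, des[, .(sample_id, condition)], by = "sample_id")
  n_total <- nrow(des)
  out <- lapply(split(amf, by = "protein_id"), function(d) {
    a <- d[condition == condition_a, amf]
    b <- d[condition == condition_b, amf]
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    yp <- transform_unit_interval(c(a, b), n_total)
    grp <- c(rep("A", length(a)), rep("B", length(b)))
    lrt <- beta_lrt(yp, grp)
    data.table(protein_id = d$protein_id[1L],
               cutoff_fraction = cutoffs[[d$protein_id[1L]]],
               n_a = length(a), n_b = length(b),
               amf_a = mean(a), amf_b = mean(b), diff = mean(a) - mean(b),
               p_value = lrt$p_value, converged = lrt$converged)
  })
  out <- rbindlist(out[!vapply(out, is.null, logical(1))])
  if (!nrow(out)) return(out)
  out[, adjusted_p := bh_adjust(p_value)]
  out[, significant := abs(diff) >= min_diff & adjusted_p <= alpha]
  out[, direction := fifelse(diff > 0, "increase", fifelse(diff < 0, "decrease", "none"))]
  setorder(out, adjusted_p)
  out[]
}
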