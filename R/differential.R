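#' Impute missing cells before intensity summation
#'
#' Inside a feature (or global) range, cells missing in single fractions,
#' replicates or whole conditions are drawn uniformly between zero and the
#' member's minimum detected signal, so that absence contributes a value
#' below anything actually measured. Members never detected anywhere are
#' excluded upstream.
#'
#' @param n number of values to draw.
#' @param min_detected the member's minimum detected (positive) intensity.
#' @return numeric vector of length `n` in `[0, min_detected)`.
#' @export
impute_differential <- function(n, min_detected) {
  if (!is.finite(min_detected) || min_detected <= 0) stop2("member never detected")
  runif(n, 0, min_detected)
}

# member x sample intensity matrix over a fraction range, with uniform
# baseline imputation of missing cells; also returns the per-fraction
# condition means used by the paired fallback test.
# traces_dt: peptide-level long table restricted to relevant samples.
range_member_matrix <- function(traces_dt, members, left, right, samples) {
  width <- right - left + 1L
  mats <- list()
  for (m in members) {
    sub <- traces_dt[peptide_id == m]
    mind <- suppressWarnings(min(sub$intensity[sub$intensity > 0]))
    if (!is.finite(mind)) next  # never detected anywhere: excluded
    mm <- matrix(NA_real_, nrow = length(samples), ncol = width,
                 dimnames = list(samples, NULL))
    inr <- sub[fraction_index >= left & fraction_index <= right]
    if (nrow(inr)) {
      mm[cbind(match(inr$sample_id, samples), inr$fraction_index - left + 1L)] <-
        inr$intensity
    }
    nmiss <- sum(is.na(mm))
    if (nmiss) mm[is.na(mm)] <- impute_differential(nmiss, mind)
    mats[[m]] <- mm
  }
  mats
}

#' Per-member feature intensities
#'
#' Sums each member's (imputed) intensities over the feature's fraction
#' range, per sample.
#'
#' @param traces peptide-level traces.
#' @param members member (peptide) ids.
#' @param left,right closed fraction interval.
#' @param samples sample ids to quantify.
#' @param seed seed for the baseline imputation.
#' @return data.table (member_id, sample_id, intensity).
#' @export
feature_member_intensity <- function(traces, members, left, right,
                                     samples = trace_samples(traces), seed = NULL) {
  dt <- as.data.table(traces)[sample_id %in% samples]
  mats <- with_seed(seed, range_member_matrix(dt, sort(members), left, right, samples))
  rbindlist(lapply(names(mats), function(m) {
    data.table(member_id = m, sample_id = samples, intensity = rowSums(mats[[m]]))
  }))
}

# two-sided Welch t test on per-replicate sums; paired per-fraction t test
# when either condition has a single replicate; p = 1 when both groups are
# constant (zero variance)
member_test <- function(mat, a_idx, b_idx) {
  sums <- rowSums(mat)
  a <- sums[a_idx]; b <- sums[b_idx]
  mean_a <- mean(a); mean_b <- mean(b)
  log2fc <- log2(mean_a / mean_b)
  p <- if (min(length(a), length(b)) >= 2L) {
    tryCatch(t.test(a, b, var.equal = FALSE)$p.value, error = function(e) 1)
  } else {
    fa <- colMeans(mat[a_idx, , drop = FALSE])
    fb <- colMeans(mat[b_idx, , drop = FALSE])
    tryCatch(t.test(fa, fb, paired = TRUE)$p.value, error = function(e) 1)
  }
  list(log2FC = log2fc, p_value = p, mean_a = mean_a, mean_b = mean_b)
}

#' Aggregate member-level statistics to their parent
#'
#' The parent (protein over peptides, or complex over proteins) log2
#' fold-change is the median of member fold-changes. Member p-values are
#' made direction-aware -- a member whose fold-change sign opposes the
#' parent median has its p replaced by 1 - p -- and the parent p-value is
#' the Beta(j, m - j + 1) CDF at the j-th smallest adjusted p (j = ceiling
#' (m/2)), the null distribution of that order statistic for m uniforms.
#'
#' @param log2fc member fold-changes (finite).
#' @param p member p-values.
#' @return list: `log2FC`, `p_value`, `n` (members aggregated).
#' @export
aggregate_to_parent <- function(log2fc, p) {
  keep <- is.finite(log2fc) & is.finite(p)
  log2fc <- log2fc[keep]; p <- p[keep]
  m <- length(p)
  if (!m) return(list(log2FC = NA_real_, p_value = NA_real_, n = 0L))
  parent_fc <- median(log2fc)
  adj <- p
  if (parent_fc != 0) {
    discord <- sign(log2fc) == -sign(parent_fc)
    adj[discord] <- 1 - p[discord]
  }
  if (m == 1L) return(list(log2FC = parent_fc, p_value = adj, n = 1L))
  j <- ceiling(m / 2)
  med <- sort(adj)[j]
  list(log2FC = parent_fc, p_value = pbeta(med, j, m - j + 1), n = m)
}

# shared engine for feature-wise / global differential testing
differential_engine <- function(features, traces, design, condition_a, condition_b,
                                seed, log2fc_min, alpha, level) {
  des <- as.data.table(design)[condition %in% c(condition_a, condition_b)]
  dt <- as.data.table(traces)[sample_id %in% des$sample_id]
  samples <- sort(des$sample_id)
  a_idx <- which(samples %in% des[condition == condition_a, sample_id])
  b_idx <- which(samples %in% des[condition == condition_b, sample_id])
  rows <- with_seed(seed, {
    lapply(seq_len(nrow(features)), function(i) {
      f <- features[i]
      memb <- sort(f$members[[1L]])
      mats <- range_member_matrix(dt[peptide_id %in% memb], memb,
                                  f$left_boundary, f$right_boundary, samples)
      if (!length(mats)) return(NULL)
      stats <- lapply(mats, member_test, a_idx = a_idx, b_idx = b_idx)
      agg <- aggregate_to_parent(vapply(stats, `[[`, numeric(1), "log2FC"),
                                 vapply(stats, `[[`, numeric(1), "p_value"))
      data.table(entity_id = f$feature_id, owner_id = f$owner_id, level = level,
                 log2FC = agg$log2FC, p_value = agg$p_value,
                 mean_intensity_A = sum(vapply(stats, `[[`, numeric(1), "mean_a")),
                 mean_intensity_B = sum(vapply(stats, `[[`, numeric(1), "mean_b")),
                 n_members_aggregated = agg$n)
    })
  })
  out <- rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (!nrow(out)) return(out)
  out[, adjusted_p := bh_adjust(p_value)]
  out[, significant := abs(log2FC) >= log2fc_min & adjusted_p <= alpha]
  setorder(out, adjusted_p)
  out[]
}

#' Feature-specific differential intensity analysis
#'
#' For each detected protein feature, member (peptide) intensities are
#' summed over the feature range per sample (missing cells imputed at a
#' uniform sub-detection baseline), compared between the two conditions by
#' a two-sided Welch t test on replicate sums (paired per-fraction t test
#' when a condition lacks replicates), and aggregated to the protein with
#' [aggregate_to_parent()]. Benjamini-Hochberg adjustment runs across
#' features; significance requires |log2FC| >= `log2fc_min` and adjusted
#' p <= `alpha`.
#'
#' @param features feature table from [find_features()] (peptide-level
#'   members).
#' @param traces [peptide_traces()].
#' @param design design matrix.
#' @param condition_a,condition_b conditions compared (fold-change is A/B).
#' @param seed imputation seed.
#' @param log2fc_min,alpha significance thresholds.
#' @return data.table of `DifferentialResult` rows.
#' @export
feature_differential <- function(features, traces, design, condition_a, condition_b,
                                 seed = NULL, log2fc_min = 1, alpha = 0.05) {
  differential_engine(features, traces, design, condition_a, condition_b,
                      seed, log2fc_min, alpha, level = "feature")
}

#' Global (whole-gradient) differential analysis
#'
#' Identical to [feature_differential()] but integrating over the entire
#' fraction range of every protein, making it equivalent to a conventional
#' total-abundance proteomics comparison.
#'
#' @param traces [peptide_traces()].
#' @inheritParams feature_differential
#' @export
global_differential <- function(traces, design, condition_a, condition_b,
                                seed = NULL, log2fc_min = 1, alpha = 0.05) {
  dt <- as.data.table(traces)
  map <- unique(dt[, .(protein_id, peptide_id)])
  feats <- data.table(
    feature_id = paste0(unique(map$protein_id), "@global"),
    owner_id = unique(map$protein_id),
    members = lapply(unique(map$protein_id), function(p) map[protein_id == p, peptide_id]),
    left_boundary = 1L, right_boundary = n_fractions(traces))
  differential_engine(feats, traces, design, condition_a, condition_b,
                      seed, log2fc_min, alpha, level = "protein_global")
}

#' Feature-specific mass fractions
#'
#' FMF of a member in a sample: detected signal inside the feature range
#' divided by the member's total detected signal in that sample. Samples
#' with zero total signal for a member are excluded.
#'
#' @param traces peptide-level traces.
#' @param members member ids.
#' @param left,right closed feature interval.
#' @return data.table (member_id, sample_id, fmf).
#' @export
compute_fmf <- function(traces, members, left, right) {
  dt <- as.data.table(traces)[peptide_id %in% members]
  res <- dt[, .(fmf = {
    tot <- sum(intensity)
    if (tot > 0) sum(intensity[fraction_index >= left & fraction_index <= right]) / tot
    else NA_real_
  }), by = .(member_id = peptide_id, sample_id)]
  res[!is.na(fmf)]
}

#' Differential feature-specific mass-fraction (rewiring) analysis
#'
#' Distinguishes redistribution of a protein across assembly states from
#' plain expression change: per feature and peptide, the FMF is computed per
#' sample, the condition difference of means is taken, and significance is
#' assessed by [beta_lrt()] on boundary-shrunk values, aggregated to the
#' protein with the direction-adjusted order-statistic rule of
#' [aggregate_to_parent()]. Significance requires |mean difference| >=
#' `min_diff` and Benjamini-Hochberg adjusted p <= `alpha`.
#'
#' @param features protein feature table ([find_features()]).
#' @param traces [peptide_traces()].
#' @param design design matrix.
#' @param condition_a,condition_b conditions compared.
#' @param min_diff minimum absolute mean FMF difference.
#' @param alpha adjusted-p threshold.
#' @return data.table: entity_id, owner_id, fmf_a, fmf_b, diff, p_value,
#'   adjusted_p, significant.
#' @export
fmf_differential <- function(features, traces, design, condition_a, condition_b,
                             min_diff = 0.3, alpha = 0.05) {
  des <- as.data.table(design)[condition %in% c(condition_a, condition_b)]
  dt <- as.data.table(traces)[sample_id %in% des$sample_id]
  setattr(dt, "n_fractions", n_fractions(traces))
  n_total <- nrow(des)
  rows <- lapply(seq_len(nrow(features)), function(i) {
    f <- features[i]
    fmf <- compute_fmf(dt, f$members[[1L]], f$left_boundary, f$right_boundary)
    if (!nrow(fmf)) return(NULL)
    fmf <- merge(fmf, des[, .(sample_id, condition)], by = "sample_id")
    per_member <- lapply(split(fmf, by = "member_id"), function(d) {
      a <- d[condition == condition_a, fmf]
      b <- d[condition == condition_b, fmf]
      if (length(a) < 2L || length(b) < 2L) return(NULL)
      lrt <- beta_lrt(transform_unit_interval(c(a, b), n_total),
                      c(rep("A", length(a)), rep("B", length(b))))
      data.table(diff_ = mean(a) - mean(b), p_value = lrt$p_value,
                 fmf_a = mean(a), fmf_b = mean(b))
    })
    per_member <- rbindlist(per_member[!vapply(per_member, is.null, logical(1))])
    if (!nrow(per_member)) return(NULL)
    agg <- aggregate_to_parent(per_member$diff_, per_member$p_value)
    data.table(entity_id = f$feature_id, owner_id = f$owner_id, level = "protein_FMF",
               fmf_a = mean(per_member$fmf_a), fmf_b = mean(per_member$fmf_b),
               diff = agg$log2FC,  # median member FMF difference
               p_value = agg$p_value, n_members_aggregated = agg$n)
  })
  out <- rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (!nrow(out)) return(out)
  out[, adjusted_p := bh_adjust(p_value)]
  out[, significant := abs(diff) >= min_diff & adjusted_p <= alpha]
  setorder(out, adjusted_p)
  out[]
}
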