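#' Integrate traces across samples
#'
#' Sums each member's intensities fractionwise over all samples (missing as
#' zero), giving one composite trace per member. Feature detection runs on
#' integrated traces so that peak-group boundaries are consistent across
#' conditions and replicates.
#'
#' @param traces [peptide_traces()] or [protein_traces()].
#' @return `integrated_traces`: list with `mat` (member x fraction matrix),
#'   `owner` (member -> protein map; identity at protein level) and
#'   `n_fractions`.
#' @export
integrate_traces <- function(traces) {
  dt <- as.data.table(traces)
  idc <- id_col(dt)
  nf <- n_fractions(traces)
  agg <- dt[, .(intensity = sum(intensity)), by = c(idc, "fraction_index")]
  members <- sort(unique(agg[[idc]]))
  mat <- matrix(0, nrow = length(members), ncol = nf, dimnames = list(members, NULL))
  mat[cbind(match(agg[[idc]], members), agg$fraction_index)] <- agg$intensity
  owner <- if (idc == "peptide_id") {
    map <- unique(dt[, .(peptide_id, protein_id)])
    setNames(map$protein_id, map$peptide_id)[members]
  } else {
    setNames(members, members)
  }
  structure(list(mat = mat, owner = owner, n_fractions = nf),
            class = "integrated_traces")
}

#' Feature finder parameters
#'
#' @param corr_cutoff minimum mean pairwise member correlation inside the
#'   sliding window (and, after refinement, inside the peak boundaries).
#' @param window_size sliding window width in fractions (odd, >= 3).
#' @param rt_height peaks at most this many fractions from a higher peak are
#'   merged into it.
#' @param smoothing_length centered moving-average length for trace smoothing.
#' @param perturb_cutoff recorded decoy perturbation magnitude (no effect on
#'   scoring in this implementation; kept as run metadata).
#' @param collapse_method recorded collapsing mode label.
#' @export
feature_finder_params <- function(corr_cutoff = 0.9, window_size = 7L,
                                  rt_height = 1, smoothing_length = 7L,
                                  perturb_cutoff = "5%",
                                  collapse_method = c("apex_only", "apex_network")) {
  window_size <- as.integer(window_size)
  if (window_size < 3L || window_size %% 2L == 0L) stop2("window_size must be odd and >= 3")
  if (corr_cutoff <= 0 || corr_cutoff >= 1) stop2("corr_cutoff must be in (0,1)")
  structure(list(corr_cutoff = corr_cutoff, window_size = window_size,
                 rt_height = rt_height, smoothing_length = as.integer(smoothing_length),
                 perturb_cutoff = perturb_cutoff,
                 collapse_method = match.arg(collapse_method)),
            class = "feature_finder_params")
}

# feature finding on one owner's member x fraction matrix (unsmoothed)
find_features_one <- function(mat, params, n_queried = nrow(mat)) {
  nf <- ncol(mat)
  if (nrow(mat) < 2L) return(NULL)
  sm <- t(apply(mat, 1L, moving_average, k = params$smoothing_length))
  w <- params$window_size
  nwin <- nf - w + 1L
  if (nwin < 1L) return(NULL)
  wcor <- vapply(seq_len(nwin), function(s) {
    v <- mean_pairwise_cor(sm[, s:(s + w - 1L), drop = FALSE])
    if (is.na(v)) 0 else v
  }, numeric(1))

  hits <- wcor >= params$corr_cutoff
  if (!any(hits)) return(NULL)
  r <- rle(hits)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (ri in which(r$values)) {
    lo <- starts[ri]                 # first window start
    hi <- ends[ri] + w - 1L          # last window end
    ssum <- colSums(sm)
    seg <- ssum[lo:hi]
    peaks <- local_maxima(seg) + lo - 1L
    ## merge peaks within rt_height of a higher one
    peaks <- peaks[order(-ssum[peaks], peaks)]
    kept <- integer(0)
    for (p in peaks) {
      if (!length(kept) || all(abs(kept - p) > params$rt_height)) kept <- c(kept, p)
    }
    for (apex in sort(kept)) {
      ## boundaries: walk to nearest local minimum of the summed smoothed trace
      left <- apex
      while (left > lo && ssum[left - 1L] < ssum[left]) left <- left - 1L
      right <- apex
      while (right < hi && ssum[right + 1L] < ssum[right]) right <- right + 1L
      ## refine membership greedily on unsmoothed traces over [left, right]
      memb <- rownames(mat)
      repeat {
        sub <- mat[memb, left:right, drop = FALSE]
        score <- mean_pairwise_cor(sub)
        if (is.na(score)) score <- 0
        if (score >= params$corr_cutoff || length(memb) < 3L) break
        cc <- suppressWarnings(cor(t(sub)))
        cc[is.na(cc)] <- 0
        diag(cc) <- NA
        memb <- memb[-which.min(rowMeans(cc, na.rm = TRUE))]
      }
      if (length(memb) < 2L || score < params$corr_cutoff) next
      out[[length(out) + 1L]] <- data.table(
        members = list(sort(memb)), n_members = length(memb),
        completeness = length(memb) / n_queried,
        apex_fraction = apex, left_boundary = left, right_boundary = right,
        coelution_score = score,
        area = sum(mat[memb, left:right]))
    }
  }
  if (!length(out)) NULL else rbindlist(out)
}

#' Detect coelution features on integrated traces
#'
#' Slides a window along the fraction dimension of the smoothed member
#' traces of each owner (protein over its peptides, or complex query over
#' its subunit proteins); windows whose mean pairwise Pearson correlation
#' reaches `corr_cutoff` seed candidate regions, within which peaks of the
#' summed smoothed trace become feature apexes. Boundaries extend to the
#' nearest local minima, low-coherence members are greedily pruned, and the
#' final coelution score is recomputed on the unsmoothed traces inside the
#' boundaries.
#'
#' @param int [integrate_traces()] output.
#' @param params [feature_finder_params()].
#' @param cal optional [fit_calibration()] for apex molecular weights.
#' @param groups optional named list owner -> member ids; defaults to the
#'   peptide -> protein grouping carried by `int`.
#' @return data.table of features (one row each; `members` is a list column),
#'   or an empty table when nothing coelutes.
#' @export
find_features <- function(int, params = feature_finder_params(), cal = NULL,
                          groups = NULL) {
  stopifnot(inherits(int, "integrated_traces"))
  if (is.null(groups)) groups <- split(names(int$owner), int$owner)
  res <- list()
  for (ow in names(groups)) {
    memb <- intersect(groups[[ow]], rownames(int$mat))
    if (length(memb) < 2L) next
    ft <- find_features_one(int$mat[memb, , drop = FALSE], params,
                            n_queried = length(groups[[ow]]))
    if (!is.null(ft)) {
      ft[, owner_id := ow]
      res[[length(res) + 1L]] <- ft
    }
  }
  out <- if (length(res)) rbindlist(res) else empty_features()
  if (nrow(out)) {
    out[, apex_mw := if (is.null(cal)) NA_real_ else fraction_to_mw(cal, apex_fraction)]
    out[, feature_id := paste0(owner_id, "@", apex_fraction)]
    setcolorder(out, c("feature_id", "owner_id"))
  }
  out[]
}

empty_features <- function() {
  data.table(feature_id = character(0), owner_id = character(0),
             members = list(), n_members = integer(0), completeness = numeric(0),
             apex_fraction = integer(0), left_boundary = integer(0),
             right_boundary = integer(0), coelution_score = numeric(0),
             area = numeric(0), apex_mw = numeric(0))
}

#' Random peptide-to-protein decoy assignment
#'
#' Builds one decoy "protein" per target protein by sampling, without
#' replacement within the decoy, one peptide from each of as many distinct
#' real proteins as the target has peptides. Decoy features scored alongside
#' target features calibrate the null coelution score distribution.
#'
#' @param traces peptide-level traces (or anything with a peptide -> protein
#'   map in columns `peptide_id`, `protein_id`).
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return named list decoy owner id -> peptide ids, usable as `groups` in
#'   [find_features()].
#' @export
make_peptide_decoys <- function(traces, seed) {
  map <- unique(as.data.table(traces)[, .(peptide_id, protein_id)])
  setkey(map, protein_id, peptide_id)
  prots <- unique(map$protein_id)
  if (length(prots) < 2L) stop2("need >= 2 proteins to build decoys")
  sizes <- map[, .N, by = protein_id]
  if (max(sizes$N) > length(prots)) {
    stop2("too few proteins to draw a decoy of size ", max(sizes$N),
          " from distinct proteins")
  }
  pep_by_prot <- split(map$peptide_id, map$protein_id)
  with_seed(seed, {
    decoys <- lapply(seq_len(nrow(sizes)), function(i) {
      k <- sizes$N[i]
      src <- sample(prots, k)
      vapply(pep_by_prot[src], function(p) if (length(p) == 1L) p else sample(p, 1L),
             character(1), USE.NAMES = FALSE)
    })
    names(decoys) <- paste0("DECOY_", sizes$protein_id)
    decoys
  })
}

#' Target-decoy q-value estimation for coelution features
#'
#' At a score threshold s, FDR(s) = (#decoy features >= s) / (#target
#' features >= s); a feature's q-value is the minimum FDR over thresholds at
#' or below its own score, and its p-value the decoy exceedance
#' (#decoys >= s + 1)/(#decoys + 1). Complex features rank by completeness
#' first, then coelution score (`by_completeness = TRUE`).
#'
#' @param targets,decoys feature tables from [find_features()].
#' @param by_completeness rank lexicographically by (completeness, score)
#'   instead of score alone.
#' @return `targets` with `p_value` and `q_value` columns, sorted best-first.
#' @export
estimate_q_values <- function(targets, decoys, by_completeness = FALSE) {
  if (!nrow(decoys)) stop2("empty decoy set: cannot estimate FDR")
  if (!nrow(targets)) return(cbind(targets, p_value = numeric(0), q_value = numeric(0)))
  t <- copy(targets)
  key_rank <- function(comp, score) {
    ## combined dense rank, best (highest) first; lexicographic when requested
    if (by_completeness) frank(list(-comp, -score), ties.method = "dense")
    else frank(-score, ties.method = "dense")
  }
  allc <- c(if (by_completeness) t$completeness else rep(0, nrow(t)),
            if (by_completeness) decoys$completeness else rep(0, nrow(decoys)))
  alls <- c(t$coelution_score, decoys$coelution_score)
  rk <- key_rank(allc, alls)
  rt <- rk[seq_len(nrow(t))]
  rd <- rk[-seq_len(nrow(t))]
  nd_ge <- vapply(rt, function(r) sum(rd <= r), integer(1))
  nt_ge <- vapply(rt, function(r) sum(rt <= r), integer(1))
  fdr <- pmin(nd_ge / nt_ge, 1)
  ## q = min FDR over thresholds at or below the feature's own score
  ord <- order(rt)                        # best target first
  q <- numeric(length(fdr))
  q[ord] <- rev(cummin(rev(fdr[ord])))
  t[, p_value := (nd_ge + 1) / (length(rd) + 1)]
  t[, q_value := q]
  setorderv(t, if (by_completeness) c("completeness", "coelution_score")
            else "coelution_score", order = -1L)
  t[]
}
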