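#' Read protein complex hypotheses
#'
#' Complex queries (e.g. CORUM entries or clusters cut from a scored PPI
#' network) arrive as a long membership table. Subunits are deduplicated;
#' subunits absent from the measured data are retained so that feature
#' completeness is counted against the full query. Hypotheses with fewer
#' than two subunits are dropped with a warning.
#'
#' @param path TSV with header `complex_id`, `protein_id`.
#' @return data.table (complex_id, subunits list column, n_subunits).
#' @export
read_hypotheses <- function(path) {
  h <- fread(path, sep = "\t", colClasses = list(character = c("complex_id", "protein_id")))
  complex_hypotheses(h)
}

#' @rdname read_hypotheses
#' @param data data.frame with `complex_id`, `protein_id` membership rows.
#' @export
complex_hypotheses <- function(data) {
  h <- unique(as.data.table(data)[, .(complex_id, protein_id)])
  out <- h[, .(subunits = list(sort(unique(protein_id)))), by = complex_id]
  out[, n_subunits := lengths(subunits)]
  small <- out[n_subunits < 2L, complex_id]
  if (length(small)) {
    warning("dropping hypotheses with < 2 subunits: ", paste(small, collapse = ", "))
    out <- out[n_subunits >= 2L]
  }
  out[]
}

#' Read a scored PPI edge list
#' @param path TSV with header `protein_a`, `protein_b` and optionally
#'   `combined_score`.
#' @export
read_ppi_edges <- function(path) {
  e <- fread(path, sep = "\t", colClasses = list(character = c("protein_a", "protein_b")))
  if (!all(c("protein_a", "protein_b") %in% names(e))) {
    stop2("edge list needs columns protein_a, protein_b")
  }
  e
}

#' Random complex decoy hypotheses with a minimum PPI edge distance
#'
#' For each target hypothesis a decoy of identical size is drawn from the
#' protein universe such that every decoy member pair has shortest-path
#' distance >= `min_edge_distance` in the PPI graph (unreachable pairs
#' qualify). Without an edge list the constraint degrades to "no two members
#' share a target complex". Decoys failing the constraint within the retry
#' budget are emitted with the `relaxed` flag.
#'
#' @param hypotheses [complex_hypotheses()] table.
#' @param edges PPI edge list (protein_a, protein_b) or NULL.
#' @param universe candidate proteins for decoys; defaults to the union of
#'   hypothesis subunits.
#' @param min_edge_distance minimum pairwise shortest-path distance.
#' @param seed integer seed.
#' @param max_tries rejection-sampling budget per decoy.
#' @return data.table like `hypotheses` with decoy ids, plus `relaxed` flag.
#' @export
make_complex_decoys <- function(hypotheses, edges = NULL, universe = NULL,
                                min_edge_distance = 3L, seed = 1L,
                                max_tries = 200L) {
  if (is.null(universe)) universe <- sort(unique(unlist(hypotheses$subunits)))
  dist_ok <- if (!is.null(edges)) {
    g <- igraph::graph_from_data_frame(
      as.data.table(edges)[, .(protein_a, protein_b)], directed = FALSE,
      vertices = data.frame(name = union(universe,
        unique(c(edges$protein_a, edges$protein_b)))))
    function(members) {
      d <- igraph::distances(g, v = members, to = members)
      all(d[upper.tri(d)] >= min_edge_distance)
    }
  } else {
    memb_sets <- hypotheses$subunits
    function(members) {
      !any(vapply(memb_sets, function(s) sum(members %in% s) >= 2L, logical(1)))
    }
  }
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(hypotheses)), function(i) {
      k <- hypotheses$n_subunits[i]
      relaxed <- TRUE
      cand <- sample(universe, k)
      for (try in seq_len(max_tries)) {
        cand <- sample(universe, k)
        if (dist_ok(cand)) { relaxed <- FALSE; break }
      }
      data.table(complex_id = paste0("DECOY_", hypotheses$complex_id[i]),
                 subunits = list(sort(cand)), n_subunits = k, relaxed = relaxed)
    })
    rbindlist(rows)
  })
}

#' Hypothesis-driven complex feature detection with FDR control
#'
#' Runs [find_features()] for every target and decoy query over its subunit
#' protein traces, discards features whose apex molecular weight is not
#' larger than twice the largest subunit monomeric MW (such peaks are
#' compatible with monomers), keeps per query the most complete feature
#' (ties: higher score, then earlier apex) as its primary, estimates
#' q-values over the primaries against the decoy primaries (ranking by
#' completeness then score), retains queries with q <= `fdr`, and re-attaches
#' the retained queries' remaining features with score >= `secondary_corr`
#' as secondary features.
#'
#' @param hypotheses target [complex_hypotheses()].
#' @param decoys decoy hypotheses ([make_complex_decoys()]).
#' @param int integrated protein traces ([integrate_traces()] of
#'   [protein_traces()]).
#' @param params [feature_finder_params()].
#' @param cal [fit_calibration()].
#' @param mw protein MW annotation (protein_id, mw_kda).
#' @param fdr q-value threshold on primary features.
#' @param secondary_corr minimum coelution score for secondary features.
#' @return list: `features` (detected primaries with q-values, plus
#'   secondaries flagged `is_secondary`), `primaries_all` (all scored
#'   primaries incl. decoys), `n_skipped` (queries with < 2 measured
#'   subunits).
#' @export
detect_complex_features <- function(hypotheses, decoys, int, params, cal, mw,
                                    fdr = 0.05, secondary_corr = 0.7) {
  mwv <- setNames(as.data.table(mw)$mw_kda, as.data.table(mw)$protein_id)
  run_queries <- function(hyp, decoy_flag) {
    n_skipped <- 0L
    prim <- list(); rest <- list()
    for (i in seq_len(nrow(hyp))) {
      sub <- hyp$subunits[[i]]
      present <- intersect(sub, rownames(int$mat))
      if (length(present) < 2L) { n_skipped <- n_skipped + 1L; next }
      ft <- find_features_one(int$mat[present, , drop = FALSE], params,
                              n_queried = length(sub))
      if (is.null(ft)) next
      ft[, owner_id := hyp$complex_id[i]]
      ft[, apex_mw := fraction_to_mw(cal, apex_fraction)]
      ## MW plausibility: a genuine complex peak must sit above twice the
      ## heaviest subunit monomer
      maxmmw <- suppressWarnings(max(mwv[present], na.rm = TRUE))
      if (is.finite(maxmmw)) ft <- ft[apex_mw > 2 * maxmmw]
      if (!nrow(ft)) next
      setorder(ft, -n_members, -coelution_score, apex_fraction)
      prim[[length(prim) + 1L]] <- ft[1L]
      if (nrow(ft) > 1L) rest[[length(rest) + 1L]] <- ft[-1L]
    }
    list(primaries = if (length(prim)) rbindlist(prim) else NULL,
         rest = if (length(rest)) rbindlist(rest) else NULL,
         n_skipped = n_skipped)
  }
  tg <- run_queries(hypotheses, FALSE)
  dc <- run_queries(decoys, TRUE)
  if (is.null(tg$primaries)) {
    return(list(features = empty_features(), primaries_all = empty_features(),
                n_skipped = tg$n_skipped))
  }
  scored <- if (is.null(dc$primaries)) {
    ## no decoy query coeluted at all: the empirical null carries no mass at
    ## any score, so every target primary is assigned q = 0
    s <- copy(tg$primaries)
    s[, p_value := 1 / (0 + 1)]
    s[, q_value := 0]
    setorder(s, -completeness, -coelution_score)
    s
  } else {
    estimate_q_values(tg$primaries, dc$primaries, by_completeness = TRUE)
  }
  scored[, `:=`(is_decoy = FALSE, is_secondary = FALSE)]
  kept <- scored[q_value <= fdr]
  secondary <- if (!is.null(tg$rest)) {
    s <- tg$rest[owner_id %in% kept$owner_id & coelution_score >= secondary_corr]
    if (nrow(s)) s[, `:=`(is_decoy = FALSE, is_secondary = TRUE,
                          p_value = NA_real_, q_value = NA_real_)]
    s
  } else NULL
  feats <- rbindlist(list(kept, secondary), use.names = TRUE, fill = TRUE)
  if (nrow(feats)) {
    feats[, feature_id := paste0(owner_id, "@", apex_fraction)]
  }
  list(features = feats[], primaries_all = scored[], n_skipped = tg$n_skipped)
}

#' Collapse redundant complex features across queries
#'
#' Overlapping queries (e.g. CORUM and a STRING cluster of the same
#' machine) detect near-identical features. Features whose apexes lie
#' within `distance_cutoff` fractions of each other and whose subunit sets
#' overlap (Jaccard > 0) are grouped by single linkage; each group is
#' represented by its feature with the largest subunit set (ties: highest
#' coelution score).
#'
#' @param features detected complex feature table.
#' @param distance_cutoff maximum apex distance (fractions) for linking.
#' @param rt_height recorded for parity with the detection parameters; 0
#'   means no additional peak-merge tolerance beyond the apex distance.
#' @return list: `collapsed` (representative features with `group_id` and
#'   `n_collapsed`), `mapping` (feature_id -> representative feature_id).
#' @export
collapse_features <- function(features, distance_cutoff = 1.25, rt_height = 0) {
  f <- copy(as.data.table(features))
  if (!nrow(f)) {
    return(list(collapsed = f, mapping = data.table(feature_id = character(0),
                                                    representative = character(0))))
  }
  n <- nrow(f)
  edges <- list()
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    if (abs(f$apex_fraction[i] - f$apex_fraction[j]) <= distance_cutoff + rt_height &&
        length(intersect(f$members[[i]], f$members[[j]])) > 0L) {
      edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  comp <- if (length(edges)) {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    igraph::components(g)$membership[seq_len(n)]
  } else seq_len(n)
  f[, group_id := comp]
  setorder(f, group_id, -n_members, -coelution_score)
  collapsed <- f[, c(.SD[1L], .(n_collapsed = .N)), by = group_id]
  mapping <- merge(f[, .(feature_id, group_id)],
                   collapsed[, .(group_id, representative = feature_id)],
                   by = "group_id")[, .(feature_id, representative)]
  list(collapsed = collapsed[], mapping = mapping[])
}

#' Complex-level differential intensity analysis
#'
#' Within each (collapsed) complex feature range, peptide-level tests are
#' run exactly as in [feature_differential()], aggregated first to each
#' subunit protein and then -- by the same median / order-statistic rule --
#' to the complex. Benjamini-Hochberg adjustment runs across complexes.
#'
#' @param features complex feature table (members are subunit proteins).
#' @param traces [peptide_traces()] (peptide level, with protein mapping).
#' @param design design matrix.
#' @param condition_a,condition_b conditions compared.
#' @param seed imputation seed.
#' @param log2fc_min,alpha significance thresholds.
#' @return data.table of complex-level `DifferentialResult` rows.
#' @export
complex_differential <- function(features, traces, design, condition_a, condition_b,
                                 seed = NULL, log2fc_min = 1, alpha = 0.05) {
  des <- as.data.table(design)[condition %in% c(condition_a, condition_b)]
  dt <- as.data.table(traces)[sample_id %in% des$sample_id]
  samples <- sort(des$sample_id)
  a_idx <- which(samples %in% des[condition == condition_a, sample_id])
  b_idx <- which(samples %in% des[condition == condition_b, sample_id])
  map <- unique(dt[, .(protein_id, peptide_id)])
  rows <- with_seed(seed, {
    lapply(seq_len(nrow(features)), function(i) {
      f <- features[i]
      prot_stats <- lapply(intersect(f$members[[1L]], unique(map$protein_id)), function(pr) {
        peps <- map[protein_id == pr, sort(peptide_id)]
        mats <- range_member_matrix(dt[peptide_id %in% peps], peps,
                                    f$left_boundary, f$right_boundary, samples)
        if (!length(mats)) return(NULL)
        st <- lapply(mats, member_test, a_idx = a_idx, b_idx = b_idx)
        agg <- aggregate_to_parent(vapply(st, `[[`, numeric(1), "log2FC"),
                                   vapply(st, `[[`, numeric(1), "p_value"))
        data.table(log2FC = agg$log2FC, p_value = agg$p_value,
                   mean_a = sum(vapply(st, `[[`, numeric(1), "mean_a")),
                   mean_b = sum(vapply(st, `[[`, numeric(1), "mean_b")))
      })
      prot_stats <- rbindlist(prot_stats[!vapply(prot_stats, is.null, logical(1))])
      if (!nrow(prot_stats)) return(NULL)
      agg <- aggregate_to_parent(prot_stats$log2FC, prot_stats$p_value)
      data.table(entity_id = f$feature_id, owner_id = f$owner_id, level = "complex",
                 log2FC = agg$log2FC, p_value = agg$p_value,
                 mean_intensity_A = sum(prot_stats$mean_a),
                 mean_intensity_B = sum(prot_stats$mean_b),
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
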