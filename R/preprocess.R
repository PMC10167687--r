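#' Impute single-fraction internal gaps by spline interpolation
#'
#' A missing cell is eligible only when both the previous and the following
#' fraction of the same peptide and sample are measured. Eligible gaps are
#' filled from a cubic interpolating spline fitted per (peptide, sample)
#' across the measured fractions, floored at zero; traces with fewer than 4
#' measured points fall back to linear interpolation. Measured cells are
#' never altered and imputed cells are flagged in the `imputed` column.
#'
#' @param traces [peptide_traces()].
#' @return `peptide_traces` with imputed cells appended.
#' @export
impute_internal_gaps <- function(traces) {
  stopifnot(inherits(traces, "peptide_traces"))
  nf <- n_fractions(traces)
  new_rows <- traces[, {
    pf <- fraction_index
    gaps <- setdiff(seq_len(nf), pf)
    gaps <- gaps[(gaps - 1L) %in% pf & (gaps + 1L) %in% pf]
    if (length(gaps) && length(pf) >= 2L) {
      vals <- if (length(pf) >= 4L) {
        splinefun(pf, intensity, method = "fmm")(gaps)
      } else {
        approx(pf, intensity, xout = gaps)$y
      }
      .(fraction_index = gaps, intensity = pmax(vals, 0))
    } else {
      .(fraction_index = integer(0), intensity = numeric(0))
    }
  }, by = .(peptide_id, protein_id, sample_id)]
  if (nrow(new_rows)) {
    new_rows[, imputed := TRUE]
    out <- rbind(as.data.table(traces), new_rows, use.names = TRUE)
  } else {
    out <- as.data.table(traces)
  }
  peptide_traces(out, nf)
}

#' Cyclic loess normalization across samples
#'
#' Equalizes intensity scale across conditions and replicates by repeated
#' pairwise MA-plot loess correction on log2 intensities: for every sample
#' pair, a loess curve of M = x_i - x_j on A = (x_i + x_j)/2 is fitted over
#' the peptide-by-fraction cells measured in both samples, and half the
#' fitted M is subtracted from sample i and added to sample j; the pass over
#' all pairs is repeated `cycles` times. Cells measured in only one sample
#' of a pair are untouched by that pair. Returns intensities on the original
#' linear scale.
#'
#' @param traces [peptide_traces()] (imputed; intensities > 0 where measured).
#' @param cycles number of passes over all sample pairs.
#' @param span loess smoothing span.
#' @param min_shared a sample sharing fewer than this many measured cells with
#'   every other sample is passed through unnormalized, with a warning.
#' @return normalized `peptide_traces`.
#' @export
cyclic_loess_normalize <- function(traces, cycles = 3L, span = 0.7,
                                   min_shared = 100L) {
  stopifnot(inherits(traces, "peptide_traces"))
  dt <- as.data.table(traces)
  samps <- trace_samples(traces)
  if (length(samps) < 2L) stop2("need at least 2 samples to normalize")
  pos <- dt$intensity > 0
  cells <- dt[pos, .(peptide_id, fraction_index, sample_id, value = log2(intensity))]
  wide <- dcast(cells, peptide_id + fraction_index ~ sample_id, value.var = "value")
  m <- as.matrix(wide[, samps, with = FALSE])

  shared <- crossprod(!is.na(m))
  diag(shared) <- 0L
  ok <- apply(shared, 1L, max) >= min_shared
  if (!all(ok)) {
    warning("samples passed through unnormalized (too few shared cells): ",
            paste(samps[!ok], collapse = ", "))
  }
  use <- which(ok)
  if (length(use) >= 2L) {
    for (cyc in seq_len(cycles)) {
      for (a in seq_along(use)[-length(use)]) {
        for (b in seq((a + 1L), length(use))) {
          i <- use[a]; j <- use[b]
          both <- which(!is.na(m[, i]) & !is.na(m[, j]))
          if (length(both) < 10L) next
          M <- m[both, i] - m[both, j]
          A <- (m[both, i] + m[both, j]) / 2
          fit <- lowess(A, M, f = span)
          mfit <- approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
          m[both, i] <- m[both, i] - mfit / 2
          m[both, j] <- m[both, j] + mfit / 2
        }
      }
    }
  }
  norm <- data.table(peptide_id = rep(wide$peptide_id, length(samps)),
                     fraction_index = rep(wide$fraction_index, length(samps)),
                     sample_id = rep(samps, each = nrow(wide)),
                     value = as.vector(m))[!is.na(value)]
  out <- merge(dt, norm, by = c("peptide_id", "sample_id", "fraction_index"),
               all.x = TRUE)
  out[!is.na(value), intensity := 2^value]
  out[, value := NULL]
  peptide_traces(out, n_fractions(traces))
}

#' Remove low-confidence peptides
#'
#' Applies, in order: (1) detection consistency -- a peptide is kept only if
#' some single sample contains at least `min_consecutive` consecutive
#' detected fractions; (2)+(3) sibling-peptide coelution -- Pearson
#' correlation between every pair of same-protein peptides, computed on
#' full-grid traces concatenated across all samples (missing cells as 0); a
#' peptide needs a maximum sibling correlation >= `max_sibling_corr_min` and
#' a mean sibling correlation >= `avg_sibling_corr_min`. Proteins left with
#' fewer than two peptides are removed (protein inference requires more than
#' one proteotypic peptide).
#'
#' @param traces [peptide_traces()] (imputed/normalized).
#' @param design design matrix (unused by the rules themselves; retained so
#'   the reported grouping matches the experiment).
#' @param min_consecutive minimum consecutive detections in one sample.
#' @param max_sibling_corr_min threshold on the best sibling correlation.
#' @param avg_sibling_corr_min threshold on the mean sibling correlation.
#' @return list with `traces` (filtered `peptide_traces`) and `report`
#'   (counts and per-rule drop lists).
#' @export
filter_peptides <- function(traces, design = NULL, min_consecutive = 3L,
                            max_sibling_corr_min = 0.5,
                            avg_sibling_corr_min = 0.2) {
  stopifnot(inherits(traces, "peptide_traces"))
  dt <- as.data.table(traces)
  n_input <- uniqueN(dt$peptide_id)

  ## rule 1: >= min_consecutive consecutive detections in any one sample
  cons <- dt[, .(ok = {
    runs <- vapply(split(fraction_index, sample_id), function(f) {
      longest_run(seq_len(n_fractions(traces)) %in% f)
    }, integer(1))
    any(runs >= min_consecutive)
  }), by = .(peptide_id)]
  drop1 <- cons[ok == FALSE, peptide_id]
  dt1 <- dt[!peptide_id %in% drop1]

  ## rules 2+3: sibling correlations on concatenated full-grid traces
  drop2 <- character(0)
  if (nrow(dt1)) {
    pt1 <- peptide_traces(dt1, n_fractions(traces))
    prot_pep <- unique(dt1[, .(protein_id, peptide_id)])
    for (prot in unique(prot_pep$protein_id)) {
      peps <- prot_pep[protein_id == prot, sort(peptide_id)]
      if (length(peps) < 2L) next  # handled by the <2 peptide rule below
      m <- trace_matrix(pt1[peptide_id %in% peps], fill = 0, members = peps)
      cc <- suppressWarnings(cor(t(m)))
      diag(cc) <- NA
      maxc <- apply(cc, 1L, max, na.rm = TRUE)
      avgc <- rowMeans(cc, na.rm = TRUE)
      bad <- !is.finite(maxc) | maxc < max_sibling_corr_min |
        !is.finite(avgc) | avgc < avg_sibling_corr_min
      drop2 <- c(drop2, peps[bad])
    }
  }
  dt2 <- dt1[!peptide_id %in% drop2]

  ## proteins need > 1 surviving proteotypic peptide
  npep <- unique(dt2[, .(protein_id, peptide_id)])[, .N, by = protein_id]
  drop3_prot <- npep[N < 2L, protein_id]
  lone <- unique(dt2[, .(protein_id, peptide_id)])[protein_id %in% drop3_prot, peptide_id]
  dt3 <- dt2[!protein_id %in% drop3_prot]

  report <- list(
    n_input_peptides = n_input,
    n_after_consecutive = n_input - length(drop1),
    n_after_sibling_corr = n_input - length(drop1) - length(unique(drop2)),
    n_after_min_peptides = uniqueN(dt3$peptide_id),
    dropped_consecutive = sort(drop1),
    dropped_sibling_corr = sort(unique(drop2)),
    dropped_min_peptides = sort(lone)
  )
  list(traces = peptide_traces(dt3, n_fractions(traces)), report = report)
}

#' Protein quantification from top-intensity peptides
#'
#' Per protein, peptides are ranked by their intensity summed over all
#' samples and fractions; the same `top_n` peptides (ties broken by
#' lexicographic peptide id) are selected for every sample and summed
#' fractionwise into the protein trace.
#'
#' @param traces filtered [peptide_traces()].
#' @param top_n number of peptides summed per protein.
#' @return [protein_traces()] with the `selected_peptides` attribute.
#' @export
quantify_proteins <- function(traces, top_n = 2L) {
  stopifnot(inherits(traces, "peptide_traces"))
  dt <- as.data.table(traces)
  totals <- dt[, .(total = sum(intensity)), by = .(protein_id, peptide_id)]
  setorder(totals, protein_id, -total, peptide_id)
  totals[, rank_ := seq_len(.N), by = protein_id]
  sel <- totals[rank_ <= top_n, .(protein_id, peptide_id, rank = rank_)]
  sub <- dt[sel[, .(protein_id, peptide_id)], on = c("protein_id", "peptide_id")]
  prot <- sub[, .(intensity = sum(intensity)),
              by = .(protein_id, sample_id, fraction_index)]
  protein_traces(prot, n_fractions(traces), selected_peptides = sel)
}
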