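#' Global quality-control summary
#'
#' Reproducibility diagnostics across samples: per-entity coefficient of
#' variation (sd/mean) of peak areas within each condition and across all
#' samples; a sample-by-sample Spearman correlation matrix with an
#' average-linkage dendrogram ordering; and per-fraction peptide and
#' protein counts. When a feature table is supplied the entities are
#' feature peak areas (per-sample sums of member intensities inside the
#' feature boundaries); otherwise per-protein total intensities are used.
#'
#' @param traces [peptide_traces()] or [protein_traces()].
#' @param design design matrix (>= 2 samples for the correlation matrix).
#' @param features optional feature table from [find_features()].
#' @return list: `cv` (entity_id, condition -- incl. "all" --, cv, n),
#'   `areas` (entity x sample matrix), `correlation` (Spearman matrix or
#'   NULL), `sample_order` (dendrogram order), `fraction_counts`.
#' @export
qc_summary <- function(traces, design, features = NULL) {
  dt <- as.data.table(traces)
  des <- as.data.table(design)
  idc <- id_col(dt)
  samps <- sort(des$sample_id)

  ## entity x sample peak-area matrix
  if (!is.null(features) && nrow(features)) {
    areas <- matrix(NA_real_, nrow(features), length(samps),
                    dimnames = list(features$feature_id, samps))
    for (i in seq_len(nrow(features))) {
      f <- features[i]
      sub <- dt[get(idc) %in% f$members[[1L]] &
                  fraction_index >= f$left_boundary &
                  fraction_index <= f$right_boundary,
                .(area = sum(intensity)), by = sample_id]
      areas[i, sub$sample_id] <- sub$area
    }
    areas[is.na(areas)] <- 0
  } else {
    ent <- if (idc == "peptide_id") "protein_id" else idc
    tot <- dt[, .(area = sum(intensity)), by = c(ent, "sample_id")]
    wide <- dcast(tot, stats::as.formula(paste(ent, "~ sample_id")),
                  value.var = "area", fill = 0)
    areas <- as.matrix(wide, rownames = ent)
    areas <- areas[, samps, drop = FALSE]
  }

  groups <- c(split(des$sample_id, des$condition), list(all = des$sample_id))
  cv <- rbindlist(lapply(names(groups), function(gn) {
    m <- areas[, intersect(samps, groups[[gn]]), drop = FALSE]
    data.table(entity_id = rownames(areas), condition = gn,
               cv = apply(m, 1L, function(x) if (mean(x) > 0) sd(x) / mean(x) else NA_real_),
               n = ncol(m))
  }))

  correlation <- NULL; sample_order <- samps
  if (length(samps) >= 2L) {
    correlation <- suppressWarnings(cor(areas, method = "spearman"))
    if (length(samps) > 2L && all(is.finite(correlation))) {
      hc <- hclust(as.dist(1 - correlation), method = "average")
      sample_order <- samps[hc$order]
    }
  } else {
    warning("single sample: correlation matrix omitted")
  }

  fc <- dt[, .(n_peptides = if (idc == "peptide_id") uniqueN(peptide_id) else NA_integer_,
               n_proteins = uniqueN(protein_id)),
           by = .(sample_id, fraction_index)]
  setorder(fc, sample_id, fraction_index)

  list(cv = cv[], areas = areas, correlation = correlation,
       sample_order = sample_order, fraction_counts = fc[])
}
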