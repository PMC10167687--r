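#' Construct a peptide trace set
#'
#' The universal input container: long-format peptide-level SEC elution
#' intensities. Only measured (or imputed) cells are stored; a cell absent
#' from the table is missing, which is distinct from an intensity of zero.
#'
#' @param data data.frame/data.table with columns `peptide_id`, `protein_id`,
#'   `sample_id`, `fraction_index`, `intensity` and optionally `imputed`.
#' @param n_fractions number of fractions on the (contiguous, 1-based) grid
#'   shared by all samples.
#' @return An object of class `peptide_traces`: a data.table plus the
#'   `n_fractions` attribute.
#' @export
peptide_traces <- function(data, n_fractions) {
  dt <- as.data.table(data)
  req <- c("peptide_id", "protein_id", "sample_id", "fraction_index", "intensity")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop2("missing columns: ", paste(miss, collapse = ", "))
  if (!"imputed" %in% names(dt)) dt[, imputed := FALSE]
  dt <- dt[, c(req, "imputed"), with = FALSE]
  dt[, fraction_index := as.integer(fraction_index)]
  n_fractions <- as.integer(n_fractions)
  if (nrow(dt)) {
    if (dt[, any(fraction_index < 1L | fraction_index > n_fractions)]) {
      stop2("fraction_index outside 1..", n_fractions)
    }
    if (dt[, any(!is.finite(intensity) | intensity < 0)]) {
      stop2("intensities must be finite and non-negative")
    }
    dup <- dt[duplicated(dt, by = c("peptide_id", "sample_id", "fraction_index"))]
    if (nrow(dup)) {
      stop2("duplicate (peptide, sample, fraction) keys, e.g.: ",
            paste(utils::head(unique(dup[, paste(peptide_id, sample_id,
                  fraction_index, sep = "/")]), 5L), collapse = ", "))
    }
    multi <- dt[, uniqueN(protein_id), by = peptide_id][V1 > 1L, peptide_id]
    if (length(multi)) {
      stop2("peptides mapped to more than one protein: ",
            paste(utils::head(multi, 5L), collapse = ", "))
    }
  }
  setkey(dt, protein_id, peptide_id, sample_id, fraction_index)
  setattr(dt, "n_fractions", n_fractions)
  setattr(dt, "class", c("peptide_traces", class(data.table())))
  dt[]
}

#' Read peptide traces from a TSV file
#'
#' Rows with `fraction_index > fraction_max` are dropped (late SEC fractions
#' carry sub-monomeric material); rows with zero or missing intensity are
#' recorded as missing cells rather than zeros.
#'
#' @param path TSV with header `peptide_id`, `protein_id`, `sample_id`,
#'   `fraction_index`, `intensity`.
#' @param fraction_max last fraction retained; the grid becomes
#'   `1..fraction_max` for every sample.
#' @return [peptide_traces()] object.
#' @export
read_traces <- function(path, fraction_max = 49L) {
  dt <- fread(path, sep = "\t", colClasses = list(
    character = c("peptide_id", "protein_id", "sample_id")))
  dt <- dt[fraction_index >= 1L & fraction_index <= fraction_max]
  dt <- dt[!is.na(intensity) & intensity > 0]
  peptide_traces(dt, n_fractions = fraction_max)
}

#' Write a trace set to TSV
#' @param x `peptide_traces` or `protein_traces`.
#' @param path output file.
#' @export
write_traces <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t")
  invisible(path)
}

#' Read an experimental design matrix
#'
#' @param path TSV with header `sample_id`, `condition`, `replicate`.
#' @param samples optional character vector of sample ids that must match.
#' @return data.table keyed by sample_id.
#' @export
read_design <- function(path, samples = NULL) {
  d <- fread(path, sep = "\t", colClasses = list(character = c("sample_id", "condition")))
  design_matrix(d, samples)
}

#' @rdname read_design
#' @param data data.frame with the design columns.
#' @export
design_matrix <- function(data, samples = NULL) {
  d <- as.data.table(data)
  req <- c("sample_id", "condition", "replicate")
  if (!all(req %in% names(d))) stop2("design needs columns ", paste(req, collapse = ", "))
  d[, replicate := as.integer(replicate)]
  if (anyDuplicated(d$sample_id)) stop2("duplicate sample_id in design")
  if (!is.null(samples) && !setequal(d$sample_id, samples)) {
    stop2("design samples do not match trace samples")
  }
  setkey(d, sample_id)
  d[]
}

#' Read the protein monomeric molecular weight annotation
#' @param path TSV with header `protein_id`, `mw_kda`.
#' @return data.table (protein_id, mw_kda), mw in kDa.
#' @export
read_mw_annotation <- function(path) {
  m <- fread(path, sep = "\t", colClasses = list(character = "protein_id"))
  if (!all(c("protein_id", "mw_kda") %in% names(m))) {
    stop2("annotation needs columns protein_id, mw_kda")
  }
  if (m[, any(!is.finite(mw_kda) | mw_kda <= 0)]) stop2("monomeric MW must be > 0")
  unique(m[, .(protein_id, mw_kda)])
}

#' Number of fractions on the grid
#' @param x trace set.
#' @export
n_fractions <- function(x) attr(x, "n_fractions", exact = TRUE)

#' Sample identifiers of a trace set
#' @param x trace set.
#' @export
trace_samples <- function(x) sort(unique(x$sample_id))

# id column for the level of a trace table
id_col <- function(x) if ("peptide_id" %in% names(x)) "peptide_id" else "protein_id"

#' Dense member-by-fraction intensity matrix
#'
#' Rows are members (peptides or proteins), columns the fraction grid of one
#' sample, or the concatenated grids of all samples (ordered by sample id).
#'
#' @param x trace set.
#' @param sample one sample id, or NULL for the concatenation of all samples.
#' @param fill value for missing cells (0 for correlation work, NA to keep
#'   missingness explicit).
#' @param members optional member ids fixing row order (absent ids give rows
#'   of `fill`).
#' @return numeric matrix with member rownames.
#' @export
trace_matrix <- function(x, sample = NULL, fill = 0, members = NULL) {
  nf <- n_fractions(x)
  idc <- id_col(x)
  dt <- as.data.table(x)
  samps <- if (is.null(sample)) trace_samples(x) else sample
  if (is.null(members)) members <- sort(unique(dt[[idc]]))
  mat <- matrix(fill, nrow = length(members), ncol = nf * length(samps),
                dimnames = list(members, NULL))
  for (k in seq_along(samps)) {
    sub <- dt[sample_id == samps[k] & get(idc) %in% members]
    if (nrow(sub)) {
      mat[cbind(match(sub[[idc]], members), (k - 1L) * nf + sub$fraction_index)] <-
        sub$intensity
    }
  }
  mat
}

#' Construct a protein trace set
#' @param data columns `protein_id`, `sample_id`, `fraction_index`, `intensity`.
#' @param n_fractions fraction grid size.
#' @param selected_peptides data.table (protein_id, peptide_id, rank) recording
#'   which peptides were summed; may be NULL.
#' @export
protein_traces <- function(data, n_fractions, selected_peptides = NULL) {
  dt <- as.data.table(data)[, .(protein_id, sample_id,
                                fraction_index = as.integer(fraction_index), intensity)]
  setkey(dt, protein_id, sample_id, fraction_index)
  setattr(dt, "n_fractions", as.integer(n_fractions))
  setattr(dt, "selected_peptides", selected_peptides)
  setattr(dt, "class", c("protein_traces", class(data.table())))
  dt[]
}

#' @export
print.peptide_traces <- function(x, ...) {
  cat(sprintf("<peptide_traces> %d peptides / %d proteins / %d samples / %d fractions\n",
              uniqueN(x$peptide_id), uniqueN(x$protein_id),
              uniqueN(x$sample_id), n_fractions(x)))
  NextMethod()
}

#' @export
print.protein_traces <- function(x, ...) {
  cat(sprintf("<protein_traces> %d proteins / %d samples / %d fractions\n",
              uniqueN(x$protein_id), uniqueN(x$sample_id), n_fractions(x)))
  NextMethod()
}
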