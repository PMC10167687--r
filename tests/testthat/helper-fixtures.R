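library(data.table)

# long-format rows for one peptide trace in one sample
pep_rows <- function(peptide, protein, sample, fractions, intensity) {
  data.table(peptide_id = peptide, protein_id = protein, sample_id = sample,
             fraction_index = as.integer(fractions), intensity = intensity)
}

# dense Gaussian trace rows on a grid (values below `floor` omitted)
gauss_rows <- function(peptide, protein, sample, pos, sigma = 1.5, height = 100,
                       nf = 49L, floor = 0.05) {
  x <- height * exp(-(seq_len(nf) - pos)^2 / (2 * sigma^2))
  keep <- x >= floor
  pep_rows(peptide, protein, sample, which(keep), x[keep])
}

# traces where every peptide of every protein is an identical Gaussian
toy_protein_traces <- function(proteins, positions, samples = c("S1", "S2"),
                               n_pep = 3L, nf = 49L, height = 100) {
  rows <- list()
  for (i in seq_along(proteins)) {
    for (p in seq_len(n_pep)) {
      for (s in samples) {
        rows[[length(rows) + 1L]] <- gauss_rows(
          sprintf("%s_pep%02d", proteins[i], p), proteins[i], s,
          positions[i], nf = nf, height = height)
      }
    }
  }
  peptide_traces(rbindlist(rows), nf)
}

# linear calibration used throughout the tests: log10(MW) = -0.05 f + 3
toy_calibration <- function(slope = -0.05, intercept = 3) {
  f <- c(5, 15, 25, 35, 45)
  suppressWarnings(fit_calibration(data.table(fraction_index = f,
                                              mw_kda = 10^(slope * f + intercept))))
}

toy_design <- function(conditions = c("A", "B"), replicates = 3L) {
  d <- CJ(condition = conditions, replicate = seq_len(replicates), sorted = FALSE)
  d[, sample_id := sprintf("%s_R%d", condition, replicate)]
  design_matrix(d[, .(sample_id, condition, replicate)])
}

write_tsv <- function(dt, path = tempfile(fileext = ".tsv")) {
  fwrite(dt, path, sep = "\t")
  path
}
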