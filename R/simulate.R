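#' Configuration for the synthetic SEC-MS generator
#'
#' Describes a multi-condition cofractionation experiment: proteins elute as
#' Gaussian peaks positioned by apparent molecular weight through the
#' fraction calibration, complex subunits share an assembled peak at the
#' complex MW while the remainder of each protein's mass sits at its
#' monomer position, peptides report the protein trace through a fixed
#' lognormal response factor with multiplicative lognormal cell noise, and
#' low-intensity cells drop out with logistic probability.
#'
#' @param n_fractions SEC grid size.
#' @param slope,intercept fraction calibration, log10(MW kDa) = slope *
#'   fraction + intercept.
#' @param conditions condition labels.
#' @param replicates biological replicates per condition.
#' @param n_complexes number of true complexes.
#' @param complex_size subunits per complex.
#' @param n_monomers additional monomer-only proteins.
#' @param peptides_per_protein range of proteotypic peptides per protein.
#' @param peak_sigma Gaussian peak width (fractions).
#' @param base_abundance median protein peak height (arbitrary units).
#' @param abundance_sdlog lognormal spread of protein abundances.
#' @param response_sdlog lognormal spread of peptide response factors.
#' @param noise_cv coefficient of variation of the multiplicative
#'   measurement noise per cell.
#' @param dropout_midpoint intensity at which the dropout probability is
#'   50%; set to 0 to disable dropout.
#' @param dropout_steepness logistic width (log2 intensity units) of the
#'   dropout curve.
#' @param detection_floor cells below this intensity are never reported.
#' @param amf_base assembled mass fraction of complex subunits in the
#'   reference state.
#' @param n_amf_shift number of complex subunits whose assembled fraction
#'   shifts between the first and second condition.
#' @param amf_shift size of that shift (second minus first condition).
#' @param n_abundance_change number of complexes whose member proteins
#'   change total abundance in the second condition.
#' @param log2fc log2 fold-change of that abundance change (condition 2
#'   over condition 1).
#' @return `sim_config` list.
#' @export
sim_config <- function(n_fractions = 49L, slope = -0.0542, intercept = 3.6542,
                       conditions = c("C1", "C2", "C3"), replicates = 3L,
                       n_complexes = 10L, complex_size = 3L, n_monomers = 20L,
                       peptides_per_protein = 3:6, peak_sigma = 1.5,
                       base_abundance = 100, abundance_sdlog = 0.5,
                       response_sdlog = 0.5, noise_cv = 0.1,
                       dropout_midpoint = 0.5, dropout_steepness = 1,
                       detection_floor = 0.05, amf_base = 0.6,
                       n_amf_shift = 0L, amf_shift = 0.4,
                       n_abundance_change = 0L, log2fc = 2) {
  cfg <- as.list(environment())
  if (slope >= 0) stop2("calibration slope must be negative")
  if (amf_base < 0 || amf_base > 1) stop2("amf_base must be in [0,1]")
  if (length(conditions) < 2L && (n_amf_shift > 0L || n_abundance_change > 0L)) {
    stop2("planted effects need >= 2 conditions")
  }
  structure(cfg, class = "sim_config")
}

# gaussian component on the fraction grid: height at apex = h
gauss_peak <- function(grid, pos, sigma, h) h * exp(-(grid - pos)^2 / (2 * sigma^2))

#' Simulate a multi-condition SEC-MS dataset with ground truth
#'
#' @param config [sim_config()].
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return list: `traces` ([peptide_traces()]), `design`, `mw` (protein MW
#'   annotation), `hypotheses` (true complexes, [complex_hypotheses()]
#'   layout), `calibration` ([fit_calibration()] object refit from the
#'   configured line), `truth` (per-protein design values: positions,
#'   per-condition assembled fraction and abundance, planted effects).
#' @export
simulate_secms <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(seed, {
    ## calibration object from the configured log-linear law
    std_f <- c(5, 15, 25, 35, 45)
    cal <- fit_calibration(data.table(
      fraction_index = std_f, mw_kda = 10^(cfg$slope * std_f + cfg$intercept)))

    ## protein roster
    n_cplx_prot <- cfg$n_complexes * cfg$complex_size
    n_prot <- n_cplx_prot + cfg$n_monomers
    prot_ids <- sprintf("P%04d", seq_len(n_prot))
    mmw <- pmin(pmax(exp(stats::rnorm(n_prot, log(60), 0.35)), 20), 150)
    complex_of <- c(rep(sprintf("CPX%03d", seq_len(cfg$n_complexes)),
                        each = cfg$complex_size),
                    rep(NA_character_, cfg$n_monomers))

    proteins <- data.table(protein_id = prot_ids, mmw = mmw, complex_id = complex_of)
    cplx <- proteins[!is.na(complex_id),
                     .(subunits = list(protein_id),
                       complex_mw = max(4 * max(mmw), sum(mmw))), by = complex_id]
    ## keep complex peaks on the measured grid (>= fraction 3)
    mw_at_f3 <- 10^(cfg$slope * 3 + cfg$intercept)
    cplx[, complex_mw := pmin(complex_mw, mw_at_f3)]
    if (cplx[, any(complex_mw < vapply(subunits, function(s)
      max(proteins[protein_id %in% s, mmw]), numeric(1)))]) {
      stop2("complex MW below largest subunit monomeric MW")
    }

    proteins <- merge(proteins, cplx[, .(complex_id, complex_mw)],
                      by = "complex_id", all.x = TRUE)
    setorder(proteins, protein_id)
    proteins[, f_mono := mw_to_fraction(cal, mmw)]
    proteins[, f_complex := NA_real_]
    proteins[!is.na(complex_mw), f_complex := mw_to_fraction(cal, complex_mw)]
    proteins[, abundance := exp(stats::rnorm(.N, log(cfg$base_abundance),
                                             cfg$abundance_sdlog))]

    ## per-condition design values
    nc <- length(cfg$conditions)
    amf_design <- matrix(0, n_prot, nc, dimnames = list(prot_ids, cfg$conditions))
    amf_design[!is.na(proteins$complex_id), ] <- cfg$amf_base
    ## shifted subunits keep their roster AMF in condition 2 and sit lower by
    ## `amf_shift` in condition 1 (e.g. 0.3 -> 0.7 with base 0.7, shift 0.4)
    shifted <- head(proteins[!is.na(complex_id), protein_id], cfg$n_amf_shift)
    if (length(shifted)) {
      lo <- max(cfg$amf_base - cfg$amf_shift, 0.02)
      amf_design[shifted, 1L] <- lo
      amf_design[shifted, 2L] <- lo + cfg$amf_shift
    }
    fold <- matrix(1, n_prot, nc, dimnames = list(prot_ids, cfg$conditions))
    ## abundance changes are planted from the end of the roster so they do
    ## not overlap the AMF-shifted subunits
    changed_cplx <- tail(cplx$complex_id, cfg$n_abundance_change)
    changed_prot <- proteins[complex_id %in% changed_cplx, protein_id]
    if (length(changed_prot)) fold[changed_prot, 2L] <- 2^cfg$log2fc

    ## peptides
    npep <- sample(cfg$peptides_per_protein, n_prot, replace = TRUE)
    pep_tab <- proteins[rep(seq_len(n_prot), npep), .(protein_id)]
    pep_tab[, peptide_id := sprintf("%s_pep%02d", protein_id,
                                    unlist(lapply(npep, seq_len)))]
    pep_tab[, response := exp(stats::rnorm(.N, 0, cfg$response_sdlog))]

    ## design matrix
    design <- CJ(condition = cfg$conditions, replicate = seq_len(cfg$replicates),
                 sorted = FALSE)
    design[, sample_id := sprintf("%s_R%d", condition, replicate)]
    setcolorder(design, c("sample_id", "condition", "replicate"))

    grid <- seq_len(cfg$n_fractions)
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    acc_pep <- list(); acc_prot <- list(); acc_samp <- list()
    acc_fr <- list(); acc_int <- list()
    k <- 0L
    pep_split <- split(pep_tab, by = "protein_id")
    for (ip in seq_len(n_prot)) {
      pr <- proteins[ip]
      peps <- pep_split[[pr$protein_id]]
      for (is in seq_len(nrow(design))) {
        cond <- design$condition[is]
        a <- amf_design[pr$protein_id, cond]
        amp <- pr$abundance * fold[pr$protein_id, cond]
        tr <- gauss_peak(grid, pr$f_mono, cfg$peak_sigma, amp * (1 - a))
        if (a > 0 && !is.na(pr$f_complex)) {
          tr <- tr + gauss_peak(grid, pr$f_complex, cfg$peak_sigma, amp * a)
        }
        for (jp in seq_len(nrow(peps))) {
          x <- tr * peps$response[jp]
          if (cfg$noise_cv > 0) {
            x <- x * exp(stats::rnorm(length(x), -sdlog^2 / 2, sdlog))
          }
          keep <- x >= cfg$detection_floor
          if (cfg$dropout_midpoint > 0 && any(keep)) {
            pmiss <- plogis((log2(cfg$dropout_midpoint) - log2(x[keep])) /
                              cfg$dropout_steepness)
            keep[keep] <- runif(sum(keep)) >= pmiss
          }
          if (any(keep)) {
            k <- k + 1L
            acc_pep[[k]] <- rep(peps$peptide_id[jp], sum(keep))
            acc_prot[[k]] <- rep(pr$protein_id, sum(keep))
            acc_samp[[k]] <- rep(design$sample_id[is], sum(keep))
            acc_fr[[k]] <- grid[keep]
            acc_int[[k]] <- x[keep]
          }
        }
      }
    }
    traces <- peptide_traces(data.table(
      peptide_id = unlist(acc_pep), protein_id = unlist(acc_prot),
      sample_id = unlist(acc_samp), fraction_index = unlist(acc_fr),
      intensity = unlist(acc_int)), cfg$n_fractions)

    truth <- list(
      proteins = proteins[, .(protein_id, complex_id, mmw, complex_mw,
                              f_mono, f_complex, abundance)],
      amf = amf_design, fold = fold,
      amf_shifted = shifted, abundance_changed = changed_prot,
      changed_complexes = changed_cplx,
      log2fc = cfg$log2fc, amf_shift = cfg$amf_shift)

    list(traces = traces,
         design = design_matrix(design),
         mw = proteins[, .(protein_id, mw_kda = mmw)],
         hypotheses = {
           h <- cplx[, .(complex_id, subunits)]
           h[, n_subunits := lengths(subunits)]
           h[]
         },
         calibration = cal, truth = truth, config = cfg)
  })
}

#' Simulate a dataset with all condition effects removed
#'
#' Same generative process as [simulate_secms()] with every planted effect
#' zeroed; used for type-I error and FDR calibration.
#'
#' @param config [sim_config()].
#' @param seed integer seed.
#' @export
null_dataset <- function(config, seed = 1L) {
  config$n_amf_shift <- 0L
  config$n_abundance_change <- 0L
  simulate_secms(config, seed)
}
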