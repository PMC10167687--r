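test_that("hypothesis reading deduplicates subunits and drops singletons", {
  tab <- data.table(complex_id = c("c1", "c1", "c1", "c1", "c2"),
                    protein_id = c("A", "B", "C", "B", "Z"))
  expect_warning(h <- complex_hypotheses(tab), "c2")
  expect_equal(nrow(h), 1L)
  expect_equal(h$subunits[[1L]], c("A", "B", "C"))
  expect_equal(h$n_subunits, 3L)

  path <- write_tsv(tab[1:4])
  h2 <- read_hypotheses(path)
  expect_equal(h2$subunits, h$subunits)
})

test_that("complex decoys respect the minimum PPI edge distance and the seed", {
  ## path graph a-b-c-d-e: d(a,e) = 4 passes, d(a,c) = 2 fails
  edges <- data.table(protein_a = c("a", "b", "c", "d"),
                      protein_b = c("b", "c", "d", "e"))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  expect_gte(igraph::distances(g, "a", "e")[1, 1], 3)
  expect_lt(igraph::distances(g, "a", "c")[1, 1], 3)

  hyp <- complex_hypotheses(data.table(
    complex_id = rep(c("c1", "c2"), each = 2),
    protein_id = c("a", "b", "c", "d")))
  universe <- letters[1:5]
  dec <- make_complex_decoys(hyp, edges, universe = universe,
                             min_edge_distance = 3L, seed = 5L)
  expect_equal(nrow(dec), nrow(hyp))
  expect_equal(dec$n_subunits, hyp$n_subunits)
  for (i in seq_len(nrow(dec))) {
    if (!dec$relaxed[i]) {
      d <- igraph::distances(g, dec$subunits[[i]], dec$subunits[[i]])
      expect_true(all(d[upper.tri(d)] >= 3))
    }
  }
  expect_identical(dec$subunits, make_complex_decoys(hyp, edges, universe = universe,
                                                     min_edge_distance = 3L,
                                                     seed = 5L)$subunits)

  ## without edges the constraint degrades to no shared target complex
  dec2 <- make_complex_decoys(hyp, NULL, universe = letters[1:10], seed = 2L)
  for (i in seq_len(nrow(dec2))) {
    if (!dec2$relaxed[i]) {
      for (s in hyp$subunits) expect_lt(sum(dec2$subunits[[i]] %in% s), 2L)
    }
  }
})

test_that("complex feature detection applies the molecular-weight plausibility filter", {
  cal <- toy_calibration()
  params <- feature_finder_params()
  ## apex MW at fraction f is 10^(3 - 0.05 f):
  ##   fraction 12 -> ~251 kDa > 2 * 100; fraction 18 -> ~126 kDa <= 200
  mk_case <- function(pos) {
    ## A, B, C coelute at `pos`; D, E, F elute apart (decoy material)
    tr <- toy_protein_traces(c("A", "B", "C", "D", "E", "F"),
                             c(rep(pos, 3), 8, 26, 40), samples = "S1",
                             n_pep = 1L)
    dt <- as.data.table(tr)[, .(protein_id, sample_id, fraction_index, intensity)]
    integrate_traces(protein_traces(dt, 49L))
  }
  hyp <- complex_hypotheses(data.table(complex_id = "cpx",
                                       protein_id = c("A", "B", "C")))
  mw <- data.table(protein_id = c("A", "B", "C", "D", "E", "F"),
                   mw_kda = c(100, 80, 60, 50, 50, 50))
  decoy <- data.table(complex_id = "DECOY_cpx",
                      subunits = list(c("D", "E", "F")), n_subunits = 3L)

  keep <- detect_complex_features(hyp, decoy, mk_case(12), params, cal, mw)
  expect_equal(nrow(keep$features[is_secondary == FALSE]), 1L)
  expect_gt(keep$features$apex_mw[1L], 200)
  expect_equal(keep$features$completeness[1L], 1)

  drop <- detect_complex_features(hyp, decoy, mk_case(18), params, cal, mw)
  expect_equal(nrow(drop$features), 0L)
})

test_that("feature collapsing is single-linkage on apex distance plus subunit overlap", {
  mk <- function(id, apex, members, score = 0.95) {
    data.table(feature_id = id, owner_id = id, members = list(members),
               n_members = length(members), completeness = 1,
               apex_fraction = apex, left_boundary = apex - 2,
               right_boundary = apex + 2, coelution_score = score,
               area = 1, apex_mw = NA_real_)
  }
  ## same subunits, apexes 20 and 20.5: one representative
  f <- rbind(mk("f1", 20, c("A", "B", "C")), mk("f2", 20.5, c("A", "B", "C"), 0.9))
  col <- collapse_features(f)
  expect_equal(nrow(col$collapsed), 1L)
  expect_equal(col$collapsed$feature_id, "f1")
  expect_equal(col$mapping[feature_id == "f2", representative], "f1")

  ## disjoint subunit sets at the same apex stay apart
  f2 <- rbind(mk("f1", 20, c("A", "B")), mk("f2", 20, c("C", "D")))
  expect_equal(nrow(collapse_features(f2)$collapsed), 2L)

  ## chain A~B, B~C with A and C too far apart: one single-linkage group,
  ## matching brute-force connected components
  f3 <- rbind(mk("f1", 20, c("A", "B")), mk("f2", 21, c("B", "C")),
              mk("f3", 22, c("C", "D")))
  col3 <- collapse_features(f3, distance_cutoff = 1.25)
  expect_equal(nrow(col3$collapsed), 1L)
  adj <- matrix(FALSE, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    adj[i, j] <- abs(f3$apex_fraction[i] - f3$apex_fraction[j]) <= 1.25 &&
      length(intersect(f3$members[[i]], f3$members[[j]])) > 0
  }
  reach <- adj
  for (k in 1:3) reach <- reach | (reach %*% reach > 0)
  expect_true(all(reach))

  ## idempotence
  col_again <- collapse_features(col3$collapsed)
  expect_equal(nrow(col_again$collapsed), nrow(col3$collapsed))
  expect_equal(col_again$collapsed$feature_id, col3$collapsed$feature_id)
})

test_that("complex differential aggregates peptides to proteins to the complex", {
  des <- toy_design()
  nf <- 30L
  set.seed(91)
  mk_traces <- function(fold_a) {
    rows <- list()
    for (pr in c("A", "B", "C")) for (p in 1:2) for (s in des$sample_id) {
      fac <- if (startsWith(s, "A")) fold_a else 1
      rows[[length(rows) + 1L]] <- gauss_rows(
        sprintf("%s_pep%d", pr, p), pr, s, 15, nf = nf,
        height = fac * 80 * exp(rnorm(1, 0, 0.03)))
    }
    peptide_traces(rbindlist(rows), nf)
  }
  feat <- data.table(feature_id = "cpx@15", owner_id = "cpx",
                     members = list(c("A", "B", "C")), n_members = 3L,
                     completeness = 1, apex_fraction = 15L, left_boundary = 11L,
                     right_boundary = 19L, coelution_score = 1, area = NA_real_,
                     apex_mw = NA_real_)
  ## every peptide changes 4-fold: complex log2FC = 2
  cd <- complex_differential(feat, mk_traces(4), des, "A", "B", seed = 17L)
  expect_equal(cd$log2FC, 2, tolerance = 0.1)
  expect_true(cd$significant)
  expect_equal(cd$n_members_aggregated, 3L)

  ## appearance pattern: complex present only in condition A
  rows <- list()
  for (pr in c("A", "B", "C")) for (p in 1:2) for (s in des$sample_id) {
    h <- if (startsWith(s, "A")) 80 else 0.2   # condition B at trace baseline
    rows[[length(rows) + 1L]] <- gauss_rows(sprintf("%s_pep%d", pr, p), pr, s,
                                            15, nf = nf, height = h)
  }
  cd2 <- complex_differential(feat, peptide_traces(rbindlist(rows), nf),
                              des, "A", "B", seed = 17L)
  expect_gt(cd2$log2FC, 4)
  expect_lt(cd2$adjusted_p, 0.05)
})
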