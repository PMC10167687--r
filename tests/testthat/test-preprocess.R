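test_that("spline imputation fills only internal single gaps and preserves measured cells", {
  ## flat neighborhood: gap imputed to ~10
  r <- pep_rows("p1", "A", "S1", c(8, 9, 11, 12), 10)
  tr <- impute_internal_gaps(peptide_traces(r, 20L))
  gap <- as.data.table(tr)[fraction_index == 10L]
  expect_true(gap$imputed)
  expect_equal(gap$intensity, 10, tolerance = 1e-6)

  ## linear series (2,4,.,8,10): interpolant gives exactly 6
  r <- pep_rows("p1", "A", "S1", c(1, 2, 4, 5), c(2, 4, 8, 10))
  tr <- impute_internal_gaps(peptide_traces(r, 10L))
  expect_equal(as.data.table(tr)[fraction_index == 3L, intensity], 6)

  ## leading missing fraction and double gaps stay untouched
  r <- pep_rows("p1", "A", "S1", c(2, 3, 6, 7), c(5, 5, 5, 5))
  tr <- impute_internal_gaps(peptide_traces(r, 10L))
  expect_identical(sort(tr$fraction_index), c(2L, 3L, 6L, 7L))

  ## measured cells never altered; imputed count equals eligible-gap count
  set.seed(7)
  rows <- rbindlist(lapply(1:6, function(i) {
    f <- sort(sample(1:30, 18))
    pep_rows(paste0("p", i), "A", "S1", f, runif(18, 1, 50))
  }))
  tr0 <- peptide_traces(rows, 30L)
  tr1 <- impute_internal_gaps(tr0)
  merged <- merge(as.data.table(tr0), as.data.table(tr1),
                  by = c("peptide_id", "sample_id", "fraction_index"))
  expect_equal(merged$intensity.x, merged$intensity.y)
  eligible <- rows[, {
    miss <- setdiff(1:30, fraction_index)
    sum((miss - 1L) %in% fraction_index & (miss + 1L) %in% fraction_index)
  }, by = peptide_id][, sum(V1)]
  expect_equal(sum(tr1$imputed), eligible)
})

test_that("cyclic loess removes constant between-sample offsets and is a no-op on identical samples", {
  set.seed(11)
  base <- rbindlist(lapply(1:40, function(p) {
    pep_rows(paste0("p", p), paste0("prot", (p - 1) %/% 4), "S1",
             1:10, exp(rnorm(10, 3, 1)))
  }))
  mk <- function(factors) {
    rows <- rbindlist(lapply(seq_along(factors), function(i) {
      b <- copy(base)[, `:=`(sample_id = paste0("S", i),
                             intensity = intensity * factors[i])]
    }))
    peptide_traces(rows, 10L)
  }

  ## identical samples: output equals input
  tr <- mk(c(1, 1))
  out <- cyclic_loess_normalize(tr, min_shared = 10L)
  expect_equal(as.data.table(out)$intensity, as.data.table(tr)$intensity,
               tolerance = 1e-9)

  ## sample 2 at 2x: the mean log2 ratio collapses below 0.01
  tr <- mk(c(1, 2))
  out <- cyclic_loess_normalize(tr, min_shared = 10L)
  w <- dcast(as.data.table(out), peptide_id + fraction_index ~ sample_id,
             value.var = "intensity")
  expect_lt(abs(mean(log2(w$S2 / w$S1))), 0.01)

  ## three samples, pairwise constant offsets: all pairwise mean M < 0.01,
  ## and the grand mean of log2 intensities is preserved within 0.1%
  tr <- mk(c(1, 2, 0.5))
  out <- cyclic_loess_normalize(tr, min_shared = 10L)
  w <- dcast(as.data.table(out), peptide_id + fraction_index ~ sample_id,
             value.var = "intensity")
  for (pair in list(c("S1", "S2"), c("S1", "S3"), c("S2", "S3"))) {
    expect_lt(abs(mean(log2(w[[pair[1]]] / w[[pair[2]]]))), 0.01)
  }
  gm0 <- mean(log2(as.data.table(tr)$intensity))
  gm1 <- mean(log2(as.data.table(out)$intensity))
  expect_lt(abs(gm1 - gm0) / abs(gm0), 0.001)

  ## a sample sharing too few cells passes through with a warning
  lone <- rbind(as.data.table(mk(c(1, 2))),
                pep_rows("q1", "protq", "S3", 1:3, c(5, 5, 5)), fill = TRUE)
  expect_warning(out <- cyclic_loess_normalize(peptide_traces(lone, 10L),
                                               min_shared = 10L), "S3")
  expect_equal(as.data.table(out)[sample_id == "S3", intensity], c(5, 5, 5))
})

test_that("peptide filtering applies the consecutive-detection and sibling-correlation rules in order", {
  nf <- 20L
  des <- toy_design()
  samples <- des$sample_id

  ## detections {3,4,5} in a single sample pass rule 1; {3,5,7} everywhere fails
  good <- rbindlist(lapply(samples, function(s) pep_rows("pA", "X", s, 3:5, 10)))
  sparse <- rbindlist(lapply(samples, function(s) pep_rows("pB", "X", s, c(3, 5, 7), 10)))
  twin <- rbindlist(lapply(samples, function(s) pep_rows("pC", "X", s, 3:5, 10)))
  fl <- filter_peptides(peptide_traces(rbind(good, sparse, twin), nf), des)
  expect_setequal(unique(fl$traces$peptide_id), c("pA", "pC"))
  expect_identical(fl$report$dropped_consecutive, "pB")

  ## identical siblings kept (max corr 1), a noise sibling dropped
  set.seed(13)
  ## pN passes rule 1 (4 consecutive detections) but elutes away from its
  ## siblings, so both correlation rules reject it
  noise <- rbindlist(lapply(samples, function(s) {
    pep_rows("pN", "X", s, 10:13, runif(4, 1, 20))
  }))
  fl2 <- filter_peptides(peptide_traces(rbind(good, twin, noise), nf), des)
  expect_setequal(unique(fl2$traces$peptide_id), c("pA", "pC"))
  expect_identical(fl2$report$dropped_sibling_corr, "pN")

  ## counts are monotone through the rule sequence
  rep <- fl2$report
  expect_true(rep$n_after_consecutive <= rep$n_input_peptides)
  expect_true(rep$n_after_sibling_corr <= rep$n_after_consecutive)
  expect_true(rep$n_after_min_peptides <= rep$n_after_sibling_corr)

  ## filtering is idempotent on its own output
  fl3 <- filter_peptides(fl2$traces, des)
  expect_equal(as.data.table(fl3$traces), as.data.table(fl2$traces))
})

test_that("protein quantification selects the same top peptides for every sample", {
  nf <- 10L
  rows <- rbind(
    pep_rows("p1", "A", "S1", 1:5, 20), pep_rows("p1", "A", "S2", 1:5, 20),
    pep_rows("p2", "A", "S1", 1:5, 10), pep_rows("p2", "A", "S2", 1:5, 10),
    pep_rows("p3", "A", "S1", 1:5, 2),  pep_rows("p3", "A", "S2", 1:5, 2))
  pt <- quantify_proteins(peptide_traces(rows, nf), top_n = 2L)
  sel <- attr(pt, "selected_peptides")
  expect_setequal(sel$peptide_id, c("p1", "p2"))
  expect_equal(as.data.table(pt)[sample_id == "S1" & fraction_index == 1L, intensity], 30)

  ## tie at rank 2 resolved lexicographically
  rows2 <- rbind(
    pep_rows("pz", "A", "S1", 1:5, 10), pep_rows("pa", "A", "S1", 1:5, 10),
    pep_rows("pm", "A", "S1", 1:5, 20))
  sel2 <- attr(quantify_proteins(peptide_traces(rows2, nf), 2L), "selected_peptides")
  expect_setequal(sel2$peptide_id, c("pm", "pa"))

  ## single-peptide protein: trace equals the peptide
  rows3 <- pep_rows("p9", "B", "S1", 1:5, 7)
  pt3 <- quantify_proteins(peptide_traces(rows3, nf), 2L)
  expect_equal(as.data.table(pt3)$intensity, rep(7, 5))

  ## invariant to sample ordering
  shuf <- peptide_traces(rows[sample(.N)], nf)
  pt_b <- quantify_proteins(shuf, 2L)
  expect_equal(as.data.table(pt_b), as.data.table(pt))
})
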