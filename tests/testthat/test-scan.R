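brute_force_substrings <- function(reference, min_len, include_full) {
  L <- nchar(reference)
  out <- character(0)
  for (start in 1:L) for (end in start:L) {
    len <- end - start + 1
    if (len >= min_len && (include_full || len < L))
      out <- c(out, paste0(start, ":", end))
  }
  out
}

test_that("fragment patterns enumerate registered substrings, longest first", {
  pats <- fragment_patterns("SIINFEKL", min_len = 3)
  expect_equal(nrow(pats), 20)
  expect_setequal(pats$template[pats$length == 7],
                  c("xIINFEKL", "SIINFEKx"))
  expect_true(all(diff(pats$length) <= 0))  # length descending
  # every fragment sits at its original register
  for (i in seq_len(nrow(pats)))
    expect_equal(substr(pats$template[i], pats$start[i],
                        pats$start[i] + pats$length[i] - 1),
                 pats$fragment[i])
  full <- fragment_patterns("SIINFEKL", min_len = 8, include_full = TRUE)
  expect_equal(full$template, "SIINFEKL")
  expect_error(fragment_patterns("SIINFEKL", min_len = 9), "exceeds")
})

test_that("pattern counts match the brute-force substring oracle", {
  for (L in 3:12) {
    ref <- random_peptides(1, L, seed = 200 + L)
    for (min_len in c(3, L - 1)) {
      if (min_len < 1 || min_len >= L) next
      expect_equal(nrow(fragment_patterns(ref, min_len)),
                   length(brute_force_substrings(ref, min_len, FALSE)))
      # closed form: sum over lengths of (L - l + 1)
      expect_equal(nrow(fragment_patterns(ref, min_len)),
                   sum(L - (min_len:(L - 1)) + 1))
    }
  }
})

test_that("group enumeration expands wildcards exhaustively under the cap", {
  g1 <- enumerate_group("xIINFEKL")
  expect_length(g1, 20)
  expect_false(attr(g1, "sampled"))
  g2 <- enumerate_group("xxINFEKL")
  expect_length(g2, 400)
  expect_equal(attr(g2, "group_size"), 400)
  expect_equal(length(unique(g2)), 400)
  # fixed positions are never altered
  expect_true(all(substr(g2, 3, 8) == "INFEKL"))
  expect_true(all(substr(g1, 2, 8) == "IINFEKL"))
  # no-wildcard pattern is the single peptide itself
  expect_equal(as.character(enumerate_group("SIINFEKL")), "SIINFEKL")
})

test_that("a cap of exactly 20^k reproduces the exhaustive multiset", {
  exhaustive <- enumerate_group("xxINFEKL", cap = 1e9)
  capped <- enumerate_group("xxINFEKL", cap = 400)
  expect_setequal(as.character(capped), as.character(exhaustive))
  sampled <- enumerate_group("xxINFEKL", cap = 100, seed = 2)
  expect_length(sampled, 100)
  expect_true(attr(sampled, "sampled"))
  expect_true(all(substr(sampled, 3, 8) == "INFEKL"))
  expect_identical(as.character(sampled),
                   as.character(enumerate_group("xxINFEKL", cap = 100,
                                                seed = 2)))
})

test_that("group summaries report medians on the score scale", {
  model <- get_recovery_model()
  ref <- motif_consensus(recovery_spec())
  gs <- group_score_summary(model, ref)  # no wildcard: one peptide
  expect_equal(gs$median, jury_score(model, ref))
  expect_equal(gs$n_peptides, 1)
  tmpl <- paste0("x", substr(ref, 2, 8))
  gs2 <- group_score_summary(model, tmpl)
  expect_equal(gs2$n_peptides, 20)
  expect_true(gs2$median >= 0 && gs2$median < 1)
  expect_lte(gs2$q1, gs2$median)
  expect_lte(gs2$median, gs2$q3)
  expect_error(group_score_summary(model, "xIINF"), "length")
})

test_that("anchor-preserving groups outscore anchor-randomizing groups", {
  model <- get_recovery_model()
  ref <- motif_consensus(recovery_spec())
  # randomize two non-anchor positions vs the two main anchor positions
  keep <- ref; substr(keep, 1, 2) <- "xx"
  lose <- ref; substr(lose, 5, 5) <- "x"; substr(lose, 8, 8) <- "x"
  m_keep <- group_score_summary(model, keep, seed = 3)$median
  m_lose <- group_score_summary(model, lose, seed = 3)$median
  expect_gt(m_keep, m_lose)
})

test_that("position-effect profiling flags the planted anchors", {
  model <- get_recovery_model()
  ref <- motif_consensus(recovery_spec())
  prof <- position_effect_profile(model, ref, seed = 5)
  expect_equal(nrow(prof), 8)
  expect_equal(sort(prof$position), 1:8)
  planted <- c(3, 5, 8)
  expect_true(all(prof$position[1:2] %in% planted))
  # unplanted positions barely move the median
  expect_lt(max(prof$drop[!prof$position %in% planted]), 0.05)
  expect_true(all(prof$group_median >= 0 & prof$group_median < 1))
})

test_that("proteome scanning scores every canonical window", {
  model <- get_recovery_model()
  prot10 <- random_peptides(1, 10, seed = 71)
  sc <- scan_proteome(model, c(p = prot10))
  expect_equal(sc$summary$n_windows, 3)  # 10 - 8 + 1
  expect_equal(sc$summary$n_scored + sc$summary$n_skipped, 3)
  expect_equal(sc$windows$end - sc$windows$start + 1, rep(8, 3))

  withx <- paste0(random_peptides(1, 8, seed = 72), "X",
                  random_peptides(1, 8, seed = 73))
  sc2 <- scan_proteome(model, c(p = withx))
  expect_equal(sc2$summary$n_windows, 10)
  expect_equal(sc2$summary$n_skipped, 8)  # every window touching the X
  expect_equal(sc2$summary$n_scored, 2)
  expect_error(scan_proteome(model, character(0)), "no protein")
})

test_that("spiked motif windows rise above the background score median", {
  model <- get_recovery_model()
  ref <- motif_consensus(recovery_spec())
  set.seed(75)
  bg <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                          collapse = "")
  prot <- paste0(bg(60), ref, bg(60), ref, bg(60), ref, bg(40))
  sc <- scan_proteome(model, c(spiked = prot), threshold = 0.9)
  w <- sc$windows
  spike_starts <- c(61, 129, 197)
  expect_equal(w$peptide[w$start %in% spike_starts], rep(ref, 3))
  spiked_scores <- w$score[w$start %in% spike_starts]
  background_median <- median(w$score[!w$start %in% spike_starts])
  expect_true(all(spiked_scores > background_median))
  expect_true(sc$summary$fraction_confident >= 0 &&
                sc$summary$fraction_confident <= 1)
})

test_that("epitope dissection tabulates every fragment group", {
  model <- get_recovery_model()
  ref <- motif_consensus(recovery_spec())
  dis <- dissect_epitope(model, ref, min_len = 6, seed = 7)
  expect_equal(nrow(dis), 5)  # lengths 7 (2 groups) and 6 (3 groups)
  expect_true(all(dis$median >= 0 & dis$median < 1))
  expect_true(all(dis$n_peptides == 20^(8 - dis$length)))
})
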