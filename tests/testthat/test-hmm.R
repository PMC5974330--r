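test_that("build_profile emission formula matches hand-computed values", {
  ## 4 identical ungapped sequences, pseudocount 1: observed base gets
  ## (n + pc) / (n + 4 pc) = 5/8
  seqs <- rep("ACGTACGTACGTACGTACGT", 4)
  hmm <- build_profile(seqs, pseudocount = 1)
  expect_equal(hmm$L, 20L)
  for (j in 1:20) {
    b <- substr(seqs[1], j, j)
    expect_equal(unname(hmm$match_emissions[j, b]), 5 / 8)
    expect_equal(unname(sum(hmm$match_emissions[j, ])), 1)
  }
  ## one column 50% A / 50% C, n = 4, pseudocount 1 -> (3/8,3/8,1/8,1/8)
  hmm2 <- build_profile(c("A", "A", "C", "C"), pseudocount = 1)
  expect_equal(unname(hmm2$match_emissions[1, ]), c(3, 3, 1, 1) / 8)
})

test_that("build_profile rejects bad input and obeys its invariants", {
  expect_error(build_profile(character(0)), "empty")
  expect_error(build_profile(c("ACGT", "ACXT")), "A/C/G/T")
  expect_error(build_profile(c("ACGT", "ACG")), "equal length")
  ## gap-heavy columns become insert columns, not match states
  hmm <- build_profile(c("AC-GT", "AC-GT", "ACAGT", "AC-GT"))
  expect_equal(hmm$L, 4L)
  tr <- hmm$transitions
  expect_equal(unname(tr$BM + tr$BD), 1)
  expect_true(all(abs(tr$MM + tr$MI + tr$MD - 1) < 1e-9))
  expect_true(all(abs(tr$IM + tr$II - 1) < 1e-9))
  expect_true(all(abs(tr$DM + tr$DD - 1) < 1e-9))
})

test_that("viterbi_locate matches the exhaustive per-start oracle", {
  set.seed(71)
  seed_aln <- {
    cons <- random_dna(1, 25)
    vapply(1:6, function(i) mutate_seq(cons, 2), character(1))
  }
  hmm <- build_profile(seed_aln)
  for (case in 1:25) {
    n <- sample(30:120, 1)
    seqv <- if (case %% 2 == 0) {
      at <- sample(0:(n - 25), 1)
      paste0(random_dna(1, at), mutate_seq(profile_consensus(hmm), 2),
             random_dna(1, n - at - 25))
    } else random_dna(1, n)
    got <- viterbi_locate(hmm, seqv, strands = "+", threshold = -Inf)
    ora <- oracle_viterbi(hmm, seqv)
    expect_equal(got$score, ora$score, tolerance = 1e-9)
    ## the reported coordinates attain the optimal score
    expect_equal(ora$score_at(got$start, got$end), ora$score,
                 tolerance = 1e-9)
  }
})

test_that("viterbi_locate finds embedded consensus at exact coordinates", {
  set.seed(72)
  hmm <- HMMS$hmm_28S
  cons <- profile_consensus(hmm)
  seqv <- paste0(random_dna(1, 37), cons, random_dna(1, 80))
  hit <- viterbi_locate(hmm, seqv)
  expect_equal(hit$start, 37L)
  expect_equal(hit$end, 37L + hmm$L)
  expect_equal(hit$strand, "+")
  ## boundary case: motif at position 0
  hit0 <- viterbi_locate(hmm, paste0(cons, random_dna(1, 60)))
  expect_equal(hit0$start, 0L)
  ## minus strand: coordinates mapped back
  hitm <- viterbi_locate(hmm, revcomp(seqv))
  expect_equal(hitm$strand, "-")
  expect_equal(hitm$start, nchar(seqv) - 37L - hmm$L)
  ## context invariance: same motif, different background, same score
  seqv2 <- paste0(random_dna(1, 61), cons, random_dna(1, 13))
  hit2 <- viterbi_locate(hmm, seqv2)
  expect_equal(hit2$score, hit$score, tolerance = 1e-9)
  expect_equal(hit2$start, 61L)
})

test_that("calibrated threshold suppresses shuffled decoys", {
  set.seed(73)
  cons <- profile_consensus(HMMS$hmm_5p8S)
  targets <- paste0(random_dna(100, 60), cons, random_dna(100, 60))
  hmm <- calibrate_threshold(HMMS$hmm_5p8S, targets, q = 0.95)
  ## on the 100-shuffle null the threshold was set from, at least 95
  ## score below it (return none)
  null_scores <- attr(hmm, "null_scores")
  expect_gte(sum(null_scores < hmm$score_threshold), 95)
  ## and an independent batch of shuffles behaves comparably
  fresh <- vapply(targets[1:50], dinuc_shuffle, character(1))
  n_none <- sum(vapply(fresh, function(s)
    is.null(viterbi_locate(hmm, s, threshold = hmm$score_threshold)),
    logical(1)))
  expect_gte(n_none, 45)
  ## while the true motif still scores far above threshold
  hit <- viterbi_locate(hmm, targets[1])
  expect_gt(hit$score, hmm$score_threshold + 20)
})

test_that("annotate_its2 locates the ITS2 span between the flanks", {
  set.seed(74)
  its2 <- random_dna(1, 250)
  f5 <- profile_consensus(HMMS$hmm_5p8S) # 60 nt
  f28 <- profile_consensus(HMMS$hmm_28S) # 80 nt
  ann <- annotate_its2(paste0(f5, its2, f28), HMMS$hmm_5p8S, HMMS$hmm_28S)
  expect_equal(ann$status, "both_flanks")
  expect_equal(ann$its2_start, 60L)
  expect_equal(ann$its2_end, 60L + 250L)
  ## conservation for both_flanks records
  expect_equal((ann$its2_end - ann$its2_start) +
                 ann$its2_start + (nchar(paste0(f5, its2, f28)) - ann$its2_end),
               nchar(paste0(f5, its2, f28)))
  ## bare ITS2: no flanks, no trim
  ann2 <- annotate_its2(its2, HMMS$hmm_5p8S, HMMS$hmm_28S)
  expect_equal(ann2$status, "none")
  expect_equal(c(ann2$its2_start, ann2$its2_end), c(0L, 250L))
  ## re-annotating the trimmed span finds nothing
  trimmed <- substr(paste0(f5, its2, f28), ann$its2_start + 1, ann$its2_end)
  ann3 <- annotate_its2(trimmed, HMMS$hmm_5p8S, HMMS$hmm_28S)
  expect_equal(ann3$status, "none")
})

test_that("trim_batch trims, drops short records and reports", {
  set.seed(75)
  f5 <- profile_consensus(HMMS$hmm_5p8S)
  f28 <- profile_consensus(HMMS$hmm_28S)
  its2s <- random_dna(5, c(250, 300, 200, 260, 40))
  seqs <- stats::setNames(paste0(f5, its2s, f28), sprintf("x%d", 1:5))
  tb <- trim_batch(seqs, HMMS)
  expect_equal(sum(tb$report$kept), 4L)
  expect_false(tb$report$kept[tb$report$id == "x5"]) # 40 nt: dropped
  expect_equal(unname(tb$seqs[paste0("x", 1:4)]), its2s[1:4])
  expect_true(all(tb$report$status == "both_flanks"))
  ## empty input -> empty outputs
  tb0 <- trim_batch(character(0), HMMS)
  expect_equal(length(tb0$seqs), 0L)
  expect_equal(nrow(tb0$report), 0L)
})

test_that("profile JSON round-trip preserves the model", {
  path <- withr::local_tempfile(fileext = ".json")
  write_profile(HMMS$hmm_28S, path)
  back <- read_profile(path)
  expect_equal(back$match_emissions, HMMS$hmm_28S$match_emissions)
  expect_equal(back$transitions, HMMS$hmm_28S$transitions)
  expect_equal(back$score_threshold, HMMS$hmm_28S$score_threshold)
  set.seed(76)
  s <- paste0(random_dna(1, 40), profile_consensus(back), random_dna(1, 40))
  expect_equal(viterbi_locate(back, s)$score,
               viterbi_locate(HMMS$hmm_28S, s)$score)
})
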