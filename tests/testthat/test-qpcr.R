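test_that("find_binding locates exact and degenerate sites", {
  set.seed(61)
  primer <- "TGGCCCACCATGCACGTCGA"
  tmpl <- paste0(random_dna(1, 12), primer, random_dna(1, 80))
  b <- find_binding(primer, tmpl)
  plus <- b[b$strand == "+", ]
  expect_equal(plus$pos, 12L)
  expect_equal(plus$total_mm, 0L)
  expect_equal(plus$three_prime_mm, 0L)
  ## absent primer: best site still reported, with many mismatches
  b2 <- find_binding(primer, random_dna(1, 200))
  expect_true(all(b2$total_mm >= 6))
  ## ties resolved to the leftmost position
  tmpl3 <- paste0("AAAAAAAAAAAA", "CCCC", "AAAAAAAAAAAA")
  b3 <- find_binding("AAAAAAAAAAAAAAAAAAAA", tmpl3) # 20 A vs A12 C4 A12
  expect_equal(b3$pos[b3$strand == "+"], 0L)
})

test_that("predict_amplification enforces mismatch, 3' and length rules", {
  set.seed(62)
  pair <- primer_pair("p", "TGGCCCACCATGCACGTCGA", "TGAGCATTGTCCACCACT")
  insert <- random_dna(1, 112) # product = 20 + 112 + 18 = 150
  tmpl <- paste0(random_dna(1, 30), pair$forward, insert,
                 revcomp(pair$reverse), random_dna(1, 40))
  res <- predict_amplification(pair, tmpl)
  expect_true(res$amplifies)
  expect_equal(unname(res$span["end"] - res$span["start"]), 150)
  ## two mismatches in the forward primer's last 4 bases kill it
  fwd_bad <- paste0(substr(pair$forward, 1, 16), "AGCA") # ...GTCGA -> mutated
  tmpl_bad <- paste0(random_dna(1, 30), fwd_bad, insert,
                     revcomp(pair$reverse), random_dna(1, 40))
  ## template carries the mutated site; the true primer now has 3' mismatches
  expect_false(predict_amplification(pair, tmpl_bad)$amplifies)
  ## 1500 bp apart with max_amplicon 1000: no product
  far <- paste0(pair$forward, random_dna(1, 1462), revcomp(pair$reverse))
  expect_false(predict_amplification(pair, far)$amplifies)
  expect_true(predict_amplification(
    primer_pair("p2", pair$forward, pair$reverse, max_amplicon = 2000),
    far)$amplifies)
  ## with zero tolerated mismatches the rule is exact substring search:
  ## random templates carry neither site; a constructed one carries both
  set.seed(63)
  for (i in 1:10) {
    t2 <- random_dna(1, 250)
    hasF <- grepl(pair$forward, t2, fixed = TRUE)
    hasR <- grepl(revcomp(pair$reverse), t2, fixed = TRUE)
    expect_equal(predict_amplification(pair, t2,
                                       max_total_mm = 0)$amplifies,
                 hasF && hasR)
  }
  expect_true(predict_amplification(pair, tmpl,
                                    max_total_mm = 0)$amplifies)
})

test_that("specificity_matrix is diagonal on the congener fixtures", {
  fix <- make_congener_templates(seed = 64)
  m <- specificity_matrix(fix$pairs, fix$templates)
  expect_equal(unname(m), diag(2) == 1)
  ## congener-level similarity preserved
  h <- align_read(fix$templates[["congener_A"]],
                  fix$templates[["congener_B"]])
  expect_gte(h$identity, 97)
  ## identical templates: both assays amplify both, with a warning
  same <- c(t1 = fix$templates[[1]], t2 = fix$templates[[1]])
  expect_warning(m2 <- specificity_matrix(fix$pairs["assay_A"], same),
                 "non-specific")
  expect_true(all(m2))
  ## empty template list: empty matrix
  expect_equal(ncol(specificity_matrix(fix$pairs,
                                       character(0))), 0L)
})

test_that("call_presence boundary behaviour at the Ct threshold", {
  expect_true(call_presence(31))
  expect_false(call_presence(32)) # exactly at threshold: absent
  expect_false(call_presence(33))
  expect_false(call_presence(NA)) # no amplification
  expect_equal(call_presence(c(30, 32, NA, 35)),
               c(TRUE, FALSE, FALSE, FALSE))
})

test_that("dpcr_quantify implements the Poisson occupancy model", {
  ## closed form: p = 0.5 -> lambda = ln 2
  q <- dpcr_quantify(10000, 20000, well_volume = 1)
  expect_equal(q$lambda, log(2), tolerance = 1e-9)
  ## zero positives: zero copies, CI lower bound 0
  q0 <- dpcr_quantify(0, 20000, well_volume = 1)
  expect_equal(q0$copies_per_ul, 0)
  expect_equal(unname(q0$ci["lower"]), 0)
  expect_gt(unname(q0$ci["upper"]), 0)
  ## saturation is an error
  expect_error(dpcr_quantify(20000, 20000), "saturated")
  ## strictly increasing in positive wells
  lam <- vapply(seq(100, 19900, by = 600), function(k)
    dpcr_quantify(k, 20000)$lambda, numeric(1))
  expect_true(all(diff(lam) > 0))
  ## low-occupancy limit: lambda ~ p within 1% for p <= 0.01
  for (p in c(0.001, 0.005, 0.01)) {
    qq <- dpcr_quantify(p * 1e6, 1e6, well_volume = 1)
    expect_lt(abs(qq$lambda - p) / p, 0.01)
  }
  ## dilution and volume scaling
  qs <- dpcr_quantify(5000, 20000, well_volume = 0.000755, dilution = 10)
  expect_equal(qs$copies_per_ul,
               -log(1 - 0.25) / 0.000755 * 10, tolerance = 1e-12)
})

test_that("assay primer table loads the published pairs", {
  pairs <- assay_primers()
  expect_equal(length(pairs), 2L)
  expect_equal(pairs[[1]]$forward, "TGGCCCACCATGCACGTCGA")
  expect_equal(pairs[[2]]$forward, "TGGCCCACCGTGCACTCACG")
  ## the congener assays share their forward 5' motif and diverge 3'-ward
  expect_equal(substr(pairs[[1]]$forward, 1, 9),
               substr(pairs[[2]]$forward, 1, 9))
  expect_false(substr(pairs[[1]]$forward, 10, 20) ==
                 substr(pairs[[2]]$forward, 10, 20))
})
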