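test_that("align_read basics: identity, coverage, strand", {
  set.seed(51)
  s <- random_dna(1, 300)
  h <- align_read(s, s)
  expect_equal(h$identity, 100)
  expect_equal(h$query_coverage, 100)
  expect_equal(h$score, 300)
  ## one substitution in 100 aligned columns -> 99.0
  t100 <- random_dna(1, 100)
  h2 <- align_read(mutate_seq(t100, 1), t100)
  expect_equal(h2$identity, 99)
  ## reverse complement: perfect identity on the minus strand
  h3 <- align_read(revcomp(s), s)
  expect_equal(h3$identity, 100)
  expect_equal(h3$strand, "-")
  ## reference span reported 0-based half-open
  sub <- substr(s, 51, 200)
  h4 <- align_read(sub, s)
  expect_equal(c(h4$ref_start, h4$ref_end), c(50L, 200L))
})

test_that("align_read agrees with the quadratic-DP oracle", {
  set.seed(52)
  for (case in 1:60) {
    n <- sample(40:80, 1)
    r <- random_dna(1, n)
    q <- mutate_seq(r, sample(0:12, 1))
    ## sometimes add indel-like edits and overhangs
    if (case %% 3 == 0) q <- paste0(random_dna(1, sample(1:8, 1)), q)
    if (case %% 4 == 0) q <- sub("^(.{10})(.{2})", "\\1", q) # 2-nt deletion
    got <- align_read(q, r, strands = "+")
    ora <- oracle_align(q, r)
    expect_equal(got$score, ora$score, tolerance = 1e-9)
    expect_equal(got$identity, ora$identity, tolerance = 1e-9)
  }
})

test_that("candidate_refs prefilters without losing qualifying hits", {
  fix <- make_test_db(5, seed = 53)
  db <- fix$curated$db
  params <- classify_params()
  ## a read identical to a reference is always a candidate
  expect_true(1L %in% candidate_refs(db$records$seq[1], db, params))
  ## random reads against an unrelated database: frozen-seed null case
  ## (expected shared 8-mers under the null ~0.8 << min_shared_kmers = 5;
  ## seed distinct from the database seed so the draws are independent)
  set.seed(9001)
  expect_equal(length(candidate_refs(random_dna(1, 100), db, params)), 0L)
  ## superset guarantee versus exhaustive alignment on mutated reads
  set.seed(54)
  for (i in 1:20) {
    j <- sample(nrow(db$records), 1)
    q <- mutate_seq(db$records$seq[j], sample(0:20, 1))
    cand <- candidate_refs(q, db, params)
    qualifying <- which(vapply(db$records$seq, function(r) {
      h <- align_read(q, r)
      h$identity >= params$min_identity &&
        h$query_coverage >= params$min_query_coverage
    }, logical(1), USE.NAMES = FALSE))
    expect_true(all(qualifying %in% cand))
  }
})

test_that("assign_read applies the 97% rule, coverage floor and tie logic", {
  params <- classify_params()
  hit <- function(sp, gen, id, cov = 100, score = id)
    data.frame(species = sp, genus = gen, identity = id,
               query_coverage = cov, score = score)
  ## single hit at 98%: assigned
  a <- assign_read(hit("Sp A", "G", 98), params)
  expect_equal(a$label, "Sp A")
  expect_equal(a$status, "assigned")
  ## best hit below the cutoff: unassigned
  expect_equal(assign_read(hit("Sp A", "G", 96.5), params)$status,
               "unassigned")
  ## boundary: identity exactly at the cutoff qualifies (>= rule)
  expect_equal(assign_read(hit("Sp A", "G", 97), params)$status,
               "assigned")
  ## coverage floor disqualifies short spurious matches
  expect_equal(assign_read(hit("Sp A", "G", 99, cov = 60), params)$status,
               "unassigned")
  ## two species tied within one genus: collapsed to genus ambiguity
  two <- rbind(hit("Sp A", "G", 99), hit("Sp B", "G", 99))
  a2 <- assign_read(two, params)
  expect_equal(a2$label, "AMBIGUOUS(G)")
  expect_equal(a2$status, "ambiguous")
  ## tie across genera: species set reported
  three <- rbind(hit("Sp A", "G1", 99), hit("Sp B", "G2", 99))
  expect_match(assign_read(three, params)$label,
               "AMBIGUOUS\\(Sp A\\|Sp B\\)")
  ## no hits at all
  expect_equal(assign_read(NULL, params)$label, "UNASSIGNED")
})

test_that("error-free reads classify perfectly; identity is monotone", {
  fix <- make_test_db(5, seed = 55)
  db <- fix$curated$db
  refs <- fix$refs
  cfg <- sim_config(stats::setNames(c(0.4, 0.3, 0.3),
                                    refs$taxonomy$species[1:3]),
                    n_reads = 60, substitution_rate = 0,
                    homopolymer_indel_rate = 0, truncation_fraction = 0,
                    low_quality_fraction = 0, seed = 56)
  sim <- sample_reads(cfg, stats::setNames(refs$flanked,
                                           refs$taxonomy$species))
  res <- classify_reads(sim$reads, db, primers = sim_primer_pair(),
                        hmms = HMMS)
  merged <- merge(res$assignments, sim$truth, by = "id")
  expect_true(all(merged$status == "assigned"))
  expect_equal(merged$label, merged$species)
  ## conservation: assigned + ambiguous + unassigned == input reads
  tab <- abundance_table(res$assignments)
  expect_equal(sum(tab$count) + attr(tab, "ambiguous") +
                 attr(tab, "unassigned"), nrow(sim$reads))
  ## raising min_identity never increases assigned reads
  n_assigned <- vapply(c(90, 95, 97, 99, 99.9), function(mi) {
    r <- classify_reads(sim$reads[1:20, ], db,
                        classify_params(min_identity = mi),
                        primers = sim_primer_pair(), hmms = HMMS)
    sum(r$assignments$status == "assigned")
  }, numeric(1))
  expect_true(all(diff(n_assigned) <= 0))
})

test_that("abundance_table counts and sorts; totals conserved", {
  asg <- data.frame(
    id = sprintf("r%02d", 1:10),
    label = c(rep("Sp A", 7), rep("Sp B", 2), "UNASSIGNED"),
    status = c(rep("assigned", 9), "unassigned"))
  tab <- abundance_table(asg)
  expect_equal(tab$species, c("Sp A", "Sp B"))
  expect_equal(tab$count, c(7L, 2L))
  expect_equal(attr(tab, "unassigned"), 1L)
  expect_equal(attr(tab, "total"), 10L)
  ## empty input
  tab0 <- abundance_table(asg[0, ])
  expect_equal(nrow(tab0), 0L)
  expect_equal(attr(tab0, "total"), 0L)
  ## all ambiguous: no species rows
  asg_amb <- data.frame(id = c("a", "b"), label = "AMBIGUOUS(G)",
                        status = "ambiguous")
  tab_amb <- abundance_table(asg_amb)
  expect_equal(nrow(tab_amb), 0L)
  expect_equal(attr(tab_amb, "ambiguous"), 2L)
})

test_that("screen_prescription partitions present/absent/extra", {
  tab <- abundance_table(data.frame(
    id = sprintf("r%03d", 1:106),
    label = c(rep("Sp A", 100), rep("Sp X", 5), "Sp Y"),
    status = "assigned"))
  rep <- screen_prescription(tab, c("Sp A", "Sp B"))
  expect_equal(rep$present, "Sp A")
  expect_equal(rep$absent, "Sp B")
  expect_equal(rep$extra, "Sp X") # Sp Y has 1 read < detection_min
  ## singleton suppressed at the detection threshold boundary
  expect_false("Sp Y" %in% rep$detected$species)
  ## fully covered prescription, no extras
  rep2 <- screen_prescription(tab[tab$species == "Sp A", , drop = FALSE],
                              "Sp A")
  expect_equal(rep2$absent, character(0))
  expect_equal(rep2$extra, character(0))
})
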