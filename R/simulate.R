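#' Simulation configuration
#'
#' The defaults state the world the simulator emulates: single-end
#' amplicon reads with an Ion-Torrent-like length distribution peaking
#' at 488 bp, a 0.5% per-base substitution rate, homopolymer-driven
#' +/-1 indels at 1% per run of length >= 3 (the platform's dominant
#' error mode), 5% of reads truncated short, 5% of reads low-quality
#' (flat Q15 versus flat Q30 for passing reads — so the Q20 mean filter
#' is exactly predictable), and half the reads reverse-complemented
#' (fragment-library amplicon inserts have no fixed orientation).
#'
#' @param species named numeric vector of relative proportions (must sum
#'   to 1).
#' @param n_reads number of reads to simulate.
#' @param read_length_mode modal read length in bp (default 488; reads
#'   never exceed their amplicon).
#' @param read_length_sd standard deviation of the length draw.
#' @param substitution_rate per-base substitution probability.
#' @param homopolymer_indel_rate per-homopolymer (run >= 3) probability
#'   of a +/-1 length error.
#' @param truncation_fraction fraction of reads truncated to 50-299 bp.
#' @param low_quality_fraction fraction of reads with flat Q15 quality.
#' @param minus_strand_fraction fraction of reads emitted as reverse
#'   complements.
#' @param seed RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(species, n_reads = 1000L, read_length_mode = 488L,
                       read_length_sd = 15, substitution_rate = 0.005,
                       homopolymer_indel_rate = 0.01,
                       truncation_fraction = 0.05,
                       low_quality_fraction = 0.05,
                       minus_strand_fraction = 0.5, seed = 1L) {
  stopifnot(abs(sum(species) - 1) < 1e-9, !is.null(names(species)),
            n_reads >= 0,
            substitution_rate >= 0, substitution_rate <= 1,
            homopolymer_indel_rate >= 0, homopolymer_indel_rate <= 1,
            truncation_fraction >= 0, truncation_fraction <= 1,
            low_quality_fraction >= 0, low_quality_fraction <= 1,
            minus_strand_fraction >= 0, minus_strand_fraction <= 1)
  structure(list(species = species, n_reads = as.integer(n_reads),
                 read_length_mode = as.integer(read_length_mode),
                 read_length_sd = read_length_sd,
                 substitution_rate = substitution_rate,
                 homopolymer_indel_rate = homopolymer_indel_rate,
                 truncation_fraction = truncation_fraction,
                 low_quality_fraction = low_quality_fraction,
                 minus_strand_fraction = minus_strand_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## fixture amplification primers used by the simulator (generic 20/18-mers)
#' @rdname sim_config
#' @export
sim_primer_pair <- function() {
  primer_pair("sim_ITS2", "ACTTGGTCATTTAGAGGAAG", "GCGTTCAAAGACTCGAT")
}

## majority-rule consensus of a gapped seed alignment (match columns only)
seed_consensus <- function(alignment) {
  mat <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  keep <- colMeans(mat != "-") >= 0.5
  paste(apply(mat[, keep, drop = FALSE], 2, function(col) {
    col <- col[col != "-"]
    names(sort(table(col), decreasing = TRUE))[1L]
  }), collapse = "")
}

## packaged flank motifs (consensus of the shipped seed alignments)
flank_motifs <- function() {
  f <- function(x) seed_consensus(read_seed_alignment(
    system.file("extdata", x, package = "herbauth", mustWork = TRUE)))
  list(flank5 = f("synthetic_5p8S_seed.afa"),
       flank3 = f("synthetic_28S_seed.afa"))
}

## mutate `m` distinct positions (1-based indices `pos`) to different bases
mutate_at <- function(seq, pos) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
  paste(b, collapse = "")
}

#' Generate a synthetic reference set with known divergence
#'
#' Builds `n_species` ITS2 sequences by mutating a common ancestor at
#' disjoint position sets, so every pair differs at twice the per-
#' species mutation load and the pairwise divergence is at least
#' `divergence` percent. Each sequence is wrapped in 5.8S-tail and
#' 28S-head flank motifs: identical across species when
#' `shared_flanks` (the conserved-rRNA mechanism behind cross-species
#' false positives), otherwise per-species variants (10% substitutions).
#'
#' @param n_species number of species.
#' @param its2_length ITS2 length in bp (default 300).
#' @param divergence minimum pairwise divergence in percent (default 5).
#' @param shared_flanks logical (default TRUE).
#' @param seed RNG seed.
#' @return list with `flanked` (named vector: flank5 + ITS2 + flank3),
#'   `its2` (bare ITS2), `taxonomy` (data frame id/species/genus),
#'   `flank5`, `flank3`.
#' @export
make_reference_set <- function(n_species, its2_length = 300L,
                               divergence = 5, shared_flanks = TRUE,
                               seed = 1L) {
  stopifnot(n_species >= 1, its2_length >= 1)
  motifs <- flank_motifs()
  with_seed(seed, {
    m <- ceiling(divergence / 100 * its2_length)
    if (n_species > 1 && n_species * m > its2_length)
      stop("its2_length too short for the requested divergence")
    ancestor <- random_dna(1, its2_length)
    pool <- sample(seq_len(its2_length))
    its2 <- character(n_species)
    for (i in seq_len(n_species)) {
      pos <- if (n_species > 1) pool[((i - 1) * m + 1):(i * m)] else integer(0)
      its2[i] <- mutate_at(ancestor, pos)
    }
    ids <- sprintf("SP%02d", seq_len(n_species))
    species <- sprintf("Species %02d", seq_len(n_species))
    genus <- sprintf("Genus%02d", seq_len(n_species))
    flank5 <- rep(motifs$flank5, n_species)
    flank3 <- rep(motifs$flank3, n_species)
    if (!shared_flanks && n_species > 1) {
      for (i in seq_len(n_species)) {
        n5 <- max(1L, round(0.1 * nchar(motifs$flank5)))
        n3 <- max(1L, round(0.1 * nchar(motifs$flank3)))
        flank5[i] <- mutate_at(motifs$flank5,
                               sample(nchar(motifs$flank5), n5))
        flank3[i] <- mutate_at(motifs$flank3,
                               sample(nchar(motifs$flank3), n3))
      }
    }
    list(flanked = stats::setNames(paste0(flank5, its2, flank3), ids),
         its2 = stats::setNames(its2, ids),
         taxonomy = data.frame(id = ids, species = species, genus = genus,
                               source = "synthetic",
                               stringsAsFactors = FALSE),
         flank5 = motifs$flank5, flank3 = motifs$flank3)
  })
}

## apply substitutions and homopolymer +/-1 indels to one sequence
apply_errors <- function(seq, sub_rate, hp_rate) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(b)) < sub_rate)
  for (p in hit) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
  if (hp_rate > 0) {
    r <- rle(b)
    runs <- which(r$lengths >= 3L)
    if (length(runs)) {
      flip <- runs[stats::runif(length(runs)) < hp_rate]
      if (length(flip)) {
        r$lengths[flip] <- r$lengths[flip] +
          sample(c(-1L, 1L), length(flip), replace = TRUE)
        b <- rep(r$values, r$lengths)
      }
    }
  }
  paste(b, collapse = "")
}

#' Simulate reads from amplicon templates with ground truth
#'
#' Each read is drawn from a species per the configured proportions; its
#' amplicon is forward primer + flanked template + reverse-complemented
#' reverse primer, copied with substitutions and homopolymer indels.
#' Read length is normal around `read_length_mode` (capped at the
#' amplicon length); truncated reads are cut to 50-299 bp. Qualities
#' are flat Q30 (or flat Q15 for the low-quality fraction); a configured
#' fraction of reads is reverse-complemented.
#'
#' @param config a [sim_config].
#' @param templates named character vector of flanked templates, names =
#'   species labels in `config$species`.
#' @param primers a [primer_pair] (default [sim_primer_pair()]).
#' @return list with `reads` (a [seq_reads]), `truth` (data frame id /
#'   species / truncated / low_quality), and `expected_counts` (named
#'   realized per-species counts, summing to `n_reads`).
#' @export
sample_reads <- function(config, templates, primers = sim_primer_pair()) {
  if (!length(templates)) stop("empty template set")
  missing <- setdiff(names(config$species), names(templates))
  if (length(missing))
    stop("no template for species: ", paste(missing, collapse = ", "))
  with_seed(config$seed, {
    n <- config$n_reads
    sp <- sample(names(config$species), n, replace = TRUE,
                 prob = config$species)
    truncated <- stats::runif(n) < config$truncation_fraction
    lowq <- stats::runif(n) < config$low_quality_fraction
    minus <- stats::runif(n) < config$minus_strand_fraction
    ids <- sprintf("read%06d", seq_len(n))
    seqs <- character(n)
    quals <- character(n)
    for (i in seq_len(n)) {
      amp <- paste0(primers$forward, templates[[sp[i]]],
                    revcomp(primers$reverse))
      amp <- apply_errors(amp, config$substitution_rate,
                          config$homopolymer_indel_rate)
      len <- if (truncated[i]) sample(50:299, 1L)
             else round(stats::rnorm(1, config$read_length_mode,
                                     config$read_length_sd))
      len <- max(1L, min(nchar(amp), len))
      s <- substr(amp, 1L, len)
      if (minus[i]) s <- revcomp(s)
      seqs[i] <- s
      quals[i] <- strrep(intToUtf8(33L + if (lowq[i]) 15L else 30L), len)
    }
    reads <- seq_reads(ids, seqs, quals)
    truth <- data.frame(id = ids, species = sp, truncated = truncated,
                        low_quality = lowq, stringsAsFactors = FALSE)
    counts <- table(factor(sp, levels = names(config$species)))
    list(reads = reads, truth = truth,
         expected_counts = stats::setNames(as.integer(counts),
                                           names(counts)))
  })
}

#' Synthetic congener templates and matched species-specific assays
#'
#' Two templates of congener-level similarity (identity >= 97%),
#' identical except near each assay primer's 3' binding end, plus two
#' primer pairs built from the respective sites — so the specificity
#' matrix over (assays x templates) is diagonal by construction. This
#' is the in-silico analogue of a species-specific real-time PCR assay
#' pair distinguishing a medicinal species from its adulterant
#' congener: both forward primers share their 5' sequence and diverge
#' 3'-wards.
#'
#' @param seed RNG seed.
#' @param length template length (default 300).
#' @return list with `templates` (named vector `congener_A`,
#'   `congener_B`) and `pairs` (list of two [primer_pair]s,
#'   `assay_A`, `assay_B`).
#' @export
make_congener_templates <- function(seed = 1L, length = 300L) {
  stopifnot(length >= 120)
  with_seed(seed, {
    tA <- random_dna(1, length)
    f_start <- 41L; f_len <- 20L
    r_start <- length - 80L; r_len <- 18L # rc(reverse) site on plus strand
    ## B differs from A only in the two primer 3' windows
    b <- strsplit(tA, "", fixed = TRUE)[[1]]
    for (p in (f_start + f_len - 4L):(f_start + f_len - 1L))
      b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
    ## reverse primer 3' end maps to the start of the rc site
    for (p in r_start:(r_start + 3L))
      b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
    tB <- paste(b, collapse = "")
    site <- function(t, s, l) substr(t, s, s + l - 1L)
    pairs <- list(
      assay_A = primer_pair("assay_A", site(tA, f_start, f_len),
                            revcomp(site(tA, r_start, r_len))),
      assay_B = primer_pair("assay_B", site(tB, f_start, f_len),
                            revcomp(site(tB, r_start, r_len))))
    list(templates = c(congener_A = tA, congener_B = tB), pairs = pairs)
  })
}

#' Read-through fixtures for the conserved-flank false-positive effect
#'
#' Emulates the mechanism by which residual conserved 28S rRNA in an
#' uncurated reference database attracts reads from a different
#' species: species A's reference is a clean ITS2, species B's carries
#' a long shared 28S head, and every simulated read is an A read that
#' runs through its ITS2 into the same shared 28S sequence. Against
#' the uncurated database those reads fail A's coverage cutoff but
#' match B end-to-end above the identity cutoff; after curation (and
#' read trimming) they all return to A.
#'
#' @param seed RNG seed.
#' @param n_reads number of read-through reads (default 200).
#' @param its2_length ITS2 length (default 300).
#' @param divergence A/B ITS2 divergence in percent (default 3).
#' @param tail_extra shared 28S sequence beyond the flank motif
#'   (default 120 bp).
#' @return list with `records` (reference data frame, uncurated),
#'   `reads` (a [seq_reads], error-free, flat Q30), and `truth`
#'   (all reads belong to species A).
#' @export
make_readthrough_experiment <- function(seed = 1L, n_reads = 200L,
                                        its2_length = 300L,
                                        divergence = 3,
                                        tail_extra = 120L) {
  motifs <- flank_motifs()
  with_seed(seed, {
    m <- ceiling(divergence / 100 * its2_length)
    its2_A <- random_dna(1, its2_length)
    its2_B <- mutate_at(its2_A, sample(its2_length, m)) # pairwise = m
    tail28 <- paste0(motifs$flank3, random_dna(1, tail_extra))
    records <- data.frame(
      id = c("REC_A", "REC_B"),
      species = c("Species A", "Species B"),
      genus = c("GenusA", "GenusB"),
      seq = c(its2_A, paste0(its2_B, tail28)),
      source = "synthetic",
      stringsAsFactors = FALSE)
    rseq <- paste0(its2_A, tail28)
    reads <- seq_reads(sprintf("rt%04d", seq_len(n_reads)),
                       rep(rseq, n_reads),
                       rep(strrep(intToUtf8(63L), nchar(rseq)), n_reads))
    truth <- data.frame(id = reads$id, species = "Species A",
                        stringsAsFactors = FALSE)
    list(records = records, reads = reads, truth = truth)
  })
}
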