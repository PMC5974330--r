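#' Classification parameters
#'
#' `min_identity` defaults to 97 — the identity cutoff used for species
#' assignment (derived, like OTU clustering criteria, from the locus'
#' inter-specific divergence). `min_query_coverage` (default 80) guards
#' against short spurious matches: a read must have at least this
#' percentage of its bases aligned to reference bases to qualify.
#'
#' @param min_identity percent identity cutoff (default 97).
#' @param min_query_coverage percent query coverage cutoff (default 80).
#' @param k k-mer size of the candidate prefilter (default 8; must match
#'   the database index).
#' @param min_shared_kmers shared k-mers required to become an alignment
#'   candidate (default 5).
#' @param detection_min minimum read count for a species to count as
#'   detected when screening (default 2).
#' @return a `classify_params` list.
#' @export
classify_params <- function(min_identity = 97, min_query_coverage = 80,
                            k = 8L, min_shared_kmers = 5L,
                            detection_min = 2L) {
  stopifnot(min_identity > 0, min_identity <= 100,
            min_query_coverage > 0, min_query_coverage <= 100,
            min_shared_kmers >= 1, detection_min >= 1)
  structure(list(min_identity = min_identity,
                 min_query_coverage = min_query_coverage,
                 k = as.integer(k),
                 min_shared_kmers = as.integer(min_shared_kmers),
                 detection_min = as.integer(detection_min)),
            class = "classify_params")
}

#' Candidate references for a read (k-mer prefilter)
#'
#' Records sharing at least `min_shared_kmers` k-mers with the read on
#' either strand. Stands in for BLAST seeding: cheap, and a superset of
#' the records with qualifying alignments on realistic data (tested
#' against exhaustive alignment).
#'
#' @param seq read sequence (character).
#' @param db an `its2_refdb`.
#' @param params a [classify_params].
#' @return integer vector of record row indices in `db$records`.
#' @export
candidate_refs <- function(seq, db, params = classify_params()) {
  codes <- sort(unique(c(kmer_codes_cpp(seq, db$k),
                         kmer_codes_cpp(revcomp(seq), db$k))))
  shared <- vapply(db$kmer_index, shared_codes_cpp, integer(1), a = codes)
  which(shared >= params$min_shared_kmers)
}

#' Align a read against one reference
#'
#' Semi-global alignment with free end gaps on the reference (the read
#' is aligned end to end): match +1, mismatch -1, gap open -2, gap
#' extend -1. Identity is matches over aligned columns (the span
#' between the first and last aligned base pair, BLAST-style); query
#' coverage is the percentage of read bases aligned to reference bases.
#' Both strands are aligned and the better one reported.
#'
#' @param seq read sequence.
#' @param ref reference sequence.
#' @param strands strands to try (default both; restricting to one is a
#'   cheap speed-up when the read orientation is already known).
#' @return an `alignment_hit` list: `identity`, `query_coverage` (both
#'   percent), `score`, `strand`, `ref_start`, `ref_end` (0-based
#'   half-open span of the reference consumed by the alignment).
#' @export
align_read <- function(seq, ref, strands = c("+", "-")) {
  stopifnot(nchar(seq) > 0, nchar(ref) > 0)
  pick <- NULL
  for (st in strands) {
    q <- if (st == "+") seq else revcomp(seq)
    a <- sg_align_cpp(q, ref)
    if (is.null(pick) || a$score > pick$score) {
      pick <- a
      pick$strand <- st
    }
  }
  structure(list(
    identity = if (pick$aligned_cols > 0)
      100 * pick$matches / pick$aligned_cols else 0,
    query_coverage = 100 * (pick$matches + pick$mismatches) / nchar(seq),
    score = pick$score,
    matches = pick$matches,
    aligned_cols = pick$aligned_cols,
    strand = pick$strand,
    ref_start = pick$ref_start,
    ref_end = pick$ref_end), class = "alignment_hit")
}

#' Assign a read from its alignment hits
#'
#' Qualifying hits satisfy both the identity and the coverage cutoff.
#' No qualifying hit gives `UNASSIGNED`; a unique best-scoring species
#' gives that species; a best score attained by two or more species
#' gives an ambiguous call, collapsed to the genus when all tied species
#' share one (congener ties are reported honestly, never broken at
#' random).
#'
#' @param hits data frame with columns `species`, `genus`, `identity`,
#'   `query_coverage`, `score` (one row per reference hit).
#' @param params a [classify_params].
#' @return list with `label` (species name, `"AMBIGUOUS(...)"`, or
#'   `"UNASSIGNED"`), `status` (`"assigned"`, `"ambiguous"`,
#'   `"unassigned"`), and `best` (the qualifying best-score hits).
#' @export
assign_read <- function(hits, params = classify_params()) {
  if (is.null(hits) || !nrow(hits))
    return(list(label = "UNASSIGNED", status = "unassigned", best = NULL))
  a <- assign_rule(hits$species, hits$genus, hits$identity,
                   hits$query_coverage, hits$score, params)
  list(label = a$label, status = a$status,
       best = if (length(a$best_idx)) hits[a$best_idx, , drop = FALSE]
              else NULL)
}

## the assignment rule on plain vectors (shared by assign_read and the
## classify_reads fast path)
assign_rule <- function(species, genus, identity, coverage, score,
                        params) {
  ok <- identity >= params$min_identity &
    coverage >= params$min_query_coverage
  if (!any(ok))
    return(list(label = "UNASSIGNED", status = "unassigned",
                best_idx = integer(0)))
  idx <- which(ok)
  best_idx <- idx[score[idx] == max(score[idx])]
  sp <- unique(species[best_idx])
  if (length(sp) == 1L)
    return(list(label = sp, status = "assigned", best_idx = best_idx))
  gen <- unique(genus[best_idx])
  label <- if (length(gen) == 1L) sprintf("AMBIGUOUS(%s)", gen)
           else sprintf("AMBIGUOUS(%s)", paste(sort(sp), collapse = "|"))
  list(label = label, status = "ambiguous", best_idx = best_idx)
}

#' Classify reads against a curated database
#'
#' Full read pipeline: optional primer masking, optional orientation-
#' aware ITS2 flank trimming, k-mer candidate prefilter, semi-global
#' alignment against the candidates, and the identity-threshold
#' assignment rule.
#'
#' @param reads a [seq_reads] object.
#' @param db an `its2_refdb`.
#' @param params a [classify_params].
#' @param primers optional [primer_pair] for [mask_primers()].
#' @param hmms optional flank profiles; when supplied, reads are trimmed
#'   with [hmm_trim_reads()] before alignment (recommended with a
#'   curated database).
#' @param min_read_len reads shorter than this after masking/trimming
#'   are reported unassigned without alignment (default 50).
#' @return list with `assignments` (data frame: id, label, status) and
#'   `hits` (data frame of all alignments computed, BLAST-outfmt6-like).
#' @export
classify_reads <- function(reads, db, params = classify_params(),
                           primers = NULL, hmms = NULL,
                           min_read_len = 50L) {
  if (!is.null(primers))
    reads <- mask_primers(reads, primers)
  if (!is.null(hmms)) reads <- hmm_trim_reads(reads, hmms)
  n <- nrow(reads)
  labels <- character(n)
  status <- character(n)
  hit_rows <- vector("list", n)
  rec <- db$records
  for (i in seq_len(n)) {
    s <- reads$seq[i]
    if (nchar(s) < min_read_len) {
      labels[i] <- "UNASSIGNED"
      status[i] <- "unassigned"
      next
    }
    codes_f <- kmer_codes_cpp(s, db$k)
    codes_r <- kmer_codes_cpp(revcomp(s), db$k)
    shared_f <- vapply(db$kmer_index, shared_codes_cpp, integer(1),
                       a = codes_f)
    shared_r <- vapply(db$kmer_index, shared_codes_cpp, integer(1),
                       a = codes_r)
    cand <- which(shared_f + shared_r >= params$min_shared_kmers)
    if (!length(cand)) {
      labels[i] <- "UNASSIGNED"
      status[i] <- "unassigned"
      next
    }
    ## align only the strand the k-mer evidence supports (both on a tie)
    strands <- if (sum(shared_f[cand]) > sum(shared_r[cand])) "+"
               else if (sum(shared_r[cand]) > sum(shared_f[cand])) "-"
               else c("+", "-")
    nc <- length(cand)
    identity <- coverage <- score <- numeric(nc)
    strand <- character(nc)
    ref_start <- ref_end <- integer(nc)
    for (ci in seq_len(nc)) {
      h <- align_read(s, rec$seq[cand[ci]], strands = strands)
      identity[ci] <- h$identity
      coverage[ci] <- h$query_coverage
      score[ci] <- h$score
      strand[ci] <- h$strand
      ref_start[ci] <- h$ref_start
      ref_end[ci] <- h$ref_end
    }
    a <- assign_rule(rec$species[cand], rec$genus[cand], identity,
                     coverage, score, params)
    labels[i] <- a$label
    status[i] <- a$status
    hit_rows[[i]] <- list(read_id = rep(reads$id[i], nc),
                          record_id = rec$id[cand],
                          species = rec$species[cand],
                          genus = rec$genus[cand],
                          identity = identity, query_coverage = coverage,
                          score = score, strand = strand,
                          ref_start = ref_start, ref_end = ref_end)
  }
  keep <- !vapply(hit_rows, is.null, logical(1))
  hits <- if (any(keep)) {
    hr <- hit_rows[keep]
    as.data.frame(lapply(stats::setNames(nm = names(hr[[1L]])), function(f)
      unlist(lapply(hr, `[[`, f), use.names = FALSE)),
      stringsAsFactors = FALSE)
  } else NULL
  list(assignments = data.frame(id = reads$id, label = labels,
                                status = status, stringsAsFactors = FALSE),
       hits = hits)
}

#' Tabulate assignments into an abundance table
#'
#' Per-species read counts sorted descending (zero-count species
#' omitted), with ambiguous and unassigned totals appended; the counts
#' always sum to the number of classified reads. Counts are read
#' counts, not biomass: no quantitative composition claim is implied.
#'
#' @param assignments the `assignments` data frame of
#'   [classify_reads()].
#' @return an `abundance_table` data frame (`species`, `count`) with
#'   attributes `ambiguous`, `unassigned`, `total`.
#' @export
abundance_table <- function(assignments) {
  assigned <- assignments[assignments$status == "assigned", , drop = FALSE]
  tab <- sort(table(assigned$label), decreasing = TRUE)
  out <- data.frame(species = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  structure(out, class = c("abundance_table", "data.frame"),
            ambiguous = sum(assignments$status == "ambiguous"),
            unassigned = sum(assignments$status == "unassigned"),
            total = nrow(assignments))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> total=%d, ambiguous=%d, unassigned=%d\n",
              attr(x, "total"), attr(x, "ambiguous"), attr(x, "unassigned")))
  print(as.data.frame(x))
  invisible(x)
}

#' Screen an abundance table against a prescription
#'
#' Partitions detected species (count at least `detection_min`) into
#' prescribed-and-present, prescribed-but-absent, and non-prescribed
#' extras (putative adulterants or contaminants).
#'
#' @param table an [abundance_table].
#' @param prescription character vector of prescribed species.
#' @param detection_min detection threshold in reads (default 2).
#' @return list with `present`, `absent`, `extra` (character vectors)
#'   and `detected` (data frame of detected species with counts).
#' @export
screen_prescription <- function(table, prescription, detection_min = 2L) {
  detected <- table[table$count >= detection_min, , drop = FALSE]
  list(present = intersect(prescription, detected$species),
       absent = setdiff(prescription, detected$species),
       extra = setdiff(detected$species, prescription),
       detected = as.data.frame(detected))
}

#' Write classifier outputs
#'
#' `write_hits` emits a BLAST-outfmt-6-like TSV, `write_abundance` the
#' abundance table (species, count, plus ambiguous/unassigned/total
#' footer rows).
#'
#' @param hits,table objects from [classify_reads()] /
#'   [abundance_table()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
write_abundance <- function(table, path) {
  foot <- data.frame(species = c("AMBIGUOUS", "UNASSIGNED", "TOTAL"),
                     count = c(attr(table, "ambiguous"),
                               attr(table, "unassigned"),
                               attr(table, "total")))
  utils::write.table(rbind(as.data.frame(table), foot), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
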