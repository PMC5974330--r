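#' Load ITS2 reference records from FASTA plus taxonomy TSV
#'
#' The taxonomy table must have columns `id`, `species`, `genus`; every
#' FASTA id must appear in it. Duplicate FASTA ids and ids missing from
#' the taxonomy are errors that name the offending ids.
#'
#' @param fasta path to the reference FASTA.
#' @param taxonomy path to the taxonomy TSV.
#' @return data frame of reference records: `id`, `species`, `genus`,
#'   `seq`, `source`.
#' @export
load_references <- function(fasta, taxonomy) {
  seqs <- read_fasta(fasta)
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  tax <- utils::read.delim(taxonomy, stringsAsFactors = FALSE)
  need <- c("id", "species", "genus")
  if (!all(need %in% names(tax)))
    stop("taxonomy TSV needs columns: ", paste(need, collapse = ", "))
  missing <- setdiff(names(seqs), tax$id)
  if (length(missing))
    stop("FASTA id(s) missing from taxonomy: ",
         paste(missing, collapse = ", "))
  m <- match(names(seqs), tax$id)
  if (!"source" %in% names(tax)) tax$source <- ""
  if (any(!nzchar(tax$species[m]))) stop("empty species name in taxonomy")
  data.frame(id = names(seqs), species = tax$species[m],
             genus = tax$genus[m], seq = unname(seqs),
             source = tax$source[m], stringsAsFactors = FALSE)
}

#' Curate reference records into a classification-ready database
#'
#' Optionally trims every record to its ITS2 span with the flank
#' profiles (the step that removes the conserved 5.8S/28S sequence
#' responsible for cross-species false positives), drops records whose
#' trimmed span is shorter than `min_len`, deduplicates identical
#' `(species, sequence)` pairs, flags identical sequences labelled with
#' different species as conflicts (kept — the classifier's tie logic
#' expresses the ambiguity), and builds the k-mer index.
#'
#' @param records data frame from [load_references()].
#' @param hmms list with `hmm_5p8S` and `hmm_28S`, or `NULL` to index
#'   the records as-is (no flank trimming; used e.g. to demonstrate the
#'   false-positive effect of an uncurated database).
#' @param k k-mer size for the prefilter index (default 8).
#' @param min_len minimum sequence length kept after trimming.
#' @return list with `db` (an `its2_refdb`) and `report` (data frame:
#'   id, action, detail).
#' @export
curate <- function(records, hmms = NULL, k = 8L, min_len = 100L) {
  report <- data.frame(id = character(0), action = character(0),
                       detail = character(0), stringsAsFactors = FALSE)
  note <- function(id, action, detail = "") {
    report <<- rbind(report, data.frame(id = id, action = action,
                                        detail = detail))
  }
  if (!is.null(hmms) && nrow(records)) {
    tb <- trim_batch(stats::setNames(records$seq, records$id), hmms,
                     min_len = min_len)
    keep <- records$id %in% names(tb$seqs)
    for (id in records$id[!keep]) note(id, "dropped_short_after_trim")
    records <- records[keep, , drop = FALSE]
    records$seq <- unname(tb$seqs[records$id])
    for (i in seq_len(nrow(tb$report)))
      if (tb$report$kept[i])
        note(tb$report$id[i], "trimmed", tb$report$status[i])
  }
  dup <- duplicated(paste(records$species, records$seq, sep = "\r"))
  for (id in records$id[dup]) note(id, "deduplicated")
  records <- records[!dup, , drop = FALSE]
  conflict <- logical(nrow(records))
  if (nrow(records)) {
    by_seq <- split(seq_len(nrow(records)), records$seq)
    for (idx in by_seq) {
      if (length(unique(records$species[idx])) > 1L) {
        conflict[idx] <- TRUE
        note(paste(records$id[idx], collapse = ","), "conflict",
             paste(unique(records$species[idx]), collapse = "|"))
      }
    }
  }
  records$conflict <- conflict
  rownames(records) <- NULL
  db <- structure(list(
    records = records,
    k = as.integer(k),
    kmer_index = lapply(records$seq, kmer_codes_cpp, k = as.integer(k)),
    species = sort(unique(records$species))
  ), class = "its2_refdb")
  list(db = db, report = report)
}

#' @export
print.its2_refdb <- function(x, ...) {
  cat(sprintf("<its2_refdb> %d record(s), %d species, k=%d\n",
              nrow(x$records), length(x$species), x$k))
  invisible(x)
}

#' Validate a curated database against the flank profiles
#'
#' Rescans every record with both flank models; any hit above threshold
#' is residual-flank contamination. An empty report means the database
#' is clean.
#'
#' @param db an `its2_refdb`.
#' @param hmms list with `hmm_5p8S` and `hmm_28S`.
#' @return data frame (id, flank, score) of contaminated records; zero
#'   rows iff the database is valid.
#' @export
validate_db <- function(db, hmms) {
  out <- data.frame(id = character(0), flank = character(0),
                    score = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(db$records))) {
    for (fl in c("hmm_5p8S", "hmm_28S")) {
      h <- viterbi_locate(hmms[[fl]], db$records$seq[i])
      if (!is.null(h))
        out <- rbind(out, data.frame(id = db$records$id[i],
                                     flank = hmms[[fl]]$name,
                                     score = h$score))
    }
  }
  out
}

#' Write / read a reference database directory
#'
#' The directory holds the trimmed FASTA (`references.fasta`), the
#' taxonomy TSV (`taxonomy.tsv`) and the index parameters
#' (`index.json`); [read_refdb()] rebuilds the k-mer index from the
#' sequences.
#'
#' @param db an `its2_refdb`.
#' @param dir database directory.
#' @return `write_refdb`: `dir` invisibly; `read_refdb`: the
#'   `its2_refdb`.
#' @export
write_refdb <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(stats::setNames(db$records$seq, db$records$id),
              file.path(dir, "references.fasta"))
  utils::write.table(db$records[, c("id", "species", "genus", "source",
                                    "conflict")],
                     file.path(dir, "taxonomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(k = db$k), file.path(dir, "index.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_refdb
#' @export
read_refdb <- function(dir) {
  seqs <- read_fasta(file.path(dir, "references.fasta"))
  tax <- utils::read.delim(file.path(dir, "taxonomy.tsv"),
                           stringsAsFactors = FALSE)
  k <- jsonlite::read_json(file.path(dir, "index.json"))$k
  m <- match(names(seqs), tax$id)
  records <- data.frame(id = names(seqs), species = tax$species[m],
                        genus = tax$genus[m], seq = unname(seqs),
                        source = tax$source[m],
                        conflict = as.logical(tax$conflict[m]),
                        stringsAsFactors = FALSE)
  structure(list(records = records, k = as.integer(k),
                 kmer_index = lapply(records$seq, kmer_codes_cpp,
                                     k = as.integer(k)),
                 species = sort(unique(records$species))),
            class = "its2_refdb")
}
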