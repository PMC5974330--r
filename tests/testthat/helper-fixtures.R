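# Shared fixtures. flank_hmms() is deterministic but costs a couple of
# seconds (threshold calibration), so build it once per test session.

HMMS <- flank_hmms()

## reference records data frame from a make_reference_set() result
records_from_refs <- function(refs, flanked = TRUE) {
  data.frame(id = refs$taxonomy$id,
             species = refs$taxonomy$species,
             genus = refs$taxonomy$genus,
             seq = unname(if (flanked) refs$flanked else refs$its2),
             source = "synthetic",
             stringsAsFactors = FALSE)
}

## curated database fixture (5 species, shared flanks)
make_test_db <- function(n_species = 5, seed = 11, hmms = HMMS, ...) {
  refs <- make_reference_set(n_species, seed = seed, ...)
  list(refs = refs, curated = curate(records_from_refs(refs), hmms))
}

## write reads to a temporary FASTQ, returning the path
tmp_fastq <- function(reads) {
  path <- withr::local_tempfile(fileext = ".fastq",
                                .local_envir = parent.frame())
  write_fastq(reads, path)
  path
}

## substitute k random positions of a sequence
mutate_seq <- function(seq, k) {
  b <- strsplit(seq, "")[[1]]
  for (p in sample(length(b), k))
    b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  paste(b, collapse = "")
}

## flat-quality read constructor
flat_reads <- function(seqs, q = 30, ids = sprintf("r%03d", seq_along(seqs))) {
  seq_reads(ids, seqs, vapply(nchar(seqs),
                              function(l) strrep(intToUtf8(33 + q), l),
                              character(1)))
}
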