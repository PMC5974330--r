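#' Reverse complement of DNA strings
#'
#' Vectorised over `x`. IUPAC N is preserved; gaps (`-`) are preserved so
#' aligned sequences can be flipped too.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  flipped <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

#' Random DNA sequences
#'
#' Uniform i.i.d. bases; used by the simulator and the test fixtures.
#' Draws from the current RNG stream (set a seed upstream for determinism).
#'
#' @param n number of sequences.
#' @param len length of each sequence (recycled to `n`).
#' @return character vector of length `n`.
#' @export
random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

#' Dinucleotide shuffle
#'
#' Permutes a sequence while preserving its dinucleotide (and hence
#' mononucleotide) composition, by randomising the order in which the
#' Eulerian walk over the dinucleotide graph consumes edges and retrying
#' until a full walk is found. Used to build the empirical null for the
#' flank-model score threshold.
#'
#' @param seq a single DNA string.
#' @param max_tries attempts before falling back to the original sequence.
#' @return shuffled sequence (same length, same dinucleotide counts).
#' @export
dinuc_shuffle <- function(seq, max_tries = 200L) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  if (n < 3L) return(seq)
  src <- b[-n]
  dst <- b[-1L]
  for (i in seq_len(max_tries)) {
    edges <- lapply(split(dst, src), sample)
    ptr <- stats::setNames(rep(1L, length(edges)), names(edges))
    out <- character(n)
    out[1L] <- b[1L]
    cur <- b[1L]
    ok <- TRUE
    for (j in 2:n) {
      e <- edges[[cur]]
      p <- ptr[[cur]]
      if (is.null(e) || p > length(e)) { ok <- FALSE; break }
      ptr[[cur]] <- p + 1L
      cur <- e[[p]]
      out[j] <- cur
    }
    if (ok) return(paste(out, collapse = ""))
  }
  seq
}

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]; sequences are
#' uppercased and names are truncated at the first whitespace.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a named character vector to FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

## internal: check DNA alphabet
is_dna <- function(x, extra = "N") {
  !grepl(sprintf("[^ACGT%s]", extra), x)
}
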