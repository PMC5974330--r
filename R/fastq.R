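#' Amplicon read container
#'
#' A `seq_reads` object is a data frame with one row per read and columns
#' `id`, `seq` (uppercase A/C/G/T/N) and `qual` (phred+33 string, same
#' length as `seq`). Single-end only: the platform emulated here (Ion
#' Torrent) has no read pairing.
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of DNA sequences.
#' @param qual character vector of phred+33 quality strings.
#' @return a `seq_reads` data frame.
#' @export
seq_reads <- function(id = character(), seq = character(), qual = character()) {
  seq <- toupper(seq)
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop("seq/qual length mismatch for read(s): ",
         paste(id[utils::head(bad, 5)], collapse = ", "))
  if (length(seq) && any(!is_dna(seq)))
    stop("sequences must contain only A/C/G/T/N")
  structure(data.frame(id = id, seq = seq, qual = qual,
                       stringsAsFactors = FALSE),
            class = c("seq_reads", "data.frame"))
}

#' @export
print.seq_reads <- function(x, ...) {
  cat(sprintf("<seq_reads> %d read(s)\n", nrow(x)))
  if (nrow(x)) print(utils::head(data.frame(id = x$id, length = nchar(x$seq),
                                            mean_q = round(mean_quality(x), 2)), 10))
  invisible(x)
}

#' Per-read phred statistics
#'
#' @param reads a `seq_reads` object.
#' @return `mean_quality`: numeric vector of mean phred scores (NA for
#'   empty reads); `read_lengths`: integer vector of read lengths.
#' @export
mean_quality <- function(reads) {
  vapply(reads$qual, function(q) {
    if (!nchar(q)) return(NA_real_)
    mean(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

#' @rdname mean_quality
#' @export
read_lengths <- function(reads) nchar(reads$seq)

#' Read a phred+33 FASTQ file
#'
#' Strict four-line-per-record parser. Malformed records (missing `@` or
#' `+` lines, sequence/quality length mismatch, truncated final record)
#' raise an error naming the offending line. Quality characters outside
#' the phred+33 range 0..93 raise an error; files whose qualities all sit
#' in the phred+64 range are rejected loudly rather than silently
#' rescaled.
#'
#' @param path FASTQ file (uncompressed, phred+33).
#' @return a [seq_reads] object, record order preserved.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) return(seq_reads())
  if (length(lines) %% 4L != 0L)
    stop(sprintf("truncated FASTQ record starting at line %d",
                 (length(lines) %/% 4L) * 4L + 1L))
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop(sprintf("line %d: expected '@' header", (bad[1L] - 1L) * 4L + 1L))
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop(sprintf("line %d: expected '+' separator", (bad[1L] - 1L) * 4L + 3L))
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad))
    stop(sprintf("line %d: sequence and quality lengths differ (%d vs %d)",
                 (bad[1L] - 1L) * 4L + 4L, nchar(seqs[bad[1L]]), nchar(qual[bad[1L]])))
  qmin <- min(vapply(qual[nchar(qual) > 0L],
                     function(q) min(utf8ToInt(q)), numeric(1)), Inf)
  qmax <- max(vapply(qual[nchar(qual) > 0L],
                     function(q) max(utf8ToInt(q)), numeric(1)), -Inf)
  if (is.finite(qmax) && qmax - 33 > 93)
    stop("quality characters exceed phred+33 range; ",
         if (qmin - 33 >= 31) "this looks like phred+64 encoding, " else "",
         "only phred+33 is supported")
  if (is.finite(qmin) && qmin < 33)
    stop("quality characters below '!' are not valid phred+33")
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  seq_reads(ids, seqs, qual)
}

#' Write reads to a phred+33 FASTQ file
#'
#' @param reads a [seq_reads] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq,
                               "+", reads$qual)), con)
  invisible(path)
}
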