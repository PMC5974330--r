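#' Read-level QC parameters
#'
#' Defaults follow the pipeline this package implements: mean read phred
#' at least Q20, lengths between 300 bp (shorter amplicons cannot span
#' ITS2 plus its primers) and 500 bp (upper end of the high-quality
#' length range), and up to 2 mismatches when locating a PCR primer.
#'
#' The quality rule is a mean-phred test by default ("QV" is read as the
#' per-read average, the usual amplicon-pipeline convention). Set
#' `method = "window"` for a stricter per-base alternative that rejects a
#' read if any `window` consecutive bases average below `min_quality`.
#'
#' @param min_quality minimum phred score (default 20).
#' @param min_length minimum read length in bp (default 300).
#' @param max_length maximum read length in bp (default 500).
#' @param primer_max_mismatch maximum Hamming mismatches for primer
#'   masking (default 2).
#' @param method `"mean"` (default) or `"window"`.
#' @param window window size in bases for `method = "window"`.
#' @return a `qc_params` list.
#' @export
qc_params <- function(min_quality = 20, min_length = 300, max_length = 500,
                      primer_max_mismatch = 2, method = c("mean", "window"),
                      window = 25L) {
  method <- match.arg(method)
  stopifnot(min_quality >= 0, min_length > 0, min_length <= max_length,
            primer_max_mismatch >= 0, window >= 1)
  structure(list(min_quality = min_quality, min_length = min_length,
                 max_length = max_length,
                 primer_max_mismatch = primer_max_mismatch,
                 method = method, window = as.integer(window)),
            class = "qc_params")
}

## worst sliding-window mean phred of one quality string
min_window_quality <- function(qual, window) {
  q <- utf8ToInt(qual) - 33
  if (length(q) <= window) return(mean(q))
  mw <- stats::filter(q, rep(1 / window, window), sides = 1)
  min(mw, na.rm = TRUE)
}

#' Filter reads on quality and length
#'
#' Keeps a read iff its quality statistic passes `min_quality` AND its
#' length lies in `[min_length, max_length]`. Rejected reads are counted
#' by the first failing rule, quality before length, so the accounting is
#' deterministic and `nrow(kept) + sum(stats$count) == nrow(reads)`.
#'
#' @param reads a [seq_reads] object.
#' @param params a [qc_params] object.
#' @return list with `kept` (a [seq_reads]) and `stats` (data frame with
#'   columns `rule`, `count`).
#' @export
filter_reads <- function(reads, params = qc_params()) {
  if (!nrow(reads)) {
    return(list(kept = reads,
                stats = data.frame(rule = c("quality", "length"),
                                   count = c(0L, 0L))))
  }
  qstat <- if (params$method == "mean") mean_quality(reads)
           else vapply(reads$qual, min_window_quality, numeric(1),
                       window = params$window, USE.NAMES = FALSE)
  len <- read_lengths(reads)
  fail_q <- qstat < params$min_quality
  fail_l <- !fail_q & (len < params$min_length | len > params$max_length)
  list(kept = reads[!(fail_q | fail_l), , drop = FALSE],
       stats = data.frame(rule = c("quality", "length"),
                          count = c(sum(fail_q), sum(fail_l))))
}

## Hamming distance between equal-length strings
hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

## best start of `primer` inside `seq` restricted to `starts` (1-based);
## returns c(start, mismatches) or NULL
best_primer_site <- function(seq, primer, starts, max_mismatch) {
  lp <- nchar(primer)
  best <- NULL
  for (s in starts) {
    if (s < 1L || s + lp - 1L > nchar(seq)) next
    d <- hamming(substr(seq, s, s + lp - 1L), primer)
    if (d <= max_mismatch && (is.null(best) || d < best[2L]))
      best <- c(s, d)
  }
  best
}

#' Mask PCR primers off read ends
#'
#' Searches for the forward primer within the first `primer length + 3`
#' bases and the reverse complement of the reverse primer within the last
#' `primer length + 3` bases (Hamming distance up to `max_mismatch`);
#' whatever matches is trimmed together with everything outside it. If
#' neither end matches in that (plus) orientation the reverse-strand
#' layout is tried (reverse primer at the 5' end, reverse complement of
#' the forward primer at the 3' end). Reads with no primer at either end
#' are returned unchanged and flagged `unprimed`.
#'
#' @param reads a [seq_reads] object.
#' @param primers a [primer_pair].
#' @param max_mismatch maximum Hamming mismatches per primer (default 2).
#' @return a [seq_reads] with extra columns `unprimed` (logical) and
#'   `orientation` (`"+"`, `"-"`, or `NA` when unprimed).
#' @export
mask_primers <- function(reads, primers, max_mismatch = 2L) {
  stopifnot(inherits(primers, "primer_pair"))
  fwd <- primers$forward
  rev_rc <- revcomp(primers$reverse)
  rev_as_is <- primers$reverse
  fwd_rc <- revcomp(primers$forward)
  n <- nrow(reads)
  unprimed <- logical(n)
  orientation <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- reads$seq[i]
    q <- reads$qual[i]
    len <- nchar(s)
    trim_with <- function(p5, p3) {
      l5 <- nchar(p5); l3 <- nchar(p3)
      hit5 <- best_primer_site(s, p5, 1:4, max_mismatch)
      hit3 <- best_primer_site(s, p3, (len - l3 - 2L):(len - l3 + 1L),
                               max_mismatch)
      if (is.null(hit5) && is.null(hit3)) return(NULL)
      from <- if (!is.null(hit5)) hit5[1L] + l5 else 1L
      to <- if (!is.null(hit3)) hit3[1L] - 1L else len
      list(from = from, to = to)
    }
    cut <- trim_with(fwd, rev_rc)
    ori <- "+"
    if (is.null(cut)) {
      cut <- trim_with(rev_as_is, fwd_rc)
      ori <- "-"
    }
    if (is.null(cut)) {
      unprimed[i] <- TRUE
    } else {
      if (cut$from > cut$to) { # primers overlap: nothing left
        reads$seq[i] <- ""
        reads$qual[i] <- ""
      } else {
        reads$seq[i] <- substr(s, cut$from, cut$to)
        reads$qual[i] <- substr(q, cut$from, cut$to)
      }
      orientation[i] <- ori
    }
  }
  reads$unprimed <- unprimed
  reads$orientation <- orientation
  reads
}

#' Run-level QC thresholds
#'
#' Defaults encode the run-acceptance gates used for the sequencing data
#' this pipeline targets: at least 10,000 reads per sample, and 99% of
#' targeted positions covered at depth 1, 97% at 20 and 95% at 100.
#'
#' @param min_reads minimum reads per sample (default 10000).
#' @param coverage_rules data frame with columns `min_fraction` (in
#'   `[0,1]`) and `depth` (positive, increasing).
#' @return a `run_qc_thresholds` list.
#' @export
run_qc_thresholds <- function(min_reads = 10000L,
                              coverage_rules = data.frame(
                                min_fraction = c(0.99, 0.97, 0.95),
                                depth = c(1L, 20L, 100L))) {
  stopifnot(min_reads >= 0,
            all(coverage_rules$min_fraction >= 0),
            all(coverage_rules$min_fraction <= 1),
            all(coverage_rules$depth > 0),
            !is.unsorted(coverage_rules$depth, strictly = TRUE))
  structure(list(min_reads = as.integer(min_reads),
                 coverage_rules = coverage_rules),
            class = "run_qc_thresholds")
}

#' Run-level QC report
#'
#' Maps every read onto reference coordinates via `hook`, pools per-
#' position depth over all reference positions, and evaluates the read-
#' count and coverage gates.
#'
#' @param reads a [seq_reads] object.
#' @param references named character vector of reference sequences (the
#'   targeted positions).
#' @param thresholds a [run_qc_thresholds].
#' @param hook function mapping a [seq_reads] to a data frame with
#'   columns `ref` (reference name or NA), `start`, `end` (0-based
#'   half-open span on that reference), one row per read. Defaults to a
#'   best-hit mapping with [align_read()].
#' @return a `run_qc_report` list: `n_reads`, `pass_min_reads`,
#'   `coverage` (per-rule fractions and flags) and overall `pass`
#'   (true iff every individual flag is true).
#' @export
run_qc <- function(reads, references, thresholds = run_qc_thresholds(),
                   hook = NULL) {
  stopifnot(length(references) > 0)
  if (is.null(hook)) hook <- alignment_hook(references)
  depth <- lapply(references, function(r) integer(nchar(r)))
  if (nrow(reads)) {
    map <- hook(reads)
    for (i in seq_len(nrow(map))) {
      rn <- map$ref[i]
      if (is.na(rn)) next
      s <- max(map$start[i] + 1L, 1L)
      e <- min(map$end[i], length(depth[[rn]]))
      if (e >= s) depth[[rn]][s:e] <- depth[[rn]][s:e] + 1L
    }
  }
  pooled <- unlist(depth, use.names = FALSE)
  rules <- thresholds$coverage_rules
  rules$fraction <- vapply(rules$depth,
                           function(d) mean(pooled >= d), numeric(1))
  rules$pass <- rules$fraction >= rules$min_fraction
  n_reads <- nrow(reads)
  pass_min <- n_reads >= thresholds$min_reads
  structure(list(n_reads = n_reads, pass_min_reads = pass_min,
                 coverage = rules, pass = pass_min && all(rules$pass)),
            class = "run_qc_report")
}

#' @export
print.run_qc_report <- function(x, ...) {
  cat(sprintf("<run_qc_report> n_reads=%d (min-reads %s); overall %s\n",
              x$n_reads, if (x$pass_min_reads) "pass" else "FAIL",
              if (x$pass) "PASS" else "FAIL"))
  print(x$coverage)
  invisible(x)
}

## default run_qc hook: best alignment per read against the references
alignment_hook <- function(references) {
  force(references)
  function(reads) {
    out <- data.frame(ref = rep(NA_character_, nrow(reads)),
                      start = NA_integer_, end = NA_integer_)
    for (i in seq_len(nrow(reads))) {
      best <- NULL
      for (rn in names(references)) {
        h <- align_read(reads$seq[i], references[[rn]])
        if (is.null(best) || h$score > best$score) {
          best <- h
          best$ref <- rn
        }
      }
      if (!is.null(best)) {
        out$ref[i] <- best$ref
        out$start[i] <- best$ref_start
        out$end[i] <- best$ref_end
      }
    }
    out
  }
}

#' Write per-filter rejection counts as TSV
#'
#' @param stats the `stats` component of [filter_reads()].
#' @param path output TSV (`rule`, `count`).
#' @return `path`, invisibly.
#' @export
write_filter_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
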