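## encode DNA string as 0..3 integers, -1 for anything else
encode_dna <- function(s) {
  lut <- rep(-1L, 256)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  lut[utf8ToInt(s) + 1L]
}

DNA4 <- c("A", "C", "G", "T")

#' Build a DNA profile HMM from a seed alignment
#'
#' Constructs a small Plan7-like profile (match/insert/delete states,
#' begin entering only at the first column, exit only from the last) for
#' a conserved flank such as the 3' end of 5.8S or the 5' end of 28S
#' rRNA. Columns with at least 50% residues become match states; the
#' rest are insert columns. Emissions are Laplace-smoothed counts,
#' `(count + pseudocount) / (total + 4 * pseudocount)`; transitions are
#' estimated from the observed state paths with the same pseudocount;
#' the background is the overall residue frequency (same smoothing).
#'
#' @param seed_alignment character vector of equal-length gapped DNA
#'   strings (characters A/C/G/T/-).
#' @param pseudocount Laplace weight added to every count (default 1).
#' @param name model name.
#' @return a `profile_hmm` object with a default `score_threshold` of 0
#'   bits; see [calibrate_threshold()] for a data-driven cutoff.
#' @export
build_profile <- function(seed_alignment, pseudocount = 1, name = "profile") {
  if (!length(seed_alignment)) stop("empty seed alignment")
  seed_alignment <- toupper(seed_alignment)
  w <- unique(nchar(seed_alignment))
  if (length(w) != 1L) stop("seed alignment rows must have equal length")
  if (any(grepl("[^ACGT-]", seed_alignment)))
    stop("seed alignment may contain only A/C/G/T/-")
  mat <- do.call(rbind, strsplit(seed_alignment, "", fixed = TRUE))
  nseq <- nrow(mat)
  resid_frac <- colMeans(mat != "-")
  is_match <- resid_frac >= 0.5
  L <- sum(is_match)
  if (L < 1L) stop("no match columns (all columns mostly gaps)")
  pc <- pseudocount

  counts4 <- function(ch) {
    ch <- ch[ch != "-"]
    tab <- table(factor(ch, levels = DNA4))
    as.numeric(tab)
  }
  match_cols <- which(is_match)
  match_emissions <- t(vapply(match_cols, function(cc) {
    cnt <- counts4(mat[, cc])
    (cnt + pc) / (sum(cnt) + 4 * pc)
  }, numeric(4)))
  colnames(match_emissions) <- DNA4

  ins_res <- mat[, !is_match, drop = FALSE]
  cnt_i <- counts4(as.vector(ins_res))
  all_cnt <- counts4(as.vector(mat))
  background <- (all_cnt + pc) / (sum(all_cnt) + 4 * pc)
  insert_emission <- if (sum(cnt_i) > 0) (cnt_i + pc) / (sum(cnt_i) + 4 * pc)
                     else background
  names(insert_emission) <- names(background) <- DNA4

  ## transition counts from observed state paths
  z <- numeric(max(L - 1L, 0L))
  cBM <- cBD <- 0
  cMM <- cMI <- cMD <- cIM <- cII <- cDM <- cDD <- z
  mi_of_col <- cumsum(is_match) # match index at/before each column
  for (s in seq_len(nseq)) {
    path <- list() # elements c(type, j); type 1=M 2=I 3=D
    for (cc in seq_len(ncol(mat))) {
      res <- mat[s, cc] != "-"
      if (is_match[cc]) {
        path[[length(path) + 1L]] <- c(if (res) 1L else 3L, mi_of_col[cc])
      } else if (res) {
        j <- mi_of_col[cc]
        if (j >= 1L && j <= L - 1L)
          path[[length(path) + 1L]] <- c(2L, j)
      }
    }
    if (!length(path)) next
    first <- path[[1L]]
    if (first[1L] == 1L) cBM <- cBM + 1 else cBD <- cBD + 1
    if (length(path) > 1L) for (k in seq_len(length(path) - 1L)) {
      a <- path[[k]]; b <- path[[k + 1L]]
      j <- a[2L]
      if (a[1L] == 1L) {
        if (b[1L] == 1L) cMM[j] <- cMM[j] + 1
        else if (b[1L] == 2L) cMI[j] <- cMI[j] + 1
        else cMD[j] <- cMD[j] + 1
      } else if (a[1L] == 2L) {
        ## I -> D is outside the model topology; fold it into I -> M
        if (b[1L] == 2L) cII[j] <- cII[j] + 1 else cIM[j] <- cIM[j] + 1
      } else {
        if (b[1L] == 1L) cDM[j] <- cDM[j] + 1
        else if (b[1L] == 3L) cDD[j] <- cDD[j] + 1
        ## D -> I not modelled; dropped
      }
    }
  }
  norm2 <- function(a, b) {
    tot <- a + b + 2 * pc
    list((a + pc) / tot, (b + pc) / tot)
  }
  norm3 <- function(a, b, c) {
    tot <- a + b + c + 3 * pc
    list((a + pc) / tot, (b + pc) / tot, (c + pc) / tot)
  }
  tB <- norm2(cBM, cBD)
  tM <- norm3(cMM, cMI, cMD)
  tI <- norm2(cIM, cII)
  tD <- norm2(cDM, cDD)
  hmm <- structure(list(
    name = name, L = L,
    match_emissions = match_emissions,
    insert_emission = insert_emission,
    background = background,
    transitions = list(BM = tB[[1]], BD = tB[[2]],
                       MM = tM[[1]], MI = tM[[2]], MD = tM[[3]],
                       IM = tI[[1]], II = tI[[2]],
                       DM = tD[[1]], DD = tD[[2]]),
    score_threshold = 0,
    pseudocount = pc
  ), class = "profile_hmm")
  validate_profile(hmm)
  hmm$log <- hmm_log(hmm)
  hmm
}

validate_profile <- function(hmm) {
  stopifnot(hmm$L >= 1)
  stopifnot(all(abs(rowSums(hmm$match_emissions) - 1) < 1e-9))
  stopifnot(abs(sum(hmm$insert_emission) - 1) < 1e-9,
            abs(sum(hmm$background) - 1) < 1e-9)
  tr <- hmm$transitions
  stopifnot(abs(tr$BM + tr$BD - 1) < 1e-9)
  if (hmm$L > 1) {
    stopifnot(all(abs(tr$MM + tr$MI + tr$MD - 1) < 1e-9),
              all(abs(tr$IM + tr$II - 1) < 1e-9),
              all(abs(tr$DM + tr$DD - 1) < 1e-9))
  }
  invisible(hmm)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm> '%s': L=%d, threshold=%.2f bits\n",
              x$name, x$L, x$score_threshold))
  invisible(x)
}

## log2-odds pieces consumed by the C decoder
hmm_log <- function(hmm) {
  bg <- hmm$background
  list(lm = log2(sweep(hmm$match_emissions, 2, bg, "/")),
       li = log2(hmm$insert_emission / bg),
       tBM = log2(hmm$transitions$BM), tBD = log2(hmm$transitions$BD),
       tMM = log2(hmm$transitions$MM), tMI = log2(hmm$transitions$MI),
       tMD = log2(hmm$transitions$MD),
       tIM = log2(hmm$transitions$IM), tII = log2(hmm$transitions$II),
       tDM = log2(hmm$transitions$DM), tDD = log2(hmm$transitions$DD))
}

viterbi_raw <- function(hmm, seq) {
  lg <- if (!is.null(hmm$log)) hmm$log else hmm_log(hmm)
  viterbi_glocal_cpp(lg$lm, lg$li, lg$tBM, lg$tBD, lg$tMM, lg$tMI, lg$tMD,
                     lg$tIM, lg$tII, lg$tDM, lg$tDD, encode_dna(seq))
}

#' Locate the best hit of a profile on a sequence
#'
#' Glocal Viterbi decode: the full model is aligned to the best-scoring
#' substring (log-odds in bits against the model background). Both
#' strands are scanned unless restricted; minus-strand coordinates are
#' mapped back to the input sequence.
#'
#' @param hmm a `profile_hmm`.
#' @param seq a DNA string.
#' @param strands strands to scan, subset of `c("+", "-")`.
#' @param threshold score cutoff in bits; defaults to
#'   `hmm$score_threshold`. Hits scoring below it return `NULL`.
#' @return `NULL`, or a `flank_hit` list with `start`, `end` (0-based
#'   half-open on `seq`), `score` (bits) and `strand`.
#' @export
viterbi_locate <- function(hmm, seq, strands = c("+", "-"),
                           threshold = hmm$score_threshold) {
  stopifnot(nchar(seq) >= 1)
  best <- NULL
  n <- nchar(seq)
  for (st in strands) {
    s <- if (st == "+") seq else revcomp(seq)
    r <- viterbi_raw(hmm, s)
    if (!is.finite(r$score)) next
    if (st == "-") {
      tmp <- r$start
      r$start <- n - r$end
      r$end <- n - tmp
    }
    if (is.null(best) || r$score > best$score)
      best <- list(start = r$start, end = r$end, score = r$score,
                   strand = st)
  }
  if (is.null(best) || best$score < threshold) return(NULL)
  structure(best, class = "flank_hit")
}

#' Calibrate a profile's score threshold from a shuffled null
#'
#' Dinucleotide-shuffles each input sequence (destroying the motif while
#' preserving composition), records the best glocal Viterbi score of each
#' shuffle, and sets the threshold to the `q`-th quantile of that
#' empirical null distribution.
#'
#' @param hmm a `profile_hmm`.
#' @param sequences character vector of motif-bearing (or representative
#'   target) sequences; each is shuffled once.
#' @param q quantile of the null used as threshold (default 0.95).
#' @return the `hmm` with `score_threshold` set; the null scores are
#'   attached as attribute `"null_scores"`.
#' @export
calibrate_threshold <- function(hmm, sequences, q = 0.95) {
  stopifnot(length(sequences) > 0)
  shuffled <- vapply(sequences, dinuc_shuffle, character(1),
                     USE.NAMES = FALSE)
  scores <- vapply(shuffled, function(s) {
    h <- viterbi_locate(hmm, s, threshold = -Inf)
    if (is.null(h)) -Inf else h$score
  }, numeric(1), USE.NAMES = FALSE)
  hmm$score_threshold <- stats::quantile(scores[is.finite(scores)], q,
                                         names = FALSE, type = 7)
  attr(hmm, "null_scores") <- scores
  hmm
}

#' Consensus sequence of a profile
#'
#' Highest-emission base of each match state.
#'
#' @param hmm a `profile_hmm`.
#' @return DNA string of length `hmm$L`.
#' @export
profile_consensus <- function(hmm) {
  paste(DNA4[max.col(hmm$match_emissions, ties.method = "first")],
        collapse = "")
}

#' Annotate the ITS2 span of a sequence using the two flank profiles
#'
#' ITS2 proper starts where the best 5.8S hit ends and ends where the
#' best 28S hit starts (0-based half-open). A missing left flank puts
#' the start at 0; a missing right flank puts the end at the sequence
#' length. Overlapping or crossing hits yield status `"none"` and no
#' trim. Scanning is plus-strand by default (curated references are
#' stored in plus orientation); see [hmm_trim_reads()] for
#' orientation-aware read trimming.
#'
#' @param seq a DNA string.
#' @param hmm_5p8S profile for the 5.8S 3'-end flank.
#' @param hmm_28S profile for the 28S 5'-end flank.
#' @param strands strands scanned for each flank.
#' @return an `annotated_its2` list: `its2_start`, `its2_end`, `status`
#'   (one of both_flanks/left_only/right_only/none), `left_hit`,
#'   `right_hit`.
#' @export
annotate_its2 <- function(seq, hmm_5p8S, hmm_28S, strands = "+") {
  stopifnot(nchar(seq) >= 1)
  n <- nchar(seq)
  left <- viterbi_locate(hmm_5p8S, seq, strands = strands)
  right <- viterbi_locate(hmm_28S, seq, strands = strands)
  status <- if (!is.null(left) && !is.null(right)) "both_flanks"
            else if (!is.null(left)) "left_only"
            else if (!is.null(right)) "right_only"
            else "none"
  s <- if (!is.null(left)) left$end else 0L
  e <- if (!is.null(right)) right$start else n
  if (s > e) { # flank hits cross: refuse to trim
    status <- "none"
    s <- 0L
    e <- n
  }
  structure(list(its2_start = s, its2_end = e, status = status,
                 left_hit = left, right_hit = right),
            class = "annotated_its2")
}

#' Trim a batch of sequences to their ITS2 span
#'
#' Applies [annotate_its2()] to every record; records whose trimmed span
#' is shorter than `min_len` are dropped and reported.
#'
#' @param seqs named character vector of DNA sequences.
#' @param hmms list with elements `hmm_5p8S` and `hmm_28S`.
#' @param min_len minimum trimmed length kept (default 100).
#' @return list with `seqs` (named character vector of trimmed, kept
#'   records) and `report` (data frame: id, status, its2_start,
#'   its2_end, left_score, right_score, kept).
#' @export
trim_batch <- function(seqs, hmms, min_len = 100L) {
  if (!length(seqs)) {
    return(list(seqs = stats::setNames(character(0), character(0)),
                report = data.frame(id = character(0), status = character(0),
                                    its2_start = integer(0),
                                    its2_end = integer(0),
                                    left_score = numeric(0),
                                    right_score = numeric(0),
                                    kept = logical(0))))
  }
  ann <- lapply(seqs, annotate_its2, hmm_5p8S = hmms$hmm_5p8S,
                hmm_28S = hmms$hmm_28S)
  report <- data.frame(
    id = names(seqs),
    status = vapply(ann, `[[`, character(1), "status"),
    its2_start = vapply(ann, `[[`, numeric(1), "its2_start"),
    its2_end = vapply(ann, `[[`, numeric(1), "its2_end"),
    left_score = vapply(ann, function(a)
      if (is.null(a$left_hit)) NA_real_ else a$left_hit$score, numeric(1)),
    right_score = vapply(ann, function(a)
      if (is.null(a$right_hit)) NA_real_ else a$right_hit$score, numeric(1)),
    row.names = NULL)
  trimmed <- vapply(seq_along(seqs), function(i)
    substr(seqs[[i]], ann[[i]]$its2_start + 1L, ann[[i]]$its2_end),
    character(1))
  names(trimmed) <- names(seqs)
  report$kept <- nchar(trimmed) >= min_len
  list(seqs = trimmed[report$kept], report = report)
}

#' Orientation-aware ITS2 trimming of reads
#'
#' Annotates each read on both orientations (the flank layout is only
#' meaningful in plus orientation) and trims to the span supported by the
#' higher total flank score; qualities are trimmed in step. Reads keep
#' their original orientation — the classifier is strand-aware.
#'
#' @param reads a [seq_reads] object.
#' @param hmms list with `hmm_5p8S` and `hmm_28S`.
#' @param orientation optional per-read orientation hint (`"+"`, `"-"`,
#'   `NA`), e.g. the `orientation` column set by [mask_primers()]; when
#'   known, only that orientation is annotated.
#' @return the trimmed [seq_reads].
#' @export
hmm_trim_reads <- function(reads, hmms, orientation = reads$orientation) {
  ann_score <- function(a) {
    (if (is.null(a$left_hit)) 0 else a$left_hit$score) +
      (if (is.null(a$right_hit)) 0 else a$right_hit$score)
  }
  if (is.null(orientation)) orientation <- rep(NA_character_, nrow(reads))
  for (i in seq_len(nrow(reads))) {
    s <- reads$seq[i]
    if (!nchar(s)) next
    n <- nchar(s)
    ori <- orientation[i]
    ap <- if (is.na(ori) || ori == "+")
      annotate_its2(s, hmms$hmm_5p8S, hmms$hmm_28S) else NULL
    am <- if (is.na(ori) || ori == "-")
      annotate_its2(revcomp(s), hmms$hmm_5p8S, hmms$hmm_28S) else NULL
    if (!is.null(am) && (is.null(ap) || ann_score(am) > ann_score(ap))) {
      from <- n - am$its2_end + 1L
      to <- n - am$its2_start
    } else {
      from <- ap$its2_start + 1L
      to <- ap$its2_end
    }
    reads$seq[i] <- substr(s, from, to)
    reads$qual[i] <- substr(reads$qual[i], from, to)
  }
  reads
}

#' Serialize / deserialize a profile to JSON
#'
#' @param hmm a `profile_hmm`.
#' @param path JSON file.
#' @return `write_profile`: `path` invisibly; `read_profile`: the
#'   `profile_hmm`.
#' @export
write_profile <- function(hmm, path) {
  obj <- unclass(hmm)
  obj$log <- NULL
  attr(obj, "null_scores") <- NULL
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$match_emissions <- matrix(obj$match_emissions, ncol = 4,
                                dimnames = list(NULL, DNA4))
  names(obj$insert_emission) <- names(obj$background) <- DNA4
  obj$transitions <- lapply(obj$transitions, as.numeric)
  obj$log <- NULL
  hmm <- structure(obj, class = "profile_hmm")
  validate_profile(hmm)
  hmm$log <- hmm_log(hmm)
  hmm
}

#' Flank profiles from the packaged synthetic seed alignments
#'
#' Builds the 5.8S-tail and 28S-head models from the seed alignments
#' shipped under `inst/extdata` (synthetic conserved motifs used by the
#' simulator and the tests; substitute real 5.8S/28S seeds for real
#' data) and calibrates each score threshold on `n_null` dinucleotide-
#' shuffled decoys.
#'
#' @param pseudocount Laplace weight for [build_profile()].
#' @param n_null null size for [calibrate_threshold()] (0 skips
#'   calibration and keeps the 0-bit default).
#' @param seed RNG seed for the null (restored afterwards).
#' @return list with `hmm_5p8S` and `hmm_28S`.
#' @export
flank_hmms <- function(pseudocount = 1, n_null = 100L, seed = 1L) {
  seed_file <- function(f) system.file("extdata", f, package = "herbauth",
                                       mustWork = TRUE)
  a58 <- read_seed_alignment(seed_file("synthetic_5p8S_seed.afa"))
  a28 <- read_seed_alignment(seed_file("synthetic_28S_seed.afa"))
  h58 <- build_profile(a58, pseudocount, name = "5.8S_3prime")
  h28 <- build_profile(a28, pseudocount, name = "28S_5prime")
  if (n_null > 0) {
    with_seed(seed, {
      decoys58 <- paste0(random_dna(n_null, 60), profile_consensus(h58),
                         random_dna(n_null, 60))
      decoys28 <- paste0(random_dna(n_null, 60), profile_consensus(h28),
                         random_dna(n_null, 60))
      h58 <- harden_threshold(calibrate_threshold(h58, decoys58))
      h28 <- harden_threshold(calibrate_threshold(h28, decoys28))
    })
  }
  list(hmm_5p8S = h58, hmm_28S = h28)
}

## A threshold sitting exactly on the null's 95th percentile admits ~5%
## chance hits per scan by construction, which is far too loose for
## database validation (every clean record would have a 1-in-20 shot at
## a phantom flank). True flank hits score two orders of magnitude
## above the null here, so the packaged models push the cutoff to the
## midpoint between the null maximum and the consensus score.
harden_threshold <- function(hmm) {
  cons <- viterbi_locate(hmm, profile_consensus(hmm), strands = "+",
                         threshold = -Inf)$score
  null_max <- max(attr(hmm, "null_scores")[
    is.finite(attr(hmm, "null_scores"))])
  hmm$score_threshold <- max(hmm$score_threshold, (null_max + cons) / 2)
  hmm
}

#' Read an aligned FASTA seed alignment
#'
#' Like [read_fasta()] but keeps gap characters.
#'
#' @param path aligned FASTA file.
#' @return character vector of equal-length gapped rows.
#' @export
read_seed_alignment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  idx <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  stats::setNames(unname(seqs), sub("^>\\s*", "", lines[hdr]))
}

## evaluate expr under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
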