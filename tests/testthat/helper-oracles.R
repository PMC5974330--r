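# Independent reference implementations used to cross-check the compiled
# dynamic-programming kernels. Deliberately written as plain, readable R
# (per-start / per-cell recurrences) rather than mirroring the C code.

## quadratic-DP semi-global aligner (free end gaps on the reference,
## affine gaps, no X<->Y switches); returns score and BLAST-like identity
oracle_align <- function(q, r, match = 1, mis = -1, open = -2, ext = -1) {
  qs <- strsplit(q, "")[[1]]
  rs <- strsplit(r, "")[[1]]
  n <- length(qs)
  m <- length(rs)
  NEG <- -1e15
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  bM <- bX <- bY <- matrix(0L, n + 1, m + 1) # 1=M,2=X,3=Y,0=start
  for (i in 1:n) {
    for (jj in 1:(m + 1)) {
      j <- jj - 1
      if (j >= 1) {
        if (i == 1) {
          prev <- 0; back <- 0L
        } else {
          vals <- c(M[i, jj - 1], X[i, jj - 1], Y[i, jj - 1])
          back <- which.max(vals) # first max wins: prefer M, X, Y
          prev <- vals[back]
        }
        sc <- if (qs[i] == rs[j] && qs[i] != "N") match else mis
        M[i + 1, jj] <- prev + sc
        bM[i + 1, jj] <- back
      }
      vals <- c(if (i == 1) 0 + open else M[i, jj] + open,
                if (i == 1) NEG else X[i, jj] + ext)
      back <- which.max(vals)
      X[i + 1, jj] <- vals[back]
      bX[i + 1, jj] <- if (i == 1) 0L else c(1L, 2L)[back]
      if (j >= 1) {
        vals <- c(M[i + 1, jj - 1] + open, Y[i + 1, jj - 1] + ext)
        back <- which.max(vals)
        Y[i + 1, jj] <- vals[back]
        bY[i + 1, jj] <- c(1L, 3L)[back]
      }
    }
  }
  best <- NEG; bjj <- 1L; blayer <- 1L
  for (jj in 1:(m + 1)) {
    if (M[n + 1, jj] > best) { best <- M[n + 1, jj]; bjj <- jj; blayer <- 1L }
    if (X[n + 1, jj] > best) { best <- X[n + 1, jj]; bjj <- jj; blayer <- 2L }
  }
  i <- n; jj <- bjj; layer <- blayer
  matches <- 0L; cols <- integer(0)
  repeat {
    if (layer == 1L) {
      back <- bM[i + 1, jj]
      if (qs[i] == rs[jj - 1] && qs[i] != "N") matches <- matches + 1L
      cols <- c(cols, 1L)
      i <- i - 1L; jj <- jj - 1L
      if (i == 0L) break
    } else if (layer == 2L) {
      back <- bX[i + 1, jj]
      cols <- c(cols, 2L)
      i <- i - 1L
      if (i == 0L) break
    } else {
      back <- bY[i + 1, jj]
      cols <- c(cols, 3L)
      jj <- jj - 1L
    }
    layer <- back
  }
  diag_idx <- which(cols == 1L)
  core <- if (length(diag_idx)) max(diag_idx) - min(diag_idx) + 1L else 0L
  list(score = best,
       identity = if (core > 0) 100 * matches / core else 0,
       matches = matches, aligned_cols = core)
}

## exhaustive glocal Viterbi oracle: one independent DP per entry
## boundary s, maximising over all exit boundaries; returns the best
## score and, for a given (start, end), whether it attains it
oracle_viterbi <- function(hmm, seq) {
  x <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T")) # NA for N
  n <- length(x)
  L <- hmm$L
  emM <- log2(sweep(hmm$match_emissions, 2, hmm$background, "/"))
  emI <- log2(hmm$insert_emission / hmm$background)
  tr <- lapply(hmm$transitions, log2)
  e_at <- function(pos, j) if (is.na(x[pos])) 0 else emM[j, x[pos]]
  ei_at <- function(pos) if (is.na(x[pos])) 0 else emI[x[pos]]
  best <- -Inf
  ends_of_start <- list()
  for (s in 0:(n - 1)) {
    len <- n - s + 1 # boundary indices b = 0..n-s (absolute s+b)
    Ms <- Is <- Ds <- matrix(-Inf, len, L)
    Ei <- cumsum(c(0, vapply(seq_len(n - s), function(k) ei_at(s + k),
                             numeric(1))))
    for (j in 1:L) {
      if (j == 1) {
        Ms[2, 1] <- tr$BM + e_at(s + 1, 1)
        Ds[1, 1] <- tr$BD
      } else {
        Ms[2:len, j] <- vapply(2:len, function(b)
          e_at(s + b - 1, j) + max(Ms[b - 1, j - 1] + tr$MM[j - 1],
                                   Is[b - 1, j - 1] + tr$IM[j - 1],
                                   Ds[b - 1, j - 1] + tr$DM[j - 1]),
          numeric(1))
        Ds[, j] <- pmax(Ms[, j - 1] + tr$MD[j - 1],
                        Ds[, j - 1] + tr$DD[j - 1])
      }
      if (j <= L - 1 && len >= 2) {
        ## inserts: last match at boundary b0, then b - b0 inserted bases
        A <- Ms[, j] - Ei - (0:(len - 1)) * tr$II[j]
        cm <- cummax(A)
        Is[2:len, j] <- Ei[2:len] + tr$MI[j] + (1:(len - 1) - 1) * tr$II[j] +
          cm[1:(len - 1)]
      }
    }
    ends <- pmax(Ms[, L], Ds[, L])
    ends[1] <- -Inf # pure-delete path emits nothing
    ends_of_start[[s + 1]] <- ends
    best <- max(best, max(ends))
  }
  list(score = best,
       score_at = function(start, end) ends_of_start[[start + 1]][end - start + 1])
}

## brute-force sliding Hamming primer scan (the mask_primers oracle)
oracle_primer_site <- function(seq, primer, window_starts, max_mm) {
  lp <- nchar(primer)
  hits <- list()
  for (s in window_starts) {
    if (s < 1 || s + lp - 1 > nchar(seq)) next
    d <- sum(utf8ToInt(substr(seq, s, s + lp - 1)) != utf8ToInt(primer))
    if (d <= max_mm) hits[[length(hits) + 1]] <- c(s, d)
  }
  if (!length(hits)) return(NULL)
  hits <- do.call(rbind, hits)
  hits[order(hits[, 2], hits[, 1]), , drop = FALSE][1, ]
}
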