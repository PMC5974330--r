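#' Species-specific PCR primer pair
#'
#' @param name assay name.
#' @param forward,reverse primer sequences 5'->3' (15-35 nt, ACGT only).
#' @param max_amplicon maximum product length in bp (default 1000).
#' @return a `primer_pair` list.
#' @export
primer_pair <- function(name, forward, reverse, max_amplicon = 1000L) {
  forward <- toupper(forward)
  reverse <- toupper(reverse)
  for (p in c(forward, reverse)) {
    if (nchar(p) < 15 || nchar(p) > 35)
      stop("primers must be 15-35 nt: ", p)
    if (!is_dna(p, extra = ""))
      stop("primers must be ACGT only: ", p)
  }
  structure(list(name = name, forward = forward, reverse = reverse,
                 max_amplicon = as.integer(max_amplicon)),
            class = "primer_pair")
}

#' Read primer pairs from a TSV table
#'
#' Expected columns: `name`, `forward`, `reverse` (the layout of a
#' published assay table).
#'
#' @param path TSV file.
#' @return list of [primer_pair] objects.
#' @export
read_primer_pairs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i)
    primer_pair(tab$name[i], tab$forward[i], tab$reverse[i]))
}

#' The packaged congener assay primers
#'
#' The two published species-specific real-time PCR assays for
#' Arisaematis Rhizoma (assay "DB") and its common adulterant
#' *Pinellia pedatisecta* (assay "HZ"). Both forward primers share the
#' 5' motif `TGGCCCACC` and diverge towards their 3' ends — the region
#' the in-silico specificity rule keys on.
#'
#' @return list of two [primer_pair] objects.
#' @export
assay_primers <- function() {
  read_primer_pairs(system.file("extdata", "assay_primers.tsv",
                                package = "herbauth", mustWork = TRUE))
}

## ungapped mismatch profile of `primer` placed at 1-based `start`
site_mismatches <- function(primer, template, start) {
  lp <- nchar(primer)
  frag <- substr(template, start, start + lp - 1L)
  d <- utf8ToInt(frag) != utf8ToInt(primer)
  c(total = sum(d), three_prime = sum(d[(lp - 3L):lp]))
}

#' Best ungapped binding site of a primer on each strand
#'
#' Exhaustive scan of the template and its reverse complement. The best
#' site has the fewest total mismatches; ties prefer fewer mismatches in
#' the last 4 bases of the primer 3' end, then the leftmost template
#' position.
#'
#' @param primer primer sequence 5'->3'.
#' @param template template DNA.
#' @return data frame with one row per strand: `strand`, `pos` (0-based
#'   template position of the site's leftmost base on the plus strand),
#'   `total_mm`, `three_prime_mm`.
#' @export
find_binding <- function(primer, template) {
  lp <- nchar(primer)
  n <- nchar(template)
  scan <- function(tmpl) {
    if (n < lp) return(c(NA_integer_, NA_integer_, NA_integer_))
    best <- NULL
    for (s in 1:(n - lp + 1L)) {
      mm <- site_mismatches(primer, tmpl, s)
      if (is.null(best) || mm[1L] < best[2L] ||
          (mm[1L] == best[2L] && mm[2L] < best[3L]))
        best <- c(s, mm[[1L]], mm[[2L]])
    }
    best
  }
  plus <- scan(template)
  minus <- scan(revcomp(template))
  ## map minus-strand scan position back to plus-strand coordinates
  if (!is.na(minus[1L])) minus[1L] <- n - (minus[1L] - 1L) - lp + 1L
  data.frame(strand = c("+", "-"),
             pos = c(plus[1L], minus[1L]) - 1L,
             total_mm = c(plus[2L], minus[2L]),
             three_prime_mm = c(plus[3L], minus[3L]))
}

#' Predict whether a primer pair amplifies a template
#'
#' Mismatch-count rule standing in for thermodynamic modelling: the
#' forward primer must bind the plus strand and the reverse primer the
#' minus strand downstream of it, each with at most `max_total_mm` total
#' mismatches and at most `max_3p_mm` mismatches within the last 4
#' bases of its 3' end, and the product must not exceed
#' `pair$max_amplicon`. 3'-terminal mismatches block extension, which
#' is exactly how congener-discriminating assays are designed.
#'
#' @param pair a [primer_pair].
#' @param template template DNA.
#' @param max_total_mm total mismatch tolerance per primer (default 2).
#' @param max_3p_mm 3'-window mismatch tolerance (default 0).
#' @return list with `amplifies` (logical) and `span` (0-based half-open
#'   product span including both primers, or `NULL`).
#' @export
predict_amplification <- function(pair, template, max_total_mm = 2L,
                                  max_3p_mm = 0L) {
  lf <- nchar(pair$forward)
  lr <- nchar(pair$reverse)
  n <- nchar(template)
  ok_site <- function(mm) mm[1L] <= max_total_mm && mm[2L] <= max_3p_mm
  ## qualifying forward sites on the plus strand
  fsites <- integer(0)
  if (n >= lf) for (s in 1:(n - lf + 1L))
    if (ok_site(site_mismatches(pair$forward, template, s)))
      fsites <- c(fsites, s)
  ## qualifying reverse sites: rev primer binds the minus strand, i.e.
  ## revcomp(reverse) appears on the plus strand
  rrc <- revcomp(pair$reverse)
  rsites <- integer(0)
  if (n >= lr) {
    rc_t <- revcomp(template)
    for (s in 1:(n - lr + 1L))
      if (ok_site(site_mismatches(pair$reverse, rc_t, s)))
        rsites <- c(rsites, n - (s - 1L) - lr + 1L) # plus-strand start
  }
  for (f in fsites) {
    ends <- rsites[rsites >= f] + lr - 1L
    ends <- ends[ends - f + 1L <= pair$max_amplicon & ends - f + 1L >= lf + lr]
    if (length(ends))
      return(list(amplifies = TRUE,
                  span = c(start = f - 1L, end = min(ends))))
  }
  list(amplifies = FALSE, span = NULL)
}

#' Cross-specificity matrix of assays against templates
#'
#' One [predict_amplification()] call per (pair, template). A warning is
#' emitted if any assay amplifies more than one template (non-specific
#' assay).
#'
#' @param pairs list of [primer_pair] objects.
#' @param templates named character vector of template sequences.
#' @param ... passed to [predict_amplification()].
#' @return logical matrix, rows = assays, columns = templates.
#' @export
specificity_matrix <- function(pairs, templates, ...) {
  m <- matrix(FALSE, nrow = length(pairs), ncol = length(templates),
              dimnames = list(vapply(pairs, `[[`, character(1), "name"),
                              names(templates)))
  for (i in seq_along(pairs))
    for (j in seq_along(templates))
      m[i, j] <- predict_amplification(pairs[[i]], templates[[j]],
                                       ...)$amplifies
  if (length(templates) && any(rowSums(m) > 1))
    warning("non-specific assay(s): ",
            paste(rownames(m)[rowSums(m) > 1], collapse = ", "))
  m
}

#' Presence call from a qPCR Ct value
#'
#' Present iff the Ct is a number strictly below the threshold; a Ct
#' exactly at the threshold, above it, or absent (no amplification,
#' `NA`) is called absent.
#'
#' @param ct Ct value in cycles, or `NA` for no amplification
#'   (vectorised).
#' @param ct_threshold cycle cutoff (default 32).
#' @return logical vector.
#' @export
call_presence <- function(ct, ct_threshold = 32) {
  !is.na(ct) & ct < ct_threshold
}

#' Poisson quantification of a digital PCR chip
#'
#' With a fraction `p` of positive wells, the mean occupancy is
#' `lambda = -ln(1 - p)` copies per well; the concentration is
#' `lambda / well_volume * dilution` copies/uL. The 95% CI is a
#' Clopper-Pearson binomial interval on `p` propagated through the same
#' transform. A saturated chip (`p = 1`) is unquantifiable and raises
#' an error.
#'
#' @param positive_wells,total_wells well counts.
#' @param well_volume well volume in uL (default 0.000755, the 755 pL of
#'   a 20k-well chip).
#' @param dilution dilution factor applied to the loaded sample
#'   (default 1).
#' @param conf confidence level (default 0.95).
#' @return list with `p`, `lambda` (copies/well), `copies_per_ul`, and
#'   `ci` (length-2 copies/uL interval).
#' @export
dpcr_quantify <- function(positive_wells, total_wells,
                          well_volume = 0.000755, dilution = 1,
                          conf = 0.95) {
  stopifnot(total_wells > 0, positive_wells >= 0,
            positive_wells <= total_wells, well_volume > 0, dilution > 0)
  if (positive_wells == total_wells)
    stop("saturated chip (all wells positive): unquantifiable")
  p <- positive_wells / total_wells
  lambda <- -log1p(-p)
  alpha <- 1 - conf
  lo_p <- if (positive_wells == 0) 0 else
    stats::qbeta(alpha / 2, positive_wells, total_wells - positive_wells + 1)
  hi_p <- stats::qbeta(1 - alpha / 2, positive_wells + 1,
                       total_wells - positive_wells)
  to_conc <- function(pp) -log1p(-pp) / well_volume * dilution
  list(p = p, lambda = lambda,
       copies_per_ul = lambda / well_volume * dilution,
       ci = c(lower = to_conc(lo_p), upper = to_conc(hi_p)))
}
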