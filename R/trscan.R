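## Tandem-repeat detection (unit 6-57 bp by default, fractional final
## copies) and cross-accession copy-number comparison. Detection is by
## period-shift equality runs: position i matches position i+u for a run of
## length r implies a periodic stretch of span r+u and copies (r+u)/u.

#' Find tandem repeats in a sequence
#'
#' Scans every unit length in `[min_unit, max_unit]` for maximal periodic
#' stretches with at least `min_copies` copies (final partial copy counted
#' fractionally). Overlapping candidates are resolved by longer span, then
#' smaller unit, then leftmost start; a stretch periodic at several unit
#' lengths is reported once at its smallest unit. With `min_purity < 1`
#' exact cores are greedily extended across isolated mismatches while the
#' matching-base fraction stays above the threshold.
#'
#' @param sequence Character scalar.
#' @param min_unit,max_unit Unit-length window (default 6-57; raise
#'   `max_unit` for large-unit mode, e.g. nrDNA IGS sub-repeats).
#' @param min_copies Minimum copy number to report (default 2).
#' @param min_purity Minimum fraction of period-matching bases (default 1).
#' @return data.frame: start, end, unit_length, unit, copies, span, purity.
#'   `copies` is exact span/unit_length; display rounding is left to callers.
#' @export
find_tandem_repeats <- function(sequence, min_unit = 6L, max_unit = 57L,
                                min_copies = 2, min_purity = 1) {
  stopifnot(min_unit >= 1L, max_unit >= min_unit)
  x <- charToRaw(toupper(sequence))
  n <- length(x)
  cands <- list()
  for (u in min_unit:max_unit) {
    if (n < 2L * u) break
    eq <- x[1:(n - u)] == x[(u + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    run_min <- ceiling(u * (min_copies - 1))
    sel <- which(r$values & r$lengths >= run_min)
    for (s in sel) {
      i <- starts[s]; len <- r$lengths[s]
      mism <- 0L
      if (min_purity < 1) {
        ## greedy right-extension across isolated mismatch columns
        jend <- ends[s]
        while (jend < length(eq)) {
          k2 <- jend + 1L
          while (k2 <= length(eq) && !eq[k2]) k2 <- k2 + 1L
          if (k2 > length(eq) || !eq[k2]) break
          nxt <- k2
          run2 <- 0L
          while (nxt + run2 <= length(eq) && eq[nxt + run2]) run2 <- run2 + 1L
          new_m <- mism + (nxt - jend - 1L)
          new_len <- (nxt + run2 - 1L) - i + 1L
          if ((new_len - new_m) / new_len < min_purity) break
          mism <- new_m; len <- new_len; jend <- nxt + run2 - 1L
        }
      }
      span <- len + u
      cands[[length(cands) + 1L]] <- data.frame(
        start = i, end = i + span - 1L, unit_length = u,
        copies = span / u, span = span,
        purity = (len - mism + u) / span)
    }
  }
  empty <- data.frame(start = integer(0), end = integer(0),
                      unit_length = integer(0), unit = character(0),
                      copies = numeric(0), span = integer(0),
                      purity = numeric(0))
  if (!length(cands)) return(empty)
  cand <- do.call(rbind, cands)
  cand <- cand[cand$copies >= min_copies, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  ## resolution: longer span, then smaller unit, then leftmost; greedy
  ## non-overlap acceptance
  cand <- cand[order(-cand$span, cand$unit_length, cand$start), ]
  acc <- logical(nrow(cand))
  occ_start <- integer(0); occ_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!length(occ_start) ||
        all(cand$end[i] < occ_start | cand$start[i] > occ_end)) {
      acc[i] <- TRUE
      occ_start <- c(occ_start, cand$start[i])
      occ_end <- c(occ_end, cand$end[i])
    }
  }
  out <- cand[acc, , drop = FALSE]
  out <- out[order(out$start), ]
  out$unit <- substring(sequence, out$start, out$start + out$unit_length - 1L)
  rownames(out) <- NULL
  out[, c("start", "end", "unit_length", "unit", "copies", "span", "purity")]
}

#' Compare a tandem-repeat locus across accessions
#'
#' Locates the locus by its flanking anchor sequences (which must occur
#' exactly once per accession) and derives the copy number from the
#' inter-flank span: `copies = (span - non_repeat_residue) / unit_length`.
#'
#' @param reference Reference sequence.
#' @param locus_start,locus_end Reference interval of the repeat array.
#' @param unit_length Repeat unit length.
#' @param sequences Named list of accession sequences.
#' @param flank_length Anchor length each side (default 100).
#' @param flank_mismatch Substitutions tolerated inside a flank anchor
#'   (default 3; covers other cohort SNPs falling into the flank).
#' @return A `cnv_call`: list(locus, unit_length, copies_per_accession,
#'   informative).
#' @export
compare_tr_locus <- function(reference, locus_start, locus_end, unit_length,
                             sequences, flank_length = 100L,
                             flank_mismatch = 3L) {
  lf <- substr(reference, locus_start - flank_length, locus_start - 1L)
  rf <- substr(reference, locus_end + 1L, locus_end + flank_length)
  ref_span <- locus_end - locus_start + 1L
  residue <- ref_span %% unit_length
  copies <- vapply(names(sequences), function(acc) {
    s <- Biostrings::DNAString(sequences[[acc]])
    pl <- IRanges::start(Biostrings::matchPattern(lf, s,
      max.mismatch = flank_mismatch, with.indels = FALSE))
    pr <- IRanges::start(Biostrings::matchPattern(rf, s,
      max.mismatch = flank_mismatch, with.indels = FALSE))
    if (length(pl) != 1L)
      stop("anchor error: left flank of locus ",
           if (length(pl)) "duplicated" else "missing", " in accession ",
           acc, call. = FALSE)
    if (length(pr) != 1L)
      stop("anchor error: right flank of locus ",
           if (length(pr)) "duplicated" else "missing", " in accession ",
           acc, call. = FALSE)
    span <- pr[1] - (pl[1] + flank_length)
    (span - residue) / unit_length
  }, numeric(1))
  structure(list(locus = c(start = locus_start, end = locus_end),
                 unit_length = unit_length, copies_per_accession = copies,
                 informative = length(unique(copies)) >= 2L),
            class = "cnv_call")
}

#' Summarize tandem repeats of a genome
#'
#' @param sequence Character scalar.
#' @param ... Passed to [find_tandem_repeats()].
#' @return list(count, by_unit_length (table), genome_share, repeats).
#' @export
summarize_trs <- function(sequence, ...) {
  tr <- find_tandem_repeats(sequence, ...)
  list(count = nrow(tr),
       by_unit_length = table(tr$unit_length),
       genome_share = sum(tr$span) / nchar(sequence),
       repeats = tr)
}
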