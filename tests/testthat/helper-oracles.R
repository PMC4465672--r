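## Independent brute-force enumeration used as the oracle on short strings:
## grows every (start, unit) candidate base by base with explicit character
## comparison, then applies the same resolution rules (longer span, smaller
## unit, leftmost) by exhaustive pairwise pruning.
brute_force_trs <- function(sequence, min_unit = 6L, max_unit = 57L,
                            min_copies = 2) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  rows <- list()
  for (u in min_unit:max_unit) {
    i <- 1L
    while (i + 2L * u - 1L <= n) {
      j <- i + u
      while (j <= n && ch[j] == ch[j - u]) j <- j + 1L
      span <- (j - 1L) - i + 1L
      if (span >= u * min_copies &&
          !(i > u && ch[i - 1L] == ch[i - 1L + u])) { # maximal on the left
        rows[[length(rows) + 1L]] <-
          data.frame(start = i, end = i + span - 1L, unit_length = u,
                     copies = span / u, span = span)
        i <- j - u + 1L
      } else i <- i + 1L
    }
  }
  if (!length(rows)) return(data.frame(start = integer(0)))
  cand <- do.call(rbind, rows)
  cand <- cand[cand$copies >= min_copies, ]
  cand <- cand[order(-cand$span, cand$unit_length, cand$start), ]
  keep <- logical(nrow(cand))
  iv <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(nrow(cand))) {
    if (!nrow(iv) || all(cand$end[k] < iv[, 1] | cand$start[k] > iv[, 2])) {
      keep[k] <- TRUE
      iv <- rbind(iv, c(cand$start[k], cand$end[k]))
    }
  }
  out <- cand[keep, ]
  out[order(out$start), ]
}

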