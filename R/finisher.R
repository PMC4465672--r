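## Reference-anchored finishing of a circular genome from overlapping de novo
## contigs: anchor (shared-k-mer placement), order and merge terminal
## overlaps, polish by read pileup, canonicalize rotation/orientation.

ANCHOR_K <- 21L
POLISH_K <- 31L

## k-mer placement of one contig against a (doubled, for circularity)
## reference using k-mers that are unique in the reference. Returns NULL when
## nothing anchors.
kmer_place <- function(contig, ref_kmers, ref_len, k = ANCHOR_K,
                       ref_kmers_all = ref_kmers) {
  n <- nchar(contig)
  if (n < k) return(NULL)
  place_one <- function(seqn) {
    km <- seq_kmers(seqn, k)
    ## placement diagonals come from reference-unique k-mers only;
    ## identity is k-mer containment against the full table (repeat-array
    ## k-mers count towards identity but cannot place)
    ident <- mean(!is.na(match(km, ref_kmers_all)))
    hit <- match(km, ref_kmers)
    ok <- !is.na(hit)
    if (sum(ok) < 5L) return(NULL)
    ## implied ref_start - 1 per k-mer, mod L so origin-spanning contigs
    ## yield one consistent diagonal; small InDels between contig and
    ## reference shift the diagonal by their cumulative length, so hits
    ## within a band around the modal diagonal are kept
    j <- which(ok)
    off <- (hit[ok] - j) %% ref_len
    tb <- table(off)
    modal <- as.integer(names(tb)[which.max(tb)])
    circ_d <- pmin(abs(off - modal), ref_len - abs(off - modal))
    keep <- circ_d <= 1000L
    if (!sum(keep)) return(NULL)
    jk <- j[keep]
    start <- (off[keep][which.min(jk)]) %% ref_len + 1L
    list(offset = start - 1L, identity = ident, nhits = sum(ok))
  }
  fwd <- place_one(contig)
  rev <- place_one(revcomp(contig))
  if (is.null(fwd) && is.null(rev)) return(NULL)
  sc_f <- if (is.null(fwd)) -1 else fwd$nhits
  sc_r <- if (is.null(rev)) -1 else rev$nhits
  if (sc_f >= sc_r) list(offset = fwd$offset, identity = fwd$identity,
                         orientation = "forward")
  else list(offset = rev$offset, identity = rev$identity,
            orientation = "reverse")
}

#' Anchor contigs to a reference genome
#'
#' Places each contig on the (circular) reference by shared-k-mer seeding
#' (unique 21-mers, modal diagonal) and verifies the placement base by base.
#' Contigs below the identity/length thresholds are reported as
#' non-target and excluded; reverse-orientation placements flag the contig
#' for reverse complementing downstream.
#'
#' @param contigs A `contig_set` (or data.frame with `id`, `sequence`).
#' @param reference Character scalar, circular reference sequence.
#' @param min_identity Minimum placement identity (default 0.95).
#' @param min_anchor_length Minimum placed length in bases (default 500).
#' @return data.frame of placements: contig_id, ref_start, ref_end (may
#'   exceed the reference length when the placement wraps the origin),
#'   orientation, identity, aligned_length; excluded contigs in
#'   `attr(, "excluded")`.
#' @export
anchor_contigs <- function(contigs, reference, min_identity = 0.95,
                           min_anchor_length = 500L) {
  stopifnot(nrow(contigs) > 0L)
  L <- nchar(reference)
  doubled <- paste0(reference, reference)
  ref_kmers_all <- seq_kmers(doubled, ANCHOR_K)
  ## only k-mers unique within one genome copy are usable as anchors
  first_copy <- seq_kmers(reference, ANCHOR_K)
  dup <- unique(first_copy[duplicated(first_copy)])
  ref_kmers <- ref_kmers_all
  ref_kmers[ref_kmers %in% dup] <- NA_character_

  rows <- list(); excluded <- character(0)
  for (i in seq_len(nrow(contigs))) {
    sq <- contigs$sequence[i]
    pl <- kmer_place(sq, ref_kmers, L, ref_kmers_all = ref_kmers_all)
    if (is.null(pl) || pl$identity < min_identity ||
        nchar(sq) < min_anchor_length) {
      excluded <- c(excluded, contigs$id[i]); next
    }
    start <- ((pl$offset) %% L) + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = contigs$id[i], ref_start = start,
      ref_end = start + nchar(sq) - 1L, orientation = pl$orientation,
      identity = pl$identity, aligned_length = nchar(sq))
  }
  if (!length(rows))
    stop("no contig anchors to the reference; relax min_identity/",
         "min_anchor_length or check the inputs", call. = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(out$ref_start), ]
  rownames(out) <- NULL
  structure(out, excluded = excluded, genome_length = L)
}

## longest terminal overlap (suffix of a == prefix of b) with mismatch
## tolerance, searched downward from `expect`; returns length or 0.
find_overlap <- function(a, b, min_overlap, expect, max_mismatch_frac) {
  na <- nchar(a); nb <- nchar(b)
  hi <- min(na, nb)
  if (hi < min_overlap) return(list(length = 0L, mismatches = NA_integer_))
  cand <- seq.int(hi, min_overlap)
  if (!is.na(expect)) {
    ## placement-derived register first, then its neighbourhood (InDels
    ## between contig and anchoring reference shift it), then longest-first
    deltas <- c(0L, as.vector(rbind(1:600, -(1:600))))
    near <- expect + deltas
    near <- unique(near[near >= min_overlap & near <= hi])
    cand <- c(near, setdiff(cand, near))
  }
  for (ov in cand) {
    sa <- charToRaw(substr(a, na - ov + 1L, na))
    sb <- charToRaw(substr(b, 1L, ov))
    mm <- sum(sa != sb)
    if (mm <= max_mismatch_frac * ov) return(list(length = ov, mismatches = mm))
  }
  list(length = 0L, mismatches = NA_integer_)
}

#' Order and merge anchored contigs into a draft genome
#'
#' Contigs are ordered by their reference placement and adjacent terminal
#' overlaps are merged (near-exact, mismatch fraction below
#' `max_overlap_mismatch_frac`). When the last contig overlaps the first
#' across the origin the draft is circular.
#'
#' @param placements Result of [anchor_contigs()].
#' @param contigs The `contig_set` the placements refer to.
#' @param min_overlap Minimum acceptable merge overlap (default 200).
#' @param max_overlap_mismatch_frac Mismatch tolerance inside the overlap.
#' @return A `draft_genome`: list(sequence, circular, joins, placements).
#' @export
order_and_merge <- function(placements, contigs, min_overlap = 200L,
                            max_overlap_mismatch_frac = 0.01) {
  L <- attr(placements, "genome_length")
  pl <- placements[order(placements$ref_start), ]
  seqs <- contigs$sequence[match(pl$contig_id, contigs$id)]
  flip <- pl$orientation == "reverse"
  seqs[flip] <- vapply(seqs[flip], revcomp, character(1))
  n <- length(seqs)

  ## coverage check against the reference circle
  cov_end <- pl$ref_end[1]
  for (i in seq_len(n)[-1]) {
    if (pl$ref_start[i] > cov_end + 1L)
      stop(sprintf("gap between %s and %s: reference interval %d-%d uncovered",
                   pl$contig_id[i - 1L], pl$contig_id[i], cov_end + 1L,
                   pl$ref_start[i] - 1L), call. = FALSE)
    cov_end <- max(cov_end, pl$ref_end[i])
  }
  circular <- n > 1L && (pl$ref_end[n] - L) >= pl$ref_start[1] - 1L ||
    (n == 1L && pl$ref_end[1] - pl$ref_start[1] + 1L >= L)
  if (cov_end - pl$ref_start[1] + 1L < L && !circular)
    stop(sprintf("gap between %s and %s: reference interval %d-%d uncovered",
                 pl$contig_id[n], pl$contig_id[1], cov_end + 1L,
                 pl$ref_start[1] - 1L + L), call. = FALSE)

  merged <- seqs[1]
  joins <- list()
  if (n > 1L) {
    for (i in 2:n) {
      expect <- pl$ref_end[i - 1L] - pl$ref_start[i] + 1L
      ov <- find_overlap(merged, seqs[i], min_overlap, expect,
                         max_overlap_mismatch_frac)
      if (ov$length == 0L)
        stop(sprintf("no qualifying overlap between %s and %s",
                     pl$contig_id[i - 1L], pl$contig_id[i]), call. = FALSE)
      joins[[length(joins) + 1L]] <- data.frame(
        left_contig = pl$contig_id[i - 1L], right_contig = pl$contig_id[i],
        overlap_length = ov$length, mismatches = ov$mismatches)
      merged <- paste0(merged, substr(seqs[i], ov$length + 1L, nchar(seqs[i])))
    }
  }
  if (circular) {
    expect <- (pl$ref_end[n] - L) - pl$ref_start[1] + 1L
    ov <- find_overlap(merged, seqs[1], min_overlap, expect,
                       max_overlap_mismatch_frac)
    if (ov$length == 0L)
      stop(sprintf("no qualifying circular-closure overlap between %s and %s",
                   pl$contig_id[n], pl$contig_id[1]), call. = FALSE)
    joins[[length(joins) + 1L]] <- data.frame(
      left_contig = pl$contig_id[n], right_contig = pl$contig_id[1],
      overlap_length = ov$length, mismatches = ov$mismatches)
    merged <- substr(merged, 1L, nchar(merged) - ov$length)
  }
  structure(list(sequence = merged, circular = circular,
                 joins = if (length(joins)) do.call(rbind, joins) else
                   data.frame(left_contig = character(0)),
                 placements = pl),
            class = "draft_genome")
}

## ---- pileup polishing ------------------------------------------------------

BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

## Map reads onto a draft by exact 31-mer seed + full-length ungapped check;
## returns per-position base counts (5 x L matrix).
pileup_counts <- function(draft_seq, reads, circular = TRUE) {
  L <- nchar(draft_seq)
  k <- POLISH_K
  tmpl <- if (circular) paste0(draft_seq, substr(draft_seq, 1L, 400L)) else draft_seq
  tk <- seq_kmers(tmpl, k)
  ## seeds must be unique in the draft: k-mers inside tandem arrays or other
  ## exact repeats cannot place a read and are masked
  single <- seq_kmers(draft_seq, k)
  dup <- unique(single[duplicated(single)])
  if (length(dup)) tk[tk %in% dup] <- NA_character_
  allreads <- c(reads$read1, reads$read2)
  rl <- nchar(allreads[1])
  seed_offs <- unique(pmax(1L, c(1L, (rl - k) %/% 2L + 1L, rl - k + 1L)))
  pos <- rep(NA_integer_, length(allreads))
  for (orient in 1:2) {
    if (orient == 2L) {
      na <- is.na(pos)
      allreads[na] <- vapply(allreads[na], revcomp, character(1),
                             USE.NAMES = FALSE)
    }
    for (off in seed_offs) {
      na <- which(is.na(pos))
      if (!length(na)) break
      m <- match(substr(allreads[na], off, off + k - 1L), tk)
      pos[na] <- m - (off - 1L)
    }
  }
  keep <- !is.na(pos)
  allreads <- allreads[keep]; pos <- pos[keep]
  if (!length(allreads)) return(NULL)
  ## verify the whole read at the seed-implied placement; reads straddling
  ## repeat junctions can seed on one side and disagree on the other
  L_t <- nchar(tmpl)
  if (circular) pos <- ifelse(pos < 1L, pos + L, pos)
  inb <- pos >= 1L & pos + rl - 1L <= L_t
  allreads <- allreads[inb]; pos <- pos[inb]
  if (!length(allreads)) return(NULL)
  segs <- substring(tmpl, pos, pos + rl - 1L)
  mism <- vapply(seq_along(allreads), function(i)
    sum(charToRaw(segs[i]) != charToRaw(allreads[i])), integer(1))
  ok <- mism <= ceiling(0.1 * rl)
  allreads <- allreads[ok]; pos <- pos[ok]
  if (!length(allreads)) return(NULL)
  offs <- rep(pos, each = rl) + 0:(rl - 1L)
  offs <- ((offs - 1L) %% L) + 1L
  bases <- unlist(lapply(allreads, charToRaw), use.names = FALSE)
  code <- integer(length(bases))
  code[bases == charToRaw("A")] <- 1L
  code[bases == charToRaw("C")] <- 2L
  code[bases == charToRaw("G")] <- 3L
  code[bases == charToRaw("T")] <- 4L
  code[code == 0L] <- 5L
  cnt <- tabulate((offs - 1L) * 5L + code, nbins = 5L * L)
  matrix(cnt, nrow = 5L)
}

#' Polish a draft genome by read pileup
#'
#' Maps reads (exact 31-mer seed, ungapped) and corrects draft positions
#' where a majority read base disagrees with the draft, subject to minimum
#' depth and majority fraction. Positions with a second allele at fraction
#' \eqn{\ge} 0.2 are reported as heterogeneous (IUPAC code in the record) and
#' left uncorrected.
#'
#' @param draft A `draft_genome` (or character scalar).
#' @param reads A `read_set`.
#' @param min_depth Minimum depth to act (default 5).
#' @param min_majority Majority fraction required to correct (default 0.8).
#' @return list(draft, polish_record): corrected draft and a data.frame of
#'   corrections/heterogeneous calls (position, draft_base, corrected_base,
#'   depth, majority_fraction, status).
#' @export
correct_by_pileup <- function(draft, reads, min_depth = 5L,
                              min_majority = 0.8) {
  seqn <- if (inherits(draft, "draft_genome")) draft$sequence else draft
  circular <- !inherits(draft, "draft_genome") || isTRUE(draft$circular)
  cnt <- pileup_counts(seqn, reads, circular)
  empty <- data.frame(position = integer(0), draft_base = character(0),
                      corrected_base = character(0), depth = integer(0),
                      majority_fraction = numeric(0), status = character(0))
  if (is.null(cnt)) {
    warning("no reads mapped to the draft; polishing skipped")
    return(list(draft = draft, polish_record = empty))
  }
  depth <- colSums(cnt[1:4, , drop = FALSE])
  top <- apply(cnt[1:4, , drop = FALSE], 2L, which.max)
  topn <- cnt[cbind(top, seq_len(ncol(cnt)))]
  frac <- ifelse(depth > 0, topn / depth, 0)
  draft_chars <- strsplit(seqn, "")[[1]]
  top_base <- DNA_BASES_STRICT[top]
  second <- depth - topn
  het <- depth >= min_depth & second / pmax(depth, 1L) >= 0.2
  fixable <- depth >= min_depth & frac >= min_majority &
    top_base != draft_chars & !het
  rec <- empty
  if (any(fixable)) {
    idx <- which(fixable)
    rec <- rbind(rec, data.frame(
      position = idx, draft_base = draft_chars[idx],
      corrected_base = top_base[idx], depth = depth[idx],
      majority_fraction = frac[idx], status = "corrected"))
    draft_chars[idx] <- top_base[idx]
  }
  if (any(het)) {
    idx <- which(het)
    codes <- vapply(idx, function(j) {
      bs <- DNA_BASES_STRICT[cnt[1:4, j] / depth[j] >= 0.2]
      iupac_code(bs)
    }, character(1))
    rec <- rbind(rec, data.frame(
      position = idx, draft_base = draft_chars[idx], corrected_base = codes,
      depth = depth[idx], majority_fraction = frac[idx],
      status = "heterogeneous"))
  }
  out_seq <- paste(draft_chars, collapse = "")
  if (inherits(draft, "draft_genome")) draft$sequence <- out_seq
  else draft <- out_seq
  rec <- rec[order(rec$position), ]
  rownames(rec) <- NULL
  list(draft = draft, polish_record = rec)
}

#' Canonicalize a circular draft against the reference rotation
#'
#' Rotates (and if needed reverse-complements) a circular genome so its
#' position 1 aligns with reference position 1 and its strand matches the
#' reference forward strand. Idempotent; linear input is returned unchanged
#' with a warning.
#'
#' @param draft `draft_genome` or character scalar (assumed circular if bare).
#' @param reference Character scalar reference in canonical rotation.
#' @return Character scalar, the canonical-rotation sequence.
#' @export
canonicalize <- function(draft, reference) {
  seqn <- if (inherits(draft, "draft_genome")) draft$sequence else draft
  if (inherits(draft, "draft_genome") && !isTRUE(draft$circular)) {
    warning("draft is linear; returned unchanged")
    return(seqn)
  }
  k <- min(200L, nchar(reference))
  probe <- substr(reference, 1L, k)
  hit <- regexpr(probe, paste0(seqn, substr(seqn, 1L, k)), fixed = TRUE)
  if (hit > 0L) return(rotate_seq(seqn, as.integer(hit)))
  rc <- revcomp(seqn)
  hit <- regexpr(probe, paste0(rc, substr(rc, 1L, k)), fixed = TRUE)
  if (hit > 0L) return(rotate_seq(rc, as.integer(hit)))
  ## fall back to anchoring when the origin-spanning probe carries variants
  ctg <- data.frame(id = "draft", sequence = seqn)
  pl <- anchor_contigs(ctg, reference, min_identity = 0.5,
                       min_anchor_length = 100L)
  oriented <- if (pl$orientation[1] == "reverse") rc else seqn
  rotate_seq(oriented, nchar(oriented) - (pl$ref_start[1] - 1L) + 1L)
}

#' Finish a genome from contigs end to end
#'
#' Convenience wrapper: anchor, order/merge, optional pileup polish,
#' canonicalize.
#'
#' @inheritParams anchor_contigs
#' @inheritParams order_and_merge
#' @param reads Optional `read_set` for polishing.
#' @return list(sequence, draft, placements, polish_record).
#' @export
finish_genome <- function(contigs, reference, reads = NULL,
                          min_overlap = 200L, min_identity = 0.95,
                          min_anchor_length = 500L) {
  pl <- anchor_contigs(contigs, reference, min_identity, min_anchor_length)
  draft <- order_and_merge(pl, contigs, min_overlap = min_overlap)
  rec <- NULL
  if (!is.null(reads)) {
    pol <- correct_by_pileup(draft, reads)
    draft <- pol$draft
    rec <- pol$polish_record
  }
  list(sequence = canonicalize(draft, reference), draft = draft,
       placements = pl, polish_record = rec)
}
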