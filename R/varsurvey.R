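## Pairwise survey of finished genomes against the cohort reference:
## anchored global alignment, left-aligned SNP/InDel calling with repeat
## context, cohort merging (IR-mirrored events collapse to one row), effect
## classification, and 45S nrDNA unit segmentation.

#' Globally align two near-identical genomes
#'
#' Shared-unique-21-mer anchors are chained collinearly; the short segments
#' between anchors are aligned with affine-gap Needleman-Wunsch
#' ([Biostrings::pairwiseAlignment()]). Suitable for conspecific sequences
#' that differ at a handful of sites; diverged inputs are rejected.
#'
#' @param genome_a,genome_b Character scalars (a taken as the reference).
#' @param k Anchor k-mer size.
#' @return A `pairwise_alignment`: list(a, b) of equal-length gapped strings.
#' @export
align_pair <- function(genome_a, genome_b, k = 21L) {
  if (identical(genome_a, genome_b))
    return(structure(list(a = genome_a, b = genome_b),
                     class = "pairwise_alignment"))
  ka <- seq_kmers(genome_a, k); kb <- seq_kmers(genome_b, k)
  ua <- !(ka %in% ka[duplicated(ka)])
  ub <- !(kb %in% kb[duplicated(kb)])
  hit <- match(ka, kb)
  shared <- !is.na(hit) & ua & ub[pmax(hit, 1L)]
  if (mean(!is.na(hit)) < 0.5)
    stop("sequences share fewer than half their k-mers; ",
         "inputs are too diverged for a cohort alignment", call. = FALSE)
  pa <- which(shared); pb <- hit[shared]
  ## enforce a collinear chain (strictly increasing in both coordinates)
  keep <- !logical(length(pa))
  last_b <- 0L
  for (i in seq_along(pa)) {
    if (pb[i] <= last_b) keep[i] <- FALSE else last_b <- pb[i]
  }
  pa <- pa[keep]; pb <- pb[keep]
  ## collapse runs of consecutive anchors into blocks
  brk <- c(TRUE, diff(pa) != 1L | diff(pb) != 1L)
  block <- cumsum(brk)
  bs_a <- tapply(pa, block, min); be_a <- tapply(pa, block, max) + k - 1L
  bs_b <- tapply(pb, block, min); be_b <- tapply(pb, block, max) + k - 1L
  nb <- length(bs_a)
  ## drop overlaps between consecutive blocks (trim block starts)
  outs_a <- character(0); outs_b <- character(0)
  cur_a <- 1L; cur_b <- 1L
  emit_gap <- function(sa, ea, sb, eb) {
    seg_a <- if (ea >= sa) substr(genome_a, sa, ea) else ""
    seg_b <- if (eb >= sb) substr(genome_b, sb, eb) else ""
    if (!nchar(seg_a) && !nchar(seg_b)) return(c("", ""))
    if (!nchar(seg_a)) return(c(strrep("-", nchar(seg_b)), seg_b))
    if (!nchar(seg_b)) return(c(seg_a, strrep("-", nchar(seg_a))))
    if (identical(seg_a, seg_b)) return(c(seg_a, seg_b))
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seg_a), Biostrings::DNAString(seg_b),
      type = "global", gapOpening = 10, gapExtension = 0.5,
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = FALSE))
    c(as.character(Biostrings::alignedPattern(al)),
      as.character(Biostrings::alignedSubject(al)))
  }
  for (i in seq_len(nb)) {
    ## blocks are diagonal runs; trim synchronously if the previous block
    ## already consumed part of this one
    trim <- max(cur_a - bs_a[i], cur_b - bs_b[i], 0L)
    sa <- bs_a[i] + trim; sb <- bs_b[i] + trim
    if (sa > be_a[i]) next
    gp <- emit_gap(cur_a, sa - 1L, cur_b, sb - 1L)
    outs_a <- c(outs_a, gp[1]); outs_b <- c(outs_b, gp[2])
    outs_a <- c(outs_a, substr(genome_a, sa, be_a[i]))
    outs_b <- c(outs_b, substr(genome_b, sb, be_b[i]))
    cur_a <- be_a[i] + 1L; cur_b <- be_b[i] + 1L
  }
  gp <- emit_gap(cur_a, nchar(genome_a), cur_b, nchar(genome_b))
  outs_a <- c(outs_a, gp[1]); outs_b <- c(outs_b, gp[2])
  a <- paste(outs_a, collapse = ""); b <- paste(outs_b, collapse = "")
  stopifnot(nchar(a) == nchar(b))
  structure(list(a = a, b = b), class = "pairwise_alignment")
}

## shift an InDel left while the base preceding it equals the last base of
## the inserted/deleted sequence (canonical left-alignment in repeat context)
left_align_indel <- function(refseq, pos, seqrep) {
  n <- nchar(seqrep)
  while (pos > 1L &&
         substr(refseq, pos - 1L, pos - 1L) == substr(seqrep, n, n)) {
    seqrep <- paste0(substr(refseq, pos - 1L, pos - 1L),
                     substr(seqrep, 1L, n - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, seqrep = seqrep)
}

## smallest period of a string (d | n with s == strrep(unit, n/d))
smallest_period <- function(s) {
  n <- nchar(s)
  for (d in seq_len(n)) {
    if (n %% d != 0L) next
    if (identical(strrep(substr(s, 1L, d), n %/% d), s)) return(d)
  }
  n
}

## annotate repeat context of a normalized InDel against the reference:
## homopolymer run notation or tandem-repeat copy notation
repeat_context <- function(refseq, pos, seqrep, is_ins) {
  n <- nchar(seqrep)
  first <- substr(seqrep, 1L, 1L)
  if (identical(strrep(first, n), seqrep)) {
    ## homopolymer: count the reference run starting after the anchor
    run <- 0L; p <- pos + 1L
    while (p <= nchar(refseq) && substr(refseq, p, p) == first) {
      run <- run + 1L; p <- p + 1L
    }
    ## `run` counts reference bases after the anchor, so for deletions it
    ## already includes the deleted bases
    ref_len <- run
    alt_len <- if (is_ins) run + n else run - n
    return(list(kind = "homopolymer",
                notation = sprintf("(%s)%d>(%s)%d", first, ref_len, first,
                                   alt_len)))
  }
  d <- smallest_period(seqrep)
  if (d < n || d >= 6L) {
    unit <- substr(seqrep, 1L, d)
    ## count adjacent copies of the unit in the reference after the anchor
    cops <- 0L; p <- pos + 1L
    while (p + d - 1L <= nchar(refseq) &&
           substr(refseq, p, p + d - 1L) == unit) {
      cops <- cops + 1L; p <- p + d
    }
    if (cops >= 1L) {
      delta <- n %/% d
      ref_c <- cops      # reference copies include any to-be-deleted units
      alt_c <- if (is_ins) cops + delta else cops - delta
      return(list(kind = "tr_cnv",
                  notation = sprintf("%dx%d>%dx%d", d, ref_c, d, alt_c)))
    }
  }
  list(kind = "simple",
       notation = if (is_ins) sprintf("+%dbp", n) else sprintf("-%dbp", n))
}

#' Call normalized variants from a pairwise alignment
#'
#' Walks the alignment columns; gap runs collapse into single InDel events
#' that are left-aligned against the reference and anchored with one
#' reference base (VCF convention). Homopolymer and tandem-repeat InDels
#' additionally carry full-run notation. IUPAC ambiguity codes in the
#' subject that include the reference base are reported as heterogeneous
#' SNPs.
#'
#' @param alignment A `pairwise_alignment` from [align_pair()] (pattern =
#'   reference).
#' @return data.frame: type, pos (reference coordinate), ref, alt,
#'   heterogeneous, context, notation.
#' @export
call_variants <- function(alignment) {
  a <- alignment$a; b <- alignment$b
  refseq <- gsub("-", "", a, fixed = TRUE)
  ca <- charToRaw(a); cb <- charToRaw(b)
  gap <- charToRaw("-")
  n <- length(ca)
  refpos <- cumsum(ca != gap)    # reference coordinate per column
  diffcol <- which(ca != cb)
  empty <- data.frame(type = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      heterogeneous = logical(0), context = character(0),
                      notation = character(0))
  if (!length(diffcol)) return(empty)
  rows <- list()
  i <- 1L
  while (i <= length(diffcol)) {
    col <- diffcol[i]
    if (ca[col] != gap && cb[col] != gap) {
      ref_b <- rawToChar(ca[col]); alt_b <- rawToChar(cb[col])
      het <- alt_b %in% setdiff(names(IUPAC_EXPAND), DNA_BASES_STRICT) &&
        ref_b %in% IUPAC_EXPAND[[alt_b]]
      rows[[length(rows) + 1L]] <- data.frame(
        type = "SNP", pos = refpos[col], ref = ref_b, alt = alt_b,
        heterogeneous = het, context = "snp",
        notation = paste0(ref_b, ">",
                          if (het) paste(IUPAC_EXPAND[[alt_b]], collapse = "/")
                          else alt_b))
      i <- i + 1L
      next
    }
    ## gap run: extend over consecutive gap columns on the same side
    gap_in_a <- ca[col] == gap
    j <- col
    if (gap_in_a) while (j < n && ca[j + 1L] == gap) j <- j + 1L
    else while (j < n && cb[j + 1L] == gap) j <- j + 1L
    if (gap_in_a) {            # insertion relative to reference
      ins <- rawToChar(cb[col:j])
      anchor <- refpos[col]    # base before the gap (refpos stays flat)
      la <- left_align_indel(refseq, anchor + 1L, ins)
      pos <- la$pos - 1L
      ctx <- repeat_context(refseq, pos, la$seqrep, is_ins = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        type = "insertion", pos = pos,
        ref = substr(refseq, pos, pos),
        alt = paste0(substr(refseq, pos, pos), la$seqrep),
        heterogeneous = FALSE, context = ctx$kind, notation = ctx$notation)
    } else {                   # deletion relative to reference
      del <- rawToChar(ca[col:j])
      start <- refpos[col]
      la <- left_align_indel(refseq, start, del)
      pos <- la$pos - 1L
      ctx <- repeat_context(refseq, pos, la$seqrep, is_ins = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        type = "deletion", pos = pos,
        ref = paste0(substr(refseq, pos, pos), la$seqrep),
        alt = substr(refseq, pos, pos),
        heterogeneous = FALSE, context = ctx$kind, notation = ctx$notation)
    }
    i <- i + sum(diffcol >= col & diffcol <= j)
  }
  out <- do.call(rbind, rows)
  out[order(out$pos), ]
}

#' Survey one genome against the reference
#'
#' @param reference,genome Character scalars in canonical rotation.
#' @return The [call_variants()] table.
#' @export
survey_genome <- function(reference, genome) {
  call_variants(align_pair(reference, genome))
}

#' Merge per-accession variant calls into a cohort table
#'
#' One row per distinct site (keyed by position, type and alleles) with the
#' carrier accessions collected; accessions with identical genotypes share
#' identical columns. Events mirrored across the two inverted-repeat copies
#' collapse into a single row carrying both coordinates.
#'
#' @param calls Named list (accession -> [call_variants()] data.frame).
#' @param layout Optional plastome layout (for IR mirror collapsing).
#' @return Cohort table: pos, type, ref, alt, carriers, n_carriers,
#'   heterogeneous, context, notation, ir_mirror.
#' @export
merge_cohort <- function(calls, layout = NULL) {
  rows <- list()
  for (acc in names(calls)) {
    v <- calls[[acc]]
    if (!nrow(v)) next
    v$accession <- acc
    rows[[acc]] <- v
  }
  empty <- data.frame(pos = integer(0), type = character(0),
                      ref = character(0), alt = character(0),
                      carriers = character(0), n_carriers = integer(0),
                      heterogeneous = logical(0), context = character(0),
                      notation = character(0), ir_mirror = integer(0))
  if (!length(rows)) return(empty)
  all <- do.call(rbind, rows)
  key <- paste(all$pos, all$type, all$ref, all$alt, sep = "|")
  ## consistency: one accession must not claim two alleles at one site
  dupacc <- tapply(all$accession, paste(all$pos, all$type), anyDuplicated)
  if (any(unlist(dupacc) > 0L))
    stop("conflicting alleles at one site within one accession", call. = FALSE)
  agg <- lapply(split(seq_len(nrow(all)), key), function(ix) {
    x <- all[ix[1], c("pos", "type", "ref", "alt", "heterogeneous",
                      "context", "notation")]
    x$carriers <- paste(sort(unique(all$accession[ix])), collapse = ",")
    x$n_carriers <- length(unique(all$accession[ix]))
    x
  })
  tab <- do.call(rbind, agg)
  tab$ir_mirror <- NA_integer_
  rownames(tab) <- NULL
  tab <- tab[order(tab$pos), ]
  if (!is.null(layout)) tab <- collapse_ir_mirrors(tab, layout)
  rownames(tab) <- NULL
  tab
}

## Collapse rows that are IR mirror images of one another (same type and
## carriers, mirrored coordinates up to the event span, reverse-complement
## alleles) into the lower-coordinate row with `ir_mirror` set.
collapse_ir_mirrors <- function(tab, layout) {
  r <- layout$regions
  ira <- r[r$name == "IRa", ]; irb <- r[r$name == "IRb", ]
  in_ir <- function(p) (p >= ira$start & p <= ira$end) |
    (p >= irb$start & p <= irb$end)
  drop <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (drop[i] || !in_ir(tab$pos[i])) next
    for (j in seq_len(nrow(tab))) {
      if (j == i || drop[j] || !in_ir(tab$pos[j])) next
      if (tab$type[i] != tab$type[j]) next
      if (tab$carriers[i] != tab$carriers[j]) next
      ## left-aligned anchors sit at opposite ends of mirrored repeat
      ## arrays, so allow the full reference repeat span
      span <- max(nchar(tab$ref[i]), nchar(tab$alt[i])) + 2L
      if (tab$context[i] == "homopolymer") {
        m0 <- regmatches(tab$notation[i],
                         regexec("\\)([0-9]+)>", tab$notation[i]))[[1]]
        span <- span + as.integer(m0[2])
      } else if (tab$context[i] == "tr_cnv") {
        m0 <- regmatches(tab$notation[i],
                         regexec("^([0-9]+)x([0-9]+)>[0-9]+x([0-9]+)",
                                 tab$notation[i]))[[1]]
        span <- span + as.integer(m0[2]) *
          max(as.integer(m0[3]), as.integer(m0[4]))
      }
      m <- ir_mirror_pos(tab$pos[j], layout)
      if (is.na(m) || abs(m - tab$pos[i]) > span) next
      ok_alleles <- if (tab$type[i] == "SNP") {
        identical(revcomp(tab$ref[i]), tab$ref[j]) &&
          identical(revcomp(tab$alt[i]), tab$alt[j])
      } else {
        ## anchored alleles: compare the event payload up to revcomp
        pay_i <- substr(if (tab$type[i] == "insertion") tab$alt[i] else tab$ref[i], 2L, 10000L)
        pay_j <- substr(if (tab$type[j] == "insertion") tab$alt[j] else tab$ref[j], 2L, 10000L)
        nchar(pay_i) == nchar(pay_j) &&
          smallest_period(pay_i) == smallest_period(pay_j)
      }
      if (!ok_alleles) next
      lo <- which.min(c(tab$pos[i], tab$pos[j]))
      keep_ix <- c(i, j)[lo]; drop_ix <- c(i, j)[-lo]
      tab$ir_mirror[keep_ix] <- tab$pos[drop_ix]
      drop[drop_ix] <- TRUE
      break
    }
  }
  tab[!drop, ]
}

#' Classify the coding effect of a variant
#'
#' SNPs inside CDS features are translated in both alleles with strand-aware
#' codon extraction; variants in introns are intronic, in tRNA/rRNA
#' non-coding, elsewhere intergenic (labelled with the flanking feature
#' pair). For InDels only the region label is assigned.
#'
#' @param variant One row of a cohort/variant table (needs pos, type, ref,
#'   alt, optionally ir_mirror).
#' @param annotation Annotation data.frame (name, start, end, strand, type).
#' @param reference Reference sequence.
#' @return list(region, consequence, aa_change) where `aa_change` is
#'   c(ref_aa, alt_aa, codon_index) for non-synonymous SNPs, else NULL.
#' @export
classify_effect <- function(variant, annotation, reference) {
  pos_candidates <- c(variant$pos,
                      if (!is.null(variant$ir_mirror)) variant$ir_mirror)
  pos_candidates <- pos_candidates[!is.na(pos_candidates)]
  hit_at <- function(p, types) {
    h <- annotation[annotation$start <= p & annotation$end >= p &
                    annotation$type %in% types, , drop = FALSE]
    if (nrow(h)) h[1, ] else NULL
  }
  ## precedence: intron, CDS, structural RNA; checked at either IR coordinate
  for (p in pos_candidates) {
    h <- hit_at(p, "intron")
    if (!is.null(h))
      return(list(region = paste(h$name, "intron"), consequence = "intronic",
                  aa_change = NULL))
  }
  for (p in pos_candidates) {
    h <- hit_at(p, "CDS")
    if (is.null(h)) next
    if (variant$type != "SNP")
      return(list(region = h$name, consequence = "coding_indel",
                  aa_change = NULL))
    cds <- annotation[annotation$name == h$name & annotation$type == "CDS", ]
    cds <- cds[order(cds$start), ]
    ## position within the spliced CDS, 5' to 3'
    if (h$strand == "+") {
      prior <- sum(pmax(0L, pmin(cds$end, p) - cds$start + 1L) *
                     (cds$end < p)) # full exons before
      inex <- p - h$start + 1L
      idx <- sum((cds$end < p) * (cds$end - cds$start + 1L)) + inex
    } else {
      idx <- sum((cds$start > p) * (cds$end - cds$start + 1L)) +
        (h$end - p + 1L)
    }
    codon_index <- (idx - 1L) %/% 3L + 1L
    codon_pos <- (idx - 1L) %% 3L + 1L
    ## extract the codon's genomic span within this exon
    get_codon <- function(seqn) {
      if (h$strand == "+") {
        start <- p - (codon_pos - 1L)
        substr(seqn, start, start + 2L)
      } else {
        endp <- p + (codon_pos - 1L)
        revcomp(substr(seqn, endp - 2L, endp))
      }
    }
    ref_codon <- get_codon(reference)
    altseq <- reference
    substr(altseq, p, p) <- variant$alt
    alt_codon <- get_codon(altseq)
    ref_aa <- translate_codon(ref_codon); alt_aa <- translate_codon(alt_codon)
    if (identical(ref_aa, alt_aa))
      return(list(region = h$name, consequence = "synonymous",
                  aa_change = NULL))
    return(list(region = h$name, consequence = "non-synonymous",
                aa_change = c(ref_aa = ref_aa, alt_aa = alt_aa,
                              codon_index = codon_index)))
  }
  for (p in pos_candidates) {
    h <- hit_at(p, c("tRNA", "rRNA"))
    if (!is.null(h))
      return(list(region = h$name, consequence = "non-coding",
                  aa_change = NULL))
  }
  ## intergenic: name the flanking gene-level features
  p <- pos_candidates[1]
  feats <- annotation[annotation$type %in% c("gene", "tRNA", "rRNA"), ]
  feats <- feats[order(feats$start), ]
  left <- feats[feats$end < p, ]
  right <- feats[feats$start > p, ]
  lname <- if (nrow(left)) left$name[nrow(left)] else feats$name[nrow(feats)]
  rname <- if (nrow(right)) right$name[1] else feats$name[1]
  list(region = paste0(lname, "-", rname), consequence = "intergenic",
       aa_change = NULL)
}

#' Survey a whole cohort and build the polymorphism table
#'
#' Aligns every accession against the reference, merges calls, collapses IR
#' mirrors, and attaches region/effect columns.
#'
#' @param reference Character scalar.
#' @param sequences Named list of accession sequences.
#' @param annotation Optional annotation data.frame.
#' @param layout Optional layout (IR collapapsing); taken from a
#'   `synthetic_cohort` automatically by [survey_cohort()].
#' @return Cohort table with region/consequence/aa_change columns.
#' @export
survey_cohort <- function(reference, sequences, annotation = NULL,
                          layout = NULL) {
  calls <- lapply(sequences, function(s) survey_genome(reference, s))
  tab <- merge_cohort(calls, layout)
  if (!is.null(annotation) && nrow(tab)) {
    eff <- lapply(seq_len(nrow(tab)), function(i)
      classify_effect(tab[i, ], annotation, reference))
    tab$region <- vapply(eff, `[[`, character(1), "region")
    tab$consequence <- vapply(eff, `[[`, character(1), "consequence")
    tab$aa_change <- vapply(eff, function(e)
      if (is.null(e$aa_change)) NA_character_ else
        paste0(e$aa_change[["ref_aa"]], ">", e$aa_change[["alt_aa"]]),
      character(1))
  }
  tab
}

## ---- 45S nrDNA segmentation ------------------------------------------------

#' Segment a 45S nrDNA unit by reference models
#'
#' Locates each segment (18S, ITS1, 5.8S, ITS2, 26S, IGS) in a query unit by
#' matching short boundary anchors taken from the reference model (small
#' mismatch allowance covers cohort SNPs). N-runs inside the IGS are
#' tolerated and reported as gap intervals.
#'
#' @param unit_sequence Query unit.
#' @param reference Reference unit sequence.
#' @param segments Reference segment table (name, start, end).
#' @param anchor_k Boundary anchor length.
#' @return list(segments = data.frame(name, start, end),
#'   gaps = data.frame(start, end), heterogeneous_sites = data.frame).
#' @export
segment_nrdna <- function(unit_sequence, reference, segments,
                          anchor_k = 24L) {
  find_anchor <- function(refpos, last_end) {
    probe <- substr(reference, refpos, refpos + anchor_k - 1L)
    m <- Biostrings::matchPattern(probe,
                                  Biostrings::DNAString(unit_sequence),
                                  max.mismatch = 2, fixed = FALSE)
    st <- IRanges::start(m)
    st <- st[st > last_end]
    if (!length(st)) NA_integer_ else st[1]
  }
  res <- segments
  res$start <- NA_integer_; res$end <- NA_integer_
  last <- 0L
  for (i in seq_len(nrow(segments))) {
    st <- find_anchor(segments$start[i], last)
    if (is.na(st))
      stop("segmentation failed: segment ", segments$name[i], " not found",
           call. = FALSE)
    res$start[i] <- st
    if (i > 1L) res$end[i - 1L] <- st - 1L
    last <- st
  }
  res$end[nrow(res)] <- nchar(unit_sequence)
  if (any(res$start > res$end))
    stop("segmentation failed: inverted segment order", call. = FALSE)
  ## N-gap intervals (reported, not fatal)
  gaps <- data.frame(start = integer(0), end = integer(0))
  nrun <- gregexpr("N+", unit_sequence)[[1]]
  if (nrun[1] != -1L)
    gaps <- data.frame(start = as.integer(nrun),
                       end = as.integer(nrun) + attr(nrun, "match.length") - 1L)
  ## IUPAC heterogeneous positions in the consensus
  het_hits <- gregexpr("[RYSWKM]", unit_sequence)[[1]]
  hets <- data.frame(position = integer(0), code = character(0))
  if (het_hits[1] != -1L)
    hets <- data.frame(position = as.integer(het_hits),
                       code = vapply(as.integer(het_hits), function(p)
                         substr(unit_sequence, p, p), character(1)))
  list(segments = res, gaps = gaps, heterogeneous_sites = hets)
}
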