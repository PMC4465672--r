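## Genotyping assays from cohort polymorphisms: InDel size markers, dCAPS
## designs (one engineered primer mismatch completes a restriction site over
## one SNP allele), in-silico PCR and digestion, and the accession x marker
## authentication matrix.

#' Restriction enzyme catalog
#'
#' A small catalog of common 5-6 bp cutters. `cut_offset` is the number of
#' bases of the recognition site left of the cut on the top strand.
#'
#' @return data.frame: name, site (IUPAC), cut_offset.
#' @export
enzyme_catalog <- function() {
  data.frame(
    name = c("XbaI", "ScaI", "EcoRI", "BamHI", "HindIII", "KpnI", "AvaII",
             "DraI", "SpeI", "NheI"),
    site = c("TCTAGA", "AGTACT", "GAATTC", "GGATCC", "AAGCTT", "GGTACC",
             "GGWCC", "TTTAAA", "ACTAGT", "GCTAGC"),
    cut_offset = c(1L, 3L, 1L, 1L, 1L, 5L, 1L, 3L, 1L, 1L))
}

## ---- melting temperature ---------------------------------------------------

## SantaLucia (1998) unified nearest-neighbor parameters.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)

#' Oligo melting temperature (nearest-neighbor)
#'
#' SantaLucia unified parameters with entropy salt correction;
#' defaults 50 mM monovalent salt and 500 nM total oligo.
#'
#' @param primer Character scalar (5'->3').
#' @param na_mM Monovalent cation concentration, mM.
#' @param oligo_nM Total oligo concentration, nM.
#' @return Tm in degrees Celsius.
#' @export
primer_tm <- function(primer, na_mM = 50, oligo_nM = 500) {
  s <- toupper(primer)
  n <- nchar(s)
  stopifnot(n >= 8L)
  pairs <- substring(s, 1:(n - 1L), 2:n)
  dh <- sum(NN_DH[pairs])
  ds <- sum(NN_DS[pairs])
  ends <- substr(s, 1L, 1L); endl <- substr(s, n, n)
  for (e in c(ends, endl)) {
    if (e %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1L) * log(na_mM / 1000)
  R <- 1.987
  dh * 1000 / (ds + R * log(oligo_nM * 1e-9 / 4)) - 273.15
}

gc_frac <- function(s) {
  b <- charToRaw(toupper(s))
  mean(b == charToRaw("G") | b == charToRaw("C"))
}

## longest self-complementary stretch (primer vs its own reverse complement)
## serves as a combined hairpin/homodimer screen
max_selfcomp_run <- function(primer) {
  a <- primer; b <- revcomp(primer)
  na <- nchar(a)
  best <- 0L
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  for (shift in (-na + 1L):(na - 1L)) {
    ia <- max(1L, 1L + shift); ib <- max(1L, 1L - shift)
    len <- na - abs(shift)
    eq <- av[ia:(ia + len - 1L)] == bv[ib:(ib + len - 1L)]
    r <- rle(eq)
    m <- suppressWarnings(max(r$lengths[r$values], 0L))
    if (m > best) best <- m
  }
  best
}

primer_ok <- function(primer, tm_range = c(55, 62), gc_range = c(0.35, 0.65),
                      max_run = 4L, len_range = c(18L, 27L)) {
  n <- nchar(primer)
  if (n < len_range[1] || n > len_range[2]) return(FALSE)
  g <- gc_frac(primer)
  if (g < gc_range[1] || g > gc_range[2]) return(FALSE)
  ## 3' end must not sit in a homopolymer run of 4+
  tail4 <- substr(primer, n - 3L, n)
  if (length(unique(strsplit(tail4, "")[[1]])) == 1L) return(FALSE)
  tm <- primer_tm(primer)
  if (tm < tm_range[1] || tm > tm_range[2]) return(FALSE)
  if (max_selfcomp_run(primer) > max_run) return(FALSE)
  TRUE
}

## ---- in-silico PCR ---------------------------------------------------------

## primer binding sites on the plus strand of `template` (primer must equal
## the template substring up to max_mismatch substitutions; an engineered
## dCAPS position, given 1-based from primer start, is always tolerated)
primer_hits <- function(primer, template, max_mismatch = 0L,
                        engineered_at = NA_integer_) {
  m <- Biostrings::matchPattern(
    primer, Biostrings::DNAString(template),
    max.mismatch = max_mismatch + !is.na(engineered_at), with.indels = FALSE)
  st <- IRanges::start(m)
  if (!length(st)) return(integer(0))
  if (!is.na(engineered_at)) {
    keep <- vapply(st, function(s0) {
      seg <- substr(template, s0, s0 + nchar(primer) - 1L)
      mmpos <- which(strsplit(seg, "")[[1]] != strsplit(primer, "")[[1]])
      length(setdiff(mmpos, engineered_at)) <= max_mismatch
    }, logical(1))
    st <- st[keep]
  }
  st
}

#' In-silico PCR
#'
#' Predicts every product formed by convergent primer hits within
#' `max_product` bases. Both primers are searched on both strands; product
#' sequences carry the primer sequences at their ends (as real amplicons
#' do), which matters for dCAPS digestion. Circular templates allow
#' origin-spanning products.
#'
#' @param template Character scalar.
#' @param forward,reverse Primer sequences, 5'->3'.
#' @param circular Is the template circular?
#' @param max_mismatches Tolerated mismatches per primer (default 0).
#' @param max_product Longest product reported (default 5000).
#' @param engineered Optional list(primer = "forward"|"reverse",
#'   position = k) marking a dCAPS engineered mismatch always tolerated at
#'   primer position k.
#' @return data.frame: start, end, length, sequence (primer-substituted).
#' @export
insilico_pcr <- function(template, forward, reverse, circular = FALSE,
                         max_mismatches = 0L, max_product = 5000L,
                         engineered = NULL) {
  L <- nchar(template)
  tmpl <- if (circular) paste0(template, substr(template, 1L, max_product)) else template
  eng_of <- function(which_primer, prim) {
    if (!is.null(engineered) && identical(engineered$primer, which_primer))
      engineered$position else NA_integer_
  }
  prims <- list(forward = forward, reverse = reverse)
  hits_plus <- list(); hits_minus <- list()
  for (nm in names(prims)) {
    p <- prims[[nm]]
    ea <- eng_of(nm, p)
    ea_rc <- if (is.na(ea)) NA_integer_ else nchar(p) - ea + 1L
    hp <- primer_hits(p, tmpl, max_mismatches, ea)
    hm <- primer_hits(revcomp(p), tmpl, max_mismatches, ea_rc)
    if (length(hp) > 50L || length(hm) > 50L)
      stop("low-complexity primer: more than 50 binding sites", call. = FALSE)
    hits_plus[[nm]] <- hp
    hits_minus[[nm]] <- hm
  }
  out <- list()
  for (a in names(prims)) for (b in names(prims)) {
    pa <- prims[[a]]; pb <- prims[[b]]
    for (s0 in hits_plus[[a]]) for (t0 in hits_minus[[b]]) {
      endp <- t0 + nchar(pb) - 1L
      len <- endp - s0 + 1L
      if (len < nchar(pa) + nchar(pb) || len > max_product) next
      if (circular && s0 > L) next
      if (circular && len >= L) next
      mid <- substr(tmpl, s0 + nchar(pa), endp - nchar(pb))
      seqn <- paste0(pa, mid, revcomp(pb))
      out[[length(out) + 1L]] <- data.frame(
        start = s0, end = endp, length = len, forward_primer = a,
        reverse_primer = b, sequence = seqn)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), forward_primer = character(0),
                      reverse_primer = character(0), sequence = character(0)))
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res[order(res$start, res$length), ]
}

#' Digest a linear amplicon with a restriction enzyme
#'
#' Cuts at every occurrence of the recognition site on either strand
#' (IUPAC-aware) at the enzyme's offset. Fragment lengths always sum to the
#' amplicon length.
#'
#' @param amplicon Character scalar.
#' @param enzyme One row of [enzyme_catalog()] (or list with site,
#'   cut_offset).
#' @return Integer vector of fragment lengths (single element when uncut).
#' @export
digest <- function(amplicon, enzyme) {
  site <- enzyme$site
  m <- nchar(site)
  subj <- Biostrings::DNAString(amplicon)
  f <- IRanges::start(Biostrings::matchPattern(site, subj, fixed = FALSE))
  cuts <- f + enzyme$cut_offset - 1L
  rcsite <- revcomp(site)
  if (!identical(rcsite, site)) {
    r <- IRanges::start(Biostrings::matchPattern(rcsite, subj, fixed = FALSE))
    cuts <- c(cuts, r + (m - enzyme$cut_offset) - 1L)
  }
  cuts <- sort(unique(cuts))
  cuts <- cuts[cuts >= 1L & cuts < nchar(amplicon)]
  diff(c(0L, cuts, nchar(amplicon)))
}

## ---- marker design ---------------------------------------------------------

## candidate primers from a window of the reference, excluding positions
## carrying other cohort variants
candidate_primers <- function(reference, win_start, win_end, variant_pos,
                              lengths = 18:27, tm_range = c(55, 62)) {
  out <- list()
  for (st in win_start:(win_end - min(lengths) + 1L)) {
    for (len in lengths) {
      en <- st + len - 1L
      if (en > win_end) next
      if (any(variant_pos >= st & variant_pos <= en)) next
      p <- substr(reference, st, en)
      if (primer_ok(p, tm_range)) {
        out[[length(out) + 1L]] <- data.frame(start = st, end = en, seq = p,
                                              tm = primer_tm(p))
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Design an InDel/TR-CNV size marker
#'
#' Picks a primer pair flanking the locus (length 18-27, nearest-neighbor
#' Tm 55-62 degC, GC 35-65%, no self-complementary run > 4, 3' end outside
#' homopolymers), predicts per-accession product sizes by in-silico PCR,
#' and requires the smallest between-class size difference to reach
#' `min_size_diff` for gel resolvability.
#'
#' @param reference Reference sequence.
#' @param locus_start,locus_end Reference interval of the polymorphic locus.
#' @param sequences Named accession sequences (for product-size prediction).
#' @param other_variant_pos Reference positions of other cohort variants
#'   (primer binding sites must avoid them).
#' @param search_window Bases searched on each side of the locus.
#' @param min_size_diff Smallest acceptable allele size difference (bases).
#' @return An `indel_marker`: list(forward, reverse, tm, product_sizes,
#'   informative) or an error describing the binding constraint.
#' @export
design_indel_marker <- function(reference, locus_start, locus_end, sequences,
                                other_variant_pos = integer(0),
                                search_window = 300L, min_size_diff = 5L) {
  lwin <- c(max(1L, locus_start - search_window), locus_start - 15L)
  rwin <- c(locus_end + 15L, min(nchar(reference), locus_end + search_window))
  fw <- candidate_primers(reference, lwin[1], lwin[2], other_variant_pos)
  if (is.null(fw))
    stop("design failure: no acceptable forward primer in the left window",
         call. = FALSE)
  rv <- candidate_primers(reference, rwin[1], rwin[2], other_variant_pos)
  if (is.null(rv))
    stop("design failure: no acceptable reverse primer in the right window",
         call. = FALSE)
  ## prefer primers close to the locus with matched Tm
  fw <- fw[order(-fw$end, abs(fw$tm - 58)), ][seq_len(min(25L, nrow(fw))), ]
  rv <- rv[order(rv$start, abs(rv$tm - 58)), ][seq_len(min(25L, nrow(rv))), ]
  best <- NULL; best_score <- Inf
  for (i in seq_len(nrow(fw))) for (j in seq_len(nrow(rv))) {
    score <- abs(fw$tm[i] - rv$tm[j]) +
      0.01 * ((locus_start - fw$end[i]) + (rv$start[j] - locus_end))
    if (score < best_score) { best <- c(i, j); best_score <- score }
  }
  fseq <- fw$seq[best[1]]
  rseq <- revcomp(rv$seq[best[2]])
  ## size-marker amplicons are short; the tight product cutoff also rejects
  ## single-primer artifacts between the two inverted-repeat copies. A
  ## locus inside the IR amplifies identically from both copies; products
  ## equal up to reverse complement are one band.
  sizes <- vapply(sequences, function(s) {
    pr <- insilico_pcr(s, fseq, rseq, circular = FALSE, max_product = 1500L)
    if (nrow(pr) > 1L) {
      canon <- vapply(pr$sequence, function(x) min(x, revcomp(x)), character(1))
      pr <- pr[!duplicated(canon), , drop = FALSE]
    }
    if (nrow(pr) != 1L) NA_integer_ else pr$length[1]
  }, integer(1))
  if (anyNA(sizes))
    stop("design failure: primer pair does not amplify uniquely in every ",
         "accession", call. = FALSE)
  classes <- sort(unique(sizes))
  if (length(classes) >= 2L && min(diff(classes)) < min_size_diff)
    stop("design failure: allele size difference below resolvability limit",
         call. = FALSE)
  structure(list(forward = fseq, reverse = rseq,
                 tm = c(forward = fw$tm[best[1]], reverse = rv$tm[best[2]]),
                 product_sizes = sizes,
                 informative = length(classes) >= 2L),
            class = "indel_marker")
}

#' Design a dCAPS marker for a biallelic SNP
#'
#' Searches both strands and every catalog enzyme for a primer placement in
#' which exactly one engineered mismatch within the last five bases of the
#' primer (never the 3'-terminal base) completes the recognition site over
#' the SNP for exactly one allele. The returned design maximizes site
#' specificity within the amplicon, then Tm closeness to 58 degC. When no
#' enzyme admits a placement a `no_design` result is returned (the
#' assay-design analogue of "no restriction site available").
#'
#' @param reference Reference sequence.
#' @param snp_pos SNP position (1-based).
#' @param ref_allele,alt_allele The two alleles.
#' @param enzymes Catalog (default [enzyme_catalog()]).
#' @param amplicon_half Reverse-primer placement distance (bases 3' of the
#'   SNP) used for the companion primer.
#' @return A `dcaps_design`: list(enzyme, strand, cut_allele, forward,
#'   reverse, engineered (primer position, from, to), fragment_lengths per
#'   allele) or object of class `no_design`.
#' @export
design_dcaps <- function(reference, snp_pos, ref_allele, alt_allele,
                         enzymes = enzyme_catalog(), amplicon_half = 150L) {
  alleles <- c(ref = ref_allele, alt = alt_allele)
  candidates <- list()
  for (strand in c("+", "-")) {
    ## analyze in a frame where the primer runs left-to-right toward the SNP
    if (strand == "+") {
      tmpl <- reference; p0 <- snp_pos; al <- alleles
    } else {
      tmpl <- revcomp(reference); p0 <- nchar(reference) - snp_pos + 1L
      al <- vapply(alleles, revcomp, character(1))
    }
    for (ei in seq_len(nrow(enzymes))) {
      site <- strsplit(enzymes$site[ei], "")[[1]]
      msite <- length(site)
      for (o in seq_len(msite)) {      # SNP at site offset o
        w <- p0 - o + 1L               # site spans [w, w + msite - 1]
        if (w < 30L || w + msite - 1L > nchar(tmpl) - 30L) next
        for (which_allele in c("ref", "alt")) {
          snp_base <- al[[which_allele]]
          if (!iupac_match1(site[o], snp_base)) next
          other <- setdiff(names(al), which_allele)
          if (iupac_match1(site[o], al[[other]])) next  # must discriminate
          ## template bases over the site, with the SNP allele substituted
          tpl_site <- strsplit(substr(tmpl, w, w + msite - 1L), "")[[1]]
          tpl_site[o] <- snp_base
          conflict <- which(!vapply(seq_len(msite), function(q)
            iupac_match1(site[q], tpl_site[q]), logical(1)))
          conflict <- setdiff(conflict, o)
          if (length(conflict) != 1L) next
          cq <- conflict[1]
          if (cq >= o) next            # engineered base must be primer-side
          ## primer 3' end e between the engineered base and the SNP
          for (e in (w + cq - 1L + 1L):(p0 - 1L)) {
            d3 <- e - (w + cq - 1L)    # distance of engineered base from 3'
            if (d3 < 1L || d3 > 4L) next
            for (plen in 18:30) {
              pst <- e - plen + 1L
              if (pst < 1L) next
              primer <- substr(tmpl, pst, e)
              ## install the engineered base (any base admitted by the site)
              need <- IUPAC_EXPAND[[site[cq]]][1]
              substr(primer, plen - d3, plen - d3) <- need
              ## dCAPS primers are position-locked against the SNP, so
              ## composition constraints are advisory: palindromic sites
              ## force ~half a site of self-complementarity, and AT-rich
              ## contexts force lower Tm/GC than freely placed primers
              if (!primer_ok(primer, tm_range = c(48, 68),
                             gc_range = c(0.2, 0.8), max_run = 6L,
                             len_range = c(18L, 30L))) next
              candidates[[length(candidates) + 1L]] <- list(
                enzyme = enzymes[ei, ], strand = strand,
                cut_allele = which_allele, primer = primer,
                primer_start = pst, primer_end = e, site_w = w,
                engineered = c(position = plen - d3,
                               from = substr(tmpl, e - d3, e - d3),
                               to = need),
                tm = primer_tm(primer), p0 = p0, tmpl_strand = strand)
              break                    # one length per placement is enough
            }
          }
        }
      }
    }
  }
  if (!length(candidates))
    return(structure(list(reason = "no enzyme/placement completes a site over the SNP"),
                     class = "no_design"))
  ## rank by site scarcity near the SNP, then Tm closeness to 58 degC, and
  ## accept the first candidate whose digestion fully validates: the uncut
  ## allele yields a single fragment, the cut allele exactly two, separable
  ## by at least 10 bases
  score <- vapply(candidates, function(cd) {
    tmpl <- if (cd$strand == "+") reference else revcomp(reference)
    win <- substr(tmpl, max(1L, cd$primer_start - 20L),
                  min(nchar(tmpl), cd$p0 + amplicon_half))
    nsite <- length(IRanges::start(Biostrings::matchPattern(
      cd$enzyme$site, Biostrings::DNAString(win), fixed = FALSE)))
    1000 * nsite + abs(cd$tm - 58)
  }, numeric(1))
  for (cd in candidates[order(score)]) {
    tmpl <- if (cd$strand == "+") reference else revcomp(reference)
    rv <- candidate_primers(tmpl, cd$p0 + 30L,
                            min(nchar(tmpl), cd$p0 + amplicon_half),
                            integer(0), tm_range = c(48, 68))
    if (is.null(rv)) next
    rv <- rv[order(abs(rv$tm - cd$tm)), ]
    reverse <- revcomp(rv$seq[1])
    frags <- lapply(alleles, function(ab) {
      alt_ref <- reference
      substr(alt_ref, snp_pos, snp_pos) <- ab
      t2 <- if (cd$strand == "+") alt_ref else revcomp(alt_ref)
      pr <- insilico_pcr(t2, cd$primer, reverse, max_product = 1500L,
                         engineered = list(primer = "forward",
                                           position = as.integer(cd$engineered[["position"]])))
      if (nrow(pr) != 1L) return(NULL)
      digest(pr$sequence[1], cd$enzyme)
    })
    names(frags) <- names(alleles)
    cut <- frags[[cd$cut_allele]]
    unc <- frags[[setdiff(names(alleles), cd$cut_allele)]]
    if (is.null(cut) || is.null(unc)) next
    if (length(unc) != 1L || length(cut) != 2L || min(cut) < 10L) next
    return(structure(list(enzyme = cd$enzyme, strand = cd$strand,
                          cut_allele = unname(alleles[[cd$cut_allele]]),
                          cut_allele_class = cd$cut_allele,
                          forward = cd$primer, reverse = reverse,
                          engineered = cd$engineered,
                          fragment_lengths = frags),
                     class = "dcaps_design"))
  }
  structure(list(reason = "no candidate validated by in-silico digestion"),
            class = "no_design")
}

## ---- authentication matrix -------------------------------------------------

#' Build the accession x marker authentication matrix
#'
#' Genotypes every accession for every marker and partitions the cohort into
#' classes of accessions indistinguishable by the panel. Markers are either
#' assay-derived (`indel_marker`: product size; `dcaps_design`: cut/uncut)
#' or direct site genotypes taken from the cohort table (`site` markers,
#' for surveyed positions without a PCR assay).
#'
#' @param cohort_table A [survey_cohort()]/[merge_cohort()] table.
#' @param markers Named list; each element is an `indel_marker`, a
#'   `dcaps_design` plus its target row, or `list(type = "site", pos = p)`.
#' @param sequences Named accession sequences (for assay outcomes).
#' @param accessions Accessions to genotype (default: names of `sequences`).
#' @return An `auth_matrix`: list(genotypes (data.frame), partition (list of
#'   character vectors)).
#' @export
build_auth_matrix <- function(cohort_table, markers, sequences,
                              accessions = names(sequences)) {
  geno <- matrix(NA_character_, nrow = length(accessions),
                 ncol = length(markers),
                 dimnames = list(accessions, names(markers)))
  for (mk in names(markers)) {
    m <- markers[[mk]]
    if (inherits(m, "indel_marker")) {
      for (acc in accessions)
        geno[acc, mk] <- as.character(m$product_sizes[[acc]])
    } else if (inherits(m, "dcaps_design")) {
      for (acc in accessions) {
        pr <- insilico_pcr(if (m$strand == "+") sequences[[acc]] else
                             revcomp(sequences[[acc]]),
                           m$forward, m$reverse,
                           engineered = list(primer = "forward",
                                             position = as.integer(m$engineered[["position"]])))
        geno[acc, mk] <- if (nrow(pr) != 1L) "no_product"
          else paste(digest(pr$sequence[1], m$enzyme), collapse = "+")
      }
    } else if (identical(m$type, "site")) {
      tab <- if (is.data.frame(cohort_table)) cohort_table
        else cohort_table[[if (is.null(m$genome)) 1L else m$genome]]
      row <- tab[tab$pos == m$pos, , drop = FALSE]
      if (!nrow(row)) {
        warning("marker ", mk, " has no informative cohort site; excluded")
        geno[, mk] <- "n/a"
        next
      }
      carr <- strsplit(row$carriers[1], ",")[[1]]
      for (acc in accessions)
        geno[acc, mk] <- if (acc %in% carr) row$alt[1] else row$ref[1]
    } else stop("unknown marker type for ", mk)
  }
  keys <- apply(geno, 1L, paste, collapse = "|")
  partition <- unname(split(accessions, factor(keys, levels = unique(keys))))
  structure(list(genotypes = as.data.frame(geno), partition = partition),
            class = "auth_matrix")
}

#' Minimal distinguishing marker subsets
#'
#' For each accession, reports a smallest marker subset that separates it
#' from every other accession, or its indistinguishability group.
#'
#' @param auth An `auth_matrix`.
#' @return Named list: character vector of marker names, or the group.
#' @export
distinguishing_markers <- function(auth) {
  g <- auth$genotypes
  out <- list()
  for (acc in rownames(g)) {
    others <- setdiff(rownames(g), acc)
    sep <- vapply(others, function(o) any(g[acc, ] != g[o, ]), logical(1))
    if (!all(sep)) {
      out[[acc]] <- list(group = c(acc, others[!sep]))
      next
    }
    ## greedy set cover over markers
    uncov <- others
    chosen <- character(0)
    while (length(uncov)) {
      gain <- vapply(colnames(g), function(mk)
        sum(g[uncov, mk] != g[acc, mk][[1]]), integer(1))
      best <- names(which.max(gain))
      chosen <- c(chosen, best)
      uncov <- uncov[g[uncov, best] == g[acc, best][[1]]]
    }
    out[[acc]] <- list(markers = chosen)
  }
  out
}
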