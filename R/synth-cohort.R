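## Synthetic cohort generator: a quadripartite circular plastome
## (LSC + IRa + SSC + IRb, IRa = revcomp(IRb)), per-cultivar haplotypes that
## differ from the reference only at declared polymorphic loci, an ~11 kb
## 45S nrDNA unit (18S-ITS1-5.8S-ITS2-26S-IGS) with a GC-rich IGS carrying a
## 641-bp sub-repeat at 3.5 copies, plus contig fragmentation and paired-end
## read simulation. Every downstream stage is testable against the planted
## truth set.

CP_ACCESSIONS <- c("ChP", "YP", "GU", "GO", "SO", "SU", "SP", "SH", "CS",
                   "JK", "HS", "Damaya", "Ermaya", "Gaolishen")
NR_ACCESSIONS <- c("ChP", "YP", "GU", "GO", "SO", "SU", "SP", "SH", "CS",
                   "JK", "HS")
## The three Chinese collections are cohort members whose genotypes duplicate
## the landrace JK at every surveyed site; they are not independent sequence
## sources.
CHINESE_ACCESSIONS <- c("Damaya", "Ermaya", "Gaolishen")

#' Cohort configuration for the ginseng-like synthetic fixture
#'
#' Two profiles share one proportional layout: `"mini"` is a 30 kb plastome
#' for fast desk-scale analysis, `"full"` a 156 kb plastome. Both carry the
#' same 12 plastome polymorphisms (6 SNPs, 6 InDels including homopolymer and
#' tandem-repeat copy-number alleles) and 5 nrDNA SNPs, at proportionally
#' placed positions. Feature-internal geometry (codon phases, repeat arrays)
#' is scale-invariant: only inter-feature filler scales.
#'
#' @param profile `"mini"` (30 kb) or `"full"` (156 kb).
#' @param seed Integer root seed; all randomness derives from it.
#' @param igs_gap_len Length of an N-run planted in the nrDNA IGS of
#'   accessions other than ChP/YP (0 = none), emulating an unclosed gap in
#'   the degenerate GC-rich repeats.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(profile = c("mini", "full"), seed = 1L,
                          igs_gap_len = 0L) {
  profile <- match.arg(profile)
  scale <- if (profile == "mini") 1 else 5.2
  layout <- make_cp_layout(scale)
  structure(list(profile = profile, seed = as.integer(seed), scale = scale,
                 layout = layout, nrdna = make_nrdna_layout(),
                 igs_gap_len = as.integer(igs_gap_len)),
            class = "cohort_config")
}

## ---- plastome layout -------------------------------------------------------

## All coordinates 1-based inclusive on the forward strand of the canonical
## rotation. Region order LSC, IRa, SSC, IRb with IRa = revcomp(IRb).
make_cp_layout <- function(scale) {
  lsc <- round(16600 * scale)
  ir  <- round(5100 * scale)
  ssc <- round(3200 * scale)
  L <- lsc + 2L * ir + ssc
  ira_s <- lsc + 1L; ira_e <- lsc + ir
  ssc_s <- ira_e + 1L; ssc_e <- ira_e + ssc
  irb_s <- ssc_e + 1L; irb_e <- L

  b1 <- round(900 * scale)                  # rps16 .. trnUUG block (LSC)
  b2 <- round(3801 * scale)                 # rpoC2/rpoC1 block (LSC)
  b3 <- round(6100 * scale)                 # trnUUC/trnGGU block (LSC)
  b4 <- ira_s + round(3599 * scale)         # trnUGC block (IRa)
  b5 <- ssc_s + round(199 * scale)          # ndhF .. ccsA block (SSC)
  ## ycf1 spans the SSC/IRb junction; anchored to the junction, unscaled.
  ycf1_s <- ssc_e - 599L; ycf1_e <- ssc_e + 450L

  genes <- rbind(
    data.frame(name = "rps16",  start = b1,          end = b1 + 400L, strand = "-", type = "gene"),
    data.frame(name = "rps16",  start = b1,          end = b1 + 100L, strand = "-", type = "CDS"),
    data.frame(name = "rps16",  start = b1 + 101L,   end = b1 + 220L, strand = "-", type = "intron"),
    data.frame(name = "rps16",  start = b1 + 221L,   end = b1 + 400L, strand = "-", type = "CDS"),
    data.frame(name = "trnUUG", start = b1 + 700L,   end = b1 + 780L, strand = "-", type = "tRNA"),
    data.frame(name = "rpoC2",  start = b2,          end = b2 + 449L, strand = "-", type = "gene"),
    data.frame(name = "rpoC2",  start = b2,          end = b2 + 449L, strand = "-", type = "CDS"),
    data.frame(name = "rpoC1",  start = b2 + 459L,   end = b2 + 899L, strand = "-", type = "gene"),
    data.frame(name = "rpoC1",  start = b2 + 459L,   end = b2 + 899L, strand = "-", type = "CDS"),
    data.frame(name = "trnUUC", start = b3,          end = b3 + 80L,  strand = "+", type = "tRNA"),
    data.frame(name = "trnGGU", start = b3 + 400L,   end = b3 + 470L, strand = "+", type = "tRNA"),
    data.frame(name = "trnUGC", start = b4,          end = b4 + 220L, strand = "+", type = "gene"),
    data.frame(name = "trnUGC", start = b4 + 50L,    end = b4 + 150L, strand = "+", type = "intron"),
    data.frame(name = "ndhF",   start = b5,          end = b5 + 200L, strand = "-", type = "gene"),
    data.frame(name = "ndhF",   start = b5,          end = b5 + 200L, strand = "-", type = "CDS"),
    data.frame(name = "rpl32",  start = b5 + 500L,   end = b5 + 600L, strand = "-", type = "gene"),
    data.frame(name = "rpl32",  start = b5 + 500L,   end = b5 + 600L, strand = "-", type = "CDS"),
    data.frame(name = "trnUAG", start = b5 + 800L,   end = b5 + 880L, strand = "-", type = "tRNA"),
    data.frame(name = "ccsA",   start = b5 + 950L,   end = b5 + 1450L, strand = "+", type = "gene"),
    data.frame(name = "ccsA",   start = b5 + 950L,   end = b5 + 1450L, strand = "+", type = "CDS"),
    data.frame(name = "ycf1",   start = ycf1_s,      end = ycf1_e,    strand = "-", type = "gene"),
    data.frame(name = "ycf1",   start = ycf1_s,      end = ycf1_e,    strand = "-", type = "CDS")
  )

  loci <- list(
    snp_rps16_trnUUG = list(kind = "snp", pos = b1 + 480L, ref = "G", alt = "T",
                            carriers = "SH"),
    snp_rpoC2 = list(kind = "snp", pos = b2 + 299L, ref = "C", alt = "T",
                     carriers = c("GU", "CS"),
                     ## minus-strand Gly codon GGT (forward ACC) preceded by
                     ## "GA" so a GGWCC-class site is one primer fix away
                     context = list(start = b2 + 295L, seq = "GAACC")),
    snp_rpoC1 = list(kind = "snp", pos = b2 + 489L, ref = "T", alt = "G",
                     carriers = setdiff(NR_ACCESSIONS, "ChP"),
                     ## synonymous Leu codon, minus strand; allele G completes
                     ## an XbaI site (TCTAGA) given one engineered primer base
                     context = list(start = b2 + 483L, seq = "GATCCATAG")),
    snp_ndhF_rpl32 = list(kind = "snp", pos = b5 + 330L, ref = "G", alt = "T",
                          carriers = "SH"),
    snp_ccsA = list(kind = "snp", pos = b5 + 1101L, ref = "A", alt = "G",
                    carriers = c("GU", "CS"),
                    ## Gln codon CAG -> Arg CGG; reference allele completes a
                    ## natural ScaI site AGTACT starting at the SNP
                    context = list(start = b5 + 1100L, seq = "CAGTACTC")),
    snp_ycf1 = list(kind = "snp", pos = ssc_e - 460L, ref = "A", alt = "T",
                    carriers = "HS",
                    context = list(start = ssc_e - 461L, seq = "AAT")),
    hp_rps16_intron = list(kind = "homopolymer", pos = b1 + 150L, base = "C",
                           ref_len = 8L, alt_len = 9L, carriers = c("GU", "CS")),
    tr13_rps16_trnUUG = list(kind = "tr_cnv", pos = b1 + 530L, unit_length = 13L,
                             ref_copies = 1L, alt_copies = 2L, carriers = "SH"),
    tr33_rps16_trnUUG = list(kind = "tr_cnv", pos = b1 + 570L, unit_length = 33L,
                             ref_copies = 2L, alt_copies = 2L, carriers = character(0)),
    ins59_trnUUC_trnGGU = list(kind = "insertion", pos = b3 + 220L, length = 59L,
                               carriers = "SH"),
    hp_trnUGC_intron = list(kind = "homopolymer", pos = b4 + 70L, base = "G",
                            ref_len = 11L, alt_len = 10L, carriers = "SH",
                            in_ir = TRUE),
    tr57_ycf1 = list(kind = "tr_cnv", pos = ssc_e + 250L, unit_length = 57L,
                     ref_copies = 3L, alt_copies = 4L,
                     carriers = setdiff(NR_ACCESSIONS, c("ChP", "HS")),
                     in_ir = TRUE),
    tr7_rpl32_trnUAG = list(kind = "tr_cnv", pos = b5 + 660L, unit = "ACCTATT",
                            unit_length = 7L, ref_copies = 3L, alt_copies = 2L,
                            carriers = setdiff(NR_ACCESSIONS, "ChP"))
  )

  list(genome_length = L,
       regions = data.frame(name = c("LSC", "IRa", "SSC", "IRb"),
                            start = c(1L, ira_s, ssc_s, irb_s),
                            end = c(lsc, ira_e, ssc_e, irb_e)),
       genes = genes, loci = loci)
}

## nrDNA unit: fixed full-scale layout (11,091 bp), linear.
make_nrdna_layout <- function() {
  segments <- data.frame(
    name = c("18S", "ITS1", "5.8S", "ITS2", "26S", "IGS"),
    start = c(1L, 1810L, 2021L, 2185L, 2415L, 5801L),
    end = c(1809L, 2020L, 2184L, 2414L, 5800L, 11091L))
  loci <- list(
    snp_58S = list(kind = "snp", pos = 2044L, ref = "A", alt = "G",
                   carriers = c("GU", "GO")),
    snp_26S_het = list(kind = "snp", pos = 4165L, ref = "C", alt = "S",
                       carriers = c("GU", "GO"), heterogeneous = TRUE),
    snp_igs1 = list(kind = "snp", pos = 6674L, ref = "A", alt = "G",
                    carriers = c("GU", "GO")),
    snp_igs2 = list(kind = "snp", pos = 7668L, ref = "T", alt = "C",
                    carriers = c("GU", "GO")),
    snp_igs3 = list(kind = "snp", pos = 8365L, ref = "G", alt = "T",
                    carriers = "SP"))
  list(unit_length = 11091L, segments = segments, loci = loci,
       subrepeat = list(start = 8500L, unit_length = 641L, full_copies = 3L,
                        partial = 321L))
}

## ---- reference construction ------------------------------------------------

ir_mirror_pos <- function(p, layout) {
  r <- layout$regions
  ira <- r[r$name == "IRa", ]; irb <- r[r$name == "IRb", ]
  ifelse(p >= ira$start & p <= ira$end, irb$start + (ira$end - p),
         ifelse(p >= irb$start & p <= irb$end, ira$start + (irb$end - p),
                NA_integer_))
}

## Interval table of every planted locus (reference-allele footprint plus a
## one-base guard on each side), used for the disjointness precondition.
planted_intervals <- function(layout) {
  rows <- lapply(names(layout$loci), function(nm) {
    lc <- layout$loci[[nm]]
    w <- switch(lc$kind,
      snp = c(lc$pos, lc$pos),
      homopolymer = c(lc$pos, lc$pos + lc$ref_len - 1L),
      tr_cnv = c(lc$pos, lc$pos + lc$unit_length * lc$ref_copies - 1L),
      insertion = c(lc$pos, lc$pos + 1L))
    if (!is.null(lc$context))
      w <- range(c(w, lc$context$start,
                   lc$context$start + nchar(lc$context$seq) - 1L))
    data.frame(locus = nm, start = w[1] - 1L, end = w[2] + 1L)
  })
  do.call(rbind, rows)
}

#' Build the synthetic reference plastome and its annotation
#'
#' Generates a circular quadripartite reference (IRa equal to the reverse
#' complement of IRb by construction), plants all locus contexts (codon
#' windows, homopolymer runs, tandem-repeat arrays with repeat-breaking
#' flanks), and returns the sequence with a gene-model annotation table.
#' Deterministic under the config seed.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `sequence` (character scalar), `annotation`
#'   (data.frame: name, start, end, strand, type), `layout`, and `units`
#'   (realized random repeat-unit sequences, keyed by locus).
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  layout <- config$layout
  iv <- planted_intervals(layout)
  ord <- order(iv$start)
  iv <- iv[ord, ]
  bad <- which(iv$start[-1] <= iv$end[-nrow(iv)])
  if (length(bad))
    stop("overlapping planted loci: ", iv$locus[bad[1]], " and ",
         iv$locus[bad[1] + 1L], call. = FALSE)
  g <- layout$genes
  if (any(g$start < 1L | g$end > layout$genome_length))
    stop("gene model outside genome bounds", call. = FALSE)

  set.seed(derive_seed(config$seed, "reference"))
  r <- layout$regions
  lsc_len <- r$end[1]; ir_len <- r$end[2] - r$start[2] + 1L
  ssc_len <- r$end[3] - r$start[3] + 1L
  core_len <- lsc_len + ir_len + ssc_len      # LSC + IRa + SSC
  chars <- strsplit(paste0(random_dna(core_len)), "")[[1]]

  put <- function(pos, s) {
    stopifnot(pos >= 1L, pos + nchar(s) - 1L <= core_len)
    chars[pos:(pos + nchar(s) - 1L)] <<- strsplit(s, "")[[1]]
  }
  other_base <- function(avoid) sample(setdiff(DNA_BASES_STRICT, avoid), 1L)

  units <- list()
  for (nm in names(layout$loci)) {
    lc <- layout$loci[[nm]]
    if (lc$kind == "snp") {
      if (!is.null(lc$context)) put(lc$context$start, lc$context$seq)
      put(lc$pos, lc$ref)
    } else if (lc$kind == "homopolymer") {
      run <- strrep(lc$base, lc$ref_len)
      put(lc$pos - 1L, paste0(other_base(lc$base), run, other_base(lc$base)))
    } else if (lc$kind == "tr_cnv") {
      unit <- lc[["unit"]]
      if (is.null(unit)) unit <- random_dna(lc$unit_length)
      in_ir <- isTRUE(lc$in_ir)
      ## IR-resident arrays are planted into IRa (reverse-complemented); the
      ## forward-sense array materializes in IRb when IRb = revcomp(IRa).
      if (in_ir) {
        mir_end <- ir_mirror_pos(lc$pos + lc$unit_length * lc$ref_copies - 1L, layout)
        a1 <- mir_end
        v <- revcomp(unit)
        arr <- strrep(v, lc$ref_copies)
        put(a1 - 1L, paste0(other_base(substr(v, lc$unit_length, lc$unit_length)),
                            arr, other_base(substr(v, 1L, 1L))))
      } else {
        arr <- strrep(unit, lc$ref_copies)
        put(lc$pos - 1L,
            paste0(other_base(substr(unit, lc$unit_length, lc$unit_length)),
                   arr, other_base(substr(unit, 1L, 1L))))
      }
      units[[nm]] <- unit
    } else if (lc$kind == "insertion") {
      ins <- random_dna(lc$length)
      ## forbid left-shift of the normalized insertion: last inserted base
      ## must differ from the anchor base
      anchor <- other_base(substr(ins, lc$length, lc$length))
      put(lc$pos, anchor)
      units[[nm]] <- ins
    }
  }

  core <- paste(chars, collapse = "")
  ira <- substr(core, r$start[2], r$end[2])
  seqn <- paste0(core, revcomp(ira))
  stopifnot(nchar(seqn) == layout$genome_length)
  list(sequence = seqn, annotation = layout$genes, layout = layout,
       units = units)
}

## Build the nrDNA reference unit (GC-rich IGS, 641-bp sub-repeat at
## 3 + 321/641 copies) and return sequence + realized sub-repeat unit.
build_nrdna_reference <- function(config) {
  nr <- config$nrdna
  set.seed(derive_seed(config$seed, "nrdna"))
  seg <- nr$segments
  igs <- seg[seg$name == "IGS", ]
  pre <- random_dna(igs$start - 1L, gc = 0.48)
  igs_seq <- random_dna(igs$end - igs$start + 1L, gc = 0.63)
  chars <- strsplit(paste0(pre, igs_seq), "")[[1]]
  put <- function(pos, s) chars[pos:(pos + nchar(s) - 1L)] <<- strsplit(s, "")[[1]]
  for (lc in nr$loci) put(lc$pos, lc$ref)
  sr <- nr$subrepeat
  unit <- random_dna(sr$unit_length, gc = 0.6)
  arr <- paste0(strrep(unit, sr$full_copies), substr(unit, 1L, sr$partial))
  lflank <- sample(setdiff(DNA_BASES_STRICT,
                           substr(unit, sr$unit_length, sr$unit_length)), 1L)
  rflank <- sample(setdiff(DNA_BASES_STRICT,
                           substr(unit, sr$partial + 1L, sr$partial + 1L)), 1L)
  put(sr$start - 1L, paste0(lflank, arr, rflank))
  list(sequence = paste(chars, collapse = ""), segments = seg,
       subrepeat_unit = unit, layout = nr)
}

## ---- variant planting ------------------------------------------------------

## Expand a carrier set: the Chinese collections always duplicate JK.
expand_carriers <- function(carriers, accessions) {
  if ("JK" %in% carriers) carriers <- c(carriers, CHINESE_ACCESSIONS)
  intersect(accessions, carriers)
}

## Edits (ref-coordinate interval replacements) implied by one locus for a
## carrier accession. IR-resident loci yield the mirrored edit as well.
locus_edits <- function(lc, units_unit, layout) {
  e <- switch(lc$kind,
    snp = data.frame(start = lc$pos, end = lc$pos, repl = lc$alt),
    homopolymer = data.frame(start = lc$pos, end = lc$pos + lc$ref_len - 1L,
                             repl = strrep(lc$base, lc$alt_len)),
    tr_cnv = {
      u <- if (!is.null(lc[["unit"]])) lc[["unit"]] else units_unit
      data.frame(start = lc$pos,
                 end = lc$pos + lc$unit_length * lc$ref_copies - 1L,
                 repl = strrep(u, lc$alt_copies))
    },
    insertion = data.frame(start = lc$pos + 1L, end = lc$pos,
                           repl = units_unit))
  if (isTRUE(lc$in_ir)) {
    if (e$end >= e$start) {
      ## replacement of [start..end] mirrors to [m(end)..m(start)]
      e2 <- data.frame(start = ir_mirror_pos(e$end, layout),
                       end = ir_mirror_pos(e$start, layout),
                       repl = revcomp(e$repl))
    } else {
      ## insertion after anchor = e$end mirrors to after m(anchor + 1)
      anchor_m <- ir_mirror_pos(e$end + 1L, layout)
      e2 <- data.frame(start = anchor_m + 1L, end = anchor_m,
                       repl = revcomp(e$repl))
    }
    e <- rbind(e, e2)
  }
  e
}

#' Plant declared variants into per-accession haplotypes
#'
#' Applies the configured polymorphism plan to the reference: each accession
#' listed as a carrier receives the alternate allele, everyone else keeps the
#' reference allele, and variants inside the inverted repeat are planted in
#' both IR copies (reverse-complemented in the second copy). The Chinese
#' collections always receive JK's genotype.
#'
#' @param reference Result of [build_reference()].
#' @param config The [cohort_config()] used to build it.
#' @param accessions Accession names (default: the 14 cp cohort members).
#' @return A truth set: list with `sequences` (named list of haplotypes) and
#'   `variants` (normalized truth table, see [truth_variants()]).
#' @export
plant_variants <- function(reference, config,
                           accessions = CP_ACCESSIONS) {
  layout <- reference$layout
  refseq <- reference$sequence
  ## data-consistency precondition: stated reference alleles must match
  for (nm in names(layout$loci)) {
    lc <- layout$loci[[nm]]
    if (lc$kind == "snp") {
      have <- substr(refseq, lc$pos, lc$pos)
      if (have != lc$ref)
        stop(sprintf("reference allele mismatch at %d: spec %s, sequence %s",
                     lc$pos, lc$ref, have), call. = FALSE)
    }
  }
  seqs <- list()
  for (acc in accessions) {
    if (acc %in% CHINESE_ACCESSIONS) next
    edits <- list()
    for (nm in names(layout$loci)) {
      lc <- layout$loci[[nm]]
      if (!(acc %in% expand_carriers(lc$carriers, accessions))) next
      edits[[length(edits) + 1L]] <- locus_edits(lc, reference$units[[nm]], layout)
    }
    if (!length(edits)) { seqs[[acc]] <- refseq; next }
    ed <- do.call(rbind, edits)
    ed <- ed[order(ed$start, decreasing = TRUE), , drop = FALSE]
    s <- refseq
    for (i in seq_len(nrow(ed))) {
      left <- substr(s, 1L, ed$start[i] - 1L)
      right <- substr(s, max(ed$start[i], ed$end[i] + 1L), nchar(s))
      s <- paste0(left, ed$repl[i], right)
    }
    seqs[[acc]] <- s
  }
  for (acc in intersect(accessions, CHINESE_ACCESSIONS))
    seqs[[acc]] <- seqs[["JK"]]
  seqs <- seqs[accessions]
  list(sequences = seqs,
       variants = truth_variants(reference, config, accessions))
}

#' Normalized truth table of planted variants
#'
#' One row per distinct site in VCF-like left-aligned normalization (InDels
#' carry a one-base left anchor); IR-resident variants give a single row with
#' the mirrored coordinate recorded. Carriers are comma-collapsed in cohort
#' order.
#'
#' @inheritParams plant_variants
#' @return data.frame: locus, type, pos, ref, alt, carriers, region,
#'   ir_mirror, notation.
#' @export
truth_variants <- function(reference, config, accessions = CP_ACCESSIONS) {
  layout <- reference$layout
  refseq <- reference$sequence
  base_at <- function(p) substr(refseq, p, p)
  rows <- list()
  for (nm in names(layout$loci)) {
    lc <- layout$loci[[nm]]
    carr <- expand_carriers(lc$carriers, accessions)
    if (!length(carr)) next
    carr <- paste(intersect(accessions, carr), collapse = ",")
    if (lc$kind == "snp") {
      rows[[nm]] <- data.frame(locus = nm, type = "SNP", pos = lc$pos,
                               ref = lc$ref, alt = lc$alt, carriers = carr,
                               ir_mirror = NA_integer_,
                               notation = paste0(lc$ref, ">", lc$alt))
    } else if (lc$kind == "homopolymer") {
      a <- lc$pos - 1L; ins <- lc$alt_len > lc$ref_len
      d <- abs(lc$alt_len - lc$ref_len)
      run <- strrep(lc$base, d)
      mir <- if (isTRUE(lc$in_ir))
        ir_mirror_pos(lc$pos + lc$ref_len - 1L, layout) - 1L else NA_integer_
      rows[[nm]] <- data.frame(
        locus = nm, type = if (ins) "insertion" else "deletion", pos = a,
        ref = if (ins) base_at(a) else paste0(base_at(a), run),
        alt = if (ins) paste0(base_at(a), run) else base_at(a),
        carriers = carr, ir_mirror = mir,
        notation = sprintf("(%s)%d>(%s)%d", lc$base, lc$ref_len, lc$base,
                           lc$alt_len))
    } else if (lc$kind == "tr_cnv") {
      if (lc$alt_copies == lc$ref_copies) next
      u <- if (!is.null(lc[["unit"]])) lc[["unit"]] else reference$units[[nm]]
      ins <- lc$alt_copies > lc$ref_copies
      d <- abs(lc$alt_copies - lc$ref_copies)
      if (isTRUE(lc$in_ir)) {
        ## event exists in both copies; report the lower-coordinate (IRa)
        ## event, whose unit is the reverse complement of the planted unit
        arr_end <- lc$pos + lc$unit_length * lc$ref_copies - 1L
        a_ira <- ir_mirror_pos(arr_end, layout) - 1L
        a_irb <- lc$pos - 1L
        ua <- revcomp(u)
        seqrep <- strrep(ua, d)
        rows[[nm]] <- data.frame(
          locus = nm, type = if (ins) "insertion" else "deletion", pos = a_ira,
          ref = if (ins) base_at(a_ira) else paste0(base_at(a_ira), seqrep),
          alt = if (ins) paste0(base_at(a_ira), seqrep) else base_at(a_ira),
          carriers = carr, ir_mirror = a_irb,
          notation = sprintf("%dx%d>%dx%d", lc$unit_length, lc$ref_copies,
                             lc$unit_length, lc$alt_copies))
      } else {
        a <- lc$pos - 1L
        seqrep <- strrep(u, d)
        rows[[nm]] <- data.frame(
          locus = nm, type = if (ins) "insertion" else "deletion", pos = a,
          ref = if (ins) base_at(a) else paste0(base_at(a), seqrep),
          alt = if (ins) paste0(base_at(a), seqrep) else base_at(a),
          carriers = carr, ir_mirror = NA_integer_,
          notation = sprintf("%dx%d>%dx%d", lc$unit_length, lc$ref_copies,
                             lc$unit_length, lc$alt_copies))
      }
    } else if (lc$kind == "insertion") {
      a <- lc$pos
      rows[[nm]] <- data.frame(
        locus = nm, type = "insertion", pos = a, ref = base_at(a),
        alt = paste0(base_at(a), reference$units[[nm]]), carriers = carr,
        ir_mirror = NA_integer_, notation = sprintf("+%dbp", lc$length))
    }
  }
  if (!length(rows))
    return(data.frame(locus = character(0), type = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), carriers = character(0),
                      ir_mirror = integer(0), notation = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$pos), ]
}

## nrDNA cohort: 11 accessions, heterogeneous site as IUPAC in consensus.
#' @rdname plant_variants
#' @param nr_reference Result of [build_nrdna_reference()].
#' @export
plant_nrdna_variants <- function(nr_reference, config,
                                 accessions = NR_ACCESSIONS) {
  nr <- nr_reference$layout
  refseq <- nr_reference$sequence
  seqs <- list(); rows <- list()
  for (acc in accessions) seqs[[acc]] <- refseq
  for (nm in names(nr$loci)) {
    lc <- nr$loci[[nm]]
    for (acc in intersect(accessions, lc$carriers)) {
      s <- seqs[[acc]]
      substr(s, lc$pos, lc$pos) <- lc$alt
      seqs[[acc]] <- s
    }
    rows[[nm]] <- data.frame(locus = nm, type = "SNP", pos = lc$pos,
                             ref = lc$ref, alt = lc$alt,
                             carriers = paste(intersect(accessions, lc$carriers),
                                              collapse = ","),
                             ir_mirror = NA_integer_,
                             notation = paste0(lc$ref, ">", lc$alt))
  }
  if (config$igs_gap_len > 0L) {
    gap_at <- nr$segments$start[nr$segments$name == "IGS"] + 60L
    for (acc in setdiff(accessions, c("ChP", "YP"))) {
      s <- seqs[[acc]]
      substr(s, gap_at, gap_at + config$igs_gap_len - 1L) <-
        strrep("N", config$igs_gap_len)
      seqs[[acc]] <- s
    }
  }
  vt <- do.call(rbind, rows); rownames(vt) <- NULL
  list(sequences = seqs, variants = vt[order(vt$pos), ])
}

## ---- fragmentation and reads -----------------------------------------------

#' Fragment a circular genome into overlapping contigs
#'
#' Cuts the circle into `n_fragments` pieces whose adjacent ends share at
#' least `overlap` identical terminal bases (the last contig overlaps the
#' first across the origin). A random subset is emitted reverse-complemented
#' and the output order is shuffled.
#'
#' @param genome Character scalar, circular sequence.
#' @param n_fragments Number of contigs (>= 2).
#' @param overlap Minimum terminal overlap in bases (>= 1).
#' @param seed Integer seed.
#' @param rc_fraction Expected fraction of contigs emitted reverse-complemented.
#' @return A `contig_set`: data.frame (id, sequence, true_start, true_length,
#'   orientation) plus attributes `genome_length`, `overlap`.
#' @export
fragment_into_contigs <- function(genome, n_fragments, overlap, seed = 1L,
                                  rc_fraction = 0.3) {
  L <- nchar(genome)
  stopifnot(n_fragments >= 2L, overlap >= 1L)
  if (as.numeric(overlap) * n_fragments >= L)
    stop("infeasible fragmentation: overlap * n_fragments >= genome length",
         call. = FALSE)
  set.seed(derive_seed(seed, "fragment"))
  base_starts <- round((0:(n_fragments - 1L)) * L / n_fragments) + 1L
  jit <- round(stats::runif(n_fragments, -L / (6 * n_fragments),
                            L / (6 * n_fragments)))
  starts <- sort(((base_starts + jit - 1L) %% L) + 1L)
  spans <- diff(c(starts, starts[1] + L))
  if (any(spans <= overlap))
    stop("infeasible fragmentation: a fragment would be swallowed by overlap",
         call. = FALSE)
  lens <- spans + overlap
  seqsv <- vapply(seq_len(n_fragments),
                  function(i) circ_substr(genome, starts[i], lens[i]),
                  character(1))
  rc <- stats::runif(n_fragments) < rc_fraction
  seqsv[rc] <- vapply(seqsv[rc], revcomp, character(1))
  ord <- sample(n_fragments)
  out <- data.frame(id = paste0("contig_", seq_len(n_fragments)),
                    sequence = seqsv[ord], true_start = starts[ord],
                    true_length = lens[ord],
                    orientation = ifelse(rc[ord], "reverse", "forward"))
  structure(out, genome_length = L, overlap = overlap, class =
              c("contig_set", "data.frame"))
}

#' Simulate paired-end reads from a (circular) genome
#'
#' Uniform fragment starts on the circle, fixed insert size, substitution
#' errors only. The pair count is `ceiling(depth * L / (2 * read_length))`.
#'
#' @param genome Character scalar.
#' @param depth Target mean coverage (x).
#' @param insert_size Fragment length (default 300).
#' @param read_length Read length (default 101).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @param circular Allow fragments to span the origin.
#' @return A `read_set`: data.frame (id, read1, read2, start, strand) with
#'   attributes for the parameters.
#' @export
simulate_reads <- function(genome, depth, insert_size = 300L,
                           read_length = 101L, error_rate = 0, seed = 1L,
                           circular = TRUE) {
  L <- nchar(genome)
  stopifnot(depth > 0, insert_size >= read_length)
  set.seed(derive_seed(seed, "reads"))
  n <- ceiling(depth * L / (2 * read_length))
  max_start <- if (circular) L else L - insert_size + 1L
  starts <- sample.int(max_start, n, replace = TRUE)
  tmpl <- if (circular) paste0(genome, substr(genome, 1L, insert_size)) else genome
  frags <- substring(tmpl, starts, starts + insert_size - 1L)
  r1 <- substring(frags, 1L, read_length)
  r2 <- vapply(substring(frags, insert_size - read_length + 1L, insert_size),
               revcomp, character(1), USE.NAMES = FALSE)
  minus <- stats::runif(n) < 0.5
  tmp <- r1[minus]; r1[minus] <- r2[minus]; r2[minus] <- tmp
  if (error_rate > 0) {
    r1 <- inject_errors(r1, error_rate)
    r2 <- inject_errors(r2, error_rate)
  }
  structure(data.frame(id = sprintf("read_%06d", seq_len(n)), read1 = r1,
                       read2 = r2, start = starts,
                       strand = ifelse(minus, "-", "+")),
            insert_size = insert_size, read_length = read_length,
            error_rate = error_rate, genome_length = L,
            class = c("read_set", "data.frame"))
}

inject_errors <- function(reads, rate) {
  nerr <- stats::rbinom(length(reads), nchar(reads), rate)
  for (i in which(nerr > 0L)) {
    s <- strsplit(reads[i], "")[[1]]
    at <- sample.int(length(s), nerr[i])
    s[at] <- vapply(s[at], function(b)
      sample(setdiff(DNA_BASES_STRICT, b), 1L), character(1))
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

## ---- top-level cohort builder ----------------------------------------------

#' Build the complete synthetic cohort
#'
#' Convenience wrapper: reference plastome + annotation, 14 cp haplotypes,
#' nrDNA reference + 11 nrDNA units, and normalized truth tables.
#'
#' @inheritParams cohort_config
#' @return A `synthetic_cohort` list: `config`, `cp` (reference, annotation,
#'   truth, sequences), `nrdna` (reference, segments, truth, sequences).
#' @export
build_cohort <- function(profile = c("mini", "full"), seed = 1L,
                         igs_gap_len = 0L) {
  config <- cohort_config(profile, seed, igs_gap_len)
  ref <- build_reference(config)
  ts <- plant_variants(ref, config)
  nr_ref <- build_nrdna_reference(config)
  nr_ts <- plant_nrdna_variants(nr_ref, config)
  structure(list(config = config,
                 cp = list(reference = ref, truth = ts$variants,
                           sequences = ts$sequences),
                 nrdna = list(reference = nr_ref, truth = nr_ts$variants,
                              sequences = nr_ts$sequences)),
            class = "synthetic_cohort")
}

#' Write cohort fixtures to disk
#'
#' Emits reference and haplotype FASTA, annotation TSV (1-based inclusive),
#' truth table TSV, a JSON sidecar describing tandem-repeat loci, and paired
#' FASTQ for one accession if requested.
#'
#' @param cohort A [build_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param reads_for Accession name to simulate reads for (NULL = none).
#' @param depth Coverage for the simulated reads.
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir, reads_for = NULL, depth = 30) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "reference.fa")
  write_fasta(list(reference = cohort$cp$reference$sequence), p)
  paths <- c(paths, p)
  p <- file.path(dir, "haplotypes.fa")
  write_fasta(cohort$cp$sequences, p); paths <- c(paths, p)
  p <- file.path(dir, "annotation.tsv")
  utils::write.table(cohort$cp$reference$annotation, p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "truth_cp.tsv")
  utils::write.table(cohort$cp$truth, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "nrdna.fa")
  write_fasta(cohort$nrdna$sequences, p); paths <- c(paths, p)
  tr <- cohort$cp$reference$layout$loci
  tr <- tr[vapply(tr, function(x) x$kind == "tr_cnv", logical(1))]
  p <- file.path(dir, "tr_loci.json")
  jsonlite::write_json(
    lapply(tr, function(x) x[c("pos", "unit_length", "ref_copies", "alt_copies")]),
    p, auto_unbox = TRUE)
  paths <- c(paths, p)
  if (!is.null(reads_for)) {
    rs <- simulate_reads(cohort$cp$sequences[[reads_for]], depth,
                         seed = cohort$config$seed)
    p1 <- file.path(dir, paste0(reads_for, "_R1.fastq"))
    p2 <- file.path(dir, paste0(reads_for, "_R2.fastq"))
    write_fastq(rs$read1, paste0(rs$id, "/1"), p1)
    write_fastq(rs$read2, paste0(rs$id, "/2"), p2)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}
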