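test_that("alignment of identical and single-SNP sequences behaves exactly", {
  co <- mini_cohort()
  ref <- co$cp$reference$sequence
  al <- align_pair(ref, ref)
  expect_equal(nrow(call_variants(al)), 0L)

  one <- ref
  substr(one, 9999L, 9999L) <- if (substr(ref, 9999, 9999) == "A") "G" else "A"
  v <- call_variants(align_pair(ref, one))
  expect_equal(nrow(v), 1L)
  expect_identical(v$type, "SNP")
  expect_equal(v$pos, 9999L)

  expect_error(align_pair(ref, random_dna(30000)), "diverged")
})

test_that("the recovered cohort table equals the planted truth set", {
  co <- mini_cohort()
  tab <- cp_table()
  truth <- co$cp$truth
  expect_equal(nrow(tab), nrow(truth))
  expect_equal(tab$pos, truth$pos)
  expect_identical(tab$type, truth$type)
  expect_identical(tab$ref, truth$ref)
  expect_identical(tab$alt, truth$alt)
  for (i in seq_len(nrow(tab)))
    expect_setequal(strsplit(tab$carriers[i], ",")[[1]],
                    strsplit(truth$carriers[i], ",")[[1]])
  expect_equal(tab$ir_mirror, truth$ir_mirror)
  ## notation carries the repeat-context allele naming
  expect_true(all(c("(C)8>(C)9", "(G)11>(G)10", "57x3>57x4", "13x1>13x2",
                    "7x3>7x2") %in% tab$notation))
})

test_that("truth-set recovery holds across many generator seeds", {
  for (sd in c(3L, 11L, 27L, 55L, 91L)) {
    co <- build_cohort("mini", seed = sd)
    tab <- survey_cohort(co$cp$reference$sequence, co$cp$sequences,
                         layout = co$cp$reference$layout)
    expect_equal(tab$pos, co$cp$truth$pos, info = paste("seed", sd))
    expect_identical(tab$ref, co$cp$truth$ref, info = paste("seed", sd))
    expect_identical(tab$alt, co$cp$truth$alt, info = paste("seed", sd))
  }
})

test_that("InDel calls are left-aligned regardless of gap placement phase", {
  co <- mini_cohort()
  ref <- co$cp$reference$sequence
  lay <- co$cp$reference$layout
  lc <- lay$loci$tr7_rpl32_trnUAG
  arr <- lc$pos
  ## delete one 7-mer unit at each of the three phases; all must normalize
  ## to the same anchored variant
  calls <- lapply(0:2, function(k) {
    s <- paste0(substr(ref, 1, arr + k * 7L - 1L),
                substr(ref, arr + (k + 1L) * 7L, nchar(ref)))
    call_variants(align_pair(ref, s))
  })
  for (v in calls) {
    expect_equal(nrow(v), 1L)
    expect_equal(v$pos, arr - 1L)
    expect_identical(v$notation, "7x3>7x2")
  }
  ## homopolymer: inserting the base anywhere in the run normalizes the same
  hp <- lay$loci$hp_rps16_intron
  calls <- lapply(c(0L, 4L, 8L), function(k) {
    s <- paste0(substr(ref, 1, hp$pos + k - 1L), "C",
                substr(ref, hp$pos + k, nchar(ref)))
    call_variants(align_pair(ref, s))
  })
  for (v in calls) {
    expect_equal(v$pos, hp$pos - 1L)
    expect_identical(v$notation, "(C)8>(C)9")
  }
})

test_that("pairwise calling is symmetric for substitution sites", {
  co <- mini_cohort()
  a <- co$nrdna$sequences$ChP
  b <- co$nrdna$sequences$SP
  v_ab <- call_variants(align_pair(a, b))
  v_ba <- call_variants(align_pair(b, a))
  expect_equal(v_ab$pos, v_ba$pos)
  expect_identical(v_ab$ref, v_ba$alt)
  expect_identical(v_ab$alt, v_ba$ref)
})

test_that("effect classification is strand- and frame-aware", {
  co <- mini_cohort()
  ref <- co$cp$reference$sequence
  ann <- co$cp$reference$annotation
  tab <- cp_table()
  eff <- function(pos) classify_effect(tab[tab$pos == pos, ], ann, ref)
  lay <- co$cp$reference$layout

  e <- eff(lay$loci$snp_ccsA$pos)                    # plus strand, codon mid
  expect_identical(e$consequence, "non-synonymous")
  expect_identical(unname(e$aa_change[c("ref_aa", "alt_aa")]), c("Q", "R"))

  e <- eff(lay$loci$snp_rpoC2$pos)                   # minus strand, codon 1st
  expect_identical(unname(e$aa_change[c("ref_aa", "alt_aa")]), c("G", "S"))

  e <- eff(lay$loci$snp_ycf1$pos)                    # minus strand, codon mid
  expect_identical(unname(e$aa_change[c("ref_aa", "alt_aa")]), c("I", "N"))

  e <- eff(lay$loci$snp_rpoC1$pos)                   # third codon position
  expect_identical(e$consequence, "synonymous")

  e <- eff(lay$loci$snp_rps16_trnUUG$pos)
  expect_identical(e$consequence, "intergenic")
  expect_identical(e$region, "rps16-trnUUG")

  e <- eff(lay$loci$hp_rps16_intron$pos - 1L)
  expect_identical(e$consequence, "intronic")
  expect_identical(e$region, "rps16 intron")
})

test_that("cohort merging collapses identical genotypes and flags conflicts", {
  tab <- cp_table()
  jk_rows <- grepl("JK", tab$carriers)
  for (i in which(jk_rows)) {
    carr <- strsplit(tab$carriers[i], ",")[[1]]
    expect_true(all(c("Damaya", "Ermaya", "Gaolishen") %in% carr))
  }
  ## conflicting alleles within one accession at one site
  calls <- list(
    X = data.frame(type = "SNP", pos = 10L, ref = "A", alt = "G",
                   heterogeneous = FALSE, context = "snp", notation = "A>G"))
  calls$X <- rbind(calls$X, within(calls$X, alt <- "T"))
  expect_error(merge_cohort(calls), "conflicting alleles")
  ## empty input
  expect_equal(nrow(merge_cohort(list(A = cp_table()[0, 1:7]))), 0L)
})

test_that("heterogeneous consensus codes become heterogeneous SNP calls", {
  nr <- nrdna_table()
  het <- nr[nr$heterogeneous, ]
  expect_equal(nrow(het), 1L)
  expect_identical(het$alt, "S")
  expect_identical(het$notation, "C>G/C")
  expect_setequal(strsplit(het$carriers, ",")[[1]], c("GU", "GO"))
})

test_that("nrDNA units segment into the six canonical regions", {
  co <- mini_cohort()
  nr_ref <- co$nrdna$reference
  seg <- segment_nrdna(co$nrdna$sequences$GU, nr_ref$sequence,
                       nr_ref$segments)
  expect_identical(seg$segments$name,
                   c("18S", "ITS1", "5.8S", "ITS2", "26S", "IGS"))
  expect_true(all(diff(seg$segments$start) > 0))
  expect_equal(seg$segments$end[6], nchar(co$nrdna$sequences$GU))
  expect_equal(seg$heterogeneous_sites$position, 4165L)

  ## an N-run inside the IGS is tolerated and reported
  gapped <- co$nrdna$sequences$GU
  substr(gapped, 6000L, 6199L) <- strrep("N", 200L)
  seg2 <- segment_nrdna(gapped, nr_ref$sequence, nr_ref$segments)
  expect_equal(seg2$gaps$start, 6000L)
  expect_equal(seg2$gaps$end, 6199L)

  ## a unit missing its 26S cannot be segmented
  s26 <- nr_ref$segments[nr_ref$segments$name == "26S", ]
  broken <- paste0(substr(nr_ref$sequence, 1, s26$start - 1L),
                   substr(nr_ref$sequence, s26$end + 1L, nchar(nr_ref$sequence)))
  expect_error(segment_nrdna(broken, nr_ref$sequence, nr_ref$segments),
               "26S")
})

test_that("the IGS is visibly GC-rich in sliding windows", {
  co <- mini_cohort()
  nr <- co$nrdna$reference$sequence
  seg <- co$nrdna$reference$segments
  igs_gc <- gc_windows(substr(nr, seg$start[6], seg$end[6]))
  s18_gc <- gc_windows(substr(nr, seg$start[1], seg$end[1]))
  expect_gt(mean(igs_gc), mean(s18_gc) + 0.08)
  expect_equal(length(gc_windows(strrep("G", 150), 100)), 51L)
  expect_true(all(gc_windows(strrep("G", 150), 100) == 1))
})
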