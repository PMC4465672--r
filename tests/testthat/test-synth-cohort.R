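test_that("reference plastome has the quadripartite structure and is deterministic", {
  cfg <- cohort_config("mini", seed = 5)
  ref1 <- build_reference(cfg)
  ref2 <- build_reference(cfg)
  expect_identical(ref1$sequence, ref2$sequence)
  expect_equal(nchar(ref1$sequence), 30000L)
  r <- ref1$layout$regions
  ira <- substr(ref1$sequence, r$start[r$name == "IRa"], r$end[r$name == "IRa"])
  irb <- substr(ref1$sequence, r$start[r$name == "IRb"], r$end[r$name == "IRb"])
  expect_identical(ira, revcomp(irb))
  expect_true(all(ref1$annotation$start >= 1 &
                  ref1$annotation$end <= nchar(ref1$sequence)))

  full <- build_reference(cohort_config("full", seed = 5))
  expect_equal(nchar(full$sequence), 156000L)
  rf <- full$layout$regions
  expect_identical(substr(full$sequence, rf$start[2], rf$end[2]),
                   revcomp(substr(full$sequence, rf$start[4], rf$end[4])))
})

test_that("overlapping planted loci are rejected by name", {
  cfg <- cohort_config("mini", seed = 1)
  cfg$layout$loci$snp_rps16_trnUUG$pos <- cfg$layout$loci$tr13_rps16_trnUUG$pos
  expect_error(build_reference(cfg), "overlapping planted loci")
})

test_that("planted haplotypes carry exactly the declared alleles", {
  co <- mini_cohort()
  ref <- co$cp$reference$sequence
  lay <- co$cp$reference$layout
  seqs <- co$cp$sequences
  expect_identical(seqs$ChP, ref)              # reference accession
  expect_identical(seqs$JK, seqs$Damaya)       # Chinese duplicates of JK
  expect_identical(seqs$JK, seqs$Gaolishen)
  ## single SNP carrier: SH holds T at the intergenic site, everyone else G
  p <- lay$loci$snp_rps16_trnUUG$pos
  expect_identical(substr(seqs$SH, p, p), "T")
  for (acc in c("YP", "GU", "JK", "HS"))
    expect_identical(substr(seqs[[acc]], p, p), "G")
  ## length arithmetic: IR-resident events count twice
  expect_equal(nchar(seqs$SH) - nchar(ref), 13 + 59 - 2 - 7 + 2 * 57)
  expect_equal(nchar(seqs$YP) - nchar(ref), 2 * 57 - 7)
  expect_equal(nchar(seqs$GU) - nchar(ref), 1 + 2 * 57 - 7)
})

test_that("a reference-allele mismatch in the plan is a data error", {
  co <- mini_cohort()
  cfg <- co$config
  ref <- co$cp$reference
  p <- cfg$layout$loci$snp_ccsA$pos
  broken <- ref
  substr(broken$sequence, p, p) <- "T"   # plan says reference A
  expect_error(plant_variants(broken, cfg), "reference allele mismatch")
})

test_that("an empty variant plan reproduces the reference everywhere", {
  cfg <- cohort_config("mini", seed = 8)
  for (nm in names(cfg$layout$loci)) cfg$layout$loci[[nm]]$carriers <- character(0)
  ref <- build_reference(cfg)
  ts <- plant_variants(ref, cfg, accessions = c("ChP", "YP", "SH"))
  for (s in ts$sequences) expect_identical(s, ref$sequence)
  expect_equal(nrow(ts$variants), 0L)
})

test_that("contig fragmentation covers the circle with the demanded overlaps", {
  co <- mini_cohort()
  g <- co$cp$sequences$GU
  cs <- fragment_into_contigs(g, 4L, 250L, seed = 9)
  expect_equal(nrow(cs), 4L)
  ## reconstruct from truth intervals: ordered fragments minus overlaps
  ord <- order(cs$true_start)
  starts <- cs$true_start[ord]; lens <- cs$true_length[ord]
  spans <- diff(c(starts, starts[1] + nchar(g)))
  expect_true(all(lens - spans == 250L))
  expect_equal(sum(spans), nchar(g))
  ## terminal overlap is identical sequence
  a <- cs$sequence[ord][1]
  if (cs$orientation[ord][1] == "reverse") a <- revcomp(a)
  b <- cs$sequence[ord][2]
  if (cs$orientation[ord][2] == "reverse") b <- revcomp(b)
  expect_identical(substr(a, nchar(a) - 249L, nchar(a)), substr(b, 1L, 250L))

  expect_error(fragment_into_contigs(g, 3L, 100000L, seed = 1),
               "infeasible")
  expect_identical(fragment_into_contigs(g, 4L, 250L, seed = 9)$sequence,
                   cs$sequence)
})

test_that("read simulation conserves pair count, bases and determinism", {
  co <- mini_cohort()
  g <- co$cp$sequences$ChP
  rs <- simulate_reads(g, depth = 80, seed = 4)
  expect_equal(nrow(rs), ceiling(80 * nchar(g) / (2 * 101)))
  total_bases <- sum(nchar(rs$read1)) + sum(nchar(rs$read2))
  expect_lt(abs(total_bases - 80 * nchar(g)) / (80 * nchar(g)), 0.05)
  ## error-free reads are exact substrings of the circularized genome
  doubled <- paste0(g, g)
  drc <- revcomp(doubled)
  for (i in sample(nrow(rs), 25)) {
    expect_true(grepl(rs$read1[i], doubled, fixed = TRUE) ||
                grepl(rs$read1[i], drc, fixed = TRUE))
  }
  rs2 <- simulate_reads(g, depth = 80, seed = 4)
  expect_identical(rs$read1, rs2$read1)
  expect_identical(rs$read2, rs2$read2)
  ## substitution errors appear at roughly the configured rate
  rs_err <- simulate_reads(g, depth = 5, error_rate = 0.01, seed = 4)
  mm <- sum(vapply(seq_len(50), function(i) {
    sum(charToRaw(rs_err$read1[i]) !=
          charToRaw(substr(paste0(g, g), rs_err$start[i], rs_err$start[i] + 100L)))
  }, numeric(1)))
  expect_gt(mm, 0)
})

test_that("cohort fixtures round-trip through the plain-text writers", {
  co <- mini_cohort()
  dir <- file.path(tempdir(), "cohort_out")
  write_cohort(co, dir)
  ref_back <- cpkit:::read_fasta(file.path(dir, "reference.fa"))
  expect_identical(unname(ref_back[1]), co$cp$reference$sequence)
  hap <- cpkit:::read_fasta(file.path(dir, "haplotypes.fa"))
  expect_identical(unname(hap[["SH"]]), co$cp$sequences$SH)
  ann <- read.delim(file.path(dir, "annotation.tsv"))
  expect_identical(ann$name, co$cp$reference$annotation$name)
  tr <- jsonlite::read_json(file.path(dir, "tr_loci.json"))
  expect_equal(tr$tr7_rpl32_trnUAG$unit_length, 7L)
})
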