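test_that("digestion cuts at engineered sites and conserves length", {
  xba <- enzyme_catalog()[enzyme_catalog()$name == "XbaI", ]
  ## 212-base toy amplicon with one XbaI site placed so the cut falls
  ## 22 bases from the left end; AC background cannot form a second site
  bg <- function(n) substr(strrep("AC", ceiling(n / 2)), 1, n)
  amp <- paste0(bg(21), "TCTAGA", bg(212 - 21 - 6))
  fr <- digest(amp, xba)
  expect_equal(sort(fr), sort(c(22L, 190L)))

  no_site <- bg(300)
  expect_equal(digest(no_site, xba), nchar(no_site))

  two <- paste0(bg(50), "TCTAGA", bg(80), "TCTAGA", bg(40))
  fr2 <- digest(two, xba)
  expect_equal(length(fr2), 3L)
  expect_equal(sum(fr2), nchar(two))

  ## degenerate site: AvaII GGWCC cuts both GGACC and GGTCC
  ava <- enzyme_catalog()[enzyme_catalog()$name == "AvaII", ]
  expect_equal(length(digest(paste0(bg(30), "GGACC", bg(30), "GGTCC",
                                    bg(30)), ava)), 3L)
})

test_that("digestion length conservation holds on random amplicons", {
  set.seed(91)
  cat <- enzyme_catalog()
  for (i in seq_len(300)) {
    amp <- random_dna(sample(60:500, 1))
    enz <- cat[sample(nrow(cat), 1), ]
    fr <- digest(amp, enz)
    expect_equal(sum(fr), nchar(amp))
    expect_true(all(fr > 0))
  }
})

test_that("in-silico PCR honours orientation, size limits and circularity", {
  set.seed(52)
  core <- random_dna(600)
  fwd <- substr(core, 51, 72)
  rev <- revcomp(substr(core, 451, 472))
  pr <- insilico_pcr(core, fwd, rev)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$length, 422L)
  expect_identical(pr$sequence, substr(core, 51, 472))

  ## no binding site: empty result
  expect_equal(nrow(insilico_pcr(core, random_dna(22), rev)), 0L)

  ## divergent (tail-to-tail) orientation yields no product
  pr2 <- insilico_pcr(core, revcomp(fwd), rev)
  expect_equal(nrow(pr2[pr2$length < 500, ]), 0L)

  ## circular template: origin-spanning product
  circ <- paste0(substr(core, 301, 600), substr(core, 1, 300))
  pr3 <- insilico_pcr(circ, fwd, rev, circular = TRUE)
  expect_equal(pr3$length, 422L)
})

test_that("nearest-neighbor Tm behaves physically", {
  expect_gt(primer_tm("GCGCGCGCGCGCGCGCGCGC"), primer_tm("ATATATATATATATATATAT"))
  t20 <- primer_tm("ACGTTGCAACGGTCAGATCA")
  expect_gt(t20, 45); expect_lt(t20, 70)
  ## longer oligo of same composition melts higher
  expect_gt(primer_tm(strrep("ACGT", 7)), primer_tm(strrep("ACGT", 5)))
  ## more salt stabilizes
  expect_gt(primer_tm("ACGTTGCAACGGTCAGATCA", na_mM = 200),
            primer_tm("ACGTTGCAACGGTCAGATCA", na_mM = 50))
})

test_that("size markers resolve every planted InDel class exactly", {
  run <- full_run()
  mk <- run$results$markers
  diffs <- c(tr57_ycf1 = 57L, tr7_rpl32_trnUAG = 7L,
             tr13_rps16_trnUUG = 13L, ins59_trnUUC_trnGGU = 59L)
  for (nm in names(diffs)) {
    m <- mk[[nm]]
    expect_s3_class(m, "indel_marker")
    cls <- sort(unique(m$product_sizes))
    expect_equal(length(cls), 2L)
    expect_equal(diff(cls), unname(diffs[nm]), info = nm)
    expect_true(m$informative)
  }
  ## carriers of the 57-bp three-copy allele give the shorter product
  m57 <- mk$tr57_ycf1$product_sizes
  expect_true(all(m57[c("ChP", "HS")] == min(m57)))
  expect_true(all(m57[c("YP", "JK", "SH")] == max(m57)))
})

test_that("a locus with unusable flanks is a design failure", {
  co <- mini_cohort()
  ref <- co$cp$reference$sequence
  blanked <- paste0(strrep("N", 600), substr(ref, 601, nchar(ref)))
  expect_error(design_indel_marker(blanked, 300L, 320L,
                                   co$cp$sequences["ChP"], integer(0)),
               "design failure")
})

test_that("an engineered context yields an XbaI dCAPS cutting the declared allele", {
  ## toy context: reference allele A at the site's G-position complement;
  ## constructed so one primer mismatch completes TCTAGA over the reference
  set.seed(64)
  left <- random_dna(90)
  ## template: ...TCCAGA with SNP at the 'G' (ref G, alt T): one engineered
  ## change (C->T at -2) completes TCTAGA only when the template gives G
  ctx <- paste0(left, "TC", "C", "A", "G", "A", random_dna(104))
  snp_pos <- nchar(left) + 5L
  expect_identical(substr(ctx, snp_pos, snp_pos), "G")
  d <- design_dcaps(ctx, snp_pos, "G", "T")
  expect_s3_class(d, "dcaps_design")
  expect_identical(d$enzyme$name, "XbaI")
  expect_identical(d$cut_allele, "G")       # reference allele is cut
  expect_equal(length(d$fragment_lengths$ref), 2L)
  expect_equal(length(d$fragment_lengths$alt), 1L)

  ## no completable site anywhere: all-A/T context defeats every 6-cutter
  flat <- paste0(strrep("AT", 100), "ACGATC", strrep("TA", 100))
  res <- design_dcaps(flat, 201L, "A", "C")
  expect_s3_class(res, "no_design")
})

test_that("the search agrees with exhaustive enumeration of valid placements", {
  ## independent oracle: enumerate every (enzyme, strand, site offset)
  ## tuple on a toy context and test the dCAPS validity predicate directly
  set.seed(64)
  left <- random_dna(90)
  ctx <- paste0(left, "TCCAGA", random_dna(104))
  snp_pos <- nchar(left) + 5L
  alleles <- c(ref = "G", alt = "T")
  cat <- enzyme_catalog()
  feasible <- character(0)
  for (strand in c("+", "-")) {
    tmpl <- if (strand == "+") ctx else revcomp(ctx)
    p0 <- if (strand == "+") snp_pos else nchar(ctx) - snp_pos + 1L
    al <- if (strand == "+") alleles else
      vapply(alleles, revcomp, character(1))
    for (ei in seq_len(nrow(cat))) {
      site <- strsplit(cat$site[ei], "")[[1]]
      for (o in seq_along(site)) {
        w <- p0 - o + 1L
        if (w < 10L || w + length(site) - 1L > nchar(tmpl) - 10L) next
        for (wa in c("ref", "alt")) {
          sb <- al[[wa]]; ob <- al[[setdiff(c("ref", "alt"), wa)]]
          admit <- function(code, b) b %in% cpkit:::IUPAC_EXPAND[[code]]
          if (!admit(site[o], sb) || admit(site[o], ob)) next
          tpl <- strsplit(substr(tmpl, w, w + length(site) - 1L), "")[[1]]
          tpl[o] <- sb
          bad <- which(!mapply(admit, site, tpl))
          bad <- setdiff(bad, o)
          if (length(bad) == 1L && bad < o && (o - 1L) - bad <= 4L)
            feasible <- c(feasible, cat$name[ei])
        }
      }
    }
  }
  expect_true("XbaI" %in% feasible)
  d <- design_dcaps(ctx, snp_pos, "G", "T")
  expect_true(d$enzyme$name %in% feasible)
})

test_that("cohort dCAPS assays cut exactly the declared allele in every accession", {
  run <- full_run()
  co <- run$results$cohort
  lay <- co$cp$reference$layout
  designs <- run$results$markers[intersect(c("snp_rpoC1", "snp_rpoC2"),
                                           names(run$results$markers))]
  expect_gt(length(designs), 0L)
  for (nm in names(designs)) {
    d <- designs[[nm]]
    lc <- lay$loci[[nm]]
    carriers <- cpkit:::expand_carriers(lc$carriers, names(co$cp$sequences))
    for (acc in names(co$cp$sequences)) {
      tmpl <- if (d$strand == "+") co$cp$sequences[[acc]] else
        revcomp(co$cp$sequences[[acc]])
      pr <- insilico_pcr(tmpl, d$forward, d$reverse, max_product = 1500L,
                         engineered = list(primer = "forward",
                                           position = as.integer(d$engineered[["position"]])))
      expect_equal(nrow(pr), 1L, info = paste(nm, acc))
      fr <- digest(pr$sequence[1], d$enzyme)
      has_allele <- if (acc %in% carriers) lc$alt else lc$ref
      should_cut <- d$cut_allele == has_allele
      expect_equal(length(fr) > 1L, should_cut, info = paste(nm, acc))
      expect_equal(sum(fr), pr$length[1], info = paste(nm, acc))
    }
  }
})

test_that("the published primer panel ships as a well-formed fixture", {
  path <- system.file("extdata", "published_primers.tsv", package = "cpkit")
  expect_true(nzchar(path))
  pp <- read.delim(path, check.names = FALSE)
  expect_equal(nrow(pp), 6L)
  expect_setequal(pp$type, c("dCAPS", "InDel"))
  for (p in c(pp$forward, pp$reverse)) {
    expect_true(nchar(p) >= 18 && nchar(p) <= 30)
    expect_true(grepl("^[ACGT]+$", p))
    tm <- primer_tm(p)
    expect_gt(tm, 40); expect_lt(tm, 75)
  }
  ## the two dCAPS rows name the enzymes used downstream of these primers
  expect_setequal(pp$enzyme[pp$type == "dCAPS"], c("XbaI", "ScaI"))
  expect_true(all(c("XbaI", "ScaI") %in% enzyme_catalog()$name))
})

test_that("cp-only markers merge GU with CS; adding nrDNA markers splits them", {
  run <- full_run()
  cptab <- run$results$cp_table
  nrtab <- run$results$nrdna_table
  co <- run$results$cohort
  site <- function(p, g) list(type = "site", pos = p, genome = g)
  cp_sites <- lapply(cptab$pos, site, g = "cp")
  names(cp_sites) <- paste0("cp_", cptab$pos)
  am_cp <- build_auth_matrix(list(cp = cptab, nrdna = nrtab), cp_sites,
                             co$cp$sequences)
  gu_class <- Filter(function(g) "GU" %in% g, am_cp$partition)[[1]]
  expect_true("CS" %in% gu_class)

  nr_sites <- lapply(nrtab$pos, site, g = "nrdna")
  names(nr_sites) <- paste0("nr_", nrtab$pos)
  am_all <- build_auth_matrix(list(cp = cptab, nrdna = nrtab),
                              c(cp_sites, nr_sites), co$cp$sequences)
  gu_class2 <- Filter(function(g) "GU" %in% g, am_all$partition)[[1]]
  expect_false("CS" %in% gu_class2)

  ## single accession: trivial one-class partition
  am_one <- build_auth_matrix(list(cp = cptab, nrdna = nrtab), cp_sites,
                              co$cp$sequences["ChP"])
  expect_equal(length(am_one$partition), 1L)
})
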