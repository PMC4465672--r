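test_that("a planted 7-bp repeat is found with exact copy count", {
  set.seed(41)
  s <- paste0(random_dna(400), strrep("ACCTATT", 3), random_dna(400))
  tr <- find_tandem_repeats(s)
  hit <- tr[tr$unit == "ACCTATT", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$copies, 3)
  expect_equal(hit$unit_length, 7L)
  expect_equal(hit$start, 401L)
})

test_that("detection equals the brute-force oracle on short strings", {
  for (sd in c(2L, 9L, 17L, 33L, 58L)) {
    set.seed(sd)
    parts <- c(random_dna(500),
               strrep(random_dna(11), 3),
               random_dna(300),
               strrep(random_dna(6), 4),
               random_dna(500))
    s <- paste(parts, collapse = "")
    got <- find_tandem_repeats(s)
    want <- brute_force_trs(s)
    expect_equal(got$start, want$start, info = paste("seed", sd))
    expect_equal(got$unit_length, want$unit_length, info = paste("seed", sd))
    expect_equal(got$copies, want$copies, info = paste("seed", sd))
  }
})

test_that("fractional final copies are counted and reported to one decimal", {
  set.seed(7)
  unit <- random_dna(641)
  ## flanks explicitly break the period so the array is exactly 3.5 units
  lflank <- setdiff(c("A", "C", "G", "T"), substr(unit, 641, 641))[1]
  rflank <- setdiff(c("A", "C", "G", "T"), substr(unit, 322, 322))[1]
  igs <- paste0(random_dna(799), lflank, strrep(unit, 3),
                substr(unit, 1, 321), rflank, random_dna(799))
  tr <- find_tandem_repeats(igs, min_unit = 100L, max_unit = 700L)
  big <- tr[which.max(tr$span), ]
  expect_equal(big$unit_length, 641L)
  expect_equal(round(big$copies, 1), 3.5)
  expect_equal(big$span, 3 * 641 + 321)
})

test_that("the synthetic IGS sub-repeat reports 3.5 copies", {
  co <- mini_cohort()
  seg <- co$nrdna$reference$segments
  igs <- substr(co$nrdna$reference$sequence, seg$start[seg$name == "IGS"],
                seg$end[seg$name == "IGS"])
  tr <- find_tandem_repeats(igs, min_unit = 100L, max_unit = 700L)
  big <- tr[which.max(tr$span), ]
  expect_equal(big$unit_length, 641L)
  expect_equal(round(big$copies, 1), 3.5)
})

test_that("copy-number comparison recovers the planted per-accession counts", {
  co <- mini_cohort()
  ref <- co$cp$reference$sequence
  lay <- co$cp$reference$layout
  lc <- lay$loci$tr57_ycf1
  cv <- compare_tr_locus(ref, lc$pos, lc$pos + 57L * 3L - 1L, 57L,
                         co$cp$sequences)
  expect_true(cv$informative)
  expect_equal(unname(cv$copies_per_accession[c("ChP", "HS")]), c(3, 3))
  expect_equal(unname(cv$copies_per_accession[c("YP", "SH", "JK")]),
               c(4, 4, 4))

  lc13 <- lay$loci$tr13_rps16_trnUUG
  cv13 <- compare_tr_locus(ref, lc13$pos, lc13$pos + 12L, 13L,
                           co$cp$sequences)
  expect_equal(unname(cv13$copies_per_accession[["SH"]]), 2)
  expect_true(all(cv13$copies_per_accession[setdiff(names(cv13$copies_per_accession), "SH")] == 1))

  ## span difference = unit_length x copy difference, exactly
  lc7 <- lay$loci$tr7_rpl32_trnUAG
  cv7 <- compare_tr_locus(ref, lc7$pos, lc7$pos + 20L, 7L, co$cp$sequences)
  expect_equal(unname(cv7$copies_per_accession[["ChP"]] -
                        cv7$copies_per_accession[["YP"]]), 1)

  ## a locus with identical copies everywhere is uninformative
  same <- compare_tr_locus(ref, lc7$pos, lc7$pos + 20L, 7L,
                           co$cp$sequences["ChP"])
  expect_false(same$informative)

  ## missing flank is an anchor error naming the accession
  broken <- co$cp$sequences["YP"]
  broken$YP <- substr(broken$YP, 1, lc7$pos - 200L)
  expect_error(compare_tr_locus(ref, lc7$pos, lc7$pos + 20L, 7L, broken),
               "anchor error.*YP")
})

test_that("TR summaries count planted repeats on repeat-free backgrounds", {
  set.seed(19)
  bg <- random_dna(3000)
  while (nrow(find_tandem_repeats(bg)) > 0) bg <- random_dna(3000)
  pieces <- character(0)
  offs <- c(1, 600, 1200, 1800, 2400)
  s <- bg
  for (k in seq_along(offs)) {
    u <- random_dna(8L + k)
    arr <- strrep(u, 3)
    s <- paste0(substr(s, 1, offs[k] + 100 * k), arr,
                substr(s, offs[k] + 100 * k + 1, nchar(s)))
  }
  sm <- summarize_trs(s)
  expect_equal(sm$count, 5L)
  expect_equal(sum(sm$by_unit_length), 5L)
})

test_that("lowering the purity floor never removes a reported repeat", {
  for (sd in c(5L, 23L)) {
    set.seed(sd)
    s <- paste0(random_dna(600), strrep(random_dna(9), 4), random_dna(600))
    strict <- find_tandem_repeats(s, min_purity = 1)
    loose <- find_tandem_repeats(s, min_purity = 0.9)
    for (i in seq_len(nrow(strict))) {
      covered <- any(loose$start <= strict$start[i] &
                     loose$end >= strict$end[i] - 0L &
                     loose$unit_length == strict$unit_length[i])
      expect_true(covered)
    }
  }
})
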