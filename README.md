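# cpkit

Chloroplast genomes and 45S nuclear ribosomal DNA (nrDNA) are the standard
barcoding targets for plant cytoplasm and nucleus. Within a species they are
almost invariant, which is exactly what makes the *rare* intra-species
polymorphisms valuable: a handful of SNPs, homopolymer length variants and
tandem-repeat copy-number variants (TR-CNVs) can authenticate individual
cultivars — for example the elite Korean ginseng cultivars, where a
14-accession plastome comparison yields only 12 polymorphic sites (6 SNPs +
6 InDels) and an 11-accession 45S nrDNA comparison adds 5 more, 17
informative sites in all.

`cpkit` implements the full workflow that turns low-coverage shotgun
assemblies into such authentication panels:

* **finisher** — reference-anchored finishing of a circular plastome from
  3–5 overlapping de novo contigs: shared-*k*-mer anchoring (unique 21-mers,
  modal diagonal), ordering and merging of terminal overlaps (≥ 200 bp,
  ≤ 1% mismatch), pileup polishing from paired reads (corrections need depth
  ≥ 5 and majority ≥ 0.8; sites with a second allele ≥ 0.2 are reported as
  IUPAC heterogeneous, not corrected), and canonical rotation.
* **varsurvey** — anchored global pairwise alignment of each accession
  against the reference, VCF-style left-aligned variant normalization with
  repeat-context notation ("(C)8 → (C)9", "57×3 → 57×4"), cohort merging in
  which events mirrored across the two inverted repeats (IRa/IRb) collapse
  to a single dual-coordinate row, strand- and frame-aware effect
  classification, and 45S nrDNA unit segmentation
  (18S–ITS1–5.8S–ITS2–26S–IGS) with sliding-window GC content.
* **trscan** — tandem-repeat detection by period-shift equality runs
  (default unit window 6–57 bp; fractional final copies, e.g. 3.5 copies of
  a 641-bp IGS sub-repeat, found in a large-unit mode) and per-accession
  copy-number calls from flank-anchored spans.
* **markerlab** — assay design: InDel/TR-CNV size markers (Primer
  constraints: 18–27 nt, nearest-neighbour Tm 55–62 °C with SantaLucia
  unified parameters, GC 35–65%, self-complementarity ≤ 4), dCAPS designs in
  which exactly one engineered mismatch in the last five primer bases
  completes a restriction site over one SNP allele, in-silico PCR whose
  products carry the primer sequences, IUPAC-aware restriction digestion,
  and the accession × marker authentication matrix with its
  indistinguishability partition.
* **synthetic cohort** — a fully specified generator (quadripartite
  ~30 kb or ~156 kb plastome with IRa = revcomp(IRb), cultivar haplotypes
  differing only at the planted loci, an 11,091-bp nrDNA unit with GC-rich
  IGS, contig fragmentation, paired-end read simulation) so that every stage
  is testable against a known truth set.
* **pipeline** — `run_pipeline()` chains the stages with one root seed and
  writes a manifest of parameters and output checksums.

## Worked example

```r
library(cpkit)

co  <- build_cohort("mini", seed = 1)       # 14 cp + 11 nrDNA accessions
tab <- survey_cohort(co$cp$reference$sequence, co$cp$sequences,
                     co$cp$reference$annotation, co$cp$reference$layout)
tab[, c("pos", "type", "notation", "region", "consequence", "aa_change")]
#>      pos type      notation    region        consequence    aa_change
#> 1   1049 insertion (C)8>(C)9   rps16 intron  intronic       <NA>
#> 2   1380 SNP       G>T         rps16-trnUUG  intergenic     <NA>
#> 3   1429 insertion 13x1>13x2   rps16-trnUUG  intergenic     <NA>
#> 4   4100 SNP       C>T         rpoC2         non-synonymous G>S
#> 5   4290 SNP       T>G         rpoC1         synonymous     <NA>
#> 6   6320 insertion +59bp       trnUUC-trnGGU intergenic     <NA>
#> 7  20269 deletion  (G)11>(G)10 trnUGC intron intronic       <NA>
#> 8  21280 insertion 57x3>57x4   ycf1          coding_indel   <NA>
#> 9  22230 SNP       G>T         ndhF-rpl32    intergenic     <NA>
#> 10 22559 deletion  7x3>7x2     rpl32-trnUAG  intergenic     <NA>
#> 11 23001 SNP       A>G         ccsA          non-synonymous Q>R
#> 12 24440 SNP       A>T         ycf1          non-synonymous I>N
```

Twelve plastome rows: six SNPs (three non-synonymous: Gly→Ser in *rpoC2*,
Gln→Arg in *ccsA*, Ile→Asn in *ycf1*; the *rpoC1* SNP is synonymous) and six
InDels. Rows 7 and 8 sit inside the inverted repeat and carry a second
mirrored coordinate (`ir_mirror` 26320 and 25149).

A size marker for the 7-bp TR in the *rpl32–trnUAG* spacer:

```r
lc <- co$cp$reference$layout$loci$tr7_rpl32_trnUAG
m  <- design_indel_marker(co$cp$reference$sequence, lc$pos, lc$pos + 20L,
                          co$cp$sequences, setdiff(tab$pos, lc$pos - 1L))
sort(unique(m$product_sizes))
#> [1] 89 96
```

The two product classes differ by exactly one 7-bp unit: the three-copy
reference class (ChP) gives 96 bp, everyone else 89 bp. A dCAPS assay for
the *rpoC1* SNP:

```r
d <- design_dcaps(co$cp$reference$sequence,
                  co$cp$reference$layout$loci$snp_rpoC1$pos, "T", "G")
d$enzyme$name; d$cut_allele
#> [1] "XbaI"
#> [1] "G"
d$fragment_lengths
#> $ref            # allele T: amplicon uncut
#> [1] 135
#> $alt            # allele G: XbaI site completed by the engineered primer
#> [1]  15 120
```

`build_auth_matrix()` then genotypes every accession for the panel; on the
full synthetic cohort the partition isolates seven cultivars and leaves one
four-way class (Yunpoong, Sunun, Sunone, Jakyung — plus the three Chinese
collections that genotype identically to Jakyung) that no cp/nrDNA marker
can separate.

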