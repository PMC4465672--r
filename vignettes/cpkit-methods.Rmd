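---
title: "Methods: plastome finishing, intra-species polymorphism survey and marker design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plastome finishing, intra-species polymorphism survey and marker design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cpkit` works at the intra-species end of plant barcoding, where a cohort of
cultivars differs from a reference plastome at a dozen sites or fewer. That
regime justifies design choices throughout the package that would be wrong
for divergent genomes, and this vignette records them.

## The finishing model

A circular plastome is reconstructed from a few (typically 3–5) overlapping
de novo contigs by anchoring them to a conspecific reference.

**Anchoring.** Each contig is placed by shared 21-mers. Only k-mers that are
unique within one copy of the reference are allowed to vote for a placement
diagonal; the modal diagonal (computed modulo the genome length, so
origin-spanning contigs are handled) gives the placement, and votes within a
1 kb band of the mode absorb the diagonal shifts that cohort InDels cause.
Reported identity is k-mer containment against the full reference table, so
tandem-array k-mers — unusable for placement — still count toward identity.
Defaults `min_identity = 0.95` and `min_anchor_length = 500` are generous
for conspecific contigs (observed containment ≥ 0.97 even for the most
InDel-laden haplotype) while excluding random decoys, whose containment is
effectively zero. Orientation is chosen by vote count between the contig and
its reverse complement.

**Merging.** Contigs ordered by reference placement are joined at terminal
overlaps of at least 200 bp with at most 1% mismatches. The
placement-derived overlap register is tried first, then its ±600-base
neighbourhood (InDels between contig and anchoring reference shift the
expected register by their cumulative length), then all registers
longest-first. When the last contig overlaps the first, the draft closes
into a circle; join provenance (overlap length, mismatches) is recorded.
Uncovered reference intervals and unmergeable neighbours raise errors that
name the offending contigs — silent gaps would corrupt every downstream
coordinate.

**Polishing.** Reads are mapped by exact 31-mer seeds at three offsets per
read (both orientations). Seeds that are not unique in the draft are masked:
a read seeded inside a tandem array or an inverted-repeat copy cannot be
placed and must not vote. After seeding, the whole read is verified against
the draft (≤ 10% mismatches); this rejects reads that straddle
single-copy/IR junctions, which otherwise seed on one side and vote garbage
on the other. A position is corrected when depth ≥ 5 and the majority base
reaches 0.8; a second allele at ≥ 0.2 is reported as an IUPAC heterogeneous
call and left alone — this is how a G/C site in a multi-copy 26S rDNA
appears in read data and it must survive polishing. Polishing is a fixed
point: re-polishing a polished draft changes nothing.

**Canonicalization.** The circle is rotated (and if necessary
reverse-complemented) so position 1 matches reference position 1, first by
exact search for the reference's 200-base prefix, falling back to k-mer
anchoring when variants or the origin interfere. All cohort coordinates are
1-based, inclusive, on this canonical rotation, so positions in the cohort
table can be read against the reference annotation directly.

## The survey model

Because cohort members differ at ≤ 17 sites, multi-accession comparison is
implemented as N pairwise alignments against the reference, merged —
not a joint multiple alignment. Pairwise merging is exact in this regime and
each step is independently checkable.

**Alignment** chains shared unique 21-mers (collinear, strictly increasing)
and aligns only the short inter-anchor segments with affine-gap
Needleman–Wunsch (`Biostrings::pairwiseAlignment`; match 1, mismatch −2, gap
open 10, extend 0.5). Inputs sharing fewer than half their k-mers are
rejected as non-conspecific rather than aligned badly.

**Normalization.** Gap runs collapse into single InDel events, left-aligned
with a one-base anchor (the VCF convention). On top of that, events get
repeat-context notation: a homopolymer InDel is reported as full-run alleles
("(C)8>(C)9"), and an InDel whose payload has period *d* with at least one
adjacent reference copy of the unit becomes copy-number notation
("57x3>57x4"). A subject base that is an IUPAC ambiguity code containing the
reference base becomes a heterogeneous SNP ("C>G/C"); consensus-only cohorts
can therefore carry heterogeneity only where the upstream consensus encodes
it, which is the only honest reading of consensus input.

**Inverted-repeat duality.** A variant inside IRa exists, reverse
complemented, in IRb. The merger collapses two rows into one
dual-coordinate row when they have the same type and carriers, payloads of
equal length and period (up to reverse complement), and mirrored coordinates
within the span of the repeat context. The span allowance matters: a
left-aligned event sits at the *left* edge of its array in both copies, and
mirroring maps the left edge of one array to the *right* edge of the other,
so mirrored anchors differ by up to the array length.

**Effects.** SNPs in CDS are translated in both alleles with strand-aware
codon extraction (intron-containing genes use spliced coordinates);
precedence is intron → CDS → structural RNA → intergenic, checked at both
IR coordinates so that a variant annotated only in one IR copy is still
labelled by its gene. Intergenic variants are named by their flanking
feature pair ("rps16-trnUUG"). For InDels only the region label is
assigned.

## Tandem repeats

Detection is by period-shift equality: for unit length *u*, a run of
`s[i] == s[i+u]` of length *r* means a periodic stretch of span *r + u* and
*span/u* copies, so the final partial copy is counted fractionally and
exactly (display rounds to one decimal, matching how fractional copies are
conventionally quoted). The default unit window is 6–57 bp; the large-unit
IGS sub-repeat (641 bp at 3.5 copies) is found by raising `max_unit` rather
than widening the default, which keeps the plastome scan comparable across
runs. Overlapping candidates resolve by longer span, then smaller unit, then
leftmost — the smallest-period representative of a stretch always wins.
Default `min_purity = 1` (exact repeats); with a lower floor, exact cores
are greedily extended across isolated mismatches while the matching fraction
stays above the floor. Copy-number comparison across accessions measures the
span between 100-bp flank anchors (up to 3 substitutions tolerated per
flank, since another cohort SNP may fall inside a flank — this happens in
the fixture, where a SNP sits 50 bp from a TR locus, mirroring how close
together real hotspot polymorphisms can be).

## Marker design

**Melting temperature** uses nearest-neighbour thermodynamics with the
SantaLucia unified parameter set, entropy salt correction at 50 mM
monovalent salt and 500 nM total oligo. A stated, reproducible model was
preferred over wrapping an external designer.

**Size markers**: primers 18–27 nt, Tm 55–62 °C, GC 35–65%,
self-complementary run ≤ 4, 3′ end outside homopolymers, binding sites free
of other cohort variants (the amplicon interior may contain them — product
sizes are predicted per accession anyway). Predicted products come from
in-silico PCR with zero primer mismatches: cohort templates are
near-identical, and any tolerance would invent phantom products. The product
cutoff during design is 1,500 bp, which also discards the single-primer
artifact that a primer binding both IR copies would otherwise form; a locus
inside the IR amplifies identically from both copies, and products equal up
to reverse complement are collapsed into one band. A minimum between-class
size difference of 5 bp (configurable) enforces gel resolvability — the
two 1-bp homopolymer InDels in the fixture are deliberately not assayed by
size.

**dCAPS**: the search enumerates both strands, every catalog enzyme, and
every site offset over the SNP, and requires *exactly one* engineered
mismatch, located in the last five primer bases but never the 3′-terminal
base, that completes the recognition site for exactly one allele. Designs
are ranked by scarcity of natural sites near the SNP, then Tm closeness to
58 °C, and the first candidate that passes full in-silico validation — the
uncut allele's amplicon yields one fragment, the cut allele's exactly two,
separable by ≥ 10 bp — is returned. Two constraint relaxations apply only to
the dCAPS primer, and deliberately: palindromic recognition sites force
about half a site of self-complementarity into the primer (screen relaxed to
6), and the primer cannot move away from an AT-rich context (Tm 48–68 °C,
GC 20–80%, length up to 30 nt). When no placement validates, a `no_design`
result is returned; that is a legitimate outcome (an assay exists only "if
any restriction enzyme site is available"), and the packaged tests assert
that every design that *is* returned cuts exactly its declared allele in
every accession.

**Authentication** genotypes each accession for each marker (product sizes
for size markers, fragment patterns for dCAPS, direct site genotypes for
surveyed positions without a PCR assay) and partitions the cohort into
classes with identical genotype vectors. Two accessions are separable if and
only if they fall in different classes.

## The synthetic cohort

The generator is first-class, tested code: it is the package's study system,
not a fixture of convenience. It emulates:

* a circular quadripartite plastome (LSC–IRa–SSC–IRb, IRa exactly the
  reverse complement of IRb) in two profiles, 30 kb for desk-scale work and
  156 kb at conventional proportions; feature-internal geometry (codon
  phases, repeat arrays, locus spacing) is identical in both, only
  inter-feature filler scales, so all sequence-level behaviour is
  profile-invariant;
* 14 plastome accessions: a reference cultivar, ten further cultivars
  differing only at 12 planted loci (6 SNPs; homopolymer runs (C)8/(C)9 and
  (G)11/(G)10; TR-CNVs 57×3/4, 13×1/2, 7×3/2 with the 7-bp unit ACCTATT; one
  59-bp insertion), and three collections modelled as genotype-duplicates of
  one landrace — they are cohort members, not independent sequence sources;
* IR-resident loci planted in both IR copies (reverse complemented in the
  second), so the survey must prove it can collapse them to one
  dual-coordinate row;
* codon contexts engineered so the genic SNPs produce the intended effects:
  Gly→Ser on the minus strand at codon position 1, Gln→Arg on the plus
  strand at position 2, Ile→Asn on the minus strand at position 2, and one
  strictly synonymous third-position change. One SNP context additionally
  admits an XbaI dCAPS with a single engineered mismatch, and another
  contains a natural ScaI site completed by the reference allele — the
  enzyme geometry available at a SNP is constrained by its codon, and the
  Gly/Ser codon in particular is incompatible with completing ScaI's AGTACT
  under the one-mismatch rule, so the second true dCAPS in the fixture uses
  a degenerate-site enzyme (GGWCC) instead;
* an 11,091-bp nrDNA unit (18S 1–1809, ITS1, 5.8S, ITS2, 26S, IGS from
  5801) with a GC-rich IGS (≈ 0.63 vs ≈ 0.48 elsewhere) carrying a 641-bp
  sub-repeat at exactly 3 + 321/641 copies (3.5 to one decimal), five
  planted SNPs across 11 accessions, one of them a G/C heterogeneous site
  written as IUPAC `S` in the affected consensi, and an optional N-run in
  the IGS emulating an unclosed assembly gap;
* contig fragmentation with configurable count and terminal overlap
  (adjacent fragments share ≥ 200 identical terminal bases; a random subset
  is reverse-complemented, order shuffled) and paired-end reads (300-bp
  insert, 101-base reads, substitution errors only) with the pair count
  `ceiling(depth · L / (2 · read_length))`.

What it does **not** emulate — and what green tests therefore do not show
about real data: sequencing quality profiles and indel errors, coverage
bias (the GC-rich IGS is exactly as covered as everything else),
heteroplasmy beyond the single planted heterogeneous site, structural
rearrangements, and real inter-species divergence. The generator's flank
rules (array boundaries break the repeat period; an insertion's last base
differs from its anchor) make the planted truth set the *unique* left-aligned
normalization, which is what lets the test suite demand byte-exact recovery.

## Reproducibility and problem sizes

All randomness flows from one root seed through named substreams
(`derive_seed(seed, stream)`, kept below 2^31). The default test and
acceptance runs use the 30 kb profile with 14 + 11 accessions, 4-contig
fragmentation, 30× polishing reads, and re-assemble a three-accession subset
end to end; the finishing round-trip property is exercised over 20
fragmentation seeds and the full survey over several generator seeds. These
sizes were chosen as the smallest at which every structural feature (IR
duality, origin wrap, junction reads, hotspot spacing) is still present.

## Known limitations

* The finisher starts from contigs; it does not assemble contigs from reads,
  and it cannot scaffold across true sequence gaps (an uncovered interval is
  an error, not an N-gap).
* IR placement relies on unique flanking k-mers; a contig lying entirely
  inside one IR copy cannot be placed and is excluded rather than guessed.
* The pairwise aligner is built for conspecific inputs; it refuses diverged
  pairs instead of degrading.
* Heterogeneous sites are detected from read evidence or IUPAC consensus
  codes only; a plain consensus cohort cannot create them.
* `primer_tm` models a two-state duplex with monovalent salt only (no Mg²⁺
  or dangling-end corrections); values are for ranking candidates, not for
  predicting instrument melting curves.
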