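## Low-level sequence helpers shared by all modules. Sequences are plain
## uppercase character scalars internally; Biostrings objects are used at the
## boundaries (file IO, IUPAC-aware pattern matching, banded alignment).

DNA_BASES_STRICT <- c("A", "C", "G", "T")

IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented correctly (e.g. R -> Y, S -> S).
#'
#' @param x Character scalar, DNA sequence.
#' @return Character scalar, the reverse complement.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  rawToChar(rev(charToRaw(comp)))
}

#' Random DNA sequence
#'
#' @param n Length in bases.
#' @param gc Target GC fraction (sampling probability, not an exact quota).
#' @return Character scalar of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES_STRICT, n, replace = TRUE, prob = p), collapse = "")
}

## substring on the circular extension of a sequence: positions beyond the
## length wrap to the start. `from` must be in [1, nchar(x)].
circ_substr <- function(x, from, len) {
  n <- nchar(x)
  stopifnot(from >= 1L, from <= n, len <= n)
  if (from + len - 1L <= n) return(substr(x, from, from + len - 1L))
  paste0(substr(x, from, n), substr(x, 1L, from + len - 1L - n))
}

## Rotate a circular sequence so that position `from` becomes position 1.
rotate_seq <- function(x, from) {
  n <- nchar(x)
  from <- ((from - 1L) %% n) + 1L
  if (from == 1L) return(x)
  paste0(substr(x, from, n), substr(x, 1L, from - 1L))
}

## All k-mers of a sequence as a character vector (position i -> kmer at i).
seq_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1:(n - k + 1L), k:n)
}

## Does IUPAC pattern letter `pat` admit concrete base `base`?
iupac_match1 <- function(pat, base) {
  base %in% IUPAC_EXPAND[[pat]]
}

## IUPAC code for a set of bases (sorted, deduplicated).
iupac_code <- function(bases) {
  bases <- sort(unique(bases))
  key <- paste(bases, collapse = "")
  codes <- c(A = "A", C = "C", G = "G", T = "T",
             AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
             ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  unname(codes[key])
}

## Genetic-code translation of a single codon (standard code).
translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[toupper(codon)]]
  if (is.null(aa)) NA_character_ else aa
}

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              `*` = "Ter")

## Derive a reproducible child seed from a root seed and a stream name.
## Keeps results < 2^31 so they remain valid R integers.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

## GC fraction in sliding windows (step 1). Returns numeric vector of
## length n - window + 1; used for nrDNA IGS reporting.
#' GC content in sliding windows
#'
#' @param x DNA sequence (character scalar).
#' @param window Window width in bases (default 100).
#' @return Numeric vector of per-window GC fractions (window start order).
#' @export
gc_windows <- function(x, window = 100L) {
  b <- charToRaw(toupper(x))
  isgc <- as.integer(b == charToRaw("G") | b == charToRaw("C"))
  n <- length(isgc)
  if (n < window) return(numeric(0))
  cs <- c(0L, cumsum(isgc))
  (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
}

## Write a named list of sequences as FASTA via Biostrings.
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

## Minimal FASTQ writer (constant qualities); reads are error-injected
## synthetic sequences so per-base quality modelling is out of scope.
write_fastq <- function(seqs, ids, path) {
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

read_fastq <- function(path) {
  lines <- readLines(path)
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  names(seqs) <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
  seqs
}
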