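# Small sequence helpers shared across modules. Reverse complement and the
# genetic code come from Biostrings; wrappers keep plain character strings as
# the internal currency (variant alleles are short).

revcomp <- function(x) {
  if (is.na(x) || !nzchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Translate an in-frame nucleotide string codon-by-codon; trailing partial
# codon is dropped. Returns 1-letter amino acids, "*" for stop.
translate_nt <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return("")
  codons <- substring(x, seq(1L, by = 3L, length.out = n), seq(3L, by = 3L, length.out = n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

AA3 <- c(Biostrings::AMINO_ACID_CODE, "*" = "Ter", "X" = "Xaa")

aa_1to3 <- function(x) {
  if (!nzchar(x)) return("")
  paste0(AA3[strsplit(x, "", fixed = TRUE)[[1]]], collapse = "")
}

AA1 <- stats::setNames(names(AA3), unname(AA3))

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substr with interbase (0-based half-open) coordinates
substr_ib <- function(seq, start, end) {
  if (end <= start) return("")
  substr(seq, start + 1L, end)
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- utf8ToInt(substr(a, 1L, n))
  bv <- utf8ToInt(substr(b, 1L, n))
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

common_suffix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- rev(utf8ToInt(a))[seq_len(n)]
  bv <- rev(utf8ToInt(b))[seq_len(n)]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}
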