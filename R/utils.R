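AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA_BASES <- c("A", "C", "G", "T")

#' Default codon table (one designated codon per amino acid)
#'
#' A commonly used human-preferred codon for each of the 20 amino acids.
#' Library construction assigns exactly one codon per substitution, so
#' a designated-codon map (rather than a full degenerate table) is the
#' natural representation.
#'
#' @return Named character vector: amino acid -> DNA codon.
#' @export
default_codon_table <- function() {
  c(A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
    G = "GGC", H = "CAC", I = "ATC", K = "AAG", L = "CTG",
    M = "ATG", N = "AAC", P = "CCC", Q = "CAG", R = "AGA",
    S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAC")
}

# Run `code` under a fixed RNG state when seed is non-NULL; otherwise as-is.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Translate DNA (multiple of 3) using the standard genetic code.
# no.init.codon: segments are internal, so a leading CTG/TTG is Leu, not Met.
translate_dna <- function(dna) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(dna),
                                     no.init.codon = TRUE))
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

# Count mismatches between each element of `chunks` (all same width) and
# `pattern` of that width. Byte-level, vectorised.
mismatch_counts <- function(chunks, pattern) {
  w <- nchar(pattern)
  n <- length(chunks)
  if (n == 0L) return(integer(0))
  stopifnot(all(nchar(chunks) == w))
  m <- matrix(charToRaw(paste(chunks, collapse = "")), nrow = w)
  as.integer(colSums(m != charToRaw(pattern)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
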