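# Shared sequence utilities. All sequences are plain upper-case character
# vectors; Biostrings is used at the IO boundary and for alignment.

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of DNA strings
#'
#' IUPAC degeneracy codes are complemented correctly.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert an IUPAC primer to a regular expression
#'
#' Each degenerate base becomes a character class, so a "perfect match to the
#' primer" means every position matches one of its allowed bases.
#'
#' @param primer single DNA string, possibly with IUPAC degeneracy codes.
#' @return regex string (unanchored).
#' @export
iupac_regex <- function(primer) {
  chars <- strsplit(toupper(primer), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "))
  paste0(vapply(chars, function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Translate nucleotide sequences
#'
#' Standard genetic code; stop codons are "*". Trailing bases that do not fill
#' a codon are ignored. Codons containing non-ACGT characters translate to "X".
#'
#' @param x character vector of nucleotide sequences.
#' @param frame 1-based frame offset (1, 2 or 3).
#' @return character vector of amino-acid sequences.
#' @export
translate_nt <- function(x, frame = 1L) {
  stopifnot(frame %in% 1:3)
  code <- Biostrings::GENETIC_CODE
  vapply(toupper(x), function(s) {
    s <- substr(s, frame, nchar(s))
    n_codon <- nchar(s) %/% 3L
    if (n_codon == 0L) return("")
    starts <- seq(1L, by = 3L, length.out = n_codon)
    codons <- substring(s, starts, starts + 2L)
    aa <- code[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Test for an internal stop codon
#'
#' @param x nucleotide sequences.
#' @param frame reading frame (1-3).
#' @return logical: TRUE if the translation contains "*" before the final codon.
#' @export
has_internal_stop <- function(x, frame = 1L) {
  aa <- translate_nt(x, frame)
  vapply(aa, function(a) {
    if (nchar(a) <= 1L) return(FALSE)
    grepl("\\*", substr(a, 1L, nchar(a) - 1L))
  }, logical(1), USE.NAMES = FALSE)
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

# split equal-length sequences into a character matrix (sequences x sites)
seq_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences must be of equal length (got lengths ",
         paste(unique(lens), collapse = ", "), ")")
  m <- matrix(toupper(unlist(strsplit(seqs, ""))),
              nrow = length(seqs), ncol = lens[1], byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
  }, character(1))
}

# Derive a stage-specific seed from a master seed so pipeline stages are
# individually reproducible. Kept strictly below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
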