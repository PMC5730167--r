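#' @importFrom Biostrings DNAString DNAStringSet AAStringSet readDNAStringSet
#'   readAAStringSet writeXStringSet pairwiseAlignment pattern subject nmatch
#'   GENETIC_CODE
#' @importFrom stats rbinom rpois runif sd setNames
#' @importFrom utils read.delim write.table combn head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of a DNA string
#'
#' @param x a single DNA sequence (character scalar, A/C/G/T/N and IUPAC codes)
#' @return the reverse complement as a character scalar
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# split a sequence string into a character vector of single residues
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

chars_seq <- function(x) paste(x, collapse = "")

# all 64 codons in lexicographic (A,C,G,T) order
all_codons <- function() {
  b <- DNA_BASES
  paste0(rep(b, each = 16), rep(rep(b, each = 4), times = 4), rep(b, times = 16))
}

.codon_table_env <- new.env(parent = emptyenv())

codon_aa <- function() {
  if (is.null(.codon_table_env$map)) {
    gc <- Biostrings::GENETIC_CODE
    names(gc) <- gsub("U", "T", names(gc))
    .codon_table_env$map <- gc
  }
  .codon_table_env$map
}

#' Translate a coding sequence
#'
#' Standard-code translation; stop codons translate to "*".
#'
#' @param cds coding DNA sequence, length divisible by 3
#' @return amino-acid string
#' @export
translate_cds <- function(cds) {
  stopifnot(nchar(cds) %% 3 == 0)
  if (nchar(cds) == 0L) return("")
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  aa <- codon_aa()[codons]
  if (anyNA(aa)) stop("non-ACGT codon in coding sequence: ",
                      codons[which(is.na(aa))[1L]])
  chars_seq(aa)
}

# codon indices of stop codons before the final codon
internal_stop_positions <- function(cds) {
  aa <- seq_chars(translate_cds(cds))
  which(aa == "*" & seq_along(aa) < length(aa))
}

has_internal_stop <- function(cds) length(internal_stop_positions(cds)) > 0L

random_dna <- function(n) chars_seq(sample(DNA_BASES, n, replace = TRUE))

# random CDS of n_codons sense codons (no stops anywhere)
random_cds <- function(n_codons) {
  sense <- setdiff(all_codons(), STOP_CODONS)
  chars_seq(sample(sense, n_codons, replace = TRUE))
}

read_fasta_dna <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

read_fasta_aa <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

write_fasta <- function(seqs, path, aa = FALSE) {
  set <- if (aa) Biostrings::AAStringSet(seqs) else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
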