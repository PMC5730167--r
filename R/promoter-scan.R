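# Local promoter cis-element survey: IUPAC pattern scanning over upstream
# sequences and a species-by-element presence/count matrix.

IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# base classes of an IUPAC pattern; errors on non-IUPAC characters
iupac_classes <- function(pattern) {
  ch <- seq_chars(toupper(pattern))
  bad <- setdiff(ch, names(IUPAC_DNA))
  if (length(bad))
    stop("non-IUPAC pattern character: ", paste(unique(bad), collapse = ", "))
  IUPAC_DNA[ch]
}

# bitmask encoding: A=1, C=2, G=4, T=8; sequence N = 0 (matches only the
# fully degenerate class N, mask 15)
.base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 0L)

iupac_masks <- function(pattern) {
  cls <- iupac_classes(pattern)
  vapply(cls, function(b) sum(.base_bits[b]), 0L)
}

scan_one_strand <- function(seq_bits, masks) {
  n <- length(seq_bits); w <- length(masks)
  if (w > n) return(integer(0))
  ok <- rep(TRUE, n - w + 1L)
  for (j in seq_len(w)) {
    b <- seq_bits[j:(j + n - w)]
    ok <- ok & (bitwAnd(b, masks[j]) != 0L | (b == 0L & masks[j] == 15L))
  }
  which(ok)
}

#' Scan a promoter sequence for IUPAC elements
#'
#' Every position where all pattern classes match is reported.  Minus-strand
#' hits are found on the reverse complement and reported in plus-strand
#' coordinates with strand "-".  An N in the sequence matches only the
#' fully degenerate class N.
#'
#' @param promoter DNA sequence (A/C/G/T/N)
#' @param elements data.frame with columns \code{name}, \code{pattern}
#'   (IUPAC codes only; validated at load)
#' @param strands "both" or "plus"
#' @return data.frame of hits: \code{name}, \code{start}, \code{end}
#'   (1-based, plus coordinates), \code{strand}, \code{match}
#' @export
promoter_scan <- function(promoter, elements, strands = c("both", "plus")) {
  strands <- match.arg(strands)
  elements <- as.data.frame(elements)
  masks_list <- lapply(elements$pattern, iupac_masks)   # validates patterns
  empty <- data.frame(name = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      match = character(0))
  n <- nchar(promoter)
  if (n == 0L) return(empty)
  s <- seq_chars(toupper(promoter))
  if (!all(s %in% names(.base_bits)))
    stop("promoter sequence must be A/C/G/T/N")
  bits <- unname(.base_bits[s])
  rc_bits <- NULL
  if (strands == "both") {
    rc <- seq_chars(revcomp(chars_seq(s)))
    rc_bits <- unname(.base_bits[rc])
  }
  hits <- list()
  for (i in seq_len(nrow(elements))) {
    masks <- masks_list[[i]]
    w <- length(masks)
    for (st in scan_one_strand(bits, masks)) {
      hits[[length(hits) + 1L]] <- data.frame(
        name = elements$name[i], start = st, end = st + w - 1L,
        strand = "+", match = chars_seq(s[st:(st + w - 1L)]))
    }
    if (!is.null(rc_bits)) {
      for (st in scan_one_strand(rc_bits, masks)) {
        plus_start <- n - (st + w - 1L) + 1L
        hits[[length(hits) + 1L]] <- data.frame(
          name = elements$name[i], start = plus_start,
          end = plus_start + w - 1L, strand = "-",
          match = chars_seq(s[plus_start:(plus_start + w - 1L)]))
      }
    }
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$name, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Species-by-element hit count matrix
#'
#' @param promoters named character vector (or list) of promoter sequences
#' @param elements element dictionary (name, pattern)
#' @param strands "both" or "plus"
#' @return integer matrix species x element of hit counts; the per-hit
#'   tables are attached as the \code{hits} attribute
#' @export
presence_matrix <- function(promoters, elements, strands = "both") {
  if (length(promoters) == 0L) stop("need at least one species")
  elements <- as.data.frame(elements)
  counts <- matrix(0L, length(promoters), nrow(elements),
                   dimnames = list(names(promoters), elements$name))
  all_hits <- list()
  for (sp in names(promoters)) {
    h <- promoter_scan(promoters[[sp]], elements, strands)
    all_hits[[sp]] <- h
    if (nrow(h)) {
      tab <- table(h$name)
      counts[sp, names(tab)] <- as.integer(tab)
    }
  }
  attr(counts, "hits") <- all_hits
  counts
}

#' Read a promoter element dictionary from TSV
#'
#' @param path TSV with columns \code{name}, \code{pattern}, \code{note}
#' @return the dictionary, with every pattern validated as IUPAC
#' @export
read_promoter_elements <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "pattern") %in% names(d)))
    stop("dictionary needs name and pattern columns")
  invisible(lapply(d$pattern, iupac_classes))  # validate at load time
  d
}

#' Shipped default promoter element dictionary
#'
#' Common consensus strings for the cis-elements of the SSIII promoter survey
#' (TATA-box, CAAT-box, G-box, CCGTCC-box, ARE, ERE, HSE, CAT-box); each
#' entry is a dictionary default to be verified against PlantCARE for any
#' new analysis.
#'
#' @return data.frame name/pattern/note
#' @export
default_promoter_elements <- function() {
  read_promoter_elements(system.file("extdata", "promoter_elements.tsv",
                                     package = "orthoarch", mustWork = TRUE))
}
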