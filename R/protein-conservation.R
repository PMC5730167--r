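# Consensus protein construction with group conservation scores, motif
# location, motif-architecture comparison and per-domain identity.

.blosum_env <- new.env(parent = emptyenv())

#' Shipped BLOSUM62 substitution matrix
#'
#' Read from the plain-text copy under \code{inst/extdata}; used to class
#' residue changes as conservative (positive score) or non-conservative.
#'
#' @return integer matrix with residue dimnames
#' @export
blosum62_matrix <- function() {
  if (is.null(.blosum_env$m)) {
    path <- system.file("extdata", "blosum62.tsv", package = "orthoarch",
                        mustWork = TRUE)
    m <- as.matrix(read.delim(path, row.names = 1L, check.names = FALSE))
    storage.mode(m) <- "integer"
    .blosum_env$m <- m
  }
  .blosum_env$m
}

msa_matrix <- function(msa) {
  w <- unique(nchar(msa))
  if (length(w) != 1L) stop("alignment sequences must have equal length")
  m <- do.call(rbind, strsplit(unname(msa), "", fixed = TRUE))
  rownames(m) <- names(msa)
  m
}

#' Build a consensus protein with monocot/dicot conservation scores
#'
#' Per column, the consensus is the most frequent non-gap residue; when the
#' maximum is shared by two or more residues, or all sequences are gapped,
#' the reference residue is used instead and the column is flagged
#' reference-imputed.  The monocot score (0-6 for six monocots) and dicot
#' score (0-2) count the group members whose residue equals the consensus.
#' Columns that exist only as insertions in some species are retained.
#'
#' @param msa named character vector of aligned protein sequences
#' @param reference_id name of the reference sequence (e.g. maize)
#' @param groups named character vector mapping each id to "monocot" or
#'   "dicot"
#' @return data.frame: \code{column}, \code{consensus}, \code{monocot_score},
#'   \code{dicot_score}, \code{imputed}; the consensus string is attached as
#'   the \code{consensus} attribute (gaps dropped)
#' @export
build_consensus <- function(msa, reference_id, groups) {
  if (!reference_id %in% names(msa)) stop("reference not present in alignment")
  if (!all(names(msa) %in% names(groups)))
    stop("every sequence needs a group label")
  gl <- groups[names(msa)]
  if (!all(gl %in% c("monocot", "dicot")))
    stop("unknown group label: ", paste(setdiff(gl, c("monocot", "dicot")),
                                        collapse = ", "))
  m <- msa_matrix(msa)
  ref_row <- which(names(msa) == reference_id)
  W <- ncol(m)
  consensus <- character(W); imputed <- logical(W)
  mono <- names(msa)[gl == "monocot"]; dico <- names(msa)[gl == "dicot"]
  mono_score <- integer(W); dicot_score <- integer(W)
  for (j in seq_len(W)) {
    col <- m[, j]
    res <- col[col != "-"]
    if (length(res) == 0L) {
      consensus[j] <- "-"; imputed[j] <- TRUE
    } else {
      tab <- table(res)
      top <- names(tab)[tab == max(tab)]
      if (length(top) > 1L) {
        consensus[j] <- m[ref_row, j]   # may be "-" when reference gapped
        imputed[j] <- TRUE
      } else consensus[j] <- top
    }
    mono_score[j] <- sum(m[mono, j] == consensus[j] & consensus[j] != "-")
    dicot_score[j] <- sum(m[dico, j] == consensus[j] & consensus[j] != "-")
  }
  out <- data.frame(column = seq_len(W), consensus = consensus,
                    monocot_score = mono_score, dicot_score = dicot_score,
                    imputed = imputed, stringsAsFactors = FALSE)
  attr(out, "consensus") <- paste(consensus[consensus != "-"], collapse = "")
  out
}

#' Locate motifs in a protein sequence
#'
#' Sliding-window match allowing up to \code{max_mismatches} residue
#' mismatches per motif ("X" in a pattern matches any residue).
#' Overlapping matches of the same motif are resolved to the best one
#' (fewest mismatches, then leftmost).
#'
#' @param protein protein sequence (character scalar)
#' @param motifs data.frame with columns \code{name}, \code{pattern} and
#'   optionally \code{max_mismatches} (default 0)
#' @return data.frame of hits: \code{name}, \code{start}, \code{end}
#'   (1-based inclusive), \code{matched}, \code{mismatches}
#' @export
locate_motifs <- function(protein, motifs) {
  motifs <- as.data.frame(motifs)
  if (is.null(motifs$max_mismatches)) motifs$max_mismatches <- 0L
  empty <- data.frame(name = character(0), start = integer(0),
                      end = integer(0), matched = character(0),
                      mismatches = integer(0))
  n <- nchar(protein)
  if (n == 0L || nrow(motifs) == 0L) return(empty)
  s <- seq_chars(protein)
  hits <- list()
  for (i in seq_len(nrow(motifs))) {
    pat <- seq_chars(motifs$pattern[i])
    w <- length(pat)
    if (w > n) next
    mm_allow <- motifs$max_mismatches[i]
    fixed <- pat != "X"
    cand <- list()
    for (st in seq_len(n - w + 1L)) {
      win <- s[st:(st + w - 1L)]
      mm <- sum(win[fixed] != pat[fixed])
      if (mm <= mm_allow)
        cand[[length(cand) + 1L]] <- data.frame(
          name = motifs$name[i], start = st, end = st + w - 1L,
          matched = chars_seq(win), mismatches = mm)
    }
    if (length(cand) == 0L) next
    cand <- do.call(rbind, cand)
    # resolve overlapping same-motif matches: fewest mismatches, then leftmost
    cand <- cand[order(cand$mismatches, cand$start), , drop = FALSE]
    kept <- cand[0L, ]
    for (k in seq_len(nrow(cand))) {
      ck <- cand[k, ]
      if (nrow(kept) == 0L ||
          all(ck$start > kept$end | ck$end < kept$start))
        kept <- rbind(kept, ck)
    }
    hits[[length(hits) + 1L]] <- kept
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif architecture: ordered hits and inter-motif distances
#'
#' @param hits data.frame of motif hits from one sequence (see
#'   \code{\link{locate_motifs}})
#' @return list of class \code{motif_architecture}: \code{hits} ordered by
#'   start and \code{distances} (residues strictly between consecutive
#'   hits, as annotated between conserved motifs)
#' @export
motif_architecture <- function(hits) {
  hits <- hits[order(hits$start), , drop = FALSE]
  n <- nrow(hits)
  if (n > 1L) {
    overlap <- which(hits$start[-1L] <= hits$end[-n])
    if (length(overlap))
      stop(sprintf("overlapping motif hits: %s [%d..%d] and %s [%d..%d]",
                   hits$name[overlap[1L]], hits$start[overlap[1L]],
                   hits$end[overlap[1L]], hits$name[overlap[1L] + 1L],
                   hits$start[overlap[1L] + 1L], hits$end[overlap[1L] + 1L]))
  }
  distances <- if (n > 1L) hits$start[-1L] - hits$end[-n] - 1L else integer(0)
  structure(list(hits = hits, distances = as.integer(distances)),
            class = "motif_architecture")
}

#' @export
print.motif_architecture <- function(x, ...) {
  cat("motif architecture:", nrow(x$hits), "hits\n")
  if (nrow(x$hits)) {
    lab <- paste0(x$hits$name, "[", x$hits$start, "..", x$hits$end, "]")
    cat(paste(lab, collapse = paste0(" -- ")), "\n")
    if (length(x$distances))
      cat("inter-motif distances (aa):", paste(x$distances, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare motif architectures against a reference
#'
#' Per motif: presence/absence in each species; per mismatched residue of a
#' present motif: conservative (substitution score > 0) or non-conservative;
#' per consecutive motif pair: difference of the inter-motif distance from
#' the reference.
#'
#' @param ref reference \code{\link{motif_architecture}}
#' @param others named list of architectures to compare
#' @param substitution_matrix scoring matrix (default shipped BLOSUM62)
#' @return list with \code{presence} (motif x species logical),
#'   \code{residue_changes} (data.frame species/motif/position/ref/alt/class)
#'   and \code{distance_delta} (species x gap matrix, other minus reference)
#' @export
compare_architectures <- function(ref, others,
                                  substitution_matrix = blosum62_matrix()) {
  ref_hits <- ref$hits
  motifs <- ref_hits$name
  presence <- matrix(FALSE, length(motifs), length(others),
                     dimnames = list(motifs, names(others)))
  changes <- list()
  deltas <- matrix(NA_integer_, length(others),
                   max(0L, length(ref$distances)),
                   dimnames = list(names(others), NULL))
  for (sp in names(others)) {
    o <- others[[sp]]
    presence[, sp] <- motifs %in% o$hits$name
    for (mi in seq_along(motifs)) {
      nm <- motifs[mi]
      oi <- match(nm, o$hits$name)
      if (is.na(oi)) next
      ra <- seq_chars(ref_hits$matched[mi])
      oa <- seq_chars(o$hits$matched[oi])
      if (length(ra) != length(oa)) next
      for (p in which(ra != oa)) {
        sc <- substitution_matrix[ra[p], oa[p]]
        changes[[length(changes) + 1L]] <- data.frame(
          species = sp, motif = nm, position = p,
          ref = ra[p], alt = oa[p],
          class = if (sc > 0) "conservative" else "non-conservative")
      }
    }
    if (length(ref$distances) && length(o$distances) == length(ref$distances) &&
        identical(o$hits$name, ref_hits$name))
      deltas[sp, ] <- o$distances - ref$distances
  }
  list(presence = presence,
       residue_changes = if (length(changes)) do.call(rbind, changes)
                         else data.frame(species = character(0),
                                         motif = character(0),
                                         position = integer(0),
                                         ref = character(0),
                                         alt = character(0),
                                         class = character(0)),
       distance_delta = deltas)
}

#' Default protein motif dictionary
#'
#' The catalytic and linker motifs of the SSIII protein (KVGGL, KTGGL,
#' ITRLT, FEPCGLT, AER, KAEMK); the eleven novel conserved motifs CM1-CM11
#' are figure-only and must be supplied by the user.
#'
#' @return data.frame name/pattern/max_mismatches/note
#' @export
default_protein_motifs <- function() {
  read.delim(system.file("extdata", "protein_motifs.tsv",
                         package = "orthoarch", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' Per-domain percent identity against a reference through an alignment
#'
#' Regions are given in ungapped reference coordinates, projected through
#' the alignment; identity is matches / region columns x 100 with gap
#' columns counted.
#'
#' @param msa named character vector of aligned protein sequences
#' @param regions named list of \code{c(start, end)} 1-based inclusive
#'   intervals in ungapped reference coordinates
#' @param reference_id reference sequence name
#' @return data.frame species x region of percent identities; regions fully
#'   deleted in a species score 0 and are listed in the \code{deleted}
#'   attribute
#' @export
domain_identity <- function(msa, regions, reference_id) {
  m <- msa_matrix(msa)
  if (!reference_id %in% rownames(m)) stop("reference not in alignment")
  ref <- m[reference_id, ]
  ref_len <- sum(ref != "-")
  colmap <- which(ref != "-")      # alignment column of each reference residue
  out <- matrix(NA_real_, nrow(m), length(regions),
                dimnames = list(rownames(m), names(regions)))
  deleted <- character(0)
  for (rg in names(regions)) {
    iv <- regions[[rg]]
    if (iv[1L] < 1L || iv[2L] > ref_len || iv[1L] > iv[2L])
      stop("region ", rg, " exceeds the ungapped reference length")
    cols <- colmap[iv[1L]]:colmap[iv[2L]]
    for (sp in rownames(m)) {
      other <- m[sp, cols]
      if (all(other == "-")) {
        out[sp, rg] <- 0
        deleted <- c(deleted, paste(sp, rg, sep = ":"))
      } else {
        out[sp, rg] <- 100 * sum(other == ref[cols] & other != "-") /
          length(cols)
      }
    }
  }
  res <- as.data.frame(out)
  attr(res, "deleted") <- deleted
  res
}
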