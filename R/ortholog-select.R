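# Three-criterion "true ortholog" selection over candidate hit tables:
# 1. highest query coverage x identity, 2. all reference motifs present,
# 3. comparative size and inter-motif distance equivalence.

#' Score and select ortholog candidates by the three-criterion rule
#'
#' Criterion 1 ranks candidates by coverage x identity (highest first; the
#' combining rule is a documented package choice, ties broken by identity
#' then candidate id ascending).  Criterion 2 requires every reference
#' motif present.  Criterion 3 requires the candidate length within
#' \code{length_tolerance} (relative) of the reference length and every
#' inter-motif distance within \code{distance_tolerance} residues of the
#' reference distances.  The selected ortholog is the top-ranked candidate
#' passing criteria 2 and 3.
#'
#' @param hits data.frame with columns \code{id}, \code{coverage} (0-1),
#'   \code{identity} (0-100), \code{length}; motif presence as logical
#'   columns \code{motif.<name>}; inter-motif distances as a list column
#'   \code{distances} or numeric columns \code{dist.<k>}
#' @param required_motifs character vector of motif names that must be
#'   present
#' @param reference_length reference protein length (residues)
#' @param reference_distances numeric vector of reference inter-motif
#'   distances (aa); NULL skips the distance part of criterion 3
#' @param length_tolerance relative length tolerance (default 0.25, spanning
#'   the accepted 1094-1688 aa ortholog range)
#' @param distance_tolerance inter-motif distance tolerance in aa
#' @return list of class \code{ortholog_report}: \code{ranked} data.frame
#'   with per-criterion results and failure reasons, and \code{selected}
#'   (id or NA)
#' @export
score_candidates <- function(hits, required_motifs = character(0),
                             reference_length, reference_distances = NULL,
                             length_tolerance = 0.25,
                             distance_tolerance = 15) {
  hits <- as.data.frame(hits)
  if (nrow(hits) == 0L) stop("empty candidate hit table")
  stopifnot(all(hits$coverage >= 0 & hits$coverage <= 1),
            all(hits$identity >= 0 & hits$identity <= 100))
  score <- hits$coverage * hits$identity
  ord <- order(-score, -hits$identity, hits$id)
  ranked <- hits[ord, , drop = FALSE]
  ranked$score <- score[ord]
  ranked$rank <- seq_len(nrow(ranked))

  motif_cols <- paste0("motif.", required_motifs)
  crit2 <- logical(nrow(ranked)); crit2_note <- character(nrow(ranked))
  for (k in seq_len(nrow(ranked))) {
    if (length(required_motifs) == 0L) { crit2[k] <- TRUE; next }
    if (!all(motif_cols %in% names(ranked))) {
      crit2[k] <- NA; crit2_note[k] <- "motif presence unevaluable"
      next
    }
    present <- unlist(ranked[k, motif_cols])
    if (anyNA(present)) {
      crit2[k] <- NA; crit2_note[k] <- "motif presence unevaluable"
    } else if (all(present)) crit2[k] <- TRUE
    else {
      crit2[k] <- FALSE
      crit2_note[k] <- paste("missing motif:",
        paste(required_motifs[!present], collapse = ", "))
    }
  }

  crit3 <- logical(nrow(ranked)); crit3_note <- character(nrow(ranked))
  for (k in seq_len(nrow(ranked))) {
    rel <- abs(ranked$length[k] - reference_length) / reference_length
    ok_len <- rel <= length_tolerance
    note <- if (!ok_len)
      sprintf("length %d deviates %.0f%% from reference %d (tolerance %.0f%%)",
              ranked$length[k], 100 * rel, as.integer(reference_length),
              100 * length_tolerance) else ""
    ok_dist <- TRUE
    if (!is.null(reference_distances)) {
      dd <- ranked$distances[[k]]
      if (is.null(dd) || length(dd) != length(reference_distances)) {
        ok_dist <- FALSE
        note <- paste(note, "inter-motif distances unavailable")
      } else {
        dev <- abs(dd - reference_distances)
        if (any(dev > distance_tolerance)) {
          ok_dist <- FALSE
          note <- paste(note, sprintf("inter-motif distance deviates by %d aa",
                                      max(dev)))
        }
      }
    }
    crit3[k] <- ok_len && ok_dist
    crit3_note[k] <- trimws(note)
  }

  ranked$criterion2 <- crit2
  ranked$criterion2_note <- crit2_note
  ranked$criterion3 <- crit3
  ranked$criterion3_note <- crit3_note
  eligible <- which(!is.na(crit2) & crit2 & crit3)
  selected <- if (length(eligible)) ranked$id[eligible[1L]] else NA_character_
  structure(list(ranked = ranked, selected = selected),
            class = "ortholog_report")
}

#' @export
print.ortholog_report <- function(x, ...) {
  cat("ortholog selection:",
      if (is.na(x$selected)) "no candidate passes all criteria"
      else paste("selected", x$selected), "\n")
  cols <- intersect(c("id", "rank", "score", "criterion2", "criterion3",
                      "criterion2_note", "criterion3_note"), names(x$ranked))
  print(x$ranked[, cols], row.names = FALSE)
  invisible(x)
}
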