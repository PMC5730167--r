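# Gene structure: splice-aware cDNA-to-genomic alignment, intron phase
# classification, indel cataloguing, and exon/intron length tables.
#
# Coordinates are 0-based half-open internally; all reports and GFF3 output
# are 1-based inclusive.

#' Construct a gene model
#'
#' @param species species identifier
#' @param genomic genomic sequence (character scalar)
#' @param exons integer matrix with columns \code{start}, \code{end}
#'   (0-based half-open), rows strictly increasing and non-overlapping
#' @param strand "+" or "-"
#' @param group "monocot", "dicot" or NA
#' @return a \code{gene_model} with the derived cDNA
#' @export
gene_model <- function(species, genomic, exons, strand = "+", group = NA) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  n <- nrow(exons)
  if (any(exons[, "end"] <= exons[, "start"]))
    stop("empty or inverted exon interval")
  if (n > 1L) {
    gaps <- exons[-1L, "start"] - exons[-n, "end"]
    if (any(gaps < 4L))
      stop("exons must be strictly increasing with introns of at least 4 bp")
  }
  if (exons[n, "end"] > nchar(genomic)) stop("exon beyond genomic sequence")
  cdna <- paste(substring(genomic, exons[, "start"] + 1L, exons[, "end"]),
                collapse = "")
  structure(list(species = species, genomic = genomic, exons = exons,
                 strand = strand, cdna = cdna, group = group),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", x$species,
      sprintf("(%s, %d exons, cDNA %d bp, span %d bp)\n",
              ifelse(is.na(x$group), "ungrouped", x$group), nrow(x$exons),
              nchar(x$cdna), x$exons[nrow(x$exons), "end"] - x$exons[1, "start"]))
  invisible(x)
}

exon_lengths <- function(model) model$exons[, "end"] - model$exons[, "start"]

intron_lengths_of <- function(model) {
  n <- nrow(model$exons)
  if (n < 2L) return(integer(0))
  model$exons[-1L, "start"] - model$exons[-n, "end"]
}

# longest common extension: number of initial positions where a and b agree
lce <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  d <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(d) == 0L) n else d[1L] - 1L
}

#' Infer exon/intron boundaries by splice-aware cDNA-to-genomic alignment
#'
#' Greedy left-to-right chaining of exact anchor matches: each exon is
#' extended as far as the cDNA and genomic agree (isolated mismatches are
#' crossed when the following \code{min_anchor} bases realign), then an
#' intron is opened at the first disagreement and closed at the next
#' occurrence of the upcoming cDNA anchor.  Because junction sequence can be
#' ambiguous (the same bases fit the end of one exon or the start of the
#' next), each boundary is shifted -- by up to an anchor length leftwards,
#' 3 bp rightwards -- to make the intron start with GT and end with AG
#' (then GC..AG), ties resolved leftmost.
#'
#' @param cdna spliced transcript sequence
#' @param genomic genomic sequence containing it
#' @param min_anchor minimum exact-match anchor opening an exon (bp)
#' @param max_mismatch_frac maximum tolerated fraction of mismatched cDNA
#'   bases
#' @param species,group passed through to the returned model
#' @return a \code{\link{gene_model}}
#' @export
spliced_align <- function(cdna, genomic, min_anchor = 12L,
                          max_mismatch_frac = 0.02,
                          species = "query", group = NA) {
  if (nchar(cdna) > nchar(genomic))
    stop("cDNA longer than genomic sequence")
  cd <- seq_chars(cdna); gn <- seq_chars(genomic)
  nc <- length(cd); ng <- length(gn)
  max_mm <- floor(max_mismatch_frac * nc)

  find_anchor <- function(cpos, from) {
    # leftmost genomic position >= from matching cd[cpos .. cpos+min_anchor-1]
    w <- min(min_anchor, nc - cpos + 1L)
    anchor <- chars_seq(cd[cpos:(cpos + w - 1L)])
    hit <- regexpr(anchor, chars_seq(gn[from:ng]), fixed = TRUE)
    if (hit == -1L) return(NA_integer_)
    from + as.integer(hit) - 1L
  }

  g0 <- find_anchor(1L, 1L)
  if (is.na(g0)) stop("cDNA start (first ", min_anchor,
                      " bp) not found in genomic sequence")
  exons <- NULL
  cpos <- 1L; gpos <- g0; ex_start <- g0; mm <- 0L
  repeat {
    # extend the current exon
    repeat {
      k <- lce(cd[cpos:nc], gn[gpos:ng])
      cpos <- cpos + k; gpos <- gpos + k
      if (cpos > nc) break
      # cross an isolated substitution if the next anchor realigns
      if (gpos < ng && mm < max_mm &&
          lce(cd[min(cpos + 1L, nc):nc], gn[min(gpos + 1L, ng):ng]) >=
            min(min_anchor, nc - cpos)) {
        mm <- mm + 1L; cpos <- cpos + 1L; gpos <- gpos + 1L
        if (cpos > nc) break
      } else break
    }
    if (cpos > nc) {                       # all cDNA placed
      exons <- rbind(exons, c(ex_start - 1L, gpos - 1L))
      break
    }
    # open an intron: find next exon's anchor downstream (intron >= 4 bp)
    acc <- find_anchor(cpos, gpos + 4L)
    if (is.na(acc)) {
      unplaced <- nc - cpos + 1L
      if (unplaced > (1 - 0.9) * nc)
        stop(sprintf("could not place %d of %d cDNA bases (from cDNA position %d)",
                     unplaced, nc, cpos))
      exons <- rbind(exons, c(ex_start - 1L, gpos - 1L))
      break
    }
    # junction refinement: shift the boundary by s (cDNA bases moved from the
    # donor side to the acceptor side if s>0, the reverse if s<0), valid only
    # where the shifted bases still match the cDNA on the other side.  The
    # exact-match extension can overshoot into the intron by the length of
    # the repeat shared by the intron start and the next exon start, so the
    # left scan covers a full anchor length.
    best <- NULL
    for (s in seq.int(-min_anchor, 3L)) {
      d_end <- gpos - 1L + s                 # last exon base (genomic, 1-based)
      a_start <- acc + s                     # next exon start (genomic, 1-based)
      if (d_end < ex_start || a_start - d_end - 1L < 4L) next
      c_end <- cpos - 1L + s                 # last cDNA base in donor exon
      if (c_end < 0L || c_end > nc) next
      ok <- TRUE
      if (s > 0L)       # bases cd[cpos .. cpos+s-1] must match after the donor
        ok <- lce(cd[cpos:(cpos + s - 1L)], gn[gpos:(gpos + s - 1L)]) == s
      else if (s < 0L)  # bases cd[c_end+1 .. cpos-1] must match before acceptor
        ok <- a_start >= 1L &&
          lce(cd[(c_end + 1L):(cpos - 1L)], gn[a_start:(a_start - s - 1L)]) == -s
      if (!ok) next
      don <- chars_seq(gn[(d_end + 1L):(d_end + 2L)])
      acp <- chars_seq(gn[(a_start - 2L):(a_start - 1L)])
      score <- if (don == "GT" && acp == "AG") 2L
               else if (don == "GC" && acp == "AG") 1L else 0L
      # s scanned left to right, so on ties the leftmost placement is kept
      if (is.null(best) || score > best$score) best <- list(s = s, score = score)
    }
    s <- if (is.null(best)) 0L else best$s
    exons <- rbind(exons, c(ex_start - 1L, gpos - 1L + s))
    cpos <- cpos + s
    gpos <- acc + s
    ex_start <- gpos
  }
  colnames(exons) <- c("start", "end")
  model <- gene_model(species, genomic, exons, strand = "+", group = group)
  # verify the recovered cDNA; mismatches beyond the tolerated fraction fail
  placed <- sum(exon_lengths(model))
  if (placed < 0.9 * nc)
    stop(sprintf("only %d of %d cDNA bases placed", placed, nc))
  model
}

#' Classify intron phases from exon CDS contributions
#'
#' Phase 0 marks an intron inserted between two codons, phase 1 after the
#' first nucleotide of a codon, phase 2 after the second; equivalently, the
#' phase of intron i is the cumulative CDS length upstream of it modulo 3.
#'
#' @param model a \code{\link{gene_model}} (or an integer vector of exon
#'   lengths)
#' @param cds_start_offset 0-based offset of the translation start within
#'   the cDNA (untranslated leading bases); spill-over beyond exon 1 is
#'   handled
#' @return integer vector of phases in \{0,1,2\}, one per intron
#' @export
classify_intron_phases <- function(model, cds_start_offset = 0L) {
  exlen <- if (inherits(model, "gene_model")) exon_lengths(model)
           else as.integer(model)
  n <- length(exlen)
  if (n < 2L) return(integer(0))
  cds_total <- sum(exlen) - cds_start_offset
  if (cds_total %% 3L != 0L)
    warning("CDS length from offset is not divisible by 3; phases reported anyway")
  cds_up <- pmax(cumsum(exlen)[-n] - cds_start_offset, 0L)
  as.integer(cds_up %% 3L)
}

#' Catalogue indels between a reference exon and an ortholog exon
#'
#' Global (Needleman-Wunsch) alignment with affine gap penalties; each
#' maximal gap run is one event.  Gaps in the ortholog are deletions
#' relative to the reference, gaps in the reference are insertions.  The
#' reported position is the 1-based reference coordinate of the first
#' deleted base (deletions), or of the base immediately left of the
#' insertion point (0 when inserting before the first base).
#'
#' @param ref_exon,orth_exon DNA sequences
#' @param gap_open,gap_extend gap penalties (positive numbers)
#' @return data.frame with columns exon-agnostic \code{position},
#'   \code{length}, \code{kind}; attribute \code{cumulative} holds total
#'   inserted/deleted bp
#' @export
catalog_indels <- function(ref_exon, orth_exon, gap_open = 10, gap_extend = 0.5) {
  stopifnot(nchar(ref_exon) > 0L, nchar(orth_exon) > 0L)
  if (ref_exon == orth_exon) {
    out <- data.frame(position = integer(0), length = integer(0),
                      kind = character(0))
    attr(out, "cumulative") <- c(insertion = 0L, deletion = 0L)
    return(out)
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref_exon), Biostrings::DNAString(orth_exon),
    type = "global", gapOpening = gap_open, gapExtension = gap_extend)
  ra <- seq_chars(as.character(Biostrings::pattern(al)))
  oa <- seq_chars(as.character(Biostrings::subject(al)))
  ref_pos <- cumsum(ra != "-")            # reference coordinate per column
  events <- list()
  run_start <- NA_integer_; run_kind <- NA_character_
  flush <- function(col_end) {
    len <- col_end - run_start + 1L
    pos <- if (run_kind == "deletion") ref_pos[run_start]
           else if (run_start == 1L) 0L else ref_pos[run_start - 1L]
    data.frame(position = as.integer(pos), length = len, kind = run_kind)
  }
  for (j in seq_along(ra)) {
    kind <- if (oa[j] == "-") "deletion" else if (ra[j] == "-") "insertion" else NA
    if (is.na(kind)) {
      if (!is.na(run_kind)) {
        events[[length(events) + 1L]] <- flush(j - 1L)
        run_kind <- NA_character_
      }
    } else if (is.na(run_kind)) {
      run_start <- j; run_kind <- kind
    } else if (kind != run_kind) {
      events[[length(events) + 1L]] <- flush(j - 1L)
      run_start <- j; run_kind <- kind
    }
  }
  if (!is.na(run_kind))
    events[[length(events) + 1L]] <- flush(length(ra))
  out <- if (length(events)) do.call(rbind, events)
         else data.frame(position = integer(0), length = integer(0),
                         kind = character(0))
  attr(out, "cumulative") <- c(
    insertion = sum(out$length[out$kind == "insertion"]),
    deletion = sum(out$length[out$kind == "deletion"]))
  out
}

#' Build a species-by-feature exon/intron length table
#'
#' @param models named list of \code{\link{gene_model}}s
#' @return data.frame with columns \code{species}, \code{group},
#'   \code{exon1..exonK}, \code{intron1..intron(K-1)}
#' @export
exon_intron_table <- function(models) {
  K <- nrow(models[[1L]]$exons)
  rows <- lapply(models, function(m) {
    if (nrow(m$exons) != K) stop("models disagree on exon count")
    c(exon_lengths(m), intron_lengths_of(m))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c(paste0("exon", seq_len(K)), paste0("intron", seq_len(K - 1L)))
  data.frame(species = names(models),
             group = vapply(models, function(m) as.character(m$group), ""),
             tab, row.names = NULL, stringsAsFactors = FALSE)
}

#' Read an exon/intron length table from TSV
#'
#' @param path TSV with \code{species}, \code{group}, exon/intron columns
#' @return the table as a data.frame
#' @export
read_exon_intron_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("species", "group")
  if (!all(need %in% names(tab))) stop("table must have species and group columns")
  feat <- setdiff(names(tab), need)
  if (any(!vapply(tab[feat], is.numeric, TRUE)))
    stop("feature columns must be numeric")
  if (any(unlist(tab[feat]) <= 0)) stop("all lengths must be positive")
  tab
}

#' Shipped exon/intron length table of the starch synthase III orthologs
#'
#' Eight species (six monocots, two dicots), 16 exons and 15 introns each,
#' lengths in bp.
#'
#' @return data.frame (see \code{\link{read_exon_intron_table}})
#' @export
ssiii_length_table <- function() {
  read_exon_intron_table(system.file("extdata", "ssiii_exon_intron_lengths.tsv",
                                     package = "orthoarch", mustWork = TRUE))
}

feature_columns <- function(tab) setdiff(names(tab), c("species", "group"))

#' Signed exon-length differences relative to a reference species
#'
#' Positive values are net deletions relative to the reference (the
#' reference exon is longer), negative values net insertions.
#'
#' @param table an exon/intron length table
#' @param ref_species reference species id
#' @param exon_index exon number
#' @return named numeric vector, reference length minus species length
#' @export
exon_length_delta <- function(table, ref_species, exon_index) {
  col <- paste0("exon", exon_index)
  if (!col %in% names(table)) stop("no such exon: ", exon_index)
  if (!ref_species %in% table$species) stop("unknown species: ", ref_species)
  ref <- table[[col]][table$species == ref_species]
  setNames(ref - table[[col]], table$species)
}

#' Summary statistics of an exon/intron length table
#'
#' Per-feature sample standard deviation (n-1 denominator) over the
#' non-excluded species, per-species exon and intron totals, per-group mean
#' totals truncated to integer bp, and per-feature min/max with the species
#' attaining them.
#'
#' @param table an exon/intron length table
#' @param exclude optional character vector of species excluded from the
#'   per-feature sd (e.g. a draft-assembly outlier)
#' @return list with \code{feature_sd}, \code{species_totals},
#'   \code{group_mean_totals}, \code{feature_range}
#' @export
summarize_lengths <- function(table, exclude = NULL) {
  feat <- feature_columns(table)
  keep <- !(table$species %in% exclude)
  feature_sd <- vapply(table[feat], function(x) {
    x <- x[keep]
    if (length(x) < 2L) NA_real_ else sd(x)
  }, 0)
  is_exon <- grepl("^exon", feat)
  exon_tot <- rowSums(table[feat[is_exon]])
  intron_tot <- rowSums(table[feat[!is_exon]])
  species_totals <- data.frame(species = table$species, group = table$group,
                               exon_total = exon_tot, intron_total = intron_tot,
                               gene_total = exon_tot + intron_tot)
  group_mean_totals <- do.call(rbind, lapply(split(species_totals,
                                                   species_totals$group),
    function(d) data.frame(group = d$group[1L],
                           exon_total = floor(mean(d$exon_total)),
                           intron_total = floor(mean(d$intron_total)))))
  rownames(group_mean_totals) <- NULL
  feature_range <- data.frame(
    feature = feat,
    min = vapply(table[feat], min, 0),
    min_species = table$species[vapply(table[feat], which.min, 0L)],
    max = vapply(table[feat], max, 0),
    max_species = table$species[vapply(table[feat], which.max, 0L)],
    row.names = NULL)
  list(feature_sd = feature_sd, species_totals = species_totals,
       group_mean_totals = group_mean_totals, feature_range = feature_range)
}

#' Percent identity of two sequences under global alignment
#'
#' Identity = matches / alignment columns x 100, gap columns counted.
#'
#' @param a,b sequences (DNA or protein, character scalars)
#' @param type "dna" or "protein"
#' @return percentage in [0, 100]
#' @export
percent_identity <- function(a, b, type = c("dna", "protein")) {
  type <- match.arg(type)
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  if (a == b) return(100)
  if (type == "dna") {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global")
  } else {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = blosum62_matrix())
  }
  pa <- as.character(Biostrings::pattern(al))
  sa <- as.character(Biostrings::subject(al))
  cols <- nchar(pa)
  matches <- sum(seq_chars(pa) == seq_chars(sa) & seq_chars(pa) != "-")
  100 * matches / cols
}
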