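# Synthetic ortholog-family generator.
#
# Emulates an eight-species starch-synthase-like ortholog family (six monocot,
# two dicot labels) with a known ancestral 16-exon/15-intron architecture,
# lineage substitutions at a controllable dN/dS, codon-multiple exon indels
# concentrated in a configurable set of exons (default exons 1 and 3),
# intron-length drift, canonical GT..AG splice sites, and promoters with
# planted cis-elements.  Every downstream stage of the pipeline can therefore
# be checked against exact ground truth without any sequence download.

# Reference exon/intron architecture: the maize row of the shipped
# exon/intron length table (16 exons summing to 5082 bp, 15 introns).
MAIZE_EXONS <- c(99L, 70L, 2901L, 217L, 276L, 182L, 115L, 111L, 104L, 173L,
                 136L, 186L, 135L, 114L, 127L, 136L)
MAIZE_INTRONS <- c(666L, 78L, 177L, 464L, 645L, 113L, 404L, 1466L, 408L,
                   133L, 399L, 125L, 99L, 103L, 111L)

MONOCOT_NAMES <- c("maize", "sorghum", "brachypodium", "rice", "barley", "wheat")
DICOT_NAMES <- c("soybean", "arabidopsis")

#' Configuration for a synthetic ortholog family
#'
#' Defines the ancestral gene architecture and the evolutionary parameters
#' under which each lineage diverges.  Defaults mirror the SSIII ortholog family:
#' six monocots and two dicots sharing a 16-exon gene whose exon lengths are
#' the maize reference row of the exon/intron table, with exon indels
#' targeted at exons 1 and 3.
#'
#' @param n_monocot,n_dicot number of species carrying each group label
#' @param exon_lengths ancestral exon lengths in bp (must sum to a multiple
#'   of 3: the gene is modelled translation-start to stop)
#' @param intron_lengths ancestral intron lengths in bp (one fewer than
#'   exons, each >= 4)
#' @param intron_indel_rate expected indel events per intron per tip lineage
#' @param exon_indel_rate expected codon-multiple indel events per target
#'   exon per tip lineage
#' @param target_exons_for_indels exon indices receiving exon indels
#' @param substitution_rate expected proposed substitutions per site per
#'   branch (each tip lineage = one clade stem branch + one tip branch)
#' @param target_dnds ratio of nonsynonymous to synonymous acceptance
#'   probabilities (>= 0); 0.391 is the family-wide mean pairwise Ka/Ks
#'   reported for the starch synthase III orthologs
#' @param promoter_length promoter length in bp, between 500 and 1000
#' @param planted_elements data.frame with columns \code{name},
#'   \code{position} (1-based start in the promoter) and optionally
#'   \code{strand} ("+" or "-"); the same elements are planted in every
#'   species' promoter
#' @param seed integer seed making the family fully reproducible
#' @return a \code{family_config} list, validated
#' @export
family_config <- function(n_monocot = 6L, n_dicot = 2L,
                          exon_lengths = MAIZE_EXONS,
                          intron_lengths = MAIZE_INTRONS,
                          intron_indel_rate = 1,
                          exon_indel_rate = 1,
                          target_exons_for_indels = c(1L, 3L),
                          substitution_rate = 0.05,
                          target_dnds = 0.391,
                          promoter_length = 800L,
                          planted_elements = NULL,
                          seed = 1L) {
  cfg <- list(n_monocot = as.integer(n_monocot), n_dicot = as.integer(n_dicot),
              exon_lengths = as.integer(exon_lengths),
              intron_lengths = as.integer(intron_lengths),
              intron_indel_rate = intron_indel_rate,
              exon_indel_rate = exon_indel_rate,
              target_exons_for_indels = as.integer(target_exons_for_indels),
              substitution_rate = substitution_rate,
              target_dnds = target_dnds,
              promoter_length = as.integer(promoter_length),
              planted_elements = planted_elements,
              seed = as.integer(seed))
  class(cfg) <- "family_config"
  validate_family_config(cfg)
  cfg
}

validate_family_config <- function(cfg) {
  with(cfg, {
    if (length(exon_lengths) != length(intron_lengths) + 1L)
      stop("exon count must equal intron count + 1")
    if (any(exon_lengths <= 0L) || any(intron_lengths < 4L))
      stop("all exon lengths must be positive and introns at least 4 bp")
    if (sum(exon_lengths) %% 3L != 0L)
      stop("total CDS length must be divisible by 3")
    if (promoter_length < 500L || promoter_length > 1000L)
      stop("promoter_length must lie in [500, 1000]")
    if (n_monocot < 1L || n_dicot < 0L) stop("need at least one monocot")
    if (substitution_rate < 0 || target_dnds < 0)
      stop("rates must be non-negative")
    if (any(target_exons_for_indels < 1L) ||
        any(target_exons_for_indels > length(exon_lengths)))
      stop("target exon index out of range")
  })
  invisible(cfg)
}

#' Apply substitutions to a coding sequence at a controlled dN/dS
#'
#' Proposes random single-nucleotide substitutions at the given per-site
#' rate, then accepts or rejects each so that the expected ratio of accepted
#' nonsynonymous to synonymous changes (per respective Nei-Gojobori site)
#' matches \code{target_dnds}: for a target at or below 1, synonymous
#' proposals are always accepted and nonsynonymous ones with probability
#' \code{target_dnds}; above 1 the roles flip.  Proposals that would create
#' a stop codon are always rejected; because stop-creating changes
#' nevertheless count as nonsynonymous mutational opportunities in the
#' Nei-Gojobori site tally, the nonsynonymous acceptance probability is
#' scaled up by the sequence's ratio of all nonsynonymous changes to its
#' stop-free nonsynonymous changes, so the realized rate per nonsynonymous
#' site still matches the target.
#'
#' @param cds coding sequence, length divisible by 3, no internal stops
#' @param substitution_rate per-site proposal probability
#' @param target_dnds acceptance ratio target (>= 0)
#' @param seed optional integer; when given, a local seed is set so the call
#'   is reproducible in isolation
#' @return list with \code{cds} (mutated sequence), \code{n_syn} and
#'   \code{n_nonsyn} accepted counts, and \code{n_proposed}
#' @export
mutate_coding <- function(cds, substitution_rate, target_dnds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(cds)
  if (L %% 3L != 0L) stop("coding sequence length must be divisible by 3")
  if (has_internal_stop(cds)) stop("coding sequence contains an internal stop codon")
  if (substitution_rate < 0 || target_dnds < 0) stop("rates must be non-negative")
  s <- seq_chars(cds)
  n_syn <- 0L; n_nonsyn <- 0L
  n_prop <- rbinom(1L, L, substitution_rate)
  if (n_prop == 0L)
    return(list(cds = cds, n_syn = 0L, n_nonsyn = 0L, n_proposed = 0L))
  # stop-change compensation: fraction of nonsynonymous single-nt changes
  # (the NG86 nonsynonymous opportunities) that would create a stop codon
  comp <- stop_compensation_factor(cds)
  p_nonsyn <- min(target_dnds * comp, 1)
  p_syn <- if (target_dnds * comp > 1) 1 / (target_dnds * comp) else 1
  pos <- sample.int(L, n_prop, replace = FALSE)
  aa_of <- codon_aa()
  for (i in pos) {
    old <- s[i]
    new <- sample(setdiff(DNA_BASES, old), 1L)
    ci <- (i - 1L) %/% 3L            # 0-based codon index
    cstart <- ci * 3L + 1L
    codon_old <- chars_seq(s[cstart:(cstart + 2L)])
    s2 <- s[cstart:(cstart + 2L)]
    s2[i - cstart + 1L] <- new
    codon_new <- chars_seq(s2)
    if (aa_of[[codon_new]] == "*") next      # never introduce a stop
    syn <- aa_of[[codon_new]] == aa_of[[codon_old]]
    p_acc <- if (syn) p_syn else p_nonsyn
    if (runif(1L) <= p_acc) {
      s[i] <- new
      if (syn) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
    }
  }
  list(cds = chars_seq(s), n_syn = n_syn, n_nonsyn = n_nonsyn,
       n_proposed = n_prop)
}

# ratio of all nonsynonymous single-nt changes (stop-creating included, as
# in the NG86 site tally) to the stop-free ones, over the whole sequence
stop_compensation_factor <- function(cds) {
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  aa <- codon_aa()
  if (is.null(.codon_table_env$stop_changes)) {
    sc <- ns <- integer(64)
    names(sc) <- names(ns) <- all_codons()
    for (cod in all_codons()) {
      if (aa[[cod]] == "*") { sc[cod] <- NA; ns[cod] <- NA; next }
      cc <- strsplit(cod, "")[[1L]]
      for (p in 1:3) for (b in setdiff(DNA_BASES, cc[p])) {
        alt <- cc; alt[p] <- b
        alt <- paste(alt, collapse = "")
        if (aa[[alt]] == "*") { sc[cod] <- sc[cod] + 1L; ns[cod] <- ns[cod] + 1L }
        else if (aa[[alt]] != aa[[cod]]) ns[cod] <- ns[cod] + 1L
      }
    }
    .codon_table_env$stop_changes <- sc
    .codon_table_env$nonsyn_changes <- ns
  }
  tot_ns <- sum(.codon_table_env$nonsyn_changes[codons])
  tot_stop <- sum(.codon_table_env$stop_changes[codons])
  if (is.na(tot_ns) || tot_ns == tot_stop) return(1)
  tot_ns / (tot_ns - tot_stop)
}

# neutral substitutions on a non-coding sequence, preserving a protected
# prefix/suffix (used for intron GT..AG dinucleotides)
mutate_neutral <- function(x, rate, protect = 0L) {
  L <- nchar(x)
  if (L <= 2L * protect || rate <= 0) return(x)
  s <- seq_chars(x)
  free <- (protect + 1L):(L - protect)
  n <- rbinom(1L, length(free), rate)
  if (n == 0L) return(x)
  pos <- sample(free, n)
  s[pos] <- vapply(s[pos], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  chars_seq(s)
}

# one indel in an intron interior (never the first/last 2 bp); length drawn
# uniform on 1..60 bp, insertion or deletion with equal probability
intron_indel <- function(intron) {
  L <- nchar(intron)
  len <- sample.int(60L, 1L)
  del <- runif(1L) < 0.5 && L - len >= 4L
  if (del) {
    start <- sample(seq.int(3L, L - len - 1L), 1L)
    paste0(substr(intron, 1L, start - 1L), substr(intron, start + len, L))
  } else {
    at <- sample(seq.int(3L, L - 2L), 1L)   # insert before position `at`
    paste0(substr(intron, 1L, at - 1L), random_dna(len),
           substr(intron, at, L))
  }
}

# draw codon-multiple exon indel events for one lineage against the
# ancestral CDS coordinates; returns a data.frame of events (possibly empty)
draw_exon_indels <- function(exon_lengths, targets, rate) {
  ev <- list()
  bounds <- c(0L, cumsum(exon_lengths))   # CDS offsets of exon starts (0-based)
  used <- integer(0)                      # codon indices consumed by deletions
  n_codons_total <- sum(exon_lengths) %/% 3L
  for (e in targets) {
    n_ev <- rpois(1L, rate)
    if (n_ev == 0L) next
    for (k in seq_len(n_ev)) {
      n_codons <- sample.int(8L, 1L)
      len <- 3L * n_codons
      # codon c (1-based) occupies CDS positions 3(c-1)+1 .. 3c; require the
      # whole run inside exon e
      c_lo <- ceiling(bounds[e] / 3) + 1L
      c_hi <- floor(bounds[e + 1L] / 3) - n_codons + 1L
      if (c_hi < c_lo) next
      cand <- setdiff(seq.int(c_lo, c_hi), unlist(lapply(used, function(u)
        seq.int(u - n_codons + 1L, u + n_codons - 1L))))
      if (length(cand) == 0L) next
      c0 <- if (length(cand) == 1L) cand else sample(cand, 1L)
      kind <- if (runif(1L) < 0.5) "deletion" else "insertion"
      if (kind == "deletion") used <- c(used, seq.int(c0, c0 + n_codons - 1L))
      ev[[length(ev) + 1L]] <- data.frame(
        exon = e,
        position = 3L * (c0 - 1L) + 1L - bounds[e],  # 1-based within ref exon
        codon_start = c0, n_codons = n_codons, length = len,
        kind = kind, stringsAsFactors = FALSE)
    }
  }
  if (length(ev) == 0L)
    return(data.frame(exon = integer(0), position = integer(0),
                      codon_start = integer(0), n_codons = integer(0),
                      length = integer(0), kind = character(0)))
  ev <- do.call(rbind, ev)
  ev[order(ev$codon_start), , drop = FALSE]
}

# apply drawn exon indel events to a CDS (ancestral coordinates), updating
# the per-exon lengths; events are applied right-to-left so recorded
# ancestral coordinates stay valid
apply_exon_indels <- function(cds, exon_lengths, events) {
  if (nrow(events) == 0L) return(list(cds = cds, exon_lengths = exon_lengths))
  s <- cds
  exlen <- exon_lengths
  for (i in rev(seq_len(nrow(events)))) {
    ev <- events[i, ]
    p <- 3L * (ev$codon_start - 1L) + 1L   # CDS position of codon start
    if (ev$kind == "deletion") {
      s <- paste0(substr(s, 1L, p - 1L), substr(s, p + ev$length, nchar(s)))
      exlen[ev$exon] <- exlen[ev$exon] - ev$length
    } else {
      ins <- random_cds(ev$n_codons)
      s <- paste0(substr(s, 1L, p - 1L), ins, substr(s, p, nchar(s)))
      exlen[ev$exon] <- exlen[ev$exon] + ev$length
    }
  }
  list(cds = s, exon_lengths = exlen)
}

#' Generate a synthetic ortholog family with full ground truth
#'
#' Builds an ancestral gene from the configured architecture, evolves one
#' clade stem per group (monocot, dicot) and one tip branch per species
#' (coding substitutions at the target dN/dS, neutral intron substitutions,
#' intron indels that never touch the 2 bp splice dinucleotides, and
#' codon-multiple exon indels in the target exons), reassembles each
#' species' genomic sequence, and attaches a promoter with planted elements.
#'
#' @param config a \code{\link{family_config}}
#' @param out_dir optional directory; when given, FASTA/GFF3/TSV truth files
#'   are written there (see \code{\link{write_family}})
#' @return a \code{family_truth} list: \code{models} (named list of
#'   \code{gene_model}s), \code{proteins}, \code{promoters},
#'   \code{planted_elements}, \code{indel_events} (per species),
#'   \code{true_dnds} (pairwise matrix), \code{tree} (ape \code{phylo} with
#'   realized branch lengths), \code{ancestor} (list with cds, introns),
#'   and \code{config}
#' @export
generate_family <- function(config, out_dir = NULL) {
  validate_family_config(config)
  set.seed(config$seed)
  exlen <- config$exon_lengths
  K <- length(exlen)

  anc_cds <- random_cds(sum(exlen) %/% 3L)
  anc_introns <- vapply(config$intron_lengths, function(L)
    paste0("GT", random_dna(L - 4L), "AG"), "")

  species <- c(
    if (config$n_monocot == 6L) MONOCOT_NAMES
    else paste0("monocot_", seq_len(config$n_monocot)),
    if (config$n_dicot == 2L) DICOT_NAMES
    else if (config$n_dicot > 0L) paste0("dicot_", seq_len(config$n_dicot)))
  groups <- c(rep("monocot", config$n_monocot), rep("dicot", config$n_dicot))

  # clade stems: substitutions only (keeps ancestral exon coordinates valid
  # for indel bookkeeping at the tips)
  stems <- list()
  for (g in unique(groups)) {
    m <- mutate_coding(anc_cds, config$substitution_rate, config$target_dnds)
    ii <- vapply(anc_introns, mutate_neutral, "",
                 rate = config$substitution_rate, protect = 2L)
    stems[[g]] <- list(cds = m$cds, introns = unname(ii),
                       n_syn = m$n_syn, n_nonsyn = m$n_nonsyn,
                       n_sub = m$n_syn + m$n_nonsyn)
  }

  dictionary <- default_promoter_elements()
  models <- list(); proteins <- character(0); promoters <- character(0)
  indel_events <- list(); tipsub <- list(); planted <- list()

  for (i in seq_along(species)) {
    sp <- species[i]; g <- groups[i]
    stem <- stems[[g]]
    ev <- draw_exon_indels(exlen, config$target_exons_for_indels,
                           config$exon_indel_rate)
    ap <- apply_exon_indels(stem$cds, exlen, ev)
    m <- mutate_coding(ap$cds, config$substitution_rate, config$target_dnds)
    introns <- stem$introns
    for (j in seq_along(introns)) {
      introns[j] <- mutate_neutral(introns[j], config$substitution_rate,
                                   protect = 2L)
      n_ind <- rpois(1L, config$intron_indel_rate)
      for (k in seq_len(n_ind)) introns[j] <- intron_indel(introns[j])
    }
    # reassemble genomic sequence from evolved exons and introns
    ex_seq <- substring(m$cds, c(0L, cumsum(ap$exon_lengths))[seq_len(K)] + 1L,
                        cumsum(ap$exon_lengths))
    genomic <- ex_seq[1L]
    for (j in seq_len(K - 1L))
      genomic <- paste0(genomic, introns[j], ex_seq[j + 1L])
    starts0 <- cumsum(c(0L, head(ap$exon_lengths, -1L) +
                            nchar(introns)))         # 0-based exon starts
    exons <- cbind(start = starts0, end = starts0 + ap$exon_lengths)
    models[[sp]] <- gene_model(sp, genomic, exons, strand = "+", group = g)
    proteins[sp] <- translate_cds(m$cds)
    prom <- plant_promoter(config$promoter_length, config$planted_elements,
                           dictionary)
    promoters[sp] <- prom
    planted[[sp]] <- attr(prom, "planted")
    indel_events[[sp]] <- ev[, c("exon", "position", "length", "kind")]
    tipsub[[sp]] <- list(n_syn = stem$n_syn + m$n_syn,
                         n_nonsyn = stem$n_nonsyn + m$n_nonsyn)
  }

  # pairwise "true" dN/dS from realized accepted counts on independent
  # lineage paths, normalised by ancestral NG86 site counts
  sites <- count_sites(anc_cds)
  n_sp <- length(species)
  true_dnds <- matrix(NA_real_, n_sp, n_sp, dimnames = list(species, species))
  for (a in seq_len(n_sp)) for (b in seq_len(n_sp)) if (a != b) {
    sd_ <- tipsub[[a]]$n_syn + tipsub[[b]]$n_syn
    nd_ <- tipsub[[a]]$n_nonsyn + tipsub[[b]]$n_nonsyn
    if (groups[a] == groups[b]) {       # shared stem cancels out of the path
      sd_ <- sd_ - 2L * stems[[groups[a]]]$n_syn
      nd_ <- nd_ - 2L * stems[[groups[a]]]$n_nonsyn
    }
    true_dnds[a, b] <- if (sd_ > 0L) (nd_ / sites["N"]) / (sd_ / sites["S"])
                       else NA_real_
  }

  L_cds <- nchar(anc_cds)
  tip_bl <- vapply(species, function(sp) {
    extra <- (tipsub[[sp]]$n_syn + tipsub[[sp]]$n_nonsyn -
                stems[[groups[match(sp, species)]]]$n_sub)
    extra / L_cds
  }, 0)
  stem_bl <- vapply(unique(groups), function(g) stems[[g]]$n_sub / L_cds, 0)
  nwk <- paste0("(",
    paste0("(", paste0(species[groups == "monocot"], ":",
                       format(tip_bl[groups == "monocot"], digits = 6),
                       collapse = ","), "):",
           format(stem_bl["monocot"], digits = 6)),
    if (any(groups == "dicot")) paste0(",(",
      paste0(species[groups == "dicot"], ":",
             format(tip_bl[groups == "dicot"], digits = 6), collapse = ","),
      "):", format(stem_bl["dicot"], digits = 6)) else "",
    ");")
  tree <- ape::read.tree(text = nwk)

  truth <- structure(list(
    models = models, proteins = proteins, promoters = promoters,
    planted_elements = planted, indel_events = indel_events,
    true_dnds = true_dnds, tree = tree,
    ancestor = list(cds = anc_cds, introns = anc_introns,
                    exon_lengths = exlen),
    species = species, groups = setNames(groups, species),
    config = config), class = "family_truth")
  if (!is.null(out_dir)) write_family(truth, out_dir)
  truth
}

#' Plant promoter elements into a random background sequence
#'
#' @param length promoter length in bp
#' @param elements data.frame with columns \code{name}, \code{position}
#'   (1-based start) and optional \code{strand}; NULL for background only
#' @param dictionary element dictionary as returned by
#'   \code{\link{read_promoter_elements}} (name, pattern, note)
#' @param seed optional local seed
#' @return the promoter sequence (character scalar) with a \code{planted}
#'   attribute (data.frame name/start/end/strand/instance)
#' @export
plant_promoter <- function(length, elements = NULL,
                           dictionary = default_promoter_elements(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- sample(DNA_BASES, length, replace = TRUE)
  if (is.null(elements) || NROW(elements) == 0L) {
    out <- chars_seq(s)
    attr(out, "planted") <- data.frame(name = character(0), start = integer(0),
                                       end = integer(0), strand = character(0),
                                       instance = character(0))
    return(out)
  }
  elements <- as.data.frame(elements)
  if (is.null(elements$strand)) elements$strand <- "+"
  rows <- list()
  for (i in seq_len(nrow(elements))) {
    nm <- elements$name[i]; pos <- as.integer(elements$position[i])
    strand <- elements$strand[i]
    pat <- dictionary$pattern[match(nm, dictionary$name)]
    if (is.na(pat)) stop("element not in dictionary: ", nm)
    inst <- instantiate_iupac(pat)
    if (strand == "-") inst_placed <- revcomp(inst) else inst_placed <- inst
    w <- nchar(inst)
    if (pos < 1L || pos + w - 1L > length)
      stop("planted element ", nm, " does not fit within the promoter")
    rows[[i]] <- data.frame(name = nm, start = pos, end = pos + w - 1L,
                            strand = strand, instance = inst_placed)
    s[pos:(pos + w - 1L)] <- seq_chars(inst_placed)
  }
  placed <- do.call(rbind, rows)
  o <- placed[order(placed$start), , drop = FALSE]
  if (nrow(o) > 1L && any(o$start[-1L] <= o$end[-nrow(o)]))
    stop("planted elements overlap")
  out <- chars_seq(s)
  attr(out, "planted") <- placed
  out
}

# concrete instance of an IUPAC pattern (random choice at degenerate codes)
instantiate_iupac <- function(pattern) {
  cls <- iupac_classes(pattern)
  chars_seq(vapply(cls, function(b) if (length(b) == 1L) b else sample(b, 1L), ""))
}

#' Write a synthetic family's sequences and truth tables to disk
#'
#' Emits genomic, cDNA, protein and promoter FASTA, a 1-based inclusive GFF3
#' of the true exon intervals, and TSV truth tables (exon/intron lengths,
#' indel events, pairwise true dN/dS, planted promoter elements) plus the
#' true tree in Newick format.  Output is byte-identical for a fixed config.
#'
#' @param truth a \code{family_truth}
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
write_family <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  models <- truth$models
  write_fasta(vapply(models, function(m) m$genomic, ""),
              file.path(dir, "genomic.fa"))
  write_fasta(vapply(models, function(m) m$cdna, ""),
              file.path(dir, "cdna.fa"))
  write_fasta(truth$proteins, file.path(dir, "protein.fa"), aa = TRUE)
  write_fasta(setNames(as.character(truth$promoters), names(truth$promoters)),
              file.path(dir, "promoters.fa"))
  write_gff3(models, file.path(dir, "truth.gff3"))

  tab <- exon_intron_table(models)
  write.table(tab, file.path(dir, "exon_intron_lengths.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ev <- do.call(rbind, lapply(names(truth$indel_events), function(sp) {
    e <- truth$indel_events[[sp]]
    if (nrow(e) == 0L) return(NULL)
    cbind(species = sp, e)
  }))
  if (is.null(ev))
    ev <- data.frame(species = character(0), exon = integer(0),
                     position = integer(0), length = integer(0),
                     kind = character(0))
  write.table(ev, file.path(dir, "indel_events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(truth$true_dnds), file.path(dir, "dnds_true.tsv"),
              sep = "\t", quote = FALSE, row.names = TRUE, col.names = NA)
  pl <- do.call(rbind, lapply(names(truth$planted_elements), function(sp) {
    p <- truth$planted_elements[[sp]]
    if (nrow(p) == 0L) return(NULL)
    cbind(species = sp, p)
  }))
  if (is.null(pl))
    pl <- data.frame(species = character(0), name = character(0),
                     start = integer(0), end = integer(0),
                     strand = character(0), instance = character(0))
  write.table(pl, file.path(dir, "planted_elements.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ape::write.tree(truth$tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}

# minimal GFF3 writer for exon features (1-based inclusive)
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    n <- nrow(m$exons)
    gstart <- m$exons[1L, "start"] + 1L
    gend <- m$exons[n, "end"]
    lines <- c(lines, paste(m$species, "orthoarch", "gene", gstart, gend,
                            ".", m$strand, ".",
                            paste0("ID=gene:", m$species), sep = "\t"))
    for (j in seq_len(n)) {
      lines <- c(lines, paste(
        m$species, "orthoarch", "exon",
        m$exons[j, "start"] + 1L, m$exons[j, "end"], ".", m$strand, ".",
        paste0("ID=exon:", m$species, ":", j, ";Parent=gene:", m$species),
        sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read exon intervals back from a truth GFF3
#'
#' @param path GFF3 file written by \code{\link{write_family}} (1-based
#'   inclusive exon features)
#' @return named list of integer matrices (0-based half-open start/end)
#' @export
read_gff3_exons <- function(path) {
  g <- read.delim(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  g <- g[g$V3 == "exon", , drop = FALSE]
  out <- list()
  for (sp in unique(g$V1)) {
    gs <- g[g$V1 == sp, , drop = FALSE]
    out[[sp]] <- cbind(start = as.integer(gs$V4) - 1L,
                       end = as.integer(gs$V5))
  }
  out
}
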