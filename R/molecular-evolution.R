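# Molecular evolution: Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor
# correction, Poisson-corrected protein distances, neighbor-joining trees
# and column-bootstrap support.

.ng_env <- new.env(parent = emptyenv())

# per-codon fraction of synonymous sites: at each of the 3 positions, the
# fraction of the 3 possible nucleotide changes that are synonymous
# (changes to a stop codon count as nonsynonymous)
syn_site_table <- function() {
  if (!is.null(.ng_env$sites)) return(.ng_env$sites)
  aa <- codon_aa()
  codons <- all_codons()
  s <- setNames(numeric(length(codons)), codons)
  for (cod in codons) {
    if (aa[[cod]] == "*") { s[cod] <- NA_real_; next }
    cc <- seq_chars(cod)
    nsyn <- 0
    for (p in 1:3) for (b in setdiff(DNA_BASES, cc[p])) {
      alt <- cc; alt[p] <- b
      alt <- chars_seq(alt)
      if (aa[[alt]] != "*" && aa[[alt]] == aa[[cod]]) nsyn <- nsyn + 1
    }
    s[cod] <- nsyn / 3
  }
  .ng_env$sites <- s
  s
}

#' Nei-Gojobori synonymous and nonsynonymous site counts
#'
#' Each codon position contributes the fraction of its three possible
#' nucleotide changes that are synonymous; changes creating a stop codon
#' count as nonsynonymous.  S is the sum of these fractions, N the
#' remainder (3 per codon).
#'
#' @param codon_seq gap-free coding sequence, length divisible by 3
#' @return named vector \code{c(S=, N=)}; codons with ambiguity codes are
#'   skipped and reported via the \code{skipped} attribute
#' @export
count_sites <- function(codon_seq) {
  L <- nchar(codon_seq)
  if (L %% 3L != 0L) stop("sequence length must be divisible by 3")
  if (L == 0L) return(c(S = 0, N = 0))
  codons <- substring(codon_seq, seq(1L, L, 3L), seq(3L, L, 3L))
  tab <- syn_site_table()
  known <- codons %in% names(tab)        # FALSE for ambiguity codes
  vals <- ifelse(known, tab[codons], NA_real_)
  stop_idx <- which(known & is.na(tab[codons]))
  if (length(stop_idx))
    stop("stop codon at codon position ", stop_idx[1L])
  S <- sum(vals[known])
  out <- c(S = S, N = 3 * sum(known) - S)
  attr(out, "skipped") <- which(!known)
  out
}

# classify one single-nucleotide codon change: "syn", "nonsyn" or "stop"
step_class <- function(from, to, aa) {
  if (aa[[to]] == "*") return("stop")
  if (aa[[to]] == aa[[from]]) "syn" else "nonsyn"
}

# pathway-averaged (Sd, Nd) contribution of one codon pair; pathways through
# stop codons are dropped (weights renormalised) unless no stop-free
# pathway exists, in which case all pathways count and stop steps are
# nonsynonymous
codon_pair_diff <- function(c1, c2, aa = codon_aa()) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  a <- seq_chars(c1); b <- seq_chars(c2)
  d <- which(a != b)
  k <- length(d)
  perms <- if (k == 1L) list(d)
           else if (k == 2L) list(d, rev(d))
           else list(d[c(1,2,3)], d[c(1,3,2)], d[c(2,1,3)],
                     d[c(2,3,1)], d[c(3,1,2)], d[c(3,2,1)])
  walk <- function(ord, allow_stop) {
    cur <- a; sd_ <- 0; nd_ <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      cfrom <- chars_seq(cur); cto <- chars_seq(nxt)
      cl <- step_class(cfrom, cto, aa)
      if (cl == "stop") {
        if (!allow_stop) return(NULL)
        nd_ <- nd_ + 1
      } else if (cl == "syn") sd_ <- sd_ + 1 else nd_ <- nd_ + 1
      cur <- nxt
    }
    c(sd = sd_, nd = nd_)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
  if (length(res) == 0L) res <- lapply(perms, walk, allow_stop = TRUE)
  m <- do.call(rbind, res)
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

#' Pathway-averaged synonymous and nonsynonymous difference counts
#'
#' For codons differing at k positions, the classification is averaged over
#' all k! orderings of the single changes (Nei-Gojobori pathway counting).
#'
#' @param a,b gap-free coding sequences of equal length, divisible by 3
#' @return named vector \code{c(Sd=, Nd=)}
#' @export
count_differences <- function(a, b) {
  La <- nchar(a)
  if (La != nchar(b)) stop("sequences must be of equal length")
  if (La %% 3L != 0L) stop("length must be divisible by 3")
  if (La == 0L) return(c(Sd = 0, Nd = 0))
  ca <- substring(a, seq(1L, La, 3L), seq(3L, La, 3L))
  cb <- substring(b, seq(1L, La, 3L), seq(3L, La, 3L))
  aa <- codon_aa()
  sd_ <- 0; nd_ <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    if (!all(seq_chars(ca[i]) %in% DNA_BASES) ||
        !all(seq_chars(cb[i]) %in% DNA_BASES)) next  # ambiguity: skip codon
    r <- codon_pair_diff(ca[i], cb[i], aa)
    sd_ <- sd_ + r["sd"]; nd_ <- nd_ + r["nd"]
  }
  c(Sd = unname(sd_), Nd = unname(nd_))
}

#' Nei-Gojobori Ka/Ks with Jukes-Cantor correction
#'
#' Site counts are averaged over the two sequences; proportions pS = Sd/S
#' and pN = Nd/N are corrected as d = -(3/4) ln(1 - (4/3) p).  The ratio is
#' Ka/Ks, undefined (and flagged) when Ks = 0; a proportion at or above 3/4
#' sets the \code{saturated} flag and an NA distance rather than silent NaN.
#'
#' @param a,b gap-free codon-aligned coding sequences of equal length
#' @param ids optional pair labels
#' @return object of class \code{kaks_result}: list with S, N, Sd, Nd, pS,
#'   pN, Ks, Ka, ratio, flags
#' @export
kaks <- function(a, b, ids = c("seq1", "seq2")) {
  if (nchar(a) != nchar(b)) stop("sequences must be of equal length")
  sites_a <- count_sites(a); sites_b <- count_sites(b)
  S <- unname(sites_a["S"] + sites_b["S"]) / 2
  N <- unname(sites_a["N"] + sites_b["N"]) / 2
  d <- count_differences(a, b)
  pS <- if (S > 0) d[["Sd"]] / S else NA_real_
  pN <- if (N > 0) d[["Nd"]] / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- jc(pS); Ka <- jc(pN)
  flags <- character(0)
  if (!is.na(pS) && pS >= 0.75 || !is.na(pN) && pN >= 0.75)
    flags <- c(flags, "saturated")
  ratio <- if (is.na(Ks) || is.na(Ka) || Ks == 0) {
    if (!is.na(Ks) && Ks == 0) flags <- c(flags, "ks_zero")
    NA_real_
  } else Ka / Ks
  structure(list(ids = ids, S = S, N = N,
                 Sd = d[["Sd"]], Nd = d[["Nd"]],
                 pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka, ratio = ratio, flags = flags),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("Ka/Ks (%s vs %s): S=%.2f N=%.2f Sd=%.2f Nd=%.2f Ka=%s Ks=%s ratio=%s%s\n",
              x$ids[1], x$ids[2], x$S, x$N, x$Sd, x$Nd,
              format(x$Ka, digits = 4), format(x$Ks, digits = 4),
              format(x$ratio, digits = 4),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Summarise a matrix of pairwise Ka/Ks ratios
#'
#' @param m numeric matrix (lower triangle or full, NA for undefined pairs)
#'   with taxon dimnames
#' @param reference optional taxon id; when given, only the pairs involving
#'   the reference are summarised (the "with respect to" reading of a
#'   pairwise table)
#' @return list with \code{mean} (rounded to 3 decimals in the
#'   \code{mean_reported} field), \code{min}, \code{max} and the pairs
#'   attaining them
#' @export
kaks_summary <- function(m, reference = NULL) {
  m <- as.matrix(m)
  idx <- which(lower.tri(m) & !is.na(m), arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    idx <- which(!is.na(m) & upper.tri(m), arr.ind = TRUE)
  }
  if (!is.null(reference)) {
    if (!reference %in% rownames(m)) stop("unknown reference: ", reference)
    ri <- match(reference, rownames(m))
    idx <- idx[idx[, 1] == ri | idx[, 2] == ri, , drop = FALSE]
  }
  if (nrow(idx) == 0L) stop("no defined Ka/Ks ratios in the matrix")
  vals <- m[idx]
  pair_label <- function(i) paste(rownames(m)[idx[i, 1]],
                                  colnames(m)[idx[i, 2]], sep = "-")
  i_min <- which.min(vals); i_max <- which.max(vals)
  list(mean = mean(vals), mean_reported = round(mean(vals), 3),
       n = length(vals),
       min = vals[i_min], argmin = pair_label(i_min),
       max = vals[i_max], argmax = pair_label(i_max))
}

#' Read a lower-triangular pairwise Ka/Ks table from TSV
#'
#' @param path TSV: first column species, remaining columns the ratios
#'   against earlier-listed species (lower triangle, blank above diagonal)
#' @return full symmetric matrix with NA diagonal
#' @export
read_kaks_table <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  sp <- raw[[1L]]
  m <- matrix(NA_real_, length(sp), length(sp), dimnames = list(sp, sp))
  for (i in seq_along(sp)) for (j in seq_len(i - 1L)) {
    v <- suppressWarnings(as.numeric(raw[i, j + 1L]))
    m[i, j] <- v; m[j, i] <- v
  }
  m
}

#' Shipped pairwise Ka/Ks table of the starch synthase III orthologs
#'
#' Lower-triangular Ka/Ks values for all 28 species pairs (with respect to
#' maize and each other).
#'
#' @return symmetric matrix with NA diagonal
#' @export
ssiii_kaks_table <- function() {
  read_kaks_table(system.file("extdata", "ssiii_kaks_pairwise.tsv",
                              package = "orthoarch", mustWork = TRUE))
}

#' Poisson-corrected distance between two aligned protein sequences
#'
#' Columns containing a gap in either sequence are dropped; with p the
#' proportion of differing compared columns, d = -ln(1 - p).
#'
#' @param a,b aligned protein sequences of equal length (gaps "-")
#' @return distance in substitutions per site; \code{Inf} with an
#'   \code{infinite} attribute when p = 1
#' @export
poisson_distance <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  if (length(ca) != length(cb)) stop("aligned sequences must have equal length")
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) stop("no gap-free columns to compare")
  p <- mean(ca[keep] != cb[keep])
  if (p >= 1) {
    out <- Inf
    attr(out, "infinite") <- TRUE
    return(out)
  }
  -log(1 - p)
}

#' Poisson-corrected distance matrix of a protein alignment
#'
#' @param msa named character vector of aligned protein sequences
#' @return symmetric distance matrix, zero diagonal
#' @export
poisson_distance_matrix <- function(msa) {
  n <- length(msa)
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d <- poisson_distance(msa[[i]], msa[[j]])
    D[i, j] <- D[j, i] <- as.numeric(d)
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration on the Q-criterion; ties are broken by
#' the lexicographically lowest taxon-index pair, so the result is
#' deterministic.  Negative branch lengths are clamped to zero and flagged
#' via the \code{clamped} attribute.
#'
#' @param dm symmetric distance matrix with taxon dimnames, >= 3 taxa
#' @return unrooted \code{ape::phylo} tree
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  labels <- rownames(dm)
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0) clamped <<- TRUE
    sprintf("%.10g", max(0, x))
  }
  # active node labels: tips, or "(...)" newick fragments for joined clades
  lab <- labels
  is_comp <- rep(FALSE, n)     # composite (internal) node?
  D <- dm
  while (length(lab) > 2L) {
    m <- length(lab)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    pick <- best[order(best[, 1], best[, 2])[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    newlab <- paste0("(", lab[i], ":", bl(bi), ",", lab[j], ":", bl(bj), ")")
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    lab <- c(lab[keep], newlab)
    is_comp <- c(is_comp[keep], TRUE)
  }
  # closing edge between the two remaining nodes: attach one as an extra
  # child of the other's root, giving the usual unrooted basal multifurcation
  d12 <- D[1L, 2L]
  host <- if (is_comp[2L]) 2L else 1L
  other <- 3L - host
  inner <- sub("^\\(", "", sub("\\)$", "", lab[host]))
  nwk <- paste0("(", inner, ",", lab[other], ":", bl(d12), ");")
  tr <- ape::read.tree(text = nwk)
  attr(tr, "clamped") <- clamped
  tr
}

# tip bipartitions of the internal edges of an unrooted tree, each encoded
# as a canonical sorted label set (the side not containing the first label)
tree_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  parts <- list()
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2L]
    if (child <= n_tip) next
    tips <- sort(tree$tip.label[tips_under(tree, child)])
    if (tree$tip.label[1L] %in% tips)
      tips <- sort(setdiff(tree$tip.label, tips))
    if (length(tips) < 2L || length(tips) > n_tip - 2L) next
    parts[[paste(tips, collapse = "|")]] <- tips
  }
  parts
}

tips_under <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == v, 2L]
    out <- c(out, kids[kids <= n_tip])
    stack <- c(stack, kids[kids > n_tip])
  }
  out
}

#' Neighbor-joining tree with column-bootstrap support
#'
#' Computes the Poisson-distance NJ tree of the alignment, then resamples
#' alignment columns with replacement \code{n_replicates} times, rebuilds
#' the tree each time, and reports for each internal edge of the original
#' tree the percentage of replicates containing the same tip bipartition.
#'
#' @param msa named character vector of aligned protein sequences
#' @param n_replicates bootstrap replicates (study setting: 1000)
#' @param seed integer seed for the resampling
#' @return the original tree (\code{ape::phylo}) with \code{node.label}
#'   support percentages and a \code{support} attribute (named vector per
#'   bipartition); identical input sequences yield a zero distance matrix
#'   and a \code{degenerate} flag
#' @export
bootstrap_support <- function(msa, n_replicates = 1000L, seed = 1L) {
  if (length(msa) < 3L) stop("need at least 3 sequences")
  width <- unique(nchar(msa))
  if (length(width) != 1L) stop("sequences must be aligned to equal length")
  D <- poisson_distance_matrix(msa)
  degenerate <- all(D == 0)
  tree <- neighbor_joining(D)
  orig_parts <- tree_bipartitions(tree)
  counts <- setNames(numeric(length(orig_parts)), names(orig_parts))
  mat <- do.call(rbind, strsplit(unname(msa), "", fixed = TRUE))
  rownames(mat) <- names(msa)
  set.seed(seed)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(width, width, replace = TRUE)
    rep_msa <- setNames(apply(mat[, cols, drop = FALSE], 1L, paste,
                              collapse = ""), names(msa))
    rep_tree <- try(neighbor_joining(poisson_distance_matrix(rep_msa)),
                    silent = TRUE)
    if (inherits(rep_tree, "try-error")) next
    rep_parts <- names(tree_bipartitions(rep_tree))
    hit <- names(counts) %in% rep_parts
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_replicates
  # attach as node labels: find the internal node of each bipartition
  n_tip <- length(tree$tip.label)
  node_lab <- rep("", tree$Nnode)
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2L]
    if (child <= n_tip) next
    tips <- sort(tree$tip.label[tips_under(tree, child)])
    if (tree$tip.label[1L] %in% tips)
      tips <- sort(setdiff(tree$tip.label, tips))
    key <- paste(tips, collapse = "|")
    if (key %in% names(support))
      node_lab[child - n_tip] <- format(support[[key]], digits = 4)
  }
  tree$node.label <- node_lab
  attr(tree, "support") <- support
  attr(tree, "degenerate") <- degenerate
  attr(tree, "method") <- "Poisson-corrected distance + neighbor joining"
  tree
}
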