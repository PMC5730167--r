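# Independent oracles used across the suite.  They deliberately use a
# different genetic-code source (seqinr) and different control flow than the
# package implementation.

oracle_translate_codon <- function(codon) {
  seqinr::translate(strsplit(tolower(codon), "")[[1]])
}

# per-codon synonymous site fraction by direct enumeration of the 9 changes
oracle_codon_sites <- function(codon) {
  aa0 <- oracle_translate_codon(codon)
  stopifnot(aa0 != "*")
  syn <- 0L
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- b
      aa1 <- oracle_translate_codon(alt)
      if (aa1 != "*" && aa1 == aa0) syn <- syn + 1L
    }
  }
  c(S = syn / 3, N = 3 - syn / 3)
}

oracle_count_sites <- function(seq) {
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  rowSums(vapply(codons, oracle_codon_sites, c(S = 0, N = 0)))
}

perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# pathway-averaged (sd, nd) for one codon pair, full enumeration
oracle_codon_pair <- function(c1, c2) {
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(d) == 0L) return(c(sd = 0, nd = 0))
  paths <- perms_of(d)
  classify_path <- function(ord, allow_stop) {
    cur <- c1
    sd_ <- 0; nd_ <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracle_translate_codon(nxt) == "*") {
        if (!allow_stop) return(NULL)
        nd_ <- nd_ + 1
      } else if (oracle_translate_codon(nxt) == oracle_translate_codon(cur))
        sd_ <- sd_ + 1
      else nd_ <- nd_ + 1
      cur <- nxt
    }
    c(sd = sd_, nd = nd_)
  }
  res <- Filter(Negate(is.null), lapply(paths, classify_path, allow_stop = FALSE))
  if (length(res) == 0L) res <- lapply(paths, classify_path, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

oracle_count_differences <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  tot <- c(sd = 0, nd = 0)
  for (i in seq_along(ca)) tot <- tot + oracle_codon_pair(ca[i], cb[i])
  c(Sd = unname(tot["sd"]), Nd = unname(tot["nd"]))
}

sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all64 <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
  all64[vapply(all64, oracle_translate_codon, "") != "*"]
}

# naive position-by-position IUPAC matcher (plus strand only)
oracle_iupac_scan <- function(seq, pattern) {
  classes <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  hits <- integer(0)
  for (st in seq_len(max(0, length(s) - length(p) + 1))) {
    ok <- TRUE
    for (j in seq_along(p)) {
      base <- s[st + j - 1]
      cls <- classes[[p[j]]]
      match_j <- if (base == "N") length(cls) == 4L else base %in% cls
      if (!match_j) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, st)
  }
  hits
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                    collapse = "")

random_protein_str <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}
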