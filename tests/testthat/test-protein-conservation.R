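make_groups <- function(msa) {
  setNames(c(rep("monocot", 6), rep("dicot", 2))[seq_along(msa)], names(msa))
}

test_that("consensus of identical sequences scores full conservation", {
  sq <- random_protein_str(40)
  msa <- setNames(rep(sq, 8), c(paste0("m", 1:6), paste0("d", 1:2)))
  prof <- build_consensus(msa, "m1", make_groups(msa))
  expect_identical(attr(prof, "consensus"), sq)
  expect_true(all(prof$monocot_score == 6))
  expect_true(all(prof$dicot_score == 2))
  expect_false(any(prof$imputed))
})

test_that("ties fall back to the reference residue and are flagged", {
  msa <- setNames(c("A", "A", "A", "K", "K", "K", "A", "K"),
                  c(paste0("m", 1:6), paste0("d", 1:2)))
  # 4 A vs 4 K overall; within monocots 3-3: a global tie either way
  prof <- build_consensus(msa, "m4", make_groups(msa))  # reference has K
  expect_identical(prof$consensus, "K")
  expect_true(prof$imputed)
  expect_identical(prof$monocot_score, 3L)
  expect_identical(prof$dicot_score, 1L)
})

test_that("consensus equals a per-column counting oracle on random alignments", {
  set.seed(30)
  for (rep in 1:5) {
    W <- 25
    msa <- setNames(replicate(8, random_protein_str(W)),
                    c(paste0("m", 1:6), paste0("d", 1:2)))
    groups <- make_groups(msa)
    prof <- build_consensus(msa, "m1", groups)
    m <- do.call(rbind, strsplit(unname(msa), ""))
    for (j in seq_len(W)) {
      tab <- sort(table(m[, j]), decreasing = TRUE)
      if (sum(tab == max(tab)) == 1L) {
        expect_identical(prof$consensus[j], names(tab)[1])
        expect_identical(prof$monocot_score[j],
                         sum(m[1:6, j] == names(tab)[1]))
      } else {
        expect_identical(prof$consensus[j], m[1, j])
        expect_true(prof$imputed[j])
      }
    }
    # order invariance (same reference)
    prof2 <- build_consensus(msa[sample(8)], "m1", groups)
    expect_identical(prof2$consensus, prof$consensus)
    expect_identical(prof2$monocot_score, prof$monocot_score)
  }
})

test_that("gap-only and insertion columns are retained", {
  msa <- setNames(c("A-C", "A-C", "AKC", "A-C", "A-C", "A-C", "A-C", "A-C"),
                  c(paste0("m", 1:6), paste0("d", 1:2)))
  prof <- build_consensus(msa, "m1", make_groups(msa))
  expect_identical(nrow(prof), 3L)
  expect_identical(prof$consensus[2], "K")  # sole non-gap residue
  expect_identical(prof$monocot_score[2], 1L)
  expect_error(build_consensus(msa, "m1", setNames(rep("fern", 8), names(msa))),
               "unknown group")
})

test_that("motif location finds planted motifs within mismatch budgets", {
  set.seed(31)
  bg <- random_protein_str(500)
  prot <- paste0(substr(bg, 1, 249), "KVGGL", substr(bg, 255, 500))
  motifs <- data.frame(name = "KVGGL", pattern = "KVGGL", max_mismatches = 0)
  hits <- locate_motifs(prot, motifs)
  expect_true(any(hits$start == 250 & hits$mismatches == 0))

  expect_identical(nrow(locate_motifs("", motifs)), 0L)

  near <- data.frame(name = "KVGGL", pattern = "KVGGL", max_mismatches = 1)
  h2 <- locate_motifs("AAAKTGGLAAA", near)
  expect_identical(nrow(h2), 1L)
  expect_identical(h2$mismatches, 1L)
  expect_identical(h2$matched, "KTGGL")
})

test_that("zero-mismatch hits exist exactly when the pattern is a substring", {
  set.seed(32)
  for (rep in 1:20) {
    prot <- random_protein_str(60)
    pat <- random_protein_str(4)
    hits <- locate_motifs(prot, data.frame(name = "p", pattern = pat,
                                           max_mismatches = 0))
    expect_identical(nrow(hits) > 0L, grepl(pat, prot, fixed = TRUE))
  }
})

test_that("motif architecture reports residues strictly between hits", {
  hits <- data.frame(name = c("a", "b"), start = c(10L, 20L),
                     end = c(14L, 24L), matched = c("XXXXX", "YYYYY"),
                     mismatches = 0L)
  arch <- motif_architecture(hits)
  expect_identical(arch$distances, 5L)
  one <- motif_architecture(hits[1, ])
  expect_identical(one$distances, integer(0))
  bad <- data.frame(name = c("a", "b"), start = c(10L, 12L),
                    end = c(14L, 16L), matched = c("XXXXX", "YYYYY"),
                    mismatches = 0L)
  expect_error(motif_architecture(bad), "overlapping")
})

test_that("planted motif series yields the planted inter-motif gaps", {
  set.seed(33)
  gaps <- c(7L, 30L, 12L)
  motifs <- data.frame(name = paste0("CM", 1:4),
                       pattern = c("KVGGL", "ITRLT", "FEPCW", "KAEMK"),
                       max_mismatches = 0)
  parts <- character(0)
  for (i in 1:4) {
    parts <- c(parts, motifs$pattern[i])
    if (i < 4) parts <- c(parts, random_protein_str(gaps[i]))
  }
  prot <- paste0(random_protein_str(50), paste(parts, collapse = ""),
                 random_protein_str(50))
  arch <- motif_architecture(locate_motifs(prot, motifs))
  expect_identical(arch$hits$name, motifs$name)
  expect_identical(arch$distances, gaps)
})

test_that("architecture comparison classes residue changes by substitution score", {
  ref_hits <- data.frame(name = c("m1", "m2"), start = c(1L, 20L),
                         end = c(5L, 24L),
                         matched = c("KVGGL", "GDEAR"), mismatches = 0L)
  ref <- motif_architecture(ref_hits)
  same <- compare_architectures(ref, list(s1 = ref))
  expect_true(all(same$presence))
  expect_identical(nrow(same$residue_changes), 0L)
  expect_true(all(same$distance_delta == 0))

  # L->I scores +2 in BLOSUM62 (conservative); G->D scores -1
  alt_hits <- ref_hits
  alt_hits$matched <- c("KVGGI", "DDEAR")
  alt <- motif_architecture(alt_hits)
  cmp <- compare_architectures(ref, list(s2 = alt))
  ch <- cmp$residue_changes
  expect_identical(ch$class[ch$ref == "L" & ch$alt == "I"], "conservative")
  expect_identical(ch$class[ch$ref == "G" & ch$alt == "D"], "non-conservative")
})

test_that("domain identity projects reference intervals through the alignment", {
  ref <- paste0(paste(rep("A", 30), collapse = ""),
                paste(rep("K", 30), collapse = ""))
  # species 2: mutations only inside the "variable" second half
  v <- strsplit(ref, "")[[1]]
  v[31:40] <- "R"
  msa <- setNames(c(ref, paste(v, collapse = "")), c("ref", "sp"))
  regions <- list(catalytic = c(1L, 30L), variable = c(31L, 60L))
  di <- domain_identity(msa, regions, "ref")
  expect_equal(di["ref", "catalytic"], 100)
  expect_equal(di["ref", "variable"], 100)
  expect_equal(di["sp", "catalytic"], 100)
  expect_lt(di["sp", "variable"], 100)
  # fully deleted region scores zero and is flagged
  gap <- c(ref, paste0(paste(rep("-", 30), collapse = ""),
                       paste(rep("K", 30), collapse = "")))
  names(gap) <- c("ref", "del")
  di2 <- domain_identity(gap, regions, "ref")
  expect_equal(di2["del", "catalytic"], 0)
  expect_true("del:catalytic" %in% attr(di2, "deleted"))
  expect_error(domain_identity(msa, list(bad = c(1L, 99L)), "ref"), "exceeds")
})
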