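test_that("site counts match direct enumeration of single-codon changes", {
  # TTT (Phe): only the third position change T->C is synonymous
  s <- count_sites("TTT")
  expect_equal(unname(s["S"]), 1 / 3)
  expect_equal(unname(s["N"]), 8 / 3)
  expect_equal(unname(count_sites("")), c(0, 0))
  set.seed(20)
  seqs <- replicate(3, paste(sample(sense_codons(), 100, TRUE), collapse = ""))
  for (sq in seqs) {
    expect_equal(as.numeric(count_sites(sq)),
                 as.numeric(oracle_count_sites(sq)))
    expect_equal(sum(count_sites(sq)), nchar(sq))  # S + N = length in nt
  }
})

test_that("ambiguous codons are skipped and reported", {
  s <- count_sites("TTTNNNAAA")
  expect_identical(attr(s, "skipped"), 2L)
  expect_equal(sum(s), 6)  # two valid codons
  expect_error(count_sites("TTTTAAAAA"), "stop codon")
})

test_that("difference counts average over mutational pathways", {
  expect_equal(unname(count_differences("TTTAAA", "TTTAAA")), c(0, 0))
  expect_equal(unname(count_differences("TTT", "TTA")), c(0, 1))
  set.seed(21)
  sense <- sense_codons()
  for (rep in 1:5) {
    a <- paste(sample(sense, 30, TRUE), collapse = "")
    b <- paste(sample(sense, 30, TRUE), collapse = "")
    expect_equal(unname(count_differences(a, b)),
                 unname(oracle_count_differences(a, b)), tolerance = 1e-12)
  }
})

test_that("kaks applies the Jukes-Cantor correction and flags edge cases", {
  set.seed(22)
  a <- paste(sample(sense_codons(), 50, TRUE), collapse = "")
  same <- kaks(a, a)
  expect_equal(same$Ka, 0)
  expect_equal(same$Ks, 0)
  expect_true(is.na(same$ratio))
  expect_true("ks_zero" %in% same$flags)

  # synonymous-only pair: 20 Phe codons, two third-position changes
  x <- paste(rep("TTT", 20), collapse = "")
  y <- paste(c("TTC", "TTC", rep("TTT", 18)), collapse = "")
  k <- kaks(x, y)
  expect_equal(k$Nd, 0)
  expect_equal(k$Sd, 2)
  expect_equal(k$Ka, 0)
  # the Jukes-Cantor correction in closed form: d = -(3/4) ln(1 - (4/3) p)
  expect_equal(k$Ks, -0.75 * log(1 - (4 / 3) * k$pS))
  expect_equal(k$pS, 2 / k$S)
})

test_that("kaks is symmetric in its two sequences", {
  set.seed(23)
  sense <- sense_codons()
  a <- paste(sample(sense, 40, TRUE), collapse = "")
  b <- paste(sample(sense, 40, TRUE), collapse = "")
  k1 <- kaks(a, b); k2 <- kaks(b, a)
  expect_equal(k1$Ka, k2$Ka)
  expect_equal(k1$Ks, k2$Ks)
  expect_equal(k1$S, k2$S)
})

test_that("the pairwise Ka/Ks fixture reproduces the published summary", {
  km <- ssiii_kaks_table()
  s <- kaks_summary(km)
  expect_identical(s$n, 28L)
  expect_equal(s$mean_reported, 0.391)
  expect_equal(s$max, 0.569)
  ref <- kaks_summary(km, reference = "maize")
  expect_equal(ref$min, 0.076)
  expect_identical(ref$argmin, "sorghum-maize")
  one <- matrix(c(NA, 0.4, 0.4, NA), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  s1 <- kaks_summary(one)
  expect_equal(s1$mean, 0.4)
  expect_equal(s1$min, s1$max)
  expect_error(kaks_summary(matrix(NA_real_, 2, 2)), "no defined")
})

test_that("Poisson distance is the -ln(1-p) correction over gap-free columns", {
  expect_equal(poisson_distance("ACDEF", "ACDEF"), 0)
  expect_equal(poisson_distance("AAAA", "AACC"), -log(1 - 0.5))
  # gap columns dropped
  expect_equal(poisson_distance("AC-EF", "ACD-F"), 0)
  # strictly increasing in p
  d <- vapply(seq(0, 0.9, 0.1), function(p) {
    n <- 100
    a <- paste(rep("A", n), collapse = "")
    b <- paste(c(rep("C", round(p * n)), rep("A", n - round(p * n))),
               collapse = "")
    poisson_distance(a, b)
  }, 0)
  expect_true(all(diff(d) > 0))
  inf <- poisson_distance("AA", "CC")
  expect_true(is.infinite(inf))
  expect_true(attr(inf, "infinite"))
})

test_that("neighbor joining recovers a hand-built additive 4-taxon tree", {
  # tree: ((a:2,b:3):1,(c:4,d:5)) with internal edge 1
  D <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 9, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(D)
  expect_s3_class(tr, "phylo")
  expect_false(ape::is.rooted(tr))
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[rownames(D), colnames(D)]),
               unname(D), tolerance = 1e-9)
  ref <- ape::read.tree(text = "((a:2,b:3):1,c:4,d:5);")
  expect_equal(ape::dist.topo(tr, ref)[[1]], 0)
})

test_that("neighbor joining matches the independent implementation on random matrices", {
  set.seed(24)
  for (rep in 1:10) {
    n <- sample(5:8, 1)
    tr0 <- ape::rtree(n, rooted = FALSE)
    tr0$edge.length <- runif(nrow(tr0$edge), 0.2, 1.5)
    D <- ape::cophenetic.phylo(tr0)
    mine <- neighbor_joining(D)
    oracle <- ape::nj(as.dist(D))
    expect_equal(ape::dist.topo(mine, tr0)[[1]], 0)
    expect_equal(ape::dist.topo(mine, oracle)[[1]], 0)
    expect_equal(as.matrix(ape::cophenetic.phylo(mine))[rownames(D), colnames(D)],
                 D, tolerance = 1e-8)
  }
})

test_that("neighbor joining validates its input", {
  D <- matrix(runif(9), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(D), "symmetric")
  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least 3")
})

test_that("3-taxon star has solvable branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(D)
  expect_identical(length(tr$tip.label), 3L)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(D), colnames(D)],
               D, tolerance = 1e-9)
})

test_that("bootstrap support finds the deep group split and is deterministic", {
  fam <- generate_family(family_config(seed = 25, exon_indel_rate = 0,
                                       intron_indel_rate = 0))
  msa <- fam$proteins          # no indels: equal length, gap-free alignment
  expect_length(unique(nchar(msa)), 1L)
  tr1 <- bootstrap_support(msa, n_replicates = 100, seed = 7)
  tr2 <- bootstrap_support(msa, n_replicates = 100, seed = 7)
  expect_identical(attr(tr1, "support"), attr(tr2, "support"))
  sup <- attr(tr1, "support")
  expect_true(all(sup >= 0 & sup <= 100))
  dicot_key <- paste(sort(c("soybean", "arabidopsis")), collapse = "|")
  expect_true(dicot_key %in% names(sup))
  expect_gte(sup[[dicot_key]], 95)
  # support is attached to tip-set keys, so taxon order cannot matter
  tr3 <- bootstrap_support(msa[rev(seq_along(msa))], n_replicates = 100, seed = 7)
  expect_equal(attr(tr3, "support")[[dicot_key]], sup[[dicot_key]])
})

test_that("identical sequences give a degenerate zero-distance tree", {
  msa <- setNames(rep(paste(rep("ACDEF", 20), collapse = ""), 4),
                  paste0("s", 1:4))
  tr <- bootstrap_support(msa, n_replicates = 10, seed = 1)
  expect_true(attr(tr, "degenerate"))
})
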