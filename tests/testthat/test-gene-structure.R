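test_that("spliced_align handles an intronless gene as one exon", {
  set.seed(10)
  g <- random_dna_str(300)
  m <- spliced_align(g, g)
  expect_identical(nrow(m$exons), 1L)
  expect_identical(unname(m$exons[1, ]), c(0L, 300L))
  expect_identical(m$cdna, g)
})

test_that("spliced_align recovers truth boundaries on noise-free families", {
  fam <- generate_family(family_config(substitution_rate = 0,
                                       intron_indel_rate = 0,
                                       exon_indel_rate = 0, seed = 12))
  for (sp in fam$species) {
    truth <- fam$models[[sp]]
    rec <- spliced_align(truth$cdna, truth$genomic, species = sp)
    expect_identical(rec$exons, truth$exons)
  }
})

test_that("spliced_align recovers boundaries through lineage divergence", {
  fam <- generate_family(family_config(seed = 13))
  hits <- 0L
  for (sp in fam$species) {
    truth <- fam$models[[sp]]
    rec <- spliced_align(truth$cdna, truth$genomic, species = sp)
    hits <- hits + identical(rec$exons, truth$exons)
  }
  expect_identical(hits, length(fam$species))
})

test_that("ambiguous junctions resolve to the canonical GT..AG placement", {
  # two exons sharing an "AG" at the junction: the exact-match extension
  # overshoots into the intron, and only the shifted placement gives GT..AG
  exon1 <- "ATGGCTGCTGCTAG"          # ends ...AG
  exon2 <- "AGCCCGGGAAACCCGGGTTTAAA" # starts AG too
  intron <- paste0("GT", "ACGTACGTACGTACGTAAGTTACG", "AG")
  genomic <- paste0(exon1, intron, exon2)
  cdna <- paste0(exon1, exon2)
  m <- spliced_align(cdna, genomic)
  expect_identical(nrow(m$exons), 2L)
  don <- substring(genomic, m$exons[1, "end"] + 1L, m$exons[1, "end"] + 2L)
  acc <- substring(genomic, m$exons[2, "start"] - 1L, m$exons[2, "start"])
  expect_identical(don, "GT")
  expect_identical(acc, "AG")
  expect_identical(m$cdna, cdna)
})

test_that("intron phases follow cumulative CDS length modulo 3", {
  # 99 bp first exon: phase 0 after exon 1 (the reference gene's intron 1)
  expect_identical(suppressWarnings(classify_intron_phases(c(99L, 70L, 2901L)))[1],
                   0L)
  expect_identical(classify_intron_phases(c(4L, 5L, 9L))[2], 0L)
  # brute-force codon-walk oracle: write codon position base by base
  set.seed(14)
  for (rep in 1:20) {
    n_ex <- sample(3:8, 1)
    exlen <- sample(3:50, n_ex, replace = TRUE)
    while (sum(exlen) %% 3 != 0) exlen[1] <- exlen[1] + 1L
    codon_pos <- ((seq_len(sum(exlen)) - 1L) %% 3L)  # 0,1,2 per CDS base
    boundaries <- cumsum(exlen)[-n_ex]
    oracle <- codon_pos[boundaries + 1L]  # phase = position of next base
    oracle[boundaries == sum(exlen)] <- 0L
    expect_identical(classify_intron_phases(exlen), as.integer(oracle))
  }
})

test_that("intron phases ignore intron lengths and honour the CDS offset", {
  fam <- generate_family(family_config(seed = 15))
  for (sp in fam$species[1:3]) {
    m <- fam$models[[sp]]
    exlen <- m$exons[, "end"] - m$exons[, "start"]
    expect_identical(classify_intron_phases(m), classify_intron_phases(exlen))
  }
  # 5' UTR offset shifts the frame; an offset that breaks the reading frame
  # still yields phases, with a warning
  expect_warning(
    ph <- classify_intron_phases(c(10L, 5L, 9L), cds_start_offset = 1L),
    "divisible")
  expect_identical(ph, as.integer(c((10 - 1) %% 3, (15 - 1) %% 3)))
  # offset spilling past exon 1
  expect_identical(
    suppressWarnings(classify_intron_phases(c(6L, 7L, 5L),
                                            cds_start_offset = 8L))[1], 0L)
})

test_that("catalog_indels finds planted gaps and balances lengths", {
  set.seed(16)
  ref <- random_dna_str(240)
  expect_identical(nrow(catalog_indels(ref, ref)), 0L)

  cut <- paste0(substr(ref, 1, 100), substr(ref, 113, 240))
  ev <- catalog_indels(ref, cut)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "deletion")
  expect_identical(ev$length, 12L)
  cum <- attr(ev, "cumulative")
  expect_identical(unname(cum["deletion"] - cum["insertion"]),
                   nchar(ref) - nchar(cut))

  ins <- paste0(substr(ref, 1, 60), "CCCCCCGGG", substr(ref, 61, 240))
  ev2 <- catalog_indels(ref, ins)
  expect_identical(sum(ev2$length[ev2$kind == "insertion"]), 9L)
  cum2 <- attr(ev2, "cumulative")
  expect_identical(unname(cum2["deletion"] - cum2["insertion"]),
                   nchar(ref) - nchar(ins))
})

test_that("planted exon indels are recovered from the synthetic truth", {
  fam <- generate_family(family_config(seed = 17, substitution_rate = 0,
                                       intron_indel_rate = 0,
                                       exon_indel_rate = 1.5))
  anc_ex <- substring(fam$ancestor$cds,
                      c(0L, cumsum(fam$ancestor$exon_lengths))[1:16] + 1L,
                      cumsum(fam$ancestor$exon_lengths))
  checked <- 0L
  for (sp in fam$species) {
    ev_true <- fam$indel_events[[sp]]
    m <- fam$models[[sp]]
    exlen <- m$exons[, "end"] - m$exons[, "start"]
    sp_ex <- substring(m$cdna, c(0L, cumsum(exlen))[1:16] + 1L, cumsum(exlen))
    for (e in unique(ev_true$exon)) {
      sub <- ev_true[ev_true$exon == e, ]
      if (nrow(sub) != 1L) next  # adjacent events can merge in an alignment
      found <- catalog_indels(anc_ex[e], sp_ex[e])
      expect_identical(nrow(found), 1L)
      expect_identical(found$kind, sub$kind)
      expect_identical(found$length, sub$length)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 2L)
})

test_that("exon length deltas reproduce the reference-relative indel totals", {
  tab <- ssiii_length_table()
  d <- exon_length_delta(tab, "maize", 3)
  expect_equal(unname(d["rice"]), 1359)
  expect_equal(unname(d["arabidopsis"]), 1765)
  expect_equal(unname(d["maize"]), 0)
  expect_error(exon_length_delta(tab, "tomato", 3), "unknown species")
})

test_that("length summaries match the published totals and variability", {
  tab <- ssiii_length_table()
  s <- summarize_lengths(tab)
  tot <- s$species_totals
  expect_identical(tot$exon_total[tot$species == "maize"], 5082)
  expect_identical(
    s$group_mean_totals$intron_total[s$group_mean_totals$group == "dicot"],
    5090)
  s_nowheat <- summarize_lengths(tab, exclude = "wheat")
  expect_equal(unname(s_nowheat$feature_sd["intron13"]), 10.73, tolerance = 1e-3)
  expect_identical(
    s$feature_range$max[s$feature_range$feature == "exon3"], 2940)
  expect_identical(
    s$feature_range$max_species[s$feature_range$feature == "exon3"],
    "brachypodium")
  # excluding all but one species leaves the sd undefined
  s1 <- summarize_lengths(tab, exclude = tab$species[-1])
  expect_true(all(is.na(s1$feature_sd)))
})

test_that("percent identity counts gaps as alignment columns", {
  expect_equal(percent_identity("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(percent_identity("ACGT", "ACGA"), 75)
  set.seed(18)
  for (rep in 1:10) {
    a <- random_dna_str(120)
    k <- sample(1:6, 1)
    pos <- sample(120, k)
    b <- strsplit(a, "")[[1]]
    for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
    # equal length, substitutions only: the optimal global alignment is
    # gap-free, so identity is the Hamming fraction
    expect_equal(percent_identity(a, paste(b, collapse = "")),
                 100 * (120 - k) / 120)
  }
})
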