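---
title: "Methods: comparative gene-architecture analysis of ortholog families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative gene-architecture analysis of ortholog families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoarch)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the choices made where the
design was genuinely open. The running system is the starch synthase III
(SSIII) ortholog family — a 16-exon, 15-intron gene shared by six monocots
and two dicots — but every function is generic over ortholog families with
a common exon/intron architecture.

## The synthetic family generator

`generate_family()` exists so that every downstream stage can be validated
against exact ground truth. It emulates the SSIII ortholog family:

* **Ancestor.** A random coding sequence partitioned into the configured
  exon lengths (default: the maize reference row of the shipped table —
  16 exons totalling 5082 bp, so 1694 sense codons with no stop anywhere),
  with introns of the configured lengths forced to start `GT` and end
  `AG`.
* **Phylogeny.** One stem branch per group (monocot, dicot) and one tip
  branch per species. This two-level design produces a deep group split —
  the feature the tree-inference tests interrogate — without simulating a
  full birth–death history. Within-group resolution is limited to a star;
  the generator's "true tree" records realized substitutions per site as
  branch lengths.
* **Coding substitutions at a controlled dN/dS.** `mutate_coding()`
  proposes single-nucleotide changes at `substitution_rate` per site
  (default 0.05 per branch) and accepts synonymous proposals with
  probability 1 and nonsynonymous ones with probability `target_dnds`
  (roles flip above 1). Proposals that would create a stop codon are
  always rejected; because the Nei–Gojobori site tally counts stop-creating
  changes as nonsynonymous opportunities, the nonsynonymous acceptance
  probability is scaled by the sequence's ratio of all-to-stop-free
  nonsynonymous changes (about 1.06 for random coding sequence), so the
  realized rate per nonsynonymous site matches the target. Without this
  calibration the estimation round trip settles about 5% below the target.
  The default `target_dnds = 0.391` is the family-wide mean pairwise Ka/Ks
  of the SSIII orthologs. This is an acceptance-ratio construction, not a
  codon substitution model: it is simple and auditable, which is what
  estimator-recovery tests need; it does not reproduce
  transition/transversion bias, codon-frequency effects or rate
  heterogeneity, so passing tests say nothing about those features of real
  data.
* **Indels.** Intron indels (Poisson with mean `intron_indel_rate = 1` per
  intron per tip, lengths uniform on 1–60 bp) never touch the first or
  last 2 bp of an intron, preserving the splice dinucleotides. Exon indels
  (mean `exon_indel_rate = 1` per target exon per tip, default targets
  exons 1 and 3, mirroring where the real family varies) are whole-codon
  events, 3–24 bp, applied at codon boundaries so that deletions can never
  create a stop codon; they are recorded against ancestral exon
  coordinates right-to-left so the truth positions stay valid.
* **Promoters.** A uniform-random background of `promoter_length` bp
  (default 800, within the 500–1000 bp upstream window the survey uses)
  with elements planted at fixed positions from the IUPAC dictionary,
  optionally on the minus strand. Overlapping plantings are rejected.

What the generator does *not* emulate: sequencing error, assembly gaps
(the real wheat ortholog is a draft assembly), alternative isoforms,
non-canonical splice sites, GC heterogeneity, and realistic indel length
distributions. Tests that pass on synthetic families therefore certify
the algorithms' correctness on clean input, not their robustness to every
artefact of real genome data.

Determinism: a `family_config(seed=)` fixes every draw; emitting the same
configuration twice produces byte-identical files.

## Gene structure

`spliced_align()` chains exact anchor matches left to right: an exon is
extended while cDNA and genomic agree (isolated substitutions are crossed
when the next `min_anchor = 12` bp realign; total mismatches are capped at
`max_mismatch_frac = 0.02` of the cDNA), an intron opens at the first
disagreement and closes at the next anchor occurrence. Because junction
sequence is often ambiguous — the same bases can terminate one exon or
begin the next, and the greedy extension overshoots into the intron by the
length of any repeat shared by the intron start and the next exon start —
each boundary is shifted (up to one anchor length leftwards, 3 bp
rightwards) to prefer `GT..AG`, then `GC..AG`, else the unshifted
placement, ties resolved leftmost. Less than 90% of the cDNA placeable is an error naming
the unplaced span, not a silent partial model. Coordinates are 0-based
half-open internally and 1-based inclusive in every report and in GFF3.

Intron phase is purely a function of exon CDS lengths: phase of intron
*i* is the cumulative coding length upstream of it modulo 3 (0 = between
codons, 1 = after the first base, 2 = after the second). A translation
start offset is supported and may spill past exon 1; an offset that breaks
the reading frame yields a warning, not an error, because draft gene
models are exactly where one wants to inspect the resulting phases.

`catalog_indels()` reports maximal gap runs of a global affine-gap
alignment (gap open 10, extend 0.5 — values in the range every pairwise
aligner defaults to; both exposed). Deletion positions are the first
deleted reference base; insertion positions the reference base left of
the insertion point (0 for an insertion before base 1). Equivalent gap
placements in repeats are resolved by the aligner; the invariant that is
guaranteed is cumulative deletion − cumulative insertion = length
difference.

`summarize_lengths()` uses the sample standard deviation (n−1). Group
mean totals are reported truncated to integer bp, matching how such
tables are conventionally printed. The exclusion parameter exists because
a draft-assembly outlier (wheat, with a 795 bp intron 13 against 83–117 bp
in every other species) otherwise dominates exactly the per-feature sd it
is excluded from in the shipped fixture configuration.

## Molecular evolution

Ka/Ks follows Nei–Gojobori (1986) with Jukes–Cantor correction — the
default of the standard desktop phylogenetics suites, which is the method
a reader should assume when only the software is named. Sites: each codon
position contributes the fraction of its three possible changes that are
synonymous; stop-creating changes count as nonsynonymous. Differences:
codons differing at k positions average the classification over all k!
single-change orderings; pathways through stop codons are dropped and the
weights renormalised unless no stop-free pathway exists, in which case all
pathways count and stop steps are nonsynonymous (the convention only
matters for rare codon pairs). Correction: d = −(3/4) ln(1 − (4/3)p),
undefined at p ≥ 3/4 — such pairs carry a `saturated` flag rather than a
silent NaN, and Ks = 0 flags the ratio undefined.

Protein distances use the Poisson correction d = −ln(1 − p) over gap-free
columns. Tree inference is distance-based: neighbor joining on the
Q-criterion with ties broken by the lowest taxon-index pair (fully
deterministic), negative branch lengths clamped to zero and flagged.
Bootstrap support resamples alignment columns with replacement, rebuilds
the tree per replicate, and counts each original internal-edge bipartition
(encoded as a canonical tip set, so taxon order cannot matter). The
conventional setting is 1000 replicates; tests use 100–200 to keep the
suite fast, and
the acceptance script uses 200 — support percentages at these sizes have
Monte-Carlo noise of a few points, which is why the guarantee is stated as
a ≥95% threshold on a deep split rather than an exact value.

Distance-based inference is a deliberate scope choice: the Poisson + NJ
combination is self-consistent, fast and fully deterministic, and the
output metadata labels trees accordingly; no maximum-likelihood search is
attempted.

## Protein conservation

The consensus keeps, per column, the most frequent non-gap residue; when
the maximum is shared, or a column is all gaps, the *reference* residue is
imputed (flagged), even when the reference is not among the modal
residues — this is the "reference arbitrates" rule, and it is what makes
the consensus deterministic. Group conservation scores count group members
matching the consensus: 0–6 for the six monocots, 0–2 for the two dicots.
The lower bound is 0, not 1: a column where no monocot matches the imputed
consensus must score 0, so the 1–6 phrasing found in descriptions of such
scales is read as the range attained when at least one member matches.

Motif search is a sliding Hamming window ('X' matches anything) with a
per-motif mismatch budget; overlapping matches of the same motif collapse
to the fewest-mismatch, then leftmost, hit. Inter-motif distances count
residues strictly between consecutive hits. Substitutions inside motifs
are classed conservative when their BLOSUM62 score is positive — the only
sensible protein-level reading of a synonymous/non-synonymous colouring —
and the matrix ships as an editable TSV. The eleven novel conserved motifs
(CM1–CM11) of the SSIII carbohydrate-binding domains have no
machine-readable residue strings; the shipped dictionary therefore carries
the six named motifs (KVGGL, KTGGL, ITRLT, FEPCGLT, AER, KAEMK) and users
supply their own CM definitions.

## Promoter scanning

Patterns are IUPAC classes validated at load time; a hit requires every
class to match. A sequence `N` matches only the fully degenerate class, so
hit counts are monotone in pattern degeneracy and unknown bases never
manufacture hits. Minus-strand hits are found on the reverse complement
and reported in plus coordinates. All overlapping occurrences are
reported; counts mean occurrences, not covered positions. The shipped
dictionary encodes the common consensus strings for the surveyed elements
and marks every entry as a default to verify against the curated plant
cis-element databases — curated per-species element lists are not machine-readable, so no
per-species count is asserted anywhere.

## Structure comparison

`kabsch_superpose()` is the closed-form least-squares rigid superposition
via SVD with the determinant correction that excludes reflections;
collinear point sets (second singular value ≈ 0) are an error because the
rotation is not unique. The Q-score is
Q = N_align² / ((1 + (RMSD/R₀)²)·N₁·N₂) with R₀ = 3 Å — the standard
superposition-quality statistic of the secondary-structure-matching
tradition; because the score is often reported without an accompanying
definition, the formula choice is recorded in the output metadata. Correspondence defaults to
positional pairing of equal-length models and is otherwise user-supplied:
published aligned-residue counts depend on homology models that are not
reproducible from text, so the package exposes the pairing rather than
guessing it.

## Expression

The expression call is strict FPKM > 0, exactly as the rule is stated,
with the threshold exposed (default 0) because the rule is permissive.
Peak conditions break ties by file order and flag them.

## Problem sizes

The test suite and acceptance script run on: families of 8 species with a
5082 bp CDS (the reference architecture); the full 61 × 61 sense-codon
pair grid for the counting oracle; 100 simulated pairs at 1694 codons for
dN/dS recovery (the family's own CDS length, where the ratio-estimator
bias of small synonymous counts is negligible); 100 random additive
matrices of 5–8 taxa; 100–200 bootstrap replicates. These sizes were
chosen so each guarantee is tested at the scale of the reference family.

## Known limitations

* `spliced_align` is a greedy exact-anchor chainer, appropriate for
  same-species cDNA-to-genomic mapping; it is not a spliced aligner for
  cross-species mapping at high divergence.
* NG86 underestimates dN/dS when substitution is transition-biased; no
  codon model beyond NG86 is provided.
* NJ is the only tree method; no likelihood search, no rate
  heterogeneity.
* The consensus tie rule depends on the reference; two different
  references can yield different imputed columns (by design).
* The promoter dictionary is a starting point, not a curated database.
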