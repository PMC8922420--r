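---
title: "Methods: desk-scale analysis of river-water viral communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale analysis of river-water viral communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`rivervirome` implements a complete viral-metagenomics workflow for
multi-library freshwater surveys, together with a ground-truthed simulator
that stands in for the sequencer and the public protein databases. The
pipeline stages are:

1. **Read QC** — window-based PCR-duplicate removal, Phred tail trimming,
   adapter masking;
2. **Assembly** — per-library greedy overlap-layout-consensus with a
   length-based chimera filter, plus read-back mapping;
3. **Classification** — six-frame translated homology search against a
   viral protein database, competitive filtering against a non-virus
   non-redundant (NVNR) database, and profile-HMM rescue of remote
   homologs;
4. **Community ecology** — family/species abundance profiles, analytic
   rarefaction, Bray-Curtis distances, PCoA, UPGMA clustering, the
   Friedman rank-sum test, shared/unique species and top-10 rankings;
5. **Annotation and phylogenetics** — contig extension and merging, ORF
   prediction, hallmark-gene extraction (TerL, MCP, NS1, Rep, RdRp) and
   gap-masked neighbor-joining trees.

This vignette records the model assumptions, the parameters that matter,
and the design decisions taken where more than one faithful reading was
possible.

# Read cleaning

Reads are PCR duplicates when the bases inside a fixed window are
identical; one copy per duplicate group is kept, chosen uniformly at
random under the run seed. The window default is bases 5–55, read as
1-based inclusive coordinates (a 51 nt key). Reads shorter than the
window end key on their sequence from base 5, so short reads remain
dedup-able; reads shorter than base 5 key on their full sequence.

Quality trimming removes the *maximal 3' suffix in which every base is
below the Phred threshold* (default 10). This is deliberately the
simplest faithful tail rule — not the running-sum trimmer used by some
read cleaners — because only a threshold semantics is specified for the
workflow being reproduced.

Adapter removal is an ungapped suffix-versus-adapter-prefix comparison:
a read suffix of length $o \ge 10$ matching an adapter prefix with at
most $10\%$ mismatches is removed, longest qualifying match first. This
is a self-contained stand-in for VecScreen-style screening (which is a
BLASTn parameterisation); the package never shells out to external
aligners.

Stage order is dedup → quality trim → adapter trim. A consequence worth
knowing: when the quality tail eats into a short adapter remnant, the
leftover may fall below the 10 nt match floor and survive into assembly.
The overlap-identity threshold (98%) then keeps such tails from seeding
false joins.

# Greedy overlap assembly

Assembly is classic greedy overlap-layout-consensus: repeatedly merge
the pair of items (reads or growing contigs) with the longest
suffix-prefix overlap of at least `min_overlap` (30 nt) at
`min_overlap_identity` (0.98), breaking ties by the lexicographically
smallest id pair; consensus is per-position majority with quality-sum
tie-break. Both orientations are considered. Merged items are assigned
ids `c100001, c100002, …` in merge order, which makes the whole
procedure deterministic and reproducible.

Overlap candidates are found by exact 16-mer seeding on the right-hand
item's first 16 bases. With error-free simulated reads this is lossless
for overlaps at the identity threshold; on real data with scattered
errors it is a heuristic (an overlap whose first 16 right-hand bases are
corrupted is missed).

"Chimera filtering by length" is implemented as a minimum contig length
(default 250 nt): shorter merged items are demoted back to their member
reads as singlets. Read-back mapping counts a read as mapped when it has
an ungapped alignment of ≥ 50 nt at ≥ 95% identity to some contig on
either strand; the mapped percentage is taken over raw (pre-QC) reads.

# Translated homology search and classification

Queries are translated in all six frames under the standard genetic
code. Exact amino-acid 4-mers seed the search; each seed is extended
ungapped with an X-drop of 20, and subject/frame pairs whose best
ungapped extension reaches the trigger score (38) get a banded gapped
Smith–Waterman (band half-width 16 around the seed diagonal, BLOSUM62,
gap open 11 / extend 1). The ungapped trigger between seeding and gapped
extension bounds work on high-volume queries while keeping single-seed
sensitivity; on small inputs the test suite checks score equality
against full, seedless Smith–Waterman.

Raw scores convert to bit scores $S' = (\lambda S - \ln K)/\ln 2$ and
E-values $E = K m n e^{-\lambda S}$ with $m$ the query frame peptide
length and $n$ the total database residues. $\lambda = 0.267$ and
$K = 0.041$ are the published gapped BLOSUM62(11,1) constants; fixing
them (rather than calibrating per search) keeps E-values deterministic.
Hits require $E < 10^{-5}$.

**Competitive filtering.** A query is *viral* iff it has a viral hit
under the cutoff and either no NVNR hit under the cutoff exists or the
best viral bit score strictly exceeds the best NVNR bit score. A query
whose best evidence is an NVNR hit — including queries with *no* viral
hit at all — is *non-viral*; an exact bit-score tie is resolved to
non-viral. Both choices are conservative by design: the NVNR stage
exists to remove false-positive viral calls, and a sequence whose only
credible homology is non-viral should be reported as such even when no
viral candidate was found. Queries with no hit in either database are
*unclassified*, except that contigs are given a second chance through
the profile HMMs (below). Each viral query inherits the taxonomy of its
best viral hit (lowest E-value) — simple best-hit assignment, no LCA.

**Profile-HMM rescue.** Contigs — the queries long enough to carry
useful remote-homology signal — with no database hit are fragmented at
stop codons across all six frames and scored against each hallmark-gene
profile. Scoring is Viterbi/forward DP in log2-odds against the
background, global in the model and local in the sequence (free
background flanks). A best Viterbi score of at least 20 bits yields the
verdict `viral_by_hmm`. Rescued contigs are not re-screened against the
NVNR database; the rescue stage is meant for remote homologs that by
construction have no close relatives in either database. Profiles use
emission pseudocount 0.5 and transition pseudocount 0.05 — the small
transition prior keeps single- or few-sequence profiles from being
dominated by prior mass, so a profile built from one sequence strongly
recognises that sequence through an all-match path.

# Community ecology

Counts are viral-assigned *reads*: a singlet contributes 1, a contig its
mapped-read total. Relative abundances use viral-assigned reads as the
denominator. Queries rescued by HMM (which carry no taxonomy) are
tracked under the reserved taxon `unclassified virus`.

- **Rarefaction** is analytic (hypergeometric):
  $E[S_n] = \sum_i \left(1 - \binom{N-N_i}{n}\big/\binom{N}{n}\right)$,
  computed through `vegan::rarefy`.
- **Bray-Curtis**: $d(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$
  via `vegan::vegdist`; a pair of all-zero libraries is defined to be at
  distance 0.
- **PCoA** is classical metric scaling (`stats::cmdscale`): Gower-centre
  $-D^2/2$, eigendecompose, scale eigenvectors by the square root of
  positive eigenvalues. Negative eigenvalues (routine for semi-metric
  ecological distances) are reported, never corrected.
- **UPGMA** is size-weighted average-linkage agglomeration
  (`hclust`/`phangorn::upgma`); leaf heights are half the merge
  distance, so the tree is ultrametric. Labels are sorted
  lexicographically before clustering so tie-breaking is reproducible.
- **Friedman test**: taxa are blocks, libraries are treatments — the
  question is whether the six sites differ, so sites are the
  "treatments" compared within each taxon. Mid-ranks with the standard
  tie-correction divisor $1 - \sum(t^3 - t)/(b(k^3 - k))$ are used, as
  implemented by `stats::friedman.test`; an all-tied profile returns
  statistic 0 and p = 1 by convention. The test suite verifies the
  statistic against an independently coded textbook formula and checks
  the empirical type-I error under a within-row permutation null.
- **Venn regions** are computed exactly by membership-pattern counting
  (six libraries in scope; the pattern space is small).

# Annotation and phylogenetics

Viral contigs are first extended by mapping reads over their ends
(≥ 20 nt overlap at ≥ 95% identity, majority-vote overhang consensus,
default one round) and then merged when their best hits target the same
subject protein on disjoint, consistently ordered subject intervals;
joins use a 100 N spacer, recorded in provenance. The spacer length is
arbitrary but harmless: ORF calling cannot cross a run of `N` (ambiguous
codons translate to `X`, never to a start or a sense codon chain), and
downstream steps carry member provenance.

ORFs are predicted on both strands in all frames: ATG start, standard
code, minimum size 300 *nucleotides* including the stop codon. The
nucleotide reading of the minimum size follows the convention of desktop
annotation suites and is consistent with hallmark sequences shorter than
300 amino acids being reported in survey work. Nested ORFs sharing a
stop report the longest (first ATG). An ORF is *complete* when both its
ATG and its stop lie inside the contig; ORFs running off the edge are
reported incomplete and excluded from phylogenies.

ORF peptides are annotated by their best database hit under
$E < 10^{-5}$, else labelled "putative protein". Hallmark genes map to
fixed target groups: TerL → *Caudovirales*, MCP → *Microviridae*,
NS1 → *Parvoviridae*, Rep → CRESS-DNA viruses, RdRp → *Riboviria*.

Complete hallmark peptides are aligned progressively: pairwise 3-mer
distances feed a UPGMA guide tree; profiles are merged by global affine
profile-profile alignment (BLOSUM62, gap open 8 / extend 1). Columns
with strictly more than 50% gaps are removed before tree building.
Trees are neighbor-joining on p-distances (mismatch fraction over
mutually ungapped columns), with negative branch lengths clamped to
zero. Bayesian or maximum-likelihood inference is deliberately out of
scope at desk scale; NJ fills the same role (a distance-based summary of
hallmark-gene diversity) and is exactly checkable against closed-form
examples.

# The simulator and what it does (not) show

The generator emulates a six-site river survey plus a blank control:

- **Community**: 17 viral families — nine dsDNA (tailed-phage families
  dominant), four ssDNA (*Microviridae*, *Parvoviridae* and two
  CRESS-DNA families) and four RNA families — with default base
  abundances dominated by *Caudovirales*-like phages, mild lognormal
  site-to-site jitter, and one site (Nanjing) carrying a strong
  *Parvoviridae* bloom. The default reference set holds 34 species (two
  per family, geometrically weighted within families).
- **Genomes**: random nucleotide backbones at scaled-down lengths
  (≈ 12 kb dsDNA, ≈ 5 kb ssDNA, ≈ 8 kb RNA, ± 10%) with implanted ORFs
  at ≈ 85% coding density: one family hallmark gene plus accessory
  proteins. Hallmark peptides descend from per-gene ancestors via
  family-level (25%) and species-level (8%) point mutations plus
  occasional short indels, so profiles and trees see realistic
  divergence structure. Scaled-down genome lengths keep the run desk
  sized while leaving duplicate-collision bias in the abundance
  estimates far below the sampling noise.
- **Background**: 12 bacterial/host-like genomes whose implanted
  proteins form the NVNR database; 20% of NVNR proteins are decoys
  carrying short (6-aa) segments copied from viral proteins, so the
  competitive filter faces genuinely ambiguous seeds.
- **Reads**: single-end 250 nt uniform substrings (either strand),
  linear 3'-quality decay from Q37 to Q9 with jitter, 10% PCR duplicate
  re-emissions, 10% of reads carrying a 14–30 nt adapter prefix at the
  3' end. Paired-end layout is metadata only — no pipeline stage uses
  pairing. The default depth is 10,000 reads per sample library (± 8%)
  and 1% of that for the control, i.e. ≈ 60,000 reads per survey, with
  an 80% non-viral background fraction chosen so the viral-mapped read
  percentage lands in the low tens of percent, as is typical for
  filtered freshwater viromes.

Everything is seeded: one integer seed drives per-operation derived
streams, and identical seeds give byte-identical outputs end to end.

What the simulator deliberately omits — and hence what green tests do
*not* demonstrate about real data: there is no substitution/indel
sequencing-error model (only quality decay), no chimeric library
artefacts, no strain-level microdiversity, no uneven genome coverage
(GC bias), and databases are complete for the simulated community
except where a test removes entries on purpose. Classification
accuracy, assembly contiguity and abundance fidelity measured here are
therefore upper bounds; the value of the synthetic runs is exactness of
ground truth, not realism of noise.

# Numerical conventions and degenerate inputs

- Alignment coordinates are 0-based half-open (GFF3 output converts to
  1-based inclusive); dedup window coordinates are 1-based inclusive.
- The E-value uses the per-frame peptide length as $m$; the best local
  alignment per (query, subject) across frames defines the reported hit.
- Ties: duplicate representative chosen uniformly under the seed;
  assembly ties by smallest id pair; competitive-filter bit ties →
  non-viral; top-species count ties → lexicographic.
- Degenerate inputs: empty libraries flow through every stage as empty
  tables with zeroed reports; an all-zero distance pair is at
  Bray-Curtis distance 0; a fully tied Friedman profile returns p = 1;
  NJ branch lengths are clamped at 0.
- Problem sizes in the shipped tests: oracle equivalences run at
  ≤ 200 reads (dedup), ≤ 30 reads (assembly), ≤ 30 aa (alignment),
  2-position models (HMM), 5×5/10×4 matrices (UPGMA/Friedman); the
  end-to-end synthetic survey runs at the default ≈ 60,000-read scale;
  the Friedman null calibration uses 2,000 seeded permutations.

# Known limitations

- The greedy assembler is exact-seeded and mismatch-tolerant only inside
  verified overlaps; it is not a de Bruijn assembler and will fragment
  genuinely repetitive genomes.
- Best-hit taxonomy has no lowest-common-ancestor fallback; a query
  equidistant from two species is assigned to the better-scoring one.
- The banded gapped extension can in principle miss alignments whose
  optimal path drifts more than 16 diagonals from the seed; at the
  divergence levels simulated this does not occur (and the test suite
  cross-checks small cases against full Smith–Waterman).
- Profile HMMs are single-domain and un-calibrated: scores are honest
  log-odds, but the 20-bit rescue threshold is a package default, not an
  E-value.
- CCA-style constrained ordination and differential-abundance testing
  are out of scope; the ecology layer reports unconstrained structure
  only.
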