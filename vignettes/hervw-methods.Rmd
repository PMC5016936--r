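---
title: "Methods: reference-anchored characterization of HERV-W loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-anchored characterization of HERV-W loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hervw)
```

This vignette is the package's own account of its models, parameters and
design choices.  It states no empirical result that the test suite does not
itself compute.

## The coordinate backbone

Every analysis in this package reads element bases through the coordinate
frame of a single group reference: an LTR–internal–LTR assembly of
10,186 nt with 780-nt LTRs.  Canonical landmarks (1-based, inclusive):
5′ LTR 1–780, *gag* 2718–4191, *pro–pol* 4195–7692, *env* 7720–9348,
3′ LTR at the tail; nucleocapsid zinc fingers at 4021–4062 and 4093–4130,
integrase GPY/F at 7501–7521, an *env* island at 8289–8318 that survives
the surrounding recurrent deletion, and a PBS window at 784–801 (internal
positions 4–21).  Within the LTR, U3 = 1–255, R = 256–326, U5 = 327–780;
the two R boundaries (256 and 326) double as the truncation anchors of
L1-processed pseudogenes.

Two deliberate coordinate decisions:

* The literature prints the 3′ LTR as 9406–10186, which is 781 nt while
  the LTR consensus is 780 nt.  We require the two LTR landmarks to be the
  same length (the LTR–LTR molecular clock depends on a shared frame), so
  the canonical 3′ LTR is 9407–10186.
* The second zinc finger's printed interval (4093–4130, 38 nt) cannot hold
  the 13-residue CX2CX3HX4C motif (39 nt).  The landmark keeps the printed
  interval; motif work pads landmark slices to the next codon boundary.

Elements are anchored to this frame by one global affine-gap alignment
(compiled Gotoh DP).  Default scores — match +1, mismatch −2, gap open −5,
gap extend −1 — are long-indel-tolerant because most elements of the group
carry kilobase deletions; they are configurable, and downstream results
near the 20 % retention boundary are mildly parameter-sensitive.  `N`
matches anything at score 0.  Ties break deterministically
(diagonal > gap-in-query > gap-in-reference).  For projection we restrict
the DP to a diagonal band: the optimal path's offsets are bracketed by the
net length difference, padded by a 600-nt margin (covering the recurrent
deletions plus drift).  Banded and full alignments are verified identical
on representative elements in the test suite; `band_margin = NULL` forces
the full DP.

A consequence of cheap gap extension worth knowing: the "identity over
aligned columns" statistic stays high even for unrelated input, because
the optimal alignment parks unalignable stretches in gaps.  The
`not_group_member` flag (identity < 0.5) therefore fires only for inputs
that are forced to align column-by-column; with stiff gap penalties it
behaves like a conventional identity filter.

## The synthetic world

The reference objects that normally come from sequence databases cannot be
downloaded in this build environment, so the package ships deterministic
**synthetic stand-ins** (filenames prefixed `synthetic_`, regenerated by
`data-raw/make_fixtures.R`): a 10,186-nt reference whose landmarks, key
positions, PBS, zinc fingers, GPY/F, AG-rich leader and 538-aa Env CDS are
planted at the canonical coordinates; a tRNA 3′-end library in which every
tail ends CCA (so every PBS starts TGG, as in the real group, and entries
are ≥ 6 mismatches apart); and a 538-aa Env precursor carrying the furin
RKNR site, SU CWIC, TM CX6CC, the receptor-binding SDGGGX2DX2R motif, the
fusion-peptide alanine at residue 332, the heptad-repeat arginine at 433,
an immunosuppressive-domain stretch, and *no* LQMV at the R-peptide
cleavage window (the 4-residue deletion that makes the real protein
constitutively fusogenic).  Base and residue identities outside these
constraints are random; conclusions that depend on real sequence content
do not transfer, while everything coordinate- and algorithm-level does.

The simulator inverts the group's descriptive biology into a generator:

* **provirus** — full reference copy;
* **processed pseudogene** — 5′ LTR truncated to start at 256, 3′ LTR cut
  at 326, a poly(A) tail (default 12 nt, ≥ 8), "TT" closing the 5′ flank
  and a TSD beginning "AAAA" (the L1 endonuclease signature), TSD length
  5–15 (uniform in cohorts);
* **solo LTR** — a single LTR with flanks and TSD.

Subgroup ground truth installs the key-position alternates in **both**
LTRs (all 7 main positions for subgroup 2, plus the 2A or 2B tier).
Deletions are explicit reference intervals (the four recurrent ones are
packaged); the neutral clock is substitutions-only at 0.13 %/nt/My with a
transition/transversion ratio κ = 2 (no HERV-W-specific estimate exists in
the source material; κ = 2 is a generic mammalian default, and the dating
modules do not depend on it).  Each LTR mutates under an independent
substream, so the LTR–LTR divergence of an age-*T* provirus is two
independent 0.13·*T* % branches.  Keeping indels out of the clock keeps
the dating ground truth exact; flanks are i.i.d. uniform DNA and are not
mutated.  Everything is bit-reproducible from the spec's seed.

What a green test therefore establishes: the algorithms recover planted
structure, genotypes, ages, breakpoints and reading frames under neutral
substitution noise at realistic rates.  What it does not establish:
robustness to CpG-hypermutation rate heterogeneity, nested/tandem
insertions, flank mutation, or real genomic repeat context.

## Structural classification

Retention per landmark is the covered fraction of its reference interval;
"retained" means ≥ 0.20 with ties retained.  The classifier:

1. **provirus** if the 5′ LTR covers ≥ 50 % of U3 *or* the 3′ LTR covers
   ≥ 50 % of U5 (at least one LTR shows the full-length form);
2. **processed pseudogene** if neither does, the observed truncation
   points sit within ±25 nt of the 256/326 anchors, and at least one of
   {poly(A), TSD, TT/AAAA} is present (`strict_signatures = TRUE`
   additionally demands the TSD; the source material lists the three
   hallmarks without saying how many were required, and requiring all
   three would misclassify eroded elements);
3. **undefined** otherwise.

Truncation points are read from the *longest* covered run of the LTR, not
the raw first/last covered position: a poly(A) tail happily aligns to any
A-rich patch and must not move the observed terminus.  The ±25 nt
tolerance is ~3 % of the LTR, allowing eroded termini.  The poly(A)
detector accepts one interruption in a ≥ 8-A run ("variable length" tails
decay in old elements).  With empty flanks, TSD and TT/AAAA are
*undeterminable* (`NA`), never false.  Solo LTRs are outside the
classifier's label set: a solo LTR projects onto an LTR landmark with its
U3 intact and is labeled provirus by rule (1); callers that simulate solo
LTRs should treat the label accordingly.

## Subgroup calls

Genotypes are read at the key positions of whichever LTRs exist, in the
780-nt LTR frame; pseudogenic forms observe only positions ≥ 256 (5′,
R-U5) or ≤ 326 (3′, U3-R) — which is why the 3′ LTR of a pseudogene still
carries 5 of the 7 main positions and remains classifiable.  Pooled over
both LTRs, the main-tier alt fraction decides: ≥ 0.6 → subgroup 2,
≤ 0.4 → subgroup 1, at least 3 observations required, abstention in
between.  The dead zone is deliberate: the source classification rests on
tree clusters with weak bootstrap support validated by key positions with
a 95–100 % versus 0–3.5 % frequency split, so a vote with an explicit
abstention band is more reproducible than guessing at intermediate
fractions.  2A requires both its positions alt and the 2B criterion not
met (and symmetrically for 2B): the extra tiers are documented as not
mutually exclusive, so conflicts degrade to plain 2.

Consensus building is per reference column: majority base among non-gap
observations, ties resolved toward the reference (stability under
resampling), columns gapped in more than half the members emit nothing.

## Dating

Three methods per element: (1) 5′ versus 3′ LTR, T halved; (2) each LTR
versus the subgroup consensus LTR; (3) ~300-nt windows centered in *gag*,
*pro*, *pol*-RT, *pol*-IN and *env* versus the consensus (the retained
portion if shorter).  All divergences are K2P with gap columns excluded
and, by default, every column in CpG context *in either sequence* excluded
(both positions of the dinucleotide); the source's convention is
ambiguous, so the switch is exposed.  Distances need ≥ 50 surviving
columns and a non-saturated log domain, otherwise the method is dropped
for that element.  The per-element summary is the mean and sample SD over
the available methods; SD/mean > 0.20 flags the element, and cohort
summaries exclude flagged elements rather than silently dropping
individual methods — the source's exclusion protocol ("excluding those
value with a standard deviation > 20 %") does not say which reading was
intended, so the element-level flag keeps both options open.

Using the reference as the stand-in ancestor inflates consensus-based ages
for subgroup-2 elements (their key-position alternates count as
divergence); passing the subgroup's own consensus removes the bias.  This
mirrors the method's stated assumption that the consensus represents the
ancestral state.

## Phylogeny

p-distances use pairwise deletion with a 30-column minimum overlap per
pair.  Neighbor joining is the canonical Saitou–Nei agglomeration with two
determinism guarantees: among tied minimal Q values the lexicographically
smallest label pair joins, and negative branch lengths clamp to zero (and
are counted).  Trees are unrooted and serialized with an arbitrary
trifurcating root, so comparisons should use split sets (`tree_splits()`),
not rooted shapes.  Bootstrap resamples reference columns with
replacement — with reference-anchored pairwise alignments, columns *are*
reference positions, which is equivalent to resampling the columns of a
multiple alignment for this use.  Replicates with an undefined distance
are dropped and counted (> 20 % dropped is an error).  Splits carried by
zero-length edges report support 1.0: with identical sequences every
resolution is arbitrary and equally supported, and the policy keeps the
degenerate case deterministic.  The convention is 500 replicates; tests
use 100 for speed.

## PBS and motif features

The PBS is the 18-nt window at reference 784–801, scanned at ±3 nt of
offset; each tRNA type's expected PBS is the reverse complement of its 3′
18-mer.  Assignment requires ≤ 4 mismatches and a unique best hit —
otherwise "ambiguous", matching the observation that near-identical tRNA
types (W/R) can tie after a single-nucleotide shift.  Zinc fingers are
regular patterns CX2CX4HX4C and CX2CX3HX4C; GPY/F is WXnGPY/FXV with the
unbounded spacer capped at 3–30 residues (the canonical hit must fall in
the integrase landmark, so a generous bound plus landmark filtering is
safe).  Composition flags are A-rich > 0.28 and G-poor < 0.24 (around the
group's reported ~30 % A / ~22 % G bias); the AG-rich leader is reported
as the longest ≥ 100-nt window with purine fraction ≥ 0.7 between the 5′
LTR and *gag* — descriptive only.  Sequence logos are replaced by numeric
position frequency matrices with per-column information content.

## Env puteins

`reconstruct_putein()` translates all three frames, aligns each
translation to the Env precursor reference (BLOSUM62), and stitches one
protein by a Viterbi pass over reference residues in which switching
frames costs 10 matched residues — a frameshift must buy a sustained
identity gain, which suppresses single-residue frame hops; the source
reconstructed puteins manually and gives no stitching rule, so the penalty
is this package's explicit convention.  Stops within the final 5 % of the
aligned span count as terminal, not internal — likewise our convention,
since published stop/shift counts do not say whether genuine terminators
were counted.  Domain statuses (conserved / substituted / truncated /
absent) are read off the putein-to-reference alignment at fixed reference
residue coordinates from the packaged configuration; the LQMV R-peptide
site reports *deleted* when the four residues are absent at the cleavage
window — as in the reference protein itself — and *present* when a putein
carries the ancestral insertion.

## Mosaic assignment

Candidates come from ranking loci by identity over the query's covered
span (ties: fewer discordant bases, then id).  The segmentation DP charges
1 per mismatching column, 1 per candidate gap run (a k-nt indel is one
discordance, the same rule as `count_discordant()`; whether the original
transcript tables counted gap runs once or per base is not stated, so the
rule is switchable there), and λ = 4 per template switch, so a breakpoint
must save at least four discordant bases — single-SNP "recombination" is
suppressed.  λ = 0 degenerates to the per-column best locus and λ = ∞ to
the single best locus.  Between two informative columns every breakpoint
placement is cost-optimal; the reported breakpoint is the midpoint of that
tie interval, the minimax choice (at 5 % inter-locus divergence
informative columns are ~20 nt apart, so raw left- or right-edge reporting
would misplace breakpoints by the full gap).

## Genomic context

Gene/exon features are supplied locally (data frame, GFF3 or BED; no
network access ever).  Introns are derived as gene minus exons; a locus is
intronic/exonic/mixed by which derived parts it touches, the host gene is
the maximal-overlap gene, and orientation is sense iff strands agree.
Interval arithmetic is 0-based half-open internally (GenomicRanges) and
1-based inclusive at the interface.

## Numerical and testing conventions

Acceptance criteria run against the synthetic world at its stated sizes
(200-element classifier cohorts, 100-LTR subgroup panels, 100 chimeras,
100 putein constructions) with fixed seeds chosen before the criteria were
evaluated.  Dating recovery extracts the two LTRs of each simulated
provirus from the simulator's truth intervals: the criterion measures the
estimator, and the substitution-only clock keeps both LTRs exactly 780 nt,
so they pair without re-alignment.  Oracles are deliberately naive
re-implementations (column-counting K2P, full-matrix NW score, exhaustive
segmentation, per-base interval overlap, random additive trees) kept in
the test helpers, independent of the package code paths they check.

## Known limitations

* No insertion polymorphism, nested elements, or primate orthology; the
  out-of-scope discovery steps (genome-wide search, repeat masking,
  ortholog dating) are not reimplemented.
* The clock has no rate heterogeneity and no CpG-context mutation model —
  CpG exclusion in K2P is therefore conservative on simulated data.
* Identity-based group membership flagging is weak under the default
  long-indel-tolerant gap scores (see above).
* The synthetic reference stand-ins preserve geometry, not sequence
  content; analyses that depend on real base identities (e.g. comparing
  against database sequences) require user-supplied references via
  `load_reference()`.
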