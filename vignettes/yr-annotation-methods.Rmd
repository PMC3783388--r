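---
title: "Methods: structural annotation of DIRS and Ngaro retrotransposons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural annotation of DIRS and Ngaro retrotransposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`yrscan` annotates tyrosine-recombinase (YR) retrotransposons in nucleotide
assemblies. The two superfamilies it targets differ along two independent
axes, and the pipeline exploits both:

* **domain composition** — both superfamilies encode reverse transcriptase
  (RT), RNase H (RH) and the YR integrase; a DNA N-6-adenine
  methyltransferase (MT) occurs only in DIRS;
* **terminal-repeat order** — DIRS elements are bounded by inverted
  terminal repeats (ITRs, with an optional internal complementary region),
  Ngaro elements by split direct repeats in `A1 – core – B1 – A2 – B2`
  order.

The pipeline stages are: six-frame translation with invertible coordinate
maps; profile scanning of every frame; merging of frame-split hits into
element cores; repeat-structure resolution around each core; rule-based
classification; greedy identity clustering into families; an all-vs-all
similarity graph over family representatives; and a neighbor-joining tree
of representatives. Each stage is exposed as ordinary R functions, and the
`yr_pipeline()` driver chains them.

# Six-frame translation

Translation uses the standard genetic code. Stops are retained as `*`
rather than splitting the translation into ORFs: decayed elements carry
in-frame stops, and a profile match interrupted by a stop is still evidence
of a domain. The scanner charges a fixed −8 for a stop aligned to any
profile column — strongly deleterious but survivable for an otherwise good
match. Codons containing N translate to `X`, which scores exactly 0 against
every column, so assembly ambiguity neither creates nor destroys hits.

Every peptide position maps back to a unique forward-strand genomic
interval (`map_to_genome()`); the map is exact and invertible on all six
frames, which the tests fuzz over random windows.

# Domain profiles and scanning

Profiles are position score matrices over the 20 amino acids. Scores are
natural-log odds with a +1 pseudocount against a background distribution
(uniform 1/20 by default):

    s_a = log( ((c_a + 1) / (N + 20)) / bg_a )

where `c_a` counts residue `a` in the seed-alignment column and `N` is the
number of members. The normalised pseudocount keeps never-observed residues
mildly negative, which is what gives local alignments a negative drift on
random sequence — the property the scanner's specificity rests on.
Columns with more than 50% gaps are dropped before scoring.

Scanning is local (Smith–Waterman) alignment of each frame translation
against each profile with affine gaps (defaults −10 open, −2 extend per
residue). All non-overlapping local optima at or above the profile's score
threshold are reported, greedily from the best score with aligned-region
masking. Long translations are scanned in overlapping chunks (5000 aa,
overlap 400 aa) purely to bound memory; since no reportable alignment
approaches the overlap length, results equal a single-pass scan, and a test
asserts exactly that. The per-profile threshold defaults to 30% of the
profile's maximal self-score; for the packaged ~50–60-column profiles this
sits far above the maxima observed on megabases of simulated random
translations while remaining below the score of a planted domain decayed to
~50% residue identity.

Each reported hit receives an **empirical shuffle p-value**: the matched
peptide stretch (plus 30 residues of context) is residue-shuffled
`n_shuffles` times (default 199) and rescanned;
`p = (1 + #[shuffled ≥ observed]) / (n_shuffles + 1)`. The pipeline keeps
hits at `p ≤ 0.01`. This self-contained null replaces extreme-value
E-values; it is deterministic given the run seed.

HMMER3 ASCII profiles (`HMMER3/f`, amino alphabet) can be read directly:
match-state emissions are converted to log-odds columns, and insert states
are deliberately not modelled — gap structure is carried by the two
per-profile affine constants. The intent is profile *scanning*, not full
plan7 decoding; fidelity is tested against an exhaustive dynamic-programming
oracle rather than against HMMER bit scores.

`build_profile_from_members()` constructs a profile from ≥ 5 member
peptides (aligning them first with the internal progressive aligner when
they are unaligned), which also supports the workflow of rebuilding a
domain profile from clustered representatives when the RT/RH parity check
(below) flags profile insensitivity.

# Merging hits into cores

Hits on one sequence and strand are chained by single linkage whenever
their intervals are within `max_gap_nt` (default 3000 nt — a few kilobases
matches the span of a multi-domain *pol* region; no canonical value exists,
so it is configurable). Same-class hits overlapping by more than half of
the shorter hit are first deduplicated (best score, ties by longer
alignment then leftmost start). A core whose retained hits occupy more than
one frame on the same strand is flagged `has_frameshift` — the expected
signature of the frameshifted Ngaro YR ORF. Opposite strands never merge,
so nested elements on opposite strands surface as separate cores.

The **RT/RH parity report** (`qc_rt_rh_parity()`) counts RT- and RH-bearing
cores. The two domains co-occur in the *pol* region, so a surplus of
RH-only cores indicates an insensitive RT profile; the report flags, never
deletes.

# Repeat-structure detection

Both detectors share one ungapped matcher. Candidate pairing offsets
(diagonals) come from shared exact 11-mers; when the two search windows are
small (product ≤ 600 × 600 nt) every diagonal is enumerated instead, making
the search exact — seeding is purely a speed optimisation for genome-scale
flanks. On each diagonal the candidate is the maximum-scoring segment under
+1 match / −2 mismatch scoring (N never matches). Ties on the segment score
prefer the *shortest* window, then the leftmost start: zero-net fringes of
chance matches are trimmed, which keeps reported boundaries tight.
Candidates must be ≥ 20 nt at ≥ 80% identity (defaults; both configurable),
and structures are ranked by `length × identity`.

* `find_itr()` matches the upstream flank against the reverse complement of
  the downstream flank (flank width 2000 nt by default); copies may overlap
  the domain envelope by at most 30 nt, which prevents coding sequence from
  doubling as "repeat".
* `find_split_direct()` forms A-pair candidates (one copy upstream, one
  downstream) and B-pair candidates (both downstream, searched in a window
  of twice the flank width so it can hold B1, A2 and B2), then scores every
  (A, B) combination satisfying `start(B1) < start(A2) < start(B2)` with
  all three after the core, by `len_A·id_A + len_B·id_B`. The element outer
  boundary is `start(A1)..end(B2)`. For minus-strand cores the same
  algorithm runs on the reverse complement of a window around the core and
  the copies are mapped back to forward coordinates.
* `find_icr()` searches the element interior for a segment matching the
  reverse complement of the left ITR copy (minimum 15 nt). It is reported
  as supporting evidence only and never required for classification.

The choice of ungapped candidate segments reflects the data: terminal
repeats decayed by substitutions stay on one diagonal, and the exhaustive
oracle the tests compare against (every diagonal, every window, identical
scoring and tie-breaks) is then well defined. Indels inside a repeat copy
split it into two candidate segments, of which the better is used — a
conservative behaviour that shortens, never misplaces, a boundary.

# Classification

`classify_superfamily()` applies a fixed ladder: (1) an MT hit implies
DIRS; (2) ITR implies DIRS; (3) split direct repeats imply Ngaro; (4)
otherwise the best hit of each domain class votes through its profile
affinity tag (`DIRS-specific` / `Ngaro-like` / `generic`, generic
abstains); (5) ties or all-generic evidence yield `undetermined`. MT
together with split direct repeats is contradictory and yields
`undetermined` with both evidences recorded. MT outranks repeat evidence
because it is the one domain unique to DIRS; repeat order is the second
axis; affinity voting mirrors the use of superfamily-specific profiles.

`call_completeness()`: an element is `complete` when it has the full
expected domain set (DIRS: RT, RH, MT, YR; Ngaro: RT, RH, YR), every hit
covers ≥ 80% of its profile, and the full repeat structure was found;
`remnant` when every hit covers < 50% or only one domain class is present;
`truncated` otherwise. The 0.8/0.5 coverage cutoffs are declared
conventions — the underlying distinction is qualitative — and are
configurable at the profile-coverage level.

Clade assignment (`Ngaro1..4`, and DIRS lineages `DIRS_A`/`DIRS_B`) scores
the element's available RT/RH/YR hit peptides against per-group motif
profiles; the winner is reported with margin `(best − second)/|best|`, and
margins below 0.05 give `unassigned`. Ngaro clades 1 and 4 share motifs by
construction, so near-ties between them are genuinely ambiguous and the
margin rule makes that explicit. The packaged motif profiles are
**synthetic reconstructions** (seed alignments generated together with the
generator's consensus peptides), not sequences copied from any database;
clade assignment can therefore be validated only on synthetic data.

# Families, similarity graph, layout

Concatenated best-hit peptides (fixed RT, RH, YR, MT order, absent domains
skipped) are clustered greedily: sequences sorted by length descending
(ties lexicographic), each joining the first representative at ≥ 60%
identity, else founding a cluster. Identity is the number of identical
aligned residues in the optimal global alignment (match +2, mismatch −1,
gap open −2, extend −1) divided by the *shorter* length — the CD-HIT
denominator convention. The mismatch and gap penalties matter: a
gap-free-cost alignment would chase matches through unrelated sequence and
inflate identity between non-homologs. A shared-word prefilter (word length
4) applies the standard exclusion bound; at the 0.60 threshold it is
intentionally permissive (CD-HIT uses short words at low thresholds for the
same reason), so correctness never depends on it.

The similarity graph computes all-vs-all local BLOSUM62 scores (gap −11/−1)
and converts each to a p-value under a Gumbel null fitted by the method of
moments (location/scale from mean and SD) to 50 shuffles of the shorter
sequence; edges are kept at `p ≤ 1e-06`. P-values are floored at 1e-300;
a degenerate null (zero variance) maps scores above the null mean to the
floor and everything else to 1. Connected components (via igraph) define
the higher-level grouping. The seeded force-directed 2D layout (edge
attraction ∝ −log10 p, all-pairs repulsion, linear step decay) is for
visualisation only — no classification decision reads coordinates.

In the pipeline the graph and the tree are built over family
representatives; clustering first removes near-identical copies, which is
also what keeps the quadratic all-vs-all stage cheap.

# Representative tree

For each of RT, RH and YR (MT is DIRS-only and excluded so the matrix stays
comparable across superfamilies), representative hit peptides are aligned
with the internal progressive aligner: a guide tree from pairwise 3-mer
distances (UPGMA — progressive merging needs a rooted merge order, which is
why UPGMA stands in for an unrooted NJ guide here), then profile–profile
global alignments on BLOSUM62 expected-substitution column scores
(gap −11/−1). Columns with more than 5% gaps are removed — a gap-fraction
rule approximating strict conserved-column selection — and the partitions
are concatenated, padding elements missing a domain with all-gap rows
rather than dropping them, so incomplete elements stay in the tree.

Distances are computed over columns where both rows are ungapped:
p-distance by default in the pipeline (bounded, robust for decayed
remnants), Poisson (−ln(1 − p)) available and used where distances should
be additive; a saturated pair (p = 1) is an explicit error under the
Poisson model, as is a pair with no shared ungapped columns. Trees come
from Saitou–Nei neighbor joining (negative branch lengths clamped to zero
with a warning) and can be rooted on a user-supplied outgroup: the root is
placed at the midpoint of the branch separating a monophyletic outgroup,
and a non-monophyletic outgroup is an error naming the offending tips.
Distance-based NJ deliberately replaces maximum-likelihood inference: the
claim this stage supports — that DIRS and Ngaro representatives separate
into disjoint clades — is testable at the distance level, and ML would add
heavy numerics without changing that claim.

# The synthetic-genome generator

`synthesize_element()` builds one element from packaged per-group consensus
peptides (reverse-translated with seeded codon choice) in the architecture
of its superfamily; `synthesize_genome()` places elements on i.i.d.
background at a stated GC content, in random order and orientation. Decay
is applied in a fixed order — substitutions uniformly at rate `mu`,
truncation of a stated fraction from a uniformly chosen end, then outright
deletion of listed domains — and the truth annotations are updated to
post-decay coordinates. Truncation and loss produce exactly the remnant
states the classifier must handle.

Two generator design points deserve emphasis:

* **Spacing.** Top-level elements are separated by at least `min_spacing`
  (default 5000 nt), which exceeds the default hit-merging distance, so two
  distinct planted elements can never be chained into one core. Nested
  insertions (probability `nesting_prob`) go into a host element's
  interior, avoiding its domains and repeat copies.
* **Unambiguous termini.** Background immediately flanking a planted repeat
  can chance-match the repeat's extension partner, in which case the genome
  truly contains a longer repeat than the recorded truth and "the planted
  boundary" is not a well-defined quantity. The generator therefore forces
  the two background bases outside each outer repeat end to mismatch their
  pairing partners. Only background is touched; element sequence and truth
  coordinates are unchanged.

The study conditions used by the acceptance checks are the generator's
defaults: intact study — 20 elements (10 DIRS, 10 Ngaro) in 500 kb at
`mu = 0`; decayed study — 200 elements at `mu = 0.10` with 30% of elements
truncated (each truncated element losing a uniform 10–50% from a random
end) in 2 Mb, plus 1 Mb of element-free background. Repeat copy lengths
default to 150 nt (ITR) and 100 nt (A and B) — within the range reported
for these superfamilies and long enough that a 10% substitution rate leaves
them near the 0.80 identity floor, exercising the detector's hard region.

What the generator does **not** emulate: real fungal base composition
(isochores, RIP signatures), insertion-age structure, segmental
duplications, tandem repeats, or assembly artefacts. Passing tests
demonstrate algorithmic correctness against a clean truth model, not
performance on real assemblies; on real data, profile quality (packaged
profiles are synthetic stand-ins — users should supply Pfam/CDD-derived
HMMER3 profiles via `read_hmmer3_profile()`) and repeat-region assembly
quality will dominate.

# Numerical and determinism choices

* All internal coordinates are 0-based half-open; every file written
  (GFF3, TSV) is 1-based inclusive. A round-trip test pins the convention.
* Non-ACGTN IUPAC codes collapse to N on input (counted per record);
  N is a universal mismatch in repeat detection and X in translation.
* Every stochastic step (shuffle nulls, simulation, layout) takes an
  explicit seed; per-pair and per-hit seeds are derived deterministically
  from the run seed, so reruns are identical and results do not depend on
  evaluation order.
* Tie-breaks are fixed everywhere: hit dedup by score, then longer
  alignment, then leftmost; repeat candidates by `length × identity`, then
  segment score, then length, then leftmost; greedy clustering order by
  length then identifier.
* Degenerate inputs have defined behaviour: records shorter than 3 nt
  translate to empty peptides with a warning; an empty element list writes
  a header-only GFF3; a zero-variance shuffle null yields p = 1e-300 or 1;
  trimming that removes every column is an error.

# Limitations

* Repeat copies are modelled as ungapped direct (or inverted) matches;
  heavily indel-riddled repeats are shortened or missed rather than
  gap-aligned.
* The scanner's profile model has no insert states and no
  composition-adjusted statistics; its p-values are empirical and
  resolution-limited by `n_shuffles`.
* Clade/lineage assignment is only as good as the motif profiles supplied;
  the packaged ones are synthetic.
* VIPER elements, target-site duplications, tandem-repeat annotation and
  genome-wide de novo repeat-family discovery are out of scope.
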