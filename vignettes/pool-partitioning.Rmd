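---
title: "Models and methods behind poolprimers"
author: "poolprimers maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poolprimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

Large multiplex PCR panels — preamplification pools of hundreds to thousands
of primer pairs ahead of targeted sequencing — fail in two characteristic
ways: primers cross-hybridize (primer dimers compete with the template), and
in tiling designs overlapping amplicons placed in the same reaction yield
short chimeric products instead of the intended full-length ones.
`poolprimers` quantifies both risks and then splits the panel into a
user-chosen number of subpools so that the strongest risks never share a
reaction.  This vignette explains the models, the tunable parameters, and
the design decisions where the choices were genuinely open.

## Bit-plane bonding model

Every primer is encoded in two parallel bit planes: `at_plane` (base is A or
T) and `gt_plane` (base is G or T), giving A = 10, C = 00, G = 01, T = 11.
Two bases are Watson–Crick complementary exactly when their A|T digits are
equal and their G|T digits differ, so the bonding pattern of a whole
alignment is one vectorized expression,

```
bonds = XNOR(at1, at2) & XOR(gt1, gt2) & valid1 & valid2,
```

with primer 2 presented antiparallel (reversed) and slid across all offsets.
Any encoding satisfying the bonding criterion would do; this one is fixed so
tests are deterministic.  The planes live in R logical vectors — the results
contract is representation-independent, and the one genuinely
performance-critical inner loop (the genome scan) packs bases into 64-bit
words in C++ instead.  Primers up to 128 bases (after 5′ tag concatenation)
are supported; longer tagged primers are rejected with the offending record
named.

Degenerate (IUPAC) primers use four planes instead — `R_A`, `R_C`, `R_G`,
`R_T`, one per base the code at that position might be — and the bonding rule
becomes "some base choice on each side is complementary":

```
bonds = (RA1 & RT2) | (RC1 & RG2) | (RG1 & RC2) | (RT1 & RA2).
```

A position with all four planes clear is invalid, so no separate validity
plane is needed.  On non-degenerate input the four-plane and two-plane forms
agree at every offset (tested exhaustively on the 15 × 15 IUPAC code table
and on random sequences).

## Interaction measures

**Match score.** The literature the tool builds on names a "matching score"
without printing its arithmetic, so the package fixes one definition: at
each offset, the score is the number of bonded positions minus the number of
non-bonded positions strictly between the first and last bond, maximized
over offsets (ties to the smallest signed offset).  This rewards long
complementary runs, penalizes gapped pairings, and keeps the conventional
"score 7–8 is worth inspecting" rule of thumb meaningful.  Mismatches
outside the bonded span are not counted; that is a deliberate choice and a
known divergence risk against other tools' scores.

**Free energy.** The recommended measure is the nearest-neighbour duplex
free energy.  Each maximal run of two or more consecutive bonds contributes
the sum of its dinucleotide stack energies; a single internal mismatch
flanked by bonds contributes its two tabulated mismatch stacks; longer
interior gaps contribute nothing.  Stack free energy at temperature T is

```
dG(T) = dH − (T + 273.15) · (dS + 0.368 · ln[Na+]) / 1000
```

with dH in kcal/mol and dS in cal/(mol·K).  The embedded table is the
unified oligonucleotide Watson–Crick set together with the published single
internal mismatch series (G·T, G·A, C·T, A·C and the like-with-like
mismatches); table revisions differ in the second decimal between sources,
which is why the package ships its own fixed copy.  The salt correction is
entropic, 0.368·ln[Na+] per stack.  Duplex initiation terms are omitted:
dimer interactions are only ever compared with one another, so the constant
offset cancels; absolute dG values are therefore slightly more negative than
a full duplex calculation would give.  Defaults are 37 °C and 50 mM Na+;
the worked examples use 60 °C / 50 mM, typical preamplification conditions.

**Degenerate energies.** For degenerate primers the bonded runs come from
the four-plane bond pattern, and each stack takes the most stable base
choice per step (choices are made per step, not jointly across the run).
This is a worst-case stability estimate in the sense of "assume the most
dangerous realization locally"; it is *not* guaranteed to bound every
concrete expansion's energy, because a concrete mismatch path can
occasionally beat a forced weak complementary path.  The invariant that does
hold, and is tested, is that the degenerate bond set is the union of the
expansions' bond sets.

Only the extreme over all offsets (maximum score, minimum dG) is stored per
primer pair.  The interaction table is complete and symmetric over all
primers, self-pairs included, and always evaluates the *tagged* sequences:
a shared 5′ tag is part of every reaction, and tag–tag annealing is a real
failure mode.

## Genome scan and overlap detection

The scan maps every primer onto the genome in a single pass without a
prebuilt index.  All concrete expansions of every untagged primer, plus
their reverse complements for the negative strand, are truncated to their
last (3′-most) 32 bases and encoded as 2-bit integers.  The last N bases of
each variant — N being the length of the shortest primer, at most 32 — form
a fixed-width key in a sorted table.  Each chromosome is then shifted one
base at a time through a 64-bit window; at every position the last N bases
are binary-searched among the keys, and only a key hit triggers
verification of the variant's full window.  Windows containing a non-ACGT
base match nothing; soft-masked (lowercase) bases are treated as their
uppercase equivalents, since primers legitimately target masked repeats.
Primers longer than 32 bases are matched by their last 32 bases only and are
listed in a warning.  The per-primer expansion cap defaults to 4096
variants, enough for any realistic degenerate primer while keeping the index
bounded.

Genomes are read from FASTA or UCSC 2bit (detected by magic number); both
formats yield identical scans, which the test-suite checks on generated
twins.  Coordinates are 1-based inclusive everywhere, the genome-browser
convention native to R's range infrastructure; BED output converts to
0-based half-open as the format requires.

Primer hits become events in a positional sweep.  An amplicon forms when a
pair's two sites occur convergently within the user's maximum amplicon
length (an inclusive bound on `end − start + 1`, measured on the matched
windows, tags excluded): forward site on the plus strand followed by the
reverse primer's site on the minus strand, or the mirror-image
negative-strand-first arrangement.  A pair may produce several amplicons;
all of them take part in overlap detection.  A pair with none goes to the
unmatched list with a warning that notes which of its primers mapped at all
— such a pair cannot be cleared of overlapping anything.  Pairs whose
primers map to different chromosomes form no amplicon.  Overlaps are
intersecting closed intervals on one chromosome between amplicons of
different pairs; each overlapping pair of pairs has all four cross-primer
interaction entries saturated to the top of the range scale (65535), which
makes co-pooling them strictly worse than any alternative and so guarantees
the partitioner separates them and keeps them apart.  The original values
stay in the table for reporting.

## Pool partitioning

Interaction values map to integer "ranges": a score maps to itself, a free
energy to `int(−2 · dG)` (truncation toward zero), splitting the dG axis
into 0.5 kcal/mol ranges — range 14 corresponds to −7 kcal/mol, the
conventional dimer-risk threshold.  A pair's pool score in a pool is the
4-tuple

1. `d1`: the worst range among the interactions between its two primers and
   the primers of every other pair in the pool,
2. `d2`: how many interactions sit at `d1`,
3. `d3`: how many at `d1 − 1`,
4. `d4`: how many at `d1 − 2`,

compared lexicographically, counters saturating at 65535 (the 16-bit packing
of the original formulation is kept as the semantic bound).  Range-0
entries — no interaction — never enter the counts.  A pair's own
forward–reverse interaction is pool-invariant and excluded from pool scores;
it appears in the interaction report instead.

Partitioning starts from a uniform-random assignment (randomized round-robin
when a pool size cap is set, which keeps every pool within the cap whenever
the instance is feasible).  Hill climbing repeatedly applies the best
positive-benefit move of any single pair to another pool, ranking benefits
lexicographically (worst-range reduction first), breaking ties to the lowest
pair id and then the lowest target pool so runs are reproducible.  At a
local optimum the state is saved and between 1 and `max(2, n/10)` random
"bad moves" are applied; if the next climb converges on a worse or equal
state the pools are re-randomized entirely, which in practice escapes local
optima faster than tuning the bad-move count.  The best state ever seen is
returned; the saved-best score sequence is monotone by construction and is
exposed as the `trace` attribute.  The run stops after 200 consecutive
cycles without improvement (configurable), at an optional wall-clock limit,
or immediately once the score reaches all-zero.  Whole runs are
deterministic given `(input, k, size_cap, seed)`.

Before asking for `k`, the package computes a suggestion by single-pass
first-fit packing: each pair, in input order, joins the first pool where its
worst cross-interaction stays below range 14 (−7 kcal/mol) and no overlap
constraint binds, opening a new pool when none fits.  The user's `k` always
wins.

On instances small enough to enumerate (up to ~10 pairs, 2–3 pools) the hill
climber reproduces the exhaustive lexicographic optimum across seeded random
tables; that equivalence is part of the test suite.  For 100 pairs and 2
pools the assignment space already exceeds 10^30, which is why local search
rather than enumeration is the only practical route.

## Synthetic data

The package generates its own test universe: primer panels with the naming,
tag, case and degeneracy conventions of real input files; toy genomes
(written as FASTA and 2bit twins) with amplicons planted at known
coordinates in both orientations, including deliberate tiling overlaps and
N-blocks; and interaction tables with planted clique structure or seeded
random entries.  Genome generation verifies that every planted primer window
occurs exactly as often as planted and redraws the background otherwise, so
the expected hits, amplicons and overlaps are exact ground truth, not
probabilistic.  Backgrounds are uniform over ACGT: there is no repeat
structure, GC skew or polymorphism model.  Passing the suite therefore
demonstrates algorithmic correctness — completeness and soundness of the
scan against a string-search oracle, overlap detection against brute-force
interval intersection, partitioner optimality against enumeration — but not
robustness to repetitive genomes, where a primer may legitimately hit
hundreds of sites and amplicon reconstruction becomes design-dependent.

Test problem sizes are deliberately modest so the full suite runs quickly:
twenty 100 kb single-chromosome genomes for the scan-oracle comparison,
1000 random primer pairs for the bit-parallel/naive bond-count equivalence,
and exhaustive partitioning checks up to 10 pairs and 3 pools.  These sizes
are the package's own choice of test conditions; nothing in the
implementation depends on them, and the scan itself is routinely used on
megabase genomes.

## Numerical and edge-case choices

* Truncation, not rounding, in `int(−2 · dG)`; positive (unstable) energies
  clamp to range 0.
* A duplex with no two consecutive bonds at any offset has no stacked run
  and reports dG = 0, "no stable interaction".
* Offset ties (equal score or energy at several alignments) resolve to the
  smallest signed offset.
* A missing nearest-neighbour entry (conceivable only for steps outside the
  tabulated single-mismatch families) raises an error naming the step rather
  than silently contributing zero.
* Empty primer files, duplicate record names, non-IUPAC characters and
  infeasible pool constraints (`k` larger than the pair count,
  `size_cap · k` smaller than it) all fail fast with the record or
  constraint named; records that merely cannot be paired are kept, warned
  about, analysed for hybridization, and ignored by the partitioner.

## Known limitations

No melting-temperature calculation, hairpin/secondary-structure model,
dangling-end terms or mismatch-tolerant genome matching; the scan finds
exact matches of the 3′ windows only, so a primer whose 3′ 32 bases contain
a SNP against the reference will be reported unmatched rather than
approximately located.  The match-score arithmetic is a fixed in-package
definition, not a reimplementation of any other tool's undocumented formula.
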