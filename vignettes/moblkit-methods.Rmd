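---
title: "moblkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{moblkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

moblkit re-implements, at desk scale and with synthetic ground truth, the
in-silico workflow by which a new family of conjugative relaxases can be
delineated from a single seed protein: iterative profile homology search,
redundancy reduction, motif ("signature") discovery and cross-family
scanning, neighbor-joining clade analysis, plasmid localization, and
annotation of the oriT neighborhood (intrinsic DNA curvature, repeats,
GC-rich stretches, the nic site). A small closed-form hydrodynamics module
covers the Svedberg molar-mass estimate and the frictional ratio used to
characterize the purified relaxase. This vignette records the models, the
tunable parameters, and the design decisions that were genuinely open.

## Sequence model and conventions

Sequences live in a light `seq_set` container (protein or nucleotide; the
nucleotide flavor carries a per-record circularity flag). All internal
coordinates are 0-based half-open; everything reported to the user is
1-based inclusive, matching how plasmid positions are conventionally
printed. `N` contributes to neither GC numerators nor denominators and
curvature steps across `N` carry zero wedge; `X` mismatches everything in
alignments. Circular sequences wrap in every windowed computation
(curvature, GC, nick search, translated matching); linear sequences never
wrap.

## Pairwise alignment

One affine-gap Gotoh kernel (Rcpp) backs every alignment in the package, in
three modes: local (Smith-Waterman), global, and overlap (free end gaps).
Scores are BLOSUM62 half-bits with gap open 11 / extend 1, the standard
protein-search defaults. Traceback ties resolve diagonal, then up, then
left, which makes every alignment — and everything downstream —
deterministic. The test suite checks the local mode against two independent
routes: an exhaustive alignment enumerator on tiny pairs and the Biostrings
implementation on longer ones.

## Iterative profile search and E-values

Family collection mimics the psi-blast procedure. Round one scores the
database with a PSSM built from the seed alone; because column pseudocounts
are substitution-matrix conditioned (`g(a) = sum_b f(b) q(a|b)` with
`q(a|b)` derived from BLOSUM62), a single-row profile with large
pseudocount weight *is* substitution-matrix search. Later rounds stack the
accepted hit segments by their alignment to the query (the seed row is
always included, so no profile column is ever empty) and rebuild the PSSM.
Membership is monotone — once accepted, never dropped — which guarantees
convergence and matches the collection semantics of a cumulative hit list.
The default inclusion threshold is E = 1e-15 with up to 10 rounds; the
round actually attained is recorded, since the source workflow reports both
"up to 10 rounds" and "7 iterations" in different places.

E-values use the Karlin-Altschul form `E = K m n exp(-lambda S)` with
`lambda` and `K` fitted by the method of moments to maximal PSSM scores
against residue-shuffled decoys drawn from the database itself. Analytic
parameters for gapped PSSMs are not available in closed form; an empirical
Gumbel calibration is testable (the E-value of the best decoy score is ~1
by construction, and E scales linearly with database size).

## Redundancy reduction

Greedy centroid clustering processes sequences longest-first (ties by id);
a sequence joins the first centroid with identity at or above the
threshold, else founds a cluster. Identity is computed on the optimal
global alignment with free end gaps: matching columns over alignment
columns, internal gaps counted, end gaps free. At threshold 1.0 this
definition reduces exactly to a substring test, which the implementation
uses as a fast path (it is an equivalence, not an approximation). The
pipeline applies the two reductions of the source workflow: exact dedup
(1.0) after the search, and 0.50 centroids before motif discovery.

## Signature discovery (ZOOPS EM) and its null

Signatures are fixed-width position-weight matrices fitted by
expectation-maximization under the zero-or-one-occurrence-per-sequence
model. For each candidate width (a geometric grid over the 6-50 range), EM
is seeded from sampled data subsequences, short-run on all starts and
long-run on the best few. Discovery is sequential: keep the best motif if
it passes the E-value threshold (default 1e-15, up to 10 motifs), erase its
sites by background resampling, repeat.

Two empirical findings shaped the E-value design, and both are worth
stating because they would silently corrupt results otherwise:

* A null made of *random site sets* (the cheap Monte-Carlo shuffle one
  might first write) ignores the EM optimizer's selection effect and
  declares signatures in pure i.i.d. noise at nominal E-values far below
  1e-15. The null here therefore re-runs the same EM optimization on
  within-sequence residue-shuffled copies of the data (6 replicates per
  width), so observed and null statistics have seen the same optimizer.
* Any empirical p-value is floored at 1/replicates and can never reach
  1e-15. A Gaussian tail fitted to the null optima provides the
  extrapolated upper-tail probability; it is Bonferroni-scaled by the
  number of widths tried. Planted motifs sit dozens of null standard
  deviations out, noise sits near zero, so the threshold is meaningful in
  both directions.

Because strong-motif p-values underflow to zero, widths cannot be ranked by
E-value; among widths that pass the threshold, the fit with the largest LLR
*in excess of its own width's null mean* wins (raw LLR would favor widths
that classify more spurious sites), and uninformative edge columns are then
trimmed. The trim cutoff is the largest of three terms: a 0.5-bit floor;
the sampling noise of apparent information content (a background column
over n sites shows ~19/(2 ln2 n) bits by chance, and edges below that mean
plus three standard deviations go); and a quarter of the median column IC,
because EM can slide all sites coherently and thereby *select* its flank
columns, inflating them beyond i.i.d. noise. The per-width null is computed
once on the intact data and reused across motif iterations — erasure
replaces a few percent of residues by background and leaves the null
essentially unchanged — and the null fits receive the same optimization
effort (same number of starts and long refinements) as the observed fit,
since a weaker-effort null is both biased low and unstable.

Scanning uses exact per-position p-values obtained by convolving the
per-column score distributions under the background on an integer grid
(columns are independent, so the convolution is exact up to the grid), and
converts them to sequence E-values as `p x scannable positions x number of
sequences`; a sequence "contains" a signature at the default threshold
E = 1e-6. Occurrence tables report, per signature and target family, the
percentage of that family's members flagged, to one decimal.

## Trees, supports, and the two-clade cut

Tree building is deliberately self-contained: a center-star progressive
alignment (the center maximizes total pairwise global score; pairwise
alignments merge on center coordinates) feeds Poisson-corrected distances
(`-ln(1 - p)`, pairwise deletion of gapped columns; plain p-distance is a
flag), and neighbor joining follows the Saitou-Nei Q-criterion with
negative branch lengths clamped to zero and ties broken by the smallest
current index pair. The source workflow named its tree program but not its
alignment, distance model, or condensation threshold, so all three are
exposed as configuration with conventional defaults (Poisson, 50%).
Bootstrap supports resample alignment columns (default 1000 replicates),
rebuild the tree, and count bipartitions of the point-estimate tree.
Condensing sets internal branches below the support threshold to length 0,
retaining topology. The two-clade partition cuts at the internal branch
maximizing support x length (ties prefer the more balanced split, then the
lexicographically smallest side); the clade containing the seed protein is
clade 1. The cut rule is a package decision: the source asserts a two-clade
structure without defining the cut.

## Plasmid localization

A protein is called plasmid-encoded when its best local alignment against
the six frame translations of a plasmid exceeds 95% identity over more than
80% of the *entire protein length*. Circular plasmids are scanned as the
doubled sequence minus one codon, so origin-spanning genes are intact in
some frame; calls are invariant to rotation and reverse complement (tested
properties). The source's Methods say "identity" where its Results say
"similarity"; identity is implemented as the operational definition and a
similarity mode (positive-scoring substitutions) is available as an option.
A word prescreen (exact shared 10-mer at stride 4) skips the dynamic
program when a positive call is impossible; at 95% identity over 80%
coverage the probability of no shared exact 10-mer is negligible, and the
prescreen cannot flip a call, only skip hopeless work.

## Wedge-model curvature

The helical path composes, per dinucleotide step, a twist rotation about
the local axis followed by roll and tilt wedge deflections, advancing one
unit per step. Curvature at a position is the angle between the chords over
the preceding and following w bp divided by w (default w = 10); the
curvature-angle is the undivided chord angle at w = 15. The "10 and 15 bp
respectively" wording in the source maps the windows to the two quantities
(not to the two parameter sets); both windows are arguments, so the other
reading is one flag away. Profiles are smoothed with a sliding window of
exactly 600 bp (for even windows the extra position sits right of center)
and z-normalized to mean 0, sd 1 — the stated normalization, verified to
1e-9 in the acceptance suite.

The two bundled parameter tables, `"AAWedge"` (nonzero wedge only on AA/TT,
~7.8 degrees, helical repeat 10.5 bp) and `"CDS"` (a full 16-dinucleotide
roll/tilt set), are synthetic stand-ins in the lineage of the classic
A-tract wedge and conformational-energy tables: the original numeric tables
live in an external program that is not redistributable here and the source
does not print them. Peak *positions* are the supported contract, not
absolute curvature magnitudes; user tables with the same structure are
accepted everywhere.

One property of the stated normalization deserves emphasis: because the
z-profile has unit standard deviation by construction, the maximum of a
*noise* profile spanning several smoothing-window correlation lengths
routinely exceeds 2. Absolute peak counts on featureless sequence are
therefore not a meaningful null; what the tests (and the synthetic
recovery criteria) assert instead is discriminative: a planted phased
A-tract bend is the global z-maximum, localizes within 300 bp of its
planted center, and always beats matched bend-free noise, and phased
A-tracts beat their own shuffles in at least 19/20 trials.

## oriT annotation

The repeat finder is an exhaustive diagonal/anti-diagonal scan for direct
repeats (any separation, non-overlapping arms), inverted repeats (loop at
most 20 bp by default) and palindromes (loop 0), with at most one mismatch
per arm pairing by default. A hit must begin and end with a match and be
maximal at its own mismatch count — a shorter clean hit is reported even
when a longer one-mismatch hit contains it. The scan is quadratic and meant
for oriT-scale regions (the pipeline applies it to a 1.5-kb window around
the located nic site, not to whole plasmids); the suite verifies it against
a brute-force window enumerator on strings up to 200 bp. GC content uses
1-bp-stepped windows (default 30 bp). The nic site is located by searching
both strands for the recognition 14-mer 5'-GAATCGGGGGCCGG-3'; the nick
position is the first base 3' of the match on the matched strand, wrapping
across the origin on circular sequences, with multiple occurrences all
returned and flagged ambiguous.

## Hydrodynamics

`svedberg_mass` evaluates M = RTs / ((1 - vbar rho) D) with SI conversions
internal (s in Svedberg, D in um^2/s, output g/mol).
`frictional_ratio` compares the frictional coefficient implied by (M, s20w,
vbar) with the Stokes coefficient of the equivalent anhydrous sphere, using
water-at-20-C constants. For the worked example the solvent density comes
from additive increments for the stated buffer (20 mM Tris, 500 mM NaCl,
10 mM MgCl2, 1% glycerol: rho ~ 1.022 g/mL) and vbar is the field-standard
0.730 mL/g, since the protein's composition is not available offline; a
Cohn-Edsall composition calculator (`vbar_from_sequence`) is included for
when it is. With these inputs the *in-buffer* convention (s = 2.8 S against
buffer density) reproduces the printed 47,760 Da within 1%, and the
standard-condition pair (M = 50,329 g/mol, s20w = 3.3 S, vbar 0.73) gives
f/f0 = 1.49; the function records which convention was used.

## Synthetic data: what it emulates, and what it does not

`gen_family` draws a root ancestor, two clade ancestors (13% substitution
each), and members (30% substitution from their clade ancestor), then
plants signature sites sampled from planted PWMs at 95% per-residue
fidelity at recorded, non-overlapping positions. With these defaults
within-clade pairs sit near 55% identity and cross-clade pairs near 43% —
the 40-60% band the emulated family occupies — so the 50% centroid step
retains a meaningful set and the two clades remain separable. One
signature is always present in every member (the analog of the universal
histidine-motif signature); the others are clade-biased. `gen_decoys`
draws i.i.d. background sequences. `gen_plasmid` writes non-overlapping
features at recorded coordinates into background of ~40% GC: uniform-codon
back-translated member CDSs (minus strand and origin-spanning supported),
phased-A-tract bent regions (A6 tracts at alternating 10/11 bp spacing,
the classic curvature-maximizing 10.5 bp period), and an oriT cassette
(three direct-repeat copies, a 73%-GC 30-mer, the nic 14-mer, the
arms-10/loop-4 inverted repeat, the TGGTACCA palindrome). Every generator
is deterministic in (spec, seed).

What the generators do *not* emulate: indels and rate heterogeneity in
family evolution (alignments are trivially correct by construction, so MSA
quality is exercised only lightly), genomic context around plasmid genes,
database-scale composition biases, and real taxonomic structure. A green
synthetic test therefore establishes that each stage recovers what was
planted under its stated statistical model — not that the desk-scale
pipeline would reproduce database-snapshot-dependent counts (817 members,
306 plasmid hits, 99.6% Firmicutes), which are explicitly out of reach
offline.

## Numerical choices and degenerate inputs

Curvature equivariance under rotation is exact in exact arithmetic; after
thousands of composed rotations the tests allow 1e-6 of frame drift.
Saturated Poisson distances (p = 1) and gap-only row overlaps are errors,
not silent clamps. A constant curvature profile cannot be z-normalized and
errors. Zero positive localization calls yield an explicit
zero-denominator flag rather than 0/0. Motif discovery on fewer than two
usable sequences, all-gap PSSM columns, and degenerate (zero-variance)
decoy score distributions are all errors by contract.

## Runtime scaling in the test suite

The acceptance suite runs the profile-search recovery at the stated
60-members + 500-decoys scale, but scales down where the statistic does not
depend on size: two-clade agreement uses 12+12-member families with 40
bootstrap replicates (the statistic is per-leaf agreement), and the
end-to-end determinism check uses a 5+5-member fixture (determinism does
not depend on scale). Bootstrap defaults remain 1000 replicates in the
user-facing configuration.
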