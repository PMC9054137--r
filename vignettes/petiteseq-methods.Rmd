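---
title: "Methods: inferring Petite mtDNA repeat structures from long-read alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring Petite mtDNA repeat structures from long-read alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petiteseq)
library(dplyr)
```

## The biological problem

Respiration-deficient *Saccharomyces cerevisiae* Petite colonies carry
mitochondrial genomes reduced to sub-genomic repeat units: short segments
excised from the 85,779 bp wild-type molecule by recombination between
repeated homology, then amplified into tandem concatemers by rolling-circle
replication. A long read sampled from such a molecule is a window onto the
concatemer: it shows the repeat unit's alignments over and over, punctuated
by *breakpoint signals* wherever two reference-disjoint (non-inverted) or
oppositely stranded (inverted) alignments meet. From per-read alignment
records this package reconstructs the coexisting repeat structures in a
colony, quantifies their frequencies with a read-length sampling-bias
correction, classifies secondary excisions against the primary structure,
tests excision-placement null models against replication-origin proximity,
and fits a phenomenological model of suppressivity - the competitive
fitness of a Petite mtDNA against wild type.

## Breakpoint detection

Alignments are consumed as PAF records (interval endpoints only; CIGAR
strings are ignored) and filtered to mapping quality strictly above 20 and
reference length strictly above 300 bp; the length gate exists because the
eight mitochondrial replication origins are highly homologous and short
alignments cannot be placed. All coordinates are 0-based half-open; the
molecule is biologically circular but coordinates and distances are linear
unless a function exposes a `circular` switch.

For each adjacent pair of segments in a read, a strand change always emits
an inverted signal, whatever the coordinate separation. Same-strand pairs
emit a non-inverted signal only when the observed reference start of the
second segment deviates by more than 30 bp from the position extrapolated
from the first segment's reference progression across the read-coordinate
gap. The extrapolated form (rather than a plain reference-gap rule) is a
deliberate choice: a low-complexity stretch that advances read and
reference together is not a junction, and the extrapolation leaves it
silent. Junction edges are reported as the reference boundaries of the two
alignment termini facing the junction; read termini are never junctions.

## Inverted-duplication artifacts

The dominant artifact in this sequencing chemistry is a template re-read:
the complementary strand follows its template through the pore, producing a
read concatenated with a strand-flipped, quality-degraded mirror of its own
suffix. The spurious inversion sits near the read centre (sometimes skewed
late) and its two reference edges fall within 1 kbp of each other. The fold
position is modelled as Beta(a, b) over relative read position with
defaults a = 8, b = 6 (mode about 0.54); the same parametric family drives
both the simulator and the detector, so detection power is testable against
a known generator. An inverted signal is an artifact candidate when its
position's two-sided tail probability under the Beta exceeds 1% (a density
rule is available via `position_test = "density"`) *and* its fold gap is
under 1 kbp; a candidate is called an artifact when it is the only
artifact-consistent signal in its read. We read the published criterion
"reads with only a single inverted duplication signal" as counting
artifact-consistent signals: on structures whose repeat units themselves
contain inverted junctions, nearly every artifact read also carries real
inversions, and counting those would leave essentially all artifacts in
place; a switch (`count = "all_inverted"`) restores the literal reading.
Called artifacts are removed before clustering, but the read and its fold
position are kept: the mirrored half duplicates every junction it covers,
which the cluster filter turns to its advantage.

## Clustering and cluster filtering

Signals are clustered separately by kind with DBSCAN (minPts = 3) in the
canonically sorted edge plane `(edge_lo, edge_hi)`, so LH/HL orientation
cannot split one junction. Non-inverted signals use a lenient epsilon of
1 kbp. Inverted signals - the kind artifact residue contaminates - use
`min(elbow, 1 kbp)`, where the elbow is the sorted nearest-neighbour
distance at the point of largest discrete curvature (raw distances by
default; a log-scale switch exists). DBSCAN is implemented in-package (no
density-clustering package ships with this stack) and is tested against a
brute-force density-connectivity oracle. Because DBSCAN can merge two
genuine junctions, every sufficiently large cluster is re-examined with a
deterministic 2-means split (initialised at the two farthest members); the
split is accepted only when some read transitions between the two halves -
the signature of two distinct junctions - *and* the halves are separated
by more than four times their internal spread. The second guard matters:
2-means always partitions, and halving a single junction's jitter scatter
produces a separation of about 2.7 times the within-half spread, so
without the guard every well-sampled junction would split along its own
noise.

Clusters then need at least three distinct supporting reads, and must win a
vote. In reads with a removed fold, `P` counts reads where the cluster is
recapitulated on both sides of the fold and `N` reads where it appears on
one side only; `P > N` keeps the cluster. Matching is by proximity (within
1 kbp of the centroid) rather than strict cluster membership, because the
degraded mirrored halves recapitulate junctions with extra scatter. When no
fold read contains the cluster, the vote falls back to within-read
repetition (`PR` reads repeat it, `NR` reads repeat something else but hold
it once), the expected signature of concatemers. A cluster with no votes of
either kind is retained on read support alone: primaries with periods
beyond half the read length essentially never repeat within a read, and a
vote with no voters is not evidence against them. Ties with votes cast drop
the cluster.

## Structure reconstruction

Each read becomes two token sequences over cluster labels - numeric
(`2LH`, cluster plus low-to-high/high-to-low transition) and orientation
(`2++`, cluster plus strand pair) - plus its reference footprint. Units
small enough to repeat within single reads are detected directly: the
shortest unit whose repetition in *both* encodings covers at least two
periods, reported in canonical rotation (lexicographically smallest).
Mixed-structure samples additionally yield partial repeats - the same
alignment repeated in the same orientation around a single inverted
alignment - detectable at 1.5 periods.

Units too large to repeat within reads are inferred from the breakpoint
transition matrix `T[i, j]` (within-read adjacent label pairs). Transitions
sharing a breakpoint merge when each count differs from their mean by less
than 34% (a binomial one-standard-deviation criterion), recursively,
processing pairs in descending count order so the merge is deterministic. A
merged list is a structure only when its distinct breakpoints equal its
unique transitions - the closure condition of a true repeat. Structure
alignments are recovered as the fused reference footprints of the reads
whose labels live entirely inside the structure's cluster set (and in no
smaller candidate's), which converges on the exact unit intervals because
interior segments of concatemer reads are complete copies.

The structure with the largest reference span is the primary. Spans tie in
one important case - an alternate spanning the primary junction covers the
same extremes - so ties break toward supporting reads, then lower start
coordinate. Within-read transition counts are not used for this tie-break:
they under-count any unit longer than a typical read. Alternates are
classified against the primary by shared cluster edges, where two edges are
shared when their means agree within one standard deviation (the more
permissive `max` of the two SDs by default; pooled SD optional): no shared
edge is Type I (interior excision), both primary edges shared with more
than one alignment is Type II (excision across the primary junction in
concatemer form), exactly one shared edge with a single alignment is
Type III (reuse of one primary excision site). Anything else is labelled
`unclassified` rather than forced into a class.

## Frequencies and the read-length bias

Read lengths are fitted as a shifted exponential, `mu = min`,
`beta = mean - min` (the MLE for this family). A repeat unit of period `L`
is visible in a read only if the read is long enough to show its junction,
so raw counts under-represent long units. The visibility

$$Q(L_k) = \int_{L_k}^{\infty} P_R(x)\,dx +
  \int_{u}^{L_k} \frac{x}{L_k} P_R(x)\,dx$$

is evaluated in closed form (the integrand `x f(x)` has antiderivative
`-(x + beta) e^{-(x-mu)/beta}`) and verified against numerical quadrature
to below 1e-6 relative error. The lower bound `u` defaults to the fitted
`mu`: reads shorter than the location parameter do not exist under the
model. For `L < mu` the exponential survival factor is clamped at 1.
`Q(L_k)` is exactly the probability that a uniformly phased read shows a
given junction at least once, which is why the default breakpoint count
`J_k` is the number of assigned reads showing at least one of the
structure's breakpoints; with that pairing, `freq_k \propto J_k / Q(L_k)`
is a consistent estimator of base-pair frequency (instance counting, the
other reading of the published procedure, is provided as a switch but is
biased by a factor `E[x]/L_k / Q(L_k)` and fails parameter recovery in
simulation). Reads are assigned to the structure sharing the most breakpoint
labels among those whose footprint contains all the read's mapped content;
ties go to the larger span, then higher support, which biases conservative
- toward the primary.

Mixed structures need their own correction because breakpoint identity does
not determine alignments there. Complete (junction-bounded, interior)
segments are counted per alignment and corrected by
`Q(L) = (1 - L/\sum L_i)\, e^{-(L-\mu)/\beta}` - the probability that a
read is long enough to contain the alignment and does not truncate it. This
form removes the dominant exponential length bias; a residual truncation
term of order `L/\sum L_i` remains relative to the exact renewal
expectation `E[(x-L)^+]/\sum L_i`, and at the scales used in the test suite
(alignments of 4.1-5.9 kbp against reads of mean 3.5 kbp, a few hundred
counts) it stays below sampling error. The per-colony alternate content
fraction deliberately abandons cluster support: it is the base-pair
fraction of reads carrying any non-primary breakpoint internal to the
primary alignments, excluding artifact-bearing reads, which keeps rare
alternates visible in samples too shallow to form clusters.

## Excision null models

Three models place excised fragments on the reference: uniform placement
with the empirical length distribution; placement between a uniformly drawn
pair of occurrences of a maximal exact direct repeat of at least 11 bp
(direct repeats only - excision between direct repeats deletes the
intervening segment; an inverted-repeat switch is out of scope); and
uniform placement conditioned on overlapping a uniformly pre-selected
origin, drawn directly from the exact conditional rather than by rejection.
Both edges of each fragment are pooled into the displacement sample (the
plural reading of "breakpoint edges"; a per-fragment-minimum switch was
considered and rejected as less informative). Fragments extending past the
linear reference end are resampled; no wraparound. The repeat index is an
exhaustive k-mer-seeded enumeration of maximal pairs, tested against an
O(n^2) oracle.

## The suppressivity model

Suppressivity - the Petite progeny fraction of a Petite x Grande cross -
is modelled as exponential competition of monomeric repeat units: each
parent contributes mtDNA content inversely proportional to its unit length
(`L_P`, `L_G`), and units replicate exponentially at speed times origin
density (`nu rho`), giving

$$S = \frac{1}{1 + \frac{L_P}{L_G}\, e^{(\nu_G \rho_G - \nu_P \rho_P)\,t}}.$$

The fit parameters are the products `nu_G t*` and `nu_P t*` (bp), estimated
by bounded Levenberg-Marquardt least squares on untransformed
suppressivities with a fixed multiplicative fan of five starts spanning
roughly 0.08x-12x the initial guess, so a guess an order of magnitude off
still brackets the optimum. An origin counts toward `rho_P` only when fully
contained in the structure's alignments (perturbed origins are known to
lose function; a fractional option exists). Model variants - dropping the
input-fraction prefactor, replacing exponential with linear growth, or both
- are fitted by the same machinery for comparison. The back-of-envelope
wild-type replication speed assumes one genome duplication per 90 min
competition window at genome-derived origin density (8 per 85,779 bp),
giving `ln 2 * (L_G/8) / 90 ~ 82.6` bp/min; the genome-derived density is
the default precisely because it reproduces this figure, with the nominal
1-per-10-kbp density available through `grande_params()`.

## The synthetic generator and what passing tests mean

`simulate_reads()` draws each read's structure proportional to target
base-pair frequency, its length from the shifted exponential, and its
content from a uniformly phased window on an infinite concatemer (the
infinite-concatemer approximation matches the frequency formulas'
assumption of random periodic sampling). Junction-facing reference
endpoints take symmetric Gaussian jitter, truncated to half the segment
length - symmetric because the cluster-centroid consistency property
(error shrinking as `3s/sqrt(n)`) requires unbiased scatter. Artifacts
append a strand-flipped mirror of the read suffix with fold position drawn
from the Beta model (draws below 0.5 clamp to a full duplication, the
construction's geometric floor); each mirrored segment is displaced by its
own length-preserving offset (SD 250 bp, clamped below 1 kbp), emulating
degraded-half mapping without destroying short segments. Mixed structures
are generated from the crossover grammar: two partial units - largest plus
inverted smallest, second-largest plus inverted second-smallest, which
forces the shared-region identity `L_1 + L_4 = L_2 + L_3` - drawn
independently each period, which reproduces exactly two distinct inverted
junction coordinate pairs, as observed.

The generator emulates alignment-level structure only: no base-level error
model, no pore signal, no nuclear contamination, no mapper idiosyncrasies
(Z-drop rescue, supplementary-alignment fragmentation). Passing tests
therefore demonstrate the inference machinery is correct under the stated
statistical assumptions, not that those assumptions exhaust real Nanopore
data.

## Problem sizes, determinism, and numerical choices

The validation suite runs at desk scale, chosen as the smallest sizes at
which the targeted effects are comfortably resolved: 5,000 reads
(`mu` = 1 kbp, `beta` = 5 kbp) for end-to-end recovery of a 30 kbp primary
with Type I/II/III alternates at 5% each, within three binomial standard
errors; 1,500 reads at 30% artifact rate for filter power (at least 95%
removal, no real inverted cluster lost); 4,000 reads for the
mixed-structure correction; a 50 kbp toy genome with four origins and
densely planted repeats for the excision-model comparisons (the
origin-conditioned displacement CDF must dominate uniform, and uniform
versus perfect-repeat must be indistinguishable by a two-sample KS test at
alpha 0.01 - dense repeated homology is the mechanism behind that
coincidence, so repeat seeds are planted inside origins as well, mirroring
the origins' real mutual homology). All simulations fix seeds; k-means uses
deterministic farthest-point initialisation; transition merging processes
counts in fixed descending order. Degenerate inputs are handled
explicitly: constant read lengths warn and floor `beta` at machine epsilon,
constant suppressivities warn and report non-positive R-squared, fewer than
three inverted signals fall back to the 1 kbp epsilon cap, and empty
structure sets propagate as empty tibbles rather than errors.

## Known limitations

Real alignment records bring complications the generator does not emulate:
mapper-fragmented alignments inside one repeat copy, reference circularity
(a junction at the linearisation point is indistinguishable from the
genome's own origin join), segmental coverage bias, and chimeric reads
other than the modelled fold artifact. The mixed-structure correction
carries the documented `O(L/\sum L)` residual. Excision null models treat
excision sites as sequence-independent beyond perfect-repeat pairing; no
mechanistic recombination model is attempted. The suppressivity model is
phenomenological: its parameters are coarse-grained speed-time products and
should not be compared to directly measured fork velocities.
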