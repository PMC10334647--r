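---
title: "Methods: consensus scaffolding and phasing with Hi-C and long reads"
author: "hapscaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus scaffolding and phasing with Hi-C and long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`hapscaf` assembles chromosome-scale, phased scaffolds from a partially
phased diploid contig assembly plus two sources of linking evidence:
long-read alignments and Hi-C read pairs. The pipeline has three stages.

1. **Merge.** Homologous contig pairs are merged into *consensus contigs*.
   A consensus contig stands for one locus and records its two members in
   an array `T`: a phased pair `[u, v]`, an unpaired heterozygous contig
   `[u, -]`, or a homozygous contig `[u, u]`. The consensus sequence is the
   primary member's sequence, verbatim — no consensus-calling between the
   members is attempted.
2. **Scaffold.** Consensus contigs are first chained with long-read links
   (only unambiguous, non-branching connections), then iteratively joined
   through a Hi-C end-node graph while a contact-map statistic vets every
   candidate junction and screens existing scaffolds for misassemblies.
3. **Phase.** Each scaffold is re-expanded into haplotype blocks (its
   members' `T` entries), blocks are assigned to two global phases by a
   greedy agreement rule over long-read and Hi-C links between members,
   and two haplotype FASTA records are emitted per scaffold piece.

The package also contains a seed-deterministic diploid simulator with full
truth tracking, so that every stage is testable without external data, and
truth-based evaluation metrics (N50, phasing accuracy, misassembly and
switch-error counts).

## Input styles

Three contig input styles are accepted, mirroring the common assembler
outputs:

* **paired-haplotype** — bubble pairs with coverage, carried in a sidecar
  TSV (`contig_id`, `partner_id`, `coverage`). Within a pair, the contig
  with more non-N bases is the primary bubble. We deliberately do not
  parse any specific assembler's header syntax — the encoding of bubble
  metadata in headers varies between assembler versions — but
  `platanus_sidecar()` converts a simple `cov<number>` + `_p`/`_s` id
  convention into the sidecar format.
* **pseudo-haplotype** — a primary FASTA (pseudo-haplotype sequences,
  possibly containing collapsed regions) plus an alternative FASTA.
* **haplotype-ignorant** — a flat FASTA with no haplotype annotation.

The latter two styles are converted to paired-haplotype form by
self-alignment: minimap2 (`-D --secondary=no`) aligns the contig set
against itself, alignments under 80% identity (`identity_min`) or under
1 kb (`min_opposite_alignment`) are discarded, and each contig's *opposite*
is the contig with the longest total retained alignment. Opposites are
committed greedily in decreasing alignment length; a contig whose claim on
its opposite overlaps (by at least 1 bp) a claim already committed by a
different contig is removed as a repeat. Contigs are then minced at the
boundaries of their association intervals so that each piece is either
fully associated with one opposite piece or unassociated; pieces shorter
than 200 bp (`min_piece`) are merged into a neighbour to avoid unusable
slivers. Associated pieces are assigned the coverage constant
`C_consensus` (default 40) and unassociated pieces `2 * C_consensus`,
reproducing the coverage semantics expected of paired-haplotype input.

Non-bubble contigs are classified by coverage: heterozygous iff coverage
is strictly below `C_hetero * r_upper_threshold` (default multiplier
1.75). `C_hetero` is estimated as the mean coverage of contigs in
committed bubble pairs; if there are none, half the main peak of the
coverage histogram is used. This is a self-contained re-definition of a
quantity that upstream assemblers compute internally.

## The Hi-C junction statistic

All Hi-C decisions rest on one statistic computed on a binned contact
matrix (default `bin_size` 100 kb; trailing partial bins are dropped to
avoid biased band means). For a junction between bins `b-1` and `b`, and
for each diagonal distance `k = 1..k_max` (default 10):

* *inner* pixels are same-side pixels at distance exactly `k` within a
  `k_max`-bin window adjacent to the junction (upper side: `j < b`,
  `i >= b - k_max`; lower side mirrored);
* *outer* pixels are the cross-junction pixels at distance `k`
  (`i < b <= j`, `j - i = k`).

The separation score per side is the summed two-class between-class
variance (in the sense of Otsu's thresholding method) of inner versus
outer pixel values,

$$S = \sum_k \frac{N_{in,k} N_{out,k} (\mu_{in,k} - \mu_{out,k})^2}
                  {(N_{in,k} + N_{out,k})^2},$$

normalised by $S_0$, the same quantity with all outer pixels set to zero
(the score a fully separated junction would achieve). The companion score

$$R = \frac{\sum_k L_{out,k}}{\sum_k N_{out,k}},$$

where $L_{out,k}$ counts outer pixels below the matching inner mean,
guards against sparse maps in which $S$ alone misfires. A candidate
junction is *erroneous* when both

$$S_{upper}/S_{upper,0} + S_{lower}/S_{lower,0} \ge s
\quad\text{and}\quad R_{upper} + R_{lower} \ge r$$

hold (defaults $s = 1.0$, $r = 1.6$). A zero normaliser (no inner signal,
as in a nearly empty map) contributes a ratio of 0, so degenerate maps are
never flagged. Note the per-$k$ pairing of inner and outer pixels at the
*same* distance: both classes then share the expected distance-decay
level, so a true junction gives $\mu_{in,k} \approx \mu_{out,k}$ and
$R \approx 0.5$ per side, while a junction between different chromosomes
gives $S = S_0$ and $R = 1$ per side. Averaging inner pixels across mixed
distances instead would contaminate $\mu_{in,k}$ with near-diagonal counts
and push $R$ toward 1 even at true junctions; the per-distance pairing is
what makes the between-class-variance reading coherent.

### Misassembly score

Within an existing scaffold, each bin `b` receives

$$\mathrm{Score}(b) = \sum_{k=1}^{10}
  \frac{(\mu_{all,k} - \mu_{target,k}(b))^2}{\mu_{target,k}(b)},$$

where $\mu_{all,k}$ is the genome-wide mean pixel value at distance $k$
(pooled over all pixels of scaffolds at least `min_matrix_scaffold` long,
default 300 kb — a pooled mean, not a mean of per-scaffold means) and
$\mu_{target,k}(b)$ is the mean over the triangular motif of pixels
crossing bin `b` (pixels $(i, i+k)$ with $i \le b \le i+k$). Zero target
means are floored at half a count so sparse bins stay finite. A chimeric
junction suppresses exactly the crossing pixels, producing a sharp peak.

Peaks (strict local maxima over a +/-2-bin window, leftmost bin of a
plateau, complete windows only) are screened by an automatically selected
threshold `P`: for each trial `P` over `{0} ∪ {peak heights}` the scaffold
is notionally split at every peak above `P` and the mean junction
separation score over the cuts is computed; the `P` maximising that mean
wins (ties toward larger `P`, i.e. fewer splits). Because a peak *bin*
spans the misassembly, the junction boundary is ambiguous by one bin; both
boundaries are scored and the stronger one used. Peaks above the selected
`P` must additionally pass the erroneous-edge test at their boundary
before a split is made. The split point is the minimum-coverage position
(long-read coverage; plateau midpoint on ties) inside the flagged bin,
realised at the nearest member boundary — consensus contigs are the atomic
units of this implementation, so splits and joins conserve contig bases
exactly.

## Scaffolding

**Long-read stage.** Long-read alignments (PAF) are filtered to 500 bp
minimum length and selected greedily per read in decreasing sequence
identity (`nmatch / alen`; ties to the longer alignment, then target id —
identity order, not match-count order). Consecutive selected alignments to
different contigs yield an end-to-end link with the read-interval distance
as its gap estimate. Links are aggregated into edges between consensus
contig ends; an edge is used only when its count exceeds `min_link`
(default 0) and both its end nodes have exactly one incident edge (the
indegree = outdegree = 1 rule), and only if the Hi-C junction test does
not reject it. Surviving chains become scaffolds with the median link gap
(floor 1 N) between members. Cyclic chains are broken at their weakest
edge.

**Hi-C stage.** An undirected graph over scaffold ends is built: the
weight of edge (a, b) is the number of Hi-C pairs with one end within `L`
of scaffold end a and the other within `L` of end b. Edges below 50
(`L < 100 kb`) or 100 (`L >= 100 kb`) pairs are removed — these cutoffs
scale with sequencing depth, not genome size, so the desk profile keeps
them. The heaviest edge is taken (ties broken lexicographically for
determinism), vetted by the junction statistic and, in the first pass, by
the long-read check below; it is then either deleted or contracted: the
two scaffolds are joined end-to-end (orientations implied by which ends
meet) with a fixed `hic_join_gap` of 500 N — Hi-C carries no gap-size
information, so a fixed filler is used — and all other edges incident to
the consumed ends disappear. This repeats until the graph is stable, for
each `L` in the schedule (10–100 kb by 10 kb, then 200 kb–1 Mb by
100 kb), with a misassembly screen before every round. The whole schedule
then runs once more *without* the long-read check, so that joins across
repeats longer than a read can still be made; the Hi-C test always
applies.

**Long-read junction check.** For candidate ends (u, w): if long-read
(and PE) links supporting (u, w) exceed `min_link`, the edge is correct;
otherwise, if (u, w'), (u', w) or (u', w') is supported, that pairing
replaces the edge; otherwise reads in the 300 kb end windows
(`end_search_window`) whose partner lies on a third scaffold indicate a
misassembled end — the candidate interval (for paired libraries, insert
tolerance `a + 3d` from the mapped start; for long reads, to the projected
partner position) is split at its minimum-coverage point and candidates
are re-derived; with no such evidence the edge is erroneous.

## Phasing

Scaffold members expand to haplotype blocks via `T`. Links between members
of two different blocks of one scaffold count as *parallel* (same slot) or
*cross* (opposite slots); long-read and Hi-C links pool with equal weight
(no weighting is prescribed, and the simulator gives no reason to prefer
one), and consensus-kind short-read records are excluded by construction.
Block pairs are processed in decreasing `|parallel - cross|` (ties to the
smaller index pair); a pair spanning two phase components merges them,
flipping one component when cross dominates; `parallel == cross` pairs
never merge. Scaffolds are divided between adjacent blocks of different
components, except that an unphased block strictly inside one component's
span receives a seeded-random phase and no division — the random draw is
part of the run's seed, so outputs are reproducible. Homozygous blocks are
copied into both haplotypes; `[u, -]` blocks render their absent side as
an equal-length N run. Candidate pairs are restricted to blocks within one
scaffold, since the division step operates within scaffolds.

## The simulator and what it does (not) emulate

`sim_diploid()` derives haplotype 1 from a random haplotype 0 by seeded
variants — by default 91% SNVs and 9% 1–10 bp indels, with inversions
(1–10 kb) available through `type_probs` — and returns a piecewise-linear
liftover map and complete variant table. `sim_hic()` draws intra-
chromosomal pair separations from $P(d) \propto d^{-1}$ (configurable
exponent) between 1 kb and the chromosome length, a 5% uniform
inter-chromosomal background, and re-draws the mate haplotype for half the
pairs (`trans_hap_frac = 0.5`), diluting but not destroying the
haplotype-specific contact signal; at `trans_hap_frac = 1` parallel and
cross counts equalise and phasing is impossible by construction.
`sim_long_reads()` draws exponential lengths (mean 15 kb) per haplotype;
alignments are emitted directly as truth-derived PAF so the pipeline runs
without an external aligner. `fragment_to_style()` cuts the genome at
shared breakpoints (lifted through the map, kept out of inversions),
collapses fragments whose variant density falls below
`collapse_threshold`, and packages the pieces in any of the three input
styles with a truth table retained.

The desk-scale study conditions used throughout the tests are 2
chromosomes x 500 kb, 0.5% heterozygosity (SNV + indel; inversions are
exercised separately by the simulator's own tests, since their liftover
and pairing behaviour — not their effect on contact decay — is what needs
verification), 30x Hi-C, 20x long reads, 5 kb bins with all length
thresholds scaled by the same 1/20 factor (`desk_config()`). These sizes
keep the full suite within minutes on one CPU while every code path —
merge (all three styles), both scaffolding stages, misassembly screening
and phasing — is exercised.

What the simulator does *not* model, and hence what passing tests cannot
show: restriction-site chemistry and ligation artefacts of real Hi-C
(contacts are ideal distance-decay draws), TAD-like local structure that
inflates near-diagonal variance, base-quality error profiles, mapping
ambiguity in repeats (truth-derived alignments are unique by
construction), and structural variation beyond SNV/indel/inversion. Real
datasets will show weaker junction-score margins and imperfect link
purity; the statistic's thresholds (`s`, `r`, the edge-weight minima) are
the knobs to revisit there.

## Numerical and design choices

* Internal coordinates are 0-based half-open; AGP and reports are 1-based
  inclusive.
* Ties everywhere break deterministically (lexicographic ids, smaller
  index pairs, leftmost plateau bins, larger `P`), so identical inputs and
  seed give byte-identical FASTA/AGP/report output.
* `k_max = 10` applies to the junction statistic as well as the
  misassembly score, which is defined with that bound.
* The secondary member of a consensus contig is assumed co-oriented with
  its primary when member coordinates are lifted to consensus coordinates;
  secondary positions are scaled proportionally (`pos * len0/len1`), which
  is exact up to indel drift at contact-map resolution.
* `map_short_reads()` uses exact unique 32-mer matching; a k-mer hitting
  exactly the two members of one consensus contig maps to the primary
  member as a consensus link (usable for scaffolding, never for phasing);
  any other multi-hit is discarded.
* The evaluation metrics score sequences of at least 500 bp, the
  convention the assembly-evaluation literature reports under.

## Known limitations

Switch errors already present inside input contigs are neither detected
nor corrected — the phaser trusts each contig to be internally
haplotype-pure. Polyploid genomes are out of scope (the phase state is
binary). Gap sizes at Hi-C joins are nominal (fixed 500 N). Misassembly
splits resolve to member boundaries, so an error strictly inside one input
contig is flagged but can only be cut where the merge stage created a
boundary.
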