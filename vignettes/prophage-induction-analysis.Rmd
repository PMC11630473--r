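---
title: "Coverage-based prophage discovery and comparative analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based prophage discovery and comparative analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prophagetools)
```

This vignette documents the statistical model behind `prophagetools`, the
parameters that matter, the synthetic data used to validate the pipeline,
and the design decisions taken where the underlying procedure left choices
open.

## The detection model

Chemical induction (e.g. mitomycin C triggering the host SOS response)
makes resident prophages excise and replicate. After mapping reads from
the induced culture back to the host reference, a prophage appears as a
contiguous region whose depth exceeds the host background by a factor
close to the number of phage genome copies per chromosome. Detection is
therefore a change-point problem on a noisy, overdispersed count signal.

**Background statistics.** The background depth of a segment is summarised
by its median $m$ and a *corrected* standard deviation
$\sigma = \mathrm{sd}\{d_i : d_i \le 3m\}$ (population SD, divisor $n$).
The median is robust to elevated regions; the $3m$ truncation keeps a
strongly amplified prophage (which can reach tens of times the background)
from inflating $\sigma$ and thereby masking weaker elements. Statistics
are computed per contig for contigs over 80 kb; contigs above 350 kb are
sliced into $\lceil L/300\,000\rceil$ equal pieces (each $\le$ 300 kb) so
that genuine long-range coverage trends — origin-of-replication bias,
GC effects — do not widen $\sigma$ genome-wide. When a contig is sliced,
each sliding window is tested against the statistics of the slice
containing its midpoint, so a call can legitimately extend across a slice
boundary.

**Window calling.** Mean depth is computed in 250-bp windows stepped by
50 bp; the trailing partial window is dropped. Maximal runs of windows are
called in two passes: spans longer than 1500 bp in which every window mean
exceeds $m + 1\sigma$, and spans of 500–1500 bp in which every window
exceeds $m + 3\sigma$. Short elements must clear the stricter threshold
because a 500-bp excursion above $1\sigma$ is compatible with background
noise, whereas multi-kilobase runs above $1\sigma$ are not. The element
span is the union of member-window intervals (first window start to last
window end), so raw borders carry up to one window of overhang on each
side — border refinement (below) removes it. "Every window" (rather than
the run average) is the conservative reading of run-based calling and
keeps calls from being dragged outward by a single hot window. A run above
$3\sigma$ longer than 1500 bp is already kept by the first pass; the union
of both passes is reduced before merging. With $\sigma = 0$ (uniform
background) the thresholds degenerate to "any excess over the median",
which is logged.

**Plasmid rule.** Prophages that replicate as plasmids have no flanking
host background on their own contig. Contigs of 5–80 kb are therefore
recorded whole as candidates when
$\mathrm{median}(\text{contig}) > \mathrm{median}(\text{genome}) +
1\sigma(\text{contig})$. Contigs under 5 kb are ignored for calling:
window statistics are meaningless near the window size, and such contigs
are usually assembly fragments.

**Merging and cross-contig links.** Calls on the same contig closer than
1000 bp (strictly) are merged, with length-weighted mean coverage. A call
ending within 1000 bp of its contig end and one starting within 1000 bp of
the next contig's start are *linked*, never concatenated: in a draft
assembly the contig order is arbitrary, so coordinate concatenation would
fabricate geometry. Merging is idempotent.

**Border refinement hierarchy.** Three evidence tiers, best first:

1. *Clipped reads.* Reads spanning the circularised phage/host junction
   map partly to the host and are clipped exactly at the integration
   border. If at least 3 clip positions agree within ±5 bp at a location
   within 500 bp of a candidate border, the modal clip position is the
   border. These parameters are exposed in `detection_params()`; 3 reads
   at ±5 bp is robust at ~30× coverage while a single clipped read is not
   trustworthy evidence.
2. *Coverage step.* For induction-derived elements without clip support,
   each border is placed at the position maximising the absolute
   difference between the flanking 250-bp mean depths within ±500 bp — a
   matched filter for a step edge, whose response peaks uniquely at the
   step (a smoothed-gradient argmax would tie across the whole smoothing
   ramp). On sharp synthetic steps this recovers the border to within a
   few bases.
3. *Gene span.* Inactive candidates known only from genomic-island
   predictions are clamped to the span from their first to their last
   gene, discarding non-coding ends.

The hierarchy is applied element-wise: tier 1 is used only when both
borders have sufficient clip support, otherwise the whole element falls
through to the next tier, and the reported `border_method` names the tier
used. If no tier applies, raw window borders are kept and flagged.

One step of the original workflow is deliberately *not* reproduced:
manual inspection of coverage plots (adding faint elements the caller
missed, nudging borders by eye). The pipeline is fully deterministic; no
rule was ever stated for the manual step, so any imitation would be
invention. Detection sensitivity quoted by the test suite therefore refers
to the algorithmic caller alone.

## Curation and realm assignment

Candidates need at least five genes, plus either a realm marker gene —
terminase (large/endonuclease subunit) or major capsid for tailed phages
(Duplodnaviria), a pI-like ATPase / "gene 1" / zonular occludens toxin
homolog for filamentous phages (Monodnaviria), a double jelly-roll capsid
for tailless phages (Varidnaviria) — or at least two *distinct genes*
matching viral keywords (`coat`, `capsid`, `head`, `tail`, `virion`,
`phage`, `holin`, `terminase`, `replication`, `packaging`, plus the
filamentous-specific `Vpf81`, `BPPHL_Gene_1_protein`,
`BPFD_Gene_1_protein`). One gene matching two keywords counts once; the
requirement is two independent indications of viral origin, not two
strings. Matching is case-insensitive substring matching on annotation
label text: annotation itself (HMM/BLAST against viral databases) is an
input, not something this package performs.

When markers of several realms co-occur — possible in a mis-merged tandem
of adjacent prophages — precedence is tailless > filamentous > tailed and
a warning records the conflict for review. Realm-specific minimum sizes
(filamentous/other 4 kb, tailless 10 kb, tailed 25 kb) are inclusive
($\ge$), the natural reading when no boundary semantics are stated.

**dif sites.** Filamentous prophages integrate at *dif*, the short
chromosome-dimer-resolution motif. `find_dif_sites()` reports every
position on either strand where a 20–40 bp query matches ungapped with at
most 4 mismatches. It is implemented as a vectorised all-position Hamming
scan rather than a word-size-12 seeded search: a 24–28 bp query with 4
scattered mismatches need not contain any exact 12-mer, so seeding of
conserved-but-degenerate motifs can silently miss true sites, while the
exhaustive scan is still instantaneous at replicon scale (a few million
vectorised comparisons per query) and is exactly checkable against an
independent oracle. Gaps are not modelled: *dif* motifs are short and
length-conserved.

## Activity

PtoH = mean(prophage depth) / median(neighbourhood depth) estimates phage
genome copies per host chromosome. Classes use the corrected SD of the
neighbourhood: highly active at mean $\ge m + 3\sigma$, active at
$\ge m + 1\sigma$, inactive below; boundaries are inclusive. For plasmid
prophages the raw ratio is taken against the whole-genome median and then
divided by the plasmid copy number estimated from *non-induced*
sequencing — but only when the copy number exceeds 1, so the correction
can only decrease PtoH (a sub-single-copy estimate is clamped to 1 with a
warning rather than allowed to inflate activity). Group comparisons run
Shapiro–Wilk per group, then a two-sided Wilcoxon rank-sum test — exact
when both groups have $\le 25$ observations and no ties, otherwise the
normal approximation with tie-corrected variance and continuity
correction. Under a same-distribution null the test's type-I error at
$\alpha = 0.05$ is verified to sit in [0.03, 0.07] by simulation.

## Similarity, dereplication, gene families

**ANI.** The shorter sequence is cut into 1000-bp fragments (trailing
fragment kept at $\ge 500$ bp); each fragment is anchored by an exact
15-mer seed (five offsets tried, both strands) and aligned by gapped
extension within a ±32-bp band around the seeded location. A fragment
counts as mapped only above 70% identity — without this floor, one
spurious seed hit between unrelated 10-kb sequences would map a junk
fragment and report 10% coverage, contradicting the intended semantics of
coverage as "fraction of the genome in real homology". ANI is the
length-weighted mean identity over mapped fragments, evaluated in both
directions and averaged (making the estimate symmetric); coverage is
mapped fragment bases over total fragment bases of the shorter sequence,
so identical sequences score coverage 1.0 regardless of whether their
length is a multiple of the fragment size. For substitution-only pairs the
estimate agrees with an exact global-alignment oracle to within 0.05 ANI,
which is what makes the 99.9% retention boundary sharp: 10 substitutions
in 10 kb (99.90%) is retained, 11 (99.89%) is not.

**Dereplication** is greedy longest-first (ties by id, ascending): each
sequence joins the first representative at $\ge 99.9\%$ ANI and $\ge 80\%$
coverage of the shorter, else founds a new representative. The coverage
threshold is a parameter (`similarity_params()`): only the identity level
is inherent to the procedure, and 0.8 keeps truncated variants of one
prophage together without collapsing genuinely different genomes.

**Markov Clustering.** Protein similarity edges are weighted
$\min(\lceil -\log_{10} e \rceil, 200)$ with reciprocal hits collapsed to
the maximum; hits above $e = 10^{-5}$ are dropped and $e \le 0$ gets the
cap. MCL adds self-loops at each node's maximum incident weight (standard
regularisation; 1 for isolated nodes), column-normalises, and alternates
expansion (matrix squaring) with inflation (elementwise power 3 and
renormalisation), pruning entries below $10^{-6}$, until the matrix
changes by less than $10^{-8}$ or 200 iterations. Clusters are read as
connected components of the converged non-zero structure; node order is
fixed, so the procedure is deterministic, and disconnected graph
components are never merged. Matrices are dense: protein sets within a
prophage cluster are hundreds of nodes at most, well below the size where
sparsity matters.

**Core/variable classification.** Within a prophage cluster, a family's
frequency is the fraction of members carrying at least one gene of the
family: core above 0.8 (strict), variable at or below 0.3. Clusters under
5 members are excluded from locus analysis — below that, the
core/variable split is statistically meaningless. A variable locus is a
maximal run of non-core genes, bounded on both sides by core genes,
containing at least one variable gene; its span runs from the first to the
last *variable* gene of the run. A run of only intermediate-frequency
genes yields no locus, and a variable gene at an element edge (unflanked)
yields none either. The fine-grained clustering that groups prophages
before this analysis is taken as input (or, where needed, single-linkage
on pairwise ANI): the upstream protein-profile clustering tool is outside
this package's scope, so cluster-level percentages from any particular
study are not claimed to be reproducible here.

**Defense flags** are annotation-driven: adjacent toxin + antitoxin labels
(or an external defense tool's complete-system report, accepted as an
input flag) make a complete system; any defense-related label (abortive
infection, toxin, antitoxin, restriction, retron) without completeness is
incomplete; otherwise "other". No HMM models are bundled.

## The synthetic-data generator

`simulation_config()` / `simulate_depth_profile()` generate per-base depth
directly — not via read simulation — as negative binomial with mean 50 and
size (dispersion) 20 by default, the overdispersion regime typical of
short-read sequencing depth; a Poisson switch exists for the
equidispersed limit. Real coverage noise has no published distributional
form in this setting, so NB is this package's modelling assumption, made
explicit here. Planted elements multiply the mean by their fold (the true
phage-to-host ratio; PtoH estimation then carries a small positive bias of
order the NB mean/median gap, about 2% at the default parameters);
plasmid contigs multiply it by their copy number. Clipped-read fixtures
place exactly `reads_per_border` clip positions at each true border.
`mutate_sequence()` plants an exact Hamming distance for
identity-controlled pairs; `generate_phage_cluster()` builds clusters with
identically ordered core families and an accessory pool filled
most-available-first, which guarantees every accessory family stays at
$\le 30\%$ frequency whenever the pool capacity allows it (and refuses
otherwise). All generators take mandatory seeds and are byte-deterministic
under them.

What the generator does **not** emulate: read-level error profiles,
mapping artefacts around repeats, GC-dependent coverage waves,
ssDNA under-recovery of filamentous phages during library preparation, and
biological heterogeneity of induction timing. Passing tests therefore
demonstrate correctness of the algorithms under the stated noise model,
not end-to-end performance on wet-lab data.

## Validation scales

The test suite and `scripts/acceptance.R` exercise detection on simulated
1-Mb genomes (150–200 replicates with 1–5 planted elements of fold 5–20
and length 2–40 kb, dispersion 5, plus null genomes), PtoH recovery at
folds 2–50 on 100-kb contigs (dispersion 20, 50 replicates per fold), ANI
on 6–20-kb pairs, MCL on reference graphs, variable-locus recovery on 50
cluster fixtures, and rank-sum calibration on 1000 null replicates. These
sizes were chosen as the smallest at which the statistical properties
under test are stable; all expected values in tests were computed by
independent oracles (brute-force statistics, exhaustive Hamming scans,
exact global alignment, reference MCL runs, greedy traces) before being
frozen.

## Known limitations

- Detection sensitivity degrades if elevated elements occupy a large
  fraction of a background segment (the median itself shifts); slicing
  bounds but does not eliminate this.
- The plasmid rule cannot distinguish a prophage plasmid from any other
  multi-copy replicon; curation by gene content is what separates them.
- ANI is fragment-based and ungapped at the seeding stage; highly
  rearranged homologs map fragment-by-fragment and may under-cover.
- Keyword curation inherits the vocabulary of the annotation source;
  unannotated ("hypothetical") viral genes reduce sensitivity of rule (b).
- Cross-contig merges are reported as links; downstream size filters see
  the parts, not a joined whole.
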