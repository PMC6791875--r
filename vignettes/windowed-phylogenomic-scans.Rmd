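---
title: "Windowed phylogenomic scans: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed phylogenomic scans: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloscan)
```

## The problem

Species complexes with ongoing gene flow — the *Anopheles gambiae* complex
being the canonical example — do not have a single genome-wide phylogeny.
Incomplete lineage sorting (ILS) scatters gene trees around the species
tree, introgression replaces whole genomic tracts with a donor lineage's
history, and chromosomal inversions lock distinct genealogies into
megabase-scale blocks. The windowed scan turns this heterogeneity from a
nuisance into the signal: tile the genome alignment into fixed windows,
infer a tree per window, and read the genomic *distribution* of topologies
— which topology dominates (the species tree), where the minority
topologies cluster (introgression tracts, inversion intervals), and how
per-window genetic distances convert into divergence times.

`phyloscan` implements that workflow end to end for a nine-taxon system
modelled on the complex (a focal taxon placed as sister to *An. bwambae*,
with *An. christyi* as outgroup), together with a coalescent simulator
that generates alignments whose true genealogy per window is known, so
that every stage of the scan can be verified quantitatively.

## The scan

**Windows.** A MAF alignment anchored on a reference taxon is tiled into
non-overlapping windows of 50 kb (configurable). Every alignment column
is assigned to the window containing its reference coordinate; columns
where the reference is gapped (insertions) follow the preceding
reference base. Coordinates are 0-based half-open internally; all BED
output follows that convention. Windows with fewer than 10% *informative*
columns — columns with a determined base (non-gap, non-N) in **every**
taxon — are excluded. The threshold is absolute
(`min_informative_fraction * window_size`, 5,000 bp at the defaults,
applied unchanged to short terminal windows) and exclusion is strict:
4,999 informative columns fail, 5,000 pass. We interpret "informative"
as per-column completeness rather than parsimony informativeness because
10% of a 50 kb window must equal the 5,000 bp the filter is defined by.

**Trees.** Each retained window gets Jukes–Cantor distances computed per
taxon pair over the columns determined in both (`p >= 0.75` is flagged
saturated; pairs sharing no column are flagged missing and the window
skipped), followed by neighbor joining. Two details make the engine fully
deterministic: ties in the Q-criterion are broken by the lexicographically
smallest pair of cluster labels, so taxon order never changes the result,
and negative NJ branch lengths are clamped to zero with the deficit moved
to the sibling branch, preserving the joined pair's path length. The tree
is rooted on the outgroup. Taxa with under 50% determined characters in a
window are dropped from that window's tree; windows losing the focal,
sister or outgroup taxon are skipped with a logged reason. Bootstrap
supports resample alignment columns with replacement and count, for each
clade of the full-data tree, the percentage of replicate trees containing
it. Neighbor joining stands in for per-window maximum likelihood: the
quantities the scan consumes (topology frequencies, patristic-distance
medians) are insensitive to the engine at these divergences, and NJ is
fast enough to bootstrap thousands of windows.

**Classification.** Window trees are canonicalized (children sorted
recursively by smallest descendant label) and classified on the rooted
tree with the outgroup removed: does the focal taxon form a clade with
its expected sister? If yes, the window is an "after-speciation" pattern
and the reported neighbour is that clade's sister group; if no, a
"before-speciation" pattern with the focal taxon's own sister group.
Neighbour sets matching a configured clade definition (e.g. GC =
gambiae + coluzzii) are reported under the clade name. Maximal runs of
equal class become topology blocks; the gap between adjacent blocks is
the inferred breakpoint interval. `min_run` defaults to 1 (no smoothing),
matching a scan that reports raw per-window topologies; smoothing is
opt-in and merges sub-minimal runs into the longer flank, ties leftward.
Windows are assigned to named regions (e.g. centromere-proximal) by their
midpoint, which is unambiguous for windows straddling a region edge.

**Dating.** For a taxon pair, the per-window patristic distance (path
length on the window tree, substitutions/site) is collected across
windows; the point estimate is the **median** with a percentile-bootstrap
CI (2.5/97.5 quantiles of the resampled median; the interval type is our
choice — the generic bootstrap does not prescribe one), and ages follow

> T (Ma) = d / (2 · mu · g) / 10^6,

with mu = 1.1e-9 substitutions/site/generation and g = 10
generations/year by default. Both published forms of the rate appear in
different places of the source literature (1.1e-9 and "11e-9"); only
1.1e-9 reproduces ~0.53 Ma and ~0.31 Ma from the observed medians 0.0117
and 0.0067, so 1.1e-9 is the default and the rate is an explicit config
value. Because the conversion is linear, CI endpoints transform
monotonically. For inside/outside-region contrasts (inversion dating), a
window counts as *inside* only when fully within the region shrunk by the
flank (500 kb by default) and *outside* only when fully beyond the region
grown by it; flank-straddling windows are dropped. Two estimates are
called "distinct" iff their median CIs are disjoint; the difference of
medians is also reported with its own bootstrap CI. Alongside the CI we
report the window-wise SD, since spread can be quoted either way.

**Scaffold grafting.** To add a taxon known only from a fragmented
assembly, each alignment region is searched against the scaffold set with
a seed-and-extend matcher (11-bp exact seeds, diagonal clustering, gapped
Smith–Waterman refinement via Biostrings, +2/−3 match/mismatch, gap
open/extend 5/2) and Karlin–Altschul e-values
(E = K·m·n·exp(−lambda·S), lambda = 0.625, K = 0.41, n = total scaffold
length). The placement rule: a single raw hit is selected outright;
otherwise hits with e-value > 1e-4 or coverage <= 0.40 (inclusive at the
boundary) are excluded and a region reduced to exactly one hit is
*recovered*; zero or several survivors give no placement. Placed slices
are strand-normalized, aligned to the block's reference row, and threaded
in: reference-matching bases land in existing columns, insertions become
gap-only columns for all existing taxa — existing ungapped sequences are
byte-identical before and after, which is the tested contract. An
external tabular-hits file (outfmt-6 style columns `evalue`, `coverage`)
can be fed to `select_unique_hit()` directly when a full BLAST run is
preferred.

## The simulator

Ground truth comes from a multispecies-coalescent simulator on a dated
species tree (ages in generations, one haploid sample per taxon,
per-branch haploid effective size Ne). Each window receives **one**
genealogy — the window is the unit of inference, so intra-window
recombination adds nothing testable — drawn by coalescing lineages
within each species-tree branch at rate k(k−1)/2/Ne. Three window types:

* **species**: plain MSC draw; the probability that a quartet with
  internal branch T shows a discordant topology is (2/3)·exp(−T/Ne),
  which the test suite checks against simulated frequencies.
* **introgressed**: with the event's per-window probability, the
  recipient lineage is forced to coalesce with the donor lineage exactly
  at the event time and continues through the donor's ancestral
  populations — block-wise lineage replacement, matching the tract-like
  signal the scan detects, rather than continuous migration.
* **inversion**: windows overlapping a configured inversion interval are
  drawn under an override species tree; the shipped override places the
  inverted-karyotype clade (focal, bwambae, melas) outside all other taxa
  at 2.53 Ma, predating the 2.0 Ma radiation, so inside-region dating
  must exceed outside-region dating.

Sequences evolve by an exact Jukes–Cantor process (change probability
(3/4)(1−exp(−4d/3)) per branch, uniform among the three other bases;
vectorized over sites). Missing data is injected as i.i.d. gap columns
per taxon; the reference taxon is exempt so that its coordinates tile the
chromosome exactly. Richer models (rate heterogeneity, indels,
recombination maps, selection, demography) are deliberately out of scope:
the scan consumes topology frequencies and median distances, and the JC
single-rate model is what the dating formula assumes.

All randomness derives from one seed by arithmetic splitting: one stream
per chromosome (keyed by a hash of its name, so chromosome order is
irrelevant) and one per window. Identical configurations produce
byte-identical MAF output.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| mu | 1.1e-9 /site/generation | the only rate form consistent with the printed medians and ages |
| generations/year | 10 | standard for these mosquitoes |
| window size | 50 kb (scans), scaled in demos | the scan's unit of inference |
| informative fraction | 0.10 (strict `<` exclusion) | the 5,000 bp gloss on 10% of 50 kb |
| node ages | 0.31–4.0 Ma (table in `?gambiae_complex_tree`) | X-chromosome species topology with published split estimates |
| Ne (haploid) | 5e3 | see below |
| bootstrap replicates | 1,000 | conventional depth for supports and median CIs |
| flank | 500 kb | inversion-edge exclusion for inside/outside dating |

Ne deserves its own paragraph. No effective population sizes are
published for the complex in a form this simulator could adopt, so Ne is
a free parameter. The dating estimator (median patristic distance
converted linearly to time) ignores ancestral coalescence and therefore
overestimates a split by roughly Ne generations — 0.0005 Ma at the
default, but ~0.1 Ma at the Ne ~ 10^6 plausible for real *Anopheles*
populations. The default must represent the regime in which the method
it verifies is self-consistent: with 300 windows of 20 kb, the bootstrap
CI halfwidth is ~0.005 Ma, so Ne = 5e3 keeps the coalescent bias an
order of magnitude below it and the recovery experiments test the
estimator rather than its known bias. The ILS-calibration tests use
their own quartet trees with Ne set to produce substantial discordance.
Consequently, passing tests show the pipeline is correct *given its
model assumptions*; they do not show that patristic dating is unbiased
at realistic population sizes, and the simulator makes the opposite easy
to demonstrate by raising `ne`.

### Scaled problem sizes

The shipped demonstration and the verification suites run on scaled
problems chosen so the full workflow stays interactive: the demo genome
is one 400 kb arm at 5 kb windows; recovery experiments use 300 windows
of 20 kb per replicate; the inversion experiments use forty 2 kb windows
with a 20-window inversion. The 20 kb window length in the recovery
experiments is a numerical requirement, not a convenience: per-window
distances live on a lattice with spacing 1/L (one substitution), and the
scaled design must keep several lattice steps inside the bootstrap CI of
the median, otherwise the interval degenerates onto one or two lattice
points and coverage statements become meaningless. At 1 kb windows one
substitution is worth ~0.05 Ma and the experiment is degenerate; at
20 kb it is ~0.002 Ma against a ~0.005 Ma halfwidth.

## Numerical and degenerate-input choices

* JC correction is undefined at p >= 0.75; such pairs are flagged
  saturated, and any window with a saturated or missing pair is skipped
  rather than patched.
* NJ tie-breaks and negative-branch clamping as above; the final
  three-cluster resolution clamps at zero without redistribution.
* Bootstrap replicates that lose all shared columns for some pair are
  dropped from the support denominator.
* Empty windows, all-gap rows, windows shorter than the window size at
  chromosome ends, and blocks missing taxa (gap-padded) are all
  well-defined inputs, exercised in the tests.
* `segment_blocks` with `min_run > 1` merges the leftmost sub-minimal
  run first; each merge reduces the run count, so the procedure
  terminates.
* Forced introgression requires the event time to predate both taxa's
  first species split; the configuration constructor rejects anything
  else.

## Known limitations

* One genealogy per window and free recombination between windows —
  breakpoint intervals are only as sharp as the window grid.
* JC-only mutation; no indels, so simulated MAF blocks are exactly
  window-sized and real-alignment fragmentation is emulated only through
  the missing-data rate.
* Patristic dating inherits the source method's assumptions: strict
  clock, one rate, no coalescent correction (see the Ne discussion).
* The seed-and-extend matcher is a faithful stand-in for the filtering
  logic around it, not a statistical replica of BLAST; e-values use fixed
  Karlin–Altschul constants for the +2/−3 scheme.
* Classification assumes binary trees (NJ output); for multifurcating
  input the smallest enclosing clade rule applies and ambiguity is
  flagged by the reported taxon list rather than a named clade.
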