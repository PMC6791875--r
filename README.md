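# phyloscan

Window-based phylogenomic scans for placing a taxon inside a reticulate
species complex — detecting introgression tracts and chromosomal
inversion blocks from gene-tree discordance, and dating splits from
patristic-distance distributions. The workflow is modelled on the
genome scans used in the *Anopheles gambiae* complex, where a genome
does not have one phylogeny: incomplete lineage sorting scatters window
trees around the species tree, introgression replaces whole tracts with
a donor lineage's history, and paracentric inversions (2La-, 3La-like)
lock older genealogies into megabase blocks.

## What it does

Given a multi-species whole-genome alignment (MAF, anchored on a
reference taxon), `phyloscan`:

1. tiles the reference coordinates into fixed non-overlapping windows
   (50 kb by default) and excludes windows with fewer than 10%
   informative positions (columns determined in every taxon; < 5,000 bp
   at the defaults, strict exclusion);
2. infers a neighbor-joining tree per window from Jukes–Cantor
   distances, rooted on the outgroup, with column-resampling bootstrap
   supports (deterministic tie-breaking, so results never depend on
   taxon order);
3. canonicalizes and tallies topologies, classifies each window by the
   placement of a focal taxon (does it pair with its expected sister,
   and which clade is the neighbour?), and segments chromosomes into
   topology blocks whose edges estimate breakpoints;
4. converts per-pair patristic-distance medians into divergence times
   with percentile-bootstrap CIs,

   T (Ma) = d / (2 · μ · g) / 10⁶,  μ = 1.1×10⁻⁹ /site/generation, g = 10,

   including inside-vs-outside-inversion contrasts with 500 kb flanks
   excluded;
5. places de novo assembly scaffolds into an existing alignment as a new
   taxon row (seed-and-extend homology search with Karlin–Altschul
   e-values, the single-hit / recovered-unique / ambiguous selection
   rule at e ≤ 10⁻⁴ and coverage > 40%, and column-preserving grafting).

A multispecies-coalescent simulator generates MAF alignments with a
known dated species tree, introgression pulses (block-wise lineage
replacement at a set time) and an inversion interval whose genealogy
predates the complex radiation — so every stage is verifiable against
ground truth without any downloads.

## Worked example

The `analysis/` directory is a numbered workflow over the package; run
the scripts in order from the repository root. `analysis/01_simulate.R`
builds the demonstration genome (one 400 kb arm, nine taxa, 5 kb
windows, an introgression pulse from *gambiae* into the focal taxon over
the first 50 kb, an inversion over 100–300 kb), and the later stages
window, infer, classify and date it. Typical output:

```
$ Rscript analysis/04_scan.R
80 windows classified; focal+sister clade in 72 (90.0%)
topology blocks:
  chrom                 class first_start last_end n_windows
  chr3L        before:gambiae           0    25000         5
  ...
  chr3L after:quadriannulatus       50000   100000        10
  chr3L           after:melas      100000   300000        40
  chr3L after:quadriannulatus      300000   400000        20

$ Rscript analysis/05_date.R
fontenillei - bwambae: n = 80 windows
  median d = 0.0120 [0.0115, 0.0127]   age = 0.54 Ma [0.52, 0.58]
gambiae - coluzzii: n = 80 windows
  median d = 0.0068 [0.0066, 0.0071]   age = 0.31 Ma [0.30, 0.32]
focal pair vs gambiae-coluzzii: distinct (diff 0.0052 [0.0046, 0.0060])
fontenillei-quadriannulatus, inside vs outside the inversion:
  inside:  median d = 0.0557   age = 2.53 Ma [2.48, 2.64]
  outside: median d = 0.0282   age = 1.28 Ma [1.25, 1.36]
```

Reading the numbers: most windows show the focal taxon as sister to
*bwambae* (the "after-speciation" pattern); the inversion interval forms
a single block where the pair's neighbour switches to *melas*, and its
breakpoints fall on the true interval edges. The focal pair's median
distance converts to ~0.53 Ma — clearly distinct from the
gambiae–coluzzii 0.31 Ma — and the inversion interval dates far older
inside than outside, the signature of an inversion genealogy predating
the radiation. `analysis/06_recovery.R` repeats the dating on fresh
simulations (how often the CI covers the generating split),
`analysis/07_graft.R` re-places a fragmented copy of one taxon and
grafts it back into the alignment.

The same workflow runs from a single YAML file
(`inst/extdata/demo_config.yaml`) via

```r
library(phyloscan)
run_pipeline(system.file("extdata", "demo_config.yaml",
                         package = "phyloscan"), "results/run")
```

which writes the MAF, ground truth, filter log, Newick trees + index,
calls/tally/block tables, the dating table and a run manifest, all
deterministic under the configured seed.

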