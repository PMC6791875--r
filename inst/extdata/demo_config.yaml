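# Demonstration configuration for the windowed phylogenomic scan.
#
# A scaled-down genome (one 400 kb chromosome arm, 5 kb windows) so the
# full simulate -> windows -> trees -> scan -> date workflow runs in
# seconds. Mutation and dating parameters are the study conditions
# (mu = 1.1e-9 /site/generation, 10 generations per year); window size,
# chromosome length, bootstrap depth and flank are scaled for the demo.
# For a full-scale emulation set window_size: 50000, flank: 500000,
# n_boot: 1000 and chromosome lengths in the tens of Mb.

seed: 1

simulate:
  ne: 5000                  # haploid effective size per branch
  mu: 1.1e-9                # substitutions / site / generation
  gens_per_year: 10
  window_size: 5000
  missing_data_rate: 0.02
  reference: gambiae
  chrom_lengths:
    chr3L: 400000
  # recent gene flow from the gambiae-coluzzii group into the focal taxon,
  # confined to the centromere-proximal end of the arm
  introgression_events:
    - donor: gambiae
      recipient: fontenillei
      chrom: chr3L
      start: 0
      end: 50000
      time: 100000          # generations before present (0.01 Ma)
      prob: 0.5
  # inversion whose genealogy predates the complex radiation
  inversion_regions:
    - chrom: chr3L
      start: 100000
      end: 300000

scan:
  focal: fontenillei
  expected_sister: bwambae
  outgroup: christyi
  min_informative_fraction: 0.10
  n_boot: 50
  min_run: 1
  clades:
    GC: [gambiae, coluzzii]
    "A(GC)": [arabiensis, gambiae, coluzzii]

dating:
  mu: 1.1e-9
  gens_per_year: 10
  n_boot: 1000
  flank: 5000               # scaled analogue of the 500 kb flank exclusion
  pairs:
    - [fontenillei, bwambae]
    - [gambiae, coluzzii]
    - [fontenillei, quadriannulatus]
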