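---
title: "Reconstructing and authenticating an ancient mitochondrial genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and authenticating an ancient mitochondrial genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palaeomito)
library(dplyr)
```

## The problem

DNA recovered from archaeological skeletal remains is short, chemically
damaged, and mixed with modern human DNA introduced during excavation and
handling. Reconstructing a credible mitochondrial genome from such material
requires four things beyond ordinary read mapping: an assembler that
tolerates damage-driven mismatches and a circular coordinate frame; an
explicit check that the molecules carry the post-mortem damage signature
that authenticates ancient DNA; a quantitative bound on modern
contamination; and a placement of the finished genome on the mitochondrial
haplogroup tree using masked, substitution-level comparison. `palaeomito`
implements this pipeline end to end, together with a simulator that
generates read data with all of these properties under known truth, so
every stage can be tested quantitatively.

All user-facing functions take and return tidy data frames; fitted objects
have `tidy()`/`glance()` accessors and `autoplot()` methods.

## Coordinate frame, masks and variants

All positions are 1-based and inclusive on a circular frame (position
`L + 1` is position 1); the bundled frame is 16,569 bp, the length of the
standard human mitochondrial reference. Substitutions are written in the
field's printed notation (`C10822A`), and `parse_variant()` /
`format_variant()` are exact inverses.

Hypermutable regions are excluded from all phylogenetic comparison via a
region mask: the two poly-C runs at 303–315 and 16182–16194, the AC repeat
at 515–525, and the single hotspot site 16519. On the 16,569-position frame
this leaves 16,531 comparable positions genome-wide:

```{r}
masked_length(16569, default_hotspot_mask())
```

The coding region is fixed at positions 577–16023 inclusive. That window is
the standard mitochondrial coding span outside the control region, and
under the default mask it contains 15,447 comparable positions (none of the
hotspot intervals intersect it). Both counts are exact invariants of the
mask arithmetic, not measurements.

The bundled reference (`fixture_reference()`) is a deterministically
generated synthetic sequence with human-mtDNA-like base composition,
constrained so that every variant used by the bundled fixtures and the mini
haplogroup tree has a matching reference allele. It is a stand-in frame,
not the real reference genome; any same-length FASTA can be supplied
instead.

## The read simulator

`simulate_reads()` emulates the data-generating process of a degraded
ancient sample:

* **Fragmentation.** Fragment start positions and strands are uniform on
  the circle; lengths are log-normal (non-negative, right-skewed, the usual
  shape of ancient fragment-length distributions), truncated below at 20 nt
  to keep fragments seedable. Defaults mirror study-like libraries: means
  of 50 (tooth-like) or 56 (rib-like) nt.
* **Deamination damage.** Cytosine deamination is modelled on the read
  strand, after strand assignment: C→T with probability
  `baseline + p5_max * exp(-decay * (d - 1))` at distance `d` from the 5'
  end, and symmetrically G→A from the 3' end. Exponential decay with
  distance is the standard single-strand-overhang approximation. The
  defaults (`p_max` 0.35–0.40, `decay` 0.3) are chosen to reproduce the
  ">35% of terminal cytosines" regime typical of severely degraded
  material; real damage curves are not published with fitted constants, so
  these are calibrated to the terminal rate only. Contaminant-source
  fragments are left undamaged — deamination is post-mortem, and its
  absence in modern DNA is exactly what makes damage an authentication
  signal.
* **Sequencing error.** Per-base Phred scores are drawn from a truncated
  normal (default mean 35, sd 3, clipped to [2, 40]) and errors are
  injected at rate `10^(-q/10)`, uniformly over the three alternative
  bases.
* **Contamination.** Each fragment derives from the contaminant genome
  independently with probability `contamination_fraction`.

One global seed drives four independent per-stage generators (source
assignment, fragmentation, damage, error), so disabling one stage does not
perturb the draws of the others — a property the tests rely on. Every read
is recorded in a truth table (source, placement, strand, damaged
positions), which is what makes parameter-recovery tests possible.

What the simulator does **not** model: library-preparation chemistry
differences (single- vs double-stranded protocols), indels, index hopping,
nuclear mitochondrial insertions (NUMTs), and non-uniform fragmentation.
Tests passing on simulated data therefore demonstrate correctness of the
algorithms under the stated generative model, not robustness to every
artefact of real libraries.

## Iterative circular assembly

`iterative_assemble()` follows the classical mapping-iterative-assembler
scheme:

1. **Align** every read to the current reference (`align_reads()`):
   ungapped placement on the circle, both strands. Candidates come from an
   exact k-mer index (k = 12) over the wrap-extended reference,
   supplemented by a shorter 7-mer seed; the supplement exists because a
   heavily deaminated short read can easily lack any undamaged 12-mer, and
   dropping such reads would bias every damage statistic downward.
   Candidates are scored exhaustively (+1 match, −1 mismatch), with
   damage-consistent mismatches (reference C read as T, reference G read as
   A) charged half by default (`damage_aware = "half"`; `"off"` and
   `"full"` are available since the classical damage-aware matrix is not
   published). Complementation maps C→T onto G→A, so one rule serves both
   strands. A placement is kept when its score reaches 0.25 of the read
   length — calibrated so that random off-target sequence is accepted at
   well under 0.1% while >98% of reads remain alignable even when a third
   of all C and G sites are damaged. Ties are broken deterministically:
   higher score, plus strand before minus, smaller start.
2. **Collapse** reads sharing (start, end, strand) into unique molecules —
   they are treated as PCR duplicates of one original fragment. The
   representative carries the highest-quality base per position (ties to
   the alphabetically first base; `N` never outranks a called base).
3. **Call** the consensus: per position, qualities are summed per candidate
   base over covering molecules and the argmax is called; ties go to the
   current reference base if it is among the tied candidates, else to the
   alphabetically first. Positions covered by fewer than `min_depth`
   molecules are `N`; the default of 2 mirrors the quality-control floor
   conventionally demanded of ancient consensus positions.
4. **Iterate** with the new consensus as reference (unresolved `N`
   positions backfilled from the previous reference so seeding is not
   interrupted) until two successive consensus sequences agree at all
   mutually called positions, or `max_iter` (default 10) is reached.
   Ignoring `N` positions in the comparison prevents oscillation at
   low-depth sites.

The report records reads in/aligned, the on-target fraction, unique
molecules, and both unique-molecule and raw-read coverage (published
coverage figures do not always state which is meant, so both are given).

## Damage profiling

`damage_profile()` tabulates, for every aligned molecule and every position
within `window` (default 25) bases of each fragment end, the reference base
X and read base Y, and reports the frequency of each of the 12 ordered
substitutions as a function of distance from the 5' and 3' ends. Minus-strand
molecules are oriented read-wise first, so the profile reflects molecule
ends. Cells with zero denominator are `NA`, not 0. Authentic ancient
libraries show the C→T (5') / G→A (3') pair elevated far above the other
ten curves; `terminal_damage_summary()` reports the distance-1 rates, a
distance-1–3 average (published terminal-damage figures do not always say
which is meant), and an aDNA-consistency flag (default threshold 0.10).

By default the pipeline profiles unique molecules (post-collapse, matching
the assembler's data model) against the final consensus, so true variants
relative to the initial reference do not inflate apparent damage; flags
allow raw-read mode and profiling against the initial reference, the
convention of classical damage-pattern tools.

## Contamination from diagnostic positions

A diagnostic position is a site where at least 99% (configurable) of a
modern reference panel agrees on one base and that base differs from the
sample consensus. `find_diagnostic_positions()` derives the panel;
`estimate_contamination()` classifies every (molecule, covered diagnostic
position) observation as clean (sample base) or contaminating (panel base)
— each molecule contributes one observation per covered site, the counting
unit implied by published observation totals — and reports the proportion
with a Wilson score interval:

```{r}
wilson_interval(4, 1678)
round(100 * wilson_upper(0, 391), 1)
```

The Wilson upper endpoint is the conventional conservative contamination
bound: it remains informative at zero observed contaminant reads. Reads
carrying `N` or a third base at a diagnostic site are excluded from the
denominator, since only the two informative states are defined. The normal
quantile is computed from the confidence level rather than hard-coded, so
non-95% intervals are available. One caveat the estimator inherits from the
design: at diagnostic sites where the contaminant base happens to equal a
deamination product of the sample base (sample C / contaminant T, sample G
/ contaminant A), damage inflates the apparent contamination slightly; the
conservative direction of the bias is the safe one for an upper bound.

## Haplogroup classification, private variants and trees

All genome comparison is coordinate-anchored: fixture and user genomes are
same-length sequences in one reference frame (the substitution-only model),
so no multiple alignment is needed. This is a deliberate v1 restriction;
indels are out of scope throughout.

* `pairwise_comparison()` counts differences over unmasked, mutually
  non-`N` positions and reports similarity with the difference list as
  variants. Similarity can be computed masked (default) or unmasked, since
  published similarity figures rarely state the denominator.
* `private_variants()` reports unmasked positions where a focal genome
  differs from all other clade members while those agree — the arithmetic
  behind statements like "nine private variants separate the ancient
  genome from its two closest relatives".
* `classify_haplogroup()` descends a defining-variant tree greedily,
  entering a child when the genome carries at least 80% of its unmasked
  defining variants. The threshold is below 1 so that isolated `N`
  positions (which count as not carried) do not block an otherwise clear
  descent; exact matching is available via `min_fraction = 1`. Two
  qualifying children flag the call ambiguous. The bundled mini-tree (a
  TSV users can extend) covers only the L0d2c backbone through the three
  L0d2c1 subclades; it is data, not code.
* `nj_tree()` is a full neighbor-joining implementation (Q-criterion,
  standard branch-length formulas, deterministic label-order tie-breaks),
  exact on additive matrices — the tests exploit this by generating random
  trees, deriving their distance matrices, and requiring exact recovery.
  Neighbor joining was chosen over approximate maximum likelihood because
  the topological claims at fixture scale (clade membership, sister
  relationships) are recoverable by NJ, and NJ is fully specified and
  deterministic. Distances are hotspot-masked p-distances
  (`p_distance_matrix()`), over the whole frame or the coding window.

## Pipeline orchestration

`run_pipeline()` executes simulate → assemble → damage → contam → classify
→ tree with plain-file handoff (FASTQ/FASTA/TSV/JSON) in a run directory,
so each stage is independently inspectable and re-runnable. A manifest
records the package version, seed, full configuration and MD5 checksum of
every output; re-running a stage first verifies its inputs against the
manifest (tampering is an error), and re-running the whole pipeline with
one configuration is byte-identical. `validate_config()` fills defaults,
rejects unknown keys, aggregates all errors, and insists on a seed whenever
simulation is enabled. A thin shell entry point
(`inst/scripts/palaeomito`) wraps these functions for command-line use.

## Numerical and design choices

* **Determinism.** Every stochastic component is seeded; assemblies and
  simulated libraries are bit-reproducible at fixed seed. All tie-breaks
  (alignment, collapse, consensus, NJ) are documented and deterministic.
* **Degenerate inputs.** Zero aligned reads, an all-`N` comparison, an
  empty panel, zero informative observations, and `n = 0` proportions are
  errors with typed condition classes, not silent zeros.
* **Problem sizes in the tests.** The suite simulates libraries of roughly
  2,000–50,000 reads (coverages of about 6–150×) — large enough that
  binomial standard errors on recovered rates are a few parts per thousand,
  small enough that the whole suite runs in about a minute and a half.
  Stochastic recovery tests use 3-standard-error tolerances against
  closed-form expectations computed from the generative model.
* **The fixture genomes are constructions, not data.** The ancient-like
  genome and its clade are rebuilt from printed-style variant lists on the
  synthetic frame; the contaminant differs from the ancient genome at
  exactly 32 engineered unmasked sites, mirroring the size of a published
  diagnostic panel. Quantities derived from them (private-variant counts,
  similarities, classifications) are exact consequences of the
  construction and verify the arithmetic, not the biology.

## Known limitations

Substitution-only throughout (no indels, no structural variation); no
heteroplasmy or mixture fractions in the consensus model; no
likelihood-based authenticity scoring or EM-style contamination mixtures;
no NUMT-aware filtering; haplogroup nomenclature limited to whatever tree
the user supplies. Real published damage profiles are computed against the
real reference genome, which is not bundled; users reproducing such
figures must supply it.
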