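# palaeomito

Reconstruction, authentication and phylogenetic placement of ancient human
mitochondrial genomes from short, damaged sequencing reads — with a seeded
simulator so every stage can be validated against known truth.

Ancient skeletal DNA poses four linked problems that ordinary read mapping
does not solve: fragments are ~50 nt and carry post-mortem cytosine
deamination (C→T at 5' ends, G→A at 3' ends, often >35% at the terminal
base); the mitochondrial genome is circular; modern human DNA contaminates
every sample and must be bounded quantitatively; and the finished genome
must be placed on the haplogroup tree using hotspot-masked,
substitution-level comparison. `palaeomito` provides:

* **Simulation** (`simulate_reads()`, `make_study_fixture()`) — log-normal
  fragments, exponentially decaying terminal deamination
  `p(d) = baseline + p_max·e^(−decay·(d−1))`, Phred-conditioned sequencing
  error, and contaminant admixture, with a per-read truth table.
* **Assembly** (`iterative_assemble()`) — damage-aware k-mer-seeded
  ungapped alignment to a circular reference, PCR-duplicate collapsing by
  (start, end, strand), quality-argmax consensus calling with a minimum
  unique-molecule depth of 2, iterated until the consensus is a fixed
  point. The alignment core is compiled (Rcpp).
* **Damage profiling** (`damage_profile()`) — the 12 substitution
  frequencies by distance from each fragment end, read-wise oriented, plus
  a terminal-deamination summary and `autoplot()`.
* **Contamination** (`find_diagnostic_positions()`,
  `estimate_contamination()`) — diagnostic sites where ≥99% of a modern
  panel differs from the sample; per-observation clean/contaminating
  counts; Wilson score interval, whose upper endpoint
  `(p̂ + z²/2n + z·√(p̂(1−p̂)/n + z²/4n²)) / (1 + z²/n)` is the
  conservative contamination bound.
* **Phylogenetics** (`pairwise_comparison()`, `private_variants()`,
  `classify_haplogroup()`, `nj_tree()`) — hotspot-masked p-distances,
  private-variant arithmetic, defining-variant haplogroup classification,
  and an exact neighbor-joining implementation with Newick output.
* **Orchestration** (`run_pipeline()`) — all stages with plain-file
  handoff, a checksummed manifest, and byte-identical re-runs.

Everything is tidyverse-native: tibbles in and out, `tidy()`/`glance()`
accessors, `autoplot()` methods.

## Worked example

Simulate a study-like library (20,000 reads, 2% modern contamination,
35% terminal deamination decaying at 0.3/nt) from the bundled ancient-like
genome, assemble it, and run the authentication and placement stages:

```r
library(palaeomito)

fx  <- make_study_fixture(seed = 1)
g   <- function(id) fx$genomes$sequence[fx$genomes$id == id]
sim <- simulate_reads(
  sim_config(g("StHe"), contaminant = g("contaminant"),
             contamination_fraction = 0.02, n_reads = 20000, seed = 42),
  damage_model(p5_max = 0.35, p3_max = 0.35, decay = 0.3, baseline = 0.001))

asm <- iterative_assemble(sim$reads, fx$reference)
asm
#> <mito_assembly: 20000/20000 reads aligned (100.0%), 19867 unique molecules,
#>  mean depth 59.8x, 2 iteration(s), converged: TRUE>

terminal_damage_summary(damage_profile(asm$molecules, asm$consensus$sequence))
#>      ct5_d1    ga3_d1 ct5_d1to3 ga3_d1to3 adna_consistent
#> 1 0.3527953 0.3419252 0.2699058 0.2632384            TRUE

panel <- find_diagnostic_positions(g("StHe"), genome_record("modern", g("contaminant")))
glance(estimate_contamination(asm$molecules, panel, fx$reference$length))
#>   n_clean n_contaminant n_other      point wilson_low wilson_high confidence
#> 1    1927            43      16 0.02182741 0.01624504  0.02927101       0.95

tree <- read_haplogroup_tree(system.file("extdata", "haplogroup_tree.tsv",
                                         package = "palaeomito"))
classify_haplogroup(asm$consensus$sequence, tree)
#> <haplogroup_call: L0d2c1c; path root > L0d2c > L0d2c1 > L0d2c1c>
```

Reading the numbers: every read aligned (the library is pure
mitochondrial), duplicates collapsed to 19,867 unique molecules at ~60×
depth, and the assembly reached its fixed point in two iterations. The
terminal C→T rate of 0.353 recovers the simulated 0.351 hazard
(0.35 + baseline) and flags the library as damage-consistent. Of 1,970
informative observations at the 32 diagnostic sites, 43 carried the
contaminant base — a point estimate of 2.2% with a Wilson 95% upper bound
of 2.9%, bracketing the injected 2%. The consensus classifies to the
deepest subclade, L0d2c1c, via both of its defining variants.

Private-variant arithmetic on the fixture clade reproduces its
construction exactly:

```r
clade <- fx$genomes[fx$genomes$id %in% c("StHe", "NAM117", "NAM168"), ]
private_variants(clade, "StHe")$label
#> [1] "T408A"   "A2581G"  "A4824G"  "C11279T" "C11431T" "A11884G" "T16086C"
#> [8] "C16261T" "A16399C"
```

A full pipeline run with file handoff and a checksummed manifest:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "palaeomito"),
             outdir = "demo_run")
```

or from a shell: `inst/scripts/palaeomito run --config demo.yaml --out demo_run`.

## Method vignette

`vignettes/palaeomito-methods.Rmd` documents the models and their
assumptions, all tunable parameters with defaults and rationale, what the
simulator does and does not emulate, numerical tie-breaks, and known
limitations.
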