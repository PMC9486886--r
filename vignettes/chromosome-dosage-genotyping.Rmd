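---
title: "Methods: allele-dosage chromosome painting in a sexual-unisexual polyploid fish complex"
author: "polypaint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-dosage chromosome painting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made where the design
was genuinely open, and what the simulation-based tests do and do not
demonstrate about real data.

# The biological system

The *Carassius* complex couples two reproductive modes. The amphidiploid
goldfish (*C. auratus*, "Ca", 100 chromosomes, subgenomes A and B) is
sexual. The amphitriploid gibel carp (*C. gibelio*, "Cg", ~150
chromosomes) is a gynogenetic clone: its type-II oocytes skip pairing,
recombination and the first meiotic division entirely and develop into
unreduced 3n eggs that sperm activate but do not fertilize. Adding a
haploid Ca sperm genome to such an egg produces an amphitetraploid
(AAAABBBB-like, ~200 chromosomes) whose four-copy homolog groups can pair
as two bivalents each, restoring regular spermatogenesis. Backcrossing
this male to Ca females yields novel amphitriploids carrying one maternal
Ca set plus two paternal sets that are mosaics of Cg and Ca material —
the individuals whose chromosome composition the package infers.

# The inference model

## Diagnostic loci and the four criteria

A locus is *effective* for painting when it separates the lineages
cleanly: (i) the Cg female and both Ca parents are homozygous, (ii) the
two Ca parents agree, (iii) Cg and Ca differ, and (iv) the triploid
offspring is heterozygous. Criteria are applied in order and the first
violated one is recorded, after a `depth` check for missing calls. Hard
calls come from read fractions: `hom_ca` at or below the lower band
bound, `hom_cg` at or above the upper, `het` between, `missing` under
`min_depth` (default 5). The default band (0.1, 0.9) is a conventional
hard-call bound; it is deliberately loose so that true heterozygotes at
moderate depth are not lost.

For later generations (clonal offspring of a triploid mother), the
pairwise criterion is used instead: both parents homozygous and
different. For *set attribution* the package tightens the band to
(0.02, 0.98): in a polyploid parent "homozygous" means every copy carries
the allele, and a tetraploid site with dosage 3/4 (read fraction ~0.73
after bias) must not slip through the 0.9 bound, or attribution
frequencies inflate toward 1/2. At 30× this strict band misclassifies
essentially no truly fixed site while excluding 3/4-dosage sites with
probability near one.

## Windowed dosage and bias calibration

For each homolog group, fixed-width windows (the analysis operates at
1 Mb genome-wide on real-scale data; the scaled simulations use 100 kb)
average the per-site Cg read fraction over kept loci with nonzero depth.
Windows with fewer than `min_snps_per_window` (default 2) contributing
loci are undefined, as are windows removed by user-supplied BED masks
(the generalization of masking a repeat-divergent chromosome arm rather
than hard-coding one).

In a triploid, window means concentrate at 1/3 (one Cg copy) and 2/3
(two). Mapping against the Ca reference loses a fraction of Cg-allele
reads, shifting both modes down; with 5% bias the modes sit near 0.32 and
0.655. Rather than fixing a cutoff, `calibrate = TRUE` runs 2-means on
the genome-wide defined window frequencies (initialized at the 25th and
75th percentiles, which makes the clustering deterministic) and uses the
midpoint of the two centers. If the centers are closer than 0.05 the
data do not show two modes and the fixed threshold (default 0.5) is kept.
Windows exactly at the threshold take state 2, an arbitrary but fixed
tie-break.

## Segmentation and breakpoint calls

Undefined windows inherit the nearest defined state (ties to the left).
Interior runs shorter than `min_run` windows (default 3) are merged into
the longer neighbor (ties to the left), removing isolated noise blips.
*Terminal* runs are exempt from merging: a crossover near a chromosome
end produces exactly such a short terminal run, and near-end
recombination is a real, observed signal in this system — an
unconditional minimum-run rule would silently delete every crossover
within `min_run` windows of an end (~15% of each chromosome at the
simulated scale) and visibly bias the recombinant:nonrecombinant ratio.
Noise cannot fake a terminal run here: window means at 30× sit ~19
standard deviations from the threshold.

Each surviving state change emits one breakpoint, reported as the
interval spanning the two flanking windows — never a point estimate,
since the true exchange lies somewhere inside the window whose mean is
intermediate. Group composition is the majority state (CgCgCa vs
CgCaCa); a window-count tie is resolved by comparing the group's mean
frequency to the threshold. A group with no defined window propagates as
uncallable.

Segmentation is a threshold-plus-run-length rule rather than an HMM or
changepoint optimizer: the states are discrete, far apart relative to
noise, and the transparent rule is exactly testable.

## Set attribution and IBS

Generation-wise attribution averages, over parent-diagnostic loci, the
fraction of reads carrying the maternal (resp. paternal) allele, and
multiplies by ploidy to get whole-set counts. Identity-by-state is
defined natively on genotype dosage fractions, `IBS = 1 − mean |p_i −
p_j|` with pairwise deletion, where `p` is the read fraction rounded to
the nearest dosage attainable at the individual's ploidy. This differs
from diploid-oriented toolkits, whose genotype encoding for triploids is
not well defined; published absolute IBS values from such toolkits are
therefore treated as ordering targets only (clonal siblings above sexual
siblings; offspring–mother above offspring–father), and the package's
tests assert exactly those orderings.

# The forward simulator

## What it emulates

* **Genome**: 50 homolog groups ("1A"…"25B", two subgenomes), by default
  2 Mb each — a ~12× linear scale-down of real chromosomes that keeps
  20 windows per group, enough to place and recover breakpoints while
  keeping the full pipeline fast. Diagnostic SNP density is 1e-3/bp,
  the same order as the real effective-SNP density (hundreds of
  thousands of loci over a ~1.4 Gb genome); the real genomic
  distribution of those loci is unknown, so positions are uniform
  (Poisson process), with a regular-grid option for exact tests.
* **Decoy loci** (default 30%, split evenly) violate, one-to-one, the
  failure modes of filter criteria (i)–(iii); criterion (iv) failures
  arise naturally in offspring. `decoy_parents_differ` loci carry the Cg
  allele matching the Ca male for half of them and the Ca female for the
  other half. This split emulates within-species polymorphism and is
  what makes pairwise parent-diagnostic locus sets non-empty in every
  generation: loci where Cg matches the Ca male are exactly those at
  which the amphitetraploid father is fixed relative to the Ca mother,
  and loci where Cg matches the Ca female are those at which a triploid
  mother can be homozygous relative to a Ca sperm donor.
* **Meiosis**: bivalent pairing is uniform over the perfect
  configurations (the data give no evidence of homology-biased pairing;
  this is exposed as the single pairing rule rather than a fitted
  preference). Crossover counts per bivalent default to 1 or 2 with
  equal probability, matching the one-to-two recombination foci seen per
  bivalent; positions are uniform with no interference, since only
  counts, not a position model, are observed. Exchanges are resolved at
  the four-chromatid stage among the four non-sister pairs; the two
  meiotic divisions are collapsed into one uniform chromatid draw per
  bivalent, which is equivalent in the absence of sister-chromatid
  exchange. Type-I triploid oocytes (one bivalent + one univalent per
  group) are modeled as a census-only terminal fate, since they are
  apoptotic; type-II oocytes are the ameiotic identity map. Rare
  cytological variants (occasional univalents in spermatocytes,
  trivalents, sporadic type-II synapsis) are not simulated.
* **Sequencing**: per-site depth is Poisson (fixed-depth mode exists for
  exact tests), each read samples one chromosome copy uniformly, flips
  allele with the base error rate, and is lost with probability
  `ref_bias` if it reports the Cg allele. Bias acting on reads
  (post-error) is the simplest mechanism producing the observed skew
  toward the reference genotype; its real magnitude is unknown, so it is
  a free parameter with default 0.05. For dosage d of ploidy p the
  expected Cg fraction is `(d/p)(1−e)(1−β) / ((d/p)(1−e)(1−β) +
  (1−(d/p)(1−e)))` up to the error cross-terms, e.g. 0.310 for d/p = 1/3
  and β = 0.1.
* **Sex chromosomes**: X/Y labels ride on the copies of one designated
  homolog group and follow centromeres through meiosis; any Y makes a
  male. The founders are XXX (Cg female), XX, and XY; the synthesized
  tetraploid male is XXXY, so his sperm are XX or XY in equal proportion
  and backcross offspring are XXX females or XXY males.

## What it does not emulate

Real read mapping and variant calling (and their locus-specific error
structure), linkage disequilibrium and recombination hotspots, repeat
and structural variation, aneuploidy and paternal leakage, microchromosomes
and temperature-dependent sex determination. Passing tests therefore
demonstrate that the *inference logic* is correct under the stated
generative model — not that real libraries are free of artifacts the
model lacks. The interfaces accept real data in the same VCF/TSV dialect
precisely so the inference can be applied beyond the simulator.

# Numerical and design choices

* Coordinates are 0-based half-open everywhere; 1-based only in VCF
  output, whose REF is the Ca allele (reads map to the Ca reference).
* A chromosome copy's centromere origin is its origin at position 0
  (acrocentric convention; the data do not localize centromeres). It is
  used only to attribute whole-chromosome origin of mosaic copies.
* Truth-versus-inferred composition accuracy is scored over groups whose
  true majority is decidable at window resolution: a group whose mosaic
  copy is split within one window of 50:50 has no well-defined majority,
  and such groups (~2–4% under the default conditions) are counted and
  reported separately rather than graded. Breakpoint recall is reported
  at a ±1-window tolerance against the recorded crossover positions.
* Derived per-stage seeds make every scenario fully reproducible; the
  same seed gives bit-identical outputs, checked in the tests.

# Problem sizes used by the test suite

The standard simulation is 50 groups × 2 Mb, density 1e-3, 30% decoys,
one obligate crossover per bivalent, 30× depth with 0.2% error and 5%
bias, 100 kb windows, `min_run` 3, and 10–20 offspring — sizes chosen so
the complete suite exercises the full pipeline (roughly 100,000 loci ×
dozens of individuals) in well under a minute while keeping Monte Carlo
tolerances meaningful (3 standard errors for stochastic checks; exact
assertions wherever fixed-depth, zero-error models make outcomes
deterministic).

# Known limitations

* Crossovers within about half a window of a chromosome end round into
  the terminal window's state and are undetectable (~5% of events at the
  simulated scale); the recombinant:nonrecombinant ratio is accordingly
  biased upward by a few percent.
* The dosage model assumes euploid triploids; aneuploid groups would
  produce intermediate frequency modes the classifier does not model.
* Calibration assumes both dosage states are present genome-wide; an
  individual with (implausibly) uniform dosage falls back to the fixed
  threshold.
* IBS values depend on the locus set supplied; only orderings, not
  absolute values, are comparable across locus sets.
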