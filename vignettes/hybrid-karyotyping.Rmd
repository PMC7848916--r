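---
title: "Characterizing allopolyploid yeast hybrids from variants and depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing allopolyploid yeast hybrids from variants and depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokaryo)
```

## The problem

Interspecies *Saccharomyces* hybrids — lager yeasts being the canonical
case — carry two subgenomes, one *S. cerevisiae*-like ("Sc") and one
*S. eubayanus*-like ("Se"), in copy numbers that vary by strain and by
chromosome. When short reads from such a strain are mapped competitively
against a chimeric reference (the two species' assemblies concatenated),
reads align almost exclusively to the subgenome they came from, and two
cheap observables carry nearly all of the karyotype information:

* the **alternate allele frequency (AF)** at each variant site — the read
  fraction of the most abundant non-reference allele; and
* the **binned read depth** along each chromosome.

`allokaryo` turns these two tracks, plus the parents' variant calls, into
a strain characterization: subgenome content, mitotype, per-chromosome
integer copy number, aneuploidies, ploidy, and the parental origin of
each chromosome.

## The model

### Allele-frequency modality

At a heterozygous site on a chromosome present in $c$ copies, $a$ of
which carry the alternate allele, the read fraction of that allele is
binomial around $a/c$. Pooling sites across a region, the AF histogram is
multimodal with peaks on the lattice $\{a/c : 1 \le a \le c\}$:

| copy number | expected peaks |
|---|---|
| 2 | 0.5 |
| 3 | 0.33, 0.66 |
| 4 | 0.25, 0.5, 0.75 |
| homozygous / single copy | ~1 |

`af_peak_profile()` detects peaks in a 0.02-wide histogram (3-bin moving
average smoothing; a peak needs at least 10% of the region's sites in
its 3-bin window) and matches them against these canonical sets within
±0.05. Matching requires every *detected* heterozygous peak to be
explained by the set, but not every set member to be detected: a
triploid region in which nearly all informative sites carry a single
alternate copy shows only its 1/3 peak and is still a valid triploid
signature. Ties between eligible sets go to the set with fewer alleles.
A near-1 peak is treated separately because homozygous sites occur at
any copy number; it never vetoes a heterozygous match.

### Depth quantization

A chromosome in $c$ copies sequences to mean bin depth $c \cdot u$,
where $u$ is the per-copy depth unit. `estimate_per_copy_depth()`
recovers $u$ by grid search over $[\max(d)/8, \max(d)]$, maximizing the
quantization score

$$ S(u) = \mathrm{mean}_{d > 0}\; \exp\!\left(-\frac{(d/u -
  \mathrm{round}(d/u))^2}{2\sigma^2}\right), \qquad \sigma = 0.15, $$

with the rounded multiplier restricted to $1..8$. Ties are broken toward
the larger $u$ (fewest copies). $\sigma$ is a width in copy units: 0.15
tolerates the relative depth noise of multi-kilobase bins at tens of
reads per copy while cleanly separating adjacent integer levels.

### AF anchoring of the global scale

Depth quantization fixes copies only up to an integer factor: a genome
whose chromosomes all sit at one depth level scores equally well as
all-single-copy at $u$ or all-diploid at $u/2$, and the tie-break alone
would read every uniform genome as haploid. The AF modality supplies the
missing absolute anchor — a genome-wide 0.5 signature is diploid, not
haploid. `infer_karyotype()` therefore evaluates the candidate units
$u, u/2, u/3, u/4$ and keeps the one whose per-chromosome depth-implied
copies agree with the most AF profiles, ties toward the larger unit.
This is a single global decision; given the scale, **depth decides every
chromosome** (`copy = round(modal depth / u)`, clipped to $[0, 8]$), and
an AF profile that disagrees with the depth call is flagged
(`agreement = FALSE`, confidence `low`) but never averaged in. Fully
homozygous genomes at one depth level remain genuinely unidentifiable —
there the haploid reading is reported, flagged by the absence of
heterozygous AF support.

A chromosome whose modal (median) bin depth falls below $0.25\,u$ is a
whole-chromosome deletion ($c = 0$). The copy ceiling of 8 is beyond
plausible yeast biology and prevents degenerate small-$u$ solutions.

### Karyotype, ploidy, aneuploidy

`call_karyotype()` takes the mode of the copy calls per subgenome (ties
toward the smaller value), reports the ratio string `"Sc:Se"`, the
ploidy as modal Sc + modal Se (e.g. `"4N"`), and lists chromosomes above
the subgenome mode as duplications and below it as deletions.

### Parental tracing

A **private homozygous SNP** is homozygous-alternate in one parent and
absent (or homozygous-reference) in the other; being monoallelic in its
owner, its allele can be traced into the hybrid. The per-site parental
allele frequency is AD(parental allele)/sum(AD); a marker position
missing from the hybrid's calls but covered by the depth track is
genuine evidence of non-inheritance and contributes frequency 0
(dropping such sites would bias medians upward), while positions in
deleted regions are dropped. The chromosome-wide **median** frequency
per parent then reads off the contribution: with copy number $c$ the
integer split $k_A + k_B = c$ is chosen to minimize
$|k_A - m_A c| + |(c - k_A) - m_B c|$ jointly (independent rounding
could break the sum constraint); ties favour the parent with more
informative markers. Medians deviating more than 0.15 from the nearest
$k/c$ lower confidence rather than failing, since copy-number variation
within a chromosome legitimately shifts aggregated medians.

### Subgenome content and mitotype

The covered proportion of a subgenome is the length-weighted fraction of
its nuclear positions in bins with depth ≥ 1 read ("covered" is not
standardized; 1 read is the most literal reading and the cutoff is
configurable). The Se/Sc **mapping ratio** — the ratio of covered
proportions — separates pure strains (near 0 or very large) from
hybrids (near 1). The covered length in Mb is reported in place of an
assembly-based genome length and is labelled as such. The **mitotype**
is called from mitochondrial contig coverage: mitochondria are
uniparentally inherited, so one contig dominates overwhelmingly; the
call requires 5-fold dominance (a deliberately conservative threshold
for an effectively binary signal) and returns `ambiguous` otherwise.

## The synthetic-data generator

Because the method's inputs are variant calls and depth tracks — not
reads — the simulator operates at the variant/pileup level:

* `build_references()` makes an Sc and an Se subgenome (Roman-numeral
  vs Arabic chromosome names, one mitochondrial contig each) differing
  at exactly `round(divergence × length)` recorded positions. Default
  divergence 0.2, matching the roughly 20% nucleotide divergence of the
  two species.
* `simulate_parents()` plants heterozygous sites (0/1, one haplotype)
  and homozygous private SNPs (1/1, all haplotypes) at Poisson site
  counts per chromosome, with positions coordinated so that no two
  parents share a position and none collides with a fixed divergence
  site. Defaults of 1 site/kb per class are in the range of
  heterozygous domesticated yeast strains at desk scale.
* `mate()` forms a hybrid from an explicit per-chromosome haplotype
  list (`union_karyotype()` models rare mating, which fuses whole
  genomes), giving exact truth for per-site allele copies and
  per-chromosome parental contributions.
* `simulate_observed()` draws `DP ~ Poisson(u·c)`, allele depths
  binomial with a symmetric base-error leakage (default 0.002), and bin
  depths normal with variance shrunk by the bin-to-read-length ratio;
  the inherited mitochondrial contig gets `u ×` a multiplier (default
  20; organelle genomes are high-copy), the other only error leakage.
  An `exact = TRUE` mode suppresses all noise for oracle tests.

Default desk-scale geometry is 16 chromosomes of 50 kb per subgenome
(a ~250× linear scale-down of the 12.5 Mb subgenomes) with 10 kb depth
bins; tests use 2–7 chromosomes of 10–50 kb and 1–2 kb bins so the full
suite runs in well under a minute, and the acceptance experiments use
500 sites per AF region, ~200 markers per traced chromosome, and the
full 16+16-chromosome cross.

What the simulator deliberately does **not** model: cross-subgenome
read mis-mapping (competitive mapping is assumed perfect except for the
error leakage — real pure-Sc controls show small but nonzero Se-mapped
fractions, so real mapping ratios for pure strains are small rather
than zero), indels (every downstream statistic is exercised fully by
SNPs), read-level artifacts (GC bias, mappability, duplicates), and
sub-chromosomal recombination or LOH tracts. Passing recovery tests
therefore demonstrates correctness of the inference given the stated
observation model, not robustness to alignment pathology.

## Numerical choices and degenerate inputs

* Frequency denominator is `sum(AD)`, not `DP`: `DP` may count reads
  without an allele assignment.
* Ties among alternate alleles break toward the lowest allele index;
  multi-allelic records are kept whole.
* Missing QD/FS/MQ annotations fail closed (site removed) by default,
  with a permissive switch for foreign VCFs; all filter comparisons are
  strict (`DP > 40`, `QD > 2`, `FS < 60`, `MQ > 40` by default).
* `sum(AD) = 0` is an error for a single site and such sites are
  unusable for AF profiling.
* A VCF record on an unrecognized contig, or lacking AD, is skipped
  with a warning.
* Fewer than 20 nonzero bins make the depth unit a warning-level
  estimate; zero nonzero bins are an error.
* Chromosomes with fewer than 20 informative sites get AF profile
  `none` (depth alone decides, agreement trivially true) and
  `undetermined` parental status.
* All randomness flows from one user seed through labelled sub-streams
  (`derive_seed()`), so adding a stage never perturbs another stage's
  draws and identical seeds give byte-identical outputs.

## Limitations

* Whole-chromosome resolution: segmental CNVs shift medians and modal
  depths and surface only as low-confidence flags, not breakpoints.
* The AF anchor needs at least some heterozygous signal somewhere in
  the genome; a fully homozygous, depth-uniform genome is reported as
  haploid with no AF support.
* Copy numbers above 8 are clipped by design.
* Mitotype calls assume the depth track includes both mitochondrial
  contigs; heteroplasmy is not modeled and would surface as
  `ambiguous`.
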