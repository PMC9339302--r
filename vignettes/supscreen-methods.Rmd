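---
title: "Methods: pooled-segregant suppressor mapping and ROI-mask condensation scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-segregant suppressor mapping and ROI-mask condensation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supscreen)
```

## The problem

A temperature-sensitive yeast strain throws off spontaneous revertants:
colonies that regain growth at the restrictive temperature because a
second-site *suppressor* mutation arose somewhere in the genome. Each
revertant isolate also carries unrelated *passenger* mutations acquired at
the same time. The mapping problem is to tell the one causal mutation from
the passengers using pooled-segregant (bulk segregant) whole-genome
sequencing:

1. The revertant is backcrossed to the wildtype parent (twice, by
   default) to shed unlinked mutations.
2. Haploid segregants with the revertant phenotype are selected, so every
   one of them carries the suppressor allele.
3. Several segregants (6 per pool by default) are pooled and sequenced;
   the pooled allele frequency of each variant is the fraction of reads
   carrying it.

Because selection forces the suppressor into every pooled segregant, its
pooled frequency is 1.0 in every pool. An unlinked passenger is inherited
by each selected segregant independently with probability 1/2, so it sits
near intermediate frequencies and reaches 1.0 in a pool of $k$ only with
probability $2^{-k}$. Filtering each pool for fixed variants and
intersecting the fixed sets across independently derived pools isolates
the suppressor; with $m$ passengers, $k$ segregants per pool and $n$
pools, the expected number of passengers fixed everywhere by chance is

$$E[\text{false fixed}] = m \cdot \left(2^{-k}\right)^{n}.$$

For the default $m = 8$, $k = 6$: $8/64 = 0.125$ with one pool, and
$8/4096 \approx 0.002$ with two — which is why two modest pools suffice.

## Simulation model and its defaults

`simulate_screen()` generates a full screen with known ground truth. The
defaults are the study conditions of the assay the package models:

* **pool size `k = 6`** segregants per pool;
* **2 backcrosses** to wildtype with phenotype selection;
* **suppressor**: a 4-base frameshift deletion in a random gene
  (loss-of-function alleles are the typical spontaneous suppressor
  class); **passengers**: coding SNVs at distinct loci;
* **sequencing**: per-site depth $\sim$ Poisson(`depth`), alt reads
  $\sim$ Binomial(depth, $f(1-e) + (1-f)e$) with per-read error
  `base_error`; the observed frequency is the read ratio. The achieved
  depth of the motivating experiment is not published; `depth = 100` and
  `base_error = 0.001` are this package's choices of a realistic pooled
  short-read regime.

Segregation is deliberately simple. Under the default `"unlinked"` model
every passenger allele is an independent fair coin per selected
segregant, for any number of backcrosses; the simulator does not track
passenger loss in intermediate generations (the final cross is modeled as
heterozygous at all founder loci). This matches the marginal behaviour
that matters for fixation filtering and keeps the closed form above
exact. The `"haldane"` model adds linkage to the suppressor: a passenger
at map distance $d$ cM recombines with probability
$r = (1 - e^{-2d/100})/2$ and is co-inherited with probability
$(1 - r)^{b}$ over $b$ backcrosses. Linked passengers are the one
mechanism that genuinely breaks the $2^{-k}$ argument, which is why the
knob exists; the default map rate 0.35 cM/kb is a typical budding-yeast
average.

What the simulator does **not** emulate: read-level artifacts (mapping
bias, indel realignment), copy-number variation, aneuploidy, and
non-random spore viability. Passing the end-to-end recovery test
therefore shows the inference is correct *given* honest pooled
frequencies, not that any VCF from any caller is clean.

## Variant representation and the deletion coordinate convention

Positions are 1-based throughout. A deletion is stored as
(`pos` = first deleted base, `ref` = deleted bases, `alt` = `""`),
matching the printed `chrXVI_65946 delACTT` shorthand; conversion to and
from the left-aligned VCF anchor representation shifts by one base. The
anchor base read from a VCF is retained so round-trips are exact; records
that never came from a VCF are written with an `N` anchor rather than
requiring a reference genome. Whether a printed position refers to the
first deleted base or the VCF anchor is not stated anywhere
authoritative; the first-deleted-base reading is this package's
convention and is applied consistently.

## Coding-effect annotation

Codon numbering is 1-based from the initiator ATG. An SNV's codon is
`ceiling(cds_offset / 3)`; the affected codon is re-translated to
classify missense / synonymous / nonsense and render labels like
`K407E`. An indel whose length is not a multiple of 3 is a frameshift
reported at the codon containing the leftmost altered base in coding
orientation — so a 4-base deletion starting at CDS nucleotide 664 is a
frameshift at codon `ceiling(664/3) = 222`, preserving 221 upstream
residues. Both frameshift label styles in circulation are supported
(`"Y87fs"` by default, `"Frameshift at T222"` via `style = "long"`).
Minus-strand genes are handled by complementing plus-strand alleles into
coding orientation. The annotator is validated against a brute-force
oracle that translates the full mutant CDS and diffs proteins.

Real genome coordinates are not bundled: the printed-table examples are
validated on synthetic CDSs engineered (via `synth_cds()` overrides) so
that the printed DNA change lands on the printed codon — e.g. the
`L588F` row implies codon 588 is `TTG`, since `TTG -> TTC` is the only
single-base G-to-C change that converts leucine to phenylalanine.

## Fixation filter

The default `min_frequency` is 0.95, not 1.0: observed frequencies are
finite-depth read ratios, and a truly fixed site at depth 100 with
per-read error 0.001 reads below 1.0 about 10% of the time. Printed
tables carry exact values, so the printed-table reproduction path pins
`min_frequency = 1.0`. Raising `min_frequency` can only shrink the fixed
set (a tested monotonicity invariant). Known genes (e.g. ones already
excluded by plasmid complementation) are dropped via `exclude_genes`;
matching across pools is variant-level by default with gene-level
matching as a flag, since independent revertants may carry different
alleles of the same suppressor gene.

## Condensation scoring

The imaging assay classifies each DAPI-stained DNA mass against a fixed
circular region-of-interest mask:

1. **Segmentation**: threshold (Otsu, or fixed for synthetic images) and
   8-connected labeling; components under `min_area_px` (default 50) are
   specks and dropped.
2. **Overlap omission**: masses whose footprints touch after a 5 px
   dilation have obscured boundaries and are omitted from all
   percentages.
3. **Protrusion pruning**: morphological opening with a 7 px disc
   removes structures thinner than 7 px — the rDNA loop extensions —
   before any area is measured. The width default is sized against the
   62 px mask; a mass that opens to nothing is unscorable. A mass is
   flagged `loop_pruned` when opening removed more than 1% of its area
   (plain rasterization already costs a sub-percent rim, which must not
   count).
4. **Classification**: the mask (default diameter 62 px) is centred on
   the core centroid; the mass is `matched` when it covers at least 90%
   of the mask area **or** at least 75% of the mask-boundary pixels lie
   within 2 px of the mass, else `failed`. The OR semantics implement
   the "filled, or contacted the majority of the edges" reading; the
   0.90 fill threshold (rather than exactly 1.0) tolerates antialiased
   edges, and the 75% edge fraction with a 2 px band operationalizes a
   judgment that was originally made by eye with no stated tolerance.

A "62 pixel circle" is read as a 62 px *diameter* — a 62 px radius would
dwarf a yeast nucleus at any plausible magnification — and mask placement
at the mass centroid is this package's choice (placement was not
specified). Per-field results report `100 * n_matched / n_scored`;
replicate fields pool their counts.

The synthetic fields render each nucleus as an isotropic Gaussian blob
whose full width at the segmentation threshold equals
`compaction * mask_diameter` — so `compaction = 1` is a wildtype-sized
mass and smaller values are hypercondensed — with optional thin loop
protrusions and additive Gaussian noise. Blobs carry no chromatin
texture: the classifier only consumes area and edge geometry, so texture
would add realism without adding test power. On these noiseless blobs the
classifier provably reduces to the analytic rule "matched iff
$\theta^2 \ge 0.9$ or $31(1-\theta) \le 2$ px", which is tested on a
0.05-grid of $\theta$, alongside monotonicity of the matched percentage
in $\theta$ (20 fields of 4 nuclei per $\theta$ level, 256 px fields —
sizes chosen to exercise the full pipeline while keeping the suite
quick). Because the original micrographs and their pixel scale are not
recoverable, published matched percentages are **not** reproduction
targets; the property-based checks above are the package's validation.

## Statistics

`chi_square_gof()` compares observed category counts against expected
proportions ($\chi^2 = \sum (O-E)^2/E$, df = categories − 1);
`chi_square_independence()` is the uncorrected Pearson test
($E_{ij} = r_i c_j / N$, df = $(r-1)(c-1)$). No continuity correction is
applied anywhere. Upper-tail p-values come from the chi-square
distribution (the regularized incomplete gamma function); tests verify
agreement with an independent incomplete-gamma evaluation to 1e-8 and
nominal type-I error at $\alpha = 0.05$ under simulated nulls.
`t_two_sample()` is the two-tailed Student test (pooled variance) with a
Welch option, intended for per-field matched percentages; both
zero-variance degeneracies are defined (p = 1 for equal means, flagged
p = 0 otherwise). The exact observed/expected construction behind the
published condensation chi-square values is ambiguous as printed, so the
package exposes both test shapes and does not claim to reproduce those
p-values.

## Numerical and design notes

* Every random stage takes an explicit seed; one run seed is fanned out
  deterministically to per-stage streams, and no function perturbs the
  caller's RNG state.
* `EBImage` supplies morphology (dilation, opening, Otsu); connected
  components are labeled on the 8-neighbour pixel graph via `igraph`,
  since `EBImage::bwlabel()` is 4-connected.
* Candidate ranking is deterministic: truncating effects before
  missense before the rest, then mean frequency, then genomic
  coordinate.
* Degenerate inputs: empty VCFs and header-only TSVs parse to empty
  tables; a blank image segments to zero masses; a field with no
  scorable mass is excluded from summaries with a warning; a pool locus
  that draws Poisson depth 0 gets frequency `NA` rather than a silent 0.

## Known limitations

* Single-interval gene models only — no introns, UTRs, or splice
  effects; annotation is deliberately minimal (no effect-impact scores).
* The backcross simulator does not model meiotic interference,
  chromosome-level linkage between passengers, or segregant relatedness
  within a pool beyond selection at the suppressor.
* The condensation classifier assumes roughly convex masses; strongly
  lobed nuclei would interact with the centroid placement (an
  overlap-maximizing placement is the natural extension).
* Printed-table ingestion trusts the table's own frequencies; it cannot
  detect caller-side artifacts.
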