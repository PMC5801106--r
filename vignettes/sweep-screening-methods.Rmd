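---
title: "Methods: two-group sweep scanning and staged expression screening"
author: "sweepscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-group sweep scanning and staged expression screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(message = FALSE, warning = FALSE)
library(sweepscreen)
```

## The screening problem

The package implements a candidate-gene screen for a panel of resequenced
accessions split into two phenotype groups — the motivating case is rice
accessions that accumulate anthocyanin pigment ("high" group) versus
accessions that do not ("none" group). Artificial selection for the
phenotype is expected to leave *selective sweeps*: genomic intervals where
the selected group has lost genetic diversity relative to the control
group. The screen therefore has two independent arms:

1. a **sweep scan** over genome-wide SNPs contrasting windowed diversity
   between the groups, and
2. a **staged expression screen** over per-accession FPKM tables at three
   developmental time points, looking for consistent twofold changes.

Genes recovered by either arm are candidate regulators of the phenotype.

## SNP quality control

Raw variants are reduced to the analysis set in three stages:

* **bi-allelic screen** — only records with exactly one single-nucleotide
  alternate allele are kept (`filterBiallelic()`);
* **Hardy–Weinberg filter** — each site's pooled genotype counts are
  compared to Hardy–Weinberg proportions with a 1-df chi-square
  goodness-of-fit test (`hweTest()`); sites with `p < 0.001` are removed
  as likely mapping artifacts. The published filter sentence is ambiguous
  about the direction of the `p > 0.001` clause; we implement the standard
  reading — *retain* sites consistent with HWE (`p ≥ 0.001`) — and expose
  an exact conditional test and a per-group mode behind `QcConfig` flags.
  Monomorphic sites return `p = 1` by convention.
* **MAF filter** — sites with pooled minor-allele frequency below 0.1 are
  removed. The boundary is non-strict (`MAF ≥ 0.1` keeps the site).

Missing genotypes are excluded site-wise from all counts; sites with more
than 50% missingness are dropped (configurable, `maxMissing`). Because
retention is the conjunction of the two tests, the retained set does not
depend on filter order — a property the test suite asserts.

Transitions (A↔G, C↔T) and transversions are tallied per site
(`classifySubstitution()`, `tstvSummary()`); their ratio near 2.4 is the
usual sanity check that a SNP set is dominated by genuine variants.

## The sweep scan

### Window schemes

`makeWindows()` lays fixed windows along each chromosome: starts at
`0, step, 2·step, …` (a window is emitted iff its start is inside the
chromosome; the terminal window is clipped and flagged `short`). With
`step = size` this is the non-overlapping scheme used for genome
partitioning (10/50/100/500 kb); the default scan uses 100-kb windows
sliding by 20 kb. Windows with fewer than `minSnpsPerWindow = 30` SNPs are
left unscored: they keep their SNP count but contribute neither ZHp
moments nor ROD quantiles. The 30-SNP rule is attached to the sliding
scan; the non-overlapping schemes can set it to 0.

### Statistics

For a window \(w\) of span \(L\) bp and a group with \(n\) called alleles
per site:

* **nucleotide diversity** — per site
  \(\hat\pi = 2 p (1-p)\,n/(n-1)\) (the unbiased mean pairwise
  difference), summed over the window's SNPs and divided by \(L\)
  (`windowPi()`). The per-bp denominator is chosen because the candidate
  rule \(\pi \le 0.005\) reads naturally as a per-bp quantity over
  kb-scale windows.
* **reduction of diversity** —
  \(\mathrm{ROD} = 1 - \pi_\text{high}/\pi_\text{none}\) (`rod()`);
  values near 1 mean the high group has lost diversity. When
  \(\pi_\text{none} = 0\) the statistic is undefined and the window is
  excluded from the ROD quantile: such windows carry no usable contrast.
* **pooled heterozygosity** —
  \(H_p = 2\,\Sigma n_\text{MAJ}\,\Sigma n_\text{MIN} /
  (\Sigma n_\text{MAJ}+\Sigma n_\text{MIN})^2\) over the window's
  major/minor allele counts (`windowHp()`), computed on the high group
  (the sweep target; a pooled mode exists behind `pooledHp`).
* **ZHp** — the genome-wide z-transform of \(H_p\) over scored windows
  (`zhpScores()`); ZHp has mean 0 and sd 1 by construction, and strongly
  negative values flag candidate sweeps. A scan in which every window has
  identical \(H_p\) is degenerate and is an error, not a silent zero.
* **FST track** — Hudson's two-population estimator accumulated as a
  ratio of sums over each window's SNPs (`windowFst()`). The published
  screen does not name its estimator; Hudson's is our documented choice
  (ratio-of-sums averaging avoids the instability of per-site ratios).

### Calling sweep regions

A scored window is a hit when

* `ZHp ≤ −1.5`, **or**
* its ROD reaches the empirical 99th percentile of defined ROD values
  (`rodQuantileAlpha = 0.01`), is positive, and
  \(\pi_\text{high} \le 0.005\).

The published screen applies the ZHp and ROD rules in separate passes and
never states a conjunction, so the two routes are combined by OR here.
"Significance level \(p \le 0.01\) of the ROD distribution" is
operationalized as the empirical upper quantile — no parametric null is
claimed anywhere for ROD. Overlapping or book-ended hit windows merge
into maximal regions (the merge rule is likewise unstated in the source
screen; adjacent-or-overlapping is the conservative choice), and a
region's ZHp is the minimum over member windows. `genesInRegions()` then
reports every annotated gene overlapping a called region by ≥ 1 bp with
its in-gene SNP count and its region's ZHp. Because thresholding happens
at region level, a reported gene's own ZHp may sit slightly above the
window cutoff — consistent with how the published gene table contains one
gene at −1.49 under a −1.5 rule.

### Coordinates

Internally everything lives in 1-based-inclusive `GRanges` — the natural
container in this ecosystem. VCF and GFF3 are 1-based and pass through
unchanged; BED output converts to 0-based half-open at the boundary, and
each report file carries a comment line stating its convention. The
conversions are involutive (asserted in the I/O tests).

## The staged expression screen

Per-accession FPKM values are summarized to a group mean per transcript
and time point (median behind a flag), and the high/none ratio is
computed with a pseudocount:
\(r_t = (\bar F_\text{high,t} + c)/(\bar F_\text{none,t} + c)\),
`c = 0.01` by default — small enough to leave ratios like 36.0 or 0.01
intact, large enough that a silent transcript in one group yields a
finite ratio.

A time point *passes* at `r ≥ 2` (up) or `r ≤ 0.5` (down). The stages are

* `any` — at least one passing time point;
* `at_least_k` — at least 2 of 3 (the intermediate published stage);
* `all` — every time point.

Passing time points must agree in direction for the staged screens
(default `strictDirection = TRUE`): the published final gene set is
direction-consistent, and a transcript that is twofold up at one time
point and twofold down at another is biologically a different object
than a monotone responder. A relaxation flag exists. The stages are
provably monotone (`all ⊆ at_least_k ⊆ any`), and `classifyRegulation()`
(up iff all ratios ≥ 2; down iff all ≤ 0.5) cannot return both labels.
The final report prints per-time-point ratios plus their geometric mean,
since the source tables do not state whether their single printed ratio
is per-time-point or aggregated.

### Enrichment

Term membership is a generic two-column gene→term table — the published
screen's ontology tooling is out of scope, but any term system
(GO slims, pathways) fits this shape. Per term, enrichment of the
stage-2 selection is the upper-tail hypergeometric probability
\(P[X \ge k]\) (`fisherEnrichment()`, a one-sided Fisher exact test).
The FDR follows the source's "100 randomizations" recipe, which names no
estimator; ours is documented as: permute the selection labels over the
universe, recompute all term p-values per permutation, and set
\(\mathrm{FDR}(t) = \frac{\overline{\#\{p_\text{null} \le p_t\}}}
{\#\{p_\text{obs} \le p_t\}}\), clipped to [0, 1]. The estimator is
seed-deterministic and, under a label-random null, flags ≤ 5% of terms
at FDR < 0.05 (asserted by simulation in the acceptance tests).

## The synthetic-data generator

No generative model is published for the panel, so the generator is
deliberately minimal — sufficient to exercise every statistic, and no
more:

* per-site **independent** bi-allelic frequencies (no linkage,
  recombination, or demography — coalescent simulation is a non-goal);
* the minor-allele frequency is drawn from Uniform(0.05, 0.5) — a flat
  spectrum that exercises the MAF filter on both sides of its 0.1
  boundary; real site-frequency spectra skew low, which matters for
  absolute diversity levels but not for the contrasts the screen tests;
* diploid genotypes drawn per sample under HWE at the group's site
  frequency; inside a planted sweep the high group's frequency is scaled
  by \(1 - \text{reduction}\), so `reduction = 1` is a complete sweep
  (\(\pi_\text{high} = 0\), ROD = 1) and `reduction = 0` is a no-op
  (asserted indistinguishable from background);
* default panel sizes 8 high + 9 none diploid accessions — the
  resequencing design of the motivating study — and 8 + 2 for the
  RNA-seq arm;
* transitions drawn with probability 0.7, giving a ts/tv ratio near the
  ~2.4 expected of genuine SNP sets;
* expression: lognormal baselines, planted DE transcripts carry a
  constant fold (≥ 2 by construction) in a fixed direction at **all**
  time points, multiplicative lognormal noise with configurable CV
  (mean 1), and an FPKM floor so expressed transcripts never report
  exactly zero — zero-handling is tested separately with hand-built
  fixtures. Time points are exchangeable labels; the 5/10/15
  days-after-heading design implies no trend model we would be justified
  in inventing.

Seeds are mandatory and all randomness is routed through a local RNG
scope, so equal seeds give byte-identical output files; the planted
regions are recorded in the VCF header, making every fixture
self-describing (`sweepRegionsFromVcf()`).

Passing tests on these simulations demonstrate that the statistics,
thresholds, and plumbing behave as specified. They do **not** demonstrate
robustness to linkage disequilibrium, population structure within groups,
batch effects in FPKM, or reference-bias artifacts — none of which the
generator emulates.

## Problem sizes and numerical choices

The recovery and calibration simulations use 1-Mb chromosomes with
10 000 SNPs (≈ 0.004/bp background diversity, matching the candidate
rule's scale), 20 seeded replicates for sweep recovery, and
1000-transcript panels for DEG sensitivity — sizes at which the
Monte-Carlo properties under test are stable and a full run stays
comfortably interactive. Other choices worth knowing:

* empirical quantiles use R's default type-7 interpolation;
* the ROD quantile is computed over *defined* ROD values only;
* windows failing `minSnpsPerWindow` keep their diversity values but are
  set `NA` for Hp/ZHp/ROD/FST and excluded from scoring; clipped terminal
  windows are scored but flagged (`dropShortWindows` excludes them);
* `hweTest()` uses no continuity correction; at very small counts the
  chi-square p can differ noticeably from the exact test (the gap is
  quantified in the tests), which is why the exact test is available;
* ties in region merging cannot occur: merging is purely positional.

## Limitations

* ROD is undefined where the control group is monomorphic; long runs of
  such windows are invisible to the ROD route (the ZHp route still sees
  them).
* With ~17 accessions, heterozygosity is estimated from few alleles;
  the published screen itself notes that small panels underestimate
  heterozygosity and weaken ZHp thresholds.
* The permutation FDR redraws selections of fixed size; it does not
  condition on selection structure (e.g. chromosomal clustering of
  DEGs).
* The expression arm assumes non-replicated per-accession FPKM, as in
  the motivating design; count-based differential testing with
  replicates is deliberately out of scope.
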