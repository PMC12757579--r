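---
title: "Tracking parental genome contribution in biparental crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking parental genome contribution in biparental crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosspaint)
```

## The model

crosspaint analyzes progeny of a cross between two diploid parents that are
(near-)fully homozygous and divergent — inbred lines, the standard material
of plant breeding. Under that assumption, any site where the two parents are
homozygous for different single-base alleles is *informative*: a progeny
genotype there maps directly onto parental origin. Writing A and B for the
two parental alleles, a progeny call is

* `hom_a` — both alleles A: two alleles inherited from parent A;
* `hom_b` — both alleles B: two from parent B;
* `het_ab` — one of each;
* `missing` — no callable genotype (including half-calls like `0/.`);
* `other` — a resolved allele matching neither parent (possible at
  multiallelic sites, or from contamination and genotyping artifacts).

The contribution of parent A to a progeny, over any scope (one chromosome or
the genome), is the fraction of alleles it supplied at informative sites:

$$
\%A = 100 \cdot \frac{2 n_{AA} + n_{AB}}{2 n_{AA} + 2 n_{BB} + 2 n_{AB}}
$$

This is an identity-by-state estimate: it assumes informative markers are
dense and evenly spread enough that allele counting approximates genomic
fractions. It makes no use of a genetic map, phase, or linkage.

### Assumptions and their failure modes

* **Parents homozygous and divergent.** Residual parental heterozygosity
  silently removes sites (they are not informative) — fine — but a
  *mislabeled* parent sample produces few or no informative sites; the
  pipeline stops with a diagnostic rather than producing nonsense.
* **Diploidy.** GT fields must carry exactly two alleles. Polyploid and
  multi-parent designs are out of scope.
* **Upstream quality control.** FILTER and QUAL columns are ignored; the
  input VCF is assumed to be already filtered to trustworthy calls.

## Marker discovery choices

Multiallelic records qualify whenever both parents are homozygous for
different single-base alleles — including two different ALT alleles —
because informativeness is a property of the parental pair, not of
biallelism. Indels and multi-base alleles never qualify: block-length
variants have different error processes and the contribution model is a SNP
model. Symbolic alleles and breakends are dropped up front with a counter.
Duplicate (chromosome, position) records keep the first occurrence,
deterministically. Sites are sorted by chromosome — in length-file order
when provided, otherwise first appearance — then position, the order the
window filter and binning assume.

## The sliding-window error filter

Sporadic genotyping errors show up as single-site class flips inside long
parental blocks. The filter relabels a classified call when its positional
neighborhood disagrees:

* The window holds the nearest $(w-1)/2$ classified calls on each side of
  the center, where $w$ (default 5) counts the **full window including the
  center** — so the default consults 4 neighbors. $w$ must be odd and at
  least 3; even values are rejected at argument checking because a centered
  window needs a center.
* `missing`/`other` calls are transparent — skipped over when collecting
  neighbors, never counted, never modified. The filter corrects genotype
  labels; it does not impute.
* The center is relabeled only when a **strict majority** of its neighbors
  (center excluded) agree on a different class. Ties change nothing.
* All relabelings of a round are applied **synchronously** after the full
  scan, so the result is independent of scan direction; the tests assert
  forward/reverse equivalence and equality with an exhaustive
  window-materializing oracle on all length-8 class sequences.
* At chromosome ends windows truncate — an end site is judged by the
  neighbors that exist, with no wrap-around and no compensation from the
  other side.
* `times` bounds the number of rounds; a round with zero changes stops the
  iteration early, and 0 disables the filter. Because a label only ever
  moves to a strict-majority neighbor label, iteration reaches a fixed
  point on every finite input.

These semantics (window counted including the center, synchronous strict
majority) are one concrete choice among several defensible readings of
"consider the neighboring SNPs"; they were fixed once for determinism and
are stated here prominently since window semantics affect how aggressively
single-site flips are absorbed.

One deliberate consequence of majority voting: a *true* double-recombinant
covering a single marker is indistinguishable from an error and will be
smoothed away. With dense markers this costs little; with sparse markers
leave the filter off (its default).

## Contribution accounting

`missing` and `other` sites are counted and reported for transparency but
excluded from allele tallies and percentage denominators: a site that
resolves to no parental allele carries no contribution information, and
including it would bias percentages toward 50 for high-missingness samples.
A scope with zero classified sites reports its percentages as undefined
(`.` in the TSV output) rather than 0 or NA-as-zero. Genome-wide counts are
exact integer sums of per-chromosome counts — asserted exactly, not
approximately, in the tests. Percentages print with 4 decimal places.

## Binning and rendering

Bins are 1-based closed intervals $[(k-1)s+1,\,ks]$ of width $s$ (default
1 Mb, a readable resolution at crop-genome scale and freely overridable), so
position $s$ belongs to bin 1 and $s+1$ opens bin 2, matching VCF's 1-based
POS convention. The final bin truncates at the declared chromosome length.
Empty bins are kept so ideograms render continuous chromosomes; halving the
bin size and re-merging adjacent pairs reproduces the coarser counts
exactly.

The renderer draws each chromosome as a horizontal bar whose pixel length is
proportional to its physical length (one shared scale across chromosomes),
each bin a vertical stack in fixed order `hom_a` / `het_ab` / `hom_b` top to
bottom; the fixed order keeps images comparable across samples. Hiding a
class renormalizes the remaining segments to full bar height. SVG is the
primary format and is emitted directly with fixed two-decimal coordinates,
no generated ids and no timestamps, so identical inputs give byte-identical
files — a property the pipeline's reproducibility tests rely on. PNG/JPEG
rasterize the same geometry through the grid graphics system. Annotations
draw as ticks at the scaled midpoint of their interval; bins are not
visually flagged for low marker counts (the binned TSV export carries the
counts for anyone who needs that).

## The cross simulator

`simulate_cross()` exists so that every pipeline stage can be exercised
against known truth. It emulates:

* two fully homozygous, fully divergent parents (REF/REF and ALT/ALT at
  every marker), markers placed uniformly at unique positions;
* meioses with a Poisson number of crossovers per chromosome (default mean
  2, a typical per-chromosome recombination load in crop genomes), placed
  uniformly, no interference — interference changes block-length
  distributions but not any property the pipeline's correctness depends on;
* designs: F1 (one gamete from each parent), F2 (selfed F1), BC1 (F1 ×
  parent A), RIL (default 6 selfing generations from an F2, leaving
  residual heterozygosity near $0.5^6 \approx 1.6\%$);
* per-call noise applied *after* truth is recorded: class flips (uniform
  over the two wrong classes), non-parental-allele injection (off by
  default; when on, markers are emitted triallelic so the allele exists),
  and missingness;
* optional decoy sites where the parents are not homozygous-divergent, for
  testing marker discovery specificity.

What it does **not** emulate — and what passing tests therefore do not
demonstrate about real data: segregation distortion, position-dependent
error and missingness (real missingness clusters in repeats and near
structural variants), reference-bias toward parent A's alleles, linkage
between error and recombination hotspots, genetic-map (cM) coordinates, and
residual parental heterozygosity. The simulator validates the *pipeline's
arithmetic and bookkeeping*, not variant-calling quality.

Defaults (10 chromosomes × 50 Mb, 200 markers/chromosome, crossover rate 2,
no noise) describe a modest crop-genotyping experiment and were fixed once;
tests that need other scales say so explicitly.

## Numerical and degenerate-input choices

* Phase separators (`|` vs `/`) are equivalent; phase is discarded.
* Half-calls are `missing`, conservatively.
* Percentages are exact rational arithmetic in doubles; `pct_a + pct_b`
  is asserted to equal 100 within $10^{-6}$ wherever defined.
* Chromosome-length files may list chromosomes absent from the VCF (drawn
  empty, summarized with zero counts) and the VCF may contain chromosomes
  missing from the length file (kept in tables, dropped from plots with a
  warning): assembly metadata and variant data are deliberately decoupled.
* Parallelism is a determinism contract, not a mechanism: chromosomes are
  processed independently (`parallel::mclapply`) and merged in canonical
  order, so outputs are byte-identical for any thread count.

## Verification scales

The test suite checks exact recovery of simulated truth for all four
designs at small scale (2 chromosomes × 40–60 markers), filter behavior
exhaustively on all $3^8$ length-8 class sequences for $w \in \{3, 5\}$,
Mendelian recovery at moderate scale (BC1: 50 progeny × 2,000 markers
within 75 ± 3%; F2: 200 progeny × 10,000 markers within 1% of 25/50/25),
and byte-level determinism of all outputs across thread counts and input
paths. The F1 purity check (3 hybrids × 10 chromosomes × 2,000 markers)
must produce exactly 50.0000% — not approximately — because an error-free
F1 is heterozygous at every informative site by construction.

## Known limitations

Biparental diploid crosses only; no HMM-based ancestry smoothing (the
window filter is a deliberate, simpler alternative — an HMM would impute
`missing` sites and model error rates, at the cost of parameters to fit);
no imputation; no confidence intervals on contribution percentages; no
comparative multi-sample canvas in a single image (one file per sample).
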