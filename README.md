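# crosspaint

Parental genome contribution and graphical genotypes for biparental crosses.

## The problem

Breeders working with biparental populations — backcross programs chasing
rapid recurrent-parent genome recovery, F2 analyses, RIL development, F1
hybrid seed purity checks — constantly need to answer the same question:
*which parent contributed which part of each progeny genome?* Whole-genome
SNP data answers it, but only after a chain of bookkeeping: pick the markers
that are actually informative, classify every progeny genotype, clean up
sporadic genotyping errors, tally contributions, and draw the result so a
human can act on it. crosspaint packages that chain as a tested R library
with a small command-line front end.

## The method

From a multi-sample VCF containing two homozygous parents and their progeny:

1. **Informative SNPs.** Keep sites where parent A and parent B are
   homozygous for *different* single-base alleles. At such a site every
   progeny genotype reveals parental origin unambiguously.
2. **Classification.** Each progeny call at each informative site becomes
   `hom_a`, `hom_b`, `het_ab`, `missing`, or `other` (a resolved allele
   matching neither parent).
3. **Optional error filtering.** An iterative sliding-window majority vote:
   a classified call whose `(w-1)/2` nearest classified neighbors per side
   hold a strict majority for a different class is relabeled; updates are
   synchronous within a round, `times = 0` disables the filter.
4. **Contribution tally.** With n_AA, n_BB and n_AB the per-scope class
   counts,

   ```
   alleles_A = 2·n_AA + n_AB     alleles_B = 2·n_BB + n_AB
   %A = 100 · alleles_A / (alleles_A + alleles_B)
   ```

   reported per chromosome and genome-wide. An ideal F1 is heterozygous
   everywhere, hence exactly 50% from each parent; a BC1 averages 75% from
   the recurrent parent.
5. **Rendering.** Chromosomes draw to scale as ideograms; user-sized bins
   are stacked bars of class proportions (`hom_a` red, `het_ab` green,
   `hom_b` blue by default), with optional gene/marker overlays, exported
   as deterministic SVG or rasterized PNG/JPEG.

A seeded simulator (`simulate_cross()`) generates F1/F2/BC1/RIL crosses with
Poisson crossovers, known truth tables, and optional error/missingness, so
every stage is testable without external data.

## Worked example

```r
library(crosspaint)

sim <- simulate_cross(
  cross_sim_config(design = "BC1", n_progeny = 3, n_chrom = 2,
                   chrom_length = 40e6, markers_per_chrom = 400,
                   crossover_rate = 2, error_rate = 0.01, seed = 42),
  dir = tempfile()
)

run <- run_pipeline(
  vcf = sim$vcf, progeny = sim$progeny,
  output_prefix = file.path(tempdir(), "bc1_demo"),
  parent_a = "parent_A", parent_b = "parent_B",
  times = 1,                       # one round of w=5 window filtering
  chrom_lengths = sim$chrom_lengths_path
)
run
#> <crosspaint_run> 800 informative sites on 2 chromosome(s), 3 progeny
#> filter: window_size=5, times=1
#>   p001: parent A 55.2500%, parent B 44.7500%
#>   p002: parent A 71.0625%, parent B 28.9375%
#>   p003: parent A 67.0625%, parent B 32.9375%
```

Each line is one backcross progeny's genome-wide contribution split: p002
carries 71.1% parent-A alleles across the 800 informative markers — close to
the 75% BC1 expectation — while p001's 55.3% marks it as a poor choice for
further backcrossing. Per-chromosome rows, class counts and allele tallies
are in `run$summary` (also written to `<prefix>.summary.tsv`), and

```r
run_render(run$paths$site_details, sim$chrom_lengths_path,
           file.path(tempdir(), "ideogram"), bin_size = 1e6)
```

writes one SVG ideogram per progeny showing the parental blocks and
recombination points. The same pipeline is scriptable via the bundled CLI:

```sh
crosspaint calc -v cross.vcf.gz -a P1 -b P2 -s s1,s2,s3 -o out -w 5 -f 1
crosspaint render --site-details out.site_details.tsv \
  --chrom-lengths chroms.tsv -o out --format svg
```

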