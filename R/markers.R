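#' Identify informative SNPs between two parents
#'
#' An informative site is a locus where both parents are homozygous for
#' different single-base alleles, so every progeny genotype there reveals
#' parental origin unambiguously. Multiallelic records qualify whenever the
#' two parental homozygous alleles differ — including two different ALT
#' alleles — because informativeness is a property of the parents, not of
#' biallelism. Indels and multi-base alleles never qualify (SNP markers only).
#'
#' Non-qualifying records are skipped silently; a tally of skip reasons is
#' attached as the `"skip_tally"` attribute. Duplicate (chrom, pos) records
#' keep the first occurrence. Sites are returned sorted by chromosome (order
#' of `chrom_order` when given, else first appearance in the VCF) and
#' ascending position, the order every downstream step assumes.
#'
#' @param vcf A `cross_vcf` object from [read_cross_vcf()].
#' @param parent_a,parent_b Sample names of the two homozygous parents.
#' @param chrom_order Optional character vector fixing chromosome sort order
#'   (typically `read_chromosome_lengths()$chrom`).
#' @return Tibble with columns `chrom`, `pos`, `allele_a`, `allele_b`.
#' @export
#' @examples
#' sim <- simulate_cross(cross_sim_config(
#'   design = "F2", n_progeny = 2, n_chrom = 1, markers_per_chrom = 20, seed = 1
#' ), dir = tempdir())
#' vcf <- read_cross_vcf(sim$vcf)
#' identify_informative_sites(vcf, "parent_A", "parent_B")
identify_informative_sites <- function(vcf, parent_a, parent_b,
                                       chrom_order = NULL) {
  stopifnot(inherits(vcf, "cross_vcf"))
  for (p in c(parent_a, parent_b)) {
    if (!p %in% vcf$samples) stop_cp("parent sample not in VCF header: ", p)
  }
  ga <- parse_gt(vcf$gt[, parent_a])
  gb <- parse_gt(vcf$gt[, parent_b])

  hom_a <- !is.na(ga$a1) & ga$a1 == ga$a2
  hom_b <- !is.na(gb$a1) & gb$a1 == gb$a2
  base_a <- rep(NA_character_, nrow(vcf$variants))
  base_b <- base_a
  base_a[hom_a] <- resolve_alleles(vcf$alleles, ifelse(hom_a, ga$a1, NA_integer_))[hom_a]
  base_b[hom_b] <- resolve_alleles(vcf$alleles, ifelse(hom_b, gb$a1, NA_integer_))[hom_b]

  single <- function(x) !is.na(x) & x %in% c("A", "C", "G", "T")
  qualifies <- hom_a & hom_b & single(base_a) & single(base_b) & base_a != base_b

  tally <- c(
    parent_not_homozygous = sum(!(hom_a & hom_b)),
    identical_parental_alleles = sum(hom_a & hom_b & !is.na(base_a) &
                                       !is.na(base_b) & base_a == base_b),
    not_single_base = sum(hom_a & hom_b & base_a != base_b &
                            !(single(base_a) & single(base_b)))
  )

  sites <- tibble(
    chrom = vcf$variants$chrom[qualifies],
    pos = vcf$variants$pos[qualifies],
    allele_a = base_a[qualifies],
    allele_b = base_b[qualifies]
  )

  dup <- duplicated(sites[, c("chrom", "pos")])
  if (any(dup)) {
    warn(sprintf("%d duplicate (chrom, pos) record(s) skipped; first kept", sum(dup)))
    sites <- sites[!dup, ]
  }
  sites <- sort_by_chrom(sites, chrom_order)
  attr(sites, "skip_tally") <- tally
  sites
}

# Canonical ordering: chrom_order if supplied (unknown chroms appended in
# first-appearance order), else first appearance; positions ascending.
sort_by_chrom <- function(df, chrom_order = NULL) {
  seen <- unique(df$chrom)
  lev <- if (is.null(chrom_order)) seen else c(chrom_order, setdiff(seen, chrom_order))
  df[order(match(df$chrom, lev), df$pos), , drop = FALSE]
}
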