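#' Classify progeny genotypes at informative sites
#'
#' At each informative site, a progeny call is resolved to allele bases and
#' classified: `hom_a` (both bases equal parent A's allele), `hom_b` (both
#' equal parent B's), `het_ab` (one of each), `missing` (any missing allele
#' slot, including half-calls), or `other` (a resolved base matching neither
#' parental allele — e.g. the REF base at a site where both parents carry ALT
#' alleles, or a non-SNP allele).
#'
#' @param vcf A `cross_vcf` object containing the progeny genotypes.
#' @param sites Informative-sites tibble ([identify_informative_sites()] or
#'   [read_informative_sites()]). Every site must be present in `vcf`.
#' @param progeny Character vector of progeny sample names.
#' @return Tibble with columns `chrom`, `pos`, `sample`, `klass` (factor over
#'   [klass_levels()]); one row per sample x site, samples in the order given,
#'   sites in their input order within each sample.
#' @export
classify_progeny <- function(vcf, sites, progeny) {
  stopifnot(inherits(vcf, "cross_vcf"))
  if (length(progeny) == 0) stop_cp("no progeny samples given")
  absent <- setdiff(progeny, vcf$samples)
  if (length(absent) > 0) {
    stop_cp("progeny sample(s) not in VCF header: ", paste(absent, collapse = ", "))
  }
  check_informative_sites(sites)

  key_vcf <- paste(vcf$variants$chrom, vcf$variants$pos)
  rec <- match(paste(sites$chrom, sites$pos), key_vcf)  # first record wins
  if (anyNA(rec)) {
    i <- which(is.na(rec))[1]
    stop_cp(sprintf("informative site %s:%s not present in VCF",
                    sites$chrom[i], format(sites$pos[i], scientific = FALSE)))
  }

  per_sample <- purrr::map(progeny, function(s) {
    g <- parse_gt(vcf$gt[rec, s])
    b1 <- resolve_alleles(vcf$alleles[rec], g$a1)
    b2 <- resolve_alleles(vcf$alleles[rec], g$a2)
    a <- sites$allele_a
    b <- sites$allele_b
    klass <- rep("other", nrow(sites))
    klass[is.na(b1) | is.na(b2)] <- "missing"
    klass[b1 == a & b2 == a] <- "hom_a"
    klass[b1 == b & b2 == b] <- "hom_b"
    klass[(b1 == a & b2 == b) | (b1 == b & b2 == a)] <- "het_ab"
    tibble(chrom = sites$chrom, pos = sites$pos, sample = s,
           klass = klass_factor(klass))
  })
  bind_rows(per_sample)
}

#' Sliding-window correction of sporadic genotype errors
#'
#' Iteratively relabels isolated, locally inconsistent genotype calls by a
#' strict majority vote of their positional neighbors. For each classified
#' call (`hom_a`/`hom_b`/`het_ab`) the window holds the nearest
#' `(window_size - 1) / 2` classified calls on each side — `missing`/`other`
#' calls are skipped over when collecting neighbors and are themselves never
#' modified; near chromosome ends fewer neighbors are available. If a strict
#' majority class exists among the neighbors (center excluded) and differs
#' from the center's class, the center is relabeled. All relabelings of one
#' round are applied simultaneously after the full scan (synchronous update,
#' so the result does not depend on scan direction); a round that changes
#' nothing terminates the iteration early. `times = 0` disables the filter
#' and returns the input unchanged.
#'
#' The filter is a pure relabeling: row count, positions, and all
#' `missing`/`other` calls are identical before and after.
#'
#' @param calls Site-call tibble from [classify_progeny()]; any mix of
#'   samples and chromosomes (each sample x chromosome track is filtered
#'   independently). Positions must be sorted within each track.
#' @param window_size Odd integer >= 3: total window size including the
#'   center, so the default 5 consults 2 neighbors per side.
#' @param times Maximum number of filtering rounds; 0 disables.
#' @return The calls tibble with corrected `klass`, same row order.
#' @export
sliding_window_filter <- function(calls, window_size = 5, times = 0) {
  if (window_size < 3 || window_size %% 2 == 0) {
    stop_cp("window_size must be an odd integer >= 3, got ", window_size)
  }
  if (times < 0) stop_cp("times must be >= 0, got ", times)
  if (times == 0 || nrow(calls) == 0) return(calls)

  k <- (window_size - 1L) %/% 2L
  code <- match(as.character(calls$klass), KLASS_CLASSIFIED)  # NA = missing/other
  grp <- paste(calls$sample, calls$chrom, sep = "\r")
  out <- code
  for (g in split(seq_len(nrow(calls)), grp)) {
    if (is.unsorted(calls$pos[g], strictly = FALSE)) {
      stop_cp("calls are not position-sorted within sample/chromosome; sort first")
    }
    cls <- g[!is.na(code[g])]       # classified subsequence, in positional order
    if (length(cls) < 2) next
    x <- code[cls]
    for (r in seq_len(times)) {
      x_new <- majority_round(x, k)
      if (identical(x_new, x)) break
      x <- x_new
    }
    out[cls] <- x
  }
  changed <- !is.na(code) & out != code
  if (any(changed)) {
    calls$klass[changed] <- klass_factor(KLASS_CLASSIFIED[out[changed]])
  }
  calls
}

# One synchronous majority round on an integer vector over 1:3.
# Window = up to k nearest elements on each side (truncated at the ends),
# center excluded; replace only on strict majority differing from the center.
majority_round <- function(x, k) {
  n <- length(x)
  idx <- seq_len(n)
  lo <- pmax(idx - k, 1L)
  hi <- pmin(idx + k, n)
  nn <- hi - lo  # neighbor count (window minus the center)
  best <- integer(n)
  for (c in 1:3) {
    cs <- cumsum(x == c)
    cnt <- cs[hi] - c(0L, cs)[lo] - (x == c)
    best[2L * cnt > nn] <- c  # at most one class can hold a strict majority
  }
  replace_i <- best != 0L & best != x & nn > 0L
  x[replace_i] <- best[replace_i]
  x
}
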