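#' Read a multi-sample VCF for a biparental cross
#'
#' Loads the fields of a VCF 4.x file that the pipeline consumes (CHROM, POS,
#' REF, ALT and the per-sample GT) into a compact in-memory object. Plain-text
#' and gzipped files are both accepted; compression is detected from the file
#' content, not the extension. FILTER and QUAL are deliberately ignored: the
#' pipeline assumes standard variant quality control has already been applied.
#'
#' Records with symbolic alleles (`<DEL>`, `<INS>`, ...) or breakend notation
#' are not SNP data; they are dropped and counted in `$n_skipped_symbolic`.
#'
#' @param path Path to a `.vcf` or `.vcf.gz` file.
#' @param samples_required Character vector of sample names that must be
#'   present in the VCF header. An absent sample is a fatal error naming it.
#'   `NULL` skips the check.
#' @return A `cross_vcf` object: a list with `variants` (tibble of `chrom`,
#'   `pos`, `ref`, `alt`), `alleles` (per-record character vector
#'   `c(REF, ALT...)`), `gt` (character matrix, records x samples, raw GT
#'   strings), `samples`, and `n_skipped_symbolic`.
#' @seealso [identify_informative_sites()], [classify_progeny()]
#' @export
read_cross_vcf <- function(path, samples_required = NULL) {
  if (!file.exists(path)) {
    stop_cp("VCF file not found: ", path)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0) {
    stop_cp("VCF has no sample genotype columns: ", path)
  }
  samples <- colnames(gt)
  if (!is.null(samples_required)) {
    absent <- setdiff(samples_required, samples)
    if (length(absent) > 0) {
      stop_cp("sample(s) not in VCF header: ", paste(absent, collapse = ", "))
    }
  }
  chrom <- unname(fix[, "CHROM"])
  pos <- as.numeric(fix[, "POS"])
  ref <- unname(fix[, "REF"])
  alt <- unname(fix[, "ALT"])
  alt[is.na(alt)] <- ""

  symbolic <- grepl("[][<>]", alt)
  n_sym <- sum(symbolic)
  if (n_sym > 0) {
    keep <- !symbolic
    chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]
    gt <- gt[keep, , drop = FALSE]
    inform(sprintf("skipped %d record(s) with symbolic/breakend alleles", n_sym))
  }
  if (anyNA(pos) || any(pos < 1)) {
    stop_cp("VCF contains a non-positive or unparseable POS")
  }

  alleles <- strsplit(ifelse(alt == "", ref, paste(ref, alt, sep = ",")), ",",
                      fixed = TRUE)
  structure(
    list(
      variants = tibble(chrom = chrom, pos = pos, ref = ref, alt = alt),
      alleles = alleles,
      gt = gt,
      samples = samples,
      n_skipped_symbolic = n_sym
    ),
    class = "cross_vcf"
  )
}

#' @export
print.cross_vcf <- function(x, ...) {
  cat(sprintf(
    "<cross_vcf> %d record(s), %d sample(s): %s\n",
    nrow(x$variants), length(x$samples),
    paste(head(x$samples, 8), collapse = ", ")
  ))
  invisible(x)
}

# Parse VCF GT strings into two integer allele slots (NA = missing).
# "0/1" and "0|1" are equivalent; half-calls like "0/." are fully missing.
parse_gt <- function(gt) {
  gt[is.na(gt)] <- "./."
  parts <- strsplit(gt, "[/|]")
  bad <- lengths(parts) != 2
  if (any(bad)) {
    i <- which(bad)[1]
    stop_cp(sprintf("malformed diploid GT '%s' at record %d", gt[i], i))
  }
  m <- matrix(suppressWarnings(as.integer(unlist(parts))), ncol = 2, byrow = TRUE)
  # a half-call leaves one slot NA; treat the whole call as missing
  half <- xor(is.na(m[, 1]), is.na(m[, 2]))
  m[half, ] <- NA_integer_
  list(a1 = m[, 1], a2 = m[, 2])
}

# Resolve allele indices to base strings using the per-record allele lists.
# Out-of-range indices are fatal (corrupt GT); NA stays NA.
resolve_alleles <- function(alleles, idx) {
  nall <- lengths(alleles)
  bad <- !is.na(idx) & (idx < 0 | idx >= nall)
  if (any(bad)) {
    i <- which(bad)[1]
    stop_cp(sprintf("GT allele index %d out of range at record %d", idx[i], i))
  }
  flat <- unlist(alleles, use.names = FALSE)
  offset <- cumsum(c(0L, nall[-length(nall)]))
  out <- rep(NA_character_, length(idx))
  ok <- !is.na(idx)
  out[ok] <- flat[offset[ok] + idx[ok] + 1L]
  out
}

#' Read a chromosome-length file
#'
#' Two tab-separated columns: chromosome name and physical length in bp. A
#' header line is allowed and auto-detected (a non-numeric second field).
#' File order is preserved — it controls ideogram drawing order and the
#' canonical chromosome sort used throughout the pipeline.
#'
#' @param path Path to the tab-separated file.
#' @return Tibble with columns `chrom` (character) and `length` (numeric bp).
#' @export
read_chromosome_lengths <- function(path) {
  if (!file.exists(path)) stop_cp("chromosome-length file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_cp("chromosome-length file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first_line <- 1L
  if (is.na(suppressWarnings(as.numeric(fields[[1]][2])))) first_line <- 2L
  if (first_line > length(lines)) stop_cp("chromosome-length file has no data rows: ", path)
  out <- purrr::map2_dfr(fields[first_line:length(fields)],
                         seq(first_line, length(fields)), function(f, ln) {
    if (length(f) < 2) {
      stop_cp(sprintf("line %d: expected 2 tab-separated columns", ln))
    }
    len <- suppressWarnings(as.numeric(f[2]))
    if (is.na(len) || len != floor(len)) {
      stop_cp(sprintf("line %d: length '%s' is not an integer", ln, f[2]))
    }
    if (len < 1) stop_cp(sprintf("line %d: length must be >= 1, got %s", ln, f[2]))
    tibble(chrom = f[1], length = len)
  })
  dup <- out$chrom[duplicated(out$chrom)]
  if (length(dup) > 0) {
    stop_cp("duplicate chromosome name(s): ", paste(unique(dup), collapse = ", "))
  }
  out
}

#' Read a gene/marker annotation file
#'
#' Tab-separated columns `chrom`, `start`, `end`, `label` with a header line;
#' `end` may be omitted or "." for point markers, in which case it equals
#' `start`. Coordinates are 1-based bp.
#'
#' @param path Path to the annotation TSV.
#' @return Tibble with columns `chrom`, `start`, `end`, `label`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_cp("annotation file not found: ", path)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = ".", progress = FALSE)
  need <- c("chrom", "start", "label")
  if (!all(need %in% names(df))) {
    stop_cp("annotation file must have columns chrom, start[, end], label; got: ",
            paste(names(df), collapse = ", "))
  }
  start <- as.numeric(df$start)
  end <- if ("end" %in% names(df)) as.numeric(df$end) else rep(NA_real_, nrow(df))
  end[is.na(end)] <- start[is.na(end)]
  if (anyNA(start) || any(start < 1) || any(start > end)) {
    stop_cp("annotation coordinates must satisfy 1 <= start <= end")
  }
  tibble(chrom = df$chrom, start = start, end = end, label = df$label)
}

check_informative_sites <- function(sites) {
  need <- c("chrom", "pos", "allele_a", "allele_b")
  if (!all(need %in% names(sites))) {
    stop_cp("informative sites need columns ", paste(need, collapse = ", "),
            "; got: ", paste(names(sites), collapse = ", "))
  }
  bases <- c("A", "C", "G", "T")
  if (!all(sites$allele_a %in% bases) || !all(sites$allele_b %in% bases)) {
    stop_cp("informative-site alleles must be single bases in A/C/G/T")
  }
  if (any(sites$allele_a == sites$allele_b)) {
    stop_cp("informative site with identical parental alleles (allele_a == allele_b)")
  }
  if (anyDuplicated(sites[, c("chrom", "pos")]) > 0) {
    stop_cp("duplicate (chrom, pos) in informative sites")
  }
  invisible(sites)
}

#' Write / read the informative-sites table
#'
#' Tab-separated with a single header line and columns `chrom`, `pos`,
#' `allele_a`, `allele_b`. The round trip is lossless: reading a written file
#' reproduces the input tibble exactly. This file is the `-i` fast-path input
#' of [run_pipeline()], letting repeated analyses skip the parental scan.
#'
#' @param sites Tibble of informative sites (see
#'   [identify_informative_sites()]). Must be non-empty.
#' @param path Output / input path.
#' @return `write_informative_sites()` returns `path` invisibly;
#'   `read_informative_sites()` returns the validated tibble.
#' @export
write_informative_sites <- function(sites, path) {
  if (nrow(sites) == 0) stop_cp("no informative sites to write")
  check_informative_sites(sites)
  readr::write_tsv(sites[, c("chrom", "pos", "allele_a", "allele_b")], path,
                   na = ".", progress = FALSE)
  invisible(path)
}

#' @rdname write_informative_sites
#' @export
read_informative_sites <- function(path) {
  if (!file.exists(path)) stop_cp("informative-sites file not found: ", path)
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, c("chrom", "pos", "allele_a", "allele_b"))) {
    stop_cp("unknown informative-sites column layout; expected columns ",
            "chrom, pos, allele_a, allele_b; got: ", paste(hdr, collapse = ", "))
  }
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_double(),
      allele_a = readr::col_character(), allele_b = readr::col_character()
    ),
    na = ".", progress = FALSE
  )
  check_informative_sites(as_tibble(df))
}

#' Write / read the per-site genotype classification table
#'
#' One row per progeny sample per informative site, columns `chrom`, `pos`,
#' `sample`, `klass` (see [klass_levels()]). This is the "site details" file
#' the ideogram renderer consumes.
#'
#' @param calls Tibble of site calls (see [classify_progeny()]).
#' @param path Output / input path.
#' @return The path (write, invisibly) or the calls tibble (read).
#' @export
write_site_details <- function(calls, path) {
  out <- calls[, c("chrom", "pos", "sample", "klass")]
  out$klass <- as.character(out$klass)
  readr::write_tsv(out, path, na = ".", progress = FALSE)
  invisible(path)
}

#' @rdname write_site_details
#' @export
read_site_details <- function(path) {
  if (!file.exists(path)) stop_cp("site-details file not found: ", path)
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_double(),
      sample = readr::col_character(), klass = readr::col_character()
    ),
    progress = FALSE
  )
  bad <- setdiff(unique(df$klass), KLASS_LEVELS)
  if (length(bad) > 0) {
    stop_cp("unknown genotype class label(s): ", paste(bad, collapse = ", "))
  }
  df$klass <- klass_factor(df$klass)
  as_tibble(df)
}

#' Write the contribution summary table
#'
#' Tab-separated, one row per sample x scope (each chromosome plus a
#' `genome-wide` row). Percentages are printed with 4 decimal places;
#' undefined percentages (no classified sites in scope) print as ".".
#'
#' @param summary Tibble from [summarize_contribution()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contribution_summary <- function(summary, path) {
  out <- summary
  names(out)[names(out) == "scope"] <- "chromosome"
  out$parent_a_contribution_pct <- ifelse(is.na(out$pct_a), NA_character_,
                                          sprintf("%.4f", out$pct_a))
  out$parent_b_contribution_pct <- ifelse(is.na(out$pct_b), NA_character_,
                                          sprintf("%.4f", out$pct_b))
  out <- out[, c("sample", "chromosome", "n_hom_a", "n_hom_b", "n_het",
                 "n_missing", "n_other", "alleles_a", "alleles_b",
                 "parent_a_contribution_pct", "parent_b_contribution_pct")]
  readr::write_tsv(out, path, na = ".", progress = FALSE)
  invisible(path)
}

#' Write the binned genotype table
#'
#' Optional export of [bin_calls()] output: columns `sample`, `chrom`,
#' `start`, `end`, `n_hom_a`, `n_hom_b`, `n_het`.
#'
#' @param bins Tibble from [bin_calls()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bins <- function(bins, path) {
  readr::write_tsv(
    bins[, c("sample", "chrom", "start", "end", "n_hom_a", "n_hom_b", "n_het")],
    path, na = ".", progress = FALSE
  )
  invisible(path)
}
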