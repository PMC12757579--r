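#' Tally parental genome contributions
#'
#' Applies the two-allele tally rule: a `hom_a` site contributes two parent-A
#' alleles, a `hom_b` site two parent-B alleles, and a `het_ab` site one of
#' each. Tallies are reported per chromosome and genome-wide, in absolute
#' allele counts and as percentages. `missing`/`other` sites are counted for
#' transparency but contribute no alleles and are excluded from percentage
#' denominators; a scope with zero classified sites reports `NA` percentages
#' (printed as "." by [write_contribution_summary()]).
#'
#' @param calls Site-call tibble ([classify_progeny()], optionally after
#'   [sliding_window_filter()]).
#' @param chrom_order Optional character vector of chromosome names fixing
#'   row order and guaranteeing a row for every listed chromosome (even with
#'   zero sites); defaults to first-appearance order in `calls`.
#' @return Tibble with one row per sample x scope, scopes being each
#'   chromosome then the literal `"genome-wide"`; columns `sample`, `scope`,
#'   `n_hom_a`, `n_hom_b`, `n_het`, `n_missing`, `n_other`, `alleles_a`,
#'   `alleles_b`, `pct_a`, `pct_b`.
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   chrom = "Chr01", pos = 1:6 * 100, sample = "s1",
#'   klass = factor(c("hom_a", "hom_a", "hom_a", "hom_b", "het_ab", "het_ab"),
#'                  levels = klass_levels())
#' )
#' summarize_contribution(calls)  # 8 vs 4 alleles: 66.6667% from parent A
summarize_contribution <- function(calls, chrom_order = NULL) {
  chroms <- chrom_order %||% unique(calls$chrom)
  samples <- unique(calls$sample)
  if (length(samples) == 0) stop_cp("no calls to summarize")

  counts <- calls |>
    mutate(chrom = factor(.data$chrom, levels = chroms),
           sample = factor(.data$sample, levels = samples)) |>
    count(.data$sample, .data$chrom, .data$klass, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "klass", values_from = "n", values_fill = 0L)
  for (kl in KLASS_LEVELS) if (!kl %in% names(counts)) counts[[kl]] <- 0L

  per_chrom <- counts |>
    filter(!is.na(.data$chrom)) |>
    mutate(scope = as.character(.data$chrom))
  genome <- per_chrom |>
    group_by(.data$sample) |>
    summarise(across(all_of(KLASS_LEVELS), sum), .groups = "drop") |>
    mutate(scope = "genome-wide")

  out <- bind_rows(per_chrom |> select(-"chrom"), genome) |>
    mutate(
      n_hom_a = .data$hom_a, n_hom_b = .data$hom_b, n_het = .data$het_ab,
      n_missing = .data$missing, n_other = .data$other,
      alleles_a = 2L * .data$hom_a + .data$het_ab,
      alleles_b = 2L * .data$hom_b + .data$het_ab,
      denom = .data$alleles_a + .data$alleles_b,
      pct_a = ifelse(.data$denom > 0, 100 * .data$alleles_a / .data$denom, NA_real_),
      pct_b = ifelse(.data$denom > 0, 100 * .data$alleles_b / .data$denom, NA_real_),
      sample = as.character(.data$sample)
    ) |>
    arrange(match(.data$sample, samples),
            match(.data$scope, c(chroms, "genome-wide"))) |>
    select("sample", "scope", "n_hom_a", "n_hom_b", "n_het", "n_missing",
           "n_other", "alleles_a", "alleles_b", "pct_a", "pct_b")

  empty <- out$scope == "genome-wide" & out$alleles_a + out$alleles_b == 0
  if (any(empty)) {
    warn(paste0("sample(s) with no classified informative sites: ",
                paste(out$sample[empty], collapse = ", ")))
  }
  out
}
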