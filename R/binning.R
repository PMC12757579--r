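#' Aggregate site calls into fixed-width chromosome bins
#'
#' Tiles each chromosome in `chrom_specs` with 1-based closed intervals
#' `[(k-1)*bin_size + 1, k*bin_size]` (the last bin truncated at the
#' chromosome length) and counts the classified calls falling in each: a
#' site at position `p` lands in bin `ceiling(p / bin_size)`, so position
#' `bin_size` is in bin 1 and `bin_size + 1` opens bin 2. `missing`/`other`
#' calls are excluded from counts and totals. Zero-site bins are kept so
#' ideograms render continuous chromosomes.
#'
#' @param calls Site-call tibble; every call's chromosome must appear in
#'   `chrom_specs` and its position must not exceed the declared length.
#' @param chrom_specs Tibble from [read_chromosome_lengths()] (`chrom`,
#'   `length`); its row order sets bin/ideogram order.
#' @param bin_size Bin width in bp (default 1 Mb).
#' @return Tibble with one row per sample x bin: `sample`, `chrom`, `start`,
#'   `end`, `n_hom_a`, `n_hom_b`, `n_het`, `total`, `prop_hom_a`,
#'   `prop_hom_b`, `prop_het` (proportions `NA` when `total` is 0).
#' @export
bin_calls <- function(calls, chrom_specs, bin_size = 1e6) {
  if (bin_size < 1) stop_cp("bin_size must be >= 1, got ", bin_size)
  unknown <- setdiff(unique(calls$chrom), chrom_specs$chrom)
  if (length(unknown) > 0) {
    stop_cp("call chromosome(s) absent from the length file: ",
            paste(unknown, collapse = ", "))
  }
  len <- setNames(chrom_specs$length, chrom_specs$chrom)
  over <- calls$pos > len[calls$chrom]
  if (any(over)) {
    i <- which(over)[1]
    stop_cp(sprintf("call at %s:%s exceeds declared chromosome length %s",
                    calls$chrom[i], format(calls$pos[i], scientific = FALSE),
                    format(len[calls$chrom[i]], scientific = FALSE)))
  }

  samples <- unique(calls$sample)
  if (length(samples) == 0) samples <- NA_character_

  tiling <- chrom_specs |>
    mutate(bin = purrr::map(.data$length, ~seq_len(ceiling(.x / bin_size)))) |>
    tidyr::unnest("bin") |>
    mutate(start = (.data$bin - 1) * bin_size + 1,
           end = pmin(.data$bin * bin_size, .data$length)) |>
    select("chrom", "bin", "start", "end")
  grid <- tidyr::expand_grid(sample = samples, tiling)

  counted <- calls |>
    filter(.data$klass %in% KLASS_CLASSIFIED) |>
    mutate(bin = ceiling(.data$pos / bin_size)) |>
    count(.data$sample, .data$chrom, .data$bin, .data$klass) |>
    tidyr::pivot_wider(names_from = "klass", values_from = "n", values_fill = 0L)
  for (kl in KLASS_CLASSIFIED) if (!kl %in% names(counted)) counted[[kl]] <- 0L

  grid |>
    left_join(counted, by = c("sample", "chrom", "bin")) |>
    mutate(across(all_of(KLASS_CLASSIFIED), ~tidyr::replace_na(.x, 0L))) |>
    mutate(
      n_hom_a = .data$hom_a, n_hom_b = .data$hom_b, n_het = .data$het_ab,
      total = .data$n_hom_a + .data$n_hom_b + .data$n_het,
      prop_hom_a = ifelse(.data$total > 0, .data$n_hom_a / .data$total, NA_real_),
      prop_hom_b = ifelse(.data$total > 0, .data$n_hom_b / .data$total, NA_real_),
      prop_het = ifelse(.data$total > 0, .data$n_het / .data$total, NA_real_)
    ) |>
    select("sample", "chrom", "start", "end", "n_hom_a", "n_hom_b", "n_het",
           "total", "prop_hom_a", "prop_hom_b", "prop_het")
}
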