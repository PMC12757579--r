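#' Run the full contribution pipeline
#'
#' End-to-end backend: read the VCF, find (or load) informative sites,
#' classify every progeny at every site, optionally apply the sliding-window
#' error filter, and tally parental contributions. Writes the three
#' tab-separated outputs (`<prefix>.informative_sites.tsv`,
#' `<prefix>.site_details.tsv`, `<prefix>.summary.tsv`) plus a JSON run
#' report (`<prefix>.run_report.json`), and returns everything as tibbles.
#'
#' Chromosomes are processed independently, up to `threads` at a time;
#' results are merged in canonical chromosome order (the length-file order
#' when given, else first appearance) so output files are byte-identical for
#' any thread count.
#'
#' When `informative_sites` is supplied the parental scan is skipped and
#' `parent_a`/`parent_b` are not required — the fast path for re-analysing
#' progeny subsets; it reproduces the direct-VCF path's outputs exactly on
#' the same data.
#'
#' @param vcf Path to the multi-sample VCF (plain or gzipped).
#' @param progeny Character vector of progeny sample names.
#' @param output_prefix Path prefix for the output files.
#' @param parent_a,parent_b Parent sample names; required unless
#'   `informative_sites` is given.
#' @param informative_sites Optional path to (or tibble of) a pre-computed
#'   informative-sites table.
#' @param window_size,times Sliding-window filter parameters
#'   ([sliding_window_filter()]); `times = 0` (default) disables filtering.
#' @param threads Maximum chromosomes processed concurrently.
#' @param chrom_lengths Optional path to (or tibble of) the chromosome-length
#'   file; fixes chromosome order.
#' @return A `crosspaint_run` object (list with `sites`, `calls`, `summary`,
#'   `chrom_order`, `paths`, `params`); see also [tidy()] / [glance()]
#'   methods.
#' @export
run_pipeline <- function(vcf, progeny, output_prefix,
                         parent_a = NULL, parent_b = NULL,
                         informative_sites = NULL,
                         window_size = 5, times = 0,
                         threads = 1, chrom_lengths = NULL) {
  if (is.null(informative_sites) && (is.null(parent_a) || is.null(parent_b))) {
    stop_cp("parent_a and parent_b are required unless informative_sites is provided")
  }
  if (length(progeny) == 0) stop_cp("progeny list must be non-empty")
  clash <- intersect(c(parent_a, parent_b), progeny)
  if (length(clash) > 0) {
    stop_cp("sample(s) listed as both parent and progeny: ",
            paste(clash, collapse = ", "))
  }
  if (threads < 1) stop_cp("threads must be >= 1")

  chrom_specs <- NULL
  if (!is.null(chrom_lengths)) {
    chrom_specs <- if (is.data.frame(chrom_lengths)) as_tibble(chrom_lengths)
                   else read_chromosome_lengths(chrom_lengths)
  }

  need <- c(if (is.null(informative_sites)) c(parent_a, parent_b), progeny)
  vcf_obj <- read_cross_vcf(vcf, samples_required = need)

  if (is.null(informative_sites)) {
    sites <- identify_informative_sites(vcf_obj, parent_a, parent_b,
                                        chrom_order = chrom_specs$chrom)
  } else {
    sites <- if (is.data.frame(informative_sites)) {
      check_informative_sites(as_tibble(informative_sites))
    } else {
      read_informative_sites(informative_sites)
    }
    sites <- sort_by_chrom(sites, chrom_specs$chrom)
  }
  if (nrow(sites) == 0) {
    stop_cp("no informative sites found — parents may not be homozygous-divergent")
  }

  chrom_order <- unique(c(chrom_specs$chrom, sites$chrom))
  extra <- setdiff(unique(sites$chrom), chrom_specs$chrom %||% unique(sites$chrom))
  if (length(extra) > 0) {
    warn(paste0("chromosome(s) in VCF but not in the length file ",
                "(kept in tables, dropped from plots): ",
                paste(extra, collapse = ", ")))
  }

  site_chroms <- intersect(chrom_order, unique(sites$chrom))
  worker <- function(ch) {
    ch_sites <- sites[sites$chrom == ch, , drop = FALSE]
    calls <- classify_progeny(vcf_obj, ch_sites, progeny)
    sliding_window_filter(calls, window_size = window_size, times = times)
  }
  per_chrom <- if (threads > 1 && .Platform$OS.type != "windows") {
    parallel::mclapply(site_chroms, worker, mc.cores = threads)
  } else {
    lapply(site_chroms, worker)
  }
  failed <- vapply(per_chrom, inherits, logical(1), "try-error")
  if (any(failed)) stop_cp("chromosome worker failed: ", per_chrom[[which(failed)[1]]])
  calls <- bind_rows(per_chrom)

  summary <- summarize_contribution(calls, chrom_order = chrom_order)

  paths <- list(
    informative_sites = paste0(output_prefix, ".informative_sites.tsv"),
    site_details = paste0(output_prefix, ".site_details.tsv"),
    summary = paste0(output_prefix, ".summary.tsv"),
    run_report = paste0(output_prefix, ".run_report.json")
  )
  dir.create(dirname(paths$summary), showWarnings = FALSE, recursive = TRUE)
  write_informative_sites(sites, paths$informative_sites)
  write_site_details(calls, paths$site_details)
  write_contribution_summary(summary, paths$summary)

  gw <- summary[summary$scope == "genome-wide", ]
  report <- list(
    n_informative_sites = nrow(sites),
    n_chromosomes = length(site_chroms),
    n_progeny = length(progeny),
    filter = list(window_size = window_size, times = times),
    skip_tally = as.list(attr(sites, "skip_tally") %||%
                           setNames(list(), character(0))),
    n_skipped_symbolic = vcf_obj$n_skipped_symbolic,
    genome_wide_pct_a = setNames(as.list(gw$pct_a), gw$sample)
  )
  jsonlite::write_json(report, paths$run_report, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  structure(
    list(sites = sites, calls = calls, summary = summary,
         chrom_order = chrom_order, chrom_specs = chrom_specs, paths = paths,
         params = list(parent_a = parent_a, parent_b = parent_b,
                       progeny = progeny, window_size = window_size,
                       times = times, threads = threads)),
    class = "crosspaint_run"
  )
}

#' Render ideograms for every sample of a pipeline run
#'
#' The frontend counterpart of [run_pipeline()]: bins the site-detail calls
#' and writes one ideogram per progeny sample
#' (`<prefix>.<sample>.<format>`). Calls on chromosomes absent from the
#' length file are dropped from plots with a warning.
#'
#' @param site_details Path to (or tibble of) the site-details table written
#'   by [run_pipeline()].
#' @param chrom_lengths Path to (or tibble of) the chromosome-length file
#'   (required: sets bar lengths and drawing order).
#' @param output_prefix Path prefix for the image files.
#' @param annotations Optional path to (or tibble of) an annotation file.
#' @param style A [render_style()].
#' @param bin_size Bin width in bp (default 1 Mb).
#' @param out_format `"svg"`, `"png"` or `"jpeg"`.
#' @param samples Samples to render (default: all in the site details); a
#'   requested sample absent from the data is fatal.
#' @return Named character vector of written image paths, invisibly.
#' @export
run_render <- function(site_details, chrom_lengths, output_prefix,
                       annotations = NULL, style = render_style(),
                       bin_size = 1e6, out_format = "svg", samples = NULL) {
  calls <- if (is.data.frame(site_details)) as_tibble(site_details)
           else read_site_details(site_details)
  chrom_specs <- if (is.data.frame(chrom_lengths)) as_tibble(chrom_lengths)
                 else read_chromosome_lengths(chrom_lengths)
  ann <- if (is.null(annotations)) NULL
         else if (is.data.frame(annotations)) as_tibble(annotations)
         else read_annotations(annotations)

  have <- unique(calls$sample)
  samples <- samples %||% have
  absent <- setdiff(samples, have)
  if (length(absent) > 0) {
    stop_cp("sample(s) not present in site details: ",
            paste(absent, collapse = ", "))
  }
  drop <- !calls$chrom %in% chrom_specs$chrom
  if (any(drop)) {
    warn(paste0("dropping calls on chromosome(s) not in the length file: ",
                paste(unique(calls$chrom[drop]), collapse = ", ")))
    calls <- calls[!drop, , drop = FALSE]
  }

  bins <- bin_calls(calls[calls$sample %in% samples, , drop = FALSE],
                    chrom_specs, bin_size = bin_size)
  dir.create(dirname(paste0(output_prefix, ".x")), showWarnings = FALSE,
             recursive = TRUE)
  out <- vapply(samples, function(s) {
    path <- paste0(output_prefix, ".", s, ".", out_format)
    render_ideogram(bins, chrom_specs, path, annotations = ann, style = style,
                    out_format = out_format, sample = s)
    path
  }, character(1))
  invisible(out)
}

#' @export
print.crosspaint_run <- function(x, ...) {
  gw <- x$summary[x$summary$scope == "genome-wide", ]
  cat(sprintf(
    "<crosspaint_run> %d informative sites on %d chromosome(s), %d progeny\n",
    nrow(x$sites), length(unique(x$sites$chrom)), length(x$params$progeny)
  ))
  cat(sprintf("filter: window_size=%d, times=%d\n",
              x$params$window_size, x$params$times))
  for (i in seq_len(nrow(gw))) {
    cat(sprintf("  %s: parent A %s%%, parent B %s%%\n", gw$sample[i],
                ifelse(is.na(gw$pct_a[i]), ".", sprintf("%.4f", gw$pct_a[i])),
                ifelse(is.na(gw$pct_b[i]), ".", sprintf("%.4f", gw$pct_b[i]))))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pipeline run into its contribution summary
#'
#' @param x A `crosspaint_run`.
#' @param ... Unused.
#' @return The contribution summary tibble (one row per sample x scope).
#' @method tidy crosspaint_run
#' @export
tidy.crosspaint_run <- function(x, ...) x$summary

#' One-row overview of a pipeline run
#'
#' @param x A `crosspaint_run`.
#' @param ... Unused.
#' @return A one-row tibble: site/chromosome/progeny counts, filter
#'   settings, and the mean genome-wide parent-A contribution.
#' @method glance crosspaint_run
#' @export
glance.crosspaint_run <- function(x, ...) {
  gw <- x$summary[x$summary$scope == "genome-wide", ]
  tibble(
    n_informative_sites = nrow(x$sites),
    n_chromosomes = length(unique(x$sites$chrom)),
    n_progeny = length(x$params$progeny),
    window_size = x$params$window_size,
    filter_times = x$params$times,
    mean_pct_a = mean(gw$pct_a, na.rm = TRUE)
  )
}
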