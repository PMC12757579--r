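#' Configure a synthetic biparental cross
#'
#' Describes a simulated cross between two fully homozygous, fully divergent
#' parents. Meioses place a Poisson-distributed number of crossovers
#' (`crossover_rate` expected per chromosome, no interference) uniformly
#' along the chromosome and alternate parental haplotypes between
#' breakpoints. Supported designs: `F1` (one gamete from each parent — every
#' progeny heterozygous everywhere), `F2` (selfed F1, 1:2:1 per locus), `BC1`
#' (F1 backcrossed to parent A, no `hom_b` possible), and `RIL`
#' (`ril_generations` successive selfings from an F2, near-homozygous
#' mosaics).
#'
#' Genotyping noise is applied after the true classes are recorded:
#' `error_rate` flips a call to one of the other two classes uniformly,
#' `other_rate` replaces a call with a homozygous non-parental allele (this
#' also makes every marker triallelic in the emitted VCF so the allele
#' exists), and `missing_rate` blanks a call to `./.`.
#'
#' @param design One of `"F1"`, `"F2"`, `"BC1"`, `"RIL"`.
#' @param n_progeny Number of progeny samples.
#' @param n_chrom,chrom_length Number of chromosomes and their common length
#'   in bp; ignored when `chrom_specs` is given.
#' @param chrom_specs Optional tibble (`chrom`, `length`) for unequal
#'   chromosomes.
#' @param markers_per_chrom Informative markers per chromosome, placed
#'   uniformly at unique positions.
#' @param crossover_rate Expected crossovers per chromosome per meiosis.
#' @param error_rate,missing_rate,other_rate Per-call noise probabilities.
#' @param noninformative_per_chrom Extra decoy sites per chromosome at which
#'   the parents are not homozygous-divergent (half identical-homozygous,
#'   half heterozygous parent A); they must not be picked up as markers.
#' @param ril_generations Selfing generations for the `RIL` design.
#' @param seed RNG seed; a fixed seed makes the simulated VCF and truth
#'   table byte-identical across runs.
#' @return A `cross_sim_config` list, validated.
#' @seealso [simulate_cross()]
#' @export
cross_sim_config <- function(design = c("F1", "F2", "BC1", "RIL"),
                             n_progeny = 20,
                             n_chrom = 10,
                             chrom_length = 5e7,
                             chrom_specs = NULL,
                             markers_per_chrom = 200,
                             crossover_rate = 2,
                             error_rate = 0,
                             missing_rate = 0,
                             other_rate = 0,
                             noninformative_per_chrom = 0,
                             ril_generations = 6,
                             seed = 1) {
  design <- match.arg(design)
  if (is.null(chrom_specs)) {
    chrom_specs <- tibble(chrom = sprintf("chr%02d", seq_len(n_chrom)),
                          length = rep(chrom_length, n_chrom))
  }
  stopifnot(
    n_progeny >= 1, markers_per_chrom >= 1, crossover_rate >= 0,
    error_rate >= 0, error_rate <= 1, missing_rate >= 0, missing_rate <= 1,
    other_rate >= 0, other_rate <= 1, noninformative_per_chrom >= 0,
    ril_generations >= 1, all(chrom_specs$length >= 1)
  )
  if (any(markers_per_chrom + noninformative_per_chrom > chrom_specs$length)) {
    stop_cp("more sites requested than positions on a chromosome")
  }
  structure(
    list(design = design, n_progeny = n_progeny, chrom_specs = chrom_specs,
         markers_per_chrom = markers_per_chrom, crossover_rate = crossover_rate,
         error_rate = error_rate, missing_rate = missing_rate,
         other_rate = other_rate,
         noninformative_per_chrom = noninformative_per_chrom,
         ril_generations = ril_generations, seed = seed),
    class = "cross_sim_config"
  )
}

#' Simulate a biparental cross to VCF with ground truth
#'
#' Generates a standard multi-sample VCF (parents `parent_A`, `parent_B`,
#' progeny `p001`, `p002`, ...) plus a truth table of each progeny's true
#' genotype class at every marker, recorded before any noise is applied.
#' Also writes the matching chromosome-length file. With a fixed seed the
#' outputs are byte-identical across runs.
#'
#' @param config A [cross_sim_config()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix for the three outputs.
#' @return List with `vcf`, `truth_path`, `chrom_lengths_path` (paths),
#'   `truth` (tibble `chrom`, `pos`, `sample`, `true_klass`), `chrom_specs`,
#'   `parent_a`, `parent_b`, `progeny`.
#' @export
#' @examples
#' sim <- simulate_cross(cross_sim_config(
#'   design = "F1", n_progeny = 2, n_chrom = 2,
#'   markers_per_chrom = 10, seed = 42
#' ), dir = tempdir())
#' readLines(sim$vcf, n = 6)
simulate_cross <- function(config,
                           dir = tempfile("crosspaint_sim"),
                           prefix = "sim") {
  stopifnot(inherits(config, "cross_sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  progeny <- sprintf("p%03d", seq_len(config$n_progeny))
  samples <- c("parent_A", "parent_B", progeny)
  bases <- c("A", "C", "G", "T")
  triallelic <- config$other_rate > 0

  body_lines <- character(0)
  truth_parts <- list()

  for (ci in seq_len(nrow(config$chrom_specs))) {
    chrom <- config$chrom_specs$chrom[ci]
    clen <- config$chrom_specs$length[ci]
    m <- config$markers_per_chrom
    n_extra <- config$noninformative_per_chrom
    all_pos <- sort(sample.int(clen, m + n_extra))
    marker_i <- sort(sample.int(m + n_extra, m))
    pos <- all_pos[marker_i]

    ref <- sample(bases, m, replace = TRUE)
    alt1 <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    alt2 <- if (triallelic) {
      purrr::map2_chr(ref, alt1, ~sample(setdiff(bases, c(.x, .y)), 1))
    } else NULL

    # true ancestry of each progeny haplotype at each marker ("A"/"B")
    anc <- sim_design_ancestry(config, pos, clen)  # list(h1, h2): m x n_progeny
    true_class <- matrix("het_ab", m, config$n_progeny)
    true_class[anc$h1 == "A" & anc$h2 == "A"] <- "hom_a"
    true_class[anc$h1 == "B" & anc$h2 == "B"] <- "hom_b"

    truth_parts[[ci]] <- tibble(
      chrom = chrom,
      pos = rep(pos, times = config$n_progeny),
      sample = rep(progeny, each = m),
      true_klass = as.vector(true_class)
    )

    obs <- true_class
    if (config$error_rate > 0) {
      flip <- matrix(runif(length(obs)) < config$error_rate, m)
      if (any(flip)) {
        others <- rbind(hom_a = c("hom_b", "het_ab"),
                        hom_b = c("hom_a", "het_ab"),
                        het_ab = c("hom_a", "hom_b"))
        pick <- sample(1:2, sum(flip), replace = TRUE)
        obs[flip] <- others[cbind(match(obs[flip], rownames(others)), pick)]
      }
    }
    gt_map <- c(hom_a = "0/0", hom_b = "1/1", het_ab = "0/1")
    gt <- matrix(gt_map[obs], m)
    if (triallelic) {
      oth <- matrix(runif(length(gt)) < config$other_rate, m)
      gt[oth] <- "2/2"
    }
    if (config$missing_rate > 0) {
      mis <- matrix(runif(length(gt)) < config$missing_rate, m)
      gt[mis] <- "./."
    }

    alt_field <- if (triallelic) paste(alt1, alt2, sep = ",") else alt1
    rows <- matrix("", m + n_extra, 1)
    marker_rows <- paste(
      chrom, format(pos, scientific = FALSE, trim = TRUE), ".", ref, alt_field,
      ".", ".", ".", "GT", "0/0", "1/1",
      apply(gt, 1, paste, collapse = "\t"),
      sep = "\t"
    )
    rows[marker_i] <- marker_rows

    if (n_extra > 0) {
      extra_i <- setdiff(seq_len(m + n_extra), marker_i)
      epos <- all_pos[extra_i]
      eref <- sample(bases, n_extra, replace = TRUE)
      ealt <- vapply(eref, function(b) sample(setdiff(bases, b), 1), character(1))
      # half: both parents identical homozygous; half: parent A heterozygous
      pa <- rep(c("0/0", "0/1"), length.out = n_extra)
      pb <- "0/0"
      prog_gt <- paste(rep("0/0", config$n_progeny), collapse = "\t")
      rows[extra_i] <- paste(
        chrom, format(epos, scientific = FALSE, trim = TRUE), ".", eref, ealt,
        ".", ".", ".", "GT", pa, pb, prog_gt,
        sep = "\t"
      )
    }
    body_lines <- c(body_lines, rows[, 1])
  }

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=crosspaint_simulate_cross",
    sprintf("##contig=<ID=%s,length=%s>", config$chrom_specs$chrom,
            format(config$chrom_specs$length, scientific = FALSE, trim = TRUE)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )

  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  writeLines(c(header, body_lines), vcf_path)

  truth <- bind_rows(truth_parts) |>
    arrange(match(.data$chrom, config$chrom_specs$chrom), .data$sample, .data$pos)
  truth_path <- file.path(dir, paste0(prefix, ".truth.tsv"))
  readr::write_tsv(truth, truth_path, progress = FALSE)

  chrom_lengths_path <- file.path(dir, paste0(prefix, ".chrom_lengths.tsv"))
  readr::write_tsv(config$chrom_specs, chrom_lengths_path, progress = FALSE)

  list(vcf = vcf_path, truth = truth, truth_path = truth_path,
       chrom_specs = config$chrom_specs, chrom_lengths_path = chrom_lengths_path,
       parent_a = "parent_A", parent_b = "parent_B", progeny = progeny)
}

# One recombinant gamete from a diploid parent: Poisson(rate) breakpoints,
# uniform on [0, len], alternating between the parent's two haplotypes.
sim_gamete <- function(h1, h2, pos, len, rate) {
  ncx <- rpois(1, rate)
  start <- sample(1:2, 1)
  if (ncx == 0) return(if (start == 1) h1 else h2)
  bp <- sort(runif(ncx, 0, len))
  seg <- findInterval(pos, bp)  # segment 0..ncx; haplotype alternates by segment
  ifelse(seg %% 2 == (if (start == 1) 0 else 1), h1, h2)
}

# Per-chromosome ancestry of every progeny under the configured design.
# Returns list(h1, h2): character matrices (markers x progeny) of "A"/"B".
sim_design_ancestry <- function(config, pos, clen) {
  m <- length(pos)
  n <- config$n_progeny
  A <- rep("A", m); B <- rep("B", m)
  h1 <- matrix("", m, n); h2 <- h1
  for (j in seq_len(n)) {
    hap <- switch(
      config$design,
      F1 = list(A, B),
      F2 = list(sim_gamete(A, B, pos, clen, config$crossover_rate),
                sim_gamete(A, B, pos, clen, config$crossover_rate)),
      BC1 = list(sim_gamete(A, B, pos, clen, config$crossover_rate), A),
      RIL = {
        ind <- list(sim_gamete(A, B, pos, clen, config$crossover_rate),
                    sim_gamete(A, B, pos, clen, config$crossover_rate))
        for (g in seq_len(config$ril_generations)) {
          ind <- list(
            sim_gamete(ind[[1]], ind[[2]], pos, clen, config$crossover_rate),
            sim_gamete(ind[[1]], ind[[2]], pos, clen, config$crossover_rate)
          )
        }
        ind
      }
    )
    h1[, j] <- hap[[1]]
    h2[, j] <- hap[[2]]
  }
  list(h1 = h1, h2 = h2)
}
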