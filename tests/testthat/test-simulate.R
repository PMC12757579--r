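test_that("design constraints hold exactly in error-free simulations", {
  f1 <- simulate_cross(cross_sim_config(design = "F1", n_progeny = 3,
                                        n_chrom = 2, markers_per_chrom = 30,
                                        seed = 2), dir = tempfile())
  expect_true(all(f1$truth$true_klass == "het_ab"))

  bc1 <- simulate_cross(cross_sim_config(design = "BC1", n_progeny = 5,
                                         n_chrom = 2, markers_per_chrom = 50,
                                         seed = 3), dir = tempfile())
  expect_false(any(bc1$truth$true_klass == "hom_b"))
})

test_that("a fixed seed reproduces the VCF and truth table byte for byte", {
  cfg <- cross_sim_config(design = "F2", n_progeny = 4, n_chrom = 2,
                          markers_per_chrom = 25, error_rate = 0.05,
                          missing_rate = 0.02, seed = 77)
  s1 <- simulate_cross(cfg, dir = tempfile())
  s2 <- simulate_cross(cfg, dir = tempfile())
  expect_identical(readLines(s1$vcf), readLines(s2$vcf))
  expect_identical(readLines(s1$truth_path), readLines(s2$truth_path))

  s3 <- simulate_cross(cross_sim_config(design = "F2", n_progeny = 4,
                                        n_chrom = 2, markers_per_chrom = 25,
                                        error_rate = 0.05, missing_rate = 0.02,
                                        seed = 78), dir = tempfile())
  expect_false(identical(readLines(s1$vcf), readLines(s3$vcf)))
})

test_that("the simulator does not disturb the caller's RNG stream", {
  set.seed(1); before <- runif(1)
  set.seed(1)
  simulate_cross(cross_sim_config(design = "F1", n_progeny = 1, n_chrom = 1,
                                  markers_per_chrom = 5, seed = 9),
                 dir = tempfile())
  expect_identical(runif(1), before)
})

test_that("noise-free pipelines recover the truth table for every design", {
  for (design in c("F1", "F2", "BC1", "RIL")) {
    sim <- simulate_cross(cross_sim_config(design = design, n_progeny = 4,
                                           n_chrom = 2, markers_per_chrom = 40,
                                           seed = 13), dir = tempfile())
    run <- run_pipeline(sim$vcf, progeny = sim$progeny,
                        output_prefix = file.path(tempfile(), "r"),
                        parent_a = sim$parent_a, parent_b = sim$parent_b,
                        chrom_lengths = sim$chrom_lengths_path)
    merged <- dplyr::inner_join(run$calls, sim$truth,
                                by = c("chrom", "pos", "sample"))
    expect_equal(nrow(merged), nrow(sim$truth))
    expect_true(all(as.character(merged$klass) == merged$true_klass),
                info = design)
  }
})

test_that("RIL selfing drives heterozygosity far below the F2 level", {
  ril <- simulate_cross(cross_sim_config(design = "RIL", ril_generations = 6,
                                         n_progeny = 20, n_chrom = 2,
                                         markers_per_chrom = 100, seed = 21),
                        dir = tempfile())
  het <- mean(ril$truth$true_klass == "het_ab")
  expect_lt(het, 0.10)  # ~ 0.5^6 expected residual heterozygosity
})

test_that("noise knobs inject the requested artifacts", {
  sim <- simulate_cross(cross_sim_config(design = "F2", n_progeny = 10,
                                         n_chrom = 1, markers_per_chrom = 200,
                                         missing_rate = 0.1, other_rate = 0.05,
                                         seed = 31), dir = tempfile())
  run <- run_pipeline(sim$vcf, progeny = sim$progeny,
                      output_prefix = file.path(tempfile(), "r"),
                      parent_a = sim$parent_a, parent_b = sim$parent_b)
  frac <- table(as.character(run$calls$klass)) / nrow(run$calls)
  expect_gt(frac[["missing"]], 0.05)
  expect_gt(frac[["other"]], 0.01)

  # the filter with 1% flips strictly reduces mismatches vs truth (20 seeds)
  before_all <- 0; after_all <- 0
  for (seed in 1:20) {
    s <- simulate_cross(cross_sim_config(design = "BC1", n_progeny = 2,
                                         n_chrom = 1, markers_per_chrom = 120,
                                         crossover_rate = 1,
                                         error_rate = 0.01, seed = seed),
                        dir = tempfile())
    vcf <- read_cross_vcf(s$vcf)
    sites <- identify_informative_sites(vcf, "parent_A", "parent_B")
    raw <- classify_progeny(vcf, sites, s$progeny)
    flt <- sliding_window_filter(raw, window_size = 5, times = 1)
    truth_key <- s$truth[order(s$truth$sample, s$truth$chrom, s$truth$pos), ]
    raw_o <- raw[order(raw$sample, raw$chrom, raw$pos), ]
    flt_o <- flt[order(flt$sample, flt$chrom, flt$pos), ]
    before_all <- before_all + sum(as.character(raw_o$klass) != truth_key$true_klass)
    after_all <- after_all + sum(as.character(flt_o$klass) != truth_key$true_klass)
  }
  expect_gt(before_all, 0)
  expect_lt(after_all, before_all)
})
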