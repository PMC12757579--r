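test_that("progeny calls classify by resolved parental bases", {
  path <- write_toy_vcf(
    c(
      vcf_row("c1", 100, "A", "G", "0/0", "1/1", "0/0", "0/1", "1|0"),
      vcf_row("c1", 200, "A", "G,T", "1/1", "2/2", "0/1", "1/2", "./1"),
      vcf_row("c1", 300, "A", "G", "0/0", "1/1", "1/1", "./.", "0/1")
    ),
    samples = c("PA", "PB", "s1", "s2", "s3")
  )
  vcf <- read_cross_vcf(path)
  sites <- identify_informative_sites(vcf, "PA", "PB")
  calls <- classify_progeny(vcf, sites, c("s1", "s2", "s3"))

  get <- function(s, p) as.character(calls$klass[calls$sample == s & calls$pos == p])
  expect_equal(get("s1", 100), "hom_a")
  expect_equal(get("s2", 100), "het_ab")   # 0/1
  expect_equal(get("s3", 100), "het_ab")   # 1|0: unordered multiset
  # site(G,T): 0/1 carries the REF base A, a non-parental allele
  expect_equal(get("s1", 200), "other")
  expect_equal(get("s2", 200), "het_ab")   # 1/2 = G/T
  expect_equal(get("s3", 200), "missing")  # half-call ./1
  expect_equal(get("s1", 300), "hom_b")
  expect_equal(get("s2", 300), "missing")
})

test_that("filter corrects an inconsistent center by strict neighbor majority", {
  A <- "hom_a"; B <- "hom_b"; H <- "het_ab"
  # center with neighbors A,A,A,A: majority A wins
  expect_equal(filter_labels(c(A, A, B, A, A)), rep(A, 5))
  # center of [A,B,A,B,A] sees neighbors A,B,B,A: tie, so it stays put
  # (flanking B's do change — their own windows hold an A majority)
  out <- filter_labels(c(A, B, A, B, A))
  expect_equal(out[3], A)
  expect_equal(out, oracle_filter_round(c(A, B, A, B, A), 5))
  # chromosome end: index 1 sees only its 2 nearest right sites
  expect_equal(filter_labels(c(B, A, A, A, A)), rep(A, 5))
  # f = 0 disables the filter entirely
  expect_equal(filter_labels(c(A, A, B, A, A), f = 0), c(A, A, B, A, A))
  expect_equal(filter_labels(c(A, H, B, H, A), f = 0), c(A, H, B, H, A))
})

test_that("window size must be odd and at least 3", {
  calls <- make_calls(c("hom_a", "hom_b", "hom_a"))
  expect_error(sliding_window_filter(calls, window_size = 4, times = 1), "odd")
  expect_error(sliding_window_filter(calls, window_size = 1, times = 1), "odd")
  expect_error(sliding_window_filter(calls, times = -1), ">= 0")
})

test_that("missing/other are transparent to windows and never modified", {
  A <- "hom_a"; B <- "hom_b"
  x <- c(A, "missing", A, B, "other", A, A)
  out <- filter_labels(x)
  # classified subsequence (A,A,B,A,A) corrects to all A; gaps untouched
  expect_equal(out, c(A, "missing", A, A, "other", A, A))
})

test_that("one filter round equals the brute-force window oracle", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    x <- sample(c("hom_a", "hom_b", "het_ab"), n, replace = TRUE)
    for (w in c(3, 5)) {
      expect_equal(filter_labels(x, w = w), oracle_filter_round(x, w),
                   info = paste(w, paste(x, collapse = ",")))
    }
  }
})

test_that("filtering is synchronous: scan direction does not matter", {
  set.seed(7)
  for (i in 1:50) {
    x <- sample(c("hom_a", "hom_b", "het_ab"), 30, replace = TRUE)
    fwd <- filter_labels(x, w = 5, f = 1)
    rev_out <- rev(filter_labels(rev(x), w = 5, f = 1))
    expect_equal(fwd, rev_out)
  }
})

test_that("iteration reaches a fixed point and is a pure relabeling", {
  set.seed(99)
  for (i in 1:10) {
    x <- sample(c("hom_a", "hom_b", "het_ab", "missing", "other"),
                200, replace = TRUE)
    calls <- make_calls(x)
    out10 <- sliding_window_filter(calls, window_size = 5, times = 10)
    out11 <- sliding_window_filter(calls, window_size = 5, times = 11)
    expect_equal(out10$klass, out11$klass)  # converged within 10 rounds
    expect_equal(out10$pos, calls$pos)
    keep <- x %in% c("missing", "other")
    expect_equal(as.character(out10$klass)[keep], x[keep])
  }
})

test_that("unsorted positions are rejected", {
  calls <- make_calls(c("hom_a", "hom_b", "hom_a"), pos = c(300, 100, 200))
  expect_error(sliding_window_filter(calls, times = 1), "sort")
})

test_that("one pass at w=5 cleans sporadic errors against simulated truth", {
  # blocks of >= 20 markers with 1% random flips, aggregated over 20 seeds
  set.seed(123)
  worse <- 0; before_all <- 0; after_all <- 0
  for (seed in 1:20) {
    truth <- rep(rep(c("hom_a", "hom_b"), 3), each = 25)  # 6 blocks of 25
    x <- truth
    flips <- runif(length(x)) < 0.01
    x[flips] <- ifelse(truth[flips] == "hom_a", "hom_b", "hom_a")
    out <- filter_labels(x, w = 5, f = 1)
    before_all <- before_all + sum(x != truth)
    after_all <- after_all + sum(out != truth)
  }
  expect_gt(before_all, 0)
  expect_lt(after_all, before_all)
})
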