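# shared small simulations used by several estimator tests
set.seed(1)
.sim30 <- simulate_survey(sim_config(150000, gc_content = 0.45,
                                     coverage = 30, seed = 101))
.hist30 <- count_canonical_kmers(.sim30$reads, 17)

test_that("tiny reads produce the expected canonical histograms", {
  # "AAAA" holds two windows, both the canonical k-mer AAA: one distinct
  # k-mer at depth 2
  h <- count_canonical_kmers("AAAA", k = 3)
  expect_identical(h$depth, 2L)
  expect_identical(h$count, 1)
  expect_identical(h$total_occurrences, 2)
})

test_that("reverse-complement windows collapse onto one canonical k-mer", {
  h <- count_canonical_kmers("ACGT", k = 3)
  # windows ACG and CGT; CGT's reverse complement is ACG
  expect_identical(h$depth, 2L)
  expect_identical(h$count, 1)
})

test_that("histogram equals the naive window-table oracle", {
  set.seed(42)
  reads <- replicate(100, random_dna(50))
  h <- count_canonical_kmers(reads, 5)
  expect_identical(hist_as_named(h), oracle_kmer_hist(reads, 5))
})

test_that("histogram is invariant under reverse-complementing every read", {
  set.seed(43)
  reads <- replicate(50, random_dna(60, gc = 0.4))
  h1 <- count_canonical_kmers(reads, 7)
  h2 <- count_canonical_kmers(oracle_revcomp(reads), 7)
  expect_identical(as.data.frame(h1), as.data.frame(h2))
})

test_that("total occurrences equal the number of N-free windows", {
  reads <- c("ACGTACGTAC", "ACGNTACGTT", "NNNNN", "ACG")
  h <- count_canonical_kmers(reads, 5)
  n_windows <- 0
  for (s in reads) {
    n <- nchar(s)
    if (n < 5) next
    for (i in 1:(n - 4)) {
      if (!grepl("N", substr(s, i, i + 4))) n_windows <- n_windows + 1
    }
  }
  expect_equal(h$total_occurrences, n_windows)
})

test_that("even k and out-of-range k are rejected", {
  expect_error(count_canonical_kmers("ACGTACGT", 4), "odd")
  expect_error(count_canonical_kmers("ACGTACGT", 33), "between")
  expect_error(kmer_histogram(c(1, 2), c(10, 5), k = 16), "odd")
})

test_that("main peak and low-depth cutoff follow the first local minimum", {
  h <- kmer_histogram(c(1, 2, 3, 10, 11, 12), c(1000, 100, 10, 500, 800, 400),
                      k = 17)
  pk <- find_main_peak(h)
  expect_identical(pk$low_depth_cutoff, 3L)
  expect_identical(pk$peak_depth, 11L)
})

test_that("a strictly decreasing spectrum raises an insufficient-coverage error", {
  h <- kmer_histogram(1:6, c(1000, 500, 200, 80, 20, 5), k = 17)
  expect_error(find_main_peak(h), "insufficient coverage")
})

test_that("simulated 30x reads peak near the expected k-mer depth", {
  pk <- find_main_peak(.hist30)
  expected <- 30 * (150 - 17 + 1) / 150
  expect_lte(abs(pk$peak_depth - expected), 2)
})

test_that("genome size formula reproduces the published arithmetic", {
  expect_identical(estimate_genome_size(47338914261, 24), 1972454761)
  expect_identical(estimate_genome_size(1000, 10), 100)
  expect_error(estimate_genome_size(1000, 0), "peak_depth")
})

test_that("error revision scales the size by one minus the error rate", {
  expect_identical(revise_genome_size(100, 0), 100)
  expect_identical(revise_genome_size(100, 0.5), 50)
  # published inputs stay at 1.97 Gb after revision
  gs <- estimate_genome_size(47338914261, 24)
  expect_equal(round(revise_genome_size(gs, 0.000282) / 1e9, 2), 1.97)
  expect_error(revise_genome_size(100, 1), "error_rate")
})

test_that("genome size is recovered within 5% from error-free reads", {
  est <- survey_estimates(.hist30)
  truth <- .sim30$truth$haploid_genome_length
  expect_lt(abs(est$genome_size - truth) / truth, 0.05)
})

test_that("repeat ratio is zero when all mass sits at the peak", {
  h <- kmer_histogram(24, 1000, k = 17)
  expect_identical(estimate_repeat_ratio(h, 24), 0)
})

test_that("repeat ratio matches hand arithmetic on a constructed spectrum", {
  h <- kmer_histogram(c(24, 48), c(900, 50), k = 17)
  expect_equal(estimate_repeat_ratio(h, 24, multiplier = 1.8,
                                     low_depth_cutoff = 0), 0.1)
})

test_that("repeat ratio increases with the simulated repeat fraction", {
  ratios <- vapply(c(0, 0.2, 0.4), function(rho) {
    s <- simulate_survey(sim_config(150000, repeat_fraction = rho,
                                    coverage = 30, seed = 202))
    h <- count_canonical_kmers(s$reads, 17)
    est <- survey_estimates(h)
    est$repeat_ratio
  }, numeric(1))
  expect_lt(ratios[1], 0.05) # repeat-free null
  expect_true(all(diff(ratios) > 0))
})

test_that("heterozygosity is near zero for a homozygous genome", {
  est <- survey_estimates(.hist30) # het_rate = 0 simulation
  expect_lt(est$heterozygosity, 0.0005)
})

test_that("heterozygosity estimate rises when the true rate doubles", {
  h_of <- function(rate, seed) {
    s <- simulate_survey(sim_config(200000, het_rate = rate, coverage = 30,
                                    seed = seed))
    survey_estimates(count_canonical_kmers(s$reads, 17))$heterozygosity
  }
  lo <- h_of(0.0035, 303)
  hi <- h_of(0.007, 303)
  expect_gt(hi, lo)
  expect_gt(hi, 0.0035) # within factor 2 of 0.7%
  expect_lt(hi, 0.014)
})

test_that("0.1% sequencing error shifts the genome size by less than 10%", {
  est0 <- survey_estimates(.hist30)
  se <- simulate_survey(sim_config(150000, gc_content = 0.45, coverage = 30,
                                   error_rate = 0.001, seed = 101))
  este <- survey_estimates(count_canonical_kmers(se$reads, 17))
  expect_gt(este$low_depth_cutoff, 0L)
  expect_lt(abs(este$genome_size - est0$genome_size) / est0$genome_size, 0.10)
})

test_that("windowed GC honours window boundaries and partial tails", {
  gw <- windowed_gc(c(ref = strrep("GGCC", 2500)), window = 10000)
  expect_equal(nrow(gw), 1L)
  expect_equal(gw$gc, 1.0)

  gw2 <- windowed_gc(c(a = strrep("A", 25000)), window = 10000)
  expect_equal(gw2$start, c(1L, 10001L, 20001L))
  expect_equal(gw2$end, c(10000L, 20000L, 25000L))
  expect_error(windowed_gc("ACGT", window = 0), "window")
})

test_that("length-weighted window GC conserves whole-sequence GC", {
  set.seed(77)
  s <- random_dna(100000, gc = 0.42)
  gw <- windowed_gc(c(x = s), window = 7000)
  w <- gw$end - gw$start + 1
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  whole <- mean(ch %in% c("G", "C"))
  expect_equal(sum(gw$gc * w) / sum(w), whole, tolerance = 1e-12)
})

test_that("histograms survive the TSV dump round trip", {
  f <- tempfile(fileext = ".tsv")
  write_kmer_histogram(.hist30, f)
  h2 <- read_kmer_histogram(f, k = 17)
  expect_identical(as.data.frame(.hist30), as.data.frame(h2))
})
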