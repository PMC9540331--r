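test_that("window count per read is L - k + 1", {
  s <- count_canonical_kmers("ACGTACGTACGTACG", k = 11)  # 15 bp
  expect_equal(s$total_instances, 5)
})

test_that("a k-mer and its reverse complement share one canonical key", {
  s <- count_canonical_kmers(c("AAAAAAAAAAA", "TTTTTTTTTTT"), k = 11)
  expect_equal(nrow(s$histogram), 1L)
  expect_equal(s$histogram$multiplicity, 2L)
  expect_equal(s$histogram$count, 1)
})

test_that("even k is rejected and windows with N are skipped", {
  expect_error(count_canonical_kmers("ACGT", k = 12), "odd")
  expect_error(count_canonical_kmers("ACGT", k = 9), "\\[11, 31\\]")
  s <- count_canonical_kmers("AAAAAAAAAAANAAAAAAAAAAA", k = 11)
  expect_equal(s$total_instances, 2)  # one valid window per N-free run
})

test_that("compiled counter matches the brute-force oracle", {
  set.seed(123)
  for (trial in 1:3) {
    reads <- vapply(1:40, function(i)
      paste(sample(c("A", "C", "G", "T", "N"), 120, replace = TRUE,
                   prob = c(.24, .24, .24, .24, .04)), collapse = ""),
      character(1))  # < 10 kbp total
    for (k in c(11L, 21L)) {
      got <- count_canonical_kmers(reads, k)$histogram
      want <- oracle_kmer_histogram(reads, k)
      expect_equal(got$multiplicity, want$multiplicity)
      expect_equal(got$count, want$count)
    }
  }
})

test_that("spectrum is invariant under reverse complement of all reads", {
  set.seed(99)
  reads <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
          collapse = ""), character(1))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads)))
  s1 <- count_canonical_kmers(reads)
  s2 <- count_canonical_kmers(rc)
  expect_identical(s1$histogram, s2$histogram)
})

test_that("histogram mass identity holds", {
  set.seed(5)
  reads <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
          collapse = ""), character(1))
  s <- count_canonical_kmers(reads)
  expect_equal(sum(s$histogram$multiplicity * s$histogram$count),
               s$total_instances)
})

test_that("haploid reads yield one peak at the k-mer coverage", {
  b <- quick_scenario("haploid", seed = 2, genome_size = 1e5,
                      n_scaffolds = 3)
  reads <- simulate_reads(b$assembly, b$truth, b$sc)
  pk <- detect_spectrum_peaks(count_canonical_kmers(reads))
  expect_false(pk$undiagnosable)
  expect_equal(pk$n_peaks, 1L)
  # base coverage 30x -> k-mer coverage 30 * (100 - 21 + 1) / 100 = 24
  expect_lt(abs(pk$haploid_coverage - 24), 2.5)
  expect_equal(classify_spectrum(pk), "haploid-or-homozygous")
})

test_that("heterozygous diploid reads yield two ~2:1 peaks", {
  b <- quick_scenario("diploid_het", seed = 4, genome_size = 2e5,
                      n_scaffolds = 4)
  reads <- simulate_reads(b$assembly, b$truth, b$sc)
  pk <- detect_spectrum_peaks(count_canonical_kmers(reads))
  expect_equal(pk$n_peaks, 2L)
  m <- sort(pk$peaks$multiplicity)
  expect_gt(m[2] / m[1], 1.6)
  expect_lt(m[2] / m[1], 2.4)
  expect_equal(classify_spectrum(pk), "heterozygous-diploid-like")
})

test_that("genome size is recovered within 10% on error-free reads", {
  for (seed in 1:2) {
    b <- quick_scenario("haploid", seed = seed, genome_size = 2e5,
                        n_scaffolds = 3)
    reads <- simulate_reads(b$assembly, b$truth, b$sc)
    pk <- detect_spectrum_peaks(count_canonical_kmers(reads))
    expect_lt(abs(pk$genome_size_estimate - b$assembly$total_length) /
                b$assembly$total_length, 0.1)
  }
})

test_that("sequencing errors create a shoulder below the error threshold", {
  b <- quick_scenario("haploid", seed = 6, genome_size = 1e5,
                      n_scaffolds = 3, error_rate = 0.01)
  reads <- simulate_reads(b$assembly, b$truth, b$sc)
  s <- count_canonical_kmers(reads)
  pk <- detect_spectrum_peaks(s)
  expect_gt(pk$error_threshold, 1L)
  # most singleton k-mers are errors, far more than genomic ripple
  singletons <- s$histogram$count[s$histogram$multiplicity == 1]
  expect_gt(singletons, 1000)
  expect_equal(pk$n_peaks, 1L)
})

test_that("monotone histograms are flagged undiagnosable", {
  s <- new_spectrum_for_test(c(1000, 400, 150, 60, 20, 5, 1))
  pk <- detect_spectrum_peaks(s)
  expect_true(pk$undiagnosable)
  expect_equal(classify_spectrum(pk), "undiagnosable")
})

test_that("classification bands follow the peak multiplicity ratio", {
  mk <- function(mult) {
    # two clean gaussian-ish bumps at the requested multiplicities
    counts <- rep(1, max(mult) + 10)
    for (m in mult) counts[(m - 1):(m + 1)] <- c(50, 100, 50)
    new_spectrum_for_test(counts)
  }
  expect_equal(classify_spectrum(detect_spectrum_peaks(mk(c(30, 60)))),
               "heterozygous-diploid-like")
  expect_equal(classify_spectrum(detect_spectrum_peaks(mk(c(30, 40)))),
               "multi-peak-complex")
})

test_that("spectrum TSV round-trips through the KAT-style format", {
  set.seed(12)
  reads <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
          collapse = ""), character(1))
  s <- count_canonical_kmers(reads)
  p <- tempfile(fileext = ".tsv")
  write_kmer_histogram(s, p)
  s2 <- import_kmer_histogram(p, k = 21)
  expect_equal(s2$histogram$multiplicity, s$histogram$multiplicity)
  expect_equal(s2$histogram$count, s$histogram$count)
  expect_equal(s2$total_instances, s$total_instances)
})
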