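test_that("GC check warns strictly outside [gc_low, gc_high]", {
  mk <- function(gc, n = 10000) {
    set.seed(1)
    s <- paste(sample(c("G", "A"), n, replace = TRUE, prob = c(gc, 1 - gc)),
               collapse = "")
    read_assembly_fasta(write_tmp_fasta(c(s1 = s)))
  }
  low <- gc_content_check(mk(0.326))
  expect_equal(low$verdict, "low")
  expect_equal(low$warnings$code, "LOW_GC")
  ok <- gc_content_check(mk(0.50))
  expect_equal(ok$verdict, "ok")
  expect_equal(nrow(ok$warnings), 0L)
  hi <- gc_content_check(mk(0.80))
  expect_equal(hi$warnings$code, "HIGH_GC")
  # boundary is strict: 0.349 warns, exactly 0.35 does not
  a349 <- read_assembly_fasta(write_tmp_fasta(c(
    s1 = paste(c(rep("G", 349), rep("A", 651)), collapse = ""))))
  expect_equal(gc_content_check(a349)$verdict, "low")
  a350 <- read_assembly_fasta(write_tmp_fasta(c(
    s1 = paste(c(rep("G", 350), rep("A", 650)), collapse = ""))))
  expect_equal(gc_content_check(a350)$verdict, "ok")
  # all-N assembly: GC undefined
  nn <- read_assembly_fasta(write_tmp_fasta(c(s1 = strrep("N", 100))))
  expect_equal(gc_content_check(nn)$warnings$code, "UNDEFINED_GC")
})

test_that("raising gc_low only adds LOW_GC warnings", {
  set.seed(2)
  s <- paste(sample(c("G", "A"), 5000, replace = TRUE, prob = c(.45, .55)),
             collapse = "")
  a <- read_assembly_fasta(write_tmp_fasta(c(s1 = s)))
  th1 <- default_thresholds()
  th2 <- default_thresholds()
  th2$gc_low <- 0.48
  r1 <- gc_content_check(a, th1)
  r2 <- gc_content_check(a, th2)
  expect_equal(nrow(r1$warnings), 0L)
  expect_equal(r2$warnings$code, "LOW_GC")
})

test_that("mapped-fraction and BUSCO checks threshold and validate", {
  expect_equal(mapped_fraction_check(0.50)$verdict, "low")
  expect_equal(mapped_fraction_check(0.99)$verdict, "ok")
  expect_equal(mapped_fraction_check(NULL)$verdict, "not assessed")
  expect_error(mapped_fraction_check(1.2), "\\[0, 1\\]")
  expect_equal(busco_check(0.5)$warnings$code, "LOW_BUSCO")
  expect_equal(busco_check(0.95)$verdict, "ok")
})

test_that("coverage bimodality separates planted 30x/60x from uniform", {
  mk_summ <- function(depths) {
    data.frame(scaffold = sprintf("s%03d", seq_along(depths)),
               length = rep(10000L, length(depths)),
               mean_depth = depths, n_snps = 0L, snp_density = 0,
               gc_fraction = 0.5, stringsAsFactors = FALSE)
  }
  set.seed(3)
  two <- mk_summ(c(stats::rnorm(50, 30, 3), stats::rnorm(50, 60, 6)))
  r2 <- coverage_bimodality_check(two)
  expect_equal(r2$verdict, "bimodal")
  expect_equal(r2$warnings$code, "BIMODAL_COVERAGE")
  expect_lt(abs(sort(r2$component_means)[1] - 30), 5)
  one <- mk_summ(stats::rnorm(100, 40, 2))
  expect_equal(coverage_bimodality_check(one)$verdict, "unimodal")
  few <- mk_summ(stats::rnorm(5, 40, 2))
  expect_equal(coverage_bimodality_check(few)$verdict, "insufficient")
})

test_that("window population check separates hemidiploid from diploid", {
  hemi <- quick_scenario("hemidiploid", seed = 4, genome_size = 4e5,
                         n_scaffolds = 60)
  w <- window_stats(tile_windows(hemi$assembly), hemi$variants,
                    hemi$depth)
  r <- variation_coverage_population_check(w)
  expect_equal(r$verdict, "multi-population")
  dip <- quick_scenario("diploid_het", seed = 5, genome_size = 4e5,
                        n_scaffolds = 60)
  wd <- window_stats(tile_windows(dip$assembly), dip$variants, dip$depth)
  expect_equal(variation_coverage_population_check(wd)$verdict,
               "single-population")
  expect_equal(variation_coverage_population_check(wd[1:50, ])$verdict,
               "insufficient")
})

test_that("clean haploid report carries metrics and no composition warnings", {
  b <- quick_scenario("haploid", seed = 6, genome_size = 2e5,
                      n_scaffolds = 25)
  rep1 <- compose_report(b$assembly, b$variants, b$depth)
  expect_s3_class(rep1, "diagnostic_report")
  expect_equal(rep1$metrics$n_scaffolds, 25)
  expect_false(any(rep1$warnings$code %in%
                     c("LOW_GC", "HIGH_GC", "BIMODAL_COVERAGE")))
  expect_equal(rep1$verdicts$gc, "ok")
  expect_match(rep1$interpretations[1], "no unusual")
})

test_that("contaminated scenario is flagged with an interpretation", {
  b <- quick_scenario("contaminated", seed = 7, genome_size = 6e5,
                      n_scaffolds = 100)
  w <- window_stats(tile_windows(b$assembly), b$variants, b$depth)
  rep1 <- compose_report(b$assembly, b$variants, b$depth, windows = w)
  fired <- any(c("BIMODAL_COVERAGE", "MULTI_POPULATION") %in%
                 rep1$warnings$code)
  expect_true(fired)
  expect_true(any(grepl("contaminat", rep1$interpretations)))
})

test_that("report serialization is deterministic", {
  b <- quick_scenario("diploid_het", seed = 8, genome_size = 1.5e5,
                      n_scaffolds = 6)
  rep1 <- compose_report(b$assembly, b$variants, b$depth)
  rep2 <- compose_report(b$assembly, b$variants, b$depth)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  t1 <- tempfile(fileext = ".txt")
  t2 <- tempfile(fileext = ".txt")
  write_report(rep1, f1, t1)
  write_report(rep2, f2, t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
})
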