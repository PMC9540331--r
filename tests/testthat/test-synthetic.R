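test_that("simulated genomes hit their GC target", {
  for (gc in c(0.326, 0.5)) {
    sc <- scenario("haploid", seed = 1, genome_size = 2e5,
                   n_scaffolds = 5, gc_target = gc)
    g <- simulate_genome(sc)
    expect_lt(abs(ploidyscan:::assembly_gc(g$assembly) - gc), 0.01)
  }
  expect_error(simulate_genome(scenario("haploid", seed = 1,
                                        genome_size = 1e4)), "50 kb")
  expect_error(scenario("nonsense", seed = 1), "unknown scenario")
  expect_error(scenario("haploid"), "seed")
})

test_that("planted SNP counts match the heterozygosity rate", {
  # 3% heterozygosity over ~1 Mb: Binomial mean 30,000, sd ~170
  sc <- scenario("hybrid_high_het", seed = 2, genome_size = 1e6,
                 n_scaffolds = 10)
  g <- simulate_genome(sc)
  vd <- simulate_variants_and_depth(g$assembly, g$truth, sc)
  expect_lt(abs(nrow(vd$variants$records) - 30000), 600)
})

test_that("haploid scenarios have no heterozygous sites", {
  b <- quick_scenario("haploid", seed = 3)
  expect_equal(nrow(b$variants$records), 0L)
})

test_that("triploid fractions mix 1/3 and 2/3 with mean 1/2", {
  b <- quick_scenario("triploid", seed = 4, genome_size = 4e5,
                      n_scaffolds = 5)
  f <- with(b$variants$records, alt_depth / (ref_depth + alt_depth))
  expect_lt(abs(mean(f) - 0.5), 0.02)        # mixture mean
  d <- stats::density(f)
  modes <- d$x[which(diff(sign(diff(d$y))) == -2) + 1]
  main_modes <- sort(modes[order(-d$y[match(modes, d$x)])][1:2])
  expect_lt(abs(main_modes[1] - 1 / 3), 0.05)
  expect_lt(abs(main_modes[2] - 2 / 3), 0.05)
})

test_that("read counts follow the coverage arithmetic", {
  sc <- scenario("haploid", seed = 5, genome_size = 1e5, n_scaffolds = 2)
  g <- simulate_genome(sc)
  vd <- simulate_variants_and_depth(g$assembly, g$truth, sc)
  reads <- simulate_reads(g$assembly, vd$truth, sc)
  # 100 kb at 30x with 100-bp reads -> ~30,000 reads (rounding per scaffold)
  expect_lt(abs(length(reads) - 30000), 5)
  expect_true(all(nchar(reads) == 100L))
})

test_that("aneuploid and hemidiploid architectures are planted as described", {
  an <- quick_scenario("aneuploid", seed = 6, genome_size = 3e5,
                       n_scaffolds = 20)
  arch <- an$truth$architecture
  expect_equal(sum(arch$copy_mult == 1.5), 10L)
  expect_equal(arch$ploidy_state[arch$copy_mult == 1.5][1], "triploid")
  hemi <- quick_scenario("hemidiploid", seed = 7, genome_size = 3e5,
                         n_scaffolds = 20)
  ha <- hemi$truth$architecture
  snp_free <- ha$scaffold[ha$het_rate == 0]
  expect_equal(ha$copy_mult[ha$het_rate == 0], rep(2, 10))
  expect_false(any(hemi$variants$records$scaffold %in% snp_free))
})

test_that("bundles are byte-identical under a fixed seed", {
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  unlink(c(d1, d2), recursive = TRUE)
  make_scenario("diploid_het", seed = 11, out_dir = d1,
                genome_size = 6e4, n_scaffolds = 3)
  make_scenario("diploid_het", seed = 11, out_dir = d2,
                genome_size = 6e4, n_scaffolds = 3)
  for (f in c("genome.fa", "variants.vcf", "depth.tsv", "reads.fastq",
              "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("emitted files agree with the planted truth (audit pass)", {
  for (label in c("haploid", "diploid_het", "triploid")) {
    for (seed in 1:3) {
      d <- file.path(tempdir(), sprintf("audit_%s_%d", label, seed))
      unlink(d, recursive = TRUE)
      bnd <- make_scenario(label, seed, out_dir = d, genome_size = 8e4,
                           n_scaffolds = 3, reads = FALSE)
      audit <- bnd$truth$audit
      expect_lt(abs(audit$realized_gc - bnd$scenario$gc_target), 0.01)
      expect_lt(audit$max_depth_rel_error, 0.05)
      if (label == "haploid") {
        expect_equal(audit$realized_snps, 0L)
      } else {
        expect_lt(abs(audit$realized_snps - audit$expected_snps),
                  4 * sqrt(audit$expected_snps) + 5)
      }
      # re-reading the bundle reproduces the in-memory objects
      a <- read_assembly_fasta(bnd$paths$fasta)
      expect_identical(a$seqs, bnd$assembly$seqs)
      v <- read_variants_vcf(bnd$paths$vcf, assembly = a,
                             min_total_depth = 0)
      expect_equal(nrow(v$records), nrow(bnd$variants$records))
      dt <- read_depth_table(bnd$paths$depth, a)
      expect_identical(lapply(dt, as.integer),
                       lapply(bnd$depth[a$ids], as.integer))
    }
  }
})

test_that("contaminated bundles plant alien scaffolds at distinct GC/coverage", {
  b <- quick_scenario("contaminated", seed = 8, genome_size = 3e5,
                      n_scaffolds = 30)
  arch <- b$truth$architecture
  alien <- arch$contaminant
  expect_equal(sum(alien), 3L)
  gc_alien <- mean(b$assembly$gc_fraction[arch$scaffold[alien]])
  gc_host <- mean(b$assembly$gc_fraction[arch$scaffold[!alien]])
  expect_gt(gc_alien, 0.6)
  expect_lt(gc_host, 0.55)
  cov_alien <- mean(vapply(arch$scaffold[alien],
                           function(s) mean(b$depth[[s]]), numeric(1)))
  expect_lt(cov_alien, 0.3 * b$sc$base_coverage)
})
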