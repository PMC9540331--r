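test_that("free mixture recovers planted means", {
  set.seed(1)
  x <- stats::rnorm(200, 0.5, 0.03)
  f1 <- fit_free_mixture(x, 1, seed = 2)
  expect_lt(abs(f1$means - 0.5), 0.01)
  y <- c(stats::rnorm(200, 1 / 3, 0.04), stats::rnorm(200, 2 / 3, 0.04))
  f2 <- fit_free_mixture(y, 2, seed = 3)
  expect_lt(abs(f2$means[1] - 1 / 3), 0.02)
  expect_lt(abs(f2$means[2] - 2 / 3), 0.02)
  expect_equal(sum(f2$weights), 1, tolerance = 1e-9)
})

test_that("too few fractions is a precondition error", {
  expect_error(fit_free_mixture(c(0.4, 0.5, 0.6), 1, min_snps = 10),
               "at least 10")
  expect_error(loglik_fixed_model(c(0.5, 0.5), "diploid"), "at least")
})

test_that("fixed-hypothesis likelihoods order by the planted model", {
  set.seed(4)
  dip <- stats::rbinom(300, 100, 0.5) / 100
  expect_gte(loglik_fixed_model(dip, "diploid")$loglik,
             loglik_fixed_model(dip, "triploid")$loglik)
  tri <- planted_fractions("triploid", 400, 100)
  expect_gte(loglik_fixed_model(tri, "triploid")$loglik,
             loglik_fixed_model(tri, "diploid")$loglik)
})

test_that("degenerate constant input hits the sigma floor, diploid wins", {
  x <- rep(0.5, 50)
  fits <- lapply(c("diploid", "triploid", "tetraploid"),
                 function(h) loglik_fixed_model(x, h))
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  expect_true(all(is.finite(lls)))
  expect_equal(fits[[1]]$sigma, 0.01)
  expect_true(fits[[1]]$degenerate)
  expect_equal(which.max(lls), 1L)
})

test_that("free model dominates every fixed hypothesis", {
  set.seed(6)
  for (h in c("diploid", "triploid", "tetraploid")) {
    f <- planted_fractions(h, 120, 80)
    for (hyp in c("diploid", "triploid", "tetraploid")) {
      fixed <- loglik_fixed_model(f, hyp)
      free <- fit_free_mixture(f, length(fixed$means), seed = 7,
                               extra_inits = list(list(
                                 means = fixed$means,
                                 weights = fixed$weights,
                                 sigma = fixed$sigma)))
      expect_gte(free$loglik, fixed$loglik - 1e-6)
    }
  }
})

test_that("window scores are softmax-normalized and order-invariant", {
  b <- quick_scenario("triploid", seed = 8, genome_size = 8e4,
                      n_scaffolds = 3)
  win <- tile_windows(b$assembly)
  s <- window_ploidy_scores(b$variants, win, min_snps = 5)
  scored <- s[!s$missing, ]
  expect_gt(nrow(scored), 0)
  sums <- scored$score_diploid + scored$score_triploid +
    scored$score_tetraploid
  expect_equal(sums, rep(1, nrow(scored)), tolerance = 1e-9)
  # shuffling SNP order changes nothing
  v2 <- b$variants
  set.seed(9)
  v2$records <- v2$records[sample.int(nrow(v2$records)), ]
  s2 <- window_ploidy_scores(v2, win, min_snps = 5)
  expect_equal(s$score_triploid, s2$score_triploid)
})

test_that("SNP-free windows are missing, as unassessable homozygous tracts", {
  a <- read_assembly_fasta(write_tmp_fasta(c(s1 = strrep("ACGT", 500))))
  v <- structure(list(records = ploidyscan:::empty_snp_records(),
                      n_excluded = 0L), class = "variant_table")
  s <- window_ploidy_scores(v, tile_windows(a))
  expect_true(all(s$missing))
  expect_true(all(is.na(s$best)))
  prof <- scaffold_ploidy_profile(s)
  expect_equal(prof$frac_missing, 1)
})

test_that("planted ploidy wins in >= 90% of well-powered windows", {
  set.seed(10)
  for (h in c("diploid", "triploid", "tetraploid")) {
    wins <- 0L
    n_windows <- 60L
    for (w in seq_len(n_windows)) {
      f <- planted_fractions(h, 60, 100)
      ll <- vapply(c("diploid", "triploid", "tetraploid"),
                   function(hh) loglik_fixed_model(f, hh)$loglik,
                   numeric(1))
      if (names(which.max(ll)) == h) wins <- wins + 1L
    }
    expect_gte(wins / n_windows, 0.9)
  }
})

test_that("scaffold profiles track the planted architecture", {
  b <- quick_scenario("diploid_het", seed = 12, genome_size = 1e5,
                      n_scaffolds = 4)
  win <- tile_windows(b$assembly)
  s <- window_ploidy_scores(b$variants, win, min_snps = 5)
  prof <- scaffold_ploidy_profile(s)
  expect_equal(rowSums(prof[, c("frac_diploid", "frac_triploid",
                                "frac_tetraploid", "frac_missing")]),
               rep(1, nrow(prof)), tolerance = 1e-9)
  assessed <- prof$frac_diploid + prof$frac_triploid + prof$frac_tetraploid
  expect_true(all(prof$frac_diploid / pmax(assessed, 1e-9) >= 0.8))
})
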