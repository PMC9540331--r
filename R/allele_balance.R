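#' Alternative-allele fractions for a scope
#'
#' Collects `alt_depth / (ref_depth + alt_depth)` for every SNP in the
#' requested scope (whole genome or a single scaffold), dropping sites with
#' zero total depth.
#'
#' @param variants A `variant_table` (already depth-filtered on reading).
#' @param scope `"genome"` or a scaffold id.
#' @return An object of class `alt_fractions`: list with `scope`,
#'   `fractions` and the matching `coverages` (total depths).
#' @export
alt_fractions <- function(variants, scope = "genome") {
  rec <- variants$records
  if (!identical(scope, "genome")) rec <- rec[rec$scaffold == scope, ,
                                              drop = FALSE]
  tot <- rec$ref_depth + rec$alt_depth
  keep <- tot > 0L
  structure(list(scope = scope,
                 fractions = rec$alt_depth[keep] / tot[keep],
                 coverages = as.integer(tot[keep])),
            class = "alt_fractions")
}

#' Simulate allele fractions by per-site binomial sampling
#'
#' For each observed site coverage and each replicate, draws an alternative
#' read count from Binomial(coverage, `p`) and records the resulting
#' fraction. With `p = 0.5` this is the ideal-diploid ("fair coin")
#' expectation used as the reference curve; `p = 1/3` and `p = 1/4`
#' correspond to ideal triploid (AAB) and tetraploid (AAAB) sites.
#'
#' @param coverages Integer vector of per-site total depths (all >= 1).
#' @param p True alternative-allele probability (default 0.5).
#' @param replicates Draws per site (default 10).
#' @param seed Optional seed; a fixed seed gives bit-identical output.
#' @return Numeric vector of simulated fractions, length
#'   `length(coverages) * replicates`.
#' @export
simulate_allele_fractions <- function(coverages, p = 0.5, replicates = 10L,
                                      seed = NULL) {
  if (!length(coverages)) stop2("empty coverage list")
  if (any(coverages < 1L)) stop2("all coverages must be >= 1")
  with_seed(seed, {
    n <- rep.int(as.integer(coverages), replicates)
    stats::rbinom(length(n), size = n, prob = p) / n
  })
}

#' @rdname simulate_allele_fractions
#' @param ... Passed to [simulate_allele_fractions()].
#' @export
simulate_ideal_diploid <- function(coverages, replicates = 10L,
                                   seed = NULL, ...) {
  simulate_allele_fractions(coverages, p = 0.5, replicates = replicates,
                            seed = seed, ...)
}

# two-sample Kolmogorov-Smirnov distance (max absolute ECDF difference)
ks_distance <- function(x, y) {
  if (!length(x) || !length(y)) return(NA_real_)
  grid <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(grid)
  fy <- stats::ecdf(y)(grid)
  max(abs(fx - fy))
}

#' Compare empirical allele balance against a simulated ideal
#'
#' Bins both fraction sets on identical edges over \[0, 1\], normalizes to
#' unit mass, computes the two-sample Kolmogorov-Smirnov distance, and
#' locates the empirical mode after width-3 smoothing. The mode is
#' classified against the ideal ploidy balances 0.25, 1/3, 0.5, 2/3, 0.75
#' (mirrored triploid/tetraploid fractions map to the same ploidy) with a
#' tolerance of `mode_tol`; outside every band the result is "ambiguous".
#'
#' @param empirical An `alt_fractions` object.
#' @param simulated Numeric vector of simulated fractions (see
#'   [simulate_ideal_diploid()]).
#' @param bins Number of histogram bins over \[0, 1\] (default 50).
#' @param mode_tol Classification tolerance around the reference fractions
#'   (default 0.05; coverage >= 30 separates 0.5 from 1/3 at this width).
#' @return An object of class `fair_coin_result`: list with `scope`,
#'   `n_snps`, `empirical_hist`, `simulated_hist` (densities summing to 1),
#'   `bin_mid`, `ks_distance`, `modal_fraction`, `modal_class`.
#' @export
fair_coin_compare <- function(empirical, simulated, bins = 50L,
                              mode_tol = 0.05) {
  f <- empirical$fractions
  if (!length(f)) stop2("empirical fraction set is empty")
  if (!length(simulated)) stop2("simulated fraction set is empty")
  edges <- seq(0, 1, length.out = bins + 1L)
  bin_of <- function(v) pmin(pmax(findInterval(v, edges,
                                               rightmost.closed = TRUE), 1L),
                             bins)
  emp <- tabulate(bin_of(f), nbins = bins)
  sim <- tabulate(bin_of(simulated), nbins = bins)
  emp <- emp / sum(emp)
  sim <- sim / sum(sim)
  mid <- (edges[-1L] + edges[-(bins + 1L)]) / 2

  sm <- sma3(emp)
  modal_fraction <- mid[which.max(sm)]
  refs <- c(0.25, 1 / 3, 0.5, 2 / 3, 0.75)
  cls <- c("tetraploid", "triploid", "diploid", "triploid", "tetraploid")
  d <- abs(modal_fraction - refs)
  modal_class <- if (min(d) <= mode_tol) cls[which.min(d)] else "ambiguous"

  structure(list(scope = empirical$scope, n_snps = length(f),
                 empirical_hist = emp, simulated_hist = sim, bin_mid = mid,
                 ks_distance = ks_distance(f, simulated),
                 modal_fraction = modal_fraction, modal_class = modal_class),
            class = "fair_coin_result")
}

#' @export
print.fair_coin_result <- function(x, ...) {
  cat(sprintf(
    "fair_coin [%s]: %d SNPs, mode %.3f (%s), KS distance %.4f\n",
    x$scope, x$n_snps, x$modal_fraction, x$modal_class, x$ks_distance))
  invisible(x)
}

#' Genome-wide and per-scaffold fair-coin analysis
#'
#' Runs the allele-balance comparison for the whole genome and for each
#' scaffold with at least `min_snps` kept SNPs; scaffolds below that count
#' are reported as `"insufficient data"` rather than classified.
#'
#' @param variants A `variant_table`.
#' @param replicates Binomial replicates per site for the ideal-diploid
#'   simulation (default 10).
#' @param bins Histogram bins (default 50).
#' @param min_snps Minimum SNPs for a per-scaffold result (default 20).
#' @param seed Seed for the simulation.
#' @return List with `genome` (a `fair_coin_result` or `NULL` when there
#'   are no SNPs), `per_scaffold` (named list of results), and `table`
#'   (data.frame: scaffold, n_snps, modal_fraction, modal_class,
#'   ks_distance; unclassified scaffolds carry `"insufficient data"`).
#' @export
fair_coin_scan <- function(variants, replicates = 10L, bins = 50L,
                           min_snps = 20L, seed = NULL) {
  scaffolds <- unique(variants$records$scaffold)
  genome_af <- alt_fractions(variants, "genome")
  genome <- NULL
  if (length(genome_af$fractions)) {
    sim <- simulate_ideal_diploid(genome_af$coverages,
                                  replicates = replicates, seed = seed)
    genome <- fair_coin_compare(genome_af, sim, bins = bins)
  }
  per_scaffold <- list()
  rows <- list()
  for (i in seq_along(scaffolds)) {
    sc <- scaffolds[i]
    af <- alt_fractions(variants, sc)
    if (length(af$fractions) < min_snps) {
      rows[[sc]] <- data.frame(scaffold = sc,
                               n_snps = length(af$fractions),
                               modal_fraction = NA_real_,
                               modal_class = "insufficient data",
                               ks_distance = NA_real_,
                               stringsAsFactors = FALSE)
      next
    }
    sim <- simulate_ideal_diploid(af$coverages, replicates = replicates,
                                  seed = if (is.null(seed)) NULL
                                         else child_seed(seed, i))
    res <- fair_coin_compare(af, sim, bins = bins)
    per_scaffold[[sc]] <- res
    rows[[sc]] <- data.frame(scaffold = sc, n_snps = res$n_snps,
                             modal_fraction = res$modal_fraction,
                             modal_class = res$modal_class,
                             ks_distance = res$ks_distance,
                             stringsAsFactors = FALSE)
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scaffold = character(), n_snps = integer(),
               modal_fraction = numeric(), modal_class = character(),
               ks_distance = numeric(), stringsAsFactors = FALSE)
  rownames(table) <- NULL
  list(genome = genome, per_scaffold = per_scaffold, table = table)
}

#' Write the per-scaffold fair-coin table as TSV
#'
#' @param scan Output of [fair_coin_scan()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fair_coin_tsv <- function(scan, path) {
  write_commented_tsv(scan$table, path)
}
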