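#' Default diagnostic thresholds
#'
#' * `gc_low` 0.35 / `gc_high` 0.65 — extreme-composition warnings; many
#'   zygomycetous fungi sit just above the low cutoff.
#' * `mapped_min` 0.90 — minimum acceptable mapped-read fraction.
#' * `busco_min` 0.90 — minimum acceptable BUSCO complete fraction.
#' * `min_scaffold` 1000 bp — scaffolds shorter than this are excluded from
#'   mixture-based checks.
#' * `window` 1000 bp — default window length.
#' * `bimodality_delta_bic` 10 — "decisive" BIC margin required before a
#'   two-component model is preferred.
#'
#' @return Named list of thresholds, to be passed to the check functions.
#' @export
default_thresholds <- function() {
  list(gc_low = 0.35, gc_high = 0.65, mapped_min = 0.90, busco_min = 0.90,
       min_scaffold = 1000L, window = 1000L, bimodality_delta_bic = 10)
}

warning_entry <- function(code, severity, message) {
  data.frame(code = code, severity = severity, message = message,
             stringsAsFactors = FALSE)
}

no_warnings <- function() {
  data.frame(code = character(), severity = character(),
             message = character(), stringsAsFactors = FALSE)
}

#' Global GC content check
#'
#' Computes GC over all non-N bases of the assembly and warns when it
#' falls strictly below `gc_low` or strictly above `gc_high`.
#'
#' @param assembly An `assembly`.
#' @param thresholds See [default_thresholds()].
#' @return List with `gc` (global GC, `NA` when undefined), `verdict`
#'   (`"ok"`, `"low"`, `"high"`, `"undefined"`) and `warnings`.
#' @export
gc_content_check <- function(assembly, thresholds = default_thresholds()) {
  if (!length(assembly$ids)) stop2("empty assembly")
  gc <- assembly_gc(assembly)
  if (is.na(gc)) {
    return(list(gc = NA_real_, verdict = "undefined",
                warnings = warning_entry("UNDEFINED_GC", "warning",
                                         "GC undefined: assembly is all N")))
  }
  if (gc < thresholds$gc_low) {
    list(gc = gc, verdict = "low",
         warnings = warning_entry("LOW_GC", "warning",
                                  sprintf("global GC %.1f%% below %.0f%%",
                                          100 * gc,
                                          100 * thresholds$gc_low)))
  } else if (gc > thresholds$gc_high) {
    list(gc = gc, verdict = "high",
         warnings = warning_entry("HIGH_GC", "warning",
                                  sprintf("global GC %.1f%% above %.0f%%",
                                          100 * gc,
                                          100 * thresholds$gc_high)))
  } else {
    list(gc = gc, verdict = "ok", warnings = no_warnings())
  }
}

#' Mapped-read fraction check
#'
#' @param mapped_fraction Fraction of reads mapped (from mapping logs), or
#'   `NULL` when unavailable.
#' @param thresholds See [default_thresholds()].
#' @return List with `verdict` (`"ok"`, `"low"`, `"not assessed"`) and
#'   `warnings`.
#' @export
mapped_fraction_check <- function(mapped_fraction = NULL,
                                  thresholds = default_thresholds()) {
  if (is.null(mapped_fraction) || is.na(mapped_fraction)) {
    return(list(verdict = "not assessed", warnings = no_warnings()))
  }
  if (mapped_fraction < 0 || mapped_fraction > 1) {
    stop2("mapped_fraction must be in [0, 1]")
  }
  if (mapped_fraction < thresholds$mapped_min) {
    list(verdict = "low",
         warnings = warning_entry("LOW_MAPPED", "warning",
                                  sprintf("mapped-read fraction %.2f below %.2f",
                                          mapped_fraction,
                                          thresholds$mapped_min)))
  } else {
    list(verdict = "ok", warnings = no_warnings())
  }
}

#' BUSCO completeness check
#'
#' Consumes a precomputed BUSCO complete fraction (the tool itself is
#' never executed here).
#'
#' @param busco_complete Complete-BUSCO fraction in \[0, 1\], or `NULL`.
#' @param thresholds See [default_thresholds()].
#' @return List with `verdict` and `warnings`.
#' @export
busco_check <- function(busco_complete = NULL,
                        thresholds = default_thresholds()) {
  if (is.null(busco_complete) || is.na(busco_complete)) {
    return(list(verdict = "not assessed", warnings = no_warnings()))
  }
  if (busco_complete < 0 || busco_complete > 1) {
    stop2("busco_complete must be in [0, 1]")
  }
  if (busco_complete < thresholds$busco_min) {
    list(verdict = "low",
         warnings = warning_entry("LOW_BUSCO", "warning",
                                  sprintf("BUSCO complete %.2f below %.2f",
                                          busco_complete,
                                          thresholds$busco_min)))
  } else {
    list(verdict = "ok", warnings = no_warnings())
  }
}

# length-weighted 1-D Gaussian mixture with shared sigma; returns loglik
# (weights sum to the number of observations so BIC uses n = #scaffolds)
weighted_em_1d <- function(x, w, k, seed = 1L, restarts = 5L) {
  n <- length(x)
  w <- w / sum(w) * n
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(max(1L, restarts * (k > 1L)))) {
      mu <- if (k == 1L) sum(w * x) / n else
        sort(stats::quantile(x, stats::runif(k, 0.05, 0.95), names = FALSE))
      pi_k <- rep(1 / k, k)
      sigma <- max(sqrt(sum(w * (x - mean(x))^2) / n), 0.05)
      ll_old <- -Inf
      for (it in 1:300) {
        dens <- vapply(1:k, function(j)
          pi_k[j] * stats::dnorm(x, mu[j], sigma), numeric(n))
        dens <- matrix(dens, nrow = n)
        rs <- rowSums(dens)
        rs[rs == 0] <- .Machine$double.xmin
        ll <- sum(w * log(rs))
        resp <- dens / rs
        wk <- colSums(w * resp)
        pi_k <- wk / n
        mu <- colSums(w * resp * x) / wk
        sigma <- max(sqrt(sum(w * resp * (outer(x, mu, "-"))^2) / n), 0.02)
        if (is.finite(ll_old) && ll - ll_old < 1e-8) break
        ll_old <- ll
      }
      if (is.null(best) || ll > best$loglik) {
        best <- list(means = sort(mu), weights = pi_k[order(mu)],
                     sigma = sigma, loglik = ll,
                     resp = resp[, order(mu), drop = FALSE])
      }
    }
  })
  best$n_params <- (k - 1L) + k + 1L  # weights + means + shared sigma
  best
}

#' Coverage bimodality check (aneuploidy / hemidiploidy signature)
#'
#' Fits one- and two-component Gaussian mixtures to `log2(mean_depth)` of
#' usable scaffolds (length >= `min_scaffold`, positive coverage), with
#' scaffolds weighted by length. The coverage distribution is called
#' bimodal when the two-component model is decisively preferred
#' (`BIC(1) - BIC(2) > bimodality_delta_bic`) and the component means are
#' at least 0.5 apart on the log2 scale (>= ~1.4-fold coverage ratio).
#'
#' @param summaries Output of [scaffold_summaries()].
#' @param thresholds See [default_thresholds()].
#' @param seed Seed for mixture restarts (default 1).
#' @return List with `verdict` (`"unimodal"`, `"bimodal"`,
#'   `"insufficient"`), `n_used`, `delta_bic`, `component_means`
#'   (coverage scale), `cluster` (per-usable-scaffold component labels)
#'   and `warnings`.
#' @export
coverage_bimodality_check <- function(summaries,
                                      thresholds = default_thresholds(),
                                      seed = 1L) {
  use <- summaries$length >= thresholds$min_scaffold &
    summaries$mean_depth > 0
  if (sum(use) < 20L) {
    return(list(verdict = "insufficient", n_used = sum(use),
                delta_bic = NA_real_, component_means = NA_real_,
                cluster = NULL, warnings = no_warnings()))
  }
  x <- log2(summaries$mean_depth[use])
  w <- as.numeric(summaries$length[use])
  n <- length(x)
  f1 <- weighted_em_1d(x, w, 1L, seed = seed)
  f2 <- weighted_em_1d(x, w, 2L, seed = seed)
  bic1 <- -2 * f1$loglik + f1$n_params * log(n)
  bic2 <- -2 * f2$loglik + f2$n_params * log(n)
  delta <- bic1 - bic2
  sep <- abs(diff(f2$means))
  bimodal <- delta > thresholds$bimodality_delta_bic && sep >= 0.5
  cluster <- rep(NA_integer_, nrow(summaries))
  cluster[use] <- if (bimodal) max.col(f2$resp) else 1L
  warnings <- if (bimodal) {
    warning_entry("BIMODAL_COVERAGE", "warning",
                  sprintf("scaffold coverage is bimodal (modes ~%.0fx and ~%.0fx): possible aneuploidy or mixed haploid/diploid content",
                          2^f2$means[1], 2^f2$means[2]))
  } else no_warnings()
  list(verdict = if (bimodal) "bimodal" else "unimodal", n_used = n,
       delta_bic = delta, component_means = 2^f2$means, cluster = cluster,
       warnings = warnings)
}

#' Window population-structure check (SNP density vs coverage)
#'
#' Standardizes `(snp_count, log2 mean_depth)` over usable windows and
#' compares one- against two-component bivariate Gaussian mixtures.
#' Multiple populations are reported when the two-component model wins by
#' more than `bimodality_delta_bic` BIC and the component centroids are at
#' least one pooled within-component standard deviation apart on either
#' axis — the signature of aneuploid, mixed haploid/diploid or
#' contaminated genomes.
#'
#' @param windows Windows with statistics (see [window_stats()]).
#' @param thresholds See [default_thresholds()].
#' @importFrom mclust Mclust mclustBIC
#' @return List with `verdict` (`"single-population"`,
#'   `"multi-population"`, `"insufficient"`), `n_used`, `delta_bic`,
#'   `centroid_separation`, `cluster` labels and `warnings`.
#' @export
variation_coverage_population_check <- function(windows,
                                                thresholds = default_thresholds()) {
  # truncated terminal windows have inflated variance on both axes and
  # would masquerade as a second population; only full-length windows
  # enter the mixture. sqrt stabilizes the Poisson-like SNP counts.
  full <- (windows$end - windows$start) ==
    max(windows$end - windows$start)
  use <- windows$mean_depth > 0 & full
  if (sum(use) < 100L) {
    return(list(verdict = "insufficient", n_used = sum(use),
                delta_bic = NA_real_, centroid_separation = NA_real_,
                cluster = NULL, warnings = no_warnings()))
  }
  X <- cbind(snp = sqrt(windows$snp_count[use]),
             cov = log2(windows$mean_depth[use]))
  X <- scale(X)
  X[is.nan(X)] <- 0  # zero-variance axis
  pri <- mclust::priorControl()  # regularizes point-mass clusters
  m1 <- mclust::Mclust(X, G = 1, modelNames = "VVV", prior = pri,
                       verbose = FALSE)
  m2 <- mclust::Mclust(X, G = 2, modelNames = "VVV", prior = pri,
                       verbose = FALSE)
  if (is.null(m1) || is.null(m2)) {
    return(list(verdict = "single-population", n_used = sum(use),
                delta_bic = NA_real_, centroid_separation = NA_real_,
                cluster = NULL, warnings = no_warnings()))
  }
  # mclust BIC = 2*loglik - p*log(n): larger is better, so the classical
  # BIC(1) - BIC(2) margin equals m2$bic - m1$bic
  delta <- as.numeric(m2$bic - m1$bic)
  mu <- m2$parameters$mean          # 2 x G matrix
  pro <- m2$parameters$pro
  sig <- m2$parameters$variance$sigma  # 2 x 2 x G
  pooled_sd <- sqrt(pro[1] * diag(sig[, , 1]) + pro[2] * diag(sig[, , 2]))
  sep <- max(abs(mu[, 1] - mu[, 2]) / pmax(pooled_sd, 1e-9))
  multi <- delta > thresholds$bimodality_delta_bic && sep >= 1
  cluster <- rep(NA_integer_, nrow(windows))
  cluster[use] <- if (multi) m2$classification else 1L
  warnings <- if (multi) {
    warning_entry("MULTI_POPULATION", "warning",
                  "windows form multiple SNP-density/coverage populations: possible aneuploidy, loss of heterozygosity, mixed ploidy or contamination")
  } else no_warnings()
  list(verdict = if (multi) "multi-population" else "single-population",
       n_used = sum(use), delta_bic = delta, centroid_separation = sep,
       cluster = cluster, warnings = warnings)
}

#' Compose the diagnostic report
#'
#' Aggregates assembly metrics, the threshold checks, the mixture-based
#' population checks, the k-mer classification, the genome-wide ploidy
#' profile and the fair-coin summary into a single report with stable
#' warning codes and deterministic ordering, plus one-line interpretations
#' for recognizable verdict combinations.
#'
#' @param assembly An `assembly`.
#' @param variants Optional `variant_table`.
#' @param depth Optional `depth_track`.
#' @param summaries Optional [scaffold_summaries()] output (computed when
#'   omitted and variants/depth allow).
#' @param windows Optional windows with statistics.
#' @param spectrum_peaks Optional `spectrum_peaks`.
#' @param ploidy_profile Optional [scaffold_ploidy_profile()] output.
#' @param fair_coin Optional [fair_coin_scan()] output.
#' @param mapped_fraction Optional mapped-read fraction.
#' @param busco_complete Optional BUSCO complete fraction.
#' @param thresholds See [default_thresholds()].
#' @param seed Seed for the mixture checks (default 1).
#' @return An object of class `diagnostic_report`: list with `metrics`,
#'   `verdicts`, `warnings` (data.frame code/severity/message, unique
#'   codes), `interpretations` (character vector) and `thresholds`.
#' @export
compose_report <- function(assembly, variants = NULL, depth = NULL,
                           summaries = NULL, windows = NULL,
                           spectrum_peaks = NULL, ploidy_profile = NULL,
                           fair_coin = NULL, mapped_fraction = NULL,
                           busco_complete = NULL,
                           thresholds = default_thresholds(), seed = 1L) {
  if (is.null(summaries) && (!is.null(variants) || !is.null(depth))) {
    summaries <- scaffold_summaries(assembly, variants, depth)
  }

  metrics <- list(genome_size = assembly$total_length,
                  n_scaffolds = length(assembly$ids))
  warnings <- no_warnings()
  verdicts <- list()

  gc_res <- gc_content_check(assembly, thresholds)
  metrics$global_gc <- gc_res$gc
  verdicts$gc <- gc_res$verdict
  warnings <- rbind(warnings, gc_res$warnings)

  map_res <- mapped_fraction_check(mapped_fraction, thresholds)
  verdicts$mapped_reads <- map_res$verdict
  warnings <- rbind(warnings, map_res$warnings)

  busco_res <- busco_check(busco_complete, thresholds)
  verdicts$busco <- busco_res$verdict
  warnings <- rbind(warnings, busco_res$warnings)

  if (!is.null(variants)) {
    metrics$n_snps <- nrow(variants$records)
    metrics$snp_density <- 1000 * nrow(variants$records) /
      assembly$total_length
  }
  if (!is.null(summaries)) {
    metrics$global_mean_depth <-
      sum(summaries$mean_depth * summaries$length) / sum(summaries$length)
    bim <- coverage_bimodality_check(summaries, thresholds, seed = seed)
    verdicts$coverage_bimodality <- bim$verdict
    warnings <- rbind(warnings, bim$warnings)
  } else {
    bim <- NULL
  }
  if (!is.null(windows)) {
    pop <- variation_coverage_population_check(windows, thresholds)
    verdicts$window_populations <- pop$verdict
    warnings <- rbind(warnings, pop$warnings)
  } else {
    pop <- NULL
  }
  if (!is.null(spectrum_peaks)) {
    metrics$kmer_n_peaks <- spectrum_peaks$n_peaks
    metrics$kmer_haploid_coverage <- spectrum_peaks$haploid_coverage
    metrics$kmer_genome_size_estimate <- spectrum_peaks$genome_size_estimate
    verdicts$kmer_spectrum <- classify_spectrum(spectrum_peaks)
  }
  if (!is.null(ploidy_profile)) {
    nw <- sum(ploidy_profile$n_windows)
    metrics$ploidy_frac_diploid <-
      sum(ploidy_profile$frac_diploid * ploidy_profile$n_windows) / nw
    metrics$ploidy_frac_triploid <-
      sum(ploidy_profile$frac_triploid * ploidy_profile$n_windows) / nw
    metrics$ploidy_frac_tetraploid <-
      sum(ploidy_profile$frac_tetraploid * ploidy_profile$n_windows) / nw
    metrics$ploidy_frac_missing <-
      sum(ploidy_profile$frac_missing * ploidy_profile$n_windows) / nw
    fracs <- c(diploid = metrics$ploidy_frac_diploid,
               triploid = metrics$ploidy_frac_triploid,
               tetraploid = metrics$ploidy_frac_tetraploid)
    assessed <- 1 - metrics$ploidy_frac_missing
    verdicts$ploidy_profile <- if (assessed < 0.05) "mostly missing"
      else names(fracs)[which.max(fracs)]
  }
  if (!is.null(fair_coin) && !is.null(fair_coin$genome)) {
    metrics$fair_coin_modal_fraction <- fair_coin$genome$modal_fraction
    metrics$fair_coin_ks <- fair_coin$genome$ks_distance
    verdicts$fair_coin <- fair_coin$genome$modal_class
  }

  interpretations <- interpret_verdicts(metrics, verdicts, summaries,
                                        thresholds)
  warnings <- warnings[!duplicated(warnings$code), , drop = FALSE]
  rownames(warnings) <- NULL
  structure(list(metrics = metrics, verdicts = verdicts,
                 warnings = warnings, interpretations = interpretations,
                 thresholds = thresholds),
            class = "diagnostic_report")
}

# fixed rule order => deterministic report text
interpret_verdicts <- function(metrics, verdicts, summaries, thresholds) {
  out <- character(0)
  bim <- identical(verdicts$coverage_bimodality, "bimodal")
  multi <- identical(verdicts$window_populations, "multi-population")
  low_het <- !is.null(metrics$snp_density) && metrics$snp_density < 5
  if (bim && low_het) {
    out <- c(out, "bimodal coverage with low heterozygosity: possible hemidiploid (part haploid, part homozygous diploid) genome")
  } else if (bim) {
    out <- c(out, "bimodal scaffold coverage: possible aneuploidy")
  }
  if (multi && !bim) {
    out <- c(out, "multiple SNP-density/coverage window populations: possible aneuploidy, loss of heterozygosity or mixed ploidy")
  }
  if (identical(verdicts$kmer_spectrum, "heterozygous-diploid-like")) {
    hint <- if (!is.null(metrics$snp_density) && metrics$snp_density >= 20)
      "heterozygous diploid with extreme heterozygosity: possible hybrid"
      else "two k-mer coverage peaks: heterozygous diploid"
    out <- c(out, hint)
  }
  if (identical(verdicts$ploidy_profile, "triploid")) {
    out <- c(out, "triploid-dominant windowed ploidy profile")
  }
  if (identical(verdicts$ploidy_profile, "tetraploid")) {
    out <- c(out, "tetraploid-dominant windowed ploidy profile")
  }
  # contamination signature: a subset of scaffolds with deviant GC and
  # depressed coverage relative to the bulk
  if (!is.null(summaries) && !is.na(metrics$global_gc %||% NA) &&
      !is.null(metrics$global_mean_depth)) {
    alien <- !is.na(summaries$gc_fraction) &
      abs(summaries$gc_fraction - metrics$global_gc) > 0.1 &
      summaries$mean_depth < 0.5 * metrics$global_mean_depth
    if (mean(alien) >= 0.05) {
      out <- c(out, sprintf("%.0f%% of scaffolds have deviant GC and low coverage: possible contaminating sequences",
                            100 * mean(alien)))
    }
  }
  if (!length(out)) out <- "no unusual genomic configuration detected"
  out
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

# deterministic human-readable rendering
format_report <- function(report) {
  fmt_num <- function(v) {
    if (is.na(v)) "NA" else if (abs(v) >= 1000) sprintf("%.0f", v)
    else sprintf("%.4g", v)
  }
  lines <- c("== genome diagnostic report ==", "", "-- metrics --")
  for (nm in names(report$metrics)) {
    lines <- c(lines, sprintf("%-28s %s", nm, fmt_num(report$metrics[[nm]])))
  }
  lines <- c(lines, "", "-- verdicts --")
  for (nm in names(report$verdicts)) {
    lines <- c(lines, sprintf("%-28s %s", nm, report$verdicts[[nm]]))
  }
  lines <- c(lines, "", "-- warnings --")
  if (nrow(report$warnings)) {
    lines <- c(lines, sprintf("[%s] %s", report$warnings$code,
                              report$warnings$message))
  } else {
    lines <- c(lines, "(none)")
  }
  c(lines, "", "-- interpretation --", report$interpretations)
}

#' Write a diagnostic report as JSON and text
#'
#' Serialization is deterministic: identical reports produce byte-identical
#' files.
#'
#' @param report A `diagnostic_report`.
#' @param json_path Output JSON path (`NULL` to skip).
#' @param txt_path Output text path (`NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, json_path = NULL, txt_path = NULL) {
  if (!is.null(json_path)) {
    obj <- list(metrics = report$metrics, verdicts = report$verdicts,
                warnings = report$warnings,
                interpretations = report$interpretations)
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  if (!is.null(txt_path)) {
    writeLines(format_report(report), txt_path)
  }
  invisible(c(json = json_path, txt = txt_path))
}
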