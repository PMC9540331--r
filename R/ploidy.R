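# Windowed ploidy scoring from allele-balance mixtures.
#
# Heterozygous allele fractions in a window are modelled as a Gaussian
# mixture with a shared standard deviation. Three fixed-mean hypotheses are
# compared: diploid {1/2}, triploid {1/3, 2/3}, tetraploid {1/4, 1/2, 3/4}.
# A free-mean mixture of the same size serves as a goodness-of-fit
# reference (its likelihood dominates every fixed hypothesis).

HYPOTHESIS_MEANS <- list(diploid = 0.5,
                         triploid = c(1 / 3, 2 / 3),
                         tetraploid = c(1 / 4, 1 / 2, 3 / 4))

SIGMA_FLOOR <- 0.01

# clip fractions away from 0/1: fixation and sequencing noise otherwise
# produce unbounded likelihood terms at the boundary
clip_fractions <- function(f, lo = 0.02, hi = 0.98) pmin(pmax(f, lo), hi)

# one EM run with shared sigma; means updated only when fixed_means = FALSE
em_shared_sigma <- function(x, means, fixed_means, weights = NULL,
                            sigma = NULL, tol = 1e-6, maxit = 500L) {
  n <- length(x)
  k <- length(means)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (is.null(sigma)) sigma <- max(stats::sd(x), SIGMA_FLOOR)
  if (is.na(sigma) || sigma < SIGMA_FLOOR) sigma <- SIGMA_FLOOR
  degenerate <- isTRUE(stats::sd(x) == 0)
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    dens <- vapply(seq_len(k), function(j)
      weights[j] * stats::dnorm(x, means[j], sigma), numeric(n))
    dens <- matrix(dens, nrow = n)
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    resp <- dens / rowsum_d
    weights <- colMeans(resp)
    if (!fixed_means) {
      means <- colSums(resp * x) / pmax(colSums(resp), 1e-12)
    }
    sigma <- sqrt(sum(resp * (outer(x, means, "-"))^2) / n)
    if (!is.finite(sigma) || sigma < SIGMA_FLOOR) sigma <- SIGMA_FLOOR
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  ord <- order(means)
  structure(list(means = means[ord], weights = weights[ord], sigma = sigma,
                 loglik = ll, fixed_means = fixed_means,
                 degenerate = degenerate, n = n, iterations = it),
            class = "balance_mixture")
}

#' @export
print.balance_mixture <- function(x, ...) {
  cat(sprintf(
    "balance_mixture (%s means): mu = {%s}, w = {%s}, sigma = %.4f, logLik = %.3f\n",
    if (x$fixed_means) "fixed" else "free",
    paste(sprintf("%.3f", x$means), collapse = ", "),
    paste(sprintf("%.3f", x$weights), collapse = ", "),
    x$sigma, x$loglik))
  invisible(x)
}

#' @export
logLik.balance_mixture <- function(object, ...) {
  p <- length(object$weights) - 1L + 1L +
    (if (object$fixed_means) 0L else length(object$means))
  structure(object$loglik, df = p, nobs = object$n, class = "logLik")
}

#' Fit a free-mean Gaussian mixture to allele fractions
#'
#' EM with free means, free weights and a shared standard deviation
#' (floored at 0.01), best of `restarts` seeded restarts plus any
#' `extra_inits`. Fractions are clipped to \[0.02, 0.98\] before fitting.
#'
#' @param fractions Numeric vector of alt-allele fractions in (0, 1).
#' @param n_components Number of mixture components (1-3).
#' @param seed Seed controlling the restarts.
#' @param min_snps Minimum number of observations (default 10).
#' @param restarts Number of random restarts (default 5).
#' @param extra_inits Optional list of `list(means=, weights=, sigma=)`
#'   starting points, e.g. fixed-hypothesis solutions.
#' @return A `balance_mixture` object (fields `means`, `weights`, `sigma`,
#'   `loglik`, `fixed_means`, `degenerate`).
#' @export
fit_free_mixture <- function(fractions, n_components = 2L, seed = NULL,
                             min_snps = 10L, restarts = 5L,
                             extra_inits = NULL) {
  if (length(fractions) < min_snps) {
    stop2("need at least ", min_snps, " fractions (got ",
          length(fractions), ")")
  }
  if (n_components < 1L || n_components > 3L) {
    stop2("n_components must be 1, 2 or 3")
  }
  x <- clip_fractions(fractions)
  fits <- list()
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      init_means <- sort(stats::runif(n_components,
                                      min = stats::quantile(x, 0.05),
                                      max = stats::quantile(x, 0.95)))
      fits[[r]] <- em_shared_sigma(x, init_means, fixed_means = FALSE)
    }
  })
  for (ini in extra_inits %||% list()) {
    fits[[length(fits) + 1L]] <-
      em_shared_sigma(x, ini$means, fixed_means = FALSE,
                      weights = ini$weights, sigma = ini$sigma)
  }
  fits[[which.max(vapply(fits, `[[`, numeric(1L), "loglik"))]]
}

#' Fit a fixed-mean ploidy hypothesis to allele fractions
#'
#' Means are pinned at the ideal allele balances of the hypothesis
#' (diploid 1/2; triploid 1/3, 2/3; tetraploid 1/4, 1/2, 3/4); weights and
#' the shared standard deviation are fitted by EM.
#'
#' @param fractions Numeric vector of alt-allele fractions.
#' @param hypothesis `"diploid"`, `"triploid"` or `"tetraploid"`.
#' @param min_snps Minimum number of observations (default 10).
#' @return A `balance_mixture` with `fixed_means = TRUE`.
#' @export
loglik_fixed_model <- function(fractions,
                               hypothesis = c("diploid", "triploid",
                                              "tetraploid"),
                               min_snps = 10L) {
  hypothesis <- match.arg(hypothesis)
  if (length(fractions) < min_snps) {
    stop2("need at least ", min_snps, " fractions (got ",
          length(fractions), ")")
  }
  x <- clip_fractions(fractions)
  em_shared_sigma(x, HYPOTHESIS_MEANS[[hypothesis]], fixed_means = TRUE)
}

#' Windowed ploidy likelihood scores
#'
#' For every window with at least `min_snps` SNPs, fits the three
#' fixed-mean hypotheses to the window's allele fractions and converts
#' their log-likelihoods into normalized support scores
#' `score_m = exp(LL_m - LL_max) / sum_m' exp(LL_m' - LL_max)`, which are
#' bounded, comparable across windows and sum to 1. Windows with fewer
#' SNPs are flagged missing — homozygous tracts carry no allele-balance
#' information and cannot be assessed.
#'
#' @param variants A `variant_table`.
#' @param windows A `genome_windows` tiling (statistics not required).
#' @param min_snps Minimum SNPs per scored window (default 10).
#' @param seed Unused by the fixed fits (kept for interface stability with
#'   the free-model diagnostics).
#' @return A data.frame of class `ploidy_windows`: the window coordinates
#'   plus `n_snps`, `score_diploid`, `score_triploid`, `score_tetraploid`,
#'   `best` (`NA` when missing) and `missing`.
#' @export
window_ploidy_scores <- function(variants, windows, min_snps = 10L,
                                 seed = NULL) {
  rec <- variants$records
  tot <- rec$ref_depth + rec$alt_depth
  rec <- rec[tot > 0L, , drop = FALSE]
  frac <- rec$alt_depth / (rec$ref_depth + rec$alt_depth)

  out <- as.data.frame(windows)[, c("scaffold", "start", "end")]
  n <- nrow(out)
  out$n_snps <- 0L
  out$score_diploid <- NA_real_
  out$score_triploid <- NA_real_
  out$score_tetraploid <- NA_real_
  out$best <- NA_character_
  out$missing <- TRUE

  hyp <- names(HYPOTHESIS_MEANS)
  for (sc in unique(out$scaffold)) {
    wi <- which(out$scaffold == sc)
    sel <- rec$scaffold == sc
    pos <- rec$pos0[sel]
    f <- frac[sel]
    if (!length(pos)) next
    idx <- findInterval(pos, out$start[wi])
    ok <- idx >= 1L & pos < out$end[wi][pmax(idx, 1L)]
    out$n_snps[wi] <- tabulate(idx[ok], nbins = length(wi))
    for (j in seq_along(wi)) {
      fw <- f[ok & idx == j]
      if (length(fw) < min_snps) next
      ll <- vapply(hyp, function(h)
        loglik_fixed_model(fw, h, min_snps = min_snps)$loglik, numeric(1L))
      w <- exp(ll - max(ll))
      w <- w / sum(w)
      out$score_diploid[wi[j]] <- w[["diploid"]]
      out$score_triploid[wi[j]] <- w[["triploid"]]
      out$score_tetraploid[wi[j]] <- w[["tetraploid"]]
      out$best[wi[j]] <- hyp[which.max(ll)]
      out$missing[wi[j]] <- FALSE
    }
  }
  structure(out, class = c("ploidy_windows", "data.frame"),
            min_snps = as.integer(min_snps))
}

#' Per-scaffold ploidy profile
#'
#' Fraction of each scaffold's windows assigned to every hypothesis (or
#' missing); the four fractions sum to 1 per scaffold.
#'
#' @param scores A `ploidy_windows` data.frame.
#' @return Data.frame: `scaffold`, `n_windows`, `frac_diploid`,
#'   `frac_triploid`, `frac_tetraploid`, `frac_missing`.
#' @export
scaffold_ploidy_profile <- function(scores) {
  sc_ids <- unique(scores$scaffold)
  rows <- lapply(sc_ids, function(sc) {
    s <- scores[scores$scaffold == sc, , drop = FALSE]
    nw <- nrow(s)
    data.frame(scaffold = sc, n_windows = nw,
               frac_diploid = sum(!s$missing & s$best == "diploid",
                                  na.rm = TRUE) / nw,
               frac_triploid = sum(!s$missing & s$best == "triploid",
                                   na.rm = TRUE) / nw,
               frac_tetraploid = sum(!s$missing & s$best == "tetraploid",
                                     na.rm = TRUE) / nw,
               frac_missing = sum(s$missing) / nw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the per-window ploidy score table as TSV
#'
#' @param scores A `ploidy_windows` data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ploidy_tsv <- function(scores, path) {
  write_commented_tsv(as.data.frame(scores), path)
}
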