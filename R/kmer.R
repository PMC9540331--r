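#' Count canonical k-mers and build the multiplicity spectrum
#'
#' Every k-long window of every read contributes one instance of its
#' canonical form, the lexicographic minimum of the k-mer and its reverse
#' complement; the spectrum is therefore strand-independent. Windows
#' containing any non-ACGT character (e.g. N) are skipped. Odd k is
#' enforced: for even k a k-mer can equal its own reverse complement,
#' making the canonical form ambiguous for palindromes.
#'
#' @param reads Character vector of read sequences (see
#'   [read_fastq_reads()]), or a path to a FASTQ(.gz) file.
#' @param k K-mer length; odd, between 11 and 31 (default 21, the de facto
#'   standard for genome profiling).
#' @return An object of class `kmer_spectrum`: list with `k`, `histogram`
#'   (data.frame: `multiplicity`, `count` of distinct canonical k-mers) and
#'   `total_instances`.
#' @export
count_canonical_kmers <- function(reads, k = 21L) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop2("k must be odd (palindromic k-mers have no ",
                           "unambiguous canonical form for even k)")
  if (k < 11L || k > 31L) stop2("k must be in [11, 31]")
  if (length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq_reads(reads)
  }
  h <- cpp_kmer_histogram(reads, k)
  new_kmer_spectrum(k, data.frame(multiplicity = h$multiplicity,
                                  count = h$count),
                    h$total_instances)
}

new_kmer_spectrum <- function(k, histogram, total_instances) {
  structure(list(k = k, histogram = histogram,
                 total_instances = total_instances),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("kmer_spectrum: k=%s, %.0f instances, %.0f distinct k-mers\n",
              ifelse(is.na(x$k), "?", x$k), x$total_instances,
              sum(x$histogram$count)))
  invisible(x)
}

#' @export
plot.kmer_spectrum <- function(x, xlim = NULL, ...) {
  h <- x$histogram
  if (is.null(xlim)) {
    cw <- cumsum(h$count) / sum(h$count)
    xlim <- c(1, h$multiplicity[which(cw >= 0.999)[1L]])
  }
  plot(h$multiplicity, h$count, type = "h", xlim = xlim,
       xlab = "k-mer multiplicity", ylab = "distinct k-mers",
       main = sprintf("k-mer spectrum (k=%s)", x$k), ...)
  invisible(x)
}

#' Write / read a k-mer spectrum as 2-column TSV
#'
#' The file layout (multiplicity, distinct count) matches KAT/Jellyfish
#' histogram output, so externally computed histograms can be imported.
#'
#' @param spectrum A `kmer_spectrum`.
#' @param path File path.
#' @param k K value to attach on import (unknown, `NA`, by default).
#' @return `write_kmer_histogram`: the path; `import_kmer_histogram`: a
#'   `kmer_spectrum`.
#' @export
write_kmer_histogram <- function(spectrum, path) {
  data.table::fwrite(spectrum$histogram, path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_kmer_histogram
#' @export
import_kmer_histogram <- function(path, k = NA_integer_) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("multiplicity", "count"))
  dt <- as.data.frame(dt)
  new_kmer_spectrum(k, dt, sum(dt$multiplicity * dt$count))
}

#' Detect peaks in a k-mer spectrum
#'
#' The histogram is smoothed with a width-3 centered moving average. The
#' error threshold is the multiplicity of the first local minimum — the
#' valley between the low-multiplicity error shoulder and the genomic
#' peaks. Spectra from error-free reads have no error shoulder; if the
#' smoothed histogram rises from the start but still has an interior
#' maximum, the threshold is 0. Peaks are local maxima above the threshold
#' whose height reaches 5% of the tallest such maximum (ripple
#' suppression). The haploid coverage is the multiplicity of the
#' highest-multiplicity major peak, so a heterozygous half-coverage peak is
#' not mistaken for the homozygous peak; the genome size estimate is the
#' number of k-mer instances above the threshold divided by that coverage.
#'
#' @param spectrum A `kmer_spectrum`.
#' @param min_peak_frac Minimum peak height as a fraction of the tallest
#'   above-threshold maximum (default 0.05).
#' @return An object of class `spectrum_peaks`: list with
#'   `error_threshold`, `peaks` (data.frame: multiplicity, height),
#'   `haploid_coverage`, `genome_size_estimate`, `n_peaks`,
#'   `undiagnosable`.
#' @export
detect_spectrum_peaks <- function(spectrum, min_peak_frac = 0.05) {
  h <- spectrum$histogram
  if (!nrow(h)) stop2("empty k-mer histogram")
  m_max <- max(h$multiplicity)
  dense <- numeric(m_max)
  dense[h$multiplicity] <- h$count
  s <- sma3(dense)
  n <- length(s)

  undiag <- function() {
    structure(list(error_threshold = NA_integer_,
                   peaks = data.frame(multiplicity = integer(),
                                      height = numeric()),
                   haploid_coverage = NA_real_,
                   genome_size_estimate = NA_real_,
                   n_peaks = 0L, undiagnosable = TRUE),
              class = "spectrum_peaks")
  }
  if (n < 3L) return(undiag())

  # first local minimum (error valley); plateaus resolve to their start
  thr <- 0L
  found_min <- FALSE
  for (m in 2:(n - 1L)) {
    if (s[m] <= s[m - 1L] && s[m] < s[m + 1L]) {
      thr <- m; found_min <- TRUE; break
    }
  }
  # interior maxima above the threshold
  cand <- integer(0)
  lo <- max(2L, thr + 1L)
  if (lo <= n - 1L) {
    for (m in lo:(n - 1L)) {
      if (s[m] >= s[m - 1L] && s[m] > s[m + 1L]) cand <- c(cand, m)
    }
  }
  if (n >= 2L && s[n] > s[n - 1L]) cand <- c(cand, n)
  if (!length(cand)) return(undiag())
  if (!found_min) thr <- 0L

  tallest <- max(s[cand])
  cand <- cand[s[cand] >= min_peak_frac * tallest]
  peaks <- data.frame(multiplicity = cand, height = s[cand])
  hap_cov <- max(peaks$multiplicity)
  instances <- sum(as.numeric(h$multiplicity[h$multiplicity > thr]) *
                     h$count[h$multiplicity > thr])
  structure(list(error_threshold = as.integer(thr), peaks = peaks,
                 haploid_coverage = as.numeric(hap_cov),
                 genome_size_estimate = instances / hap_cov,
                 n_peaks = nrow(peaks), undiagnosable = FALSE),
            class = "spectrum_peaks")
}

#' @export
print.spectrum_peaks <- function(x, ...) {
  if (x$undiagnosable) {
    cat("spectrum_peaks: undiagnosable (no interior maximum)\n")
  } else {
    cat(sprintf(
      "spectrum_peaks: %d peak(s) at {%s}; error threshold %d;\n  haploid coverage %.0f; genome size estimate %.3g bp\n",
      x$n_peaks, paste(x$peaks$multiplicity, collapse = ", "),
      x$error_threshold, x$haploid_coverage, x$genome_size_estimate))
  }
  invisible(x)
}

#' Classify a k-mer spectrum by its peak structure
#'
#' One peak indicates a haploid or fully homozygous genome; two peaks with
#' a multiplicity ratio near 2 indicate a heterozygous diploid (the
#' half-coverage peak carries the heterozygous k-mers); anything else is
#' flagged as a complex multi-peak architecture.
#'
#' @param peaks A `spectrum_peaks` object.
#' @param ratio_band Acceptable high/low multiplicity ratio for the
#'   diploid-like call (default `c(1.6, 2.4)`).
#' @return One of `"haploid-or-homozygous"`, `"heterozygous-diploid-like"`,
#'   `"multi-peak-complex"`, `"undiagnosable"`.
#' @export
classify_spectrum <- function(peaks, ratio_band = c(1.6, 2.4)) {
  if (peaks$undiagnosable || peaks$n_peaks == 0L) return("undiagnosable")
  if (peaks$n_peaks == 1L) return("haploid-or-homozygous")
  if (peaks$n_peaks == 2L) {
    m <- sort(peaks$peaks$multiplicity)
    r <- m[2] / m[1]
    if (r >= ratio_band[1] && r <= ratio_band[2]) {
      return("heterozygous-diploid-like")
    }
  }
  "multi-peak-complex"
}
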