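#' Tile scaffolds into fixed-length windows
#'
#' Produces a non-overlapping tiling of every scaffold into windows of
#' `window_size` bp (0-based, half-open); the last window of each scaffold
#' is truncated at the scaffold end so every base belongs to exactly one
#' window. An optional `step` smaller than `window_size` yields overlapping
#' sliding windows.
#'
#' @param assembly An `assembly`.
#' @param window_size Window length in bp (default 1000; must be >= 100,
#'   smaller windows give degenerate statistics).
#' @param step Step between window starts (default `window_size`).
#' @return A data.frame of class `genome_windows` with columns `scaffold`,
#'   `start`, `end`, `gc_fraction`, and empty statistic columns
#'   `snp_count`, `mean_depth` to be filled by [window_stats()].
#' @export
tile_windows <- function(assembly, window_size = 1000L, step = window_size) {
  if (window_size < 100L) {
    stop2("window_size must be >= 100 bp (got ", window_size, ")")
  }
  if (step < 1L || step > window_size) {
    stop2("step must be in [1, window_size]")
  }
  pieces <- lapply(assembly$ids, function(sc) {
    len <- assembly$lengths[[sc]]
    starts <- seq.int(0L, max(0L, len - 1L), by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + window_size, len)
    gc <- window_gc(assembly$seqs[[sc]], starts, ends)
    data.frame(scaffold = sc, start = as.integer(starts),
               end = as.integer(ends), gc_fraction = gc,
               snp_count = NA_integer_, mean_depth = NA_real_,
               stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, pieces)
  rownames(win) <- NULL
  structure(win, class = c("genome_windows", "data.frame"),
            window_size = as.integer(window_size), step = as.integer(step))
}

# per-window GC over non-N bases via cumulative counts
window_gc <- function(seq, starts, ends) {
  r <- charToRaw(seq)
  is_gc <- cumsum(r == as.raw(71L) | r == as.raw(67L))   # G, C
  is_n <- cumsum(r == as.raw(78L))                        # N
  gc <- (at0(is_gc, ends) - at0(is_gc, starts))
  nn <- (ends - starts) - (at0(is_n, ends) - at0(is_n, starts))
  ifelse(nn > 0, gc / nn, NA_real_)
}

# cumulative-sum lookup allowing index 0
at0 <- function(cs, i) ifelse(i == 0L, 0, cs[pmax(i, 1L)] * (i > 0L))

#' Fill SNP and coverage statistics into a window tiling
#'
#' For each window, counts SNPs with `start <= pos0 < end` and averages the
#' per-base depth over the window. Windows with no SNPs or no coverage get
#' zeros.
#'
#' @param windows Output of [tile_windows()].
#' @param variants A `variant_table` (may be empty).
#' @param depth A `depth_track` (scaffolds absent from it count as depth 0).
#' @return The windows data.frame with `snp_count` and `mean_depth` filled.
#' @export
window_stats <- function(windows, variants = NULL, depth = NULL) {
  rec <- if (is.null(variants)) empty_snp_records() else variants$records
  unknown <- setdiff(unique(rec$scaffold), unique(windows$scaffold))
  if (length(unknown)) stop2("variants reference scaffold outside tiling: ",
                             unknown[1L])
  windows$snp_count <- 0L
  windows$mean_depth <- 0
  for (sc in unique(windows$scaffold)) {
    wi <- which(windows$scaffold == sc)
    starts <- windows$start[wi]
    ends <- windows$end[wi]
    pos <- rec$pos0[rec$scaffold == sc]
    if (length(pos)) {
      idx <- findInterval(pos, starts)                 # windows are sorted
      ok <- idx >= 1L & pos < ends[pmax(idx, 1L)]
      windows$snp_count[wi] <- tabulate(idx[ok], nbins = length(wi))
    }
    d <- depth[[sc]]
    if (!is.null(d) && length(d)) {
      cs <- cumsum(as.numeric(d))
      windows$mean_depth[wi] <-
        (at0(cs, ends) - at0(cs, starts)) / (ends - starts)
    }
  }
  windows
}

#' Per-scaffold summaries: length, mean depth, SNP density, GC
#'
#' SNP density is reported in SNPs per kbp, so a density of 30 on a
#' scaffold corresponds to ~3% per-site heterozygosity.
#'
#' @param assembly An `assembly`.
#' @param variants A `variant_table` (optional).
#' @param depth A `depth_track` (optional).
#' @return A data.frame of class `scaffold_summary` with columns
#'   `scaffold`, `length`, `mean_depth`, `n_snps`, `snp_density`,
#'   `gc_fraction`.
#' @export
scaffold_summaries <- function(assembly, variants = NULL, depth = NULL) {
  rec <- if (is.null(variants)) empty_snp_records() else variants$records
  n_snps <- vapply(assembly$ids,
                   function(sc) sum(rec$scaffold == sc), integer(1L))
  mean_depth <- vapply(assembly$ids, function(sc) {
    d <- depth[[sc]]
    if (is.null(d) || !length(d)) 0 else mean(d)
  }, numeric(1L))
  out <- data.frame(scaffold = assembly$ids,
                    length = as.integer(assembly$lengths),
                    mean_depth = mean_depth,
                    n_snps = n_snps,
                    snp_density = 1000 * n_snps / as.numeric(assembly$lengths),
                    gc_fraction = as.numeric(assembly$gc_fraction),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("scaffold_summary", "data.frame"))
}

#' Partition an assembly by a minimum scaffold length
#'
#' Very short scaffolds add noise to windowed and per-scaffold statistics;
#' this splits the assembly into kept (length >= `min_length`) and dropped
#' parts. The boundary is inclusive: a scaffold exactly `min_length` long
#' is kept.
#'
#' @param assembly An `assembly`.
#' @param min_length Minimum length in bp (default 1000).
#' @return A list with `kept` and `dropped` assemblies (either may have
#'   zero scaffolds). Warns when nothing is kept.
#' @export
filter_short_scaffolds <- function(assembly, min_length = 1000L) {
  if (min_length < 0L) stop2("min_length must be >= 0")
  keep <- assembly$lengths >= min_length
  if (!any(keep)) {
    warning("no scaffold reaches min_length = ", min_length, call. = FALSE)
  }
  subset0 <- function(sel) {
    if (!any(sel)) {
      structure(list(ids = character(), seqs = character(),
                     lengths = integer(), gc_fraction = numeric(),
                     total_length = 0), class = "assembly")
    } else {
      new_assembly(assembly$seqs[sel])
    }
  }
  list(kept = subset0(keep), dropped = subset0(!keep))
}

#' Export windows as a BED-compatible TSV
#'
#' Columns: scaffold, start (0-based), end (exclusive), then statistics.
#' A commented header line names the columns.
#'
#' @param windows A `genome_windows` data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_windows_tsv <- function(windows, path) {
  write_commented_tsv(as.data.frame(windows), path)
}

# TSV writer with "#"-prefixed header, used for all tabular outputs
write_commented_tsv <- function(df, path) {
  writeLines(paste0("#", paste(names(df), collapse = "\t")), path)
  if (nrow(df)) {
    data.table::fwrite(df, path, sep = "\t", col.names = FALSE,
                       append = TRUE)
  }
  invisible(path)
}
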