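#' Read a genome assembly from FASTA
#'
#' Reads a multi-record FASTA file into an `assembly` object. Sequence
#' identifiers are the first whitespace-delimited token of each header;
#' sequences are case-folded to upper case. Only `A`, `C`, `G`, `T` and `N`
#' are accepted. GC fraction is computed over non-N bases and is `NA`
#' (flagged undefined) for all-N scaffolds.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `assembly`: a list with `ids`, `seqs` (named
#'   upper-case character vector), `lengths`, `gc_fraction` (named, `NA`
#'   when undefined) and `total_length`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGT"), fa)
#' a <- read_assembly_fasta(fa)
#' a$gc_fraction  # 0.5
#' @export
read_assembly_fasta <- function(path) {
  if (!file.exists(path)) stop2("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop2("duplicate scaffold id in FASTA: ", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L)) {
    stop2("empty sequence for scaffold: ", ids[nchar(seqs) == 0L][1L])
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop2("scaffold ", ids[bad][1L],
          " contains characters outside {A,C,G,T,N}")
  }
  new_assembly(seqs)
}

# construct an assembly from a named character vector of sequences
new_assembly <- function(seqs) {
  stopifnot(!is.null(names(seqs)))
  dss <- Biostrings::DNAStringSet(seqs)
  lens <- Biostrings::width(dss)
  lf <- Biostrings::letterFrequency(dss, letters = c("G", "C", "N"))
  non_n <- lens - lf[, "N"]
  gc <- ifelse(non_n > 0, (lf[, "G"] + lf[, "C"]) / non_n, NA_real_)
  structure(
    list(ids = names(seqs), seqs = seqs,
         lengths = stats::setNames(as.integer(lens), names(seqs)),
         gc_fraction = stats::setNames(as.numeric(gc), names(seqs)),
         total_length = sum(as.numeric(lens))),
    class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("assembly: %d scaffolds, %.0f bp total, global GC %.4f\n",
              length(x$ids), x$total_length, assembly_gc(x)))
  invisible(x)
}

# global GC over all non-N bases, pooled across scaffolds
assembly_gc <- function(assembly) {
  dss <- Biostrings::DNAStringSet(assembly$seqs)
  lf <- Biostrings::letterFrequency(dss, letters = c("G", "C", "N"))
  non_n <- sum(assembly$lengths) - sum(lf[, "N"])
  if (non_n == 0) return(NA_real_)
  (sum(lf[, "G"]) + sum(lf[, "C"])) / non_n
}

#' Write an assembly to FASTA
#'
#' @param assembly An `assembly` object.
#' @param path Output file path.
#' @param width Line width for wrapping sequences.
#' @return The path, invisibly.
#' @export
write_assembly_fasta <- function(assembly, path, width = 70L) {
  dss <- Biostrings::DNAStringSet(assembly$seqs)
  names(dss) <- assembly$ids
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

# keep a subset of scaffolds, preserving order
assembly_subset <- function(assembly, ids) {
  new_assembly(assembly$seqs[assembly$ids[assembly$ids %in% ids]])
}

#' Read biallelic SNPs with allele depths from a VCF
#'
#' Parses a VCF 4.x file and keeps biallelic SNPs (single-base REF, exactly
#' one single-base ALT) whose `AD`-derived total depth reaches
#' `min_total_depth`. Positions are converted to the package's 0-based
#' convention (`pos0 = POS - 1`). Multiallelic sites, indels, low-depth
#' records and duplicated positions are dropped and counted in
#' `n_excluded`.
#'
#' @param path Path to a VCF file.
#' @param sample Which sample column to use (1-based; default the first).
#' @param min_total_depth Minimum `ref_depth + alt_depth` for a record to be
#'   kept (default 10; allele-balance fractions are unstable below this).
#' @param assembly Optional `assembly`; when supplied, every VCF scaffold
#'   must exist in it and every kept record's REF base must match the
#'   assembly base at `pos0`.
#' @return An object of class `variant_table`: list with `records` (a
#'   data.frame with columns scaffold, pos0, ref, alt, ref_depth,
#'   alt_depth, sorted by scaffold then pos0) and `n_excluded`.
#' @export
read_variants_vcf <- function(path, sample = 1L, min_total_depth = 10L,
                              assembly = NULL) {
  if (!file.exists(path)) stop2("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(new_variant_table(empty_snp_records(), 0L))
  }
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < sample + 1L) {
    stop2("VCF has no sample column ", sample)
  }
  fmt_has_ad <- grepl("(^|:)AD(:|$)", gt[, 1L])
  if (!all(fmt_has_ad)) {
    stop2("AD field missing from FORMAT in VCF: ", path)
  }
  ad <- vcfR::extract.gt(v, element = "AD")[, sample]
  chrom <- fix$CHROM
  pos0 <- as.integer(fix$POS) - 1L
  ref <- fix$REF
  alt <- fix$ALT

  biallelic_snp <- nchar(ref) == 1L & !grepl(",", alt, fixed = TRUE) &
    nchar(alt) == 1L & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  ad_parts <- strsplit(ifelse(is.na(ad), "", ad), ",", fixed = TRUE)
  ref_depth <- suppressWarnings(as.integer(vapply(
    ad_parts, function(p) if (length(p) >= 1L) p[1L] else NA_character_,
    character(1L))))
  alt_depth <- suppressWarnings(as.integer(vapply(
    ad_parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_,
    character(1L))))
  has_ad <- !is.na(ref_depth) & !is.na(alt_depth)
  deep_enough <- has_ad & (ref_depth + alt_depth >= min_total_depth)
  keep <- biallelic_snp & deep_enough
  n_excluded <- sum(!keep)

  rec <- data.frame(scaffold = chrom[keep], pos0 = pos0[keep],
                    ref = ref[keep], alt = alt[keep],
                    ref_depth = ref_depth[keep], alt_depth = alt_depth[keep],
                    stringsAsFactors = FALSE)
  # drop duplicated positions (first occurrence wins)
  dup <- duplicated(rec[c("scaffold", "pos0")])
  n_excluded <- n_excluded + sum(dup)
  rec <- rec[!dup, , drop = FALSE]

  scaff_order <- if (!is.null(assembly)) assembly$ids else unique(chrom)
  if (!is.null(assembly)) {
    unknown <- setdiff(unique(rec$scaffold), assembly$ids)
    if (length(unknown)) {
      stop2("VCF scaffold absent from assembly: ", unknown[1L])
    }
    out_of_range <- rec$pos0 >= assembly$lengths[rec$scaffold]
    if (any(out_of_range)) {
      stop2("VCF position beyond scaffold end on ",
            rec$scaffold[out_of_range][1L])
    }
    obs <- substring(assembly$seqs[rec$scaffold], rec$pos0 + 1L,
                     rec$pos0 + 1L)
    if (any(obs != rec$ref)) {
      i <- which(obs != rec$ref)[1L]
      stop2("REF mismatch at ", rec$scaffold[i], ":", rec$pos0[i] + 1L,
            " (VCF ", rec$ref[i], ", assembly ", obs[i], ")")
    }
  }
  rec <- rec[order(match(rec$scaffold, scaff_order), rec$pos0), ,
             drop = FALSE]
  rownames(rec) <- NULL
  new_variant_table(rec, n_excluded)
}

empty_snp_records <- function() {
  data.frame(scaffold = character(), pos0 = integer(), ref = character(),
             alt = character(), ref_depth = integer(), alt_depth = integer(),
             stringsAsFactors = FALSE)
}

new_variant_table <- function(records, n_excluded) {
  structure(list(records = records, n_excluded = as.integer(n_excluded)),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d biallelic SNPs (%d records excluded)\n",
              nrow(x$records), x$n_excluded))
  invisible(x)
}

#' Read per-base depth from a samtools-depth style TSV
#'
#' Expects three tab-separated columns: scaffold, 1-based position, depth.
#' Produces dense 0-indexed per-base arrays; positions absent from the
#' input get depth 0.
#'
#' @param path Path to the TSV (may be empty).
#' @param assembly An `assembly` defining scaffold ids and lengths.
#' @return An object of class `depth_track`: a named list of integer
#'   vectors, one per scaffold, each of length equal to the scaffold.
#' @export
read_depth_table <- function(path, assembly) {
  if (!file.exists(path)) stop2("depth file not found: ", path)
  track <- lapply(assembly$lengths, function(n) integer(n))
  if (file.size(path) > 0L) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            col.names = c("scaffold", "pos", "depth"),
                            colClasses = list(character = 1L))
    unknown <- setdiff(unique(dt$scaffold), assembly$ids)
    if (length(unknown)) stop2("depth scaffold absent from assembly: ",
                               unknown[1L])
    if (any(dt$depth < 0)) stop2("negative depth in ", path)
    lens <- assembly$lengths[dt$scaffold]
    if (any(dt$pos < 1L | dt$pos > lens)) {
      i <- which(dt$pos < 1L | dt$pos > lens)[1L]
      stop2("depth position out of bounds: ", dt$scaffold[i], ":",
            dt$pos[i])
    }
    for (sc in unique(dt$scaffold)) {
      sel <- dt$scaffold == sc
      track[[sc]][dt$pos[sel]] <- as.integer(dt$depth[sel])
    }
  }
  structure(track, class = "depth_track")
}

#' Write a depth track as a samtools-depth style TSV
#'
#' @param depth A `depth_track`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_depth_table <- function(depth, path) {
  dts <- lapply(names(depth), function(sc) {
    data.table::data.table(scaffold = sc, pos = seq_along(depth[[sc]]),
                           depth = depth[[sc]])
  })
  data.table::fwrite(data.table::rbindlist(dts), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read sequences from a FASTQ file
#'
#' Accepts plain or gzipped FASTQ; returns upper-cased read sequences.
#' Quality lines are parsed (the format requires them) but not used.
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @return Character vector of read sequences.
#' @export
read_fastq_reads <- function(path) {
  if (!file.exists(path)) stop2("FASTQ file not found: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path, format = "fastq"),
                 error = function(e) stop2("malformed FASTQ (", path, "): ",
                                           conditionMessage(e)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  n_lines <- 0L
  while (length(chunk <- readLines(con, n = 262144L))) {
    n_lines <- n_lines + length(chunk)
  }
  close(con)
  if (n_lines %% 4L != 0L || n_lines %/% 4L != length(ss)) {
    stop2("malformed FASTQ (", path, "): ", n_lines,
          " lines is not 4 per record")
  }
  unname(toupper(as.character(ss)))
}

#' Write reads to FASTQ
#'
#' @param reads Character vector of sequences.
#' @param path Output path (plain text; `.gz` suffix writes gzip).
#' @param ids Optional read names (default `read_1..n`).
#' @return The path, invisibly.
#' @export
write_fastq_reads <- function(reads, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("read_", seq_along(reads))
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1L))
  lines <- as.vector(rbind(paste0("@", ids), reads, "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
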