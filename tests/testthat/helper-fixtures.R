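# shared fixtures and independent oracles, all built in code at test time

write_tmp_fasta <- function(..., path = tempfile(fileext = ".fa")) {
  seqs <- c(...)
  lines <- as.vector(rbind(paste0(">", names(seqs)), seqs))
  writeLines(lines, path)
  path
}

# minimal VCF writer for hand-built records; rows are character vectors of
# (CHROM, POS, REF, ALT, AD) with AD like "12,10"
write_tmp_vcf <- function(rows, contigs = NULL, format = "GT:AD:DP",
                          path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              if (!is.null(contigs))
                sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                        contigs),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1")
  body <- vapply(rows, function(r) {
    ad <- r[5]
    dp <- sum(as.integer(strsplit(ad, ",")[[1]]))
    sample_field <- paste(c("0/1", ad, dp)[match(strsplit(format, ":")[[1]],
                                                 c("GT", "AD", "DP"))],
                          collapse = ":")
    paste(r[1], r[2], ".", r[3], r[4], ".", "PASS", ".", format,
          sample_field, sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

write_tmp_depth <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# brute-force canonical k-mer histogram: plain substring dictionary count,
# independent of the compiled counter
oracle_kmer_histogram <- function(reads, k) {
  kmers <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) return(character(0))
    substring(r, 1:(n - k + 1), k:n)
  }))
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (!length(kmers)) {
    return(data.frame(multiplicity = integer(), count = numeric()))
  }
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  canon <- ifelse(kmers <= rc, kmers, rc)
  mult_per_kmer <- table(canon)
  h <- table(as.integer(mult_per_kmer))
  data.frame(multiplicity = as.integer(names(h)),
             count = as.numeric(h))
}

# small in-memory scenario bundle for fast tests
quick_scenario <- function(label, seed, genome_size = 1.2e5,
                           n_scaffolds = 6L, ...) {
  sc <- scenario(label, seed, genome_size = genome_size,
                 n_scaffolds = n_scaffolds, ...)
  g <- simulate_genome(sc)
  vd <- simulate_variants_and_depth(g$assembly, g$truth, sc)
  list(sc = sc, assembly = g$assembly, variants = vd$variants,
       depth = vd$depth, truth = vd$truth)
}

# hand-built spectrum from a dense count vector (index = multiplicity)
new_spectrum_for_test <- function(counts, k = 21L) {
  keep <- counts > 0
  ploidyscan:::new_kmer_spectrum(
    k,
    data.frame(multiplicity = seq_along(counts)[keep],
               count = counts[keep]),
    sum(seq_along(counts)[keep] * counts[keep]))
}

# window-sized allele-fraction sample with planted ploidy at given coverage
planted_fractions <- function(hypothesis, n, coverage = 100L) {
  p <- switch(hypothesis, diploid = 0.5, triploid = c(1 / 3, 2 / 3),
              tetraploid = c(1 / 4, 1 / 2, 3 / 4))
  pr <- sample(p, n, replace = TRUE)
  stats::rbinom(n, coverage, pr) / coverage
}
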