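# Planted-truth scenario simulator. Every analysis module can be exercised
# on bundles produced here, with ground truth recorded for scoring.

SCENARIO_LABELS <- c("haploid", "diploid_het", "triploid", "aneuploid",
                     "hemidiploid", "hybrid_high_het", "contaminated")

#' Define a synthetic genome scenario
#'
#' Builds the parameter set for one of the planted genome architectures.
#' Label defaults (documented in the methods vignette) emulate the
#' archetypes the diagnostics are meant to separate:
#'
#' * `haploid` — no heterozygosity, 30x.
#' * `diploid_het` — 1% heterozygosity, balanced alleles, 60x total.
#' * `triploid` — 1% heterozygosity, allele fractions 1/3 or 2/3, 100x.
#' * `aneuploid` — diploid baseline at 60x; half the scaffolds carry a
#'   third copy (coverage multiplier 1.5, triploid allele fractions).
#' * `hemidiploid` — half the scaffolds SNP-free at doubled coverage
#'   (collapsed homozygous-diploid regions), half heterozygous-diploid at
#'   baseline 30x; GC 0.326 (very low, below the 35% warning threshold).
#' * `hybrid_high_het` — diploid with extreme 3% heterozygosity, 60x.
#' * `contaminated` — diploid_het plus ~10% alien scaffolds at GC 0.65 and
#'   0.2x relative coverage with no heterozygosity.
#'
#' @param label One of the supported scenario labels.
#' @param seed Mandatory integer seed; all emitted files are deterministic
#'   functions of (label, seed, parameters).
#' @param genome_size Total assembly length in bp (default 1e6).
#' @param n_scaffolds Number of scaffolds (default 20; 100 for the
#'   scaffold-population scenarios aneuploid/hemidiploid/contaminated).
#' @param gc_target Genome GC fraction (label-specific default).
#' @param heterozygosity Heterozygous sites per bp (label default).
#' @param base_coverage Baseline total read depth (label default).
#' @param error_rate Per-base sequencing error rate for simulated reads
#'   (default 0).
#' @param read_length Simulated read length (default 100).
#' @return An object of class `scenario` (named parameter list).
#' @export
scenario <- function(label, seed, genome_size = NULL, n_scaffolds = NULL,
                     gc_target = NULL, heterozygosity = NULL,
                     base_coverage = NULL, error_rate = 0,
                     read_length = 100L) {
  if (!label %in% SCENARIO_LABELS) {
    stop2("unknown scenario label: ", label, " (known: ",
          paste(SCENARIO_LABELS, collapse = ", "), ")")
  }
  if (missing(seed) || is.null(seed)) stop2("seed is mandatory")
  def <- switch(label,
    haploid         = list(gc = 0.50, het = 0,    cov = 30,  nsc = 20L),
    diploid_het     = list(gc = 0.50, het = 0.01, cov = 60,  nsc = 20L),
    triploid        = list(gc = 0.50, het = 0.01, cov = 100, nsc = 20L),
    aneuploid       = list(gc = 0.50, het = 0.01, cov = 60,  nsc = 100L),
    hemidiploid     = list(gc = 0.326, het = 0.01, cov = 30, nsc = 100L),
    hybrid_high_het = list(gc = 0.50, het = 0.03, cov = 60,  nsc = 20L),
    contaminated    = list(gc = 0.50, het = 0.01, cov = 60,  nsc = 100L))
  p <- list(label = label, seed = as.integer(seed),
            genome_size = as.numeric(genome_size %||% 1e6),
            n_scaffolds = as.integer(n_scaffolds %||% def$nsc),
            gc_target = gc_target %||% def$gc,
            heterozygosity = heterozygosity %||% def$het,
            base_coverage = base_coverage %||% def$cov,
            error_rate = error_rate, read_length = as.integer(read_length),
            contaminant_gc = 0.65, contaminant_cov_mult = 0.2)
  if (p$heterozygosity < 0 || p$heterozygosity > 0.1) {
    stop2("heterozygosity must be in [0, 0.1]")
  }
  if (p$base_coverage < 1) stop2("base_coverage must be >= 1")
  structure(p, class = "scenario")
}

# per-scaffold architecture implied by the label:
# copy_mult scales total coverage; ploidy_state picks allele fractions
scenario_architecture <- function(sc) {
  n <- sc$n_scaffolds
  ids <- sprintf("scf_%03d", seq_len(n))
  mult <- rep(1, n)
  state <- switch(sc$label,
    haploid = rep("haploid", n),
    diploid_het = rep("diploid", n),
    triploid = rep("triploid", n),
    hybrid_high_het = rep("diploid", n),
    aneuploid = rep("diploid", n),
    hemidiploid = rep("diploid", n),
    contaminated = rep("diploid", n))
  het <- rep(sc$heterozygosity, n)
  contaminant <- rep(FALSE, n)
  if (sc$label == "aneuploid") {
    tri <- seq_len(n) %% 2L == 0L  # alternate: half the scaffolds trisomic
    state[tri] <- "triploid"
    mult[tri] <- 1.5
  }
  if (sc$label == "hemidiploid") {
    hap <- seq_len(n) %% 2L == 0L  # collapsed homozygous-diploid half
    state[hap] <- "haploid"
    het[hap] <- 0
    mult[hap] <- 2
  }
  if (sc$label == "contaminated") {
    n_alien <- max(1L, round(0.1 * n))
    alien <- seq_len(n) > (n - n_alien)
    contaminant[alien] <- TRUE
    state[alien] <- "haploid"
    het[alien] <- 0
    mult[alien] <- sc$contaminant_cov_mult
  }
  data.frame(scaffold = ids, copy_mult = mult, ploidy_state = state,
             het_rate = het, contaminant = contaminant,
             stringsAsFactors = FALSE)
}

#' Simulate a genome assembly for a scenario
#'
#' Bases are i.i.d. with `P(G or C) = gc_target` (contaminant scaffolds use
#' their own GC); scaffold lengths are drawn log-uniform in \[5 kb, 200 kb\]
#' and rescaled to `genome_size` (minimum 1.5 kb after rescaling).
#'
#' @param sc A `scenario`.
#' @return List with `assembly` and `truth` (per-scaffold architecture
#'   plus realized global values).
#' @export
simulate_genome <- function(sc) {
  if (sc$genome_size < 5e4) stop2("genome_size must be >= 50 kb")
  arch <- scenario_architecture(sc)
  n <- nrow(arch)
  with_seed(child_seed(sc$seed, 1L), {
    raw <- exp(stats::runif(n, log(5e3), log(2e5)))
    lens <- pmax(1500L, as.integer(round(raw * sc$genome_size / sum(raw))))
    # reconcile the rounding/floor drift against the requested size by
    # adjusting the largest scaffolds (never below the 1500 bp floor)
    drift <- as.integer(sc$genome_size - sum(lens))
    while (drift != 0L) {
      i <- which.max(lens)
      step <- if (drift > 0L) drift else -min(-drift, lens[i] - 1500L)
      lens[i] <- lens[i] + step
      drift <- drift - step
      if (step == 0L) break  # everything at the floor; accept the drift
    }
    seqs <- vapply(seq_len(n), function(i) {
      gc <- if (arch$contaminant[i]) sc$contaminant_gc else sc$gc_target
      paste(sample(c("A", "T", "G", "C"), lens[i], replace = TRUE,
                   prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
            collapse = "")
    }, character(1L))
    names(seqs) <- arch$scaffold
    assembly <- new_assembly(seqs)
    truth <- list(scenario = unclass(sc), architecture = arch,
                  genome_size = assembly$total_length,
                  gc_target = sc$gc_target,
                  realized_gc = assembly_gc(assembly))
    list(assembly = assembly, truth = truth)
  })
}

# ideal allele fractions available to each ploidy state
state_fractions <- function(state) {
  switch(state,
         haploid = numeric(0),
         diploid = 0.5,
         triploid = c(1 / 3, 2 / 3),
         tetraploid = c(1 / 4, 1 / 2, 3 / 4))
}

#' Simulate variants and per-base depth for a scenario
#'
#' Heterozygous sites are placed uniformly at each scaffold's rate; site
#' total depth is Poisson(base_coverage x copy multiplier) and the
#' alternative depth binomial at the true allele fraction of the
#' scaffold's ploidy state. Per-base depth is Poisson at the same rate.
#'
#' @param assembly Assembly from [simulate_genome()].
#' @param truth Truth from [simulate_genome()]; updated and returned.
#' @param sc The `scenario`.
#' @return List with `variants` (a `variant_table`), `depth` (a
#'   `depth_track`) and augmented `truth` (`sites` table of true per-site
#'   fractions).
#' @export
simulate_variants_and_depth <- function(assembly, truth, sc) {
  arch <- truth$architecture
  with_seed(child_seed(sc$seed, 2L), {
    site_rows <- list()
    depth <- list()
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(nrow(arch))) {
      scf <- arch$scaffold[i]
      len <- assembly$lengths[[scf]]
      lambda <- sc$base_coverage * arch$copy_mult[i]
      depth[[scf]] <- stats::rpois(len, lambda)
      fr <- state_fractions(arch$ploidy_state[i])
      n_sites <- stats::rbinom(1L, len, arch$het_rate[i])
      if (n_sites == 0L || !length(fr)) next
      pos0 <- sort(sample.int(len, n_sites)) - 1L
      ref <- substring(assembly$seqs[[scf]], pos0 + 1L, pos0 + 1L)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L),
                    character(1L), USE.NAMES = FALSE)
      f_true <- sample(fr, n_sites, replace = TRUE)
      total <- stats::rpois(n_sites, lambda)
      keep <- total > 0L
      alt_d <- stats::rbinom(sum(keep), total[keep], f_true[keep])
      site_rows[[scf]] <- data.frame(
        scaffold = scf, pos0 = pos0[keep], ref = ref[keep],
        alt = alt[keep], ref_depth = total[keep] - alt_d,
        alt_depth = alt_d, f_true = f_true[keep],
        stringsAsFactors = FALSE)
    }
    sites <- if (length(site_rows)) do.call(rbind, site_rows) else
      cbind(empty_snp_records(), f_true = numeric(0))
    rownames(sites) <- NULL
    rec <- sites[, c("scaffold", "pos0", "ref", "alt", "ref_depth",
                     "alt_depth")]
    truth$sites <- sites
    truth$n_planted_snps <- nrow(sites)
    list(variants = new_variant_table(rec, 0L),
         depth = structure(depth, class = "depth_track"),
         truth = truth)
  })
}

#' Simulate reads for a scenario
#'
#' Explicit haplotype sequences are built per scaffold (alternative
#' alleles assigned to haplotypes according to the true per-site
#' fractions) and reads are drawn uniformly from each haplotype so that
#' the expected total per-base coverage is `base_coverage x copy
#' multiplier`. Per-base errors are substituted at `error_rate`.
#'
#' @param assembly Assembly from [simulate_genome()].
#' @param truth Truth including the `sites` table.
#' @param sc The `scenario`.
#' @return Character vector of read sequences.
#' @export
simulate_reads <- function(assembly, truth, sc) {
  arch <- truth$architecture
  L <- sc$read_length
  with_seed(child_seed(sc$seed, 3L), {
    reads <- list()
    for (i in seq_len(nrow(arch))) {
      scf <- arch$scaffold[i]
      len <- assembly$lengths[[scf]]
      if (len < L) next
      cov_total <- sc$base_coverage * arch$copy_mult[i]
      n_hap <- switch(arch$ploidy_state[i], haploid = 1L, diploid = 2L,
                      triploid = 3L, tetraploid = 4L)
      haps <- build_haplotypes(assembly$seqs[[scf]],
                               truth$sites[truth$sites$scaffold == scf, ,
                                           drop = FALSE], n_hap)
      for (h in seq_len(n_hap)) {
        n_reads <- as.integer(round(cov_total / n_hap * len / L))
        if (n_reads == 0L) next
        starts <- sample.int(len - L + 1L, n_reads, replace = TRUE)
        rd <- substring(haps[h], starts, starts + L - 1L)
        if (sc$error_rate > 0) rd <- add_read_errors(rd, sc$error_rate)
        reads[[paste(scf, h)]] <- rd
      }
    }
    unlist(reads, use.names = FALSE)
  })
}

# distribute alt alleles over n_hap haplotype copies of a scaffold so the
# allele dosage matches each site's true fraction
build_haplotypes <- function(seq, sites, n_hap) {
  haps <- rep(seq, n_hap)
  if (!nrow(sites) || n_hap == 1L) return(haps)
  chars <- lapply(seq_len(n_hap), function(h) strsplit(haps[h], "")[[1L]])
  for (s in seq_len(nrow(sites))) {
    n_alt <- round(sites$f_true[s] * n_hap)
    if (n_alt < 1L) next
    carriers <- sample.int(n_hap, n_alt)
    for (h in carriers) chars[[h]][sites$pos0[s] + 1L] <- sites$alt[s]
  }
  vapply(chars, paste, character(1L), collapse = "")
}

# substitute random bases at the given per-base rate
add_read_errors <- function(reads, rate) {
  L <- nchar(reads[1L])
  n_err <- stats::rbinom(1L, length(reads) * L, rate)
  if (n_err == 0L) return(reads)
  ridx <- sample.int(length(reads), n_err, replace = TRUE)
  pidx <- sample.int(L, n_err, replace = TRUE)
  for (e in seq_len(n_err)) {
    old <- substr(reads[ridx[e]], pidx[e], pidx[e])
    substr(reads[ridx[e]], pidx[e], pidx[e]) <-
      sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  reads
}

#' Generate a complete scenario bundle on disk
#'
#' One call produces a self-consistent input set: `genome.fa`,
#' `variants.vcf` (VCF 4.2 with AD), `depth.tsv` (samtools-depth dialect),
#' optionally `reads.fastq`, and `truth.json` recording the planted
#' architecture plus realized (audited) summary values. Identical
#' label+seed produce byte-identical bundles.
#'
#' @param label Scenario label (see [scenario()]).
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @param reads Whether to simulate and write FASTQ reads (default TRUE;
#'   the k-mer module is their only consumer).
#' @param ... Further parameters passed to [scenario()].
#' @return Invisibly, a list with the file paths, the in-memory objects
#'   and the truth (including the audit block).
#' @export
make_scenario <- function(label, seed, out_dir, reads = TRUE, ...) {
  sc <- scenario(label, seed, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- simulate_genome(sc)
  vd <- simulate_variants_and_depth(g$assembly, g$truth, sc)
  truth <- vd$truth

  fa <- file.path(out_dir, "genome.fa")
  vcf <- file.path(out_dir, "variants.vcf")
  dtsv <- file.path(out_dir, "depth.tsv")
  tj <- file.path(out_dir, "truth.json")
  write_assembly_fasta(g$assembly, fa)
  write_scenario_vcf(vd$variants, g$assembly, vcf)
  write_depth_table(vd$depth, dtsv)
  fq <- NULL
  read_seqs <- NULL
  if (reads) {
    fq <- file.path(out_dir, "reads.fastq")
    read_seqs <- simulate_reads(g$assembly, truth, sc)
    write_fastq_reads(read_seqs, fq)
  }

  truth$audit <- audit_scenario(g$assembly, vd$variants, vd$depth, truth, sc)
  truth_out <- truth
  truth_out$sites <- NULL  # per-site table can be large; files carry it
  jsonlite::write_json(truth_out, tj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(list(paths = list(fasta = fa, vcf = vcf, depth = dtsv,
                              fastq = fq, truth = tj),
                 scenario = sc, assembly = g$assembly,
                 variants = vd$variants, depth = vd$depth,
                 reads = read_seqs, truth = truth))
}

# consistency audit: realized files vs planted truth
audit_scenario <- function(assembly, variants, depth, truth, sc) {
  arch <- truth$architecture
  mean_depths <- vapply(arch$scaffold,
                        function(s) mean(depth[[s]]), numeric(1L))
  expected <- sc$base_coverage * arch$copy_mult
  het_bases <- sum(assembly$lengths[arch$scaffold[arch$het_rate > 0]])
  list(realized_gc = assembly_gc(assembly),
       realized_snps = nrow(variants$records),
       expected_snps = sum(as.numeric(assembly$lengths[arch$scaffold]) *
                             arch$het_rate),
       het_bases = het_bases,
       max_depth_rel_error = if (all(expected > 0))
         max(abs(mean_depths - expected) / expected) else NA_real_,
       mean_alt_fraction = if (nrow(variants$records))
         mean(variants$records$alt_depth /
                (variants$records$ref_depth + variants$records$alt_depth))
         else NA_real_)
}

# minimal deterministic VCF 4.2 writer with GT:AD:DP
write_scenario_vcf <- function(variants, assembly, path) {
  rec <- variants$records
  header <- c("##fileformat=VCFv4.2",
              "##source=ploidyscan-simulator",
              sprintf("##contig=<ID=%s,length=%d>", assembly$ids,
                      assembly$lengths),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsim")
  body <- if (nrow(rec)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP\t0/1:%d,%d:%d",
            rec$scaffold, rec$pos0 + 1L, rec$ref, rec$alt,
            rec$ref_depth, rec$alt_depth, rec$ref_depth + rec$alt_depth)
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}
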