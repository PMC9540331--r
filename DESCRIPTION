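Package: ploidyscan
Title: Ploidy, Aneuploidy and Contamination Diagnostics for Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnostic toolkit for genome assemblies of organisms with
    uncertain ploidy. Computes canonical k-mer spectra from reads, windowed
    SNP-density and coverage statistics, allele-balance ("fair coin")
    distributions against a per-site binomial ideal-diploid simulation,
    windowed ploidy likelihood scores from fixed-mean Gaussian mixtures
    (diploid, triploid, tetraploid hypotheses), and a warning report that
    flags polyploidy, aneuploidy, hybridization, contamination and extreme
    GC composition. Includes a planted-truth scenario simulator emitting
    standard FASTA, VCF, per-base depth and FASTQ files, diagnostic plots,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    vcfR,
    data.table,
    jsonlite,
    mclust,
    MASS,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
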