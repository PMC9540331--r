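---
title: "Methods: ploidy and contamination diagnostics from assembly evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ploidy and contamination diagnostics from assembly evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidyscan)
```

# Motivation and scope

Non-model eukaryotes — zygomycete fungi are the archetype — frequently
carry genome architectures that violate the haploid/diploid assumptions
baked into assembly and annotation pipelines: whole-genome polyploidy,
per-chromosome aneuploidy, hybrid genomes with extreme heterozygosity,
hemidiploid mixtures of haploid and collapsed homozygous-diploid regions,
heterokaryosis, and plain contamination. None of these are visible from an
assembly FASTA alone, but all leave characteristic fingerprints in three
cheap data layers: the k-mer spectrum of the reads, the per-base coverage
of the assembly, and the allele balance of heterozygous variant calls.
`ploidyscan` computes those fingerprints and composes them into a report.

The package deliberately stops at the diagnostic layer. It does not wrap
trimmers, assemblers, mappers, variant callers or completeness tools;
their outputs (FASTA, VCF with `AD`, samtools-depth TSV, FASTQ, a mapped
fraction, a BUSCO complete fraction) are its inputs.

All internal coordinates are 0-based and half-open; 1-based VCF and depth
positions are converted once, at the reading boundary, so no off-by-one
arithmetic exists anywhere downstream.

# The k-mer spectrum

Every k-long window of every read contributes one instance of its
canonical form — the lexicographic minimum of the k-mer and its reverse
complement — so the spectrum is strand-independent; windows containing N
are skipped. `k` defaults to 21, the de facto standard for genome
profiling: long enough that random 21-mers are unique in megabase genomes,
short enough to be robust to errors. Odd `k` is enforced because an even-k
k-mer can equal its own reverse complement, making the canonical choice
ambiguous. Counting is compiled (2-bit rolling encoding, one hash table);
the R-level brute-force dictionary count is kept in the test suite as the
independent oracle on small read sets.

Peak detection smooths the multiplicity histogram with a width-3 centered
moving average, then takes the first local minimum as the *error
threshold*: with sequencing errors, erroneous k-mers are mostly unique and
pile up below the valley that separates them from genomic peaks. Spectra
from error-free reads have no error shoulder and hence no local minimum;
in that case, if an interior maximum exists, the threshold is zero and
analysis proceeds — a histogram with no interior maximum at all is flagged
undiagnosable. Peaks are local maxima above the threshold whose smoothed
height reaches 5% of the tallest such maximum (ripple suppression). The
*haploid coverage* is the multiplicity of the highest-multiplicity major
peak, so the half-coverage heterozygous peak of a diploid is never
mistaken for the homozygous peak, and the genome size estimate is the
number of k-mer instances above the threshold divided by that coverage.

One arithmetic subtlety: with read length $L$ and k-mer length $k$, a
genome sequenced at per-base coverage $c$ yields k-mer coverage
$c\,(L-k+1)/L$ — at $L = 100$, $k = 21$, a 30× library peaks at
multiplicity 24, not 30. The spectrum reports multiplicities as observed;
the genome-size estimate is self-consistent because the same factor
appears in numerator and denominator. Classification uses only the peak
*count* and the peak multiplicity *ratio* (two peaks with ratio in
[1.6, 2.4] → heterozygous-diploid-like), both invariant to the factor.

# Windows and scaffold summaries

Scaffolds are tiled into non-overlapping windows (default 1000 bp, the
customary window for this kind of scan; a smaller `step` enables
overlapping windows but defaults off — per-window bars and scores are
easiest to read when each base belongs to exactly one window). The last
window of each scaffold is truncated. Windows below 100 bp are refused:
SNP counts and mean depths over a handful of bases are noise. SNP density
is reported in SNPs/kbp, so density 30 ≡ 3% per-site heterozygosity.
N bases are excluded from GC denominators but count toward window length
and depth averaging. Scaffolds shorter than 1 kbp mostly add noise; the
filter keeps scaffolds exactly at the boundary ("shorter than" is strict).

Conservation invariants — window SNP counts sum to scaffold totals, and
the length-weighted mean of window depths equals the scaffold mean — are
enforced by tests at tolerance 1e-9.

# Allele balance: the fair-coin comparison

At a heterozygous site with total depth $n$, the alternative-read count is
$\mathrm{Binomial}(n, f)$ with $f$ determined by ploidy: $1/2$ for a
diploid, $1/3$ or $2/3$ for a triploid (AAB vs ABB), $1/4$, $1/2$ or
$3/4$ for a tetraploid. Because observed fractions are quantized by finite
coverage, the ideal-diploid reference is built by *per-site simulation*:
for each observed site coverage, draw Binomial(coverage, 0.5) (10
replicates per site by default) — this bakes the exact coverage
distribution of the data into the null.

Sites enter the analysis only if their total depth reaches
`min_total_depth = 10` (set at reading time): allele fractions below that
are dominated by sampling noise, and the ±0.05 modal-classification
tolerance used later needs coverage ≈ 30 to separate 1/2 from 1/3 at all.
Empirical and simulated fractions are binned on 50 shared bins over
[0, 1]; the comparison statistic is the two-sample Kolmogorov–Smirnov
distance — distribution-free, bounded in [0, 1], and computable directly
from the two samples. The empirical mode (after width-3 smoothing of the
binned mass) is classified against {1/4, 1/3, 1/2, 2/3, 3/4} within
±0.05, with the mirrored fractions mapping to the same ploidy; anything
else is "ambiguous". Scaffolds with fewer than 20 usable SNPs are
reported as "insufficient data" rather than classified.

# Windowed ploidy scores

Within a window, allele fractions are modelled as a Gaussian mixture with
a shared standard deviation. Three fixed-mean hypotheses are fitted by EM
(weights and σ free, means pinned at the ideal balances); their
log-likelihoods are converted to normalized support
$\mathrm{score}_m = \exp(LL_m - LL_{\max}) / \sum_{m'} \exp(LL_{m'} - LL_{\max})$,
which is bounded, sums to 1, and is comparable across windows. A
free-means mixture of the same size is kept as a goodness-of-fit
reference; since EM is monotone, seeding one free-model restart at the
fixed-model solution guarantees $LL_{\text{free}} \ge LL_{\text{fixed}}$,
an invariant the tests assert.

Numerical choices: fractions are clipped to [0.02, 0.98] before fitting
(fixation and noise otherwise put mass at the boundary where the
likelihood degenerates); σ is floored at 0.01, which also handles the
all-identical degenerate input; EM stops when the log-likelihood improves
by less than 1e-6 or at 500 iterations; the free model uses 5 seeded
restarts with quantile-range initial means. Windows with fewer than
`min_snps = 10` SNPs are *missing*, not scored — homozygous tracts carry
no allele-balance information. Note the hypotheses are nested (the
tetraploid mean set contains the diploid mean), so on truly diploid data
the tetraploid fit can match the diploid likelihood; ties resolve to the
simpler hypothesis, and the planted-recovery tests confirm ≥90% top-1
recovery at 50+ SNPs and coverage 100.

# Mixture-based population checks

**Coverage bimodality.** Scaffold mean depths (log2 scale, scaffolds
≥ 1 kbp with positive coverage, length-weighted so that fragment count
does not dominate sequence content) are fitted with 1- and 2-component
shared-σ Gaussian mixtures (5 seeded restarts; weighted EM is authored
here because no installed package fits weighted univariate mixtures). Two
modes are called when the 2-component model wins by more than ΔBIC = 10 —
the conventional "decisive" margin — *and* the means are ≥ 0.5 apart in
log2 (≥ ~1.4× coverage ratio). Both guards matter: BIC alone flags
heavy-tailed unimodal data, separation alone flags overlapping components.
Fewer than 20 usable scaffolds is "insufficient".

**Window populations.** Windows are summarized as (√SNP-count,
log2 coverage), standardized, and fitted with 1- vs 2-component bivariate
Gaussian mixtures (mclust, `VVV`, with a conjugate-prior regularization so
that a point-mass cluster — e.g. SNP-free haploid windows at exactly 0 —
does not make the covariance singular). The square root stabilizes the
Poisson-like variance of SNP counts; without it, the skewness of raw
counts is itself "evidence" for a second Gaussian and the null fires.
Truncated terminal windows are excluded for the same reason: their
shorter denominators inflate variance on both axes and masquerade as a
population. Multi-population requires ΔBIC > 10 and centroid separation
≥ 1 pooled within-component SD on either axis. Fewer than 100 usable
windows is "insufficient".

# The warning report

Stable codes: `LOW_GC` / `HIGH_GC` (global GC strictly below 0.35 /
above 0.65 — the low threshold is the operative one for AT-rich fungal
genomes and the high one mirrors it, since both extremes distort mapping
and composition statistics), `UNDEFINED_GC` (all-N assembly),
`LOW_MAPPED` (< 0.90), `LOW_BUSCO` (< 0.90; both consumed as externally
computed numbers and "not assessed" when absent), `BIMODAL_COVERAGE`,
`MULTI_POPULATION`. Interpretations are composed by a fixed rule order
(bimodal + low heterozygosity → possible hemidiploid; two k-mer peaks →
heterozygous diploid, hybrid if heterozygosity is extreme; a ≥5% subset
of scaffolds with deviant GC and under-half coverage → possible
contamination), so identical inputs serialize byte-identically.

# The scenario simulator

The generator emulates the data *statistics* the diagnostics consume, not
the read-level physics. Genomes are i.i.d. bases at a target GC; scaffold
lengths are log-uniform in [5 kb, 200 kb] rescaled to the requested
genome size (floor 1.5 kb). Heterozygous sites are planted uniformly at
the scenario's rate; site depths are Poisson(base coverage × per-scaffold
copy multiplier) and alternative depths Binomial at the true fraction;
per-base depth tracks are Poisson at the same rate. Reads are drawn
uniformly from explicit haplotype sequences (alternative alleles assigned
to haplotype copies to match each site's dosage) with optional uniform
substitution errors.

Scenario defaults are fixed once: 1 Mb genomes; 20 scaffolds for
homogeneous architectures and 100 for the scaffold-population scenarios
(the bimodality operating characteristics need ≥ 50 scaffolds per
coverage mode); total coverage 30× (haploid; hemidiploid baseline), 60×
(diploid, aneuploid, hybrid-like), 100× (triploid, where three balance
modes must be resolved); heterozygosity 1% for heterozygous scenarios and
3% for the hybrid-like one; hemidiploid GC 0.326, a realistically extreme
AT-rich composition that also exercises the low-GC warning; contaminant
scaffolds (~10% of the count) at GC 0.65 and 0.2× coverage, the
low-coverage alien-composition cloud typical of bacterial contamination.

What the generator does **not** emulate — and what passing tests
therefore do not demonstrate about real data: mapping bias and multi-read
error correlation, indels and structural variants, repeat-induced
coverage inflation, quality-score structure, GC-coverage coupling,
reference bias in variant calls, and heterokaryotic allele fractions off
the ideal ratios. The checks' operating characteristics on real libraries
will be somewhat worse than on these clean planted scenarios.

# Problem sizes and determinism

The test and acceptance workloads are sized to run comfortably on one
CPU: fair-coin constants on 10⁴ sites at coverage 100; ploidy recovery on
20 windows × 5 seeds per hypothesis (50 SNPs, coverage 100); k-mer
genome-size recovery on an error-free 1-Mb genome at 50×; operating
characteristics on 20 seeded 0.6-Mb scenarios per condition. Every
stochastic step takes an explicit seed, derived seeds stay below 2³¹, and
the simulator restores the caller's RNG state, so identical seeds give
byte-identical FASTA/VCF/TSV/JSON outputs (images are excluded from
byte-exactness).

# Known limitations

Ploidy hypotheses stop at tetraploid; AAB and ABB triploids are
distinguished only as mirrored balance modes; contamination is flagged
structurally (GC/coverage), never assigned taxonomically; the k-mer
module holds its table in memory (fine to a few hundred million
instances) and does no GenomeScope-style mixture fit of the full
spectrum; equivalence with external windowed-ploidy tools is not claimed
— the normalization of the scores is this package's own (likelihood
softmax), chosen because the raw per-window log-likelihoods are
unbounded and not comparable across windows of different SNP counts.
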