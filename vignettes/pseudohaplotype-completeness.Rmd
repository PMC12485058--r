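---
title: "K-mer validation of pseudo-haplotype assemblies: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{K-mer validation of pseudo-haplotype assemblies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(purgecheck)
```

## The problem

Assemblies of heterozygous diploid genomes — outcrossing crops such as
cassava are the canonical case — are usually published as a single
*pseudo-haplotype*: after initial assembly, haplotig purging removes the
redundant copy of every region that was assembled twice because its two
alleles diverged. Purging can fail in both directions. If it is
*incomplete*, both haplotypes survive in the "purged" assembly, which then
looks suspiciously complete and is roughly twice the haploid size; if it is
*excessive*, genuine single-copy sequence is discarded. Both failure modes
are invisible to contiguity metrics like N50 but leave a clear signature in
k-mer space, which is what this package measures.

## The completeness ceiling

Let $r$ be the per-base heterozygosity rate and $k$ the k-mer size. Under
independent per-base heterozygosity, a k-mer window is free of heterozygous
sites with probability $q = (1-r)^k$. A diploid genome of haploid size $G$
then carries about $Gq$ distinct k-mers shared by both haplotypes and
$2G(1-q)$ k-mers private to one haplotype, i.e. $G\,(2 - (1-r)^k)$ distinct
k-mers in total, while a perfect pseudo-haplotype carries $G$. The k-mer
completeness of an ideal purged assembly, measured against all distinct
read k-mers of the diploid sample, is therefore capped at

$$C_{\max} = \frac{1}{2 - (1-r)^k},$$

which is strictly decreasing in both $r$ and $k$ and confined to
$(0.5, 1]$. At $k = 21$ the ceiling runs from about 91% at $r = 0.5\%$ down
to about 74% at $r = 2\%$ — a sub-100% completeness is *expected* for a
correctly purged assembly, not a defect.

Real pre-purge assemblies do not capture every read k-mer either
(coverage gaps, consensus errors, collapsed repeats). The pre-purge
completeness $s$ is treated as an opaque scaling factor, giving the
expectation for the purged assembly:

$$C_{\mathrm{expected}} = s \cdot C_{\max}.$$

The verdict statistic is the deviation of the observed completeness from
this expectation, in percentage points. `purging_verdict()` reports
`INCOMPLETE_PURGING` above `+tolerance_pp`, `OVER_PURGED` below
`-tolerance_pp` (or when the assembly-to-haploid size ratio falls below its
band), and `CONSISTENT` otherwise. The defaults — 5 pp tolerance, size band
0.8–1.25 — are this package's own operational choices: published analyses
describe the incomplete-purging failure qualitatively ("substantially
higher than expected", "nearly twice the haploid size") without numeric
cut-offs, so the thresholds are configurable and a size ratio above the
band is reported as *corroborating* an INCOMPLETE_PURGING verdict rather
than forcing one on its own. The deviation statistic is symmetric so both
failure modes are detected by the same machinery.

## Measuring completeness and QV

`count_kmers()` counts canonical k-mers (the lexicographic minimum of a
window and its reverse complement, the Jellyfish `-C` convention) in C++
with 2-bit rolling encoding; windows containing non-ACGT characters are
skipped and tallied. Keys are exact for $k \le 26$; the default is
$k = 21$ throughout. Counting is strictly in-memory, which is the right
trade-off for the desk scale this package targets (tens of megabases).

`kmer_completeness()` is the Merqury-style asymmetric definition: the
fraction of *distinct reliable* read k-mers present in the assembly.
Reliable means multiplicity strictly above the error cutoff, found by
`find_error_cutoff()` as the first local minimum of the spectrum scanning
up from multiplicity 1 (falling error peak, then the valley before the
genomic peak), with a conventional fallback of 2 when no error peak exists
(e.g. error-free simulated reads).

`qv_estimate()` uses the complementary positional definition: assembly
k-mer positions, counted with multiplicity, that are absent from the reads
(multiplicity $\ge 1$) indicate consensus error. With supported fraction
$P = (\mathrm{shared}/\mathrm{total})^{1/k}$, the per-base error rate is
$E = 1 - P$ and $\mathrm{QV} = -10\log_{10}E$. A fully supported assembly
has $E = 0$; its QV is reported capped (default 99) with an explicit flag
rather than as infinity.

## Estimating $r$ and $G$ from the read spectrum

`fit_profile()` is a deliberately light-weight spectrum profiler, not a
negative-binomial mixture fitter: peaks are located by smoothed argmax
(moving average, window 3). For a diploid, the heterozygous (1-copy) peak
sits at the haploid k-mer coverage $\lambda$ and the homozygous (2-copy)
peak near $2\lambda$. The global peak above the error cutoff is classified
by looking for a companion peak near half its position (then it is the
homozygous peak) or near twice its position (then it is the heterozygous
peak); companion candidates must be local maxima with at least 10% / 5% of
the global peak's smoothed height, respectively. A spectrum with a single
peak is treated as effectively haploid: the peak is the homozygous
coverage and $r$ is reported as 0. This rule matters — a haploid sample's
only peak sits at the full diploid coverage, and treating it as the
heterozygous peak would halve the genome size estimate.

Haploid genome size is mass over modal coverage,
$\hat G = \sum_{m > \mathrm{cutoff}} m\,h[m] / \mathrm{hom}$, which
includes the repeat tail in the numerator as it should. Heterozygosity
inverts the distinct-k-mer mass ratio: with
$\rho = D_{het}/D_{hom} = 2\,((1-r)^{-k} - 1)$,

$$\hat r = 1 - \left(\frac{2}{\rho + 2}\right)^{1/k}.$$

$D_{het}$ is summed over multiplicities in $[0.5\lambda, 1.5\lambda)$ and
$D_{hom}$ over $[1.5\lambda, 1.5\,\mathrm{hom})$. The two windows are
deliberately disjoint, split at $1.5\lambda$ (the inter-peak valley for
$\mathrm{hom} \approx 2\lambda$): windows centred symmetrically on each
peak would overlap on $[\lambda, 1.5\lambda)$ and double-count the upper
shoulder of the heterozygous peak into $D_{hom}$, which biases $\hat r$
low by over 20% relative at $r = 1.5\%$ (Poisson-shape calculation) —
larger than the estimator's entire error budget. K-mers above
$1.5\,\mathrm{hom}$ (repeats) are excluded from the ratio because they
would inflate $\rho$. Residual bias from peak-tail leakage across the
$1.5\lambda$ boundary remains the dominant error term at low $r$ (about
+10% relative at $r = 0.5\%$, under 3% at $r \ge 1.5\%$), well inside the
20% relative recovery target the package tests.

This profiler is a validation instrument, not a replacement for a full
mixture model: it has no duplication terms, no ploidy above 2, no
confidence intervals, and it will report $r = 0$ for genomes whose
heterozygous peak is too weak to detect (roughly $r \lesssim 0.05\%$ at
$k = 21$). Published per-genotype heterozygosity values from full profilers
are therefore not reproduction targets for it.

## The simulator: what it emulates and what it does not

`simulate_diploid()` builds haplotype A as i.i.d. bases at a target GC
(default 0.37, a typical plant nuclear genome), plants SNPs independently
at rate $r$ (a substitution always changes the base, uniform over the
three alternatives), and records the truth. `simulate_reads()` draws
fixed-length reads (default 150 bp, short-read scale) from uniform
positions on random haplotypes and strands until per-haplotype coverage
(default 30×) is reached, with optional i.i.d. substitution errors
(default 0). All generators are deterministic under a seed; sub-seeds for
the mutation and read stages are derived arithmetically from the master
seed so each stage is independently reproducible.

The defaults are the package's study conditions: 1 Mb haploid size for
full-scale validation runs, $r \in \{0.5\%, 1.5\%, 4.5\%\}$ spanning the
range from typical cultivated-crop heterozygosity to the highly
heterozygous wild-relative regime, 30× error-free reads per haplotype.
Unit tests use 10–200 kb genomes for speed; the full 1 Mb conditions are
exercised by the validation suite (seeds 1–10 per rate, about 11 s per
fixture on one CPU).

The simulator matches the model's assumptions *on purpose*: SNP-only
heterozygosity, no indels or structural variants, no repeats, no
ONT-style error profiles. That alignment is what makes the closed-form
ceiling an exact oracle for the pipeline, so passing tests demonstrate
internal correctness of counting, profiling and the completeness
arithmetic — they do not demonstrate that real genomes obey the
independence assumption. On real data, clustered SNPs, indel
heterozygosity and repeat-induced k-mer sharing all push the true ceiling
up or down from $1/(2-(1-r)^k)$; the model should be read there as a
well-motivated reference line, which is exactly how the verdict uses it.

## Numerical choices and degenerate inputs

* Rates are fractions internally everywhere; percent only at I/O
  boundaries. Report TSVs format model columns at 2 decimals and echo the
  observed column at its input precision.
* `find_error_cutoff()` treats a non-decreasing start (`h[2] >= h[1]`) as
  "no error peak" and returns 2; plateaus of zeros inside a decay are
  walked through until the first strict rise.
* NXX ties: descending sort, first length whose cumulative sum reaches the
  threshold.
* Degenerate inputs fail loudly: empty spectra, spectra with no peak above
  the cutoff, empty assemblies, zero reliable read k-mers, invalid rates
  and malformed histogram lines (reported with their line number) are all
  errors, not silent defaults.
* `count_kmers()` accepts $k \le 26$ so 2-bit codes remain exact in
  doubles; the bundled analyses all use $k = 21$.

## Known limitations

Beyond the modeling non-goals above: the in-memory counter is not meant
for gigabase read sets; the verdict thresholds are heuristics to be tuned
per project; and heterozygosity estimates below the peak-detection floor
are reported as 0 rather than with uncertainty.
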