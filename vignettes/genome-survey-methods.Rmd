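---
title: "Genome survey methods: k-mer spectra, microsatellites and mitogenome structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome survey methods: k-mer spectra, microsatellites and mitogenome structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomesurvey)
```

## The problem

Genome survey sequencing (GSS) uses moderate-coverage short reads to
characterize a genome before any serious assembly effort: how big is the
haploid genome, how heterozygous are the two haplotypes, how much of the
genome is repetitive, is the base composition amenable to Illumina
chemistry, and what simple sequence repeats (SSRs) are available as marker
candidates. `genomesurvey` implements that survey layer for non-model
organisms — typically a single wild-caught individual of a species with no
reference genome — together with the mitogenome structure analysis that
commonly rides along as a by-product of the same sequencing run.

Because real survey data sets are tens of gigabases, the package also ships
a diploid read simulator with complete ground truth. Every estimator in the
package is validated by *parameter recovery* on that simulator, not only by
unit arithmetic.

## The k-mer spectrum model

All length-$k$ windows of the reads (windows containing `N` are skipped)
are counted in canonical form — the lexicographic minimum of the window and
its reverse complement; $k$ must be odd so no k-mer is its own reverse
complement. The *depth* of a distinct canonical k-mer is its total
occurrence count, and the histogram of depths is the k-mer spectrum.

For uniform coverage the depth of a single-copy homozygous k-mer is
approximately Poisson with mean

$$\lambda = c\,\frac{L - k + 1}{L},$$

where $c$ is the fold coverage and $L$ the read length. The spectrum
therefore shows a main peak at depth $D \approx \lambda$, an error
component at very low depth, and repeat mass at multiples of $\lambda$.

The estimators follow the standard survey formulas:

* **Low-depth cutoff.** Scanning the populated depth bins upward from depth
  1, the first local minimum separates error k-mers from genuine genomic
  ones. Depths at or below the cutoff are excluded from all totals. A
  strictly decreasing spectrum has no genomic peak and is reported as
  insufficient coverage. An optional window-3 moving average
  (`find_main_peak(smooth = TRUE)`) is available for noisy spectra; the
  default is the raw histogram, which is what small simulations produce.
* **Genome size.** $\widehat{G} = N / D$ where $N$ is the *k-mer number*
  (total retained occurrences, i.e. $\sum_{d > \text{cutoff}} d \cdot
  \text{count}(d)$) and $D$ the main-peak depth.
* **Revised genome size.** $\widehat{G}_{rev} = \widehat{G} \times (1 - e)$
  with $e$ the sequencing error rate, removing the residual inflation from
  erroneous k-mers. In `run_survey()` the default $e$ is the Phred-expected
  error computed by the QC stage; callers may supply a vendor-reported rate
  instead.
* **Repeat ratio.** The occurrence-weighted fraction of retained k-mer mass
  at depths above $1.8 \times D$. The 1.8 multiplier sits beyond the
  diploid main peak but below the two-copy repeat peak at $2D$, so two-copy
  and higher repeat families fall above it. Occurrence weighting is used
  because repeat *content* is a base-pair quantity: a k-mer present in ten
  copies represents ten times the sequence.

### Heterozygosity

A k-mer overlapping a heterozygous SNP exists in only one haplotype, so its
depth is Poisson with mean $\lambda/2$ rather than $\lambda$ — each
haplotype is sequenced at $c/2$. The spectrum of a diploid is therefore a
two-component mixture, and the package decomposes it directly: over depths
in $(\text{cutoff},\, 1.5 D]$, distinct counts are fitted by non-negative
least squares to

$$\text{count}(d) \approx A\,\mathrm{Pois}(d;\lambda/2) +
  B\,\mathrm{Pois}(d;\lambda),$$

with $\lambda$ re-estimated as the count-weighted mean depth over
$[0.8D, 1.2D]$ (the integer peak is a truncation of the real-valued
$\lambda$). The occurrence-weighted heterozygous share is

$$f = \frac{A\,\lambda/2}{A\,\lambda/2 + B\,\lambda},$$

and since a k-mer is affected when any of its $k$ bases is heterozygous,
the per-base rate is recovered by

$$h = 1 - (1 - f)^{1/k}.$$

A simpler rule — assigning every k-mer below a fixed fraction of the peak
(say $0.75 D$) to the heterozygous component — was considered and rejected:
the Poisson left tail of the homozygous peak alone places roughly 10% of
k-mers below $0.75D$ at survey-typical $\lambda \approx 35$, so a fully
homozygous genome would report $\sim$0.7% "heterozygosity". The mixture fit
has the correct null: on homozygous simulations it returns $<0.01\%$, and
at a true rate of 0.7% it recovers $\sim$0.7–0.9% (the residual upward bias
comes from homozygous mass inside the fit window at finite genome size).
When the fitted $A \le 0$ — no half-depth component is detectable — the
estimate is 0.

### Windowed GC

GC content along contigs is computed in fixed, non-overlapping windows
(default 10 kb; the trailing window keeps its actual length) as
$(G + C)/(A + C + G + T)$, with ambiguous bases excluded from the
denominator. The length-weighted mean of the window values equals the
whole-sequence GC, which is asserted as a conservation test.

## Read QC and assembly statistics

Q20 and Q30 are the percentages of bases with Phred quality *strictly*
greater than 20 and 30. The strict inequality matters: a run with constant
Q30 has a Q30 percentage of 0, not 100. The expected error percentage is
$100 \times \overline{10^{-Q/10}}$. Per-position base content covers
positions 1..max read length with A/C/G/T/N fractions that sum to one at
every covered position. On strand-symmetric data, A balances T and G
balances C — the complementary-strand symmetry one expects from an unbiased
library.

N50 (N90) is the length of the contig at which the cumulative length of
contigs sorted in decreasing order first reaches 50% (90%) of the total;
both are permutation-invariant in the contig order.

## Microsatellite mining

`find_ssrs()` reports all maximal perfect tandem repeats of primitive
1–6 bp motifs meeting the minimum repeat counts (defaults: mono $\ge 10$,
di $\ge 6$, tri/tetra/penta/hexa $\ge 5$ — the common MISA settings).
Conventions, each of which is exercised by a dedicated test:

* **Primitivity.** $(AT)_6$ is never additionally reported as $(ATAT)_3$;
  a motif that is a repetition of a shorter motif is reported only at the
  smallest unit size.
* **Maximality and phase.** A perfect repeat region whose span is not an
  exact multiple of the unit admits several whole-unit placements shifted
  by one base; the leftmost placement is reported (MISA behaviour), and the
  reported motif is the rotation as read at the locus start. Coordinates
  are 1-based inclusive and always satisfy
  `end - start + 1 == unit_size * n_repeats`.
* **Containment.** A locus strictly contained in a longer reported locus is
  suppressed (longest-span precedence; identical spans keep the smaller
  unit size), preventing double counting.
* **Ambiguity.** Runs are broken at `N`.
* **Compounds.** Two loci on the same sequence with an inter-locus gap of
  at most 100 bp (the common MISA default; the gap is configurable) share a
  compound id, transitively.

Motif classes collapse the 4 rotations/reverse-complement redundancy:
the representative is the lexicographically smallest string over all
rotations of the motif and of its reverse complement, rendered `"X/Y"`
with `Y` the smallest rotation of `X`'s reverse complement. The four
dinucleotide classes are exactly `AC/GT`, `AG/CT`, `AT/AT`, `CG/CG`; the
sixty primitive trinucleotides form exactly ten classes.

Census percentages are rounded half-up to two decimals (`pct_half_up()`),
matching the convention of published SSR tables; a small numeric nudge
keeps exact decimal boundaries (1.005) rounding upward despite binary
floating point.

## Mitogenome composition and gene order

`base_composition()` reports A/C/G/T percentages over unambiguous bases
(half-up, two decimals) and the A+T and G+C contents summed *before*
rounding, so the printed A+T equals the sum of unrounded A and T.

`canonical_vertebrate_order()` encodes the standard 37-gene vertebrate
mitochondrial arrangement plus the control region, with ND6 and eight tRNAs
(Gln, Ala, Asn, Cys, Tyr, Ser(UCN), Glu, Pro) on the L-strand. Feature
names are normalized through an alias table (single-letter tRNA codes,
`trnX` styles, `COI`/`COX1`, `CR`/`D-loop`; the serine/leucine isotypes use
S1 = Ser(UCN), S2 = Ser(AGY), L1 = Leu(CUN), L2 = Leu(UUR)).

`compare_gene_order()` treats the annotation as circular, ordered by start
coordinate and linearized at tRNA-Phe (the conventional anchor, which makes
the comparison rotation-invariant). Features occurring more than once are
reported as *duplicated*; for each duplicated feature the copy that best
aligns with the reference is retained. The *translocated* set is the
minimum set of features whose removal makes the remaining order equal to
the reference as a circular sequence; with at most 38 features this is
computed exactly by maximizing the longest common subsequence over all
rotation pairs of both circular orders (compiled code; the minimal removal
set is the complement of the longest common circular subsequence). Strand
flips are reported separately and do not count as translocations.
Translocation is defined purely on order — coordinates, overlaps and
spacers are out of scope.

## The simulator: what it emulates and what it does not

`simulate_survey()` produces, deterministically for a given seed:

1. a background genome of i.i.d. bases at a target GC content;
2. segmental duplications: a fraction of the genome (default unit 500 bp)
   is overwritten with copies of blocks sampled from elsewhere, which is
   exactly the mechanism that creates k-mer mass at twice the main peak —
   what the repeat-ratio estimator measures. With fraction $\rho$
   overwritten, about $2\rho$ of the genome belongs to two-copy families
   (source plus copy);
3. planted SSR tracts *inserted* (not overwritten) at positions at least
   two motif lengths apart, each flanked by guard bases chosen so the tract
   cannot be extended by another unit — the planted catalog is therefore
   maximal and unambiguous. Any spontaneous background tandem that meets
   the default thresholds is then broken by a single-base change, so the
   truth catalog is the *complete* set of detectable loci and recall/false
   positive rates are exact;
4. a second haplotype with i.i.d. SNPs at the requested per-base rate, the
   alternative base uniform over the other three;
5. fixed-length reads drawn uniformly from both haplotypes and strands of
   the *linear* genome (no origin-spanning reads), with i.i.d. substitution
   errors and either constant (default Q30) or two-state per-base
   qualities. Total read bases are coverage × haploid length, split evenly
   across haplotypes.

It deliberately does **not** model indels, structural variants, paired-end
insert sizes, PCR duplicates, quality-by-cycle decay, coverage bias along
GC, or non-uniform repeat families. Passing recovery tests on this
simulator shows the estimators implement their models correctly under the
models' own assumptions; it does not certify behaviour on real libraries,
where coverage bias and error structure can shift the spectrum's shape.

## Numerical and design choices

* $k = 17$ by default; all operations are parameterized over odd
  $3 \le k \le 31$ (2-bit packing in a 64-bit word).
* The low-depth cutoff scan works on the populated (sparse) bins; k-mer
  histograms are dense through their informative region, and empty interior
  bins only occur in toy inputs.
* The NNLS mixture fit clamps a negative component to zero and refits the
  other, so the heterozygosity estimate is never negative and returns
  exactly 0 for spectra with no half-depth component.
* Rounding in reported percentages is half-up (`floor(x·100 + 0.5)/100`)
  with a $10^{-9}$ nudge; genome sizes are rounded to whole base pairs.
* Each simulation stage derives its own seed (`seed`, `seed + 1`,
  `seed + 2` for genome, haplotype, reads) so stages remain individually
  reproducible when called standalone.
* Report JSON contains no timestamps; identical configurations produce
  byte-identical files.

### Problem sizes used in the test suite

Module tests run on 150–200 kb genomes at 30× coverage, where every
recovery band used (genome size within 5%, heterozygosity within a factor
of two, repeat-ratio monotonicity) holds with margin; the end-to-end
recovery check runs at 1 Mb and 40×, the scale at which the spectrum's
components are cleanly separated. Oracle-equivalence tests use 100 random
small instances per operation against deliberately naive reimplementations
(plain window tables, exhaustive `(start, unit, count)` scans, prefix
scans, per-column tallies, exhaustive single-move enumeration).

## Known limitations

* The heterozygosity model assumes isolated SNPs; clustered variants that
  place several SNPs within one k-mer violate the two-component mixture
  and bias $h$ downward.
* The repeat ratio depends on the 1.8 multiplier convention; genomes whose
  repeat families sit below $1.8 D$ (very recent duplications with depth
  between $D$ and $1.8D$) are undercounted.
* Genome-size estimates inherit the integer discretization of the peak
  depth (about $\pm 1/D$ relative error, ~3% at $D = 35$).
* The gene-order comparison requires features drawn from the vertebrate
  vocabulary; taxa with novel gene content need an extended alias table.
* `windowed_gc()` and the SSR miner hold each sequence in memory; they are
  meant for survey-scale contigs, not chromosome-scale assemblies.

## A minimal session

```{r example, eval = FALSE}
cfg <- sim_config(genome_length = 1e6, gc_content = 0.43, het_rate = 0.007,
                  repeat_fraction = 0.2, coverage = 40, seed = 1)
sim <- simulate_survey(cfg)
hist <- count_canonical_kmers(sim$reads, k = 17)
est <- survey_estimates(hist, error_rate = 0)
est
loci <- find_ssrs(sim$reference, "ref")
compare_gene_order(canonical_vertebrate_order())
```
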