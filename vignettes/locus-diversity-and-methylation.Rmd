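---
title: "Diversity scans and allele-specific methylation at a candidate locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity scans and allele-specific methylation at a candidate locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popmeth)
```

popmeth analyses a candidate locus on two fronts: sequence variation
(did the locus diversify or differentiate between populations?) and DNA
methylation (is its regulation breed- or allele-specific?). This vignette
is the package's own account of the models behind each step, the
parameters that matter, and what the synthetic-data validation does and
does not show.

## Coordinates and data containers

All internal coordinates are 0-based, half-open `[start, end)`; file
formats keep their native convention (BED 0-based; VCF, cytosine reports
and the phased-read TSV 1-based) and are converted exactly once, at the
read/write boundary. The one deliberate exception is the shipped SNP
survey (`h19_snp_table()`), whose positions are transcript coordinates
(TSS = 1) as published; they are never mixed with genomic coordinates.

A `haplotype_alignment` stores an equal-length panel of haplotypes over
`A, C, G, T, N, -` with one group label per sequence. Other IUPAC
ambiguity codes are rejected rather than silently mapped to N: every
diversity statistic below assumes resolved bases, and a silently mapped
code would deflate diversity invisibly.

## Diversity and neutrality statistics

For a panel of $n$ haplotypes, `diversity_stats()` computes the number of
segregating sites $S$, nucleotide diversity as the mean pairwise
difference $\pi = \sum_{i<j} d_{ij} / \binom{n}{2}$, Watterson's
$\theta_w = S / a_1$ with $a_1 = \sum_{k=1}^{n-1} 1/k$, and haplotype
diversity $H_d = \frac{n}{n-1}\left(1 - \sum_h f_h^2\right)$. Columns
containing N or a gap are excluded before anything is counted
("complete deletion", the convention of the classical sequence-panel
software this mirrors); pairwise deletion is available as an option. The
implementation counts alleles per column rather than looping over
sequence pairs; the test suite holds it equal to an explicit brute-force
pairwise count and to the frequency form
$\sum_\text{sites} \frac{n}{n-1} (1 - \sum_a p_a^2)$ on random panels.

`tajimas_d()` standardises $\pi - S/a_1$ with the 1989 variance
constants. `fu_li_star_tests()` implements the no-outgroup D\*/F\*
statistics, contrasting the singleton count $\eta_s$ (alleles observed in
exactly one sequence — the standard within-sample definition) with total
polymorphism $\eta$; the F\* variance uses the corrected constants of
Simonsen et al. (1995). `fay_wu_h()` computes the unnormalised
$H = \pi - \theta_H$ with
$\theta_H = \sum_i \frac{2 i^2 S_i}{n(n-1)}$ over derived-allele counts
$i$, and therefore needs an ancestral base per column; segregating sites
whose ancestral state is absent from the sample are skipped with a
warning rather than guessed. Statistics that are undefined (monomorphic
panel, no ancestral states) are returned as `NA` with an attached
`reason`, never as 0 — a 0 would read as "neutral", which is not what
"not computable" means.

## Differentiation, trees, scans

The locus-scale differentiation estimator is Hudson's
$F_{st} = 1 - H_w/H_b$, with $H_w$ the unweighted mean of the two
within-group mean pairwise differences and $H_b$ the mean over all
cross-group pairs. The choice is deliberate: for two-panel sequence data
it is the standard estimator, it is brute-force verifiable pair by pair,
and its expectation under the Balding–Nichols model equals the model's
divergence parameter, which gives the simulator calibration below a
closed form. Weir–Cockerham-style weighting is not offered; output is
labelled as Hudson. Note the finite-sample quirk that literally
duplicating one panel into two "populations" gives
$F_{st} = -1/(n-1)$, not 0; the estimator is unbiased around 0 for two
samples *drawn from* one population, which is what the tests check.

Breed trees use Nei's net divergence
$d_A(X,Y) = d_{XY} - (d_X + d_Y)/2$ per site — between-group distance
with the average within-group diversity subtracted, so that a diverse
breed is not pushed away from its neighbours merely for being diverse.
Negative $d_A$ (within exceeding between) is reported, not clamped, and
the matrix deliberately does not promise the triangle inequality.
Neighbor joining is delegated to `ape::nj` (Saitou–Nei, Q-criterion)
behind `nj_tree()`, with two determinism policies on top: labels are
sorted before joining so ties resolve by label order, and negative branch
lengths are clamped to zero with the excess moved to the sister branch,
preserving path lengths through the parent.

Sliding windows default to 1000 bp width and 300 bp step for locus scans
(100 kb / 10 kb are the config defaults for genome-scale backgrounds).
Terminal partial windows are emitted and flagged `partial` rather than
dropped — the information is real, only the window is shorter — and
per-window $\pi$ divides by the usable columns actually covered.
Window-level outlier screening is a Z-test against a genome background
supplied as a mean and standard deviation (or simulated by
`sim_window_background()`); the default side is `greater` because the
motivating screen looks for *elevated* diversity in domesticates. Whether
to screen window $\pi$ directly or the $\pi$ ratio between populations is
left to the caller — both are exposed, since either reading of the
published procedure is defensible.

## SNP sharing

`classify_site_sharing()` reduces a per-breed allele-count table to one
label per position: polymorphic only within the domestic groups, only
within the wild groups, in both, or in none. A group is polymorphic at a
position when its minor-allele count is at least 1 — presence, not
frequency, is the criterion, matching how such survey tables are read.
The shipped eight-SNP survey of the porcine *H19* 3' region classifies as
7 domestic-only, 1 shared, 0 wild-only; the parser validates every cell's
counts against the group's sample size, which is also how the table's
transcription was verified.

## Methylation quantification

Bisulfite levels are methylated reads over total reads per CpG, defined
only at coverage `min_cov` (default 5 — a config key, not a claim about
any particular study). MeDIP "levels" are raw mapped read counts; they
are unitless, library-size-dependent, and the package refuses to compare
them with bisulfite fractions in one test. CpGs are reported per strand
by default (lossless); a symmetric-CpG merge is a documented possible
extension rather than a default, since merging discards strand
information irreversibly.

Region summaries give both the unweighted mean of defined site levels and
the pooled (coverage-weighted) mean $\sum m_i / \sum t_i$; the two
diverge exactly when coverage varies, and the tests pin the pooled form
to a brute-force pooled count. The conversion rate is estimated on a
control contig assumed unmethylated (all cytosine contexts pooled), with
a warning below 0.98. No conversion correction is applied to levels
anywhere by default; `conversion_adjust()` implements
$\max(0, (\ell - (1-r))/r)$ for callers who want it.

Group comparisons dispatch what the design calls for: Welch's t-test for
two groups (pooled-variance Student by flag — Welch is the safer default
when only "t-test" is specified), one-way ANOVA or Bonferroni-corrected
pairwise t-tests for more, and additive two-way ANOVA for crossed
tissue × breed layouts. Bonferroni uses $m = \binom{k}{2}$ comparisons,
$p_\text{adj} = \min(1, m p)$.

## DMS and ASM calling

A differential methylation site between two samples is a shared CpG, with
both totals at or above `min_cov` (default 10), whose 2×2 table
(methylated/unmethylated × sample) is significant under a 1-df chi-square
without continuity correction. Zero-margin tables (e.g. both samples
fully methylated) are defined as $\chi^2 = 0$, $p = 1$. Raw p values
drive the calls — site-level chi-square screens of this kind are
conventionally reported unadjusted — with a Benjamini–Hochberg column
available for reference. The coverage gate and $\alpha = 0.05$ are
config keys.

The ASM procedure follows the published recipe exactly where it is
specified and documents its choices where it is silent:

1. **Phasing.** Reads covering a heterozygous biallelic SNP are split by
   the allele they carry. SNPs whose alleles bisulfite conversion
   confounds — C/T for plus-strand reads, G/A for minus-strand reads —
   cannot be phased soundly and are excluded with a count. Reads carrying
   neither declared allele, or anchoring two SNPs with conflicting
   assignments, are dropped and counted. Phased reads enter as a plain
   TSV contract (read id, SNP, allele, CpG, call) rather than BAM, which
   keeps the caller testable without alignment machinery.
2. **Tracks.** Per-allele methylated/total counts per CpG; a CpG joins
   the shared track only when both alleles have at least
   `min_cov_allele` (default 5) reads.
3. **Windows.** Five consecutive shared CpGs, step one CpG (the step is
   a choice; the recipe states only the window). A window is a candidate
   when fold change ≥ 2 **and** absolute mean difference ≥ 0.3, both
   inclusive ("reached" implies attainment). A window whose smaller mean
   is 0 passes the fold criterion — division by zero must not silently
   discard the strongest ASM — but still needs the 0.3 difference.
4. **Regions.** Overlapping candidate windows merge into maximal
   regions (idempotently); each region is tested with a *paired* t-test
   of per-CpG level pairs — paired because the two alleles are measured
   at the same sites — and kept at $p < 0.05$. Both the pairing and the
   $\alpha$ are choices the recipe leaves open; both are config keys.

Every stage increments an audit log (SNPs excluded, reads dropped,
windows tested) so an empty result is distinguishable from an input that
never reached the scan.

## Simulators and what the validation shows

`sim_coalescent()` is the textbook single-population neutral coalescent
without recombination: exponential waiting times with rate
$\binom{k}{2}$ in units of $2N$ generations, mutations Poisson with mean
$\theta_\text{locus} T_\text{total} / 2$ dropped on branches
proportionally to length at distinct sites. Its closed-form expectations
$E[\pi] = \theta$ and $E[S] = \theta a_1(n)$ are what the calibration
tests assert (within 3 Monte-Carlo standard errors). Two-population
structure uses the Balding–Nichols model rather than a split coalescent,
again because the closed form $E[F_{st}] = F$ makes the check exact.
`sim_bisulfite()` works at CpG-call granularity: coverage is Poisson,
methylated calls are Binomial with success
$\ell + (1-\ell)(1-r)$ — the conversion-failure term — and ASM mode emits
phased reads, each spanning a contiguous run of CpGs. All generators take
explicit seeds, restore the global RNG state, and are bit-reproducible.

Problem sizes used by the tests and the acceptance script, chosen to give
stable Monte-Carlo verdicts at desk scale: 500 coalescent replicates at
$n = 20$, $\theta_\text{locus} = 10$, 2000 sites for the $\pi$ and
neutrality-statistic means (the exact-expectation check for $S$ runs
1000 replicates at $n = 10$, where $\theta a_1 = 28.29$); 200
Balding–Nichols loci at $F = 0.2$ with 25 + 25 haplotypes; 1000 null
CpGs at coverage 30 for the DMS type-I error; 100 seeds each for planted
($\Delta = 0.7$ across 8 CpGs, per-allele coverage 20) and null ASM
datasets; 50 random 6-leaf additive trees for NJ split recovery. The
breed-level methylation effect sizes in examples
($\Delta \in \{0.2, 0.3, 0.5, 0.7\}$) are not estimates from any dataset;
they bracket what single-base methylome comparisons typically report and
are documented as arbitrary.

What passing these tests shows: the estimators are algebraically correct
(brute-force equalities, frozen constants-oracle values), calibrated
under their own generative models, and the callers recover planted
signals at the stated strengths while controlling false positives on
null data. What it does not show: robustness to features the generators
deliberately omit — recombination, demographic history, alignment error,
sequencing error beyond conversion failure, MeDIP enrichment bias and
library-size effects, and non-independence of neighbouring CpGs. Real
data carry all of these; conclusions about a real locus still need the
usual caution.

## Known limitations

- Tajima's D and the Fu & Li statistics have a small negative bias under
  the neutral coalescent at finite $n$ (the normalisation is approximate);
  the calibration asserts the mean is within Monte-Carlo error of 0, which
  holds at the replicate counts used but is not an exact-zero claim.
- The HKA test is out of scope: it needs multi-locus interspecific
  divergence inputs this package does not model.
- DMR-style region-level differential methylation between samples is not
  implemented — only per-site DMS; the ASM caller is the only
  region-forming step.
- Whether published clone-derived allele-count tables equal the inputs of
  published per-breed $\pi$ values is not assumed anywhere; the shipped
  survey is used for sharing classification only, and diversity is always
  recomputed from sequence panels.
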