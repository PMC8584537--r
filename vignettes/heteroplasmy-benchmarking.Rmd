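---
title: "Benchmarking mtDNA heteroplasmy calling on a duplicated-reference amplicon panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking mtDNA heteroplasmy calling on a duplicated-reference amplicon panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitofold)
```

## The setting

Human mtDNA is a 16,569-bp circle present in many copies per cell, so a
sample is a population of genomes and a variant has a continuous *variant
level* (VL) — the fraction of reads carrying the alternate allele —
rather than a discrete genotype. Amplicon panels that tile the circle with
short PCR products sometimes align reads to an *extended* linear
reference: the canonical sequence followed by a duplicate of its first 80
bases, so the amplicon spanning the origin maps contiguously. This
vignette describes the models and conventions behind `mitofold`, which
provides the call-level machinery for validating heteroplasmy detection in
that setting: coordinate folding, a pileup caller, cross-run grading,
mixture benchmarking, threshold optimization and false-positive
annotation, all exercised end to end on synthetic data.

## Coordinate model

Coordinates are 1-based inclusive everywhere; BED interchange converts to
0-based half-open at the I/O boundary only. Folding maps extended position
$p$ to $p - L$ when $p > L$ (with $L = 16{,}569$) and is the identity
otherwise; its inverse maps canonical $p \le d$ (the duplication length,
default $d = 80$) to the pair $\{p, p + L\}$. Records of one variant
observed in both copies of the duplicated region are merged by the
arithmetic mean of their coverages and of their VLs. The mean rule is
stated for pairs; we extend it associatively to $k$ records as the
unweighted mean of all $k$, the natural generalization when the copy
provenance of each record is unknown. Folding is idempotent, so canonical
callsets pass through unchanged; the contig length declared in a VCF
header (16,569 vs 16,649) selects the behaviour.

The position blacklist — 302–315, 523–524 and 3104–3110, homopolymeric
and artifact-prone stretches — is applied on *canonical* coordinates after
folding, never on extended coordinates, since exclusion rules are defined
on the canonical genome.

## The caller

The caller is a transparent frequency estimator over strand-split per-site
base counts: at each site, each non-reference base $b$ with
$\hat{v}_b = n_b / \text{depth} \ge t$ is emitted at threshold $t$. This
implements the stage contract of mutserve-class mtDNA callers — threshold
filtering, base quality $\ge 20$ enforced at pileup construction,
SNV-only scope, blacklist exclusion — with a plain binomial-frequency
estimator rather than any particular caller's likelihood model; it is a
faithful-contract, not bit-identical, re-implementation. Additional
conventions:

* at most the two most frequent non-reference bases per site, ties broken
  alphabetically (determinism);
* a double-strand rule: at least `min_per_strand` (default 1) alternate
  reads on each strand, disabled at 0; single-strand support is the
  classic artifact signature;
* zero-depth and reference-N sites are uncallable;
* threshold sweeps filter a single base callset computed at the smallest
  grid value, so callsets are *nested by construction*.

The default grid is 0.4% plus 0.5% to 10% in 0.5% steps — 21 values
matching the published count and endpoints; the intermediate values are
not printed anywhere authoritative, so the uniform 0.5% spacing is our
choice. The default operating threshold is 2.5%.

Two homoplasmy bounds coexist deliberately: grading calls a variant
homoplasmic at VL ≥ 95%, while VCF genotype export writes the homoplasmic
code at VL ≥ 90% (both inclusive, both configurable). They serve different
consumers (reliability classification vs downstream haplogroup tools) and
are kept separate.

## Cross-run grading

Reference truth comes from three independent sequencing runs of the same
sample (exome, lowCov, highCov), ingested at a 0.4% detection threshold.
Grades follow concordance:

| grade | rule |
|---|---|
| A | mean VL ≥ 95%, present in both highCov and lowCov (exome irrelevant) |
| B | both highCov and lowCov with mean VL < 95%, or exactly two runs one of which is exome |
| C | a single run |
| novel | test platform only |

Two boundary decisions are ours. First, the printed A and B bounds touch
at exactly 95%; we resolve the tie to Grade A (the higher-reliability
class). Second, the rules as stated are not exhaustive: a *homoplasmic*
variant seen in highCov + exome but not lowCov satisfies neither the A
pattern (needs both deep runs) nor the B level bound. We grade any
two-run pattern that is not Grade A as Grade B, making the four rules a
partition over all presence patterns × VL regimes — the property the test
suite asserts by exhaustive enumeration. The mean VL is computed over the
runs where the variant is *observed*; absent runs contribute nothing, not
zero, since presence and level are conditioned separately.

Grade C variants are excluded from the true-positive/false-negative
ledger (metrics are defined on Grade A/B variants) but retained in
reports with an explicit `excluded` outcome.

## Mixtures

A mixture of a minor haplotype at fraction $m$ with a major at $1-m$ has
expected VL

$$ E[v] = m\,v_\text{minor} + (1-m)\,v_\text{major}, $$

with $v = 0$ for a component lacking the variant. Linear mixing is the
only physically sensible model for ideal volume mixtures and is verified
in the tests against brute-force genome-copy accounting. The default
design is three ordered pairs × fractions {1, 2, 5, 10, 25}%, 15 mixtures
named minor + fraction + major (`U0.01H` = U at 1% in H).

Mixture variants classify by component presence: minor-derived,
major-derived, shared, novel, or mixed-status when the two components
carry *different* alternate bases at one position (excluded from metric
datasets — origin undecidable under SNV-only scope). For shared variants
the *lower* grade prevails (A < B < C on the reliability lattice). The
original scheme's finer micro/meso layers derive from an appendix
enumeration that is not in the main text; we implement the five-way macro
scheme plus effective grade and accept a user-supplied mapping table for
anything finer.

Expected-vs-observed comparisons come in two modes: *external* mixes the
cross-platform reference-run mean VLs; *internal* mixes the VLs observed
in the unmixed test-platform runs, isolating platform-specific bias.
Differences are reported raw ($v_\text{obs} - v_\text{exp}$) and relative
(divided by $v_\text{exp}$; $-1$ for a lost variant; undefined at
$v_\text{exp} = 0$). Per model group an OLS fit of observed on expected
yields an adjusted $R^2$ and model p-value; p-values are
Benjamini–Hochberg adjusted across the batch (the standard FDR procedure,
used for every "FDR-adjusted" step in the package), and the correlation
indicator is $\log_{10}(R^2_\text{adj} / p_\text{adj})$. Groups with
fewer than 3 pairs or constant expected VL are flagged NA, not errors.

## Metrics and threshold choice

Per dataset (primary/mixture × Grade A/B): tp = found, fn = lost,
fp = novel calls. Novel calls carry no grade, so each dataset counts *all*
novel calls of its samples as false positives while restricting tp/fn to
its grade. The true-negative space is (non-blacklisted canonical
positions) × 3 alternate alleles — the per-position-allele convention of
mtDNA caller benchmarking; no authoritative TN definition exists for this
design, so this choice is recorded here. Undefined ratios are NA, never
0; $F_1$ is the harmonic mean of precision and sensitivity. The optimal
threshold maximizes the unweighted mean $F_1$ across the four datasets,
ties breaking toward the *higher* (more conservative) threshold; datasets
with undefined $F_1$ drop from the mean with a warning.

`paired_compare` wraps the two-sided paired t-test with its t-based CI. A
zero-spread difference vector is degenerate: identical vectors report
p = 1 (no evidence), a constant non-zero shift reports NA rather than
raising, because batch comparisons must not abort on one pathological
pair.

## The synthetic generator

The generator stands in for samples that cannot ship with a package:

* **Haplotypes** — three synthetic haplotypes with 30 private homoplasmic
  and 5 private heteroplasmic variants each (VLs uniform on 0.1–0.9) plus
  10 homoplasmic sites shared by all three (a phylogeny stand-in),
  avoiding the blacklist. Real mtDNA haplotypes differ from the reference
  at a few dozen sites, so these sizes give realistic truth-set sizes.
* **Depth** — a per-amplicon log-normal factor ($\sigma = 0.3$,
  mean-one parameterization) models amplicon-to-amplicon coverage
  heterogeneity; per-position depth is Poisson around the amplicon mean.
  Default mean depth 5,000 reads/bp — the order of magnitude of deep
  mtDNA panel runs.
* **Counts** — the alternate base is Binomial(depth,
  $v(1-e) + e/3$) with substitution error rate $e$ (default 0.001);
  the other two non-reference bases receive background errors at $e/3$;
  every base count splits between strands as Binomial(n, 1/2). The error
  model is uniform across substitutions for analyzability; real platform
  errors are transition-biased, which the NUMT injector reflects by
  defaulting to transition alternates.
* **NUMT-like signal** — adds alternate reads at chosen positions to a
  target fraction with a skewed strand split (default 90% forward),
  reproducing the strand-bias signature by which such contamination is
  caught.
* **Panel** — 162 amplicons tiling the circle exactly once, callable
  lengths drawn uniformly in 73–137 bp then nudged within range to close
  the circle; real panel coordinates are proprietary, so the synthetic
  panel reproduces the published count and length range only. Reads
  assign to the amplicon of maximal callable overlap (ties to the smaller
  id) and crop at 160 bp. Edge distance is two-sided — the minimum over
  both callable ends and all covering amplicons — since "distance to the
  callable extremity" does not specify a side.

All randomness flows from explicit seeds; no global RNG state is touched
(`with_local_seed` restores `.Random.seed`).

What the generator does *not* emulate — and hence what green tests do not
establish about real data: homopolymer (poly-C) error patterns, read-level
NUMT sequences and their mapping behaviour, PCR efficiency differences
between amplicons beyond a symmetric log-normal, volume-mixing inaccuracy
(nominal fractions are treated as truth), and real haplogroup phylogeny.
Conclusions transfer to the extent that the binomial sampling + uniform
error abstraction holds.

## Problem sizes and numerical checks

The test suite runs the full benchmark (3 primary samples + 15 mixtures,
21 thresholds, 16,569-bp genome) in a few seconds; recovery properties
use 20 seeded replicates of 5,000× mixtures, asserting that minor-specific
homoplasmies with expected VL ≥ 5% are always recovered at the 2.5%
threshold and ≥ 99% of VL estimates fall within 3 binomial standard
errors. Threshold-separation checks inject a 1% NUMT-like noise floor
against 5% signal and require the F1-optimal grid threshold to lie
strictly between them. Degenerate inputs (zero depth, reference N, empty
callsets, zero expected VL, constant-expected regressions, zero-variance
paired differences) are exercised explicitly and return flagged NA values
rather than errors wherever a batch analysis should survive them.

## Limitations

Insertions and deletions are out of scope throughout (SNV-only), as are
alignment, read-level NUMT removal, contamination checks and haplogroup
assignment, which belong to external tools. The caller is a frequency
estimator: it inherits none of the error-model sophistication of
likelihood-based callers, which is precisely what makes it a transparent
reference implementation for benchmarking rather than a production
caller.
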