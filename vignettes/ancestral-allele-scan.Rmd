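---
title: "Inferring cattle ancestral alleles and scanning for their retention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cattle ancestral alleles and scanning for their retention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aascan)
library(data.table)
```

## The problem

Haplotype-based selection statistics (iHS, xp-EHH, and relatives) require
SNPs to be *polarized*: each allele must be labelled ancestral or derived.
For cattle there is no single close outgroup genome that settles this, so
aascan polarizes cattle variation by consensus across three outgroup
lineages within the Bovinae subfamily, all genotyped against the cattle
reference:

* **yak**,
* **bison** — American and European bison pooled,
* **gagaba** — gayal, gaur and banteng pooled.

Taurine and zebu cattle are the *focal groups* that are scored against the
inferred ancestral states. Aurochs samples, when present in a cohort, are
deliberately excluded from both roles: they cluster with domestic cattle
and are not an outgroup.

## The consensus rule

At each biallelic SNP, let $p(A)$ be the frequency of allele $A$ among the
pooled non-missing alleles of one outgroup lineage. Allele $A$ is called
**ancestral** (AA) at the site when $p(A) = 1$ in at least two of the
three lineages. Pooling happens at the lineage level (both bison species
together; all three gagaba species together) because the lineages, not the
six species groups, are the units whose independent divergence the
consensus guards against. With three lineages at most one allele can be
fixed in two of them, so the call is unique; a 2-vs-1 conflict resolves to
the majority pair, and a 1-vs-1 conflict yields no call.

The call is a deterministic function of the allele counts — no likelihood
model, no sampling — which is why rerunning the inference on the same
input reproduces the identical list.

Upstream of the consensus, SNP records pass hard filters: a record is
dropped when MQ < 40, QUAL < 30 or QD < 30 (equality passes, since the
filters remove strictly smaller values), and non-SNP, multiallelic or
unannotated records are removed and accounted for separately. A QD floor
of 30 is far above the usual operating point of that annotation; it is
kept as the default because it is the operating point of the
variant-calling recipe this pipeline mirrors, and it is configurable via
`filter_thresholds()`.

## Retention scoring

For a site with a defined AA and a focal group with matched AA frequency
$x$ (the AA may be the group's major or minor allele),

$$\vartheta = x - p(A_{AA}) = x - 1 \in [-1, 0],$$

and the retention indicator is $f(\vartheta) = 1$ iff $\vartheta = 0$,
else 0. Two consequences worth stating plainly:

* $f = 1$ requires the AA to be **fixed** in the focal group, not merely
  the major allele. The definition forces this reading; a
  majority-based notion of "retention" would be a different statistic.
* A focal group with no called genotype at a site scores $f = 0$:
  absence of evidence is not retention. These sites are flagged
  (`n_uncalled_sites`) in the window output.

Retained sites are summed over non-overlapping windows,
$T = \sum_{\text{sites in window}} f$. Window $t$ spans positions
$[10000(t-1)+1,\; 10000t]$; a 1-based position $p$ belongs to window
$\lceil p/10000 \rceil$, so boundary positions are counted exactly once.
The 10 kb default is configurable (`window_bp`); 1 kb trades stability for
resolution and 50 kb the reverse. Every window of every chromosome is
emitted, including empty ones — zero-count windows are an analysis
endpoint, not missing data.

## Extreme windows

Per chromosome and focal group, the **high** threshold is the nearest-rank
99.9th percentile of window counts: the smallest order statistic whose
cumulative rank reaches 0.999, i.e. rank $\lceil 0.999\,n \rceil$
(evaluated with a $10^{-9}$ slack so a floating-point ulp cannot shift the
rank). Windows with `count >= threshold` are selected, ties included —
counts are small integers and dropping ties would be arbitrary. The
mean + 3 sd of the counts is reported as a diagnostic only: on the
heavy-tailed count distributions this scan targets, selected thresholds
exceed it, but on near-uniform counts they need not, and the
`exceeds_mean_3sd` flag records which situation obtains.

**Null** windows ($T = 0$) are classified by cause: `null_no_aa` when no
AA was definable anywhere in the window, `null_derived` when AA sites
exist but the derived allele has displaced the ancestral one at every one
of them. One degenerate corner is resolved explicitly: on an all-zero
chromosome the nearest-rank threshold is 0 and every window would qualify
as "high"; zero-count windows take the null label, because a window with
no retained AA is not evidence of conservation. Every window therefore
receives exactly one of `high`, `null_no_aa`, `null_derived`,
`background`.

## Annotation

Selected windows are intersected with gene models (BED or GFF3, both
normalized to 1-based inclusive coordinates). A window is `genic` on any
overlap (≥ 1 bp) with a gene body; otherwise `upstream` or `downstream`
when within the flank of a gene (1000 bp by default, the convention of
region-based annotators; strand-aware, with unstranded genes eligible on
both sides); otherwise `intergenic`. Only genic windows contribute to the
gene lists, and genes implicated by high-count windows are removed when
they also occur in null windows — the resulting ranked lists are meant
for external enrichment tools, which are out of scope here.

Two summary statistics accompany the AA list: its GC fraction, and the
fraction of AA positions inside transcript intervals. "Transcript" means
any interval supplied as such; no expression filter is applied.

## The synthetic cohort generator

Real input would be a joint-genotyped whole-genome cohort of the eight
groups. The generator (`simulate_cohort()`) replaces it with a
deterministic miniature that preserves exactly the structure the method
consumes: biallelic SNPs with QUAL/MQ/QD annotations, diploid genotypes
with missingness, the eight-group composition (defaults follow a published
cohort: 13 yak, 4 + 5 bison, 4 + 4 + 5 gagaba, 23 taurine, 8 zebu), and
per-window ground truth. Windows can be planted as

* `conserved` — every AA site retained in both focal groups,
* `mutated_derived` — AA defined, never retained,
* `mutated_no_aa` — polymorphic sites, no definable AA,

against a background where a site carries an AA with probability 0.6 and
each focal group retains it with probability 0.35 — chosen so that, at the
default 2 SNPs/kb, background windows average a handful of retained sites
and planted conserved windows (all ~20 sites retained) stand clear of the
background without being degenerate. The planted AA base is G/C with
probability 0.58, mirroring the elevated GC observed among inferred
ancestral alleles, so the GC summary statistic can be checked against a
known value.

One design choice matters for interpreting the tests: the genotype calls
that define each pattern are protected from the missingness mask (one
call per fixed group, one homozygote per allele in polymorphic groups),
so the truth table is exact by construction, and planted classes survive
any missingness rate. The generator is a test harness, not a population
model: it has no coalescent structure, no LD, no realistic site-frequency
spectrum, and no read-level error. Passing its tests demonstrates that
the implementation computes the defined quantities exactly — not that the
method is robust to the messiness of real resequencing data.

## Numerical choices and degenerate inputs

* Fixation and $\vartheta = 0$ are tested with tolerance $10^{-9}$;
  frequencies are ratios of integer allele counts, so the tolerance only
  matters for externally supplied non-integer tables.
* `min_called = 2` pooled chromosomes per lineage by default: a lineage
  observed on a single chromosome is not evidence of fixation. Raising
  `min_called` can only remove calls, never add them.
* Records lacking MQ or QD cannot be filtered honestly and are dropped
  (and counted) rather than passed.
* Empty chromosomes, empty AA lists and gene-free annotation inputs
  either return well-typed empty results or raise a named error
  (documented per function); empty windows are always enumerated.
* All artifacts are plain text with fixed formatting; rerunning any stage
  on identical inputs reproduces byte-identical files, and the run
  manifest records md5 checksums (and no timestamps) to make that
  checkable.

## Problem sizes used in validation

The shipped test suite validates on cohorts of 2 chromosomes x 100 kb
(module tests) and 5 chromosomes x 1 Mb (end-to-end planted-window
recovery), both at 2 SNPs/kb with the full 66-sample cohort — large
enough that every code path (missingness, all planted classes, ties at
thresholds, empty windows) is exercised, and small enough to iterate on
quickly. The consensus rule itself is verified exhaustively over all 64
lineage-fixation patterns, and window counting and percentile selection
against brute-force oracles.

## Limitations

* The consensus rule is frequency-only; it ignores genotype likelihoods
  and coverage, and a lineage fixed by chance at low sample size will
  satisfy it (mitigated, not removed, by `min_called`).
* Retention is fixation-based; a focal group at AA frequency 0.99 counts
  as non-retained, exactly as the statistic defines.
* Thresholds are per-chromosome order statistics: they adapt to
  chromosome-level count distributions but are not significance
  statements, and no multiple-testing control is applied or implied.
* Annotation stops at gene lists; enrichment against live ontology
  services is intentionally out of scope.
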