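---
title: "Deconvolving pre-RNA isoform abundance from nascent RNA-seq: models and methods"
author: "nasdeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving pre-RNA isoform abundance from nascent RNA-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nasdeconv)
```

## The problem

Nascent RNA-sequencing protocols (PRO-seq, GRO-seq) sequence RNA still
engaged with polymerase, so the signal covers whole transcription units,
introns included. Splice junctions — the main handle RNA-seq methods use
to tell isoforms apart — are therefore uninformative, but genes still
produce mixtures of *pre-RNA isoforms*: transcription units with
different start sites (TSSs) and cleavage/polyadenylation sites (PASs)
that overlap heavily in genomic coordinates. `nasdeconv` estimates the
abundance of each pre-RNA isoform from strand-specific per-base
coverage, plus gene-level sums and dominant-isoform calls.

## The core model

Isoform annotations are grouped into strand-specific, non-overlapping
clusters (the transitive closure of same-strand overlap). Each cluster
is tiled with fixed-width bins (default 250 bp, anchored at the
cluster's 5' end on its own strand) and mature isoforms are collapsed,
per gene, whenever they share both their TSS bin and PAS bin — the
resulting *pre-RNA models* are the units the data can actually
distinguish. For a cluster with $m$ bins and $n$ models, the bin counts
$Y$ are modeled as $Y \approx X\beta$ where $x_{ij}$ is nonzero exactly
when model $j$ spans bin $i$ unmasked, and

$$\hat\beta = \arg\min_{\beta \ge 0} \; (Y - X\beta)^\top (Y - X\beta).$$

In linear mode this non-negative least-squares problem is solved exactly
by an active-set (Lawson–Hanson) routine written for this package; a
box-constrained quasi-Newton path (`optim(method = "L-BFGS-B")`, lower
bound zero) is kept as a cross-check and is the solver for the optional
log mode, where both $Y$ and $X\beta$ are log-transformed after adding a
pseudocount (default 1, configurable; the choice matters only for
near-empty bins). The optimizer starts from each model's mean bin count
divided by its mean design weight, runs at gradient tolerance `1e-8` up
to 500 iterations, and non-convergence returns the best iterate with a
warning. Bins covered by no unmasked model are dropped from the
objective entirely; bins masked for one model but covered by another are
kept, which means a masked model's residual reads are attributed to
whatever unmasked model spans them — a known, intended consequence of
masking.

Raw weights are depth-normalized ($\beta \cdot 10^6 /$ library depth),
summed per gene, and the within-gene argmax is reported as the dominant
isoform (ties broken by longer isoform, then lexicographic id).

### Masking

Promoter-proximal pausing and termination-related deceleration pile
reads at the ends of transcription units in ways the uniform-occupancy
model cannot express. By default the first bin after the TSS and the
last four bins before the PAS of every isoform are masked (masks of 1
and 4 at a 250-bp bin size). The masked 5' bin is the bin containing
the TSS itself; an isoform too short to keep any unmasked bin retains
its single central bin, with a warning, rather than disappearing.

## TSS activity calling

Active TSSs in nascent data are marked by divergent transcription:
near-symmetric pause peaks on both strands. The feature vector for a
candidate TSS holds strand-specific read counts in 21 bins of 51 bp
(1071 bp) centered on the TSS, sense bins first, z-scored jointly; a
constant window yields the all-zero vector and an automatic "inactive"
call, avoiding NaNs. Two interchangeable classifier backends satisfy the
42-features-to-probability contract:

* a regularized logistic regression (the default — fast, convex,
  and on simulated data as accurate as the alternative), and
* a small 1-D convolutional network (16 filters, kernel 5, ReLU,
  max-pool 2, dropout 0.3, dense, sigmoid) written in plain R and
  trained with Adam and early stopping on a validation split.

The decision threshold is 0.5, boundary inclusive. Isoforms whose TSS
fails classification can be *rescued* by the upstream polymerase ratio
(UPR): sense-strand density in [+0.5 kb, +2 kb] from the TSS divided by
density in [−3 kb, −0.5 kb]. A failed isoform with UPR ≥ 5 (inclusive)
and no active TSS within 5 kb upstream / 6 kb downstream (TSS-to-TSS,
strand-aware, either strand) is re-admitted: high inside density with a
quiet upstream flank means no upstream unit explains the signal. Both
windows use sense-strand counts only — the divergent antisense peak
would otherwise leak into the upstream window of closely spaced units;
this choice is configurable in spirit but fixed here. Zero-denominator
rule: upstream 0 with inside > 0 gives +∞ (eligible), both zero gives 0.
A user-supplied inactive-isoform list always overrides classifier calls.
Disallowed models have their design-matrix columns removed before
optimization and report exactly zero.

Because no cap-analysis ground truth ships with the package, classifiers
are trained on simulator-generated labels (isoform TSSs vs gene-body and
intergenic positions); `build_training_set()` implements the
evidence-file labeling rules (peak overlap keeps the strongest candidate
per peak; negatives must be >100 bp from active TSSs and >25 bp from cap
reads) for users with real data.

## The shape profile

Even between the pause and termination peaks, polymerase density is not
uniform: it is typically U-shaped along the gene body. The correction is
estimated from the data, not assumed. Reference isoforms must be ≥10 kb,
the sole model in their cluster, ≥5 kb from any neighboring cluster on
either strand, and in the top expression quartile of the surviving
candidates (all four thresholds are arguments; they are concrete
stand-ins for informal "long, robustly expressed, sole-source"
criteria). Each reference's unmasked bin densities are divided by their
own mean (a scale-free normalizer), placed at the canonical coordinate
of the bin midpoint, pooled across references, and loess-smoothed
(span 0.1, fit on the pooled points rather than per-reference curves —
the alternative reading of "averaging … using a loess fit"; pooling
weights references by their bin counts, which is what we want). The
curve is evaluated on a 1000-point grid, floored at 0.05 against
smoothing artifacts, and rescaled so its **median is one**.

The canonical coordinate fixes promoter and terminator scales: for
length $l > 6$ kb the first 3 kb maps onto $[0, 0.2]$, the last 3 kb
onto $[0.8, 1]$, the body onto $(0.2, 0.8)$; for $l \le 6$ kb the first
$0.75\,l$ maps onto $[0, 0.2]$ and the last $0.25\,l$ onto $[0.8, 1]$,
leaving $(0.2, 0.8)$ unused. Applying the profile replaces each design
matrix 1 by the profile density at the bin midpoint's canonical
coordinate; zeros stay zero, and a flat profile reproduces the
uncorrected fit bit-for-bit. With fewer than 5 references the fit is
refused in favor of the flat profile (warning); fewer than 20 warns.

## The simulator

The simulator provides ground truth for benchmarking by resampling
read-count *archetypes* — single-isoform count templates — into
realistic multi-isoform clusters, in five steps: cluster the template
annotations; resample clusters and inter-cluster gaps with replacement;
substitute each isoform by the archetype nearest in genomic length,
keeping the TSS at its offset from the cluster start; draw each
isoform's true abundance from a log-normal distribution
($\mu = 4$, $\sigma = 1.2$ on the log scale, a TPM-like unit — the
stand-in for an empirical isoform-abundance distribution); and draw
per-base counts as Poisson resamples of the archetype counts scaled by
(true abundance / archetype native abundance). Poisson resampling
deliberately allows scale factors above one (amplification), not just
binomial thinning. Overlapping isoforms add, and each isoform also
contributes its archetype's divergent antisense peak just upstream of
its TSS on the opposite strand.

Packaged archetypes are synthetic: a U-shaped body, a Gaussian pause
peak within the first 500 bp, a termination bump near the 3' end, an
upstream antisense peak, and negative-binomial per-base noise
(size 5). The shape is normalized so the *gene-body interior* (past the
pause, before the termination region) has mean density one — "abundance"
therefore means body polymerase density, and peak reads sit on top of
it, as in real data. The default expected body depth is 0.02 reads per
base per abundance unit, which at 1500 genes yields a ~30M-read library,
a realistic bulk PRO-seq scale.

Template annotations are likewise synthetic: 1–6 isoforms per gene
(mean ≈ 2.6), gene bodies log-normal around 12 kb, both strands.
Isoform boundaries are discrete, as real promoters and cleavage sites
are: isoforms either share a boundary up to sub-bin annotation jitter
(≤200–300 bp, collapsed away during binning) or differ genuinely
(alternative TSSs ≥1.2 kb downstream, alternative PASs ≥2 kb apart).
Sixty percent of eligible multi-isoform genes carry an internal-TSS
isoform, which with iid abundance draws makes the truly dominant isoform
use an internal TSS in ~15% of genes — the regime in which read-count
baselines over-normalize by the full gene length.

What the simulator does **not** emulate: transcriptional run-on past the
PAS, enhancer RNAs, unannotated TSSs, mappability gaps, overdispersion
beyond the archetype noise, and zero-abundance annotated isoforms (every
placed isoform is expressed at some level). Passing benchmarks therefore
demonstrate correct mixture recovery under realistic *shapes* and
*overlap structure*, not robustness to every artifact of real libraries.
In particular, the narrow (~3-decade) abundance distribution makes the
read-count baseline's correlations look better than they do on data with
a realistic low-expression tail, because contamination floors barely
register against well-expressed genes.

## The read-count baseline and the benchmark

The baseline (RCB) estimates abundance as
$q_i = r_i \cdot 10^6 / (f_i T)$ with $T = \sum_g r_g / f_g$: reads over
the union of a gene's isoform spans (gene mode), or over the isoform
span trimmed 250 bp after the TSS and 1000 bp before the PAS (isoform
mode, with $T$ still computed at the gene level so values share a
scale). An isoform shorter than its trims falls back to its full span
rather than erroring.

The benchmark compares both methods and the truth in per-million space —
truth scaled to TPM over the gene set, deconvolution weights
self-normalized the same way, the baseline by its own formula. Pearson r
is invariant to this; RMSE becomes comparable across methods because
method-specific global scale factors (peak read mass in totals, profile
scaling conventions) cancel. Three levels are scored: genes, each gene's
truly dominant model, and each gene's longest model; the internal-TSS
stratification uses the truth-dominant model against the gene's 5'-most
annotated TSS, boundary (≥1 kb) inclusive. The 72-scheme option grid
({TSS on/off} × {shape on/off} × {log on/off} × masks {0,1,4}²) can be
run on moderate datasets with `run_option_grid()`.

Problem sizes used by the shipped tests: the full benchmark runs at
1500 genes (≈3800 isoforms, ≈30M reads) with the classifier trained on
an independent 150-gene simulation; property tests use 25–220-gene
simulations. These sizes give stable correlations (repeating at 10× the
gene count changes them only in the third decimal) while keeping the
suite quick.

## Entropy decomposition

With pre-RNA isoform usage $X$ (per-gene probabilities proportional to
pre-RNA abundances) and mature-RNA usage $Y$, and each mature isoform
compatible with exactly one pre-RNA isoform, the joint entropy satisfies
$H(X,Y) = H(Y)$, so the chain rule splits mature-isoform diversity into
a transcriptional part $H(X)$ and a post-transcriptional part
$H(Y|X) = H(Y) - H(X)$, with the transcriptional fraction
$H(X)/H(X,Y)$. Set-level quantities are sums over genes (independence
assumption), reported also per gene; the set-level fraction uses summed
entropies rather than a mean of per-gene ratios, which would be
undefined for single-isoform genes (0/0). Because $X$ and $Y$ come from
different upstream estimators, individual genes can show $H(Y) < H(X)$;
negative conditional entropies are reported as-is and flagged rather
than clipped. Uncertainty comes from bootstrap resampling of genes
(default 100 replicates, seeded).

## Numerical and interface conventions

* Coordinates are 0-based half-open everywhere internally; GTF (1-based
  closed) is converted on read, BED passes through. TSS/PAS are the
  strand-aware interval endpoints.
* Minus-strand coverage files storing negative values are
  absolute-valued on read (the common PRO-seq convention), with a flag
  to disable; missing regions and chromosomes read as zero (with a
  warning for whole missing chromosomes — supply harmonized chromosome
  names).
* Collapsing never merges isoforms of different genes, even with
  identical bins, so gene aggregation conserves abundance exactly;
  cross-gene duplicates instead yield collinear design columns, where
  the fit is non-unique in coefficients but unique in fitted values.
* "At least 1 kb downstream" for internal TSSs is inclusive (≥ 1000).
* Ties in TSS-group representatives go to the longest isoform, then the
  lexicographically smallest transcript id, for determinism.

## Limitations

The method assumes iid Gaussian (or log-normal) bin residuals; real
nascent coverage is overdispersed and autocorrelated, and spiky bins can
pull weight onto short models that happen to coincide with them. Nested
models that share a TSS are identified only through their 3'-end
difference, so closely spaced alternative PASs split weight noisily —
dominant-isoform calls are correspondingly less reliable than gene-level
sums. There is no sparsity penalty and no discovery of unannotated
isoforms; candidates come entirely from the provided annotation.
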