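---
title: "Methods: chromatin and transcriptional analyses of the stomatal lineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin and transcriptional analyses of the stomatal lineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

Stomatal development in the *Arabidopsis* leaf epidermis is driven by
stage-specific bHLH transcription factors (SPCH, MUTE, FAMA) heterodimerising
with SCRM/ICE1. Several questions about this system are quantitative: does
per-cell transcriptional entropy fall as cells commit to guard-cell fate? Do
these factors bind nucleosome-occupied (closed) DNA, and does motif
stringency differ between nucleosomal and open sites? Are the binding sites
of interacting factors spaced in a constrained or relaxed way at co-bound
peaks? Which proteins are enriched around a bait in proximity-labeling
proteomics once multiple controls are accounted for?

This package implements the computational core of each of those analyses —
per-cell Shannon entropy, peak-to-gene annotation, interval-overlap
permutation testing, occupancy-based nucleosome classification, PWM scanning
with motif-presence comparison, binding-site spacing with KS testing, an
expression-plus-binding target rule, and an S0-moderated t statistic with
permutation FDR — together with synthetic-data generators that plant ground
truth for every classifier and test, so the whole pipeline is exercised
end-to-end without any external download. Upstream sequencing steps (read
alignment, peak calling, nucleosome-region calling, clustering, spectral
search) are out of scope: their outputs are the package's inputs.

# Transcriptional entropy

For one cell with counts $c_i$ over genes, $p_i = c_i / \sum_j c_j$ is the
probability of expressing gene $i$, and the entropy is
$S = -\sum_i p_i \ln p_i$, summing over expressed genes ($0 \ln 0 := 0$).
Choices worth stating:

* **Natural log.** Monotone orderings are base-invariant; a `log_base`
  argument converts for display only.
* **No pseudocount, no normalisation.** Probabilities come from raw counts;
  zero-count genes contribute nothing. "Expressed" means a raw count of at
  least 1.
* **Bounds.** $0 \le S \le \ln(\text{genes expressed})$, with equality at a
  degenerate or uniform profile; these are asserted as properties.

The concentration model behind the entropy illustration is deliberately
minimal: a two-level probability vector in which the top
$k = \lceil 0.1\,G \rceil$ genes share a mass $m$ (0.40 or 0.50) uniformly
and the rest share $1-m$ uniformly. Its population entropy has the closed
form $S^* = -[m \ln(m/k) + (1-m)\ln((1-m)/(G-k))]$.

A subtlety matters when validating simulations against $S^*$: the plug-in
entropy of a finite multinomial sample is biased low by roughly
$(K-1)/(2N)$ (about 0.1 nats at $G = 2000$, $N = 10^4$ counts per cell),
which dwarfs the standard error of a mean over hundreds of cells. The
package therefore also provides the *exact* finite-depth expectation,
$E[\hat S] = \ln N - \tfrac{1}{N}\sum_i E[c_i \ln c_i]$ with
$c_i \sim \mathrm{Binomial}(N, p_i)$ (multinomial marginals; the sum is a
truncated binomial series over the two distinct probability values).
Simulated means are checked against this expectation within 3 SE, and the
expectation is checked to converge to $S^*$ as $N$ grows. Default problem
sizes — 200 cells, 10,000 counts per cell, gene numbers 100–2,000 — keep
every grid point's Monte Carlo error tiny while the full curve runs in
seconds.

# Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its parameters and a seed, and each
emits the planted truth needed to score the downstream method:

* `sim_counts()` draws multinomial cells from the two-level model.
* `sim_peak_genome()` emits one contig per peak with i.i.d. uniform ACGT
  background, one site of factor A sampled from its PWM with midpoint at
  the summit, and one site of factor B at `offset + Normal(0, jitter_sd)`
  (constrained/relaxed) or uniform within ±window (random), on random
  strands. Uniform background keeps null log-odds scores exactly zero-mean
  and lets null hit probabilities be enumerated exactly for small motifs.
* `sim_occupancy()` adds a 147 bp plateau (the canonical nucleosome core
  footprint) over half-normal noise |N(0, amp/10)|.
* `sim_lfq()` draws protein baselines N(25, 2) in log2, replicate scatter
  N(0, 0.3) (a typical label-free replicate SD; the concentration of the
  model is between proteins, not within), shifts enriched proteins by
  `+effect` in the bait group, and censors values below the matrix-wide
  25% quantile with the given probability — low-abundance-biased
  missingness, the regime downshifted imputation presumes.

The example G-box PWM uses 0.97 per consensus base, reflecting the
near-invariant CACGTG core of G-box-family ChIP motifs; with a much softer
matrix, consensus-*sampled* sites routinely carry mismatches that fall below
any sensible hit threshold, which models motif degeneracy rather than
planted signal.

Deliberately not emulated: read-level noise (FASTQ, alignment artifacts),
doublets and ambient RNA, GC or mappability structure in the genome
background, correlated nucleosome arrays, and interference between planted
sites (in random mode two sites may overlap; the truth table, not the
sequence, is the reference there). Passing tests therefore demonstrate
correctness of the statistics and classifiers under their stated models,
not robustness to every artifact of real libraries.

# Peaks: annotation, overlap testing, nucleosome classes, metaprofiles

Coordinates are 0-based half-open throughout (BED convention), never
auto-detected; `one_based = TRUE` shifts explicitly on read. "Peak center"
always means the summit (`start + summit_offset`), falling back to the
floored midpoint when no summit exists. Chromosome names are matched
exactly; disjoint name sets raise an error rather than being normalised.

* **Annotation.** A peak overlapping a gene body is assigned to that gene;
  otherwise to the gene with minimal |summit − TSS| within 3 kb
  (inclusive at exactly 3000), signed negative upstream on the gene's
  strand. Ties break to the smaller gene start, then lexicographic id.
* **Overlap permutation test.** The observed statistic is the number of
  peaks in A intersecting any peak in B; the null re-places each A peak
  uniformly on its own chromosome, preserving length. This exchangeable
  null ignores accessibility and blacklist structure and is documented as
  conservative. The empirical p is `(1 + #(null >= obs)) / (1 + n_perm)`.
* **Nucleosome classification.** The mean occupancy over a 147 bp
  summit-centred window is compared to an explicit threshold (default:
  track mean + 1 SD), label nucleosomal when greater than or equal
  (boundary inclusive). This is a transparent thresholding rule, not a
  reimplementation of dedicated nucleosome callers; the scientific claim
  it supports is about relative occupancy at binding sites.
* **Metaprofiles.** Anchor bodies are scaled to `n_bins` bins with
  fixed-width flank bins; minus-strand anchors are reversed; with an input
  track the per-bin value is `log2((num + 1)/(den + 1))` — the pseudo-signal
  of 1 keeps ratios finite and is recorded in output metadata. Anchors
  shorter than the bin count are linearly interpolated.

# Motifs and spacing

PWM columns are `(count + pseudocount) / (N + 4 pseudocount)`; scores are
summed log2-odds against the background (bits), background uniform unless a
4-vector is supplied explicitly — a genome-derived background is an option,
never a silent default. Both strands are scanned (the minus strand via the
reverse-complement PWM, so coordinates stay forward), `N` bases contribute 0
bits, palindromic duplicate hits collapse to the plus strand, and the
default hit threshold is 0.8 × the consensus score — an explicit
configuration value, since no hit threshold is standard.

Hit positions follow one convention everywhere: *midpoint-anchored*. A
hit's `offset` is its midpoint minus the summit, the ±window restriction
applies to midpoints, and the spacing distance at a shared peak is
`offset_B − offset_A` (second-named factor minus first), signed. Ties in
best-hit selection break to smaller |offset|, then leftmost. Center-to-center
distances were chosen over start-to-start because they are invariant to the
two motifs' widths.

The two-sample KS statistic is computed by a sorted sweep with ties handled
by evaluating the ECDF difference at pooled unique values; the p-value uses
the asymptotic Kolmogorov distribution with the Stephens continuity
correction `lambda = (sqrt(ne) + 0.12 + 0.11/sqrt(ne)) D`. A brute-force
ECDF oracle and the reference implementation back it in tests.

Spacing regimes are called in two steps: distances are first tested for
uniformity (KS against Uniform(−window, window), implemented as a
two-sample test versus a dense 10·n grid); non-uniform distributions are
then split at a robust SD (1.4826 × MAD) of 3 bp into constrained versus
relaxed. The uniform reference spans ±window — not ±2·window — because the
generator and the best-hit convention anchor factor A at the summit, so a
non-coordinated partner is uniform over the scan window itself; with both
factors free the support would double, and `window` should then be passed
accordingly. α = 0.01 and s_c = 3 bp are package defaults, exposed in the
interface; the constrained/relaxed distinction is inherently graphical in
origin, so the boundary is a declared convention.

# Target calling

A gene is a target of a TF when (i) it is expressed (raw count ≥ 1) in at
least 25% of the TF-expressing cells, (ii) its log2 fold change against the
out-group is at least 0.223, and (iii) it carries at least one binding site
of the TF within the annotation cutoff. All thresholds are inclusive. The
fold change is computed on per-10k depth-normalised means with a pseudocount
of 1 — a standard single-cell convention chosen because 0.223 ≈ log2(1.168)
matches typical marker-gene floors; the out-group defaults to all cells not
expressing the TF. Raising any threshold provably only shrinks the target
set, which is asserted as a property.

# Proximity-labeling enrichment

The enrichment statistic is SE-inflated: `t_mod = diff / (se_pooled + s0)`
with s0 = 0.5 by default; s0 = 0 recovers Student's pooled t exactly, which
anchors the implementation to a textbook oracle. Imputation draws missing
values from `Normal(mu − 1.8 sigma, (0.3 sigma)^2)` with moments taken from
the whole observed matrix (total-matrix mode); width 0.3 and downshift 1.8
are the conventional defaults of this analysis style and are surfaced in
output metadata. Bait normalisation subtracts the bait's log2 value per
sample and is applied, by default, only to the contrast confounded by
unequal bait expression.

The permutation FDR uses all distinct group-label assignments when the
design admits no more than `n_perm` of them (a 3v3 design has 18 informative
assignments once the identity and its mirror — which reproduce the observed
|t| exactly — are excluded), otherwise a seeded sample. Null |t| values are
pooled matrix-wide, and the FDR at threshold c is estimated as
`((1 + #null >= c) / n_perm) / #obs >= c`. The add-one numerator is the
standard guard against the anti-conservatism of a zero null count at the top
statistic; without it, null-only simulations show rejections in ~14% of
runs at a nominal 5%. Estimates are monotonised with a running minimum over
decreasing |t| (q-value style), so the significant set is always a
|t|-threshold set and shrinks as s0 grows or the FDR target falls. High
confidence requires enrichment in every configured contrast, detection in
at least two bait+biotin replicates before imputation, and MS/MS evidence.

# Pipeline and reproducibility

`run_pipeline()` drives six stages (entropy; annotation; nucleosome
classification; motif presence + spacing; target calling; proteomics) from
a single flat YAML config. Unknown keys are errors; referenced paths are
checked before any stage runs; a failed stage marks its dependents skipped.
Per-stage seeds derive deterministically from the global seed, every output
table starts with `#key=value` metadata headers naming parameters and seed,
numbers are formatted stably, and repeated runs with the same config are
byte-identical. `demo_dataset()` writes a complete synthetic input set with
truth tables sized to run the whole pipeline in well under two minutes.

# Known limitations

* The overlap null ignores chromosome composition effects (no gap or
  blacklist model) and is conservative when binding is confined to a
  subset of the genome.
* The nucleosome classifier is a single-threshold rule on mean occupancy;
  it does not model fuzzy or phased nucleosomes.
* KS p-values are asymptotic; for very small samples an exact or
  permutation p would be preferable (the D statistic itself is exact).
* The spacing analysis considers pairwise distances only — no strand
  grammar, no helical-phase periodicity, no three-factor joint spacing.
* The permutation FDR pools null statistics across proteins, assuming
  exchangeable null behaviour; strong variance heterogeneity between
  proteins would argue for per-protein nulls at a steep cost in
  permutations.
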