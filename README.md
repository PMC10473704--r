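# stomatalchrom

Quantitative analyses of how stomatal-lineage transcription factors interact
with chromatin, for researchers working on regulatory genomics in the
*Arabidopsis* leaf epidermis (and anyone who needs the same statistics on
their own ChIP-seq / scRNA-seq / MNase-seq / proximity-labeling data).

Stomatal development is driven by stage-specific bHLH factors (SPCH, MUTE,
FAMA) heterodimerising with SCRM. Asking whether these factors behave like
pioneer factors raises a set of computable questions, each implemented here
as a tested, seedable operation:

* **Transcriptional entropy.** Per cell, with $p_i = c_i/\sum_j c_j$,
  $S = -\sum_i p_i \ln p_i$ (nats, no pseudocount). A two-level
  concentration model — the top 10% of genes carrying 40% or 50% of
  transcripts — illustrates how entropy rises with expressed-gene number and
  falls with expression concentration; both the infinite-depth closed form
  and the exact finite-depth expectation of the plug-in estimator are
  provided (`two_level_entropy()`, `expected_plugin_entropy()`).
* **Peak integration.** Peak-to-gene annotation by body overlap or nearest
  TSS within an inclusive 3 kb cutoff; interval-overlap permutation testing
  with a length-preserving per-chromosome uniform null; nucleosome
  classification by mean occupancy in a 147 bp summit window versus an
  explicit threshold; scaled metaprofiles with log2((ChIP+1)/(Input+1))
  ratios.
* **Motifs and spacing.** PWM construction with pseudocounts, both-strand
  log2-odds scanning in bits, best-hit selection within ±50 bp of summits
  (midpoint-anchored), motif-presence stringency comparison between peak
  subsets, signed center-to-center spacing at shared peaks,
  a two-sample KS test (sorted ECDF sweep, Stephens-corrected asymptotic p),
  and constrained / relaxed / random spacing calls.
* **Target calling.** Gene is a target iff expressed in ≥ 25% of
  TF-positive cells, log2 fold change ≥ 0.223 (per-10k normalised means,
  pseudocount 1), and bound within the annotation cutoff.
* **Proximity-labeling enrichment.** Downshifted-normal imputation
  (total-matrix mode, width 0.3 SD, downshift 1.8 SD), bait normalisation,
  the S0-moderated statistic $t = \Delta/(\mathrm{se} + S_0)$ with
  $S_0 = 0.5$, permutation-based FDR (exhaustive label assignments on small
  designs, add-one-guarded plug-in estimate, monotonised), and the
  multi-control high-confidence candidate filter.
* **Synthetic data with planted truth** for every stage, and a six-stage
  pipeline (`run_pipeline()`) that is byte-identical under a fixed seed.

## Worked example

Simulate 300 peaks co-bound by a G-box bHLH and a partner factor at a
constrained 8 bp spacing, then recover the spacing from sequence alone:

```r
library(stomatalchrom)

pwm_a <- example_pwm("CACGTG", name = "bHLH")
pwm_b <- example_pwm("TTGACC", name = "partner")
gen <- sim_peak_genome(300, 260, pwm_a, pwm_b, mode = "constrained",
                       offset = 8, jitter_sd = 1, seed = 42)

hits_a <- best_hits(pwm_a, gen$peaks, gen$genome, window = 50)
hits_b <- best_hits(pwm_b, gen$peaks, gen$genome, window = 50)
sp <- shared_peak_distances(hits_a, hits_b)
call <- classify_spacing(sp, window = 50)
```

This prints:

```
shared peaks: 208
modal distance: +8 bp (planted +8)
spacing call: constrained (robust SD 1.48 bp, uniformity p = 3.98e-51)
```

208 of 300 peaks yield a confident best hit for *both* factors (sampled
sites with mismatches fall below the 0.8 × consensus score threshold and
drop out); their signed center-to-center distances pile up at the planted
+8 bp, and the distribution is far from uniform with a robust SD under the
3 bp constrained/relaxed boundary — the signature of a complex binding DNA
as a single unit. The entropy side of the package behaves the same way:

```r
hom <- sim_counts(2000, 100, 10000, seed = 1)
con <- sim_counts(2000, 100, 10000, mass_in_top = 0.5, seed = 2)
# mean entropy: homogeneous 7.496 vs 50%-concentrated 6.978 nats
```

Concentrating half of all transcripts into the top 10% of genes costs about
half a nat of entropy at equal gene number — the behaviour that makes
entropy a proxy for differentiation state.

## Analysis workflow

`analysis/` contains numbered drivers that run the full study on synthetic
data and write tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R    # inputs + planted truth
Rscript analysis/02_entropy.R          # entropy curves and cluster summaries
Rscript analysis/03_nucleosome_motifs.R
Rscript analysis/04_spacing.R
Rscript analysis/05_plms.R
```

Each script states what it found on stdout; `vignettes/` documents the
models, defaults and their rationale.

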