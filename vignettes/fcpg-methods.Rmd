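---
title: "Calling single-cell 5fCpG and quantifying its landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling single-cell 5fCpG and quantifying its landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcpg)
```

## The measurement and its statistical model

5-formylcytosine (5fC) is an oxidized derivative of 5-methylcytosine
produced by TET enzymes during active DNA demethylation. In
chemical-labeling C-to-T conversion sequencing, malononitrile labels 5fC so
that it reads out as T; a formylated CpG therefore shows up as an excess of
T-supporting reads at a cytosine position. Two control molecules spiked
into every single-cell library calibrate the read-out:

* a synthetic model molecule with known 5fC positions measures the
  *labeling (conversion) efficiency* — the probability that a read over a
  true 5fC reads out T;
* unmodified lambda DNA measures the *random C-to-T background* — the
  probability that a read over any unmodified C reads out T (PCR and
  sequencing errors, spontaneous deamination).

At a CpG site with `NT` T-supporting and `NC` C-supporting reads, the
chance of the observed conversion arising from background alone is the
upper binomial tail

$$P(X \ge N_T), \qquad X \sim \mathrm{Binomial}(N_T + N_C,\ p_0),$$

with `p0` the cell's lambda background rate. A point binomial density is
not a p-value; the upper-tail sum is the only direction consistent with
asking how surprising the observed (or stronger) conversion is under the
null, and it is what `binomial_pvalue()` computes (via the exact
distribution function; tests verify it against brute-force enumeration).

## The calling scheme, gate by gate

A site becomes a final 5fCpG call in one cell when it passes every gate:

1. **Candidate pool** — C-to-T ratio at least `ratio_min` (0.65) in at
   least `min_cells_pool` (2) treated cells. This removes PCR amplification
   artifacts private to one library.
2. **Noise pool subtraction** — the same construction over untreated
   (unlabeled) cells defines sites whose high conversion cannot come from
   5fC; candidates found there are vetoed.
3. **SNP mask** — C>T germline variants mimic full conversion and are
   excluded by position.
4. **Per-cell evidence** — depth of at least `min_depth_call` (3) and
   ratio at least 0.65 in the cell being called.
5. **Binomial test with Holm–Bonferroni correction** — the adjustment runs
   across the candidate sites *of that cell* (the natural testing family:
   each cell's calls stand alone), and calls need adjusted p below
   `adj_p_max` (0.01).

Sites covered at least 3 times with ratio at most `ratio_unmod_max` (0.25)
are called unmodified CpGs. Two summary scales follow: **abundance**
(5fCpG calls over all sequenced CpGs, depth ≥ 1) and **level** (5fCpG over
5fCpG + unmodified CpG). Untreated cells run through the identical
procedure; the ratio of their mean abundance to the treated mean is the
false-positive detection rate.

Decisions the scheme leaves open, resolved here:

* **Background rate source.** The rate is estimated per cell from lambda C
  sites covered at least `min_depth_lambda` (4) times; a cell without
  qualifying sites falls back to the rate pooled over all cells'
  qualifying sites (`compute_qc()` records which source was used). The
  per-read reading of the lambda ratio — T read-outs over total read-outs
  at qualifying sites — is the only one that yields a probability usable
  as a binomial null parameter.
* **Pool depth floor.** Pool membership uses the ratio at any depth ≥ 1;
  the depth ≥ 3 gate applies only at per-cell calling. Requiring depth in
  the pooling cells as well would silently couple the pool to coverage,
  which the per-cell gate already handles.
* **Strand handling.** Counts are keyed to the CpG dyad's plus-strand C;
  `read_counts_table(merge_strands = TRUE)` folds minus-strand rows onto
  the dyad coordinate and sums counts. The chemistry does not distinguish
  strands.

## Landscape statistics

* `stage_callset()` merges a developmental stage: union of per-cell calls,
  a commonly covered backbone (depth ≥ 3 in every member cell), and the
  fraction of that backbone formylated in at least one cell.
* `relative_enrichment()` reports, per annotation class,
  `log2[(fc fraction in class) / (background fraction in class)]` with the
  covered CpG set as background. No standard definition exists for
  "relative enrichment" at site level; this fraction-ratio is the
  conventional choice and uses only quantities the pipeline computes.
  Classes with zero background occupancy are `NA`, not infinite.
* `window_profile()` / `window_stats()` tile the genome (1-kb default) and
  measure per-window levels and their cross-cell sample variance (n − 1
  denominator), over windows carrying a 5fCpG site in at least one
  profile. Windows where neither a 5fC nor an unmodified call occurred are
  *excluded*, not zero-filled: zero-filling would conflate absence of
  coverage with absence of formylation.
* `stage_transition()` classifies a later stage's sites as inherited
  (formylated earlier), newly generated (unmodified earlier at depth ≥ 3,
  never formylated earlier), or undetermined (uncovered earlier). Making
  the residual class explicit keeps the three counts an exact partition.
* `correlation_cluster()` uses Spearman correlation over jointly defined
  windows and average linkage on 1 − ρ (a robust, standard choice for
  correlation-based epigenomic clustering; configurable in principle via
  the returned matrix). Pairs with fewer than 3 joint windows are flagged
  undefined.
* `classify_promoter()` applies the canonical 500-bp window criteria: HCP
  when any window reaches GC ≥ 0.55 and CpG observed/expected ≥ 0.75, LCP
  when no window reaches observed/expected 0.48, ICP otherwise. Promoters
  are TSS − 1 kb to TSS + 0.5 kb, strand-aware; the TTS-region class is
  transcript end ± 1 kb.
* `signal_profile()` averages a piecewise-constant track in bins around
  site centers, weighting by covered bases; bins with no track coverage
  are `NA`. The input track is taken as already normalized.
* `matched_repeat_comparison()` draws seeded, size-matched control repeats
  (only unmodified CpG covered) and applies a two-tailed two-sample
  Student t test; `rpkm()` computes
  `count / (length_kb × mapped_millions)`.

For stacked per-element fractions (`assign_sites(mode = "precedence")`)
one label per site is forced by the order promoter > exon > intron >
TTS-region > intergenic — most-specific-regulatory first, so fractions sum
to 1. Enrichment uses `all_overlaps` mode instead, because a site in an L1
inside an intron genuinely belongs to both denominators.

## What the synthetic generator emulates — and what it does not

`make_genome()`, `make_truth()` and `simulate_cells()` generate the
statistical structure the caller assumes, at desk scale:

| parameter | default | rationale |
|---|---|---|
| labeling efficiency | 0.80 | average spike-in conversion of this assay class |
| random C-to-T background | 0.0115 | average lambda rate of this assay class |
| mean depth per site per cell | 5× | typical single-cell coverage |
| true 5fC rate | 5 × 10⁻⁴ baseline | 5fC is rare (10⁻⁴–10⁻³ of CpGs) |
| hot-spot classes | L1, ERVK at 2.5 × 10⁻³ | repeat subfamilies where 5fC concentrates |
| spike-in | 137 C positions, 12 true 5fC | a short model molecule; only counts matter |
| lambda | 500 C positions | unmodified control |

Per-site depth is Poisson with the stated mean, independent across cells;
reads are independent Bernoulli draws. This deliberately omits MALBAC
amplification correlation, region-dependent coverage bias, allele- and
strand-specific effects, copy-number aberration and sequence context. The
one truth class per CpG uses the precedence repeat subfamily > CGI >
promoter > exon > intron > TTS-region > intergenic, so subfamily-specific
rates are exact. Consequently, passing tests demonstrate that the
*inference machinery* is correct under the model it assumes — calibrated
rate estimates, near-perfect precision, coverage-limited recall that rises
with depth and labeling efficiency, null behavior under zero truth — not
that real single-cell libraries satisfy those assumptions.

## Numerical choices and degenerate inputs

* Probabilities are validated at the boundaries; the binomial null must be
  strictly inside (0, 1), while the generator accepts 0 and 1 (noiseless
  limits are useful tests).
* Empty inputs degrade explicitly: empty cell lists give empty pools with
  a warning; an empty candidate pool gives empty call sets; a level with a
  zero denominator is `NA`, never 0; rate estimators with no qualifying
  read raise an undefined-rate error.
* Coordinates: BED files are 0-based half-open, internal CpG positions are
  1-based; conversions happen only in readers/writers and `export_flanks()`.
* All randomness flows through explicit integer seeds (`withr::with_seed`),
  so identical parameters give byte-identical outputs; the bundled demo
  config reproduces its committed reference tables exactly.

## Validation scale

The test suite and acceptance checks run on one chromosome of 1–4 Mb with
~10⁴–10⁵ CpGs and 10 treated plus 4 untreated cells — large enough for
the binomial concentration arguments the checks rely on (3-standard-error
bands, enrichment rank stability over 10 seeds) and small enough to run in
under a minute per scenario on one CPU.

## Known limitations

* The caller tests each site independently; regional smoothing or
  neighbor-aware priors are out of scope.
* Chemistry cannot distinguish 5fC from other conversion-inducing lesions
  beyond what the controls capture; 5hmC/5caC calling is not attempted.
* Cells are assumed euploid and pre-filtered; no copy-number correction.
* Dimensionality-reduction embeddings are not computed — the windowed
  level matrices they consume are exported instead.
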