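---
title: "Anchor-ratio survival screening: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-ratio survival screening: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The screen

`ratiosurv` asks, for every gene *i* in a bulk RNA-Seq cohort, whether the
*relative* expression of an anchor gene — the ratio of the anchor to gene
*i* — stratifies overall survival better than gene *i* does on its own.
The procedure per gene:

1. **Scale.** Normalized expression `x` is mapped to `log2(x + 4)`. The
   offset gives a floor of exactly 2.0 at `x = 0`, so every downstream
   ratio denominator is bounded away from zero, and compresses the heavy
   right tail of expression values.
2. **Ratio.** `r_i(s) = log2(x_anchor(s)+4) / log2(x_i(s)+4)` per subject
   `s`. The transform-then-divide order is deliberate: dividing raw counts
   and then taking logs would reintroduce near-zero denominators, which
   the floor of 2.0 is there to prevent.
3. **Stratify.** The cohort splits at the sample median of `r_i`; ties at
   the median go to the low group, so with an odd cohort the low group is
   the larger one.
4. **Contrast.** A two-sided log-rank test compares the two
   Kaplan–Meier curves, and a univariate Cox model with the single binary
   covariate `I(high ratio)` gives the hazard ratio of the high-ratio
   group relative to the low-ratio group (Efron tie handling, fixed).
5. **Symmetrize and standardize.** `HRsym = HR - 1` for `HR >= 1` and
   `-1/HR + 1` below; this is exactly antisymmetric under `HR -> 1/HR`,
   zero only at `HR = 1`, and strictly increasing. The `HRsym` values of
   all non-skipped genes in the screen are then Z-scored with their own
   mean and sample (n−1) standard deviation into `HRz`.
6. **Filter.** A gene's ratio result is only eligible if
   `p_ratio <= 0.9 * p_single` — the ratio stratification must be at least
   10% more significant than the median split on gene *i*'s own
   expression. This removes genes whose apparent ratio effect is just
   their own single-gene effect wearing a different split.

Genes with `HRz` below the lower boundary and a passing filter form the
`OPCML_plus` group (better survival with high relative anchor expression);
those above the upper boundary form `GENEi_plus`. Everything else is `ns`.

The screen is univariate by design; no covariate adjustment is attempted.
Censoring is honored through the event flag everywhere (log-rank, Cox),
although the default cohort filter — like the inclusion rule of the study
design this emulates — keeps only subjects with an observed death strictly
inside the 10-year horizon.

## Null calibration

Because one screen fits tens of thousands of survival contrasts,
significance boundaries for `HRz` are taken from an empirical null rather
than from normal theory. Each Monte Carlo iteration permutes **every
feature row independently** across subjects and permutes the survival
records (days and event flag as a pair), then reruns the entire screen and
Z-standardizes within the replicate. This scheme was chosen over
alternatives (e.g. permuting subjects wholesale) because it preserves all
marginal distributions exactly while destroying every feature–survival
*and* feature–anchor dependence, which is the null the screen's p-values
assume. Standardizing within each replicate keeps the null self-contained:
no statistic from the real data leaks into it.

The pooled null `HRz` yields the 0.025/0.975 quantiles (the two-tailed
alpha = 0.05 boundaries) and the false-positive rate at the fixed ±2.0
cut, reported both pooled and averaged per iteration (the two agree when
every iteration screens the same number of genes; both are reported
because the averaging convention matters for small feature panels). The
default is 25 iterations; the acceptance check uses 10, which at
189 × 2000 already pools ~20,000 null genes and pins the FP rate to
roughly ±0.004 (binomial standard error).

A note on normality: `calibrate()` records a Shapiro–Wilk p-value on the
pooled null. `HRsym` of a null log-hazard estimate behaves like
`sign(e)·(exp|e| − 1)` for a roughly normal `e`, i.e. symmetric but
slightly heavy-tailed; with tens of thousands of pooled values the test
has power to detect that mild excess kurtosis and will often reject even
though the ±2 tail mass is within a few per mille of Gaussian. The value
is recorded as a diagnostic, not asserted.

Production thresholds default to the fixed ±2.0 boundaries
(`group_thresholds()`); `empirical_thresholds(calibrate(...))` switches to
the calibrated quantiles.

## The synthetic world

The generator states one cohort design and sticks to it:

* **189 subjects** (stage IIIC label throughout), **10-year horizon**,
  features named `OPCML`, `G00001`, … — the design scale of the study the
  screen is modeled on.
* **Expression**: per-feature baseline abundance log-normal across
  features (`meanlog ~ N(log 500, 1.5)`, spanning a few orders of
  magnitude) with subject-level log-normal noise (`sdlog = 0.8`, a
  biological CV typical of bulk tumor RNA-Seq); a negative-binomial option
  (`size = 2`) for count-like realism. Features are pairwise independent —
  no co-expression structure, batch effects or tumor-purity gradients are
  simulated.
* **Survival**: exponential event times at a baseline hazard of 1/1000
  per day (median survival near two years, realistic for advanced serous
  ovarian cancer; no value was prescribed, chosen once). Effect genes add
  `theta` to the log hazard of subjects in the **high anchor/gene ratio
  half**, where the split is the very same median dichotomization the
  screen estimates. That makes `exp(theta)` the true group hazard ratio by
  construction, so parameter-recovery tests are well-defined; it also
  means a *positive* `theta` lands effect genes in the `GENEi_plus` tail
  and a negative one in `OPCML_plus`. Times are rounded up to integer
  days; subjects alive at the horizon are censored there (~2.6% at the
  defaults).
* **Gene sets / citations**: random GMT sets plus one set planted to
  overlap the effect genes at a stated fraction; citation counts drawn
  from a rounded log-normal (heavy-tailed, like real per-gene literature
  counts) and clearly labelled synthetic.

A green test on this world establishes that the pipeline recovers what it
is pointed at — a ratio-linked group hazard under independent noise — and
that its null behavior is calibrated. It does **not** establish robustness
to correlated features, confounded survival, platform effects, or
informative censoring, none of which are simulated.

## Numerical and procedural choices

* **"10% more significant"** is read multiplicatively on the p-value scale
  (`p_ratio <= 0.9 * p_single`); a `-log10` reading exists but is less
  direct, and the factor is a parameter.
* **Cox ties**: Efron, fixed, so results reproduce across implementations.
  Fits with `|log HR| > 15` (separation) or non-finite variance are
  skipped with a reason, as are genes with fewer than two distinct ratio
  values; skips never abort a screen.
* **Anchor outliers** are removed on normalized (pre-log) counts at
  `|Z| >= 6` — far beyond biological variation yet far below the 16.2-sd
  case the rule exists for. The detection scale was an open choice; raw
  versus normalized counts differ only by per-subject factors that the
  anchor's own Z-score largely absorbs.
* **KM p-value**: the log-rank test. The Cox Wald p is exposed in a
  separate column (`cox_wald_p`) for users who prefer the model-based
  test; the two typically agree closely for a binary covariate.
* **ORA universe** = all non-skipped genes of the screen (its actual
  sampling frame), not the genome.
* **Majority rule** counts groups within the *significant member genes* of
  a function (`member_hits`), not the full curated set: the composition
  claim is about what the survival screen found.
* **Dedup** keeps, per repeated function ID, the instance with the highest
  (most conservative) p-value; ties keep the first seen.
* **Clustering**: Jaccard distance on `member_hits`, average linkage,
  cut at `k` (default 20) top-level clusters. Neither metric nor linkage
  was prescribed; Jaccard + average is the standard choice for binary
  membership profiles and is invariant to gene relabeling.
* **OVca pseudocount**: the geometric mean uses `count + 1` and subtracts
  the 1 back (floored at 0), so zero-count genes attenuate rather than
  annihilate a score, and round fixtures stay round. Triage ties break by
  adjusted p, then function ID — no RNG anywhere downstream of the screen.
* **Seeds**: every stochastic step derives its stream from one integer
  seed (kept inside 32-bit range); equal seeds give byte-identical
  outputs, which the determinism test enforces end to end.
* **Config files** are JSON (round-tripping doubles at full precision)
  rather than YAML, keeping the dependency footprint to packages the
  analysis stack already carries.

## Limitations

* Enrichment is plain hypergeometric ORA over supplied GMT collections — a
  declared stand-in for subnetwork-based enrichment over protein
  interaction networks; function counts from such analyses are therefore
  not comparable.
* The literature client ships as an offline fixture interface; live
  citation counts drift with database date and are intentionally outside
  the tested surface.
* The empirical null assumes exchangeable subjects; with informative
  censoring or strong cohort structure the permutation null would be too
  permissive.
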