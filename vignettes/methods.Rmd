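---
title: "Methods: MDL segmentation and one-vs-rest calling of tissue-specific DMRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MDL segmentation and one-vs-rest calling of tissue-specific DMRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A 450K-style methylation array reports, for each of several hundred
thousand CpG probes, a beta value in [0, 1] per sample. Given a panel of
somatic tissues from a few individuals, the question is which *contiguous
blocks of probes* are differentially methylated in exactly one tissue group
relative to all others (tDMRs). Single-probe tests are noisy and ignore the
strong spatial coherence of methylation; region-based tests need a
principled way to decide where regions start and end. `tdmrseg` decides
boundaries by the minimum description length (MDL) principle and then tests
each resulting segment.

# Model and procedure

## Runs (search space)

Probes are sorted by (chromosome, position) and split into **runs**
wherever the gap between consecutive probes is ≥ 3,000 bp (strict `<` rule:
a gap of exactly 3 kb breaks the run). Rationale: inter-probe correlation
of beta values decays with distance, and past a few kb adjacent probes are
essentially independent, so a single region should not span such a gap.
Segmentation and calling never cross a run boundary. The 3 kb cutoff and
the 50-probe maximum segment length are `max_gap` / `max_window` arguments
throughout.

## Description length of a segment

For a candidate segment of $p$ probes and $s$ samples in $G$ tissue groups
($n = ps$ observations), the model is one mean per tissue group, shared
across all probes of the segment, with pooled variance $\sigma^2$:

$$\mathrm{DL} = \underbrace{-\log_2 \hat L}_{\text{data cost}}
  + \underbrace{\tfrac{G+1}{2}\,\log_2 n}_{\text{model cost}},$$

where $\hat L$ is the Gaussian likelihood at the MLE (group means and
$\hat\sigma^2 = \mathrm{RSS}/n$). The parameter count is $G$ means plus one
variance, with the usual $\tfrac12\log_2 n$ bits per parameter (a BIC-style
two-part code). The mechanism that grows segments is the model cost: if two
adjacent probes share the same group-mean structure, one $(G{+}1)$-parameter
model for both costs fewer bits than two separate models, while the data
cost is nearly additive. Conversely a probe whose group structure differs
pulls the pooled fit down and is cheaper to split off.

Design choices worth stating:

* **Pooled means across probes, not per-probe means.** A per-probe-mean
  model would remove the saving that makes merging attractive; pooling is
  what encodes "similar methylation dynamics" as compressibility.
* **Raw beta scale, no M-value transform.** Inputs and outputs stay on the
  scale the effect sizes ($\Delta\beta$) are defined on; the Gaussian code
  is a scoring device, not a claimed generative model.
* **No explicit boundary-encoding term.** Some two-part MDL formulations add
  bits for encoding the cut positions; here that term is omitted and its
  role (preferring fewer segments) is played by deterministic tie-breaking.

## Optimal segmentation

The partition of a run minimizing total DL over segments of ≤ 50 probes is
found by dynamic programming over cut points, $O(\text{run length} \times
50)$ segment evaluations via cumulative sums. Ties within $10^{-9}$ bits
are broken toward fewer segments, then toward lexicographically earlier
boundaries, so output is deterministic. `exhaustive_segment()` enumerates
all $2^{L-1}$ partitions for runs of $L \le 16$ probes with the same
tie-breaking; the test suite checks DP/oracle agreement on 200 seeded
instances. The equivalent of scanning "windows of 1–50 probes" is thus an
exact optimum without window-phase artifacts.

## Calling

For each tissue group $g$ and each segment with ≥ 3 probes:

1. per sample, the mean beta over the segment's probes is taken (technical
   replicates are first averaged into their source sample so they do not
   inflate group sizes);
2. a one-way ANOVA with two groups — $g$ versus all remaining samples —
   yields an F-test p-value on those per-sample means;
3. $p_{\mathrm{bonf}} = \min(1, p \cdot m_g)$, where $m_g$ is the number of
   segments tested for group $g$ (the default `per-group` family; a
   `global` family over segments × groups is available);
4. calls with $p_{\mathrm{bonf}} < \alpha$ (default 0.05) are kept, with
   direction hyper/hypo by the sign of $\Delta\beta$.

Testing per-sample segment means rather than probe-level values avoids
pseudo-replication: probes within a segment are strongly correlated, so
counting each probe-sample value as an observation would overstate the
evidence. Zero between-group variance returns $p = 1$ rather than NaN.

Calls are annotated with the union of gene symbols over their probes, a
promoter-dominant location class (any promoter-region probe ⇒ `Promoter`,
else any genic probe ⇒ `Body`, else `Intergenic`), and the majority CGI
class with ties resolved Island > Shore > Shelf > OpenSea.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `max_gap` | 3000 | bp | run-breaking gap; inter-probe correlation is materially higher below it than above it |
| `max_window` | 50 | probes | maximum segment length |
| `min_probes` | 3 | probes | a region needs at least 3 concordant probes to be credible |
| `alpha` | 0.05 | — | family-wise level after Bonferroni |
| `hi`, `lo` | 0.9, 0.1 | beta | strict thresholds for invariant hyper-/hypomethylation |
| `strong` | 0.5 | PCC | threshold for "strong" methylation–expression correlation |
| `bonferroni` | per-group | — | correction family; `global` multiplies by segments × groups |

# The synthetic-data generator

`sim_config()` / `simulate_dataset()` produce datasets whose structure
mirrors a 17-tissue, 4-individual somatic autopsy panel measured on a
450K-style array, collapsed to 12 tissue groups, with technical replicate
pairs. What it emulates, and how:

* **Probe geography.** Positions are laid down with a two-component gap
  mixture: short within-cluster gaps (geometric, mean 150 bp, probability
  `w_cluster` = 0.9) and long between-cluster gaps (≥ 3 kb plus an
  exponential tail), giving tight probe clusters separated by run-breaking
  gaps.
* **Annotation in zones.** Gene-region and CGI classes are assigned to
  contiguous *zones* (mean ~13 probes) rather than per probe: islands,
  shores and gene regions are blocks in real manifests. Promoter-class
  zones are CGI-dense, body/intergenic zones open-sea-dense.
* **Bimodal baselines.** Mean beta is a function of (region class, CGI
  class): promoter islands 0.05, gene-body open sea 0.90 (the two anchors),
  shelves near full methylation (0.90–0.92 — shelf CpGs are observed to be
  nearly fully methylated), shores intermediate. With the default
  concentration this puts roughly 60% of all values in
  $[0, 0.1] \cup [0.9, 1]$, the qualitative global histogram of somatic
  tissues; the calibration test asserts ≥ 50%.
* **Noise.** Each observation is Beta$(\mu\kappa, (1-\mu)\kappa)$ — values
  stay in [0, 1] and variance shrinks near the boundaries, as on arrays.
  Default $\kappa = 150$ (per-sample sd ≈ 0.04 at $\mu = 0.5$, ≈ 0.018 at
  $\mu = 0.05$); tests that specify $\kappa = 100$ or $200$ set it
  explicitly.
* **Random effects.** Individual effects (sd `individual_sd` = 0.1, logit
  scale) and optional tissue effects (`tissue_sd`, default 0) are drawn per
  *cluster*, shared by the cluster's probes — neighbouring CpGs move
  together across samples, which is what produces the higher short-gap
  inter-probe correlation seen in real data. `tissue_sd` defaults to 0 so
  that with no planted DMRs the tissue groups differ only by noise; the
  variance-decomposition tests switch it on.
* **Planted tDMRs.** DMRs are contiguous blocks placed inside homogeneous
  zones within runs (so they are coherent and in-principle detectable),
  non-overlapping, 3–20 probes, with a logit shift for one target group
  calibrated so the expected beta-scale effect equals the drawn
  $\Delta\beta \in [0.3, 0.5]$. The hypo/hyper direction is flipped when
  the local baseline leaves no headroom (a hypomethylation of 0.4 cannot be
  planted on a 0.05 baseline). Ground truth is returned as a `truth` table
  for recovery scoring.
* **Replicates.** Technical replicates copy the latent $\mu$ of their
  source sample and redraw only the measurement noise.
* **Coupled expression.** `generate_expression()` mixes the standardized
  per-gene methylation profile with Gaussian noise so the expected
  methylation–expression PCC equals a target $\rho$.

What the generator does **not** emulate: probe cross-hybridization, type
I/II chemistry differences, batch and position effects, detection-p
missingness structure, age/environment covariates, and real CGI geography
(zone lengths are geometric, not drawn from a genome). A green recovery
test therefore establishes that the algorithm recovers coherent planted
blocks under realistic noise and bimodal baselines — not that it would
attain the same operating characteristics on any particular real dataset.

## Recovery scoring

A planted DMR counts as detected when at least one call in its target
group, with matching direction, shares a probe with it. A call is a false
positive when it overlaps no planted DMR in any group; calls at a true
locus but in the wrong group/direction count as neither (they are echoes of
real signal, and region-level error is what matters for follow-up). The
acceptance suite requires pooled sensitivity ≥ 0.9 and false discovery
proportion ≤ 0.05 over 50 seeded datasets at $\Delta\beta \ge 0.3$, ≥ 4
probes, 4 samples/group, $\kappa = 100$.

# Numerical conventions

* **Variance floor.** Degenerate segments (zero residual variance) are
  scored at $\sigma^2 = 10^{-6}$, keeping DL finite and comparisons stable.
* **Tie-breaking.** DL ties within $10^{-9}$ bits: fewer segments, then
  earlier boundaries. Clustering sorts tissues lexicographically before
  `hclust`, making dendrograms invariant to input row order.
* **Rounding.** Printed percentages are rounded half-up to one decimal
  (`percent_half_up`), matching the convention of the summary tables this
  package reproduces; R's own `round()` is half-even and disagrees on exact
  `.x5` boundaries.
* **Strict thresholds.** Invariant labels use strict inequalities
  (β = 0.9 exactly is not hyper); strong-correlation thresholds are strict
  (`PCC = −0.5` is not strong); `PCC = 0` counts as positive so the
  negative/positive dichotomy sums to the total.
* **Missing data.** A probe is excluded from an operation only for samples
  where it is missing; segmentation requires complete rows and drops (and
  counts) probes with any missing value. All-missing probes classify as
  `Variable`.
* **Coordinates.** Annotation positions are 1-based; exported BED is
  0-based half-open (`start = first_pos − 1`, `end = last_pos`), score =
  −log10 adjusted p capped at 1000.
* **Multi-region probes.** A probe annotated to several gene regions
  contributes to each region's tally (manifest semantics); distribution
  percentages use the number of (probe, class) entries as denominator so
  they sum to 100.
* **Invariant-fraction denominators.** Published invariant percentages are
  consistent with the pre-filter probe total; `run_pipeline` computes its
  percentages on the post-filter matrix it actually analyses, and both
  counts and percentages are reported so either denominator can be formed.

# Open design decisions, resolved

* **Bonferroni universe.** "Bonferroni correction" does not pin the family.
  Default: per target group (the set of segments tested for that group),
  exposed as `bonferroni = "per-group" | "global"`. Per-group matches the
  one-comparison-per-region reading; global is available for the stricter
  reading.
* **SNP probes.** Filtering trusts a boolean `snp_flag` column; whether an
  upstream list or manifest flag produced it is out of scope.
* **Shore/shelf sides.** North/south variants are collapsed to
  `Shore`/`Shelf` before entry; the analyses never distinguish sides.
* **Expression probe sets.** Multiple expression rows per gene are
  collapsed by median before correlation.
* **Region inclusion rule.** A gene belongs to a region stratum if it has
  ≥ 1 qualifying probe (not all probes qualifying).

# Known limitations

* **Skewed nulls at minimal segment size.** For 3-probe segments at extreme
  baselines (μ near 0.05 or 0.95) with a small target group (4 vs 44), the
  F-test's deep-tail p-values are anti-conservative because beta noise is
  skewed; in a null experiment with artificial fixed 3-probe blocks the
  per-family error rate measured ~0.08 at nominal 0.05. In the pipeline's
  own operating regime this does not materialize (under the null, MDL
  segmentation merges runs into long segments whose per-sample means are
  near-Gaussian; the measured family-wise rate over 200 null pipelines is
  ~0.01), but callers supplying hand-made minimal segments should be aware.
* **No FDR control, covariates, or paired designs.** Bonferroni only, by
  design; no cell-type deconvolution.
* **Upstream processing is out of scope.** Input is a normalized beta
  matrix; IDAT parsing, background correction, dye-bias normalization and
  detection p-values belong to upstream tools, as does expression
  preprocessing (RMA) and probe-set-to-gene mapping.
* **Desk-scale validation.** The test suite validates behaviour on
  simulated data of a few thousand probes; full-array results (hundreds of
  thousands of probes, dataset-specific tDMR counts) depend on the
  particular dataset and constants not reproducible here, and are not
  asserted.
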