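---
title: "Meta-QTL integration on a single physical reference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-QTL integration on a single physical reference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melonmeta)
```

## The problem

Hundreds of melon QTLs have been mapped over three decades, each study on
its own genetic map, its own parents, its own reference assembly. Before
those results can guide candidate-gene cloning they must be brought onto one
physical coordinate system and statistically combined: independent studies
that keep finding a locus in the same place are jointly far more precise
than any one of them. `melonmeta` implements that integration as a
reproducible pipeline with four stages — projection, filtering, landscape
summary, and consensus (meta-QTL) estimation — plus a seeded generator of
ground-truthed synthetic inputs so every stage can be tested offline.

## Projection by flanking-sequence alignment

Each curated QTL contributes two 1-kb flanking sequences, extracted from its
*original* reference immediately outside the mapping interval and named
`<qtl_id>__L` / `<qtl_id>__R`. After alignment to the target assembly
(any PAF-emitting aligner; minimap2 is the natural choice — running it is
out of scope here), the projected interval is bounded by the flank edges
that face the QTL: on a forward-strand placement, the end of the left flank
and the start of the right flank. Three design points the source literature
leaves open, fixed here for determinism:

* **Best-hit policy.** Multi-mapping flanks are resolved by a fixed
  deterministic cascade: primary alignments before secondary, then highest
  mapq, then longest alignment, then lowest (target name, target start).
* **Strand handling.** Both flanks must land on the same strand; on `-` the
  layout is mirrored and the flank roles swap. Discordant strands give
  `failed_orientation` — a conservative failure is preferable to a wrong
  interval.
* **Failure taxonomy.** Every QTL ends in exactly one status
  (`projected`, `failed_flank_missing`, `failed_cross_chrom`,
  `failed_orientation`, `excluded_quarter_filter`), so projection-rate
  summaries can be recomputed per reason and the stage ledger is conserved:
  collected = projected + failed.

**Quarter-chromosome filter.** Projected intervals strictly larger than a
quarter of their chromosome are excluded as positionally uninformative. The
inequality is strict — an interval of exactly one quarter is retained — by a
literal reading of "larger than". The filter is applied to the *physical*
projected interval (its natural position in the pipeline), never alters
coordinates, and is idempotent. Whether the original analysis measured the
physical or the genetic interval is not stated; this choice is flagged here.

**Positional renaming.** Retained QTLs are renamed
`<trait><chromosome>.<rank>` per trait and chromosome, ranks by ascending
locus start, where a *locus* is a single-linkage component of same-trait
intervals under intersection — so a locus replicated by several studies
carries one shared name.

## Landscape summaries

* **Hotspot clusters**: a cluster region is a ≤ 5-Mb window harboring more
  than five QTLs (i.e. ≥ 6), positions taken as interval midpoints. "A 5-Mb
  region" is a rule, not an algorithm, so the scan must be anchor-free:
  every maximal run of ≥ 6 sorted midpoints with span ≤ 5 Mb seeds a
  candidate and overlapping candidates merge, trimmed to member extremes.
* **Same-trait overlap groups** use single linkage (union semantics): the
  replicated loci reported in this literature span up to seven studies,
  consistent with transitive chaining. A group requires ≥ 2 distinct study
  references — replication within one study is not independent evidence.
* **Cross-trait co-localizations** use common-intersection semantics: a
  group is a maximal set of intervals sharing a common point (for 1-D
  intervals these are exactly the maximal cliques of the intersection
  graph) with ≥ 2 distinct traits, and the reported locus is the common
  intersection, never longer than the shortest member. This keeps the
  reported region interpretable; it is a documented divergence risk, since
  the upstream procedure is unstated. Note a geometric subtlety: 1-D
  intervals obey the Helly property, so "pairwise overlapping but no common
  point" cannot occur; a chain A∩B, B∩C with A∩C = ∅ yields two groups.

## The consensus model

Within one trait × chromosome, each retained QTL *i* is reduced to a
Gaussian observation: position $x_i$ (Mb) and known standard deviation
$s_i$. The true architecture is K loci at unknown positions
$\mu_1 < \dots < \mu_K$:

$$x_i \sim \sum_{k=1}^{K} \pi_k \, \mathcal{N}(\mu_k,\, s_i^2),$$

i.e. a Gaussian mixture in which the variances are *per-observation and
known* — components differ only in mean. This is the classical two-step
consensus device: (1) select K and assign members; (2) combine assigned
members by inverse-variance weighting.

* **Position**: the interval midpoint; when the source record carries a
  genetic peak, the peak is placed proportionally inside the projected
  interval (for a centered peak this is the midpoint).
* **sd from CI width**: treating the projected interval as a 95% confidence
  interval, $s_i = w_i / 3.92$ (the conventional $2 \times 1.96$), floored
  at `sd_min` = 0.01 Mb so zero-width literature intervals cannot acquire
  infinite weight. Missing or zero widths take the trait × chromosome
  median width and are flagged, not dropped — silent drops would bias
  counts.
* **Fitting**: EM with responsibilities
  $r_{ik} \propto \pi_k \phi(x_i; \mu_k, s_i^2)$ and precision-weighted
  M-step $\mu_k = \sum_i r_{ik} x_i / s_i^2 \big/ \sum_i r_{ik}/s_i^2$,
  $\pi_k = \overline{r_{\cdot k}}$. Log-likelihoods use log-sum-exp; the EM
  monotonicity guarantee is asserted at every iteration. Restarts: one
  deterministic quantile initialization plus nine seeded random draws of K
  observations; K = 1 is closed-form (the inverse-variance mean), so no EM
  at all. All seeds derive from one integer via a stable string hash, so
  runs are bit-reproducible.
* **Model selection**: AIC $= -2\log L + 2(2K-1)$ over $K = 1..K_{max}$
  (default 5; the upstream cap is unstated), ties toward smaller K. The
  free-parameter count $2K-1$ is K means plus K−1 proportions; variances
  are known, not estimated.
* **Consensus**: members are MAP-assigned; each locus reports
  $\hat\mu = \sum x_i/s_i^2 \big/ \sum 1/s_i^2$,
  $\hat s = (\sum 1/s_i^2)^{-1/2}$, and CI95 $= \hat\mu \pm 1.96\hat s$
  clamped to the chromosome. By construction $\hat s \le \min_i s_i$ with
  equality only for singletons — the interval-reduction property that makes
  meta-analysis worthwhile, and a strict test invariant. Groups need at
  least `min_members = 2` observations (a consensus of one is not a
  meta-analysis); single-member components are kept but flagged
  `singleton`.

Analysis runs in projected physical Mb. The alternative — a consensus
genetic map — is not available for this integration, and projecting first
makes studies directly commensurable.

## What the synthetic generator emulates

`sim_config()` states a world and `simulate_truth()` /
`simulate_studies()` / `emit_synthetic_paf()` realize it deterministically
under one seed:

* 12 chromosomes of 25–40 Mb totalling exactly 379.2 Mb (the real genome's
  total; per-chromosome lengths are a stated default, not data).
* True loci placed uniformly with a minimum same-group separation
  (default 8 Mb) by exact uniform-with-gap sampling, effects 5–30% PVE.
* 20 studies (F2/RIL/DH/BC, n = 60–250), each detecting each locus with
  probability 0.8.
* Observed peak = truth + Gaussian noise. By default (`noise_mode = "ci"`)
  the noise sd equals the sd implied by the study's own CI width — the
  consensus model's generative assumption, which is exactly what parameter-
  recovery tests must probe. `"none"` gives the noise-free oracle limit.
* CI width tied to population size and effect: the Darvasi–Soller-style
  approximation $w = c/(N \cdot \mathrm{PVE\%})$ cM with $c = 530$, a knob
  rather than a biological claim; `ci_mode = "uniform_sd"` instead draws
  the implied sd uniformly (used by the acceptance tests to realize their
  stated 0.3–1.5 Mb range, which realistic N and PVE under $c=530$ do not
  reach). LOD follows $-(N/2)\log_{10}(1-\mathrm{PVE})$.
* One global cM↔bp rate (default 1 cM = 250 kb) so flank placement is
  exactly reconstructable from the emitted table; PAF records are perfect
  primary placements, with corruption modes (dropped flank, cross-
  chromosome flank) to exercise each failure path.

What it does **not** emulate: sequence-level alignment noise and repeat-
induced multi-mapping, study-specific map inflation, shared parents between
studies (observations are independent given the truth), trait correlations,
and real per-chromosome recombination-rate variation. A green recovery test
therefore establishes that the inference machinery is correct under its own
assumptions — not that those assumptions hold for any particular literature
compilation.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally (BED/PAF native); 1-based
  appears only in prose reports.
* `sd_min` = 0.01 Mb; EM tolerance 1e-8 on the log-likelihood; 500
  iteration cap; proportions floored at 1e-12 and renormalized.
* Identical observations collapse gracefully (duplicate means, finite
  likelihood); empty chromosomes report NA means with zero denominators;
  LOD/PVE averages skip missing values and report denominators.
* Tie-breaks are total orders everywhere (hit selection, AIC ties to small
  K, MAP ties to the lower component), so every output is
  permutation-invariant and byte-reproducible.

## Known limitations

* The upstream cluster/overlap/meta procedures are under-specified in the
  source literature; counts such as "47 clusters" or "20 MQTLs" depend on
  those details and on supplementary tables not shipped here, so the test
  suite asserts properties (exact recovery in the noise-free limit,
  K-selection and coverage rates under stated noise, strict interval
  shrinkage, oracle equivalence on small groups) rather than those
  headline counts.
* AIC is the only selection criterion, as stated upstream; no small-sample
  correction is applied.
* The quarter filter is applied to physical intervals; if the upstream
  filter was genetic, retained counts would differ near the boundary.
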