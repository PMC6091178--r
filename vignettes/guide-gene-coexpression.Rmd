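---
title: "Guide-gene co-expression screening: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide-gene co-expression screening: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guideCoex)
```

## The screening model

The package implements a guide-gene co-expression screen over an ordered
developmental gradient transcriptome.  The biological premise is the
guilt-by-association principle: genes acting in the same regulatory process
tend to share expression dynamics across a series of samples in which that
process varies systematically.  The motivating use case is photoperiodic
flowering in rice, where a set of well-characterized flowering-time
regulators (*OsGI*, *Ghd7*, *Hd1*, *Ehd1*, *RFT1*, *Hd3a*, *OsMADS14*,
*OsMADS15*) serves as anchors ("guide genes") and the samples are eleven
consecutive sections of a developing leaf, forming an immature-to-mature
gradient.  A transcription factor whose profile tracks — or mirrors — the
guides across that gradient is a candidate member of the same pathway; a
mirrored (negatively correlated) profile in particular suggests a repressor,
since higher expression of such a gene accompanies lower expression of the
flowering promoters.

Similarity is quantified by the sample Pearson correlation coefficient

$$ r(x, y) \;=\; \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
{\sqrt{\sum_i (x_i - \bar x)^2\,\sum_i (y_i - \bar y)^2}} $$

computed over the ordered samples.  The screen is deliberately simple:
no rank correlation, no partial correlation, no soft thresholding, no
significance testing — the coefficient itself is thresholded.  Two cutoffs
play different roles:

* a **stringent screen** at $|r| > 0.8$ feeds the family-abundance ranking:
  for each guide, the transcription factors passing the screen are grouped
  by family and the five most abundant families are retained;
* a **permissive cutoff** at $|r| > 0.6$ defines the edges of the
  sign-stratified guide–TF network, once a family of interest has been
  singled out.

The family step asks *which kind* of transcription factor is
over-represented among strong co-expression partners of every guide — the
per-guide top-family sets are intersected (a Venn analysis), and a family
present in every set is a robust signal not tied to one anchor.  The
network step then maps *which members* of that family connect to which
guides and in which direction, and candidate negative regulators are read
off as TFs with negative edges to at least `min_negative_partners` guides.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `family_tau` | 0.8 | absolute-correlation screen feeding the family ranking |
| `network_tau` | 0.6 | absolute-correlation cutoff for network edges |
| `strict` | `TRUE` | both cutoffs are strict (`>`), matching a "greater than" reading; set `FALSE` for `>=` |
| `top_k` | 5 | families kept per guide before intersecting |
| `network_family` | `"G2-like"` | family restriction of the network TF pool (`"all"` disables) |
| `min_negative_partners` | 2 | negative edges required to nominate a candidate repressor |
| `venn_guides` | `"all"` | subset of guides used for the top-family intersection |
| `log_transform` | `FALSE` | apply $\log_2(x+1)$ before correlating |

Correlations are computed on the expression values as read (FPKM scale).
Pearson $r$ is not invariant to a log transform, and published gradient
screens of this kind do not state one; the default therefore mirrors the
untransformed procedure, while `log_transform` exposes the sensitivity for
users who want a variance-stabilized view.

`min_negative_partners = 2` is the weakest defensible reading of
"negatively co-expressed with many regulators"; the flagship candidate in
the motivating study had four negative partners, and the cutoff is a plain
configuration knob.

`venn_guides` exists because a screen run over eight guides may be
summarized over a subset (the motivating analysis tabulated four:
*OsGI*, *Ghd7*, *OsMADS14*, *Hd3a*).  Rather than guessing why, the
package lets the user name the subset explicitly.

## Numerical and procedural choices

* **Undefined coefficients.**  A zero-variance profile makes $r$
  mathematically undefined.  Such pairs are stored as `NA`, never as 0:
  a silent zero would be indistinguishable from "uncorrelated" and would
  corrupt the positive/negative sign bookkeeping.  Undefined values never
  pass a threshold, and their count is reported.
* **Self-pairs and bipartiteness.**  A guide is never its own partner.
  The network is strictly bipartite guide–TF: guide–guide and TF–TF edges
  are not emitted, which is the minimal reading of a guide-anchored map.
  A TF co-expressed with several guides contributes one node and several
  edges.
* **Per-gene sign classification.**  Published networks of this kind count
  genes, not edges, as "positively" or "negatively" co-expressed.  A TF
  with edges of both signs is classified by majority; an exact tie is
  reported as `mixed` rather than silently assigned.
* **Tie-breaks in the family ranking.**  Families with equal member counts
  are ordered lexicographically, and a tie straddling the `top_k` boundary
  is truncated deterministically (and flagged).  Any rule here is
  arbitrary; a deterministic one is testable.
* **Export formatting.**  Coefficients in SIF/GraphML/TSV outputs are
  rounded half-to-even to 6 decimals and element order is fully specified
  (edges by guide id then TF id), so exports are byte-for-byte
  reproducible and diffable.
* **Missing input data.**  Empty or `NA` cells in the expression matrix
  are a hard error.  The pipeline assumes a complete, already-quantified
  matrix; imputation is out of scope and failing loudly is safer.

## The synthetic generator

`generateDataset()` realizes a `SyntheticSpec`: anchor profiles over
`n_sections = 11` ordered samples (the gradient design the package
targets), genes planted at chosen correlations to anchors, and a
background of independent noise genes, all with family labels so every
pipeline stage — screen, ranking, Venn, network, candidate selection — is
exercisable without external data.

A planted gene with target correlation $\rho$ against anchor profile $a$
is generated as

$$ y \;=\; \rho\, z(a) \;+\; \sqrt{1-\rho^2}\,\sigma\,\varepsilon,
\qquad \varepsilon_i \sim \mathcal N(0, 1) \ \text{i.i.d.}, $$

where $z(a)$ is the standardized anchor and $\sigma$ is `noiseSd`; the
vector is then shifted to be nonnegative, which leaves every correlation
unchanged.  With $\sigma = 1$ (the default) the population correlation
equals $\rho$ exactly, so the target is attained in expectation; at
$|\rho| = 1$ the noise term vanishes algebraically and the *sample*
correlation equals $\mathrm{sign}(\rho)$ exactly, giving the noise-free
exactness the recovery tests assert.  The `noiseSd` knob scales only the
orthogonal noise component; values other than 1 trade realized correlation
against the nominal target and are intended for robustness exploration.

Anchor shapes are `increasing` (strictly monotone, expression accumulating
towards the mature end), `decreasing` (exactly the reverse of the
increasing profile for the same arguments) and `peaked` (unimodal with one
interior maximum) — the three qualitative patterns a developmental
gradient produces.  A small seeded jitter, bounded by a third of the
deterministic step so the shape contracts survive, prevents distinct
anchors from being perfectly collinear.

Randomness follows a substream contract: a single root seed is combined
with a stable hash of each gene id, so adding a gene to a spec never
perturbs any other gene's profile, and identical specs yield bit-identical
datasets on any platform.

**What the generator does not emulate.**  Gaussian noise on a standardized
scale is not FPKM noise: real FPKM values are heteroscedastic,
approximately log-normal, zero-inflated at low expression, and subject to
library-size and gene-length effects.  Anchors in real data are themselves
noisy and mutually correlated in uncontrolled ways.  Passing recovery
tests on this generator therefore demonstrates that the *pipeline
machinery* (thresholding, sign handling, ranking, intersection, export) is
correct under known ground truth — not that a 0.8 cutoff has any
particular sensitivity or specificity on real leaf-gradient data, where
the correlation null distribution is wider than the independent-noise
null.  The default design (`defaultSyntheticSpec()`) mirrors the study
geometry — 8 anchors, 11 sections, one planted family ("G2-like")
contributing a strong positive and a strong negative partner per anchor, a
weaker decoy family, 200 background genes over six decoy families.

## Validation problem sizes

The shipped tests validate the numerics against naive two-pass and
exhaustive-enumeration oracles on 100 random 20×11 matrices (agreement to
1e−12) and random 5-guide × 50-gene toys; planted-structure recovery is
scored over 200 replicate datasets at $|\rho| = 0.95$ (11 sections, 25
background genes per replicate) plus noise-free $|\rho| = 1$ designs; the
background false-positive rate is checked against an independent
Monte-Carlo null on a 1000-gene background.  These sizes make the whole
suite run in well under a minute while leaving the Monte-Carlo checks
statistically meaningful.

## Known limitations

* Pearson correlation captures monotone-linear association only; a TF
  coupled to the guides through a strongly nonlinear response can be
  missed at both cutoffs.
* With 11 samples the coefficient is noisy (the two-sided null tail beyond
  $|r| = 0.6$ is about 5%), so the permissive network cutoff admits
  false edges at a predictable rate; the stringent 0.8 screen and the
  cross-guide intersection are what keep the family-level conclusion
  robust.
* Results are conditional on the family annotation supplied: substituting
  a different annotation version changes the TF pool and hence node and
  sign counts.  The package pins the annotation it ships and records input
  checksums in the run manifest for exactly this reason.
* The screen ranks and prioritizes; it does not test significance.  Edges
  are hypotheses for downstream genetics, not inferences.
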