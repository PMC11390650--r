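---
title: "Methods: cross-species comparison of exon inclusion"
author: "orthopsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species comparison of exon inclusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthopsi)
```

# Scope and model

`orthopsi` compares alternative splicing of cassette exons (and,
through the same machinery, retained introns) between two species
profiled under two conditions, basal and stimulated. The unit of
analysis is a splice event anchored by four genomic boundaries —
upstream exon end, alternative exon start and end, downstream exon
start — held in 0-based half-open coordinates on the genomic axis.
Replicate junction counts quantify each event: inclusion reads `I`
(spanning either inclusion junction) and skipping reads `S` (spanning
the exon-skipping junction).

## PSI

Per replicate,
$$\mathrm{PSI} = 100\,\frac{I/l_I}{I/l_I + S/l_S},$$
where the effective lengths default to $l_I = 2$, $l_S = 1$ for
junction-count quantification: the inclusion isoform presents two
junctions where the skipping isoform presents one, so raw inclusion
counts accrue at twice the rate per transcript. Replicates are averaged
on the PSI scale (a mean of per-replicate ratios, not a pooled-count
ratio), which keeps each replicate's weight equal regardless of its
depth. A replicate with `I = S = 0` is undefined and excluded from the
mean; an event undefined in all replicates is flagged unquantifiable.

Events are classed primarily included (PI, PSI > 80), primarily skipped
(PS, PSI < 20) or alternatively spliced (AS). The class boundaries as
usually quoted are strict on both sides and leave 20 and 80 unassigned;
we close the outer bins (80 → PI, 20 → PS) so the three classes
partition $[0, 100]$. Two phrasings of the expression filter are in
circulation and both are implemented: `all_samples` (max of `I`, `S`
strictly above the threshold in every replicate of every condition;
used for differential calls) and `mean_over_samples` (mean of the
per-replicate max above the threshold; used for enrichment
backgrounds). The threshold defaults to 5 reads, strict.

## Coordinate lifting

Chain files describe gapped pairwise genome alignments as blocks with
target (`dt`) and query (`dq`) gaps. The package parses them with full
arithmetic validation (block sums must reproduce both spans) and lifts
single positions: the highest-scoring chain covering the position wins,
with deterministic `(t_start, q_name)` tie-breaks; a position inside a
`dt` gap is reported as `gap`, an uncovered one as `unmapped`; positions
lifted through a reverse-strand chain are converted to the forward
strand of the query genome. Events lift boundary-by-boundary —
half-open ends as `(end − 1) + 1` to avoid off-by-one at block edges —
and succeed only when all four boundaries map through the same chain to
the same chromosome with order preserved (or uniformly reversed, in
which case upstream/downstream roles swap and strand toggles).
Interval-level semantics such as liftOver's `-minMatch` are deliberately
out of scope: the matching step applies its own tolerance, so
boundary-tuple lifting is the cleaner primitive. A per-base chain
expansion oracle in the test suite checks every position of synthetic
chains, and `rtracklayer::liftOver` serves as an independent
cross-check.

## Orthologous event matching

A lifted source event and a target event are candidate orthologs when
they share chromosome, event type and post-lift strand, their genes are
paired in the 1:1 ortholog map (when one is supplied), and all four
boundary offsets satisfy $|\delta| \le$ tolerance (default 10 bp,
inclusive — "within ten base pairs" is read as $\le$). Because several
candidates can compete, a 1:1 assignment is chosen greedily by
ascending total absolute offset with coordinate-based tie-breaks; the
result is independent of input order, and on realistically separated
events (≥ 25 bp) it coincides with the exhaustive minimum-total-offset
assignment, which the suite verifies by brute force. Whether gene-level
orthology is demanded before coordinate matching or only used as an
annotation is switchable (`require_gene_match`), since either order is
defensible.

## Differential inclusion

Each event is tested for a condition effect with a likelihood-ratio
test comparing a shared inclusion-read probability against
per-condition probabilities (binomial likelihood, one degree of
freedom; a beta-binomial variant with a shared intra-class correlation
is available for overdispersed replicates). The likelihood is evaluated
on the **raw** junction counts: the map between the inclusion-read
probability $q = \psi l_I / (\psi l_I + (1-\psi) l_S)$ and PSI is
strictly monotone and identical in both conditions, so equal $q$ is
equivalent to equal PSI and the raw-count test addresses exactly the
PSI hypothesis. We considered normalising counts by the effective
lengths before the likelihood (dividing and rounding), but that
under-disperses the data relative to the binomial model and makes the
test conservative (null rejection ≈ 0.027 at nominal 0.05 in our
simulations); the raw-count formulation is exactly calibrated, which
the acceptance suite verifies (type-I error within $[0.04, 0.07]$ at
10,000 null events, depth 100, 3 replicates; power > 0.9 at a true
20-PSI shift). This test is a deliberately simple stand-in for
hierarchical GLM approaches used by dedicated differential-splicing
tools: downstream logic consumes only (ΔPSI, p) per event, and the
effect-size filter dominates behaviour at realistic depths.

Significance applies three strict filters exactly as printed wherever
these conventions are used: raw `p < 0.05`, junction support `> 5` in
all samples, `|ΔPSI| > 10` PSI points (we read "inclusion level
difference > 10" as PSI points, consistent with the companion phrasing
"changed > 10%"). No multiple-testing correction is applied to the
per-event calls by default — the effect-size filter, not the p-value,
is the main gatekeeper — though an rMATS FDR column, when present in
the input, is carried through untouched.

## Percent of maximum possible change

An exon's feasible ΔPSI is bounded by its basal level, so comparisons
of response magnitude across exons (or species) with different basal
PSI are skewed. The normalised statistic is
$$\%\,\mathrm{max} = \begin{cases}
100\,\Delta/(100 - \mathrm{basal}) & \Delta \ge 0\\
100\,\Delta/\mathrm{basal} & \Delta < 0,
\end{cases}$$
undefined at degenerate denominators. A basal PSI of 95 rising to 98
scores 60%, which is why downstream comparisons gate on
$20 < \mathrm{basal} < 80$: tiny absolute changes near the boundaries
otherwise dominate. The gate is applied at comparison time, not inside
the statistic, keeping the operation total for testing.

## Enrichment and correlation statistics

Enrichment of one event class within another is summarised from the
2×2 table $a = |R \cap Q|$, $b = |Q \setminus R|$, $c = |R \setminus Q|$,
$d$ the remainder of the universe, as a **fold enrichment**
$\frac{a/(a+b)}{c/(c+d)}$ (ratio of proportions, conditioning on the
query set by default; conditioning on the universe is available because
either convention is seen in practice and the choice cannot be settled
from summary numbers alone) with a Katz-type log interval, and as an
**odds ratio** with the Woolf standard error
$\sqrt{1/a + 1/b + 1/c + 1/d}$. Two enrichment factors are compared by
the normal approximation to the difference in log odds ratios. The
Fisher exact p is two-sided; zero cells receive the Haldane–Anscombe
0.5 correction for the ratio estimates only, always flagged, never for
the exact p. Pearson correlations carry Fisher-z intervals
($\mathrm{SE} = 1/\sqrt{n-3}$) and a z-based two-sided p; pairwise
dataset matrices are symmetric with unit diagonal and per-cell n.

"Genes expressed at similar levels (within 20% in either direction)"
is implemented as the log-symmetric ratio band $[1/1.2, 1.2]$ rather
than the asymmetric $[0.8, 1.2]$, because the direction of the ratio
is arbitrary; the arithmetic band is available behind a flag.

## Conservation gene sets

The background is the set of genes with at least one orthologous event
pair expressed (mean-over-samples rule) in the target dataset and in at
least one source dataset. A gene is **conservedly regulated** when it
has a significant event in the target species and its orthologous gene
has a significant event in at least one source dataset (gene-level
conservation, following the set-building convention; the stricter
event-level rule — the same orthologous event significant on both
sides — is used for splicing-factor target enrichment, where the exon
itself is the unit). **Species-specific** genes are regulated in the
target species while their ortholog is testable but never significant
in any source dataset. Genes whose ortholog is untestable everywhere
are excluded from the species-specific set rather than included:
absence of evidence in an unexpressed ortholog is not evidence of
divergence. The permissive reading is available via
`include_untestable = TRUE`. Per-term gene-set enrichment is plain
per-term Fisher; ontology-graph decorrelation algorithms (such as
topGO's weight01) are intentionally not reimplemented, so p-values for
nested terms are not mutually adjusted — results are comparable to a
"classic" Fisher analysis, not to weight-adjusted p-values.

# The synthetic generator

The generator emulates the statistical structure of a two-species
splicing comparison with complete ground truth. Genes with cassette
exons are laid on synthetic source chromosomes; target copies arise
through per-chromosome block maps with intergenic insertions and
deletions (the emitted UCSC chain encodes the map exactly), occasional
whole-chromosome strand flips, and per-boundary jitter up to
`jitter_max` (default 6 bp, within the 10 bp matching tolerance) for
orthologous events. Gaps never cover an orthologous boundary, so
planted orthologs are liftable by construction; a configurable fraction
of decoy events straddle gaps to exercise failure paths, and
non-orthologous target genes sit outside the chain's query span.

True basal PSI is drawn from a PI/PS/AS mixture on the logit scale
(class means ±2.2 and 0, standard deviations 0.7–0.8), with the
cross-species correlation imposed on the logits through a Gaussian
copula — PSI is bounded, so correlating logits is the well-defined
choice — and the **realized** PSI-scale correlation recorded in the
truth tables so recovery tests compare like with like (sharing class
membership across a pair adds between-class correlation on top of the
within-class copula, so realized PSI correlation exceeds the logit
parameter; with the default mixture and a logit correlation of 0.7 the
realized basal-PSI correlation is ≈ 0.95, in the range seen in real
cross-species neuronal comparisons). A fraction of orthologous pairs
(default 15%) respond to stimulation; half of those (default) respond
in both species with a shared direction and correlated magnitudes
(|ΔPSI| ~ Normal(25, 5), correlation 0.8), the rest in exactly one
species. Response direction is drawn with a 0.35 probability of
increased inclusion — activity-induced skipping being the more common
direction in neurons — and flipped when it would overshoot a PSI
bound, the realized values being what the truth records. Replicate
counts are Poisson totals (expected depth 200, 3 replicates by
default) split binomially with
$p^\* = \psi l_I / (\psi l_I + (1-\psi) l_S)$, so the PSI estimator is
centred on the truth; a beta-binomial option adds replicate-level
overdispersion. All randomness derives from the single configuration
seed; bundles rewrite byte-identically from their JSON manifest.

What the generator does **not** emulate: read-level artefacts
(mapping bias, positional coverage), annotation errors, correlated
expression changes, partial gene-level orthology (the map is strictly
1:1), or overdispersion beyond exchangeable beta-binomial replicates.
Passing recovery tests therefore demonstrates the correctness of the
pipeline's logic under its stated model, not robustness to those
real-data pathologies.

# Problem sizes and numerical choices

The default study conditions — 1250 genes × 2 events, 80% orthologous
(2000 orthologous pairs), depth 200, 3 replicates — were chosen as a
desk-scale replica of a cortical-neuron comparison: large enough that
matching rates, correlations and gene-set recovery are estimated with
useful precision (the Fisher-z interval at n = 2000 spans about ±0.03
at r ≈ 0.95), small enough to simulate and analyse in seconds.
Calibration suites use 10,000 null events (type-I error), 500
correlation runs and 2000 table pairs, sized so that the binomial
Monte-Carlo error is well inside the asserted bands. Ties in chain
selection and event assignment are broken lexicographically for exact
reproducibility; boundary conventions are inclusive tolerances
(≤ 10 bp), strict significance thresholds, closed outer PSI classes
and an open basal-PSI gate, each asserted by boundary tests. Degenerate
inputs (all-zero replicates, empty universes, zero-variance
correlations, query-equals-universe tables) return flagged results
rather than errors wherever a downstream stage can continue.

# Known limitations

* The differential test ignores replicate-level overdispersion by
  default; the beta-binomial variant exists but costs a per-event
  optimisation, and neither reproduces the hierarchical per-sample
  uncertainty models of dedicated splicing tools.
* Fold-enrichment conditioning conventions differ across published
  analyses; both are implemented, but numeric comparability with any
  specific published value depends on which convention that analysis
  used.
* Term enrichment is plain Fisher; weight-adjusted ontology p-values
  will not match it numerically.
* Matching is purely coordinate-based; exons that moved more than the
  tolerance, or genes outside the 1:1 map, are invisible to it by
  design.
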