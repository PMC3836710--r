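---
title: "Substitution dynamics around nucleosome dyads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substitution dynamics around nucleosome dyads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsub)
```

## The problem

Nucleotide substitution rates around nucleosome dyads differ from the
genomic background: weak-to-strong (A/T to G/C) changes are more common
near experimentally mapped dyads, strong-to-weak changes further away.
Three forces can in principle produce such a pattern:

1. **Mutation bias** — the nucleosome modulates local mutation or repair
   rates;
2. **Selection** — purifying selection preserves sequence that keeps the
   nucleosome in place;
3. **Repositioning** — nucleosomes move in response to sequence change,
   so the observed dyad positions are themselves an outcome of the
   substitutions.

The three are distinguishable through a focal/sister comparison. Dyads
are mapped in one (focal) species; substitutions are assigned by
parsimony to the focal and sister branches of a species triplet and
profiled against the focal dyads. Mutation bias and selection act on
both branches at orthologous positions and predict *concordant* trends;
repositioning couples the focal dyads to the focal branch's own
substitutions and predicts trends in the focal lineage with flat sister
profiles. `dyadsub` implements the full analysis path and a forward
simulator that generates data under each of the three regimes.

## Substitution calling

`call_substitutions()` applies three-taxon parsimony per alignment
column: where focal and sister disagree and the outgroup matches one of
them, the mismatching lineage carries a substitution from the outgroup
(ancestral) base; columns where the outgroup matches neither are
skipped, as are columns containing gaps or ambiguity codes. Columns
adjacent to gaps are kept — there is no indel exclusion zone by default.

Two site classifications are provided. `fourfold_mask()` marks third
positions of 4-fold degenerate codon families (derived from the
standard genetic code, minus-strand CDS evaluated on the reverse
complement), skipping transcripts with frame violations or internal
stop codons. `flag_cpg()` marks substitutions whose *ancestral* base
was a C followed by an ancestral G (or the strand-symmetric
equivalent), using the reconstructed ancestral states of the flanking
columns rather than the extant focal sequence — the deamination
hypothesis concerns the ancestral CpG, not the extant one. Contig-edge
substitutions with a missing flank are conservatively non-CpG.

With the simulator's default configuration the outgroup branch has
length zero (the outgroup *is* the ancestor), which makes parsimony
exact at every position substituted on at most one branch. Positions
hit on both branches are unidentifiable in principle — the outgroup
matches neither ingroup base and the column is skipped, which is the
same filter the empirical pipeline applies. At the default divergence
(0.003–0.005 substitutions per site) such positions are of order
`L * mu^2`, i.e. about one per 50-kb triplet.

## Dyad-anchored profiles and trend tests

`build_profile()` bins substitutions of one strand-symmetric base-change
category by absolute (folded) distance `0..max_dist` to the nearest
focal dyad. Distances are folded because the two flanks are equivalent
under strand symmetry; a site within reach of two dyads is counted once,
at the nearer one. The denominator at each distance is the number of
*eligible* sites: mask-eligible ancestral positions carrying the
category's source state (W or A/T for weak-to-strong, S or G/C for
strong-to-weak), so `rate = substitutions / opportunities` and
compositional gradients around dyads cancel out of the rate.

`weighted_linear_trend()` fits rate against distance by weighted least
squares with the eligible-site counts as weights (via `stats::lm`) and
reports the two-sided t-test p-value for zero slope; no multiple-testing
correction is applied because the six categories are reported
separately. `lowess_profile()` overlays a locally weighted regression
with tricube weights over the nearest `ceiling(f * n)` points and three
bisquare robustifying iterations; the default span is `f = 0.6`. The
smoother is implemented in the package because its neighbourhood rule is
part of the package's documented contract (`ceiling(f * n)`), which the
floor-based neighbour count inside `stats::lowess` does not match; the
test suite checks it against a direct per-point local-regression
computation at 1e-6 and against `stats::lowess` at loose tolerance.

`classify_trend_pair()` reduces a focal/sister pair of fits to one of
four classes at a significance level `alpha` (default 0.05):
`concordant` (both significant, same sign), `discordant` (both
significant, opposite signs), `focal_only`, `none`.

Default geometry: `max_dist = 100` nt suits the 147-nt eukaryotic
footprint plus linker; `max_dist = 60` with `footprint = 85` suits the
archaeal tetramer geometry. Both are plain arguments.

## Occupancy scoring and local shift metrics

All occupancy operations are scorer-agnostic: a scorer is any function
`(genome, pos) -> score`, and `track_scorer()` adapts precomputed
per-nucleotide score tables from external occupancy models. The default
`gc_scorer(window)` is the mean GC fraction of a centred window of the
footprint width — GC content is the dominant, strand-symmetric
correlate of nucleosome affinity in both eukaryotes and archaea, and
its integer window counts make argmax tie-breaking exact.

`compute_offset_D()` reports the signed offset from a dyad to the
highest-scoring position within ±`halfwidth` (default 100 nt); ties
resolve to the smallest absolute offset, then the negative side, which
matters on synthetic homopolymers where ties are guaranteed.
`delta_D()` takes the difference `D_ancestral − D_extant` at the same
dyad coordinate on a gapless ancestor/extant pair: a measure of how the
locally most attractive position moved. `single_substitution_windows()`
restricts to dyads with exactly one focal substitution within
±`halfwidth`, so the shift can be attributed to an individual change.
Note the *influence radius* of a substitution is
`halfwidth + (window−1)/2`: a change up to 173 nt away (defaults) can
alter scores of in-window positions, so `delta_D` can be nonzero for a
dyad with no substitution inside ±100.

`periodicity_profile()` summarises nonzero `|delta|` values as the
fold-enrichment of lags within ±1 nt of multiples of ~10 nt (the
rotational spacing) over the remaining lags. Because no well-defined
random expectation exists for these lags, the reference is a uniform
permutation interval reported descriptively, not as a p-value.

## The simulator

`simulate_triplet()` builds one dataset: an i.i.d. ancestor with target
GC content, nucleosomes placed greedily by descending affinity with a
`footprint + min_linker` exclusion (deterministic given a seed, which
only breaks exact score ties), two branches evolved independently, and
the ancestor reused as outgroup. Per site, the directed change X>Y
occurs with probability `(mu/3) * spectrum(X>Y)`, multiplied by the
category's `dyad_bias` within half a footprint of a dyad; at most one
substitution per site per branch (star-like, appropriate for the close
divergences at which the analysis is informative and required for exact
parsimony). Selection, when enabled, is rejection sampling: a candidate
whose single-change re-optimised dyad offset exceeds `sel_threshold`
(default 10 nt) is rejected with probability `selection_s`; candidates
are evaluated independently against the ancestral background plus that
one change, consistent with the single-hit regime.

### The repositioning model

Two repositioning operations exist and differ deliberately.

`reposition_dyads()` is plain local re-optimisation: each dyad moves to
the scorer argmax within ±`search_halfwidth`, ties toward positional
inertia, spacing re-enforced in descending score order (a displaced dyad
takes its best admissible in-window position and is dropped only if none
exists). This operation is useful for re-calling positions on a changed
landscape, but it is *not* what branch evolution uses, for a
quantitative reason established during development: greedy placement
anchors every dyad at a local maximum of the very score being
re-optimised, and a single substitution changes any GC window score by
only ±1/window, so it flips the incumbent argmax in well under 10% of
cases regardless of window width. At realistic divergence the resulting
dyad movement is an order of magnitude too rare to couple dyads to
substitutions detectably.

`reposition_biased()` is therefore the evolutionary model: nucleosomes
shift *in response to* the changes themselves. A dyad with an
affinity-increasing (W>S) change within its search window re-optimises
over the admissible positions centred within `attract_radius` (default
10 nt, one helical turn — rotationally equivalent positions are the
locally available alternatives) of any such change; a strengthened
contact is most effective near the dyad axis, so changed sites act as
attractors and the scorer picks among their neighbourhoods. A dyad with
only affinity-decreasing (S>W) changes under its footprint re-optimises
over in-window positions whose footprint excludes all of them, staying
put when escape is impossible. GC-conserving changes trigger no
movement, and dyads without triggering changes keep their position —
which is exactly why sister-branch substitutions, being uncoupled from
the focal dyads, produce flat profiles under this regime.

### Presets and study conditions

`scenario_preset()` bundles the five regimes: `null`,
`mutation-bias-only` (weak-to-strong rate doubled inside the
footprint on both branches, no repositioning), `selection-only`
(`selection_s = 0.8`), `repositioning-only`, and
`bias-plus-repositioning`. The default conditions — 200-kb genomes at
GC 0.5, footprint 147 nt, minimum linker 30 nt, `mu = 0.003` per
branch with a uniform spectrum, `search_halfwidth = 73` — are a
realistic close-divergence regime: roughly one substitution per two
nucleosomal domains per branch, the range in which single-substitution
attribution is meaningful. `run_scenario()` executes the replicates,
re-calls substitutions by parsimony, profiles both lineages against the
focal dyads, and tabulates trend-class frequencies per category
(including pooled `W>S` and `S>W`).

Reproducibility: replicate `i` of a scenario with master seed `s` uses
seed `(s + 1000003 * i) mod (2^31 − 1)`; within a replicate the
ancestor, placement, focal and sister stages use that seed plus
0, 1, 2, 3. The large replicate stride keeps stage streams from ever
colliding across replicates.

```{r scenario, eval = FALSE}
out <- run_scenario(scenario_preset("repositioning-only", n_reps = 50,
                                    seed = 1))
out$class_freq
summary(out)
```

## What the synthetic data does and does not emulate

The generator reproduces the *design* of the comparative analysis —
gapless orthologous triplets, dyad calls on the focal species,
close-divergence substitution counts, GC-driven positioning — under
fully known ground truth. It deliberately omits: indels and alignment
error (real triplets are alignment-filtered), rate heterogeneity beyond
the dyad bias (no CpG hypermutability, no regional mutation-rate
variation), realistic occupancy models (the GC scorer replaces trained
sequence models; `track_scorer()` accepts their output), histone
variants and modification states, and any thermodynamic ensemble of
overlapping nucleosome configurations. Passing tests therefore show
that the *inference machinery* recovers each planted regime and is
calibrated under the null — not that real genomes evolve under any
particular regime, and not that empirical effect sizes are reproduced.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; BED is native, GFF3 is
  converted on read; every output table carries a provenance header
  (package version, seed, config hash, conventions).
* Distances to dyads fold both flanks; `signed = TRUE` is available.
* Rates are undefined (and excluded from fits) at distances with zero
  eligible sites; trend fits require at least three usable distances;
  a category with zero substitutions in a replicate contributes the
  class `none`.
* Exactly constant rate profiles return slope 0 with p = 1 (an exact
  zero-residual fit otherwise produces an ill-defined t statistic).
* Argmax ties anywhere (placement, repositioning, offsets D) are broken
  deterministically: smaller |offset| first, then the lower coordinate;
  placement breaks exact affinity ties by a seeded random order.
* Problem sizes in the shipped tests: unit tests run on 5–50-kb
  genomes; the end-to-end suite uses 100 triplets at 50 kb for the
  parsimony oracle, 200 null replicates and 50 replicates per recovery
  scenario at 200 kb — the same conditions the presets default to.

## Known limitations

* The substitution-coupled repositioning rule is deterministic
  (attraction always wins over repulsion when both apply); a
  probabilistic mobility parameter would be a natural extension.
* Selection re-scores candidates one at a time, so epistasis between
  same-branch substitutions within a footprint is ignored.
* Parsimony misassigns nothing only because the default outgroup branch
  has length zero; with a nonzero outgroup branch (supported via
  `scenario_spec(outgroup = ...)`) the usual parsimony caveats apply.
* The periodicity descriptor is intentionally descriptive; it inherits
  the lack of a defensible null distribution for shift lags.
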