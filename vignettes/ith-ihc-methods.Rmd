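---
title: "Methods: clonal ordering of IHC loss patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal ordering of IHC loss patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ithIHC)
```

# The measurement model

The unit of observation is a *focus*: one core of a tissue microarray,
scored for nuclear staining of a marker protein. `ithIHC` starts from
ordinal scores (0/1/2) or staining fractions; `call_score()` maps a
fraction $f$ to

$$\mathrm{score}(f) = \begin{cases} 0 & f \le t_0 \\ 1 & t_0 < f \le t_1 \\ 2 & f > t_1 \end{cases}$$

with defaults $t_0 = 0.05$, $t_1 = 0.50$. The loss boundary is
*inclusive* at 5% — "0–5% positive" counts as loss — and both thresholds
are exposed as arguments because the written convention at exactly 5%
staining is genuinely ambiguous in this assay tradition. Score 1 (weak,
spotty staining) is deliberately treated as *retained*: it is the
conservative reading, and distinguishing degraded staining from partial
loss is a wet-lab question, not a computational one.

A tumor loses a marker when **any** evaluable focus scores 0
(`tumor_marker_loss()`). This mirrors how a single-biopsy DNA study would
call a subclonal mutation: detection anywhere counts. The rule is
monotone — adding foci can only flip a tumor call from retained to lost —
and it is why tumor-level prevalence generally exceeds focus-level
prevalence.

Missing cells are *non-evaluable*, never imputed. Absence of signal on a
failed core is not evidence of loss; non-evaluable cells are excluded from
support sets, denominators and 2×2 tables. Dual-pathologist scoring is
assumed to be consensus-resolved upstream; the reader reports but never
auto-resolves discordant inputs.

## A boundary case worth knowing

Tumor-level prevalence $\ge$ focus-level prevalence is a theorem only when
every tumor contributes the same number of evaluable foci: then
$\sum_i l_i \le f \cdot \#\{i : l_i > 0\}$ divides through by $Nf$. With
unequal denominators — the cohort design includes one two-focus tumor, and
missingness shrinks per-marker focus counts — a marker whose few losses
are all truncal can violate the inequality by a hair (e.g. one fully lost
tumor: $1/40 < 4/158$). The test suite therefore asserts the strict
per-stratum inequality on equal-foci cohorts, and the cohort-level
per-marker inequality on full-size study-design cohorts, where the mixture
of truncal and subclonal losses makes it robust.

# Clonal ordering

For one tumor, the *support* of a marker is the set of evaluable foci in
which it is lost. `extract_events()` groups markers with identical support
into one *loss event* — co-occurring losses in exactly the same foci are
most parsimoniously one clonal event (this is also how bundled losses such
as ARID1A+BRM appear in practice). Markers never lost produce no event.

Two support sets can be equal, nested, disjoint, or *conflicting*
(overlapping, neither containing the other; `pair_relation()`). A family
of sets that is conflict-free — a **laminar family** — is exactly the
structure representable as a rooted tree, and `build_tree()` builds it
directly: the root is the loss-free founder (WT) supported by all
evaluable foci; each event's parent is the event with the smallest support
strictly containing it, or the root.

Conflicts cannot be drawn as a single tree. The default `split` policy
interprets them as convergent evolution: the event later in the
deterministic order is split on its intersection and difference with the
event it conflicts with, and the pieces are carried as parallel,
independent occurrences of the same marker loss. The split is greedy and
per-event minimal: each event is cut into as few pieces as any partition
of its support compatible with the family accepted so far (the test suite
verifies this against exhaustive enumeration of set partitions). A piece
whose support coincides with an existing event merges into it, keeping
supports unique so that sibling supports stay pairwise disjoint. A
`strict` policy errors instead, for auditing. Whether conflicting patterns
occur in real TMA data at all cannot be settled here; the policy is
surfaced rather than buried.

Determinism is a design goal throughout: events are ordered by descending
support size, ties broken by the fixed marker registry order (PBRM1,
ARID1A, SETD2, BRG1, BRM), and siblings inherit that order. Identical
input yields byte-identical trees and Newick strings.

## Truncal versus branch, and tree shapes

An event attached to the root is **truncal** when its support covers at
least $\tau$ of the denominator foci, default $\tau = 0.75$ over evaluable
foci — "all or most regions", and the value under which a 3-of-4-foci event
is truncal, matching the canonical worked example whether or not its
fourth focus was evaluable. All other events are **branch**. A root
child below the threshold is labelled branch but flagged, since
topologically it heads a trunk. The denominator is switchable to
`"any-loss"` (foci carrying at least one loss) because the source material
is ambiguous about whether loss-free foci were evaluable in its drawings;
neither convention is privileged.

Shapes: `NO_LOSS` (root only), `MULTI_TRUNK` (root with ≥ 2 immediate
lineages), `BIFURCATED` (some non-root node with ≥ 2 children), else a
chain — `TRUNK_ONLY` at depth 1, `BRANCHED` deeper. The trunk-only /
branched distinction is depth-based on purpose: one event covering the
tumor is a trunk, a nested chain is a trunk with a branch.

Newick serialization labels internal nodes (`((PBRM1+BRG1)ARID1A+BRM)WT;`),
uses `+` to join markers of one event, and omits branch lengths, which
have no meaning here.

# Co-loss statistics

`contingency()` counts joint loss at tumor or focus level, excluding units
non-evaluable for either marker. Focus-level tables pool foci across
tumors and therefore ignore within-tumor correlation; that replicates the
original analysis procedure and is documented rather than "fixed", because
changing it would change what the numbers mean.

`fisher_two_sided()` is implemented from log-factorials. Two-sided exact
tests have competing definitions; this one uses the **point-probability
method**: the p-value is the sum of hypergeometric probabilities, over all
tables with the observed margins, of tables whose point probability is at
most that of the observed table, with relative tolerance $10^{-7}$ on the
comparison. That matches the most common implementations and is verified
in the tests against full enumeration (all tables with total $\le 40$, to
$10^{-12}$) and against an independent reference implementation. Degenerate
margins (an empty row or column) give $p = 1$ by convention, flagged. The
exact test is conservative on discrete tables: its true size at
$\alpha = 0.05$ is about 0.038 for 160 balanced units and approaches the
nominal level as tables grow; the calibration test uses 640-unit tables
for that reason.

Odds ratios use the cross-product, optionally with the Haldane 0.5
correction; `all_pairs()` adds Benjamini–Hochberg q-values across the
pair × level tests as a companion — raw p-values remain the replication
output, since the original analysis reported raw p only.

# The synthetic cohort generator

`simulate_cohort()` exists so that every stage of the pipeline can be
tested against known truth. Its defaults *are* the study design: 160
tumors, 40 per stage, four foci each, one stage-I tumor with two foci,
five markers.

**Generative model.** Per tumor: co-loss bundles (default
{PBRM1, ARID1A} and {BRG1, BRM}, mirroring the strong observed co-losses)
are sampled first as single events; remaining markers draw independent
truncal or branch events. All truncal events sit on one trunk clone
present in every focus; each branch event is its own clone attached
uniformly at random below the trunk, or to the root when no trunk exists
(which is what produces multi-trunk tumors). Every focus is then assigned
to exactly one clone, categorically with weight 1 for the trunk and a
Beta(2, 2) clone fraction per branch clone; a marker is truly lost in a
focus iff an ancestor-or-self clone carries its event. Scores are 0 where
lost, otherwise 2, or 1 with the score-noise rate (default 0.10 — weak
staining is common but a minority); cells are blanked at the missing-cell
rate (default 0.02, a typical TMA core-failure scale). Stage enters only
as a per-marker multiplier on the loss probabilities, normalised to mean
1, taken from the study's per-stage prevalence profile — a descriptive
trend, not a biological model.

**Calibration.** Under the Beta(2, 2) clone-fraction model a branch clone
receives no focus with probability
$\mathbb{E}\,(1+\varphi)^{-4} = 0.25$, so planted branch and bundle
probabilities are inflated by the corresponding observation factors
($1/0.75$ for branch events, $1/(0.5 + 0.5 \times 0.75)$ for bundles at
the default 50% truncal share) so that *observed* tumor-level prevalences
match the study's printed per-marker means (31/51/14/15/38%). This
arithmetic was done once, analytically, and the resulting defaults are
fixed. Focus-level prevalences come out somewhat above the study's
(roughly 0.75 of the tumor-level value rather than 0.55–0.65) because half
of planted losses are truncal; lowering the truncal share would trade one
marginal for the other, and tumor-level fidelity was chosen as the anchor.

**What the generator does not emulate:** spatial autocorrelation between
foci (clone assignment is independent per focus), copy-number or mutation
processes, scoring drift between pathologists, or any biological
stage–loss mechanism. Passing recovery tests therefore demonstrates
algorithmic correctness on data *shaped like* the study's, not clinical
validity on real TMAs.

**Ground truth and identifiability.** The observable truth tree merges
planted events with identical realized support — two truncal events are
one node, because no assay can separate them — and ground-truth
truncal/branch labels are positional: the same prevalence rule applied to
the planted tree. With no score noise, no missing cells and every clone
sampled by at least one focus (`require_all_sampled = TRUE`), the pipeline
provably recovers the planted tree exactly; `recovery_report()` checks
label-preserving topology identity via a canonical serialization
(children sorted lexicographically, so sibling order is irrelevant),
truncal/branch label agreement per marker, and support-set Jaccard.
Branch clones sampled by no focus are counted as sampling misses, not
errors — they are unobservable in principle.

# Numerical and testing choices

- Exhaustive oracles are used where the state space permits: all 135,750
  2×2 tables with total ≤ 40 for the Fisher test; all 65,536 4×4 binary
  matrices for event grouping; all 1,941 families of ≤ 4 distinct
  non-empty supports on 4 foci for tree construction (topology depends
  only on the support family, so this is equivalent to enumerating all
  matrices).
- Stochastic checks use fixed seeds and pre-computed tolerances: tree
  recovery on 500 noiseless fully sampled tumors (exactness is the
  designed property, so the expected rate is 1.0, not "high"); Fisher
  type-I calibration on 1,000 null tables of 640 units, sized so the exact
  test's conservatism stays within three binomial standard errors of the
  nominal level.
- Degenerate inputs are defined, not accidental: empty score tables error
  (`"no records"`); tumors with a single focus are retained with a
  warning; a tumor with no evaluable focus is dropped from tree building;
  zero-margin 2×2 tables give $p = 1$ flagged; zero conditional-co-loss
  denominators give `NA` flagged.

# Limitations

Protein loss is an imperfect proxy for genetic inactivation (mutations
without expression change, losses without mutation). Four foci bound the
resolution of clonal ordering: events are unordered within a node, nested
chains deeper than the focus count are unobservable, and a branch event
can be missed entirely. The convergence (`split`) interpretation of
conflicting supports is a modelling choice that real multi-region
sequencing could contradict. Focus-level pair tests inherit the pooling
caveat above. Survival and outcome analyses are out of scope.
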