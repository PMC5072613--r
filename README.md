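# ithIHC

Intratumoral heterogeneity (ITH) analysis of focus-level immunohistochemistry
(IHC) scores from tissue microarrays (TMAs).

Multi-region DNA sequencing showed that clear cell renal cell carcinoma
(ccRCC) evolves in branches: different regions of one tumor share founding
alterations but diverge in later ones. Sequencing many regions of many tumors
is expensive, so cohorts stay small. IHC on a TMA is a cheap alternative:
score several spatially separated foci per tumor for loss of nuclear staining
of chromatin regulators (PBRM1, ARID1A, SETD2, BRG1, BRM), and treat each
expression loss as a clonal marker. `ithIHC` implements the full analysis for
that design, for pathologists and computational biologists working with
focus × marker loss grids:

- **Loss calling.** A focus scores 0 (lost) when ≤ 5% of tumor cells stain
  positive, 1 when 5–50%, 2 when > 50%; a tumor has lost a marker if *any*
  evaluable focus scores 0. Prevalence tables by marker, level (tumor/focus)
  and stage.
- **Clonal phylogeny.** Markers lost in the same focus set form one loss
  event; the support sets of a tumor's events form (after conflict
  resolution) a laminar family — any two sets nested or disjoint — which is
  exactly the structure representable as a rooted clone tree. Each event's
  parent is the smallest support strictly containing it; the root is the
  loss-free founder (WT). Events attached to the root covering ≥ τ of the
  evaluable foci (default τ = 0.75) are *truncal* (early), all others
  *branch* (late). Trees are classified as NO_LOSS, TRUNK_ONLY, BRANCHED,
  BIFURCATED or MULTI_TRUNK and exported as Newick.
- **Co-loss statistics.** For every marker pair, 2×2 tables of joint loss at
  tumor and focus level, an exact two-sided Fisher test (point-probability
  method, computed internally from log-factorials), Haldane-corrected odds
  ratios, conditional co-loss fractions, and Benjamini–Hochberg q-values.
- **Synthetic cohorts.** A generator plants clone trees (truncal events in
  all foci, branch clones below them, co-loss bundles such as PBRM1+ARID1A)
  and emits scored cohorts with configurable noise and missingness, plus the
  ground truth, so the whole pipeline is testable end to end
  (`simulate_cohort()`, `recovery_report()`).

## Worked example

One stage-I tumor, four foci: ARID1A and BRM are lost in foci R1–R3, PBRM1
and BRG1 only in R3.

```r
library(ithIHC)

scores <- data.frame(
  tumor_id = "T05", stage = "I",
  focus_id = rep(c("R1", "R2", "R3", "R4"), times = 5),
  marker   = rep(ith_markers(), each = 4),
  score    = c(2,2,0,2,  0,0,0,2,  2,2,2,2,  2,2,0,2,  0,0,0,2))
cohort <- as_cohort(scores)

tree <- build_cohort_trees(cohort)[["T05"]]
tree
#> clone_tree [T05]: 2 event(s)
#>   ((PBRM1+BRG1)ARID1A+BRM)WT;

classify_events(tree, tau = 0.75)
#>   node label_markers n_support   label flagged
#> 1    2    ARID1A+BRM         3 truncal   FALSE
#> 2    3    PBRM1+BRG1         1  branch   FALSE

classify_shape(tree)
#> [1] "BRANCHED"
```

The joint ARID1A+BRM loss supported by 3 of 4 foci is called truncal (it
covers ≥ 75% of evaluable foci); the PBRM1+BRG1 loss nested inside it is a
branch event; the tree is a single chain with depth 2, i.e. BRANCHED. The
Newick string labels internal nodes, so the chain reads
`((PBRM1+BRG1)ARID1A+BRM)WT;`.

A full run over a score table — prevalence tables, one Newick per tumor,
shape summary, all-pairs co-loss CSV — is one call:

```r
run_pipeline(list(input = "scores.csv", out_dir = "results/"))
```

or from a shell via the thin dispatcher
`Rscript inst/cli/ith-ihc.R run --config run.yaml` (subcommands `call`,
`summarize`, `trees`, `coloss`, `simulate`, `reproduce`).

`reproduce_study()` re-derives the original study's published summary
numbers (tumor-level loss counts 49/81/23/24/61 of 160, focus-level
percentages, per-stage any-loss fractions, the maximum pairwise Fisher p)
from its supplementary focus-level score workbook and reports a
computed-vs-published comparison; it needs that workbook
(`pone.0164554.s003.xls`), which is not redistributed here.

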