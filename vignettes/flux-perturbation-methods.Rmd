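---
title: "Context-specific metabolic models and perturbation-based target ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-specific metabolic models and perturbation-based target ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FluxPerturb)
```

# Overview

FluxPerturb ranks metabolic drug targets for T-cell-mediated immune
disease by asking, for every druggable gene in a cell-type-specific
metabolic model, whether its deletion pushes the cell's flux state
*against* the disease's transcriptional signature. The pipeline has
five stages: (1) integrate transcriptomics and proteomics into binary
gene-activity calls; (2) extract one context-specific model per
CD4+ T-cell subtype from a template network (GIMME); (3) delete each
drug-target gene through its gene-protein-reaction (GPR) rule and
predict the perturbed fluxes (MoMA); (4) classify per-reaction flux
changes against the disease's differentially expressed genes (DEGs)
and compute a perturbation effect score (PES); (5) rank, standardize
and aggregate the scores across cell types and select targets.

This vignette documents the models and their assumptions, the
parameters that matter, the numerical choices, what the synthetic data
emulate, and the design decisions taken where the problem left them
open. It states no empirical result beyond what the package's tests
and acceptance script themselves compute.

# The constraint-based core

A `MetabolicModel` is a stoichiometric matrix $S$ (metabolites by
reactions) with flux bounds $lb \le v \le ub$ (mmol/gDW/hr), parsed
GPR rules, and a designated biomass objective. Reversibility is
encoded purely by a negative lower bound; an exchange reaction touches
exactly one metabolite in the extracellular compartment and is written
`met_e <-> nothing`, so uptake is negative flux (single-metabolite
reactions on internal compartments are demands/sinks, which media
handling and the leak test deliberately leave alone). Media are maps
from exchange ids to maximum uptake rates; applying a medium closes
every unlisted non-basal uptake and never touches secretion bounds or
internal reactions.

**Flux balance analysis (FBA)** maximizes objective flux subject to
$Sv = 0$ and the bounds. **Flux variability analysis (FVA)** reports
per-reaction flux ranges with the objective held at a fraction of its
optimum; blocked-reaction detection uses fraction 0, because "blocked"
must mean infeasible under any objective. **MoMA** predicts a
knockout's flux state as the feasible point minimizing the squared
distance to the wild-type FBA solution — the biological assumption is
that a perturbed cell has had no time to re-optimize growth and stays
as close as possible to its previous operating point. A linearized
(sum of absolute deviations) variant is available where a linear
program is preferred; the quadratic form is the default.

## Solver strategy and numerical choices

All linear and quadratic programs go through one engine,
`quadprog::solve.QP` (dual active-set, exact for strictly convex
QPs), behind a thin internal port:

* Linear programs (FBA, FVA, GIMME, leak and task probes) are solved
  by **bisection on the objective level**: each probe "is there a
  feasible point with $c'v \ge t$?" is a strictly convex minimum-norm
  QP. This is numerically robust where naive regularized-LP
  formulations break down, and it terminates at a relative gap of
  $10^{-9}$.
* Because the final iterate is the minimum-norm point of the optimal
  slice, FBA returns the *unique minimum-norm optimal flux vector*
  rather than an arbitrary optimal vertex. This is a deliberate
  choice: degenerate optimal faces are common in metabolic networks,
  and a deterministic, reproducible representative makes the
  downstream flux-ratio classification stable across runs and
  platforms.
* MoMA eliminates the steady-state equalities through an orthonormal
  null-space basis and solves one small inequality-only QP in the
  degrees of freedom of the flux cone. Degenerate active sets can
  make dual active-set methods fail spuriously; a deterministic
  relaxation ladder (constraint levels eased by $10^{-9}$, then
  $10^{-8}$, far below every downstream tolerance) breaks such
  degeneracy, and a genuine infeasibility is confirmed by an
  independent feasibility probe before being reported.
* The zero-flux tolerance is $10^{-6}$ everywhere (a typical LP
  feasibility tolerance) and configurable. Equality systems are
  rank-reduced before reaching the solver, since mass-conserving
  networks always carry linearly dependent rows of $S$. Unbounded
  model bounds are capped at $10^4$.

# Omics integration

Gene activity is binary. A gene is active in a transcriptomics
dataset when expressed in *more than* 50% of the samples where its
probe was detected (strict inequality — a literal reading of "more
than half"); genes never detected are *undetermined*, not inactive.
Several datasets for one cell type are combined by the same strict
majority across datasets, so large datasets cannot dominate small
ones. Proteomics presence follows the same majority rule, and each
protein also gets an abundance rank statistic: its within-sample
quantile among detected proteins, averaged over the samples where it
was detected (computing quantiles per sample first keeps differing
abundance scales between runs from mixing).

Integration assigns consensus tiers: active in both layers = high
confidence; active only in transcriptomics = kept (moderate) when
expressed in at least 90% of samples; active only in proteomics =
kept when its abundance quantile is in the top quartile
($\ge 0.75$). The two moderate cutoffs are inclusive, the majority
itself strict. Everything else is inactive.

# Context-specific model extraction

GIMME solves: minimize the total penalized flux through
expression-inactive reactions, subject to steady state, bounds, and
the objective held at at least $f$ times the template optimum. Under
binary activity the GIMME expression penalty collapses to a constant
(1 per unit flux). Reactions kept: all active and gene-free
reactions, plus inactive reactions that carry flux in the minimizing
solution — the data-unsupported reactions the objective cannot do
without. Reversible fluxes are split into nonnegative forward/reverse
variables to keep $|v|$ linear. Hygiene order is media → GIMME →
dead-end removal → blocked-reaction removal (pruning before media
application would misclassify exchanges); because blocked and
dead-end reactions carry zero flux in every feasible state, the
extracted model always retains $\ge f \times$ the template optimum,
and the build errors out if it ever did not.

$f$ defaults to 0.9. The problem statement leaves GIMME's objective
fraction open; 0.9 is common practice and is exposed in the
configuration. A reaction catalyzed by isozymes stays active when any
one isozyme is expressed, and kept reactions retain their complete
GPR rule — which is why a knockout of one isozyme is later silent
even if that isozyme happened to be the expressed one: the full rule,
not the expression state, decides deletions.

# Knockouts, flux classification and the score

Deleting gene $g$ closes exactly the reactions whose GPR was true
with the full gene set and turns false without $g$. A knockout that
disables nothing is *silent* (isozyme-backed) and is excluded from
target scoring, mirroring the filter "targets whose deletion blocks
at least one reaction". The perturbed flux state comes from MoMA
against one cached wild-type FBA solution per model.

Flux changes are classified on magnitudes $|v|$: for reversible
reactions the sign encodes direction rather than activity, and ratios
of signed fluxes are undefined under sign changes. Sign reversals are
additionally logged, and a signed mode is available behind a flag.
With $m_{wt} = |v_{wt}|$, $m_{ko} = |v_{ko}|$, relative tolerance 5%
and absolute tolerance $10^{-6}$ (both configurable; the problem
statement names no classification tolerance): unchanged when the
magnitudes differ by at most the absolute tolerance or their ratio
lies in $[0.95, 1.05]$; down/up outside the band; when
$m_{wt} \approx 0$ the ratio is undefined and the reaction is up only
if $m_{ko}$ exceeds the absolute tolerance.

The up group of a knockout is the set of distinct reactions whose GPR
contains at least one disease-upregulated DEG (union semantics: a
reaction regulated by several same-direction DEGs counts once; one
regulated by both directions contributes to both groups — the
alternative, counting per gene, would weight promiscuous reactions
arbitrarily). Partitioned by class this gives UpDec/UpInc/UpUnc, and
analogously for the down group, then

$$PES = \frac{UpDec - UpInc}{UpDec + UpInc + UpUnc}
      + \frac{DownInc - DownDec}{DownInc + DownDec + DownUnc}.$$

A term with zero denominator contributes 0, keeping the score total
and bounded in $[-2, 2]$; the maximum 2 is attained exactly by
perfect reversals (both numerator counts positive, all opposing and
neutral counts zero). DEG tables are filtered at adjusted
$p < 0.05$ with a two-fold change cutoff, falling back to 1.5-fold
when the two-fold cutoff leaves too few metabolic DEGs (default
threshold: 10).

# Ranking, aggregation, selection

Within one model/disease the gene with the highest PES gets rank 1;
ties receive averaged ranks (the source problem is silent on ties).
Ranks are standardized as $z = (x - \mu)/\sigma$ using the sample
(n−1) standard deviation (population mode behind a switch; the
convention is unspecified upstream). Per disease, z-scores are summed
over the cell-type models for genes scored in every model (genes
missing from a model are excluded and logged). Selection applies the
−1 cutoff to the *re-standardized* aggregate — the cutoff is glossed
upstream as "one standard deviation lower than the mean aggregated
z-score", which is a statement about the distribution of aggregates,
not about the raw sum; a raw-sum mode is available behind a flag for
the other reading.

# Validation experiments

The validation module reproduces the qualitative checks used for the
real cell models as reusable procedures: nutrient sweeps with
windowed averaging (the growth reported at uptake 3.0 with window 5
and step 0.1 averages the growths at 2.8–3.2, mirroring the original
averaging scheme), factorial two-nutrient dependency surfaces (does
glutamine matter only when glucose is limiting?), forced-flux
response curves (does pushing flux through pyruvate dehydrogenase
lower lactate secretion?), and a qualitative behavior suite with
agree/partial/disagree verdicts, where "partial" marks an outcome in
the expected direction but of different severity.

# The synthetic-data module

`makeToyTemplate()` builds a fixed, mass-consistent toy network with
the pathway anatomy that matters for T-cell metabolism: lumped
glycolysis ending in a pyruvate node that branches to lactate export
and an oxygen-limited TCA-like cycle with ATP yield, glutamine →
glutamate → alpha-ketoglutarate with a transaminase bypass running
the other way, pyruvate-carboxylase anaplerosis, a fatty-acid
oxidation branch, an ATP maintenance sink, and a biomass reaction
drawing six precursors. Isozyme pairs (glucose transporter,
hexokinase, IDH, LDH, glutaminase) and enzyme complexes (lumped
glycolysis, mitochondrial pyruvate carrier, PDH, carnitine shuttle)
give the GPR logic real work. Stoichiometric coefficients conserve a
carbon-like weight, so the leak test is clean by construction. The
naive medium carries fatty acids with modest glucose; the effector
medium is glucose- and glutamine-rich, fatty-acid-free, with tighter
oxygen. Oxygen is deliberately a constrained nutrient rather than a
free one at this scale: the respiratory capacity limit is what makes
the lactate/oxidation tradeoff observable in a 30-reaction network.

`simulateOmics()` draws per-sample binary calls from per-gene
activity probabilities, flips them with probability 0.05, drops
probes out with probability 0.1, and gives proteomics a
detection-plus-lognormal-abundance model in which genuinely active
genes concentrate in the top abundance quartile. Sample sizes default
to 8 transcriptomics and 4 proteomics samples per cell type — the
real inputs' "many transcriptomic, few proteomic samples" shape at
toy scale.

`simulateDisease()` plants the ground truth self-consistently: it
runs the package's own build/knockout/classification code on the very
context models the pipeline will score, deletes the planted target
(default `g_slc1a5`, the glutamine transporter, chosen because its
loss *reroutes* — glutamate synthesis shifts onto the transaminase
bypass while growth is preserved, producing a clean bidirectional
signature rather than a global collapse), and draws disease-up DEGs
from genes whose reactions consistently decrease and disease-down
DEGs from genes whose reactions consistently increase. Decoy DEGs are
non-metabolic gene identifiers with no flux linkage, half of the
final table by default, so recovery is nontrivial. The planted gene
and its two reroute anchors (glutaminase, the transaminase) are
pinned active in the omics layers themselves; the engineered
invariant — the planted target maps to a reaction with no active
isozyme in every scored model — must hold regardless of noise, and
pinning the data rather than the calls keeps written scenario
directories bit-faithful to the in-memory scenario. Everything else
keeps its noisy draws.

What passing tests on these data do show: the pipeline's logic —
integration rules, extraction contracts, GPR deletions, flux
classification, scoring, aggregation and selection — is correct and
deterministic end to end, and a target engineered to reverse a
disease signature is recovered at rank 1 and selected across seeds.
What they do not show: performance on real genome-scale networks
(four orders of magnitude larger, with compartment proton balancing,
thermodynamically infeasible loops and heavily degenerate optima),
robustness to probe-annotation error, or any statement about real
disease biology.

# Problem sizes

The default study conditions are deliberately small so the full
pipeline runs in seconds: templates of roughly 30 reactions and 27
genes, two cell types, 8 + 4 omics samples, about 15–25 DEGs, and 80%
drug-annotation coverage; planted-target recovery is evaluated over
20 seeded scenarios. The generator also offers a `"medium"` size
class with a pentose-phosphate/nucleotide branch.

# Known limitations

* No SBML I/O; models exchange through the community JSON dialect
  only.
* The directionality-override table for template curation is a
  configuration hook, not an inference procedure.
* MoMA reference states are single minimum-norm FBA solutions;
  sampling-based references (e.g. flux sampling) are out of scope.
* Enrichment runs only on user-supplied pathway maps (one-sided
  Fisher/hypergeometric with Benjamini-Hochberg FDR); no online
  annotation services are queried.
* The metabolic task checker is generic; no curated task catalogue
  ships with the package.
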