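---
title: "Methods: expression-driven tissue-specific flux analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-driven tissue-specific flux analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxshift)
```

## The problem

Transcript abundance is an imperfect proxy for metabolic activity: between
tissues or developmental stages, many genes change expression while the
fluxes they govern do not, and vice versa. fluxshift implements a complete
workflow for asking where metabolism actually shifts: gene expression per
tissue is discretized into high/moderate/low states, projected onto the
reactions of a genome-scale stoichiometric model through
gene-protein-reaction (GPR) rules, and an integer program selects, per
tissue, a steady-state flux distribution that agrees with as many of those
expression states as possible. The resulting tissue-specific flux
distributions are then compared with a set of statistics designed for
fluxes rather than transcripts.

## Model and procedure

### Discretization (the 15 % rule)

Within each sample, genes in the top 15 % of FPKM are "highly expressed"
(+1), the bottom 15 % "lowly expressed" (−1), the rest moderate (0). The
cutoffs are empirical order statistics with $k = \lceil q\,n \rceil$; the
rule is rank-based, hence invariant under any strictly monotone transform
of a sample, and quantiles are taken **per sample** so that states are
comparable across libraries of different depth. Ties are resolved
conservatively: when the cutoff value is shared by more genes than the
nominal fraction admits, the tied genes stay moderate, so an extreme class
never exceeds $k$ members and a degenerate all-equal sample has no extreme
genes at all. FPKM is computed as
$\mathrm{fpkm} = \text{fragments} / (\text{mapped reads (millions)} \times
\text{exon length (kb)})$ when raw counts are supplied.

### Reaction states through GPR rules

A reaction's state is its GPR rule evaluated over gene states with
`and` = min and `or` = max — a complex is only as available as its
scarcest subunit; one isozyme suffices. The mapping over the trilean
domain is the standard convention for expression-state propagation onto
reactions. Genes present in the model but absent from the expression
table evaluate as moderate, so missing measurements never force an
activity claim; reactions with empty rules (exchanges) are always
moderate.

### The iMAT program

Let $S$ be the metabolite × reaction stoichiometric matrix, $v$ the flux
vector with bounds $lb \le v \le ub$ (by convention $[-1000, 1000]$, or
$[0, 1000]$ if irreversible). With $R_H$ the reactions expected active and
$R_L$ those expected inactive, the program is

$$
\max \; \sum_{r \in R_H} (y^+_r + y^-_r) + \sum_{r \in R_L} y_r
\quad \text{s.t.} \quad S v = 0, \; lb \le v \le ub,
$$

where $y^+_r = 1 \Rightarrow v_r \ge \varepsilon$,
$y^-_r = 1 \Rightarrow v_r \le -\varepsilon$ (reversible reactions only,
with $y^+_r + y^-_r \le 1$), and $y_r = 1 \Rightarrow v_r = 0$. The
implications are linearized with the usual bound-shifted big-M rows (e.g.
$v_r - (\varepsilon - lb_r)\,y^+_r \ge lb_r$). The objective counts
reactions whose activity is consistent with their expression state; no
biomass objective is needed. The tissue-specific model keeps the active
reactions, $\{r : |v_r| > \text{activity\_tol}\}$.

### Solver

No linear- or integer-programming backend is assumed: the package ships a
dense bounded-variable two-phase primal simplex (C++), using Bland's rule
throughout, which guarantees termination under degeneracy and makes every
solve deterministic. The MILP is solved by depth-first branch and bound on
the binaries: the LP relaxation bounds each node, nodes are pruned when
$\lfloor \text{bound} \rfloor$ cannot beat the incumbent (the objective is
integral), branching picks the most fractional binary (ties to the lowest
index, one-branch first). Desk-scale instances (tens of reactions, up to
a few dozen flagged) solve in milliseconds; a wall-clock `time_limit`
(default 60 s per tissue) surfaces as status `"time-limit"` with the
incumbent, never silently.

**Alternate optima.** MILP solutions are not unique; heatmaps and
downstream statistics need a reproducible representative. After the
optimal binary assignment is found, a secondary LP fixes the binaries and
minimizes $\sum_r |v_r|$ (linearized with one auxiliary $t_r \ge |v_r|$
per reaction). Combined with the deterministic simplex, identical inputs
give byte-identical outputs. The returned solution is one canonicalized
optimum; `fva()` at fixed context can be used to explore alternate
activity if needed.

### Flux variability analysis

`fva()` minimizes and maximizes each reaction's flux subject to $S v = 0$
and bounds — two LPs per reaction, purely feasibility-based (no
objective-optimality constraint, consistent with a workflow that never
defines one). By default FVA runs on the **generic** network rather than
per-tissue models: the range normalizes the flux-change ratio below, and
the two compared tissues must share a normalization for the ratio to be
comparable. `fva_scope = "union"` restricts to reactions active in at
least one tissue model.

### Comparative statistics

* **Total variation** of a reaction across an ordered tissue series
  $f_1, \dots, f_k$ is $\sum_{i=2}^{k} |f_i - f_{i-1}|$ — $k$ values
  contribute $k-1$ consecutive differences. The printed-index alternative
  (an implicit $f_0 = 0$) would make the statistic depend on the first
  tissue's absolute flux, which contradicts its purpose of measuring
  fluctuation, and is not used. The series order comes from the sample
  manifest; reactions absent from a tissue model contribute flux 0.
* **Flux-change ratio** between two tissues:
  $(|flux_2| - |flux_1|) / (maxflux - minflux)$, with calls up ($> 0.5$),
  down ($< -0.5$), else unchanged. Magnitudes are compared because
  reversible fluxes can be negative. A degenerate range yields an
  `"undefined"` call, never an error.
* **Expression fold change** $(\mathrm{fpkm}_2 + c)/(\mathrm{fpkm}_1 + c)$
  with calls up ($> 2$) and down ($< 0.5$); the default pseudocount
  $c = 1$ guards zero FPKM, $c = 0$ gives the literal ratio.
* **Rate-limiting reactions**: those whose flux attains its upper bound
  (forward saturation by default; reverse saturation under a flag).
  Generic network bounds are used.
* **Enrichment**: upper-tail hypergeometric $P(X \ge k)$ per pathway via
  the survival function (log-space, numerically stable). The gene
  universe is the expression table's genes; the reaction universe is the
  network. Benjamini–Hochberg adjusted values are always reported
  alongside raw p-values; the significance flag uses raw $p < \alpha$
  unless `adjust = "BH"` is chosen, since the upstream convention reports
  unadjusted hypergeometric tests.
* **Clustering**: agglomerative, Euclidean distance and average linkage
  by default (both configurable and recorded in the output metadata).
  Labels are sorted before computing distances so equal-distance merges
  resolve deterministically toward the earlier label.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `low_q`, `high_q` | 0.15, 0.15 | fraction | the highest/lowest-15 % convention |
| `epsilon` | 1 | flux | activation threshold; conventional choice on a ±1000 bound scale |
| `activity_tol` | 1e-6 | flux | separates numerical zeros from activity; deliberately distinct from `epsilon` |
| `ratio_threshold` | 0.5 | – | flux-change call threshold (±0.5 rule) |
| `fc_up`, `fc_down` | 2, 0.5 | – | expression fold-change thresholds |
| `pseudocount` | 1 | FPKM | zero-FPKM guard |
| `alpha`, `adjust` | 0.05, none | – | raw-p significance by default; BH reported always |
| `time_limit` | 60 | s | per-tissue MILP cap, status surfaced |

## The synthetic generator

Real tissue atlases and curated genome-scale models are large, private or
unpackaged; the generator provides study-shaped data with known answers.
`make_network()` emits chains of irreversible/reversible internal
reactions, each chain a subsystem with its own uptake and secretion, plus
connector reactions between chains; GPRs cycle through single-gene, `and`
and `or` forms with genes unique to their reaction. `plant_expression()`
assigns each sample's genes to low/mid/high FPKM strata (defaults 2, 50,
500) according to an on/off pathway plan. Two constructions make the
truth exactly recoverable at zero noise:

* **Gap construction.** Strata are constant within a sample, so the
  quantile cutoff always lands on the tied middle stratum; the tie rule
  drops tied genes to moderate, leaving exactly the planted extremes —
  discretization inverts the planting without tolerance fudging. The
  generator rejects plans whose extreme strata exceed the quantile
  capacity $\lceil q\,n\rceil$.
* **Realizability check.** For every sample an LP verifies a steady-state
  flux with $|v| \ge \varepsilon$ on all planted-active reactions and
  $v = 0$ on all planted-inactive ones; unrealizable plans fail at
  generation time naming the sample.

The default scenario (`make_scenario()`) has 8 chains of 4 reactions
(50 reactions, ~55 model genes plus 50 background genes), 4 samples over
two stages, `pathway_1` always on, `pathway_2` toggled on in the mature
stage (the planted differential pathway), `pathway_3` always off.
Generation is a pure function of the seed.

What the generator does **not** emulate: realistic FPKM distributions
(strata, not log-normal mixtures), genome-scale topology (no cofactor
coupling, no compartments), shared genes between reactions, or noisy GPR
structure. Passing the planted-recovery tests therefore demonstrates the
pipeline's correctness on its own contracts, not calibration on real
tissue data.

One planted property deserves a note: with bounds at ±1000, generic FVA
ranges are ~1000 while canonicalized iMAT fluxes sit near
$\varepsilon = 1$, so the flux-change ratio cannot cross ±0.5 in the
synthetic scenario — realistic saturation-scale fluxes are what make that
rule fire on real models. End-to-end recovery of the planted differential
pathway is therefore asserted on the gene-level up-set and on the
newly-active reaction set, both of which the pipeline also computes.

## Numerical choices

* Simplex tolerances: reduced-cost and pivot thresholds 1e-9,
  phase-1 feasibility 1e-7. Lower bounds must be finite (fluxes are
  box-bounded); slack upper bounds may be infinite.
* MILP integrality tolerance 1e-6; objective bounds rounded through
  `floor(x + 1e-6)` before pruning.
* Degenerate FVA range (`maxflux − minflux < 1e-9`) is reported as an
  undefined flux change rather than dividing by a near-zero width.
* Tie-breaking is everywhere deterministic and documented: lexicographic
  reaction ids in the fluctuation ranking, sorted labels in clustering,
  lowest-index branching in the MILP.

## Problem sizes used in validation

The shipped tests validate the MILP against a brute-force oracle that
enumerates every satisfiable flag subset with LP feasibility checks
(direction-split for reversible high flags, supersets of infeasible
subsets pruned) on 1000 random networks of up to 12 reactions and 8
flags; statistics are property-tested on hundreds to a thousand random
instances each; end-to-end recovery runs the default 50-reaction,
4-sample scenario. These sizes were chosen so the whole suite exercises
every code path in under a minute on one core.

## Known limitations

* The MILP solver is a dense simplex with branch and bound: appropriate
  for networks up to a few hundred reactions, not for genome-scale models
  with thousands — there it would need a sparse LP backend.
* One canonical optimum is reported; biological conclusions that depend
  on flux uniqueness should be checked against `fva()` ranges.
* The SBML reader covers Level 3 + FBC as produced by mainstream
  constraint-based tooling (species, stoichiometry, parameter-referenced
  bounds, `geneProductAssociation`, COBRA-style `SUBSYSTEM:` notes); it
  is not a general SBML implementation. The tabular dialect is the
  primary interchange format.
* Enrichment treats pathways as flat labels: no ontology propagation.
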