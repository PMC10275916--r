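---
title: "Methods: draft reconstruction and parsimonious-flux gap-filling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: draft reconstruction and parsimonious-flux gap-filling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genrecon)
```

# Scope and model

`genrecon` builds draft genome-scale metabolic network reconstructions
(GENREs) from protein-annotation evidence and completes them by
parsimonious-flux gap-filling.  A GENRE is the standard constraint-based
object: a stoichiometric matrix $S$ (metabolites $\times$ reactions), flux
bounds $l \le v \le u$ in mmol·gDW$^{-1}$·h$^{-1}$, gene–protein–reaction
(GPR) boolean rules, and a biomass pseudo-reaction whose flux is the growth
objective.  Flux balance analysis (FBA) solves

$$\max_v \; v_{\text{biomass}} \quad \text{s.t.} \quad S v = 0,\; l \le v \le u,$$

and parsimonious FBA (pFBA) then minimises $\sum_r |v_r|$ holding
$v_{\text{biomass}} \ge f \cdot z^\*$ (default $f = 1$), modelling the
assumption that high flux implies costly enzyme turnover, so of all
optimal-growth states the cell realises a minimal-flux one.

# The two-step gap-filling program

The package's central algorithm selects reactions from a curated universal
database to make a draft grow.  Rather than minimising the *number* of added
reactions, it minimises *flux through added reactions*: the draft is merged
with every database reaction not already present (the candidates), each flux
is split into nonnegative forward/reverse parts $v = v^+ - v^-$, and one LP
is solved:

$$\min \; \sum_r w_r (v_r^+ + v_r^-) \quad \text{s.t.} \quad
S(v^+ - v^-) = 0,\; \text{bounds},\; v_{\text{biomass}} \ge \mu_{\min},$$

with $w_r = 0$ for draft (gene-supported) reactions and $w_r = 1$ for
candidates.  Candidates with optimal activity $v^+ + v^- > \varepsilon$ are
copied into the model, tagged `source = "gapfilled"` with an empty GPR.
Gap-filling runs twice: step 1 under complete media (every exchange open,
securing core biosynthetic routes) and step 2 under the user's media
(typically adding the uptake/transport routes the restricted environment
requires).  Additions are cumulative — step 2 never removes a step-1
addition, because a reaction that was flux-necessary under complete media
retains its genetic-evidence-free audit trail even if an alternative route
exists under the final media.

Two formulation choices were genuinely open and are worth recording:

* **Draft flux is free by default** ($w_{\text{gene}} = 0$).  Penalising
  only candidate flux isolates the selection objective: the program asks
  "which candidate flux is unavoidable", not "which total flux is minimal".
  A strictly parsimonious variant ($w_{\text{gene}} = 10^{-4}$) is available
  through the `weights` argument for users who want draft flux penalised
  too; the default keeps the added set independent of how wasteful the
  evidenced network happens to be.
* **Growth floor rather than growth maximisation.**  The gap-fill LP fixes
  $v_{\text{biomass}} \ge \mu_{\min}$ with $\mu_{\min} = 0.01$ by default.
  A floor makes the LP well-posed (an unconstrained "maximise growth while
  minimising flux" is bi-objective) and mirrors how the added set should not
  depend on the arbitrary magnitude of the optimum.

Among alternate optima the solver's returned vertex is accepted as-is; the
test oracles therefore compare *objective values*, not reaction identity,
wherever degeneracy could make set identity ill-posed.

# Universal-database curation

Curation makes three passes over a raw database:

1. **Balance filtering.**  Each reaction's elemental balance is the
   coefficient-weighted sum of parsed formula counts; charge balance is the
   analogous sum over formal charges.  A reaction is removed only when a
   delta is provably nonzero.  Reactions with any unparseable participant
   formula are *retained and flagged* `undetermined` — discarding them would
   gut real databases, where polymerised and generic-group species abound.
   Charge checking can be disabled (`check_charge = FALSE`) for databases
   with unreliable charge assignments.
2. **Exchange completion.**  Every extracellular metabolite receives exactly
   one exchange reaction `EX_<cpd>_e` with bounds (−1000, 1000).
3. **Biomass installation.**  The configured biomass template becomes
   reaction `biomass`.  The template is data, not code: it ships inside the
   database file, so users curating their own database control their own
   biomass composition.

The formula grammar is deliberately flat — `(ElementSymbol)(count)` tokens
only.  Parenthesised groups, `*` wildcards and similar constructions yield
`undetermined`, never a guess.  Pseudo-elements like `R` that happen to fit
the token grammar are treated as ordinary symbols that must cancel across
the reaction; this conservatively catches dangling generic groups.
Exchange, biomass and same-species transport reactions are exempt from
removal: they are unbalanced by construction.

# From hits to a draft

Type 2 input is a 12-column tabular alignment (the BLAST/DIAMOND
"outfmt 6" dialect).  Defaults: hits are kept at e-value ≤ 1e-10 and
bitscore ≥ 50, then deduplicated to the best hit per (query, subject) pair.
Whether a per-query best-hit-only policy is preferable depends on the
annotation pipeline that produced the table, so both behaviours exist behind
`best_per_query` (default `FALSE`, keeping all subjects a query hits —
multifunctional enzymes legitimately map to several orthologs).  Subject ids
map to reactions through a user-supplied dictionary; genes supporting the
same reaction are combined with OR.  AND relationships (enzyme complexes)
are never inferred: a hit table carries no subunit structure, and inventing
complexes would overstate knockout fragility.

Media handling at the draft stage adds, per media metabolite, its exchange
reaction and — only when neither the draft nor the database provides one — a
generic reversible transport (`source = "media_added"`).  When the database
does contain a transport it is copied instead, keeping the namespace
consistent.  Note the interaction with two-step gap-filling: a draft built
against a named media already contains an uptake route for every media
metabolite, so step 2 usually contributes nothing for those compounds; the
two-step separation is most visible for Type 3 inputs and for drafts built
under complete media.

Type 1 input (annotated protein FASTA) is accepted only through an explicit
external-aligner hook (`aligner_cmd`); without one the pipeline refuses with
instructions to supply Type 2 hits.  The alignment step is environment,
not method.

# Solver

All linear programs — FBA, pFBA, gap-filling, the sampler's interior-point
seed — run on a dense two-phase primal simplex written for this package
(`solve_lp()`), with box bounds translated to standard form.  Problems here
are small (tens of variables after forward/reverse splitting), dense and
numerous, which favours a dependency-free exact method over an iterative
one.  Numerical choices:

* pivot tolerance $10^{-9}$; phase-1 feasibility tolerance $10^{-7}$;
* Dantzig pricing with lowest-index tie-breaks, switching to Bland's rule
  after a fixed iteration budget so cycling cannot occur;
* a single shared constant `FLUX_TOL = 1e-6` for steady-state residuals,
  nonzero-flux reporting and the gap-fill inclusion threshold
  ($\varepsilon$); activity in $(0, 10^{-6}]$ is numerical noise, coupled
  to the LP tolerance;
* all id ordering uses byte (radix) collation, so models serialise
  identically regardless of the session locale — this is what makes two
  runs byte-identical across shells.

The solver is validated in the test suite against hand-solved programs and
an independently implemented simplex, and was cross-checked during
development against an interior-point/HiGHS reference on random
box-bounded instances.

# Downstream analyses

**Essentiality.** Single-gene deletion evaluates every GPR under the
knockout, closes reactions whose rule goes inactive, and recomputes FBA.  A
gene is essential when knockout growth falls below 1 % of wild type
(`threshold_fraction = 0.01`, exposed).

**Flux sampling.** A seeded hit-and-run walk: movement directions are drawn
in the null space of $S$ (computed by SVD), so every sample satisfies mass
balance by construction; step lengths are uniform over the admissible
interval given the box bounds.  The walk starts from a most-interior point
(an LP maximising the smallest slack to any bound), discards 100 warm-up
steps and keeps every 10th step.  The contract is *feasibility and
determinism under a fixed seed*; statistical uniformity of the sampler is
not asserted, and nothing downstream here depends on it.

# What the fixture generator emulates — and what it does not

The generator (`make_universal_fixture()` and friends) produces, at toy
scale, every artifact the pipeline consumes: universal databases with
seeded-unbalanced reactions, outfmt-6 hit tables with known gene→reaction
ground truth, media definitions, and SBML models.  Its defaults define the
study conditions used throughout the tests: a linear uptake pathway of 5
conversions at 1:1 stoichiometry (so designed biomass yield per unit uptake
is exactly 1), carbon-source uptake bound 10 mmol·gDW$^{-1}$·h$^{-1}$ (a
conventional glucose-scale uptake), 4 balanced decoys, 2 seeded-unbalanced
reactions built by perturbing one product coefficient by +1, and optional
short/long bypass pairs whose flux-minimal completion is known by
construction.  Every ground-truth record is verified in the suite by an
independent subset-enumeration oracle (a plain feasibility LP per candidate
subset) before being used as a test expectation.

These are topological and stoichiometric toys.  They exercise exact
arithmetic, LP optimality, GPR logic and media semantics; they do not
emulate real biochemistry — no cofactor coupling, no realistic biomass
composition, no thermodynamic direction assignment, no noisy annotation.
Passing tests therefore demonstrate that the *algorithms* are correct on
networks with known answers, not that reconstructions of real genomes are
biologically accurate; that depends on the universal database and mapping
dictionaries the user supplies.

Test problem sizes, chosen as the package's own study scale: gap-fill
optimality is enumerated exhaustively on 50 seeded fixtures with at most 12
candidate reactions each (the largest size at which full subset enumeration
stays exact and brisk); curation exactness runs on 100 seeded databases;
sampling contracts are checked on 500 draws.

# Known limitations

* Gap-filled GENREs inherit whatever biases the supplied universal database
  carries; curation removes provable imbalance, nothing more.
* The gap-filler never removes reactions, and step-2 additions are
  cumulative with step 1.
* Compartments are fixed to cytosol/extracellular, matching the
  two-compartment namespace convention of the dictionaries the pipeline
  reads.
* The simplex is dense; it is sized for curated-database scale (hundreds of
  reactions), not for multi-compartment eukaryotic models with tens of
  thousands of reactions.
* MILP-style minimum-reaction-count gap-filling is deliberately out of
  scope: the method here is defined by flux parsimony, not set cardinality.
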