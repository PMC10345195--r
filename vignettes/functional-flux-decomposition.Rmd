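---
title: "Functional decomposition of metabolic fluxes: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional decomposition of metabolic fluxes: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxdecomp)
```

# The model

A constraint-based metabolic model fixes steady-state fluxes v by mass
balance, S·v = 0, bounds, and a set of empirically prescribed *demand
fluxes* J_γ: one per biomass building block (J_γ = c_γ(μ)·μ from the
measured biomass composition), the maintenance ATP hydrolysis
(J_ATPM = σ₀ + σ·μ), and any excretion flux constrained to data (acetate in
aerobic growth; succinate anaerobically, where the acetate constraint is
dropped). We select a unique optimum with two-stage parsimonious FBA: stage
1 minimizes the substrate uptake magnitude, stage 2 fixes that optimum (to
a relative tolerance of 1e-9) and minimizes Σᵢvᵢ², a strictly convex
objective with a unique minimizer.

Because both stages are (piecewise) linear-quadratic in the right-hand
side, the optimal fluxes are, within one active-set region, an exactly
linear function of the demands: v = Σ_γ ξ^(γ)·J_γ. Each response vector
ξ^(γ) satisfies the network balance with a unit flux through its own
demand reaction and zero through the others, so each *component*
v^(γ) = ξ^(γ)·J_γ is a complete, mass-balanced pathway serving one
function. The package computes ξ^(γ) by central finite differences: each
demand is perturbed by δ_γ = delta·max(J_γ, J_floor) (defaults
delta = 1e-6, J_floor = 1e-6 mmol/gDW/h), the full two-stage problem is
re-solved — the substrate minimum is re-optimized, since uptake is a
dependent variable, not a demand — and one-sided differences are used as a
fallback when a perturbation direction is infeasible. The reconstruction
identity Σ_γ v^(γ) = v is then verified to 1e-6·max(1, ‖v‖∞); a violation
is raised as an error, because it signals an active-set change inside the
perturbation interval or a non-unique optimum, and a decomposition computed
across such a kink is not meaningful.

## Mixed fractions and shares

Opposite-signed components on one reaction indicate cancellation —
typically an intermediate (NADPH, DHAP-like species) produced by one
function and consumed by another, with an anaplerotic pathway absorbing the
difference. The mixed fraction
F_mix = (Σ_γ|v^(γ)| − |v|) / Σ_γ|v^(γ)| quantifies it; the remaining
1 − F_mix is distributed over the components whose sign matches the total
flux, proportionally to their magnitudes. This remainder rule is one of
several continuous allocations compatible with the definition of F_mix; we
chose it because it reduces exactly to F^(γ) = v^(γ)/v when no mismatch is
present and degrades continuously as mismatches appear. Components that are
numerically zero (below 1e-9 mmol/gDW/h in summed magnitude, the
finite-difference noise floor) are treated as carrying no cancellation.

## Coupling

Components can be linearly recombined without changing their sum. The
canonical case couples the maintenance (energy) component with a
constrained byproduct component into a *fermentation mode*
(byproduct + β·energy) and a *respiration mode* ((1−β)·energy). β is
derived, not fitted: the candidate values are the sign-change breakpoints
−v_i^(byp)/v_i^(energy) of the fermentation mode's entries, and the
smallest candidate minimizing the flux-weighted total mismatch is taken. At
that β the fermentation mode's flux through the maintenance reaction equals
the stoichiometric ATP yield of the excretion route times the excretion
flux, which is what makes the mode individually interpretable. The greedy
`auto_coupling_search()` instead merges candidate pairs by summation,
accepting at each step the merge that maximally reduces Σᵢ|vᵢ|·F_i^mix and
stopping when no merge improves it by more than 1e-6 mmol/gDW/h (kept above
the finite-difference noise so that numerically spurious merges are never
taken); ties break lexicographically. Not every mismatch can or should be
removed: in the two-cofactor fixture the balancing pathways retain
F_mix ≈ 2/3 under any pairwise merge, which is the expected signature of a
shared intermediate rather than an artifact.

## Costs and energy bookkeeping

Every component is mass-balanced, so its net ATP production equals its flux
through the maintenance hydrolysis reaction, and these balances sum to
J_ATPM exactly — the package's central conservation check. We deliberately
do not convert GTP/CTP/UTP turnover into ATP equivalents: conversions
happen through the network itself, and only maintenance-reaction flux
counts as a component's net energy. Carbon costs divide a component's
substrate carbon uptake by its demand; pathway-only ATP costs re-evaluate
the energy balance on the component restricted to non-central reactions
(the central set is an editable list of subsystem tags: glycolysis, TCA,
pentose phosphate, oxidative phosphorylation, anaplerotic), which reduces
to the full cost when the central set is empty. CO₂ and byproduct carbon
are attributed to the component carrying the flux, without re-proration.

## Proteome projection and the sector model

Reaction shares project onto proteins through the gene–protein–reaction
rules: a gene inherits the flux-magnitude-weighted average of the shares of
its active reactions (|v| ≥ 1e-4 mmol/gDW/h). Every gene in a rule receives
the reaction's shares — no splitting among OR-isozymes and no normalization
inside AND-complexes — because shares are weights applied to each protein's
measured mass fraction, not flux attributions. Protein mass comes solely
from the abundance table.

The coarse-grained allocation model uses two condition parameters, carbon
quality ν_C and translational capacity ν_R, with x = μ/ν_C and y = μ/ν_R:
foraging = x, translation = y, energy = φ_E,0 + κ_C·x + κ_R·y,
housekeeping constant, biomass = φ_B,0 + b·μ, and growth closed by a
proteome budget b·μ = Ψ − foraging − translation − energy − housekeeping.
Setting the foraging and translation response coefficients to one is a
normalization, not an assumption: it defines the scales of ν_C and ν_R and
removes the gauge freedom between sector offsets and the per-condition
latent parameters that would otherwise make the fit unidentifiable. The
closure is a pluggable design choice; all packaged defaults use this one.
The fit minimizes χ² = Σ(Δφ)² + c·Σ(Δμ)² with c = 0.1 h², chosen so that
growth-rate residuals are weighted like the typical experimental
uncertainty on μ (about 0.02/h) relative to that on sector fractions.
Initialization is closed-form (ordinary least squares on the observed
sectors), which is exact for noiseless data; refinement alternates
per-condition latent updates with a global Nelder–Mead pass from a
deterministic 16-point lattice of starts, and standard errors come from the
observed information of the full parameter vector.

Overflow prediction splits φ_E into respiration and fermentation protein so
their efficiency-weighted ATP supply (ε_res, ε_fer, in mmol ATP/gDW/h per
percent of proteome) meets the condition's energy demand:
φ_f = (J_E − ε_res·φ_E)/(ε_fer − ε_res), clipped to [0, φ_E]. Fermentation
protein therefore appears exactly when the demand exceeds what respiration
alone can deliver within the regulatorily allotted φ_E, and the acetate
flux follows from the fermentation ATP flux divided by the fermentation
mode's ATP-per-acetate stoichiometry — taken from the coupled
decomposition, not hard-coded. The prediction is continuous in φ_E and in
the demand, with a kink only at the φ_f = 0 boundary.

# Numerical choices

Both optimization stages run on the dual active-set method of
`quadprog::solve.QP`. Stage 2 is solved directly. Stage 1 is a linear
program solved by exact Tikhonov regularization: minimizing
c'v + (ε/2)‖v‖² returns, for every ε below a finite problem-dependent
threshold, exactly the least-norm optimizer of the LP; an ε-continuation
(1e-2, 1e-4, 1e-6) with an agreement check on the objective (1e-9 relative)
detects when the threshold has been passed, so the stage-1 value carries no
regularization bias. Fixed variables are folded into the equality block
(avoiding degenerate bound pairs), and linearly dependent equality rows are
removed by QR with a consistency check on the solution. Feasibility and
optimality tolerances default to 1e-9. Determinism is global: there is no
randomness anywhere in the decomposition path, ties break lexicographically
by reaction/function id, and all synthetic generators are seeded.

The maintenance fit (σ₀, σ) uses a deterministic 9×9 coarse grid on
[0, 50] × [0, 100] followed by Gauss–Newton refinement with
finite-difference Jacobians; because the stage-1 optimum is piecewise
linear in J_ATPM, the refinement lands on the exact optimum within one
linearity region. Candidate parameters that make the network infeasible
(e.g. maintenance below the ATP obligately produced by a constrained
excretion route) are treated as infinite-residual points.

# What the generators emulate

The toy fixtures reproduce the motif structure that makes decompositions
interesting — a linear pathway, redundant parallel routes (exercising the
L2 stage), an efficient/wasteful branch (exercising the uptake stage),
aerobic overflow with a constrained acetate-analog (whose raw component
fixes carbon through the respiratory reaction, i.e. carries negative
entries), a two-cofactor network with irremovable mismatch, and an
anaerobic network with a constrained succinate-analog yielding two
fermentation modes. Each fixture's optimum is determined by its equality
structure, so the response matrix is known in closed form and packaged as
an oracle; the test suite requires finite differences to agree with it to
1e-6.

The synthetic condition series emulates a ladder of eight carbon-limited
cultures with growth rates 0.3–1.0/h on the overflow network: maintenance
law σ₀ = 20, σ = 50 (J_ATPM ≈ 70 mmol/gDW/h at the reference growth rate of
1/h), biomass coefficient 8 mmol/gDW, an acetate law J_ac = −4 + 10·μ
clipped at zero (onset near μ = 0.4/h), and 2% multiplicative Gaussian
noise on the "measured" uptake — which comes out near 9.6 mmol glucose/gDW/h
at reference, a physiologically sensible magnitude. The sector generator
uses φ_E,0 = 0.05, κ_C = 0.3, κ_R = 0.1, φ_B,0 = 0.05, b = 0.2 h,
φ_H,0 = 0.25 and Ψ = 0.905, giving a reference state at μ = 1/h with an
energy sector of ~10.5%, biomass ~25%, translation 25%, foraging 10% — and,
combined with ε_res = 5.33 and ε_fer = 9.62, an acetate overflow that
switches off near μ ≈ 0.85/h on the carbon-limitation ladder. These values
were chosen once, jointly, so that the energy sector can meet the
maintenance demand across the whole series (a mutually consistent "study
design"); the coarse-grained model and the toy-network acetate law are
independent generator pieces and are not numerically reconciled with each
other. Noise levels (0.005 on fractions, 0.02/h on growth rates, 2–5%
relative on fluxes) reflect typical proteomics and physiology uncertainty.

Problem sizes throughout the tests — networks of 5–12 reactions, series of
8–12 conditions — are chosen so each property is exercised with exact
oracles; they are toy scales by design, and nothing in the implementation
depends on them.

# What passing tests do and do not show

The fixtures have unique, non-degenerate optima, complete formulas/GPRs and
noise-free stoichiometry. Passing on them validates the decomposition
arithmetic, the conservation laws, the coupling constructions and the
fitters — it does not establish that a particular genome-scale model has a
unique pFBA optimum (degeneracy there surfaces as a reconstruction-residual
error rather than silent nonsense), nor that real proteomes follow the
closure's functional forms. Two further limitations are worth naming.
First, in tractable toy networks with a free overflow valve, a raw
biosynthesis component balances its own ATP internally, so its net energy
balance is zero until a coupling assigns it a maintenance slice; the
aerobic net-ATP-producing biosynthesis pattern is reproduced by the
ATP-producing overflow variant, but the anaerobic net-consuming pattern
seen in real networks requires mismatch structures these toys do not
generate. Second, F_mix is computed over all functions, not after
restricting to a clustered subset; the clustering merely appends F_mix as
one extra profile coordinate.

# Parameters at a glance

| parameter | default | units | role |
|---|---|---|---|
| `delta` | 1e-6 | relative | demand perturbation for finite differences |
| `J_floor` | 1e-6 | mmol/gDW/h | absolute perturbation floor for zero demands |
| reconstruction tol | 1e-6 | relative to max(1, ‖v‖∞) | decomposition validity |
| activity threshold | 1e-4 | mmol/gDW/h | reporting/clustering flux filter |
| stage-1 fix tol | 1e-9 | relative | uptake fixing entering stage 2 |
| feasibility/optimality | 1e-9 | — | solver tolerances |
| coupling search tol | 1e-6 | mmol/gDW/h | minimal mismatch improvement per merge |
| `c` | 0.1 | h² | growth-rate weight in the sector χ² |
| σ₀, σ bounds | [0,50], [0,100] | mmol/gDW/h, mmol/gDW | maintenance search box |

# Worked micro-example

```{r}
fx  <- make_toy_network("overflow")
xi  <- compute_response_matrix(fx$model, fx$demands, fx$substrate_id)
dec <- decompose_fluxes(xi, fx$demands)
cpl <- couple_energy_byproduct(dec, "ATPM", "acetate")
component_atp_balance(cpl)
```
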