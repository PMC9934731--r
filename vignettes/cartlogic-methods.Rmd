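---
title: "Stochastic logic simulation of CAR T-cell / tumor cell signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic logic simulation of CAR T-cell / tumor cell signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model class

`cartlogic` simulates *stochastic discrete logic models* (a flavor of
probabilistic Boolean network). Each molecular species, complex or cellular
event is a node with value 0 (inactive) or 1 (active). A node carries:

* an **update rule**: a Boolean expression over other nodes (`&`, `|`, `!`),
  encoding which regulators switch it on and which inhibit it;
* an **activation propensity** `p_a`: the probability that a node whose rule
  is currently satisfied, but which is OFF, switches ON in one iteration;
* a **degradation propensity** `p_d`: the probability that a node whose rule
  is unsatisfied, but which is ON, switches OFF in one iteration. This
  represents decay of activated signaling molecules (dephosphorylation,
  ubiquitination, internalization) once their upstream drive is gone.

When the rule value equals the node's state nothing happens. Time is a
sequence of discrete iterations in arbitrary units: trajectories order events
causally but do not map onto wall-clock kinetics.

Updates are **random-order asynchronous**: each iteration draws a fresh
uniformly random permutation of all nodes and applies the single-node update
in that order, with later nodes seeing earlier nodes' new values within the
same iteration. We chose within-iteration visibility (true asynchrony over an
evolving state) because it is the standard semantics for asynchronous Boolean
networks and avoids the artificial oscillations synchronous updating can
create; a synchronous variant is available behind an explicit flag
(`simulate_ensemble(update = "synchronous")`) for comparison only.

The defaults `p_a = 0.5` and `p_d = 0.05` encode fast, all-or-none activation
with slow decay, which matches the bimodal character of T-cell activation
responses. With these values a self-inhibiting node (`A = !A`) is a two-state
birth–death chain whose stationary ON-fraction is
`p_a / (p_a + p_d) = 10/11 ≈ 0.909` — one of the closed-form results the test
suite checks against the simulator.

An alternative reading of the propensities — gating whether the rule is
*evaluated* at all, rather than gating the OFF→ON and ON→OFF transitions — is
conceivable. We implement the transition-gating semantics: it is the one the
stochastic-logic formalism defines, and it is the only one under which the
stated role of `p_d` (decay of an active node whose drive has disappeared)
makes sense.

## The packaged CAR T-cell model

`build_cart_model()` returns a curated 59-node network of a CD3ζ/CD28 CAR
T-cell engaging a tumor cell: CAR ligation (scFv–antigen through the immune
synapse), LCK/ZAP70 proximal signaling, the LAT–SLP76–PLCγ1 signalosome,
MAPK, PI3K–AKT–MTORC1, calcium/calcineurin and PKCθ branches, IL2
receptor/JAK/STAT5 cytokine signaling, cytotoxic granule release with
FasL/perforin-granzyme killing, the PD1 and CTLA4 inhibitory axes with SHP1/
SHP2 phosphatases, and the downstream transcription factors (AP1, NFκB,
NFAT, CREB, STAT5, BATF). Four *input* nodes represent ligand availability —
`TAex` (tumor antigen), `IL2ex`, `PDL1L2ex`, `CD8086ex` — and three *readout*
nodes summarize signaling signatures:

* `CFUNC` (CART function) = `AP1 & NFAT & MTORC1`;
* `CINHIB` (CART inhibition) = `dNFAT | BATF` — NFAT homodimers without AP1
  drive anergy, PD1-induced BATF drives exhaustion;
* `TAPOP` (tumor apoptosis) = `CASP3CASP7`.

Three textual defects in the published rule table are corrected in the
packaged file and recorded in the model metadata: the LCK rule's unbalanced
parentheses are minimally balanced preserving the printed token sequence;
the perforin/granzyme node is canonically `PERGRZB` and the inhibition
readout `CINHIB` (the variants `PERGRZM`/`CINHI` are accepted as aliases at
load time); and the undefined symbol `CDSYF` is dropped from the `CFUNC`
rule, which therefore reads `AP1 & NFAT & MTORC1`. The parser itself is
strict — user files with unbalanced parentheses are rejected with a position,
never repaired; the corrections live only in the curated packaged file.
The model is otherwise implemented exactly as printed: in particular the
PI3K rule (`CD28 | CTLA4`) carries no SHP2 inhibition even though the
surrounding biology would suggest one, and `CASP3CASP7` reads
`FASL | PERGRZB` (not `FAS`).

## Scenarios, initial conditions and input semantics

A scenario names the active input ligands and the run parameters. Initial
states: every node starts at 0, except `LCK`, which starts at 1 (T-cells
maintain a basal pool of active LCK), forced initial values from
perturbations, and each *active* input node, which starts at an independent
fair coin flip. Inactive inputs are held at 0.

The published description randomizes active-input initial states and holds
inactive inputs at 0 but does not give active inputs an update rule. We give
active inputs a constant-TRUE rule: they re-engage through `p_a` and never
degrade, realizing continuous antigen/ligand exposure over the simulated
window (the "enclosed loop" of sustained CART–tumor contact). Inactive
inputs carry a constant-FALSE rule. Scenario onset is simultaneous for all
active ligands; staggered schedules (e.g. IL2 added after CAR ligation) are
possible by composing runs but are not part of the named library.

The named library mirrors the receptor-ligation experiments: `A` = CAR
ligation only (`TAex`); `B` = `A` + IL2; `C` = `B` + both inhibitory ligands;
`D` = `C` minus PDL1L2 (PD1 axis blocked); `E` = `C` minus CD8086 (CTLA4
axis blocked).

Ensembles default to `R = 10000` replicates (the published averaging depth).
Horizon and steady-state window are not stated in the source; we default to
`T = 100` iterations with the steady summary averaged over the final
`W = 20`, values at which all 59 trajectories are visually flat, and both are
configurable everywhere. The acceptance checks scale some experiments to
`R = 5000`; each test states its own sizes.

## Reproducibility and the random number generator

The compiled ensemble engine uses xoshiro256++ seeded via splitmix64, with
replicate `r` seeded deterministically from `(base seed, r)`. Consequences:
ensembles are byte-identical across runs and platforms for a fixed
`(model, scenario, seed)`; replicates are individually reproducible; and the
engine neither reads nor perturbs R's own RNG state. One uniform is consumed
per node per iteration *unconditionally* (even when no event is possible), so
runs that share a seed but differ by a perturbation remain aligned
draw-for-draw — control and perturbed ensembles are coupled (common random
numbers), which the test suite exploits for paired comparisons. The
R-level `step()`/`make_initial_state()` reference implementations use R's RNG
(`set.seed()`) since they exist for single-trajectory inspection and testing,
not ensemble production.

Percent changes in the perturbation scan are reported unclipped, with the
raw fractions and binomial standard errors `sqrt(p(1-p)/R)` alongside; the
binomial form is an upper bound on the true SE of a window-averaged
fraction, and `steady_state_se()` provides the sharper empirical estimate
`sd(per-replicate window means)/sqrt(R)`. A percent change over a control
fraction of exactly 0 is reported as `NA` (undefined), never as 0.

## Validation strategy

Three independent layers check the simulator:

1. **Exact Markov kernel.** For models of at most 6 nodes,
   `exact_transition_matrix()` builds the one-iteration transition matrix by
   averaging, over all `n!` permutations, the ordered product of single-node
   update kernels. Monte-Carlo joint state distributions from the engine are
   compared to exact distributions in total variation; marginals, one-step
   hand enumerations (e.g. a two-node relay reaches the downstream node after
   one iteration with probability exactly 1/2) and stationary distributions
   provide further fixed points.
2. **Closed forms.** A constantly-satisfied rule follows
   `P(t+1) = P(t) + (1 - P(t)) p_a` exactly in expectation; the
   self-inhibiting toggle converges to `p_a/(p_a+p_d)`.
3. **Structural zeros.** `activatable_closure()` computes the least fixed
   point of "a node can ever be ON": a node outside the closure must show
   activity exactly 0 at every iteration of every replicate, with no
   statistical tolerance. The closure deliberately over-approximates (any
   node is allowed to be 0 when a negation needs it), which keeps the
   "outside ⇒ silent" direction sound. Examples in the packaged model: with
   no active inputs `TAPOP` is silent; under CAR ligation alone `PD1` and
   `BATF` are silent; a ZAP70 knockout silences `CFUNC` because NFAT needs
   calcineurin or P38 and both trace back to ZAP70.

## What the experiments show (and their limits)

Under the packaged model the ligation scenarios reproduce the published
qualitative ordering of the functional signature: IL2 raises steady
`p_cfunc`; engaging both inhibitory ligands collapses it (the PD1→SHP2 arm
activates within a few iterations, faster than the multi-step CAR cascade,
so proximal activation is suppressed almost from the start); blocking PDL1L2
restores function while blocking CD8086 has negligible effect (CTLA4
engagement needs calcium-driven CTLA4 externalization, which the suppressed
network rarely achieves, and PD1 compensates through the same SHP2 node).
Under full ligation the apoptotic signature stays positive but small —
steady-state readout fractions under scenario C are of order 10⁻³ at
`R = 5000`, i.e. a handful of ON replicates, so any comparison conditioned
on that control carries substantial Monte-Carlo error; the knockout-scan
tests use paired common-random-number differences for exactly this reason,
and effects much smaller than the control fraction itself (such as the LAT
knockout, which the rules `SLP76 = ZAP70 | LAT` and
`GRB2SOS = LAT | JAK13 | CD28` largely compensate) are below 3-sigma
resolution at that depth.

The model is a coarse-grained logic abstraction: activity fractions are
population proportions, not concentrations; iteration counts are not
seconds; terminal differentiation, CART subtypes (CD4/CD8), 4-1BB designs
and tumor population dynamics are out of scope; and inhibition here is
transient by construction — there is no commitment to exhaustion, only
continuous competition between activating and inhibitory signals. Passing
the validation suite demonstrates that the *simulator* implements the
stochastic update process correctly and that the *packaged rules* reproduce
the published qualitative behavior; it does not validate the rules against
new biological data.

## Random models and the fixture generator

`generate_random_model()` produces syntactically valid random models
(rules reference only defined nodes) reproducibly from a seed, with
propensities drawn from configurable ranges (`p_a ∈ [0.2, 1]`,
`p_d ∈ [0, 0.3]` by default — wide enough to exercise both fast and slow
dynamics while keeping activation events common in short horizons). These
fixtures drive the oracle-equivalence property tests and the CLI
`make-fixture` subcommand; they emulate the *mechanics* of signaling models
(small rule depth, mixed signs, loops), not their biological structure.

## Numerical notes

* The exact kernel costs `O(n! · 2^{2n})`; it refuses models with more than
  6 nodes by default. Row-stochasticity holds to 1e-12.
* State indexing everywhere (kernel, joint recordings) is binary with the
  first declared node as the most significant bit.
* Ensemble activities are exact fractions of integer counts; determinism of
  exported CSV/JSON is byte-level for a fixed seed.
* Degenerate inputs: an empty model, a rule referencing an undefined node, a
  propensity outside [0,1], and a steady window exceeding the horizon are
  all rejected with explicit messages listing every problem found.
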