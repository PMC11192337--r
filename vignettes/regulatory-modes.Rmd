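---
title: "Two-mode models of transcription-factor regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-mode models of transcription-factor regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfmodes)
```

## The model and its assumptions

`tfmodes` treats a bacterial promoter regulated by a single TF with a single
binding site. The TF's mechanism is decomposed into two dimensionless modes:
stabilization β multiplies the residence of the TF–RNAP co-bound complex
(both the TF and the polymerase off-rates from that state are divided by β;
a switch `beta_scope = "rnap_only"` restricts it to the polymerase off-rate
for sensitivity checks), and acceleration α multiplies the initiation rate
when the TF is co-bound. Both run over (0, ∞); values above 1 promote
expression, below 1 repress it. Classifying a TF by these two numbers,
rather than as "activator" or "repressor", is the point: the net sign of
regulation depends on the promoter.

Two levels of description are implemented.

**Equilibrium level.** The four promoter states (empty, RNAP-bound,
TF-bound, co-bound) carry weights {1, P, R, βPR} with P = N~P~/k~D,P~ and
R = N~TF~/k~D,TF~. Expression is read off as the initiation-weighted
occupancy, giving `fold_change()`, `fc_max_thermo()`, `chi()`,
`alpha_critical()`, `switch_promoter_strength()` and the six-region
`classify_region()`. These are closed forms; the partition-function identity
is property-tested against the weight table at 10⁻¹² relative tolerance.

**Kinetic level.** A chemical master equation on the same four states with
explicit rates (`kinetic_rates()`), productive initiation that ejects the
polymerase (RNAP-bound → empty at r; co-bound → TF-bound at αr), one protein
emitted per initiation, and first-order dilution γ. mRNA is not represented:
the production rate r lumps transcription and translation, so "protein" here
is the gene's output in units of expressed molecules. Cell-cycle time is
defined as T~cc~ = ln 2/γ, which makes the half-response of a constitutive
step change exactly one cell cycle and anchors all reported response times.

The kinetic level adds three things the equilibrium level cannot see:

1. *Initiation back-action.* FC~max~ = αβ(1 + P + V2)/(1 + βP + αβV2) with
   V2 = r/k~off,P~; the equilibrium result is the V2 → 0 limit. The β = 1
   dividing line of the equilibrium phase space moves to
   β = (N~P~ + r)/(N~P~ + αr) (off-rate titration of P) or
   β = 1/(1 + V2(1 − α)) (on-rate titration), implemented in
   `tuning_boundary_beta()`; on those lines FC~max~ is provably flat in P,
   and the tests verify flatness numerically.
2. *Noise.* `protein_moments()` solves the closed linear system for the
   state probabilities and the state-conditioned first and second moments of
   the protein count — production increments the count simultaneously with
   the promoter transition that carries it. This is exact (no moment
   closure). At saturating TF the Fano factor has the closed form
   1 − αβV2·βP/[(1 + αβV2 + βP)(1 + αβV2 + βP + βV4)], V4 = γ/k~off,P~,
   exported as `fano_max_kinetic()` and used only as a cross-check of the
   moment system. Expression is sub-Poissonian here because every initiation
   ejects the polymerase, anti-correlating successive productions.
3. *Dynamics.* `response_time()` integrates the linear ODE for
   (π~i~(t), ⟨n·1~i~⟩(t)) from the constitutive steady state with the TF
   switched on at t = 0, and reports the first crossing of the midpoint
   between the two mean levels, in cell cycles (eigendecomposition when well
   conditioned, `Matrix::expm()` otherwise; bisection at 10⁻⁶ relative
   tolerance).

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| α, β | TF regulatory mode | 1, 1 | neutral TF |
| P = kon~P~/koff~P~ | promoter strength | input | the promoter's identity |
| R = kon~TF~/koff~TF~ | TF concentration | input | the regulatory input |
| V2 = r/koff~P~ | initiation back-action | world-specific | 0 recovers equilibrium |
| γ | dilution rate (1/time) | 1 | sets the clock; T~cc~ = ln 2/γ |
| saturating TF | kon~TF~ = 10⁶·koff~TF~ | factor configurable | results insensitive to 10× more |

"Saturating R" in the equilibrium functions is the distinguished value
`Inf`, handled by limit formulas rather than large floats, so FC(R = Inf)
equals FC~max~ exactly. P = 0 and R = 0 are legal degenerate inputs that
return exact limits (α~c~ at P = 0 warns).

Finite-R response-time experiments default to promoter rates 100γ (promoter
kinetics fast relative to dilution). The saturating-TF "one cell cycle"
statement needs stronger separation: with β of order 100 the saturating
FC~max~ sits within 1% of 1 and the fast promoter-redistribution transient
is then comparable to the tiny midpoint gap, so the acceptance experiments
use promoter rates 10⁴γ — the actual bacterial regime (promoter rates of
order 1 s⁻¹ against a ~30–60 min division time). This choice satisfies the
assumption the limit statement is conditioned on; it is not a tuned value.

## Stochastic simulation and autoregulation

`simulate_ssa()` is an exact Gillespie simulation of the same reaction set
(Rcpp kernel, R's RNG, so a seed gives bit-identical trajectories). Three
topologies: `simple` (external TF pool, fixed binding propensity),
`autoreg_monomer`, and `autoreg_dimer` (monomers associate at
k~dim~·n(n−1)/2, dissociate at k~mon~; the dimer is the binding species).
DNA-bound TF is sequestered from the free pool and, by default, protected
from dilution; `dilute_bound = TRUE` adds loss of the bound molecule at γ,
since published model variants differ on this detail. Estimators
(`estimate_moments()`, `estimate_occupancy()`, `estimate_response_time()`)
use time averages with batch-mean standard errors (20 batches), batching
over whole trajectories when there are enough and over contiguous time
blocks otherwise.

The mean-field autoregulation analysis (`autoreg_fold_change()`,
`autoreg_alpha_critical()`, `autoreg_response_time()`) closes the loop
R = ⟨n(R)⟩/k~D,TF~ on the *equilibrium* occupancy — a fast-promoter
assumption. The tests therefore compare it to SSA runs at V2 = 0.01; at
V2 ≈ 1 the comparison fails by construction (initiation back-action is
outside the mean-field), which is a limit of the approximation, not a bug.
The expression scale (r/γ = 100 molecules) and binding scale
(k~D,TF~ = 50 molecules) are package defaults chosen to put the
self-consistent TF level in the occupancy-sensitive regime; the source
analysis does not pin them, so autoregulation results are validated on
qualitative shape (all FC(P) curves → 1 as P → 0; auto-repression faster
than auto-activation; response times on the one-cell-cycle scale) rather
than on printed numbers.

## Noise profiles

`cv_profile()` scans the regulated/constitutive CV ratio over a log-spaced
TF-binding-rate grid (64 points, 8 decades around koff~TF~ by default) and
auto-extends the grid until the top decade is within 1% of the saturating
limit, so classification always sees the plateau. `classify_noise_profile()`
reads the sign pattern of first differences above a 10⁻⁶ relative tolerance
(the moments are deterministic; the tolerance only guards floating-point
noise) into `monotonic`, `internal_max`, `max_and_min`, or — never silently —
`unclassified`. Default scan rates: koff~P~ = r = 100γ (V2 = 1,
V4 = 0.01) and koff~TF~ = 10γ.

With these defaults the weak-promoter diagram (P = 0.01) is fully monotonic
over α, β ∈ [10⁻², 10²], activators at strong promoters show the internal
maximum, and the strong-promoter repressor wedge orders
blue → magenta → red along an α-transect (the red band sits near β ≈ 3·10³).
One caveat found while testing: at P = 0.01 but β ≳ 600 (so βP ≳ 1 — the
co-bound promoter is no longer weak) a max-and-min structure of ~1%
amplitude appears. The "weak promoter ⇒ monotonic" statement is therefore
asserted on the βP ≤ 1 domain its premise implies.

## Fitting (α, β)

`fit_regulation_params()` does least squares on log FC over
(log α, log β) against the FC~max~(P) curve (equilibrium, or kinetic with a
fixed V2), multi-started from the four quadrants around α = β = 1 and
polished; a soft-L1 option robustifies against outliers; an `fc_floor`
mask drops measurements near background before fitting. Loss on log FC
because fold-change errors are multiplicative.

Identifiability is policed, not papered over: a ladder collapsed onto one
promoter strength constrains only the composite FC~max~(P) and raises an
error, as does a near-singular Jacobian. Confidence intervals are seeded
residual bootstraps; the default is the *studentized* (bootstrap-t)
interval with analytic-Jacobian standard errors, because at n = 8 the
percentile and basic intervals measurably undercover (~88% at nominal 95%
in a 100-replicate study run by the test suite) while bootstrap-t and
Wald-t sit at 92–94%, within binomial noise of nominal. Recovery contracts:
exact truth to 10⁻⁶ at sd = 0, and ~95% CI coverage at sd(log FC) = 0.1 on
an 8-point, 3-decade ladder.

Published parameter values for specific TFs are *not* reproduced here: they
derive from external experimental datasets that are not shipped. The fitting
machinery is validated entirely by parameter recovery on
`generate_synthetic_fc_data()` (model curve × seeded lognormal noise).

## Numerical choices and degenerate inputs

* Steady states solve the 4-state null space by QR with an explicit
  normalization row; reduced chains (kon~P~ = 0 or kon~TF~ = 0) stay
  solvable; negative round-off is clipped after a −10⁻⁹ sanity bound.
* The moment system is block-triangular (π, then first, then second
  moments); each block is a dense 4×4 solve.
* Midpoint crossings are bracketed on a dense scan (log-spaced early times
  for promoter transients, linear tail for the γ relaxation) before
  bisection; responses with |FC − 1| below tolerance are refused
  ("response time undefined"), mirroring the physical statement that the
  midpoint of a vanishing gap means nothing. Grid sweeps
  (`response_time_grid()`) return `NA` inside a configurable FC ≈ 1 guard
  band instead.
* Region classification is done in log coordinates with a relative
  tolerance (10⁻⁹) so points on the α = 1, β = 1, αβ = 1 lines map to
  `boundary` deterministically.
* The autoregulation fixed point uses damped iteration with a bracketed
  root fall-back and a sign-scan uniqueness check; the response integrator
  is classic RK4 at 10⁻³ T~cc~ steps (the mean-field ODE is
  one-dimensional and smooth).

## What a green test establishes — and what it does not

The synthetic worlds are stated parameter sets, not measurements. Agreement
of the SSA with the moment system, of the kinetic model with the
equilibrium limit, and of recovered (α, β) with generating truth
establishes internal consistency of the implementation at the stated rates.
It does not establish that any real promoter follows the 4-state scheme,
that mRNA dynamics are negligible (they are simply not modelled), or that
the default expression/binding scales describe any particular organism.
Known limitations: no cooperativity or multiple binding sites, no explicit
polymerase depletion, no elongation-speed ceiling on acceleration, and no
extrinsic noise.
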