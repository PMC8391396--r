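---
title: "Methods: thermodynamically constrained flux comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermodynamically constrained flux comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the models and numerical
choices behind its pipeline: fitting growth and exchange rates from
time-course data, building a thermodynamically constrained flux model,
computing parsimonious flux variability ranges, and comparing paired
resistant/control model instances through a normalization cascade.

## Rate fitting

Cell counts are modelled as exponential growth,
$X(t) = X_0 e^{\mu t}$, fitted by minimizing the robust soft-L1
objective $\sum_i \rho(r_i/f_{\mathrm{scale}})$ with
$\rho(z) = 2(\sqrt{1+z^2}-1)$. Residuals are standardized by the
series' median absolute count before the scale is applied: a fixed
dimensional scale applied to raw counts would mean different things for
different seeding densities, whereas on standardized residuals
$f_{\mathrm{scale}} = 0.3$ (the default) marks a consistent transition
to outlier down-weighting. Standard errors come from the weighted
Gauss–Newton Jacobian at the optimum, with the cross-product inverted
after rescaling to unit diagonal because $X_0$ (cells) and $\mu$ (1/h)
live on scales eight orders of magnitude apart.

Medium amounts follow the integrated uptake of an exponentially growing
culture,
$$C(t) = C_0 + q\,\frac{B_0}{\mu}\left(e^{\mu t}-1\right),$$
with $B_0 = X_0 m_{dw}$ the initial dry biomass and $q$ the specific
exchange rate in mmol/(gDW·h), positive for secretion. With $\mu$ and
$B_0$ fixed from the growth fit this is linear in $(C_0, q)$ and is
solved by least squares; $C_0$ is fitted jointly with $q$ by default
(fixing it at the measured $t=0$ mean is available behind `fix_c0`
because the data do not decide between the two conventions). For
$\mu \to 0$ the biomass integral degenerates continuously to $B_0 t$
via `expm1(x)/x`, so near-zero growth rates need no special casing.

A compound that decays abiotically is handled by fitting a first-order
decay constant $k$ to its cell-free control series (log-linear fit) and
fixing it in the joint mass balance $dC/dt = q B(t) - kC$, whose closed
solution
$$C(t) = C_0 e^{-kt} + q\,\frac{B_0}{\mu + k}\left(e^{\mu t} -
  e^{-kt}\right)$$
is again linear in $(C_0, q)$ after multiplying by $e^{kt}$ — the fit
reduces to the non-decaying case with $\mu + k$ in place of $\mu$ in
the biomass-exposure integral. We fit the ODE's exact solution rather
than discounting the whole accumulation term by $e^{-kt}$: the two
differ noticeably once $kt$ is not small, and only the mass-balance
form recovers the true rate from data generated by the decay ODE.
First-order kinetics is the only model a single control series can
identify, and the correction is applied only to compounds that have a
control series.

**Error convention.** The reported exchange-rate error follows a
measurement-repeatability convention: the residual scatter is treated
as the technical error of one measurement and propagated through a
one-observation-per-time-point design, *without* the $\sqrt{N}$ gain of
replicate averaging, then combined in quadrature with the relative
errors of $\mu$ and $B_0$. This mirrors how assay repeatability (an
RSD, not a standard error of a mean) is quoted for the underlying
measurements, and it makes the propagated interval a conservative
bound for the flux constraints rather than a confidence interval. The
biomass-flux bounds use the quadrature combination of the relative
errors of $\mu$ and of the dry mass per cell, applied to $\mu$.

## The thermodynamic flux model

Each reaction is split into forward and backward flux variables
$v^+, v^- \in [0, M]$ with $M = 1000$ mmol/(gDW·h), the conventional
genome-scale bound. For every *estimable* reaction (all participants
covered by the formation-energy table; exchange half-reactions are
excluded) the transformed reaction Gibbs energy is a variable tied to
metabolite log-concentrations:
$$\Delta_r G' = \Delta_r G'^\circ + \gamma + RT \sum_j s_j \ln c_j,
  \qquad \gamma \in [-e, +e],$$
where $e$ is the quadrature-propagated formation-energy error and
$\Delta_r G'^\circ$ includes, for transport, the electrical work
$F \sum_j s_j z_j \psi_j$ (membrane potentials referenced to the
external compartment) and $RT\ln 10$ per pH unit for translocated
protons. Direction-use binaries enforce the second law:
$$v^+ \le M\,FU,\quad v^- \le M\,BU,\quad FU + BU \le 1,$$
$$\Delta_r G' \le -\epsilon + K(1 - FU),\qquad
 -\Delta_r G' \le -\epsilon + K(1 - BU).$$

Numerical choices:

* $\epsilon = 10^{-6}$ kJ/mol replaces the strict inequality
  $\Delta_r G' < 0$ — a MILP needs closed feasible sets.
* $K$ is computed per reaction from the attainable range of
  $\Delta_r G'$ given the concentration bounds (plus 1 kJ/mol), not set
  to a global big-M; loose couplings are a classic source of MILP
  integrality leaks.
* Unmeasured metabolites get the default concentration range
  $10^{-12}$–$0.1$ mol per total protein; measured intervals are
  clipped into that range with a warning. Only concentration *ratios*
  enter $\Delta_r G'$, so the per-protein unit convention cancels
  within a compartment.
* The pFBA stage fixes the biomass flux at its constrained optimum with
  an absolute slack of $10^{-9}$ (the solver feasibility tolerance); no
  relative slack is added to the minimum-flux-sum constraint before the
  variability sweeps.

pTFVA then minimizes and maximizes each reaction's net flux under the
fixed biomass optimum and the fixed minimum total flux. The work is
partitionable by reaction — results are identical whichever way the
reaction list is split — and all objectives for one instance are
dispatched to the backend in a single batch.

**Solver backend.** The environment provides no R linear-programming
package, so the problems are serialized (sparse triplets, staged and
batched objectives) to a small Python helper that calls scipy's HiGHS
interface single-threaded; statuses come back as
optimal/infeasible/unbounded/limit. The bridge is a dumb transport: all
model construction, staging logic and result interpretation stay in R.

## The comparison cascade

For each resistant/control pair the cascade is:

1. **Growth normalization** — every range endpoint is divided by the
   instance's biomass flux (the pFBA biomass value), so the biomass
   reaction maps to $[1,1]$ and uniform flux rescalings cancel.
2. **Dual-bound flagging** — per bound the relative difference is
   $|x_a - x_b| / \max(|x_a|, |x_b|, \delta)$ with $\delta = 10^{-8}$;
   a reaction is *different* only when **both** the lower and the upper
   bound differ by at least the threshold (default 0.15). The
   symmetric max-denominator avoids division by zero and makes the
   flag independent of argument order.
3. **Feature scaling** — per reaction, all endpoint values of all four
   instances are min–max mapped onto $[0,1]$ jointly. Scaling each
   reaction separately preserves cross-instance comparability where a
   single global scaling would crush small fluxes. Degenerate
   reactions (identical endpoints everywhere) map to 0.5, which keeps
   the downstream ratios defined and equal, hence never spuriously
   flagged.
4. **Control division** — each resistant instance's scaled bounds are
   divided by its own control's, with the denominator floored at
   $\delta$; reactions whose control value falls below the floor are
   marked incomparable and excluded from flagging (their count is
   logged). The two ratio sets (one per drug) are then compared with
   the same dual-bound rule, and subsystem summaries report the
   proportion flagged per subsystem and each subsystem's share of all
   flagged non-transport reactions.

The threshold default of 0.15 matches the largest relative standard
error of the underlying metabolite measurements; it is symmetric
(neither instance is privileged as the baseline), with the one-sided
variant expressible by swapping arguments.

## What the synthetic generator emulates — and what it does not

`make_bundle()` produces a two-compartment toy network (glycolysis,
TCA, oxidative phosphorylation, fatty-acid oxidation, transport,
biomass; ten internal metabolites by default, up to 60 with filler
glycolytic intermediates) together with formation energies constructed
so that the designed reference flux pattern is thermodynamically
downhill, plus four condition datasets: cell counts and medium curves
that follow the exact closed forms above, a glutamine-like compound
with first-order abiotic decay and a matching cell-free series,
multiplicative lognormal noise (concentrations are positive and the
assays quote CVs, not SDs), and intracellular concentration windows
bracketing the construction's reference point.

The toy's free rates (glucose uptake, lactate secretion,
glutamine-like uptake, two fatty-acid fluxes) determine every other
flux, including biomass, through linear balances, so each condition
embeds an exact reference flux vector. The default "resistant"
reprogramming scales glucose uptake by 0.8 and lactate secretion by
0.5 and triples both fatty-acid fluxes — injected into the glycolysis
and fatty-acid-oxidation subsystems, with a stoichiometrically forced
echo in TCA. Growth rates (0.033/0.031 h⁻¹ sensitive, 0.022/0.026 h⁻¹
resistant, resistant slower), the seeding density $X_0 = 2\times10^5$
cells, the dry mass per cell 400 pg, a decay constant of 0.01 h⁻¹ and
a 5% assay CV with 4 replicate wells are fixed at values typical for
exponential-phase colorectal-carcinoma cultures; none is derivable
from the network itself, so they are generator defaults, documented
here.

The optional *solvent effect* multiplies the growth rates of both
members of one pair by 0.9 — a proportional slowdown that scales all
of that pair's fluxes without reprogramming them. This is the one form
of pair-shared perturbation the cascade removes *exactly*: the
growth-normalization step absorbs it completely. A solvent effect that
altered individual reactions selectively would cancel only
approximately, because per-reaction min–max scaling amplifies relative
differences near a reaction's range minimum; with thresholded flags
that residual can surface as spurious differences. Passing the
solvent-cancellation check therefore demonstrates that pair-shared
*proportional* effects are removed, not that arbitrary solvent
responses are.

The loop LOOP1–3 is a deliberately closed 3-cycle: its three
metabolites carry zero formation-energy error, so the three reaction
energies sum to zero exactly and no feasible solution can run all
three in the same orientation — the thermodynamic loop-exclusion
property is exercised by construction in every bundle.

What the generator does **not** emulate: LC-MS peak-level artifacts,
instrument drift or isotope labelling; lag or stationary growth phases
(all fits assume exponential phase, as the constraints of the real
protocol do); gene–protein–reaction rules and expression-based model
extraction; and the scale of a genome-wide network — passing tests on
toys of 10–60 metabolites shows the algorithms are correct, not that a
4500-reaction model is computationally cheap or that real measurement
error is as well-behaved as lognormal noise.

## Envelopes

`sweep_min_fa()` pins the oxygen exchange at each grid value (equality
by default — an upper bound is available, and only the upper-bound
variant is monotone by construction) and minimizes total fatty-acid
influx, then resolves the per-substrate composition by lexicographic
secondary minimization in the configured substrate order, because the
total-minimizing optimum is typically degenerate across substrates.
`sweep_min_o2()` pins the summed fatty-acid influx and minimizes
oxygen influx, optionally per biomass level. By default each grid
point re-minimizes and fixes the total flux sum first (the pTFVA
convention), which makes the sweeps agree with the instance's own
pTFVA extrema at the operating point; `parsimonious = FALSE` gives the
plain two-stage LP. Curves are reported raw and divided by the
realized biomass flux of each point. The interior minimum of the
forced-influx oxygen curve — falling while the substrate displaces a
costlier oxidation route, rising once excess influx must be burned —
is demonstrated on `make_envelope_toy()`, which contains an explicit
oxidation-cost disposal sink for excess substrate.

## Problem sizes used in the checks

The shipped test-suite and acceptance script run on: toy bundles of 10
internal metabolites (24 reactions); 100 seeded noisy instances for
the second-law and range-nesting audit; 200 seeded conditions for the
rate-fit calibration (median relative error and ±1-SE coverage of
$\mu$, null-exchange coverage); brute-force per-reaction MILP oracles
on networks of at most 12 reactions; and 12–14-point envelope grids.
These sizes were chosen so that each property is exercised with
non-trivial variety while a full run stays in the minutes range on a
single CPU.

## Known limitations

* Ionic-strength (Debye–Hückel) corrections and pseudoisomer
  transforms are out of scope: the formation-energy table is taken as
  already transformed to compartment conditions.
* Coverage statistics and $\Delta_r G'^\circ$ assume a many-to-one
  metabolite-to-compound mapping; isomer-specific energies need
  distinct compound ids.
* The cascade compares exactly two ratio sets; designs with more than
  two resistance models per control would need a different final
  comparison.
* Growth normalization and control division are applied sequentially;
  effects that emerge only from the *interaction* of growth and
  solvent differences are not separable, and the package does not try.
* No statistical test is attached to the 15% rule — it is a
  reproducible threshold classifier, deliberately, and inherits the
  measurement-error rationale of its default value.
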