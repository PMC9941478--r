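---
title: "A hybrid stochastic-deterministic model of IP3-driven calcium puffs"
author: "puffr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid stochastic-deterministic model of IP3-driven calcium puffs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Inositol 1,4,5-trisphosphate (IP3) is produced at the plasma membrane and
must diffuse through the cytosol to reach its receptors (IP3Rs) on the
endoplasmic reticulum. Clusters of IP3Rs fire localized Ca2+ release events
-- puffs -- whose *latency* after an IP3 flash reports how fast IP3 arrived
at the cluster. `puffr` implements a simulation pipeline built around this
idea: a deterministic reaction-diffusion description of the IP3 and Ca2+
concentration fields coupled to stochastic four-state gating of IP3R
clusters, together with the latency statistics and the simulation-based
inference that turn photorelease experiments into an estimate of the
*effective* IP3 diffusion coefficient `D_I`.

Two analytical results frame the pipeline. First, reversible binding of IP3
to receptor monomers that are not fully occupied acts as an immobile buffer;
under rapid-equilibrium buffering the effective diffusion coefficient is

    D_I = D / (1 + R),   R = S_T * K_D / (K_D + [IP3])^2

with `D` the free coefficient (default 283 um^2/s), `S_T` the monomer
concentration and `K_D` the dissociation constant (default 0.119 uM);
`effective_D()` evaluates this. Second, the range of action of a messenger
scales as the square root of its diffusion coefficient
(`range_of_action()`), anchored at 24 um for the free coefficient.

## Model structure

### Deterministic fields

Both concentration fields live on a regular square (2D) or cubic (3D)
lattice restricted to the cytosol of a `domain_mask`; walls (plasma membrane,
ER obstacles) are reflecting. Per time step, operator splitting applies:

1. IP3: 5/7-point Laplacian diffusion plus the photorelease source,
2. Ca2+: diffusion, a constant ER leak, SERCA uptake
   `Vmax * c^2/(K^2 + c^2)`, and a release flux into the grid cell of every
   cluster currently open,
3. one stochastic gating update per cluster.

The leak is set so that it balances SERCA exactly at the basal Ca2+
concentration: the resting state is stationary by construction, which the
test suite verifies to below 1e-6 uM over 10^4 steps. The explicit step obeys
`dt <= h^2 / (2 * dim * D_max)` with a safety factor of 0.4
(`stability_dt()`); a convergence check in the tests bounds the residual
discretization error (halving `h` moves a probe IP3 time course by < 2%).

Photorelease of caged IP3 comes in three protocols (`protocol_spot()`,
`protocol_distributed()`, `protocol_uniform_step()`): a source term of rate
`theta` (uM/s) in a 0.25-um-radius spot while `t <= t_ph`; ten spots at
`theta/10` each (same total amount) placed evenly along the major axis at
mid-height, mimicking a near-uniform uncaging; or an instantaneous uniform
concentration step. There is no IP3 degradation term: the experiments the
pipeline emulates use a non-metabolizable IP3 analog.

In 2D an effective depth `d_eff` converts areal cells to volumes. Its
default, 1/2.25 um, makes the 1.5 x 1.5 um^2 detection footprint equal to
1 fL, so that "the average over the monitoring volume" means the same thing
in 2D and 3D.

### Stochastic cluster gating

Each cluster of 10-20 IP3Rs is one stochastic unit with states C (closed),
O (open), I1 and I2 (inhibited), and edges C->O, O->C, O<->I1, I1<->I2,
I2->C. The opening propensity couples the cluster to both fields:

    P(C -> O) = k_co * Ca * ( [IP3] / ([IP3] + k_ip) )^4

with `Ca` and `[IP3]` the detection-volume averages. The fourth power
expresses that a tetrameric receptor conducts only with all four monomers
IP3-bound; it makes the mean first-puff latency fall steeply with [IP3], as
observed. In molecule-number form the saturating ratio carries the
extensivity factor Omega in numerator and denominator, so it cancels and
concentrations can be used directly; Omega is kept in `model_params()` as
bookkeeping only. The I1->I2 transition carries a steep Ca dependence
(`k_i1i2 * Ca^4`): an isolated cluster, whose own puff raises the local
average only slightly above threshold, almost never reaches the deeply
inhibited state, whereas synchronized release by many coupled clusters
drives them into I2 collectively. This separation is what allows rare
cell-wide spikes to coexist with frequent local puffs.

The hybrid update freezes all propensities over one step `dt` and lets each
cluster fire at most one transition with probability `1 - exp(-a_tot*dt)`.
The scheme is exact for constant propensities and its time-discretization
bias is bounded in the tests against a zero-dimensional exact Gillespie
implementation (`gillespie_exact()`, kept solely as an oracle). A warning is
raised when `a_tot*dt` exceeds 0.1.

### Puff detection and latency observables

A puff is an excursion of the 1 fL detection-volume Ca2+ average above
0.1 uM (`detect_puffs()`); a spike is the same detector applied to the
domain-average concentration. Two latency conventions coexist, and the
package uses each where it belongs:

* **threshold crossing** (the puff definition) for trace statistics, the
  latency-versus-[IP3] curve and the minimal-latency floor;
* **first cluster opening** for the distance-keyed latency scans used in
  inference, where each run is terminated at the first opening.

`summarize_latencies()` computes the mean latency (ML) and the minimal
first-puff latency (MFP, the mean of per-group minima). The default grouping
is 10 groups of 5 replicates; an alternative reading of the grouping (5 x 10)
exists in the literature, so the grouping is an explicit argument and is
recorded in the output. Sample (n-1) standard deviations are used throughout;
censored runs are excluded with a warning above 10%.

## Parameter choices and calibration

Transport constants are taken from consensus values: `D_Ca` = 40 um^2/s
(effective, buffered), basal [IP3] = 50 nM, basal [Ca2+] = 50 nM, free IP3
diffusion 283 um^2/s and `K_D` = 0.119 uM for the buffering calculator, and
`D_I` = 100 um^2/s as the default effective coefficient (the value obtained
when evaluating the buffering relation at oscillatory IP3 concentrations and
neuroblastoma receptor densities).

The cluster rate constants are phenomenological and cannot be measured
directly; they were calibrated **once**, before the acceptance checks were
frozen, so that an isolated cluster reproduces reference puff statistics of
EGTA-uncoupled SH-SY5Y-like conditions:

* interpuff intervals of ~4.6 s at [IP3] = 0.15 uM and ~1.9 s at 0.38 uM;
* a mean first-puff latency versus [IP3] relation that, inverted through the
  closed mass balance of the ten-spot distributed flash, maps latency
  targets of 8.9/6.4/1.9 s (for 0.1/0.2/0.5 s flashes) onto a photorelease
  rate near 600 uM/s;
* a minimal first-puff latency floor of ~0.3 s, nearly independent of
  [IP3], realized as the rise time of the 1 fL average after an opening
  (the release flux `j_release` and SERCA `Vmax` were chosen jointly to
  give a ~0.25 s rise with a puff amplitude just above threshold).

The resulting defaults in `model_params()` are `k_co` = 553 /(uM s),
`k_ip` = 0.345 uM, open-state exits `k_oc` = 0.583 and `k_oi1` = 0.25 /s,
fast I1->O return `k_i1o` = 2.5 /s, collective inhibition
`k_i1i2` = 150 uM^-4 s^-1 with recovery `k_i2c` = 0.02 /s, SERCA
Vmax 3 uM/s (K 0.2 uM, Hill 2) and a release rate of 3 uM um^3/s per open
cluster. `k_ip` is an *effective cluster-level* constant, larger than the
single-channel dissociation constant, because the latency curve constrains
the fourth-power saturation jointly with the interpuff intervals.

Note the chain of constraints this calibration closes: the interpuff
intervals fix the opening rate at two concentrations, the latency-target
inversion fixes the curvature of the opening rate in between, and the
latency floor fixes the detection rise time. The collective (spike) regime
is *not* part of the calibration and is an emergent prediction -- see
Limitations.

## Photorelease-rate calibration and D_I inference

`calibrate_theta()` reproduces the two-stage procedure used with distributed
photorelease data: (1) simulate the single-cluster mean latency on a uniform
[IP3] grid (0.06-0.40 uM, 8 log-spaced points, 50 replicates each) and invert
the monotone curve at each observed mean latency to get the concentration
`c_k` each flash must reach; (2) since the distributed flash adds
`theta * t_ph * V_spot / V_cell` (measured on the lattice) to a closed
domain, solve the resulting linear relation for the least-squares `theta`
over all targets. Extrapolation beyond the simulated curve is refused.

`estimate_DI()` scores a grid of candidate diffusion coefficients (default
10/50/100/200 um^2/s) against a distance-keyed latency dataset: for each
candidate it simulates the spot-photorelease, one-cluster-at-a-time protocol
at the observed distances, summarizes ML and MFP, and accumulates
`(sim - obs)^2 / (SEM_obs^2 + SEM_sim^2)` over both curves. Both curves
enter because mean latencies alone cannot separate a slower diffusion
coefficient from a stronger flash: the minimal latencies carry the arrival
time of IP3, the means carry the equilibrium opening rate. The simulated SEM
appears in the weights because the candidate curves are Monte Carlo
estimates; with observed-only weights a single lucky small SEM on a group
minimum dominates the objective.

### The fast latency sampler

Before its first opening a solitary cluster does not perturb the Ca2+ field
(leak and SERCA balance at basal), and the IP3 field is deterministic.
First-opening latencies are therefore sampled *exactly* from the
inhomogeneous Poisson process whose rate follows the deterministic IP3 time
course at the cluster: one PDE integration per (geometry, D_I, t_ph) serves
every replicate, and because the diffusion equation is linear in the source,
a unit-rate course is rescaled for any `theta`. Beyond the recorded horizon
(`default_t_pde()`, 20-60 s depending on D_I) the rate is held at its final
value; for fast diffusion the field has equilibrated by then, for slow
diffusion this slightly *underestimates* the late rate rise at distal sites,
an approximation shared by every candidate in a grid search. The sampler is
tested for distributional agreement (Kolmogorov-Smirnov) against the full
hybrid simulation.

## The synthetic-data generator

`generate_spot_dataset()` runs the simulator at a known ground truth
`(D_I, theta)` and emits per-distance first-puff latencies in the same CSV
schema the inference consumes; the ground truth travels in a sidecar JSON
that `estimate_DI()` never reads. `generate_parametric_dataset()` is a
simulator-free fixture: exponential latencies around a given mean curve with
a 0.3 s offset floor, matching the observed dispersion shape. The generators
emulate the *statistical structure* of photorelease experiments -- 50
replicates per condition, exponential dispersion, censoring at the recording
horizon -- but not camera noise, optical point spread, spatial heterogeneity
of receptor density, or any drift between replicates; passing recovery tests
therefore demonstrates the estimator's self-consistency, not robustness to
experimental artifacts.

## Numerical choices

* Grid: cell-centered, half-open cells, origin at the bounding-box corner;
  `h` = 0.25 um in 2D (resolving the 0.25 um spot), 0.5 um in 3D.
* Release flux is an amount rate (uM um^3/s) divided by the cell volume, so
  the deposited Ca2+ mass is grid-independent.
* Near-membrane placement clamps the tolerance to the wall-adjacent cell
  layer when it is below `h`: sub-grid placement is meaningless.
* Procedural ER bars avoid wall-adjacent and protected cells and each bar
  must leave the cytosol connected; a drawn ER mask is rejected if it
  disconnects the cytosol or covers a cluster.
* While no cluster is open and the Ca2+ field has relaxed back to the basal
  uniform value (deviation < 1e-7 uM), the deterministic Ca2+ update is the
  identity and is skipped; this accelerates long waiting phases without
  changing the dynamics beyond the 1e-7 uM snap.
* Ties and degenerate inputs: empty traces, all-equal latencies, fewer than
  two events, and extrapolated calibration targets raise errors rather than
  returning silent defaults.
* Reproducibility: every stochastic entry point takes one seed; per-replica
  seeds derive from it by a fixed linear splitting rule, so any single
  replicate can be rerun in isolation.

### Problem sizes used by the test and acceptance runs

Interpuff intervals: 50 replicates x 60 s per concentration. Coupled spikes:
3 replicates x 600 s on an h = 0.5 um lattice. Latency curve: 8
concentrations x 50 replicates. Recovery: 10 trials per ground truth, 12
distances x 50 replicates each, candidate grid {10, 50, 100, 200}. These
sizes keep the full suite within a desk-scale run while leaving every
comparison its stated statistical tolerance.

## Limitations

* **Collective spike statistics are not quantitative.** The calibration
  pins the solo-cluster regime; the puff mass it implies (a sustained
  ~0.3 s release per event) is large relative to a 5 x 10 um^2 domain, so
  the coupled ten-cluster preset produces frequent, small domain-average
  crossings rather than ~2-minute cell-wide spikes. Reproducing reference
  interspike intervals (~130/108 s) would require the underlying base-model
  constants, which are not recoverable from the solo statistics alone. The
  acceptance suite asserts the reference values anyway and documents the
  failure rather than hiding it.
* **Basal spontaneous activity floors the distal minimal latencies.** At
  basal [IP3] the opening rate is small but nonzero; over 50 replicates the
  earliest event at a distant site can be a spontaneous opening, which
  compresses the contrast between slow- and fast-diffusion minimal-latency
  curves at large distances.
* **Distributed-flash inhomogeneity decays fast.** With ten evenly spaced
  spots the longest excited spatial mode has the inter-spot wavelength, so
  even at D_I = 10 um^2/s the spatial CV falls below 5% within seconds;
  claims of inhomogeneity persisting for tens of seconds require release
  layouts that leave concentration differences on a >30 um scale.
* The ER is a static binary obstacle field; tubular 3D network geometry and
  its remodeling are out of scope, as are single-channel IP3R gating models
  and IP3 metabolism.
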