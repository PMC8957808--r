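---
title: "A firing-rate model of the rodent social-fear circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A firing-rate model of the rodent social-fear circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialfear)
```

## The model

`socialfear` simulates the brain system that turns repeated social defeat
into social avoidance in rodents, and extinguishes that avoidance again
under repeated safe exposure. Each unit represents a neural population as a
leaky firing-rate node,

$$\tau \dot V_{post} = -V_{post} + I + \sum_{pre} w_{post,pre}\,F(V_{pre}),
\qquad F(V) = [\tanh(V)]^+,$$

integrated with the explicit Euler method (default $\Delta t/\tau = 0.1$,
500 steps per trial). The rectified tanh keeps every rate in $[0,1]$; the
voltage itself may go negative, so inhibition can hyperpolarise a unit
below its firing threshold. The update is synchronous: every presynaptic
term uses the rates from the previous step, so unit ordering is
irrelevant. There is no noise anywhere in the simulator — identical
configurations produce bit-identical trajectories.

A subset of connections learns through a simplified
Bienenstock–Cooper–Munro rule with a fixed threshold,

$$\Delta w = \alpha\,(F_{post} - \theta)\,F_{pre},$$

clipped to a per-edge $[w_{min}, w_{max}]$ range after every step.
Postsynaptic activity above $\theta$ potentiates (LTP), activity below
depresses (LTD), and a silent presynapse gates the update off. The rule is
applied once per time step, immediately after the Euler update, using that
step's rates; with the small learning rates shipped here this produces the
gradual within-trial drift visible in the weight snapshots.

### Architecture

The main circuit (`build_basic_model()`) has 16 units in seven areas.
Three inputs drive it: the *conspecific* (medial amygdala, MeA), the
*context* (two ventral-hippocampal units, Hip1/Hip2, one per context) and
the *defeat* (the nociceptive lateral parabrachial nucleus, lPBN, plus the
prefrontal somatostatin unit Som1). Inside the ventrolateral ventromedial
hypothalamus (VMHvl) the threat unit Hyp1 and the interaction unit Hyp2
compete through the GABAergic interneurons HypIN1 and HypIN2 — a
winner-take-all in which HypIN1 inhibits Hyp1 (driven by Hyp2) and HypIN2
inhibits Hyp2 (driven by Hyp1); the naming convention indexes the
*inhibited* target. MeA also reaches the mediodorsal thalamus (MDT), whose
plastic projections onto the prefrontal pyramidal populations Pyr1
(fear-ON) and Pyr2 (fear-OFF) and onto the parvalbumin unit Pv reorganise
with defeat. Pyr1 and Pyr2 inhibit each other through the somatostatin
units Som2 and Som3, and Som1+Pv form the double-inhibition circuit that
disinhibits Pyr1 during defeat. The output unit dPag1 (dorsal
periaqueductal gray) receives exactly two afferents — excitatory from Hyp1
and inhibitory from Pyr2 — and its activation is the model's readout of
social avoidance. The Pyr2→dPag1 weight is negative despite the
glutamatergic presynapse: it stands in for an indirect suppressive
mechanism, abstracted into a direct inhibition, and is the single
documented exception to the sign rule that `validate_spec()` enforces.

Pyr1 has no direct projection to dPag1; its fear-promoting role is
expressed through Som2-mediated inhibition of Pyr2, i.e. disinhibition of
the output. The primary literature contains one sentence attributing the
dPAG-inhibiting projection to Pyr1; we follow the architecture
description, under which Pyr2 is the projecting population.

The alternative circuit (`build_alternative_model()`) adds a single
GABAergic lateral-septum unit (LS), driven by the conspecific input, with
one fixed inhibitory edge onto Hyp1. The two variants are structurally
identical apart from that unit and its links, but the variant carries its
own weight calibration of the VMHvl pathway (see below).

### Protocol and manipulations

`default_protocol()` encodes the three-phase social-fear procedure: one
baseline trial (conspecific + context 1), three conditioning trials that
add the defeat input, and eleven extinction trials of re-exposure.
Voltages reset to zero at every trial start — trials are separate
exposures — while weights persist; whether membrane state should carry
over between exposures is not constrained by the phenomenology, and the
reset is the simplest reproducible convention.

In-silico experiments are expressed as timed `manipulation()` objects:
silencing clamps a unit's rate to zero (its leak dynamics continue, which
matches pharmacogenetic or optogenetic output suppression), stimulation
adds a tonic term to the external input, block/scale act on the
*effective* weight used by the dynamics while plasticity continues to act
on the stored weight, and freezes disable the BCM update on selected
edges. Outside its phase/trial/step window a manipulation has provably no
effect on the trajectory.

## Calibration

The anatomy fixes the sign, existence and plasticity of every edge; the
numeric weights are free parameters. They were calibrated by
coordinate-wise adjustment until the full qualitative checklist passes
(`qualitative_criteria()`): quiet baseline, conditioning that recruits
dPag1, extinction completing within eleven trials, stability of the VMHvl
weights during extinction, and the five target-experiment reproductions.
That checklist is kept as a permanent regression test, so any future
parameter change must re-establish the full phenomenology.

Choices worth making explicit:

* **Thresholds.** Avoidance is scored as the trial-mean dPag1 rate; a mean
  of at least 0.1 counts as avoidance and extinction completes at the
  first extinction trial below 0.1. Unit classification uses a
  responsiveness cutoff of 0.15 on the trial-mean rate at the first and
  last extinction trials. Both cutoffs are arguments throughout the API.
* **Per-edge plasticity parameters.** The BCM threshold is global
  ($\theta = 0.5$, the midpoint of the rate range) except on MDT→Pyr2
  ($\theta = 0.12$), and learning rates differ across the three MDT
  efferents. These per-edge values are what let a single fixed-threshold
  rule express, at 500 steps per trial, (i) fast acquisition, (ii) a
  fear-OFF population that is suppressed right after conditioning yet
  re-potentiates over extinction, and (iii) the bistable Pv pathway that
  the low-frequency-stimulation prediction requires. With one global
  $(\alpha, \theta)$ these demands are mutually unsatisfiable.
* **Extinction pacing.** In the main model, extinction is paced by slow
  re-potentiation of MDT→Pv: after defeat has depressed that edge, the Pv
  rate sits just above $\theta$, so its recovery accelerates over trials,
  progressively shuts down Pyr1, releases Pyr2 from Som2 inhibition, and
  the re-potentiating MDT→Pyr2 edge then ratchets the brake back on
  (avoidance falls below threshold on extinction trial 7). The VMHvl
  weights cannot drift during extinction because conditioning drives them
  into their clip bounds — saturation, not absence of drive, is what makes
  the subcortical memory stable.
* **MDT stimulation.** High- and low-frequency stimulation of MDT are
  modelled as tonic drive regimes (amplitude 2.0 for 20 trials, 0.35 for
  15 trials) with plasticity enabled only on the MDT efferents, inserted
  between conditioning and extinction. The contract is the end state — net
  LTP on MDT→Pyr2 and MDT→Pv for HFS, rates strictly between zero and the
  edge threshold (net LTD) for LFS — and
  `mdt_stimulation_block(check = TRUE)` verifies it, erroring on
  mis-calibrated amplitudes. LFS abolishes extinction by pushing MDT→Pv
  below the bistability point of its recovery dynamics, which leaves Pyr1
  elevated and Pyr2 suppressed indefinitely.

### The alternative model's quantitative brackets

The alternative variant is calibrated so that the in-silico lateral-septum
inhibition experiment reproduces the published brackets: scaling the
LS→Hyp1 output down *during extinction* in 1% steps, trials-to-extinction
first exceeds the unmanipulated control at a **30%** reduction and
extinction stops completing within eleven trials at a **38%** reduction
(`ls_scaling_sweep()`, `ls_thresholds()`). Landing both integer
thresholds requires the variant to re-calibrate the VMHvl pathway rather
than inherit the main model's weights: the threat unit's afferents get
tighter bounds and faster learning, the WTA becomes asymmetric, and the
dPAG afferents are rebalanced so that the late extinction trials are
decided in the flat part of the prefrontal brake's recovery, where the
residual Hyp1 floor activity controls the crossing. Under this
calibration the control extinguishes on trial 7, every reduction below
30% behaves identically to control, and the 30–37% window spans
trials-to-extinction 8 through 11.

Two consequences are documented deviations. First, the variant's threat
unit declines across extinction, so under the first/last-trial
responsiveness table it classifies as a *fear* unit; the VMHvl's
*extinction*-class population is the interaction unit Hyp2 (suppressed
right after conditioning, responsive again after extinction). This is how
"the persistent population is substituted by an extinction population"
is realised here: persistence disappears from the VMHvl, and an
extinction-class population appears. Second, the Hyp2 afferents do not
visibly re-potentiate during extinction in the shipped calibration — a
variant that shows that potentiation exists (lower the Hyp2-afferent BCM
thresholds), but it destroys the exact 30/38 brackets, and we prioritised
the quantitative result.

## Unit classes

After the default protocol, responsiveness on the first versus last
extinction trial sorts units into fear (yes/no), extinction (no/yes),
persistent (yes/yes) and unresponsive (no/no) classes. The main model
yields Pyr1 = fear, Pyr2 = extinction and Hyp1 = persistent — the cortex
returns to its naive configuration while the subcortical threat memory
survives extinction; the alternative model removes that persistence, as
described above.

## Sensitivity analysis

`sensitivity_sweep()` rescales each connection's initial weight over a
multiplicative grid (0 to 2 in steps of 0.05) and re-evaluates the
qualitative suite at every scale, reporting the widest contiguous pass
interval around the shipped value. On the shipped calibration the
narrowest tolerated ranges belong to MDT→Pv (the extinction pacemaker),
MDT→Pyr1 (the fear-acquisition pathway, which must both ignite during
defeat and stay quiet at baseline) and Pv→Pyr1; everything else tolerates
at least roughly ±50% on at least one side, and most edges the whole
grid. The published analysis instead names MDT→Pyr1 and lPBN→Hyp1 as the
two fragile edges. The first is reproduced; the second is not — here
lPBN→Hyp1 tolerates (−35%, +100%) because its upper side merely saturates
the already-winning threat unit, and the fragility the original work
attributes to it is absorbed by the Pv pathway that paces extinction in
this calibration. The corresponding acceptance test records this
difference as a failing expectation rather than weakening the check.
Structurally, deleting the interneuron HypIN1 or removing the Som1→Pyr2
edge (or both) leaves every qualitative criterion passing, matching the
published removability claim.

## Scope and limitations

The generator of all inputs is the protocol itself — there are no data.
What passing tests show is that this circuit, under the shipped
calibration, reproduces the qualitative phenomenology and the two
quantitative LS brackets; they do not validate the model against neural
recordings, and population rates in $[0,1]$ are dimensionless
abstractions. Spiking dynamics, conduction delays, oscillations, noise,
and areas outside the minimal circuit (NAcc, PVT, BNST, pre-mammillary
nucleus, layered mPFC structure) are out of scope. Problem sizes are
small by construction — a full protocol is 15 trials of 500 Euler steps
over at most 17 units — so every experiment in the package, including the
complete sensitivity sweep, runs in seconds to a couple of minutes on one
CPU.
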