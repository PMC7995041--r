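---
title: "Reduced-order modeling of a fluidic-oscillator ventilator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order modeling of a fluidic-oscillator ventilator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscvent)
```

## The system being modeled

A bistable fluidic oscillator can turn a constant air supply into a
ventilation waveform with no moving parts: a planar jet attaches to one
of two walls (the Coanda effect), either charging a lung through a
vortex chamber or venting it through an exhaust channel, and the lung's
own pressure flips the jet between the two states. Three set-screws
partially occlude the exhaust (EC), feedback (FC) and side (SC)
channels, giving the user bedside-style control of the oscillation
period and of the peak inspiratory and end-expiratory pressures (PIP,
PEEP).

`oscvent` replaces the 3-D jet dynamics with the smallest model that
reproduces this behavior: a **switched linear system**.

* **Lung.** A single-compartment first-order Windkessel: airway
  resistance $R_{aw}$ in series with compliance $C$, inflated above a
  baseline $P_{peep}$. Alveolar pressure is algebraic in the state,
  $$P_{alv}(t) = Q R_{aw} + \tfrac{1}{C}\textstyle\int_0^t Q\,dt +
  P_{peep} + P_{pl},$$
  with $Q$ the lung flow and $P_{pl}$ the pleural (patient-effort)
  pressure. The accumulated volume $V=\int Q\,dt$ is the only
  integrated state, which keeps flow and volume exactly consistent.
* **Diverter.** The jet's two attachment states become two phases with
  a hysteresis rule: inspiration ends when $P_{alv}$ reaches an upper
  threshold $P_{high}$, expiration ends when it falls to $P_{low}$,
  and between the thresholds the phase is held. This abstraction is
  justified by the way the physical device is characterized: switching
  is reported purely as a function of lung pressure at the transitions
  (20 and 8 cmH2O on the reference configuration).
* **Inspiration** is constant-flow charging: a fraction
  $\eta_{insp}$ of the source flow $Q_{src}$ reaches the lung, the
  remainder venting through the side channel. The device is driven by
  a fixed 30 L/min supply and shows near-constant inspiratory times,
  which this law reproduces by construction.
* **Expiration** is a passive discharge through the exhaust path,
  $Q = -P_{alv}/R_{exp}$, where $R_{exp}$ is the EC screw's resistance
  law plus the airway contribution. Combined with the pressure
  equation this gives a linear RC relaxation of $P_{alv}$ toward
  atmosphere with time constant $(R_{exp}+R_{aw})\,C$ — the closed form
  `expiration_closed_form()` used as the integrator's oracle.

All pressures are gauge (atmosphere = 0). Internal units are cmH2O, L,
s; configuration files use mL/cmH2O, L/min and mm and are converted on
load.

## Screw models

Each screw maps an occlusion fraction $d \in [0,1]$ to a resistance
$$R(d) = R_{open} + R_{span}\,\frac{d}{1-d+\delta},$$
monotone and finite at full closure. The taper constant $\delta$
decides where along the screw travel the resistance change happens. A
very small $\delta$ concentrates essentially all of it in the last few
percent of travel, which would make the period jump from its minimum to
its maximum near $d=1$ instead of growing steadily; the EC channel
therefore uses $\delta_{EC} = 0.75$, which spreads the change across
the travel and gives the near-linear depth-to-period relation the
physical device exhibits ($r^2 = 0.95$ over an 11-point sweep).

The FC and SC screws act on the switching thresholds rather than on a
flow path — the feedback channel's physical role is jet steering, not
bulk flow — through affine maps
$$P_{high} = 20 + 8\,d_{SC} - 8\,d_{FC}, \qquad
  P_{low} = 8 + 4\,d_{SC} - 4\,d_{FC},$$
whose signs encode the observed directions (closing SC raises PIP,
closing FC lowers it, with PEEP moving half as fast). At the screw
midpoints the thresholds are the reference 20/8 cmH2O, and the maps
keep $P_{high} > P_{low}$ over the whole admissible screw box, so no
reachable setting can deadlock the oscillator; `diverter_config()`
rejects threshold constants that could.

## Calibration

Four constants are not identifiable from first principles and were
fitted once against the device's published operating points
(`tools/calibrate.R`, a one-off script outside the runtime path), then
frozen as the `diverter_config()` defaults:

| constant    | value | fixed by                                        |
|-------------|-------|-------------------------------------------------|
| `eta_insp`  | 0.6945 | inspiratory time ≈ 0.92 s on the healthy lung  |
| `R_EC_open` | 77.86 | period 3.00 s at $d_{EC}=0$                     |
| `R_EC_span` | 57.57 | period 5.00 s at $d_{EC}=1$                     |
| `delta_EC`  | 0.75  | near-linearity of period vs depth               |

The inspiratory-time target 0.921 s balances the I:E ratio at the two
ends of the sweep. With constant-flow charging the inspiratory time is
nearly independent of the EC screw, so $T_e/T_i$ runs from 2.26 at the
3 s setting to 4.36 at the 5 s setting; exactly 1:2 and 1:5 would
require $T_i$ itself to fall from 1.0 to 0.83 s as the period grows,
which a constant-flow inspiration cannot do. This is a known, accepted
bias of the reduced model (both ends sit within 15% of the nominal
ratios).

## Patient trigger

Inspiratory effort is a forced pleural-pressure step with first-order
dynamics, $P_{pl}(t) = -A\,(1-e^{-(t-t_0)/\tau})$, default $A = 3$
cmH2O and $\tau = R_{aw} C$ of the active lung (0.09 s for the healthy
preset); a 5.5 cmH2O "bench" profile is also named. Efforts start at
scheduled times (default every 4 s) but only if the diverter is in
expiration — efforts scheduled during inspiration are skipped, not
queued — and reset to zero the instant the diverter answers with an
inspiration, because the model's purpose is the effect on switch
timing, not the full muscle-pressure profile.

The dip lowers $P_{alv}$, so the $P_{low}$ crossing happens earlier: a
premature inspiration, the intended trigger response. One consequence
worth knowing: at the premature switch the lung is fuller than at a
natural end-expiration by roughly $|P_{pl}|\,C$, because the effort —
not emptying — brought the pressure down. An effort initiated shortly
before the natural switch (alveolar pressure already inside the
8–11 cmH2O trigger band) is only partially developed when the switch
fires, and the following cycle matches the untriggered steady state
within 5% in PIP, PEEP and period. An effort initiated mid-expiration
is fully developed (the full 3 cmH2O) by the time the pressure reaches
$P_{low}$; the next inspiration then starts about $A C / Q \approx
0.26$ s early and that cycle's period deviates by up to ~7% (PIP and
PEEP are unaffected — they are set by the thresholds). Under the
periodic 4 s protocol both kinds of effort occur.

## Numerics

* **Integrator.** Fixed-step explicit midpoint (RK2), default
  $dt = 1$ ms. The system is piecewise linear and non-stiff at these
  parameters; a fixed step keeps runs bit-identical, which the test
  suite asserts. Against the closed-form expiratory discharge the
  integrator is accurate to well under 0.01 cmH2O, and halving $dt$
  moves no reported cycle metric by more than 0.5%.
* **Event location.** Threshold crossings are refined by bisection on
  the step to $dt/100$; the state at the switch instant is recorded
  twice (end of one phase, start of the next) so segmentation sees
  exact boundaries. Time in a record is therefore nondecreasing, with
  duplicates only at switch instants. PIP and PEEP of a simulated
  breath equal the thresholds to ~$10^{-4}$ cmH2O.
* **Degenerate inputs.** A zero source flow, an over-resistive exhaust,
  or threshold maps with $P_{high} \le P_{low}$ cannot oscillate; the
  engine watches for a missing switch within 10 times the analytically
  expected period and raises a diagnostic naming the violated
  condition. Compliances below 5 mL/cmH2O are accepted with a warning
  (the presets are 10/30/50).
* **Problem sizes.** The package's own checks use 60 s runs at
  $dt = 1$ ms (12–20 steady-state breaths, first two discarded) and an
  11-point EC sweep — a few seconds each on one core; shorter 25–40 s
  horizons are used where only steady state matters.

## The synthetic fixture generator

`make_synthetic_waveform()` builds the analytic waveform the analytics
are tested against: per cycle an exponential rise placed to pass
through PIP at exactly $T_i$, a decay returning to PEEP at exactly
$T_e$, phase labels with duplicated switch samples (mirroring the
engine), and optional seeded Gaussian noise — the only random element
in the package. Its default 17/11 cmH2O levels mirror the pressure
band reported for the physical prototype on a hardware lung simulator.
Noise-free fixtures are recovered exactly by both segmentation routes;
with noise of SD $\sigma$ the recovered PIP/PEEP are within $3\sigma$.
The fixture emulates waveform *shape* only: it has no flow/volume
channels, no cycle-to-cycle variability, no drift, and kink-sharp phase
transitions, so passing analytics tests demonstrates correct index
extraction, not robustness to every artifact of measured data.

## Segmentation conventions

PEEP is the pressure at the expiration-to-inspiration switch
(end-expiratory), not the cycle minimum: with a monotone expiratory
decay they coincide, but a patient effort can undercut the
end-expiratory level, and the clinical PEEP concept is end-expiratory.
I:E is reported as the scalar $T_e/T_i$ (displayed "1:x"). Triggered
cycles are flagged and excluded from steady-state summaries unless
requested. On bare pressure traces (no phase labels) cycles are cut at
detected troughs; turning points are filtered by prominence (10% of
the trace range) and spacing (0.5 s), and a record edge only counts as
a trough if it sits in the bottom quarter of the pressure band, so a
trace cut off mid-decay does not close a spurious cycle. Sample
standard deviations (n−1) are used throughout.

## Known limitations

* One lung compartment, linear compliance, no inertance: no
  volume-dependent stiffening, no airway collapse, no second-order
  resistive losses of the kind a physical piston simulator shows.
* No jet physics: vortex strength, feedback-channel transients,
  compressibility and acoustics are all folded into two thresholds and
  a flow-split fraction, so the model cannot predict how *geometry*
  changes those constants — the chamber-fill calculator
  (`characteristic_time()`) is a design-stage scaling law, not a
  coupled model.
* Constant-flow inspiration fixes $T_i$, biasing the I:E extremes as
  described above, and makes inspiratory pressure rise linearly rather
  than with the slight concavity of a real pneumatic charge.
* The hysteresis band equals $P_{high}-P_{low} = 12$ cmH2O on the
  reference configuration; the device's reported overall oscillation
  amplitude of 13 cmH2O is not reproduced, as the model ties the
  excursion to the thresholds.
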