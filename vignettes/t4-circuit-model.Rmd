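---
title: "Passive multiplication in a T4 neuron: models, analyses and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive multiplication in a T4 neuron: models, analyses and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t4circuit)
```

## The model

A T4 dendrite integrates five columnar input classes: glutamatergic Mi9
(reversal −71 mV, close to rest — a *shunting* input that is tonically
active in darkness), cholinergic Tm3 and Mi1 (reversal −21 mV, excitatory)
and GABAergic Mi4 and C3 (reversal −68 mV, delayed inhibitory). Because the
cell is electrotonically compact and capacitive currents are small and fast
relative to the synaptic conductance time courses, the membrane potential
can be written algebraically as the conductance-weighted mean of the
reversal potentials — no differential equation is needed:

$$V_m = \frac{E_{Glu}\,g_{Mi9} + E_{ACh}(g_{Tm3}+g_{Mi1}) +
E_{GABA}(g_{Mi4}+g_{C3}) + E_{leak}\,g_{leak}}{\sum_i g_i + g_{leak}}.$$

`simulate_vm()` evaluates this pointwise in time. Two structural facts
follow directly from the quotient and are enforced as tested invariants:

* **Boundedness** — $V_m$ is a convex combination of reversal potentials and
  can never leave their range.
* **Scale degeneracy** — multiplying all gains and $g_{leak}$ by a common
  factor leaves $V_m$ unchanged, exactly. Conductances are therefore
  dimensionless and only *ratios to* $g_{leak}$ are physically meaningful;
  all fitting output reports these ratios alongside raw values.

Presynaptic voltages are jointly min–max normalized per class across all
stimulus conditions (`normalize_inputs()`, preserving amplitude ratios
between conditions) and converted to conductances by a rectilinear transfer
function with two free parameters per class, a threshold and a gain.

**Transfer-function convention.** The verbal definition — a threshold below
which conductance is zero, and a gain — admits a continuous form
$g = \gamma\,\max(0, v-\theta)$ and a jump form
$g = \gamma\,v\,[v>\theta]$. The continuous form is the default
(`transfer(..., form = "continuous")`): it makes the least-squares surface
continuous in $\theta$, which bounded quasi-Newton optimization needs; the
jump form is available behind the `form` switch.

**Motion geometry.** The columnar receptive fields are spaced one
inter-ommatidial angle $\theta = 4.8°$ apart along the PD axis. For an edge
moving at angle $\varphi$ and velocity $v = 30°\,\mathrm{s^{-1}}$, the
spacing becomes a time shift $\Delta t = \theta\cos\varphi/v$
(`motion_delay()`), applied as an *advance* to Mi9 and a *delay* to Mi4/C3
relative to Mi1/Tm3. Sign convention: PD motion crosses the Mi9 column
first (Mi9 sits upstream along the motion vector of a PD stimulus), so its
release of inhibition leads the cholinergic drive; GABAergic inhibition
arrives last. At $\varphi = 0$, $\Delta t = 0.16$ s.

## Multiplicative disinhibition

`linearity_index()` quantifies the interaction between an excitatory
conductance event and the release of a tonically active inhibitory
conductance: the index is the voltage excursion of the coincident events
minus the sum of the excursions of each event alone, all measured from the
tonic baseline. For $E_{exc} = -21$, $E_{inh} = -68$, $E_{leak} = -65$ mV
and unit conductances the index is $+6.83$ mV — supralinear — while two
excitatory inputs always combine sublinearly in a passive membrane
(driving-force saturation). On a $50\times50$ grid over
$g_{exc}, g_{inh} \in (0, 5]$ the index is positive everywhere; exceptions
exist only when the excitatory reversal potential lies closer to the leak
reversal than the inhibitory one does (e.g. $E_{exc} = -64$ mV), which the
test suite exercises as a brute-force property.

Released shunting inhibition also *raises the input resistance*:
`predicted_input_resistance()` returns
$R(t) = (g_{leak}+\sum g_{dark}) / (g_{leak}+\sum g(t))$ relative to a
baseline epoch. With the reference parameters, PD edge motion opens a
window in which total conductance drops before the cholinergic drive peaks,
so the resistance transient *precedes* the depolarization — the ordering the
time-locked current-clamp analysis checks.

## The cable model

To assess space-clamp artefacts and dendro-somatic signal propagation, the
package builds a passive compartmental model from SWC reconstructions.
Every SWC sample point is one compartment; edge length is the distance to
the parent point and the edge uses the child point's diameter (this keeps
assembly linear-time and makes the compartment count equal the retained
point count). The root has no parent edge; its membrane area uses the
distance to its first child. Membrane leak per compartment is
$\pi d L / R_m$, capacitance $C_m \pi d L$, axial conductance
$(\pi d^2/4)/(R_a L)$, with $R_a = 150\ \Omega$ cm, $R_m = 28$ kΩ cm²,
$C_m = 1$ µF cm⁻² by default. Discretization note: the root's extra
membrane segment makes a coarse unbranched cylinder slightly larger than
its nominal geometry; at realistic point densities (hundreds of points) the
effect is below one percent, and a 501-point, 100 µm × 1 µm cylinder
reproduces the closed-form input resistance $R_m/(\pi d L) \approx 8.9$ GΩ.

The dynamic solver is implicit Euler at $\Delta t = 0.1$ ms,
$(M + c_m/\Delta t)\,V(t) = c_m/\Delta t\,V(t-1) + E_{leak} g_{leak} + I(t)$,
unconditionally stable, with the steady state as its fixed point; a single
compartment relaxes with $\tau = R_m C_m = 28$ ms. Synaptic conductances
enter the matrix diagonal at their site and, multiplied by their reversal
potential, the right-hand side.

**Voltage clamp.** The amplifier is a proportional–integral controller,
$I(t) = K_p (V_{cmd} - V_{soma}(t)) + K_i I(t-1)$ with $K_p = 2\times10^9$ S
and $K_i = 1$. Because the controller references the *same-step* soma
voltage, it is folded into the implicit solve ($K_p$ on the clamp-site
diagonal; $K_p V_{cmd} + K_i I(t-1)$ on the right-hand side) — the explicit
(previous-step) variant diverges at this gain. Numerically, the injected
current is recovered from the network balance at the clamp site rather than
from $K_p(V_{cmd} - V_{soma})$: the latter multiplies the solver's
machine-precision voltage error by $K_p$ and would drown the picoampere-scale
physiological currents. With this scheme the soma sits on the command
voltage to machine precision and the holding current settles on the Ohmic
value.

**Space clamp.** `iv_reversal()` estimates a synapse's reversal potential by
regressing the leak-subtracted evoked current on the command voltage. At
the clamp site the estimate is exact. For a distal synapse the local
dendritic voltage is attenuated *towards* $E_{leak}$ relative to the
command, so the command at which the local driving force vanishes — the
apparent reversal — lies *farther from* $E_{leak}$ than the true $E_{syn}$:
analytically $V^* = E_{leak} + (E_{syn}-E_{leak})/a$ with voltage-transfer
ratio $a \in (0,1]$. The simulation reproduces this closed form (e.g.
$a = 0.87$ gives $V^* \approx -14.5$ mV for a −21 mV synapse), which is the
quantitative face of the space-clamp artefact the model exists to expose.

## Receptive-field analysis

`reverse_correlate()` computes $K(x,\tau) = \sum_t S(x, t-\tau) V_m(t)\,
\Delta t$ at the stimulus frame rate over lags $-0.5$ to $+3$ s, after the
voltage has been drift-corrected (subtraction of a 60 s-s.d. Gaussian
low-pass) and resampled to the stimulus clock — the kernel is then
independent of the physiological sampling rate. Kernels are z-scored
(reference region: the whole kernel by default, configurable to the
pre-zero lags) and screened: the extremum must reach 4 s.d. and the centre
must lie at least 22.48° from the screen bezel; rejection is a typed
outcome, not an error. Accepted kernels are re-referenced so the extremum
sits at 0°, optionally rotated to each cell's PD, cropped to the largest
common region, averaged, upsampled ×10 and smoothed (1.8 px s.d.).

A caveat the tests make explicit: the screening threshold is a fixed
4 s.d., but the maximum of the thousands of near-standard-normal values in
a kernel grows like $\sqrt{2\ln m}$, so a pure-noise cell is accepted with
appreciable probability once the kernel holds more than a few hundred
effectively independent values. On the 8×6-pixel test screen the measured
null rejection rate is ~65%, not near-certain rejection; with realistic
full-screen kernels the criterion is even more permissive. The acceptance
checks report the measured rate rather than asserting an unattainable one.

Directional statistics follow the vector-sum convention: the preferred
direction is the angle of the resultant of direction-tagged response
vectors (`preferred_direction()`, with a typed undefined outcome for a
vanishing resultant), and the tuning index is
$L_{dir} = |\sum_\varphi \mathbf v(\varphi)| / \sum_\varphi |\mathbf
v(\varphi)| \in [0,1]$. Edge-tuning amplitudes are the maxima of Voigt
profiles fitted in a 700 ms window around the raw peak (1 s pre-stimulus
baseline; centre initialized at the raw argmax, Gaussian width at
window/8, Lorentzian width at zero, centre bounded to the window). The
Voigt profile is evaluated through the Faddeeva function using Humlicek's
four-region rational approximation — the textbook erf-based formula
overflows for near-real arguments, exactly the Gaussian limit the fits
visit. Non-converging fits fall back to the raw peak with a warning.

## Synthetic data: what it emulates, and what it does not

The generator produces the *qualitative signatures the analysis relies on*,
not calibrated physiology: Mi9 holds a tonic depolarized level in darkness
and hyperpolarizes at ON (anticorrelated with luminance); Mi1/Tm3 are fast
ON-depolarizing; Mi4/C3 are delayed (≈150 ms vs ≈30 ms); receptive fields
sit one column (4.8°) apart along the PD axis. Each class filters the
rectified local luminance contrast in a Gaussian receptive field with a
unit-area double-exponential kernel, shifted by its latency, scaled to its
amplitude and corrupted with additive white Gaussian voltage noise
(correlated noise is deliberately absent). Response amplitudes in mV are
free parameters, not measurements. The four classes' kinetics are
deliberately distinct (Tm3 faster and larger than Mi1, C3 slower than Mi4):
identical traces would make the members of each transmitter pair exactly
exchangeable in the voltage equation and their thresholds structurally
unidentifiable.

The generator normalizes its own traces by each class's known physiological
range rather than by the realized data min–max, so degenerate stimuli
(darkness) remain well defined; for stimuli that sweep the full range the
two normalizations coincide, and the forward-consistency test asserts that
a zero-noise synthetic T4 sweep at zero holding current is *bit-identical*
to `simulate_vm()` on the synthetic presynaptic drives.

Episode sets add the holding-current offset $I_{hold} R_{in}(t)$, with
$R_{in}(t)$ following the model's total conductance scaled to a dark-state
baseline of 5.28 GΩ (the wild-type mean used as synthetic ground truth); at
−5 pA in darkness the offset is −26.4 mV.

Because the generator's edge responses are sustained (luminance steps and
stays), the model's directional tuning derives from the transient overshoot
over the late direction-independent plateau. Silencing Mi9 in the model
broadens the tuning curve — larger half-width at half-maximum, lower
$L_{dir}$ — with the broadening concentrated at 90–150° off PD rather than
at ±60° where in vivo curves differ most; the tests assert the qualitative
broadening, not in vivo amplitudes. More generally, passing tests on this
synthetic data demonstrate the *correctness of the analysis chain*, not the
biological fidelity of the generator.

## Fitting and uncertainty

The 12 free parameters (five gains, five thresholds, $E_{leak}$,
$g_{leak}$) are bounded to $[0,2]$, $[0,1]$, $[-80,-45]$ mV and $[0,3]$
respectively. `fit_point_model()` minimizes the summed squared voltage
residual over all stimulus conditions (equal per-sample weight; the
four conditions have equal durations, so per-sample and per-condition
weighting coincide here) with `L-BFGS-B`, an analytic gradient of the
quotient model (verified against central differences), Latin-hypercube
multi-start (16 starts by default) and a final polish of the best start.
The returned loss never exceeds the loss of any supplied initializer.
Thresholds at their upper bound zero out a class's conductance path and its
gradient, which is why multi-start matters.

`posterior_point_model()` replaces the study's neural-network
simulation-based inference with rejection sampling over the *same* uniform
priors and simulation budget (20,000 draws; distance = RMS voltage error
concatenated over conditions; the 10,000 — here configurable — smallest
distances kept with uniform weights). This is dependency-free and exhibits
the same scientific point: the generating parameters fall inside the
high-probability region (central 95% intervals of every identifiable
marginal), while the exact scale-degenerate direction stays unconstrained —
measured as the accepted $g_{leak}$ marginal retaining at least half the
prior spread, the clean one-dimensional proxy of the multiplicative
degeneracy.

Parameter recovery under the study conditions (reference parameter set,
four conditions, 1 mV voltage noise, 20 seeds) attains a pooled median
relative error of a few percent on the identifiable quantities
(gain/$g_{leak}$ ratios, thresholds, $E_{leak}$), comfortably inside the
15% acceptance bound; the numbers are recomputed by
`scripts/acceptance.R`, never hard-coded.

## Problem sizes and numerical choices

Analyses run at 1 kHz after resampling; stimuli at 60 Hz. The bundled
experiments use a 12×3-pixel edge corridor (~1.7 s per condition), an
8×6- to 9×9-pixel white-noise screen of 60–120 s, cables of 2–501
compartments and random trees of up to 50 compartments; these sizes keep
the full suite and the acceptance script at desk scale while leaving every
algorithmic path identical to a full-size analysis. Other fixed choices:
Gaussian filters are zero-phase with reflected padding and 6 s.d.
truncation; trace alignment uses normalized cross-correlation of
low-pass-filtered (50 ms s.d.) derivatives with edge blanking, searching
lags up to ±250 ms; tie-breaks in extremum searches take the first index;
flat traces yield typed undefined outcomes (`NA` offsets, rejection
records) rather than errors; the strict `< −25 mV` resting-potential
inequality rejects a cell sitting exactly on the criterion.

## Known limitations

* The generator omits adaptation, correlated noise, spiking and presynaptic
  nonlinearities; OFF-pathway (T5) processing and the wide-field TmY15/CT1
  inputs are out of scope.
* Screen geometry is a flat virtual plane; cylindrical pre-distortion and
  luminance calibration are display-hardware concerns, not modelled.
* The neural-network density estimator of simulation-based inference is
  intentionally replaced by rejection sampling; hierarchical across-cell
  models are not attempted.
* Serialization uses CSV/JSON/YAML; no HDF5 container is used.
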