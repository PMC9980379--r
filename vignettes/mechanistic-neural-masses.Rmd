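---
title: "Mechanistic neural masses: from membrane models to mean-field elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic neural masses: from membrane models to mean-field elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Classical neural mass models convert the summed input of a population into a
firing rate through an assumed sigmoid. That choice severs the link between
the mass's parameters and anything measurable at the membrane: the sigmoid
knows nothing about depolarization block (DB), and nothing about how the
transfer function deforms when extracellular potassium rises. `mnm` builds
*mechanistic* neural masses instead: the transfer function, its thresholds,
and its coupling to slow environmental variables are all parametrized from a
conductance-based single-neuron model, so that the mass inherits the
neuron's firing onset, its DB transition, and its potassium sensitivity.

This vignette records the modelling decisions, parameter meanings, and
numerical choices, in enough detail that a reader can judge what the
package's tests do and do not demonstrate.

## The neuron models

Two single-compartment Hodgkin–Huxley-type models stand behind the two mass
kinds. Both share the membrane equation

$$C_m \dot V_m = I_{inj} - G_K\,(V_m-\nu_K) - G_{Na}\,(V_m-\nu_{Na})
  - g_L\,(V_m-\nu_l) - I_{pump} \;(-\,I_{K\text{-}AHP}),$$

with gating variables $n$ (potassium activation) and $h$ (sodium
inactivation) following first-order kinetics in the usual
$\alpha/\beta$ form, and sodium activation $m$ instantaneous at
$m_\infty(V_m)$.

**Inhibitory: Wang–Buzsáki (WB) interneuron.** $C_m = 1\,\mu F/cm^2$,
$g_{Na} = 35$, $g_K = 9$, $g_L = 0.1\,mS/cm^2$, $\nu_{Na} = 55$,
$\nu_l = -65$ mV, gating rates of $n$ and $h$ scaled by $\psi = 5$,
$G_K = g_K n^4$, $G_{Na} = g_{Na} m_\infty^3 h$. The nominal potassium
Nernst potential is $\hat\nu_K = -90$ mV.

**Excitatory: single-compartment excitatory accommodating neuron (SEAN).**
A one-compartment reduction of the Pinsky–Rinzel pyramidal-cell soma,
keeping the somatic current forms of that model:
$G_K = g_K\,n$ (first power) and $G_{Na} = g_{Na}\, m_\infty^2 h$, with
$C_m = 3\,\mu F/cm^2$, $g_{Na} = 30$, $g_K = 15$, $g_L = 0.1$,
$g_{K\text{-}AHP} = 0.8\,mS/cm^2$, $\nu_{Na} = 60$, $\nu_l = -60$ mV and
$\hat\nu_K = -75$ mV. The rate functions are the Pinsky–Rinzel somatic ones
shifted by $-60$ mV into the standard voltage convention (rest near
$-60$ mV). We deliberately retain the canonical somatic channel exponents:
raising them to the WB powers ($n^4$, $m_\infty^3$) makes the steady-state
current dip far below zero near the depolarized eigenvalue crossing, which
destroys the ordered firing-onset/DB structure the reduction relies on.

The accommodation (after-hyperpolarization) current
$I_{K\text{-}AHP} = g_{K\text{-}AHP}\, q\,(V_m-\nu_K)$ is split into a fast
part with the calcium-gated activation frozen at
$\hat q = q_\infty(Ca = 0.2) \approx 0.00398$ and a slow, calcium-dependent
remainder. The mass parametrization uses the fast part only; the slow part
can be injected through the additive current hook `I_extra` of
`simulate_neuron()`.

**Pump.** The sodium–potassium exchanger current is a product of logistics,
$I_{pump} = \rho\,[1+e^{(\widehat{Na}_i-Na_i)/3}]^{-1}
[1+e^{\hat K_o-K_o}]^{-1}$ with $\rho = 1.25\,\mu A/cm^2$. Intracellular
concentrations are held constant ($Na_i = \widehat{Na}_i = 25$ mM,
$K_i = 140$ mM), so at nominal conditions $I_{pump} = \rho/4 = 0.3125$ and it
saturates at $\rho/2$ as $K_o$ rises.

**Potassium flux sign convention.** The reported transmembrane potassium
flux is $K_{flux} = G_K (V_m-\nu_K) + I_{K\text{-}AHP} - 2 I_{pump}$: the
pump imports two potassium ions per cycle, so its contribution is negative.
This makes the flux negative at rest (potassium is pumped back in faster
than it leaks out) and strongly positive in DB, which is the signature used
to tell DB apart from the quiescent state.

**Potassium as the slow variable.** The shift of the Nernst potential from
nominal is $\Delta\nu_K = (RT/F)\,\ln(K_o/\hat K_o)$ with
$RT/F = 26.64$ mV. With $K_i = 140$ mM the nominal Nernst potentials imply
nominal extracellular concentrations of about $4.77$ mM (inhibitory) and
$8.38$ mM (excitatory); a $+15$ mV shift corresponds to roughly a 75%
increase of extracellular potassium. Both masses of a network share one bath
and hence one $\Delta\nu_K$.

## From neuron to mass

The reduction exploits time-scale separation: action potentials are fast,
the drive and the potassium environment are slow. All the mass needs is the
*time-averaged* response surface of the neuron over (injected current,
$\Delta\nu_K$), which splits into not-firing (NF), firing (F), and
depolarization block (DB) regions.

1. **Fixed points.** Parametrizing fixed points by the membrane potential,
   the gates sit at their steady values and the steady-state current
   $I_{SS}(V_m;\nu_K)$ (pump included) is the injected current that holds
   the membrane there — `iss_of_vm()`.
2. **Stability.** With $m$ instantaneous the system is three-dimensional
   $(V, n, h)$; `neuron_jacobian()` evaluates the analytic Jacobian and
   `trace_boundaries()` scans $V_m \in [-100, 20]$ mV (step 0.25 mV,
   crossings refined by bisection to $10^{-6}$ mV) for zero crossings of the
   largest eigenvalue real part. The lower crossing mapped through $I_{SS}$
   is the firing-onset current $ISS_F$, the upper one the DB-onset current
   $ISS_{DB}$. At high $\Delta\nu_K$ the two currents cross and the firing
   window closes (for the WB model near $\nu_K \approx -61$ mV); beyond that
   the model is bistable between a quiescent and a depolarized state and the
   row is marked absent.
3. **Maxima near the DB boundary.** The averaged firing rate, membrane
   potential and potassium flux grow toward the DB boundary, but the limit
   cycle actually dies *before* the fixed point stabilizes (the transition
   is subcritical): for the WB model at nominal potassium the last ~16% of
   the firing window is already non-firing. The maxima $M_1, M_2, M_3$ are
   therefore measured on a line shifted inside the boundary,
   $I_{SS,DB} - \delta$ with $\delta$ a fixed fraction of the window: the
   fraction starts at 0.05 and is escalated (×1.6) until every row of the
   grid fires, giving one uniform, smooth line as close to DB as the
   dynamics allow. Each measurement is a 2.5 s simulation with the first
   0.5 s discarded (tens of inter-spike intervals at the rates involved).
4. **Boundary extrapolation.** The shifted line sits at normalized current
   $Q_m = 1-\delta/W < 1$, while the functionals below place the maxima at
   $Q = 1$. The measured means are therefore extrapolated through the
   functional form itself ($M_1 = FR_{meas}/Q_m^{1/2}$, and likewise for
   $M_2, M_3$ with their exponents) before fitting. Without this step every
   in-window prediction would inherit a uniform $Q_m^{p}$ deficit (about
   10% at the escalated shift).
5. **Polynomial parametrization.** The thresholds are fit with lines in the
   absolute Nernst potential and the maxima with low-order polynomials
   (inhibitory: cubic/quadratic/linear for $M_1/M_2/M_3$; excitatory:
   quadratic/quadratic/cubic). Fits are computed on a centred predictor for
   conditioning and stored in raw powers of $\nu_K$.

**The fitted potassium window is $\Delta\nu_K \in [0, 20]$ mV.** Two
reasons. First, it covers the physiological range of interest up to the
~75% potassium elevation used in the network studies, while staying well
inside the region where the firing window exists for both cell types.
Second, the firing-onset current is not globally linear in $\nu_K$ — its
shape is dominated by the logistic rise and saturation of the pump — so a
linear threshold fit is meaningful only on a window over which the curve is
close to straight; over $[0, 20]$ mV the WB onset line fits with slope
$\approx 0.0137\,(\mu A/cm^2)/mV$ and intercept $\approx 1.76\,\mu A/cm^2$,
while stretching the window to $[0, 40]$ would flatten the fitted slope by
a factor of three. Evaluation outside the window is a polynomial
continuation and is flagged.

## The mass functionals

For a total input current $X$ the normalized current is
$Q = (X - i_{th1})/(i_{th2} - i_{th1})$. Inside the window ($0 \le Q \le 1$):

$$FR = M_1\,Q^{1/2}, \qquad
  V_m = C_1 + (M_2 - C_1)\,Q^{p_V}, \qquad
  K_{flux} = C_2 + (M_3 - C_2)\,Q^{p_K},$$

with exponents $(1/2, 1/2, 1/2)$ and $C_1 = -60$ mV for the inhibitory mass
and $(1/2, 0.62, 0.28)$ with $C_1 = -65$ mV, $C_2 = 0.1\,\mu A/cm^2$ for the
excitatory mass. The outputs start at $(0, C_1, C_2)$ at the firing
threshold and reach the maxima at the DB threshold; the drop of $FR$ from
$M_1$ to $0$ at $i_{th2}$ is the DB transition and is intentionally
discontinuous (smoothed in time by the network's relaxation). Outside the
window the firing rate is identically zero and the mean potential and flux
are taken from the stable fixed point of the underlying neuron model,
located by root-finding $I_{SS}(V) = X$ on the quiescent or depolarized
branch.

**The pump is not re-added to the total current.** The thresholds are fits
of the steady-state current, which contains the pump and its potassium
dependence. The total current of a mass is therefore
$X = I_{inj} + \sum \pm g\,h$ over its synapses; re-adding $I_{pump}$ would
double-count it and — because the excitatory onset threshold is smaller
than the pump current — would make the excitatory mass fire spontaneously
at zero input. The literal injected-plus-pump form remains available via
`total_current(..., pump = TRUE)` for comparison.

## Synapses and the coupled network

Synaptic filtering uses the alpha kernel $t\,e^{-t/\tau}$ realized as the
critically damped second-order system
$\ddot h = (F - h)/\tau^2 - 2\dot h/\tau$, normalized to unit DC gain so
that a steady presynaptic rate $F$ gives $h = F$. The update over a step
with constant input is exact (matrix exponential in closed form). Default
time constants: $\tau_E = 10$ ms (pyramidal), $\tau_I = 20$ ms (slow
GABA-B, the default inhibition in the network studies); a fast 2 ms
GABA-A synapse is available but unused by default. Per-connection delays
are supported through `delayed_read()`; the two-mass circuit uses zero
delay.

The excitatory–inhibitory couplet evolves by rate relaxation toward the
mass transfer functions $\Phi$ (a discretized Wilson–Cowan form):

$$\dot{FR}_E = (\Phi_E(X_E) - FR_E)/\lambda_E, \qquad
  \dot{FR}_I = (\Phi_I(X_I) - FR_I)/\lambda_I,$$

with $X_E = I_{E,inj}(t) - g_{IE} h_I$ and $X_I = I_{I,inj} + g_{EI} h_E$
(signs explicit: inhibition enters negatively). Defaults:
$\lambda_E = \lambda_I = 1$ ms, nominal couplings $\hat g_{EI} = 0.2$ and
$\hat g_{IE} = 0.04\,\mu A/cm^2$ per Hz, no external drive to the
inhibitory mass. Firing rates are in Hz; rescaling to other rate units
rescales the couplings inversely. Integration is fixed-step RK4 at
$dt = 0.05$ ms (the functionals are algebraic, so stiffness is mild), with
drive waveforms that are continuous and piecewise linear: constant steps,
symmetric triangular ramps, and trains of ramp-fronted pulses (250 ms
fronts, duty cycle 0.75 by default).

**Regime classification.** A window is `NF` when the excitatory rate is
below 0.5 Hz with $Q_E < 0$; `F` when both masses fire; `RAE` (runaway
excitation) when the excitatory mass fires while the inhibitory mass is
blocked ($Q_I > 1$); `DB` when the excitatory mass itself is blocked.
Transition detection on ramps requires a threshold crossing to persist for
50 ms, so that brief oscillatory excursions do not register as transitions.

## Analytic regime boundaries

Working in absolute currents, with all thresholds and maxima evaluated at
the shared $\nu_K$:

* firing onset: $I_{FO} = i^E_{th1}$;
* runaway excitation: the inhibitory mass blocks when
  $g_{EI} FR_E = i^I_{th2} - I_{I,inj}$; inverting
  $\Phi_E$ gives the required $Q_E$, and with the inhibitory mass still at
  its maximal rate just below the boundary,
  $I_{RAE} = i^E_{th1} + Q_E (i^E_{th2} - i^E_{th1}) + g_{IE} M_1^I$
  (absent when the required rate exceeds $M_1^E$);
* bistability: $I_{BS} = I_{RAE} - g_{IE} M_1^I$ — the same state without
  the inhibitory current that is about to vanish; the band
  $[I_{BS}, I_{RAE}]$ is the hysteretic region;
* depolarization block: bare line $i^E_{th2}$ (no inhibition left in RAE);
  the *effective* DB onset is capped at the RAE boundary,
  $\min(i^E_{th2}, I_{RAE})$, since past the inhibitory failure the
  network is committed to the pathological branch.

Quasi-static ramp simulations reproduce $I_{RAE}$ and $I_{BS}$ to a
fraction of a percent at nominal potassium. Two dynamical caveats, both
visible in the package's tests: near the excitatory DB line the momentary
rebound of the inhibitory mass (released when $FR_E$ collapses) can pull
the excitatory mass back out, so full commitment to DB on a rising ramp
settles up to ~10% above the bare line; and at elevated potassium the
balanced state loses stability through a delayed-inhibition oscillation
*before* the quasi-static RAE boundary, so the simulated entry falls inside
the bistable band rather than at its upper edge. The analytic boundary is
then an upper bound, not a sharp prediction.

## Synthetic fixtures

`make_fixture_mass()` generates structurally valid parametrizations from
smooth synthetic boundary curves (ordered thresholds over the standard
window, correct orders, exponents and offsets, 0.2% seeded jitter). They
emulate the *shape* of fitted masses well enough to exercise the mass
functionals, the network and the atlas quickly, but carry no neuron model,
so fixed-point closures and fidelity comparisons require a genuinely fitted
mass. Tests that pass on fixtures demonstrate algebraic correctness, not
agreement with any membrane model.

## Problem sizes and tolerances

Default problem sizes, chosen to resolve the quantities they feed: 21–50
point potassium grids over $[0, 20]$ mV; membrane simulations of 2.5 s
(0.5 s transient + 2 s averaging window, i.e. a 0.5 Hz rate resolution);
adaptive integration at `rtol` $10^{-8}$ / `atol` $10^{-10}$ with maximal
step 0.1 ms (action-potential upstrokes are sub-millisecond); spike
detection by upward crossings of 0 mV with a 2 ms lockout; fidelity
comparisons on 20 currents spanning the central 80% of the firing window at
$\Delta\nu_K \in \{0, 7.5, 15\}$ mV; network ramps of 40 s total for
quasi-static transition detection. Fidelity summaries are computed over the
grid points where the neuron model actually fires: the bins at the very
onset and past the dynamic DB edge are the known mismatch zone of this
class of parametrization and are reported but not summarized.

## Limitations

* Only Type-1 (square-root) firing onset and the subsequent DB transition
  are parametrized; burst firing and other onset classes are out of scope.
* The excitatory model inherits the Pinsky–Rinzel soma's unrealistically
  high maximal firing rates; couplings are calibrated in Hz accordingly.
* Each mass represents a homogeneous population with identical parameters;
  parameter heterogeneity would smooth the onset and DB transitions.
* Extracellular potassium is a *parameter*, not a dynamical variable: there
  is no diffusion, glial buffering, or volume change. The masses expose the
  potassium flux precisely so that such couplings can be added on top.
* Intracellular concentrations are frozen; the pump varies only through
  extracellular potassium.
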