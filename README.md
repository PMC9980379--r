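# mnm — mechanistic neural mass models

Neural mass models describe brain dynamics as the mean-field activity of
neuronal populations. The classical construction maps a population's summed
input to a firing rate through an assumed sigmoid, which disconnects the
mass from membrane physiology: it cannot enter depolarization block (DB),
and it does not respond to extracellular potassium. `mnm` builds masses
whose transfer function is *derived* from a conductance-based neuron model,
for computational neuroscientists studying seizure-like transitions,
runaway excitation, and spreading-depolarization-adjacent dynamics where
those two omissions are fatal.

## The model in brief

For a neuron model with steady-state current `I_SS(V; nu_K)` (pump
included), the firing window at a given potassium Nernst potential `nu_K`
is bounded by the two currents where the largest eigenvalue of the
(V, n, h) Jacobian crosses zero: the firing onset `i_th1 = ISS_F` and the
DB onset `i_th2 = ISS_DB`. With the normalized current

    Q = (X - i_th1) / (i_th2 - i_th1),      X = I_inj + sum(±g·h)

the mass outputs inside the window are

    FR     = M1(nu_K) · Q^(1/2)
    <Vm>   = C1 + (M2(nu_K) - C1) · Q^p_V
    K_flux = C2 + (M3(nu_K) - C2) · Q^p_K

where `M1, M2, M3` are the maxima of the time-averaged firing rate,
membrane potential and transmembrane potassium flux measured along a line
just inside the DB boundary, and all thresholds and maxima are low-order
polynomials of `nu_K`. Outside the window the rate is zero and `<Vm>`,
`K_flux` come from the stable fixed point (quiescent or depolarized
branch). Two masses are provided: an inhibitory one from the Wang–Buzsáki
interneuron (exponents 1/2, 1/2, 1/2; `C1 = -60` mV) and an excitatory,
accommodating one from a single-compartment Pinsky–Rinzel reduction
(exponents 1/2, 0.62, 0.28; `C1 = -65` mV, `C2 = 0.1`). Coupling two masses
through alpha-function synapses gives an E–I network with not-firing,
firing, bistable, runaway-excitation (inhibitory mass in DB) and DB
regimes, whose boundaries the package also computes analytically.

## Worked example

```r
library(mnm)

## derive the inhibitory mass from the Wang-Buzsaki interneuron
imass <- mnm_fit(wb_neuron(), dnuK_grid = seq(0, 20, by = 2))
imass
#> <mechanistic neural mass: I kind, from WB neuron>
#>   nominal nu_K = -90 mV; fitted over dnuK in [0, 20] mV
#>   at dnuK = 0: i_th1 = 0.525, i_th2 = 25.46 uA/cm2; M1 = 456 Hz
#>   exponents (FR, Vm, KF) = (0.5, 0.5, 0.5); C1 = -60 mV, C2 = 0

## the fitted firing-onset line i_th1 = a·nu_K + b
coef(imass)$th1
#> [1] 1.7560829 0.0136769
```

The onset line says the inhibitory population starts firing at
`0.0137·nu_K + 1.756` µA/cm²: about 0.525 µA/cm² at nominal potassium
(`nu_K = -90` mV), less as potassium rises. At a +15 mV Nernst shift
(~75% more extracellular potassium) the whole firing window has collapsed
toward lower currents and rates:

```r
round(thresholds_and_maxima(imass, dnuK = 15), 3)
#>   dnuK nu_K i_th1  i_th2      M1      M2     M3 I_pump
#> 1   15  -75  0.73 12.729 386.951 -31.235 37.421  0.608
```

Couple it to the excitatory mass and drive the pair with a slow symmetric
current ramp to see the hysteretic regime transitions:

```r
emass <- mnm_fit(sean_neuron(), dnuK_grid = seq(0, 20, by = 2))
net <- mnm_network(emass, imass, dnuK = 0)   # g_EI = 0.2, g_IE = 0.04
h <- hysteresis_scan(net, peak = 120, duration = 30000)
round(h$rising, 2); round(h$falling, 2); round(h$bistable, 2)
#> I_db_entry E_db_entry
#>      40.30      98.58
#> E_db_exit I_db_exit
#>     91.87     21.79
#> lower upper
#> 21.79 40.30
```

On the way up the inhibitory mass blocks at 40.3 µA/cm² (runaway
excitation begins) and the excitatory mass itself blocks near 99; on the
way down inhibition only recovers at 21.8, so the band [21.8, 40.3] is
bistable — the network's state there depends on its history. The analytic
boundary reproduces the simulated transition:

```r
rae_boundary(emass, imass, g_EI = 0.2, g_IE = 0.04, dnuK = 0)
#> [1] 40.21442
```

`regime_atlas()` assembles these boundaries over potassium or
coupling-ratio grids, `simulate()` on a network runs arbitrary pulse/ramp
protocols, and `fidelity()` quantifies how closely the mass functionals
track the underlying membrane model (median relative errors of firing rate
and mean potential are a few percent over the firing range). A thin
command-line front end for sweeps, parametrization, network simulation and
atlases is installed at `inst/cli/mnm`.

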