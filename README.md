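# coilrelax

Relaxometry and stability analytics for lanthanide(III)-binding
coiled-coil MRI contrast agents.

Peptide three-helix bundles that bind Gd(III) are a promising class of
metallopeptide contrast agents, but characterising them takes a battery
of quantitative experiments: ¹H nuclear magnetic relaxation dispersion
(NMRD) profiles, luminescence titrations against a competing chelator,
challenge kinetics, circular dichroism, proteolytic mapping, and
hydration statistics from simulation trajectories. `coilrelax` packages
the analysis of all of these for researchers working on such systems.

## The core model

These complexes have **no inner-sphere water** (q = 0), so the
longitudinal relaxivity is modelled as second sphere + outer sphere:

- **Second sphere (SBM + Lipari–Szabo):** q^ss water molecules at a
  Gd–H distance r^ss, exchanging with residence time τ_M^SS, moving
  with a fast local correlation time τ_RL inside the slow global
  tumbling τ_RG, coupled by the order parameter S². The spectral
  density is J(ω) = S²τ_g/(1+ω²τ_g²) + (1−S²)τ_l/(1+ω²τ_l²), with
  electron relaxation (transient ZFS: Δ², τ_v) and exchange folded into
  the effective correlation times.
- **Outer sphere (Freed):** freely diffusing water with closest
  approach a and relative diffusion coefficient D, τ_D = a²/D.

Affinity inference solves the two-equilibrium mass balance
M_T = M + K_P·M·P_T/(1+K_P·M) + K_E·M·E_T/(1+K_E·M) exactly at every
titration point (EGTA competition), or fits the Hill equation for
direct titrations. Kinetic stability is summarised by the **ratio
index** — the time for the challenge signal to fall to 80 % of its
initial value.

## Worked example

```r
library(coilrelax)

# forward NMRD profile of the cross-linked trimer parameterization
model <- relaxation_model(
  second_sphere_params(q_ss = 2, r_ss_A = 3.6, tau_M_ss = 5.0e-9,
                       tau_RG = 7e-9, tau_RL = 318e-12, S2 = 0.5),
  outer_sphere_params(a_A = 4, D = 2.3e-10))
total_r1_profile(c(0.01, 1, 20, 60), model)
#> NMRD profile 'simulated': 4 points, 0.01-60 MHz, T = 298 K
#>   freq_mhz       r1
#> 1     0.01 48.43962
#> 2     1.00 33.62881
#> 3    20.00 36.66343
#> 4    60.00 34.50286
```

r1 is in mM⁻¹ s⁻¹: a low-field plateau near 48, dispersion through the
MHz range, and ~34.5 at the clinical 60 MHz field. Refitting a
generated profile recovers the second-sphere dynamics from a deliberately
wrong starting point:

```r
start <- model
start$second_sphere$tau_RL <- 1e-10
start$second_sphere$tau_M_ss <- 1e-9
start$second_sphere$S2 <- 0.3
fit_nmrd(total_r1_profile(default_freq_grid(), model),
         fit_spec(free = c("tau_RL", "tau_M_ss", "S2"), model = start))
#> NMRD fit: converged
#>   tau_RL    = 3.18e-10     # 318 ps local rotation
#>   tau_M_ss  = 5e-09        # 5.0 ns second-sphere residence
#>   S2        = 0.5
```

EGTA competition, speciation-exact:

```r
mt <- seq(0, 6.6, length.out = 20)                 # uM Tb(III), 3.3 uM sites
ser <- gen_competition_titration(mt, peptide_total = 3.3, logKa_P = 13.9)
competition_fit(ser, logKa_E = egta_logKa_default)$logKa_peptide
#> [1] 13.9
```

Kinetics and digestion:

```r
ratio_index(gen_decay(log(1.25) / 100))$time_min   # crosses 80% at t = 100
#> [1] 100
tryptic_fragments(mb12_sequence("A"))$fragment     # cross-linked Lys15 resists
#> [1] "GIAAIEQK" "IAANEWKDAAIEQK" "IAAIEQK" "IAAIEQK" "G"
```

The joined `IAANEWKDAAIEQK` fragment is the diagnostic signature of the
isopeptide cross-link between Lys15 and Glu20; without the cross-link
the two heptads appear separately.

A command-line wrapper covering every stage is installed as
`exec/coilrelax` (`coilrelax --help`).

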