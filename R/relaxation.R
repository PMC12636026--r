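#' Angular frequencies of proton and electron spins
#'
#' Converts a proton Larmor frequency in MHz to the proton and electron
#' angular frequencies. The electron frequency follows from
#' \eqn{\gamma_S = g \mu_B / \hbar}, so \eqn{\omega_S/\omega_I \approx 658}
#' for g = 2.
#'
#' @param nu_mhz proton Larmor frequency, MHz (vectorised, > 0)
#' @param electron [electron_spin_params()] (g enters the ratio)
#' @return list with `omega_I` and `omega_S` in rad s^-1
#' @export
angular_frequencies <- function(nu_mhz, electron = electron_spin_params()) {
  if (any(!is.finite(nu_mhz)) || any(nu_mhz <= 0))
    stop("Larmor frequency must be positive")
  k <- physical_constants
  omega_I <- 2 * pi * nu_mhz * 1e6
  gamma_S <- electron$g * k$mu_B / k$hbar
  list(omega_I = omega_I, omega_S = (gamma_S / k$gamma_H) * omega_I)
}

#' Lipari-Szabo model-free spectral density
#'
#' Two-Lorentzian spectral density splitting the motion into a slow
#' global component (correlation time `tau_global`, weight S2) and a fast
#' local component (`tau_local`, weight 1 - S2):
#' \deqn{J(\omega) = S^2 \tau_g / (1 + \omega^2\tau_g^2) +
#'       (1 - S^2) \tau_l / (1 + \omega^2\tau_l^2).}
#'
#' @param omega angular frequency, rad s^-1 (vectorised)
#' @param tau_global,tau_local correlation times, s (> 0)
#' @param S2 order parameter in \[0, 1\]
#' @return spectral density in s; non-negative, non-increasing in |omega|
#' @export
lipari_szabo_J <- function(omega, tau_global, tau_local, S2) {
  if (tau_global <= 0 || tau_local <= 0) stop("correlation times must be > 0")
  if (S2 < 0 || S2 > 1) stop("order parameter `S2` must lie in [0, 1]")
  S2 * tau_global / (1 + (omega * tau_global)^2) +
    (1 - S2) * tau_local / (1 + (omega * tau_local)^2)
}

#' Electron spin relaxation rates from transient ZFS
#'
#' Longitudinal and transverse electron relaxation rates for an S-state
#' ion with a fluctuating zero-field splitting of mean-square amplitude
#' \eqn{\Delta^2} modulated on timescale \eqn{\tau_v}:
#' \deqn{1/T_{1e} = (\Delta^2\tau_v/25)[4S(S+1)-3]
#'       [ (1+\omega_S^2\tau_v^2)^{-1} + 4(1+4\omega_S^2\tau_v^2)^{-1} ]}
#' \deqn{1/T_{2e} = (\Delta^2\tau_v/50)[4S(S+1)-3]
#'       [ 3 + 5(1+\omega_S^2\tau_v^2)^{-1} + 2(1+4\omega_S^2\tau_v^2)^{-1} ].}
#'
#' @param omega_S electron angular frequency, rad s^-1 (vectorised)
#' @param electron [electron_spin_params()]
#' @return list with rates `R1e` and `R2e` in s^-1
#' @export
electron_relaxation_rates <- function(omega_S, electron = electron_spin_params()) {
  S <- electron$S
  f <- 4 * S * (S + 1) - 3
  x <- (omega_S * electron$tau_v)^2
  base <- electron$delta2 * electron$tau_v * f
  list(R1e = (base / 25) * (1 / (1 + x) + 4 / (1 + 4 * x)),
       R2e = (base / 50) * (3 + 5 / (1 + x) + 2 / (1 + 4 * x)))
}

#' Second-sphere contribution to longitudinal relaxivity
#'
#' Solomon-Bloembergen-Morgan dipolar relaxation of second-sphere water
#' protons at distance r_ss from the Gd(III), in exchange (residence time
#' tau_M^SS) with bulk. Effective correlation times combine global and
#' local rotation, exchange, and electron relaxation:
#' 1/tau_{g,i} = 1/tau_RG + 1/tau_M^SS + 1/T_ie and likewise for the
#' local times, the omega_I term pairing with T1e and the omega_S term
#' with T2e. The bound-proton rate is
#' \deqn{1/T_{1m} = (2/15)(\mu_0/4\pi)^2 \gamma_I^2 g^2\mu_B^2 S(S+1)
#'       r_{ss}^{-6} [3 J(\omega_I) + 7 J(\omega_S)]}
#' and the per-mM relaxivity is (q_ss / 55500) / (T_1m + tau_M^SS).
#'
#' @param nu_mhz proton Larmor frequency, MHz (vectorised)
#' @param ss [second_sphere_params()]
#' @param electron [electron_spin_params()]
#' @return second-sphere relaxivity r1_ss, mM^-1 s^-1
#' @export
second_sphere_r1 <- function(nu_mhz, ss = second_sphere_params(),
                             electron = electron_spin_params()) {
  if (ss$r_ss_A <= 0) stop("`r_ss_A` must be > 0")
  k <- physical_constants
  w <- angular_frequencies(nu_mhz, electron)
  er <- electron_relaxation_rates(w$omega_S, electron)
  tau_g1 <- 1 / (1 / ss$tau_RG + 1 / ss$tau_M_ss + er$R1e)
  tau_l1 <- 1 / (1 / ss$tau_RL + 1 / ss$tau_M_ss + er$R1e)
  tau_g2 <- 1 / (1 / ss$tau_RG + 1 / ss$tau_M_ss + er$R2e)
  tau_l2 <- 1 / (1 / ss$tau_RL + 1 / ss$tau_M_ss + er$R2e)
  JI <- S2J(w$omega_I, tau_g1, tau_l1, ss$S2)
  JS <- S2J(w$omega_S, tau_g2, tau_l2, ss$S2)
  r_m <- ss$r_ss_A * 1e-10
  S <- electron$S
  K_dd <- (2 / 15) * k$mu0_4pi^2 * k$gamma_H^2 * electron$g^2 * k$mu_B^2 *
    S * (S + 1) / r_m^6
  inv_T1m <- K_dd * (3 * JI + 7 * JS)
  (ss$q_ss / k$water_mM) * inv_T1m / (1 + inv_T1m * ss$tau_M_ss)
}

# Lipari-Szabo form with vectorised effective times (electron rates vary
# with field, so the correlation times are per-frequency here).
S2J <- function(omega, tau_g, tau_l, S2) {
  S2 * tau_g / (1 + (omega * tau_g)^2) +
    (1 - S2) * tau_l / (1 + (omega * tau_l)^2)
}

#' Freed spectral density for translational diffusion
#'
#' Dimensionless outer-sphere spectral density with electron-relaxation
#' leakage: with \eqn{z = \sqrt{i\omega\tau_D + \tau_D/T_{je}}},
#' \deqn{J_F = \mathrm{Re}\left[\frac{1 + z/4}
#'       {1 + z + 4z^2/9 + z^3/9}\right] \in (0, 1].}
#'
#' @param omega angular frequency, rad s^-1 (vectorised)
#' @param tau_D translational correlation time a^2/D, s
#' @param T_je electron relaxation time, s; `Inf` for no leakage
#' @return dimensionless spectral density in (0, 1]
#' @export
freed_J <- function(omega, tau_D, T_je = Inf) {
  if (tau_D <= 0) stop("`tau_D` must be > 0")
  if (any(T_je <= 0)) stop("`T_je` must be > 0")
  leak <- ifelse(is.finite(T_je), tau_D / T_je, 0)
  z <- sqrt(complex(real = leak, imaginary = omega * tau_D))
  Re((1 + z / 4) / (1 + z + 4 * z^2 / 9 + z^3 / 9))
}

#' Outer-sphere contribution to longitudinal relaxivity
#'
#' Freed model for water diffusing past the complex with closest approach
#' a and relative diffusion coefficient D (tau_D = a^2/D):
#' \deqn{r_1^{OS} = \frac{C_{OS}}{aD}
#'   [3 J_F(\omega_I, \tau_D, T_{1e}) + 7 J_F(\omega_S, \tau_D, T_{2e})]}
#' with \eqn{C_{OS} = (32\pi/405)(\mu_0/4\pi)^2\gamma_I^2\gamma_S^2
#' \hbar^2 S(S+1) N_A}; the Avogadro factor converts a 1 mM = 1 mol m^-3
#' number density, so the result is per-mM.
#'
#' @param nu_mhz proton Larmor frequency, MHz (vectorised)
#' @param os [outer_sphere_params()]
#' @param electron [electron_spin_params()]
#' @return outer-sphere relaxivity r1_os, mM^-1 s^-1
#' @export
outer_sphere_r1 <- function(nu_mhz, os = outer_sphere_params(),
                            electron = electron_spin_params()) {
  k <- physical_constants
  w <- angular_frequencies(nu_mhz, electron)
  er <- electron_relaxation_rates(w$omega_S, electron)
  a_m <- os$a_A * 1e-10
  tau_D <- a_m^2 / os$D
  gamma_S <- electron$g * k$mu_B / k$hbar
  S <- electron$S
  C_os <- (32 * pi / 405) * k$mu0_4pi^2 * k$gamma_H^2 * gamma_S^2 *
    k$hbar^2 * S * (S + 1) * k$N_A
  (C_os / (a_m * os$D)) *
    (3 * freed_J(w$omega_I, tau_D, 1 / er$R1e) +
       7 * freed_J(w$omega_S, tau_D, 1 / er$R2e))
}

#' Total longitudinal relaxivity dispersion profile
#'
#' Pointwise sum of the second-sphere and outer-sphere contributions
#' (no inner-sphere term: q_inner = 0 in this model family).
#'
#' @param freq_mhz proton Larmor frequencies, MHz, strictly increasing
#' @param model a [relaxation_model()]
#' @param label label forwarded to the resulting profile
#' @return an [nmrd_profile()] of the simulated r1(nu)
#' @export
total_r1_profile <- function(freq_mhz, model, label = "simulated") {
  stopifnot(inherits(model, "relaxation_model"))
  if (any(diff(freq_mhz) <= 0)) stop("frequencies must be strictly increasing")
  r1 <- second_sphere_r1(freq_mhz, model$second_sphere, model$electron) +
    outer_sphere_r1(freq_mhz, model$outer_sphere, model$electron)
  nmrd_profile(freq_mhz, r1, temperature = model$temperature, label = label)
}

#' Default log-spaced NMRD frequency grid
#'
#' 30 logarithmically spaced proton Larmor frequencies from 0.01 to
#' 70 MHz, spanning the range of a fast field-cycling relaxometer plus a
#' clinical 1.4 T point.
#'
#' @param n number of points
#' @param from,to range in MHz
#' @return numeric vector of frequencies, MHz
#' @export
default_freq_grid <- function(n = 30, from = 0.01, to = 70) {
  exp(seq(log(from), log(to), length.out = n))
}
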