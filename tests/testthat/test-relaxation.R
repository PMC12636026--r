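# Forward relaxivity model: spectral densities, electron relaxation,
# second-sphere and outer-sphere terms, and their sum.

test_that("angular frequencies scale correctly and reject bad input", {
  expect_error(angular_frequencies(0), "positive")
  expect_error(angular_frequencies(-5), "positive")
  w <- angular_frequencies(10)
  expect_equal(w$omega_I, 2 * pi * 1e7)
  # electron/proton frequency ratio is a field-independent constant
  w60 <- angular_frequencies(60)
  ratio <- physical_constants$mu_B * 2 / physical_constants$hbar /
    physical_constants$gamma_H
  expect_equal(w60$omega_S / w60$omega_I, ratio)
  expect_equal(w$omega_S / w$omega_I, ratio)
})

test_that("Lipari-Szabo spectral density matches closed forms and limits", {
  # zero-frequency closed form S2*tau_g + (1-S2)*tau_l
  expect_equal(lipari_szabo_J(0, 7e-9, 3.18e-10, 0.4), 2.9908e-9,
               tolerance = 1e-12)
  # S2 = 1 collapses to a single Lorentzian
  w <- 2 * pi * 3e7
  expect_equal(lipari_szabo_J(w, 7e-9, 5e-10, 1),
               7e-9 / (1 + (w * 7e-9)^2))
  # frozen value from the independent high-precision evaluation
  expect_equal(lipari_szabo_J(2 * pi * 60e6, 7e-9, 3.18e-10, 0.5),
               5.96225275696939e-10, tolerance = 1e-12)
  expect_error(lipari_szabo_J(0, 7e-9, 3e-10, 1.2), "S2")
  expect_error(lipari_szabo_J(0, -1e-9, 3e-10, 0.5), "times")
})

test_that("spectral densities and electron rates are non-increasing in |omega|", {
  set.seed(42)
  omegas <- sort(10^runif(40, 4, 12))
  for (i in 1:20) {
    tg <- 10^runif(1, -10, -8); tl <- 10^runif(1, -11, -9.5)
    S2 <- runif(1)
    J <- lipari_szabo_J(omegas, tg, tl, S2)
    expect_true(all(diff(J) <= 1e-15 * J[-length(J)]))
    expect_true(all(J >= 0))
    el <- electron_spin_params(delta2 = 10^runif(1, 17, 20),
                               tau_v = 10^runif(1, -12, -10))
    er <- electron_relaxation_rates(omegas, el)
    expect_true(all(diff(er$R1e) <= 0))
    expect_true(all(diff(er$R2e) <= 0))
    expect_true(all(er$R1e >= 0) && all(er$R2e >= 0))
  }
})

test_that("electron relaxation rates match the transient-ZFS forms", {
  # zero-frequency: 1/T1e = 12 Delta2 tau_v for S = 7/2
  el <- electron_spin_params(delta2 = 1.0e19, tau_v = 2.0e-11)
  er0 <- electron_relaxation_rates(0, el)
  expect_equal(er0$R1e, 2.4e9)
  expect_equal(er0$R2e, 2.4e9)  # bracket = 10 at omega = 0
  # frozen term-by-term values at the 60 MHz proton Larmor field
  wS <- angular_frequencies(60, el)$omega_S
  er <- electron_relaxation_rates(wS, el)
  expect_equal(er$R1e, 38107794.653581, tolerance = 1e-10)
  expect_equal(er$R2e, 771760183.406759, tolerance = 1e-10)
})

test_that("electron-spin parameter invariants are enforced", {
  expect_error(electron_spin_params(delta2 = -1), ">= 0")
  expect_error(electron_spin_params(tau_v = 0), "> 0")
  expect_error(electron_spin_params(S = 0.6), "half-integer")
  expect_silent(electron_spin_params(S = 0.5))
})

test_that("second-sphere relaxivity is linear in q_ss and r^-6 in the dipolar rate", {
  el <- electron_spin_params()
  base <- second_sphere_params()
  nu <- c(0.05, 1, 20, 60)
  expect_equal(second_sphere_r1(nu, second_sphere_params(q_ss = 0), el),
               rep(0, 4))
  r1_1 <- second_sphere_r1(nu, base, el)
  ss2 <- base; ss2$q_ss <- 4
  expect_equal(second_sphere_r1(nu, ss2, el), 2 * r1_1, tolerance = 1e-14)
  # T1m extracted from r1 scales as r_ss^6 (dipolar prefactor isolation)
  T1m <- function(r_ss) {
    ss <- second_sphere_params(r_ss_A = r_ss)
    r1 <- second_sphere_r1(20, ss, el)
    (ss$q_ss / physical_constants$water_mM) / r1 - ss$tau_M_ss
  }
  expect_equal(T1m(7.2) / T1m(3.6), 2^6, tolerance = 1e-9)
  expect_error(second_sphere_params(r_ss_A = 0), "> 0")
})

test_that("Freed spectral density obeys limits, bounds, frozen value", {
  expect_equal(freed_J(0, 1e-9, Inf), 1)
  expect_lt(freed_J(1e14, 1e-9, Inf), 1e-3)
  # frozen: omega*tau_D = 1, tau_D/T_je = 0.1
  expect_equal(freed_J(1 / 1e-9, 1e-9, 1e-9 / 0.1),
               0.507716892778617, tolerance = 1e-12)
  set.seed(7)
  for (i in 1:50) {
    J <- freed_J(10^runif(1, 0, 12), 10^runif(1, -11, -8),
                 10^runif(1, -10, -6))
    expect_true(J > 0 && J <= 1)
  }
})

test_that("outer-sphere relaxivity follows the 1/(aD) scaling and zero-frequency limit", {
  # electron relaxation switched off so T_je is infinite
  el0 <- electron_spin_params(delta2 = 0)
  k <- physical_constants
  gamma_S <- 2 * k$mu_B / k$hbar
  C_os <- (32 * pi / 405) * k$mu0_4pi^2 * k$gamma_H^2 * gamma_S^2 *
    k$hbar^2 * 3.5 * 4.5 * k$N_A
  nu_lo <- 1e-12  # effectively zero field (Freed J decays as sqrt(omega))
  os <- outer_sphere_params(a_A = 4, D = 2.3e-10)
  expect_equal(outer_sphere_r1(nu_lo, os, el0),
               10 * C_os / (4e-10 * 2.3e-10), tolerance = 1e-6)
  # halving a and D quadruples the low-frequency value
  os_half <- outer_sphere_params(a_A = 2, D = 1.15e-10)
  expect_equal(outer_sphere_r1(nu_lo, os_half, el0),
               4 * outer_sphere_r1(nu_lo, os, el0), tolerance = 1e-6)
  # r1 * a * D constant when tau_D and electron rates are held fixed
  os_b <- outer_sphere_params(a_A = 8, D = (8e-10)^2 / ((4e-10)^2 / 2.3e-10))
  expect_equal(outer_sphere_r1(nu_lo, os_b, el0) * 8e-10 * os_b$D,
               outer_sphere_r1(nu_lo, os, el0) * 4e-10 * os$D,
               tolerance = 1e-9)
  # frozen chained-evaluation value at 20 MHz, default parameters
  expect_equal(outer_sphere_r1(20, outer_sphere_params(),
                               electron_spin_params()),
               13.65691818, tolerance = 1e-8)
})

test_that("total profile is the pointwise sum of its components", {
  m <- kh2_20x_model()
  nu <- default_freq_grid()
  prof <- total_r1_profile(nu, m)
  expect_s3_class(prof, "nmrd_profile")
  expect_equal(prof$r1,
               second_sphere_r1(nu, m$second_sphere, m$electron) +
                 outer_sphere_r1(nu, m$outer_sphere, m$electron))
  # q_ss = 0 leaves the outer-sphere term alone
  m0 <- m; m0$second_sphere$q_ss <- 0
  expect_equal(total_r1_profile(nu, m0)$r1,
               outer_sphere_r1(nu, m$outer_sphere, m$electron))
  expect_error(total_r1_profile(c(10, 10, 20), m), "increasing")
})

test_that("forward model agrees with the independent brute-force oracle", {
  set.seed(2024)
  nu <- default_freq_grid(15)
  for (i in 1:30) {
    m <- random_model()
    expect_equal(total_r1_profile(nu, m)$r1, oracle_r1_model(nu, m),
                 tolerance = 1e-10)
  }
})

test_that("nmrd_profile enforces its invariants", {
  expect_error(nmrd_profile(c(1, 2), c(1, -2)), "positive")
  expect_error(nmrd_profile(c(2, 1), c(1, 2)), "increasing")
  expect_error(nmrd_profile(c(1, 2), c(1, 2, 3)), "length")
  p <- nmrd_profile(c(1, 2), c(3, 4), r1_err = c(0.1, 0.1))
  expect_named(p, c("freq_mhz", "r1", "r1_err"))
})
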