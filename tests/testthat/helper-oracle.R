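# Independent brute-force oracles, deliberately written as a separate
# code path from the package: explicit constants, scalar chained
# arithmetic, complex evaluation. These are the reference the
# implementation is checked against; they never call package internals.

ORC <- list(mu0_4pi = 1e-7,
            gamma_H = 2.6752218744e8,
            mu_B = 9.2740100783e-24,
            hbar = 1.054571817e-34,
            N_A = 6.02214076e23)

# total r1 (and components) by direct term-by-term evaluation
oracle_r1 <- function(nu_mhz, q_ss, r_ss_A, tau_M, tau_RG, tau_RL, S2,
                      a_A, D, delta2, tau_v, g = 2.0, S = 3.5) {
  vapply(nu_mhz, function(nu) {
    wI <- 2 * pi * nu * 1e6
    gammaS <- g * ORC$mu_B / ORC$hbar
    wS <- (gammaS / ORC$gamma_H) * wI
    f <- 4 * S * (S + 1) - 3
    x <- (wS * tau_v)^2
    R1e <- (delta2 * tau_v / 25) * f * (1 / (1 + x) + 4 / (1 + 4 * x))
    R2e <- (delta2 * tau_v / 50) * f * (3 + 5 / (1 + x) + 2 / (1 + 4 * x))
    J <- function(w, tg, tl)
      S2 * tg / (1 + (w * tg)^2) + (1 - S2) * tl / (1 + (w * tl)^2)
    tg1 <- 1 / (1 / tau_RG + 1 / tau_M + R1e)
    tl1 <- 1 / (1 / tau_RL + 1 / tau_M + R1e)
    tg2 <- 1 / (1 / tau_RG + 1 / tau_M + R2e)
    tl2 <- 1 / (1 / tau_RL + 1 / tau_M + R2e)
    r_m <- r_ss_A * 1e-10
    Kdd <- (2 / 15) * ORC$mu0_4pi^2 * ORC$gamma_H^2 * g^2 * ORC$mu_B^2 *
      S * (S + 1) / r_m^6
    invT1m <- Kdd * (3 * J(wI, tg1, tl1) + 7 * J(wS, tg2, tl2))
    r1_ss <- (q_ss / 55500) * invT1m / (1 + invT1m * tau_M)
    a_m <- a_A * 1e-10
    tauD <- a_m^2 / D
    jf <- function(w, Rje) {
      z <- sqrt(complex(real = tauD * Rje, imaginary = w * tauD))
      Re((1 + z / 4) / (1 + z + 4 * z^2 / 9 + z^3 / 9))
    }
    Cos <- (32 * pi / 405) * ORC$mu0_4pi^2 * ORC$gamma_H^2 * gammaS^2 *
      ORC$hbar^2 * S * (S + 1) * ORC$N_A
    r1_os <- Cos / (a_m * D) * (3 * jf(wI, R1e) + 7 * jf(wS, R2e))
    r1_ss + r1_os
  }, numeric(1))
}

oracle_r1_model <- function(nu_mhz, model) {
  ss <- model$second_sphere; os <- model$outer_sphere; el <- model$electron
  oracle_r1(nu_mhz, ss$q_ss, ss$r_ss_A, ss$tau_M_ss, ss$tau_RG, ss$tau_RL,
            ss$S2, os$a_A, os$D, el$delta2, el$tau_v, el$g, el$S)
}

# a random admissible relaxivity model under a given RNG state
random_model <- function() {
  relaxation_model(
    second_sphere_params(q_ss = runif(1, 0.5, 4),
                         r_ss_A = runif(1, 2.5, 5),
                         tau_M_ss = 10^runif(1, -9.5, -7.5),
                         tau_RG = 10^runif(1, -9.5, -8),
                         tau_RL = 10^runif(1, -10.5, -9.3),
                         S2 = runif(1, 0.05, 0.95)),
    outer_sphere_params(a_A = runif(1, 3, 6), D = 10^runif(1, -10, -9)),
    electron_spin_params(delta2 = 10^runif(1, 18, 20),
                         tau_v = 10^runif(1, -11.5, -10.5)))
}

# free-metal speciation by coarse grid scan + local refinement
oracle_speciation <- function(MT, PT, ET, KaP, KaE) {
  kP <- KaP * 1e-6; kE <- KaE * 1e-6
  f <- function(M) M + kP * M * PT / (1 + kP * M) +
    kE * M * ET / (1 + kE * M) - MT
  grid <- seq(0, MT, length.out = 1e6 + 1)
  i <- which.min(abs(f(grid)))
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  M <- (lo + hi) / 2
  list(free_M = M, MP = kP * M * PT / (1 + kP * M),
       ME = kE * M * ET / (1 + kE * M))
}

# earliest threshold crossing by exhaustive scan over adjacent pairs
oracle_first_crossing <- function(t, s, threshold) {
  s <- s / s[1]
  for (i in seq_along(s)) {
    if (s[i] <= threshold) {
      if (i == 1) return(t[1])
      return(t[i - 1] + (threshold - s[i - 1]) * (t[i] - t[i - 1]) /
               (s[i] - s[i - 1]))
    }
  }
  NA_real_
}

# character-by-character tryptic scanner (regex-free)
oracle_digest <- function(residues, crosslinked = integer()) {
  chars <- strsplit(residues, "")[[1]]
  frags <- character(0)
  cur <- ""
  for (i in seq_along(chars)) {
    cur <- paste0(cur, chars[i])
    is_site <- (chars[i] == "K" || chars[i] == "R") &&
      i < length(chars) && chars[i + 1] != "P" && !(i %in% crosslinked)
    if (is_site) { frags <- c(frags, cur); cur <- "" }
  }
  if (nchar(cur)) frags <- c(frags, cur)
  frags
}

# brute-force centre-target distances for one frame
oracle_frame_dists <- function(traj, f) {
  ctr <- which(startsWith(traj$labels, traj$center_label))
  sel <- which(startsWith(traj$labels, traj$water_h_label))
  vapply(sel, function(a)
    sqrt(sum((traj$coords[a, , f] - traj$coords[ctr, , f])^2)), numeric(1))
}

# random admissible sequence of length n (standard letters)
random_sequence <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
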