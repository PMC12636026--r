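# Seeded synthetic-data generators. Each generator emulates the
# statistical structure one analysis stage assumes, so the whole
# pipeline can be exercised without instrument data: NMRD dispersion
# profiles, two-equilibrium competition titrations, first-order
# challenge decays, and exponential-dwell hydration-shell trajectories.
# Every generator is bit-reproducible under a fixed seed and records its
# noise model in the output attributes.

apply_noise <- function(x, noise = c("none", "multiplicative", "additive"),
                        sigma = 0) {
  noise <- match.arg(noise)
  if (sigma < 0) stop("noise sigma must be >= 0")
  switch(noise,
         none = x,
         multiplicative = x * (1 + stats::rnorm(length(x), 0, sigma)),
         additive = x + stats::rnorm(length(x), 0, sigma))
}

#' Generate a synthetic NMRD profile
#'
#' Forward-simulates r1 over a frequency grid from a
#' [relaxation_model()] and applies the configured noise. With
#' `noise = "none"` the output equals [total_r1_profile()] exactly.
#'
#' @param model a [relaxation_model()]
#' @param freq_mhz frequency grid, MHz (default [default_freq_grid()])
#' @param noise `"none"`, `"multiplicative"` or `"additive"`
#' @param sigma noise scale (relative for multiplicative, mM^-1 s^-1
#'   for additive)
#' @param seed integer seed
#' @param label profile label
#' @return an [nmrd_profile()] with `noise` metadata attributes
#' @export
gen_nmrd <- function(model, freq_mhz = default_freq_grid(),
                     noise = "none", sigma = 0.02, seed = 0,
                     label = "synthetic") {
  clean <- total_r1_profile(freq_mhz, model, label = label)
  set.seed(seed)
  r1 <- apply_noise(clean$r1, noise, if (noise == "none") 0 else sigma)
  r1 <- pmax(r1, 1e-9)
  out <- nmrd_profile(freq_mhz, r1,
                      r1_err = if (noise == "multiplicative") sigma * clean$r1,
                      temperature = model$temperature, label = label)
  attr(out, "noise") <- list(model = noise, sigma = sigma, seed = seed)
  out
}

#' Generate a synthetic competition (or direct) titration
#'
#' For each total-metal point, partitions the metal between the peptide
#' site and the competitor with [speciation_1to1()] and produces
#' \eqn{signal = baseline + s_P [MP] + s_E [ME]} plus noise. With
#' `competitor_total = 0` this produces a direct titration.
#'
#' @param metal_total total metal series, uM
#' @param peptide_total peptide site total, uM
#' @param competitor_total competitor total, uM (scalar or per point;
#'   use `metal_total` itself for a metal-competitor co-delivery design)
#' @param logKa_P,logKa_E association constants, log10 M^-1
#' @param s_P,s_E,baseline signal coefficients (a.u. per uM, a.u.)
#' @param noise,sigma,seed noise configuration as in [gen_nmrd()]
#' @return a [titration_series()] with noise metadata
#' @export
gen_competition_titration <- function(metal_total, peptide_total = 3.3,
                                      competitor_total = metal_total,
                                      logKa_P = 13.9,
                                      logKa_E = egta_logKa_default,
                                      s_P = 1, s_E = 0.2, baseline = 0.05,
                                      noise = "none", sigma = 0.03, seed = 0) {
  Ka_P <- 10^logKa_P
  Ka_E <- 10^logKa_E
  n <- length(metal_total)
  competitor_total <- rep_len(competitor_total, n)
  peptide_total <- rep_len(peptide_total, n)
  clean <- vapply(seq_len(n), function(i) {
    s <- speciation_1to1(metal_total[i], peptide_total[i],
                         competitor_total[i], Ka_P, Ka_E)
    baseline + s_P * s$MP + s_E * s$ME
  }, numeric(1))
  set.seed(seed)
  sig <- apply_noise(clean, noise, if (noise == "none") 0 else sigma)
  out <- titration_series(metal_total, sig, peptide_total, competitor_total)
  attr(out, "noise") <- list(model = noise, sigma = sigma, seed = seed)
  attr(out, "truth") <- list(logKa_P = logKa_P, logKa_E = logKa_E,
                             s_P = s_P, s_E = s_E, baseline = baseline)
  out
}

#' Generate a first-order challenge decay series
#'
#' Exponential emission loss exp(-k t) under a challenge, with an
#' optional flat control channel at 1.0 (both noisy under the same
#' model), emulating phosphate-challenge kinetics.
#'
#' @param k first-order rate, min^-1 (>= 0)
#' @param t_min time grid, minutes, from 0
#' @param control include a control channel
#' @param noise,sigma,seed noise configuration
#' @return a [decay_series()] with noise metadata
#' @export
gen_decay <- function(k, t_min = seq(0, 1320, by = 10), control = FALSE,
                      noise = "none", sigma = 0.01, seed = 0) {
  if (k < 0) stop("rate `k` must be >= 0")
  clean <- exp(-k * t_min)
  set.seed(seed)
  sig <- apply_noise(clean, noise, if (noise == "none") 0 else sigma)
  ctrl <- if (control)
    apply_noise(rep(1, length(t_min)), noise, if (noise == "none") 0 else sigma)
  out <- decay_series(t_min, sig, ctrl)
  attr(out, "noise") <- list(model = noise, sigma = sigma, seed = seed)
  attr(out, "truth") <- list(k = k)
  out
}

#' Generate a hydration-shell trajectory
#'
#' One fixed Gd centre at the origin; `n_bulk` bulk waters redrawn
#' uniformly in a sphere of radius `r_sphere` every frame (ideal gas);
#' `n_tethered` waters that alternate between the shell and the bulk as
#' a symmetric telegraph process with per-frame switching probability
#' `dt / tau_res`, so in-shell dwells are geometric with mean
#' `tau_res`. While in shell a tethered water sits at `shell_radius`
#' (small radial jitter, random direction); in bulk it is uniform in
#' the sphere outside the shell. Each water contributes two hydrogen
#' atoms sharing a per-molecule label (`HW<i>`), 0.15 A apart.
#'
#' @param n_frames number of frames
#' @param dt frame spacing, ns
#' @param n_bulk,n_tethered water counts
#' @param tau_res mean in-shell residence time, ns (`Inf` = permanently
#'   tethered)
#' @param shell_radius tethered-water Gd-H distance, Angstrom
#' @param r_sphere analysis sphere radius, Angstrom
#' @param jitter radial jitter of tethered waters, Angstrom (sd)
#' @param seed integer seed
#' @return a [trajectory_frames()]
#' @export
gen_trajectory <- function(n_frames = 1000, dt = 0.1,
                           n_bulk = 0, n_tethered = 2,
                           tau_res = 4, shell_radius = 3.6,
                           r_sphere = 12, jitter = 0.1, seed = 0) {
  if (n_bulk < 0 || n_tethered < 0) stop("water counts must be >= 0")
  if (tau_res <= 0) stop("`tau_res` must be > 0")
  if (shell_radius >= r_sphere)
    stop("`shell_radius` must lie inside the analysis sphere")
  set.seed(seed)
  n_wat <- n_bulk + n_tethered
  n_atoms <- 1 + 2 * n_wat
  labels <- c("GD", rep(paste0("HW", seq_len(max(n_wat, 0))), each = 2))
  coords <- array(0, c(n_atoms, 3, n_frames))
  p_switch <- min(1, dt / tau_res)

  rand_dir <- function(n) {
    v <- matrix(stats::rnorm(3 * n), n, 3)
    v / sqrt(rowSums(v^2))
  }
  unif_sphere <- function(n, r_lo, r_hi) {
    r <- (stats::runif(n, r_lo^3, r_hi^3))^(1 / 3)
    rand_dir(n) * r
  }
  place_water <- function(o_pos) {
    # two H atoms 0.15 A either side of the water position
    d <- rand_dir(nrow(o_pos)) * 0.075
    rbind_interleave(o_pos + d, o_pos - d)
  }
  rbind_interleave <- function(a, b) {
    out <- matrix(0, 2 * nrow(a), 3)
    out[seq(1, 2 * nrow(a), by = 2), ] <- a
    out[seq(2, 2 * nrow(a), by = 2), ] <- b
    out
  }

  state <- rep(TRUE, n_tethered)  # tethered waters start in shell
  for (f in seq_len(n_frames)) {
    pos <- matrix(0, 0, 3)
    if (n_tethered > 0) {
      if (f > 1 && is.finite(tau_res)) {
        flip <- stats::runif(n_tethered) < p_switch
        state <- xor(state, flip)
      }
      o <- matrix(0, n_tethered, 3)
      n_in <- sum(state)
      if (n_in > 0)
        o[state, ] <- rand_dir(n_in) *
          pmax(0.5, shell_radius + stats::rnorm(n_in, 0, jitter))
      if (n_tethered - n_in > 0)
        o[!state, ] <- unif_sphere(n_tethered - n_in,
                                   shell_radius + 1.5, r_sphere)
      pos <- rbind(pos, place_water(o))
    }
    if (n_bulk > 0)
      pos <- rbind(pos, place_water(unif_sphere(n_bulk, 0, r_sphere)))
    coords[-1, , f] <- pos
  }
  # atom order: tethered waters first, then bulk; labels follow that order
  trajectory_frames(coords, labels, dt)
}
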