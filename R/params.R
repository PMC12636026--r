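#' Electron-spin parameters for Gd(III)
#'
#' Transient zero-field-splitting (ZFS) parameters governing the electron
#' spin relaxation of the paramagnetic centre. Gd(III) is an S = 7/2 ion
#' with g close to 2.
#'
#' @param delta2 mean-square ZFS energy \eqn{\Delta^2} (s^-2)
#' @param tau_v ZFS modulation correlation time \eqn{\tau_v} (s)
#' @param g electron g-factor (dimensionless)
#' @param S electron spin quantum number (half-integer)
#' @return object of class `electron_spin_params`
#' @export
electron_spin_params <- function(delta2 = 1.0e19, tau_v = 20e-12,
                                 g = 2.0, S = 3.5) {
  stopifnot(is.numeric(delta2), length(delta2) == 1L, is.finite(delta2),
            is.numeric(tau_v), length(tau_v) == 1L, is.finite(tau_v))
  if (delta2 < 0) stop("zfs_mean_square `delta2` must be >= 0")
  if (tau_v <= 0) stop("zfs correlation time `tau_v` must be > 0")
  if (S <= 0 || abs(2 * S - round(2 * S)) > 1e-12)
    stop("spin quantum number `S` must be positive and half-integer")
  structure(list(delta2 = delta2, tau_v = tau_v, g = g, S = S),
            class = "electron_spin_params")
}

#' Second-sphere water parameters
#'
#' Describes the population of water molecules hydrogen-bonded near (but
#' not coordinated to) the metal: their number, Gd-H distance, mean
#' residence time, and the Lipari-Szabo model-free description of their
#' motion (slow global tumbling, fast local rotation, order parameter).
#'
#' @param q_ss number of second-sphere water molecules (>= 0)
#' @param r_ss_A Gd(III)-H(water) distance in Angstrom
#' @param tau_M_ss mean residence time of a second-sphere water (s)
#' @param tau_RG global rotational correlation time of the complex (s)
#' @param tau_RL local rotational correlation time of the water (s)
#' @param S2 Lipari-Szabo order parameter in \[0, 1\]: 0 = local and
#'   global motions fully independent, 1 = fully correlated
#' @return object of class `second_sphere_params`
#' @export
second_sphere_params <- function(q_ss = 2, r_ss_A = 3.6, tau_M_ss = 5.0e-9,
                                 tau_RG = 7e-9, tau_RL = 318e-12, S2 = 0.5) {
  if (q_ss < 0) stop("`q_ss` must be >= 0")
  if (r_ss_A <= 0) stop("`r_ss_A` must be > 0")
  if (tau_M_ss <= 0 || tau_RG <= 0 || tau_RL <= 0)
    stop("all correlation/residence times must be > 0")
  if (S2 < 0 || S2 > 1) stop("order parameter `S2` must lie in [0, 1]")
  structure(list(q_ss = q_ss, r_ss_A = r_ss_A, tau_M_ss = tau_M_ss,
                 tau_RG = tau_RG, tau_RL = tau_RL, S2 = S2),
            class = "second_sphere_params")
}

#' Outer-sphere (Freed) parameters
#'
#' @param a_A distance of closest approach of freely diffusing water
#'   protons to the metal, Angstrom
#' @param D relative water-complex diffusion coefficient, m^2 s^-1
#' @return object of class `outer_sphere_params`
#' @export
outer_sphere_params <- function(a_A = 4.0, D = 2.3e-10) {
  if (a_A <= 0) stop("closest approach `a_A` must be > 0")
  if (D <= 0) stop("diffusion coefficient `D` must be > 0")
  structure(list(a_A = a_A, D = D), class = "outer_sphere_params")
}

#' Full relaxivity model (second sphere + outer sphere, no inner sphere)
#'
#' The inner-sphere hydration number is identically zero in this model
#' family; relaxivity arises from second-sphere and outer-sphere
#' mechanisms only.
#'
#' @param second_sphere a [second_sphere_params()] object
#' @param outer_sphere an [outer_sphere_params()] object
#' @param electron an [electron_spin_params()] object
#' @param temperature temperature in K (metadata only; the model is
#'   single-temperature)
#' @return object of class `relaxation_model`
#' @export
relaxation_model <- function(second_sphere = second_sphere_params(),
                             outer_sphere = outer_sphere_params(),
                             electron = electron_spin_params(),
                             temperature = 298) {
  stopifnot(inherits(second_sphere, "second_sphere_params"),
            inherits(outer_sphere, "outer_sphere_params"),
            inherits(electron, "electron_spin_params"))
  structure(list(second_sphere = second_sphere, outer_sphere = outer_sphere,
                 electron = electron, temperature = temperature),
            class = "relaxation_model")
}

#' @export
print.relaxation_model <- function(x, ...) {
  ss <- x$second_sphere; os <- x$outer_sphere; el <- x$electron
  cat("Relaxivity model (second sphere + outer sphere; q_inner = 0)\n")
  cat(sprintf("  second sphere: q_ss = %g, r_ss = %g A, tau_M^SS = %g ns,\n",
              ss$q_ss, ss$r_ss_A, ss$tau_M_ss * 1e9))
  cat(sprintf("                 tau_RG = %g ns, tau_RL = %g ps, S2 = %g\n",
              ss$tau_RG * 1e9, ss$tau_RL * 1e12, ss$S2))
  cat(sprintf("  outer sphere:  a = %g A, D = %g m2/s\n", os$a_A, os$D))
  cat(sprintf("  electron spin: S = %g, g = %g, Delta2 = %g s-2, tau_v = %g ps\n",
              el$S, el$g, el$delta2, el$tau_v * 1e12))
  cat(sprintf("  temperature:   %g K (metadata)\n", x$temperature))
  invisible(x)
}

#' Construct an NMRD profile
#'
#' A nuclear magnetic relaxation dispersion profile: longitudinal water
#' proton relaxivity r1 as a function of proton Larmor frequency.
#'
#' @param freq_mhz proton Larmor frequencies, MHz; strictly increasing
#' @param r1 longitudinal relaxivity, mM^-1 s^-1; positive
#' @param r1_err optional 1-sigma uncertainties, same units
#' @param temperature K, metadata
#' @param concentration mM, metadata
#' @param label free-text label
#' @return a data frame of class `nmrd_profile` with columns `freq_mhz`,
#'   `r1` and optionally `r1_err`
#' @export
nmrd_profile <- function(freq_mhz, r1, r1_err = NULL,
                         temperature = 298, concentration = NA_real_,
                         label = "") {
  freq_mhz <- as.numeric(freq_mhz); r1 <- as.numeric(r1)
  if (length(freq_mhz) != length(r1))
    stop("`freq_mhz` and `r1` must have equal length")
  if (any(!is.finite(freq_mhz)) || any(freq_mhz <= 0))
    stop("frequencies must be positive and finite")
  if (any(diff(freq_mhz) <= 0))
    stop("frequencies must be strictly increasing")
  if (any(!is.finite(r1)) || any(r1 <= 0))
    stop("relaxivities must be positive and finite")
  df <- data.frame(freq_mhz = freq_mhz, r1 = r1)
  if (!is.null(r1_err)) {
    r1_err <- as.numeric(r1_err)
    if (length(r1_err) != length(r1)) stop("`r1_err` length mismatch")
    if (any(!is.finite(r1_err)) || any(r1_err <= 0))
      stop("`r1_err` must be positive and finite")
    df$r1_err <- r1_err
  }
  structure(df, class = c("nmrd_profile", "data.frame"),
            temperature = temperature, concentration = concentration,
            label = label)
}

#' @export
print.nmrd_profile <- function(x, ...) {
  cat(sprintf("NMRD profile '%s': %d points, %.3g-%.3g MHz, T = %g K\n",
              attr(x, "label"), nrow(x), min(x$freq_mhz), max(x$freq_mhz),
              attr(x, "temperature")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
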