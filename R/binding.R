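# Lanthanide binding analysis: 1:1 two-ligand speciation, Hill fits of
# direct luminescence titrations, and apparent log Ka from EGTA
# competition titrations.

#' Construct a titration series
#'
#' Total metal versus integrated sensitised emission, with the per-site
#' peptide total and (for competition experiments) the competitor total
#' at each point. Concentrations are micromolar throughout.
#'
#' @param metal_total total metal per point, uM, non-decreasing
#' @param signal integrated emission, arbitrary units
#' @param peptide_total peptide binding-site total, uM (scalar or per point);
#'   one Ln(III) site per assembled three-helix bundle, so this is the
#'   trimer concentration
#' @param competitor_total competitor (e.g. EGTA) total, uM; 0 for a
#'   direct titration
#' @param pH metadata
#' @return data frame of class `titration_series`
#' @export
titration_series <- function(metal_total, signal, peptide_total,
                             competitor_total = 0, pH = 7.5) {
  n <- length(metal_total)
  if (length(signal) != n) stop("`metal_total` and `signal` length mismatch")
  if (any(!is.finite(metal_total)) || any(metal_total < 0))
    stop("`metal_total` must be non-negative and finite")
  if (any(diff(metal_total) < 0)) stop("`metal_total` must be non-decreasing")
  if (any(!is.finite(signal))) stop("`signal` must be finite")
  df <- data.frame(metal_total = metal_total, signal = signal,
                   peptide_total = rep_len(peptide_total, n),
                   competitor_total = rep_len(competitor_total, n))
  structure(df, class = c("titration_series", "data.frame"), pH = pH)
}

#' Equilibrium speciation of one metal between two 1:1 ligands
#'
#' Solves the mass balance
#' \deqn{M_T = M + \frac{K_P M P_T}{1 + K_P M} + \frac{K_E M E_T}{1 + K_E M}}
#' for free metal M by bracketed root finding on \[0, M_T\] (the left side
#' is strictly increasing in M so the bracket always works), then reports
#' the bound species. Ligand depletion is always modelled; no
#' free-approximately-total shortcut.
#'
#' @param metal_total,peptide_total,competitor_total totals, uM (scalars)
#' @param Ka_P,Ka_E association constants, M^-1 (> 0; use a tiny value
#'   rather than 0 for an absent ligand, or 0 which is treated as absent)
#' @return list with `free_M`, `MP`, `ME` (uM), satisfying both mass
#'   balances to relative error < 1e-10
#' @export
speciation_1to1 <- function(metal_total, peptide_total, competitor_total,
                            Ka_P, Ka_E) {
  stopifnot(metal_total >= 0, peptide_total >= 0, competitor_total >= 0,
            Ka_P >= 0, Ka_E >= 0)
  if (metal_total == 0) return(list(free_M = 0, MP = 0, ME = 0))
  # per-uM association constants
  kP <- Ka_P * 1e-6
  kE <- Ka_E * 1e-6
  f <- function(M) M + kP * M * peptide_total / (1 + kP * M) +
    kE * M * competitor_total / (1 + kE * M) - metal_total
  if (f(metal_total) < -1e-12 * metal_total)
    stop("internal error: no sign change in speciation bracket")
  root <- stats::uniroot(f, c(0, metal_total),
                         tol = .Machine$double.eps * metal_total)$root
  # Newton polish for the 1e-10 mass-balance contract
  for (i in 1:3) {
    fp <- 1 + kP * peptide_total / (1 + kP * root)^2 +
      kE * competitor_total / (1 + kE * root)^2
    root <- max(0, min(metal_total, root - f(root) / fp))
  }
  M <- root
  list(free_M = M,
       MP = kP * M * peptide_total / (1 + kP * M),
       ME = kE * M * competitor_total / (1 + kE * M))
}

#' Hill fit of a direct titration
#'
#' Fits \eqn{signal = baseline + amplitude \cdot M^n / (K_d^n + M^n)} to
#' a direct titration by bounded least squares (`nlminb` on log Kd,
#' log n, with amplitude and baseline free). The Hill coefficient n
#' captures the apparent cooperativity of metal-templated assembly; the
#' midpoint Kd is in uM.
#'
#' @param series a [titration_series()] (competitor ignored)
#' @return list with `Kd` (uM), `hill_n`, `amplitude`, `baseline`,
#'   `residual_sum_squares`, `warnings`
#' @export
hill_fit <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  M <- series$metal_total
  y <- series$signal
  if (length(M) < 6) stop("need at least 6 titration points")
  span <- diff(range(y))
  obj <- function(th) {
    kd <- exp(th[1]); n <- exp(th[2]); amp <- th[3]; b0 <- th[4]
    frac <- ifelse(M > 0, M^n / (kd^n + M^n), 0)
    sum((b0 + amp * frac - y)^2)
  }
  kd0 <- stats::approx(y, M, xout = min(y) + span / 2, ties = "ordered")$y
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(M[M > 0])
  fit <- stats::nlminb(c(log(kd0), 0, span, min(y)), obj,
                       lower = c(log(min(M[M > 0]) / 100), log(0.2), -Inf, -Inf),
                       upper = c(log(max(M) * 100), log(10), Inf, Inf),
                       control = list(rel.tol = 1e-10, iter.max = 500))
  rss <- fit$objective
  warnings <- character()
  resid_scale <- sqrt(rss / max(1, length(y) - 4))
  if (span < 3 * resid_scale)
    warnings <- c(warnings, "saturation not reached: Kd weakly identified")
  list(Kd = exp(fit$par[1]), hill_n = exp(fit$par[2]),
       amplitude = fit$par[3], baseline = fit$par[4],
       residual_sum_squares = rss, converged = fit$convergence == 0,
       warnings = warnings)
}

#' Apparent association constant from an EGTA competition titration
#'
#' At each titration point the metal is partitioned between the peptide
#' site and the competitor by [speciation_1to1()]; the predicted signal
#' is \eqn{baseline + s_P \cdot [MP] + s_E \cdot [ME]}. Because the
#' signal model is linear in (baseline, s_P, s_E), those coefficients
#' are profiled out exactly by linear least squares at each candidate
#' log Ka, and the apparent peptide constant is found by 1-D
#' minimisation of the profiled residual. Uncertainty is read off the
#' 1-D residual profile (the log Ka interval whose profiled RSS stays
#' within one residual variance of the minimum).
#'
#' @param series a [titration_series()] with non-zero competitor somewhere
#' @param logKa_E conditional association constant of the metal-competitor
#'   complex, log10 M^-1 (see [egta_logKa_default])
#' @param fit_signal_coeffs character subset of `c("baseline", "s_P", "s_E")`
#'   to free; the rest are fixed at `fixed_coeffs`
#' @param fixed_coeffs named list of fixed signal coefficients
#' @param logKa_range search interval for the apparent log Ka
#' @return list with `logKa_peptide`, `logKa_interval` (profile-based),
#'   `coeffs`, `residual_sum_squares`, `warnings`
#' @export
competition_fit <- function(series, logKa_E,
                            fit_signal_coeffs = c("baseline", "s_P", "s_E"),
                            fixed_coeffs = list(baseline = 0, s_P = 1, s_E = 0),
                            logKa_range = c(6, 20)) {
  stopifnot(inherits(series, "titration_series"))
  if (all(series$competitor_total <= 0))
    stop("competition fit requires non-zero competitor totals")
  Ka_E <- 10^logKa_E
  y <- series$signal
  n <- length(y)

  species <- function(logKa_P) {
    Ka_P <- 10^logKa_P
    out <- vapply(seq_len(n), function(i) {
      s <- speciation_1to1(series$metal_total[i], series$peptide_total[i],
                           series$competitor_total[i], Ka_P, Ka_E)
      c(s$MP, s$ME)
    }, numeric(2))
    list(MP = out[1, ], ME = out[2, ])
  }

  profiled_rss <- function(logKa_P) {
    sp <- species(logKa_P)
    cols <- list(baseline = rep(1, n), s_P = sp$MP, s_E = sp$ME)
    X <- do.call(cbind, cols[fit_signal_coeffs])
    offset <- rep(0, n)
    for (nm in setdiff(c("baseline", "s_P", "s_E"), fit_signal_coeffs))
      offset <- offset + fixed_coeffs[[nm]] *
        (if (nm == "baseline") rep(1, n) else if (nm == "s_P") sp$MP else sp$ME)
    if (is.null(X) || ncol(X) == 0) {
      rss <- sum((y - offset)^2)
      return(list(rss = rss, coeffs = numeric(0)))
    }
    ft <- stats::lm.fit(X, y - offset)
    list(rss = sum(ft$residuals^2),
         coeffs = stats::setNames(ft$coefficients, fit_signal_coeffs),
         rank = ft$rank)
  }

  grid <- seq(logKa_range[1], logKa_range[2], by = 0.25)
  rss_grid <- vapply(grid, function(g) profiled_rss(g)$rss, numeric(1))
  g0 <- grid[which.min(rss_grid)]
  opt <- stats::optimize(function(g) profiled_rss(g)$rss,
                         interval = c(max(logKa_range[1], g0 - 0.5),
                                      min(logKa_range[2], g0 + 0.5)),
                         tol = 1e-7)
  best <- profiled_rss(opt$minimum)

  warnings <- character()
  if (!is.null(best$rank) && best$rank < length(fit_signal_coeffs))
    warnings <- c(warnings,
                  "signal model rank-deficient: logKa not identifiable (s_P and s_E degenerate)")
  # sensitivity check: does logKa move the profiled RSS at all?
  spread <- max(rss_grid) - min(rss_grid)
  scale0 <- max(sum((y - mean(y))^2), .Machine$double.eps)
  if (spread < 1e-9 * scale0)
    warnings <- c(warnings,
                  "no sensitivity of the signal to logKa over the search range: identifiability failure")

  # profile interval: logKa where RSS <= RSS_min + s2 (1-sigma-like)
  dof <- max(1, n - length(fit_signal_coeffs) - 1)
  s2 <- max(best$rss / dof, 1e-300)
  dense <- seq(logKa_range[1], logKa_range[2], by = 0.01)
  ok <- vapply(dense, function(g) profiled_rss(g)$rss, numeric(1)) <=
    best$rss + s2
  interval <- if (any(ok)) range(dense[ok]) else c(NA_real_, NA_real_)

  list(logKa_peptide = opt$minimum,
       logKa_interval = interval,
       coeffs = best$coeffs,
       residual_sum_squares = best$rss,
       warnings = warnings)
}

#' Default conditional Tb(III)-EGTA association constant
#'
#' Conditional (pH 7.5, I = 0.1 M) association constant of the
#' Tb(III)-EGTA complex used as the competition reference, log10 M^-1.
#' This is experiment metadata the user should override with the value
#' appropriate to their buffer; the default combines the critical
#' TbEGTA stability constant with the EGTA protonation correction at
#' pH 7.5. In self-consistent generate-then-fit analyses its absolute
#' value cancels.
#' @export
egta_logKa_default <- 14.0
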