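# NMRD profile fitting: weighted least squares on a declared free/fixed
# parameter partition, bounded via log (logit for S2) transforms, with
# seeded log-uniform multi-start and residual-resampling bootstrap.

FREE_PARAM_NAMES <- c("tau_RL", "tau_M_ss", "S2", "delta2", "tau_v", "q_ss")

default_bounds <- function(names) {
  all <- list(tau_RL   = c(1e-12, 1e-8),
              tau_M_ss = c(1e-11, 1e-6),
              S2       = c(1e-4, 1 - 1e-4),
              delta2   = c(1e16, 1e22),
              tau_v    = c(1e-13, 1e-9),
              q_ss     = c(0.01, 20))
  all[names]
}

#' Specification of an NMRD fit
#'
#' Declares which model parameters are free, the fixed values of the
#' rest (via a template [relaxation_model()]), per-parameter bounds, the
#' number of multi-start initialisations and the seed.
#'
#' @param free character vector, subset of
#'   `c("tau_RL", "tau_M_ss", "S2", "delta2", "tau_v", "q_ss")`
#' @param model template [relaxation_model()] supplying every fixed value
#'   (and the starting neighbourhood for free ones)
#' @param bounds named list of `c(lower, upper)` per free parameter;
#'   defaults cover the physically plausible range
#' @param starts number of multi-start initialisations (>= 1)
#' @param seed integer seed for the start draws
#' @return object of class `fit_spec`
#' @export
fit_spec <- function(free = c("tau_RL", "tau_M_ss", "S2"),
                     model = relaxation_model(),
                     bounds = NULL, starts = 8, seed = 0) {
  if (!all(free %in% FREE_PARAM_NAMES))
    stop("free parameters must be among: ",
         paste(FREE_PARAM_NAMES, collapse = ", "))
  if (anyDuplicated(free)) stop("duplicated free parameter names")
  b <- default_bounds(free)
  if (!is.null(bounds)) {
    if (!all(names(bounds) %in% free))
      stop("bounds supplied for non-free parameters")
    b[names(bounds)] <- bounds
  }
  for (nm in free) {
    bb <- b[[nm]]
    if (length(bb) != 2 || any(!is.finite(bb)) || bb[1] <= 0 || bb[2] <= bb[1])
      stop("bounds for ", nm, " must be finite, positive and increasing")
  }
  structure(list(free = free, model = model, bounds = b,
                 starts = as.integer(starts), seed = as.integer(seed)),
            class = "fit_spec")
}

# get/set free parameters inside a relaxation_model
model_get <- function(model, names) {
  vapply(names, function(nm) {
    if (nm %in% c("delta2", "tau_v")) model$electron[[nm]]
    else model$second_sphere[[nm]]
  }, numeric(1))
}

model_set <- function(model, values) {
  for (nm in names(values)) {
    if (nm %in% c("delta2", "tau_v")) model$electron[[nm]] <- values[[nm]]
    else model$second_sphere[[nm]] <- values[[nm]]
  }
  model
}

# bounded <-> unbounded transforms: log for positive scales, logit for S2
to_internal <- function(values, free) {
  ifelse(free == "S2", stats::qlogis(values), log(values))
}
from_internal <- function(theta, free) {
  out <- ifelse(free == "S2", stats::plogis(theta), exp(theta))
  names(out) <- free
  out
}

fit_objective <- function(profile, spec) {
  wts <- if ("r1_err" %in% names(profile)) 1 / profile$r1_err^2 else
    rep(1, nrow(profile))
  freq <- profile$freq_mhz
  obs <- profile$r1
  model0 <- spec$model
  free <- spec$free
  function(theta) {
    vals <- from_internal(theta, free)
    m <- model_set(model0, as.list(vals))
    pred <- second_sphere_r1(freq, m$second_sphere, m$electron) +
      outer_sphere_r1(freq, m$outer_sphere, m$electron)
    sum(wts * (pred - obs)^2)
  }
}

#' Fit an NMRD profile by weighted least squares
#'
#' Minimises the (inverse-variance weighted when `r1_err` is present)
#' sum of squared residuals between the measured profile and the
#' second-sphere + outer-sphere forward model over the free parameters
#' declared in the [fit_spec()]. Free parameters are optimised on log
#' scale (logit for S2), which enforces bounds smoothly; the bounded
#' quasi-Newton PORT routine (`nlminb`) is run from `starts` seeded
#' log-uniform initialisations (the first start is the template model's
#' own values) and the best minimum is kept.
#'
#' @param profile an [nmrd_profile()]
#' @param spec a [fit_spec()]
#' @param bootstrap number of residual-resampling bootstrap replicates
#'   for percentile confidence intervals (0 = none)
#' @param bootstrap_level nominal two-sided CI level
#' @return object of class `fit_result`: list with `fitted_values`,
#'   `residual_sum_squares`, `converged`, `n_starts_agreeing`, `model`
#'   (template with fitted values substituted), `warnings`, and
#'   `bootstrap_ci` when requested
#' @export
fit_nmrd <- function(profile, spec, bootstrap = 0, bootstrap_level = 0.90) {
  stopifnot(inherits(profile, "nmrd_profile"), inherits(spec, "fit_spec"))
  if (nrow(profile) < 2 * length(spec$free))
    stop("need at least twice as many data points as free parameters")
  warnings <- character()
  if (stats::sd(profile$r1) < 1e-12 * mean(profile$r1))
    warnings <- c(warnings, "degenerate profile: r1 is constant; parameters may not be identifiable")

  obj <- fit_objective(profile, spec)
  free <- spec$free
  lower <- to_internal(vapply(spec$bounds, `[`, numeric(1), 1), free)
  upper <- to_internal(vapply(spec$bounds, `[`, numeric(1), 2), free)

  # start 1: template values (clamped into bounds); rest: log-uniform draws
  starts <- matrix(NA_real_, spec$starts, length(free))
  t0 <- to_internal(pmin(pmax(model_get(spec$model, free),
                              vapply(spec$bounds, `[`, numeric(1), 1)),
                         vapply(spec$bounds, `[`, numeric(1), 2)), free)
  starts[1, ] <- t0
  if (spec$starts > 1) {
    # one row of draws per start, so the draw stream for k starts is a
    # prefix of the stream for k' > k starts under the same seed
    rng <- local({
      set.seed(spec$seed)
      t(replicate(spec$starts - 1, stats::runif(length(free))))
    })
    rng <- matrix(rng, spec$starts - 1, length(free))
    starts[-1, ] <- sweep(sweep(rng, 2, upper - lower, `*`), 2, lower, `+`)
  }

  runs <- apply(starts, 1, function(th0) {
    res <- tryCatch(
      stats::nlminb(th0, obj, lower = lower, upper = upper,
                    control = list(rel.tol = 1e-10, iter.max = 500,
                                   eval.max = 1000)),
      error = function(e) list(objective = Inf, par = th0, convergence = 1L))
    list(par = res$par, value = res$objective,
         converged = identical(res$convergence, 0L))
  })
  values <- vapply(runs, `[[`, numeric(1), "value")
  best <- which.min(values)
  if (!any(vapply(runs, `[[`, logical(1), "converged")))
    warnings <- c(warnings, "no start converged; best objective reported")
  agree <- sum(values <= values[best] * (1 + 1e-3) + 1e-300)

  fitted <- from_internal(runs[[best]]$par, free)
  out <- structure(list(
    fitted_values = fitted,
    residual_sum_squares = values[best],
    converged = runs[[best]]$converged,
    n_starts_agreeing = agree,
    model = model_set(spec$model, as.list(fitted)),
    free = free,
    warnings = warnings,
    bootstrap_ci = NULL), class = "fit_result")

  if (bootstrap > 0)
    out$bootstrap_ci <- bootstrap_nmrd(profile, spec, out, bootstrap,
                                       bootstrap_level)
  out
}

# Residual resampling on the fixed design grid: refit `n` pseudo-profiles
# built from fitted curve + resampled residuals; percentile intervals.
bootstrap_nmrd <- function(profile, spec, fit, n, level) {
  m <- fit$model
  pred <- second_sphere_r1(profile$freq_mhz, m$second_sphere, m$electron) +
    outer_sphere_r1(profile$freq_mhz, m$outer_sphere, m$electron)
  resid <- profile$r1 - pred
  spec1 <- spec
  spec1$starts <- 1L
  spec1$model <- m  # start each refit from the point estimate
  draws <- local({
    set.seed(spec$seed + 1L)
    replicate(n, {
      r1b <- pred + sample(resid, length(resid), replace = TRUE)
      r1b <- pmax(r1b, 1e-6)
      pb <- profile
      pb$r1 <- r1b
      fit_nmrd(pb, spec1)$fitted_values
    })
  })
  draws <- matrix(draws, nrow = length(spec$free))
  alpha <- (1 - level) / 2
  ci <- t(apply(draws, 1, stats::quantile, probs = c(alpha, 1 - alpha)))
  rownames(ci) <- spec$free
  colnames(ci) <- c("lower", "upper")
  ci
}

#' @export
print.fit_result <- function(x, ...) {
  cat("NMRD fit:", if (x$converged) "converged" else "NOT converged",
      sprintf("(%d starts agree within 0.1%% residual)\n",
              x$n_starts_agreeing), sep = " ")
  for (nm in names(x$fitted_values))
    cat(sprintf("  %-9s = %.6g\n", nm, x$fitted_values[[nm]]))
  cat(sprintf("  weighted RSS = %.6g\n", x$residual_sum_squares))
  if (!is.null(x$bootstrap_ci)) { cat("  bootstrap CI:\n"); print(x$bootstrap_ci) }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Scan candidate second-sphere hydration numbers
#'
#' Refits the profile once per candidate q_ss (held fixed) and ranks the
#' candidates by residual sum of squares, the model-selection step that
#' identifies how many second-sphere waters the dispersion supports.
#'
#' @param profile an [nmrd_profile()]
#' @param spec a [fit_spec()]; `q_ss` must not be in its free set
#' @param q_candidates non-negative hydration-number candidates
#' @return list of `fit_result`s sorted by increasing residual; each
#'   carries its `q_ss` element
#' @export
scan_q_ss <- function(profile, spec, q_candidates = c(1, 2, 3)) {
  if (length(q_candidates) == 0) stop("`q_candidates` must be non-empty")
  if (any(q_candidates < 0)) stop("`q_candidates` must be non-negative")
  if ("q_ss" %in% spec$free) stop("`q_ss` cannot be free during a q_ss scan")
  fits <- lapply(q_candidates, function(q) {
    s <- spec
    s$model$second_sphere$q_ss <- q
    f <- fit_nmrd(profile, s)
    f$q_ss <- q
    f
  })
  fits[order(vapply(fits, `[[`, numeric(1), "residual_sum_squares"))]
}

#' Compare two NMRD profiles
#'
#' Mean and maximum relative difference |r1_1 - r1_2| / r1_1 between two
#' profiles, e.g. buffer vs serum matrix. Differing grids are linearly
#' interpolated in log-frequency onto the coarser grid, restricted to
#' the overlapping frequency range.
#'
#' @param p1,p2 [nmrd_profile()] objects; `p1` is the reference
#' @param symmetry_tol flag the comparison as asymmetric when swapping
#'   the reference changes the mean relative difference by more than this
#' @return list with `mean_rel_diff`, `max_rel_diff`, `n_points`,
#'   `symmetric` (logical)
#' @export
compare_profiles <- function(p1, p2, symmetry_tol = 0.01) {
  stopifnot(inherits(p1, "nmrd_profile"), inherits(p2, "nmrd_profile"))
  lo <- max(min(p1$freq_mhz), min(p2$freq_mhz))
  hi <- min(max(p1$freq_mhz), max(p2$freq_mhz))
  if (lo >= hi) stop("profiles have no overlapping frequency range")
  interp <- function(p, f) {
    stats::approx(log(p$freq_mhz), p$r1, xout = log(f))$y
  }
  same_grid <- length(p1$freq_mhz) == length(p2$freq_mhz) &&
    all(abs(p1$freq_mhz - p2$freq_mhz) < 1e-12 * p1$freq_mhz)
  if (same_grid) {
    f <- p1$freq_mhz; a <- p1$r1; b <- p2$r1
  } else {
    g1 <- p1$freq_mhz[p1$freq_mhz >= lo & p1$freq_mhz <= hi]
    g2 <- p2$freq_mhz[p2$freq_mhz >= lo & p2$freq_mhz <= hi]
    f <- if (length(g1) <= length(g2)) g1 else g2
    a <- interp(p1, f); b <- interp(p2, f)
  }
  rel <- abs(a - b) / a
  rel_swapped <- abs(a - b) / b
  list(mean_rel_diff = mean(rel), max_rel_diff = max(rel),
       n_points = length(f),
       symmetric = abs(mean(rel) - mean(rel_swapped)) <= symmetry_tol)
}
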