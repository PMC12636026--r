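# Hydration-shell statistics around the Gd(III) centre: radial
# distribution function of water hydrogens, second-shell occupancy,
# continuous residence lifetimes.

#' Construct a labelled trajectory
#'
#' Time-ordered frames of labelled coordinates with a single metal
#' centre. Coordinates are Angstrom, frame spacing in ns. Water
#' hydrogens are selected by label prefix; atoms sharing an identical
#' full label (e.g. both hydrogens labelled `HW7`) are grouped into one
#' water molecule for per-molecule statistics.
#'
#' @param coords numeric array `[n_atoms, 3, n_frames]`, Angstrom
#' @param labels character vector of atom labels, length `n_atoms`,
#'   constant across frames
#' @param dt frame spacing, ns (> 0)
#' @param center_label label (prefix) identifying the metal centre;
#'   exactly one atom must match
#' @param water_h_label label prefix selecting water hydrogens
#' @param box optional orthorhombic box lengths (Angstrom, length 3) for
#'   minimum-image distances; NULL for a non-periodic cluster
#' @return object of class `trajectory_frames`
#' @export
trajectory_frames <- function(coords, labels, dt,
                              center_label = "GD", water_h_label = "HW",
                              box = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("`coords` must be an [n_atoms, 3, n_frames] array")
  if (dim(coords)[3] < 1) stop("need at least one frame")
  if (length(labels) != dim(coords)[1]) stop("label/atom count mismatch")
  if (!is.numeric(dt) || dt <= 0) stop("frame spacing `dt` must be > 0")
  if (sum(startsWith(labels, center_label)) != 1)
    stop("exactly one atom must match the centre label '", center_label, "'")
  if (!is.null(box)) {
    if (length(box) != 3 || any(box <= 0)) stop("invalid box lengths")
  }
  structure(list(coords = coords, labels = labels, dt = dt,
                 center_label = center_label, water_h_label = water_h_label,
                 box = box),
            class = "trajectory_frames")
}

#' @export
print.trajectory_frames <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("Trajectory: %d frames x %d atoms, dt = %g ns (%g ns total)%s\n",
              d[3], d[1], x$dt, d[3] * x$dt,
              if (is.null(x$box)) ", non-periodic" else ", periodic"))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]

traj_target_index <- function(traj) {
  sel <- which(startsWith(traj$labels, traj$water_h_label))
  if (length(sel) == 0)
    stop("no atoms match water selector '", traj$water_h_label,
         "'; labels present: ",
         paste(utils::head(unique(traj$labels), 8), collapse = ", "))
  sel
}

# distances centre -> targets for one frame, with optional minimum image
frame_distances <- function(traj, frame, sel, center) {
  slice <- matrix(traj$coords[, , frame], ncol = 3)
  d <- slice[sel, , drop = FALSE] -
    matrix(slice[center, ], length(sel), 3, byrow = TRUE)
  if (!is.null(traj$box)) {
    for (k in 1:3) d[, k] <- d[, k] - traj$box[k] * round(d[, k] / traj$box[k])
  }
  sqrt(rowSums(d^2))
}

#' Radial distribution function of water hydrogens about the centre
#'
#' Frame-averaged histogram of centre-target distances normalised by the
#' ideal-gas shell count \eqn{4\pi r^2 \Delta r \rho}, where the density
#' rho is the mean number of selected atoms inside the analysis sphere
#' of radius `r_max` divided by its volume (minimum-image distances when
#' a box is present). g(r) = 1 for uniformly distributed targets.
#'
#' @param traj a [trajectory_frames()]
#' @param r_max outer radius, Angstrom
#' @param dr bin width, Angstrom (`r_max > dr > 0`)
#' @return list with `r` (bin centres), `g`, `counts` (mean per frame),
#'   `density` (atoms / A^3)
#' @export
hydration_rdf <- function(traj, r_max = 8, dr = 0.1) {
  stopifnot(inherits(traj, "trajectory_frames"))
  if (!(r_max > dr && dr > 0)) stop("need r_max > dr > 0")
  if (!is.null(traj$box) && r_max > min(traj$box) / 2)
    stop("`r_max` exceeds half the shortest box length")
  sel <- traj_target_index(traj)
  center <- which(startsWith(traj$labels, traj$center_label))
  breaks <- seq(0, r_max, by = dr)
  nb <- length(breaks) - 1
  counts <- numeric(nb)
  n_in <- 0
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    dists <- frame_distances(traj, f, sel, center)
    dists <- dists[dists < r_max]
    n_in <- n_in + length(dists)
    counts <- counts + tabulate(findInterval(dists, breaks,
                                             rightmost.closed = FALSE), nb)
  }
  counts <- counts / nf
  rho <- (n_in / nf) / ((4 / 3) * pi * r_max^3)
  r_mid <- breaks[-1] - dr / 2
  shell_vol <- 4 * pi * r_mid^2 * dr
  list(r = r_mid, g = counts / (shell_vol * rho), counts = counts,
       density = rho)
}

# per-frame, per-molecule in-shell indicator matrix [n_molecules, n_frames]
shell_membership <- function(traj, r_min, r_max) {
  if (!(r_min >= 0 && r_min < r_max)) stop("need 0 <= r_min < r_max")
  sel <- traj_target_index(traj)
  center <- which(startsWith(traj$labels, traj$center_label))
  mol <- match(traj$labels[sel], unique(traj$labels[sel]))
  # bare element-style labels (no per-molecule suffix, e.g. plain "H")
  # carry no molecule identity: fall back to per-atom counting
  if (max(mol) == 1 && length(sel) > 1 &&
      identical(traj$labels[sel][1], traj$water_h_label)) {
    warning("selected atoms carry no per-molecule label suffix; ",
            "counting each atom as its own molecule")
    mol <- seq_along(sel)
  }
  nf <- n_frames(traj)
  inshell <- matrix(FALSE, max(mol), nf)
  for (f in seq_len(nf)) {
    dists <- frame_distances(traj, f, sel, center)
    hit <- dists >= r_min & dists < r_max
    inshell[, f] <- as.logical(tabulate(mol[hit], max(mol)))
  }
  inshell
}

#' Second-shell water occupancy statistics
#'
#' Counts, frame by frame, the water molecules with any selected
#' hydrogen at a centre distance in `[r_min, r_max)` (per-molecule
#' counting: a molecule is in shell when any of its selected atoms is).
#' The default bounds bracket the ~3.6 Angstrom Gd-H(water) second-shell
#' peak.
#'
#' @param traj a [trajectory_frames()]
#' @param r_min,r_max shell bounds, Angstrom
#' @return list with `histogram` (named fractions over occupancy counts,
#'   summing to 1), `mean_occupancy`, `empty_fraction`, `per_frame`
#' @export
shell_occupancy <- function(traj, r_min = 3.0, r_max = 4.5) {
  stopifnot(inherits(traj, "trajectory_frames"))
  occ <- colSums(shell_membership(traj, r_min, r_max))
  tab <- table(factor(occ, levels = 0:max(max(occ), 1)))
  hist <- as.numeric(tab) / length(occ)
  names(hist) <- names(tab)
  list(histogram = hist,
       mean_occupancy = mean(occ),
       empty_fraction = mean(occ == 0),
       per_frame = occ)
}

#' Continuous residence lifetimes in the hydration shell
#'
#' For each water molecule, maximal runs of consecutive in-shell frames
#' are converted to durations (run length x dt). A single out-of-shell
#' frame terminates a run (no grace period). Runs touching either end
#' of the trajectory are censored and reported separately. The survival
#' curve S(t) is the fraction of uncensored lifetimes >= t.
#'
#' @param traj a [trajectory_frames()]
#' @param r_min,r_max shell bounds, Angstrom
#' @return list with `lifetimes` (uncensored, ns), `censored` (ns),
#'   `mean_lifetime` (ns, uncensored), `survival` (data frame `t`, `S`)
#' @export
residence_lifetimes <- function(traj, r_min = 3.0, r_max = 4.5) {
  stopifnot(inherits(traj, "trajectory_frames"))
  if (is.null(traj$dt) || !is.finite(traj$dt)) stop("frame spacing `dt` missing")
  inshell <- shell_membership(traj, r_min, r_max)
  nf <- ncol(inshell)
  lifetimes <- numeric(0)
  censored <- numeric(0)
  for (m in seq_len(nrow(inshell))) {
    r <- rle(inshell[m, ])
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      dur <- r$lengths[j] * traj$dt
      if (starts[j] == 1 || ends[j] == nf) censored <- c(censored, dur)
      else lifetimes <- c(lifetimes, dur)
    }
  }
  surv <- if (length(lifetimes)) {
    ts <- sort(unique(lifetimes))
    data.frame(t = ts,
               S = vapply(ts, function(t0) mean(lifetimes >= t0), numeric(1)))
  } else data.frame(t = numeric(0), S = numeric(0))
  list(lifetimes = lifetimes, censored = censored,
       mean_lifetime = if (length(lifetimes)) mean(lifetimes) else NA_real_,
       survival = surv)
}
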