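# Hydration-shell trajectory statistics: RDF, occupancy, lifetimes.

# tiny hand-built trajectory: centre + waters at chosen radii
fixture_traj <- function(radii_by_frame, dt = 0.1) {
  # radii_by_frame: list of numeric vectors (one radius per water, per frame)
  n_wat <- length(radii_by_frame[[1]])
  nf <- length(radii_by_frame)
  coords <- array(0, c(1 + 2 * n_wat, 3, nf))
  for (f in seq_len(nf)) {
    for (w in seq_len(n_wat)) {
      r <- radii_by_frame[[f]][w]
      coords[2 * w, , f] <- c(r, 0, 0)
      coords[2 * w + 1, , f] <- c(r, 0.05, 0)
    }
  }
  trajectory_frames(coords, c("GD", rep(paste0("HW", 1:n_wat), each = 2)),
                    dt = dt)
}

test_that("trajectory constructor validates shapes and selectors", {
  coords <- array(0, c(3, 3, 2))
  expect_error(trajectory_frames(coords, c("GD", "HW1"), 0.1), "mismatch")
  expect_error(trajectory_frames(coords, c("GD", "GD2", "HW1"), 0.1),
               "exactly one")
  expect_error(trajectory_frames(coords, c("GD", "HW1", "HW1"), 0),
               "dt")
  traj <- trajectory_frames(coords, c("GD", "HW1", "HW1"), 0.1)
  expect_s3_class(traj, "trajectory_frames")
})

test_that("a single fixed target puts all RDF mass in its bin", {
  traj <- fixture_traj(rep(list(3.6), 5))
  out <- hydration_rdf(traj, r_max = 6, dr = 0.2)
  hot <- which(out$counts > 0)
  expect_true(all(out$r[hot] > 3.4 & out$r[hot] < 3.8))
  expect_equal(sum(out$counts), 2)  # both hydrogens of the one water
})

test_that("RDF normalisation gives g ~ 1 for an ideal gas", {
  traj <- gen_trajectory(n_frames = 200, n_bulk = 300, n_tethered = 0,
                         r_sphere = 12, seed = 4)
  out <- hydration_rdf(traj, r_max = 10, dr = 0.5)
  inner <- out$g[out$r > 2 & out$r < 9]
  expect_true(all(abs(inner - 1) < 0.12))
  expect_equal(mean(inner), 1, tolerance = 0.02)
})

test_that("RDF bin counts equal a brute-force pair count", {
  traj <- gen_trajectory(n_frames = 6, n_bulk = 40, n_tethered = 2,
                         tau_res = 0.5, seed = 13)
  out <- hydration_rdf(traj, r_max = 8, dr = 0.25)
  breaks <- seq(0, 8, by = 0.25)
  manual <- numeric(length(breaks) - 1)
  for (f in 1:6) {
    d <- oracle_frame_dists(traj, f)
    manual <- manual + hist(d[d < 8], breaks = breaks, plot = FALSE)$counts
  }
  expect_equal(out$counts, manual / 6)
})

test_that("periodic boxes bound the RDF range", {
  coords <- array(runif(3 * 3 * 2, 0, 10), c(3, 3, 2))
  traj <- trajectory_frames(coords, c("GD", "HW1", "HW1"), 0.1,
                            box = c(10, 10, 10))
  expect_error(hydration_rdf(traj, r_max = 6), "half the shortest box")
  expect_silent(hydration_rdf(traj, r_max = 4.9, dr = 0.5))
})

test_that("static tethered waters give exact occupancy statistics", {
  traj <- fixture_traj(rep(list(c(3.6, 3.6)), 10))
  occ <- shell_occupancy(traj, 3.0, 4.5)
  expect_equal(occ$mean_occupancy, 2)
  expect_equal(unname(occ$histogram[["2"]]), 1)
  expect_equal(occ$empty_fraction, 0)
})

test_that("occupancy histogram is a distribution and matches brute force", {
  traj <- gen_trajectory(n_frames = 300, n_bulk = 10, n_tethered = 2,
                         tau_res = 0.5, seed = 17)
  occ <- shell_occupancy(traj, 3.0, 4.5)
  expect_equal(sum(occ$histogram), 1)
  counts <- as.numeric(names(occ$histogram))
  expect_equal(sum(counts * occ$histogram), occ$mean_occupancy)
  # brute-force per-frame molecule filter
  sel_labels <- traj$labels[startsWith(traj$labels, "HW")]
  for (f in c(1, 50, 300)) {
    d <- oracle_frame_dists(traj, f)
    mols <- unique(sel_labels[d >= 3.0 & d < 4.5])
    expect_equal(occ$per_frame[f], length(mols))
  }
  expect_error(shell_occupancy(traj, 4.5, 3.0), "r_min")
})

test_that("RDF integral reproduces the mean in-range neighbour count", {
  traj <- gen_trajectory(n_frames = 100, n_bulk = 150, n_tethered = 2,
                         tau_res = 1, seed = 23)
  out <- hydration_rdf(traj, r_max = 9, dr = 0.15)
  integral <- sum(4 * pi * out$r^2 * 0.15 * out$density * out$g)
  expect_equal(integral, sum(out$counts), tolerance = 0.01)
})

test_that("lifetime bookkeeping: censoring, minimal runs, relabeling", {
  # permanently in shell: one censored lifetime, nothing uncensored
  traj <- fixture_traj(rep(list(3.6), 100), dt = 0.1)
  lt <- residence_lifetimes(traj, 3.0, 4.5)
  expect_length(lt$lifetimes, 0)
  expect_equal(lt$censored, 10)
  # alternating in/out every frame: all uncensored lifetimes = dt
  radii <- lapply(1:50, function(f) if (f %% 2 == 0) 3.6 else 8)
  lt2 <- residence_lifetimes(fixture_traj(radii), 3.0, 4.5)
  expect_true(all(lt2$lifetimes == 0.1))
  # unbounded shell: every water contributes one censored trajectory-length run
  traj3 <- gen_trajectory(n_frames = 40, n_bulk = 3, n_tethered = 2,
                          tau_res = 1, seed = 3)
  lt3 <- residence_lifetimes(traj3, 0, Inf)
  expect_length(lt3$lifetimes, 0)
  expect_equal(lt3$censored, rep(4, 5))
  # relabeling waters (order-preserving) leaves lifetimes unchanged
  traj4 <- traj3
  traj4$labels <- sub("HW", "HWx", traj4$labels)
  lt4 <- residence_lifetimes(traj4, 3.0, 4.5)
  expect_equal(sort(lt4$lifetimes),
               sort(residence_lifetimes(traj3, 3.0, 4.5)$lifetimes))
})

test_that("survival curve is a proper tail distribution", {
  traj <- gen_trajectory(n_frames = 2000, n_tethered = 3, tau_res = 0.8,
                         seed = 29)
  lt <- residence_lifetimes(traj, 3.0, 4.5)
  s <- lt$survival
  expect_equal(s$S[1], 1)          # everyone survives past the minimum
  expect_true(all(diff(s$S) <= 0)) # non-increasing
  expect_true(all(lt$lifetimes >= traj$dt))
})

test_that("telegraph-process dwell statistics recover the configured mean", {
  traj <- gen_trajectory(n_frames = 2500, dt = 0.1, n_tethered = 2,
                         tau_res = 2, seed = 37)
  lt <- residence_lifetimes(traj, 3.0, 4.5)
  expect_gt(length(lt$lifetimes), 50)
  expect_equal(lt$mean_lifetime, 2, tolerance = 0.2)
})
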