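# Readers and writers for the package's plain-text formats: NMRD
# profile CSV, titration CSV, decay CSV, CD CSV, annotated FASTA,
# multi-frame XYZ trajectories, and YAML/JSON model configs. CSV
# dialect: comma separator, '.' decimal, UTF-8, mandatory header.

read_csv_strict <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  for (col in intersect(c(required, optional), names(df))) {
    v <- df[[col]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("non-numeric cell in ", path, ", column '", col, "', row ", bad[1])
    df[[col]] <- v
  }
  df
}

#' Read / write an NMRD profile CSV
#'
#' Schema: header `freq_mhz,r1_mM_s[,r1_err]`, one row per frequency,
#' strictly increasing frequencies.
#'
#' @param path file path
#' @return [nmrd_profile()]
#' @export
read_profile <- function(path) {
  df <- read_csv_strict(path, c("freq_mhz", "r1_mM_s"), "r1_err")
  if (any(diff(df$freq_mhz) <= 0)) {
    bad <- which(diff(df$freq_mhz) <= 0)[1] + 1
    stop("frequencies not strictly increasing in ", path, " at row ", bad)
  }
  nmrd_profile(df$freq_mhz, df$r1_mM_s, df$r1_err,
               label = sub("\\.csv$", "", basename(path)))
}

#' @rdname read_profile
#' @param profile an [nmrd_profile()]
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "nmrd_profile"))
  df <- data.frame(freq_mhz = format(profile$freq_mhz, digits = 15),
                   r1_mM_s = format(profile$r1, digits = 15))
  if ("r1_err" %in% names(profile))
    df$r1_err <- format(profile$r1_err, digits = 15)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a titration CSV
#'
#' Schema: `metal_total_uM,signal[,competitor_total_uM,peptide_total_uM]`.
#' Missing peptide/competitor columns default to `peptide_total` and 0.
#'
#' @param path file path
#' @param peptide_total fallback peptide-site total, uM
#' @return [titration_series()]
#' @export
read_titration <- function(path, peptide_total = NA_real_) {
  df <- read_csv_strict(path, c("metal_total_uM", "signal"),
                        c("competitor_total_uM", "peptide_total_uM"))
  pt <- if ("peptide_total_uM" %in% names(df)) df$peptide_total_uM else
    peptide_total
  if (all(is.na(pt))) stop("peptide total absent from ", path,
                           " and no fallback given")
  ct <- if ("competitor_total_uM" %in% names(df)) df$competitor_total_uM else 0
  titration_series(df$metal_total_uM, df$signal, pt, ct)
}

#' @rdname read_titration
#' @param series a [titration_series()]
#' @export
write_titration <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  df <- data.frame(metal_total_uM = format(series$metal_total, digits = 15),
                   signal = format(series$signal, digits = 15),
                   competitor_total_uM = format(series$competitor_total,
                                                digits = 15),
                   peptide_total_uM = format(series$peptide_total, digits = 15))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a decay time-series CSV (`time_min,signal[,control]`)
#'
#' @param path file path
#' @return [decay_series()]
#' @export
read_decay <- function(path) {
  df <- read_csv_strict(path, c("time_min", "signal"), "control")
  decay_series(df$time_min, df$signal, df$control)
}

#' @rdname read_decay
#' @param series a [decay_series()]
#' @export
write_decay <- function(series, path) {
  stopifnot(inherits(series, "decay_series"))
  df <- data.frame(time_min = format(series$time_min, digits = 15),
                   signal = format(series$signal, digits = 15))
  if ("control" %in% names(series))
    df$control <- format(series$control, digits = 15)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an annotated FASTA of capped, cross-linked peptides
#'
#' Description-line tags after the identifier:
#' `XL=15` (comma-separated cross-linked Lys positions),
#' `NTERM=Ac`, `CTERM=NH2`.
#'
#' @param path file path
#' @return named list of [peptide_sequence()] objects
#' @export
read_peptides <- function(path) {
  lines <- readLines(path, warn = FALSE)
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no FASTA records in ", path)
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    seq_str <- gsub("\\s", "", paste(lines[from:to], collapse = ""))
    header <- trimws(sub("^>", "", lines[heads[i]]))
    parts <- strsplit(header, "\\s+")[[1]]
    id <- parts[1]
    tags <- parts[-1]
    tagval <- function(key) {
      hit <- grep(paste0("^", key, "="), tags, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA
    }
    xl <- tagval("XL")
    xl <- if (is.na(xl)) integer() else
      as.integer(strsplit(xl, "[,;]")[[1]])
    out[[id]] <- peptide_sequence(
      seq_str,
      n_term_cap = if (identical(tagval("NTERM"), "Ac")) "acetyl" else "none",
      c_term_cap = if (identical(tagval("CTERM"), "NH2")) "amide" else "none",
      crosslinked_positions = xl)
  }
  out
}

#' Read / write a multi-frame XYZ trajectory
#'
#' Standard XYZ: per frame an atom-count line, a comment line carrying
#' `t=<ns>`, then one `label x y z` line per atom. Atom counts must be
#' constant across frames and timestamps equally spaced.
#'
#' @param path file path
#' @param center_label,water_h_label selector prefixes (see
#'   [trajectory_frames()])
#' @return [trajectory_frames()]
#' @export
read_xyz_trajectory <- function(path, center_label = "GD",
                                water_h_label = "HW") {
  lines <- readLines(path, warn = FALSE)
  i <- 1
  frames <- list()
  times <- numeric(0)
  labels0 <- NULL
  fidx <- 0
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop("expected atom-count line at line ", i, " of ", path)
    nat <- as.integer(lines[i])
    fidx <- fidx + 1
    comment <- lines[i + 1]
    tm <- regmatches(comment, regexpr("t=\\s*[-0-9.eE+]+", comment))
    if (!length(tm))
      stop("frame ", fidx, ": comment line missing 't=' timestamp")
    times <- c(times, as.numeric(sub("t=\\s*", "", tm)))
    block <- lines[(i + 2):(i + 1 + nat)]
    if (length(block) < nat || any(is.na(block)))
      stop("frame ", fidx, ": truncated coordinate block")
    parts <- strsplit(trimws(block), "\\s+")
    if (any(lengths(parts) < 4))
      stop("frame ", fidx, ": malformed coordinate line")
    lab <- vapply(parts, `[`, character(1), 1)
    xyz <- t(vapply(parts, function(p)
      suppressWarnings(as.numeric(p[2:4])), numeric(3)))
    if (any(!is.finite(xyz)))
      stop("frame ", fidx, ": non-numeric coordinates")
    if (is.null(labels0)) labels0 <- lab
    else if (length(lab) != length(labels0))
      stop("inconsistent atom count at frame ", fidx)
    frames[[fidx]] <- xyz
    i <- i + 2 + nat
  }
  if (length(frames) >= 2) {
    dts <- diff(times)
    if (any(abs(dts - dts[1]) > 1e-9 * max(abs(dts[1]), 1e-12)))
      stop("timestamps are not equally spaced")
    dt <- dts[1]
  } else dt <- 1
  coords <- array(0, c(length(labels0), 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  trajectory_frames(coords, labels0, dt, center_label, water_h_label)
}

#' @rdname read_xyz_trajectory
#' @param traj a [trajectory_frames()]
#' @param digits coordinate precision
#' @export
write_xyz_trajectory <- function(traj, path, digits = 6) {
  stopifnot(inherits(traj, "trajectory_frames"))
  con <- file(path, "w")
  on.exit(close(con))
  nat <- dim(traj$coords)[1]
  for (f in seq_len(n_frames(traj))) {
    writeLines(as.character(nat), con)
    writeLines(sprintf("t=%.9g", (f - 1) * traj$dt), con)
    writeLines(sprintf("%s %.*f %.*f %.*f", traj$labels,
                       digits, traj$coords[, 1, f],
                       digits, traj$coords[, 2, f],
                       digits, traj$coords[, 3, f]), con)
  }
  invisible(path)
}

#' Read a relaxivity model from a YAML/JSON config
#'
#' Keys mirror the parameter constructors, with explicit units:
#' `q_ss`, `r_ss_A`, `tau_M_ss_ns`, `tau_RG_ns`, `tau_RL_ps`, `S2`,
#' `a_A`, `D_m2s`, `delta2_s2`, `tau_v_ps`, `g`, `S`. Unknown keys are
#' rejected.
#'
#' @param path YAML (or JSON) file
#' @return a [relaxation_model()]
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("q_ss", "r_ss_A", "tau_M_ss_ns", "tau_RG_ns", "tau_RL_ps", "S2",
             "a_A", "D_m2s", "delta2_s2", "tau_v_ps", "g", "S",
             "temperature_K")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  # YAML 1.1 reads exponent literals without a sign (1.0e19) as strings
  pick <- function(key, default) {
    v <- cfg[[key]]
    if (is.null(v)) return(default)
    v <- suppressWarnings(as.numeric(v))
    if (!is.finite(v)) stop("non-numeric value for config key '", key, "'")
    v
  }
  relaxation_model(
    second_sphere_params(
      q_ss = pick("q_ss", 2),
      r_ss_A = pick("r_ss_A", 3.6),
      tau_M_ss = pick("tau_M_ss_ns", 5.0) * 1e-9,
      tau_RG = pick("tau_RG_ns", 7) * 1e-9,
      tau_RL = pick("tau_RL_ps", 318) * 1e-12,
      S2 = pick("S2", 0.5)),
    outer_sphere_params(a_A = pick("a_A", 4), D = pick("D_m2s", 2.3e-10)),
    electron_spin_params(delta2 = pick("delta2_s2", 1e19),
                         tau_v = pick("tau_v_ps", 20) * 1e-12,
                         g = pick("g", 2), S = pick("S", 3.5)),
    temperature = pick("temperature_K", 298))
}
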