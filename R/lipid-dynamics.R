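#' Lateral mean squared displacement of a lipid species
#'
#' 2-D (xy) MSD averaged over all time origins and all molecules of the
#' species: `MSD(t) = <|r(t0 + t) - r(t0)|^2>` with `r` the molecular
#' centre of geometry.  Coordinates are unwrapped by frame-to-frame
#' minimum-image continuity before analysis (assumes no molecule moves
#' more than half a box edge per frame), and the species-set centre of
#' mass is subtracted per frame to remove collective drift.  Lags run to
#' half the trajectory length.  The multiple-origin average is computed
#' with the FFT autocorrelation identity, which is exactly equivalent to
#' the quadratic-time double loop.
#'
#' @param traj a [trajectory].
#' @param species species name.
#' @param use_com remove the species-set centre-of-mass drift per frame
#'   (skipped with a warning when only one molecule is present, which
#'   would zero the signal).
#' @return an `msd_series`: `lags` (ns), `msd` (nm^2), `n_pairs` per lag,
#'   `species`.
#' @export
msd <- function(traj, species, use_com = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (nf < 2) stop("msd needs at least 2 frames")
  idx <- select_particles(traj, species = species)
  if (!length(idx)) stop("species not present: ", species)
  un <- unwrap_trajectory(traj$coords[idx, , , drop = FALSE], traj$box)
  mol <- traj$topology$particles$molecule_id[idx]
  ids <- sort(unique(mol))
  n_mol <- length(ids)
  # molecular centre of geometry per frame, x and y only
  fmol <- factor(mol, levels = ids)
  cnt <- as.vector(table(fmol))
  comx <- sapply(seq_len(nf), function(f)
    rowsum(un[, 1, f], fmol) / cnt)
  comy <- sapply(seq_len(nf), function(f)
    rowsum(un[, 2, f], fmol) / cnt)
  comx <- matrix(comx, n_mol, nf)
  comy <- matrix(comy, n_mol, nf)
  if (use_com) {
    if (n_mol < 2) {
      warning("single molecule: centre-of-mass drift removal skipped")
    } else {
      comx <- sweep(comx, 2, colMeans(comx))
      comy <- sweep(comy, 2, colMeans(comy))
    }
  }
  max_lag <- floor(nf / 2)
  acc <- numeric(max_lag + 1)
  for (m in seq_len(n_mol)) {
    acc <- acc + msd_fft(comx[m, ])[seq_len(max_lag + 1)] +
                 msd_fft(comy[m, ])[seq_len(max_lag + 1)]
  }
  lag_idx <- 0:max_lag
  dt <- traj$times[2] - traj$times[1]
  structure(list(lags = lag_idx * dt, msd = acc / n_mol,
                 n_pairs = (nf - lag_idx) * n_mol, species = species),
            class = "msd_series")
}

# Multiple-origin 1-D MSD for all lags 0..n-1 via the FFT
# autocorrelation identity:
#   msd(m) = [ sum_k (x_k^2 + x_{k+m}^2) - 2 sum_k x_k x_{k+m} ] / (n - m)
msd_fft <- function(x) {
  n <- length(x)
  fx <- stats::fft(c(x, numeric(n)))
  s2 <- Re(stats::fft(fx * Conj(fx), inverse = TRUE))[seq_len(n)] / (2 * n)
  d <- x^2
  q <- 2 * sum(d)
  s1 <- numeric(n)
  s1[1] <- q
  for (m in seq_len(n - 1)) {
    q <- q - d[m] - d[n - m + 1]
    s1[m + 1] <- q
  }
  (s1 - 2 * s2) / (n - seq_len(n) + 1)
}

# Quadratic-time reference estimator (explicit lag loop); test oracle.
msd_direct <- function(x, max_lag = length(x) - 1) {
  n <- length(x)
  vapply(0:max_lag, function(m) {
    if (m == 0) return(0)
    mean((x[(m + 1):n] - x[seq_len(n - m)])^2)
  }, numeric(1))
}

#' @export
print.msd_series <- function(x, ...) {
  cat(sprintf("MSD of %s: %d lags up to %.3g ns, msd(max) = %.4g nm^2\n",
              x$species, length(x$lags), max(x$lags), x$msd[length(x$msd)]))
  invisible(x)
}

#' Fit the Einstein relation to an MSD curve
#'
#' Ordinary least squares of `msd = 4*D*t + c` over a lag window given
#' as fractions of the maximum lag (default 10-50%, avoiding origin
#' noise and the poorly averaged tail).  `D = slope/4` (2-D lateral
#' convention); a negative estimate is reported and flagged, never
#' suppressed.
#'
#' @param series an `msd_series`.
#' @param window length-2 numeric, fractions of the maximum lag.
#' @return a `diffusion_fit`: `D` (nm^2/ns), `D_um2_s` (mirror, factor
#'   1000), `intercept` (nm^2), `stderr`, `window` (ns), `negative` flag.
#' @export
fit_diffusion <- function(series, window = c(0.1, 0.5)) {
  stopifnot(inherits(series, "msd_series"), length(window) == 2,
            window[1] < window[2], window[1] >= 0, window[2] <= 1)
  lmax <- max(series$lags)
  keep <- series$lags >= window[1] * lmax & series$lags <= window[2] * lmax
  if (sum(keep) < 3) stop("fewer than 3 MSD points in the fit window")
  fit <- stats::lm(y ~ t, data = data.frame(t = series$lags[keep],
                                            y = series$msd[keep]))
  co <- suppressWarnings(summary(fit))$coefficients  # exact lines are legal
  D <- co["t", "Estimate"] / 4
  se <- co["t", "Std. Error"] / 4
  structure(list(D = D, D_um2_s = D * 1000, intercept = co[1, 1],
                 stderr = se, window = range(series$lags[keep]),
                 species = series$species, negative = D < 0),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf(
    "D(%s) = %.4g nm^2/ns (%.4g um^2/s) +/- %.2g, window [%.3g, %.3g] ns%s\n",
    x$species, x$D, x$D_um2_s, x$stderr, x$window[1], x$window[2],
    if (x$negative) "  [NEGATIVE: no diffusive regime]" else ""))
  invisible(x)
}

#' Assign molecules to leaflets by reference-bead z
#'
#' Centres the frame at the mean z of all reference beads and
#' labels each molecule `upper`/`lower` by the sign of its z; molecules
#' within the dead band `|z| < dead_band` are labelled `midplane` and
#' excluded from leaflet counts.
#'
#' @param traj a [trajectory] (first frame used unless `frame` given).
#' @param species optional species subset.
#' @param frame frame index.
#' @param ref_bead reference bead label (default `"GL1"`).
#' @param dead_band nm (default 0.3).
#' @return named character vector: molecule id -> `"upper"`, `"lower"`
#'   or `"midplane"`.
#' @export
assign_leaflets <- function(traj, species = NULL, frame = 1,
                            ref_bead = "GL1", dead_band = 0.3) {
  stopifnot(inherits(traj, "trajectory"))
  all_ref <- select_particles(traj, bead = ref_bead)
  mid <- mean(traj$coords[all_ref, 3, frame])
  idx <- select_particles(traj, species = species, bead = ref_bead)
  z <- traj$coords[idx, 3, frame] - mid
  lab <- ifelse(abs(z) < dead_band, "midplane",
                ifelse(z > 0, "upper", "lower"))
  stats::setNames(lab, traj$topology$particles$molecule_id[idx])
}

#' Detect lipid flip-flop events along the membrane normal
#'
#' Membrane-crossing events counted with a two-threshold hysteresis
#' rule: a molecule established in the upper leaflet (z above
#' `+hysteresis_z`, relative to the per-frame midplane) generates one
#' event when its z later drops below `-hysteresis_z`, and vice versa.
#' Excursions that re-cross the midplane without reaching the far
#' threshold are not counted, so dwell noise near the midplane cannot
#' inflate the count.
#'
#' @param traj a [trajectory].
#' @param species species to monitor.
#' @param hysteresis_z threshold distance from the midplane, nm
#'   (default 0.5).
#' @param ref_bead reference bead (default `"GL1"`).
#' @return a `flipflop_events`: `events` data.frame (molecule_id,
#'   time_ns, direction), `total`, `rate_per_us` (per membrane),
#'   `rate_per_us_per_molecule`, `n_molecules`, `hysteresis_z`.
#' @export
detect_flipflops <- function(traj, species, hysteresis_z = 0.5,
                             ref_bead = "GL1") {
  stopifnot(inherits(traj, "trajectory"), hysteresis_z > 0)
  idx <- select_particles(traj, species = species, bead = ref_bead)
  if (!length(idx)) stop("species not present: ", species)
  all_ref <- select_particles(traj, bead = ref_bead)
  nf <- n_frames(traj)
  mid <- vapply(seq_len(nf), function(f)
    mean(traj$coords[all_ref, 3, f]), numeric(1))
  z <- matrix(traj$coords[idx, 3, ], length(idx), nf)
  z <- sweep(z, 2, mid)
  # membrane extent from every reference bead, not just the monitored
  # species: sub-threshold excursions of one species are legal (0 events)
  z_all <- sweep(matrix(traj$coords[all_ref, 3, ], length(all_ref), nf),
                 2, mid)
  if (hysteresis_z >= max(abs(z_all)))
    stop("thresholds outside membrane: hysteresis_z >= max |z|")
  mols <- traj$topology$particles$molecule_id[idx]
  ev <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    res <- flip_state_machine(z[i, ], hysteresis_z)
    if (length(res$frames))
      ev[[i]] <- data.frame(molecule_id = mols[i],
                            time_ns = traj$times[res$frames],
                            direction = res$direction)
  }
  ev <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
  if (is.null(ev))
    ev <- data.frame(molecule_id = integer(0), time_ns = numeric(0),
                     direction = character(0))
  total <- nrow(ev)
  span_us <- (traj$times[nf] - traj$times[1]) / 1000
  structure(list(events = ev, total = total,
                 rate_per_us = if (span_us > 0) total / span_us else NA_real_,
                 rate_per_us_per_molecule =
                   if (span_us > 0) total / span_us / length(idx) else NA_real_,
                 n_molecules = length(idx), species = species,
                 hysteresis_z = hysteresis_z),
            class = "flipflop_events")
}

# Two-threshold state machine over one z path.  States: +1 (upper),
# -1 (lower), 0 (undetermined until |z| first exceeds the threshold).
flip_state_machine <- function(z, h) {
  state <- 0
  frames <- integer(0); direction <- character(0)
  for (t in seq_along(z)) {
    if (z[t] > h) {
      if (state == -1) {
        frames <- c(frames, t); direction <- c(direction, "lower_to_upper")
      }
      state <- 1
    } else if (z[t] < -h) {
      if (state == 1) {
        frames <- c(frames, t); direction <- c(direction, "upper_to_lower")
      }
      state <- -1
    }
  }
  list(frames = frames, direction = direction)
}

#' @export
print.flipflop_events <- function(x, ...) {
  cat(sprintf(
    "Flip-flop (%s): %d events, %.3g /us per membrane, %.3g /us per molecule (%d molecules, |z| > %.2f nm)\n",
    x$species, x$total, x$rate_per_us, x$rate_per_us_per_molecule,
    x$n_molecules, x$hysteresis_z))
  invisible(x)
}
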