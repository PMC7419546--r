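#' Per-frame area per lipid
#'
#' Surface area per lipid: the lateral box area divided by the number of
#' lipids per leaflet, per frame.  The summary mean carries a standard
#' error from block averaging (5 blocks).
#'
#' @param traj a [trajectory] with an orthorhombic box.
#' @param N_per_leaflet lipids per leaflet; taken from the topology's
#'   leaflet hints when missing.
#' @param temperature K, stored for downstream compressibility.
#' @return an `area_series`: list with `times`, `per_lipid_area` (nm^2),
#'   `N_per_leaflet`, `temperature`, `mean`, `se`, and possibly
#'   `warnings` in `meta`.
#' @export
area_per_lipid <- function(traj, N_per_leaflet = NULL, temperature = 293) {
  stopifnot(inherits(traj, "trajectory"))
  meta <- list()
  if (is.null(N_per_leaflet)) {
    hints <- traj$topology$molecules$leaflet
    if (all(is.na(hints)))
      stop("leaflet count unknown: supply N_per_leaflet or leaflet hints")
    tab <- table(hints[!is.na(hints)])
    if (length(tab) != 2)
      stop("expected two leaflets in topology hints, found ", length(tab))
    if (abs(diff(range(tab))) / max(tab) > 0.10)
      meta$warnings <- sprintf(
        "leaflets unequal beyond 10%%: %s", paste(tab, collapse = " vs "))
    N_per_leaflet <- round(mean(tab))
  }
  a <- traj$box[, 1] * traj$box[, 2] / N_per_leaflet
  area_series(traj$times, a, N_per_leaflet, temperature, meta)
}

area_series <- function(times, per_lipid_area, N_per_leaflet, temperature,
                        meta = list()) {
  stopifnot(all(per_lipid_area > 0),
            length(times) == length(per_lipid_area))
  blocks <- block_means(per_lipid_area, 5L)
  structure(list(times = times, per_lipid_area = per_lipid_area,
                 N_per_leaflet = N_per_leaflet, temperature = temperature,
                 mean = mean(per_lipid_area),
                 se = if (length(blocks) > 1)
                        stats::sd(blocks) / sqrt(length(blocks)) else 0,
                 meta = meta),
            class = "area_series")
}

#' @export
print.area_series <- function(x, ...) {
  cat(sprintf("Area per lipid: %.4f +/- %.4f nm^2 (%d frames, N = %d/leaflet)\n",
              x$mean, x$se, length(x$per_lipid_area), x$N_per_leaflet))
  invisible(x)
}

block_means <- function(x, n_blocks) {
  n <- length(x)
  if (n < n_blocks) return(mean(x))
  idx <- ceiling(seq_along(x) / (n / n_blocks))
  as.numeric(tapply(x, idx, mean))
}

#' Area compressibility modulus from area fluctuations
#'
#' `K_A = kB * T * A0 / (N * <(A - A0)^2>)` with `A0` the sample mean
#' per-lipid area and `N` the number of lipids per leaflet, converted to
#' mN/m (1 J/nm^2 = 1e21 mN/m).  The standard error is a 5-block
#' delete-one jackknife.
#'
#' @param series an `area_series` from [area_per_lipid] or
#'   [gen_area_series] with at least 100 frames.
#' @return list with `KA` (mN/m), `se`, `A0` (nm^2), `var_A` (nm^4),
#'   `N`, `temperature`; class `compressibility_fit`.
#' @export
compressibility <- function(series) {
  stopifnot(inherits(series, "area_series"))
  a <- series$per_lipid_area
  if (length(a) < 100) stop("compressibility needs >= 100 frames")
  A0 <- mean(a)
  v <- mean((a - A0)^2)
  if (v < 1e-15) stop("degenerate fluctuation series (variance < 1e-15 nm^4)")
  ka_of <- function(x) {
    m <- mean(x)
    .kB * series$temperature * m / (series$N_per_leaflet * mean((x - m)^2)) *
      .J_PER_NM2_TO_MN_PER_M
  }
  KA <- ka_of(a)
  # delete-one-block jackknife over 5 contiguous blocks
  nb <- 5L
  idx <- ceiling(seq_along(a) / (length(a) / nb))
  loo <- vapply(seq_len(nb), function(b) ka_of(a[idx != b]), numeric(1))
  se <- sqrt((nb - 1) / nb * sum((loo - mean(loo))^2))
  structure(list(KA = KA, se = se, A0 = A0, var_A = v,
                 N = series$N_per_leaflet, temperature = series$temperature),
            class = "compressibility_fit")
}

#' @export
print.compressibility_fit <- function(x, ...) {
  cat(sprintf("K_A = %.1f +/- %.1f mN/m  (A0 = %.4f nm^2, N = %d, T = %g K)\n",
              x$KA, x$se, x$A0, x$N, x$temperature))
  invisible(x)
}

#' Number density profile along the membrane normal
#'
#' Time-averaged histogram of particle z-positions, normalised by bin
#' volume and frame count.  Frames are centred so the bilayer midplane
#' (mean z of the selected particles, per frame) sits at z = 0.
#'
#' @param traj a [trajectory].
#' @param selection particle indices (default: all particles).
#' @param bin_width nm (default 0.1).
#' @param center centre each frame at the mean z (default TRUE).
#' @return a `density_profile`: `z` (bin centres, nm), `density`
#'   (particles/nm^3), `bin_width`, `n_frames`, `selection_size`.
#' @export
density_profile <- function(traj, selection = NULL, bin_width = 0.1,
                            center = TRUE) {
  stopifnot(inherits(traj, "trajectory"), bin_width > 0)
  if (is.null(selection)) selection <- seq_len(nrow(traj$topology$particles))
  if (!length(selection)) stop("empty selection")
  nf <- n_frames(traj)
  zs <- lapply(seq_len(nf), function(f) {
    z <- traj$coords[selection, 3, f]
    if (center) z - mean(z) else z
  })
  allz <- unlist(zs)
  half <- max(abs(allz)) + bin_width
  breaks <- seq(-ceiling(half / bin_width) * bin_width,
                ceiling(half / bin_width) * bin_width, by = bin_width)
  counts <- hist(allz, breaks = breaks, plot = FALSE)$counts
  area_xy <- mean(traj$box[, 1] * traj$box[, 2])
  dens <- counts / (nf * area_xy * bin_width)
  structure(list(z = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 density = dens, bin_width = bin_width, n_frames = nf,
                 selection_size = length(selection), area_xy = area_xy),
            class = "density_profile")
}

#' Bilayer thickness from a density profile
#'
#' The distance between the density maxima of the two leaflets, i.e.
#' between the argmax over z > 0 and the argmax over z < 0 (leaflets
#' split at z = 0).  With `interpolate = TRUE` each peak position is
#' refined by a quadratic fit through the peak bin and its neighbours.
#'
#' @param profile a `density_profile`.
#' @param interpolate refine peaks by quadratic interpolation.
#' @return list with `thickness` (nm), `z_upper`, `z_lower`,
#'   `interpolated` flag; class `thickness_result`.
#' @export
thickness <- function(profile, interpolate = FALSE) {
  stopifnot(inherits(profile, "density_profile"))
  z <- profile$z; d <- profile$density
  up <- which(z > 0); lo <- which(z < 0)
  if (!length(up) || !length(lo) || all(d[up] == 0) || all(d[lo] == 0))
    stop("no bilayer signature: need density maxima on both sides of z = 0")
  iu <- up[which.max(d[up])]
  il <- lo[which.max(d[lo])]
  # unimodal guard: the two peaks must be distinct maxima, not one
  # central mode spilling over z = 0
  mid <- (d[iu] + d[il]) / 2
  between <- d[z > z[il] & z < z[iu]]
  if (!length(between) || min(between) >= 0.95 * mid)
    stop("no bilayer signature: profile is unimodal about z = 0")
  zu <- z[iu]; zl <- z[il]
  if (interpolate) {
    zu <- quad_peak(z, d, iu)
    zl <- quad_peak(z, d, il)
  }
  structure(list(thickness = zu - zl, z_upper = zu, z_lower = zl,
                 interpolated = interpolate),
            class = "thickness_result")
}

quad_peak <- function(z, d, i) {
  if (i <= 1 || i >= length(z)) return(z[i])
  y1 <- d[i - 1]; y2 <- d[i]; y3 <- d[i + 1]
  den <- y1 - 2 * y2 + y3
  if (abs(den) < 1e-30) return(z[i])
  z[i] + 0.5 * (y1 - y3) / den * (z[2] - z[1])
}

#' @export
print.thickness_result <- function(x, ...) {
  cat(sprintf("Bilayer thickness d = %.3f nm (peaks at %.3f / %.3f nm%s)\n",
              x$thickness, x$z_upper, x$z_lower,
              if (x$interpolated) ", quadratic-interpolated" else ""))
  invisible(x)
}
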