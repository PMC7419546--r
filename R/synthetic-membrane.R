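#' Specification of a synthetic bilayer trajectory
#'
#' Defines the ground truth for [gen_bilayer_trajectory]: a two-leaflet
#' bilayer whose lipids perform independent 2-D Brownian lateral motion,
#' whose per-lipid area fluctuates as a Gaussian consistent with a target
#' area compressibility modulus, whose leaflet z-positions are Gaussian
#' around +/- thickness/2, and in which one designated species may
#' flip-flop between leaflets as a two-state Markov process.
#'
#' @param composition a [membrane_composition].
#' @param n_lipids_per_leaflet lipids per leaflet (default 100).
#' @param box_xy lateral box edge (nm); must satisfy
#'   `box_xy^2 = n_lipids_per_leaflet * A0_true` within 5%.  Defaults to
#'   the consistent value `sqrt(n * A0_true)`.
#' @param temperature K (default 293, the CG production temperature).
#' @param n_frames number of frames.
#' @param dt frame spacing (ns).
#' @param D_true named per-species lateral diffusion coefficients
#'   (nm^2/ns); unnamed scalar recycled to all species.
#' @param A0_true mean area per lipid (nm^2).
#' @param KA_true area compressibility modulus (mN/m).
#' @param flip_species species name undergoing flip-flop, or `NULL`.
#' @param flip_rate_true flip events per microsecond per molecule.
#' @param thickness_true bilayer thickness: distance between leaflet
#'   reference-bead planes (nm).
#' @param leaflet_z_sigma Gaussian z spread of the reference beads about
#'   the leaflet plane (nm).
#' @param layout_mode `"uniform"` or `"clustered"` initial lateral layout.
#' @param cluster_params list passed to [gen_lateral_layout] in clustered
#'   mode: `species`, `parent_intensity` (parents per nm^2), `radius`
#'   (nm), `mean_children`.
#' @param seed integer seed; all generator randomness derives from it.
#' @return an object of class `membrane_spec`.
#' @export
membrane_spec <- function(composition,
                          n_lipids_per_leaflet = 100L,
                          box_xy = NULL,
                          temperature = 293,
                          n_frames = 1000L,
                          dt = 0.1,
                          D_true = 0.03,
                          A0_true = 0.64,
                          KA_true = 400,
                          flip_species = NULL,
                          flip_rate_true = 0,
                          thickness_true = 2.9,
                          leaflet_z_sigma = 0.3,
                          layout_mode = c("uniform", "clustered"),
                          cluster_params = NULL,
                          seed = 1L) {
  stopifnot(inherits(composition, "membrane_composition"))
  layout_mode <- match.arg(layout_mode)
  n <- as.integer(n_lipids_per_leaflet)
  if (is.null(box_xy)) box_xy <- sqrt(n * A0_true)
  pos <- c(n_lipids_per_leaflet = n, temperature = temperature,
           n_frames = n_frames, dt = dt, A0_true = A0_true,
           KA_true = KA_true, thickness_true = thickness_true,
           leaflet_z_sigma = leaflet_z_sigma, box_xy = box_xy)
  if (any(pos <= 0))
    stop("all rates, lengths and counts must be strictly positive; bad: ",
         paste(names(pos)[pos <= 0], collapse = ", "))
  if (is.null(names(D_true))) {
    if (length(D_true) != 1)
      stop("D_true must be a named vector or a single value")
    D_true <- stats::setNames(rep(D_true, length(composition)),
                              names(composition))
  }
  if (!all(names(composition) %in% names(D_true)))
    stop("D_true must cover every species in the composition")
  if (any(D_true < 0)) stop("diffusion coefficients must be >= 0")
  rel <- abs(box_xy^2 - n * A0_true) / (n * A0_true)
  if (rel > 0.05)
    stop(sprintf(
      "box_xy^2 = %.3f nm^2 deviates from n_lipids_per_leaflet * A0_true = %.3f nm^2 by %.1f%% (bound: 5%%)",
      box_xy^2, n * A0_true, 100 * rel))
  if (!is.null(flip_species)) {
    if (!flip_species %in% names(composition))
      stop("flip_species not present in composition")
    if (flip_rate_true <= 0)
      stop("flip_rate_true must be > 0 when flip_species is set")
  }
  structure(list(
    composition = composition, n_lipids_per_leaflet = n, box_xy = box_xy,
    temperature = temperature, n_frames = as.integer(n_frames), dt = dt,
    D_true = D_true, A0_true = A0_true, KA_true = KA_true,
    flip_species = flip_species, flip_rate_true = flip_rate_true,
    thickness_true = thickness_true, leaflet_z_sigma = leaflet_z_sigma,
    layout_mode = layout_mode, cluster_params = cluster_params,
    seed = as.integer(seed)), class = "membrane_spec")
}

#' Gaussian per-lipid area series with a known compressibility modulus
#'
#' Draws i.i.d. Gaussian per-lipid areas with mean `A0` and variance
#' `kB*T*A0 / (N*KA)` (units reconciled: 1 J/nm^2 = 1e21 mN/m), the
#' equilibrium fluctuation implied by an area compressibility modulus
#' `KA` for a patch of `N` lipids per leaflet at temperature `T`.
#'
#' @param A0 mean area per lipid (nm^2).
#' @param KA area compressibility modulus (mN/m).
#' @param N lipids per leaflet.
#' @param T_K temperature (K).
#' @param n_frames number of frames.
#' @param dt frame spacing (ns).
#' @param seed integer seed.
#' @return an object of class `area_series` (see [area_per_lipid]).
#' @export
gen_area_series <- function(A0, KA, N, T_K = 293, n_frames = 1000L,
                            dt = 0.1, seed = 1L) {
  stopifnot(A0 > 0, KA > 0, N > 0, T_K > 0, n_frames > 0, dt > 0)
  sd_A <- sqrt(.kB * T_K * A0 / (N * KA / .J_PER_NM2_TO_MN_PER_M))
  set.seed(seed)
  a <- stats::rnorm(n_frames, mean = A0, sd = sd_A)
  area_series(times = (seq_len(n_frames) - 1) * dt, per_lipid_area = a,
              N_per_leaflet = N, temperature = T_K)
}

#' Generate a single-frame lateral layout of labelled lipids
#'
#' Uniform mode scatters all lipids as a binomial point process in the
#' periodic patch.  Clustered mode places the designated species by a
#' Matern cluster process -- Poisson-distributed parent points, children
#' uniform in a disc of `radius` around a parent -- and the remaining
#' species uniformly; the number of points per species is fixed exactly
#' by largest-remainder apportionment of the composition.
#'
#' @param composition a [membrane_composition].
#' @param n total number of lipids (>= 2).
#' @param box_xy lateral box edge (nm).
#' @param mode `"uniform"` or `"clustered"`.
#' @param cluster_params list with `species` (character; which species
#'   cluster), `parent_intensity` (parents per nm^2), `radius` (disc
#'   radius, nm), `mean_children` (informs the default parent count).
#' @param seed integer seed.
#' @return a one-frame [trajectory] of GL1 beads at z = 0, one molecule
#'   per lipid, with species labels in the topology.
#' @export
gen_lateral_layout <- function(composition, n, box_xy,
                               mode = c("uniform", "clustered"),
                               cluster_params = NULL, seed = 1L) {
  stopifnot(inherits(composition, "membrane_composition"), n >= 2)
  mode <- match.arg(mode)
  set.seed(seed)
  counts <- species_counts(composition, n)
  species <- rep(names(counts), counts)
  xy <- matrix(stats::runif(2 * n, 0, box_xy), n, 2)
  if (mode == "clustered") {
    cp <- cluster_params
    if (is.null(cp) || is.null(cp$species) || is.null(cp$radius))
      stop("clustered mode needs cluster_params with species and radius")
    if (cp$radius >= box_xy / 2)
      stop("cluster_radius >= box_xy/2: cluster not resolvable under minimum image")
    idx <- which(species %in% cp$species)
    n_clu <- length(idx)
    if (n_clu) {
      n_parents <- if (!is.null(cp$parent_intensity)) {
        max(1L, stats::rpois(1, cp$parent_intensity * box_xy^2))
      } else {
        max(1L, round(n_clu / max(1, cp$mean_children)))
      }
      parents <- matrix(stats::runif(2 * n_parents, 0, box_xy), n_parents, 2)
      assign <- sample.int(n_parents, n_clu, replace = TRUE)
      r <- cp$radius * sqrt(stats::runif(n_clu))
      th <- stats::runif(n_clu, 0, 2 * pi)
      pts <- parents[assign, , drop = FALSE] + cbind(r * cos(th), r * sin(th))
      xy[idx, ] <- pts - floor(pts / box_xy) * box_xy
    }
  }
  layout_frame(xy, species, box_xy)
}

# assemble a one-frame GL1-only trajectory from xy points + species labels
layout_frame <- function(xy, species, box_xy, box_z = 8) {
  n <- nrow(xy)
  top <- topology(
    data.frame(particle_id = seq_len(n), bead = "GL1",
               molecule_id = seq_len(n)),
    data.frame(molecule_id = seq_len(n), species = species,
               leaflet = "upper"))
  coords <- array(0, c(n, 3, 1))
  coords[, 1:2, 1] <- xy
  coords[, 3, 1] <- box_z / 2   # mid-height of the box; z plays no role
  trajectory(top, coords, 0, c(box_xy, box_xy, box_z))
}

#' Generate a synthetic bilayer trajectory with known ground truth
#'
#' Builds a two-leaflet bilayer trajectory per a [membrane_spec]:
#' \itemize{
#'   \item each lipid carries a `GL1` reference bead plus one auxiliary
#'     tail bead (`C1A`) displaced toward the bilayer midplane;
#'   \item lateral positions evolve as independent 2-D Brownian steps of
#'     per-axis variance `2*D_true*dt`, wrapped into the periodic box;
#'   \item each frame's per-lipid area is Gaussian with mean `A0_true`
#'     and the equilibrium variance implied by `KA_true`; the box (and
#'     the lateral coordinates) are rescaled isotropically in xy, z fixed;
#'   \item z-coordinates are `+/- thickness_true/2` plus Gaussian noise of
#'     sd `leaflet_z_sigma`;
#'   \item if `flip_species` is set, those molecules switch leaflets as a
#'     two-state Markov process with per-molecule rate `flip_rate_true`
#'     (events/us), z relaxing to the new leaflet within one frame;
#'   \item per-leaflet species counts follow the composition with
#'     largest-remainder rounding.
#' }
#'
#' Ground truth is attached as attribute `"truth"`: per-frame leaflet
#' assignments (`n_molecules x n_frames` matrix of +1/-1), per-molecule
#' flip counts, and the spec itself.
#'
#' @param spec a [membrane_spec].
#' @return a [trajectory] with `attr(, "truth")`.
#' @export
gen_bilayer_trajectory <- function(spec) {
  stopifnot(inherits(spec, "membrane_spec"))
  set.seed(spec$seed)
  n <- spec$n_lipids_per_leaflet
  counts <- species_counts(spec$composition, n)
  species_leaf <- rep(names(counts), counts)
  n_mol <- 2L * n
  species <- c(species_leaf, species_leaf)
  leaflet0 <- rep(c(1, -1), each = n)       # +1 upper, -1 lower
  nf <- spec$n_frames
  L0 <- sqrt(n * spec$A0_true)              # reference lateral box edge
  box_z <- spec$thickness_true + 6 * spec$leaflet_z_sigma + 2

  # per-frame per-lipid area -> per-frame box edge (isotropic xy rescale)
  sd_A <- sqrt(.kB * spec$temperature * spec$A0_true /
                 (n * spec$KA_true / .J_PER_NM2_TO_MN_PER_M))
  A_t <- stats::rnorm(nf, spec$A0_true, sd_A)
  L_t <- sqrt(pmax(A_t, 1e-12) * n)

  # initial lateral layout in the reference box, one point process per
  # leaflet; layout species labels equal species_leaf (same counts)
  lay_u <- gen_lateral_layout(spec$composition, n, L0,
                              mode = spec$layout_mode,
                              cluster_params = spec$cluster_params,
                              seed = spec$seed + 1L)
  lay_l <- gen_lateral_layout(spec$composition, n, L0,
                              mode = spec$layout_mode,
                              cluster_params = spec$cluster_params,
                              seed = spec$seed + 2L)
  set.seed(spec$seed + 3L)   # layout calls reset the stream; re-arm it
  xy <- rbind(matrix(lay_u$coords[, 1:2, 1], ncol = 2),
              matrix(lay_l$coords[, 1:2, 1], ncol = 2))

  # Brownian lateral paths in the reference box (fractional motion),
  # wrapped; per-axis step sd by species
  sd_step <- sqrt(2 * spec$D_true[species] * spec$dt)
  frac <- array(NA_real_, c(n_mol, 2, nf))
  frac[, , 1] <- xy
  if (nf > 1) {
    for (f in 2:nf) {
      step <- matrix(stats::rnorm(2 * n_mol, 0, sd_step), n_mol, 2)
      p <- frac[, , f - 1] + step
      frac[, , f] <- p - floor(p / L0) * L0
    }
  }

  # leaflet state over time (Markov flips for the designated species)
  leaf <- matrix(leaflet0, n_mol, nf)
  flips <- integer(n_mol)
  if (!is.null(spec$flip_species) && nf > 1) {
    idx <- which(species == spec$flip_species)
    p_flip <- 1 - exp(-(spec$flip_rate_true / 1000) * spec$dt) # rate /us -> /ns
    for (f in 2:nf) {
      do_flip <- stats::runif(length(idx)) < p_flip
      # leaf[, f] was initialised to the f-1 recursion's value for
      # non-flipping rows; flipping rows are set frame by frame
      leaf[idx, f] <- ifelse(do_flip, -leaf[idx, f - 1], leaf[idx, f - 1])
      flips[idx] <- flips[idx] + do_flip
    }
  }

  # z: leaflet plane +/- thickness/2 plus Gaussian spread, fresh each frame
  z_gl1 <- leaf * spec$thickness_true / 2 +
    matrix(stats::rnorm(n_mol * nf, 0, spec$leaflet_z_sigma), n_mol, nf)
  z_gl1 <- z_gl1 + box_z / 2                 # midplane at box centre
  # auxiliary tail bead sits 0.3 nm toward the midplane
  z_aux <- z_gl1 - leaf * 0.3

  top <- topology(
    data.frame(particle_id = seq_len(2L * n_mol),
               bead = rep(c("GL1", "C1A"), n_mol),
               molecule_id = rep(seq_len(n_mol), each = 2L)),
    data.frame(molecule_id = seq_len(n_mol), species = species,
               leaflet = ifelse(leaflet0 > 0, "upper", "lower")))
  coords <- array(NA_real_, c(2L * n_mol, 3, nf))
  gi <- seq(1L, 2L * n_mol, by = 2L)         # GL1 rows
  ai <- gi + 1L                              # aux rows
  for (f in seq_len(nf)) {
    s <- L_t[f] / L0
    coords[gi, 1:2, f] <- frac[, , f] * s
    coords[ai, 1:2, f] <- frac[, , f] * s
    coords[gi, 3, f] <- z_gl1[, f]
    coords[ai, 3, f] <- z_aux[, f]
  }
  traj <- trajectory(top, coords, (seq_len(nf) - 1) * spec$dt,
                     cbind(L_t, L_t, box_z))
  attr(traj, "truth") <- list(spec = spec, leaflet = leaf,
                              flips = flips, box_z = box_z,
                              midplane_z = box_z / 2)
  traj
}
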