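# Shared fixture builders; everything is generated in code.

# minimal bilayer-like trajectory: n molecules per leaflet, GL1-only,
# fixed z planes at +/- thick/2 (around box_z/2), static xy grid
static_bilayer <- function(n_per_leaflet = 16, thick = 2.9, box_xy = 8,
                           box_z = 8, n_frames = 1, species = "PG") {
  n <- 2 * n_per_leaflet
  g <- ceiling(sqrt(n_per_leaflet))
  xy <- as.matrix(expand.grid(x = seq(0.5, box_xy - 0.5, length.out = g),
                              y = seq(0.5, box_xy - 0.5, length.out = g)))
  xy <- xy[seq_len(n_per_leaflet), , drop = FALSE]
  top <- topology(
    data.frame(particle_id = seq_len(n), bead = "GL1",
               molecule_id = seq_len(n)),
    data.frame(molecule_id = seq_len(n),
               species = rep(species, length.out = n),
               leaflet = rep(c("upper", "lower"), each = n_per_leaflet)))
  coords <- array(NA_real_, c(n, 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[, 1:2, f] <- rbind(xy, xy)
    coords[, 3, f] <- box_z / 2 +
      rep(c(thick / 2, -thick / 2), each = n_per_leaflet)
  }
  trajectory(top, coords, seq_len(n_frames) - 1, c(box_xy, box_xy, box_z))
}

# single-molecule trajectory with a prescribed z path (flip-flop tests);
# molecule 2 mirrors the path so the mean z (midplane) stays fixed, and
# molecules 3/4 sit statically at +/- half_thick as the membrane body
z_path_trajectory <- function(z, box = c(5, 5, 8), species = "DAG",
                              half_thick = 1.45) {
  nf <- length(z)
  top <- topology(
    data.frame(particle_id = 1:4, bead = "GL1", molecule_id = 1:4),
    data.frame(molecule_id = 1:4, species = c(species, rep("REF", 3))))
  coords <- array(0, c(4, 3, nf))
  coords[, 1, ] <- 1:4; coords[, 2, ] <- 1:4
  coords[1, 3, ] <- z + box[3] / 2
  coords[2, 3, ] <- box[3] / 2 - z
  coords[3, 3, ] <- box[3] / 2 + half_thick
  coords[4, 3, ] <- box[3] / 2 - half_thick
  trajectory(top, coords, seq_len(nf) - 1, box)
}

# brute-force two-threshold replay used as the flip-flop oracle
oracle_flip_count <- function(z, h) {
  state <- 0L; count <- 0L
  for (v in z) {
    if (v > h) { if (state == -1L) count <- count + 1L; state <- 1L }
    else if (v < -h) { if (state == 1L) count <- count + 1L; state <- -1L }
  }
  count
}

# trajectory from explicit per-molecule xy paths (GL1 only, one leaflet)
xy_path_trajectory <- function(xs, ys, box = c(100, 100, 10), dt = 1,
                               species = "PG") {
  n <- nrow(xs); nf <- ncol(xs)
  top <- topology(
    data.frame(particle_id = seq_len(n), bead = "GL1",
               molecule_id = seq_len(n)),
    data.frame(molecule_id = seq_len(n), species = species))
  coords <- array(0, c(n, 3, nf))
  coords[, 1, ] <- xs %% box[1]
  coords[, 2, ] <- ys %% box[2]
  coords[, 3, ] <- box[3] / 2
  trajectory(top, coords, (seq_len(nf) - 1) * dt, box)
}
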