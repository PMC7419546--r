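#' Topology of a molecular system
#'
#' Maps particles to molecules and molecules to species.  Particle ids
#' must be the dense sequence 1..n in order; each molecule belongs to
#' exactly one species.
#'
#' @param particles data.frame with columns `particle_id`, `bead`
#'   (bead/atom label), `molecule_id`.
#' @param molecules data.frame with columns `molecule_id`, `species`, and
#'   optionally `leaflet` (initial leaflet hint, `"upper"`/`"lower"`/`NA`).
#' @param protein_calpha integer vector of particle ids that are protein
#'   C-alpha sites (possibly empty).
#' @return an object of class `topology`.
#' @export
topology <- function(particles, molecules, protein_calpha = integer(0)) {
  stopifnot(is.data.frame(particles), is.data.frame(molecules))
  need_p <- c("particle_id", "bead", "molecule_id")
  need_m <- c("molecule_id", "species")
  if (!all(need_p %in% names(particles)))
    stop("particles needs columns: ", paste(need_p, collapse = ", "))
  if (!all(need_m %in% names(molecules)))
    stop("molecules needs columns: ", paste(need_m, collapse = ", "))
  if (!identical(as.integer(particles$particle_id), seq_len(nrow(particles))))
    stop("particle ids must be dense 1..n in order")
  if (anyDuplicated(molecules$molecule_id))
    stop("duplicated molecule ids")
  if (!all(particles$molecule_id %in% molecules$molecule_id))
    stop("particles reference unknown molecule ids")
  if (!all(molecules$molecule_id %in% particles$molecule_id))
    stop("every molecule id must be referenced by at least one particle")
  if (!"leaflet" %in% names(molecules)) molecules$leaflet <- NA_character_
  if (length(protein_calpha) &&
      !all(protein_calpha %in% particles$particle_id))
    stop("protein_calpha references unknown particle ids")
  structure(
    list(particles = particles, molecules = molecules,
         species = unique(molecules$species),
         protein_calpha = as.integer(protein_calpha)),
    class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("Topology: %d particles, %d molecules, %d species (%s)\n",
              nrow(x$particles), nrow(x$molecules), length(x$species),
              paste(x$species, collapse = ", ")))
  if (length(x$protein_calpha))
    cat(sprintf("  %d protein C-alpha sites\n", length(x$protein_calpha)))
  invisible(x)
}

#' Trajectory container
#'
#' Ordered frames of particle coordinates with orthorhombic box
#' dimensions and timestamps.  Lengths are nm, times ns.  Coordinates
#' are stored wrapped into the box; analyses that need continuous paths
#' unwrap internally.
#'
#' @param topology a [topology].
#' @param coords numeric array `n_particles x 3 x n_frames` (nm).
#' @param times numeric vector of frame times (ns), strictly increasing.
#' @param box numeric `n_frames x 3` matrix of box edge lengths (nm), or
#'   a length-3 vector recycled over frames.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, times, box) {
  stopifnot(inherits(topology, "topology"))
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n_frames <- dim(coords)[3]
  if (dim(coords)[1] != nrow(topology$particles))
    stop("coordinate rows (", dim(coords)[1],
         ") do not match particle count (", nrow(topology$particles), ")")
  times <- as.numeric(times)
  if (length(times) != n_frames) stop("times length must equal frame count")
  if (n_frames > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (is.null(dim(box))) box <- matrix(box, n_frames, 3, byrow = TRUE)
  box <- as.matrix(box)
  if (nrow(box) == 1L && n_frames > 1L)
    box <- box[rep(1L, n_frames), , drop = FALSE]
  if (nrow(box) != n_frames || ncol(box) != 3L)
    stop("box must be n_frames x 3")
  if (any(box <= 0)) stop("box components must be strictly positive")
  structure(list(topology = topology, coords = coords,
                 times = times, box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, %d particles, t = [%g, %g] ns\n",
              n_frames(x), nrow(x$topology$particles),
              x$times[1], x$times[n_frames(x)]))
  cat(sprintf("  box (first frame): %.3f x %.3f x %.3f nm\n",
              x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  print(x$topology)
  invisible(x)
}

#' @export
#' @rdname trajectory
n_frames <- function(topology) UseMethod("n_frames")

#' @export
n_frames.trajectory <- function(topology) dim(topology$coords)[3]

#' Select particle indices by species and bead label
#'
#' Deterministic, order-preserving selection over the topology.  Unknown
#' species or bead labels are an error; an empty result is legal.
#'
#' @param traj a [trajectory] or [topology].
#' @param species optional character vector of species names.
#' @param bead optional character vector of bead labels.
#' @param molecule_id optional molecule ids.
#' @return integer vector of particle indices (possibly empty).
#' @examples
#' # GL1 beads of PG lipids:
#' # select_particles(traj, species = "PG", bead = "GL1")
#' @export
select_particles <- function(traj, species = NULL, bead = NULL,
                             molecule_id = NULL) {
  top <- if (inherits(traj, "trajectory")) traj$topology else traj
  stopifnot(inherits(top, "topology"))
  keep <- rep(TRUE, nrow(top$particles))
  if (!is.null(species)) {
    unknown <- setdiff(species, top$species)
    if (length(unknown))
      stop("unknown species: ", paste(unknown, collapse = ", "))
    mols <- top$molecules$molecule_id[top$molecules$species %in% species]
    keep <- keep & top$particles$molecule_id %in% mols
  }
  if (!is.null(bead)) {
    unknown <- setdiff(bead, unique(top$particles$bead))
    if (length(unknown))
      stop("unknown bead labels: ", paste(unknown, collapse = ", "))
    keep <- keep & top$particles$bead %in% bead
  }
  if (!is.null(molecule_id))
    keep <- keep & top$particles$molecule_id %in% molecule_id
  which(keep)
}

#' Minimum-image displacement in an orthorhombic box
#'
#' Componentwise displacement `b - a` wrapped to the nearest periodic
#' image, so each component has magnitude at most `box/2`.
#'
#' @param a,b numeric matrices (n x 3) or length-3 vectors.
#' @param box length-3 box edge vector (nm).
#' @return matrix (or vector) of minimum-image displacements.
#' @export
minimum_image <- function(a, b, box) {
  d <- b - a
  if (is.null(dim(d))) {
    d - round(d / box) * box
  } else {
    boxm <- matrix(box, nrow(d), 3, byrow = TRUE)
    d - round(d / boxm) * boxm
  }
}

#' Wrap coordinates into the primary box [0, box)
#' @param x n x 3 coordinate matrix.
#' @param box length-3 box vector.
#' @return wrapped matrix.
#' @export
wrap_coords <- function(x, box) {
  boxm <- matrix(box, nrow(x), 3, byrow = TRUE)
  x - floor(x / boxm) * boxm
}

# Unwrap one particle set across frames by minimum-image continuity.
# coords: n x 3 x n_frames (wrapped); box: n_frames x 3.
# Asserts no displacement exceeds box/2 after unwrapping assumptions.
unwrap_trajectory <- function(coords, box) {
  nf <- dim(coords)[3]
  out <- coords
  if (nf < 2) return(out)
  for (f in 2:nf) {
    d <- coords[, , f, drop = FALSE] - coords[, , f - 1, drop = FALSE]
    d <- matrix(d, ncol = 3)
    bx <- matrix(box[f, ], nrow(d), 3, byrow = TRUE)
    d <- d - round(d / bx) * bx
    out[, , f] <- matrix(out[, , f - 1], ncol = 3) + d
  }
  out
}

#' Extract one frame of a trajectory
#' @param traj a [trajectory].
#' @param frame frame index.
#' @return a one-frame [trajectory].
#' @export
get_frame <- function(traj, frame) {
  stopifnot(inherits(traj, "trajectory"),
            frame >= 1, frame <= n_frames(traj))
  trajectory(traj$topology,
             traj$coords[, , frame, drop = FALSE],
             traj$times[frame], traj$box[frame, , drop = FALSE])
}

#' Per-molecule centre of geometry for one frame
#' @param traj a [trajectory].
#' @param frame frame index.
#' @param indices optional particle index subset.
#' @return matrix of molecule centres with rownames = molecule ids.
#' @export
molecule_centers <- function(traj, frame = 1, indices = NULL) {
  xyz <- matrix(traj$coords[, , frame], ncol = 3)
  mol <- traj$topology$particles$molecule_id
  if (!is.null(indices)) {
    xyz <- xyz[indices, , drop = FALSE]
    mol <- mol[indices]
  }
  ids <- sort(unique(mol))
  f <- factor(mol, levels = ids)
  cx <- rowsum(xyz, f) / as.vector(table(f))
  rownames(cx) <- ids
  cx
}
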