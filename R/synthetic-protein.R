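#' Specification of a synthetic protein C-alpha ensemble
#'
#' Frames are drawn from a multivariate Gaussian centred on a reference
#' structure, with covariance either given explicitly (any symmetric
#' positive-semidefinite 3n x 3n matrix) or derived from an anisotropic
#' network model of the reference structure (pseudo-inverse of the ANM
#' Hessian).  Optional random rigid-body motions can be composed onto
#' every frame to exercise superposition.
#'
#' @param n_residues number of residues (>= 2); ignored when
#'   `reference_coordinates` is given.
#' @param reference_coordinates `n x 3` matrix (nm); default: a coarse
#'   helix-like curve, which keeps the ANM contact network connected.
#' @param covariance_source `"anm"` or `"explicit"`.
#' @param anm_cutoff,anm_gamma ANM parameters (nm; energy/nm^2).
#' @param anm_kT fluctuation scale multiplying the ANM pseudo-inverse
#'   covariance (default 0.005): keeps per-residue RMSF an order of
#'   magnitude below the fold size, as in a folded protein, so that
#'   iterative superposition of sampled frames is well posed.
#' @param explicit_covariance `3n x 3n` symmetric PSD matrix (nm^2);
#'   required for `"explicit"`.  Asymmetry beyond 1e-8 or negative
#'   eigenvalues are an error; exact singularity is accepted.
#' @param n_frames number of frames.
#' @param rigid_motion add random rotations/translations per frame.
#' @param seed integer seed.
#' @return an object of class `protein_spec`.
#' @export
protein_spec <- function(n_residues = 20L,
                         reference_coordinates = NULL,
                         covariance_source = c("anm", "explicit"),
                         anm_cutoff = 1.5, anm_gamma = 1, anm_kT = 0.005,
                         explicit_covariance = NULL,
                         n_frames = 1000L,
                         rigid_motion = FALSE,
                         seed = 1L) {
  covariance_source <- match.arg(covariance_source)
  if (is.null(reference_coordinates))
    reference_coordinates <- helix_reference(n_residues)
  reference_coordinates <- as.matrix(reference_coordinates)
  n <- nrow(reference_coordinates)
  if (n < 2) stop("n_residues must be >= 2")
  if (covariance_source == "explicit") {
    cv <- explicit_covariance
    if (is.null(cv)) stop("explicit covariance_source needs explicit_covariance")
    if (!isTRUE(all.equal(dim(cv), c(3 * n, 3 * n))))
      stop("explicit_covariance must be 3n x 3n")
    if (max(abs(cv - t(cv))) > 1e-8)
      stop("explicit_covariance not symmetric within 1e-8")
    ev <- eigen((cv + t(cv)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stop("explicit_covariance has negative eigenvalues: not PSD")
  }
  structure(list(n_residues = n, reference = reference_coordinates,
                 covariance_source = covariance_source,
                 anm_cutoff = anm_cutoff, anm_gamma = anm_gamma,
                 anm_kT = anm_kT,
                 explicit_covariance = explicit_covariance,
                 n_frames = as.integer(n_frames),
                 rigid_motion = rigid_motion, seed = as.integer(seed)),
            class = "protein_spec")
}

# coarse helical backbone: ~0.55 nm rise per 3.6 residues keeps
# consecutive and near-neighbour C-alphas inside a 1.5 nm ANM cutoff
helix_reference <- function(n) {
  i <- seq_len(n)
  th <- 2 * pi * i / 3.6
  cbind(0.23 * cos(th), 0.23 * sin(th), 0.15 * i)
}

#' Generate a protein ensemble with known covariance
#'
#' @param spec a [protein_spec].
#' @return a [protein_ensemble] with attribute `"truth"` holding the
#'   generator covariance (3n x 3n) and the spec.
#' @export
gen_protein_ensemble <- function(spec) {
  stopifnot(inherits(spec, "protein_spec"))
  n <- spec$n_residues
  cv <- switch(spec$covariance_source,
    explicit = (spec$explicit_covariance + t(spec$explicit_covariance)) / 2,
    anm = anm_covariance(anm(spec$reference, spec$anm_cutoff,
                             spec$anm_gamma), kT_scale = spec$anm_kT))
  eig <- eigen(cv, symmetric = TRUE)
  vals <- eig$values
  if (min(vals) < -1e-8 * max(abs(vals), 1))
    stop("covariance has negative eigenvalues: not PSD")
  vals <- pmax(vals, 0)
  set.seed(spec$seed)
  nz <- vals > 0
  zmat <- matrix(stats::rnorm(spec$n_frames * sum(nz)), sum(nz),
                 spec$n_frames)
  dev <- eig$vectors[, nz, drop = FALSE] %*% (sqrt(vals[nz]) * zmat)
  mu <- as.vector(t(spec$reference))        # residue-major x1 y1 z1 ...
  coords <- array(NA_real_, c(n, 3, spec$n_frames))
  for (f in seq_len(spec$n_frames)) {
    fr <- matrix(mu + dev[, f], n, 3, byrow = TRUE)
    if (spec$rigid_motion) {
      r <- random_rotation()
      fr <- fr %*% r +
        matrix(stats::rnorm(3, 0, 1), n, 3, byrow = TRUE)
    }
    coords[, , f] <- fr
  }
  out <- protein_ensemble(coords, reference = spec$reference,
                          aligned = !spec$rigid_motion)
  attr(out, "truth") <- list(covariance = cv, spec = spec)
  out
}

# uniform random rotation via QR of a Gaussian matrix, det corrected
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Normalise a 3n x 3n covariance to a residue-residue correlation map
#'
#' Collapses 3x3 superelement traces: `C_ij = tr(S_ij) /
#' sqrt(tr(S_ii) tr(S_jj))`.  This is the ground-truth map a
#' [cross_correlation] of an infinite sample from that covariance would
#' approach.
#'
#' @param cv `3n x 3n` covariance matrix.
#' @return `n x n` matrix in \[-1, 1\].
#' @export
covariance_to_ccmap <- function(cv) {
  n3 <- nrow(cv)
  stopifnot(n3 %% 3 == 0)
  n <- n3 / 3
  tr <- matrix(0, n, n)
  for (a in 1:3) {
    idx <- seq(a, n3, by = 3)
    tr <- tr + cv[idx, idx]
  }
  d <- diag(tr)
  tr / sqrt(outer(d, d))
}
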