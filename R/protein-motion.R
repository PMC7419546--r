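#' Protein C-alpha ensemble
#'
#' Frames of n C-alpha coordinates (nm) with a reference structure.
#'
#' @param coords array `n_residues x 3 x n_frames` (nm).
#' @param reference `n_residues x 3` reference structure; defaults to
#'   the first frame.
#' @param aligned logical: rigid-body motions already removed.
#' @return an object of class `protein_ensemble`.
#' @export
protein_ensemble <- function(coords, reference = NULL, aligned = FALSE) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L,
            dim(coords)[1] >= 2L)
  if (is.null(reference)) reference <- matrix(coords[, , 1], ncol = 3)
  stopifnot(nrow(reference) == dim(coords)[1])
  structure(list(coords = coords, reference = reference,
                 n_residues = dim(coords)[1], n_frames = dim(coords)[3],
                 aligned = aligned),
            class = "protein_ensemble")
}

#' @export
print.protein_ensemble <- function(x, ...) {
  cat(sprintf("Protein ensemble: %d residues x %d frames%s\n",
              x$n_residues, x$n_frames,
              if (x$aligned) " (aligned)" else ""))
  invisible(x)
}

# optimal proper rotation (Kabsch) mapping x onto y, both centred
kabsch_rotation <- function(x, y) {
  if (qr(x)$rank < 2)
    stop("degenerate structure: coordinate rank < 2 (collinear), ",
         "rotation ill-defined")
  h <- crossprod(x, y)
  s <- svd(h)
  # row-vector convention: x %*% R ~ y, hence R = U diag(1,1,d) V^T
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Least-squares superposition of an ensemble
#'
#' Removes overall translation and rotation from every frame by the
#' Kabsch algorithm (proper rotations only: reflections are rejected via
#' the determinant correction).  By default the reference is refined
#' iteratively: frames are aligned to the running mean structure until
#' the mean moves by less than `tol` (at most `max_iter` passes).
#'
#' @param ensemble a [protein_ensemble].
#' @param reference optional fixed reference (`n x 3`); when given, no
#'   iterative refinement is done.
#' @param max_iter,tol iterative-refinement controls.
#' @return an aligned [protein_ensemble].
#' @export
superpose <- function(ensemble, reference = NULL, max_iter = 10L,
                      tol = 1e-8) {
  stopifnot(inherits(ensemble, "protein_ensemble"))
  co <- ensemble$coords
  nf <- ensemble$n_frames
  align_to <- function(co, ref) {
    refc <- scale(ref, scale = FALSE)
    for (f in seq_len(nf)) {
      x <- matrix(co[, , f], ncol = 3)
      xc <- scale(x, scale = FALSE)
      r <- kabsch_rotation(xc, refc)
      co[, , f] <- xc %*% r
    }
    co
  }
  if (!is.null(reference)) {
    stopifnot(nrow(reference) == ensemble$n_residues)
    co <- align_to(co, reference)
    ref <- scale(reference, scale = FALSE)
  } else {
    # start from the stored reference (frame 1 for raw ensembles, the
    # converged mean for previously aligned ones): makes superposition
    # idempotent instead of re-picking an orientation each call
    ref <- ensemble$reference
    for (it in seq_len(max_iter)) {
      co <- align_to(co, ref)
      new_ref <- apply(co, c(1, 2), mean)
      delta <- sqrt(mean((new_ref - scale(ref, scale = FALSE))^2))
      ref <- new_ref
      if (delta < tol) break
    }
  }
  out <- protein_ensemble(co, reference = ref, aligned = TRUE)
  out
}

#' Per-residue root-mean-square fluctuation
#'
#' `rmsf_i = sqrt(<|r_i - <r_i>|^2>)` over frames of an aligned
#' ensemble.  Unaligned input is an error: rigid-body motion would
#' silently inflate the fluctuations.
#'
#' @param ensemble an aligned [protein_ensemble] with >= 2 frames.
#' @return numeric vector of per-residue RMSF (nm).
#' @export
rmsf <- function(ensemble) {
  stopifnot(inherits(ensemble, "protein_ensemble"))
  if (!ensemble$aligned)
    stop("ensemble is not aligned: superpose() first")
  if (ensemble$n_frames < 2) stop("rmsf needs >= 2 frames")
  mu <- apply(ensemble$coords, c(1, 2), mean)
  dev2 <- sweep(ensemble$coords, c(1, 2), mu)^2
  sqrt(apply(dev2, 1, sum) / ensemble$n_frames)
}

#' Convert RMSF to crystallographic B-factors
#'
#' `B_i = (8 pi^2 / 3) * rmsf_i^2` with the RMSF expressed in Angstrom,
#' giving B in Angstrom^2.
#'
#' @param rmsf_nm per-residue RMSF in nm.
#' @return per-residue B-factors (Angstrom^2).
#' @export
rmsf_to_bfactor <- function(rmsf_nm) {
  stopifnot(all(rmsf_nm >= 0))
  (8 * pi^2 / 3) * (rmsf_nm * 10)^2
}

#' Dynamical cross-correlation map
#'
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` with
#' `dr_i(t) = r_i(t) - <r_i>`, over an aligned ensemble.  Residues with
#' zero fluctuation yield `NA` entries (flagged, never silently 0); an
#' all-zero-fluctuation ensemble is an error.
#'
#' @param ensemble an aligned [protein_ensemble] with >= 2 frames.
#' @return a `ccmap`: `C` (n x n, entries in \[-1, 1\] or NA),
#'   `zero_variance` (logical vector).
#' @export
cross_correlation <- function(ensemble) {
  stopifnot(inherits(ensemble, "protein_ensemble"))
  if (!ensemble$aligned) stop("ensemble is not aligned: superpose() first")
  if (ensemble$n_frames < 2) stop("cross_correlation needs >= 2 frames")
  n <- ensemble$n_residues; nf <- ensemble$n_frames
  mu <- apply(ensemble$coords, c(1, 2), mean)
  dev <- sweep(ensemble$coords, c(1, 2), mu)
  # inner products <dr_i . dr_j> = sum over axes of per-axis covariances
  dot <- matrix(0, n, n)
  for (ax in 1:3) {
    m <- matrix(dev[, ax, ], n, nf)
    dot <- dot + tcrossprod(m) / nf
  }
  v <- diag(dot)
  zero <- v < 1e-30
  if (all(zero)) stop("all residues have zero fluctuation")
  denom <- sqrt(outer(v, v))
  C <- dot / denom
  C[zero, ] <- NA_real_; C[, zero] <- NA_real_
  diag(C)[!zero] <- 1
  structure(list(C = C, zero_variance = zero), class = "ccmap")
}

#' @export
print.ccmap <- function(x, ...) {
  n <- nrow(x$C)
  cat(sprintf("Cross-correlation map: %d x %d, %d zero-variance residues\n",
              n, n, sum(x$zero_variance)))
  invisible(x)
}

#' Principal component analysis of an aligned ensemble
#'
#' Eigendecomposition of the `3n x 3n` Cartesian covariance matrix of
#' the aligned coordinates.  Components are sorted by decreasing
#' eigenvalue; frame projections onto the leading components are
#' returned.
#'
#' @param ensemble an aligned [protein_ensemble] with >= 2 frames.
#' @param n_proj number of components to project frames onto (default 2).
#' @return a `pca_result`: `eigenvalues` (nm^2, descending),
#'   `eigenvectors` (3n x 3n, orthonormal columns), `projections`
#'   (n_frames x n_proj), `trace`.
#' @export
pca_ensemble <- function(ensemble, n_proj = 2L) {
  stopifnot(inherits(ensemble, "protein_ensemble"))
  if (!ensemble$aligned) stop("ensemble is not aligned: superpose() first")
  if (ensemble$n_frames < 2) stop("pca needs >= 2 frames")
  n <- ensemble$n_residues; nf <- ensemble$n_frames
  # flatten frames to nf x 3n (residue-major: x1 y1 z1 x2 ...)
  flat <- t(apply(ensemble$coords, 3, function(m) as.vector(t(m))))
  flat <- matrix(flat, nf, 3 * n)
  mu <- colMeans(flat)
  dev <- sweep(flat, 2, mu)
  covm <- crossprod(dev) / nf
  eig <- eigen(covm, symmetric = TRUE)
  n_proj <- min(n_proj, ncol(eig$vectors))
  proj <- dev %*% eig$vectors[, seq_len(n_proj), drop = FALSE]
  structure(list(eigenvalues = eig$values, eigenvectors = eig$vectors,
                 projections = proj, trace = sum(diag(covm))),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ev <- x$eigenvalues
  cat(sprintf(
    "PCA: %d modes, top eigenvalues %s (%.1f%% of trace in PC1-2)\n",
    length(ev), paste(signif(ev[1:min(3, length(ev))], 3), collapse = ", "),
    100 * sum(ev[1:min(2, length(ev))]) / sum(pmax(ev, 0))))
  invisible(x)
}

#' Anisotropic network model of a C-alpha structure
#'
#' Builds the ANM Hessian: for residue pairs within `cutoff`, the
#' off-diagonal 3x3 superelement is `-(gamma/d^2) * (d_vec %o% d_vec)`;
#' diagonal superelements are minus the sum of the row's off-diagonal
#' blocks, so rigid translations are exact zero modes.  Eigenmodes and
#' per-residue B-factors (trace of the diagonal 3x3 blocks of the
#' pseudo-inverse, the 6 rigid-body modes excluded) are returned on a
#' raw and a unit-mean scale.
#'
#' @param structure `n x 3` C-alpha coordinate matrix (nm).
#' @param cutoff interaction cutoff, nm (default 1.5).
#' @param gamma uniform spring constant (default 1).
#' @return an `anm_model`: `hessian` (3n x 3n), `eigenvalues` (ascending),
#'   `eigenvectors`, `bfactors` (raw), `bfactors_norm` (unit mean),
#'   `cutoff`, `gamma`, `n_zero_modes`.
#' @export
anm <- function(structure, cutoff = 1.5, gamma = 1) {
  structure <- as.matrix(structure)
  stopifnot(ncol(structure) == 3, nrow(structure) >= 2)
  if (cutoff <= 0) stop("cutoff must be > 0")
  n <- nrow(structure)
  d2 <- as.matrix(stats::dist(structure))^2
  adj <- d2 <= cutoff^2 & upper.tri(d2)
  # connectivity check before anything else
  g <- igraph::graph_from_adjacency_matrix(adj | t(adj), mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1)
    stop("contact network disconnected at cutoff ", cutoff, " nm: ",
         comp$no, " components of sizes ",
         paste(comp$csize, collapse = ", "))
  H <- matrix(0, 3 * n, 3 * n)
  pairs <- which(adj, arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    dv <- structure[j, ] - structure[i, ]
    blk <- -(gamma / sum(dv^2)) * tcrossprod(dv)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- blk; H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  eig <- eigen(H, symmetric = TRUE)
  ev <- rev(eig$values)                     # ascending
  vecs <- eig$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  n_zero <- sum(ev < 1e-8 * max(ev))
  # pseudo-inverse over non-rigid modes
  keep <- seq(n_zero + 1, 3 * n)
  pinv_diag3 <- function(vecs, vals) {
    b <- numeric(n)
    for (m in seq_along(vals)) {
      v <- vecs[, m]
      b <- b + rowSums(matrix(v^2, n, 3, byrow = TRUE)) / vals[m]
    }
    b
  }
  b <- pinv_diag3(vecs[, keep, drop = FALSE], ev[keep])
  structure(list(hessian = H, eigenvalues = ev, eigenvectors = vecs,
                 bfactors = b, bfactors_norm = b / mean(b),
                 cutoff = cutoff, gamma = gamma, n_zero_modes = n_zero),
            class = "anm_model")
}

#' @export
print.anm_model <- function(x, ...) {
  cat(sprintf(
    "ANM: %d residues, cutoff %.2f nm, gamma %g; %d zero modes, lowest nonzero eigenvalue %.4g\n",
    length(x$bfactors), x$cutoff, x$gamma, x$n_zero_modes,
    x$eigenvalues[x$n_zero_modes + 1]))
  invisible(x)
}

#' Covariance matrix implied by an ANM model
#'
#' The pseudo-inverse of the Hessian over its non-rigid modes, scaled by
#' `kT_scale` (an arbitrary energy scale; B-factor shapes are invariant
#' to it).
#'
#' @param model an `anm_model`.
#' @param kT_scale multiplicative scale (default 1).
#' @return `3n x 3n` positive-semidefinite covariance matrix.
#' @export
anm_covariance <- function(model, kT_scale = 1) {
  stopifnot(inherits(model, "anm_model"))
  keep <- seq(model$n_zero_modes + 1, length(model$eigenvalues))
  v <- model$eigenvectors[, keep, drop = FALSE]
  kT_scale * v %*% diag(1 / model$eigenvalues[keep],
                        nrow = length(keep)) %*% t(v)
}
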