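ref_structure <- function(n = 12, seed = 1) {
  set.seed(seed)
  membranekit:::helix_reference(n) + matrix(rnorm(3 * n, 0, 0.02), n, 3)
}

test_that("superposition recovers rigid transforms and rejects reflections", {
  ref <- ref_structure(10)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- ref %*% R + matrix(c(2, -1, 3), 10, 3, byrow = TRUE)
  en <- protein_ensemble(array(c(ref, moved), c(10, 3, 2)))
  al <- superpose(en, reference = ref)
  expect_lt(sqrt(mean((al$coords[, , 2] - al$coords[, , 1])^2)), 1e-10)
  expect_true(al$aligned)

  # mirror image: proper rotations cannot undo it, RMSD stays > 0
  mirrored <- ref %*% diag(c(-1, 1, 1))
  enm <- protein_ensemble(array(c(ref, mirrored), c(10, 3, 2)))
  alm <- superpose(enm, reference = ref)
  expect_gt(sqrt(mean((alm$coords[, , 2] - alm$coords[, , 1])^2)), 0.01)

  # collinear structures are refused by name
  line <- cbind(1:5, 0, 0)
  enl <- protein_ensemble(array(c(line, line), c(5, 3, 2)))
  expect_error(superpose(enl, reference = line), "collinear")
})

test_that("superposition is idempotent and removes injected rigid motion", {
  ps <- protein_spec(n_residues = 12, covariance_source = "anm",
                     n_frames = 400, seed = 4)
  clean <- gen_protein_ensemble(ps)
  ps_rigid <- protein_spec(n_residues = 12, covariance_source = "anm",
                           n_frames = 400, rigid_motion = TRUE, seed = 4)
  dirty <- gen_protein_ensemble(ps_rigid)
  expect_false(dirty$aligned)
  al <- superpose(dirty)
  r1 <- rmsf(al)
  r0 <- rmsf(superpose(clean))
  expect_equal(r1, r0, tolerance = 0.02)
  # aligning an aligned ensemble is a no-op
  al2 <- superpose(al)
  expect_lt(max(abs(al2$coords - al$coords)), 1e-8)
})

test_that("superposition matches the bio3d Kabsch fit", {
  skip_if_not_installed("bio3d")
  ref <- ref_structure(15, seed = 2)
  set.seed(3)
  frame <- ref + matrix(rnorm(45, 0, 0.05), 15, 3)
  frame <- frame %*% membranekit:::random_rotation() +
    matrix(c(1, 2, 3), 15, 3, byrow = TRUE)
  en <- protein_ensemble(array(c(ref, frame), c(15, 3, 2)))
  ours <- superpose(en, reference = ref)$coords[, , 2]
  theirs <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(ref)),
                   mobile = matrix(as.vector(t(frame)), nrow = 1)))
  theirs <- matrix(theirs, 15, 3, byrow = TRUE)
  ours_c <- sweep(ours, 2, colMeans(ours))
  theirs_c <- sweep(theirs, 2, colMeans(theirs))
  expect_equal(ours_c, theirs_c, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("rmsf obeys closed forms and refuses unaligned input", {
  n <- 8; nf <- 6000
  set.seed(5)
  co <- array(rnorm(n * 3 * nf, 0, 0.1), c(n, 3, nf)) +
    array(rep(ref_structure(n), nf), c(n, 3, nf))
  en <- protein_ensemble(co, aligned = TRUE)
  # isotropic per-axis sd 0.1 -> rmsf = 0.1 * sqrt(3)
  expect_equal(rmsf(en), rep(0.1 * sqrt(3), n), tolerance = 0.03,
               ignore_attr = TRUE)
  # frozen ensemble: all zeros
  frozen <- protein_ensemble(array(rep(ref_structure(n), 3), c(n, 3, 3)),
                             aligned = TRUE)
  expect_equal(rmsf(frozen), rep(0, n))
  # one mobile residue among frozen ones
  co2 <- array(rep(ref_structure(n), 100), c(n, 3, 100))
  co2[4, 1, ] <- co2[4, 1, ] + rnorm(100, 0, 0.2)
  r <- rmsf(protein_ensemble(co2, aligned = TRUE))
  expect_true(which.max(r) == 4 && all(r[-4] == 0))
  expect_error(rmsf(protein_ensemble(co2, aligned = FALSE)), "not aligned")
})

test_that("B-factor conversion is the exact closed form and invertible", {
  expect_equal(rmsf_to_bfactor(0), 0)
  # rmsf^2 = 3/(8 pi^2) A^2 -> B = 1 A^2 (input in nm)
  expect_equal(rmsf_to_bfactor(sqrt(3 / (8 * pi^2)) / 10), 1)
  r <- c(0, 0.05, 0.2, 1)
  back <- sqrt(rmsf_to_bfactor(r) / (8 * pi^2 / 3)) / 10
  expect_equal(back, r, tolerance = 1e-12)
})

test_that("cross-correlation maps are exact on constructed motions", {
  n <- 5; nf <- 50
  base <- ref_structure(n)
  co <- array(rep(base, nf), c(n, 3, nf))
  s <- rnorm(nf)
  co[1, 1, ] <- co[1, 1, ] + s          # residues 1 and 2 move together
  co[2, 1, ] <- co[2, 1, ] + s
  co[3, 1, ] <- co[3, 1, ] - s          # residue 3 moves opposite
  cc <- cross_correlation(protein_ensemble(co, aligned = TRUE))
  expect_equal(cc$C[1, 2], 1)
  expect_equal(cc$C[1, 3], -1)
  expect_equal(diag(cc$C)[1:3], rep(1, 3))
  # zero-variance residues are flagged NA, not zero
  expect_true(all(is.na(cc$C[4, ])))
  expect_true(cc$zero_variance[4])
  expect_true(isSymmetric(cc$C))
  frozen <- protein_ensemble(array(rep(base, 3), c(n, 3, 3)), aligned = TRUE)
  expect_error(cross_correlation(frozen), "zero fluctuation")
})

test_that("DCCM recovers a known covariance within 0.05 at 5000 frames", {
  ps <- protein_spec(n_residues = 15, covariance_source = "anm",
                     n_frames = 5000, seed = 3)
  en <- gen_protein_ensemble(ps)
  truth <- covariance_to_ccmap(attr(en, "truth")$covariance)
  cc <- cross_correlation(en)
  expect_lt(max(abs(cc$C - truth)), 0.05)
  expect_true(all(abs(cc$C) <= 1 + 1e-12))
})

test_that("DCCM agrees with the bio3d implementation", {
  skip_if_not_installed("bio3d")
  ps <- protein_spec(n_residues = 10, covariance_source = "anm",
                     n_frames = 300, seed = 9)
  en <- gen_protein_ensemble(ps)
  ours <- cross_correlation(en)$C
  xyz <- t(apply(en$coords, 3, function(m) as.vector(t(m))))
  theirs <- suppressWarnings(bio3d::dccm.xyz(xyz))
  expect_equal(ours, unclass(theirs), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("PCA conserves the trace, stays orthonormal, finds planted modes", {
  ps <- protein_spec(n_residues = 10, covariance_source = "anm",
                     n_frames = 5000, seed = 6)
  en <- gen_protein_ensemble(ps)
  p <- pca_ensemble(en)
  expect_equal(sum(p$eigenvalues), p$trace, tolerance = 1e-8)
  v <- p$eigenvectors
  expect_lt(max(abs(crossprod(v) - diag(ncol(v)))), 1e-8)
  truth_v <- eigen(attr(en, "truth")$covariance, symmetric = TRUE)$vectors[, 1]
  expect_gt(abs(sum(truth_v * p$eigenvectors[, 1])), 0.99)
  expect_equal(dim(p$projections), c(5000L, 2L))
  # variance along one known axis only
  n <- 4; nf <- 2000
  co <- array(rep(ref_structure(n), nf), c(n, 3, nf))
  set.seed(8)
  co[2, 3, ] <- co[2, 3, ] + rnorm(nf, 0, 0.3)
  p2 <- pca_ensemble(protein_ensemble(co, aligned = TRUE))
  expect_equal(p2$eigenvalues[1], 0.09, tolerance = 0.1)
  expect_equal(abs(p2$eigenvectors[6, 1]), 1, tolerance = 1e-9)
})

test_that("ANM has six rigid modes, the exact two-node spectrum, and", {
  # two nodes in contact: five zero modes and one stretching mode at 2*gamma
  two <- rbind(c(0, 0, 0), c(1, 0, 0))
  m <- anm(two, cutoff = 1.5, gamma = 1.7)
  expect_equal(sum(m$eigenvalues < 1e-10), 5)
  expect_equal(max(m$eigenvalues), 2 * 1.7, tolerance = 1e-12)
  # brute-force 6x6 oracle: H assembled from the dyadic definition
  dvec <- c(1, 0, 0)
  blk <- -1.7 * tcrossprod(dvec)
  H <- rbind(cbind(-blk, blk), cbind(blk, -blk))
  expect_equal(sort(eigen(H, symmetric = TRUE)$values),
               sort(m$eigenvalues), tolerance = 1e-12)

  ref <- ref_structure(14, seed = 4)
  model <- anm(ref, cutoff = 1.5)
  expect_equal(model$n_zero_modes, 6)
  expect_true(all(model$bfactors >= 0))
  expect_equal(mean(model$bfactors_norm), 1, tolerance = 1e-12)
  # rigid translation leaves modes and B-factors unchanged
  shifted <- anm(ref + matrix(c(5, -2, 1), 14, 3, byrow = TRUE), cutoff = 1.5)
  expect_equal(shifted$eigenvalues, model$eigenvalues, tolerance = 1e-9)
  expect_equal(shifted$bfactors, model$bfactors, tolerance = 1e-8)
  # Hessian superelement row sums vanish (translation invariance, exact)
  n <- nrow(ref)
  rows <- matrix(0, 3, 3 * n)
  for (i in seq_len(n))
    rows <- rows + model$hessian[(3 * i - 2):(3 * i), ]
  expect_lt(max(abs(rows)), 1e-10)
  # disconnected graphs are refused with component information
  far <- rbind(ref, ref + 100)
  expect_error(anm(far, cutoff = 1.5), "disconnected")
  expect_error(anm(ref, cutoff = -1), "cutoff")
})

test_that("ANM covariance round-trips through ensemble RMSF", {
  ps <- protein_spec(n_residues = 15, covariance_source = "anm",
                     n_frames = 5000, seed = 12)
  en <- gen_protein_ensemble(ps)
  model <- anm(ps$reference, 1.5)
  r2 <- rmsf(en)^2
  expect_gt(stats::cor(r2, model$bfactors), 0.95)
})

test_that("difference maps flag the residue pairs whose coupling changed", {
  n <- 6
  base <- diag(0.02, 3 * n)
  cpl <- base
  # couple residues 2 and 5 along x in ensemble B only
  cpl[3 * 1 + 1, 3 * 4 + 1] <- cpl[3 * 4 + 1, 3 * 1 + 1] <- 0.018
  ref <- ref_structure(n, seed = 7)
  mk <- function(cv, seed) gen_protein_ensemble(protein_spec(
    reference_coordinates = ref, covariance_source = "explicit",
    explicit_covariance = cv, n_frames = 4000, seed = seed))
  Ca <- cross_correlation(mk(base, 1))$C
  Cb <- cross_correlation(mk(cpl, 2))$C
  dC <- Cb - Ca
  truth_d <- covariance_to_ccmap(cpl) - covariance_to_ccmap(base)
  big <- which(abs(truth_d) > 0.2, arr.ind = TRUE)
  expect_gt(nrow(big), 0)
  for (r in seq_len(nrow(big)))
    expect_equal(sign(dC[big[r, 1], big[r, 2]]),
                 sign(truth_d[big[r, 1], big[r, 2]]))
  small <- abs(truth_d) < 1e-9 & upper.tri(truth_d)
  expect_lt(max(abs(dC[small])), 0.2)
})
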