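test_that("cell-list neighbour search equals the all-pairs oracle exactly", {
  set.seed(31)
  for (i in 1:250) {
    n <- sample(40:250, 1)
    box <- stats::runif(3, 2, 10)
    x <- cbind(stats::runif(n, -2, box[1] + 2),  # unwrapped inputs too
               stats::runif(n, 0, box[2]),
               stats::runif(n, 0, box[3]))
    cutoff <- stats::runif(1, 0.2, min(box) / 2)
    expect_identical(neighbor_pairs(x, box, cutoff, "cell"),
                     neighbor_pairs(x, box, cutoff, "brute"))
  }
  expect_error(neighbor_pairs(matrix(0, 2, 3), c(1, 5, 5), 0.6),
               "minimum image")
})

test_that("contact rules follow their geometric definitions", {
  # two lipids, GL1-GL1 at 0.5 nm: contact under both rules
  top <- topology(
    data.frame(particle_id = 1:4, bead = c("GL1", "C1A", "GL1", "C1A"),
               molecule_id = c(1, 1, 2, 2)),
    data.frame(molecule_id = 1:2, species = c("PG", "DAG")))
  co <- array(0, c(4, 3, 1))
  co[, 1, 1] <- c(1.0, 1.0, 1.5, 3.0)
  co[, 2, 1] <- 1; co[, 3, 1] <- 1
  tr <- trajectory(top, co, 0, c(6, 6, 6))
  for (rule in c("gl1_any", "gl1_gl1")) {
    cm <- contact_matrix(tr, 0.8, rule)
    expect_equal(cm$counts["PG", "DAG"], 1)
  }
  # separation 1.0 nm with no bridging beads: no contact
  co[, 1, 1] <- c(1.0, 0.2, 2.0, 3.5)
  tr2 <- trajectory(top, co, 0, c(6, 6, 6))
  expect_equal(sum(contact_matrix(tr2, 0.8, "gl1_gl1")$counts), 0)
  # but an auxiliary bead of molecule 2 near GL1 of molecule 1 makes a
  # gl1_any contact without a gl1_gl1 one
  co[, 1, 1] <- c(1.0, 0.2, 2.0, 1.5)
  tr3 <- trajectory(top, co, 0, c(6, 6, 6))
  expect_equal(contact_matrix(tr3, 0.8, "gl1_any")$counts["PG", "DAG"], 1)
  expect_equal(sum(contact_matrix(tr3, 0.8, "gl1_gl1")$counts), 0)
})

test_that("contact fractions are row-stochastic and near expectation", {
  frs <- lapply(1:40, function(s)
    contact_matrix(gen_lateral_layout(composition_preset("M1"), 200, 8,
                                      seed = s), 0.8, "gl1_gl1")$fractions)
  for (fr in frs[1:5]) expect_equal(rowSums(fr), c(DAG = 1, PG = 1))
  avg <- Reduce(`+`, frs) / length(frs)
  expect_equal(avg["PG", "PG"], 0.75, tolerance = 0.03)
  expect_equal(avg["DAG", "DAG"], 0.25, tolerance = 0.10)
})

test_that("permutation null matches the finite-n expectation and calibrates", {
  lay <- gen_lateral_layout(composition_preset("M1"), 200, 8, seed = 2)
  mn <- mixing_null(lay, "PG", n_perm = 2000, seed = 5)
  expect_equal(mn$expected_finite_n, 149 / 199)
  expect_equal(mn$expected_large_n, 0.75)
  expect_equal(mean(mn$null), mn$expected_finite_n, tolerance = 0.01)
  expect_true(mn$p_value > 0 && mn$p_value <= 1)
  # on uniform layouts p is roughly uniform: sub-0.05 calls stay rare
  ps <- vapply(1:60, function(s)
    mixing_null(gen_lateral_layout(composition_preset("M1"), 200, 8,
                                   seed = 100 + s),
                "DAG", n_perm = 199, seed = s)$p_value, numeric(1))
  expect_lt(mean(ps <= 0.05), 0.20)
  expect_gt(mean(ps), 0.30)
  # degenerate single-species layout: observed 1, null at 1, p = 1
  uni <- gen_lateral_layout(membrane_composition(PG = 1), 50, 8, seed = 1)
  m1 <- mixing_null(uni, "PG", n_perm = 100, seed = 1)
  expect_equal(m1$observed, 1)
  expect_true(all(m1$null == 1))
  expect_equal(m1$p_value, 1)
  expect_error(mixing_null(uni, "DAG", n_perm = 100), "absent")
})

test_that("Matern-clustered minorities are rejected by the mixing null", {
  hits <- vapply(1:100, function(s) {
    lay <- gen_lateral_layout(
      composition_preset("M1"), 200, 8, "clustered",
      cluster_params = list(species = "DAG", radius = 1, mean_children = 8),
      seed = s)
    mixing_null(lay, "DAG", n_perm = 199, seed = s)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("single-linkage clustering is transitive and splits leaflets", {
  # 5 beads in a chain at 0.7 nm spacing: one cluster of 5
  top <- topology(
    data.frame(particle_id = 1:5, bead = "GL1", molecule_id = 1:5),
    data.frame(molecule_id = 1:5, species = "PG"))
  co <- array(0, c(5, 3, 1))
  co[, 1, 1] <- 0.7 * (0:4) + 1; co[, 2, 1] <- 1; co[, 3, 1] <- 4
  tr <- trajectory(top, co, 0, c(8, 8, 8))
  cs <- find_clusters(tr, 0.8, "PG", per_leaflet = FALSE)
  expect_equal(cs$sizes, 5L)
  expect_length(cs$singletons, 0)
  # two groups 2 nm apart: two clusters
  co[, 1, 1] <- c(1, 1.7, 4.4, 5.1, 5.8)
  tr2 <- trajectory(top, co, 0, c(12, 8, 8))
  cs2 <- find_clusters(tr2, 0.8, "PG", per_leaflet = FALSE)
  expect_equal(sort(cs2$sizes), c(2L, 3L))
  # opposite leaflets never merge even at zero lateral separation
  spec <- membrane_spec(composition_preset("M1"), n_lipids_per_leaflet = 30,
                        n_frames = 1, D_true = 0, seed = 3)
  trb <- gen_bilayer_trajectory(spec)
  csb <- find_clusters(trb, 0.8, c("PG", "DAG"))
  leafs <- assign_leaflets(trb)
  for (k in seq_along(csb$clusters)) {
    got <- unique(leafs[as.character(csb$clusters[[k]])])
    expect_length(got, 1)
  }
})

test_that("cluster partitions are invariant to ordering and translation", {
  lay <- gen_lateral_layout(
    composition_preset("M1"), 120, 8, "clustered",
    cluster_params = list(species = "DAG", radius = 0.9, mean_children = 6),
    seed = 13)
  base <- find_clusters(lay, 0.8, "DAG", per_leaflet = FALSE)
  canon <- function(cs) unname(lapply(cs$clusters, sort))
  # rigid translation with periodic wrap
  sh <- lay
  sh$coords[, 1, 1] <- (sh$coords[, 1, 1] + 3.3) %% 8
  sh$coords[, 2, 1] <- (sh$coords[, 2, 1] + 5.1) %% 8
  expect_setequal(canon(find_clusters(sh, 0.8, "DAG", per_leaflet = FALSE)),
                  canon(base))
  expect_identical(sort(find_clusters(sh, 0.8, "DAG",
                                      per_leaflet = FALSE)$singletons),
                   sort(base$singletons))
})

test_that("cluster size statistics pool frames and respect the singleton policy", {
  # all singletons: zero clusters, n singletons, NA mean
  top <- topology(
    data.frame(particle_id = 1:4, bead = "GL1", molecule_id = 1:4),
    data.frame(molecule_id = 1:4, species = "PG"))
  co <- array(0, c(4, 3, 1))
  co[, 1, 1] <- c(1, 3, 5, 7); co[, 2, 1] <- 1; co[, 3, 1] <- 4
  tr <- trajectory(top, co, 0, c(9, 9, 9))
  st <- cluster_size_stats(tr, 0.8, "PG", per_leaflet = FALSE)
  expect_equal(length(st$sizes), 0)
  expect_true(is.na(st$mean))
  expect_equal(st$n_singletons, 4)
  # one 5-cluster in every frame: mean 5, zero variance
  co2 <- array(0, c(4, 3, 3))
  co2[, 1, ] <- c(1, 1.5, 2, 2.5); co2[, 2, ] <- 1; co2[, 3, ] <- 4
  tr2 <- trajectory(top, co2, 0:2, c(9, 9, 9))
  st2 <- cluster_size_stats(tr2, 0.8, "PG", per_leaflet = FALSE)
  expect_equal(st2$sizes, rep(4L, 3))
  expect_equal(st2$mean, 4)
  # clustered layouts dominate uniform ones in mean size
  mean_size <- function(mode, s) {
    lay <- gen_lateral_layout(
      composition_preset("M1"), 200, 8, mode,
      cluster_params = if (mode == "clustered")
        list(species = "DAG", radius = 1, mean_children = 8),
      seed = s)
    st <- cluster_size_stats(lay, 0.8, "DAG", per_leaflet = FALSE)
    if (is.na(st$mean)) 0 else st$mean
  }
  wins <- vapply(1:50, function(s)
    mean_size("clustered", s) > mean_size("uniform", s), logical(1))
  expect_gt(mean(wins), 0.9)
})

test_that("Matern parents sized for 8 children give nano-domain-sized clusters", {
  sizes <- unlist(lapply(1:30, function(s) {
    lay <- gen_lateral_layout(
      composition_preset("M2"), 200, 8, "clustered",
      cluster_params = list(species = c("PG", "DAG"), radius = 0.9,
                            mean_children = 8),
      seed = s)
    cluster_size_stats(lay, 0.8, c("PG", "DAG"), per_leaflet = FALSE)$sizes
  }))
  expect_gt(mean(sizes), 5)
  expect_lt(mean(sizes), 11)
})
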