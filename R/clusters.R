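#' Species-species contact matrix
#'
#' Two lipids are in contact when, under rule `"gl1_any"`, the GL1 bead
#' of either molecule lies within `cutoff` of any bead of the other
#' (symmetrised), or, under rule `"gl1_gl1"`, when their GL1 beads are
#' within `cutoff`.  Distances are 3-D minimum image.  The normalised
#' matrix is row-stochastic: row `s` gives the distribution of contact
#' partners of species-`s` molecules (each contact pair contributes one
#' count to each of its endpoint rows).  For a multi-frame trajectory
#' the normalised fractions are averaged over frames (pooled raw counts
#' are also returned).
#'
#' @param traj a [trajectory] (one or many frames).
#' @param cutoff nm (default 0.8, the first CG solvation shell).
#' @param rule `"gl1_any"` (contact-percentage convention) or
#'   `"gl1_gl1"` (cluster convention).
#' @param ref_bead reference bead label (default `"GL1"`).
#' @param method neighbour engine passed to [neighbor_pairs].
#' @return a `contact_matrix`: `fractions` (row-stochastic, species x
#'   species, frame-averaged), `counts` (pooled raw pair counts, symmetric),
#'   `cutoff`, `rule`, `n_frames`.
#' @export
contact_matrix <- function(traj, cutoff = 0.8, rule = c("gl1_any", "gl1_gl1"),
                           ref_bead = "GL1", method = "cell") {
  stopifnot(inherits(traj, "trajectory"))
  rule <- match.arg(rule)
  top <- traj$topology
  sp_names <- sort(top$species)
  ns <- length(sp_names)
  counts <- matrix(0, ns, ns, dimnames = list(sp_names, sp_names))
  fr_sum <- matrix(0, ns, ns, dimnames = list(sp_names, sp_names))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    ed <- contact_edges(traj, f, cutoff, rule, ref_bead, method)
    tab <- table(factor(ed$species_i, levels = sp_names),
                 factor(ed$species_j, levels = sp_names))
    cm <- unclass(tab) + t(unclass(tab))   # each pair counted in both rows
    counts <- counts + cm
    rs <- rowSums(cm)
    frac <- cm / ifelse(rs > 0, rs, 1)
    fr_sum <- fr_sum + frac
  }
  structure(list(fractions = fr_sum / nf, counts = counts,
                 cutoff = cutoff, rule = rule, n_frames = nf),
            class = "contact_matrix")
}

# molecule-level contact edge list for one frame
contact_edges <- function(traj, frame, cutoff, rule, ref_bead, method) {
  top <- traj$topology
  box <- traj$box[frame, ]
  xyz <- matrix(traj$coords[, , frame], ncol = 3)
  gl1 <- select_particles(traj, bead = ref_bead)
  if (!length(gl1)) stop("no reference bead '", ref_bead, "' in topology")
  mol_of <- top$particles$molecule_id
  if (anyDuplicated(mol_of[gl1]))
    stop("reference bead must be unique per molecule")
  if (rule == "gl1_gl1") {
    pr <- neighbor_pairs(xyz[gl1, , drop = FALSE], box, cutoff,
                         method = method)
    mi <- mol_of[gl1][pr[, 1]]; mj <- mol_of[gl1][pr[, 2]]
  } else {
    # GL1 of i within cutoff of ANY bead of j, symmetrised: search all
    # (GL1, any-bead) particle pairs and map to molecule pairs
    is_ref <- seq_len(nrow(xyz)) %in% gl1
    pr <- neighbor_pairs(xyz, box, cutoff, method = method)
    keep <- (is_ref[pr[, 1]] | is_ref[pr[, 2]]) &
            mol_of[pr[, 1]] != mol_of[pr[, 2]]
    mi <- mol_of[pr[keep, 1]]; mj <- mol_of[pr[keep, 2]]
  }
  swap <- mi > mj
  tmp <- mi[swap]; mi[swap] <- mj[swap]; mj[swap] <- tmp
  keep <- mi != mj
  edges <- unique(cbind(mi, mj)[keep, , drop = FALSE])
  sp <- top$molecules$species[match(edges[, 1], top$molecules$molecule_id)]
  sq <- top$molecules$species[match(edges[, 2], top$molecules$molecule_id)]
  list(mol_i = edges[, 1], mol_j = edges[, 2],
       species_i = sp, species_j = sq)
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("Contact matrix (rule %s, cutoff %.2f nm, %d frame%s):\n",
              x$rule, x$cutoff, x$n_frames, if (x$n_frames > 1) "s" else ""))
  print(round(x$fractions, 4))
  invisible(x)
}

#' Random-mixing permutation null for self-contacts
#'
#' Builds the molecule contact graph once from the frame geometry, then
#' permutes the species labels uniformly `n_perm` times and recomputes
#' the self-contact fraction of `species` under each permutation.  The
#' observed fraction is compared to this null by a one-sided exceedance
#' p-value with add-one smoothing, `p = (b + 1)/(n_perm + 1)`.  The
#' analytic large-n expectation (the mole fraction) and the exact
#' finite-n expectation `(n_s - 1)/(n - 1)` are reported alongside.
#'
#' @param traj a one-frame [trajectory] (first frame used otherwise).
#' @param species species whose self-contact fraction is tested.
#' @param cutoff nm.
#' @param rule contact rule, see [contact_matrix].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @return a `mixing_null`: `observed`, `null` (length `n_perm`),
#'   `p_value`, `expected_large_n`, `expected_finite_n`, `n_perm`.
#' @export
mixing_null <- function(traj, species, cutoff = 0.8,
                        rule = c("gl1_gl1", "gl1_any"),
                        n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(traj, "trajectory"), n_perm >= 100)
  rule <- match.arg(rule)
  top <- traj$topology
  if (!species %in% top$species) stop("species absent: ", species)
  ed <- contact_edges(traj, 1, cutoff, rule, "GL1", "cell")
  mol_ids <- top$molecules$molecule_id
  labels <- top$molecules$species
  e1 <- match(ed$mol_i, mol_ids)
  e2 <- match(ed$mol_j, mol_ids)
  self_frac <- function(lab) {
    si <- lab[e1]; sj <- lab[e2]
    denom <- sum(si == species) + sum(sj == species)
    if (denom == 0) return(NA_real_)
    2 * sum(si == species & sj == species) / denom
  }
  observed <- self_frac(labels)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) self_frac(sample(labels)),
                 numeric(1))
  n <- length(labels)
  n_s <- sum(labels == species)
  b <- sum(null >= observed, na.rm = TRUE)
  structure(list(observed = observed, null = null,
                 p_value = (b + 1) / (n_perm + 1),
                 expected_large_n = n_s / n,
                 expected_finite_n = if (n > 1) (n_s - 1) / (n - 1) else NA,
                 n_perm = n_perm, species = species, cutoff = cutoff,
                 rule = rule),
            class = "mixing_null")
}

#' @export
print.mixing_null <- function(x, ...) {
  cat(sprintf(
    "Mixing null for %s: observed self-contact %.3f, null mean %.3f (expect %.3f finite-n, %.3f large-n), p = %.4g (%d permutations)\n",
    x$species, x$observed, mean(x$null, na.rm = TRUE),
    x$expected_finite_n, x$expected_large_n, x$p_value, x$n_perm))
  invisible(x)
}

#' Single-linkage lipid clusters per leaflet
#'
#' Connected components of the GL1-GL1 <= cutoff graph restricted to
#' the given species set, computed separately per leaflet (from
#' [assign_leaflets]; midplane molecules are skipped).  Singletons are
#' excluded from mean-size statistics by default and reported apart.
#'
#' @param traj a one-frame [trajectory] (or `frame` index into a longer
#'   one).
#' @param cutoff nm (default 0.8).
#' @param species_set character vector, e.g. `c("PG", "DAG")`.
#' @param frame frame index.
#' @param per_leaflet split by leaflet before clustering (default TRUE;
#'   set FALSE for flat single-layer layouts).
#' @return a `cluster_set`: `clusters` (list of molecule-id vectors),
#'   `sizes`, `leaflet` per cluster, `singletons` (molecule ids),
#'   `cutoff`, `species_set`.
#' @export
find_clusters <- function(traj, cutoff = 0.8, species_set, frame = 1,
                          per_leaflet = TRUE) {
  stopifnot(inherits(traj, "trajectory"), length(species_set) >= 1)
  if (cutoff > min(traj$box[frame, ]) / 2)
    stop("cutoff exceeds min(box)/2: minimum image invalid")
  top <- traj$topology
  unknown <- setdiff(species_set, top$species)
  if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
  gl1 <- select_particles(traj, species = species_set, bead = "GL1")
  mols <- top$particles$molecule_id[gl1]
  if (per_leaflet) {
    leaf <- assign_leaflets(traj, frame = frame)
    leaf <- leaf[as.character(mols)]
  } else {
    leaf <- stats::setNames(rep("upper", length(mols)), mols)
  }
  clusters <- list(); sizes <- integer(0); leaflets <- character(0)
  singles <- integer(0)
  for (lf in intersect(c("upper", "lower"), unique(leaf))) {
    sel <- which(leaf == lf)
    if (!length(sel)) next
    xyz <- matrix(traj$coords[gl1[sel], , frame], ncol = 3)
    pr <- neighbor_pairs(xyz, traj$box[frame, ], cutoff)
    g <- igraph::graph_from_edgelist(cbind(pr[, 1], pr[, 2]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(sel) - igraph::vcount(g)))
    comp <- igraph::components(g)
    for (ci in seq_len(comp$no)) {
      members <- mols[sel][comp$membership == ci]
      if (length(members) == 1) {
        singles <- c(singles, members)
      } else {
        clusters[[length(clusters) + 1]] <- sort(members)
        sizes <- c(sizes, length(members))
        leaflets <- c(leaflets, lf)
      }
    }
  }
  structure(list(clusters = clusters, sizes = sizes, leaflet = leaflets,
                 singletons = sort(singles), cutoff = cutoff,
                 species_set = species_set),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf(
    "Clusters of {%s} at %.2f nm: %d clusters (sizes %s), %d singletons\n",
    paste(x$species_set, collapse = ", "), x$cutoff, length(x$clusters),
    if (length(x$sizes)) paste(sort(x$sizes, decreasing = TRUE),
                               collapse = ",") else "-",
    length(x$singletons)))
  invisible(x)
}

#' Cluster-size statistics over a trajectory
#'
#' Pools per-frame single-linkage cluster sizes over all frames and
#' summarises them.  Singletons are counted separately and never enter
#' the mean; if every molecule is a singleton in every frame the mean is
#' reported as `NA` with zero clusters.
#'
#' @inheritParams find_clusters
#' @return a `cluster_stats`: `sizes` (pooled), `mean`, `median`, `max`,
#'   `histogram` (table), `n_singletons`, `n_frames`.
#' @export
cluster_size_stats <- function(traj, cutoff = 0.8, species_set,
                               per_leaflet = TRUE) {
  stopifnot(inherits(traj, "trajectory"), n_frames(traj) >= 1)
  sizes <- integer(0); n_single <- 0L
  for (f in seq_len(n_frames(traj))) {
    cs <- find_clusters(traj, cutoff, species_set, frame = f,
                        per_leaflet = per_leaflet)
    sizes <- c(sizes, cs$sizes)
    n_single <- n_single + length(cs$singletons)
  }
  structure(list(sizes = sizes,
                 mean = if (length(sizes)) mean(sizes) else NA_real_,
                 median = if (length(sizes)) stats::median(sizes) else NA_real_,
                 max = if (length(sizes)) max(sizes) else 0L,
                 histogram = table(sizes), n_singletons = n_single,
                 n_frames = n_frames(traj)),
            class = "cluster_stats")
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf(
    "Cluster sizes over %d frame(s): mean %.2f, median %g, max %d (%d clusters, %d singletons)\n",
    x$n_frames, x$mean, x$median, x$max, length(x$sizes), x$n_singletons))
  invisible(x)
}
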