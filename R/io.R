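#' Read a coordinate file into a trajectory
#'
#' Reads GRO (possibly concatenated multi-frame) or PDB (possibly
#' multi-model) coordinate files.  PDB coordinates are converted from
#' Angstrom to nm; the box is taken from the GRO box line or the PDB
#' CRYST1 record.  Every residue (molecule) name must be covered by the
#' species map; unmapped names are an error listing the offenders.
#'
#' @param path file path.
#' @param format `"gro"` or `"pdb"`; guessed from the extension when
#'   missing.
#' @param species_map named character vector or list mapping residue
#'   names to species names, or the path of a YAML species-map file (see
#'   [write_species_map]).  Residue names mapped to `"CA"` are treated as
#'   protein C-alpha sites.
#' @return a [trajectory].
#' @export
read_structure <- function(path, format = NULL, species_map = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("gro", "pdb"))
  if (is.character(species_map) && length(species_map) == 1 &&
      file.exists(species_map))
    species_map <- read_species_map(species_map)
  if (is.list(species_map)) species_map <- unlist(species_map)
  switch(format,
         gro = read_gro(path, species_map),
         pdb = read_pdb(path, species_map))
}

resolve_species <- function(resnames, species_map) {
  if (is.null(species_map))
    return(resnames)   # identity map: residue name is the species
  unmapped <- setdiff(unique(resnames), names(species_map))
  if (length(unmapped))
    stop("species map does not cover molecule name(s): ",
         paste(unmapped, collapse = ", "))
  unname(species_map[resnames])
}

build_topology <- function(resid, resname, bead, species_map) {
  mol_id <- cumsum(c(TRUE, resid[-1] != resid[-length(resid)] |
                           resname[-1] != resname[-length(resname)]))
  particles <- data.frame(particle_id = seq_along(bead), bead = bead,
                          molecule_id = mol_id)
  first <- !duplicated(mol_id)
  species <- resolve_species(resname[first], species_map)
  molecules <- data.frame(molecule_id = mol_id[first], species = species)
  calpha <- integer(0)
  if (!is.null(species_map)) {
    ca_res <- names(species_map)[species_map == "CA"]
    if (length(ca_res))
      calpha <- which(resname %in% ca_res & bead %in% c("CA", "BB"))
  }
  topology(particles, molecules, calpha)
}

read_gro <- function(path, species_map = NULL) {
  lines <- readLines(path)
  frames <- list(); boxes <- list(); times <- numeric(0)
  i <- 1; fidx <- 0
  top <- NULL
  while (i <= length(lines)) {
    title <- lines[i]
    natoms <- as.integer(trimws(lines[i + 1]))
    if (is.na(natoms)) stop("malformed GRO atom-count line at line ", i + 1)
    atom_lines <- lines[(i + 2):(i + 1 + natoms)]
    box_line <- strsplit(trimws(lines[i + 2 + natoms]), "\\s+")[[1]]
    bv <- as.numeric(box_line)
    if (length(bv) < 3 || any(is.na(bv[1:3])))
      stop("missing or malformed GRO box line (analyses require a periodic box)")
    if (length(bv) > 3 && any(abs(bv[-(1:3)]) > 1e-9))
      stop("triclinic GRO box not supported (orthorhombic boxes only)")
    fidx <- fidx + 1
    resid <- as.integer(substr(atom_lines, 1, 5))
    resname <- trimws(substr(atom_lines, 6, 10))
    bead <- trimws(substr(atom_lines, 11, 15))
    x <- as.numeric(substr(atom_lines, 21, 28))
    y <- as.numeric(substr(atom_lines, 29, 36))
    z <- as.numeric(substr(atom_lines, 37, 44))
    if (fidx == 1) top <- build_topology(resid, resname, bead, species_map)
    frames[[fidx]] <- cbind(x, y, z)
    boxes[[fidx]] <- bv[1:3]
    tmatch <- regmatches(title, regexpr("t=\\s*[0-9.eE+-]+", title))
    # GRO title time stamps are ps by convention; stored internally as ns
    times[fidx] <- if (length(tmatch))
      as.numeric(sub("t=\\s*", "", tmatch)) / 1000 else fidx - 1
    i <- i + 3 + natoms
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1
  }
  coords <- array(unlist(frames), c(nrow(frames[[1]]), 3, fidx))
  trajectory(top, coords, times, do.call(rbind, boxes))
}

read_pdb <- function(path, species_map = NULL) {
  lines <- readLines(path)
  cryst <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cryst))
    stop("PDB lacks a CRYST1 record (analyses require a periodic box)")
  box_A <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                        substr(cryst[1], 25, 33)))
  atom_idx <- grep("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (!length(atom_idx)) stop("no ATOM/HETATM records in ", path)
  n_models <- max(1L, length(model_starts))
  per_model <- length(atom_idx) / n_models
  if (per_model != round(per_model))
    stop("models have unequal atom counts")
  al <- lines[atom_idx]
  bead <- trimws(substr(al, 13, 16))
  resname <- trimws(substr(al, 18, 21))
  resid <- as.integer(substr(al, 23, 26))
  x <- as.numeric(substr(al, 31, 38)) / 10
  y <- as.numeric(substr(al, 39, 46)) / 10
  z <- as.numeric(substr(al, 47, 54)) / 10
  sel <- seq_len(per_model)
  top <- build_topology(resid[sel], resname[sel], bead[sel], species_map)
  coords <- array(NA_real_, c(per_model, 3, n_models))
  for (m in seq_len(n_models)) {
    rows <- (m - 1) * per_model + sel
    coords[, , m] <- cbind(x[rows], y[rows], z[rows])
  }
  trajectory(top, coords, seq_len(n_models) - 1, box_A / 10)
}

#' Write a trajectory to GRO, PDB or the internal columnar container
#'
#' Output is bit-stable for fixed input: no timestamps or hostnames are
#' embedded in data records.  Multi-frame trajectories become
#' concatenated GRO frames or PDB MODEL/ENDMDL blocks.
#'
#' @param traj a [trajectory].
#' @param path output file path.
#' @param format `"gro"`, `"pdb"` or `"internal"` (tab-separated columnar
#'   text with a `#`-prefixed metadata header); guessed from the
#'   extension when missing (`.tsv` for internal).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gro", "pdb")) ext else "internal"
  }
  format <- match.arg(format, c("gro", "pdb", "internal"))
  switch(format,
         gro = write_gro(traj, path),
         pdb = write_pdb(traj, path),
         internal = write_internal(traj, path))
  invisible(path)
}

write_gro <- function(traj, path) {
  top <- traj$topology
  con <- file(path, "w"); on.exit(close(con))
  resname <- top$molecules$species[match(top$particles$molecule_id,
                                         top$molecules$molecule_id)]
  for (f in seq_len(n_frames(traj))) {
    xyz <- matrix(traj$coords[, , f], ncol = 3)
    if (any(xyz >= 10000 | xyz <= -1000))
      stop("coordinates exceed GRO fixed-column width (need -1000 < x < 10000 nm)")
    writeLines(sprintf("membranekit frame, t= %.6f", traj$times[f] * 1000), con)
    writeLines(sprintf("%5d", nrow(xyz)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       top$particles$molecule_id %% 100000L,
                       substr(resname, 1, 5),
                       substr(top$particles$bead, 1, 5),
                       top$particles$particle_id %% 100000L,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f",
                       traj$box[f, 1], traj$box[f, 2], traj$box[f, 3]), con)
  }
}

write_pdb <- function(traj, path) {
  top <- traj$topology
  con <- file(path, "w"); on.exit(close(con))
  resname <- top$molecules$species[match(top$particles$molecule_id,
                                         top$molecules$molecule_id)]
  b <- traj$box[1, ] * 10
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    b[1], b[2], b[3], 90, 90, 90), con)
  multi <- n_frames(traj) > 1
  for (f in seq_len(n_frames(traj))) {
    if (multi) writeLines(sprintf("MODEL %8d", f), con)
    xyz <- matrix(traj$coords[, , f], ncol = 3) * 10
    writeLines(sprintf(
      "ATOM  %5d %-4s%-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00",
      top$particles$particle_id %% 100000L,
      substr(top$particles$bead, 1, 4),
      substr(resname, 1, 4),
      top$particles$molecule_id %% 10000L,
      xyz[, 1], xyz[, 2], xyz[, 3]), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

write_internal <- function(traj, path) {
  top <- traj$topology
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# membranekit trajectory container v1", con)
  writeLines(paste0("# species: ", paste(top$species, collapse = ",")), con)
  if (length(top$protein_calpha))
    writeLines(paste0("# protein_calpha: ",
                      paste(top$protein_calpha, collapse = ",")), con)
  writeLines(paste("frame", "time_ns", "box_x", "box_y", "box_z",
                   "particle_id", "bead", "molecule_id", "species",
                   "x", "y", "z", sep = "\t"), con)
  species <- top$molecules$species[match(top$particles$molecule_id,
                                         top$molecules$molecule_id)]
  for (f in seq_len(n_frames(traj))) {
    xyz <- matrix(traj$coords[, , f], ncol = 3)
    writeLines(paste(f, format_exact(traj$times[f]),
                     format_exact(traj$box[f, 1]),
                     format_exact(traj$box[f, 2]),
                     format_exact(traj$box[f, 3]),
                     top$particles$particle_id, top$particles$bead,
                     top$particles$molecule_id, species,
                     format_exact(xyz[, 1]), format_exact(xyz[, 2]),
                     format_exact(xyz[, 3]), sep = "\t"), con)
  }
}

# full-precision decimal text that round-trips doubles exactly
format_exact <- function(x) formatC(x, digits = 17, format = "g")

#' Read the internal columnar trajectory container
#' @param path file written by [write_trajectory] with `format = "internal"`.
#' @return a [trajectory] with exact float round-trip.
#' @export
read_internal <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  calpha <- integer(0)
  ca_line <- grep("# protein_calpha:", hdr, value = TRUE)
  if (length(ca_line))
    calpha <- as.integer(strsplit(sub(".*: ", "", ca_line), ",")[[1]])
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         colClasses = c("integer", "numeric", "numeric",
                                        "numeric", "numeric", "integer",
                                        "character", "integer", "character",
                                        "numeric", "numeric", "numeric"))
  f1 <- d[d$frame == 1L, ]
  top <- topology(
    data.frame(particle_id = f1$particle_id, bead = f1$bead,
               molecule_id = f1$molecule_id),
    data.frame(molecule_id = f1$molecule_id[!duplicated(f1$molecule_id)],
               species = f1$species[!duplicated(f1$molecule_id)]),
    calpha)
  nf <- max(d$frame); np <- nrow(f1)
  ord <- order(d$frame, d$particle_id)
  d <- d[ord, ]
  coords <- array(NA_real_, c(np, 3, nf))
  coords[, 1, ] <- d$x; coords[, 2, ] <- d$y; coords[, 3, ] <- d$z
  first <- !duplicated(d$frame)
  trajectory(top, coords, d$time_ns[first],
             cbind(d$box_x[first], d$box_y[first], d$box_z[first]))
}

#' Write / read a species map (YAML dialect)
#'
#' A sidecar key-value file mapping residue/molecule names to lipid
#' species or `"CA"` for protein C-alpha sites.
#'
#' @param map named character vector or list.
#' @param path file path.
#' @return `path` (write) or a named character vector (read).
#' @export
write_species_map <- function(map, path) {
  yaml::write_yaml(as.list(map), path)
  invisible(path)
}

#' @rdname write_species_map
#' @export
read_species_map <- function(path) {
  unlist(yaml::read_yaml(path))
}
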