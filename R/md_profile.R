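# Conformation-level metrics from atomic coordinates: interfacial density
# profiles, mass-center distances, contact counts, RMSD, and comparison of
# simulation-derived density profiles with reflectivity-derived
# volume-fraction profiles.

#' Construct an atom set
#'
#' Coordinates, masses and optional labels/group tags for one conformation.
#' Groups distinguish e.g. "protein" from "surface" atoms.
#'
#' @param xyz numeric matrix n x 3, Angstrom
#' @param mass atomic masses, amu (> 0)
#' @param label optional per-atom labels (element/residue)
#' @param group optional per-atom group tags
#' @return object of class `atom_set`
#' @export
atom_set <- function(xyz, mass, label = NULL, group = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) >= 1, all(is.finite(xyz)),
            length(mass) == nrow(xyz), all(is.finite(mass)), all(mass > 0))
  if (!is.null(label)) stopifnot(length(label) == nrow(xyz))
  if (!is.null(group)) stopifnot(length(group) == nrow(xyz))
  colnames(xyz) <- c("x", "y", "z")
  structure(list(xyz = xyz, mass = as.numeric(mass), label = label,
                 group = group), class = "atom_set")
}

#' @export
print.atom_set <- function(x, ...) {
  cat(sprintf("<atom_set> %d atoms, total mass %.3g amu", nrow(x$xyz), sum(x$mass)))
  if (!is.null(x$group)) cat(" [groups: ", paste(unique(x$group), collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Subset an atom set by group tag
#'
#' @param atoms an `atom_set`
#' @param group group tag to keep
#' @return an `atom_set`
#' @export
atom_group <- function(atoms, group) {
  stopifnot(inherits(atoms, "atom_set"), !is.null(atoms$group))
  keep <- atoms$group == group
  if (!any(keep)) stop("no atoms in group '", group, "'")
  atom_set(atoms$xyz[keep, , drop = FALSE], atoms$mass[keep],
           label = atoms$label[keep], group = atoms$group[keep])
}

#' Read atoms from a PDB file
#'
#' Parses ATOM/HETATM records via `bio3d`, assigns element masses with
#' `bio3d::atom2mass`, and tags all atoms with one group.
#'
#' @param path PDB file
#' @param group group tag applied to all atoms (default "protein")
#' @return an `atom_set`
#' @export
read_pdb_atoms <- function(path, group = "protein") {
  pdb <- bio3d::read.pdb(path)
  xyz <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  symb <- bio3d::atom2ele(pdb)
  ev <- new.env()
  utils::data("elements", package = "bio3d", envir = ev)
  mass <- ev$elements$mass[match(symb, ev$elements$symb)]
  if (any(is.na(mass)))
    stop("unknown element(s): ", paste(unique(symb[is.na(mass)]), collapse = ", "))
  atom_set(xyz, mass, label = pdb$atom$elety,
           group = rep(group, nrow(xyz)))
}

#' Read atoms from a plain XYZ-with-mass table
#'
#' Whitespace- or comma-delimited text with columns x, y, z, mass and
#' optional label and group columns (header optional; `#` comments
#' allowed).
#'
#' @param path input file
#' @return an `atom_set`
#' @export
read_xyz_mass <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  sep <- if (grepl(",", body[1])) "," else ""
  has_header <- grepl("[A-Za-z]", strsplit(trimws(body[1]),
                                           if (sep == ",") "," else "\\s+")[[1]][1])
  tab <- read.table(text = body, sep = sep, header = has_header,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("need at least columns x, y, z, mass")
  if (!has_header) names(tab)[1:4] <- c("x", "y", "z", "mass")
  atom_set(as.matrix(tab[, c("x", "y", "z")]), tab$mass,
           label = tab$label, group = tab$group)
}

#' Locate the surface plane of a surface-tagged atom set
#'
#' The surface plane is the z of the topmost surface-atom layer (max z
#' among surface-tagged atoms), since distances are measured from the SiO2
#' surface.
#'
#' @param atoms an `atom_set` containing a "surface" group (or pass the
#'   surface atoms directly)
#' @return z of the surface plane, Angstrom
#' @export
surface_plane <- function(atoms) {
  s <- if (!is.null(atoms$group) && any(atoms$group == "surface"))
    atom_group(atoms, "surface") else atoms
  max(s$xyz[, "z"])
}

#' Mass density profile along the surface normal
#'
#' Histogram of atomic mass along z - surface_z, expressed as mass per
#' Angstrom of height per unit area (amu / Angstrom / area). Conserves
#' total mass under any binning. Atoms below the surface plane are flagged
#' with a warning but still binned.
#'
#' @param atoms an `atom_set` (use [atom_group()] to select)
#' @param surface_z z of the surface plane, Angstrom
#' @param bin_width Angstrom (> 0)
#' @param area lateral area used for normalization, Angstrom^2 (default 1)
#' @param z_range optional c(lo, hi) range of z - surface_z to cover
#' @return object of class `density_profile` with `z` (bin centers),
#'   `density`, `normalized` (unit-area variant), `bin_width`, `total_mass`
#' @export
density_profile <- function(atoms, surface_z = 0, bin_width = 1, area = 1,
                            z_range = NULL) {
  stopifnot(inherits(atoms, "atom_set"), bin_width > 0, area > 0)
  zz <- atoms$xyz[, "z"] - surface_z
  if (any(zz < 0))
    warning(sum(zz < 0), " atom(s) below the surface plane; binned anyway")
  if (is.null(z_range))
    z_range <- c(floor(min(zz) / bin_width) * bin_width,
                 ceiling(max(zz) / bin_width) * bin_width)
  edges <- seq(z_range[1], z_range[2] + bin_width * 0.5, by = bin_width)
  if (max(zz) >= max(edges)) edges <- c(edges, max(edges) + bin_width)
  idx <- findInterval(zz, edges, rightmost.closed = TRUE)
  m <- vapply(seq_len(length(edges) - 1),
              function(i) sum(atoms$mass[idx == i]), 0)
  dens <- m / (bin_width * area)
  tot <- sum(m)
  structure(list(z = (head_(edges, -1) + tail_(edges, -1)) / 2,
                 density = dens,
                 normalized = if (tot > 0) dens / (tot / area) else dens,
                 bin_width = bin_width, total_mass = tot, area = area),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> %d bins of %.2g A, total mass %.4g amu\n",
              length(x$z), x$bin_width, x$total_mass))
  invisible(x)
}

#' Mass-center-to-surface distance of an atom set
#'
#' Mass-weighted mean of z - surface_z over the selected atoms.
#'
#' @param atoms an `atom_set`; if it carries group tags, the "protein"
#'   group is used when present
#' @param surface_z z of the surface plane, Angstrom
#' @return distance, Angstrom
#' @export
md_mass_center_distance <- function(atoms, surface_z = 0) {
  stopifnot(inherits(atoms, "atom_set"))
  if (!is.null(atoms$group) && any(atoms$group == "protein") &&
      !all(atoms$group == "protein"))
    atoms <- atom_group(atoms, "protein")
  sum(atoms$mass * (atoms$xyz[, "z"] - surface_z)) / sum(atoms$mass)
}

#' Count protein atoms in contact with the surface
#'
#' Number of distinct protein atoms having at least one surface atom within
#' the Euclidean cutoff (closed boundary: an atom exactly at the cutoff
#' counts). Implemented with a cell list over the surface atoms; no
#' periodicity is applied.
#'
#' @param protein an `atom_set` of protein atoms
#' @param surface an `atom_set` of surface atoms
#' @param cutoff Angstrom (> 0, default 5 = 0.5 nm)
#' @return integer count
#' @export
contact_count <- function(protein, surface, cutoff = 5) {
  stopifnot(cutoff > 0)
  if (nrow(protein$xyz) == 0 || nrow(surface$xyz) == 0) {
    warning("empty protein or surface group: contact count is 0")
    return(0L)
  }
  sp <- surface$xyz
  pp <- protein$xyz
  cell <- function(m) floor(m / cutoff)
  sc <- cell(sp)
  skey <- paste(sc[, 1], sc[, 2], sc[, 3])
  cells <- split(seq_len(nrow(sp)), skey)
  pc <- cell(pp)
  cut2 <- cutoff^2
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  n <- 0L
  for (i in seq_len(nrow(pp))) {
    keys <- paste(pc[i, 1] + off[, 1], pc[i, 2] + off[, 2], pc[i, 3] + off[, 3])
    cand <- unlist(cells[keys], use.names = FALSE)
    if (is.null(cand) || !length(cand)) next
    d2 <- (sp[cand, 1] - pp[i, 1])^2 + (sp[cand, 2] - pp[i, 2])^2 +
      (sp[cand, 3] - pp[i, 3])^2
    if (any(d2 <= cut2)) n <- n + 1L
  }
  n
}

#' Root-mean-square deviation between two conformations
#'
#' sqrt(mean squared deviation) over paired atoms. With
#' `superpose = TRUE` the second set is first optimally aligned to the
#' first by rigid-body rotation + translation (Kabsch superposition via
#' SVD, optionally mass-weighted), so the superposed RMSD never exceeds
#' the raw one.
#'
#' @param a,b n x 3 coordinate matrices or `atom_set`s with equal atom
#'   counts and consistent ordering
#' @param superpose logical
#' @param weights optional per-atom weights (e.g. masses)
#' @return RMSD, Angstrom
#' @export
rmsd <- function(a, b, superpose = FALSE, weights = NULL) {
  A <- if (inherits(a, "atom_set")) a$xyz else as.matrix(a)
  B <- if (inherits(b, "atom_set")) b$xyz else as.matrix(b)
  if (nrow(A) != nrow(B)) stop("mismatched atom counts")
  if (is.null(weights)) weights <- rep(1, nrow(A))
  w <- weights / sum(weights)
  if (superpose) {
    ca <- colSums(A * w); cb <- colSums(B * w)
    A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
    H <- t(B0 * w) %*% A0
    s <- svd(H)
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    B <- B0 %*% t(R)
    A <- A0
  }
  sqrt(sum(w * rowSums((A - B)^2)))
}

#' Extent of a profile: z containing a given mass fraction
#'
#' Smallest z at which the cumulative (trapezoid) integral of the profile
#' reaches `frac` of its total.
#'
#' @param z,y profile grid and values (y >= 0)
#' @param frac mass fraction (default 0.95)
#' @return z value, Angstrom
#' @export
profile_extent <- function(z, y, frac = 0.95) {
  stopifnot(length(z) == length(y), frac > 0, frac <= 1)
  seg <- diff(z) * (head_(y, -1) + tail_(y, -1)) / 2
  cum <- c(0, cumsum(seg))
  tot <- cum[length(cum)]
  if (tot <= 0) stop("empty profile")
  approx(cum / tot, z, xout = frac, ties = "ordered")$y
}

#' Compare a simulation density profile with a reflectivity profile
#'
#' Both profiles are scaled to unit area on a common grid (the density
#' profile from coordinates, the volume-fraction profile from a slab fit),
#' then compared by mass-center difference, 95%-mass extents, and the
#' normalized overlap integral of the two unit-area curves (1 for
#' identical shapes, 0 for disjoint supports).
#'
#' @param md a `density_profile`
#' @param nr an `nr_profile` (volume-fraction profile)
#' @return object of class `profile_comparison`
#' @export
compare_profiles <- function(md, nr) {
  stopifnot(inherits(md, "density_profile"), inherits(nr, "nr_profile"))
  grid <- seq(min(md$z[1], nr$z[1]), max(md$z[length(md$z)], nr$z[length(nr$z)]),
              length.out = 2048)
  p1 <- approx(md$z, md$density, xout = grid, yleft = 0, yright = 0)$y
  p2 <- approx(nr$z, nr$phi, xout = grid, yleft = 0, yright = 0)$y
  a1 <- trapz_(grid, p1); a2 <- trapz_(grid, p2)
  if (a1 <= 0 || a2 <= 0) stop("profile with zero integral")
  p1 <- p1 / a1; p2 <- p2 / a2
  c1 <- trapz_(grid, grid * p1); c2 <- trapz_(grid, grid * p2)
  structure(list(
    center_md = c1, center_nr = c2, center_diff = c1 - c2,
    extent_md = profile_extent(grid, p1), extent_nr = profile_extent(grid, p2),
    overlap = trapz_(grid, pmin(p1, p2))
  ), class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf(paste0("<profile_comparison> centers %.1f (MD) vs %.1f (NR) A ",
                     "(diff %.2f A); 95%% extents %.1f vs %.1f A; overlap %.3f\n"),
              x$center_md, x$center_nr, x$center_diff,
              x$extent_md, x$extent_nr, x$overlap))
  invisible(x)
}
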