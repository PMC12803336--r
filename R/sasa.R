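# Solvent accessible surface area (Shrake-Rupley) and relative SASA.
#
# Interface residues are defined through the change in relative SASA on
# complex formation: a residue whose rSASA drops when the partner chain is
# present must be burying surface at the interface.

# Heavy-atom van der Waals radii (Angstrom), Bondi set; DEFAULT covers
# uncommon elements.
VDW_RADII <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  DEFAULT = 1.70
)

# Reference per-residue SASA (Angstrom^2) in an extended Gly-X-Gly tripeptide
# (theoretical maximum accessibility values of Tien et al. 2013).
GXG_REFERENCE_SASA <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0
)

# deterministic quasi-uniform unit sphere points (golden-spiral lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(elements) {
  r <- VDW_RADII[toupper(elements)]
  r[is.na(r)] <- VDW_RADII[["DEFAULT"]]
  unname(r)
}

# per-atom accessible area for an arbitrary heavy-atom set
atom_sasa <- function(xyz, elements, probe_radius = 1.4, n_points = 960L) {
  n <- nrow(xyz)
  rad <- atom_radii(elements) + probe_radius
  pts <- sphere_points(n_points)
  area <- numeric(n)
  max_r <- max(rad)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < rad[i] + max_r & di > 0)
    surf <- xyz[rep(i, n_points), , drop = FALSE] + pts * rad[i]
    if (length(nb) > 0L) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
          (surf[, 3] - xyz[j, 3])^2
        acc <- acc & (dj2 >= rad[j]^2)
        if (!any(acc)) break
      }
      frac <- sum(acc) / n_points
    } else {
      frac <- 1
    }
    area[i] <- frac * 4 * pi * rad[i]^2
  }
  area
}

#' Per-residue solvent accessible surface area
#'
#' Shrake-Rupley SASA with a deterministic golden-spiral point lattice
#' (default 960 points per atom) and Bondi heavy-atom radii, summed per
#' residue. All chains present in `structure` occlude each other, so passing
#' a single chain gives the isolated-monomer areas.
#'
#' @param structure A `dimer_structure`, or any atom data.frame with the same
#'   columns (a single chain is allowed).
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param n_points Sphere points per atom (default 960).
#' @return Named numeric vector of areas (Angstrom^2), one entry per residue,
#'   named `chain|resno|ins`.
#' @export
residue_sasa <- function(structure, probe_radius = 1.4, n_points = 960L) {
  if (probe_radius <= 0) stop("probe_radius must be positive")
  if (nrow(structure) == 0L) stop("structure has no atoms")
  a <- atom_sasa(coords(structure), structure$element, probe_radius, n_points)
  keys <- atom_residue_key(structure)
  out <- tapply(a, factor(keys, levels = unique(keys)), sum)
  v <- as.numeric(out)
  names(v) <- names(out)
  v
}

#' Per-residue relative solvent accessibility
#'
#' rSASA = SASA of the residue in its structural context divided by the SASA
#' of the same residue type in an extended Gly-X-Gly reference tripeptide.
#'
#' @inheritParams residue_sasa
#' @return Named numeric vector of dimensionless rSASA values per residue.
#' @export
relative_sasa <- function(structure, probe_radius = 1.4, n_points = 960L) {
  areas <- residue_sasa(structure, probe_radius, n_points)
  keys <- unique(atom_residue_key(structure))
  restype <- structure$resid[match(keys, atom_residue_key(structure))]
  ref <- GXG_REFERENCE_SASA[toupper(restype)]
  if (anyNA(ref)) {
    bad <- unique(restype[is.na(ref)])
    stop("no reference SASA for residue type(s): ", paste(bad, collapse = ", "))
  }
  areas / unname(ref)
}

#' Interface residues by change in relative SASA
#'
#' A residue is at the interface iff its rSASA in the bound dimer is strictly
#' lower than in the isolated monomer taken in the bound conformation
#' (delta-rSASA < 0): burying any surface on complexation flags the residue.
#'
#' @param dimer A `dimer_structure`.
#' @param probe_radius Solvent probe radius in Angstrom.
#' @param n_points Sphere points per atom.
#' @return List with `receptor_residues` and `ligand_residues`, character
#'   vectors of residue keys (`chain|resno|ins`); either may be empty.
#' @export
interface_residues <- function(dimer, probe_radius = 1.4, n_points = 960L) {
  bound <- relative_sasa(dimer, probe_radius, n_points)
  out <- list()
  for (role in c("receptor", "ligand")) {
    ch <- attr(dimer, role)
    mono <- chain_atoms(dimer, ch)
    free <- relative_sasa(mono, probe_radius, n_points)
    keys <- names(free)
    delta <- bound[keys] - free
    out[[paste0(role, "_residues")]] <- keys[delta < 0]
  }
  out
}
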