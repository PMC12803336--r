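# The DockQ model-quality metric and its components, plus the rSASA-based
# interface RMSD used for interpolated monomer conformations.
#
# DockQ = (Fnat + 1/(1+(LRMSD/d1)^2) + 1/(1+(iRMSD/d2)^2)) / 3
# with d1 = 8.5 A scaling the ligand RMSD and d2 = 1.5 A scaling the
# interface RMSD, so that 0 <= DockQ <= 1 and DockQ = 1 only for a model
# identical to the target.

DOCKQ_D1 <- 8.5
DOCKQ_D2 <- 1.5
DOCKQ_POSITIVE_CUTOFF <- 0.23

#' Native cross-chain contacts
#'
#' All cross-chain heavy-atom pairs separated by strictly less than `cutoff`
#' (default 5 Angstrom), identified by their (chain, residue, atom name)
#' identities so they can be looked up in any model sharing the target's
#' atoms.
#'
#' @param native A `dimer_structure`.
#' @param cutoff Contact cutoff in Angstrom (default 5).
#' @param by_residue If TRUE, collapse atom pairs to unique residue pairs
#'   (the convention of the original DockQ implementation); default FALSE
#'   keeps heavy-atom pairs.
#' @return Character vector of contact identifiers.
#' @export
native_contacts <- function(native, cutoff = 5, by_residue = FALSE) {
  rec <- chain_atoms(native, receptor_chain(native))
  lig <- chain_atoms(native, ligand_chain(native))
  d2 <- cross_dist2(coords(rec), coords(lig))
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(character(0))
  if (by_residue) {
    ids <- paste(atom_residue_key(rec)[hit[, 1]],
                 atom_residue_key(lig)[hit[, 2]], sep = "::")
  } else {
    ids <- paste(atom_key(rec)[hit[, 1]], atom_key(lig)[hit[, 2]], sep = "::")
  }
  unique(ids)
}

#' Fraction of native contacts reproduced by a model
#'
#' @param model,native `dimer_structure` objects sharing atom identities.
#' @param cutoff Contact cutoff in Angstrom (default 5).
#' @param by_residue Residue-pair contact mode (see [native_contacts()]).
#' @return Fnat in `[0, 1]`.
#' @export
fnat <- function(model, native, cutoff = 5, by_residue = FALSE) {
  nat <- native_contacts(native, cutoff, by_residue)
  if (length(nat) == 0L) stop("native structure has no cross-chain contacts")
  mod <- native_contacts(model, cutoff, by_residue)
  length(intersect(nat, mod)) / length(nat)
}

#' Ligand backbone RMSD after receptor superposition
#'
#' Superposes the model's receptor backbone (N, CA, C, O) onto the native
#' receptor backbone, then reports the RMSD over the ligand backbone atoms
#' with no further fitting.
#'
#' @param model,native `dimer_structure` objects sharing atom identities.
#' @return LRMSD in Angstrom.
#' @export
lrmsd <- function(model, native) {
  rec <- receptor_chain(native)
  lig <- ligand_chain(native)
  mrec <- backbone_atoms(model, rec)
  nrec <- backbone_atoms(native, rec)
  mr <- match_atoms(mrec, nrec)
  tf <- kabsch_superpose(coords(mrec)[mr$a, , drop = FALSE],
                         coords(nrec)[mr$b, , drop = FALSE])
  mlig <- backbone_atoms(model, lig)
  nlig <- backbone_atoms(native, lig)
  ml <- match_atoms(mlig, nlig)
  moved <- apply_transform(coords(mlig)[ml$a, , drop = FALSE], tf)
  rmsd_between(moved, coords(nlig)[ml$b, , drop = FALSE])
}

# residues of the native with any heavy atom < cutoff from the other chain
dockq_interface_keys <- function(native, cutoff = 10) {
  rec <- chain_atoms(native, receptor_chain(native))
  lig <- chain_atoms(native, ligand_chain(native))
  d2 <- cross_dist2(coords(rec), coords(lig))
  near <- d2 < cutoff^2
  keys <- c(
    unique(atom_residue_key(rec)[rowSums(near) > 0]),
    unique(atom_residue_key(lig)[colSums(near) > 0])
  )
  keys
}

#' Interface backbone RMSD (DockQ convention)
#'
#' Interface residues are those of the native with any heavy atom strictly
#' closer than 10 Angstrom to the other chain; the backbone atoms of those
#' residues (in both structures) are superposed and their fit RMSD reported.
#'
#' @param model,native `dimer_structure` objects sharing atom identities.
#' @param cutoff Interface distance cutoff in Angstrom (default 10).
#' @return iRMSD in Angstrom.
#' @export
irmsd_dockq <- function(model, native, cutoff = 10) {
  keys <- dockq_interface_keys(native, cutoff)
  if (length(keys) == 0L) stop("native structure has an empty interface")
  nbb <- native[atom_residue_key(native) %in% keys, , drop = FALSE]
  nbb <- nbb[trimws(nbb$elety) %in% BACKBONE_ATOMS, , drop = FALSE]
  mbb <- model[atom_key(model) %in% atom_key(nbb), , drop = FALSE]
  m <- match_atoms(mbb, nbb)
  kabsch_superpose(coords(mbb)[m$a, , drop = FALSE],
                   coords(nbb)[m$b, , drop = FALSE])$rmsd
}

#' DockQ structural similarity of a model to its target
#'
#' Composite score averaging Fnat, a scaled ligand-RMSD term and a scaled
#' interface-RMSD term. DockQ = 1 iff the model reproduces the target
#' exactly; models with DockQ >= 0.23 are conventionally called positive
#' (acceptable or better).
#'
#' @param model,native `dimer_structure` objects sharing atom identities.
#' @param by_residue Residue-pair Fnat mode (see [native_contacts()]).
#' @return Object of class `dockq_result`: list with `fnat`, `lrmsd`,
#'   `irmsd`, `dockq`, `d1`, `d2`.
#' @export
dockq <- function(model, native, by_residue = FALSE) {
  fn <- fnat(model, native, by_residue = by_residue)
  lr <- lrmsd(model, native)
  ir <- irmsd_dockq(model, native)
  q <- (fn + 1 / (1 + (lr / DOCKQ_D1)^2) + 1 / (1 + (ir / DOCKQ_D2)^2)) / 3
  structure(
    list(fnat = fn, lrmsd = lr, irmsd = ir, dockq = q,
         d1 = DOCKQ_D1, d2 = DOCKQ_D2),
    class = "dockq_result"
  )
}

#' @export
print.dockq_result <- function(x, ...) {
  cat(sprintf("DockQ %.4f  (Fnat %.4f, LRMSD %.3f A, iRMSD %.3f A)\n",
              x$dockq, x$fnat, x$lrmsd, x$irmsd))
  invisible(x)
}

#' Interface RMSD from delta-rSASA interface residues
#'
#' The interface residues are defined on the bound reference dimer by the
#' drop in relative SASA on complexation. Each monomer conformation's
#' interface C-alpha set is superposed onto its bound counterpart; the
#' squared displacements of both monomers are pooled:
#' iRMSD = sqrt((d1 + d2) / (N1 + N2)).
#'
#' @param conformation A `dimer_structure` (or two-chain atom table) holding
#'   both monomer conformations to compare against the bound reference.
#' @param bound_reference The bound dimer defining the interface.
#' @param interface Optional precomputed result of
#'   [interface_residues()] on `bound_reference`, to avoid recomputing SASA.
#' @return iRMSD in Angstrom.
#' @export
irmsd_rsasa <- function(conformation, bound_reference, interface = NULL) {
  if (is.null(interface)) interface <- interface_residues(bound_reference)
  keys <- c(interface$receptor_residues, interface$ligand_residues)
  if (length(keys) == 0L) stop("bound reference has an empty interface")
  total_d <- 0
  total_n <- 0L
  for (ch in c(receptor_chain(bound_reference), ligand_chain(bound_reference))) {
    bca <- ca_atoms(bound_reference, ch)
    bca <- bca[atom_residue_key(bca) %in% keys, , drop = FALSE]
    if (nrow(bca) == 0L) next
    cca <- conformation[atom_key(conformation) %in% atom_key(bca), , drop = FALSE]
    m <- match_atoms(cca, bca)
    if (length(m$a) < 3L) {
      moved <- coords(cca)[m$a, , drop = FALSE]
    } else {
      tf <- kabsch_core(coords(cca)[m$a, , drop = FALSE],
                        coords(bca)[m$b, , drop = FALSE])
      moved <- apply_transform(coords(cca)[m$a, , drop = FALSE], tf)
    }
    total_d <- total_d + sum(rowSums((moved - coords(bca)[m$b, , drop = FALSE])^2))
    total_n <- total_n + length(m$a)
  }
  if (total_n == 0L) stop("no interface C-alpha atoms to compare")
  sqrt(total_d / total_n)
}
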