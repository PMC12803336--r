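# PDB I/O and the internal two-chain heavy-atom representation.
#
# A dimer_structure is a data.frame of heavy-atom records (one row per atom)
# with columns chain, resno, ins, resid, elety, element, x, y, z, plus
# attributes "receptor" and "ligand" naming the two chains.

#' Construct a dimer structure from atom records
#'
#' Builds the internal two-chain heavy-atom representation used throughout the
#' package. Hydrogens (and deuterium) are removed, the invariants are checked,
#' and receptor/ligand chains are assigned by [assign_receptor_ligand()].
#'
#' @param atoms data.frame with columns `chain`, `resno`, `ins` (insertion
#'   code, `""` when absent), `resid` (3-letter residue name), `elety` (PDB
#'   atom name), `element` (element symbol), `x`, `y`, `z` (Angstrom).
#' @return An object of class `dimer_structure`: the heavy-atom data.frame
#'   with attributes `receptor` and `ligand`.
#' @export
dimer_structure <- function(atoms) {
  needed <- c("chain", "resno", "ins", "resid", "elety", "element", "x", "y", "z")
  miss <- setdiff(needed, names(atoms))
  if (length(miss) > 0L) {
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[, needed]
  atoms$ins[is.na(atoms$ins)] <- ""
  atoms <- atoms[!(toupper(atoms$element) %in% c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no heavy atoms in structure")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  chains <- unique(atoms$chain)
  if (length(chains) != 2L) {
    stop("structure must contain exactly two chains, found ", length(chains))
  }
  rownames(atoms) <- NULL
  s <- structure(atoms, class = c("dimer_structure", "data.frame"))
  assign_receptor_ligand(s)
}

#' Assign receptor and ligand chains
#'
#' The receptor is the chain with more residues; ties are broken by
#' lexicographic chain id. The rule is deterministic, so an assignment made on
#' a target carries over unchanged to every re-read of its docked models.
#'
#' @param structure A `dimer_structure`.
#' @return The structure with `receptor`/`ligand` attributes set.
#' @export
assign_receptor_ligand <- function(structure) {
  chains <- sort(unique(structure$chain))
  nres <- vapply(chains, function(ch) {
    sub <- structure[structure$chain == ch, ]
    length(unique(paste(sub$resno, sub$ins)))
  }, integer(1))
  receptor <- chains[order(-nres, chains)][1L]
  ligand <- setdiff(chains, receptor)
  attr(structure, "receptor") <- receptor
  attr(structure, "ligand") <- ligand
  structure
}

#' Read a two-chain PDB structure
#'
#' Parses ATOM records from a PDB file into a [dimer_structure()]. HETATM
#' records, waters and ions are dropped; alternate locations other than `' '`
#' or `'A'` are dropped (single-conformer model); hydrogens are removed.
#'
#' @param path Path to a PDB file with exactly two protein chains.
#' @return A `dimer_structure`.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  at <- at[is.na(at$alt) | at$alt %in% c("", " ", "A"), , drop = FALSE]
  elem <- at$elesy
  # fall back on the atom-name convention when the element column is blank
  blank <- is.na(elem) | elem == ""
  elem[blank] <- substr(gsub("^[0-9]", "", trimws(at$elety[blank])), 1L, 1L)
  atoms <- data.frame(
    chain = at$chain,
    resno = at$resno,
    ins = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    elety = at$elety,
    element = toupper(elem),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  dimer_structure(atoms)
}

#' Write a structure as PDB ATOM records
#'
#' Writes standard wwPDB v3.3 ATOM records; a read/write round trip preserves
#' atoms, names, chains and coordinates to format precision (1e-3 Angstrom).
#'
#' @param structure A `dimer_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  if (!inherits(structure, "dimer_structure")) structure <- dimer_structure(structure)
  if (nrow(structure) == 0L) stop("empty structure")
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(structure[, c("x", "y", "z")]))),
    resno = structure$resno,
    resid = structure$resid,
    eleno = seq_len(nrow(structure)),
    elety = structure$elety,
    chain = structure$chain,
    insert = ifelse(structure$ins == "", "", structure$ins)
  )
  invisible(path)
}

#' @export
print.dimer_structure <- function(x, ...) {
  rec <- attr(x, "receptor")
  lig <- attr(x, "ligand")
  cat("Two-chain heavy-atom structure\n")
  for (ch in c(rec, lig)) {
    sub <- x[x$chain == ch, ]
    cat(sprintf(
      "  chain %s: %d residues, %d heavy atoms%s\n",
      ch, length(unique(paste(sub$resno, sub$ins))), nrow(sub),
      if (ch == rec) "  (receptor)" else "  (ligand)"
    ))
  }
  invisible(x)
}

# ---- internal coordinate helpers -------------------------------------------

# unique residue keys, in order of first appearance
residue_keys <- function(structure, chain = NULL) {
  s <- structure
  if (!is.null(chain)) s <- s[s$chain %in% chain, , drop = FALSE]
  unique(paste(s$chain, s$resno, s$ins, sep = "|"))
}

atom_residue_key <- function(structure) {
  paste(structure$chain, structure$resno, structure$ins, sep = "|")
}

atom_key <- function(structure) {
  paste(structure$chain, structure$resno, structure$ins, structure$elety, sep = "|")
}

coords <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}

chain_atoms <- function(structure, chain) {
  structure[structure$chain == chain, , drop = FALSE]
}

receptor_chain <- function(structure) attr(structure, "receptor")
ligand_chain <- function(structure) attr(structure, "ligand")

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

backbone_atoms <- function(structure, chain = NULL) {
  s <- structure
  if (!is.null(chain)) s <- s[s$chain %in% chain, , drop = FALSE]
  s[trimws(s$elety) %in% BACKBONE_ATOMS, , drop = FALSE]
}

ca_atoms <- function(structure, chain = NULL) {
  s <- structure
  if (!is.null(chain)) s <- s[s$chain %in% chain, , drop = FALSE]
  s[trimws(s$elety) == "CA", , drop = FALSE]
}

# match two structures on shared atom identities (chain, residue, atom name);
# returns row indices into each, in a common order
match_atoms <- function(a, b) {
  ka <- atom_key(a)
  kb <- atom_key(b)
  common <- intersect(ka, kb)
  if (length(common) == 0L) stop("structures share no atom identities")
  list(a = match(common, ka), b = match(common, kb))
}
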