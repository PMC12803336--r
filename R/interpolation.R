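# Linear interpolation of monomer conformations between bound and unbound
# forms, and the interface-RMSD progression along the path.

#' Match bound and unbound conformations of one monomer
#'
#' Globally aligns the two sequences, removes trailing unaligned termini,
#' drops substituted (mismatched) residues, and drops residues whose
#' heavy-atom name sets differ between the two conformers, leaving an exact
#' atom-by-atom pairing. By default the unbound conformer is then
#' Kabsch-superposed onto the bound one, so the displacement field captures
#' internal deformation rather than global pose.
#'
#' @param bound,unbound Single-chain atom data.frames (columns as in a
#'   `dimer_structure`).
#' @param superpose Superpose unbound onto bound after matching (default
#'   TRUE).
#' @param min_identity Minimum sequence identity of the alignment (default
#'   0.3); below this the two structures are rejected as different proteins.
#' @return List of class `conformer_pair` with elements `bound` and
#'   `unbound` (atom tables with identical row counts and paired rows) and
#'   `n_atoms`.
#' @export
match_conformations <- function(bound, unbound, superpose = TRUE,
                                min_identity = 0.3) {
  bres <- residue_table(bound)
  ures <- residue_table(unbound)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(bres$aa, collapse = "")),
    Biostrings::AAString(paste(ures$aa, collapse = "")),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  pchars <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  schars <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  bi <- cumsum(pchars != "-")
  ui <- cumsum(schars != "-")
  aligned <- pchars != "-" & schars != "-"
  n_match <- sum(aligned & pchars == schars)
  # identity over the shorter chain, so gap-riddled alignments of unrelated
  # sequences cannot masquerade as near-identical
  identity <- n_match / min(nrow(bres), nrow(ures))
  if (identity < min_identity) {
    stop("sequence identity ", round(identity, 2), " below ", min_identity,
         ": not the same protein")
  }
  # matched residue pairs with identical amino acids (SNP positions dropped)
  same <- aligned & pchars == schars
  pairs <- cbind(bi[same], ui[same])
  bkeep <- integer(0)
  ukeep <- integer(0)
  for (r in seq_len(nrow(pairs))) {
    bidx <- which(atom_residue_key(bound) == bres$key[pairs[r, 1]])
    uidx <- which(atom_residue_key(unbound) == ures$key[pairs[r, 2]])
    bn <- trimws(bound$elety[bidx])
    un <- trimws(unbound$elety[uidx])
    if (length(bn) != length(un) || !setequal(bn, un) || anyDuplicated(bn)) next
    bkeep <- c(bkeep, bidx[order(bn)])
    ukeep <- c(ukeep, uidx[order(un)])
  }
  if (length(bkeep) == 0L) stop("no atoms could be paired")
  b <- bound[bkeep, , drop = FALSE]
  u <- unbound[ukeep, , drop = FALSE]
  rownames(b) <- rownames(u) <- NULL
  if (superpose && nrow(b) >= 3L) {
    tf <- kabsch_superpose(coords(u), coords(b))
    u[, c("x", "y", "z")] <- apply_transform(coords(u), tf)
  }
  structure(list(bound = b, unbound = u, n_atoms = nrow(b)),
            class = "conformer_pair")
}

# one-letter sequence and residue keys, in chain order
residue_table <- function(chain_atoms) {
  keys <- unique(atom_residue_key(chain_atoms))
  resid <- chain_atoms$resid[match(keys, atom_residue_key(chain_atoms))]
  aa <- vapply(resid, function(r) {
    a <- bio3d::aa321(r)
    if (is.na(a) || a == "X") "X" else a
  }, character(1))
  data.frame(key = keys, aa = unname(aa), stringsAsFactors = FALSE)
}

#' Displacement matrix between matched conformers
#'
#' Row i is the displacement of heavy atom i from its bound to its unbound
#' position. Pure per-atom subtraction: any pre-superposition must already
#' have been applied (see [match_conformations()]).
#'
#' @param pair A `conformer_pair`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
displacement_matrix <- function(pair) {
  coords(pair$unbound) - coords(pair$bound)
}

# RMS per-atom displacement: the |D| used for image spacing
displacement_norm <- function(D) {
  sqrt(mean(rowSums(D^2)))
}

#' Linearly interpolated conformations between bound and unbound
#'
#' Image n (0 <= n <= n_images) places every atom at
#' bound + (n / n_images) * displacement, so image 0 is the bound conformer
#' exactly and image n_images the (superposed) unbound conformer exactly.
#' With `n_images = "auto"` the image count starts at 6 and is raised until
#' the inter-image spacing |D| / n_images is at most 1 Angstrom.
#'
#' @param pair A `conformer_pair`.
#' @param n_images Number of intervals N_I (default 6), or `"auto"`.
#' @return List of class `interpolation_set` with `images` (list of atom
#'   tables indexed 0..N_I), `displacement`, `n_images`, `spacing`.
#' @export
interpolate_images <- function(pair, n_images = 6L) {
  D <- displacement_matrix(pair)
  nd <- displacement_norm(D)
  if (identical(n_images, "auto")) {
    n_images <- 6L
    while (nd / n_images > 1 && n_images < 10000L) n_images <- n_images + 1L
  }
  n_images <- as.integer(n_images)
  if (n_images < 1L) stop("n_images must be >= 1")
  base <- coords(pair$bound)
  images <- lapply(0:n_images, function(n) {
    img <- pair$bound
    img[, c("x", "y", "z")] <- base + (n / n_images) * D
    img
  })
  names(images) <- as.character(0:n_images)
  structure(list(
    images = images, displacement = D, n_images = n_images,
    spacing = nd / n_images
  ), class = "interpolation_set")
}

#' Interface-RMSD progression along an interpolation path
#'
#' For each image index n, assembles the two monomer images into one
#' conformation and computes the delta-rSASA interface RMSD against the
#' bound dimer (Eqs. of [irmsd_rsasa()]); iRMSD* is iRMSD normalized by its
#' value at the unbound endpoint, so iRMSD*(N_I) = 1.
#'
#' @param images_receptor,images_ligand `interpolation_set` objects for the
#'   two monomers (same `n_images`).
#' @param bound_dimer The bound `dimer_structure` defining the interface.
#' @return data.frame with columns `n`, `irmsd`, `irmsd_star`.
#' @export
irmsd_progression <- function(images_receptor, images_ligand, bound_dimer) {
  if (images_receptor$n_images != images_ligand$n_images) {
    stop("both monomers must use the same number of images")
  }
  iface <- interface_residues(bound_dimer)
  ni <- images_receptor$n_images
  vals <- vapply(0:ni, function(n) {
    conf <- rbind(images_receptor$images[[as.character(n)]],
                  images_ligand$images[[as.character(n)]])
    irmsd_rsasa(conf, bound_dimer, interface = iface)
  }, numeric(1))
  ref <- vals[ni + 1L]
  data.frame(
    n = 0:ni,
    irmsd = vals,
    irmsd_star = if (ref > 0) vals / ref else ifelse(vals == 0, 0, NA_real_)
  )
}
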