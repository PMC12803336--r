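# Physical interface features: heavy-atom contact count Nc and the SVM
# interface separability S.

#' Count cross-chain heavy-atom contacts
#'
#' Nc is the number of heavy-atom pairs, one atom in each chain, whose
#' Euclidean separation is strictly less than the cutoff (default 4.5
#' Angstrom). Symmetric in chain order and invariant under rigid motions of
#' the whole dimer.
#'
#' @param dimer A `dimer_structure`.
#' @param cutoff Contact distance cutoff in Angstrom (default 4.5).
#' @return Integer contact count.
#' @export
count_interface_contacts <- function(dimer, cutoff = 4.5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  a <- coords(chain_atoms(dimer, receptor_chain(dimer)))
  b <- coords(chain_atoms(dimer, ligand_chain(dimer)))
  sum(cross_dist2(a, b) < cutoff^2)
}

# squared cross-distance matrix, rows a x rows b
cross_dist2 <- function(a, b) {
  ra <- rowSums(a^2)
  rb <- rowSums(b^2)
  d2 <- outer(ra, rb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Separability of two labelled point clouds
#'
#' Core of the interface separability feature: the training accuracy of a
#' degree-3 polynomial-kernel maximum-margin classifier (soft margin, fixed
#' regularization) predicting the chain label from 3-D coordinates.
#' Coordinates are standardized before fitting and classes receive balanced
#' weights. S = 1 means a cubic surface perfectly separates the two clouds;
#' S near 0.5 means the clouds are fully intermixed.
#'
#' @param xyz Numeric matrix (n x 3) of coordinates.
#' @param labels Length-n vector of two distinct labels.
#' @param regularization Soft-margin cost constant (default 1).
#' @param coef0,degree Polynomial kernel constants (default 1 and 3).
#' @return Separability in `[0, 1]`.
#' @export
separability_points <- function(xyz, labels, regularization = 1,
                                coef0 = 1, degree = 3) {
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("labels must contain exactly two classes")
  if (min(table(y)) < 1L) stop("one class is empty")
  w <- 1 / (table(y) / length(y)) / 2
  fit <- e1071::svm(
    x = xyz, y = y, kernel = "polynomial", degree = degree, coef0 = coef0,
    gamma = 1 / ncol(xyz), cost = regularization, scale = TRUE,
    class.weights = w
  )
  mean(predict(fit, xyz) == y)
}

#' Interface separability of a dimer
#'
#' Computes S on the heavy atoms of the delta-rSASA interface residues (see
#' [interface_residues()]); when the interface is empty (non-touching chains)
#' or either chain contributes fewer than `min_atoms` interface atoms, all
#' heavy atoms of both chains are used instead so far-apart decoys remain
#' scoreable. libsvm training is deterministic given the data, so S is
#' reproducible; `seed` is accepted for interface stability.
#'
#' @param dimer A `dimer_structure`.
#' @param regularization Soft-margin cost constant (default 1).
#' @param min_atoms Minimum interface atoms per chain before falling back to
#'   all heavy atoms (default 10).
#' @param seed Optional integer seed (fitting is deterministic regardless).
#' @param interface_only Use interface-residue atoms when available (default
#'   TRUE); FALSE forces the all-atom point set.
#' @return Separability S in `[0, 1]`.
#' @export
interface_separability <- function(dimer, regularization = 1, min_atoms = 10L,
                                   seed = NULL, interface_only = TRUE) {
  rec <- receptor_chain(dimer)
  lig <- ligand_chain(dimer)
  if (nrow(chain_atoms(dimer, rec)) == 0L || nrow(chain_atoms(dimer, lig)) == 0L) {
    stop("both chains must contain atoms")
  }
  sel <- NULL
  if (interface_only) {
    iface <- interface_residues(dimer)
    keys <- c(iface$receptor_residues, iface$ligand_residues)
    if (length(keys) > 0L) {
      cand <- dimer[atom_residue_key(dimer) %in% keys, , drop = FALSE]
      if (nrow(chain_atoms(cand, rec)) >= min_atoms &&
          nrow(chain_atoms(cand, lig)) >= min_atoms) {
        sel <- cand
      }
    }
  }
  if (is.null(sel)) sel <- dimer
  if (!is.null(seed)) set.seed(seed)
  separability_points(coords(sel), sel$chain == rec,
                      regularization = regularization)
}

#' Contact-count cutoff scan
#'
#' Utility loop returning Nc over a range of distance cutoffs, as used to
#' examine how the contact feature depends on the cutoff choice.
#'
#' @param dimer A `dimer_structure`.
#' @param cutoffs Numeric vector of cutoffs in Angstrom (default 1 to 30 by
#'   0.1).
#' @return data.frame with columns `cutoff` and `n_contacts`.
#' @export
contact_cutoff_scan <- function(dimer, cutoffs = seq(1, 30, by = 0.1)) {
  a <- coords(chain_atoms(dimer, receptor_chain(dimer)))
  b <- coords(chain_atoms(dimer, ligand_chain(dimer)))
  d <- sqrt(cross_dist2(a, b))
  data.frame(
    cutoff = cutoffs,
    n_contacts = vapply(cutoffs, function(cc) sum(d < cc), numeric(1))
  )
}
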