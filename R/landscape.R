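# The DockQ landscape: ligand center-of-mass directions of a decoy ensemble
# in the native receptor frame, and the DockQ^3-weighted inertia anisotropy.

#' Spherical-coordinate landscape points for a decoy ensemble
#'
#' Each model is superposed on the native receptor C-alpha atoms, translated
#' so the native receptor C-alpha center of mass sits at the origin, and its
#' ligand C-alpha center of mass is reduced to a direction (theta, phi). The
#' point is placed at the common radius R, the receptor-ligand C-alpha COM
#' distance of the native. theta is measured from +z and phi from +x in the
#' native receptor frame.
#'
#' @param models List of `dimer_structure` models sharing atom identities
#'   with the native.
#' @param native The target `dimer_structure`.
#' @param dockq Optional numeric vector of DockQ weights per model; computed
#'   with [dockq()] when omitted.
#' @return data.frame with columns `radius`, `theta`, `phi`, `dockq`, and
#'   `x`, `y`, `z` (the Cartesian point at radius R); attribute `R`.
#' @export
landscape_points <- function(models, native, dockq = NULL) {
  rec <- receptor_chain(native)
  lig <- ligand_chain(native)
  nrec_ca <- ca_atoms(native, rec)
  if (nrow(nrec_ca) < 3L) stop("degenerate receptor: fewer than 3 C-alpha atoms")
  origin <- colMeans(coords(nrec_ca))
  nlig_com <- colMeans(coords(ca_atoms(native, lig)))
  R <- sqrt(sum((nlig_com - origin)^2))
  out <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    mrec_ca <- ca_atoms(m, rec)
    mm <- match_atoms(mrec_ca, nrec_ca)
    tf <- kabsch_superpose(coords(mrec_ca)[mm$a, , drop = FALSE],
                           coords(nrec_ca)[mm$b, , drop = FALSE])
    lcom <- colMeans(apply_transform(coords(ca_atoms(m, lig)), tf)) - origin
    r <- sqrt(sum(lcom^2))
    u <- if (r > 0) lcom / r else c(0, 0, 1)
    q <- if (is.null(dockq)) dockq(m, native)$dockq else dockq[i]
    data.frame(
      radius = R,
      theta = acos(pmin(1, pmax(-1, u[3]))),
      phi = atan2(u[2], u[1]) %% (2 * pi),
      dockq = q,
      x = R * u[1], y = R * u[2], z = R * u[3]
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "R") <- R
  res
}

#' DockQ^3-weighted moment-of-inertia tensor of landscape points
#'
#' I_ab = (1/Nm) * sum_i DockQ_i^3 (r_i^2 delta_ab - r_ai r_bi) over the
#' Cartesian coordinates of the landscape points. The cubic weight
#' emphasizes native-like models.
#'
#' @param points data.frame from [landscape_points()] (columns `x`, `y`, `z`,
#'   `dockq`), or any point table with those columns.
#' @return List of class `inertia_summary` with `tensor` (symmetric 3 x 3),
#'   `eigenvalues` (ascending, nonnegative up to roundoff) and `kappa2`
#'   (NA when the tensor vanishes).
#' @export
dockq_weighted_inertia <- function(points) {
  if (nrow(points) == 0L) stop("at least one landscape point is required")
  xyz <- as.matrix(points[, c("x", "y", "z")])
  w <- points$dockq^3
  n <- nrow(xyz)
  r2 <- rowSums(xyz^2)
  I <- diag(3) * sum(w * r2)
  I <- I - crossprod(xyz * w, xyz)
  I <- I / n
  dimnames(I) <- NULL
  ev <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
  k2 <- if (sum(ev) > 0) relative_anisotropy(ev) else NA_real_
  structure(list(tensor = I, eigenvalues = ev, kappa2 = k2),
            class = "inertia_summary")
}

#' Relative anisotropy of an inertia spectrum
#'
#' kappa^2 = 1 - 3 (l1 l2 + l2 l3 + l1 l3) / (l1 + l2 + l3)^2, in `[0, 1]`:
#' 0 for an isotropic spectrum (all eigenvalues equal), 1 when only one
#' eigenvalue is nonzero. Invariant under uniform rescaling of the spectrum.
#'
#' @param x An `inertia_summary` or a numeric vector of three nonnegative
#'   eigenvalues.
#' @return kappa^2.
#' @export
relative_anisotropy <- function(x) {
  ev <- if (inherits(x, "inertia_summary")) x$eigenvalues else as.numeric(x)
  if (length(ev) != 3L) stop("three eigenvalues are required")
  s <- sum(ev)
  if (s <= 0) stop("eigenvalue sum must be positive")
  1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] + ev[1] * ev[3]) / s^2
}

#' @export
print.inertia_summary <- function(x, ...) {
  cat("DockQ-weighted inertia summary\n")
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 6), collapse = ", "), "\n")
  cat("  kappa^2:    ", signif(x$kappa2, 6), "\n")
  invisible(x)
}

#' Landscape summary of a decoy ensemble
#'
#' Convenience wrapper: builds the landscape points and returns them together
#' with the weighted inertia tensor and its anisotropy.
#'
#' @inheritParams landscape_points
#' @return List with `points`, `inertia` (an `inertia_summary`) and `kappa2`.
#' @export
dockq_landscape <- function(models, native, dockq = NULL) {
  pts <- landscape_points(models, native, dockq)
  inertia <- dockq_weighted_inertia(pts)
  list(points = pts, inertia = inertia, kappa2 = inertia$kappa2)
}
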