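# Optimal rigid-body superposition (Kabsch algorithm).

#' Kabsch superposition of paired point sets
#'
#' Finds the proper rigid transform (rotation + translation, no reflection)
#' minimizing the RMSD between `mobile` and `reference`, paired row by row.
#'
#' @param mobile,reference Numeric n x 3 matrices, n >= 3, paired rows.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3) such
#'   that `mobile %*% t(rotation) + translation` best fits `reference`, and
#'   `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3L || ncol(reference) != 3L) {
    stop("point sets must be paired n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3L) stop("at least 3 paired points are required")
  if (svd(sweep(mobile, 2, colMeans(mobile)))$d[2] < 1e-10 ||
      svd(sweep(reference, 2, colMeans(reference)))$d[2] < 1e-10) {
    stop("degenerate (collinear) point set")
  }
  kabsch_core(mobile, reference)
}

# Kabsch without the collinearity guard: rank-deficient point sets still have
# a well-defined minimum RMSD (the rotation is just not unique), which is all
# interface-RMSD computations need.
kabsch_core <- function(mobile, reference) {
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cr - R %*% cm)
  fitted <- tcrossprod(A, R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 coordinate matrix.
#' @param transform List with `rotation` and `translation` as returned by
#'   [kabsch_superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  sweep(as.matrix(xyz) %*% t(transform$rotation), 2, -transform$translation)
}

rmsd_between <- function(a, b) {
  sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
}
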