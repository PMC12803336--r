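# Fixtures are built in code: tiny hand-placed dimers plus the package's own
# synthetic generators.

# a minimal dimer: `spacing` controls the gap between the two chains along x
tiny_dimer <- function(spacing = 4, n_res = 3L, with_h = FALSE) {
  one_chain <- function(chain, x0) {
    idx <- seq_len(n_res)
    data.frame(
      chain = chain,
      resno = rep(idx, each = 2L),
      ins = "",
      resid = "ALA",
      elety = rep(c("CA", "CB"), n_res),
      element = "C",
      x = x0 + rep(c(0, 1.0), n_res),
      y = as.numeric(rep(idx * 3.8, each = 2L)),
      z = rep(c(0, 1.0), n_res),
      stringsAsFactors = FALSE
    )
  }
  atoms <- rbind(one_chain("A", 0), one_chain("B", spacing))
  if (with_h) {
    h <- atoms[1, ]
    h$elety <- "H"
    h$element <- "H"
    atoms <- rbind(atoms, h)
  }
  atoms
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

rigid_move <- function(structure, R = diag(3), shift = c(0, 0, 0)) {
  out <- structure
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  out[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2, -shift)
  out
}

coords_of <- function(s) as.matrix(s[, c("x", "y", "z")])
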