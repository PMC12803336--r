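# toy monomer with a varied (non-homopolymer) sequence so alignments have a
# unique register; CA+CB atom pairs are kept for every residue type
toy_monomer <- function(n = 40L, seed = 1L) {
  d <- make_toy_dimer(n, 0, seed = seed)
  m <- d[d$chain == "A", ]
  cycle <- c("ALA", "ARG", "ASN", "ASP", "GLN", "GLU", "HIS", "ILE", "LEU",
             "LYS", "MET", "PHE", "SER", "THR", "TRP", "TYR", "VAL")
  m$resid <- cycle[(m$resno - 1L) %% length(cycle) + 1L]
  m
}

deform <- function(mono, sd = 0.8, seed = 2L) {
  set.seed(seed)
  mono[, c("x", "y", "z")] <- coords_of(mono) +
    matrix(rnorm(nrow(mono) * 3, sd = sd), ncol = 3)
  mono
}

test_that("identical conformers pair atom for atom; termini and SNPs are dropped", {
  b <- toy_monomer()
  p <- match_conformations(b, b)
  expect_equal(p$n_atoms, nrow(b))
  expect_equal(coords_of(p$unbound), coords_of(p$bound), tolerance = 1e-9)

  # extra N-terminal residues on the unbound side are trimmed away
  extra <- b[b$resno <= 3, ]
  extra$resno <- extra$resno - 3L
  extra$resid <- "GLY"  # distinct from the chain's own start
  u2 <- rbind(extra, b)
  u2[, c("x", "y", "z")] <- coords_of(u2) + 0.1
  p2 <- match_conformations(b, u2)
  expect_equal(p2$n_atoms, nrow(b))
  expect_false(any(p2$unbound$resno < 1))

  # a point substitution drops that residue, keeps the rest
  u3 <- deform(b, sd = 0.1)
  u3$resid[u3$resno == 10] <- "GLY"
  stopifnot(b$resid[b$resno == 10][1] != "GLY")
  u3 <- u3[!(u3$resno == 10 & trimws(u3$elety) == "CB"), ]
  p3 <- match_conformations(b, u3)
  expect_false(any(p3$bound$resno == 10))
  expect_equal(p3$n_atoms, nrow(b) - 2L)
})

test_that("unrelated sequences are rejected", {
  b <- toy_monomer()
  u <- b
  u$resid <- "TRP"  # every aligned position mismatches
  expect_error(match_conformations(b, u), "identity")
})

test_that("displacement matrix is a plain per-atom subtraction", {
  b <- toy_monomer()
  u <- b
  u$x <- u$x + 1
  p <- match_conformations(b, u, superpose = FALSE)
  D <- displacement_matrix(p)
  expect_true(all(abs(D[, 1] - 1) < 1e-12))
  expect_true(all(abs(D[, 2:3]) < 1e-12))

  # random pair against direct subtraction
  u2 <- deform(b, seed = 5)
  p2 <- match_conformations(b, u2, superpose = FALSE)
  expect_equal(displacement_matrix(p2), coords_of(u2) - coords_of(b),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("pre-superposition removes global pose from the displacement field", {
  b <- toy_monomer()
  set.seed(6)
  u <- rigid_move(b, random_rotation(), c(12, -4, 9))
  p <- match_conformations(b, u, superpose = TRUE)
  expect_lt(ppiscore:::displacement_norm(displacement_matrix(p)), 1e-6)
})

test_that("interpolation endpoints are exact and intermediate images linear", {
  b <- toy_monomer()
  u <- deform(b, seed = 7)
  p <- match_conformations(b, u, superpose = FALSE)
  imgs <- interpolate_images(p, n_images = 6)
  expect_length(imgs$images, 7L)
  expect_identical(coords_of(imgs$images[["0"]]), coords_of(p$bound))
  expect_equal(coords_of(imgs$images[["6"]]), coords_of(p$unbound),
               tolerance = 1e-12)
  expect_equal(coords_of(imgs$images[["3"]]),
               (coords_of(p$bound) + coords_of(p$unbound)) / 2,
               tolerance = 1e-12)
  expect_equal(imgs$spacing,
               ppiscore:::displacement_norm(displacement_matrix(p)) / 6)

  # auto mode raises the image count until spacing <= 1 A
  big <- p
  big$unbound[, c("x", "y", "z")] <- coords_of(p$bound) +
    10 * displacement_matrix(p)
  auto <- interpolate_images(big, n_images = "auto")
  expect_lte(auto$spacing, 1)
  expect_gte(auto$n_images, 6L)
})

test_that("iRMSD progression starts at zero and normalizes to one at the unbound end", {
  d <- make_toy_dimer(50, 0.3, seed = 9)
  bA <- d[d$chain == "A", ]
  bB <- d[d$chain == "B", ]
  pA <- match_conformations(bA, deform(bA, sd = 0.8, seed = 10))
  pB <- match_conformations(bB, deform(bB, sd = 0.8, seed = 11))
  prog <- irmsd_progression(interpolate_images(pA, 6),
                            interpolate_images(pB, 6), d)
  expect_equal(prog$irmsd[1], 0, tolerance = 1e-8)
  expect_equal(prog$irmsd_star[1], 0, tolerance = 1e-8)
  expect_equal(prog$irmsd_star[7], 1)
  expect_true(all(diff(prog$irmsd) >= -1e-9))
  expect_true(all(prog$irmsd <= prog$irmsd[7] + 1e-9))

  # zero deformation gives a flat curve (normalization degenerate, iRMSD 0)
  pA0 <- match_conformations(bA, bA)
  pB0 <- match_conformations(bB, bB)
  prog0 <- irmsd_progression(interpolate_images(pA0, 3),
                             interpolate_images(pB0, 3), d)
  expect_true(all(prog0$irmsd < 1e-8))
})
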