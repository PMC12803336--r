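# DockQ and components against brute-force and independent oracles.

test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(3)
  P <- matrix(rnorm(30), ncol = 3)
  s <- kabsch_superpose(P, P)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$rotation, diag(3), tolerance = 1e-8)

  R <- random_rotation()
  Q <- sweep(P %*% t(R), 2, -c(4, -2, 7))
  s2 <- kabsch_superpose(Q, P)
  expect_equal(s2$rmsd, 0, tolerance = 1e-10)
  expect_equal(apply_transform(Q, s2), P, tolerance = 1e-8)
  expect_equal(det(s2$rotation), 1, tolerance = 1e-10)
})

test_that("Kabsch RMSD is optimal against a random-rotation search oracle", {
  set.seed(9)
  A <- matrix(rnorm(30), ncol = 3)
  B <- matrix(rnorm(30), ncol = 3)
  s <- kabsch_superpose(A, B)
  # oracle 1: independent reference implementation
  ref <- suppressWarnings(bio3d::fit.xyz(as.numeric(t(B)), as.numeric(t(A))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - B)^2)))
  expect_equal(s$rmsd, ref_rmsd, tolerance = 1e-3)
  # oracle 2: no sampled proper rotation does better
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  best <- min(vapply(seq_len(2000), function(i) {
    sqrt(mean(rowSums((Ac %*% t(random_rotation()) - Bc)^2)))
  }, numeric(1)))
  expect_lte(s$rmsd, best + 1e-9)

  expect_error(kabsch_superpose(A[1:2, ], B[1:2, ]), "3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("native contacts respect the 5 A strict boundary and match brute force", {
  pair_at <- function(d) {
    atoms <- tiny_dimer(spacing = 100)[c(1, 7), ]
    atoms$x <- c(0, d); atoms$y <- 0; atoms$z <- 0
    dimer_structure(atoms)
  }
  expect_length(native_contacts(pair_at(4.9)), 1L)
  expect_length(native_contacts(pair_at(5.1)), 0L)
  expect_length(native_contacts(dimer_structure(tiny_dimer(60))), 0L)

  d <- make_toy_dimer(50, 0.6, seed = 13)
  got <- native_contacts(d)
  A <- d[d$chain == "A", ]
  B <- d[d$chain == "B", ]
  brute <- character(0)
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      dist <- sqrt(sum((coords_of(A)[i, ] - coords_of(B)[j, ])^2))
      if (dist < 5) {
        brute <- c(brute, paste(ppiscore:::atom_key(A)[i],
                                ppiscore:::atom_key(B)[j], sep = "::"))
      }
    }
  }
  expect_setequal(got, brute)
})

test_that("fnat is 1 for the native, 0 for a displaced ligand, and counts intersections", {
  d <- make_toy_dimer(50, 0.3, seed = 17)
  expect_equal(fnat(d, d), 1)
  shifted <- d
  idx <- shifted$chain == attr(d, "ligand")
  shifted$x[idx] <- shifted$x[idx] + 100
  expect_equal(fnat(shifted, d), 0)
  expect_error(fnat(d, dimer_structure(tiny_dimer(60))), "no cross-chain contacts")
})

test_that("lrmsd equals the applied displacement for a pure ligand translation", {
  d <- make_toy_dimer(50, 0, seed = 19)
  expect_equal(lrmsd(d, d), 0, tolerance = 1e-10)
  shifted <- d
  idx <- shifted$chain == attr(d, "ligand")
  shifted$z[idx] <- shifted$z[idx] + 3
  expect_equal(lrmsd(shifted, d), 3, tolerance = 1e-8)
})

test_that("lrmsd of a random decoy matches an independent two-step reference", {
  d <- make_toy_dimer(50, 0.2, seed = 23)
  set.seed(5)
  model <- ppiscore:::perturb_ligand(d, angle = 0.4, axis = rnorm(3),
                                     shift = c(2, -1, 3))
  got <- lrmsd(model, d)
  # independent route: backbone CA superposition via bio3d, then plain RMSD
  rec <- attr(d, "receptor"); lig <- attr(d, "ligand")
  bb <- function(s, ch) coords_of(s[s$chain == ch & trimws(s$elety) %in%
                                      c("N", "CA", "C", "O"), ])
  fitted <- bio3d::fit.xyz(
    fixed = as.numeric(t(bb(d, rec))),
    mobile = c(as.numeric(t(bb(model, rec))), as.numeric(t(bb(model, lig)))),
    fixed.inds = seq_len(3 * nrow(bb(d, rec))),
    mobile.inds = seq_len(3 * nrow(bb(model, rec))))
  mlig <- matrix(fitted[-seq_len(3 * nrow(bb(model, rec)))], ncol = 3, byrow = TRUE)
  ref <- sqrt(mean(rowSums((mlig - bb(d, lig))^2)))
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("interface RMSD is 0 at identity and bounded by a rigid shift", {
  d <- make_toy_dimer(50, 0, seed = 29)
  expect_equal(irmsd_dockq(d, d), 0, tolerance = 1e-10)
  shifted <- d
  idx <- shifted$chain == attr(d, "ligand")
  shifted$z[idx] <- shifted$z[idx] + 1
  v <- irmsd_dockq(shifted, d)
  expect_gt(v, 0)
  expect_lte(v, 1)
  expect_error(irmsd_dockq(dimer_structure(tiny_dimer(60)),
                           dimer_structure(tiny_dimer(60))), "interface")
})

test_that("composite DockQ reproduces its analytic values and invariants", {
  d <- make_toy_dimer(50, 0.4, seed = 31)
  r <- dockq(d, d)
  expect_equal(r$dockq, 1)
  expect_equal(r$fnat, 1)

  # each term equals 1/2 at (0.5, 8.5 A, 1.5 A)
  composite <- function(fn, lr, ir) (fn + 1 / (1 + (lr / 8.5)^2) +
                                       1 / (1 + (ir / 1.5)^2)) / 3
  expect_equal(composite(0.5, 8.5, 1.5), 0.5)
  expect_equal(composite(0, 1e9, 1e9), 0, tolerance = 1e-12)

  # rigid co-transform of both structures leaves DockQ unchanged
  set.seed(4)
  R <- random_rotation(); tr <- c(7, -5, 2)
  dm <- assign_receptor_ligand(rigid_move(d, R, tr))
  model <- ppiscore:::perturb_ligand(d, 0.3, c(1, 1, 0), c(1, 0, 0))
  mm <- assign_receptor_ligand(rigid_move(model, R, tr))
  expect_equal(dockq(mm, dm)$dockq, dockq(model, d)$dockq, tolerance = 1e-8)
})

test_that("median DockQ decreases as rigid perturbations grow", {
  d <- make_toy_dimer(50, 0.2, seed = 37)
  set.seed(6)
  med <- vapply(c(0.5, 2, 8, 30), function(mag) {
    qs <- vapply(1:5, function(i) {
      m <- ppiscore:::perturb_ligand(d, angle = mag / 50 * pi, axis = rnorm(3),
                                     shift = rnorm(3) / sqrt(3) * mag)
      dockq(m, d)$dockq
    }, numeric(1))
    median(qs)
  }, numeric(1))
  expect_true(all(diff(med) <= 0))
})

test_that("rSASA-based interface RMSD follows its pooled-displacement formula", {
  d <- make_toy_dimer(50, 0.3, seed = 41)
  expect_equal(irmsd_rsasa(d, d), 0, tolerance = 1e-10)

  # manual evaluation: per-monomer alignment, pooled squared displacements
  iface <- interface_residues(d)
  conf <- d
  set.seed(7)
  conf[, c("x", "y", "z")] <- coords_of(conf) + matrix(rnorm(nrow(conf) * 3, sd = 0.6),
                                                       ncol = 3)
  got <- irmsd_rsasa(conf, d, interface = iface)
  total_d <- 0; total_n <- 0
  keys <- c(iface$receptor_residues, iface$ligand_residues)
  for (ch in c("A", "B")) {
    bca <- d[d$chain == ch & trimws(d$elety) == "CA", ]
    bca <- bca[ppiscore:::atom_residue_key(bca) %in% keys, ]
    cca <- conf[match(ppiscore:::atom_key(bca), ppiscore:::atom_key(conf)), ]
    fit <- kabsch_superpose(coords_of(cca), coords_of(bca))
    moved <- apply_transform(coords_of(cca), fit)
    total_d <- total_d + sum(rowSums((moved - coords_of(bca))^2))
    total_n <- total_n + nrow(bca)
  }
  expect_equal(got, sqrt(total_d / total_n), tolerance = 1e-10)
})
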