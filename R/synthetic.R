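# Synthetic fixtures: toy dimers with controllable interface geometry,
# rigid-body decoy ensembles spanning the DockQ range, and score/DockQ
# tables with calibrated Spearman correlation and negative-dominance mu.
#
# Toy chains are coarse-grained: one C-alpha plus one alanine-like
# pseudo-C-beta per residue, placed on a 3.8 Angstrom lattice. That is
# enough to exercise contacts, SASA, separability and the full DockQ
# machinery at desk scale.

#' Generate a toy two-chain structure with controllable intertwining
#'
#' Builds two self-avoiding serpentine chains of C-alpha + pseudo-C-beta
#' atoms on a 3.8 Angstrom lattice, packed against a shared interface.
#' `intertwine = 0` gives a flat (planar) interface; as `intertwine` grows
#' the boundary corrugates into interdigitated fingers that a low-degree
#' polynomial surface cannot separate. Consecutive C-alpha atoms are one
#' lattice unit apart within a column and at most sqrt(2) units apart at
#' column turns.
#'
#' @param n_residues_per_chain Residues per chain (>= 50 mirrors the
#'   chain-length floor of real heterodimer sets; smaller values are allowed
#'   for unit tests).
#' @param intertwine Degree of interface interdigitation in `[0, 1]`.
#' @param seed Integer seed (controls the pseudo-side-chain jitter).
#' @return A `dimer_structure` with chains "A" and "B".
#' @export
make_toy_dimer <- function(n_residues_per_chain = 96L, intertwine = 0,
                           seed = 1L) {
  if (intertwine < 0 || intertwine > 1) stop("intertwine must be in [0, 1]")
  n <- as.integer(n_residues_per_chain)
  if (n < 4L) stop("n_residues_per_chain too small")
  set.seed(seed)
  a <- 3.8
  depth <- 3L
  cols_needed <- ceiling(n / depth)
  ny <- ceiling(cols_needed / 32)
  nx <- ceiling(cols_needed / ny)
  # corrugation: triangle wave in x, period 8 columns, amplitude 2 layers
  tri8 <- c(0, 1, 2, 1, 0, -1, -2, -1)
  boundary <- function(i) round(intertwine * tri8[(i - 1L) %% 8L + 1L])

  build_chain <- function(side) {
    # side +1 = above boundary (chain B), -1 = below (chain A)
    pos <- matrix(NA_real_, nrow = n, ncol = 3)
    k <- 0L
    up <- TRUE
    for (j in seq_len(ny)) {
      xs <- if (j %% 2L == 1L) seq_len(nx) else rev(seq_len(nx))
      for (i in xs) {
        b <- boundary(i)
        layers <- if (up) seq_len(depth) else rev(seq_len(depth))
        for (l in layers) {
          k <- k + 1L
          if (k > n) break
          z <- (b + side * (l - 0.5)) * a
          pos[k, ] <- c(i * a, j * a, z)
        }
        up <- !up
        if (k >= n) break
      }
      if (k >= n) break
    }
    pos
  }

  make_atoms <- function(ca, chain_id) {
    phi <- stats::runif(nrow(ca), -0.3, 0.3)
    cb <- ca + 1.5 * cbind(cos(phi), sin(phi), 0)
    idx <- rep(seq_len(nrow(ca)), each = 2L)
    data.frame(
      chain = chain_id,
      resno = idx,
      ins = "",
      resid = "ALA",
      elety = rep(c("CA", "CB"), nrow(ca)),
      element = "C",
      x = as.numeric(t(cbind(ca[, 1], cb[, 1]))),
      y = as.numeric(t(cbind(ca[, 2], cb[, 2]))),
      z = as.numeric(t(cbind(ca[, 3], cb[, 3]))),
      stringsAsFactors = FALSE
    )
  }

  atoms <- rbind(
    make_atoms(build_chain(-1), "A"),
    make_atoms(build_chain(+1), "B")
  )
  dimer_structure(atoms)
}

# rigid perturbation of the ligand chain: rotate about the ligand COM by
# `angle` (radians) around `axis`, then translate by `shift`
perturb_ligand <- function(native, angle, axis, shift) {
  lig <- ligand_chain(native)
  out <- native
  idx <- which(out$chain == lig)
  xyz <- coords(out)[idx, , drop = FALSE]
  com <- colMeans(xyz)
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  moved <- sweep(sweep(xyz, 2, com) %*% t(R), 2, -(com + shift))
  out[idx, c("x", "y", "z")] <- moved
  out
}

#' Generate a rigid-body decoy ensemble spanning the DockQ range
#'
#' Applies random rigid rotations/translations to the ligand with
#' perturbation magnitudes drawn from a log-uniform schedule, scoring each
#' candidate with [dockq()] (the metric itself, never a synthesized value)
#' and stratified-rejecting so that every feasible 0.05-wide DockQ bin
#' gathers models without any bin dominating. The zero-perturbation decoy
#' (DockQ 1) is always included.
#'
#' @param native A `dimer_structure`.
#' @param n_models Number of decoys to generate.
#' @param seed Integer seed.
#' @param max_attempts Attempt budget (default `40 * n_models`).
#' @return List with `models` (list of `dimer_structure`) and `scores`
#'   (scored model set with columns `model_id`, `dockq`).
#' @export
make_decoy_set <- function(native, n_models = 200L, seed = 1L,
                           max_attempts = 40L * n_models) {
  set.seed(seed)
  n_models <- as.integer(n_models)
  cap <- ceiling(n_models / 20) + 1L
  bin_count <- integer(20)
  models <- vector("list", n_models)
  qs <- numeric(n_models)
  # the unperturbed native is decoy 1
  models[[1]] <- native
  qs[1] <- dockq(native, native)$dockq
  bin_count[20] <- 1L
  got <- 1L
  attempts <- 0L
  while (got < n_models && attempts < max_attempts) {
    attempts <- attempts + 1L
    m <- exp(stats::runif(1, log(3e-3), log(1)))
    axis <- stats::rnorm(3)
    dirv <- stats::rnorm(3)
    dirv <- dirv / sqrt(sum(dirv^2))
    cand <- perturb_ligand(native, angle = m * pi, axis = axis,
                           shift = dirv * m * 50)
    q <- dockq(cand, native)$dockq
    b <- min(floor(q * 20) + 1L, 20L)
    if (bin_count[b] >= cap) next
    got <- got + 1L
    bin_count[b] <- bin_count[b] + 1L
    models[[got]] <- cand
    qs[got] <- q
  }
  if (got < n_models) {
    models <- models[seq_len(got)]
    qs <- qs[seq_len(got)]
  }
  list(
    models = models,
    scores = data.frame(
      model_id = sprintf("decoy_%04d", seq_len(got)),
      dockq = qs,
      stringsAsFactors = FALSE
    )
  )
}

#' Synthetic score/DockQ table with calibrated rho and mu
#'
#' DockQ values are uniform on `[0, 1]` (or balanced 1:1 around the 0.23
#' cutoff when `balanced`); the score is a monotone transform of DockQ plus
#' Gaussian noise whose amplitude is calibrated by bisection so the measured
#' Spearman correlation hits `rho_target` (within 0.005 before mu
#' injection). A negative `rho_target` yields an energy-like score (lower =
#' better). Finally `ceiling(mu_target * n)` negatives are re-scored to
#' strictly outrank every positive, which slightly perturbs rho; the
#' re-measured rho is attached to the result.
#'
#' @param n Number of models.
#' @param rho_target Target Spearman correlation in `(-1, 1)`.
#' @param mu_target Target negative-dominance fraction in `[0, 1]`.
#' @param balanced Balance classes 1:1 at DockQ 0.23 (default TRUE).
#' @param seed Integer seed.
#' @return Scored model set (columns `model_id`, `dockq`, `score`) with
#'   attributes `lower_is_better` and `achieved_rho`.
#' @export
make_score_dockq_dataset <- function(n, rho_target = -0.5, mu_target = 0,
                                     balanced = TRUE, seed = 1L) {
  if (abs(rho_target) >= 1) stop("|rho_target| must be < 1")
  if (mu_target < 0 || mu_target > 1) stop("mu_target must be in [0, 1]")
  set.seed(seed)
  n <- as.integer(n)
  if (balanced) {
    npos <- n %/% 2L
    dq <- c(stats::runif(npos, 0.23, 1), stats::runif(n - npos, 0, 0.23))
    dq <- sample(dq)
  } else {
    dq <- stats::runif(n)
  }
  lower_is_better <- rho_target <= 0
  sgn <- if (lower_is_better) -1 else 1
  noise <- stats::rnorm(n)
  score_at <- function(lambda) sgn * dq + lambda * noise
  if (rho_target == 0) {
    score <- noise
  } else {
    target <- abs(rho_target)
    lo <- 0
    hi <- 1
    while (abs(spearman_rho(dq, score_at(hi))) > target && hi < 1e4) hi <- hi * 2
    for (it in seq_len(60)) {
      mid <- (lo + hi) / 2
      if (abs(spearman_rho(dq, score_at(mid))) > target) lo <- mid else hi <- mid
      if (abs(abs(spearman_rho(dq, score_at(mid))) - target) < 0.005) break
    }
    score <- score_at((lo + hi) / 2)
  }
  neg <- which(dq < 0.23)
  pos <- which(dq >= 0.23)
  m <- ceiling(mu_target * n)
  if (m > length(neg)) stop("mu_target infeasible: only ", length(neg),
                            " negatives for ", m, " dominating models")
  gap <- max(stats::sd(score), 1e-6) * 0.01
  if (m > 0L) {
    if (length(pos) == 0L) stop("mu injection requires at least one positive")
    chosen <- sample(neg, m)
    sp <- score[pos]
    if (lower_is_better) {
      best <- min(sp)
      score[chosen] <- best - gap * seq_len(m)
    } else {
      best <- max(sp)
      score[chosen] <- best + gap * seq_len(m)
    }
  } else if (length(pos) > 0L && length(neg) > 0L) {
    # mu = 0 is a construction guarantee: nudge any negative that happens to
    # outrank every positive to just behind the best positive
    sp <- score[pos]
    if (lower_is_better) {
      bad <- neg[score[neg] < min(sp)]
      if (length(bad) > 0L) score[bad] <- min(sp) + gap * seq_along(bad)
    } else {
      bad <- neg[score[neg] > max(sp)]
      if (length(bad) > 0L) score[bad] <- max(sp) - gap * seq_along(bad)
    }
  }
  out <- data.frame(
    model_id = sprintf("model_%06d", seq_len(n)),
    dockq = dq,
    score = score,
    stringsAsFactors = FALSE
  )
  attr(out, "lower_is_better") <- lower_is_better
  attr(out, "achieved_rho") <- spearman_rho(dq, score)
  out
}
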