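# End-to-end assessment orchestration.

#' Default run configuration
#'
#' All defaults equal the standard constants of the assessment protocol:
#' 20 DockQ bins, at most 50 models per bin, 1000 extra negatives, positive
#' cutoff DockQ 0.23, 4.5 Angstrom contact cutoff, 6 interpolation images.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
run_config <- function(...) {
  cfg <- list(
    n_bins = 20L,
    per_bin = 50L,
    n_extra_negatives = 1000L,
    positive_cutoff = 0.23,
    contact_cutoff = 4.5,
    n_images = 6L,
    svr_gamma = 0.5,
    svr_cost = 1,
    svr_epsilon = 0.1,
    seed = 1L
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full per-target assessment
#'
#' For each target: DockQ-uniform subsampling, class balancing, then
#' Spearman rho and AUC per score column; the native's physical features
#' (Nc, S); and, when decoy structures are supplied, the landscape
#' anisotropy kappa^2. Targets that fail (e.g. single-class score tables)
#' are skipped with a recorded reason and the rest continue.
#'
#' @param targets Named list; each element a list with `native` (a
#'   `dimer_structure`), `scores` (scored model set with one or more score
#'   columns beyond `model_id`/`dockq`), optionally `models` (list of decoy
#'   `dimer_structure`s aligned with `scores` rows) and `pool` (extra
#'   scored models for balancing).
#' @param config From [run_config()].
#' @param score_orientations Named logical vector: `TRUE` where lower score
#'   means better, per score column. Defaults to `FALSE` for unknown scores.
#' @return List of class `assessment_report`: `per_target` data.frame,
#'   `mean_rho_by_score`, `skipped` (named character reasons).
#' @export
run_assessment <- function(targets, config = run_config(),
                           score_orientations = NULL) {
  if (length(targets) < 1L) stop("at least one target is required")
  nm <- names(targets)
  if (is.null(nm)) nm <- paste0("target_", seq_along(targets))
  rows <- list()
  skipped <- character(0)
  for (k in seq_along(targets)) {
    tg <- targets[[k]]
    res <- tryCatch({
      sel <- uniform_subsample(tg$scores, per_bin = config$per_bin,
                               n_bins = config$n_bins, seed = config$seed)
      sel <- balance_classes(sel, pool = tg$pool,
                             cutoff = config$positive_cutoff,
                             n_extra_negatives = config$n_extra_negatives,
                             seed = config$seed)
      score_cols <- setdiff(names(sel), c("model_id", "dockq"))
      stats_list <- lapply(score_cols, function(sc) {
        lib <- isTRUE(score_orientations[[sc]])
        c(rho = spearman_rho(sel$dockq, sel[[sc]]),
          auc = roc_auc(sel[[sc]], sel$dockq, config$positive_cutoff, lib))
      })
      feats <- featurize(tg$native, contact_cutoff = config$contact_cutoff)
      kappa2 <- NA_real_
      if (!is.null(tg$models)) {
        keep <- match(sel$model_id, tg$scores$model_id)
        pts <- landscape_points(tg$models[keep], tg$native, dockq = sel$dockq)
        kappa2 <- dockq_weighted_inertia(pts)$kappa2
      }
      row <- data.frame(target = nm[k], n_models = nrow(sel),
                        n_contacts = feats$n_contacts,
                        separability = feats$separability,
                        kappa2 = kappa2, stringsAsFactors = FALSE)
      for (i in seq_along(score_cols)) {
        row[[paste0("rho_", score_cols[i])]] <- stats_list[[i]][["rho"]]
        row[[paste0("auc_", score_cols[i])]] <- stats_list[[i]][["auc"]]
      }
      row
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[nm[k]] <- conditionMessage(res)
      message("skipping target ", nm[k], ": ", conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  per_target <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  mean_rho <- NULL
  if (!is.null(per_target)) {
    rc <- grep("^rho_", names(per_target), value = TRUE)
    mean_rho <- colMeans(per_target[, rc, drop = FALSE])
    names(mean_rho) <- sub("^rho_", "", names(mean_rho))
  }
  structure(list(per_target = per_target, mean_rho_by_score = mean_rho,
                 skipped = skipped),
            class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("Assessment report:",
      if (is.null(x$per_target)) 0L else nrow(x$per_target),
      "target(s) evaluated,", length(x$skipped), "skipped\n")
  if (!is.null(x$per_target)) print(x$per_target, row.names = FALSE)
  if (length(x$mean_rho_by_score) > 0) {
    cat("mean rho by score:\n")
    print(round(x$mean_rho_by_score, 4))
  }
  invisible(x)
}

#' Assessment of scoring along a bound-to-unbound interpolation path
#'
#' For each interpolation image: the interface RMSD (and iRMSD* normalized
#' by the unbound endpoint) from the image conformations, and per-score
#' Spearman rho from the image's scored model set, normalized by the
#' bound-image rho.
#'
#' @param images_receptor,images_ligand `interpolation_set` objects from
#'   [interpolate_images()] for the two monomers.
#' @param bound_dimer The bound `dimer_structure`.
#' @param image_tables List of scored model sets, one per image index
#'   0..N_I, each with a `score` column.
#' @param score_name Score column in the image tables (default "score").
#' @return data.frame with columns `n`, `irmsd`, `irmsd_star`, `rho`,
#'   `rho_normalized` (rho / rho at n = 0).
#' @export
run_interpolation_assessment <- function(images_receptor, images_ligand,
                                         bound_dimer, image_tables,
                                         score_name = "score") {
  prog <- irmsd_progression(images_receptor, images_ligand, bound_dimer)
  ni <- images_receptor$n_images
  if (length(image_tables) != ni + 1L) {
    stop("image_tables must have one scored set per image (", ni + 1L, ")")
  }
  rho <- vapply(seq_len(ni + 1L), function(i) {
    set <- image_tables[[i]]
    spearman_rho(set$dockq, set[[score_name]])
  }, numeric(1))
  prog$rho <- rho
  prog$rho_normalized <- rho / rho[1L]
  prog
}
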