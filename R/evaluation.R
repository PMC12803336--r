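# Assessment statistics: Spearman correlation, ROC AUC versus DockQ cutoff,
# hit rate, effective hit rate, and the negative-dominance fraction mu.

#' Spearman rank correlation
#'
#' Pearson correlation of the two variables after replacing each value by its
#' (average, for ties) rank. Invariant under strictly monotone transforms of
#' either variable; in `[-1, 1]` with |rho| = 1 for a monotone relation.
#'
#' @param x,y Equal-length numeric vectors, n >= 2.
#' @return rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("at least two observations are required")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("Spearman correlation is undefined for a constant input")
  }
  stats::cor(rx, ry)
}

# rank-orientation helper: larger oriented score = better model
orient_scores <- function(scores, lower_is_better) {
  if (lower_is_better) -scores else scores
}

#' ROC AUC of a score against a DockQ label cutoff
#'
#' The probability that a randomly chosen positive (DockQ >= cutoff)
#' outranks a randomly chosen negative, with ties counting one half
#' (Mann-Whitney form). Scores where lower means better are negated first,
#' so AUC > 0.5 always means better-than-random classification.
#'
#' @param scores Numeric score per model.
#' @param dockq DockQ per model.
#' @param cutoff Positive cutoff (default 0.23).
#' @param lower_is_better TRUE for energy-like scores (default FALSE).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, dockq, cutoff = 0.23, lower_is_better = FALSE) {
  if (length(scores) != length(dockq)) stop("scores and dockq length mismatch")
  pos <- dockq >= cutoff
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be nonempty at cutoff ", cutoff)
  }
  s <- orient_scores(scores, lower_is_better)
  r <- rank(s)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC over a range of DockQ cutoffs
#'
#' @param set Scored model set (data.frame with `dockq` and score columns).
#' @param score_name Name of the score column.
#' @param cutoffs DockQ cutoffs (default 0.2 to 0.8 by 0.1).
#' @param lower_is_better Score orientation flag.
#' @return data.frame with columns `cutoff` and `auc`.
#' @export
auc_curve <- function(set, score_name, cutoffs = seq(0.2, 0.8, by = 0.1),
                      lower_is_better = FALSE) {
  check_scored_set(set)
  data.frame(
    cutoff = cutoffs,
    auc = vapply(cutoffs, function(cc) {
      roc_auc(set[[score_name]], set$dockq, cc, lower_is_better)
    }, numeric(1))
  )
}

#' Hit rate over a set of targets
#'
#' h(R) = fraction of targets with at least one positive model among the top
#' R models ranked by the score (best first). Nondecreasing in R.
#'
#' @param sets List of scored model sets, one per target.
#' @param score_name Score column used for ranking.
#' @param R_max Maximum rank considered (default 100).
#' @param cutoff Positive cutoff (default 0.23).
#' @param lower_is_better Score orientation flag.
#' @return data.frame with columns `R` and `hit_rate`.
#' @export
hit_rate <- function(sets, score_name, R_max = 100L, cutoff = 0.23,
                     lower_is_better = FALSE) {
  hits <- vapply(sets, function(set) {
    check_scored_set(set)
    s <- orient_scores(set[[score_name]], lower_is_better)
    ord <- order(-s)  # ties broken by stable input order
    pos <- set$dockq[ord] >= cutoff
    first_pos <- if (any(pos)) which(pos)[1L] else Inf
    first_pos
  }, numeric(1))
  R <- seq_len(R_max)
  data.frame(
    R = R,
    hit_rate = vapply(R, function(r) mean(hits <= r), numeric(1))
  )
}

#' Effective hit rate of one target under repeated subsampling
#'
#' Draws `Ns` subsets of `Nm` models without replacement; for each subset the
#' models are ranked by the score and h_k(R) is the fraction of draws whose
#' top R contain at least one positive model.
#'
#' @param set Scored model set for the target.
#' @param score_name Score column used for ranking.
#' @param Nm Subset size (must not exceed the number of models).
#' @param Ns Number of draws (default 1000).
#' @param R_max Maximum rank considered (default 100).
#' @param cutoff Positive cutoff (default 0.23).
#' @param lower_is_better Score orientation flag.
#' @param seed Integer seed.
#' @return data.frame with columns `R` and `hit_rate`.
#' @export
effective_hit_rate <- function(set, score_name, Nm, Ns = 1000L, R_max = 100L,
                               cutoff = 0.23, lower_is_better = FALSE,
                               seed = 1L) {
  check_scored_set(set)
  n <- nrow(set)
  if (Nm > n) stop("Nm exceeds the number of models")
  s <- orient_scores(set[[score_name]], lower_is_better)
  pos <- set$dockq >= cutoff
  set.seed(seed)
  rmax <- min(R_max, Nm)
  # first_pos[l] = rank of the best-scored positive in draw l (Inf if none)
  first_pos <- vapply(seq_len(Ns), function(l) {
    idx <- sample.int(n, Nm)
    ord <- idx[order(-s[idx])]
    p <- pos[ord]
    if (any(p)) which(p)[1L] else Inf
  }, numeric(1))
  R <- seq_len(R_max)
  data.frame(
    R = R,
    hit_rate = vapply(R, function(r) mean(first_pos <= min(r, rmax)),
                      numeric(1))
  )
}

#' Negative-dominance fraction mu
#'
#' The fraction of all models that are negative (DockQ < cutoff) and strictly
#' outrank every positive model under the score's orientation. A nonzero mu
#' drives the large-sample effective hit rate to zero.
#'
#' @param set Scored model set.
#' @param score_name Score column.
#' @param cutoff Positive cutoff (default 0.23).
#' @param lower_is_better Score orientation flag.
#' @return mu in `[0, 1]`.
#' @export
negative_dominance_mu <- function(set, score_name, cutoff = 0.23,
                                  lower_is_better = FALSE) {
  check_scored_set(set)
  s <- orient_scores(set[[score_name]], lower_is_better)
  pos <- set$dockq >= cutoff
  if (!any(pos)) stop("at least one positive model is required")
  best_pos <- max(s[pos])
  sum(!pos & s > best_pos) / length(s)
}

#' Full evaluation summary for one scored model set
#'
#' @param set Scored model set.
#' @param score_name Score column.
#' @param cutoff Positive cutoff for AUC at the standard threshold and mu.
#' @param cutoffs Cutoff range for the AUC curve.
#' @param lower_is_better Score orientation flag.
#' @param R_max Maximum rank for the hit-rate curve.
#' @return List of class `eval_summary` with `rho`, `auc`, `auc_by_cutoff`,
#'   `hit_rate_curve`, `mu`.
#' @export
evaluate_scores <- function(set, score_name, cutoff = 0.23,
                            cutoffs = seq(0.2, 0.8, by = 0.1),
                            lower_is_better = FALSE, R_max = 100L) {
  check_scored_set(set)
  structure(list(
    score = score_name,
    rho = spearman_rho(set$dockq, set[[score_name]]),
    auc = roc_auc(set[[score_name]], set$dockq, cutoff, lower_is_better),
    auc_by_cutoff = auc_curve(set, score_name, cutoffs, lower_is_better),
    hit_rate_curve = hit_rate(list(set), score_name, R_max, cutoff,
                              lower_is_better),
    mu = negative_dominance_mu(set, score_name, cutoff, lower_is_better)
  ), class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("Evaluation of score '%s'\n", x$score))
  cat(sprintf("  Spearman rho: %.4f\n", x$rho))
  cat(sprintf("  AUC(0.23):    %.4f\n", x$auc))
  cat(sprintf("  mu:           %.4f\n", x$mu))
  invisible(x)
}
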