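# DockQ-uniform subsampling and class balancing of scored decoy ensembles.
#
# A scored model set is a plain data.frame with columns `model_id`, `dockq`
# and one or more score columns; the positive/negative cutoff is DockQ 0.23.

check_scored_set <- function(set) {
  if (!all(c("model_id", "dockq") %in% names(set))) {
    stop("scored model set needs columns model_id and dockq")
  }
  if (any(set$dockq < 0 | set$dockq > 1)) stop("dockq values must lie in [0, 1]")
  invisible(set)
}

#' Assign models to evenly spaced DockQ bins
#'
#' Bin k (0-based) covers `[k/n_bins, (k+1)/n_bins)`; the last bin is
#' right-closed so DockQ = 1 falls in bin `n_bins - 1`.
#'
#' @param set Scored model set (data.frame with `model_id`, `dockq`).
#' @param n_bins Number of bins (default 20).
#' @return Integer vector of 0-based bin indices, one per record.
#' @export
bin_models <- function(set, n_bins = 20L) {
  check_scored_set(set)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  pmin(floor(set$dockq * n_bins), n_bins - 1L)
}

#' DockQ-uniform subsampling
#'
#' Keeps at most `per_bin` records per DockQ bin, drawn uniformly at random
#' without replacement; bins holding fewer records keep all of them. On an
#' abundant pool the resulting DockQ histogram is flat up to binomial noise.
#'
#' @param set Scored model set.
#' @param per_bin Maximum records retained per bin (default 50).
#' @param n_bins Number of bins (default 20).
#' @param seed Integer seed for reproducible selection.
#' @return The subsampled scored model set.
#' @export
uniform_subsample <- function(set, per_bin = 50L, n_bins = 20L, seed = 1L) {
  check_scored_set(set)
  if (per_bin < 1L) stop("per_bin must be >= 1")
  bins <- bin_models(set, n_bins)
  set.seed(seed)
  keep <- unlist(lapply(sort(unique(bins)), function(b) {
    idx <- which(bins == b)
    if (length(idx) <= per_bin) idx else sort(sample(idx, per_bin))
  }))
  out <- set[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Balance positive and negative classes
#'
#' Adds up to `n_extra_negatives` negatives (DockQ < cutoff) drawn at random
#' from `pool` (excluding model ids already selected), then randomly trims
#' the majority class until the positive (DockQ >= cutoff) and negative
#' counts are exactly equal.
#'
#' @param selected Scored model set (e.g. the output of
#'   [uniform_subsample()]).
#' @param pool Optional larger scored model set to draw extra negatives from.
#' @param cutoff Positive/negative DockQ cutoff (default 0.23).
#' @param n_extra_negatives Negatives to add from the pool (default 1000).
#' @param seed Integer seed.
#' @return Balanced scored model set with a 1:1 class ratio.
#' @export
balance_classes <- function(selected, pool = NULL, cutoff = 0.23,
                            n_extra_negatives = 1000L, seed = 1L) {
  check_scored_set(selected)
  set.seed(seed)
  out <- selected
  if (!is.null(pool) && n_extra_negatives > 0L) {
    check_scored_set(pool)
    cand <- pool[pool$dockq < cutoff & !(pool$model_id %in% out$model_id), ,
                 drop = FALSE]
    if (nrow(cand) > 0L) {
      take <- min(n_extra_negatives, nrow(cand))
      out <- rbind(out, cand[sort(sample(nrow(cand), take)), , drop = FALSE])
    }
  }
  pos <- which(out$dockq >= cutoff)
  neg <- which(out$dockq < cutoff)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both positive and negative models are required for balancing")
  }
  n <- min(length(pos), length(neg))
  keep <- c(
    if (length(pos) > n) sort(sample(pos, n)) else pos,
    if (length(neg) > n) sort(sample(neg, n)) else neg
  )
  out <- out[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
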