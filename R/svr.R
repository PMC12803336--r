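# Two-feature support vector regression scoring function on (Nc, S).
#
# The SVR predicts DockQ from the heavy-atom contact count and the interface
# separability, so larger predicted values mean more native-like models
# (the opposite orientation to energy scores).

#' Physical feature vector of a dimer model
#'
#' @param model A `dimer_structure`.
#' @param contact_cutoff Contact cutoff in Angstrom (default 4.5).
#' @param ... Passed to [interface_separability()].
#' @return Named list with `n_contacts`, `separability`, `contact_cutoff`.
#' @export
featurize <- function(model, contact_cutoff = 4.5, ...) {
  list(
    n_contacts = count_interface_contacts(model, contact_cutoff),
    separability = interface_separability(model, ...),
    contact_cutoff = contact_cutoff
  )
}

feature_matrix <- function(features) {
  if (is.matrix(features)) {
    m <- features[, c("n_contacts", "separability"), drop = FALSE]
  } else if (is.data.frame(features)) {
    m <- as.matrix(features[, c("n_contacts", "separability")])
  } else {
    m <- t(vapply(features, function(f) {
      c(f$n_contacts, f$separability)
    }, numeric(2)))
    colnames(m) <- c("n_contacts", "separability")
  }
  m
}

#' Fit the two-feature SVR scoring function
#'
#' Gaussian (radial basis) kernel epsilon-regression of DockQ on the
#' standardized features (Nc, S). Hyperparameter defaults: kernel width
#' gamma = 0.5 (the 1/(2 x unit feature variance) heuristic after
#' standardization), regularization cost 1, epsilon tube 0.1. Training is
#' deterministic given the data.
#'
#' @param features data.frame with columns `n_contacts` and `separability`,
#'   or a list of feature vectors from [featurize()].
#' @param dockq Numeric DockQ per training model.
#' @param gamma,cost,epsilon SVR hyperparameters.
#' @param seed Optional integer seed (fitting is deterministic regardless).
#' @return Object of class `ppi_svr` holding the trained regressor, its
#'   feature scaling state and the hyperparameters.
#' @export
svr_fit <- function(features, dockq, gamma = 0.5, cost = 1, epsilon = 0.1,
                    seed = NULL) {
  X <- feature_matrix(features)
  if (nrow(X) != length(dockq)) stop("features and dockq length mismatch")
  if (nrow(X) < 10L) stop("at least 10 training models are required")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature: ", paste(colnames(X)[sds == 0], collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  center <- colMeans(X)
  Xs <- scale(X, center = center, scale = sds)
  fit <- e1071::svm(
    x = Xs, y = dockq, type = "eps-regression", kernel = "radial",
    gamma = gamma, cost = cost, epsilon = epsilon, scale = FALSE
  )
  structure(list(
    fit = fit,
    center = center, scale = sds,
    gamma = gamma, cost = cost, epsilon = epsilon,
    feature_names = colnames(X), n_train = nrow(X)
  ), class = "ppi_svr")
}

#' Predict DockQ-like scores from features
#'
#' @param object A fitted `ppi_svr`.
#' @param newdata Feature data.frame or list of feature vectors.
#' @param ... Unused.
#' @return Numeric score per input; higher = predicted more native-like.
#' @export
predict.ppi_svr <- function(object, newdata, ...) {
  X <- feature_matrix(newdata)
  Xs <- scale(X, center = object$center, scale = object$scale)
  as.numeric(stats::predict(object$fit, Xs))
}

#' @export
print.ppi_svr <- function(x, ...) {
  cat("Two-feature SVR scoring function (Gaussian kernel)\n")
  cat(sprintf("  features: %s\n", paste(x$feature_names, collapse = ", ")))
  cat(sprintf("  gamma %.3g, cost %.3g, epsilon %.3g, trained on %d models\n",
              x$gamma, x$cost, x$epsilon, x$n_train))
  invisible(x)
}

#' @export
coef.ppi_svr <- function(object, ...) {
  c(gamma = object$gamma, cost = object$cost, epsilon = object$epsilon)
}

#' Leave-one-target-out evaluation of the SVR score
#'
#' For each target, the SVR is fitted on all other targets and the Spearman
#' correlation between predicted score and DockQ is evaluated on the held-out
#' target.
#'
#' @param targets Named list; each element is a list with `features` (feature
#'   data.frame) and `dockq` (numeric vector).
#' @param gamma,cost,epsilon SVR hyperparameters.
#' @param seed Optional integer seed.
#' @return List with `per_target` (named rho vector) and `mean_rho`.
#' @export
svr_leave_target_out <- function(targets, gamma = 0.5, cost = 1,
                                 epsilon = 0.1, seed = NULL) {
  if (length(targets) < 2L) stop("at least two targets are required")
  nm <- names(targets)
  if (is.null(nm)) nm <- as.character(seq_along(targets))
  nm <- sort(nm)
  rho <- vapply(nm, function(held) {
    rest <- targets[setdiff(nm, held)]
    X <- do.call(rbind, lapply(rest, function(t) feature_matrix(t$features)))
    y <- unlist(lapply(rest, function(t) t$dockq))
    fit <- svr_fit(X, y, gamma = gamma, cost = cost, epsilon = epsilon,
                   seed = seed)
    pred <- predict(fit, targets[[held]]$features)
    spearman_rho(pred, targets[[held]]$dockq)
  }, numeric(1))
  list(per_target = rho, mean_rho = mean(rho))
}
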