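# Repeated cross-validated class-comparison regressions and the combined
# elastic-net importance model.
#
# Predictive fit is always the mean, over all train/test splits, of the
# per-split test RMSE; z-scoring uses training-split means/SDs applied to
# the held-out fold (leakage-free), with a config switch for whole-dataset
# scaling.

#' Repeated k-fold cross-validation configuration
#'
#' @param n_folds Folds per repeat (default 5).
#' @param n_repeats Number of repeats (default 50, giving 250 splits).
#' @param seed Seed for fold assignment.
#' @param scaling `"train"` (z-score with training-split statistics,
#'   default) or `"whole"` (z-score once on the full dataset).
#' @return A `cv_config` list.
#' @export
cv_config <- function(n_folds = 5L, n_repeats = 50L, seed = 1L,
                      scaling = c("train", "whole")) {
  stopifnot(n_folds >= 2L, n_repeats >= 1L)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed),
                 scaling = match.arg(scaling)),
            class = "cv_config")
}

#' Elastic-net hyperparameter grid
#'
#' `alpha` is the L1 mixing fraction (0 = ridge, 1 = lasso) and `lambda`
#' the overall penalty strength, the dominant parametrisation; the
#' objective is
#' `(1/2n)*RSS + lambda * ((1-alpha)/2 * ||b||_2^2 + alpha * ||b||_1)`
#' with the intercept unpenalised and predictors z-scored.
#'
#' @param alpha_grid Mixing values in `[0, 1]`.
#' @param lambda_grid Penalty strengths `> 0`, log-spaced by default from
#'   1e-4 to 10 (spanning near-OLS to the all-zero model on z-scored
#'   predictors).
#' @return An `elastic_net_spec` list.
#' @export
elastic_net_spec <- function(alpha_grid = seq(0, 1, by = 0.1),
                             lambda_grid = 10^seq(-4, 1,
                                                  length.out = 50)) {
  stopifnot(length(alpha_grid) >= 1L, length(lambda_grid) >= 1L,
            all(alpha_grid >= 0 & alpha_grid <= 1), all(lambda_grid > 0))
  structure(list(alpha_grid = as.numeric(alpha_grid),
                 lambda_grid = as.numeric(lambda_grid)),
            class = "elastic_net_spec")
}

#' Random train/test splits for repeated k-fold CV
#'
#' Within each repeat, faces are randomly partitioned into `n_folds` test
#' folds whose sizes differ by at most one; every face appears in exactly
#' one test fold per repeat.
#'
#' @param n_faces Number of faces.
#' @param cfg A [cv_config()].
#' @return List with `fold_id` (an `n_faces x n_repeats` integer matrix of
#'   fold labels) and `splits` (list of `(train, test)` index pairs in
#'   repeat-then-fold order).
#' @export
make_splits <- function(n_faces, cfg = cv_config()) {
  if (n_faces < cfg$n_folds)
    stop("make_splits: fewer faces than folds", call. = FALSE)
  fold_id <- with_local_seed(cfg$seed, {
    vapply(seq_len(cfg$n_repeats), function(r) {
      sample(rep(seq_len(cfg$n_folds), length.out = n_faces))
    }, integer(n_faces))
  })
  splits <- list()
  for (r in seq_len(cfg$n_repeats))
    for (k in seq_len(cfg$n_folds)) {
      test <- which(fold_id[, r] == k)
      splits[[length(splits) + 1L]] <- list(train = setdiff(seq_len(n_faces),
                                                            test),
                                            test = test)
    }
  list(fold_id = fold_id, splits = splits)
}

#' Root mean square error
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("rmse: length mismatch", call. = FALSE)
  sqrt(mean((predicted - observed)^2))
}

#' Fit one elastic net
#'
#' Coordinate descent on the stated objective; `lambda = 0` reproduces OLS
#' on well-conditioned data, and `alpha = 1` with `lambda >= max|X'y_c|/n`
#' zeroes every coefficient, leaving `intercept = mean(y)`.
#'
#' @param X Numeric predictor matrix (typically z-scored).
#' @param y Numeric outcome.
#' @param alpha L1 mixing fraction in `[0, 1]`.
#' @param lambda Penalty strength `>= 0`.
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param maxit Iteration cap.
#' @return List with `beta` (named), `intercept`, `iterations`,
#'   `converged`.
#' @export
fit_elastic_net <- function(X, y, alpha, lambda, tol = 1e-9,
                            maxit = 100000L) {
  X <- as.matrix(X)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("fit_elastic_net: non-finite input", call. = FALSE)
  fit <- enet_fit_cpp(X, as.numeric(y), alpha, lambda, tol = tol,
                      maxit = maxit)
  if (!fit$converged)
    stop(sprintf(
      "fit_elastic_net: no convergence in %d iterations (alpha=%g, lambda=%g)",
      maxit, alpha, lambda), call. = FALSE)
  names(fit$beta) <- colnames(X)
  fit
}

#' Elastic-net objective value
#'
#' @inheritParams fit_elastic_net
#' @param beta,intercept Candidate solution.
#' @return Scalar objective value.
#' @export
enet_objective <- function(X, y, beta, intercept, alpha, lambda) {
  n <- length(y)
  r <- y - intercept - as.numeric(as.matrix(X) %*% beta)
  sum(r^2) / (2 * n) +
    lambda * ((1 - alpha) / 2 * sum(beta^2) + alpha * sum(abs(beta)))
}

# z-score columns, erroring on constants.
.zscore_matrix <- function(X) {
  for (j in seq_len(ncol(X))) X[, j] <- zscore(X[, j],
                                               name = colnames(X)[j])
  X
}

#' Tune elastic-net hyperparameters by repeated CV
#'
#' Evaluates the whole `(alpha, lambda)` grid with the same repeated-CV
#' splits used downstream and returns the grid point with the lowest mean
#' test RMSE.  Ties are broken toward larger `lambda`, then larger `alpha`
#' (the sparser model).
#'
#' @inheritParams fit_elastic_net
#' @param spec An [elastic_net_spec()].
#' @param cfg A [cv_config()].
#' @param fold_id Optional precomputed fold matrix from [make_splits()].
#' @return List `(alpha, lambda, cv_rmse, grid)`; `grid` is a tibble of
#'   mean CV RMSE for every grid point.
#' @export
tune_elastic_net <- function(X, y, spec = elastic_net_spec(),
                             cfg = cv_config(), fold_id = NULL) {
  X <- as.matrix(X)
  if (stats::sd(y) == 0)
    stop("tune_elastic_net: constant outcome", call. = FALSE)
  if (is.null(fold_id)) fold_id <- make_splits(nrow(X), cfg)$fold_id
  scale_cols <- cfg$scaling == "train"
  if (!scale_cols) X <- .zscore_matrix(X)
  M <- enet_cv_grid_cpp(X, as.numeric(y), fold_id, spec$alpha_grid,
                        spec$lambda_grid, scale_cols = scale_cols)
  grid <- tidyr::expand_grid(alpha = spec$alpha_grid,
                             lambda = spec$lambda_grid) |>
    dplyr::mutate(cv_rmse = as.numeric(t(M)))
  best <- grid |>
    dplyr::arrange(.data$cv_rmse, dplyr::desc(.data$lambda),
                   dplyr::desc(.data$alpha)) |>
    dplyr::slice(1)
  list(alpha = best$alpha, lambda = best$lambda, cv_rmse = best$cv_rmse,
       grid = grid)
}

# Minimum-norm OLS coefficients via SVD; warns once on rank deficiency.
.ols_min_norm <- function(X, y, warn = TRUE) {
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(sv$d, 0)
  keep <- sv$d > tol
  if (warn && sum(keep) < ncol(X))
    warning("rank-deficient design; using the minimum-norm solution",
            call. = FALSE)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  as.numeric(sv$v %*% (dinv * crossprod(sv$u, y)))
}

# Cross-validated OLS RMSE for one predictor set: z-score with training
# stats (or whole-data), fit minimum-norm OLS, score the held-out fold.
.ols_cv_rmse <- function(X, y, splits, scaling = "train") {
  X <- as.matrix(X)
  if (scaling == "whole") X <- .zscore_matrix(X)
  vapply(splits, function(sp) {
    Xtr <- X[sp$train, , drop = FALSE]
    Xte <- X[sp$test, , drop = FALSE]
    mu <- colMeans(Xtr)
    if (scaling == "train") {
      sdv <- apply(Xtr, 2, stats::sd)
      sdv[sdv < 1e-12] <- Inf  # constant on this split: column drops to 0
    } else sdv <- rep(1, ncol(X))
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
    ym <- mean(y[sp$train])
    beta <- .ols_min_norm(Xtr, y[sp$train] - ym, warn = FALSE)
    rmse(ym + as.numeric(Xte %*% beta), y[sp$test])
  }, numeric(1))
}

#' Compare the predictive power of the three feature classes
#'
#' Fits, for each preference attribute and each feature class, an ordinary
#' least-squares model on that class's predictors alone under repeated
#' k-fold CV, and reports the mean and SD of the per-split test RMSE.  The
#' contrast class uses all 12 contrast features, including the deltaE
#' contrasts.  Rank-deficient training designs fall back to the
#' minimum-norm solution.
#'
#' @param features Tibble with `face_id` and the 19 feature columns.
#' @param scores Tibble from [mean_scores()].
#' @param cfg A [cv_config()].
#' @param partition Named list of feature classes
#'   (default [feature_classes()]).
#' @param attributes Attributes to model (default all score columns).
#' @return Object of class `facecolr_classcmp`: tibble
#'   `(attribute, class, mean_rmse, sd_rmse)` with per-split RMSEs in the
#'   `splits` attribute.
#' @export
separate_class_models <- function(features, scores, cfg = cv_config(),
                                  partition = feature_classes(),
                                  attributes = NULL) {
  merged <- dplyr::inner_join(features, scores, by = "face_id")
  if (nrow(merged) < 3L)
    stop("separate_class_models: need at least 3 faces", call. = FALSE)
  if (is.null(attributes))
    attributes <- setdiff(colnames(scores), c("face_id", "n_observers"))
  splits <- make_splits(nrow(merged), cfg)$splits
  per_split <- tidyr::expand_grid(attribute = attributes,
                                  class = names(partition)) |>
    purrr::pmap_dfr(function(attribute, class) {
      rs <- .ols_cv_rmse(merged[, partition[[class]], drop = FALSE],
                         merged[[attribute]], splits,
                         scaling = cfg$scaling)
      tibble::tibble(attribute = attribute, class = class,
                     split = seq_along(rs), rmse = rs)
    })
  out <- per_split |>
    dplyr::group_by(.data$attribute, .data$class) |>
    dplyr::summarise(mean_rmse = mean(.data$rmse),
                     sd_rmse = stats::sd(.data$rmse),
                     n_splits = dplyr::n(), .groups = "drop")
  attr(out, "splits") <- per_split
  class(out) <- c("facecolr_classcmp", class(out))
  out
}

#' Combined elastic-net importance model
#'
#' Enters the sixteen colour characteristics (the deltaE contrasts are
#' excluded as near-collinear with their channel contrasts) into one
#' penalised regression: `(alpha, lambda)` are tuned once over the full
#' grid by repeated-CV mean RMSE, then the model is refit on each of the
#' training splits at the chosen pair, collecting per-split test RMSEs and
#' standardized coefficients.  Predictor importance is the rank of the
#' absolute mean signed coefficient.
#'
#' @inheritParams separate_class_models
#' @param attribute Single attribute to model.
#' @param spec An [elastic_net_spec()].
#' @param predictors Predictor columns (default [combined_predictors()]).
#' @return Object of class `facecolr_enet`.
#' @export
combined_model <- function(features, scores, attribute,
                           cfg = cv_config(), spec = elastic_net_spec(),
                           predictors = combined_predictors()) {
  merged <- dplyr::inner_join(features, scores, by = "face_id")
  miss <- setdiff(predictors, colnames(merged))
  if (length(miss) > 0)
    stop("combined_model: missing predictor(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(merged[, predictors, drop = FALSE])
  y <- merged[[attribute]]
  fold_id <- make_splits(nrow(merged), cfg)$fold_id
  tuned <- tune_elastic_net(X, y, spec, cfg, fold_id = fold_id)
  scale_cols <- cfg$scaling == "train"
  Xr <- if (scale_cols) X else .zscore_matrix(X)
  refit <- enet_refit_splits_cpp(Xr, as.numeric(y), fold_id, tuned$alpha,
                                 tuned$lambda, scale_cols = scale_cols)
  betas <- refit$beta
  colnames(betas) <- predictors
  beta_bar <- colMeans(betas)
  coef_tbl <- tibble::tibble(term = predictors, estimate = beta_bar,
                             abs_estimate = abs(beta_bar)) |>
    dplyr::arrange(dplyr::desc(.data$abs_estimate)) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(list(attribute = attribute, alpha = tuned$alpha,
                 lambda = tuned$lambda, tuning_grid = tuned$grid,
                 split_rmse = refit$rmse, split_beta = betas,
                 coefficients = coef_tbl,
                 mean_rmse = mean(refit$rmse),
                 sd_rmse = stats::sd(refit$rmse),
                 n_splits = length(refit$rmse),
                 n_faces = nrow(merged), cfg = cfg),
            class = "facecolr_enet")
}

#' @export
print.facecolr_enet <- function(x, ...) {
  cat(sprintf(
    "Combined elastic-net model for '%s' (n = %d faces, %d splits)\n",
    x$attribute, x$n_faces, x$n_splits))
  cat(sprintf("  alpha = %.2f, lambda = %.4g\n", x$alpha, x$lambda))
  cat(sprintf("  mean RMSE = %.3f (SD %.3f)\n", x$mean_rmse, x$sd_rmse))
  cat("  top predictors by |mean beta|:\n")
  top <- utils::head(x$coefficients, 5)
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %2d. %-14s %+0.3f\n", top$rank[i], top$term[i],
                top$estimate[i]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.facecolr_enet <- function(x, ...) x$coefficients

#' @importFrom generics glance
#' @export
glance.facecolr_enet <- function(x, ...) {
  tibble::tibble(attribute = x$attribute, mean_rmse = x$mean_rmse,
                 sd_rmse = x$sd_rmse, alpha = x$alpha, lambda = x$lambda,
                 n_splits = x$n_splits, n_faces = x$n_faces)
}

#' @export
tidy.facecolr_classcmp <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
autoplot.facecolr_enet <- function(object, ...) {
  df <- object$coefficients
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$term,
                                                      .data$abs_estimate),
                                   y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean standardized coefficient",
                  title = sprintf("Predictor importance: %s",
                                  object$attribute)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.facecolr_classcmp <- function(object, ...) {
  df <- attr(object, "splits")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$rmse)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "black",
                          size = 2) +
    ggplot2::facet_wrap(~attribute, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "test RMSE") +
    ggplot2::theme_minimal()
}
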