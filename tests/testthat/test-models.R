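# Cross-validation layout, elastic-net correctness and the two modelling
# surfaces.

test_that("repeated CV splits partition faces with near-equal folds", {
  sp <- make_splits(10, cv_config(n_folds = 5, n_repeats = 3, seed = 1))
  expect_equal(dim(sp$fold_id), c(10L, 3L))
  expect_length(sp$splits, 15L)
  for (r in 1:3) {
    sizes <- table(sp$fold_id[, r])
    expect_true(all(sizes == 2))
  }
  # every id is tested exactly n_repeats times
  test_counts <- table(unlist(lapply(sp$splits, `[[`, "test")))
  expect_true(all(test_counts == 3))
  # reproducibility, and uneven n handled with sizes differing by <= 1
  sp2 <- make_splits(10, cv_config(n_folds = 5, n_repeats = 3, seed = 1))
  expect_identical(sp$fold_id, sp2$fold_id)
  sp3 <- make_splits(13, cv_config(n_folds = 5, n_repeats = 2, seed = 4))
  sizes <- table(sp3$fold_id[, 1])
  expect_lte(diff(range(sizes)), 1)
  expect_error(make_splits(3, cv_config(n_folds = 5)), "fewer faces")
})

test_that("rmse matches its definition", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(2, 0), c(1, 1)), 1)
  expect_error(rmse(1:3, 1:4), "length")
  set.seed(6)
  p <- rnorm(40); o <- rnorm(40)
  expect_equal(rmse(p, o), naive_rmse(p, o), tolerance = 1e-12)
})

test_that("elastic net reproduces OLS at lambda = 0", {
  set.seed(20)
  for (i in 1:5) {
    X <- matrix(rnorm(60 * 5), 60, 5)
    y <- rnorm(60)
    fit <- fit_elastic_net(X, y, alpha = runif(1), lambda = 0)
    ref <- normal_equations_ols(X, y)
    expect_lt(max(abs(c(fit$intercept, fit$beta) - ref)), 1e-6)
  }
})

test_that("lasso null threshold zeroes all coefficients", {
  set.seed(21)
  X <- scale(matrix(rnorm(50 * 8), 50, 8))
  y <- rnorm(50)
  lam_max <- max(abs(crossprod(X, y - mean(y)))) / 50
  fit <- fit_elastic_net(X, y, alpha = 1, lambda = lam_max * 1.0001)
  expect_true(all(fit$beta == 0))
  expect_equal(fit$intercept, mean(y))
})

test_that("ridge splits the coefficient equally over duplicated predictors", {
  set.seed(22)
  x <- rnorm(80)
  X <- cbind(x, x)
  y <- 2 * x + rnorm(80, 0, 0.1)
  fit <- fit_elastic_net(X, y, alpha = 0, lambda = 0.5)
  expect_equal(fit$beta[[1]], fit$beta[[2]], tolerance = 1e-8)
  single <- fit_elastic_net(cbind(x), y, alpha = 0, lambda = 0.5)
  expect_gt(abs(fit$beta[[1]]), 0)
  expect_lt(abs(fit$beta[[1]]), abs(single$beta[[1]]))
})

test_that("soft-threshold closed form holds on orthonormal designs", {
  set.seed(23)
  n <- 64; p <- 6
  # mean-zero orthonormal columns: orthonormalise centred random vectors
  M <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  X <- qr.Q(qr(M)) * sqrt(n)            # ||x_j||^2 / n = 1, X'X/n = I
  y <- rnorm(n); y <- y - mean(y)
  rho <- as.numeric(crossprod(X, y)) / n
  prev <- NULL
  for (lam in c(0.5, 0.2, 0.1, 0.05, 0.01)) {
    fit <- fit_elastic_net(X, y, alpha = 1, lambda = lam)
    closed <- sign(rho) * pmax(abs(rho) - lam, 0)
    expect_equal(unname(fit$beta), closed, tolerance = 1e-6)
    # coefficient magnitudes are non-increasing in lambda
    if (!is.null(prev)) expect_true(all(abs(fit$beta) >= abs(prev) - 1e-10))
    prev <- fit$beta
  }
})

test_that("returned solutions are locally optimal for the stated objective", {
  set.seed(24)
  X <- matrix(rnorm(50 * 6), 50, 6)
  y <- rnorm(50)
  for (pars in list(c(0.3, 0.2), c(1, 0.05), c(0, 0.4))) {
    fit <- fit_elastic_net(X, y, pars[1], pars[2])
    o0 <- enet_objective(X, y, fit$beta, fit$intercept, pars[1], pars[2])
    for (i in 1:30) {
      d <- rnorm(6, 0, 1e-3)
      o1 <- enet_objective(X, y, fit$beta + d, fit$intercept, pars[1],
                           pars[2])
      expect_gte(o1, o0 - 1e-12)
    }
  }
})

test_that("solver attains at least the glmnet objective at equal penalties", {
  skip_if_not_installed("glmnet")
  set.seed(25)
  X <- scale(matrix(rnorm(40 * 10), 40, 10))
  y <- rnorm(40)
  for (pars in list(c(0.5, 0.1), c(1, 0.05), c(0.2, 0.3))) {
    g <- glmnet::glmnet(X, y, alpha = pars[1], lambda = pars[2],
                        standardize = FALSE, thresh = 1e-14, maxit = 1e7)
    fit <- fit_elastic_net(X, y, pars[1], pars[2])
    o_mine <- enet_objective(X, y, fit$beta, fit$intercept, pars[1],
                             pars[2])
    o_glm <- enet_objective(X, y, as.numeric(g$beta), as.numeric(g$a0),
                            pars[1], pars[2])
    expect_lte(o_mine, o_glm + 1e-8)
    expect_lt(max(abs(fit$beta - as.numeric(g$beta))), 0.02)
  }
})

test_that("hyperparameter tuning finds near-OLS fits for noiseless outcomes", {
  set.seed(26)
  co <- generate_cohort(cohort_spec(n_faces = 40L, seed = 26L),
                        render = FALSE)
  ft <- co$ground_truth
  Z <- apply(as.matrix(ft[, combined_predictors()]), 2, zscore)
  y <- as.numeric(Z[, "L"] * 1.0 - Z[, "MCDM"] * 0.8)
  spec <- elastic_net_spec(alpha_grid = c(0, 0.5, 1),
                           lambda_grid = 10^seq(-4, 1, length.out = 15))
  tuned <- tune_elastic_net(Z, y, spec, cv_config(n_repeats = 10, seed = 2))
  expect_lt(tuned$lambda, 0.01)
  expect_lt(tuned$cv_rmse, 0.05 * sd(y))
  # grid of one point returns it
  one <- elastic_net_spec(alpha_grid = 0.4, lambda_grid = 0.2)
  t1 <- tune_elastic_net(Z, y, one, cv_config(n_repeats = 3, seed = 2))
  expect_equal(t1$alpha, 0.4)
  expect_equal(t1$lambda, 0.2)
})

test_that("tuning shrinks coefficients when the outcome is independent noise", {
  set.seed(27)
  co <- generate_cohort(cohort_spec(n_faces = 40L, seed = 27L),
                        render = FALSE)
  ft <- co$ground_truth
  sc <- tibble::tibble(face_id = ft$face_id, attractiveness = rnorm(40))
  m <- combined_model(ft, sc, "attractiveness",
                      cv_config(n_repeats = 10, seed = 3),
                      elastic_net_spec(alpha_grid = c(0, 0.5, 1),
                                       lambda_grid = 10^seq(-4, 1,
                                                            length.out = 15)))
  expect_lt(max(abs(m$coefficients$estimate)), 0.25)
  expect_lt(abs(m$mean_rmse - sd(sc$attractiveness)),
            0.25 * sd(sc$attractiveness))
})

test_that("class comparison attributes predictive power to the generating class", {
  set.seed(28)
  co <- generate_cohort(cohort_spec(n_faces = 40L, seed = 28L),
                        render = FALSE)
  ft <- co$ground_truth
  # noiseless outcome from class-1 features only
  Z1 <- apply(as.matrix(ft[, feature_classes()$average_local]), 2, zscore)
  y <- as.numeric(Z1 %*% c(0.8, -0.5, 0.4, 0.3, -0.3))
  sc <- tibble::tibble(face_id = ft$face_id, attractiveness = y)
  cc <- separate_class_models(ft, sc, cv_config(n_repeats = 10, seed = 5))
  tbl <- tidy(cc)
  r1 <- tbl$mean_rmse[tbl$class == "average_local"]
  expect_lt(r1, 0.05 * sd(y))
  expect_gt(min(tbl$mean_rmse[tbl$class != "average_local"]), 0.4 * sd(y))
  expect_equal(unique(tbl$n_splits), 50L)
  # pure-noise outcome: every class near the outcome SD
  sc2 <- tibble::tibble(face_id = ft$face_id, attractiveness = rnorm(40))
  cc2 <- separate_class_models(ft, sc2, cv_config(n_repeats = 10, seed = 6))
  tbl2 <- tidy(cc2)
  expect_true(all(abs(tbl2$mean_rmse - sd(sc2$attractiveness)) <
                    0.45 * sd(sc2$attractiveness)))
})

test_that("single perfect predictor gives zero CV error", {
  set.seed(29)
  x <- rnorm(30)
  ft <- tibble::tibble(face_id = paste0("f", 1:30), L = x)
  sc <- tibble::tibble(face_id = ft$face_id, attractiveness = 2 * x + 1)
  cc <- separate_class_models(ft, sc, cv_config(n_repeats = 5, seed = 7),
                              partition = list(average_local = "L"))
  expect_lt(tidy(cc)$mean_rmse, 1e-8)
})

test_that("combined model is exactly reproducible and reports a full ranking", {
  set.seed(31)
  co <- generate_cohort(cohort_spec(n_faces = 40L, seed = 31L),
                        render = FALSE)
  ft <- co$ground_truth
  Z <- apply(as.matrix(ft[, combined_predictors()]), 2, zscore)
  y <- as.numeric(Z[, "MCDM"] * -0.5) + rnorm(40, 0, 0.5)
  sc <- tibble::tibble(face_id = ft$face_id, healthiness = y)
  spec <- elastic_net_spec(alpha_grid = c(0, 0.5, 1),
                           lambda_grid = 10^seq(-3, 0.5, length.out = 10))
  m1 <- combined_model(ft, sc, "healthiness",
                       cv_config(n_repeats = 10, seed = 8), spec)
  m2 <- combined_model(ft, sc, "healthiness",
                       cv_config(n_repeats = 10, seed = 8), spec)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$split_rmse, m2$split_rmse)
  expect_setequal(m1$coefficients$term, combined_predictors())
  expect_equal(sort(m1$coefficients$rank), 1:16)
  expect_equal(m1$n_splits, 50L)
  g <- glance(m1)
  expect_named(g, c("attribute", "mean_rmse", "sd_rmse", "alpha", "lambda",
                    "n_splits", "n_faces"))
  expect_s3_class(tidy(m1), "tbl_df")
})

test_that("whole-dataset scaling mode is available and distinct", {
  set.seed(32)
  co <- generate_cohort(cohort_spec(n_faces = 30L, seed = 32L),
                        render = FALSE)
  ft <- co$ground_truth
  y <- zscore(ft$MCDM) * 0.7 + rnorm(30, 0, 0.5)
  sc <- tibble::tibble(face_id = ft$face_id, attractiveness = y)
  spec <- elastic_net_spec(alpha_grid = 0.5,
                           lambda_grid = 10^seq(-3, 0, length.out = 8))
  mt <- combined_model(ft, sc, "attractiveness",
                       cv_config(n_repeats = 5, seed = 9), spec)
  mw <- combined_model(ft, sc, "attractiveness",
                       cv_config(n_repeats = 5, seed = 9,
                                 scaling = "whole"), spec)
  expect_false(identical(mt$split_rmse, mw$split_rmse))
  # both recover the true driver as top predictor
  expect_equal(mt$coefficients$term[1], "MCDM")
  expect_equal(mw$coefficients$term[1], "MCDM")
})
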