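# Independent naive oracles used across the suite.  All are deliberately
# written as explicit per-element loops over the textbook formulas, not via
# the package's own code paths.

naive_delta_e <- function(c1, c2) {
  s <- 0
  for (k in 1:3) s <- s + (c1[k] - c2[k])^2
  sqrt(s)
}

# px: n x 3 matrix of Lab pixels
naive_mcdm <- function(px) {
  n <- nrow(px)
  mu <- c(sum(px[, 1]), sum(px[, 2]), sum(px[, 3])) / n
  tot <- 0
  for (i in seq_len(n)) tot <- tot + naive_delta_e(px[i, ], mu)
  tot / n
}

naive_region_mean <- function(px) {
  n <- nrow(px)
  out <- c(0, 0, 0)
  for (i in seq_len(n)) out <- out + px[i, ]
  out / n
}

naive_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

naive_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df = df))
}

naive_cronbach <- function(M) {
  k <- ncol(M)
  item_var <- 0
  for (j in seq_len(k)) item_var <- item_var + stats::var(M[, j])
  k / (k - 1) * (1 - item_var / stats::var(rowSums(M)))
}

naive_rmse <- function(pred, obs) {
  s <- 0
  for (i in seq_along(pred)) s <- s + (pred[i] - obs[i])^2
  sqrt(s / length(pred))
}

# OLS coefficients (with intercept) via the normal equations.
normal_equations_ols <- function(X, y) {
  X1 <- cbind(1, X)
  as.numeric(solve(t(X1) %*% X1, t(X1) %*% y))
}

# Build a lab_image + region_mask pair from a named list of pixel blocks.
# Each block is painted as a horizontal strip; remaining rows become
# background.  `colours` maps region -> single Lab colour; `pixels` maps
# region -> n x 3 matrix painted into the strip.
make_strip_face <- function(pixels) {
  regions <- names(pixels)
  ncol_img <- max(vapply(pixels, nrow, integer(1)))
  H <- length(regions)
  img <- array(0, dim = c(H, ncol_img, 3))
  labels <- matrix(0L, H, ncol_img)
  legend <- stats::setNames(seq_along(regions), regions)
  for (i in seq_along(regions)) {
    px <- pixels[[i]]
    for (j in seq_len(nrow(px))) {
      img[i, j, ] <- px[j, ]
      labels[i, j] <- legend[[regions[i]]]
    }
  }
  list(image = lab_image(img), mask = region_mask(labels, legend))
}

random_lab_pixels <- function(n, L = c(30, 80), a = c(-20, 30),
                              b = c(-20, 40)) {
  cbind(stats::runif(n, L[1], L[2]), stats::runif(n, a[1], a[2]),
        stats::runif(n, b[1], b[2]))
}

# Fast tiny pipeline config for smoke/determinism tests.
small_run_config <- function(seed, out_dir) {
  cfg <- default_run_config(seed = seed, out_dir = out_dir,
                            n_faces = 12L, image_size = 96L,
                            n_observers = 6L, n_folds = 4L,
                            n_repeats = 5L)
  cfg$enet <- list(alpha_grid = c(0, 0.5, 1),
                   lambda_grid = 10^seq(-3, 0.5, length.out = 12))
  cfg
}
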