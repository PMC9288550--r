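# The nineteen colour characteristics against naive per-pixel oracles.

test_that("region_mean averages exactly, including against a loop oracle", {
  f <- make_strip_face(list(
    cheek = matrix(rep(c(60, 12, 15), 4), ncol = 3, byrow = TRUE),
    nose = matrix(c(50, 0, 0, 70, 10, 20), ncol = 3, byrow = TRUE)))
  expect_equal(unname(region_mean(f$image, f$mask, "cheek")), c(60, 12, 15))
  expect_equal(unname(region_mean(f$image, f$mask, "nose")), c(60, 5, 10))
  set.seed(8)
  px <- random_lab_pixels(137)
  f2 <- make_strip_face(list(forehead = px))
  expect_equal(unname(region_mean(f2$image, f2$mask, "forehead")),
               naive_region_mean(px), tolerance = 1e-9)
})

test_that("empty regions raise errors naming the region", {
  f <- make_strip_face(list(cheek = matrix(c(60, 12, 15), ncol = 3)))
  expect_error(region_mean(f$image, f$mask, "chin"), "chin")
  expect_error(mcdm(f$image, f$mask, "forehead"), "forehead")
})

test_that("average facial colour pools skin labels and excludes features", {
  skin <- c(65, 10, 14)
  f <- make_strip_face(list(
    facial_skin = matrix(rep(skin, 5), ncol = 3, byrow = TRUE),
    forehead = matrix(rep(skin, 3), ncol = 3, byrow = TRUE),
    mouth = matrix(rep(c(40, 30, 10), 4), ncol = 3, byrow = TRUE),
    eyes = matrix(rep(c(20, 0, 0), 2), ncol = 3, byrow = TRUE),
    nose = matrix(rep(c(80, 0, 0), 2), ncol = 3, byrow = TRUE)))
  expect_equal(unname(average_facial_colour(f$image, f$mask)), skin)
  # single-pixel facial skin region
  f1 <- make_strip_face(list(facial_skin = matrix(c(61, 9, 13), ncol = 3)))
  expect_equal(unname(average_facial_colour(f1$image, f1$mask)),
               c(61, 9, 13))
})

test_that("local skin colour picks cheek a* and periorbital L*", {
  f <- make_strip_face(list(
    cheek = matrix(rep(c(60, 13, 15), 3), ncol = 3, byrow = TRUE),
    periorbital = matrix(rep(c(58, 9, 12), 3), ncol = 3, byrow = TRUE)))
  loc <- local_skin_colour(f$image, f$mask)
  expect_equal(unname(loc["cheek_a"]), 13)
  expect_equal(unname(loc["periorbital_L"]), 58)
  set.seed(21)
  px1 <- random_lab_pixels(40); px2 <- random_lab_pixels(33)
  f2 <- make_strip_face(list(cheek = px1, periorbital = px2))
  loc2 <- local_skin_colour(f2$image, f2$mask)
  expect_equal(unname(loc2["cheek_a"]), naive_region_mean(px1)[2],
               tolerance = 1e-9)
  expect_equal(unname(loc2["periorbital_L"]), naive_region_mean(px2)[1],
               tolerance = 1e-9)
})

test_that("MCDM matches the naive per-pixel oracle and its invariances", {
  # uniform region
  f <- make_strip_face(list(cheek = matrix(rep(c(60, 12, 15), 6), ncol = 3,
                                           byrow = TRUE)))
  expect_identical(mcdm(f$image, f$mask, "cheek"), 0)
  # symmetric two-pixel pair: each 1 unit from the mean
  f2 <- make_strip_face(list(cheek = matrix(c(50, 0, 0, 50, 0, 2),
                                            ncol = 3, byrow = TRUE)))
  expect_equal(mcdm(f2$image, f2$mask, "cheek"), 1)
  set.seed(13)
  for (i in 1:5) {
    px <- random_lab_pixels(2500)  # a 50 x 50 patch
    f3 <- make_strip_face(list(forehead = px))
    m <- mcdm(f3$image, f3$mask, "forehead")
    expect_equal(m, naive_mcdm(px), tolerance = 1e-9)
    # permutation invariance
    f4 <- make_strip_face(list(forehead = px[sample(nrow(px)), ]))
    expect_equal(mcdm(f4$image, f4$mask, "forehead"), m, tolerance = 1e-9)
    # rigid rotation about the region mean (CIE76 is an isometry);
    # recentre at mid-grey so rotated lightness stays in range
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    mu <- colMeans(px)
    pxr <- sweep(sweep(px, 2, mu) %*% Q, 2, c(50, 0, 0), "+")
    f5 <- make_strip_face(list(forehead = pxr))
    expect_equal(mcdm(f5$image, f5$mask, "forehead"), m, tolerance = 1e-9)
    # scaling deviations by k scales MCDM by k
    k <- runif(1, 0, 2)
    pxs <- sweep(sweep(px, 2, mu) * k, 2, mu, "+")
    f6 <- make_strip_face(list(forehead = pxs))
    expect_equal(mcdm(f6$image, f6$mask, "forehead"), k * m,
                 tolerance = 1e-9)
  }
})

test_that("whole-face MCDM is the unweighted grand mean of four regions", {
  # two-pixel regions at distance 2d have MCDM d
  mk <- function(d) matrix(c(50, 0, -d, 50, 0, d), ncol = 3, byrow = TRUE)
  f <- make_strip_face(list(forehead = mk(1), cheek = mk(2), nose = mk(3),
                            chin = mk(4)))
  expect_equal(mcdm_whole_face(f$image, f$mask), 2.5)
  # uniform regions give zero
  u <- matrix(rep(c(60, 10, 10), 2), ncol = 3, byrow = TRUE)
  f0 <- make_strip_face(list(forehead = u, cheek = u, nose = u, chin = u))
  expect_identical(mcdm_whole_face(f0$image, f0$mask), 0)
  # differs from pooled-pixel MCDM when region means differ
  set.seed(4)
  pieces <- lapply(c(0, 15, 30, 45), function(off)
    sweep(random_lab_pixels(50, L = c(40, 50)), 2, c(off, 0, 0), "+"))
  names(pieces) <- c("forehead", "cheek", "nose", "chin")
  f2 <- make_strip_face(pieces)
  grand <- mcdm_whole_face(f2$image, f2$mask)
  pooled <- naive_mcdm(do.call(rbind, pieces))
  expect_equal(grand, mean(vapply(pieces, naive_mcdm, numeric(1))),
               tolerance = 1e-9)
  expect_gt(abs(grand - pooled), 1)
})

test_that("Michelson contrast arithmetic and degeneracy guard", {
  expect_equal(michelson_contrast(60, 20), 0.5)
  expect_equal(michelson_contrast(35, 35), 0)
  expect_error(michelson_contrast(10, -10), "degenerate")
  err <- tryCatch(michelson_contrast(1e-7, -2e-8, channel = "mouth-a"),
                  error = identity)
  expect_s3_class(err, "facecolr_degenerate_contrast")
  expect_match(conditionMessage(err), "mouth-a")
  # scale invariance
  set.seed(31)
  for (i in 1:50) {
    s <- runif(1, 10, 80); fv <- runif(1, 1, 80); k <- runif(1, 0.1, 5)
    expect_equal(michelson_contrast(s, fv), michelson_contrast(k * s, k * fv),
                 tolerance = 1e-12)
  }
})

test_that("feature contrasts combine channel contrasts and deltaE", {
  f <- make_strip_face(list(
    mouth = matrix(rep(c(30, 20, 10), 3), ncol = 3, byrow = TRUE),
    mouth_surround = matrix(rep(c(60, 10, 15), 4), ncol = 3, byrow = TRUE)))
  fc <- feature_contrasts(f$image, f$mask, "mouth")
  expect_equal(unname(fc["C_L"]), 30 / 90)
  expect_equal(unname(fc["C_a"]), 10 / 30)
  expect_equal(unname(fc["C_b"]), 5 / 25)
  expect_equal(unname(fc["dE"]), sqrt(1025))
  # feature identical to surround: all zero
  u <- matrix(rep(c(55, 12, 9), 2), ncol = 3, byrow = TRUE)
  f0 <- make_strip_face(list(eyes = u, eyes_surround = u))
  expect_equal(unname(feature_contrasts(f0$image, f0$mask, "eyes")),
               c(0, 0, 0, 0))
  # against the scalar oracle on random region contents
  set.seed(44)
  px_f <- random_lab_pixels(30, L = c(20, 40), a = c(2, 20), b = c(2, 20))
  px_s <- random_lab_pixels(50, L = c(50, 70), a = c(2, 20), b = c(2, 20))
  f2 <- make_strip_face(list(brows = px_f, brows_surround = px_s))
  fc2 <- feature_contrasts(f2$image, f2$mask, "brows")
  mf <- naive_region_mean(px_f); ms <- naive_region_mean(px_s)
  expect_equal(unname(fc2["C_L"]), abs((ms[1] - mf[1]) / (ms[1] + mf[1])),
               tolerance = 1e-9)
  expect_equal(unname(fc2["dE"]), naive_delta_e(mf, ms), tolerance = 1e-9)
})

test_that("extract_features fills all 19 fields and is deterministic", {
  face <- generate_face(face_spec(size = 96L, seed = 5L))
  ft <- extract_features(face$image, face$mask, face_id = "f1")
  expect_named(ft, c("face_id", feature_names()))
  ft2 <- extract_features(face$image, face$mask, face_id = "f1")
  expect_identical(ft, ft2)
  expect_true(all(as.matrix(ft[, c("MCDM", "MCDM_cheek",
                                   grep("_C_|_dE", feature_names(),
                                        value = TRUE))]) >= 0))
})

test_that("a fully uniform face yields zero variation and contrast", {
  spec <- face_spec(skin_mean = c(60, 10, 12),
                    region_offsets = list(forehead = c(0, 0, 0),
                                          cheek = c(0, 0, 0),
                                          nose = c(0, 0, 0),
                                          chin = c(0, 0, 0),
                                          periorbital = c(0, 0, 0)),
                    target_mcdm = c(facial_skin = 0, forehead = 0,
                                    cheek = 0, nose = 0, chin = 0,
                                    periorbital = 0),
                    feature_means = list(eyes = c(60, 10, 12),
                                         brows = c(60, 10, 12),
                                         mouth = c(60, 10, 12)),
                    feature_mcdm = 0, size = 96L, seed = 1L)
  face <- generate_face(spec)
  ft <- extract_features(face$image, face$mask)
  expect_equal(c(ft$L, ft$a, ft$b), c(60, 10, 12))
  expect_equal(ft$MCDM, 0)
  expect_equal(max(abs(as.matrix(ft[, grep("_C_|_dE|MCDM",
                                           colnames(ft))]))), 0)
})

test_that("feature vector is invariant to pixel permutation within regions", {
  face <- generate_face(face_spec(size = 64L, seed = 33L))
  ft <- extract_features(face$image, face$mask)
  set.seed(99)
  img <- face$image
  px <- matrix(img, ncol = 3)
  for (lab in unname(face$mask$legend)) {
    idx <- which(face$mask$labels == lab)
    if (length(idx) > 1) px[idx, ] <- px[sample(idx), ]
  }
  img2 <- lab_image(array(px, dim = dim(img)))
  expect_equal(extract_features(img2, face$mask), ft, tolerance = 1e-12)
})

test_that("surround dilation builds a ring from allowed skin labels only", {
  labels <- matrix(0L, 20, 20)
  labels[5:16, 5:16] <- 1L    # facial skin block
  labels[10:11, 10:11] <- 2L  # mouth
  m <- region_mask(labels, c(facial_skin = 1L, mouth = 2L))
  m2 <- add_surround(m, "mouth", radius = 2L)
  ring <- m2$labels == m2$legend[["mouth_surround"]]
  expect_gt(sum(ring), 0)
  expect_true(all(m$labels[ring] == 1L))          # only skin converted
  expect_identical(sum(m2$labels == 2L), sum(labels == 2L))  # mouth intact
  rows <- which(ring, arr.ind = TRUE)
  expect_true(all(rows >= 8 & rows <= 13))        # Chebyshev radius 2
})

test_that("masks round trip through PNG + JSON legend", {
  face <- generate_face(face_spec(size = 48L, seed = 3L))
  d <- withr::local_tempdir()
  p <- file.path(d, "mask.png")
  write_region_mask(face$mask, p)
  back <- read_region_mask(p)
  expect_identical(back$labels, face$mask$labels)
  expect_identical(back$legend, face$mask$legend)
})
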