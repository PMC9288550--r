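# Synthetic face cohorts with known ground truth.
#
# Schematic faces: an elliptical face on a mid-grey background
# (L*, a*, b* = 50, 0, 0), with rectangles/ellipses for the four skin
# regions, periorbital bands, three features and a surround ring per
# feature.  Region colours are painted at their configured means plus
# isotropic Gaussian Lab noise whose per-channel SD is calibrated so the
# region's expected MCDM equals the requested target: for i.i.d. Gaussian
# noise in three Lab channels the distance from the mean is sigma times a
# chi(3) variate, with mean sigma * sqrt(8/pi).

# E[MCDM] / sigma for isotropic 3-channel Gaussian noise.
.CHI3_MEAN <- sqrt(8 / pi)

#' Specification of one synthetic face
#'
#' @param skin_mean CIELAB mean of the facial skin.
#' @param region_offsets Named list of Lab offsets (added to `skin_mean`)
#'   for `forehead`, `cheek`, `nose`, `chin`, `periorbital`.
#' @param target_mcdm Named vector of target MCDM values for the noisy skin
#'   regions (`facial_skin`, `forehead`, `cheek`, `nose`, `chin`,
#'   `periorbital`); features/surrounds take `feature_mcdm`.
#' @param feature_means Named list of CIELAB means for `eyes`, `brows`,
#'   `mouth`.
#' @param surround_means Named list of CIELAB means for the three surround
#'   rings; defaults to the skin mean.
#' @param feature_mcdm Target MCDM inside features and surrounds.
#' @param size Image side length in pixels (square image).
#' @param surround_radius Surround ring width in pixels.
#' @param seed Integer seed; the face is deterministic given the spec.
#' @return A `face_spec` list.
#' @export
face_spec <- function(skin_mean = c(66, 12, 14),
                      region_offsets = list(
                        forehead = c(1.5, -0.5, 0.5),
                        cheek = c(-0.5, 1.5, 0),
                        nose = c(-1, 1, 0.5),
                        chin = c(-1.5, 0.5, 0.5),
                        periorbital = c(-2.5, 0.5, 0)),
                      target_mcdm = c(facial_skin = 2, forehead = 2,
                                      cheek = 2, nose = 2, chin = 2,
                                      periorbital = 2),
                      feature_means = list(eyes = c(30, 6, 8),
                                           brows = c(35, 8, 10),
                                           mouth = c(55, 25, 16)),
                      surround_means = NULL,
                      feature_mcdm = 1,
                      size = 256L,
                      surround_radius = 6L,
                      seed = 1L) {
  if (is.null(surround_means))
    surround_means <- list(eyes = skin_mean, brows = skin_mean,
                           mouth = skin_mean)
  stopifnot(all(target_mcdm >= 0), feature_mcdm >= 0, size >= 32L)
  structure(list(skin_mean = skin_mean, region_offsets = region_offsets,
                 target_mcdm = target_mcdm, feature_means = feature_means,
                 surround_means = surround_means,
                 feature_mcdm = feature_mcdm, size = as.integer(size),
                 surround_radius = as.integer(surround_radius),
                 seed = as.integer(seed)),
            class = "face_spec")
}

# Unit-square geometry of the schematic face.  Row/col extents are
# fractions of the image side; painted in order, later regions overwrite
# earlier ones so the final label map is exclusive.
.face_geometry <- function(size) {
  s <- function(x) pmax(1L, pmin(size, as.integer(round(x * size))))
  rects <- list(
    forehead = list(rows = s(c(0.16, 0.29)), cols = s(c(0.30, 0.70))),
    periorbital_l = list(rows = s(c(0.345, 0.47)), cols = s(c(0.22, 0.45))),
    periorbital_r = list(rows = s(c(0.345, 0.47)), cols = s(c(0.55, 0.78))),
    cheek_l = list(rows = s(c(0.50, 0.64)), cols = s(c(0.23, 0.40))),
    cheek_r = list(rows = s(c(0.50, 0.64)), cols = s(c(0.60, 0.77))),
    nose = list(rows = s(c(0.43, 0.60)), cols = s(c(0.46, 0.54))),
    chin = list(rows = s(c(0.80, 0.88)), cols = s(c(0.40, 0.60))),
    brows_l = list(rows = s(c(0.295, 0.325)), cols = s(c(0.28, 0.41))),
    brows_r = list(rows = s(c(0.295, 0.325)), cols = s(c(0.59, 0.72)))
  )
  ellipses <- list(
    face = list(centre = c(0.5, 0.5), semi = c(0.43, 0.33)),
    eye_l = list(centre = c(0.405, 0.345), semi = c(0.025, 0.055)),
    eye_r = list(centre = c(0.405, 0.655), semi = c(0.025, 0.055)),
    mouth = list(centre = c(0.72, 0.5), semi = c(0.035, 0.09))
  )
  list(rects = rects, ellipses = ellipses)
}

.paint_rect <- function(lab, r, value) {
  lab[r$rows[1]:r$rows[2], r$cols[1]:r$cols[2]] <- value
  lab
}

.paint_ellipse <- function(lab, e, value, size) {
  rr <- (row(lab) / size - e$centre[1]) / e$semi[1]
  cc <- (col(lab) / size - e$centre[2]) / e$semi[2]
  lab[rr^2 + cc^2 <= 1] <- value
  lab
}

# Label maps depend only on (size, surround_radius); cache them.
.mask_cache <- new.env(parent = emptyenv())

# Build the exclusive label map for the schematic face.
.build_mask <- function(size, surround_radius) {
  key <- sprintf("s%d_r%d", size, surround_radius)
  cached <- .mask_cache[[key]]
  if (!is.null(cached)) return(cached)
  .mask_cache[[key]] <- .build_mask_impl(size, surround_radius)
}

.build_mask_impl <- function(size, surround_radius) {
  geom <- .face_geometry(size)
  legend <- stats::setNames(seq_along(region_vocabulary()[-1]),
                            region_vocabulary()[-1])
  lab <- matrix(0L, size, size)
  lab <- .paint_ellipse(lab, geom$ellipses$face, legend[["facial_skin"]],
                        size)
  lab <- .paint_rect(lab, geom$rects$forehead, legend[["forehead"]])
  lab <- .paint_rect(lab, geom$rects$periorbital_l, legend[["periorbital"]])
  lab <- .paint_rect(lab, geom$rects$periorbital_r, legend[["periorbital"]])
  lab <- .paint_rect(lab, geom$rects$cheek_l, legend[["cheek"]])
  lab <- .paint_rect(lab, geom$rects$cheek_r, legend[["cheek"]])
  lab <- .paint_rect(lab, geom$rects$nose, legend[["nose"]])
  lab <- .paint_rect(lab, geom$rects$chin, legend[["chin"]])
  lab <- .paint_rect(lab, geom$rects$brows_l, legend[["brows"]])
  lab <- .paint_rect(lab, geom$rects$brows_r, legend[["brows"]])
  lab <- .paint_ellipse(lab, geom$ellipses$eye_l, legend[["eyes"]], size)
  lab <- .paint_ellipse(lab, geom$ellipses$eye_r, legend[["eyes"]], size)
  lab <- .paint_ellipse(lab, geom$ellipses$mouth, legend[["mouth"]], size)
  mask <- region_mask(lab, legend)
  for (f in c("eyes", "brows", "mouth"))
    mask <- add_surround(mask, f, radius = surround_radius)
  mask
}

#' Render one synthetic face
#'
#' Paints every region at its configured mean colour plus isotropic Gaussian
#' Lab noise calibrated so the region's expected MCDM equals its target
#' (`sigma = target / sqrt(8/pi)` per channel).  The background is exact
#' mid-grey.  Deterministic given the spec's seed.
#'
#' @param spec A [face_spec()].
#' @return List with elements `image` ([lab_image()]) and `mask`
#'   ([region_mask()]).
#' @export
generate_face <- function(spec) {
  stopifnot(inherits(spec, "face_spec"))
  mask <- .build_mask(spec$size, spec$surround_radius)
  n <- spec$size^2
  px <- matrix(rep(c(50, 0, 0), each = n), ncol = 3L)  # mid-grey background
  region_mean_of <- function(region) {
    if (region == "facial_skin") return(spec$skin_mean)
    if (region %in% names(spec$region_offsets))
      return(spec$skin_mean + spec$region_offsets[[region]])
    if (region %in% names(spec$feature_means))
      return(spec$feature_means[[region]])
    f <- sub("_surround$", "", region)
    spec$surround_means[[f]]
  }
  target_of <- function(region) {
    if (region %in% names(spec$target_mcdm)) spec$target_mcdm[[region]]
    else spec$feature_mcdm
  }
  with_local_seed(spec$seed, {
    for (region in names(mask$legend)) {
      idx <- which(mask$labels == mask$legend[[region]])
      if (length(idx) == 0L) {
        if (region %in% c("forehead", "cheek", "nose", "chin", "eyes",
                          "brows", "mouth", "facial_skin"))
          stop(sprintf("face geometry yields empty region '%s'", region),
               call. = FALSE)
        next
      }
      mu <- region_mean_of(region)
      sigma <- target_of(region) / .CHI3_MEAN
      for (k in 1:3) {
        px[idx, k] <- mu[k] +
          if (sigma > 0) stats::rnorm(length(idx), 0, sigma) else 0
      }
    }
  })
  px[, 1] <- pmin(pmax(px[, 1], 0), 100)
  list(image = lab_image(array(px, dim = c(spec$size, spec$size, 3L))),
       mask = mask)
}

#' Specification of a synthetic face cohort
#'
#' Per-face parameters are drawn independently from truncated normal
#' distributions; the defaults span natural skin gamuts with within-region
#' variation (MCDM) around 2 CIELAB units.
#'
#' @param n_faces Number of faces (default 40, the cohort size the pipeline
#'   emulates).
#' @param group Cohort label.
#' @param skin_mean,skin_sd Length-3 mean/SD for the per-face skin colour
#'   draw.
#' @param mcdm_mean,mcdm_sd Mean/SD of the per-face whole-face MCDM level
#'   (shared by forehead/nose/chin and facial skin).
#' @param mcdm_cheek_mean,mcdm_cheek_sd Mean/SD of the cheek MCDM.
#' @param cheek_a_offset,cheek_a_sd Cheek redness offset distribution.
#' @param periorbital_L_offset,periorbital_L_sd Periorbital lightness offset
#'   distribution.
#' @param feature_mean,feature_sd Named lists of length-3 means/SDs for the
#'   per-face `eyes`, `brows`, `mouth` colour draws.
#' @param size Image side length.
#' @param seed Master seed; per-face child seeds are derived from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_faces = 40L,
                        group = "cohortA",
                        skin_mean = c(66, 12, 14),
                        skin_sd = c(3, 1.2, 1.5),
                        mcdm_mean = 2.2, mcdm_sd = 0.5,
                        mcdm_cheek_mean = 2.0, mcdm_cheek_sd = 0.5,
                        cheek_a_offset = 1.5, cheek_a_sd = 0.8,
                        periorbital_L_offset = -2.5, periorbital_L_sd = 1.0,
                        feature_mean = list(eyes = c(30, 6, 8),
                                            brows = c(35, 8, 10),
                                            mouth = c(55, 25, 16)),
                        feature_sd = list(eyes = c(3, 1.5, 1.5),
                                          brows = c(3, 1.5, 1.5),
                                          mouth = c(3, 2, 1.5)),
                        size = 256L,
                        seed = 1L) {
  stopifnot(n_faces >= 2L, all(skin_sd >= 0), mcdm_sd >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

.rtruncnorm <- function(n, mean, sd, lower) {
  pmax(stats::rnorm(n, mean, sd), lower)
}

# Draw the per-face parameters and compute the configured (ground-truth)
# feature vector implied by them.
.draw_face_params <- function(cs) {
  skin <- c(stats::rnorm(1, cs$skin_mean[1], cs$skin_sd[1]),
            stats::rnorm(1, cs$skin_mean[2], cs$skin_sd[2]),
            stats::rnorm(1, cs$skin_mean[3], cs$skin_sd[3]))
  skin[1] <- min(max(skin[1], 30), 90)
  mcdm_face <- .rtruncnorm(1, cs$mcdm_mean, cs$mcdm_sd, 0.2)
  mcdm_cheek <- .rtruncnorm(1, cs$mcdm_cheek_mean, cs$mcdm_cheek_sd, 0.2)
  cheek_da <- stats::rnorm(1, cs$cheek_a_offset, cs$cheek_a_sd)
  peri_dL <- stats::rnorm(1, cs$periorbital_L_offset, cs$periorbital_L_sd)
  feats <- lapply(c(eyes = "eyes", brows = "brows", mouth = "mouth"),
                  function(f) {
                    v <- stats::rnorm(3, cs$feature_mean[[f]],
                                      cs$feature_sd[[f]])
                    v[1] <- min(max(v[1], 5), 95)
                    v
                  })
  list(skin = skin, mcdm_face = mcdm_face, mcdm_cheek = mcdm_cheek,
       cheek_da = cheek_da, peri_dL = peri_dL, feats = feats)
}

.params_to_spec <- function(p, cs, seed) {
  face_spec(
    skin_mean = p$skin,
    region_offsets = list(forehead = c(1.5, -0.5, 0.5),
                          cheek = c(-0.5, p$cheek_da, 0),
                          nose = c(-1, 1, 0.5),
                          chin = c(-1.5, 0.5, 0.5),
                          periorbital = c(p$peri_dL, 0.5, 0)),
    target_mcdm = c(facial_skin = p$mcdm_face, forehead = p$mcdm_face,
                    cheek = p$mcdm_cheek, nose = p$mcdm_face,
                    chin = p$mcdm_face, periorbital = p$mcdm_face),
    feature_means = p$feats,
    surround_means = list(eyes = p$skin + c(p$peri_dL, 0.5, 0),
                          brows = p$skin, mouth = p$skin),
    size = cs$size, seed = seed)
}

# Configured feature vector implied by one face's drawn parameters.
.ground_truth_features <- function(p) {
  skin <- p$skin
  vals <- c(L = skin[1], a = skin[2], b = skin[3],
            cheek_a = skin[2] + p$cheek_da,
            periorbital_L = skin[1] + p$peri_dL,
            MCDM = (3 * p$mcdm_face + p$mcdm_cheek) / 4,
            MCDM_cheek = p$mcdm_cheek)
  surround <- list(eyes = skin + c(p$peri_dL, 0.5, 0), brows = skin,
                   mouth = skin)
  for (f in c("eyes", "brows", "mouth")) {
    fm <- p$feats[[f]]; sm <- surround[[f]]
    C <- abs((sm - fm) / (sm + fm))
    vals[paste0(f, "_C_L")] <- C[1]
    vals[paste0(f, "_C_a")] <- C[2]
    vals[paste0(f, "_C_b")] <- C[3]
    vals[paste0(f, "_dE")] <- sqrt(sum((fm - sm)^2))
  }
  vals[feature_names()]
}

#' Generate a synthetic face cohort
#'
#' Draws `n_faces` face specifications from the cohort distribution.  With
#' `render = TRUE` each face is rasterised ([generate_face()]); with
#' `render = FALSE` only the configured ground-truth feature vectors are
#' produced (sufficient for statistical simulation experiments, where pixel
#' rendering adds nothing).
#'
#' @param spec A [cohort_spec()].
#' @param render Rasterise images and masks?
#' @return List with `faces` (list of `face_id`/`image`/`mask`, or `NULL`
#'   when `render = FALSE`) and `ground_truth` (tibble of configured feature
#'   vectors, one row per face).
#' @export
generate_cohort <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- sprintf("%s_%02d", spec$group, seq_len(spec$n_faces))
  params <- with_local_seed(derive_seed(spec$seed, 0L, salt = 11L),
                            lapply(seq_len(spec$n_faces),
                                   function(i) .draw_face_params(spec)))
  truth <- purrr::map2_dfr(params, ids, function(p, id)
    dplyr::bind_cols(tibble::tibble(face_id = id),
                     tibble::as_tibble(as.list(.ground_truth_features(p)))))
  faces <- NULL
  if (render) {
    faces <- purrr::imap(params, function(p, i) {
      fs <- .params_to_spec(p, spec, seed = derive_seed(spec$seed, i,
                                                        salt = 29L))
      f <- generate_face(fs)
      list(face_id = ids[i], image = f$image, mask = f$mask, spec = fs)
    })
  }
  list(faces = faces, ground_truth = truth, group = spec$group)
}

#' Observer rating model
#'
#' Latent-score model for simulated preference ratings: each face's latent
#' score is `intercept + sum(beta * z(feature)) + face noise`; each
#' observer adds a stable bias and per-rating noise; ratings are rounded
#' half-up and clamped to the attribute's scale.
#'
#' @param attributes Named list; each element has `scale` (length-2 integer
#'   bounds), `intercept`, `beta` (named coefficients on z-scored features),
#'   `face_noise_sd`, `observer_noise_sd`, `observer_bias_sd`.
#' @param n_observers Number of observers (default 22).
#' @param seed Integer seed.
#' @return A `rating_model` list.
#' @export
rating_model <- function(attributes = list(
                           attractiveness = list(
                             scale = c(1L, 7L), intercept = 4,
                             beta = c(MCDM = -0.35, MCDM_cheek = -0.30,
                                      mouth_C_a = 0.30, L = 0.25),
                             face_noise_sd = 0.3, observer_noise_sd = 1.0,
                             observer_bias_sd = 0.3),
                           healthiness = list(
                             scale = c(1L, 7L), intercept = 4.2,
                             beta = c(MCDM = -0.40, MCDM_cheek = -0.25,
                                      mouth_C_a = 0.30, L = 0.20),
                             face_noise_sd = 0.3, observer_noise_sd = 1.0,
                             observer_bias_sd = 0.3),
                           age = list(
                             scale = c(1L, 99L), intercept = 35,
                             beta = c(MCDM = 4, MCDM_cheek = 3, L = -3,
                                      brows_C_a = 2),
                             face_noise_sd = 1.5, observer_noise_sd = 4,
                             observer_bias_sd = 1.5)),
                         n_observers = 22L,
                         seed = 1L) {
  for (a in attributes)
    stopifnot(length(a$scale) == 2L, a$scale[1] < a$scale[2],
              a$face_noise_sd >= 0, a$observer_noise_sd >= 0,
              a$observer_bias_sd >= 0)
  structure(list(attributes = attributes,
                 n_observers = as.integer(n_observers),
                 seed = as.integer(seed)),
            class = "rating_model")
}

#' Simulate observer ratings for a cohort
#'
#' @param features Tibble with `face_id` and feature columns (extracted or
#'   ground-truth vectors).
#' @param model A [rating_model()].
#' @return Tibble `(observer_id, face_id, attribute, rating)`, a complete
#'   observers-by-faces-by-attributes crossing.
#' @export
simulate_ratings <- function(features, model) {
  stopifnot(inherits(model, "rating_model"), nrow(features) >= 2L)
  n <- nrow(features)
  out <- purrr::imap_dfr(model$attributes, function(att, att_name) {
    beta <- att$beta
    if (length(beta) > 0) {
      miss <- setdiff(names(beta), names(features))
      if (length(miss) > 0)
        stop("simulate_ratings: unknown feature(s) in beta: ",
             paste(miss, collapse = ", "), call. = FALSE)
      Z <- vapply(names(beta), function(nm) {
        v <- features[[nm]]
        if (stats::sd(v) == 0)
          stop(sprintf(
            "simulate_ratings: feature '%s' is constant; cannot z-score",
            nm), call. = FALSE)
        zscore(v)
      }, numeric(n))
      signal <- as.numeric(Z %*% beta)
    } else signal <- rep(0, n)
    with_local_seed(derive_seed(model$seed, match(att_name,
                                                  names(model$attributes)),
                                salt = 101L), {
      latent <- att$intercept + signal +
        stats::rnorm(n, 0, att$face_noise_sd)
      bias <- stats::rnorm(model$n_observers, 0, att$observer_bias_sd)
      purrr::map_dfr(seq_len(model$n_observers), function(o) {
        raw <- latent + bias[o] +
          stats::rnorm(n, 0, att$observer_noise_sd)
        tibble::tibble(observer_id = sprintf("obs_%02d", o),
                       face_id = features$face_id,
                       attribute = att_name,
                       rating = as.integer(pmin(pmax(round_half_up(raw),
                                                     att$scale[1]),
                                                att$scale[2])))
      })
    })
  })
  out
}
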