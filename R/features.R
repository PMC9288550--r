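# The nineteen facial colour characteristics.
#
# Three classes: average/local skin colour (L, a, b, cheek_a, periorbital_L),
# skin colour variation (MCDM of the whole face and of the cheek), and
# facial colour contrast (channel-wise Michelson contrast plus CIE76 deltaE
# between each of eyes/brows/mouth and its surrounding skin).

#' Region vocabulary for face label maps
#'
#' Fixed set of region names a label map may use.  `background` is label 0;
#' every other pixel carries exactly one region label.
#'
#' @return Character vector of region names.
#' @export
region_vocabulary <- function() {
  c("background", "facial_skin", "forehead", "cheek", "nose", "chin",
    "periorbital", "eyes", "brows", "mouth",
    "eyes_surround", "brows_surround", "mouth_surround")
}

# Skin-type labels pooled for the average facial colour: the whole face
# excluding the mouth, nose, eyes and eyebrows.
.SKIN_UNION <- c("facial_skin", "forehead", "cheek", "chin", "periorbital",
                 "eyes_surround", "brows_surround", "mouth_surround")

#' Construct a region label map
#'
#' @param labels Integer `H x W` matrix; 0 is background.
#' @param legend Named integer vector mapping region name to label value.
#'   Names must come from [region_vocabulary()].
#' @return A `region_mask` object.
#' @export
region_mask <- function(labels, legend) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  bad <- setdiff(names(legend), region_vocabulary())
  if (length(bad) > 0)
    stop("region_mask: unknown region name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(legend))
    stop("region_mask: legend values must be unique", call. = FALSE)
  unknown <- setdiff(unique(as.vector(labels)), c(0L, unname(legend)))
  if (length(unknown) > 0)
    stop("region_mask: labels not in legend: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(labels = labels, legend = legend), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  counts <- table(factor(x$labels, levels = c(0L, unname(x$legend)),
                         labels = c("background", names(x$legend))))
  cat(sprintf("<region_mask %d x %d>\n", nrow(x$labels), ncol(x$labels)))
  print(counts)
  invisible(x)
}

.check_pair <- function(img, mask) {
  d <- dim(img)
  if (d[1] != nrow(mask$labels) || d[2] != ncol(mask$labels))
    stop("image and mask dimensions differ", call. = FALSE)
}

# Logical index into the flattened H*W pixel grid for one region, or for the
# pooled skin union via the pseudo-region "skin_union".
.region_idx <- function(mask, region) {
  if (identical(region, "skin_union")) {
    labs <- unname(mask$legend[intersect(.SKIN_UNION, names(mask$legend))])
    return(mask$labels %in% labs)
  }
  if (!region %in% names(mask$legend))
    stop(sprintf("region '%s' not present in mask legend", region),
         call. = FALSE)
  mask$labels == mask$legend[[region]]
}

# Pixels of one region as an n x 3 Lab matrix.
.region_pixels <- function(img, mask, region) {
  .check_pair(img, mask)
  idx <- .region_idx(mask, region)
  n <- sum(idx)
  if (n == 0L)
    stop(sprintf("region '%s' is empty", region), call. = FALSE)
  cbind(L = img[, , 1][idx], a = img[, , 2][idx], b = img[, , 3][idx])
}

#' Mean CIELAB colour of a region
#'
#' Arithmetic mean of L*, a*, b* over the region's pixels, in double
#' precision.
#'
#' @param img A [lab_image()].
#' @param mask A [region_mask()] of matching dimensions.
#' @param region Region name from the mask legend.
#' @return Named numeric vector `(L, a, b)`.
#' @export
region_mean <- function(img, mask, region) {
  colMeans(.region_pixels(img, mask, region))
}

#' Average facial skin colour
#'
#' Mean CIELAB colour over the whole facial skin, excluding the mouth, nose,
#' eyes and eyebrows — i.e. the union of all skin-type region labels
#' (facial_skin, forehead, cheek, chin, periorbital and the three feature
#' surrounds that are present).
#'
#' @inheritParams region_mean
#' @return Named numeric vector `(L, a, b)`.
#' @export
average_facial_colour <- function(img, mask) {
  region_mean(img, mask, "skin_union")
}

#' Local skin colour: cheek redness and periorbital lightness
#'
#' @inheritParams region_mean
#' @return Named numeric vector `(cheek_a, periorbital_L)`.
#' @export
local_skin_colour <- function(img, mask) {
  c(cheek_a = unname(region_mean(img, mask, "cheek")["a"]),
    periorbital_L = unname(region_mean(img, mask, "periorbital")["L"]))
}

#' Mean colour difference from the mean (MCDM)
#'
#' Skin-uniformity statistic: the mean, over a region's pixels, of the CIE76
#' distance of each pixel from the region's mean colour,
#' \deqn{MCDM = \frac{1}{N}\sum_{i=1}^{N}
#'   \sqrt{(L_i^*-\bar L^*)^2 + (a_i^*-\bar a^*)^2 + (b_i^*-\bar b^*)^2}.}
#' Zero for a perfectly uniform region; the smaller the value, the more
#' homogeneous the skin colour.
#'
#' @inheritParams region_mean
#' @return Non-negative scalar.
#' @export
mcdm <- function(img, mask, region) {
  px <- .region_pixels(img, mask, region)
  mu <- colMeans(px)
  mean(sqrt((px[, 1] - mu[1])^2 + (px[, 2] - mu[2])^2 + (px[, 3] - mu[3])^2))
}

#' Whole-face skin colour variation
#'
#' The grand mean of the MCDM values of the forehead, cheek, nose and chin
#' regions — an unweighted mean of the four per-region statistics regardless
#' of their pixel counts, not a pooled-pixel MCDM.
#'
#' @inheritParams region_mean
#' @return Non-negative scalar.
#' @export
mcdm_whole_face <- function(img, mask) {
  mean(vapply(c("forehead", "cheek", "nose", "chin"),
              function(r) mcdm(img, mask, r), numeric(1)))
}

#' Adapted Michelson contrast
#'
#' \deqn{C = \left|\frac{A_{skin} - A_{feature}}{A_{skin} + A_{feature}}\right|}
#' computed channel-wise on region mean values.  Because a* and b* can be
#' negative, the denominator can approach zero for unnatural colour pairs;
#' rather than returning an unbounded value, a denominator below `eps` in
#' magnitude raises a degenerate-contrast error carrying the offending
#' values.
#'
#' @param skin_val,feature_val Channel mean for the surrounding skin and the
#'   feature.
#' @param eps Degeneracy threshold for `|skin_val + feature_val|`.
#' @param channel Optional channel name for error messages.
#' @return Non-negative scalar.
#' @export
michelson_contrast <- function(skin_val, feature_val, eps = 1e-6,
                               channel = NULL) {
  den <- skin_val + feature_val
  if (abs(den) < eps) {
    stop(structure(class = c("facecolr_degenerate_contrast", "error",
                             "condition"),
                   list(message = sprintf(
                     "degenerate Michelson contrast%s: skin = %.6g, feature = %.6g",
                     if (is.null(channel)) "" else paste0(" on ", channel),
                     skin_val, feature_val),
                     call = NULL)))
  }
  abs((skin_val - feature_val) / den)
}

#' Colour contrasts of one facial feature against its surrounding skin
#'
#' Channel-wise Michelson contrast between the mean colour of a feature's
#' explicit surround region and the feature region, plus the CIE76 colour
#' difference between the two means.
#'
#' @inheritParams region_mean
#' @param feature One of `"eyes"`, `"brows"`, `"mouth"`.
#' @return Named numeric vector `(C_L, C_a, C_b, dE)`.
#' @export
feature_contrasts <- function(img, mask, feature = c("eyes", "brows",
                                                     "mouth")) {
  feature <- match.arg(feature)
  feat_mu <- region_mean(img, mask, feature)
  skin_mu <- region_mean(img, mask, paste0(feature, "_surround"))
  ch <- c("L", "a", "b")
  C <- vapply(ch, function(k) {
    michelson_contrast(skin_mu[[k]], feat_mu[[k]],
                       channel = paste0(feature, "-", k))
  }, numeric(1))
  c(C_L = unname(C["L"]), C_a = unname(C["a"]), C_b = unname(C["b"]),
    dE = delta_e(feat_mu, skin_mu))
}

#' Schema of the nineteen colour characteristics
#'
#' Fixed, ordered names of the nineteen facial colour characteristics; the
#' order doubles as the CSV column schema.
#'
#' @return Character vector of length 19.
#' @export
feature_names <- function() {
  c("L", "a", "b", "cheek_a", "periorbital_L",
    "MCDM", "MCDM_cheek",
    "eyes_C_L", "eyes_C_a", "eyes_C_b", "eyes_dE",
    "brows_C_L", "brows_C_a", "brows_C_b", "brows_dE",
    "mouth_C_L", "mouth_C_a", "mouth_C_b", "mouth_dE")
}

#' Partition of the characteristics into three classes
#'
#' Class 1 is average/local skin colour, class 2 skin colour variation,
#' class 3 facial colour contrast.  The classes partition the nineteen
#' characteristics.
#'
#' @return Named list with elements `average_local`, `variation`,
#'   `contrast`.
#' @export
feature_classes <- function() {
  list(
    average_local = c("L", "a", "b", "cheek_a", "periorbital_L"),
    variation = c("MCDM", "MCDM_cheek"),
    contrast = c("eyes_C_L", "eyes_C_a", "eyes_C_b", "eyes_dE",
                 "brows_C_L", "brows_C_a", "brows_C_b", "brows_dE",
                 "mouth_C_L", "mouth_C_a", "mouth_C_b", "mouth_dE")
  )
}

#' Predictors entering the combined importance model
#'
#' The sixteen characteristics used when all classes are modelled jointly:
#' the three deltaE contrasts are dropped because each is nearly collinear
#' with one of its per-channel Michelson contrasts.
#'
#' @return Character vector of length 16.
#' @export
combined_predictors <- function() {
  setdiff(feature_names(), c("eyes_dE", "brows_dE", "mouth_dE"))
}

#' Extract the nineteen facial colour characteristics from one face
#'
#' Computes the full colour-characteristic vector: average facial colour
#' (L, a, b over all skin excluding mouth/nose/eyes/brows), local skin colour
#' (cheek a*, periorbital L*), skin colour variation (whole-face and cheek
#' MCDM) and the twelve feature contrasts.  Deterministic for a fixed
#' image/mask pair.
#'
#' @inheritParams region_mean
#' @param face_id Optional identifier included as the first column.
#' @return A one-row tibble with `face_id` (if given) and the 19 columns of
#'   [feature_names()].
#' @export
extract_features <- function(img, mask, face_id = NULL) {
  res <- tryCatch({
    avg <- average_facial_colour(img, mask)
    loc <- local_skin_colour(img, mask)
    vals <- c(avg["L"], avg["a"], avg["b"],
              loc["cheek_a"], loc["periorbital_L"],
              MCDM = mcdm_whole_face(img, mask),
              MCDM_cheek = mcdm(img, mask, "cheek"))
    for (f in c("eyes", "brows", "mouth")) {
      fc <- feature_contrasts(img, mask, f)
      names(fc) <- paste0(f, "_", names(fc))
      vals <- c(vals, fc)
    }
    vals
  }, error = function(e) {
    stop(sprintf("feature extraction failed%s: %s",
                 if (is.null(face_id)) "" else paste0(" for face '", face_id,
                                                      "'"),
                 conditionMessage(e)), call. = FALSE)
  })
  names(res) <- feature_names()
  out <- tibble::as_tibble(as.list(res))
  if (!is.null(face_id)) out <- dplyr::bind_cols(tibble::tibble(face_id =
                                                                  face_id),
                                                 out)
  out
}

#' Extract characteristics for a list of faces
#'
#' @param faces A list whose elements each contain `image`, `mask` and
#'   `face_id` (as produced by [generate_cohort()]).
#' @return Tibble with one row per face: `face_id` plus the 19 feature
#'   columns.
#' @export
extract_features_cohort <- function(faces) {
  purrr::map_dfr(faces, function(f)
    extract_features(f$image, f$mask, face_id = f$face_id))
}

#' Grow a surround ring around a feature region in a label map
#'
#' Convenience for building masks: labels the `radius`-pixel neighbourhood
#' of a feature region (excluding the feature itself and any pixel already
#' carrying a non-skin label) as the feature's surround.
#'
#' @param mask A [region_mask()].
#' @param feature One of `"eyes"`, `"brows"`, `"mouth"`.
#' @param radius Ring width in pixels.
#' @param from_labels Labels that may be overwritten by the surround;
#'   defaults to facial skin labels.
#' @return A new [region_mask()] with the surround label added/extended.
#' @export
add_surround <- function(mask, feature = c("eyes", "brows", "mouth"),
                         radius = 6L,
                         from_labels = c("facial_skin", "forehead", "cheek",
                                         "chin", "periorbital")) {
  feature <- match.arg(feature)
  lab <- mask$labels
  target <- .region_idx(mask, feature)
  # Chebyshev-distance dilation by `radius` via iterated 1-pixel shifts.
  dil <- target
  for (i in seq_len(radius)) {
    d <- dil
    d[-1, ] <- d[-1, ] | dil[-nrow(dil), ]
    d[-nrow(d), ] <- d[-nrow(d), ] | dil[-1, ]
    d[, -1] <- d[, -1] | dil[, -ncol(dil)]
    d[, -ncol(d)] <- d[, -ncol(d)] | dil[, -1]
    dil <- d
  }
  ring <- dil & !target
  allowed_labs <- unname(mask$legend[intersect(from_labels,
                                               names(mask$legend))])
  ring <- ring & (lab %in% allowed_labs)
  sur_name <- paste0(feature, "_surround")
  legend <- mask$legend
  if (!sur_name %in% names(legend)) {
    legend <- c(legend, stats::setNames(max(legend) + 1L, sur_name))
  }
  lab[ring] <- legend[[sur_name]]
  region_mask(lab, legend)
}

#' Write / read a region mask as a PNG label raster plus JSON legend
#'
#' The label matrix is stored as an 8-bit greyscale PNG (labels `0..255`)
#' and the legend as JSON at `paste0(path, ".json")`.
#'
#' @param mask A [region_mask()].
#' @param path PNG path.
#' @export
write_region_mask <- function(mask, path) {
  if (max(mask$labels) > 255L)
    stop("write_region_mask: labels exceed 8-bit range", call. = FALSE)
  png::writePNG(mask$labels / 255, target = path)
  jsonlite::write_json(as.list(mask$legend), paste0(path, ".json"),
                       auto_unbox = TRUE)
}

#' @rdname write_region_mask
#' @return `read_region_mask()` returns the [region_mask()].
#' @export
read_region_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  labels <- matrix(as.integer(round(m * 255)), nrow = nrow(m))
  legend <- unlist(jsonlite::read_json(paste0(path, ".json")))
  storage.mode(legend) <- "integer"
  region_mask(labels, legend)
}
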