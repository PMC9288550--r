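# Descriptives, reliability, zero-order correlations and group comparison
# for per-face preference scores.

#' z-standardise a numeric vector
#'
#' Centres to mean 0 and scales to sample SD 1 (denominator `n - 1`).
#'
#' @param x Numeric vector, `length(x) >= 2`.
#' @param name Optional variable name for error messages.
#' @return Standardised vector.
#' @export
zscore <- function(x, name = NULL) {
  if (length(x) < 2L) stop("zscore: need at least two values", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop(sprintf("zscore: constant predictor%s",
                 if (is.null(name)) "" else paste0(" '", name, "'")),
         call. = FALSE)
  (x - mean(x)) / s
}

#' Per-face mean preference scores
#'
#' Averages ratings across all observers to create one score per face per
#' attribute.
#'
#' @param ratings Tibble `(observer_id, face_id, attribute, rating)`.
#' @return Tibble with `face_id`, one column per attribute, and
#'   `n_observers`.
#' @export
mean_scores <- function(ratings) {
  cover <- ratings |>
    dplyr::distinct(.data$face_id, .data$attribute)
  full <- tidyr::expand_grid(face_id = unique(ratings$face_id),
                             attribute = unique(ratings$attribute))
  missing <- dplyr::anti_join(full, cover, by = c("face_id", "attribute"))
  if (nrow(missing) > 0)
    stop(sprintf("mean_scores: %d (face, attribute) cell(s) have no ratings",
                 nrow(missing)), call. = FALSE)
  ratings |>
    dplyr::group_by(.data$face_id, .data$attribute) |>
    dplyr::summarise(score = mean(.data$rating),
                     n_observers = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(id_cols = "face_id", names_from = "attribute",
                       values_from = "score",
                       unused_fn = list(n_observers = min))
}

#' Cronbach's alpha across observers
#'
#' Internal-consistency coefficient with observers as items and faces as
#' cases: `alpha = k/(k-1) * (1 - sum(var_i) / var_total)`, where `var_i` is
#' the sample variance of observer `i`'s ratings over faces and `var_total`
#' the sample variance of the per-face rating sums.
#'
#' @param ratings_matrix Numeric matrix, observers in columns, faces in
#'   rows; or a long ratings tibble for one attribute.
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(ratings_matrix) {
  if (is.data.frame(ratings_matrix)) {
    stopifnot(all(c("observer_id", "face_id", "rating") %in%
                    colnames(ratings_matrix)))
    ratings_matrix <- ratings_matrix |>
      tidyr::pivot_wider(id_cols = "face_id", names_from = "observer_id",
                         values_from = "rating") |>
      dplyr::select(-"face_id") |>
      as.matrix()
  }
  k <- ncol(ratings_matrix)
  if (k < 2L || nrow(ratings_matrix) < 2L)
    stop("cronbach_alpha: need >= 2 observers and >= 2 faces",
         call. = FALSE)
  vt <- stats::var(rowSums(ratings_matrix))
  if (!is.finite(vt) || vt <= 0)
    stop("cronbach_alpha: total variance is zero; reliability undefined",
         call. = FALSE)
  vi <- sum(apply(ratings_matrix, 2, stats::var))
  k / (k - 1) * (1 - vi / vt)
}

#' Two-tailed Pearson correlation
#'
#' Product-moment correlation with a two-tailed p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return Tibble `(r, p, n)`.
#' @export
pearson_two_tailed <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("pearson_two_tailed: length mismatch",
                           call. = FALSE)
  if (n < 3L) stop("pearson_two_tailed: need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_two_tailed: zero variance; correlation undefined",
         call. = FALSE)
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(r = r, p = p, n = n)
}

.stars <- function(p) {
  dplyr::case_when(p <= 0.001 ~ "***", p <= 0.01 ~ "**", p <= 0.05 ~ "*",
                   TRUE ~ "")
}

#' Correlations between colour characteristics and preference scores
#'
#' Computes the two-tailed Pearson correlation of every colour
#' characteristic with every preference attribute, plus the inter-attribute
#' correlations, with significance stars at 0.05 / 0.01 / 0.001 applied on
#' the exact p-values.  No multiple-testing correction is applied; the
#' number of tests performed is recorded in the `n_tests` attribute.
#'
#' @param features Tibble with `face_id` and feature columns.
#' @param scores Tibble from [mean_scores()].
#' @param feature_cols Feature columns to correlate (default the 19-name
#'   schema intersected with what is present).
#' @return Tibble of class `facecolr_corr`:
#'   `(feature, attribute, r, p, n, stars)`; inter-attribute rows carry the
#'   first attribute in `feature`.
#' @export
correlation_matrix <- function(features, scores,
                               feature_cols = intersect(feature_names(),
                                                        colnames(features))) {
  stopifnot(nrow(features) >= 3L)
  merged <- dplyr::inner_join(features, scores, by = "face_id")
  attrs <- setdiff(colnames(scores), c("face_id", "n_observers"))
  pairs <- tidyr::expand_grid(feature = feature_cols, attribute = attrs)
  res <- purrr::pmap_dfr(pairs, function(feature, attribute) {
    out <- tryCatch(pearson_two_tailed(merged[[feature]],
                                       merged[[attribute]]),
                    error = function(e) tibble::tibble(r = NA_real_,
                                                      p = NA_real_,
                                                      n = nrow(merged)))
    dplyr::bind_cols(tibble::tibble(feature = feature,
                                    attribute = attribute), out)
  })
  inter <- utils::combn(attrs, 2, simplify = FALSE) |>
    purrr::map_dfr(function(pr)
      dplyr::bind_cols(tibble::tibble(feature = pr[1], attribute = pr[2]),
                       pearson_two_tailed(merged[[pr[1]]],
                                          merged[[pr[2]]])))
  out <- dplyr::bind_rows(res, inter) |>
    dplyr::mutate(stars = .stars(.data$p))
  attr(out, "n_tests") <- nrow(out)
  class(out) <- c("facecolr_corr", class(out))
  out
}

#' Welch two-sample t-test per feature between two cohorts
#'
#' Compares each colour characteristic between two groups of faces with
#' Welch's unequal-variance t-test (two-tailed).
#'
#' @param groupA,groupB Tibbles of per-face feature values.
#' @param feature_cols Columns to test (default shared feature-schema
#'   columns).
#' @return Tibble `(feature, mean_A, mean_B, t, df, p)`.
#' @export
group_difference_test <- function(groupA, groupB,
                                  feature_cols =
                                    intersect(intersect(feature_names(),
                                                        colnames(groupA)),
                                              colnames(groupB))) {
  if (nrow(groupA) < 2L || nrow(groupB) < 2L)
    stop("group_difference_test: each group needs n >= 2", call. = FALSE)
  purrr::map_dfr(feature_cols, function(f) {
    a <- groupA[[f]]; b <- groupB[[f]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      same <- isTRUE(all.equal(mean(a), mean(b)))
      return(tibble::tibble(feature = f, mean_A = mean(a), mean_B = mean(b),
                            t = if (same) 0 else Inf, df = NA_real_,
                            p = if (same) 1 else 0))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    tibble::tibble(feature = f, mean_A = mean(a), mean_B = mean(b),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
  })
}

#' Descriptive statistics of features and scores
#'
#' @param df Tibble of per-face values.
#' @param cols Columns to describe.
#' @return Tibble `(variable, mean, sd, min, max)`.
#' @export
describe_cohort <- function(df, cols = setdiff(colnames(df), "face_id")) {
  purrr::map_dfr(cols, function(v)
    tibble::tibble(variable = v, mean = mean(df[[v]]),
                   sd = stats::sd(df[[v]]), min = min(df[[v]]),
                   max = max(df[[v]])))
}

#' @export
autoplot.facecolr_corr <- function(object, ...) {
  df <- object |>
    dplyr::filter(.data$feature %in% feature_names())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$r,
                                   fill = .data$r > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), vjust = 0.3,
                       size = 3) +
    ggplot2::facet_wrap(~attribute, ncol = 1) +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = "Pearson r",
                  caption = "*p ≤ 0.05, **p ≤ 0.01, ***p ≤ 0.001") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}
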