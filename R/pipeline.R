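# End-to-end pipeline: generate (or read) a cohort, extract the nineteen
# characteristics, simulate/collect ratings, run the correlation and model
# analyses and write every artefact plus a manifest.  Each cohort is
# analysed fully separately; no pooled-cohort model is produced.

#' Default pipeline configuration
#'
#' One nested list drives the whole run; any scalar can be overridden.
#' Synthetic mode emulates two cohorts of 40 faces rated by 22 observers
#' each.
#'
#' @param seed Master seed; every stage derives its own child seed.
#' @param out_dir Output directory.
#' @param n_faces Faces per cohort.
#' @param image_size Image side length in pixels.
#' @param write_images Also export per-face PNG images and masks?
#' @param n_observers Observers per cohort.
#' @param n_folds,n_repeats Cross-validation layout.
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("facecolr_run"),
                               n_faces = 40L, image_size = 256L,
                               write_images = FALSE, n_observers = 22L,
                               n_folds = 5L, n_repeats = 50L) {
  list(
    mode = "synthetic",
    out_dir = out_dir,
    seed = as.integer(seed),
    write_images = write_images,
    groups = list(
      cohortA = list(skin_mean = c(66, 12, 14)),
      cohortB = list(skin_mean = c(62, 13, 17))
    ),
    n_faces = as.integer(n_faces),
    image_size = as.integer(image_size),
    n_observers = as.integer(n_observers),
    cv = list(n_folds = as.integer(n_folds),
              n_repeats = as.integer(n_repeats)),
    enet = list(alpha_grid = seq(0, 1, by = 0.1),
                lambda_grid = 10^seq(-4, 1, length.out = 50))
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Values present in the file override the defaults of
#' [default_run_config()].
#'
#' @param path YAML or JSON config file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- if (tolower(tools::file_ext(path)) == "json")
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg <- default_run_config()
  utils::modifyList(cfg, raw)
}

.write_csv <- function(df, path) {
  readr::write_csv(df, path)
  path
}

# Analyse one cohort: features + ratings already in hand.
.analyse_cohort <- function(features, ratings, cohort_dir, cfg) {
  scores <- mean_scores(ratings)
  attrs <- setdiff(colnames(scores), c("face_id", "n_observers"))
  .write_csv(scores, file.path(cohort_dir, "scores.csv"))

  reliability <- purrr::map_dfr(attrs, function(a) {
    alpha <- cronbach_alpha(dplyr::filter(ratings, .data$attribute == a))
    tibble::tibble(attribute = a, cronbach_alpha = alpha,
                   n_observers = length(unique(ratings$observer_id)))
  })
  .write_csv(reliability, file.path(cohort_dir, "reliability.csv"))

  .write_csv(describe_cohort(features), file.path(cohort_dir,
                                                  "descriptives.csv"))

  corr <- correlation_matrix(features, scores)
  .write_csv(tibble::as_tibble(corr), file.path(cohort_dir,
                                                "correlations.csv"))
  jsonlite::write_json(tibble::as_tibble(corr),
                       file.path(cohort_dir, "correlations.json"),
                       digits = NA)

  cvcfg <- cv_config(n_folds = cfg$cv$n_folds,
                     n_repeats = cfg$cv$n_repeats,
                     seed = derive_seed(cfg$seed, 7L, salt = 3L))
  spec <- elastic_net_spec(alpha_grid = cfg$enet$alpha_grid,
                           lambda_grid = cfg$enet$lambda_grid)

  classes <- separate_class_models(features, scores, cvcfg)
  .write_csv(tidy(classes), file.path(cohort_dir, "class_rmse.csv"))
  .write_csv(attr(classes, "splits"),
             file.path(cohort_dir, "class_rmse_splits.csv"))

  combined <- purrr::map(attrs, function(a)
    combined_model(features, scores, a, cvcfg, spec))
  names(combined) <- attrs
  purrr::iwalk(combined, function(m, a) {
    .write_csv(tidy(m), file.path(cohort_dir,
                                  sprintf("combined_coefficients_%s.csv",
                                          a)))
    jsonlite::write_json(
      list(attribute = m$attribute, alpha = m$alpha, lambda = m$lambda,
           mean_rmse = m$mean_rmse, sd_rmse = m$sd_rmse,
           n_splits = m$n_splits,
           coefficients = m$coefficients,
           split_rmse = m$split_rmse),
      file.path(cohort_dir, sprintf("combined_model_%s.json", a)),
      auto_unbox = TRUE, digits = NA)
  })
  list(scores = scores, reliability = reliability, correlations = corr,
       classes = classes, combined = combined)
}

#' Run the full pipeline
#'
#' Synthetic mode: for each configured group, generate a cohort, extract
#' the nineteen colour characteristics, simulate observer ratings, then run
#' reliability, correlation, class-comparison and combined-model analyses,
#' writing CSV/JSON artefacts and a manifest under `cfg$out_dir`.
#' Image-dir mode: read exported images/masks/ratings from
#' `cfg$input_dir` (one subdirectory per cohort) and run the same analysis
#' stages.
#'
#' @param cfg A `run_config` list ([default_run_config()],
#'   [read_run_config()]) or a path to a YAML/JSON config.
#' @return Invisibly, a list with per-cohort results and the manifest.
#' @export
run_pipeline <- function(cfg = default_run_config()) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  warnings_log <- character()
  results <- list()
  all_features <- list()

  for (gi in seq_along(cfg$groups)) {
    gname <- names(cfg$groups)[gi]
    cohort_dir <- file.path(cfg$out_dir, gname)
    dir.create(cohort_dir, showWarnings = FALSE, recursive = TRUE)
    tg <- Sys.time()

    res <- withCallingHandlers({
      if (identical(cfg$mode, "synthetic")) {
        cspec <- do.call(cohort_spec, c(
          list(n_faces = cfg$n_faces, group = gname,
               size = cfg$image_size,
               seed = derive_seed(cfg$seed, gi, salt = 17L)),
          cfg$groups[[gi]]))
        cohort <- generate_cohort(cspec, render = TRUE)
        features <- extract_features_cohort(cohort$faces)
        .write_csv(cohort$ground_truth,
                   file.path(cohort_dir, "ground_truth.csv"))
        if (isTRUE(cfg$write_images))
          write_cohort(cohort, file.path(cohort_dir, "images"))
        model <- rating_model(n_observers = cfg$n_observers,
                              seed = derive_seed(cfg$seed, gi, salt = 23L))
        ratings <- simulate_ratings(features, model)
      } else if (identical(cfg$mode, "image-dir")) {
        faces <- read_cohort_dir(file.path(cfg$input_dir, gname))
        features <- extract_features_cohort(faces)
        ratings <- readr::read_csv(file.path(cfg$input_dir, gname,
                                             "ratings.csv"),
                                   show_col_types = FALSE)
      } else stop("run_pipeline: unknown mode '", cfg$mode, "'",
                  call. = FALSE)
      .write_csv(features, file.path(cohort_dir, "features.csv"))
      .write_csv(ratings, file.path(cohort_dir, "ratings.csv"))
      all_features[[gname]] <- features
      .analyse_cohort(features, ratings, cohort_dir, cfg)
    }, warning = function(w) {
      warnings_log <<- c(warnings_log,
                         sprintf("[%s] %s", gname, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    results[[gname]] <- res
    timings[[gname]] <- as.numeric(difftime(Sys.time(), tg,
                                            units = "secs"))
  }

  if (length(all_features) >= 2L) {
    gd <- group_difference_test(all_features[[1]], all_features[[2]])
    .write_csv(gd, file.path(cfg$out_dir, "group_differences.csv"))
    results$group_differences <- gd
  }

  files <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  hashes <- tools::md5sum(files)
  names(hashes) <- sub(paste0("^", cfg$out_dir, "/?"), "", names(hashes))
  manifest <- list(
    package_version = as.character(utils::packageVersion("facecolr")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    stage_seconds = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    warnings = warnings_log,
    file_md5 = as.list(hashes))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

#' Export a rendered cohort to disk
#'
#' Writes per-face sRGB PNG images and mask rasters (PNG + JSON legend)
#' plus the ground-truth feature CSV.
#'
#' @param cohort Result of [generate_cohort()] with `render = TRUE`.
#' @param dir Output directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in cohort$faces) {
    write_lab_image(f$image, file.path(dir, paste0(f$face_id, ".png")))
    write_region_mask(f$mask, file.path(dir, paste0(f$face_id,
                                                    "_mask.png")))
  }
  readr::write_csv(cohort$ground_truth,
                   file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' Read an exported cohort directory
#'
#' Expects `<id>.png` image files with matching `<id>_mask.png` +
#' `<id>_mask.png.json` label maps.
#'
#' @param dir Directory written by [write_cohort()].
#' @return List of faces (`face_id`, `image`, `mask`).
#' @export
read_cohort_dir <- function(dir) {
  imgs <- list.files(dir, pattern = "\\.png$", full.names = FALSE)
  imgs <- imgs[!grepl("_mask\\.png$", imgs)]
  ids <- sub("\\.png$", "", imgs)
  purrr::map2(imgs, ids, function(f, id) {
    list(face_id = id,
         image = read_lab_image(file.path(dir, f)),
         mask = read_region_mask(file.path(dir, paste0(id, "_mask.png"))))
  })
}

#' Render a human-readable run summary
#'
#' Builds a markdown report from a completed run directory: reliability and
#' correlation tables (with significance stars at 0.05/0.01/0.001),
#' per-class RMSE comparison and the combined-model coefficient ranking.
#' Missing outputs are flagged rather than fatal.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param path Output markdown path (default `report.md` inside
#'   `run_dir`).
#' @return Invisibly, the report path.
#' @export
render_report <- function(run_dir, path = file.path(run_dir, "report.md")) {
  lines <- c("# Facial colour preference analysis", "")
  cohorts <- list.dirs(run_dir, recursive = FALSE)
  fmt_tbl <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.3f", x))
    c(paste0("| ", paste(colnames(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                      " |")))
  }
  for (cd in cohorts) {
    gname <- basename(cd)
    lines <- c(lines, sprintf("## Cohort `%s`", gname), "")
    rel_f <- file.path(cd, "reliability.csv")
    if (file.exists(rel_f)) {
      rel <- readr::read_csv(rel_f, show_col_types = FALSE)
      lines <- c(lines, "### Observer reliability (Cronbach's alpha)", "",
                 fmt_tbl(rel), "")
    } else lines <- c(lines, "_reliability output missing_", "")
    cor_f <- file.path(cd, "correlations.csv")
    if (file.exists(cor_f)) {
      co <- readr::read_csv(cor_f, show_col_types = FALSE)
      sig <- co[!is.na(co$stars) & co$stars != "" &
                  co$feature %in% feature_names(), ]
      lines <- c(lines,
                 "### Significant feature-preference correlations",
                 "", "Stars: \\*p ≤ 0.05, \\*\\*p ≤ 0.01, \\*\\*\\*p ≤ 0.001.",
                 "",
                 if (nrow(sig) > 0) fmt_tbl(sig) else "(none)", "")
    }
    cls_f <- file.path(cd, "class_rmse.csv")
    if (file.exists(cls_f)) {
      cls <- readr::read_csv(cls_f, show_col_types = FALSE)
      lines <- c(lines, "### Class-comparison models (mean test RMSE)", "",
                 fmt_tbl(cls), "")
    } else lines <- c(lines, "_class-model output missing_", "")
    for (f in list.files(cd, pattern = "^combined_model_.*\\.json$",
                         full.names = TRUE)) {
      m <- jsonlite::read_json(f, simplifyVector = TRUE)
      lines <- c(lines,
                 sprintf("### Combined model: %s", m$attribute), "",
                 sprintf(
                   "Predicted %s within %.2f points on its rating scale (mean RMSE = %.2f, SD = %.2f; alpha = %.2f, lambda = %.4g).",
                   m$attribute, m$mean_rmse, m$mean_rmse, m$sd_rmse,
                   m$alpha, m$lambda), "",
                 fmt_tbl(utils::head(m$coefficients, 16)), "")
    }
  }
  gd_f <- file.path(run_dir, "group_differences.csv")
  if (file.exists(gd_f)) {
    gd <- readr::read_csv(gd_f, show_col_types = FALSE)
    lines <- c(lines, "## Between-cohort feature differences (Welch t)",
               "", fmt_tbl(gd), "")
  }
  writeLines(lines, path)
  invisible(path)
}
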