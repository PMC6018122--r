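feature_cols <- c("mean", "std", "integrated_density", "skewness",
                  "kurtosis_excess", "energy", "inertia", "correlation",
                  "idm", "entropy")

fos_cols <- feature_cols[1:5]
glcm_cols <- feature_cols[6:10]

format_sig <- function(x) {
  # floating outputs are written with 12 significant digits so reruns are
  # byte-stable across platforms
  if (is.numeric(x) && !is.integer(x)) formatC(x, digits = 12, format = "g")
  else x
}

write_pipeline_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, format_sig), stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Batch pipeline run configuration
#'
#' Bundles the co-occurrence protocol settings and bookkeeping shared by
#' the batch commands; round-trips unchanged through a JSON config file.
#'
#' @param input input directory or manifest path.
#' @param output output directory.
#' @param distance,symmetric,log_base,correlation_mode protocol settings
#'   (see [glcm_features_protocol()]).
#' @param seed RNG seed for commands that generate data.
#' @param log_level `"info"` or `"debug"`.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(input = ".", output = ".", distance = 3L,
                       symmetric = TRUE, log_base = exp(1),
                       correlation_mode = "rooted", seed = 1L,
                       log_level = "info") {
  structure(list(input = input, output = output,
                 distance = as.integer(distance), symmetric = symmetric,
                 log_base = log_base, correlation_mode = correlation_mode,
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file to read or write.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

list_image_paths <- function(input) {
  if (length(input) == 1L && dir.exists(input)) {
    input <- list.files(input, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
  }
  sort(input)  # deterministic output ordering
}

#' Extract the ten texture features from a batch of images
#'
#' Computes the five first-order statistics and the five four-angle
#' co-occurrence features for every image in a directory (or an explicit
#' path vector), one row per image, sorted by path. A failing image is
#' reported with a warning and skipped; the run continues.
#'
#' @param input directory containing PNG/TIFF images, or a character
#'   vector of image paths.
#' @param output_csv optional path; when given, the table is written as
#'   CSV with 12-significant-digit floats.
#' @param distance,symmetric,correlation_mode,log_base co-occurrence
#'   protocol settings.
#' @param roi optional region of interest passed to [load_image()].
#' @return Data frame: `path`, `height`, `width`, `n_levels`, `distance`,
#'   `symmetric`, `log_base`, `correlation_mode`, then the ten feature
#'   columns.
#' @export
pipeline_features <- function(input, output_csv = NULL, distance = 3L,
                              symmetric = TRUE,
                              correlation_mode = "rooted",
                              log_base = exp(1), roi = NULL) {
  paths <- list_image_paths(input)
  if (length(paths) == 0L) stop("no images found in input")
  rows <- list()
  for (p in paths) {
    row <- tryCatch({
      img <- load_image(p, roi = roi)
      f <- compute_fos(img)
      g <- glcm_features_protocol(img, distance = distance,
                                  symmetric = symmetric,
                                  correlation_mode = correlation_mode,
                                  log_base = log_base)
      cbind(data.frame(path = p, height = img$height, width = img$width,
                       n_levels = img$n_levels, distance = distance,
                       symmetric = symmetric, log_base = log_base,
                       correlation_mode = correlation_mode),
            as.data.frame(f), as.data.frame(g))
    }, error = function(e) {
      warning("skipping ", p, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) stop("every image failed to process")
  out <- do.call(rbind, rows)
  if (!is.null(output_csv)) write_pipeline_csv(out, output_csv)
  out
}

#' Fit the exponential response law per texture parameter
#'
#' Groups a feature table by condition, averages each texture parameter
#' per condition, and fits the saturating exponential law to every
#' parameter's condition series.
#'
#' @param features feature data frame (from [pipeline_features()]) or a
#'   CSV path; must carry a condition column.
#' @param condition_col name of the condition column.
#' @param output_csv optional CSV destination.
#' @param weighted passed to [fit_texture_law()].
#' @return Data frame with one row per texture parameter: `parameter`,
#'   `delta0`, `k`, `delta_s`, `rss`, `r_squared`, `converged`. The list
#'   of fitted `texture_law` objects is attached as attribute `fits`.
#' @export
pipeline_fit <- function(features, condition_col = "condition",
                         output_csv = NULL, weighted = FALSE) {
  if (is.character(features)) features <- utils::read.csv(features)
  if (!condition_col %in% names(features))
    stop("no condition column '", condition_col, "' in features")
  cond <- features[[condition_col]]
  xs <- sort(unique(cond))
  present <- intersect(feature_cols, names(features))
  fits <- list()
  rows <- list()
  for (fc in present) {
    ym <- vapply(xs, function(x) mean(features[[fc]][cond == x],
                                      na.rm = TRUE), numeric(1))
    ys <- vapply(xs, function(x) stats::sd(features[[fc]][cond == x],
                                           na.rm = TRUE), numeric(1))
    sds <- if (!anyNA(ys) && all(ys > 0)) ys else NULL
    fit <- fit_texture_law(condition_series(xs, ym, y_sd = sds),
                           weighted = weighted)
    fits[[fc]] <- fit
    rows[[fc]] <- data.frame(parameter = fc, delta0 = fit$delta0,
                             k = fit$k, delta_s = fit$delta_s,
                             rss = fit$rss, r_squared = fit$r_squared,
                             converged = fit$converged)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  if (!is.null(output_csv)) write_pipeline_csv(out, output_csv)
  out
}

#' Discriminant classification of a labelled feature table
#'
#' Fits a canonical discriminant model on the chosen feature set
#' (first-order, co-occurrence, or both) and reports the coefficient
#' table, the sequential Wilks'-lambda table, the training confusion
#' matrix and error rates.
#'
#' @param features labelled feature data frame or CSV path.
#' @param feature_set `"both"`, `"fos"` or `"glcm"`.
#' @param label_col name of the group-label column.
#' @param alpha retention significance level.
#' @param output_dir optional directory; when given, writes
#'   `cda_coefficients.csv`, `cda_wilks.csv`, `cda_confusion.csv`,
#'   `cda_scores.csv`.
#' @return List with `model` (the [fit_cda()] object), `coefficients`,
#'   `wilks_table`, `confusion`, `error`, `scores`.
#' @export
pipeline_classify <- function(features, feature_set = c("both", "fos",
                                                        "glcm"),
                              label_col = "group", alpha = 0.05,
                              output_dir = NULL) {
  feature_set <- match.arg(feature_set)
  if (is.character(features)) features <- utils::read.csv(features)
  if (!label_col %in% names(features))
    stop("no label column '", label_col, "' in features")
  cols <- switch(feature_set, both = feature_cols, fos = fos_cols,
                 glcm = glcm_cols)
  cols <- intersect(cols, names(features))
  if (length(cols) < 2L) stop("feature set '", feature_set,
                              "' not present in the table")
  model <- fit_cda(features[, cols, drop = FALSE], features[[label_col]],
                   alpha = alpha)
  tab <- cbind(features[, cols, drop = FALSE],
               .group = features[[label_col]])
  er <- error_rate(model, tab)
  wilks_table <- data.frame(
    test = paste0("functions ", seq_along(model$wilks), "..",
                  length(model$wilks)),
    eigenvalue = model$eigenvalues, wilks_lambda = model$wilks,
    chi_square = model$chi2, df = model$dof, p_value = model$p_values)
  scores <- canonical_scores(model, tab)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_pipeline_csv(as.data.frame(model$coefficients),
                       file.path(output_dir, "cda_coefficients.csv"))
    write_pipeline_csv(wilks_table, file.path(output_dir, "cda_wilks.csv"))
    utils::write.csv(as.data.frame.matrix(er$confusion),
                     file.path(output_dir, "cda_confusion.csv"))
    write_pipeline_csv(scores$scores,
                       file.path(output_dir, "cda_scores.csv"))
  }
  list(model = model, coefficients = model$coefficients,
       wilks_table = wilks_table, confusion = er$confusion,
       error = er$overall, scores = scores)
}

#' Texture trajectory and stage segmentation for a frame directory
#'
#' @param input directory of ordered frame images (sorted by file name) or
#'   a path vector in time order.
#' @param output_dir optional directory for `trajectory.csv` and
#'   `stages.json`.
#' @param feature series used for segmentation (default `"entropy"`).
#' @param glcm_distance co-occurrence displacement.
#' @param n_stages number of stages (default 3).
#' @return List with `trajectory` (data frame) and `segmentation`
#'   (a [segment_stages()] result).
#' @export
pipeline_timeseries <- function(input, output_dir = NULL,
                                feature = "entropy", glcm_distance = 3L,
                                n_stages = 3L) {
  paths <- list_image_paths(input)
  if (length(paths) == 0L) stop("no frames found in input")
  seq <- load_sequence(paths)
  traj <- compute_trajectory(seq, glcm_distance = glcm_distance)
  seg <- segment_stages(traj, feature = feature, n_stages = n_stages)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_pipeline_csv(as.data.frame(traj),
                       file.path(output_dir, "trajectory.csv"))
    jsonlite::write_json(
      list(boundaries = seg$boundaries,
           boundary_times = seg$boundary_times,
           stage_labels = seg$stage_labels, score = seg$score,
           feature = seg$feature, method = seg$method),
      file.path(output_dir, "stages.json"), auto_unbox = FALSE, digits = NA)
  }
  list(trajectory = traj, segmentation = seg)
}

#' Generate and write a synthetic deposit corpus
#'
#' Renders a full synthetic condition series to disk: one PNG per image
#' plus a manifest CSV carrying every seed and the generating ground
#' truth, so downstream runs are reproducible fixtures.
#'
#' @param spec a [series_spec()].
#' @param output_dir destination directory.
#' @return The manifest data frame (with a `path` column), invisibly; the
#'   mapping ground truth is also written to `manifest_truth.json`.
#' @export
pipeline_synth <- function(spec, output_dir) {
  stopifnot(inherits(spec, "series_spec"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  ser <- generate_series(spec)
  man <- ser$manifest
  man$path <- file.path(output_dir,
                        sprintf("deposit_x%03d_rep%02d.png",
                                match(man$condition, sort(unique(man$condition))),
                                man$rep))
  for (i in seq_along(ser$images))
    png::writePNG(ser$images[[i]]$pixels / 255, man$path[i])
  write_pipeline_csv(man, file.path(output_dir, "manifest.csv"))
  jsonlite::write_json(as.list(attr(ser$manifest, "truth")),
                       file.path(output_dir, "manifest_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(man)
}
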