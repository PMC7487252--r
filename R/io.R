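## File formats: annotation and detection CSVs, PNG/TIFF micrographs,
## YAML run configuration, JSON reports, JSON-lines run log.

ANN_HEADER <- c("image_id", "x_px", "y_px", "length_px")
DET_HEADER <- c("image_id", "x_px", "y_px", "confidence", "cluster_size")

check_header <- function(df, expected, path) {
  if (!identical(names(df), expected)) {
    stop(sprintf("'%s': unexpected header (%s); expected columns %s",
                 path, paste(names(df), collapse = ","),
                 paste(expected, collapse = ",")), call. = FALSE)
  }
}

#' Read and write stoma annotation CSVs
#'
#' The annotation format has the exact header
#' `image_id,x_px,y_px,length_px`, one row per stoma; `length_px` may be
#' empty (120 px default). Malformed rows are reported with their line
#' number. Writing then reading returns identical values.
#'
#' @param path CSV file path.
#' @return [read_annotations()]: a [stoma_annotations()] data.frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("'%s' not found", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_header(df, ANN_HEADER, path)
  if (!nrow(df)) return(stoma_annotations())
  bad <- which(!is.finite(df$x_px) | !is.finite(df$y_px) |
                 df$x_px < 0 | df$y_px < 0 |
                 (!is.na(df$length_px) & df$length_px <= 0))
  if (length(bad)) {
    stop(sprintf("'%s': invalid annotation at line %s (coordinates must be >= 0, length_px > 0)",
                 path, paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  stoma_annotations(df$image_id, df$x_px, df$y_px, df$length_px)
}

#' @param anns A [stoma_annotations()] data.frame.
#' @rdname read_annotations
#' @export
write_annotations <- function(anns, path) {
  df <- as.data.frame(anns)[, ANN_HEADER]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write detection CSVs
#'
#' Detections use the exact header
#' `image_id,x_px,y_px,confidence,cluster_size`. Round-trips preserve
#' values to full double precision.
#'
#' @param path CSV file path.
#' @return [read_detections()]: a `"detection_set"` data.frame.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop(sprintf("'%s' not found", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_header(df, DET_HEADER, path)
  bad <- which(!is.finite(df$x_px) | !is.finite(df$y_px) |
                 df$confidence < 0 | df$confidence > 1)
  if (length(bad)) {
    stop(sprintf("'%s': invalid detection at line %s", path,
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  class(df) <- c("detection_set", "data.frame")
  df
}

#' @param dets A `"detection_set"` data.frame.
#' @rdname read_detections
#' @export
write_detections <- function(dets, path) {
  df <- as.data.frame(dets)[, DET_HEADER]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read micrographs from image files
#'
#' Loads 8-bit PNG or TIFF images as [micrograph()] objects (grayscale in
#' `[0, 1]`; RGB converted by luminance). `read_images()` loads every
#' PNG/TIFF in a directory, sorted by file name, using file names (without
#' extension) as image ids.
#'
#' @param path Image file path.
#' @param image_id Identifier; defaults to the file name.
#' @param calibration Optional [calibration()] attached to each image.
#' @return A [micrograph()], or for [read_images()] a list of them.
#' @export
read_micrograph <- function(path, image_id = NULL, calibration = NULL) {
  if (!file.exists(path)) stop(sprintf("'%s' not found", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               png = png::readPNG(path),
               tif = ,
               tiff = tiff::readTIFF(path),
               stop(sprintf("'%s': unsupported image format '%s' (PNG/TIFF only)",
                            path, ext), call. = FALSE))
  if (is.null(image_id)) image_id <- tools::file_path_sans_ext(basename(path))
  micrograph(px, image_id = image_id, calibration = calibration)
}

#' @param dir Directory to scan.
#' @rdname read_micrograph
#' @export
read_images <- function(dir, calibration = NULL) {
  if (!dir.exists(dir)) stop(sprintf("'%s' is not a directory", dir), call. = FALSE)
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  lapply(files, read_micrograph, calibration = calibration)
}

#' Save and load classifiers
#'
#' `save_classifier()` writes the weights as an RDS file plus a JSON
#' sidecar (`<path>.json`) recording the architecture, input shape and
#' training history; `load_classifier()` restores the classifier.
#'
#' @param clf A `"stoma_classifier"`.
#' @param path RDS file path.
#' @return `load_classifier()`: the restored classifier.
#' @export
save_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "stoma_classifier"))
  saveRDS(clf, path)
  sidecar <- list(architecture = clf$spec$name,
                  input_shape = clf$spec$input_shape,
                  parameters = clf$num_params$total,
                  trainable_parameters = clf$num_params$trainable,
                  normalization = "pixel/255, grayscale replicated to 3 channels",
                  trained = clf$trained,
                  hyperparams = unclass(clf$hyper),
                  history = clf$history)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  clf <- readRDS(path)
  if (!inherits(clf, "stoma_classifier")) {
    stop(sprintf("'%s' does not contain a stoma_classifier", path),
         call. = FALSE)
  }
  clf
}

#' Run configuration
#'
#' A nested list mirroring the module structure (calibration, simulate,
#' patch, detection, training, paths) with the workflow defaults: 120 px
#' patches, threshold 0.7, the 0.05..0.95 threshold grid, and the standard
#' per-architecture training hyperparameters. Configs round-trip through
#' YAML unchanged.
#'
#' @return A nested list of class `"run_config"`.
#' @export
default_run_config <- function() {
  structure(list(
    calibration = list(image_width_px = 1600L, image_height_px = 1200L,
                       field_width_um = 344, field_height_um = 258),
    simulate = list(n_train_images = 4L, n_eval_images = 3L,
                    width_px = 600L, height_px = 440L,
                    n_stomata_min = 4L, n_stomata_max = 7L,
                    stoma_major_min_px = 60, stoma_major_max_px = 90,
                    min_separation_px = 140, artifact_rate = 2,
                    noise_level = 0.02, blur_sigma_px = 1),
    patch = list(patch_size_px = 120L, stride_px = 30L, flush = FALSE),
    detection = list(threshold = 0.7, bandwidth_px = 60,
                     min_cluster_size = 1L, match_radius_px = 60,
                     tau_grid_min = 0.05, tau_grid_max = 0.95,
                     tau_grid_step = 0.05),
    training = list(arch = "basic_shallow", learning_rate = 5e-4,
                    batch_size = 32L, epochs = 6L, dropout_rate = 0.5,
                    augment = TRUE, neg_pos_ratio = 6, seed = 1L),
    paths = list(out_dir = "stomata_run")),
    class = "run_config")
}

#' @param path YAML file path.
#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("'%s' not found", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  for (sec in names(base)) {
    if (!is.null(cfg[[sec]])) {
      base[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
    }
  }
  base
}

#' @param cfg A `"run_config"` list.
#' @rdname default_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

append_run_log <- function(out_dir, record) {
  record$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = file.path(out_dir, "run_log.jsonl"),
      append = TRUE)
  invisible(record)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the end-to-end pipeline
#'
#' Executes simulate -> patchify -> train -> detect -> evaluate -> density
#' on seeded synthetic data, writing every stage artifact (images,
#' annotation/label/detection CSVs, classifier weights with JSON sidecar,
#' evaluation report JSON, PR-curve and density CSVs, a JSON-lines run
#' log) under `out_dir`. Fully reproducible from (config, seed).
#'
#' The default configuration is a minutes-scale demonstration (a handful
#' of 600 x 440 px scenes, few training epochs); scale the `simulate` and
#' `training` blocks up for real experiments.
#'
#' @param cfg A [default_run_config()]-style config (or path to a YAML).
#' @param seed Master seed overriding `cfg$training$seed`.
#' @param out_dir Output directory overriding `cfg$paths$out_dir`.
#' @param quiet Suppress progress messages.
#' @return An `"eval_report"` list: `match`, `pr_curve`, `count_accuracy`,
#'   `regression`, `density`, `f_at_threshold`, plus paths to artifacts.
#' @export
run_pipeline <- function(cfg = default_run_config(), seed = NULL,
                         out_dir = NULL, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (!is.null(seed)) cfg$training$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$paths$out_dir <- out_dir
  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  master_seed <- cfg$training$seed

  ## calibration scaled to the simulated image size (same um/px)
  cal_ref <- calibration(cfg$calibration$image_width_px,
                         cfg$calibration$image_height_px,
                         cfg$calibration$field_width_um,
                         cfg$calibration$field_height_um)
  upp <- um_per_px(cal_ref)
  cal <- calibration(cfg$simulate$width_px, cfg$simulate$height_px,
                     cfg$simulate$width_px * upp,
                     cfg$simulate$height_px * upp)

  ## --- simulate ---
  scfg <- synth_config(width_px = cfg$simulate$width_px,
                       height_px = cfg$simulate$height_px,
                       n_stomata = c(cfg$simulate$n_stomata_min,
                                     cfg$simulate$n_stomata_max),
                       stoma_major_axis_px = c(cfg$simulate$stoma_major_min_px,
                                               cfg$simulate$stoma_major_max_px),
                       min_separation_px = cfg$simulate$min_separation_px,
                       artifact_rate = cfg$simulate$artifact_rate,
                       noise_level = cfg$simulate$noise_level,
                       blur_sigma_px = cfg$simulate$blur_sigma_px,
                       seed = master_seed)
  img_dir <- file.path(out_dir, "images")
  n_all <- cfg$simulate$n_train_images + cfg$simulate$n_eval_images
  say("simulate: %d scenes (%d train / %d eval)", n_all,
      cfg$simulate$n_train_images, cfg$simulate$n_eval_images)
  scenes <- pipeline_stage("simulate",
                           generate_dataset(n_all, scfg, img_dir))
  train_scenes <- scenes[seq_len(cfg$simulate$n_train_images)]
  eval_scenes <- scenes[cfg$simulate$n_train_images + seq_len(cfg$simulate$n_eval_images)]

  ## --- patchify ---
  pcfg <- patch_config(cfg$patch$patch_size_px, cfg$patch$stride_px,
                       cfg$patch$flush)
  ds <- pipeline_stage("patchify",
                       build_training_set(train_scenes, pcfg,
                                          neg_pos_ratio = cfg$training$neg_pos_ratio,
                                          seed = master_seed))
  say("patchify: %d patches (%d positive)", length(ds$label),
      ds$class_counts[["positive"]])
  utils::write.csv(cbind(ds$meta, label = as.character(ds$label)),
                   file.path(out_dir, "patch_labels.csv"), row.names = FALSE,
                   quote = FALSE)

  ## --- train ---
  hyper <- training_hyperparams(cfg$training$arch,
                                learning_rate = cfg$training$learning_rate,
                                batch_size = cfg$training$batch_size,
                                epochs = cfg$training$epochs,
                                dropout_rate = cfg$training$dropout_rate,
                                augment = cfg$training$augment,
                                seed = master_seed)
  say("train: %s for %d epochs", cfg$training$arch, hyper$epochs)
  clf <- pipeline_stage("train", {
    clf <- build_classifier(architecture_spec(cfg$training$arch), hyper)
    train_classifier(clf, ds)
  })
  save_classifier(clf, file.path(out_dir, "classifier.rds"))

  ## --- detect ---
  dcfg <- detection_config(cfg$detection$threshold, cfg$detection$bandwidth_px,
                           cfg$detection$min_cluster_size)
  say("detect: threshold %.2f on %d scene(s)", dcfg$threshold,
      length(eval_scenes))
  maps <- pipeline_stage("detect", lapply(eval_scenes, function(s)
    score_image(clf, s$micrograph, pcfg)))
  det_list <- lapply(maps, detections_from_scoremap, det_cfg = dcfg)
  dets <- do.call(rbind, det_list)
  class(dets) <- c("detection_set", "data.frame")
  write_detections(dets, file.path(out_dir, "detections.csv"))

  ## --- evaluate ---
  radius <- cfg$detection$match_radius_px
  tau_grid <- seq(cfg$detection$tau_grid_min, cfg$detection$tau_grid_max,
                  by = cfg$detection$tau_grid_step)
  report <- pipeline_stage("evaluate", {
    TP <- FP <- FN <- 0L
    for (k in seq_along(eval_scenes)) {
      mr <- match_detections(det_list[[k]], eval_scenes[[k]]$annotations,
                             radius)
      TP <- TP + mr$TP; FP <- FP + mr$FP; FN <- FN + mr$FN
    }
    prf <- precision_recall_f(TP, FP, FN)
    curve <- pr_curve(clf, eval_scenes, pcfg, dcfg, tau_grid, radius)
    counts <- data.frame(
      image_id = vapply(eval_scenes, function(s) s$micrograph$image_id, ""),
      computed = vapply(det_list, nrow, numeric(1)),
      manual = vapply(eval_scenes, function(s) nrow(s$annotations), numeric(1)))
    acc <- count_accuracy(counts)
    reg <- if (nrow(counts) >= 3L && stats::var(counts$manual) > 0) {
      fit_counts_regression(counts)
    } else NULL
    list(match = list(TP = TP, FP = FP, FN = FN), f_at_threshold = prf,
         pr_curve = curve, count_accuracy = acc, regression = reg)
  })
  utils::write.csv(as.data.frame(report$pr_curve),
                   file.path(out_dir, "pr_curve.csv"), row.names = FALSE,
                   quote = FALSE)

  ## --- density ---
  dens <- pipeline_stage("density", {
    counts <- vapply(det_list, nrow, integer(1))
    ids <- vapply(eval_scenes, function(s) s$micrograph$image_id, "")
    density_result(ids, counts, view_field_area_mm2(cal))
  })
  utils::write.csv(dens, file.path(out_dir, "density.csv"),
                   row.names = FALSE, quote = FALSE)
  report$density <- dens

  write_run_config(cfg, file.path(out_dir, "config.yaml"))
  append_run_log(out_dir, list(
    config_md5 = unname(tools::md5sum(file.path(out_dir, "config.yaml"))),
    seed = master_seed,
    package_version = as.character(utils::packageVersion("stomatadetect")),
    n_train_images = cfg$simulate$n_train_images,
    n_eval_images = cfg$simulate$n_eval_images,
    n_patches = length(ds$label),
    n_detections = nrow(dets),
    f_score = report$f_at_threshold$f_score,
    mean_count_accuracy_pct = report$count_accuracy$mean_accuracy_pct))

  json_report <- report
  json_report$pr_curve <- as.data.frame(report$pr_curve)
  json_report$count_accuracy <- unclass(report$count_accuracy)
  if (!is.null(json_report$regression)) {
    json_report$regression <- unclass(json_report$regression)
  }
  jsonlite::write_json(json_report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  say("done: report written to %s", file.path(out_dir, "report.json"))
  report$out_dir <- out_dir
  class(report) <- "eval_report"
  invisible(report)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report: TP=%d FP=%d FN=%d; P=%.3f R=%.3f F=%.3f; mean count accuracy %.1f%%\n",
    x$match$TP, x$match$FP, x$match$FN, x$f_at_threshold$precision,
    x$f_at_threshold$recall, x$f_at_threshold$f_score,
    x$count_accuracy$mean_accuracy_pct))
  invisible(x)
}
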