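#' Read a grayscale TIFF as an image_grid
#'
#' Accepts single-channel 8- or 16-bit grayscale TIFF and preserves the
#' native integer intensity scale (no rescaling to `[0, 1]`, no silent 8-bit
#' downcast of 16-bit data).
#'
#' @param path Path to a TIFF file.
#' @return An `image_grid`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("File not found: ", path),
                 class = "spotbelief_error_io")
  }
  px <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                 error = function(e) {
                   rlang::abort(paste0("Cannot read TIFF: ", path, " (",
                                       conditionMessage(e), ")"),
                                class = "spotbelief_error_io")
                 })
  if (length(dim(px)) == 3 && dim(px)[3] > 1) {
    rlang::abort("Multi-channel / RGB TIFF is not supported; supply a single-channel grayscale image.",
                 class = "spotbelief_error_unsupported_format")
  }
  if (length(dim(px)) == 3) px <- px[, , 1]
  bits <- attr(px, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(px) > 255) 16L else 8L
  if (!bits %in% c(8L, 16L)) {
    rlang::abort(paste0(bits, "-bit TIFF is not supported (8 or 16 only)."),
                 class = "spotbelief_error_unsupported_format")
  }
  image_grid(matrix(as.numeric(px), nrow(px), ncol(px)),
             bit_depth = as.integer(bits))
}

#' Write an image_grid as a grayscale TIFF
#'
#' @param image An `image_grid` or numeric matrix (values on the native
#'   integer scale of `bit_depth`).
#' @param path Output path.
#' @param bit_depth 8 or 16; defaults to the image's own.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bit_depth = NULL) {
  image <- as_image_grid(image)
  if (is.null(bit_depth)) bit_depth <- image$bit_depth
  maxval <- 2^bit_depth - 1
  px <- round(pmin(pmax(image$pixels, 0), maxval))
  tiff::writeTIFF(px / maxval, path, bits.per.sample = bit_depth)
  invisible(path)
}

#' Read or write a component label map as 16-bit TIFF
#'
#' Component ids are stored directly as 16-bit gray levels (0 = background).
#'
#' @param components A `component_set`.
#' @param path File path.
#' @return `write_label_map` returns `path` invisibly; `read_label_map`
#'   returns the integer label matrix.
#' @export
write_label_map <- function(components, path) {
  stopifnot(inherits(components, "component_set"))
  if (length(components$components) > 65535) {
    rlang::abort("More than 65535 components cannot be stored in 16 bits.",
                 class = "spotbelief_error_io")
  }
  tiff::writeTIFF(components$label_map / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  px <- tiff::readTIFF(path, as.is = TRUE)
  matrix(as.integer(round(px)), nrow(px), ncol(px))
}

run_config_keys <- c("input_dirs", "target_dir", "output_dir", "detection",
                     "z_scope", "cantelli", "log_base", "seed", "verbose")
detection_keys <- c("pre_sigma", "post_sigma", "prc", "connectivity",
                    "min_area", "prune_local_maxima", "kurtosis_fallback",
                    "kurtosis_scope", "threshold_mode")

#' Pipeline run configuration
#'
#' A single JSON-serializable document capturing every pipeline parameter.
#' Unknown keys are rejected by name, so typos never silently fall back to
#' defaults.
#'
#' @param input_dirs Named list: label -> directory of reference TIFFs.
#' @param target_dir Directory of target TIFFs to label.
#' @param output_dir Directory receiving all artifacts.
#' @param detection A [detection_config()] (or list of its fields).
#' @param z_scope,cantelli Belief options (see [assign_plausibility()]).
#' @param log_base Fusion log base (see [dempster_combine()]).
#' @param seed Integer seed recorded in the run log.
#' @param verbose Emit progress messages.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dirs, target_dir, output_dir,
                       detection = detection_config(),
                       z_scope = "image", cantelli = "literal",
                       log_base = "e", seed = 1L, verbose = FALSE) {
  if (!inherits(detection, "detection_config")) {
    unknown <- setdiff(names(detection), detection_keys)
    if (length(unknown)) {
      rlang::abort(paste0("Unknown detection key(s): ",
                          paste(unknown, collapse = ", ")),
                   class = "spotbelief_error_invalid_input")
    }
    detection <- do.call(detection_config, detection)
  }
  structure(
    list(input_dirs = input_dirs, target_dir = target_dir,
         output_dir = output_dir, detection = detection,
         z_scope = z_scope, cantelli = cantelli, log_base = log_base,
         seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "run_config"
  )
}

#' Read or write a run configuration as JSON
#'
#' @param cfg A `run_config`.
#' @param path File path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   the validated `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  obj <- unclass(cfg)
  obj$detection <- unclass(obj$detection)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(obj), run_config_keys)
  if (length(unknown)) {
    rlang::abort(paste0("Unknown configuration key(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "spotbelief_error_invalid_input")
  }
  obj$input_dirs <- as.list(obj$input_dirs)
  do.call(run_config, obj)
}

detect_dir <- function(dir, det_cfg, out_dir = NULL, prefix = "",
                       verbose = FALSE, log = NULL) {
  paths <- sort(list.files(dir, pattern = "\\.tiff?$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(paths) == 0) {
    rlang::abort(paste0("No TIFF files in ", dir),
                 class = "spotbelief_error_io")
  }
  tables <- purrr::map(paths, function(p) {
    id <- sub("\\.tiff?$", "", basename(p), ignore.case = TRUE)
    img <- read_image(p)
    comp <- detect_objects(img, det_cfg)
    response <- adaptive_threshold(compute_response(img, det_cfg), det_cfg)
    if (!is.null(log)) {
      log_line <- sprintf(
        "image=%s%s kurtosis=%.6g z=%.6g threshold=%.6g components=%d",
        prefix, id, attr(comp, "kurtosis"), attr(comp, "z_score"),
        attr(comp, "threshold"), length(comp$components))
      cat(log_line, "\n", file = log, append = TRUE, sep = "")
      if (verbose) message(log_line)
    }
    if (!is.null(out_dir)) {
      write_label_map(comp, file.path(out_dir,
                                      paste0(prefix, id, "_labels.tif")))
    }
    object_table(comp, img, response, image_id = paste0(prefix, id))
  })
  features_table(dplyr::bind_rows(tables))
}

#' Run the full detection-and-labelling pipeline
#'
#' Detects objects in every reference directory, fits one reference model
#' per label, detects and scores the target directory against each model,
#' and (with exactly two reference labels) emits belief triplets using the
#' swapped-model construction. Writes label maps, object CSVs, model JSONs,
#' labelled CSVs and a run log capturing all parameters; reruns with the
#' same configuration are byte-identical.
#'
#' @param cfg A [run_config()].
#' @return Named list of output file paths, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$output_dir, "run_log.txt")
  cat("spotbelief ", as.character(utils::packageVersion("spotbelief")),
      " seed=", cfg$seed, "\n", file = log_path, sep = "")
  write_run_config(cfg, file.path(cfg$output_dir, "run_config.json"))
  outputs <- list(run_log = log_path)

  models <- list()
  for (label in names(cfg$input_dirs)) {
    tab <- detect_dir(cfg$input_dirs[[label]], cfg$detection,
                      out_dir = cfg$output_dir, prefix = paste0(label, "_"),
                      verbose = cfg$verbose, log = log_path)
    obj_csv <- file.path(cfg$output_dir, paste0("objects_", label, ".csv"))
    write_objects_csv(tab, obj_csv)
    models[[label]] <- fit_reference_model(tab, label)
    model_json <- file.path(cfg$output_dir, paste0("model_", label, ".json"))
    write_reference_model(models[[label]], model_json)
    outputs[[paste0("objects_", label)]] <- obj_csv
    outputs[[paste0("model_", label)]] <- model_json
  }

  target_tab <- detect_dir(cfg$target_dir, cfg$detection,
                           out_dir = cfg$output_dir, prefix = "target_",
                           verbose = cfg$verbose, log = log_path)
  target_csv <- file.path(cfg$output_dir, "objects_target.csv")
  write_objects_csv(target_tab, target_csv)
  outputs$objects_target <- target_csv

  labels <- names(models)
  for (i in seq_along(labels)) {
    swap <- if (length(labels) == 2) models[[labels[-i][1]]]
    labelled <- label_objects(target_tab, models[[labels[i]]],
                              swap_model = swap,
                              z_scope = cfg$z_scope,
                              convention = cfg$cantelli)
    out_csv <- file.path(cfg$output_dir,
                         paste0("labelled_", labels[i], ".csv"))
    write_labelled_csv(labelled, out_csv)
    outputs[[paste0("labelled_", labels[i])]] <- out_csv
  }
  invisible(outputs)
}
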