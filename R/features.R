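#' Per-object feature descriptor
#'
#' Computes the three-component evidence descriptor of a detected object:
#' summed raw intensity, area in pixels, and summed negative-Laplacian
#' response. Features are kept in raw (unnormalized) units; all
#' standardization happens later, inside the belief stage.
#'
#' @param component Two-column `(row, col)` matrix of pixel coordinates, or
#'   one element of a `component_set`'s `components` list.
#' @param image An `image_grid` or numeric matrix.
#' @param response A `response_map` aligned with the image.
#' @return A one-row tibble with columns `intensity_sum`, `area`,
#'   `laplacian_sum`.
#' @export
extract_features <- function(component, image, response) {
  image <- as_image_grid(image)
  if (is.null(dim(component)) || nrow(component) == 0) {
    rlang::abort("Empty component: no pixels to summarize.",
                 class = "spotbelief_error_invalid_input")
  }
  if (any(component[, 1] < 1 | component[, 1] > image$height |
          component[, 2] < 1 | component[, 2] > image$width)) {
    rlang::abort("Component pixels fall outside the image.",
                 class = "spotbelief_error_invalid_input")
  }
  tibble::tibble(
    intensity_sum = sum(image$pixels[component]),
    area = nrow(component),
    laplacian_sum = sum(response$values[component])
  )
}

#' Object table for one image
#'
#' Expands a `component_set` into the canonical one-row-per-object table:
#' bounding-box origin, pixel count, and the feature descriptor.
#'
#' @param components A `component_set` from [detect_objects()].
#' @param image The source `image_grid` (or matrix).
#' @param response The `response_map` for the same image.
#' @param image_id Character id recorded in the table.
#' @return A tibble with columns `image_id`, `object_id`, `row_min`,
#'   `col_min`, `n_pixels`, `intensity_sum`, `area`, `laplacian_sum`.
#' @export
object_table <- function(components, image, response,
                         image_id = "image") {
  stopifnot(inherits(components, "component_set"))
  image <- as_image_grid(image)
  if (length(components$components) == 0) {
    return(tibble::tibble(
      image_id = character(), object_id = integer(),
      row_min = integer(), col_min = integer(), n_pixels = integer(),
      intensity_sum = double(), area = double(), laplacian_sum = double()))
  }
  rows <- purrr::imap(components$components, function(px, i) {
    fv <- extract_features(px, image, response)
    tibble::tibble(
      image_id = image_id, object_id = as.integer(i),
      row_min = min(px[, 1]), col_min = min(px[, 2]),
      n_pixels = nrow(px),
      intensity_sum = fv$intensity_sum, area = fv$area,
      laplacian_sum = fv$laplacian_sum)
  })
  dplyr::bind_rows(rows)
}

#' Assemble and validate a multi-image feature table
#'
#' Binds per-image object tables into one table in a stable order (by
#' `image_id`, then `object_id`) and rejects duplicate object keys, so the
#' result round-trips losslessly through the CSV schema.
#'
#' @param objects A tibble (or list of tibbles) in the [object_table()]
#'   schema.
#' @return A tibble sorted by `(image_id, object_id)`.
#' @export
features_table <- function(objects) {
  if (is.list(objects) && !is.data.frame(objects)) {
    objects <- dplyr::bind_rows(objects)
  }
  objects <- tibble::as_tibble(objects)
  if (nrow(objects) == 0) {
    if (ncol(objects) > 0) return(objects)
    return(tibble::tibble(
      image_id = character(), object_id = integer(),
      row_min = integer(), col_min = integer(), n_pixels = integer(),
      intensity_sum = double(), area = double(), laplacian_sum = double()))
  }
  if (nrow(objects) > 0 &&
      anyDuplicated(objects[, c("image_id", "object_id")]) > 0) {
    dup <- objects[duplicated(objects[, c("image_id", "object_id")]), ]
    rlang::abort(paste0("Duplicate object keys: ",
                        paste(dup$image_id, dup$object_id, sep = "/",
                              collapse = ", ")),
                 class = "spotbelief_error_invalid_input")
  }
  dplyr::arrange(objects, .data$image_id, .data$object_id)
}

#' Run-length encode component pixel masks
#'
#' Encodes each component's pixels as runs over the row-major (raster) linear
#' index, the sidecar representation used next to the object CSV.
#'
#' @param components A `component_set`.
#' @param image_id Character id recorded in the table.
#' @return A tibble with columns `image_id`, `object_id`, `start`, `length`
#'   (1-based raster offsets).
#' @export
components_to_rle <- function(components, image_id = "image") {
  stopifnot(inherits(components, "component_set"))
  m <- ncol(components$label_map)
  rows <- purrr::imap(components$components, function(px, i) {
    key <- sort((px[, 1] - 1L) * m + px[, 2])
    brk <- c(TRUE, diff(key) != 1L)
    grp <- cumsum(brk)
    starts <- key[brk]
    lens <- as.integer(tabulate(grp))
    tibble::tibble(image_id = image_id, object_id = as.integer(i),
                   start = starts, length = lens)
  })
  dplyr::bind_rows(rows)
}

#' Decode a run-length mask table back to pixel coordinates
#'
#' @param rle_table Tibble from [components_to_rle()].
#' @param height,width Image dimensions.
#' @return A `component_set` (components only; ids follow the table).
#' @export
rle_to_components <- function(rle_table, height, width) {
  label_map <- matrix(0L, height, width)
  split_tbl <- split(rle_table, rle_table$object_id)
  components <- lapply(split_tbl, function(tb) {
    key <- unlist(purrr::map2(tb$start, tb$length, function(s, l) s + 0:(l - 1L)))
    key <- sort(key)
    cbind(row = (key - 1L) %/% width + 1L, col = (key - 1L) %% width + 1L)
  })
  names(components) <- NULL
  for (i in seq_along(components)) label_map[components[[i]]] <- i
  structure(list(label_map = label_map, components = components,
                 connectivity = NA_integer_, min_area = NA_integer_),
            class = "component_set")
}

#' Read or write the object CSV
#'
#' Plain comma-separated UTF-8 with a header row, `.` decimal separator.
#'
#' @param objects Tibble in the [object_table()] schema.
#' @param path File path.
#' @return `write_objects_csv` returns `path` invisibly; `read_objects_csv`
#'   returns the validated tibble.
#' @export
write_objects_csv <- function(objects, path) {
  readr::write_csv(features_table(objects), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_objects_csv
#' @export
read_objects_csv <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  features_table(tb)
}
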