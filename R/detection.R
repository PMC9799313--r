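#' Detection configuration
#'
#' Parameters of the self-tuning detector. The detector smooths the image,
#' takes the negative Laplacian response `V = |min(laplacian, 0)|`, and
#' thresholds it at a level derived from the kurtosis of `V`, so that a single
#' precision-recall intent parameter (`prc`) behaves consistently across
#' images with very different intensity distributions.
#'
#' @param pre_sigma Gaussian standard deviation (pixels) applied to the image
#'   before the Laplacian; 0 skips this stage (appropriate when the
#'   acquisition pipeline already deconvolves with the instrument PSF).
#' @param post_sigma Gaussian standard deviation (pixels) applied after the
#'   Laplacian to smooth rectilinear stencil artifacts; must be positive.
#' @param prc Precision-recall intent, positive. Values above 1 lower the
#'   adaptive threshold (favour recall); values at or below 1 raise it
#'   (favour precision).
#' @param connectivity Pixel adjacency for connected components: 4 or 8.
#' @param min_area Minimum component size in pixels; smaller components are
#'   discarded.
#' @param prune_local_maxima If `TRUE`, components that contain no local
#'   intensity maximum of the smoothed image are discarded (a heuristic that
#'   suppresses noise-induced false positives).
#' @param kurtosis_fallback `"error"` raises a domain error when the excess
#'   kurtosis of the response is negative (its fourth root is then undefined);
#'   `"clamp"` clamps the kurtosis to zero with a warning, which degenerates
#'   the threshold to the geometric mean.
#' @param kurtosis_scope `"positive"` (default) computes the kurtosis over
#'   the strictly positive response pixels -- the same population the
#'   geometric moments describe, so the threshold is a coherent statement
#'   about one distribution; `"all"` includes the exact zeros. The two
#'   scopes nearly coincide on noisy images (where the response support
#'   covers most pixels) but `"all"` inflates the scale exponent on sparse,
#'   near-noiseless images whose fourth moment is dominated by the zero
#'   fraction.
#' @param threshold_mode `"geometric"` (default) thresholds at
#'   `g_mu * g_sd^(z/prc)` with geometric mean/sd over the positive response;
#'   `"arithmetic"` uses `mean + sd * z / prc` over the positive response.
#'
#' @return A `detection_config` list.
#' @export
#' @examples
#' detection_config(prc = 4, connectivity = 4)
detection_config <- function(pre_sigma = 0,
                             post_sigma = 1,
                             prc = 2,
                             connectivity = 8L,
                             min_area = 1L,
                             prune_local_maxima = FALSE,
                             kurtosis_fallback = c("error", "clamp"),
                             kurtosis_scope = c("positive", "all"),
                             threshold_mode = c("geometric", "arithmetic")) {
  kurtosis_fallback <- match.arg(kurtosis_fallback)
  kurtosis_scope <- match.arg(kurtosis_scope)
  threshold_mode <- match.arg(threshold_mode)
  if (pre_sigma < 0 || post_sigma <= 0 || prc <= 0 || min_area < 1) {
    rlang::abort(
      "Need pre_sigma >= 0, post_sigma > 0, prc > 0, min_area >= 1.",
      class = "spotbelief_error_invalid_input")
  }
  if (!connectivity %in% c(4L, 8L)) {
    rlang::abort("`connectivity` must be 4 or 8.",
                 class = "spotbelief_error_invalid_input")
  }
  structure(
    list(pre_sigma = pre_sigma, post_sigma = post_sigma, prc = prc,
         connectivity = as.integer(connectivity),
         min_area = as.integer(min_area),
         prune_local_maxima = isTRUE(prune_local_maxima),
         kurtosis_fallback = kurtosis_fallback,
         kurtosis_scope = kurtosis_scope,
         threshold_mode = threshold_mode),
    class = "detection_config"
  )
}

#' Negative-Laplacian response map
#'
#' Computes `V = |min(G_post * laplacian(G_pre * I), 0)|`: the image is
#' optionally pre-smoothed, differentiated with the 4-neighbour Laplacian
#' stencil (mirror boundary), smoothed again, and the negative part is kept
#' as a nonnegative magnitude. Over a bell-shaped fluorescent deposit the
#' Laplacian is negative, so `V` peaks on (and outlines) such objects while
#' staying near zero over flat background.
#'
#' @param image An `image_grid` or numeric matrix.
#' @param cfg A [detection_config()].
#' @return A `response_map`: list with `values` (matrix, same shape as the
#'   image, all >= 0), and `kurtosis`, `z_score`, `threshold` slots filled in
#'   by [adaptive_threshold()] (`NA` until then).
#' @export
compute_response <- function(image, cfg = detection_config()) {
  image <- as_image_grid(image)
  sm <- gaussian_smooth(image$pixels, cfg$pre_sigma)
  lap <- laplacian4(sm)
  lap <- gaussian_smooth(lap, cfg$post_sigma)
  structure(
    list(values = pmax(-lap, 0),
         kurtosis = NA_real_, z_score = NA_real_, threshold = NA_real_),
    class = "response_map"
  )
}

#' @export
print.response_map <- function(x, ...) {
  cat(sprintf("<response_map> %d x %d, max V = %g", nrow(x$values),
              ncol(x$values), max(x$values)))
  if (!is.na(x$threshold)) {
    cat(sprintf(", kurtosis = %.4g, z = %.4g, threshold = %.4g",
                x$kurtosis, x$z_score, x$threshold))
  }
  cat("\n")
  invisible(x)
}

#' Excess kurtosis (population moments)
#'
#' Fourth standardized central moment minus 3, computed with population
#' (1/n) moments. Positive for distributions with tails heavier than the
#' normal; exactly 0 for the normal.
#'
#' @param values Numeric vector with at least 2 values and positive variance.
#' @return A single number.
#' @export
#' @examples
#' excess_kurtosis(rep(c(0, 1), 50)) # symmetric two-point mass: -2
excess_kurtosis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2 || any(!is.finite(values))) {
    rlang::abort("Need >= 2 finite values.",
                 class = "spotbelief_error_degenerate")
  }
  s <- sd_pop(values)
  if (s == 0) {
    rlang::abort("Zero variance: kurtosis undefined.",
                 class = "spotbelief_error_degenerate")
  }
  mean(((values - mean(values)) / s)^4) - 3
}

#' Kurtosis-scaled adaptive threshold
#'
#' Derives the per-image detection threshold from the response distribution
#' itself. With `k` the excess kurtosis of the response pixels (over the
#' positive support by default, see [detection_config()]) and `z = k^(1/4)`
#' -- a lower bound on the expected standardized score of the response --
#' the threshold is
#' `T = g_mu * g_sd^(z / prc)`, where `g_mu` and `g_sd` are the geometric
#' mean and geometric standard deviation of the strictly positive response
#' pixels. Multiplying the image by a constant multiplies `T` by the same
#' constant (kurtosis and `g_sd` are scale-invariant), so detections are
#' invariant to global intensity scaling.
#'
#' @param response A `response_map` from [compute_response()].
#' @param cfg A [detection_config()].
#' @return The `response_map` with `kurtosis`, `z_score` and `threshold`
#'   filled in.
#' @export
adaptive_threshold <- function(response, cfg = detection_config()) {
  stopifnot(inherits(response, "response_map"))
  v <- response$values
  pos <- v[v > 0]
  if (length(pos) == 0) {
    rlang::abort("Response has no positive pixels; nothing to threshold.",
                 class = "spotbelief_error_degenerate")
  }
  k <- excess_kurtosis(
    if (cfg$kurtosis_scope == "all") as.numeric(v) else pos)
  if (k < 0) {
    if (cfg$kurtosis_fallback == "error") {
      rlang::abort(paste0(
        "Negative excess kurtosis (", signif(k, 4), "): its fractional ",
        "power is undefined. This occurs at very low signal-to-noise; ",
        "denoise or deconvolve the image first, or set ",
        "kurtosis_fallback = \"clamp\"."),
        class = "spotbelief_error_domain")
    }
    rlang::warn(paste0("Negative excess kurtosis (", signif(k, 4),
                       ") clamped to 0; threshold falls back to the ",
                       "geometric mean of the response."))
    k <- 0
  }
  z <- k^(1 / 4)
  if (cfg$threshold_mode == "geometric") {
    lp <- log(pos)
    g_mu <- exp(mean(lp))
    g_sd <- exp(sd_pop(lp))
    thr <- g_mu * g_sd^(z / cfg$prc)
  } else {
    thr <- mean(pos) + sd_pop(pos) * z / cfg$prc
  }
  response$kurtosis <- k
  response$z_score <- z
  response$threshold <- thr
  response
}

#' Threshold a response map and label connected components
#'
#' Pixels with response strictly above the threshold form the foreground,
#' which is decomposed into connected components under the configured
#' adjacency; components smaller than `min_area` are dropped. Component ids
#' are assigned in raster-scan (row-major) order of each component's first
#' pixel, so labelling is fully deterministic.
#'
#' @param response A `response_map`.
#' @param threshold Scalar >= 0; defaults to the threshold stored on the
#'   response map.
#' @param cfg A [detection_config()].
#' @return A `component_set`: list with `label_map` (integer matrix, 0 =
#'   background) and `components` (list of two-column `(row, col)` matrices).
#' @export
binarize_and_label <- function(response, threshold = response$threshold,
                               cfg = detection_config()) {
  stopifnot(inherits(response, "response_map"))
  if (is.na(threshold) || threshold < 0) {
    rlang::abort("`threshold` must be a nonnegative number.",
                 class = "spotbelief_error_invalid_input")
  }
  mask <- response$values > threshold
  label_mask(mask, connectivity = cfg$connectivity, min_area = cfg$min_area)
}

#' Label connected components of a binary mask
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @param min_area Minimum component pixel count.
#' @return A `component_set` (see [binarize_and_label()]).
#' @export
label_mask <- function(mask, connectivity = 8L, min_area = 1L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  n <- nrow(mask)
  m <- ncol(mask)
  fg <- which(mask)
  empty <- function() {
    structure(list(label_map = matrix(0L, n, m), components = list(),
                   connectivity = as.integer(connectivity),
                   min_area = as.integer(min_area)),
              class = "component_set")
  }
  if (length(fg) == 0) return(empty())
  vid <- matrix(0L, n, m)
  vid[fg] <- seq_along(fg)

  edge_pairs <- function(dr, dc) {
    ra <- seq_len(n - abs(dr)) + max(0L, -dr)
    ca <- seq_len(m - abs(dc)) + max(0L, -dc)
    rb <- ra + dr
    cb <- ca + dc
    both <- mask[ra, ca, drop = FALSE] & mask[rb, cb, drop = FALSE]
    w <- which(both)
    if (length(w) == 0) return(NULL)
    wr <- (w - 1L) %% length(ra) + 1L
    wc <- (w - 1L) %/% length(ra) + 1L
    cbind(vid[cbind(ra[wr], ca[wc])], vid[cbind(rb[wr], cb[wc])])
  }
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) {
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  }
  edges <- do.call(rbind, lapply(shifts, function(s) edge_pairs(s[1], s[2])))
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  membership <- igraph::components(g)$membership

  rows <- (fg - 1L) %% n + 1L
  cols <- (fg - 1L) %/% n + 1L
  raster_key <- (rows - 1L) * m + cols  # row-major position
  sizes <- tabulate(membership)
  keep <- which(sizes >= min_area)
  if (length(keep) == 0) return(empty())
  first_key <- vapply(keep, function(comp) {
    min(raster_key[membership == comp])
  }, numeric(1))
  keep <- keep[order(first_key)]
  label_map <- matrix(0L, n, m)
  components <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    sel <- membership == keep[i]
    label_map[fg[sel]] <- i
    ord <- order(raster_key[sel])
    components[[i]] <- cbind(row = rows[sel][ord], col = cols[sel][ord])
  }
  structure(list(label_map = label_map, components = components,
                 connectivity = as.integer(connectivity),
                 min_area = as.integer(min_area)),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d components on a %d x %d grid (%d-connectivity)\n",
              length(x$components), nrow(x$label_map), ncol(x$label_map),
              x$connectivity))
  invisible(x)
}

#' Prune components lacking a local intensity maximum
#'
#' Retains only components containing at least one pixel that is >= all of
#' its 8 neighbours in the smoothed image. Components induced purely by
#' noise gradients or smoothing artifacts rarely contain such a peak, so
#' pruning reduces false positives without touching genuine spots, whose
#' peak pixel is always a local maximum.
#'
#' @param components A `component_set`.
#' @param smoothed_image An `image_grid` or matrix aligned with the
#'   components (typically the Gaussian-smoothed input image).
#' @return A `component_set` with surviving components relabelled
#'   consecutively in their original order.
#' @export
prune_by_local_maxima <- function(components, smoothed_image) {
  stopifnot(inherits(components, "component_set"))
  img <- as_image_grid(smoothed_image)$pixels
  if (!all(dim(img) == dim(components$label_map))) {
    rlang::abort("Image and component set have different shapes.",
                 class = "spotbelief_error_invalid_input")
  }
  if (length(components$components) == 0) return(components)
  lm <- local_maxima_mask(img)
  keep <- vapply(components$components, function(px) {
    any(lm[px])
  }, logical(1))
  relabel_components(components, keep)
}

relabel_components <- function(components, keep) {
  label_map <- matrix(0L, nrow(components$label_map),
                      ncol(components$label_map))
  kept <- components$components[keep]
  for (i in seq_along(kept)) {
    label_map[kept[[i]]] <- i
  }
  structure(list(label_map = label_map, components = kept,
                 connectivity = components$connectivity,
                 min_area = components$min_area),
            class = "component_set")
}

#' Self-tuning object detection
#'
#' Full detection pipeline: negative-Laplacian response, kurtosis-scaled
#' adaptive threshold, connected-component labelling, and optional
#' local-maxima pruning. Deterministic: identical input and configuration
#' give a bit-identical label map.
#'
#' @param image An `image_grid` or numeric matrix.
#' @param cfg A [detection_config()].
#' @return A `component_set` carrying the diagnostics `kurtosis`, `z_score`
#'   and `threshold` as attributes.
#' @export
#' @examples
#' sim <- simulate_image(simulation_config(
#'   height = 128, width = 128, n_bright = 4, n_dim = 0,
#'   gauss_sigma_frac = 0, poisson_lambda_frac = 0,
#'   min_separation = 30, seed = 7))
#' det <- detect_objects(sim$image, detection_config(prc = 2))
#' length(det$components)
detect_objects <- function(image, cfg = detection_config()) {
  image <- as_image_grid(image)
  response <- compute_response(image, cfg)
  response <- adaptive_threshold(response, cfg)
  comp <- binarize_and_label(response, response$threshold, cfg)
  if (cfg$prune_local_maxima) {
    sm <- gaussian_smooth(gaussian_smooth(image$pixels, cfg$pre_sigma),
                          cfg$post_sigma)
    comp <- prune_by_local_maxima(comp, sm)
  }
  attr(comp, "kurtosis") <- response$kurtosis
  attr(comp, "z_score") <- response$z_score
  attr(comp, "threshold") <- response$threshold
  comp
}
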