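#' Synthetic image configuration
#'
#' Describes one synthetic fluorescence image: randomly placed point sources
#' rendered with a generalized-normal profile
#' `amplitude * exp(-(d / alpha)^beta)` (with `alpha = sigma * sqrt(2)`, so
#' `beta = 2` is exactly a Gaussian PSF of the given sigma), in two
#' populations -- bright (PSF sigma 3) and dim (sigma 6 with peak intensity
#' divided by 4) -- over additive Gaussian and Poisson noise expressed as
#' fractions of the 8-bit dynamic range. Defaults reproduce the in-silico
#' validation conditions: 512x512 images, noise fractions 0.062, a balanced
#' 25 + 25 mixture, bright peak amplitude 200 (near-saturated on the 8-bit
#' scale, a typical well-exposed acquisition).
#'
#' @param height,width Image size in pixels.
#' @param n_bright,n_dim Counts of bright and dim sources.
#' @param sigma_bright,sigma_dim PSF standard deviations in pixels.
#' @param amplitude Peak intensity of bright sources (8-bit scale).
#' @param dim_factor Peak-intensity divisor for dim sources.
#' @param gauss_sigma_frac Gaussian noise standard deviation as a fraction
#'   of 255.
#' @param poisson_lambda_frac Poisson background mean as a fraction of 255.
#' @param noise_mode `"additive"` (independent background counts, default)
#'   or `"shot"` (signal-dependent Poisson resampling of signal plus
#'   background).
#' @param min_separation Minimum distance between source centers in pixels
#'   (0 = unconstrained placement).
#' @param beta Generalized-normal shape in `[1, 3]`; 2 = Gaussian.
#' @param seed RNG seed; fixes the image bit-for-bit.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(height = 512L, width = 512L,
                              n_bright = 25L, n_dim = 25L,
                              sigma_bright = 3, sigma_dim = 6,
                              amplitude = 200, dim_factor = 4,
                              gauss_sigma_frac = 0.062,
                              poisson_lambda_frac = 0.062,
                              noise_mode = c("additive", "shot"),
                              min_separation = 0,
                              beta = 2, seed = 1L) {
  noise_mode <- match.arg(noise_mode)
  if (n_bright < 0 || n_dim < 0 || sigma_bright <= 0 || sigma_dim <= 0 ||
      amplitude <= 0 || dim_factor <= 0 ||
      gauss_sigma_frac < 0 || poisson_lambda_frac < 0 ||
      min_separation < 0 || beta < 1 || beta > 3) {
    rlang::abort("Invalid simulation parameters.",
                 class = "spotbelief_error_invalid_input")
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         n_bright = as.integer(n_bright), n_dim = as.integer(n_dim),
         sigma_bright = sigma_bright, sigma_dim = sigma_dim,
         amplitude = amplitude, dim_factor = dim_factor,
         gauss_sigma_frac = gauss_sigma_frac,
         poisson_lambda_frac = poisson_lambda_frac,
         noise_mode = noise_mode,
         min_separation = min_separation, beta = beta,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# contribution of one source over the whole grid
render_source <- function(height, width, row, col, sigma, amplitude, beta) {
  alpha <- sigma * sqrt(2)
  dr2 <- (seq_len(height) - row)^2
  dc2 <- (seq_len(width) - col)^2
  d <- sqrt(outer(dr2, dc2, `+`))
  amplitude * exp(-(d / alpha)^beta)
}

place_sources <- function(n, height, width, min_separation,
                          existing = NULL, max_attempts = 1e4) {
  placed <- existing
  out <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  while (nrow(out) < n) {
    cand <- c(stats::runif(1, 1, height), stats::runif(1, 1, width))
    ok <- TRUE
    if (min_separation > 0 && !is.null(placed) && nrow(placed) > 0) {
      ok <- all(sqrt((placed[, 1] - cand[1])^2 +
                     (placed[, 2] - cand[2])^2) >= min_separation)
    }
    if (ok) {
      out <- rbind(out, cand)
      placed <- rbind(placed, cand)
    }
    attempts <- attempts + 1L
    if (attempts >= max_attempts && nrow(out) < n) {
      rlang::abort(paste0(
        "Could not place all sources after ", max_attempts,
        " attempts; reduce the source count or min_separation."),
        class = "spotbelief_error_invalid_input")
    }
  }
  unname(out)
}

#' Simulate a synthetic fluorescence image with ground truth
#'
#' Places the configured bright and dim sources uniformly at random
#' (rejection-sampled to respect `min_separation`), renders each with its
#' generalized-normal profile, sums the contributions, applies the noise
#' model, clips to `[0, 255]` and quantizes to integer gray levels -- the
#' image an 8-bit detector actually records, in which PSF tails below half
#' a gray level vanish exactly as they do in real acquisitions.
#' Deterministic for a fixed seed; the caller's RNG state is left
#' untouched.
#'
#' @param cfg A [simulation_config()].
#' @return List with `image` (an `image_grid`) and `truth`: a list with
#'   `sources` (tibble: `source`, `row`, `col`, `sigma`, `amplitude`,
#'   `population`) and `footprints` (per-source pixel matrices where that
#'   source's noiseless contribution is at least half its peak).
#' @export
simulate_image <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(cfg$seed)

  centers <- place_sources(cfg$n_bright + cfg$n_dim, cfg$height, cfg$width,
                           cfg$min_separation)
  n_total <- cfg$n_bright + cfg$n_dim
  pop <- rep(c("bright", "dim"), c(cfg$n_bright, cfg$n_dim))
  sigma <- ifelse(pop == "bright", cfg$sigma_bright, cfg$sigma_dim)
  amp <- ifelse(pop == "bright", cfg$amplitude,
                cfg$amplitude / cfg$dim_factor)

  img <- matrix(0, cfg$height, cfg$width)
  footprints <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    contrib <- render_source(cfg$height, cfg$width, centers[i, 1],
                             centers[i, 2], sigma[i], amp[i], cfg$beta)
    img <- img + contrib
    fp <- which(contrib >= amp[i] / 2, arr.ind = TRUE)
    colnames(fp) <- c("row", "col")
    footprints[[i]] <- fp
  }
  img <- add_noise(img, cfg$gauss_sigma_frac, cfg$poisson_lambda_frac,
                   mode = cfg$noise_mode)
  img <- round(pmin(pmax(img, 0), 255))

  truth <- list(
    sources = tibble::tibble(
      source = seq_len(n_total),
      row = centers[, 1], col = centers[, 2],
      sigma = sigma, amplitude = amp, population = pop),
    footprints = footprints
  )
  list(image = image_grid(img, bit_depth = 8L), truth = truth)
}

#' Add Gaussian and Poisson noise
#'
#' In `"additive"` mode (the default) each pixel receives independent
#' Gaussian noise with standard deviation `gauss_sigma_frac * 255` plus an
#' independent Poisson background count with mean
#' `poisson_lambda_frac * 255`. In `"shot"` mode the Poisson component is
#' signal-dependent: the pixel value plus background mean is Poisson
#' resampled. The result is clipped to `[0, 255]`.
#'
#' @param image An `image_grid` or numeric matrix.
#' @param gauss_sigma_frac,poisson_lambda_frac Noise parameters as fractions
#'   of the 8-bit dynamic range.
#' @param mode `"additive"` or `"shot"`.
#' @return A numeric matrix (or `image_grid` when given one) clipped to
#'   `[0, 255]`.
#' @export
add_noise <- function(image, gauss_sigma_frac, poisson_lambda_frac,
                      mode = c("additive", "shot")) {
  mode <- match.arg(mode)
  if (gauss_sigma_frac < 0 || poisson_lambda_frac < 0) {
    rlang::abort("Noise fractions must be >= 0.",
                 class = "spotbelief_error_invalid_input")
  }
  was_grid <- inherits(image, "image_grid")
  px <- if (was_grid) image$pixels else image
  n <- length(px)
  if (mode == "shot") {
    px <- matrix(stats::rpois(n, px + poisson_lambda_frac * 255),
                 nrow(px), ncol(px))
  } else if (poisson_lambda_frac > 0) {
    px <- px + stats::rpois(n, poisson_lambda_frac * 255)
  }
  if (gauss_sigma_frac > 0) {
    px <- px + stats::rnorm(n, 0, gauss_sigma_frac * 255)
  }
  px <- pmin(pmax(px, 0), 255)
  if (was_grid) image_grid(px, bit_depth = image$bit_depth) else px
}

#' Match detected components against simulated ground truth
#'
#' A source counts as recovered when at least one pixel of its half-maximum
#' footprint overlaps a detected component. Assignment is greedy one-to-one
#' by descending overlap, ties broken by lower component id then lower
#' source index. Unmatched components are false positives, unmatched sources
#' false negatives.
#'
#' @param components A `component_set`.
#' @param truth Ground truth from [simulate_image()].
#' @return A `match_result` list: `tp`, `fp`, `fn`, `precision` (1 when
#'   there are no detections), `recall`, and `matches` (tibble `source`,
#'   `component`, `overlap`).
#' @export
match_objects <- function(components, truth) {
  stopifnot(inherits(components, "component_set"))
  n_sources <- nrow(truth$sources)
  n_comp <- length(components$components)
  lm <- components$label_map
  cand <- purrr::imap(truth$footprints, function(fp, i) {
    labs <- lm[fp]
    labs <- labs[labs > 0]
    if (length(labs) == 0) return(NULL)
    tab <- table(labs)
    tibble::tibble(source = i,
                   component = as.integer(names(tab)),
                   overlap = as.integer(tab))
  })
  cand <- dplyr::bind_rows(cand)
  matches <- tibble::tibble(source = integer(), component = integer(),
                            overlap = integer())
  if (nrow(cand) > 0) {
    cand <- dplyr::arrange(cand, dplyr::desc(.data$overlap),
                           .data$component, .data$source)
    used_s <- logical(n_sources)
    used_c <- logical(n_comp)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      s <- cand$source[i]
      co <- cand$component[i]
      if (!used_s[s] && !used_c[co]) {
        used_s[s] <- TRUE
        used_c[co] <- TRUE
        keep[i] <- TRUE
      }
    }
    matches <- cand[keep, ]
  }
  tp <- nrow(matches)
  fp <- n_comp - tp
  fn <- n_sources - tp
  structure(
    list(tp = tp, fp = fp, fn = fn,
         precision = if (n_comp == 0) 1 else tp / (tp + fp),
         recall = if (n_sources == 0) 1 else tp / (tp + fn),
         matches = matches),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> tp %d, fp %d, fn %d; precision %.3f, recall %.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall))
  invisible(x)
}

#' Per-population recall of a match result
#'
#' @param match A `match_result`.
#' @param truth The ground truth it was computed from.
#' @return Tibble with `population`, `n_sources`, `recall`.
#' @export
recall_by_population <- function(match, truth) {
  truth$sources |>
    dplyr::mutate(matched = .data$source %in% match$matches$source) |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(n_sources = dplyr::n(),
                     recall = mean(.data$matched), .groups = "drop")
}

#' Fixed absolute-threshold detector
#'
#' A baseline detector applying one frozen threshold to the response map of
#' every image -- the non-adaptive strategy the self-tuning detector is
#' compared against. Returns a function usable as the `detector` argument of
#' [consistency_experiment()].
#'
#' @param threshold Absolute threshold on the response `V`.
#' @param cfg A [detection_config()] supplying smoothing and connectivity.
#' @return `function(image) -> component_set`.
#' @export
fixed_threshold_detector <- function(threshold, cfg = detection_config()) {
  force(threshold)
  force(cfg)
  function(image) {
    response <- compute_response(image, cfg)
    binarize_and_label(response, threshold, cfg)
  }
}

#' Calibrate a fixed absolute threshold on ground truth
#'
#' Tunes the non-adaptive baseline the way a practitioner with ground truth
#' on one dataset would: scan a logarithmic threshold grid, score each
#' candidate by mean F1 over the calibration images, and return the
#' geometric midpoint of the optimal plateau (with perfect detection a wide
#' range of thresholds ties at F1 = 1, and nothing on the calibration data
#' distinguishes them).
#'
#' @param sims List of [simulate_image()] results used for calibration.
#' @param cfg A [detection_config()] supplying smoothing and connectivity.
#' @param grid Candidate thresholds (default 60 log-spaced values spanning
#'   the positive response range of the first image).
#' @return List with `threshold`, `f1` (its calibration score) and `grid`
#'   (tibble of all candidates and scores).
#' @export
calibrate_fixed_threshold <- function(sims, cfg = detection_config(),
                                      grid = NULL) {
  responses <- purrr::map(sims, function(s) compute_response(s$image, cfg))
  if (is.null(grid)) {
    pos <- responses[[1]]$values[responses[[1]]$values > 0]
    grid <- exp(seq(log(stats::quantile(pos, 0.5)), log(max(pos)),
                    length.out = 60))
  }
  f1 <- vapply(grid, function(th) {
    mean(purrr::map2_dbl(responses, sims, function(r, s) {
      m <- match_objects(binarize_and_label(r, th, cfg), s$truth)
      if (m$tp == 0) 0 else 2 * m$precision * m$recall /
        (m$precision + m$recall)
    }))
  }, numeric(1))
  best <- which(f1 >= max(f1) - 1e-12)
  thr <- exp((log(grid[min(best)]) + log(grid[max(best)])) / 2)
  list(threshold = thr, f1 = max(f1),
       grid = tibble::tibble(threshold = grid, f1 = f1))
}

#' Detection-consistency experiment across source mixtures
#'
#' Simulates the three-scenario grid -- images dominated by dim sources, a
#' balanced mixture, and images dominated by bright sources -- detects, and
#' matches against ground truth. The across-scenario range of mean recall is
#' the consistency statistic: a detector that translates the same intent
#' across very different intensity distributions should have a small range.
#'
#' @param prc Precision-recall intent of the adaptive detector (ignored when
#'   `detector` is supplied).
#' @param scenarios List of `c(n_bright, n_dim)` pairs.
#' @param seeds Integer vector; each scenario is simulated once per seed.
#' @param base_cfg A [simulation_config()] providing all other simulation
#'   parameters.
#' @param det_cfg A [detection_config()] for the adaptive detector.
#' @param detector Optional `function(image) -> component_set` overriding the
#'   adaptive detector (e.g. [fixed_threshold_detector()]).
#' @return Tibble with one row per scenario (`n_bright`, `n_dim`,
#'   `mean_precision`, `mean_recall`, `n_runs`) and attribute
#'   `recall_range`: `max(mean_recall) - min(mean_recall)`.
#' @export
consistency_experiment <- function(prc = 2,
                                   scenarios = list(c(1L, 50L), c(25L, 25L),
                                                    c(50L, 1L)),
                                   seeds = 1:10,
                                   base_cfg = simulation_config(),
                                   det_cfg = NULL,
                                   detector = NULL) {
  if (is.null(det_cfg)) det_cfg <- detection_config(prc = prc)
  if (is.null(detector)) {
    detector <- function(image) detect_objects(image, det_cfg)
  }
  rows <- purrr::map(scenarios, function(sc) {
    res <- purrr::map(seeds, function(sd) {
      cfg <- base_cfg
      cfg$n_bright <- as.integer(sc[1])
      cfg$n_dim <- as.integer(sc[2])
      cfg$seed <- as.integer(sd)
      sim <- simulate_image(cfg)
      match_objects(detector(sim$image), sim$truth)
    })
    tibble::tibble(
      n_bright = as.integer(sc[1]), n_dim = as.integer(sc[2]),
      mean_precision = mean(purrr::map_dbl(res, "precision")),
      mean_recall = mean(purrr::map_dbl(res, "recall")),
      n_runs = length(seeds))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "recall_range") <- diff(range(out$mean_recall))
  out
}

#' Noise-robustness experiment
#'
#' Sweeps the Gaussian/Poisson noise level over a mixture of bright and dim
#' sources and reports recall (overall and for the dim population) at each
#' level, averaged over seeds.
#'
#' @param noise_fracs Numeric vector of noise fractions applied to both the
#'   Gaussian sigma and Poisson lambda.
#' @param seeds Integer vector of simulation seeds.
#' @param base_cfg A [simulation_config()].
#' @param det_cfg A [detection_config()].
#' @return Tibble with `noise_frac`, `mean_recall`, `mean_recall_dim`,
#'   `mean_precision`, `n_runs`.
#' @export
noise_robustness_experiment <- function(noise_fracs = c(16, 64, 96) / 255,
                                        seeds = 1:10,
                                        base_cfg = simulation_config(),
                                        det_cfg = detection_config()) {
  rows <- purrr::map(noise_fracs, function(nf) {
    res <- purrr::map(seeds, function(sd) {
      cfg <- base_cfg
      cfg$gauss_sigma_frac <- nf
      cfg$poisson_lambda_frac <- nf
      cfg$seed <- as.integer(sd)
      sim <- simulate_image(cfg)
      m <- match_objects(detect_objects(sim$image, det_cfg), sim$truth)
      byp <- recall_by_population(m, sim$truth)
      dim_recall <- byp$recall[byp$population == "dim"]
      list(recall = m$recall, precision = m$precision,
           recall_dim = if (length(dim_recall)) dim_recall else NA_real_)
    })
    tibble::tibble(
      noise_frac = nf,
      mean_recall = mean(purrr::map_dbl(res, "recall")),
      mean_recall_dim = mean(purrr::map_dbl(res, "recall_dim")),
      mean_precision = mean(purrr::map_dbl(res, "precision")),
      n_runs = length(seeds))
  })
  dplyr::bind_rows(rows)
}
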