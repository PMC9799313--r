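canonical_features <- c("intensity_sum", "area", "laplacian_sum")

feature_matrix <- function(features, feature_names = NULL) {
  if (is.data.frame(features)) {
    if (is.null(feature_names)) {
      feature_names <- if (all(canonical_features %in% names(features))) {
        canonical_features
      } else {
        names(features)[vapply(features, is.numeric, logical(1))]
      }
    }
    features <- as.matrix(features[, feature_names, drop = FALSE])
  } else {
    features <- as.matrix(features)
    if (is.null(feature_names)) {
      feature_names <- colnames(features) %||%
        paste0("f", seq_len(ncol(features)))
    }
    colnames(features) <- feature_names
  }
  storage.mode(features) <- "double"
  features
}

#' Fit a reference model for one label
#'
#' Estimates the mean vector and sample covariance of the feature descriptors
#' of a labelled object population. This distribution is the evidence source
#' for the label: new objects are scored by their Mahalanobis distance to it.
#' Near-singular covariances (condition number above `cond_threshold`) are
#' stabilized with a small recorded ridge so the distance stays defined.
#'
#' @param features Feature matrix or data frame (defaults to the canonical
#'   `intensity_sum`, `area`, `laplacian_sum` columns when present; extra
#'   columns are ignored).
#' @param label Label name the model provides evidence for.
#' @param feature_names Optional explicit feature column selection.
#' @param cond_threshold Condition number above which the ridge is applied.
#' @return A `reference_model`: list with `label`, `mean`, `covariance`,
#'   `ridge`, `n_objects`, `condition_number`, `feature_names`.
#' @export
#' @examples
#' x <- cbind(a = c(0, 1, 0, 1), b = c(0, 0, 1, 1))
#' fit_reference_model(x, "demo")
fit_reference_model <- function(features, label,
                                feature_names = NULL,
                                cond_threshold = 1e12) {
  x <- feature_matrix(features, feature_names)
  n <- nrow(x)
  d <- ncol(x)
  if (any(!is.finite(x))) {
    rlang::abort("Non-finite feature values.",
                 class = "spotbelief_error_invalid_input")
  }
  if (n < d + 1) {
    rlang::abort(sprintf(
      "Need at least %d objects to fit a %d-feature model (got %d).",
      d + 1, d, n), class = "spotbelief_error_degenerate")
  }
  vars <- apply(x, 2, stats::var)
  if (any(vars == 0)) {
    bad <- colnames(x)[vars == 0]
    rlang::abort(paste0("Zero-variance feature(s): ",
                        paste(bad, collapse = ", "),
                        ". The covariance is singular in these directions."),
                 class = "spotbelief_error_degenerate")
  }
  mu <- colMeans(x)
  sigma <- stats::cov(x)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  cond <- if (min(ev) <= 0) Inf else max(ev) / min(ev)
  ridge <- 0
  if (cond > cond_threshold) {
    ridge <- 1e-9 * sum(diag(sigma)) / d
  }
  structure(
    list(label = label, mean = mu, covariance = sigma, ridge = ridge,
         n_objects = n, condition_number = cond,
         feature_names = colnames(x)),
    class = "reference_model"
  )
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("<reference_model> label '%s': %d objects, %d features (%s)%s\n",
              x$label, x$n_objects, length(x$mean),
              paste(x$feature_names, collapse = ", "),
              if (x$ridge > 0) sprintf(", ridge %.3g", x$ridge) else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reference model
#'
#' @param x A `reference_model`.
#' @param ... Unused.
#' @return One row per feature with its mean and standard deviation.
#' @export
tidy.reference_model <- function(x, ...) {
  tibble::tibble(
    feature = x$feature_names,
    mean = unname(x$mean),
    sd = sqrt(diag(x$covariance))
  )
}

#' One-row model summary
#'
#' @param x A `reference_model`.
#' @param ... Unused.
#' @return Tibble with label, n, dimensionality, ridge, condition number.
#' @export
glance.reference_model <- function(x, ...) {
  tibble::tibble(
    label = x$label, n_objects = x$n_objects,
    n_features = length(x$mean), ridge = x$ridge,
    condition_number = x$condition_number
  )
}

regularized_cov <- function(model) {
  model$covariance + diag(model$ridge, length(model$mean))
}

#' Mahalanobis distance to a reference model
#'
#' `sqrt((x - mu)' (Sigma + ridge I)^-1 (x - mu))`: the statistical distance
#' accounting for feature covariance.
#'
#' @param x Numeric vector, matrix, or data frame of feature rows.
#' @param model A `reference_model`.
#' @return Numeric vector of nonnegative distances, one per row of `x`.
#' @export
mahalanobis_distance <- function(x, model) {
  stopifnot(inherits(model, "reference_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- feature_matrix(x, if (is.data.frame(x)) model$feature_names else NULL)
  if (ncol(x) != length(model$mean)) {
    rlang::abort(sprintf(
      "Feature dimension %d does not match the model's %d.",
      ncol(x), length(model$mean)),
      class = "spotbelief_error_invalid_input")
  }
  sqrt(stats::mahalanobis(x, model$mean, regularized_cov(model)))
}

#' Standardize distances within an image
#'
#' Centers and scales (population standard deviation) the Mahalanobis
#' distances of one image's objects. When only one object exists or all
#' distances coincide, all z-scores are set to 0 with a warning.
#'
#' @param distances Numeric vector of distances from one image.
#' @return Numeric vector of z-scores.
#' @export
z_normalize <- function(distances) {
  if (length(distances) == 0) return(numeric(0))
  if (length(distances) == 1) {
    rlang::warn("Single object: z-score set to 0.")
    return(0)
  }
  s <- sd_pop(distances)
  if (s == 0) {
    rlang::warn("All distances identical: z-scores set to 0.")
    return(rep(0, length(distances)))
  }
  (distances - mean(distances)) / s
}

#' Cantelli plausibility
#'
#' Converts a standardized distance into a plausibility via the one-sided
#' Chebyshev (Cantelli) tail bound `Pr(Z >= z) <= 1 / (1 + z^2)`: the
#' theoretical upper limit on the probability that an object this far from a
#' reference population still belongs to it. Two conventions are offered:
#' `"literal"` squares z as given (below-mean objects are also discounted);
#' `"one-sided"` clamps negative z to 0 first, so any object at or below the
#' mean distance gets plausibility 1 (Cantelli only bounds the upper tail).
#'
#' @param z Numeric vector of z-scores.
#' @param convention `"literal"` or `"one-sided"`.
#' @return Plausibilities in `(0, 1]`.
#' @export
#' @examples
#' cantelli_plausibility(c(0, 1, 3)) # 1, 0.5, 0.1
cantelli_plausibility <- function(z, convention = c("literal", "one-sided")) {
  convention <- match.arg(convention)
  if (any(!is.finite(z))) {
    rlang::abort("Non-finite z-score.",
                 class = "spotbelief_error_invalid_input")
  }
  if (convention == "one-sided") z <- pmax(z, 0)
  1 / (1 + z^2)
}

#' Score objects against a reference model
#'
#' Per image: Mahalanobis distances to the model, within-image
#' standardization, and conversion to plausibility through Cantelli's bound.
#'
#' @param objects Tibble with `image_id`, `object_id` and the model's feature
#'   columns (an [object_table()] works directly).
#' @param model A `reference_model`.
#' @param z_scope `"image"` (standardize within each image, the default) or
#'   `"dataset"` (pool all images).
#' @param convention Passed to [cantelli_plausibility()].
#' @return The input tibble with columns `label`, `mahalanobis`, `z`, `pl`
#'   appended.
#' @export
assign_plausibility <- function(objects, model,
                                z_scope = c("image", "dataset"),
                                convention = c("literal", "one-sided")) {
  z_scope <- match.arg(z_scope)
  convention <- match.arg(convention)
  objects <- tibble::as_tibble(objects)
  d <- mahalanobis_distance(
    objects[, model$feature_names, drop = FALSE], model)
  objects$label <- model$label
  objects$mahalanobis <- d
  if (z_scope == "dataset") {
    objects$z <- z_normalize(d)
  } else {
    objects <- objects |>
      dplyr::group_by(.data$image_id) |>
      dplyr::mutate(z = z_normalize(.data$mahalanobis)) |>
      dplyr::ungroup()
  }
  objects$pl <- cantelli_plausibility(objects$z, convention)
  objects
}

#' Belief triplet from a pair of swapped-model plausibilities
#'
#' For label `L_J`, plausibility comes from the model of the `J` population
#' (`q_j`), while belief comes from the swapped model (`q_i`, the
#' plausibility of the object under its own population's model):
#' `Bel = 1 - q_i` since belief in a proposition equals one minus the
#' plausibility of its complement. The triplet is `(p, q, r)` with
#' `p = 1 - q_i` (belief for), `q = 1 - q_j` (belief against), and
#' `r = Pl - Bel` (uncertainty). When `q_i + q_j < 1` the raw `r` would be
#' negative -- a case the bidirectional construction does not forbid -- so
#' `r` is clamped to 0, `p` is capped at the plausibility, and `clamped` is
#' flagged.
#'
#' @param q_j Plausibility of the object under the label's model, in `[0,1]`.
#' @param q_i Plausibility under the swapped model, in `[0,1]`. Vectors are
#'   recycled in the usual way.
#' @return Tibble with columns `p`, `q`, `r`, `clamped`; `p + q + r` is 1 by
#'   construction and `p <= 1 - q` always.
#' @export
#' @examples
#' bidirectional_triplet(0.9, 0.2) # p 0.8, q 0.1, r 0.1
bidirectional_triplet <- function(q_j, q_i) {
  if (any(q_j < 0 | q_j > 1 | q_i < 0 | q_i > 1, na.rm = TRUE) ||
      any(!is.finite(c(q_j, q_i)))) {
    rlang::abort("Plausibilities must lie in [0, 1].",
                 class = "spotbelief_error_invalid_input")
  }
  pl <- q_j
  p <- 1 - q_i
  r <- pl - p
  clamped <- r < 0
  p[clamped] <- pl[clamped]
  r[clamped] <- 0
  tibble::tibble(p = p, q = 1 - pl, r = r, clamped = clamped)
}

#' Nested-label plausibility subtraction
#'
#' The plausibility that an object carries a label unique to a superset
#' population (e.g. scaffold = PC3 minus background) is the superset
#' plausibility minus the subset plausibility, floored at zero so outliers
#' with `q_super < q_sub` receive exactly 0 rather than negative support.
#'
#' @param q_super,q_sub Plausibilities in `[0, 1]` (vectorized).
#' @return `max(q_super - q_sub, 0)` elementwise.
#' @export
subtract_plausibility <- function(q_super, q_sub) {
  if (any(c(q_super, q_sub) < 0 | c(q_super, q_sub) > 1) ||
      any(!is.finite(c(q_super, q_sub)))) {
    rlang::abort("Plausibilities must lie in [0, 1].",
                 class = "spotbelief_error_invalid_input")
  }
  pmax(q_super - q_sub, 0)
}

#' Belief that an object belongs to none of a set of labels
#'
#' The belief that an object is unique to the most specific population --
#' e.g. a caveola, an object in neither the background nor the scaffold
#' class -- is the product of the complements of the excluded labels'
#' plausibilities: `prod(1 - q_i)`.
#'
#' @param qs Numeric vector of plausibilities of the excluded labels.
#' @return A single belief in `[0, 1]`.
#' @export
unique_label_belief <- function(qs) {
  if (length(qs) == 0) {
    rlang::warn("No excluded labels: unique-label belief is vacuously 1.")
    return(1)
  }
  if (any(qs < 0 | qs > 1) || any(!is.finite(qs))) {
    rlang::abort("Plausibilities must lie in [0, 1].",
                 class = "spotbelief_error_invalid_input")
  }
  prod(1 - qs)
}

#' Label objects with a reference model
#'
#' Scores target objects against `model` and emits the full labelled table
#' including belief triplets. With a `swap_model` (a model fitted on the
#' targets' own population) belief is `1 - pl_swap`; without one, belief
#' falls back to the vacuous lower bound 0, leaving all support as
#' uncertainty.
#'
#' @param objects Target [object_table()].
#' @param model Reference model providing the label's plausibility.
#' @param swap_model Optional reference model of the targets' own population.
#' @inheritParams assign_plausibility
#' @return Labelled tibble with columns `image_id`, `object_id`, `label`,
#'   `mahalanobis`, `z`, `pl`, `p`, `q`, `r`, `clamped`.
#' @export
label_objects <- function(objects, model, swap_model = NULL,
                          z_scope = c("image", "dataset"),
                          convention = c("literal", "one-sided")) {
  scored <- assign_plausibility(objects, model, z_scope, convention)
  if (is.null(swap_model)) {
    trip <- tibble::tibble(p = 0, q = 1 - scored$pl, r = scored$pl,
                           clamped = FALSE)
  } else {
    swap <- assign_plausibility(objects, swap_model, z_scope, convention)
    trip <- bidirectional_triplet(scored$pl, swap$pl)
  }
  dplyr::bind_cols(
    scored[, c("image_id", "object_id", "label", "mahalanobis", "z", "pl")],
    trip)
}

#' Save or load a reference model as JSON
#'
#' The file stores the label, feature names, mean, covariance, ridge, object
#' count and package version, so labelling is reproducible without the
#' reference images.
#'
#' @param model A `reference_model`.
#' @param path File path.
#' @return `write_reference_model` returns `path` invisibly;
#'   `read_reference_model` returns the `reference_model`.
#' @export
write_reference_model <- function(model, path) {
  stopifnot(inherits(model, "reference_model"))
  obj <- list(
    label = model$label,
    feature_names = model$feature_names,
    mean = unname(model$mean),
    covariance = unname(model$covariance),
    ridge = model$ridge,
    n_objects = model$n_objects,
    condition_number = model$condition_number,
    spotbelief_version = as.character(utils::packageVersion("spotbelief"))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference_model
#' @export
read_reference_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mu <- as.numeric(obj$mean)
  names(mu) <- obj$feature_names
  sigma <- matrix(as.numeric(obj$covariance), length(mu), length(mu))
  dimnames(sigma) <- list(obj$feature_names, obj$feature_names)
  structure(
    list(label = obj$label, mean = mu, covariance = sigma,
         ridge = obj$ridge, n_objects = obj$n_objects,
         condition_number = obj$condition_number,
         feature_names = obj$feature_names),
    class = "reference_model"
  )
}

#' Read or write a labelled object CSV
#'
#' @param labelled Tibble from [label_objects()].
#' @param path File path.
#' @return `write_labelled_csv` returns `path` invisibly; `read_labelled_csv`
#'   the tibble.
#' @export
write_labelled_csv <- function(labelled, path) {
  readr::write_csv(labelled, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_labelled_csv
#' @export
read_labelled_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
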