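#' Dempster's combination of two singleton masses
#'
#' Fuses two independent sources' masses `t` and `s` for the same singleton
#' proposition (object carries label). The conflict is
#' `kappa = (1 - s) t + (1 - t) s` (the probability mass falling on empty
#' intersections), the joint mass is `m = t s / (1 - kappa)`, and the weight
#' of conflict is `W = -log(1 - kappa)`. When the sources are in complete
#' contradiction -- `(t, s)` equal to `(0, 1)` or `(1, 0)` -- combination is
#' meaningless: the pair is flagged `contradictory` with `W = Inf` and an
#' undefined (`NA`) joint mass, rather than raising an error, so batch
#' fusion completes and the sanity check surfaces in the output.
#'
#' @param t,s Masses in `[0, 1]` (vectorized, recycled).
#' @param log_base `"e"` (natural log, default) or `"2"` for the conflict
#'   weight.
#' @return Tibble with columns `mass_a`, `mass_b`, `joint_mass`, `conflict`,
#'   `conflict_weight`, `contradictory`.
#' @export
#' @examples
#' dempster_combine(0.5, 0.8) # a maximally uncertain source is neutral
dempster_combine <- function(t, s, log_base = c("e", "2")) {
  log_base <- match.arg(log_base)
  if (any(!is.finite(c(t, s))) || any(c(t, s) < 0 | c(t, s) > 1)) {
    rlang::abort("Masses must lie in [0, 1].",
                 class = "spotbelief_error_invalid_input")
  }
  n <- max(length(t), length(s))
  t <- rep_len(t, n)
  s <- rep_len(s, n)
  contradictory <- (t == 0 & s == 1) | (t == 1 & s == 0)
  kappa <- (1 - s) * t + (1 - t) * s
  m <- ifelse(contradictory, NA_real_, t * s / (1 - kappa))
  w <- ifelse(contradictory, Inf, -log(1 - kappa))
  if (log_base == "2") w <- w / log(2)
  w[w == 0] <- 0  # normalize -0 from kappa = 0
  tibble::tibble(mass_a = t, mass_b = s, joint_mass = m, conflict = kappa,
                 conflict_weight = w, contradictory = contradictory)
}

#' Fuse two labelled object tables
#'
#' Inner-joins two labelled tables on the object key and combines their
#' per-object beliefs with Dempster's rule. Because the propositions are
#' singleton focal elements, each table's belief `p` equals its mass for the
#' proposition and feeds the combination directly.
#'
#' @param table_a,table_b Labelled tibbles (see [label_objects()]) covering
#'   the same objects for the same label.
#' @param mass_col Column carrying the per-object mass (default `"p"`).
#' @param by Join key columns.
#' @param log_base Passed to [dempster_combine()].
#' @return Tibble with the key columns plus `mass_a`, `mass_b`, `joint_mass`,
#'   `conflict`, `conflict_weight`, `contradictory`.
#' @export
combine_labelled_tables <- function(table_a, table_b, mass_col = "p",
                                    by = c("image_id", "object_id"),
                                    log_base = c("e", "2")) {
  table_a <- tibble::as_tibble(table_a)
  table_b <- tibble::as_tibble(table_b)
  ka <- table_a[, by, drop = FALSE]
  kb <- table_b[, by, drop = FALSE]
  only_a <- dplyr::anti_join(ka, kb, by = by)
  only_b <- dplyr::anti_join(kb, ka, by = by)
  if (nrow(only_a) + nrow(only_b) > 0) {
    miss <- dplyr::bind_rows(only_a, only_b)
    rlang::abort(paste0(
      "Tables label different objects; unmatched keys: ",
      paste(apply(miss, 1, paste, collapse = "/"), collapse = ", ")),
      class = "spotbelief_error_invalid_input")
  }
  joined <- dplyr::inner_join(
    dplyr::select(table_a, dplyr::all_of(by), .a = dplyr::all_of(mass_col)),
    dplyr::select(table_b, dplyr::all_of(by), .b = dplyr::all_of(mass_col)),
    by = by)
  dplyr::bind_cols(
    joined[, by, drop = FALSE],
    dempster_combine(joined$.a, joined$.b, log_base = log_base))
}
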