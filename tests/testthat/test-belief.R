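test_that("reference model matches hand-computed moments", {
  x <- cbind(f1 = c(0, 1, 0, 1), f2 = c(0, 0, 1, 1))
  m <- fit_reference_model(x, "demo")
  expect_equal(unname(m$mean), c(0.5, 0.5))
  expect_equal(unname(m$covariance), diag(1 / 3, 2), tolerance = 1e-12)
  expect_equal(m$ridge, 0)
  expect_equal(m$n_objects, 4L)
})

test_that("degenerate reference sets are ridged or rejected", {
  col3 <- cbind(f1 = c(0, 1, 2), f2 = c(0, 2, 4))  # collinear
  m <- fit_reference_model(col3, "thin")
  expect_gt(m$ridge, 0)
  expect_error(
    fit_reference_model(cbind(a = 1:2, b = c(2, 1), c = c(0, 5)), "few"),
    class = "spotbelief_error_degenerate")
  expect_error(
    fit_reference_model(cbind(a = c(1, 1, 1, 1), b = rnorm(4)), "flat"),
    regexp = "a", class = "spotbelief_error_degenerate")
})

test_that("tidy and glance summarize a model", {
  set.seed(2)
  m <- fit_reference_model(matrix(rnorm(60), 20, 3), "lab")
  td <- tidy(m)
  expect_equal(nrow(td), 3)
  expect_named(td, c("feature", "mean", "sd"))
  gl <- glance(m)
  expect_equal(gl$n_objects, 20L)
  expect_equal(gl$label, "lab")
})

test_that("Mahalanobis distance matches an explicit 2x2 inverse", {
  m <- structure(
    list(label = "o", mean = c(0, 0),
         covariance = matrix(c(2, 1, 1, 2), 2, 2), ridge = 0,
         n_objects = 10L, condition_number = 3,
         feature_names = c("f1", "f2")),
    class = "reference_model")
  # explicit inverse of [[2,1],[1,2]] is 1/3 [[2,-1],[-1,2]]
  inv <- matrix(c(2, -1, -1, 2), 2, 2) / 3
  x <- c(1, 1)
  oracle <- sqrt(drop(t(x) %*% inv %*% x))
  expect_equal(mahalanobis_distance(x, m), oracle, tolerance = 1e-12)
  expect_equal(mahalanobis_distance(c(0, 0), m), 0)
  expect_error(mahalanobis_distance(c(1, 2, 3), m),
               class = "spotbelief_error_invalid_input")
  # identity covariance reduces to the Euclidean norm
  mi <- m
  mi$covariance <- diag(2)
  expect_equal(mahalanobis_distance(c(3, 4), mi), 5)
})

test_that("z-normalization uses population moments with defined fallbacks", {
  z <- z_normalize(c(1, 2, 3))
  expect_equal(z, c(-sqrt(3 / 2), 0, sqrt(3 / 2)), tolerance = 1e-12)
  set.seed(6)
  d <- rexp(50)
  z2 <- z_normalize(d)
  expect_equal(mean(z2), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z2^2)), 1, tolerance = 1e-12)
  expect_warning(expect_equal(z_normalize(5), 0), "Single")
  expect_warning(expect_equal(z_normalize(rep(2, 4)), rep(0, 4)), "identical")
})

test_that("Cantelli conversion hits closed-form anchors", {
  expect_equal(cantelli_plausibility(0), 1)
  expect_equal(cantelli_plausibility(1), 0.5)
  expect_equal(cantelli_plausibility(3), 0.1)
  expect_equal(cantelli_plausibility(-2), 0.2)
  expect_equal(cantelli_plausibility(-2, "one-sided"), 1)
  z <- seq(-3, 3, by = 0.5)
  expect_true(all(cantelli_plausibility(z) > 0 &
                    cantelli_plausibility(z) <= 1))
})

test_that("assign_plausibility composes the three sub-operations per image", {
  set.seed(15)
  ref <- matrix(rnorm(300, mean = 10), 100, 3,
                dimnames = list(NULL, c("f1", "f2", "f3")))
  model <- fit_reference_model(ref, "ref")
  objects <- tibble::tibble(
    image_id = rep(c("a", "b"), c(5, 7)), object_id = c(1:5, 1:7),
    f1 = rnorm(12, 10), f2 = rnorm(12, 10), f3 = rnorm(12, 10))
  got <- assign_plausibility(objects, model)
  for (img in c("a", "b")) {
    sub <- objects[objects$image_id == img, ]
    d <- mahalanobis_distance(sub[, c("f1", "f2", "f3")], model)
    z <- z_normalize(d)
    pl <- cantelli_plausibility(z)
    expect_equal(got$pl[got$image_id == img], pl, tolerance = 1e-12)
  }
  # identical objects in one image: all z 0, all pl 1
  same <- tibble::tibble(image_id = "c", object_id = 1:4,
                         f1 = 1, f2 = 2, f3 = 3)
  suppressWarnings(got2 <- assign_plausibility(same, model))
  expect_equal(got2$pl, rep(1, 4))
})

test_that("plausibility ranks own-population objects above shifted ones", {
  set.seed(42)
  mu <- c(10, 5, 3)
  ref <- sapply(1:3, function(j) rnorm(400, mu[j], 1))
  colnames(ref) <- c("f1", "f2", "f3")
  model <- fit_reference_model(ref, "ref")
  n <- 200
  near <- sapply(1:3, function(j) rnorm(n, mu[j], 1))
  far <- sapply(1:3, function(j) rnorm(n, mu[j] + 5 / sqrt(3), 1))
  feats <- rbind(near, far)
  colnames(feats) <- c("f1", "f2", "f3")
  obj <- dplyr::bind_cols(
    tibble::tibble(image_id = "i", object_id = seq_len(2 * n)),
    tibble::as_tibble(feats))
  sc <- assign_plausibility(obj, model, convention = "one-sided")
  expect_gt(mean(sc$pl[seq_len(n)]), mean(sc$pl[n + seq_len(n)]))
  expect_gt(rank_auc(sc$pl[seq_len(n)], sc$pl[n + seq_len(n)]), 0.9)
})

test_that("triplet algebra conserves mass and flags clamping", {
  t1 <- bidirectional_triplet(0.9, 0.2)
  expect_equal(unlist(t1[, c("p", "q", "r")]), c(p = 0.8, q = 0.1, r = 0.1))
  expect_false(t1$clamped)
  t2 <- bidirectional_triplet(1, 0)
  expect_equal(unlist(t2[, c("p", "q", "r")]), c(p = 1, q = 0, r = 0))
  t3 <- bidirectional_triplet(0.3, 0.3)
  expect_true(t3$clamped)
  expect_equal(t3$p, 0.3)
  expect_equal(t3$r, 0)
  expect_equal(t3$p + t3$q + t3$r, 1)
  expect_error(bidirectional_triplet(1.2, 0.5),
               class = "spotbelief_error_invalid_input")
})

test_that("nested-label algebra behaves", {
  expect_equal(subtract_plausibility(0.8, 0.3), 0.5)
  expect_equal(subtract_plausibility(0.2, 0.5), 0)
  q <- runif(20)
  expect_equal(subtract_plausibility(q, rep(0, 20)), q)
  expect_true(all(subtract_plausibility(q, runif(20)) <= q))

  expect_equal(unique_label_belief(c(0, 0)), 1)
  expect_equal(unique_label_belief(c(1, 0.5)), 0)
  expect_equal(unique_label_belief(c(0.5, 0.5)), 0.25)
  expect_warning(expect_equal(unique_label_belief(numeric(0)), 1))
  # monotone decreasing in every argument
  expect_lt(unique_label_belief(c(0.6, 0.3)), unique_label_belief(c(0.5, 0.3)))
})

test_that("reference models round-trip through JSON", {
  set.seed(31)
  m <- fit_reference_model(matrix(rexp(80), 20, 4,
                                  dimnames = list(NULL, paste0("f", 1:4))),
                           "json_label")
  path <- withr::local_tempfile(fileext = ".json")
  write_reference_model(m, path)
  back <- read_reference_model(path)
  expect_equal(back$mean, m$mean)
  expect_equal(back$covariance, m$covariance)
  expect_equal(back$label, m$label)
  x <- matrix(rexp(8), 2, 4, dimnames = list(NULL, paste0("f", 1:4)))
  expect_equal(mahalanobis_distance(x, back), mahalanobis_distance(x, m))
})

test_that("label_objects emits complete triplet tables", {
  set.seed(77)
  mk <- function(center) {
    m <- sapply(1:3, function(j) rnorm(60, center[j], 1))
    colnames(m) <- c("f1", "f2", "f3")
    m
  }
  model_j <- fit_reference_model(mk(c(5, 5, 5)), "J")
  model_i <- fit_reference_model(mk(c(9, 9, 9)), "I")
  targets <- dplyr::bind_cols(
    tibble::tibble(image_id = "t", object_id = 1:30),
    tibble::as_tibble(mk(c(7, 7, 7))[1:30, ]))
  lab <- label_objects(targets, model_j, swap_model = model_i)
  expect_named(lab, c("image_id", "object_id", "label", "mahalanobis",
                      "z", "pl", "p", "q", "r", "clamped"))
  expect_equal(lab$p + lab$q + lab$r, rep(1, 30))
  expect_true(all(lab$p <= 1 - lab$q + 1e-12))
  # without a swap model belief is the vacuous lower bound
  lab0 <- label_objects(targets, model_j)
  expect_true(all(lab0$p == 0))
  expect_equal(lab0$r, lab0$pl)
})
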