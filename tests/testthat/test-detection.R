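test_that("response is zero on constant and linear-ramp images", {
  cfg <- detection_config(post_sigma = 1)
  const <- matrix(7, 32, 32)
  expect_equal(max(abs(compute_response(const, cfg)$values)), 0)
  ramp <- matrix(rep(seq_len(32), each = 32), 32, 32) * 2.5
  v <- compute_response(ramp, cfg)$values
  # mirror padding folds the ramp at the high edge; the interior (beyond
  # the smoothing kernel's reach) must be exactly zero
  expect_equal(max(abs(v[, 6:26])), 0)
})

test_that("response peaks within 1 px of a Gaussian spot center", {
  img <- gaussian_spot(64, 64, 30.3, 41.7, sigma = 3, amplitude = 100)
  v <- compute_response(img, detection_config(pre_sigma = 0,
                                              post_sigma = 1))$values
  peak <- which(v == max(v), arr.ind = TRUE)[1, ]
  expect_lt(max(abs(peak - c(30.3, 41.7))), 1)
  # positive in a disk around the center
  expect_gt(v[30, 42], 0)
  expect_gt(sum(v > 0.1 * max(v)), 10)
})

test_that("non-finite pixels are rejected", {
  bad <- matrix(1, 8, 8)
  bad[3, 3] <- NaN
  expect_error(compute_response(bad), class = "spotbelief_error_invalid_input")
  neg <- matrix(1, 8, 8)
  neg[2, 2] <- -1
  expect_error(as_image_grid(neg), class = "spotbelief_error_invalid_input")
})

test_that("excess kurtosis matches closed forms and rejects degenerate input", {
  # symmetric two-point distribution: all standardized values are +-1,
  # fourth moment 1, excess kurtosis -2
  expect_equal(excess_kurtosis(rep(c(0, 1), 500)), -2)
  set.seed(7)
  expect_lt(abs(excess_kurtosis(rnorm(1e6))), 0.05)
  expect_error(excess_kurtosis(rep(3, 10)),
               class = "spotbelief_error_degenerate")
  expect_error(excess_kurtosis(5), class = "spotbelief_error_degenerate")
})

test_that("adaptive threshold equals the closed form on lognormal data", {
  set.seed(11)
  vals <- rlnorm(4000, meanlog = -1, sdlog = 0.8)
  resp <- as_response(matrix(vals, 50, 80))
  cfg <- detection_config(prc = 2)
  out <- adaptive_threshold(resp, cfg)
  # independent arithmetic re-evaluation
  k <- mean(((vals - mean(vals)) / sqrt(mean((vals - mean(vals))^2)))^4) - 3
  lp <- log(vals)
  oracle <- exp(mean(lp)) * exp(sqrt(mean((lp - mean(lp))^2)))^(k^0.25 / 2)
  expect_equal(out$threshold, oracle, tolerance = 1e-9)
  expect_equal(out$z_score, k^0.25, tolerance = 1e-12)
})

test_that("prc -> Inf drives the threshold to the geometric mean", {
  set.seed(3)
  vals <- rlnorm(2000)
  resp <- as_response(matrix(vals, 40, 50))
  out <- adaptive_threshold(resp, detection_config(prc = 1e9))
  expect_equal(out$threshold, exp(mean(log(vals))), tolerance = 1e-6)
})

test_that("negative excess kurtosis errors by default and clamps on request", {
  set.seed(5)
  vals <- runif(3000, 0.5, 1.5)  # sub-Gaussian: excess kurtosis ~ -1.2
  resp <- as_response(matrix(vals, 50, 60))
  expect_error(adaptive_threshold(resp, detection_config()),
               class = "spotbelief_error_domain")
  expect_warning(
    out <- adaptive_threshold(resp,
                              detection_config(kurtosis_fallback = "clamp")),
    "clamped")
  expect_equal(out$threshold, exp(mean(log(vals))), tolerance = 1e-12)
})

test_that("thresholding and labelling handle simple geometries", {
  v <- matrix(0, 32, 32)
  v[10:14, 20:24] <- 5
  comp <- binarize_and_label(as_response(v), 1, detection_config())
  expect_length(comp$components, 1)
  expect_equal(nrow(comp$components[[1]]), 25)

  # checkerboard has no 4-adjacent foreground pairs
  chk <- outer(1:16, 1:16, function(r, c) (r + c) %% 2 == 0)
  comp4 <- label_mask(chk, connectivity = 4L)
  expect_length(comp4$components, sum(chk))
  expect_true(all(vapply(comp4$components, nrow, integer(1)) == 1L))
})

test_that("component ids follow raster-scan order and min_area filters", {
  mask <- matrix(FALSE, 10, 10)
  mask[8, 2] <- TRUE            # late row, early column
  mask[2, 8:9] <- TRUE          # early row, late column
  comp <- label_mask(mask, connectivity = 8L)
  expect_equal(comp$components[[1]][1, ], c(row = 2L, col = 8L))
  expect_equal(comp$components[[2]][1, ], c(row = 8L, col = 2L))
  comp2 <- label_mask(mask, connectivity = 8L, min_area = 2L)
  expect_length(comp2$components, 1)
  expect_equal(nrow(comp2$components[[1]]), 2)
})

test_that("connected components agree with a flood-fill oracle", {
  set.seed(21)
  for (i in 1:20) {
    mask <- matrix(runif(32 * 32) < 0.4, 32, 32)
    for (conn in c(4L, 8L)) {
      got <- label_mask(mask, connectivity = conn)
      oracle <- flood_fill_components(mask, connectivity = conn)
      expect_identical(partition_signature(got$label_map),
                       partition_signature(oracle))
    }
  }
})

test_that("local-maxima pruning keeps peaks and drops ramps", {
  img <- gaussian_spot(40, 40, 20, 20, 3, 50)
  mask <- img > 10
  comp <- label_mask(mask)
  expect_length(prune_by_local_maxima(comp, img)$components, 1)

  ramp <- matrix(rep(1:40, each = 40), 40, 40)
  mask2 <- matrix(FALSE, 40, 40)
  mask2[10:15, 10:15] <- TRUE   # interior patch on a strict column ramp
  comp2 <- label_mask(mask2)
  expect_length(prune_by_local_maxima(comp2, ramp)$components, 0)
})

test_that("blank images raise a degenerate-distribution error", {
  expect_error(detect_objects(matrix(0, 32, 32)),
               class = "spotbelief_error_degenerate")
})

test_that("detection is deterministic and finds isolated spots", {
  sim <- simulate_image(simulation_config(
    height = 128, width = 128, n_bright = 5, n_dim = 0,
    min_separation = 30, seed = 2))
  cfg <- experiment_detcfg()
  d1 <- detect_objects(sim$image, cfg)
  d2 <- detect_objects(sim$image, cfg)
  expect_identical(d1$label_map, d2$label_map)
  expect_length(d1$components, 5)
})
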