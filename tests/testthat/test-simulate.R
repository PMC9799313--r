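test_that("empty configuration yields a blank image and empty truth", {
  sim <- simulate_image(simulation_config(
    height = 64, width = 64, n_bright = 0, n_dim = 0,
    gauss_sigma_frac = 0, poisson_lambda_frac = 0))
  expect_equal(max(sim$image$pixels), 0)
  expect_equal(nrow(sim$truth$sources), 0)
})

test_that("a single noiseless source follows the Gaussian profile", {
  sim <- simulate_image(simulation_config(
    height = 128, width = 128, n_bright = 1, n_dim = 0,
    amplitude = 200, gauss_sigma_frac = 0, poisson_lambda_frac = 0,
    seed = 5))
  src <- sim$truth$sources
  px <- sim$image$pixels
  peak <- which(px == max(px), arr.ind = TRUE)[1, ]
  expect_lt(max(abs(peak - c(src$row, src$col))), 1)
  # value at the nearest pixel to the center is ~ amplitude (quantized)
  expect_equal(px[round(src$row), round(src$col)], 200, tolerance = 0.05)
  # value one sigma away (along rows) ~ amplitude * exp(-1/2)
  r1 <- round(src$row + src$sigma)
  analytic <- 200 * exp(-(((r1 - src$row)^2 + (round(src$col) - src$col)^2) /
                            (2 * src$sigma^2)))
  expect_equal(px[r1, round(src$col)], analytic, tolerance = 0.02)
})

test_that("noiseless render equals the analytic source sum", {
  cfg <- simulation_config(height = 96, width = 96, n_bright = 3, n_dim = 2,
                           gauss_sigma_frac = 0, poisson_lambda_frac = 0,
                           min_separation = 10, seed = 17)
  sim <- simulate_image(cfg)
  src <- sim$truth$sources
  analytic <- matrix(0, 96, 96)
  for (i in seq_len(nrow(src))) {
    analytic <- analytic + gaussian_spot(96, 96, src$row[i], src$col[i],
                                         src$sigma[i], src$amplitude[i])
  }
  expect_lt(max(abs(sim$image$pixels - round(pmin(analytic, 255)))), 1e-9)
})

test_that("simulation is deterministic and leaves the RNG untouched", {
  cfg <- simulation_config(height = 64, width = 64, n_bright = 3, n_dim = 3,
                           seed = 99)
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  s1 <- simulate_image(cfg)
  after <- runif(1)
  s2 <- simulate_image(cfg)
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$truth$sources, s2$truth$sources)
  expect_equal(before, after)
})

test_that("impossible packing raises a placement error", {
  expect_error(
    simulate_image(simulation_config(height = 32, width = 32,
                                     n_bright = 50, n_dim = 0,
                                     min_separation = 20)),
    class = "spotbelief_error_invalid_input")
})

test_that("noise model matches an integration oracle and zero is identity", {
  img <- matrix(10, 16, 16)
  expect_identical(add_noise(img, 0, 0), img)

  set.seed(2)
  blank <- matrix(0, 512, 512)
  noisy <- add_noise(blank, 0.062, 0.062)
  # oracle: E[clip(K + G, 0, 255)], K ~ Pois(15.81), G ~ N(0, 15.81),
  # by summing the Poisson pmf against the clipped-normal mean (computed
  # once, frozen): 17.246
  expect_equal(mean(noisy), 17.246, tolerance = 0.01)
  expect_true(all(noisy >= 0 & noisy <= 255))
})

test_that("at severe noise the dim peaks sink below the background level", {
  cfg <- simulation_config()
  dim_peak <- cfg$amplitude / cfg$dim_factor
  noise_sd <- sqrt((96 / 255 * 255)^2 + 96 / 255 * 255)
  expect_lt(dim_peak / noise_sd, 1)
})

test_that("matching conserves counts and handles edge cases", {
  sim <- simulate_image(simulation_config(
    height = 128, width = 128, n_bright = 4, n_dim = 3,
    gauss_sigma_frac = 0, poisson_lambda_frac = 0,
    min_separation = 25, seed = 3))
  # detection equal to the truth footprints
  lm <- matrix(0L, 128, 128)
  comps <- sim$truth$footprints
  for (i in seq_along(comps)) lm[comps[[i]]] <- i
  cs <- structure(list(label_map = lm, components = comps,
                       connectivity = 8L, min_area = 1L),
                  class = "component_set")
  m <- match_objects(cs, sim$truth)
  expect_equal(m$tp, 7)
  expect_equal(m$fp, 0)
  expect_equal(m$fn, 0)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)

  empty <- label_mask(matrix(FALSE, 128, 128))
  m0 <- match_objects(empty, sim$truth)
  expect_equal(m0$fn, 7)
  expect_equal(m0$precision, 1)
  expect_equal(m0$recall, 0)

  # shifted detection overlapping no footprint
  far <- matrix(FALSE, 128, 128)
  far[1:2, 1:2] <- TRUE
  in_fp <- any(vapply(comps, function(fp) any(fp[, 1] <= 2 & fp[, 2] <= 2),
                      logical(1)))
  if (!in_fp) {
    mf <- match_objects(label_mask(far), sim$truth)
    expect_equal(mf$fp, 1)
    expect_equal(mf$fn, 7)
  }
  expect_equal(m$tp + m$fn, nrow(sim$truth$sources))
})

test_that("consistency harness reports one complete row per scenario", {
  out <- consistency_experiment(
    prc = 2, scenarios = list(c(3L, 3L)), seeds = 1L,
    base_cfg = simulation_config(height = 128, width = 128,
                                 min_separation = 20),
    det_cfg = experiment_detcfg())
  expect_equal(nrow(out), 1)
  expect_true(all(is.finite(unlist(out))))
  expect_true(out$mean_recall >= 0 && out$mean_recall <= 1)
})

test_that("noiseless well-separated scenes give perfect recall everywhere", {
  base <- simulation_config(height = 256, width = 256,
                            gauss_sigma_frac = 0, poisson_lambda_frac = 0,
                            min_separation = 30)
  # small homogeneous noiseless scenes can be platykurtic; clamp rather
  # than error so the threshold degenerates to the geometric mean
  out <- suppressWarnings(consistency_experiment(
    prc = 2, scenarios = list(c(2L, 10L), c(6L, 6L), c(10L, 2L)),
    seeds = 1:2, base_cfg = base,
    det_cfg = experiment_detcfg()))
  expect_equal(out$mean_recall, rep(1, 3))
})
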