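test_that("MGM follows the geodesic Gaussian with the exact prefactor", {
  gd <- folded_gd()
  sigma <- 5
  kmax <- 40L
  mgm <- build_mgm(gd, kmax, sigma)
  expect_equal(mgm$m[kmax], 1 / (sigma * sqrt(2 * pi)), tolerance = 1e-15)
  expect_identical(which.max(mgm$m), kmax)
  # ratio at one sigma of distance is exp(-1/2)
  d <- gd[kmax, ]
  k1 <- which.min(abs(d - sigma))
  expect_equal(mgm$m[k1] / mgm$m[kmax],
               exp(-d[k1]^2 / (2 * sigma^2)), tolerance = 1e-12)
  # equal geodesic distance implies equal excitability
  expect_equal(mgm$m, dnorm(d, sd = sigma), tolerance = 0)
  expect_error(build_mgm(gd, kmax, 0), "positive")
  expect_error(build_mgm(gd, 10^6, 5), "range")
})

test_that("excitability decays with geodesic distance from kmax", {
  gd <- folded_gd()
  mgm <- build_mgm(gd, 11L, 4)
  ord <- order(gd[11L, ])
  expect_true(all(diff(mgm$m[ord]) <= 1e-15))
})

test_that("discrete MGM mass matches the continuous surface integral", {
  # the Eq.-style density uses the 1-D Gaussian prefactor with a 2-D
  # distance, so its surface integral is sigma * sqrt(2 * pi), approximated
  # by the compartment-area-weighted sum away from the patch boundary
  m <- build_synthetic_roi(2500, 0, 10, 20, seed = 14)
  gd <- geodesic_distance_matrix(m)
  cen <- m$compartment_centers
  k0 <- which.min(cen[, 1]^2 + cen[, 2]^2)
  sigma <- 3
  mgm <- build_mgm(gd, k0, sigma)
  mass <- sum(mgm$m * compartment_areas(m))
  expect_lt(abs(mass - sigma * sqrt(2 * pi)) / (sigma * sqrt(2 * pi)), 0.1)
})

test_that("stimulation strength is the plain inner product", {
  expect_identical(stimulation_strength(c(0, 1, 0), c(7, 2, 9)), 2)
  expect_equal(stimulation_strength(c(0.1, 0.2), c(3, 4)), 1.1,
               tolerance = 1e-15)
  expect_identical(stimulation_strength(c(0.3, 0.7), c(0, 0)), 0)
  # matrix form gives one strength per row
  mm <- rbind(c(1, 0), c(0, 2))
  expect_equal(stimulation_strength(c(2, 3), mm), c(2, 6))
  expect_error(stimulation_strength(c(1, 2, 3), c(1, 2)), "compartments")
})

test_that("sigmoid response hits its turning point and limits", {
  p <- mep_model_params(x0 = 1, ymax = 2, slope = 1, noise_p = 0)
  expect_identical(sigmoid_response(1, p), 1)
  expect_equal(sigmoid_response(2, p), 2 / (1 + exp(-1)), tolerance = 1e-15)
  expect_equal(sigmoid_response(1e3, p), 2, tolerance = 1e-12)
  expect_lt(sigmoid_response(-1e3, p), 1e-12)
  x <- seq(-5, 5, length.out = 50)
  expect_true(all(diff(sigmoid_response(x, p)) > 0))
})

test_that("noise-free generation reproduces the clean sigmoid", {
  p <- mep_model_params(x0 = 0.5, ymax = 1.5, slope = 2, noise_p = 0)
  x <- seq(-2, 3, length.out = 20)
  expect_identical(noisy_mep(x, p, seed = 1), sigmoid_response(x, p))
})

test_that("noisy MEPs are clamped at zero and reproducible", {
  p <- mep_model_params(x0 = 0, ymax = 0.2, slope = 1, noise_p = 5)
  y1 <- noisy_mep(rep(0, 2000), p, seed = 8)
  expect_true(all(y1 >= 0))
  expect_true(any(y1 == 0))  # the huge noise amplitude forces clamping
  expect_identical(y1, noisy_mep(rep(0, 2000), p, seed = 8))
})

test_that("noise heteroscedasticity saturates at P along the sigmoid", {
  p <- mep_model_params(x0 = 2, ymax = 50, slope = 1.5, noise_p = 0.5)
  xs <- p$x0 + c(-4, -1, 0, 1, 20) / p$slope
  sds <- vapply(seq_along(xs), function(i) {
    y <- noisy_mep(rep(xs[i], 1e5), p, seed = 100 + i)
    sd(y - sigmoid_response(xs[i], p))
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
  expect_lt(abs(sds[5] - p$noise_p) / p$noise_p, 0.02)
  expect_equal(mep_noise_sd(xs, p), p$noise_p * plogis(p$slope * (xs - p$x0)),
               tolerance = 1e-15)
})

test_that("simulate_meps applies the model per candidate with shared noise", {
  gd <- folded_gd()
  m <- folded_mesh()
  cs <- build_candidate_set(m, generate_coil_grid(10, 5, 45, 135),
                            percent_mso = 60)
  mgm <- build_mgm(gd, 25L, 5)
  p <- calibrate_mep_params(mgm, cs)
  sim <- simulate_meps(mgm, cs, p, noise_seed = 4)
  expect_identical(nrow(sim), nrow(cs$maps))
  expect_true(all(sim$y_noisy >= 0))
  expect_true(all(sim$y_clean > 0 & sim$y_clean < p$ymax))
  expect_identical(sim, simulate_meps(mgm, cs, p, noise_seed = 4))
  # the noise stream is indexed by candidate: a subset sees the same draws
  idx <- c(5L, 17L, 3L)
  sub <- simulate_meps(mgm, cs, p, noise_seed = 4, indices = idx)
  expect_identical(sub$y_noisy, sim$y_noisy[idx])
  expect_error(simulate_meps(build_mgm(gd, 1L, 5), cs$maps[, 1:10], p),
               "compartments")
})

test_that("noise-free records are monotone in a single-compartment MGM", {
  m <- flat_mesh()
  cs <- build_candidate_set(m, generate_coil_grid(10, 5, 45, 135))
  mvec <- rep(0, ncol(cs$maps))
  mvec[7L] <- 1
  p <- mep_model_params(x0 = median(cs$maps[, 7L]), ymax = 1,
                        slope = 4 / max(cs$maps[, 7L]), noise_p = 0)
  sim <- simulate_meps(mvec, cs, p)
  ord <- order(cs$maps[, 7L])
  expect_true(all(diff(sim$y_noisy[ord]) >= 0))
})

test_that("parameter calibration anchors the sigmoid to the strength sweep", {
  gd <- flat_gd()
  cs <- build_candidate_set(flat_mesh(), generate_coil_grid(10, 5, 45, 135),
                            percent_mso = 60)
  mgm <- build_mgm(gd, 3L, 5)
  p <- calibrate_mep_params(mgm, cs, ymax = 2, noise_rel = 0.1)
  x <- stimulation_strength(mgm, cs)
  expect_equal(p$x0, median(x), tolerance = 1e-12)
  q <- quantile(x, c(0.1, 0.9), names = FALSE)
  expect_equal(p$slope, 8 / (q[2] - q[1]), tolerance = 1e-12)
  expect_identical(p$noise_p, 0.2)
  expect_identical(p$ymax, 2)
})
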