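test_that("noise-free sigmoid data recover the generating parameters", {
  p <- mep_model_params(x0 = 3, ymax = 1.8, slope = 1.2, noise_p = 0)
  x <- seq(p$x0 - 6 / p$slope, p$x0 + 6 / p$slope, length.out = 50)
  fit <- fit_sigmoid_lm(x, sigmoid_response(x, p))
  expect_false(fit$failed)
  expect_gte(fit$r2, 1 - 1e-9)
  truth <- c(x0 = p$x0, ymax = p$ymax, slope = p$slope)
  expect_lt(max(abs(fit$params - truth) / truth), 1e-4)
})

test_that("degenerate responses are flagged with r2 zero", {
  x <- 1:10
  # constant response
  fit <- fit_sigmoid_lm(x, rep(2, 10))
  expect_true(fit$failed)
  expect_identical(fit$r2, 0)
  # fully saturated response is the same degeneracy, not a spurious fit
  fit2 <- fit_sigmoid_lm(x, rep(5, 10))
  expect_true(fit2$failed)
  expect_identical(fit2$r2, 0)
  # constant predictor
  fit3 <- fit_sigmoid_lm(rep(1, 10), c(1:9, 20))
  expect_true(fit3$failed)
  expect_identical(fit3$r2, 0)
  expect_error(fit_sigmoid_lm(1:3, 1:3), "at least 4")
  expect_error(fit_sigmoid_lm(1:5, c(-1, 1, 1, 1, 1)), "non-negative")
})

test_that("own LM fitter agrees with minpack.lm on noisy data", {
  set.seed(17)
  for (rep in 1:5) {
    p <- mep_model_params(x0 = runif(1, 2, 4), ymax = runif(1, 0.5, 2),
                          slope = runif(1, 0.8, 2), noise_p = 0)
    x <- seq(p$x0 - 5 / p$slope, p$x0 + 5 / p$slope, length.out = 80)
    y <- pmax(0, sigmoid_response(x, p) + rnorm(80, sd = 0.03 * p$ymax))
    fit <- fit_sigmoid_lm(x, y)
    ref <- minpack.lm::nlsLM(
      y ~ ymax / (1 + exp(-slope * (x - x0))),
      start = list(x0 = p$x0, ymax = p$ymax, slope = p$slope),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(ref)[c("x0", "ymax", "slope")]
    expect_lt(max(abs(fit$params - cf) / abs(cf)), 0.01)
    r2_ref <- 1 - sum(resid(ref)^2) / sum((y - mean(y))^2)
    expect_lt(abs(fit$r2 - r2_ref), 1e-3)
  }
})

test_that("R2 maps are order-invariant and localize a noise-free source", {
  m <- flat_mesh()
  gd <- flat_gd()
  cs <- build_candidate_set(m, generate_coil_grid(14, 7, 30, 150),
                            percent_mso = 60)
  kmax <- placement_compartment(m, "crown-center")
  mgm <- build_mgm(gd, kmax, 5)
  p <- calibrate_mep_params(mgm, cs, noise_rel = 0)
  sim <- simulate_meps(mgm, cs, p)
  r2 <- compute_r2_map(seq_len(nrow(cs$maps)), cs, sim$y_noisy)
  expect_true(all(r2$r2 >= 0 & r2$r2 <= 1))
  # dense noise-free fitting puts the peak within one adjacency edge of kmax
  nb <- compartment_edges(m)
  neighbors <- c(nb$to[nb$from == kmax], nb$from[nb$to == kmax], kmax)
  expect_true(which.max(r2$r2) %in% neighbors)
  # permuting (selection, MEP) pairs leaves the map unchanged
  set.seed(3)
  perm <- sample(nrow(cs$maps))
  r2p <- compute_r2_map(perm, cs, sim$y_noisy[perm])
  expect_equal(r2p$r2, r2$r2, tolerance = 1e-12)
  # identical MEPs for every stimulation degenerate the whole map
  r2c <- compute_r2_map(seq_len(nrow(cs$maps)), cs,
                        rep(1, nrow(cs$maps)))
  expect_true(all(r2c$r2 == 0) && all(r2c$failed))
  expect_error(compute_r2_map(1:3, cs, rep(1, 4)), "match")
  expect_error(compute_r2_map(1:3, cs, rep(1, 3)), "minimum fit size")
})

test_that("overlap score matches its closed-form examples", {
  expect_equal(fitting_score(c(1, 0, 1), c(1, 1, 0)), 0.5,
               tolerance = 1e-15)
  expect_identical(fitting_score(c(1, 0, 1), c(0, 1, 0)), 0)
  v <- c(0.2, 0.5, 0.1)
  expect_equal(fitting_score(v, v), 1, tolerance = 1e-12)
  expect_error(fitting_score(c(0, 0), c(1, 1)), "all-zero")
  expect_error(fitting_score(c(1, 0), c(1, 1, 0)), "length")
})

test_that("overlap score is invariant under positive rescaling", {
  set.seed(9)
  for (rep in 1:50) {
    a <- runif(12)
    b <- runif(12)
    s <- fitting_score(a, b)
    expect_lt(abs(fitting_score(a * runif(1, 0.01, 100), b) - s), 1e-12)
    expect_lt(abs(fitting_score(a, b * runif(1, 0.01, 100)) - s), 1e-12)
    expect_true(s >= 0 && s <= 1 + 1e-12)
  }
})

test_that("peak distance is symmetric and resolves ties to low indices", {
  m <- strip_mesh()
  gd <- geodesic_distance_matrix(m, ring = 1L, adjacency = "edge")
  a <- c(1, 0, 0, 0)
  b <- c(0, 1, 0, 0)
  expect_identical(peak_geodesic_distance(a, a, gd), 0)
  expect_equal(peak_geodesic_distance(a, b, gd), gd[1, 2])
  expect_identical(peak_geodesic_distance(a, b, gd),
                   peak_geodesic_distance(b, a, gd))
  # tie in the estimated map resolves to the smallest index
  expect_equal(peak_geodesic_distance(a, c(0, 1, 1, 0), gd), gd[1, 2])
})

test_that("samples-to-criterion reads the curve and censors at budget", {
  curve <- data.frame(n = seq(4, 20, 2),
                      score = c(0.1, 0.3, 0.5, 0.7, 0.92, 0.96, 0.97, 0.9,
                                0.99))
  expect_identical(samples_to_criterion(curve, 0.95, 150),
                   list(n95 = 14L, censored = FALSE))
  low <- transform(curve, score = score * 0.9)
  expect_identical(samples_to_criterion(low, 0.95, 150),
                   list(n95 = 150L, censored = TRUE))
  # crossing at the very first evaluated n
  first <- data.frame(n = c(4, 6), score = c(0.99, 0.2))
  expect_identical(samples_to_criterion(first, 0.95, 150)$n95, 4L)
  expect_error(samples_to_criterion(curve, 1.2, 150), "inside")
  expect_error(samples_to_criterion(curve[0, ], 0.95, 150), "empty")
})

test_that("high-resolution reference bounds subset maps via Cauchy-Schwarz", {
  m <- flat_mesh()
  gd <- flat_gd()
  cs <- build_candidate_set(m, generate_coil_grid(12, 4, 30, 150),
                            percent_mso = 60)
  mgm <- build_mgm(gd, placement_compartment(m, "crown-center"), 5)
  p <- calibrate_mep_params(mgm, cs)
  sim <- simulate_meps(mgm, cs, p, noise_seed = 6)
  hr <- high_res_reference(cs, sim$y_noisy)
  expect_equal(fitting_score(hr, hr), 1, tolerance = 1e-12)
  sub <- compute_r2_map(1:40, cs, sim$y_noisy[1:40])
  expect_lte(fitting_score(hr, sub), 1 + 1e-12)
})

test_that("score curves stop early at the threshold and record distances", {
  m <- flat_mesh()
  gd <- flat_gd()
  cs <- build_candidate_set(m, generate_coil_grid(12, 4, 30, 150),
                            percent_mso = 60)
  mgm <- build_mgm(gd, placement_compartment(m, "crown-center"), 5)
  p <- calibrate_mep_params(mgm, cs)
  sim <- simulate_meps(mgm, cs, p, noise_seed = 2)
  ref <- compute_r2_map(seq_len(nrow(cs$maps)), cs, sim$y_noisy)
  sel <- fps_sample(cs, 60, seed = 3)
  full <- score_curve(sel, cs, sim$y_noisy[sel$order], ref, gd = gd,
                      eval_n = seq(4, 60, 2))
  expect_identical(full$n, seq(4L, 60L, 2L))
  expect_true(all(full$peak_distance >= 0))
  early <- score_curve(sel, cs, sim$y_noisy[sel$order], ref, gd = gd,
                       eval_n = seq(4, 60, 2), early_stop_threshold = 0.9)
  expect_lte(nrow(early), nrow(full))
  expect_equal(early$score, full$score[seq_len(nrow(early))],
               tolerance = 1e-12)
})

test_that("r2 map CSV export carries fits and failure flags", {
  m <- flat_mesh()
  cs <- build_candidate_set(m, generate_coil_grid(10, 5, 45, 135))
  mvec <- rep(0, ncol(cs$maps)); mvec[5] <- 1
  p <- mep_model_params(x0 = median(cs$maps[, 5]), ymax = 1,
                        slope = 4 / max(cs$maps[, 5]), noise_p = 0.1)
  sim <- simulate_meps(mvec, cs, p, noise_seed = 1)
  r2 <- compute_r2_map(seq_len(nrow(cs$maps)), cs, sim$y_noisy)
  path <- file.path(tempdir(), "r2map.csv")
  write_r2_map(r2, path)
  tab <- read.csv(path)
  expect_identical(nrow(tab), length(r2$r2))
  expect_equal(tab$r2, r2$r2, tolerance = 1e-6)
})
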