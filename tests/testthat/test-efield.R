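test_that("coil grid construction counts and endpoints are exact", {
  # single position when the search radius collapses
  g0 <- generate_coil_grid(0, 3, 5, 175)
  expect_identical(nrow(g0), 36L)
  expect_true(all(g0$x == 0 & g0$y == 0))

  # endpoint inclusion of the angle sequence
  g2 <- generate_coil_grid(0, 3, 175, 175)
  expect_identical(sort(unique(g2$alpha)), c(0, 175))

  # origin-anchored lattice contains the origin
  g <- generate_coil_grid(9, 3, 90, 90)
  expect_true(any(g$x == 0 & g$y == 0))

  expect_error(generate_coil_grid(30, 3, 5, 180), "180")
  expect_error(generate_coil_grid(30, 0, 5, 175), "spacing")
  expect_error(generate_coil_grid(30, 3, 0, 175), "angle_step")
})

test_that("synthetic field is isotropic at beta 0 and 180-degree periodic", {
  m <- folded_mesh()
  iso <- field_model(beta = 0)
  e1 <- synthetic_efield(list(x = 3, y = -2, alpha = 0), m, iso)
  e2 <- synthetic_efield(list(x = 3, y = -2, alpha = 137), m, iso)
  expect_identical(e1$values, e2$values)

  ani <- field_model(beta = 0.4)
  a1 <- synthetic_efield(list(x = 3, y = -2, alpha = 30), m, ani)
  a2 <- synthetic_efield(list(x = 3, y = -2, alpha = 210), m, ani)
  expect_equal(a1$values, a2$values, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(
    a1$values, synthetic_efield(list(x = 3, y = -2, alpha = 75), m,
                                ani)$values)))
})

test_that("field peaks at the model amplitude under the coil on a crown", {
  m <- flat_mesh()
  k <- 17L
  cfg <- list(x = m$compartment_centers[k, 1L],
              y = m$compartment_centers[k, 2L], alpha = 0, standoff = 0)
  e <- synthetic_efield(cfg, m, field_model(peak = 1.5, beta = 0))
  expect_identical(e$values[k], 1.5)
  expect_identical(which.max(e$values), k)
})

test_that("field magnitude decays with tangent distance and with depth", {
  m <- folded_mesh()
  mod <- field_model(beta = 0)
  e <- synthetic_efield(list(x = 0, y = 6, alpha = 0), m, mod)$values
  cen <- m$compartment_centers
  rho <- sqrt((cen[, 1L])^2 + (cen[, 2L] - 6)^2)
  # at matched depth, larger tangent distance never means a stronger field
  set.seed(5)
  checked_rho <- 0L
  for (rep in 1:2000) {
    ij <- sample(length(e), 2L)
    if (abs(m$depth[ij[1L]] - m$depth[ij[2L]]) > 0.2) next
    if (abs(rho[ij[1L]] - rho[ij[2L]]) < 1) next
    ij <- ij[order(rho[ij])]
    checked_rho <- checked_rho + 1L
    expect_gte(e[ij[1L]] + 1e-9, e[ij[2L]])
  }
  expect_gt(checked_rho, 50L)
  # at matched tangent distance near the coil axis, deeper is weaker
  checked_depth <- 0L
  for (rep in 1:2000) {
    ij <- sample(which(rho < 8), 2L)
    if (abs(rho[ij[1L]] - rho[ij[2L]]) > 0.3) next
    if (abs(m$depth[ij[1L]] - m$depth[ij[2L]]) < 0.5) next
    ij <- ij[order(m$depth[ij])]
    checked_depth <- checked_depth + 1L
    expect_gte(e[ij[1L]] + 1e-9, e[ij[2L]])
  }
  expect_gt(checked_depth, 20L)
})

test_that("nearby coil configurations yield nearby maps", {
  m <- folded_mesh()
  set.seed(21)
  for (i in 1:10) {
    base <- list(x = runif(1, -10, 10), y = runif(1, -10, 10),
                 alpha = runif(1, 0, 175))
    e0 <- synthetic_efield(base, m)$values
    dists <- vapply(c(1, 0.1, 0.01), function(h) {
      pert <- list(x = base$x + h, y = base$y - h, alpha = base$alpha + h)
      sqrt(sum((synthetic_efield(pert, m)$values - e0)^2))
    }, numeric(1))
    expect_true(all(diff(dists) < 0))
    expect_lt(dists[3], 5e-2 * max(1, dists[1]))
  }
})

test_that("intensity scaling is exactly linear and composes", {
  m <- flat_mesh()
  e <- synthetic_efield(list(x = 0, y = 0, alpha = 0), m)
  expect_identical(scale_to_intensity(e, 1)$values, e$values)
  expect_identical(scale_to_intensity(e, 0)$values, e$values * 0)
  s <- scale_to_intensity(scale_to_intensity(e, 3), 40)
  expect_equal(s$values, e$values * 120, tolerance = 1e-15)
  expect_identical(s$intensity_scale, 120)
  # 120% MSO example: map maximum scales by the factor exactly
  e$values <- e$values / max(e$values) * 0.5
  expect_equal(max(scale_to_intensity(e, 120)$values), 60, tolerance = 1e-12)
  expect_error(scale_to_intensity(e, -5), "non-negative")
})

test_that("cylindrical ROI extraction uses a closed boundary and area ratio", {
  m <- cached("flat30", function() build_synthetic_roi(2000, 0, 10, 30,
                                                       seed = 9))
  sel <- extract_cylindrical_roi(m, radius = 20)
  frac <- length(sel$indices) / nrow(m$triangles)
  expect_lt(abs(frac - (20 / 30)^2), 0.05 * (20 / 30)^2 + 0.01)
  expect_identical(sel$indices, sort(sel$indices))
  # radius beyond the patch keeps everything
  all_sel <- extract_cylindrical_roi(m, radius = 100)
  expect_identical(all_sel$indices, seq_len(nrow(m$triangles)))
  # closed boundary: a compartment exactly at the radius is included
  cen <- m$compartment_centers
  r <- sqrt(cen[, 1]^2 + cen[, 2]^2)
  k <- which.min(abs(r - 15))
  expect_true(k %in% extract_cylindrical_roi(m, radius = r[k])$indices)
  expect_error(extract_cylindrical_roi(m, radius = -1), "positive")
})

test_that("candidate sets validate their invariants", {
  expect_error(candidate_set(matrix(numeric(0), 0, 3)), "at least one")
  expect_error(candidate_set(rbind(c(1, 2), c(0, 0))), "all-zero")
  expect_error(candidate_set(rbind(c(1, -2), c(1, 1))), "non-negative")
  expect_error(candidate_set(matrix(1, 2, 2),
                             data.frame(config_id = 1)), "config count")
})

test_that("candidate save/load round-trips the matrix exactly", {
  m <- flat_mesh()
  grid <- generate_coil_grid(6, 3, 60, 120)
  cs <- build_candidate_set(m, grid, percent_mso = 60)
  path <- file.path(tempdir(), "cands.csv")
  save_candidates(cs, path)
  cs2 <- load_candidates(path)
  expect_identical(cs2$maps, cs$maps)
  expect_equal(cs2$configs$x, cs$configs$x, tolerance = 0)
  expect_identical(cs2$intensity_scale, cs$intensity_scale)

  # externally authored file: 5 configurations over 3 compartments
  ext <- file.path(tempdir(), "ext.csv")
  writeLines(c("config_id,x,y,alpha,E01,E02,E03",
               paste(1:5, 0, 0, 0, 1:5, 6:10, 11:15, sep = ",")), ext)
  cs3 <- load_candidates(ext)
  expect_identical(dim(cs3$maps), c(5L, 3L))
  # an empty table is rejected
  empty <- file.path(tempdir(), "empty.csv")
  writeLines("config_id,x,y,alpha,E01", empty)
  expect_error(load_candidates(empty), "no configurations")
})

test_that("coil affine export writes one valid pose per configuration", {
  grid <- generate_coil_grid(3, 3, 90, 90)
  path <- file.path(tempdir(), "affines.csv")
  export_coil_affines(grid, path)
  tab <- read.csv(path)
  expect_identical(nrow(tab), nrow(grid))
  m1 <- matrix(as.numeric(tab[1, -1]), 4, 4, byrow = TRUE)
  # rigid in-plane rotation block and homogeneous last row
  expect_equal(det(m1[1:2, 1:2]), 1, tolerance = 1e-12)
  expect_identical(m1[4, ], c(0, 0, 0, 1))
})
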