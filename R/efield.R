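# Coil configuration grids, parametric synthetic |E| model, intensity
# scaling, cylindrical ROI extraction and candidate-set persistence.

#' Generate a coil-configuration candidate grid
#'
#' Square lattice of coil center offsets (x, y) within a search radius of the
#' scalp projection of the ROI center, crossed with coil orientation angles.
#' The lattice is axis-aligned and anchored at the origin. Orientations at
#' and beyond 180 degrees are excluded: the field magnitude is 180-degree
#' periodic in the coil angle.
#'
#' @param search_radius coil search radius in mm (>= 0); default 30.
#' @param spacing lattice spacing in mm (> 0); default 3.
#' @param angle_step orientation increment in degrees; default 5.
#' @param angle_max largest orientation in degrees (< 180); default 175.
#' @param standoff scalp-to-coil distance in mm (>= 0).
#' @return Data frame of coil configurations with columns `config_id`, `x`,
#'   `y`, `alpha`, `standoff`. Defaults give 317 positions x 36 angles =
#'   11,412 configurations.
#' @export
generate_coil_grid <- function(search_radius = 30, spacing = 3,
                               angle_step = 5, angle_max = 175,
                               standoff = 0) {
  check_scalar_number(search_radius, "search_radius")
  check_scalar_number(spacing, "spacing")
  check_scalar_number(angle_step, "angle_step")
  check_scalar_number(angle_max, "angle_max")
  if (search_radius < 0) stop_invalid("search_radius must be non-negative")
  if (spacing <= 0) stop_invalid("spacing must be positive")
  if (angle_step <= 0 || angle_step > angle_max) {
    stop_invalid("angle_step must satisfy 0 < angle_step <= angle_max")
  }
  if (angle_max >= 180) {
    stop_invalid("angle_max must be below 180 degrees: ",
                 "field magnitude is 180-degree periodic in coil orientation")
  }
  if (standoff < 0) stop_invalid("standoff must be non-negative")
  m <- floor(search_radius / spacing)
  g <- seq.int(-m, m) * spacing
  pos <- expand.grid(x = g, y = g, KEEP.OUT.ATTRS = FALSE)
  pos <- pos[pos$x^2 + pos$y^2 <= search_radius^2, , drop = FALSE]
  pos <- pos[order(pos$y, pos$x), , drop = FALSE]
  angles <- seq(0, angle_max, by = angle_step)
  out <- data.frame(
    x = rep(pos$x, each = length(angles)),
    y = rep(pos$y, each = length(angles)),
    alpha = rep(angles, times = nrow(pos)),
    standoff = standoff)
  out <- cbind(config_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Parametric field-model parameters
#'
#' Parameters of the synthetic |E| model standing in for FEM simulation.
#' `peak` is the field magnitude (V/m) directly under the coil on a crown
#' compartment at the 1%-MSO reference intensity; `lambda` the lateral
#' Gaussian spread (mm) at the cortical surface; `delta` the exponential
#' depth-attenuation scale (mm); `beta` the orientation-sensitivity
#' amplitude of the `1 + beta * cos(2 * (alpha - phi))` term (180-degree
#' periodic, like a figure-of-eight coil); `spread_rate` the growth of the
#' lateral spread per mm of coil-to-compartment distance,
#' `lambda_k = lambda + spread_rate * (depth_k + standoff)`. The spread
#' growth reproduces the focality loss with depth of induced fields: deep
#' compartments see smoother, more mutually correlated maps, which is what
#' makes representations inside a fold genuinely harder to localize.
#'
#' @param peak V/m at the reference intensity.
#' @param lambda mm.
#' @param delta mm.
#' @param beta dimensionless in `[0, 1)`.
#' @param spread_rate dimensionless (mm of extra lateral spread per mm of
#'   depth; >= 0).
#' @return A list of class `field_model`.
#' @export
field_model <- function(peak = 1.5, lambda = 10, delta = 12, beta = 0.2,
                        spread_rate = 0.5) {
  if (peak <= 0) stop_invalid("peak must be positive")
  if (lambda <= 0 || delta <= 0) stop_invalid("lambda and delta must be positive")
  if (beta < 0 || beta >= 1) stop_invalid("beta must be in [0, 1)")
  if (spread_rate < 0) stop_invalid("spread_rate must be non-negative")
  structure(list(peak = peak, lambda = lambda, delta = delta, beta = beta,
                 spread_rate = spread_rate),
            class = "field_model")
}

# Preferred per-compartment field direction phi (degrees, mod 180): in-plane
# direction of the local surface height gradient; falls back to 90 degrees
# (across the fold axis) where the surface is locally flat.
compartment_fold_direction <- function(mesh) {
  v <- mesh$vertices
  t <- mesh$triangles
  e1 <- v[t[, 2L], , drop = FALSE] - v[t[, 1L], , drop = FALSE]
  e2 <- v[t[, 3L], , drop = FALSE] - v[t[, 1L], , drop = FALSE]
  nx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  ny <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  nz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  gx <- -nx / nz
  gy <- -ny / nz
  phi <- (atan2(gy, gx) * 180 / pi) %% 180
  phi[sqrt(gx * gx + gy * gy) < 1e-9] <- 90
  phi
}

#' Synthetic |E| magnitude map for one coil configuration
#'
#' Parametric stand-in for an FEM electric-field simulation. For compartment
#' k at tangent-plane distance `rho_k` from the coil center and sulcal depth
#' `depth_k`, the field magnitude is
#' `peak * exp(-rho^2 / (2 lambda_k^2)) * exp(-(depth + standoff) / delta) *
#' (1 + beta * cos(2 * (alpha - phi_k)))`, clipped at 0, with the
#' depth-widened lateral spread `lambda_k` of [field_model()]. The magnitude
#' is 180-degree periodic in `alpha`, non-increasing in `rho` everywhere,
#' and non-increasing in `depth` near the coil axis (`rho` up to about
#' `lambda`; far off-axis, the spread growth lets deep compartments retain
#' relatively more field, as induced fields do).
#'
#' @param config a single-row coil configuration (data frame row or list with
#'   `x`, `y`, `alpha` and optionally `standoff`).
#' @param mesh an [roi_mesh()].
#' @param model a [field_model()].
#' @return An object of class `efield_map`: list with `values` (length-K,
#'   V/m), `config`, `intensity_scale`.
#' @export
synthetic_efield <- function(config, mesh, model = field_model()) {
  cfg <- as.list(config)
  standoff <- cfg$standoff %||% 0
  if (standoff < 0) stop_invalid("standoff must be non-negative")
  cen <- mesh$compartment_centers
  rho2 <- (cen[, 1L] - cfg$x)^2 + (cen[, 2L] - cfg$y)^2
  phi <- compartment_fold_direction(mesh)
  lam <- model$lambda + model$spread_rate * (mesh$depth + standoff)
  vals <- model$peak *
    exp(-rho2 / (2 * lam^2)) *
    exp(-(mesh$depth + standoff) / model$delta) *
    (1 + model$beta * cos(2 * (cfg$alpha - phi) * pi / 180))
  structure(list(values = pmax(vals, 0), config = cfg, intensity_scale = 1),
            class = "efield_map")
}

#' Candidate set of |E| maps
#'
#' Bundles an `Nc x K` matrix of field magnitudes (rows = coil
#' configurations, columns = ROI compartments) with the generating
#' configurations.
#'
#' @param maps numeric `Nc x K` matrix of |E| values (V/m, all >= 0, no row
#'   all-zero).
#' @param configs data frame of coil configurations with `Nc` rows; a
#'   placeholder table is created when omitted (useful for imported or toy
#'   matrices).
#' @param intensity_scale multiplier relative to the 1%-MSO reference.
#' @return An object of class `candidate_set`.
#' @export
candidate_set <- function(maps, configs = NULL, intensity_scale = 1) {
  maps <- as.matrix(maps)
  if (nrow(maps) < 1L) stop_invalid("candidate set must contain at least one map")
  if (any(!is.finite(maps)) || any(maps < 0)) {
    stop_invalid("|E| values must be finite and non-negative")
  }
  if (any(rowSums(maps) == 0)) {
    stop_invalid("candidate set contains an all-zero |E| map")
  }
  if (is.null(configs)) {
    configs <- data.frame(config_id = seq_len(nrow(maps)),
                          x = NA_real_, y = NA_real_, alpha = NA_real_,
                          standoff = 0)
  }
  if (nrow(configs) != nrow(maps)) {
    stop_invalid("row count of maps (", nrow(maps),
                 ") does not match config count (", nrow(configs), ")")
  }
  dimnames(maps) <- NULL
  structure(list(maps = maps, configs = configs,
                 intensity_scale = intensity_scale),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> ", nrow(x$maps), " coil configurations x ",
      ncol(x$maps), " compartments (intensity scale ",
      x$intensity_scale, ")\n", sep = "")
  invisible(x)
}

# Accept a candidate_set or a bare matrix wherever maps are consumed.
candidate_maps <- function(candidates) {
  if (inherits(candidates, "candidate_set")) return(candidates$maps)
  m <- as.matrix(candidates)
  dimnames(m) <- NULL
  m
}

#' Build the |E| maps for a whole configuration grid
#'
#' Evaluates the parametric field model for every coil configuration,
#' optionally scaling from the 1%-MSO reference to a stimulator intensity.
#' Computation is chunked over configurations to bound peak memory on large
#' (high-resolution) grids.
#'
#' @param mesh an [roi_mesh()].
#' @param configs configuration data frame from [generate_coil_grid()].
#' @param model a [field_model()].
#' @param percent_mso stimulation intensity in % of maximum stimulator
#'   output; the reference simulation corresponds to 1% MSO and scaling is
#'   linear.
#' @param chunk_size configurations per evaluation block.
#' @return A [candidate_set()].
#' @export
build_candidate_set <- function(mesh, configs, model = field_model(),
                                percent_mso = 1, chunk_size = 2048L) {
  if (percent_mso < 0) stop_invalid("percent_mso must be non-negative")
  cen <- mesh$compartment_centers
  phi <- compartment_fold_direction(mesh)
  K <- nrow(cen)
  Nc <- nrow(configs)
  standoff <- if (is.null(configs$standoff)) rep(0, Nc) else configs$standoff
  maps <- matrix(0, Nc, K)
  for (start in seq(1L, Nc, by = chunk_size)) {
    sel <- start:min(start + chunk_size - 1L, Nc)
    rho2 <- outer(configs$x[sel], cen[, 1L], "-")^2 +
      outer(configs$y[sel], cen[, 2L], "-")^2
    ori <- 1 + model$beta *
      cos(2 * pi / 180 * outer(configs$alpha[sel], phi, "-"))
    # depth + per-config standoff enter both the attenuation and the
    # depth-widened lateral spread
    dtot <- outer(standoff[sel], mesh$depth, "+")
    lam <- model$lambda + model$spread_rate * dtot
    block <- model$peak * exp(-rho2 / (2 * lam^2)) * ori *
      exp(-dtot / model$delta)
    maps[sel, ] <- pmax(block, 0)
  }
  cs <- candidate_set(maps, configs)
  if (percent_mso != 1) cs <- scale_to_intensity(cs, percent_mso) else cs
}

#' Scale |E| maps linearly with stimulator intensity
#'
#' Field magnitude scales linearly with stimulator output, so a map simulated
#' at the 1%-MSO reference is multiplied by `percent_mso`.
#'
#' @param x an `efield_map` or [candidate_set()].
#' @param percent_mso intensity in % MSO (>= 0).
#' @return The same class of object with scaled values and the cumulative
#'   `intensity_scale` recorded.
#' @export
scale_to_intensity <- function(x, percent_mso) {
  check_scalar_number(percent_mso, "percent_mso")
  if (percent_mso < 0) stop_invalid("percent_mso must be non-negative")
  if (inherits(x, "efield_map")) {
    x$values <- x$values * percent_mso
    x$intensity_scale <- x$intensity_scale * percent_mso
    return(x)
  }
  if (inherits(x, "candidate_set")) {
    if (percent_mso == 0) {
      stop_invalid("scaling a candidate set to zero intensity would violate ",
                   "the no-all-zero-map invariant")
    }
    x$maps <- x$maps * percent_mso
    x$intensity_scale <- x$intensity_scale * percent_mso
    return(x)
  }
  stop_invalid("x must be an efield_map or candidate_set")
}

#' Select compartments inside a cylindrical analysis ROI
#'
#' Keeps compartments whose centroid lies within the vertical cylinder of
#' the given radius about the ROI-center axis. The boundary is closed
#' (distance exactly equal to the radius is kept). Indices are sorted and
#' stable across calls.
#'
#' @param mesh an [roi_mesh()].
#' @param radius cylinder radius in mm (> 0); default 20.
#' @param center axis center; defaults to the mesh ROI center.
#' @param values optional per-compartment values over the full mesh to
#'   subset alongside.
#' @return List with `indices` (sorted integer vector) and, when `values`
#'   was given, `values` restricted to the selection.
#' @export
extract_cylindrical_roi <- function(mesh, radius = 20,
                                    center = NULL, values = NULL) {
  check_scalar_number(radius, "radius")
  if (radius <= 0) stop_invalid("radius must be positive")
  center <- center %||% mesh$roi_center
  cen <- mesh$compartment_centers
  d <- sqrt((cen[, 1L] - center[1L])^2 + (cen[, 2L] - center[2L])^2)
  idx <- which(d <= radius)
  if (length(idx) == 0L) stop_invalid("no compartments inside the cylinder")
  out <- list(indices = sort(idx))
  if (!is.null(values)) out$values <- values[out$indices]
  out
}

# --- candidate persistence --------------------------------------------------

CANDIDATE_SCHEMA <- "fpsmap-candidates v1"

#' Save / load a candidate set as CSV
#'
#' Single schema-versioned CSV: configuration columns followed by one column
#' per compartment (`E0001`, ...). Doubles are written with 17 significant
#' digits, so save/load round-trips the matrix exactly.
#'
#' @param candidates a [candidate_set()].
#' @param path file path.
#' @return `save_candidates` returns `path` invisibly; `load_candidates` the
#'   reconstructed [candidate_set()].
#' @export
save_candidates <- function(candidates, path) {
  stopifnot(inherits(candidates, "candidate_set"))
  K <- ncol(candidates$maps)
  emat <- candidates$maps
  colnames(emat) <- sprintf("E%04d", seq_len(K))
  df <- cbind(candidates$configs, as.data.frame(emat))
  df[] <- lapply(df, function(col) {
    if (is.double(col)) format_double(col) else col
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", CANDIDATE_SCHEMA,
                    " intensity_scale=",
                    format_double(candidates$intensity_scale)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_candidates
#' @export
load_candidates <- function(path) {
  header <- readLines(path, n = 1L)
  scale <- 1
  if (startsWith(header, "#")) {
    if (!grepl(CANDIDATE_SCHEMA, header, fixed = TRUE)) {
      stop_invalid("unrecognized candidate-set schema: ", header)
    }
    m <- regmatches(header, regexpr("intensity_scale=[-0-9.eE+]+", header))
    if (length(m) == 1L) scale <- as.numeric(sub("intensity_scale=", "", m))
  }
  df <- utils::read.csv(path, comment.char = "#")
  ecols <- grep("^E[0-9]+$", colnames(df))
  if (length(ecols) == 0L) stop_invalid("no |E| columns (E0001, ...) in file")
  if (nrow(df) == 0L) stop_invalid("candidate file contains no configurations")
  maps <- as.matrix(df[, ecols, drop = FALSE])
  candidate_set(maps, df[, -ecols, drop = FALSE], intensity_scale = scale)
}

#' Export coil configurations as 4x4 affine pose matrices
#'
#' One row per configuration with the flattened row-major 4x4 matrix mapping
#' the canonical coil frame (handle along +y at alpha = 0, coil normal -z)
#' to scanner-like coordinates: in-plane rotation by alpha about z, then
#' translation to (x, y, standoff). A text interchange format in the spirit
#' of FEM-toolbox pose files; the dialect is documented, not bit-cloned.
#'
#' @param configs configuration data frame.
#' @param path file path.
#' @return `path` invisibly.
#' @export
export_coil_affines <- function(configs, path) {
  rows <- lapply(seq_len(nrow(configs)), function(i) {
    a <- configs$alpha[i] * pi / 180
    m <- diag(4)
    m[1:2, 1:2] <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L)
    m[3L, 3L] <- -1
    m[1:3, 4L] <- c(configs$x[i], configs$y[i],
                    (configs$standoff %||% rep(0, nrow(configs)))[i])
    c(configs$config_id[i], as.vector(t(m)))
  })
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("config_id",
                     paste0("m", rep(1:4, each = 4L), rep(1:4, times = 4L)))
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
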