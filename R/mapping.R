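# Per-compartment sigmoid fitting, R^2 maps, normalized overlap score,
# peak geodesic distance, samples-to-criterion.

MIN_FIT_POINTS <- 4L  # 3 sigmoid parameters + 1

#' Fit the sigmoid input-output curve by Levenberg-Marquardt
#'
#' Least-squares fit of `y = ymax / (1 + exp(-slope * (x - x0)))` with
#' analytic Jacobian. Initialization: `ymax0 = max(y)`, `x00` = median of x
#' weighted by y, `slope0 = 4 * ymax0 / range(x)`; bounds
#' `ymax in (0, 2 * max(y)]`, `slope > 0`. The goodness of fit is the
#' coefficient of determination `r2 = 1 - SS_res / SS_tot`, floored at 0.
#' Degenerate data (constant response or constant predictor) and
#' non-convergent fits are flagged failed and carry `r2 = 0`.
#'
#' @param x numeric predictor (stimulation strength or per-compartment |E|);
#'   at least 4 finite values.
#' @param y non-negative MEP amplitudes (mV), same length.
#' @return List with `params` (named vector `x0`, `ymax`, `slope`), `r2` and
#'   `failed`.
#' @export
fit_sigmoid_lm <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop_invalid("x and y lengths differ")
  if (length(x) < MIN_FIT_POINTS) {
    stop_invalid("sigmoid fit needs at least ", MIN_FIT_POINTS,
                 " data points, got ", length(x))
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_invalid("x and y must be finite")
  }
  if (any(y < 0)) stop_invalid("MEP amplitudes must be non-negative")
  fit <- .fit_sigmoid_cpp(x, y)
  list(params = c(x0 = fit$x0, ymax = fit$ymax, slope = fit$slope),
       r2 = fit$r2, failed = !fit$converged)
}

#' R^2 motor map from a sample selection
#'
#' For every compartment k, fits the sigmoid of MEP amplitude against that
#' compartment's |E| across the selected stimulations and assembles the
#' per-compartment coefficients of determination into an R^2 map. The fit is
#' order-invariant in the (stimulation, MEP) pairs. Failed or degenerate
#' compartments carry `r2 = 0` and are flagged.
#'
#' @param selection a `sample_selection` or integer vector of candidate
#'   indices.
#' @param candidates a [candidate_set()] or maps matrix.
#' @param meps numeric MEP amplitudes, one per selected stimulation.
#' @return Object of class `r2_map`: `r2` (length-K in `[0, 1]`),
#'   `fitted_params` (K x 3 matrix), `failed` (logical K),
#'   `n_samples_used`.
#' @export
compute_r2_map <- function(selection, candidates, meps) {
  idx <- if (inherits(selection, "sample_selection")) {
    selection$order
  } else {
    as.integer(selection)
  }
  maps <- candidate_maps(candidates)
  if (length(meps) != length(idx)) {
    stop_invalid("MEP count (", length(meps),
                 ") does not match selection length (", length(idx), ")")
  }
  if (length(idx) < MIN_FIT_POINTS) {
    stop_invalid("selection shorter than the minimum fit size (",
                 MIN_FIT_POINTS, ")")
  }
  if (any(idx < 1L) || any(idx > nrow(maps))) {
    stop_invalid("selection indices out of range")
  }
  X <- maps[idx, , drop = FALSE]
  fit <- .fit_sigmoid_batch_cpp(X, as.numeric(meps))
  params <- cbind(x0 = fit$x0, ymax = fit$ymax, slope = fit$slope)
  structure(list(r2 = fit$r2, fitted_params = params,
                 failed = !fit$converged,
                 n_samples_used = length(idx)),
            class = "r2_map")
}

#' @export
print.r2_map <- function(x, ...) {
  cat("<r2_map> ", length(x$r2), " compartments from ", x$n_samples_used,
      " samples; peak r2 = ", sprintf("%.3f", max(x$r2)),
      " at compartment ", which.max(x$r2), "\n", sep = "")
  invisible(x)
}

# Extract the plain nonnegative map vector from the objects that can act as
# a motor map (r2_map, mgm, numeric vector).
map_values <- function(map) {
  if (inherits(map, "r2_map")) return(map$r2)
  if (inherits(map, "mgm")) return(map$m)
  as.numeric(map)
}

#' Normalized overlap score between two motor maps
#'
#' Inner product of the two maps after l2-normalization (cosine similarity):
#' `score = <ref, est> / (||ref|| * ||est||)`. For nonnegative maps the
#' score lies in `[0, 1]`; 1 is a perfect overlap (equality up to positive
#' scale) and 0 means disjoint support. Invariant under positive rescaling
#' of either map.
#'
#' @param ref,est reference and estimated maps: `r2_map`, [build_mgm()]
#'   objects or bare nonnegative vectors of equal length.
#' @return The score (dimensionless scalar).
#' @export
fitting_score <- function(ref, est) {
  a <- map_values(ref)
  b <- map_values(est)
  if (length(a) != length(b)) stop_invalid("maps differ in length")
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) {
    stop_invalid("overlap score undefined for an all-zero map")
  }
  sum(a * b) / (na * nb)
}

#' Geodesic distance between map peaks
#'
#' Distance between the peak (argmax) compartments of two maps; ties are
#' broken by the smallest compartment index.
#'
#' @param ref,est maps as in [fitting_score()].
#' @param gd K x K geodesic distance matrix.
#' @return Distance in mm (>= 0).
#' @export
peak_geodesic_distance <- function(ref, est, gd) {
  a <- map_values(ref)
  b <- map_values(est)
  if (length(a) != length(b)) stop_invalid("maps differ in length")
  gd <- as.matrix(gd)
  gd[which.max(a), which.max(b)]
}

#' Samples needed to reach a target overlap
#'
#' Smallest evaluated sample count whose score strictly exceeds the
#' threshold. Runs that never exceed the threshold within the budget are
#' censored and reported at the budget value.
#'
#' @param score_curve data frame with columns `n` (increasing) and `score`,
#'   or a numeric vector of scores with `n` given separately via attributes
#'   of the data frame form.
#' @param threshold overlap fraction in (0, 1); default 0.95.
#' @param budget sample budget for censoring.
#' @return List with `n95` (count) and `censored` (logical).
#' @export
samples_to_criterion <- function(score_curve, threshold = 0.95, budget) {
  if (threshold <= 0 || threshold >= 1) {
    stop_invalid("threshold must be inside (0, 1)")
  }
  if (NROW(score_curve) == 0L) stop_invalid("empty score curve")
  n <- score_curve$n
  score <- score_curve$score
  if (is.unsorted(n, strictly = TRUE)) {
    stop_invalid("score curve must be evaluated at increasing n")
  }
  hit <- which(score > threshold)
  if (length(hit) == 0L) {
    list(n95 = as.integer(budget), censored = TRUE)
  } else {
    list(n95 = as.integer(n[hit[1L]]), censored = FALSE)
  }
}

#' High-resolution reference map
#'
#' Fits the R^2 map from the full high-resolution candidate sample (one MEP
#' per configuration), the upper-performance-limit target subset maps are
#' scored against.
#'
#' @param hr_candidates a [candidate_set()] built on a dense
#'   (high-resolution) grid.
#' @param meps MEP amplitudes, one per HR configuration.
#' @return An `r2_map`.
#' @export
high_res_reference <- function(hr_candidates, meps) {
  maps <- candidate_maps(hr_candidates)
  compute_r2_map(seq_len(nrow(maps)), maps, meps)
}

#' Overlap score as a function of sample count
#'
#' Evaluates subset R^2 maps along a selection order at the given sample
#' counts and scores each against a reference map. Compartment maps that are
#' all-zero at small n score 0 (no recovered structure). With
#' `early_stop_threshold` set, evaluation stops at the first score strictly
#' above the threshold (the samples-to-criterion use case).
#'
#' @param selection a `sample_selection` or index vector (processed in
#'   order).
#' @param candidates a [candidate_set()] or maps matrix.
#' @param meps MEP amplitudes aligned with the selection order.
#' @param ref reference map ([fitting_score()] forms).
#' @param gd optional geodesic matrix; when given, the peak distance to the
#'   reference peak is recorded per evaluation.
#' @param eval_n increasing sample counts to evaluate (default: every other
#'   sample from the minimum fit size to the selection length).
#' @param early_stop_threshold optional overlap threshold for early
#'   stopping.
#' @return Data frame with columns `n`, `score` and (with `gd`)
#'   `peak_distance`.
#' @export
score_curve <- function(selection, candidates, meps, ref, gd = NULL,
                        eval_n = NULL, early_stop_threshold = NULL) {
  idx <- if (inherits(selection, "sample_selection")) {
    selection$order
  } else {
    as.integer(selection)
  }
  maps <- candidate_maps(candidates)
  if (length(meps) != length(idx)) {
    stop_invalid("MEP count does not match selection length")
  }
  if (is.null(eval_n)) {
    eval_n <- seq(MIN_FIT_POINTS, length(idx), by = 2L)
  }
  ref_v <- map_values(ref)
  peak_ref <- which.max(ref_v)
  rows <- vector("list", length(eval_n))
  used <- 0L
  for (n in eval_n) {
    if (n > length(idx)) break
    sub <- idx[seq_len(n)]
    fit <- .fit_sigmoid_batch_cpp(maps[sub, , drop = FALSE],
                                  as.numeric(meps[seq_len(n)]))
    r2 <- fit$r2
    sc <- if (all(r2 == 0)) 0 else {
      sum(ref_v * r2) / (sqrt(sum(ref_v^2)) * sqrt(sum(r2^2)))
    }
    used <- used + 1L
    rows[[used]] <- if (is.null(gd)) {
      data.frame(n = as.integer(n), score = sc)
    } else {
      data.frame(n = as.integer(n), score = sc,
                 peak_distance = gd[peak_ref, which.max(r2)])
    }
    if (!is.null(early_stop_threshold) && sc > early_stop_threshold) break
  }
  do.call(rbind, rows[seq_len(used)])
}

#' Persist an R^2 map as CSV
#'
#' @param r2map an `r2_map`.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_r2_map <- function(r2map, path) {
  df <- data.frame(compartment_id = seq_along(r2map$r2), r2 = r2map$r2,
                   x0 = r2map$fitted_params[, "x0"],
                   ymax = r2map$fitted_params[, "ymax"],
                   slope = r2map$fitted_params[, "slope"],
                   failed = r2map$failed)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
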