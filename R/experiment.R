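# Experiment orchestration: synthetic fixture, placement sweep, FPS-vs-random
# subsampling comparison, summary statistics.

#' Experiment configuration
#'
#' Collects all knobs of the synthetic mapping experiments with the
#' package's default study conditions: a folded patch (radius 25 mm,
#' wavelength 24 mm, amplitude 7 mm, about 1560 compartments) restricted to
#' a 20 mm analysis cylinder (about 1000 compartments); a sampling grid of
#' 30 mm / 5 mm spacing / 10-degree angles (2034 candidate configurations)
#' and a high-resolution grid of 2 mm / 10 degrees (12,762 configurations);
#' mapping intensity 60% MSO; MGM width 5 mm; sigmoid saturation 1 mV with
#' noise amplitude 0.2 mV; budget 150 samples per method, evaluation stride
#' 2, overlap threshold 0.95; 10 sampling seeds crossed with 5 noise seeds
#' (50 paired runs per method and placement).
#'
#' @param n_compartments,fold_amplitude,fold_wavelength,patch_radius,mesh_seed
#'   patch geometry (see [build_synthetic_roi()]).
#' @param roi_radius analysis-cylinder radius in mm.
#' @param search_radius,spacing,angle_step,angle_max sampling-grid
#'   parameters (see [generate_coil_grid()]).
#' @param hr_spacing,hr_angle_step high-resolution grid parameters.
#' @param percent_mso mapping intensity in % MSO.
#' @param field a [field_model()].
#' @param sigma MGM width in mm.
#' @param ymax,noise_rel sigmoid saturation (mV) and noise amplitude as a
#'   fraction of `ymax`.
#' @param placements character vector of MGM placements
#'   (`crown-center`, `wall-center`, `crown-edge`, `fundus-center`) or a
#'   list of explicit compartment indices.
#' @param budget sampler budget Ns per run.
#' @param stride score-curve evaluation stride (every other sample by
#'   default).
#' @param threshold overlap threshold in (0, 1).
#' @param sampling_seeds,noise_seeds non-empty integer seed vectors; runs
#'   are their Cartesian product, paired across methods.
#' @param reference reference-map mode: `hr` (high-resolution map),
#'   `mgm` (the generating map) or `all-samples` (map fitted from every
#'   candidate under the run's noise).
#' @param hr_noise_seed seed for the HR reference MEP noise.
#' @param store_curves keep the full score curves (disables early stopping).
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(n_compartments = 1560L, fold_amplitude = 7,
                              fold_wavelength = 24, patch_radius = 25,
                              mesh_seed = 101L, roi_radius = 20,
                              search_radius = 30, spacing = 5,
                              angle_step = 10, angle_max = 170,
                              hr_spacing = 2, hr_angle_step = 10,
                              percent_mso = 60, field = field_model(),
                              sigma = 5, ymax = 1, noise_rel = 0.2,
                              placements = c("crown-center", "wall-center",
                                             "crown-edge"),
                              budget = 150L, stride = 2L, threshold = 0.95,
                              sampling_seeds = 1:10, noise_seeds = 1:5,
                              reference = c("hr", "mgm", "all-samples"),
                              hr_noise_seed = 9001L,
                              store_curves = FALSE) {
  reference <- match.arg(reference)
  if (length(sampling_seeds) == 0L || length(noise_seeds) == 0L) {
    stop_invalid("seed lists must be non-empty")
  }
  if (threshold <= 0 || threshold >= 1) {
    stop_invalid("threshold must be inside (0, 1)")
  }
  if (budget < MIN_FIT_POINTS) {
    stop_invalid("budget must allow at least one fit (>= ",
                 MIN_FIT_POINTS, ")")
  }
  if (stride < 1L) stop_invalid("stride must be at least 1")
  structure(
    list(n_compartments = n_compartments, fold_amplitude = fold_amplitude,
         fold_wavelength = fold_wavelength, patch_radius = patch_radius,
         mesh_seed = as.integer(mesh_seed), roi_radius = roi_radius,
         search_radius = search_radius, spacing = spacing,
         angle_step = angle_step, angle_max = angle_max,
         hr_spacing = hr_spacing, hr_angle_step = hr_angle_step,
         percent_mso = percent_mso, field = field, sigma = sigma,
         ymax = ymax, noise_rel = noise_rel, placements = placements,
         budget = as.integer(budget), stride = as.integer(stride),
         threshold = threshold,
         sampling_seeds = as.integer(sampling_seeds),
         noise_seeds = as.integer(noise_seeds), reference = reference,
         hr_noise_seed = as.integer(hr_noise_seed),
         store_curves = store_curves),
    class = "experiment_config")
}

#' Build the synthetic study fixture for a configuration
#'
#' Generates the folded patch, restricts it to the cylindrical analysis ROI,
#' computes compartment geodesics and evaluates the candidate |E| maps at
#' the mapping intensity.
#'
#' @param config an [experiment_config()].
#' @return List of class `experiment_fixture` with `mesh`, `gd`,
#'   `candidates` and `config`.
#' @export
build_experiment_fixture <- function(config = experiment_config()) {
  patch <- build_synthetic_roi(config$n_compartments, config$fold_amplitude,
                               config$fold_wavelength, config$patch_radius,
                               seed = config$mesh_seed)
  roi <- extract_cylindrical_roi(patch, radius = config$roi_radius)
  mesh <- subset_mesh(patch, roi$indices)
  gd <- geodesic_distance_matrix(mesh)
  grid <- generate_coil_grid(config$search_radius, config$spacing,
                             config$angle_step, config$angle_max)
  cs <- build_candidate_set(mesh, grid, config$field,
                            percent_mso = config$percent_mso)
  structure(list(mesh = mesh, gd = gd, candidates = cs, config = config),
            class = "experiment_fixture")
}

#' Pick the MGM compartment for a named placement
#'
#' Placements are defined on the depth bands of [depth_bands()]:
#' `crown-center` and `wall-center` take the band member closest to the ROI
#' center (in-plane), `crown-edge` the crown member farthest from it and
#' `fundus-center` the fundus member closest to it. Ties resolve to the
#' smallest compartment index.
#'
#' @param mesh an [roi_mesh()].
#' @param where placement name, or an integer taken as an explicit
#'   compartment index.
#' @return Compartment index.
#' @export
placement_compartment <- function(mesh,
                                  where = c("crown-center", "wall-center",
                                            "crown-edge",
                                            "fundus-center")) {
  if (is.numeric(where)) {
    k <- as.integer(where)
    if (k < 1L || k > nrow(mesh$triangles)) {
      stop_invalid("compartment index out of range")
    }
    return(k)
  }
  where <- match.arg(where)
  band <- depth_bands(mesh$depth)
  cen <- mesh$compartment_centers
  r <- sqrt((cen[, 1L] - mesh$roi_center[1L])^2 +
              (cen[, 2L] - mesh$roi_center[2L])^2)
  pick_band <- switch(where,
                      "crown-center" = "crown", "crown-edge" = "crown",
                      "wall-center" = "wall", "fundus-center" = "fundus")
  i <- which(band == pick_band)
  if (length(i) == 0L) {
    stop_invalid("no compartments in the ", pick_band,
                 " band (flat patch?)")
  }
  if (where == "crown-edge") i[which.max(r[i])] else i[which.min(r[i])]
}

#' Sigmoid parameters of a study fixture
#'
#' Calibrates the MEP input-output parameters once per fixture, against the
#' crown-center MGM placement: the analog of fixing the stimulator intensity
#' relative to the resting motor threshold at the motor hotspot. The same
#' parameters are then used for every simulated representation placement, so
#' representations in attenuated-field regions (deep folds) are genuinely
#' harder to map, as in a fixed-intensity experiment.
#'
#' @param fixture a [build_experiment_fixture()] result.
#' @return A [mep_model_params()] object.
#' @export
fixture_mep_params <- function(fixture) {
  config <- fixture$config
  anchor <- placement_compartment(fixture$mesh, "crown-center")
  mgm0 <- build_mgm(fixture$gd, anchor, config$sigma)
  calibrate_mep_params(mgm0, fixture$candidates, ymax = config$ymax,
                       noise_rel = config$noise_rel)
}

# Build the HR candidate set for a config on an existing ROI mesh.
build_hr_candidates <- function(config, mesh) {
  grid <- generate_coil_grid(config$search_radius, config$hr_spacing,
                             config$hr_angle_step,
                             (180 / config$hr_angle_step - 1) *
                               config$hr_angle_step)
  build_candidate_set(mesh, grid, config$field,
                      percent_mso = config$percent_mso)
}

#' Placement sweep: achievable overlap by muscle-representation location
#'
#' For each requested compartment, places the MGM there, generates one noisy
#' MEP per candidate configuration of the dense sampling grid, fits the R^2
#' map from all samples and records the overlap score of the fitted map
#' against the generating MGM. Emits the per-compartment score map together
#' with the MDS-flattened coordinates and depths for plotting.
#'
#' @param config an [experiment_config()].
#' @param placements integer compartment indices to sweep; default all.
#' @param n_per_band alternatively, sweep this many evenly spaced
#'   compartments per depth band (overrides `placements = NULL` subsetting).
#' @param bands bands to include when `n_per_band` is used.
#' @param fixture optional pre-built [build_experiment_fixture()] result.
#' @return List of class `placement_sweep` with `scores` (data frame:
#'   `compartment`, `depth`, `band`, `score`), `flat` (K x 2 MDS
#'   coordinates), `depth` and `config`.
#' @export
run_placement_sweep <- function(config = experiment_config(),
                                placements = NULL, n_per_band = NULL,
                                bands = c("crown", "wall", "fundus"),
                                fixture = NULL) {
  fx <- fixture %||% build_experiment_fixture(config)
  mesh <- fx$mesh
  band <- depth_bands(mesh$depth)
  K <- nrow(mesh$triangles)
  if (is.null(placements)) {
    if (is.null(n_per_band)) {
      placements <- seq_len(K)
    } else {
      placements <- unlist(lapply(bands, function(b) {
        members <- which(band == b)
        if (length(members) == 0L) return(integer())
        members[unique(round(seq(1L, length(members),
                                 length.out = min(n_per_band,
                                                  length(members)))))]
      }))
    }
  }
  params <- fixture_mep_params(fx)
  rows <- lapply(placements, function(k) {
    mgm <- build_mgm(fx$gd, k, config$sigma)
    sim <- simulate_meps(mgm, fx$candidates, params,
                         noise_seed = config$noise_seeds[1L] + 1000L * k)
    r2 <- compute_r2_map(seq_len(nrow(fx$candidates$maps)),
                         fx$candidates, sim$y_noisy)$r2
    sc <- if (all(r2 == 0)) 0 else fitting_score(mgm$m, r2)
    data.frame(compartment = k, depth = mesh$depth[k],
               band = as.character(band[k]), score = sc)
  })
  structure(list(scores = do.call(rbind, rows), flat = flatten_mds(fx$gd),
                 depth = mesh$depth, config = config),
            class = "placement_sweep")
}

#' FPS-versus-random subsampling experiment
#'
#' The package's main benchmark. For every MGM placement and every
#' (sampling seed, noise seed) pair, both samplers draw a budget of
#' configurations from the candidate set; MEPs are simulated with a noise
#' stream indexed by candidate (identical for both methods of a pair);
#' subset R^2 maps are fitted every `stride` samples and scored against the
#' configured reference map; the samples-to-criterion count n95 is recorded,
#' censored at the budget. FPS selections depend only on the candidate maps
#' and the sampling seed, so they are computed once per seed and shared
#' across placements and noise seeds.
#'
#' @param config an [experiment_config()].
#' @param fixture optional pre-built fixture (for reuse across analyses).
#' @param verbose print per-placement progress.
#' @return List of class `experiment_result`: `runs` (tidy data frame with
#'   `method`, `placement`, `sampling_seed`, `noise_seed`, `n95`,
#'   `censored`, `score_final`, `peak_distance_final`), `curves` (per-step
#'   records when `store_curves`), `placement_k` (chosen compartments),
#'   `config`, and fixture sizes `K`, `Nc`.
#' @export
run_subsampling_experiment <- function(config = experiment_config(),
                                       fixture = NULL,
                                       verbose = FALSE) {
  fx <- fixture %||% build_experiment_fixture(config)
  maps <- fx$candidates$maps
  Nc <- nrow(maps)
  K <- ncol(maps)
  if (config$budget > Nc) {
    stop_invalid("budget (", config$budget,
                 ") exceeds candidate count (", Nc, ")")
  }
  eval_n <- seq(config$stride, config$budget, by = config$stride)
  eval_n <- eval_n[eval_n >= MIN_FIT_POINTS]
  if (length(eval_n) == 0L) stop_invalid("no evaluable sample counts")

  selections <- list(
    fps = lapply(config$sampling_seeds, function(s) {
      fps_sample(maps, config$budget, seed = s)$order
    }),
    random = lapply(config$sampling_seeds, function(s) {
      random_sample(maps, config$budget, seed = s)$order
    }))

  placement_names <- if (is.list(config$placements)) {
    vapply(config$placements, as.character, character(1L))
  } else {
    as.character(config$placements)
  }
  placement_k <- vapply(seq_along(placement_names), function(i) {
    placement_compartment(fx$mesh,
                          if (is.list(config$placements)) {
                            config$placements[[i]]
                          } else {
                            config$placements[i]
                          })
  }, integer(1L))
  names(placement_k) <- placement_names

  params <- fixture_mep_params(fx)
  run_rows <- list()
  curve_rows <- list()
  for (p in seq_along(placement_names)) {
    kmax <- placement_k[p]
    mgm <- build_mgm(fx$gd, kmax, config$sigma)
    ref_fixed <- switch(
      config$reference,
      mgm = mgm$m,
      hr = {
        hrcs <- build_hr_candidates(config, fx$mesh)
        hr_sim <- simulate_meps(mgm, hrcs, params,
                                noise_seed = config$hr_noise_seed + p)
        hr_map <- high_res_reference(hrcs, hr_sim$y_noisy)$r2
        rm(hrcs, hr_sim)
        hr_map
      },
      `all-samples` = NULL)
    if (verbose) {
      message("placement ", placement_names[p], " (compartment ", kmax, ")")
    }
    for (ns in config$noise_seeds) {
      sim <- simulate_meps(mgm, fx$candidates, params, noise_seed = ns)
      y_noisy <- sim$y_noisy
      ref_v <- ref_fixed %||%
        compute_r2_map(seq_len(Nc), fx$candidates, y_noisy)$r2
      for (method in c("fps", "random")) {
        for (si in seq_along(config$sampling_seeds)) {
          ord <- selections[[method]][[si]]
          cur <- score_curve(
            ord, maps, y_noisy[ord], ref_v, gd = fx$gd, eval_n = eval_n,
            early_stop_threshold = if (config$store_curves) NULL else
              config$threshold)
          crit <- samples_to_criterion(cur, config$threshold,
                                       config$budget)
          last <- nrow(cur)
          run_rows[[length(run_rows) + 1L]] <- data.frame(
            method = method, placement = placement_names[p],
            sampling_seed = config$sampling_seeds[si], noise_seed = ns,
            n95 = crit$n95, censored = crit$censored,
            score_final = cur$score[last],
            peak_distance_final = cur$peak_distance[last])
          if (config$store_curves) {
            curve_rows[[length(curve_rows) + 1L]] <- cbind(
              method = method, placement = placement_names[p],
              sampling_seed = config$sampling_seeds[si], noise_seed = ns,
              cur)
          }
        }
      }
    }
  }
  structure(list(runs = do.call(rbind, run_rows),
                 curves = if (config$store_curves) {
                   do.call(rbind, curve_rows)
                 } else {
                   NULL
                 },
                 placement_k = placement_k, config = config,
                 K = K, Nc = Nc),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> ", nrow(x$runs), " runs over ",
      length(x$placement_k), " placements (K = ", x$K, ", Nc = ", x$Nc,
      ")\n", sep = "")
  invisible(x)
}

#' Summary statistics of samples-to-criterion
#'
#' Per method and placement (plus a pooled `all` row per method): number of
#' runs, mean, standard deviation, median and the 5th/95th percentiles of
#' n95, with the censored-run count. Censored runs enter at the budget
#' value. Percentiles interpolate linearly between closest ranks
#' (`stats::quantile` type 7). A pure function of the per-run table.
#'
#' @param result an `experiment_result` (or any list with a `runs` data
#'   frame holding `method`, `placement`, `n95`, `censored`).
#' @return Data frame of summary rows.
#' @export
summarize_experiment <- function(result) {
  runs <- if (is.data.frame(result)) result else result$runs
  if (is.null(runs) || nrow(runs) == 0L) stop_invalid("empty result")
  one <- function(df, method, placement) {
    q <- stats::quantile(df$n95, c(0.05, 0.5, 0.95), names = FALSE,
                         type = 7)
    data.frame(method = method, placement = placement,
               n_runs = nrow(df), mean = mean(df$n95),
               sd = stats::sd(df$n95), median = q[2L], p05 = q[1L],
               p95 = q[3L], n_censored = sum(df$censored))
  }
  out <- list()
  for (m in unique(runs$method)) {
    sub_m <- runs[runs$method == m, , drop = FALSE]
    for (p in unique(sub_m$placement)) {
      out[[length(out) + 1L]] <-
        one(sub_m[sub_m$placement == p, , drop = FALSE], m, p)
    }
    out[[length(out) + 1L]] <- one(sub_m, m, "all")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
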