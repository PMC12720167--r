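# Farthest point sampling over |E| maps, random baseline, brute-force oracle.

new_selection <- function(order, method, seed, trace) {
  structure(list(order = as.integer(order), method = method,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 min_dist_trace = trace),
            class = "sample_selection")
}

#' @export
print.sample_selection <- function(x, ...) {
  cat("<sample_selection> ", x$method, ", ", length(x$order),
      " samples, first index ", x$order[1L], "\n", sep = "")
  invisible(x)
}

# Euclidean distances from candidate row j to every row of maps.
row_distances <- function(maps, j) {
  dif <- maps - rep(maps[j, ], each = nrow(maps))
  sqrt(.rowSums(dif * dif, nrow(maps), ncol(maps)))
}

check_sample_args <- function(maps, n_samples) {
  if (nrow(maps) < 1L) stop_invalid("empty candidate set")
  if (n_samples < 1L || n_samples > nrow(maps)) {
    stop_invalid("n_samples must be between 1 and the candidate count (",
                 nrow(maps), ")")
  }
}

#' Farthest point sampling of coil configurations
#'
#' Greedy max-min selection over |E| maps: the first sample is drawn
#' uniformly at random (or forced via `first_index`); each subsequent sample
#' is the candidate whose minimum Euclidean distance to all already-selected
#' maps is largest. Ties in the argmax are broken by the smallest candidate
#' index, so results are deterministic across platforms. The selection order
#' is invariant to a global positive rescaling of the maps.
#'
#' The implementation maintains, per candidate, its current minimum distance
#' to the selected set (cost `O(Nc * K)` per step) and is exactly equivalent
#' to the from-scratch [fps_bruteforce_oracle()].
#'
#' @param candidates a [candidate_set()] or bare `Nc x K` matrix.
#' @param n_samples number of configurations to select (1..Nc).
#' @param seed integer seed for the random first sample (ignored when
#'   `first_index` is given).
#' @param first_index optional forced first candidate index.
#' @return A `sample_selection`: `order` (selected indices), `method`,
#'   `seed`, and `min_dist_trace` (the selected sample's min distance to the
#'   previously selected set; `NA` for the first sample). The trace is
#'   non-increasing from step 2 onward.
#' @export
fps_sample <- function(candidates, n_samples, seed = NULL,
                       first_index = NULL) {
  maps <- candidate_maps(candidates)
  check_sample_args(maps, n_samples)
  nc <- nrow(maps)
  if (!is.null(first_index)) {
    first_index <- as.integer(first_index)
    if (first_index < 1L || first_index > nc) {
      stop_invalid("first_index out of range")
    }
    first <- first_index
  } else {
    first <- with_seed(seed, sample.int(nc, 1L))
  }
  ord <- integer(n_samples)
  trace <- rep(NA_real_, n_samples)
  ord[1L] <- first
  if (n_samples > 1L) {
    mind <- row_distances(maps, first)
    mind[first] <- -Inf
    for (n in 2:n_samples) {
      j <- which.max(mind)
      ord[n] <- j
      trace[n] <- mind[j]
      mind[j] <- -Inf
      if (n < n_samples) mind <- pmin(mind, row_distances(maps, j))
    }
  }
  new_selection(ord, "fps", seed, trace)
}

#' Uniform random sampling baseline
#'
#' Draws configurations uniformly without replacement: the candidate set is
#' finite and experimental designs use distinct configurations.
#'
#' @inheritParams fps_sample
#' @return A `sample_selection` with `method = "random"` (the min-distance
#'   trace is not computed and holds `NA`).
#' @export
random_sample <- function(candidates, n_samples, seed = NULL) {
  maps <- candidate_maps(candidates)
  check_sample_args(maps, n_samples)
  ord <- with_seed(seed, sample.int(nrow(maps), n_samples))
  new_selection(ord, "random", seed, rep(NA_real_, n_samples))
}

#' Brute-force farthest-point-sampling oracle
#'
#' Re-evaluates the greedy max-min condition from scratch at every step with
#' no incremental caching, using the same distance expression and the same
#' smallest-index tie rule as [fps_sample()]. Intended as a test oracle on
#' small candidate sets; cost is `O(Ns^2 * Nc * K)`.
#'
#' @inheritParams fps_sample
#' @param first_index first candidate index (required: the oracle takes no
#'   RNG).
#' @return A `sample_selection` identical to the one [fps_sample()] returns
#'   for the same first index.
#' @export
fps_bruteforce_oracle <- function(candidates, n_samples, first_index) {
  maps <- candidate_maps(candidates)
  check_sample_args(maps, n_samples)
  nc <- nrow(maps)
  first_index <- as.integer(first_index)
  if (first_index < 1L || first_index > nc) {
    stop_invalid("first_index out of range")
  }
  selected <- first_index
  trace <- rep(NA_real_, n_samples)
  while (length(selected) < n_samples) {
    best_c <- 0L
    best_d <- -Inf
    for (cand in seq_len(nc)) {
      if (cand %in% selected) next
      dmin <- Inf
      for (j in selected) {
        d <- sqrt(sum((maps[cand, ] - maps[j, ])^2))
        if (d < dmin) dmin <- d
      }
      if (dmin > best_d) {
        best_d <- dmin
        best_c <- cand
      }
    }
    selected <- c(selected, best_c)
    trace[length(selected)] <- best_d
  }
  new_selection(selected, "fps", NULL, trace)
}

#' Write a selection to CSV
#'
#' Tidy per-step table (step, candidate_index, x, y, alpha, min_dist) for
#' hand-off to neuronavigation tooling.
#'
#' @param selection a `sample_selection`.
#' @param candidates the [candidate_set()] it was drawn from.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_selection <- function(selection, candidates, path) {
  cfg <- candidates$configs[selection$order, , drop = FALSE]
  df <- data.frame(step = seq_along(selection$order),
                   candidate_index = selection$order,
                   x = cfg$x, y = cfg$y, alpha = cfg$alpha,
                   min_dist = selection$min_dist_trace)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
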