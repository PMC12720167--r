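# Synthetic folded-cortex ROI geometry, compartment geodesics, MDS flattening.

#' Construct a cortical ROI mesh from raw components
#'
#' Builds the triangulated region-of-interest (ROI) surface object used
#' throughout the package. Compartments are the mesh triangles; each
#' compartment carries its centroid and a sulcal depth (mm, 0 = gyral crown).
#' Depths are shifted so the shallowest compartment sits exactly at 0.
#'
#' @param vertices numeric matrix (V x 3) of vertex coordinates in mm.
#' @param triangles integer matrix (K x 3) of vertex index triples (1-based).
#' @param depth optional numeric vector of per-compartment sulcal depths (mm);
#'   defaults to all zero (a flat patch).
#' @param roi_center numeric length-3 ROI center coordinate (mm).
#' @return An object of class `roi_mesh` with fields `vertices`, `triangles`,
#'   `compartment_centers`, `depth` and `roi_center`.
#' @export
roi_mesh <- function(vertices, triangles, depth = NULL,
                     roi_center = c(0, 0, 0)) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3L)
  if (ncol(vertices) != 3L) stop_invalid("vertices must be a V x 3 matrix")
  K <- nrow(triangles)
  if (K < 3L) stop_invalid("a ROI mesh needs at least 3 compartments")
  if (any(triangles < 1L) || any(triangles > nrow(vertices))) {
    stop_invalid("triangle indices out of range")
  }
  centers <- (vertices[triangles[, 1L], , drop = FALSE] +
                vertices[triangles[, 2L], , drop = FALSE] +
                vertices[triangles[, 3L], , drop = FALSE]) / 3
  if (is.null(depth)) depth <- rep(0, K)
  if (length(depth) != K || any(!is.finite(depth))) {
    stop_invalid("depth must be one finite value per compartment")
  }
  depth <- depth - min(depth)
  structure(
    list(vertices = vertices, triangles = triangles,
         compartment_centers = centers, depth = as.numeric(depth),
         roi_center = as.numeric(roi_center)),
    class = "roi_mesh")
}

#' @export
print.roi_mesh <- function(x, ...) {
  cat("<roi_mesh> ", nrow(x$triangles), " compartments, ",
      nrow(x$vertices), " vertices, max depth ",
      sprintf("%.2f", max(x$depth)), " mm\n", sep = "")
  invisible(x)
}

#' Generate a synthetic folded cortical patch
#'
#' Builds a disc-like triangulated patch of the requested radius with a
#' sinusoidal fold along one axis, a lightweight stand-in for a gyral
#' crown / sulcal wall / fundus geometry. The height field is
#' `z = A * sin(2 * pi * y / lambda)`; sulcal depth is the vertical drop from
#' the crown envelope, `A - z`, shifted so the shallowest compartment has
#' depth 0. Vertex positions are jittered (seeded) so compartment layout is
#' irregular, as on a real surface extraction.
#'
#' @param n_compartments target number of triangles (>= 3); the realized
#'   count varies slightly with the disc boundary.
#' @param fold_amplitude fold amplitude A in mm (0 gives a flat disc).
#' @param fold_wavelength fold wavelength lambda in mm (> 0).
#' @param radius patch radius in mm (> 0).
#' @param seed integer seed for the vertex jitter; identical inputs give
#'   bitwise-identical meshes.
#' @param jitter jitter magnitude as a fraction of the grid step (< 0.5 keeps
#'   all triangles non-degenerate).
#' @return An [roi_mesh()] object.
#' @export
build_synthetic_roi <- function(n_compartments = 1500L, fold_amplitude = 7,
                                fold_wavelength = 24, radius = 25,
                                seed = 1L, jitter = 0.2) {
  check_scalar_number(n_compartments, "n_compartments")
  check_scalar_number(radius, "radius")
  check_scalar_number(fold_wavelength, "fold_wavelength")
  check_scalar_number(fold_amplitude, "fold_amplitude")
  if (n_compartments < 3) stop_invalid("n_compartments must be at least 3")
  if (radius <= 0) stop_invalid("radius must be positive")
  if (fold_wavelength <= 0) stop_invalid("fold_wavelength must be positive")
  if (fold_amplitude < 0) stop_invalid("fold_amplitude must be non-negative")

  # grid step chosen so 2 * area / h^2 ~ n_compartments
  h <- radius * sqrt(2 * pi / n_compartments)
  g <- seq(-(radius + h), radius + h, by = h)
  nx <- length(g)
  vx <- rep(g, times = nx)
  vy <- rep(g, each = nx)
  jit <- with_seed(seed,
                   matrix(stats::runif(2L * nx * nx, -jitter * h, jitter * h),
                          ncol = 2L))
  vx <- vx + jit[, 1L]
  vy <- vy + jit[, 2L]
  vz <- if (fold_amplitude > 0) {
    fold_amplitude * sin(2 * pi * vy / fold_wavelength)
  } else {
    rep(0, length(vx))
  }

  ix <- rep(seq_len(nx - 1L), times = nx - 1L)
  iy <- rep(seq_len(nx - 1L), each = nx - 1L)
  v1 <- (iy - 1L) * nx + ix
  v2 <- v1 + 1L
  v3 <- v1 + nx
  v4 <- v3 + 1L
  tris <- rbind(cbind(v1, v2, v3), cbind(v2, v4, v3))

  cx <- (vx[tris[, 1L]] + vx[tris[, 2L]] + vx[tris[, 3L]]) / 3
  cy <- (vy[tris[, 1L]] + vy[tris[, 2L]] + vy[tris[, 3L]]) / 3
  keep <- cx * cx + cy * cy <= radius * radius
  tris <- tris[keep, , drop = FALSE]
  if (nrow(tris) < 3L) stop_invalid("patch too small: fewer than 3 compartments")

  used <- sort(unique(as.vector(tris)))
  remap <- integer(length(vx))
  remap[used] <- seq_along(used)
  tris <- matrix(remap[tris], ncol = 3L)
  vertices <- cbind(vx[used], vy[used], vz[used])
  colnames(vertices) <- c("x", "y", "z")

  mesh <- roi_mesh(vertices, tris, depth = rep(0, nrow(tris)))
  ycen <- mesh$compartment_centers[, 2L]
  depth_raw <- fold_amplitude -
    fold_amplitude * sin(2 * pi * ycen / fold_wavelength)
  mesh$depth <- depth_raw - min(depth_raw)

  # keep only the largest edge-connected component (rarely, a sliver of
  # boundary triangles survives the centroid test without an edge neighbour)
  ed <- compartment_edges(mesh)
  gr <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(tris))))
  comp <- igraph::components(gr)
  if (comp$no > 1L) {
    main <- which.max(comp$csize)
    mesh <- subset_mesh(mesh, which(comp$membership == main))
  }
  mesh$fold_amplitude <- fold_amplitude
  mesh$fold_wavelength <- fold_wavelength
  mesh$radius <- radius
  mesh$seed <- as.integer(seed)
  mesh
}

#' Restrict a ROI mesh to a subset of compartments
#'
#' Keeps the given compartments (triangles), drops unused vertices and
#' re-normalizes depth so the shallowest kept compartment has depth 0.
#'
#' @param mesh an [roi_mesh()].
#' @param idx integer compartment indices to keep.
#' @return A new `roi_mesh`.
#' @export
subset_mesh <- function(mesh, idx) {
  idx <- sort(unique(as.integer(idx)))
  if (any(idx < 1L) || any(idx > nrow(mesh$triangles))) {
    stop_invalid("compartment indices out of range")
  }
  tris <- mesh$triangles[idx, , drop = FALSE]
  used <- sort(unique(as.vector(tris)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  out <- roi_mesh(mesh$vertices[used, , drop = FALSE],
                  matrix(remap[tris], ncol = 3L),
                  depth = mesh$depth[idx],
                  roi_center = mesh$roi_center)
  for (f in c("fold_amplitude", "fold_wavelength", "radius", "seed")) {
    if (!is.null(mesh[[f]])) out[[f]] <- mesh[[f]]
  }
  out
}

#' Compartment adjacency edges of a ROI mesh
#'
#' Two compartments are adjacent when their triangles share a mesh vertex
#' (`adjacency = "vertex"`, the default: the usual one-ring neighbourhood)
#' or a full mesh edge (`adjacency = "edge"`, the manifold-dual graph).
#' Edge weights are Euclidean distances between compartment centroids; this
#' graph is the backend for the geodesic distance computation and defines
#' what "one graph edge" means for peak-localization checks.
#'
#' @param mesh an [roi_mesh()].
#' @param adjacency `"vertex"` (default) or `"edge"`.
#' @return A data frame with columns `from`, `to`, `weight` (mm), each
#'   unordered pair listed once.
#' @export
compartment_edges <- function(mesh, adjacency = c("vertex", "edge")) {
  adjacency <- match.arg(adjacency)
  tri <- mesh$triangles
  K <- nrow(tri)
  if (adjacency == "edge") {
    ee <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(1L, 3L)])
    a <- pmin(ee[, 1L], ee[, 2L])
    b <- pmax(ee[, 1L], ee[, 2L])
    key <- a * (nrow(mesh$vertices) + 1) + b
    tid <- rep(seq_len(K), times = 3L)
    ord <- order(key, tid)
    key <- key[ord]
    tid <- tid[ord]
    shared <- which(key[-1L] == key[-length(key)])
    from <- tid[shared]
    to <- tid[shared + 1L]
  } else {
    stars <- split(rep(seq_len(K), times = 3L), as.vector(tri))
    pairs <- lapply(stars, function(s) {
      if (length(s) < 2L) return(NULL)
      t(utils::combn(sort(s), 2L))
    })
    pp <- unique(do.call(rbind, pairs))
    from <- pp[, 1L]
    to <- pp[, 2L]
  }
  d <- mesh$compartment_centers[from, , drop = FALSE] -
    mesh$compartment_centers[to, , drop = FALSE]
  data.frame(from = from, to = to, weight = sqrt(rowSums(d * d)))
}

#' Per-compartment triangle areas
#'
#' @param mesh an [roi_mesh()].
#' @return Numeric vector of triangle areas (mm^2).
#' @export
compartment_areas <- function(mesh) {
  v <- mesh$vertices
  t <- mesh$triangles
  e1 <- v[t[, 2L], , drop = FALSE] - v[t[, 1L], , drop = FALSE]
  e2 <- v[t[, 3L], , drop = FALSE] - v[t[, 1L], , drop = FALSE]
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  sqrt(rowSums(cr * cr)) / 2
}

#' Geodesic distance matrix between compartments
#'
#' Shortest-path distances between compartment centroids along the
#' compartment-adjacency graph (edge weight = centroid Euclidean distance).
#' By default the one-ring vertex adjacency is augmented with chords to all
#' two-ring neighbours (`ring = 2`), which widens the available move
#' directions and keeps the metric stretch of the graph approximation to a
#' few percent of the true surface distance on a flat patch. `ring = 1`
#' restricts paths to direct neighbours; the `adjacency` rule is forwarded
#' to [compartment_edges()], keeping the backend pluggable.
#'
#' @param mesh an [roi_mesh()].
#' @param ring neighbourhood order of the path graph (1 or 2).
#' @param adjacency adjacency rule, see [compartment_edges()].
#' @return A symmetric K x K numeric matrix of distances in mm with zero
#'   diagonal.
#' @export
geodesic_distance_matrix <- function(mesh, ring = 2L,
                                     adjacency = c("vertex", "edge")) {
  adjacency <- match.arg(adjacency)
  if (!ring %in% c(1L, 2L)) stop_invalid("ring must be 1 or 2")
  K <- nrow(mesh$triangles)
  ed <- compartment_edges(mesh, adjacency)
  gr <- igraph::graph_from_data_frame(
    ed, directed = FALSE, vertices = data.frame(name = seq_len(K)))
  comp <- igraph::components(gr)
  if (comp$no > 1L) {
    main <- which.max(comp$csize)
    isolated <- which(comp$membership != main)
    stop_invalid("mesh is disconnected; compartments in isolated component: ",
                 paste(head(isolated, 10L), collapse = ", "),
                 if (length(isolated) > 10L) ", ..." else "")
  }
  if (ring == 2L) {
    gr <- igraph::connect(gr, 2L)
    el <- igraph::as_edgelist(gr, names = FALSE)
    d <- mesh$compartment_centers[el[, 1L], , drop = FALSE] -
      mesh$compartment_centers[el[, 2L], , drop = FALSE]
    igraph::E(gr)$weight <- sqrt(rowSums(d * d))
  }
  D <- igraph::distances(gr, weights = igraph::E(gr)$weight)
  dimnames(D) <- NULL
  D
}

#' Flatten a ROI to two dimensions by multidimensional scaling
#'
#' Classical (Torgerson) metric scaling of the geodesic distance matrix to a
#' 2-D embedding, used for map visualization only, never in computation.
#' The solution is an eigendecomposition and therefore deterministic.
#'
#' @param gd K x K geodesic distance matrix.
#' @return K x 2 matrix of embedding coordinates.
#' @export
flatten_mds <- function(gd) {
  gd <- as.matrix(gd)
  if (nrow(gd) < 3L) stop_invalid("MDS flattening needs at least 3 compartments")
  xy <- stats::cmdscale(gd, k = 2L)
  colnames(xy) <- c("u", "v")
  xy
}

#' Classify compartments into depth bands
#'
#' Splits compartments into gyral crown, sulcal wall and fundus bands by
#' fractions of the maximum sulcal depth. On a flat patch all compartments
#' are crown.
#'
#' @param depth per-compartment depth vector (mm).
#' @param crown_frac depths below `crown_frac * max(depth)` are crown.
#' @param fundus_frac depths above `fundus_frac * max(depth)` are fundus.
#' @return Factor with levels `crown`, `wall`, `fundus`.
#' @export
depth_bands <- function(depth, crown_frac = 0.25, fundus_frac = 0.75) {
  dmax <- max(depth)
  if (dmax <= 0) {
    return(factor(rep("crown", length(depth)),
                  levels = c("crown", "wall", "fundus")))
  }
  band <- ifelse(depth <= crown_frac * dmax, "crown",
                 ifelse(depth >= fundus_frac * dmax, "fundus", "wall"))
  factor(band, levels = c("crown", "wall", "fundus"))
}

# --- mesh persistence -------------------------------------------------------

#' Write / read a ROI mesh as CSV tables
#'
#' Persists a mesh as four small CSV files (`<prefix>_vertices.csv`,
#' `<prefix>_triangles.csv`, `<prefix>_compartments.csv`,
#' `<prefix>_meta.csv`). Doubles are written with 17 significant digits so
#' the round trip is exact.
#'
#' @param mesh an [roi_mesh()].
#' @param prefix file path prefix.
#' @return `write_roi_mesh` returns `prefix` invisibly; `read_roi_mesh`
#'   returns the reconstructed `roi_mesh`.
#' @export
write_roi_mesh <- function(mesh, prefix) {
  wr <- function(df, suffix) {
    df[] <- lapply(df, function(col) {
      if (is.double(col)) format_double(col) else col
    })
    utils::write.csv(df, paste0(prefix, "_", suffix, ".csv"),
                     row.names = FALSE, quote = FALSE)
  }
  wr(as.data.frame(mesh$vertices), "vertices")
  wr(as.data.frame(mesh$triangles), "triangles")
  comp <- data.frame(mesh$compartment_centers, depth = mesh$depth)
  colnames(comp) <- c("cx", "cy", "cz", "depth")
  wr(comp, "compartments")
  wr(data.frame(key = c("roi_center_x", "roi_center_y", "roi_center_z"),
                value = mesh$roi_center), "meta")
  invisible(prefix)
}

#' @rdname write_roi_mesh
#' @export
read_roi_mesh <- function(prefix) {
  v <- as.matrix(utils::read.csv(paste0(prefix, "_vertices.csv")))
  t <- as.matrix(utils::read.csv(paste0(prefix, "_triangles.csv")))
  comp <- utils::read.csv(paste0(prefix, "_compartments.csv"))
  meta <- utils::read.csv(paste0(prefix, "_meta.csv"))
  roi_mesh(v, t, depth = comp$depth, roi_center = meta$value)
}

#' Write / read mesh geometry in OFF format
#'
#' Plain-text Object File Format (vertices and faces only) for interchange
#' with external mesh tools. Depth and ROI metadata are not part of OFF;
#' `read_off` returns a flat-depth mesh.
#'
#' @param mesh an [roi_mesh()].
#' @param path file path.
#' @return `write_off` returns `path` invisibly; `read_off` an `roi_mesh`.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nrow(mesh$vertices), nrow(mesh$triangles), 0L), con)
  writeLines(apply(mesh$vertices, 1L,
                   function(r) paste(format_double(r), collapse = " ")), con)
  writeLines(apply(mesh$triangles - 1L, 1L,
                   function(r) paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_off
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (toupper(trimws(lines[1L])) != "OFF") stop_invalid("not an OFF file")
  counts <- scan(text = lines[2L], quiet = TRUE)
  nv <- counts[1L]
  nf <- counts[2L]
  v <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE),
              ncol = 3L, byrow = TRUE)
  f <- matrix(scan(text = lines[(3 + nv):(2 + nv + nf)], quiet = TRUE),
              ncol = 4L, byrow = TRUE)
  roi_mesh(v, f[, 2:4, drop = FALSE] + 1L)
}
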