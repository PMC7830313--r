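# Landmark-guided dense correspondence.
#
# Training corpora for model building must be in dense semantic
# correspondence: every scan carries the same number of vertices and the
# i-th vertex means the same anatomical location everywhere.  This module
# achieves that for raw scans by partitioning the face into landmark-bounded
# regions and resampling each region on a fixed barycentric grid, so the
# j-th sample of any scan matches the j-th sample of every other scan.

#' Define a region scheme
#'
#' A scheme names the non-overlapping regions the face is partitioned
#' into.  Each region is bounded by ordered landmarks and resampled with a
#' fixed number of points.
#'
#' @param regions list of region descriptors, each a list with elements
#'   `id` (character), `landmarks` (ordered character vector of boundary
#'   landmark names) and `count` (number of resampled points).
#' @param id optional scheme identifier; derived from the regions when
#'   omitted.
#' @return object of class `region_scheme`.
#' @export
region_scheme <- function(regions, id = NULL) {
  if (!length(regions)) stop("scheme needs at least one region")
  for (r in regions) {
    if (is.null(r$id) || is.null(r$landmarks) || is.null(r$count)) {
      stop("each region needs 'id', 'landmarks' and 'count'")
    }
    if (r$count < 1L) stop("region '", r$id, "': count must be >= 1")
  }
  ids <- vapply(regions, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("region ids must be unique")
  if (is.null(id)) {
    counts <- vapply(regions, function(r) as.integer(r$count), 1L)
    id <- paste0("scheme-", paste(ids, counts, sep = ":", collapse = "-"))
  }
  structure(list(regions = regions, id = id), class = "region_scheme")
}

#' Read a region scheme from a YAML config
#'
#' Expected layout: top-level `id` (optional) and `regions`, a sequence of
#' mappings with `id`, `landmarks` and `count`.
#'
#' @param path YAML file path.
#' @return a [region_scheme()].
#' @export
read_region_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$regions)) stop("scheme config has no 'regions' entry")
  region_scheme(cfg$regions, id = cfg$id)
}

#' Partition the face domain into the scheme's regions
#'
#' Verifies all landmarks the scheme requires are present and freezes the
#' per-region sample counts, producing the `region_map` that every scan is
#' registered against.  The assignment is deterministic: same landmarks,
#' same map.
#'
#' @param landmarks named landmark coordinates (l x 3 matrix with rownames)
#'   or a [trimesh()] carrying landmarks.
#' @param scheme a [region_scheme()].
#' @return object of class `region_map` with elements `regions`,
#'   `total_samples` and `topology_id`.
#' @export
partition_regions <- function(landmarks, scheme) {
  if (inherits(landmarks, "trimesh")) landmarks <- landmarks$landmarks
  if (is.null(landmarks) || is.null(rownames(landmarks))) {
    stop("named landmarks are required to partition regions")
  }
  if (!inherits(scheme, "region_scheme")) stop("'scheme' must be a region_scheme")
  for (r in scheme$regions) {
    missing <- setdiff(r$landmarks, rownames(landmarks))
    if (length(missing)) {
      stop("landmark '", missing[1L], "' required by region '", r$id,
           "' is missing")
    }
  }
  counts <- vapply(scheme$regions, function(r) as.integer(r$count), 1L)
  structure(
    list(regions = scheme$regions,
         total_samples = sum(counts),
         topology_id = scheme$id),
    class = "region_map"
  )
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("region_map '%s': %d regions, %d samples total\n",
              x$topology_id, length(x$regions), x$total_samples))
  invisible(x)
}

# --- barycentric grid generators ------------------------------------------
# All grids are ordered lexicographically over (row, column) so the sample
# order is a fixed, documented convention shared by every scan.

tri_grid_weights <- function(count) {
  if (count == 1L) return(matrix(1 / 3, 1L, 3L))
  d <- 1L
  while ((d + 1L) * (d + 2L) / 2L < count) d <- d + 1L
  w <- matrix(0, 0L, 3L)
  for (i in 0:d) for (j in 0:(d - i)) {
    w <- rbind(w, c(i, j, d - i - j) / d)
  }
  w[seq_len(count), , drop = FALSE]
}

quad_grid_uv <- function(count) {
  if (count == 1L) return(cbind(0.5, 0.5))
  rows <- max(1L, floor(sqrt(count)))
  if (rows * ceiling(count / rows) < count) rows <- rows + 1L
  cols <- ceiling(count / rows)
  us <- if (rows == 1L) 0.5 else seq(0, 1, length.out = rows)
  vs <- if (cols == 1L) 0.5 else seq(0, 1, length.out = cols)
  uv <- expand.grid(v = vs, u = us)[, c("u", "v")]  # row-major over (u, v)
  as.matrix(uv)[seq_len(count), , drop = FALSE]
}

# Grid points in 3D from ordered boundary landmarks lm (q x 3).
region_grid_points <- function(lm, count) {
  q <- nrow(lm)
  if (q < 3L) stop("a region needs at least 3 boundary landmarks")
  ctr <- colMeans(lm)
  fan_area <- sum(vapply(seq_len(q), function(i) {
    a <- lm[i, ]; b <- lm[if (i == q) 1L else i + 1L, ]
    sqrt(sum(crossprod3(a - ctr, b - ctr)^2)) / 2
  }, numeric(1)))
  if (fan_area < 1e-9) stop("degenerate region: boundary landmarks span zero area")
  if (count == 1L) return(matrix(ctr, 1L, 3L))
  if (q == 3L) {
    w <- tri_grid_weights(count)
    return(w %*% lm)
  }
  if (q == 4L) {
    uv <- quad_grid_uv(count)
    u <- uv[, 1L]; v <- uv[, 2L]
    w <- cbind((1 - u) * (1 - v), u * (1 - v), u * v, (1 - u) * v)
    return(w %*% lm)
  }
  # q > 4: fan triangulation around the centroid, counts split as evenly
  # as possible in boundary order.
  per <- rep(count %/% q, q)
  extra <- count %% q
  if (extra) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  pts <- matrix(0, 0L, 3L)
  for (i in seq_len(q)) {
    if (per[i] == 0L) next
    tri <- rbind(ctr, lm[i, ], lm[if (i == q) 1L else i + 1L, ])
    w <- tri_grid_weights(per[i])
    pts <- rbind(pts, w %*% tri)
  }
  pts
}

crossprod3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Closest point on triangle (a, b, c) to p (Ericson's algorithm).
closest_point_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + (d1 / (d1 - d3)) * ab)
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + (d2 / (d2 - d6)) * ac)
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    return(b + ((d4 - d3) / ((d4 - d3) + (d5 - d6))) * (c - b))
  }
  denom <- 1 / (va + vb + vc)
  a + ab * (vb * denom) + ac * (vc * denom)
}

# Project points onto the mesh surface: exact closest point over candidate
# triangles near the nearest vertex.  For point clouds (no faces) a local
# plane is fitted through the nearest neighbours and the point projected
# onto it — snapping to the single nearest vertex would inherit half the
# cloud spacing as jitter.
project_to_surface <- function(points, mesh) {
  v <- mesh$vertices
  if (is.null(mesh$faces) || nrow(mesh$faces) == 0L) {
    k <- min(8L, nrow(v))
    out <- matrix(0, nrow(points), 3L)
    for (i in seq_len(nrow(points))) {
      p <- points[i, ]
      d2 <- colSums((t(v) - p)^2)
      nb <- v[order(d2)[seq_len(k)], , drop = FALSE]
      ctr <- colMeans(nb)
      if (k < 3L) {
        out[i, ] <- nb[1L, ]
        next
      }
      sv <- svd(sweep(nb, 2L, ctr), nu = 0L)
      n <- sv$v[, 3L]
      out[i, ] <- p - sum((p - ctr) * n) * n
    }
    return(out)
  }
  f <- mesh$faces
  # faces incident to each vertex
  vert_faces <- split(rep(seq_len(nrow(f)), 3L), as.vector(f))
  nn <- nearest_vertex(points, v)
  out <- matrix(0, nrow(points), 3L)
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    cand <- vert_faces[[as.character(nn$index[i])]]
    if (is.null(cand)) {  # isolated vertex
      out[i, ] <- v[nn$index[i], ]
      next
    }
    best <- v[nn$index[i], ]
    bestd <- sum((p - best)^2)
    for (fi in cand) {
      q <- closest_point_triangle(p, v[f[fi, 1L], ], v[f[fi, 2L], ], v[f[fi, 3L], ])
      d <- sum((p - q)^2)
      if (d < bestd) { bestd <- d; best <- q }
    }
    out[i, ] <- best
  }
  out
}

#' Resample a landmark-bounded region on a fixed barycentric grid
#'
#' Generates `count` ordered sample points spanning the region's boundary
#' landmarks (triangular grid for 3 landmarks, tensor grid for 4, centroid
#' fan otherwise) and projects each onto the mesh surface.  The grid and
#' its ordering are fixed, so the j-th sample of any scan is semantically
#' matched to the j-th sample of every other scan.
#'
#' @param mesh a [trimesh()] carrying the region's boundary landmarks.
#' @param landmark_names ordered boundary landmark names, or a region
#'   descriptor list with `landmarks` (and optionally `count`).
#' @param count number of samples; `count = 1` returns the region centroid.
#' @return numeric `count` x 3 matrix of ordered surface samples.
#' @export
resample_region <- function(mesh, landmark_names, count = NULL) {
  if (is.list(landmark_names)) {
    count <- count %||% landmark_names$count
    landmark_names <- landmark_names$landmarks
  }
  if (is.null(count)) stop("'count' is required")
  lmset <- mesh$landmarks
  missing <- setdiff(landmark_names, rownames(lmset))
  if (length(missing)) stop("landmark '", missing[1L], "' is missing from the mesh")
  lm <- lmset[landmark_names, , drop = FALSE]
  grid <- region_grid_points(lm, as.integer(count))
  project_to_surface(grid, mesh)
}

#' Register a raw scan against a region map
#'
#' Resamples every region of the map in fixed region order and concatenates
#' the samples into one registered shape vector of length
#' `3 * total_samples` on the map's topology.
#'
#' @param mesh a [trimesh()] carrying the scheme landmarks.
#' @param region_map a [partition_regions()] result.
#' @return a [registered_shape()].
#' @export
register_scan <- function(mesh, region_map) {
  if (!inherits(region_map, "region_map")) stop("'region_map' must be a region_map")
  pts <- do.call(rbind, lapply(region_map$regions, function(r) {
    resample_region(mesh, r$landmarks, r$count)
  }))
  registered_shape(flatten_points(pts), region_map$topology_id)
}
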