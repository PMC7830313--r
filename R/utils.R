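# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Brute-force nearest neighbours between two 3D point sets
#'
#' Finds, for every row of `query`, the index of the nearest row of `ref`
#' (Euclidean distance).  Ties are broken deterministically towards the
#' lowest `ref` index.  Computed in blocks so the full distance matrix never
#' exceeds a few million entries.
#'
#' @param query numeric matrix, n x 3.
#' @param ref numeric matrix, r x 3.
#' @return list with integer `index` (length n) and numeric `dist` (mm).
#' @keywords internal
nearest_vertex <- function(query, ref) {
  query <- as_point_matrix(query)
  ref <- as_point_matrix(ref)
  if (nrow(ref) < 1L) stop("reference point set is empty")
  n <- nrow(query)
  idx <- integer(n)
  d2 <- numeric(n)
  r2 <- rowSums(ref * ref)
  step <- max(1L, as.integer(4e6 / nrow(ref)))
  s <- 1L
  while (s <= n) {
    e <- min(n, s + step - 1L)
    q <- query[s:e, , drop = FALSE]
    dd <- rowSums(q * q) - 2 * (q %*% t(ref))
    dd <- sweep(dd, 2L, r2, "+")
    j <- max.col(-dd, ties.method = "first")
    idx[s:e] <- j
    d2[s:e] <- dd[cbind(seq_len(e - s + 1L), j)]
    s <- e + 1L
  }
  list(index = idx, dist = sqrt(pmax(d2, 0)))
}

# Coerce anything point-like (trimesh, registered_shape, matrix, vector)
# to an m x 3 coordinate matrix.
as_point_matrix <- function(x) {
  if (inherits(x, "trimesh")) return(x$vertices)
  if (inherits(x, "registered_shape")) {
    return(matrix(x$vector, ncol = 3L, byrow = TRUE))
  }
  if (is.matrix(x)) {
    if (ncol(x) != 3L) stop("point matrix must have 3 columns")
    return(x)
  }
  if (is.numeric(x)) {
    if (length(x) %% 3L != 0L) stop("coordinate vector length must be divisible by 3")
    return(matrix(x, ncol = 3L, byrow = TRUE))
  }
  stop("cannot interpret object of class '", class(x)[1L], "' as 3D points")
}

# Row-major flattening [x1,y1,z1,...,xm,ym,zm] of an m x 3 matrix.
flatten_points <- function(pts) as.numeric(t(pts))

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values (NaN/Inf)")
  invisible(x)
}
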