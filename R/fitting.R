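# Dense 3D-3D model fitting.
#
# The model is deformed onto a raw target scan by iterating four steps:
# nearest-neighbour correspondence, closed-form similarity estimation with
# QR factorization into rotation and scale, realignment of the target, and
# a closed-form regularized solve for the deformation coefficients.  All
# point matrices use the row-vector convention: a transform acts as
# `points %*% P + T`.

#' Similarity transform (rotation, scale, translation)
#'
#' @param P 3 x 3 matrix combining rotation and scale (`P = R %*% Sc`).
#' @param R 3 x 3 proper rotation.
#' @param Sc 3 x 3 upper-triangular scale factor (positive diagonal).
#' @param T length-3 translation.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(P, R, Sc, T) {
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6) {
    stop("R must be a proper rotation (orthonormal, det +1)")
  }
  if (max(abs(R %*% Sc - P)) > 1e-8 * max(1, max(abs(P)))) {
    stop("P must equal R %*% Sc")
  }
  structure(list(P = P, R = R, Sc = Sc, T = as.numeric(T)),
            class = "rigid_transform")
}

identity_transform <- function() {
  rigid_transform(diag(3), diag(3), diag(3), c(0, 0, 0))
}

#' Apply a similarity transform to points
#'
#' Row-vector convention: `points %*% P + T`, identical to applying the
#' factored form `(points %*% R) %*% Sc + T`.
#'
#' @param points n x 3 matrix (or anything [trimesh()]-like).
#' @param transform a [rigid_transform()].
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(points, transform) {
  pts <- as_point_matrix(points)
  sweep(pts %*% transform$P, 2L, transform$T, "+")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$R)) - 1) / 2))) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.2f deg, scale diag (%.3f, %.3f, %.3f), |T| = %.3f mm\n",
              ang, x$Sc[1, 1], x$Sc[2, 2], x$Sc[3, 3], sqrt(sum(x$T^2))))
  invisible(x)
}

#' Preliminary rigid ICP alignment
#'
#' Iterative closest point with rotation and translation only (unit
#' scale): alternates nearest-neighbour matching of `source` into `target`
#' with the closed-form orthogonal Procrustes (SVD) update, until the
#' relative improvement of the mean nearest-neighbour distance drops below
#' `tol` or `max_iter` iterations.  Deterministic.
#'
#' @param source,target point sets (n x 3 matrices or meshes).
#' @param init optional initial [rigid_transform()] applied to `source`.
#' @param opts list: `max_iter` (default 50), `tol` (default 1e-6).
#' @return a [rigid_transform()] mapping `source` onto `target`.
#' @export
icp_align <- function(source, target, init = NULL, opts = list()) {
  src <- as_point_matrix(source)
  tgt <- as_point_matrix(target)
  if (nrow(src) < 3L || nrow(tgt) < 1L) stop("ICP needs at least 3 source points")
  ctr <- sweep(src, 2L, colMeans(src))
  if (svd(ctr)$d[2L] < 1e-9 * max(1, svd(ctr)$d[1L])) {
    stop("degenerate point set: fewer than 3 non-collinear points")
  }
  max_iter <- opts$max_iter %||% 50L
  tol <- opts$tol %||% 1e-6
  R <- init$R %||% diag(3)
  T <- init$T %||% c(0, 0, 0)
  prev_err <- Inf
  for (it in seq_len(max_iter)) {
    cur <- sweep(src %*% R, 2L, T, "+")
    nn <- nearest_vertex(cur, tgt)
    err <- mean(nn$dist)
    if (is.finite(prev_err) && (prev_err - err) < tol * max(prev_err, 1e-12)) break
    prev_err <- err
    m <- tgt[nn$index, , drop = FALSE]
    sc <- colMeans(src); mc <- colMeans(m)
    H <- crossprod(sweep(src, 2L, sc), sweep(m, 2L, mc))   # 3 x 3
    sv <- svd(H)
    d <- det(sv$u %*% t(sv$v))
    R <- sv$u %*% diag(c(1, 1, sign(d))) %*% t(sv$v)
    T <- mc - drop(sc %*% R)
  }
  rigid_transform(R, R, diag(3), T)
}

#' Nearest-neighbour correspondence from model to target
#'
#' For every model vertex, the Euclidean-nearest target vertex
#' (many-to-one allowed; ties broken towards the lowest target index).
#'
#' @param S model shape: [registered_shape()] or m x 3 matrix.
#' @param target target scan: [trimesh()] or n x 3 matrix.
#' @return m x 3 matrix of corresponded target points.
#' @export
correspond <- function(S, target) {
  Sm <- as_point_matrix(S)
  tm <- as_point_matrix(target)
  if (nrow(tm) < 1L) stop("target is empty")
  nn <- nearest_vertex(Sm, tm)
  tm[nn$index, , drop = FALSE]
}

#' Closed-form similarity estimation
#'
#' Solves `argmin_P || S - tc %*% P ||^2` for the 3 x 3 rotation-scale
#' matrix `P` (centered least squares, row-vector convention), recovers
#' the translation from the centroids, and factors `P = R %*% Sc` by QR
#' with signs fixed so the scale diagonal is positive and `R` is a proper
#' rotation.  Realigning `tc %*% R %*% Sc + T` maps the corresponded
#' target back onto the model frame.
#'
#' @param S m x 3 model point matrix (or registered shape).
#' @param tc m x 3 corresponded target points.
#' @return a [rigid_transform()].
#' @export
estimate_similarity <- function(S, tc) {
  Sm <- as_point_matrix(S)
  tm <- as_point_matrix(tc)
  if (nrow(tm) != nrow(Sm)) stop("S and corresponded points must have equal row counts")
  if (nrow(Sm) < 4L) stop("similarity estimation needs at least 4 points")
  Sc0 <- colMeans(Sm); tc0 <- colMeans(tm)
  A <- sweep(tm, 2L, tc0)
  B <- sweep(Sm, 2L, Sc0)
  AtA <- crossprod(A)
  if (rcond(AtA) < 1e-12) stop("rank-deficient correspondence: cannot estimate similarity")
  P <- solve(AtA, crossprod(A, B))
  T <- Sc0 - drop(tc0 %*% P)
  qrp <- qr(P)
  Q <- qr.Q(qrp); Rm <- qr.R(qrp)
  s <- sign(diag(Rm)); s[s == 0] <- 1
  Q <- Q %*% diag(s); Rm <- diag(s) %*% Rm
  if (det(Q) < 0) stop("similarity estimate contains a reflection")
  rigid_transform(P = Q %*% Rm, R = Q, Sc = Rm, T = T)
}

#' Closed-form regularized deformation coefficients
#'
#' Solves the regularized least squares for the coefficient vector given
#' the residual `X` between corresponded target and current model:
#' `alpha = (C' C + lambda diag(1/mu))^{-1} C' X`, computed by a
#' symmetric positive-definite (Cholesky) solve, never an explicit
#' inverse.  With `penalty = "mu-inverse-squared"` the inverse weights are squared
#' (`diag(1/mu^2)`), the penalty implied by a squared norm over
#' `alpha / mu`.
#'
#' @param X length-3m residual vector (`tc - S`, row-major flattened).
#' @param basis 3m x k matrix whose columns are the deformation components
#'   (the transpose of the model's `components`).
#' @param mu positive length-k component weights.
#' @param lambda regularization strength, `> 0`.
#' @param penalty `"mu-inverse"` (default, `diag(1/mu)`) or `"mu-inverse-squared"`
#'   (`diag(1/mu^2)`).
#' @return length-k coefficient vector.
#' @export
solve_coefficients <- function(X, basis, mu, lambda, penalty = c("mu-inverse", "mu-inverse-squared")) {
  penalty <- match.arg(penalty)
  if (lambda <= 0) stop("lambda must be > 0")
  if (any(mu <= 0)) stop("all component weights mu must be > 0")
  basis <- as.matrix(basis)
  k <- ncol(basis)
  if (length(X) != nrow(basis)) stop("residual length does not match basis rows")
  if (length(mu) != k) stop("mu length does not match component count")
  w <- if (penalty == "mu-inverse") 1 / mu else 1 / mu^2
  A <- crossprod(basis) + lambda * diag(w, k)
  ch <- chol(A)
  backsolve(ch, forwardsolve(t(ch), crossprod(basis, X)))[, 1L]
}

#' Deform a shape along model components
#'
#' `base + sum_j alpha_j * component_j`, reshaped back to 3D points.
#'
#' @param base [registered_shape()] or length-3m vector.
#' @param components k x 3m component matrix.
#' @param alpha length-k coefficients.
#' @return same type as `base` (registered shape in, registered shape out).
#' @export
apply_deformation <- function(base, components, alpha) {
  if (nrow(components) != length(alpha)) stop("alpha length must match component count")
  if (inherits(base, "registered_shape")) {
    vec <- base$vector + drop(crossprod(components, alpha))
    return(registered_shape(vec, base$topology_id))
  }
  v <- as.numeric(base)
  if (length(v) != ncol(components)) stop("base length does not match components")
  v + drop(crossprod(components, alpha))
}

#' Mean per-vertex distance from a model shape to a target scan
#'
#' Average, over model vertices, of the Euclidean distance to the nearest
#' target vertex (mm).
#'
#' @param S [registered_shape()] or point matrix.
#' @param target [trimesh()] or point matrix.
#' @return scalar error in mm.
#' @export
per_vertex_error <- function(S, target) {
  tm <- as_point_matrix(target)
  if (nrow(tm) < 1L) stop("target is empty")
  mean(nearest_vertex(as_point_matrix(S), tm)$dist)
}

#' Fit a morphable model to a raw target scan
#'
#' After an optional preliminary rigid ICP, iterates: nearest-neighbour
#' correspondence, similarity estimation, realignment of the (full and
#' corresponded) target onto the model frame, the closed-form regularized
#' coefficient solve, deformation of the model, and the per-vertex error.
#' Stops when the error change between consecutive iterations falls below
#' `tau_e` or after `max_iter` iterations.  Deterministic for fixed
#' inputs.
#'
#' @param model an `slc_model`.
#' @param target a [trimesh()] (raw scan; vertex order and faces
#'   irrelevant).
#' @param base optional [registered_shape()] used as the starting shape in
#'   place of the model mean (e.g. a fitted neutral for expression
#'   fitting); must share the model topology.
#' @param opts list: `lambda` (default 0.05), `tau_e` (mm, default 1e-3),
#'   `max_iter` (default 30), `icp` (default TRUE), `penalty`
#'   (`"mu-inverse"`/`"mu-inverse-squared"`), `aggregate` (strategy for the aggregated
#'   coefficient vector, default `"mean"`).
#' @return object of class `fit_result`: `deformed` (registered shape),
#'   `transform` (last similarity), `icp_transform`, `target_transform`
#'   (composed scan-frame to model-frame similarity), `target_aligned`
#'   (target points in the model frame), `alphas` (one vector per
#'   iteration), `alpha` (aggregated), `errors` (mm, per iteration),
#'   `iterations`, `converged`.
#' @export
fit_model <- function(model, target, base = NULL, opts = list()) {
  if (!inherits(model, "slc_model")) stop("'model' must be an slc_model")
  lambda <- opts$lambda %||% 0.05
  tau_e <- opts$tau_e %||% 1e-3
  max_iter <- opts$max_iter %||% 30L
  if (max_iter < 1L) stop("max_iter must be >= 1")
  use_icp <- opts$icp %||% TRUE
  penalty <- opts$penalty %||% "mu-inverse"
  strategy <- opts$aggregate %||% "mean"

  base_vec <- if (is.null(base)) model$mean else {
    if (inherits(base, "registered_shape") &&
        !identical(base$topology_id, model$topology_id)) {
      stop("base topology '", base$topology_id,
           "' does not match model topology '", model$topology_id, "'")
    }
    if (inherits(base, "registered_shape")) base$vector else as.numeric(base)
  }
  if (length(base_vec) != ncol(model$components)) {
    stop("base shape length does not match model")
  }
  S <- matrix(base_vec, ncol = 3L, byrow = TRUE)
  tp <- as_point_matrix(target)
  basis <- t(model$components)
  mu <- model$weights

  icp_tf <- identity_transform()
  if (isTRUE(use_icp)) {
    icp_tf <- icp_align(tp, S)
    tp <- apply_transform(tp, icp_tf)
  }
  Pc <- icp_tf$P
  Tc <- icp_tf$T
  S_base <- S                     # deformation is always applied to the base
  err_prev <- per_vertex_error(S, tp)
  alphas <- vector("list", max_iter)
  errors <- numeric(max_iter)
  tf <- identity_transform()
  converged <- FALSE
  t_used <- 0L
  for (t in seq_len(max_iter)) {
    # correspondences come from the current deformed model; the
    # coefficient solve estimates the full deformation from the base, so
    # each iteration's alpha is a complete (re-)estimate and averaging
    # across iterations cancels noise without diluting the signal
    nn <- nearest_vertex(S, tp)
    tc <- tp[nn$index, , drop = FALSE]
    tf <- tryCatch(estimate_similarity(S, tc), error = function(e) NULL)
    if (!is.null(tf)) {
      tp <- apply_transform(tp, tf)
      tc <- apply_transform(tc, tf)
      Pc <- Pc %*% tf$P
      Tc <- drop(Tc %*% tf$P) + tf$T
    } else {
      tf <- identity_transform()
    }
    X <- flatten_points(tc - S_base)
    alpha <- solve_coefficients(X, basis, mu, lambda, penalty = penalty)
    S <- S_base + matrix(drop(crossprod(model$components, alpha)),
                         ncol = 3L, byrow = TRUE)
    err <- per_vertex_error(S, tp)
    alphas[[t]] <- alpha
    errors[t] <- err
    t_used <- t
    if (abs(err - err_prev) < tau_e) {
      converged <- TRUE
      break
    }
    err_prev <- err
  }
  alphas <- alphas[seq_len(t_used)]
  errors <- errors[seq_len(t_used)]
  structure(
    list(deformed = registered_shape(flatten_points(S), model$topology_id),
         transform = tf, icp_transform = icp_tf,
         target_transform = list(P = Pc, T = Tc),  # scan frame -> model frame
         target_aligned = tp,
         alphas = alphas,
         alpha = aggregate_coefficients(alphas, strategy),
         errors = errors, iterations = t_used, converged = converged),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: %d iterations, final error %.4f mm%s\n",
              x$iterations, x$errors[x$iterations],
              if (x$converged) " (converged)" else ""))
  invisible(x)
}
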