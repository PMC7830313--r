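# SLC-3DMM construction.
#
# The distinguishing idea: instead of treating each registered scan as a
# training sample, every vertex coordinate is one.  The displacement of a
# coordinate across the N scans is an N-dimensional sample, giving 3m
# samples in total (the transposed training matrix V').  Sparse coding of
# these samples under an elastic-net penalty with positivity constraints
# yields deformation components that are sparse and spatially localized —
# precisely the support structure of facial muscle activations.

#' Registered training set
#'
#' @param F numeric 3m x N matrix; columns are registered shape vectors
#'   (see [linearize()]), all on the same template topology.
#' @param topology_id shared template identifier.
#' @param subjects,labels optional per-column metadata.
#' @return object of class `training_set`.
#' @export
training_set <- function(F, topology_id, subjects = NULL, labels = NULL) {
  F <- as.matrix(F)
  if (ncol(F) < 2L) stop("a training set needs at least N = 2 scans")
  if (nrow(F) %% 3L != 0L) stop("row count must be 3m (divisible by 3)")
  assert_finite(F, "training matrix")
  structure(list(F = F, topology_id = as.character(topology_id),
                 subjects = subjects, labels = labels),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("training_set: %d scans x %d vertices on topology '%s'\n",
              ncol(x$F), nrow(x$F) / 3L, x$topology_id))
  invisible(x)
}

#' Average 3D face of a training set
#'
#' @param F a [training_set()] or plain 3m x N matrix.
#' @return length-3m mean shape vector.
#' @export
compute_mean <- function(F) {
  if (inherits(F, "training_set")) F <- F$F
  rowMeans(F)
}

#' Displacement (training) matrix V
#'
#' Subtracts the average face from every scan: column i is the set of
#' directions transforming the mean into training scan i.
#'
#' @param F a [training_set()] or 3m x N matrix.
#' @param m mean shape vector; computed from `F` when omitted.
#' @return 3m x N displacement matrix.
#' @export
build_training_matrix <- function(F, m = NULL) {
  if (inherits(F, "training_set")) F <- F$F
  if (is.null(m)) m <- rowMeans(F)
  if (length(m) != nrow(F)) stop("mean length does not match training matrix rows")
  F - m
}

slc_objective <- function(Vs, D, C, lambda1, lambda2) {
  R <- Vs - D %*% C
  (sum(R * R) + lambda1 * sum(C) + lambda2 * sum(C * C)) / ncol(Vs)
}

project_dictionary <- function(D) {
  D[D < 0] <- 0
  nrm <- sqrt(colSums(D * D))
  scale <- pmax(nrm, 1)
  sweep(D, 2L, scale, "/")
}

#' Learn sparse locally-coherent deformation components
#'
#' Solves, over the transposed training matrix `V' = t(V)` whose 3m columns
#' are the per-coordinate displacement samples,
#' \deqn{\min_{D \ge 0, C \ge 0} \frac{1}{3m}\sum_i \|v'_i - D c_i\|^2
#'   + \lambda_1 \|c_i\|_1 + \lambda_2 \|c_i\|^2}
#' by alternating minimization: exact per-coordinate non-negative
#' elastic-net coordinate descent for `C`, and block-coordinate descent
#' over dictionary columns with exact projection onto the non-negative
#' unit ball for `D`.  Both steps are exact constrained minimizations, so
#' the objective trace is non-increasing across outer iterations.
#'
#' Because the non-negativity constraints cannot reconstruct signed
#' displacements directly, learning operates on `V'` shifted by its global
#' minimum; the shift is returned as `data_offset` and only affects
#' training-side reconstruction — fitting uses `C` with unconstrained
#' coefficients.
#'
#' @param V 3m x N displacement matrix (see [build_training_matrix()]).
#' @param k number of components, `k < N`.
#' @param lambda1 L1 sparsity weight, `>= 0`.
#' @param lambda2 L2 grouping weight, `>= 0`.
#' @param opts solver options: `max_iter` (outer iterations, default 150),
#'   `tol` (relative objective decrease stopping tolerance, default 1e-8),
#'   `cd_sweeps` (coordinate-descent sweeps per outer iteration, default 2),
#'   `seed` (dictionary initialization seed, default 1).
#' @return list with `D` (N x k dictionary), `C` (k x 3m components),
#'   `objective` (per-outer-iteration trace), `data_offset`, `iterations`.
#' @export
learn_slc_components <- function(V, k, lambda1 = 0.5, lambda2 = 0.05,
                                 opts = list()) {
  V <- as.matrix(V)
  Vp <- t(V)                               # N x 3m, columns are samples
  N <- nrow(Vp); p <- ncol(Vp)
  if (k >= N) stop("k must be smaller than the number of scans N = ", N)
  if (k < 1L) stop("k must be >= 1")
  if (lambda1 < 0 || lambda2 < 0) stop("lambda1 and lambda2 must be >= 0")
  max_iter <- opts$max_iter %||% 150L
  tol <- opts$tol %||% 1e-8
  cd_sweeps <- opts$cd_sweeps %||% 2L
  seed <- opts$seed %||% 1L

  off <- min(Vp)
  Vs <- Vp - off                            # entrywise >= 0

  init <- opts$init %||% "sample"
  D <- with_seed(seed, {
    if (identical(init, "sample")) {
      # seed atoms from random training samples: already valid non-negative
      # activation patterns, typically close to single deformation modes
      cols <- sample.int(p, k)
      D0 <- Vs[, cols, drop = FALSE]
    } else {
      D0 <- matrix(stats::runif(N * k), N, k)
    }
    project_dictionary(D0)
  })

  C <- matrix(0, k, p)

  # C step: exact non-negative elastic-net coordinate descent, vectorized
  # across all samples (each column of C is independent).
  update_C <- function(D, C) {
    G <- crossprod(D)                       # k x k
    B <- crossprod(D, Vs)                   # k x p
    for (sw in seq_len(cd_sweeps)) {
      for (j in seq_len(k)) {
        num <- B[j, ] - drop(G[j, , drop = FALSE] %*% C) + G[j, j] * C[j, ]
        C[j, ] <- pmax(0, (num - lambda1 / 2) / (G[j, j] + lambda2 + 1e-12))
      }
    }
    C
  }
  # D step: block-coordinate descent over dictionary columns.  Each column
  # solve is an exact quadratic minimization followed by the exact
  # projection onto {d >= 0, ||d|| <= 1} (clip, then rescale), so the
  # objective cannot increase.
  update_D <- function(D, C) {
    A <- tcrossprod(C)                      # k x k
    B2 <- Vs %*% t(C)                       # N x k
    for (sw in seq_len(cd_sweeps)) {
      for (j in seq_len(k)) {
        if (A[j, j] > 1e-12) {
          u <- D[, j] + (B2[, j] - D %*% A[, j]) / A[j, j]
        } else {
          u <- D[, j]
        }
        u[u < 0] <- 0
        nrm <- sqrt(sum(u * u))
        if (nrm > 1) u <- u / nrm
        D[, j] <- u
      }
    }
    D
  }
  # Atom maintenance: an unused atom, or one nearly collinear with an
  # earlier one, contributes nothing and traps the alternating scheme in a
  # local minimum.  Replace it with the worst-reconstructed sample
  # (deterministic).  May transiently raise the objective, so the caller
  # only keeps the result if the subsequent refit still descends.
  replace_atoms <- function(D, C) {
    usage <- rowSums(C)
    nrm <- sqrt(colSums(D * D))
    Dn <- sweep(D, 2L, pmax(nrm, 1e-12), "/")
    gram <- abs(crossprod(Dn))
    gram[lower.tri(gram, diag = TRUE)] <- 0
    dup <- apply(gram, 2L, max) > 0.999
    dead <- which(usage < 1e-9 * max(usage, 1e-12) | nrm < 1e-9 | dup)
    if (!length(dead)) return(NULL)
    res <- colSums((Vs - D %*% C)^2)
    worst <- order(res, decreasing = TRUE)[seq_along(dead)]
    for (d_i in seq_along(dead)) {
      u <- Vs[, worst[d_i]]
      un <- sqrt(sum(u * u))
      if (un > 0) D[, dead[d_i]] <- u / max(un, 1)
      C[dead[d_i], ] <- 0
    }
    list(D = D, C = C)
  }

  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    cand <- NULL
    if (it > 1L && it < max_iter - 5L) cand <- replace_atoms(D, C)
    if (!is.null(cand)) {
      Cc <- update_C(cand$D, cand$C)
      Dc <- update_D(cand$D, Cc)
      f_cand <- slc_objective(Vs, Dc, Cc, lambda1, lambda2)
      if (f_cand <= trace[it - 1L]) {
        D <- Dc; C <- Cc
        trace <- c(trace, f_cand)
        if ((trace[it - 1L] - f_cand) < tol * max(1, trace[it - 1L])) break
        next
      }
    }
    C <- update_C(D, C)
    D <- update_D(D, C)
    f_new <- slc_objective(Vs, D, C, lambda1, lambda2)
    trace <- c(trace, f_new)
    if (it > 1L && (trace[it - 1L] - f_new) < tol * max(1, trace[it - 1L])) break
  }
  list(D = D, C = C, objective = trace, data_offset = off,
       iterations = length(trace))
}

#' Per-component weight vector
#'
#' Weighs each component by its average intensity: the mean of its row of
#' `C` over the 3m coordinates, floored at 1e-8 so the fitting
#' regularizer's inverse weights stay finite.
#'
#' @param C k x 3m non-negative component matrix.
#' @return positive length-k vector.
#' @export
compute_component_weights <- function(C) {
  if (any(C < 0)) stop("component matrix must be entry-wise non-negative")
  pmax(rowMeans(C), 1e-8)
}

new_slc_model <- function(mean, components, weights, kind, topology_id,
                          hyperparams, dictionary = NULL, objective = NULL) {
  structure(
    list(mean = as.numeric(mean), components = components,
         weights = as.numeric(weights), kind = kind,
         topology_id = as.character(topology_id),
         hyperparams = hyperparams, dictionary = dictionary,
         objective = objective),
    class = "slc_model"
  )
}

#' @export
print.slc_model <- function(x, ...) {
  cat(sprintf("%s-3DMM: %d components over %d vertices (topology '%s')\n",
              toupper(x$kind), nrow(x$components), length(x$mean) / 3L,
              x$topology_id))
  invisible(x)
}

#' Build a morphable model from a registered training set
#'
#' Computes the average face and displacement matrix, then learns the
#' deformation basis: sparse locally-coherent components
#' ([learn_slc_components()]) for `kind = "slc"`, or the orthonormal PCA
#' baseline ([build_pca_model()]) for `kind = "pca"`.
#'
#' @param ts a [training_set()].
#' @param k number of components.
#' @param kind `"slc"` or `"pca"`.
#' @param lambda1,lambda2 elastic-net weights (SLC only).
#' @param opts solver options, see [learn_slc_components()].
#' @return an `slc_model` with fields `mean`, `components` (k x 3m),
#'   `weights`, `kind`, `topology_id`, `hyperparams`.
#' @export
build_model <- function(ts, k, kind = c("slc", "pca"),
                        lambda1 = 0.5, lambda2 = 0.05, opts = list()) {
  kind <- match.arg(kind)
  if (!inherits(ts, "training_set")) stop("'ts' must be a training_set")
  m <- compute_mean(ts)
  V <- build_training_matrix(ts, m)
  if (kind == "pca") {
    mod <- build_pca_model(V, k, topology_id = ts$topology_id, mean = m)
    return(mod)
  }
  fitres <- learn_slc_components(V, k, lambda1, lambda2, opts)
  mu <- compute_component_weights(fitres$C)
  new_slc_model(
    mean = m, components = fitres$C, weights = mu, kind = "slc",
    topology_id = ts$topology_id,
    hyperparams = list(k = k, lambda1 = lambda1, lambda2 = lambda2,
                       data_offset = fitres$data_offset,
                       iterations = fitres$iterations,
                       seed = opts$seed %||% 1L),
    dictionary = fitres$D, objective = fitres$objective
  )
}

#' PCA baseline morphable model
#'
#' Standard global 3DMM: components are the top-k right-singular directions
#' of `t(V)` (mutually orthonormal, ordered by decreasing singular value);
#' weights are the corresponding standard deviations, floored at 1e-8.
#'
#' @param V 3m x N displacement matrix.
#' @param k number of components, `k <= N - 1`.
#' @param topology_id template identifier stored in the model.
#' @param mean mean shape vector stored in the model (defaults to zeros).
#' @return an `slc_model` with `kind = "pca"`.
#' @export
build_pca_model <- function(V, k, topology_id = "pca", mean = NULL) {
  V <- as.matrix(V)
  N <- ncol(V)
  if (k > N - 1L) stop("k must be <= N - 1 = ", N - 1L)
  sv <- svd(V, nu = k, nv = 0L)
  comps <- t(sv$u[, seq_len(k), drop = FALSE])   # k x 3m, orthonormal rows
  sdev <- pmax(sv$d[seq_len(k)] / sqrt(N - 1), 1e-8)
  new_slc_model(
    mean = mean %||% numeric(nrow(V)), components = comps, weights = sdev,
    kind = "pca", topology_id = topology_id,
    hyperparams = list(k = k, lambda1 = 0, lambda2 = 0, data_offset = 0,
                       iterations = 1L, seed = NA_integer_)
  )
}

MODEL_ARCHIVE_VERSION <- "slcau-model-1"

#' Save a model to a single-file JSON archive
#'
#' All fields round-trip losslessly (full double precision) through
#' [load_model()]; the archive carries a version tag.
#'
#' @param model an `slc_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "slc_model")) stop("'model' must be an slc_model")
  payload <- list(
    version = MODEL_ARCHIVE_VERSION,
    kind = model$kind,
    topology_id = model$topology_id,
    k = nrow(model$components),
    n_coords = length(model$mean),
    mean = model$mean,
    components = as.numeric(model$components),   # column-major flattening
    components_dim = dim(model$components),
    weights = model$weights,
    hyperparams = model$hyperparams,
    dictionary = if (is.null(model$dictionary)) NULL else as.numeric(model$dictionary),
    dictionary_dim = if (is.null(model$dictionary)) NULL else dim(model$dictionary),
    objective = model$objective
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model archive written by [save_model()]
#'
#' @param path archive path.
#' @return an `slc_model`.
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop("failed to parse model archive '", path, "': ",
                             conditionMessage(e))
                      })
  if (!identical(payload$version, MODEL_ARCHIVE_VERSION)) {
    stop("unsupported model archive version '", payload$version,
         "' (expected '", MODEL_ARCHIVE_VERSION, "')")
  }
  comps <- matrix(payload$components, payload$components_dim[1L],
                  payload$components_dim[2L])
  dict <- NULL
  if (!is.null(payload$dictionary)) {
    dict <- matrix(payload$dictionary, payload$dictionary_dim[1L],
                   payload$dictionary_dim[2L])
  }
  hp <- payload$hyperparams
  new_slc_model(mean = payload$mean, components = comps,
                weights = payload$weights, kind = payload$kind,
                topology_id = payload$topology_id, hyperparams = hp,
                dictionary = dict, objective = payload$objective)
}

#' Training-side reconstruction of the transposed training matrix
#'
#' Returns `D %*% C + data_offset`, the model's approximation of `V'`;
#' used to audit dictionary-learning quality.
#'
#' @param model an `slc_model` of kind `"slc"` with a stored dictionary, or
#'   a raw [learn_slc_components()] result.
#' @return N x 3m matrix.
#' @export
slc_reconstruct <- function(model) {
  if (inherits(model, "slc_model")) {
    if (is.null(model$dictionary)) stop("model carries no training dictionary")
    model$dictionary %*% model$components + model$hyperparams$data_offset
  } else {
    model$D %*% model$C + model$data_offset
  }
}

#' Spatial locality of learned components
#'
#' For each component row, takes the coordinates whose magnitude exceeds
#' `support` times the row maximum, maps them to vertices, and reports the
#' largest fraction falling inside a single labelled region.  Values near
#' 1 mean the component deforms one region only; global (PCA-like)
#' components score near the largest region's share of the face.
#'
#' @param components k x 3m component matrix (or an `slc_model`).
#' @param assignment per-vertex region labels (length m).
#' @param support support threshold as a fraction of the row maximum
#'   (default 0.5).
#' @return length-k vector of modal-region support fractions.
#' @export
component_locality <- function(components, assignment, support = 0.5) {
  if (inherits(components, "slc_model")) components <- components$components
  m <- ncol(components) / 3L
  if (length(assignment) != m) stop("assignment length must equal vertex count")
  vertex_of <- rep(seq_len(m), each = 3L)
  apply(components, 1L, function(row) {
    a <- abs(row)
    idx <- which(a >= support * max(a))
    if (!length(idx)) return(0)
    max(table(assignment[vertex_of[idx]])) / length(idx)
  })
}
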