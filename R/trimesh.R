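#' Triangular surface mesh
#'
#' Container for a raw 3D face surface: vertex coordinates in millimetres,
#' triangle connectivity, and optional named landmarks.  Vertex order is
#' authoritative for dense correspondence; the faces are carried along for
#' IO and visualization but never used by the numerics, which are purely
#' point-based.
#'
#' @param vertices numeric m x 3 matrix of vertex coordinates (mm).
#' @param faces integer f x 3 matrix of 1-based vertex indices, or `NULL`
#'   for a point cloud.
#' @param landmarks optional named landmark set: numeric l x 3 matrix with
#'   unique rownames (e.g. `"nose_tip"`).
#' @param subject_id optional subject identifier.
#' @param label optional AU/expression/neutral tag.
#' @return object of class `trimesh`.
#' @examples
#' tet <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'                faces = rbind(c(1, 2, 3), c(1, 2, 4)))
#' tet
#' @export
trimesh <- function(vertices, faces = NULL, landmarks = NULL,
                    subject_id = NULL, label = NULL) {
  vertices <- as_point_matrix(vertices)
  storage.mode(vertices) <- "double"
  if (nrow(vertices) < 1L) stop("mesh has an empty vertex set")
  assert_finite(vertices, "vertices")
  if (!is.null(faces)) {
    faces <- as.matrix(faces)
    if (ncol(faces) != 3L) stop("faces must be triangles (3 indices per face)")
    storage.mode(faces) <- "integer"
    if (nrow(faces) > 0L &&
        (min(faces) < 1L || max(faces) > nrow(vertices))) {
      stop("face index out of range: indices must lie in [1, ", nrow(vertices), "]")
    }
  }
  if (!is.null(landmarks)) {
    landmarks <- as_point_matrix(landmarks)
    nm <- rownames(landmarks)
    if (is.null(nm) || anyNA(nm) || any(nm == "")) {
      stop("landmarks must have non-empty rownames")
    }
    if (anyDuplicated(nm)) stop("landmark names must be unique")
    assert_finite(landmarks, "landmarks")
  }
  structure(
    list(vertices = vertices, faces = faces, landmarks = landmarks,
         subject_id = subject_id, label = label),
    class = "trimesh"
  )
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d faces", nrow(x$vertices),
              if (is.null(x$faces)) 0L else nrow(x$faces)))
  if (!is.null(x$landmarks)) cat(sprintf(", %d landmarks", nrow(x$landmarks)))
  if (!is.null(x$subject_id)) cat(sprintf(" [subject %s]", x$subject_id))
  if (!is.null(x$label)) cat(sprintf(" [label %s]", x$label))
  cat("\n")
  invisible(x)
}

#' Linearized registered shape vector
#'
#' A shape on the common template topology, stored as the length-3m vector
#' `[x1, y1, z1, ..., xm, ym, zm]` (mm).  Two registered shapes are
#' combinable only when their `topology_id` matches.
#'
#' @param vector numeric vector of length 3m.
#' @param topology_id identifier of the shared template topology.
#' @return object of class `registered_shape`.
#' @export
registered_shape <- function(vector, topology_id) {
  vector <- as.numeric(vector)
  if (length(vector) %% 3L != 0L) {
    stop("registered shape length must be divisible by 3")
  }
  assert_finite(vector, "shape vector")
  structure(list(vector = vector, topology_id = as.character(topology_id)),
            class = "registered_shape")
}

#' @export
print.registered_shape <- function(x, ...) {
  cat(sprintf("registered_shape: %d vertices on topology '%s'\n",
              length(x$vector) / 3L, x$topology_id))
  invisible(x)
}

#' Convert a mesh to a registered shape vector
#'
#' Flattens vertex i into positions `3i-2..3i` of the vector, so that
#' [delinearize()] is an exact inverse.
#'
#' @param mesh a [trimesh()].
#' @param topology_id template identifier attached to the result.
#' @return a [registered_shape()].
#' @seealso [delinearize()]
#' @export
linearize <- function(mesh, topology_id) {
  registered_shape(flatten_points(as_point_matrix(mesh)), topology_id)
}

#' Reconstruct a mesh from a registered shape vector
#'
#' @param shape a [registered_shape()] or plain length-3m numeric vector.
#' @param faces optional triangle matrix to attach (template connectivity).
#' @param landmarks,subject_id,label passed through to [trimesh()].
#' @return a [trimesh()].
#' @export
delinearize <- function(shape, faces = NULL, landmarks = NULL,
                        subject_id = NULL, label = NULL) {
  trimesh(as_point_matrix(shape), faces = faces, landmarks = landmarks,
          subject_id = subject_id, label = label)
}
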