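# OBJ / PLY mesh IO with ".lnd" landmark sidecar files.
#
# Only triangular geometry is handled; texture, UV and material records are
# ignored on read and never written.  Coordinates round-trip to well below
# 1e-6 mm (ascii writes use 9 significant decimals; binary PLY uses doubles).

lnd_path <- function(path) paste0(tools::file_path_sans_ext(path), ".lnd")

read_landmark_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(NULL)
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(vapply(parts, length, 1L) != 4L)
  if (length(bad)) {
    stop("malformed landmark file '", path, "' at line ", bad[1L],
         ": expected 'name x y z'")
  }
  coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(coords)) stop("malformed landmark file '", path, "': non-numeric coordinate")
  rownames(coords) <- vapply(parts, `[[`, "", 1L)
  coords
}

write_landmark_file <- function(landmarks, path) {
  writeLines(sprintf("%s %.9f %.9f %.9f", rownames(landmarks),
                     landmarks[, 1L], landmarks[, 2L], landmarks[, 3L]),
             path)
}

#' Read a triangular mesh from OBJ or PLY
#'
#' Supports Wavefront OBJ (`v`/`f` records) and PLY in both ascii and
#' binary little-endian form.  A landmark sidecar file with the same
#' basename and extension `.lnd` (one `name x y z` line per landmark) is
#' loaded automatically when present.
#'
#' @param path file path.
#' @param format `"obj"`, `"ply"` or `"auto"` (from the file extension).
#' @param subject_id,label optional metadata attached to the mesh.
#' @return a [trimesh()].
#' @export
read_mesh <- function(path, format = c("auto", "obj", "ply"),
                      subject_id = NULL, label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, obj = "obj", ply = "ply",
                     stop("cannot infer mesh format from extension '.", ext, "'"))
  }
  parsed <- if (format == "obj") read_obj(path) else read_ply(path)
  lm <- NULL
  if (file.exists(lnd_path(path))) lm <- read_landmark_file(lnd_path(path))
  trimesh(parsed$vertices, faces = parsed$faces, landmarks = lm,
          subject_id = subject_id, label = label)
}

#' Write a triangular mesh to OBJ or PLY
#'
#' Landmarks, when present, are emitted to a `.lnd` sidecar next to the
#' mesh file.  Files written here round-trip through [read_mesh()] with
#' coordinates preserved to better than 1e-6 mm.
#'
#' @param mesh a [trimesh()].
#' @param path output file path.
#' @param format `"obj"` or `"ply"`; default from the file extension.
#' @param binary for PLY, write binary little-endian (doubles) instead of
#'   ascii.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "obj", "ply"),
                       binary = FALSE) {
  if (!inherits(mesh, "trimesh")) stop("'mesh' must be a trimesh")
  assert_finite(mesh$vertices, "vertices")
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, obj = "obj", ply = "ply",
                     stop("cannot infer mesh format from extension '.", ext, "'"))
  }
  ok <- tryCatch({
    if (format == "obj") write_obj(mesh, path) else write_ply(mesh, path, binary)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ", conditionMessage(e)))
  if (!is.null(mesh$landmarks)) write_landmark_file(mesh$landmarks, lnd_path(path))
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v[[:space:]]", lines)
  flines <- grep("^f[[:space:]]", lines)
  if (length(vlines) == 0L) stop("OBJ parse error in '", path, "': no vertices")
  vparts <- strsplit(trimws(sub("^v", "", lines[vlines])), "[[:space:]]+")
  nv <- vapply(vparts, length, 1L)
  if (any(nv < 3L)) {
    stop("OBJ parse error at line ", vlines[which(nv < 3L)[1L]],
         ": vertex record needs 3 coordinates")
  }
  verts <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3)))
  if (anyNA(verts)) {
    bad <- which(apply(is.na(verts), 1L, any))[1L]
    stop("OBJ parse error at line ", vlines[bad], ": non-numeric coordinate")
  }
  faces <- NULL
  if (length(flines)) {
    fparts <- strsplit(trimws(sub("^f", "", lines[flines])), "[[:space:]]+")
    nf <- vapply(fparts, length, 1L)
    if (any(nf != 3L)) {
      stop("OBJ parse error at line ", flines[which(nf != 3L)[1L]],
           ": only triangular faces are supported")
    }
    idx <- t(vapply(fparts,
                    function(p) as.integer(sub("/.*$", "", p)), integer(3)))
    if (anyNA(idx)) {
      bad <- which(apply(is.na(idx), 1L, any))[1L]
      stop("OBJ parse error at line ", flines[bad], ": bad face index")
    }
    if (min(idx) < 1L || max(idx) > nrow(verts)) {
      bad <- which(apply(idx < 1L | idx > nrow(verts), 1L, any))[1L]
      stop("OBJ parse error at line ", flines[bad],
           ": face index out of range [1, ", nrow(verts), "]")
    }
    faces <- idx
  }
  list(vertices = verts, faces = faces)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  writeLines(sprintf("v %.9f %.9f %.9f", v[, 1L], v[, 2L], v[, 3L]), con)
  if (!is.null(mesh$faces) && nrow(mesh$faces)) {
    f <- mesh$faces
    writeLines(sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  }
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64")) {
    readBin(con, "double", 1L, size = sz, endian = "little")
  } else {
    readBin(con, "integer", 1L, size = sz, endian = "little",
            signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("PLY parse error in '", path, "': missing 'ply' magic")
  fmt <- NULL
  elements <- list()  # each: list(name, count, props = list(list(name, type, list_count_type)))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("PLY parse error in '", path, "': truncated header")
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
    if (length(tok) == 0L || tok[1L] == "comment") next
    if (tok[1L] == "format") {
      fmt <- tok[2L]
      if (!fmt %in% c("ascii", "binary_little_endian")) {
        stop("PLY parse error in '", path, "': unsupported format '", fmt, "'")
      }
    } else if (tok[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property") {
      if (is.null(cur)) stop("PLY parse error in '", path, "': property before element")
      if (tok[2L] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5L], type = tok[4L], count_type = tok[3L])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3L], type = tok[2L], count_type = NULL)
      }
    } else if (tok[1L] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(fmt)) stop("PLY parse error in '", path, "': no format line")
  vel <- elements[["vertex"]]
  if (is.null(vel) || vel$count < 1L) stop("PLY parse error in '", path, "': no vertices")
  pnames <- vapply(vel$props, `[[`, "", "name")
  if (!all(c("x", "y", "z") %in% pnames)) {
    stop("PLY parse error in '", path, "': vertex element lacks x/y/z")
  }
  fel <- elements[["face"]]

  if (fmt == "ascii") {
    toks <- scan(con, what = character(), quiet = TRUE)
    pos <- 1L
    take <- function(n) {
      if (pos + n - 1L > length(toks)) stop("PLY parse error in '", path, "': truncated body")
      out <- toks[pos:(pos + n - 1L)]
      pos <<- pos + n
      out
    }
    verts <- matrix(0, vel$count, 3L)
    for (i in seq_len(vel$count)) {
      row <- as.numeric(take(length(vel$props)))
      if (anyNA(row)) stop("PLY parse error in '", path, "': non-numeric vertex ", i)
      verts[i, ] <- row[match(c("x", "y", "z"), pnames)]
    }
    faces <- NULL
    if (!is.null(fel) && fel$count > 0L) {
      faces <- matrix(0L, fel$count, 3L)
      for (i in seq_len(fel$count)) {
        cnt <- as.integer(take(1L))
        if (is.na(cnt)) stop("PLY parse error in '", path, "': bad face count, face ", i)
        idx <- as.integer(take(cnt))
        if (cnt != 3L) stop("PLY parse error in '", path, "': only triangular faces supported")
        faces[i, ] <- idx + 1L
      }
    }
  } else {
    verts <- matrix(0, vel$count, 3L)
    xyz <- match(c("x", "y", "z"), pnames)
    for (i in seq_len(vel$count)) {
      vals <- vapply(vel$props, function(p) {
        if (!is.null(p$count_type)) stop("PLY parse error: list property on vertex")
        as.numeric(ply_read_scalar(con, p$type))
      }, numeric(1))
      verts[i, ] <- vals[xyz]
    }
    faces <- NULL
    if (!is.null(fel) && fel$count > 0L) {
      lp <- fel$props[[1L]]
      faces <- matrix(0L, fel$count, 3L)
      for (i in seq_len(fel$count)) {
        cnt <- as.integer(ply_read_scalar(con, lp$count_type))
        if (length(cnt) == 0L || is.na(cnt)) {
          stop("PLY parse error in '", path, "': truncated face ", i)
        }
        if (cnt != 3L) stop("PLY parse error in '", path, "': only triangular faces supported")
        idx <- vapply(seq_len(cnt), function(j)
          as.integer(ply_read_scalar(con, lp$type)), integer(1))
        faces[i, ] <- idx + 1L
      }
    }
  }
  if (!is.null(faces) && nrow(faces) &&
      (min(faces) < 1L || max(faces) > nrow(verts))) {
    stop("PLY parse error in '", path, "': face index out of range")
  }
  list(vertices = verts, faces = faces)
}

write_ply <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  nf <- if (is.null(f)) 0L else nrow(f)
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    sprintf("element vertex %d", nrow(v)),
    sprintf("property %s x", if (binary) "double" else "float"),
    sprintf("property %s y", if (binary) "double" else "float"),
    sprintf("property %s z", if (binary) "double" else "float"),
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices",
    "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    writeBin(as.numeric(t(v)), con, size = 8L, endian = "little")
    if (nf) {
      for (i in seq_len(nf)) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
      }
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%.9f %.9f %.9f", v[, 1L], v[, 2L], v[, 3L]), con)
    if (nf) writeLines(sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L), con)
  }
}
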