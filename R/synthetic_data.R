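# Synthetic face corpora.
#
# The licensed scan databases the method targets cannot ship with the
# package, so experiments run on a parametric stand-in: a half-ellipsoid
# template with labelled facial regions, smooth low-frequency identity
# fields per subject, and compact AU-like bump/pull fields supported on
# single regions.  The generator emits both registered ground truth (for
# model building and oracles) and resampled noisy point clouds standing in
# for raw scanner output.  Everything is a deterministic function of the
# seeds.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

derive_seed <- function(seed, ...) {
  off <- sum(c(...))
  as.integer((as.numeric(seed) * 7919 + off * 104729 + 12345) %% 2147483647)
}

# Ellipsoid semi-axes (mm): lateral, vertical, depth — adult-face scale.
TEMPLATE_AXES <- c(60, 80, 50)

ellipsoid_point <- function(theta, phi, axes = TEMPLATE_AXES) {
  cbind(axes[1L] * sin(theta) * cos(phi),
        axes[2L] * sin(theta) * sin(phi),
        axes[3L] * cos(theta))
}

template_region_of <- function(thn, phd) {
  ifelse(thn < 0.22, "nose",
  ifelse(phd >= 30 & phd < 90, "brow_right",
  ifelse(phd >= 90 & phd < 150, "brow_left",
  ifelse(phd >= 150 & phd < 210, "cheek_left",
  ifelse(phd >= 210 & phd < 330, ifelse(thn < 0.65, "mouth", "jaw"),
         "cheek_right")))))
}

#' Synthetic face template with landmarks and regions
#'
#' Builds a smooth half-ellipsoid mesh of exactly `m` vertices (apex plus
#' latitude rings), annotated with a `nose_tip` landmark at the apex — the
#' maximal-z vertex — plus a grid of boundary landmarks, and partitioned
#' into 7 labelled regions (nose, brows L/R, cheeks L/R, mouth, jaw) that
#' cover every vertex exactly once.  Fully deterministic.
#'
#' @param m vertex count, `>= 100`.
#' @param seed kept for interface symmetry; the template is deterministic.
#' @return object of class `face_template`: `mesh` (a [trimesh()] with
#'   landmarks), `region_map` (see [partition_regions()]), `scheme`,
#'   `assignment` (region id per vertex), `topology_id`.
#' @export
make_template <- function(m = 300L, seed = 1L) {
  m <- as.integer(m)
  if (m < 100L) stop("template needs m >= 100 vertices")
  n_rings <- max(6L, as.integer(round(sqrt(m))))
  theta <- seq_len(n_rings) / n_rings * (pi / 2)
  w <- sin(theta)
  counts <- pmax(3L, as.integer(round(w / sum(w) * (m - 1L))))
  while (sum(counts) != m - 1L) {
    j <- which.max(counts)
    counts[j] <- counts[j] + sign((m - 1L) - sum(counts))
  }
  verts <- matrix(0, m, 3L)
  verts[1L, ] <- c(0, 0, TEMPLATE_AXES[3L])
  ring_idx <- vector("list", n_rings)
  pos <- 2L
  thn <- numeric(m); phd <- numeric(m)
  thn[1L] <- 0; phd[1L] <- 0
  for (r in seq_len(n_rings)) {
    cnt <- counts[r]
    phi <- (seq_len(cnt) - 0.5) / cnt * 2 * pi
    idx <- pos:(pos + cnt - 1L)
    verts[idx, ] <- ellipsoid_point(theta[r], phi)
    thn[idx] <- theta[r] / (pi / 2)
    phd[idx] <- (phi * 180 / pi) %% 360
    ring_idx[[r]] <- idx
    pos <- pos + cnt
  }
  # Triangulation: apex fan plus, between consecutive rings, each ring-2
  # edge tied to the angularly nearest ring-1 vertex and vice versa.
  faces <- list()
  first <- ring_idx[[1L]]
  for (j in seq_along(first)) {
    faces[[length(faces) + 1L]] <-
      c(1L, first[j], first[if (j == length(first)) 1L else j + 1L])
  }
  ring_phi <- function(idx) atan2(verts[idx, 2L] / TEMPLATE_AXES[2L],
                                  verts[idx, 1L] / TEMPLATE_AXES[1L]) %% (2 * pi)
  for (r in seq_len(n_rings - 1L)) {
    i1 <- ring_idx[[r]]; i2 <- ring_idx[[r + 1L]]
    p1 <- ring_phi(i1); p2 <- ring_phi(i2)
    nearest_in <- function(phi, ps) {
      d <- abs(ps - phi)
      which.min(pmin(d, 2 * pi - d))
    }
    for (j in seq_along(i2)) {
      jn <- if (j == length(i2)) 1L else j + 1L
      mid <- atan2(mean(sin(c(p2[j], p2[jn]))), mean(cos(c(p2[j], p2[jn])))) %% (2 * pi)
      faces[[length(faces) + 1L]] <- c(i2[j], i2[jn], i1[nearest_in(mid, p1)])
    }
    for (j in seq_along(i1)) {
      jn <- if (j == length(i1)) 1L else j + 1L
      mid <- atan2(mean(sin(c(p1[j], p1[jn]))), mean(cos(c(p1[j], p1[jn])))) %% (2 * pi)
      faces[[length(faces) + 1L]] <- c(i1[j], i2[nearest_in(mid, p2)], i1[jn])
    }
  }
  faces <- do.call(rbind, faces)
  faces <- faces[faces[, 1L] != faces[, 2L] & faces[, 2L] != faces[, 3L] &
                   faces[, 1L] != faces[, 3L], , drop = FALSE]

  assignment <- template_region_of(thn, phd)
  # Boundary landmarks at the analytic sector corners.
  tlev <- c(0.22, 0.65, 0.98) * (pi / 2)
  pcor <- c(30, 90, 150, 210, 270, 330)
  lms <- list(nose_tip = c(0, 0, TEMPLATE_AXES[3L]))
  for (i in seq_along(tlev)) for (p in pcor) {
    lms[[sprintf("c%d_%03d", i, p)]] <- drop(ellipsoid_point(tlev[i], p * pi / 180))
  }
  lm_mat <- do.call(rbind, lms)
  rownames(lm_mat) <- names(lms)

  corner <- function(i, p) sprintf("c%d_%03d", i, p)
  region_defs <- list(
    list(id = "nose", landmarks = c(corner(1, 30), corner(1, 150),
                                    corner(1, 210), corner(1, 330))),
    list(id = "brow_right", landmarks = c(corner(1, 30), corner(1, 90),
                                          corner(3, 90), corner(3, 30))),
    list(id = "brow_left", landmarks = c(corner(1, 90), corner(1, 150),
                                         corner(3, 150), corner(3, 90))),
    list(id = "cheek_left", landmarks = c(corner(1, 150), corner(1, 210),
                                          corner(3, 210), corner(3, 150))),
    list(id = "mouth", landmarks = c(corner(1, 210), corner(1, 330),
                                     corner(2, 330), corner(2, 210))),
    list(id = "jaw", landmarks = c(corner(2, 210), corner(2, 330),
                                   corner(3, 330), corner(3, 210))),
    list(id = "cheek_right", landmarks = c(corner(1, 330), corner(1, 30),
                                           corner(3, 30), corner(3, 330)))
  )
  tab <- table(assignment)
  regions <- lapply(region_defs, function(r) {
    r$count <- as.integer(tab[[r$id]])
    r
  })
  scheme <- region_scheme(regions, id = sprintf("synthface-m%d", m))
  mesh <- trimesh(verts, faces = faces, landmarks = lm_mat)
  lmk_vidx <- nearest_vertex(lm_mat, verts)$index
  structure(
    list(mesh = mesh, scheme = scheme,
         region_map = partition_regions(lm_mat, scheme),
         assignment = assignment, topology_id = scheme$id,
         landmark_vertex = lmk_vidx),
    class = "face_template"
  )
}

#' @export
print.face_template <- function(x, ...) {
  cat(sprintf("face_template: %d vertices, %d regions (topology '%s')\n",
              nrow(x$mesh$vertices), length(x$region_map$regions),
              x$topology_id))
  invisible(x)
}

#' Fixed smooth identity basis of a template
#'
#' A deterministic set of `q` smooth low-frequency displacement fields
#' (sinusoids of wavelength 30-80 mm in random spatial directions, fixed
#' by the template), each normalized to unit per-vertex RMS.  Identities
#' are random coefficients over this basis: face identity variation is
#' low-dimensional relative to the corpus size, which is the premise that
#' lets a morphable model built from one set of subjects fit unseen ones.
#'
#' @param template a [make_template()] result.
#' @param q number of basis fields.
#' @return 3m x q matrix of unit-RMS displacement fields.
#' @export
identity_basis <- function(template, q = 8L) {
  P <- template$mesh$vertices
  with_seed(derive_seed(8191L, nrow(P), q), {
    vapply(seq_len(q), function(l) {
      wavelength <- stats::runif(1, 30, 80)
      k <- stats::rnorm(3); k <- k / sqrt(sum(k * k)) / wavelength
      phase <- stats::runif(1, 0, 2 * pi)
      s <- drop(sin(2 * pi * (P %*% k) + phase))
      d <- s %o% stats::rnorm(3)
      d <- d / sqrt(mean(rowSums(d * d)))
      flatten_points(d)
    }, numeric(3L * nrow(P)))
  })
}

#' Sample a synthetic identity
#'
#' Draws standard-normal coefficients over the template's fixed smooth
#' identity basis ([identity_basis()]) and scales the resulting
#' displacement field so its per-vertex RMS equals `identity_scale`.
#'
#' @param template a [make_template()] result.
#' @param identity_scale RMS displacement in mm (0 returns the template).
#' @param seed RNG seed; distinct seeds give distinct identities.
#' @return a [registered_shape()] on the template topology.
#' @export
sample_identity <- function(template, identity_scale = 3, seed = 1L) {
  base <- flatten_points(template$mesh$vertices)
  if (identity_scale <= 0) return(registered_shape(base, template$topology_id))
  B <- identity_basis(template)
  coef <- with_seed(seed, stats::rnorm(ncol(B)))
  disp <- drop(B %*% coef)
  rms <- sqrt(mean(rowSums(matrix(disp, ncol = 3L, byrow = TRUE)^2)))
  disp <- disp * (identity_scale / rms)
  registered_shape(base + disp, template$topology_id)
}

#' Apply a synthetic AU deformation field
#'
#' Adds a compact smooth displacement field supported exactly on the
#' spec's template region: a cosine taper from the region's central vertex
#' to zero at its far boundary, along the outward surface normal
#' (`"bump"`), along a constant downward pull direction (`"pull"`), or a
#' bump restricted to one lateral half of the region (`"asymmetric"`).
#' The field is identical for every subject (only the shape it is added to
#' differs) and scales linearly with `intensity`.
#'
#' @param shape a [registered_shape()] on the template topology.
#' @param au_spec list with `au_id`, `region`, `type`
#'   (`"bump"`/`"pull"`/`"asymmetric"`), `magnitude` (peak mm).
#' @param intensity activation level in `[0, 1]`.
#' @param template the [make_template()] the shape lives on.
#' @return deformed [registered_shape()].
#' @export
apply_synthetic_au <- function(shape, au_spec, intensity = 1,
                               template = NULL) {
  if (is.null(template)) stop("'template' is required")
  if (au_spec$magnitude <= 0) stop("AU magnitude must be > 0")
  if (intensity == 0) return(shape)
  field <- synthetic_au_field(au_spec, template)
  registered_shape(shape$vector + intensity * field, shape$topology_id)
}

#' Ground-truth displacement field of a synthetic AU (unit intensity)
#'
#' @inheritParams apply_synthetic_au
#' @return length-3m displacement vector (mm).
#' @export
synthetic_au_field <- function(au_spec, template) {
  P <- template$mesh$vertices
  idx <- which(template$assignment == au_spec$region)
  if (!length(idx)) stop("unknown template region '", au_spec$region, "'")
  if (identical(au_spec$type, "asymmetric")) {
    idx <- idx[P[idx, 1L] > stats::median(P[idx, 1L])]
  }
  ctr <- colMeans(P[idx, , drop = FALSE])
  seedv <- idx[which.min(rowSums(sweep(P[idx, , drop = FALSE], 2L, ctr)^2))]
  r <- sqrt(rowSums(sweep(P[idx, , drop = FALSE], 2L, P[seedv, ])^2))
  rmax <- max(r) * 1.0001
  w <- 0.5 * (1 + cos(pi * r / rmax))
  disp <- matrix(0, nrow(P), 3L)
  if (identical(au_spec$type, "pull")) {
    dir <- c(0, -1, -0.25); dir <- dir / sqrt(sum(dir^2))
    disp[idx, ] <- (au_spec$magnitude * w) %o% dir
  } else {
    n <- sweep(P[idx, , drop = FALSE], 2L, TEMPLATE_AXES^2, "/")
    n <- n / sqrt(rowSums(n * n))
    disp[idx, ] <- au_spec$magnitude * w * n
  }
  flatten_points(disp)
}

#' Default synthetic AU catalogue
#'
#' Four AU-like fields mirroring common FACS actions at reduced scale:
#' a left outer-brow raise, a right cheek puff, an asymmetric lip-corner
#' pull, and a jaw drop.
#'
#' @param magnitude peak displacement in mm.
#' @return list of AU spec lists.
#' @export
default_au_specs <- function(magnitude = 6) {
  list(
    list(au_id = "AU-BROW-RAISE-L", region = "brow_left", type = "bump",
         magnitude = magnitude),
    list(au_id = "AU-CHEEK-PUFF-R", region = "cheek_right", type = "bump",
         magnitude = magnitude),
    list(au_id = "AU-LIP-PULL", region = "mouth", type = "asymmetric",
         magnitude = magnitude),
    list(au_id = "AU-JAW-DROP", region = "jaw", type = "pull",
         magnitude = magnitude)
  )
}

#' Synthetic corpus configuration
#'
#' Defaults are the package's reduced-scale analogue of the method's study
#' conditions: 10 subjects, 4 AU activations each plus a neutral,
#' 3 mm RMS identity variation, 6 mm peak AU displacement, 0.2 mm
#' Gaussian scanner noise, and raw scans resampled to 85% of the vertices
#' in shuffled order.
#'
#' @param seed master seed; fully determines the corpus.
#' @param m template vertex count.
#' @param n_subjects number of subjects.
#' @param identity_scale RMS identity displacement (mm).
#' @param au_specs AU catalogue, see [default_au_specs()].
#' @param scans_per_condition repeats of each (subject, AU) condition.
#' @param noise_sigma Gaussian vertex jitter sd (mm).
#' @param resample emit raw scans as shuffled vertex subsets.
#' @param keep_fraction fraction of cloud points kept when resampling.
#' @param oversample raw-cloud density relative to the template (extra
#'   points drawn uniformly on the deformed surface; scanner clouds are
#'   denser than the model topology).
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, m = 300L, n_subjects = 10L,
                             identity_scale = 3, au_specs = default_au_specs(),
                             scans_per_condition = 1L, noise_sigma = 0.2,
                             resample = TRUE, keep_fraction = 0.85,
                             oversample = 1.5) {
  if (any(vapply(au_specs, `[[`, 0, "magnitude") <= 0)) {
    stop("AU magnitudes must be > 0")
  }
  structure(list(seed = as.integer(seed), m = as.integer(m),
                 n_subjects = as.integer(n_subjects),
                 identity_scale = identity_scale, au_specs = au_specs,
                 scans_per_condition = as.integer(scans_per_condition),
                 noise_sigma = noise_sigma, resample = isTRUE(resample),
                 keep_fraction = keep_fraction, oversample = oversample),
            class = "synthetic_config")
}

#' Read a synthetic corpus configuration from YAML
#'
#' @param path YAML file whose keys mirror [synthetic_config()] arguments.
#' @return a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(synthetic_config, cfg)
}

# Degrade a registered ground-truth shape into a raw scan point cloud.
# Raw scanner clouds are denser than the model topology, so extra surface
# points are drawn uniformly on the deformed triangles (area-weighted)
# before subsetting, jittering and shuffling.
make_raw_scan <- function(reg, template, config, seed, subject_id, label) {
  pts <- as_point_matrix(reg)
  m <- nrow(pts)
  f <- template$mesh$faces
  with_seed(seed, {
    cloud <- pts
    n_extra <- round(m * max(0, (config$oversample %||% 1.5) - 1))
    if (n_extra > 0L && !is.null(f) && nrow(f)) {
      ab <- pts[f[, 2L], ] - pts[f[, 1L], ]
      ac <- pts[f[, 3L], ] - pts[f[, 1L], ]
      cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
                  ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
                  ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
      area <- sqrt(rowSums(cr * cr)) / 2
      fi <- sample.int(nrow(f), n_extra, replace = TRUE, prob = area)
      u <- stats::runif(n_extra); v <- stats::runif(n_extra)
      flip <- u + v > 1
      u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
      cloud <- rbind(cloud,
                     pts[f[fi, 1L], ] + u * ab[fi, , drop = FALSE] +
                       v * ac[fi, , drop = FALSE])
    }
    keep <- seq_len(nrow(cloud))
    if (config$resample) {
      keep <- sample.int(nrow(cloud),
                         max(10L, round(config$keep_fraction * nrow(cloud))))
    }
    out <- cloud[keep, , drop = FALSE]
    if (config$noise_sigma > 0) {
      out <- out + matrix(stats::rnorm(length(out), 0, config$noise_sigma),
                          nrow(out), 3L)
    }
    lm <- template$mesh$landmarks +
      (pts - template$mesh$vertices)[template$landmark_vertex, , drop = FALSE]
    if (config$noise_sigma > 0) {
      lm <- lm + matrix(stats::rnorm(length(lm), 0, config$noise_sigma),
                        nrow(lm), 3L)
    }
    rownames(lm) <- rownames(template$mesh$landmarks)
    trimesh(out, landmarks = lm, subject_id = subject_id, label = label)
  })
}

#' Generate a synthetic evaluation corpus in memory
#'
#' Per subject: one registered ground-truth neutral plus one registered
#' shape per AU spec (and repeat), each paired with a degraded raw scan.
#' Neutral scans carry zero AU field; AU fields are identical across
#' subjects up to the identity deformation, so coefficient disentangling
#' is achievable in principle.
#'
#' @param config a [synthetic_config()].
#' @param template optional pre-built [make_template()] (must match
#'   `config$m`).
#' @return list with `template`, `config` and `subjects`, where each
#'   subject holds `neutral` / `scans` entries of `(reg, scan, label)`.
#' @export
generate_corpus <- function(config = synthetic_config(), template = NULL) {
  if (is.null(template)) template <- make_template(config$m, config$seed)
  subjects <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    neutral_reg <- sample_identity(template, config$identity_scale,
                                   seed = derive_seed(config$seed, s))
    neutral_scan <- make_raw_scan(neutral_reg, template, config,
                                  seed = derive_seed(config$seed, s, 500000L),
                                  subject_id = sid, label = "neutral")
    scans <- list()
    for (a in seq_along(config$au_specs)) {
      spec <- config$au_specs[[a]]
      for (rep in seq_len(config$scans_per_condition)) {
        reg <- apply_synthetic_au(neutral_reg, spec, intensity = 1,
                                  template = template)
        scan <- make_raw_scan(reg, template, config,
                              seed = derive_seed(config$seed, s, a * 1000L, rep),
                              subject_id = sid, label = spec$au_id)
        scans[[length(scans) + 1L]] <-
          list(reg = reg, scan = scan, label = spec$au_id, rep = rep)
      }
    }
    subjects[[sid]] <- list(subject_id = sid, neutral_reg = neutral_reg,
                            neutral_scan = neutral_scan, scans = scans)
  }
  list(template = template, config = config, subjects = subjects)
}

#' Build a registered training set of synthetic faces
#'
#' Emulates a registered training database: per subject a neutral plus one
#' scan per AU at a random intensity.  Used to learn the deformation
#' components; subjects here are distinct from any evaluation corpus
#' generated with a different seed.
#'
#' @param template a [make_template()] result.
#' @param n_subjects number of training subjects.
#' @param au_specs AU catalogue.
#' @param identity_scale RMS identity displacement (mm).
#' @param intensity_range range of per-scan AU activation levels.
#' @param seed RNG seed.
#' @return a [training_set()] with `labels` and `subjects` metadata.
#' @export
build_training_set <- function(template, n_subjects = 14L,
                               au_specs = default_au_specs(),
                               identity_scale = 3,
                               intensity_range = c(0.4, 1),
                               seed = 2L) {
  cols <- list(); labels <- character(0); subs <- character(0)
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("T%02d", s)
    neutral <- sample_identity(template, identity_scale,
                               seed = derive_seed(seed, s, 900000L))
    cols[[length(cols) + 1L]] <- neutral$vector
    labels <- c(labels, "neutral"); subs <- c(subs, sid)
    for (a in seq_along(au_specs)) {
      inten <- with_seed(derive_seed(seed, s, a * 3000L),
                         stats::runif(1, intensity_range[1L], intensity_range[2L]))
      reg <- apply_synthetic_au(neutral, au_specs[[a]], intensity = inten,
                                template = template)
      cols[[length(cols) + 1L]] <- reg$vector
      labels <- c(labels, au_specs[[a]]$au_id); subs <- c(subs, sid)
    }
  }
  training_set(do.call(cbind, cols), topology_id = template$topology_id,
               subjects = subs, labels = labels)
}

#' Write a synthetic corpus to disk
#'
#' Emits, under `out_dir`: raw scans as ascii PLY point clouds with `.lnd`
#' landmark sidecars, ground-truth registered shapes as whitespace-
#' delimited `x y z` text files, and a `manifest.json` recording the
#' configuration, per-file subject/label metadata and seeds.  Running the
#' same configuration twice produces byte-identical output.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
generate_dataset <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  corpus <- generate_corpus(config)
  write_mesh(corpus$template$mesh, file.path(out_dir, "template.ply"))
  entries <- list()
  emit <- function(reg, scan, sid, label, tag) {
    ply <- sprintf("%s_%s.ply", sid, tag)
    gt <- sprintf("%s_%s_gt.txt", sid, tag)
    write_mesh(scan, file.path(out_dir, ply))
    utils::write.table(as_point_matrix(reg), file.path(out_dir, gt),
                       row.names = FALSE, col.names = FALSE)
    list(scan = ply, ground_truth = gt, subject = sid, label = label)
  }
  for (sub in corpus$subjects) {
    sid <- sub$subject_id
    entries[[length(entries) + 1L]] <-
      emit(sub$neutral_reg, sub$neutral_scan, sid, "neutral", "neutral")
    for (i in seq_along(sub$scans)) {
      sc <- sub$scans[[i]]
      tag <- sprintf("%s_r%d", gsub("[^A-Za-z0-9]+", "-", sc$label), sc$rep)
      entries[[length(entries) + 1L]] <-
        emit(sc$reg, sc$scan, sid, sc$label, tag)
    }
  }
  manifest <- list(format = "slcau-corpus-1",
                   config = unclass(config), files = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Registered corpus of independent region-localized deformations
#'
#' Every scan activates each deformable region independently (uniform
#' random amplitude over a bump field), plus Gaussian vertex noise.  The
#' generating factors are spatially compact and mutually independent, so
#' deformation components learned from this corpus should localize to
#' single regions — the corpus the locality diagnostics run on.
#'
#' @param template a [make_template()] result.
#' @param n_scans number of registered scans.
#' @param regions region ids to activate (default: all but the nose cap).
#' @param magnitude peak bump displacement (mm).
#' @param amp_range per-scan activation range.
#' @param noise_sigma Gaussian vertex jitter sd (mm).
#' @param seed RNG seed.
#' @return a [training_set()].
#' @export
build_region_activation_set <- function(template, n_scans = 60L,
                                        regions = c("brow_left", "brow_right",
                                                    "cheek_left", "cheek_right",
                                                    "mouth", "jaw"),
                                        magnitude = 6, amp_range = c(0.2, 1),
                                        noise_sigma = 0.1, seed = 3L) {
  base <- flatten_points(template$mesh$vertices)
  fields <- vapply(regions, function(r) {
    synthetic_au_field(list(au_id = r, region = r, type = "bump",
                            magnitude = magnitude), template)
  }, numeric(length(base)))
  F <- with_seed(seed, {
    vapply(seq_len(n_scans), function(i) {
      amps <- stats::runif(length(regions), amp_range[1L], amp_range[2L])
      base + drop(fields %*% amps) +
        stats::rnorm(length(base), 0, noise_sigma)
    }, numeric(length(base)))
  })
  training_set(F, topology_id = template$topology_id)
}
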