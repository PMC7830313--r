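# Shared fixtures, built lazily and cached for the whole test run.  The
# heavy objects (template, trained model, evaluation corpus, extracted
# coefficient records) are used by several files; building them once keeps
# the suite fast without any fixture files on disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fx_template <- function() fixture("template", function() make_template(300L, 1L))

fx_training_set <- function() {
  fixture("training_set", function() {
    build_training_set(fx_template(), n_subjects = 14L, seed = 2L)
  })
}

fx_model <- function() {
  fixture("model", function() {
    build_model(fx_training_set(), k = 30L, lambda1 = 0.5, lambda2 = 0.05,
                opts = list(seed = 1L, max_iter = 250L))
  })
}

fx_corpus <- function() {
  fixture("corpus", function() {
    generate_corpus(synthetic_config(seed = 11L), template = fx_template())
  })
}

# Records for every (subject, AU) pair plus neutral-vs-neutral controls.
fx_records_all <- function() {
  fixture("records_all", function() {
    extract_corpus_records(fx_model(), fx_corpus(), neutral_control = TRUE)
  })
}

fx_records <- function() {
  Filter(function(r) r$au_label != "neutral", fx_records_all())
}

fx_neutral_records <- function() {
  Filter(function(r) r$au_label == "neutral", fx_records_all())
}

# Region-localized corpus and the two models the locality contrast needs.
fx_locality_set <- function() {
  fixture("locality_set", function() {
    build_region_activation_set(fx_template(), n_scans = 60L, seed = 3L)
  })
}

fx_locality_slc <- function() {
  fixture("locality_slc", function() {
    V <- build_training_matrix(fx_locality_set())
    learn_slc_components(V, k = 12L, lambda1 = 0.5, lambda2 = 0.05,
                         opts = list(seed = 1L, max_iter = 250L))
  })
}

fx_locality_pca <- function() {
  fixture("locality_pca", function() {
    V <- build_training_matrix(fx_locality_set())
    build_pca_model(V, k = 50L, topology_id = fx_template()$topology_id)
  })
}

fx_loocv <- function() {
  fixture("loocv", function() loocv_evaluate(fx_records()))
}

# Small helpers ------------------------------------------------------------

coef_matrix <- function(records) {
  do.call(rbind, lapply(records, `[[`, "alpha_e"))
}

record_labels <- function(records) vapply(records, `[[`, "", "au_label")
record_subjects <- function(records) vapply(records, `[[`, "", "subject_id")

vertex_norms <- function(vec) sqrt(rowSums(matrix(vec, ncol = 3L, byrow = TRUE)^2))

random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# A small well-formed mesh used across the IO tests.
unit_tetra <- function(landmarks = FALSE) {
  lm <- NULL
  if (landmarks) {
    lm <- rbind(nose_tip = c(0, 0, 1), chin = c(1, 0, 0))
  }
  trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
          faces = rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)),
          landmarks = lm)
}
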