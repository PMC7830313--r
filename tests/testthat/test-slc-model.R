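test_that("mean shape and displacement matrix follow their definitions", {
  set.seed(1)
  F <- matrix(rnorm(30 * 8), 30, 8)
  ts <- training_set(F, "t")
  expect_equal(compute_mean(ts), rowMeans(F), tolerance = 1e-12)
  f <- F[, 1]
  expect_equal(compute_mean(training_set(cbind(f, f), "t")), f)
  expect_equal(compute_mean(training_set(cbind(rep(0, 6), rep(2, 6)), "t")),
               rep(1, 6))
  V <- build_training_matrix(ts)
  expect_equal(rowSums(V), rep(0, 30), tolerance = 1e-12)
  expect_equal(V + rowMeans(F), F, tolerance = 1e-12)
  expect_true(all(build_training_matrix(training_set(cbind(f, f), "t")) == 0))
  expect_error(build_training_matrix(ts, m = rep(0, 5)), "match")
})

test_that("training sets validate their invariants", {
  expect_error(training_set(matrix(0, 30, 1), "t"), "at least N = 2")
  expect_error(training_set(matrix(0, 31, 3), "t"), "divisible by 3")
})

test_that("dictionary learning recovers noiseless generative data", {
  set.seed(7)
  N <- 30L; p <- 300L; k <- 5L
  D0 <- matrix(runif(N * k), N, k)
  D0 <- sweep(D0, 2, sqrt(colSums(D0^2)), "/")
  C0 <- matrix(rexp(k * p) * (runif(k * p) < 0.25), k, p)
  Vp <- D0 %*% C0
  f <- learn_slc_components(t(Vp), k, 0.01, 0.01,
                            opts = list(seed = 1, max_iter = 400))
  rel <- norm(Vp - (f$D %*% f$C + f$data_offset), "F") / norm(Vp, "F")
  expect_lt(rel, 0.05)
  expect_true(all(f$D >= 0))
  expect_true(all(f$C >= 0))
})

test_that("the elastic-net objective is non-increasing across iterations", {
  set.seed(11)
  V <- matrix(rnorm(240 * 20), 240, 20)
  f <- learn_slc_components(V, 6, 0.3, 0.05,
                            opts = list(seed = 2, max_iter = 50, tol = 0))
  expect_true(all(diff(f$objective) <= 1e-9))
})

test_that("a positive L1 weight yields strictly sparser components", {
  V <- build_training_matrix(fx_locality_set())
  f0 <- learn_slc_components(V, 8, 0, 0.05, opts = list(seed = 1, max_iter = 60))
  f1 <- learn_slc_components(V, 8, 0.5, 0.05, opts = list(seed = 1, max_iter = 60))
  expect_gt(mean(abs(f1$C) < 1e-6), mean(abs(f0$C) < 1e-6))
})

test_that("a very large L1 weight drives the coefficients to zero", {
  set.seed(3)
  V <- matrix(rnorm(60 * 10), 60, 10)
  f <- learn_slc_components(V, 3, 1e6, 0.05, opts = list(seed = 1, max_iter = 20))
  expect_true(all(f$C == 0))
  Vs <- t(V) - f$data_offset
  expect_equal(tail(f$objective, 1), sum(Vs^2) / ncol(Vs), tolerance = 1e-8)
})

test_that("dictionary learning validates its preconditions", {
  V <- matrix(rnorm(30 * 5), 30, 5)
  expect_error(learn_slc_components(V, 5, 0.1, 0.1), "smaller than")
  expect_error(learn_slc_components(V, 2, -0.1, 0.1), ">= 0")
})

test_that("component weights are per-row means floored at 1e-8", {
  C <- rbind(rep(2, 12), rep(0, 12))
  mu <- compute_component_weights(C)
  expect_equal(mu[1], 2)
  expect_equal(mu[2], 1e-8)
  set.seed(4)
  Cr <- matrix(rexp(5 * 30), 5, 30)
  expect_equal(compute_component_weights(Cr), rowMeans(Cr), tolerance = 1e-12)
  expect_error(compute_component_weights(-C), "non-negative")
})

test_that("PCA baseline matches the SVD oracle", {
  set.seed(8)
  V <- matrix(rnorm(90 * 12), 90, 12)
  pm <- build_pca_model(V, 5)
  expect_equal(tcrossprod(pm$components), diag(5), tolerance = 1e-8)
  sv <- svd(V)
  # reconstruction error with k components equals the tail singular energy
  proj <- t(pm$components) %*% (pm$components %*% V)
  expect_equal(norm(V - proj, "F"), sqrt(sum(sv$d[6:12]^2)), tolerance = 1e-8)
  # rank-1 case: one component explains everything
  V1 <- outer(rnorm(90), rnorm(12))
  p1 <- build_pca_model(V1, 3)
  r1 <- t(p1$components[1, , drop = FALSE]) %*%
    (p1$components[1, , drop = FALSE] %*% V1)
  expect_lt(norm(V1 - r1, "F"), 1e-8)
  expect_error(build_pca_model(V, 12), "N - 1")
})

test_that("model archives round-trip losslessly and check their version", {
  mod <- fx_model()
  path <- file.path(tempdir(), "model.json")
  save_model(mod, path)
  back <- load_model(path)
  expect_equal(back$mean, mod$mean, tolerance = 1e-12)
  expect_equal(back$components, mod$components, tolerance = 1e-12)
  expect_equal(back$weights, mod$weights, tolerance = 1e-12)
  expect_identical(back$kind, mod$kind)
  expect_identical(back$topology_id, mod$topology_id)
  # reloaded model gives identical fits downstream
  target <- fx_corpus()$subjects[[1]]$neutral_scan
  f1 <- fit_model(mod, target)
  f2 <- fit_model(back, target)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-9)
  # corrupted archive
  txt <- readLines(path, warn = FALSE)
  trunc <- file.path(tempdir(), "trunc.json")
  writeLines(substr(paste(txt, collapse = ""), 1, 500), trunc)
  expect_error(load_model(trunc), "parse")
  other <- file.path(tempdir(), "other.json")
  jsonlite::write_json(list(version = "something-else"), other, auto_unbox = TRUE)
  expect_error(load_model(other), "version")
})

test_that("learned SLC components localize; PCA components do not", {
  tpl <- fx_template()
  loc_slc <- component_locality(fx_locality_slc()$C, tpl$assignment)
  loc_pca <- component_locality(fx_locality_pca(), tpl$assignment)
  expect_gte(mean(loc_slc >= 0.7), 0.5)
  expect_lt(mean(loc_pca >= 0.7), 0.5)
})
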