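test_that("coefficient aggregation strategies follow their definitions", {
  v <- c(1, -2, 3)
  for (s in c("mean", "max", "first", "threshold")) {
    expect_equal(aggregate_coefficients(list(v), s), v)
  }
  expect_equal(aggregate_coefficients(list(v, -v), "mean"), c(0, 0, 0))
  set.seed(1)
  alphas <- replicate(6, rnorm(4), simplify = FALSE)
  expect_equal(aggregate_coefficients(alphas, "mean"),
               colMeans(do.call(rbind, alphas)), tolerance = 1e-12)
  expect_equal(aggregate_coefficients(list(c(1, -5), c(-3, 2)), "max"), c(-3, -5))
  expect_equal(aggregate_coefficients(list(c(1e-4, 1), c(-1e-4, 1)), "threshold"),
               c(0, 1))
  expect_error(aggregate_coefficients(list()), "empty")
})

test_that("feature preparation normalizes, standardizes and projects", {
  set.seed(2)
  X <- matrix(rnorm(40 * 6), 40, 6)
  fp <- prepare_features(X, variance = 0.95)
  Xl2 <- X / sqrt(rowSums(X^2))
  expect_equal(sqrt(rowSums(Xl2^2)), rep(1, 40))
  Z <- sweep(sweep(Xl2, 2, fp$preproc$center), 2, fp$preproc$scale, "/")
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_lt(max(abs(apply(Z, 2, var) - 1)), 1e-8)
  expect_equal(fp$train, Z %*% fp$preproc$rotation, tolerance = 1e-12)
  expect_error(prepare_features(rbind(X, 0)), "zero")
})

test_that("isotropic features keep nearly all dimensions at 95% variance", {
  set.seed(3)
  X <- matrix(rnorm(600 * 20), 600, 20)
  fp <- prepare_features(X, variance = 0.95)
  expect_gte(fp$preproc$ncomp, 18L)
})

test_that("test records are transformed with frozen training statistics", {
  set.seed(4)
  tr <- matrix(rnorm(30 * 5), 30, 5)
  te <- matrix(rnorm(10 * 5), 10, 5)
  fp <- prepare_features(tr, te)
  manual <- te / sqrt(rowSums(te^2))
  manual <- sweep(sweep(manual, 2, fp$preproc$center), 2, fp$preproc$scale, "/")
  expect_equal(fp$test, manual %*% fp$preproc$rotation, tolerance = 1e-12)
})

test_that("early fusion concatenates aligned feature sets", {
  a <- matrix(rnorm(12 * 50), 12, 50)
  b <- matrix(rnorm(12 * 300), 12, 300)
  expect_identical(ncol(fuse_features(a, b)), 350L)
  expect_identical(fuse_features(a, NULL), a)
  rownames(a) <- paste0("r", 1:12)
  b2 <- b; rownames(b2) <- paste0("x", 1:12)
  expect_error(fuse_features(a, b2), "aligned")
})

test_that("feature order does not change RBF-SVM predictions", {
  set.seed(5)
  n <- 40
  a <- matrix(rnorm(n * 3), n, 3) + rep(c(0, 3), each = n / 2)
  b <- matrix(rnorm(n * 2), n, 2)
  y <- rep(c("p", "q"), each = n / 2)
  c1 <- train_au_classifier(fuse_features(a, b), y, sigma = 2)
  c2 <- train_au_classifier(fuse_features(b, a), y, sigma = 2)
  p1 <- predict(c1, fuse_features(a, b))
  p2 <- predict(c2, fuse_features(b, a))
  expect_identical(p1$class, p2$class)
  expect_equal(p1$decision, p2$decision, tolerance = 1e-8)
})

test_that("the One-vs-Rest classifier separates well-separated classes", {
  set.seed(6)
  X <- rbind(matrix(rnorm(60, 0), 20, 3), matrix(rnorm(60, 6), 20, 3),
             matrix(rnorm(60, -6), 20, 3))
  y <- rep(c("a", "b", "c"), each = 20)
  clf <- train_au_classifier(X, y)
  expect_identical(length(clf$svms), 3L)    # one binary classifier per class
  pr <- predict(clf, X)
  expect_identical(pr$class, y)
  expect_error(train_au_classifier(X, rep("a", 60)), "2 classes")
})

test_that("identity fitting on generator subjects matches ground truth", {
  mod <- fx_model()
  corpus <- fx_corpus()
  # neutral equal to the mean gives near-zero identity coefficients
  idf0 <- fit_identity(mod, delinearize(mod$mean), opts = list(icp = FALSE))
  expect_lt(sqrt(sum(idf0$alpha_id^2)), 1e-6)
  expect_lt(per_vertex_error(idf0$s_n, delinearize(mod$mean)), 1e-3)
  # real subject: fitted neutral close to the registered ground truth
  sub <- corpus$subjects[[1]]
  idf <- fit_identity(mod, sub$neutral_scan)
  d <- mean(sqrt(rowSums((matrix(idf$s_n$vector, ncol = 3, byrow = TRUE) -
                            matrix(sub$neutral_reg$vector, ncol = 3, byrow = TRUE))^2)))
  expect_lt(d, 1.0)
})

test_that("neutral resampling returns exact scan vertices near the fit", {
  mod <- fx_model()
  sub <- fx_corpus()$subjects[[2]]
  idf <- fit_identity(mod, sub$neutral_scan)
  aligned <- aligned_target_mesh(idf$fit, sub$neutral_scan)
  sh <- resample_neutral(idf$s_n, aligned)
  pts <- matrix(sh$vector, ncol = 3, byrow = TRUE)
  scan_pts <- aligned$vertices
  # every resampled point is an exact scan vertex
  hits <- slcau:::nearest_vertex(pts, scan_pts)
  expect_lt(max(abs(pts - scan_pts[hits$index, ])), 1e-9)
  # the snap moves points no farther than the fitting residual scale
  expect_lte(mean(sqrt(rowSums((pts - matrix(idf$s_n$vector, ncol = 3,
                                             byrow = TRUE))^2))),
             tail(idf$fit$errors, 1) * 3)
  # identity case: a scan equal to the fitted shape resamples to itself
  self <- resample_neutral(idf$s_n, delinearize(idf$s_n$vector))
  expect_equal(self$vector, idf$s_n$vector, tolerance = 1e-12)
})

test_that("coefficients of the same AU align across subjects", {
  recs <- fx_records()
  A <- coef_matrix(recs)
  labs <- record_labels(recs)
  cs <- A / sqrt(rowSums(A^2))
  sim <- cs %*% t(cs)
  same <- outer(labs, labs, "==")
  diag(same) <- NA
  within <- mean(sim[which(same)], na.rm = TRUE)
  across <- mean(sim[which(!same)], na.rm = TRUE)
  expect_gt(within, across)
  # activated components overlap the deformed region
  tpl <- fx_template()
  mod <- fx_model()
  spec <- fx_corpus()$config$au_specs[[1]]
  rec <- recs[[which(labs == spec$au_id)[1]]]
  act <- which(abs(rec$alpha_e) > 0.5 * max(abs(rec$alpha_e)))
  vert <- rep(seq_len(nrow(tpl$mesh$vertices)), each = 3)
  support <- unique(unlist(lapply(act, function(j) {
    row <- abs(mod$components[j, ])
    tpl$assignment[vert[which(row >= 0.5 * max(row))]]
  })))
  expect_true(spec$region %in% support)
})

test_that("LOOCV bookkeeping is consistent", {
  ev <- fx_loocv()
  recs <- fx_records()
  labs <- record_labels(recs)
  expect_equal(rowSums(ev$confusion), as.vector(table(labs)[rownames(ev$confusion)]),
               ignore_attr = TRUE)
  expect_identical(sum(ev$confusion), length(recs))
  expect_true(all(ev$per_class$auc >= 0 & ev$per_class$auc <= 1))
})

test_that("a class confined to one subject triggers a warning", {
  recs <- fx_records()
  subs <- record_subjects(recs)
  labs <- record_labels(recs)
  keep <- labs != labs[1] | subs == subs[1]
  expect_warning(loocv_evaluate(recs[keep]), "single subject")
})

test_that("AU prototypes are the arithmetic mean of their records", {
  recs <- fx_records()
  lab <- record_labels(recs)[1]
  sel <- Filter(function(r) r$au_label == lab, recs)
  expect_equal(compute_au_prototype(recs, lab),
               colMeans(coef_matrix(sel)), tolerance = 1e-12)
  expect_equal(compute_au_prototype(sel[1], lab), sel[[1]]$alpha_e)
  expect_error(compute_au_prototype(recs, "no-such-au"), "no records")
})

test_that("synthesis is linear and respects topology", {
  mod <- fx_model()
  base <- registered_shape(mod$mean, mod$topology_id)
  k <- nrow(mod$components)
  expect_equal(synthesize_au(base, mod, rep(0, k))$vertices,
               matrix(mod$mean, ncol = 3, byrow = TRUE))
  set.seed(7)
  p1 <- rnorm(k); p2 <- rnorm(k)
  via_list <- synthesize_au(base, mod, list(p1, p2))
  via_mean <- synthesize_au(base, mod, (p1 + p2) / 2)
  expect_lt(max(abs(via_list$vertices - via_mean$vertices)), 1e-12)
  wrong <- registered_shape(mod$mean, "elsewhere")
  expect_error(synthesize_au(wrong, mod, p1), "topology")
})

test_that("a region-supported prototype deforms only that region", {
  # prototype obtained by projecting the generator's AU field onto the
  # component basis: synthesis must keep the deformation in the region
  mod <- fx_model()
  tpl <- fx_template()
  spec <- default_au_specs()[[1]]
  field <- synthetic_au_field(spec, tpl)
  proto <- qr.solve(t(mod$components), field)
  base <- registered_shape(mod$mean, mod$topology_id)
  out <- synthesize_au(base, mod, proto)
  disp <- sqrt(rowSums((out$vertices - matrix(mod$mean, ncol = 3, byrow = TRUE))^2))
  gt <- vertex_norms(field)
  expect_gt(mean(disp[gt > 1e-9]), 5 * mean(disp[gt <= 1e-9]))
})
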