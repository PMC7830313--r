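test_that("ICP recovers a known rigid transform", {
  set.seed(2)
  S <- matrix(rnorm(150, sd = 25), 50, 3)
  th <- 10 * pi / 180
  R0 <- rbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
  T0 <- c(4, -2, 7)
  tgt <- sweep(S %*% R0, 2, T0, "+")
  tf <- icp_align(S, tgt)
  ang <- acos((sum(diag(crossprod(tf$R, R0))) - 1) / 2)
  expect_lt(abs(ang), 1e-3)
  expect_lt(max(abs(tf$T - T0)), 1e-3)
  # identity case
  tf0 <- icp_align(S, S)
  expect_lt(max(abs(tf0$R - diag(3))), 1e-8)
  expect_lt(max(abs(tf0$T)), 1e-8)
  # degenerate input
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(icp_align(line, tgt), "collinear")
})

test_that("correspondence matches the exhaustive nearest-neighbour oracle", {
  set.seed(3)
  S <- matrix(rnorm(90), 30, 3)
  tgt <- matrix(rnorm(120), 40, 3)
  got <- correspond(S, tgt)
  oracle <- t(apply(S, 1, function(p) {
    d <- colSums((t(tgt) - p)^2)
    tgt[which.min(d), ]
  }))
  expect_equal(got, oracle, tolerance = 1e-12)
  # single-vertex target: everything maps to it
  one <- matrix(c(1, 2, 3), 1, 3)
  expect_true(all(correspond(S, one) == rep(c(1, 2, 3), each = 30)))
  # target equal to the model maps onto itself
  expect_equal(correspond(S, S), S)
  expect_error(correspond(S, matrix(numeric(0), 0, 3)), "empty")
})

test_that("similarity estimation round-trips synthetic transforms", {
  set.seed(4)
  S <- matrix(rnorm(60, sd = 30), 20, 3)
  tf0 <- estimate_similarity(S, S)
  expect_lt(max(abs(tf0$P - diag(3))), 1e-8)
  expect_lt(max(abs(tf0$T)), 1e-8)
  for (i in 1:20) {
    R0 <- random_rotation(100 + i)
    s0 <- runif(1, 0.7, 1.4)
    T0 <- rnorm(3, sd = 10)
    tc <- sweep(s0 * (S %*% R0), 2, T0, "+")
    tf <- estimate_similarity(S, tc)
    back <- apply_transform(tc, tf)
    expect_lt(max(abs(back - S)), 1e-6)
    # factored form agrees with P
    back2 <- sweep((tc %*% tf$R) %*% tf$Sc, 2, tf$T, "+")
    expect_lt(max(abs(back2 - back)), 1e-8)
    expect_lt(abs(det(tf$R) - 1), 1e-6)
    expect_true(all(diag(tf$Sc) > 0))
  }
  # optimality: the closed-form P beats random alternatives
  tc <- sweep(0.9 * (S %*% random_rotation(7)), 2, c(1, 2, 3), "+")
  tf <- estimate_similarity(S, tc)
  ctrS <- sweep(S, 2, colMeans(S)); ctrT <- sweep(tc, 2, colMeans(tc))
  best <- sum((ctrS - ctrT %*% tf$P)^2)
  set.seed(5)
  rand <- replicate(300, sum((ctrS - ctrT %*% matrix(rnorm(9), 3))^2))
  expect_true(all(best <= rand))
  expect_error(estimate_similarity(S, matrix(0, 20, 3)), "rank-deficient")
})

test_that("the closed-form coefficient solve matches a numerical minimizer", {
  set.seed(6)
  for (i in 1:25) {
    k <- sample(2:10, 1); n3m <- sample(30:100, 1)
    B <- matrix(rnorm(n3m * k), n3m, k)
    X <- rnorm(n3m)
    mu <- runif(k, 0.2, 3)
    lam <- runif(1, 0.01, 1)
    a <- solve_coefficients(X, B, mu, lam)
    obj <- function(v) sum((X - B %*% v)^2) + lam * sum(v^2 / mu)
    gr <- function(v) as.numeric(-2 * t(B) %*% (X - B %*% v) + 2 * lam * v / mu)
    o <- stats::optim(rep(0, k), obj, gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
    expect_lt(max(abs(a - o$par)), 1e-6)
  }
})

test_that("the literal squared-inverse-weight penalty is available", {
  set.seed(7)
  B <- matrix(rnorm(60 * 5), 60, 5)
  X <- rnorm(60)
  mu <- runif(5, 0.2, 2)
  a <- solve_coefficients(X, B, mu, 0.4, penalty = "mu-inverse-squared")
  obj <- function(v) sum((X - B %*% v)^2) + 0.4 * sum(v^2 / mu^2)
  gr <- function(v) as.numeric(-2 * t(B) %*% (X - B %*% v) + 0.8 * v / mu^2)
  o <- stats::optim(rep(0, 5), obj, gr, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-15))
  expect_lt(max(abs(a - o$par)), 1e-6)
})

test_that("coefficient solve limits and error conditions hold", {
  set.seed(8)
  B <- qr.Q(qr(matrix(rnorm(60 * 4), 60, 4)))   # orthonormal columns
  X <- rnorm(60)
  expect_equal(solve_coefficients(rep(0, 60), B, rep(1, 4), 0.3), rep(0, 4))
  a <- solve_coefficients(X, B, rep(1, 4), 1e-12)
  expect_equal(a, drop(crossprod(B, X)), tolerance = 1e-9)
  expect_error(solve_coefficients(X, B, c(1, 1, 0, 1), 0.1), "mu")
  expect_error(solve_coefficients(X, B, rep(1, 4), 0), "lambda")
})

test_that("deformation application is linear and exact", {
  comp <- matrix(0, 1, 30)
  comp[1, 13] <- 1      # vertex 5, x coordinate
  base <- registered_shape(rep(0, 30), "t")
  out <- apply_deformation(base, comp, 2)
  expect_equal(out$vector[13], 2)
  expect_equal(sum(abs(out$vector)), 2)
  expect_equal(apply_deformation(base, comp, 0)$vector, base$vector)
  set.seed(9)
  comps <- matrix(rnorm(5 * 30), 5, 30)
  a <- rnorm(5)
  fwd <- apply_deformation(base, comps, a)
  bk <- apply_deformation(fwd, comps, -a)
  expect_lt(max(abs(bk$vector - base$vector)), 1e-12)
})

test_that("per-vertex error agrees with the exhaustive oracle", {
  set.seed(10)
  S <- as.matrix(expand.grid(x = seq(0, 20, 5), y = seq(0, 20, 5), z = 0))
  expect_equal(per_vertex_error(S, S), 0)
  # spacing far exceeds the shift, so each vertex matches its own copy
  expect_equal(per_vertex_error(S, sweep(S, 2, c(1, 0, 0), "+")), 1,
               tolerance = 1e-9)
  S <- matrix(rnorm(60), 20, 3)
  tgt <- matrix(rnorm(90), 30, 3)
  oracle <- mean(apply(S, 1, function(p) sqrt(min(colSums((t(tgt) - p)^2)))))
  expect_equal(per_vertex_error(S, tgt), oracle, tolerance = 1e-12)
  expect_error(per_vertex_error(S, matrix(numeric(0), 0, 3)), "empty")
})

test_that("self-fitting the mean converges immediately with tiny coefficients", {
  mod <- fx_model()
  fr <- fit_model(mod, delinearize(mod$mean), opts = list(icp = FALSE))
  expect_true(fr$converged)
  expect_identical(fr$iterations, 1L)
  expect_lt(tail(fr$errors, 1), 1e-3)
  expect_lt(sqrt(sum(fr$alpha^2)), 1e-6)
})

test_that("fitting recovers known in-basis deformation fields", {
  mod <- fx_model()
  set.seed(3)
  alpha0 <- rnorm(nrow(mod$components))
  gt <- drop(crossprod(mod$components, alpha0))
  gt <- gt * 2 / sqrt(mean(vertex_norms(gt)^2))   # 2 mm RMS, AU scale
  target <- delinearize(mod$mean + gt)
  fr <- fit_model(mod, target, opts = list(icp = FALSE))
  rec <- fr$deformed$vector - mod$mean
  expect_lt(tail(fr$errors, 1), 0.5)
  expect_gt(cor(rec, gt), 0.95)
  expect_lte(tail(fr$errors, 1), fr$errors[1])   # weak progress
})

test_that("fitting is invariant to rigid perturbation of the target", {
  mod <- fx_model()
  set.seed(13)
  alpha0 <- rnorm(nrow(mod$components))
  gt <- drop(crossprod(mod$components, alpha0))
  gt <- gt * 1.5 / sqrt(mean(vertex_norms(gt)^2))
  tv <- matrix(mod$mean + gt, ncol = 3, byrow = TRUE)
  f0 <- fit_model(mod, trimesh(tv), opts = list(icp = TRUE))
  # modest rotation (8 degrees about an oblique axis) within ICP's basin
  th <- 8 * pi / 180
  ax <- c(1, 2, 3) / sqrt(14)
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R0 <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  tv2 <- sweep(tv %*% R0, 2, c(8, -5, 3), "+")
  f1 <- fit_model(mod, trimesh(tv2), opts = list(icp = TRUE))
  expect_lt(abs(tail(f1$errors, 1) - tail(f0$errors, 1)), 2 * 1e-3)
})

test_that("fit options and topology mismatches are validated", {
  mod <- fx_model()
  expect_error(fit_model(mod, delinearize(mod$mean), opts = list(max_iter = 0)),
               "max_iter")
  wrong <- registered_shape(mod$mean, "other-topology")
  expect_error(fit_model(mod, delinearize(mod$mean), base = wrong), "topology")
})

test_that("rigid transform objects enforce rotation validity", {
  expect_error(rigid_transform(diag(3), 2 * diag(3), diag(3), c(0, 0, 0)),
               "rotation")
  R0 <- random_rotation(77)
  Sc <- diag(c(1.2, 0.9, 1.1))
  tf <- rigid_transform(R0 %*% Sc, R0, Sc, c(1, 2, 3))
  pts <- matrix(rnorm(30), 10, 3)
  expect_lt(max(abs(apply_transform(pts, tf) -
                      (sweep((pts %*% R0) %*% Sc, 2, c(1, 2, 3), "+")))), 1e-8)
})
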