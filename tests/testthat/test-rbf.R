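test_that("basis functions match their closed forms", {
  expect_equal(basis_eval("tps", 1), 0)
  expect_equal(basis_eval("tps", 0), 0)
  expect_equal(basis_eval("tps", exp(1)), exp(2))
  expect_equal(basis_eval("mq", 0, c = 2), 2)
  expect_equal(basis_eval("imq", 0, c = 2), 0.5)
  expect_equal(basis_eval("mq", 3, c = 4), 5)
  # compact support boundary, continuous from below
  expect_equal(basis_eval("wendland", 2, c = 2), 0)
  expect_equal(basis_eval("wendland", 2 - 1e-9, c = 2), 0, tolerance = 1e-7)
  expect_gt(basis_eval("wendland", 1, c = 2), 0)
  expect_equal(basis_eval("wendland", 3, c = 2), 0)
  expect_error(basis_eval("mq", -1, c = 1), "negative")
  expect_error(basis_eval("imq", 1, c = 0), "requires c > 0")
})

test_that("c parameter follows delta * r_max with range checks", {
  m <- array(FALSE, c(21, 11)); m[1:21, 1:11] <- TRUE
  dom <- cdt_domain(m, spacing = c(5, 5))   # extents 100 x 50
  expect_equal(compute_c(0.05, dom), 5)
  expect_warning(compute_c(0.7, dom), "useful range")
  expect_error(compute_c(0, dom), "delta")
  single <- array(FALSE, c(3, 3)); single[2, 2] <- TRUE
  expect_error(compute_c(0.05, cdt_domain(single)), "degenerate")
})

test_that("fitting interpolates exactly and honours the side conditions for all kinds", {
  set.seed(5)
  for (d in 2:3) {
    ctr <- matrix(runif(20 * d), 20, d)
    D <- matrix(rnorm(20 * d), 20, d)
    lm <- cdt_landmarks(ctr, D)
    pd <- as.matrix(dist(ctr))
    nD <- max(abs(D))
    for (k in c("tps", "mq", "imq", "wendland")) {
      mod <- fit_rbf(lm, pd, k, c = 0.5)
      pred <- evaluate_rbf(mod, ctr, pd)
      expect_lt(max(abs(pred - D)), 1e-8 * nD)
      expect_lt(max(abs(colSums(mod$lambda))), 1e-8 * nD)
      expect_lt(max(abs(t(ctr) %*% mod$lambda)), 1e-8 * nD)
    }
  }
})

test_that("affine displacement data gives vanishing basis coefficients", {
  set.seed(6)
  ctr <- matrix(runif(30), 15, 2)
  A <- matrix(c(0.3, -0.2, 0.1, 0.4), 2, 2)
  b <- c(2, -1)
  D <- ctr %*% A + matrix(b, 15, 2, byrow = TRUE)
  pd <- as.matrix(dist(ctr))
  for (k in c("tps", "mq", "imq", "wendland")) {
    mod <- fit_rbf(cdt_landmarks(ctr, D), pd, k, c = 0.4)
    expect_lt(max(abs(mod$lambda)), 1e-8 * max(abs(D)))
    q <- matrix(runif(24, -0.5, 1.5), 12, 2)
    pred <- evaluate_rbf(mod, q)
    expect_equal(pred, q %*% A + matrix(b, 12, 2, byrow = TRUE), tolerance = 1e-7)
  }
})

test_that("minimal landmark sets and zero displacements give zero coefficients", {
  ctr <- rbind(c(0, 0), c(1, 0), c(0, 1))
  mod <- fit_rbf(cdt_landmarks(ctr, matrix(0, 3, 2)), as.matrix(dist(ctr)), "mq", c = 1)
  expect_lt(max(abs(mod$lambda)), 1e-12)
  expect_lt(max(abs(mod$a)), 1e-12)
})

test_that("degenerate centre configurations are reported", {
  ctr <- cbind(seq(0, 1, length.out = 5), 0.5)   # collinear
  expect_error(fit_rbf(cdt_landmarks(ctr, matrix(1, 5, 2)), as.matrix(dist(ctr)), "tps"),
               "rank deficient")
  expect_error(cdt_landmarks(rbind(c(0, 0), c(0, 0), c(1, 1)), matrix(0, 3, 2)),
               "coincide")
})

test_that("rescaling improves the design-matrix condition number", {
  set.seed(8)
  for (rep in 1:5) {
    ctr <- matrix(runif(24, 1000, 1100), 12, 2)  # far from the origin
    pd <- as.matrix(dist(ctr))
    shift <- apply(ctr, 2, min)
    scale <- max(apply(ctr, 2, function(x) diff(range(x))))
    build <- function(x, dd, cc) {
      R <- matrix(basis_eval("mq", dd, cc), nrow(x), nrow(x))
      X <- rbind(1, t(x))
      rbind(cbind(matrix(0, 3, 3), X), cbind(t(X), R))
    }
    k_raw <- kappa(build(ctr, pd, 5), exact = TRUE)
    k_scaled <- kappa(build(sweep(ctr, 2, shift) / scale, pd / scale, 5 / scale),
                      exact = TRUE)
    expect_lte(k_scaled, k_raw)
  }
})

test_that("Euclidean and geodesic evaluation agree on a convex domain", {
  dom <- full_domain(c(30, 30))
  mesh <- generate_mesh_2d(dom, 2)
  set.seed(13)
  idx <- sample(nrow(mesh$nodes), 8)
  ctr <- mesh$nodes[idx, ]
  lm <- cdt_landmarks(ctr, matrix(rnorm(16), 8, 2))
  dfl <- landmark_distance_fields(mesh, lm)
  eu <- as.matrix(dist(ctr))
  expect_equal(dfl$cross, eu, tolerance = 1e-9, ignore_attr = TRUE)
  modG <- fit_rbf(lm, dfl$cross, "imq", c = 2)
  modE <- fit_rbf(lm, eu, "imq", c = 2)
  node_g <- vapply(dfl$fields, function(f) f$distance, numeric(nrow(mesh$nodes)))
  predG <- evaluate_rbf(modG, mesh$nodes, node_g)
  predE <- evaluate_rbf(modE, mesh$nodes)
  expect_equal(predG, predE, tolerance = 1e-9)
})

test_that("landmark TSV and model JSON round trips preserve the data", {
  set.seed(14)
  tgt <- matrix(runif(12), 6, 2)
  src <- tgt + matrix(rnorm(12, sd = 0.1), 6, 2)
  lm <- landmarks_from_pairs(tgt, src)
  p <- tempfile(fileext = ".tsv")
  write_landmarks(lm, p)
  back <- read_landmarks(p)
  expect_equal(back$centres, lm$centres, ignore_attr = TRUE)
  expect_equal(back$displacements, lm$displacements, ignore_attr = TRUE)
  mod <- fit_rbf(lm, as.matrix(dist(tgt)), "imq", c = 0.3)
  mp <- tempfile(fileext = ".json")
  write_rbf_model(mod, mp)
  back2 <- read_rbf_model(mp)
  q <- matrix(runif(10), 5, 2)
  expect_equal(evaluate_rbf(back2, q), evaluate_rbf(mod, q), tolerance = 1e-12)
})
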