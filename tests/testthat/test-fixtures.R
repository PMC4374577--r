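test_that("corridor construction matches its stated geometry", {
  fx <- make_corridor_domain(2, c(100, 100), 20, "c", spacing = 1)
  # area of the rectangle union: two uprights plus the bottom bar
  expect_equal(sum(fx$domain$mask), 20 * 100 * 2 + 60 * 20)
  lab <- label_components(fx$domain)
  expect_equal(max(lab), 1)
  expect_error(make_corridor_domain(2, c(100, 100), 50, "c"), "width")
  expect_equal(bounding_box(fx$domain)$r_max, 99)  # voxel-centre extent
  # 3D mask is the extruded 2D mask
  fx3 <- make_corridor_domain(3, c(100, 100, 50), 20, "c", spacing = 1)
  for (k in c(1, 20, 40)) {
    expect_identical(fx3$domain$mask[, , k], fx$domain$mask)
  }
})

test_that("analytic corridor distances follow the taut string", {
  fx <- make_corridor_domain(2, c(100, 100), 20, "l", spacing = 1)
  # same arm, unobstructed: Euclidean
  expect_equal(analytic_distance(fx$oracle, c(10, 90), c(10, 10)), 80)
  # around the inner corner at (20, 20)
  p <- c(10, 90); q <- c(90, 10)
  w <- c(20, 20)
  expect_equal(analytic_distance(fx$oracle, p, q),
               sqrt(sum((p - w)^2)) + sqrt(sum((q - w)^2)))
  expect_error(analytic_distance(fx$oracle, c(60, 60), c(10, 10)), "outside")
  # 3D: in-plane geodesic combines with the axial offset
  fx3 <- make_corridor_domain(3, c(100, 100, 50), 20, "l", spacing = 1)
  g2 <- analytic_distance(fx$oracle, p, q)
  expect_equal(analytic_distance(fx3$oracle, c(p, 5), c(q, 45)),
               sqrt(g2^2 + 40^2))
})

test_that("analytic distances are bracketed by Euclid and grid Dijkstra", {
  fx <- make_corridor_domain(2, c(50, 50), 12, "c", spacing = 1)
  seed_idx <- c(6, 45)
  seed <- index_to_world(fx$domain, matrix(seed_idx, 1))
  dj <- grid_dijkstra(fx$domain, seed_idx)
  set.seed(31)
  cells <- which(fx$domain$mask)
  pick <- sample(cells, 500)
  pts <- index_to_world(fx$domain, arrayInd(pick, dim(fx$domain$mask)))
  ex <- analytic_distance(fx$oracle, pts, seed)
  dd <- dj[pick]
  eu <- sqrt(rowSums(sweep(pts, 2, as.numeric(seed))^2))
  # 8-connected grid paths overestimate by at most ~8%, and never underestimate
  expect_true(all(ex <= dd + 1e-9))
  expect_true(all(ex >= dd / 1.09 - 1e-9))
  expect_true(all(ex >= eu - 1e-9))
})

test_that("pattern images are deterministic and as specified", {
  dom <- full_domain(c(4, 4))
  ch <- make_pattern_image(dom, "checker", period = 2)
  expect_equal(ch$values[1:2, 1:2], matrix(0, 2, 2))
  expect_equal(ch$values[3:4, 1:2], matrix(255, 2, 2))
  expect_equal(ch$values[3:4, 3:4], matrix(0, 2, 2))
  rp <- make_pattern_image(cdt_domain(array(TRUE, c(3, 3)), origin = c(10, 0),
                                      spacing = c(2, 1)), "ramp")
  expect_equal(rp$values[, 1], c(10, 12, 14))
  two <- array(FALSE, c(9, 5))
  two[1:3, 2:4] <- TRUE; two[6:9, 2:4] <- TRUE
  lb <- make_pattern_image(cdt_domain(two), "labels")
  expect_equal(sort(unique(lb$values[two])), c(1, 2))
})

test_that("the tail fixture realises Euclidean-close but geodesically-distant anatomy", {
  tf <- make_tail_fixture()
  expect_silent(audit_conformity(tf$mesh))
  f <- geodesic_field(tf$mesh, tf$tip_point)
  gd <- distance_at(f, matrix(tf$head_point, 1))
  eu <- sqrt(sum((tf$tip_point - tf$head_point)^2))
  expect_lt(eu, 0.2 * gd)
  # all non-tip landmarks have exactly zero displacement
  mags <- sqrt(rowSums(tf$landmarks$displacements^2))
  expect_true(all(mags %in% c(0, sqrt(sum(tf$tail_displacement^2)))))
  expect_gt(sum(mags > 0), 0)
  expect_gt(sum(mags == 0), 10)
  expect_gt(length(tf$head_nodes), 10)
  expect_gt(length(tf$tail_nodes), 5)
})

test_that("the distance-error table is deterministic and near-exact on convex fixtures", {
  rect <- list(domain = full_domain(c(30, 30)),
               oracle = make_corridor_domain(2, c(30, 30), 14, "l")$oracle)
  # a full rectangle is convex: build an ad-hoc single-rectangle oracle
  rect$oracle$rects <- list(c(-0.5, 29.5, -0.5, 29.5))  # voxel-box union
  rect$oracle$corners <- matrix(numeric(0), 0, 2)
  mesh <- generate_mesh_2d(rect$domain, 2)
  tab <- distance_error_table(rect, mesh, c(8.2, 9.3), algorithms = "mesh")
  expect_lt(abs(tab$mean_pct), 1e-4)
  fx <- make_corridor_domain(2, c(40, 40), 10, "c", spacing = 1)
  m2 <- generate_mesh_2d(fx$domain, 1.5)
  t1 <- distance_error_table(fx, m2, c(5, 35), algorithms = c("mesh", "c8"))
  t2 <- distance_error_table(fx, m2, c(5, 35), algorithms = c("mesh", "c8"))
  expect_identical(t1[, setdiff(names(t1), "seconds")],
                   t2[, setdiff(names(t2), "seconds")])
})

test_that("zero and affine landmark fields interpolate exactly at centroids", {
  fx3 <- make_corridor_domain(3, c(30, 30, 20), 7, "l", spacing = 1)
  mesh <- generate_mesh_3d(fx3$domain, 3)
  set.seed(17)
  ctr <- matrix(runif(6 * 3, 5, 25), 6, 3)
  # zero displacements
  w0 <- build_warp(mesh, cdt_landmarks(ctr, matrix(0, 6, 3)),
                   cdt_config(constrained = FALSE))
  expect_lt(max(abs(w0$displacement)), 1e-10)
  # affine displacements: piecewise-linear interpolation is exact
  A <- diag(c(0.1, -0.05, 0.2)); b <- c(1, 2, -1)
  lmA <- cdt_landmarks(ctr, ctr %*% A + matrix(b, 6, 3, byrow = TRUE))
  wA <- build_warp(mesh, lmA, cdt_config(constrained = FALSE))
  el <- mesh$elements
  cent <- (mesh$nodes[el[, 1], ] + mesh$nodes[el[, 2], ] +
           mesh$nodes[el[, 3], ] + mesh$nodes[el[, 4], ]) / 4
  direct <- evaluate_rbf(wA$model, cent)
  interp <- (wA$displacement[el[, 1], ] + wA$displacement[el[, 2], ] +
             wA$displacement[el[, 3], ] + wA$displacement[el[, 4], ]) / 4
  expect_lt(max(abs(direct - interp)), 1e-7)
})

test_that("the displacement study is reproducible for a fixed seed", {
  fx <- make_corridor_domain(3, c(40, 40, 24), 9, "l", spacing = 1)
  r1 <- displacement_error_study(fx, landmark_count = 15, resolutions = c(2e3, 4e3, 8e3, 1.6e4),
                                 seed = 99)
  r2 <- displacement_error_study(fx, landmark_count = 15, resolutions = c(2e3, 4e3, 8e3, 1.6e4),
                                 seed = 99)
  expect_identical(r1$rows, r2$rows)
  expect_true(all(diff(r1$rows$eps_mean) < 0))
})
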