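# Shared tail fixture for the warp tests.
tf <- make_tail_fixture()

test_that("landmark distance fields cache per centre and report outside centres", {
  mesh <- generate_mesh_2d(full_domain(c(20, 20)), 2)
  one <- cdt_landmarks(rbind(c(5, 5), c(10, 10), c(15, 5)), matrix(0, 3, 2))
  dfl <- landmark_distance_fields(mesh, one)
  expect_length(dfl$fields, 3)
  expect_equal(diag(dfl$cross), rep(0, 3))
  expect_equal(dfl$cross, t(dfl$cross))
  # edit landmark 2: fields 1 and 3 come back bit-identical from the cache
  two <- cdt_landmarks(rbind(c(5, 5), c(11, 9), c(15, 5)), matrix(0, 3, 2))
  dfl2 <- landmark_distance_fields(mesh, two, cache = dfl)
  expect_identical(dfl2$fields[[1]]$distance, dfl$fields[[1]]$distance)
  expect_identical(dfl2$fields[[3]]$distance, dfl$fields[[3]]$distance)
  expect_false(identical(dfl2$fields[[2]]$distance, dfl$fields[[2]]$distance))
  bad <- cdt_landmarks(rbind(c(5, 5), c(100, 100), c(15, 5)), matrix(0, 3, 2))
  expect_error(landmark_distance_fields(mesh, bad), "centre 2")
})

test_that("zero and translational landmark displacements reproduce exactly", {
  n <- tf$landmarks$n
  zero <- cdt_landmarks(tf$landmarks$centres, matrix(0, n, 2))
  w0 <- build_warp(tf$mesh, zero, cdt_config(constrained = FALSE))
  expect_equal(max(abs(w0$displacement)), 0, tolerance = 1e-10)
  tr <- cdt_landmarks(tf$landmarks$centres, matrix(c(3, -2), n, 2, byrow = TRUE))
  for (constrained in c(FALSE, TRUE)) {
    w <- build_warp(tf$mesh, tr, cdt_config(kind = "mq", constrained = constrained))
    expect_equal(sweep(w$displacement, 2, c(3, -2)), 0 * w$displacement,
                 tolerance = 1e-8)
  }
})

test_that("constrained warps are local along the mesh; unconstrained ones are not", {
  wC <- build_warp(tf$mesh, tf$landmarks, cdt_config(kind = "mq", constrained = TRUE))
  wU <- build_warp(tf$mesh, tf$landmarks, cdt_config(kind = "mq", constrained = FALSE))
  mag <- sqrt(sum(tf$tail_displacement^2))
  hC <- max(sqrt(rowSums(wC$displacement[tf$head_nodes, ]^2)))
  hU <- max(sqrt(rowSums(wU$displacement[tf$head_nodes, ]^2)))
  expect_lt(hC, 0.01 * mag)
  expect_gt(hU, 10 * hC)
  # the tail tip itself moves by about the applied displacement in both
  tC <- max(sqrt(rowSums(wC$displacement[tf$tail_nodes, ]^2)))
  expect_gt(tC, 0.8 * mag)
})

test_that("pull-back output support equals the mesh footprint regardless of content", {
  zero <- cdt_landmarks(tf$landmarks$centres, matrix(0, tf$landmarks$n, 2))
  w0 <- build_warp(tf$mesh, zero, cdt_config(constrained = FALSE))
  fp <- mesh_footprint(tf$mesh, tf$domain)
  for (pat in c("checker", "ramp")) {
    src <- make_pattern_image(tf$domain, pat)
    out <- pullback_resample(src, w0, tf$domain)
    expect_identical(out$image$domain$mask, fp)
  }
  # identity warp returns the source values on the footprint
  src <- make_pattern_image(tf$domain, "checker")
  out <- pullback_resample(src, w0, tf$domain, cdt_config(interp = "nearest"))
  inb <- fp & tf$domain$mask
  expect_equal(out$image$values[inb], src$values[inb])
})

test_that("translation warps pull back shifted values and respect the value range", {
  full <- full_domain(dim(tf$domain$mask), tf$domain$spacing)
  ramp <- make_pattern_image(full, "ramp")
  n <- tf$landmarks$n
  tr <- cdt_landmarks(tf$landmarks$centres, matrix(c(2, 1), n, 2, byrow = TRUE))
  w <- build_warp(tf$mesh, tr, cdt_config(constrained = FALSE))
  out <- pullback_resample(ramp, w, tf$domain)
  m <- out$image$domain$mask & !out$unmapped
  idx <- which(m, arr.ind = TRUE)
  expect_equal(out$image$values[m],
               index_to_world(tf$domain, idx)[, 1] + 2, tolerance = 1e-6)
  # checkerboard under the constrained tail warp: range and support audit
  checker <- make_pattern_image(full, "checker")
  wC <- build_warp(tf$mesh, tf$landmarks, cdt_config(kind = "mq"))
  outC <- pullback_resample(checker, wC, tf$domain)
  expect_identical(outC$image$domain$mask, mesh_footprint(tf$mesh, tf$domain))
  vals <- outC$image$values[outC$image$domain$mask & !outC$unmapped]
  expect_true(all(vals >= -1e-6 & vals <= 255 + 1e-6))
})

test_that("forward transform preserves support under identity and scales areas", {
  sq <- unit_square_mesh()
  dom <- cdt_domain(array(TRUE, c(21, 21)), origin = c(-0.25, -0.25),
                    spacing = c(0.05, 0.05))
  src <- make_pattern_image(dom, "ramp")
  lm <- cdt_landmarks(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), matrix(0, 4, 2))
  w0 <- build_warp(sq, lm, cdt_config(kind = "mq", constrained = FALSE))
  f0 <- forward_transform(src, w0, cdt_config(interp = "nearest"))
  a0 <- sum(f0$image$domain$mask) * prod(f0$image$domain$spacing)
  expect_equal(a0, 1, tolerance = 0.15)   # one-voxel rasterisation band
  # uniform scaling by 2 about the origin: area 4x
  lm2 <- cdt_landmarks(lm$centres, lm$centres)   # u = 2x  =>  du = x
  w2 <- build_warp(sq, lm2, cdt_config(kind = "mq", constrained = FALSE))
  f2 <- forward_transform(src, w2, cdt_config(interp = "nearest"))
  a2 <- sum(f2$image$domain$mask) * prod(f2$image$domain$spacing)
  expect_equal(a2 / a0, 4, tolerance = 0.15)
})

test_that("forward transform then pull-back recovers a smooth source image", {
  full <- full_domain(dim(tf$domain$mask), tf$domain$spacing)
  idx <- which(full$mask, arr.ind = TRUE)
  wpts <- index_to_world(full, idx)
  vals <- array(127.5 * (1 + sin(wpts[, 1] / 4) * sin(wpts[, 2] / 4)),
                dim = dim(full$mask))
  src <- cdt_image(full, vals)
  n <- tf$landmarks$n
  tr <- cdt_landmarks(tf$landmarks$centres, matrix(c(4, -3), n, 2, byrow = TRUE))
  w <- build_warp(tf$mesh, tr, cdt_config(constrained = FALSE))
  fwd <- forward_transform(src, w, cdt_config())
  # pulling the forward image back through the same warp recovers the source
  back <- pullback_resample(fwd$image, w, tf$domain)
  m <- back$image$domain$mask & !back$unmapped & tf$domain$mask
  # exclude the support boundary band, where linear samples mix the fill value
  m <- m & !cdt:::dilate_mask(!back$image$domain$mask, 2L)
  diffs <- abs(back$image$values[m] - src$values[m])
  expect_lt(mean(diffs), 0.02 * 255)
})

test_that("end-to-end registration maps a bent corridor onto a straight atlas", {
  # atlas: straight horizontal bar; source: L-bend corridor
  atlas_mask <- array(FALSE, c(80, 24))
  atlas_mask[4:76, 6:18] <- TRUE
  atlas <- cdt_domain(atlas_mask, spacing = c(1, 1))
  mesh <- generate_mesh_2d(atlas, 2.5)
  srcfx <- make_corridor_domain(2, c(60, 60), 14, "l", spacing = 1)
  # full-raster ramp with a margin so extrapolated positions still sample
  src <- make_pattern_image(cdt_domain(array(TRUE, c(70, 70)),
                                       srcfx$domain$origin - 5,
                                       srcfx$domain$spacing),
                            "ramp")
  # landmark arcs: atlas centreline to source centreline (down the L)
  tpar <- seq(0.05, 0.95, length.out = 9)
  tgt <- cbind(4 + tpar * 72, 12)
  # source path: along the vertical arm down then the horizontal arm
  path_src <- function(s) {
    len1 <- 45
    len2 <- 45
    s <- s * (len1 + len2)
    ifelse_m <- function(c, a, b) if (c) a else b
    t(vapply(s, function(si) {
      if (si < len1) c(7, 52 - si) else c(7 + (si - len1), 7)
    }, numeric(2)))
  }
  srcp <- path_src(tpar)
  shift <- function(m, dy) m + matrix(c(0, dy), nrow(m), 2, byrow = TRUE)
  tgt3 <- rbind(shift(tgt, -4), tgt, shift(tgt, 4))
  src3 <- rbind(shift(srcp, -4), srcp, shift(srcp, 4))
  # keep target landmarks inside the mesh
  keep <- locate_point(mesh, tgt3)$element > 0
  pairs <- landmarks_from_pairs(tgt3[keep, ], src3[keep, ])
  res <- register(src, atlas, mesh, pairs, cdt_config(kind = "imq", delta = 0.1))
  expect_lt(res$report$landmark_residual_max, 1e-6)
  expect_gt(res$report$mapped_voxels - res$report$unmapped_voxels,
            0.99 * res$report$mapped_voxels)
  expect_identical(res$image$domain$mask, mesh_footprint(mesh, atlas))
})

test_that("many-to-one mappings complete without error", {
  # two disjoint source blobs fused onto one atlas bar
  src_mask <- array(FALSE, c(60, 30))
  src_mask[5:25, 10:20] <- TRUE
  src_mask[35:55, 10:20] <- TRUE
  src_dom <- cdt_domain(array(TRUE, c(60, 30)))
  src <- make_pattern_image(src_dom, "ramp")
  atlas_mask <- array(FALSE, c(40, 30)); atlas_mask[6:34, 10:20] <- TRUE
  atlas <- cdt_domain(atlas_mask)
  mesh <- generate_mesh_2d(atlas, 2.5)
  tgt <- rbind(c(8, 12), c(8, 18), c(18, 15), c(22, 15), c(32, 12), c(32, 18))
  srcp <- rbind(c(7, 11), c(7, 19), c(22, 15), c(38, 15), c(53, 11), c(53, 19))
  keep <- locate_point(mesh, tgt)$element > 0
  res <- register(src, atlas, mesh, landmarks_from_pairs(tgt[keep, ], srcp[keep, ]),
                  cdt_config(kind = "imq", delta = 0.2))
  expect_equal(res$report$unmapped_voxels, 0)
  expect_identical(res$image$domain$mask, mesh_footprint(mesh, atlas))
})
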