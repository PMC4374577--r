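#' Synthetic non-convex corridor domain with an analytic geodesic oracle
#'
#' Builds an axis-aligned corridor (rectangles joined at right angles) that is
#' markedly non-convex yet admits a closed-form constrained distance: the
#' shortest in-domain path is a taut string around the corridor's inner
#' (reflex) corners, so its length is an explicit sum of straight segments.
#' Shapes: `"l"` (one bend, one inner corner) and `"c"` (U shape, two inner
#' corners). The 3D variant extrudes the 2D cross-section along the third
#' axis; since the domain is a product, the 3D geodesic is
#' `sqrt(g2d^2 + dz^2)`.
#'
#' @param dim 2 or 3.
#' @param extents outer extents per axis (world units), length `dim`.
#' @param width corridor width (world units), strictly less than half of every
#'   outer extent.
#' @param shape `"c"` or `"l"`.
#' @param spacing isotropic voxel size.
#' @return list with `domain` (a [cdt_domain]) and `oracle` (handle for
#'   [analytic_distance()]).
#' @export
make_corridor_domain <- function(dim = 2, extents = c(100, 100), width = 20,
                                 shape = c("c", "l"), spacing = 1) {
  shape <- match.arg(shape)
  extents <- as.numeric(extents)
  if (length(extents) != dim) stop("extents must have one entry per axis")
  if (any(extents <= 0) || width <= 0 || spacing <= 0) stop("all parameters must be positive")
  if (any(width >= extents / 2)) stop("corridor width must be below half of every extent")
  ex <- extents[1]; ey <- extents[2]
  rects <- if (shape == "l") {
    list(c(0, width, 0, ey), c(0, ex, 0, width))
  } else {
    list(c(0, width, 0, ey), c(0, ex, 0, width), c(ex - width, ex, 0, ey))
  }
  corners <- if (shape == "l") {
    matrix(c(width, width), ncol = 2)
  } else {
    rbind(c(width, width), c(ex - width, width))
  }
  nx <- round(ex / spacing); ny <- round(ey / spacing)
  cx <- (seq_len(nx) - 0.5) * spacing
  cy <- (seq_len(ny) - 0.5) * spacing
  m2 <- matrix(FALSE, nx, ny)
  for (r in rects) {
    ix <- cx >= r[1] & cx <= r[2]
    iy <- cy >= r[3] & cy <= r[4]
    m2[ix, iy] <- TRUE
  }
  if (dim == 2) {
    mask <- m2
    origin <- rep(spacing / 2, 2)
  } else {
    nz <- round(extents[3] / spacing)
    mask <- array(m2, dim = c(nx, ny, nz))
    origin <- rep(spacing / 2, 3)
  }
  oracle <- structure(list(rects = rects, corners = corners, dim = dim,
                           spacing = spacing, extents = extents),
                      class = "cdt_corridor_oracle")
  list(domain = cdt_domain(mask, origin, rep(spacing, dim)), oracle = oracle)
}

# Project points onto the rectangle union when within `snap` of it; errors
# otherwise (mesh boundary nodes may sit up to half a voxel outside).
snap_to_rects <- function(oracle, p, snap) {
  p <- matrix(as.numeric(p), ncol = 2)
  best <- matrix(NA_real_, nrow(p), 2)
  bd <- rep(Inf, nrow(p))
  for (r in oracle$rects) {
    qx <- pmin(pmax(p[, 1], r[1]), r[2])
    qy <- pmin(pmax(p[, 2], r[3]), r[4])
    d <- sqrt((p[, 1] - qx)^2 + (p[, 2] - qy)^2)
    upd <- d < bd
    best[upd, ] <- cbind(qx, qy)[upd, , drop = FALSE]
    bd[upd] <- d[upd]
  }
  if (any(bd > snap)) stop("point outside the corridor domain")
  best
}

# Fraction-of-segment coverage test: are the segments p->q fully inside the
# rectangle union? Vectorised over rows of p (q fixed).
segments_visible <- function(oracle, p, q) {
  p <- matrix(as.numeric(p), ncol = 2)
  eps <- 1e-9 * max(oracle$extents)
  n <- nrow(p)
  k <- length(oracle$rects)
  t0 <- matrix(Inf, n, k)
  t1 <- matrix(-Inf, n, k)
  for (j in seq_len(k)) {
    r <- oracle$rects[[j]]
    lo <- rep(0, n); hi <- rep(1, n)
    for (ax in 1:2) {
      a <- p[, ax]; d <- q[ax] - a
      rl <- r[2 * ax - 1] - eps; rh <- r[2 * ax] + eps
      par <- abs(d) < 1e-300
      inside_slab <- a >= rl & a <= rh
      tA <- ifelse(par, ifelse(inside_slab, -Inf, Inf), (rl - a) / d)
      tB <- ifelse(par, ifelse(inside_slab, Inf, Inf), (rh - a) / d)
      lo <- pmax(lo, pmin(tA, tB))
      hi <- pmin(hi, pmax(tA, tB))
    }
    t0[, j] <- lo
    t1[, j] <- hi
  }
  t1[t0 > t1] <- -Inf
  cover <- rep(0, n)
  tol <- 1e-9
  for (pass in 1:(k + 1)) {
    for (j in seq_len(k)) {
      upd <- t0[, j] <= cover + tol & t1[, j] > cover
      cover[upd] <- t1[upd, j]
    }
  }
  cover >= 1 - tol
}

#' Exact geodesic distance inside a corridor domain
#'
#' Taut-string shortest path over the corridor's inner-corner waypoints:
#' enumerates the admissible corner sequences, keeps those whose consecutive
#' legs are unobstructed (segment fully inside the rectangle union) and
#' returns the shortest total length. For 3D (extruded) corridors the
#' in-plane geodesic combines with the axial offset as `sqrt(g^2 + dz^2)`.
#' Points within half a voxel of the domain are projected onto it.
#'
#' @param oracle oracle handle from [make_corridor_domain()].
#' @param p single point or matrix of points (world coordinates).
#' @param q single point (world coordinates).
#' @return numeric vector of exact geodesic lengths.
#' @export
analytic_distance <- function(oracle, p, q) {
  stopifnot(inherits(oracle, "cdt_corridor_oracle"))
  d <- oracle$dim
  p <- matrix(as.numeric(p), ncol = d)
  q <- as.numeric(q)
  snap <- oracle$spacing
  p2 <- snap_to_rects(oracle, p[, 1:2, drop = FALSE], snap)
  q2 <- as.numeric(snap_to_rects(oracle, matrix(q[1:2], ncol = 2), snap))
  corners <- oracle$corners
  nc <- nrow(corners)
  n <- nrow(p2)
  seqs <- list(integer(0))
  if (nc >= 1) for (i in seq_len(nc)) seqs <- c(seqs, list(i))
  if (nc >= 2) {
    for (i in seq_len(nc)) for (j in seq_len(nc)) if (i != j) seqs <- c(seqs, list(c(i, j)))
  }
  best <- rep(Inf, n)
  for (s in seqs) {
    if (length(s) == 0) {
      vis <- segments_visible(oracle, p2, q2)
      len <- sqrt(rowSums(sweep(p2, 2, q2)^2))
      best <- ifelse(vis & len < best, len, best)
    } else {
      w1 <- corners[s[1], ]
      ok <- TRUE
      fixed <- 0
      pts <- rbind(corners[s, , drop = FALSE], q2)
      for (t in seq_len(nrow(pts) - 1)) {
        ok <- ok && segments_visible(oracle, matrix(pts[t, ], ncol = 2), pts[t + 1, ])
        fixed <- fixed + sqrt(sum((pts[t, ] - pts[t + 1, ])^2))
      }
      if (!ok) next
      vis <- segments_visible(oracle, p2, w1)
      len <- sqrt(rowSums(sweep(p2, 2, w1)^2)) + fixed
      best <- ifelse(vis & len < best, len, best)
    }
  }
  if (d == 3) {
    dz <- p[, 3] - q[3]
    best <- sqrt(best^2 + dz^2)
  }
  best
}

#' Deterministic pattern images over a domain
#'
#' `checker`: alternating blocks of `period` voxels valued 0/255; `ramp`:
#' value equals the first world coordinate of the voxel centre; `labels`:
#' face-connected component labels.
#'
#' @param domain a [cdt_domain].
#' @param pattern one of `"checker"`, `"ramp"`, `"labels"`.
#' @param period block size in voxels (checker only).
#' @return A [cdt_image].
#' @export
make_pattern_image <- function(domain, pattern = c("checker", "ramp", "labels"),
                               period = 4) {
  pattern <- match.arg(pattern)
  dm <- dim(domain$mask)
  nd <- length(dm)
  vals <- switch(pattern,
    checker = {
      blk <- 0
      for (ax in seq_len(nd)) {
        idx <- slice.index(domain$mask, ax) - 1L
        blk <- blk + idx %/% as.integer(period)
      }
      array(255 * (blk %% 2L), dim = dm)
    },
    ramp = {
      idx <- slice.index(domain$mask, 1) - 1L
      array(domain$origin[1] + idx * domain$spacing[1], dim = dm)
    },
    labels = {
      array(as.numeric(cpp_label_components(as.logical(domain$mask), dm)), dim = dm)
    })
  if (pattern != "labels") vals[!domain$mask] <- 0
  cdt_image(domain, vals)
}

#' Embryo-like tail fixture for locality experiments
#'
#' A 2D silhouette made of a body disc and a curled tail whose tip approaches
#' the head in Euclidean space while remaining geodesically distant, with a
#' conforming mesh, a checkerboard value pattern, and one landmark set:
#' zero-displacement landmarks distributed around the body and along the tail,
#' and tail-tip landmarks displaced away from the head. Constrained and
#' unconstrained warps share these landmarks; only the distance semantics
#' differ.
#'
#' @param spacing voxel size (world units).
#' @param target_edge mesh edge length.
#' @return list with `image`, `domain`, `mesh`, `landmarks`, `head_nodes`,
#'   `tail_nodes` (node index sets), `head_point`, `tip_point` and
#'   `tail_displacement` (the applied tip displacement vector).
#' @export
make_tail_fixture <- function(spacing = 0.5, target_edge = 1.6) {
  body_c <- c(35, 62); body_r <- 20
  arc_c <- c(58, 62); arc_r <- 30; half_w <- 3.5
  ang0 <- 205 * pi / 180            # attachment inside the body
  ang1 <- 118 * pi / 180            # tip, above and right of the head
  sweep_ang <- (2 * pi - ang0) + ang1   # going through 270, 0, 90 degrees

  nx <- round(100 / spacing); ny <- round(100 / spacing)
  cx <- (seq_len(nx) - 0.5) * spacing
  cy <- (seq_len(ny) - 0.5) * spacing
  gx <- matrix(cx, nx, ny)
  gy <- matrix(cy, nx, ny, byrow = TRUE)
  in_body <- (gx - body_c[1])^2 + (gy - body_c[2])^2 <= body_r^2
  ang <- atan2(gy - arc_c[2], gx - arc_c[1]) %% (2 * pi)
  rel <- (ang - ang0) %% (2 * pi)
  on_arc <- rel <= sweep_ang
  rad <- sqrt((gx - arc_c[1])^2 + (gy - arc_c[2])^2)
  in_tail <- on_arc & abs(rad - arc_r) <= half_w
  tipc <- arc_c + arc_r * c(cos(ang1), sin(ang1))
  in_tipcap <- (gx - tipc[1])^2 + (gy - tipc[2])^2 <= half_w^2
  mask <- in_body | in_tail | in_tipcap
  domain <- cdt_domain(mask, rep(spacing / 2, 2), rep(spacing, 2))
  mesh <- generate_mesh_2d(domain, target_edge)
  image <- make_pattern_image(domain, "checker", period = 8)

  head_point <- body_c + c(0, body_r - 3)
  # zero landmarks: ring just inside the body boundary + along both tail edges
  ring_ang <- seq(0, 2 * pi, length.out = 25)[-25]
  ring <- cbind(body_c[1] + (body_r - 1) * cos(ring_ang),
                body_c[2] + (body_r - 1) * sin(ring_ang))
  tail_fracs <- seq(0.12, 0.72, length.out = 6)
  tail_ang <- (ang0 + tail_fracs * sweep_ang) %% (2 * pi)
  tail_pts <- rbind(
    cbind(arc_c[1] + (arc_r - half_w + 1) * cos(tail_ang),
          arc_c[2] + (arc_r - half_w + 1) * sin(tail_ang)),
    cbind(arc_c[1] + (arc_r + half_w - 1) * cos(tail_ang),
          arc_c[2] + (arc_r + half_w - 1) * sin(tail_ang)))
  # displaced landmarks at the tail tip, pushed away from the head
  tip_ang <- (ang0 + c(0.9, 0.96) * sweep_ang) %% (2 * pi)
  tip_pts <- cbind(arc_c[1] + arc_r * cos(tip_ang), arc_c[2] + arc_r * sin(tip_ang))
  u <- tipc - head_point
  u <- u / sqrt(sum(u^2))
  tail_disp <- 15 * u
  centres <- rbind(ring, tail_pts, tip_pts)
  disp <- rbind(matrix(0, nrow(ring) + nrow(tail_pts), 2),
                matrix(tail_disp, nrow(tip_pts), 2, byrow = TRUE))
  # keep landmarks strictly inside the mesh
  loc <- locate_point(mesh, centres)
  inside <- loc$element > 0
  lm <- cdt_landmarks(centres[inside, , drop = FALSE], disp[inside, , drop = FALSE])

  nodes <- mesh$nodes
  head_nodes <- which((nodes[, 1] - body_c[1])^2 + (nodes[, 2] - body_c[2])^2 <= body_r^2 &
                      nodes[, 2] >= body_c[2] + body_r / 2)
  tipd <- sqrt((nodes[, 1] - tipc[1])^2 + (nodes[, 2] - tipc[2])^2)
  tail_nodes <- which(tipd <= 3 * half_w)
  list(image = image, domain = domain, mesh = mesh, landmarks = lm,
       head_nodes = head_nodes, tail_nodes = tail_nodes,
       head_point = head_point, tip_point = tipc, tail_displacement = tail_disp)
}
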