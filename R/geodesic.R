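#' Two-stage geodesic distance field on a mesh
#'
#' Computes the geodesic distance (shortest path constrained to the meshed
#' domain) from a seed point to every mesh node. Stage one is a
#' nearest-neighbour line-of-sight propagation assigning exact Euclidean
#' distances to a (conservative) subset of the nodes visible from the seed;
#' stage two is mesh-based fast marching propagating the front through the
#' rest of the mesh in causal (increasing-distance) order. Line-of-sight
#' distances are exact and are never overwritten by fast marching.
#'
#' The seed need not be a mesh node: a seed within `1e-6` of the local edge
#' length of a node is snapped to it; otherwise the nodes of the containing
#' element are initialised with their Euclidean distances.
#'
#' @param mesh a [cdt_mesh].
#' @param seed numeric world point inside the mesh.
#' @param use_los run the line-of-sight initialisation stage? When `FALSE` the
#'   containing element's nodes are seeded with Euclidean distances and marked
#'   plainly known (the "no line-of-sight initialisation" variant).
#' @return A `cdt_distfield`: list with `mesh`, `seed`, `distance` (per node,
#'   `Inf` where unreachable), `state` (0 far, 1 trial, 2 known, 3
#'   known-by-line-of-sight) and `accepted` (fast-marching acceptance order).
#' @export
geodesic_field <- function(mesh, seed, use_los = TRUE) {
  init <- geodesic_init(mesh, seed, use_los)
  fast_march(init)
}

#' Line-of-sight initialisation stage
#'
#' Runs only stage one of the geodesic solver: all returned distances are
#' exact Euclidean norms to the seed and the marked node set is a subset of
#' the set of nodes actually visible from the seed.
#'
#' @inheritParams geodesic_field
#' @return A `cdt_distfield` with states 0 (far) and 3 (known-los) only.
#' @export
line_of_sight_init <- function(mesh, seed) {
  geodesic_init(mesh, seed, use_los = TRUE)
}

geodesic_init <- function(mesh, seed, use_los) {
  stopifnot(inherits(mesh, "cdt_mesh"))
  seed <- as.numeric(seed)
  if (length(seed) != mesh$dim) stop("seed dimensionality does not match the mesh")
  loc <- locate_point(mesh, seed)
  if (loc$element == 0) stop("seed outside mesh")
  enodes <- mesh$elements[loc$element, ]
  epts <- mesh$nodes[enodes, , drop = FALSE]
  edge <- mean(sqrt(rowSums((epts - epts[c(2:nrow(epts), 1), , drop = FALSE])^2)))
  d2n <- sqrt(colSums((t(epts) - seed)^2))
  if (min(d2n) < 1e-6 * edge) seed <- epts[which.min(d2n), ]
  if (use_los) {
    res <- cpp_los_init(mesh$nodes, mesh$elements, mesh$neighbors, seed,
                        loc$element)
    dist <- res$distance
    state <- res$state
  } else {
    dist <- rep(Inf, nrow(mesh$nodes))
    state <- integer(nrow(mesh$nodes))
    dist[enodes] <- d2n
    state[enodes] <- 2L
  }
  structure(list(mesh = mesh, seed = seed, distance = dist, state = state,
                 accepted = numeric(0)),
            class = "cdt_distfield")
}

#' Fast-marching stage
#'
#' Propagates a partially known distance field to all reachable nodes.
#' Acceptance order is monotone non-decreasing (up to floating point);
#' known and known-los distances are frozen.
#'
#' @param field a `cdt_distfield` with at least one known node.
#' @return The completed `cdt_distfield`.
#' @export
fast_march <- function(field) {
  stopifnot(inherits(field, "cdt_distfield"))
  if (!any(field$state >= 2L)) stop("field has no known node to march from")
  mesh <- field$mesh
  star <- cpp_node_star(mesh$elements, nrow(mesh$nodes))
  res <- cpp_fast_march(mesh$nodes, mesh$elements, star$ptr, star$idx,
                        field$distance, field$state)
  field$distance <- res$distance
  field$state <- res$state
  field$accepted <- res$accepted
  field
}

#' @export
print.cdt_distfield <- function(x, ...) {
  cat(sprintf("<cdt_distfield> %d nodes: %d known-los, %d known, %d unreached\n",
              length(x$distance), sum(x$state == 3), sum(x$state == 2),
              sum(!is.finite(x$distance))))
  invisible(x)
}

#' Local fast-marching update on one simplex
#'
#' First-arrival candidate distance at an unknown node given the known nodes
#' of the simplex: the plane-wave (unit-speed Eikonal) solution when its
#' characteristic passes through the known facet, dropping to the
#' interpolated-virtual-node update for obtuse configurations and to the
#' one-dimensional edge update when the characteristic leaves the simplex
#' (all realised as the exact minimisation of
#' `sum(lambda * d) + ||x_u - sum(lambda * p)||` over the known facet).
#'
#' @param unknown coordinates of the node being updated.
#' @param known_pts matrix of known node coordinates (one per row, at most
#'   `dim` rows).
#' @param known_dist their distances.
#' @return candidate distance (scalar).
#' @export
local_update <- function(unknown, known_pts, known_dist) {
  known_pts <- matrix(as.numeric(known_pts), ncol = length(unknown))
  if (nrow(known_pts) < 1) stop("no known neighbor")
  cpp_local_update(as.numeric(unknown), known_pts, as.numeric(known_dist))
}

#' Interpolate a distance field at arbitrary points
#'
#' Barycentric interpolation within the containing element.
#'
#' @param field a `cdt_distfield`.
#' @param points numeric matrix (one point per row) or a single point.
#' @return numeric vector of distances (`NA` outside the mesh).
#' @export
distance_at <- function(field, points) {
  single <- is.null(dim(points))
  pm <- if (single) matrix(as.numeric(points), nrow = 1) else as.matrix(points)
  loc <- locate_point(field$mesh, pm)
  out <- rep(NA_real_, nrow(pm))
  ok <- loc$element > 0
  if (any(ok)) {
    el <- field$mesh$elements[loc$element[ok], , drop = FALSE]
    dmat <- matrix(field$distance[el], nrow = sum(ok))
    out[ok] <- rowSums(loc$bary[ok, , drop = FALSE] * dmat)
  }
  out
}

#' Edge-graph Dijkstra distances over a mesh
#'
#' Shortest-path distances restricted to mesh edges, from the same initial
#' known set as a distance field. Edge paths are admissible geodesic
#' approximants, so these distances bound the fast-marching solution from
#' above; used as an independent cross-check.
#'
#' @param field a `cdt_distfield` (typically the output of
#'   [line_of_sight_init()] or [geodesic_init][geodesic_field]).
#' @return numeric vector of per-node Dijkstra distances.
#' @export
mesh_dijkstra <- function(field) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("mesh_dijkstra requires the igraph package")
  mesh <- field$mesh
  el <- mesh$elements
  k <- ncol(el)
  pairs <- utils::combn(k, 2)
  ed <- NULL
  for (j in seq_len(ncol(pairs)))
    ed <- rbind(ed, cbind(el[, pairs[1, j]], el[, pairs[2, j]]))
  ed <- unique(cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2])))
  w <- sqrt(rowSums((mesh$nodes[ed[, 1], , drop = FALSE] -
                     mesh$nodes[ed[, 2], , drop = FALSE])^2))
  n <- nrow(mesh$nodes)
  known <- which(field$state >= 2L & is.finite(field$distance))
  if (!length(known)) stop("field has no known node")
  virt <- n + 1L
  edges <- rbind(ed, cbind(rep(virt, length(known)), known))
  weights <- c(w, field$distance[known])
  g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
  as.numeric(igraph::distances(g, v = virt, weights = weights))[seq_len(n)]
}

#' Morphological region-growing raster distances
#'
#' Iterative constrained dilation of the seed within the mask; each cell's
#' distance is the iteration count at which it is reached times the voxel
#' spacing. Connectivities: `c4`/`c8`/`oct` in 2D, `c6`/`c26`/`oct` in 3D
#' (`oct` alternates the full and axis neighbourhoods, starting with the full
#' one, approximating the Euclidean ball better than either alone). Requires
#' isotropic spacing.
#'
#' @param domain a [cdt_domain].
#' @param seed 1-based voxel multi-index of the seed (inside the mask).
#' @param connectivity metric name.
#' @return A [cdt_image] whose values are distances (`Inf` for in-mask cells
#'   not reached, `NA` outside the mask).
#' @export
raster_geodesic <- function(domain, seed,
                            connectivity = c("c4", "c8", "oct", "c6", "c26")) {
  connectivity <- match.arg(connectivity)
  stopifnot(inherits(domain, "cdt_domain"))
  nd <- domain$dim
  if (nd == 2 && connectivity %in% c("c6", "c26"))
    stop("3D connectivity requested for a 2D domain")
  if (nd == 3 && connectivity %in% c("c4", "c8"))
    stop("2D connectivity requested for a 3D domain")
  sp <- domain$spacing
  if (diff(range(sp)) > 1e-12 * max(sp))
    stop("raster_geodesic requires isotropic spacing")
  s <- sp[1]
  mask <- domain$mask
  seed <- as.integer(seed)
  if (length(seed) != nd) stop("seed must be a voxel multi-index")
  seedlin <- linear_index(matrix(seed, 1), dim(mask))
  if (seed[1] < 1 || any(seed > dim(mask)) || !mask[seedlin]) stop("seed outside mask")
  axis_conn <- if (nd == 2) "c4" else "c6"
  full_conn <- if (nd == 2) "c8" else "c26"
  sh_axis <- shift_set(nd, axis_conn)
  sh_full <- shift_set(nd, full_conn)
  dist <- array(NA_real_, dim = dim(mask))
  dist[mask] <- Inf
  reached <- array(FALSE, dim = dim(mask))
  reached[seedlin] <- TRUE
  dist[seedlin] <- 0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    sh <- switch(connectivity,
                 c4 = , c6 = sh_axis,
                 c8 = , c26 = sh_full,
                 oct = if (iter %% 2L == 1L) sh_full else sh_axis)
    grown <- reached
    for (o in sh) grown <- grown | shift_array(reached, o)
    new <- grown & mask & !reached
    if (!any(new)) {
      # octagonal growth may stall on the axis step; try the other one
      if (connectivity == "oct") {
        grown <- reached
        for (o in sh_full) grown <- grown | shift_array(reached, o)
        if (!any(grown & mask & !reached)) break
        next
      }
      break
    }
    dist[new] <- iter * s
    reached <- reached | new
  }
  cdt_image(domain, dist)
}

#' Percent-error statistics against exact distances
#'
#' Per-point percent error `100 * (computed - exact) / exact`; the seed (zero
#' exact distance) must be excluded by the caller.
#'
#' @param computed,exact equal-length numeric vectors, `exact > 0`.
#' @return list with `mean`, `sd` and the per-point `percent` errors.
#' @export
error_stats <- function(computed, exact) {
  if (length(computed) != length(exact)) stop("paired inputs of equal length required")
  if (!length(computed)) stop("empty input")
  if (any(exact <= 0)) stop("exact distances must be positive (exclude the seed)")
  pct <- 100 * (computed - exact) / exact
  list(mean = mean(pct), sd = stats::sd(pct), percent = pct)
}
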