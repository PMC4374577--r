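#' Simplicial conforming mesh
#'
#' Triangle (2D) or tetrahedral (3D) mesh in world coordinates. Elements are
#' stored with positive orientation (counter-clockwise triangles / positive
#' determinant tets); `neighbors[e, k]` is the element sharing the facet
#' opposite node `k` of element `e`, or 0 on the boundary. Construction
#' verifies conformity (no facet shared by more than two elements).
#'
#' @param nodes numeric matrix of node coordinates (n x dim).
#' @param elements integer matrix of 1-based node indices (m x (dim+1)).
#' @return An object of class `cdt_mesh` with fields `nodes`, `elements`,
#'   `neighbors`, `dim`.
#' @export
cdt_mesh <- function(nodes, elements) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  dim <- ncol(nodes)
  if (!dim %in% c(2L, 3L)) stop("mesh must be 2D or 3D")
  if (ncol(elements) != dim + 1) stop("elements must have dim+1 nodes each")
  if (nrow(elements) < 1) stop("mesh has no elements")
  if (min(elements) < 1 || max(elements) > nrow(nodes)) stop("element node index out of range")
  # enforce positive orientation by swapping the first two nodes
  meas <- cpp_signed_measures(nodes, elements)
  flip <- meas < 0
  if (any(flip)) {
    tmp <- elements[flip, 1]
    elements[flip, 1] <- elements[flip, 2]
    elements[flip, 2] <- tmp
    meas[flip] <- -meas[flip]
  }
  if (any(meas <= 0)) stop("mesh contains degenerate (zero measure) elements")
  nb <- cpp_build_neighbors(elements)
  structure(list(nodes = nodes, elements = elements, neighbors = nb, dim = dim),
            class = "cdt_mesh")
}

#' @export
print.cdt_mesh <- function(x, ...) {
  cat(sprintf("<cdt_mesh> %dD, %d nodes, %d elements\n", x$dim, nrow(x$nodes),
              nrow(x$elements)))
  invisible(x)
}

#' Elements incident to a node
#' @param mesh a [cdt_mesh].
#' @param node 1-based node index.
#' @return integer vector of element indices.
#' @export
node_star <- function(mesh, node) {
  node <- as.integer(node)
  if (node < 1 || node > nrow(mesh$nodes)) stop("node index out of range")
  star <- mesh_star_csr(mesh)
  star$idx[seq(star$ptr[node] + 1L, star$ptr[node + 1L])]
}

mesh_star_csr <- function(mesh) {
  if (is.null(attr(mesh, "star_csr"))) {
    attr(mesh, "star_csr") <- cpp_node_star(mesh$elements, nrow(mesh$nodes))
  }
  attr(mesh, "star_csr")
}

#' Facet-opposite neighbours of an element
#' @param mesh a [cdt_mesh].
#' @param element 1-based element index.
#' @return integer vector of length dim+1; 0 marks a boundary facet. Entry `k`
#'   is the element across the facet opposite node `k`.
#' @export
element_neighbors <- function(mesh, element) {
  element <- as.integer(element)
  if (element < 1 || element > nrow(mesh$elements)) stop("element index out of range")
  mesh$neighbors[element, ]
}

#' Locate points in a mesh
#'
#' @param mesh a [cdt_mesh].
#' @param p numeric vector (one point) or matrix (one row per point).
#' @return For a single point, a list with `element` (0 when outside the mesh)
#'   and `bary`; for a matrix, a list of vectors/matrix. Points on shared
#'   facets resolve to the lowest element index.
#' @export
locate_point <- function(mesh, p) {
  single <- is.null(dim(p))
  pm <- if (single) matrix(as.numeric(p), nrow = 1) else as.matrix(p)
  if (ncol(pm) != mesh$dim) stop("point dimensionality does not match the mesh")
  storage.mode(pm) <- "double"
  res <- cpp_locate_points(mesh$nodes, mesh$elements, pm)
  if (single) list(element = res$element[1], bary = res$bary[1, ]) else res
}

#' Total measure (area/volume) of a mesh
#' @param mesh a [cdt_mesh].
#' @return total element area (2D) or volume (3D).
#' @export
mesh_measure <- function(mesh) sum(cpp_signed_measures(mesh$nodes, mesh$elements))

#' Edge lengths of a mesh
#' @param mesh a [cdt_mesh].
#' @return numeric vector of unique edge lengths.
#' @export
mesh_edge_lengths <- function(mesh) {
  el <- mesh$elements
  k <- ncol(el)
  pairs <- utils::combn(k, 2)
  ed <- NULL
  for (j in seq_len(ncol(pairs))) {
    ed <- rbind(ed, cbind(el[, pairs[1, j]], el[, pairs[2, j]]))
  }
  ed <- unique(cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2])))
  sqrt(rowSums((mesh$nodes[ed[, 1], , drop = FALSE] -
                mesh$nodes[ed[, 2], , drop = FALSE])^2))
}

#' Audit mesh conformity
#'
#' Checks that all elements have positive measure, that every facet is shared
#' by at most two elements with identical node sets (enforced structurally by
#' the facet-matching neighbour build) and that the neighbour relation is
#' symmetric.
#'
#' @param mesh a [cdt_mesh].
#' @return `TRUE` invisibly; errors on violation.
#' @export
audit_conformity <- function(mesh) {
  meas <- cpp_signed_measures(mesh$nodes, mesh$elements)
  if (any(meas <= 0)) stop("element with non-positive measure")
  nb <- cpp_build_neighbors(mesh$elements)  # errors if a facet is over-shared
  if (!identical(nb, mesh$neighbors)) stop("stored neighbour table is stale")
  k <- ncol(mesh$elements)
  for (f in seq_len(k)) {
    e2 <- nb[, f]
    has <- which(e2 > 0)
    back <- vapply(has, function(e) any(nb[e2[e], ] == e), logical(1))
    if (!all(back)) stop("neighbour relation is not symmetric")
  }
  invisible(TRUE)
}

# Test whether world points fall in the union of (dilated) voxel boxes of the
# mask: point p is a member iff some TRUE cell c has |index(p) - c| <=
# 0.5 + dilate on every axis (Chebyshev box dilation, valid beyond the raster
# bounds).
points_in_mask <- function(domain, pts, dilate = 0L) {
  mask <- domain$mask
  d <- dim(mask)
  nd <- length(d)
  f <- world_to_index(domain, pts)
  out <- rep(FALSE, nrow(f))
  reach <- 0.5 + dilate + 1e-9
  offs <- as.matrix(expand.grid(rep(list(seq(-dilate, dilate)), nd)))
  base <- round(f)
  for (r in seq_len(nrow(offs))) {
    cand <- sweep(base, 2, offs[r, ], "+")
    ok <- !out
    for (i in seq_len(nd)) {
      ok <- ok & cand[, i] >= 1 & cand[, i] <= d[i] & abs(f[, i] - cand[, i]) <= reach
    }
    if (any(ok)) {
      wok <- which(ok)
      hit <- mask[linear_index(matrix(as.integer(cand[wok, , drop = FALSE]), ncol = nd), d)]
      out[wok[hit]] <- TRUE
    }
  }
  out
}

#' Generate a conforming triangle mesh over a 2D domain
#'
#' Lays an equilateral-triangle lattice with edge `target_edge` over the
#' domain's bounding box, keeps triangles whose centroid falls inside the
#' 1-voxel-dilated mask, and snaps nodes lying outside the mask onto the mask
#' support (nearest foreground-voxel box), capped at two lattice edges.
#' Nodes brought into coincidence are merged; elements degenerated or
#' inverted by snapping are dropped.
#'
#' @param domain a 2D [cdt_domain].
#' @param target_edge requested edge length (world units).
#' @return A [cdt_mesh].
#' @export
generate_mesh_2d <- function(domain, target_edge) {
  stopifnot(inherits(domain, "cdt_domain"))
  if (domain$dim != 2) stop("domain must be 2D")
  bb <- bounding_box(domain)
  if (any(bb$upper - bb$lower <= 0))
    stop("degenerate domain (single row or column) cannot be meshed")
  h <- as.numeric(target_edge)
  if (!is.finite(h) || h <= 0) stop("target_edge must be positive")
  pad <- h
  x0 <- bb$lower[1] - pad
  y0 <- bb$lower[2] - pad
  nxn <- ceiling((bb$upper[1] - x0 + pad) / h) + 2L
  nyn <- ceiling((bb$upper[2] - y0 + pad) / (h * sqrt(3) / 2)) + 2L
  jj <- rep(seq_len(nyn) - 1L, each = nxn)
  ii <- rep(seq_len(nxn) - 1L, nyn)
  nx_ <- x0 + (ii + 0.5 * (jj %% 2L)) * h
  ny_ <- y0 + jj * h * sqrt(3) / 2
  nodes <- cbind(nx_, ny_)
  nid <- function(i, j) j * nxn + i + 1L
  tri <- vector("list", 2)
  i <- rep(0:(nxn - 2L), nyn - 1L)
  j <- rep(0:(nyn - 2L), each = nxn - 1L)
  even <- j %% 2L == 0L
  up <- cbind(nid(i, j), nid(i + 1L, j), ifelse(even, nid(i, j + 1L), nid(i + 1L, j + 1L)))
  dn <- cbind(ifelse(even, nid(i + 1L, j), nid(i, j)),
              nid(i + 1L, j + 1L), nid(i, j + 1L))
  elements <- rbind(up, dn)
  finish_lattice_mesh(domain, nodes, elements, h)
}

#' Generate a conforming tetrahedral mesh over a 3D domain
#'
#' Freudenthal decomposition (six tetrahedra per cube) of a cubic lattice at
#' `target_edge`, clipped and snapped as in [generate_mesh_2d()].
#'
#' @param domain a 3D [cdt_domain].
#' @param target_edge requested lattice edge length (world units).
#' @return A [cdt_mesh].
#' @export
generate_mesh_3d <- function(domain, target_edge) {
  stopifnot(inherits(domain, "cdt_domain"))
  if (domain$dim != 3) stop("domain must be 3D")
  bb <- bounding_box(domain)
  if (any(bb$upper - bb$lower <= 0)) stop("degenerate domain cannot be meshed")
  h <- as.numeric(target_edge)
  if (!is.finite(h) || h <= 0) stop("target_edge must be positive")
  pad <- h
  lo <- bb$lower - pad
  n <- ceiling((bb$upper - lo + pad) / h) + 2L
  idx <- expand_grid_int(n)
  nodes <- sweep(sweep(idx, 2, c(h, h, h), "*"), 2, lo, "+")
  nid <- function(i, j, k) 1L + i + n[1] * (j + n[2] * k)
  ci <- expand_grid_int(n - 1L)
  i <- ci[, 1]; j <- ci[, 2]; k <- ci[, 3]
  v000 <- nid(i, j, k);       v100 <- nid(i + 1L, j, k)
  v010 <- nid(i, j + 1L, k);  v110 <- nid(i + 1L, j + 1L, k)
  v001 <- nid(i, j, k + 1L);  v101 <- nid(i + 1L, j, k + 1L)
  v011 <- nid(i, j + 1L, k + 1L); v111 <- nid(i + 1L, j + 1L, k + 1L)
  # six tets around the main diagonal v000-v111 (conforming across cubes)
  elements <- rbind(
    cbind(v000, v100, v110, v111),
    cbind(v000, v110, v010, v111),
    cbind(v000, v010, v011, v111),
    cbind(v000, v011, v001, v111),
    cbind(v000, v001, v101, v111),
    cbind(v000, v101, v100, v111))
  finish_lattice_mesh(domain, nodes, elements, h)
}

expand_grid_int <- function(n) {
  i <- rep.int(seq_len(n[1]) - 1L, n[2] * n[3])
  j <- rep.int(rep(seq_len(n[2]) - 1L, each = n[1]), n[3])
  k <- rep(seq_len(n[3]) - 1L, each = n[1] * n[2])
  cbind(i, j, k)
}

# Shared tail of lattice mesh generation: clip to the dilated mask, drop
# unused nodes, snap outside nodes to the mask support, drop degenerates.
finish_lattice_mesh <- function(domain, nodes, elements, h) {
  k <- ncol(elements)
  cent <- matrix(0, nrow(elements), domain$dim)
  for (j in seq_len(k)) cent <- cent + nodes[elements[, j], , drop = FALSE]
  cent <- cent / k
  keep <- points_in_mask(domain, cent, dilate = 1L)
  if (!any(keep)) stop("no mesh element lies inside the domain")
  elements <- elements[keep, , drop = FALSE]
  used <- sort(unique(as.vector(elements)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  elements <- matrix(remap[elements], ncol = k)
  nodes <- nodes[used, , drop = FALSE]

  # orient consistently before snapping so post-snap inversions are detectable
  storage.mode(elements) <- "integer"
  meas0 <- cpp_signed_measures(nodes, elements)
  flip <- meas0 < 0
  if (any(flip)) {
    tmp <- elements[flip, 1]
    elements[flip, 1] <- elements[flip, 2]
    elements[flip, 2] <- tmp
  }

  outside <- which(!points_in_mask(domain, nodes))
  if (length(outside)) {
    qidx <- round(world_to_index(domain, nodes[outside, , drop = FALSE])) - 1
    d <- dim(domain$mask)
    for (i in seq_len(ncol(qidx))) qidx[, i] <- pmin(pmax(qidx[, i], 0), d[i] - 1)
    maxr <- as.integer(ceiling(2 * h / min(domain$spacing))) + 2L
    nearest <- cpp_nearest_true_cell(as.logical(domain$mask), dim(domain$mask),
                                     matrix(as.integer(qidx), ncol = ncol(qidx)), maxr)
    for (t in seq_along(outside)) {
      if (nearest[t] < 0) next
      ci <- arrayInd(nearest[t] + 1L, d)
      cw <- domain$origin + (as.numeric(ci) - 1) * domain$spacing
      target <- pmin(pmax(nodes[outside[t], ], cw - domain$spacing / 2),
                     cw + domain$spacing / 2)
      delta <- target - nodes[outside[t], ]
      len <- sqrt(sum(delta^2))
      if (len > 2 * h) delta <- delta * (2 * h / len)  # snap cap: two lattice edges
      nodes[outside[t], ] <- nodes[outside[t], ] + delta
    }
  }

  # merge nodes brought into coincidence by snapping (duplicate boundary
  # vertices would leave zero-length edges that degrade the Eikonal updates)
  key <- apply(round(sweep(nodes, 2, 1e-6 * h, "/")), 1, paste, collapse = ",")
  first <- match(key, key)
  if (any(first != seq_along(key))) {
    used <- sort(unique(first))
    remap2 <- integer(nrow(nodes))
    remap2[used] <- seq_along(used)
    elements <- matrix(remap2[first[elements]], ncol = k)
    nodes <- nodes[used, , drop = FALSE]
    storage.mode(elements) <- "integer"
    # elements collapsed onto a repeated node are degenerate; drop them below
  }

  meas <- cpp_signed_measures(nodes, elements)
  scale <- h^domain$dim
  ok <- meas > 1e-9 * scale  # drop elements degenerated or inverted by snapping
  elements <- elements[ok, , drop = FALSE]
  used <- sort(unique(as.vector(elements)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  elements <- matrix(remap[elements], ncol = k)
  storage.mode(elements) <- "integer"
  cdt_mesh(nodes[used, , drop = FALSE], elements)
}

#' Rasterised footprint of a mesh
#'
#' The set of raster cells (on a domain's grid) whose centres lie inside some
#' mesh element.
#'
#' @param mesh a [cdt_mesh].
#' @param domain a [cdt_domain] supplying the grid geometry.
#' @return A logical array shaped like `domain$mask`.
#' @export
mesh_footprint <- function(mesh, domain) {
  zero <- matrix(0, nrow(mesh$nodes), mesh$dim)
  res <- cpp_pullback(mesh$nodes, mesh$elements, zero,
                      dim(domain$mask), domain$origin, domain$spacing,
                      numeric(0), integer(length(dim(domain$mask))),
                      domain$origin, domain$spacing, 0L, 0, FALSE)
  array(res$mask, dim = dim(domain$mask))
}
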