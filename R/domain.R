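#' Spatial domain of an image object
#'
#' A domain is the support region of an image: a logical raster together with
#' the world coordinate of the first voxel centre (`origin`) and per-axis voxel
#' sizes (`spacing`). The world position of voxel index `(i1, ..., id)`
#' (1-based) is `origin + (index - 1) * spacing`; all distances in the package
#' are in world units.
#'
#' @param mask logical array, 2D or 3D, with at least one `TRUE` cell.
#' @param origin numeric vector, world coordinate of the centre of voxel
#'   `(1, ..., 1)`. Defaults to zeros.
#' @param spacing numeric vector of strictly positive voxel sizes. Defaults to
#'   ones.
#' @return An object of class `cdt_domain`.
#' @export
cdt_domain <- function(mask, origin = NULL, spacing = NULL) {
  if (is.null(dim(mask))) stop("mask must be a 2D or 3D array")
  nd <- length(dim(mask))
  if (!nd %in% c(2L, 3L)) stop("mask must be 2D or 3D")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("mask must not contain NA")
  if (!any(mask)) stop("domain is empty: mask has no TRUE cell")
  if (is.null(origin)) origin <- rep(0, nd)
  if (is.null(spacing)) spacing <- rep(1, nd)
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  if (length(origin) != nd || length(spacing) != nd)
    stop("origin and spacing must have one entry per mask axis")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing components must be strictly positive")
  structure(list(mask = mask, origin = origin, spacing = spacing, dim = nd),
            class = "cdt_domain")
}

#' @export
print.cdt_domain <- function(x, ...) {
  cat(sprintf("<cdt_domain> %dD, raster %s, %d foreground cells\n", x$dim,
              paste(dim(x$mask), collapse = "x"), sum(x$mask)))
  cat(sprintf("  origin (%s), spacing (%s)\n", paste(signif(x$origin, 6), collapse = ", "),
              paste(signif(x$spacing, 6), collapse = ", ")))
  invisible(x)
}

#' Image object: domain plus optional value table
#'
#' Separates the support region of an image (its domain, Omega) from the
#' intensity values defined over it (its value table, V). The value table,
#' when present, is a numeric array congruent with the domain mask; values are
#' only meaningful where the mask is `TRUE`.
#'
#' @param domain a [cdt_domain].
#' @param values optional numeric array with the same shape as `domain$mask`.
#' @return An object of class `cdt_image`.
#' @export
cdt_image <- function(domain, values = NULL) {
  stopifnot(inherits(domain, "cdt_domain"))
  if (!is.null(values)) {
    if (!identical(dim(values), dim(domain$mask)))
      stop("values must have the same shape as the domain mask")
    values <- array(as.numeric(values), dim = dim(values))
  }
  structure(list(domain = domain, values = values), class = "cdt_image")
}

#' @export
print.cdt_image <- function(x, ...) {
  print(x$domain)
  if (is.null(x$values)) {
    cat("  no value table\n")
  } else {
    v <- x$values[x$domain$mask]
    cat(sprintf("  values in [%g, %g]\n", min(v), max(v)))
  }
  invisible(x)
}

#' Look up image values at voxel indices
#'
#' Querying outside the domain yields the background `fill` (default `NA`),
#' never a value-table entry.
#'
#' @param obj a [cdt_image] with values.
#' @param index integer matrix of 1-based voxel indices, one row per query.
#' @param fill background value returned outside the domain.
#' @return numeric vector of values.
#' @export
image_value_at <- function(obj, index, fill = NA_real_) {
  stopifnot(inherits(obj, "cdt_image"))
  if (is.null(obj$values)) stop("image object has no value table")
  index <- matrix(as.integer(index), ncol = obj$domain$dim)
  d <- dim(obj$domain$mask)
  ok <- rep(TRUE, nrow(index))
  for (i in seq_len(ncol(index))) ok <- ok & index[, i] >= 1L & index[, i] <= d[i]
  out <- rep(fill, nrow(index))
  if (any(ok)) {
    lin <- linear_index(index[ok, , drop = FALSE], d)
    inside <- obj$domain$mask[lin]
    vals <- obj$values[lin]
    vals[!inside] <- fill
    out[ok] <- vals
  }
  out
}

linear_index <- function(index, dims) {
  lin <- index[, 1]
  stride <- 1
  for (i in seq_along(dims)[-1]) {
    stride <- stride * dims[i - 1]
    lin <- lin + (index[, i] - 1L) * stride
  }
  lin
}

#' World coordinates of voxel centres
#' @param domain a [cdt_domain].
#' @param index 1-based integer index matrix (one row per voxel).
#' @return numeric matrix of world coordinates.
#' @export
index_to_world <- function(domain, index) {
  index <- matrix(as.numeric(index), ncol = domain$dim)
  sweep(sweep(index - 1, 2, domain$spacing, "*"), 2, domain$origin, "+")
}

#' @rdname index_to_world
#' @param world numeric matrix of world coordinates.
#' @return For `world_to_index`, the fractional 1-based voxel index.
#' @export
world_to_index <- function(domain, world) {
  world <- matrix(as.numeric(world), ncol = domain$dim)
  sweep(sweep(world, 2, domain$origin, "-"), 2, domain$spacing, "/") + 1
}

#' Threshold segmentation of an image's value table
#'
#' Keeps cells whose value lies in `[low, high]`; optionally restricts the
#' result to the largest face-connected foreground component (the simple
#' grey-value thresholding used to extract a foreground domain before meshing).
#'
#' @param obj a [cdt_image] with values.
#' @param low,high inclusive value bounds.
#' @param largest_component keep only the largest connected component?
#' @return A [cdt_domain]. Errors if the result is empty.
#' @export
threshold_segment <- function(obj, low = -Inf, high = Inf, largest_component = FALSE) {
  stopifnot(inherits(obj, "cdt_image"))
  if (is.null(obj$values)) stop("image object has no value table")
  m <- obj$domain$mask & obj$values >= low & obj$values <= high
  if (!any(m)) stop("threshold produced an empty domain")
  if (largest_component) {
    lab <- cpp_label_components(as.logical(m), dim(m))
    keep <- which.max(tabulate(lab[lab > 0L]))
    m <- array(lab == keep, dim = dim(m))
  }
  cdt_domain(m, obj$domain$origin, obj$domain$spacing)
}

#' Connected-component labels of a domain
#' @param domain a [cdt_domain].
#' @return integer array of labels (0 = background), face connectivity.
#' @export
label_components <- function(domain) {
  stopifnot(inherits(domain, "cdt_domain"))
  array(cpp_label_components(as.logical(domain$mask), dim(domain$mask)),
        dim = dim(domain$mask))
}

#' Tight bounding box and maximum extent of a domain
#'
#' The box is tight over `TRUE` voxel centres, in world coordinates. `r_max`,
#' the maximum per-axis extent `max_i(max_i - min_i)`, is the scale used to
#' set radial basis support via `c = delta * r_max`.
#'
#' @param domain a [cdt_domain].
#' @return list with `lower`, `upper` (world coordinates of extreme voxel
#'   centres) and `r_max`.
#' @export
bounding_box <- function(domain) {
  stopifnot(inherits(domain, "cdt_domain"))
  idx <- which(domain$mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  lower <- domain$origin + (lo - 1) * domain$spacing
  upper <- domain$origin + (hi - 1) * domain$spacing
  list(lower = lower, upper = upper, r_max = max(upper - lower))
}

#' Dilate a domain mask by one voxel (face + diagonal neighbourhood)
#' @keywords internal
dilate_mask <- function(mask, times = 1L) {
  d <- dim(mask)
  nd <- length(d)
  for (t in seq_len(times)) {
    out <- mask
    shifts <- shift_set(nd, if (nd == 2) "c8" else "c26")
    for (s in shifts) out <- out | shift_array(mask, s)
    mask <- out
  }
  mask
}

# Shift a logical array by integer offset, padding with FALSE.
shift_array <- function(a, off) {
  d <- dim(a)
  nd <- length(d)
  out <- array(FALSE, dim = d)
  src <- dst <- vector("list", nd)
  for (i in seq_len(nd)) {
    o <- off[i]
    if (abs(o) >= d[i]) return(out)
    src[[i]] <- if (o >= 0) seq_len(d[i] - o) else seq(1 - o, d[i])
    dst[[i]] <- if (o >= 0) seq(1 + o, d[i]) else seq_len(d[i] + o)
  }
  if (nd == 2) out[dst[[1]], dst[[2]]] <- a[src[[1]], src[[2]]]
  else out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Offsets for a named raster connectivity.
shift_set <- function(nd, conn) {
  axes <- diag(nd)
  ax <- rbind(axes, -axes)
  if (conn %in% c("c4", "c6")) return(asplit(ax, 1))
  g <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  asplit(g, 1)
}
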