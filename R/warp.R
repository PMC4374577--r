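#' Registration configuration
#'
#' Collects the tunable choices of a CDT registration. Defaults follow the
#' atlas-registration setup: inverse multiquadric basis with `delta = 0.05`,
#' line-of-sight initialisation on, geodesic (constrained) distances, linear
#' value interpolation and background fill 0.
#'
#' @param kind basis kind (see [basis_eval()]).
#' @param delta dimensionless basis support factor in (0, 1].
#' @param use_los use line-of-sight initialisation for the distance fields?
#' @param constrained use geodesic distances (`TRUE`, the CDT) or Euclidean
#'   distances (`FALSE`, the conventional unconstrained RBF warp)?
#' @param interp value interpolation, `"linear"` or `"nearest"` (for labels).
#' @param fill background value for unmapped locations.
#' @return A list of class `cdt_config`.
#' @export
cdt_config <- function(kind = "imq", delta = 0.05, use_los = TRUE,
                       constrained = TRUE, interp = c("linear", "nearest"),
                       fill = 0) {
  interp <- match.arg(interp)
  if (!is.finite(delta) || delta <= 0 || delta > 1) stop("delta must be in (0, 1]")
  structure(list(kind = kind, delta = delta, use_los = use_los,
                 constrained = constrained, interp = interp, fill = fill),
            class = "cdt_config")
}

#' Geodesic distance fields for a landmark set
#'
#' One geodesic field per landmark centre, plus the N x N centre-centre
#' geodesic distance matrix (each field evaluated at the other centres by
#' barycentric interpolation, then symmetrised). Fields are keyed by centre
#' coordinates: when a previous result is passed as `cache`, only fields whose
#' centre changed are recomputed, so editing one landmark recomputes exactly
#' one field.
#'
#' @param mesh a [cdt_mesh].
#' @param landmarks a [cdt_landmarks] with all centres inside the mesh.
#' @param use_los use line-of-sight initialisation?
#' @param cache optional previous return value of this function.
#' @return list with `fields` (list of `cdt_distfield`) and `cross` (N x N
#'   symmetric geodesic distance matrix, zero diagonal).
#' @export
landmark_distance_fields <- function(mesh, landmarks, use_los = TRUE, cache = NULL) {
  stopifnot(inherits(mesh, "cdt_mesh"), inherits(landmarks, "cdt_landmarks"))
  n <- landmarks$n
  key <- function(p) paste(sprintf("%.12g", p), collapse = ",")
  cached <- if (!is.null(cache)) {
    stats::setNames(cache$fields, vapply(cache$fields, function(f) key(f$seed_input),
                                         character(1)))
  } else {
    list()
  }
  fields <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- landmarks$centres[i, ]
    k <- key(ci)
    if (!is.null(cached[[k]])) {
      fields[[i]] <- cached[[k]]
      next
    }
    loc <- locate_point(mesh, ci)
    if (loc$element == 0) stop("landmark centre ", i, " lies outside the mesh")
    f <- geodesic_field(mesh, ci, use_los = use_los)
    f$seed_input <- ci
    fields[[i]] <- f
  }
  cross <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n)) {
      cross[i, ] <- distance_at(fields[[i]], landmarks$centres)
    }
    cross <- (cross + t(cross)) / 2
    diag(cross) <- 0
  }
  list(fields = fields, cross = cross)
}

#' Warp field: per-node displacements over a mesh
#'
#' Fits the RBF model to the landmarks (geodesic or Euclidean centre-centre
#' distances according to `config$constrained`) and evaluates it at every mesh
#' node, using each landmark's geodesic distance field (constrained) or
#' Euclidean norms (unconstrained). Displacements inside elements follow by
#' barycentric interpolation of the nodal values.
#'
#' @param mesh a [cdt_mesh].
#' @param landmarks a [cdt_landmarks].
#' @param config a [cdt_config].
#' @param c basis parameter; defaults to `delta * r_max` with `r_max` the
#'   maximum axis extent of the mesh nodes.
#' @param dist optional precomputed [landmark_distance_fields()] result
#'   (constrained case), to reuse cached fields.
#' @return An object of class `cdt_warp` with fields `mesh`, `displacement`
#'   (nodes x dim), `model` and `landmarks`.
#' @export
build_warp <- function(mesh, landmarks, config = cdt_config(), c = NULL, dist = NULL) {
  stopifnot(inherits(mesh, "cdt_mesh"))
  if (is.null(c)) {
    rmax <- max(apply(mesh$nodes, 2, function(x) diff(range(x))))
    c <- config$delta * rmax
  }
  if (config$constrained) {
    if (is.null(dist)) dist <- landmark_distance_fields(mesh, landmarks, config$use_los)
    cross <- dist$cross
    node_dist <- vapply(dist$fields, function(f) f$distance, numeric(nrow(mesh$nodes)))
    if (any(!is.finite(node_dist)))
      stop("mesh has nodes unreachable from a landmark (disconnected mesh)")
  } else {
    cross <- euclid_cross(landmarks$centres, landmarks$centres)
    node_dist <- euclid_cross(mesh$nodes, landmarks$centres)
  }
  model <- fit_rbf(landmarks, cross, kind = config$kind, c = c)
  model$delta <- config$delta
  disp <- evaluate_rbf(model, mesh$nodes, node_dist)
  structure(list(mesh = mesh, displacement = disp, model = model,
                 landmarks = landmarks, config = config),
            class = "cdt_warp")
}

#' @export
print.cdt_warp <- function(x, ...) {
  mag <- sqrt(rowSums(x$displacement^2))
  cat(sprintf("<cdt_warp> %d nodes, |u| in [%.4g, %.4g], basis %s\n",
              nrow(x$displacement), min(mag), max(mag), x$model$kind))
  invisible(x)
}

#' Pull-back resampling (mesh on the target)
#'
#' Defines the output on the footprint of the warp mesh (rasterised on
#' `grid`): each covered cell interpolates the nodal displacement
#' barycentrically, samples the source at the displaced position, and is
#' flagged unmapped (and filled) when that position leaves the source raster.
#' The output domain equals the mesh footprint whatever the source content —
#' registration and foreground segmentation in a single operation.
#'
#' @param source a [cdt_image] with values.
#' @param warp a `cdt_warp` whose mesh conforms to the target domain and whose
#'   displacements map target positions into source space.
#' @param grid a [cdt_domain] supplying the output raster geometry (e.g. the
#'   atlas domain).
#' @param config a [cdt_config] (interpolation and fill).
#' @return list with `image` (a [cdt_image] on the footprint domain) and
#'   `unmapped` (logical array).
#' @export
pullback_resample <- function(source, warp, grid, config = cdt_config()) {
  stopifnot(inherits(source, "cdt_image"), inherits(warp, "cdt_warp"),
            inherits(grid, "cdt_domain"))
  if (is.null(source$values)) stop("source image has no value table")
  res <- cpp_pullback(warp$mesh$nodes, warp$mesh$elements, warp$displacement,
                      dim(grid$mask), grid$origin, grid$spacing,
                      as.numeric(source$values), dim(source$values),
                      source$domain$origin, source$domain$spacing,
                      if (config$interp == "nearest") 0L else 1L,
                      config$fill, TRUE)
  mask <- array(res$mask, dim = dim(grid$mask))
  vals <- array(res$values, dim = dim(grid$mask))
  vals[!mask] <- config$fill
  dom <- cdt_domain(mask, grid$origin, grid$spacing)
  list(image = cdt_image(dom, vals),
       unmapped = array(res$unmapped, dim = dim(grid$mask)))
}

#' Forward transform (mesh on the source)
#'
#' Displaces the mesh nodes, rasterises each displaced element by scanline,
#' and for every covered output cell inverts barycentrically to source
#' coordinates and samples there. Overlapping displaced elements (fold-over:
#' one-to-many mappings are permitted) resolve deterministically by
#' last-written-wins in ascending element order. Degenerate (zero measure)
#' displaced elements are skipped and counted.
#'
#' @param source a [cdt_image] with values; the warp mesh conforms to its
#'   domain.
#' @param warp a `cdt_warp`.
#' @param config a [cdt_config].
#' @param grid optional [cdt_domain] for the output geometry; default covers
#'   the displaced mesh at the source spacing.
#' @return list with `image`, `unmapped` and `degenerate` (skipped element
#'   count).
#' @export
forward_transform <- function(source, warp, config = cdt_config(), grid = NULL) {
  stopifnot(inherits(source, "cdt_image"), inherits(warp, "cdt_warp"))
  if (is.null(source$values)) stop("source image has no value table")
  mesh <- warp$mesh
  if (is.null(grid)) {
    disp_nodes <- mesh$nodes + warp$displacement
    sp <- source$domain$spacing
    lo <- apply(disp_nodes, 2, min) - sp
    hi <- apply(disp_nodes, 2, max) + sp
    n <- pmax(2L, as.integer(ceiling((hi - lo) / sp)) + 1L)
    grid <- cdt_domain(array(TRUE, dim = n), origin = lo, spacing = sp)
  }
  res <- cpp_forward(mesh$nodes, mesh$elements, warp$displacement,
                     dim(grid$mask), grid$origin, grid$spacing,
                     as.numeric(source$values), dim(source$values),
                     source$domain$origin, source$domain$spacing,
                     if (config$interp == "nearest") 0L else 1L,
                     config$fill, TRUE)
  mask <- array(res$mask, dim = dim(grid$mask))
  if (!any(mask)) stop("forward transform produced an empty support")
  vals <- array(res$values, dim = dim(grid$mask))
  vals[!mask] <- config$fill
  dom <- cdt_domain(mask, grid$origin, grid$spacing)
  if (res$degenerate > 0)
    warning(res$degenerate, " degenerate displaced element(s) skipped")
  list(image = cdt_image(dom, vals),
       unmapped = array(res$unmapped, dim = dim(grid$mask)),
       degenerate = res$degenerate)
}

#' End-to-end constrained registration to an atlas domain
#'
#' Driver composing the CDT pipeline: displacements `source - target` at the
#' target-space landmark centres, per-landmark geodesic distance fields,
#' RBF warp over the atlas mesh, pull-back resampling of the source onto the
#' atlas grid.
#'
#' @param source a [cdt_image] (the assay image).
#' @param atlas_domain a [cdt_domain]; the mesh conforms to it and the output
#'   is rasterised on its grid.
#' @param mesh a [cdt_mesh] over the atlas domain.
#' @param pairs a [cdt_landmarks] (see [landmarks_from_pairs()]) or a matrix
#'   of `tx ty [tz] sx sy [sz]` rows.
#' @param config a [cdt_config].
#' @return list with `image`, `unmapped`, `warp`, and `report` (landmark
#'   residuals, unmapped voxel count, node/element counts, stage timings).
#' @export
register <- function(source, atlas_domain, mesh, pairs, config = cdt_config()) {
  stopifnot(inherits(source, "cdt_image"), inherits(atlas_domain, "cdt_domain"),
            inherits(mesh, "cdt_mesh"))
  if (!inherits(pairs, "cdt_landmarks")) {
    pairs <- as.matrix(pairs)
    d <- ncol(pairs) / 2
    pairs <- landmarks_from_pairs(pairs[, 1:d, drop = FALSE],
                                  pairs[, (d + 1):(2 * d), drop = FALSE])
  }
  t0 <- proc.time()[["elapsed"]]
  dist <- if (config$constrained) {
    landmark_distance_fields(mesh, pairs, config$use_los)
  } else {
    NULL
  }
  t1 <- proc.time()[["elapsed"]]
  c_par <- compute_c(config$delta, atlas_domain)
  warp <- build_warp(mesh, pairs, config, c = c_par, dist = dist)
  t2 <- proc.time()[["elapsed"]]
  out <- pullback_resample(source, warp, atlas_domain, config)
  t3 <- proc.time()[["elapsed"]]
  cross <- if (config$constrained) dist$cross else euclid_cross(pairs$centres, pairs$centres)
  resid <- evaluate_rbf(warp$model, pairs$centres, cross) - pairs$displacements
  report <- list(
    landmark_residual_max = max(abs(resid)),
    unmapped_voxels = sum(out$unmapped),
    mapped_voxels = sum(out$image$domain$mask),
    nodes = nrow(mesh$nodes), elements = nrow(mesh$elements),
    basis = config$kind, delta = config$delta, c = c_par,
    constrained = config$constrained,
    timings = list(distance_fields = t1 - t0, warp = t2 - t1, resample = t3 - t2))
  list(image = out$image, unmapped = out$unmapped, warp = warp, report = report)
}
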