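#' Landmark correspondence set
#'
#' Landmark centres with per-landmark displacement vectors. For registration
#' with the mesh on the target (atlas), centres are the target points and
#' displacements are `source - target`, so that adding the interpolated
#' displacement to a target-space position yields the corresponding
#' source-space position.
#'
#' @param centres N x dim matrix of landmark centres.
#' @param displacements N x dim matrix of displacement vectors.
#' @param source,target optional N x dim matrices recording the point pairs
#'   the displacements were derived from.
#' @return An object of class `cdt_landmarks`.
#' @export
cdt_landmarks <- function(centres, displacements, source = NULL, target = NULL) {
  centres <- as.matrix(centres)
  displacements <- as.matrix(displacements)
  storage.mode(centres) <- storage.mode(displacements) <- "double"
  d <- ncol(centres)
  if (!d %in% c(2L, 3L)) stop("landmarks must be 2D or 3D")
  if (!identical(dim(centres), dim(displacements)))
    stop("displacement dimensionality must match the centres")
  if (nrow(centres) < d + 1)
    stop("need at least dim+1 landmarks for the first-order polynomial block")
  ext <- max(apply(centres, 2, function(x) diff(range(x))), 0)
  dd <- as.matrix(stats::dist(centres))
  diag(dd) <- Inf
  if (min(dd) <= 1e-9 * max(ext, 1))
    stop("two landmark centres coincide (closer than 1e-9 of the extent)")
  structure(list(centres = centres, displacements = displacements,
                 source = source, target = target, n = nrow(centres), dim = d),
            class = "cdt_landmarks")
}

#' Build landmarks from point pairs
#' @param target,source N x dim matrices of corresponding points.
#' @return A [cdt_landmarks] with centres at the target points and
#'   displacements `source - target`.
#' @export
landmarks_from_pairs <- function(target, source) {
  target <- as.matrix(target)
  source <- as.matrix(source)
  cdt_landmarks(target, source - target, source = source, target = target)
}

#' @export
print.cdt_landmarks <- function(x, ...) {
  cat(sprintf("<cdt_landmarks> %d landmarks, %dD, mean |displacement| %.4g\n",
              x$n, x$dim, mean(sqrt(rowSums(x$displacements^2)))))
  invisible(x)
}

#' Read / write landmark pairs as TSV
#'
#' Column layout: target coordinates then source coordinates
#' (`tx ty [tz] sx sy [sz]`), one header line, world units.
#'
#' @param path TSV path.
#' @return A [cdt_landmarks].
#' @export
read_landmarks <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  nc <- ncol(tab)
  if (!nc %in% c(4L, 6L)) stop("landmark TSV must have 4 (2D) or 6 (3D) columns")
  d <- nc / 2L
  landmarks_from_pairs(as.matrix(tab[, 1:d]), as.matrix(tab[, (d + 1):nc]))
}

#' @rdname read_landmarks
#' @param lm a [cdt_landmarks] with pair provenance (or displacements, from
#'   which source points are reconstructed).
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "cdt_landmarks"))
  target <- if (!is.null(lm$target)) lm$target else lm$centres
  source <- if (!is.null(lm$source)) lm$source else lm$centres + lm$displacements
  d <- lm$dim
  cols <- if (d == 2) c("tx", "ty", "sx", "sy") else c("tx", "ty", "tz", "sx", "sy", "sz")
  tab <- data.frame(cbind(target, source))
  names(tab) <- cols
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Radial basis functions
#'
#' Evaluates the basis kinds used for displacement interpolation: thin plate
#' spline `r^2 log r` (0 at r = 0), multiquadric `sqrt(r^2 + c^2)`, inverse
#' multiquadric `1/sqrt(r^2 + c^2)` and Wendland's compactly supported
#' `(1 - r/c)^4 (4 r/c + 1)` for `r <= c` (0 beyond), the C2-smooth member
#' positive definite in both 2D and 3D.
#'
#' @param kind one of `"tps"`, `"mq"`, `"imq"`, `"wendland"`.
#' @param r nonnegative distances.
#' @param c support/shape parameter (ignored by `tps`; for `wendland` the
#'   support radius).
#' @return basis values, same length as `r`.
#' @export
basis_eval <- function(kind = c("tps", "mq", "imq", "wendland"), r, c = NULL) {
  kind <- match.arg(kind)
  if (any(r < 0)) stop("negative distance")
  if (kind != "tps") {
    if (is.null(c) || !is.finite(c) || c <= 0) stop("basis kind '", kind, "' requires c > 0")
  }
  switch(kind,
    tps = ifelse(r > 0, r^2 * log(r), 0),
    mq = sqrt(r^2 + c^2),
    imq = 1 / sqrt(r^2 + c^2),
    wendland = {
      s <- r / c
      ifelse(s <= 1, (1 - s)^4 * (4 * s + 1), 0)
    })
}

#' Basis support parameter from the domain extent
#'
#' `c = delta * r_max`, with `r_max` the maximum axis extent of the domain
#' (see [bounding_box()]). `delta` balances deformation accuracy against
#' smoothness; its useful range is about 0.001 to 0.5 (a warning is issued
#' outside it).
#'
#' @param delta dimensionless shape factor in (0, 1].
#' @param domain a [cdt_domain].
#' @return c, in world units.
#' @export
compute_c <- function(delta, domain) {
  if (!is.finite(delta) || delta <= 0 || delta > 1) stop("delta must be in (0, 1]")
  if (delta < 0.001 || delta > 0.5)
    warning("delta outside the useful range [0.001, 0.5]")
  rmax <- bounding_box(domain)$r_max
  if (rmax <= 0) stop("degenerate domain: r_max is zero")
  delta * rmax
}

#' Fit a radial basis function displacement model
#'
#' Solves the block design system
#' \deqn{\begin{pmatrix} 0 & X \\ X^T & R \end{pmatrix}
#'       \begin{pmatrix} a \\ \lambda \end{pmatrix} =
#'       \begin{pmatrix} 0 \\ D \end{pmatrix}}
#' per displacement component, where `R` holds basis values at centre-centre
#' distances and `X` the first-order polynomial block (rows `1, x_i`).
#' Coordinates (and distances, isotropically) are rescaled to the unit box
#' before solving to reduce the condition number; the system is solved by SVD
#' with a relative singular-value cutoff of 1e-12, one factorisation shared
#' across the displacement components. The zero upper block enforces the side
#' conditions `sum(lambda) = 0` and `sum(lambda * x) = 0`.
#'
#' @param landmarks a [cdt_landmarks].
#' @param pairwise_dist N x N matrix of centre-centre distances (Euclidean or
#'   geodesic); symmetrised as `(M + t(M))/2` before use, zero diagonal.
#' @param kind basis kind, see [basis_eval()].
#' @param c basis parameter in world units (see [compute_c()]); ignored by tps.
#' @return An object of class `cdt_rbf` with coefficients `lambda` (N x dim),
#'   `a` ((dim+1) x dim) and the rescaling applied.
#' @export
fit_rbf <- function(landmarks, pairwise_dist, kind = c("tps", "mq", "imq", "wendland"),
                    c = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(landmarks, "cdt_landmarks"))
  n <- landmarks$n
  d <- landmarks$dim
  pd <- as.matrix(pairwise_dist)
  if (!identical(dim(pd), c(n, n))) stop("pairwise_dist must be N x N")
  if (any(!is.finite(pd))) stop("non-finite centre-centre distance")
  pd <- (pd + t(pd)) / 2
  diag(pd) <- 0
  shift <- apply(landmarks$centres, 2, min)
  scale <- max(apply(landmarks$centres, 2, function(x) diff(range(x))))
  if (scale <= 0) stop("landmark centres are coincident along every axis")
  xs <- sweep(landmarks$centres, 2, shift) / scale
  cs <- if (is.null(c)) NULL else c / scale
  R <- matrix(basis_eval(kind, pd / scale, cs), n, n)
  X <- rbind(1, t(xs))                       # (d+1) x N
  p <- d + 1L
  A <- rbind(cbind(matrix(0, p, p), X), cbind(t(X), R))
  B <- rbind(matrix(0, p, d), landmarks$displacements)
  sv <- svd(A)
  cutoff <- 1e-12 * max(sv$d)
  if (any(sv$d < cutoff)) {
    stop(sprintf(paste0("design matrix is rank deficient after the SVD cutoff ",
                        "(smallest/largest singular value = %.3g): collinear or ",
                        "coplanar centres with this basis?"), min(sv$d) / max(sv$d)))
  }
  sol <- sv$v %*% ((t(sv$u) %*% B) / sv$d)
  a <- sol[seq_len(p), , drop = FALSE]
  lambda <- sol[-seq_len(p), , drop = FALSE]
  structure(list(kind = kind, c = c, delta = NULL, centres = landmarks$centres,
                 lambda = lambda, a = a,
                 rescale = list(shift = shift, scale = scale), dim = d),
            class = "cdt_rbf")
}

#' Evaluate an RBF displacement model
#'
#' `Delta u_j(x) = P_j(x) + sum_i lambda[i, j] * f(dist(x, x_i))`. The
#' polynomial term always uses the query point's coordinates; the basis term
#' uses the supplied distances, which may be Euclidean or geodesic.
#'
#' @param model a `cdt_rbf`.
#' @param points M x dim matrix of query coordinates.
#' @param dist_to_centres M x N matrix of distances from each query point to
#'   each model centre (columns in model-centre order). Defaults to Euclidean
#'   distances.
#' @return M x dim matrix of displacement vectors.
#' @export
evaluate_rbf <- function(model, points, dist_to_centres = NULL) {
  stopifnot(inherits(model, "cdt_rbf"))
  points <- matrix(as.numeric(points), ncol = model$dim)
  n <- nrow(model$centres)
  if (is.null(dist_to_centres)) {
    dist_to_centres <- euclid_cross(points, model$centres)
  }
  dist_to_centres <- as.matrix(dist_to_centres)
  if (nrow(dist_to_centres) != nrow(points) || ncol(dist_to_centres) != n)
    stop("dist_to_centres must be M x N with columns in model-centre order")
  if (any(dist_to_centres < 0)) stop("negative distance")
  sc <- model$rescale$scale
  cs <- if (is.null(model$c)) NULL else model$c / sc
  Phi <- matrix(basis_eval(model$kind, dist_to_centres / sc, cs),
                nrow(points), n)
  xs <- sweep(points, 2, model$rescale$shift) / sc
  cbind(1, xs) %*% model$a + Phi %*% model$lambda
}

euclid_cross <- function(a, b) {
  # M x N Euclidean distances without forming huge intermediates
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Serialise / restore an RBF model (JSON text)
#' @param model a `cdt_rbf`.
#' @param path file path.
#' @export
write_rbf_model <- function(model, path) {
  stopifnot(inherits(model, "cdt_rbf"))
  obj <- list(kind = model$kind, c = model$c, delta = model$delta,
              dim = model$dim, centres = model$centres, lambda = model$lambda,
              a = model$a, rescale = model$rescale)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rbf_model
#' @export
read_rbf_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(kind = o$kind, c = o$c, delta = o$delta,
                 centres = as.matrix(o$centres), lambda = as.matrix(o$lambda),
                 a = as.matrix(o$a),
                 rescale = list(shift = as.numeric(o$rescale$shift),
                                scale = as.numeric(o$rescale$scale)),
                 dim = as.integer(o$dim)),
            class = "cdt_rbf")
}
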