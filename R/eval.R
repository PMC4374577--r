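#' Distance-error table on a corridor fixture
#'
#' Runs the requested distance algorithms from one seed and reports the mean
#' and standard deviation of the percent error against the analytic corridor
#' geodesic: mesh algorithms are probed at all mesh nodes except the seed,
#' raster algorithms at all mask cells except the seed cell.
#'
#' @param fixture list with `domain` and `oracle`, from [make_corridor_domain()].
#' @param mesh a [cdt_mesh] over the fixture domain.
#' @param seed world point inside the domain and mesh.
#' @param algorithms subset of `"mesh"`, `"mesh_nlsi"` and the raster
#'   connectivities valid for the fixture's dimension.
#' @return data.frame with one row per algorithm: `algorithm`, `mean_pct`,
#'   `sd_pct`, `n_probes`, `seconds`.
#' @export
distance_error_table <- function(fixture, mesh, seed,
                                 algorithms = c("mesh", "mesh_nlsi", "c4", "c8", "oct")) {
  domain <- fixture$domain
  oracle <- fixture$oracle
  seed <- as.numeric(seed)
  rows <- list()
  for (alg in algorithms) {
    t0 <- proc.time()[["elapsed"]]
    if (alg %in% c("mesh", "mesh_nlsi")) {
      fld <- geodesic_field(mesh, seed, use_los = (alg == "mesh"))
      exact <- analytic_distance(oracle, mesh$nodes, seed)
      keep <- exact > 1e-9 & is.finite(fld$distance)
      st <- error_stats(fld$distance[keep], exact[keep])
    } else {
      sidx <- as.integer(round(world_to_index(domain, matrix(seed, 1))))
      fld <- raster_geodesic(domain, sidx, alg)
      centres <- index_to_world(domain, which(domain$mask, arr.ind = TRUE))
      exact <- analytic_distance(oracle, centres, seed)
      got <- fld$values[domain$mask]
      keep <- exact > 1e-9 & is.finite(got)
      st <- error_stats(got[keep], exact[keep])
    }
    rows[[alg]] <- data.frame(algorithm = alg, mean_pct = st$mean, sd_pct = st$sd,
                              n_probes = length(st$percent),
                              seconds = proc.time()[["elapsed"]] - t0)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Evaluate an RBF model at many points in fixed-size chunks (keeps the
# point-to-centre distance matrix small).
evaluate_rbf_chunked <- function(model, points, chunk = 200000L) {
  n <- nrow(points)
  out <- matrix(0, n, model$dim)
  s <- 1L
  while (s <= n) {
    e <- min(n, s + chunk - 1L)
    out[s:e, ] <- evaluate_rbf(model, points[s:e, , drop = FALSE])
    s <- e + 1L
  }
  out
}

#' Mesh-resolution displacement-error study
#'
#' Quantifies the error of approximating an RBF displacement field by linear
#' interpolation over a conforming mesh. For each requested resolution a
#' tetrahedral mesh of the 3D corridor fixture is built; a fixed set of random
#' landmarks (displacements drawn uniformly in a ball of radius
#' `0.1 * r_max`) defines an RBF warp (Euclidean distances, so it can be
#' evaluated anywhere); at every element centroid the directly evaluated
#' displacement is compared with the barycentric interpolation from the
#' element nodes. The per-centroid error is
#' `eps = (l_RBF - l_MESH) / l_RBF` (difference of displacement lengths over
#' the direct length); the normalised length of the error vector
#' `|u_RBF - u_MESH| / l_RBF` is reported alongside. The summary correlates
#' mean `eps` with `N^(-1/3)` across resolutions (Pearson).
#'
#' @param spec3d list with `domain` from [make_corridor_domain()] (3D).
#' @param landmark_count number of random landmarks.
#' @param delta basis support factor.
#' @param kind basis kind.
#' @param resolutions target node counts (at least 4, ideally spanning two
#'   orders of magnitude).
#' @param seed RNG seed for landmark placement and displacements.
#' @return list with `rows` (data.frame: `N`, `inv_cbrt_N`, `l_rbf_mean`,
#'   `l_rbf_sd`, `l_mesh_mean`, `l_mesh_sd`, `eps_mean`, `eps_sd`,
#'   `eps_vec_mean`, `eps_vec_sd`) and `correlation` (Pearson, mean eps vs
#'   `N^(-1/3)`).
#' @export
displacement_error_study <- function(spec3d, landmark_count = 75, delta = 0.05,
                                     kind = "imq", resolutions = c(8e3, 2.7e4, 9e4, 3e5, 1e6),
                                     seed = 1L) {
  domain <- spec3d$domain
  if (domain$dim != 3) stop("the displacement-error study runs on a 3D fixture")
  if (length(resolutions) < 4) stop("need at least 4 resolutions")
  set.seed(seed)
  bb <- bounding_box(domain)
  rmax <- bb$r_max
  cells <- which(domain$mask)
  pick <- sample(cells, landmark_count)
  centres <- index_to_world(domain, arrayInd(pick, dim(domain$mask)))
  # displacements uniform in the ball of radius 0.1 * r_max
  dirs <- matrix(stats::rnorm(3 * landmark_count), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rad <- 0.1 * rmax * stats::runif(landmark_count)^(1 / 3)
  lm <- cdt_landmarks(centres, dirs * rad)
  cfg <- cdt_config(kind = kind, delta = delta, constrained = FALSE)
  c_par <- delta * rmax
  vol <- sum(domain$mask) * prod(domain$spacing)
  rows <- vector("list", length(resolutions))
  for (i in seq_along(resolutions)) {
    # lattice nodes track cells/h^3 plus a boundary band; the 0.6 factor
    # calibrates the request to the node count actually produced
    h <- (vol / (0.6 * resolutions[i]))^(1 / 3)
    mesh <- generate_mesh_3d(domain, h)
    warp <- build_warp(mesh, lm, cfg, c = c_par)
    el <- mesh$elements
    cent <- (mesh$nodes[el[, 1], ] + mesh$nodes[el[, 2], ] +
             mesh$nodes[el[, 3], ] + mesh$nodes[el[, 4], ]) / 4
    direct <- evaluate_rbf_chunked(warp$model, cent)
    interp <- (warp$displacement[el[, 1], ] + warp$displacement[el[, 2], ] +
               warp$displacement[el[, 3], ] + warp$displacement[el[, 4], ]) / 4
    l_rbf <- sqrt(rowSums(direct^2))
    l_mesh <- sqrt(rowSums(interp^2))
    ok <- l_rbf > 0
    eps <- (l_rbf[ok] - l_mesh[ok]) / l_rbf[ok]
    eps_vec <- sqrt(rowSums((direct - interp)^2))[ok] / l_rbf[ok]
    rows[[i]] <- data.frame(
      N = nrow(mesh$nodes), inv_cbrt_N = nrow(mesh$nodes)^(-1 / 3),
      l_rbf_mean = mean(l_rbf), l_rbf_sd = stats::sd(l_rbf),
      l_mesh_mean = mean(l_mesh), l_mesh_sd = stats::sd(l_mesh),
      eps_mean = mean(eps), eps_sd = stats::sd(eps),
      eps_vec_mean = mean(eps_vec), eps_vec_sd = stats::sd(eps_vec))
    rm(mesh, warp, cent, direct, interp)
  }
  rows <- do.call(rbind, rows)
  list(rows = rows,
       correlation = stats::cor(rows$eps_mean, rows$inv_cbrt_N),
       correlation_vec = stats::cor(rows$eps_vec_mean, rows$inv_cbrt_N))
}
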