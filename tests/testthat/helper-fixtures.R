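# Shared fixture builders (all generated in code; nothing on disk).

# Two-triangle unit square mesh.
unit_square_mesh <- function() {
  cdt_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
           rbind(c(1, 2, 3), c(1, 3, 4)))
}

# Full-raster rectangular domain.
full_domain <- function(dims, spacing = rep(1, length(dims))) {
  cdt_domain(array(TRUE, dim = dims), spacing = spacing)
}

# Straight triangulated strip of `n` square cells, unit height.
strip_mesh <- function(n = 20, len = 20) {
  dx <- len / n
  nodes <- rbind(cbind(seq(0, len, dx), 0), cbind(seq(0, len, dx), 1))
  k <- n + 1
  el <- NULL
  for (i in seq_len(n)) {
    el <- rbind(el, c(i, i + 1, k + i), c(i + 1, k + i + 1, k + i))
  }
  cdt_mesh(nodes, el)
}

# Grid-graph Dijkstra over the mask (8- or 26-connected), independent oracle.
grid_dijkstra <- function(domain, seed_index) {
  skip_if_not_installed("igraph")
  mask <- domain$mask
  d <- dim(mask)
  nd <- length(d)
  lin <- array(seq_along(mask), dim = d)
  offs <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  edges <- NULL
  w <- NULL
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2, offs[r, ], "+")
    ok <- rep(TRUE, nrow(nb))
    for (i in seq_len(nd)) ok <- ok & nb[, i] >= 1 & nb[, i] <= d[i]
    a <- lin[idx[ok, , drop = FALSE]]
    b <- lin[nb[ok, , drop = FALSE]]
    keep <- mask[b] & a < b
    edges <- rbind(edges, cbind(a[keep], b[keep]))
    w <- c(w, rep(sqrt(sum((offs[r, ] * domain$spacing)^2)), sum(keep)))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  s <- lin[matrix(seed_index, 1)]
  res <- as.numeric(igraph::distances(g, v = s, weights = w))
  dd <- rep(Inf, length(mask))
  dd[seq_along(res)] <- res
  dd
}
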