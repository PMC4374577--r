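#' Export a mesh to Gmsh (.msh v2 ASCII), VTK legacy ASCII or OFF
#'
#' Coordinates are written with 17 significant digits so that an
#' export/import round trip preserves them to better than 1e-12. OFF output is
#' available for 2D (planar triangle) meshes only.
#'
#' @param mesh a [cdt_mesh].
#' @param path output path; format chosen by extension (`.msh`, `.vtk`, `.off`).
#' @export
export_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "cdt_mesh"))
  ext <- tolower(sub(".*\\.", "", path))
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elements)
  xyz <- cbind(mesh$nodes, matrix(0, n, 3 - mesh$dim))
  coord <- sprintf("%.17g %.17g %.17g", xyz[, 1], xyz[, 2], xyz[, 3])
  el <- mesh$elements
  if (ext == "msh") {
    type <- if (mesh$dim == 2) 2L else 4L
    lines <- c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$Nodes", as.character(n),
               paste(seq_len(n), coord),
               "$EndNodes", "$Elements", as.character(m),
               paste(seq_len(m), type, 2L, 0L, 0L,
                     apply(el, 1, paste, collapse = " ")),
               "$EndElements")
  } else if (ext == "vtk") {
    ctype <- if (mesh$dim == 2) 5L else 10L
    k <- ncol(el)
    lines <- c("# vtk DataFile Version 3.0", "cdt mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n), coord,
               sprintf("CELLS %d %d", m, m * (k + 1)),
               paste(k, apply(el - 1L, 1, paste, collapse = " ")),
               sprintf("CELL_TYPES %d", m),
               rep(as.character(ctype), m))
  } else if (ext == "off") {
    if (mesh$dim != 2) stop("OFF export is limited to 2D (planar triangle) meshes")
    lines <- c("OFF", sprintf("%d %d 0", n, m), coord,
               paste(3L, apply(el - 1L, 1, paste, collapse = " ")))
  } else {
    stop("unsupported mesh format: .", ext)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Import a simplicial mesh
#'
#' Supports Gmsh .msh (v2 ASCII), VTK legacy ASCII and OFF. Meshes mixing
#' element types, or containing non-simplicial cells (quads, hexahedra, ...),
#' are rejected. Planar meshes (all-zero third coordinate) are returned as 2D.
#'
#' @param path mesh file path.
#' @return A [cdt_mesh].
#' @export
import_mesh <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  lines <- readLines(path, warn = FALSE)
  parsed <- switch(ext,
    msh = parse_msh(lines),
    vtk = parse_vtk(lines),
    off = parse_off(lines),
    stop("unsupported mesh format: .", ext))
  nodes <- parsed$nodes
  el <- parsed$elements
  k <- ncol(el)
  if (k == 3 && all(abs(nodes[, 3]) < 1e-12)) {
    nodes <- nodes[, 1:2, drop = FALSE]
  } else if (k == 3) {
    stop("triangle mesh with non-planar coordinates is not a 2D simplicial mesh")
  }
  cdt_mesh(nodes, el)
}

parse_msh <- function(lines) {
  ni <- which(lines == "$Nodes")
  ei <- which(lines == "$Elements")
  if (!length(ni) || !length(ei)) stop("malformed .msh file")
  n <- as.integer(lines[ni + 1])
  ntab <- do.call(rbind, lapply(strsplit(trimws(lines[ni + 1 + seq_len(n)]), "\\s+"),
                                as.numeric))
  nodes <- matrix(0, n, 3)
  nodes[ntab[, 1], ] <- ntab[, 2:4]
  m <- as.integer(lines[ei + 1])
  etab <- lapply(strsplit(trimws(lines[ei + 1 + seq_len(m)]), "\\s+"), as.integer)
  types <- vapply(etab, `[`, integer(1), 2)
  if (!all(types %in% c(2L, 4L)))
    stop("mesh contains non-simplicial or unsupported element types")
  if (length(unique(types)) > 1) stop("mixed-element meshes are rejected")
  kk <- if (types[1] == 2L) 3L else 4L
  el <- t(vapply(etab, function(r) {
    ntags <- r[3]
    conn <- r[(4 + ntags):(3 + ntags + kk)]
    if (length(r) != 3 + ntags + kk) stop("malformed element record")
    conn
  }, integer(kk)))
  list(nodes = nodes, elements = el)
}

parse_vtk <- function(lines) {
  pi <- grep("^POINTS", lines)[1]
  ci <- grep("^CELLS", lines)[1]
  ti <- grep("^CELL_TYPES", lines)[1]
  if (is.na(pi) || is.na(ci) || is.na(ti)) stop("malformed VTK legacy file")
  n <- as.integer(strsplit(lines[pi], "\\s+")[[1]][2])
  coords <- as.numeric(unlist(strsplit(trimws(lines[(pi + 1):(ci - 1)]), "\\s+")))
  coords <- coords[!is.na(coords)]
  if (length(coords) != 3 * n) stop("malformed VTK POINTS block")
  nodes <- matrix(coords, ncol = 3, byrow = TRUE)
  m <- as.integer(strsplit(lines[ci], "\\s+")[[1]][2])
  ctypes <- as.integer(unlist(strsplit(trimws(lines[(ti + 1):length(lines)]), "\\s+")))
  ctypes <- ctypes[!is.na(ctypes)][seq_len(m)]
  if (!all(ctypes %in% c(5L, 10L)))
    stop("mesh contains non-simplicial or unsupported cell types")
  if (length(unique(ctypes)) > 1) stop("mixed-element meshes are rejected")
  rows <- strsplit(trimws(lines[ci + seq_len(m)]), "\\s+")
  kk <- if (ctypes[1] == 5L) 3L else 4L
  el <- t(vapply(rows, function(r) {
    r <- as.integer(r)
    if (r[1] != kk) stop("mixed-element meshes are rejected")
    r[2:(kk + 1)] + 1L
  }, integer(kk)))
  list(nodes = nodes, elements = el)
}

parse_off <- function(lines) {
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (toupper(trimws(lines[1])) != "OFF") stop("malformed OFF file")
  hdr <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  n <- hdr[1]; m <- hdr[2]
  nodes <- do.call(rbind, lapply(strsplit(trimws(lines[2 + seq_len(n)]), "\\s+"),
                                 as.numeric))[, 1:3, drop = FALSE]
  el <- t(vapply(strsplit(trimws(lines[2 + n + seq_len(m)]), "\\s+"), function(r) {
    r <- as.integer(r)
    if (r[1] != 3L) stop("mesh contains non-simplicial cells (only triangles supported in OFF)")
    r[2:4] + 1L
  }, integer(3)))
  list(nodes = nodes, elements = el)
}
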