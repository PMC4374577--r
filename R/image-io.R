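#' Read an image file into an image object
#'
#' PNG and TIFF files are read as 2D objects (axis 1 = image column, axis 2 =
#' image row, so `values[x, y]`), NIfTI-1 files (`.nii`, `.nii.gz`) as 3D
#' objects with spacing and origin taken from the header. RGB input is
#' collapsed to luminance with Rec. 601 weights unless a single channel is
#' requested. The returned object has a full-raster (all-`TRUE`) domain; use
#' [threshold_segment()] to extract a foreground domain.
#'
#' PNG/TIFF sample values are rescaled to the integer range 0-255 so that
#' integer rasters survive a write/read round trip bit-exactly.
#'
#' @param path file path.
#' @param kind `"auto"` (by extension), `"2d"` or `"3d"`.
#' @param channel for RGB input, `"luminance"` or a channel index.
#' @return A [cdt_image].
#' @export
read_image <- function(path, kind = c("auto", "2d", "3d"), channel = "luminance") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- image_ext(path)
  if (kind == "auto") kind <- if (ext %in% c("nii", "nii.gz")) "3d" else "2d"
  if (kind == "2d") {
    img <- switch(ext,
      png = png::readPNG(path),
      tif = , tiff = tiff::readTIFF(path),
      stop("unsupported 2D image format: .", ext))
    if (length(dim(img)) == 3) {
      if (identical(channel, "luminance")) {
        nch <- dim(img)[3]
        img <- if (nch >= 3) {
          0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
        } else {
          img[, , 1]
        }
      } else {
        img <- img[, , as.integer(channel)]
      }
    }
    vals <- t(img) * 255          # [x, y], 0-255 scale
    r <- round(vals)
    near <- abs(vals - r) < 1e-6
    vals[near] <- r[near]
    dom <- cdt_domain(array(TRUE, dim = dim(vals)))
    return(cdt_image(dom, vals))
  }
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3) stop("unsupported dimensionality: expected a 3D NIfTI volume")
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  dom <- cdt_domain(array(TRUE, dim = dim(a)), origin = origin, spacing = sp)
  cdt_image(dom, array(as.numeric(a), dim = dim(a)))
}

#' Write an image object to file
#'
#' Locations outside the domain are written as `fill`. The format follows the
#' file extension: PNG/TIFF for 2D (values interpreted on the 0-255 scale),
#' NIfTI-1 for 3D (values written as-is, spacing and origin stored in the
#' header). A domain without values is written as a 0/255 (2D) or 0/1 (NIfTI)
#' mask.
#'
#' @param obj a [cdt_image] or [cdt_domain].
#' @param path output path (`.png`, `.tif`/`.tiff`, `.nii`, `.nii.gz`).
#' @param fill scalar written outside the domain.
#' @export
write_image <- function(obj, path, fill = 0) {
  if (inherits(obj, "cdt_domain")) obj <- cdt_image(obj)
  stopifnot(inherits(obj, "cdt_image"))
  ext <- image_ext(path)
  dom <- obj$domain
  vals <- obj$values
  if (is.null(vals)) {
    vals <- array(0, dim = dim(dom$mask))
    vals[dom$mask] <- if (ext %in% c("nii", "nii.gz")) 1 else 255
  } else {
    vals[!dom$mask] <- fill
  }
  if (ext %in% c("png", "tif", "tiff")) {
    if (dom$dim != 2) stop("PNG/TIFF output requires a 2D object")
    img <- t(vals) / 255
    img[img < 0] <- 0
    img[img > 1] <- 1
    if (ext == "png") png::writePNG(img, path) else tiff::writeTIFF(img, path)
  } else if (ext %in% c("nii", "nii.gz")) {
    if (dom$dim != 3) stop("NIfTI output requires a 3D object")
    img <- RNifti::asNifti(vals)
    m <- diag(c(dom$spacing, 1))
    m[1:3, 4] <- dom$origin
    img <- RNifti::`qform<-`(img, structure(m, code = 2L))
    img <- RNifti::`pixdim<-`(img, dom$spacing)
    RNifti::writeNifti(img, path)
  } else {
    stop("unsupported image format: .", ext)
  }
  invisible(path)
}

image_ext <- function(path) {
  if (grepl("\\.nii\\.gz$", path, ignore.case = TRUE)) return("nii.gz")
  tolower(sub(".*\\.", "", path))
}

#' Read a mask image as a domain
#'
#' Nonzero sample values become foreground.
#' @param path image path.
#' @return A [cdt_domain].
#' @export
read_mask <- function(path) {
  obj <- read_image(path)
  threshold_segment(obj, low = .Machine$double.eps)
}
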