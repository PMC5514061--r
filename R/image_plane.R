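#' Image planes with physical (micron) metadata
#'
#' An `image_plane` couples a pixel array with its microns-per-pixel (mpp)
#' resolution and the level-0 pixel offset of its top-left corner, so that
#' pixel coordinates convert unambiguously to physical micron coordinates.
#' Pixel coordinates are 0-based, (x, y) with x rightward and y downward;
#' a pixel index refers to the pixel center. The array is stored
#' `[row = y, col = x(, channel)]` with intensities in 0-255.
#'
#' @param pixels 2-D (grey) or 3-D (RGB) numeric array, values 0-255.
#' @param mpp microns per pixel (isotropic, > 0).
#' @param origin_offset (x, y) offset of this plane's top-left corner, in
#'   level-0 pixels.
#' @param mpp0 microns per pixel at level 0 (defaults to `mpp` for
#'   non-pyramidal images).
#' @return an object of class `image_plane`.
#' @export
image_plane <- function(pixels, mpp, origin_offset = c(0, 0), mpp0 = mpp) {
  stopifnot(is.numeric(pixels), length(dim(pixels)) %in% c(2L, 3L),
            is.numeric(mpp), length(mpp) == 1L, mpp > 0,
            length(origin_offset) == 2L, mpp0 > 0)
  d <- dim(pixels)
  stopifnot(d[1] >= 1L, d[2] >= 1L)
  structure(list(pixels = pixels, mpp = as.numeric(mpp),
                 origin_offset = as.numeric(origin_offset),
                 mpp0 = as.numeric(mpp0)),
            class = "image_plane")
}

#' @export
print.image_plane <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("image_plane: %d x %d px%s, mpp %.4g um/px, origin (%g, %g) level-0 px\n",
              d[2], d[1], if (length(d) == 3L) sprintf(" x %d ch", d[3]) else "",
              x$mpp, x$origin_offset[1], x$origin_offset[2]))
  invisible(x)
}

plane_width <- function(plane) dim(plane$pixels)[2]
plane_height <- function(plane) dim(plane$pixels)[1]

#' Convert between pixel and micron coordinates of a plane
#'
#' @param plane an [image_plane()].
#' @param px n x 2 matrix of 0-based (x, y) pixel coordinates.
#' @return n x 2 matrix of micron coordinates.
#' @export
px_to_um <- function(plane, px) {
  p <- as_points(px)
  sweep(p * plane$mpp, 2L, plane$origin_offset * plane$mpp0, "+")
}

#' @rdname px_to_um
#' @param um n x 2 matrix of micron coordinates.
#' @export
um_to_px <- function(plane, um) {
  p <- as_points(um)
  sweep(p, 2L, plane$origin_offset * plane$mpp0) / plane$mpp
}

#' Convert an RGB plane to grey luminance
#'
#' Rec. 601 luminance weights; grey planes pass through.
#' @param plane an [image_plane()].
#' @return matrix of luminance values in 0-255.
#' @export
plane_grey <- function(plane) {
  px <- plane$pixels
  if (length(dim(px)) == 2L) return(px)
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

sidecar_path <- function(path) {
  cand <- sub("\\.[A-Za-z0-9]+$", ".json", path)
  if (identical(cand, path) || !file.exists(cand)) cand <- paste0(path, ".json")
  cand
}

#' Read an image file as an `image_plane`
#'
#' Reads PNG or TIFF images. Resolution metadata is taken from a JSON sidecar
#' (`<stem>.json` or `<path>.json`, with an `"mpp"` entry) or from the `mpp`
#' argument; it is an error if neither is present. If `level_or_mpp` requests
#' a coarser resolution than the native one, the image is downsampled
#' (bilinear) to that mpp.
#'
#' @param path image file (.png, .tif/.tiff).
#' @param level_or_mpp requested microns-per-pixel, or `NULL` for native.
#' @param mpp native mpp override when no sidecar metadata exists.
#' @return an [image_plane()] with RGB channel order (R, G, B).
#' @export
read_plane <- function(path, level_or_mpp = NULL, mpp = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext)
  )
  px <- px * 255
  if (length(dim(px)) == 3L && dim(px)[3] > 3L) px <- px[, , 1:3]  # drop alpha
  native_mpp <- mpp
  sc <- sidecar_path(path)
  if (is.null(native_mpp)) {
    if (!file.exists(sc)) {
      stop("no resolution metadata for ", path,
           ": supply mpp= or provide a JSON sidecar with an \"mpp\" entry")
    }
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(meta$mpp)) stop("sidecar ", sc, " lacks an \"mpp\" entry")
    native_mpp <- as.numeric(meta$mpp)
  }
  plane <- image_plane(px, mpp = native_mpp)
  if (!is.null(level_or_mpp) && level_or_mpp > native_mpp * (1 + 1e-9)) {
    plane <- downsample_plane(plane, level_or_mpp)
  }
  plane
}

#' Downsample a plane to a coarser resolution
#' @param plane an [image_plane()].
#' @param target_mpp requested mpp (>= the plane's own).
#' @export
downsample_plane <- function(plane, target_mpp) {
  stopifnot(target_mpp >= plane$mpp)
  f <- plane$mpp / target_mpp
  h <- max(1L, round(plane_height(plane) * f))
  w <- max(1L, round(plane_width(plane) * f))
  px <- plane$pixels
  if (length(dim(px)) == 2L) {
    out <- resize_bilinear(px, h, w)
  } else {
    out <- array(0, dim = c(h, w, dim(px)[3]))
    for (k in seq_len(dim(px)[3])) out[, , k] <- resize_bilinear(px[, , k], h, w)
  }
  image_plane(out, mpp = plane$mpp * plane_height(plane) / h,
              origin_offset = plane$origin_offset, mpp0 = plane$mpp0)
}

# bilinear resize of a matrix to h x w
resize_bilinear <- function(m, h, w) {
  sy <- nrow(m) / h
  sx <- ncol(m) / w
  yi <- (seq_len(h) - 0.5) * sy - 0.5
  xi <- (seq_len(w) - 0.5) * sx - 0.5
  bilinear_sample(m, matrix(rep(xi, each = h), h, w),
                  matrix(rep(yi, times = w), h, w), fill = NA_real_, clamp = TRUE)
}

# Sample matrix m at fractional 0-based (x, y) coordinates. Out-of-range
# coordinates give `fill` unless clamp = TRUE (edge clamping).
bilinear_sample <- function(m, x, y, fill = 255, clamp = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  if (clamp) {
    x <- pmin(pmax(x, 0), nc - 1)
    y <- pmin(pmax(y, 0), nr - 1)
  }
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;  fy <- y - y0
  x0i <- pmin(pmax(x0, 0), nc - 1); x1i <- pmin(x0i + 1, nc - 1)
  y0i <- pmin(pmax(y0, 0), nr - 1); y1i <- pmin(y0i + 1, nr - 1)
  idx <- function(yy, xx) m[cbind(as.vector(yy) + 1, as.vector(xx) + 1)]
  v <- (1 - fx) * (1 - fy) * idx(y0i, x0i) + fx * (1 - fy) * idx(y0i, x1i) +
       (1 - fx) * fy       * idx(y1i, x0i) + fx * fy       * idx(y1i, x1i)
  out <- matrix(v, nrow(as.matrix(x)), ncol(as.matrix(x)))
  if (!clamp) {
    bad <- x < 0 | x > nc - 1 | y < 0 | y > nr - 1
    out[bad] <- fill
  }
  out
}

#' Write an `image_plane` to disk with its metadata sidecar
#'
#' @param plane an [image_plane()].
#' @param path output path (.png or .tif); a `<stem>.json` sidecar holding
#'   the mpp is written alongside.
#' @export
write_plane <- function(plane, path) {
  px <- plane$pixels / 255
  px[px < 0] <- 0; px[px > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path),
    stop("unsupported image format: .", ext)
  )
  jsonlite::write_json(list(mpp = plane$mpp), sub("\\.[A-Za-z0-9]+$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Resample a moving image into a reference frame under a rigid transform
#'
#' Renders the moving plane as it appears in the frame geometry after the
#' transform `T` (which maps moving-frame microns into frame microns): output
#' pixel (x, y) samples the moving image at `invert(T)` of its micron
#' position. Out-of-bounds samples are filled with background white (255).
#'
#' @param moving an [image_plane()].
#' @param T a [rigid_transform()] mapping moving coordinates into the frame.
#' @param frame an [image_plane()] (only its geometry is used), or a list
#'   with `width`, `height` (px) and `mpp`.
#' @return an [image_plane()] with the frame's geometry.
#' @export
resample_registered <- function(moving, T, frame) {
  if (inherits(frame, "image_plane")) {
    h <- plane_height(frame); w <- plane_width(frame)
    geo <- image_plane(matrix(0, h, w), frame$mpp, frame$origin_offset, frame$mpp0)
  } else {
    h <- frame$height; w <- frame$width
    geo <- image_plane(matrix(0, h, w), frame$mpp)
  }
  grid <- cbind(rep(seq_len(w) - 1, each = h), rep(seq_len(h) - 1, times = w))
  um <- px_to_um(geo, grid)
  src_um <- apply_transform(invert_transform(T), um)
  src_px <- um_to_px(moving, src_um)
  X <- matrix(src_px[, 1], h, w); Y <- matrix(src_px[, 2], h, w)
  px <- moving$pixels
  if (length(dim(px)) == 2L) {
    out <- bilinear_sample(px, X, Y, fill = 255)
  } else {
    out <- array(0, dim = c(h, w, dim(px)[3]))
    for (k in seq_len(dim(px)[3])) out[, , k] <- bilinear_sample(px[, , k], X, Y, fill = 255)
  }
  image_plane(out, geo$mpp, geo$origin_offset, geo$mpp0)
}
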