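#' Tissue segmentation and boundary extraction
#'
#' Tissue sections are segmented from the glass background by thresholding a
#' local-entropy filter response (empty glass is near-uniform and so has low
#' entropy), cleaned of artefacts with an LBP/SVM window classifier, and each
#' remaining section's external boundary is parametrised into N equally
#' spaced points for registration.
#'
#' @name tissue_segmentation
NULL

# 8-connected labelling: EBImage::bwlabel is 4-connected, so diagonal-only
# adjacencies are merged with a union-find pass.
label8 <- function(mask) {
  L <- EBImage::bwlabel(mask)
  L <- matrix(as.integer(L), nrow(mask), ncol(mask))
  n <- max(L)
  if (n <= 1L) return(L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(L); nc <- ncol(L)
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    dy <- sh[1]; dx <- sh[2]
    ys <- seq_len(nr - 1L)
    if (dx > 0) { xa <- seq_len(nc - 1L); xb <- xa + 1L } else { xa <- 2:nc; xb <- xa - 1L }
    A <- L[ys, xa, drop = FALSE]; B <- L[ys + dy, xb, drop = FALSE]
    pair <- which(A > 0L & B > 0L & A != B)
    if (length(pair)) {
      ab <- unique(cbind(A[pair], B[pair]))
      for (r in seq_len(nrow(ab))) unite(ab[r, 1], ab[r, 2])
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- L
  out[L > 0L] <- relab[L[L > 0L]]
  out
}

disc_kernel <- function(radius) {
  d <- 2L * as.integer(radius) + 1L
  yy <- matrix(rep(-radius:radius, times = d), d, d)
  k <- (yy^2 + t(yy)^2 <= radius^2) * 1
  k / sum(k)
}

#' Tissue mask container
#'
#' @param mask binary matrix (values 0/1), stored `[y, x]`.
#' @param mpp microns per pixel of the mask.
#' @param labels optional precomputed 8-connected label matrix.
#' @return a `tissue_mask`: mask, labels, mpp, and a `regions` data frame
#'   (label, area_px, area_um2).
#' @export
tissue_mask <- function(mask, mpp, labels = NULL) {
  stopifnot(all(mask %in% c(0, 1)), mpp > 0)
  if (is.null(labels)) labels <- label8(mask)
  tab <- tabulate(labels[labels > 0L])
  regions <- data.frame(label = seq_along(tab), area_px = tab,
                        area_um2 = tab * mpp^2)
  structure(list(mask = mask, labels = labels, mpp = mpp, regions = regions),
            class = "tissue_mask")
}

#' Otsu threshold of a 256-bin histogram
#'
#' Exhaustively maximizes the between-class variance over all split levels;
#' returns the level `t` such that the foreground class is `> t` (on the
#' 0-255 bin scale).
#'
#' @param histogram 256 non-negative bin counts for levels 0..255.
#' @return the threshold level (integer in 0..254).
#' @export
otsu_threshold <- function(histogram) {
  stopifnot(length(histogram) == 256L, all(histogram >= 0))
  if (sum(histogram > 0) < 2L) stop("degenerate histogram: fewer than two occupied levels")
  p <- histogram / sum(histogram)
  levels <- 0:255
  omega <- cumsum(p)                  # class-0 mass for t = 0..255
  mu <- cumsum(p * levels)
  mu_total <- mu[256]
  t_all <- 1:255                       # split after level t-1
  w0 <- omega[t_all]; w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  m0 <- mu[t_all] / w0
  m1 <- (mu_total - mu[t_all]) / w1
  sb <- w0 * w1 * (m0 - m1)^2
  sb[!valid] <- -Inf
  # tie-break: midpoint of the maximal plateau (delta-mass histograms give
  # a flat optimum; the midpoint is the conventional choice)
  top <- which(sb >= max(sb) - 1e-12 * abs(max(sb)))
  as.integer(round(mean(t_all[top] - 1L)))
}

#' Entropy-filter tissue segmentation
#'
#' Computes a local-entropy response over a disc window on the grey image,
#' thresholds it by Otsu's method, and removes connected components below a
#' minimum physical area. Empty glass has near-zero entropy and drops out.
#'
#' @param plane an [image_plane()] (grey or RGB).
#' @param window_radius entropy window disc radius in pixels (default 5).
#' @param n_bins grey quantization bins for the local histogram.
#' @param min_area_um2 minimum region area retained, in square microns
#'   (default 0.5 mm^2).
#' @return a [tissue_mask()] at the plane's resolution.
#' @export
entropy_segment <- function(plane, window_radius = 5, n_bins = 32,
                            min_area_um2 = 5e5) {
  stopifnot(window_radius >= 1)
  g <- plane_grey(plane)
  q <- pmin(floor(g / (256 / n_bins)), n_bins - 1)
  k <- disc_kernel(window_radius)
  H <- matrix(0, nrow(g), ncol(g))
  for (b in 0:(n_bins - 1)) {
    ind <- (q == b) * 1
    if (!any(ind > 0)) next
    p <- EBImage::filter2(ind, k, boundary = "replicate")
    p[p < 1e-12] <- 0
    pos <- p > 0
    H[pos] <- H[pos] - p[pos] * log2(p[pos])
  }
  if (max(H) < 1e-6) {
    warning("blank image: entropy response is zero everywhere; returning empty mask")
    return(tissue_mask(matrix(0, nrow(g), ncol(g)), plane$mpp))
  }
  hmax <- log2(n_bins)
  bins <- pmin(floor(H / hmax * 256), 255)
  histo <- tabulate(bins + 1L, nbins = 256L)
  lev <- otsu_threshold(histo)
  mask <- (bins > lev) * 1
  L <- label8(mask)
  if (max(L) > 0L) {
    areas <- tabulate(L[L > 0L])
    small <- which(areas * plane$mpp^2 < min_area_um2)
    if (length(small)) mask[L %in% small] <- 0
  }
  tissue_mask(mask, plane$mpp)
}

# -- LBP texture descriptor -------------------------------------------------

#' Rotation-invariant uniform LBP descriptor of a 64 x 64 window
#'
#' 8-neighbour, radius-1 local binary patterns with the rotation-invariant
#' uniform (riu2) code mapping: uniform patterns map to their bit count
#' (0..8), all non-uniform patterns share code 9. A neighbour counts as
#' "above" the center only when it exceeds it by `tolerance` grey levels,
#' so sensor noise in flat regions does not masquerade as texture; flat
#' windows concentrate on code 0. Returns the normalized 10-bin histogram.
#'
#' @param window numeric 64 x 64 grey matrix (0-255).
#' @param tolerance comparison dead-band in grey levels.
#' @return numeric vector of length 10 summing to 1.
#' @export
lbp_descriptor <- function(window, tolerance = 3) {
  if (!is.matrix(window) || any(dim(window) != c(64L, 64L)))
    stop("LBP window must be exactly 64 x 64")
  h <- nrow(window); w <- ncol(window)
  ctr <- window[2:(h - 1), 2:(w - 1)]
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  bits <- lapply(offs, function(o) {
    window[2:(h - 1) + o[1], 2:(w - 1) + o[2]] >= ctr + tolerance
  })
  s <- Reduce(`+`, bits)
  trans <- Reduce(`+`, lapply(seq_along(bits), function(k) {
    bits[[k]] != bits[[if (k == length(bits)) 1L else k + 1L]]
  }))
  code <- ifelse(trans <= 2L, s, 9L)
  histo <- tabulate(code + 1L, nbins = 10L)
  histo / sum(histo)
}

#' Train the tissue-vs-artefact window classifier
#'
#' Fits an RBF-kernel SVM on LBP descriptors of 64 x 64 grey windows.
#'
#' @param windows list of 64 x 64 grey matrices.
#' @param labels factor or character vector, `"tissue"` / `"artefact"`.
#' @return a fitted `svm` model operating on [lbp_descriptor()] vectors.
#' @export
train_tissue_classifier <- function(windows, labels) {
  X <- t(vapply(windows, lbp_descriptor, numeric(10)))
  e1071::svm(X, factor(labels, levels = c("artefact", "tissue")), kernel = "radial")
}

# windows of a region on the 2x plane: top-left (0-based) pixel coords
region_windows <- function(region_mask2x, win = 64L, min_cover = 0.5) {
  nr <- nrow(region_mask2x); nc <- ncol(region_mask2x)
  ys <- seq(1L, nr - win + 1L, by = win)
  xs <- seq(1L, nc - win + 1L, by = win)
  out <- NULL
  for (y in ys) for (x in xs) {
    block <- region_mask2x[y:(y + win - 1L), x:(x + win - 1L)]
    if (mean(block) >= min_cover) out <- rbind(out, c(x - 1L, y - 1L))
  }
  out
}

#' Remove artefact windows and regions from a tissue mask
#'
#' Classifies 64 x 64 windows of each segmented region on a plane at twice
#' the mask's resolution. Windows rejected by the classifier are zeroed in
#' the mask; a region with strictly more than half of its windows rejected
#' is removed entirely. With `model = NULL` the mask passes through
#' unchanged.
#'
#' @param mask a [tissue_mask()].
#' @param plane an [image_plane()] at half the mask's mpp (twice the
#'   resolution).
#' @param model classifier from [train_tissue_classifier()], or `NULL` for
#'   pass-through.
#' @return a cleaned [tissue_mask()]; output foreground is a subset of the
#'   input foreground.
#' @export
classify_and_clean <- function(mask, plane, model) {
  stopifnot(inherits(mask, "tissue_mask"), inherits(plane, "image_plane"))
  if (is.null(model)) return(mask)
  if (abs(plane$mpp * 2 - mask$mpp) > 1e-6 * mask$mpp)
    stop("classification plane must be at twice the mask's resolution")
  g <- plane_grey(plane)
  out <- mask$mask
  for (lab in mask$regions$label) {
    reg2x <- matrix(0, nrow(g), ncol(g))
    rm1 <- (mask$labels == lab) * 1
    # upscale region mask by 2 (nearest)
    yy <- pmin(ceiling(seq_len(nrow(g)) / 2), nrow(rm1))
    xx <- pmin(ceiling(seq_len(ncol(g)) / 2), ncol(rm1))
    reg2x <- rm1[yy, xx, drop = FALSE]
    wins <- region_windows(reg2x)
    if (is.null(wins)) next
    keep <- logical(nrow(wins))
    for (i in seq_len(nrow(wins))) {
      x0 <- wins[i, 1]; y0 <- wins[i, 2]
      patch <- g[(y0 + 1):(y0 + 64), (x0 + 1):(x0 + 64)]
      pr <- predict(model, matrix(lbp_descriptor(patch), 1))
      keep[i] <- as.character(pr) == "tissue"
    }
    if (sum(!keep) > 0.5 * length(keep)) {
      out[mask$labels == lab] <- 0
    } else {
      for (i in which(!keep)) {
        x0 <- wins[i, 1] %/% 2L; y0 <- wins[i, 2] %/% 2L
        ys <- (y0 + 1):min(y0 + 32L, nrow(out))
        xs <- (x0 + 1):min(x0 + 32L, ncol(out))
        blk <- out[ys, xs, drop = FALSE]
        blk[mask$labels[ys, xs, drop = FALSE] == lab] <- 0
        out[ys, xs] <- blk
      }
    }
  }
  tissue_mask(out, mask$mpp)
}

# -- boundary parametrisation ----------------------------------------------

#' N-point boundary of a tissue section
#'
#' An ordered, closed polygon of exactly N points in micron coordinates,
#' equally spaced by arc length, oriented counter-clockwise (positive
#' shoelace area in (x, y) with y downward on screen), starting at the
#' contour point with minimum (y, then x).
#'
#' @param points N x 2 matrix of (x, y) micron coordinates.
#' @param section_id label of the source region.
#' @export
boundary <- function(points, section_id = 1L) {
  p <- as_points(points)
  structure(list(points = p, section_id = section_id), class = "boundary")
}

#' @export
print.boundary <- function(x, ...) {
  cat(sprintf("boundary: %d points, section %s\n", nrow(x$points), x$section_id))
  invisible(x)
}

shoelace_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

# Resample a closed polygon (vertex matrix, no repeated endpoint) into N
# points equally spaced by arc length, starting at vertex `start_idx`.
resample_closed <- function(verts, N, start_idx = 1L) {
  v <- rbind(verts[start_idx:nrow(verts), , drop = FALSE],
             verts[seq_len(start_idx - 1L), , drop = FALSE])
  v <- rbind(v, v[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(v)^2))
  keep <- c(TRUE, seg > 0)
  v <- v[keep, , drop = FALSE]
  seg <- seg[seg > 0]
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  target <- (0:(N - 1)) * L / N
  xi <- approx(s, v[, 1], xout = target, rule = 2)$y
  yi <- approx(s, v[, 2], xout = target, rule = 2)$y
  cbind(xi, yi, deparse.level = 0)
}

#' Extract the N-point external boundary of a mask region
#'
#' The region is hole-filled, its external contour traced, and the contour
#' resampled into N points equally spaced by arc length. Orientation is
#' enforced counter-clockwise and the start point is the contour point with
#' minimum (y, then x), so repeated extraction is bit-identical.
#'
#' @param mask a [tissue_mask()] or a binary matrix.
#' @param N number of boundary points (default 2000).
#' @param label region label to extract (for a multi-region mask).
#' @param mpp microns per pixel (required when `mask` is a bare matrix).
#' @return a [boundary()].
#' @export
extract_boundary <- function(mask, N = 2000, label = 1L, mpp = NULL) {
  if (inherits(mask, "tissue_mask")) {
    m <- (mask$labels == label) * 1
    mpp <- mask$mpp
  } else {
    stopifnot(!is.null(mpp))
    m <- (mask > 0) * 1
  }
  if (!any(m > 0)) stop("empty region")
  m <- EBImage::fillHull(m)
  oc <- EBImage::ocontour(m)
  if (length(oc) == 0L) stop("no contour found")
  cont <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  # ocontour indexes the matrix [i, j] 0-based; our storage is [y, x]
  verts_px <- cbind(cont[, 2], cont[, 1])
  perim <- sum(sqrt(rowSums((verts_px - verts_px[c(2:nrow(verts_px), 1), ])^2))) * mpp
  if (perim < N * 0.05 * mpp)
    stop("region too small to carry ", N, " boundary points; use a smaller N")
  # counter-clockwise: positive shoelace area
  if (shoelace_area(verts_px) < 0) verts_px <- verts_px[rev(seq_len(nrow(verts_px))), , drop = FALSE]
  start <- order(verts_px[, 2], verts_px[, 1])[1]
  # dense resample + light circular smoothing irons out the one-pixel
  # zigzag of the traced contour, then the final equal-arc resample
  dense_n <- max(4L * N, nrow(verts_px))
  dense <- resample_closed(verts_px, dense_n, start_idx = start)
  if (nrow(dense) >= 32L) {
    # sigma ~1.5 contour pixels, expressed in dense samples
    sm <- smooth_boundary(dense, sigma = max(2, 1.5 * dense_n / nrow(verts_px)))
    start2 <- order(sm[, 2], sm[, 1])[1]
    pts_px <- resample_closed(sm, N, start_idx = start2)
  } else {
    pts_px <- resample_closed(verts_px, N, start_idx = start)
  }
  boundary(pts_px * mpp, section_id = label)
}

#' Write / read a boundary as CSV
#'
#' Columns: `section_id, idx, x_um, y_um` (idx 0-based).
#' @param b a [boundary()].
#' @param path CSV path.
#' @export
write_boundary_csv <- function(b, path) {
  df <- data.frame(section_id = b$section_id, idx = seq_len(nrow(b$points)) - 1L,
                   x_um = b$points[, 1], y_um = b$points[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boundary_csv
#' @export
read_boundary_csv <- function(path) {
  df <- utils::read.csv(path)
  boundary(cbind(df$x_um, df$y_um), section_id = df$section_id[1])
}
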