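#' Tissue feature detection for registration refinement
#'
#' Two feature types drive the stage-2 refinement: pockets of fat (bright,
#' texture-free regions fully enclosed by darker connective tissue) and
#' nuclei clusters (density-clustered haematoxylin-positive components,
#' converted to an equally spaced lattice of points so that partially
#' overlapping clusterings of serial sections can still match).
#'
#' @name feature_detection
NULL

#' Estimate the slide-background luminance threshold
#'
#' Samples luminance in a rectangle known to contain no tissue and returns
#' `mean - k * sd`: pixels above this are as bright as empty glass.
#'
#' @param plane an [image_plane()].
#' @param empty_region_rect rectangle `c(x, y, w, h)` in microns, outside
#'   all tissue.
#' @param tissue_mask optional [tissue_mask()]; overlap raises an error.
#' @param k number of standard deviations subtracted (default 2).
#' @return luminance threshold (0-255 scale).
#' @export
estimate_background_threshold <- function(plane, empty_region_rect,
                                          tissue_mask = NULL, k = 2) {
  r <- empty_region_rect
  px0 <- um_to_px(plane, rbind(r[1:2], r[1:2] + r[3:4]))
  xs <- max(1L, floor(px0[1, 1]) + 1L):min(ncol(plane$pixels), ceiling(px0[2, 1]))
  ys <- max(1L, floor(px0[1, 2]) + 1L):min(nrow(plane$pixels), ceiling(px0[2, 2]))
  if (!is.null(tissue_mask)) {
    scale <- plane$mpp / tissue_mask$mpp
    mys <- unique(pmin(pmax(round(ys * scale), 1L), nrow(tissue_mask$mask)))
    mxs <- unique(pmin(pmax(round(xs * scale), 1L), ncol(tissue_mask$mask)))
    if (any(tissue_mask$mask[mys, mxs] > 0))
      stop("empty_region_rect overlaps the tissue mask")
  }
  g <- plane_grey(plane)[ys, xs]
  mean(g) - k * stats::sd(c(g, recursive = TRUE))
}

# outer boundary ring of a binary component (8-connected dilation minus it)
component_ring <- function(comp) {
  nr <- nrow(comp); nc <- ncol(comp)
  dil <- comp
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ys <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
    xs <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
    dil <- dil | comp[ys, xs, drop = FALSE]
  }
  dil & !comp
}

#' Detect pockets of fat
#'
#' Fat does not stain and appears as bright as empty glass; a pocket is
#' distinguishable from glass only by the connective-tissue rim around it.
#' Bright (>= threshold) connected components lying strictly inside the
#' tissue mask whose entire outer boundary ring is below the threshold are
#' emitted as one feature point each, at the pocket centroid.
#'
#' @param plane an [image_plane()].
#' @param threshold luminance threshold from
#'   [estimate_background_threshold()].
#' @param tissue_mask a [tissue_mask()] at the plane's resolution.
#' @return data frame of feature points: `ftype` ("fat"), `source_id`,
#'   `x`, `y` (microns), `area_um2`.
#' @export
detect_fat <- function(plane, threshold, tissue_mask) {
  g <- plane_grey(plane)
  tm <- tissue_mask$mask
  if (any(dim(tm) != dim(g))) stop("tissue mask and plane dimensions differ")
  bright <- (g >= threshold) * 1
  L <- label8(bright)
  nr <- nrow(g); nc <- ncol(g)
  out <- NULL
  for (lab in seq_len(max(L))) {
    comp <- L == lab
    if (!all(tm[comp] > 0)) next            # must lie inside tissue
    # a component reaching the image or mask border is open to the glass
    if (any(comp[1, ]) || any(comp[nr, ]) || any(comp[, 1]) || any(comp[, nc])) next
    ring <- component_ring(comp)
    if (!any(ring)) next
    if (any(tm[ring] == 0)) next            # rim must stay inside tissue
    if (any(g[ring] >= threshold)) next     # rim must be fully sub-threshold
    idx <- which(comp, arr.ind = TRUE)
    cen <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1) * plane$mpp
    out <- rbind(out, data.frame(ftype = "fat", source_id = lab,
                                 x = cen[1], y = cen[2],
                                 area_um2 = sum(comp) * plane$mpp^2))
  }
  if (is.null(out))
    out <- data.frame(ftype = character(0), source_id = integer(0),
                      x = numeric(0), y = numeric(0), area_um2 = numeric(0))
  out
}

# -- stain separation -------------------------------------------------------

rgb_to_od <- function(px, I0 = 255, cap = 3) {
  od <- -log10(pmax(px, 1) / I0)
  od[od > cap] <- cap
  od[od < 0] <- 0
  od
}

#' Automatic stain separation (haematoxylin channel extraction)
#'
#' Converts the RGB image to optical densities (Beer-Lambert, white
#' calibration `I0`), estimates the two dominant stain vectors from the
#' principal plane of the OD cloud with angular percentile clipping
#' (Macenko-style), and unmixes by pseudo-inverse. The channel whose
#' estimated vector lies closest in angle to the canonical haematoxylin
#' reference is returned as `h`; the other stain as `second`. When too few
#' pixels are stained for a stable estimate the published
#' haematoxylin/eosin/DAB reference vectors are used instead
#' (`vectors = "ruifrok_he"` / `"ruifrok_hdab"` force them).
#'
#' @param plane an RGB [image_plane()].
#' @param vectors `"auto"` (Macenko-style estimation), `"ruifrok_he"`, or
#'   `"ruifrok_hdab"`.
#' @param I0 white calibration intensity per channel.
#' @param od_floor minimum OD norm for pixels entering the estimation.
#' @return list with `h`, `second` (non-negative concentration matrices),
#'   `stain_vectors` (3 x 2), `method`.
#' @export
separate_stains <- function(plane, vectors = "auto", I0 = 255, od_floor = 0.15) {
  px <- plane$pixels
  stopifnot(length(dim(px)) == 3L)
  nr <- dim(px)[1]; nc <- dim(px)[2]
  od <- matrix(0, nr * nc, 3)
  for (k in 1:3) od[, k] <- as.vector(rgb_to_od(px[, , k], I0 = I0))
  V <- ruifrok_vectors()
  method <- vectors
  S <- NULL
  if (vectors == "auto") {
    sel <- od[rowSums(od^2) > od_floor^2, , drop = FALSE]
    if (nrow(sel) >= 200L) {
      ev <- eigen(crossprod(sel) / nrow(sel), symmetric = TRUE)
      basis <- ev$vectors[, 1:2]
      if (sum(basis[, 1]) < 0) basis[, 1] <- -basis[, 1]
      proj <- sel %*% basis
      ang <- atan2(proj[, 2], proj[, 1])
      qa <- stats::quantile(ang, c(0.01, 0.99))
      v1 <- basis %*% c(cos(qa[1]), sin(qa[1]))
      v2 <- basis %*% c(cos(qa[2]), sin(qa[2]))
      S <- cbind(v1, v2)
      S[S < 0] <- 0
      nrm <- sqrt(colSums(S^2))
      if (all(nrm > 1e-6)) {
        S <- sweep(S, 2L, nrm, "/")
        cosang <- abs(sum(S[, 1] * S[, 2]))
        if (cosang > 0.999) S <- NULL      # collinear: estimation failed
      } else S <- NULL
      method <- if (is.null(S)) "ruifrok_fallback" else "macenko"
    } else method <- "ruifrok_fallback"
  }
  if (is.null(S)) {
    S <- switch(method,
                ruifrok_he = V[, c("h", "e")],
                ruifrok_hdab = V[, c("h", "d")],
                V[, c("h", "e")])
  }
  href <- V[, "h"]
  sim <- abs(t(S) %*% href)
  h_col <- which.max(sim)
  conc <- od %*% t(pinv_stains(S))          # pixels x 2
  conc[conc < 0] <- 0
  list(h = matrix(conc[, h_col], nr, nc),
       second = matrix(conc[, 3 - h_col], nr, nc),
       stain_vectors = S[, c(h_col, 3 - h_col)], method = method)
}

# Moore-Penrose pseudo-inverse of a 3 x 2 stain matrix
pinv_stains <- function(S) {
  sv <- svd(S)
  d <- sv$d
  d[d > 1e-10] <- 1 / d[d > 1e-10]
  sv$v %*% diag(d, length(d)) %*% t(sv$u)
}

#' Detect nucleus centroids on a haematoxylin channel
#'
#' Otsu-thresholds the H optical-density channel and keeps connected
#' components within physical area bounds, emitting one centroid per
#' nucleus.
#'
#' @param h_channel H concentration/OD matrix (from [separate_stains()]).
#' @param mpp microns per pixel of the channel.
#' @param area_um2 `c(min, max)` nucleus area bounds in square microns.
#' @param threshold optional fixed threshold (otherwise Otsu).
#' @param aux_channel optional second channel (e.g. DAB OD); its mean over
#'   each nucleus component is returned as `mean_aux`.
#' @return data frame with `x`, `y` (microns), `area_um2`, `mean_od` (and
#'   `mean_aux` when `aux_channel` is given).
#' @export
detect_nuclei <- function(h_channel, mpp, area_um2 = c(10, 300), threshold = NULL,
                          aux_channel = NULL) {
  h <- h_channel
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      area_um2 = numeric(0), mean_od = numeric(0))
  if (!is.null(aux_channel)) empty$mean_aux <- numeric(0)
  if (max(h) < 1e-6) return(empty)
  if (is.null(threshold)) {
    sc <- pmin(floor(h / max(h) * 256), 255)
    histo <- tabulate(sc + 1L, nbins = 256L)
    lev <- tryCatch(otsu_threshold(histo), error = function(e) NULL)
    if (is.null(lev)) return(empty)
    threshold <- (lev + 0.5) / 256 * max(h)
  }
  bin <- (h > threshold) * 1
  L <- label8(bin)
  if (max(L) == 0L) return(empty)
  labs <- L[L > 0L]
  areas <- tabulate(labs) * mpp^2
  keep <- which(areas >= area_um2[1] & areas <= area_um2[2])
  if (!length(keep)) return(empty)
  idx <- which(L > 0L, arr.ind = TRUE)
  lab_v <- L[L > 0L]
  sel <- lab_v %in% keep
  idx <- idx[sel, , drop = FALSE]; lab_v <- lab_v[sel]
  hx <- h[cbind(idx[, 1], idx[, 2])]
  cx <- tapply((idx[, 2] - 1) * mpp, lab_v, mean)
  cy <- tapply((idx[, 1] - 1) * mpp, lab_v, mean)
  mo <- tapply(hx, lab_v, mean)
  out <- data.frame(x = as.numeric(cx), y = as.numeric(cy),
                    area_um2 = areas[as.integer(names(cx))],
                    mean_od = as.numeric(mo))
  if (!is.null(aux_channel)) {
    ax <- aux_channel[cbind(idx[, 1], idx[, 2])]
    out$mean_aux <- as.numeric(tapply(ax, lab_v, mean))
  }
  out
}

#' Density-based clustering of nucleus centroids (DBSCAN)
#'
#' Standard DBSCAN on Euclidean distance: core points have at least
#' `min_pts` neighbours (self included) within `eps`; clusters grow from
#' core points; non-core, non-reachable points are noise (label -1).
#'
#' @param centroids n x 2 matrix or data frame with `x`, `y` (microns).
#' @param eps neighbourhood radius, microns.
#' @param min_pts minimum neighbourhood size for a core point.
#' @return integer vector of cluster labels (1..k, or -1 for noise).
#' @export
cluster_nuclei <- function(centroids, eps = 30, min_pts = 5) {
  p <- if (is.data.frame(centroids)) cbind(centroids$x, centroids$y) else as_points(centroids)
  n <- nrow(p)
  if (n == 0L) return(integer(0))
  d2 <- outer(rowSums(p^2), rowSums(p^2), "+") - 2 * tcrossprod(p)
  nb <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- nb[[i]]
    while (length(frontier)) {
      j <- frontier[1]; frontier <- frontier[-1]
      if (labels[j] == -1L) labels[j] <- cl
      if (labels[j] != 0L) next
      labels[j] <- cl
      if (core[j]) frontier <- c(frontier, nb[[j]])
    }
  }
  labels[labels == 0L] <- -1L
  labels
}

#' Convert a nuclei cluster to an equally spaced point lattice
#'
#' Fills the cluster's region with a square lattice of spacing
#' `1/sqrt(density)` (15.81 um at the default density of 0.004 points per
#' square micron). The region is either a supplied binary mask or, for a
#' set of member centroids, the union of discs of radius `region_radius`
#' around them (a raster stand-in for a hull of the cluster). At least one
#' point (the centroid) is always emitted.
#'
#' @param cluster either an n x 2 matrix of member centroids (microns) or a
#'   list `list(mask = <binary matrix>, mpp = <um/px>)`.
#' @param density points per square micron (default 0.004).
#' @param region_radius disc radius around member centroids, microns.
#' @param source_id cluster label attached to the output.
#' @return data frame of feature points: `ftype` ("nuclei_cluster"),
#'   `source_id`, `x`, `y`.
#' @export
cluster_to_points <- function(cluster, density = 0.004, region_radius = 30,
                              source_id = 1L) {
  stopifnot(density > 0)
  spacing <- 1 / sqrt(density)
  if (is.list(cluster) && !is.null(cluster$mask)) {
    m <- cluster$mask; mpp <- cluster$mpp
    idx <- which(m > 0, arr.ind = TRUE)
    if (!nrow(idx)) stop("empty cluster mask")
    xr <- range((idx[, 2] - 1) * mpp); yr <- range((idx[, 1] - 1) * mpp)
    inside <- function(q) {
      pxy <- cbind(pmin(pmax(round(q[, 2] / mpp) + 1, 1), nrow(m)),
                   pmin(pmax(round(q[, 1] / mpp) + 1, 1), ncol(m)))
      m[pxy] > 0
    }
    centroid <- c(mean((idx[, 2] - 1) * mpp), mean((idx[, 1] - 1) * mpp))
    area <- sum(m > 0) * mpp^2
  } else {
    pts <- as_points(cluster)
    xr <- range(pts[, 1]) + c(-1, 1) * region_radius
    yr <- range(pts[, 2]) + c(-1, 1) * region_radius
    inside <- function(q) {
      d2 <- dist2(q, pts)
      apply(d2, 1L, min) <= region_radius^2
    }
    centroid <- colMeans(pts)
    # region area estimated on a fine probe grid over the bounding box
    fs <- spacing / 4
    fx <- if (xr[1] + fs / 2 <= xr[2]) seq(xr[1] + fs / 2, xr[2], by = fs) else numeric(0)
    fy <- if (yr[1] + fs / 2 <= yr[2]) seq(yr[1] + fs / 2, yr[2], by = fs) else numeric(0)
    if (length(fx) && length(fy)) {
      fg <- cbind(rep(fx, times = length(fy)), rep(fy, each = length(fx)))
      area <- sum(inside(fg)) * fs^2
    } else area <- 0
  }
  target <- max(1L, as.integer(round(density * area)))
  lattice_at <- function(ox, oy) {
    gx <- if (xr[1] + ox <= xr[2]) seq(xr[1] + ox, xr[2], by = spacing) else numeric(0)
    gy <- if (yr[1] + oy <= yr[2]) seq(yr[1] + oy, yr[2], by = spacing) else numeric(0)
    if (!length(gx) || !length(gy)) return(matrix(numeric(0), 0, 2))
    grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
    grid[inside(grid), , drop = FALSE]
  }
  # sweep the lattice phase and keep the count closest to density * area
  phases <- seq(spacing / 10, spacing, by = spacing / 5)
  best <- NULL; best_gap <- Inf
  for (ox in phases) for (oy in phases) {
    cand <- lattice_at(ox, oy)
    gap <- abs(nrow(cand) - target)
    if (gap < best_gap) { best <- cand; best_gap <- gap }
  }
  out <- best
  if (is.null(out) || nrow(out) == 0L) out <- matrix(centroid, 1L, 2L)
  if (nrow(out) > target) {
    # trim edge points (farthest from the centroid) down to the target count
    d <- rowSums(sweep(out, 2L, centroid)^2)
    out <- out[order(d)[seq_len(target)], , drop = FALSE]
  }
  data.frame(ftype = "nuclei_cluster", source_id = source_id,
             x = out[, 1], y = out[, 2])
}

#' Feature-set container
#'
#' Typed landmark points with both the detected position `z = (x, y)` and
#' the position after approximate registration `z~ = (xt, yt)`.
#'
#' @param points data frame with columns `ftype`, `source_id`, `x`, `y`,
#'   `xt`, `yt`.
#' @param mpp source resolution.
#' @param frame free-form frame descriptor (slide id, rectangle).
#' @export
feature_set <- function(points, mpp = NA_real_, frame = NULL) {
  need <- c("ftype", "source_id", "x", "y", "xt", "yt")
  stopifnot(all(need %in% names(points)),
            all(points$ftype %in% c("fat", "nuclei_cluster")))
  structure(list(points = points[, need], mpp = mpp, frame = frame),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set: %d points (%d fat, %d nuclei-cluster)\n",
              nrow(x$points), sum(x$points$ftype == "fat"),
              sum(x$points$ftype == "nuclei_cluster")))
  invisible(x)
}

#' Build the refinement feature set of a slide
#'
#' Runs fat detection and the nuclei pipeline (stain separation, nucleus
#' detection, DBSCAN clustering, lattice conversion) and applies the
#' approximate transform to fill the registered positions `z~`. For the
#' reference slide pass the identity transform, making `z~ = z`.
#'
#' @param plane RGB [image_plane()] at the refinement resolution.
#' @param tissue_mask a [tissue_mask()] at the same resolution.
#' @param approx_T [rigid_transform()] from this slide's frame into the
#'   reference frame (identity for the reference slide).
#' @param config parameter list, see [default_config()].
#' @param background_threshold optional precomputed luminance threshold;
#'   when `NULL` a default of 220 is used (fixtures carry near-white
#'   glass).
#' @return a [feature_set()].
#' @export
build_feature_set <- function(plane, tissue_mask, approx_T = identity_transform(),
                              config = default_config(),
                              background_threshold = NULL) {
  if (is.null(background_threshold)) background_threshold <- 220
  fat <- detect_fat(plane, background_threshold, tissue_mask)
  st <- separate_stains(plane, vectors = "auto")
  h <- st$h
  h[tissue_mask$mask == 0] <- 0
  nuc <- detect_nuclei(h, plane$mpp, area_um2 = config$nucleus_area_um2)
  pts <- NULL
  if (nrow(nuc) > 0) {
    labels <- cluster_nuclei(nuc, eps = config$eps_um, min_pts = config$min_pts)
    for (cl in setdiff(unique(labels), -1L)) {
      mem <- cbind(nuc$x[labels == cl], nuc$y[labels == cl])
      pts <- rbind(pts, cluster_to_points(mem, density = config$density,
                                          region_radius = config$eps_um,
                                          source_id = cl))
    }
  }
  df <- rbind(
    if (nrow(fat)) data.frame(ftype = fat$ftype, source_id = fat$source_id,
                              x = fat$x, y = fat$y),
    pts)
  if (is.null(df))
    df <- data.frame(ftype = character(0), source_id = integer(0),
                     x = numeric(0), y = numeric(0))
  if (nrow(df)) {
    zt <- apply_transform(approx_T, cbind(df$x, df$y))
    df$xt <- zt[, 1]; df$yt <- zt[, 2]
  } else {
    df$xt <- numeric(0); df$yt <- numeric(0)
  }
  feature_set(df, mpp = plane$mpp)
}

#' Write a feature set as CSV
#'
#' Columns: `ftype, source_id, z_x, z_y, ztilde_x, ztilde_y`.
#' @param fs a [feature_set()].
#' @param path CSV path.
#' @export
write_feature_csv <- function(fs, path) {
  df <- data.frame(ftype = fs$points$ftype, source_id = fs$points$source_id,
                   z_x = fs$points$x, z_y = fs$points$y,
                   ztilde_x = fs$points$xt, ztilde_y = fs$points$yt)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
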