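#' Localized multi-IHC Allred scoring
#'
#' The case-study pipeline: a region of interest annotated on an H&E slide
#' is mapped through the composed registration chain onto the ER / PR
#' slides, a common set of fields of view is sampled inside it, each FOV
#' is scored with the Allred system (proportion score 0-5 plus intensity
#' score 0-3 of DAB-positive nuclei, total 0 or 2-8), and the slide's
#' final score is the mode of the FOV scores, with five additional FOVs on
#' a tie. Scoring the same physical FOVs on every stain is what the
#' registration buys: expression of several markers is read off exactly
#' the same tissue.
#'
#' @name ihc_scoring
NULL

#' Region of interest polygon
#'
#' @param polygon n x 2 matrix of micron coordinates (closed implicitly;
#'   do not repeat the first vertex).
#' @param slide_id identifier of the slide the ROI is annotated on.
#' @export
roi <- function(polygon, slide_id = "annotated") {
  p <- as_points(polygon)
  stopifnot(nrow(p) >= 3L)
  structure(list(polygon = p, slide_id = slide_id), class = "roi")
}

#' Map an ROI through a registration chain
#'
#' Transforms the polygon vertices with a (composed) rigid transform; the
#' area is preserved exactly because the transform is rigid.
#'
#' @param r a [roi()].
#' @param chain a [rigid_transform()] mapping the annotated slide's frame
#'   into the target slide's frame.
#' @param slide_id id for the mapped ROI.
#' @export
map_roi <- function(r, chain, slide_id = "target") {
  stopifnot(inherits(r, "roi"), inherits(chain, "rigid_transform"))
  roi(apply_transform(chain, r$polygon), slide_id = slide_id)
}

# ray-casting point-in-polygon (vectorized over points)
point_in_polygon <- function(pts, poly) {
  pts <- as_points(pts)
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# does an axis-aligned square [x0,x1]x[y0,y1] lie entirely inside poly?
square_in_polygon <- function(x0, y0, side, poly) {
  x1 <- x0 + side; y1 <- y0 + side
  corners <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1),
                   c((x0 + x1) / 2, (y0 + y1) / 2))
  if (!all(point_in_polygon(corners, poly))) return(FALSE)
  # no polygon edge may cross the square
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  # reject edges whose bounding box misses the square, test the rest
  cand <- which(pmax(a[, 1], b[, 1]) >= x0 & pmin(a[, 1], b[, 1]) <= x1 &
                  pmax(a[, 2], b[, 2]) >= y0 & pmin(a[, 2], b[, 2]) <= y1)
  for (k in cand) {
    if (segment_hits_rect(a[k, ], b[k, ], x0, y0, x1, y1)) return(FALSE)
  }
  TRUE
}

segment_hits_rect <- function(p, q, x0, y0, x1, y1) {
  # Liang-Barsky clipping: does segment pq intersect the rectangle?
  d <- q - p
  tmin <- 0; tmax <- 1
  for (axis in 1:2) {
    lo <- c(x0, y0)[axis]; hi <- c(x1, y1)[axis]
    if (abs(d[axis]) < 1e-12) {
      if (p[axis] < lo || p[axis] > hi) return(FALSE)
    } else {
      t1 <- (lo - p[axis]) / d[axis]; t2 <- (hi - p[axis]) / d[axis]
      if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp }
      tmin <- max(tmin, t1); tmax <- min(tmax, t2)
      if (tmin > tmax) return(FALSE)
    }
  }
  TRUE
}

#' Sample fields of view inside an ROI
#'
#' Draws `n` axis-aligned square FOVs of `fov_px` pixels at resolution
#' `mpp` whose footprints lie entirely inside the ROI polygon; centres are
#' uniform over the admissible region (rejection sampling from the
#' bounding box). Fully deterministic given the seed.
#'
#' @param r a [roi()].
#' @param n number of FOVs (default 10).
#' @param fov_px FOV side length in pixels (default 1000).
#' @param mpp scoring resolution (default 0.55 um/px, i.e. 20x).
#' @param seed integer seed.
#' @return data frame with `x`, `y` (top-left corner, microns), `side_um`.
#' @export
sample_fovs <- function(r, n = 10L, fov_px = 1000L, mpp = 0.55, seed = 1L) {
  stopifnot(inherits(r, "roi"))
  side <- fov_px * mpp
  poly <- r$polygon
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  if (diff(xr) < side || diff(yr) < side)
    stop("ROI is too small to contain a single FOV")
  set.seed(seed)
  out <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(out) < n) {
    tries <- tries + 1L
    if (tries > 20000L) stop("ROI is too small to contain a single FOV")
    x0 <- runif(1, xr[1], xr[2] - side)
    y0 <- runif(1, yr[1], yr[2] - side)
    if (square_in_polygon(x0, y0, side, poly)) out <- rbind(out, c(x0, y0))
  }
  data.frame(x = out[, 1], y = out[, 2], side_um = side)
}

#' Crop a rectangular field from a plane
#'
#' @param plane an [image_plane()].
#' @param rect_um `c(x, y)` top-left corner in microns.
#' @param size_px side length of the square crop in pixels.
#' @return an [image_plane()] of size `size_px` (edge-clamped).
#' @export
crop_plane <- function(plane, rect_um, size_px) {
  px0 <- round(um_to_px(plane, matrix(rect_um, 1)))
  x0 <- min(max(px0[1, 1], 0), ncol(plane$pixels) - size_px)
  y0 <- min(max(px0[1, 2], 0), nrow(plane$pixels) - size_px)
  px <- plane$pixels
  sel_y <- (y0 + 1):(y0 + size_px); sel_x <- (x0 + 1):(x0 + size_px)
  out <- if (length(dim(px)) == 3L) px[sel_y, sel_x, , drop = FALSE] else px[sel_y, sel_x, drop = FALSE]
  image_plane(out, plane$mpp,
              origin_offset = c(x0, y0) * plane$mpp / plane$mpp0 +
                plane$origin_offset, mpp0 = plane$mpp0)
}

allred_proportion_score <- function(frac) {
  if (frac <= 0) 0L
  else if (frac < 0.01) 1L
  else if (frac <= 0.10) 2L
  else if (frac <= 1 / 3) 3L
  else if (frac <= 2 / 3) 4L
  else 5L
}

allred_intensity_score <- function(mean_od, cutpoints) {
  if (is.na(mean_od)) 0L
  else if (mean_od < cutpoints[1]) 0L
  else if (mean_od < cutpoints[2]) 1L
  else if (mean_od < cutpoints[3]) 2L
  else 3L
}

#' Allred score of one field of view
#'
#' Separates haematoxylin and DAB, detects nuclei on the combined
#' optical-density channel, calls a nucleus DAB-positive when its mean
#' DAB-OD exceeds the positivity threshold, and converts the positive
#' fraction and mean positive intensity into the Allred proportion score
#' (bins 0; <1%; 1-10%; 10-33%; 33-66%; >66%) and intensity score (three
#' OD cut-points for weak / intermediate / strong). Total = PS + IS, with
#' 0 when PS = 0. All detected nuclei are treated as tumour nuclei; an
#' external tumour mask can restrict the field before scoring.
#'
#' @param fov_plane RGB [image_plane()] of the field.
#' @param config parameter list, see [default_config()]; uses
#'   `nucleus_area_um2`, `dab_positive_od`, `intensity_cutpoints`.
#' @return list with `total` (NA when no nuclei were detected — the caller
#'   should exclude and resample such a field), `ps`, `is`, `n_nuclei`,
#'   `stained_fraction`, `mean_dab_od`.
#' @export
score_fov_allred <- function(fov_plane, config = default_config()) {
  st <- separate_stains(fov_plane, vectors = "ruifrok_hdab")
  comb <- st$h + st$second
  nuc <- detect_nuclei(comb, fov_plane$mpp, area_um2 = config$nucleus_area_um2,
                       aux_channel = st$second)
  if (nrow(nuc) == 0L) {
    return(list(total = NA_integer_, ps = NA_integer_, is = NA_integer_,
                n_nuclei = 0L, stained_fraction = NA_real_,
                mean_dab_od = NA_real_))
  }
  # per-nucleus DAB measured over the nucleus component itself, so the
  # surrounding unstained background cannot dilute the intensity estimate
  mean_dab <- nuc$mean_aux
  positive <- mean_dab >= config$dab_positive_od
  frac <- mean(positive)
  ps <- allred_proportion_score(frac)
  mo <- if (any(positive)) mean(mean_dab[positive]) else NA_real_
  is_ <- allred_intensity_score(mo, config$intensity_cutpoints)
  total <- if (ps == 0L) 0L else ps + is_
  list(total = as.integer(total), ps = ps, is = is_, n_nuclei = nrow(nuc),
       stained_fraction = frac, mean_dab_od = mo)
}

#' Aggregate FOV scores into a final slide score
#'
#' Returns the mode of the FOV scores. On a tie, `resampler(5)` must
#' supply five additional scored FOVs and the mode is recomputed; after
#' `tie_rounds` unresolved rounds the higher tied score wins (a
#' clinically conservative, documented tie-break).
#'
#' @param fov_scores integer vector of per-FOV Allred scores.
#' @param resampler function taking a count and returning that many new
#'   scores, or `NULL` (ties then resolve immediately by the tie-break).
#' @param tie_rounds maximum number of resampling rounds.
#' @return integer final score.
#' @export
aggregate_scores <- function(fov_scores, resampler = NULL, tie_rounds = 3L) {
  scores <- as.integer(fov_scores)
  stopifnot(length(scores) >= 1L)
  for (round in 0:tie_rounds) {
    tab <- table(scores)
    top <- as.integer(names(tab)[tab == max(tab)])
    if (length(top) == 1L) return(top)
    if (is.null(resampler) || round == tie_rounds) return(max(top))
    scores <- c(scores, as.integer(resampler(5L)))
  }
  max(top)
}

#' Score one slide over a mapped ROI
#'
#' Samples FOVs inside the ROI, scores each, replaces any FOV with no
#' detectable nuclei, and aggregates by mode with the five-FOV tie-break.
#'
#' @param plane RGB [image_plane()] of the slide at scoring resolution.
#' @param r the [roi()] mapped onto this slide.
#' @param stain label recorded in the result (e.g. "ER", "PR").
#' @param seed sampling seed.
#' @param config parameter list, see [default_config()]; uses `n_fovs`,
#'   `fov_px`, `score_mpp`, `tie_rounds`.
#' @return a `score_record`: slide_id, stain, fov_scores, final_score,
#'   seed, fov_rects.
#' @export
score_slide <- function(plane, r, stain = "ER", seed = 1L,
                        config = default_config()) {
  fov_px <- config$fov_px
  rects <- sample_fovs(r, n = config$n_fovs, fov_px = fov_px,
                       mpp = plane$mpp, seed = seed)
  pool_seed <- seed + 1000L
  score_one <- function(rect) {
    sc <- score_fov_allred(crop_plane(plane, c(rect$x, rect$y), fov_px), config)
    sc$total
  }
  scores <- integer(0)
  for (i in seq_len(nrow(rects))) {
    s <- score_one(rects[i, ])
    while (is.na(s)) {  # FOV without nuclei: excluded and resampled
      pool_seed <- pool_seed + 1L
      rects[i, ] <- sample_fovs(r, n = 1L, fov_px = fov_px,
                                mpp = plane$mpp, seed = pool_seed)[1, ]
      s <- score_one(rects[i, ])
    }
    scores <- c(scores, s)
  }
  resampler <- function(k) {
    out <- integer(0)
    while (length(out) < k) {
      pool_seed <<- pool_seed + 1L
      rect <- sample_fovs(r, n = 1L, fov_px = fov_px, mpp = plane$mpp,
                          seed = pool_seed)[1, ]
      s <- score_one(rect)
      if (!is.na(s)) {
        out <- c(out, s)
        rects <<- rbind(rects, rect)
      }
    }
    out
  }
  final <- aggregate_scores(scores, resampler, tie_rounds = config$tie_rounds)
  structure(list(slide_id = r$slide_id, stain = stain, fov_scores = scores,
                 final_score = final, seed = seed, fov_rects = rects),
            class = "score_record")
}

#' @export
print.score_record <- function(x, ...) {
  cat(sprintf("score_record: %s %s final %d (FOVs: %s)\n", x$slide_id,
              x$stain, x$final_score, paste(x$fov_scores, collapse = " ")))
  invisible(x)
}

#' Mean absolute error of automated vs manual Allred scores
#'
#' Before the comparison every 0 is remapped to 1 on both sides so the
#' possible scores (0, 2-8) are equally spaced. With a `stains` grouping
#' the overall error is the unweighted mean of the per-stain MAEs.
#'
#' @param predicted,manual equal-length integer vectors.
#' @param stains optional grouping vector (e.g. "ER"/"PR").
#' @return list with `per_stain` (named numeric, or single "all" entry)
#'   and `overall`.
#' @export
evaluate_mae <- function(predicted, manual, stains = NULL) {
  if (length(predicted) != length(manual))
    stop("predicted and manual score vectors differ in length")
  remap <- function(x) ifelse(x == 0, 1, x)
  p <- remap(as.numeric(predicted)); m <- remap(as.numeric(manual))
  if (is.null(stains)) {
    mae <- mean(abs(p - m))
    return(list(per_stain = c(all = mae), overall = mae))
  }
  per <- tapply(abs(p - m), stains, mean)
  list(per_stain = per, overall = mean(per))
}
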