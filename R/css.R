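#' Curvature Scale Space boundary registration
#'
#' Stage-1 alignment: two tissue boundaries are compared through a modified
#' Curvature Scale Space (CSS) representation. Each boundary is smoothed
#' with Gaussian kernels of exponentially increasing bandwidth, signed
#' curvature is computed at every point and scale, and the strict local
#' maxima of curvature (stable convexities of the outline) form the feature
#' set. Maxima of the two boundaries are matched with the Hungarian
#' algorithm over a sweep of circular index offsets, and the matched points
#' yield a least-squares rigid transform. Curvature is invariant to rotation
#' and translation, which makes the representation suitable for rigid
#' registration; maxima rather than the classical zero crossings are
#' tracked, because inflection points along near-straight stretches of a
#' tissue edge flicker between sections while convex prominences persist.
#'
#' @name approximate_registration
NULL

# circular Gaussian filter of a periodic sequence, via FFT
gauss_circular <- function(x, sigma) {
  n <- length(x)
  d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  k <- exp(-d^2 / (2 * sigma^2))
  k <- k / sum(k)
  Re(fft(fft(x) * fft(k), inverse = TRUE)) / n
}

#' Smooth a closed boundary with a circular Gaussian filter
#'
#' The x and y coordinate sequences are convolved circularly with a Gaussian
#' kernel of standard deviation `sigma` (in units of boundary-index
#' samples). Point count is unchanged and index correspondence across
#' scales is preserved (no arc-length re-parametrisation), so a given
#' column of the CSS image tracks the same material point.
#'
#' @param P a [boundary()] or an N x 2 point matrix.
#' @param sigma Gaussian standard deviation in index samples (> 0).
#' @return N x 2 matrix of smoothed points.
#' @export
smooth_boundary <- function(P, sigma) {
  stopifnot(sigma > 0)
  p <- if (inherits(P, "boundary")) P$points else as_points(P)
  cbind(gauss_circular(p[, 1], sigma), gauss_circular(p[, 2], sigma))
}

#' Signed curvature of a closed curve
#'
#' Central-difference derivatives with circular wrap-around:
#' kappa = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2), positive on convexities
#' of a counter-clockwise curve. Units are 1/micron for micron input.
#' Setting `standard_sign = FALSE` flips the numerator to x'y'' + y'x''
#' (retained purely as a fidelity toggle; the standard form is the default
#' because the summed form is not a curvature).
#'
#' @param points N x 2 matrix (closed curve, no repeated endpoint).
#' @param standard_sign use the standard signed-curvature numerator.
#' @return numeric vector of length N.
#' @export
curvature <- function(points, standard_sign = TRUE) {
  p <- if (inherits(points, "boundary")) points$points else as_points(points)
  n <- nrow(p)
  if (n < 5L) stop("need at least 5 points on a closed curve")
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
  x <- p[, 1]; y <- p[, 2]
  x1 <- (x[ip] - x[im]) / 2; y1 <- (y[ip] - y[im]) / 2
  x2 <- x[ip] - 2 * x + x[im]; y2 <- y[ip] - 2 * y + y[im]
  seg2 <- (x[ip] - x)^2 + (y[ip] - y)^2
  speed2 <- x1^2 + y1^2
  if (any(seg2 == 0) || any(speed2 == 0))
    stop("repeated consecutive points (zero speed) on curve")
  num <- if (standard_sign) x1 * y2 - y1 * x2 else x1 * y2 + y1 * x2
  num / speed2^1.5
}

#' Exponentially spaced scale schedule
#'
#' Geometric sequence of Gaussian bandwidths from `sigma_min` to
#' `sigma_max` inclusive. Exponential rather than linear spacing keeps the
#' number of costly smoothing passes small while still sampling the
#' evolution of curvature maxima across scales.
#'
#' @param m number of levels (>= 2).
#' @param sigma_min,sigma_max schedule endpoints (0 < min < max), in
#'   boundary-index samples.
#' @return numeric vector of length `m`, strictly increasing, constant
#'   ratio.
#' @export
sigma_schedule <- function(m, sigma_min, sigma_max) {
  stopifnot(m >= 2, sigma_min > 0, sigma_max > sigma_min)
  sigma_min * (sigma_max / sigma_min)^((0:(m - 1)) / (m - 1))
}

# strict circular local maxima of a vector; the tolerance (relative to the
# curvature magnitude) keeps floating-point jitter on constant stretches
# from minting spurious maxima
circular_strict_maxima <- function(v, rel_tol = 1e-9) {
  n <- length(v)
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
  tol <- rel_tol * max(abs(v), .Machine$double.xmin)
  v > v[ip] + tol & v > v[im] + tol
}

#' Build the CSS image of a boundary
#'
#' Computes the n x m curvature matrix (n boundary points, m scales) by
#' smoothing the boundary at every scale of the schedule and evaluating
#' signed curvature, plus the binary mask of strict circular local maxima
#' per scale. With `require_convex = TRUE` (default) only maxima with
#' positive curvature (convexities) are marked; set it to `FALSE` to mark
#' all strict extrema of |kappa|.
#'
#' @param P a [boundary()].
#' @param sigmas scale schedule from [sigma_schedule()].
#' @param require_convex keep only positive-curvature maxima.
#' @return a `css_image`: `kappa` (n x m), `maxima` (n x m, 0/1),
#'   `sigmas`, `smoothed` (list of smoothed boundaries), `boundary_ref`.
#' @export
build_css <- function(P, sigmas, require_convex = TRUE) {
  stopifnot(inherits(P, "boundary"))
  n <- nrow(P$points); m <- length(sigmas)
  kappa <- matrix(0, n, m)
  maxima <- matrix(0L, n, m)
  smoothed <- vector("list", m)
  for (j in seq_len(m)) {
    sm <- smooth_boundary(P, sigmas[j])
    smoothed[[j]] <- sm
    k <- curvature(sm)
    kappa[, j] <- k
    mx <- circular_strict_maxima(k)
    if (require_convex) mx <- mx & k > 0
    maxima[, j] <- as.integer(mx)
  }
  structure(list(kappa = kappa, maxima = maxima, sigmas = sigmas,
                 smoothed = smoothed, boundary_ref = P$section_id, n = n),
            class = "css_image")
}

# Feature list of a CSS image: one feature per maximum at the coarsest
# usable scale, with scale persistence and curvature magnitude.
css_features <- function(css, min_maxima = 3L, track_window = NULL) {
  m <- ncol(css$kappa); n <- css$n
  if (is.null(track_window)) track_window <- max(2L, round(n / 100))
  jstar <- 0L
  for (j in rev(seq_len(m))) {
    if (sum(css$maxima[, j]) >= min_maxima) { jstar <- j; break }
  }
  if (jstar == 0L) {
    counts <- colSums(css$maxima)
    if (all(counts == 0L)) return(NULL)
    jstar <- max(which(counts > 0L))
  }
  idx <- which(css$maxima[, jstar] == 1L)
  pers <- vapply(idx, function(i) {
    cnt <- 0L
    for (j in seq_len(jstar)) {
      lo <- ((i - 1L - track_window):(i - 1L + track_window)) %% n + 1L
      if (any(css$maxima[lo, j] == 1L)) cnt <- cnt + 1L
    }
    cnt
  }, integer(1))
  list(index = idx, persistence = pers, kappa = css$kappa[idx, jstar],
       scale = jstar, n = n, m = m)
}

circ_index_dist <- function(a, b, n) {
  d <- abs(a - b) %% n
  pmin(d, n - d)
}

#' Match curvature maxima of two CSS images
#'
#' For each candidate circular index offset (a coarse grid around the
#' circle, refined around the most promising candidates), solves a
#' Hungarian assignment between the maxima of the two boundaries. A
#' maximum's descriptor is its circular index position, its scale
#' persistence, and its curvature magnitude at the coarsest surviving
#' scale; unmatched maxima absorb a dummy cost set at the 95th percentile
#' of the pairwise costs. The offset/assignment of minimum total cost is
#' returned, together with the runner-up candidates so a caller can
#' arbitrate between near-tied offsets with an external criterion.
#'
#' @param cssA,cssB `css_image` objects built with the same schedule and N.
#' @param n_coarse number of coarse offset candidates around the circle.
#' @param top_k number of best coarse offsets refined and retained.
#' @param extra_offsets additional circular offsets to refine (e.g. from an
#'   independent shape-overlap sweep).
#' @return a `maxima_match`: `pairs` (index pairs into A's and B's
#'   boundaries), `total_cost`, `circular_offset` (B index i matches A
#'   index i + offset), `scale`, `candidates`.
#' @export
match_maxima <- function(cssA, cssB, n_coarse = 64L, top_k = 6L,
                         extra_offsets = NULL) {
  stopifnot(inherits(cssA, "css_image"), inherits(cssB, "css_image"),
            cssA$n == cssB$n, length(cssA$sigmas) == length(cssB$sigmas))
  fA <- css_features(cssA); fB <- css_features(cssB)
  if (is.null(fA) || is.null(fB))
    stop("no curvature maxima at any scale; fall back to centroid/principal-axis alignment")
  n <- cssA$n
  kscale <- max(abs(c(fA$kappa, fB$kappa)), 1e-12)
  mlev <- fA$m
  eval_offset <- function(off) {
    off <- as.integer(off)
    nA <- length(fA$index); nB <- length(fB$index)
    C <- outer(fA$index, (fB$index + off - 1L) %% n + 1L,
               function(a, b) circ_index_dist(a, b, n) / n)
    C <- C + 0.5 * abs(outer(fA$persistence, fB$persistence, "-")) / mlev
    C <- C + 0.5 * abs(outer(fA$kappa, fB$kappa, "-")) / kscale
    dummy <- as.numeric(stats::quantile(C, 0.95))
    size <- nA + nB
    big <- matrix(dummy * 2, size, size)
    big[seq_len(nA), seq_len(nB)] <- C
    big[seq_len(nA), nB + seq_len(nA)] <- dummy * 2
    big[cbind(seq_len(nA), nB + seq_len(nA))] <- dummy
    big[nA + seq_len(nB), seq_len(nB)] <- dummy * 2
    big[cbind(nA + seq_len(nB), seq_len(nB))] <- dummy
    big[nA + seq_len(nB), nB + seq_len(nA)] <- 0
    sol <- solve_assignment(big)
    matched <- which(sol$assignment[seq_len(nA)] <= nB)
    pairs <- cbind(A = fA$index[matched], B = fB$index[sol$assignment[matched]])
    list(offset = off, cost = sol$cost, pairs = pairs)
  }
  step <- max(1L, round(n / n_coarse))
  coarse <- lapply(seq(0L, n - 1L, by = step), eval_offset)
  costs <- vapply(coarse, `[[`, numeric(1), "cost")
  r <- max(1L, ceiling(step / 2) + 1L)   # fine ranges overlap the coarse grid
  fine_step <- max(1L, round(r / 8))
  seeds_off <- unique(c(as.integer(vapply(coarse[order(costs)[seq_len(min(top_k, length(coarse)))]],
                                          `[[`, numeric(1), "offset")),
                        as.integer(extra_offsets) %% n))
  refined <- lapply(seeds_off, function(o0) {
    fine <- c(list(eval_offset(o0)),
              lapply(setdiff((o0 + seq(-r, r, by = fine_step)) %% n, o0), eval_offset))
    best <- fine[[which.min(vapply(fine, `[[`, numeric(1), "cost"))]]
    if (fine_step > 1L) {
      o1 <- best$offset
      fine2 <- c(list(best),
                 lapply(setdiff((o1 + (-fine_step):fine_step) %% n, o1), eval_offset))
      best <- fine2[[which.min(vapply(fine2, `[[`, numeric(1), "cost"))]]
    }
    best
  })
  winner <- refined[[which.min(vapply(refined, `[[`, numeric(1), "cost"))]]
  structure(list(pairs = winner$pairs, total_cost = winner$cost,
                 circular_offset = winner$offset,
                 scale = fA$scale,
                 candidates = refined),
            class = "maxima_match")
}

#' Least-squares rigid fit of paired points
#'
#' Finds the rotation + translation (no scaling, no reflection) minimizing
#' the weighted sum of squared residuals between transformed source points
#' and destination points. Closed form: the angle comes from the atan2 of
#' the summed cross and dot products of the centered pairs, which
#' guarantees a proper rotation (determinant +1).
#'
#' @param src,dst n x 2 matrices of corresponding points (n >= 2).
#' @param weights optional non-negative weights.
#' @return a [rigid_transform()] with center at the weighted source
#'   centroid.
#' @export
fit_rigid <- function(src, dst, weights = NULL) {
  src <- as_points(src); dst <- as_points(dst)
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 2L)
  if (is.null(weights)) weights <- rep(1, nrow(src))
  w <- weights / sum(weights)
  cs <- colSums(src * w); cd <- colSums(dst * w)
  s <- sweep(src, 2L, cs); d <- sweep(dst, 2L, cd)
  if (max(abs(s)) < 1e-12) stop("all source points coincident; rigid fit undefined")
  dot <- sum(w * (s[, 1] * d[, 1] + s[, 2] * d[, 2]))
  crs <- sum(w * (s[, 1] * d[, 2] - s[, 2] * d[, 1]))
  theta <- atan2(crs, dot)
  rigid_transform(theta, t = cd - cs, center = cs)
}

#' Chamfer distance between two boundaries
#'
#' Sum over the reference boundary's points of the Euclidean distance to
#' the nearest point of the registered boundary; with `normalize = TRUE`
#' (default) the sum is divided by the number of reference points, giving
#' the per-point mean. Not symmetric in its arguments. Units follow the
#' input units.
#'
#' @param B_ref,B_reg [boundary()] objects or point matrices.
#' @param normalize divide by the number of reference points.
#' @return non-negative scalar distance.
#' @export
chamfer_distance <- function(B_ref, B_reg, normalize = TRUE) {
  a <- if (inherits(B_ref, "boundary")) B_ref$points else as_points(B_ref)
  b <- if (inherits(B_reg, "boundary")) B_reg$points else as_points(B_reg)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty boundary")
  chunk <- max(1L, floor(2e6 / nrow(b)))
  total <- 0
  i <- 1L
  while (i <= nrow(a)) {
    j <- min(i + chunk - 1L, nrow(a))
    d2 <- dist2(a[i:j, , drop = FALSE], b)
    total <- total + sum(sqrt(do.call(pmin, as.data.frame(d2))))
    i <- j + 1L
  }
  if (normalize) total / nrow(a) else total
}

# principal-axis fallback alignment when a boundary has no curvature maxima
principal_axis_register <- function(boundaryA, boundaryB) {
  pa <- boundaryA$points; pb <- boundaryB$points
  ca <- colMeans(pa); cb <- colMeans(pb)
  ang <- function(p, c0) {
    cc <- sweep(p, 2L, c0)
    e <- eigen(crossprod(cc) / nrow(cc))
    atan2(e$vectors[2, 1], e$vectors[1, 1])
  }
  base <- ang(pa, ca) - ang(pb, cb)
  cand <- lapply(c(base, base + pi), function(th) {
    rigid_transform(th, t = ca - cb, center = cb)
  })
  scores <- vapply(cand, function(T) {
    chamfer_distance(pa, apply_transform(T, pb))
  }, numeric(1))
  cand[[which.min(scores)]]
}

#' Approximate rigid registration of two boundaries
#'
#' Stage-1 pipeline: build both CSS images, match their curvature maxima
#' (Hungarian assignment over circular offsets), and fit a rigid transform
#' to the matched maxima's coordinates on the sigma_min-smoothed boundaries
#' (pixel-level jitter is suppressed at that scale). Each candidate offset's
#' fit is then consolidated by trimmed least squares over the dense index
#' correspondence the offset implies, polished by a trimmed
#' nearest-neighbour rigid descent, and the candidate with the smallest
#' Chamfer distance between the (decimated, smoothed) boundaries wins;
#' small-rotation restarts around the winner guard against local minima.
#' Because near-symmetric outlines can produce near-tied matchings at wrong
#' offsets, candidate offsets are also seeded from a coarse shape-overlap
#' sweep. If either boundary has no curvature maxima at any scale,
#' alignment falls back to centroid + principal axis.
#'
#' @param boundaryA reference [boundary()].
#' @param boundaryB moving [boundary()] (same N).
#' @param config parameter list, see [default_config()]; uses `css_levels`,
#'   `sigma_min`, `sigma_max`.
#' @return a [rigid_transform()] mapping B's coordinates into A's frame.
#' @export
approximate_register <- function(boundaryA, boundaryB, config = default_config()) {
  stopifnot(inherits(boundaryA, "boundary"), inherits(boundaryB, "boundary"),
            nrow(boundaryA$points) == nrow(boundaryB$points))
  n <- nrow(boundaryA$points)
  sig <- sigma_schedule(config$css_levels, config$sigma_min,
                        if (is.null(config$sigma_max)) n / 16 else config$sigma_max)
  cssA <- build_css(boundaryA, sig)
  cssB <- build_css(boundaryB, sig)
  smA <- cssA$smoothed[[1]]
  smB <- cssB$smoothed[[1]]
  di <- seq(1L, n, by = max(1L, floor(n / 400)))
  src_all <- smB[di, , drop = FALSE]
  dst_ref <- smA[di, , drop = FALSE]
  offset_fit <- function(offset) {
    ja <- (di + offset - 1L) %% n + 1L
    fit_rigid(src_all, smA[ja, , drop = FALSE])
  }
  # shape-overlap sweep: dense index-correspondence fit per coarse offset,
  # scored by Chamfer; seeds extra matching candidates for near-symmetric
  # outlines
  sweep_off <- seq(0L, n - 1L, by = max(1L, round(n / 64)))
  sweep_scores <- vapply(sweep_off, function(o) {
    chamfer_distance(dst_ref, apply_transform(offset_fit(o), src_all))
  }, numeric(1))
  extra <- sweep_off[order(sweep_scores)[1:3]]
  mm <- tryCatch(match_maxima(cssA, cssB, extra_offsets = extra),
                 error = function(e) NULL)
  if (is.null(mm)) return(principal_axis_register(boundaryA, boundaryB))
  refine_fit <- function(offset, pairs = NULL) {
    T1 <- NULL
    if (!is.null(pairs) && nrow(pairs) >= 2L) {
      T1 <- tryCatch(fit_rigid(smB[pairs[, "B"], , drop = FALSE],
                               smA[pairs[, "A"], , drop = FALSE]),
                     error = function(e) NULL)
    }
    if (is.null(T1)) T1 <- offset_fit(offset)
    # trimmed LS on the dense index correspondence implied by the offset
    ja <- (di + offset - 1L) %% n + 1L
    dst <- smA[ja, , drop = FALSE]
    for (it in 1:3) {
      res <- rowSums((apply_transform(T1, src_all) - dst)^2)
      keep <- res <= stats::quantile(res, 0.8)
      if (sum(keep) < 3L) break
      T1 <- fit_rigid(src_all[keep, , drop = FALSE], dst[keep, , drop = FALSE])
    }
    icp_polish(T1, src_all, dst_ref)
  }
  cands <- lapply(mm$candidates, function(cc) refine_fit(cc$offset, cc$pairs))
  scores <- vapply(cands, function(T) {
    chamfer_distance(dst_ref, apply_transform(T, src_all))
  }, numeric(1))
  best <- cands[[which.min(scores)]]
  # multi-start escape: re-polish from small rotations about the winner and
  # keep whichever basin scores best
  ctr <- colMeans(src_all)
  restarts <- lapply(c(-3, -1.5, 1.5, 3) * pi / 180, function(dth) {
    icp_polish(compose_transform(rigid_transform(dth, center = ctr), best),
               src_all, dst_ref)
  })
  all_c <- c(list(best), restarts)
  all_s <- vapply(all_c, function(T) {
    chamfer_distance(dst_ref, apply_transform(T, src_all))
  }, numeric(1))
  all_c[[which.min(all_s)]]
}

# trimmed symmetric nearest-neighbour rigid polish (boundary-level ICP from
# a good initialization); removes the tangential slip a fixed index
# correspondence cannot express. Correspondences are pooled in both
# directions (reducing the one-sided matching bias) and the trim fraction
# anneals from loose to tight.
icp_polish <- function(T0, src, dst, iters = 15L, trim_from = 0.9, trim_to = 0.7) {
  T1 <- T0
  for (it in seq_len(iters)) {
    trim <- trim_from + (trim_to - trim_from) * (it - 1) / max(iters - 1, 1)
    cur <- apply_transform(T1, src)
    d2 <- dist2(cur, dst)
    nn_fwd <- max.col(-d2, ties.method = "first")
    nn_bwd <- max.col(-t(d2), ties.method = "first")
    s_all <- rbind(src, src[nn_bwd, , drop = FALSE])
    d_all <- rbind(dst[nn_fwd, , drop = FALSE], dst)
    res <- c(d2[cbind(seq_len(nrow(src)), nn_fwd)],
             d2[cbind(nn_bwd, seq_len(nrow(dst)))])
    keep <- res <= stats::quantile(res, trim)
    if (sum(keep) < 3L) break
    T1 <- fit_rigid(s_all[keep, , drop = FALSE], d_all[keep, , drop = FALSE])
  }
  T1
}
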