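#' Distance-gated rigid Coherent Point Drift refinement
#'
#' Stage-2 refinement registers the two slides' feature sets with a rigid
#' Coherent Point Drift: the moving set's points are the centroids of an
#' isotropic Gaussian mixture (equal membership weights, plus a uniform
#' outlier component) fitted to the reference set by EM, with the search
#' restricted to rotation + translation. The mixture term for a pair of
#' features is multiplied by a distance gate d(z, z~)^beta that vanishes
#' when the two features lie further than delta apart after approximate
#' registration, or when their types differ — so only plausibly
#' corresponding features can attract each other, and when the sections
#' share too little structure the refinement declines and the approximate
#' transform stands. A phase-correlation translation correction, accepted
#' only when its peak lies in the central 20% of the spectrum image, can
#' follow.
#'
#' @name cpd_refinement
NULL

#' Feature-pair distance gate
#'
#' Closed form `sqrt(max(delta^2 - ||z - z~||^2, 0)) / delta` for features
#' of the same type, 0 otherwise: 1 at zero separation, falling to 0 at
#' separation `delta`.
#'
#' @param z n x 2 matrix (or length-2 vector) of current positions,
#'   microns.
#' @param z_tilde matching positions after approximate registration.
#' @param same_type logical (scalar or length n): do the paired features
#'   share a type?
#' @param delta gate radius, microns (> 0).
#' @return numeric weights in `[0, 1]`.
#' @export
gate <- function(z, z_tilde, same_type = TRUE, delta = 33) {
  stopifnot(delta > 0)
  z <- as_points(z); z_tilde <- as_points(z_tilde)
  d2 <- rowSums((z - z_tilde)^2)
  w <- sqrt(pmax(delta^2 - d2, 0)) / delta
  w * as.numeric(same_type)
}

#' Refinement configuration
#'
#' @param beta gate exponent (>= 0; default 1).
#' @param delta gate radius in microns (default 33).
#' @param max_iter EM iteration cap.
#' @param tol relative objective-change convergence tolerance.
#' @param outlier_w uniform outlier-component weight in [0, 1).
#' @param mass_floor minimum effective correspondence mass for accepting
#'   the refinement; below it the approximate transform is returned.
#' @export
refinement_config <- function(beta = 1, delta = 33, max_iter = 100L,
                              tol = 1e-6, outlier_w = 0.1, mass_floor = 5) {
  stopifnot(beta >= 0, delta > 0, outlier_w >= 0, outlier_w < 1)
  list(beta = beta, delta = delta, max_iter = max_iter, tol = tol,
       outlier_w = outlier_w, mass_floor = mass_floor)
}

# gated E-step numerators for target points X against centroids Y under
# transform T; G is the frozen gate matrix (N x M)
cpd_estep <- function(X, Y, T, sigma2, G, beta, outlier_w, V) {
  TY <- apply_transform(T, Y)
  N <- nrow(X); M <- nrow(Y)
  d2 <- dist2(X, TY)
  num <- exp(-d2 / (2 * sigma2)) * (if (beta == 0) 1 else G^beta)
  dens <- num / (2 * pi * sigma2)                      # N x M component densities
  mix <- rowSums(dens) * (1 - outlier_w) / M + outlier_w / V
  denom <- rowSums(num) + (2 * pi * sigma2) * outlier_w * M / ((1 - outlier_w) * V)
  P <- num / pmax(denom, .Machine$double.xmin)
  P[denom <= 0, ] <- 0
  list(P = P, d2 = d2, loglik = sum(log(pmax(mix, .Machine$double.xmin))))
}

#' Modified CPD responsibilities of a target point
#'
#' Exposes the gated E-step for one target point `z` against a set of GMM
#' centroids: isotropic Gaussian densities times `gate^beta`, normalized
#' together with the uniform outlier component. With `beta = 0` or an
#' effectively infinite `delta` this reduces to the unmodified rigid CPD
#' responsibilities.
#'
#' @param z length-2 target position (microns).
#' @param centroids M x 2 matrix of mixture centroids (current positions).
#' @param centroids_tilde M x 2 matrix of the centroids' positions after
#'   approximate registration (the gate anchor).
#' @param z_type,centroid_types feature types of the target and centroids.
#' @param sigma2 mixture variance (> 0).
#' @param config a [refinement_config()].
#' @param volume support volume of the uniform outlier component.
#' @return list with `responsibilities` (length M, the outlier share is
#'   `1 - sum`) and `outlier`.
#' @export
modified_responsibility <- function(z, centroids, centroids_tilde,
                                    z_type = "nuclei_cluster",
                                    centroid_types = "nuclei_cluster",
                                    sigma2 = 1, config = refinement_config(),
                                    volume = 1e6) {
  stopifnot(sigma2 > 0)
  C <- as_points(centroids); Ct <- as_points(centroids_tilde)
  M <- nrow(C)
  same <- rep_len(centroid_types, M) == z_type
  g <- gate(matrix(z, M, 2, byrow = TRUE), Ct, same, config$delta)
  d2 <- rowSums(sweep(C, 2L, z)^2)
  num <- exp(-d2 / (2 * sigma2)) * g^config$beta
  denom <- sum(num) + (2 * pi * sigma2) * config$outlier_w * M /
    ((1 - config$outlier_w) * volume)
  if (denom <= 0) return(list(responsibilities = rep(0, M), outlier = 1))
  r <- num / denom
  list(responsibilities = r, outlier = 1 - sum(r))
}

#' Rigid CPD with the feature-type / distance gate
#'
#' EM loop: gated responsibilities (E-step), closed-form weighted rigid
#' update and variance re-estimate (M-step). The gate is anchored at the
#' post-approximate-registration positions of both sets and frozen, so
#' each EM iteration exactly maximizes the gated likelihood and the
#' objective trace is monotone. If the total effective correspondence mass
#' at convergence is below `mass_floor` — dissimilar or too-sparse feature
#' sets — the approximate transform is returned unchanged.
#'
#' @param source moving [feature_set()] (GMM centroids), its `xt`/`yt`
#'   positions are the starting point.
#' @param target reference [feature_set()].
#' @param config a [refinement_config()].
#' @param approx_T the approximate transform (returned on fallback;
#'   the refinement correction is composed with it otherwise).
#' @return a `refinement_result`: `transform` (composed), `correction`
#'   (the CPD increment in the reference frame), `objective_trace`,
#'   `n_effective_pairs`, `sigma2`, `fallback`.
#' @export
cpd_rigid <- function(source, target, config = refinement_config(),
                      approx_T = identity_transform()) {
  stopifnot(inherits(source, "feature_set"), inherits(target, "feature_set"))
  fallback <- function(reason) {
    structure(list(transform = approx_T, correction = identity_transform(),
                   objective_trace = numeric(0), n_effective_pairs = 0,
                   sigma2 = NA_real_, fallback = reason,
                   phase_shift_applied = NULL),
              class = "refinement_result")
  }
  if (nrow(source$points) == 0L || nrow(target$points) == 0L) {
    warning("empty feature set; falling back to the approximate transform")
    return(fallback("empty_feature_set"))
  }
  X <- cbind(target$points$xt, target$points$yt)
  Y <- cbind(source$points$xt, source$points$yt)
  N <- nrow(X); M <- nrow(Y)
  same <- outer(target$points$ftype, source$points$ftype, "==")
  sep2 <- dist2(X, Y)
  G <- sqrt(pmax(config$delta^2 - sep2, 0)) / config$delta * same
  rngx <- apply(X, 2L, range)
  V <- max(prod(rngx[2, ] - rngx[1, ]), config$delta^2)
  sigma2 <- max(sum(sep2) / (2 * N * M), 1e-6)
  T <- identity_transform()
  trace <- numeric(0)
  for (it in seq_len(config$max_iter)) {
    es <- cpd_estep(X, Y, T, sigma2, G, config$beta, config$outlier_w, V)
    trace <- c(trace, es$loglik)
    Np <- sum(es$P)
    if (Np < 1e-10) break
    w_y <- colSums(es$P)          # mass per centroid
    w_x <- rowSums(es$P)          # mass per target point
    mu_x <- colSums(X * w_x) / Np
    mu_y <- colSums(Y * w_y) / Np
    Xc <- sweep(X, 2L, mu_x); Yc <- sweep(Y, 2L, mu_y)
    A <- t(Xc) %*% es$P %*% Yc    # 2 x 2 cross-covariance
    theta <- atan2(A[2, 1] - A[1, 2], A[1, 1] + A[2, 2])
    R <- rotation_matrix(theta)
    t_vec <- mu_x - as.numeric(R %*% mu_y)
    T_new <- rigid_transform(theta, t = t_vec + as.numeric(R %*% mu_y) - mu_y,
                             center = mu_y)
    sigma2 <- max(sum(es$P * dist2(X, apply_transform(T_new, Y))) / (2 * Np), 1e-4)
    conv <- length(trace) >= 2L &&
      abs(trace[it] - trace[it - 1L]) <= config$tol * (abs(trace[it - 1L]) + 1e-12)
    T <- T_new
    if (conv) break
  }
  es <- cpd_estep(X, Y, T, sigma2, G, config$beta, config$outlier_w, V)
  trace <- c(trace, es$loglik)
  n_eff <- sum(es$P)
  if (n_eff < config$mass_floor) {
    res <- fallback("mass_floor")
    res$objective_trace <- trace
    res$n_effective_pairs <- n_eff
    return(res)
  }
  structure(list(transform = compose_transform(T, approx_T), correction = T,
                 objective_trace = trace, n_effective_pairs = n_eff,
                 sigma2 = sigma2, fallback = NA_character_,
                 phase_shift_applied = NULL),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("refinement_result: %s, %d EM iterations, effective pairs %.2f\n",
              if (is.na(x$fallback)) "refined" else paste0("fallback (", x$fallback, ")"),
              length(x$objective_trace), x$n_effective_pairs))
  print(x$transform)
  invisible(x)
}

#' Phase-correlation translation estimate with central-peak gating
#'
#' Estimates the residual translation between two equal-size grey images
#' from the peak of the inverse-transformed cross-power spectrum (Hann
#' windowed). The shift is returned only if it is below `max_frac` (10%)
#' of the image size in each direction — the peak lies inside the central
#' 20% of the phase image; larger peaks are treated as spurious and no
#' correction is made.
#'
#' @param ref_image,reg_image grey matrices of equal size (the registered
#'   field and its reference).
#' @param max_frac maximum accepted |shift| as a fraction of size.
#' @return integer `c(dx, dy)` pixel shift to apply to `reg_image`, or
#'   `NULL` if rejected / featureless.
#' @export
phase_correct <- function(ref_image, reg_image, max_frac = 0.1) {
  stopifnot(all(dim(ref_image) == dim(reg_image)))
  nr <- nrow(ref_image); nc <- ncol(ref_image)
  if (stats::sd(ref_image) < 1e-9 || stats::sd(reg_image) < 1e-9) return(NULL)
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  W <- outer(hann(nr), hann(nc))
  F1 <- stats::fft((ref_image - mean(ref_image)) * W)
  F2 <- stats::fft((reg_image - mean(reg_image)) * W)
  R <- F1 * Conj(F2)
  R <- R / pmax(Mod(R), 1e-12)
  r <- Re(stats::fft(R, inverse = TRUE)) / (nr * nc)
  pk <- as.integer(which(r == max(r), arr.ind = TRUE)[1, ])
  dy <- pk[1] - 1L; dx <- pk[2] - 1L
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  if (abs(dx) >= max_frac * nc || abs(dy) >= max_frac * nr) return(NULL)
  c(dx = dx, dy = dy)
}

#' Full stage-2 refinement of a registered pair
#'
#' Builds both slides' feature sets, runs the gated rigid CPD, resamples
#' the moving image into the reference frame under the refined transform,
#' and applies the gated phase-correlation translation correction. Every
#' failure mode degrades gracefully to the approximate transform.
#'
#' @param ref_slide,mov_slide lists with `plane` (RGB [image_plane()]) and
#'   `mask` ([tissue_mask()]) at the refinement resolution.
#' @param approx_T approximate [rigid_transform()] (moving into reference
#'   frame).
#' @param config parameter list, see [default_config()].
#' @return a `refinement_result` whose `transform` maps the moving slide
#'   into the reference frame.
#' @export
refine <- function(ref_slide, mov_slide, approx_T, config = default_config()) {
  rc <- refinement_config(beta = config$beta, delta = config$delta_um,
                          max_iter = config$max_iter, tol = config$tol,
                          outlier_w = config$outlier_w,
                          mass_floor = config$mass_floor)
  fs_ref <- build_feature_set(ref_slide$plane, ref_slide$mask,
                              identity_transform(), config)
  fs_mov <- build_feature_set(mov_slide$plane, mov_slide$mask, approx_T, config)
  res <- cpd_rigid(fs_mov, fs_ref, rc, approx_T = approx_T)
  # phase-correlation correction on the aligned grey fields
  reg_plane <- resample_registered(mov_slide$plane, res$transform,
                                   ref_slide$plane)
  shift <- tryCatch(phase_correct(plane_grey(ref_slide$plane),
                                  plane_grey(reg_plane)),
                    error = function(e) NULL)
  if (!is.null(shift)) {
    dt <- c(shift[["dx"]], shift[["dy"]]) * ref_slide$plane$mpp
    res$transform <- compose_transform(rigid_transform(0, t = dt), res$transform)
    res$phase_shift_applied <- dt
  }
  res
}
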