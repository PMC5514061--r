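#' Case-level registration pipeline
#'
#' Orchestrates consecutive pairwise registration across a case of serial
#' sections: each slide is registered to its neighbour (approximate
#' boundary alignment, then feature-based refinement) and the pairwise
#' transforms are composed toward a user-chosen reference section, giving a
#' case-wide registration. Chamfer distances before and after refinement
#' are reported per adjacent pair, mirroring a two-column
#' approximate-vs-refined quality table.
#'
#' @name pipeline
NULL

#' Register one neighbouring pair end to end
#'
#' Runs the approximate boundary registration, then the gated rigid CPD
#' refinement on the two feature sets, and accepts the refinement only if
#' it does not worsen the Chamfer distance between the external boundaries
#' — when the refinement cannot improve on the boundary alignment, the
#' approximate result is preferable and is kept (the same philosophy as the
#' refinement's own fallback for dissimilar feature sets).
#'
#' @param boundaryA,boundaryB reference and moving [boundary()] objects.
#' @param fsA,fsB optional [feature_set()]s for the two slides; `fsB`'s
#'   registered positions are refreshed under the approximate transform.
#'   With either missing, the pair keeps the approximate transform.
#' @param config parameter list, see [default_config()].
#' @return list with `transform` (final), `approx_transform`,
#'   `refinement` (the `refinement_result`, or `NULL`),
#'   `chamfer_approx`, `chamfer_refined`, `chamfer_final` (normalized,
#'   microns), `refinement_accepted`.
#' @export
register_pair <- function(boundaryA, boundaryB, fsA = NULL, fsB = NULL,
                          config = default_config()) {
  approx_T <- approximate_register(boundaryA, boundaryB, config)
  ch_a <- chamfer_distance(boundaryA, apply_transform(approx_T, boundaryB$points))
  out <- list(transform = approx_T, approx_transform = approx_T,
              refinement = NULL, chamfer_approx = ch_a,
              chamfer_refined = NA_real_, chamfer_final = ch_a,
              refinement_accepted = FALSE)
  if (is.null(fsA) || is.null(fsB) ||
      nrow(fsA$points) == 0L || nrow(fsB$points) == 0L) return(out)
  zt <- apply_transform(approx_T, cbind(fsB$points$x, fsB$points$y))
  fsB$points$xt <- zt[, 1]; fsB$points$yt <- zt[, 2]
  rc <- refinement_config(beta = config$beta, delta = config$delta_um,
                          max_iter = config$max_iter, tol = config$tol,
                          outlier_w = config$outlier_w,
                          mass_floor = config$mass_floor)
  res <- cpd_rigid(fsB, fsA, rc, approx_T = approx_T)
  out$refinement <- res
  ch_r <- chamfer_distance(boundaryA, apply_transform(res$transform, boundaryB$points))
  out$chamfer_refined <- ch_r
  if (is.na(res$fallback) && ch_r <= ch_a) {
    out$transform <- res$transform
    out$chamfer_final <- ch_r
    out$refinement_accepted <- TRUE
  }
  out
}

#' Register a whole case of serial sections
#'
#' Registers each slide to its predecessor and composes the pairwise
#' transforms toward the reference slide. Any pair whose refinement fails
#' falls back to its approximate transform; a failed pair never aborts the
#' case.
#'
#' @param slides list of slides; each a list with at least `boundary`
#'   (a [boundary()]) and optionally `nuclei`/`fat` ground-truth tables or
#'   `plane` + `mask` for image-based feature detection.
#' @param reference_index index of the reference slide (default 1).
#' @param config parameter list, see [default_config()].
#' @param features how to obtain feature sets: `"auto"` uses
#'   `plane`/`mask` when present, else structure tables, else none.
#' @return list with `pair_results`, `composed_transforms` (one per slide,
#'   mapping that slide's frame into the reference frame), and `report`
#'   (data frame with approximate and refined Chamfer columns).
#' @export
register_case <- function(slides, reference_index = 1L,
                          config = default_config(), features = "auto") {
  n <- length(slides)
  stopifnot(n >= 2L, reference_index >= 1L, reference_index <= n)
  fs_of <- function(sl) {
    if (!identical(features, "auto")) return(NULL)
    if (!is.null(sl$plane) && !is.null(sl$mask)) {
      return(tryCatch(build_feature_set(sl$plane, sl$mask,
                                        identity_transform(), config),
                      error = function(e) NULL))
    }
    if (!is.null(sl$nuclei) || !is.null(sl$fat)) {
      return(tryCatch(feature_set_from_structures(sl$nuclei, sl$fat, config),
                      error = function(e) NULL))
    }
    NULL
  }
  fsets <- lapply(slides, fs_of)
  pair_results <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    pair_results[[i]] <- tryCatch(
      register_pair(slides[[i]]$boundary, slides[[i + 1L]]$boundary,
                    fsets[[i]], fsets[[i + 1L]], config),
      error = function(e) {
        warning("pair ", i, " failed (", conditionMessage(e),
                "); keeping identity")
        list(transform = identity_transform(),
             approx_transform = identity_transform(), refinement = NULL,
             chamfer_approx = NA_real_, chamfer_refined = NA_real_,
             chamfer_final = NA_real_, refinement_accepted = FALSE)
      })
  }
  # compose toward the reference: transform of slide j maps j's frame into
  # the reference frame; pair i maps slide i+1 into slide i
  composed <- vector("list", n)
  composed[[reference_index]] <- identity_transform()
  if (reference_index < n) {
    for (j in (reference_index + 1L):n) {
      composed[[j]] <- compose_transform(composed[[j - 1L]],
                                         pair_results[[j - 1L]]$transform)
    }
  }
  if (reference_index > 1L) {
    for (j in (reference_index - 1L):1L) {
      composed[[j]] <- compose_transform(composed[[j + 1L]],
                                         invert_transform(pair_results[[j]]$transform))
    }
  }
  report <- data.frame(
    pair = paste(seq_len(n - 1L), seq(2L, n), sep = "-"),
    chamfer_approx = vapply(pair_results, `[[`, numeric(1), "chamfer_approx"),
    chamfer_refined = vapply(pair_results, function(p) {
      if (is.na(p$chamfer_refined)) p$chamfer_final else p$chamfer_refined
    }, numeric(1)),
    chamfer_final = vapply(pair_results, `[[`, numeric(1), "chamfer_final"),
    refinement_accepted = vapply(pair_results, `[[`, logical(1),
                                 "refinement_accepted"))
  list(pair_results = pair_results, composed_transforms = composed,
       report = report, reference_index = reference_index)
}

#' Build a feature set from ground-truth structure tables
#'
#' Convenience used for fixture slides that carry nuclei / fat coordinate
#' tables instead of rendered images: nuclei are clustered (DBSCAN) and
#' converted to lattices exactly as in the image pipeline.
#'
#' @param nuclei data frame with `x`, `y` (microns), or `NULL`.
#' @param fat data frame with `x`, `y` (microns), or `NULL`.
#' @param config parameter list, see [default_config()].
#' @return a [feature_set()].
#' @export
feature_set_from_structures <- function(nuclei = NULL, fat = NULL,
                                        config = default_config()) {
  pts <- NULL
  if (!is.null(nuclei) && nrow(nuclei)) {
    lab <- cluster_nuclei(cbind(nuclei$x, nuclei$y),
                          eps = config$eps_um, min_pts = config$min_pts)
    for (cl in setdiff(unique(lab), -1L)) {
      mem <- cbind(nuclei$x[lab == cl], nuclei$y[lab == cl])
      pts <- rbind(pts, cluster_to_points(mem, density = config$density,
                                          region_radius = config$eps_um,
                                          source_id = cl))
    }
  }
  df <- rbind(
    if (!is.null(fat) && nrow(fat))
      data.frame(ftype = "fat", source_id = seq_len(nrow(fat)),
                 x = fat$x, y = fat$y),
    pts)
  if (is.null(df))
    df <- data.frame(ftype = character(0), source_id = integer(0),
                     x = numeric(0), y = numeric(0))
  df$xt <- df$x; df$yt <- df$y
  feature_set(df)
}
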