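#' Default pipeline parameters
#'
#' Central defaults for every stage. Notable values: boundaries carry
#' `n_points = 2000` points; the refinement gate has radius `delta_um = 33`
#' microns with exponent `beta = 1`; nuclei-cluster lattices use a density
#' of 0.004 points per square micron; scoring samples 10 fields of view of
#' 1000 x 1000 px at 0.55 um/px (20x).
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    # boundary / CSS
    n_points = 2000L,
    css_levels = 16L,
    sigma_min = 2,
    sigma_max = NULL,          # NULL -> n_points / 16
    # segmentation
    seg_mpp = 8,
    classify_mpp = 4,
    entropy_radius = 5,
    min_region_area_um2 = 5e5,
    # feature detection
    refine_mpp = 2.2,
    bg_k = 2,
    eps_um = 30,
    min_pts = 5L,
    density = 0.004,
    nucleus_area_um2 = c(10, 300),
    # CPD refinement
    delta_um = 33,
    beta = 1,
    outlier_w = 0.1,
    max_iter = 100L,
    tol = 1e-6,
    mass_floor = 5,
    # scoring
    n_fovs = 10L,
    fov_px = 1000L,
    score_mpp = 0.55,
    dab_positive_od = 0.15,
    intensity_cutpoints = c(0.15, 0.40, 0.80),
    tie_rounds = 3L
  )
}

#' Merge configuration from file and overrides
#'
#' Precedence: package defaults, overridden by a YAML file, overridden by
#' explicit `overrides` (e.g. command-line flags). Unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML config file, or `NULL`.
#' @param overrides named list of final overrides.
#' @return merged parameter list with attribute `"provenance"`.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  merge_into <- function(cfg, vals, src) {
    unknown <- setdiff(names(vals), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s) in ", src, ": ",
           paste(unknown, collapse = ", "))
    for (k in names(vals)) cfg[[k]] <- vals[[k]]
    cfg
  }
  if (!is.null(path)) {
    vals <- tryCatch(yaml::read_yaml(path), error = function(e) {
      stop("malformed config file ", path, ": ", conditionMessage(e))
    })
    if (is.null(vals)) vals <- list()
    cfg <- merge_into(cfg, vals, path)
  }
  if (length(overrides)) cfg <- merge_into(cfg, overrides, "overrides")
  attr(cfg, "provenance") <- list(file = path, overrides = names(overrides))
  cfg
}
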