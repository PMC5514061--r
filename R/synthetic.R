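#' Synthetic serial-section fixtures
#'
#' Deterministic generators of tissue-section-like images and boundaries:
#' blob-shaped silhouettes from low-order random Fourier perturbations of a
#' circle, nuclei stamped as stained discs grouped into Gaussian clusters,
#' fat pockets as white discs ringed by a dark connective-tissue rim, and
#' stain colouring by a Beer-Lambert forward model (haematoxylin, eosin,
#' DAB). Serial pairs and multi-slide cases come with known rigid ground
#' truth and a controllable fraction of structures shared between sections,
#' so every registration and scoring stage can be tested without any
#' external data.
#'
#' @name synthetic_fixtures
NULL

# stain OD vectors (columns: haematoxylin, eosin, DAB), unit length
ruifrok_vectors <- function() {
  v <- cbind(h = c(0.650, 0.704, 0.286),
             e = c(0.072, 0.990, 0.105),
             d = c(0.268, 0.570, 0.776))
  sweep(v, 2L, sqrt(colSums(v^2)), "/")
}

#' Section specification
#'
#' @param seed integer seed fixing every random draw of the section.
#' @param radius_um mean blob radius.
#' @param blob_complexity highest Fourier harmonic of the outline (2..).
#' @param blob_amp relative amplitude of the outline harmonics.
#' @param n_nuclei_clusters number of nuclei clusters.
#' @param nuclei_per_cluster mean nuclei per cluster.
#' @param cluster_sd_um spread of each cluster.
#' @param n_fat_pockets number of fat pockets.
#' @param stain_profile one of `"HE"`, `"ER"`, `"PR"`,
#'   `"negative_control"`.
#' @param positive_fraction fraction of DAB-positive nuclei (IHC profiles).
#' @param dab_od mean DAB optical density of positive nuclei.
#' @param mpp rendering resolution, microns per pixel.
#' @param field_um rendered field side length, microns.
#' @param artefact_rect optional `c(x, y, w, h)` rectangle (microns) in
#'   which a smudge-like artefact is painted: high entropy at coarse
#'   scale, locally smooth, so the entropy filter captures it but the
#'   texture classifier can reject it.
#' @return a `section_spec` list.
#' @export
section_spec <- function(seed, radius_um = 800, blob_complexity = 8L,
                         blob_amp = 0.12, n_nuclei_clusters = 6L,
                         nuclei_per_cluster = 50L, cluster_sd_um = 60,
                         n_fat_pockets = 3L, stain_profile = "HE",
                         positive_fraction = 0, dab_od = 0,
                         mpp = 2.5, field_um = 3000, artefact_rect = NULL) {
  stopifnot(stain_profile %in% c("HE", "ER", "PR", "negative_control"),
            n_nuclei_clusters >= 0, n_fat_pockets >= 0)
  structure(as.list(environment()), class = "section_spec")
}

# radial outline function r(phi) built from seeded Fourier harmonics
blob_radial <- function(seed, radius_um, harmonics = 2:8, amp = 0.12) {
  rng <- local({ set.seed(seed); list(a = runif(length(harmonics), 0.3, 1),
                                      ph = runif(length(harmonics), 0, 2 * pi)) })
  a <- amp * rng$a / sqrt(seq_along(harmonics))
  a <- a * min(1, 0.35 / sum(a * harmonics))  # cap slope: keep curve simple
  function(phi) {
    out <- rep(1, length(phi))
    for (k in seq_along(harmonics)) out <- out + a[k] * cos(harmonics[k] * phi + rng$ph[k])
    radius_um * out
  }
}

# boundary from a radial function, equally spaced, CCW, deterministic start
radial_boundary <- function(rfun, center, N, dense = 8L * N) {
  phi <- (0:(dense - 1)) * 2 * pi / dense
  r <- rfun(phi)
  verts <- cbind(center[1] + r * cos(phi), center[2] + r * sin(phi))
  if (shoelace_area(verts) < 0) verts <- verts[rev(seq_len(nrow(verts))), ]
  start <- order(verts[, 2], verts[, 1])[1]
  boundary(resample_closed(verts, N, start_idx = start))
}

#' Generate an analytic blob boundary
#'
#' @param seed integer seed.
#' @param N number of points.
#' @param radius_um mean radius.
#' @param amp harmonic amplitude.
#' @param harmonics Fourier harmonics of the outline.
#' @param center blob center, microns.
#' @return a [boundary()].
#' @export
generate_blob_boundary <- function(seed, N = 2000, radius_um = 800,
                                   amp = 0.12, harmonics = 2:8,
                                   center = c(0, 0)) {
  radial_boundary(blob_radial(seed, radius_um, harmonics, amp), center, N)
}

# seeded structure layout: cluster centers, nuclei, fat pockets, all in um
section_structures <- function(spec, rfun, center) {
  set.seed(spec$seed + 1L)
  sample_inside <- function(n, margin = 0.75) {
    out <- matrix(0, 0, 2)
    while (nrow(out) < n) {
      phi <- runif(2 * n, 0, 2 * pi)
      rr <- sqrt(runif(2 * n)) * margin * rfun(phi)
      cand <- cbind(center[1] + rr * cos(phi), center[2] + rr * sin(phi))
      out <- rbind(out, cand)
    }
    out[seq_len(n), , drop = FALSE]
  }
  ncl <- spec$n_nuclei_clusters
  cl_centers <- if (ncl > 0) sample_inside(ncl) else matrix(0, 0, 2)
  nuclei <- NULL
  for (i in seq_len(ncl)) {
    nn <- max(5L, rpois(1, spec$nuclei_per_cluster))
    pts <- cbind(rnorm(nn, cl_centers[i, 1], spec$cluster_sd_um),
                 rnorm(nn, cl_centers[i, 2], spec$cluster_sd_um))
    nuclei <- rbind(nuclei, cbind(pts, i))
  }
  nf <- spec$n_fat_pockets
  fat <- if (nf > 0) cbind(sample_inside(nf, margin = 0.55),
                           runif(nf, 45, 75)) else matrix(0, 0, 3)
  list(cluster_centers = cl_centers,
       nuclei = if (is.null(nuclei))
         data.frame(x = numeric(0), y = numeric(0), cluster = integer(0))
       else data.frame(x = nuclei[, 1], y = nuclei[, 2], cluster = nuclei[, 3]),
       fat = data.frame(x = fat[, 1], y = fat[, 2], r = fat[, 3]))
}

# stamp a disc of optical density into a channel matrix (um geometry)
stamp_disc <- function(ch, mpp, cx, cy, r_um, od) {
  r_px <- r_um / mpp
  x0 <- max(1L, floor(cx / mpp - r_px)); x1 <- min(ncol(ch), ceiling(cx / mpp + r_px) + 1L)
  y0 <- max(1L, floor(cy / mpp - r_px)); y1 <- min(nrow(ch), ceiling(cy / mpp + r_px) + 1L)
  if (x0 > x1 || y0 > y1) return(ch)
  xs <- ((x0:x1) - 1) * mpp; ys <- ((y0:y1) - 1) * mpp
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  blk <- ch[y0:y1, x0:x1, drop = FALSE]
  inside <- d2 <= r_um^2
  blk[inside] <- pmax(blk[inside], od)
  ch[y0:y1, x0:x1] <- blk
  ch
}

#' Render a synthetic tissue section
#'
#' Produces an RGB [image_plane()] plus complete ground truth: the true
#' tissue mask and N-point boundary, nuclei positions with their cluster
#' labels, DAB positivity per nucleus, and fat-pocket centers/radii.
#'
#' @param spec a [section_spec()].
#' @param n_boundary_points points on the emitted ground-truth boundary.
#' @return list with `plane`, `mask` (truth, [tissue_mask()]), `boundary`
#'   (truth), `nuclei`, `fat`, `cluster_centers`, `spec`.
#' @export
generate_section <- function(spec, n_boundary_points = 2000L) {
  stopifnot(inherits(spec, "section_spec"))
  mpp <- spec$mpp
  npx <- as.integer(ceiling(spec$field_um / mpp))
  center <- c(spec$field_um / 2, spec$field_um / 2)
  rfun <- blob_radial(spec$seed, spec$radius_um, harmonics = 2:spec$blob_complexity,
                      amp = spec$blob_amp)
  st <- section_structures(spec, rfun, center)

  xs <- ((seq_len(npx)) - 1) * mpp
  X <- matrix(rep(xs, each = npx), npx, npx)
  Y <- matrix(rep(xs, times = npx), npx, npx)
  phi <- atan2(Y - center[2], X - center[1])
  rr <- sqrt((X - center[1])^2 + (Y - center[2])^2)
  tissue <- rr <= rfun(phi)

  set.seed(spec$seed + 2L)
  h_od <- matrix(0, npx, npx)
  e_od <- matrix(0, npx, npx)
  d_od <- matrix(0, npx, npx)
  # counterstain + texture inside tissue (texture drives the entropy filter)
  e_base <- if (spec$stain_profile == "HE") 0.35 else 0.12
  e_od[tissue] <- e_base + abs(rnorm(sum(tissue), 0, 0.10))
  h_od[tissue] <- 0.06 + abs(rnorm(sum(tissue), 0, 0.05))

  nuc <- st$nuclei
  positive <- logical(nrow(nuc))
  if (nrow(nuc)) {
    set.seed(spec$seed + 3L)
    radii <- runif(nrow(nuc), 3.6, 4.8)
    if (spec$stain_profile %in% c("ER", "PR") && spec$positive_fraction > 0) {
      positive <- runif(nrow(nuc)) < spec$positive_fraction
    }
    for (i in seq_len(nrow(nuc))) {
      if (!tissue[pmin(pmax(round(nuc$y[i] / mpp) + 1, 1), npx),
                  pmin(pmax(round(nuc$x[i] / mpp) + 1, 1), npx)]) next
      h_od <- stamp_disc(h_od, mpp, nuc$x[i], nuc$y[i], radii[i], 0.75)
      if (positive[i])
        d_od <- stamp_disc(d_od, mpp, nuc$x[i], nuc$y[i], radii[i], spec$dab_od)
    }
    nuc$radius_um <- radii
  }
  nuc$positive <- positive

  fat <- st$fat
  for (i in seq_len(nrow(fat))) {
    rim <- fat$r[i] + 7
    # dark connective rim, then clear interior
    e_od <- stamp_disc(e_od, mpp, fat$x[i], fat$y[i], rim, 1.1)
    h_od <- stamp_disc(h_od, mpp, fat$x[i], fat$y[i], rim, 0.5)
    r_px <- fat$r[i] / mpp
    x0 <- max(1L, floor(fat$x[i] / mpp - r_px)); x1 <- min(npx, ceiling(fat$x[i] / mpp + r_px) + 1L)
    y0 <- max(1L, floor(fat$y[i] / mpp - r_px)); y1 <- min(npx, ceiling(fat$y[i] / mpp + r_px) + 1L)
    xs2 <- ((x0:x1) - 1) * mpp; ys2 <- ((y0:y1) - 1) * mpp
    d2 <- outer((ys2 - fat$y[i])^2, (xs2 - fat$x[i])^2, "+")
    inside <- d2 <= fat$r[i]^2
    for (ch in c("h_od", "e_od", "d_od")) {
      m <- get(ch); blk <- m[y0:y1, x0:x1, drop = FALSE]
      blk[inside] <- 0
      m[y0:y1, x0:x1] <- blk
      assign(ch, m)
    }
  }

  if (spec$stain_profile == "negative_control") d_od[] <- 0
  h_od[!tissue] <- 0; e_od[!tissue] <- 0; d_od[!tissue] <- 0

  V <- ruifrok_vectors()
  od_rgb <- array(0, dim = c(npx, npx, 3))
  for (k in 1:3)
    od_rgb[, , k] <- V[k, "h"] * h_od + V[k, "e"] * e_od + V[k, "d"] * d_od
  rgb <- 255 * 10^(-od_rgb)
  if (!is.null(spec$artefact_rect)) {
    rgb <- paint_smudge(rgb, spec$artefact_rect, mpp, seed = spec$seed + 9L)
  }
  set.seed(spec$seed + 4L)
  sensor <- matrix(rnorm(npx * npx, 0, 1.2), npx, npx)
  for (k in 1:3) rgb[, , k] <- pmin(pmax(rgb[, , k] * (250 / 255) + sensor, 0), 255)

  list(plane = image_plane(rgb, mpp),
       mask = tissue_mask(tissue * 1, mpp),
       boundary = radial_boundary(rfun, center, n_boundary_points),
       nuclei = nuc, fat = fat, cluster_centers = st$cluster_centers,
       rfun = rfun, center = center, spec = spec)
}

#' Serial-pair specification
#'
#' @param base a [section_spec()] for the first section.
#' @param true_transform [rigid_transform()] mapping the second section's
#'   frame into the first's (the registration ground truth).
#' @param persistence fraction of structures shared between the two
#'   sections (0-1).
#' @param boundary_noise_um RMS radial perturbation of the second
#'   section's outline.
#' @param jitter_um per-structure positional jitter of shared structures.
#' @param perturb_seed seed governing which structures persist and how the
#'   outline is perturbed (defaults to the base section's seed); giving
#'   different values produces different serial neighbours of one block.
#' @return a `serial_pair_spec` list.
#' @export
serial_pair_spec <- function(base, true_transform = rigid_transform(),
                             persistence = 0.8, boundary_noise_um = 35,
                             jitter_um = 4, perturb_seed = NULL) {
  stopifnot(inherits(base, "section_spec"), persistence >= 0, persistence <= 1)
  if (is.null(perturb_seed)) perturb_seed <- base$seed
  structure(list(base = base, true_transform = true_transform,
                 persistence = persistence,
                 boundary_noise_um = boundary_noise_um,
                 jitter_um = jitter_um, perturb_seed = perturb_seed),
            class = "serial_pair_spec")
}

# high-order harmonic radial noise with given RMS amplitude (um)
radial_noise <- function(seed, rms_um) {
  set.seed(seed)
  ks <- 9:16
  a <- rnorm(length(ks)); ph <- runif(length(ks), 0, 2 * pi)
  a <- a / sqrt(sum(a^2) / 2) * rms_um   # RMS of sum of cosines = sqrt(sum a^2/2)
  function(phi) {
    out <- numeric(length(phi))
    for (k in seq_along(ks)) out <- out + a[k] * cos(ks[k] * phi + ph[k])
    out
  }
}

#' Generate a serial section pair with known rigid ground truth
#'
#' The second section shares a `persistence` fraction of the first's
#' clusters and fat pockets (the remainder are resampled), carries a
#' perturbed outline, and lives in its own frame: its content equals the
#' first section's perturbed content mapped through the inverse of
#' `true_transform`. Registering B onto A should therefore recover
#' `true_transform`.
#'
#' @param pair_spec a [serial_pair_spec()].
#' @param n_boundary_points boundary point count.
#' @param render if `TRUE`, render both sections as images; otherwise only
#'   boundaries and structure ground truth are produced (fast).
#' @return list with `A`, `B` (each: boundary, nuclei, fat,
#'   cluster_centers, and when rendered plane/mask), and `true_transform`.
#' @export
generate_serial_pair <- function(pair_spec, n_boundary_points = 2000L,
                                 render = FALSE) {
  stopifnot(inherits(pair_spec, "serial_pair_spec"))
  base <- pair_spec$base
  Tt <- pair_spec$true_transform
  Tinv <- invert_transform(Tt)
  center <- c(base$field_um / 2, base$field_um / 2)
  rfunA <- blob_radial(base$seed, base$radius_um, harmonics = 2:base$blob_complexity,
                       amp = base$blob_amp)
  stA <- section_structures(base, rfunA, center)

  # perturbed outline for section B (in A's frame)
  ps <- pair_spec$perturb_seed
  noise <- radial_noise(ps + 11L, pair_spec$boundary_noise_um)
  rfunB <- function(phi) rfunA(phi) + noise(phi)

  set.seed(ps + 12L)
  keep_cl <- runif(nrow(stA$cluster_centers)) < pair_spec$persistence
  keep_fat <- runif(nrow(stA$fat)) < pair_spec$persistence
  altspec <- base; altspec$seed <- ps + 13L
  stAlt <- section_structures(altspec, rfunB, center)
  jit <- function(m, sd) m + matrix(rnorm(length(m), 0, sd), nrow(m), ncol(m))

  ncl_new <- sum(!keep_cl)
  clB <- rbind(
    if (any(keep_cl)) jit(stA$cluster_centers[keep_cl, , drop = FALSE], pair_spec$jitter_um),
    if (ncl_new > 0) stAlt$cluster_centers[seq_len(ncl_new), , drop = FALSE])
  nucB_list <- list()
  kept_ids <- which(keep_cl)
  for (i in seq_along(kept_ids)) {
    sub <- stA$nuclei[stA$nuclei$cluster == kept_ids[i], c("x", "y")]
    sub <- as.data.frame(jit(as.matrix(sub), pair_spec$jitter_um))
    sub$cluster <- i
    nucB_list[[length(nucB_list) + 1L]] <- sub
  }
  for (j in seq_len(ncl_new)) {
    sub <- stAlt$nuclei[stAlt$nuclei$cluster == j, c("x", "y")]
    sub$cluster <- length(kept_ids) + j
    nucB_list[[length(nucB_list) + 1L]] <- sub
  }
  nucB <- if (length(nucB_list)) do.call(rbind, nucB_list) else stA$nuclei[0, ]
  nf_new <- sum(!keep_fat)
  fatB <- rbind(
    stA$fat[keep_fat, , drop = FALSE],
    stAlt$fat[seq_len(min(nf_new, nrow(stAlt$fat))), , drop = FALSE])

  # map section-B content into B's own frame
  to_B <- function(m) if (nrow(m)) apply_transform(Tinv, m) else m
  boundaryA <- radial_boundary(rfunA, center, n_boundary_points)
  bBpts_A <- radial_boundary(rfunB, center, n_boundary_points)$points
  bBpts <- apply_transform(Tinv, bBpts_A)
  # re-canonicalize B's boundary in its own frame (CCW + min-(y,x) start)
  startB <- order(bBpts[, 2], bBpts[, 1])[1]
  boundaryB <- boundary(resample_closed(bBpts, n_boundary_points, start_idx = startB))

  nucB_own <- nucB
  if (nrow(nucB)) nucB_own[, c("x", "y")] <- to_B(as.matrix(nucB[, c("x", "y")]))
  fatB_own <- fatB
  if (nrow(fatB)) fatB_own[, c("x", "y")] <- to_B(as.matrix(fatB[, c("x", "y")]))

  A <- list(boundary = boundaryA, nuclei = stA$nuclei, fat = stA$fat,
            cluster_centers = stA$cluster_centers)
  B <- list(boundary = boundaryB, nuclei = nucB_own, fat = fatB_own,
            cluster_centers = to_B(clB))
  if (render) {
    secA <- generate_section(base, n_boundary_points)
    A <- utils::modifyList(secA[c("plane", "mask", "boundary", "nuclei", "fat",
                                  "cluster_centers")], A["boundary"])
    B <- c(B, render_section_from_truth(base, rfunB, center, Tinv, nucB_own,
                                        fatB_own, n_boundary_points))
  }
  list(A = A, B = B, true_transform = Tt, pair_spec = pair_spec)
}

# render section B: its outline is rfunB in A's frame mapped through Tinv
render_section_from_truth <- function(base, rfunB, centerA, Tinv, nuclei, fat,
                                      n_boundary_points) {
  mpp <- base$mpp
  npx <- as.integer(ceiling(base$field_um / mpp))
  xs <- ((seq_len(npx)) - 1) * mpp
  X <- matrix(rep(xs, each = npx), npx, npx)
  Y <- matrix(rep(xs, times = npx), npx, npx)
  # tissue test in A's frame
  pA <- apply_transform(invert_transform(Tinv), cbind(as.vector(X), as.vector(Y)))
  phi <- atan2(pA[, 2] - centerA[2], pA[, 1] - centerA[1])
  rr <- sqrt((pA[, 1] - centerA[1])^2 + (pA[, 2] - centerA[2])^2)
  tissue <- matrix(rr <= rfunB(phi), npx, npx)

  set.seed(base$seed + 2L)
  h_od <- matrix(0, npx, npx); e_od <- matrix(0, npx, npx); d_od <- matrix(0, npx, npx)
  e_base <- if (base$stain_profile == "HE") 0.35 else 0.12
  e_od[tissue] <- e_base + abs(rnorm(sum(tissue), 0, 0.10))
  h_od[tissue] <- 0.06 + abs(rnorm(sum(tissue), 0, 0.05))
  if (nrow(nuclei)) {
    set.seed(base$seed + 3L)
    radii <- runif(nrow(nuclei), 3.6, 4.8)
    for (i in seq_len(nrow(nuclei)))
      h_od <- stamp_disc(h_od, mpp, nuclei$x[i], nuclei$y[i], radii[i], 0.75)
  }
  for (i in seq_len(nrow(fat))) {
    rim <- fat$r[i] + 7
    e_od <- stamp_disc(e_od, mpp, fat$x[i], fat$y[i], rim, 1.1)
    h_od <- stamp_disc(h_od, mpp, fat$x[i], fat$y[i], rim, 0.5)
    r_px <- fat$r[i] / mpp
    x0 <- max(1L, floor(fat$x[i] / mpp - r_px)); x1 <- min(npx, ceiling(fat$x[i] / mpp + r_px) + 1L)
    y0 <- max(1L, floor(fat$y[i] / mpp - r_px)); y1 <- min(npx, ceiling(fat$y[i] / mpp + r_px) + 1L)
    if (x0 > x1 || y0 > y1) next
    xs2 <- ((x0:x1) - 1) * mpp; ys2 <- ((y0:y1) - 1) * mpp
    d2 <- outer((ys2 - fat$y[i])^2, (xs2 - fat$x[i])^2, "+")
    inside <- d2 <= fat$r[i]^2
    for (ch in c("h_od", "e_od", "d_od")) {
      m <- get(ch); blk <- m[y0:y1, x0:x1, drop = FALSE]
      blk[inside] <- 0
      m[y0:y1, x0:x1] <- blk
      assign(ch, m)
    }
  }
  h_od[!tissue] <- 0; e_od[!tissue] <- 0; d_od[!tissue] <- 0
  V <- ruifrok_vectors()
  rgb <- array(0, dim = c(npx, npx, 3))
  for (k in 1:3)
    rgb[, , k] <- 255 * 10^(-(V[k, "h"] * h_od + V[k, "e"] * e_od + V[k, "d"] * d_od))
  set.seed(base$seed + 4L)
  sensor <- matrix(rnorm(npx * npx, 0, 1.2), npx, npx)
  for (k in 1:3) rgb[, , k] <- pmin(pmax(rgb[, , k] * (250 / 255) + sensor, 0), 255)
  list(plane = image_plane(rgb, mpp), mask = tissue_mask(tissue * 1, mpp))
}

#' Generate a multi-slide case with chained ground truth
#'
#' Emulates a case of serial sections (5-slide breast-style or 10-slide
#' lymph-node-style stacks): consecutive serial pairs are chained, each
#' adjacent pair carrying its own true rigid transform. Composed transforms
#' toward slide 1 are returned for case-wide checks.
#'
#' @param n_slides number of slides (>= 2).
#' @param stains character vector of stain labels, recycled to
#'   `n_slides`; labels containing "ER"/"PR" get an IHC profile,
#'   "negative" a negative control, anything else H&E-like.
#' @param seed master seed.
#' @param render render images for every slide.
#' @param persistence,boundary_noise_um,jitter_um serial-pair parameters,
#'   see [serial_pair_spec()].
#' @param ... passed to [section_spec()] for the base section.
#' @return list with `slides` (each as from [generate_serial_pair()]'s
#'   sections), `pair_transforms` (slide i+1 -> slide i), and
#'   `composed_transforms` (slide i -> slide 1).
#' @export
generate_case <- function(n_slides = 5L, stains = c("ER", "PR", "HER2", "HE", "negative"),
                          seed = 1L, render = FALSE, persistence = 0.8,
                          boundary_noise_um = 35, jitter_um = 4, ...) {
  stopifnot(n_slides >= 2L)
  stains <- rep_len(stains, n_slides)
  set.seed(seed)
  thetas <- runif(n_slides - 1L, -20, 20) * pi / 180
  shifts <- matrix(runif(2L * (n_slides - 1L), -150, 150), ncol = 2L)
  base <- section_spec(seed = seed * 1000L, ...)
  # composed ground truth: C[[j]] maps slide j's frame into slide 1's frame
  composed <- vector("list", n_slides)
  composed[[1L]] <- identity_transform()
  for (i in seq_len(n_slides - 1L)) {
    T_step <- rigid_transform(thetas[i], t = shifts[i, ],
                              center = c(base$field_um / 2, base$field_um / 2))
    composed[[i + 1L]] <- compose_transform(composed[[i]], T_step)
  }
  # every slide is an independently perturbed copy of the same base
  # section (so adjacent slides share ~persistence^2 of their structures),
  # placed in its own frame through the inverse composed truth
  slides <- vector("list", n_slides)
  for (j in seq_len(n_slides)) {
    if (j == 1L) {
      pair <- generate_serial_pair(
        serial_pair_spec(base, identity_transform(), persistence = 1,
                         boundary_noise_um = 1e-9, jitter_um = 0),
        render = render)
      slides[[j]] <- c(pair$A, list(stain = stains[j]))
    } else {
      pair <- generate_serial_pair(
        serial_pair_spec(base, composed[[j]], persistence = persistence,
                         boundary_noise_um = boundary_noise_um,
                         jitter_um = jitter_um,
                         perturb_seed = base$seed + j * 7L),
        render = render)
      slides[[j]] <- c(pair$B, list(stain = stains[j]))
    }
  }
  pair_transforms <- vector("list", n_slides - 1L)
  for (i in seq_len(n_slides - 1L)) {
    pair_transforms[[i]] <- compose_transform(invert_transform(composed[[i]]),
                                              composed[[i + 1L]])
  }
  list(slides = slides, pair_transforms = pair_transforms,
       composed_transforms = composed, stains = stains, seed = seed)
}

#' Render a stained field of view with planted Allred ground truth
#'
#' Uniformly scattered nuclei, a planted fraction of which carry DAB at a
#' planted optical density; used to test the scoring chain end to end.
#'
#' @param seed integer seed.
#' @param n_nuclei nuclei in the field.
#' @param positive_fraction fraction of DAB-positive nuclei.
#' @param dab_od DAB optical density of positive nuclei.
#' @param size_px field side, pixels.
#' @param mpp microns per pixel.
#' @return list with `plane`, `nuclei` data frame, and the planted values.
#' @export
generate_fov <- function(seed, n_nuclei = 150L, positive_fraction = 0,
                         dab_od = 0, size_px = 300L, mpp = 1) {
  set.seed(seed)
  field <- size_px * mpp
  # minimum-separation placement so stamped nuclei stay resolvable
  pts <- matrix(numeric(0), 0, 2)
  min_sep <- 11
  tries <- 0L
  while (nrow(pts) < n_nuclei && tries < 200L * n_nuclei) {
    tries <- tries + 1L
    cand <- c(runif(1, 8, field - 8), runif(1, 8, field - 8))
    if (nrow(pts) == 0L ||
        min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= min_sep^2)
      pts <- rbind(pts, cand)
  }
  n_nuclei <- nrow(pts)
  nuc <- data.frame(x = pts[, 1], y = pts[, 2])
  nuc$positive <- runif(n_nuclei) < positive_fraction
  nuc$radius_um <- runif(n_nuclei, 3.6, 4.4)
  h_od <- matrix(0, size_px, size_px)
  d_od <- matrix(0, size_px, size_px)
  e_od <- matrix(0.10, size_px, size_px)
  for (i in seq_len(n_nuclei)) {
    h_od <- stamp_disc(h_od, mpp, nuc$x[i], nuc$y[i], nuc$radius_um[i], 0.75)
    if (nuc$positive[i])
      d_od <- stamp_disc(d_od, mpp, nuc$x[i], nuc$y[i], nuc$radius_um[i], dab_od)
  }
  V <- ruifrok_vectors()
  rgb <- array(0, dim = c(size_px, size_px, 3))
  for (k in 1:3)
    rgb[, , k] <- 255 * 10^(-(V[k, "h"] * h_od + V[k, "e"] * e_od + V[k, "d"] * d_od))
  sensor <- matrix(rnorm(size_px^2, 0, 1), size_px, size_px)
  for (k in 1:3) rgb[, , k] <- pmin(pmax(rgb[, , k] + sensor, 0), 255)
  list(plane = image_plane(rgb, mpp), nuclei = nuc,
       positive_fraction = positive_fraction, dab_od = dab_od)
}

# paint a smudge artefact: coarse blotches (high entropy over a disc
# window) that are locally smooth (flat LBP codes)
paint_smudge <- function(rgb, rect_um, mpp, seed) {
  set.seed(seed)
  x0 <- max(1L, round(rect_um[1] / mpp)); y0 <- max(1L, round(rect_um[2] / mpp))
  w <- round(rect_um[3] / mpp); h <- round(rect_um[4] / mpp)
  x1 <- min(dim(rgb)[2], x0 + w); y1 <- min(dim(rgb)[1], y0 + h)
  hh <- y1 - y0 + 1L; ww <- x1 - x0 + 1L
  coarse_h <- max(2L, ceiling(hh / 12)); coarse_w <- max(2L, ceiling(ww / 12))
  field <- matrix(runif(coarse_h * coarse_w, 90, 210), coarse_h, coarse_w)
  blot <- resize_bilinear(field, hh, ww)
  for (k in 1:3) rgb[y0:y1, x0:x1, k] <- blot * c(0.95, 0.9, 1.0)[k]
  rgb
}

#' Synthetic training windows for the tissue/artefact classifier
#'
#' Renders a synthetic section and a synthetic smudge field with the same
#' appearance models as [generate_section()], downsampled to the
#' classification resolution, and cuts 64 x 64 grey windows from each:
#' windows inside the true tissue mask are labelled tissue, smudge windows
#' artefact. Retraining on user data is a matter of supplying real windows
#' to [train_tissue_classifier()] instead.
#'
#' @param seed integer seed.
#' @param n_per_class windows per class.
#' @param classify_mpp resolution the classifier operates at.
#' @return list with `windows` (list of matrices) and `labels`.
#' @export
synth_training_windows <- function(seed = 1L, n_per_class = 60L,
                                   classify_mpp = 4) {
  sec <- generate_section(section_spec(seed = seed, radius_um = 700,
                                       n_nuclei_clusters = 10L,
                                       field_um = 2000),
                          n_boundary_points = 400L)
  pl <- downsample_plane(sec$plane, classify_mpp)
  g <- plane_grey(pl)
  scale <- pl$mpp / sec$mask$mpp
  tissue_windows <- list()
  ys <- seq(1L, nrow(g) - 64L, by = 32L)
  xs <- seq(1L, ncol(g) - 64L, by = 32L)
  for (y in ys) for (x in xs) {
    my <- pmin(pmax(round((y:(y + 63)) * scale), 1L), nrow(sec$mask$mask))
    mx <- pmin(pmax(round((x:(x + 63)) * scale), 1L), ncol(sec$mask$mask))
    if (mean(sec$mask$mask[my, mx]) >= 0.98)
      tissue_windows[[length(tissue_windows) + 1L]] <- g[y:(y + 63), x:(x + 63)]
  }
  set.seed(seed + 1L)
  if (length(tissue_windows) > n_per_class)
    tissue_windows <- tissue_windows[sample(length(tissue_windows), n_per_class)]
  # smudge field: coarse blotches plus sensor noise, like slide artefacts
  smudge_px <- 64L * ceiling(sqrt(n_per_class)) + 64L
  art <- array(245, dim = c(smudge_px, smudge_px, 3))
  art <- paint_smudge(art, c(0, 0, smudge_px * classify_mpp,
                             smudge_px * classify_mpp), classify_mpp,
                      seed = seed + 2L)
  set.seed(seed + 3L)
  ga <- 0.299 * art[, , 1] + 0.587 * art[, , 2] + 0.114 * art[, , 3] +
    matrix(rnorm(smudge_px^2, 0, 1.2), smudge_px, smudge_px)
  art_windows <- list()
  for (y in seq(1L, smudge_px - 64L, by = 64L)) {
    for (x in seq(1L, smudge_px - 64L, by = 64L)) {
      art_windows[[length(art_windows) + 1L]] <- ga[y:(y + 63), x:(x + 63)]
    }
  }
  set.seed(seed + 4L)
  if (length(art_windows) > n_per_class)
    art_windows <- art_windows[sample(length(art_windows), n_per_class)]
  list(windows = c(tissue_windows, art_windows),
       labels = rep(c("tissue", "artefact"),
                    c(length(tissue_windows), length(art_windows))))
}
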