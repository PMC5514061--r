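test_that("background threshold estimation matches its definition", {
  # zero-variance background: threshold equals the mean exactly
  pl <- image_plane(array(240, dim = c(100, 100, 3)), 2)
  expect_equal(estimate_background_threshold(pl, c(10, 10, 100, 100)), 240)
  # seeded noisy background: mean - k*sd recomputed directly
  set.seed(12)
  g <- matrix(rnorm(100 * 100, 240, 3), 100, 100)
  pl2 <- image_plane(g, 2)
  thr <- estimate_background_threshold(pl2, c(20, 20, 80, 80), k = 2)
  xs <- 11:50; ys <- 11:50
  expect_equal(thr, mean(g[ys, xs]) - 2 * sd(g[ys, xs]), tolerance = 1e-9)
  # rectangle inside tissue errors
  tm <- tissue_mask(matrix(1, 100, 100), 2)
  expect_error(estimate_background_threshold(pl, c(10, 10, 50, 50), tm),
               "overlaps")
})

fat_fixture <- function() {
  # tissue field (grey 150) with a white disc ringed by dark connective
  # tissue, plus a white region open to the glass edge
  g <- matrix(150, 120, 120)
  for (i in 1:120) for (j in 1:120) {
    d1 <- sqrt((i - 50)^2 + (j - 40)^2)
    if (d1 <= 13) g[i, j] <- 40            # dark rim
    if (d1 <= 9) g[i, j] <- 250            # fat interior
  }
  g[1:25, 90:120] <- 250                    # bright, touching the mask border
  mask <- matrix(1, 120, 120)
  list(plane = image_plane(g, 2), mask = tissue_mask(mask, 2))
}

test_that("fat detection requires a fully enclosing sub-threshold rim", {
  fx <- fat_fixture()
  fat <- detect_fat(fx$plane, 220, fx$mask)
  expect_equal(nrow(fat), 1L)
  expect_equal(fat$ftype, "fat")
  # centroid at the disc center within one pixel (coordinates in microns)
  expect_lt(abs(fat$x - 39 * 2), 2)
  expect_lt(abs(fat$y - 49 * 2), 2)
  # tissue with no holes yields nothing
  plain <- image_plane(matrix(150, 60, 60), 2)
  expect_equal(nrow(detect_fat(plain, 220, tissue_mask(matrix(1, 60, 60), 2))), 0L)
  # bright regions outside the tissue mask are ignored
  fx2 <- fat_fixture()
  m2 <- fx2$mask$mask; m2[, 100:120] <- 0
  fat2 <- detect_fat(fx2$plane, 220, tissue_mask(m2, 2))
  expect_equal(nrow(fat2), 1L)
  expect_equal(fat2$x, fat$x)
})

test_that("stain separation recovers Beer-Lambert mixtures", {
  V <- serialreg:::ruifrok_vectors()
  # pure white has zero optical density
  white <- image_plane(array(255, dim = c(20, 20, 3)), 1)
  st_w <- separate_stains(white, vectors = "ruifrok_he")
  expect_lt(max(st_w$h), 1e-6)
  # known haematoxylin concentration, no second stain
  conc_h <- 0.8
  px <- array(0, dim = c(30, 30, 3))
  for (k in 1:3) px[, , k] <- 255 * 10^(-V[k, "h"] * conc_h)
  st <- separate_stains(image_plane(px, 1), vectors = "ruifrok_he")
  expect_lt(abs(mean(st$h) - conc_h) / conc_h, 0.05)
  expect_lt(mean(st$second), 0.05)
  # mixed image: unmixing residual no worse than the pseudo-inverse oracle
  set.seed(13)
  ch <- matrix(runif(900, 0, 1), 30, 30)
  cd <- matrix(runif(900, 0, 0.8), 30, 30)
  px2 <- array(0, dim = c(30, 30, 3))
  for (k in 1:3) px2[, , k] <- 255 * 10^(-(V[k, "h"] * ch + V[k, "d"] * cd))
  st2 <- separate_stains(image_plane(px2, 1), vectors = "ruifrok_hdab")
  od <- sapply(1:3, function(k) as.vector(-log10(pmax(px2[, , k], 1) / 255)))
  S <- V[, c("h", "d")]
  oracle <- t(S %*% (solve(crossprod(S)) %*% t(S) %*% t(od)))
  res_oracle <- sum((od - oracle)^2)
  recon <- cbind(as.vector(st2$h), as.vector(st2$second)) %*%
    t(st2$stain_vectors)
  expect_lte(sum((od - recon)^2), res_oracle + 1e-6)
  # automatic estimation on a two-stain image lands near the truth
  st3 <- separate_stains(image_plane(px2, 1), vectors = "auto")
  expect_equal(st3$method, "macenko")
  expect_gt(abs(sum(st3$stain_vectors[, 1] * V[, "h"])), 0.95)
})

test_that("nucleus detection recovers planted discs within tolerance", {
  f <- generate_fov(seed = 3, n_nuclei = 50, size_px = 300, mpp = 1)
  st <- separate_stains(f$plane, vectors = "ruifrok_hdab")
  nuc <- detect_nuclei(st$h + st$second, 1)
  expect_gte(nrow(nuc), 48L); expect_lte(nrow(nuc), 52L)
  d <- sqrt(serialreg:::dist2(cbind(nuc$x, nuc$y),
                              cbind(f$nuclei$x, f$nuclei$y)))
  expect_lt(max(apply(d, 1, min)), 2)
  # blank channel: nothing detected
  expect_equal(nrow(detect_nuclei(matrix(0, 50, 50), 1)), 0L)
  # one giant smear above the area cap is excluded
  smear <- matrix(0, 80, 80); smear[10:70, 10:70] <- 1
  expect_equal(nrow(detect_nuclei(smear, 1, threshold = 0.5)), 0L)
})

test_that("DBSCAN clustering matches its definition on planted geometry", {
  set.seed(14)
  blob1 <- cbind(rnorm(30, 0, 5), rnorm(30, 0, 5))
  blob2 <- cbind(rnorm(30, 300, 5), rnorm(30, 300, 5))   # 10 x eps apart
  lab <- cluster_nuclei(rbind(blob1, blob2), eps = 30, min_pts = 5)
  expect_equal(length(setdiff(unique(lab), -1L)), 2L)
  expect_equal(length(unique(lab[1:30])), 1L)
  expect_equal(length(unique(lab[31:60])), 1L)
  # fewer than min_pts isolated points are all noise
  iso <- cbind(c(0, 1000, 2000, 3000), c(0, 0, 0, 0))
  expect_true(all(cluster_nuclei(iso, eps = 30, min_pts = 5) == -1L))
  # a single dense blob is one cluster containing every point
  expect_true(all(cluster_nuclei(blob1, eps = 30, min_pts = 5) == 1L))
})

test_that("cluster lattices have the stated density and spacing", {
  expect_equal(1 / sqrt(0.004), 15.811388, tolerance = 1e-6)
  # mask region of known area: count = density x area within 10%
  m <- matrix(0, 120, 120); m[11:110, 11:110] <- 1   # 100x100 px at mpp 1
  pts <- cluster_to_points(list(mask = m, mpp = 1), density = 0.004)
  expect_equal(nrow(pts), 0.004 * 10000, tolerance = 0.1)
  expect_true(all(pts$ftype == "nuclei_cluster"))
  # lattice spacing equals 1/sqrt(density)
  xs <- sort(unique(round(pts$x, 6)))
  expect_equal(min(diff(xs)), 15.811388, tolerance = 1e-4)
  # count scales linearly with area (slope = density within 10%)
  set.seed(15)
  for (rep in 1:5) {
    side <- sample(60:140, 1)
    mr <- matrix(0, side + 20, side + 20); mr[11:(10 + side), 11:(10 + side)] <- 1
    n_pts <- nrow(cluster_to_points(list(mask = mr, mpp = 1), density = 0.004))
    expect_equal(n_pts / side^2, 0.004, tolerance = 0.1)
  }
  # degenerate tiny cluster: exactly one point at the centroid
  tiny <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1))
  p1 <- cluster_to_points(tiny, density = 0.004, region_radius = 0.05)
  expect_equal(nrow(p1), 1L)
  expect_equal(c(p1$x, p1$y), colMeans(tiny), tolerance = 0.2)
})

test_that("splitting a cluster perturbs the lattice cloud only mildly", {
  set.seed(16)
  pts <- cbind(runif(60, 0, 200), runif(60, 0, 120))
  one <- cluster_to_points(pts, density = 0.004, region_radius = 30)
  split_a <- pts[pts[, 1] <= 100, , drop = FALSE]
  split_b <- pts[pts[, 1] > 100, , drop = FALSE]
  two <- rbind(cluster_to_points(split_a, density = 0.004, region_radius = 30),
               cluster_to_points(split_b, density = 0.004, region_radius = 30,
                                 source_id = 2L))
  sym_nn <- function(a, b) {
    d2 <- serialreg:::dist2(a, b)
    (mean(sqrt(apply(d2, 1, min))) + mean(sqrt(apply(d2, 2, min)))) / 2
  }
  d <- sym_nn(cbind(one$x, one$y), cbind(two$x, two$y))
  expect_lt(d / (1 / sqrt(0.004)), 0.6)   # well under one lattice spacing
})

test_that("build_feature_set fills both positions and falls back cleanly", {
  sec <- generate_section(section_spec(seed = 42, mpp = 2.5),
                          n_boundary_points = 200)
  fs <- build_feature_set(sec$plane, sec$mask, identity_transform())
  expect_s3_class(fs, "feature_set")
  expect_gt(nrow(fs$points), 10)
  expect_true(all(fs$points$ftype %in% c("fat", "nuclei_cluster")))
  # reference slide: z equals z~
  expect_equal(fs$points$x, fs$points$xt)
  expect_equal(fs$points$y, fs$points$yt)
  # a moving slide's z~ is the transformed z
  T1 <- rigid_transform(0.1, t = c(50, -20), center = c(1500, 1500))
  fs2 <- build_feature_set(sec$plane, sec$mask, T1)
  expect_equal(cbind(fs2$points$xt, fs2$points$yt),
               apply_transform(T1, cbind(fs2$points$x, fs2$points$y)),
               ignore_attr = TRUE)
  # featureless slide: empty set
  blank <- image_plane(array(245, dim = c(200, 200, 3)), 2.5)
  fs3 <- build_feature_set(blank, tissue_mask(matrix(0, 200, 200), 2.5))
  expect_equal(nrow(fs3$points), 0L)
})
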