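test_that("otsu_threshold equals the brute-force between-class optimum", {
  # exhaustive between-class-variance maximization; empty-bin stretches
  # give exact plateaus, resolved (as documented) at the plateau midpoint
  brute_otsu <- function(h) {
    p <- h / sum(h); lev <- 0:255
    sb <- rep(-Inf, 255)
    for (t in 0:254) {
      w0 <- sum(p[1:(t + 1)]); w1 <- 1 - w0
      if (w0 == 0 || w1 == 0) next
      m0 <- sum(p[1:(t + 1)] * lev[1:(t + 1)]) / w0
      m1 <- sum(p[(t + 2):256] * lev[(t + 2):256]) / w1
      sb[t + 1] <- w0 * w1 * (m0 - m1)^2
    }
    plateau <- which(sb >= max(sb) - 1e-12 * abs(max(sb))) - 1L
    as.integer(round(mean(plateau)))
  }
  # two delta masses
  h <- integer(256); h[10 + 1] <- 40; h[200 + 1] <- 60
  t1 <- otsu_threshold(h)
  expect_gt(t1, 10); expect_lt(t1, 200)
  expect_equal(t1, brute_otsu(h))
  # seeded two-Gaussian mixture
  set.seed(42)
  v <- round(c(rnorm(4000, 60, 12), rnorm(6000, 190, 15)))
  h2 <- tabulate(pmin(pmax(v, 0), 255) + 1L, nbins = 256L)
  expect_equal(otsu_threshold(h2), brute_otsu(h2))
  # degenerate single level
  h3 <- integer(256); h3[100] <- 50
  expect_error(otsu_threshold(h3), "degenerate")
})

test_that("entropy segmentation finds textured tissue and ignores flat areas", {
  # constant image: zero entropy everywhere -> empty mask with a warning
  flat <- image_plane(matrix(128, 80, 80), 8)
  expect_warning(tm0 <- entropy_segment(flat, 5), "blank")
  expect_equal(sum(tm0$mask), 0)
  # rendered blob: one region covering >= 95% of the true mask
  sec <- generate_section(section_spec(seed = 31), n_boundary_points = 200)
  pl8 <- downsample_plane(sec$plane, 8)
  tm <- entropy_segment(pl8, 5)
  expect_equal(nrow(tm$regions), 1L)
  truth <- (serialreg:::resize_bilinear(sec$mask$mask, nrow(tm$mask),
                                        ncol(tm$mask)) > 0.5) * 1
  expect_gt(sum(tm$mask * truth) / sum(truth), 0.95)
  # region bookkeeping: areas sum to the foreground count
  expect_equal(sum(tm$regions$area_px), sum(tm$mask))
  # a flat-grey "label" rectangle has no texture and is not captured
  lab <- pl8
  lab$pixels[5:30, 5:30, ] <- 120
  tml <- entropy_segment(lab, 5)
  expect_lt(mean(tml$mask[8:27, 8:27]), 0.05)
})

test_that("LBP descriptor has the documented invariances", {
  # constant window: all mass on the flat code
  d_flat <- lbp_descriptor(matrix(50, 64, 64))
  expect_equal(sum(d_flat), 1)
  expect_equal(d_flat[1], 1)
  # 90-degree rotation leaves the riu2 descriptor unchanged
  set.seed(2)
  w <- matrix(runif(64 * 64) * 255, 64, 64)
  rot90 <- t(w[64:1, ])
  expect_equal(lbp_descriptor(w), lbp_descriptor(rot90))
  # checkerboard and noise textures are far apart
  cb <- (outer(1:64, 1:64, "+") %% 2) * 255
  expect_gt(sum(abs(lbp_descriptor(cb) - lbp_descriptor(w))), 0.5)
  expect_error(lbp_descriptor(matrix(0, 32, 32)), "64 x 64")
})

test_that("classifier cleanup removes artefact regions, never adds foreground", {
  tw <- synth_training_windows(1, 40)
  model <- train_tissue_classifier(tw$windows, tw$labels)
  sec <- generate_section(section_spec(seed = 21, radius_um = 600,
                                       artefact_rect = c(60, 60, 800, 800)),
                          n_boundary_points = 200)
  pl8 <- downsample_plane(sec$plane, 8)
  tm <- entropy_segment(pl8, 5)
  expect_equal(nrow(tm$regions), 2L)   # tissue + smudge artefact
  pl4 <- downsample_plane(sec$plane, 4)
  cleaned <- classify_and_clean(tm, pl4, model)
  expect_equal(nrow(cleaned$regions), 1L)
  expect_true(all(cleaned$mask <= tm$mask))   # output subset of input
  truth <- (serialreg:::resize_bilinear(sec$mask$mask, nrow(tm$mask),
                                        ncol(tm$mask)) > 0.5) * 1
  expect_gt(sum(cleaned$mask * truth) / sum(truth), 0.9)
  # pass-through mode
  expect_identical(classify_and_clean(tm, pl4, NULL)$mask, tm$mask)
})

test_that("a region with a majority of rejected windows is removed whole", {
  # stub classifier driven by the LBP flat-bin mass (flat -> artefact)
  stub <- structure(list(), class = "stub_clf")
  assign("predict.stub_clf",
         function(object, newdata, ...) {
           ifelse(newdata[, 1] > 0.5, "artefact", "tissue")
         }, envir = globalenv())
  on.exit(rm("predict.stub_clf", envir = globalenv()))
  # one full region whose 2x plane is 60% flat (9 of 15 windows rejected)
  set.seed(6)
  m <- matrix(1, 96, 160)
  tm <- tissue_mask(m, 8)
  plane2x <- matrix(runif(192 * 320) * 255, 192, 320)
  plane2x[, 1:192] <- 120                      # flat band: 3 of 5 window columns
  cleaned <- classify_and_clean(tm, image_plane(plane2x, 4), stub)
  expect_equal(sum(cleaned$mask), 0)
  # with only 40% rejected the region survives, minus the rejected windows
  plane2x2 <- matrix(runif(192 * 320) * 255, 192, 320)
  plane2x2[, 1:128] <- 120                     # 2 of 5 window columns flat
  cleaned2 <- classify_and_clean(tm, image_plane(plane2x2, 4), stub)
  expect_gt(sum(cleaned2$mask), 0)
  expect_lt(sum(cleaned2$mask), sum(tm$mask))
  expect_true(all(cleaned2$mask <= tm$mask))
})

test_that("boundary extraction is deterministic with equal spacing", {
  sec <- generate_section(section_spec(seed = 31), n_boundary_points = 200)
  pl8 <- downsample_plane(sec$plane, 8)
  tm <- entropy_segment(pl8, 5)
  b1 <- extract_boundary(tm, N = 2000)
  b2 <- extract_boundary(tm, N = 2000)
  expect_identical(b1$points, b2$points)
  expect_equal(nrow(b1$points), 2000L)
  seg <- sqrt(rowSums(diff(rbind(b1$points, b1$points[1, ]))^2))
  expect_lt(max(abs(seg - mean(seg))) / mean(seg), 0.01)
  expect_gt(serialreg:::shoelace_area(b1$points), 0)   # counter-clockwise
  # close to the analytic truth (within segmentation-scale error)
  expect_lt(chamfer_distance(sec$boundary, b1), 30)
})

test_that("boundary geometry matches simple analytic shapes", {
  # disc of radius 40 px: all points within 1 px of the radius
  dm <- matrix(0, 101, 101)
  for (i in 1:101) for (j in 1:101) if ((i - 51)^2 + (j - 51)^2 <= 40^2) dm[i, j] <- 1
  b <- extract_boundary(dm, N = 360, mpp = 1)
  rr <- sqrt(rowSums(sweep(b$points, 2, c(50, 50))^2))
  expect_true(all(abs(rr - 40) < 1.5))
  # square: equal spacing and perimeter near 4 x side
  sq <- matrix(0, 60, 60); sq[21:41, 21:41] <- 1     # side 21 px at mpp 5
  b8 <- extract_boundary(sq, N = 8, mpp = 5)
  seg <- sqrt(rowSums(diff(rbind(b8$points, b8$points[1, ]))^2))
  expect_lt(max(seg) / min(seg), 1.1)
  expect_equal(sum(seg), 4 * 20 * 5, tolerance = 0.08)
  # too-small region for many points errors with advice
  tiny <- matrix(0, 8, 8); tiny[4:5, 4:5] <- 1
  expect_error(extract_boundary(tiny, N = 2000, mpp = 1), "smaller N")
})

test_that("boundary CSV round-trips", {
  b <- circle_boundary(100, 64)
  path <- withr::local_tempfile(fileext = ".csv")
  write_boundary_csv(b, path)
  b2 <- read_boundary_csv(path)
  expect_equal(b$points, b2$points, ignore_attr = TRUE)
})
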