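test_that("the distance gate takes its closed-form values", {
  d <- 33
  expect_equal(gate(c(0, 0), c(0, 0), TRUE, d), 1)
  expect_equal(gate(c(d, 0), c(0, 0), TRUE, d), 0)
  expect_equal(gate(c(2 * d, 0), c(0, 0), TRUE, d), 0)
  expect_equal(gate(c(d / 2, 0), c(0, 0), TRUE, d), sqrt(3) / 2)
  expect_equal(gate(c(0, 0), c(0, 0), FALSE, d), 0)   # cross-type pair
  # vectorized over rows
  z <- rbind(c(0, 0), c(d / 2, 0), c(d, 0))
  expect_equal(gate(z, matrix(0, 3, 2), TRUE, d), c(1, sqrt(3) / 2, 0))
})

test_that("gated responsibilities reduce to plain CPD in the limits", {
  set.seed(21)
  X <- matrix(runif(20, 0, 100), ncol = 2)
  Y <- matrix(runif(20, 0, 100), ncol = 2)
  w <- 0.1; V <- 1e4; sigma2 <- 400
  plain <- plain_cpd_responsibilities(X, Y, sigma2, w, V)
  # beta = 0: gate is ignored entirely
  cfg0 <- refinement_config(beta = 0, delta = 1e-6, outlier_w = w)
  for (n in seq_len(nrow(X))) {
    r <- modified_responsibility(X[n, ], Y, Y, sigma2 = sigma2, config = cfg0,
                                 volume = V)
    expect_lt(max(abs(r$responsibilities - plain[n, ])), 1e-9)
  }
  # delta -> infinity: the gate is 1 pointwise
  cfg_inf <- refinement_config(beta = 1, delta = 1e9, outlier_w = w)
  for (n in seq_len(nrow(X))) {
    r <- modified_responsibility(X[n, ], Y, Y, sigma2 = sigma2, config = cfg_inf,
                                 volume = V)
    expect_lt(max(abs(r$responsibilities - plain[n, ])), 1e-9)
  }
  # cross-type contributions are exactly zero
  r_cross <- modified_responsibility(X[1, ], Y, Y, z_type = "fat",
                                     centroid_types = "nuclei_cluster",
                                     sigma2 = sigma2,
                                     config = refinement_config(),
                                     volume = V)
  expect_true(all(r_cross$responsibilities == 0))
  expect_equal(r_cross$outlier, 1)
})

test_that("gated rigid CPD recovers sub-gate displacements", {
  set.seed(22)
  n <- 120
  pts <- cbind(runif(n, 0, 1200), runif(n, 0, 1200))
  types <- sample(c("fat", "nuclei_cluster"), n, TRUE, prob = c(0.1, 0.9))
  T_res <- rigid_transform(3 * pi / 180, t = c(20, -10), center = c(600, 600))
  fs_src <- typed_feature_set(pts, types)
  fs_tgt <- typed_feature_set(apply_transform(T_res, pts), types)
  res <- cpd_rigid(fs_src, fs_tgt, refinement_config())
  expect_true(is.na(res$fallback))
  expect_lt(rotation_error_deg(res$correction$theta, T_res$theta), 0.5)
  expect_lt(transform_error_um(res$correction, T_res,
                               grid = as.matrix(expand.grid(c(300, 900), c(300, 900)))), 5)
  # EM objective is monotone non-decreasing
  expect_true(all(diff(res$objective_trace) >= -1e-9))
  # an already-aligned pair stays put
  res_id <- cpd_rigid(fs_src, fs_src, refinement_config())
  expect_lt(abs(res_id$correction$theta) * 180 / pi, 0.1)
  expect_lt(sqrt(sum(res_id$correction$t^2)), 1)
})

test_that("dissimilar or empty feature sets fall back to the approximate transform", {
  set.seed(23)
  pts <- cbind(runif(50, 0, 500), runif(50, 0, 500))
  types <- rep("nuclei_cluster", 50)
  fs_a <- typed_feature_set(pts, types)
  fs_far <- typed_feature_set(pts + 5000, types)   # disjoint supports >> delta
  approx_T <- rigid_transform(0.12, t = c(7, -3), center = c(250, 250))
  res <- cpd_rigid(fs_a, fs_far, refinement_config(), approx_T = approx_T)
  expect_equal(res$fallback, "mass_floor")
  expect_identical(res$transform, approx_T)
  # empty set
  empty <- feature_set(data.frame(ftype = character(0), source_id = integer(0),
                                  x = numeric(0), y = numeric(0),
                                  xt = numeric(0), yt = numeric(0)))
  expect_warning(res2 <- cpd_rigid(empty, fs_a, refinement_config(),
                                   approx_T = approx_T), "empty")
  expect_identical(res2$transform, approx_T)
})

test_that("consistently permuting feature-type labels leaves the result invariant", {
  set.seed(24)
  n <- 80
  pts <- cbind(runif(n, 0, 800), runif(n, 0, 800))
  types <- sample(c("fat", "nuclei_cluster"), n, TRUE)
  swap <- ifelse(types == "fat", "nuclei_cluster", "fat")
  T_res <- rigid_transform(2 * pi / 180, t = c(10, 5), center = c(400, 400))
  tgt <- apply_transform(T_res, pts)
  r1 <- cpd_rigid(typed_feature_set(pts, types), typed_feature_set(tgt, types),
                  refinement_config())
  r2 <- cpd_rigid(typed_feature_set(pts, swap), typed_feature_set(tgt, swap),
                  refinement_config())
  expect_equal(r1$correction$theta, r2$correction$theta, tolerance = 1e-12)
  expect_equal(r1$correction$t, r2$correction$t, tolerance = 1e-9)
})

test_that("phase correlation recovers small shifts and rejects large ones", {
  set.seed(25)
  img <- EBImage::filter2(matrix(runif(128 * 128) * 255, 128, 128),
                          serialreg:::disc_kernel(3), boundary = "replicate")
  shift_img <- function(m, dy, dx) {
    out <- matrix(mean(m), nrow(m), ncol(m))
    ys <- 1:(nrow(m) - abs(dy)); xs <- 1:(ncol(m) - abs(dx))
    out[ys + max(dy, 0), xs + max(dx, 0)] <- m[ys - min(dy, 0), xs - min(dx, 0)]
    out
  }
  # content displaced by (dx 7, dy -3): the corrective shift is (-7, 3)
  sh <- phase_correct(img, shift_img(img, -3, 7))
  expect_equal(unname(sh), c(-7, 3))
  # 25% of the width: outside the central 20% of the phase image, rejected
  expect_null(phase_correct(img, shift_img(img, 0, 32)))
  # identical images: zero shift
  expect_equal(unname(phase_correct(img, img)), c(0, 0))
  # featureless images give no correction
  expect_null(phase_correct(matrix(5, 64, 64), matrix(5, 64, 64)))
})

test_that("refine() improves a sub-gate misalignment on rendered sections", {
  T_true <- rigid_transform(1.2 * pi / 180, t = c(15, -8), center = c(1100, 1100))
  pr <- generate_serial_pair(
    serial_pair_spec(section_spec(seed = 71, field_um = 2200, radius_um = 650),
                     T_true, persistence = 1, boundary_noise_um = 2,
                     jitter_um = 2),
    n_boundary_points = 1000, render = TRUE)
  # start from a slightly wrong approximate transform (sub-gate residual)
  T_approx <- compose_transform(rigid_transform(0, t = c(12, 9)), T_true)
  res <- refine(pr$A, pr$B, T_approx, default_config())
  err_before <- transform_error_um(T_approx, T_true,
                                   grid = as.matrix(expand.grid(c(700, 1500), c(700, 1500))))
  err_after <- transform_error_um(res$transform, T_true,
                                  grid = as.matrix(expand.grid(c(700, 1500), c(700, 1500))))
  expect_lt(err_after, err_before)
})
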