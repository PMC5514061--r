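test_that("boundary smoothing behaves like a circular Gaussian", {
  b <- circle_boundary(50, 500)
  # near-zero bandwidth is the identity
  expect_lt(max(abs(smooth_boundary(b, 1e-6) - b$points)), 1e-6)
  # a circle stays a circle with the same center and a smaller radius
  sm <- smooth_boundary(b, 20)
  expect_lt(max(abs(colMeans(sm))), 1e-6)
  rr <- sqrt(rowSums(sm^2))
  expect_lt(diff(range(rr)), 1e-6)
  expect_lt(mean(rr), 50)
  # smoothing a star reduces the curvature extremes
  st <- star_boundary(5, 100, 0.3, 800)
  k0 <- max(abs(curvature(st$points)))
  k1 <- max(abs(curvature(smooth_boundary(st, 100))))
  expect_lt(k1, k0)
})

test_that("curvature matches analytic values", {
  # circle of radius 10: kappa = 1/r everywhere
  k <- curvature(circle_boundary(10, 2000)$points)
  expect_lt(max(abs(k - 0.1)) / 0.1, 0.01)
  # straight stretches of a rounded rectangle have near-zero curvature
  t_seq <- seq(0, 1, length.out = 200)[-200]
  side <- cbind(t_seq * 100, rep(0, 199))
  arc <- function(c0, a0, a1) {
    a <- seq(a0, a1, length.out = 100)[-100]
    cbind(c0[1] + 10 * cos(a), c0[2] + 10 * sin(a))
  }
  rect <- rbind(cbind(seq(0, 100, length.out = 100)[-100], -10),
                arc(c(100, 0), -pi / 2, pi / 2),
                cbind(seq(100, 0, length.out = 100)[-100], 10),
                arc(c(0, 0), pi / 2, 3 * pi / 2))
  kr <- curvature(rect)
  mid_straight <- 40:60
  expect_true(all(abs(kr[mid_straight]) < 1e-3))
  # ellipse a = 200, b = 100 um: max curvature a/b^2 at the major axis ends
  phi <- seq(0, 2 * pi, length.out = 4001)[-4001]
  ell <- cbind(200 * cos(phi), 100 * sin(phi))
  ke <- curvature(ell)
  expect_equal(max(ke), 200 / 100^2, tolerance = 0.01)
  # degenerate input: repeated points
  bad <- rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_error(curvature(bad), "zero speed")
  # the printed-sum fidelity toggle is not the standard curvature
  expect_false(isTRUE(all.equal(curvature(ell), curvature(ell, standard_sign = FALSE))))
})

test_that("sigma_schedule is geometric with exact endpoints", {
  expect_equal(sigma_schedule(3, 1, 4), c(1, 2, 4))
  expect_equal(sigma_schedule(2, 0.7, 9.1), c(0.7, 9.1))
  s <- sigma_schedule(16, 2, 125)
  expect_equal(s[1], 2); expect_equal(s[16], 125)
  ratios <- s[-1] / s[-16]
  expect_lt(diff(range(ratios)), 1e-12)
  expect_equal(ratios[1], (125 / 2)^(1 / 15), tolerance = 1e-12)
  expect_error(sigma_schedule(3, 5, 2))
})

test_that("the CSS image marks strict curvature maxima per scale", {
  sig <- sigma_schedule(6, 2, 50)
  # constant curvature: no strict maxima at any scale
  css_circle <- build_css(circle_boundary(100, 800), sig)
  expect_equal(sum(css_circle$maxima), 0L)
  # 5-lobed star: exactly 5 maxima at every scale
  css_star <- build_css(star_boundary(5, 500, 0.25, 1000), sig)
  expect_equal(unname(colSums(css_star$maxima)), rep(5L, 6))
  # brute-force per-scale scan agrees with the mask
  for (j in seq_along(sig)) {
    k <- css_star$kappa[, j]
    n <- length(k)
    brute <- vapply(seq_len(n), function(i) {
      ip <- if (i == n) 1L else i + 1L
      im <- if (i == 1L) n else i - 1L
      as.integer(k[i] > k[ip] && k[i] > k[im] && k[i] > 0)
    }, integer(1))
    expect_equal(css_star$maxima[, j], brute)
  }
})

test_that("CSS is invariant to rotation/translation up to a circular shift", {
  b <- generate_blob_boundary(11, N = 600, radius_um = 700)
  sig <- sigma_schedule(5, 2, 30)
  cssA <- build_css(b, sig)
  k <- 137L
  n <- 600L
  rolled <- b$points[((seq_len(n) - 1L + k) %% n) + 1L, ]
  moved <- apply_transform(rigid_transform(0.6, t = c(300, -120), center = c(10, 20)),
                           rolled)
  cssB <- build_css(boundary(moved), sig)
  expect_lt(max(abs(cssB$kappa - cssA$kappa[((seq_len(n) - 1L + k) %% n) + 1L, ])),
            1e-6)
  expect_equal(cssB$maxima, cssA$maxima[((seq_len(n) - 1L + k) %% n) + 1L, ])
})

test_that("maxima matching recovers self-identity and planted shifts", {
  b <- generate_blob_boundary(7, N = 1024, radius_um = 800)
  sig <- sigma_schedule(8, 2, 64)
  css <- build_css(b, sig)
  self <- match_maxima(css, css)
  expect_equal(self$circular_offset, 0L)
  expect_equal(self$total_cost, 0)
  expect_equal(nrow(self$pairs), sum(css$maxima[, serialreg:::css_features(css)$scale]))
  # planted circular shift: B[i] = A[i + 137]
  k <- 137L; n <- 1024L
  rolled <- boundary(b$points[((seq_len(n) - 1L + k) %% n) + 1L, ])
  cssB <- build_css(rolled, sig)
  mm <- match_maxima(css, cssB)
  expect_equal(mm$circular_offset, k)
})

test_that("the Hungarian solver equals brute force on small instances", {
  set.seed(1234)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n, n)
    sol <- solve_assignment(cost)
    expect_equal(sort(sol$assignment), seq_len(n))
    expect_equal(sol$cost, brute_assignment_cost(cost), tolerance = 1e-12)
  }
})

test_that("fit_rigid recovers exact and noisy rigid motions", {
  set.seed(9)
  src <- matrix(runif(40, -500, 500), ncol = 2)
  T_true <- rigid_transform(30 * pi / 180, t = c(5, -2), center = c(0, 0))
  dst <- apply_transform(T_true, src)
  T_fit <- fit_rigid(src, dst)
  expect_lt(transform_error_um(T_fit, T_true, grid = src), 1e-9)
  # identity pairs give the identity
  T_id <- fit_rigid(src, src)
  expect_lt(abs(T_id$theta), 1e-12)
  expect_lt(max(abs(T_id$t)), 1e-12)
  # noisy pairs: same residual as the SVD (Kabsch) oracle
  dst_n <- dst + matrix(rnorm(40, 0, 1), ncol = 2)
  T_n <- fit_rigid(src, dst_n)
  kabsch <- function(src, dst) {
    cs <- colMeans(src); cd <- colMeans(dst)
    H <- t(sweep(src, 2, cs)) %*% sweep(dst, 2, cd)
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
    list(R = R, t = cd - as.numeric(R %*% cs))
  }
  kb <- kabsch(src, dst_n)
  res_fit <- sum((apply_transform(T_n, src) - dst_n)^2)
  res_kb <- sum((t(kb$R %*% t(src)) + rep(kb$t, each = nrow(src)) - dst_n)^2)
  expect_lt(abs(res_fit - res_kb), 1e-9)
  # degenerate: coincident sources
  expect_error(fit_rigid(matrix(1, 5, 2), dst[1:5, ]), "coincident")
})

test_that("chamfer distance matches its definition and brute force", {
  set.seed(10)
  a <- matrix(runif(100, 0, 100), ncol = 2)
  b <- matrix(runif(100, 0, 100), ncol = 2)
  expect_equal(chamfer_distance(a, a), 0)
  expect_lt(abs(chamfer_distance(a, b) - brute_chamfer(a, b)), 1e-9)
  expect_lt(abs(chamfer_distance(a, b, normalize = FALSE) -
                  brute_chamfer(a, b, normalize = FALSE)), 1e-9)
  # four far-apart points shifted by (3, 4): each nearest is its own translate
  p4 <- rbind(c(0, 0), c(100, 0), c(0, 100), c(100, 100))
  expect_equal(chamfer_distance(p4, sweep(p4, 2, c(-3, -4))), 5)
  # not symmetric: a dense set against a sparse subset
  dense <- circle_boundary(50, 200)$points
  sparse <- dense[c(1, 101), ]
  expect_gt(chamfer_distance(dense, sparse), chamfer_distance(sparse, dense))
  expect_error(chamfer_distance(matrix(numeric(0), 0, 2), b), "empty")
})

test_that("approximate registration recovers planted rigid motions", {
  set.seed(61)
  ok <- 0L
  for (i in 1:5) {
    T_true <- rigid_transform(runif(1, -30, 30) * pi / 180,
                              t = runif(2, -300, 300), center = c(1500, 1500))
    pr <- generate_serial_pair(serial_pair_spec(section_spec(seed = 400 + i),
                                                T_true, boundary_noise_um = 5),
                               n_boundary_points = 2000)
    T_hat <- approximate_register(pr$A$boundary, pr$B$boundary)
    if (rotation_error_deg(T_hat$theta, T_true$theta) < 2 &&
        transform_error_um(T_hat, T_true) < 20) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
  # registering a boundary to itself is the identity within tolerance
  b <- generate_blob_boundary(3, N = 2000, radius_um = 800, center = c(1500, 1500))
  T_id <- approximate_register(b, b)
  expect_lt(rotation_error_deg(T_id$theta, 0), 0.1)
  expect_lt(transform_error_um(T_id, identity_transform()), 2)
})

test_that("alignment reduces the chamfer distance of a perturbed pair", {
  set.seed(62)
  T_true <- rigid_transform(15 * pi / 180, t = c(150, -80), center = c(1500, 1500))
  pr <- generate_serial_pair(serial_pair_spec(section_spec(seed = 55), T_true,
                                              boundary_noise_um = 5),
                             n_boundary_points = 1000)
  before <- chamfer_distance(pr$A$boundary, pr$B$boundary)
  T_hat <- approximate_register(pr$A$boundary, pr$B$boundary)
  after <- chamfer_distance(pr$A$boundary,
                            apply_transform(T_hat, pr$B$boundary$points))
  expect_lt(after, before)
})
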