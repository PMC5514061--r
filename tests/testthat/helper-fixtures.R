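# shared test helpers: random rigid transforms, error metrics, small
# geometric fixtures

random_rigid <- function() {
  rigid_transform(runif(1, -pi, pi), t = runif(2, -500, 500),
                  center = runif(2, -200, 200))
}

rotation_error_deg <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  min(d, 2 * pi - d) * 180 / pi
}

# mean displacement between two transforms over a grid of probe points
transform_error_um <- function(T1, T2,
                               grid = as.matrix(expand.grid(seq(1000, 2000, 500),
                                                            seq(1000, 2000, 500)))) {
  mean(sqrt(rowSums((apply_transform(T1, grid) - apply_transform(T2, grid))^2)))
}

circle_boundary <- function(r = 10, n = 2000, center = c(0, 0)) {
  phi <- (0:(n - 1)) * 2 * pi / n
  boundary(cbind(center[1] + r * cos(phi), center[2] + r * sin(phi)))
}

star_boundary <- function(lobes = 5, r = 100, amp = 0.3, n = 2000) {
  phi <- (0:(n - 1)) * 2 * pi / n
  rr <- r * (1 + amp * cos(lobes * phi))
  boundary(cbind(rr * cos(phi), rr * sin(phi)))
}

# brute-force minimal assignment cost by permutation enumeration
brute_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  min(vapply(perms(seq_len(n)), function(p) {
    sum(cost[cbind(seq_len(n), p)])
  }, numeric(1)))
}

# brute-force chamfer oracle (double loop)
brute_chamfer <- function(a, b, normalize = TRUE) {
  total <- 0
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
      if (d < best) best <- d
    }
    total <- total + best
  }
  if (normalize) total / nrow(a) else total
}

# feature sets with all points typed and already "registered" (z~ = z)
typed_feature_set <- function(pts, types) {
  feature_set(data.frame(ftype = types, source_id = 1L,
                         x = pts[, 1], y = pts[, 2],
                         xt = pts[, 1], yt = pts[, 2]))
}

# unmodified rigid-CPD E-step responsibilities (independent oracle)
plain_cpd_responsibilities <- function(X, Y, sigma2, w, V) {
  M <- nrow(Y)
  num <- matrix(0, nrow(X), M)
  for (n in seq_len(nrow(X))) {
    for (m in seq_len(M)) {
      num[n, m] <- exp(-sum((X[n, ] - Y[m, ])^2) / (2 * sigma2))
    }
  }
  denom <- rowSums(num) + (2 * pi * sigma2) * w * M / ((1 - w) * V)
  num / denom
}
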