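test_that("zero-lag Butterworth filtering preserves DC and introduces no
           lag", {
  n <- 240
  tt <- (0:(n - 1)) / 120
  const <- trajectory(tt, matrix(5, n, 3), 120)
  out <- butterworth_zero_lag(const)
  expect_equal(out$displacement, const$displacement, tolerance = 1e-5,
               ignore_attr = TRUE)

  # 1 Hz sinusoid: cross-correlation peak at zero lag
  s <- sin(2 * pi * 1 * tt)
  tr <- trajectory(tt, cbind(s, s, s), 120)
  f <- butterworth_zero_lag(tr)$displacement[, 1]
  cc <- ccf(f, s, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(butterworth_zero_lag(trajectory(tt[1:4],
                                               matrix(0, 4, 3), 120)),
               "too short")
  expect_error(butterworth_zero_lag(tr, fc = 70), "Nyquist")
})

test_that("30 Hz attenuation matches the analytic squared magnitude
           response", {
  fs <- 120; fc <- 6; f0 <- 30
  n <- 1200
  tt <- (0:(n - 1)) / fs
  s <- sin(2 * pi * f0 * tt)
  tr <- trajectory(tt, cbind(s, 0 * s, 0 * s), fs)
  y <- butterworth_zero_lag(tr, fc = fc)$displacement[, 1]
  # analytic: squared magnitude of the designed 2nd-order digital filter
  bf <- signal::butter(2, fc / (fs / 2), type = "low")
  H <- signal::polyval(rev(bf$b), exp(-1i * 2 * pi * f0 / fs)) /
    signal::polyval(rev(bf$a), exp(-1i * 2 * pi * f0 / fs))
  expected <- Mod(H)^2
  mid <- 300:900   # steady-state portion away from the edges
  measured <- sqrt(mean(y[mid]^2)) / sqrt(mean(s[mid]^2))
  expect_equal(measured, expected, tolerance = 0.01)
})

test_that("filtering is nearly idempotent on band-limited signals", {
  n <- 600
  tt <- (0:(n - 1)) / 120
  # content well inside the 6 Hz passband (near the cutoff a second pass
  # legitimately attenuates further)
  s <- 3 * sin(2 * pi * 1.5 * tt) + 1.5 * sin(2 * pi * 2 * tt)
  tr <- trajectory(tt, cbind(s, s, s), 120)
  once <- butterworth_zero_lag(tr)
  twice <- butterworth_zero_lag(once)
  rel <- sqrt(mean((twice$displacement[, 1] - once$displacement[, 1])^2)) /
    sqrt(mean(once$displacement[, 1]^2))
  expect_lt(rel, 0.01)
})

test_that("RMAE reproduces hand-worked values and its invariances", {
  expect_equal(rmae(c(10, 20), c(9, 22))$rmae, 0.10)
  expect_equal(rmae(c(10, 20, 30), c(10, 20, 30))$rmae, 0)
  x <- c(2, 5, -4, 8, 3)
  expect_equal(rmae(x, 1.05 * x)$rmae, 0.05)
  # scale invariance
  for (c0 in c(-3, 0.5, 10)) {
    expect_equal(rmae(c0 * x, c0 * 1.2 * x)$rmae, rmae(x, 1.2 * x)$rmae)
  }
  # near-zero experimental frames are excluded and counted
  r <- rmae(c(0.1, 10, 20), c(5, 9, 22), eps = 0.5)
  expect_equal(r$excluded_frames, 1L)
  expect_equal(r$rmae, 0.10)
  expect_error(rmae(c(0.01, 0.02), c(1, 2), eps = 0.5), "excluded")
  expect_error(rmae(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("surface distance: offset plane and identity", {
  plane <- list(nodes = as.matrix(expand.grid(x = 0:5 * 10, y = 0:5 * 10,
                                              z = 0)),
                triangles = NULL)
  # triangulate the grid
  idx <- matrix(seq_len(36), 6, 6)
  tris <- NULL
  for (j in 1:5) for (i in 1:5) {
    tris <- rbind(tris, c(idx[i, j], idx[i + 1, j], idx[i + 1, j + 1]),
                  c(idx[i, j], idx[i + 1, j + 1], idx[i, j + 1]))
  }
  plane$triangles <- tris
  ref <- surface_sequence(list(plane))
  h <- 3.7
  pts <- cbind(runif(40, 5, 45), runif(40, 5, 45), h)
  sim <- surface_sequence(list(list(nodes = pts)))
  expect_equal(surface_distance(sim, ref)$d, h, tolerance = 1e-12)
  expect_equal(surface_distance(sim, ref, mode = "squared")$d, h^2,
               tolerance = 1e-12)
  same <- surface_sequence(list(list(nodes = plane$nodes)))
  expect_equal(surface_distance(same, ref)$d, 0)
})

test_that("spatially pruned nearest-triangle search matches the
           exhaustive scan", {
  for (seed in 1:3) {
    surf <- random_sphere_mesh(10, 20, jitter = 0.15, seed = seed)
    set.seed(seed + 100)
    pts <- matrix(rnorm(200 * 3, 0, 8), ncol = 3)
    fast <- mammotion:::point_triangle_distances(
      pts, surf$nodes, matrix(as.integer(surf$triangles), ncol = 3))
    slow <- brute_point_tri(pts, surf$nodes, surf$triangles)
    expect_lt(max(abs(fast - slow)), 1e-9)
  }
})

test_that("surface distance is invariant under a common rigid
           transform", {
  surf <- random_sphere_mesh(8, 14, seed = 4)
  set.seed(9)
  pts <- matrix(rnorm(60 * 3, 0, 8), ncol = 3)
  ref <- surface_sequence(list(surf))
  sim <- surface_sequence(list(list(nodes = pts)))
  d0 <- surface_distance(sim, ref)$d
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  tvec <- c(5, -3, 11)
  move <- function(x) sweep(x %*% t(R), 2, -tvec)
  ref2 <- surface_sequence(list(list(nodes = move(surf$nodes),
                                     triangles = surf$triangles)))
  sim2 <- surface_sequence(list(list(nodes = move(pts))))
  expect_equal(surface_distance(sim2, ref2)$d, d0, tolerance = 1e-9)
})

test_that("validation reports combine per-point RMAE and the surface
           distance", {
  tt <- (0:119) / 120
  mk <- function(a) trajectory(tt, cbind(a * sin(2 * pi * tt),
                                         a * cos(2 * pi * tt), 0), 120)
  rep <- validation_report(list(clavicle = mk(10), nipple = mk(15)),
                           list(clavicle = mk(10.5), nipple = mk(14)))
  expect_equal(nrow(rep$rmae), 4L)
  expect_true(all(rep$rmae$rmae_pct >= 0))
  expect_true(is.na(rep$surface_d))
})
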