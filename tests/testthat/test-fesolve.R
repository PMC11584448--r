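test_that("internal forces vanish in the reference state and under rigid
           motion", {
  mesh <- block_mesh(10, 10, 10, 2, 2, 2, component = "gland")
  n3 <- 3 * nrow(mesh$nodes)
  asm <- assemble_internal(mesh, MT, numeric(n3), tangent = FALSE,
                           stress = TRUE)
  expect_equal(max(abs(asm$fint)), 0)
  expect_equal(asm$energy, 0)
  expect_equal(max(asm$vm), 0)

  # rigid translation and finite rotation are stress free (objectivity)
  u_trans <- rep(c(3, -2, 7), nrow(mesh$nodes))
  a1 <- assemble_internal(mesh, MT, u_trans, tangent = FALSE,
                          stress = TRUE)
  expect_lt(max(abs(a1$fint)), 1e-9)
  expect_lt(max(a1$vm), 1e-9)
  th <- 0.4
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  u_rot <- as.vector(t(mesh$nodes %*% t(R) - mesh$nodes))
  a2 <- assemble_internal(mesh, MT, u_rot, tangent = FALSE, stress = TRUE)
  expect_lt(max(abs(a2$fint)), 1e-6)
  expect_lt(max(a2$vm), 1e-8)
})

test_that("a uniform deformation gradient produces a uniform stress field", {
  mesh <- block_mesh(10, 10, 10, 2, 2, 2, component = "adipose")
  F <- diag(3) + matrix(c(0.05, 0.02, 0, 0.01, -0.03, 0.02,
                          0, 0.01, 0.04), 3)
  u <- as.vector(t(mesh$nodes %*% t(F) - mesh$nodes))
  asm <- assemble_internal(mesh, MT, u, tangent = FALSE, stress = TRUE)
  expect_lt(diff(range(asm$vm)) / mean(asm$vm), 1e-10)
})

test_that("the assembled tangent matches finite differences of the
           residual", {
  mesh <- block_mesh(10, 10, 10, 2, 2, 2, component = "soft_layer")
  set.seed(8)
  n3 <- 3 * nrow(mesh$nodes)
  u <- rnorm(n3, 0, 0.05)
  K <- as.matrix(assemble_internal(mesh, MT, u, tangent = TRUE)$K)
  h <- 1e-6
  Kfd <- matrix(0, n3, n3)
  for (j in seq_len(n3)) {
    up <- u; up[j] <- up[j] + h
    um <- u; um[j] <- um[j] - h
    Kfd[, j] <- (assemble_internal(mesh, MT, up, tangent = FALSE)$fint -
                 assemble_internal(mesh, MT, um, tangent = FALSE)$fint) /
      (2 * h)
  }
  expect_lt(max(abs(K - Kfd)) / max(abs(Kfd)), 1e-4)
})

test_that("static solve: zero gravity means zero displacement and load
           scales linearly with density", {
  mesh <- block_mesh(20, 20, 20, 2, 2, 2, component = "gland")
  bcs0 <- boundary_conditions(mesh, gravity = c(0, 0, 0))
  st <- solve_static(mesh, MT, bcs0, store_stress = FALSE)
  expect_equal(max(abs(st$nodal_displacement)), 0)

  f1 <- mammotion:::gravity_force(mesh, MT, c(0, -9800, 0),
                                  names(MT))
  mt2 <- MT
  mt2$gland$density <- 2 * MT$gland$density
  f2 <- mammotion:::gravity_force(mesh, mt2, c(0, -9800, 0), names(MT))
  expect_equal(f2, 2 * f1)
})

test_that("hanging column deflection is mesh-converged (refinement
           oracle)", {
  tips <- vapply(c(2, 4), function(n) {
    rc <- roller_column(n)
    st <- solve_static(rc$mesh, MT, rc$bcs, store_stress = FALSE)
    u <- matrix(st$nodal_displacement[, 1], ncol = 3, byrow = TRUE)
    u[rc$mesh$node_sets$nipple, 2]
  }, numeric(1))
  expect_equal(tips[1], tips[2], tolerance = 0.02)
  # and the coarse answer is near the small-strain analytic estimate
  expect_equal(tips[1], -1.05e-9 * 9800 * 40^2 / (2 * 0.01),
               tolerance = 0.06)
})

test_that("Newton iterations stay below the budget with tight residuals", {
  rc <- roller_column(3)
  st <- solve_static(rc$mesh, MT, rc$bcs, store_stress = FALSE)
  expect_true(all(st$convergence_log$iterations <= 25))
  expect_true(all(st$convergence_log$residual < 1e-5))
})

test_that("von Mises stress has the textbook closed forms", {
  expect_equal(von_mises(diag(c(7, 7, 7))), 0)
  s <- matrix(0, 3, 3); s[1, 1] <- -3.2
  expect_equal(von_mises(s), 3.2)
  tau <- 1.7
  sh <- matrix(0, 3, 3); sh[1, 2] <- sh[2, 1] <- tau
  expect_equal(von_mises(sh), sqrt(3) * tau)
})

test_that("dynamics: gravity equilibrium is a fixed point under zero
           driving", {
  mesh <- block_mesh(20, 40, 20, 2, 4, 2, component = "soft_layer")
  bcs <- boundary_conditions(mesh)
  st <- solve_static(mesh, MT, bcs, store_stress = FALSE)
  n <- 61
  traj0 <- trajectory((0:(n - 1)) / 120, matrix(0, n, 3), 120)
  dyn <- solve_dynamic(mesh, MT, bcs, traj0, dt = 0.005, n_steps = 30,
                       static = st, store_stress = FALSE)
  drift <- max(abs(dyn$nodal_displacement - st$nodal_displacement[, 1]))
  expect_lt(drift, 1e-6)
})

test_that("dynamics: a driven column responds at the driving frequency", {
  mesh <- block_mesh(20, 40, 20, 2, 4, 2, component = "soft_layer")
  bcs <- boundary_conditions(mesh)
  st <- solve_static(mesh, MT, bcs, store_stress = FALSE)
  f0 <- 3
  tt <- (0:180) / 120
  traj <- trajectory(tt, cbind(0, 5 * sin(2 * pi * f0 * tt), 0), 120)
  dyn <- solve_dynamic(mesh, MT, bcs, traj, dt = 0.005, n_steps = 200,
                       static = st, store_stress = FALSE)
  tip <- mesh$node_sets$nipple
  uy <- dyn$nodal_displacement[3 * (tip - 1) + 2, ]
  sp <- Mod(fft(uy - mean(uy)))[2:80]
  fr <- (1:79) / (length(uy) * 0.005)
  expect_equal(fr[which.max(sp)], f0, tolerance = 0.1)
})

test_that("displacement-controlled uniaxial stretch matches the
           incompressible closed form", {
  mesh <- block_mesh(10, 10, 10, 2, 2, 2, component = "gland")
  mu <- MT$gland$mu
  for (lam in c(0.92, 1.15)) {
    bcs <- boundary_conditions(
      mesh, gravity = c(0, 0, 0), driven = integer(0),
      symmetry = integer(0),
      extra_fixed = list(
        list(nodes = mesh$node_sets$ymin, comp = 2),
        list(nodes = mesh$node_sets$xmin, comp = 1),
        list(nodes = mesh$node_sets$zmin, comp = 3),
        list(nodes = mesh$node_sets$ymax, comp = 2,
             value = (lam - 1) * 10)))
    st <- solve_static(mesh, MT, bcs, store_stress = FALSE)
    u <- matrix(st$nodal_displacement[, 1], ncol = 3, byrow = TRUE)
    Ry <- sum(st$reactions[3 * (mesh$node_sets$ymax - 1) + 2, 1])
    lx <- 10 + max(u[mesh$node_sets$xmax, 1])
    lz <- 10 + max(u[mesh$node_sets$zmax, 3])
    sigma <- Ry / (lx * lz) * 1000   # N/mm^2 -> kPa
    expect_equal(sigma, mu * (lam^2 - 1 / lam), tolerance = 0.05)
  }
})
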