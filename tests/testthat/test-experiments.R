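test_that("gait events are located at the analytic extrema of a noiseless
           trajectory", {
  tr <- build_synthetic_gait(duration = 1, noise_sd = 0, impact_depth = 0,
                             asym = 0)
  ev <- detect_events(tr)
  wf <- attr(tr, "waveform")
  P <- wf$half_cycle
  expect_equal(ev$t1, wf$t0, tolerance = 1e-9)
  expect_equal(ev$t3, wf$t0 + P / 2, tolerance = 1e-9)
  # sampled extrema lie within one sample of the analytic times
  expect_lte(abs(ev$t2 - (wf$t0 + P / 4)), 1 / 120 + 1e-12)
  expect_lte(abs(ev$t4 - (wf$t0 + 3 * P / 4)), 1 / 120 + 1e-12)
  expect_true(ev$t1 < ev$t2 && ev$t2 < ev$t3 && ev$t3 < ev$t4)

  # second half-cycle is offset by one period (to sampling resolution)
  ev2 <- detect_events(tr, cycle = 2)
  expect_lte(abs(ev2$t2 - ev$t2 - P), 2 / 120 + 1e-12)
  expect_equal(ev2$window[1], ev$window[1] + P)

  expect_error(detect_events(trajectory((0:119) / 120,
                                        matrix(1, 120, 3), 120)),
               "flat")
})

test_that("marker noise shifts filtered events by at most two samples", {
  clean <- build_synthetic_gait(duration = 1, noise_sd = 0)
  noisy <- build_synthetic_gait(duration = 1, noise_sd = 0.5, seed = 3)
  ev_c <- detect_events(butterworth_zero_lag(clean))
  ev_n <- detect_events(butterworth_zero_lag(noisy))
  dt <- 1 / 120
  expect_lte(abs(ev_n$t2 - ev_c$t2), 2 * dt + 1e-12)
  expect_lte(abs(ev_n$t4 - ev_c$t4), 2 * dt + 1e-12)
})

test_that("regional element sets cover the anatomy and are disjoint where
           they partition it", {
  mesh <- build_anatomy(anatomy_params(mesh_size_fine = 10,
                                       mesh_size_coarse = 16))
  regs <- regional_element_sets(mesh)
  need <- c("lig_anterior", "lig_posterior", paste0("L", 1:8),
            "area_A", "area_B", "area_C", "N1", "B1", "B2",
            "gland_D", "gland_E", "gland_F", "gland_G",
            "adipose_near_gland")
  expect_true(all(need %in% names(regs)))
  # the gland areas partition the gland without overlap
  gl <- unlist(regs[c("gland_D", "gland_E", "gland_F", "gland_G")])
  expect_equal(anyDuplicated(gl), 0L)
  expect_true(all(mesh$element_component[gl] == "gland"))
  # ligament contact areas are ligament elements
  expect_true(all(mesh$element_component[unlist(
    regs[c("area_A", "area_B", "area_C")])] == "ligament"))
})

test_that("regional stress means are exact for degenerate fields", {
  mesh <- build_anatomy(anatomy_params(mesh_size_fine = 14,
                                       mesh_size_coarse = 22,
                                       n_cap_layers = 3))
  regs <- regional_element_sets(mesh)
  nf <- 3
  zero <- structure(list(times = (0:(nf - 1)) * 0.005,
                         nodal_displacement = NULL,
                         element_von_mises = matrix(0, nrow(mesh$tets),
                                                    nf)),
                    class = "simulation_result")
  rs0 <- regional_stress_summary(zero, mesh, regs)
  expect_true(all(rs0$mean_history == 0))

  s0 <- 4.25
  unif <- zero
  unif$element_von_mises <- matrix(s0, nrow(mesh$tets), nf)
  rs1 <- regional_stress_summary(unif, mesh, regs)
  expect_equal(as.numeric(rs1$mean_history),
               rep(s0, length(regs) * nf), tolerance = 1e-12)

  expect_error(regional_stress_summary(unif, mesh,
                                       c(regs, list(empty = integer(0)))),
               "empty region")
})

test_that("component kinematics of a static solution have zero
           acceleration and rigid motion is reported identically", {
  mesh <- build_anatomy(anatomy_params(mesh_size_fine = 16,
                                       mesh_size_coarse = 26,
                                       n_cap_layers = 3))
  n3 <- 3 * nrow(mesh$nodes)
  # synthetic rigid history: every node translated by the same vector
  nf <- 4
  U <- matrix(rep(rep(c(1, -2, 3), nrow(mesh$nodes)), nf), n3, nf)
  U <- U * matrix(rep(seq_len(nf), each = n3), n3, nf)
  rigid <- structure(list(times = (0:(nf - 1)) * 0.005,
                          nodal_displacement = U,
                          nodal_velocity = NULL,
                          nodal_acceleration = NULL),
                     class = "simulation_result")
  kin <- extract_component_kinematics(rigid, mesh)
  # identical total displacement for every component at every frame
  expect_lt(max(apply(kin$displacement, 1, function(r)
    diff(range(r)))), 1e-9)
  expect_true(all(kin$acceleration == 0))
})

test_that("sweep grids default to the five-level tables", {
  expect_identical(default_sweep_grid("gland"), c(5, 7.5, 10, 12.5, 15))
  expect_identical(default_sweep_grid("ligament"),
                   c(80, 100, 120, 140, 160))
})
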