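# mesh generation is deterministic and cheap enough to rebuild per block
desk_params <- anatomy_params(mesh_size_fine = 10, mesh_size_coarse = 16)

test_that("default anatomy contains all components with 18 lobes and
           1.5 mm skin", {
  mesh <- build_anatomy(anatomy_params())
  expect_setequal(unique(mesh$element_component),
                  c("soft_layer", "adipose", "pectoralis", "ligament",
                    "gland"))
  expect_true(all(mesh$shell_component == "skin"))
  expect_true(all(mesh$shell_thickness == 1.5))

  # each of the 18 lobes is resolved: assign lobe-labelled elements to
  # their nearest lobe centre and count the distinct lobes hit
  g <- attr(mesh, "geometry")
  expect_equal(nrow(g$lobe_xy), 18L)
  lobe_el <- which(mesh$element_part %in% "lobe")
  expect_gt(length(lobe_el), 0)
  cen <- (mesh$nodes[mesh$tets[lobe_el, 1], ] +
          mesh$nodes[mesh$tets[lobe_el, 2], ] +
          mesh$nodes[mesh$tets[lobe_el, 3], ] +
          mesh$nodes[mesh$tets[lobe_el, 4], ]) / 4
  nearest <- apply(cen, 1, function(p) {
    which.min((g$lobe_xy[, 1] - p[1])^2 + (g$lobe_xy[, 2] - p[2])^2)
  })
  expect_equal(length(unique(nearest)), 18L)

  # lobe diameters drawn within the stated range
  expect_true(all(g$lobe_diam >= 15 & g$lobe_diam <= 18))
})

test_that("every tetrahedron has positive volume and indices are in range", {
  for (pp in list(desk_params,
                  anatomy_params(mesh_size_fine = 14, mesh_size_coarse = 22,
                                 n_cap_layers = 3, seed = 7))) {
    mesh <- build_anatomy(pp)
    v <- tet_volumes(mesh)
    expect_gt(min(v), 0)
    expect_true(all(mesh$tets >= 1 & mesh$tets <= nrow(mesh$nodes)))
    expect_true(all(vapply(mesh$node_sets, function(s)
      all(s >= 1 & s <= nrow(mesh$nodes)), logical(1))))
  }
})

test_that("interfaces are conforming: no duplicated coincident nodes", {
  mesh <- build_anatomy(desk_params)
  key <- paste(round(mesh$nodes[, 1], 6), round(mesh$nodes[, 2], 6),
               round(mesh$nodes[, 3], 6))
  expect_equal(anyDuplicated(key), 0L)
})

test_that("generation is deterministic under a fixed seed", {
  m1 <- build_anatomy(desk_params)
  m2 <- build_anatomy(desk_params)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tets, m2$tets)
  expect_identical(m1$element_component, m2$element_component)
  m3 <- build_anatomy(anatomy_params(mesh_size_fine = 10,
                                     mesh_size_coarse = 16, seed = 99))
  expect_false(identical(attr(m1, "geometry")$lobe_diam,
                         attr(m3, "geometry")$lobe_diam))
})

test_that("component volumes are sane: gland + ligament < adipose", {
  for (seed in c(1, 42)) {
    mesh <- build_anatomy(anatomy_params(mesh_size_fine = 10,
                                         mesh_size_coarse = 16,
                                         seed = seed))
    cv <- component_volumes(mesh)
    expect_lt(cv[["gland"]] + cv[["ligament"]], cv[["adipose"]])
  }
})

test_that("geometric doubling scales the mesh volume by ~8x", {
  base <- anatomy_params(mesh_size_fine = 12, mesh_size_coarse = 20,
                         n_cap_layers = 3)
  dbl <- anatomy_params(breast_base_radius = 120, breast_protrusion = 100,
                        soft_layer_thickness = 50, skin_thickness = 3,
                        lobe_diameter_range = c(30, 36),
                        duct_diameter_range = c(4, 8),
                        pec_center_thickness = 24, pec_edge_thickness = 8,
                        ligament_shell_thickness = 6,
                        mesh_size_fine = 24, mesh_size_coarse = 40,
                        n_cap_layers = 3)
  v1 <- sum(tet_volumes(build_anatomy(base)))
  v2 <- sum(tet_volumes(build_anatomy(dbl)))
  expect_equal(v2 / v1, 8, tolerance = 0.1)
})

test_that("infeasible lobe packing is rejected with a parameter error", {
  expect_error(build_anatomy(anatomy_params(breast_base_radius = 40,
                                            breast_protrusion = 33)),
               "cannot be contained")
})

test_that("synthetic gait has the designed frame count, amplitude and
           extremum structure", {
  tr <- build_synthetic_gait(duration = 3, sample_rate = 120,
                             noise_sd = 0)
  expect_equal(length(tr$times), 360L)
  expect_equal(diff(range(diff(tr$times))), 0, tolerance = 1e-12)

  # designed peak-to-peak: sinusoid + braking-pulse depth
  Y <- tr$displacement[, "Y"]
  expect_equal(max(Y) - min(Y), 70 + 5, tolerance = 0.01 * 75)

  # one maximum and one minimum per half-cycle (interior window)
  wf <- attr(tr, "waveform")
  win <- tr$times >= wf$t0 + wf$half_cycle &
    tr$times <= wf$t0 + 2 * wf$half_cycle
  yw <- Y[win]
  d1 <- diff(yw)
  sign_changes <- sum(diff(sign(d1)) != 0)
  expect_equal(sign_changes, 2L)

  # degenerate flat trajectory is allowed
  flat <- build_synthetic_gait(duration = 1, amp_y = 0, amp_x = 0,
                               asym = 0, impact_depth = 0, noise_sd = 0)
  expect_true(all(flat$displacement == 0))
})

test_that("gait noise realization is seed-deterministic", {
  a <- build_synthetic_gait(duration = 1, seed = 4)
  b <- build_synthetic_gait(duration = 1, seed = 4)
  c <- build_synthetic_gait(duration = 1, seed = 5)
  expect_identical(a$displacement, b$displacement)
  expect_false(identical(a$displacement, c$displacement))
})

test_that("trajectories survive a CSV round trip", {
  tr <- build_synthetic_gait(duration = 0.5, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$displacement, tr$displacement, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(back$sample_rate, 120, tolerance = 1e-6)
})

test_that("mesh exports produce well-formed VTU and surface files", {
  mesh <- build_anatomy(anatomy_params(mesh_size_fine = 14,
                                       mesh_size_coarse = 24,
                                       n_cap_layers = 3))
  vtu <- tempfile(fileext = ".vtu")
  write_vtu(mesh, vtu, cell_values = list(volume = tet_volumes(mesh)))
  doc <- xml2::read_xml(vtu)
  piece <- xml2::xml_find_first(doc, "//Piece")
  expect_equal(as.integer(xml2::xml_attr(piece, "NumberOfPoints")),
               nrow(mesh$nodes))
  expect_equal(as.integer(xml2::xml_attr(piece, "NumberOfCells")),
               nrow(mesh$tets))

  obj <- tempfile(fileext = ".obj")
  write_surface(mesh, obj)
  surf <- read_surface(obj)
  expect_equal(nrow(surf$triangles),
               sum(rowSums(matrix(mesh$shells %in%
                 mesh$node_sets$breast_surface, ncol = 3)) == 3))
  expect_true(all(surf$triangles <= nrow(surf$nodes)))
})
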