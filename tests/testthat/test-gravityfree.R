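test_that("zero gravity returns the input mesh unchanged in one
           iteration", {
  mesh <- block_mesh(20, 30, 20, 2, 3, 2, component = "soft_layer")
  bcs <- boundary_conditions(mesh, gravity = c(0, 0, 0))
  res <- estimate_unloaded(mesh, MT, inverse_settings(), bcs = bcs)
  expect_true(res$converged)
  expect_equal(res$iterations, 1L)
  expect_identical(res$mesh$nodes, mesh$nodes)
})

test_that("the inverse iteration recovers a known reference (round
           trip)", {
  ref <- block_mesh(20, 30, 20, 2, 3, 2, component = "soft_layer")
  bcs <- boundary_conditions(ref)
  st <- solve_static(ref, MT, bcs, store_stress = FALSE)
  loaded <- ref
  loaded$nodes <- ref$nodes +
    matrix(st$nodal_displacement[, 1], ncol = 3, byrow = TRUE)

  settings <- inverse_settings(tol = 0.05, max_iter = 30)
  res <- estimate_unloaded(loaded, MT, settings)
  expect_true(res$converged)
  # recovered reference close to the true one
  surf <- ref$node_sets$breast_surface
  err <- sqrt(rowSums((res$mesh$nodes[surf, ] - ref$nodes[surf, ])^2))
  expect_lt(max(err), 5 * settings$tol)
  # deformed recovered reference reproduces the observed surface
  derr <- sqrt(rowSums((res$deformed$nodes[surf, ] -
                          loaded$nodes[surf, ])^2))
  expect_lt(max(derr), settings$tol)
})

test_that("residual history decreases and topology is preserved", {
  ref <- block_mesh(20, 30, 20, 2, 3, 2, component = "adipose")
  bcs <- boundary_conditions(ref)
  st <- solve_static(ref, MT, bcs, store_stress = FALSE)
  loaded <- ref
  loaded$nodes <- ref$nodes +
    matrix(st$nodal_displacement[, 1], ncol = 3, byrow = TRUE)
  res <- estimate_unloaded(loaded, MT, inverse_settings(tol = 0.02))
  expect_true(res$converged)
  expect_true(all(diff(res$residuals) <= 1e-12))
  expect_identical(res$mesh$tets, ref$tets)
  expect_identical(res$mesh$element_component, ref$element_component)
})
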