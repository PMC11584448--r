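test_that("E/nu conversion gives the small-strain shear and penalty moduli", {
  md <- convert_E_nu(10, 0.49)
  expect_equal(md[["mu"]], 10 / (2 * 1.49), tolerance = 1e-12)
  expect_equal(md[["mu"]], 3.3557, tolerance = 1e-4)
  expect_equal(md[["d_incomp"]], 0.012, tolerance = 1e-12)
  # skin
  expect_equal(convert_E_nu(500, 0.49)[["mu"]], 167.79, tolerance = 1e-4)
  # identity scaling: E = 2(1+v) gives mu = 1 for any admissible v
  for (v in c(0.1, 0.3, 0.45, 0.499)) {
    expect_equal(convert_E_nu(2 * (1 + v), v)[["mu"]], 1)
  }
  expect_error(convert_E_nu(10, 0.5), "between 0 and 0.5")
  expect_error(constitutive_model("neo_hookean", E = 10, v = 0.5),
               "volumetric penalty")
})

test_that("deformation point kinematics satisfy the isochoric invariants", {
  for (F in random_F(20, scale = 0.2, seed = 11)) {
    p <- deformation_point(F)
    expect_equal(det(p$B_bar), 1, tolerance = 1e-8)
    expect_gte(p$I1_bar, 3 - 1e-9)
    expect_gte(p$I2_bar, 3 - 1e-9)
    expect_equal(p$J, det(F))
  }
  expect_error(deformation_point(-diag(3)), "inverted")
})

test_that("strain energy vanishes at the identity and matches closed forms", {
  models <- list(nh = constitutive_model("neo_hookean", E = 10, v = 0.49),
                 mr = MT$adipose)
  for (m in models) expect_equal(strain_energy(m, diag(3)), 0)

  # isochoric uniaxial stretch, Neo-Hookean closed form
  m <- models$nh
  for (lam in c(0.9, 1.1, 1.3)) {
    F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
    expect_equal(strain_energy(m, F),
                 m$mu / 2 * (lam^2 + 2 / lam - 3), tolerance = 1e-12)
  }

  # small isochoric simple shear: W -> (C10 + C01) * gamma^2 as gamma -> 0
  C <- MT$adipose$coefficients
  for (gam in c(1e-3, 1e-4)) {
    F <- diag(3); F[1, 2] <- gam
    W <- strain_energy(MT$adipose, F)
    expect_equal(W / gam^2, C[["C10"]] + C[["C01"]], tolerance = 1e-4)
  }
})

test_that("Cauchy stress is symmetric, zero at identity, and matches the
           incompressible uniaxial closed form", {
  models <- list(constitutive_model("neo_hookean", E = 10, v = 0.49),
                 MT$adipose)
  for (m in models) {
    expect_equal(cauchy_stress(m, diag(3)), matrix(0, 3, 3))
    for (F in random_F(5, seed = 3)) {
      s <- cauchy_stress(m, F)
      expect_equal(s, t(s), tolerance = 1e-10)
    }
  }
  # incompressible uniaxial: axial minus lateral stress = mu (lam^2 - 1/lam)
  m <- models[[1]]
  for (lam in c(0.9, 1.05, 1.2)) {
    F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
    s <- cauchy_stress(m, F)
    expect_equal(s[1, 1] - s[2, 2], m$mu * (lam^2 - 1 / lam),
                 tolerance = 1e-10)
  }
})

test_that("first Piola-Kirchhoff stress equals the gradient of the energy", {
  models <- list(constitutive_model("neo_hookean", E = 10, v = 0.49),
                 MT$adipose, MT$skin)
  h <- 1e-6
  for (m in models) {
    for (F in random_F(6, scale = 0.08, seed = 7)) {
      P <- first_pk_stress(m, F)
      Pfd <- matrix(0, 3, 3)
      for (i in 1:3) for (j in 1:3) {
        Fp <- F; Fp[i, j] <- Fp[i, j] + h
        Fm <- F; Fm[i, j] <- Fm[i, j] - h
        Pfd[i, j] <- (strain_energy(m, Fp) - strain_energy(m, Fm)) / (2 * h)
      }
      expect_lt(max(abs(P - Pfd)) / max(abs(P)), 1e-5)
    }
  }
})

test_that("five-parameter Mooney-Rivlin reduces to Neo-Hookean", {
  mu <- 4.2
  nh <- constitutive_model("neo_hookean", E = 2 * mu * 1.49, v = 0.49)
  mr <- constitutive_model("mooney_rivlin_5",
                           coefficients = c(C10 = mu / 2, C01 = 0,
                                            C11 = 0, C20 = 0, C02 = 0),
                           v = 0.49)
  for (F in random_F(10, scale = 0.15, seed = 5)) {
    expect_equal(strain_energy(mr, F), strain_energy(nh, F),
                 tolerance = 1e-12)
    expect_equal(cauchy_stress(mr, F), cauchy_stress(nh, F),
                 tolerance = 1e-12)
  }
})

test_that("material table carries the reference assignment", {
  expect_equal(MT$ligament$E, 100)
  expect_equal(MT$skin$E, 500)
  expect_equal(MT$soft_layer$E, 10)
  expect_equal(MT$pectoralis$E, 10)
  expect_equal(MT$gland$E, 10)
  expect_equal(unname(MT$adipose$coefficients),
               c(0.31, 0.3, 2.25, 3.8, 4.72))
  expect_equal(MT$gland$density, 1070)
  expect_equal(MT$adipose$density, 950)
  expect_equal(MT$ligament$density, 1040)
  expect_equal(MT$pectoralis$density, 1050)
  for (m in MT) expect_equal(m$v, 0.49)
  # Neo-Hookean round trip of the effective modulus
  expect_equal(small_strain_modulus(MT$ligament), 100)
})

test_that("material tables survive a YAML round trip", {
  path <- tempfile(fileext = ".yaml")
  write_material_yaml(MT, path)
  back <- read_material_yaml(path)
  expect_equal(names(back), names(MT))
  expect_equal(back$adipose$coefficients, MT$adipose$coefficients)
  expect_equal(back$skin$E, MT$skin$E)
  expect_equal(back$gland$density, MT$gland$density)
})
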