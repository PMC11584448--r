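#' Hyperelastic constitutive models for breast soft tissues
#'
#' Constructs a nearly incompressible hyperelastic material description.
#' Two strain-energy forms are supported: the single-parameter
#' Neo-Hookean model
#' \deqn{W = \frac{\mu}{2}(\bar I_1 - 3) + \frac{1}{d}(J - 1)^2}
#' and the five-parameter (second-order polynomial) Mooney--Rivlin model
#' \deqn{W = \sum_{i+j \le 2} C_{ij} (\bar I_1 - 3)^i (\bar I_2 - 3)^j
#'       + \frac{1}{d}(J - 1)^2}
#' where \eqn{\bar I_1,\bar I_2} are the isochoric invariants of the left
#' Cauchy--Green tensor and \eqn{J = \det F}.  Both use the decoupled
#' (isochoric/volumetric) convention; the volumetric penalty coefficient
#' \eqn{d} and shear modulus \eqn{\mu} derive from a small-strain Young's
#' modulus and Poisson ratio via [convert_E_nu()].
#'
#' @param kind `"neo_hookean"` or `"mooney_rivlin_5"`.
#' @param E Young's modulus in kPa (Neo-Hookean only).
#' @param v Poisson ratio, in (0, 0.5).
#' @param coefficients named numeric vector `c(C10=, C01=, C11=, C20=, C02=)`
#'   in kPa (Mooney--Rivlin only).
#' @param density mass density in kg/m^3 (converted internally to
#'   tonne/mm^3 by the solver).
#' @return An object of class `constitutive_model` with derived fields
#'   `mu` (initial shear modulus, kPa) and `d_incomp` (incompressibility
#'   parameter, 1/kPa).  For the Mooney--Rivlin form, `mu` is the
#'   small-strain equivalent \eqn{2(C_{10}+C_{01})} and `d_incomp` is
#'   computed from the matching small-strain Young's modulus.
#' @seealso [material_table()], [small_strain_modulus()], [strain_energy()]
#' @export
constitutive_model <- function(kind = c("neo_hookean", "mooney_rivlin_5"),
                               E = NULL, v = 0.49, coefficients = NULL,
                               density = 1000) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
  if (v <= 0 || v >= 0.5) {
    stop("Poisson ratio must lie strictly between 0 and 0.5 ",
         "(v = 0.5 makes the volumetric penalty 1/d undefined)")
  }
  stopifnot(is.numeric(density), density > 0)
  if (kind == "neo_hookean") {
    stopifnot(is.numeric(E), length(E) == 1L, E > 0)
    md <- convert_E_nu(E, v)
    coefficients <- NULL
  } else {
    need <- c("C10", "C01", "C11", "C20", "C02")
    if (is.null(coefficients) || !all(need %in% names(coefficients))) {
      stop("mooney_rivlin_5 requires coefficients C10, C01, C11, C20, C02")
    }
    coefficients <- coefficients[need]
    stopifnot(all(is.finite(coefficients)))
    if (coefficients[["C10"]] + coefficients[["C01"]] <= 0) {
      stop("C10 + C01 must be positive (initial shear modulus)")
    }
    mu_eff <- 2 * (coefficients[["C10"]] + coefficients[["C01"]])
    E_eff <- 2 * mu_eff * (1 + v)
    md <- convert_E_nu(E_eff, v)
    E <- NULL
  }
  structure(
    list(kind = kind, E = E, v = v, coefficients = coefficients,
         density = density, mu = md[["mu"]], d_incomp = md[["d_incomp"]]),
    class = "constitutive_model")
}

#' @export
print.constitutive_model <- function(x, ...) {
  cat("<constitutive_model>", x$kind, "\n")
  if (x$kind == "neo_hookean") {
    cat("  E =", x$E, "kPa, v =", x$v, "\n")
  } else {
    cat("  C =", paste(names(x$coefficients), signif(x$coefficients, 4),
                       sep = "=", collapse = ", "), "kPa\n")
  }
  cat("  mu =", signif(x$mu, 6), "kPa, d =", signif(x$d_incomp, 6),
      "1/kPa, density =", x$density, "kg/m^3\n")
  invisible(x)
}

#' Convert Young's modulus and Poisson ratio to shear and penalty moduli
#'
#' Small-strain conversion used throughout:
#' \eqn{\mu = E / (2(1+\nu))} and \eqn{d = 6(1-2\nu)/E}.
#'
#' @param E Young's modulus, kPa.  Must be positive.
#' @param v Poisson ratio in (0, 0.5); the incompressible limit
#'   \eqn{\nu = 0.5} is rejected because the penalty \eqn{1/d} is then
#'   undefined.
#' @return Named numeric vector `c(mu =, d_incomp =)` in kPa and 1/kPa.
#' @examples
#' convert_E_nu(10, 0.49)   # mu ~ 3.356 kPa, d = 0.012 1/kPa
#' @export
convert_E_nu <- function(E, v) {
  stopifnot(is.numeric(E), length(E) == 1L, is.finite(E), E > 0,
            is.numeric(v), length(v) == 1L, is.finite(v))
  if (v <= 0 || v >= 0.5) {
    stop("Poisson ratio must lie strictly between 0 and 0.5")
  }
  c(mu = E / (2 * (1 + v)), d_incomp = 6 * (1 - 2 * v) / E)
}

#' Kinematic quantities at a material point
#'
#' Computes the volume ratio, isochoric left Cauchy--Green tensor and its
#' invariants from a deformation gradient.
#'
#' @param F 3x3 deformation gradient (dimensionless), `det(F) > 0`.
#' @return Object of class `deformation_point` with fields `F`, `J`,
#'   `B_bar` (\eqn{\bar B = J^{-2/3} F F^T}), `I1_bar`, `I2_bar`.
#' @export
deformation_point <- function(F) {
  F <- as.matrix(F)
  stopifnot(identical(dim(F), c(3L, 3L)), all(is.finite(F)))
  J <- det(F)
  if (J <= 0) stop("inverted deformation state: det(F) <= 0")
  B_bar <- J^(-2 / 3) * (F %*% t(F))
  I1 <- sum(diag(B_bar))
  I2 <- 0.5 * (I1^2 - sum(diag(B_bar %*% B_bar)))
  structure(list(F = F, J = J, B_bar = B_bar, I1_bar = I1, I2_bar = I2),
            class = "deformation_point")
}

mr5_terms <- function() {
  # (i, j) exponents of the five polynomial terms, order C10 C01 C11 C20 C02
  cbind(i = c(1, 0, 1, 2, 0), j = c(0, 1, 1, 0, 2))
}

#' Strain-energy density
#'
#' Evaluates the stored-energy function of a [constitutive_model] at a
#' [deformation_point].  Units follow the coefficients (kPa when the
#' model is built from kPa moduli).
#'
#' @param model a `constitutive_model`.
#' @param p a `deformation_point` (or a 3x3 deformation gradient).
#' @return Scalar energy per unit reference volume.
#' @export
strain_energy <- function(model, p) {
  if (is.matrix(p)) p <- deformation_point(p)
  stopifnot(inherits(model, "constitutive_model"),
            inherits(p, "deformation_point"))
  vol <- (1 / model$d_incomp) * (p$J - 1)^2
  if (model$kind == "neo_hookean") {
    return(model$mu / 2 * (p$I1_bar - 3) + vol)
  }
  ij <- mr5_terms()
  iso <- sum(model$coefficients *
               (p$I1_bar - 3)^ij[, "i"] * (p$I2_bar - 3)^ij[, "j"])
  iso + vol
}

# dW/dI1_bar and dW/dI2_bar for either material kind (kPa)
energy_derivatives <- function(model, I1, I2) {
  if (model$kind == "neo_hookean") {
    return(c(W1 = model$mu / 2, W2 = 0))
  }
  C <- model$coefficients
  c(W1 = C[["C10"]] + C[["C11"]] * (I2 - 3) + 2 * C[["C20"]] * (I1 - 3),
    W2 = C[["C01"]] + C[["C11"]] * (I1 - 3) + 2 * C[["C02"]] * (I2 - 3))
}

#' Cauchy stress of a hyperelastic material
#'
#' Standard push-forward of the decoupled strain energy:
#' \deqn{\sigma = \frac{2}{J}\,\mathrm{dev}\!\left[(W_1 + \bar I_1 W_2)\bar B
#'   - W_2 \bar B^2\right] + \frac{2}{d}(J-1)\,I}
#' with \eqn{W_k = \partial W/\partial \bar I_k}.
#'
#' @inheritParams strain_energy
#' @return Symmetric 3x3 Cauchy stress in the units of the model moduli
#'   (kPa for models built by [constitutive_model()]).
#' @export
cauchy_stress <- function(model, p) {
  if (is.matrix(p)) p <- deformation_point(p)
  stopifnot(inherits(model, "constitutive_model"),
            inherits(p, "deformation_point"))
  w <- energy_derivatives(model, p$I1_bar, p$I2_bar)
  B <- p$B_bar
  S <- (w[["W1"]] + p$I1_bar * w[["W2"]]) * B - w[["W2"]] * (B %*% B)
  S <- S - diag(mean(diag(S)), 3)              # deviatoric part
  sig <- (2 / p$J) * S + diag(2 / model$d_incomp * (p$J - 1), 3)
  (sig + t(sig)) / 2
}

#' First Piola--Kirchhoff stress
#'
#' Pull-back \eqn{P = J \sigma F^{-T}} of [cauchy_stress()]; this is the
#' work-conjugate of the deformation gradient and the quantity checked
#' against finite differences of [strain_energy()] in the test suite.
#'
#' @inheritParams strain_energy
#' @return 3x3 first Piola--Kirchhoff stress.
#' @export
first_pk_stress <- function(model, p) {
  if (is.matrix(p)) p <- deformation_point(p)
  sig <- cauchy_stress(model, p)
  p$J * sig %*% t(solve(p$F))
}

#' Effective small-strain Young's modulus
#'
#' Linearization of the material about the undeformed state:
#' \eqn{E_\mathrm{eff} = 2 \mu_\mathrm{eff} (1 + \nu)} with
#' \eqn{\mu_\mathrm{eff} = \mu} for the Neo-Hookean form and
#' \eqn{\mu_\mathrm{eff} = 2(C_{10} + C_{01})} for the five-parameter
#' Mooney--Rivlin form.
#'
#' @param model a `constitutive_model`.
#' @return Effective Young's modulus in kPa.
#' @examples
#' # adipose tissue: five-parameter Mooney-Rivlin, ~3.6 kPa
#' small_strain_modulus(material_table()$adipose)
#' @export
small_strain_modulus <- function(model) {
  stopifnot(inherits(model, "constitutive_model"))
  mu_eff <- if (model$kind == "neo_hookean") model$mu else
    2 * (model$coefficients[["C10"]] + model$coefficients[["C01"]])
  2 * mu_eff * (1 + model$v)
}

#' Reference material table for the breast components
#'
#' Material assignment used by the multi-component model: Neo-Hookean for
#' skin (500 kPa), subcutaneous soft-tissue layer (10 kPa), pectoralis
#' major (10 kPa), Cooper's ligaments (100 kPa) and glandular tissue
#' (10 kPa); five-parameter Mooney--Rivlin for adipose tissue with
#' C10 = 0.31, C01 = 0.3, C11 = 2.25, C20 = 3.8, C02 = 4.72 kPa.
#' Densities: 950 (adipose), 1040 (ligament), 1070 (gland), 1050
#' (pectoralis and soft layer) kg/m^3.  Skin density is not reported in
#' the source literature for this assignment; 1050 kg/m^3 is used and can
#' be overridden.  Poisson ratio is 0.49 for every component
#' (quasi-incompressible soft tissue).
#'
#' @param skin_density skin density in kg/m^3 (default 1050).
#' @return Named list of [constitutive_model] objects with components
#'   `soft_layer`, `adipose`, `pectoralis`, `ligament`, `gland`, `skin`.
#' @export
material_table <- function(skin_density = 1050) {
  nu <- 0.49
  list(
    soft_layer = constitutive_model("neo_hookean", E = 10, v = nu,
                                    density = 1050),
    adipose = constitutive_model(
      "mooney_rivlin_5",
      coefficients = c(C10 = 0.31, C01 = 0.3, C11 = 2.25,
                       C20 = 3.8, C02 = 4.72),
      v = nu, density = 950),
    pectoralis = constitutive_model("neo_hookean", E = 10, v = nu,
                                    density = 1050),
    ligament = constitutive_model("neo_hookean", E = 100, v = nu,
                                  density = 1040),
    gland = constitutive_model("neo_hookean", E = 10, v = nu,
                               density = 1070),
    skin = constitutive_model("neo_hookean", E = 500, v = nu,
                              density = skin_density)
  )
}

#' Read or write a material table as YAML
#'
#' Serializes the six-component material table to a YAML file whose header
#' comment states the unit conventions (kPa, kg/m^3), and reads it back.
#'
#' @param materials named list of `constitutive_model` objects.
#' @param path file path.
#' @return `write_material_yaml` returns `path` invisibly;
#'   `read_material_yaml` returns a named list of `constitutive_model`s.
#' @export
write_material_yaml <- function(materials, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required for material YAML I/O")
  }
  as_rec <- function(m) {
    r <- list(kind = m$kind, v = m$v, density = m$density)
    if (m$kind == "neo_hookean") r$E <- m$E else
      r$coefficients <- as.list(m$coefficients)
    r
  }
  txt <- c("# material table: moduli in kPa, densities in kg/m^3",
           yaml::as.yaml(lapply(materials, as_rec)))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_material_yaml
#' @export
read_material_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required for material YAML I/O")
  }
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r) {
    if (r$kind == "neo_hookean") {
      constitutive_model("neo_hookean", E = r$E, v = r$v,
                         density = r$density)
    } else {
      constitutive_model("mooney_rivlin_5",
                         coefficients = unlist(r$coefficients),
                         v = r$v, density = r$density)
    }
  })
}
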