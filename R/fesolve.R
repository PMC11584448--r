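#' Boundary conditions for the breast model
#'
#' Bundles the kinematic constraints and loading of a simulation: the
#' sagittal symmetry plane (zero mediolateral displacement), the driven
#' rigid-torso node set whose X and Y displacement follow a prescribed
#' trajectory (Z is held at zero), and the gravity vector.  Where a node
#' belongs to both sets the rigid-torso prescription takes precedence,
#' since the torso slides along the symmetry plane when mediolateral
#' motion is prescribed.
#'
#' @param mesh a `labelled_tet_mesh`.
#' @param gravity gravity acceleration vector in mm/s^2
#'   (default `c(0, -9800, 0)`).
#' @param driven node indices whose motion is fully prescribed; defaults
#'   to the `torso_base` node set (the rigid torso, glued to the tissue).
#' @param symmetry node indices constrained normal to the sagittal plane;
#'   defaults to the `symmetry_plane` node set.
#' @param gravity_components components that carry gravity load
#'   (default: every deformable component including the skin).
#' @param extra_fixed optional list of additional single-component
#'   constraints, each `list(nodes =, comp =, value =)` with `comp` in
#'   1:3 (x, y, z) and `value` a prescribed displacement (default 0);
#'   used e.g. for roller supports and displacement-controlled stretch
#'   in verification problems.
#' @return An object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(mesh,
                                gravity = c(0, -9800, 0),
                                driven = mesh$node_sets$torso_base,
                                symmetry = mesh$node_sets$symmetry_plane,
                                gravity_components = c("soft_layer",
                                  "adipose", "pectoralis", "ligament",
                                  "gland", "skin"),
                                extra_fixed = list()) {
  stopifnot(inherits(mesh, "labelled_tet_mesh"),
            length(gravity) == 3, all(is.finite(gravity)))
  structure(list(driven = sort(unique(as.integer(driven))),
                 symmetry = sort(unique(as.integer(symmetry))),
                 gravity = as.numeric(gravity),
                 gravity_components = gravity_components,
                 extra_fixed = extra_fixed),
            class = "boundary_conditions")
}

# unit conversions: user-facing kPa / kg/m^3 -> solver MPa / tonne/mm^3
KPA_TO_MPA <- 1e-3
KGM3_TO_TMM3 <- 1e-12

# per-element material row matrix (MPa) and densities (tonne/mm^3)
solver_materials <- function(mesh, materials) {
  comp <- mesh$element_component
  need <- unique(comp)
  miss <- setdiff(need, names(materials))
  if (length(miss)) stop("materials missing for components: ",
                         paste(miss, collapse = ", "))
  row_of <- function(m) {
    if (m$kind == "neo_hookean") {
      c(0, m$mu, m$d_incomp / KPA_TO_MPA, 0, 0, 0, 0, 0) *
        c(1, KPA_TO_MPA, 1, rep(KPA_TO_MPA, 5))
    } else {
      co <- m$coefficients * KPA_TO_MPA
      c(1, m$mu * KPA_TO_MPA, m$d_incomp / KPA_TO_MPA,
        co[["C10"]], co[["C01"]], co[["C11"]], co[["C20"]], co[["C02"]])
    }
  }
  tab <- t(vapply(materials[need], row_of, numeric(8)))
  rownames(tab) <- need
  list(matrow = tab[match(comp, need), , drop = FALSE],
       density = vapply(materials, function(m) m$density * KGM3_TO_TMM3,
                        numeric(1)))
}

#' Lumped (row-sum) mass vector
#'
#' @param mesh a `labelled_tet_mesh`.
#' @param materials named list of [constitutive_model()]s per component.
#' @return Length-`3n` vector of nodal masses in tonnes (equal for the
#'   three DOFs of a node).
#' @export
lumped_mass <- function(mesh, materials) {
  sm <- solver_materials(mesh, materials)
  rho_e <- sm$density[mesh$element_component]
  v <- tet_volumes(mesh)
  nm <- numeric(nrow(mesh$nodes))
  for (a in 1:4) {
    part <- tapply(rho_e * v / 4, mesh$tets[, a], sum)
    nm[as.integer(names(part))] <- nm[as.integer(names(part))] + part
  }
  if (nrow(mesh$shells) > 0 && "skin" %in% names(materials)) {
    rho_s <- materials$skin$density * KGM3_TO_TMM3
    ar <- triangle_areas(mesh$nodes, mesh$shells)
    for (a in 1:3) {
      part <- tapply(rho_s * mesh$shell_thickness * ar / 3,
                     mesh$shells[, a], sum)
      nm[as.integer(names(part))] <- nm[as.integer(names(part))] + part
    }
  }
  rep(nm, each = 3)
}

triangle_areas <- function(nodes, tris) {
  a <- nodes[tris[, 1], , drop = FALSE]
  u <- nodes[tris[, 2], , drop = FALSE] - a
  v <- nodes[tris[, 3], , drop = FALSE] - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# gravity nodal force vector (N), restricted to the selected components
gravity_force <- function(mesh, materials, gravity, components) {
  sm <- solver_materials(mesh, materials)
  rho_e <- sm$density[mesh$element_component]
  rho_e[!(mesh$element_component %in% components)] <- 0
  v <- tet_volumes(mesh)
  f <- numeric(3 * nrow(mesh$nodes))
  nm <- numeric(nrow(mesh$nodes))
  for (a in 1:4) {
    part <- tapply(rho_e * v / 4, mesh$tets[, a], sum)
    nm[as.integer(names(part))] <- nm[as.integer(names(part))] + part
  }
  if (nrow(mesh$shells) > 0 && "skin" %in% components &&
      "skin" %in% names(materials)) {
    rho_s <- materials$skin$density * KGM3_TO_TMM3
    ar <- triangle_areas(mesh$nodes, mesh$shells)
    for (a in 1:3) {
      part <- tapply(rho_s * mesh$shell_thickness * ar / 3,
                     mesh$shells[, a], sum)
      nm[as.integer(names(part))] <- nm[as.integer(names(part))] + part
    }
  }
  for (c in 1:3) f[seq(c, by = 3, length.out = length(nm))] <-
    nm * gravity[c]
  f
}

#' Assemble internal forces and consistent tangent
#'
#' Total-Lagrangian assembly of the tetrahedral hyperelastic elements and
#' the skin membrane shells at a nodal displacement state.  The tangent is
#' the consistent linearization of the internal force (element-level
#' central differencing of the first Piola--Kirchhoff stress).
#'
#' @param mesh a `labelled_tet_mesh`.
#' @param materials named list of [constitutive_model()]s per component
#'   (including `skin` when the mesh has shells).
#' @param u length-`3n` nodal displacement vector (mm), DOF order
#'   `(node1 x,y,z, node2 x,y,z, ...)`.
#' @param tangent assemble the sparse tangent stiffness as well?
#' @param stress return per-tet von Mises stress (kPa)?
#' @param free optional integer vector of free DOFs; when given together
#'   with `cache`, the returned tangent is restricted to `free` x `free`.
#' @param cache optional environment reusing the sparse pattern across
#'   calls on the same mesh (the triplet layout is deterministic, so
#'   only the values change between Newton iterations).
#' @return List with `fint` (N), `K` (sparse `dgCMatrix`, N/mm; `NULL`
#'   unless requested; restricted to free DOFs when `free` is given),
#'   `energy` (strain energy, mJ), `vm` (kPa, or `NULL`), `minJ`, and
#'   `bad_element` (one-based index of an inverted element, or -1).
#' @export
assemble_internal <- function(mesh, materials, u, tangent = TRUE,
                              stress = FALSE, free = NULL,
                              cache = NULL) {
  stopifnot(length(u) == 3 * nrow(mesh$nodes), all(is.finite(u)))
  sm <- solver_materials(mesh, materials)
  patch <- mesh$patch
  if (is.null(patch)) patch <- seq_len(nrow(mesh$tets))
  res <- fem_assemble_tets(mesh$nodes, mesh$tets, sm$matrow,
                           as.integer(patch), u, tangent, stress)
  if (res$minJ <= 0) {
    return(list(fint = NULL, K = NULL, energy = NA_real_, vm = NULL,
                minJ = res$minJ, bad_element = res$bad_element))
  }
  fint <- res$fint
  energy <- res$energy
  ki <- res$ki; kj <- res$kj; kx <- res$kx
  if (nrow(mesh$shells) > 0) {
    if (!("skin" %in% names(materials))) {
      stop("mesh has skin shells but no 'skin' material was supplied")
    }
    mres <- fem_assemble_membrane(mesh$nodes, mesh$shells,
                                  mesh$shell_thickness,
                                  materials$skin$mu * KPA_TO_MPA,
                                  u, tangent)
    if (!mres$ok) {
      return(list(fint = NULL, K = NULL, energy = NA_real_, vm = NULL,
                  minJ = 0, bad_element = NA_integer_))
    }
    fint <- fint + mres$fint
    energy <- energy + mres$energy
    if (tangent) {
      ki <- c(ki, mres$ki); kj <- c(kj, mres$kj); kx <- c(kx, mres$kx)
    }
  }
  K <- NULL
  if (tangent) {
    if (!is.null(cache) && !is.null(free)) {
      if (is.null(cache$slot)) {
        nf <- length(free)
        fidx <- integer(length(u))
        fidx[free] <- seq_along(free)
        cache$keep <- fidx[ki] > 0L & fidx[kj] > 0L
        keys <- (as.numeric(fidx[kj[cache$keep]]) - 1) * nf +
          as.numeric(fidx[ki[cache$keep]])
        uk <- sort(unique(keys))
        cache$slot <- match(keys, uk)
        cache$template <- Matrix::sparseMatrix(
          i = as.integer((uk - 1) %% nf + 1),
          j = as.integer((uk - 1) %/% nf + 1),
          x = seq_along(uk), dims = c(nf, nf))
        stopifnot(length(cache$template@x) == length(uk))
      }
      K <- cache$template
      K@x <- as.numeric(accumulate_slots(kx[cache$keep], cache$slot,
                                         length(cache$template@x)))
    } else {
      K <- Matrix::sparseMatrix(i = ki, j = kj, x = kx,
                                dims = c(length(u), length(u)))
      if (!is.null(free)) K <- K[free, free, drop = FALSE]
    }
  }
  list(fint = fint, K = K, energy = energy,
       vm = if (stress) res$vm / KPA_TO_MPA else NULL,
       minJ = res$minJ, bad_element = res$bad_element)
}

#' Von Mises equivalent stress of a stress tensor
#'
#' \eqn{\sigma_{vm} = \sqrt{\tfrac{3}{2}\, \mathrm{dev}\sigma :
#' \mathrm{dev}\sigma}}.
#'
#' @param stress symmetric 3x3 stress tensor.
#' @return Non-negative scalar in the units of `stress`.
#' @examples
#' von_mises(diag(c(5, 5, 5)))                  # hydrostatic -> 0
#' von_mises(matrix(c(0,1,0, 1,0,0, 0,0,0), 3)) # pure shear -> sqrt(3)
#' @export
von_mises <- function(stress) {
  stress <- as.matrix(stress)
  stopifnot(identical(dim(stress), c(3L, 3L)),
            isTRUE(all.equal(stress, t(stress), tolerance = 1e-8)))
  s <- stress - diag(mean(diag(stress)), 3)
  sqrt(1.5 * sum(s * s))
}

# DOF bookkeeping: returns prescribed dof indices and a function giving
# their values at time t (driven nodes follow the trajectory in X and Y,
# Z pinned; symmetry nodes have u_x = 0 unless driven)
dof_plan <- function(mesh, bcs, traj = NULL) {
  n <- nrow(mesh$nodes)
  driven <- bcs$driven
  sym <- setdiff(bcs$symmetry, driven)
  base <- c(as.vector(t(outer(3 * (driven - 1), 1:3, `+`))),
            3 * (sym - 1) + 1)
  extra <- unlist(lapply(bcs$extra_fixed, function(f)
    3 * (as.integer(f$nodes) - 1) + f$comp))
  extra_val <- unlist(lapply(bcs$extra_fixed, function(f) {
    v <- if (is.null(f$value)) 0 else f$value
    rep_len(v, length(f$nodes))
  }))
  if (is.null(extra)) extra <- integer(0)
  keep <- !(extra %in% base) & !duplicated(extra)
  extra <- extra[keep]
  extra_val <- if (length(extra_val)) extra_val[keep] else numeric(0)
  pdofs <- c(base, extra)
  driven_x <- c(seq_len(length(driven) * 3) %% 3 == 1,
                logical(length(sym) + length(extra)))
  driven_y <- c(seq_len(length(driven) * 3) %% 3 == 2,
                logical(length(sym) + length(extra)))
  extra_mask <- c(logical(length(base)), rep(TRUE, length(extra)))
  # smooth (spline) interpolation of the driven motion: the implicit
  # integrator differentiates the prescribed history twice, so slope
  # kinks of linear interpolation would ring in the driven accelerations
  fx <- fy <- NULL
  if (!is.null(traj)) {
    fx <- stats::splinefun(traj$times, traj$displacement[, 1],
                           method = "fmm")
    fy <- stats::splinefun(traj$times, traj$displacement[, 2],
                           method = "fmm")
  }
  value_at <- function(t) {
    v <- numeric(length(pdofs))
    if (!is.null(traj)) {
      v[driven_x] <- fx(t) - fx(0)
      v[driven_y] <- fy(t) - fy(0)
    }
    if (length(extra)) v[extra_mask] <- extra_val
    v
  }
  free <- setdiff(seq_len(3 * n), pdofs)
  list(prescribed = pdofs, free = free, value_at = value_at)
}

new_simulation_result <- function(times, U, V = NULL, A = NULL, vm = NULL,
                                  energy = NULL, convergence = NULL,
                                  reactions = NULL) {
  structure(list(times = times, nodal_displacement = U,
                 nodal_velocity = V, nodal_acceleration = A,
                 element_von_mises = vm, energy = energy,
                 convergence_log = convergence, reactions = reactions),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>", length(x$times), "frames,",
      nrow(x$nodal_displacement) / 3, "nodes\n")
  if (!is.null(x$convergence_log)) {
    cat("  mean Newton iterations/step:",
        signif(mean(x$convergence_log$iterations), 3), "\n")
  }
  invisible(x)
}

# one Newton solve at fixed external load / prescribed displacements.
# Returns list(u, iters, res, energy, ok, fint)
newton_solve <- function(mesh, materials, u, fext, plan, uP,
                         rtol = 1e-6, atol = 1e-9, max_iter = 25,
                         mass_term = NULL, cache = NULL) {
  freeD <- plan$free
  u[plan$prescribed] <- uP
  ref <- NULL
  for (it in seq_len(max_iter)) {
    asm <- assemble_internal(mesh, materials, u, tangent = TRUE,
                             free = freeD, cache = cache)
    if (is.null(asm$fint)) {
      return(list(ok = FALSE, u = u, iters = it, res = Inf,
                  inverted = TRUE))
    }
    r <- asm$fint - fext
    if (!is.null(mass_term)) r <- r + mass_term$force(u)
    rn <- sqrt(sum(r[freeD]^2))
    if (is.null(ref)) {
      ref <- max(sqrt(sum(fext[freeD]^2)), rn, atol)
    }
    if (rn <= rtol * ref + atol) {
      return(list(ok = TRUE, u = u, iters = it, res = rn,
                  energy = asm$energy, fint = asm$fint, inverted = FALSE))
    }
    K <- asm$K
    if (!is.null(mass_term)) {
      K <- K + Matrix::Diagonal(x = mass_term$Kdiag[freeD])
    }
    # the elastic + mass tangent is symmetric positive definite near a
    # minimum: try sparse Cholesky first, fall back to LU
    du <- tryCatch(
      as.numeric(Matrix::solve(Matrix::forceSymmetric(K), -r[freeD])),
      error = function(e) tryCatch(
        as.numeric(Matrix::solve(K, -r[freeD])),
        error = function(e) NULL))
    if (is.null(du) || any(!is.finite(du))) {
      return(list(ok = FALSE, u = u, iters = it, res = rn,
                  inverted = FALSE))
    }
    u[freeD] <- u[freeD] + du
  }
  list(ok = FALSE, u = u, iters = max_iter, res = rn, inverted = FALSE)
}

#' Quasi-static gravity loading
#'
#' Solves for the equilibrium configuration under gravity by incremental
#' load stepping with a full Newton--Raphson iteration at every
#' increment.  Convergence requires the free-DOF residual norm to fall
#' below `rtol` times the external force norm.  Non-converged increments
#' are bisected automatically (up to `max_cuts` halvings).
#'
#' @param mesh a `labelled_tet_mesh`.
#' @param materials named list of [constitutive_model()]s.
#' @param bcs a [boundary_conditions()] object.
#' @param load_steps initial number of equal gravity increments.
#' @param rtol relative residual tolerance (default 1e-6).
#' @param max_iter Newton iterations per increment (default 25).
#' @param max_cuts maximum step bisections (default 4).
#' @param u0 optional starting displacement (default zero).
#' @param store_stress keep per-element von Mises stress in the result?
#' @param cache optional assembly-pattern cache environment (created
#'   internally when `NULL`; pass one to share across repeated solves on
#'   the same mesh).
#' @return A `simulation_result` with a single frame: fields
#'   `nodal_displacement` (3n x 1), `element_von_mises` (m x 1, kPa),
#'   `energy` and the Newton `convergence_log`.
#' @export
solve_static <- function(mesh, materials, bcs, load_steps = 5,
                         rtol = 1e-6, max_iter = 25, max_cuts = 4,
                         u0 = NULL, store_stress = TRUE, cache = NULL) {
  stopifnot(inherits(bcs, "boundary_conditions"))
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  plan <- dof_plan(mesh, bcs, traj = NULL)
  fgrav <- gravity_force(mesh, materials, bcs$gravity,
                         bcs$gravity_components)
  n3 <- 3 * nrow(mesh$nodes)
  u <- if (is.null(u0)) numeric(n3) else u0
  uP_full <- plan$value_at(0)   # nonzero for displacement-controlled BCs
  log <- list()
  lambda <- 0; dl <- 1 / load_steps; cuts <- 0
  while (lambda < 1 - 1e-12) {
    dl <- min(dl, 1 - lambda)
    ns <- newton_solve(mesh, materials, u, (lambda + dl) * fgrav, plan,
                       (lambda + dl) * uP_full,
                       rtol = rtol, max_iter = max_iter, cache = cache)
    if (!ns$ok) {
      cuts <- cuts + 1
      if (cuts > max_cuts) {
        stop("static solve did not converge (load factor ",
             signif(lambda, 4), ", last residual ", signif(ns$res, 4), ")")
      }
      dl <- dl / 2
      next
    }
    lambda <- lambda + dl
    u <- ns$u
    log[[length(log) + 1]] <- data.frame(step = length(log) + 1,
                                         lambda = lambda,
                                         iterations = ns$iters,
                                         residual = ns$res)
  }
  vm <- NULL
  if (store_stress) {
    asm <- assemble_internal(mesh, materials, u, tangent = FALSE,
                             stress = TRUE)
    vm <- matrix(asm$vm, ncol = 1)
  }
  react <- numeric(n3)
  asm0 <- assemble_internal(mesh, materials, u, tangent = FALSE)
  react[plan$prescribed] <- (asm0$fint - fgrav)[plan$prescribed]
  new_simulation_result(times = 0, U = matrix(u, ncol = 1),
                        vm = vm,
                        energy = data.frame(time = 0, SE = asm0$energy,
                                            KE = 0, Wext = NA_real_),
                        convergence = do.call(rbind, log),
                        reactions = matrix(react, ncol = 1))
}

#' Implicit transient dynamics with prescribed torso motion
#'
#' Newmark time integration (average acceleration, `gamma = 0.5`,
#' `beta = 0.25`) with a full Newton--Raphson solve per step.  The driven
#' node set follows the trajectory in X and Y (Z pinned); gravity acts
#' throughout.  The initial state is the static gravity equilibrium
#' (computed internally when `static` is not supplied).  Non-converged
#' steps are bisected in time (up to 4 halvings) and recombined.
#'
#' @inheritParams solve_static
#' @param trajectory a [trajectory()] giving the driven motion; its span
#'   must cover `n_steps * dt`.  The trajectory is applied relative to
#'   its first sample.
#' @param dt time step in s (default 0.005).
#' @param n_steps number of steps (default 600, i.e. 3 s).
#' @param static optional `simulation_result` from [solve_static()] used
#'   as the initial condition.
#' @param newmark `c(gamma, beta)` Newmark parameters.
#' @param rayleigh_alpha mass-proportional damping coefficient (1/s);
#'   zero by default (no damping).
#' @param store_stress keep the per-element von Mises history?
#' @return A `simulation_result` with `length(times) == n_steps + 1`
#'   frames: displacement/velocity/acceleration histories (3n x frames),
#'   von Mises history (m x frames, kPa), an `energy` data frame (KE,
#'   SE, accumulated external work `Wext`) and the Newton
#'   `convergence_log`.
#' @export
solve_dynamic <- function(mesh, materials, bcs, trajectory,
                          dt = 0.005, n_steps = 600,
                          static = NULL, newmark = c(0.5, 0.25),
                          rayleigh_alpha = 0, rtol = 1e-6, max_iter = 25,
                          store_stress = TRUE) {
  stopifnot(inherits(bcs, "boundary_conditions"),
            inherits(trajectory, "trajectory"))
  if (max(trajectory$times) + 1e-9 < n_steps * dt) {
    stop("trajectory duration is shorter than n_steps * dt")
  }
  gamma <- newmark[1]; beta <- newmark[2]
  cache <- new.env(parent = emptyenv())
  plan <- dof_plan(mesh, bcs, traj = trajectory)
  fgrav <- gravity_force(mesh, materials, bcs$gravity,
                         bcs$gravity_components)
  Mv <- lumped_mass(mesh, materials)
  n3 <- 3 * nrow(mesh$nodes)
  if (is.null(static)) {
    static <- solve_static(mesh, materials, bcs, store_stress = FALSE)
  }
  u <- static$nodal_displacement[, 1]
  v <- numeric(n3); a <- numeric(n3)
  # driven nodes start with the trajectory's initial velocity
  h <- min(dt, 1 / trajectory$sample_rate)
  vP0 <- (plan$value_at(h) - plan$value_at(0)) / h
  v[plan$prescribed] <- vP0

  nf <- n_steps + 1
  U <- matrix(0, n3, nf); V <- matrix(0, n3, nf); A <- matrix(0, n3, nf)
  U[, 1] <- u; V[, 1] <- v
  vm <- NULL
  if (store_stress) {
    asm <- assemble_internal(mesh, materials, u, tangent = FALSE,
                             stress = TRUE)
    vm <- matrix(0, length(asm$vm), nf)
    vm[, 1] <- asm$vm
    SE0 <- asm$energy
  } else {
    SE0 <- assemble_internal(mesh, materials, u, tangent = FALSE)$energy
  }
  energy <- data.frame(time = numeric(nf), KE = numeric(nf),
                       SE = numeric(nf), Wext = numeric(nf))
  energy$time <- (0:n_steps) * dt
  energy$KE[1] <- 0.5 * sum(Mv * v^2)
  energy$SE[1] <- SE0
  Wext <- 0
  react_prev <- {
    r0 <- assemble_internal(mesh, materials, u, tangent = FALSE)$fint -
      fgrav
    r0[plan$prescribed]
  }
  fext_free <- fgrav
  log <- vector("list", n_steps)

  step_once <- function(u, v, a, t0, dtl) {
    # Newmark predictors for the step t0 -> t0 + dtl
    ut <- u + dtl * v + dtl^2 / 2 * (1 - 2 * beta) * a
    vt <- v + dtl * (1 - gamma) * a
    c1 <- 1 / (beta * dtl^2); c2 <- gamma / (beta * dtl)
    Kdiag <- Mv * c1 + rayleigh_alpha * Mv * c2
    force <- function(uu) {
      aa <- c1 * (uu - ut)
      vv <- vt + gamma * dtl * aa
      Mv * aa + rayleigh_alpha * Mv * vv
    }
    uP <- plan$value_at(t0 + dtl)
    ns <- newton_solve(mesh, materials, u, fgrav, plan, uP,
                       rtol = rtol, max_iter = max_iter,
                       mass_term = list(force = force, Kdiag = Kdiag),
                       cache = cache)
    if (!ns$ok) return(NULL)
    anew <- c1 * (ns$u - ut)
    vnew <- vt + gamma * dtl * anew
    list(u = ns$u, v = vnew, a = anew, iters = ns$iters, res = ns$res,
         fint = ns$fint, energy = ns$energy)
  }

  for (s in seq_len(n_steps)) {
    t0 <- (s - 1) * dt
    res <- step_once(u, v, a, t0, dt)
    iters <- if (!is.null(res)) res$iters else NA
    if (is.null(res)) {
      # bisect the step in time, up to 4 halvings
      done <- FALSE
      for (cut in 1:4) {
        nsub <- 2^cut
        uu <- u; vv <- v; aa <- a; okall <- TRUE; itt <- 0
        for (k in seq_len(nsub)) {
          r <- step_once(uu, vv, aa, t0 + (k - 1) * dt / nsub, dt / nsub)
          if (is.null(r)) { okall <- FALSE; break }
          uu <- r$u; vv <- r$v; aa <- r$a; itt <- itt + r$iters
        }
        if (okall) {
          res <- r; res$u <- uu; res$v <- vv; res$a <- aa
          iters <- itt; done <- TRUE; break
        }
      }
      if (!done) stop("dynamic step ", s, " did not converge after 4 ",
                      "time-step bisections")
    }
    du <- res$u - u
    u <- res$u; v <- res$v; a <- res$a
    U[, s + 1] <- u; V[, s + 1] <- v; A[, s + 1] <- a
    # external work: gravity on all DOFs + reactions on prescribed DOFs
    react <- (res$fint + Mv * a + rayleigh_alpha * Mv * v - fgrav)
    react <- react[plan$prescribed]
    Wext <- Wext + sum(fext_free * du) +
      0.5 * sum((react + react_prev) * du[plan$prescribed])
    react_prev <- react
    energy$KE[s + 1] <- 0.5 * sum(Mv * v^2)
    energy$SE[s + 1] <- res$energy
    energy$Wext[s + 1] <- Wext
    if (store_stress) {
      asm <- assemble_internal(mesh, materials, u, tangent = FALSE,
                               stress = TRUE)
      vm[, s + 1] <- asm$vm
    }
    log[[s]] <- data.frame(step = s, iterations = iters, residual = res$res)
  }
  new_simulation_result(times = energy$time, U = U, V = V, A = A,
                        vm = vm, energy = energy,
                        convergence = do.call(rbind, log))
}
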